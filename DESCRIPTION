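Package: covpower
Title: Covariation Power Analysis for Conserved RNA Secondary Structure
Version: 0.1.0
Authors@R: person("covpower", "developers", email = "covpower@example.org",
    role = c("aut", "cre"))
Description: Tests whether an RNA multiple sequence alignment shows
    statistically significant pairwise covariation in support of a proposed
    consensus secondary structure, against a phylogeny-aware null model, and
    estimates the statistical power to have detected such covariation from
    the inferred number of substitutions per basepair. Lack of covariation in
    a high-power alignment is evidence against a conserved structure; in a
    low-power alignment it is inconclusive. Includes Stockholm/WUSS input and
    output, Fitch parsimony substitution counting, G-test/mutual-information
    covariation statistics with empirical E-values, a basepair-aware
    evolutionary alignment simulator used to calibrate the method, and
    fitting of the empirical power(s) curve.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
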