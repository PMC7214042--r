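make_sigmoid_bins <- function(smax = 60, n = 30) {
  s <- 0:smax
  data.frame(s = s, fraction = round(1 / (1 + exp(-(s - 12) / 4)), 4) *
               (s > 0), n = rep(n, length(s)))
}

test_that("bin_pairs computes per-bin significance fractions", {
  b <- bin_pairs(s = c(3, 3, 3, 3, 7), evalue = c(.01, .2, .2, .2, .001))
  expect_equal(b$fraction[b$s == 3], 0.25)
  expect_equal(b$fraction[b$s == 7], 1.0)
  expect_equal(b$n, c(4, 1))
  # equal-size binning agrees with integer binning on balanced input
  set.seed(2)
  s <- rep(0:69, each = 10)
  ev <- ifelse(stats::runif(700) < pmin(s / 50, 1), 0.01, 0.5)
  bi <- bin_pairs(s, ev)
  be <- bin_pairs(s, ev, equal_size = TRUE, n_bins = 70)
  expect_equal(nrow(be), 70L)
  expect_lt(mean(abs(bi$fraction - be$fraction[order(be$s)])), 0.2)
  expect_error(bin_pairs(numeric(0), numeric(0)), class = "covpower_stat_error")
})

test_that("fit_power_curve recovers monotone input and applies the filter", {
  bins <- make_sigmoid_bins()
  curve <- fit_power_curve(bins)
  expect_s3_class(curve, "power_curve")
  at <- power_of(curve, bins$s)
  expect_lt(max(abs(at - bins$fraction)), 0.05)
  # filtering rule: noisy low-power bins beyond s = 150 are dropped
  noisy <- rbind(bins, data.frame(s = c(160, 170, 180), fraction = c(0.2, 0.95, 0.1),
                                  n = c(1, 2, 1)))
  c2 <- fit_power_curve(noisy)
  expect_false(any(c2$knots$s %in% c(160, 180)))
  expect_true(170 %in% c2$knots$s)
  # continuity at the filter boundary on smooth input
  smooth <- data.frame(s = seq(0, 300, by = 2),
                       fraction = pmin(seq(0, 300, by = 2) / 120, 1), n = 20)
  c3 <- fit_power_curve(smooth)
  expect_lt(abs(power_of(c3, 149) - power_of(c3, 151)), 0.1)
  expect_error(fit_power_curve(bins[1:3, ]), class = "covpower_stat_error")
})

test_that("alternative fit modes stay within [0,1] and track the data", {
  bins <- make_sigmoid_bins()
  for (fm in c("polynomial", "exponential")) {
    cv <- fit_power_curve(bins, fit_mode = fm)
    g <- power_of(cv, seq(0, 60, by = 0.5))
    expect_true(all(g >= 0 & g <= 1))
    expect_equal(power_of(cv, 0), 0)
  }
  # the one-parameter exponential is a worse fit than isotonic on sigmoid data
  ci <- fit_power_curve(bins, fit_mode = "isotonic")
  ce <- fit_power_curve(bins, fit_mode = "exponential")
  sse <- function(cv) sum((power_of(cv, bins$s) - bins$fraction)^2)
  expect_lt(sse(ci), sse(ce))
})

test_that("power_of clamps, interpolates and is monotone for isotonic fits", {
  curve <- fit_power_curve(make_sigmoid_bins())
  expect_identical(power_of(curve, 0), 0)
  expect_identical(power_of(curve, 227), 1)
  expect_identical(power_of(curve, 1000), 1)
  expect_error(power_of(curve, -1), class = "covpower_stat_error")
  # fractional s: linear interpolation between knots
  p10 <- power_of(curve, 10); p11 <- power_of(curve, 11)
  expect_equal(power_of(curve, 10.5), (p10 + p11) / 2, tolerance = 1e-9)
  g <- power_of(curve, seq(0, 300, by = 1))
  expect_true(all(diff(g) >= -1e-12))
  # curve file round-trip
  path <- withr::local_tempfile(fileext = ".tsv")
  write_power_curve(curve, path)
  back <- read_power_curve(path)
  expect_equal(back$clamp_hi, curve$clamp_hi)
  expect_equal(power_of(back, c(0, 5.5, 20, 300)),
               power_of(curve, c(0, 5.5, 20, 300)), tolerance = 1e-5)
})

test_that("power_report aggregates per-basepair power exactly", {
  curve <- structure(list(knots = data.frame(s = c(0, 1, 2, 3, 4),
                                             power = c(0, .1, .2, .3, .4)),
                          fit_mode = "isotonic", clamp_hi = 226,
                          domain_lo = 0), class = "power_curve")
  res <- data.frame(left_pos = 1:5, right_pos = 11:15,
                    in_structure = c(TRUE, TRUE, TRUE, TRUE, FALSE),
                    stat = 1, pvalue = .5, evalue = c(.01, .5, .5, .5, .5),
                    significant = c(TRUE, FALSE, FALSE, FALSE, FALSE),
                    s_ij = c(1, 2, 3, 4, 4), power = NA_real_,
                    untestable = FALSE, n_tests = 4)
  rep <- power_report(res, curve, evalue_threshold = 0.05)
  expect_equal(rep$B, 4L)
  expect_equal(rep$cov_bp_exp, 1.0)
  expect_equal(rep$alignment_power, 0.25)
  expect_equal(rep$observed, 1L)
  expect_equal(rep$cov_bp_exp, sum(rep$per_bp$power), tolerance = 1e-9)
  # all substitution counts zero -> zero power
  res0 <- res; res0$s_ij <- 0
  rep0 <- power_report(res0, curve)
  expect_equal(rep0$cov_bp_exp, 0)
  expect_equal(rep0$alignment_power, 0)
  # no basepairs -> undefined
  expect_error(power_report(res[!res$in_structure, ], curve),
               class = "covpower_stat_error")
})

test_that("classification threshold is strict at 10% power", {
  mk <- function(p) structure(list(alignment_power = p), class = "power_report")
  expect_equal(classify_alignment(mk(0.05)), "low_power")
  expect_equal(classify_alignment(mk(0.10)), "low_power")
  expect_equal(classify_alignment(mk(0.101)), "high_power")
  expect_equal(classify_alignment(mk(0.66)), "high_power")
})

test_that("the shipped default curve satisfies the curve invariants", {
  curve <- default_power_curve()
  g <- power_of(curve, seq(0, 300, by = 1))
  expect_true(all(g >= 0 & g <= 1))
  expect_identical(power_of(curve, 0), 0)
  expect_identical(power_of(curve, 227), 1)
  expect_true(all(diff(g) >= -1e-12))
})
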