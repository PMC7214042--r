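# The empirical power(s) curve: the probability that a basepair with s
# total substitutions reaches significant covariation support (E < 0.05),
# fitted from binned (s, E-value) data, and the alignment-level summaries
# built on it: cov-bp-exp = sum_b power(s_b) and alignment power =
# cov-bp-exp / B.

#' Bin basepairs by substitution count and score significance frequency
#'
#' @param s numeric vector of per-pair substitution counts.
#' @param evalue matching vector of E-values.
#' @param threshold significance threshold (default 0.05).
#' @param equal_size if `TRUE`, use `n_bins` equal-occupancy bins ranked by
#'   `s` (a plotting convention) instead of integer-s bins (the fitting
#'   convention); bin `s` is then the mean `s` of its members.
#' @param n_bins number of equal-size bins (default 70).
#' @return data.frame with `s`, `fraction` (significant/total), `n`;
#'   integer-s bins with no pairs are omitted.
#' @export
bin_pairs <- function(s, evalue, threshold = 0.05, equal_size = FALSE,
                      n_bins = 70) {
  if (!length(s)) cp_stat_error("no pairs to bin")
  sig <- evalue < threshold
  if (!equal_size) {
    key <- round(s)
    agg <- stats::aggregate(cbind(sig = sig, n = 1, smean = s),
                            by = list(s = key), FUN = sum)
    out <- data.frame(s = agg$s, fraction = agg$sig / agg$n, n = agg$n)
  } else {
    o <- order(s)
    grp <- ceiling(seq_along(o) / (length(o) / n_bins))
    out <- do.call(rbind, lapply(split(o, grp), function(ix) {
      data.frame(s = mean(s[ix]), fraction = mean(sig[ix]), n = length(ix))
    }))
    rownames(out) <- NULL
  }
  out[order(out$s), ]
}

# weighted pool-adjacent-violators (increasing)
pava_increasing <- function(y, w) {
  n <- length(y)
  ybar <- numeric(n); wt <- numeric(n); size <- integer(n)
  nb <- 0L
  for (i in seq_len(n)) {
    nb <- nb + 1L
    ybar[nb] <- y[i]; wt[nb] <- w[i]; size[nb] <- 1L
    while (nb > 1L && ybar[nb - 1L] > ybar[nb]) {
      tw <- wt[nb - 1L] + wt[nb]
      ybar[nb - 1L] <- (wt[nb - 1L] * ybar[nb - 1L] + wt[nb] * ybar[nb]) / tw
      wt[nb - 1L] <- tw
      size[nb - 1L] <- size[nb - 1L] + size[nb]
      nb <- nb - 1L
    }
  }
  rep.int(ybar[seq_len(nb)], size[seq_len(nb)])
}

#' Fit the empirical power(s) curve from binned data
#'
#' Applies the fitting filter (all bins with `s <= 150`; for `s > 150` only
#' bins with fraction >= 0.8, where sparse bins are noisy), then fits the
#' curve: weighted isotonic regression by default (monotone by
#' construction), or a weighted degree-10 least-squares polynomial forced
#' through the origin, or the single-parameter `1 - exp(-lambda s)` family
#' as a comparison mode. The result is clamped into \[0,1\], forced through
#' `power(0) = 0`, and set to 1 above `clamp_hi`.
#'
#' @param binned data.frame from [bin_pairs()] (`s`, `fraction`, `n`).
#' @param fit_mode `"isotonic"` (default), `"polynomial"` or `"exponential"`.
#' @param clamp_hi s value above which power is 1 (default 226).
#' @param degree polynomial degree (default 10).
#' @return an object of class `power_curve`: list with `knots` (ordered
#'   `s`/`power` data.frame), `fit_mode`, `clamp_hi`, `domain_lo`.
#' @export
fit_power_curve <- function(binned, fit_mode = c("isotonic", "polynomial",
                                                 "exponential"),
                            clamp_hi = 226, degree = 10) {
  fit_mode <- match.arg(fit_mode)
  b <- binned[order(binned$s), , drop = FALSE]
  keep <- b$s <= 150 | b$fraction >= 0.8
  b <- b[keep, , drop = FALSE]
  if (nrow(b) < 5L) cp_stat_error("fewer than 5 usable bins after filtering")
  w <- if (is.null(b$n)) rep(1, nrow(b)) else b$n
  if (fit_mode == "isotonic") {
    fitted <- pava_increasing(b$fraction, w)
    knots <- data.frame(s = b$s, power = pmin(pmax(fitted, 0), 1))
  } else if (fit_mode == "polynomial") {
    X <- outer(b$s, seq_len(degree), "^")
    fit <- stats::lm.wfit(X, b$fraction, w)
    grid <- sort(unique(c(b$s, seq(0, max(b$s), length.out = 200))))
    yhat <- outer(grid, seq_len(degree), "^") %*% fit$coefficients
    knots <- data.frame(s = grid, power = pmin(pmax(as.vector(yhat), 0), 1))
  } else {
    sse <- function(lam) sum(w * (b$fraction - (1 - exp(-lam * b$s)))^2)
    lam <- stats::optimize(sse, c(1e-6, 5))$minimum
    grid <- sort(unique(c(b$s, seq(0, max(b$s), length.out = 200))))
    knots <- data.frame(s = grid, power = 1 - exp(-lam * grid))
  }
  if (knots$s[1] == 0) knots$power[1] <- 0 else knots <- rbind(data.frame(s = 0, power = 0), knots)
  structure(list(knots = knots, fit_mode = fit_mode, clamp_hi = clamp_hi,
                 domain_lo = min(binned$s)),
            class = "power_curve")
}

#' Evaluate a power curve
#'
#' Linear interpolation between knots; exact clamps `power(0) = 0` and
#' `power(s) = 1` for `s > clamp_hi`. Fractional `s` is supported.
#'
#' @param curve a `power_curve`.
#' @param s nonnegative substitution count(s).
#' @return power value(s) in \[0, 1\].
#' @export
power_of <- function(curve, s) {
  stopifnot(inherits(curve, "power_curve"))
  if (any(s < 0)) cp_stat_error("s must be >= 0")
  p <- stats::approx(curve$knots$s, curve$knots$power, xout = s, rule = 2,
                     ties = "ordered")$y
  p[s == 0] <- 0
  p[s > curve$clamp_hi] <- 1
  pmin(pmax(p, 0), 1)
}

#' Per-basepair and alignment-level power report
#'
#' Restricts a covariation result table (two-set mode) to the proposed
#' basepairs, evaluates the power curve at each pair's substitution count,
#' and aggregates: `cov_bp_exp = sum_b power(s_b)` is the expected number of
#' basepairs with significant covariation support, `alignment_power =
#' cov_bp_exp / B` the expected fraction, `observed` the count actually
#' significant at the E-value threshold.
#'
#' @param results a `cov_results` table containing structure pairs
#'   (`in_structure`).
#' @param curve a `power_curve`.
#' @param evalue_threshold threshold used for the observed count (default:
#'   the one recorded in `results`, falling back to 0.05).
#' @return object of class `power_report`: list with `per_bp` (data.frame),
#'   `B`, `cov_bp_exp`, `alignment_power`, `observed`.
#' @export
power_report <- function(results, curve, evalue_threshold = NULL) {
  bp <- results[results$in_structure, , drop = FALSE]
  if (nrow(bp) == 0L) cp_stat_error("no proposed basepairs: alignment power undefined")
  if (is.null(evalue_threshold)) {
    evalue_threshold <- attr(results, "evalue_threshold")
    if (is.null(evalue_threshold)) evalue_threshold <- 0.05
  }
  pw <- power_of(curve, bp$s_ij)
  per_bp <- data.frame(left_pos = bp$left_pos, right_pos = bp$right_pos,
                       s = bp$s_ij, power = pw, evalue = bp$evalue,
                       significant = bp$evalue < evalue_threshold & !bp$untestable)
  structure(list(per_bp = per_bp, B = nrow(per_bp),
                 cov_bp_exp = sum(pw), alignment_power = mean(pw),
                 observed = sum(per_bp$significant),
                 evalue_threshold = evalue_threshold),
            class = "power_report")
}

#' Classify an alignment as low- or high-power
#'
#' High power means `alignment_power > power_threshold` (strict), i.e. the
#' alignment carries enough variation that absence of covariation is
#' informative.
#'
#' @param report a `power_report`.
#' @param power_threshold default 0.10.
#' @return `"high_power"` or `"low_power"`.
#' @export
classify_alignment <- function(report, power_threshold = 0.10) {
  stopifnot(inherits(report, "power_report"))
  if (report$alignment_power > power_threshold) "high_power" else "low_power"
}

#' @export
print.power_report <- function(x, ...) {
  cat(sprintf("total bp: %d | expected covary: %.2f | observed covary: %d | alignment power: %.1f%% | %s\n",
              x$B, x$cov_bp_exp, x$observed, 100 * x$alignment_power,
              classify_alignment(x)))
  invisible(x)
}

#' Write a power curve to a two-column text file
#'
#' @param curve a `power_curve`.
#' @param path output path; a header comment records fit metadata.
#' @return invisibly, `path`.
#' @export
write_power_curve <- function(curve, path) {
  hdr <- sprintf("# covpower power curve; fit_mode=%s clamp_hi=%g domain_lo=%g",
                 curve$fit_mode, curve$clamp_hi, curve$domain_lo)
  lines <- c(hdr, "# s power",
             sprintf("%.6g %.6g", curve$knots$s, curve$knots$power))
  writeLines(lines, path)
  invisible(path)
}

#' Read a power curve written by [write_power_curve()]
#'
#' @param path curve file path.
#' @return a `power_curve`.
#' @export
read_power_curve <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[grepl("^#", lines)][1]
  fit_mode <- sub(".*fit_mode=(\\S+).*", "\\1", hdr)
  clamp_hi <- as.numeric(sub(".*clamp_hi=(\\S+).*", "\\1", hdr))
  domain_lo <- as.numeric(sub(".*domain_lo=(\\S+).*", "\\1", hdr))
  if (is.na(clamp_hi)) clamp_hi <- 226
  dat <- utils::read.table(text = lines[!grepl("^#", lines)],
                           col.names = c("s", "power"))
  structure(list(knots = dat, fit_mode = fit_mode, clamp_hi = clamp_hi,
                 domain_lo = if (is.na(domain_lo)) min(dat$s) else domain_lo),
            class = "power_curve")
}

#' The default power curve shipped with the package
#'
#' Fitted on in-repo simulated structural alignments (synthetic data; see
#' the methods vignette), not on the reference implementation's table.
#'
#' @return a `power_curve`.
#' @export
default_power_curve <- function() {
  read_power_curve(system.file("extdata", "power_curve_synthetic_default.tsv",
                               package = "covpower", mustWork = TRUE))
}
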