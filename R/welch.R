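#' Welch's t-test from summary statistics
#'
#' Two-sample location test without the equal-variance assumption:
#' \code{t = (m1 - m2) / sqrt(sd1^2/n1 + sd2^2/n2)} with
#' Welch--Satterthwaite degrees of freedom (not rounded) and a two-sided p
#' from the t distribution.
#'
#' @param mean1,sd1,n1 Summary statistics of group 1 (sd >= 0, n >= 2).
#' @param mean2,sd2,n2 Summary statistics of group 2.
#' @return A list of class \code{"welch_result"}: \code{t_statistic},
#'   \code{df}, \code{p_two_sided}, \code{mean_difference}.
#' @details When both SDs are zero and the means are equal the test is
#'   defined as t = 0, p = 1; when both SDs are zero with unequal means the
#'   statistic is undefined and an error is raised.
#' @export
welch_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  for (v in list(c(sd1, 1), c(sd2, 1)))
    if (v[1] < 0) stop("standard deviations must be non-negative")
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  diff <- mean1 - mean2
  v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
  if (sd1 == 0 && sd2 == 0) {
    if (diff == 0)
      return(new_welch_result(0, n1 + n2 - 2, 1, 0))
    stop("both SDs are zero with unequal means: t is undefined")
  }
  se <- sqrt(v1 + v2)
  t <- diff / se
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  p <- 2 * pt(abs(t), df, lower.tail = FALSE)
  new_welch_result(t, df, p, diff)
}

new_welch_result <- function(t, df, p, diff) {
  structure(list(t_statistic = t, df = df, p_two_sided = p,
                 mean_difference = diff), class = "welch_result")
}

#' @export
print.welch_result <- function(x, ...) {
  cat(sprintf("Welch's t-test: t = %.4g, df = %.4g, p = %.4g (difference %.4g)\n",
              x$t_statistic, x$df, x$p_two_sided, x$mean_difference))
  invisible(x)
}

#' Welch's t-test from raw samples
#'
#' Computes group summaries and delegates to [welch_from_summary()].
#'
#' @param groupA,groupB Numeric vectors, each of length >= 2.
#' @return A \code{"welch_result"}.
#' @export
welch_from_samples <- function(groupA, groupB) {
  if (length(groupA) < 2 || length(groupB) < 2)
    stop("each group needs n >= 2")
  welch_from_summary(mean(groupA), sd(groupA), length(groupA),
                     mean(groupB), sd(groupB), length(groupB))
}

#' Sample size for a two-sample t-test
#'
#' Smallest per-group n such that a two-sample t-test at level \code{alpha}
#' attains at least the requested power against a standardized mean
#' difference \code{effect_size_d}, evaluated with the noncentral t
#' distribution (noncentrality \code{d * sqrt(n / 2)}, df \code{2n - 2}).
#'
#' @param effect_size_d Cohen's d (> 0).
#' @param alpha Significance level in (0, 1).
#' @param power Target power in (0, 1).
#' @param two_sided Two-sided test (default) or one-sided.
#' @return Integer n per group (>= 2).
#' @export
sample_size_two_sample_t <- function(effect_size_d, alpha = 0.05,
                                     power = 0.8, two_sided = TRUE) {
  if (!is_scalar_num(effect_size_d) || effect_size_d <= 0)
    stop("effect_size_d must be > 0")
  stop_if_not_scalar(alpha, "alpha", lower = 0, upper = 1,
                     strict_lower = TRUE)
  if (alpha >= 1) stop("alpha must lie in (0, 1)")
  stop_if_not_scalar(power, "power", lower = 0, upper = 1,
                     strict_lower = TRUE)
  if (power >= 1) stop("power must lie in (0, 1)")
  # normal-approximation start, then exact noncentral-t search
  za <- qnorm(1 - if (two_sided) alpha / 2 else alpha)
  zb <- qnorm(power)
  n <- max(2, floor(2 * ((za + zb) / effect_size_d)^2) - 2)
  while (t_test_power(effect_size_d, n, alpha, two_sided) < power) n <- n + 1
  while (n > 2 &&
         t_test_power(effect_size_d, n - 1, alpha, two_sided) >= power)
    n <- n - 1
  as.integer(n)
}

#' @rdname sample_size_two_sample_t
#' @param n Per-group sample size (>= 2).
#' @return \code{t_test_power}: attained power at the given n.
#' @export
t_test_power <- function(effect_size_d, n, alpha = 0.05, two_sided = TRUE) {
  df <- 2 * n - 2
  ncp <- effect_size_d * sqrt(n / 2)
  if (two_sided) {
    crit <- qt(1 - alpha / 2, df)
    pt(crit, df, ncp = ncp, lower.tail = FALSE) +
      pt(-crit, df, ncp = ncp)
  } else {
    pt(qt(1 - alpha, df), df, ncp = ncp, lower.tail = FALSE)
  }
}

#' Welch tests across probe conditions
#'
#' Runs one Welch test per probe (e.g. per FITC-dextran molecular weight)
#' and optionally applies a Holm adjustment to the family of p values.  No
#' adjustment is applied by default.
#'
#' @param groupsA,groupsB Named lists of numeric vectors (same probe names).
#' @param adjust \code{"none"} (default) or \code{"holm"}.
#' @return Data.frame with \code{probe_label}, \code{t_statistic},
#'   \code{df}, \code{p_two_sided}, \code{p_adjusted}.
#' @export
welch_by_probe <- function(groupsA, groupsB, adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  probes <- names(groupsA)
  if (is.null(probes) || !setequal(probes, names(groupsB)))
    stop("'groupsA' and 'groupsB' must be named lists over the same probes")
  res <- lapply(probes, function(p)
    welch_from_samples(groupsA[[p]], groupsB[[p]]))
  p_raw <- vapply(res, `[[`, numeric(1), "p_two_sided")
  data.frame(
    probe_label = probes,
    t_statistic = vapply(res, `[[`, numeric(1), "t_statistic"),
    df = vapply(res, `[[`, numeric(1), "df"),
    p_two_sided = p_raw,
    p_adjusted = if (adjust == "holm") stats::p.adjust(p_raw, "holm")
                 else p_raw)
}
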