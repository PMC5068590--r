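#' Sample size for detecting a Pearson correlation
#'
#' Fisher z-transformation approximation: with `z_r = atanh(r)` the
#' required sample size is
#' `n = ((z_{1-alpha(/2)} + z_{power}) / atanh(r))^2 + 3`,
#' rounded to the nearest integer (the `+3` is the small-sample correction
#' of the Fisher variance `1/(n-3)`). One-sided by default.
#'
#' @param r target correlation, nonzero, in (-1, 1).
#' @param alpha significance level (default 0.05).
#' @param power target power (default 0.85).
#' @param sided `"one"` (default) or `"two"`.
#' @return Minimum sample size, an integer.
#' @export
corr_sample_size <- function(r, alpha = 0.05, power = 0.85,
                             sided = c("one", "two")) {
  sided <- match.arg(sided)
  stopifnot(alpha > 0, alpha < 1, power > 0, power < 1, abs(r) < 1)
  if (r == 0) stop("r = 0 requires an infinite sample", call. = FALSE)
  za <- qnorm(1 - alpha / ifelse(sided == "two", 2, 1))
  zb <- qnorm(power)
  as.integer(round(((za + zb) / atanh(abs(r)))^2 + 3))
}

#' Power to detect a Pearson correlation at a given sample size
#'
#' Normal approximation on the Fisher z scale:
#' `power = Phi(sqrt(n - 3) * atanh(|r|) - z_{1-alpha(/2)})`.
#'
#' @param r true correlation, in (-1, 1).
#' @param n sample size, at least 4.
#' @param alpha significance level (default 0.05).
#' @param sided `"one"` (default) or `"two"`.
#' @return Achieved power in (0, 1).
#' @export
corr_power <- function(r, n, alpha = 0.05, sided = c("one", "two")) {
  sided <- match.arg(sided)
  stopifnot(alpha > 0, alpha < 1, abs(r) < 1)
  if (n < 4) stop("n must be at least 4", call. = FALSE)
  za <- qnorm(1 - alpha / ifelse(sided == "two", 2, 1))
  pnorm(sqrt(n - 3) * atanh(abs(r)) - za)
}
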