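# Nonparametric power / sample-size calculations used to justify the
# group sizes.

#' Sample size for detecting a Spearman correlation
#'
#' Fisher-z closed form:
#' `n = ceil( ((z_{1-alpha/2} + z_{power}) / atanh(r))^2 + 3 )`.
#'
#' @param r Target correlation, `0 < |r| < 1`.
#' @param alpha Two-sided significance level.
#' @param power Target power.
#' @return Required number of subjects.
#' @examples
#' sample_size_spearman(0.6, 0.05, 0.8)  # 20
#' @export
sample_size_spearman <- function(r, alpha = 0.05, power = 0.8) {
  if (abs(r) >= 1 || abs(r) <= 0) stop("need 0 < |r| < 1")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1) {
    stop("alpha and power must lie in (0, 1)")
  }
  z_a <- stats::qnorm(1 - alpha / 2)
  z_b <- stats::qnorm(power)
  ceiling(((z_a + z_b) / atanh(abs(r)))^2 + 3)
}

#' Per-group sample size for the Mann-Whitney test
#'
#' Normal-theory two-sample size
#' `n_t = 2 ((z_{1-alpha/2} + z_{power}) / d)^2` for a standardized shift
#' `d`, inflated by the asymptotic relative efficiency of the rank test:
#' `n = ceil(n_t / are)`. The default ARE 0.864 is the worst-case
#' efficiency of the Mann-Whitney test against the t-test; `pi/3` (0.955)
#' is the normal-theory value.
#'
#' @param d Cohen's d effect size, > 0.
#' @param alpha Two-sided significance level.
#' @param power Target power.
#' @param are Asymptotic relative efficiency factor (default 0.864).
#' @return Required subjects per group.
#' @examples
#' sample_size_mann_whitney(0.9, 0.1, 0.8)  # 18
#' @export
sample_size_mann_whitney <- function(d, alpha = 0.1, power = 0.8,
                                     are = 0.864) {
  if (d <= 0) stop("effect size must be positive")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1) {
    stop("alpha and power must lie in (0, 1)")
  }
  z_a <- stats::qnorm(1 - alpha / 2)
  z_b <- stats::qnorm(power)
  n_t <- 2 * ((z_a + z_b) / d)^2
  ceiling(n_t / are)
}

#' Simulate the power of the Mann-Whitney test under a Gaussian shift
#'
#' @param n Per-group sample size.
#' @param d Standardized mean shift.
#' @param alpha Two-sided level.
#' @param reps Simulation replicates.
#' @param seed Integer seed.
#' @return Rejection fraction.
#' @export
simulate_mw_power <- function(n, d, alpha = 0.1, reps = 2000, seed = 1) {
  with_seed(seed, {
    rej <- vapply(seq_len(reps), function(i) {
      x <- stats::rnorm(n)
      y <- stats::rnorm(n, mean = d)
      mann_whitney_u(x, y)$p_value < alpha
    }, logical(1))
    mean(rej)
  })
}
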