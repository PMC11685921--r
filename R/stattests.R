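#' Paired TOST equivalence test
#'
#' Two one-sided t tests on paired differences `d = x - y` against
#' standardized equivalence bounds `+/- bound_d * sd(d)` (Cohen's dz bound;
#' default 0.25, the effect size of interest used for the drifter
#' validation). Equivalence is declared when the larger of the two
#' one-sided p-values is below `alpha`. The 90 percent confidence interval
#' of the mean difference is reported (the conventional 1 - 2*alpha
#' interval for TOST at alpha = 0.05).
#'
#' @param x,y Paired numeric vectors of equal length (n >= 3).
#' @param bound_d Standardized equivalence bound (> 0, default 0.25).
#' @param alpha Significance level (default 0.05).
#' @param raw_bound Optional raw-unit bound overriding the standardized one.
#' @return A list of class `tost_result`: `t_lower`, `t_upper`, `df`, `p`,
#'   `mean_diff`, `ci90`, `bound`, `equivalent`.
#' @export
tost_paired <- function(x, y, bound_d = 0.25, alpha = 0.05, raw_bound = NULL) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (is.null(raw_bound) && bound_d <= 0) stop("tost_paired: bound_d must be > 0")
  d <- x - y
  n <- length(d)
  sdd <- stats::sd(d)
  if (sdd == 0) stop("tost_paired: zero variance in differences")
  bound <- if (is.null(raw_bound)) bound_d * sdd else raw_bound
  se <- sdd / sqrt(n)
  df <- n - 1
  m <- mean(d)
  t_lower <- (m + bound) / se      # H0: mu <= -bound, reject for large t
  t_upper <- (m - bound) / se      # H0: mu >= +bound, reject for small t
  p_lower <- stats::pt(t_lower, df, lower.tail = FALSE)
  p_upper <- stats::pt(t_upper, df, lower.tail = TRUE)
  p <- max(p_lower, p_upper)
  ci <- m + c(-1, 1) * stats::qt(1 - alpha, df) * se
  structure(list(t_lower = t_lower, t_upper = t_upper, df = df, p = p,
                 mean_diff = m, ci90 = ci, bound = bound,
                 equivalent = p < alpha),
            class = "tost_result")
}

#' Wilcoxon rank-sum test with normal approximation
#'
#' Rank-sum (Mann-Whitney) test with tie correction and optional continuity
#' correction; reports the Z statistic with the sign convention that Z < 0
#' when the first group's ranks are lower.
#'
#' @param x,y Numeric vectors (non-empty).
#' @param continuity Apply the continuity correction (default TRUE).
#' @return List with `z`, `p` (two-sided), `u` (Mann-Whitney U of `x`),
#'   `degenerate` (all values tied).
#' @export
wilcoxon_z <- function(x, y, continuity = TRUE) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sig2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  if (sig2 <= 0)
    return(list(z = NA_real_, p = NA_real_, u = u, degenerate = TRUE))
  cc <- if (continuity) 0.5 * sign(u - mu) else 0
  z <- (u - mu - cc) / sqrt(sig2)
  list(z = z, p = 2 * stats::pnorm(-abs(z)), u = u, degenerate = FALSE)
}

#' Welch's two-sample t test
#'
#' Welch statistic with Satterthwaite degrees of freedom and two-sided
#' p-value.
#'
#' @param x,y Numeric vectors with n >= 2 each.
#' @return List with `t`, `df`, `p`, `mean_diff`.
#' @export
welch_t <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  v1 <- stats::var(x) / length(x)
  v2 <- stats::var(y) / length(y)
  if (v1 + v2 == 0) stop("welch_t: zero variance in both groups")
  t <- (mean(x) - mean(y)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (length(x) - 1) + v2^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df),
       mean_diff = mean(x) - mean(y))
}
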