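#' Pooled-variance two-sample Student t-test
#'
#' Two-tailed p-value of the classical equal-variance two-sample t statistic
#' with `n_x + n_y - 2` degrees of freedom. Degenerate inputs follow the
#' screening convention: zero pooled variance with equal means gives p = 1
#' (no evidence of a difference), zero pooled variance with different means
#' gives p = 0 (an infinite t).
#'
#' @param x,y numeric vectors, one per group; each needs at least 2 finite
#'   values.
#' @return the two-tailed p-value.
#' @export
#' @examples
#' student_t_test(c(1, 2, 3), c(4, 5, 6))   # ~ 0.0214
student_t_test <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2)
    stop("insufficient data: each group needs at least 2 finite values")
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  delta <- mean(x) - mean(y)
  if (sp2 == 0) return(if (delta == 0) 1 else 0)
  tstat <- delta / sqrt(sp2 * (1 / nx + 1 / ny))
  2 * stats::pt(-abs(tstat), df = nx + ny - 2)
}

#' Mann-Whitney U test
#'
#' Two-tailed rank-sum test. With no ties and a smaller group of at most
#' `exact_limit` observations the exact null distribution of U is used
#' (two-tailed p = twice the smaller tail, capped at 1); otherwise the
#' normal approximation with tie correction and continuity correction.
#'
#' @param x,y numeric vectors, both non-empty.
#' @param method `"auto"` (default: exact when possible), `"exact"`, or
#'   `"normal"`.
#' @param exact_limit largest min-group size for the exact path.
#' @return the two-tailed p-value.
#' @export
#' @examples
#' mannwhitney_u_test(c(1, 2), c(3, 4))   # exact: 2/6
mannwhitney_u_test <- function(x, y, method = c("auto", "exact", "normal"),
                               exact_limit = 8L) {
  method <- match.arg(method)
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 1 || length(y) < 1)
    stop("insufficient data: both groups must be non-empty")
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  ties <- anyDuplicated(c(x, y)) > 0
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2   # U statistic for x
  use_exact <- switch(method,
    exact = TRUE,
    normal = FALSE,
    auto = !ties && min(nx, ny) <= exact_limit
  )
  if (use_exact) {
    if (ties) stop("exact Mann-Whitney p-value is undefined with ties")
    lower <- stats::pwilcox(u, nx, ny)
    upper <- stats::pwilcox(u - 1, nx, ny, lower.tail = FALSE)
    return(min(1, 2 * min(lower, upper)))
  }
  n <- nx + ny
  tie_counts <- table(c(x, y))
  sigma2 <- (nx * ny / 12) *
    ((n + 1) - sum(tie_counts^3 - tie_counts) / (n * (n - 1)))
  if (sigma2 == 0) return(1)   # all observations identical
  z <- u - nx * ny / 2
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)   # continuity correction
  2 * stats::pnorm(-abs(z))
}

# Newton inversion of the trigamma function, needed to fit the scaled
# inverse-chi-square prior on gene variances by moments of log s^2.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-8) break
  }
  y
}

# Empirical-Bayes fit of the variance prior (d0, s0^2) from observed
# per-gene variances s2 with df degrees of freedom each, by method of
# moments on z = log(s2): E[z] and Var[z] have closed forms in digamma /
# trigamma under the scaled inverse-chi-square model.
fit_variance_prior <- function(s2, df) {
  s2 <- pmax(s2, 1e-10)
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  if (length(e) < 2) return(list(d0 = 0, s02 = mean(s2)))
  evar <- stats::var(e) - trigamma(df / 2)
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # observed spread no larger than sampling noise: variances look common
    d0 <- Inf
    s02 <- exp(mean(e))
  }
  list(d0 = d0, s02 = s02)
}

#' Empirical-Bayes moderated two-sample t-test
#'
#' Per-gene two-sample t statistic whose variance estimate is shrunk toward
#' an ensemble prior, gaining degrees of freedom for small cohorts. The
#' per-gene pooled variance \eqn{s_g^2} (with \eqn{d_g = n_1 + n_2 - 2} df)
#' is replaced by the posterior
#' \deqn{\tilde{s}_g^2 = (d_0 s_0^2 + d_g s_g^2) / (d_0 + d_g),}
#' where the prior \eqn{(d_0, s_0^2)} is estimated from the ensemble of gene
#' variances by method of moments on the log variances; p-values come from a
#' t distribution with \eqn{d_0 + d_g} degrees of freedom. With `d0 = 0`
#' this is the ordinary Student t-test per gene; as `d0` grows all genes
#' share the prior variance.
#'
#' @param values numeric genes x samples matrix of log2 intensities.
#' @param groups character/factor of length `ncol(values)` with exactly two
#'   levels; the first level in sort order is taken as group A.
#' @param d0,s02 optional prior overrides; by default both are estimated
#'   from the data. `d0 = 0` disables shrinkage.
#' @return a `data.frame` with one row per gene: `gene`, `mean_diff` (group
#'   A minus group B), `t`, `df`, `p_value`, plus the fitted prior in
#'   attributes `d0` and `s02`.
#' @export
moderated_t_test <- function(values, groups, d0 = NULL, s02 = NULL) {
  values <- as.matrix(values)
  groups <- as.character(groups)
  lev <- sort(unique(groups))
  if (length(lev) != 2) stop("groups must have exactly two levels")
  a <- values[, groups == lev[1], drop = FALSE]
  b <- values[, groups == lev[2], drop = FALSE]
  n1 <- ncol(a); n2 <- ncol(b)
  if (n1 < 2 || n2 < 2)
    stop("insufficient data: each group needs at least 2 samples")
  dg <- n1 + n2 - 2
  mean_diff <- rowMeans(a) - rowMeans(b)
  s2 <- ((n1 - 1) * apply(a, 1, stats::var) +
           (n2 - 1) * apply(b, 1, stats::var)) / dg
  if (nrow(values) < 2 && is.null(d0)) {
    warning("single-gene input: falling back to the ordinary t-test (no ",
            "ensemble to estimate a prior from)")
    d0 <- 0
  }
  if (is.null(d0)) {
    prior <- fit_variance_prior(s2, dg)
    d0 <- prior$d0
    if (is.null(s02)) s02 <- prior$s02
  } else if (is.null(s02)) {
    s02 <- if (d0 > 0) mean(s2) else 0
  }
  s2_post <- if (is.infinite(d0)) rep(s02, length(s2))
             else (d0 * s02 + dg * s2) / (d0 + dg)
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  tstat <- ifelse(se == 0, ifelse(mean_diff == 0, 0, sign(mean_diff) * Inf),
                  mean_diff / se)
  df_total <- d0 + dg
  p <- if (is.infinite(df_total)) 2 * stats::pnorm(-abs(tstat))
       else 2 * stats::pt(-abs(tstat), df = df_total)
  out <- data.frame(
    gene = if (is.null(rownames(values))) as.character(seq_len(nrow(values)))
           else rownames(values),
    mean_diff = mean_diff, t = tstat, df = df_total, p_value = p,
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "d0") <- d0
  attr(out, "s02") <- s02
  out
}
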