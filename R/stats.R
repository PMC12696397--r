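# Core statistical primitives: Fisher's exact test, age-adjusted logistic
# regression odds ratios, Mann-Whitney U, Spearman correlation, and
# Benjamini-Hochberg adjustment over declared test families.

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p under the minimum-likelihood rule: the sum of
#' hypergeometric probabilities of all tables with the observed margins
#' whose probability does not exceed that of the observed table (with a
#' 1e-7 relative tolerance for ties). A table with an all-zero margin
#' yields p = 1 with a warning.
#'
#' @param a,b,c,d Cell counts: `a`/`b` carriers/non-carriers among LOY
#'   subjects, `c`/`d` among ROY subjects (or any 2x2 layout).
#' @return The two-sided p-value.
#' @examples
#' fisher_exact_2x2(5, 5, 5, 5) # 1
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("cell counts must be non-negative integers")
  }
  if (sum(counts) < 1) abort("empty table")
  tab <- matrix(counts, nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warn("degenerate 2x2 table (all-zero margin): p = 1")
    return(1)
  }
  fisher.test(tab, alternative = "two.sided")$p.value
}

#' Age-adjusted logistic regression odds ratio
#'
#' Fits `carrier ~ loy + age + age^2` by maximum likelihood (age is
#' mean-centred before squaring to reduce collinearity; the LOY odds ratio
#' is unaffected by centring) and reports the LOY odds ratio with its Wald
#' 95% confidence interval and two-sided Wald p-value. Complete separation
#' is flagged (`ci_unbounded = TRUE`) rather than hidden; a Firth
#' penalized-likelihood fit is available via `firth = TRUE`.
#'
#' @param data Tibble with logical/0-1 columns `carrier` and `loy` and a
#'   numeric `age`.
#' @param conf_level Confidence level for the Wald interval.
#' @param firth Use Jeffreys-prior penalized likelihood (Firth) instead of
#'   plain maximum likelihood.
#' @return A one-row tibble: `or`, `ci_lo`, `ci_hi`, `p`, `log_or`, `se`,
#'   `n`, `n_carriers`, `ci_unbounded`, `method`.
#' @export
logistic_or <- function(data, conf_level = 0.95, firth = FALSE) {
  stopifnot(all(c("carrier", "loy", "age") %in% names(data)))
  carrier <- as.integer(data$carrier)
  loy <- as.integer(data$loy)
  if (length(unique(carrier)) < 2) {
    abort("stratum needs at least one carrier and one non-carrier")
  }
  agec <- data$age - mean(data$age)
  X <- cbind(1, loy, agec, agec^2)
  if (firth) {
    fit <- firth_logistic(X, carrier)
    beta <- fit$beta
    se <- fit$se
  } else {
    mod <- suppressWarnings(
      glm(carrier ~ loy + agec + I(agec^2), family = binomial())
    )
    beta <- coef(mod)
    se <- sqrt(diag(vcov(mod)))
  }
  z <- qnorm(1 - (1 - conf_level) / 2)
  b <- beta[["loy"]]
  s <- se[["loy"]]
  p <- 2 * pnorm(-abs(b / s))
  # Wald machinery degenerates under (quasi-)separation: the MLE diverges
  # and the standard error explodes.
  unbounded <- !is.finite(s) || s > 50 || abs(b) > 15
  tibble(
    or = exp(b),
    ci_lo = exp(b - z * s),
    ci_hi = exp(b + z * s),
    p = p,
    log_or = b,
    se = s,
    n = length(carrier),
    n_carriers = sum(carrier),
    ci_unbounded = unbounded,
    method = if (firth) "firth" else "ml"
  )
}

# Firth-penalized logistic regression (Jeffreys prior): Newton iterations on
# the modified score U*(b) = X'(y - p + h (1/2 - p)), h the leverages.
firth_logistic <- function(X, y, max_iter = 100, tol = 1e-8) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    W <- p * (1 - p)
    XW <- X * W
    info <- crossprod(X, XW)
    info_inv <- solve(info)
    h <- rowSums((X %*% info_inv) * XW)
    U <- crossprod(X, y - p + h * (0.5 - p))
    step <- drop(info_inv %*% U)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  eta <- drop(X %*% beta)
  p <- 1 / (1 + exp(-eta))
  info <- crossprod(X, X * (p * (1 - p)))
  se <- sqrt(diag(solve(info)))
  names(beta) <- names(se) <- c("(Intercept)", "loy", "agec", "agec2")
  list(beta = beta, se = se)
}

#' Mann-Whitney U test (two-sided)
#'
#' Exact p by the null distribution of the rank-sum statistic when both
#' samples are small (`min(n, m) <= 8`) and tie-free; otherwise the normal
#' approximation with tie-corrected variance and no continuity correction
#' (so identical samples give p = 1).
#'
#' @param x,y Numeric samples.
#' @return A list with `statistic` (U for `x`), `p_value`, and `method`
#'   (`"exact"` or `"normal_approx"`).
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) abort("both samples must be non-empty")
  n <- length(x)
  m <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  has_ties <- anyDuplicated(c(x, y)) > 0
  if (min(n, m) <= 8 && !has_ties) {
    # U is symmetric about nm/2 under the null
    u_lo <- min(u, n * m - u)
    p <- min(1, 2 * pwilcox(u_lo, n, m))
    return(list(statistic = u, p_value = p, method = "exact"))
  }
  mu <- n * m / 2
  tie_counts <- table(c(x, y))
  sigma2 <- (n * m / 12) *
    ((n + m + 1) - sum(tie_counts^3 - tie_counts) / ((n + m) * (n + m - 1)))
  if (sigma2 == 0) {
    return(list(statistic = u, p_value = 1, method = "normal_approx"))
  }
  z <- (u - mu) / sqrt(sigma2)
  list(
    statistic = u,
    p_value = min(1, 2 * pnorm(-abs(z))),
    method = "normal_approx"
  )
}

#' Spearman rank correlation with t-approximation p-value
#'
#' rho is the Pearson correlation of midranks; the p-value uses the
#' t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2`
#' degrees of freedom. Zero rank variance in either variable leaves rho
#' undefined (`NA`) with a warning.
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`.
#' @return A list with `rho`, `p_value`, `n`.
#' @export
spearman_rho <- function(x, y) {
  keep <- complete.cases(x, y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3) abort("spearman_rho needs at least 3 complete pairs")
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    warn("zero rank variance: rho undefined")
    return(list(rho = NA_real_, p_value = NA_real_, n = n))
  }
  rho <- cor(rx, ry)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n)
}

#' Benjamini-Hochberg adjustment over a declared family
#'
#' Step-up adjustment with an explicit family size `m`, which may exceed the
#' number of p-values supplied (the family can include tests that were not
#' estimable). Order of the input is preserved.
#'
#' @param pvals Numeric vector of raw p-values in `[0, 1]`.
#' @param m Family size; defaults to `length(pvals)` and must be at least
#'   that.
#' @return Adjusted p-values in input order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04, 0.05), m = 5) # all 0.05
#' @export
bh_adjust <- function(pvals, m = length(pvals)) {
  if (length(pvals) == 0) return(numeric(0))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]")
  }
  if (m < length(pvals)) {
    abort("family size m must be at least the number of p-values")
  }
  p.adjust(pvals, method = "BH", n = m)
}
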