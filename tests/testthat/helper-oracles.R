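# Independent oracles and small dataset builders used across the suite.
# None of these share code with the package's fitting pathway.

# a small synthetic aggregate dataset with moderate heterogeneity
tiny_agg <- function(m = 4, seed = 42, n_range = c(4L, 9L)) {
  set.seed(seed)
  wide <- data.frame(
    study_id = paste0("T", seq_len(m)),
    mean0 = round(stats::rnorm(m, 50, 10), 2),
    sd0 = round(stats::runif(m, 2, 8), 2),
    n0 = sample(seq(n_range[1], n_range[2]), m, replace = TRUE),
    mean1 = round(stats::rnorm(m, 46, 10), 2),
    sd1 = round(stats::runif(m, 2, 8), 2),
    n1 = sample(seq(n_range[1], n_range[2]), m, replace = TRUE))
  aggregate_dataset(wide, "synthetic outcome", "units")
}

# residual variance of one IPD row given the structure and a parameter vector
.oracle_sigma2_row <- function(study, arm, m, sigma2, residual) {
  switch(residual,
    FREE = sigma2[2 * (study - 1) + arm + 1],
    STUDY = sigma2[study],
    ARM = sigma2[arm + 1],
    POOLED = sigma2[1])
}

# Brute-force ML -2 log-likelihood: builds the full dense covariance matrix
# V_i = Z G Z' + R per study from the participant-level rows and evaluates
# the multivariate normal density directly. Only usable at small n.
dense_neg2ll <- function(ipd, effects, residual, beta, sigma2, G = NULL) {
  studies <- unique(ipd$study_id)
  m <- length(studies)
  val <- 0
  for (i in seq_along(studies)) {
    rows <- ipd[ipd$study_id == studies[i], ]
    ni <- nrow(rows)
    x <- rows$arm
    X <- if (effects %in% c("FF", "FR")) {
      Xi <- matrix(0, ni, m + 1)
      Xi[, i] <- 1
      Xi[, m + 1] <- x
      Xi
    } else cbind(1, x)
    Z <- switch(effects, FF = NULL, FR = cbind(x), RR = cbind(1, x))
    R <- diag(vapply(seq_len(ni), function(r)
      .oracle_sigma2_row(i, rows$arm[r], m, sigma2, residual), 0), ni)
    V <- R
    if (!is.null(Z)) V <- V + Z %*% G %*% t(Z)
    r <- rows$y - as.numeric(X %*% beta)
    val <- val + ni * log(2 * pi) +
      as.numeric(determinant(V, logarithm = TRUE)$modulus) +
      as.numeric(t(r) %*% solve(V) %*% r)
  }
  val
}

# Brute-force ordinary least squares with study dummies + treatment,
# via the normal equations.
ols_oracle <- function(ipd) {
  studies <- unique(ipd$study_id)
  X <- outer(ipd$study_id, studies, `==`) * 1
  X <- cbind(X, ipd$arm)
  beta <- solve(t(X) %*% X, t(X) %*% ipd$y)
  res <- ipd$y - X %*% beta
  list(beta1 = beta[length(beta)], rss = sum(res^2),
       sigma2_ml = sum(res^2) / nrow(ipd))
}
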