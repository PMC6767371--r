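#' Per-study mean differences and their variances
#'
#' First stage of a classical aggregate-data meta-analysis: for each study,
#' the effect estimate is the difference between the treated and control
#' group means, `d = mean1 - mean0`, with variance
#' `var_d = sd1^2 / n1 + sd0^2 / n0` (the sum of the squared standard errors
#' of the two means).
#'
#' @param data An `agg_data` object.
#' @return A `study_effects` data.frame: `study_id`, `d`, `var_d`.
#' @examples
#' study_effects(load_fixture("iron"))
#' @export
study_effects <- function(data) {
  stopifnot(inherits(data, "agg_data"))
  c0 <- data[data$arm == 0L, ]
  c1 <- data[data$arm == 1L, ][match(c0$study_id,
                                     data$study_id[data$arm == 1L]), ]
  out <- data.frame(study_id = c0$study_id,
                    d = c1$mean - c0$mean,
                    var_d = c1$sd^2 / c1$n + c0$sd^2 / c0$n)
  structure(out, class = c("study_effects", "data.frame"),
            outcome_units = attr(data, "outcome_units"))
}

new_two_stage <- function(method, mu, se, ci, tau_sq, k, iterations = NA) {
  structure(list(method = method, mu_hat = mu, se = se, ci = ci,
                 tau_sq = tau_sq, k = k, iterations = iterations),
            class = "two_stage_fit")
}

#' DerSimonian-Laird random-effects meta-analysis
#'
#' Moment estimator of the between-study variance based on Cochran's Q,
#' truncated at zero:
#' `tau^2 = max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))` with
#' fixed-effect weights `w = 1 / var_d`. The pooled estimate uses
#' random-effects inverse-variance weights `w* = 1 / (var_d + tau^2)`, with
#' `SE = 1 / sqrt(sum(w*))` and a normal-quantile 95% CI.
#'
#' @param effects A [study_effects()] data.frame (or any data.frame with
#'   columns `d` and `var_d`).
#' @return A `two_stage_fit` with `method = "DL"`.
#' @export
fit_dl <- function(effects) {
  d <- effects$d; v <- effects$var_d
  k <- length(d)
  if (k < 2) stop("need at least 2 studies to pool")
  w <- 1 / v
  mu_fe <- sum(w * d) / sum(w)
  Q <- sum(w * (d - mu_fe)^2)
  tau_sq <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (v + tau_sq)
  mu <- sum(ws * d) / sum(ws)
  se <- 1 / sqrt(sum(ws))
  z <- stats::qnorm(0.975)
  new_two_stage("DL", mu, se, c(mu - z * se, mu + z * se), tau_sq, k)
}

## restricted log-likelihood of the normal-normal model d_i ~ N(mu, v_i + t2)
reml_meta_ll <- function(t2, d, v) {
  w <- 1 / (v + t2)
  mu <- sum(w * d) / sum(w)
  -0.5 * (sum(log(v + t2)) + log(sum(w)) + sum(w * (d - mu)^2))
}

#' REML random-effects meta-analysis, with optional Hartung-Knapp correction
#'
#' The between-study variance maximizes the restricted likelihood of the
#' model `d_i ~ N(mu, var_d_i + tau^2)` by Fisher scoring (analytic score
#' and expected information, started at the DerSimonian-Laird estimate,
#' truncated at zero). If scoring cycles within rounding error of the
#' optimum before meeting the tolerance, the restricted likelihood is
#' maximized directly by golden-section search instead (`iterations` is then
#' `NA`); the estimator is defined by the likelihood, not the algorithm.
#'
#' Without the correction, `SE = 1 / sqrt(sum(w*))` with
#' `w* = 1 / (var_d + tau^2)` and a normal-quantile 95% CI (the convention
#' of standard meta-analysis software). With `hk = TRUE`, the Hartung-Knapp
#' variance `SE^2 = sum(w* (d - mu)^2) / ((k - 1) sum(w*))` is used together
#' with a t-quantile on `k - 1` degrees of freedom, which widens the
#' interval when the number of studies is small. The point estimate and
#' `tau^2` are identical with and without the correction.
#'
#' @param effects A [study_effects()] data.frame.
#' @param hk Apply the Hartung-Knapp small-sample correction?
#' @param maxit,tol Fisher-scoring iteration limit and convergence tolerance
#'   on `tau^2`.
#' @return A `two_stage_fit` with `method` `"REML"` or `"REML_HK"`.
#' @export
fit_reml_meta <- function(effects, hk = FALSE, maxit = 100, tol = 1e-10) {
  d <- effects$d; v <- effects$var_d
  k <- length(d)
  if (k < 2) stop("need at least 2 studies to pool")

  t2 <- fit_dl(effects)$tau_sq
  converged <- FALSE
  for (it in seq_len(maxit)) {
    w <- 1 / (v + t2)
    sw <- sum(w)
    mu <- sum(w * d) / sw
    ## score and expected information of the restricted likelihood in tau^2
    U <- 0.5 * (sum(w^2 * (d - mu)^2) - sum(w) + sum(w^2) / sw)
    I <- 0.5 * (sum(w^2) - 2 * sum(w^3) / sw + (sum(w^2) / sw)^2)
    t2_new <- max(0, t2 + U / I)
    if (abs(t2_new - t2) <= tol * (1 + t2)) { t2 <- t2_new; converged <- TRUE; break }
    t2 <- t2_new
  }
  if (!converged) {
    ## scoring can cycle within rounding error of the optimum; fall back to a
    ## direct golden-section maximization of the restricted likelihood
    upper <- max(t2, stats::var(d), 1) * 10 + max(v)
    t2 <- stats::optimize(reml_meta_ll, c(0, upper), d = d, v = v,
                          maximum = TRUE, tol = 1e-12)$maximum
    if (reml_meta_ll(0, d, v) >= reml_meta_ll(t2, d, v)) t2 <- 0
    it <- NA_integer_
  }

  w <- 1 / (v + t2)
  mu <- sum(w * d) / sum(w)
  if (hk) {
    se <- sqrt(sum(w * (d - mu)^2) / ((k - 1) * sum(w)))
    q <- stats::qt(0.975, k - 1)
  } else {
    se <- 1 / sqrt(sum(w))
    q <- stats::qnorm(0.975)
  }
  new_two_stage(if (hk) "REML_HK" else "REML", mu, se,
                c(mu - q * se, mu + q * se), t2, k, iterations = it)
}

#' Two-stage meta-analysis of an aggregate dataset
#'
#' Convenience wrapper: computes [study_effects()] and pools them with the
#' requested method.
#'
#' @param data An `agg_data` object.
#' @param method `"DL"`, `"REML"` or `"REML_HK"`.
#' @return A `two_stage_fit`.
#' @examples
#' two_stage(load_fixture("iron"), "DL")
#' @export
two_stage <- function(data, method = c("DL", "REML", "REML_HK")) {
  method <- match.arg(method)
  eff <- study_effects(data)
  switch(method,
         DL = fit_dl(eff),
         REML = fit_reml_meta(eff, hk = FALSE),
         REML_HK = fit_reml_meta(eff, hk = TRUE))
}

#' @export
print.two_stage_fit <- function(x, ...) {
  cat(sprintf("Two-stage random-effects meta-analysis (%s), k = %d studies\n",
              x$method, x$k))
  cat(sprintf("Pooled difference: %.4g (SE %.4g), 95%% CI %.4g to %.4g\n",
              x$mu_hat, x$se, x$ci[1], x$ci[2]))
  cat(sprintf("Between-study variance tau^2 = %.4g\n", x$tau_sq))
  invisible(x)
}
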