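#' Specify a one-stage linear mixed model for (pseudo) IPD meta-analysis
#'
#' The one-stage analysis of participant-level outcomes `y[ijk]` (participant
#' `k`, arm `j`, study `i`; `x = 0/1` the treatment indicator) combines one
#' of three mean/random-effect structures with one of four within-study
#' residual-variance structures.
#'
#' Effect structures:
#' \describe{
#'   \item{`"FF"`}{Fixed study-specific intercepts and a common fixed
#'     treatment effect: `y = beta0_i + beta1 * x + e`.}
#'   \item{`"FR"`}{Fixed study-specific intercepts and random study-specific
#'     treatment effects: `y = beta0_i + beta1 * x + b1_i * x + e`,
#'     `b1_i ~ N(0, tau1^2)`.}
#'   \item{`"RR"`}{Random intercepts and random treatment effects:
#'     `y = beta0 + beta1 * x + b0_i + b1_i * x + e`, with `(b0_i, b1_i)`
#'     bivariate normal with covariance matrix G (unstructured by default,
#'     so an intercept-slope covariance `tau01` is estimated).}
#' }
#'
#' Residual structures for `Var(e[ijk])`:
#' \describe{
#'   \item{`"FREE"`}{A separate variance per study-arm (`2m` parameters) —
#'     the most flexible option.}
#'   \item{`"STUDY"`}{One variance per study, shared by its two arms
#'     (`m` parameters).}
#'   \item{`"ARM"`}{One variance for all control arms and one for all
#'     treated arms (2 parameters).}
#'   \item{`"POOLED"`}{A single common variance (1 parameter).}
#' }
#'
#' @param effects `"FF"`, `"FR"` or `"RR"`.
#' @param residual `"FREE"`, `"STUDY"`, `"ARM"` or `"POOLED"`.
#' @param estimation `"REML"` (default; removes the downward bias of ML
#'   variance estimates) or `"ML"`.
#' @param df_method Degrees of freedom for the t-based CI of the treatment
#'   effect. `"containment"` (default) emulates the containment rule:
#'   `m - 1` when a random treatment effect is present, residual df
#'   (`N - rank(X)`) otherwise. `"residual"` always uses residual df.
#' @param g_structure For `"RR"` only: `"unstructured"` (default) estimates
#'   the intercept-slope covariance; `"diagonal"` fixes it at zero.
#' @param control Optimizer options from [lmm_control()].
#' @return An object of class `lmm_spec`.
#' @seealso [fit_lmm()], [model_grid()]
#' @export
lmm_spec <- function(effects = c("FF", "FR", "RR"),
                     residual = c("FREE", "STUDY", "ARM", "POOLED"),
                     estimation = c("REML", "ML"),
                     df_method = c("containment", "residual"),
                     g_structure = c("unstructured", "diagonal"),
                     control = lmm_control()) {
  structure(list(effects = match.arg(effects),
                 residual = match.arg(residual),
                 estimation = match.arg(estimation),
                 df_method = match.arg(df_method),
                 g_structure = match.arg(g_structure),
                 control = control),
            class = "lmm_spec")
}

#' Optimizer control for [fit_lmm()]
#'
#' Variance parameters are optimized on an unconstrained scale
#' (log-variances; log-Cholesky factor for the 2x2 random-effects covariance
#' under `"RR"`) by L-BFGS-B with numerical gradients, with a Nelder-Mead
#' fallback and a second start if the first does not converge.
#'
#' @param reltol Relative convergence tolerance on -2 log-likelihood.
#' @param maxit Maximum optimizer iterations.
#' @param bound Absolute bound on log-scale parameters (keeps variances in
#'   `exp(c(-bound, bound))`; hitting the lower bound is reported as a
#'   boundary estimate of 0).
#' @param ndeps Step size for numerical gradients.
#' @return A list of class `lmm_control`.
#' @export
lmm_control <- function(reltol = 1e-10, maxit = 500, bound = 30, ndeps = 1e-4) {
  structure(list(reltol = reltol, maxit = maxit, bound = bound, ndeps = ndeps),
            class = "lmm_control")
}

## ---- internal representation -----------------------------------------------
## All design matrices are arm-constant, so every likelihood quantity reduces
## to per-arm sufficient statistics: mean, within-arm sum of squares and n.

collapse_arms <- function(pipd) {
  key <- paste(pipd$study_id, pipd$arm, sep = "\r")
  keys <- unique(key)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  st <- data.frame(
    study_id = vapply(parts, `[`, "", 1L),
    arm  = as.integer(vapply(parts, `[`, "", 2L)),
    mean = as.numeric(tapply(pipd$y, key, mean)[keys]),
    ss   = as.numeric(tapply(pipd$y, key, function(v) sum((v - mean(v))^2))[keys]),
    n    = as.numeric(tapply(pipd$y, key, length)[keys]))
  order_arm_stats(st)
}

stats_from_agg <- function(data) {
  order_arm_stats(data.frame(study_id = data$study_id, arm = data$arm,
                             mean = data$mean, ss = (data$n - 1) * data$sd^2,
                             n = as.numeric(data$n)))
}

order_arm_stats <- function(st) {
  studies <- unique(st$study_id)
  st <- st[order(match(st$study_id, studies), st$arm), , drop = FALSE]
  st$study <- match(st$study_id, studies)
  rownames(st) <- NULL
  if (any(table(st$study_id) != 2L) && length(studies) > 1L)
    stop("every study must contribute exactly two arms")
  st
}

n_resid_params <- function(residual, m) {
  switch(residual, FREE = 2L * m, STUDY = m, ARM = 2L, POOLED = 1L)
}

n_g_params <- function(effects, g_structure) {
  switch(effects, FF = 0L, FR = 1L,
         RR = if (g_structure == "diagonal") 2L else 3L)
}

## expand residual-variance parameters to one value per stats row
expand_resid <- function(sigma2, st, residual) {
  switch(residual,
    FREE   = sigma2[2L * (st$study - 1L) + st$arm + 1L],
    STUDY  = sigma2[st$study],
    ARM    = sigma2[st$arm + 1L],
    POOLED = rep(sigma2[1L], nrow(st)))
}

G_from_theta <- function(theta_g, effects, g_structure) {
  if (effects == "FF") return(NULL)
  if (effects == "FR") return(matrix(exp(theta_g[1L]), 1L, 1L))
  if (g_structure == "diagonal")
    return(diag(exp(theta_g[1:2]), 2L))
  L <- matrix(c(exp(theta_g[1L]), theta_g[2L], 0, exp(theta_g[3L])), 2L, 2L)
  L %*% t(L)
}

## random-effects design for one study's two arms (rows: arm 0, arm 1)
Wbar_for <- function(effects) {
  switch(effects, FF = NULL,
         FR = matrix(c(0, 1), 2L, 1L),
         RR = matrix(c(1, 1, 0, 1), 2L, 2L))
}

## fixed design at the arm level: cell-means study dummies + treatment (FF/FR),
## intercept + treatment (RR); cell-means coding is unimodular-equivalent to
## the overparameterized CLASS coding, so the REML determinant term matches.
Xbar_for <- function(st, effects) {
  m <- max(st$study)
  if (effects %in% c("FF", "FR")) {
    X <- matrix(0, nrow(st), m + 1L)
    X[cbind(seq_len(nrow(st)), st$study)] <- 1
    X[, m + 1L] <- st$arm
    colnames(X) <- c(paste0("study:", unique(st$study_id)), "treatment")
  } else {
    X <- cbind(`(Intercept)` = 1, treatment = st$arm)
  }
  X
}

## -2 log-likelihood (ML or REML) with fixed effects profiled out by GLS.
## Uses the Woodbury/determinant-lemma collapse: with D the diagonal residual
## covariance and V = D + Z G Z',
##   log|V|   = sum n_ij log s2_ij + sum_i log|I + G M_i|,
##   r'V^-1 r = sum SS_ij/s2_ij + sum_i e_i' Sigma_i^-1 e_i,
## where M_i = W' diag(n/s2) W, Sigma_i = diag(s2/n) + W G W' is the 2x2
## covariance of the arm means and e_i their GLS residuals. Returns a large
## penalty value if a linear solve fails, so the optimizer backs off.
neg2ll_collapsed <- function(theta, st, effects, residual, g_structure, reml,
                             details = FALSE) {
  m <- max(st$study)
  nr <- n_resid_params(residual, m)
  sig2 <- expand_resid(exp(theta[seq_len(nr)]), st, residual)
  G <- G_from_theta(theta[-seq_len(nr)], effects, g_structure)
  W <- Wbar_for(effects)
  q <- if (is.null(G)) 0L else ncol(G)
  X <- Xbar_for(st, effects)
  p <- ncol(X)
  N <- sum(st$n)

  ldet <- sum(st$n * log(sig2))
  quad <- sum(st$ss / sig2)
  XtVX <- matrix(0, p, p)
  XtVy <- numeric(p)
  Sinv <- vector("list", m)
  for (i in seq_len(m)) {
    idx <- which(st$study == i)
    Sig <- diag(sig2[idx] / st$n[idx], length(idx))
    if (q > 0L) {
      M <- crossprod(W, diag(st$n[idx] / sig2[idx], length(idx))) %*% W
      dt <- determinant(diag(q) + G %*% M, logarithm = TRUE)
      if (dt$sign <= 0) return(if (details) NULL else 1e10)
      ldet <- ldet + as.numeric(dt$modulus)
      Sig <- Sig + W %*% G %*% t(W)
    }
    Si <- tryCatch(chol2inv(chol(Sig)), error = function(e) NULL)
    if (is.null(Si)) return(if (details) NULL else 1e10)
    Sinv[[i]] <- Si
    Xi <- X[idx, , drop = FALSE]
    XtVX <- XtVX + crossprod(Xi, Si %*% Xi)
    XtVy <- XtVy + crossprod(Xi, Si %*% st$mean[idx])
  }
  R <- tryCatch(chol(XtVX), error = function(e) NULL)
  if (is.null(R)) return(if (details) NULL else 1e10)
  beta <- backsolve(R, backsolve(R, XtVy, transpose = TRUE))
  for (i in seq_len(m)) {
    idx <- which(st$study == i)
    e <- st$mean[idx] - X[idx, , drop = FALSE] %*% beta
    quad <- quad + as.numeric(crossprod(e, Sinv[[i]] %*% e))
  }
  val <- N * log(2 * pi) + ldet + quad
  if (reml) val <- val - p * log(2 * pi) + 2 * sum(log(diag(R)))
  if (!is.finite(val)) return(if (details) NULL else 1e10)
  if (!details) return(val)
  vc <- chol2inv(R)
  dimnames(vc) <- list(colnames(X), colnames(X))
  list(value = val, beta = stats::setNames(as.numeric(beta), colnames(X)),
       vcov_beta = vc, sigma2 = sig2, G = G, N = N, p = p)
}

## starting values: (a) per-group sample-variance moments with a DL-informed
## tau; (b) pooled-variance start with a deflated tau
lmm_starts <- function(st, effects, residual, g_structure) {
  m <- max(st$study)
  s2row <- pmax(st$ss / pmax(st$n - 1, 1), 1e-8)
  grp <- switch(residual,
    FREE   = s2row,
    STUDY  = as.numeric(tapply(s2row, st$study, mean)),
    ARM    = as.numeric(tapply(s2row, st$arm, mean)),
    POOLED = mean(s2row))
  tau1 <- 1e-2
  tau0 <- 1e-2
  if (m >= 2L) {
    d  <- st$mean[st$arm == 1L] - st$mean[st$arm == 0L]
    vd <- s2row[st$arm == 1L] / st$n[st$arm == 1L] +
          s2row[st$arm == 0L] / st$n[st$arm == 0L]
    tau1 <- max(dl_tau_sq(d, vd), 1e-2)
    tau0 <- max(stats::var(st$mean[st$arm == 0L]), 1e-2)
  }
  mk <- function(resid, t0, t1) {
    th <- log(resid)
    if (effects == "FR") th <- c(th, log(t1))
    if (effects == "RR") {
      th <- if (g_structure == "diagonal") c(th, log(t0), log(t1))
            else c(th, 0.5 * log(t0), 0, 0.5 * log(t1))
    }
    th
  }
  list(mk(grp, tau0, tau1),
       mk(rep(mean(s2row), length(grp)), tau0 / 4, max(tau1 / 4, 1e-3)))
}

## DerSimonian-Laird moment estimate (internal helper for starting values;
## the user-facing estimator lives in the two-stage module)
dl_tau_sq <- function(d, vd) {
  w <- 1 / vd
  mu <- sum(w * d) / sum(w)
  Q <- sum(w * (d - mu)^2)
  max(0, (Q - (length(d) - 1)) / (sum(w) - sum(w^2) / sum(w)))
}

run_optim <- function(par, fn, control) {
  nd <- rep(control$ndeps, length(par))
  lbfgsb <- function(p, factr) tryCatch(
    stats::optim(p, fn, method = "L-BFGS-B",
                 lower = -control$bound, upper = control$bound,
                 control = list(maxit = control$maxit, ndeps = nd,
                                factr = factr)),
    error = function(e) NULL)
  o <- lbfgsb(par, max(control$reltol * 1e13, 1))
  if (!is.null(o)) {
    ## restart at the optimum with a stringent tolerance: resets the Hessian
    ## approximation and typically gains several digits in flat directions
    o2 <- lbfgsb(o$par, 10)
    if (!is.null(o2) && o2$value <= o$value) {
      o$par <- o2$par
      o$value <- o2$value
      if (o2$convergence == 0) o$convergence <- 0
    }
  }
  if (is.null(o) || o$convergence != 0) {
    o2 <- tryCatch(
      stats::optim(if (is.null(o)) par else o$par, fn, method = "Nelder-Mead",
                   control = list(maxit = 10 * control$maxit,
                                  reltol = control$reltol)),
      error = function(e) NULL)
    if (!is.null(o2)) {
      o2$par <- pmin(pmax(o2$par, -control$bound), control$bound)
      if (is.null(o) || o2$value <= o$value) o <- o2
    }
  }
  o
}

## indices of log-scale parameters that map one-to-one to a variance
## (everything except the off-diagonal Cholesky entry of an unstructured G)
variance_indices <- function(effects, residual, g_structure, m) {
  nr <- n_resid_params(residual, m)
  idx <- seq_len(nr)
  if (effects == "FR") idx <- c(idx, nr + 1L)
  if (effects == "RR") idx <- c(idx, nr + 1L,
                                if (g_structure == "diagonal") nr + 2L
                                else nr + 3L)
  idx
}

optimize_lmm <- function(st, effects, residual, g_structure, reml, control) {
  starts <- lmm_starts(st, effects, residual, g_structure)
  fn <- function(th) neg2ll_collapsed(th, st, effects, residual, g_structure, reml)
  best <- NULL
  trace <- list()
  for (s in seq_along(starts)) {
    o <- run_optim(starts[[s]], fn, control)
    if (!is.null(o)) {
      trace[[length(trace) + 1L]] <-
        list(start = s, value = o$value, convergence = o$convergence)
      if (is.null(best) || o$value < best$value) best <- o
    }
  }
  if (is.null(best) || best$value >= 1e10)
    stop("mixed-model optimization failed to converge; trace: ",
         paste(vapply(trace, function(t)
           sprintf("start %d value %.6g code %d", t$start, t$value,
                   t$convergence), ""), collapse = "; "))
  ## the profile likelihood is flat in log-variance near a zero boundary, so
  ## the optimizer can stall above it; snap tiny components to the bound
  ## whenever that does not worsen the objective
  for (j in variance_indices(effects, residual, g_structure, max(st$study))) {
    if (best$par[j] > -control$bound && exp(best$par[j]) < 1e-6) {
      cand <- best$par
      cand[j] <- -control$bound
      v <- fn(cand)
      if (v <= best$value + 1e-7) {
        best$par <- cand
        best$value <- min(v, best$value)
      }
    }
  }
  best$trace <- trace
  best
}

#' Fit a one-stage linear mixed model to (pseudo) IPD
#'
#' Maximizes the exact marginal (ML) or restricted (REML) Gaussian
#' log-likelihood of the model described by `spec`, with the fixed effects
#' profiled out by generalized least squares at every variance evaluation.
#' Because all covariates are constant within a study arm, the likelihood is
#' evaluated from the per-arm sufficient statistics (mean, within-arm sum of
#' squares, n); the participant-level data frame remains the interface.
#'
#' Reported -2 log-likelihoods include all normalizing constants
#' (`N log 2*pi` for ML; `(N - p) log 2*pi` plus the fixed-effects
#' cross-product determinant for REML), so values are directly comparable
#' with SAS PROC MIXED and nlme. `AIC_ML = -2logLik_ML + 2 (n_fe + n_re)`;
#' `AIC_REML = -2resLogLik + 2 n_re`.
#'
#' @param pipd A `pseudo_ipd` object (from [generate_pseudo_ipd()]) or any
#'   data.frame with columns `study_id`, `arm`, `y`.
#' @param spec An [lmm_spec()].
#' @param fit_both If `TRUE` (default) both the ML and REML criteria are
#'   maximized so the fit carries both -2 log-likelihoods and AICs; the
#'   reported estimates come from `spec$estimation`. Set to `FALSE` in
#'   tight loops (e.g. simulations) to halve the cost.
#' @return An object of class `lmm_fit`; see Details.
#' @details Fields of the returned list include `beta1_hat` (treatment
#'   effect), `se_beta1`, `ci` (95%, t-distribution with `df` degrees of
#'   freedom chosen by `spec$df_method`), `tau1_sq` (between-study variance
#'   of the treatment effect), `tau0_sq`/`tau01` (RR only),
#'   `residual_variances` (per study-arm), `m2loglik_ml`, `m2loglik_reml`,
#'   `aic_ml`, `aic_reml`, `n_fe`, `n_re`, `converged`, `boundary` (TRUE if
#'   any variance component was estimated at the zero boundary; such
#'   components are reported as 0).
#' @examples
#' iron <- load_fixture("iron")
#' pipd <- generate_pseudo_ipd(iron)
#' fit_lmm(pipd, lmm_spec("FR", "FREE", "REML"))
#' @export
fit_lmm <- function(pipd, spec, fit_both = TRUE) {
  stopifnot(inherits(spec, "lmm_spec"))
  st <- collapse_arms(pipd)
  m <- max(st$study)
  if (spec$effects != "FF" && m < 2L)
    stop("random treatment effects need at least 2 studies")
  if (spec$effects == "RR" && m < 3L)
    warning("RR with fewer than 3 studies: variance components weakly identified")
  if (spec$residual %in% c("FREE", "STUDY") && any(st$n < 2))
    stop("per-study(-arm) residual variances need n >= 2 in every arm")
  zero <- st$ss <= 0
  if (spec$residual == "FREE" && any(zero))
    stop("zero within-arm variance makes the FREE structure singular for arm(s): ",
         paste(sprintf("%s/arm %d", st$study_id[zero], st$arm[zero]),
               collapse = ", "))

  ctrl <- spec$control
  reml_first <- spec$estimation == "REML"
  opt <- optimize_lmm(st, spec$effects, spec$residual, spec$g_structure,
                      reml = reml_first, control = ctrl)
  other <- if (fit_both)
    optimize_lmm(st, spec$effects, spec$residual, spec$g_structure,
                 reml = !reml_first, control = ctrl) else NULL

  det <- neg2ll_collapsed(opt$par, st, spec$effects, spec$residual,
                          spec$g_structure, reml = reml_first, details = TRUE)
  nr <- n_resid_params(spec$residual, m)
  n_fe <- det$p
  n_re <- nr + n_g_params(spec$effects, spec$g_structure)

  ## variance components, floored to 0 at the boundary
  clean <- function(v) ifelse(v < 1e-8, 0, v)
  boundary <- FALSE
  tau0_sq <- tau01 <- tau1_sq <- NA_real_
  if (!is.null(det$G)) {
    G <- det$G
    if (spec$effects == "FR") {
      tau1_sq <- G[1L, 1L]
    } else {
      tau0_sq <- G[1L, 1L]; tau01 <- G[1L, 2L]; tau1_sq <- G[2L, 2L]
    }
    if (any(diag(G) < 1e-8)) boundary <- TRUE
    tau1_sq <- clean(tau1_sq)
    if (!is.na(tau0_sq)) tau0_sq <- clean(tau0_sq)
    if (!is.na(tau01) && tau1_sq * tau0_sq == 0) tau01 <- 0
  }
  if (any(det$sigma2 < 1e-8)) boundary <- TRUE

  beta1 <- det$beta[["treatment"]]
  se1 <- sqrt(det$vcov_beta["treatment", "treatment"])
  df <- if (spec$df_method == "containment" && spec$effects %in% c("FR", "RR"))
    m - 1L else det$N - det$p
  tq <- stats::qt(0.975, df)
  m2_this <- opt$value
  m2_other <- if (fit_both) other$value else NA_real_
  m2_ml <- if (reml_first) m2_other else m2_this
  m2_reml <- if (reml_first) m2_this else m2_other

  rv <- data.frame(study_id = st$study_id, arm = st$arm,
                   sigma2 = clean(det$sigma2))
  structure(list(
    beta = det$beta, beta1_hat = beta1, se_beta1 = se1,
    ci = c(beta1 - tq * se1, beta1 + tq * se1), df = df,
    tau1_sq = tau1_sq, tau0_sq = tau0_sq, tau01 = tau01,
    residual_variances = rv,
    m2loglik_ml = m2_ml, m2loglik_reml = m2_reml,
    aic_ml = m2_ml + 2 * (n_fe + n_re), aic_reml = m2_reml + 2 * n_re,
    n_fe = n_fe, n_re = n_re, N = det$N, m = m,
    converged = opt$convergence == 0, boundary = boundary,
    optimizer = list(par = opt$par, value = opt$value,
                     convergence = opt$convergence, trace = opt$trace),
    spec = spec), class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  s <- x$spec
  cat(sprintf("One-stage LMM fit: effects %s, residual %s, %s\n",
              s$effects, s$residual, s$estimation))
  cat(sprintf("Treatment effect: %.4g (SE %.4g), 95%% CI %.4g to %.4g (t, df = %s)\n",
              x$beta1_hat, x$se_beta1, x$ci[1], x$ci[2], format(x$df)))
  if (!is.na(x$tau1_sq))
    cat(sprintf("Between-study variance tau1^2 = %.4g%s\n", x$tau1_sq,
                if (!is.na(x$tau0_sq))
                  sprintf(" (tau0^2 = %.4g, tau01 = %.4g)", x$tau0_sq, x$tau01)
                else ""))
  cat(sprintf("-2logLik(ML) = %s, AIC(ML) = %s | -2resLogLik = %s, AIC(REML) = %s\n",
              format(x$m2loglik_ml), format(x$aic_ml),
              format(x$m2loglik_reml), format(x$aic_reml)))
  cat(sprintf("#FE = %d, #RE = %d, converged: %s%s\n", x$n_fe, x$n_re,
              x$converged, if (x$boundary) " (boundary estimate)" else ""))
  invisible(x)
}

#' Evaluate the exact model -2 log-likelihood from aggregate summaries
#'
#' Computes the Gaussian LMM -2 log-likelihood at a supplied parameter point
#' using only the per-arm (mean, sd, n) — no participant-level data. The
#' within-arm sums of squares enter through `(n - 1) sd^2`, and the arm means
#' through the marginal normal density of the per-study mean vector; a
#' Jacobian term `sum log n` accounts for the mean/deviation decomposition.
#' The value is identical to the likelihood evaluated on pseudo IPD: the
#' aggregate summaries are sufficient statistics. This routine deliberately
#' shares no code with the fitting pathway and serves as its independent
#' oracle.
#'
#' @param data An `agg_data` object.
#' @param spec An [lmm_spec()]; only `effects`, `residual` and
#'   `g_structure` are used.
#' @param params Named list with elements:
#'   \describe{
#'     \item{`beta`}{Fixed effects. For `"FF"`/`"FR"`: the `m` study means
#'       of the control arm followed by the treatment effect. For `"RR"`:
#'       intercept and treatment effect.}
#'     \item{`sigma2`}{Residual variances, length per the residual
#'       structure: `2m` (FREE; study-major, control arm first), `m`
#'       (STUDY), 2 (ARM: control then treated), or 1 (POOLED).}
#'     \item{`G`}{Random-effects covariance: absent/NULL for `"FF"`, scalar
#'       `tau1^2` for `"FR"`, a 2x2 matrix (or length-3 vector
#'       `c(tau0_sq, tau01, tau1_sq)`) for `"RR"`.}
#'   }
#' @param type `"ML"` (default) or `"REML"`. The restricted likelihood does
#'   not involve `beta`; it is ignored for `"REML"`.
#' @return The -2 log-likelihood (a single number, all constants included).
#' @export
loglik_from_sufficient_stats <- function(data, spec, params,
                                         type = c("ML", "REML")) {
  stopifnot(inherits(data, "agg_data"), inherits(spec, "lmm_spec"))
  type <- match.arg(type)
  st <- stats_from_agg(data)
  m <- max(st$study)

  sigma2 <- as.numeric(params$sigma2)
  if (length(sigma2) != n_resid_params(spec$residual, m))
    stop("sigma2 must have length ", n_resid_params(spec$residual, m),
         " for residual structure ", spec$residual)
  if (any(!is.finite(sigma2)) || any(sigma2 <= 0))
    stop("variance parameters must be positive and finite")
  G <- params$G
  if (spec$effects == "FF") {
    G <- NULL
  } else if (spec$effects == "FR") {
    G <- matrix(as.numeric(G), 1L, 1L)
    if (G[1L] < 0) stop("variance parameters must be positive and finite")
  } else {
    if (is.null(dim(G))) G <- matrix(c(G[1], G[2], G[2], G[3]), 2L, 2L)
    if (any(diag(G) < 0) || abs(G[1, 2]) > sqrt(G[1, 1] * G[2, 2]) + 1e-12)
      stop("G must be a valid covariance matrix")
  }

  s2row <- expand_resid(sigma2, st, spec$residual)
  X <- Xbar_for(st, spec$effects)
  W <- Wbar_for(spec$effects)

  ## within-arm deviations: (n_ij - 1) orthonormal contrasts with variance
  ## sigma2_ij, plus the mean/deviation Jacobian
  val <- sum((st$n - 1) * (log(2 * pi) + log(s2row)) + st$ss / s2row) +
    sum(log(st$n))

  ## per-study marginal density of the two arm means
  Sig_i <- function(idx) {
    Sig <- diag(s2row[idx] / st$n[idx], 2L)
    if (!is.null(W)) Sig <- Sig + W %*% G %*% t(W)
    Sig
  }
  if (type == "ML") {
    beta <- as.numeric(params$beta)
    if (length(beta) != ncol(X))
      stop("beta must have length ", ncol(X), " for effects ", spec$effects)
    for (i in seq_len(m)) {
      idx <- which(st$study == i)
      Sig <- Sig_i(idx)
      e <- st$mean[idx] - X[idx, , drop = FALSE] %*% beta
      val <- val + 2 * log(2 * pi) +
        as.numeric(determinant(Sig, logarithm = TRUE)$modulus) +
        as.numeric(crossprod(e, solve(Sig, e)))
    }
  } else {
    p <- ncol(X)
    XtVX <- matrix(0, p, p); XtVy <- numeric(p); parts <- vector("list", m)
    for (i in seq_len(m)) {
      idx <- which(st$study == i)
      Sig <- Sig_i(idx)
      Si <- solve(Sig)
      Xi <- X[idx, , drop = FALSE]
      XtVX <- XtVX + crossprod(Xi, Si %*% Xi)
      XtVy <- XtVy + crossprod(Xi, Si %*% st$mean[idx])
      parts[[i]] <- list(idx = idx, Sig = Sig, Si = Si)
    }
    beta <- solve(XtVX, XtVy)
    for (pt in parts) {
      e <- st$mean[pt$idx] - X[pt$idx, , drop = FALSE] %*% beta
      val <- val + 2 * log(2 * pi) +
        as.numeric(determinant(pt$Sig, logarithm = TRUE)$modulus) +
        as.numeric(crossprod(e, pt$Si %*% e))
    }
    val <- val - p * log(2 * pi) +
      as.numeric(determinant(XtVX, logarithm = TRUE)$modulus)
  }
  val
}

#' Likelihood-ratio test between two nested mixed-model fits
#'
#' For REML fits the two models must share the same fixed-effect structure
#' (restricted likelihoods are only comparable at a common mean structure);
#' the degrees of freedom are the difference in (co)variance parameter
#' counts. For ML fits the fixed-effect count difference is added.
#'
#' @param full,reduced `lmm_fit` objects, the reduced model nested in the
#'   full one.
#' @return A list `(statistic, df, p_value)` of class `lmm_lrt`. The p-value
#'   comes from the upper tail of a chi-squared distribution with `df`
#'   degrees of freedom (for `df = 0`, i.e. a model compared with itself,
#'   the p-value is 1).
#' @export
lrt_compare <- function(full, reduced) {
  stopifnot(inherits(full, "lmm_fit"), inherits(reduced, "lmm_fit"))
  est <- full$spec$estimation
  if (est != reduced$spec$estimation)
    stop("cannot compare an ML fit with a REML fit")
  same_fixed <- (full$spec$effects %in% c("FF", "FR")) ==
                (reduced$spec$effects %in% c("FF", "FR"))
  if (est == "REML" && !same_fixed)
    stop("REML likelihood-ratio tests require the same fixed-effect ",
         "structure in both models (restricted likelihoods are not ",
         "comparable across mean structures)")
  df <- (full$n_re - reduced$n_re) +
    if (est == "ML") full$n_fe - reduced$n_fe else 0L
  if (df < 0) stop("'reduced' has more parameters than 'full'; swap the arguments")
  m2_full <- if (est == "REML") full$m2loglik_reml else full$m2loglik_ml
  m2_red  <- if (est == "REML") reduced$m2loglik_reml else reduced$m2loglik_ml
  stat <- m2_red - m2_full
  p <- if (df == 0L) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  structure(list(statistic = stat, df = df, p_value = p, estimation = est),
            class = "lmm_lrt")
}

#' @export
print.lmm_lrt <- function(x, ...) {
  cat(sprintf("%s likelihood-ratio test: statistic = %.4g on %d df, p = %.4g\n",
              x$estimation, x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Fit the full grid of 12 one-stage models
#'
#' All combinations of the three effect structures (FF, FR, RR) and four
#' residual-variance structures (FREE, STUDY, ARM, POOLED), each fitted by
#' both ML and REML. Point estimates, SEs and CIs are reported from the
#' `estimation` criterion; per-cell failures are recorded in the `error`
#' column rather than aborting the grid.
#'
#' @param pipd A `pseudo_ipd` object (or data.frame with `study_id`, `arm`,
#'   `y`).
#' @param estimation `"REML"` (default) or `"ML"`: criterion for the
#'   reported estimates.
#' @param df_method,g_structure,control Passed to [lmm_spec()].
#' @return An `lmm_grid` data.frame with one row per model: `effects`,
#'   `residual`, `estimate`, `se`, `ci_low`, `ci_high`, `aic_reml`,
#'   `m2ll_reml`, `n_fe`, `n_re`, `aic_ml`, `m2ll_ml`, `tau1_sq`,
#'   `converged`, `boundary`, `error`, plus the fits themselves in
#'   `attr(, "fits")`.
#' @export
model_grid <- function(pipd, estimation = c("REML", "ML"),
                       df_method = "containment",
                       g_structure = "unstructured", control = lmm_control()) {
  estimation <- match.arg(estimation)
  if (nrow(pipd) == 0L) stop("empty dataset")
  cells <- expand.grid(residual = c("FREE", "STUDY", "ARM", "POOLED"),
                       effects = c("FF", "FR", "RR"),
                       stringsAsFactors = FALSE)[, c("effects", "residual")]
  fits <- vector("list", nrow(cells))
  out <- cbind(cells, estimate = NA_real_, se = NA_real_, ci_low = NA_real_,
               ci_high = NA_real_, aic_reml = NA_real_, m2ll_reml = NA_real_,
               n_fe = NA_integer_, n_re = NA_integer_, aic_ml = NA_real_,
               m2ll_ml = NA_real_, tau1_sq = NA_real_, converged = NA,
               boundary = NA, error = NA_character_)
  for (r in seq_len(nrow(cells))) {
    sp <- lmm_spec(cells$effects[r], cells$residual[r], estimation,
                   df_method = df_method, g_structure = g_structure,
                   control = control)
    f <- tryCatch(suppressWarnings(fit_lmm(pipd, sp, fit_both = TRUE)),
                  error = function(e) e)
    if (inherits(f, "error")) {
      out$error[r] <- conditionMessage(f)
      next
    }
    fits[[r]] <- f
    out$estimate[r] <- f$beta1_hat; out$se[r] <- f$se_beta1
    out$ci_low[r] <- f$ci[1]; out$ci_high[r] <- f$ci[2]
    out$aic_reml[r] <- f$aic_reml; out$m2ll_reml[r] <- f$m2loglik_reml
    out$n_fe[r] <- f$n_fe; out$n_re[r] <- f$n_re
    out$aic_ml[r] <- f$aic_ml; out$m2ll_ml[r] <- f$m2loglik_ml
    out$tau1_sq[r] <- f$tau1_sq
    out$converged[r] <- f$converged; out$boundary[r] <- f$boundary
  }
  structure(out, class = c("lmm_grid", "data.frame"),
            fits = fits, estimation = estimation)
}

#' @export
print.lmm_grid <- function(x, digits = 4, ...) {
  cat(sprintf("One-stage model grid (%d models, estimates by %s)\n",
              nrow(x), attr(x, "estimation")))
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], signif, digits = digits)
  print(y, ...)
  invisible(x)
}
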