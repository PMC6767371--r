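# Likelihood correctness is checked through three independent routes:
# the fitting pathway (collapsed Woodbury evaluation), the sufficient-
# statistics oracle, and a brute-force dense-matrix evaluation on the rows.

test_that("sufficient-statistics oracle equals the dense brute force", {
  dat <- tiny_agg(m = 3, seed = 8, n_range = c(3L, 5L))
  pipd <- generate_pseudo_ipd(dat)
  m <- 3
  set.seed(14)
  for (effects in c("FF", "FR", "RR")) {
    for (residual in c("FREE", "STUDY", "ARM", "POOLED")) {
      for (draw in 1:3) {
        p_fe <- if (effects == "RR") 2L else m + 1L
        beta <- rnorm(p_fe, mean = c(rep(50, p_fe - 1), -4), sd = 3)
        sigma2 <- runif(pipdmeta:::n_resid_params(residual, m), 1, 40)
        G <- switch(effects, FF = NULL, FR = runif(1, 0.5, 20),
                    RR = { t0 <- runif(1, 0.5, 20); t1 <- runif(1, 0.5, 20)
                           rho <- runif(1, -0.8, 0.8)
                           matrix(c(t0, rho * sqrt(t0 * t1),
                                    rho * sqrt(t0 * t1), t1), 2) })
        spec <- lmm_spec(effects, residual)
        oracle <- loglik_from_sufficient_stats(
          dat, spec, list(beta = beta, sigma2 = sigma2, G = G))
        dense <- dense_neg2ll(pipd, effects, residual, beta, sigma2,
                              if (is.null(G)) NULL else as.matrix(G))
        expect_equal(oracle, dense, tolerance = 1e-10)
      }
    }
  }
})

test_that("fitting pathway and oracle agree at random variance points", {
  dat <- tiny_agg(m = 4, seed = 16)
  st <- pipdmeta:::stats_from_agg(dat)
  set.seed(77)
  for (case in list(list(e = "FR", r = "FREE"), list(e = "RR", r = "ARM"),
                    list(e = "FF", r = "STUDY"))) {
    for (draw in 1:5) {
      nr <- pipdmeta:::n_resid_params(case$r, 4)
      ng <- pipdmeta:::n_g_params(case$e, "unstructured")
      theta <- c(log(runif(nr, 1, 40)), rnorm(ng, 0, 0.5))
      det <- pipdmeta:::neg2ll_collapsed(theta, st, case$e, case$r,
                                         "unstructured", reml = FALSE,
                                         details = TRUE)
      oracle <- loglik_from_sufficient_stats(
        dat, lmm_spec(case$e, case$r),
        list(beta = det$beta, sigma2 = exp(theta[seq_len(nr)]), G = det$G))
      expect_equal(det$value, oracle, tolerance = 1e-10)
      # REML route too (beta-free)
      detr <- pipdmeta:::neg2ll_collapsed(theta, st, case$e, case$r,
                                          "unstructured", reml = TRUE,
                                          details = TRUE)
      oracler <- loglik_from_sufficient_stats(
        dat, lmm_spec(case$e, case$r),
        list(sigma2 = exp(theta[seq_len(nr)]), G = detr$G), type = "REML")
      expect_equal(detr$value, oracler, tolerance = 1e-10)
    }
  }
})

test_that("oracle rejects invalid variance parameters", {
  dat <- tiny_agg(m = 3, seed = 2)
  spec <- lmm_spec("FF", "POOLED")
  expect_error(loglik_from_sufficient_stats(
    dat, spec, list(beta = rep(0, 4), sigma2 = -1)), "positive")
  expect_error(loglik_from_sufficient_stats(
    dat, spec, list(beta = rep(0, 4), sigma2 = c(1, 2))), "length")
  expect_error(loglik_from_sufficient_stats(
    dat, lmm_spec("RR", "POOLED"),
    list(beta = c(0, 0), sigma2 = 1, G = c(1, 5, 1))), "covariance")
})

test_that("FF x POOLED equals the least-squares oracle", {
  dat <- tiny_agg(m = 5, seed = 23)
  pipd <- generate_pseudo_ipd(dat)
  fit <- fit_lmm(pipd, lmm_spec("FF", "POOLED", "ML"), fit_both = FALSE)
  ols <- ols_oracle(pipd)
  # GLS with a single common variance is exactly OLS
  expect_equal(fit$beta1_hat, ols$beta1, tolerance = 1e-10)
  expect_equal(fit$residual_variances$sigma2[1], ols$sigma2_ml,
               tolerance = 1e-6)
  # the ML profile optimum in sigma^2 is RSS/N; check the deviance matches
  # the closed-form Gaussian value there
  expect_equal(fit$m2loglik_ml,
               nrow(pipd) * (log(2 * pi * ols$sigma2_ml) + 1),
               tolerance = 1e-8)
})

test_that("single-study FF x POOLED is the saturated mean model", {
  one <- aggregate_dataset(data.frame(study_id = "only", arm = c(0, 1),
                                      mean = c(10, 14.5), sd = c(2, 3),
                                      n = c(8, 9)))
  fit <- fit_lmm(generate_pseudo_ipd(one), lmm_spec("FF", "POOLED", "ML"),
                 fit_both = FALSE)
  expect_equal(fit$beta1_hat, 4.5, tolerance = 1e-9)
})

test_that("REML deviances are monotone across nested residual structures", {
  for (dat in list(load_fixture("iron"), tiny_agg(m = 6, seed = 44))) {
    pipd <- generate_pseudo_ipd(dat)
    for (effects in c("FF", "FR")) {
      m2 <- vapply(c("FREE", "STUDY", "ARM", "POOLED"), function(r)
        fit_lmm(pipd, lmm_spec(effects, r, "REML"),
                fit_both = FALSE)$m2loglik_reml, 0)
      expect_lte(m2[["FREE"]], m2[["STUDY"]] + 1e-6)
      expect_lte(m2[["STUDY"]], m2[["POOLED"]] + 1e-6)
      expect_lte(m2[["FREE"]], m2[["ARM"]] + 1e-6)
      expect_lte(m2[["ARM"]], m2[["POOLED"]] + 1e-6)
    }
  }
})

test_that("homogeneous data drive tau1^2 to the boundary", {
  # identical arms in every study: no heterogeneity, tau must hit 0
  homog <- aggregate_dataset(data.frame(
    study_id = rep(paste0("H", 1:6), each = 2),
    arm = rep(c(0, 1), 6),
    mean = rep(c(20, 21), 6), sd = 1.5, n = 30))
  pipd <- generate_pseudo_ipd(homog)
  fr <- fit_lmm(pipd, lmm_spec("FR", "POOLED", "REML"), fit_both = FALSE)
  ff <- fit_lmm(pipd, lmm_spec("FF", "POOLED", "REML"), fit_both = FALSE)
  expect_identical(fr$tau1_sq, 0)
  expect_true(fr$boundary)
  expect_equal(fr$beta1_hat, ff$beta1_hat, tolerance = 1e-6)
  expect_equal(fr$beta1_hat, 1, tolerance = 1e-8)
})

test_that("likelihood-ratio comparisons enforce comparability", {
  iron <- load_fixture("iron")
  pipd <- generate_pseudo_ipd(iron)
  ff_free <- fit_lmm(pipd, lmm_spec("FF", "FREE", "REML"), fit_both = FALSE)
  ff_study <- fit_lmm(pipd, lmm_spec("FF", "STUDY", "REML"), fit_both = FALSE)
  fr_free <- fit_lmm(pipd, lmm_spec("FR", "FREE", "REML"), fit_both = FALSE)
  rr_free <- fit_lmm(pipd, lmm_spec("RR", "FREE", "REML"), fit_both = FALSE)

  lrt <- lrt_compare(ff_free, ff_study)
  expect_equal(lrt$df, 5L)
  expect_gt(lrt$statistic, 0)

  # same fixed part (study intercepts + treatment): FR vs FF is allowed
  lrt2 <- lrt_compare(fr_free, ff_free)
  expect_equal(lrt2$df, 1L)

  # different fixed part under REML: refuse with an explanation
  expect_error(lrt_compare(rr_free, ff_free), "fixed-effect")

  self <- lrt_compare(ff_free, ff_free)
  expect_equal(self$statistic, 0)
  expect_equal(self$p_value, 1)

  expect_error(lrt_compare(ff_study, ff_free), "swap")
})

test_that("model_grid fits all 12 cells and AIC identities hold", {
  pipd <- generate_pseudo_ipd(tiny_agg(m = 4, seed = 52))
  grid <- model_grid(pipd, "REML")
  expect_equal(nrow(grid), 12L)
  expect_true(all(is.na(grid$error)))
  expect_equal(grid$aic_ml, grid$m2ll_ml + 2 * (grid$n_fe + grid$n_re))
  expect_equal(grid$aic_reml, grid$m2ll_reml + 2 * grid$n_re)
  # parameter-count bookkeeping for m = 4
  expect_equal(grid$n_fe, rep(c(5L, 5L, 2L), each = 4))
  expect_equal(grid$n_re,
               c(8L, 4L, 2L, 1L, 9L, 5L, 3L, 2L, 11L, 7L, 5L, 4L))
  expect_error(model_grid(data.frame(study_id = character(0),
                                     arm = integer(0), y = numeric(0))),
               "empty")
})

test_that("degenerate inputs are rejected with context", {
  dat0 <- aggregate_dataset(data.frame(
    study_id = rep(c("A", "B"), each = 2), arm = rep(c(0, 1), 2),
    mean = c(1, 2, 3, 4), sd = c(0, 1, 1, 1), n = 10))
  pipd <- suppressWarnings(generate_pseudo_ipd(dat0))
  expect_error(fit_lmm(pipd, lmm_spec("FF", "FREE")), "A/arm 0")
  expect_error(fit_lmm(generate_pseudo_ipd(tiny_agg(m = 1, seed = 1)),
                       lmm_spec("FR", "POOLED")), "2 studies")
})

test_that("variance components are recovered on large synthetic data", {
  # 10 replicates at m = 50 studies, n = 200/arm, generated from the
  # random/random model; mean estimates must sit within 3 MC SEs of truth
  cfg <- simulation_config(m = 50, n_per_arm = 200, theta = 3,
                           sigma_treated = 4, sigma_control = 1,
                           tau0_sq = 4, tau1_sq = 2, n_reps = 12, seed = 1)
  spec <- lmm_spec("RR", "ARM", "REML", g_structure = "diagonal")
  est <- matrix(NA_real_, cfg$n_reps, 5,
                dimnames = list(NULL, c("beta1", "tau0", "tau1", "s2c", "s2t")))
  for (r in seq_len(cfg$n_reps)) {
    ipd <- generate_ipd_rep(cfg, pipdmeta:::rep_seed_for(cfg$seed, r))
    f <- fit_lmm(ipd, spec, fit_both = FALSE)
    est[r, ] <- c(f$beta1_hat, f$tau0_sq, f$tau1_sq,
                  f$residual_variances$sigma2[1],
                  f$residual_variances$sigma2[2])
  }
  truth <- c(beta1 = 3, tau0 = 4, tau1 = 2, s2c = 1, s2t = 16)
  for (j in colnames(est)) {
    mc_se <- sd(est[, j]) / sqrt(nrow(est))
    expect_lt(abs(mean(est[, j]) - truth[[j]]), 3 * mc_se + 1e-8,
              label = sprintf("recovery of %s (got %.3f, truth %.3f)",
                              j, mean(est[, j]), truth[[j]]))
  }
})
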