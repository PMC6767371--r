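test_that("two-point construction has its closed form and exact moments", {
  # mean 0, sd 1, n 4: first value sd*(n-1)/sqrt(n) = 1.5, rest -0.5
  y <- pipdmeta:::two_point_values(0, 1, 4)
  expect_equal(y, c(1.5, -0.5, -0.5, -0.5))
  expect_equal(mean(y), 0)
  expect_equal(var(y), (2.25 + 3 * 0.25) / 3)  # = 1

  # n = 2 is the symmetric pair mean +/- sd/sqrt(2)
  y2 <- pipdmeta:::two_point_values(7, 3, 2)
  expect_equal(y2, c(7 + 3 / sqrt(2), 7 - 3 / sqrt(2)))
})

test_that("both generators reproduce the aggregate moments exactly", {
  iron <- load_fixture("iron")
  for (gen in list(generate_pseudo_ipd(iron, "two_point"),
                   generate_pseudo_ipd(iron, "rescale_normal", seed = 3))) {
    expect_equal(nrow(gen), sum(iron$n))
    rep <- verify_sufficiency(gen, iron, tol = 1e-12)
    expect_true(attr(rep, "pass"))
    # Basun 1991 control arm: mean 114, sd 25, exactly
    y <- gen$y[gen$study_id == "Basun 1991" & gen$arm == 0]
    expect_equal(mean(y), 114, tolerance = 1e-13)
    expect_equal(sd(y), 25, tolerance = 1e-13)
  }
})

test_that("affine rescaling hits arbitrary targets (property)", {
  set.seed(99)
  for (case in 1:25) {
    n <- sample(2:40, 1)
    z <- rnorm(n, sd = runif(1, 0.1, 50))     # arbitrary finite seed sample
    mu <- runif(1, -100, 100)
    s <- runif(1, 1e-3, 30)
    y <- pipdmeta:::rescale_values(z, mu, s)
    expect_equal(mean(y), mu, tolerance = 1e-12)
    expect_equal(sd(y), s, tolerance = 1e-12)
  }
})

test_that("verify_sufficiency flags perturbations and structure mismatches", {
  dat <- tiny_agg(m = 3, seed = 5)
  pipd <- generate_pseudo_ipd(dat)
  row <- which(pipd$study_id == "T2" & pipd$arm == 1)[1]
  pipd$y[row] <- pipd$y[row] + 1
  rep <- verify_sufficiency(pipd, dat)
  expect_false(attr(rep, "pass"))
  bad <- rep[rep$mean_err > 1e-12 | rep$sd_err > 1e-12, ]
  expect_equal(unique(bad$study_id), "T2")
  expect_equal(unique(bad$arm), 1L)

  expect_error(verify_sufficiency(pipd[pipd$study_id != "T3", ], dat),
               "structural mismatch.*T3")
})

test_that("seed is required for rescale_normal and sd = 0 arms warn", {
  dat <- tiny_agg(m = 3, seed = 6)
  expect_error(generate_pseudo_ipd(dat, "rescale_normal"), "seed")

  dat0 <- as.data.frame(dat)
  dat0$sd[2] <- 0
  dat0 <- aggregate_dataset(dat0)
  expect_warning(p0 <- generate_pseudo_ipd(dat0), "sd = 0")
  y <- p0$y[p0$study_id == dat0$study_id[2] & p0$arm == dat0$arm[2]]
  expect_true(all(y == dat0$mean[2]))
})

test_that("inference is invariant to generation seed and method", {
  dat <- tiny_agg(m = 5, seed = 21)
  spec <- lmm_spec("FR", "ARM", "REML")
  fits <- list(
    fit_lmm(generate_pseudo_ipd(dat, "two_point"), spec, fit_both = FALSE),
    fit_lmm(generate_pseudo_ipd(dat, "rescale_normal", seed = 1), spec,
            fit_both = FALSE),
    fit_lmm(generate_pseudo_ipd(dat, "rescale_normal", seed = 202), spec,
            fit_both = FALSE))
  ref <- fits[[1]]
  for (f in fits[-1]) {
    expect_equal(f$beta1_hat, ref$beta1_hat, tolerance = 1e-6)
    expect_equal(f$se_beta1, ref$se_beta1, tolerance = 1e-6)
    expect_equal(f$tau1_sq, ref$tau1_sq, tolerance = 1e-4)
    expect_equal(f$m2loglik_reml, ref$m2loglik_reml, tolerance = 1e-8)
  }
})

test_that("aggregate_ipd inverts generation", {
  dat <- tiny_agg(m = 4, seed = 31)
  back <- aggregate_ipd(generate_pseudo_ipd(dat),
                        outcome_label = attr(dat, "outcome_label"),
                        outcome_units = attr(dat, "outcome_units"))
  expect_equal(as.data.frame(back), as.data.frame(dat), tolerance = 1e-12)
})
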