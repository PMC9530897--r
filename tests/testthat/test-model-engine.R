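test_that("mcmc configuration validates its invariants", {
  cfg <- mcmc_config(iterations = 100, burn_in = 10, thin = 2, seed = 3)
  expect_s3_class(cfg, "mcmc_config")
  expect_error(mcmc_config(iterations = 10, burn_in = 20), "iterations")
  expect_error(fit_model(list(G = diag(3)), c(1, NA, Inf), cfg),
               "non-finite")
  expect_error(fit_model(list(G = diag(2)), c(NA_real_, NA_real_), cfg),
               "unmasked")
})

test_that("fixed-variance identity-kernel fit reproduces ridge shrinkage", {
  set.seed(21)
  n <- 60
  y <- stats::rnorm(n, 5, 2)
  fit <- fit_model(list(G = diag(n)), y,
                   mcmc_config(4000, 1000, 1, seed = 2),
                   fixed_variances = list(G = 1, residual = 1))
  # with equal signal and noise variance the effect shrinks y halfway
  z <- (y - mean(y)) / stats::sd(y)
  expected <- mean(y) + stats::sd(y) * (z / 2)
  # intercept handling leaves a small wobble; check slope and agreement
  co <- stats::coef(stats::lm(fit$linear_predictor ~ y))
  expect_equal(unname(co[2]), 0.5, tolerance = 0.05)
  expect_gt(stats::cor(fit$linear_predictor, expected), 0.999)
})

test_that("posterior-mean predictions track the direct BLUP solution", {
  tr <- toy_records(n_g = 10, n_e = 3, seed = 4)
  ks <- build_model_kernels("M2", tr$records, A = tr$A)
  truth <- c(E = 0.4, A = 1, AxE = 0.5)
  sim <- simulate_from_kernels(ks, truth, residual = 0.6, intercept = 3,
                               seed = 10)
  y <- sim$y
  y[c(3, 8, 14, 22, 27)] <- NA
  fit <- fit_model(ks, y, mcmc_config(6000, 1500, 2, seed = 5),
                   records = tr$records)
  vc <- coef(fit)
  or <- blup_oracle(ks, vc[names(ks)], vc[["residual"]], y)
  expect_gt(stats::cor(fit$linear_predictor, or), 0.99)
  # masked-record predictions agree too
  pr <- predict_masked(fit)
  expect_equal(pr$record, which(is.na(y)))
  expect_gt(stats::cor(pr$prediction, or[is.na(y)]), 0.98)
})

test_that("eigen-basis sampler agrees with the naive full-covariance sampler", {
  tr <- toy_records(n_g = 8, n_e = 3, seed = 6)
  rec <- tr$records[1:24, ]
  ks <- build_model_kernels("M2", rec, A = tr$A)
  sim <- simulate_from_kernels(ks, c(E = 0.3, A = 1, AxE = 0.4),
                               residual = 0.8, intercept = 1, seed = 2)
  y <- sim$y
  y[c(2, 11, 19)] <- NA
  fit <- fit_model(ks, y, mcmc_config(6000, 1500, 1, seed = 7))
  nv <- naive_gibbs(ks, y, iterations = 6000, burn_in = 1500, seed = 8)
  # posterior-mean linear predictors agree within Monte-Carlo error
  expect_gt(stats::cor(fit$linear_predictor, nv$prediction), 0.99)
  expect_lt(mean(abs(fit$linear_predictor - nv$prediction)) /
              stats::sd(y, na.rm = TRUE), 0.1)
  # variance posteriors in the same range
  expect_equal(unname(coef(fit)[c("E", "A", "AxE")]),
               unname(nv$s2), tolerance = 0.5)
})

test_that("identical seeds give bitwise-identical fits", {
  tr <- toy_records(n_g = 6, n_e = 2, seed = 9)
  ks <- build_model_kernels("M1", tr$records, A = tr$A)
  y <- simulate_from_kernels(ks, c(E = 0.3, A = 1), 0.5, 0, seed = 3)$y
  f1 <- fit_model(ks, y, mcmc_config(500, 100, 2, seed = 42))
  f2 <- fit_model(ks, y, mcmc_config(500, 100, 2, seed = 42))
  expect_identical(f1$vc_mean, f2$vc_mean)
  expect_identical(f1$linear_predictor, f2$linear_predictor)
  f3 <- fit_model(ks, y, mcmc_config(500, 100, 2, seed = 43))
  expect_false(identical(f3$vc_mean, f1$vc_mean))
})

test_that("masked predictions: none masked warns, unseen year reverts to main effects", {
  tr <- toy_records(n_g = 6, n_e = 3, seed = 12)
  ks <- build_model_kernels("M1", tr$records, A = tr$A)
  y <- simulate_from_kernels(ks, c(E = 0.5, A = 1), 0.3, 10, seed = 4)$y
  fit <- fit_model(ks, y, mcmc_config(800, 200, 2, seed = 1),
                   records = tr$records)
  expect_warning(pr <- predict_masked(fit), "no masked")
  expect_equal(nrow(pr), 0)

  # mask a whole environment under M1: predictions collapse to mu + a_i,
  # so records of the same genotype get identical predictions
  y2 <- y
  mask <- tr$records$environment == "E3"
  y2[mask] <- NA
  fit2 <- fit_model(ks, y2, mcmc_config(3000, 800, 2, seed = 2),
                    records = tr$records)
  pr2 <- predict_masked(fit2)
  # E3 prediction = mu + a_i; compare ordering with genotype effects learned
  # from E1/E2: prediction for genotype g in E3 should correlate strongly
  # with its mean observed value across E1/E2 minus env effects
  gmeans <- tapply(y2[!mask] - stats::ave(y2[!mask],
                                          tr$records$environment[!mask]),
                   tr$records$genotype[!mask], mean)
  expect_gt(stats::cor(pr2$prediction,
                       gmeans[as.character(pr2$genotype)]), 0.9)
})

test_that("a masked duplicate of a high-signal record is predicted near it", {
  set.seed(31)
  n_g <- 12
  ids <- sprintf("G%02d", seq_len(n_g))
  rec <- data.frame(genotype = rep(ids, 2),
                    environment = "E1", stringsAsFactors = FALSE)
  A <- diag(n_g); dimnames(A) <- list(ids, ids)
  ks <- build_model_kernels("M1", rec, A = A)
  a <- stats::rnorm(n_g, 0, 3)
  y <- 10 + a[match(rec$genotype, ids)] + stats::rnorm(nrow(rec), 0, 0.05)
  y_m <- y
  y_m[n_g + 1] <- NA   # duplicate of record 1
  fit <- fit_model(ks, y_m, mcmc_config(4000, 1000, 2, seed = 3),
                   records = rec)
  pr <- predict_masked(fit)
  or <- blup_oracle(ks, coef(fit)[names(ks)], coef(fit)[["residual"]], y_m)
  expect_equal(pr$prediction, or[n_g + 1], tolerance = 0.05)
  expect_lt(abs(pr$prediction - y[1]), 0.5)
})

test_that("variance summaries normalise and absorb unmodelled interaction", {
  tr <- toy_records(n_g = 12, n_e = 4, seed = 14)
  ks2 <- build_model_kernels("M2", tr$records, A = tr$A)
  sim <- simulate_from_kernels(ks2, c(E = 0.3, A = 1, AxE = 0.8),
                               residual = 0.4, intercept = 0, seed = 6)
  ks1 <- build_model_kernels("M1", tr$records, A = tr$A)
  f1 <- fit_model(ks1, sim$y, mcmc_config(2500, 600, 2, seed = 4))
  f2 <- fit_model(ks2, sim$y, mcmc_config(2500, 600, 2, seed = 4))
  vs1 <- variance_summary(f1); vs2 <- variance_summary(f2)
  expect_equal(sum(vs1$proportion), 1, tolerance = 1e-9)
  expect_equal(sum(vs2$proportion), 1, tolerance = 1e-9)
  expect_equal(vs2$component, c(model_components("M2"), "residual"))
  # M1 residual absorbs the interaction variance M2 assigns to AxE
  expect_gt(vs1$mean[vs1$component == "residual"],
            vs2$mean[vs2$component == "residual"])
})

test_that("doubling prior df on a well-informed component barely moves it", {
  tr <- toy_records(n_g = 40, n_e = 15, seed = 18)
  ks <- build_model_kernels("M1", tr$records, A = tr$A)  # 600 records
  sim <- simulate_from_kernels(ks, c(E = 0.3, A = 1), 1, 0, seed = 7)
  f1 <- fit_model(ks, sim$y, mcmc_config(2500, 600, 2, seed = 5,
                                         prior_df = 5))
  f2 <- fit_model(ks, sim$y, mcmc_config(2500, 600, 2, seed = 5,
                                         prior_df = 10))
  expect_lt(abs(coef(f2)[["A"]] - coef(f1)[["A"]]) / coef(f1)[["A"]], 0.10)
})

test_that("fit objects expose the standard modelling methods", {
  tr <- toy_records(n_g = 5, n_e = 2, seed = 20)
  ks <- build_model_kernels("M1", tr$records, A = tr$A)
  y <- simulate_from_kernels(ks, c(E = 0.2, A = 1), 0.5, 2, seed = 8)$y
  y[3] <- NA
  fit <- fit_model(ks, y, mcmc_config(600, 100, 2, seed = 9),
                   records = tr$records)
  expect_s3_class(fit, "pedgxe_fit")
  expect_named(coef(fit), c("E", "A", "residual"))
  expect_length(fitted(fit), length(y))
  r <- residuals(fit)
  expect_true(is.na(r[3]))
  expect_equal(r[1], y[1] - fitted(fit)[1])
  expect_output(print(fit), "Multi-kernel")
  expect_output(print(summary(fit)), "Variance components")
  expect_equal(nrow(predict(fit)), 1)
  expect_length(predict(fit, what = "all"), length(y))
})
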