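test_that("phenotype files read with optional column remapping", {
  d <- make_rcbd(seed = 9)
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(d, f, row.names = FALSE)
  d2 <- read_phenotypes(f)
  expect_equal(nrow(d2), nrow(d))

  # renamed columns recovered through a YAML mapping
  d3 <- d
  names(d3)[names(d3) == "genotype"] <- "entry"
  names(d3)[names(d3) == "gy"] <- "yield_kg_ha"
  f3 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(d3, f3, row.names = FALSE)
  ym <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("genotype: entry", "gy: yield_kg_ha"), ym)
  d4 <- read_phenotypes(f3, ym)
  expect_equal(d4$genotype, d$genotype)
  expect_equal(d4$gy, d$gy)
  expect_error(read_phenotypes(f3, list(gy = "nope")), "absent")
  expect_error(read_phenotypes(f3), "required")
})

test_that("quality filtering drops trials by missingness and metadata rules", {
  d1 <- make_rcbd(trial = "clean1", seed = 1)
  d2 <- make_rcbd(trial = "clean2", seed = 2)
  d3 <- make_rcbd(trial = "gappy", seed = 3)
  d3$gy[seq_len(ceiling(0.25 * nrow(d3)))] <- NA
  d4 <- make_rcbd(trial = "norep", seed = 4)
  d4$rep <- NA
  pheno <- rbind(d1, d2, d3, d4)
  qf <- quality_filter(pheno)
  expect_setequal(unique(qf$data$trial), c("clean1", "clean2"))
  expect_setequal(qf$report$trial, c("gappy", "norep"))
  expect_match(qf$report$reason[qf$report$trial == "gappy"], "missing > 20%")

  qf2 <- quality_filter(rbind(d1, d2))
  expect_equal(nrow(qf2$report), 0)
  d5 <- make_rcbd(trial = "allgone", seed = 5)
  d5$gy <- NA
  expect_error(quality_filter(d5), "no trials survive")
})

test_that("balanced-design BLUEs equal genotype means and the GLS oracle", {
  d <- make_rcbd(n_g = 5, n_r = 3, seed = 11)
  fit <- fit_trial_model(d, "T1", covariate = NULL, genotype_as = "fixed")
  gm <- tapply(d$gy, d$genotype, mean)
  expect_equal(fit$blues$blue, as.numeric(gm[fit$blues$genotype]),
               tolerance = 1e-6)
  # direct GLS oracle at the fitted variance components
  X <- stats::model.matrix(~ 0 + genotype, d)
  Zr <- incidence(as.character(d$rep))
  or <- gls_oracle(d$gy, X, list(Zr), fit$varcomp["rep"], fit$sigma2)
  expect_equal(fit$blues$blue, unname(or$beta), tolerance = 1e-8)
  expect_equal(fit$blues$se, unname(sqrt(diag(or$cov))), tolerance = 1e-6)
})

test_that("REML variance components match a profiled-likelihood scan", {
  for (s in 1:3) {
    d <- make_rcbd(n_g = 5, n_r = 3, sigma_e = 2, sigma_r = 1.5,
                   seed = 20 + s)
    fit <- fit_trial_model(d, "T1", covariate = NULL, genotype_as = "fixed")
    X <- stats::model.matrix(~ 0 + genotype, d)
    Zr <- incidence(as.character(d$rep))
    or <- reml_profile_oracle(d$gy, X, Zr)
    lam_fit <- max(fit$varcomp[["rep"]], 1e-10) / fit$sigma2
    expect_lt(or$ll - reml_profile_ll(d$gy, X, Zr, lam_fit), 1e-3)
    if (or$sigma2_u > 0.01 * or$sigma2 &&
        fit$varcomp[["rep"]] > 0.01 * fit$sigma2) {
      expect_equal(fit$sigma2, or$sigma2, tolerance = 1e-3)
      expect_equal(unname(fit$varcomp["rep"]), or$sigma2_u,
                   tolerance = max(1e-3, 2e-3 * or$sigma2_u))
    }
  }
})

test_that("noise-free data give a vanishing residual and exact BLUEs", {
  d <- make_rcbd(sigma_e = 0, sigma_r = 0, seed = 3)
  fit <- fit_trial_model(d, "T1", covariate = NULL, genotype_as = "fixed")
  expect_lt(fit$sigma2, 1e-6 * stats::var(d$gy))
  expect_equal(fit$blues$blue,
               as.numeric(tapply(d$gy, d$genotype, mean)[fit$blues$genotype]),
               tolerance = 1e-4)
})

test_that("the flowering-time covariate slope is recovered", {
  d <- make_rcbd(n_g = 12, n_r = 3, sigma_e = 3, dtf_slope = 30, seed = 9)
  fit <- fit_trial_model(d, "T1", covariate = "dtf", genotype_as = "fixed")
  slope <- fit$beta[".cov"]
  se <- sqrt(diag(fit$cov_beta))[".cov"]
  expect_lt(abs(slope - 30), 3 * se)
})

test_that("BLUEs are invariant to replication relabelling", {
  d <- make_rcbd(seed = 15)
  fit1 <- fit_trial_model(d, "T1", covariate = NULL)
  d2 <- d
  d2$rep <- c(3, 1, 2)[d2$rep]
  fit2 <- fit_trial_model(d2, "T1", covariate = NULL)
  expect_equal(fit1$blues$blue, fit2$blues$blue, tolerance = 1e-8)
})

test_that("a gross outlier is flagged by the Holm-corrected studentized test", {
  d <- make_rcbd(n_g = 20, n_r = 5, sigma_e = 2, seed = 31)
  fit0 <- fit_trial_model(d, "T1", covariate = NULL)
  d$gy[7] <- d$gy[7] + 10 * sqrt(fit0$sigma2) *
    sign(stats::runif(1) - 0.5)
  fit <- fit_trial_model(d, "T1", covariate = NULL)
  flags <- flag_outliers(fit, alpha = 0.05)
  expect_true(flags[7])
  expect_equal(sum(flags), 1)
  # independent check: direct Holm step-down over the same t p-values
  L <- chol(fit$V)
  ys <- backsolve(L, fit$data$.y, transpose = TRUE)
  Xs <- backsolve(L, fit$X, transpose = TRUE)
  lmfit <- stats::lm(ys ~ 0 + Xs)
  tstat <- stats::rstudent(lmfit)
  p <- sort(2 * stats::pt(-abs(tstat), lmfit$df.residual - 1))
  n <- length(p)
  holm_reject <- p < 0.05 / (n - seq_along(p) + 1)
  expect_equal(sum(cumprod(holm_reject)), sum(flags))
})

test_that("family-wise false-flag rate stays near the nominal level", {
  n_flagged <- 0L
  n_reps <- 60
  for (s in seq_len(n_reps)) {
    d <- make_rcbd(n_g = 20, n_r = 5, sigma_e = 2, seed = 500 + s)
    fit <- fit_trial_model(d, "T1", covariate = NULL)
    if (any(flag_outliers(fit, alpha = 0.05))) n_flagged <- n_flagged + 1L
  }
  # binomial(60, .05) has sd ~1.7; allow generous slack above 5%
  expect_lte(n_flagged, stats::qbinom(0.999, n_reps, 0.05) + 1)
})

test_that("degenerate trials skip the outlier test with a warning", {
  d <- make_rcbd(n_g = 2, n_r = 1, seed = 2)
  d <- d[1:2, ]
  fit <- fit_trial_model(d, "T1", covariate = NULL)
  expect_warning(flags <- flag_outliers(fit), "degrees of freedom")
  expect_false(any(flags))
})

test_that("combined model separates residual variances and treatment effect", {
  set.seed(44)
  n_g <- 25; n_r <- 4
  g <- sprintf("G%02d", seq_len(n_g))
  gm <- stats::setNames(stats::rnorm(n_g, 4000, 400), g)
  rows <- list()
  for (cond in c("non-stress", "stress")) {
    sig <- if (cond == "stress") 400 else 200   # sigma2_S = 4 x sigma2_NS
    d <- expand.grid(genotype = g, rep = seq_len(n_r),
                     stringsAsFactors = FALSE)
    d$gy <- gm[d$genotype] + (cond == "stress") * (-2000) +
      stats::rnorm(nrow(d), 0, sig)
    d$year <- 2001L; d$season <- "dry"; d$condition <- cond
    d$trial <- paste0("T_", cond); d$block <- 1L; d$design <- "RCBD"
    rows[[cond]] <- d
  }
  pheno <- do.call(rbind, rows)
  fit <- fit_combined_model(pheno, covariate = NULL)
  s2 <- fit$sigma2_by_condition
  ratio <- s2[["stress"]] / s2[["non-stress"]]
  expect_gt(ratio, 2); expect_lt(ratio, 8)
  expect_lt(abs(unname(fit$treatment_effect) - (-2000)),
            3 * unname(fit$treatment_se))
  expect_equal(nrow(fit$blues), n_g)
  expect_error(fit_combined_model(rows[["stress"]]), "single-condition")
})

test_that("Cullis heritability follows its closed form on balanced designs", {
  # balanced RCBD, genotype random: v_bar has a closed form via the MME
  sigma_g <- 6; sigma_e <- 4
  h2 <- sapply(c(2, 4, 8), function(n_r) {
    set.seed(7)
    n_g <- 30
    g <- sprintf("G%02d", seq_len(n_g))
    d <- expand.grid(genotype = g, rep = seq_len(n_r),
                     stringsAsFactors = FALSE)
    gv <- stats::rnorm(n_g, 0, sigma_g)
    d$gy <- 100 + gv[match(d$genotype, g)] + stats::rnorm(nrow(d), 0, sigma_e)
    d$year <- 1L; d$season <- "dry"; d$condition <- "non-stress"
    d$trial <- "T"; d$block <- 1L; d$design <- "RCBD"
    fit <- fit_trial_model(d, "T", covariate = NULL, genotype_as = "random")
    # closed form: v_bar = 2 sigma2_e / r * s2g/(s2g + s2e/r) at REML estimates
    s2g <- fit$sigma2_g; s2e <- fit$sigma2
    lam <- s2g / (s2g + s2e / n_r)
    v_closed <- 2 * (s2e / n_r) * lam
    expect_equal(fit$v_bar_blup, v_closed, tolerance = 1e-6)
    cullis_heritability(fit)
  })
  # monotone increasing in replication count
  expect_true(all(diff(h2) > 0))
  expect_true(all(h2 >= 0 & h2 <= 1))
})

test_that("zero genotype variance yields H2 = 0 with a warning", {
  set.seed(6)
  d <- make_rcbd(n_g = 8, n_r = 3, sigma_e = 5,
                 means = rep(100, 8), seed = 6)
  fit <- fit_trial_model(d, "T1", covariate = NULL, genotype_as = "random")
  if (fit$sigma2_g <= 1e-12) {
    expect_warning(h2 <- cullis_heritability(fit), "zero")
    expect_equal(h2, 0)
  } else {
    h2 <- suppressWarnings(cullis_heritability(fit))
    expect_true(h2 >= 0 && h2 <= 1)
  }
})

test_that("stage one merges duplicate environment BLUEs by inverse variance", {
  d1 <- make_rcbd(trial = "TA", seed = 51)
  d2 <- make_rcbd(trial = "TB", seed = 52)   # same year x condition
  s1 <- stage_one_blues(rbind(d1, d2), covariate = "dtf")
  expect_equal(sum(duplicated(paste(s1$blues$genotype,
                                    s1$blues$environment))), 0)
  # merged SE smaller than either single-trial SE
  f1 <- fit_trial_model(d1, "TA")
  expect_true(all(s1$blues$se < f1$blues$se + 1e-9))
})
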