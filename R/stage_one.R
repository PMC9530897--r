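#' Read a long-format phenotype table
#'
#' Reads trial records from CSV with one row per plot. Column names can be
#' remapped through a named list (or a YAML file containing one) whose names
#' are the canonical fields (`genotype`, `year`, `season`, `condition`,
#' `trial`, `rep`, `block`, `design`, `gy`, `dtf`, `ph`) and whose values
#' are the column names found in the file.
#'
#' @param path CSV file path.
#' @param mapping Named list/character vector mapping canonical field names
#'   to file column names, or the path of a YAML file with such a mapping;
#'   `NULL` assumes canonical names.
#' @return data.frame with canonical column names.
#' @export
read_phenotypes <- function(path, mapping = NULL) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.character(mapping) && length(mapping) == 1 && file.exists(mapping))
    mapping <- yaml::read_yaml(mapping)
  if (length(mapping)) {
    mapping <- unlist(mapping)
    missing_cols <- setdiff(unname(mapping), names(d))
    if (length(missing_cols))
      stop("mapped columns absent from file: ",
           paste(missing_cols, collapse = ", "))
    names(d)[match(unname(mapping), names(d))] <- names(mapping)
  }
  required <- c("genotype", "year", "condition", "trial", "rep", "gy")
  miss <- setdiff(required, names(d))
  if (length(miss))
    stop("phenotype table lacks required columns: ",
         paste(miss, collapse = ", "))
  if (any(d$gy < 0, na.rm = TRUE)) stop("negative grain yield value")
  d
}

#' Quality-filter a long-format phenotype table
#'
#' Drops whole trials that lack replication or design metadata, or whose
#' grain-yield (response) missingness exceeds `max_missing`.
#'
#' @param pheno PhenotypeTable: data.frame with at least `genotype`, `year`,
#'   `condition`, `trial`, `rep`, `design` and the response column.
#' @param trait Response column name (default `"gy"`).
#' @param max_missing Maximum tolerated fraction of missing response per
#'   trial (default 0.20).
#' @return List with `data` (surviving rows) and `report` (data.frame of
#'   dropped trials and reasons).
#' @export
quality_filter <- function(pheno, trait = "gy", max_missing = 0.20) {
  trials <- unique(as.character(pheno$trial))
  drop <- character(0); reason <- character(0)
  for (tr in trials) {
    d <- pheno[pheno$trial == tr, , drop = FALSE]
    if (all(is.na(d$rep)) || !("rep" %in% names(d))) {
      drop <- c(drop, tr); reason <- c(reason, "no replication metadata")
      next
    }
    if (!("design" %in% names(d)) || all(is.na(d$design))) {
      drop <- c(drop, tr); reason <- c(reason, "no design metadata")
      next
    }
    frac <- mean(is.na(d[[trait]]))
    if (frac > max_missing) {
      drop <- c(drop, tr)
      reason <- c(reason, sprintf("missing > %d%% (%.1f%%)",
                                  round(100 * max_missing), 100 * frac))
    }
  }
  keep <- !(as.character(pheno$trial) %in% drop)
  if (!any(keep)) stop("no trials survive filtering")
  list(data = pheno[keep, , drop = FALSE],
       report = data.frame(trial = drop, reason = reason,
                           stringsAsFactors = FALSE))
}

# Prepare one trial's data: factors, centred covariate (mean-imputed when
# missing), unique rep/block labels.
prepare_trial <- function(pheno, trial, trait, covariate) {
  d <- pheno[as.character(pheno$trial) == as.character(trial), , drop = FALSE]
  if (!nrow(d)) stop("trial not found: ", trial)
  d <- d[!is.na(d[[trait]]), , drop = FALSE]
  d$genotype <- factor(as.character(d$genotype))
  if (nlevels(d$genotype) < 2) stop("trial ", trial, " has < 2 genotypes")
  d$.y <- d[[trait]]
  d$.rep <- factor(paste0("r", as.character(d$rep)))
  has_block <- "block" %in% names(d) && !all(is.na(d$block)) &&
    !is.null(d$design) && any(d$design == "alpha-lattice", na.rm = TRUE)
  if (has_block) d$.block <- factor(paste(d$.rep, d$block, sep = ":"))
  has_season <- "season" %in% names(d) && length(unique(d$season)) > 1
  if (has_season) d$.season <- factor(as.character(d$season))
  if (!is.null(covariate)) {
    cv <- d[[covariate]]
    cv[is.na(cv)] <- mean(cv, na.rm = TRUE)
    d$.cov <- cv - mean(cv)
  }
  attr(d, "has_block") <- has_block
  attr(d, "has_season") <- has_season
  d
}

# Random-term incidence matrices for a prepared trial
random_design <- function(d) {
  Z <- list()
  if (nlevels(d$.rep) > 1) Z$rep <- incidence(as.character(d$.rep))
  if (isTRUE(attr(d, "has_block")) && nlevels(d$.block) > 1)
    Z$block <- incidence(as.character(d$.block))
  if (isTRUE(attr(d, "has_season")))
    Z$season <- incidence(as.character(d$.season))
  Z
}

# V = sum sigma2_k Z_k Z_k' + sigma2 I, with a tiny ridge for stability
marginal_V <- function(Zlist, varcomp, sigma2, n) {
  V <- diag(sigma2, n)
  for (nm in names(Zlist)) V <- V + varcomp[[nm]] * tcrossprod(Zlist[[nm]])
  V + diag(1e-8 * max(mean(diag(V)), 1e-12), n)
}

#' Fit the stage-1 linear mixed model for one trial
#'
#' REML fit of response on genotype with random replication (and block for
#' alpha-lattice designs, and season when the trial spans seasons), with an
#' optional centred covariate (days to 50\% flowering) as a fixed slope.
#' With `genotype_as = "fixed"` the fit yields per-genotype BLUEs (estimated
#' means at the covariate mean); with `genotype_as = "random"` it yields the
#' genotype variance, BLUPs and their prediction-error covariance, as needed
#' for the Cullis heritability.
#'
#' Variance components are estimated by REML through `lme4::lmer`; BLUEs,
#' BLUPs and prediction-error variances are then recomputed directly from
#' the generalised-least-squares / mixed-model equations at those estimates
#' so that all downstream quantities share one linear-algebra path.
#'
#' @param pheno PhenotypeTable.
#' @param trial Trial id.
#' @param trait Response column (default `"gy"`).
#' @param covariate Covariate column or `NULL` (default `"dtf"` when
#'   present).
#' @param genotype_as `"fixed"` or `"random"`.
#' @return An object of class `trial_fit`.
#' @export
fit_trial_model <- function(pheno, trial, trait = "gy",
                            covariate = if ("dtf" %in% names(pheno)) "dtf",
                            genotype_as = c("fixed", "random")) {
  genotype_as <- match.arg(genotype_as)
  d <- prepare_trial(pheno, trial, trait, covariate)
  n <- nrow(d)
  Zlist <- random_design(d)

  rand_terms <- character(0)
  if ("rep" %in% names(Zlist)) rand_terms <- c(rand_terms, "(1 | .rep)")
  if ("block" %in% names(Zlist)) rand_terms <- c(rand_terms, "(1 | .block)")
  if ("season" %in% names(Zlist)) rand_terms <- c(rand_terms, "(1 | .season)")
  fixed_part <- if (genotype_as == "fixed") "0 + genotype" else "1"
  if (!is.null(covariate)) fixed_part <- paste(fixed_part, "+ .cov")
  if (genotype_as == "random") rand_terms <- c("(1 | genotype)", rand_terms)

  varcomp <- list(); sigma2 <- NA_real_
  if (length(rand_terms)) {
    f <- stats::as.formula(paste(".y ~", fixed_part, "+",
                                 paste(rand_terms, collapse = " + ")))
    fit <- suppressWarnings(suppressMessages(
      lme4::lmer(f, data = d, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore",
                                             calc.derivs = FALSE))))
    vc <- as.data.frame(lme4::VarCorr(fit))
    sigma2 <- vc$vcov[vc$grp == "Residual"]
    grp_map <- c(.rep = "rep", .block = "block", .season = "season",
                 genotype = "genotype")
    for (i in which(vc$grp != "Residual"))
      varcomp[[grp_map[[vc$grp[i]]]]] <- vc$vcov[i]
  } else {
    f <- stats::as.formula(paste(".y ~", fixed_part))
    fit <- stats::lm(f, data = d)
    sigma2 <- summary(fit)$sigma^2
  }

  X <- stats::model.matrix(stats::as.formula(paste("~", fixed_part)), d)
  Zr <- Zlist
  g_random <- genotype_as == "random"
  if (g_random) {
    Zg <- incidence(as.character(d$genotype), levels(d$genotype))
    sigma2_g <- if (!is.null(varcomp$genotype)) varcomp$genotype else 0
  }
  V <- marginal_V(Zr, varcomp[setdiff(names(varcomp), "genotype")], sigma2, n)
  if (g_random) V <- V + sigma2_g * tcrossprod(Zg)
  Vi <- solve(V)
  XtVi <- crossprod(X, Vi)
  cov_beta <- solve(XtVi %*% X)
  beta <- drop(cov_beta %*% (XtVi %*% d$.y))
  names(beta) <- colnames(X)

  blues <- NULL; blups <- NULL; v_bar <- NA_real_
  if (!g_random) {
    gcols <- grep("^genotype", colnames(X))
    blues <- data.frame(genotype = levels(d$genotype),
                        blue = unname(beta[gcols]),
                        se = sqrt(diag(cov_beta)[gcols]),
                        stringsAsFactors = FALSE)
  } else {
    # BLUP and prediction-error covariance of genotype effects
    P <- Vi - t(XtVi) %*% cov_beta %*% XtVi
    Gz <- sigma2_g * t(Zg)
    ghat <- drop(Gz %*% P %*% d$.y)
    Cmat <- sigma2_g * diag(nlevels(d$genotype)) - Gz %*% P %*% t(Gz)
    m <- nlevels(d$genotype)
    if (m > 1) {
      dvar <- outer(diag(Cmat), diag(Cmat), `+`) - 2 * Cmat
      v_bar <- mean(dvar[upper.tri(dvar)])
    }
    blups <- data.frame(genotype = levels(d$genotype), blup = ghat,
                        pev = diag(Cmat), stringsAsFactors = FALSE)
  }
  resid <- drop(d$.y - X %*% beta)

  structure(list(trial = trial, trait = trait, genotype_as = genotype_as,
                 data = d, X = X, Zlist = Zr,
                 varcomp = unlist(varcomp), sigma2 = sigma2,
                 sigma2_g = if (g_random) sigma2_g else NA_real_,
                 beta = beta, cov_beta = cov_beta,
                 blues = blues, blups = blups, v_bar_blup = v_bar,
                 residuals = resid, V = V),
            class = "trial_fit")
}

#' @export
print.trial_fit <- function(x, ...) {
  cat("Stage-1 trial fit:", as.character(x$trial), "| trait", x$trait,
      "| genotype", x$genotype_as, "\n")
  cat("  n =", nrow(x$data), ", genotypes =", nlevels(x$data$genotype), "\n")
  vc <- c(x$varcomp, residual = x$sigma2)
  cat("  variance components:",
      paste(names(vc), signif(vc, 4), sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' Flag outlying records by Holm-corrected studentized residuals
#'
#' Whitens the trial data with the fitted marginal covariance, computes
#' externally studentized residuals of the whitened least-squares fit, and
#' tests them two-sided against a t reference with Bonferroni-Holm
#' correction over the trial's records.
#'
#' @param fit `trial_fit` (genotype fixed).
#' @param alpha Family-wise level (default 0.05).
#' @return Logical vector, one flag per record of the fitted data.
#' @export
flag_outliers <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "trial_fit"))
  n <- nrow(fit$data)
  p <- ncol(fit$X)
  if (n - p - 1 < 2) {
    warning("fewer than 2 residual degrees of freedom; outlier test skipped")
    return(rep(FALSE, n))
  }
  L <- chol(fit$V)
  ys <- backsolve(L, fit$data$.y, transpose = TRUE)
  Xs <- backsolve(L, fit$X, transpose = TRUE)
  qr_x <- qr(Xs)
  e <- qr.resid(qr_x, ys)
  h <- rowSums(qr.Q(qr_x)^2)
  h <- pmin(h, 1 - 1e-10)
  sse <- sum(e^2)
  df <- n - p - 1
  s2_i <- (sse - e^2 / (1 - h)) / df
  s2_i <- pmax(s2_i, 1e-300)
  tstat <- e / sqrt(s2_i * (1 - h))
  pval <- 2 * stats::pt(-abs(tstat), df)
  stats::p.adjust(pval, method = "holm") < alpha
}

#' Fit the combined-condition model with heteroscedastic residuals
#'
#' Joint REML fit across stress and non-stress records: fixed genotype and
#' treatment (condition) effects, random replications within trials (plus
#' blocks/season where present), and a separate residual variance per
#' condition. Yields one BLUE per genotype across treatments (evaluated at
#' the average of the condition effects).
#'
#' @param pheno PhenotypeTable containing both conditions.
#' @param trait Response column (default `"gy"`).
#' @param covariate Optional covariate column.
#' @return List of class `combined_fit` with elements `blues`, `fixef`
#'   (including the treatment contrast), `varcomp`, `sigma2_by_condition`,
#'   `model` (the glmmTMB object) and `logLik`.
#' @export
fit_combined_model <- function(pheno, trait = "gy",
                               covariate = if ("dtf" %in% names(pheno)) "dtf") {
  conds <- unique(as.character(pheno$condition))
  if (length(conds) < 2)
    stop("single-condition input: use fit_trial_model for per-trial fits")
  d <- pheno[!is.na(pheno[[trait]]), , drop = FALSE]
  d$.y <- d[[trait]]
  d$genotype <- factor(as.character(d$genotype))
  d$condition <- factor(as.character(d$condition))
  d$.rep <- factor(paste(d$trial, d$rep, sep = ":"))
  has_block <- "block" %in% names(d) && !all(is.na(d$block))
  if (has_block)
    d$.block <- factor(paste(d$trial, d$rep, d$block, sep = ":"))
  has_season <- "season" %in% names(d) && length(unique(d$season)) > 1
  if (has_season) d$.season <- factor(as.character(d$season))
  if (!is.null(covariate)) {
    cv <- d[[covariate]]; cv[is.na(cv)] <- mean(cv, na.rm = TRUE)
    d$.cov <- cv - mean(cv)
  }
  fixed_part <- "0 + genotype + condition"
  if (!is.null(covariate)) fixed_part <- paste(fixed_part, "+ .cov")
  rand <- "(1 | .rep)"
  if (has_block) rand <- paste(rand, "+ (1 | .block)")
  if (has_season) rand <- paste(rand, "+ (1 | .season)")
  f <- stats::as.formula(paste(".y ~", fixed_part, "+", rand))
  fit <- suppressWarnings(
    glmmTMB::glmmTMB(f, dispformula = ~ 0 + condition, data = d,
                     REML = TRUE,
                     control = glmmTMB::glmmTMBControl(
                       optCtrl = list(iter.max = 1000, eval.max = 1000))))
  fe <- glmmTMB::fixef(fit)
  beta <- fe$cond
  s2_cond <- exp(2 * fe$disp)   # gaussian dispersion is modelled on log-SD
  names(s2_cond) <- sub("^condition", "", names(s2_cond))
  vc <- glmmTMB::VarCorr(fit)$cond
  varcomp <- vapply(vc, function(v) as.numeric(v[1, 1]), 0)
  names(varcomp) <- sub("^\\.", "", names(varcomp))

  gcols <- grep("^genotype", names(beta))
  ccols <- grep("^condition", names(beta))
  cond_adj <- mean(c(0, unname(beta[ccols])))
  Vb <- stats::vcov(fit)$cond
  glev <- levels(d$genotype)
  se <- numeric(length(gcols))
  nc <- length(ccols)
  for (i in seq_along(gcols)) {
    cvec <- numeric(length(beta))
    cvec[gcols[i]] <- 1
    cvec[ccols] <- 1 / (nc + 1)
    se[i] <- sqrt(drop(t(cvec) %*% Vb %*% cvec))
  }
  blues <- data.frame(genotype = glev,
                      blue = unname(beta[gcols]) + cond_adj,
                      se = se, stringsAsFactors = FALSE)
  treatment <- unname(beta[ccols])
  names(treatment) <- sub("^condition", "", names(beta)[ccols])
  structure(list(blues = blues, fixef = beta, treatment_effect = treatment,
                 treatment_se = sqrt(diag(as.matrix(Vb))[ccols]),
                 varcomp = varcomp, sigma2_by_condition = s2_cond,
                 model = fit, logLik = as.numeric(stats::logLik(fit)),
                 data = d),
            class = "combined_fit")
}

#' Cullis generalised heritability
#'
#' \eqn{H^2 = 1 - \bar v_{BLUP} / (2 \sigma^2_g)}, where \eqn{\bar v_{BLUP}}
#' is the mean variance of a difference of two genotype BLUPs. Valid for
#' unbalanced designs; clipped to [0, 1] with a warning when outside.
#'
#' @param fit `trial_fit` fitted with `genotype_as = "random"`.
#' @return Heritability in [0, 1].
#' @export
cullis_heritability <- function(fit) {
  stopifnot(inherits(fit, "trial_fit"))
  if (fit$genotype_as != "random")
    stop("Cullis heritability needs a genotype-random fit")
  if (!is.finite(fit$sigma2_g) || fit$sigma2_g <= 1e-12) {
    warning("genotype variance is zero; H2 = 0 by convention")
    return(0)
  }
  h2 <- 1 - fit$v_bar_blup / (2 * fit$sigma2_g)
  if (h2 < 0 || h2 > 1) {
    warning("H2 outside [0, 1]; clipped")
    h2 <- min(max(h2, 0), 1)
  }
  h2
}

#' Run stage one over all trials: BLUEs, heritabilities, outlier handling
#'
#' Quality-filters the table, then per trial: fits the genotype-fixed model,
#' flags outliers once (Holm-corrected studentized residuals), refits with
#' flagged records removed, and extracts per-genotype BLUEs; fits the
#' genotype-random model for the Cullis heritability. Duplicate
#' genotype-by-environment BLUEs (several trials in one year-condition) are
#' merged by inverse-variance weighting. Environment = year x condition.
#'
#' @param pheno PhenotypeTable.
#' @param trait Response column.
#' @param covariate Optional covariate column.
#' @param alpha Outlier test level.
#' @param max_missing Passed to [quality_filter()].
#' @return List of class `stage_one` with `blues` (genotype, year, condition,
#'   environment, blue, se), `h2` (per trial), `dropped_trials`,
#'   `n_outliers`.
#' @export
stage_one_blues <- function(pheno, trait = "gy",
                            covariate = if ("dtf" %in% names(pheno)) "dtf",
                            alpha = 0.05, max_missing = 0.20) {
  qf <- quality_filter(pheno, trait, max_missing)
  d <- qf$data
  trials <- unique(as.character(d$trial))
  blues <- list(); h2 <- list(); n_out <- 0L
  for (tr in trials) {
    fit <- fit_trial_model(d, tr, trait, covariate, "fixed")
    flags <- tryCatch(flag_outliers(fit, alpha),
                      warning = function(w) rep(FALSE, nrow(fit$data)))
    if (any(flags)) {
      n_out <- n_out + sum(flags)
      sub <- d[as.character(d$trial) == tr, , drop = FALSE]
      sub <- sub[!is.na(sub[[trait]]), , drop = FALSE]
      keep_rows <- !flags
      d2 <- rbind(d[as.character(d$trial) != tr, , drop = FALSE],
                  sub[keep_rows, , drop = FALSE])
      fit <- fit_trial_model(d2, tr, trait, covariate, "fixed")
      fitr <- fit_trial_model(d2, tr, trait, covariate, "random")
    } else {
      fitr <- fit_trial_model(d, tr, trait, covariate, "random")
    }
    meta <- d[as.character(d$trial) == tr, ][1, ]
    b <- fit$blues
    b$trial <- tr
    b$year <- meta$year
    b$condition <- as.character(meta$condition)
    blues[[tr]] <- b
    h2[[tr]] <- data.frame(trial = tr, year = meta$year,
                           condition = as.character(meta$condition),
                           h2 = suppressWarnings(cullis_heritability(fitr)),
                           stringsAsFactors = FALSE)
  }
  bl <- do.call(rbind, blues)
  bl$environment <- paste(bl$year, bl$condition, sep = "_")
  # merge duplicate genotype x environment BLUEs by inverse-variance weight
  key <- paste(bl$genotype, bl$environment, sep = "\r")
  if (anyDuplicated(key)) {
    w <- 1 / pmax(bl$se^2, 1e-12)
    agg_b <- tapply(bl$blue * w, key, sum) / tapply(w, key, sum)
    agg_se <- sqrt(1 / tapply(w, key, sum))
    first <- !duplicated(key)
    bl2 <- bl[first, c("genotype", "year", "condition", "environment",
                       "trial")]
    k2 <- key[first]
    bl2$blue <- as.numeric(agg_b[k2])
    bl2$se <- as.numeric(agg_se[k2])
    bl <- bl2
  }
  rownames(bl) <- NULL
  structure(list(
    blues = bl[, c("genotype", "year", "condition", "environment",
                   "blue", "se", "trial")],
    h2 = do.call(rbind, c(h2, list(make.row.names = FALSE))),
    dropped_trials = qf$report, n_outliers = n_out), class = "stage_one")
}

#' @export
print.stage_one <- function(x, ...) {
  cat("Stage-1 analysis:", nrow(x$blues), "BLUEs over",
      length(unique(x$blues$environment)), "environments;",
      nrow(x$h2), "trial heritabilities;",
      x$n_outliers, "outliers removed;",
      nrow(x$dropped_trials), "trials dropped\n")
  invisible(x)
}

#' Export a BLUE table as CSV
#' @param s1 `stage_one` result or its `blues` data.frame.
#' @param path Output CSV.
#' @export
write_blues <- function(s1, path) {
  bl <- if (inherits(s1, "stage_one")) s1$blues else s1
  utils::write.csv(bl[, c("genotype", "year", "condition", "environment",
                          "blue", "se")], path, row.names = FALSE)
  invisible(path)
}
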