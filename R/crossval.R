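#' Build a cross-validation plan over a BLUE table
#'
#' Three schemes over genotype-by-environment BLUEs:
#' \describe{
#'   \item{CV2}{incomplete trials: records assigned at random to `folds`
#'     folds, each record masked exactly once per replicate.}
#'   \item{CV1}{untested lines: genotypes assigned to folds, so all records
#'     of a genotype are masked together.}
#'   \item{CV0}{novel years: one fold per year, masking every record of that
#'     year (leave-one-year-out); a single deterministic replicate.}
#' }
#' Fold assignment depends only on the scheme, seed, replicate and the
#' sorted record/genotype/year identifiers, so testing partitions are
#' identical across training-set compositions.
#'
#' @param blues BlueTable data.frame (`genotype`, `year`, `condition`,
#'   `environment`, `blue`, `se`).
#' @param scheme `"CV0"`, `"CV1"` or `"CV2"`.
#' @param composition Training composition: `"S"`, `"NS"`, `"CSN"`, or for
#'   CV0 also the crossed calibrations `"S->NS"` / `"NS->S"`.
#' @param folds Number of folds for CV1/CV2 (default 5).
#' @param replicates Replicates for CV1/CV2 (default 10); CV0 always uses 1.
#' @param seed Base RNG seed.
#' @return Object of class `cv_plan`: `masks[[replicate]][[fold]]` holds the
#'   masked row indices of `blues`.
#' @export
make_cv_plan <- function(blues, scheme = c("CV2", "CV1", "CV0"),
                         composition = "CSN", folds = 5L, replicates = 10L,
                         seed = 1L) {
  scheme <- match.arg(scheme)
  comp_ok <- c("S", "NS", "CSN", if (scheme == "CV0") c("S->NS", "NS->S"))
  if (!composition %in% comp_ok)
    stop("composition '", composition, "' not valid for ", scheme)
  if (length(unique(blues$environment)) < 2)
    stop("need at least 2 environments")
  rec_id <- paste(blues$genotype, blues$environment, sep = "\r")
  ord <- order(rec_id)

  masks <- list()
  if (scheme == "CV0") {
    years <- sort(unique(blues$year))
    if (length(years) < 2) stop("CV0 needs at least 2 years")
    replicates <- 1L
    masks[[1]] <- lapply(years, function(yy) which(blues$year == yy))
    names(masks[[1]]) <- as.character(years)
  } else if (scheme == "CV2") {
    n <- nrow(blues)
    for (r in seq_len(replicates)) {
      set.seed(seed + r)
      lab <- sample(rep_len(seq_len(folds), n))  # over sorted record ids
      fold_of <- integer(n); fold_of[ord] <- lab
      masks[[r]] <- lapply(seq_len(folds), function(f) which(fold_of == f))
    }
  } else {  # CV1
    genos <- sort(unique(as.character(blues$genotype)))
    for (r in seq_len(replicates)) {
      set.seed(seed + r)
      glab <- sample(rep_len(seq_len(folds), length(genos)))
      fold_of_g <- stats::setNames(glab, genos)
      masks[[r]] <- lapply(seq_len(folds), function(f)
        unname(which(fold_of_g[as.character(blues$genotype)] == f)))
    }
  }
  structure(list(scheme = scheme, composition = composition,
                 folds = if (scheme == "CV0") length(masks[[1]]) else folds,
                 replicates = replicates, seed = seed, masks = masks,
                 n_records = nrow(blues)),
            class = "cv_plan")
}

#' @export
print.cv_plan <- function(x, ...) {
  cat("CV plan:", x$scheme, "| composition", x$composition, "|", x$folds,
      "folds x", x$replicates, "replicate(s) | seed", x$seed, "\n")
  invisible(x)
}

#' Training / testing record sets for one fold under a composition
#'
#' Applies the training-set composition rules: `S` restricts training to
#' stress records (and scores only stress testing records), `NS` the
#' converse, `CSN` uses both conditions; the crossed CV0 calibrations
#' `S->NS` / `NS->S` train on one condition excluding the target year and
#' test on the other condition in the target year.
#'
#' @param plan `cv_plan`.
#' @param replicate,fold Indices into the plan.
#' @param blues The BlueTable the plan was built on.
#' @return List with integer `train` and `test` row indices.
#' @export
compose_training <- function(plan, replicate, fold, blues) {
  stopifnot(inherits(plan, "cv_plan"))
  masked <- plan$masks[[replicate]][[fold]]
  stress <- as.character(blues$condition) == "stress"
  comp <- plan$composition
  if (comp %in% c("S->NS", "NS->S")) {
    target_year <- blues$year[masked][1]
    train_cond <- if (comp == "S->NS") stress else !stress
    test_cond <- !train_cond
    train <- which(train_cond & blues$year != target_year)
    test <- which(test_cond & blues$year == target_year)
  } else {
    unmasked <- setdiff(seq_len(nrow(blues)), masked)
    train <- switch(comp,
                    S = unmasked[stress[unmasked]],
                    NS = unmasked[!stress[unmasked]],
                    CSN = unmasked)
    test <- switch(comp,
                   S = masked[stress[masked]],
                   NS = masked[!stress[masked]],
                   CSN = masked)
  }
  if (!length(train)) stop("empty training set for fold ", fold)
  list(train = train, test = test)
}

#' Weighted within-environment predictive ability
#'
#' Pearson correlation between predictions and observations within each
#' environment (year x condition) holding at least `min_n` scored records,
#' averaged with weights proportional to environment size.
#'
#' @param pred,obs Numeric vectors.
#' @param env Environment label per entry.
#' @param min_n Minimum records per environment to score (default 3).
#' @return List with `per_env` (environment, n, correlation) and `weighted`
#'   (the weighted average correlation).
#' @export
weighted_env_correlation <- function(pred, obs, env, min_n = 3L) {
  stopifnot(length(pred) == length(obs), length(obs) == length(env))
  ok <- is.finite(pred) & is.finite(obs)
  pred <- pred[ok]; obs <- obs[ok]; env <- as.character(env)[ok]
  envs <- sort(unique(env))
  rows <- list()
  for (e in envs) {
    i <- env == e
    n <- sum(i)
    if (n < min_n || stats::sd(obs[i]) == 0 || stats::sd(pred[i]) == 0)
      next
    rows[[e]] <- data.frame(environment = e, n = n,
                            correlation = stats::cor(pred[i], obs[i]))
  }
  if (!length(rows))
    stop("no environment has at least ", min_n, " scorable records")
  per_env <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  w <- per_env$n / sum(per_env$n)
  list(per_env = per_env, weighted = sum(w * per_env$correlation))
}

#' Run a cross-validation experiment over one or more models
#'
#' For each replicate and fold: composes the training set, builds the model
#' kernels over training plus testing records jointly, masks the testing
#' responses, fits by Gibbs sampling, and collects predictions. Per
#' replicate, the fold-wise predictions are integrated into a single vector
#' and scored by weighted within-environment correlation.
#'
#' @param blues BlueTable.
#' @param plan `cv_plan` built on the same `blues`.
#' @param models Character vector of model ids ("M1".."M7").
#' @param A Additive relationship matrix over genotypes (models with A).
#' @param parents,A_p1,A_p2 Parent maps/matrices (models M3-M7).
#' @param cfg [mcmc_config()]; its seed is combined deterministically with
#'   replicate, fold and model so the whole run is reproducible.
#' @param min_n Minimum environment size for scoring.
#' @param score_condition Optional condition (`"stress"`/`"non-stress"`):
#'   restrict scoring to testing records of that condition, so that runs
#'   with different training compositions are compared on identical record
#'   sets (e.g. combined vs stress-only calibration for predicting stress).
#' @return Object of class `cv_result` with `per_env`, `per_replicate` and
#'   `summary` data.frames.
#' @export
run_cv <- function(blues, plan, models = "M2", A = NULL, parents = NULL,
                   A_p1 = NULL, A_p2 = NULL, cfg = mcmc_config(),
                   min_n = 3L, score_condition = NULL) {
  stopifnot(inherits(plan, "cv_plan"))
  per_env <- list(); per_rep <- list()
  for (r in seq_len(plan$replicates)) {
    pred_acc <- lapply(models, function(m) rep(NA_real_, nrow(blues)))
    names(pred_acc) <- models
    test_all <- integer(0)
    for (f in seq_along(plan$masks[[r]])) {
      ct <- compose_training(plan, r, f, blues)
      if (!length(ct$test)) next
      idx <- c(ct$train, ct$test)
      rec <- blues[idx, , drop = FALSE]
      y <- rec$blue
      y[seq_along(ct$test) + length(ct$train)] <- NA
      for (mi in seq_along(models)) {
        m <- models[mi]
        ks <- build_model_kernels(m, rec, A = A, parents = parents,
                                  A_p1 = A_p1, A_p2 = A_p2)
        fit_seed <- (abs(cfg$seed) * 131L + r * 977L + f * 31L + mi) %%
          2147483629L
        cfg_f <- cfg; cfg_f$seed <- as.integer(fit_seed)
        fit <- fit_model(ks, y, cfg_f, records = rec)
        pr <- predict_masked(fit)
        pred_acc[[m]][ct$test] <- pr$prediction
      }
      test_all <- union(test_all, ct$test)
    }
    if (!length(test_all)) next
    if (!is.null(score_condition))
      test_all <- test_all[as.character(blues$condition[test_all]) ==
                             score_condition]
    for (m in models) {
      scored <- test_all[is.finite(pred_acc[[m]][test_all])]
      sc <- weighted_env_correlation(pred_acc[[m]][scored],
                                     blues$blue[scored],
                                     blues$environment[scored], min_n)
      pe <- sc$per_env
      pe$scheme <- plan$scheme; pe$model <- m
      pe$composition <- plan$composition; pe$replicate <- r
      per_env[[length(per_env) + 1L]] <- pe
      per_rep[[length(per_rep) + 1L]] <-
        data.frame(scheme = plan$scheme, model = m,
                   composition = plan$composition, replicate = r,
                   weighted = sc$weighted)
    }
  }
  pe <- do.call(rbind, c(per_env, list(make.row.names = FALSE)))
  pr <- do.call(rbind, c(per_rep, list(make.row.names = FALSE)))
  sm <- stats::aggregate(weighted ~ scheme + model + composition, pr, mean)
  names(sm)[names(sm) == "weighted"] <- "mean_weighted"
  structure(list(per_env = pe[, c("scheme", "model", "composition",
                                  "replicate", "environment", "n",
                                  "correlation")],
                 per_replicate = pr, summary = sm, plan = plan),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("Cross-validation result (", x$plan$scheme, ", ",
      x$plan$composition, "):\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Export cross-validation results as tidy CSVs
#' @param cv `cv_result` (or a list of them, row-bound).
#' @param dir Output directory.
#' @export
write_cv_result <- function(cv, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cvs <- if (inherits(cv, "cv_result")) list(cv) else cv
  pe <- do.call(rbind, lapply(cvs, `[[`, "per_env"))
  sm <- do.call(rbind, lapply(cvs, `[[`, "summary"))
  utils::write.csv(pe, file.path(dir, "cv_per_environment.csv"),
                   row.names = FALSE)
  utils::write.csv(sm, file.path(dir, "cv_summary.csv"), row.names = FALSE)
  invisible(dir)
}
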