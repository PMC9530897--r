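#' Configuration for the synthetic breeding-program generator
#'
#' Defaults emulate, at desk scale, the topology of a long-running rice
#' drought breeding program: 17 year-environments each with paired
#' non-stress and reproductive-stage drought-stress trials, long-term check
#' varieties repeated every year, and crosses whose parents recur across
#' many crosses. Variance components are in (kg/ha)^2; the drought penalty
#' multiplies the non-stress base mean; stress trials additionally draw
#' their plot residual SD from a wider range, which is what depresses
#' stress-trial heritability.
#'
#' @param n_founders Founder lines (default 24).
#' @param crosses_per_cycle Crosses (distinct parent pairs) per breeding
#'   cycle (60).
#' @param lines_per_cross Sister lines derived from each cross (2); full
#'   sibs enter the program together and are evaluated in the same trials,
#'   as derived lines of one cross are in practice.
#' @param n_cycles Breeding cycles (3).
#' @param years Year-environments (17).
#' @param n_checks Check varieties present in every trial (4). At desk scale
#'   trials hold a few dozen entries rather than the hundreds of a full
#'   program, so the check count is kept at the low end of the realistic
#'   range to keep the share of check records near what a real multi-year
#'   series has; checks also recur as parents, as elite varieties do.
#' @param eval_years Maximum years a line is evaluated (3).
#' @param advance_frac Fraction of each year's entries advanced
#'   (re-evaluated the following year), selected on observed mean yield:
#'   most lines appear in a single year, a selected minority connects
#'   adjacent years (0.2).
#' @param reps Replications per trial (3).
#' @param design_mix Proportion of trials laid out as alpha-lattice with
#'   `blocks_per_rep` incomplete blocks; the rest are RCBD (0.5).
#' @param blocks_per_rep Incomplete blocks per replicate (4).
#' @param base_mean Non-stress base yield, kg/ha (4500).
#' @param drought_penalty Multiplicative mean shift for stress trials
#'   (0.45).
#' @param sigma2_E Environment (year x condition) variance (250000).
#' @param sigma2_a Additive genetic variance (360000).
#' @param sigma2_aE Additive-by-environment variance (180000).
#' @param sigma2_aC Genotype-by-condition genetic variance (240000): a
#'   condition-specific additive deviation, independent between stress and
#'   non-stress, giving a cross-condition genetic correlation of
#'   `sigma2_a / (sigma2_a + sigma2_aC)`. This emulates drought tolerance
#'   being only partly the same trait as yield potential; none of the
#'   fitted models carries this term explicitly.
#' @param sigma2_gca1,sigma2_gca2,sigma2_sca,sigma2_gca1E,sigma2_gca2E,sigma2_scaE
#'   GCA/SCA(-by-environment) variances, used when `model` carries those
#'   terms.
#' @param resid_sd_ns,resid_sd_s Ranges (length-2) of per-trial plot
#'   residual SD under non-stress / stress.
#' @param sigma2_rep,sigma2_block Replication / block variances.
#' @param dtf_mean,dtf_sd Genotype mean and SD of days to 50\% flowering.
#' @param dtf_slope Fixed yield response per day of flowering (30 kg/ha).
#' @param model Model id (see [model_components()]) whose terms generate the
#'   genetic values ("M2").
#' @param seed RNG seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_founders = 24L, crosses_per_cycle = 60L,
                       lines_per_cross = 2L, n_cycles = 3L, years = 17L,
                       n_checks = 4L, eval_years = 3L, advance_frac = 0.2,
                       reps = 3L, design_mix = 0.5,
                       blocks_per_rep = 4L, base_mean = 4500,
                       drought_penalty = 0.45,
                       sigma2_E = 250000, sigma2_a = 360000,
                       sigma2_aE = 180000, sigma2_aC = 240000,
                       sigma2_gca1 = 180000, sigma2_gca2 = 180000,
                       sigma2_sca = 90000, sigma2_gca1E = 90000,
                       sigma2_gca2E = 90000, sigma2_scaE = 45000,
                       resid_sd_ns = c(500, 1000),
                       resid_sd_s = c(700, 1500),
                       sigma2_rep = 22500, sigma2_block = 10000,
                       dtf_mean = 85, dtf_sd = 7, dtf_slope = 30,
                       model = "M2", seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_founders >= 4, cfg$years >= 2,
            cfg$drought_penalty > 0, cfg$drought_penalty <= 1)
  vs <- grep("^sigma2", names(cfg), value = TRUE)
  if (any(unlist(cfg[vs]) < 0)) stop("variances must be >= 0")
  structure(cfg, class = "sim_config")
}

#' Simulate a multi-cycle pedigree with deliberate parent reuse
#'
#' Founders, then `n_cycles` rounds of crosses whose parents are drawn with
#' replacement from the founders and earlier crosses, so that parents recur
#' across crosses (the borrowing structure GCA models exploit).
#'
#' @param cfg [sim_config()].
#' @return Pedigree data.frame (`id`, `parent1`, `parent2`), founders first,
#'   deterministic for a given seed.
#' @export
simulate_pedigree <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  founders <- sprintf("F%03d", seq_len(cfg$n_founders))
  ped <- data.frame(id = founders, parent1 = NA_character_,
                    parent2 = NA_character_,
                    family = founders, stringsAsFactors = FALSE)
  checks <- founders[seq_len(min(cfg$n_checks, length(founders)))]
  pool <- founders
  for (cy in seq_len(cfg$n_cycles)) {
    # draw parents from a subset of the pool so each recurs in many crosses;
    # the long-term checks are elite varieties and recur as parents in every
    # cycle, tying them into the breeding material
    pp <- unique(c(checks,
                   sample(pool, min(length(pool),
                                    max(4L, cfg$crosses_per_cycle %/% 2L)))))
    p1 <- sample(pp, cfg$crosses_per_cycle, replace = TRUE)
    p2 <- sample(pp, cfg$crosses_per_cycle, replace = TRUE)
    clash <- p1 == p2
    while (any(clash)) {
      p2[clash] <- sample(pp, sum(clash), replace = TRUE)
      clash <- p1 == p2
    }
    fam <- sprintf("C%d_%02d", cy, seq_len(cfg$crosses_per_cycle))
    # sister lines: full sibs derived from the same cross
    k <- max(1L, cfg$lines_per_cross)
    ids <- sprintf("%s_%d", rep(fam, each = k), seq_len(k))
    ped <- rbind(ped, data.frame(id = ids,
                                 parent1 = rep(p1, each = k),
                                 parent2 = rep(p2, each = k),
                                 family = rep(fam, each = k),
                                 stringsAsFactors = FALSE))
    pool <- c(pool, ids)
  }
  ped
}

# lower-Cholesky draw of MVN(0, K * s2), with jitter for semidefinite K
mvn_draw <- function(K, s2) {
  if (s2 <= 0) return(stats::setNames(numeric(nrow(K)), rownames(K)))
  L <- chol(K + diag(1e-8, nrow(K)))
  stats::setNames(drop(crossprod(L, stats::rnorm(nrow(K))) * sqrt(s2)),
                  rownames(K))
}

#' Simulate multi-environment trials from a model specification
#'
#' Draws the genetic effect vectors of the configured model (`M1`..`M7`)
#' from their multivariate normals over the true relationship matrices,
#' lays records out as year-by-condition trials with replications (and
#' incomplete blocks for the alpha-lattice share), applies the drought
#' penalty and the per-condition residual SD ranges, simulates a flowering
#' covariate with a known yield slope, and keeps every check in every
#' trial.
#'
#' @param cfg [sim_config()].
#' @param ped Pedigree from [simulate_pedigree()] (regenerated when `NULL`).
#' @return List with `pheno` (PhenotypeTable), `truth` (SimTruth: effect
#'   vectors, true variance components, noiseless genetic value per record),
#'   `pedigree`, `genealogy`, `A`, and for GCA models `parents`, `A_p1`,
#'   `A_p2`.
#' @export
simulate_trials <- function(cfg, ped = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(ped)) ped <- simulate_pedigree(cfg)
  g <- build_genealogy(ped, max_depth = 7L)
  A <- additive_relationship(g)
  comps <- model_components(cfg$model)

  founders <- ped$id[is.na(ped$parent1) & is.na(ped$parent2)]
  checks <- founders[seq_len(min(cfg$n_checks, length(founders)))]
  crosses <- ped[!is.na(ped$parent1) & !is.na(ped$parent2), , drop = FALSE]
  lines <- c(checks, crosses$id)

  set.seed(cfg$seed + 1L)
  # cohort year per cross (sister lines enter together); after each year the
  # top advance_frac of the year's entries (by observed mean yield) are
  # forwarded to the next year, up to eval_years evaluations
  fams <- if ("family" %in% names(crosses)) crosses$family else crosses$id
  fam_cohort <- stats::setNames(
    sort(rep_len(seq_len(cfg$years), length(unique(fams)))), unique(fams))
  cohort <- stats::setNames(unname(fam_cohort[fams]), crosses$id)

  envs <- expand.grid(year = 2000L + seq_len(cfg$years),
                      condition = c("non-stress", "stress"),
                      stringsAsFactors = FALSE)
  envs <- envs[order(envs$year, envs$condition), ]
  envs$env <- paste(envs$year, envs$condition, sep = "_")

  # checks are founders with unknown parents: GCA models need resolvable
  # parents, so checks are entered as selfs of themselves in the maps
  parents <- rbind(
    data.frame(id = checks, parent1 = checks, parent2 = checks,
               stringsAsFactors = FALSE),
    crosses[, c("id", "parent1", "parent2")])
  pm <- parent_relationship_matrices(parents, A)

  # genotype-level and genotype-x-environment effect draws
  A_l <- A[lines, lines]
  truth_eff <- list()
  vc_true <- c()
  eff_main <- stats::setNames(numeric(length(lines)), lines)
  for (cn in comps) {
    if (cn == "E") {
      e <- stats::setNames(stats::rnorm(nrow(envs), 0, sqrt(cfg$sigma2_E)),
                           envs$env)
      truth_eff$E <- e
      vc_true["sigma2_E"] <- cfg$sigma2_E
    } else if (cn == "A") {
      a <- mvn_draw(A_l, cfg$sigma2_a)
      truth_eff$A <- a; eff_main <- eff_main + a
      vc_true["sigma2_a"] <- cfg$sigma2_a
    } else if (cn == "AxE") {
      m <- vapply(envs$env, function(e) mvn_draw(A_l, cfg$sigma2_aE),
                  numeric(length(lines)))
      truth_eff$AxE <- m
      vc_true["sigma2_aE"] <- cfg$sigma2_aE
    } else if (cn %in% c("GCA1", "GCA2")) {
      Ap <- if (cn == "GCA1") pm$A_p1 else pm$A_p2
      s2 <- if (cn == "GCA1") cfg$sigma2_gca1 else cfg$sigma2_gca2
      pcol <- if (cn == "GCA1") "parent1" else "parent2"
      gv <- mvn_draw(Ap, s2)
      truth_eff[[cn]] <- gv
      pmap <- stats::setNames(parents[[pcol]], parents$id)
      eff_main <- eff_main + gv[pmap[lines]]
      vc_true[if (cn == "GCA1") "sigma2_aP1" else "sigma2_aP2"] <- s2
    } else if (cn == "SCA") {
      K <- make_cross_kernel(parents, pm)
      sv <- mvn_draw(K, cfg$sigma2_sca)
      truth_eff$SCA <- sv
      eff_main <- eff_main + sv[lines]
      vc_true["sigma2_aP1xP2"] <- cfg$sigma2_sca
    } else if (cn %in% c("GCA1xE", "GCA2xE", "SCAxE")) {
      s2 <- switch(cn, GCA1xE = cfg$sigma2_gca1E, GCA2xE = cfg$sigma2_gca2E,
                   SCAxE = cfg$sigma2_scaE)
      K <- switch(cn,
                  GCA1xE = expand_parent_kernel(parents, pm$A_p1, "parent1",
                                                lines),
                  GCA2xE = expand_parent_kernel(parents, pm$A_p2, "parent2",
                                                lines),
                  SCAxE = make_cross_kernel(parents, pm)[lines, lines])
      m <- vapply(envs$env, function(e) mvn_draw(K, s2),
                  numeric(length(lines)))
      rownames(m) <- lines
      truth_eff[[cn]] <- m
      vc_true[switch(cn, GCA1xE = "sigma2_aE_P1", GCA2xE = "sigma2_aE_P2",
                     SCAxE = "sigma2_aE_P1xP2")] <- s2
    }
  }

  # condition-specific additive deviations (independent across conditions)
  if (cfg$sigma2_aC > 0) {
    aC <- vapply(c("non-stress", "stress"),
                 function(cc) mvn_draw(A_l, cfg$sigma2_aC),
                 numeric(length(lines)))
    rownames(aC) <- lines
    truth_eff$AxC <- aC
    vc_true["sigma2_aC"] <- cfg$sigma2_aC
  }

  # genotype DTF means and per-trial layout
  dtf_geno <- stats::setNames(
    stats::rnorm(length(lines), cfg$dtf_mean, cfg$dtf_sd), lines)

  rows <- list()
  gv_rows <- list()
  n_seen <- stats::setNames(rep(0L, nrow(crosses)), crosses$id)
  carried <- character(0)
  ei <- 0L
  for (yr in seq_len(cfg$years)) {
    yy <- 2000L + yr
    entries <- c(crosses$id[cohort[crosses$id] == yr], carried)
    genos <- c(checks, entries)
    if (length(genos) < 2) { carried <- character(0); next }
    year_sum <- stats::setNames(numeric(length(entries)), entries)
    year_n <- stats::setNames(numeric(length(entries)), entries)
    for (cond in c("non-stress", "stress")) {
      ei <- ei + 1L
      env <- paste(yy, cond, sep = "_")
      alpha_design <- (ei %% round(1 / max(cfg$design_mix, 1e-9))) == 0
      design <- if (alpha_design) "alpha-lattice" else "RCBD"
      resid_rng <- if (cond == "stress") cfg$resid_sd_s else cfg$resid_sd_ns
      resid_sd <- stats::runif(1, resid_rng[1], resid_rng[2])
      trial <- paste0("T", yy, "_", ifelse(cond == "stress", "S", "NS"))
      mean_t <- cfg$base_mean *
        (if (cond == "stress") cfg$drought_penalty else 1)
      e_env <- if (!is.null(truth_eff$E)) truth_eff$E[env] else 0

      gen_val <- eff_main[genos]
      for (cn in c("AxE", "GCA1xE", "GCA2xE", "SCAxE")) {
        if (!is.null(truth_eff[[cn]]))
          gen_val <- gen_val + truth_eff[[cn]][genos, env]
      }
      if (!is.null(truth_eff$AxC))
        gen_val <- gen_val + truth_eff$AxC[genos, cond]

      rep_eff <- stats::rnorm(cfg$reps, 0, sqrt(cfg$sigma2_rep))
      nb <- if (alpha_design) cfg$blocks_per_rep else 1L
      for (r in seq_len(cfg$reps)) {
        blk_eff <- if (alpha_design)
          stats::rnorm(nb, 0, sqrt(cfg$sigma2_block)) else 0
        blk <- rep_len(seq_len(nb), length(genos))
        dtf_plot <- dtf_geno[genos] + stats::rnorm(length(genos), 0, 2)
        y <- mean_t + e_env + gen_val + rep_eff[r] +
          (if (alpha_design) blk_eff[blk] else 0) +
          cfg$dtf_slope * (dtf_plot - cfg$dtf_mean) +
          stats::rnorm(length(genos), 0, resid_sd)
        y <- pmax(as.numeric(y), 0)
        rows[[length(rows) + 1L]] <- data.frame(
          genotype = genos, year = yy, season = "dry", condition = cond,
          trial = trial, rep = r, block = if (alpha_design) blk else 1L,
          design = design, gy = y,
          dtf = as.numeric(dtf_plot), stringsAsFactors = FALSE)
        gv_rows[[length(gv_rows) + 1L]] <- as.numeric(mean_t + e_env +
                                                        gen_val)
        is_entry <- genos %in% entries
        year_sum[genos[is_entry]] <- year_sum[genos[is_entry]] +
          y[is_entry]
        year_n[genos[is_entry]] <- year_n[genos[is_entry]] + 1
      }
    }
    # merit-based advancement: forward the top entries by observed mean GY
    n_seen[entries] <- n_seen[entries] + 1L
    elig <- entries[n_seen[entries] < cfg$eval_years]
    k <- floor(cfg$advance_frac * length(entries))
    carried <- if (k > 0 && length(elig) && yr < cfg$years) {
      ym <- (year_sum / pmax(year_n, 1))[elig]
      elig[order(-ym)][seq_len(min(k, length(elig)))]
    } else character(0)
  }
  pheno <- do.call(rbind, c(rows, list(make.row.names = FALSE)))

  truth <- list(effects = truth_eff, variance = vc_true,
                residual_model = list(ns = cfg$resid_sd_ns,
                                      s = cfg$resid_sd_s),
                genetic_value = unlist(gv_rows), dtf_slope = cfg$dtf_slope,
                model = cfg$model, seed = cfg$seed)
  list(pheno = pheno, truth = truth, pedigree = ped, genealogy = g,
       A = A, parents = parents, A_p1 = pm$A_p1, A_p2 = pm$A_p2)
}

#' Simulate responses directly from a kernel set
#'
#' Draws one effect vector per component from `N(0, K_k * s2_k)`, adds an
#' intercept and IID residual noise. This is the generative counterpart of
#' [fit_model()], used for parameter-recovery checks where the record-level
#' variances must be known exactly.
#'
#' @param kernels `kernel_set` (or named list of PSD kernels).
#' @param variances Named numeric: one variance per kernel component.
#' @param residual Residual variance.
#' @param intercept Intercept (default 0).
#' @param seed RNG seed.
#' @return List with `y`, per-component `effects`, and the noiseless
#'   `signal`.
#' @export
simulate_from_kernels <- function(kernels, variances, residual,
                                  intercept = 0, seed = 1L) {
  stopifnot(all(names(kernels) %in% names(variances)))
  set.seed(seed)
  n <- nrow(kernels[[1]])
  eff <- lapply(names(kernels), function(cn)
    as.numeric(mvn_draw(kernels[[cn]], variances[[cn]])))
  names(eff) <- names(kernels)
  signal <- intercept + Reduce(`+`, eff)
  list(y = signal + stats::rnorm(n, 0, sqrt(residual)),
       effects = eff, signal = signal)
}

# cross-level SCA kernel: Hadamard of the two parent kernels over crosses
make_cross_kernel <- function(parents, pm) {
  K1 <- pm$A_p1[parents$parent1, parents$parent1, drop = FALSE]
  K2 <- pm$A_p2[parents$parent2, parents$parent2, drop = FALSE]
  K <- K1 * K2
  dimnames(K) <- list(parents$id, parents$id)
  K
}

# line-level kernel induced by one parent's relationships
expand_parent_kernel <- function(parents, Ap, pcol, lines) {
  pmap <- stats::setNames(parents[[pcol]], parents$id)
  p <- pmap[lines]
  K <- Ap[p, p, drop = FALSE]
  dimnames(K) <- list(lines, lines)
  K
}

#' Per-trial Cullis heritability profile of a simulated dataset
#'
#' Applies the stage-1 genotype-random fit and the Cullis estimator to every
#' trial; used to calibrate generator configurations against the
#' heritability ranges expected of drought breeding trials (low under
#' stress, moderate-to-high under non-stress).
#'
#' @param pheno PhenotypeTable (typically `simulate_trials(cfg)$pheno`).
#' @param trait,covariate Passed to [fit_trial_model()].
#' @return data.frame (`trial`, `year`, `condition`, `h2`).
#' @export
trial_h2_profile <- function(pheno, trait = "gy",
                             covariate = if ("dtf" %in% names(pheno)) "dtf") {
  trials <- unique(as.character(pheno$trial))
  out <- lapply(trials, function(tr) {
    meta <- pheno[as.character(pheno$trial) == tr, ][1, ]
    fit <- fit_trial_model(pheno, tr, trait, covariate, "random")
    data.frame(trial = tr, year = meta$year,
               condition = as.character(meta$condition),
               h2 = suppressWarnings(cullis_heritability(fit)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Write a simulated dataset to disk (pedigree CSV, phenotype CSV, truth
#' JSON)
#' @param sim Result of [simulate_trials()].
#' @param dir Output directory.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(sim$pedigree, file.path(dir, "pedigree.csv"),
                   row.names = FALSE, na = "NA")
  utils::write.csv(sim$pheno, file.path(dir, "phenotypes.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(variance = as.list(sim$truth$variance),
         dtf_slope = sim$truth$dtf_slope,
         model = sim$truth$model, seed = sim$truth$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
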