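#' MCMC configuration for the multi-kernel sampler
#'
#' @param iterations Total Gibbs sweeps (default 12000).
#' @param burn_in Sweeps discarded before summarising (default 2000).
#' @param thin Keep every `thin`-th post-burn-in sweep (default 5).
#' @param seed Integer RNG seed; required for reproducibility.
#' @param prior_df Degrees of freedom of the scaled-inverse-chi-squared
#'   prior on every variance component (default 5).
#' @param prior_genetic_share Share of the phenotypic variance whose equal
#'   split across components sets each prior mode; the remainder goes to the
#'   residual (default 0.5).
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(iterations = 12000L, burn_in = 2000L, thin = 5L,
                        seed = 1L, prior_df = 5, prior_genetic_share = 0.5) {
  stopifnot(iterations > burn_in, burn_in >= 0, thin >= 1)
  structure(list(iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed), prior_df = prior_df,
                 prior_genetic_share = prior_genetic_share),
            class = "mcmc_config")
}

#' Fit a multi-kernel mixed model by Gibbs sampling
#'
#' Bayesian multi-kernel regression over stage-1 BLUEs. The linear predictor
#' is an intercept plus one random-effect vector per covariance kernel,
#' \eqn{y = \mu 1 + \sum_k u_k + e}, with \eqn{u_k \sim N(0, K_k
#' \sigma^2_k)} and IID residuals. Each kernel is eigendecomposed once and
#' its effect sampled in the eigenbasis (so every conditional update is
#' diagonal); variance components carry scaled-inverse-chi-squared priors.
#' Masked responses (`NA`) are treated as missing and imputed by data
#' augmentation each sweep; their posterior-mean linear predictors are the
#' predictions. Responses are centred and scaled internally and all
#' summaries are returned on the original scale.
#'
#' @param kernels `kernel_set` from [build_model_kernels()], or a named list
#'   of record-level PSD kernels.
#' @param y Numeric response vector, one entry per record; `NA` marks masked
#'   records to predict.
#' @param cfg [mcmc_config()].
#' @param records Optional data.frame (genotype, environment, ...) carried
#'   through to predictions.
#' @param fixed_variances Optional named list of variance components (on the
#'   standardised scale) to hold fixed instead of sampling; may include
#'   `residual`. Used for validation against closed forms.
#' @return An object of class `pedgxe_fit`.
#' @export
fit_model <- function(kernels, y, cfg = mcmc_config(), records = NULL,
                      fixed_variances = NULL) {
  if (!length(y)) stop("empty response")
  if (any(!is.finite(y) & !is.na(y))) stop("non-finite response value")
  obs <- which(!is.na(y))
  if (!length(obs)) stop("at least one unmasked response is required")
  n <- length(y)
  if (any(vapply(kernels, nrow, 0L) != n))
    stop("kernel dimension does not match number of records")
  y_mean <- mean(y[obs])
  y_sd <- stats::sd(y[obs])
  if (!is.finite(y_sd) || y_sd == 0) {
    if (length(obs) < 2) y_sd <- 1 else stop("zero-variance response")
  }
  z <- (y - y_mean) / y_sd
  miss <- which(is.na(y))

  comp <- names(kernels)
  K <- length(comp)
  # eigen-basis design per component: Phi = U diag(sqrt(lambda))
  Phi <- vector("list", K)
  lam <- vector("list", K)
  for (k in seq_len(K)) {
    ev <- eigen(kernels[[k]], symmetric = TRUE)
    keep <- ev$values > 1e-10
    if (!any(keep)) stop("kernel '", comp[k], "' is numerically zero")
    lam[[k]] <- ev$values[keep]
    Phi[[k]] <- ev$vectors[, keep, drop = FALSE] *
      rep(sqrt(lam[[k]]), each = n)
  }

  df0 <- cfg$prior_df
  share <- cfg$prior_genetic_share
  # prior mode df0*S0/(df0+2) = equal split of `share` of phenotypic var (=1)
  S0 <- rep((share / K) * (df0 + 2) / df0, K)
  names(S0) <- comp
  S0_e <- (1 - share) * (df0 + 2) / df0

  fixed <- rep(FALSE, K + 1L)
  names(fixed) <- c(comp, "residual")
  s2 <- S0 * df0 / (df0 + 2)
  s2_e <- S0_e * df0 / (df0 + 2)
  if (!is.null(fixed_variances)) {
    for (nm in names(fixed_variances)) {
      if (!nm %in% names(fixed)) stop("unknown fixed variance: ", nm)
      fixed[nm] <- TRUE
      if (nm == "residual") s2_e <- fixed_variances[[nm]]
      else s2[nm] <- fixed_variances[[nm]]
    }
  }

  set.seed(cfg$seed)
  alpha <- lapply(seq_len(K), function(k) numeric(length(lam[[k]])))
  u <- matrix(0, n, K)           # current effect vectors Phi alpha
  mu <- mean(z[obs])
  z_cur <- z
  if (length(miss)) z_cur[miss] <- mu

  keep_its <- seq.int(cfg$burn_in + cfg$thin, cfg$iterations, by = cfg$thin)
  n_keep <- length(keep_its)
  draws_s2 <- matrix(NA_real_, n_keep, K, dimnames = list(NULL, comp))
  draws_e <- numeric(n_keep)
  draws_mu <- numeric(n_keep)
  lp_sum <- numeric(n)
  lp_sq <- numeric(n)
  stored <- 0L

  for (it in seq_len(cfg$iterations)) {
    lp <- mu + rowSums(u)
    if (length(miss))
      z_cur[miss] <- lp[miss] + stats::rnorm(length(miss), 0, sqrt(s2_e))

    # intercept (flat prior)
    r <- z_cur - rowSums(u)
    mu <- stats::rnorm(1, mean(r), sqrt(s2_e / n))

    resid <- z_cur - mu - rowSums(u)
    for (k in seq_len(K)) {
      r_k <- resid + u[, k]
      prec <- lam[[k]] / s2_e + 1 / s2[k]
      m_k <- (crossprod(Phi[[k]], r_k) / s2_e) / prec
      alpha[[k]] <- m_k + stats::rnorm(length(prec)) / sqrt(prec)
      u_new <- as.vector(Phi[[k]] %*% alpha[[k]])
      resid <- r_k - u_new
      u[, k] <- u_new
      if (!fixed[k]) {
        ss <- sum(alpha[[k]]^2)
        mk <- length(alpha[[k]])
        s2[k] <- (df0 * S0[k] + ss) / stats::rchisq(1, df0 + mk)
      }
    }
    if (!fixed["residual"]) {
      ss_e <- sum(resid^2)
      s2_e <- (df0 * S0_e + ss_e) / stats::rchisq(1, df0 + n)
    }
    if (!is.finite(s2_e) || any(!is.finite(s2)))
      stop("divergent sampler state at iteration ", it)

    if (it > cfg$burn_in && (it - cfg$burn_in) %% cfg$thin == 0L) {
      stored <- stored + 1L
      draws_s2[stored, ] <- s2
      draws_e[stored] <- s2_e
      draws_mu[stored] <- mu
      lp_now <- mu + rowSums(u)
      lp_sum <- lp_sum + lp_now
      lp_sq <- lp_sq + lp_now^2
    }
  }

  lp_mean <- lp_sum / n_keep
  vc_draws <- cbind(draws_s2, residual = draws_e) * y_sd^2
  vc_mean <- colMeans(vc_draws)
  vc_sd <- apply(vc_draws, 2, stats::sd)
  ess <- apply(vc_draws, 2, ess_univariate)

  structure(list(
    model = attr(kernels, "model"),
    components = comp,
    symbols = attr(kernels, "symbols"),
    vc_mean = vc_mean, vc_sd = vc_sd, ess = ess,
    vc_draws = vc_draws,
    intercept = y_mean + y_sd * mean(draws_mu),
    linear_predictor = y_mean + y_sd * lp_mean,
    lp_sd = y_sd * sqrt(pmax(lp_sq / n_keep - (lp_sum / n_keep)^2, 0)),
    y = y, masked = miss, records = records,
    scale = c(center = y_mean, sd = y_sd),
    cfg = cfg, n_kept = n_keep), class = "pedgxe_fit")
}

# initial-positive-sequence effective sample size for one chain
ess_univariate <- function(x) {
  n <- length(x)
  if (n < 10 || stats::sd(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 1, 100), plot = FALSE)$acf[-1]
  s <- 0
  for (rho in ac) {
    if (rho <= 0) break
    s <- s + rho
  }
  max(1, n / (1 + 2 * s))
}

#' Predictions for masked records
#'
#' Returns the posterior-mean linear predictor restricted to the records
#' whose responses were masked during fitting, keyed by genotype and
#' environment when record metadata were supplied.
#'
#' @param fit `pedgxe_fit` from [fit_model()].
#' @return data.frame with columns `record`, `prediction` (original scale),
#'   plus `genotype`/`environment` when available.
#' @export
predict_masked <- function(fit) {
  stopifnot(inherits(fit, "pedgxe_fit"))
  if (!length(fit$masked)) {
    warning("fit contains no masked records")
    return(data.frame(record = integer(0), prediction = numeric(0)))
  }
  out <- data.frame(record = fit$masked,
                    prediction = fit$linear_predictor[fit$masked])
  if (!is.null(fit$records)) {
    out$genotype <- fit$records$genotype[fit$masked]
    out$environment <- fit$records$environment[fit$masked]
  }
  out
}

#' Posterior variance-component table
#'
#' One row per variance component (including the residual): posterior mean,
#' posterior SD, effective sample size, and the proportion of total variance.
#'
#' @param fit `pedgxe_fit`.
#' @return data.frame; proportions sum to 1.
#' @export
variance_summary <- function(fit) {
  stopifnot(inherits(fit, "pedgxe_fit"))
  tot <- sum(fit$vc_mean)
  syms <- fit$symbols
  if (is.null(syms)) syms <- vapply(fit$components, component_symbol, "")
  syms[is.na(syms)] <- fit$components[is.na(syms)]
  data.frame(component = names(fit$vc_mean),
             symbol = c(unname(syms), "sigma2"),
             mean = unname(fit$vc_mean),
             sd = unname(fit$vc_sd),
             ess = unname(fit$ess),
             proportion = unname(fit$vc_mean) / tot,
             row.names = NULL)
}

#' @export
print.pedgxe_fit <- function(x, ...) {
  cat("Multi-kernel pedigree model",
      if (!is.null(x$model)) paste0("(", x$model, ")"), "\n")
  cat("  records:", length(x$y), " masked:", length(x$masked), "\n")
  cat("  components:", paste(x$components, collapse = " + "), "\n")
  cat("  MCMC:", x$cfg$iterations, "sweeps,", x$cfg$burn_in, "burn-in, thin",
      x$cfg$thin, "(", x$n_kept, "kept ), seed", x$cfg$seed, "\n")
  cat("  intercept:", format(x$intercept, digits = 5), "\n")
  invisible(x)
}

#' @export
summary.pedgxe_fit <- function(object, ...) {
  vs <- variance_summary(object)
  structure(list(fit = object, variance = vs), class = "summary.pedgxe_fit")
}

#' @export
print.summary.pedgxe_fit <- function(x, ...) {
  print(x$fit)
  cat("\nVariance components (posterior):\n")
  vs <- x$variance
  vs$mean <- signif(vs$mean, 4); vs$sd <- signif(vs$sd, 3)
  vs$ess <- round(vs$ess); vs$proportion <- signif(vs$proportion, 3)
  print(vs, row.names = FALSE)
  invisible(x)
}

#' @export
coef.pedgxe_fit <- function(object, ...) object$vc_mean

#' @export
fitted.pedgxe_fit <- function(object, ...) object$linear_predictor

#' @export
residuals.pedgxe_fit <- function(object, ...) {
  r <- object$y - object$linear_predictor
  r  # NA at masked records
}

#' @export
predict.pedgxe_fit <- function(object, what = c("masked", "all"), ...) {
  what <- match.arg(what)
  if (what == "all") return(object$linear_predictor)
  predict_masked(object)
}

#' @export
plot.pedgxe_fit <- function(x, ...) {
  vs <- variance_summary(x)
  graphics::barplot(vs$proportion, names.arg = vs$component, las = 2,
                    ylab = "proportion of total variance",
                    main = paste("Variance decomposition",
                                 if (!is.null(x$model)) x$model else ""))
  invisible(x)
}

#' Serialise a fit: JSON summaries plus TSV per-record predictions
#'
#' @param fit `pedgxe_fit`.
#' @param dir Output directory.
#' @export
export_fit <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vs <- variance_summary(fit)
  jsonlite::write_json(
    list(model = fit$model, intercept = fit$intercept,
         components = vs, mcmc = unclass(fit$cfg)),
    file.path(dir, "fit.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  pred <- data.frame(record = seq_along(fit$y), observed = fit$y,
                     predicted = fit$linear_predictor,
                     masked = seq_along(fit$y) %in% fit$masked)
  utils::write.table(pred, file.path(dir, "predictions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
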