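# Independent oracles used to validate the package's implementations.
# These deliberately use brute-force formulations (gene dropping, direct
# matrix inversion, profiled likelihood scans, full-covariance Gibbs) and
# share no code with the package internals.

# --- gene-dropping Monte Carlo estimate of the additive relationship matrix
# ped must be topologically ordered (parents before children); unknown
# parents contribute unique founder alleles.
gene_drop_A <- function(ped, n_drops = 20000, seed = 1) {
  set.seed(seed)
  n <- nrow(ped)
  p1 <- match(ped$parent1, ped$id)
  p2 <- match(ped$parent2, ped$id)
  a1 <- matrix(0L, n, n_drops)
  a2 <- matrix(0L, n, n_drops)
  for (k in seq_len(n)) {
    if (is.na(p1[k])) {
      a1[k, ] <- 4L * k - 3L
    } else {
      pick <- stats::runif(n_drops) < 0.5
      a1[k, ] <- ifelse(pick, a1[p1[k], ], a2[p1[k], ])
    }
    if (is.na(p2[k])) {
      a2[k, ] <- 4L * k - 1L
    } else {
      pick <- stats::runif(n_drops) < 0.5
      a2[k, ] <- ifelse(pick, a1[p2[k], ], a2[p2[k], ])
    }
  }
  A_hat <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  A_se <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (i == j) {
        x <- 1 + (a1[i, ] == a2[i, ])
      } else {
        x <- 0.5 * ((a1[i, ] == a1[j, ]) + (a1[i, ] == a2[j, ]) +
                      (a2[i, ] == a1[j, ]) + (a2[i, ] == a2[j, ]))
      }
      A_hat[i, j] <- A_hat[j, i] <- mean(x)
      A_se[i, j] <- A_se[j, i] <- stats::sd(x) / sqrt(n_drops)
    }
  }
  list(A = A_hat, se = A_se)
}

# random valid pedigree of at most n_max members (founders first, children
# drawn from earlier members, occasional selfing / unknown single parents)
random_pedigree <- function(n_max = 12, seed = 1) {
  set.seed(seed)
  n_f <- sample(2:4, 1)
  n <- sample((n_f + 2):n_max, 1)
  id <- sprintf("I%02d", seq_len(n))
  parent1 <- rep(NA_character_, n)
  parent2 <- rep(NA_character_, n)
  for (k in (n_f + 1):n) {
    pool <- id[seq_len(k - 1)]
    parent1[k] <- sample(pool, 1)
    parent2[k] <- if (stats::runif(1) < 0.15) parent1[k] else sample(pool, 1)
    if (stats::runif(1) < 0.1) parent2[k] <- NA_character_
  }
  data.frame(id = id, parent1 = parent1, parent2 = parent2,
             stringsAsFactors = FALSE)
}

# --- direct GLS by matrix inversion: beta, cov(beta)
gls_oracle <- function(y, X, Zlist = list(), varcomp = numeric(0),
                       sigma2 = 1) {
  n <- length(y)
  V <- diag(sigma2, n)
  for (i in seq_along(Zlist)) V <- V + varcomp[i] * tcrossprod(Zlist[[i]])
  Vi <- solve(V)
  cb <- solve(t(X) %*% Vi %*% X)
  list(beta = drop(cb %*% t(X) %*% Vi %*% y), cov = cb)
}

# profiled REML log-likelihood at a given variance ratio lambda
reml_profile_ll <- function(y, X, Z, lam) {
  n <- length(y); p <- qr(X)$rank
  W <- diag(n) + lam * tcrossprod(Z)
  Wi <- solve(W)
  XtWiX <- t(X) %*% Wi %*% X
  B <- solve(XtWiX, t(X) %*% Wi)
  Py <- Wi %*% (y - X %*% (B %*% y))
  s2e <- drop(t(y) %*% Py) / (n - p)
  -0.5 * (determinant(W)$modulus + determinant(XtWiX)$modulus +
            (n - p) * log(s2e) + (n - p))
}

# --- profiled REML scan for one random term plus residual
# V = s2e (I + lambda Z Z'); for each lambda on a log grid, s2e has a
# closed-form REML estimate; returns the maximiser.
reml_profile_oracle <- function(y, X, Z, n_grid = 4001,
                                lambda_range = c(1e-6, 1e6)) {
  n <- length(y); p <- qr(X)$rank
  lambdas <- exp(seq(log(lambda_range[1]), log(lambda_range[2]),
                     length.out = n_grid))
  best <- list(ll = -Inf)
  ZZt <- tcrossprod(Z)
  for (lam in lambdas) {
    W <- diag(n) + lam * ZZt
    Wi <- solve(W)
    XtWiX <- t(X) %*% Wi %*% X
    B <- solve(XtWiX, t(X) %*% Wi)
    Py <- Wi %*% (y - X %*% (B %*% y))
    quad <- drop(t(y) %*% Py)
    s2e <- quad / (n - p)
    ll <- -0.5 * (determinant(W)$modulus + determinant(XtWiX)$modulus +
                    (n - p) * log(s2e) + (n - p))
    if (ll > best$ll)
      best <- list(ll = ll, lambda = lam, sigma2 = s2e,
                   sigma2_u = lam * s2e)
  }
  best
}

# --- BLUP predictions at fixed variances via the joint covariance
# (direct mixed-model-equation / conditional-normal solution)
blup_oracle <- function(kernels, variances, sigma2_e, y) {
  n <- length(y)
  S <- Reduce(`+`, Map(function(K, v) v * K, kernels,
                       variances[names(kernels)]))
  obs <- which(!is.na(y))
  Vo <- S[obs, obs] + diag(sigma2_e, length(obs))
  Vi <- solve(Vo)
  one <- rep(1, length(obs))
  mu <- drop((t(one) %*% Vi %*% y[obs]) / (t(one) %*% Vi %*% one))
  drop(mu + S[, obs] %*% Vi %*% (y[obs] - mu))
}

# --- naive full-covariance Gibbs sampler (oracle for the eigen-basis one)
# Samples each effect vector from its exact conditional using the joint
# normal formula, and variances from scaled-inverse-chi-square updates with
# the kernel pseudo-inverse quadratic form.
naive_gibbs <- function(kernels, y, iterations = 4000, burn_in = 1000,
                        seed = 1, df0 = 5, share = 0.5) {
  set.seed(seed)
  n <- length(y)
  obs <- which(!is.na(y)); miss <- which(is.na(y))
  ym <- mean(y[obs]); ys <- stats::sd(y[obs])
  z <- (y - ym) / ys
  K <- length(kernels)
  eig <- lapply(kernels, function(k) {
    e <- eigen(k, symmetric = TRUE)
    keep <- e$values > 1e-10
    list(U = e$vectors[, keep, drop = FALSE], d = e$values[keep])
  })
  S0 <- rep((share / K) * (df0 + 2) / df0, K)
  S0e <- (1 - share) * (df0 + 2) / df0
  s2 <- S0 * df0 / (df0 + 2); s2e <- S0e * df0 / (df0 + 2)
  b <- matrix(0, n, K)
  mu <- mean(z[obs]); zc <- z; if (length(miss)) zc[miss] <- mu
  lp_sum <- numeric(n); s2_sum <- numeric(K); s2e_sum <- 0; kept <- 0
  for (it in seq_len(iterations)) {
    lp <- mu + rowSums(b)
    if (length(miss)) zc[miss] <- lp[miss] + stats::rnorm(length(miss), 0,
                                                          sqrt(s2e))
    mu <- stats::rnorm(1, mean(zc - rowSums(b)), sqrt(s2e / n))
    for (k in seq_len(K)) {
      r <- zc - mu - rowSums(b[, -k, drop = FALSE])
      Sk <- s2[k] * kernels[[k]]
      M <- Sk + diag(s2e, n)
      W <- Sk %*% solve(M)
      m_post <- drop(W %*% r)
      C_post <- Sk - W %*% Sk
      L <- chol(C_post + diag(1e-9, n))
      b[, k] <- m_post + drop(crossprod(L, stats::rnorm(n)))
      # quadratic form via pseudo-inverse in the kernel eigenbasis
      proj <- crossprod(eig[[k]]$U, b[, k])
      qf <- sum(proj^2 / eig[[k]]$d)
      mk <- length(eig[[k]]$d)
      s2[k] <- (df0 * S0[k] + qf) / stats::rchisq(1, df0 + mk)
    }
    res <- zc - mu - rowSums(b)
    s2e <- (df0 * S0e + sum(res^2)) / stats::rchisq(1, df0 + n)
    if (it > burn_in) {
      kept <- kept + 1
      lp_sum <- lp_sum + mu + rowSums(b)
      s2_sum <- s2_sum + s2; s2e_sum <- s2e_sum + s2e
    }
  }
  list(prediction = ym + ys * lp_sum / kept,
       s2 = ys^2 * s2_sum / kept, s2e = ys^2 * s2e_sum / kept)
}

# small genotype-by-environment record grid with an unrelated-founder A
toy_records <- function(n_g = 10, n_e = 3, related = FALSE, seed = 1) {
  ids <- sprintf("G%02d", seq_len(n_g))
  if (related) {
    ped <- random_pedigree(n_max = n_g + 4, seed = seed)
  } else {
    ped <- data.frame(id = ids, parent1 = NA_character_,
                      parent2 = NA_character_, stringsAsFactors = FALSE)
  }
  g <- build_genealogy(ped)
  A <- additive_relationship(g)
  gl <- if (related) g$id[seq_len(min(n_g, length(g$id)))] else ids
  rec <- expand.grid(genotype = gl, environment = paste0("E", seq_len(n_e)),
                     stringsAsFactors = FALSE)
  list(records = rec, A = A, genealogy = g)
}
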