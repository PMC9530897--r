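# Shared small-data generators for the test suite.

# balanced RCBD phenotype table for stage-1 checks
make_rcbd <- function(n_g = 5, n_r = 3, sigma_e = 1, sigma_r = 0.5,
                      means = NULL, seed = 1, trial = "T1",
                      condition = "non-stress", dtf_slope = 0) {
  set.seed(seed)
  if (is.null(means)) means <- 100 + seq_len(n_g) * 10
  g <- sprintf("G%02d", seq_len(n_g))
  d <- expand.grid(genotype = g, rep = seq_len(n_r),
                   stringsAsFactors = FALSE)
  rep_eff <- stats::rnorm(n_r, 0, sigma_r)
  d$dtf <- stats::rnorm(nrow(d), 85, 4)
  d$gy <- means[match(d$genotype, g)] + rep_eff[d$rep] +
    dtf_slope * (d$dtf - 85) + stats::rnorm(nrow(d), 0, sigma_e)
  d$year <- 2001L; d$season <- "dry"; d$condition <- condition
  d$trial <- trial; d$block <- 1L; d$design <- "RCBD"
  d
}

# synthetic BLUE table spanning years x conditions
make_blues <- function(n_g = 20, years = 4, seed = 1) {
  set.seed(seed)
  g <- sprintf("G%02d", seq_len(n_g))
  bl <- expand.grid(genotype = g, year = 2000 + seq_len(years),
                    condition = c("non-stress", "stress"),
                    stringsAsFactors = FALSE)
  bl$environment <- paste(bl$year, bl$condition, sep = "_")
  bl$blue <- stats::rnorm(nrow(bl), 3000, 500)
  bl$se <- stats::runif(nrow(bl), 100, 200)
  bl
}
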