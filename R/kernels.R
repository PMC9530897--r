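#' Incidence matrix connecting records to factor levels
#'
#' Builds the 0/1 matrix with one row per phenotypic record and one column
#' per level of a factor (genotype, environment, parent-1 or parent-2
#' identity), exactly one 1 per row. Level ordering is deterministic
#' (sorted).
#'
#' @param levels_per_record Character vector giving, for each record, its
#'   level of the factor.
#' @param levels Optional full level set (sorted if omitted).
#' @return Numeric 0/1 matrix, `length(levels_per_record)` rows.
#' @export
incidence <- function(levels_per_record, levels = NULL) {
  if (anyNA(levels_per_record))
    stop("record ", which(is.na(levels_per_record))[1],
         " has no level for this factor")
  if (is.null(levels)) levels <- sort(unique(levels_per_record))
  j <- match(levels_per_record, levels)
  if (anyNA(j))
    stop("record level not in supplied level set: ",
         levels_per_record[which(is.na(j))[1]])
  Z <- matrix(0, length(j), length(levels),
              dimnames = list(NULL, levels))
  Z[cbind(seq_along(j), j)] <- 1
  Z
}

#' Main-effect covariance kernel Z K Z'
#'
#' Expands a level-level relationship matrix `K` to record level through an
#' incidence matrix. With `K = NULL` (identity) this gives the block
#' structure `Z Z'` used for environment main effects.
#'
#' @param Z Incidence matrix from [incidence()].
#' @param K Relationship matrix over the columns of `Z`, or `NULL` for
#'   identity. Column names of `Z` must match `rownames(K)`.
#' @return Symmetric record-by-record kernel matrix.
#' @export
main_effect_kernel <- function(Z, K = NULL) {
  if (is.null(K)) return(tcrossprod(Z))
  if (ncol(Z) != nrow(K))
    stop("incidence/relationship dimension mismatch: ",
         ncol(Z), " vs ", nrow(K))
  if (!is.null(colnames(Z)) && !is.null(rownames(K))) {
    if (!all(colnames(Z) == rownames(K)))
      K <- K[colnames(Z), colnames(Z), drop = FALSE]
  }
  Z %*% K %*% t(Z)
}

#' Hadamard (cell-by-cell) product of covariance kernels
#'
#' The entrywise product of two PSD kernels is the covariance of a
#' multiplicative interaction term (Schur product theorem keeps it PSD).
#' Used for A-by-environment, SCA, GCA-by-environment and
#' SCA-by-environment components.
#'
#' @param ... Two or more record-level kernels of identical dimension.
#' @return Entrywise product matrix.
#' @export
hadamard_interaction <- function(...) {
  ks <- list(...)
  dims <- vapply(ks, nrow, 0L)
  if (length(unique(dims)) != 1L)
    stop("kernel dimension mismatch: ", paste(dims, collapse = ", "))
  Reduce(`*`, ks)
}

#' Component registry for models M1-M7
#'
#' Each model is a fixed ordered list of variance components:
#' \describe{
#'   \item{M1}{E + A}
#'   \item{M2}{E + A + AxE}
#'   \item{M3}{E + GCA1 + GCA2}
#'   \item{M4}{E + GCA1 + GCA2 + SCA}
#'   \item{M5}{E + GCA1 + GCA2 + SCA + GCA1xE + GCA2xE + SCAxE}
#'   \item{M6}{E + GCA1 + GCA2 + SCA + GCA1xE + GCA2xE + AxE}
#'   \item{M7}{E + GCA1 + GCA2 + A + GCA1xE + GCA2xE + AxE}
#' }
#'
#' @param model Model id, "M1".."M7".
#' @return Character vector of component names.
#' @export
model_components <- function(model) {
  reg <- list(
    M1 = c("E", "A"),
    M2 = c("E", "A", "AxE"),
    M3 = c("E", "GCA1", "GCA2"),
    M4 = c("E", "GCA1", "GCA2", "SCA"),
    M5 = c("E", "GCA1", "GCA2", "SCA", "GCA1xE", "GCA2xE", "SCAxE"),
    M6 = c("E", "GCA1", "GCA2", "SCA", "GCA1xE", "GCA2xE", "AxE"),
    M7 = c("E", "GCA1", "GCA2", "A", "GCA1xE", "GCA2xE", "AxE"))
  if (!model %in% names(reg)) stop("unknown model id: ", model)
  reg[[model]]
}

#' Variance-component symbol carried by each kernel component
#' @param component Component name from [model_components()].
#' @return The conventional symbol as a string.
#' @export
component_symbol <- function(component) {
  sym <- c(E = "sigma2_E", A = "sigma2_a", AxE = "sigma2_aE",
           GCA1 = "sigma2_aP1", GCA2 = "sigma2_aP2",
           SCA = "sigma2_aP1xP2", GCA1xE = "sigma2_aE_P1",
           GCA2xE = "sigma2_aE_P2", SCAxE = "sigma2_aE_P1xP2")
  unname(sym[component])
}

#' Build the kernel set for one model over a record table
#'
#' Assembles, for the requested model, every record-level covariance kernel:
#' environment blocks `Z_E Z_E'`, the pedigree kernel `Z_g A Z_g'`, GCA
#' kernels over the parent relationship matrices, and the Hadamard-product
#' interaction kernels (A-by-E, SCA, GCA-by-E, SCA-by-E).
#'
#' @param model Model id "M1".."M7".
#' @param records data.frame with columns `genotype` and `environment`, one
#'   row per record (stage-1 BLUE), plus `parent1`/`parent2` where the model
#'   needs them (supplied via `parents`).
#' @param A Additive relationship matrix covering every genotype in
#'   `records` (required for models with an A term).
#' @param parents Optional data.frame `id, parent1, parent2` mapping
#'   genotypes to parents (required for M3-M7).
#' @param A_p1,A_p2 Parent relationship matrices from
#'   [parent_relationship_matrices()] (required for M3-M7).
#' @return A list of class `kernel_set`: named list of kernels in registry
#'   order, with attributes `model` and `symbols`.
#' @export
build_model_kernels <- function(model, records, A = NULL, parents = NULL,
                                A_p1 = NULL, A_p2 = NULL) {
  comps <- model_components(model)
  n <- nrow(records)
  kernels <- list()

  Z_E <- incidence(as.character(records$environment))
  K_E <- tcrossprod(Z_E)

  need_A <- any(comps %in% c("A", "AxE"))
  if (need_A) {
    if (is.null(A)) stop("model ", model, " needs an A matrix")
    gl <- sort(unique(as.character(records$genotype)))
    missing_g <- setdiff(gl, rownames(A))
    if (length(missing_g))
      stop("genotypes absent from A: ", paste(utils::head(missing_g, 5),
                                              collapse = ", "))
    Z_g <- incidence(as.character(records$genotype), gl)
    K_A <- main_effect_kernel(Z_g, A[gl, gl, drop = FALSE])
  }

  need_par <- any(comps %in% c("GCA1", "GCA2", "SCA", "GCA1xE", "GCA2xE",
                               "SCAxE"))
  if (need_par) {
    if (is.null(parents) || is.null(A_p1) || is.null(A_p2))
      stop("model ", model, " needs parent maps and A_p1/A_p2")
    m <- match(as.character(records$genotype), parents$id)
    bad <- unique(as.character(records$genotype)[is.na(m)])
    if (length(bad))
      stop("genotypes without resolved parents for ", model, ": ",
           paste(utils::head(bad, 5), collapse = ", "))
    p1 <- parents$parent1[m]
    p2 <- parents$parent2[m]
    Z_p1 <- incidence(p1, rownames(A_p1))
    Z_p2 <- incidence(p2, rownames(A_p2))
    K_G1 <- main_effect_kernel(Z_p1, A_p1)
    K_G2 <- main_effect_kernel(Z_p2, A_p2)
  }

  for (cn in comps) {
    kernels[[cn]] <- switch(cn,
      E = K_E,
      A = K_A,
      AxE = hadamard_interaction(K_A, K_E),
      GCA1 = K_G1,
      GCA2 = K_G2,
      SCA = hadamard_interaction(K_G1, K_G2),
      GCA1xE = hadamard_interaction(K_G1, K_E),
      GCA2xE = hadamard_interaction(K_G2, K_E),
      SCAxE = hadamard_interaction(K_G1, K_G2, K_E))
  }
  structure(kernels, class = "kernel_set", model = model,
            symbols = vapply(comps, component_symbol, ""),
            n_records = n)
}

#' Export a kernel set for inspection
#'
#' Writes one TSV per component plus a JSON manifest (model id, component
#' names, dimensions).
#'
#' @param ks `kernel_set` from [build_model_kernels()].
#' @param dir Output directory (created if needed).
#' @export
export_kernel_set <- function(ks, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (cn in names(ks)) {
    utils::write.table(ks[[cn]], file.path(dir, paste0(cn, ".tsv")),
                       sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  manifest <- list(model = attr(ks, "model"),
                   components = names(ks),
                   symbols = unname(attr(ks, "symbols")),
                   n_records = attr(ks, "n_records"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
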