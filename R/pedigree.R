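#' Read a three-column pedigree file
#'
#' Reads pedigree records from a delimited text file with a header row
#' `id,parent1,parent2` (comma- or tab-delimited; the delimiter is sniffed
#' from the header when not given). Configurable missing-value tokens are
#' mapped to unknown parents.
#'
#' @param path Path to the pedigree file.
#' @param sep Field delimiter; `NULL` (default) sniffs "," vs tab from the
#'   header line.
#' @param na_tokens Character vector of tokens denoting an unknown parent.
#' @return A data.frame with character columns `id`, `parent1`, `parent2`;
#'   unknown parents are `NA`. Rows are in file order.
#' @export
read_pedigree <- function(path, sep = NULL, na_tokens = c("NA", "", "0")) {
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  header <- readLines(path, n = 1L)
  if (is.null(sep)) sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", strip.white = TRUE,
                           na.strings = character(0), quote = "\"",
                           comment.char = "", fill = TRUE)
  if (ncol(raw) < 3L)
    stop("pedigree file must have three columns (id, parent1, parent2)")
  bad <- which(apply(raw[, 1:3, drop = FALSE], 1L, function(r) any(is.na(r))))
  if (length(bad))
    stop("malformed pedigree row at line ", bad[1] + 1L)
  ped <- data.frame(id = raw[[1]], parent1 = raw[[2]], parent2 = raw[[3]],
                    stringsAsFactors = FALSE)
  ped$parent1[ped$parent1 %in% na_tokens] <- NA_character_
  ped$parent2[ped$parent2 %in% na_tokens] <- NA_character_
  validate_pedigree(ped)
  ped
}

validate_pedigree <- function(ped) {
  if (any(!nzchar(ped$id)))
    stop("empty genotype id in pedigree")
  dup <- ped$id[duplicated(ped$id)]
  if (length(dup))
    stop("duplicated pedigree id: ", dup[1])
  selfp <- ped$id == ped$parent1 | ped$id == ped$parent2
  selfp[is.na(selfp)] <- FALSE
  if (any(selfp))
    stop("genotype listed as its own parent: ", ped$id[which(selfp)[1]])
  invisible(ped)
}

#' Build a validated, topologically ordered genealogy
#'
#' Orders pedigree records so that every parent precedes all of its
#' offspring, assigns generation depths (founders = 0), detects cycles, and
#' truncates ancestry depth: counting upward from the phenotyped (terminal)
#' lines, any ancestor more than `max_depth` generations above them is
#' dropped and the ancestor at exactly `max_depth` is re-declared a founder.
#' Parents referenced but never listed as records are added as founders.
#'
#' @param ped Pedigree data.frame from [read_pedigree()].
#' @param max_depth Maximum number of ancestral generations retained above
#'   the phenotyped set (default 7).
#' @param phenotyped Optional character vector of phenotyped line ids; by
#'   default the terminal lines (ids that are nobody's parent).
#' @return An object of class `genealogy`: a list with `id`, `parent1`,
#'   `parent2` (in topological order, `NA` = founder) and `generation`.
#' @export
build_genealogy <- function(ped, max_depth = 7L, phenotyped = NULL) {
  validate_pedigree(ped)
  ped <- ped[, c("id", "parent1", "parent2")]
  ids <- ped$id
  # implicit founders: parents that never appear as an id
  refs <- setdiff(stats::na.omit(c(ped$parent1, ped$parent2)), ids)
  if (length(refs)) {
    ped <- rbind(data.frame(id = refs, parent1 = NA_character_,
                            parent2 = NA_character_, stringsAsFactors = FALSE),
                 ped)
    ids <- ped$id
  }
  n <- nrow(ped)
  idx <- match(ped$id, ped$id)
  p1 <- match(ped$parent1, ped$id)
  p2 <- match(ped$parent2, ped$id)

  # Kahn topological sort over parent -> child edges
  indeg <- (!is.na(p1)) + (!is.na(p2))
  children <- vector("list", n)
  for (k in seq_len(n)) {
    for (p in c(p1[k], p2[k])) {
      if (!is.na(p)) children[[p]] <- c(children[[p]], k)
    }
  }
  order <- integer(0)
  queue <- which(indeg == 0L)
  indeg_work <- indeg
  while (length(queue)) {
    k <- queue[1]; queue <- queue[-1]
    order <- c(order, k)
    for (ch in children[[k]]) {
      indeg_work[ch] <- indeg_work[ch] - 1L
      if (indeg_work[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) < n) {
    left <- setdiff(seq_len(n), order)
    cyc <- trace_cycle(left, p1, p2, ped$id)
    stop("pedigree contains a cycle: ", paste(cyc, collapse = " -> "))
  }

  gen <- integer(n)
  for (k in order) {
    pg <- c(if (!is.na(p1[k])) gen[p1[k]], if (!is.na(p2[k])) gen[p2[k]])
    gen[k] <- if (length(pg)) 1L + max(pg) else 0L
  }

  # distance upward from the phenotyped set
  if (is.null(phenotyped)) {
    is_parent <- ped$id %in% c(ped$parent1, ped$parent2)
    phenotyped <- ped$id[!is_parent]
  }
  up <- rep.int(NA_integer_, n)
  up[match(intersect(phenotyped, ped$id), ped$id)] <- 0L
  for (k in rev(order)) {  # children before parents
    if (is.na(up[k])) next
    for (p in c(p1[k], p2[k])) {
      if (!is.na(p)) {
        cand <- up[k] + 1L
        if (is.na(up[p]) || cand < up[p]) up[p] <- cand
      }
    }
  }
  up[is.na(up)] <- 0L  # lines unreachable from the phenotyped set: keep as-is

  keep <- up <= max_depth
  ord_keep <- order[keep[order]]
  ped2 <- ped[ord_keep, , drop = FALSE]
  dropped <- ped$id[!keep]
  ped2$parent1[ped2$parent1 %in% dropped] <- NA_character_
  ped2$parent2[ped2$parent2 %in% dropped] <- NA_character_
  # ancestors at exactly max_depth become founders
  at_edge <- up[ord_keep] == max_depth
  ped2$parent1[at_edge] <- NA_character_
  ped2$parent2[at_edge] <- NA_character_

  gen2 <- integer(nrow(ped2))
  q1 <- match(ped2$parent1, ped2$id)
  q2 <- match(ped2$parent2, ped2$id)
  for (k in seq_len(nrow(ped2))) {
    pg <- c(if (!is.na(q1[k])) gen2[q1[k]], if (!is.na(q2[k])) gen2[q2[k]])
    gen2[k] <- if (length(pg)) 1L + max(pg) else 0L
  }

  structure(list(id = ped2$id, parent1 = ped2$parent1, parent2 = ped2$parent2,
                 generation = gen2, phenotyped = intersect(phenotyped, ped2$id),
                 n_dropped = length(dropped)),
            class = "genealogy")
}

trace_cycle <- function(left, p1, p2, ids) {
  # walk parent links from any unresolved node until a repeat
  k <- left[1]
  seen <- integer(0)
  while (!(k %in% seen)) {
    seen <- c(seen, k)
    nxt <- c(p1[k], p2[k])
    nxt <- nxt[!is.na(nxt) & nxt %in% left]
    if (!length(nxt)) break
    k <- nxt[1]
  }
  start <- which(seen == k)
  ids[c(seen[start:length(seen)], k)]
}

#' Additive (numerator) relationship matrix by the tabular method
#'
#' Applies Henderson's recursive tabular rules over a topologically ordered
#' genealogy: founders get a diagonal of 1 and zero relationship to earlier
#' lines; a line k with parents (s, d) gets \eqn{A_{ki} = 0.5 (A_{si} +
#' A_{di})} for earlier i and \eqn{A_{kk} = 1 + 0.5 A_{sd}}. An unknown
#' parent contributes nothing (treated as an unrelated, non-inbred founder).
#'
#' @param g A `genealogy` from [build_genealogy()].
#' @return A symmetric numeric matrix with `dimnames` the genealogy ids.
#'   Diagonal entries are `1 + F` with inbreeding coefficient `F in [0, 1]`.
#' @export
additive_relationship <- function(g) {
  stopifnot(inherits(g, "genealogy"))
  n <- length(g$id)
  p1 <- match(g$parent1, g$id)
  p2 <- match(g$parent2, g$id)
  A <- matrix(0, n, n, dimnames = list(g$id, g$id))
  for (k in seq_len(n)) {
    s <- p1[k]; d <- p2[k]
    if (k > 1L) {
      i <- seq_len(k - 1L)
      row <- numeric(k - 1L)
      if (!is.na(s)) row <- row + 0.5 * A[s, i]
      if (!is.na(d)) row <- row + 0.5 * A[d, i]
      A[k, i] <- row
      A[i, k] <- row
    }
    A[k, k] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  A
}

#' Relationship matrices over the two parent sets of phenotyped crosses
#'
#' For GCA/SCA models the additive relationship matrix is needed over the
#' distinct parent-1 and parent-2 identities of the phenotyped crosses,
#' together with a map from each cross to its row in each. Crosses with an
#' unresolved parent are reported and excluded.
#'
#' @param crosses data.frame with columns `id`, `parent1`, `parent2` for the
#'   phenotyped lines (parent roles as recorded, not maternal/paternal).
#' @param A Full additive relationship matrix covering all parents
#'   (from [additive_relationship()]).
#' @return List with `A_p1`, `A_p2` (sub-matrices of `A`), `map` (data.frame
#'   id, parent1, parent2 for usable crosses) and `excluded` (ids lacking a
#'   resolvable parent).
#' @export
parent_relationship_matrices <- function(crosses, A) {
  ok <- !is.na(crosses$parent1) & !is.na(crosses$parent2) &
    crosses$parent1 %in% rownames(A) & crosses$parent2 %in% rownames(A)
  excluded <- crosses$id[!ok]
  use <- crosses[ok, , drop = FALSE]
  if (!nrow(use)) stop("no crosses with both parents resolvable")
  p1 <- sort(unique(use$parent1))
  p2 <- sort(unique(use$parent2))
  list(A_p1 = A[p1, p1, drop = FALSE],
       A_p2 = A[p2, p2, drop = FALSE],
       map = use,
       excluded = excluded)
}

#' Write / read a relationship matrix as TSV
#'
#' Round-trips a labelled symmetric matrix through a TSV with an id header
#' row and id first column, lossless to 12 significant digits.
#'
#' @param A Relationship matrix with dimnames.
#' @param path Output path.
#' @export
write_relationship_matrix <- function(A, path) {
  df <- data.frame(id = rownames(A),
                   signif(A, 15),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_relationship_matrix
#' @export
read_relationship_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  A <- as.matrix(df[, -1, drop = FALSE])
  rownames(A) <- df$id
  storage.mode(A) <- "double"
  A
}

#' @export
print.genealogy <- function(x, ...) {
  cat("Genealogy:", length(x$id), "lines,",
      sum(is.na(x$parent1) & is.na(x$parent2)), "founders, max generation",
      max(x$generation), "\n")
  if (x$n_dropped)
    cat("  (", x$n_dropped, "deep ancestors truncated )\n")
  invisible(x)
}
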