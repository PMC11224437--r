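MISSING_CHARS <- c("-", "?")

# logical matrix of cells that are gap/missing/ambiguous (not a residue state)
is_missing_mat <- function(mat, alphabet) {
  m <- matrix(!(mat %in% alphabet_states(alphabet)), nrow = nrow(mat))
  dimnames(m) <- dimnames(mat)
  m
}

#' Remove gap-rich columns from a locus alignment
#'
#' Columns whose gap + missing fraction (over the taxa present in the
#' alignment) exceeds `max_gap_frac` are removed. The retained columns'
#' original indices are kept in the `"provenance"` attribute.
#'
#' @param aln A `locus_aln`.
#' @param max_gap_frac Maximum tolerated gap/missing fraction per column,
#'   in `[0, 1]` (default 0.5).
#' @return A trimmed `locus_aln` (empty, with a warning, if all columns are
#'   removed).
#' @export
trim_columns <- function(aln, max_gap_frac = 0.5) {
  stopifnot(inherits(aln, "locus_aln"),
            max_gap_frac >= 0, max_gap_frac <= 1)
  miss <- is_missing_mat(aln$mat, aln$alphabet)
  frac <- colMeans(miss)
  keep <- which(frac <= max_gap_frac)
  if (!length(keep)) {
    warn(sprintf("all columns of locus %s removed by trimming", aln$locus_id))
  }
  out <- locus_alignment(aln$locus_id,
                         aln$mat[, keep, drop = FALSE], aln$alphabet)
  attr(out, "provenance") <- keep
  out
}

#' Filter loci by taxon occupancy
#'
#' A locus is kept iff the number of taxa with a non-empty row (at least one
#' residue) is at least `ceiling(tau * length(all_taxa))` — "at least tau
#' occupancy" taken literally.
#'
#' @param loci List of `locus_aln`.
#' @param all_taxa Character vector: the full taxon panel.
#' @param tau Occupancy threshold in `(0, 1]`.
#' @return The surviving subset of `loci`.
#' @export
filter_occupancy <- function(loci, all_taxa, tau) {
  stopifnot(tau > 0, tau <= 1)
  need <- ceiling(tau * length(all_taxa))
  keep <- vapply(loci, function(a) {
    present <- rowSums(!is_missing_mat(a$mat, a$alphabet)) > 0L
    sum(present & rownames(a$mat) %in% all_taxa) >= need
  }, logical(1))
  loci[keep]
}

#' Concatenate locus alignments into a supermatrix
#'
#' One row per taxon in `all_taxa`; a locus absent for a taxon contributes
#' `?` across its span. Partition coordinates are 1-based inclusive, in
#' input locus order.
#'
#' @param loci List of `locus_aln` with distinct `locus_id`s.
#' @param all_taxa Character vector of all taxa (row order of the matrix).
#' @return List of class `"supermatrix"`: `mat` (character matrix taxa x
#'   sites), `partitions` (tibble `locus_id`, `start`, `end`), `alphabet`.
#' @export
concatenate_loci <- function(loci, all_taxa) {
  stopifnot(length(loci) >= 1L)
  ids <- vapply(loci, function(a) a$locus_id, character(1))
  if (anyDuplicated(ids)) abort("duplicate locus_id in concatenation")
  if (anyDuplicated(toupper(all_taxa))) {
    abort("taxon name collision after normalization")
  }
  alphabet <- unique(vapply(loci, function(a) a$alphabet, character(1)))
  if (length(alphabet) != 1L) abort("mixed alphabets in concatenation")
  lens <- vapply(loci, function(a) ncol(a$mat), integer(1))
  ends <- cumsum(lens)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  mat <- matrix("?", nrow = length(all_taxa), ncol = sum(lens),
                dimnames = list(all_taxa, NULL))
  for (i in seq_along(loci)) {
    rows <- intersect(all_taxa, rownames(loci[[i]]$mat))
    mat[rows, starts[i]:ends[i]] <- loci[[i]]$mat[rows, , drop = FALSE]
  }
  structure(list(mat = mat,
                 partitions = tibble(locus_id = ids, start = starts, end = ends),
                 alphabet = alphabet),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("<supermatrix> %d taxa x %s sites, %d partitions (%s)\n",
              nrow(x$mat), format(ncol(x$mat), big.mark = ","),
              nrow(x$partitions), x$alphabet))
  invisible(x)
}

#' Count parsimony-informative sites
#'
#' A column is parsimony-informative iff at least two distinct residue
#' states each occur in at least two rows. Gaps, `?`, `N`/`X` and other
#' ambiguity codes are not states.
#'
#' @param x A `locus_aln` or `supermatrix`.
#' @return Integer count of informative columns.
#' @export
count_pis <- function(x) {
  mat <- x$mat
  states <- alphabet_states(x$alphabet)
  ge2 <- matrix(0L, nrow = length(states), ncol = ncol(mat))
  for (i in seq_along(states)) {
    ge2[i, ] <- as.integer(colSums(mat == states[i]) >= 2L)
  }
  sum(colSums(ge2) >= 2L)
}

#' Summary statistics for a supermatrix
#'
#' The column structure mirrors the usual alignment-summary reports: locus
#' count, mean/median locus length, total sites, parsimony-informative sites
#' (count and %), and missing data % (both `-` and `?` count as missing).
#'
#' @param loci The loci the matrix was built from (post-trimming).
#' @param matrix_ The `supermatrix` built from `loci`.
#' @return One-row tibble: `n_loci`, `mean_locus_len`, `median_locus_len`,
#'   `n_sites`, `n_pis`, `pct_pis`, `pct_missing`.
#' @export
summarize_matrix <- function(loci, matrix_) {
  stopifnot(inherits(matrix_, "supermatrix"))
  lens <- vapply(loci, function(a) ncol(a$mat), integer(1))
  n_sites <- ncol(matrix_$mat)
  n_pis <- count_pis(matrix_)
  n_missing <- sum(is_missing_mat(matrix_$mat, matrix_$alphabet))
  tibble(n_loci = length(loci),
         mean_locus_len = mean(lens),
         median_locus_len = stats::median(lens),
         n_sites = n_sites,
         n_pis = n_pis,
         pct_pis = 100 * n_pis / n_sites,
         pct_missing = 100 * n_missing / (nrow(matrix_$mat) * n_sites))
}

#' Slice a supermatrix back into per-locus alignments
#'
#' @param sm A `supermatrix`.
#' @return Named list of `locus_aln`, one per partition.
#' @export
split_partitions <- function(sm) {
  stopifnot(inherits(sm, "supermatrix"))
  out <- purrr::pmap(sm$partitions, function(locus_id, start, end) {
    locus_alignment(locus_id, sm$mat[, start:end, drop = FALSE], sm$alphabet)
  })
  stats::setNames(out, sm$partitions$locus_id)
}

#' Build occupancy-threshold matrices and their statistics
#'
#' Applies [filter_occupancy()], [concatenate_loci()] and
#' [summarize_matrix()] at each threshold, reproducing the usual
#' occupancy-ladder table (50/75/90/100%).
#'
#' @param loci List of `locus_aln`.
#' @param all_taxa Full taxon panel.
#' @param taus Occupancy thresholds (default `c(0.5, 0.75, 0.9, 1)`).
#' @return Tibble with one row per threshold: `tau`, `min_occupancy_pct` and
#'   the [summarize_matrix()] columns; matrices themselves in the
#'   `"matrices"` attribute (named by threshold).
#' @export
occupancy_ladder <- function(loci, all_taxa, taus = c(0.5, 0.75, 0.9, 1)) {
  rows <- list(); mats <- list()
  for (tau in taus) {
    kept <- filter_occupancy(loci, all_taxa, tau)
    key <- sprintf("%g", tau)
    if (!length(kept)) {
      rows[[key]] <- tibble(tau = tau, min_occupancy_pct = 100 * tau,
                            n_loci = 0L, mean_locus_len = NA_real_,
                            median_locus_len = NA_real_, n_sites = 0L,
                            n_pis = 0L, pct_pis = NA_real_,
                            pct_missing = NA_real_)
      next
    }
    sm <- concatenate_loci(kept, all_taxa)
    rows[[key]] <- dplyr::bind_cols(
      tibble(tau = tau, min_occupancy_pct = 100 * tau),
      summarize_matrix(kept, sm))
    mats[[key]] <- sm
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "matrices") <- mats
  out
}
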