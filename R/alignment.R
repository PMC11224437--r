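#' Per-locus multiple alignment
#'
#' A `locus_aln` stores one marker locus as a character matrix with one row
#' per taxon and one column per site, over the residue alphabet plus the gap
#' (`-`) and missing (`?`) symbols. All rows have equal length.
#'
#' @param locus_id Locus identifier.
#' @param seqs Named character vector of equal-length aligned sequences, or a
#'   character matrix with taxon rownames.
#' @param alphabet `"NT"` or `"AA"`.
#' @return An object of class `"locus_aln"` with fields `locus_id`, `mat`
#'   (character matrix, taxa x sites) and `alphabet`.
#' @export
locus_alignment <- function(locus_id, seqs, alphabet = c("NT", "AA")) {
  alphabet <- match.arg(alphabet)
  if (is.matrix(seqs)) {
    mat <- seqs
  } else {
    stopifnot(!is.null(names(seqs)), length(seqs) >= 1L)
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L) {
      abort(sprintf("rows of locus %s differ in length", locus_id))
    }
    mat <- matrix("", nrow = length(seqs), ncol = lens[1],
                  dimnames = list(names(seqs), NULL))
    for (i in seq_along(seqs)) {
      mat[i, ] <- strsplit(toupper(seqs[[i]]), "", fixed = TRUE)[[1]]
    }
  }
  if (anyDuplicated(rownames(mat))) abort("duplicate taxon in alignment")
  structure(list(locus_id = locus_id, mat = mat, alphabet = alphabet),
            class = "locus_aln")
}

#' @export
print.locus_aln <- function(x, ...) {
  cat(sprintf("<locus_aln> %s: %d taxa x %d sites (%s)\n",
              x$locus_id, nrow(x$mat), ncol(x$mat), x$alphabet))
  invisible(x)
}

#' @export
dim.locus_aln <- function(x) dim(x$mat)

# rows joined back into strings
aln_strings <- function(aln) {
  apply(aln$mat, 1L, paste, collapse = "")
}

# residue states of an alphabet; gaps/missing/ambiguity are never states
alphabet_states <- function(alphabet) {
  if (alphabet == "NT") DNA_BASES else setdiff(LETTERS, c("B", "J", "O", "U", "X", "Z"))
}

#' Write one locus alignment to FASTA
#'
#' @param aln A `locus_aln`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  write_fasta(aln_strings(aln), path)
}

#' Read a locus alignment from FASTA
#'
#' @param path FASTA path; records must be equal length.
#' @param locus_id Locus id; defaults to the file name without extension.
#' @param alphabet `"NT"` or `"AA"`.
#' @return A `locus_aln`.
#' @export
read_alignment <- function(path, locus_id = NULL,
                           alphabet = c("NT", "AA")) {
  alphabet <- match.arg(alphabet)
  locus_id <- locus_id %||% sub("\\.[^.]*$", "", basename(path))
  seqs <- read_fasta(path)
  locus_alignment(locus_id, seqs, alphabet)
}
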