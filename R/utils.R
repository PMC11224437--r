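#' @importFrom rlang %||% abort warn inform
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map_chr map_int map_dbl map2 imap pmap keep
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement a DNA string
#'
#' `N` is complemented to `N`; any other character is an error.
#'
#' @param x A single DNA string over `{A,C,G,T,N}`.
#' @return The reverse complement, same length.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  comp <- chartr("ACGTN", "TGCAN", x)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

# uniform random DNA string of length n (uses the current RNG stream)
random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

assert_dna <- function(seqs, what = "sequence") {
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    abort(sprintf("%s contains characters outside {A,C,G,T,N}: %s",
                  what, paste(utils::head(names(seqs)[bad] %||% which(bad), 3), collapse = ", ")))
  }
  if (any(!nzchar(seqs))) abort(sprintf("empty %s not allowed", what))
  invisible(seqs)
}

# 0-based half-open -> 1-based inclusive (reports, partition files)
to_one_based <- function(start0, end0) list(start = start0 + 1L, end = end0)

# 1-based inclusive -> 0-based half-open (internal)
to_zero_based <- function(start1, end1) list(start = start1 - 1L, end = end1)

#' Derive a stage seed from a global seed
#'
#' Small deterministic mixer so that each pipeline stage draws from an
#' independent stream while the whole run is reproducible from one integer.
#'
#' @param seed Global integer seed.
#' @param stage Stage name (character).
#' @return An integer seed below 2^31.
#' @export
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) %% 1000003L) * 1009L + (h %% 99991L)
}
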