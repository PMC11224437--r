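#' Genome: a labelled set of contigs
#'
#' A genome assembly is a taxon label plus an ordered set of named contig
#' sequences over `{A,C,G,T,N}`. Sequences are uppercased and validated at
#' construction; contig ids must be unique and sequences non-empty.
#'
#' @param taxon Single character label for the taxon.
#' @param contigs Named character vector of DNA sequences.
#' @return An object of class `"genome"`.
#' @examples
#' g <- genome("taxonA", c(ctg1 = "ACGTACGT"))
#' @export
genome <- function(taxon, contigs) {
  stopifnot(is.character(taxon), length(taxon) == 1L, nzchar(taxon))
  if (is.null(names(contigs)) || any(!nzchar(names(contigs)))) {
    abort("all contigs must be named")
  }
  if (anyDuplicated(names(contigs))) {
    abort(sprintf("duplicate contig id: %s",
                  names(contigs)[duplicated(names(contigs))][1]))
  }
  contigs <- toupper(contigs)
  assert_dna(contigs, sprintf("contig of %s", taxon))
  structure(list(taxon = taxon, contigs = contigs), class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> %s: %d contig(s), %s bp total\n",
              x$taxon, length(x$contigs),
              format(sum(nchar(x$contigs)), big.mark = ",")))
  invisible(x)
}

#' Read a multi-record FASTA file
#'
#' Record ids are the header token up to the first whitespace; sequences are
#' uppercased and line wrapping removed. Duplicate ids and empty records are
#' errors.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (!length(lines) || !hdr[1]) abort(sprintf("not FASTA: %s", path))
  ids <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr])
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate id %s in %s", ids[duplicated(ids)][1], path))
  }
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) toupper(paste(x, collapse = "")), character(1))
  out <- character(length(ids))
  names(out) <- ids
  out[as.integer(names(seqs))] <- seqs
  if (any(!nzchar(out))) {
    abort(sprintf("empty record %s in %s", ids[!nzchar(out)][1], path))
  }
  out
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width (default 80).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 80L) {
  stopifnot(!is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Parse a Newick string into an ape phylo tree
#'
#' Numeric internal-node labels are interpreted as node support and kept in
#' `node.label`; the support scale ("0-1" or "0-100") is recorded in the
#' `"support_scale"` attribute when it can be inferred, otherwise left
#' `NA`. The tree is rooted iff the top-level node has two children.
#'
#' @param text A Newick string.
#' @return An object of class `"phylo"`.
#' @examples
#' tr <- parse_newick("((a:1,b:1)90:1,c:2);")
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  # cheap structural validation with 0-based offsets, ahead of ape
  depth <- 0L
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        abort(sprintf("newick parse error at offset %d: unmatched ')'", i - 1L))
      }
    }
    if (ch == ";" && depth != 0L) {
      abort(sprintf("newick parse error at offset %d: %d unclosed '('",
                    i - 1L, depth))
    }
  }
  if (depth != 0L) {
    abort(sprintf("newick parse error at offset %d: %d unclosed '('",
                  nchar(text), depth))
  }
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) abort(sprintf("newick parse error: %s", conditionMessage(e))))
  if (is.null(tr)) abort("newick parse error: not a tree")
  if (anyDuplicated(tr$tip.label)) {
    abort(sprintf("duplicate leaf label: %s",
                  tr$tip.label[duplicated(tr$tip.label)][1]))
  }
  sup <- suppressWarnings(as.numeric(tr$node.label))
  scale <- NA_character_
  if (!is.null(tr$node.label) && any(!is.na(sup))) {
    mx <- max(sup, na.rm = TRUE)
    scale <- if (mx <= 1) "0-1" else "0-100"
  }
  attr(tr, "support_scale") <- scale
  tr
}

#' Write a phylo tree to a Newick string or file
#'
#' @param tree A `"phylo"` object.
#' @param path Optional output path; if `NULL` the Newick string is returned.
#' @return The Newick string (invisibly when written to file).
#' @export
write_newick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Write a RAxML-style partition file
#'
#' Partitions are given in 1-based inclusive coordinates and must be
#' contiguous, ascending and non-overlapping; each line has the form
#' `DNA, <locus_id> = <start>-<end>` (`PROT` for amino-acid matrices).
#'
#' @param partitions Data frame with columns `locus_id`, `start`, `end`
#'   (1-based inclusive).
#' @param path Output path.
#' @param alphabet `"NT"` (writes `DNA`) or `"AA"` (writes `PROT`).
#' @return `path`, invisibly.
#' @export
write_partitions <- function(partitions, path, alphabet = c("NT", "AA")) {
  alphabet <- match.arg(alphabet)
  if (nrow(partitions) == 0L) {
    warn("writing empty partition file")
    writeLines(character(0), path)
    return(invisible(path))
  }
  stopifnot(all(c("locus_id", "start", "end") %in% names(partitions)))
  if (partitions$start[1] != 1L) abort("partitions must start at 1")
  if (any(partitions$end < partitions$start)) abort("partition with end < start")
  if (nrow(partitions) > 1L) {
    nxt <- partitions$start[-1]
    prev_end <- partitions$end[-nrow(partitions)]
    bad <- which(nxt != prev_end + 1L)
    if (length(bad)) {
      if (nxt[bad[1]] > prev_end[bad[1]] + 1L) {
        abort(sprintf("gap at %d", prev_end[bad[1]] + 1L))
      }
      abort(sprintf("overlap at %d", nxt[bad[1]]))
    }
  }
  tag <- if (alphabet == "NT") "DNA" else "PROT"
  writeLines(sprintf("%s, %s = %d-%d", tag, partitions$locus_id,
                     partitions$start, partitions$end), path)
  invisible(path)
}

#' Read a two-column taxon manifest
#'
#' Tab-separated, no header: taxon label, path to its assembly FASTA.
#'
#' @param path Manifest path.
#' @return Tibble with columns `taxon`, `path`.
#' @export
read_manifest <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("taxon", "path"),
                          stringsAsFactors = FALSE)
  if (anyDuplicated(df$taxon)) abort("duplicate taxon in manifest")
  as_tibble(df)
}

#' Load genomes listed in a manifest
#'
#' @param manifest Tibble from [read_manifest()] (or any data frame with
#'   `taxon` and `path` columns).
#' @return List of [genome()] objects.
#' @export
load_genomes <- function(manifest) {
  purrr::map2(manifest$taxon, manifest$path,
              function(tx, p) genome(tx, read_fasta(p)))
}
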