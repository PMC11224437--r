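# Independent oracles and tiny fixture builders used across the suite.

# brute-force parsimony-informative classifier, straight from the definition
brute_count_pis <- function(aln) {
  states <- if (aln$alphabet == "NT") c("A", "C", "G", "T") else
    setdiff(LETTERS, c("B", "J", "O", "U", "X", "Z"))
  n <- 0L
  for (j in seq_len(ncol(aln$mat))) {
    tab <- table(aln$mat[, j][aln$mat[, j] %in% states])
    if (sum(tab >= 2) >= 2) n <- n + 1L
  }
  n
}

# random alignment over ACGT with optional gaps/missing
rand_aln <- function(n_taxa, n_cols, p_gap = 0.1, id = "R1") {
  pool <- c("A", "C", "G", "T", "-", "?")
  probs <- c(rep((1 - p_gap) / 4, 4), p_gap / 2, p_gap / 2)
  mat <- matrix(sample(pool, n_taxa * n_cols, replace = TRUE, prob = probs),
                nrow = n_taxa,
                dimnames = list(sprintf("x%02d", seq_len(n_taxa)), NULL))
  locus_alignment(id, mat)
}

# random binary tree with strictly positive branch lengths
rand_tree <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, br = function(n) stats::runif(n, 0.1, 1))
  tr$tip.label <- sprintf("x%02d", seq_len(n_taxa))
  tr
}

# brute-force sliding-window matcher: every diagonal, both strands, same
# identity/coverage contract as match_probes but without k-mer seeding
brute_match <- function(genome, probes, min_identity, min_coverage) {
  hits <- list()
  for (ctg in names(genome$contigs)) {
    cseq <- genome$contigs[[ctg]]
    n <- nchar(cseq)
    for (pid in names(probes$probes)) {
      for (strand in c("+", "-")) {
        p <- probes$probes[[pid]]
        if (strand == "-") p <- revcomp(p)
        L <- nchar(p)
        for (d in (-L + 1L):(n - 1L)) {
          i1 <- max(1L, 1L - d); i2 <- min(L, n - d)
          span <- i2 - i1 + 1L
          if (span < min_coverage * L) next
          a <- strsplit(substr(p, i1, i2), "")[[1]]
          b <- strsplit(substr(cseq, d + i1, d + i2), "")[[1]]
          ident <- sum(a == b & a != "N" & b != "N") / span
          if (ident >= min_identity) {
            hits[[length(hits) + 1L]] <- data.frame(
              probe_id = pid, contig_id = ctg, start = d + i1 - 1L,
              end = d + i2, strand = strand, identity = ident)
          }
        }
      }
    }
  }
  if (!length(hits)) return(NULL)
  do.call(rbind, hits)
}

# merge brute hits the way match_probes merges (same probe/contig/strand,
# overlapping intervals, best identity kept) so hit sets are comparable
merge_brute <- function(df) {
  if (is.null(df)) return(NULL)
  out <- list()
  for (key in unique(paste(df$probe_id, df$contig_id, df$strand))) {
    sub <- df[paste(df$probe_id, df$contig_id, df$strand) == key, ]
    sub <- sub[order(sub$start), ]
    cur <- sub[1, ]
    for (i in seq_len(nrow(sub))[-1]) {
      if (sub$start[i] < cur$end) {
        cur$end <- max(cur$end, sub$end[i])
        cur$identity <- max(cur$identity, sub$identity[i])
      } else {
        out[[length(out) + 1L]] <- cur
        cur <- sub[i, ]
      }
    }
    out[[length(out) + 1L]] <- cur
  }
  res <- do.call(rbind, out)
  res[order(res$probe_id, res$contig_id, res$strand, res$start), ]
}

# the diagnostic-panel scenario: congeneric depth, uniform locus rates
diag_config <- function(seed, n_unique_regions = 1) {
  sim_config(seed = seed, n_taxa = 8, tree_depth = 0.02,
             per_locus_rate_shape = Inf,
             n_unique_regions = n_unique_regions)
}
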