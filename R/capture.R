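#' Probe set: reference marker sequences with a probe-to-locus mapping
#'
#' Multiple probes may tile one locus (UCE-style baits); every probe maps to
#' exactly one locus.
#'
#' @param probes Named character vector of probe DNA sequences.
#' @param probe_to_locus Named character vector mapping probe id -> locus id;
#'   names must equal `names(probes)`.
#' @param marker_label Free label for the marker class (e.g. "UCE-like").
#' @return An object of class `"probe_set"`.
#' @export
probe_set <- function(probes, probe_to_locus, marker_label = "marker") {
  stopifnot(!is.null(names(probes)), !is.null(names(probe_to_locus)))
  if (!setequal(names(probes), names(probe_to_locus))) {
    abort("probe_to_locus must cover exactly the probe ids")
  }
  probes <- toupper(probes)
  assert_dna(probes, "probe")
  structure(list(probes = probes,
                 probe_to_locus = probe_to_locus[names(probes)],
                 marker_label = marker_label),
            class = "probe_set")
}

#' @export
print.probe_set <- function(x, ...) {
  cat(sprintf("<probe_set> %s: %d probes targeting %d loci\n",
              x$marker_label, length(x$probes),
              length(unique(x$probe_to_locus))))
  invisible(x)
}

# positions (1-based) of every k-mer of seq, keyed by k-mer; k-mers
# containing N are dropped (N never matches anything)
kmer_index <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(list())
  starts <- seq_len(n - k + 1L)
  kmers <- substring(seq, starts, starts + k - 1L)
  ok <- !grepl("N", kmers, fixed = TRUE)
  split(starts[ok], kmers[ok])
}

# all k-mers of a set of (strand-expanded) query sequences as one table
query_kmer_table <- function(seqs, k) {
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    L <- nchar(seqs[[i]])
    if (L < k) next
    starts <- seq_len(L - k + 1L)
    km <- substring(seqs[[i]], starts, starts + k - 1L)
    ok <- !grepl("N", km, fixed = TRUE)
    out[[i]] <- list(qi = rep.int(i, sum(ok)), qpos = starts[ok], kmer = km[ok])
  }
  out <- out[!vapply(out, is.null, logical(1))]
  list(qi = unlist(lapply(out, `[[`, "qi")),
       qpos = unlist(lapply(out, `[[`, "qpos")),
       kmer = unlist(lapply(out, `[[`, "kmer")))
}

# count aligned matches between two equal-length strings; N matches nothing
count_matches <- function(a, b) {
  av <- utf8ToInt(a); bv <- utf8ToInt(b)
  nn <- utf8ToInt("N")
  sum(av == bv & av != nn)
}

#' Match probes against a genome by k-mer seeding and ungapped extension
#'
#' Exact k-mer seeds on both strands nominate diagonals; each diagonal is
#' scored by full ungapped alignment of the probe (clipped at contig ends).
#' A hit is reported iff identity >= `min_identity` over an aligned span
#' covering >= `min_coverage` of the probe. Overlapping hits of one probe on
#' one contig and strand are merged, keeping the best identity.
#'
#' @param genome A [genome()].
#' @param probes A [probe_set()].
#' @param min_identity Minimum fraction of matching bases over the aligned
#'   span (default 0.85).
#' @param min_coverage Minimum fraction of the probe covered by the aligned
#'   span (default 0.8).
#' @param k Exact seed length, 8-31 (default 15).
#' @return Tibble of raw hits: `probe_id`, `contig_id`, `start`, `end`
#'   (0-based half-open on the forward strand), `strand`, `identity`,
#'   `probe_start`, `probe_end` (0-based half-open in probe orientation).
#' @export
match_probes <- function(genome, probes, min_identity = 0.85,
                         min_coverage = 0.8, k = 15L) {
  stopifnot(inherits(genome, "genome"), inherits(probes, "probe_set"))
  stopifnot(k >= 8L, k <= 31L,
            min_identity > 0, min_identity <= 1,
            min_coverage > 0, min_coverage <= 1)
  plens <- nchar(probes$probes)
  if (any(plens < k)) {
    abort(sprintf("probe %s shorter than seed length %d",
                  names(probes$probes)[plens < k][1], k))
  }
  pid <- names(probes$probes)
  # strand-expanded queries: fwd then revcomp
  qseq <- c(probes$probes, vapply(probes$probes, revcomp, character(1)))
  qstrand <- rep(c("+", "-"), each = length(pid))
  qpid <- c(pid, pid)
  qtab <- query_kmer_table(qseq, k)

  hits <- list()
  for (ctg in names(genome$contigs)) {
    cseq <- genome$contigs[[ctg]]
    n <- nchar(cseq)
    idx <- kmer_index(cseq, k)
    if (!length(idx) || is.null(qtab$kmer)) next
    m <- match(qtab$kmer, names(idx))
    sel <- which(!is.na(m))
    if (!length(sel)) next
    pl <- idx[m[sel]]
    reps <- lengths(pl)
    gpos <- unlist(pl, use.names = FALSE)
    qi <- rep.int(qtab$qi[sel], reps)
    qpos <- rep.int(qtab$qpos[sel], reps)
    diag <- gpos - qpos
    cand <- unique(data.frame(qi = qi, diag = diag))
    for (r in seq_len(nrow(cand))) {
      i <- cand$qi[r]; d <- cand$diag[r]
      L <- nchar(qseq[[i]])
      i1 <- max(1L, 1L - d); i2 <- min(L, n - d)
      span <- i2 - i1 + 1L
      if (span < min_coverage * L) next
      pseg <- substr(qseq[[i]], i1, i2)
      gseg <- substr(cseq, d + i1, d + i2)
      ident <- count_matches(pseg, gseg) / span
      if (ident < min_identity) next
      # probe-orientation coordinates of the aligned span
      if (qstrand[i] == "+") {
        ps <- i1 - 1L; pe <- i2
      } else {
        ps <- L - i2; pe <- L - i1 + 1L
      }
      hits[[length(hits) + 1L]] <- tibble(
        probe_id = qpid[i], contig_id = ctg,
        start = d + i1 - 1L, end = d + i2,
        strand = qstrand[i], identity = ident,
        probe_start = ps, probe_end = pe)
    }
  }
  if (!length(hits)) {
    return(tibble(probe_id = character(), contig_id = character(),
                  start = integer(), end = integer(), strand = character(),
                  identity = numeric(), probe_start = integer(),
                  probe_end = integer()))
  }
  res <- dplyr::bind_rows(hits)
  merge_probe_hits(res)
}

# merge overlapping hits of one probe on one contig/strand, best identity wins
merge_probe_hits <- function(hits) {
  hits |>
    dplyr::group_by(.data$probe_id, .data$contig_id, .data$strand) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::group_modify(function(df, key) {
      if (nrow(df) <= 1L) return(df)
      keep <- df[1, ]
      out <- list()
      for (i in 2:nrow(df)) {
        if (df$start[i] < keep$end) {
          keep$end <- max(keep$end, df$end[i])
          if (df$identity[i] > keep$identity) {
            keep$identity <- df$identity[i]
            keep$probe_start <- df$probe_start[i]
            keep$probe_end <- df$probe_end[i]
          }
        } else {
          out[[length(out) + 1L]] <- keep
          keep <- df[i, ]
        }
      }
      out[[length(out) + 1L]] <- keep
      dplyr::bind_rows(out)
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$probe_id, .data$contig_id, .data$start)
}

#' Group hits by locus, remove duplicates, extract loci with flanks
#'
#' Hits are grouped by locus via the probe-to-locus map and merged into
#' contiguous regions (same contig, gap <= `join_dist`). A locus is dropped
#' for this taxon when its probes hit more than one distinct region
#' (`DUPLICATE_LOCUS`) or when a region overlaps a region claimed by another
#' locus (`SHARED_REGION`). Surviving loci are extracted with `flank` bp on
#' each side, truncated at contig ends; minus-strand regions are
#' reverse-complemented so that every sequence reads in probe orientation.
#'
#' @param hits Raw hit tibble from [match_probes()] on the same genome.
#' @param genome The [genome()] the hits refer to.
#' @param probes The [probe_set()] used.
#' @param flank Flank length retained on each side (default 400 bp).
#' @param join_dist Same-locus hits closer than this are merged (default 100).
#' @return List with `captures` (tibble: `locus_id`, `taxon`, `contig_id`,
#'   `start`, `end` (0-based half-open probe-match core), `strand`,
#'   `flank_left`, `flank_right`, `truncated`, `core_probe_offset`,
#'   `sequence`) and `drops` (tibble: `locus_id`, `taxon`, `reason`).
#' @export
dedupe_and_extract <- function(hits, genome, probes, flank = 400L,
                               join_dist = 100L) {
  stopifnot(inherits(genome, "genome"), inherits(probes, "probe_set"))
  tx <- genome$taxon
  empty_cap <- tibble(locus_id = character(), taxon = character(),
                      contig_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      flank_left = integer(), flank_right = integer(),
                      truncated = logical(), core_probe_offset = integer(),
                      sequence = character())
  drops <- tibble(locus_id = character(), taxon = character(),
                  reason = character())
  if (nrow(hits) == 0L) return(list(captures = empty_cap, drops = drops))

  hits$locus_id <- unname(probes$probe_to_locus[hits$probe_id])

  # merge same-locus hits into regions per contig
  regions <- hits |>
    dplyr::group_by(.data$locus_id, .data$contig_id) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::group_modify(function(df, key) {
      keep <- df[1, ]
      out <- list()
      if (nrow(df) > 1L) {
        for (i in 2:nrow(df)) {
          if (df$start[i] <= keep$end + join_dist) {
            keep$end <- max(keep$end, df$end[i])
            if (df$identity[i] > keep$identity) {
              keep$identity <- df$identity[i]
              keep$strand <- df$strand[i]
              keep$probe_start <- df$probe_start[i]
            }
          } else {
            out[[length(out) + 1L]] <- keep
            keep <- df[i, ]
          }
        }
      }
      out[[length(out) + 1L]] <- keep
      dplyr::bind_rows(out)
    }) |>
    dplyr::ungroup()

  # duplicate removal: locus with >1 region in this genome
  n_reg <- regions |> dplyr::count(.data$locus_id)
  dup <- n_reg$locus_id[n_reg$n > 1L]
  if (length(dup)) {
    drops <- dplyr::bind_rows(drops, tibble(locus_id = dup, taxon = tx,
                                            reason = "DUPLICATE_LOCUS"))
    regions <- dplyr::filter(regions, !(.data$locus_id %in% dup))
  }
  # shared regions: overlapping regions claimed by different loci
  if (nrow(regions) > 1L) {
    shared <- character(0)
    reg <- dplyr::arrange(regions, .data$contig_id, .data$start)
    for (i in seq_len(nrow(reg) - 1L)) {
      j <- i + 1L
      if (reg$contig_id[i] == reg$contig_id[j] &&
          reg$start[j] < reg$end[i] &&
          reg$locus_id[i] != reg$locus_id[j]) {
        shared <- union(shared, c(reg$locus_id[i], reg$locus_id[j]))
      }
    }
    if (length(shared)) {
      drops <- dplyr::bind_rows(drops, tibble(locus_id = shared, taxon = tx,
                                              reason = "SHARED_REGION"))
      regions <- dplyr::filter(regions, !(.data$locus_id %in% shared))
    }
  }
  if (nrow(regions) == 0L) return(list(captures = empty_cap, drops = drops))

  caps <- purrr::pmap(regions, function(locus_id, contig_id, start, end,
                                        strand, probe_start, ...) {
    clen <- nchar(genome$contigs[[contig_id]])
    ext_start <- max(0L, start - flank)
    ext_end <- min(clen, end + flank)
    fl_g_left <- start - ext_start     # attained genomic left flank
    fl_g_right <- ext_end - end
    seq <- substr(genome$contigs[[contig_id]], ext_start + 1L, ext_end)
    if (strand == "-") {
      seq <- revcomp(seq)
      fl <- fl_g_right; fr <- fl_g_left
    } else {
      fl <- fl_g_left; fr <- fl_g_right
    }
    tibble(locus_id = locus_id, taxon = tx, contig_id = contig_id,
           start = start, end = end, strand = strand,
           flank_left = fl, flank_right = fr,
           truncated = (fl_g_left < flank) || (fl_g_right < flank),
           core_probe_offset = probe_start, sequence = seq)
  })
  list(captures = dplyr::bind_rows(caps), drops = drops)
}

#' Capture marker loci across a panel of genomes
#'
#' Runs [match_probes()] and [dedupe_and_extract()] per genome and collates
#' captures, drop logs and per-taxon capture counts (the analogue of a
#' per-species locus-count table).
#'
#' @param genomes List of [genome()] objects.
#' @param probes A [probe_set()].
#' @param min_identity,min_coverage,k Matcher settings, see [match_probes()].
#' @param flank,join_dist Extraction settings, see [dedupe_and_extract()].
#' @return List with `captures` (one tibble over all taxa), `drops`, and
#'   `counts` (tibble: `taxon`, `n_loci`).
#' @export
capture_all <- function(genomes, probes, min_identity = 0.85,
                        min_coverage = 0.8, k = 15L, flank = 400L,
                        join_dist = 100L) {
  caps <- list(); drops <- list(); counts <- list()
  for (g in genomes) {
    h <- match_probes(g, probes, min_identity, min_coverage, k)
    de <- dedupe_and_extract(h, g, probes, flank, join_dist)
    caps[[g$taxon]] <- de$captures
    drops[[g$taxon]] <- de$drops
    counts[[g$taxon]] <- tibble(taxon = g$taxon,
                                n_loci = length(unique(de$captures$locus_id)))
  }
  list(captures = dplyr::bind_rows(caps),
       drops = dplyr::bind_rows(drops),
       counts = dplyr::bind_rows(counts))
}

#' Columnize the captured copies of one locus by probe anchor
#'
#' Places each captured copy in a common frame using its probe-match offset;
#' columns outside a taxon's attainable flanks are filled with gaps. Under
#' an indel-free model this yields a column-exact alignment without any MSA
#' step.
#'
#' @param captured Tibble of captures for a single locus (one row per taxon),
#'   as produced by [capture_all()].
#' @param core_only If `TRUE`, keep only columns of the probe-match core
#'   (drop flank columns); useful when flanks are not homologous.
#' @return A `locus_aln`.
#' @export
anchor_align <- function(captured, core_only = FALSE) {
  stopifnot(nrow(captured) >= 1L,
            length(unique(captured$locus_id)) == 1L)
  core_len <- captured$end - captured$start
  expect_len <- captured$flank_left + core_len + captured$flank_right
  bad <- nchar(captured$sequence) != expect_len
  if (any(bad)) {
    abort(sprintf("anchor inconsistency for taxon %s: sequence length %d != flanks + core %d",
                  captured$taxon[bad][1], nchar(captured$sequence[bad][1]),
                  expect_len[bad][1]))
  }
  # probe-frame span of each row
  row_start <- captured$core_probe_offset - captured$flank_left
  row_end <- captured$core_probe_offset + core_len + captured$flank_right
  f0 <- min(row_start); f1 <- max(row_end)
  width <- f1 - f0
  mat <- matrix("-", nrow = nrow(captured), ncol = width,
                dimnames = list(captured$taxon, NULL))
  for (i in seq_len(nrow(captured))) {
    cols <- (row_start[i] - f0 + 1L):(row_end[i] - f0)
    mat[i, cols] <- strsplit(captured$sequence[i], "", fixed = TRUE)[[1]]
  }
  if (core_only) {
    c0 <- min(captured$core_probe_offset)
    c1 <- max(captured$core_probe_offset + core_len)
    mat <- mat[, (c0 - f0 + 1L):(c1 - f0), drop = FALSE]
  }
  locus_alignment(captured$locus_id[1], mat)
}
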