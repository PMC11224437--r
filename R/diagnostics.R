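#' Fragment a CDS into sliding windows
#'
#' Windows of width `w` at offsets 0, s, 2s, ... while `offset + w <= L`:
#' `floor((L - w)/s) + 1` windows for `L >= w`, none otherwise.
#'
#' @param cds A single DNA string.
#' @param w Window width (default 200 bp).
#' @param s Step length (default 50 bp).
#' @return Tibble: `offset` (0-based), `sequence`.
#' @export
fragment_windows <- function(cds, w = 200L, s = 50L) {
  stopifnot(w > 0L, s > 0L)
  L <- nchar(cds)
  if (L < w) return(tibble(offset = integer(), sequence = character()))
  offsets <- seq(0L, L - w, by = s)
  tibble(offset = offsets,
         sequence = substring(cds, offsets + 1L, offsets + w))
}

#' Fragment every CDS of a set
#'
#' @param cds Named character vector of CDS sequences (one taxon's set).
#' @param w,s See [fragment_windows()].
#' @return Tibble: `cds_id`, `offset`, `sequence`, `fragment_id`.
#' @export
fragment_cds_set <- function(cds, w = 200L, s = 50L) {
  stopifnot(!is.null(names(cds)))
  rows <- purrr::imap(cds, function(seq, id) {
    fr <- fragment_windows(seq, w, s)
    if (nrow(fr) == 0L) return(NULL)
    dplyr::mutate(fr, cds_id = id, .before = 1L)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    return(tibble(cds_id = character(), offset = integer(),
                  sequence = character(), fragment_id = character()))
  }
  dplyr::mutate(out, fragment_id = sprintf("%s@%d", .data$cds_id, .data$offset))
}

#' Search fragments against a panel of genomes
#'
#' Runs the same seed-and-extend matcher as locus capture, both strands, and
#' counts hits per fragment per genome. Fragments containing `N` are skipped
#' (listed in the `"skipped"` attribute).
#'
#' @param fragments Tibble from [fragment_cds_set()].
#' @param genomes List of [genome()] objects (the panel).
#' @param min_identity,min_coverage,k Matcher settings; defaults 0.9 / 0.9 /
#'   15 define what "high sequence similarity" means for specificity.
#' @return Tibble: `fragment_id`, `taxon`, `n_hits` (complete grid), of
#'   class `"hit_report"`.
#' @export
cross_match <- function(fragments, genomes, min_identity = 0.9,
                        min_coverage = 0.9, k = 15L) {
  skipped <- fragments$fragment_id[grepl("N", fragments$sequence, fixed = TRUE)]
  if (length(skipped)) {
    inform(sprintf("skipping %d fragment(s) containing N", length(skipped)))
    fragments <- fragments[!fragments$fragment_id %in% skipped, ]
  }
  taxa <- vapply(genomes, function(g) g$taxon, character(1))
  if (nrow(fragments) == 0L) {
    out <- tibble(fragment_id = character(), taxon = character(),
                  n_hits = integer())
    attr(out, "skipped") <- skipped
    class(out) <- c("hit_report", class(out))
    return(out)
  }
  ps <- probe_set(stats::setNames(fragments$sequence, fragments$fragment_id),
                  stats::setNames(fragments$fragment_id, fragments$fragment_id),
                  marker_label = "fragments")
  rows <- purrr::map(genomes, function(g) {
    h <- match_probes(g, ps, min_identity, min_coverage, k)
    counts <- table(factor(h$probe_id, levels = fragments$fragment_id))
    tibble(fragment_id = fragments$fragment_id, taxon = g$taxon,
           n_hits = as.integer(counts))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "skipped") <- skipped
  class(out) <- c("hit_report", class(out))
  out
}

#' Select species-specific fragments and merge them into regions
#'
#' Keeps fragments with at least one hit in the target genome and zero hits
#' in every other panel genome, then merges overlapping or adjacent
#' surviving windows of the same CDS into maximal specific regions.
#'
#' @param report A `"hit_report"` from [cross_match()].
#' @param target Target taxon (must be in the report).
#' @param fragments The fragment tibble the report was computed from.
#' @param w,s Window width and step used for fragmentation.
#' @return List: `fragments` (surviving fragment tibble) and `regions`
#'   (tibble `cds_id`, `start`, `end` (0-based half-open in the CDS),
#'   `n_windows`, `sequence`).
#' @export
select_specific <- function(report, target, fragments, w = 200L, s = 50L) {
  taxa <- unique(report$taxon)
  if (!target %in% taxa) abort(sprintf("target %s not in report", target))
  if (length(taxa) == 1L) {
    warn("panel contains only the target genome; every fragment is trivially specific")
    keep_ids <- unique(report$fragment_id[report$n_hits >= 1L])
  } else {
    wide <- report |>
      dplyr::group_by(.data$fragment_id) |>
      dplyr::summarise(
        target_hits = sum(.data$n_hits[.data$taxon == target]),
        off_hits = sum(.data$n_hits[.data$taxon != target]),
        .groups = "drop")
    keep_ids <- wide$fragment_id[wide$target_hits >= 1L & wide$off_hits == 0L]
  }
  surv <- fragments[fragments$fragment_id %in% keep_ids, ]
  if (nrow(surv) == 0L) {
    return(list(fragments = surv,
                regions = tibble(cds_id = character(), start = integer(),
                                 end = integer(), n_windows = integer(),
                                 sequence = character())))
  }
  regions <- surv |>
    dplyr::group_by(.data$cds_id) |>
    dplyr::arrange(.data$offset, .by_group = TRUE) |>
    dplyr::group_modify(function(df, key) {
      cur_start <- df$offset[1]; cur_end <- df$offset[1] + w
      cur_seq <- df$sequence[1]; nw <- 1L
      out <- list()
      for (i in seq_len(nrow(df))[-1]) {
        o <- df$offset[i]
        if (o <= cur_end) {           # overlap or exactly adjacent
          add <- substr(df$sequence[i], cur_end - o + 1L, w)
          cur_seq <- paste0(cur_seq, add)
          cur_end <- o + w
          nw <- nw + 1L
        } else {
          out[[length(out) + 1L]] <- tibble(start = cur_start, end = cur_end,
                                            n_windows = nw, sequence = cur_seq)
          cur_start <- o; cur_end <- o + w
          cur_seq <- df$sequence[i]; nw <- 1L
        }
      }
      out[[length(out) + 1L]] <- tibble(start = cur_start, end = cur_end,
                                        n_windows = nw, sequence = cur_seq)
      dplyr::bind_rows(out)
    }) |>
    dplyr::ungroup()
  list(fragments = surv, regions = regions)
}

#' Wallace-rule melting temperature
#'
#' Tm = 2(A+T) + 4(G+C) degrees C.
#'
#' @param primer Primer sequence(s), 5'->3'.
#' @return Tm in degrees C, vectorized.
#' @export
wallace_tm <- function(primer) {
  at <- nchar(gsub("[^AT]", "", primer))
  gc <- nchar(gsub("[^GC]", "", primer))
  2 * at + 4 * gc
}

# per-window counts over all (start, len) combinations via cumulative sums
window_counts <- function(flags, starts, len) {
  cs <- c(0L, cumsum(flags))
  cs[starts + len] - cs[starts]
}

#' Design candidate primer pairs within a specific region
#'
#' Exhaustive enumeration of forward/reverse primers of length
#' `primer_len[1]`-`primer_len[2]` within the region, filtered on GC
#' content, Wallace-rule Tm, pair Tm difference, mononucleotide runs and
#' product size, then ranked by |pair Tm - 57| and product-size centrality.
#'
#' @param region A DNA string (a specific region from [select_specific()]).
#' @param product_size Allowed amplicon size range (default `c(100, 200)` bp).
#' @param primer_len Primer length range (default `c(18, 27)`).
#' @param gc_range Allowed GC% (default `c(40, 60)`).
#' @param tm_range Allowed Tm range in degrees C (default `c(53, 60)`, the
#'   screen's annealing window).
#' @param max_tm_diff Maximum |Tm_fwd - Tm_rev| (default 3).
#' @param max_run Longest tolerated mononucleotide run (default 4).
#' @param gc_clamp Require a G/C 3'-terminal base (default `FALSE`).
#' @param max_pairs Return at most this many ranked pairs (default 50).
#' @return Tibble of class `"primer_pairs"`: `fwd`, `rev` (5'->3', `rev` on
#'   the opposite strand), `fwd_start`, `rev_start` (0-based region
#'   coordinates of each primer's 5'-most template position), `tm_fwd`,
#'   `tm_rev`, `gc_fwd`, `gc_rev`, `product_size`. Per-filter rejection
#'   counts are in the `"rejections"` attribute; empty tibble when nothing
#'   passes.
#' @export
design_primers <- function(region, product_size = c(100L, 200L),
                           primer_len = c(18L, 27L), gc_range = c(40, 60),
                           tm_range = c(53, 60), max_tm_diff = 3,
                           max_run = 4L, gc_clamp = FALSE, max_pairs = 50L) {
  L <- nchar(region)
  empty <- tibble(fwd = character(), rev = character(),
                  fwd_start = integer(), rev_start = integer(),
                  tm_fwd = numeric(), tm_rev = numeric(),
                  gc_fwd = numeric(), gc_rev = numeric(),
                  product_size = integer())
  rej <- c(length = 0L, gc = 0L, tm = 0L, run = 0L, n_base = 0L,
           clamp = 0L, tm_diff = 0L, product = 0L)
  if (L < product_size[1]) {
    abort(sprintf("region (%d bp) shorter than minimum product size %d",
                  L, product_size[1]))
  }
  mid_product <- mean(product_size)
  ch <- strsplit(region, "", fixed = TRUE)[[1]]
  is_gc <- as.integer(ch %in% c("G", "C"))
  is_at <- as.integer(ch %in% c("A", "T"))
  is_n <- as.integer(!(ch %in% DNA_BASES))
  # run_flag[q] = 1 iff a run of (max_run + 1) identical bases starts at q
  run_flag <- integer(L)
  if (L > max_run) {
    same <- as.integer(ch[-L] == ch[-1L])
    qpos <- seq_len(L - max_run)
    run_flag[qpos] <- as.integer(window_counts(same, qpos, max_run) == max_run)
  }
  bad_run_start <- which(run_flag == 1L)

  singles <- list()
  for (len in primer_len[1]:primer_len[2]) {
    if (len > L) next
    starts <- seq_len(L - len + 1L)
    gc_n <- window_counts(is_gc, starts, len)
    at_n <- window_counts(is_at, starts, len)
    n_n <- window_counts(is_n, starts, len)
    tm <- 2 * at_n + 4 * gc_n
    gc_pct <- 100 * gc_n / len
    # a too-long run is fully inside the window iff it starts in
    # [start, start + len - (max_run + 1)]
    has_run <- rep(FALSE, length(starts))
    if (length(bad_run_start)) {
      span <- len - (max_run + 1L)
      if (span >= 0L) has_run <- window_counts(run_flag, starts, span + 1L) > 0L
    }
    ok_gc <- gc_pct >= gc_range[1] & gc_pct <= gc_range[2]
    ok_tm <- tm >= tm_range[1] & tm <= tm_range[2]
    ok_n <- n_n == 0L
    rej["gc"] <- rej["gc"] + sum(!ok_gc)
    rej["tm"] <- rej["tm"] + sum(!ok_tm)
    rej["run"] <- rej["run"] + sum(has_run)
    rej["n_base"] <- rej["n_base"] + sum(!ok_n)
    keep <- ok_gc & ok_tm & !has_run & ok_n
    if (gc_clamp) {
      fwd_clamp <- ch[starts + len - 1L] %in% c("G", "C")
      rev_clamp <- ch[starts] %in% c("G", "C")
      rej["clamp"] <- rej["clamp"] + sum(keep & !(fwd_clamp | rev_clamp))
    } else {
      fwd_clamp <- rev_clamp <- rep(TRUE, length(starts))
    }
    if (any(keep)) {
      singles[[length(singles) + 1L]] <- tibble(
        start = starts[keep] - 1L, len = len,
        tm = tm[keep], gc = gc_pct[keep],
        fwd_ok = fwd_clamp[keep], rev_ok = rev_clamp[keep])
    }
  }
  singles <- dplyr::bind_rows(singles)
  if (nrow(singles) == 0L) {
    attr(empty, "rejections") <- rej
    class(empty) <- c("primer_pairs", class(empty))
    return(empty)
  }
  singles <- dplyr::mutate(singles, end = .data$start + .data$len)
  fwd <- dplyr::filter(singles, .data$fwd_ok)
  rev <- dplyr::filter(singles, .data$rev_ok)
  pairs <- list()
  for (i in seq_len(nrow(fwd))) {
    fs <- fwd$start[i]; fe <- fwd$end[i]
    cand <- rev[rev$start >= fe &
                  rev$end >= fs + product_size[1] &
                  rev$end <= fs + product_size[2], , drop = FALSE]
    if (nrow(cand) == 0L) next
    dtm <- abs(cand$tm - fwd$tm[i])
    rej["tm_diff"] <- rej["tm_diff"] + sum(dtm > max_tm_diff)
    cand <- cand[dtm <= max_tm_diff, , drop = FALSE]
    if (nrow(cand) == 0L) next
    pairs[[length(pairs) + 1L]] <- tibble(
      fwd_start = fs, fwd_len = fwd$len[i], tm_fwd = fwd$tm[i],
      gc_fwd = fwd$gc[i],
      rev_start = cand$start, rev_len = cand$len, tm_rev = cand$tm,
      gc_rev = cand$gc,
      product_size = cand$end - fs)
  }
  pairs <- dplyr::bind_rows(pairs)
  if (nrow(pairs) == 0L) {
    attr(empty, "rejections") <- rej
    class(empty) <- c("primer_pairs", class(empty))
    return(empty)
  }
  pairs <- pairs |>
    dplyr::mutate(
      fwd = substring(region, .data$fwd_start + 1L,
                      .data$fwd_start + .data$fwd_len),
      rev = vapply(substring(region, .data$rev_start + 1L,
                             .data$rev_start + .data$rev_len),
                   revcomp, character(1), USE.NAMES = FALSE),
      rank_key = abs((.data$tm_fwd + .data$tm_rev) / 2 - 57),
      rank_key2 = abs(.data$product_size - mid_product)) |>
    dplyr::arrange(.data$rank_key, .data$rank_key2) |>
    dplyr::select("fwd", "rev", "fwd_start", "rev_start", "tm_fwd",
                  "tm_rev", "gc_fwd", "gc_rev", "product_size") |>
    utils::head(max_pairs)
  attr(pairs, "rejections") <- rej
  class(pairs) <- c("primer_pairs", class(pairs))
  pairs
}

# binding sites of pattern q (5'->3') on one contig given as an int vector.
# orientation "+": q read along the forward strand, 3' end on the right;
# "-": q anneals to the forward strand via its reverse complement, 3' end on
# the left of the matched segment. Returns 1-based segment start positions.
binding_sites <- function(cvec, q, orientation, max_mismatch, three_prime_exact) {
  qs <- if (orientation == "+") q else revcomp(q)
  qv <- utf8ToInt(qs)
  L <- length(qv)
  n <- length(cvec)
  if (n < L) return(integer(0))
  npos <- n - L + 1L
  nn <- utf8ToInt("N")
  exact_idx <- if (orientation == "+") (L - three_prime_exact + 1L):L
               else seq_len(three_prime_exact)
  mism <- integer(npos)
  viol <- integer(npos)
  for (i in seq_len(L)) {
    g <- cvec[i:(i + npos - 1L)]
    bad <- (g != qv[i]) | (g == nn) | (qv[i] == nn)
    mism <- mism + bad
    if (i %in% exact_idx) viol <- viol + bad
  }
  which(mism <= max_mismatch & viol == 0L)
}

#' In-silico PCR of a primer pair against a genome panel
#'
#' A primer binds where it anneals with at most `max_mismatch` mismatches
#' and zero mismatches in its `three_prime_exact` 3'-terminal bases, on
#' either strand (`N` never matches). Amplicons are convergent forward /
#' reverse binding-site pairs with product size inside `size_window`. The
#' verdict for the target taxon is `UNIQUE` (exactly one target amplicon,
#' none elsewhere), `SIZE_DISCRIMINABLE` (one target amplicon; off-target
#' amplicons exist but all differ in size by at least `size_margin`),
#' `NON_SPECIFIC` (otherwise, given at least one target amplicon) or
#' `FAILED` (no target amplicon).
#'
#' @param fwd,rev Primer sequences, 5'->3'.
#' @param genomes List of [genome()] objects (the panel).
#' @param target Target taxon for the verdict.
#' @param max_mismatch Mismatch tolerance per primer site (default 2).
#' @param three_prime_exact 3'-terminal bases that must match exactly
#'   (default 3).
#' @param size_window Amplicon size range considered amplifiable
#'   (default `c(50, 2000)`).
#' @param size_margin Minimum size difference for gel discrimination
#'   (default 10 bp).
#' @return List of class `"amplicon_report"`: `amplicons` (tibble `taxon`,
#'   `contig_id`, `start`, `end`, `size`, `orientation`), `verdict`,
#'   `target`.
#' @export
insilico_pcr <- function(fwd, rev, genomes, target, max_mismatch = 2L,
                         three_prime_exact = 3L, size_window = c(50L, 2000L),
                         size_margin = 10L) {
  amps <- list()
  for (g in genomes) {
    for (ctg in names(g$contigs)) {
      cvec <- utf8ToInt(g$contigs[[ctg]])
      combos <- list(list(p = fwd, q = rev, lab = "fwd+/rev-"),
                     list(p = rev, q = fwd, lab = "rev+/fwd-"))
      for (cb in combos) {
        plus <- binding_sites(cvec, cb$p, "+", max_mismatch, three_prime_exact)
        minus <- binding_sites(cvec, cb$q, "-", max_mismatch, three_prime_exact)
        if (!length(plus) || !length(minus)) next
        lq <- nchar(cb$q)
        for (a in plus) {
          ends <- minus + lq - 1L
          sizes <- ends - a + 1L
          ok <- which(minus >= a & sizes >= size_window[1] &
                        sizes <= size_window[2])
          for (ix in ok) {
            amps[[length(amps) + 1L]] <- tibble(
              taxon = g$taxon, contig_id = ctg,
              start = a - 1L, end = ends[ix], size = sizes[ix],
              orientation = cb$lab)
          }
        }
      }
    }
  }
  amplicons <- if (length(amps)) dplyr::bind_rows(amps) else
    tibble(taxon = character(), contig_id = character(), start = integer(),
           end = integer(), size = integer(), orientation = character())
  tgt <- amplicons[amplicons$taxon == target, ]
  off <- amplicons[amplicons$taxon != target, ]
  verdict <- if (nrow(tgt) == 0L) {
    "FAILED"
  } else if (nrow(tgt) == 1L && nrow(off) == 0L) {
    "UNIQUE"
  } else if (nrow(tgt) == 1L && all(abs(off$size - tgt$size) >= size_margin)) {
    "SIZE_DISCRIMINABLE"
  } else {
    "NON_SPECIFIC"
  }
  structure(list(amplicons = amplicons, verdict = verdict, target = target),
            class = "amplicon_report")
}

#' @export
print.amplicon_report <- function(x, ...) {
  cat(sprintf("<amplicon_report> target %s: %s (%d amplicon(s) total)\n",
              x$target, x$verdict, nrow(x$amplicons)))
  invisible(x)
}

#' Screen a genome panel for species-specific diagnostic primers
#'
#' The full diagnostic pipeline for one target taxon: fragment its CDS set
#' into sliding windows, exclude windows with cross-genome hits, merge the
#' survivors into specific regions, design primer pairs in each region, and
#' keep only pairs whose in-silico PCR verdict is `UNIQUE` or
#' `SIZE_DISCRIMINABLE`.
#'
#' @param cds_sets Named list: taxon -> named character vector of CDS
#'   sequences (as from [make_cds_set()]).
#' @param genomes List of [genome()] objects (the panel).
#' @param target Target taxon.
#' @param w,s Fragmentation window and step (defaults 200/50).
#' @param min_identity,min_coverage,k Cross-match settings (defaults
#'   0.9/0.9/15).
#' @param max_pairs_eval Primer pairs per region put through in-silico PCR
#'   (default 10).
#' @param ... Further arguments passed to [design_primers()] and
#'   [insilico_pcr()] (matched by name).
#' @return List of class `"screen_result"`: `primers` (tibble of accepted
#'   pairs with `verdict`, `region_cds`, `region_start`, `region_end`),
#'   `reports` (list of `amplicon_report`), `regions`, `target`.
#' @export
screen_panel <- function(cds_sets, genomes, target, w = 200L, s = 50L,
                         min_identity = 0.9, min_coverage = 0.9, k = 15L,
                         max_pairs_eval = 10L, ...) {
  taxa <- vapply(genomes, function(g) g$taxon, character(1))
  if (!target %in% taxa) abort(sprintf("target %s not in genome panel", target))
  if (!target %in% names(cds_sets)) {
    abort(sprintf("no CDS set for target %s", target))
  }
  dots <- list(...)
  dp_args <- dots[names(dots) %in% names(formals(design_primers))]
  pcr_args <- dots[names(dots) %in% names(formals(insilico_pcr))]

  frags <- fragment_cds_set(cds_sets[[target]], w, s)
  report <- cross_match(frags, genomes, min_identity, min_coverage, k)
  spec <- select_specific(report, target, frags, w, s)
  accepted <- list(); reports <- list()
  for (i in seq_len(nrow(spec$regions))) {
    reg <- spec$regions[i, ]
    pp <- tryCatch(
      do.call(design_primers, c(list(region = reg$sequence), dp_args)),
      error = function(e) NULL)
    if (is.null(pp) || nrow(pp) == 0L) next
    pp <- utils::head(pp, max_pairs_eval)
    for (j in seq_len(nrow(pp))) {
      rep_j <- do.call(insilico_pcr,
                       c(list(fwd = pp$fwd[j], rev = pp$rev[j],
                              genomes = genomes, target = target), pcr_args))
      if (rep_j$verdict %in% c("UNIQUE", "SIZE_DISCRIMINABLE")) {
        key <- sprintf("%s:%d-%d#%d", reg$cds_id, reg$start, reg$end, j)
        accepted[[key]] <- dplyr::mutate(
          pp[j, ], verdict = rep_j$verdict, region_cds = reg$cds_id,
          region_start = reg$start, region_end = reg$end)
        reports[[key]] <- rep_j
      }
    }
  }
  primers <- if (length(accepted)) dplyr::bind_rows(accepted) else
    tibble(fwd = character(), rev = character(), fwd_start = integer(),
           rev_start = integer(), tm_fwd = numeric(), tm_rev = numeric(),
           gc_fwd = numeric(), gc_rev = numeric(), product_size = integer(),
           verdict = character(), region_cds = character(),
           region_start = integer(), region_end = integer())
  structure(list(primers = primers, reports = reports,
                 regions = spec$regions, target = target),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("<screen_result> target %s: %d specific region(s), %d accepted primer pair(s)\n",
              x$target, nrow(x$regions), nrow(x$primers)))
  invisible(x)
}
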