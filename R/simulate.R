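#' Configuration for the synthetic genome generator
#'
#' Defines the study conditions emulated by [simulate_dataset()]: a known
#' ultrametric species tree, conserved single-copy marker loci evolving under
#' Jukes-Cantor with per-locus and per-site rate variation, per-(locus,taxon)
#' dropout creating taxon-occupancy structure, nonconserved background
#' sequence, and planted species-specific insertions that ground-truth the
#' diagnostic screen.
#'
#' @param n_taxa Number of taxa.
#' @param tree_mode `"yule"` (pure-birth, exponential waiting times) or
#'   `"balanced"` (requires `n_taxa` a power of two).
#' @param tree_depth Expected substitutions/site from root to tip.
#' @param n_loci Number of conserved marker loci.
#' @param locus_length_mean,locus_length_sd Locus length distribution (bp);
#'   lengths are floored at 100 bp.
#' @param per_locus_rate_shape Gamma shape for the per-locus rate multiplier
#'   (mean 1); `Inf` means no variation.
#' @param per_site_rate_shape Gamma shape for the per-site rate multiplier
#'   (mean 1); `Inf` means no variation.
#' @param dropout_prob Probability that a (locus, taxon) copy is absent from
#'   that taxon's assembly.
#' @param background_length Nonconserved background bp per genome.
#' @param n_unique_regions Planted species-specific insertions per taxon.
#' @param unique_length Length (bp) of each planted insertion.
#' @param tile_width If non-`NULL`, split each locus reference sequence into
#'   probes of this width tiled at 50% overlap (UCE-style baits); otherwise
#'   one probe per locus.
#' @param dup_locus Optional `list(locus =, taxon =)` (indices): plant a second
#'   copy of that locus in that taxon, to exercise duplicate removal.
#' @param decoy Optional `list(from =, to =, divergence =)`: copy the first
#'   planted unique region of taxon `from` into taxon `to` with the given
#'   per-site mutation rate, creating a near-miss for the specificity screen.
#' @param seed Integer seed; fully determines the output.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_taxa = 8, tree_mode = c("yule", "balanced"),
                       tree_depth = 0.1, n_loci = 20,
                       locus_length_mean = 800, locus_length_sd = 200,
                       per_locus_rate_shape = 2, per_site_rate_shape = 0.5,
                       dropout_prob = 0.1, background_length = 20000,
                       n_unique_regions = 1, unique_length = 1000,
                       tile_width = NULL, dup_locus = NULL, decoy = NULL,
                       seed = 1) {
  tree_mode <- match.arg(tree_mode)
  stopifnot(n_taxa >= 2, n_loci >= 1, tree_depth >= 0,
            per_locus_rate_shape > 0, per_site_rate_shape > 0,
            dropout_prob >= 0, dropout_prob <= 1,
            background_length > 0, n_unique_regions >= 0, unique_length > 0)
  if (tree_mode == "balanced" && log2(n_taxa) %% 1 != 0) {
    abort("balanced tree_mode requires n_taxa a power of two")
  }
  structure(as.list(environment()), class = "sim_config")
}

# gamma multipliers with mean 1; shape Inf collapses to constant 1
gamma_mult <- function(n, shape) {
  if (is.infinite(shape)) rep(1, n) else stats::rgamma(n, shape = shape, rate = shape)
}

# ultrametric species tree at the requested depth
sim_tree <- function(n_taxa, mode, depth, labels) {
  if (mode == "yule") {
    tr <- ape::rphylo(n_taxa, birth = 1, death = 0)
  } else {
    tr <- ape::stree(n_taxa, "balanced")
    tr$edge.length <- rep(1, nrow(tr$edge))
  }
  tr$tip.label <- labels
  h <- max(ape::node.depth.edgelength(tr))
  if (h > 0 && depth > 0) tr$edge.length <- tr$edge.length * (depth / h)
  if (depth == 0) tr$edge.length <- tr$edge.length * 0
  tr
}

# evolve one locus along the tree under Jukes-Cantor; rates = per-site rate
# (locus multiplier already applied). Returns the root sequence and the tip
# rows as a character matrix.
evolve_jc <- function(tree, rates) {
  n_sites <- length(rates)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  states <- matrix(NA_integer_, nrow = nnode, ncol = n_sites)
  root <- ntip + 1L
  states[root, ] <- sample.int(4L, n_sites, replace = TRUE)
  # cladewise order: each edge's parent state is set before its children's
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]; chd <- tree$edge[e, 2]
    t <- tree$edge.length[e]
    p_sub <- 0.75 * (1 - exp(-(4 / 3) * rates * t))
    s <- states[par, ]
    hit <- stats::runif(n_sites) < p_sub
    if (any(hit)) {
      # new base uniform over the three alternatives
      shift <- sample.int(3L, sum(hit), replace = TRUE)
      s[hit] <- ((s[hit] - 1L + shift) %% 4L) + 1L
    }
    states[chd, ] <- s
  }
  tips <- matrix(DNA_BASES[states[seq_len(ntip), , drop = FALSE]],
                 nrow = ntip, dimnames = list(tree$tip.label, NULL))
  list(root = paste(DNA_BASES[states[root, ]], collapse = ""), tips = tips)
}

# mutate a sequence at a fixed per-site rate (used for decoys)
mutate_seq <- function(seq, rate) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(DNA_BASES, ch[i]), 1L)
  paste(ch, collapse = "")
}

#' Simulate a complete phylogenomic dataset with truth tables
#'
#' Generates genomes, a probe set, true per-locus alignments and full truth
#' tables under the conditions in a [sim_config()]. Loci evolve on the true
#' tree under Jukes-Cantor with per-locus x per-site rate multipliers and no
#' indels, so true alignments are column-exact. Retained (locus, taxon)
#' copies are embedded in i.i.d. background sequence at recorded coordinates
#' (random strand); dropped copies are omitted. Planted unique regions are
#' i.i.d. uniform DNA inserted once, in exactly one taxon each.
#'
#' @param config A [sim_config()].
#' @return A list of class `"sim_dataset"` with elements `genomes` (list of
#'   [genome()]), `probes` (a [probe_set()]), `loci` (list of true
#'   `locus_aln`), `truth` (list: `tree`, `locus_presence` matrix,
#'   `locus_coords`, `unique_regions`, `site_rates`), and `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  taxa <- sprintf("t%02d", seq_len(config$n_taxa))
  tree <- sim_tree(config$n_taxa, config$tree_mode, config$tree_depth, taxa)

  locus_ids <- sprintf("L%03d", seq_len(config$n_loci))
  lens <- pmax(100L, as.integer(round(stats::rnorm(
    config$n_loci, config$locus_length_mean, config$locus_length_sd))))
  locus_rate <- gamma_mult(config$n_loci, config$per_locus_rate_shape)

  loci <- vector("list", config$n_loci)
  site_rates <- vector("list", config$n_loci)
  roots <- character(config$n_loci)
  for (i in seq_len(config$n_loci)) {
    sr <- gamma_mult(lens[i], config$per_site_rate_shape) * locus_rate[i]
    site_rates[[i]] <- sr
    ev <- evolve_jc(tree, sr)
    rows <- apply(ev$tips, 1L, paste, collapse = "")
    loci[[i]] <- locus_alignment(locus_ids[i], rows)
    roots[i] <- ev$root
  }
  names(loci) <- locus_ids
  names(site_rates) <- locus_ids

  # presence matrix (dropout)
  pres <- matrix(stats::runif(config$n_loci * config$n_taxa) >= config$dropout_prob,
                 nrow = config$n_loci,
                 dimnames = list(locus_ids, taxa))

  # probe set = root sequence of each locus, optionally tiled
  probes <- character(0); probe_map <- character(0)
  for (i in seq_len(config$n_loci)) {
    ref <- roots[i]
    if (is.null(config$tile_width) || config$tile_width >= nchar(ref)) {
      pid <- paste0(locus_ids[i], "_p1")
      probes[pid] <- ref
      probe_map[pid] <- locus_ids[i]
    } else {
      w <- config$tile_width
      starts <- unique(c(seq(1L, nchar(ref) - w + 1L, by = max(1L, w %/% 2L)),
                         nchar(ref) - w + 1L))
      for (j in seq_along(starts)) {
        pid <- sprintf("%s_p%d", locus_ids[i], j)
        probes[pid] <- substr(ref, starts[j], starts[j] + w - 1L)
        probe_map[pid] <- locus_ids[i]
      }
    }
  }
  probeset <- probe_set(probes, probe_map, marker_label = "SIM")

  # unique regions
  uniq <- list()
  for (tx in taxa) {
    k <- config$n_unique_regions
    if (k > 0) {
      for (j in seq_len(k)) {
        uniq[[length(uniq) + 1L]] <- list(
          taxon = tx, region_id = sprintf("%s_U%d", tx, j),
          sequence = random_dna(config$unique_length))
      }
    }
  }

  # assemble genomes: features interleaved with background chunks
  min_chunk <- 200L
  coords <- list(); ureg <- list(); genomes <- list()
  for (tx in taxa) {
    feats <- list()
    for (i in seq_len(config$n_loci)) {
      if (pres[i, tx]) {
        feats[[length(feats) + 1L]] <- list(
          kind = "locus", id = locus_ids[i],
          seq = paste(loci[[i]]$mat[tx, ], collapse = ""))
      }
    }
    if (!is.null(config$dup_locus) && taxa[config$dup_locus$taxon] == tx) {
      li <- config$dup_locus$locus
      feats[[length(feats) + 1L]] <- list(
        kind = "locus_dup", id = locus_ids[li],
        seq = paste(loci[[li]]$mat[tx, ], collapse = ""))
    }
    for (u in uniq) {
      if (u$taxon == tx) {
        feats[[length(feats) + 1L]] <- list(kind = "unique", id = u$region_id,
                                            seq = u$sequence)
      }
    }
    if (!is.null(config$decoy) && taxa[config$decoy$to] == tx) {
      src <- purrr::keep(uniq, ~ .x$taxon == taxa[config$decoy$from])[[1]]
      feats[[length(feats) + 1L]] <- list(
        kind = "decoy", id = paste0(src$region_id, "_decoy"),
        seq = mutate_seq(src$sequence, config$decoy$divergence))
    }
    nf <- length(feats)
    if (config$background_length < min_chunk * (nf + 1L)) {
      abort(sprintf(
        "background_length %d too small for %d features in %s; increase background_length (need >= %d)",
        config$background_length, nf, tx, min_chunk * (nf + 1L)))
    }
    feats <- feats[sample.int(nf)]
    # random chunk sizes >= min_chunk summing to background_length
    extra <- config$background_length - min_chunk * (nf + 1L)
    cuts <- sort(sample.int(extra + 1L, nf, replace = TRUE) - 1L)
    sizes <- diff(c(0L, cuts, extra)) + min_chunk
    pieces <- character(0); pos <- 0L
    ctg <- paste0(tx, "_ctg1")
    for (j in seq_len(nf + 1L)) {
      bg <- random_dna(sizes[j])
      pieces <- c(pieces, bg); pos <- pos + sizes[j]
      if (j <= nf) {
        f <- feats[[j]]
        strand <- if (f$kind %in% c("unique", "decoy")) "+" else sample(c("+", "-"), 1L)
        emb <- if (strand == "-") revcomp(f$seq) else f$seq
        start0 <- pos; end0 <- pos + nchar(emb)
        rec <- list(taxon = tx, contig_id = ctg, start = start0, end = end0,
                    strand = strand, kind = f$kind, id = f$id)
        if (f$kind == "unique") {
          ureg[[length(ureg) + 1L]] <- c(rec, list(sequence = f$seq))
        } else {
          coords[[length(coords) + 1L]] <- rec
        }
        pieces <- c(pieces, emb); pos <- end0
      }
    }
    contig <- paste(pieces, collapse = "")
    genomes[[tx]] <- genome(tx, stats::setNames(contig, ctg))
  }

  locus_coords <- dplyr::bind_rows(
    tibble(locus_id = character(), taxon = character(),
           contig_id = character(), start = integer(), end = integer(),
           strand = character(), kind = character()),
    purrr::map(coords, function(r) {
      tibble(locus_id = r$id, taxon = r$taxon, contig_id = r$contig_id,
             start = r$start, end = r$end, strand = r$strand, kind = r$kind)
    }))
  unique_regions <- dplyr::bind_rows(
    tibble(taxon = character(), region_id = character(),
           contig_id = character(), start = integer(), end = integer(),
           sequence = character()),
    purrr::map(ureg, function(r) {
      tibble(taxon = r$taxon, region_id = r$id, contig_id = r$contig_id,
             start = r$start, end = r$end, sequence = r$sequence)
    }))

  structure(list(genomes = genomes, probes = probeset, loci = loci,
                 truth = list(tree = tree, locus_presence = pres,
                              locus_coords = locus_coords,
                              unique_regions = unique_regions,
                              site_rates = site_rates),
                 config = config),
            class = "sim_dataset")
}

#' Build per-taxon CDS sets from a simulated dataset
#'
#' Stand-in for ab-initio gene prediction: each taxon's coding set contains
#' its retained marker-locus copies plus its planted unique regions. Record
#' ids encode `taxon|kind|feature|start-end` (0-based half-open genome
#' coordinates) so every record can be traced back to the truth tables.
#'
#' @param sim A `"sim_dataset"` from [simulate_dataset()].
#' @return Named list: taxon -> named character vector of CDS sequences.
#' @export
make_cds_set <- function(sim) {
  stopifnot(inherits(sim, "sim_dataset"))
  out <- list()
  for (tx in names(sim$genomes)) {
    recs <- character(0)
    lc <- dplyr::filter(sim$truth$locus_coords, .data$taxon == tx,
                        .data$kind == "locus")
    for (i in seq_len(nrow(lc))) {
      id <- sprintf("%s|locus|%s|%d-%d", tx, lc$locus_id[i], lc$start[i], lc$end[i])
      recs[id] <- paste(sim$loci[[lc$locus_id[i]]]$mat[tx, ], collapse = "")
    }
    ur <- dplyr::filter(sim$truth$unique_regions, .data$taxon == tx)
    for (i in seq_len(nrow(ur))) {
      id <- sprintf("%s|unique|%s|%d-%d", tx, ur$region_id[i], ur$start[i], ur$end[i])
      recs[id] <- ur$sequence[i]
    }
    out[[tx]] <- recs
  }
  out
}

#' Parse CDS record ids minted by [make_cds_set()]
#'
#' @param ids Character vector of CDS ids.
#' @return Tibble with columns `taxon`, `kind`, `feature`, `start`, `end`.
#' @export
parse_cds_id <- function(ids) {
  parts <- strsplit(ids, "|", fixed = TRUE)
  dplyr::bind_rows(purrr::map(parts, function(p) {
    iv <- as.integer(strsplit(p[4], "-", fixed = TRUE)[[1]])
    tibble(taxon = p[1], kind = p[2], feature = p[3],
           start = iv[1], end = iv[2])
  }))
}
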