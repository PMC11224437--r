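test_that("window fragmentation counts follow floor((L-w)/s) + 1", {
  set.seed(401)
  for (L in c(199, 200, 1000, 100000)) {
    cds <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
    fr <- fragment_windows(cds, w = 200, s = 50)
    expected <- if (L < 200) 0L else floor((L - 200) / 50) + 1L
    expect_equal(nrow(fr), expected)
    if (nrow(fr)) {
      expect_true(all(nchar(fr$sequence) == 200L))
      expect_true(all(fr$offset %% 50 == 0))
      expect_equal(fr$sequence[1], substr(cds, 1, 200))
    }
  }
  expect_equal(nrow(fragment_windows(strrep("A", 1000))), 17L)
})

test_that("cross-genome matching counts hits and respects the simulator truth", {
  sim <- simulate_dataset(diag_config(17))
  cds <- make_cds_set(sim)
  frags <- fragment_cds_set(cds[["t01"]])
  rep <- cross_match(frags, sim$genomes)

  # every fragment hits its own genome at least once
  own <- rep[rep$taxon == "t01", ]
  expect_true(all(own$n_hits >= 1L))
  # fragments of the planted unique region hit no other genome
  uniq_ids <- frags$fragment_id[grepl("\\|unique\\|", frags$cds_id)]
  off <- rep[rep$fragment_id %in% uniq_ids & rep$taxon != "t01", ]
  expect_true(all(off$n_hits == 0L))
  # conserved-locus fragments hit at least one other genome
  cons <- rep[!(rep$fragment_id %in% uniq_ids) & rep$taxon != "t01", ]
  per_frag <- tapply(cons$n_hits, cons$fragment_id, sum)
  expect_true(all(per_frag >= 1L))
})

test_that("fragments containing N are skipped with a log", {
  g <- genome("t1", c(c1 = strrep("ACGT", 200)))
  frags <- tibble::tibble(cds_id = "c", offset = c(0L, 50L),
                          sequence = c(strrep("ACGT", 50),
                                       paste0("N", substr(strrep("ACGT", 50), 2, 200))),
                          fragment_id = c("c@0", "c@50"))
  expect_message(rep <- cross_match(frags, list(g)), "skipping 1")
  expect_equal(attr(rep, "skipped"), "c@50")
  expect_false("c@50" %in% rep$fragment_id)
})

test_that("a decoy within the identity threshold is reported as a hit", {
  sim <- simulate_dataset(sim_config(
    seed = 19, n_taxa = 4, tree_depth = 0.02, per_locus_rate_shape = Inf,
    decoy = list(from = 1, to = 2, divergence = 0.05)))
  cds <- make_cds_set(sim)
  frags <- fragment_cds_set(cds[["t01"]])
  uniq_ids <- frags$fragment_id[grepl("\\|unique\\|", frags$cds_id)]
  rep <- cross_match(frags, sim$genomes, min_identity = 0.9)
  decoy_hits <- rep[rep$fragment_id %in% uniq_ids & rep$taxon == "t02", ]
  expect_true(any(decoy_hits$n_hits >= 1L))
  # and the decoy disqualifies those fragments from specificity
  spec <- select_specific(rep, "t01", frags)
  expect_false(any(grepl("\\|unique\\|", spec$regions$cds_id)))
})

test_that("specific windows merge into maximal regions over planted inserts", {
  sim2 <- simulate_dataset(sim_config(seed = 23, n_taxa = 8, tree_depth = 0.02,
                                      per_locus_rate_shape = Inf,
                                      n_unique_regions = 2))
  cds <- make_cds_set(sim2)
  frags <- fragment_cds_set(cds[["t03"]])
  rep <- cross_match(frags, sim2$genomes)
  spec <- select_specific(rep, "t03", frags)
  uregions <- spec$regions[grepl("\\|unique\\|", spec$regions$cds_id), ]
  # two planted 1-kb unique regions -> two merged specific regions that
  # cover each insert end to end (all 17 interior windows pass)
  expect_equal(nrow(uregions), 2L)
  expect_equal(uregions$n_windows, c(17L, 17L))
  expect_equal(uregions$start, c(0L, 0L))
  expect_equal(uregions$end, c(1000L, 1000L))
  # the reassembled region sequence equals the planted insert
  ur <- sim2$truth$unique_regions
  for (i in seq_len(nrow(uregions))) {
    planted <- ur$sequence[paste0(ur$taxon, "|unique|", ur$region_id) ==
                             sub("\\|[0-9]+-[0-9]+$", "", uregions$cds_id[i])]
    expect_equal(uregions$sequence[i], planted)
  }
})

test_that("a single-genome panel makes everything trivially specific", {
  g <- genome("solo", c(c1 = strrep("ACGTAGGCCATT", 100)))
  frags <- fragment_cds_set(c(cds1 = substr(g$contigs[[1]], 1, 400)))
  rep <- cross_match(frags, list(g))
  expect_warning(spec <- select_specific(rep, "solo", frags), "trivially")
  expect_equal(nrow(spec$fragments), nrow(frags))
})

test_that("Wallace-rule Tm is exact and drives the design filters", {
  expect_equal(wallace_tm("GGGGGCCCCCAAAAATTTTT"), 2 * 10 + 4 * 10)  # 60
  expect_equal(wallace_tm("ATATATATATATATATATAT"), 40)
  expect_equal(wallace_tm(c("ACGT", "AAAA")), c(12, 8))

  # an all-AT 20-mer fails both the GC and Tm filters
  region <- paste0(strrep("AT", 60), strrep("GCAT", 20))
  pp <- design_primers(region)
  rej <- attr(pp, "rejections")
  expect_gt(rej[["gc"]], 0)
  expect_gt(rej[["tm"]], 0)
})

test_that("designed primers satisfy every constraint", {
  set.seed(402)
  region <- paste(sample(c("A", "C", "G", "T"), 600, TRUE), collapse = "")
  pp <- design_primers(region)
  expect_gt(nrow(pp), 0)
  expect_true(all(nchar(pp$fwd) >= 18 & nchar(pp$fwd) <= 27))
  expect_true(all(pp$tm_fwd >= 53 & pp$tm_fwd <= 60))
  expect_true(all(pp$tm_rev >= 53 & pp$tm_rev <= 60))
  expect_true(all(abs(pp$tm_fwd - pp$tm_rev) <= 3))
  expect_true(all(pp$gc_fwd >= 40 & pp$gc_fwd <= 60))
  expect_true(all(pp$product_size >= 100 & pp$product_size <= 200))
  expect_true(all(!grepl("A{5}|C{5}|G{5}|T{5}", pp$fwd)))
  expect_true(all(!grepl("A{5}|C{5}|G{5}|T{5}", pp$rev)))
  expect_equal(pp$tm_fwd, wallace_tm(pp$fwd))
  expect_equal(pp$tm_rev, wallace_tm(pp$rev))
  # rev is reported 5'->3' on the opposite strand
  i <- 1L
  tmpl <- substr(region, pp$rev_start[i] + 1,
                 pp$rev_start[i] + nchar(pp$rev[i]))
  expect_equal(pp$rev[i], revcomp(tmpl))

  # a 150-bp region cannot yield products over 150 bp
  r150 <- substr(region, 1, 150)
  pp2 <- design_primers(r150)
  if (nrow(pp2)) expect_true(all(pp2$product_size <= 150))
  expect_error(design_primers(substr(region, 1, 80)), "shorter")
})

test_that("in-silico PCR finds the designed amplicon and only it", {
  sim <- simulate_dataset(diag_config(29))
  ur <- sim$truth$unique_regions
  reg <- ur$sequence[ur$taxon == "t02"]
  pp <- design_primers(reg)
  expect_gt(nrow(pp), 0)
  rep <- insilico_pcr(pp$fwd[1], pp$rev[1], sim$genomes, target = "t02")
  expect_equal(rep$verdict, "UNIQUE")
  expect_equal(nrow(rep$amplicons), 1L)
  expect_equal(rep$amplicons$size, pp$product_size[1])

  # divergent orientation never amplifies: swap rev for its own template
  # strand (both primers now anneal to the same strand)
  rev_same_strand <- revcomp(pp$rev[1])
  rep2 <- insilico_pcr(pp$fwd[1], rev_same_strand, sim$genomes, target = "t02")
  expect_equal(nrow(rep2$amplicons[rep2$amplicons$orientation == "fwd+/rev-", ]), 0L)
})

test_that("off-target products at a different size are size-discriminable", {
  set.seed(403)
  reg <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  pp <- design_primers(reg)
  amp <- substr(reg, pp$fwd_start[1] + 1,
                pp$fwd_start[1] + pp$product_size[1])
  # plant the true amplicon in the target and a lengthened version off-target
  mid <- nchar(amp) %/% 2
  spacer <- paste(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = "")
  longer <- paste0(substr(amp, 1, mid), spacer, substr(amp, mid + 1, nchar(amp)))
  bg1 <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
  bg2 <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
  gt <- genome("target", c(c1 = paste0(bg1, amp, bg2)))
  go <- genome("other", c(c1 = paste0(bg2, longer, bg1)))
  rep <- insilico_pcr(pp$fwd[1], pp$rev[1], list(gt, go), target = "target",
                      size_margin = 10)
  expect_equal(rep$verdict, "SIZE_DISCRIMINABLE")
  # same size off-target would be non-specific instead
  go2 <- genome("other", c(c1 = paste0(bg2, amp, bg1)))
  rep2 <- insilico_pcr(pp$fwd[1], pp$rev[1], list(gt, go2), target = "target")
  expect_equal(rep2$verdict, "NON_SPECIFIC")
  # and no target amplicon at all fails
  rep3 <- insilico_pcr(pp$fwd[1], pp$rev[1], list(genome("target", c(c1 = bg1)), go2),
                       target = "target")
  expect_equal(rep3$verdict, "FAILED")
})

test_that("hit and amplicon counts move monotonically with their thresholds", {
  sim <- simulate_dataset(diag_config(31))
  cds <- make_cds_set(sim)
  frags <- fragment_cds_set(cds[["t04"]])[1:40, ]
  lo <- cross_match(frags, sim$genomes, min_identity = 0.85)
  hi <- cross_match(frags, sim$genomes, min_identity = 0.95)
  m <- merge(as.data.frame(lo), as.data.frame(hi),
             by = c("fragment_id", "taxon"))
  expect_true(all(m$n_hits.y <= m$n_hits.x))

  ur <- sim$truth$unique_regions
  pp <- design_primers(ur$sequence[ur$taxon == "t04"])
  a0 <- insilico_pcr(pp$fwd[1], pp$rev[1], sim$genomes, "t04", max_mismatch = 0)
  a3 <- insilico_pcr(pp$fwd[1], pp$rev[1], sim$genomes, "t04", max_mismatch = 3)
  expect_gte(nrow(a3$amplicons), nrow(a0$amplicons))
})

test_that("the end-to-end screen is sound, complete and deterministic", {
  sim <- simulate_dataset(diag_config(37))
  cds <- make_cds_set(sim)
  sc1 <- screen_panel(cds, sim$genomes, "t05")
  sc2 <- screen_panel(cds, sim$genomes, "t05")
  expect_identical(sc1$primers, sc2$primers)
  expect_gt(sum(sc1$primers$verdict == "UNIQUE"), 0)
  # soundness: every UNIQUE pair re-amplifies exactly once in the target
  # and never off-target at the same settings
  for (k in which(sc1$primers$verdict == "UNIQUE")) {
    rep <- insilico_pcr(sc1$primers$fwd[k], sc1$primers$rev[k],
                        sim$genomes, "t05")
    expect_equal(nrow(rep$amplicons[rep$amplicons$taxon == "t05", ]), 1L)
    expect_equal(nrow(rep$amplicons[rep$amplicons$taxon != "t05", ]), 0L)
  }
})
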