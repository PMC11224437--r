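make_bg <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
}

test_that("exact and reverse-complement probe matches are found", {
  set.seed(31)
  probe <- paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
  bg <- make_bg(3000, 32)
  g_fwd <- genome("tf", c(c1 = paste0(substr(bg, 1, 1000), probe,
                                      substr(bg, 1001, 3000))))
  ps <- probe_set(c(p1 = probe), c(p1 = "L1"))
  h <- match_probes(g_fwd, ps)
  expect_equal(nrow(h), 1L)
  expect_equal(h$strand, "+")
  expect_equal(h$identity, 1.0)
  expect_equal(c(h$start, h$end), c(1000L, 1120L))

  g_rev <- genome("tr", c(c1 = paste0(substr(bg, 1, 1000), revcomp(probe),
                                      substr(bg, 1001, 3000))))
  h2 <- match_probes(g_rev, ps)
  expect_equal(nrow(h2), 1L)
  expect_equal(h2$strand, "-")
  expect_equal(h2$identity, 1.0)
})

test_that("scattered mismatches are tolerated when a seed survives", {
  # 120-bp probe, 6 mismatches spaced >= 16 bp apart: an exact 15-mer seed
  # exists and identity = 114/120 = 0.95 >= 0.9
  set.seed(33)
  probe <- paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
  target <- strsplit(probe, "")[[1]]
  flip <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]
  pos <- c(10, 30, 50, 70, 90, 110)
  for (p in pos) target[p] <- flip(target[p])
  g <- genome("t1", c(c1 = paste0(make_bg(500, 34),
                                  paste(target, collapse = ""),
                                  make_bg(500, 35))))
  ps <- probe_set(c(p1 = probe), c(p1 = "L1"))
  h <- match_probes(g, ps, min_identity = 0.9, min_coverage = 0.9, k = 15)
  expect_equal(nrow(h), 1L)
  expect_equal(h$identity, 114 / 120)
  # brute-force confirmation of the same contract
  b <- merge_brute(brute_match(g, ps, 0.9, 0.9))
  expect_equal(h$identity, b$identity)
  expect_equal(h$start, b$start)
})

test_that("probe shorter than the seed length is rejected by name", {
  g <- genome("t1", c(c1 = make_bg(200, 36)))
  ps <- probe_set(c(tiny = "ACGTACGTAC"), c(tiny = "L1"))
  expect_error(match_probes(g, ps, k = 15), "tiny")
})

test_that("seeded matcher agrees with the brute-force scan on small genomes", {
  set.seed(40)
  for (rep in 1:5) {
    bg <- make_bg(4000, 40 + rep)
    probes <- character(0); map <- character(0)
    inserts <- character(0)
    for (i in 1:3) {
      p <- paste(sample(c("A", "C", "G", "T"), sample(80:150, 1), TRUE),
                 collapse = "")
      pid <- paste0("p", i)
      probes[pid] <- p; map[pid] <- paste0("L", i)
      # plant with a couple of sparse mismatches, random strand
      ch <- strsplit(p, "")[[1]]
      for (mp in sample(seq_along(ch), 2)) {
        ch[mp] <- setdiff(c("A", "C", "G", "T"), ch[mp])[1]
      }
      ins <- paste(ch, collapse = "")
      if (runif(1) < 0.5) ins <- revcomp(ins)
      inserts <- c(inserts, ins)
    }
    cut <- sort(sample(500:3500, 3))
    seq <- paste0(substr(bg, 1, cut[1]), inserts[1],
                  substr(bg, cut[1] + 1, cut[2]), inserts[2],
                  substr(bg, cut[2] + 1, cut[3]), inserts[3],
                  substr(bg, cut[3] + 1, 4000))
    g <- genome("t1", c(c1 = seq))
    ps <- probe_set(probes, map)
    mine <- as.data.frame(match_probes(g, ps, 0.85, 0.8, k = 15))
    brut <- merge_brute(brute_match(g, ps, 0.85, 0.8))
    mine <- mine[order(mine$probe_id, mine$start),
                 c("probe_id", "start", "end", "strand", "identity")]
    brut <- brut[order(brut$probe_id, brut$start),
                 c("probe_id", "start", "end", "strand", "identity")]
    rownames(mine) <- rownames(brut) <- NULL
    expect_equal(mine, brut)
  }
})

test_that("extraction retains 400-bp flanks and truncates at contig ends", {
  set.seed(50)
  probe <- paste(sample(c("A", "C", "G", "T"), 150, TRUE), collapse = "")
  ps <- probe_set(c(p1 = probe), c(p1 = "L1"))

  g_mid <- genome("t1", c(c1 = paste0(make_bg(1000, 51), probe,
                                      make_bg(1000, 52))))
  de <- dedupe_and_extract(match_probes(g_mid, ps), g_mid, ps, flank = 400)
  expect_equal(nchar(de$captures$sequence), 150 + 800L)
  expect_false(de$captures$truncated)
  expect_equal(de$captures$flank_left, 400L)

  # probe-match core starting at position 100: left flank truncated to 100
  g_edge <- genome("t2", c(c1 = paste0(make_bg(100, 53), probe,
                                       make_bg(1000, 54))))
  de2 <- dedupe_and_extract(match_probes(g_edge, ps), g_edge, ps, flank = 400)
  expect_equal(de2$captures$flank_left, 100L)
  expect_equal(de2$captures$flank_right, 400L)
  expect_true(de2$captures$truncated)
  expect_equal(nchar(de2$captures$sequence), 150 + 500L)
})

test_that("duplicated loci are dropped for that taxon with a reason code", {
  set.seed(60)
  probe <- paste(sample(c("A", "C", "G", "T"), 150, TRUE), collapse = "")
  ps <- probe_set(c(p1 = probe), c(p1 = "L1"))
  g_dup <- genome("t1", c(c1 = paste0(make_bg(800, 61), probe,
                                      make_bg(800, 62), probe,
                                      make_bg(800, 63))))
  de <- dedupe_and_extract(match_probes(g_dup, ps), g_dup, ps)
  expect_equal(nrow(de$captures), 0L)
  expect_equal(de$drops$reason, "DUPLICATE_LOCUS")

  # a duplicate in one taxon does not affect another taxon
  g_ok <- genome("t2", c(c1 = paste0(make_bg(800, 64), probe,
                                     make_bg(800, 65))))
  res <- capture_all(list(g_dup, g_ok), ps)
  expect_equal(res$counts$n_loci, c(0L, 1L))
})

test_that("a region claimed by two loci drops both with SHARED_REGION", {
  set.seed(70)
  probe <- paste(sample(c("A", "C", "G", "T"), 150, TRUE), collapse = "")
  ps <- probe_set(c(p1 = probe, p2 = probe), c(p1 = "L1", p2 = "L2"))
  g <- genome("t1", c(c1 = paste0(make_bg(800, 71), probe, make_bg(800, 72))))
  de <- dedupe_and_extract(match_probes(g, ps), g, ps)
  expect_equal(nrow(de$captures), 0L)
  expect_setequal(de$drops$locus_id, c("L1", "L2"))
  expect_true(all(de$drops$reason == "SHARED_REGION"))
})

test_that("capture recovers planted loci and is deterministic", {
  sim <- simulate_dataset(sim_config(seed = 5, tree_depth = 0.05))
  cap1 <- capture_all(sim$genomes, sim$probes)
  cap2 <- capture_all(sim$genomes, sim$probes)
  expect_identical(cap1$captures, cap2$captures)

  pres <- sim$truth$locus_presence
  want <- paste(rep(rownames(pres), ncol(pres)),
                rep(colnames(pres), each = nrow(pres)))[as.vector(pres)]
  got <- paste(cap1$captures$locus_id, cap1$captures$taxon)
  expect_gte(mean(want %in% got), 0.95)

  # no captured interval exceeds contig bounds; minus-strand extraction is
  # the reverse complement of the forward one
  ok_bounds <- TRUE; ok_seq <- TRUE
  for (i in seq_len(nrow(cap1$captures))) {
    r <- cap1$captures[i, ]
    ctg <- sim$genomes[[r$taxon]]$contigs[[r$contig_id]]
    fw_start <- r$start - (if (r$strand == "+") r$flank_left else r$flank_right)
    fw_end <- r$end + (if (r$strand == "+") r$flank_right else r$flank_left)
    ok_bounds <- ok_bounds && fw_start >= 0 && fw_end <= nchar(ctg)
    fw <- substr(ctg, fw_start + 1, fw_end)
    ok_seq <- ok_seq &&
      identical(r$sequence, if (r$strand == "-") revcomp(fw) else fw)
  }
  expect_true(ok_bounds)
  expect_true(ok_seq)
})

test_that("anchor alignment reproduces the simulator truth on captured taxa", {
  sim <- simulate_dataset(sim_config(seed = 5, tree_depth = 0.05))
  cap <- capture_all(sim$genomes, sim$probes)
  for (lid in unique(cap$captures$locus_id)[1:5]) {
    rows <- cap$captures[cap$captures$locus_id == lid, ]
    aln <- anchor_align(rows, core_only = TRUE)
    truth <- sim$loci[[lid]]$mat[rownames(aln$mat), , drop = FALSE]
    expect_equal(dim(aln$mat), dim(truth))
    expect_equal(aln$mat, truth)
  }
})

test_that("anchor alignment pads truncated flanks with leading gaps", {
  set.seed(80)
  probe <- paste(sample(c("A", "C", "G", "T"), 150, TRUE), collapse = "")
  ps <- probe_set(c(p1 = probe), c(p1 = "L1"))
  g1 <- genome("t1", c(c1 = paste0(make_bg(400, 81), probe, make_bg(400, 82))))
  g2 <- genome("t2", c(c1 = paste0(make_bg(100, 83), probe, make_bg(400, 84))))
  caps <- capture_all(list(g1, g2), ps)$captures
  aln <- anchor_align(caps)
  expect_equal(ncol(aln$mat), 400 + 150 + 400)
  expect_equal(sum(aln$mat["t2", ] == "-"), 300L)
  expect_true(all(aln$mat["t2", 1:300] == "-"))

  # identical copies give identical rows with no gaps
  aln_core <- anchor_align(caps, core_only = TRUE)
  expect_equal(aln_core$mat["t1", ], aln_core$mat["t2", ])
  expect_false(any(aln_core$mat == "-"))
})

test_that("empty genome list yields an empty capture", {
  ps <- probe_set(c(p1 = strrep("ACGT", 10)), c(p1 = "L1"))
  res <- capture_all(list(), ps)
  expect_equal(nrow(res$captures), 0L)
  expect_equal(nrow(res$counts), 0L)
})
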