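#' Jukes-Cantor distance matrix from an alignment
#'
#' Pairwise comparisons use only columns where both rows carry a residue
#' state. The observed mismatch fraction p is corrected as
#' d = -(3/4) log(1 - (4/3) p); saturated pairs (p >= 3/4) are set to
#' `ceiling` and flagged in the `"saturated"` attribute.
#'
#' @param aln A `locus_aln` with at least two rows.
#' @param ceiling Distance assigned to saturated pairs (default 5).
#' @return Symmetric numeric matrix with taxa as dimnames.
#' @export
jc_distance <- function(aln, ceiling = 5) {
  stopifnot(inherits(aln, "locus_aln"), nrow(aln$mat) >= 2L)
  mat <- aln$mat
  n <- nrow(mat)
  ok <- !is_missing_mat(mat, aln$alphabet)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  sat <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      comp <- ok[i, ] & ok[j, ]
      m <- sum(comp)
      if (m == 0L) {
        abort(sprintf("no comparable columns between %s and %s",
                      rownames(mat)[i], rownames(mat)[j]))
      }
      p <- sum(mat[i, comp] != mat[j, comp]) / m
      if (p >= 0.75) {
        d[i, j] <- d[j, i] <- ceiling
        sat[i, j] <- sat[j, i] <- TRUE
      } else {
        d[i, j] <- d[j, i] <- -0.75 * log(1 - (4 / 3) * p)
      }
    }
  }
  attr(d, "saturated") <- sat
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Q-criterion agglomeration (via \code{ape::nj}); negative branch
#' lengths are clamped to zero and flagged in the `"clamped"` attribute. The
#' result is unrooted.
#'
#' @param d Symmetric distance matrix with labelled rows/columns, n >= 3.
#' @return An unrooted `"phylo"` tree.
#' @export
neighbor_joining <- function(d) {
  if (!isSymmetric(unname(as.matrix(d)), tol = 1e-12)) {
    abort("distance matrix must be symmetric")
  }
  if (any(!is.finite(as.matrix(d)))) abort("non-finite distances")
  stopifnot(nrow(as.matrix(d)) >= 3L)
  tr <- ape::nj(as.dist(d))
  neg <- tr$edge.length < 0
  tr$edge.length[neg] <- 0
  attr(tr, "clamped") <- any(neg)
  tr
}

# canonical keys of the non-trivial bipartitions of an unrooted tree.
# Each internal edge splits the leaves; the side NOT containing the
# lexicographically first leaf is the key. Works for polytomies.
bipartitions <- function(tree) {
  tips <- tree$tip.label
  n <- length(tips)
  if (n < 4L) return(character(0))
  ref <- sort(tips)[1]
  ntip <- n
  # leaf sets below each node, by postorder accumulation
  post <- ape::reorder.phylo(tree, "postorder")
  below <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- tips[i]
  for (e in seq_len(nrow(post$edge))) {
    par <- post$edge[e, 1]; chd <- post$edge[e, 2]
    below[[par]] <- c(below[[par]], below[[chd]])
  }
  keys <- character(0)
  root <- ntip + 1L
  for (e in seq_len(nrow(tree$edge))) {
    chd <- tree$edge[e, 2]
    if (chd <= ntip) next                      # trivial split
    side <- below[[chd]]
    k <- length(side)
    if (k < 2L || k > n - 2L) next             # trivial after unrooting
    if (ref %in% side) side <- setdiff(tips, side)
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

#' Robinson-Foulds distance between two trees
#'
#' The unnormalized symmetric-difference count of non-trivial bipartitions,
#' treating both trees as unrooted; polytomies are allowed. Use
#' `normalized = TRUE` to divide by 2(n-3).
#'
#' @param t1,t2 `"phylo"` trees on the same leaf set.
#' @param normalized Return RF / (2(n-3)) instead (default `FALSE`).
#' @return Integer distance (numeric if normalized).
#' @export
robinson_foulds <- function(t1, t2, normalized = FALSE) {
  if (!setequal(t1$tip.label, t2$tip.label)) {
    abort(sprintf("leaf sets differ: only in first: %s; only in second: %s",
                  paste(setdiff(t1$tip.label, t2$tip.label), collapse = ","),
                  paste(setdiff(t2$tip.label, t1$tip.label), collapse = ",")))
  }
  b1 <- bipartitions(t1); b2 <- bipartitions(t2)
  rf <- length(setdiff(b1, b2)) + length(setdiff(b2, b1))
  if (normalized) {
    n <- length(t1$tip.label)
    if (n <= 3L) return(0)
    return(rf / (2 * (n - 3)))
  }
  as.integer(rf)
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and reports for each internal bipartition of the point-estimate
#' tree the percentage of replicates containing it (0-100 scale, stored in
#' `node.label`).
#'
#' @param aln A `locus_aln`.
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param seed Integer seed.
#' @param ceiling Saturation ceiling passed to [jc_distance()].
#' @return The point-estimate `"phylo"` tree with `node.label` support.
#' @export
bootstrap_support <- function(aln, n_reps = 100L, seed = 1L, ceiling = 5) {
  stopifnot(n_reps >= 1L)
  point <- neighbor_joining(jc_distance(aln, ceiling))
  keys <- bipartitions(point)
  hits <- stats::setNames(numeric(length(keys)), keys)
  set.seed(seed)
  nc <- ncol(aln$mat)
  for (r in seq_len(n_reps)) {
    cols <- sample.int(nc, nc, replace = TRUE)
    rep_aln <- locus_alignment(aln$locus_id,
                               aln$mat[, cols, drop = FALSE], aln$alphabet)
    rep_tree <- tryCatch(neighbor_joining(jc_distance(rep_aln, ceiling)),
                         error = function(e) NULL)
    if (is.null(rep_tree)) next
    # zero-length internal branches are ties, not resolved signal
    bk <- bipartitions(ape::di2multi(rep_tree, tol = 1e-12))
    hit <- keys %in% bk
    hits[hit] <- hits[hit] + 1
  }
  support <- 100 * hits / n_reps
  # map supports onto internal nodes of the point tree
  ntip <- length(point$tip.label)
  labels <- rep(NA_character_, point$Nnode)
  post <- ape::reorder.phylo(point, "postorder")
  below <- vector("list", ntip + point$Nnode)
  tips <- point$tip.label
  for (i in seq_len(ntip)) below[[i]] <- tips[i]
  for (e in seq_len(nrow(post$edge))) {
    below[[post$edge[e, 1]]] <- c(below[[post$edge[e, 1]]],
                                  below[[post$edge[e, 2]]])
  }
  ref <- sort(tips)[1]
  for (nd in (ntip + 1L):(ntip + point$Nnode)) {
    side <- below[[nd]]
    k <- length(side)
    if (k < 2L || k > length(tips) - 2L) next
    if (ref %in% side) side <- setdiff(tips, side)
    key <- paste(sort(side), collapse = "|")
    if (key %in% names(support)) {
      labels[nd - ntip] <- format(support[[key]], trim = TRUE)
    }
  }
  point$node.label <- labels
  attr(point, "support_scale") <- "0-100"
  point
}

#' Pairwise Robinson-Foulds matrix over a set of trees
#'
#' Trees with unequal leaf sets are pruned to the common leaf set first
#' (with a message).
#'
#' @param trees Named list of `"phylo"` trees (>= 2).
#' @return List of class `"rf_matrix"`: `rf` (symmetric integer matrix),
#'   `tree_ids`.
#' @export
rf_matrix <- function(trees) {
  if (length(trees) < 2L) abort("need at least 2 trees")
  ids <- names(trees) %||% paste0("tree", seq_along(trees))
  common <- Reduce(intersect, purrr::map(trees, ~ .x$tip.label))
  if (length(common) < 4L) abort("fewer than 4 shared leaves across trees")
  pruned <- purrr::map(trees, function(tr) {
    if (length(tr$tip.label) > length(common)) {
      inform(sprintf("pruning tree to %d common leaves", length(common)))
      ape::keep.tip(tr, common)
    } else tr
  })
  biparts <- purrr::map(pruned, bipartitions)
  n <- length(trees)
  m <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      rf <- length(setdiff(biparts[[i]], biparts[[j]])) +
        length(setdiff(biparts[[j]], biparts[[i]]))
      m[i, j] <- m[j, i] <- as.integer(rf)
    }
  }
  structure(list(rf = m, tree_ids = ids), class = "rf_matrix")
}

#' Mean bootstrap support of a tree
#'
#' @param tree A `"phylo"` with numeric `node.label` supports.
#' @return Mean of the internal-node supports (NA labels ignored).
#' @export
avg_bootstrap <- function(tree) {
  if (is.null(tree$node.label)) return(NA_real_)
  mean(suppressWarnings(as.numeric(tree$node.label)), na.rm = TRUE)
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers the squared distance matrix, B = -1/2 J D^2 J, and embeds
#' on the top eigenvectors scaled by the square roots of their
#' (nonnegative-clamped) eigenvalues. Axes are ordered by eigenvalue; each
#' axis is sign-fixed so its first nonzero coordinate is positive.
#'
#' @param d Square symmetric distance matrix (an `rf_matrix` is accepted).
#' @param dims Number of output dimensions (default 2).
#' @return List of class `"mds_embedding"`: `coords` (tibble `id`, `axis1`,
#'   `axis2`, ...) and `eigenvalues`.
#' @export
classical_mds <- function(d, dims = 2L) {
  if (inherits(d, "rf_matrix")) d <- d$rf
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) abort("distance matrix must be symmetric")
  n <- nrow(d)
  stopifnot(dims >= 1L, n >= 2L)
  j <- diag(n) - matrix(1 / n, n, n)
  b <- -0.5 * j %*% (d^2) %*% j
  eg <- eigen((b + t(b)) / 2, symmetric = TRUE)
  k <- min(dims, n)
  vals <- pmax(eg$values[seq_len(k)], 0)
  coords <- eg$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(vals), k, k)
  # sign convention: first nonzero coordinate of each axis positive
  for (a in seq_len(k)) {
    nz <- which(abs(coords[, a]) > 1e-12)
    if (length(nz) && coords[nz[1], a] < 0) coords[, a] <- -coords[, a]
  }
  ids <- rownames(d) %||% paste0("item", seq_len(n))
  ct <- as_tibble(stats::setNames(as.data.frame(coords),
                                  paste0("axis", seq_len(k))))
  ct <- dplyr::bind_cols(tibble(id = ids), ct)
  structure(list(coords = ct, eigenvalues = eg$values),
            class = "mds_embedding")
}

#' Estimate gene trees with bootstrap for a set of loci
#'
#' @param loci List of `locus_aln`.
#' @param n_reps Bootstrap replicates per locus.
#' @param seed Global seed; per-locus seeds are derived from it.
#' @return Named list of `"phylo"` trees with `node.label` supports.
#' @export
gene_trees <- function(loci, n_reps = 100L, seed = 1L) {
  out <- purrr::imap(loci, function(aln, id) {
    bootstrap_support(aln, n_reps = n_reps,
                      seed = derive_seed(seed, paste0("gt_", id)))
  })
  out
}
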