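# Fitch parsimony step counts per column, vectorized over sites.
# State sets are bitmasks (A=1, C=2, G=4, T=8); gap/missing/N carry the full
# set and contribute no steps. Binary trees assumed (the package's own trees
# are); polytomies are resolved arbitrarily by sequential intersection.
fitch_steps <- function(aln, tree) {
  mat <- aln$mat[tree$tip.label, , drop = FALSE]
  code <- c(A = 1L, C = 2L, G = 4L, T = 8L)
  full <- 15L
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  n_sites <- ncol(mat)
  sets <- matrix(full, nrow = nnode, ncol = n_sites)
  for (i in seq_len(ntip)) {
    v <- code[mat[i, ]]
    v[is.na(v)] <- full
    sets[i, ] <- v
  }
  steps <- integer(n_sites)
  post <- ape::reorder.phylo(tree, "postorder")
  seen <- logical(nnode)
  for (e in seq_len(nrow(post$edge))) {
    par <- post$edge[e, 1]; chd <- post$edge[e, 2]
    if (!seen[par]) {
      sets[par, ] <- sets[chd, ]
      seen[par] <- TRUE
    } else {
      inter <- bitwAnd(sets[par, ], sets[chd, ])
      empty <- inter == 0L
      steps <- steps + as.integer(empty)
      inter[empty] <- bitwOr(sets[par, empty], sets[chd, empty])
      sets[par, ] <- inter
    }
  }
  steps
}

# relative root-to-tip depth spread of a tree
ultrametric_spread <- function(tree) {
  depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  if (max(depths) == 0) return(0)
  (max(depths) - min(depths)) / max(depths)
}

#' Estimate per-site substitution rates on a reference time-tree
#'
#' Each site's rate is its Fitch parsimony step count on the ultrametric
#' reference tree divided by the total tree length — a deterministic
#' minimum-change rate estimate in expected substitutions per unit time of
#' the reference tree. Rates for a whole dataset are usually rescaled to
#' mean 1 with [normalize_site_rates()].
#'
#' @param aln A `locus_aln` (nucleotide).
#' @param ref_tree Ultrametric `"phylo"`; its leaves must be a subset of the
#'   alignment's taxa.
#' @return List of class `"site_rates"`: `locus_id`, `lambda` (per site),
#'   `normalized` (flag, `FALSE` here).
#' @export
estimate_site_rates <- function(aln, ref_tree) {
  if (ultrametric_spread(ref_tree) > 1e-6) {
    abort("reference tree is not ultrametric (root-to-tip spread > 1e-6)")
  }
  missing_taxa <- setdiff(ref_tree$tip.label, rownames(aln$mat))
  if (length(missing_taxa)) {
    abort(sprintf("tree leaves not in alignment: %s",
                  paste(missing_taxa, collapse = ",")))
  }
  steps <- fitch_steps(aln, ref_tree)
  tl <- sum(ref_tree$edge.length)
  structure(list(locus_id = aln$locus_id, lambda = steps / tl,
                 normalized = FALSE),
            class = "site_rates")
}

#' Rescale a set of per-locus site rates to dataset mean 1
#'
#' @param rates List of `"site_rates"`.
#' @return The same list with `lambda` jointly rescaled (mean over all sites
#'   of the dataset = 1) and `normalized = TRUE`. If every rate is zero the
#'   rates are returned unchanged with a warning.
#' @export
normalize_site_rates <- function(rates) {
  all_lambda <- unlist(purrr::map(rates, "lambda"))
  m <- mean(all_lambda)
  if (m == 0) {
    warn("all site rates are zero; normalization skipped")
    return(rates)
  }
  purrr::map(rates, function(r) {
    r$lambda <- r$lambda / m
    r$normalized <- TRUE
    r
  })
}

#' Per-site phylogenetic informativeness
#'
#' The four-state symmetric-model informativeness profile
#' phi(t; lambda) = 16 lambda^2 t exp(-4 lambda t): for a site of rate
#' lambda, its expected power to resolve a node of age t. Maximized over t
#' at 1/(4 lambda), and over lambda at 1/(2 t).
#'
#' @param t Node age(s), same units as the reference tree.
#' @param lambda Site rate(s) (substitutions per unit time).
#' @return phi, vectorized over `t` and `lambda`.
#' @export
phi_informativeness <- function(t, lambda) {
  16 * lambda^2 * t * exp(-4 * lambda * t)
}

#' Phylogenetic-informativeness profiles over time
#'
#' Per-locus PI(t) is the sum of per-site phi over the locus's sites; the
#' dataset total is the sum over loci; the "per locus" view is the mean
#' over loci at each time point.
#'
#' @param rates List of `"site_rates"` (typically normalized).
#' @param times Time grid (>= 0). Default: 100 points from 0 to
#'   `1.5 * root_depth` when a reference depth is given, else 0 to 1.5.
#' @param root_depth Optional root age of the reference tree, used only for
#'   the default grid.
#' @return List of class `"pi_profile"`: `profile` (tibble: `locus_id`, `t`,
#'   `pi`), `total` (tibble: `t`, `pi_total`, `pi_mean_locus`), `times`.
#' @export
pi_profile <- function(rates, times = NULL, root_depth = NULL) {
  if (is.null(times)) {
    hi <- 1.5 * (root_depth %||% 1)
    times <- seq(0, hi, length.out = 100L)
  }
  stopifnot(all(times >= 0))
  per_locus <- purrr::map(rates, function(r) {
    pi_t <- vapply(times, function(t) sum(phi_informativeness(t, r$lambda)),
                   numeric(1))
    tibble(locus_id = r$locus_id, t = times, pi = pi_t)
  })
  profile <- dplyr::bind_rows(per_locus)
  total <- profile |>
    dplyr::group_by(.data$t) |>
    dplyr::summarise(pi_total = sum(.data$pi),
                     pi_mean_locus = mean(.data$pi), .groups = "drop")
  structure(list(profile = profile, total = total, times = times),
            class = "pi_profile")
}

#' @export
print.pi_profile <- function(x, ...) {
  cat(sprintf("<pi_profile> %d loci x %d time points; peak total PI %.3g at t = %.3g\n",
              length(unique(x$profile$locus_id)), length(x$times),
              max(x$total$pi_total), x$total$t[which.max(x$total$pi_total)]))
  invisible(x)
}
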