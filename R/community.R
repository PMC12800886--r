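# Community-level statistics: rarefaction, alpha diversity, Bray-Curtis
# dissimilarity, and a permutation-based PERMANOVA.

#' Rarefy a count table to a fixed depth
#'
#' Subsamples every sample without replacement to exactly `depth` reads
#' (samples already at `depth` are returned unchanged as a multiset).
#' Samples below the target depth are dropped with a warning.
#'
#' @param counts samples x ASVs integer matrix.
#' @param depth target reads per sample (default 6215, the fixed sampling
#'   effort used in the motivating study).
#' @param seed RNG seed.
#' @return rarefied integer matrix whose row sums all equal `depth`.
#' @export
rarefy_counts <- function(counts, depth = 6215, seed = 1) {
  counts <- as_weight_matrix(counts)
  check_nonnegative_matrix(counts, "count table")
  if (depth < 1) stopf("depth must be >= 1")
  keep <- rowSums(counts) >= depth
  if (!any(keep)) stopf("all samples are below depth %d", depth)
  if (!all(keep))
    warnf("dropping %d sample(s) below depth %d: %s", sum(!keep), depth,
          paste(rownames(counts)[!keep], collapse = ", "))
  sub <- counts[keep, , drop = FALSE]
  # vegan warns heuristically when a table contains no small counts;
  # depth handling is already validated here, so muffle that one message
  out <- with_seed(seed, withCallingHandlers(
    vegan::rrarefy(sub, depth),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }))
  storage.mode(out) <- "integer"
  out
}

#' Per-sample ASV richness
#' @param counts samples x ASVs matrix.
#' @return integer vector: number of ASVs with count > 0 per sample.
#' @export
richness <- function(counts) {
  counts <- as_weight_matrix(counts)
  check_nonnegative_matrix(counts, "count table")
  rowSums(counts > 0)
}

#' Per-sample Shannon diversity (natural log)
#'
#' `H = -sum p ln p` over each sample's proportions. All-zero samples have
#' no defined proportions and are reported as `NA`.
#'
#' @param counts samples x ASVs matrix.
#' @return numeric vector of Shannon indices.
#' @export
shannon_diversity <- function(counts) {
  counts <- as_weight_matrix(counts)
  check_nonnegative_matrix(counts, "count table")
  h <- vegan::diversity(counts, index = "shannon", base = exp(1))
  h[rowSums(counts) == 0] <- NA_real_
  h
}

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(x, y) = sum |x - y| / sum (x + y)`, in [0, 1]; 0 for identical
#' samples and 1 for disjoint supports. Pairs of all-zero samples have an
#' undefined dissimilarity, reported as `NA`.
#'
#' @param counts samples x ASVs matrix with at least 2 samples.
#' @return symmetric matrix with zero diagonal and sample ids as dimnames.
#' @export
bray_curtis <- function(counts) {
  counts <- as_weight_matrix(counts)
  check_nonnegative_matrix(counts, "count table")
  if (nrow(counts) < 2) stopf("need at least 2 samples")
  zero <- rowSums(counts) == 0
  d <- as.matrix(suppressWarnings(vegan::vegdist(counts, method = "bray")))
  if (any(zero)) {
    d[zero, zero] <- NA_real_
    warnf("all-zero sample(s) produce undefined dissimilarities: %s",
          paste(rownames(counts)[zero], collapse = ", "))
  }
  diag(d) <- 0
  d
}

#' One-way PERMANOVA on a distance matrix
#'
#' Partitions the total sum of squared dissimilarities into among- and
#' within-group components (Anderson's distance-based formulation):
#' `SS_total = sum_{i<j} d_ij^2 / n`, `SS_within = sum_g sum_{i<j in g}
#' d_ij^2 / n_g`, and the pseudo-F statistic
#' `F = (SS_among / (a - 1)) / (SS_within / (n - a))`. Significance comes
#' from seeded random permutations of the group labels, with
#' `p = (1 + #[F_perm >= F_obs]) / (n_permutations + 1)`.
#'
#' @param d distance matrix (`dist` or symmetric matrix).
#' @param groups group labels, one per sample (at least 2 groups with at
#'   least 2 samples each).
#' @param n_permutations number of label permutations (default 9999).
#' @param seed RNG seed for the permutations.
#' @return list of class `permanova` with `pseudo_F`, `R2`, `p_value`,
#'   `df`, `n_permutations`, `seed`, `group_sizes` and the sums of
#'   squares.
#' @export
permanova <- function(d, groups, n_permutations = 9999, seed = 1) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (length(groups) != n)
    stopf("groups length (%d) does not match distance matrix (%d samples)",
          length(groups), n)
  groups <- factor(groups)
  sizes <- table(groups)
  if (length(sizes) < 2) stopf("need at least 2 groups")
  if (any(sizes < 2))
    stopf("group(s) of size 1: %s", paste(names(sizes)[sizes < 2],
                                          collapse = ", "))
  d2 <- d^2
  a <- length(sizes)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- function(g) {
    s <- 0
    for (lev in levels(g)) {
      idx <- which(g == lev)
      s <- s + sum(d2[idx, idx][upper.tri(diag(length(idx)))]) / length(idx)
    }
    s
  }
  ssw <- ss_within(groups)
  ssa <- ss_total - ssw
  f_obs <- (ssa / (a - 1)) / (ssw / (n - a))
  perm_f <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(k) {
      gp <- groups[sample.int(n)]
      sw <- ss_within(gp)
      ((ss_total - sw) / (a - 1)) / (sw / (n - a))
    }, numeric(1))
  })
  p <- (1 + sum(perm_f >= f_obs)) / (n_permutations + 1)
  structure(list(pseudo_F = f_obs, R2 = ssa / ss_total, p_value = p,
                 df = c(among = a - 1, within = n - a),
                 n_permutations = n_permutations, seed = seed,
                 group_sizes = as.vector(sizes),
                 SS = c(among = ssa, within = ssw, total = ss_total)),
            class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4f (df %d, %d), R2 = %.4f, p = %.4g (%d permutations)\n",
              x$pseudo_F, x$df[1], x$df[2], x$R2, x$p_value,
              x$n_permutations))
  invisible(x)
}

#' Pairwise PERMANOVA post hoc comparisons
#'
#' Runs [permanova()] on every pair of groups and adjusts p-values with
#' the Benjamini-Hochberg false discovery rate.
#'
#' @inheritParams permanova
#' @return data.frame with one row per group pair: `group1`, `group2`,
#'   `pseudo_F`, `R2`, `p_value`, `p_adjusted`.
#' @export
pairwise_permanova <- function(d, groups, n_permutations = 999, seed = 1) {
  d <- as.matrix(d)
  groups <- factor(groups)
  levs <- levels(groups)
  pairs <- utils::combn(levs, 2)
  res <- apply(pairs, 2, function(pr) {
    idx <- which(groups %in% pr)
    fit <- permanova(d[idx, idx], droplevels(groups[idx]),
                     n_permutations = n_permutations,
                     seed = derive_seed(seed, match(pr[1], levs),
                                        match(pr[2], levs)))
    c(fit$pseudo_F, fit$R2, fit$p_value)
  })
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    pseudo_F = res[1, ], R2 = res[2, ], p_value = res[3, ])
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out
}
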