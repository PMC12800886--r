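# Bluethgen-family specialization indices on weighted bipartite networks.

# Largest-remainder rounding of w * K / sum(w) to integers totalling K.
integerize_weights <- function(w, K = 1000) {
  v <- as.vector(w) * K / sum(w)
  fl <- floor(v)
  rem <- K - sum(fl)
  if (rem > 0) {
    extra <- order(v - fl, decreasing = TRUE)[seq_len(rem)]
    fl[extra] <- fl[extra] + 1
  }
  matrix(as.integer(fl), nrow(w), ncol(w), dimnames = dimnames(w))
}

entropy_nat <- function(x) {
  p <- x[x > 0] / sum(x)
  -sum(p * log(p))
}

# Best-improvement search over 2x2 transfer moves that preserve both
# marginals: add s to cells (i1,j1),(i2,j2) and remove s from
# (i1,j2),(i2,j1). `direction` +1 maximizes entropy, -1 minimizes.
# sum(v log v) is convex in s, so the entropy gain is concave when
# maximizing (optimal integer step by ternary search) and is maximized at
# an endpoint when minimizing.
refine_extreme <- function(x, direction, max_sweeps = 50) {
  nr <- nrow(x); nc <- ncol(x)
  if (nr < 2 || nc < 2) return(x)
  ent_term <- function(v) if (v > 0) v * log(v) else 0
  move_val <- function(a, b, cc, d, s)
    ent_term(a + s) + ent_term(b - s) + ent_term(cc - s) + ent_term(d + s)
  sweep_count <- 0
  repeat {
    improved <- FALSE
    for (i1 in seq_len(nr - 1)) for (i2 in (i1 + 1):nr)
      for (j1 in seq_len(nc - 1)) for (j2 in (j1 + 1):nc) {
        a <- x[i1, j1]; b <- x[i1, j2]; cc <- x[i2, j1]; d <- x[i2, j2]
        smax_pos <- min(b, cc)   # +s moves mass onto the (a, d) diagonal
        smax_neg <- min(a, d)
        if (smax_pos == 0 && smax_neg == 0) next
        base <- move_val(a, b, cc, d, 0)
        gain_at <- function(s) direction * (base - move_val(a, b, cc, d, s))
        if (direction < 0) {
          cand <- c(-smax_neg, smax_pos)
          cand <- cand[cand != 0]
          gains <- vapply(cand, gain_at, numeric(1))
          best_s <- cand[which.max(gains)]
          best_gain <- max(gains)
        } else {
          lo <- -smax_neg; hi <- smax_pos
          while (hi - lo > 2L) {
            m1 <- lo + (hi - lo) %/% 3L
            m2 <- hi - (hi - lo) %/% 3L
            if (gain_at(m1) < gain_at(m2)) lo <- m1 else hi <- m2
          }
          cand <- setdiff(seq.int(lo, hi), 0L)
          gains <- vapply(cand, gain_at, numeric(1))
          best_s <- cand[which.max(gains)]
          best_gain <- max(gains)
        }
        if (best_gain > 1e-12) {
          x[i1, j1] <- a + best_s; x[i1, j2] <- b - best_s
          x[i2, j1] <- cc - best_s; x[i2, j2] <- d + best_s
          improved <- TRUE
        }
      }
    sweep_count <- sweep_count + 1
    if (!improved || sweep_count >= max_sweeps) break
  }
  x
}

# feasible table with given integer marginals, close to independence
start_proportional <- function(r, cc) {
  nr <- length(r); nc <- length(cc)
  x <- matrix(0L, nr, nc)
  r_rem <- r; c_rem <- cc
  target <- outer(r, cc) / sum(r)
  ord <- order(as.vector(target), decreasing = TRUE)
  for (k in ord) {
    i <- (k - 1) %% nr + 1; j <- (k - 1) %/% nr + 1
    x[i, j] <- min(r_rem[i], c_rem[j], ceiling(target[i, j]))
    r_rem[i] <- r_rem[i] - x[i, j]; c_rem[j] <- c_rem[j] - x[i, j]
  }
  # distribute any remainder greedily
  while (sum(r_rem) > 0) {
    i <- which.max(r_rem); j <- which.max(c_rem)
    s <- min(r_rem[i], c_rem[j])
    x[i, j] <- x[i, j] + s
    r_rem[i] <- r_rem[i] - s; c_rem[j] <- c_rem[j] - s
  }
  x
}

# feasible table packing mass into as few, large cells as possible
start_packed <- function(r, cc) {
  nr <- length(r); nc <- length(cc)
  x <- matrix(0L, nr, nc)
  r_rem <- r; c_rem <- cc
  while (sum(r_rem) > 0) {
    i <- which.max(r_rem); j <- which.max(c_rem)
    s <- min(r_rem[i], c_rem[j])
    x[i, j] <- x[i, j] + s
    r_rem[i] <- r_rem[i] - s; c_rem[j] <- c_rem[j] - s
  }
  x
}

# feasible table built by visiting rows/columns in a given priority order
start_ordered <- function(r, cc, row_ord, col_ord) {
  x <- matrix(0L, length(r), length(cc))
  r_rem <- r; c_rem <- cc
  for (i in row_ord) for (j in col_ord) {
    s <- min(r_rem[i], c_rem[j])
    if (s > 0) {
      x[i, j] <- x[i, j] + s
      r_rem[i] <- r_rem[i] - s; c_rem[j] <- c_rem[j] - s
    }
  }
  x
}

# minimal-entropy table: the packing greedy can hit local minima, so the
# search is multi-start (greedy + deterministic marginal orders + seeded
# random orders), each start refined by 2x2 transfer moves.
min_entropy_table <- function(r, cc, n_random = 20) {
  starts <- list(start_packed(r, cc),
                 start_ordered(r, cc, order(-r), order(-cc)),
                 start_ordered(r, cc, order(r), order(cc)),
                 start_ordered(r, cc, order(-r), order(cc)))
  starts <- c(starts, with_seed(derive_seed(sum(r), length(r), length(cc)), {
    lapply(seq_len(n_random), function(k)
      start_ordered(r, cc, sample(length(r)), sample(length(cc))))
  }))
  best <- NULL; best_e <- Inf
  for (x in starts) {
    x <- refine_extreme(x, direction = -1)
    e <- entropy_nat(x)
    if (e < best_e) { best_e <- e; best <- x }
  }
  best
}

#' Network-level specialization H2'
#'
#' The two-dimensional Shannon entropy of the interaction matrix,
#' `H2 = -sum p_ij ln p_ij`, standardized between the extremal entropies
#' attainable with the same marginal totals:
#' `H2' = (H2_max - H2) / (H2_max - H2_min)`, so 0 means maximal
#' generalization (interactions follow partner availability) and 1 maximal
#' specialization. The published construction assumes integer interaction
#' frequencies, so continuous weights (e.g. `|DI|`) are first scaled to a
#' total of `K` by largest-remainder rounding; observed and extremal
#' entropies are all computed from the integerized matrix, which
#' guarantees `H2_min <= H2 <= H2_max`. Extremal tables are found by
#' greedy construction (proportional fill for the maximum, packing for
#' the minimum) refined by exhaustive 2x2 transfer moves.
#'
#' @param w non-negative matrix with positive total.
#' @param K integerization total (default 1000).
#' @return list of class `specialization_report` with `H2`, `H2_min`,
#'   `H2_max`, `H2_prime` (NA when the extremes coincide, e.g. a
#'   single-cell matrix), plus `K` and the integerized marginals.
#' @export
h2_prime <- function(w, K = 1000) {
  w <- as_weight_matrix(w)
  check_nonnegative_matrix(w)
  if (sum(w) <= 0) stopf("matrix total must be positive")
  wi <- integerize_weights(w, K)
  r <- rowSums(wi); cc <- colSums(wi)
  h2 <- entropy_nat(wi)
  xmax <- refine_extreme(start_proportional(r, cc), direction = +1)
  xmin <- min_entropy_table(r, cc)
  h2max <- entropy_nat(xmax)
  h2min <- entropy_nat(xmin)
  # heuristic safety: extremes must bracket the observed value
  h2max <- max(h2max, h2)
  h2min <- min(h2min, h2)
  h2p <- if (h2max - h2min < 1e-12) NA_real_
         else (h2max - h2) / (h2max - h2min)
  structure(list(H2 = h2, H2_min = h2min, H2_max = h2max, H2_prime = h2p,
                 K = K, row_totals = r, col_totals = cc),
            class = "specialization_report")
}

#' @export
print.specialization_report <- function(x, ...) {
  cat(sprintf("H2 = %.4f in [%.4f, %.4f]; H2' = %s\n", x$H2, x$H2_min,
              x$H2_max,
              ifelse(is.na(x$H2_prime), "NA", sprintf("%.4f", x$H2_prime))))
  invisible(x)
}

#' Species-level specialization d and d'
#'
#' For each species (row by default), `d` is the Kullback-Leibler
#' divergence of its interaction distribution from overall partner
#' availability: `d_i = sum_j p'_ij ln(p'_ij / q_j)` with
#' `p'_ij = w_ij / A_i` and `q_j = C_j / W`. It is standardized to
#' `d' = (d - d_min) / (d_max - d_min)` in [0, 1], where
#' `d_max = ln(W / A_i)` (all weight monopolizing one partner) and
#' `d_min` is the divergence of the closest-to-proportional integer
#' allocation of the species' interactions at the integerization scale
#' `K` (0 exactly when a proportional allocation is attainable).
#'
#' @param w non-negative matrix with positive total.
#' @param margin `"rows"` (default) or `"columns"`.
#' @param K integerization total used for the `d_min` allocation.
#' @return data.frame with `species`, `d`, `d_min`, `d_max`, `d_prime`
#'   (`NA` for species with no interactions).
#' @export
d_prime <- function(w, margin = c("rows", "columns"), K = 1000) {
  margin <- match.arg(margin)
  w <- as_weight_matrix(w)
  check_nonnegative_matrix(w)
  if (sum(w) <= 0) stopf("matrix total must be positive")
  if (margin == "columns") w <- t(w)
  W <- sum(w)
  A <- rowSums(w)
  q <- colSums(w) / W
  out <- data.frame(species = rownames(w) %||% seq_len(nrow(w)),
                    d = NA_real_, d_min = NA_real_, d_max = NA_real_,
                    d_prime = NA_real_)
  for (i in seq_len(nrow(w))) {
    if (A[i] == 0) next
    p <- w[i, ] / A[i]
    keep <- p > 0
    out$d[i] <- sum(p[keep] * log(p[keep] / q[keep]))
    out$d_max[i] <- log(W / A[i])
    # closest-to-proportional integer allocation of this species' weight
    n_units <- max(1L, round(A[i] * K / W))
    alloc <- integerize_weights(matrix(q, nrow = 1), n_units)[1, ]
    pa <- alloc[alloc > 0] / n_units
    out$d_min[i] <- sum(pa * log(pa / q[alloc > 0]))
    denom <- out$d_max[i] - out$d_min[i]
    out$d_prime[i] <- if (denom < 1e-12) 0
                      else min(1, max(0, (out$d[i] - out$d_min[i]) / denom))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
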