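# Nestedness metrics for bipartite interaction matrices, implemented from
# their primary definitions. Exact formula conventions and tie rules are
# frozen in inst/metrics-reference.md.

coerce_binary <- function(m) {
  w <- as_weight_matrix(m)
  check_nonnegative_matrix(w)
  (w > 0) + 0
}

#' Nestedness by overlap and decreasing fill (NODF)
#'
#' For every ordered row pair (i above j) the paired term is the
#' percentage of the lower row's presences shared with the upper row,
#' counted only when the upper row's fill is strictly larger (otherwise
#' the pair contributes 0); column pairs are treated symmetrically. NODF
#' is the mean paired term over all row pairs and column pairs, in
#' [0, 100].
#'
#' @param m 0/1 matrix (positive weights are binarized), at least 2 x 2
#'   with nonzero fill.
#' @param variant `"as_is"` evaluates the matrix in the given row/column
#'   order; `"sorted"` (the NODF2 convention) first sorts rows and columns
#'   by decreasing fill, ties kept in original order.
#' @return NODF value in [0, 100].
#' @export
nodf <- function(m, variant = c("as_is", "sorted")) {
  variant <- match.arg(variant)
  m <- coerce_binary(m)
  check_nondegenerate(m, "NODF input")
  if (variant == "sorted")
    m <- m[order_desc(rowSums(m)), order_desc(colSums(m)), drop = FALSE]
  nodf_sum <- function(x) {
    f <- rowSums(x)
    ov <- x %*% t(x)
    s <- 0
    for (i in seq_len(nrow(x) - 1)) for (j in (i + 1):nrow(x))
      if (f[i] > f[j] && f[j] > 0) s <- s + 100 * ov[i, j] / f[j]
    s
  }
  npairs <- nrow(m) * (nrow(m) - 1) / 2 + ncol(m) * (ncol(m) - 1) / 2
  (nodf_sum(m) + nodf_sum(t(m))) / npairs
}

#' Weighted NODF
#'
#' Weighted extension of [nodf()]: an ordered pair (i above j) contributes
#' only when i's fill is strictly larger than j's; the term is then the
#' percentage of j's filled cells whose weight is strictly smaller than
#' i's weight in the same column. Matrices whose overlapping cells carry
#' equal weights therefore score 0 on the weighted terms.
#'
#' @param w non-negative weight matrix.
#' @param variant as in [nodf()]; `"sorted"` orders by decreasing fill
#'   with marginal totals breaking fill ties.
#' @return value in [0, 100].
#' @export
weighted_nodf <- function(w, variant = c("as_is", "sorted")) {
  variant <- match.arg(variant)
  w <- as_weight_matrix(w)
  check_nonnegative_matrix(w)
  check_nondegenerate(w, "weighted NODF input")
  if (variant == "sorted") {
    b <- w > 0
    w <- w[order(-rowSums(b), -rowSums(w), seq_len(nrow(w))),
           order(-colSums(b), -colSums(w), seq_len(ncol(w))), drop = FALSE]
  }
  wnodf_sum <- function(x) {
    f <- rowSums(x > 0)
    s <- 0
    for (i in seq_len(nrow(x) - 1)) for (j in (i + 1):nrow(x)) {
      if (f[i] <= f[j] || f[j] == 0) next
      s <- s + 100 * sum(x[j, ] > 0 & x[j, ] < x[i, ]) / f[j]
    }
    s
  }
  npairs <- nrow(w) * (nrow(w) - 1) / 2 + ncol(w) * (ncol(w) - 1) / 2
  (wnodf_sum(w) + wnodf_sum(t(w))) / npairs
}

#' Weighted nestedness by overlap and decreasing abundance (WNODA)
#'
#' Like weighted NODF but the pair condition is decreasing marginal
#' *totals* (abundance) rather than decreasing fill, and no prior
#' fill-sorting is assumed: for an unordered pair let i be the line with
#' the strictly larger marginal total (ties contribute 0); the term is the
#' percentage of j's filled cells whose weight is strictly smaller than
#' i's weight in the same position. The value is the mean over all row
#' pairs and column pairs, in [0, 100].
#'
#' @param w non-negative weight matrix.
#' @return value in [0, 100].
#' @export
wnoda <- function(w) {
  w <- as_weight_matrix(w)
  check_nonnegative_matrix(w)
  check_nondegenerate(w, "WNODA input")
  wnoda_sum <- function(x) {
    tot <- rowSums(x)
    s <- 0
    for (a in seq_len(nrow(x) - 1)) for (b in (a + 1):nrow(x)) {
      if (tot[a] == tot[b]) next
      i <- if (tot[a] > tot[b]) a else b
      j <- if (tot[a] > tot[b]) b else a
      fj <- sum(x[j, ] > 0)
      if (fj == 0) next
      s <- s + 100 * sum(x[j, ] > 0 & x[j, ] < x[i, ]) / fj
    }
    s
  }
  npairs <- nrow(w) * (nrow(w) - 1) / 2 + ncol(w) * (ncol(w) - 1) / 2
  (wnoda_sum(w) + wnoda_sum(t(w))) / npairs
}

#' Weighted-interaction nestedness estimator (WINE)
#'
#' Measures how tightly interaction weight packs into the corner of the
#' matrix. Rows and columns are sorted by decreasing marginal totals (ties
#' by original index); each filled cell at sorted position (i, j) gets the
#' Euclidean distance `d_ij = sqrt((i-1)^2 + (j-1)^2)` to the packed
#' corner, and the raw statistic is the weighted mean distance
#' `d_w = sum(w_ij d_ij) / sum(w_ij)`. Two calibration points normalize
#' it: `d_packed`, the minimum achievable `d_w` for the same weights
#' (largest weights on the closest cells), and `d_random`, the expectation
#' under uniform random placement (the unweighted mean distance over all
#' cells). The normalized estimator is
#' `eta = (d_random - d_w) / (d_random - d_packed)`: 0 for random-like,
#' 1 for maximally packed matrices; it is `NA` when the calibration
#' points coincide.
#'
#' @param w non-negative matrix with at least one positive entry.
#' @return list of class `wine_stat` with `statistic` (raw `d_w`),
#'   `d_packed`, `d_random` and `eta`.
#' @export
wine <- function(w) {
  w <- as_weight_matrix(w)
  check_nonnegative_matrix(w)
  check_nondegenerate(w, "WINE input")
  w <- w[order_desc(rowSums(w)), order_desc(colSums(w)), drop = FALSE]
  nr <- nrow(w); nc <- ncol(w)
  dmat <- sqrt(outer((seq_len(nr) - 1)^2, (seq_len(nc) - 1)^2, "+"))
  pos <- w > 0
  wt <- w[pos]
  dw <- sum(wt * dmat[pos]) / sum(wt)
  d_sorted <- sort(dmat)[seq_len(sum(pos))]
  d_packed <- sum(sort(wt, decreasing = TRUE) * d_sorted) / sum(wt)
  d_random <- mean(dmat)
  eta <- if (abs(d_random - d_packed) < 1e-12) NA_real_
         else (d_random - dw) / (d_random - d_packed)
  structure(list(statistic = dw, d_packed = d_packed, d_random = d_random,
                 eta = eta), class = "wine_stat")
}

#' @export
print.wine_stat <- function(x, ...) {
  cat(sprintf("WINE: d_w = %.4f (packed %.4f, random %.4f), eta = %s\n",
              x$statistic, x$d_packed, x$d_random,
              ifelse(is.na(x$eta), "NA", sprintf("%.4f", x$eta))))
  invisible(x)
}

# --- matrix temperature ----------------------------------------------------

# isocline of perfect nestedness: row coordinate y and column coordinate x
# on the unit square, boundary f(x) = 1 - (1 - (1-x)^p)^(1/p) with p chosen
# so the area under f equals the matrix fill.
temp_isocline_p <- function(fill) {
  f <- function(x, p) 1 - (1 - (1 - x)^p)^(1 / p)
  gap <- function(p) stats::integrate(f, 0, 1, p = p)$value - fill
  stats::uniroot(gap, c(0.05, 20), extendInt = "yes", tol = 1e-9)$root
}

# per-position unexpectedness contributions for presences/absences:
# distance from the cell to the isocline along the 45-degree diagonal
# through the cell, normalized by the diagonal's projected length.
temp_u_matrices <- function(nr, nc, fill) {
  p <- temp_isocline_p(fill)
  f <- function(x) 1 - (1 - (1 - x)^p)^(1 / p)
  r <- (seq_len(nr) - 0.5) / nr
  cc <- (seq_len(nc) - 0.5) / nc
  cross <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    a <- cc[j] - r[i]
    # point on the diagonal col = row + a where it meets the isocline
    cross[i, j] <- stats::uniroot(function(x) f(x) - a - x, c(0, 1),
                                  tol = 1e-9)$root
  }
  u <- (matrix(r, nr, nc) - cross) / (1 - abs(outer(r, cc, "-")))
  list(pres = pmax(u, 0)^2, abs = pmin(u, 0)^2)
}

#' Matrix temperature (packed-matrix disorder)
#'
#' The temperature of a presence-absence matrix measures its departure
#' from perfect nestedness after rows and columns have been reordered to
#' pack presences into one corner: 0 for a perfectly nested matrix, 100
#' for maximal disorder. Cell positions are mapped to the unit square, an
#' isocline of perfect nestedness matching the matrix fill separates the
#' expected presence and absence regions, and each unexpected presence or
#' absence contributes its squared normalized diagonal distance to the
#' isocline. Packing is found with a seeded simulated-annealing search
#' over row and column permutations, warm-started from a decreasing-fill
#' sort, so repeated calls with the same seed are identical.
#'
#' @param m 0/1 matrix (positive entries binarized), non-degenerate.
#' @param budget number of annealing proposals (default 50000).
#' @param seed RNG seed for the optimizer (default 1).
#' @return temperature in [0, 100], with attribute `p` (isocline shape
#'   parameter) and `fill`.
#' @export
matrix_temperature <- function(m, budget = 50000, seed = 1) {
  m <- coerce_binary(m)
  check_nondegenerate(m, "temperature input")
  nr <- nrow(m); nc <- ncol(m)
  fill <- sum(m) / (nr * nc)
  if (fill >= 1) return(structure(0, p = NA_real_, fill = fill))
  um <- temp_u_matrices(nr, nc, fill)
  energy <- function(rp, cp) {
    mp <- m[rp, cp, drop = FALSE]
    sum(um$pres * mp) + sum(um$abs * (1 - mp))
  }
  rp <- order_desc(rowSums(m)); cp <- order_desc(colSums(m))
  e <- energy(rp, cp)
  best <- e; best_rp <- rp; best_cp <- cp
  if (budget > 0 && (nr > 1 || nc > 1)) with_seed(seed, {
    t0 <- max(e, 1e-4) * 0.2
    cool <- (1e-4)^(1 / budget)
    temp <- t0
    for (k in seq_len(budget)) {
      if (stats::runif(1) < 0.5 && nr > 1) {
        sw <- sample.int(nr, 2)
        rp2 <- rp; rp2[sw] <- rp[rev(sw)]
        cp2 <- cp
      } else {
        sw <- sample.int(nc, 2)
        cp2 <- cp; cp2[sw] <- cp[rev(sw)]
        rp2 <- rp
      }
      e2 <- energy(rp2, cp2)
      if (e2 <= e || stats::runif(1) < exp((e - e2) / temp)) {
        rp <- rp2; cp <- cp2; e <- e2
        if (e < best) { best <- e; best_rp <- rp; best_cp <- cp }
      }
      temp <- temp * cool
    }
  })
  structure(100 * best / (nr * nc) / 0.04145,
            p = temp_isocline_p(fill), fill = fill)
}

#' Discrepancy from perfect nestedness
#'
#' The number of presences that must be relocated for the matrix to become
#' perfectly nested with the same row fills: with columns in a fixed
#' packing order, each row of fill `k` should occupy the first `k` columns
#' of that order, and every presence outside that block counts one
#' discrepancy.
#'
#' @param m 0/1 matrix (positive entries binarized).
#' @param variant `"fill_sorted"` (default; columns ordered by decreasing
#'   totals, ties by original index — the usual packed-matrix convention)
#'   or `"fixed_order"` (columns taken in the order given).
#' @return non-negative integer, at most the number of presences.
#' @export
discrepancy <- function(m, variant = c("fill_sorted", "fixed_order")) {
  variant <- match.arg(variant)
  m <- coerce_binary(m)
  if (variant == "fill_sorted")
    m <- m[, order_desc(colSums(m)), drop = FALSE]
  k <- rowSums(m)
  d <- 0L
  for (i in seq_len(nrow(m)))
    if (k[i] > 0) d <- d + as.integer(k[i] - sum(m[i, seq_len(k[i])]))
  d
}

#' Compute the full nestedness and specialization report for one network
#'
#' Runs every metric the package implements on a bipartite network (or
#' weight matrix) and records provenance: which metrics consumed the
#' binarized matrix, the temperature optimizer budget and seed, matrix
#' dimensions and fill. Rows or columns that are entirely zero are dropped
#' before metric evaluation (and the drop is recorded), since the metrics
#' are defined on interacting species.
#'
#' @param network `bipartite_network` or non-negative weight matrix.
#' @param budget annealing proposals for [matrix_temperature()].
#' @param seed seed for the temperature optimizer.
#' @param K integerization total for [h2_prime()].
#' @return named list of class `metric_report`.
#' @export
metric_report <- function(network, budget = 50000, seed = 1, K = 1000) {
  w <- as_weight_matrix(network)
  check_nonnegative_matrix(w)
  keep_r <- rowSums(w) > 0
  keep_c <- colSums(w) > 0
  w2 <- w[keep_r, keep_c, drop = FALSE]
  meta <- list(
    mode = if (inherits(network, "bipartite_network")) network$mode else NA,
    sign = if (inherits(network, "bipartite_network")) network$sign else NA,
    n_rows = nrow(w2), n_cols = ncol(w2), n_edges = sum(w2 > 0),
    fill = if (length(w2) > 0) sum(w2 > 0) / length(w2) else NA_real_,
    dropped_rows = sum(!keep_r), dropped_cols = sum(!keep_c),
    binary_metrics = c("nodf", "nodf2", "temperature", "discrepancy",
                       "discrepancy2"),
    weighted_metrics = c("weighted_nodf", "wnoda", "wine", "h2_prime"),
    sorting = "decreasing marginal totals, ties by original index",
    optimizer = list(budget = budget, seed = seed), K = K)
  if (nrow(w2) < 2 || ncol(w2) < 2 || all(w2 == 0)) {
    warnf("network too small for metrics (%d x %d after dropping empty lines)",
          nrow(w2), ncol(w2))
    return(structure(list(metrics = NULL, provenance = meta),
                     class = "metric_report"))
  }
  b <- binarize(w2)
  wn <- wine(w2)
  h2 <- h2_prime(w2, K = K)
  metrics <- list(
    nodf = nodf(b, "as_is"),
    nodf2 = nodf(b, "sorted"),
    weighted_nodf = weighted_nodf(w2, "sorted"),
    wnoda = wnoda(w2),
    wine_dw = wn$statistic,
    wine_eta = wn$eta,
    temperature = as.numeric(matrix_temperature(b, budget = budget,
                                                seed = seed)),
    discrepancy = discrepancy(b, "fixed_order"),
    discrepancy2 = discrepancy(b, "fill_sorted"),
    h2 = h2$H2, h2_min = h2$H2_min, h2_max = h2$H2_max,
    h2_prime = h2$H2_prime)
  structure(list(metrics = metrics, provenance = meta),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  if (is.null(x$metrics)) {
    cat("metric report: network too small for metrics\n")
    return(invisible(x))
  }
  cat(sprintf("metric report (%d x %d, %d edges, fill %.2f):\n",
              x$provenance$n_rows, x$provenance$n_cols,
              x$provenance$n_edges, x$provenance$fill))
  for (nm in names(x$metrics))
    cat(sprintf("  %-14s %s\n", nm,
                ifelse(is.na(x$metrics[[nm]]), "NA",
                       format(round(as.numeric(x$metrics[[nm]]), 4)))))
  invisible(x)
}
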