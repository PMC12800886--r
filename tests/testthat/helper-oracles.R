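# Independent brute-force oracles and fixture builders used across tests.
# These deliberately use plain loops over the published definitions and
# share no code with the package implementations.

# NODF by explicit double loops (matrix taken in the order given)
oracle_nodf <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  rf <- sapply(seq_len(nr), function(i) sum(m[i, ] > 0))
  cf <- sapply(seq_len(nc), function(j) sum(m[, j] > 0))
  terms <- c()
  for (i in seq_len(nr - 1)) for (j in (i + 1):nr) {
    t_ij <- 0
    if (rf[i] > rf[j] && rf[j] > 0) {
      shared <- sum(m[i, ] > 0 & m[j, ] > 0)
      t_ij <- 100 * shared / rf[j]
    }
    terms <- c(terms, t_ij)
  }
  for (i in seq_len(nc - 1)) for (j in (i + 1):nc) {
    t_ij <- 0
    if (cf[i] > cf[j] && cf[j] > 0) {
      shared <- sum(m[, i] > 0 & m[, j] > 0)
      t_ij <- 100 * shared / cf[j]
    }
    terms <- c(terms, t_ij)
  }
  mean(terms)
}

# discrepancy: count presences falling outside the per-row packed block,
# building the packed target matrix explicitly
oracle_discrepancy <- function(m, sort_cols = TRUE) {
  if (sort_cols) m <- m[, order(-colSums(m), seq_len(ncol(m))), drop = FALSE]
  total <- 0
  for (i in seq_len(nrow(m))) {
    k <- sum(m[i, ])
    packed <- rep(0, ncol(m))
    if (k > 0) packed[1:k] <- 1
    total <- total + sum(m[i, ] == 1 & packed == 0)
  }
  total
}

# all non-negative integer matrices with the given marginals (recursive
# row-by-row enumeration); returns extremal natural-log entropies
oracle_h2_range <- function(r, cc) {
  nr <- length(r); nc <- length(cc)
  best <- c(min = Inf, max = -Inf)
  ent <- function(x) {
    p <- x[x > 0] / sum(x)
    -sum(p * log(p))
  }
  rows_for <- function(total, caps) {
    # all vectors v with sum(v) = total, 0 <= v_j <= caps_j
    if (length(caps) == 1) {
      if (total <= caps[1]) return(list(total)) else return(list())
    }
    out <- list()
    for (v in 0:min(total, caps[1]))
      for (rest in rows_for(total - v, caps[-1]))
        out[[length(out) + 1]] <- c(v, rest)
    out
  }
  recurse <- function(i, remaining_cols, acc) {
    if (i > nr) {
      if (all(remaining_cols == 0)) {
        e <- ent(do.call(rbind, acc))
        best["min"] <<- min(best["min"], e)
        best["max"] <<- max(best["max"], e)
      }
      return(invisible())
    }
    for (row in rows_for(r[i], remaining_cols))
      recurse(i + 1, remaining_cols - row, c(acc, list(row)))
  }
  recurse(1, cc, list())
  best
}

# fixtures -------------------------------------------------------------

staircase <- function(n) {
  m <- matrix(0, n, n)
  for (i in 1:n) m[i, seq_len(n - i + 1)] <- 1
  m
}

weighted_staircase <- function(n) {
  m <- staircase(n)
  w <- m * 0
  v <- sum(m):1
  k <- 1
  for (i in 1:n) for (j in 1:n) if (m[i, j] == 1) { w[i, j] <- v[k]; k <- k + 1 }
  w
}

checkerboard <- function(n) {
  outer(1:n, 1:n, function(i, j) (i + j) %% 2)
}

random_binary <- function(nr, nc, fill = 0.5) {
  matrix(rbinom(nr * nc, 1, fill), nr, nc)
}

# enumerate all nr x nc binary matrices as rows of a big matrix
all_binary_matrices <- function(nr, nc) {
  n <- nr * nc
  idx <- 0:(2^n - 1)
  vapply(idx, function(k) as.integer(intToBits(k)[1:n]), integer(n))
}

# small hand-made effect table for network construction tests
toy_effect_table <- function() {
  data.frame(
    grazer = c("g1", "g1", "g2"),
    target = c("a1", "a2", "a1"),
    mode = "trophic",
    di_mean = c(0.5, -0.2, 0.9),
    ci_low = c(0.1, -0.3, -0.1),
    ci_high = c(0.9, -0.1, 1.9),
    n_boot = 999, alpha = 0.05,
    significant = c(TRUE, TRUE, FALSE))
}
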