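# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  code
}

# Deterministic sub-stream seed; keeps results < 2^31 so set.seed() accepts it.
derive_seed <- function(seed, ...) {
  k <- c(...)
  s <- as.double(seed)
  for (x in k) s <- (s * 69069 + as.double(x) * 1000003 + 1) %% 2147483647
  as.integer(s)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

# Coerce a count/weight input (matrix or bipartite_network) to a base matrix.
as_weight_matrix <- function(x) {
  if (inherits(x, "bipartite_network")) return(x$weights)
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stopf("expected a numeric matrix or a bipartite_network")
  x
}

check_nonnegative_matrix <- function(w, what = "weight matrix") {
  if (anyNA(w)) stopf("%s contains missing values", what)
  if (any(w < 0)) stopf("%s contains negative entries", what)
  invisible(w)
}

# A matrix is degenerate for nestedness metrics when it has fewer than two
# rows or columns, or no positive entries at all.
check_nondegenerate <- function(w, what = "matrix") {
  if (nrow(w) < 2L || ncol(w) < 2L)
    stopf("%s is degenerate: need at least 2 rows and 2 columns", what)
  if (all(w == 0)) stopf("%s is degenerate: no positive entries", what)
  invisible(w)
}

# Order by decreasing marginal totals, ties broken by original index.
order_desc <- function(totals) order(-totals, seq_along(totals))
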