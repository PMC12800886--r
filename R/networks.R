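#' Build signed bipartite grazer-by-ASV networks from significant effects
#'
#' Splits an effect table (trophic and non-trophic modes) into the four
#' networks analysed downstream: trophic positive (TI+), trophic negative
#' (TI-), non-trophic positive (NTI+), non-trophic negative (NTI-). An
#' edge (grazer, ASV) enters the network of its mode and sign when the
#' effect is flagged significant; its weight is `|DI|`, so all metric code
#' consumes non-negative weights and the sign lives in the network
#' metadata. ASVs with no significant edge in a network are dropped from
#' its columns; grazer rows are always retained (possibly all-zero) so the
#' species stay comparable across the four networks.
#'
#' @param effects an `effect_table` (or rbind of several) containing modes
#'   `trophic` and/or `non_trophic`.
#' @return named list of `bipartite_network` objects
#'   (`trophic_positive`, `trophic_negative`, `non_trophic_positive`,
#'   `non_trophic_negative`), each with elements `weights` (grazers x
#'   ASVs), `sign`, `mode` and `n_edges`. Empty networks are allowed and
#'   flagged with a warning.
#' @export
build_networks <- function(effects) {
  modes <- intersect(c("trophic", "non_trophic"), unique(effects$mode))
  if (length(modes) == 0)
    stopf("effect table contains neither 'trophic' nor 'non_trophic' rows")
  grazers <- sort(unique(effects$grazer))
  nets <- list()
  empty <- character()
  for (m in c("trophic", "non_trophic")) for (s in c("positive", "negative")) {
    name <- paste(m, s, sep = "_")
    sub <- effects[effects$mode == m & effects$significant &
                     (if (s == "positive") effects$di_mean > 0
                      else effects$di_mean < 0), , drop = FALSE]
    targets <- sort(unique(sub$target))
    w <- matrix(0, length(grazers), length(targets),
                dimnames = list(grazers, targets))
    if (nrow(sub) > 0)
      w[cbind(match(sub$grazer, grazers), match(sub$target, targets))] <-
        abs(sub$di_mean)
    if (length(targets) == 0) empty <- c(empty, name)
    nets[[name]] <- structure(list(weights = w, sign = s, mode = m,
                                   n_edges = sum(w > 0)),
                              class = "bipartite_network")
  }
  if (length(empty) > 0)
    warnf("empty network(s): %s", paste(empty, collapse = ", "))
  nets
}

#' Binarize a bipartite network
#'
#' @param network a `bipartite_network` or non-negative weight matrix.
#' @return 0/1 matrix with the same dimnames (entry 1 where weight > 0).
#' @export
binarize <- function(network) {
  w <- as_weight_matrix(network)
  check_nonnegative_matrix(w)
  (w > 0) + 0
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf("bipartite network [%s, %s]: %d grazers x %d ASVs, %d edges\n",
              x$mode, x$sign, nrow(x$weights), ncol(x$weights), x$n_edges))
  invisible(x)
}
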