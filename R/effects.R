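#' Per-capita Dynamic Index
#'
#' The Dynamic Index measures per-capita, per-time interaction strength by
#' comparing a target's abundance with (`N`) and without (`D`) the
#' interactor: `DI = ln(N / D) / (Y * t)`, with `Y` the interactor
#' abundance and `t` the duration. It is recommended for short experiments
#' and captures both positive and negative effects.
#'
#' Two spaces are supported. In `relative_ratio` space `N` and `D` are
#' (strictly positive) relative abundances and the formula is applied
#' literally. In `clr_difference` space `N` and `D` are clr-transformed
#' values (any reals) and `DI = (N - D) / (Y * t)`; because
#' `clr(x)_i = ln(x_i / g(x))`, the clr difference is the log-ratio of the
#' target's abundance relative to the community's geometric mean, the
#' well-defined analogue of `ln(N/D)` for compositional data.
#'
#' @param N abundance (or clr value) with the interactor present.
#' @param D abundance (or clr value) with the interactor absent.
#' @param Y interactor abundance (> 0, default 1).
#' @param t duration (> 0, default 1).
#' @param space `"relative_ratio"` (default here, matching the literal
#'   definition) or `"clr_difference"`.
#' @return numeric DI value(s); vectorized over `N` and `D`.
#' @examples
#' dynamic_index(54, 99.9)   # grazer effect on mean biofilm cover
#' @export
dynamic_index <- function(N, D, Y = 1, t = 1,
                          space = c("relative_ratio", "clr_difference")) {
  space <- match.arg(space)
  if (any(Y <= 0) || any(t <= 0)) stopf("Y and t must be positive")
  if (space == "relative_ratio") {
    if (any(N <= 0) || any(D <= 0))
      stopf("relative_ratio mode requires N > 0 and D > 0")
    log(N / D) / (Y * t)
  } else {
    (N - D) / (Y * t)
  }
}

# group-mean DI in the configured space; X is the transformed sample matrix
group_di <- function(X, trt_rows, ctl_rows, config) {
  sc <- config$Y * config$t
  if (config$di_space == "clr_difference") {
    (colMeans(X[trt_rows, , drop = FALSE]) -
       colMeans(X[ctl_rows, , drop = FALSE])) / sc
  } else {
    log(colMeans(X[trt_rows, , drop = FALSE]) /
          colMeans(X[ctl_rows, , drop = FALSE])) / sc
  }
}

# bootstrap multiplicity matrix: n_boot rows, each a resample (with
# replacement) of seq_len(n) encoded as counts, so boot means are W %*% X / n
boot_weights <- function(n, n_boot, seed) {
  with_seed(seed, {
    W <- matrix(0L, n_boot, n)
    for (b in seq_len(n_boot))
      W[b, ] <- tabulate(sample.int(n, n, replace = TRUE), nbins = n)
    W
  })
}

#' Estimate grazer effects on every ASV with bootstrap confidence intervals
#'
#' For each grazer species, compares its treatment samples against the
#' controls and returns a per-(grazer, ASV) Dynamic Index estimate. The
#' point estimate is the DI of group means in the configured space
#' (replicates are independent aquaria, so no pairing exists). Uncertainty
#' comes from a percentile bootstrap that resamples treatment and control
#' replicates independently; an effect is flagged significant when the
#' `1 - alpha` interval excludes zero (optionally after Benjamini-Hochberg
#' correction of bootstrap p-values across pairs).
#'
#' `mode = "total"` uses the grazing treatments (grazing plus mucus
#' contact; the grazer's total effect), `mode = "non_trophic"` the caged
#' mucus treatments (pedal mucus only). The control bootstrap stream
#' depends only on (seed, grazer), so the two modes share control draws
#' and [decompose_trophic()] can pair them draw-by-draw.
#'
#' @param counts samples x ASVs count matrix.
#' @param metadata data.frame with `sample_id`, `treatment_class`,
#'   `grazer` (see [read_metadata()]).
#' @param config an [analysis_config()].
#' @param mode `"total"` or `"non_trophic"`.
#' @return data.frame of class `effect_table` with columns `grazer`,
#'   `target`, `mode`, `di_mean`, `ci_low`, `ci_high`, `n_boot`, `alpha`,
#'   `significant`; bootstrap draws are attached as attribute `boot` (a
#'   named list of n_boot x ASV matrices) and the configuration as
#'   attribute `config`.
#' @export
estimate_effects <- function(counts, metadata, config = analysis_config(),
                             mode = c("total", "non_trophic")) {
  mode <- match.arg(mode)
  counts <- as_weight_matrix(counts)
  validate_metadata(metadata, counts)
  trt_class <- if (mode == "total") "grazing" else "mucus"

  if (!is.null(config$rarefy_depth)) {
    counts <- rarefy_counts(counts, config$rarefy_depth,
                            seed = derive_seed(config$seed, 777))
    metadata <- metadata[metadata$sample_id %in% rownames(counts), ]
  }
  prop <- replace_zeros(counts, config$pseudocount)
  X <- if (config$di_space == "clr_difference") clr_transform(prop) else prop

  meta <- metadata[match(rownames(counts), metadata$sample_id), ]
  ctl_rows <- which(meta$treatment_class == "control")
  if (length(ctl_rows) == 0) stopf("no control samples in metadata")
  grazers <- sort(unique(meta$grazer[meta$treatment_class == trt_class]))
  if (length(grazers) == 0)
    stopf("no '%s' samples for mode '%s'", trt_class, mode)

  A <- ncol(X)
  boots <- list()
  rows <- vector("list", length(grazers))
  for (gi in seq_along(grazers)) {
    g <- grazers[gi]
    trt_rows <- which(meta$treatment_class == trt_class & meta$grazer == g)
    est <- group_di(X, trt_rows, ctl_rows, config)
    if (length(trt_rows) < 2 || length(ctl_rows) < 2) {
      warnf("grazer '%s', mode '%s': fewer than 2 replicates in a group; CI unavailable",
            g, mode)
      ci <- matrix(NA_real_, A, 2)
      sig <- rep(FALSE, A)
    } else {
      gi_global <- match(g, sort(unique(metadata$grazer)))
      Wc <- boot_weights(length(ctl_rows), config$n_boot,
                         derive_seed(config$seed, gi_global))
      Wt <- boot_weights(length(trt_rows), config$n_boot,
                         derive_seed(config$seed, gi_global * 101,
                                     if (mode == "total") 1 else 2))
      sc <- config$Y * config$t
      mc <- (Wc %*% X[ctl_rows, , drop = FALSE]) / length(ctl_rows)
      mt <- (Wt %*% X[trt_rows, , drop = FALSE]) / length(trt_rows)
      boot <- if (config$di_space == "clr_difference") (mt - mc) / sc
              else log(mt / mc) / sc
      colnames(boot) <- colnames(X)
      boots[[g]] <- boot
      pr <- c(config$alpha / 2, 1 - config$alpha / 2)
      ci <- t(apply(boot, 2, stats::quantile, probs = pr, names = FALSE))
      sig <- ci[, 1] > 0 | ci[, 2] < 0
    }
    rows[[gi]] <- data.frame(grazer = g, target = colnames(X), mode = mode,
                             di_mean = unname(est), ci_low = ci[, 1],
                             ci_high = ci[, 2], n_boot = config$n_boot,
                             alpha = config$alpha, significant = sig)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (config$bh_correct) out <- apply_bh(out, boots, config$alpha)
  structure(out, boot = boots, config = config, class = c("effect_table",
                                                          "data.frame"))
}

# two-sided bootstrap p-values, BH-adjusted across all pairs within a mode
apply_bh <- function(out, boots, alpha) {
  p <- rep(NA_real_, nrow(out))
  for (g in names(boots)) {
    idx <- which(out$grazer == g)
    boot <- boots[[g]]
    nb <- nrow(boot)
    lo <- (colSums(boot <= 0) + 1) / (nb + 1)
    hi <- (colSums(boot >= 0) + 1) / (nb + 1)
    p[idx] <- pmin(1, 2 * pmin(lo, hi))[match(out$target[idx],
                                              colnames(boot))]
  }
  keep <- !is.na(p)
  out$p_adjusted <- NA_real_
  out$p_adjusted[keep] <- stats::p.adjust(p[keep], method = "BH")
  out$significant <- keep & !is.na(out$p_adjusted) & out$p_adjusted < alpha
  out
}

#' Decompose total grazer effects into trophic effects
#'
#' The trophic (consumptive) effect is never observed directly: the
#' grazing treatment carries grazing plus pedal-mucus exposure, while the
#' caged mucus treatment carries the mucus effect alone. Subtracting the
#' non-trophic estimate from the total estimate per (grazer, ASV) yields
#' the trophic effect. Confidence intervals come from the bootstrap
#' distribution of the difference, paired by draw index (both inputs share
#' the control bootstrap stream, see [estimate_effects()]).
#'
#' @param total effect table with `mode == "total"`.
#' @param nti effect table with `mode == "non_trophic"`.
#' @return `effect_table` with `mode == "trophic"`; point estimates satisfy
#'   `trophic = total - non_trophic` exactly for every pair.
#' @export
decompose_trophic <- function(total, nti) {
  if (!identical(unique(total$mode), "total") ||
      !identical(unique(nti$mode), "non_trophic"))
    stopf("inputs must be effect tables with modes 'total' and 'non_trophic'")
  key_t <- paste(total$grazer, total$target)
  key_n <- paste(nti$grazer, nti$target)
  miss <- c(setdiff(key_t, key_n), setdiff(key_n, key_t))
  if (length(miss) > 0)
    stopf("effect tables cover different (grazer, target) pairs: %s",
          paste(utils::head(miss, 10), collapse = "; "))
  nti <- nti[match(key_t, key_n), ]

  out <- total
  out$mode <- "trophic"
  out$di_mean <- total$di_mean - nti$di_mean

  bt <- attr(total, "boot")
  bn <- attr(nti, "boot")
  cfg <- attr(total, "config")
  alpha <- total$alpha[1]
  boots <- list()
  out$ci_low <- NA_real_
  out$ci_high <- NA_real_
  out$significant <- FALSE
  for (g in unique(out$grazer)) {
    idx <- which(out$grazer == g)
    if (is.null(bt[[g]]) || is.null(bn[[g]])) {
      warnf("grazer '%s': bootstrap draws unavailable; trophic CI not computed", g)
      next
    }
    if (nrow(bt[[g]]) != nrow(bn[[g]]))
      stopf("grazer '%s': bootstrap draw counts differ between modes", g)
    diffb <- bt[[g]] - bn[[g]]           # paired by draw index
    boots[[g]] <- diffb
    pr <- c(alpha / 2, 1 - alpha / 2)
    ci <- t(apply(diffb, 2, stats::quantile, probs = pr, names = FALSE))
    ord <- match(out$target[idx], colnames(diffb))
    out$ci_low[idx] <- ci[ord, 1]
    out$ci_high[idx] <- ci[ord, 2]
    out$significant[idx] <- ci[ord, 1] > 0 | ci[ord, 2] < 0
  }
  if (!is.null(cfg) && isTRUE(cfg$bh_correct))
    out <- apply_bh(out, boots, alpha)
  structure(out, boot = boots, config = cfg,
            class = c("effect_table", "data.frame"))
}
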