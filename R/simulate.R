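#' Configuration for a simulated grazer-biofilm experiment
#'
#' Describes a synthetic amplicon experiment with the treatment design used
#' throughout the package: one ungrazed control, one grazing treatment per
#' grazer species (grazing plus pedal-mucus contact, carrying the *total*
#' effect), and one caged pedal-mucus treatment per grazer (carrying the
#' *non-trophic* effect only). Defaults mirror the laboratory design the
#' package targets: five mollusk grazer species, 13 control and 13 grazing
#' replicates, 10 mucus replicates (128 samples in all), and sequencing
#' depths around 6215 reads per sample.
#'
#' Sparse signed per-(grazer, ASV) log-effects act multiplicatively on the
#' expected relative abundances, so the clr-difference Dynamic Index is the
#' natural estimand: a grazing sample multiplies ASV `a`'s expectation by
#' `exp(delta_total[g, a])`, a mucus sample by `exp(delta_nti[g, a])`, with
#' `delta_total = delta_ti + delta_nti` exactly.
#'
#' @param n_asv number of ASVs (default 150).
#' @param grazer_names labels for the grazer species (default five mollusk
#'   grazers).
#' @param reps_control,reps_grazing,reps_mucus replicate counts (defaults
#'   13, 13, 10).
#' @param depth_mean mean sequencing depth in reads per sample (default
#'   6215).
#' @param depth_dispersion negative-binomial size parameter for depth
#'   variation across libraries (default 50; larger = more even depths).
#' @param base_log_mean,base_log_sd mean and SD of the log-normal baseline
#'   ASV log-abundances (defaults 0 and 1.5; heavy-tailed rank-abundance
#'   typical of biofilms).
#' @param effect_sparsity fraction of (grazer, ASV) pairs with a nonzero
#'   trophic (and, independently, non-trophic) effect (default 0.1).
#' @param effect_sd SD of nonzero log-effects (default 1).
#' @param effect_magnitude optional fixed magnitude; when set, nonzero
#'   effects are exactly `+/- effect_magnitude` with random sign (used for
#'   parameter-recovery checks at known effect size).
#' @param noise_sd SD of replicate-level log-normal noise on expected
#'   abundances (default 0.3).
#' @param concentration total Dirichlet concentration controlling count
#'   overdispersion beyond multinomial sampling (default 200; `Inf`
#'   disables the Dirichlet layer and draws plain multinomial counts).
#' @param seed integer RNG seed; the whole experiment is reproducible from
#'   it.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_asv = 150,
                              grazer_names = c("C_granosus", "E_peruviana",
                                               "F_crassa", "S_araucana",
                                               "S_lessonii"),
                              reps_control = 13,
                              reps_grazing = 13,
                              reps_mucus = 10,
                              depth_mean = 6215,
                              depth_dispersion = 50,
                              base_log_mean = 0,
                              base_log_sd = 1.5,
                              effect_sparsity = 0.1,
                              effect_sd = 1,
                              effect_magnitude = NULL,
                              noise_sd = 0.3,
                              concentration = 200,
                              seed = 1) {
  if (n_asv < 2) stopf("n_asv must be at least 2")
  if (length(grazer_names) < 1 || anyDuplicated(grazer_names))
    stopf("grazer_names must be non-empty and unique")
  if (min(reps_control, reps_grazing, reps_mucus) < 1)
    stopf("replicate counts must be positive")
  if (depth_mean < 1) stopf("depth_mean must be >= 1")
  if (effect_sparsity < 0 || effect_sparsity > 1)
    stopf("effect_sparsity must lie in [0, 1]")
  if (noise_sd < 0 || effect_sd < 0) stopf("SDs must be non-negative")
  if (concentration <= 0) stopf("concentration must be positive (or Inf)")
  cfg <- list(n_asv = as.integer(n_asv), grazer_names = grazer_names,
              reps_control = as.integer(reps_control),
              reps_grazing = as.integer(reps_grazing),
              reps_mucus = as.integer(reps_mucus),
              depth_mean = depth_mean, depth_dispersion = depth_dispersion,
              base_log_mean = base_log_mean, base_log_sd = base_log_sd,
              effect_sparsity = effect_sparsity, effect_sd = effect_sd,
              effect_magnitude = effect_magnitude, noise_sd = noise_sd,
              concentration = concentration, seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  cfg
}

#' Simulate a grazer-biofilm amplicon experiment with known ground truth
#'
#' Draws baseline ASV log-abundances once, applies the sparse signed
#' treatment effects described in [simulation_config()], adds replicate
#' noise, closes each sample to proportions, and draws counts from a
#' Dirichlet-multinomial (multinomial when `concentration = Inf`) at a
#' negative-binomial library depth. Returns the count table, aligned sample
#' metadata, and the true effect matrices for estimator validation.
#'
#' @param config a [simulation_config()].
#' @return an object of class `simulated_experiment`: a list with
#'   `counts` (integer matrix, samples x ASVs), `metadata` (data.frame with
#'   `sample_id`, `treatment_class`, `grazer`, `replicate`), `truth` (list
#'   of grazer x ASV matrices `delta_ti`, `delta_nti`, `delta_total`), and
#'   the echoed `config`.
#' @export
simulate_experiment <- function(config = simulation_config()) {
  if (!inherits(config, "simulation_config"))
    stopf("config must be a simulation_config")
  with_seed(config$seed, {
    G <- length(config$grazer_names)
    A <- config$n_asv
    asv_ids <- sprintf("ASV%04d", seq_len(A))

    base_log <- stats::rnorm(A, config$base_log_mean, config$base_log_sd)

    draw_effects <- function() {
      mask <- matrix(stats::runif(G * A) < config$effect_sparsity, G, A)
      val <- if (is.null(config$effect_magnitude)) {
        matrix(stats::rnorm(G * A, 0, config$effect_sd), G, A)
      } else {
        matrix(sample(c(-1, 1), G * A, replace = TRUE) *
                 config$effect_magnitude, G, A)
      }
      out <- val * mask
      dimnames(out) <- list(config$grazer_names, asv_ids)
      out
    }
    delta_ti <- draw_effects()
    delta_nti <- draw_effects()
    delta_total <- delta_ti + delta_nti

    # sample layout: control, then grazing per grazer, then mucus per grazer
    meta <- rbind(
      data.frame(sample_id = sprintf("ctrl_%02d", seq_len(config$reps_control)),
                 treatment_class = "control", grazer = NA_character_,
                 replicate = seq_len(config$reps_control)),
      do.call(rbind, lapply(config$grazer_names, function(g)
        data.frame(sample_id = sprintf("grz_%s_%02d", g,
                                       seq_len(config$reps_grazing)),
                   treatment_class = "grazing", grazer = g,
                   replicate = seq_len(config$reps_grazing)))),
      do.call(rbind, lapply(config$grazer_names, function(g)
        data.frame(sample_id = sprintf("muc_%s_%02d", g,
                                       seq_len(config$reps_mucus)),
                   treatment_class = "mucus", grazer = g,
                   replicate = seq_len(config$reps_mucus)))))
    rownames(meta) <- NULL

    n_samp <- nrow(meta)
    counts <- matrix(0L, n_samp, A, dimnames = list(meta$sample_id, asv_ids))
    depths <- pmax(1L, stats::rnbinom(n_samp, mu = config$depth_mean,
                                      size = config$depth_dispersion))
    for (s in seq_len(n_samp)) {
      eta <- base_log
      if (meta$treatment_class[s] == "grazing")
        eta <- eta + delta_total[meta$grazer[s], ]
      else if (meta$treatment_class[s] == "mucus")
        eta <- eta + delta_nti[meta$grazer[s], ]
      eta <- eta + stats::rnorm(A, 0, config$noise_sd)
      p <- exp(eta - max(eta))
      p <- p / sum(p)            # compositional closure before count drawing
      if (is.finite(config$concentration)) {
        lam <- stats::rgamma(A, shape = p * config$concentration)
        if (sum(lam) == 0) lam <- p
        p <- lam / sum(lam)
      }
      counts[s, ] <- stats::rmultinom(1, depths[s], p)[, 1]
    }

    if (min(config$reps_control, config$reps_grazing, config$reps_mucus) < 2)
      meta$bootstrap_ok <- FALSE
    else meta$bootstrap_ok <- TRUE

    structure(list(counts = counts, metadata = meta,
                   truth = list(delta_ti = delta_ti, delta_nti = delta_nti,
                                delta_total = delta_total),
                   config = config, seed = config$seed),
              class = "simulated_experiment")
  })
}

#' True interaction edge sets from a simulated experiment
#'
#' Thresholds the ground-truth effect matrices into the four signed edge
#' sets the estimation pipeline tries to recover: trophic positive/negative
#' and non-trophic positive/negative. An edge (grazer, ASV) is present in a
#' set when the corresponding true log-effect exceeds `threshold` in
#' magnitude with the matching sign.
#'
#' @param truth the `truth` element of a [simulate_experiment()] result (a
#'   list with `delta_ti` and `delta_nti` matrices), or the
#'   `simulated_experiment` itself.
#' @param threshold non-negative magnitude cutoff (default 0).
#' @return named list of four logical grazer x ASV matrices:
#'   `trophic_positive`, `trophic_negative`, `non_trophic_positive`,
#'   `non_trophic_negative`.
#' @export
truth_networks <- function(truth, threshold = 0) {
  if (inherits(truth, "simulated_experiment")) truth <- truth$truth
  if (!is.list(truth) || is.null(truth$delta_ti) || is.null(truth$delta_nti))
    stopf("truth must contain delta_ti and delta_nti matrices")
  if (threshold < 0) stopf("threshold must be >= 0")
  list(trophic_positive = truth$delta_ti > threshold,
       trophic_negative = truth$delta_ti < -threshold,
       non_trophic_positive = truth$delta_nti > threshold,
       non_trophic_negative = truth$delta_nti < -threshold)
}

#' @export
print.simulated_experiment <- function(x, ...) {
  cat(sprintf("simulated grazer-biofilm experiment: %d samples x %d ASVs\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  grazers: %s\n", paste(x$config$grazer_names, collapse = ", ")))
  tab <- table(x$metadata$treatment_class)
  cat(sprintf("  samples: %s\n",
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
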