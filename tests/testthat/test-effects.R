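# small simulated experiment shared by several blocks
small_sim <- function(seed = 11, magnitude = 1) {
  simulate_experiment(simulation_config(
    n_asv = 50, reps_control = 10, reps_grazing = 10, reps_mucus = 10,
    effect_magnitude = magnitude, seed = seed))
}

test_that("dynamic_index matches closed forms", {
  expect_equal(dynamic_index(10, 10), 0)
  expect_equal(dynamic_index(exp(1) * 3, 3), 1)
  # per-capita grazing effect on mean biofilm cover (54% vs 99.9% control)
  expect_equal(dynamic_index(54, 99.9), log(54 / 99.9))
  expect_equal(dynamic_index(54, 99.9), -0.61519, tolerance = 1e-4)
  expect_equal(dynamic_index(54, 99.9, Y = 2), -0.61519 / 2,
               tolerance = 1e-4)
  expect_error(dynamic_index(-1, 5), "N > 0")
  expect_error(dynamic_index(1, 5, Y = 0), "positive")
})

test_that("DI is antisymmetric and scales as 1/(Y*t)", {
  set.seed(1)
  N <- rexp(50) + 0.1; D <- rexp(50) + 0.1
  expect_equal(dynamic_index(N, D), -dynamic_index(D, N))
  Y <- 3; tt <- 4
  expect_equal(dynamic_index(N, D, Y, tt), dynamic_index(N, D) / (Y * tt))
  x <- rnorm(50); y <- rnorm(50)
  expect_equal(dynamic_index(x, y, space = "clr_difference"),
               -dynamic_index(y, x, space = "clr_difference"))
  expect_equal(dynamic_index(x, y, Y, tt, space = "clr_difference"),
               (x - y) / (Y * tt))
})

test_that("copied treatment data yields zero estimates and no significance", {
  sim <- small_sim(seed = 21, magnitude = 0)
  counts <- sim$counts
  md <- sim$metadata
  ctl <- md$sample_id[md$treatment_class == "control"]
  g1 <- md$sample_id[md$treatment_class == "grazing" &
                       md$grazer == "C_granosus"]
  counts[g1, ] <- counts[ctl[seq_along(g1)], ]  # treatment == control data
  eff <- estimate_effects(counts, md, analysis_config(n_boot = 199, seed = 2),
                          mode = "total")
  sub <- eff[eff$grazer == "C_granosus", ]
  expect_equal(sub$di_mean, rep(0, nrow(sub)), tolerance = 1e-12)
  expect_false(any(sub$significant))
})

test_that("clr-difference DI is invariant to per-sample sequencing depth", {
  sim <- small_sim(seed = 31)
  counts <- sim$counts + 1L             # strictly positive counts
  cfg <- analysis_config(pseudocount = 1e-9, n_boot = 99, seed = 4)
  e1 <- estimate_effects(counts, sim$metadata, cfg, mode = "total")
  counts2 <- counts
  counts2[1, ] <- counts2[1, ] * 50L    # rescale one library
  counts2[20, ] <- counts2[20, ] * 7L
  e2 <- estimate_effects(counts2, sim$metadata, cfg, mode = "total")
  expect_equal(e1$di_mean, e2$di_mean, tolerance = 1e-6)
})

test_that("bootstrap CIs bracket the point estimate and drive significance", {
  sim <- small_sim(seed = 41)
  eff <- estimate_effects(sim$counts, sim$metadata,
                          analysis_config(n_boot = 499, seed = 5),
                          mode = "non_trophic")
  ok <- !is.na(eff$ci_low)
  expect_true(all(eff$ci_low[ok] <= eff$di_mean[ok] + 1e-6))
  expect_true(all(eff$ci_high[ok] >= eff$di_mean[ok] - 1e-6))
  expect_equal(eff$significant, eff$ci_low > 0 | eff$ci_high < 0)
})

test_that("groups with fewer than 2 replicates get flagged, not dropped", {
  sim <- small_sim(seed = 51)
  md <- sim$metadata
  drop <- md$sample_id[md$treatment_class == "mucus" &
                         md$grazer == "C_granosus"][-1]
  keep <- !(md$sample_id %in% drop)
  expect_warning(
    eff <- estimate_effects(sim$counts[keep, ], md[keep, ],
                            analysis_config(n_boot = 99, seed = 1),
                            mode = "non_trophic"),
    "fewer than 2 replicates")
  sub <- eff[eff$grazer == "C_granosus", ]
  expect_true(all(is.na(sub$ci_low)))
  expect_false(any(sub$significant))
  expect_true(all(is.finite(sub$di_mean)))
})

test_that("trophic decomposition is exactly total minus non-trophic", {
  sim <- small_sim(seed = 61)
  cfg <- analysis_config(n_boot = 299, seed = 7)
  tot <- estimate_effects(sim$counts, sim$metadata, cfg, mode = "total")
  nti <- estimate_effects(sim$counts, sim$metadata, cfg, mode = "non_trophic")
  ti <- decompose_trophic(tot, nti)
  expect_equal(ti$di_mean, tot$di_mean - nti$di_mean, tolerance = 0)
  expect_true(all(ti$mode == "trophic"))

  # identical input tables give an exactly-zero trophic table
  fake_nti <- tot
  fake_nti$mode <- "non_trophic"
  zero <- decompose_trophic(tot, fake_nti)
  expect_equal(zero$di_mean, rep(0, nrow(zero)))
  expect_false(any(zero$significant))

  # mismatched domains are rejected with the missing pairs listed
  expect_error(decompose_trophic(tot, nti[-1, ]), "different")
})

test_that("known effects are recovered at the stated design", {
  sim <- small_sim(seed = 71)
  cfg <- analysis_config(n_boot = 499, seed = 8)
  tot <- estimate_effects(sim$counts, sim$metadata, cfg, mode = "total")
  nti <- estimate_effects(sim$counts, sim$metadata, cfg, mode = "non_trophic")
  truth_tot <- sim$truth$delta_total[cbind(tot$grazer, tot$target)]
  truth_nti <- sim$truth$delta_nti[cbind(nti$grazer, nti$target)]
  for (case in list(list(tbl = tot, tru = truth_tot),
                    list(tbl = nti, tru = truth_nti))) {
    up <- case$tru == 1
    dn <- case$tru == -1
    expect_equal(mean(case$tbl$di_mean[up]), 1, tolerance = 0.25)
    expect_equal(mean(case$tbl$di_mean[dn]), -1, tolerance = 0.25)
    sig_nonnull <- case$tbl$significant & case$tru != 0
    expect_gte(mean(sign(case$tbl$di_mean[sig_nonnull]) ==
                      sign(case$tru[sig_nonnull])), 0.95)
  }
})
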