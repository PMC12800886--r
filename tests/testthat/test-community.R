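test_that("rarefaction hits the target depth exactly", {
  set.seed(30)
  counts <- matrix(rpois(60, 40), 6, 10,
                   dimnames = list(paste0("s", 1:6), paste0("a", 1:10)))
  out <- rarefy_counts(counts, depth = 100, seed = 1)
  expect_true(all(rowSums(out) == 100))
  expect_true(all(out <= counts))

  # a sample already at depth is returned unchanged
  exact <- matrix(c(60L, 40L), 1, 2, dimnames = list("s", c("a", "b")))
  expect_equal(rarefy_counts(exact, depth = 100, seed = 2), exact)

  # shallow samples are dropped with a warning
  shallow <- counts; shallow[2, ] <- 0L; shallow[2, 1] <- 5L
  expect_warning(out2 <- rarefy_counts(shallow, depth = 100, seed = 3), "s2")
  expect_false("s2" %in% rownames(out2))
  expect_error(rarefy_counts(counts, depth = 1e6), "below depth")
})

test_that("richness and Shannon match closed forms", {
  m <- matrix(c(3, 0, 1,
                5, 5, 5,
                9, 0, 0,
                0, 0, 0), 4, 3, byrow = TRUE)
  expect_equal(unname(richness(m)), c(2, 3, 1, 0))
  h <- unname(shannon_diversity(m))
  expect_equal(h[2], log(3))
  expect_equal(h[3], 0)
  expect_true(is.na(h[4]))
})

test_that("Bray-Curtis matches direct formula evaluation", {
  x <- rbind(a = c(1, 1, 0), b = c(0, 1, 1))
  d <- bray_curtis(x)
  expect_equal(d["a", "b"], 0.5)
  same <- rbind(s1 = c(2, 3), s2 = c(2, 3))
  expect_equal(bray_curtis(same)["s1", "s2"], 0)
  disjoint <- rbind(s1 = c(4, 0), s2 = c(0, 9))
  expect_equal(bray_curtis(disjoint)["s1", "s2"], 1)
  set.seed(31)
  m <- matrix(rpois(40, 5), 4, 10)
  d2 <- bray_curtis(m)
  expect_equal(d2, t(d2))
  expect_true(all(diag(d2) == 0))
  expect_true(all(d2 >= 0 & d2 <= 1))
})

test_that("PERMANOVA pseudo-F and R2 agree with vegan::adonis2", {
  set.seed(32)
  comm <- matrix(rpois(15 * 12, 8), 15, 12)
  comm[1:5, 1:4] <- comm[1:5, 1:4] + 12
  groups <- rep(c("A", "B", "C"), each = 5)
  d <- bray_curtis(comm)
  fit <- permanova(d, groups, n_permutations = 499, seed = 1)
  ref <- vegan::adonis2(stats::as.dist(d) ~ g,
                        data = data.frame(g = groups), permutations = 99)
  expect_equal(fit$pseudo_F, ref$F[1], tolerance = 1e-9)
  expect_equal(fit$R2, ref$R2[1], tolerance = 1e-9)
  expect_gte(fit$p_value, 1 / 500)
  expect_true(fit$R2 >= 0 && fit$R2 <= 1)
})

test_that("PERMANOVA is invariant to consistent sample reordering", {
  set.seed(33)
  comm <- matrix(rpois(12 * 8, 6), 12, 8)
  groups <- rep(c("A", "B"), each = 6)
  d <- bray_curtis(comm)
  perm <- sample(12)
  f1 <- permanova(d, groups, n_permutations = 99, seed = 4)$pseudo_F
  f2 <- permanova(d[perm, perm], groups[perm], n_permutations = 99,
                  seed = 4)$pseudo_F
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("well-separated groups reach the minimal p-value", {
  set.seed(35)
  comm <- rbind(
    matrix(rep(c(50, 0, 0), each = 8), 8, 3) + matrix(rpois(24, 2), 8, 3),
    matrix(rep(c(0, 50, 0), each = 8), 8, 3) + matrix(rpois(24, 2), 8, 3))
  groups <- rep(c("A", "B"), each = 8)
  nperm <- 199
  fit <- permanova(bray_curtis(comm), groups, n_permutations = nperm,
                   seed = 5)
  expect_equal(fit$p_value, 1 / (nperm + 1))
})

test_that("group-size and label validation", {
  d <- bray_curtis(matrix(rpois(12, 5), 4, 3))
  expect_error(permanova(d, c("A", "A", "A", "B")), "size 1")
  expect_error(permanova(d, c("A", "A", "B")), "length")
  expect_error(permanova(d, rep("A", 4)), "2 groups")
})

test_that("pairwise comparisons return BH-adjusted p-values per pair", {
  set.seed(34)
  comm <- matrix(rpois(18 * 10, 6), 18, 10)
  comm[1:6, 1:3] <- comm[1:6, 1:3] + 15
  groups <- rep(c("A", "B", "C"), each = 6)
  pw <- pairwise_permanova(bray_curtis(comm), groups,
                           n_permutations = 199, seed = 6)
  expect_equal(nrow(pw), 3)
  expect_true(all(pw$p_adjusted >= pw$p_value - 1e-12))
})
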