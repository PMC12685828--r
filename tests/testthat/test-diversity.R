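test_that("alpha diversity matches closed forms and the Chao1 formula", {
  # four equally abundant taxa: H = ln 4, Gini-Simpson = 0.75
  ft <- make_ft(matrix(c(25, 25, 25, 25, 10, 0, 0, 0), ncol = 2))
  a <- alpha_diversity(ft)
  expect_equal(a$shannon[1], log(4), tolerance = 1e-12)
  expect_equal(a$simpson[1], 0.75, tolerance = 1e-12)
  # second sample holds a single taxon
  expect_equal(a$shannon[2], 0)
  expect_equal(a$simpson[2], 0)
  expect_equal(a$chao1[2], 1)

  # counts (1,1,2): hand-evaluated H, Simpson, Chao1 = 3 + 2*1/(2*2)
  ft2 <- make_ft(matrix(c(1, 1, 2, 1, 1, 1), ncol = 2))
  a2 <- alpha_diversity(ft2)
  p <- c(0.25, 0.25, 0.5)
  expect_equal(a2$shannon[1], -sum(p * log(p)), tolerance = 1e-12)
  expect_equal(a2$simpson[1], 1 - sum(p^2), tolerance = 1e-12)
  expect_equal(a2$chao1[1], 3.5)
  # base-2 option scales Shannon by log(2)
  expect_equal(alpha_diversity(ft2, base = 2)$shannon[1],
               -sum(p * log2(p)), tolerance = 1e-12)
})

test_that("Shannon is maximal at the uniform composition", {
  set.seed(11)
  n <- 20
  uniform <- rep(50, n)
  for (i in 1:20) {
    bump <- pmax(1, uniform + sample(c(-20, 0, 20), n, replace = TRUE))
    if (all(bump == bump[1])) next
    ft <- make_ft(cbind(uniform, bump))
    a <- alpha_diversity(ft)
    expect_gt(a$shannon[1], a$shannon[2])
  }
})

test_that("rarefaction depth above a sample total names the sample", {
  ft <- make_ft(matrix(c(50, 50, 1000, 1000), ncol = 2), samples = c("lo", "hi"))
  expect_error(alpha_diversity(ft, rarefy_depth = 500), "lo",
               class = "micronet_validation_error")
  shallow <- alpha_diversity(ft, rarefy_depth = 100, seed = 1)
  expect_true(all(shallow$observed <= 2))
})

test_that("Bray-Curtis matches the formula and is scale invariant", {
  ft <- make_ft(matrix(c(10, 10, 5, 15), ncol = 2))
  d <- bray_curtis(ft)
  # relative abundances (.5,.5) vs (.25,.75) -> 0.25
  expect_equal(d[1, 2], 0.25, tolerance = 1e-12)
  expect_equal(diag(d), c(s01 = 0, s02 = 0))

  same <- make_ft(matrix(c(3, 7, 3, 7), ncol = 2))
  expect_equal(bray_curtis(same)[1, 2], 0)
  disjoint <- make_ft(matrix(c(5, 0, 0, 9), ncol = 2))
  expect_equal(bray_curtis(disjoint)[1, 2], 1)

  # multiplying a sample's counts by k leaves distances unchanged
  scaled <- make_ft(matrix(c(10, 10, 5 * 13, 15 * 13), ncol = 2))
  expect_equal(bray_curtis(scaled)[1, 2], d[1, 2], tolerance = 1e-12)
})

test_that("PCoA embeds exactly: collinear points and random Euclidean clouds", {
  # 3 collinear points with gaps 1 and 1: one positive axis carrying 100%
  dm <- rbind(c(0, 1, 2), c(1, 0, 1), c(2, 1, 0))
  dimnames(dm) <- list(letters[1:3], letters[1:3])
  ord <- pcoa(dm)
  expect_equal(ord$proportion_explained[1], 1, tolerance = 1e-10)
  coords <- ord$coordinates$Axis1
  expect_equal(abs(coords[1] - coords[3]), 2, tolerance = 1e-10)
  expect_equal(abs(coords[1] - coords[2]), 1, tolerance = 1e-10)

  # all-zero distances: all coordinates zero
  zero <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_true(all(abs(as.matrix(pcoa(zero)$coordinates[-1])) < 1e-10))

  # distances from random 2-D points are reconstructed to 1e-8
  set.seed(7)
  pts <- matrix(rnorm(20), ncol = 2)
  dm2 <- as.matrix(dist(pts))
  ord2 <- pcoa(dm2)
  rec <- as.matrix(dist(as.matrix(ord2$coordinates[-1])))
  expect_lt(max(abs(rec - dm2)), 1e-8)

  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2)), "symmetric",
               class = "micronet_validation_error")
})

test_that("PERMANOVA agrees with the vegan implementation on F and R2", {
  set.seed(21)
  m <- matrix(rpois(12 * 30, 20), nrow = 30)
  m[1:10, 1:4] <- m[1:10, 1:4] + 25
  ft <- make_ft(m)
  labels <- rep(c("A", "B", "C"), each = 4)
  dm <- bray_curtis(ft)
  res <- permanova(dm, labels, n_permutations = 199, seed = 5)
  ref <- vegan::adonis2(as.dist(dm) ~ g,
                        data = data.frame(g = labels), permutations = 199)
  expect_equal(res$statistic, ref$F[1], tolerance = 1e-10)
  expect_equal(res$R2, ref$R2[1], tolerance = 1e-10)
  expect_true(res$p <= 0.05)
})

test_that("PERMANOVA is zero when groups are exact duplicates", {
  pts <- matrix(rnorm(8), ncol = 2)
  dup <- rbind(pts, pts)
  dm <- as.matrix(dist(dup))
  rownames(dm) <- colnames(dm) <- paste0("s", 1:8)
  res <- permanova(dm, rep(c("A", "B"), each = 4), n_permutations = 99)
  expect_equal(res$statistic, 0, tolerance = 1e-10)
  expect_equal(res$R2, 0, tolerance = 1e-10)
})

test_that("PERMANOVA p is invariant to label renaming and sample order", {
  set.seed(31)
  pts <- matrix(rnorm(24), ncol = 2)
  dm <- as.matrix(dist(pts))
  rownames(dm) <- colnames(dm) <- paste0("s", 1:12)
  labels <- rep(c("A", "B"), each = 6)
  r1 <- permanova(dm, labels, n_permutations = 199, seed = 9)
  r2 <- permanova(dm, ifelse(labels == "A", "zz", "aa"),
                  n_permutations = 199, seed = 9)
  expect_equal(r1$p, r2$p)
  expect_equal(r1$statistic, r2$statistic)
  expect_error(permanova(dm, c("A", rep("B", 11))), "size 1",
               class = "micronet_validation_error")
})

test_that("a strongly planted community shift reaches the minimum attainable p", {
  design <- community_design(
    n_taxa = c(bacteria = 120), n_differential = c(bacteria = 50),
    log_fold = log(20), sigma_noise = 0.4, theta = 1e-4,
    shannon_offsets = list(bacteria = NULL), modules = list(), seed = 17
  )
  sim <- simulate_dataset(design)
  dm <- bray_curtis(sim$tables$bacteria)
  res <- permanova(dm, sim$metadata$treatment, n_permutations = 999, seed = 2)
  expect_equal(res$p, 1 / 1000)
})

test_that("tidy and glance methods return well-formed tibbles", {
  set.seed(41)
  dm <- as.matrix(dist(matrix(rnorm(16), ncol = 2)))
  rownames(dm) <- colnames(dm) <- paste0("s", 1:8)
  res <- permanova(dm, rep(c("A", "B"), each = 4), n_permutations = 99)
  td <- generics::tidy(res)
  expect_equal(td$term, c("groups", "residual"))
  expect_equal(sum(td$R2), 1)
  gl <- generics::glance(res)
  expect_equal(gl$p.value, res$p)
  expect_equal(sum(generics::tidy(pcoa(dm))$proportion_explained, na.rm = TRUE),
               1, tolerance = 1e-8)
})
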