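small_design <- function(...) {
  community_design(
    n_taxa = c(bacteria = 80, eukaryote = 30),
    n_differential = c(bacteria = 8, eukaryote = 4),
    modules = list(
      bacteria = list(W = list(list(size = 6, rho = 0.6, neg_frac = 0.25)),
                      SW = list(list(size = 8, rho = 0.7, neg_frac = 0.25))),
      eukaryote = list(SW = list(list(size = 5, rho = 0.7, neg_frac = 0.2)))
    ),
    ...
  )
}

test_that("identical seeds give bit-identical datasets", {
  d <- small_design(seed = 42)
  s1 <- simulate_dataset(d)
  s2 <- simulate_dataset(d)
  expect_identical(ft_counts(s1$tables$bacteria), ft_counts(s2$tables$bacteria))
  expect_identical(ft_counts(s1$tables$eukaryote), ft_counts(s2$tables$eukaryote))
  expect_identical(s1$soil, s2$soil)
  expect_identical(s1$truth$differential, s2$truth$differential)
  # different seed differs
  s3 <- simulate_dataset(small_design(seed = 43))
  expect_false(identical(ft_counts(s1$tables$bacteria),
                         ft_counts(s3$tables$bacteria)))
})

test_that("per-sample totals equal the design depth exactly", {
  sim <- simulate_dataset(small_design(seed = 7, depth = 12000))
  for (dom in names(sim$tables)) {
    expect_true(all(colSums(ft_counts(sim$tables[[dom]])) == 12000))
  }
  expect_equal(nrow(sim$metadata), 18)
  expect_equal(as.vector(table(sim$metadata$group)), rep(3L, 6))
})

test_that("infeasible designs are refused", {
  expect_error(
    community_design(n_taxa = c(bacteria = 10),
                     modules = list(bacteria = list(
                       W = list(list(size = 20, rho = 0.5, neg_frac = 0))
                     ))),
    "exceed", class = "micronet_validation_error"
  )
  expect_error(
    community_design(modules = list(bacteria = list(
      W = list(list(size = 5, rho = 1, neg_frac = 0))
    ))),
    "rho", class = "micronet_validation_error"
  )
  expect_error(community_design(depth = 500), "depth",
               class = "micronet_validation_error")
  expect_error(community_design(theta = 0), "theta",
               class = "micronet_validation_error")
})

test_that("every planted taxon exists in the generated tables", {
  sim <- simulate_dataset(small_design(seed = 9))
  for (dom in names(sim$tables)) {
    taxa <- sim$tables[[dom]]$taxon_id
    tr <- sim$truth
    expect_true(all(tr$differential$taxon_id[tr$differential$domain == dom]
                    %in% taxa))
    expect_true(all(tr$modules$taxon_id[tr$modules$domain == dom] %in% taxa))
  }
})

test_that("module correlation on counts matches the Gaussian-copula Spearman", {
  # one module (m = 10, rho = 0.9) observed over ~200 samples; the copula
  # implies a population Spearman of (6/pi) asin(rho/2)
  d <- community_design(
    n_taxa = c(bacteria = 60), blocks = 34, depth = 30000,
    sigma_log = 0.5, theta = 1e-6, sigma_noise = 1,
    n_differential = c(bacteria = 0), shannon_offsets = list(bacteria = NULL),
    gradient_sd = 0,
    modules = list(bacteria = list(
      all = list(list(size = 10, rho = 0.9, neg_frac = 0))
    )),
    seed = 101
  )
  sim <- simulate_dataset(d)
  mod_taxa <- sim$truth$modules$taxon_id
  rel <- ft_relative(sim$tables$bacteria)
  cm <- stats::cor(t(rel[mod_taxa, ]), method = "spearman")
  observed <- mean(cm[upper.tri(cm)])
  oracle <- (6 / pi) * asin(0.9 / 2)
  expect_lt(abs(observed - oracle), 0.05)

  # sign mix: negative-signed members anticorrelate with positive ones
  d2 <- community_design(
    n_taxa = c(bacteria = 40), blocks = 34, sigma_log = 0.5, theta = 1e-6,
    n_differential = c(bacteria = 0), shannon_offsets = list(bacteria = NULL),
    gradient_sd = 0,
    modules = list(bacteria = list(
      all = list(list(size = 10, rho = 0.8, neg_frac = 0.5))
    )),
    seed = 55
  )
  sim2 <- simulate_dataset(d2)
  mods <- sim2$truth$modules
  rel2 <- ft_relative(sim2$tables$bacteria)
  pos <- mods$taxon_id[mods$sign > 0]
  neg <- mods$taxon_id[mods$sign < 0]
  cross <- stats::cor(t(rel2[pos, ]), t(rel2[neg, ]), method = "spearman")
  expect_lt(mean(cross), -0.5)
})

test_that("planted Shannon offsets are analytic and realised at finite depth", {
  d0 <- small_design(seed = 1, shannon_offsets = list(bacteria = NULL))
  expect_equal(planted_diversity_offset(d0, "SW"), 0)
  d_half <- small_design(seed = 1,
                         shannon_offsets = list(bacteria = c(W = log(2))))
  # an evenness boost doubling the effective richness is a ln 2 shift
  expect_equal(planted_diversity_offset(d_half, "W"), log(2))
  expect_error(planted_diversity_offset(d0, "XX"), "unknown group",
               class = "micronet_validation_error")

  # realised group difference at depth 30,000 within 10% of the analytic
  # offset, 100 replicates
  d <- community_design(
    n_taxa = c(bacteria = 150), theta = 1e-6, sigma_noise = 0.05,
    gradient_sd = 0, n_differential = c(bacteria = 0),
    shannon_offsets = list(bacteria = c(W = -log(2))), modules = list()
  )
  shifts <- vapply(1:100, function(i) {
    d$seed <- i
    s <- simulate_dataset(d)
    a <- alpha_diversity(s$tables$bacteria) |>
      dplyr::left_join(s$metadata, by = "sample_id")
    mean(a$shannon[a$group == "W"]) - mean(a$shannon[a$group == "S"])
  }, numeric(1))
  expect_lt(abs(mean(shifts) - (-log(2))), 0.1 * log(2))
})

test_that("with theta near zero and no modules counts are multinomial", {
  d <- community_design(
    n_taxa = c(bacteria = 50), blocks = 20, depth = 5000,
    theta = 1e-9, sigma_noise = 0, gradient_sd = 0,
    n_differential = c(bacteria = 0), shannon_offsets = list(bacteria = NULL),
    modules = list(), seed = 31
  )
  sim <- simulate_dataset(d)
  m <- ft_counts(sim$tables$bacteria)  # 120 iid multinomial samples
  p_hat <- rowMeans(m) / 5000
  top <- order(p_hat, decreasing = TRUE)[1:10]
  ratio <- apply(m[top, ], 1, stats::var) /
    (5000 * p_hat[top] * (1 - p_hat[top]))
  # chi-square Monte-Carlo band for n = 120 replicates, widened
  expect_true(all(ratio > 0.6 & ratio < 1.6))
})

test_that("the written dataset round-trips through the readers", {
  sim <- simulate_dataset(small_design(seed = 3))
  dir <- withr::local_tempdir()
  write_dataset(sim, dir)
  back <- read_feature_table(file.path(dir, "bacteria_counts.tsv"))
  expect_equal(ft_counts(back), ft_counts(sim$tables$bacteria))
  meta <- read_metadata(file.path(dir, "metadata.tsv"), back)
  expect_equal(meta$group, sim$metadata$group)
  soil <- read_soil_table(file.path(dir, "soil.tsv"), meta)
  expect_equal(soil$TP, sim$soil$TP, tolerance = 1e-12)
  expect_true(file.exists(file.path(dir, "truth.json")))
})
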