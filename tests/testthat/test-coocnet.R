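test_that("identical abundance vectors give a single perfect positive edge", {
  set.seed(1)
  base <- c(5, 9, 2, 14, 7, 11)
  m <- rbind(a = base, b = base * 2, c = rpois(6, 500) + 1)
  colnames(m) <- paste0("s", 1:6)
  net <- build_network(feature_table(m), min_prevalence = 0)
  ab <- net$edges[net$edges$source == "a" & net$edges$target == "b", ]
  expect_equal(nrow(ab), 1)
  expect_equal(ab$r, 1)
  expect_equal(ab$sign, "positive")
  expect_true(all(net$edges$q < 0.05 & abs(net$edges$r) > 0.6))
})

test_that("construction validates inputs and excludes constant taxa", {
  m <- matrix(rpois(30, 50) + 1, nrow = 5,
              dimnames = list(paste0("t", 1:5), paste0("s", 1:6)))
  ft <- feature_table(m)
  expect_error(build_network(ft, samples = paste0("s", 1:3)), "4 samples",
               class = "micronet_validation_error")
  # a taxon with identical relative abundance everywhere is dropped with a
  # warning, not an error
  m2 <- m
  m2[1, ] <- colSums(m[-1, ])  # half of every sample total
  expect_warning(net <- build_network(feature_table(m2), min_prevalence = 0),
                 "constant")
  expect_false("t1" %in% net$nodes$taxon_id)
})

test_that("edge sets ignore sample order and taxon order", {
  set.seed(23)
  m <- matrix(rpois(12 * 20, 60), nrow = 12,
              dimnames = list(paste0("t", 1:12), paste0("s", 1:20)))
  m[2, ] <- m[1, ] + rpois(20, 4)
  ft <- feature_table(m)
  key <- function(net) {
    e <- net$edges
    sort(paste(pmin(e$source, e$target), pmax(e$source, e$target), round(e$r, 10)))
  }
  n1 <- build_network(ft)
  n2 <- build_network(feature_table(m[rev(seq_len(12)), sample(20)]))
  expect_equal(key(n1), key(n2))
})

test_that("topology matches hand counts on canonical graphs", {
  tri <- net_from_adjacency(rbind(c(0, 1, 1), c(1, 0, 1), c(1, 1, 0)))
  tt <- topology(tri)
  expect_equal(tt$average_degree, 2)
  expect_equal(tt$clustering_coefficient, 1)
  expect_equal(tt$n_edges, 3L)

  star <- matrix(0, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- 1
  ts <- topology(net_from_adjacency(star))
  expect_equal(ts$clustering_coefficient, 0)
  expect_equal(ts$average_degree, 2 * 4 / 5)

  empty <- micronet:::new_network(
    tibble::tibble(taxon_id = character(0), phylum = character(0),
                   degree = integer(0)),
    tibble::tibble(source = character(0), target = character(0),
                   r = numeric(0), q = numeric(0), sign = character(0))
  )
  te <- topology(empty)
  expect_true(all(te[1, ] == 0))
})

test_that("clustering matches brute-force triangle counting on random graphs", {
  set.seed(31)
  for (i in 1:25) {
    adj <- random_adjacency(sample(4:9, 1), runif(1, 0.2, 0.8))
    net <- net_from_adjacency(adj)
    expect_equal(topology(net)$clustering_coefficient, bf_mean_clustering(adj),
                 tolerance = 1e-12)
  }
})

test_that("complexity composites are ratio means with value 1 at the top", {
  s <- function(v, e, pe, ne, ad, cc) {
    tibble::tibble(n_vertices = v, n_edges = e, n_positive_edges = pe,
                   n_negative_edges = ne, average_degree = ad,
                   clustering_coefficient = cc)
  }
  # identical networks both score exactly 1
  two <- dplyr::bind_rows(s(10, 20, 15, 5, 4, 0.5), s(10, 20, 15, 5, 4, 0.5))
  expect_equal(complexity_index(two), c(1, 1))

  # hand-computed ratio means for three networks
  three <- dplyr::bind_rows(
    s(100, 200, 150, 50, 4, 0.5),
    s(50, 100, 100, 0, 4, 0.25),
    s(100, 50, 25, 25, 1, 0.5)
  )
  expect_warning(cx <- complexity_index(three), "uniformly zero",
                 regexp = NA)  # no zero columns here
  hand <- c(
    mean(c(1, 1, 1, 1, 1, 1)),
    mean(c(0.5, 0.5, 100 / 150, 0, 1, 0.5)),
    mean(c(1, 0.25, 25 / 150, 0.5, 0.25, 1))
  )
  expect_equal(cx, hand, tolerance = 1e-12)
  # the network maximal on every index scores exactly 1
  expect_equal(cx[1], 1)

  # scale consistency: a common rescaling of any index changes nothing
  scaled <- three |> dplyr::mutate(n_edges = n_edges * 7,
                                   clustering_coefficient = clustering_coefficient * 0.1)
  expect_equal(complexity_index(scaled), cx, tolerance = 1e-12)

  expect_error(complexity_index(three[1, ]), "2 networks",
               class = "micronet_validation_error")
})

test_that("robustness is exact on degenerate graphs and matches enumeration", {
  # edgeless graph: nothing retains an edge at any removal fraction
  iso <- net_from_adjacency(matrix(0, 4, 4))
  r0 <- robustness(iso, removal_fractions = c(0, 0.5), repetitions = 10, seed = 1)
  expect_equal(r0$mean, c(0, 0))

  # complete graph K_100 at p = 0.5: every survivor keeps edges, exactly 0.5
  k100 <- net_from_adjacency(matrix(1, 100, 100) - diag(100))
  r1 <- robustness(k100, removal_fractions = 0.5, repetitions = 30, seed = 2)
  expect_equal(r1$mean, 0.5, tolerance = 1e-12)
  expect_equal(r1$sd, 0)

  # star K_{1,5} at p = 0.5: exhaustive enumeration over all C(6,3) removals
  star <- matrix(0, 6, 6)
  star[1, 2:6] <- star[2:6, 1] <- 1
  sets <- utils::combn(6, 3)
  vals <- apply(sets, 2, function(rm) {
    keep <- setdiff(1:6, rm)
    sub <- star[keep, keep, drop = FALSE]
    sum(rowSums(sub) > 0) / 6
  })
  rs <- robustness(net_from_adjacency(star), removal_fractions = 0.5,
                   repetitions = 4000, seed = 3)
  expect_lt(abs(rs$mean - mean(vals)), 0.02)

  expect_error(robustness(k100, removal_fractions = 1), "0, 1",
               class = "micronet_validation_error")
})

test_that("robustness curves are monotone non-increasing in the removal fraction", {
  set.seed(5)
  adj <- random_adjacency(40, 0.08)
  net <- net_from_adjacency(adj)
  rc <- robustness(net, removal_fractions = seq(0, 0.9, 0.1),
                   repetitions = 200, seed = 4)
  se <- rc$sd / sqrt(rc$repetitions)
  slack <- 2 * (se[-1] + se[-nrow(rc)])
  expect_true(all(diff(rc$mean) <= slack))
})

test_that("vulnerability and efficiency match brute force on small graphs", {
  # path a-b-c: removing the middle vertex disconnects everything
  path3 <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))
  net <- net_from_adjacency(path3)
  expect_equal(global_efficiency(net), bf_efficiency(path3), tolerance = 1e-12)
  expect_equal(vulnerability(net), bf_vulnerability(path3), tolerance = 1e-12)
  expect_equal(vulnerability(net), 1)

  # complete graphs lose nothing: deleting any vertex leaves K_{n-1}
  for (n in 4:5) {
    kn <- matrix(1, n, n) - diag(n)
    expect_equal(vulnerability(net_from_adjacency(kn)), 0, tolerance = 1e-12)
  }

  # hub fragility: a star is far more vulnerable than a cycle
  star <- matrix(0, 6, 6); star[1, 2:6] <- star[2:6, 1] <- 1
  cyc <- matrix(0, 6, 6)
  for (i in 1:6) { j <- i %% 6 + 1; cyc[i, j] <- cyc[j, i] <- 1 }
  expect_gt(vulnerability(net_from_adjacency(star)),
            5 * vulnerability(net_from_adjacency(cyc)))

  expect_error(vulnerability(net_from_adjacency(matrix(0, 4, 4))), "edgeless",
               class = "micronet_validation_error")
})

test_that("stability reports bundle topology, robustness and vulnerability", {
  set.seed(9)
  adj <- random_adjacency(15, 0.3)
  net <- net_from_adjacency(adj)
  rep1 <- stability_report(net, repetitions = 20, seed = 6)
  rep2 <- stability_report(net, repetitions = 20, seed = 6)
  expect_identical(tidy(rep1), tidy(rep2))
  g <- glance(rep1)
  expect_equal(g$vulnerability, bf_vulnerability(adj), tolerance = 1e-12)
  expect_true(g$robustness_50 <= 1 && g$robustness_50 >= 0)
})
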