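# Alpha diversity, Bray-Curtis beta diversity, PCoA and permutation PERMANOVA.

#' Per-sample alpha diversity
#'
#' Shannon entropy H = -sum p_i log p_i (natural log by default), Gini-Simpson
#' 1 - sum p_i^2, and the bias-corrected Chao1 richness estimate
#' S_obs + F1 (F1 - 1) / (2 (F2 + 1)) where F1/F2 are singleton/doubleton
#' counts. Optionally rarefies each sample to a common depth first (seeded,
#' without replacement).
#'
#' @param tbl feature table.
#' @param base logarithm base for Shannon (default `exp(1)`; use 2 for bits).
#' @param rarefy_depth optional depth; must not exceed any sample total.
#' @param seed seed for the rarefaction draw.
#' @return tibble: sample_id, shannon, simpson, chao1, observed.
#' @export
alpha_diversity <- function(tbl, base = exp(1), rarefy_depth = NULL, seed = 1) {
  m <- ft_counts(tbl)
  if (!is.null(rarefy_depth)) {
    totals <- colSums(m)
    short <- colnames(m)[totals < rarefy_depth]
    if (length(short) > 0) {
      abort_validation(paste0(
        "rarefy_depth ", rarefy_depth, " exceeds total of sample(s): ",
        toString(short)
      ))
    }
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    # subsample each library to the common depth without replacement
    m <- apply(m, 2, function(x) {
      drawn <- sample(rep.int(seq_along(x), x), rarefy_depth)
      tabulate(drawn, nbins = length(x))
    })
    rownames(m) <- tbl$taxon_id
  }
  comm <- t(m)  # samples x taxa, vegan orientation
  shannon <- vegan::diversity(comm, index = "shannon", base = base)
  simpson <- vegan::diversity(comm, index = "simpson")
  chao1 <- apply(comm, 1, chao1_estimate)
  tibble::tibble(
    sample_id = rownames(comm),
    shannon = unname(shannon),
    simpson = unname(simpson),
    chao1 = unname(chao1),
    observed = unname(rowSums(comm > 0))
  )
}

# bias-corrected Chao1 on one sample's counts
chao1_estimate <- function(x) {
  x <- x[x > 0]
  s_obs <- length(x)
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Bray-Curtis distance matrix
#'
#' d(x, y) = sum |x_i - y_i| / sum (x_i + y_i) on per-sample relative
#' abundances, so that library size differences do not masquerade as
#' community differences.
#' @param tbl feature table.
#' @return symmetric samples x samples matrix of class `dist`-compatible
#'   square matrix with zero diagonal.
#' @export
bray_curtis <- function(tbl) {
  rel <- t(ft_relative(tbl))
  d <- as.matrix(vegan::vegdist(rel, method = "bray"))
  d
}

#' Principal coordinates analysis
#'
#' Gower double-centering of -d^2/2 followed by eigendecomposition;
#' coordinates are eigenvectors scaled by sqrt(eigenvalue) for positive
#' eigenvalues. Negative eigenvalues are reported but carry no coordinates.
#'
#' @param dm square symmetric distance matrix with sample id dimnames.
#' @return list of class `micronet_pcoa`: `coordinates` (tibble, sample_id +
#'   Axis1..Axisk), `eigenvalues` (descending, including negatives),
#'   `proportion_explained` (over positive eigenvalues).
#' @export
pcoa <- function(dm) {
  dm <- as.matrix(dm)
  if (!isSymmetric(unname(dm), tol = 1e-8)) {
    abort_validation("distance matrix must be symmetric")
  }
  n <- nrow(dm)
  ids <- rownames(dm) %||% paste0("s", seq_len(n))
  a <- -0.5 * dm^2
  centering <- diag(n) - matrix(1 / n, n, n)
  g <- centering %*% a %*% centering
  eig <- eigen((g + t(g)) / 2, symmetric = TRUE)
  vals <- eig$values
  pos <- which(vals > max(vals[1], 0) * 1e-10 & vals > 0)
  coords <- if (length(pos) > 0) {
    sweep(eig$vectors[, pos, drop = FALSE], 2, sqrt(vals[pos]), "*")
  } else {
    matrix(0, n, 1)
  }
  colnames(coords) <- paste0("Axis", seq_len(ncol(coords)))
  prop <- if (length(pos) > 0) vals[pos] / sum(vals[vals > 0]) else 0
  structure(list(
    coordinates = tibble::as_tibble(coords) |>
      tibble::add_column(sample_id = ids, .before = 1),
    eigenvalues = vals,
    proportion_explained = prop
  ), class = "micronet_pcoa")
}

#' Permutation PERMANOVA on a distance matrix
#'
#' One-way permutational multivariate ANOVA: total sum of squares
#' SS_T = sum_{i<j} d_ij^2 / n; within-group SS_W = sum over groups of the
#' group's pairwise d^2 sum divided by its size; pseudo-F =
#' (SS_B / (k - 1)) / (SS_W / (n - k)); p by unrestricted permutation of the
#' group labels, with the (1 + count) / (1 + n_permutations) estimator.
#'
#' @param dm square symmetric distance matrix.
#' @param labels group label per sample (in dm row order).
#' @param n_permutations default 999.
#' @param seed permutation seed.
#' @return list of class `micronet_permanova`: statistic (pseudo-F), R2, p,
#'   df, n_permutations, seed.
#' @export
permanova <- function(dm, labels, n_permutations = 999, seed = 1) {
  dm <- as.matrix(dm)
  labels <- as.factor(as.character(labels))
  n <- nrow(dm)
  if (length(labels) != n) abort_validation("one label per sample required")
  sizes <- table(labels)
  if (length(sizes) < 2) abort_validation("PERMANOVA needs >= 2 groups")
  if (any(sizes < 2)) {
    abort_validation(paste0(
      "group(s) of size 1: ", toString(names(sizes)[sizes < 2])
    ))
  }
  d2 <- dm^2
  k <- length(sizes)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  f_for <- function(lab) {
    ss_within <- 0
    for (g in levels(lab)) {
      sel <- lab == g
      m <- d2[sel, sel, drop = FALSE]
      ss_within <- ss_within + sum(m[upper.tri(m)]) / sum(sel)
    }
    ss_between <- ss_total - ss_within
    (ss_between / (k - 1)) / (ss_within / (n - k))
  }
  f_obs <- f_for(labels)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  count <- 0L
  for (b in seq_len(n_permutations)) {
    if (f_for(labels[sample.int(n)]) >= f_obs) count <- count + 1L
  }
  ss_within_obs <- ss_total / (1 + f_obs * (k - 1) / (n - k))
  r2 <- 1 - ss_within_obs / ss_total
  structure(list(
    statistic = f_obs,
    R2 = r2,
    p = (1 + count) / (1 + n_permutations),
    df = c(between = k - 1L, within = n - k),
    n_permutations = n_permutations,
    seed = seed
  ), class = "micronet_permanova")
}

#' @export
print.micronet_permanova <- function(x, ...) {
  cat(sprintf(
    "PERMANOVA: pseudo-F = %.3f, R2 = %.3f, p = %.4g (%d permutations)\n",
    x$statistic, x$R2, x$p, x$n_permutations
  ))
  invisible(x)
}
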