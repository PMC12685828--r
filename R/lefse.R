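# LEfSe-style biomarker discovery: per-feature Kruskal-Wallis screen across
# classes, then a bootstrapped one-axis linear discriminant effect size on a
# log10 scale. Features are analysed at a chosen taxonomic rank on relative
# abundances scaled to one million (the LEfSe convention).

#' Aggregate a feature table to a taxonomic rank
#'
#' Counts are summed within each rank label; taxa without an annotation are
#' pooled under the `"unclassified"` sentinel. Column sums are conserved.
#'
#' @param tbl feature table.
#' @param taxonomy taxonomy tibble (see [read_taxonomy()]); must cover every
#'   taxon of `tbl`.
#' @param rank one of phylum, class, order, family, genus.
#' @return feature table whose taxon ids are rank labels.
#' @export
aggregate_to_rank <- function(tbl, taxonomy, rank) {
  if (!rank %in% TAXONOMY_RANKS) {
    abort_validation(paste0(
      "unknown rank '", rank, "'; allowed: ", toString(TAXONOMY_RANKS)
    ))
  }
  lab <- taxonomy[[rank]][match(tbl$taxon_id, taxonomy$taxon_id)]
  lab[is.na(lab) | lab == ""] <- UNCLASSIFIED
  agg <- tbl |>
    dplyr::mutate(taxon_id = lab) |>
    dplyr::group_by(.data$taxon_id) |>
    dplyr::summarise(dplyr::across(dplyr::everything(), sum), .groups = "drop")
  # single-row tables are legal here even though general validation wants >= 2
  class(agg) <- unique(c("micronet_feature_table", class(agg)))
  agg
}

#' Kruskal-Wallis screen over features
#'
#' Per feature, the Kruskal-Wallis rank-sum test (with tie correction,
#' chi-square reference) of relative abundance across classes. A feature
#' constant over all samples has nothing to rank and gets p = 1.
#'
#' @param tbl feature table (any rank).
#' @param labels class label per sample, in `ft_samples(tbl)` order.
#' @param alpha screen level (default 0.05).
#' @return tibble: feature, p.value, passed.
#' @export
kruskal_wallis_screen <- function(tbl, labels, alpha = 0.05) {
  labels <- as.factor(as.character(labels))
  sizes <- table(labels)
  if (length(sizes) < 2 || any(sizes < 2)) {
    abort_validation("screen needs >= 2 classes with >= 2 samples each")
  }
  rel <- ft_relative(tbl)
  p <- apply(rel, 1, function(x) {
    if (stats::sd(x) == 0) return(1)
    stats::kruskal.test(x, labels)$p.value
  })
  tibble::tibble(
    feature = rownames(rel),
    p.value = unname(p),
    passed = unname(p) < alpha
  )
}

#' LEfSe effect sizes via bootstrapped linear discriminant analysis
#'
#' Features are relative abundances scaled to 1e6. Per bootstrap subsample
#' (fraction `boot_fraction` of each class, with replacement), a one-axis
#' linear discriminant is fitted over the passing features; for each class
#' pair the feature's score is
#' 0.5 * (|its contribution to the discriminant-axis class-mean difference| +
#' |its raw class-mean difference|), and the feature keeps its maximum over
#' class pairs. The effect size is log10(1 + mean bootstrap score); features
#' pass at `effect >= lda_threshold` (and their screen p < alpha). The
#' enriched class is the class with the highest mean relative abundance.
#'
#' @param tbl feature table at the analysis rank.
#' @param labels class label per sample.
#' @param screen output of [kruskal_wallis_screen()]; computed if NULL.
#' @param alpha Kruskal-Wallis screen level (default 0.05).
#' @param lda_threshold effect-size threshold on the log10 scale (default 2).
#' @param n_boot bootstrap rounds (default 30).
#' @param boot_fraction per-class subsample fraction (default 2/3).
#' @param seed bootstrap seed.
#' @return tibble of class `micronet_lefse`: feature, enriched_class,
#'   p.value, effect_size, passed.
#' @export
lda_effect_size <- function(tbl, labels, screen = NULL, alpha = 0.05,
                            lda_threshold = 2, n_boot = 30,
                            boot_fraction = 2 / 3, seed = 1) {
  # classes in order of first appearance, so renaming labels permutes the
  # output but never changes the bootstrap draws
  labels <- as.character(labels)
  labels <- factor(labels, levels = unique(labels))
  if (is.null(screen)) screen <- kruskal_wallis_screen(tbl, labels, alpha)
  rel <- ft_relative(tbl) * 1e6
  feats <- screen$feature[screen$passed]
  empty <- tibble::tibble(
    feature = character(0), enriched_class = character(0),
    p.value = numeric(0), effect_size = numeric(0), passed = logical(0)
  )
  if (length(feats) == 0) {
    class(empty) <- unique(c("micronet_lefse", class(empty)))
    return(empty)
  }
  x <- t(rel[feats, , drop = FALSE])  # samples x features
  colnames(x) <- feats
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  cls <- levels(labels)
  boot_scores <- replicate(n_boot, lefse_boot_score(x, labels, boot_fraction))
  boot_scores <- matrix(boot_scores, nrow = length(feats))
  mean_score <- rowMeans(boot_scores)
  class_means <- vapply(cls, function(cl) {
    colMeans(x[labels == cl, , drop = FALSE])
  }, numeric(length(feats)))
  if (length(feats) == 1) {
    class_means <- matrix(class_means, nrow = 1,
                          dimnames = list(feats, cls))
  }
  enriched <- cls[max.col(class_means)]
  effect <- log10(1 + mean_score)
  out <- tibble::tibble(
    feature = feats,
    enriched_class = enriched,
    p.value = screen$p.value[match(feats, screen$feature)],
    effect_size = effect,
    passed = effect >= lda_threshold
  ) |>
    dplyr::filter(.data$passed) |>
    dplyr::arrange(dplyr::desc(.data$effect_size))
  class(out) <- unique(c("micronet_lefse", class(out)))
  out
}

# one bootstrap round: subsample within classes, fit one-axis LDA, return the
# per-feature score vector (max over class pairs)
lefse_boot_score <- function(x, labels, boot_fraction, max_retry = 10) {
  for (try in seq_len(max_retry)) {
    idx <- unlist(lapply(levels(labels), function(cl) {
      pool <- which(labels == cl)
      sample(pool, size = max(2, ceiling(length(pool) * boot_fraction)),
             replace = TRUE)
    }))
    lab_b <- droplevels(labels[idx])
    if (nlevels(lab_b) < 2 || any(table(lab_b) < 2)) next
    xb <- x[idx, , drop = FALSE]
    keep <- apply(xb, 2, stats::sd) > 0
    w <- rep(0, ncol(x))
    names(w) <- colnames(x)
    if (sum(keep) >= 1) {
      fit <- tryCatch(
        suppressWarnings(MASS::lda(xb[, keep, drop = FALSE], grouping = lab_b,
                                   tol = 1e-10)),
        error = function(e) NULL
      )
      if (is.null(fit)) next
      w[colnames(x)[keep]] <- fit$scaling[, 1]
    }
    cls <- levels(lab_b)
    cm <- vapply(cls, function(cl) colMeans(xb[lab_b == cl, , drop = FALSE]),
                 numeric(ncol(xb)))
    if (ncol(xb) == 1) cm <- matrix(cm, nrow = 1)
    score <- rep(0, ncol(x))
    for (i in seq_len(length(cls) - 1)) {
      for (j in (i + 1):length(cls)) {
        raw_diff <- cm[, i] - cm[, j]
        attributed <- w * raw_diff
        score <- pmax(score, 0.5 * (abs(attributed) + abs(raw_diff)))
      }
    }
    return(score)
  }
  rlang::abort("bootstrap subsampling failed to keep >= 2 samples per class",
               class = "micronet_bootstrap_error")
}

#' Full LEfSe analysis across ranks
#'
#' Runs the screen and effect-size stages at each requested rank and binds
#' the results.
#' @inheritParams lda_effect_size
#' @param taxonomy taxonomy tibble.
#' @param ranks ranks to analyse (default all five).
#' @return tibble: rank plus the columns of [lda_effect_size()].
#' @export
lefse <- function(tbl, taxonomy, labels, ranks = TAXONOMY_RANKS, alpha = 0.05,
                  lda_threshold = 2, n_boot = 30, boot_fraction = 2 / 3,
                  seed = 1) {
  purrr::map_dfr(rlang::set_names(ranks), function(rk) {
    agg <- aggregate_to_rank(tbl, taxonomy, rk)
    lda_effect_size(agg, labels, alpha = alpha, lda_threshold = lda_threshold,
                    n_boot = n_boot, boot_fraction = boot_fraction, seed = seed)
  }, .id = "rank")
}
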