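# Soil-property summary machinery: two-factor block ANOVA, marginal means,
# percent differences, and Fisher's-LSD compact letter displays over the six
# (treatment x location) groups.

check_balanced <- function(meta) {
  cells <- table(meta$location, meta$treatment, meta$block)
  if (length(unique(as.vector(cells))) != 1 || any(cells == 0)) {
    abort_validation("design must be balanced: every location x treatment x block cell filled equally")
  }
  invisible(TRUE)
}

#' Two-factor block ANOVA
#'
#' Fixed-effects ANOVA of a per-sample response on block (additive),
#' sampling location (L), cropping treatment (T) and their interaction,
#' for a complete balanced design.
#'
#' @param values numeric response, one value per metadata row.
#' @param meta metadata tibble (see [read_metadata()]).
#' @return tibble of class `micronet_anova`: term, df, sumsq, meansq,
#'   statistic (F), p.value; the residual row carries NA F/p. When the
#'   residual mean square is zero the F ratios are undefined and returned as
#'   NA with a warning.
#' @export
two_factor_block_anova <- function(values, meta) {
  if (length(values) != nrow(meta)) {
    abort_validation("one response value per sample required")
  }
  check_balanced(meta)
  dat <- data.frame(
    y = values,
    block = factor(meta$block),
    location = meta$location,
    treatment = meta$treatment
  )
  fit <- stats::aov(y ~ block + location * treatment, data = dat)
  if (stats::df.residual(fit) == 0) {
    abort_validation("zero residual degrees of freedom")
  }
  # anova.lm warns on essentially perfect fits; the constant-response case is
  # flagged explicitly below, and a genuine zero-noise effect is legitimate
  a <- suppressWarnings(stats::anova(fit))
  out <- tibble::tibble(
    term = c("block", "location", "treatment", "location:treatment", "residual"),
    df = as.integer(a$Df),
    sumsq = a$`Sum Sq`,
    meansq = a$`Mean Sq`,
    statistic = a$`F value`,
    p.value = a$`Pr(>F)`
  )
  # an (essentially) constant response has no variance to partition: the
  # residual MS is numerical fuzz and every F ratio is undefined
  if (sum(out$sumsq) <= 1e-12 * length(values) * mean(values^2) + 1e-300) {
    rlang::warn("residual mean square is zero; F ratios undefined")
    out$statistic[] <- NA_real_
    out$p.value[] <- NA_real_
  }
  class(out) <- unique(c("micronet_anova", class(out)))
  out
}

#' Marginal means over locations or treatments
#'
#' Unweighted mean of the factor level's cell means (cells are the
#' location x treatment combinations), as printed in the soil tables'
#' "Sampling location (L)" and "Intercropping systems (T)" rows.
#'
#' @inheritParams two_factor_block_anova
#' @param factor_name "location" or "treatment".
#' @return tibble: level, mean.
#' @export
marginal_means <- function(values, meta, factor_name = c("location", "treatment")) {
  factor_name <- match.arg(factor_name)
  if (length(values) != nrow(meta)) {
    abort_validation("one response value per sample required")
  }
  check_balanced(meta)
  cells <- tibble::tibble(
    y = values, location = meta$location, treatment = meta$treatment
  ) |>
    dplyr::group_by(.data$location, .data$treatment) |>
    dplyr::summarise(cell_mean = mean(.data$y), .groups = "drop")
  cells |>
    dplyr::group_by(level = .data[[factor_name]]) |>
    dplyr::summarise(mean = mean(.data$cell_mean), .groups = "drop")
}

#' Percent difference between two means
#'
#' 100 * (mean_a - mean_b) / mean_b: how much higher (positive) or lower
#' (negative) a is than the reference b.
#' @param mean_a,mean_b numeric scalars; `mean_b` must be nonzero.
#' @export
percent_difference <- function(mean_a, mean_b) {
  if (mean_b == 0) abort_validation("reference mean must be nonzero")
  100 * (mean_a - mean_b) / mean_b
}

#' Fold ratio between two values
#' @param a,b numeric scalars; `b` must be nonzero.
#' @return a / b.
#' @export
fold_ratio <- function(a, b) {
  if (b == 0) abort_validation("reference value must be nonzero")
  a / b
}

#' Fisher's LSD compact letter display over the six groups
#'
#' Pairwise t tests between group means using the pooled residual mean
#' square of the two-factor block ANOVA (unprotected LSD, no multiplicity
#' correction), followed by the insertion algorithm for compact letters:
#' groups sorted descending by mean; two groups share a letter iff their
#' pairwise p >= alpha.
#'
#' @inheritParams two_factor_block_anova
#' @param alpha significance level (default 0.05).
#' @return tibble of class `micronet_letters`: group, n, mean, sd, letters,
#'   ordered by [GROUP_LEVELS]; attribute `pairwise` holds the p matrix.
#' @export
lsd_letters <- function(values, meta, alpha = 0.05) {
  if (length(values) != nrow(meta)) {
    abort_validation("one response value per sample required")
  }
  groups <- droplevels(meta$group)
  if (nlevels(groups) < 2) abort_validation("letter display needs >= 2 groups")
  anova_tbl <- two_factor_block_anova(values, meta)
  mse <- anova_tbl$meansq[anova_tbl$term == "residual"]
  df_res <- anova_tbl$df[anova_tbl$term == "residual"]
  stats_tbl <- tibble::tibble(group = groups, y = values) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(), mean = mean(.data$y), sd = stats::sd(.data$y),
      .groups = "drop"
    )
  k <- nrow(stats_tbl)
  pmat <- matrix(1, k, k, dimnames = list(stats_tbl$group, stats_tbl$group))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      se <- sqrt(mse * (1 / stats_tbl$n[i] + 1 / stats_tbl$n[j]))
      p <- if (se == 0) {
        as.numeric(stats_tbl$mean[i] != stats_tbl$mean[j]) * 0 + (stats_tbl$mean[i] == stats_tbl$mean[j])
      } else {
        tval <- (stats_tbl$mean[i] - stats_tbl$mean[j]) / se
        2 * stats::pt(abs(tval), df_res, lower.tail = FALSE)
      }
      pmat[i, j] <- pmat[j, i] <- p
    }
  }
  nonsig <- pmat >= alpha
  letters_by_group <- insertion_letters(stats_tbl$mean, nonsig)
  out <- stats_tbl |>
    dplyr::mutate(letters = letters_by_group) |>
    dplyr::arrange(.data$group)
  attr(out, "pairwise") <- pmat
  attr(out, "alpha") <- alpha
  class(out) <- unique(c("micronet_letters", class(out)))
  out
}

# Compact letter display by the insertion algorithm. `nonsig` is a symmetric
# logical matrix: TRUE where a pair is NOT significantly different. Returns
# one letter string per group such that two groups share a letter iff nonsig.
insertion_letters <- function(means, nonsig) {
  k <- length(means)
  ord <- order(means, decreasing = TRUE)
  # letter classes as sets of group indices; start with one class per run
  classes <- list()
  for (pos in seq_len(k)) {
    g <- ord[pos]
    # extend existing compatible classes, or open a new class for g
    placed <- FALSE
    for (ci in seq_along(classes)) {
      if (all(nonsig[g, classes[[ci]]])) {
        classes[[ci]] <- c(classes[[ci]], g)
        placed <- TRUE
      }
    }
    if (!placed) {
      # new class: g plus every earlier group it is compatible with, provided
      # the set is mutually compatible (greedy, in mean order)
      members <- g
      for (h in ord[seq_len(pos - 1)]) {
        if (all(nonsig[h, members])) members <- c(members, h)
      }
      classes[[length(classes) + 1]] <- members
    }
  }
  # drop classes fully contained in another
  keep <- rep(TRUE, length(classes))
  for (i in seq_along(classes)) {
    for (j in seq_along(classes)) {
      if (i != j && keep[j] &&
          all(classes[[i]] %in% classes[[j]]) &&
          (length(classes[[i]]) < length(classes[[j]]) || i > j)) {
        keep[i] <- FALSE
      }
    }
  }
  classes <- classes[keep]
  # repair: ensure every non-significant pair shares a class
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (nonsig[i, j] &&
          !any(vapply(classes, function(cl) all(c(i, j) %in% cl), logical(1)))) {
        members <- c(i, j)
        for (h in ord) {
          if (!h %in% members && all(nonsig[h, members])) members <- c(members, h)
        }
        classes[[length(classes) + 1]] <- members
      }
    }
  }
  # letters in order of the class's best (largest) mean
  class_rank <- vapply(classes, function(cl) max(means[cl]), numeric(1))
  classes <- classes[order(class_rank, decreasing = TRUE)]
  out <- character(k)
  for (ci in seq_along(classes)) {
    out[classes[[ci]]] <- paste0(out[classes[[ci]]], letters[ci])
  }
  out
}

#' Soil-property report across all variables
#'
#' Runs the full Table-style summary for every numeric soil variable:
#' per-group mean, SD and LSD letters, the two-factor block ANOVA F table,
#' and marginal means for location and treatment.
#'
#' @param soil soil tibble (see [read_soil_table()]).
#' @param meta metadata tibble; rows are matched by sample_id.
#' @param alpha significance level for the letter display.
#' @return named list (one element per variable) of lists with `letters`,
#'   `anova`, `marginal_location`, `marginal_treatment`.
#' @export
soil_report <- function(soil, meta, alpha = 0.05) {
  soil <- soil[match(meta$sample_id, soil$sample_id), ]
  vars <- setdiff(names(soil), "sample_id")
  purrr::map(rlang::set_names(vars), function(v) {
    y <- soil[[v]]
    list(
      letters = lsd_letters(y, meta, alpha = alpha),
      anova = two_factor_block_anova(y, meta),
      marginal_location = marginal_means(y, meta, "location"),
      marginal_treatment = marginal_means(y, meta, "treatment")
    )
  })
}
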