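# Distance-based redundancy analysis: community composition (a Bray-Curtis
# distance matrix, embedded by PCoA) constrained by standardized soil
# variables, with per-variable envfit-style r-squared and permutation tests.

#' Fit a distance-based redundancy analysis
#'
#' The distance matrix is embedded by PCoA keeping positive-eigenvalue axes
#' (negative eigenvalues are dropped and their total magnitude reported);
#' the constrained step projects the sample coordinates onto the standardized
#' environmental design by least squares and eigendecomposes the fitted
#' values. Axis percentages are constrained eigenvalues over total positive
#' inertia.
#'
#' @param dm square symmetric distance matrix with sample ids.
#' @param env soil tibble; rows matched to dm by sample_id.
#' @param variables character vector of env columns to constrain on.
#' @param condition_max condition-number threshold for collinearity.
#' @return list of class `micronet_dbrda`: `eigenvalues` (constrained),
#'   `percent_explained` (of total positive inertia), `site_scores`,
#'   `biplot_scores` (correlation of each variable with the constrained
#'   axes), `total_inertia`, `constrained_inertia`, `unconstrained_inertia`,
#'   `negative_inertia`, `variables`.
#' @export
dbrda_fit <- function(dm, env, variables, condition_max = 1e8) {
  dm <- as.matrix(dm)
  ids <- rownames(dm)
  env <- env[match(ids, env$sample_id), ]
  missing_vars <- setdiff(variables, names(env))
  if (length(missing_vars) > 0) {
    abort_validation(paste0("unknown soil variable(s): ", toString(missing_vars)))
  }
  x <- as.matrix(env[variables])
  if (anyNA(x)) abort_validation("missing values in selected soil variables")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    abort_validation(paste0(
      "zero-variance soil variable(s): ", toString(variables[sds == 0])
    ))
  }
  x <- scale(x)
  kappa_x <- kappa(crossprod(x), exact = TRUE)
  if (!is.finite(kappa_x) || kappa_x > condition_max) {
    abort_validation(paste0(
      "collinear environmental variables (condition number ",
      format(kappa_x, digits = 3), "): ", toString(variables)
    ))
  }
  ord <- pcoa(dm)
  y <- as.matrix(ord$coordinates[-1])  # n x k, centered by construction
  total_inertia <- sum(ord$eigenvalues[ord$eigenvalues > 0])
  negative_inertia <- -sum(ord$eigenvalues[ord$eigenvalues < 0])
  # least-squares projection of the coordinates onto the env design
  qr_x <- qr(cbind(1, x))
  fitted <- qr.fitted(qr_x, y)
  fitted <- sweep(fitted, 2, colMeans(fitted))
  sv <- svd(fitted)
  n_axes <- min(ncol(x), sum(sv$d > max(sv$d[1], 0) * 1e-8))
  eig <- (sv$d^2)[seq_len(max(n_axes, 1))]
  site_scores <- sv$u[, seq_len(max(n_axes, 1)), drop = FALSE] %*%
    diag(sv$d[seq_len(max(n_axes, 1))], nrow = max(n_axes, 1))
  colnames(site_scores) <- paste0("dbRDA", seq_len(ncol(site_scores)))
  biplot <- stats::cor(x, site_scores)
  structure(list(
    eigenvalues = eig,
    percent_explained = 100 * eig / total_inertia,
    site_scores = tibble::as_tibble(site_scores) |>
      tibble::add_column(sample_id = ids, .before = 1),
    biplot_scores = tibble::as_tibble(biplot, rownames = "variable"),
    total_inertia = total_inertia,
    constrained_inertia = sum(eig),
    unconstrained_inertia = total_inertia - sum(eig),
    negative_inertia = negative_inertia,
    variables = variables
  ), class = "micronet_dbrda")
}

#' @export
print.micronet_dbrda <- function(x, ...) {
  cat("dbRDA on", length(x$variables), "variables;",
      "axis % of total inertia:",
      toString(sprintf("%.1f", x$percent_explained[seq_len(min(2, length(x$percent_explained)))])),
      "\n")
  invisible(x)
}

#' Per-variable explanatory degree and permutation test
#'
#' The explanatory degree is the envfit-style squared multiple correlation
#' (r^2) of the standardized variable with the first two PCoA axes of the
#' community distance matrix; the p-value permutes the variable across
#' samples. The signed correlation with axis 1 is reported alongside, since
#' a multivariate r^2 carries no sign.
#'
#' @param dm square symmetric distance matrix.
#' @param env soil tibble.
#' @param variable one env column name.
#' @param n_permutations default 999 (values below 99 warn: p resolution too
#'   coarse).
#' @param seed permutation seed.
#' @param n_axes ordination axes used (default 2).
#' @return tibble: variable, r2, axis1_correlation, p.value, n_permutations.
#' @export
variable_tests <- function(dm, env, variable, n_permutations = 999, seed = 1,
                           n_axes = 2) {
  if (n_permutations < 99) {
    rlang::warn("fewer than 99 permutations: p resolution is coarse")
  }
  dm <- as.matrix(dm)
  ids <- rownames(dm)
  env <- env[match(ids, env$sample_id), ]
  if (!variable %in% names(env)) {
    abort_validation(paste0("unknown soil variable: ", variable))
  }
  v <- env[[variable]]
  if (anyNA(v)) abort_validation("missing values in soil variable")
  if (stats::sd(v) == 0) abort_validation("zero-variance soil variable")
  ord <- pcoa(dm)
  coords <- as.matrix(ord$coordinates[-1])
  coords <- coords[, seq_len(min(n_axes, ncol(coords))), drop = FALSE]
  r2_of <- function(vv) {
    fit <- stats::lm.fit(cbind(1, coords), vv)
    1 - sum(fit$residuals^2) / sum((vv - mean(vv))^2)
  }
  r2_obs <- r2_of(v)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  count <- 0L
  for (b in seq_len(n_permutations)) {
    if (r2_of(v[sample.int(length(v))]) >= r2_obs) count <- count + 1L
  }
  tibble::tibble(
    variable = variable,
    r2 = r2_obs,
    axis1_correlation = stats::cor(v, coords[, 1]),
    p.value = (1 + count) / (1 + n_permutations),
    n_permutations = n_permutations
  )
}

#' Test several soil variables against the ordination
#' @inheritParams variable_tests
#' @param variables character vector of env columns.
#' @export
all_variable_tests <- function(dm, env, variables, n_permutations = 999,
                               seed = 1, n_axes = 2) {
  purrr::map_dfr(variables, function(v) {
    variable_tests(dm, env, v, n_permutations = n_permutations,
                   seed = seed, n_axes = n_axes)
  })
}
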