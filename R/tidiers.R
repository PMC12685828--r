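# broom-style tidy()/glance() methods for the fitted result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.micronet_permanova <- function(x, ...) {
  tibble::tibble(
    term = c("groups", "residual"),
    df = as.integer(x$df),
    statistic = c(x$statistic, NA_real_),
    R2 = c(x$R2, 1 - x$R2),
    p.value = c(x$p, NA_real_)
  )
}

#' @exportS3Method generics::glance
glance.micronet_permanova <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, R2 = x$R2, p.value = x$p,
    n_permutations = x$n_permutations, seed = x$seed
  )
}

#' @exportS3Method generics::tidy
tidy.micronet_pcoa <- function(x, ...) {
  vals <- x$eigenvalues
  pos <- vals > 0
  tibble::tibble(
    axis = seq_along(vals),
    eigenvalue = vals,
    proportion_explained = ifelse(pos, vals / sum(vals[pos]), NA_real_)
  )
}

#' @exportS3Method generics::tidy
tidy.micronet_dbrda <- function(x, ...) {
  tibble::tibble(
    axis = seq_along(x$eigenvalues),
    eigenvalue = x$eigenvalues,
    percent_explained = x$percent_explained
  )
}

#' @exportS3Method generics::glance
glance.micronet_dbrda <- function(x, ...) {
  tibble::tibble(
    total_inertia = x$total_inertia,
    constrained_inertia = x$constrained_inertia,
    unconstrained_inertia = x$unconstrained_inertia,
    negative_inertia = x$negative_inertia,
    n_variables = length(x$variables)
  )
}

#' @exportS3Method generics::tidy
tidy.micronet_stability <- function(x, ...) {
  x$robustness |>
    dplyr::mutate(vulnerability = x$vulnerability)
}

#' @exportS3Method generics::glance
glance.micronet_stability <- function(x, ...) {
  r50 <- x$robustness |>
    dplyr::filter(abs(.data$removal_fraction - 0.5) < 1e-9)
  dplyr::bind_cols(
    x$topology,
    tibble::tibble(
      robustness_50 = if (nrow(r50) > 0) r50$mean else NA_real_,
      vulnerability = x$vulnerability
    )
  )
}
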