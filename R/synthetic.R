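# Dirichlet-multinomial community simulator for the 18-sample intercropping
# design (3 cropping systems x 2 sampling locations x 3 blocks), with planted
# structure that every downstream stage can be tested against:
#   * per-group Shannon-diversity offsets (an evenness tilt of the baseline
#     composition to a target entropy),
#   * differential taxa enriched in one cropping system (latent log-fold),
#   * correlation modules realised through a Gaussian copula on the latent
#     log-abundance scale (exchangeable +/- rho within a module),
#   * soil covariates linearly tied to two latent community gradients.
# Counts are Dirichlet-multinomial: overdispersion theta > 0 mimics the
# extra-multinomial variation of real amplicon libraries.

default_modules <- function() {
  # network-density contrast mirroring the study system: bacterial modules
  # densest under soybean monoculture (S), eukaryotic under intercropping
  # (SW); sign mix gives SW bacteria many negative edges and S eukaryotes
  # almost none
  list(
    bacteria = list(
      W = list(list(size = 15, rho = 0.60, neg_frac = 0.25)),
      S = list(list(size = 30, rho = 0.75, neg_frac = 0.25)),
      SW = list(list(size = 28, rho = 0.70, neg_frac = 0.40))
    ),
    eukaryote = list(
      W = list(list(size = 8, rho = 0.55, neg_frac = 0.25)),
      S = list(list(size = 10, rho = 0.60, neg_frac = 0.05)),
      SW = list(list(size = 20, rho = 0.75, neg_frac = 0.25))
    )
  )
}

default_env_links <- function() {
  # TP/AP tied to gradient 1, pH/EOC to gradient 2; all other soil variables
  # are pure-noise controls. beta is the correlation between the variable and
  # its gradient.
  tibble::tibble(
    variable = c("TP", "AP", "pH", "EOC"),
    gradient = c(1L, 1L, 2L, 2L),
    beta = c(0.9, 0.7, 0.8, 0.6)
  )
}

# marginal (mean, sd) used to put simulated soil variables on table-like
# scales; values chosen to resemble field topsoil measurements
soil_scales <- function() {
  tibble::tribble(
    ~variable, ~mean, ~sd,
    "TP", 1.45, 0.15,
    "TN", 1.17, 0.08,
    "AP", 36.4, 4.0,
    "pH", 8.2, 0.15,
    "SOC", 8.94, 0.7,
    "Cs", 43.9, 8.0,
    "WSOC", 0.54, 0.1,
    "EOC", 1.56, 0.3,
    "SN", 24.9, 2.5,
    "urease", 68.0, 8.0,
    "sucrase", 1.35, 0.3,
    "Pm", 5.1, 1.5,
    "phosphatase", 78.7, 9.0,
    "catalase", 3.4, 0.3
  )
}

#' Specify a synthetic community design
#'
#' The defaults are "paper-scale": 18 samples (3 cropping systems x 2
#' locations x 3 blocks), 600 bacterial and 150 eukaryotic taxa at depth
#' 30,000, a planted bacterial Shannon deficit for the bulk wheat group, 40
#' bacterial (10 eukaryotic) differential taxa at a latent log-fold of ln 4,
#' per-treatment correlation modules, and four soil variables tied to two
#' latent community gradients. Recovery tests typically inflate `blocks`.
#'
#' @param n_taxa named vector, taxa per domain.
#' @param depth sequencing depth per sample (>= 1000).
#' @param blocks replicate blocks (3 gives the 18-sample design).
#' @param sigma_log sd of the baseline log-abundance profile.
#' @param theta Dirichlet-multinomial overdispersion (0 < theta; smaller is
#'   closer to multinomial; 0.02 mimics typical amplicon scatter).
#' @param sigma_noise sd of the per-sample latent noise (copula scale).
#' @param n_differential named vector, differential taxa per domain.
#' @param log_fold latent log-fold enrichment of differential taxa.
#' @param shannon_offsets list per domain of named numeric vectors: planted
#'   Shannon shift (nats) of a group's limiting composition relative to
#'   baseline. Default plants a -2.15 nat deficit on bulk wheat bacteria,
#'   which puts the intercropped group roughly 69% above it.
#' @param modules list per domain of lists per treatment (or `"all"`) of
#'   modules `list(size, rho, neg_frac)`; rho in (-1, 1).
#' @param env_links tibble (variable, gradient, beta) tying soil variables to
#'   the two latent sample gradients.
#' @param gradient_sd sd of per-taxon loadings on the latent gradients.
#' @param seed integer seed; identical seeds give identical datasets.
#' @return list of class `micronet_design`.
#' @export
community_design <- function(n_taxa = c(bacteria = 600, eukaryote = 150),
                             depth = 30000,
                             blocks = 3,
                             sigma_log = 1.5,
                             theta = 0.02,
                             sigma_noise = 1,
                             n_differential = c(bacteria = 40, eukaryote = 10),
                             log_fold = log(4),
                             shannon_offsets = list(bacteria = c(W = -2.15),
                                                    eukaryote = NULL),
                             modules = default_modules(),
                             env_links = default_env_links(),
                             gradient_sd = 0.3,
                             seed = 1) {
  if (depth < 1000) abort_validation("depth must be >= 1000")
  if (theta <= 0) abort_validation("theta must be > 0")
  if (!is.finite(log_fold)) abort_validation("log_fold must be finite")
  modules <- modules[intersect(names(modules), names(n_taxa))]
  for (dom in names(modules)) {
    sizes <- 0
    for (tr in names(modules[[dom]])) {
      for (mod in modules[[dom]][[tr]]) {
        if (abs(mod$rho) >= 1) abort_validation("module rho must lie in (-1, 1)")
        sizes <- sizes + mod$size
      }
    }
    if (sizes > n_taxa[[dom]]) {
      abort_validation(paste0(
        "module sizes (", sizes, ") exceed n_taxa for domain ", dom
      ))
    }
  }
  structure(list(
    n_taxa = n_taxa, depth = depth, blocks = blocks, sigma_log = sigma_log,
    theta = theta, sigma_noise = sigma_noise, n_differential = n_differential,
    log_fold = log_fold, shannon_offsets = shannon_offsets, modules = modules,
    env_links = env_links, gradient_sd = gradient_sd, seed = seed
  ), class = "micronet_design")
}

#' Planted Shannon shift of a group
#'
#' The analytic expected difference (nats) between a group's limiting
#' (infinite-depth, noise-free) Shannon entropy and the baseline
#' composition's, i.e. the evenness offset the generator plants. An offset of
#' ln 2 corresponds to doubling the effective richness exp(H).
#'
#' @param design a `micronet_design`.
#' @param group one of the six group labels.
#' @param domain "bacteria" or "eukaryote".
#' @export
planted_diversity_offset <- function(design, group, domain = "bacteria") {
  if (!group %in% GROUP_LEVELS) {
    abort_validation(paste0(
      "unknown group '", group, "'; allowed: ", toString(GROUP_LEVELS)
    ))
  }
  offs <- design$shannon_offsets[[domain]]
  if (is.null(offs) || !group %in% names(offs)) return(0)
  unname(offs[[group]])
}

shannon_of <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

# tilt composition p0 to entropy H(p0) + delta via the exponent family
# p(gamma) ~ p0^gamma (gamma < 1 flattens, > 1 sharpens)
tilt_to_entropy <- function(p0, delta) {
  if (delta == 0) return(p0)
  h0 <- shannon_of(p0)
  target <- min(max(h0 + delta, 0.05 * log(length(p0))), log(length(p0)) - 1e-6)
  f <- function(gamma) {
    lp <- gamma * log(p0)
    lp <- lp - max(lp)
    p <- exp(lp) / sum(exp(lp))
    shannon_of(p) - target
  }
  gamma <- stats::uniroot(f, c(1e-3, 50), tol = 1e-10)$root
  lp <- gamma * log(p0)
  lp <- lp - max(lp)
  exp(lp) / sum(exp(lp))
}

rdirichlet_multinomial <- function(depth, p, theta) {
  if (theta < 1e-8) {
    return(as.integer(stats::rmultinom(1, depth, p)))
  }
  g <- stats::rgamma(length(p), shape = p / theta)
  if (sum(g) == 0) g <- p
  as.integer(stats::rmultinom(1, depth, g / sum(g)))
}

simulate_taxonomy <- function(taxa, domain) {
  n <- length(taxa)
  phyla <- if (domain == "bacteria") {
    c("Pseudomonadota", "Actinomycetota", "Bacteroidota", "Acidobacteriota",
      "Gemmatimonadota", "Nitrospirota", "Myxococcota", "Chloroflexota",
      "Methylomirabilota", "Bacillota")
  } else {
    c("TSAR", "Cercozoa", "Apicomplexa", "Chlorophyta", "Ascomycota",
      "Basidiomycota", "Ciliophora", "Amoebozoa")
  }
  n_genus <- max(5, round(n / 4))
  genus_id <- sample.int(n_genus, n, replace = TRUE)
  family_id <- (genus_id - 1) %/% 2 + 1
  order_id <- (family_id - 1) %/% 2 + 1
  class_id <- (order_id - 1) %/% 2 + 1
  phylum_id <- (class_id - 1) %% length(phyla) + 1
  pref <- if (domain == "bacteria") "b" else "e"
  tibble::tibble(
    taxon_id = taxa,
    phylum = phyla[phylum_id],
    class = paste0(pref, "_class", class_id),
    order = paste0(pref, "_order", order_id),
    family = paste0(pref, "_family", family_id),
    genus = paste0(pref, "_genus", genus_id)
  )
}

#' Simulate a two-domain intercropping dataset with known truth
#'
#' Per sample, latent log-abundances are the group's (entropy-tilted)
#' baseline log-composition plus differential-taxon effects, gradient
#' loadings and copula-correlated noise; counts are Dirichlet-multinomial
#' draws at the design depth, so per-sample totals equal `depth` exactly.
#' Soil variables are linear maps of the two latent sample gradients plus
#' Gaussian noise, on field-realistic scales.
#'
#' @param design a `micronet_design`.
#' @return list of class `micronet_sim`: `tables` (named list of feature
#'   tables per domain), `taxonomy` (per domain), `metadata`, `soil`, and
#'   `truth` (differential taxa, modules, environment links, latent
#'   matrices, gradients).
#' @export
simulate_dataset <- function(design) {
  stopifnot(inherits(design, "micronet_design"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(design$seed)

  meta <- tidyr::expand_grid(
    treatment = factor(TREATMENT_LEVELS, levels = TREATMENT_LEVELS),
    location = factor(LOCATION_LEVELS, levels = LOCATION_LEVELS),
    block = seq_len(design$blocks)
  ) |>
    dplyr::mutate(
      group = group_label(as.character(.data$treatment), as.character(.data$location)),
      sample_id = paste0(.data$group, "_", .data$block)
    ) |>
    dplyr::select("sample_id", "treatment", "location", "block", "group")
  n_samples <- nrow(meta)

  # two latent community gradients shared by both domains and the soil table
  gradients <- matrix(stats::rnorm(2 * n_samples), ncol = 2,
                      dimnames = list(meta$sample_id, c("g1", "g2")))

  tables <- list()
  taxonomy <- list()
  truth_diff <- list()
  truth_mod <- list()
  latents <- list()
  for (dom in names(design$n_taxa)) {
    nt <- design$n_taxa[[dom]]
    taxa <- sprintf("%s_ASV%04d", substr(dom, 1, 3), seq_len(nt))
    base_log <- stats::rnorm(nt, 0, design$sigma_log)
    p0 <- exp(base_log - max(base_log))
    p0 <- p0 / sum(p0)

    # per-group limiting compositions (entropy tilt)
    offs <- design$shannon_offsets[[dom]]
    group_logp <- sapply(GROUP_LEVELS, function(g) {
      delta <- if (!is.null(offs) && g %in% names(offs)) offs[[g]] else 0
      log(tilt_to_entropy(p0, delta))
    })

    # module membership: disjoint taxon blocks, then differential taxa from
    # the remainder
    mods <- design$modules[[dom]]
    mod_rows <- list()
    used <- integer(0)
    avail <- seq_len(nt)
    if (!is.null(mods)) {
      for (tr in names(mods)) {
        for (mi in seq_along(mods[[tr]])) {
          mod <- mods[[tr]][[mi]]
          pick <- sample(setdiff(avail, used), mod$size)
          used <- c(used, pick)
          signs <- rep(1, mod$size)
          n_neg <- round(mod$neg_frac * mod$size)
          if (n_neg > 0) signs[seq_len(n_neg)] <- -1
          mod_rows[[length(mod_rows) + 1]] <- tibble::tibble(
            domain = dom, treatment = tr, module = mi,
            taxon_id = taxa[pick], rho = mod$rho, sign = signs
          )
        }
      }
    }
    mod_tbl <- dplyr::bind_rows(mod_rows)

    nd <- design$n_differential[[dom]] %||% 0
    diff_tbl <- NULL
    if (nd > 0) {
      pick <- sample(setdiff(seq_len(nt), used), nd)
      diff_tbl <- tibble::tibble(
        domain = dom,
        taxon_id = taxa[pick],
        enriched_treatment = rep(TREATMENT_LEVELS, length.out = nd),
        log_fold = design$log_fold
      )
    }

    loadings <- matrix(stats::rnorm(2 * nt, 0, design$gradient_sd), ncol = 2)

    latent <- matrix(0, nt, n_samples, dimnames = list(taxa, meta$sample_id))
    for (s in seq_len(n_samples)) {
      z <- group_logp[, as.character(meta$group[s])]
      if (!is.null(diff_tbl)) {
        enr <- diff_tbl$taxon_id[diff_tbl$enriched_treatment ==
                                   as.character(meta$treatment[s])]
        z[match(enr, taxa)] <- z[match(enr, taxa)] + design$log_fold
      }
      z <- z + loadings %*% gradients[s, ]
      # copula noise: exchangeable +/- rho within this sample's modules
      eps <- stats::rnorm(nt)
      if (nrow(mod_tbl) > 0) {
        active <- mod_tbl |>
          dplyr::filter(.data$treatment %in% c("all", as.character(meta$treatment[s])))
        for (key in unique(paste(active$treatment, active$module))) {
          rows <- active[paste(active$treatment, active$module) == key, ]
          f <- stats::rnorm(1)
          i <- match(rows$taxon_id, taxa)
          rho <- rows$rho[1]
          eps[i] <- rows$sign * sqrt(abs(rho)) * f + sqrt(1 - abs(rho)) * eps[i]
        }
      }
      latent[, s] <- z + design$sigma_noise * eps
    }

    counts <- apply(latent, 2, function(z) {
      p <- exp(z - max(z))
      rdirichlet_multinomial(design$depth, p / sum(p), design$theta)
    })
    rownames(counts) <- taxa
    colnames(counts) <- meta$sample_id
    tables[[dom]] <- feature_table(counts)
    taxonomy[[dom]] <- simulate_taxonomy(taxa, dom)
    truth_diff[[dom]] <- diff_tbl
    truth_mod[[dom]] <- mod_tbl
    latents[[dom]] <- latent
  }

  # soil variables: linked ones correlate beta with their gradient, the rest
  # are pure noise; all on table-like scales
  scales <- soil_scales()
  soil <- tibble::tibble(sample_id = meta$sample_id)
  for (i in seq_len(nrow(scales))) {
    v <- scales$variable[i]
    link <- design$env_links[design$env_links$variable == v, ]
    z <- if (nrow(link) == 1) {
      link$beta * gradients[, link$gradient] +
        sqrt(1 - link$beta^2) * stats::rnorm(n_samples)
    } else {
      stats::rnorm(n_samples)
    }
    soil[[v]] <- unname(scales$mean[i] + scales$sd[i] * z)
  }

  structure(list(
    tables = tables,
    taxonomy = taxonomy,
    metadata = meta,
    soil = soil,
    truth = list(
      differential = dplyr::bind_rows(truth_diff),
      modules = dplyr::bind_rows(truth_mod),
      env_links = design$env_links,
      gradients = gradients,
      latent = latents,
      shannon_offsets = design$shannon_offsets
    ),
    design = design
  ), class = "micronet_sim")
}

#' Write a simulated dataset to disk
#'
#' Writes per-domain feature-table and taxonomy TSVs, the metadata and soil
#' TSVs, and the planted truth as JSON.
#' @param sim a `micronet_sim`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (dom in names(sim$tables)) {
    write_feature_table(sim$tables[[dom]], file.path(dir, paste0(dom, "_counts.tsv")))
    write_taxonomy(sim$taxonomy[[dom]], file.path(dir, paste0(dom, "_taxonomy.tsv")))
  }
  write_metadata(sim$metadata, file.path(dir, "metadata.tsv"))
  write_soil_table(sim$soil, file.path(dir, "soil.tsv"))
  truth <- sim$truth
  truth$latent <- NULL
  truth$gradients <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
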