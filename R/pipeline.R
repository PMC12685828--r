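# End-to-end orchestration: ingest or simulate, then soil statistics,
# diversity + PERMANOVA, LEfSe, per-treatment co-occurrence networks with
# stability, and dbRDA, written as a consolidated JSON report plus a run
# manifest. Every stochastic stage draws its seed deterministically from the
# global seed and the stage name, so adding a stage never shifts another
# stage's random stream.

#' Deterministic per-stage seed
#'
#' Polynomial hash of the stage name folded with the global seed, kept below
#' 2^31 so it is always a valid integer seed.
#' @param global_seed integer.
#' @param stage stage name.
#' @export
stage_seed <- function(global_seed, stage) {
  m <- 2147483647
  h <- as.double(global_seed %% m)
  for (ch in utf8ToInt(stage)) {
    h <- (h * 31 + ch) %% m
  }
  as.integer(h)
}

#' Assemble a pipeline run configuration
#'
#' Either `input_dir` (a directory holding `<domain>_counts.tsv`,
#' `<domain>_taxonomy.tsv`, `metadata.tsv`, `soil.tsv` as written by
#' [write_dataset()]) or a simulation `preset` must be given.
#'
#' @param input_dir optional directory of input TSVs.
#' @param preset "paper" (the full 18-sample, 600+150-taxon design) or
#'   "test" (same design at reduced taxon counts, for fast runs).
#' @param seed global seed.
#' @param out_dir output directory.
#' @param lefse_ranks ranks analysed by LEfSe.
#' @param dbrda_variables soil variables offered to dbRDA.
#' @param n_permutations permutations for PERMANOVA and dbRDA tests.
#' @param network_reps robustness repetitions.
#' @param r_threshold,q_threshold,min_prevalence network construction
#'   parameters (see [build_network()]).
#' @return list of class `micronet_config`.
#' @export
run_config <- function(input_dir = NULL, preset = c("paper", "test"), seed = 1,
                       out_dir = tempfile("micronet_run_"),
                       lefse_ranks = c("phylum", "genus"),
                       dbrda_variables = c("TP", "AP", "pH", "EOC", "WSOC", "SN"),
                       n_permutations = 999, network_reps = 100,
                       r_threshold = 0.6, q_threshold = 0.05,
                       min_prevalence = 1 / 3) {
  preset <- match.arg(preset)
  structure(list(
    input_dir = input_dir, preset = preset, seed = seed, out_dir = out_dir,
    lefse_ranks = lefse_ranks, dbrda_variables = dbrda_variables,
    n_permutations = n_permutations, network_reps = network_reps,
    r_threshold = r_threshold, q_threshold = q_threshold,
    min_prevalence = min_prevalence
  ), class = "micronet_config")
}

load_inputs <- function(config) {
  if (!is.null(config$input_dir)) {
    dir <- config$input_dir
    count_files <- list.files(dir, pattern = "_counts\\.tsv$")
    domains <- sub("_counts\\.tsv$", "", count_files)
    tables <- lapply(rlang::set_names(domains), function(d) {
      read_feature_table(file.path(dir, paste0(d, "_counts.tsv")))
    })
    meta <- read_metadata(file.path(dir, "metadata.tsv"), tables[[1]])
    taxonomy <- lapply(rlang::set_names(domains), function(d) {
      f <- file.path(dir, paste0(d, "_taxonomy.tsv"))
      if (file.exists(f)) read_taxonomy(f) else NULL
    })
    soil <- read_soil_table(file.path(dir, "soil.tsv"), meta)
    return(list(tables = tables, taxonomy = taxonomy, metadata = meta,
                soil = soil, truth = NULL))
  }
  n_taxa <- if (config$preset == "paper") {
    c(bacteria = 600, eukaryote = 150)
  } else {
    c(bacteria = 150, eukaryote = 60)
  }
  n_diff <- if (config$preset == "paper") {
    c(bacteria = 40, eukaryote = 10)
  } else {
    c(bacteria = 15, eukaryote = 6)
  }
  design <- community_design(n_taxa = n_taxa, n_differential = n_diff,
                             seed = stage_seed(config$seed, "simulate"))
  sim <- simulate_dataset(design)
  sim[c("tables", "taxonomy", "metadata", "soil", "truth")]
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    rlang::abort(
      paste0("stage '", name, "' failed: ", conditionMessage(e)),
      class = "micronet_stage_error"
    )
  })
}

#' Run the full analysis pipeline
#'
#' Simulate or ingest, then: soil-property report, alpha diversity,
#' Bray-Curtis PCoA and PERMANOVA (six groups and cropping systems), LEfSe
#' at the configured ranks, a co-occurrence network with stability report
#' per cropping system per domain plus their complexity composites, and
#' dbRDA with per-variable tests. All stage outputs, a consolidated
#' `report.json` and a `manifest.json` are written under `config$out_dir`.
#'
#' @param config a `micronet_config`.
#' @return the report, invisibly (list, also on disk as JSON).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "micronet_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  inputs <- run_stage("ingest", load_inputs(config))
  meta <- inputs$metadata
  report <- list(schema_version = "1.0", preset = config$preset,
                 seed = config$seed)

  report$soil <- run_stage("soil_stats", {
    rep <- soil_report(inputs$soil, meta)
    lapply(rep, function(r) {
      list(
        groups = tibble::tibble(
          group = as.character(r$letters$group), n = r$letters$n,
          mean = r$letters$mean, sd = r$letters$sd, letters = r$letters$letters
        ),
        anova = as.data.frame(r$anova),
        marginal_location = r$marginal_location,
        marginal_treatment = r$marginal_treatment
      )
    })
  })

  report$diversity <- run_stage("diversity", {
    lapply(rlang::set_names(names(inputs$tables)), function(dom) {
      tbl <- inputs$tables[[dom]]
      alpha <- alpha_diversity(tbl, seed = stage_seed(config$seed, "alpha"))
      dm <- bray_curtis(tbl)
      ord <- pcoa(dm)
      pm_group <- permanova(dm, meta$group[match(rownames(dm), meta$sample_id)],
                            n_permutations = config$n_permutations,
                            seed = stage_seed(config$seed, paste0("permanova_", dom)))
      pm_treat <- permanova(dm, meta$treatment[match(rownames(dm), meta$sample_id)],
                            n_permutations = config$n_permutations,
                            seed = stage_seed(config$seed, paste0("permanova_t_", dom)))
      readr::write_tsv(alpha, file.path(config$out_dir, paste0(dom, "_alpha.tsv")),
                       progress = FALSE)
      list(
        alpha = alpha,
        pcoa_proportion = ord$proportion_explained[seq_len(min(2, length(ord$proportion_explained)))],
        permanova_group = glance(pm_group),
        permanova_treatment = glance(pm_treat)
      )
    })
  })

  report$lefse <- run_stage("lefse", {
    lapply(rlang::set_names(names(inputs$tables)), function(dom) {
      if (is.null(inputs$taxonomy[[dom]])) return(NULL)
      lefse(inputs$tables[[dom]], inputs$taxonomy[[dom]],
            meta$treatment[match(ft_samples(inputs$tables[[dom]]), meta$sample_id)],
            ranks = config$lefse_ranks,
            seed = stage_seed(config$seed, paste0("lefse_", dom)))
    })
  })

  report$networks <- run_stage("networks", {
    lapply(rlang::set_names(names(inputs$tables)), function(dom) {
      tbl <- inputs$tables[[dom]]
      per_treat <- lapply(rlang::set_names(TREATMENT_LEVELS), function(tr) {
        samples <- meta$sample_id[meta$treatment == tr]
        net <- build_network(tbl, samples = samples,
                             r_threshold = config$r_threshold,
                             q_threshold = config$q_threshold,
                             min_prevalence = config$min_prevalence,
                             taxonomy = inputs$taxonomy[[dom]])
        write_network(net, file.path(config$out_dir,
                                     paste0(dom, "_", tr, "_network.graphml")),
                      format = "graphml")
        write_network(net, file.path(config$out_dir,
                                     paste0(dom, "_", tr, "_edges.csv")),
                      format = "edgelist")
        stab <- stability_report(net, repetitions = config$network_reps,
                                 seed = stage_seed(config$seed,
                                                   paste0("robustness_", dom, "_", tr)))
        readr::write_tsv(stab$robustness,
                         file.path(config$out_dir,
                                   paste0(dom, "_", tr, "_robustness.tsv")),
                         progress = FALSE)
        stab
      })
      summaries <- dplyr::bind_rows(lapply(per_treat, function(s) s$topology))
      complexity <- complexity_index(summaries)
      list(
        topology = summaries |> tibble::add_column(
          treatment = TREATMENT_LEVELS, .before = 1
        ),
        complexity = rlang::set_names(as.list(complexity), TREATMENT_LEVELS),
        robustness_50 = lapply(per_treat, function(s) {
          r <- s$robustness |>
            dplyr::filter(abs(.data$removal_fraction - 0.5) < 1e-9)
          if (nrow(r) > 0) r$mean else NA_real_
        }),
        vulnerability = lapply(per_treat, function(s) s$vulnerability)
      )
    })
  })

  report$dbrda <- run_stage("dbrda", {
    lapply(rlang::set_names(names(inputs$tables)), function(dom) {
      dm <- bray_curtis(inputs$tables[[dom]])
      fit <- dbrda_fit(dm, inputs$soil, config$dbrda_variables)
      tests <- all_variable_tests(dm, inputs$soil, config$dbrda_variables,
                                  n_permutations = config$n_permutations,
                                  seed = stage_seed(config$seed, paste0("dbrda_", dom)))
      list(
        percent_explained = fit$percent_explained[seq_len(min(2, length(fit$percent_explained)))],
        axis12_percent = sum(fit$percent_explained[seq_len(min(2, length(fit$percent_explained)))]),
        variable_tests = tests,
        biplot = fit$biplot_scores
      )
    })
  })

  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("micronet")),
    seed = config$seed,
    stage_seeds = lapply(rlang::set_names(c(
      "simulate", "alpha", "permanova_bacteria", "lefse_bacteria",
      "robustness_bacteria_W", "dbrda_bacteria"
    )), function(s) stage_seed(config$seed, s)),
    parameters = config[setdiff(names(config), "out_dir")]
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(report)
}
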