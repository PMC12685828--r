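# Reading, validating and writing the four tabular inputs plus networks.
#
# A feature table is a tibble: first column `taxon_id`, one integer column per
# sample, taxa as rows (QIIME-style orientation; the on-disk header cell for
# the taxon column is "#ASV_ID"). Relative abundances are always derived,
# never stored.

TREATMENT_LEVELS <- c("W", "S", "SW")
LOCATION_LEVELS <- c("bulk", "rhizosphere")

#' Six-group labels in canonical display order
#'
#' Bulk-soil groups first (W, SW, S), then rhizosphere groups (RW, RSW, RS),
#' the order used by the soil-property tables so letter displays and plots are
#' comparable across outputs.
#' @export
GROUP_LEVELS <- c("W", "SW", "S", "RW", "RSW", "RS")

abort_validation <- function(msg) {
  rlang::abort(msg, class = "micronet_validation_error")
}

#' Construct and validate a feature table
#'
#' @param counts integer matrix, taxa x samples, with rownames (taxon ids) and
#'   colnames (sample ids).
#' @return A tibble with a `taxon_id` column followed by one column per
#'   sample, carrying class `micronet_feature_table`.
#' @export
feature_table <- function(counts) {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort_validation("counts must have taxon rownames and sample colnames")
  }
  dup_s <- unique(colnames(counts)[duplicated(colnames(counts))])
  if (length(dup_s) > 0) {
    abort_validation(paste0("duplicate sample id(s): ", toString(dup_s)))
  }
  tbl <- tibble::as_tibble(counts, rownames = "taxon_id")
  validate_feature_table(tbl)
}

#' @rdname feature_table
#' @param tbl a tibble shaped like the output of [feature_table()].
#' @export
validate_feature_table <- function(tbl) {
  if (!"taxon_id" %in% names(tbl)) {
    abort_validation("feature table must have a taxon_id column")
  }
  taxa <- tbl$taxon_id
  samples <- setdiff(names(tbl), "taxon_id")
  dup_t <- unique(taxa[duplicated(taxa)])
  if (length(dup_t) > 0) {
    abort_validation(paste0("duplicate taxon id(s): ", toString(dup_t)))
  }
  dup_s <- unique(samples[duplicated(samples)])
  if (length(dup_s) > 0) {
    abort_validation(paste0("duplicate sample id(s): ", toString(dup_s)))
  }
  if (length(taxa) < 2 || length(samples) < 2) {
    abort_validation("feature table needs at least 2 taxa and 2 samples")
  }
  m <- ft_counts(tbl)
  if (anyNA(m) || any(m < 0)) {
    bad <- which(is.na(m) | m < 0, arr.ind = TRUE)[1, ]
    abort_validation(paste0(
      "negative or non-numeric count at taxon '", taxa[bad[1]],
      "', sample '", samples[bad[2]], "'"
    ))
  }
  if (any(abs(m - round(m)) > 1e-8)) {
    abort_validation("counts must be integers")
  }
  empty <- samples[colSums(m) == 0]
  if (length(empty) > 0) {
    abort_validation(paste0("sample(s) with all-zero counts: ", toString(empty)))
  }
  class(tbl) <- unique(c("micronet_feature_table", class(tbl)))
  tbl
}

#' Extract the count matrix (taxa x samples) from a feature table
#' @param tbl a feature table tibble.
#' @export
ft_counts <- function(tbl) {
  m <- as.matrix(tbl[setdiff(names(tbl), "taxon_id")])
  storage.mode(m) <- "double"
  rownames(m) <- tbl$taxon_id
  m
}

#' Sample ids of a feature table
#' @inheritParams ft_counts
#' @export
ft_samples <- function(tbl) setdiff(names(tbl), "taxon_id")

#' Per-sample relative abundances of a feature table
#' @inheritParams ft_counts
#' @return taxa x samples matrix with unit column sums.
#' @export
ft_relative <- function(tbl) {
  m <- ft_counts(tbl)
  sweep(m, 2, colSums(m), "/")
}

#' Read a feature table TSV
#'
#' Expects a header row of sample identifiers with a leading taxon-id cell
#' (conventionally `#ASV_ID`) and one row per taxon. Row and column order are
#' preserved.
#' @param path path to a TSV file.
#' @return a validated feature table tibble.
#' @export
read_feature_table <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         comment = "", progress = FALSE)
  if (ncol(tbl) < 2) abort_validation("feature table needs taxon ids plus samples")
  names(tbl)[1] <- "taxon_id"
  for (s in names(tbl)[-1]) {
    v <- suppressWarnings(as.numeric(tbl[[s]]))
    if (anyNA(v)) {
      row <- which(is.na(v))[1]
      abort_validation(paste0(
        "non-numeric count at row ", row, " (taxon '", tbl$taxon_id[row],
        "'), column '", s, "'"
      ))
    }
    tbl[[s]] <- v
  }
  validate_feature_table(tbl)
}

#' Write a feature table TSV
#' @param tbl a feature table tibble.
#' @param path output path.
#' @export
write_feature_table <- function(tbl, path) {
  out <- tbl
  names(out)[1] <- "#ASV_ID"
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Derive the six-group label from treatment and location
#'
#' Bulk-soil samples carry the bare cropping-system code (W, SW, S);
#' rhizosphere samples are prefixed with R (RW, RSW, RS).
#' @param treatment character vector over {W, S, SW}.
#' @param location character vector over {bulk, rhizosphere}.
#' @return factor with levels [GROUP_LEVELS].
#' @export
group_label <- function(treatment, location) {
  lab <- ifelse(location == "rhizosphere", paste0("R", treatment), treatment)
  factor(lab, levels = GROUP_LEVELS)
}

#' Read and validate sample metadata
#'
#' @param path TSV with columns sample_id, treatment, location, block.
#' @param feature_tbl optional feature table; if given, every sample of the
#'   table must appear exactly once in the metadata.
#' @return tibble with sample_id, treatment, location, block and the derived
#'   six-level `group` factor.
#' @export
read_metadata <- function(path, feature_tbl = NULL) {
  meta <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    treatment = readr::col_character(),
    location = readr::col_character(),
    block = readr::col_integer()
  ), progress = FALSE)
  validate_metadata(meta, feature_tbl)
}

#' @rdname read_metadata
#' @param meta a metadata tibble.
#' @export
validate_metadata <- function(meta, feature_tbl = NULL) {
  need <- c("sample_id", "treatment", "location", "block")
  missing_cols <- setdiff(need, names(meta))
  if (length(missing_cols) > 0) {
    abort_validation(paste0("metadata missing column(s): ", toString(missing_cols)))
  }
  dup <- unique(meta$sample_id[duplicated(meta$sample_id)])
  if (length(dup) > 0) {
    abort_validation(paste0("duplicate sample id(s) in metadata: ", toString(dup)))
  }
  bad_t <- setdiff(unique(meta$treatment), TREATMENT_LEVELS)
  if (length(bad_t) > 0) {
    abort_validation(paste0(
      "unknown treatment '", bad_t[1], "'; allowed: ", toString(TREATMENT_LEVELS)
    ))
  }
  bad_l <- setdiff(unique(meta$location), LOCATION_LEVELS)
  if (length(bad_l) > 0) {
    abort_validation(paste0(
      "unknown location '", bad_l[1], "'; allowed: ", toString(LOCATION_LEVELS)
    ))
  }
  if (any(is.na(meta$block)) || any(meta$block < 1)) {
    abort_validation("block must be an integer >= 1")
  }
  if (!is.null(feature_tbl)) {
    absent <- setdiff(ft_samples(feature_tbl), meta$sample_id)
    if (length(absent) > 0) {
      abort_validation(paste0(
        "sample(s) in counts but absent from metadata: ", toString(absent)
      ))
    }
  }
  meta |>
    dplyr::mutate(
      treatment = factor(.data$treatment, levels = TREATMENT_LEVELS),
      location = factor(.data$location, levels = LOCATION_LEVELS),
      block = as.integer(.data$block),
      group = group_label(as.character(.data$treatment), as.character(.data$location))
    )
}

#' Write sample metadata TSV
#' @param meta metadata tibble.
#' @param path output path.
#' @export
write_metadata <- function(meta, path) {
  readr::write_tsv(
    meta |> dplyr::select("sample_id", "treatment", "location", "block"),
    path, progress = FALSE
  )
  invisible(path)
}

TAXONOMY_RANKS <- c("phylum", "class", "order", "family", "genus")
UNCLASSIFIED <- "unclassified"

#' Read a taxonomy table TSV
#'
#' @param path TSV with columns taxon_id, phylum, class, order, family, genus.
#'   Missing labels may be empty or NA; they are stored as the explicit
#'   sentinel `"unclassified"`.
#' @export
read_taxonomy <- function(path) {
  tax <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  validate_taxonomy(tax)
}

#' @rdname read_taxonomy
#' @param tax taxonomy tibble.
#' @export
validate_taxonomy <- function(tax) {
  need <- c("taxon_id", TAXONOMY_RANKS)
  missing_cols <- setdiff(need, names(tax))
  if (length(missing_cols) > 0) {
    abort_validation(paste0("taxonomy missing column(s): ", toString(missing_cols)))
  }
  dup <- unique(tax$taxon_id[duplicated(tax$taxon_id)])
  if (length(dup) > 0) {
    abort_validation(paste0("duplicate taxon id(s) in taxonomy: ", toString(dup)))
  }
  tax |>
    dplyr::mutate(dplyr::across(
      dplyr::all_of(TAXONOMY_RANKS),
      ~ dplyr::if_else(is.na(.x) | .x == "", UNCLASSIFIED, .x)
    ))
}

#' Write a taxonomy table TSV
#' @param tax taxonomy tibble.
#' @param path output path.
#' @export
write_taxonomy <- function(tax, path) {
  readr::write_tsv(tax, path, progress = FALSE)
  invisible(path)
}

SOIL_VARIABLES <- c("TP", "TN", "AP", "pH", "SOC", "Cs", "WSOC", "EOC", "SN",
                    "urease", "sucrase", "Pm", "phosphatase", "catalase")

#' Read a soil-property table TSV
#'
#' Columns: sample_id plus any subset of the named soil variables (TP total
#' phosphorus g/kg, TN total nitrogen g/kg, AP available phosphorus mg/kg, pH,
#' SOC soil organic carbon g/kg, Cs electrical conductivity uS/cm, WSOC
#' water-soluble organic carbon g/kg, EOC easily oxidizable carbon mg/g, SN
#' nitrate nitrogen mg/kg, and the enzyme activities urease, sucrase, Pm
#' microbial phosphorus, phosphatase, catalase).
#' @param path TSV path.
#' @param meta optional metadata tibble; sample ids must match if given.
#' @export
read_soil_table <- function(path, meta = NULL) {
  soil <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
  validate_soil_table(soil, meta)
}

#' @rdname read_soil_table
#' @param soil soil tibble.
#' @export
validate_soil_table <- function(soil, meta = NULL) {
  if (!"sample_id" %in% names(soil)) {
    abort_validation("soil table must have a sample_id column")
  }
  dup <- unique(soil$sample_id[duplicated(soil$sample_id)])
  if (length(dup) > 0) {
    abort_validation(paste0("duplicate sample id(s) in soil table: ", toString(dup)))
  }
  if (!is.null(meta)) {
    absent <- setdiff(meta$sample_id, soil$sample_id)
    if (length(absent) > 0) {
      abort_validation(paste0("sample(s) missing from soil table: ", toString(absent)))
    }
  }
  soil
}

#' Write a soil-property table TSV
#' @param soil soil tibble.
#' @param path output path.
#' @export
write_soil_table <- function(soil, path) {
  readr::write_tsv(soil, path, progress = FALSE)
  invisible(path)
}

#' Write a co-occurrence network to GraphML or edge-list CSV
#'
#' GraphML carries node attributes (taxon_id, phylum, degree) and edge
#' attributes (r, q, sign); the edge list is a CSV with columns
#' source,target,r,q,sign. Re-reading either reproduces the graph.
#' @param network a `micronet_network` (see [build_network()]).
#' @param path output path.
#' @param format "graphml" or "edgelist".
#' @export
write_network <- function(network, path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  stopifnot(inherits(network, "micronet_network"))
  if (format == "edgelist") {
    readr::write_csv(
      network$edges |> dplyr::select("source", "target", "r", "q", "sign"),
      path, progress = FALSE
    )
  } else {
    g <- as_igraph(network)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a network back from GraphML or edge-list CSV
#' @param path file produced by [write_network()].
#' @param format "graphml" or "edgelist".
#' @return a `micronet_network`.
#' @export
read_network <- function(path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  if (format == "edgelist") {
    edges <- readr::read_csv(path, col_types = readr::cols(
      source = readr::col_character(), target = readr::col_character(),
      r = readr::col_double(), q = readr::col_double(),
      sign = readr::col_character()
    ), progress = FALSE)
    nodes <- tibble::tibble(taxon_id = unique(c(edges$source, edges$target)))
    if (nrow(nodes) > 0) {
      deg <- table(c(edges$source, edges$target))
      nodes$phylum <- NA_character_
      nodes$degree <- as.integer(deg[nodes$taxon_id])
    } else {
      nodes$phylum <- character(0)
      nodes$degree <- integer(0)
    }
    return(new_network(nodes, edges, params = list(source = path)))
  }
  g <- igraph::read_graph(path, format = "graphml")
  va <- igraph::vertex_attr(g)
  nodes <- tibble::tibble(
    taxon_id = va$taxon_id %||% va$name %||% as.character(seq_len(igraph::vcount(g))),
    phylum = va$phylum %||% rep(NA_character_, igraph::vcount(g)),
    degree = as.integer(igraph::degree(g))
  )
  el <- igraph::as_edgelist(g, names = FALSE)
  ea <- igraph::edge_attr(g)
  edges <- tibble::tibble(
    source = nodes$taxon_id[el[, 1]],
    target = nodes$taxon_id[el[, 2]],
    r = ea$r %||% rep(NA_real_, nrow(el)),
    q = ea$q %||% rep(NA_real_, nrow(el)),
    sign = ea$sign %||% rep(NA_character_, nrow(el))
  )
  new_network(nodes, edges, params = list(source = path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
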