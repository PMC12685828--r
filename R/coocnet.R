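# Signed co-occurrence networks and their stability metrics.
#
# Edges are taxon pairs whose abundance correlation passes |r| > r_threshold
# with Benjamini-Hochberg adjusted p (q) < q_threshold across all tested
# pairs. Vertices are taxa with at least one retained edge. Stability is
# summarised three ways: a composite complexity score (mean of topological
# indices normalised to their maximum across the compared networks),
# robustness (fraction of original vertices still holding >= 1 edge after
# random removal of a fraction p of vertices), and vulnerability (maximum
# relative loss of global efficiency caused by deleting one vertex).

new_network <- function(nodes, edges, params = list()) {
  structure(
    list(nodes = nodes, edges = edges, params = params),
    class = "micronet_network"
  )
}

#' @export
print.micronet_network <- function(x, ...) {
  cat("<micronet_network> ", nrow(x$nodes), " vertices, ", nrow(x$edges),
      " edges (", sum(x$edges$sign == "positive"), " positive / ",
      sum(x$edges$sign == "negative"), " negative)\n", sep = "")
  invisible(x)
}

#' Convert a co-occurrence network to an igraph graph
#' @param network a `micronet_network`.
#' @export
as_igraph <- function(network) {
  nodes <- network$nodes
  g <- igraph::make_empty_graph(n = nrow(nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = nodes$taxon_id)
  g <- igraph::set_vertex_attr(g, "taxon_id", value = nodes$taxon_id)
  g <- igraph::set_vertex_attr(g, "phylum",
                               value = nodes$phylum %||% rep(NA_character_, nrow(nodes)))
  g <- igraph::set_vertex_attr(g, "degree", value = nodes$degree)
  if (nrow(network$edges) > 0) {
    g <- igraph::add_edges(g, rbind(network$edges$source, network$edges$target))
    g <- igraph::set_edge_attr(g, "r", value = network$edges$r)
    g <- igraph::set_edge_attr(g, "q", value = network$edges$q)
    g <- igraph::set_edge_attr(g, "sign", value = network$edges$sign)
  }
  g
}

# two-sided p for a correlation via the t approximation (the standard
# large-sample test for both Pearson and Spearman rank correlation)
cor_p_value <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  t <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * stats::pt(abs(t), df = n - 2, lower.tail = FALSE)
}

#' Build a signed co-occurrence network
#'
#' All pairwise correlations among taxa passing the prevalence filter are
#' computed on per-sample relative abundances, two-sided p-values are
#' Benjamini-Hochberg adjusted across all tested pairs, and edges are kept
#' when |r| > `r_threshold` and q < `q_threshold`. Taxa ending up with no
#' edge are dropped from the vertex set.
#'
#' @param tbl feature table.
#' @param samples optional character vector of sample ids (e.g. one cropping
#'   system); defaults to all samples.
#' @param method correlation method, "spearman" (default, rank-based and
#'   insensitive to the raw/relative/log scale choice) or "pearson".
#' @param r_threshold minimum |r| for an edge (default 0.6).
#' @param q_threshold maximum BH-adjusted p for an edge (default 0.05).
#' @param min_prevalence keep taxa present (count > 0) in at least this
#'   fraction of the selected samples (default 1/3).
#' @param taxonomy optional taxonomy tibble used to attach phylum labels.
#' @return a `micronet_network`: list with `nodes` (taxon_id, phylum, degree),
#'   `edges` (source, target, r, q, sign) and `params`.
#' @export
build_network <- function(tbl, samples = NULL, method = c("spearman", "pearson"),
                          r_threshold = 0.6, q_threshold = 0.05,
                          min_prevalence = 1 / 3, taxonomy = NULL) {
  method <- match.arg(method)
  samples <- samples %||% ft_samples(tbl)
  if (length(samples) < 4) {
    abort_validation("network construction needs at least 4 samples")
  }
  rel <- ft_relative(tbl)[, samples, drop = FALSE]
  prev <- rowMeans(rel > 0)
  keep <- prev >= min_prevalence
  constant <- apply(rel, 1, function(x) stats::sd(x) == 0)
  if (any(keep & constant)) {
    rlang::warn(paste0(
      "excluding ", sum(keep & constant), " constant taxon vector(s)"
    ))
    keep <- keep & !constant
  }
  rel <- rel[keep, , drop = FALSE]
  if (nrow(rel) < 2) {
    abort_validation("fewer than 2 taxa pass the prevalence filter")
  }
  n <- ncol(rel)
  cm <- stats::cor(t(rel), method = method)
  idx <- which(upper.tri(cm), arr.ind = TRUE)
  r <- cm[idx]
  p <- cor_p_value(r, n)
  q <- stats::p.adjust(p, method = "BH")
  pass <- !is.na(r) & !is.na(q)
  pass[pass] <- abs(r[pass]) > r_threshold & q[pass] < q_threshold
  taxa <- rownames(rel)
  r_pass <- r[pass]
  edges <- tibble::tibble(
    source = taxa[idx[pass, 1]],
    target = taxa[idx[pass, 2]],
    r = r_pass,
    q = q[pass],
    sign = ifelse(r_pass >= 0, "positive", "negative")
  )
  used <- sort(unique(c(edges$source, edges$target)))
  deg <- integer(length(used))
  names(deg) <- used
  if (nrow(edges) > 0) {
    tb <- table(c(edges$source, edges$target))
    deg[names(tb)] <- as.integer(tb)
  }
  phylum <- rep(NA_character_, length(used))
  if (!is.null(taxonomy)) {
    phylum <- taxonomy$phylum[match(used, taxonomy$taxon_id)]
  }
  nodes <- tibble::tibble(taxon_id = used, phylum = phylum, degree = unname(deg))
  new_network(nodes, edges, params = list(
    method = method, r_threshold = r_threshold, q_threshold = q_threshold,
    min_prevalence = min_prevalence, n_samples = n,
    n_taxa_tested = nrow(rel), n_pairs_tested = length(r)
  ))
}

#' Topology summary of a network
#'
#' @param network a `micronet_network`.
#' @return one-row tibble: n_vertices, n_edges, n_positive_edges,
#'   n_negative_edges, average_degree (2E/V), clustering_coefficient (mean
#'   local clustering, vertices with degree < 2 contributing 0).
#' @export
topology <- function(network) {
  v <- nrow(network$nodes)
  e <- nrow(network$edges)
  if (v == 0) {
    return(tibble::tibble(
      n_vertices = 0L, n_edges = 0L, n_positive_edges = 0L,
      n_negative_edges = 0L, average_degree = 0, clustering_coefficient = 0
    ))
  }
  g <- as_igraph(network)
  cc <- igraph::transitivity(g, type = "localaverage", isolates = "zero")
  if (is.nan(cc)) cc <- 0
  tibble::tibble(
    n_vertices = v,
    n_edges = e,
    n_positive_edges = sum(network$edges$sign == "positive"),
    n_negative_edges = sum(network$edges$sign == "negative"),
    average_degree = average_degree(v, e),
    clustering_coefficient = cc
  )
}

#' Average degree of an undirected graph
#' @param n_vertices,n_edges vertex and edge counts.
#' @return 2 * n_edges / n_vertices.
#' @export
average_degree <- function(n_vertices, n_edges) {
  if (n_vertices == 0) return(0)
  2 * n_edges / n_vertices
}

#' Composite complexity of compared networks
#'
#' Each topological index is normalised to its maximum across the compared
#' networks; a network's complexity is the mean of its normalised indices, so
#' a network maximal on every index scores exactly 1.
#'
#' @param summaries tibble of topology summaries (one row per network), e.g.
#'   `dplyr::bind_rows(lapply(nets, topology))`, optionally with a leading id
#'   column.
#' @param index_set columns to include; defaults to vertices, edges,
#'   positive/negative edges, average degree and clustering coefficient.
#' @return numeric vector of composites in [0, 1], one per row.
#' @export
complexity_index <- function(summaries,
                             index_set = c("n_vertices", "n_edges",
                                           "n_positive_edges", "n_negative_edges",
                                           "average_degree",
                                           "clustering_coefficient")) {
  if (nrow(summaries) < 2) {
    abort_validation("complexity comparison needs at least 2 networks")
  }
  m <- as.matrix(summaries[, index_set, drop = FALSE])
  if (any(m < 0)) abort_validation("complexity indices must be nonnegative")
  maxima <- apply(m, 2, max)
  zero <- maxima == 0
  if (any(zero)) {
    rlang::warn(paste0(
      "index uniformly zero across networks, excluded: ",
      toString(index_set[zero])
    ))
    m <- m[, !zero, drop = FALSE]
    maxima <- maxima[!zero]
  }
  if (ncol(m) == 0) {
    abort_validation("every index is uniformly zero across the compared networks")
  }
  rowMeans(sweep(m, 2, maxima, "/"))
}

#' Robustness under random vertex removal
#'
#' For each removal fraction p, `repetitions` times remove floor(p * V)
#' vertices uniformly at random together with their incident edges; remaining
#' connectivity is the fraction of the original V vertices that survive and
#' still hold at least one edge.
#'
#' @param network a `micronet_network` with >= 2 vertices.
#' @param removal_fractions grid of fractions in [0, 1); default includes the
#'   0.5 and 0.9 checkpoints.
#' @param repetitions random repetitions per fraction (default 100).
#' @param seed integer seed for the removal draws.
#' @return tibble: removal_fraction, mean, sd, repetitions.
#' @export
robustness <- function(network, removal_fractions = seq(0, 0.9, by = 0.1),
                       repetitions = 100, seed = 1) {
  v <- nrow(network$nodes)
  if (v < 2) abort_validation("robustness needs a network with >= 2 vertices")
  if (any(removal_fractions < 0 | removal_fractions >= 1)) {
    abort_validation("removal fractions must lie in [0, 1)")
  }
  # adjacency list on integer ids
  id <- seq_len(v)
  names(id) <- network$nodes$taxon_id
  ei <- cbind(id[network$edges$source], id[network$edges$target])
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  res <- purrr::map_dfr(removal_fractions, function(p) {
    n_remove <- floor(p * v)
    vals <- vapply(seq_len(repetitions), function(rep) {
      keep <- rep(TRUE, v)
      if (n_remove > 0) keep[sample.int(v, n_remove)] <- FALSE
      if (nrow(ei) == 0) return(0)
      live <- keep[ei[, 1]] & keep[ei[, 2]]
      sum(keep & id %in% c(ei[live, 1], ei[live, 2])) / v
    }, numeric(1))
    tibble::tibble(
      removal_fraction = p, mean = mean(vals), sd = stats::sd(vals),
      repetitions = repetitions
    )
  })
  res
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Global efficiency of a network
#'
#' Mean of 1/d(i, j) over ordered vertex pairs, with unweighted shortest
#' paths and 1/Inf = 0.
#' @param network a `micronet_network` (or igraph graph).
#' @export
global_efficiency <- function(network) {
  g <- if (inherits(network, "igraph")) network else as_igraph(network)
  v <- igraph::vcount(g)
  if (v < 2) return(0)
  d <- igraph::distances(g)
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  sum(inv) / (v * (v - 1))
}

#' Vulnerability of a network
#'
#' The maximum over vertices of the relative drop in global efficiency when
#' that single vertex is deleted: max_i (E - E_i) / E.
#' @param network a `micronet_network` with >= 3 vertices and >= 1 edge.
#' @return scalar in [0, 1].
#' @export
vulnerability <- function(network) {
  g <- if (inherits(network, "igraph")) network else as_igraph(network)
  v <- igraph::vcount(g)
  if (v < 3) abort_validation("vulnerability needs >= 3 vertices")
  e0 <- global_efficiency(g)
  if (e0 == 0) abort_validation("vulnerability undefined for an edgeless network")
  drops <- vapply(seq_len(v), function(i) {
    (e0 - global_efficiency(igraph::delete_vertices(g, i))) / e0
  }, numeric(1))
  max(drops)
}

#' Stability report for a network
#'
#' Bundles the topology summary, robustness curve and vulnerability.
#' @inheritParams robustness
#' @return list of class `micronet_stability` with elements `topology`,
#'   `robustness`, `vulnerability`, `seed`.
#' @export
stability_report <- function(network, removal_fractions = seq(0, 0.9, by = 0.1),
                             repetitions = 100, seed = 1) {
  rob <- if (nrow(network$nodes) >= 2) {
    robustness(network, removal_fractions, repetitions, seed)
  } else {
    # a (near-)empty network retains nothing at any removal fraction
    tibble::tibble(removal_fraction = removal_fractions, mean = 0, sd = 0,
                   repetitions = repetitions)
  }
  structure(list(
    topology = topology(network),
    robustness = rob,
    vulnerability = if (nrow(network$nodes) >= 3 && nrow(network$edges) >= 1) {
      vulnerability(network)
    } else NA_real_,
    repetitions = repetitions,
    seed = seed
  ), class = "micronet_stability")
}

#' @export
print.micronet_stability <- function(x, ...) {
  cat("<micronet_stability>\n")
  print(x$topology)
  r50 <- x$robustness |> dplyr::filter(abs(.data$removal_fraction - 0.5) < 1e-9)
  if (nrow(r50) > 0) {
    cat("robustness at 50% removal:", signif(r50$mean, 3), "\n")
  }
  cat("vulnerability:", signif(x$vulnerability, 3), "\n")
  invisible(x)
}
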