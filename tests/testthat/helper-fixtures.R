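# Fixtures and independent brute-force oracles used across the suite.

# small feature table from a counts matrix
make_ft <- function(m, taxa = NULL, samples = NULL) {
  taxa <- taxa %||% sprintf("t%02d", seq_len(nrow(m)))
  samples <- samples %||% sprintf("s%02d", seq_len(ncol(m)))
  dimnames(m) <- list(taxa, samples)
  feature_table(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# balanced 3x2xB metadata
make_meta <- function(blocks = 3) {
  grid <- expand.grid(
    block = seq_len(blocks),
    location = c("bulk", "rhizosphere"),
    treatment = c("W", "S", "SW"),
    stringsAsFactors = FALSE
  )
  meta <- tibble::tibble(
    sample_id = paste0(grid$treatment, "_", grid$location, "_", grid$block),
    treatment = grid$treatment,
    location = grid$location,
    block = grid$block
  )
  validate_metadata(meta)
}

# network object straight from a 0/1 adjacency matrix (for topology oracles)
net_from_adjacency <- function(adj, drop_isolated = FALSE) {
  n <- nrow(adj)
  ids <- sprintf("v%02d", seq_len(n))
  idx <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
  edges <- tibble::tibble(
    source = ids[idx[, 1]], target = ids[idx[, 2]],
    r = rep(0.9, nrow(idx)), q = rep(0.01, nrow(idx)),
    sign = rep("positive", nrow(idx))
  )
  deg <- colSums(adj)
  keep <- if (drop_isolated) deg > 0 else rep(TRUE, n)
  nodes <- tibble::tibble(
    taxon_id = ids[keep], phylum = NA_character_, degree = as.integer(deg[keep])
  )
  micronet:::new_network(nodes, edges)
}

# all simple graphs on n nodes as adjacency matrices
all_graphs <- function(n) {
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  m <- nrow(pairs)
  lapply(seq_len(2^m) - 1, function(code) {
    bits <- as.integer(intToBits(code))[seq_len(m)]
    adj <- matrix(0, n, n)
    adj[pairs] <- bits
    adj + t(adj)
  })
}

random_adjacency <- function(n, p = 0.4) {
  adj <- matrix(0, n, n)
  up <- upper.tri(adj)
  adj[up] <- stats::rbinom(sum(up), 1, p)
  adj + t(adj)
}

# --- brute-force graph oracles (adjacency-matrix based, no igraph) ---

bf_local_clustering <- function(adj) {
  n <- nrow(adj)
  vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    links <- sum(adj[nb, nb]) / 2
    links / (k * (k - 1) / 2)
  }, numeric(1))
}

bf_mean_clustering <- function(adj) mean(bf_local_clustering(adj))

# all-pairs shortest paths by repeated BFS
bf_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    frontier <- s
    depth <- 0
    while (length(frontier) > 0) {
      depth <- depth + 1
      nxt <- unique(unlist(lapply(frontier, function(v) which(adj[v, ] == 1))))
      nxt <- nxt[d[s, nxt] == Inf]
      d[s, nxt] <- depth
      frontier <- nxt
    }
  }
  d
}

bf_efficiency <- function(adj) {
  n <- nrow(adj)
  if (n < 2) return(0)
  d <- bf_distances(adj)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv[is.finite(inv)]) / (n * (n - 1))
}

bf_vulnerability <- function(adj) {
  e0 <- bf_efficiency(adj)
  drops <- vapply(seq_len(nrow(adj)), function(i) {
    (e0 - bf_efficiency(adj[-i, -i, drop = FALSE])) / e0
  }, numeric(1))
  max(drops)
}

# defining property of a compact letter display: two groups share a letter
# iff their pairwise test is non-significant
letters_satisfy_property <- function(letter_strings, nonsig) {
  k <- length(letter_strings)
  sets <- lapply(letter_strings, function(s) strsplit(s, "")[[1]])
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      share <- length(intersect(sets[[i]], sets[[j]])) > 0
      if (share != nonsig[i, j]) return(FALSE)
    }
  }
  TRUE
}
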