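#' Build a residue contact network from alpha-carbon coordinates
#'
#' Nodes are residues; an (undirected) edge joins two residues whose
#' alpha-carbon Euclidean distance d satisfies `lower_cut < d < upper_cut`
#' (strict at both ends). The default 4-8 angstrom window captures
#' noncovalent contacts while the 4 angstrom lower bound naturally excludes
#' sequence-adjacent residues (consecutive CA ~ 3.8 angstrom). Intra- and
#' inter-chain pairs obey the same rule.
#'
#' @param calphas Data frame from [calpha_coordinates()] (columns `chain`,
#'   `resno`, `x`, `y`, `z`), or a `structure_model`.
#' @param lower_cut,upper_cut Distance window in angstrom (defaults 4 and 8).
#' @return A `contact_network`: list with `nodes` (data frame `chain`,
#'   `resno`), `adjacency` (symmetric 0/1 matrix, zero diagonal), `degree`,
#'   `distances` (full CA distance matrix), `lower_cut`, `upper_cut`.
#' @export
build_network <- function(calphas, lower_cut = 4, upper_cut = 8) {
  if (inherits(calphas, "structure_model")) calphas <- calpha_coordinates(calphas)
  if (lower_cut >= upper_cut) stopf("lower_cut must be < upper_cut")
  if (nrow(calphas) < 2L) stopf("need at least 2 residues")
  xyz <- as.matrix(calphas[, c("x", "y", "z")])
  d <- as.matrix(dist(xyz))
  adj <- (d > lower_cut & d < upper_cut) * 1L
  diag(adj) <- 0L
  nodes <- data.frame(chain = calphas$chain, resno = calphas$resno,
                      stringsAsFactors = FALSE)
  lab <- paste0(nodes$chain, nodes$resno)
  dimnames(adj) <- list(lab, lab)
  structure(list(nodes = nodes, adjacency = adj, degree = rowSums(adj),
                 distances = d, lower_cut = lower_cut, upper_cut = upper_cut),
            class = "contact_network")
}

#' Contact network from a precomputed adjacency matrix
#'
#' Convenience constructor for graphs that do not come from coordinates
#' (planted-partition benchmarks, random graphs).
#'
#' @param adjacency Symmetric 0/1 matrix with zero diagonal.
#' @param nodes Optional data frame `(chain, resno)`; defaults to one chain
#'   `"A"` numbered 1..n.
#' @return A `contact_network` (with `distances = NULL`).
#' @export
network_from_adjacency <- function(adjacency, nodes = NULL) {
  adjacency <- as.matrix(adjacency)
  if (!isSymmetric(unname(adjacency))) stopf("adjacency must be symmetric")
  if (any(diag(adjacency) != 0)) stopf("adjacency must have a zero diagonal")
  n <- nrow(adjacency)
  if (is.null(nodes)) {
    nodes <- data.frame(chain = rep("A", n), resno = seq_len(n),
                        stringsAsFactors = FALSE)
  }
  stopifnot(nrow(nodes) == n)
  structure(list(nodes = nodes, adjacency = (adjacency != 0) * 1L,
                 degree = rowSums(adjacency != 0), distances = NULL,
                 lower_cut = NA_real_, upper_cut = NA_real_),
            class = "contact_network")
}

#' @export
print.contact_network <- function(x, ...) {
  cat(sprintf("<contact_network> %d residues, %d edges, chains: %s, window (%s, %s) A\n",
              nrow(x$nodes), sum(x$adjacency) / 2,
              paste(unique(x$nodes$chain), collapse = ""),
              format(x$lower_cut), format(x$upper_cut)))
  invisible(x)
}

#' Graph Laplacian L = D - A of a contact network
#'
#' @param net A `contact_network`.
#' @return Symmetric matrix with zero row sums.
#' @export
laplacian_matrix <- function(net) {
  stopifnot(inherits(net, "contact_network"))
  diag(net$degree) - net$adjacency
}

# Connected components by BFS over the adjacency matrix.
graph_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] != 0 & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Fiedler vector and algebraic connectivity
#'
#' Eigenvector of the Laplacian for the second-smallest eigenvalue, with a
#' deterministic sign convention (first nonzero entry positive). Requires a
#' connected network: for a disconnected graph the zero eigenvalue is
#' degenerate and the Fiedler partition is undefined.
#'
#' @param net A `contact_network`.
#' @return List with `fiedler` (unit-norm vector), `algebraic_connectivity`,
#'   and `values` (full ascending Laplacian spectrum).
#' @export
fiedler_vector <- function(net) {
  stopifnot(inherits(net, "contact_network"))
  comp <- graph_components(net$adjacency)
  if (max(comp) > 1L) {
    stopf("network is disconnected (%d components of sizes %s); Fiedler partition undefined",
          max(comp), paste(tabulate(comp), collapse = ", "))
  }
  L <- laplacian_matrix(net)
  eg <- eigen(L, symmetric = TRUE)
  vals <- rev(eg$values)                      # ascending
  vecs <- eg$vectors[, rev(seq_len(ncol(eg$vectors))), drop = FALSE]
  v2 <- vecs[, 2]
  nz <- which(abs(v2) > 1e-12)
  if (length(nz) && v2[nz[1]] < 0) v2 <- -v2
  v2 <- v2 / sqrt(sum(v2^2))
  list(fiedler = v2, algebraic_connectivity = max(vals[2], 0), values = pmax(vals, 0))
}

#' Spectral clustering of a contact network
#'
#' `k = 2`: sign of the Fiedler vector (entries equal to zero are assigned to
#' the positive side). `k = 3`: k-means (fixed seed, 50 restarts) on the
#' embedding given by the eigenvectors of the 2nd and 3rd smallest Laplacian
#' eigenvalues. Labels are relabelled canonically by ascending minimum node
#' index, so identical partitions always carry identical labels.
#'
#' @param net A connected `contact_network`.
#' @param k Number of clusters, 2 or 3.
#' @param seed Integer seed for the k-means restarts.
#' @return A `cluster_partition`: list with `labels`, `fiedler`,
#'   `algebraic_connectivity`, `k`, `nodes`.
#' @export
spectral_clusters <- function(net, k = 2L, seed = 1L) {
  stopifnot(inherits(net, "contact_network"))
  if (!k %in% c(2L, 3L)) stopf("k must be 2 or 3")
  fv <- fiedler_vector(net)
  if (k == 2L) {
    labels <- ifelse(fv$fiedler >= 0, 1L, 2L)
  } else {
    L <- laplacian_matrix(net)
    eg <- eigen(L, symmetric = TRUE)
    nc <- ncol(eg$vectors)
    emb <- eg$vectors[, c(nc - 1L, nc - 2L), drop = FALSE]  # 2nd, 3rd smallest
    labels <- with_seed(seed, stats::kmeans(emb, centers = 3L, nstart = 50L,
                                            iter.max = 100L)$cluster)
  }
  labels <- canonical_labels(labels)
  structure(list(labels = labels, fiedler = fv$fiedler,
                 algebraic_connectivity = fv$algebraic_connectivity,
                 k = as.integer(k), nodes = net$nodes),
            class = "cluster_partition")
}

# Relabel cluster ids so cluster 1 contains the lowest node index, etc.
canonical_labels <- function(labels) {
  first <- vapply(split(seq_along(labels), labels), min, numeric(1))
  map <- integer(length(first))
  map[order(first)] <- seq_along(first)
  unname(map[match(labels, as.integer(names(first)))])
}

#' @export
print.cluster_partition <- function(x, ...) {
  cat(sprintf("<cluster_partition> k = %d, sizes: %s, algebraic connectivity %.4f\n",
              x$k, paste(tabulate(x$labels), collapse = "/"),
              x$algebraic_connectivity))
  invisible(x)
}

#' Betweenness centrality with structural tiers
#'
#' Raw (unnormalized) shortest-path betweenness: for each node, the number of
#' shortest paths between other node pairs crossing it, with fractional
#' splitting among equal-length paths (Brandes accumulation; endpoints not
#' counted). Tier thresholds follow the raw-count convention for a trimeric
#' ~500-residue network: `high` for BC > 5000, `medium` for 4000 < BC <= 5000,
#' else `low`. Disconnected networks are allowed (per-component counts).
#'
#' @param net A `contact_network`.
#' @param high,medium Raw-count tier thresholds. Defaults 5000 and 4000.
#' @return A `centrality_result` data frame `(chain, resno, bc, tier)`.
#' @export
betweenness_centrality <- function(net, high = 5000, medium = 4000) {
  stopifnot(inherits(net, "contact_network"))
  g <- igraph::graph_from_adjacency_matrix(net$adjacency, mode = "undirected")
  bc <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  tier <- ifelse(bc > high, "high", ifelse(bc > medium, "medium", "low"))
  out <- data.frame(chain = net$nodes$chain, resno = net$nodes$resno,
                    bc = unname(bc), tier = tier, stringsAsFactors = FALSE)
  class(out) <- c("centrality_result", "data.frame")
  out
}

#' Inter-chain edge counts and dominant chain pair
#'
#' Counts, for every unordered chain pair, the contacts whose endpoints lie in
#' different chains. In a C3 trimer with symmetric interfaces all three counts
#' match; dynamic 2:1 pairing shows up as one dominant pair. The asymmetry
#' score is the maximal count over the median count.
#'
#' @param net A `contact_network` with >= 2 chains.
#' @return List with `counts` (named vector, names like `"A:B"`),
#'   `dominant_pair` (character of length 2, or `NA` if all counts are zero),
#'   `asymmetry` (max/median; `NA` when the median is zero).
#' @export
interchain_pairing <- function(net) {
  stopifnot(inherits(net, "contact_network"))
  chains <- sort(unique(net$nodes$chain))
  if (length(chains) < 2L) stopf("need at least 2 chains")
  pairs <- utils::combn(chains, 2)
  counts <- apply(pairs, 2, function(p) {
    i <- net$nodes$chain == p[1]
    j <- net$nodes$chain == p[2]
    sum(net$adjacency[i, j, drop = FALSE])
  })
  names(counts) <- apply(pairs, 2, paste, collapse = ":")
  if (all(counts == 0)) {
    return(list(counts = counts, dominant_pair = NA_character_, asymmetry = NA_real_))
  }
  best <- which.max(counts)
  med <- stats::median(counts)
  list(counts = counts,
       dominant_pair = pairs[, best],
       asymmetry = if (med > 0) unname(counts[best]) / med else NA_real_)
}

#' Per-residue cluster label table (clustering colour map)
#'
#' Flattens a partition to a `(chain, residue_number, cluster)` table in
#' sequence order, the tabular form of a clustering colour map: contiguous
#' runs of one label along the sequence identify topological units.
#'
#' @param partition A `cluster_partition`.
#' @param path Optional CSV output path.
#' @return Data frame `(chain, residue_number, cluster)`, invisibly written
#'   to `path` when given.
#' @export
cluster_color_map <- function(partition, path = NULL) {
  stopifnot(inherits(partition, "cluster_partition"))
  if (length(partition$labels) == 0L) stopf("empty partition")
  out <- data.frame(chain = partition$nodes$chain,
                    residue_number = partition$nodes$resno,
                    cluster = partition$labels, stringsAsFactors = FALSE)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
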