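# Binary-graph topological metrics.
# Shortest-path distances and degree-preserving rewiring are delegated to
# igraph; clustering/efficiency are direct matrix arithmetic on the 34-node
# adjacency matrices.

check_binary <- function(A) {
  if (!is.matrix(A) || nrow(A) != ncol(A))
    stop("adjacency must be a square matrix")
  if (!all(A %in% c(0, 1)))
    stop("adjacency must be binary (0/1)")
  if (!isTRUE(all.equal(A, t(A), check.attributes = FALSE)))
    stop("adjacency must be symmetric")
  if (any(diag(A) != 0))
    stop("adjacency must have a zero diagonal")
  invisible(A)
}

adj_distances <- function(A) {
  g <- igraph::graph_from_adjacency_matrix(A != 0, mode = "undirected")
  igraph::distances(g, algorithm = "unweighted")
}

# mean over ordered pairs of 1/d; unreachable pairs contribute 0
efficiency_from_distances <- function(d) {
  n <- nrow(d)
  if (n < 2) return(0)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Node-level topological metrics of a binary network
#'
#' Degree centrality (edge count at the node), clustering coefficient
#' (fraction of neighbour pairs that are connected, 0 when degree < 2),
#' nodal global efficiency (mean inverse shortest-path length to all other
#' nodes, unreachable pairs contributing 0), and nodal local efficiency
#' (global efficiency of the subgraph induced by the node's neighbours, 0
#' when degree < 2).
#'
#' @param A Binary symmetric adjacency matrix with zero diagonal.
#' @param metrics Which metrics to compute (all four by default); the
#'   others are omitted from the result, which saves the shortest-path and
#'   neighbour-subgraph work in bulk pipelines.
#' @return Data frame with column `node` plus one column per requested
#'   metric (`degree`, `clustering`, `eglob`, `eloc`), one row per node.
#' @export
#' @examples
#' A <- 1 - diag(5)  # complete graph K5
#' compute_node_metrics(A)
compute_node_metrics <- function(A, metrics = NODE_METRICS) {
  check_binary(A)
  metrics <- match.arg(metrics, NODE_METRICS, several.ok = TRUE)
  n <- nrow(A)
  k <- rowSums(A)
  out <- data.frame(
    node = if (is.null(rownames(A))) as.character(seq_len(n)) else
      rownames(A),
    row.names = NULL, stringsAsFactors = FALSE)
  if ("degree" %in% metrics) out$degree <- k
  if ("clustering" %in% metrics) {
    tri <- diag(A %*% A %*% A) / 2
    out$clustering <- ifelse(k >= 2, 2 * tri / (k * (k - 1)), 0)
  }
  if ("eglob" %in% metrics) {
    inv <- 1 / adj_distances(A)
    diag(inv) <- 0
    inv[!is.finite(inv)] <- 0
    out$eglob <- rowSums(inv) / (n - 1)
  }
  if ("eloc" %in% metrics) {
    out$eloc <- vapply(seq_len(n), function(i) {
      nb <- which(A[i, ] != 0)
      if (length(nb) < 2) return(0)
      efficiency_from_distances(adj_distances(A[nb, nb, drop = FALSE]))
    }, numeric(1))
  }
  out
}

#' Mean clustering and characteristic path length
#'
#' `cbar` is the mean node clustering coefficient; `L` the mean shortest
#' path length over reachable ordered pairs of distinct nodes. Networks
#' with any unreachable pair are flagged disconnected (path averages then
#' cover within-component pairs only).
#'
#' @inheritParams compute_node_metrics
#' @return List with `cbar`, `L`, `disconnected`.
#' @export
compute_global_metrics <- function(A) {
  check_binary(A)
  if (sum(A) == 0)
    stop("edgeless graph: characteristic path length is undefined")
  k <- rowSums(A)
  tri <- diag(A %*% A %*% A) / 2
  cc <- ifelse(k >= 2, 2 * tri / (k * (k - 1)), 0)
  d <- adj_distances(A)
  off <- d[row(d) != col(d)]
  reach <- is.finite(off)
  list(cbar = mean(cc),
       L = mean(off[reach]),
       disconnected = !all(reach))
}

#' Degree-preserving randomization of a binary network
#'
#' Maslov-Sneppen double-edge-swap rewiring: repeatedly picks two edges and
#' exchanges endpoints when no self-loop or multi-edge would result, so the
#' degree sequence and edge count are exactly preserved. The attempt budget
#' is `rewire_factor` times the edge count. Rigid graphs that admit no swap
#' (e.g. complete graphs) come back unchanged with attribute `"no_swap"`
#' set.
#'
#' @inheritParams compute_node_metrics
#' @param rng_seed Integer seed; output is deterministic given it.
#' @param rewire_factor Attempted swaps per edge. Default 10.
#' @return Binary adjacency matrix of the same degree sequence.
#' @export
rewire_null <- function(A, rng_seed, rewire_factor = 10L) {
  check_binary(A)
  m <- sum(A) / 2
  if (m < 2) stop("need at least 2 edges to rewire")
  g <- igraph::graph_from_adjacency_matrix(A != 0, mode = "undirected")
  set.seed(as.integer(rng_seed))
  g2 <- igraph::rewire(g, igraph::keeping_degseq(
    loops = FALSE, niter = as.integer(rewire_factor * m)))
  B <- as.matrix(igraph::as_adjacency_matrix(g2, sparse = FALSE))
  storage.mode(B) <- "double"
  dimnames(B) <- dimnames(A)
  if (all(B == A)) attr(B, "no_swap") <- TRUE
  B
}

#' Small-world metrics normalized against rewired nulls
#'
#' gamma = cbar / mean(cbar of `n_null` degree-preserving rewired nulls),
#' lambda = L / mean(null L), sigma = gamma / lambda. sigma > 1 signals
#' small-world organization (lattice-like clustering with random-graph
#' path lengths).
#'
#' @inheritParams rewire_null
#' @param n_null Number of independent rewired null networks. Default 100.
#' @return List with `cbar`, `L`, `cbar_rand`, `L_rand`, `gamma`, `lambda`,
#'   `sigma`, `disconnected`.
#' @export
compute_small_world <- function(A, n_null = 100L, rng_seed = 1L,
                                rewire_factor = 10L) {
  stopifnot(n_null >= 1L)
  obs <- compute_global_metrics(A)
  set.seed(as.integer(rng_seed))
  null_seeds <- sample.int(.Machine$integer.max - 1L, n_null)
  cb <- numeric(n_null)
  ll <- numeric(n_null)
  for (r in seq_len(n_null)) {
    B <- rewire_null(A, null_seeds[r], rewire_factor)
    gb <- compute_global_metrics(B)
    cb[r] <- gb$cbar
    ll[r] <- gb$L
  }
  cbar_rand <- mean(cb)
  l_rand <- mean(ll)
  if (cbar_rand == 0 || l_rand == 0)
    stop("degenerate null networks: zero mean clustering or path length")
  gamma <- obs$cbar / cbar_rand
  lambda <- obs$L / l_rand
  list(cbar = obs$cbar, L = obs$L, cbar_rand = cbar_rand, L_rand = l_rand,
       gamma = gamma, lambda = lambda, sigma = gamma / lambda,
       disconnected = obs$disconnected)
}

NODE_METRICS <- c("degree", "clustering", "eglob", "eloc")
HEMI_METRICS <- c("gamma", "lambda", "sigma")

#' Per-subject metric panel for a cohort
#'
#' Computes, for every subject and hemisphere, the requested node-level
#' metrics (all four by default) and optionally the hemisphere-level
#' small-world metrics, on the binarized networks.
#'
#' @param networks A [build_networks()] result.
#' @param config A [hemisnet_config()] (controls null-network count, swap
#'   budget and seed for the small-world normalization).
#' @param node_metrics Subset of `c("degree", "clustering", "eglob",
#'   "eloc")`.
#' @param hemisphere Compute gamma/lambda/sigma (the expensive null-model
#'   normalization). Default TRUE.
#' @return Object of class `hemisnet_metrics`: list with `node`, an array
#'   of dim `c(n_subjects, 34, n_metrics, 2)`; `hemi`, an array of dim
#'   `c(n_subjects, 3, 2)` or NULL; and `disconnected`, a logical
#'   `n_subjects x 2` matrix.
#' @export
compute_metric_panel <- function(networks, config = hemisnet_config(),
                                 node_metrics = NODE_METRICS,
                                 hemisphere = TRUE) {
  stopifnot(inherits(networks, "hemisnet_networks"))
  node_metrics <- match.arg(node_metrics, NODE_METRICS, several.ok = TRUE)
  subj <- dimnames(networks$binary)[[1]]
  n <- length(subj)
  node <- array(NA_real_, c(n, N_REGIONS, length(node_metrics), 2L),
                dimnames = list(subj, dk_regions(), node_metrics,
                                c("L", "R")))
  hemi <- if (hemisphere)
    array(NA_real_, c(n, 3L, 2L),
          dimnames = list(subj, HEMI_METRICS, c("L", "R"))) else NULL
  disc <- matrix(FALSE, n, 2L, dimnames = list(subj, c("L", "R")))
  seed_base <- config$rng_seed %% 1000000L
  for (h in 1:2) for (k in seq_len(n)) {
    A <- networks$binary[k, , , h]
    nm <- compute_node_metrics(A, metrics = node_metrics)
    for (mname in node_metrics) node[k, , mname, h] <- nm[[mname]]
    if (hemisphere) {
      # seed depends on the subject only, not the hemisphere, so relabeling
      # L/R permutes results exactly
      sw <- compute_small_world(A, n_null = config$n_null_networks,
                                rng_seed = seed_base + k,
                                rewire_factor = config$rewire_factor)
      hemi[k, , h] <- c(sw$gamma, sw$lambda, sw$sigma)
      disc[k, h] <- sw$disconnected
    } else {
      d <- adj_distances(A)
      disc[k, h] <- any(!is.finite(d[row(d) != col(d)]))
    }
  }
  structure(list(node = node, hemi = hemi, disconnected = disc),
            class = "hemisnet_metrics")
}

#' Long-format export of a metric panel
#'
#' @param metrics A [compute_metric_panel()] result.
#' @return Data frame with columns subject, hemisphere, metric, node
#'   (`"global"` for hemisphere-level metrics), value.
#' @export
metrics_to_table <- function(metrics) {
  stopifnot(inherits(metrics, "hemisnet_metrics"))
  dn <- dimnames(metrics$node)
  out <- expand.grid(subject = dn[[1]], node = dn[[2]], metric = dn[[3]],
                     hemisphere = dn[[4]], stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
  out$value <- as.vector(metrics$node)
  if (!is.null(metrics$hemi)) {
    dh <- dimnames(metrics$hemi)
    g <- expand.grid(subject = dh[[1]], metric = dh[[2]],
                     hemisphere = dh[[3]], stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
    g$node <- "global"
    g$value <- as.vector(metrics$hemi)
    out <- rbind(out[, c("subject", "hemisphere", "metric", "node", "value")],
                 g[, c("subject", "hemisphere", "metric", "node", "value")])
  } else {
    out <- out[, c("subject", "hemisphere", "metric", "node", "value")]
  }
  out
}
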