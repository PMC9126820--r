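# Independent brute-force oracles for graph metrics, kept deliberately
# naive (explicit loops, Floyd-Warshall) so they share no code path with
# the package implementation.

bf_distances <- function(A) {
  n <- nrow(A)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[A != 0] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

bf_efficiency <- function(A) {
  n <- nrow(A)
  if (n < 2) return(0)
  d <- bf_distances(A)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j && is.finite(d[i, j]))
    s <- s + 1 / d[i, j]
  s / (n * (n - 1))
}

bf_node_metrics <- function(A) {
  n <- nrow(A)
  d <- bf_distances(A)
  k <- cc <- eg <- el <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] != 0)
    k[i] <- length(nb)
    if (k[i] >= 2) {
      links <- 0
      for (a in nb) for (b in nb) if (a < b && A[a, b] != 0)
        links <- links + 1
      cc[i] <- 2 * links / (k[i] * (k[i] - 1))
      el[i] <- bf_efficiency(A[nb, nb, drop = FALSE])
    }
    s <- 0
    for (j in seq_len(n)) if (j != i && is.finite(d[i, j]))
      s <- s + 1 / d[i, j]
    eg[i] <- s / (n - 1)
  }
  list(degree = k, clustering = cc, eglob = eg, eloc = el)
}

bf_global_metrics <- function(A) {
  d <- bf_distances(A)
  off <- d[row(d) != col(d)]
  list(cbar = mean(bf_node_metrics(A)$clustering),
       L = mean(off[is.finite(off)]),
       disconnected = !all(is.finite(off)))
}

# seeded Erdos-Renyi-style graph on n nodes, guaranteed symmetric 0/1
random_graph <- function(n, p, seed) {
  set.seed(seed)
  A <- matrix(0, n, n)
  A[upper.tri(A)] <- as.numeric(runif(n * (n - 1) / 2) < p)
  A + t(A)
}

# ring lattice: each node tied to `k` nearest neighbours on each side
ring_lattice <- function(n, k) {
  A <- matrix(0, n, n)
  for (i in seq_len(n)) for (s in seq_len(k)) {
    j <- ((i - 1 + s) %% n) + 1
    A[i, j] <- A[j, i] <- 1
  }
  A
}

# swap the left and right hemisphere columns of a cohort
swap_hemispheres <- function(cohort) {
  th <- cohort$thickness
  l <- hemisnet::region_columns("L")
  r <- hemisnet::region_columns("R")
  sw <- th
  sw[, l] <- th[, r]
  sw[, r] <- th[, l]
  colnames(sw) <- colnames(th)
  hemisnet::hemisnet_cohort(sw, cohort$subjects)
}

# all within-dataset case/control label rearrangements of a small cohort
enumerate_label_swaps <- function(subjects) {
  ds <- split(seq_len(nrow(subjects)), subjects$dataset_id)
  per_ds <- lapply(ds, function(idx) {
    n_case <- sum(subjects$diagnosis[idx] == "case")
    utils::combn(length(idx), n_case, simplify = FALSE)
  })
  grids <- do.call(expand.grid, lapply(per_ds, seq_along))
  lapply(seq_len(nrow(grids)), function(g) {
    lab <- rep("control", nrow(subjects))
    for (d in seq_along(ds)) {
      pick <- per_ds[[d]][[grids[g, d]]]
      lab[ds[[d]][pick]] <- "case"
    }
    lab
  })
}

quiet <- function(expr) suppressMessages(expr)
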