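# Packing a list of mol_graphs into flat matrices for vectorized message
# passing. All atoms of all molecules are stacked; a sparse symmetric
# adjacency matrix performs the neighbor sum, and the per-atom sum of
# incident bond feature vectors is precomputed (it is constant across
# message-passing steps because messages concatenate neighbor states with
# bond features, and concatenation distributes over the neighbor sum).

#' Pack molecular graphs into a batch for message passing
#'
#' @param graphs list of `mol_graph` objects sharing one feature spec.
#' @return a `graph_batch`: stacked atom features `X`, sparse adjacency
#'   `A`, per-atom incident-bond feature sums `Esum`, per-atom molecule
#'   index and degree-grouped atom indices.
#' @export
graph_batch <- function(graphs) {
  stopifnot(length(graphs) >= 1)
  fa <- ncol(graphs[[1]]$atom_features)
  fb <- ncol(graphs[[1]]$bond_features)
  n_atoms <- vapply(graphs, function(g) g$n_atoms, integer(1))
  offset <- cumsum(c(0L, n_atoms[-length(n_atoms)]))
  n <- sum(n_atoms)

  X <- do.call(rbind, lapply(graphs, function(g) g$atom_features))
  mol_index <- rep(seq_along(graphs), n_atoms)
  degree <- unlist(lapply(graphs, function(g) g$degree), use.names = FALSE)

  ii <- integer(0); jj <- integer(0)
  Esum <- matrix(0, n, fb)
  for (k in seq_along(graphs)) {
    g <- graphs[[k]]
    if (nrow(g$bonds) == 0) next
    i <- g$bonds$i + offset[k]
    j <- g$bonds$j + offset[k]
    ii <- c(ii, i, j); jj <- c(jj, j, i)
    for (b in seq_len(nrow(g$bonds))) {
      Esum[i[b], ] <- Esum[i[b], ] + g$bond_features[b, ]
      Esum[j[b], ] <- Esum[j[b], ] + g$bond_features[b, ]
    }
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, n))

  deg_groups <- lapply(0:5, function(d) which(degree == d))
  structure(list(
    X = X, A = A, Esum = Esum, mol_index = mol_index,
    degree = degree, deg_groups = deg_groups,
    n_atoms = n, n_mols = length(graphs), fa = fa, fb = fb
  ), class = "graph_batch")
}

#' Restrict a batch-compatible dataset to a subset of molecules
#' @param graphs list of `mol_graph`; `idx` integer indices.
#' @return `graph_batch` over `graphs[idx]`.
#' @export
graph_batch_subset <- function(graphs, idx) graph_batch(graphs[idx])

#' Subset a packed batch by molecule index
#'
#' Cheap row/column restriction of an existing [graph_batch()] (used for
#' mini-batched gradients); equivalent to re-packing the selected graphs.
#'
#' @param batch a `graph_batch`; `mols` integer molecule indices.
#' @export
subset_batch <- function(batch, mols) {
  rows <- which(batch$mol_index %in% mols)
  remap <- match(batch$mol_index[rows], mols)   # preserves mols order ids
  degree <- batch$degree[rows]
  structure(list(
    X = batch$X[rows, , drop = FALSE],
    A = batch$A[rows, rows, drop = FALSE],
    Esum = batch$Esum[rows, , drop = FALSE],
    mol_index = remap,
    degree = degree,
    deg_groups = lapply(0:5, function(d) which(degree == d)),
    n_atoms = length(rows), n_mols = length(mols),
    fa = batch$fa, fb = batch$fb
  ), class = "graph_batch")
}
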