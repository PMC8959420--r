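# Test fixtures are built in code; nothing is read from disk.

# surface_graph from an explicit dense/sparse adjacency matrix (for path,
# lattice and random graphs that are not triangle meshes)
graph_from_adjacency <- function(A) {
  A <- methods::as(Matrix::Matrix(as.matrix(A), sparse = TRUE),
                   "CsparseMatrix")
  structure(
    list(adjacency = A, degrees = as.integer(Matrix::rowSums(A != 0)),
         n_vertices = nrow(A), vertex_map = seq_len(nrow(A))),
    class = "surface_graph")
}

path_adjacency <- function(n) {
  A <- matrix(0, n, n)
  for (i in seq_len(n - 1)) A[i, i + 1] <- A[i + 1, i] <- 1
  A
}

lattice_adjacency <- function(nr, nc) {
  n <- nr * nc
  A <- matrix(0, n, n)
  id <- function(r, c) (c - 1) * nr + r
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (r < nr) A[id(r, c), id(r + 1, c)] <- A[id(r + 1, c), id(r, c)] <- 1
    if (c < nc) A[id(r, c), id(r, c + 1)] <- A[id(r, c + 1), id(r, c)] <- 1
  }
  A
}

# random connected graph: a random spanning tree plus extra random edges
random_connected_adjacency <- function(n, extra = n) {
  A <- matrix(0, n, n)
  for (v in 2:n) {
    u <- sample(v - 1, 1)
    A[u, v] <- A[v, u] <- 1
  }
  for (e in seq_len(extra)) {
    ij <- sample(n, 2)
    A[ij[1], ij[2]] <- A[ij[2], ij[1]] <- 1
  }
  A
}

# scaled Laplacian with exact lambda_max from a dense eigendecomposition
exact_scaled_laplacian <- function(A) {
  lap <- normalized_laplacian(graph_from_adjacency(A))
  ev <- eigen(as.matrix(lap$L), symmetric = TRUE, only.values = TRUE)$values
  scale_laplacian(lap, lambda_max = max(ev))
}

# mesh with given triangles; coordinates are irrelevant to the graph
mesh_from_triangles <- function(triangles, n = max(triangles), mask = NULL) {
  surface_mesh(matrix(seq_len(3 * n), n, 3), triangles, mask)
}

random_label_map <- function(n, K) {
  lab <- c(seq_len(K), sample.int(K, n - K, replace = TRUE))
  parcellation_map(sample(lab), n_parcels = K)
}

# small cohort shared by several slow tests (built once per test run)
.tiny_cohort_cache <- new.env()
tiny_cohort <- function() {
  if (!exists("coh", .tiny_cohort_cache)) {
    cfg <- cohort_config(mesh_subdivisions = 2L, n_parcels = 8L,
                         n_subjects = 6L, n_timepoints = 120L, seed = 99L)
    assign("coh", make_cohort(cfg), .tiny_cohort_cache)
  }
  get("coh", .tiny_cohort_cache)
}
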