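#' Construct a cortical surface mesh
#'
#' A `surface_mesh` is a closed (or open) triangle mesh together with a
#' per-vertex cortex mask. Vertices with `cortex_mask = FALSE` (e.g. the
#' medial wall) carry no graph edges and are dropped from all downstream
#' computations.
#'
#' @param coordinates numeric matrix, one row per vertex, 3 columns (mm).
#' @param triangles integer matrix, one row per triangle, 3 columns of
#'   1-based vertex indices.
#' @param cortex_mask logical vector, one entry per vertex; `TRUE` marks a
#'   cortical vertex. Defaults to all `TRUE`.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(coordinates, triangles, cortex_mask = NULL) {
  coordinates <- as.matrix(coordinates)
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  n <- nrow(coordinates)
  if (ncol(coordinates) != 3L) stop_input("coordinates must have 3 columns")
  if (ncol(triangles) != 3L) stop_input("triangles must have 3 columns")
  if (is.null(cortex_mask)) cortex_mask <- rep(TRUE, n)
  cortex_mask <- as.logical(cortex_mask)
  if (length(cortex_mask) != n) {
    stop_input("cortex_mask length (%d) != vertex count (%d)",
               length(cortex_mask), n)
  }
  if (nrow(triangles) > 0L) {
    if (min(triangles) < 1L || max(triangles) > n) {
      stop_input("triangle references vertex outside 1..%d", n)
    }
    degen <- triangles[, 1] == triangles[, 2] |
      triangles[, 1] == triangles[, 3] | triangles[, 2] == triangles[, 3]
    if (any(degen)) {
      stop_input("%d degenerate triangle(s) with repeated vertex index",
                 sum(degen))
    }
  }
  structure(
    list(coordinates = coordinates, triangles = triangles,
         cortex_mask = cortex_mask),
    class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices (%d cortical), %d triangles\n",
              nrow(x$coordinates), sum(x$cortex_mask), nrow(x$triangles)))
  invisible(x)
}

#' Build the vertex-level brain graph from a triangle mesh
#'
#' Two cortical vertices are adjacent iff they co-occur in at least one
#' triangle of the mesh. Non-cortical vertices (medial wall) are removed and
#' the remaining vertices compacted; the mapping back to original mesh
#' indices is kept in `vertex_map`.
#'
#' @param mesh a [surface_mesh()].
#' @return An object of class `surface_graph` with fields `adjacency`
#'   (sparse symmetric binary `dgCMatrix` over cortical vertices), `degrees`,
#'   `n_vertices`, and `vertex_map` (original 1-based index of each graph
#'   vertex).
#' @export
build_adjacency <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (!any(mesh$cortex_mask)) stop_input("cortex_mask excludes every vertex")
  tri <- mesh$triangles
  keep <- mesh$cortex_mask
  # edges of the 1-skeleton: the three sides of every triangle
  i <- c(tri[, 1], tri[, 2], tri[, 1])
  j <- c(tri[, 2], tri[, 3], tri[, 3])
  ok <- keep[i] & keep[j]
  if (!any(ok)) stop_input("no triangle edge joins two cortical vertices")
  i <- i[ok]; j <- j[ok]
  vertex_map <- which(keep)
  new_index <- integer(length(keep))
  new_index[vertex_map] <- seq_along(vertex_map)
  n <- length(vertex_map)
  A <- Matrix::sparseMatrix(
    i = new_index[c(i, j)], j = new_index[c(j, i)], x = 1,
    dims = c(n, n), use.last.ij = FALSE)
  A <- methods::as(A, "CsparseMatrix")
  A@x[] <- 1  # collapse duplicate triangle contributions to binary
  A <- Matrix::drop0(A)
  structure(
    list(adjacency = A,
         degrees = as.integer(Matrix::rowSums(A)),
         n_vertices = n,
         vertex_map = vertex_map),
    class = "surface_graph")
}

#' @export
print.surface_graph <- function(x, ...) {
  cat(sprintf("<surface_graph> %d vertices, %d edges\n",
              x$n_vertices, sum(x$degrees) / 2))
  invisible(x)
}

#' Symmetric normalized graph Laplacian
#'
#' Computes `L = I - D^{-1/2} A D^{-1/2}` over the cortical vertices. The
#' spectrum of `L` lies in `[0, 2]`; the constant (degree-weighted) vector is
#' a 0-eigenvector on each connected component.
#'
#' @param graph a [build_adjacency()] result.
#' @return An object of class `graph_laplacian` with fields `L` (sparse
#'   symmetric), `lambda_max` (`NA` until estimated), `L_scaled` (`NULL`
#'   until [scale_laplacian()] is called) and `n_vertices`.
#' @export
normalized_laplacian <- function(graph) {
  stopifnot(inherits(graph, "surface_graph"))
  iso <- which(graph$degrees == 0L)
  if (length(iso) > 0L) {
    stop_input("isolated vertex (degree 0) at graph index %s; prune or reconnect",
               paste(utils::head(iso, 5L), collapse = ", "))
  }
  dinv <- 1 / sqrt(graph$degrees)
  A <- graph$adjacency
  n <- graph$n_vertices
  L <- Matrix::Diagonal(n) - Matrix::Diagonal(n, dinv) %*% A %*% Matrix::Diagonal(n, dinv)
  L <- methods::as(Matrix::forceSymmetric(L), "CsparseMatrix")
  structure(
    list(L = L, lambda_max = NA_real_, L_scaled = NULL, n_vertices = n),
    class = "graph_laplacian")
}

#' Estimate the largest Laplacian eigenvalue by power iteration
#'
#' Deterministic for a fixed `seed` (the seed only sets the start vector).
#' The normalized Laplacian is positive semidefinite, so its largest-magnitude
#' eigenvalue is the largest eigenvalue and plain power iteration converges to
#' it; the estimate is the Rayleigh quotient at the current iterate.
#'
#' @param laplacian a [normalized_laplacian()] result.
#' @param tol relative tolerance on successive eigenvalue estimates.
#' @param max_iter iteration cap.
#' @param seed integer seed for the random start vector.
#' @return The `graph_laplacian` with `lambda_max` filled in.
#' @export
estimate_lambda_max <- function(laplacian, tol = 1e-6, max_iter = 10000L,
                                seed = 1L) {
  stopifnot(inherits(laplacian, "graph_laplacian"))
  L <- laplacian$L
  n <- nrow(L)
  if (n == 1L) {
    laplacian$lambda_max <- as.numeric(L[1, 1])
    return(laplacian)
  }
  v <- with_seed(seed, rnorm(n))
  v <- v / sqrt(sum(v^2))
  mu_old <- NA_real_
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    w <- as.numeric(L %*% v)
    nw <- sqrt(sum(w^2))
    if (nw < .Machine$double.eps) {
      # L annihilates the iterate: (numerically) zero operator
      laplacian$lambda_max <- 0
      return(laplacian)
    }
    v <- w / nw
    mu <- as.numeric(crossprod(v, as.numeric(L %*% v)))
    if (!is.na(mu_old) && abs(mu - mu_old) <= tol * max(abs(mu), 1)) {
      converged <- TRUE
      mu_old <- mu
      break
    }
    mu_old <- mu
  }
  if (!converged) {
    stop_input(paste0("power iteration did not converge in %d iterations; ",
                      "consider the lambda_max = 2 upper bound"), max_iter)
  }
  laplacian$lambda_max <- as.numeric(mu_old)
  laplacian
}

#' Scale a Laplacian for Chebyshev filtering
#'
#' Forms the rescaled operator used by Chebyshev polynomial graph filters,
#' `L_scaled = 2 L / lambda_max - I`, whose spectrum lies in `[-1, 1]` when
#' `lambda_max` is exact.
#'
#' @param laplacian a `graph_laplacian`; if `lambda_max` is `NA` and
#'   `lambda_max` argument is `NULL`, [estimate_lambda_max()] is called with
#'   defaults.
#' @param lambda_max optional override; pass `2` to use the universal upper
#'   bound for normalized Laplacians instead of the estimate.
#' @return The `graph_laplacian` with `L_scaled` and `lambda_max` set.
#' @export
scale_laplacian <- function(laplacian, lambda_max = NULL) {
  stopifnot(inherits(laplacian, "graph_laplacian"))
  if (!is.null(lambda_max)) laplacian$lambda_max <- as.numeric(lambda_max)
  if (is.na(laplacian$lambda_max)) {
    laplacian <- estimate_lambda_max(laplacian)
  }
  if (laplacian$lambda_max <= 0) {
    stop_input("lambda_max must be positive (got %g)", laplacian$lambda_max)
  }
  n <- nrow(laplacian$L)
  laplacian$L_scaled <- methods::as(
    2 / laplacian$lambda_max * laplacian$L - Matrix::Diagonal(n),
    "CsparseMatrix")
  laplacian
}

#' Export a sparse matrix as coordinate triplets
#'
#' Writes `i j x` triplets (1-based) to a whitespace-delimited text file,
#' for debugging and interchange.
#'
#' @param m a sparse (or dense) matrix.
#' @param path output file path.
#' @export
write_sparse_triplets <- function(m, path) {
  tm <- methods::as(methods::as(m, "CsparseMatrix"), "TsparseMatrix")
  df <- data.frame(i = tm@i + 1L, j = tm@j + 1L, x = tm@x)
  utils::write.table(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
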