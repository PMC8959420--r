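#' Chebyshev polynomial basis of graph signals
#'
#' Computes the list `[T_0(L~) X, ..., T_K(L~) X]` by the three-term
#' recurrence `T_0 = X`, `T_1 = L~ X`, `T_k = 2 L~ T_{k-1} - T_{k-2}`,
#' using only sparse matrix-vector products with the rescaled Laplacian.
#'
#' @param L_scaled sparse rescaled Laplacian `2L/lambda_max - I` (N x N).
#' @param X dense signal matrix (N x F).
#' @param order Chebyshev truncation order K (>= 0).
#' @return A list of `order + 1` dense N x F matrices.
#' @export
chebyshev_basis <- function(L_scaled, X, order) {
  X <- as.matrix(X)
  if (nrow(L_scaled) != ncol(L_scaled)) stop_input("L_scaled must be square")
  if (nrow(X) != nrow(L_scaled)) {
    stop_input("X has %d rows but L_scaled is %d x %d",
               nrow(X), nrow(L_scaled), ncol(L_scaled))
  }
  order <- as.integer(order)
  if (order < 0L) stop_input("order must be >= 0")
  out <- vector("list", order + 1L)
  out[[1L]] <- X
  if (order >= 1L) out[[2L]] <- as.matrix(L_scaled %*% X)
  if (order >= 2L) {
    for (k in 3L:(order + 1L)) {
      out[[k]] <- as.matrix(2 * (L_scaled %*% out[[k - 1L]])) - out[[k - 2L]]
    }
  }
  out
}

#' Chebyshev graph-convolution layer parameters
#'
#' @param theta list of `order + 1` coefficient matrices, each
#'   `n_in x n_out` (element k weights the order-(k-1) Chebyshev term).
#' @param bias optional numeric vector of length `n_out`.
#' @return An object of class `cheb_layer`.
#' @export
cheb_layer <- function(theta, bias = NULL) {
  stopifnot(is.list(theta), length(theta) >= 1L)
  d <- dim(theta[[1L]])
  for (th in theta) {
    if (!all(dim(th) == d)) stop_input("theta matrices must share dimensions")
    if (any(!is.finite(th))) stop_input("non-finite theta entries")
  }
  if (!is.null(bias) && length(bias) != d[2L]) {
    stop_input("bias length %d != output features %d", length(bias), d[2L])
  }
  structure(
    list(theta = theta, bias = bias,
         order = length(theta) - 1L, n_in = d[1L], n_out = d[2L]),
    class = "cheb_layer")
}

#' Apply a Chebyshev graph convolution
#'
#' `Y = sum_k T_k(L~) X theta_k (+ bias)`: a K-hop-localized spectral filter
#' evaluated without any eigendecomposition.
#'
#' @param layer a [cheb_layer()].
#' @param L_scaled rescaled Laplacian.
#' @param X input signals (N x n_in), or a precomputed [chebyshev_basis()]
#'   list (recycled across training epochs since the layer-1 basis is fixed).
#' @return Dense N x n_out matrix.
#' @export
cheb_conv <- function(layer, L_scaled, X) {
  stopifnot(inherits(layer, "cheb_layer"))
  basis <- if (is.list(X)) X else chebyshev_basis(L_scaled, X, layer$order)
  if (length(basis) != layer$order + 1L) {
    stop_input("basis has %d terms but layer order is %d",
               length(basis), layer$order)
  }
  if (ncol(basis[[1L]]) != layer$n_in) {
    stop_input("input has %d features but theta expects %d",
               ncol(basis[[1L]]), layer$n_in)
  }
  Y <- basis[[1L]] %*% layer$theta[[1L]]
  if (layer$order >= 1L) {
    for (k in 2L:(layer$order + 1L)) {
      Y <- Y + basis[[k]] %*% layer$theta[[k]]
    }
  }
  if (!is.null(layer$bias)) Y <- sweep(Y, 2L, layer$bias, "+")
  Y
}

# fan-in-scaled normal init, one matrix per Chebyshev order
init_cheb_layer <- function(n_in, n_out, order, bias = TRUE) {
  scale <- sqrt(2 / (n_in * (order + 1L)))
  theta <- lapply(seq_len(order + 1L), function(k) {
    matrix(rnorm(n_in * n_out, sd = scale), n_in, n_out)
  })
  cheb_layer(theta, bias = if (bias) numeric(n_out) else NULL)
}

#' Construct a two-layer masked graph-convolution parcellation model
#'
#' The default architecture maps F connectivity-fingerprint features to 64
#' hidden channels and then to `n_classes` output channels (parcels plus a
#' background class), each layer a third-order Chebyshev convolution; class
#' probabilities come from a row-wise softmax.
#'
#' @param n_features input feature count F (atlas parcels).
#' @param n_classes output classes (conventionally `n_parcels + 1`, class 1
#'   being background/unassigned label 0).
#' @param n_hidden hidden channels (default 64).
#' @param order Chebyshev order per layer (default 3).
#' @param dropout_rate probability of zeroing hidden features during
#'   training (default 0.5); inference is always dropout-free.
#' @param bias include per-channel bias terms.
#' @param seed integer seed for parameter initialization.
#' @return An object of class `msgcn_model`.
#' @export
msgcn_model <- function(n_features, n_classes, n_hidden = 64L, order = 3L,
                        dropout_rate = 0.5, bias = TRUE, seed = 1L) {
  if (dropout_rate < 0 || dropout_rate >= 1) stop_input("dropout_rate must be in [0, 1)")
  layers <- with_seed(seed, list(
    init_cheb_layer(n_features, n_hidden, order, bias),
    init_cheb_layer(n_hidden, n_classes, order, bias)
  ))
  structure(
    list(layers = layers, n_features = as.integer(n_features),
         n_hidden = as.integer(n_hidden), n_classes = as.integer(n_classes),
         order = as.integer(order), dropout_rate = dropout_rate,
         bias = bias, seed = as.integer(seed)),
    class = "msgcn_model")
}

#' @export
print.msgcn_model <- function(x, ...) {
  cat(sprintf(
    "<msgcn_model> %d -> %d -> %d channels, order-%d Chebyshev, dropout %.2f\n",
    x$n_features, x$n_hidden, x$n_classes, x$order, x$dropout_rate))
  invisible(x)
}

relu <- function(x) (x + abs(x)) / 2

row_softmax <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Forward pass of the parcellation model
#'
#' layer-1 convolution, rectifier, (training only) dropout, layer-2
#' convolution, row-wise softmax. With `training = FALSE` the output is
#' deterministic for fixed inputs.
#'
#' @param model an [msgcn_model()].
#' @param L_scaled rescaled Laplacian.
#' @param signals a `graph_signals` object, a plain N x F matrix, or a
#'   precomputed layer-1 [chebyshev_basis()] list.
#' @param training apply dropout to hidden features.
#' @param seed dropout seed (training only).
#' @param keep_cache keep intermediates needed for backpropagation.
#' @return An object of class `probability_map`: list with `P`
#'   (N x n_classes row-stochastic matrix) and, if requested, `cache`.
#' @export
msgcn_forward <- function(model, L_scaled, signals, training = FALSE,
                          seed = 1L, keep_cache = FALSE) {
  stopifnot(inherits(model, "msgcn_model"))
  X <- if (inherits(signals, "graph_signals")) signals$X else signals
  basis1 <- if (is.list(X) && !is.data.frame(X)) X else
    chebyshev_basis(L_scaled, X, model$order)
  if (ncol(basis1[[1L]]) != model$n_features) {
    stop_input("signals have %d features but model expects %d",
               ncol(basis1[[1L]]), model$n_features)
  }
  Z1 <- cheb_conv(model$layers[[1L]], L_scaled, basis1)
  if (any(!is.finite(Z1))) stop_input("non-finite values after layer 1")
  H <- relu(Z1)
  drop_mask <- NULL
  if (training && model$dropout_rate > 0) {
    keep_p <- 1 - model$dropout_rate
    drop_mask <- with_seed(seed, matrix(
      (runif(length(H)) < keep_p) / keep_p, nrow(H), ncol(H)))
    H <- H * drop_mask
  }
  basis2 <- chebyshev_basis(L_scaled, H, model$order)
  Z2 <- cheb_conv(model$layers[[2L]], L_scaled, basis2)
  if (any(!is.finite(Z2))) stop_input("non-finite values after layer 2")
  P <- row_softmax(Z2)
  out <- structure(list(P = P), class = "probability_map")
  if (keep_cache) {
    out$cache <- list(basis1 = basis1, Z1 = Z1, H = H, basis2 = basis2,
                      drop_mask = drop_mask)
  }
  out
}

# hop distances from vertex v on the graph implied by the off-diagonal
# sparsity pattern of an operator (breadth-first search); Inf = unreachable
hop_distances <- function(L_scaled, v) {
  # general storage: symmetric classes keep only one triangle of the pattern
  A <- methods::as(methods::as(L_scaled, "generalMatrix"), "CsparseMatrix")
  n <- nrow(A)
  tA <- methods::as(A, "TsparseMatrix")
  off <- tA@i != tA@j
  nbr <- split(tA@i[off] + 1L, tA@j[off] + 1L)
  dist <- rep(Inf, n)
  dist[v] <- 0
  frontier <- v
  d <- 0
  while (length(frontier) > 0L) {
    d <- d + 1
    nxt <- unique(unlist(nbr[as.character(frontier)], use.names = FALSE))
    nxt <- nxt[is.infinite(dist[nxt])]
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

#' Check the K-hop locality of the stacked network
#'
#' A stack of Chebyshev layers of orders `K_1, ..., K_m` has a receptive
#' field of `sum(K_l)` hops. This verifies empirically that perturbing input
#' features strictly farther than `hops` from vertex `v` leaves the output
#' row of `v` unchanged (within 1e-10).
#'
#' @param model an [msgcn_model()].
#' @param L_scaled rescaled Laplacian (its sparsity pattern defines hops).
#' @param v vertex to probe (1-based).
#' @param hops claimed receptive-field radius.
#' @param X input signals; random if omitted.
#' @param seed seed for the random input/perturbation.
#' @return `TRUE` if the output at `v` is invariant to all perturbations
#'   beyond `hops`, else `FALSE`.
#' @export
receptive_field_check <- function(model, L_scaled, v, hops, X = NULL,
                                  seed = 1L) {
  n <- nrow(L_scaled)
  if (is.null(X)) {
    X <- with_seed(seed, matrix(rnorm(n * model$n_features), n))
  }
  base <- msgcn_forward(model, L_scaled, X, training = FALSE)$P[v, ]
  dist <- hop_distances(L_scaled, v)
  far <- which(dist > hops)
  if (length(far) == 0L) return(TRUE)
  Xp <- X
  Xp[far, ] <- Xp[far, ] + with_seed(seed + 1L, matrix(
    rnorm(length(far) * ncol(X)), length(far)))
  pert <- msgcn_forward(model, L_scaled, Xp, training = FALSE)$P[v, ]
  max(abs(pert - base)) <= 1e-10
}
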