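#' Dice similarity kernel between two lists of parcellation maps
#'
#' Entry (i, j) is the mean per-parcel Dice between `maps_a[[i]]` and
#' `maps_b[[j]]`; with `maps_b = maps_a` the matrix is symmetric with unit
#' diagonal. Used as the Gram matrix for topography-based behavior
#' prediction ("similar parcellation topography, similar behavior").
#'
#' @param maps_a,maps_b lists of [parcellation_map()] objects sharing one
#'   vertex order (`maps_b` defaults to `maps_a`).
#' @return Numeric `length(maps_a) x length(maps_b)` matrix.
#' @export
dice_kernel_matrix <- function(maps_a, maps_b = maps_a) {
  if (length(maps_a) == 0L || length(maps_b) == 0L) stop_input("empty map list")
  same <- identical(maps_a, maps_b)
  K <- matrix(NA_real_, length(maps_a), length(maps_b))
  for (i in seq_along(maps_a)) {
    jstart <- if (same) i else 1L
    for (j in jstart:length(maps_b)) {
      K[i, j] <- dice_parcellation(maps_a[[i]], maps_b[[j]])$mean
      if (same) K[j, i] <- K[i, j]
    }
  }
  K
}

#' Fit a Dice-kernel ridge model for behavior prediction
#'
#' Kernel ridge regression in dual form: with Gram matrix
#' `G = dice_kernel_matrix(train, train)` and mean-centered scores `y`,
#' the dual weights solve `(G + lambda I) a = y`, and a new subject's score
#' is `sum_i Dice(l, l_i) a_i + mean(y)`. The regularization strength is
#' chosen from `lambda_grid` by k-fold cross-validation (seeded fold split,
#' minimizing mean squared error). Because the empirical Dice kernel is not
#' guaranteed positive semidefinite, a small diagonal jitter (up to
#' `max_jitter`) is added when needed.
#'
#' @param train_maps list of training [parcellation_map()]s.
#' @param train_scores numeric behavioral scores, one per training map.
#' @param lambda_grid candidate l2 penalties (default: 15 log-spaced points
#'   in 1e-4..1e3).
#' @param n_folds cross-validation folds (default 5).
#' @param seed seed for the fold split.
#' @param max_jitter cap on the PSD-repair diagonal jitter.
#' @return An object of class `behavior_model`.
#' @export
fit_behavior <- function(train_maps, train_scores,
                         lambda_grid = 10^seq(-4, 3, length.out = 15),
                         n_folds = 5L, seed = 1L, max_jitter = 1e-6) {
  n <- length(train_maps)
  if (n < n_folds) stop_input("need at least n_folds = %d subjects, got %d", n_folds, n)
  train_scores <- as.numeric(train_scores)
  if (length(train_scores) != n || anyNA(train_scores)) {
    stop_input("scores must be finite, one per training map")
  }
  G <- dice_kernel_matrix(train_maps)
  ev_min <- min(eigen(G, symmetric = TRUE, only.values = TRUE)$values)
  jitter <- 0
  if (ev_min < 0) {
    jitter <- min(-ev_min * 1.01, max_jitter)
    if (-ev_min > max_jitter) {
      stop_input(paste0("Dice Gram matrix is indefinite (min eigenvalue %.2e) ",
                        "beyond the jitter cap %.0e; increase max_jitter"),
                 ev_min, max_jitter)
    }
    G <- G + diag(jitter, n)
  }
  center <- mean(train_scores)
  yc <- train_scores - center
  folds <- with_seed(derive_seed(seed, "folds"),
                     sample(rep_len(seq_len(n_folds), n)))
  cv_mse <- vapply(lambda_grid, function(lam) {
    se <- 0
    for (f in seq_len(n_folds)) {
      tr <- folds != f
      a <- solve(G[tr, tr, drop = FALSE] + diag(lam, sum(tr)), yc[tr])
      pred <- as.numeric(G[!tr, tr, drop = FALSE] %*% a)
      se <- se + sum((yc[!tr] - pred)^2)
    }
    se / n
  }, numeric(1))
  best_lambda <- lambda_grid[which.min(cv_mse)]
  dual <- as.numeric(solve(G + diag(best_lambda, n), yc))
  structure(
    list(training_parcellations = train_maps, training_scores = train_scores,
         ridge_lambda = best_lambda, dual_weights = dual,
         score_centering = center, cv_mse = stats::setNames(cv_mse, lambda_grid),
         folds = folds, jitter = jitter),
    class = "behavior_model")
}

#' @export
print.behavior_model <- function(x, ...) {
  cat(sprintf("<behavior_model> %d training subjects, lambda = %.4g\n",
              length(x$dual_weights), x$ridge_lambda))
  invisible(x)
}

#' Predict behavioral scores for new subjects
#'
#' `score = sum_i Dice(l, l_i) a_i + centering offset`, where `a` are the
#' fitted dual weights. With `baseline = TRUE`, the raw normalized
#' Dice-weighted average of training scores is returned instead (weights
#' summing to one, no fitted coefficients).
#'
#' @param model a [fit_behavior()] result.
#' @param test_maps list of [parcellation_map()]s.
#' @param baseline use the unfitted Dice-weighted-average rule.
#' @return Numeric vector of predicted scores.
#' @export
predict_behavior <- function(model, test_maps, baseline = FALSE) {
  stopifnot(inherits(model, "behavior_model"))
  Kx <- dice_kernel_matrix(test_maps, model$training_parcellations)
  if (baseline) {
    W <- Kx / rowSums(Kx)
    return(as.numeric(W %*% model$training_scores))
  }
  as.numeric(Kx %*% model$dual_weights) + model$score_centering
}

#' Correlate predicted and observed behavioral scores
#'
#' @param predicted,observed numeric vectors of equal length.
#' @return List with Pearson `r` and two-sided `p`.
#' @export
evaluate_prediction <- function(predicted, observed) {
  if (length(predicted) != length(observed)) stop_input("length mismatch")
  ct <- cor.test(as.numeric(predicted), as.numeric(observed))
  list(r = unname(ct$estimate), p = ct$p.value)
}
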