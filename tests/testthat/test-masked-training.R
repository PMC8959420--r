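# brute-force oracle for the three confidence-mask rules
mask_oracle <- function(session_labels, atlas_labels) {
  n <- length(atlas_labels)
  vapply(seq_len(n), function(v) {
    labs <- vapply(session_labels, `[`, integer(1), v)
    assigned <- all(labs > 0L)                       # (1) initial label exists
    matches <- all(labs == atlas_labels[v])          # (2) equals group atlas
    consistent <- length(unique(labs)) == 1L         # (3) agrees across sessions
    as.integer(assigned && matches && consistent && atlas_labels[v] > 0L)
  }, integer(1))
}

test_that("confidence mask applies the three agreement rules", {
  atlas <- group_atlas(c(1, 1, 2, 2, 3, 3))
  # one session identical to the atlas: full coverage
  m1 <- build_confidence_mask(parcellation_map(atlas$labels), atlas)
  expect_equal(m1$weights, rep(1L, 6))
  expect_equal(m1$coverage, 1)
  # two sessions disagreeing at vertex 3: weight 0 there
  s1 <- parcellation_map(c(1, 1, 2, 2, 3, 3))
  s2 <- parcellation_map(c(1, 1, 3, 2, 3, 3))
  m2 <- build_confidence_mask(list(s1, s2), atlas)
  expect_equal(m2$weights[3], 0L)
  expect_equal(m2$weights[-3], rep(1L, 5))
  expect_error(build_confidence_mask(list(), atlas), "at least one")
})

test_that("6-vertex hand-built fixture matches the brute-force oracle", {
  atlas_labels <- c(1L, 1L, 2L, 2L, 3L, 0L)
  atlas <- group_atlas(atlas_labels)
  # sessions exercise all rules: v1 ok; v2 off-atlas; v3 inconsistent;
  # v4 unassigned in one session; v5 ok; v6 non-cortical
  s1 <- c(1L, 2L, 2L, 0L, 3L, 1L)
  s2 <- c(1L, 2L, 3L, 2L, 3L, 1L)
  maps <- list(parcellation_map(s1, 3), parcellation_map(s2, 3))
  m <- build_confidence_mask(maps, atlas)
  expect_equal(m$weights, mask_oracle(list(s1, s2), atlas_labels))
  expect_equal(m$weights, c(1L, 0L, 0L, 0L, 1L, 0L))
  expect_equal(m$coverage, 2 / 5)
})

test_that("mask subset chain holds on random inputs", {
  set.seed(61)
  for (rep in 1:10) {
    n <- 40; K <- 4
    atlas_labels <- sample(0:K, n, replace = TRUE)
    atlas_labels[1:K] <- 1:K  # keep parcels non-empty
    atlas <- group_atlas(atlas_labels)
    sessions <- replicate(3, sample(0:K, n, replace = TRUE),
                          simplify = FALSE)
    m <- build_confidence_mask(
      lapply(sessions, parcellation_map, n_parcels = K), atlas)
    expect_equal(m$weights, mask_oracle(sessions, atlas_labels))
    # mask subset of atlas-matching-in-every-session subset of cortex
    match_all <- Reduce(`&`, lapply(sessions, function(s) s == atlas_labels))
    expect_true(all(m$weights <= as.integer(match_all & atlas_labels > 0)))
    expect_true(all(m$weights <= as.integer(atlas_labels > 0)))
  }
})

test_that("masked KL loss matches analytic values", {
  n <- 30; K <- 201
  # uniform probabilities over 201 classes at M masked vertices: M log(201)
  P <- matrix(1 / K, n, K)
  y <- sample(1:(K - 1), n, replace = TRUE)
  w <- rep(0L, n); w[1:7] <- 1L
  expect_equal(masked_kl_loss(P, y, w), 7 * log(201))
  # perfect prediction: loss 0
  P1 <- matrix(0, n, K); P1[cbind(1:n, y + 1L)] <- 1
  expect_equal(masked_kl_loss(P1, y, w), 0)
  # empty mask: loss 0
  expect_equal(masked_kl_loss(P, y, rep(0L, n)), 0)
  # masked unassigned vertex is a contract violation
  y0 <- y; y0[2] <- 0L
  expect_error(masked_kl_loss(P, y0, w), "unassigned")
})

test_that("masked loss equals cross-entropy restricted to masked vertices", {
  set.seed(62)
  n <- 25; K <- 6
  Z <- matrix(rnorm(n * K), n, K)
  P <- exp(Z) / rowSums(exp(Z))
  y <- sample(1:(K - 1), n, replace = TRUE)
  w <- rbinom(n, 1, 0.5)
  ref <- -sum(log(P[cbind(which(w == 1), y[w == 1] + 1L)]))
  expect_equal(masked_kl_loss(P, y, w), ref)
})

test_that("training converges on a separable toy problem", {
  set.seed(63)
  n <- 10
  A <- path_adjacency(n)
  sl <- exact_scaled_laplacian(A)
  y <- rep(1:2, each = 5)
  X <- matrix(0, n, 2); X[cbind(1:n, y)] <- 1  # one-hot separable features
  model <- msgcn_model(2, 3, n_hidden = 4, order = 1, dropout_rate = 0,
                       seed = 7)
  subj <- list(sessions = list(X), mask = rep(1L, n), targets = y)
  cfg <- training_config(epochs = 60, patience = 60, dropout = 0,
                         learning_rate = 0.05, weight_decay = 0, seed = 8,
                         shuffle = FALSE)
  fit <- train_msgcn(model, list(subj, subj), sl$L_scaled, cfg,
                     train_idx = 1, val_idx = 2)
  expect_lt(tail(fit$history$train_loss, 1), fit$history$train_loss[1])
  pred <- predict_parcellation(fit$model, X, sl$L_scaled)
  expect_equal(pred$labels, y)  # training accuracy 1
})

test_that("early stopping halts after patience epochs without improvement", {
  set.seed(64)
  sl <- exact_scaled_laplacian(path_adjacency(8))
  X <- matrix(rnorm(16), 8, 2)
  y <- rep(1:2, 4)
  model <- msgcn_model(2, 3, n_hidden = 3, order = 1, dropout_rate = 0, seed = 1)
  subj <- list(sessions = list(X), mask = rep(1L, 8), targets = y)
  # learning rate so small that validation never improves measurably
  cfg <- training_config(epochs = 50, patience = 4, dropout = 0,
                         learning_rate = 1e-30, weight_decay = 0, seed = 2)
  fit <- train_msgcn(model, list(subj, subj), sl$L_scaled, cfg,
                     train_idx = 1, val_idx = 2)
  expect_equal(fit$best_epoch, 1L)
  expect_equal(fit$stopped_epoch, 1L + 4L)
  expect_equal(nrow(fit$history), 5L)
})

test_that("training is reproducible from the config seed", {
  set.seed(65)
  sl <- exact_scaled_laplacian(random_connected_adjacency(12))
  X1 <- matrix(rnorm(12 * 3), 12, 3)
  X2 <- matrix(rnorm(12 * 3), 12, 3)
  y <- sample(1:3, 12, replace = TRUE)
  subj <- function(X) list(sessions = list(X), mask = rep(1L, 12), targets = y)
  run <- function() {
    model <- msgcn_model(3, 4, n_hidden = 4, order = 2, seed = 9)
    train_msgcn(model, list(subj(X1), subj(X2)), sl$L_scaled,
                training_config(epochs = 8, patience = 8, seed = 10),
                train_idx = 1, val_idx = 2)
  }
  f1 <- run(); f2 <- run()
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$layers, f2$model$layers)
})

test_that("all-ones mask reduces to supervised atlas classification", {
  # zero warp: subject truth equals the atlas, so full supervision applies
  cfg <- cohort_config(mesh_subdivisions = 2L, n_parcels = 8L,
                       n_subjects = 1L, n_timepoints = 120L, snr = 2,
                       warp_steps_primary = 0, warp_steps_association = 0,
                       seed = 31L)
  coh <- make_cohort(cfg)
  fp <- connectivity_fingerprint(coh$sessions[[1]][[1]], coh$atlas)
  n <- nrow(fp$X); K <- coh$atlas$n_parcels
  subj <- list(sessions = list(fp),
               mask = as.integer(coh$atlas$labels > 0),
               targets = coh$atlas$labels)
  model <- msgcn_model(K, K + 1L, n_hidden = 16, seed = 11)
  cfg <- training_config(epochs = 40, patience = 40, dropout = 0,
                         learning_rate = 0.02, weight_decay = 0, seed = 12)
  fit <- train_msgcn(model, list(subj, subj), coh$laplacian$L_scaled, cfg,
                     train_idx = 1, val_idx = 2)
  pred <- predict_parcellation(fit$model, fp, coh$laplacian$L_scaled)
  acc <- mean(pred$labels[coh$atlas$labels > 0] ==
                coh$atlas$labels[coh$atlas$labels > 0])
  expect_gte(acc, 0.99)
})

test_that("prediction takes the argmax with ties to the lower class", {
  sl <- exact_scaled_laplacian(path_adjacency(5))
  model <- msgcn_model(2, 4, n_hidden = 3, order = 1, seed = 1)
  # zero weights, bias crafting an exact tie between classes 2 and 3
  for (l in 1:2) {
    model$layers[[l]]$theta <- lapply(model$layers[[l]]$theta, function(t) t * 0)
  }
  model$layers[[1]]$bias <- rep(0, 3)
  model$layers[[2]]$bias <- c(0, 5, 5, 1)
  pred <- predict_parcellation(model, matrix(1, 5, 2), sl$L_scaled)
  expect_equal(pred$labels, rep(1L, 5))  # classes 2 and 3 tie; lower wins
  expect_error(predict_parcellation(model, matrix(1, 5, 3), sl$L_scaled),
               "features")
})
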