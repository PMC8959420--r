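#' Build a subject-specific confidence mask
#'
#' A vertex enters the confidence mask (weight 1) iff, in every available
#' session of the subject, its similarity-based initial parcel label is
#' (1) assigned (nonzero), (2) identical to the group-atlas label, and
#' (3) identical across sessions. Only masked vertices contribute to the
#' training loss; this keeps high-confidence parcel cores aligned to the
#' atlas while leaving areal borders free to vary across subjects.
#'
#' Rules (1)+(2) imply (3), since every session must match the same atlas
#' label; the overlap rule is still applied explicitly so graded variants
#' remain possible.
#'
#' @param session_maps list of [parcellation_map()] objects, one per session
#'   of one subject (initial similarity-based parcellations).
#' @param atlas the [group_atlas()].
#' @return An object of class `confidence_mask`: `weights` (0/1 per vertex),
#'   `coverage` (fraction of atlas-assigned vertices with weight 1),
#'   `subject_id`.
#' @export
build_confidence_mask <- function(session_maps, atlas) {
  if (inherits(session_maps, "parcellation_map")) session_maps <- list(session_maps)
  if (length(session_maps) == 0L) stop_input("need at least one session map")
  stopifnot(inherits(atlas, "group_atlas"))
  n <- length(atlas$labels)
  lab0 <- session_maps[[1L]]$labels
  if (length(lab0) != n) stop_input("session map / atlas vertex-order mismatch")
  agree <- rep(TRUE, n)
  for (m in session_maps) {
    stopifnot(inherits(m, "parcellation_map"))
    if (length(m$labels) != n) stop_input("session map / atlas vertex-order mismatch")
    agree <- agree & m$labels > 0L & m$labels == atlas$labels & m$labels == lab0
  }
  w <- as.integer(agree & atlas$labels > 0L)
  cortical <- sum(atlas$labels > 0L)
  structure(
    list(weights = w,
         coverage = if (cortical > 0L) sum(w) / cortical else 0,
         subject_id = session_maps[[1L]]$subject_id),
    class = "confidence_mask")
}

#' @export
print.confidence_mask <- function(x, ...) {
  cat(sprintf("<confidence_mask> subject %s: %d vertices in mask (coverage %.1f%%)\n",
              x$subject_id, sum(x$weights), 100 * x$coverage))
  invisible(x)
}

#' Masked Kullback-Leibler (cross-entropy) parcellation loss
#'
#' `-sum_v w_v log p_{v, y_v}` with one-hot targets: the KL divergence from
#' the predicted class distribution to the one-hot group prior, accumulated
#' over confidence-masked vertices. Probabilities are floored at 1e-12
#' before the log so the loss stays finite.
#'
#' @param probs a `probability_map` (or plain row-stochastic matrix).
#' @param targets a [parcellation_map()] (or integer label vector); label
#'   `l` maps to probability column `l + 1` (column 1 = background).
#' @param mask a [build_confidence_mask()] result (or 0/1 weight vector).
#' @return Nonnegative scalar loss.
#' @export
masked_kl_loss <- function(probs, targets, mask) {
  P <- if (inherits(probs, "probability_map")) probs$P else as.matrix(probs)
  y <- if (inherits(targets, "parcellation_map")) targets$labels else as.integer(targets)
  w <- if (inherits(mask, "confidence_mask")) mask$weights else as.numeric(mask)
  if (nrow(P) != length(y) || length(y) != length(w)) stop_input("shape mismatch")
  if (any(y >= ncol(P))) stop_input("target label >= number of classes")
  sel <- which(w != 0)
  if (length(sel) == 0L) return(0)
  if (any(y[sel] == 0L)) {
    stop_input("confidence mask includes %d unassigned (label 0) vertices",
               sum(y[sel] == 0L))
  }
  p_true <- P[cbind(sel, y[sel] + 1L)]
  -sum(w[sel] * log(pmax(p_true, 1e-12)))
}

#' Training configuration
#'
#' Defaults mirror the published protocol: 100 epochs, batch of one
#' subject-session, early-stopping patience 10 epochs, l2 weight decay
#' 0.0005, dropout 0.5, adaptive moment estimation at learning rate 0.001.
#'
#' @param epochs maximum training epochs.
#' @param patience epochs without validation improvement before stopping.
#' @param weight_decay l2 regularization strength on the layer weights.
#' @param dropout hidden-feature dropout rate.
#' @param learning_rate optimizer step size.
#' @param optimizer_name only `"adam"` is implemented.
#' @param seed master seed for sample shuffling and dropout.
#' @param shuffle reshuffle the subject-session order every epoch.
#' @return An object of class `training_config`.
#' @export
training_config <- function(epochs = 100L, patience = 10L, weight_decay = 5e-4,
                            dropout = 0.5, learning_rate = 1e-3,
                            optimizer_name = "adam", seed = 1L,
                            shuffle = TRUE) {
  if (patience > epochs) stop_input("patience (%d) must be <= epochs (%d)", patience, epochs)
  if (weight_decay < 0 || learning_rate <= 0) stop_input("rates must be nonnegative")
  if (!identical(optimizer_name, "adam")) stop_input("only the 'adam' optimizer is implemented")
  structure(
    list(epochs = as.integer(epochs), batch_subjects = 1L,
         patience = as.integer(patience), weight_decay = weight_decay,
         dropout = dropout, learning_rate = learning_rate,
         optimizer_name = optimizer_name, seed = as.integer(seed),
         shuffle = isTRUE(shuffle)),
    class = "training_config")
}

# T_k(L_scaled) %*% C for a single order k, via the three-term recurrence
apply_cheb_T <- function(L_scaled, C, k) {
  if (k == 0L) return(C)
  tm1 <- C
  t <- as.matrix(L_scaled %*% C)
  if (k == 1L) return(t)
  for (i in 2L:k) {
    tn <- as.matrix(2 * (L_scaled %*% t)) - tm1
    tm1 <- t
    t <- tn
  }
  t
}

# gradient of the masked loss w.r.t. all layer parameters for one sample.
# fw: msgcn_forward(..., keep_cache = TRUE) output. Returns list(g1, g2,
# gb1, gb2, loss).
msgcn_backward <- function(model, L_scaled, fw, targets, weights) {
  P <- fw$P
  cache <- fw$cache
  sel <- which(weights != 0)
  dZ2 <- matrix(0, nrow(P), ncol(P))
  if (length(sel) > 0L) {
    Y <- matrix(0, length(sel), ncol(P))
    Y[cbind(seq_along(sel), targets[sel] + 1L)] <- 1
    dZ2[sel, ] <- (P[sel, , drop = FALSE] - Y) * weights[sel]
  }
  K <- model$order
  th2 <- model$layers[[2L]]$theta
  g2 <- lapply(seq_len(K + 1L), function(k) crossprod(cache$basis2[[k]], dZ2))
  gb2 <- colSums(dZ2)
  dH <- matrix(0, nrow(P), model$n_hidden)
  for (k in seq_len(K + 1L)) {
    dH <- dH + apply_cheb_T(L_scaled, dZ2 %*% t(th2[[k]]), k - 1L)
  }
  if (!is.null(cache$drop_mask)) dH <- dH * cache$drop_mask
  dZ1 <- dH * (cache$Z1 > 0)
  g1 <- lapply(seq_len(K + 1L), function(k) crossprod(cache$basis1[[k]], dZ1))
  gb1 <- colSums(dZ1)
  list(g1 = g1, g2 = g2, gb1 = gb1, gb2 = gb2)
}

adam_state <- function(model) {
  zero_like <- function(layer) list(
    m_theta = lapply(layer$theta, function(th) th * 0),
    v_theta = lapply(layer$theta, function(th) th * 0),
    m_bias = if (!is.null(layer$bias)) layer$bias * 0,
    v_bias = if (!is.null(layer$bias)) layer$bias * 0)
  list(t = 0L, layers = lapply(model$layers, zero_like))
}

adam_step <- function(model, grads, state, lr, weight_decay,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  gl <- list(list(theta = grads$g1, bias = grads$gb1),
             list(theta = grads$g2, bias = grads$gb2))
  for (l in 1:2) {
    layer <- model$layers[[l]]
    st <- state$layers[[l]]
    for (k in seq_along(layer$theta)) {
      g <- gl[[l]]$theta[[k]] + weight_decay * layer$theta[[k]]
      st$m_theta[[k]] <- beta1 * st$m_theta[[k]] + (1 - beta1) * g
      st$v_theta[[k]] <- beta2 * st$v_theta[[k]] + (1 - beta2) * g^2
      layer$theta[[k]] <- layer$theta[[k]] -
        lr * (st$m_theta[[k]] / bc1) / (sqrt(st$v_theta[[k]] / bc2) + eps)
    }
    if (!is.null(layer$bias)) {
      g <- gl[[l]]$bias  # no decay on biases
      st$m_bias <- beta1 * st$m_bias + (1 - beta1) * g
      st$v_bias <- beta2 * st$v_bias + (1 - beta2) * g^2
      layer$bias <- layer$bias -
        lr * (st$m_bias / bc1) / (sqrt(st$v_bias / bc2) + eps)
    }
    model$layers[[l]] <- layer
    state$layers[[l]] <- st
  }
  list(model = model, state = state)
}

# normalize one training subject entry to (basis1 per session, weights,
# targets); signals may be graph_signals, matrices, or precomputed bases
prepare_subject <- function(subj, L_scaled, order) {
  stopifnot(is.list(subj$sessions), length(subj$sessions) >= 1L)
  w <- if (inherits(subj$mask, "confidence_mask")) subj$mask$weights else as.numeric(subj$mask)
  y <- if (inherits(subj$targets, "parcellation_map")) subj$targets$labels else as.integer(subj$targets)
  if (any(w != 0 & y == 0L)) {
    stop_input("subject %s: confidence mask covers unassigned vertices",
               subj$id %||% "?")
  }
  bases <- lapply(subj$sessions, function(s) {
    X <- if (inherits(s, "graph_signals")) s$X else s
    if (is.list(X) && !is.data.frame(X)) X else chebyshev_basis(L_scaled, X, order)
  })
  list(bases = bases, weights = w, targets = y)
}

#' Train the masked graph-convolution parcellation model
#'
#' Iterates over subject-sessions one at a time (batch size one subject),
#' minimizing the confidence-masked KL loss plus l2 weight decay with
#' adaptive moment estimation. After every epoch the mean masked loss over
#' the validation subjects is computed (dropout off); training stops early
#' once `patience` epochs pass without improvement, and the parameters of
#' the best validation epoch are returned. Fully reproducible for a fixed
#' config seed.
#'
#' @param model an [msgcn_model()].
#' @param subjects list of subject entries, each a list with `sessions`
#'   (list of `graph_signals` / feature matrices / precomputed bases),
#'   `mask` ([build_confidence_mask()]), `targets` (atlas labels as a
#'   [parcellation_map()] or integer vector), and optionally `id`.
#' @param L_scaled rescaled Laplacian shared by all subjects.
#' @param config a [training_config()].
#' @param train_idx,val_idx indices into `subjects` for the training and
#'   validation split. Defaults: all but the last fifth train, last fifth
#'   (at least one subject) validates.
#' @param verbose print one line per epoch.
#' @return List with `model` (best-epoch parameters), `history` (data frame
#'   of epoch, train_loss, val_loss), `best_epoch`, `stopped_epoch`.
#' @export
train_msgcn <- function(model, subjects, L_scaled, config = training_config(),
                        train_idx = NULL, val_idx = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "msgcn_model"), inherits(config, "training_config"))
  if (length(subjects) == 0L) stop_input("empty training set")
  if (is.null(val_idx)) {
    n_val <- max(1L, floor(length(subjects) / 5))
    val_idx <- seq(length(subjects) - n_val + 1L, length(subjects))
  }
  if (is.null(train_idx)) train_idx <- setdiff(seq_along(subjects), val_idx)
  if (length(train_idx) == 0L) stop_input("empty training split")
  model$dropout_rate <- config$dropout
  prep <- lapply(subjects, prepare_subject, L_scaled = L_scaled,
                 order = model$order)
  samples <- do.call(rbind, lapply(train_idx, function(i) {
    cbind(subject = i, session = seq_along(prep[[i]]$bases))
  }))
  val_loss_fn <- function(m) {
    mean(vapply(val_idx, function(i) {
      p <- prep[[i]]
      mean(vapply(seq_along(p$bases), function(s) {
        fw <- msgcn_forward(m, L_scaled, p$bases[[s]], training = FALSE)
        masked_kl_loss(fw$P, p$targets, p$weights)
      }, numeric(1)))
    }, numeric(1)))
  }
  state <- adam_state(model)
  best <- list(loss = Inf, model = model, epoch = 0L)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  wait <- 0L
  stopped <- config$epochs
  for (epoch in seq_len(config$epochs)) {
    ord <- if (config$shuffle) {
      with_seed(derive_seed(config$seed, "shuffle", epoch),
                sample.int(nrow(samples)))
    } else seq_len(nrow(samples))
    ep_loss <- 0
    for (si in seq_along(ord)) {
      row <- samples[ord[si], ]
      p <- prep[[row[["subject"]]]]
      fw <- msgcn_forward(
        model, L_scaled, p$bases[[row[["session"]]]], training = TRUE,
        seed = derive_seed(config$seed, "dropout", epoch * 100000L + si),
        keep_cache = TRUE)
      loss <- masked_kl_loss(fw$P, p$targets, p$weights)
      if (!is.finite(loss)) {
        stop_input("non-finite loss at epoch %d, subject %d", epoch,
                   row[["subject"]])
      }
      ep_loss <- ep_loss + loss
      grads <- msgcn_backward(model, L_scaled, fw, p$targets, p$weights)
      upd <- adam_step(model, grads, state, config$learning_rate,
                       config$weight_decay)
      model <- upd$model
      state <- upd$state
    }
    vl <- val_loss_fn(model)
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = ep_loss / nrow(samples), val_loss = vl))
    if (verbose) {
      message(sprintf("epoch %3d  train %.4f  val %.4f", epoch,
                      ep_loss / nrow(samples), vl))
    }
    if (vl < best$loss - 1e-12) {
      best <- list(loss = vl, model = model, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) {
        stopped <- epoch
        break
      }
    }
  }
  list(model = best$model, history = history, best_epoch = best$epoch,
       stopped_epoch = stopped)
}

#' Predict an individualized parcellation
#'
#' Runs the trained model (dropout off) and assigns each vertex the class of
#' highest probability; probability column 1 maps to label 0 (background),
#' column `k + 1` to parcel `k`. Ties break to the lower class index.
#'
#' @param model a trained [msgcn_model()].
#' @param signals `graph_signals` / feature matrix / precomputed basis.
#' @param L_scaled rescaled Laplacian.
#' @param subject_id,session_id identifiers stored on the result.
#' @return A [parcellation_map()].
#' @export
predict_parcellation <- function(model, signals, L_scaled,
                                 subject_id = NA_character_,
                                 session_id = NA_character_) {
  if (inherits(signals, "graph_signals")) {
    if (is.na(subject_id)) subject_id <- signals$subject_id
    if (is.na(session_id)) session_id <- signals$session_id
  }
  fw <- msgcn_forward(model, L_scaled, signals, training = FALSE)
  labels <- max.col(fw$P, ties.method = "first") - 1L
  parcellation_map(labels, n_parcels = model$n_classes - 1L,
                   subject_id = subject_id, session_id = session_id)
}
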