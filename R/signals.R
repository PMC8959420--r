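#' Construct a per-session vertex time-series container
#'
#' @param data numeric matrix, vertices x timepoints (BOLD-like units).
#' @param tr repetition time in seconds.
#' @param subject_id,session_id identifiers carried through the pipeline.
#' @return An object of class `session_ts`.
#' @export
session_ts <- function(data, tr, subject_id = "s1", session_id = "r1") {
  data <- as.matrix(data)
  if (ncol(data) < 2L) stop_input("need at least 2 timepoints, got %d", ncol(data))
  if (anyNA(data)) stop_input("time series contain NA")
  if (!is.numeric(tr) || tr <= 0) stop_input("tr must be a positive number of seconds")
  structure(
    list(data = data, tr = tr,
         subject_id = as.character(subject_id),
         session_id = as.character(session_id)),
    class = "session_ts")
}

#' @export
print.session_ts <- function(x, ...) {
  cat(sprintf("<session_ts> %s/%s: %d vertices x %d timepoints, TR = %gs\n",
              x$subject_id, x$session_id, nrow(x$data), ncol(x$data), x$tr))
  invisible(x)
}

#' Zero-phase band-pass filtering of vertex time series
#'
#' Removes the per-vertex mean, then applies a forward-backward (zero-phase)
#' Butterworth band-pass. The conventional resting-state band is
#' 0.01-0.1 Hz.
#'
#' @param ts a [session_ts()].
#' @param low_hz,high_hz band edges in Hz; must satisfy
#'   `0 < low_hz < high_hz < 1/(2 tr)`.
#' @param order Butterworth section order (the effective filter after the
#'   forward-backward pass has twice the attenuation).
#' @return A filtered `session_ts` of the same shape.
#' @export
bandpass_filter <- function(ts, low_hz = 0.01, high_hz = 0.1, order = 2L) {
  stopifnot(inherits(ts, "session_ts"))
  nyquist <- 1 / (2 * ts$tr)
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyquist)) {
    stop_input("band [%g, %g] Hz must lie strictly inside (0, Nyquist = %g) Hz",
               low_hz, high_hz, nyquist)
  }
  bf <- signal::butter(order, c(low_hz, high_hz) / nyquist, type = "pass")
  x <- ts$data - rowMeans(ts$data)
  filt_one <- function(row) signal::filtfilt(bf, row)
  out <- t(apply(x, 1L, filt_one))
  out <- out - rowMeans(out)
  ts$data <- out
  ts
}

#' Regress nuisance confounds out of vertex time series
#'
#' Each vertex series is replaced by its least-squares residual against an
#' intercept plus the supplied confound columns (e.g. mean white-matter and
#' CSF signals). Residuals are exactly orthogonal to every confound column.
#'
#' @param ts a [session_ts()].
#' @param confounds numeric matrix, timepoints x C (C may be 0).
#' @return A `session_ts` of residuals (demeaned).
#' @export
regress_nuisance <- function(ts, confounds = NULL) {
  stopifnot(inherits(ts, "session_ts"))
  tp <- ncol(ts$data)
  if (is.null(confounds) || NCOL(confounds) == 0L || length(confounds) == 0L) {
    ts$data <- ts$data - rowMeans(ts$data)
    return(ts)
  }
  confounds <- as.matrix(confounds)
  if (nrow(confounds) != tp) {
    stop_input("confounds have %d rows but time series %d timepoints",
               nrow(confounds), tp)
  }
  design <- cbind(intercept = 1, confounds)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    dropped <- colnames(design)[qrd$pivot[(qrd$rank + 1L):ncol(design)]]
    stop_input("confound design is rank deficient; collinear column(s): %s",
               paste(dropped, collapse = ", "))
  }
  # residual-maker applied to all vertices at once: R = Y - Q (Q'Y)
  Q <- qr.Q(qrd)
  Yt <- t(ts$data)                       # timepoints x vertices
  ts$data <- t(Yt - Q %*% crossprod(Q, Yt))
  ts
}

#' Construct a group atlas object
#'
#' @param labels integer vector of per-vertex labels in `0..K`
#'   (0 = unassigned / medial wall).
#' @param n_parcels K; defaults to `max(labels)`.
#' @param parcel_names optional character vector of length K.
#' @param parcel_class optional per-parcel tag, e.g. `"primary"` /
#'   `"association"` (length K).
#' @return An object of class `group_atlas`.
#' @export
group_atlas <- function(labels, n_parcels = NULL, parcel_names = NULL,
                        parcel_class = NULL) {
  labels <- as.integer(labels)
  if (any(labels < 0L)) stop_input("labels must be >= 0")
  K <- as.integer(n_parcels %||% max(labels))
  if (any(labels > K)) stop_input("label exceeds n_parcels = %d", K)
  counts <- tabulate(labels, nbins = K)
  if (any(counts == 0L)) {
    stop_input("empty parcel(s): %s",
               paste(utils::head(which(counts == 0L), 5L), collapse = ", "))
  }
  if (!is.null(parcel_class) && length(parcel_class) != K) {
    stop_input("parcel_class must have length K = %d", K)
  }
  structure(
    list(labels = labels, n_parcels = K,
         parcel_names = parcel_names, parcel_class = parcel_class),
    class = "group_atlas")
}

#' @export
print.group_atlas <- function(x, ...) {
  cat(sprintf("<group_atlas> %d vertices, %d parcels (%d unassigned)\n",
              length(x$labels), x$n_parcels, sum(x$labels == 0L)))
  invisible(x)
}

#' Connectivity fingerprints as graph signals
#'
#' For every vertex, the fingerprint is the vector of Pearson correlations
#' between the vertex's time series and the mean time series of each atlas
#' parcel (ROI). The resulting N x K matrix is the signal embedded on the
#' brain graph.
#'
#' Vertices whose series have zero variance get an all-zero fingerprint row
#' and are recorded in `zero_variance`.
#'
#' @param ts a preprocessed [session_ts()].
#' @param atlas a [group_atlas()] aligned to the same vertex order.
#' @return An object of class `graph_signals` with fields `X` (N x K),
#'   `feature_meaning` (ROI id per column), `zero_variance` (vertex indices),
#'   `subject_id`, `session_id`.
#' @export
connectivity_fingerprint <- function(ts, atlas) {
  stopifnot(inherits(ts, "session_ts"), inherits(atlas, "group_atlas"))
  if (length(atlas$labels) != nrow(ts$data)) {
    stop_input("atlas has %d vertices but time series %d",
               length(atlas$labels), nrow(ts$data))
  }
  K <- atlas$n_parcels
  lab <- atlas$labels
  assigned <- lab > 0L
  # parcel mean series: K x timepoints
  sums <- rowsum(ts$data[assigned, , drop = FALSE], lab[assigned])
  counts <- tabulate(lab[assigned], nbins = K)
  roi_means <- sums / counts
  v_sd <- apply(ts$data, 1L, sd)
  roi_sd <- apply(roi_means, 1L, sd)
  if (any(roi_sd == 0)) {
    stop_input("parcel mean series with zero variance (parcel %s)",
               which(roi_sd == 0)[1L])
  }
  zero_var <- which(v_sd == 0)
  if (length(zero_var) == nrow(ts$data)) stop_input("all vertex series have zero variance")
  X <- matrix(0, nrow(ts$data), K)
  ok <- v_sd > 0
  X[ok, ] <- cor(t(ts$data[ok, , drop = FALSE]), t(roi_means))
  structure(
    list(X = X, feature_meaning = seq_len(K), zero_variance = zero_var,
         subject_id = ts$subject_id, session_id = ts$session_id),
    class = "graph_signals")
}

#' @export
print.graph_signals <- function(x, ...) {
  cat(sprintf("<graph_signals> %d vertices x %d features (%d zero-variance)\n",
              nrow(x$X), ncol(x$X), length(x$zero_variance)))
  invisible(x)
}

#' Similarity-based initial parcellation
#'
#' Assigns every cortical vertex to the atlas parcel whose centroid
#' fingerprint (mean fingerprint over the parcel's atlas vertices) is most
#' similar — highest Pearson correlation between whole fingerprint profiles —
#' to the vertex's own fingerprint. Ties break to the lowest parcel index;
#' zero-variance vertices get label 0.
#'
#' @param signals a [connectivity_fingerprint()] result.
#' @param atlas the [group_atlas()] that defined the fingerprint columns.
#' @return An object of class `parcellation_map` (see [parcellation_map()]).
#' @export
initial_parcellation <- function(signals, atlas) {
  stopifnot(inherits(signals, "graph_signals"), inherits(atlas, "group_atlas"))
  X <- signals$X
  if (length(atlas$labels) != nrow(X)) stop_input("vertex order mismatch")
  lab <- atlas$labels
  K <- atlas$n_parcels
  assigned <- lab > 0L
  sums <- rowsum(X[assigned, , drop = FALSE], lab[assigned])
  counts <- tabulate(lab[assigned], nbins = K)
  if (any(counts == 0L)) stop_input("parcel without member vertices")
  centroids <- sums / counts                       # K x F
  cen_sd <- apply(centroids, 1L, sd)
  if (any(cen_sd == 0)) stop_input("constant parcel centroid fingerprint")
  S <- suppressWarnings(cor(t(X), t(centroids)))   # N x K; NA rows for sd 0
  labels <- apply(S, 1L, function(r) if (anyNA(r)) 0L else which.max(r))
  labels[signals$zero_variance] <- 0L
  parcellation_map(labels, n_parcels = K,
                   subject_id = signals$subject_id,
                   session_id = signals$session_id)
}

#' Construct a parcellation map
#'
#' @param labels integer vector of per-vertex labels in `0..K`
#'   (0 = unassigned / background).
#' @param n_parcels label universe size K.
#' @param subject_id,session_id identifiers.
#' @return An object of class `parcellation_map`.
#' @export
parcellation_map <- function(labels, n_parcels = NULL, subject_id = NA_character_,
                             session_id = NA_character_) {
  labels <- as.integer(labels)
  if (any(labels < 0L)) stop_input("labels must be >= 0")
  K <- as.integer(n_parcels %||% max(labels))
  if (any(labels > K)) stop_input("label exceeds n_parcels = %d", K)
  structure(
    list(labels = labels, n_parcels = K,
         subject_id = as.character(subject_id),
         session_id = as.character(session_id)),
    class = "parcellation_map")
}

#' @export
print.parcellation_map <- function(x, ...) {
  cat(sprintf("<parcellation_map> %s/%s: %d vertices, %d parcels, %d unassigned\n",
              x$subject_id, x$session_id, length(x$labels), x$n_parcels,
              sum(x$labels == 0L)))
  invisible(x)
}
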