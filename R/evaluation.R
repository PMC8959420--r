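#' Per-parcel Dice overlap between two parcellation maps
#'
#' For every parcel k present in either map,
#' `dice_k = 2 |A_k intersect B_k| / (|A_k| + |B_k|)`, where `A_k`, `B_k`
#' are the vertex sets labeled k in the two maps. The whole-cortex value is
#' the unweighted mean over parcels with at least one member in either map.
#' Label 0 (unassigned) is excluded. Symmetric in its arguments.
#'
#' @param map_a,map_b [parcellation_map()] objects (or integer label
#'   vectors) over the same vertex order.
#' @return List with `per_parcel` (named numeric vector, NA for parcels
#'   absent from both maps) and `mean`.
#' @export
dice_parcellation <- function(map_a, map_b) {
  a <- if (inherits(map_a, "parcellation_map")) map_a$labels else as.integer(map_a)
  b <- if (inherits(map_b, "parcellation_map")) map_b$labels else as.integer(map_b)
  if (length(a) != length(b)) {
    stop_input("maps differ in length (%d vs %d)", length(a), length(b))
  }
  K <- max(a, b, 1L)
  size_a <- tabulate(a[a > 0L], nbins = K)
  size_b <- tabulate(b[b > 0L], nbins = K)
  both <- a == b & a > 0L
  inter <- tabulate(a[both], nbins = K)
  denom <- size_a + size_b
  d <- ifelse(denom > 0L, 2 * inter / denom, NA_real_)
  names(d) <- seq_len(K)
  list(per_parcel = d, mean = mean(d, na.rm = TRUE))
}

#' Cohen's d between two collections of variability values
#'
#' `d = (mean(inter) - mean(intra)) / sqrt(var(inter) + var(intra))` with
#' population (denominator n) variances by default; the sign is preserved,
#' so positive d means larger intersubject than intrasubject values.
#'
#' @param inter_values,intra_values numeric vectors (e.g. 1 - Dice over
#'   between-subject and within-subject map pairs).
#' @param population use denominator-n variance (default) rather than n-1.
#' @return Scalar effect size.
#' @export
cohens_d <- function(inter_values, intra_values, population = TRUE) {
  inter_values <- as.numeric(inter_values)
  intra_values <- as.numeric(intra_values)
  pvar <- function(x) {
    if (length(x) < 2L) return(0)
    if (population) mean((x - mean(x))^2) else var(x)
  }
  v <- pvar(inter_values) + pvar(intra_values)
  num <- mean(inter_values) - mean(intra_values)
  if (v == 0) {
    if (abs(num) < .Machine$double.eps^0.5) return(0)
    stop_input("both variances are zero but means differ: effect size undefined")
  }
  num / sqrt(v)
}

# all intra- (same subject) and inter-subject (different subjects) session
# pairs from a nested list maps[[subject]][[session]]
session_pairs <- function(maps) {
  idx <- do.call(rbind, lapply(seq_along(maps), function(s) {
    cbind(subject = s, session = seq_along(maps[[s]]))
  }))
  n <- nrow(idx)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  intra <- idx[pairs[, 1], "subject"] == idx[pairs[, 2], "subject"]
  list(idx = idx, pairs = pairs, intra = intra)
}

#' Topographic variability maps (Cohen's d per parcel)
#'
#' For every parcel, collects `1 - dice_k` over all intersubject session
#' pairs and all intrasubject session pairs, and reports the Cohen's d
#' between the two collections: large d marks parcels whose borders vary
#' more between subjects than between repeated sessions of one subject.
#' When the atlas carries `parcel_class` tags, class-wise mean d values are
#' summarized as well.
#'
#' @param parcellations nested list: `parcellations[[subject]][[session]]`,
#'   each a [parcellation_map()].
#' @param atlas optional [group_atlas()] supplying `parcel_class` tags.
#' @return An object of class `variability_map`: `values` (per-parcel d, NA
#'   where a parcel is absent from all maps), `index_meaning`, `by_class`
#'   (named mean d per parcel class, or NULL), plus the raw `inter`/`intra`
#'   per-parcel matrices.
#' @export
variability_maps <- function(parcellations, atlas = NULL) {
  if (length(parcellations) < 2L) stop_input("need at least 2 subjects")
  if (any(vapply(parcellations, length, 1L) < 2L)) {
    stop_input("every subject needs at least 2 sessions")
  }
  sp <- session_pairs(parcellations)
  get_map <- function(r) parcellations[[sp$idx[r, "subject"]]][[sp$idx[r, "session"]]]
  K <- get_map(1L)$n_parcels
  diss <- vapply(seq_len(nrow(sp$pairs)), function(p) {
    d <- dice_parcellation(get_map(sp$pairs[p, 1]), get_map(sp$pairs[p, 2]))
    1 - unname(d$per_parcel[seq_len(K)])
  }, numeric(K))
  diss <- matrix(diss, nrow = K)  # K x pairs
  inter <- diss[, !sp$intra, drop = FALSE]
  intra <- diss[, sp$intra, drop = FALSE]
  values <- vapply(seq_len(K), function(k) {
    iv <- inter[k, ]; av <- intra[k, ]
    if (all(is.na(iv)) || all(is.na(av))) return(NA_real_)
    cohens_d(iv[!is.na(iv)], av[!is.na(av)])
  }, numeric(1))
  by_class <- NULL
  if (!is.null(atlas) && !is.null(atlas$parcel_class)) {
    by_class <- tapply(values, atlas$parcel_class, mean, na.rm = TRUE)
  }
  structure(
    list(values = values, index_meaning = "cohens_d(1 - dice)",
         by_class = by_class, inter = inter, intra = intra),
    class = "variability_map")
}

#' Functional-connectivity variability maps (Cohen's d per parcel)
#'
#' For every pair of runs, the per-vertex fingerprint correlation is
#' computed (correlation between the two fingerprint rows of that vertex)
#' and averaged within each atlas parcel; the per-pair parcel variability is
#' `1 - mean correlation`. Cohen's d between the intersubject and
#' intrasubject collections is reported per parcel.
#'
#' @param fingerprints nested list `fingerprints[[subject]][[session]]` of
#'   [connectivity_fingerprint()] results (or plain N x F matrices).
#' @param atlas [group_atlas()] defining the parcels.
#' @return A `variability_map` (as in [variability_maps()]).
#' @export
connectivity_variability <- function(fingerprints, atlas) {
  stopifnot(inherits(atlas, "group_atlas"))
  if (length(fingerprints) < 2L) stop_input("need at least 2 subjects")
  sp <- session_pairs(fingerprints)
  get_X <- function(r) {
    x <- fingerprints[[sp$idx[r, "subject"]]][[sp$idx[r, "session"]]]
    if (inherits(x, "graph_signals")) x$X else as.matrix(x)
  }
  K <- atlas$n_parcels
  lab <- atlas$labels
  assigned <- lab > 0L
  counts <- tabulate(lab[assigned], nbins = K)
  row_cor <- function(A, B) {
    A <- A - rowMeans(A); B <- B - rowMeans(B)
    den <- sqrt(rowSums(A^2) * rowSums(B^2))
    r <- rowSums(A * B) / den
    bad <- !is.finite(r)
    if (any(bad & assigned)) {
      warning(sprintf("%d zero-variance profile(s) skipped", sum(bad & assigned)))
    }
    r[bad] <- NA_real_
    r
  }
  diss <- vapply(seq_len(nrow(sp$pairs)), function(p) {
    r <- row_cor(get_X(sp$pairs[p, 1]), get_X(sp$pairs[p, 2]))
    m <- rowsum(ifelse(is.na(r[assigned]), 0, r[assigned]), lab[assigned]) /
      rowsum(as.numeric(!is.na(r[assigned])), lab[assigned])
    1 - as.numeric(m)[seq_len(K)]
  }, numeric(K))
  diss <- matrix(diss, nrow = K)
  inter <- diss[, !sp$intra, drop = FALSE]
  intra <- diss[, sp$intra, drop = FALSE]
  values <- vapply(seq_len(K), function(k) {
    iv <- inter[k, ]; av <- intra[k, ]
    if (all(is.na(iv)) || all(is.na(av))) return(NA_real_)
    cohens_d(iv[!is.na(iv)], av[!is.na(av)])
  }, numeric(1))
  by_class <- NULL
  if (!is.null(atlas$parcel_class)) {
    by_class <- tapply(values, atlas$parcel_class, mean, na.rm = TRUE)
  }
  structure(
    list(values = values, index_meaning = "cohens_d(1 - profile correlation)",
         by_class = by_class, inter = inter, intra = intra),
    class = "variability_map")
}

#' Resting-state functional homogeneity of parcels
#'
#' Per parcel, the mean Pearson correlation over all unordered vertex pairs
#' within the parcel; globally, the parcel-size-weighted mean (parcels with
#' fewer than 2 vertices are skipped). Higher homogeneity means the parcel
#' groups vertices with similar BOLD dynamics.
#'
#' @param parcellation a [parcellation_map()] (or label vector).
#' @param ts a [session_ts()] sharing the vertex order.
#' @return List with `per_parcel` (named numeric, NA for skipped parcels),
#'   `sizes`, and `global`.
#' @export
functional_homogeneity <- function(parcellation, ts) {
  lab <- if (inherits(parcellation, "parcellation_map")) parcellation$labels
         else as.integer(parcellation)
  stopifnot(inherits(ts, "session_ts"))
  if (length(lab) != nrow(ts$data)) stop_input("vertex-order mismatch")
  K <- max(lab, 1L)
  per <- rep(NA_real_, K)
  sizes <- tabulate(lab[lab > 0L], nbins = K)
  for (k in which(sizes >= 2L)) {
    idx <- which(lab == k)
    cm <- suppressWarnings(cor(t(ts$data[idx, , drop = FALSE])))
    per[k] <- mean(cm[upper.tri(cm)], na.rm = TRUE)
  }
  if (all(is.na(per))) stop_input("no parcel has 2 or more vertices")
  ok <- !is.na(per)
  list(per_parcel = stats::setNames(per, seq_len(K)), sizes = sizes,
       global = sum(sizes[ok] * per[ok]) / sum(sizes[ok]))
}

#' Task-activation alignment of a parcellation
#'
#' Per parcel: the (population) standard deviation of the activation betas
#' within the parcel (task variability — lower means activation changes
#' follow the areal borders) and the mean beta (task homogeneity). The
#' whole-brain task variability is the parcel-size-weighted mean of the
#' per-parcel standard deviations.
#'
#' @param parcellation a [parcellation_map()] (or label vector).
#' @param beta_map numeric per-vertex activation (GLM beta) vector.
#' @return List with `per_parcel` (data frame: parcel, size, variability,
#'   homogeneity), `whole_brain_variability`, `whole_brain_homogeneity`.
#' @export
task_alignment <- function(parcellation, beta_map) {
  lab <- if (inherits(parcellation, "parcellation_map")) parcellation$labels
         else as.integer(parcellation)
  beta_map <- as.numeric(beta_map)
  if (length(lab) != length(beta_map)) stop_input("vertex-order mismatch")
  if (anyNA(beta_map[lab > 0L])) stop_input("NA betas at assigned vertices")
  K <- max(lab, 1L)
  sizes <- tabulate(lab[lab > 0L], nbins = K)
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  variability <- rep(NA_real_, K)
  homogeneity <- rep(NA_real_, K)
  for (k in which(sizes > 0L)) {
    b <- beta_map[lab == k]
    variability[k] <- pop_sd(b)
    homogeneity[k] <- mean(b)
  }
  ok <- sizes > 0L
  list(
    per_parcel = data.frame(parcel = seq_len(K), size = sizes,
                            variability = variability,
                            homogeneity = homogeneity),
    whole_brain_variability = sum(sizes[ok] * variability[ok]) / sum(sizes[ok]),
    whole_brain_homogeneity = sum(sizes[ok] * homogeneity[ok]) / sum(sizes[ok]))
}

#' Correlate two per-parcel maps
#'
#' Pearson correlation (with two-sided p) across parcels, e.g. between
#' topographic variability and connectivity variability, or against a
#' myelin-ratio covariate. Parcels missing (NA) in either map are dropped
#' pairwise.
#'
#' @param map_x,map_y numeric per-parcel vectors of equal length.
#' @return List with `r`, `p`, `n` (complete pairs used).
#' @export
correlate_maps <- function(map_x, map_y) {
  map_x <- as.numeric(map_x); map_y <- as.numeric(map_y)
  if (length(map_x) != length(map_y)) stop_input("maps differ in length")
  ok <- is.finite(map_x) & is.finite(map_y)
  if (sum(ok) < 3L) stop_input("need at least 3 complete parcel pairs, got %d", sum(ok))
  ct <- cor.test(map_x[ok], map_y[ok])
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Intra- versus intersubject parcellation reliability
#'
#' Computes mean Dice for all same-subject session pairs and all
#' different-subject pairs, plus a paired two-sided t-test across subjects
#' (each subject's mean intra Dice vs its mean inter Dice).
#'
#' @param parcellations nested list `parcellations[[subject]][[session]]`.
#' @return List with `intra` and `inter` (all pairwise mean-Dice values),
#'   `per_subject` (data frame subject/intra/inter), and `p_value`.
#' @export
reliability_summary <- function(parcellations) {
  if (length(parcellations) < 2L) stop_input("need at least 2 subjects")
  sp <- session_pairs(parcellations)
  get_map <- function(r) parcellations[[sp$idx[r, "subject"]]][[sp$idx[r, "session"]]]
  dm <- vapply(seq_len(nrow(sp$pairs)), function(p) {
    dice_parcellation(get_map(sp$pairs[p, 1]), get_map(sp$pairs[p, 2]))$mean
  }, numeric(1))
  subj1 <- sp$idx[sp$pairs[, 1], "subject"]
  subj2 <- sp$idx[sp$pairs[, 2], "subject"]
  per_subject <- do.call(rbind, lapply(seq_along(parcellations), function(s) {
    data.frame(
      subject = s,
      intra = mean(dm[sp$intra & subj1 == s]),
      inter = mean(dm[!sp$intra & (subj1 == s | subj2 == s)]))
  }))
  pt <- t.test(per_subject$intra, per_subject$inter, paired = TRUE)
  list(intra = dm[sp$intra], inter = dm[!sp$intra],
       per_subject = per_subject, p_value = pt$p.value)
}
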