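#' Synthetic cohort configuration
#'
#' Defines the study conditions the generator emulates: an icosphere
#' "cortex", a contiguous K-parcel group atlas, per-subject ground-truth
#' parcellations warped at parcel borders (more strongly in "association"
#' than "primary" parcels, mimicking the sensory-fugal variability
#' gradient), parcel-structured BOLD-like sessions at a given SNR, and
#' behavioral scores linked to parcellation topography.
#'
#' @param mesh_subdivisions icosphere refinement level (4 gives 2,562
#'   vertices — desk-scale stand-in for a 32k surface).
#' @param n_parcels number of atlas parcels K.
#' @param n_subjects,n_sessions_per_subject cohort size.
#' @param n_timepoints,tr session length and repetition time (seconds).
#' @param snr ratio of parcel-signal std to vertex-noise std. The default
#'   0.4 puts within-parcel vertex-pair correlations at
#'   `snr^2 / (1 + snr^2) = 0.14`, the magnitude of resting-state parcel
#'   homogeneity reported for HCP-grade data.
#' @param warp_steps_primary,warp_steps_association expected boundary
#'   label-flip rounds for the two parcel classes at the far end of the
#'   cohort's deformation trajectory (values below 1 are per-round flip
#'   probabilities). Defaults 0.2 / 0.7 put cohort-mean subject-to-atlas
#'   Dice near 0.89, the scale of group-vs-individual similarity reported
#'   for connectivity-based individual parcellations.
#' @param association_fraction fraction of parcels tagged "association".
#' @param medial_wall_deg angular radius (degrees) of a south-polar
#'   medial-wall cap excluded from the cortex mask (0 = none).
#' @param behavior_effect slope linking topography (per-parcel Dice to the
#'   atlas) to the behavioral score.
#' @param behavior_noise score noise standard deviation.
#' @param seed master seed; all generators draw from named substreams of it.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(mesh_subdivisions = 4L, n_parcels = 50L,
                          n_subjects = 20L, n_sessions_per_subject = 2L,
                          n_timepoints = 400L, tr = 0.72, snr = 0.4,
                          warp_steps_primary = 0.2, warp_steps_association = 0.7,
                          association_fraction = 0.4, medial_wall_deg = 0,
                          behavior_effect = 1, behavior_noise = 0.1,
                          seed = 1L) {
  stopifnot(mesh_subdivisions >= 0, n_parcels >= 1, n_subjects >= 1,
            n_sessions_per_subject >= 1, n_timepoints >= 1, tr > 0, snr > 0,
            warp_steps_primary >= 0, warp_steps_association >= 0,
            association_fraction >= 0, association_fraction <= 1,
            behavior_noise >= 0)
  structure(
    list(mesh_subdivisions = as.integer(mesh_subdivisions),
         n_parcels = as.integer(n_parcels),
         n_subjects = as.integer(n_subjects),
         n_sessions_per_subject = as.integer(n_sessions_per_subject),
         n_timepoints = as.integer(n_timepoints), tr = tr, snr = snr,
         warp_steps_primary = warp_steps_primary,
         warp_steps_association = warp_steps_association,
         association_fraction = association_fraction,
         medial_wall_deg = medial_wall_deg,
         behavior_effect = behavior_effect, behavior_noise = behavior_noise,
         seed = as.integer(seed)),
    class = "cohort_config")
}

#' Generate an icosphere surface mesh
#'
#' Starts from a regular icosahedron and subdivides each triangle into four
#' `subdivisions` times, projecting new vertices onto the sphere (radius
#' 100 mm). Optionally masks out a polar cap as a synthetic "medial wall".
#'
#' @param subdivisions refinement level, 0..7 (level s has
#'   `10 * 4^s + 2` vertices).
#' @param medial_wall_deg angular radius in degrees of a cap around the
#'   south pole with `cortex_mask = FALSE` (0 disables).
#' @return A [surface_mesh()].
#' @export
make_mesh <- function(subdivisions = 4L, medial_wall_deg = 0) {
  subdivisions <- as.integer(subdivisions)
  if (subdivisions < 0L) stop_input("subdivisions must be >= 0")
  if (subdivisions > 7L) stop_input("subdivisions > 7 refused (mesh too large)")
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    edge_key <- function(a, b) ifelse(a < b, a * 1e7 + b, b * 1e7 + a)
    midpoints <- new.env(hash = TRUE)
    nv <- nrow(v)
    newv <- list()
    get_mid <- function(a, b) {
      key <- as.character(edge_key(a, b))
      idx <- midpoints[[key]]
      if (is.null(idx)) {
        m <- (v[a, ] + v[b, ]) / 2
        m <- m / sqrt(sum(m^2))
        newv[[length(newv) + 1L]] <<- m
        idx <- nv + length(newv)
        midpoints[[key]] <- idx
      }
      idx
    }
    newf <- matrix(0L, 4L * nrow(f), 3L)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; c <- f[t, 3]
      ab <- get_mid(a, b); bc <- get_mid(b, c); ca <- get_mid(c, a)
      newf[4L * t - 3L, ] <- c(a, ab, ca)
      newf[4L * t - 2L, ] <- c(b, bc, ab)
      newf[4L * t - 1L, ] <- c(c, ca, bc)
      newf[4L * t, ] <- c(ab, bc, ca)
    }
    v <- rbind(v, do.call(rbind, newv))
    f <- newf
  }
  coords <- v * 100
  mask <- rep(TRUE, nrow(coords))
  if (medial_wall_deg > 0) {
    # cap around the south pole (z = -100)
    mask <- coords[, 3] > -100 * cos(medial_wall_deg * pi / 180)
  }
  surface_mesh(coords, f, mask)
}

# neighbor list (graph indices) from a surface_graph
neighbor_list <- function(graph) {
  tA <- methods::as(methods::as(graph$adjacency, "generalMatrix"),
                    "TsparseMatrix")
  unname(split(tA@i + 1L, factor(tA@j + 1L, levels = seq_len(graph$n_vertices))))
}

# multi-source BFS hop distances from a set of source vertices
bfs_hops <- function(nbrs, sources, n) {
  dist <- rep(Inf, n)
  dist[sources] <- 0
  frontier <- sources
  d <- 0
  while (length(frontier) > 0L) {
    d <- d + 1
    nxt <- unique(unlist(nbrs[frontier], use.names = FALSE))
    nxt <- nxt[is.infinite(dist[nxt])]
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

#' Generate a contiguous synthetic group atlas
#'
#' Seeds parcels by farthest-point sampling in graph-hop distance, then
#' grows all parcels simultaneously (multi-source breadth-first search), so
#' every parcel is connected on the surface graph. A spatially contiguous
#' block of parcels is tagged `"association"` (higher intersubject
#' variability downstream); the rest are `"primary"`.
#'
#' @param mesh a [surface_mesh()] (or a precomputed [build_adjacency()]
#'   graph via the `graph` argument).
#' @param n_parcels number of parcels K.
#' @param seed seed for the first farthest-point sample.
#' @param association_fraction fraction of parcels tagged "association".
#' @param graph optional precomputed `surface_graph` for `mesh`.
#' @return A [group_atlas()] over the mesh's full vertex order (medial-wall
#'   vertices keep label 0).
#' @export
make_group_atlas <- function(mesh, n_parcels, seed = 1L,
                             association_fraction = 0.4, graph = NULL) {
  graph <- graph %||% build_adjacency(mesh)
  n <- graph$n_vertices
  if (n_parcels > n) stop_input("n_parcels (%d) exceeds cortical vertices (%d)",
                                n_parcels, n)
  nbrs <- neighbor_list(graph)
  seeds <- integer(n_parcels)
  seeds[1L] <- with_seed(derive_seed(seed, "atlas-seed"), sample.int(n, 1L))
  mind <- bfs_hops(nbrs, seeds[1L], n)
  if (n_parcels > 1L) {
    for (k in 2L:n_parcels) {
      seeds[k] <- which.max(mind)  # deterministic farthest point
      mind <- pmin(mind, bfs_hops(nbrs, seeds[k], n))
    }
  }
  # simultaneous region growing: each vertex adopts the label of the
  # lowest-labeled neighbor that reaches it first, so parcels stay connected
  lab <- integer(n)
  lab[seeds] <- seq_len(n_parcels)
  frontier <- seeds
  while (length(frontier) > 0L) {
    cand <- unlist(nbrs[frontier], use.names = FALSE)
    src <- rep(lab[frontier], lengths(nbrs[frontier]))
    new <- cand[lab[cand] == 0L]
    src <- src[lab[cand] == 0L]
    if (length(new) == 0L) break
    o <- order(new, src)
    first <- !duplicated(new[o])
    lab[new[o][first]] <- src[o][first]
    frontier <- unique(new)
  }
  # tag a contiguous association zone by BFS over the parcel-adjacency graph
  n_assoc <- round(association_fraction * n_parcels)
  parcel_class <- rep("primary", n_parcels)
  if (n_assoc > 0L) {
    tA <- methods::as(graph$adjacency, "TsparseMatrix")
    pi_ <- lab[tA@i + 1L]; pj <- lab[tA@j + 1L]
    ok <- pi_ != pj & pi_ > 0L & pj > 0L
    padj <- unique(cbind(pi_[ok], pj[ok]))
    pnbrs <- split(padj[, 2], factor(padj[, 1], levels = seq_len(n_parcels)))
    zone <- integer(0)
    frontier <- 1L
    while (length(zone) < n_assoc && length(frontier) > 0L) {
      take <- utils::head(frontier, n_assoc - length(zone))
      zone <- c(zone, take)
      nxt <- sort(unique(unlist(pnbrs[frontier], use.names = FALSE)))
      frontier <- setdiff(nxt, zone)
    }
    parcel_class[zone] <- "association"
  }
  full <- integer(length(mesh$cortex_mask))
  full[graph$vertex_map] <- lab
  group_atlas(full, n_parcels = n_parcels, parcel_class = parcel_class)
}

#' Canonical boundary-deformation trajectory of a cohort
#'
#' Simulates a progressive warp of the group atlas: in each of
#' `ceiling(max(warp))` rounds, every boundary vertex (a vertex with a
#' neighbor of a different nonzero label) flips to the label of a random
#' such neighbor with probability `warp_class / n_rounds`, where
#' `warp_class` is `warp_steps_association` or `warp_steps_primary`
#' according to the class of the vertex's current parcel; flips that would
#' empty a parcel are skipped. Every accepted flip is recorded in order.
#' The trajectory is a cohort-level object (seeded from `config$seed`):
#' individual subjects sit at different severities along it (see
#' [make_subject_truth()]), so intersubject topographic variability is a
#' shared, low-dimensional deformation mode rather than independent
#' per-subject noise — which is what lets parcellation topography carry a
#' behavior signal expressible through whole-map Dice similarity.
#'
#' @param atlas the [make_group_atlas()] result.
#' @param graph the shared [build_adjacency()] surface graph.
#' @param config a [cohort_config()] (supplies warp intensities and seed).
#' @return An object of class `warp_trajectory`: `moves` (two-column matrix
#'   of graph-vertex index and new label, in application order) plus the
#'   atlas labels it starts from.
#' @export
warp_trajectory <- function(atlas, graph, config) {
  stopifnot(inherits(atlas, "group_atlas"), inherits(graph, "surface_graph"),
            inherits(config, "cohort_config"))
  nbrs <- neighbor_list(graph)
  lab <- atlas$labels[graph$vertex_map]
  K <- atlas$n_parcels
  warp <- c(primary = config$warp_steps_primary,
            association = config$warp_steps_association)
  n_rounds <- max(1L, ceiling(max(warp)))
  p_class <- stats::setNames(pmin(1, warp / n_rounds), names(warp))
  cls <- atlas$parcel_class %||% rep("primary", K)
  moves <- matrix(0L, 0L, 2L)
  with_seed(derive_seed(config$seed, "warp-trajectory"), {
    for (r in seq_len(n_rounds)) {
      counts <- tabulate(lab[lab > 0L], nbins = K)
      cand <- which(vapply(seq_along(lab), function(v) {
        lab[v] > 0L && any(lab[nbrs[[v]]] > 0L & lab[nbrs[[v]]] != lab[v])
      }, logical(1)))
      if (length(cand) == 0L) break
      flip <- cand[runif(length(cand)) < p_class[cls[lab[cand]]]]
      for (v in flip[sample.int(length(flip))]) {
        if (counts[lab[v]] <= 1L) next  # would empty the parcel
        opts <- nbrs[[v]]
        opts <- opts[lab[opts] > 0L & lab[opts] != lab[v]]
        if (length(opts) == 0L) next
        new_lab <- lab[opts[sample.int(length(opts), 1L)]]
        counts[lab[v]] <- counts[lab[v]] - 1L
        counts[new_lab] <- counts[new_lab] + 1L
        lab[v] <- new_lab
        moves <- rbind(moves, c(v, new_lab))
      }
    }
  })
  structure(list(moves = moves, start = atlas$labels[graph$vertex_map],
                 n_parcels = K),
            class = "warp_trajectory")
}

#' Generate a subject's ground-truth parcellation
#'
#' The subject's parcellation is an intermediate state of the cohort's
#' canonical [warp_trajectory()]: a per-subject severity `u` (drawn uniform
#' on `[0.15, 1]` from `subject_seed`, unless given) selects how many of the
#' ordered boundary flips to replay. Severity 0 reproduces the atlas;
#' larger severity gives lower Dice to the atlas, and association parcels
#' deform more than primary ones at every severity (the trajectory flips
#' them more often).
#'
#' @param atlas the [make_group_atlas()] result.
#' @param graph the shared [build_adjacency()] surface graph.
#' @param config a [cohort_config()].
#' @param subject_seed integer seed for this subject's severity draw.
#' @param severity optional explicit severity in `[0, 1]`.
#' @param trajectory optional precomputed [warp_trajectory()] (recomputed
#'   from `config` if missing; it is deterministic given the config seed).
#' @return A [parcellation_map()] over the full mesh vertex order, with the
#'   severity stored as attribute `severity`.
#' @export
make_subject_truth <- function(atlas, graph, config, subject_seed,
                               severity = NULL, trajectory = NULL) {
  trajectory <- trajectory %||% warp_trajectory(atlas, graph, config)
  stopifnot(inherits(trajectory, "warp_trajectory"))
  if (is.null(severity)) {
    severity <- with_seed(subject_seed, runif(1L, 0.15, 1))
  }
  if (severity < 0 || severity > 1) stop_input("severity must be in [0, 1]")
  lab <- trajectory$start
  n_moves <- round(severity * nrow(trajectory$moves))
  if (n_moves > 0L) {
    for (m in seq_len(n_moves)) {
      lab[trajectory$moves[m, 1L]] <- trajectory$moves[m, 2L]
    }
  }
  full <- integer(length(atlas$labels))
  full[graph$vertex_map] <- lab
  out <- parcellation_map(full, n_parcels = trajectory$n_parcels,
                          subject_id = sprintf("sub-%d", subject_seed))
  attr(out, "severity") <- severity
  out
}

#' Generate one session of parcel-structured vertex time series
#'
#' Each parcel draws an independent smooth latent series (white noise
#' band-pass filtered to 0.01-0.1 Hz at the configured TR, standardized);
#' every vertex's series is its parcel's latent plus independent Gaussian
#' noise with standard deviation `1/snr`. Sessions of the same subject share
#' the subject's ground-truth parcellation but use independent draws.
#' Unassigned (label 0) vertices get pure noise.
#'
#' @param subject_truth the subject's [make_subject_truth()] map.
#' @param config a [cohort_config()].
#' @param session_seed integer seed for this session's draws.
#' @param subject_id,session_id identifiers.
#' @return A [session_ts()] over the full mesh vertex order.
#' @export
make_session <- function(subject_truth, config, session_seed,
                         subject_id = subject_truth$subject_id,
                         session_id = "r1") {
  stopifnot(inherits(subject_truth, "parcellation_map"),
            inherits(config, "cohort_config"))
  if (config$n_timepoints < 50L) stop_input("need n_timepoints >= 50")
  lab <- subject_truth$labels
  K <- subject_truth$n_parcels
  tp <- config$n_timepoints
  low <- 0.01; high <- min(0.1, 0.45 / config$tr)
  with_seed(session_seed, {
    latent_raw <- matrix(rnorm(K * tp), K, tp)
    lat_ts <- bandpass_filter(
      session_ts(latent_raw, tr = config$tr), low, high)
    latent <- lat_ts$data / apply(lat_ts$data, 1L, sd)
    noise <- matrix(rnorm(length(lab) * tp, sd = 1 / config$snr),
                    length(lab), tp)
    data <- noise
    data[lab > 0L, ] <- data[lab > 0L, ] + latent[lab[lab > 0L], ]
  })
  session_ts(data, tr = config$tr, subject_id = subject_id,
             session_id = session_id)
}

#' Generate topography-linked behavioral scores
#'
#' `score_s = behavior_effect * sum_k c_k dice_k(truth_s, atlas) + noise`,
#' with fixed per-parcel contrasts `c_k ~ N(0, 1)` drawn once from the
#' config seed. Subjects whose parcellations deviate from the atlas in the
#' same parcels get similar scores.
#'
#' @param subject_truths list of [make_subject_truth()] maps.
#' @param atlas the group atlas.
#' @param config a [cohort_config()].
#' @return List with `scores`, `contrasts` (the generating `c_k`), and
#'   `signal` (the noiseless scores).
#' @export
make_behavior <- function(subject_truths, atlas, config) {
  if (length(subject_truths) < 2L) stop_input("need at least 2 subjects")
  K <- atlas$n_parcels
  contrasts <- with_seed(derive_seed(config$seed, "behavior-contrasts"),
                         rnorm(K))
  signal_part <- vapply(subject_truths, function(m) {
    d <- dice_parcellation(m, atlas$labels)$per_parcel[seq_len(K)]
    d[is.na(d)] <- 0
    config$behavior_effect * sum(contrasts * d)
  }, numeric(1))
  noise <- with_seed(derive_seed(config$seed, "behavior-noise"),
                     rnorm(length(subject_truths), sd = config$behavior_noise))
  list(scores = signal_part + noise, contrasts = contrasts,
       signal = signal_part)
}

#' Generate synthetic per-vertex task-activation betas
#'
#' Piecewise-constant activation on the subject's ground-truth parcels (one
#' `N(0, 1)` level per parcel, drawn per subject) plus vertex-level Gaussian
#' noise — so activation changes follow the subject's true areal borders.
#'
#' @param subject_truth the subject's ground-truth [parcellation_map()].
#' @param seed integer seed.
#' @param noise_sd within-parcel beta noise (default 0.1).
#' @return Numeric per-vertex beta vector (0 at unassigned vertices).
#' @export
make_task_betas <- function(subject_truth, seed, noise_sd = 0.1) {
  lab <- subject_truth$labels
  with_seed(seed, {
    levels_ <- rnorm(subject_truth$n_parcels)
    beta <- rnorm(length(lab), sd = noise_sd)
    beta[lab == 0L] <- 0
    beta[lab > 0L] <- beta[lab > 0L] + levels_[lab[lab > 0L]]
  })
  beta
}

#' Generate a full synthetic cohort
#'
#' Convenience wrapper: mesh, shared surface graph and scaled Laplacian,
#' group atlas, per-subject ground truths, per-session time series, and
#' behavioral scores, all reproducible from `config$seed`.
#'
#' @param config a [cohort_config()].
#' @param sessions also generate time series (set `FALSE` when only
#'   parcellations are needed, e.g. for behavior experiments).
#' @return List with `config`, `mesh`, `graph`, `laplacian` (scaled),
#'   `atlas`, `truths` (list per subject), `sessions` (nested list
#'   `[[subject]][[session]]` of `session_ts`, or NULL), `behavior`.
#' @export
make_cohort <- function(config = cohort_config(), sessions = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  mesh <- make_mesh(config$mesh_subdivisions, config$medial_wall_deg)
  graph <- build_adjacency(mesh)
  lap <- scale_laplacian(estimate_lambda_max(
    normalized_laplacian(graph), seed = derive_seed(config$seed, "lmax")))
  atlas <- make_group_atlas(mesh, config$n_parcels,
                            seed = derive_seed(config$seed, "atlas"),
                            association_fraction = config$association_fraction,
                            graph = graph)
  trajectory <- warp_trajectory(atlas, graph, config)
  truths <- lapply(seq_len(config$n_subjects), function(s) {
    truth <- make_subject_truth(atlas, graph, config,
                                derive_seed(config$seed, "subject", s),
                                trajectory = trajectory)
    truth$subject_id <- sprintf("sub-%02d", s)
    truth
  })
  sess <- NULL
  if (sessions) {
    sess <- lapply(seq_len(config$n_subjects), function(s) {
      lapply(seq_len(config$n_sessions_per_subject), function(r) {
        make_session(truths[[s]], config,
                     derive_seed(config$seed, "session", s * 1000L + r),
                     subject_id = sprintf("sub-%02d", s),
                     session_id = sprintf("ses-%d", r))
      })
    })
  }
  behavior <- if (config$n_subjects >= 2L) {
    make_behavior(truths, atlas, config)
  }
  list(config = config, mesh = mesh, graph = graph, laplacian = lap,
       atlas = atlas, truths = truths, sessions = sess, behavior = behavior)
}
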