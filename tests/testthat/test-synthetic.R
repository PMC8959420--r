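test_that("icosphere subdivision follows the closed-form counts", {
  m0 <- make_mesh(0)
  g0 <- build_adjacency(m0)
  expect_equal(nrow(m0$coordinates), 12L)
  expect_equal(nrow(m0$triangles), 20L)
  expect_equal(sum(g0$degrees) / 2, 30)
  m1 <- make_mesh(1)
  expect_equal(nrow(m1$coordinates), 42L)   # V' = V + E
  expect_equal(nrow(m1$triangles), 80L)     # F' = 4F
  # Euler characteristic of the sphere at every level
  for (s in 0:3) {
    ms <- make_mesh(s)
    gs <- build_adjacency(ms)
    V <- nrow(ms$coordinates); Fc <- nrow(ms$triangles)
    E <- sum(gs$degrees) / 2
    expect_equal(V - E + Fc, 2)
  }
  # vertices lie on the 100 mm sphere
  expect_equal(unname(sqrt(rowSums(make_mesh(2)$coordinates^2))),
               rep(100, 162), tolerance = 1e-12)
  expect_error(make_mesh(8), "refused")
  # medial-wall cap masks the south pole
  mw <- make_mesh(2, medial_wall_deg = 30)
  expect_true(any(!mw$cortex_mask))
  expect_true(all(mw$coordinates[!mw$cortex_mask, 3] < 0))
})

test_that("group atlas parcels are non-empty, exhaustive and connected", {
  mesh <- make_mesh(2, medial_wall_deg = 25)
  graph <- build_adjacency(mesh)
  atlas <- make_group_atlas(mesh, 6, seed = 5, graph = graph)
  expect_equal(sort(unique(atlas$labels[mesh$cortex_mask])), 1:6)
  expect_true(all(atlas$labels[!mesh$cortex_mask] == 0L))
  # single parcel covers the whole cortex
  a1 <- make_group_atlas(mesh, 1, seed = 5, graph = graph)
  expect_true(all(a1$labels[mesh$cortex_mask] == 1L))
  # connectivity oracle: BFS within each parcel reaches every member
  nbrs <- gcnparcel:::neighbor_list(graph)
  glab <- atlas$labels[graph$vertex_map]
  for (k in 1:6) {
    members <- which(glab == k)
    seen <- members[1]; frontier <- members[1]
    while (length(frontier) > 0) {
      nxt <- setdiff(intersect(unique(unlist(nbrs[frontier])), members), seen)
      seen <- c(seen, nxt); frontier <- nxt
    }
    expect_setequal(seen, members)
  }
  expect_error(make_group_atlas(mesh, 10000, graph = graph), "exceeds")
  expect_equal(sum(atlas$parcel_class == "association"), round(0.4 * 6))
})

test_that("subject truths deviate from the atlas along the warp gradient", {
  coh <- tiny_cohort()
  atlas <- coh$atlas
  # zero warp reproduces the atlas exactly
  cfg0 <- cohort_config(mesh_subdivisions = 2L, n_parcels = 8L,
                        warp_steps_primary = 0, warp_steps_association = 0,
                        seed = 99L)
  tr0 <- warp_trajectory(atlas, coh$graph, cfg0)
  t0 <- make_subject_truth(atlas, coh$graph, cfg0, subject_seed = 1L,
                           trajectory = tr0)
  expect_equal(t0$labels, atlas$labels)
  expect_equal(dice_parcellation(t0, atlas$labels)$mean, 1)
  # label universe unchanged, parcels stay non-empty
  for (m in coh$truths) {
    expect_true(all(sort(unique(m$labels[m$labels > 0])) == 1:8))
  }
  # association parcels lose more Dice than primary ones (cohort mean)
  per <- rowMeans(vapply(coh$truths, function(m)
    unname(dice_parcellation(m, atlas$labels)$per_parcel[1:8]), numeric(8)))
  expect_gt(mean(per[atlas$parcel_class == "primary"]),
            mean(per[atlas$parcel_class == "association"]))
  # expected Dice decreases with severity
  traj <- warp_trajectory(atlas, coh$graph, coh$config)
  d_by_sev <- vapply(c(0.2, 0.6, 1), function(u) {
    dice_parcellation(
      make_subject_truth(atlas, coh$graph, coh$config, 1L, severity = u,
                         trajectory = traj),
      atlas$labels)$mean
  }, numeric(1))
  expect_true(all(diff(d_by_sev) < 0))
})

test_that("sessions carry parcel structure at the configured SNR", {
  coh <- tiny_cohort()
  truth <- coh$truths[[1]]
  # near-noiseless limit: within-parcel correlations approach 1
  hi <- make_session(truth, cohort_config(mesh_subdivisions = 2L,
                                          n_parcels = 8L, snr = 1e6,
                                          n_timepoints = 100L, seed = 99L),
                     session_seed = 7L)
  k1 <- which(truth$labels == 1)[1:5]
  cm <- cor(t(hi$data[k1, ]))
  expect_true(all(cm[upper.tri(cm)] >= 0.99))
  # snr = 1: within-parcel correlation exceeds between-parcel correlation
  s1 <- make_session(truth, cohort_config(mesh_subdivisions = 2L,
                                          n_parcels = 8L, snr = 1,
                                          n_timepoints = 150L, seed = 99L),
                     session_seed = 8L)
  lab <- truth$labels
  C <- cor(t(s1$data[lab > 0, ]))
  same <- outer(lab[lab > 0], lab[lab > 0], "==")
  diag(same) <- NA
  expect_gt(mean(C[same & !is.na(same)]), mean(C[!same & !is.na(same)]))
  # two sessions of a subject: different data, same generating parcellation
  s2 <- make_session(truth, coh$config, session_seed = 9L)
  s3 <- make_session(truth, coh$config, session_seed = 10L)
  expect_false(identical(s2$data, s3$data))
})

test_that("behavioral scores are a seeded function of topography", {
  coh <- tiny_cohort()
  beh <- make_behavior(coh$truths, coh$atlas, coh$config)
  expect_length(beh$scores, length(coh$truths))
  expect_length(beh$contrasts, coh$atlas$n_parcels)
  # effect 0: scores are pure noise
  cfg0 <- coh$config; cfg0$behavior_effect <- 0
  beh0 <- make_behavior(coh$truths, coh$atlas, cfg0)
  expect_true(all(beh0$signal == 0))
  # a duplicated subject gets an identical noiseless score
  beh2 <- make_behavior(c(coh$truths[1], coh$truths), coh$atlas, coh$config)
  expect_equal(beh2$signal[1], beh2$signal[2])
})

test_that("cohorts are bit-reproducible and carry the reliability structure", {
  cfg <- cohort_config(mesh_subdivisions = 2L, n_parcels = 8L,
                       n_subjects = 5L, n_timepoints = 120L, seed = 77L)
  c1 <- make_cohort(cfg)
  c2 <- make_cohort(cfg)
  expect_identical(lapply(c1$truths, `[[`, "labels"),
                   lapply(c2$truths, `[[`, "labels"))
  expect_identical(c1$sessions[[3]][[2]]$data, c2$sessions[[3]][[2]]$data)
  expect_identical(c1$behavior$scores, c2$behavior$scores)
  # intrasubject similarity of initial parcellations exceeds intersubject
  initial <- lapply(c1$sessions, function(ss) {
    lapply(ss, function(ts) {
      initial_parcellation(connectivity_fingerprint(ts, c1$atlas), c1$atlas)
    })
  })
  rel <- reliability_summary(initial)
  expect_gt(mean(rel$intra), mean(rel$inter))
})

test_that("task betas are piecewise constant on the generating parcellation", {
  coh <- tiny_cohort()
  truth <- coh$truths[[2]]
  beta <- make_task_betas(truth, seed = 12L, noise_sd = 0)
  ta <- task_alignment(truth, beta)
  expect_equal(ta$whole_brain_variability, 0)
  expect_identical(beta, make_task_betas(truth, seed = 12L, noise_sd = 0))
})
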