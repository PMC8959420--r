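test_that("Dice matches analytic cases and is symmetric and bounded", {
  a <- c(1, 1, 1, 1, 2, 2, 2, 2, 0)
  b <- c(1, 1, 2, 2, 1, 1, 2, 2, 0)
  # parcel 1: |A|=4, |B|=4, overlap 2 -> 0.5 (same for parcel 2)
  d <- dice_parcellation(a, b)
  expect_equal(unname(d$per_parcel), c(0.5, 0.5))
  expect_equal(d$mean, 0.5)
  # identical maps
  d1 <- dice_parcellation(a, a)
  expect_equal(unname(d1$per_parcel), c(1, 1))
  expect_equal(d1$mean, 1)
  # disjoint support for a parcel
  expect_equal(unname(dice_parcellation(c(1, 1, 2, 2),
                                        c(2, 2, 1, 1))$per_parcel),
               c(0, 0))
  expect_error(dice_parcellation(a, b[1:5]), "length")
  # properties on random maps
  set.seed(71)
  for (rep in 1:10) {
    x <- random_label_map(50, 5); y <- random_label_map(50, 5)
    dxy <- dice_parcellation(x, y); dyx <- dice_parcellation(y, x)
    expect_equal(dxy$per_parcel, dyx$per_parcel)
    expect_true(all(dxy$per_parcel >= 0 & dxy$per_parcel <= 1, na.rm = TRUE))
    expect_equal(dice_parcellation(x, x)$mean, 1)
  }
  # label 0 never contributes
  expect_equal(dice_parcellation(c(0, 0, 1), c(0, 1, 1))$mean, 2 / 3)
})

test_that("Cohen's d uses population variances and preserves sign", {
  expect_equal(cohens_d(c(2, 4, 6), c(2, 4, 6)), 0)
  # inter {1,3}: mu 2, sigma^2 1; intra {0,2}: mu 1, sigma^2 1 -> 1/sqrt(2)
  expect_equal(cohens_d(c(1, 3), c(0, 2)), 1 / sqrt(2))
  expect_equal(cohens_d(c(0, 2), c(1, 3)), -1 / sqrt(2))  # antisymmetry
  expect_equal(cohens_d(c(5, 5), c(5, 5)), 0)  # degenerate, equal means
  expect_error(cohens_d(c(5, 5), c(4, 4)), "undefined")
  # sample-variance flag changes the scale
  expect_equal(cohens_d(c(1, 3), c(0, 2), population = FALSE), 1 / 2)
})

test_that("topographic variability is zero for identical maps and follows the warp gradient", {
  m <- random_label_map(40, 4)
  same <- list(list(m, m), list(m, m))
  vm0 <- variability_maps(same)
  expect_true(all(vm0$values[!is.na(vm0$values)] == 0))

  # cohort where association parcels are warped more than primary ones:
  # intersubject (1 - dice) spreads wider for association parcels
  cfg <- cohort_config(mesh_subdivisions = 2L, n_parcels = 10L,
                       n_subjects = 12L, association_fraction = 0.5,
                       seed = 99L)
  coh <- make_cohort(cfg, sessions = FALSE)
  sessions_of <- function(truth, seeds) lapply(seeds, function(sd) {
    # session-level map: the truth plus a few random label flips (noise)
    lab <- truth$labels
    idx <- gcnparcel:::with_seed(sd, sample(which(lab > 0), 5))
    lab[idx] <- gcnparcel:::with_seed(sd + 1L,
                                      sample(1:truth$n_parcels, 5, replace = TRUE))
    parcellation_map(lab, truth$n_parcels)
  })
  nested <- lapply(seq_along(coh$truths), function(s) {
    sessions_of(coh$truths[[s]], c(1000L + s, 2000L + s))
  })
  vm <- variability_maps(nested, coh$atlas)
  expect_gt(vm$by_class["association"], vm$by_class["primary"])
})

test_that("connectivity variability separates subject structure from noise", {
  set.seed(72)
  n <- 60; K <- 4
  atlas <- group_atlas(c(1:K, sample(1:K, n - K, replace = TRUE)))
  # identical fingerprints everywhere: d = 0
  X <- matrix(rnorm(n * K), n, K)
  fps_same <- replicate(3, list(X, X), simplify = FALSE)
  vm0 <- connectivity_variability(fps_same, atlas)
  expect_true(all(vm0$values[!is.na(vm0$values)] == 0))
  # independent random fingerprints: |d| small
  fps_rand <- replicate(5, replicate(2, matrix(rnorm(n * K), n, K),
                                     simplify = FALSE), simplify = FALSE)
  vm1 <- connectivity_variability(fps_rand, atlas)
  expect_lt(mean(abs(vm1$values)), 0.6)
  expect_lt(abs(mean(vm1$values)), 0.2)
  # subject-specific perturbations: intersubject variability dominates
  base <- matrix(rnorm(n * K), n, K)
  fps_subj <- lapply(1:5, function(s) {
    subj_part <- matrix(rnorm(n * K), n, K)
    lapply(1:2, function(r) base + subj_part + 0.3 * matrix(rnorm(n * K), n, K))
  })
  vm2 <- connectivity_variability(fps_subj, atlas)
  expect_gt(mean(vm2$values), 0)
})

test_that("functional homogeneity matches the pairwise-correlation oracle", {
  # all vertices in a parcel share one series: homogeneity 1
  tp <- 50
  shared <- rnorm(tp)
  data <- rbind(shared, shared, shared, rnorm(tp), rnorm(tp))
  h <- functional_homogeneity(c(1, 1, 1, 2, 2), session_ts(data, tr = 1))
  expect_equal(unname(h$per_parcel[1]), 1)
  # 3-vertex parcel: mean of the three pairwise correlations
  set.seed(73)
  d3 <- matrix(rnorm(3 * 40), 3, 40)
  h3 <- functional_homogeneity(rep(1, 3), session_ts(d3, tr = 1))
  ref <- mean(c(cor(d3[1, ], d3[2, ]), cor(d3[1, ], d3[3, ]),
                cor(d3[2, ], d3[3, ])))
  expect_equal(unname(h3$per_parcel[1]), ref)
  # independent white noise: global homogeneity near 0
  set.seed(74)
  dw <- matrix(rnorm(30 * 1000), 30, 1000)
  hw <- functional_homogeneity(rep(1:3, each = 10), session_ts(dw, tr = 1))
  expect_lt(abs(hw$global), 0.05)
  # singleton parcels are skipped; all-singleton input errors
  expect_error(functional_homogeneity(1:5,
                                      session_ts(matrix(rnorm(50), 5), tr = 1)),
               "2 or more")
})

test_that("global homogeneity is invariant to parcel relabeling", {
  set.seed(75)
  data <- matrix(rnorm(24 * 60), 24, 60)
  lab <- rep(1:4, each = 6)
  perm <- c(3L, 1L, 4L, 2L)
  h1 <- functional_homogeneity(lab, session_ts(data, tr = 1))
  h2 <- functional_homogeneity(perm[lab], session_ts(data, tr = 1))
  expect_equal(h1$global, h2$global)
})

test_that("task alignment reports per-parcel mean and population std", {
  lab <- c(1, 1, 1, 2, 2)
  beta <- c(1, 2, 3, 4, 4)
  ta <- task_alignment(lab, beta)
  expect_equal(ta$per_parcel$homogeneity, c(2, 4))
  expect_equal(ta$per_parcel$variability[1], sqrt(2 / 3), tolerance = 1e-4)
  expect_equal(ta$per_parcel$variability[2], 0)
  # constant beta within every parcel: all stds 0
  ta0 <- task_alignment(lab, c(7, 7, 7, -1, -1))
  expect_equal(ta0$per_parcel$variability, c(0, 0))
  expect_equal(ta0$whole_brain_variability, 0)
  expect_error(task_alignment(lab, c(1, NA, 3, 4, 5)), "NA")
})

test_that("map correlation matches cor.test and validates input", {
  x <- c(0.1, 0.5, 0.9, 0.2, 0.7)
  expect_equal(correlate_maps(x, 2 * x + 1)$r, 1)
  expect_equal(correlate_maps(x, -x)$r, -1)
  expect_error(correlate_maps(c(1, 2, NA), c(1, 2, 3)), "at least 3")
  # missing parcels dropped pairwise
  y <- 3 * x; y[2] <- NA
  out <- correlate_maps(x, y)
  expect_equal(out$n, 4)
  expect_equal(out$r, 1)
  # independent random maps across many parcels: small |r|
  set.seed(76)
  expect_lt(abs(correlate_maps(rnorm(400), rnorm(400))$r), 0.15)
})

test_that("similarity ordering: intra > inter > unrelated random maps", {
  coh <- tiny_cohort()
  atlas <- coh$atlas
  fps <- lapply(coh$sessions[1:4], function(ss)
    lapply(ss, connectivity_fingerprint, atlas = atlas))
  initial <- lapply(fps, function(fs)
    lapply(fs, initial_parcellation, atlas = atlas))
  rel <- reliability_summary(initial)
  random_map <- random_label_map(length(atlas$labels), atlas$n_parcels)
  d_rand <- mean(vapply(initial, function(ms)
    dice_parcellation(ms[[1]], random_map)$mean, numeric(1)))
  expect_gt(mean(rel$intra), mean(rel$inter))
  expect_gt(mean(rel$inter), d_rand)
})

test_that("ground-truth parcellation is more homogeneous than a shuffled one", {
  coh <- tiny_cohort()
  h_true <- h_shuf <- c()
  for (s in 1:4) for (r in 1:2) {
    ts <- coh$sessions[[s]][[r]]
    truth <- coh$truths[[s]]
    h_true <- c(h_true, functional_homogeneity(truth, ts)$global)
    lab <- truth$labels
    idx <- gcnparcel:::with_seed(400L + 10L * s + r,
                                 sample(which(lab > 0), round(0.1 * sum(lab > 0))))
    lab[idx] <- gcnparcel:::with_seed(500L + 10L * s + r,
                                      sample(1:truth$n_parcels, length(idx),
                                             replace = TRUE))
    h_shuf <- c(h_shuf, functional_homogeneity(lab, ts)$global)
  }
  expect_gt(mean(h_true - h_shuf), 0)
  expect_lt(t.test(h_true, h_shuf, paired = TRUE)$p.value, 0.05)
})
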