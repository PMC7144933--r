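test_that("ratio_from_distance: limits, frozen r = 0 anchor, monotonicity", {
  pp <- pre_parameters()
  # far-probe limit
  expect_equal(ratio_from_distance(1e6, pp), 1.0, tolerance = 1e-12)
  # r = 0 anchor, frozen from an independent evaluation of
  # exp(-3.4e7/9^6) / (1 + 4.5e8/9^6) with 9^6 = 531441:
  x0 <- 1 / 531441
  anchor <- exp(-3.4e7 * x0) / (1 + 4.5e8 * x0)
  expect_equal(ratio_from_distance(0, pp), anchor, tolerance = 1e-12)
  expect_lt(ratio_from_distance(0, pp), ratio_from_distance(30, pp))
  # strict monotone increase over [0, 60] at 0.1 A
  v <- ratio_from_distance(seq(0, 60, by = 0.1), pp)
  expect_true(all(diff(v) > 0))
  expect_true(all(v > 0 & v <= 1))
  expect_error(ratio_from_distance(-1, pp), class = "parameter_error")
})

test_that("numerical inverse round-trips distances over [1, 60] A", {
  pp <- pre_parameters()
  r <- seq(1, 60, by = 1)
  back <- ratio_to_distance(ratio_from_distance(r, pp), pp)
  expect_lt(max(abs(back - r)), 1e-6)
  expect_error(ratio_to_distance(1.0, pp), class = "parameter_error")
})

test_that("physical-parameter mode agrees with regenerated condensed mode", {
  ph <- list(K = 1.23e-32, tau_c = 4e-9, omega_h = 2 * pi * 600e6,
             R2 = 40, t_evol = 9e-3)
  cc <- derive_condensed_constants(ph)
  pp <- pre_parameters(cc$alpha_const, cc$beta_const, 9.0, physical = ph)
  r <- seq(10, 40, by = 0.5)
  a <- ratio_from_distance(r, pp, mode = "condensed")
  b <- ratio_from_distance(r, pp, mode = "physical")
  expect_lt(max(abs(a - b) / pmax(a, 1e-12)), 0.05)
})

test_that("probe_methyl_distances: literal geometry, single-methyl flag, oracle", {
  atoms <- data.frame(
    atom_name = c("NZ", "CG1", "CG2", "CG2"),
    element = c("N", "C", "C", "C"),
    residue_index = c(37L, 110L, 110L, 119L),
    residue_name = c("LYS", "VAL", "VAL", "THR"),
    segment_id = c("H3", "LH", "LH", "LH"), stringsAsFactors = FALSE)
  coords <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 12, 0), c(0, 0, 7))
  fr <- structure_frame(atoms, coords)
  probe <- probe_spec("H3", 37, "NZ")
  targets <- data.frame(segment = c("LH", "LH"), residue = c(110L, 119L))
  d <- probe_methyl_distances(fr, probe, targets)
  expect_equal(d$r_methyl_a, c(10, 7))
  expect_equal(d$r_methyl_b, c(12, NA))
  expect_equal(d$single_methyl, c(FALSE, TRUE))
  expect_error(probe_methyl_distances(fr, probe_spec("H3", 99, "NZ"), targets),
               class = "probe_resolution_error")
  # random toy structure vs brute-force distances
  set.seed(4)
  n <- 8
  atoms2 <- data.frame(
    atom_name = rep(c("CG1", "CG2"), n), element = "C",
    residue_index = rep(seq_len(n), each = 2), residue_name = "VAL",
    segment_id = "LH", stringsAsFactors = FALSE)
  atoms2 <- rbind(atoms2, data.frame(atom_name = "NZ", element = "N",
                                     residue_index = 37L,
                                     residue_name = "LYS",
                                     segment_id = "H3"))
  crd <- matrix(runif(3 * nrow(atoms2), 0, 30), ncol = 3)
  fr2 <- structure_frame(atoms2, crd)
  d2 <- probe_methyl_distances(fr2, probe_spec("H3", 37, "NZ"),
                               data.frame(segment = "LH",
                                          residue = seq_len(n)))
  p <- crd[nrow(crd), ]
  for (i in seq_len(n)) {
    expect_equal(d2$r_methyl_a[i], sqrt(sum((crd[2 * i - 1, ] - p)^2)),
                 tolerance = 1e-12)
    expect_equal(d2$r_methyl_b[i], sqrt(sum((crd[2 * i, ] - p)^2)),
                 tolerance = 1e-12)
  }
})

test_that("ensemble averaging is ratio-of-frames, not ratio-of-mean-distance", {
  pp <- pre_parameters()
  r1 <- 15; r2 <- 35
  prof <- pre_profile_from_distances(matrix(c(r1, r2), 2, 1), residues = 1L,
                                     params = pp)
  hand <- (ratio_from_distance(r1, pp) + ratio_from_distance(r2, pp)) / 2
  expect_equal(prof$ratio_mean, hand, tolerance = 1e-12)
  wrong <- ratio_from_distance((r1 + r2) / 2, pp)
  expect_gt(abs(prof$ratio_mean - wrong), 0.01)
})

test_that("single-frame and identical-frame ensembles collapse the CI", {
  pp <- pre_parameters()
  one <- pre_profile_from_distances(matrix(c(20, 25), 1), residues = 1:2,
                                    params = pp)
  expect_identical(attr(one, "source"), "single-structure")
  expect_equal(one$ci80_low, one$ratio_mean)
  expect_equal(one$ci80_high, one$ratio_mean)
  many <- pre_profile_from_distances(matrix(20, 50, 1), residues = 1L,
                                     params = pp)
  expect_identical(attr(many, "source"), "ensemble")
  expect_equal(many$ci80_high - many$ci80_low, 0)
})

test_that("predict_pre_profile runs the trajectory pipeline end to end", {
  atoms <- data.frame(
    atom_name = c("NZ", "CG1", "CG2"), element = c("N", "C", "C"),
    residue_index = c(37L, 50L, 50L), residue_name = c("LYS", "VAL", "VAL"),
    segment_id = c("H3", "LH", "LH"), stringsAsFactors = FALSE)
  c1 <- rbind(c(0, 0, 0), c(20, 0, 0), c(0, 22, 0))
  c2 <- rbind(c(0, 0, 0), c(24, 0, 0), c(0, 26, 0))
  tr <- trajectory(structure_frame(atoms, c1), list(c1, c2))
  pp <- pre_parameters()
  prof <- predict_pre_profile(tr, probe_spec("H3", 37, "NZ"),
                              data.frame(segment = "LH", residue = 50L), pp)
  hand <- mean(c((ratio_from_distance(20, pp) + ratio_from_distance(22, pp)) / 2,
                 (ratio_from_distance(24, pp) + ratio_from_distance(26, pp)) / 2))
  expect_equal(prof$ratio_mean, hand, tolerance = 1e-12)
})

test_that("compare_to_experiment: identity, constructed shift, arithmetic oracle", {
  pp <- pre_parameters()
  td <- data.frame(residue_index = 1:10, r_a = seq(12, 40, length.out = 10),
                   r_b = seq(13, 41, length.out = 10))
  ds <- make_pre_dataset(td, pp, noise_sd = 0, n_frames = 5, seed = 1)
  prof <- pre_profile_from_distances(ds$r_a, ds$r_b, td$residue_index, pp)
  cmp <- compare_to_experiment(prof, ds$experimental)
  expect_equal(cmp$mean_signed_error, 0)
  expect_equal(cmp$mean_absolute_error, 0)
  expect_equal(cmp$fraction_within_ci, 1)
  # uniform +0.05 shift of predictions
  shifted <- prof
  shifted$ratio_mean <- prof$ratio_mean + 0.05
  cmp2 <- compare_to_experiment(shifted, ds$experimental)
  expect_equal(cmp2$mean_signed_error, 0.05, tolerance = 1e-12)
  expect_equal(cmp2$mean_absolute_error, 0.05, tolerance = 1e-12)
  # random tables vs arithmetic oracle; partial overlap bookkeeping
  set.seed(6)
  pred <- pre_profile_from_distances(
    matrix(runif(10, 15, 40), 1), residues = 1:10, params = pp)
  ex <- data.frame(residue_index = 6:15, ratio = runif(10))
  cmp3 <- compare_to_experiment(pred, ex)
  common <- 6:10
  oracle <- pred$ratio_mean[common] - ex$ratio[match(common, ex$residue_index)]
  expect_equal(cmp3$mean_signed_error, mean(oracle), tolerance = 1e-12)
  expect_equal(cmp3$mean_absolute_error, mean(abs(oracle)), tolerance = 1e-12)
  expect_equal(cmp3$only_predicted, 1:5)
  expect_equal(cmp3$only_experimental, 11:15)
  expect_error(compare_to_experiment(pred,
                                     data.frame(residue_index = 90:95,
                                                ratio = 0.5)),
               class = "no_overlap")
})
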