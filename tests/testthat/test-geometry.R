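test_that("vector_angle: trivial cases, atan2 oracle, zero-vector error", {
  expect_equal(vector_angle(c(1, 0, 0), c(1, 0, 0)), 0)
  expect_equal(vector_angle(c(1, 0, 0), c(0, 1, 0)), 90)
  expect_error(vector_angle(c(0, 0, 0), c(1, 0, 0)),
               class = "degenerate_geometry")
  # independent oracle: atan2(|u x v|, u.v), a different numerical path
  set.seed(7)
  for (i in 1:1000) {
    u <- rnorm(3); v <- rnorm(3)
    cr <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
            u[1] * v[2] - u[2] * v[1])
    oracle <- atan2(sqrt(sum(cr^2)), sum(u * v)) * 180 / pi
    expect_lt(abs(vector_angle(u, v) - oracle), 1e-9)
  }
})

test_that("phi angles: parallel/perpendicular constructions and analytic case", {
  # beta_sheet axis along x; alpha1 axis along y; alpha3 at origin
  mk_frame <- function(loop_dir) {
    atoms <- data.frame(
      atom_name = "CA", element = "C",
      residue_index = 1:40, residue_name = "ALA",
      segment_id = rep(c("A1", "A3", "BL", "BS"), each = 10),
      stringsAsFactors = FALSE)
    a1 <- cbind(0, seq(0, 9) * 1.5, 0) + 50        # alpha1 along +y
    a3 <- matrix(rnorm(30, 0, 0.01), 10)           # blob at origin
    bl <- sweep(matrix(rnorm(30, 0, 0.01), 10), 2, 20 * loop_dir, "+")
    bs <- cbind(seq(0, 9) * 1.5, 0, 0) - 30        # beta_sheet along +x
    trajectory(structure_frame(atoms, rbind(a1, a3, bl, bs)),
               list(rbind(a1, a3, bl, bs)))
  }
  groups <- list(alpha1 = 1:10, alpha3 = 11:20, beta_loop = 21:30,
                 beta_sheet = 31:40)
  set.seed(1)
  # loop along +x: parallel to beta-sheet axis -> phi2 ~ 0
  r <- compute_phi_angles(mk_frame(c(1, 0, 0)), groups)
  expect_lt(r$phi2[1], 0.2)
  # loop along +x: perpendicular to alpha1 (y) -> phi1 ~ 90
  expect_lt(abs(r$phi1[1] - 90), 0.2)
  # constructed analytic angle of 52.6 deg to the beta-sheet axis
  th <- 52.6 * pi / 180
  r2 <- compute_phi_angles(mk_frame(c(cos(th), sin(th), 0)), groups)
  expect_lt(abs(r2$phi2[1] - 52.6), 0.05)
  # degenerate group
  expect_error(compute_phi_angles(mk_frame(c(1, 0, 0)),
                                  modifyList(groups, list(alpha1 = 1:2))),
               class = "degenerate_geometry")
})

test_that("nucleosomal plane: flat layout, handedness, rotation equivariance", {
  # C1' ring in z = 0
  th <- seq(0.2, 2 * pi - 0.2, length.out = 40)
  coords <- cbind(10 * cos(th), 10 * sin(th), 0)
  q <- as.character(cut(th, c(0, pi / 2, pi, 3 * pi / 2, 2 * pi),
                        labels = c("Q1", "Q2", "Q3", "Q4")))
  dyad <- which.min(abs(th - pi))
  pl <- define_nucleosomal_plane(coords, seq_along(th), q, c("Q3", "Q2"), dyad)
  expect_equal(abs(sum(pl$normal * c(0, 0, 1))), 1, tolerance = 1e-12)
  expect_equal(sqrt(sum(pl$normal^2)), 1, tolerance = 1e-12)
  # constructed: quadrant COMs at (1,0,0),(0,1,0), dyad at origin -> +z
  single <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 0))
  pl2 <- define_nucleosomal_plane(single, 1:3, c("A", "B", "D"),
                                  c("A", "B"), 3)
  expect_equal(pl2$normal, c(0, 0, 1))
  # equivariance under a rigid rotation
  set.seed(5)
  for (i in 1:20) {
    R <- random_rotation(); tsl <- rnorm(3, 0, 20)
    plR <- define_nucleosomal_plane(sweep(coords %*% t(R), 2, tsl, "+"),
                                    seq_along(th), q, c("Q3", "Q2"), dyad)
    expect_lt(max(abs(plR$normal - drop(R %*% pl$normal))), 1e-9)
  }
  # collinear degenerate case
  line <- cbind(1:3, 0, 0)
  expect_error(define_nucleosomal_plane(line, 1:3, c("A", "B", "D"),
                                        c("A", "B"), 3),
               class = "degenerate_plane")
})

test_that("linker angles: in-plane arm, normal-aligned arm, mirror antisymmetry", {
  sim <- make_toy_chromatosome(toy_chromatosome_params(
    alpha_entry = 20, alpha_exit = 35, beta_entry = 0, beta_exit = 25,
    seed = 2))
  a_e <- compute_linker_angles(sim$trajectory, sim$config$plane_spec,
                               sim$config$arm_entry)
  a_x <- compute_linker_angles(sim$trajectory, sim$config$plane_spec,
                               sim$config$arm_exit)
  # arm in plane -> beta = 0
  expect_equal(a_e$beta[1], 0, tolerance = 1e-6)
  expect_equal(a_e$alpha[1], 20, tolerance = 1e-6)
  expect_equal(a_x$alpha[1], 35, tolerance = 1e-6)
  expect_equal(a_x$beta[1], 25, tolerance = 1e-6)
  # mirror through the plane flips beta's sign, keeps magnitude
  simm <- make_toy_chromatosome(toy_chromatosome_params(
    alpha_entry = 20, alpha_exit = 35, beta_entry = 0, beta_exit = -25,
    seed = 2))
  a_xm <- compute_linker_angles(simm$trajectory, simm$config$plane_spec,
                                simm$config$arm_exit)
  expect_equal(a_xm$beta[1], -a_x$beta[1], tolerance = 1e-6)
  expect_equal(a_xm$alpha[1], a_x$alpha[1], tolerance = 1e-6)
})

test_that("arm along the plane normal gives beta = +90 and alpha = NA", {
  sim <- make_toy_chromatosome(toy_chromatosome_params(seed = 1))
  topo <- sim$trajectory$topology
  X <- sim$trajectory$frames[[1]]
  # move the entry-arm terminal bp straight above its origin bp
  oi <- sim$config$arm_entry$origin$indices
  ti <- sim$config$arm_entry$terminal$indices
  org <- colMeans(X[oi, , drop = FALSE])
  X[ti, ] <- matrix(rep(org, each = length(ti)), length(ti)) +
    cbind(c(0.5, -0.5), 0, 50)
  tr <- trajectory(topo, list(X))
  r <- compute_linker_angles(tr, sim$config$plane_spec, sim$config$arm_entry)
  expect_equal(r$beta[1], 90, tolerance = 0.6)
  expect_true(is.na(r$alpha[1]) || abs(r$beta[1] - 90) > 1e-6)
})

test_that("end_to_end_distance: 3-4-5 triangle, self-distance, formula oracle", {
  tr <- two_atom_traj(0, nf = 1)
  tr$frames[[1]] <- rbind(c(0, 0, 0), c(3, 4, 0))
  expect_equal(end_to_end_distance(tr, 1, 2), 5)
  expect_equal(end_to_end_distance(tr, 1, 1), 0)
  set.seed(9)
  sim <- make_toy_chromatosome(toy_chromatosome_params(
    n_frames = 4L, coordinate_noise_sd = 0.5, seed = 9))
  selA <- sim$config$arm_entry$terminal$indices
  selB <- sim$config$arm_exit$terminal$indices
  d <- end_to_end_distance(sim$trajectory, selA, selB)
  oracle <- vapply(sim$trajectory$frames, function(X)
    sqrt(sum((colMeans(X[selA, , drop = FALSE]) -
                colMeans(X[selB, , drop = FALSE]))^2)), numeric(1))
  expect_equal(d, oracle, tolerance = 1e-9)
})

test_that("contacts: 3.9 in / 4.1 out at the 4.0 A default, brute-force oracle", {
  t_in <- two_atom_traj(3.9, nf = 10)
  ct <- contact_table(t_in, 1, 2)
  expect_equal(ct$pairs$fraction, 1.0)
  t_out <- two_atom_traj(4.1, nf = 10)
  ct2 <- contact_table(t_out, 1, 2)
  expect_equal(nrow(ct2$pairs), 0L)
  expect_equal(ct2$per_frame_total, rep(0L, 10))
  expect_error(contact_table(t_in, 1, 2, cutoff = -1),
               class = "parameter_error")
  # 50-atom random system, 5 frames vs O(N^2) oracle
  set.seed(13)
  rs <- random_structure(25, box = 12)      # 50 atoms
  frames <- replicate(5, rs$coords + matrix(rnorm(150, 0, 0.5), ncol = 3),
                      simplify = FALSE)
  tr <- trajectory(rs, frames)
  selA <- which(rs$atoms$residue_index <= 12)
  selB <- which(rs$atoms$residue_index > 12)
  ct3 <- contact_table(tr, selA, selB, cutoff = 4.0)
  # oracle: explicit loops
  resA <- unique(rs$atoms$residue_index[selA])
  resB <- unique(rs$atoms$residue_index[selB])
  oracle <- matrix(0L, length(resA), length(resB),
                   dimnames = list(resA, resB))
  tot <- integer(5)
  for (m in 1:5) {
    X <- frames[[m]]
    for (ra in resA) for (rb in resB) {
      ia <- selA[rs$atoms$residue_index[selA] == ra]
      ib <- selB[rs$atoms$residue_index[selB] == rb]
      hit <- FALSE
      for (i in ia) for (j in ib)
        if (sqrt(sum((X[i, ] - X[j, ])^2)) <= 4.0) hit <- TRUE
      if (hit) {
        oracle[as.character(ra), as.character(rb)] <-
          oracle[as.character(ra), as.character(rb)] + 1L
        tot[m] <- tot[m] + 1L
      }
    }
  }
  expect_equal(ct3$per_frame_total, tot)
  for (k in seq_len(nrow(ct3$pairs))) {
    expect_equal(ct3$pairs$frames_in_contact[k],
                 oracle[ct3$pairs$residue_a[k], ct3$pairs$residue_b[k]])
  }
  expect_equal(sum(ct3$pairs$frames_in_contact), sum(oracle))
})

test_that("rmsd: identity, rigid rotation, known offsets; fitting reduces RMSD", {
  set.seed(21)
  rs <- random_structure(10)
  ref <- rs
  idx <- seq_len(n_atoms(ref))
  # identical frame
  tr <- trajectory(rs, list(rs$coords))
  expect_equal(rmsd(tr, idx, idx, ref), 0, tolerance = 1e-9)
  # rigid rotation with fit = measure -> 0 after fitting
  R <- random_rotation()
  rot <- sweep(rs$coords %*% t(R), 2, c(5, -3, 2), "+")
  tr2 <- trajectory(rs, list(rot))
  expect_equal(rmsd(tr2, idx, idx, ref), 0, tolerance = 1e-9)
  # known per-atom offsets after alignment: fit on half, offset the rest
  fit_idx <- 1:10; meas_idx <- 11:20
  off <- matrix(0, n_atoms(ref), 3)
  off[meas_idx, 1] <- seq(0.1, 1.0, by = 0.1)
  tr3 <- trajectory(rs, list(rs$coords + off))
  expected <- sqrt(mean(seq(0.1, 1.0, by = 0.1)^2))
  expect_equal(rmsd(tr3, fit_idx, meas_idx, ref), expected, tolerance = 1e-9)
  # property: fitted RMSD <= unfitted RMSD
  for (i in 1:10) {
    X <- rs$coords + matrix(rnorm(3 * n_atoms(ref), 0, 1), ncol = 3)
    trp <- trajectory(rs, list(X))
    unfitted <- sqrt(mean(rowSums((X - ref$coords)^2)))
    expect_lte(rmsd(trp, idx, idx, ref), unfitted + 1e-12)
  }
})

test_that("angle/distance observables are rigid-body invariant", {
  set.seed(33)
  sim <- make_toy_chromatosome(toy_chromatosome_params(
    alpha_entry = 25, alpha_exit = 10, beta_entry = 5, beta_exit = -12,
    seed = 33))
  base <- sim$trajectory
  a0 <- compute_linker_angles(base, sim$config$plane_spec,
                              sim$config$arm_exit)
  d0 <- end_to_end_distance(base, sim$config$arm_entry$terminal$indices,
                            sim$config$arm_exit$terminal$indices)
  for (i in 1:10) {
    R <- random_rotation(); tsl <- rnorm(3, 0, 30)
    trR <- trajectory(base$topology, lapply(base$frames, function(X)
      sweep(X %*% t(R), 2, tsl, "+")))
    aR <- compute_linker_angles(trR, sim$config$plane_spec,
                                sim$config$arm_exit)
    expect_equal(aR$alpha, a0$alpha, tolerance = 1e-6)
    expect_equal(aR$beta, a0$beta, tolerance = 1e-6)
    dR <- end_to_end_distance(trR, sim$config$arm_entry$terminal$indices,
                              sim$config$arm_exit$terminal$indices)
    expect_equal(dR, d0, tolerance = 1e-9)
  }
})
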