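# Synthetic-data generators. Every generator is a pure function of its
# parameter record (seed included) and emits a machine-readable ground-truth
# record alongside the data, so every downstream analysis can be checked
# against known truth without MD trajectories.

#' Parameters for the toy chromatosome builder
#'
#' The toy system is a pseudo-atom chromatosome: C1'-labelled DNA on a
#' circular core path in the z = 0 plane (the flattened superhelix), two
#' straight linker-DNA arms leaving the core at prescribed in-plane (alpha)
#' and out-of-plane (beta) angles, and a linker-histone pseudo-domain (three
#' helix CA strings, a beta-sheet and a beta-loop) posed on- or off-dyad.
#' Geometry convention: the dyad base pair sits diametrically opposite the
#' linker gap; quadrants Q1-Q4 are 90-degree arcs and the two flanking the
#' dyad (Q3, Q2, in that order) are the distal quadrants defining the plane.
#'
#' @param n_bp_core core base pairs (default 147)
#' @param superhelix_radius core path radius, Angstrom (default 42)
#' @param alpha_entry,alpha_exit,beta_entry,beta_exit ground-truth linker
#'   angles, degrees
#' @param lh_pose "on_dyad", "off_dyad", or a numeric lateral offset in
#'   Angstrom
#' @param coordinate_noise_sd per-atom Gaussian jitter sd, Angstrom (>= 0)
#' @param n_frames frames to emit (>= 1)
#' @param n_bp_linker pseudo base pairs per linker arm (default 18)
#' @param linker_rise rise per linker base pair, Angstrom (default 3.4)
#' @param seed RNG seed
#' @return parameter record (class `ToyChromatosomeParams`)
#' @export
toy_chromatosome_params <- function(n_bp_core = 147L, superhelix_radius = 42,
                                    alpha_entry = 25, alpha_exit = 25,
                                    beta_entry = 0, beta_exit = 0,
                                    lh_pose = "on_dyad",
                                    coordinate_noise_sd = 0, n_frames = 1L,
                                    n_bp_linker = 18L, linker_rise = 3.4,
                                    seed = 1L) {
  if (n_frames < 1) ck_stop("parameter_error", "n_frames must be >= 1")
  if (coordinate_noise_sd < 0) ck_stop("parameter_error", "noise sd < 0")
  if (superhelix_radius <= 0) ck_stop("parameter_error", "radius must be > 0")
  structure(as.list(environment()), class = "ToyChromatosomeParams")
}

# rotate the in-plane anti-dyad direction about the normal and tilt out of
# plane: the inverse of the decomposition in compute_linker_angles()
.arm_direction <- function(alpha, beta, side, n, d_anti) {
  s <- if (side == "entry") -1 else 1
  e <- cross3(n, d_anti)
  a <- s * alpha * pi / 180; b <- beta * pi / 180
  cos(b) * (cos(a) * d_anti + sin(a) * e) + sin(b) * n
}

#' Build a toy chromatosome trajectory with known linker-angle truth
#'
#' See [toy_chromatosome_params()] for the geometry. Returns the trajectory,
#' a ground-truth record (the prescribed angles, pose and seed) and a
#' companion analysis config carrying the selection expressions, per-atom
#' quadrant assignment and arm specs that [compute_linker_angles()] needs.
#' Deterministic given the seed. An arm whose prescribed angles would fold
#' it back across the core plane axis (|beta| >= 90) is rejected.
#'
#' @param params a [toy_chromatosome_params()]
#' @return list: `trajectory`, `truth`, `config`
#' @export
make_toy_chromatosome <- function(params) {
  stopifnot(inherits(params, "ToyChromatosomeParams"))
  p <- params
  for (ang in c(p$alpha_entry, p$alpha_exit))
    if (abs(ang) >= 180) ck_stop("construction_error", "|alpha| must be < 180")
  for (ang in c(p$beta_entry, p$beta_exit))
    if (abs(ang) >= 90)
      ck_stop("construction_error",
              "|beta| >= 90 would fold the arm through the plane normal")
  R <- p$superhelix_radius
  gap_half <- 10 * pi / 180                 # linker gap spans +-10 deg
  theta <- seq(gap_half, 2 * pi - gap_half, length.out = p$n_bp_core)
  # two C1' strands per bp, radius +-0.5 A, in the z = 0 plane
  core_xy <- cbind(cos(theta), sin(theta))
  mk_strand <- function(rad, seg, res0) {
    list(atoms = data.frame(atom_name = "C1'", element = "C",
                            residue_index = res0 + seq_along(theta) - 1L,
                            residue_name = "DA", segment_id = seg,
                            stringsAsFactors = FALSE),
         coords = cbind(rad * core_xy, 0))
  }
  sI <- mk_strand(R + 0.5, "DNAI", 1L)
  sJ <- mk_strand(R - 0.5, "DNAJ", 1L)
  # quadrants: Q1 gap-adjacent (+), Q2/Q3 flank the dyad, Q4 gap-adjacent (-)
  qlab <- cut(theta, breaks = c(0, pi / 2, pi, 3 * pi / 2, 2 * pi),
              labels = c("Q1", "Q2", "Q3", "Q4"), include.lowest = TRUE)
  qlab <- as.character(qlab)
  dyad_bp <- which.min(abs(theta - pi))     # bp nearest the dyad

  # analytic plane of the ideal construction (independent of the analyzer's
  # per-frame COM recomputation)
  n_hat <- c(0, 0, 1)
  com_arc <- function(sel) centre_of_mass(rbind(sI$coords[sel, , drop = FALSE],
                                                sJ$coords[sel, , drop = FALSE]))
  p1 <- com_arc(qlab == "Q3"); p2 <- com_arc(qlab == "Q2")
  p3 <- com_arc(seq_along(theta) == dyad_bp)
  d_anti <- unit3((p1 + p2) / 2 - p3)
  d_anti <- unit3(d_anti - sum(d_anti * n_hat) * n_hat)

  mk_arm <- function(side, alpha, beta, seg) {
    th0 <- if (side == "entry") gap_half else 2 * pi - gap_half
    origin <- R * c(cos(th0), sin(th0), 0)
    v <- .arm_direction(alpha, beta, side, n_hat, d_anti)
    # a perpendicular for the two-strand offset
    perp <- unit3(cross3(v, n_hat + c(0.01, 0, 0)))
    nres <- p$n_bp_linker + 1L
    pos <- t(vapply(seq_len(nres) - 1L, function(j)
      origin + j * p$linker_rise * v, numeric(3)))
    coords <- rbind(sweep(pos, 2, 0.5 * perp, "+"),
                    sweep(pos, 2, 0.5 * perp, "-"))
    list(atoms = data.frame(atom_name = "C1'", element = "C",
                            residue_index = rep(seq_len(nres), 2L),
                            residue_name = "DA",
                            segment_id = seg, stringsAsFactors = FALSE),
         coords = coords)
  }
  arm_e <- mk_arm("entry", p$alpha_entry, p$beta_entry, "LNE")
  arm_x <- mk_arm("exit", p$alpha_exit, p$beta_exit, "LNX")

  # linker-histone pseudo-domain near the gap (where the dyad axis crosses
  # the linker side); off-dyad slides it ~5 bp along the core path
  lh_angle <- if (identical(p$lh_pose, "on_dyad")) 0 else
    if (identical(p$lh_pose, "off_dyad")) 25 * pi / 180 else NA
  lh_centre <- if (is.na(lh_angle)) {
    c(R + 12, as.numeric(p$lh_pose), 4)
  } else {
    c((R + 12) * cos(lh_angle), (R + 12) * sin(lh_angle), 4)
  }
  mk_chain <- function(n, start, step, seg, res0, name = "CA",
                       resname = "ALA") {
    pos <- t(vapply(seq_len(n) - 1L, function(j) start + j * step, numeric(3)))
    list(atoms = data.frame(atom_name = name, element = "C",
                            residue_index = res0 + seq_len(n) - 1L,
                            residue_name = resname, segment_id = seg,
                            stringsAsFactors = FALSE),
         coords = pos)
  }
  lh <- list(
    mk_chain(11, lh_centre + c(0, -8, 0), c(1.5, 0, 0), "LH", 1L),    # alpha1
    mk_chain(11, lh_centre + c(8, 8, 0), c(0, 1.5, 0), "LH", 21L),    # alpha2
    mk_chain(11, lh_centre + c(-8, 0, 2), c(0, 0, 1.5), "LH", 41L),   # alpha3
    mk_chain(10, lh_centre + c(0, 0, 6), c(1.2, 0.6, 0), "LH", 61L),  # sheet
    mk_chain(4, lh_centre + c(5, 3, 8), c(0.8, -0.8, 0.5), "LH", 81L) # loop
  )
  parts <- c(list(sI, sJ, arm_e, arm_x), lh)
  atoms <- do.call(rbind, lapply(parts, `[[`, "atoms"))
  base <- do.call(rbind, lapply(parts, `[[`, "coords"))
  topo <- structure_frame(atoms, base)

  set.seed(p$seed)
  frames <- lapply(seq_len(p$n_frames), function(m) {
    base + if (p$coordinate_noise_sd > 0)
      matrix(stats::rnorm(length(base), 0, p$coordinate_noise_sd),
             nrow(base)) else 0
  })
  traj <- trajectory(topo, frames)

  c1p_core <- which(atoms$segment_id %in% c("DNAI", "DNAJ"))
  quadrants <- rep(qlab, 2L)
  # dyad bp: one C1' per strand (sI rows come first, then sJ)
  dyad_idx <- c(dyad_bp, length(theta) + dyad_bp)
  nres_arm <- p$n_bp_linker + 1L
  cfg <- list(
    plane_spec = list(c1p = c1p_core, quadrants = quadrants,
                      distal_quadrants = c("Q3", "Q2"),
                      dyad = dyad_idx),
    arm_entry = list(origin = resolve_selection(topo, "segid LNE and resid 1"),
                     terminal = resolve_selection(
                       topo, sprintf("segid LNE and resid %d", nres_arm)),
                     side = "entry"),
    arm_exit = list(origin = resolve_selection(topo, "segid LNX and resid 1"),
                    terminal = resolve_selection(
                      topo, sprintf("segid LNX and resid %d", nres_arm)),
                    side = "exit"),
    lh_groups = list(alpha1 = resolve_selection(topo, "segid LH and resid 1-11"),
                     alpha3 = resolve_selection(topo, "segid LH and resid 41-51"),
                     beta_sheet = resolve_selection(topo,
                                                    "segid LH and resid 61-70"),
                     beta_loop = resolve_selection(topo,
                                                   "segid LH and resid 81-84")))
  truth <- list(alpha_entry = p$alpha_entry, alpha_exit = p$alpha_exit,
                beta_entry = p$beta_entry, beta_exit = p$beta_exit,
                lh_pose = p$lh_pose, seed = p$seed,
                coordinate_noise_sd = p$coordinate_noise_sd)
  list(trajectory = traj, truth = truth, config = cfg)
}

#' Synthetic 1-D potential for umbrella-sampling tests
#'
#' Forms: `"harmonic"` (`0.5 * k0 * (x - x0)^2`), `"double_well"`
#' (quartic `barrier * ((x - centre)^2 - w^2)^2 / w^4` with minima at
#' `centre +- w` and the stated barrier at the centre), or `"tabulated"`
#' (linear interpolation of `x`/`y`).
#'
#' @param form potential form
#' @param temperature K
#' @param k0,x0 harmonic parameters (kcal/mol/deg^2, deg)
#' @param barrier,minima double-well barrier (kcal/mol) and the two minima
#'   locations (deg)
#' @param x,y tabulated abscissa/ordinate
#' @return object of class `SyntheticPotential`: callable `U(xi)`, fields
#' @export
synthetic_potential <- function(form = c("double_well", "harmonic",
                                         "tabulated"),
                                temperature = 300, k0 = 0.02, x0 = 80,
                                barrier = 3.0, minima = c(60, 100),
                                x = NULL, y = NULL) {
  form <- match.arg(form)
  U <- switch(form,
    harmonic = function(xi) 0.5 * k0 * (xi - x0)^2,
    double_well = {
      centre <- mean(minima); w <- diff(minima) / 2
      function(xi) barrier * ((xi - centre)^2 - w^2)^2 / w^4
    },
    tabulated = {
      if (is.null(x) || is.null(y))
        ck_stop("parameter_error", "tabulated potential needs x and y")
      function(xi) stats::approx(x, y, xi, rule = 2)$y
    })
  structure(list(form = form, U = U, temperature = temperature,
                 barrier = if (form == "double_well") barrier else NA,
                 minima = if (form == "double_well") minima else NA),
            class = "SyntheticPotential")
}

#' Sample correlated umbrella-window time series from a known potential
#'
#' Per window the biased density `exp(-[U(xi) + k (xi - c)^2] / kT)` is
#' tabulated on a fine grid and sampled through a Gaussian AR(1) copula:
#' a standard AR(1) series with coefficient `ar1_rho` is mapped through the
#' normal CDF and the biased inverse CDF, giving samples with the exact
#' biased marginal and lag-1 autocorrelation approximately `ar1_rho`
#' (`ar1_rho = 0` is iid). The ground-truth PMF (U shifted to minimum 0 on
#' the window range) is emitted alongside.
#'
#' @param potential a [synthetic_potential()]
#' @param centers window centres, degrees
#' @param force_constant k, kcal/mol/deg^2 (bias `k (xi-c)^2`, no 1/2)
#' @param n_per_window samples per window
#' @param ar1_rho target lag-1 autocorrelation in \[0, 1)
#' @param seed RNG seed
#' @param grid_points inverse-CDF grid resolution
#' @return list: `windows` (list of [umbrella_window()]s), `truth`
#'   (`xi`, `pmf` ground truth), `seed`
#' @export
sample_umbrella_windows <- function(potential, centers, force_constant,
                                    n_per_window = 2000L, ar1_rho = 0,
                                    seed = 1L, grid_points = 4001L) {
  stopifnot(inherits(potential, "SyntheticPotential"))
  if (ar1_rho < 0 || ar1_rho >= 1)
    ck_stop("parameter_error", "ar1_rho must be in [0, 1)")
  kT <- KB_KCAL * potential$temperature
  span <- range(centers)
  pad <- max(4, 6 * sqrt(kT / (2 * force_constant)))
  grid <- seq(span[1] - pad, span[2] + pad, length.out = grid_points)
  set.seed(seed)
  windows <- lapply(centers, function(ct) {
    Ub <- potential$U(grid) + force_constant * (grid - ct)^2
    w <- exp(-(Ub - min(Ub)) / kT)
    cdf <- cumsum(w); cdf <- cdf / cdf[length(cdf)]
    # strictly increasing sub-grid for interpolation
    keep <- c(TRUE, diff(cdf) > 0)
    z <- stats::rnorm(n_per_window)
    if (ar1_rho > 0) {
      z <- stats::filter(z * sqrt(1 - ar1_rho^2), ar1_rho, "recursive",
                         init = stats::rnorm(1))
      z <- as.numeric(z)
    }
    u <- stats::pnorm(z)
    xs <- stats::approx(cdf[keep], grid[keep], xout = u, rule = 2)$y
    umbrella_window(ct, force_constant, xs)
  })
  xi <- seq(span[1], span[2], length.out = 401)
  pmf <- potential$U(xi); pmf <- pmf - min(pmf)
  list(windows = windows, truth = list(xi = xi, pmf = pmf), seed = seed)
}

#' Synthetic PRE dataset with known distance truth
#'
#' "Experimental" ratios are the model ratios of the true distances plus
#' Gaussian noise, clipped to \[0, 1\]; the ensemble is the true distances
#' jittered per frame.
#'
#' @param true_distances data.frame with `residue_index`, `r_a`, `r_b`
#'   (Angstrom; `r_b` may be NA)
#' @param params a [pre_parameters()]
#' @param noise_sd experimental noise sd on the ratio scale (>= 0)
#' @param n_frames ensemble frames
#' @param frame_jitter_sd per-frame distance jitter sd, Angstrom
#' @param seed RNG seed
#' @return list: `r_a`, `r_b` (frames x residues matrices), `experimental`
#'   (data.frame `residue_index`, `ratio`, `error`), `truth`
#' @export
make_pre_dataset <- function(true_distances, params = pre_parameters(),
                             noise_sd = 0.05, n_frames = 50L,
                             frame_jitter_sd = 0, seed = 1L) {
  if (any(true_distances$r_a <= 0, na.rm = TRUE) ||
        any(true_distances$r_b <= 0, na.rm = TRUE))
    ck_stop("parameter_error", "distances must be > 0")
  set.seed(seed)
  nres <- nrow(true_distances)
  jit <- function(r) {
    m <- matrix(rep(r, each = n_frames), n_frames, nres)
    if (frame_jitter_sd > 0)
      m <- abs(m + matrix(stats::rnorm(length(m), 0, frame_jitter_sd),
                          n_frames))
    m
  }
  r_a <- jit(true_distances$r_a)
  r_b <- if (all(is.na(true_distances$r_b))) NULL else
    jit(true_distances$r_b)
  true_ratio_a <- ratio_from_distance(true_distances$r_a, params)
  true_ratio <- if (is.null(r_b)) true_ratio_a else
    (true_ratio_a + ratio_from_distance(true_distances$r_b, params)) / 2
  exp_ratio <- true_ratio + if (noise_sd > 0)
    stats::rnorm(nres, 0, noise_sd) else 0
  exp_ratio <- pmin(pmax(exp_ratio, 0), 1)
  list(r_a = r_a, r_b = r_b,
       experimental = data.frame(residue_index = true_distances$residue_index,
                                 ratio = exp_ratio, error = noise_sd),
       truth = list(true_ratio = true_ratio, noise_sd = noise_sd,
                    seed = seed))
}

#' Synthetic per-frame MM/GBSA energy tables
#'
#' Independent Gaussian rows per role; totals are the row-wise component
#' sums. Mean magnitudes default to the scale of chromatosome MM/GBSA
#' decompositions (hundreds to thousands of kcal/mol per role).
#'
#' @param means named list role -> named numeric
#'   `c(E_internal=, E_elec=, E_vdw=)`
#' @param sds like `means`, standard deviations
#' @param n_frames frames per role
#' @param seed RNG seed
#' @return list of three `EnergyTable`s (`complex`, `receptor`, `ligand`)
#'   plus `truth` (implied binding means per component)
#' @export
make_energy_tables <- function(means, sds, n_frames = 200L, seed = 1L) {
  roles <- c("complex", "receptor", "ligand")
  if (!all(roles %in% names(means)) || !all(roles %in% names(sds)))
    ck_stop("parameter_error", "means and sds must name all three roles")
  set.seed(seed)
  tabs <- lapply(roles, function(role) {
    m <- means[[role]][.E_COMPONENTS]; s <- sds[[role]][.E_COMPONENTS]
    if (any(s < 0)) ck_stop("parameter_error", "sds must be >= 0")
    df <- as.data.frame(lapply(seq_along(.E_COMPONENTS), function(i)
      stats::rnorm(n_frames, m[i], s[i])))
    names(df) <- .E_COMPONENTS
    energy_table(df, role)
  })
  names(tabs) <- roles
  truth <- sapply(.E_COMPONENTS, function(cp)
    means$complex[[cp]] - means$receptor[[cp]] - means$ligand[[cp]])
  truth <- c(truth, E_total = sum(truth))
  c(tabs, list(truth = truth))
}

#' Synthetic two-state CA trajectory for clustering tests
#'
#' Frames scatter around two reference pseudo-structures whose
#' `measure`-selection RMSD equals `inter_state_rmsd`; within-state spread is
#' isotropic Gaussian with sd `intra_state_sd` per coordinate. A rigid
#' "core" block shared by both states supports fit-then-measure analyses.
#'
#' @param n_frames total frames
#' @param state_fractions length-2, sums to 1
#' @param inter_state_rmsd Angstrom between state references (measure sel)
#' @param intra_state_sd per-coordinate Gaussian sd, Angstrom
#' @param n_atoms mobile (measure) atoms per state reference
#' @param seed RNG seed
#' @return list: `trajectory`, `labels` (true state per frame), `fit_sel`,
#'   `measure_sel` (index vectors), `seed`
#' @export
make_two_state_trajectory <- function(n_frames = 100L,
                                      state_fractions = c(0.5, 0.5),
                                      inter_state_rmsd = 5,
                                      intra_state_sd = 0.3, n_atoms = 20L,
                                      seed = 1L) {
  if (abs(sum(state_fractions) - 1) > 1e-9)
    ck_stop("parameter_error", "state_fractions must sum to 1")
  set.seed(seed)
  n_core <- 12L
  core <- cbind(stats::runif(n_core, -10, 10), stats::runif(n_core, -10, 10),
                stats::runif(n_core, -10, 10))
  base <- cbind(stats::runif(n_atoms, -8, 8), stats::runif(n_atoms, -8, 8),
                stats::runif(n_atoms, 12, 20))
  shift <- matrix(stats::rnorm(3 * n_atoms), n_atoms)
  shift <- shift / sqrt(mean(rowSums(shift^2))) * inter_state_rmsd
  refs <- list(base, base + shift)
  n1 <- round(n_frames * state_fractions[1])
  labels <- c(rep(1L, n1), rep(2L, n_frames - n1))
  atoms <- data.frame(
    atom_name = "CA", element = "C",
    residue_index = seq_len(n_core + n_atoms),
    residue_name = "ALA",
    segment_id = rep(c("CORE", "LH"), c(n_core, n_atoms)),
    stringsAsFactors = FALSE)
  frames <- lapply(labels, function(st) {
    mob <- refs[[st]] + matrix(stats::rnorm(3 * n_atoms, 0, intra_state_sd),
                               n_atoms)
    rbind(core, mob)
  })
  topo <- structure_frame(atoms, frames[[1]])
  list(trajectory = trajectory(topo, frames), labels = labels,
       fit_sel = seq_len(n_core), measure_sel = n_core + seq_len(n_atoms),
       seed = seed)
}
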