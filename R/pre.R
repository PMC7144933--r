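#' PRE model parameters
#'
#' Constants of the condensed intensity-ratio model
#' `I_ox/I_red = exp(-beta (r+d)^-6) / (1 + alpha (r+d)^-6)`, with the
#' defaults `alpha = 4.5e8`, `beta = 3.4e7` and `d = 9.0` Angstrom
#' (a calibration offset). Note the negative exponent: as printed in some
#' sources the exponent is positive, which is non-physical (the ratio would
#' diverge at short distance instead of vanishing); the implemented form has
#' the correct limits, ratio -> 1 far from the probe and -> 0 near it.
#'
#' An optional physical parameter set `(K, tau_c, omega_h, R2, t_evol)` lets
#' the same ratio be computed from the two-equation relaxation model
#' (`R2sp = K C(tau_c, omega_h) r^-6`; ratio
#' `= R2 exp(-R2sp t) / (R2 + R2sp)`), and lets condensed constants be
#' regenerated via [derive_condensed_constants()].
#'
#' @param alpha_const dimensionless (> 0), for r in Angstrom
#' @param beta_const dimensionless (> 0), for r in Angstrom
#' @param d_offset Angstrom (>= 0)
#' @param physical optional list with `K` (cm^6 s^-2), `tau_c` (s),
#'   `omega_h` (rad/s), `R2` (s^-1), `t_evol` (s)
#' @return object of class `PreParameters`
#' @export
pre_parameters <- function(alpha_const = 4.5e8, beta_const = 3.4e7,
                           d_offset = 9.0, physical = NULL) {
  if (alpha_const <= 0 || beta_const <= 0)
    ck_stop("parameter_error", "alpha_const and beta_const must be > 0")
  if (d_offset < 0) ck_stop("parameter_error", "d_offset must be >= 0")
  structure(list(alpha_const = alpha_const, beta_const = beta_const,
                 d_offset = d_offset, physical = physical),
            class = "PreParameters")
}

# spectral-density factor C = K * (4 tau_c + 3 tau_c / (1 + w^2 tau_c^2)),
# cm^6 s^-1; multiplied by r^-6 (r in cm) it gives R2sp in s^-1
.pre_C_cm6 <- function(ph) {
  ph$K * (4 * ph$tau_c + 3 * ph$tau_c / (1 + ph$omega_h^2 * ph$tau_c^2))
}

#' Regenerate condensed-model constants from physical parameters
#'
#' With `x = (r + d)^-6` (r in Angstrom), the relaxation model gives
#' `ratio = exp(-C' t x) / (1 + (C'/R2) x)` where `C'` is the spectral
#' factor converted to Angstrom^6 s^-1; hence `beta = C' t_evol` and
#' `alpha = C' / R2`.
#'
#' @param physical list as in [pre_parameters()]
#' @return list with `alpha_const`, `beta_const`
#' @export
derive_condensed_constants <- function(physical) {
  C_ang <- .pre_C_cm6(physical) * 1e48   # (1 cm = 1e8 Angstrom)^6
  list(alpha_const = C_ang / physical$R2,
       beta_const = C_ang * physical$t_evol)
}

#' PRE intensity ratio from a probe-methyl distance
#'
#' Strictly increasing in r, mapping \[0, Inf) into (0, 1\]; clamped to
#' \[0, 1\] against floating-point overshoot.
#'
#' @param r distance(s), Angstrom (>= 0); vectorized
#' @param params a [pre_parameters()]
#' @param mode `"condensed"` (single-equation constants) or `"physical"`
#'   (relaxation-rate model; requires `params$physical`)
#' @return ratio(s) in \[0, 1\]
#' @export
ratio_from_distance <- function(r, params = pre_parameters(),
                                mode = c("condensed", "physical")) {
  mode <- match.arg(mode)
  if (any(r < 0)) ck_stop("parameter_error", "distances must be >= 0")
  x <- (r + params$d_offset)^(-6)
  if (mode == "condensed") {
    out <- exp(-params$beta_const * x) / (1 + params$alpha_const * x)
  } else {
    ph <- params$physical
    if (is.null(ph)) ck_stop("parameter_error",
                             "physical mode needs params$physical")
    r2sp <- .pre_C_cm6(ph) * ((r + params$d_offset) * 1e-8)^(-6)
    out <- ph$R2 * exp(-r2sp * ph$t_evol) / (ph$R2 + r2sp)
  }
  pmin(pmax(out, 0), 1)
}

#' Invert the PRE ratio model (numerically)
#'
#' Bisection over r; round-trips distances in \[1, 60\] Angstrom to about
#' 1e-6.
#'
#' @param ratio ratio(s) in (0, 1)
#' @param params a [pre_parameters()]
#' @param interval search interval in Angstrom
#' @return distance(s), Angstrom
#' @export
ratio_to_distance <- function(ratio, params = pre_parameters(),
                              interval = c(0, 1e3)) {
  vapply(ratio, function(y) {
    if (y <= 0 || y >= 1)
      ck_stop("parameter_error", "ratio must lie strictly in (0, 1)")
    stats::uniroot(function(r) ratio_from_distance(r, params) - y,
                   interval = interval, tol = 1e-9)$root
  }, numeric(1))
}

#' Probe specification for PRE distance measurements
#'
#' Selects exactly one probe atom, e.g. the lysine terminal nitrogen (`NZ`)
#' for a K37-style probe or the threonine terminal methyl carbon (`CG2`) for
#' T119.
#'
#' @param segment segment id of the probe residue
#' @param residue residue index of the probe residue
#' @param atom_name probe atom name
#' @return object of class `ProbeSpec`
#' @export
probe_spec <- function(segment, residue, atom_name) {
  structure(list(segment = segment, residue = as.integer(residue),
                 atom_name = atom_name), class = "ProbeSpec")
}

# default methyl-carbon naming per residue type; two names = methyl-a/b
.METHYL_ATOMS <- list(LEU = c("CD1", "CD2"), VAL = c("CG1", "CG2"),
                      ILE = c("CG2", "CD1"), THR = "CG2", ALA = "CB",
                      MET = "CE")

.resolve_probe_atom <- function(frame, probe) {
  a <- frame$atoms
  i <- which(a$segment_id == probe$segment &
               a$residue_index == probe$residue &
               a$atom_name == probe$atom_name)
  if (length(i) != 1)
    ck_stop("probe_resolution_error",
            sprintf("probe rule %s/%d/%s resolves to %d atoms",
                    probe$segment, probe$residue, probe$atom_name, length(i)))
  i
}

#' Distances from a probe atom to target methyl carbons
#'
#' For each target residue, the Euclidean distances from the probe atom to
#' its methyl-a and methyl-b carbons. Residues with a single methyl get one
#' distance and a flag (`single_methyl = TRUE`, `r_methyl_b = NA`).
#'
#' @param frame a `StructureFrame`
#' @param probe a [probe_spec()]
#' @param targets data.frame with columns `segment`, `residue` (and
#'   optionally `methyl_a`, `methyl_b` atom-name overrides)
#' @param methyl_map named list residue-name -> methyl atom names; defaults
#'   cover Leu/Val/Ile/Thr/Ala/Met
#' @return data.frame (`segment`, `residue`, `r_methyl_a`, `r_methyl_b`,
#'   `single_methyl`)
#' @export
probe_methyl_distances <- function(frame, probe, targets,
                                   methyl_map = .METHYL_ATOMS) {
  pi_ <- .resolve_probe_atom(frame, probe)
  p <- frame$coords[pi_, ]
  a <- frame$atoms
  rows <- lapply(seq_len(nrow(targets)), function(j) {
    seg <- targets$segment[j]; res <- targets$residue[j]
    in_res <- a$segment_id == seg & a$residue_index == res
    if (!any(in_res))
      ck_stop("probe_resolution_error",
              sprintf("target residue %s/%d not found", seg, res))
    names_j <- if (!is.null(targets$methyl_a) && nzchar(targets$methyl_a[j])) {
      c(targets$methyl_a[j],
        if (!is.null(targets$methyl_b) && !is.na(targets$methyl_b[j]) &&
              nzchar(targets$methyl_b[j])) targets$methyl_b[j])
    } else {
      rn <- a$residue_name[which(in_res)[1]]
      mm <- methyl_map[[rn]]
      if (is.null(mm))
        ck_stop("probe_resolution_error",
                sprintf("no methyl rule for residue type '%s'", rn))
      mm
    }
    d <- vapply(names_j, function(nm) {
      i <- which(in_res & a$atom_name == nm)
      if (length(i) != 1)
        ck_stop("probe_resolution_error",
                sprintf("methyl atom %s not unique in %s/%d", nm, seg, res))
      sqrt(sum((frame$coords[i, ] - p)^2))
    }, numeric(1))
    data.frame(segment = seg, residue = res, r_methyl_a = d[1],
               r_methyl_b = if (length(d) > 1) d[2] else NA_real_,
               single_methyl = length(d) == 1)
  })
  do.call(rbind, rows)
}

#' Predicted PRE profile from per-frame distances
#'
#' Core of the ensemble pipeline: per frame the methyl-a and methyl-b ratios
#' are computed from the distances and averaged (ratio of each frame, NOT
#' the ratio of the mean distance); the per-frame mean ratios are then
#' time-averaged, and the 80% confidence interval is the empirical
#' 10th/90th percentile of the per-frame means. With one frame the CI
#' collapses to the value (single-structure mode).
#'
#' @param r_a matrix frames x residues of methyl-a distances, Angstrom
#' @param r_b matrix like `r_a` for methyl-b, or NULL/NA columns for
#'   single-methyl residues
#' @param residues residue indices labelling the columns
#' @param params a [pre_parameters()]
#' @return object of class `PreProfile`: data.frame with `residue_index`,
#'   `ratio_methyl_a`, `ratio_methyl_b`, `ratio_mean`, `ci80_low`,
#'   `ci80_high`; attribute `source` is "single-structure" or "ensemble"
#' @export
pre_profile_from_distances <- function(r_a, r_b = NULL, residues = NULL,
                                       params = pre_parameters()) {
  r_a <- rbind(r_a)
  if (is.null(residues)) residues <- seq_len(ncol(r_a))
  rat_a <- r_a
  rat_a[] <- ratio_from_distance(as.vector(r_a), params)
  rat_b <- if (is.null(r_b)) matrix(NA_real_, nrow(rat_a), ncol(rat_a)) else {
    r_b <- rbind(r_b)
    out <- r_b
    ok <- !is.na(r_b)
    out[ok] <- ratio_from_distance(r_b[ok], params)
    out
  }
  per_frame_mean <- (rat_a + ifelse(is.na(rat_b), rat_a, rat_b)) / 2
  df <- data.frame(
    residue_index = residues,
    ratio_methyl_a = colMeans(rat_a),
    ratio_methyl_b = colMeans(rat_b),
    ratio_mean = colMeans(per_frame_mean),
    ci80_low = apply(per_frame_mean, 2, stats::quantile, probs = 0.1,
                     type = 7, names = FALSE),
    ci80_high = apply(per_frame_mean, 2, stats::quantile, probs = 0.9,
                      type = 7, names = FALSE))
  rownames(df) <- NULL
  structure(df, class = c("PreProfile", "data.frame"),
            source = if (nrow(r_a) == 1) "single-structure" else "ensemble")
}

#' Predicted PRE profile for a trajectory ensemble
#'
#' Runs [probe_methyl_distances()] on every frame and feeds the distances to
#' [pre_profile_from_distances()].
#'
#' @param traj a `Trajectory`
#' @param probe a [probe_spec()]
#' @param targets as in [probe_methyl_distances()]
#' @param params a [pre_parameters()]
#' @return a `PreProfile`
#' @export
predict_pre_profile <- function(traj, probe, targets,
                                params = pre_parameters()) {
  nf <- n_frames(traj)
  if (nf < 1) ck_stop("empty_input", "trajectory has no frames")
  topo <- traj$topology
  per_frame <- lapply(seq_len(nf), function(m) {
    fr <- structure_frame(topo$atoms, traj$frames[[m]])
    probe_methyl_distances(fr, probe, targets)
  })
  r_a <- do.call(rbind, lapply(per_frame, `[[`, "r_methyl_a"))
  r_b <- do.call(rbind, lapply(per_frame, `[[`, "r_methyl_b"))
  pre_profile_from_distances(r_a, r_b, per_frame[[1]]$residue,
                             params = params)
}

#' Compare a predicted PRE profile with experimental ratios
#'
#' Signed error is predicted minus experimental. Residues present in only
#' one table are reported separately and excluded from the means.
#'
#' @param predicted a `PreProfile`
#' @param experimental data.frame with `residue_index`, `ratio` (optional
#'   `error`)
#' @return list: `mean_signed_error`, `mean_absolute_error`, `residuals`
#'   (per common residue), `fraction_within_ci`, `only_predicted`,
#'   `only_experimental`
#' @export
compare_to_experiment <- function(predicted, experimental) {
  common <- intersect(predicted$residue_index, experimental$residue_index)
  if (!length(common))
    ck_stop("no_overlap", "no residues common to predicted and experimental")
  p <- predicted[match(common, predicted$residue_index), ]
  e <- experimental[match(common, experimental$residue_index), ]
  resid <- p$ratio_mean - e$ratio
  within <- e$ratio >= p$ci80_low & e$ratio <= p$ci80_high
  list(mean_signed_error = mean(resid),
       mean_absolute_error = mean(abs(resid)),
       residuals = data.frame(residue_index = common, predicted = p$ratio_mean,
                              experimental = e$ratio, residual = resid,
                              within_ci = within),
       fraction_within_ci = mean(within),
       only_predicted = setdiff(predicted$residue_index, common),
       only_experimental = setdiff(experimental$residue_index, common))
}
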