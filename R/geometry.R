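#' Angle between two vectors
#'
#' Unsigned angle via the arc-cosine of the normalized dot product, with the
#' cosine clamped to \[-1, 1\] before `acos`.
#'
#' @param u,v numeric 3-vectors (any nonzero length)
#' @return angle in degrees, in \[0, 180\]
#' @export
vector_angle <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0)
    ck_stop("degenerate_geometry", "vector_angle on zero vector")
  cosang <- sum(u * v) / (nu * nv)
  acos(max(-1, min(1, cosang))) * 180 / pi
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) ck_stop("degenerate_geometry", "cannot normalize zero vector")
  v / n
}

#' Principal axis of a coordinate set
#'
#' First principal component of the centred coordinates, oriented so it
#' points from the first atom toward the last (N-to-C for a protein chain).
#'
#' @param coords n x 3 matrix, n >= 3
#' @return unit 3-vector
#' @export
principal_axis <- function(coords) {
  coords <- rbind(coords)
  if (nrow(coords) < 3)
    ck_stop("degenerate_geometry",
            "principal axis needs >= 3 atoms")
  cc <- sweep(coords, 2, colMeans(coords))
  ax <- svd(cc, nu = 0, nv = 1)$v[, 1]
  ends <- coords[nrow(coords), ] - coords[1, ]
  if (sum(ax * ends) < 0) ax <- -ax
  unit3(ax)
}

#' Beta-loop orientation angles (phi1, phi2)
#'
#' Per frame, the loop vector runs from the centre of mass of the alpha-3
#' helix to the centre of mass of the beta-loop. phi1 is its angle to the
#' principal axis of the alpha-1 helix; phi2 its angle to the principal axis
#' of the beta-sheet. Small phi2 marks the closed loop state, large (~100
#' degrees) the open state.
#'
#' @param traj a `Trajectory`
#' @param groups named list with `AtomSelection`s (or index vectors)
#'   `alpha1`, `alpha3`, `beta_loop`, `beta_sheet`
#' @return list with numeric per-frame vectors `phi1`, `phi2` (degrees)
#' @export
compute_phi_angles <- function(traj, groups) {
  req <- c("alpha1", "alpha3", "beta_loop", "beta_sheet")
  if (!all(req %in% names(groups)))
    ck_stop("parameter_error", paste("groups must contain:",
                                     paste(req, collapse = ", ")))
  g <- lapply(groups[req], sel_indices)
  for (nm in c("alpha1", "beta_sheet"))
    if (length(g[[nm]]) < 3)
      ck_stop("degenerate_geometry",
              sprintf("group '%s' needs >= 3 atoms for a principal axis", nm))
  masses <- atom_masses(traj$topology$atoms$element)
  phi1 <- phi2 <- numeric(n_frames(traj))
  for (m in seq_len(n_frames(traj))) {
    X <- traj$frames[[m]]
    v_loop <- centre_of_mass(X[g$beta_loop, , drop = FALSE],
                             masses[g$beta_loop]) -
      centre_of_mass(X[g$alpha3, , drop = FALSE], masses[g$alpha3])
    phi1[m] <- vector_angle(v_loop, principal_axis(X[g$alpha1, , drop = FALSE]))
    phi2[m] <- vector_angle(v_loop,
                            principal_axis(X[g$beta_sheet, , drop = FALSE]))
  }
  list(phi1 = phi1, phi2 = phi2)
}

#' Define the nucleosomal plane
#'
#' The nucleosomal DNA C1' atoms are divided into four quadrants; the centres
#' of mass of the two quadrants distal from the linker DNA give two points
#' (p1, p2) and the C1' centre of mass of the dyad base pair gives the third
#' (p3). The plane normal is `unit((p1 - p3) x (p2 - p3))`; its handedness is
#' therefore fixed by the order of `distal_quadrants`. When `orient_ref` is
#' supplied (e.g. the histone-core centre of mass) the normal is flipped, if
#' necessary, to point away from it.
#'
#' @param coords n x 3 frame coordinates
#' @param c1p indices (or `AtomSelection`) of the DNA C1' atoms
#' @param quadrants character vector, one quadrant label per `c1p` atom
#' @param distal_quadrants length-2 character vector naming, in order, the
#'   quadrants used for p1 and p2
#' @param dyad indices (or `AtomSelection`) of the dyad base-pair C1' atoms
#' @param orient_ref optional 3-vector the normal must point away from
#' @param tol collinearity tolerance on |(p1-p3) x (p2-p3)|, Angstrom^2
#' @return list with `p1`, `p2`, `p3`, unit `normal`
#' @export
define_nucleosomal_plane <- function(coords, c1p, quadrants, distal_quadrants,
                                     dyad, orient_ref = NULL, tol = 1e-8) {
  idx <- sel_indices(c1p)
  if (length(quadrants) != length(idx))
    ck_stop("parameter_error", "one quadrant label per C1' atom required")
  didx <- sel_indices(dyad)
  if (!length(didx)) ck_stop("parameter_error", "empty dyad selection")
  qsel <- function(q) {
    ai <- idx[quadrants == q]
    if (!length(ai))
      ck_stop("parameter_error", sprintf("quadrant '%s' has no C1' atoms", q))
    centre_of_mass(coords[ai, , drop = FALSE])
  }
  p1 <- qsel(distal_quadrants[1])
  p2 <- qsel(distal_quadrants[2])
  p3 <- centre_of_mass(coords[didx, , drop = FALSE])
  nvec <- cross3(p1 - p3, p2 - p3)
  if (sqrt(sum(nvec^2)) < tol)
    ck_stop("degenerate_plane", "plane points are collinear")
  normal <- unit3(nvec)
  if (!is.null(orient_ref)) {
    centroid <- (p1 + p2 + p3) / 3
    s <- sum(normal * (centroid - orient_ref))
    if (s < 0) normal <- -normal
  }
  list(p1 = p1, p2 = p2, p3 = p3, normal = normal)
}

#' Linker-DNA in-plane (alpha) and out-of-plane (beta) angles
#'
#' Per frame the arm vector v runs from the centre of mass of the origin
#' base-pair C1' atoms to that of the terminal base pair. beta is the signed
#' angle between v and its projection onto the nucleosomal plane, positive on
#' the +normal side (out-of-plane, "away from the nucleosomal plane").
#' alpha is the signed in-plane angle between the projected arm and the
#' anti-dyad reference direction (the in-plane unit vector from p3 toward the
#' midpoint of p1 and p2, i.e. from the dyad base pair toward the linker
#' gap), with the sense chosen per arm side so that positive alpha is motion
#' toward the dyad axis for both arms.
#'
#' Frames where the arm is within `tol_deg` of the plane normal have an
#' undefined in-plane direction; alpha is recorded as `NA` there.
#'
#' @param traj a `Trajectory`
#' @param plane_spec list with fields `c1p`, `quadrants`, `distal_quadrants`,
#'   `dyad` and optional `orient_ref`, as in [define_nucleosomal_plane()]
#' @param arm list with fields `origin` and `terminal` (selections or index
#'   vectors) and `side` ("entry" or "exit")
#' @param tol_deg tolerance (degrees) for the alpha-undefined test
#' @return list with per-frame numeric vectors `alpha`, `beta` (degrees,
#'   signed, in (-180, 180])
#' @export
compute_linker_angles <- function(traj, plane_spec, arm, tol_deg = 1e-6) {
  side <- match.arg(arm$side, c("entry", "exit"))
  s <- if (side == "entry") -1 else 1
  oi <- sel_indices(arm$origin); ti <- sel_indices(arm$terminal)
  if (!length(oi) || !length(ti))
    ck_stop("selection_empty", "arm origin/terminal selection is empty")
  nf <- n_frames(traj)
  alpha <- beta <- rep(NA_real_, nf)
  for (m in seq_len(nf)) {
    X <- traj$frames[[m]]
    pl <- define_nucleosomal_plane(X, plane_spec$c1p, plane_spec$quadrants,
                                   plane_spec$distal_quadrants, plane_spec$dyad,
                                   plane_spec$orient_ref)
    v <- centre_of_mass(X[ti, , drop = FALSE]) -
      centre_of_mass(X[oi, , drop = FALSE])
    if (sqrt(sum(v^2)) == 0)
      ck_stop("degenerate_geometry", sprintf("zero arm vector at frame %d", m))
    vhat <- unit3(v)
    n <- pl$normal
    beta[m] <- asin(max(-1, min(1, sum(vhat * n)))) * 180 / pi
    vp <- v - sum(v * n) * n
    if (sqrt(sum(vp^2)) / sqrt(sum(v^2)) < sin(tol_deg * pi / 180)) next
    dref <- (pl$p1 + pl$p2) / 2 - pl$p3           # anti-dyad direction
    dref <- dref - sum(dref * n) * n
    dhat <- unit3(dref); vph <- unit3(vp)
    alpha[m] <- s * atan2(sum(n * cross3(dhat, vph)), sum(dhat * vph)) *
      180 / pi
  }
  list(alpha = alpha, beta = beta)
}

#' Distance between the centres of mass of two selections, per frame
#' @param traj a `Trajectory`
#' @param selA,selB `AtomSelection`s or index vectors
#' @return per-frame numeric vector, Angstrom
#' @export
end_to_end_distance <- function(traj, selA, selB) {
  ia <- sel_indices(selA); ib <- sel_indices(selB)
  if (!length(ia) || !length(ib))
    ck_stop("selection_empty", "end_to_end_distance: empty selection")
  masses <- atom_masses(traj$topology$atoms$element)
  vapply(traj$frames, function(X) {
    sqrt(sum((centre_of_mass(X[ia, , drop = FALSE], masses[ia]) -
                centre_of_mass(X[ib, , drop = FALSE], masses[ib]))^2))
  }, numeric(1))
}

# squared cross-distance matrix between two coordinate sets
.cross_dist2 <- function(A, B) {
  a2 <- rowSums(A^2); b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

#' Residue-residue heavy-atom contact table
#'
#' Two residues are in contact in a frame iff any pair of their heavy atoms
#' (hydrogens excluded by element) is within `cutoff`. Returns per-pair frame
#' counts/fractions plus the per-frame total number of residue pairs in
#' contact, whose mean and standard deviation mirror "total contacts"
#' reporting for secondary-structure elements.
#'
#' @param traj a `Trajectory`
#' @param selA,selB selections (heavy atoms are filtered automatically)
#' @param cutoff contact distance, Angstrom (> 0); default 4.0
#' @return list of class `ContactTable`: `pairs` (data.frame `residue_a`,
#'   `segment_a`, `residue_b`, `segment_b`, `frames_in_contact`, `fraction`),
#'   `per_frame_total`, `total_mean`, `total_sd`, `cutoff`
#' @export
contact_table <- function(traj, selA, selB, cutoff = 4.0) {
  if (cutoff <= 0) ck_stop("parameter_error", "cutoff must be > 0")
  at <- traj$topology$atoms
  heavy <- toupper(at$element) != "H"
  ia <- intersect(sel_indices(selA), which(heavy))
  ib <- intersect(sel_indices(selB), which(heavy))
  if (!length(ia) || !length(ib))
    ck_stop("selection_empty", "contact_table: empty heavy-atom selection")
  key <- function(i) paste(at$segment_id[i], at$residue_index[i])
  ra <- key(ia); rb <- key(ib)
  ua <- unique(ra); ub <- unique(rb)
  nf <- n_frames(traj)
  counts <- matrix(0L, length(ua), length(ub), dimnames = list(ua, ub))
  per_frame_total <- integer(nf)
  c2 <- cutoff^2
  for (m in seq_len(nf)) {
    X <- traj$frames[[m]]
    d2 <- .cross_dist2(X[ia, , drop = FALSE], X[ib, , drop = FALSE])
    hit <- d2 <= c2
    # residue-level OR over atom pairs via two grouped sums
    agg <- rowsum(hit + 0, ra)                       # residues_a x atoms_b
    agg <- t(rowsum(t(agg), rb))                     # residues_a x residues_b
    inContact <- agg[ua, ub, drop = FALSE] > 0
    counts <- counts + inContact
    per_frame_total[m] <- sum(inContact)
  }
  df <- data.frame(
    residue_a = rep(sub("^\\S+ ", "", ua), times = length(ub)),
    segment_a = rep(sub(" .*$", "", ua), times = length(ub)),
    residue_b = rep(sub("^\\S+ ", "", ub), each = length(ua)),
    segment_b = rep(sub(" .*$", "", ub), each = length(ua)),
    frames_in_contact = as.vector(counts),
    fraction = as.vector(counts) / nf,
    stringsAsFactors = FALSE)
  df <- df[df$frames_in_contact > 0, , drop = FALSE]
  rownames(df) <- NULL
  structure(list(pairs = df, per_frame_total = per_frame_total,
                 total_mean = mean(per_frame_total),
                 total_sd = stats::sd(per_frame_total),
                 cutoff = cutoff),
            class = "ContactTable")
}

#' Optimal superposition (Kabsch) of two coordinate sets
#'
#' Least-squares rotation + translation mapping `mobile` onto `ref`.
#' @param mobile,ref n x 3 matrices with matched rows
#' @return list `R` (3 x 3 rotation), `t` (translation), and `transform(X)`
#' @export
kabsch <- function(mobile, ref) {
  if (nrow(mobile) != nrow(ref))
    ck_stop("structural_mismatch", "kabsch: row-count mismatch")
  cm <- colMeans(mobile); cr <- colMeans(ref)
  A <- sweep(mobile, 2, cm); B <- sweep(ref, 2, cr)
  H <- crossprod(A, B)
  s <- svd(H)
  d <- sign(det(tcrossprod(s$v, s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  t <- cr - drop(R %*% cm)
  list(R = R, t = t,
       transform = function(X) sweep(X %*% t(R), 2, t, "+"))
}

#' Per-frame RMSD to a reference after optimal superposition
#'
#' Each frame is rigid-body fitted to `reference` on `fit_sel`; RMSD is then
#' evaluated on `measure_sel` without refitting (e.g. fit on core-histone
#' helical CA, measure on linker-histone helical CA).
#'
#' @param traj a `Trajectory`
#' @param fit_sel,measure_sel selections; must resolve to equal atom counts
#'   in trajectory and reference
#' @param reference a `StructureFrame` (defaults to frame 1's coordinates on
#'   the trajectory topology)
#' @return per-frame RMSD, Angstrom
#' @export
rmsd <- function(traj, fit_sel, measure_sel, reference = NULL) {
  fi <- sel_indices(fit_sel); mi <- sel_indices(measure_sel)
  ref <- if (is.null(reference)) traj$frames[[1]] else reference$coords
  if (max(c(fi, mi)) > nrow(ref) || max(c(fi, mi)) > n_atoms(traj))
    ck_stop("structural_mismatch", "selection outside topology/reference")
  refm <- ref[mi, , drop = FALSE]
  vapply(traj$frames, function(X) {
    fit <- kabsch(X[fi, , drop = FALSE], ref[fi, , drop = FALSE])
    Xm <- fit$transform(X[mi, , drop = FALSE])
    sqrt(mean(rowSums((Xm - refm)^2)))
  }, numeric(1))
}
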