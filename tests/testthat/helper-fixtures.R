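# Shared fixture builders: everything is generated in code at test time.

# uniformly random rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# tiny 4-residue protein: CA + CB per residue, one segment
toy_protein <- function(segid = "A") {
  n <- 4L
  atoms <- data.frame(
    atom_name = rep(c("CA", "CB"), n),
    element = "C",
    residue_index = rep(seq_len(n), each = 2),
    residue_name = "ALA",
    segment_id = segid,
    stringsAsFactors = FALSE)
  coords <- cbind(seq_len(2 * n) * 1.5, 0, 0)
  structure_frame(atoms, coords)
}

# hand-written 3-atom PDB file; returns (path, expected coords)
write_tiny_pdb <- function(path) {
  lines <- c(
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00      A    C",
    "ATOM      2  CB  ALA A   1       4.500  -1.250   0.000  1.00  0.00      A    C",
    "ATOM      3  CA  GLY A   2       0.000   0.000   9.990  1.00  0.00      A    C")
  writeLines(lines, path)
  matrix(c(1, 2, 3, 4.5, -1.25, 0, 0, 0, 9.99), ncol = 3, byrow = TRUE)
}

# topology with two single-atom residues a given distance apart, nf frames
two_atom_traj <- function(d, nf = 10) {
  atoms <- data.frame(atom_name = c("C1", "C2"), element = "C",
                      residue_index = c(1L, 2L), residue_name = "UNK",
                      segment_id = c("A", "B"), stringsAsFactors = FALSE)
  coords <- rbind(c(0, 0, 0), c(d, 0, 0))
  trajectory(structure_frame(atoms, coords),
             replicate(nf, coords, simplify = FALSE))
}

# random structure with nres residues x 2 heavy atoms in a box
random_structure <- function(nres, box = 20, segid = "A", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  atoms <- data.frame(
    atom_name = rep(c("CA", "CB"), nres),
    element = "C",
    residue_index = rep(seq_len(nres), each = 2),
    residue_name = sample(c("ALA", "VAL", "LEU"), 2 * nres, replace = TRUE),
    segment_id = segid, stringsAsFactors = FALSE)
  atoms$residue_name <- rep(atoms$residue_name[seq(1, 2 * nres, 2)], each = 2)
  structure_frame(atoms, matrix(runif(6 * nres, 0, box), ncol = 3))
}

# AR(1) series with coefficient rho, unit innovations
ar1_series <- function(n, rho, seed = 1) {
  set.seed(seed)
  as.numeric(stats::filter(rnorm(n), rho, "recursive"))
}

kb_kcal <- 0.0019872041
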