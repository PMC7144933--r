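#' Construct a StructureFrame
#'
#' A `StructureFrame` is the package's coordinate substrate: an atom table
#' (name, element, residue index, residue name, segment id) plus an n x 3
#' coordinate matrix in Angstrom.
#'
#' @param atoms data.frame with columns `atom_name`, `element`,
#'   `residue_index`, `residue_name`, `segment_id`
#' @param coords numeric matrix, one row per atom, columns x/y/z in Angstrom
#' @return object of class `StructureFrame`
#' @export
structure_frame <- function(atoms, coords) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  req <- c("atom_name", "element", "residue_index", "residue_name",
           "segment_id")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols))
    ck_stop("schema_error", paste("atom table missing column(s):",
                                  paste(missing_cols, collapse = ", ")))
  if (nrow(atoms) != nrow(coords))
    ck_stop("structural_mismatch",
            sprintf("atom count (%d) != coordinate rows (%d)",
                    nrow(atoms), nrow(coords)))
  if (nrow(coords) && !all(is.finite(coords)))
    ck_stop("invalid_coordinates", "non-finite coordinates")
  atoms$residue_index <- as.integer(atoms$residue_index)
  rownames(atoms) <- NULL
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  structure(list(atoms = atoms, coords = coords), class = "StructureFrame")
}

#' @export
print.StructureFrame <- function(x, ...) {
  cat(sprintf("<StructureFrame> %d atoms, %d residues, segments: %s\n",
              nrow(x$atoms),
              length(unique(paste(x$atoms$segment_id, x$atoms$residue_index))),
              paste(unique(x$atoms$segment_id), collapse = ",")))
  invisible(x)
}

n_atoms <- function(x) UseMethod("n_atoms")
#' @export
n_atoms.StructureFrame <- function(x) nrow(x$atoms)
#' @export
n_atoms.Trajectory <- function(x) nrow(x$topology$atoms)

#' Construct a Trajectory
#'
#' Ordered frames of coordinates over a fixed topology. All frames must have
#' the same atom count as the topology.
#'
#' @param topology a [structure_frame()] carrying atom metadata
#' @param frames list of n x 3 coordinate matrices, Angstrom
#' @param frame_interval optional time between frames (arbitrary units)
#' @return object of class `Trajectory`
#' @export
trajectory <- function(topology, frames, frame_interval = NA_real_) {
  stopifnot(inherits(topology, "StructureFrame"))
  frames <- lapply(seq_along(frames), function(i) {
    f <- as.matrix(frames[[i]])
    storage.mode(f) <- "double"
    if (nrow(f) != nrow(topology$atoms))
      ck_stop("structural_mismatch",
              sprintf("frame %d has %d atoms, topology has %d",
                      i, nrow(f), nrow(topology$atoms)))
    dimnames(f) <- list(NULL, c("x", "y", "z"))
    f
  })
  structure(list(topology = topology, frames = frames,
                 frame_interval = frame_interval),
            class = "Trajectory")
}

#' Number of frames in a trajectory
#' @param traj a `Trajectory`
#' @return integer
#' @export
n_frames <- function(traj) length(traj$frames)

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("<Trajectory> %d frames x %d atoms\n",
              n_frames(x), nrow(x$topology$atoms)))
  invisible(x)
}

# ---- PDB I/O ---------------------------------------------------------------
# PDB v3 fixed-column ATOM/HETATM records. No R PDB reader ships in the
# supported environment, so the fixed-width parsing lives here; only the
# columns the analyses need are interpreted (no bonds, no chemistry).

.parse_pdb_atom_lines <- function(lines, lineno) {
  sub_f <- function(from, to) substr(lines, from, to)
  num <- function(s, what) {
    v <- suppressWarnings(as.numeric(s))
    bad <- which(is.na(v) & nzchar(trimws(s)) | !nzchar(trimws(s)))
    if (length(bad))
      ck_stop("parse_error",
              sprintf("malformed %s field in PDB record at line %d",
                      what, lineno[bad[1]]))
    v
  }
  name <- trimws(sub_f(13, 16))
  resname <- trimws(sub_f(18, 20))
  chain <- trimws(sub_f(22, 22))
  resseq <- suppressWarnings(as.integer(trimws(sub_f(23, 26))))
  if (anyNA(resseq))
    ck_stop("parse_error",
            sprintf("malformed residue number at line %d",
                    lineno[which(is.na(resseq))[1]]))
  x <- num(sub_f(31, 38), "x")
  y <- num(sub_f(39, 46), "y")
  z <- num(sub_f(47, 54), "z")
  segid <- trimws(sub_f(73, 76))
  element <- trimws(sub_f(77, 78))
  # fall back to leading atom-name character for element, chain for segid
  element <- ifelse(nzchar(element), element,
                    toupper(substr(gsub("[^A-Za-z].*$", "", name), 1, 1)))
  segid <- ifelse(nzchar(segid), segid, ifelse(nzchar(chain), chain, "A"))
  list(atoms = data.frame(atom_name = name, element = element,
                          residue_index = resseq, residue_name = resname,
                          segment_id = segid, stringsAsFactors = FALSE),
       coords = cbind(x = x, y = y, z = z))
}

#' Read a PDB structure
#'
#' Reads ATOM/HETATM records from a PDB v3 file into a [structure_frame()].
#' Multi-model files are read as the first model only (with a warning);
#' use [read_trajectory()] for multi-model trajectories. File-native
#' (1-based crystallographic) residue numbering is preserved.
#'
#' @param path path to PDB file
#' @param dialect only `"pdb"` is supported
#' @return a `StructureFrame`
#' @export
read_structure <- function(path, dialect = "pdb") {
  dialect <- match.arg(dialect, "pdb")
  if (!file.exists(path)) ck_stop("io_error", paste("no such file:", path))
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) ck_stop("empty_structure", paste("empty PDB file:", path))
  rec <- substr(lines, 1, 6)
  model_starts <- which(trimws(rec) == "MODEL")
  if (length(model_starts) > 1) {
    ck_warn("multi-model PDB read as structure: using first model only")
    endmdl <- which(trimws(rec) == "ENDMDL")
    keep <- seq_len(if (length(endmdl)) endmdl[1] else length(lines))
    lines <- lines[keep]; rec <- rec[keep]
  }
  sel <- rec %in% c("ATOM  ", "HETATM")
  if (!any(sel)) ck_stop("empty_structure",
                         paste("no ATOM/HETATM records in", path))
  p <- .parse_pdb_atom_lines(lines[sel], which(sel))
  structure_frame(p$atoms, p$coords)
}

.format_pdb_atom <- function(i, a, xyz) {
  name <- a$atom_name[i]
  # standard PDB name justification: <4 char names start in column 14
  name_f <- if (nchar(name) >= 4) substr(name, 1, 4) else
    sprintf(" %-3s", name)
  sprintf("ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f      %-4s%2s",
          (i - 1L) %% 99999L + 1L, name_f,
          substr(a$residue_name[i], 1, 3),
          substr(a$segment_id[i], 1, 1), a$residue_index[i] %% 10000L,
          xyz[i, 1], xyz[i, 2], xyz[i, 3], 1, 0,
          substr(a$segment_id[i], 1, 4), substr(a$element[i], 1, 2))
}

#' Write a structure or trajectory as PDB
#'
#' Trajectories are written as multi-model PDB (MODEL/ENDMDL blocks), the
#' package's canonical portable trajectory dialect.
#'
#' @param x a `StructureFrame` or `Trajectory`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_pdb <- function(x, path) {
  con <- file(path, "w"); on.exit(close(con))
  if (inherits(x, "StructureFrame")) {
    a <- x$atoms
    writeLines(vapply(seq_len(nrow(a)), .format_pdb_atom, "", a, x$coords), con)
    writeLines("END", con)
  } else if (inherits(x, "Trajectory")) {
    a <- x$topology$atoms
    idx <- seq_len(nrow(a))
    for (m in seq_along(x$frames)) {
      writeLines(sprintf("MODEL     %4d", m), con)
      writeLines(vapply(idx, .format_pdb_atom, "", a, x$frames[[m]]), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  } else ck_stop("type_error", "write_pdb needs StructureFrame or Trajectory")
  invisible(path)
}

#' Read a trajectory
#'
#' Two plain-text dialects are supported: multi-model PDB (`"pdb"`) and a
#' frame-table CSV (`"frame-table"`) with columns
#' `frame, atom_index, x, y, z`. Frame-table rows may appear in any order;
#' the reader sorts by `(frame, atom_index)`. All frames must share the
#' topology of frame 1.
#'
#' @param path input file
#' @param dialect `"auto"` (by extension), `"pdb"` or `"frame-table"`
#' @param topology optional `StructureFrame` providing atom metadata for the
#'   frame-table dialect; a placeholder topology is synthesized when absent
#' @return a `Trajectory`
#' @export
read_trajectory <- function(path, dialect = c("auto", "pdb", "frame-table"),
                            topology = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.(csv|tsv|txt)$", path)) "frame-table" else "pdb"
  if (!file.exists(path)) ck_stop("io_error", paste("no such file:", path))
  if (dialect == "pdb") .read_traj_pdb(path) else
    .read_traj_table(path, topology)
}

.read_traj_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- trimws(substr(lines, 1, 6))
  starts <- which(rec == "MODEL")
  if (!length(starts)) {
    s <- read_structure(path)
    return(trajectory(s, list(s$coords)))
  }
  ends <- which(rec == "ENDMDL")
  if (length(ends) < length(starts))
    ck_stop("parse_error", "MODEL without matching ENDMDL")
  frames <- vector("list", length(starts))
  topo <- NULL
  for (m in seq_along(starts)) {
    block <- lines[(starts[m] + 1):(ends[m] - 1)]
    brec <- substr(block, 1, 6)
    sel <- brec %in% c("ATOM  ", "HETATM")
    p <- .parse_pdb_atom_lines(block[sel], starts[m] + which(sel))
    if (is.null(topo)) {
      topo <- structure_frame(p$atoms, p$coords)
    } else if (nrow(p$coords) != nrow(topo$atoms)) {
      ck_stop("structural_mismatch",
              sprintf("frame %d has %d atoms, frame 1 has %d",
                      m, nrow(p$coords), nrow(topo$atoms)))
    }
    frames[[m]] <- p$coords
  }
  trajectory(topo, frames)
}

.read_traj_table <- function(path, topology) {
  df <- utils::read.csv(path)
  req <- c("frame", "atom_index", "x", "y", "z")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    ck_stop("schema_error", paste("frame-table missing column(s):",
                                  paste(missing_cols, collapse = ", ")))
  df <- df[order(df$frame, df$atom_index), , drop = FALSE]
  frames_id <- unique(df$frame)
  counts <- table(df$frame)
  if (length(unique(counts)) > 1) {
    bad <- names(counts)[counts != counts[1]][1]
    ck_stop("structural_mismatch",
            sprintf("frame %s has %d atoms, frame %s has %d", bad,
                    counts[[bad]], names(counts)[1], counts[[1]]))
  }
  nat <- unname(counts[1])
  if (is.null(topology)) {
    topology <- structure_frame(
      data.frame(atom_name = paste0("X", seq_len(nat)), element = "",
                 residue_index = seq_len(nat), residue_name = "UNK",
                 segment_id = "A", stringsAsFactors = FALSE),
      as.matrix(df[df$frame == frames_id[1], c("x", "y", "z")]))
  }
  frames <- lapply(frames_id, function(f) {
    as.matrix(df[df$frame == f, c("x", "y", "z")])
  })
  trajectory(topology, frames)
}

#' Write a trajectory as a frame-table CSV
#'
#' Columns `frame, atom_index, x, y, z`; full double precision.
#' @param traj a `Trajectory`
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_frame_table <- function(traj, path) {
  nat <- nrow(traj$topology$atoms)
  df <- do.call(rbind, lapply(seq_along(traj$frames), function(m) {
    data.frame(frame = m, atom_index = seq_len(nat),
               x = traj$frames[[m]][, 1], y = traj$frames[[m]][, 2],
               z = traj$frames[[m]][, 3])
  }))
  utils::write.csv(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Analysis configuration record
#'
#' Bundles the knobs shared across analyses: named selection expressions,
#' the equilibration cut (frames dropped from the start of a trajectory),
#' histogram bin count, RNG seed and the heavy-atom contact cutoff.
#'
#' @param selections named list of selection expressions (see
#'   [resolve_selection()])
#' @param equilibration_cut integer >= 0, frames dropped for equilibration
#' @param histogram_bins integer >= 2
#' @param seed integer RNG seed
#' @param contact_cutoff contact distance threshold, Angstrom (> 0)
#' @return object of class `AnalysisConfig`
#' @export
analysis_config <- function(selections = list(), equilibration_cut = 0L,
                            histogram_bins = 50L, seed = 1L,
                            contact_cutoff = 4.0) {
  if (equilibration_cut < 0) ck_stop("parameter_error",
                                     "equilibration_cut must be >= 0")
  if (histogram_bins < 2) ck_stop("parameter_error",
                                  "histogram_bins must be >= 2")
  if (contact_cutoff <= 0) ck_stop("parameter_error",
                                   "contact_cutoff must be > 0")
  structure(list(selections = selections,
                 equilibration_cut = as.integer(equilibration_cut),
                 histogram_bins = as.integer(histogram_bins),
                 seed = as.integer(seed),
                 contact_cutoff = contact_cutoff),
            class = "AnalysisConfig")
}
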