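.E_COMPONENTS <- c("E_internal", "E_elec", "E_vdw")

#' Per-frame MM/GBSA energy-component table
#'
#' One row per frame with columns `E_internal`, `E_elec`, `E_vdw`,
#' `E_total` (kcal/mol) and a role: `complex`, `receptor` or `ligand`.
#' `E_total` is validated against the component sum and recomputed (with a
#' warning) on mismatch beyond 1e-6.
#'
#' @param df data.frame with the component columns (and optionally `E_total`)
#' @param role one of "complex", "receptor", "ligand"
#' @return object of class `EnergyTable`
#' @export
energy_table <- function(df, role = c("complex", "receptor", "ligand")) {
  role <- match.arg(role)
  missing_cols <- setdiff(.E_COMPONENTS, names(df))
  if (length(missing_cols))
    ck_stop("schema_error", paste("energy table missing column(s):",
                                  paste(missing_cols, collapse = ", ")))
  if (nrow(df) < 2)
    ck_stop("parameter_error", "energy table needs >= 2 frames for variance")
  tot <- df$E_internal + df$E_elec + df$E_vdw
  if (is.null(df$E_total)) {
    df$E_total <- tot
  } else if (max(abs(df$E_total - tot)) > 1e-6) {
    ck_warn(sprintf(
      "E_total inconsistent with component sum (max |diff| = %.3g); recomputed",
      max(abs(df$E_total - tot))))
    df$E_total <- tot
  }
  structure(list(rows = df[c(.E_COMPONENTS, "E_total")], role = role),
            class = "EnergyTable")
}

#' Read an MMPBSA-style per-frame energy CSV
#' @param path CSV with columns `E_internal, E_elec, E_vdw[, E_total]`
#' @param role table role, as in [energy_table()]
#' @return an `EnergyTable`
#' @export
read_energy_table <- function(path, role) {
  energy_table(utils::read.csv(path), role)
}

#' Write an energy table as CSV
#' @param tab an `EnergyTable`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_energy_table <- function(tab, path) {
  utils::write.csv(format(tab$rows, digits = 17, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

.summ <- function(tab) {
  m <- vapply(tab$rows, mean, numeric(1))
  s <- vapply(tab$rows, stats::sd, numeric(1))
  list(mean = m, sd = s, n = nrow(tab$rows))
}

#' Three-trajectory MM/GBSA binding-energy assembly
#'
#' Per component X: `dE_X = mean(X_complex) - mean(X_receptor) -
#' mean(X_ligand)`. The three trajectories are independent, so the spread is
#' combined in quadrature of the per-role per-frame standard deviations.
#'
#' @param complex,receptor,ligand `EnergyTable`s with the matching roles
#' @return object of class `BindingSummary`: data.frame with `component`,
#'   `delta_mean`, `delta_sd` plus an `n_frames` attribute
#' @export
gbsa_binding <- function(complex, receptor, ligand) {
  roles <- c(complex$role, receptor$role, ligand$role)
  if (!identical(roles, c("complex", "receptor", "ligand")))
    ck_stop("role_mismatch",
            paste("expected roles complex/receptor/ligand, got",
                  paste(roles, collapse = "/")))
  sc <- .summ(complex); sr <- .summ(receptor); sl <- .summ(ligand)
  comp <- c(.E_COMPONENTS, "E_total")
  df <- data.frame(component = sub("^E_", "", comp),
                   delta_mean = sc$mean[comp] - sr$mean[comp] - sl$mean[comp],
                   delta_sd = sqrt(sc$sd[comp]^2 + sr$sd[comp]^2 +
                                     sl$sd[comp]^2))
  rownames(df) <- NULL
  structure(df, class = c("BindingSummary", "data.frame"),
            n_frames = c(complex = sc$n, receptor = sr$n, ligand = sl$n))
}

#' Binding-energy difference between two binding modes
#'
#' `ddE_X = dE_X(on) - dE_X(off)` per component, spreads combined in
#' quadrature. A negative total means the `on` mode binds more favorably.
#'
#' @param on,off `BindingSummary`s over the same component set
#' @return data.frame with `component`, `ddE_mean`, `ddE_sd`
#' @export
delta_delta <- function(on, off) {
  if (!identical(on$component, off$component))
    ck_stop("parameter_error", "component sets differ")
  data.frame(component = on$component,
             ddE_mean = on$delta_mean - off$delta_mean,
             ddE_sd = sqrt(on$delta_sd^2 + off$delta_sd^2))
}

#' Energetic strain of a binding species
#'
#' Per component, the species' own mean energy in the complexed ensemble
#' minus its mean energy in isolation; negative means the complexed state is
#' lower in energy. Spreads combine in quadrature (independent ensembles).
#'
#' @param complexed,isolated `EnergyTable`s describing the same species in
#'   the two ensembles
#' @param species label ("Nuc", "LH", ...)
#' @return object of class `StrainSummary`: data.frame with `species`,
#'   `component`, `strain_mean`, `strain_sd`
#' @export
strain <- function(complexed, isolated, species = "species") {
  sc <- .summ(complexed); si <- .summ(isolated)
  comp <- c(.E_COMPONENTS, "E_total")
  df <- data.frame(species = species, component = sub("^E_", "", comp),
                   strain_mean = sc$mean[comp] - si$mean[comp],
                   strain_sd = sqrt(sc$sd[comp]^2 + si$sd[comp]^2))
  rownames(df) <- NULL
  structure(df, class = c("StrainSummary", "data.frame"))
}
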