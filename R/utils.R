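`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a classed condition
#' @noRd
ck_stop <- function(class, message, ...) {
  stop(structure(
    class = c(class, "chromkit_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

ck_warn <- function(message) warning(message, call. = FALSE)

#' Minimal structured logger
#'
#' Writes timestamped key=value records to stderr. Verbosity is controlled by
#' `options(chromkit.log_level = )`, one of "debug", "info", "warn", "none".
#' @param level message level
#' @param msg message text
#' @param ... named fields appended as `key=value`
#' @return invisibly, the formatted line
#' @export
ck_log <- function(level = "info", msg, ...) {
  ranks <- c(debug = 1L, info = 2L, warn = 3L, none = 4L)
  opt <- getOption("chromkit.log_level", "warn")
  if (ranks[[level]] < ranks[[opt]]) return(invisible(NULL))
  fields <- list(...)
  extra <- if (length(fields)) {
    paste0(" ", paste(names(fields), vapply(fields, format, ""), sep = "=",
                      collapse = " "))
  } else ""
  line <- sprintf("[%s] %s %s%s", format(Sys.time(), "%H:%M:%S"),
                  toupper(level), msg, extra)
  message(line)
  invisible(line)
}

# Atomic masses (u) for the elements a pseudo-atom model can carry.
# Unknown/blank elements fall back to unit mass (documented behaviour).
.ATOMIC_MASSES <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                    P = 30.974, S = 32.06, FE = 55.845, MG = 24.305,
                    NA. = 22.99, K = 39.098, ZN = 65.38, MN = 54.938)

atom_masses <- function(elements) {
  el <- toupper(trimws(elements))
  m <- .ATOMIC_MASSES[el]
  m[is.na(m)] <- 1
  unname(m)
}

#' Mass-weighted centre of mass
#' @param coords n x 3 matrix
#' @param masses optional per-row masses; unit masses when NULL
#' @return length-3 numeric
#' @export
centre_of_mass <- function(coords, masses = NULL) {
  coords <- rbind(coords)
  if (is.null(masses)) masses <- rep(1, nrow(coords))
  w <- masses / sum(masses)
  drop(crossprod(w, coords))
}
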