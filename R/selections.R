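#' Resolve an atom-selection expression
#'
#' Small predicate grammar over the atom table, clauses joined with `and`:
#' \describe{
#'   \item{`name N1 N2 ...`}{atom names}
#'   \item{`resid 2-5 8 ...`}{residue indices; `a-b` ranges allowed}
#'   \item{`resname THR LYS`}{residue names}
#'   \item{`segid LH DNAI`}{segment ids}
#'   \item{`element C N`}{element symbols}
#'   \item{`all` / `heavy`}{every atom / every non-hydrogen atom}
#' }
#' Example: `"segid LH and resid 10-20 and name CA"`. Resolution is a pure
#' function of (topology, expression); an empty match is allowed but logged.
#'
#' @param topology a `StructureFrame`
#' @param expression selection text
#' @return object of class `AtomSelection` with fields `expression` and
#'   `indices` (strictly increasing 1-based atom indices)
#' @export
resolve_selection <- function(topology, expression) {
  stopifnot(inherits(topology, "StructureFrame"))
  a <- topology$atoms
  expr <- trimws(expression)
  if (!nzchar(expr))
    ck_stop("selection_grammar_error", "empty selection expression")
  clauses <- strsplit(expr, "\\s+and\\s+")[[1]]
  mask <- rep(TRUE, nrow(a))
  pos <- 1L
  for (cl in clauses) {
    toks <- strsplit(trimws(cl), "\\s+")[[1]]
    kw <- tolower(toks[1])
    args <- toks[-1]
    if (!kw %in% c("all", "heavy") && !length(args))
      ck_stop("selection_grammar_error",
              sprintf("clause %d ('%s'): keyword '%s' needs arguments",
                      pos, cl, kw))
    m <- switch(kw,
      all = rep(TRUE, nrow(a)),
      heavy = toupper(a$element) != "H",
      name = a$atom_name %in% args,
      resname = a$residue_name %in% args,
      segid = a$segment_id %in% args,
      element = toupper(a$element) %in% toupper(args),
      resid = {
        ids <- integer(0)
        for (tok in args) {
          if (grepl("^-?[0-9]+--?[0-9]+$", tok) && grepl("-", substring(tok, 2))) {
            # split on the range dash, honouring a possible leading minus
            body <- substring(tok, 2)
            dash <- regexpr("-", body) + 1L
            lo <- as.integer(substr(tok, 1, dash - 1))
            hi <- as.integer(substring(tok, dash + 1))
            ids <- c(ids, seq(lo, hi))
          } else if (grepl("^-?[0-9]+$", tok)) {
            ids <- c(ids, as.integer(tok))
          } else {
            ck_stop("selection_grammar_error",
                    sprintf("clause %d: bad resid token '%s'", pos, tok))
          }
        }
        a$residue_index %in% ids
      },
      ck_stop("selection_grammar_error",
              sprintf("clause %d: unknown keyword '%s'", pos, kw))
    )
    mask <- mask & m
    pos <- pos + 1L
  }
  idx <- which(mask)
  if (!length(idx))
    ck_log("info", "selection matched no atoms", expression = expression)
  structure(list(expression = expression, indices = idx),
            class = "AtomSelection")
}

#' @export
print.AtomSelection <- function(x, ...) {
  cat(sprintf("<AtomSelection> '%s': %d atoms\n", x$expression,
              length(x$indices)))
  invisible(x)
}

# Accept either an AtomSelection or a raw index vector everywhere.
sel_indices <- function(sel) {
  if (inherits(sel, "AtomSelection")) sel$indices
  else if (is.numeric(sel)) as.integer(sel)
  else ck_stop("type_error", "expected AtomSelection or integer indices")
}
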