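#' 2-D histogram of two angle series as a normalized joint distribution
#'
#' Counts are normalized to probability mass. When comparing systems (e.g.
#' chromatosome vs nucleosome) use a fixed common `range` so the grids match.
#'
#' @param x,y numeric series of equal length (degrees)
#' @param bins number of bins per axis (>= 2)
#' @param range optional list with elements `x` and `y`, each `c(lo, hi)`;
#'   data range used when NULL
#' @return object of class `JointDistribution`: `x_edges`, `y_edges`,
#'   `P` (bins x bins mass matrix), `n_samples`
#' @export
histogram2d <- function(x, y, bins = 50L, range = NULL) {
  if (bins < 2) ck_stop("parameter_error", "bins must be >= 2")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) != length(y) || length(x) < 1)
    ck_stop("empty_input", "histogram2d needs equal-length non-empty series")
  rx <- if (is.null(range)) base::range(x) else range$x
  ry <- if (is.null(range)) base::range(y) else range$y
  if (rx[1] == rx[2]) rx <- rx + c(-0.5, 0.5)
  if (ry[1] == ry[2]) ry <- ry + c(-0.5, 0.5)
  xe <- seq(rx[1], rx[2], length.out = bins + 1)
  ye <- seq(ry[1], ry[2], length.out = bins + 1)
  ix <- pmin(pmax(findInterval(x, xe, rightmost.closed = TRUE), 1L), bins)
  iy <- pmin(pmax(findInterval(y, ye, rightmost.closed = TRUE), 1L), bins)
  P <- matrix(0, bins, bins)
  tab <- table(factor(ix, levels = seq_len(bins)),
               factor(iy, levels = seq_len(bins)))
  P[] <- as.numeric(tab) / length(x)
  structure(list(x_edges = xe, y_edges = ye, P = P,
                 n_samples = length(x)),
            class = "JointDistribution")
}

#' Mutual information and NMI of a joint distribution
#'
#' MI and the marginal entropies are computed in bits (base-2 logs);
#' `0 * log(0)` terms are dropped. The normalized mutual information is
#' `NMI = MI / sqrt(Hx * Hy)` (geometric-mean normalization, bounded in
#' \[0, 1\]); NMI is defined as 0 when either marginal entropy vanishes.
#'
#' @param J a `JointDistribution` (or a plain normalized matrix)
#' @return list of class `MutualInformationResult`: `mi`, `h_x`, `h_y`,
#'   `nmi`
#' @export
mutual_information <- function(J) {
  P <- if (inherits(J, "JointDistribution")) J$P else as.matrix(J)
  if (abs(sum(P) - 1) > 1e-9)
    ck_stop("parameter_error", "joint distribution is not normalized")
  px <- rowSums(P); py <- colSums(P)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  h_x <- ent(px); h_y <- ent(py)
  nz <- which(P > 0, arr.ind = TRUE)
  mi <- sum(P[nz] * log2(P[nz] / (px[nz[, 1]] * py[nz[, 2]])))
  mi <- max(mi, 0)  # guard tiny negative rounding
  nmi <- if (h_x <= 0 || h_y <= 0) 0 else mi / sqrt(h_x * h_y)
  structure(list(mi = mi, h_x = h_x, h_y = h_y,
                 nmi = min(max(nmi, 0), 1)),
            class = "MutualInformationResult")
}

#' Kullback-Leibler divergence D(P || Q) on a shared grid
#'
#' `sum(P * log(P / Q))` in nats. P is the data distribution (e.g.
#' chromatosome angles) and Q the reference (nucleosome angles). Because the
#' divergence is undefined on reference bins with zero mass, a pseudo-mass
#' `epsilon` is added to every cell of both distributions, which are then
#' renormalized; the default `1 / (10 * n)` vanishes as sampling grows.
#'
#' @param P,Q `JointDistribution`s on identical grids, or plain arrays of
#'   equal shape, each summing to 1
#' @param epsilon per-cell pseudo-mass (>= 0)
#' @return divergence in nats (finite, >= 0 up to regularization)
#' @export
kl_divergence <- function(P, Q, epsilon = NULL) {
  get_p <- function(Z) if (inherits(Z, "JointDistribution")) Z$P else
    as.array(Z)
  n <- if (inherits(P, "JointDistribution")) P$n_samples else NULL
  if (inherits(P, "JointDistribution") && inherits(Q, "JointDistribution")) {
    if (!isTRUE(all.equal(P$x_edges, Q$x_edges)) ||
        !isTRUE(all.equal(P$y_edges, Q$y_edges)))
      ck_stop("grid_mismatch", "P and Q are binned on different grids")
  }
  p <- get_p(P); q <- get_p(Q)
  if (!identical(dim(p) %||% length(p), dim(q) %||% length(q)))
    ck_stop("grid_mismatch", "P and Q have different shapes")
  if (abs(sum(p) - 1) > 1e-9 || abs(sum(q) - 1) > 1e-9)
    ck_stop("parameter_error", "distributions must be normalized")
  if (is.null(epsilon)) epsilon <- 1 / (10 * (n %||% 1e4))
  if (epsilon > 0) {
    p <- p + epsilon; p <- p / sum(p)
    q <- q + epsilon; q <- q / sum(q)
  }
  nz <- p > 0
  if (any(q[nz] == 0)) return(Inf)
  sum(p[nz] * log(p[nz] / q[nz]))
}

#' Pairwise NMI/KL summary over named angle series
#'
#' Convenience twin of the paper-style angle-correlation tables: for each
#' requested pair, the NMI on the system's own joint distribution and, when a
#' reference system is given, the NMI ratio over the reference and the KL
#' divergence of the system's joint from the reference's (shared fixed grid
#' across both systems).
#'
#' @param series named list of numeric angle series for the system under study
#' @param pairs data.frame or list of length-2 character vectors naming series
#' @param reference optional named list of reference series (same names)
#' @param bins bins per axis
#' @return data.frame with columns `x`, `y`, `nmi`, and when a reference is
#'   present `nmi_ref`, `nmi_ratio`, `kl`
#' @export
dyndist_summary <- function(series, pairs, reference = NULL, bins = 50L) {
  if (is.data.frame(pairs)) pairs <- asplit(as.matrix(pairs), 1)
  rows <- lapply(pairs, function(pr) {
    x <- series[[pr[[1]]]]; y <- series[[pr[[2]]]]
    if (is.null(x) || is.null(y))
      ck_stop("parameter_error", sprintf("unknown series in pair %s:%s",
                                         pr[[1]], pr[[2]]))
    if (is.null(reference)) {
      J <- histogram2d(x, y, bins)
      return(data.frame(x = pr[[1]], y = pr[[2]],
                        nmi = mutual_information(J)$nmi))
    }
    rx <- reference[[pr[[1]]]]; ry <- reference[[pr[[2]]]]
    rng <- list(x = base::range(c(x, rx), finite = TRUE),
                y = base::range(c(y, ry), finite = TRUE))
    J <- histogram2d(x, y, bins, rng)
    Jr <- histogram2d(rx, ry, bins, rng)
    nmi <- mutual_information(J)$nmi
    nmi_ref <- mutual_information(Jr)$nmi
    data.frame(x = pr[[1]], y = pr[[2]], nmi = nmi, nmi_ref = nmi_ref,
               nmi_ratio = if (nmi_ref > 0) nmi / nmi_ref else NA_real_,
               kl = kl_divergence(J, Jr))
  })
  do.call(rbind, rows)
}
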