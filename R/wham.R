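KB_KCAL <- 0.0019872041  # Boltzmann constant, kcal mol^-1 K^-1

#' Umbrella-sampling window
#'
#' A biased time series of a reaction coordinate (degrees) harvested with a
#' harmonic restraint `w(xi) = k (xi - center)^2` (no 1/2 factor; the
#' colvars/Grossfield convention — see [wham_config()]).
#'
#' @param center restraint centre, degrees
#' @param force_constant k, kcal mol^-1 deg^-2 (> 0)
#' @param samples time-ordered reaction-coordinate values, degrees
#' @param equilibration_cut samples dropped from the front
#' @param g statistical inefficiency; `NA` until computed
#' @return object of class `UmbrellaWindow`
#' @export
umbrella_window <- function(center, force_constant, samples,
                            equilibration_cut = 0L, g = NA_real_) {
  if (force_constant < 0) ck_stop("parameter_error", "force_constant < 0")
  if (equilibration_cut > 0) samples <- samples[-seq_len(equilibration_cut)]
  if (length(samples) < 10)
    ck_stop("parameter_error", "window needs >= 10 post-cut samples")
  if (!is.na(g) && g < 1) ck_stop("parameter_error", "g must be >= 1")
  structure(list(center = center, force_constant = force_constant,
                 samples = as.numeric(samples),
                 equilibration_cut = as.integer(equilibration_cut), g = g),
            class = "UmbrellaWindow")
}

#' WHAM solver configuration
#'
#' @param n_bins number of reaction-coordinate bins (default 100)
#' @param tolerance convergence threshold on the max change of the window
#'   free-energy offsets f_i, kcal/mol
#' @param max_iterations iteration cap
#' @param temperature K
#' @param bootstrap_trials Monte-Carlo bootstrap trials (>= 1)
#' @param seed RNG seed used by [bootstrap_pmf()]
#' @param range optional fixed `c(lo, hi)` bin range, degrees
#' @param half_k use the `1/2 k (xi-c)^2` bias convention instead of
#'   `k (xi-c)^2`
#' @return object of class `WhamConfig`
#' @export
wham_config <- function(n_bins = 100L, tolerance = 1e-6,
                        max_iterations = 100000L, temperature = 300,
                        bootstrap_trials = 100L, seed = 1L, range = NULL,
                        half_k = FALSE) {
  if (tolerance <= 0) ck_stop("parameter_error", "tolerance must be > 0")
  if (bootstrap_trials < 1) ck_stop("parameter_error",
                                    "bootstrap_trials must be >= 1")
  structure(list(n_bins = as.integer(n_bins), tolerance = tolerance,
                 max_iterations = as.integer(max_iterations),
                 temperature = temperature,
                 bootstrap_trials = as.integer(bootstrap_trials),
                 seed = as.integer(seed), range = range, half_k = half_k),
            class = "WhamConfig")
}

#' Statistical inefficiency of a time series
#'
#' `g = 1 + 2 * sum(C(t))` with the normalized autocorrelation summed until
#' its first non-positive value, clamped to `g >= 1`. The effective number of
#' independent samples is `N / g`. A constant series returns `g = 1` with a
#' warning.
#'
#' @param x numeric time series (length >= 50)
#' @return g (dimensionless, >= 1)
#' @export
statistical_inefficiency <- function(x) {
  n <- length(x)
  if (n < 50) ck_stop("parameter_error",
                      "statistical_inefficiency needs >= 50 samples")
  x <- x - mean(x)
  v <- sum(x^2) / n
  if (v == 0) {
    ck_warn("zero-variance series; g = 1")
    return(1)
  }
  # FFT-based autocovariance, biased normalization (1/n)
  m <- 2^ceiling(log2(2 * n))
  fx <- stats::fft(c(x, rep(0, m - n)))
  ac <- Re(stats::fft(fx * Conj(fx), inverse = TRUE))[seq_len(n)] / m / n
  rho <- ac / ac[1]
  g <- 1
  for (t in 2:n) {
    if (rho[t] <= 0) break
    g <- g + 2 * rho[t]
  }
  max(g, 1)
}

.wham_bias <- function(centers, k, xi, half_k) {
  # windows x bins matrix of bias energies
  pref <- if (half_k) 0.5 else 1
  pref * outer(k, rep(1, length(xi))) * outer(centers, xi, function(c, x)
    (x - c)^2)
}

.wham_core <- function(counts, N, w_kT, tolerance, max_iterations) {
  # counts: windows x bins; w_kT: windows x bins bias in kT units
  f <- rep(0, nrow(counts))          # dimensionless window offsets (f_i/kT)
  tot <- colSums(counts)
  ew <- exp(-w_kT)
  for (it in seq_len(max_iterations)) {
    denom <- colSums(N * exp(f) * ew)     # per bin
    p <- tot / denom
    p[!is.finite(p)] <- 0
    fn <- -log(pmax(ew %*% p, .Machine$double.xmin))
    fn <- fn - fn[1]
    delta <- max(abs(fn - f))
    f <- as.numeric(fn)
    if (delta < tolerance) return(list(p = p, f = f, iterations = it,
                                       residual = delta))
  }
  ck_stop("convergence_error",
          sprintf("WHAM did not converge in %d iterations (residual %.3g)",
                  max_iterations, delta),
          residual = delta)
}

.wham_histograms <- function(windows, config) {
  all_x <- unlist(lapply(windows, `[[`, "samples"))
  rng <- config$range %||% range(all_x)
  edges <- seq(rng[1], rng[2], length.out = config$n_bins + 1)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  counts <- t(vapply(windows, function(w) {
    ix <- findInterval(w$samples, edges, rightmost.closed = TRUE)
    tabulate(ix[ix >= 1 & ix <= config$n_bins], nbins = config$n_bins)
  }, numeric(config$n_bins)))
  list(edges = edges, mids = mids, counts = counts)
}

.check_overlap <- function(windows, counts) {
  ord <- order(vapply(windows, `[[`, numeric(1), "center"))
  occ <- counts[ord, , drop = FALSE] > 0
  if (nrow(occ) < 2) return(invisible(TRUE))
  for (i in seq_len(nrow(occ) - 1)) {
    if (!any(occ[i, ] & occ[i + 1, ]))
      ck_stop("coverage_error",
              sprintf("windows centred at %.3g and %.3g share no occupied bin",
                      windows[[ord[i]]]$center, windows[[ord[i + 1]]]$center))
  }
  invisible(TRUE)
}

#' Solve WHAM for a set of umbrella windows
#'
#' Standard self-consistent WHAM: the unbiased bin probability is
#' `p(b) = sum_i n_i(b) / sum_i N_i exp[(f_i - w_i(b)) / kT]` with
#' `f_i = -kT log sum_b p(b) exp(-w_i(b)/kT)`, iterated until the maximum
#' change in the `f_i` falls below the tolerance. The output free energy is
#' `-kT log p`, shifted so its minimum is 0.
#'
#' @param windows list of [umbrella_window()]s with overlapping coverage
#' @param config a [wham_config()]
#' @return object of class `PmfProfile`: `bin_centers`, `free_energy`,
#'   `stderr` (NA until [bootstrap_pmf()]), `temperature`, `reference_policy`
#' @export
wham_solve <- function(windows, config = wham_config()) {
  h <- .wham_histograms(windows, config)
  .check_overlap(windows, h$counts)
  kT <- KB_KCAL * config$temperature
  w <- .wham_bias(vapply(windows, `[[`, numeric(1), "center"),
                  vapply(windows, `[[`, numeric(1), "force_constant"),
                  h$mids, config$half_k) / kT
  N <- vapply(windows, function(x) length(x$samples), numeric(1))
  sol <- .wham_core(h$counts, N, w, config$tolerance / kT,
                    config$max_iterations)
  F <- ifelse(sol$p > 0, -kT * log(sol$p), NA_real_)
  F <- F - min(F, na.rm = TRUE)
  structure(list(bin_centers = h$mids, free_energy = F,
                 stderr = rep(NA_real_, length(F)),
                 temperature = config$temperature,
                 reference_policy = "minimum-shifted-to-zero",
                 iterations = sol$iterations),
            class = "PmfProfile")
}

#' @export
print.PmfProfile <- function(x, ...) {
  cat(sprintf(
    "<PmfProfile> %d bins over [%.2f, %.2f], T = %g K, max F = %.3f kcal/mol\n",
    length(x$bin_centers), min(x$bin_centers), max(x$bin_centers),
    x$temperature, max(x$free_energy, na.rm = TRUE)))
  invisible(x)
}

#' Monte-Carlo bootstrap errors for a WHAM PMF
#'
#' Each trial redraws, per window, `ceiling(N_i / g_i)` samples with
#' replacement (the statistically independent count from the window's
#' statistical inefficiency), re-solves WHAM on the common bin grid, and
#' aligns the trial profile to minimum 0. The per-bin standard deviation over
#' trials is the bootstrap error. Windows without a precomputed `g` get one
#' computed here.
#'
#' @param windows list of [umbrella_window()]s
#' @param config a [wham_config()]; `bootstrap_trials` and `seed` are used
#' @return a `PmfProfile` with `stderr` filled in (plus `n_failed` attribute)
#' @export
bootstrap_pmf <- function(windows, config = wham_config()) {
  windows <- lapply(windows, function(w) {
    if (is.na(w$g)) w$g <- statistical_inefficiency(w$samples)
    w
  })
  base_cfg <- config
  if (is.null(base_cfg$range)) {
    allx <- unlist(lapply(windows, `[[`, "samples"))
    base_cfg$range <- range(allx)
  }
  full <- wham_solve(windows, base_cfg)
  set.seed(config$seed)
  trials <- matrix(NA_real_, config$bootstrap_trials,
                   length(full$bin_centers))
  n_failed <- 0L
  for (tr in seq_len(config$bootstrap_trials)) {
    wb <- lapply(windows, function(w) {
      n_eff <- max(10L, ceiling(length(w$samples) / w$g))
      w$samples <- sample(w$samples, n_eff, replace = TRUE)
      w
    })
    res <- tryCatch(wham_solve(wb, base_cfg), chromkit_error = function(e) e)
    if (inherits(res, "chromkit_error")) { n_failed <- n_failed + 1L; next }
    trials[tr, ] <- res$free_energy
  }
  if (n_failed > 0.2 * config$bootstrap_trials)
    ck_stop("bootstrap_instability",
            sprintf("%d of %d bootstrap trials failed", n_failed,
                    config$bootstrap_trials))
  se <- apply(trials, 2, function(col) {
    ok <- is.finite(col)
    if (sum(ok) >= 2) stats::sd(col[ok]) else NA_real_
  })
  if (config$bootstrap_trials == 1) se <- rep(0, length(se))
  full$stderr <- se
  attr(full, "n_failed") <- n_failed
  full
}

#' WHAM convergence over cumulative time blocks
#'
#' Re-solves WHAM on the first 1/n, 2/n, ..., n/n of each window's samples
#' and reports the maximum absolute free-energy deviation between the final
#' two blocks. A deviation flag is raised when that deviation exceeds
#' `flag_threshold`.
#'
#' @param windows list of [umbrella_window()]s
#' @param config a [wham_config()]
#' @param n_blocks number of cumulative blocks (>= 2)
#' @param flag_threshold kcal/mol; default 0.5
#' @return list: `profiles` (one `PmfProfile` per block), `max_deviation`
#'   (final two blocks, kcal/mol), `flagged` (logical)
#' @export
pmf_convergence <- function(windows, config = wham_config(), n_blocks = 2L,
                            flag_threshold = 0.5) {
  if (n_blocks < 2) ck_stop("parameter_error", "n_blocks must be >= 2")
  cfg <- config
  if (is.null(cfg$range))
    cfg$range <- range(unlist(lapply(windows, `[[`, "samples")))
  profiles <- lapply(seq_len(n_blocks), function(b) {
    wb <- lapply(windows, function(w) {
      n <- length(w$samples)
      keep <- max(10L, floor(n * b / n_blocks))
      w$samples <- w$samples[seq_len(min(keep, n))]
      w
    })
    wham_solve(wb, cfg)
  })
  a <- profiles[[n_blocks - 1]]$free_energy
  b <- profiles[[n_blocks]]$free_energy
  dev <- max(abs(a - b), na.rm = TRUE)
  list(profiles = profiles, max_deviation = dev,
       flagged = dev > flag_threshold)
}

#' Read Grossfield-layout umbrella metadata and window time series
#'
#' The metadata CSV has columns `path, center, force_constant`; each window
#' file is whitespace- or comma-separated with two columns (time, value).
#' Relative window paths are resolved against the metadata file's directory.
#'
#' @param meta_path metadata CSV
#' @param equilibration_cut samples dropped per window
#' @return list of `UmbrellaWindow`s
#' @export
read_umbrella_meta <- function(meta_path, equilibration_cut = 0L) {
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  req <- c("path", "center", "force_constant")
  if (!all(req %in% names(meta)))
    ck_stop("schema_error", "metadata needs columns path, center, force_constant")
  lapply(seq_len(nrow(meta)), function(i) {
    p <- meta$path[i]
    if (!file.exists(p)) p <- file.path(dirname(meta_path), meta$path[i])
    tab <- utils::read.table(p, header = FALSE, sep = "",
                             comment.char = "#")
    umbrella_window(meta$center[i], meta$force_constant[i], tab[[2]],
                    equilibration_cut = equilibration_cut)
  })
}
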