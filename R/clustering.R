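#' Pairwise RMSD matrix between trajectory frames
#'
#' Every frame is first rigid-body superposed onto a common reference using
#' `fit_sel` (align-once-to-reference, e.g. fit on core-histone helical CA);
#' the matrix entry (i, j) is then the RMSD of `measure_sel` between the
#' aligned frames i and j (e.g. linker-histone helical CA). Zero diagonal,
#' symmetric. Set `mutual = TRUE` for pairwise mutual superposition on
#' `fit_sel` instead.
#'
#' @param traj a `Trajectory` with >= 2 frames
#' @param fit_sel,measure_sel selections (or index vectors)
#' @param reference `StructureFrame`; frame 1 when NULL
#' @param mutual logical; pairwise mutual fit instead of align-once
#' @return symmetric n_frames x n_frames matrix, Angstrom
#' @export
pairwise_rmsd_matrix <- function(traj, fit_sel, measure_sel,
                                 reference = NULL, mutual = FALSE) {
  nf <- n_frames(traj)
  if (nf < 2) ck_stop("parameter_error", "need >= 2 frames")
  fi <- sel_indices(fit_sel); mi <- sel_indices(measure_sel)
  if (mutual) {
    M <- matrix(0, nf, nf)
    for (i in seq_len(nf - 1)) for (j in (i + 1):nf) {
      fit <- kabsch(traj$frames[[j]][fi, , drop = FALSE],
                    traj$frames[[i]][fi, , drop = FALSE])
      Xj <- fit$transform(traj$frames[[j]][mi, , drop = FALSE])
      M[i, j] <- M[j, i] <-
        sqrt(mean(rowSums((Xj - traj$frames[[i]][mi, , drop = FALSE])^2)))
    }
    return(M)
  }
  ref <- if (is.null(reference)) traj$frames[[1]] else reference$coords
  aligned <- lapply(traj$frames, function(X) {
    kabsch(X[fi, , drop = FALSE], ref[fi, , drop = FALSE])$transform(
      X[mi, , drop = FALSE])
  })
  flat <- do.call(rbind, lapply(aligned, as.vector))
  as.matrix(stats::dist(flat)) / sqrt(length(mi))
}

#' Hierarchical agglomerative clustering of a distance matrix
#'
#' Average-linkage agglomeration, dendrogram cut at `cutoff`. Clusters are
#' relabelled 1..k by decreasing population (ties broken by lowest member
#' frame index); the representative of each cluster is its medoid (frame
#' minimizing the summed in-cluster distance, ties to the lowest index).
#'
#' @param mat symmetric non-negative distance matrix (Angstrom)
#' @param cutoff dendrogram height cut; default 2.0
#' @param linkage only "average" is supported (exposed for config echo)
#' @return object of class `ClusterResult`: `assignments` (per frame),
#'   `populations` (data.frame `cluster`, `n`, `fraction`, descending),
#'   `representatives`, `cutoff`, `linkage`
#' @export
hierarchical_cluster <- function(mat, cutoff = 2.0,
                                 linkage = "average") {
  linkage <- match.arg(linkage, "average")
  mat <- as.matrix(mat)
  if (!isTRUE(all.equal(mat, t(mat), tolerance = 1e-8)) || any(mat < 0))
    ck_stop("matrix_validity", "distance matrix must be symmetric and >= 0")
  n <- nrow(mat)
  if (max(mat) == 0 || n == 1) {
    assign <- rep(1L, n)
  } else {
    hc <- stats::hclust(stats::as.dist(mat), method = linkage)
    assign <- stats::cutree(hc, h = cutoff)
  }
  # relabel by descending population, ties by lowest member index
  sizes <- table(assign)
  first_member <- vapply(names(sizes), function(k)
    min(which(assign == as.integer(k))), numeric(1))
  ord <- order(-as.numeric(sizes), first_member)
  relabel <- integer(length(sizes))
  relabel[as.integer(names(sizes))[ord]] <- seq_along(ord)
  assign <- relabel[assign]
  k <- max(assign)
  reps <- vapply(seq_len(k), function(cl) {
    members <- which(assign == cl)
    if (length(members) == 1) return(members)
    tot <- rowSums(mat[members, members, drop = FALSE])
    members[which.min(tot)]   # which.min takes the first (lowest index) tie
  }, integer(1))
  pops <- data.frame(cluster = seq_len(k),
                     n = as.integer(tabulate(assign, k)),
                     fraction = tabulate(assign, k) / n)
  structure(list(assignments = assign, populations = pops,
                 representatives = reps, cutoff = cutoff, linkage = linkage),
            class = "ClusterResult")
}

#' @export
print.ClusterResult <- function(x, ...) {
  cat(sprintf("<ClusterResult> %d clusters over %d frames (cutoff %.2f A)\n",
              nrow(x$populations), length(x$assignments), x$cutoff))
  invisible(x)
}

#' Clusters covering the top fraction of frames
#'
#' Smallest prefix of the population-sorted clusters whose cumulative
#' population reaches `fraction` (e.g. the clusters holding the top 90% of
#' frames).
#'
#' @param result a `ClusterResult`
#' @param fraction in (0, 1]; default 0.90
#' @return list: `clusters` (retained ids), `populations` (subset data.frame
#'   with cumulative fractions and percentages), `n_clusters`
#' @export
top_fraction <- function(result, fraction = 0.90) {
  if (fraction <= 0 || fraction > 1)
    ck_stop("parameter_error", "fraction must be in (0, 1]")
  p <- result$populations
  cum <- cumsum(p$fraction)
  keep <- seq_len(which(cum >= fraction - 1e-12)[1])
  sub <- p[keep, , drop = FALSE]
  sub$cumulative <- cum[keep]
  sub$percent <- 100 * sub$fraction
  list(clusters = sub$cluster, populations = sub, n_clusters = length(keep))
}
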