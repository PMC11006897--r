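#' Correlation-based clustering of boutons into putative axons
#'
#' Boutons belonging to one axon share trial-to-trial activity, so the
#' decoder's independence assumption requires grouping correlated ROIs
#' before decoding. All pairwise Pearson correlations are computed on the
#' full concatenated dF/F traces; pairs with `r >= r_thresh` (0.3 by
#' default) are taken as same-axon pairs. A first cluster is seeded with a
#' randomly selected qualifying pair; remaining pairs are visited in random
#' order and join an existing cluster when at least one of their ROIs is a
#' member of, or correlates at `r >= r_thresh` with at least one member of,
#' that cluster - otherwise the pair seeds a new cluster. When a pair's two
#' ROIs match different clusters it joins the cluster matched by its first
#' ROI in visiting order. ROIs in no qualifying pair become singletons.
#' Each cluster is represented by its member with the largest mean dF/F.
#'
#' @param dff ROI x time matrix of dF/F traces (full session), or an
#'   ROI x trial response matrix when trace-level data are unavailable.
#' @param r_thresh correlation threshold (default 0.3).
#' @param seed integer seed controlling the order-dependent assignment.
#' @return object of class `axon_assignment`: list with `cluster` (integer
#'   per ROI), `representative` (ROI index per cluster), `members` (list of
#'   ROI index vectors), `n_clusters`.
#' @export
cluster_axons <- function(dff, r_thresh = 0.3, seed = 1) {
  n <- nrow(dff)
  if (n < 1) stop("need at least one ROI")
  cm <- suppressWarnings(stats::cor(t(dff)))
  cm[!is.finite(cm)] <- -Inf   # zero-variance traces: below any threshold
  adj <- cm >= r_thresh
  diag(adj) <- FALSE
  pairs <- which(upper.tri(adj) & adj, arr.ind = TRUE)
  set.seed(seed)
  cluster <- rep(NA_integer_, n)
  n_clu <- 0L
  if (nrow(pairs) > 0) {
    ord <- sample.int(nrow(pairs))
    for (k in ord) {
      a <- pairs[k, 1]; b <- pairs[k, 2]
      hit <- NA_integer_
      for (roi in c(a, b)) {
        if (!is.na(cluster[roi])) { hit <- cluster[roi]; break }
        for (cl in seq_len(n_clu)) {
          if (any(adj[roi, which(cluster == cl)])) { hit <- cl; break }
        }
        if (!is.na(hit)) break
      }
      if (is.na(hit)) {
        n_clu <- n_clu + 1L
        hit <- n_clu
      }
      cluster[c(a, b)] <- ifelse(is.na(cluster[c(a, b)]), hit,
                                 cluster[c(a, b)])
    }
  }
  for (roi in which(is.na(cluster))) {
    n_clu <- n_clu + 1L
    cluster[roi] <- n_clu
  }
  members <- split(seq_len(n), cluster)
  mean_dff <- rowMeans(dff)
  representative <- vapply(members, function(m) m[which.max(mean_dff[m])],
                           integer(1))
  structure(list(cluster = cluster, representative = unname(representative),
                 members = unname(members), n_clusters = n_clu),
            class = "axon_assignment")
}

#' @export
print.axon_assignment <- function(x, ...) {
  cat(sprintf("axon_assignment: %d ROIs in %d clusters (%d multi-bouton)\n",
              length(x$cluster), x$n_clusters,
              sum(lengths(x$members) > 1)))
  invisible(x)
}

#' Axon-level trial responses
#'
#' Each cluster's activity is the trial-response row of its representative
#' ROI (the member with the largest mean dF/F), not an average over
#' members.
#'
#' @param assignment an `axon_assignment`.
#' @param responses ROI x trial matrix, rows aligned with the ROIs given to
#'   [cluster_axons()].
#' @return axon (cluster) x trial matrix.
#' @export
cluster_activity <- function(assignment, responses) {
  if (max(assignment$representative) > nrow(responses))
    stop("representative ROI missing from responses")
  responses[assignment$representative, , drop = FALSE]
}
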