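## Unfolding-intermediate detection: k-means clustering of frames in the
## (CA-RMSD, main-chain H-bond count) plane with silhouette validation.
## Features are used in raw units (nm; counts) by default so centroids are
## directly comparable to reported values; standardization is optional.

#' Build the (RMSD, H-bond count) feature matrix of a trajectory
#'
#' The two reaction coordinates used for intermediate detection: tertiary
#' structure change as CA RMSD against a reference, and secondary structure
#' as the main-chain hydrogen-bond count.
#'
#' @param traj an \code{mdtraj}.
#' @param reference reference \code{mdframe} for the RMSD (default first
#'   frame).
#' @return n x 2 matrix with columns \code{rmsd} (nm) and \code{hbonds},
#'   with frame times (ps) in attribute \code{"times"}.
#' @export
build_features <- function(traj, reference = traj$frames[[1]]) {
  m <- cbind(rmsd = rmsd_series(traj, reference),
             hbonds = vapply(traj$frames, count_mainchain_hbonds, numeric(1)))
  attr(m, "times") <- frame_times(traj)
  m
}

## k-means++ seeding (Arthur & Vassilvitskii): first centre uniform, later
## centres with probability proportional to squared distance to the nearest
## chosen centre.
.kmeanspp_centers <- function(points, k) {
  n <- nrow(points)
  centers <- matrix(NA_real_, k, ncol(points))
  centers[1, ] <- points[sample.int(n, 1), ]
  if (k > 1) for (j in 2:k) {
    d2 <- apply(points, 1, function(p)
      min(colSums((t(centers[seq_len(j - 1), , drop = FALSE]) - p)^2)))
    if (sum(d2) <= 0) {
      centers[j, ] <- points[sample.int(n, 1), ]
    } else {
      centers[j, ] <- points[sample.int(n, 1, prob = d2), ]
    }
  }
  centers
}

#' k-means clustering with seeded k-means++ restarts
#'
#' Lloyd iterations (squared-Euclidean assignment, via
#' \code{stats::kmeans(algorithm = "Lloyd")}) from 10 seeded k-means++
#' initializations; the restart with the lowest total within-cluster sum of
#' squares is kept. Deterministic given \code{seed}.
#'
#' @param points n x 2 (or n x d) numeric matrix.
#' @param k number of clusters, 1 <= k <= n.
#' @param seed integer RNG seed.
#' @param nstart number of k-means++ restarts (default 10).
#' @return object of class \code{"cluster_result"}: list with \code{k},
#'   \code{labels}, \code{centroids}, \code{inertia}, \code{seed}
#'   (silhouettes are added by \code{\link{cluster_silhouette}} /
#'   \code{\link{cluster_trajectory}}).
#' @export
kmeans_cluster <- function(points, k, seed = 1, nstart = 10) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (k < 1 || k > n) stop("need 1 <= k <= number of points")
  if (k > 1 && nrow(unique(points)) < k)
    stop("degenerate input: fewer distinct points than clusters")
  set.seed(seed)
  best <- NULL
  for (s in seq_len(nstart)) {
    ctrs <- .kmeanspp_centers(points, k)
    km <- suppressWarnings(
      kmeans(points, centers = ctrs, iter.max = 100, algorithm = "Lloyd"))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  structure(list(k = k, labels = as.integer(best$cluster),
                 centroids = unname(best$centers),
                 inertia = best$tot.withinss, seed = seed,
                 silhouettes = NULL, mean_silhouette = NA_real_,
                 points = points),
            class = "cluster_result")
}

#' Silhouette widths for a clustering
#'
#' Per-point silhouette \eqn{s(i) = (b(i) - a(i)) / \max(a(i), b(i))} with
#' Euclidean distances (via \code{cluster::silhouette}); points in singleton
#' clusters get s = 0. Values near +1 mark points far from neighbouring
#' clusters, near 0 points between clusters, negative values probable
#' misassignments.
#'
#' @param points n x d matrix.
#' @param labels integer cluster labels with >= 2 non-empty clusters.
#' @return list with \code{widths} (per point) and \code{mean}.
#' @export
cluster_silhouette <- function(points, labels) {
  if (length(unique(labels)) < 2) stop("silhouette requires k >= 2")
  sil <- cluster::silhouette(as.integer(labels), dist(as.matrix(points)))
  w <- as.numeric(sil[, "sil_width"])
  list(widths = w, mean = mean(w))
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> k = %d, inertia = %.4g, mean silhouette = %s\n",
              x$k, x$inertia,
              if (is.na(x$mean_silhouette)) "not computed"
              else sprintf("%.3f", x$mean_silhouette)))
  for (j in seq_len(x$k)) {
    cat(sprintf("  cluster %d: n = %d, centroid = (%s)\n", j,
                sum(x$labels == j),
                paste(sprintf("%.3g", x$centroids[j, ]), collapse = ", ")))
  }
  invisible(x)
}

#' @export
plot.cluster_result <- function(x, xlab = "RMSD (nm)",
                                ylab = "main-chain H-bonds", ...) {
  graphics::plot(x$points, col = x$labels, pch = 16,
                 xlab = xlab, ylab = ylab, ...)
  graphics::points(x$centroids, pch = 8, cex = 2, col = seq_len(x$k))
  invisible(x)
}

#' Cluster a trajectory into candidate intermediates
#'
#' Runs \code{\link{kmeans_cluster}} + \code{\link{cluster_silhouette}} on
#' the (RMSD, H-bond) features and reports, for each cluster, the maximal
#' contiguous time intervals in which that cluster holds more than half of
#' the frames -- the persistent phases interpreted as unfolding
#' intermediates.
#'
#' @param traj an \code{mdtraj}.
#' @param reference reference frame for the RMSD (default first frame).
#' @param k number of clusters (default 3: native-like, intermediate,
#'   unfolded).
#' @param seed RNG seed for the clustering restarts.
#' @param standardize scale each feature to unit variance before clustering
#'   (default FALSE: raw nm / count units).
#' @return a \code{cluster_result} with silhouettes filled in and a
#'   \code{phases} data.frame (cluster, start_ps, end_ps, n_frames) ordered
#'   by start time.
#' @export
cluster_trajectory <- function(traj, reference = traj$frames[[1]], k = 3,
                               seed = 1, standardize = FALSE) {
  feats <- build_features(traj, reference)
  times <- attr(feats, "times")
  pts <- feats
  if (standardize) pts <- scale(pts)
  cr <- kmeans_cluster(pts, k, seed = seed)
  if (standardize) {
    # report centroids back in raw units
    ctr <- sapply(seq_len(ncol(feats)), function(j)
      tapply(feats[, j], cr$labels, mean))
    cr$centroids <- matrix(ctr, nrow = k)
  }
  sil <- cluster_silhouette(pts, cr$labels)
  cr$silhouettes <- sil$widths
  cr$mean_silhouette <- sil$mean
  cr$points <- feats
  cr$phases <- .cluster_phases(cr$labels, times)
  cr
}

## Maximal runs of a (mode-smoothed) label series; a run is kept when its
## cluster holds > 50% of the raw frames inside the interval.
.cluster_phases <- function(labels, times, smooth = 5) {
  n <- length(labels)
  half <- smooth %/% 2
  sm <- vapply(seq_len(n), function(i) {
    w <- labels[max(1, i - half):min(n, i + half)]
    as.integer(names(which.max(table(w))))
  }, integer(1))
  r <- rle(sm)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- vapply(seq_along(r$values), function(j) {
    mean(labels[starts[j]:ends[j]] == r$values[j]) > 0.5
  }, logical(1))
  out <- data.frame(cluster = r$values[keep],
                    start_ps = times[starts[keep]],
                    end_ps = times[ends[keep]],
                    n_frames = r$lengths[keep])
  out[order(out$start_ps), , drop = FALSE]
}

#' Silhouette scan over candidate cluster counts
#'
#' @param points feature matrix.
#' @param k_range candidate k values (default 2:6).
#' @param seed RNG seed.
#' @return data.frame with columns \code{k} and \code{mean_silhouette}.
#' @export
silhouette_scan <- function(points, k_range = 2:6, seed = 1) {
  data.frame(k = k_range, mean_silhouette = vapply(k_range, function(k) {
    cr <- kmeans_cluster(points, k, seed = seed)
    cluster_silhouette(points, cr$labels)$mean
  }, numeric(1)))
}

#' Detect plateaus in a time series
#'
#' Maximal intervals over which the moving least-squares slope magnitude
#' stays below \code{slope_tol} times the global scale (range / duration).
#' Operationalizes the by-eye identification of persistence plateaus in
#' RMSD, H-bond or ellipticity traces.
#'
#' @param times times in ps.
#' @param values series values.
#' @param window moving window width in ns.
#' @param slope_tol slope tolerance relative to global range/duration
#'   (default 0.1).
#' @return data.frame with columns \code{start_ps} and \code{end_ps}, one
#'   row per plateau (possibly zero rows).
#' @export
plateau_detect <- function(times, values, window = 2, slope_tol = 0.1) {
  stopifnot(length(times) == length(values))
  t_ns <- times / 1000
  span <- diff(range(t_ns))
  if (span < 2 * window) stop("series shorter than twice the window")
  rng <- diff(range(values))
  if (rng == 0) {
    return(data.frame(start_ps = times[1], end_ps = times[length(times)]))
  }
  thresh <- slope_tol * rng / span
  flat <- vapply(seq_along(t_ns), function(i) {
    sel <- which(abs(t_ns - t_ns[i]) <= window / 2)
    if (length(sel) < 3) return(FALSE)
    tt <- t_ns[sel] - mean(t_ns[sel]); vv <- values[sel]
    abs(sum(tt * (vv - mean(vv))) / sum(tt^2)) <= thresh
  }, logical(1))
  r <- rle(flat)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= 2
  data.frame(start_ps = times[starts[keep]], end_ps = times[ends[keep]])
}
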