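# Cross-organ trajectory clustering: z-scored per-timepoint expression
# trajectories, Bezdek fuzzy c-means with k-means++ initialization, and
# data-driven choice of the cluster number via the minimum centroid
# distance (Dmin) curve.

#' Z-scored expression trajectories
#'
#' For every (feature, tissue) pair, the trajectory is the mean rpmm per
#' timepoint, standardized to mean 0 and unit sample s.d. (denominator
#' n-1). Constant trajectories carry no shape information and are dropped
#' (with a message).
#'
#' @param cm multi-tissue `count_matrix`.
#' @param features features to include (default all).
#' @param tissues tissues to include (default all).
#' @return list of class `trajectory_set`: `matrix` (key x timepoint
#'   z-scores), `keys` (data.frame feature_id, tissue), `timepoints`.
#' @export
zscore_trajectories <- function(cm, features = rownames(cm$counts),
                                tissues = unique(cm$samples$tissue)) {
  tps <- sort(unique(cm$samples$age_months))
  if (length(tps) < 2) stop("need at least 2 timepoints")
  rows <- list()
  keys <- list()
  k <- 1
  n_const <- 0
  for (t in tissues) {
    cmt <- cm_tissue(cm, t)
    feats <- intersect(features, rownames(cmt$counts))
    if (!length(feats)) next
    tp_here <- sort(unique(cmt$samples$age_months))
    if (!identical(tp_here, tps)) {
      stop("tissue '", t, "' does not cover the common timepoint grid")
    }
    traj <- vapply(tp_here, function(tp) {
      rowMeans(cmt$normalized[feats, cmt$samples$age_months == tp,
                              drop = FALSE])
    }, numeric(length(feats)))
    traj <- matrix(traj, nrow = length(feats))
    for (i in seq_along(feats)) {
      s <- stats::sd(traj[i, ])
      if (is.na(s) || s == 0) {
        n_const <- n_const + 1
        next
      }
      rows[[k]] <- (traj[i, ] - mean(traj[i, ])) / s
      keys[[k]] <- data.frame(feature_id = feats[i], tissue = t,
                              stringsAsFactors = FALSE)
      k <- k + 1
    }
  }
  if (!length(rows)) stop("no non-constant trajectories")
  mat <- do.call(rbind, rows)
  keys <- do.call(rbind, keys)
  rownames(keys) <- NULL
  colnames(mat) <- tps[seq_len(ncol(mat))]
  if (n_const > 0) message(sprintf("dropped %d constant trajectories", n_const))
  structure(list(matrix = mat, keys = keys, timepoints = tps),
            class = "trajectory_set")
}

#' Estimate the fuzzifier from data dimensions
#'
#' Schwämmle-Jensen rule relating the fuzzifier to the number of points N
#' and the dimensionality D:
#' `m = 1 + (1418/N + 22.05) D^-2 + (12.33/N + 0.243) D^(-0.0406 ln N - 0.1134)`.
#' With a fixed large fuzzifier (e.g. 2) on noise-dominated,
#' high-dimensional expression data, memberships degenerate toward
#' uniformity and all centroids collapse onto the grand mean; this
#' estimate keeps the clustering informative across data sizes.
#'
#' @param x numeric matrix (rows = points) or `trajectory_set`.
#' @return fuzzifier m > 1.
#' @export
mestimate <- function(x) {
  if (inherits(x, "trajectory_set")) x <- x$matrix
  n <- nrow(x)
  d <- ncol(x)
  1 + (1418 / n + 22.05) * d^-2 +
    (12.33 / n + 0.243) * d^(-0.0406 * log(n) - 0.1134)
}

## squared Euclidean distances points x centroids
sqdist <- function(x, centers) {
  outer(rowSums(x^2), rep(1, nrow(centers))) +
    outer(rep(1, nrow(x)), rowSums(centers^2)) - 2 * x %*% t(centers)
}

kmeanspp_init <- function(x, c) {
  n <- nrow(x)
  idx <- sample.int(n, 1)
  for (j in seq_len(c - 1)) {
    d2 <- apply(pmax(sqdist(x, x[idx, , drop = FALSE]), 0), 1, min)
    if (all(d2 == 0)) {
      idx <- c(idx, sample.int(n, 1))
    } else {
      idx <- c(idx, sample.int(n, 1, prob = d2))
    }
  }
  x[idx, , drop = FALSE]
}

#' Fuzzy c-means clustering
#'
#' Standard Bezdek updates: membership
#' `u_ik = 1 / sum_j (d_ik / d_jk)^(2/(m-1))`, centroid
#' `v_k = sum_i u_ik^m x_i / sum_i u_ik^m`; iteration stops when the
#' largest centroid shift falls below `tol`. A point coinciding with a
#' centroid receives membership 1 there (singularity rule). The objective
#' `sum u^m d^2` is checked to be non-increasing every iteration.
#' Initialization is k-means++ from `seed`, deterministic.
#'
#' @param ts `trajectory_set`, or a plain numeric matrix (rows = points).
#' @param c number of clusters (>= 2).
#' @param m fuzzifier (> 1); `NULL` (default) estimates it from the data
#'   with [mestimate()].
#' @param seed RNG seed for initialization.
#' @param tol convergence tolerance on centroid shift.
#' @param max_iter iteration cap.
#' @return list of class `fuzzy_clustering`: `centroids` (c x timepoint),
#'   `memberships` (key x c, rows sum to 1), `hard_labels`, `objective`,
#'   `iterations`, `c`, `m`.
#' @export
fuzzy_cmeans <- function(ts, c, m = NULL, seed = 1, tol = 1e-8,
                         max_iter = 300) {
  x <- if (inherits(ts, "trajectory_set")) ts$matrix else as.matrix(ts)
  if (is.null(m)) m <- mestimate(x)
  if (c < 2) stop("c must be >= 2")
  if (m <= 1) stop("fuzzifier m must be > 1")
  if (nrow(x) < c) stop("fewer points than clusters")
  set.seed(seed)
  centers <- kmeanspp_init(x, c)
  obj_prev <- Inf
  it <- 0
  for (it in seq_len(max_iter)) {
    d2 <- pmax(sqdist(x, centers), 0)
    u <- membership_from_d2(d2, m)
    um <- u^m
    obj <- sum(um * d2)
    if (obj > obj_prev + 1e-8 * max(1, obj_prev)) {
      stop("fuzzy c-means objective increased; numerical failure")
    }
    new_centers <- (t(um) %*% x) / colSums(um)
    shift <- max(abs(new_centers - centers))
    centers <- new_centers
    obj_prev <- obj
    if (shift < tol) break
  }
  d2 <- pmax(sqdist(x, centers), 0)
  u <- membership_from_d2(d2, m)
  structure(list(centroids = centers, memberships = u,
                 hard_labels = max.col(u), objective = sum(u^m * d2),
                 iterations = it, c = c, m = m),
            class = "fuzzy_clustering")
}

membership_from_d2 <- function(d2, m) {
  n <- nrow(d2)
  c <- ncol(d2)
  u <- matrix(0, n, c)
  zero <- d2 <= .Machine$double.eps
  has_zero <- rowSums(zero) > 0
  if (any(has_zero)) {
    ## singularity: all mass on coinciding centroid(s)
    u[has_zero, ] <- zero[has_zero, , drop = FALSE] /
      rowSums(zero[has_zero, , drop = FALSE])
  }
  if (any(!has_zero)) {
    w <- d2[!has_zero, , drop = FALSE]^(-1 / (m - 1))
    u[!has_zero, ] <- w / rowSums(w)
  }
  u
}

#' Minimum pairwise centroid distance
#' @param centroids c x p matrix.
#' @return smallest Euclidean distance between two centroids.
#' @export
min_centroid_distance <- function(centroids) {
  min(stats::dist(centroids))
}

#' Choose the number of clusters by the Dmin curve
#'
#' For each candidate c, fuzzy c-means is run with several restarts (best
#' objective kept) and `dmin(c)`, the minimum pairwise centroid distance,
#' is recorded. Well-separated structure keeps `dmin` large until c
#' exceeds the true cluster count, after which two centroids must share a
#' cluster and `dmin` collapses; the chosen `c_opt` maximizes the relative
#' drop `dmin(c) / dmin(c+1)`, restricted to the part of the curve where
#' `dmin` is still a meaningful fraction (5%) of its maximum — drop
#' ratios between near-coincident centroids are numerical noise. When no
#' drop is pronounced (max ratio < `min_ratio`) or the centroids have
#' collapsed, the choice is flagged low-confidence.
#'
#' @param ts `trajectory_set` or matrix.
#' @param c_range integer interval `c(lo, hi)`, default from
#'   [nc_thresholds()] (2..20); lowered with a warning when there are
#'   fewer points than `hi`.
#' @param m fuzzifier.
#' @param seeds restart seeds per c.
#' @param min_ratio confidence threshold on the best drop ratio.
#' @return list: `c_opt`, `dmin_curve` (data.frame c, dmin),
#'   `low_confidence`.
#' @export
select_c <- function(ts, c_range = nc_thresholds()$c_range, m = NULL,
                     seeds = 1:3, min_ratio = 1.5) {
  x <- if (inherits(ts, "trajectory_set")) ts$matrix else as.matrix(ts)
  if (is.null(m)) m <- mestimate(x)
  lo <- c_range[1]
  hi <- c_range[2]
  if (nrow(x) <= hi) {
    hi <- nrow(x) - 1
    warning("fewer points than c_max; lowering c_max to ", hi)
  }
  cs <- lo:hi
  dmin <- vapply(cs, function(cc) {
    best <- NULL
    for (s in seeds) {
      fit <- fuzzy_cmeans(x, cc, m = m, seed = s)
      if (is.null(best) || fit$objective < best$objective) best <- fit
    }
    min_centroid_distance(best$centroids)
  }, numeric(1))
  if (length(cs) == 1) {
    return(list(c_opt = cs, dmin_curve = data.frame(c = cs, dmin = dmin),
                low_confidence = TRUE))
  }
  ratio <- dmin[-length(dmin)] / dmin[-1]
  ## once dmin has collapsed to a sliver of its starting scale, further
  ## drop ratios are numerical noise (two centroids nearly coincide);
  ## only elbows on the meaningful part of the curve are candidates
  eligible <- dmin[-length(dmin)] >= 0.05 * max(dmin)
  c_opt <- if (any(eligible)) {
    cs[-length(cs)][eligible][which.max(ratio[eligible])]
  } else cs[which.max(ratio)]
  ## degenerate (structureless) data collapses all centroids onto the
  ## grand mean; a dmin that is negligible against the data scale means
  ## the drop ratios are numerical noise
  collapsed <- dmin[match(c_opt, cs)] < 1e-3 * stats::sd(as.numeric(x))
  list(c_opt = c_opt, dmin_curve = data.frame(c = cs, dmin = dmin),
       low_confidence = collapsed || max(ratio) < min_ratio)
}

#' Tissue specificity of clusters
#'
#' For each non-empty cluster, the share of members originating from the
#' modal tissue; a cluster is tissue-specific when that share is at least
#' `th$tissue_specific_frac` (inclusive).
#'
#' @param clustering `fuzzy_clustering`.
#' @param keys data.frame (feature_id, tissue) aligned with the clustered
#'   rows.
#' @param th [nc_thresholds()].
#' @return data.frame (cluster, n, dominant_tissue, fraction, is_specific).
#' @export
tissue_specificity <- function(clustering, keys, th = nc_thresholds()) {
  lab <- clustering$hard_labels
  out <- lapply(sort(unique(lab)), function(cl) {
    tis <- keys$tissue[lab == cl]
    tab <- sort(table(tis), decreasing = TRUE)
    frac <- as.numeric(tab[1]) / length(tis)
    data.frame(cluster = cl, n = length(tis),
               dominant_tissue = names(tab)[1], fraction = frac,
               is_specific = frac >= th$tissue_specific_frac,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Cross-tissue co-clustering rate
#'
#' For each listed feature, the fraction of its per-tissue trajectories
#' assigned to that feature's modal cluster; averaged over features. A
#' rate near 1 means a feature's trajectories from different organs land
#' in one common cluster.
#'
#' @param clustering `fuzzy_clustering`.
#' @param keys key data.frame aligned with the clustered rows.
#' @param features features to evaluate.
#' @return mean co-clustering rate in \[0, 1\].
#' @export
cross_tissue_coclustering <- function(clustering, keys, features) {
  lab <- clustering$hard_labels
  rates <- vapply(features, function(f) {
    l <- lab[keys$feature_id == f]
    if (!length(l)) return(NA_real_)
    max(table(l)) / length(l)
  }, numeric(1))
  mean(rates, na.rm = TRUE)
}
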