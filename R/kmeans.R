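#' K-means clustering by Lloyd's algorithm with k-means++ seeding
#'
#' Fits `k` clusters to per-pixel feature values: k-means++ initialization,
#' Lloyd iterations until the centroid shift falls below `tol` (or the
#' assignment stops changing), the best of `n_init` restarts by
#' within-cluster sum of squares (inertia). A cluster that empties is
#' re-seeded at the point farthest from its assigned centroid. Deterministic
#' given `seed`. If the data hold fewer distinct values than `k`, `k` is
#' reduced with a warning.
#'
#' @param x Numeric vector (scalar features) or matrix (rows = points).
#' @param k Number of clusters (the study protocol used K = 10).
#' @param seed RNG seed.
#' @param n_init Number of restarts.
#' @param max_iter Maximum Lloyd iterations per restart.
#' @param tol Convergence tolerance on the summed squared centroid shift.
#' @return An object of class `cluster_model`: `k`, `centroids` (k x p),
#'   `labels` (per-point cluster id, 1-based), `inertia`, `n_iter`,
#'   `inertia_trace` (per-iteration inertia of the winning restart), `seed`.
#' @export
kmeans_lloyd <- function(x, k = 10, seed = 1L, n_init = 10, max_iter = 300,
                         tol = 1e-6) {
  X <- if (is.matrix(x)) x else matrix(as.numeric(x), ncol = 1)
  if (nrow(X) == 0 || !all(is.finite(X))) {
    stop("features must be non-empty and finite", call. = FALSE)
  }
  stopifnot(k >= 1, n_init >= 1, max_iter >= 1)
  n_distinct <- nrow(unique(X))
  if (n_distinct < k) {
    warning(sprintf("only %d distinct values; reducing k from %d", n_distinct, k))
    k <- n_distinct
  }

  best <- NULL
  withr::with_seed(seed, {
    for (init in seq_len(n_init)) {
      fit <- lloyd_once(X, k, max_iter, tol)
      if (is.null(best) || fit$inertia < best$inertia) best <- fit
    }
  })
  structure(list(k = k, centroids = best$centroids, labels = best$labels,
                 inertia = best$inertia, n_iter = best$n_iter,
                 inertia_trace = best$trace, seed = seed),
            class = "cluster_model")
}

sq_dist_to_centers <- function(X, C) {
  # n x k squared Euclidean distances
  d2 <- outer(rowSums(X^2), rep(1, nrow(C))) - 2 * X %*% t(C) +
    outer(rep(1, nrow(X)), rowSums(C^2))
  pmax(d2, 0)
}

kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  centers[1, ] <- X[sample.int(n, 1), ]
  if (k > 1) {
    d2 <- sq_dist_to_centers(X, centers[1, , drop = FALSE])[, 1]
    for (j in 2:k) {
      p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      centers[j, ] <- X[sample.int(n, 1, prob = p), ]
      d2 <- pmin(d2, sq_dist_to_centers(X, centers[j, , drop = FALSE])[, 1])
    }
  }
  centers
}

lloyd_once <- function(X, k, max_iter, tol) {
  C <- kmeanspp_init(X, k)
  labels <- rep(0L, nrow(X))
  trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    d2 <- sq_dist_to_centers(X, C)
    new_labels <- max.col(-d2, ties.method = "first")
    point_d2 <- d2[cbind(seq_len(nrow(X)), new_labels)]
    # re-seed empty clusters at the farthest point
    for (j in which(tabulate(new_labels, k) == 0)) {
      far <- which.max(point_d2)
      C[j, ] <- X[far, ]
      new_labels[far] <- j
      point_d2[far] <- 0
    }
    trace <- c(trace, sum(point_d2))
    shift <- 0
    for (j in seq_len(k)) {
      nj <- sum(new_labels == j)
      cj <- colSums(X[new_labels == j, , drop = FALSE]) / nj
      shift <- shift + sum((cj - C[j, ])^2)
      C[j, ] <- cj
    }
    converged <- identical(new_labels, labels) || shift < tol
    labels <- new_labels
    if (converged) break
  }
  d2 <- sq_dist_to_centers(X, C)
  labels <- max.col(-d2, ties.method = "first")
  inertia <- sum(d2[cbind(seq_len(nrow(X)), labels)])
  list(centroids = C, labels = labels, inertia = inertia,
       n_iter = length(trace), trace = c(trace, inertia))
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> k = %d, n = %d points, inertia = %.6g (%d iter)\n",
              x$k, length(x$labels), x$inertia, x$n_iter))
  invisible(x)
}

#' @method tidy cluster_model
#' @export
tidy.cluster_model <- function(x, ...) {
  cent <- x$centroids
  colnames(cent) <- paste0("centroid_", seq_len(ncol(cent)))
  dplyr::bind_cols(tibble::tibble(cluster = seq_len(x$k),
                                  size = tabulate(x$labels, x$k)),
                   tibble::as_tibble(cent))
}

#' @method glance cluster_model
#' @export
glance.cluster_model <- function(x, ...) {
  tibble::tibble(k = x$k, inertia = x$inertia, n_iter = x$n_iter,
                 n = length(x$labels))
}

#' Label vein and artery clusters in a filtered band image
#'
#' Scores every cluster of a fitted [kmeans_lloyd()] model by pixel
#' fraction, mean image intensity, and elongation — the major/minor axis
#' ratio from the second-moment eigenvalues of the cluster's pixel cloud
#' (a tubular cluster scores high even when pixel noise fragments it into
#' many small connected pieces; a full-field background cluster scores
#' near 1). Clusters whose fraction lies in `[min_frac, max_frac]` and
#' whose elongation is at least `min_elongation` are vessel candidates; the
#' candidate with the lowest mean intensity is labelled the vein
#' (deoxygenated blood absorbs most in the red band), the next-lowest the
#' artery. Because K usually exceeds the number of distinct tissue levels,
#' one vessel's pixel noise is often split across near-identical clusters;
#' candidates whose means lie within `merge_tol` of a group's level (as a
#' fraction of the image's value range) are merged into that vessel's mask.
#' With a single candidate group the artery mask is empty, with a warning.
#'
#' @param model A [kmeans_lloyd()] fit on the image's pixels (in column-major
#'   order).
#' @param img The filtered [band_image()] the model was fitted on.
#' @param min_frac,max_frac Admissible cluster pixel-fraction range.
#' @param min_elongation Minimum major/minor axis ratio of the cluster's
#'   pixel cloud.
#' @param merge_tol Candidates within this fraction of the image value
#'   range of a vessel group's lowest mean are merged into that group.
#' @return An object of class `vessel_masks`: logical `vein_mask` /
#'   `artery_mask`, the chosen `vein_cluster_id` / `artery_cluster_id`, and
#'   a `diagnostics` tibble (per cluster: mean intensity, pixel fraction,
#'   elongation, candidate flag).
#' @export
label_vessels <- function(model, img, min_frac = 0.002, max_frac = 0.2,
                          min_elongation = 2.0, merge_tol = 0.05) {
  stopifnot(inherits(model, "cluster_model"), inherits(img, "band_image"))
  d <- dim(img$values)
  if (length(model$labels) != prod(d)) {
    stop("model was not fitted on this image grid", call. = FALSE)
  }
  lab_img <- matrix(model$labels, d[1], d[2])
  n <- prod(d)
  diagnostics <- purrr::map_dfr(seq_len(model$k), function(j) {
    m <- lab_img == j
    tibble::tibble(cluster = j,
                   mean_intensity = mean(img$values[m]),
                   pixel_fraction = sum(m) / n,
                   elongation = cluster_elongation(m))
  })
  diagnostics$candidate <- diagnostics$pixel_fraction >= min_frac &
    diagnostics$pixel_fraction <= max_frac &
    diagnostics$elongation >= min_elongation

  cand <- diagnostics[diagnostics$candidate, ]
  if (nrow(cand) == 0) {
    stop(paste0("no cluster passes the vessel shape test; diagnostics:\n",
                paste(utils::capture.output(print(as.data.frame(diagnostics))),
                      collapse = "\n")), call. = FALSE)
  }
  cand <- cand[order(cand$mean_intensity), ]
  rng <- diff(range(valid_values(img)))
  tol <- merge_tol * if (rng > 0) rng else 1
  vein_sel <- cand$mean_intensity <= cand$mean_intensity[1] + tol
  vein_ids <- cand$cluster[vein_sel]
  rest <- cand[!vein_sel, , drop = FALSE]
  artery_ids <- if (nrow(rest) >= 1) {
    rest$cluster[rest$mean_intensity <= rest$mean_intensity[1] + tol]
  } else integer(0)
  if (length(artery_ids) == 0) {
    warning("only one vessel candidate group; artery mask left empty")
  }
  structure(list(
    vein_mask = matrix(model$labels %in% vein_ids, d[1], d[2]),
    artery_mask = matrix(model$labels %in% artery_ids, d[1], d[2]),
    vein_cluster_id = vein_ids[1],
    artery_cluster_id = if (length(artery_ids)) artery_ids[1] else NA_integer_,
    vein_cluster_ids = vein_ids,
    artery_cluster_ids = artery_ids,
    diagnostics = diagnostics
  ), class = "vessel_masks")
}

cluster_elongation <- function(mask) {
  if (sum(mask) == 0) return(0)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < 3) return(1)
  ev <- eigen(stats::cov(idx), symmetric = TRUE, only.values = TRUE)$values
  if (ev[2] <= .Machine$double.eps) return(Inf)
  sqrt(ev[1] / ev[2])
}

#' Dice overlap between two masks
#'
#' `2|A intersect B| / (|A| + |B|)`; 1 for identical non-empty masks, and
#' defined as 1 when both masks are empty.
#'
#' @param a,b Logical matrices of equal size.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Alpha-blend a mask over a 3-channel composite
#'
#' @param composite `rows x cols x 3` array in \[0, 1\].
#' @param mask Logical matrix of matching size.
#' @param color Length-3 RGB vector in \[0, 1\].
#' @param alpha Blend weight in \[0, 1\]; 0 leaves the composite unchanged,
#'   1 paints masked pixels the pure color.
#' @return The blended `rows x cols x 3` array.
#' @export
overlay_mask <- function(composite, mask, color = c(1, 0, 0), alpha = 0.5) {
  stopifnot(length(dim(composite)) == 3, dim(composite)[3] == 3,
            all(dim(mask) == dim(composite)[1:2]),
            length(color) == 3, alpha >= 0, alpha <= 1)
  out <- composite
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[mask] <- (1 - alpha) * plane[mask] + alpha * color[ch]
    out[, , ch] <- plane
  }
  out
}
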