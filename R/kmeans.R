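# Trajectory k-means on probe methylation across time points. Lloyd
# iterations from k-means++ starts, best of n_restarts by within-cluster
# sum of squares, deterministic under the seed. Empty clusters are
# re-seeded from the point farthest from its current centroid. Clusters
# are reported in descending size order.

kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  idx <- sample.int(n, 1)
  centers[1, ] <- X[idx, ]
  d2 <- rowSums((X - matrix(centers[1, ], n, ncol(X), byrow = TRUE))^2)
  for (j in seq_len(k)[-1]) {
    if (all(d2 == 0)) idx <- sample.int(n, 1)
    else idx <- sample.int(n, 1, prob = d2)
    centers[j, ] <- X[idx, ]
    d2 <- pmin(d2, rowSums((X - matrix(centers[j, ], n, ncol(X),
                                       byrow = TRUE))^2))
  }
  centers
}

dist2_to_centers <- function(X, centers) {
  # n x k matrix of squared Euclidean distances
  xx <- rowSums(X^2)
  cc <- rowSums(centers^2)
  outer(xx, cc, "+") - 2 * X %*% t(centers)
}

lloyd_kmeans <- function(X, centers, max_iter = 100) {
  k <- nrow(centers)
  assign_old <- rep(0L, nrow(X))
  for (iter in seq_len(max_iter)) {
    D <- dist2_to_centers(X, centers)
    assign <- max.col(-D, ties.method = "first")
    # re-seed empty clusters from the point farthest from its centroid
    empty <- setdiff(seq_len(k), unique(assign))
    for (j in empty) {
      cur <- D[cbind(seq_len(nrow(X)), assign)]
      far <- which.max(cur)
      assign[far] <- j
      centers[j, ] <- X[far, ]
    }
    for (j in seq_len(k)) {
      sel <- assign == j
      if (any(sel)) centers[j, ] <- colMeans(X[sel, , drop = FALSE])
    }
    if (identical(assign, assign_old)) break
    assign_old <- assign
  }
  D <- dist2_to_centers(X, centers)
  wcss <- sum(D[cbind(seq_len(nrow(X)), assign)])
  list(assign = assign, centers = centers, wcss = wcss, iter = iter)
}

#' k-means clustering of methylation trajectories
#'
#' Clusters probes by their methylation trajectory across time points
#' (samples). Values stay on the fraction scale, unstandardised. Probes
#' with a missing value at any time point are excluded.
#'
#' @param mm long methylation matrix from [quantify_probes()]
#' @param k number of clusters (default 7)
#' @param seed RNG seed; results are deterministic given the seed
#' @param n_restarts k-means++ restarts; the restart with the lowest
#'   within-cluster sum of squares wins (default 25)
#' @param samples optional character vector fixing the time-point order;
#'   defaults to order of appearance in `mm`
#' @return object of class `germ_trajclust` with assignments, centroids,
#'   per-cluster sizes and WCSS
#' @export
kmeans_trajectories <- function(mm, k = 7, seed = 1, n_restarts = 25,
                                samples = NULL) {
  samples <- samples %||% unique(mm$sample)
  wide <- mm %>%
    filter(sample %in% samples) %>%
    meth_matrix_wide() %>%
    select(probe_id, all_of(samples))
  keep <- complete.cases(wide)
  wide <- wide[keep, ]
  X <- as.matrix(wide[, samples])
  if (nrow(X) < k) {
    abort(paste0("fewer probes (", nrow(X), ") than clusters (", k, ")"))
  }
  best <- NULL
  with_seed(as.integer(seed), {
    for (r in seq_len(n_restarts)) {
      fit <- lloyd_kmeans(X, kmeanspp_init(X, k))
      if (is.null(best) || fit$wcss < best$wcss) best <- fit
    }
  })
  # relabel clusters in descending size order (ties: first occurrence)
  sizes <- tabulate(best$assign, nbins = k)
  ord <- order(-sizes, seq_len(k))
  relabel <- match(seq_len(k), ord)
  assign <- relabel[best$assign]
  centers <- best$centers[ord, , drop = FALSE]
  colnames(centers) <- samples
  D <- dist2_to_centers(X, centers)
  withinss <- vapply(seq_len(k), function(j) {
    sum(D[cbind(which(assign == j), rep(j, sum(assign == j)))])
  }, numeric(1))
  structure(
    list(
      assignments = tibble(probe_id = wide$probe_id, cluster = assign),
      centroids = as_tibble(centers) %>%
        mutate(cluster = seq_len(k), .before = 1) %>%
        pivot_longer(-cluster, names_to = "timepoint", values_to = "value") %>%
        mutate(timepoint = factor(timepoint, levels = samples)),
      sizes = tabulate(assign, nbins = k),
      withinss = withinss,
      tot_withinss = best$wcss,
      k = k, seed = seed, n_restarts = n_restarts, samples = samples,
      iter = best$iter
    ),
    class = "germ_trajclust"
  )
}

#' @export
print.germ_trajclust <- function(x, ...) {
  cat("Methylation trajectory k-means:", x$k, "clusters over",
      length(x$samples), "time points\n")
  cat("  sizes:", paste(x$sizes, collapse = ", "), "\n")
  cat("  total WCSS:", format(x$tot_withinss, digits = 6), "\n")
  invisible(x)
}

#' @export
tidy.germ_trajclust <- function(x, ...) {
  x$centroids %>%
    pivot_wider(names_from = timepoint, values_from = value) %>%
    mutate(size = x$sizes, withinss = x$withinss) %>%
    relocate(cluster, size, withinss)
}

#' @export
glance.germ_trajclust <- function(x, ...) {
  tibble(k = x$k, n = nrow(x$assignments), tot_withinss = x$tot_withinss,
         n_restarts = x$n_restarts, iter = x$iter)
}

#' @export
augment.germ_trajclust <- function(x, data = NULL, ...) {
  out <- x$assignments
  if (!is.null(data)) out <- left_join(out, data, by = "probe_id")
  out
}

#' Plot cluster centroid trajectories
#' @param object a `germ_trajclust` object
#' @param ... ignored
#' @return a ggplot object
#' @export
autoplot.germ_trajclust <- function(object, ...) {
  ggplot(object$centroids,
         aes(x = timepoint, y = value, group = cluster,
             colour = factor(cluster))) +
    geom_line() + geom_point() +
    ylim(0, 1) +
    labs(x = NULL, y = "weighted methylation", colour = "cluster") +
    theme_minimal()
}
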