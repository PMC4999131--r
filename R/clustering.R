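#' Extract the multivariate daily series bundle of a cropping event
#'
#' @param event a [attach_weather_window()] `cropping_event`.
#' @param variables climatic series to carry (default the five raw ones).
#' @return object of class `event_series_bundle`: list with `event_id`,
#'   `series` (days x variables matrix), `yield`, `cultivar`.
#' @export
event_series_bundle <- function(event,
                                variables = c("TX", "TM", "P", "RH", "SR")) {
  stopifnot(inherits(event, "cropping_event"))
  m <- as.matrix(event$window[variables])
  structure(list(event_id = event$event_id, series = m,
                 yield = event$yield, cultivar = event$cultivar),
            class = "event_series_bundle")
}

#' Pooled z-scoring of event series bundles
#'
#' Standardizes each climatic variable using the pooled mean and standard
#' deviation over all days of all events, making the variables commensurate
#' before they are combined in a multivariate DTW distance.  A variable
#' that is constant over the whole pool is dropped with a warning.
#' Idempotent up to floating point.
#'
#' @param bundles list of [event_series_bundle()] objects (>= 2).
#' @return list of standardized bundles; attributes `"centers"`,
#'   `"scales"`, `"dropped"`.
#' @export
standardize_event_series <- function(bundles) {
  if (length(bundles) < 2)
    stopf("at least two events are required for standardization")
  vars <- colnames(bundles[[1]]$series)
  for (b in bundles)
    if (!identical(colnames(b$series), vars))
      stopf("bundles carry different variable sets")
  pooled <- do.call(rbind, lapply(bundles, function(b) b$series))
  mu <- colMeans(pooled)
  sg <- apply(pooled, 2, sd)
  dropped <- vars[sg == 0]
  if (length(dropped)) {
    warnf("dropping constant variable(s): %s", paste(dropped, collapse = ", "))
    keep <- sg > 0
  } else keep <- rep(TRUE, length(vars))
  out <- lapply(bundles, function(b) {
    s <- sweep(sweep(b$series[, keep, drop = FALSE], 2, mu[keep]),
               2, sg[keep], "/")
    b$series <- s
    b
  })
  attr(out, "centers") <- mu[keep]
  attr(out, "scales") <- sg[keep]
  attr(out, "dropped") <- dropped
  out
}

#' Dynamic time warping distance between two series
#'
#' Classic DTW with absolute-difference local cost, the symmetric
#' match/insert/delete step pattern, boundary anchoring and no window
#' constraint; returns the optimal cumulative warping-path cost.  Series
#' may differ in length.
#'
#' @param a,b numeric vectors (non-empty, finite).
#' @return non-negative distance (0 for identical series).
#' @export
dtw_distance <- function(a, b) {
  if (!length(a) || !length(b)) stopf("series must be non-empty")
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stopf("series must be finite")
  .dtw_cpp(as.numeric(a), as.numeric(b))
}

#' Multivariate event distance
#'
#' Sum over the climatic variables of the univariate DTW distances between
#' the corresponding (standardized) daily series of two events, with equal
#' weights by default ("independent" multivariate DTW).
#'
#' @param a,b [event_series_bundle()] objects with the same variable set.
#' @param weights optional named or positional weights per variable.
#' @return non-negative distance.
#' @export
event_distance <- function(a, b, weights = NULL) {
  va <- colnames(a$series); vb <- colnames(b$series)
  if (!identical(va, vb)) stopf("events carry different variable sets")
  w <- weights %||% rep(1, length(va))
  sum(vapply(seq_along(va), function(j)
    w[j] * dtw_distance(a$series[, j], b$series[, j]), 0.0))
}

#' Pairwise DTW distance matrix over events
#'
#' @param bundles list of (standardized) [event_series_bundle()] objects.
#' @param weights per-variable weights (equal by default).
#' @return symmetric matrix with zero diagonal, dimnames = event ids.
#' @export
pairwise_distance_matrix <- function(bundles, weights = NULL) {
  if (length(bundles) < 2) stopf("at least two events are required")
  vars <- colnames(bundles[[1]]$series)
  w <- weights %||% rep(1, length(vars))
  mats <- lapply(bundles, function(b) {
    if (!identical(colnames(b$series), vars))
      stopf("bundles carry different variable sets")
    if (any(!is.finite(b$series))) stopf("non-finite values in series")
    b$series
  })
  d <- .dtw_pairwise_cpp(mats, as.numeric(w))
  ids <- vapply(bundles, function(b) b$event_id, "")
  dimnames(d) <- list(ids, ids)
  d
}

#' Agglomerative hierarchical clustering via Lance-Williams updates
#'
#' Ward-style clustering on squared distances (so that merge heights track
#' within-cluster inertia), with average and complete linkage selectable.
#' Returns a standard `hclust` object (merge matrix, heights, order,
#' labels) so that [stats::cutree()] and plotting work unchanged.
#'
#' @param dmat symmetric distance matrix (e.g. from
#'   [pairwise_distance_matrix()]).
#' @param linkage `"ward"` (default), `"average"` or `"complete"`.
#' @return an object of class `hclust`.
#' @export
hierarchical_cluster <- function(dmat, linkage = c("ward", "average",
                                                   "complete")) {
  linkage <- match.arg(linkage)
  dmat <- as.matrix(dmat)
  n <- nrow(dmat)
  if (n < 2) stopf("need at least two observations")
  if (any(is.na(dmat)) || any(!is.finite(dmat)))
    stopf("distance matrix contains NA or non-finite values")
  if (max(abs(dmat - t(dmat))) > 1e-8) stopf("distance matrix not symmetric")
  D <- if (linkage == "ward") dmat^2 else dmat
  size <- rep(1L, n)
  active <- rep(TRUE, n)
  id <- -seq_len(n)            # hclust convention: negatives are singletons
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  diag(D) <- Inf
  for (m in seq_len(n - 1)) {
    idx <- which(active)
    sub <- D[idx, idx, drop = FALSE]
    k <- arrayInd(which.min(sub), dim(sub))
    i <- idx[min(k[1], k[2])]; j <- idx[max(k[1], k[2])]
    height[m] <- D[i, j]
    ## hclust row convention: singletons first (by observation index),
    ## then earlier merges
    pair <- c(id[i], id[j])
    merge[m, ] <- if (all(pair < 0)) rev(sort(pair))
                  else if (any(pair < 0)) c(pair[pair < 0], pair[pair > 0])
                  else sort(pair)
    ## Lance-Williams update into slot i
    for (l in idx) {
      if (l == i || l == j) next
      D[i, l] <- D[l, i] <- switch(linkage,
        ward = ((size[i] + size[l]) * D[i, l] +
                  (size[j] + size[l]) * D[j, l] -
                  size[l] * D[i, j]) / (size[i] + size[j] + size[l]),
        average = (size[i] * D[i, l] + size[j] * D[j, l]) /
          (size[i] + size[j]),
        complete = max(D[i, l], D[j, l]))
    }
    size[i] <- size[i] + size[j]
    active[j] <- FALSE
    id[i] <- m
  }
  structure(list(merge = merge, height = height,
                 order = dendrogram_order(merge),
                 labels = rownames(dmat) %||% as.character(seq_len(n)),
                 method = linkage,
                 call = match.call(), dist.method = "dtw"),
            class = "hclust")
}

## leaf ordering by recursive traversal of the merge matrix
dendrogram_order <- function(merge) {
  rec <- function(node) {
    if (node < 0) return(-node)
    c(rec(merge[node, 1]), rec(merge[node, 2]))
  }
  rec(nrow(merge))
}

#' Choose the number of clusters from the inertia gain
#'
#' The inertia gain of k clusters is the dendrogram height of the merge
#' that collapses k clusters into k - 1, i.e. the within-cluster inertia
#' recovered by allowing a k-th cluster.  The chosen k maximizes the
#' relative inertia gain gain(k) / W(k), where W(k) -- the within-cluster
#' inertia of the k-cluster partition -- is the sum of the merge heights
#' below the cut: the elbow is the k whose added cluster recovers the
#' largest fraction of the inertia still unexplained.  Normalizing by the
#' remaining inertia rather than by the next single gain keeps the
#' criterion stable deep in the tree, where individual merge heights are
#' tiny and their pairwise ratios are dominated by noise; the criterion is
#' invariant to uniform scaling of all distances.  Ties resolve to the
#' smallest k.  A degenerate flat dendrogram returns `k_min` with a
#' warning.
#'
#' @param hc an `hclust` object (heights on the inertia scale, as produced
#'   by [hierarchical_cluster()] with Ward linkage).
#' @param k_min,k_max search range (k_max is capped at n - 1).
#' @return the selected k (integer).
#' @export
select_k_inertia_gain <- function(hc, k_min = 2, k_max = 20) {
  n <- length(hc$height) + 1
  k_max <- min(k_max, n - 2)
  if (k_max < k_min) k_max <- k_min
  if (max(hc$height) - min(hc$height) < 1e-12 || max(hc$height) <= 0) {
    warnf("flat dendrogram: all merge heights equal; returning k_min")
    return(as.integer(k_min))
  }
  gain <- function(k) hc$height[n - k + 1]
  within <- function(k) sum(hc$height[seq_len(n - k)])
  ks <- k_min:k_max
  ratio <- vapply(ks, function(k) {
    w <- within(k)
    if (w <= 0) return(0)
    gain(k) / w
  }, 0.0)
  as.integer(ks[which.max(ratio)])
}

#' Cluster cropping events by their daily weather patterns
#'
#' Full pattern-clustering chain: pooled z-scoring of the event series,
#' pairwise multivariate DTW distances, Ward hierarchical clustering, and
#' inertia-gain selection of the number of clusters.
#'
#' @param bundles list of [event_series_bundle()] objects.
#' @param weights per-variable DTW weights.
#' @param linkage linkage method, see [hierarchical_cluster()].
#' @param k number of clusters, or `NULL` to select by inertia gain.
#' @param k_min,k_max selection range.
#' @param standardize z-score the series first (recommended).
#' @return object of class `pattern_clustering`: `labels` (named integer),
#'   `k`, `hclust`, `distance` matrix, `yields`, `cultivars`.
#' @export
weather_pattern_clusters <- function(bundles, weights = NULL,
                                     linkage = "ward", k = NULL,
                                     k_min = 2, k_max = 20,
                                     standardize = TRUE) {
  if (standardize) bundles <- standardize_event_series(bundles)
  d <- pairwise_distance_matrix(bundles, weights)
  hc <- hierarchical_cluster(d, linkage)
  if (is.null(k)) k <- select_k_inertia_gain(hc, k_min, k_max)
  labels <- cutree(hc, k = k)
  structure(list(labels = labels, k = as.integer(k), hclust = hc,
                 distance = d,
                 yields = vapply(bundles, function(b)
                   b$yield %||% NA_real_, 0.0),
                 cultivars = vapply(bundles, function(b)
                   b$cultivar %||% NA_character_, "")),
            class = "pattern_clustering")
}

#' @export
print.pattern_clustering <- function(x, ...) {
  cat(sprintf("Weather-pattern clustering: %d events in %d clusters\n",
              length(x$labels), x$k))
  print(table(cluster = x$labels))
  invisible(x)
}

#' @export
plot.pattern_clustering <- function(x, ...) {
  plot(x$hclust, labels = FALSE, main = "DTW weather-pattern dendrogram",
       xlab = "", sub = "", ...)
  invisible(x)
}

#' Per-cluster yield statistics with letter grouping
#'
#' Summarizes the yields achieved under each weather pattern and groups
#' clusters whose yield distributions do not differ significantly
#' (Kruskal-Wallis letter display).  Clusters of size one are included in
#' the summary but excluded from the letter test.
#'
#' @param labels integer cluster labels.
#' @param yields numeric yields aligned with `labels`.
#' @param alpha significance level.
#' @return object of class `cluster_yield_summary`: `summary` (per-cluster
#'   n/mean/median/sd, ordered by decreasing median), `letters`
#'   ([kw_letter_groups()] result over the testable clusters), `excluded`
#'   (singleton clusters).
#' @export
cluster_yield_analysis <- function(labels, yields, alpha = 0.05) {
  stopifnot(length(labels) == length(yields))
  sp <- split(yields, labels)
  summ <- data.frame(cluster = names(sp),
                     n = vapply(sp, length, 0L),
                     mean = vapply(sp, mean, 0.0),
                     median = vapply(sp, median, 0.0),
                     sd = vapply(sp, function(v)
                       if (length(v) > 1) sd(v) else NA_real_, 0.0),
                     row.names = NULL)
  summ <- summ[order(-summ$median), ]
  testable <- sp[vapply(sp, length, 0L) >= 2]
  letters <- if (length(testable) >= 2)
    kw_letter_groups(testable, alpha = alpha) else NULL
  structure(list(summary = summ, letters = letters,
                 excluded = setdiff(names(sp), names(testable))),
            class = "cluster_yield_summary")
}

#' @export
print.cluster_yield_summary <- function(x, ...) {
  df <- x$summary
  if (!is.null(x$letters))
    df$letters <- x$letters$letters[as.character(df$cluster)]
  print(df, row.names = FALSE)
  if (length(x$excluded))
    cat("singleton clusters excluded from the letter test:",
        paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' Cultivar comparison within each weather-pattern cluster
#'
#' Within every cluster of at least `min_cluster_n` events, compares the
#' yield distributions of the cultivars having at least `min_cultivar_n`
#' observations (smaller cultivars are pooled out of the test).  Clusters
#' below the size threshold are skipped, as are clusters with fewer than
#' two eligible cultivars.
#'
#' @param labels,yields,cultivars aligned vectors.
#' @param min_cluster_n minimum cluster size analyzed (clusters with fewer
#'   data points are not considered).
#' @param min_cultivar_n minimum per-cultivar observations inside a
#'   cluster.
#' @param alpha significance level.
#' @return named list per analyzed cluster: either a
#'   [kw_letter_groups()] result or the string `"no comparison possible"`;
#'   skipped clusters are reported in attribute `"skipped"`.
#' @export
cultivar_within_cluster <- function(labels, yields, cultivars,
                                    min_cluster_n = 10, min_cultivar_n = 5,
                                    alpha = 0.05) {
  stopifnot(length(labels) == length(yields),
            length(labels) == length(cultivars))
  out <- list()
  skipped <- character()
  for (cl in sort(unique(labels))) {
    sel <- labels == cl
    if (sum(sel) < min_cluster_n) {
      skipped <- c(skipped, as.character(cl))
      next
    }
    sp <- split(yields[sel], as.character(cultivars[sel]))
    sp <- sp[vapply(sp, length, 0L) >= min_cultivar_n]
    out[[as.character(cl)]] <- if (length(sp) >= 2)
      kw_letter_groups(sp, alpha = alpha) else "no comparison possible"
  }
  attr(out, "skipped") <- skipped
  out
}
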