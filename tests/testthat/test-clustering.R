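random_bundle <- function(id, n_days, seed, yield = NA_real_,
                          cultivar = "F733") {
  set.seed(seed)
  m <- matrix(rnorm(n_days * 5), n_days, 5,
              dimnames = list(NULL, c("TX", "TM", "P", "RH", "SR")))
  structure(list(event_id = id, series = m, yield = yield,
                 cultivar = cultivar), class = "event_series_bundle")
}

test_that("pooled standardization is idempotent and drops constants", {
  b <- lapply(1:4, function(i) random_bundle(paste0("e", i), 100, i))
  s1 <- standardize_event_series(b)
  pooled <- do.call(rbind, lapply(s1, function(x) x$series))
  expect_equal(unname(colMeans(pooled)), rep(0, 5), tolerance = 1e-12)
  expect_equal(unname(apply(pooled, 2, sd)), rep(1, 5), tolerance = 1e-12)
  s2 <- standardize_event_series(s1)
  for (i in seq_along(b))
    expect_equal(s2[[i]]$series, s1[[i]]$series, tolerance = 1e-12)
  bc <- b
  for (i in seq_along(bc)) bc[[i]]$series[, "P"] <- 3
  expect_warning(sc <- standardize_event_series(bc), "constant")
  expect_false("P" %in% colnames(sc[[1]]$series))
  expect_error(standardize_event_series(b[1]), "at least two")
})

test_that("dtw distance matches exhaustive path enumeration on short series", {
  expect_equal(dtw_distance(c(0, 1, 2), c(0, 2)), 1)
  expect_equal(dtw_distance(1:5, 1:5), 0)
  set.seed(81)
  for (i in 1:200) {
    a <- round(rnorm(sample(2:6, 1)), 2)
    b <- round(rnorm(sample(2:6, 1)), 2)
    expect_equal(dtw_distance(a, b), dtw_enumerate(a, b), tolerance = 1e-12)
  }
})

test_that("dtw identity and symmetry hold on random pairs", {
  set.seed(82)
  for (i in 1:200) {
    a <- rnorm(sample(5:40, 1))
    b <- rnorm(sample(5:40, 1))
    expect_equal(dtw_distance(a, a), 0)
    expect_equal(dtw_distance(a, b), dtw_distance(b, a))
    expect_gte(dtw_distance(a, b), 0)
  }
  expect_error(dtw_distance(c(1, NA), 1:3), "finite")
  expect_error(dtw_distance(numeric(), 1:3), "non-empty")
})

test_that("event distance is the per-variable DTW sum", {
  a <- random_bundle("a", 20, 1)
  b <- random_bundle("b", 25, 2)
  d <- event_distance(a, b)
  by_var <- sum(vapply(colnames(a$series), function(v)
    dtw_distance(a$series[, v], b$series[, v]), 0.0))
  expect_equal(d, by_var, tolerance = 1e-12)
  expect_equal(event_distance(a, a), 0)
  ## differing in exactly one variable -> that variable's DTW
  b2 <- a
  b2$series[, "SR"] <- a$series[, "SR"] + rnorm(20)
  expect_equal(event_distance(a, b2),
               dtw_distance(a$series[, "SR"], b2$series[, "SR"]),
               tolerance = 1e-12)
  ## short-fixture oracle equivalence via exhaustive enumeration
  s <- random_bundle("s", 5, 3); t <- random_bundle("t", 6, 4)
  expect_equal(event_distance(s, t),
               sum(vapply(1:5, function(j)
                 dtw_enumerate(s$series[, j], t$series[, j]), 0.0)),
               tolerance = 1e-12)
  mism <- a
  colnames(mism$series)[1] <- "XX"
  expect_error(event_distance(a, mism), "different variable sets")
})

test_that("the pairwise matrix is symmetric, zero-diagonal and consistent", {
  b <- lapply(1:6, function(i) random_bundle(paste0("e", i), 30 + i, i))
  d <- pairwise_distance_matrix(b)
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 6))
  expect_equal(length(unique(d[upper.tri(d)])), 15)
  set.seed(83)
  for (k in 1:5) {
    ij <- sample(6, 2)
    expect_equal(d[ij[1], ij[2]], event_distance(b[[ij[1]]], b[[ij[2]]]),
                 tolerance = 1e-12)
  }
})

test_that("Lance-Williams clustering reproduces the reference implementation", {
  set.seed(84)
  for (i in 1:5) {
    d <- as.matrix(dist(matrix(runif(10 * 4), 10, 4)))
    ward <- hierarchical_cluster(d, "ward")
    ref <- stats::hclust(stats::as.dist(d^2), method = "ward.D")
    expect_identical(ward$merge, ref$merge)
    expect_equal(ward$height, ref$height, tolerance = 1e-10)
    for (lk in c("average", "complete")) {
      mine <- hierarchical_cluster(d, lk)
      ref2 <- stats::hclust(stats::as.dist(d), method = lk)
      expect_identical(mine$merge, ref2$merge)
      expect_equal(mine$height, ref2$height, tolerance = 1e-10)
    }
  }
  ## two tight groups far apart: final merge towers over the rest
  pts <- c(rnorm(5, 0, 0.1), rnorm(5, 100, 0.1))
  d2 <- as.matrix(dist(pts))
  hc <- hierarchical_cluster(d2)
  expect_gt(hc$height[9], 100 * max(hc$height[1:8]))
  ## smallest pair merges first
  d3 <- as.matrix(dist(c(0, 0.1, 5)))
  expect_equal(hierarchical_cluster(d3)$merge[1, ], c(-1, -2))
  d3[1, 2] <- NA; d3[2, 1] <- NA
  expect_error(hierarchical_cluster(d3), "NA")
})

test_that("inertia-gain selection recovers separation and is scale invariant", {
  set.seed(85)
  pts <- c(rnorm(20, 0), rnorm(20, 30))
  d <- as.matrix(dist(pts))
  hc <- hierarchical_cluster(d)
  expect_equal(select_k_inertia_gain(hc), 2L)
  hc_scaled <- hierarchical_cluster(d * 7.3)
  expect_equal(select_k_inertia_gain(hc_scaled), 2L)
  ## all points identical -> degenerate, k_min with warning
  dflat <- matrix(0, 8, 8)
  hflat <- hierarchical_cluster(dflat)
  expect_warning(k <- select_k_inertia_gain(hflat), "flat")
  expect_equal(k, 2L)
})

test_that("cluster labels are invariant to event input order", {
  mix <- generate_regime_mixture(k = 2, events_per_regime = 15, seed = 86)
  cl <- weather_pattern_clusters(mix$bundles, k = 2)
  set.seed(87)
  perm <- sample(length(mix$bundles))
  cl2 <- weather_pattern_clusters(mix$bundles[perm], k = 2)
  ids <- names(cl$labels)
  agree <- mclust::adjustedRandIndex(cl$labels[ids], cl2$labels[ids])
  expect_equal(agree, 1)
})

test_that("cluster yield summaries and letters behave under null and shift", {
  set.seed(88)
  y_null <- c(rnorm(100, 7000, 900), rnorm(100, 7000, 900))
  lab <- rep(1:2, each = 100)
  null_res <- cluster_yield_analysis(lab, y_null)
  expect_equal(sum(null_res$summary$n), 200)
  expect_equal(null_res$letters$letters[["1"]],
               null_res$letters$letters[["2"]])
  ## separation on the scale reported for contrasting weather patterns
  set.seed(89)
  y_sep <- c(rnorm(50, 7885, 900), rnorm(50, 5659, 900))
  sep_res <- cluster_yield_analysis(rep(1:2, each = 50), y_sep)
  l <- sep_res$letters$letters
  expect_false(l[["1"]] == l[["2"]])
  expect_equal(sep_res$summary$cluster[1], "1")   # ordered by median
  ## singleton clusters summarized but excluded from the test
  res1 <- cluster_yield_analysis(c(lab, 3), c(y_null, 7000))
  expect_true("3" %in% res1$excluded)
  expect_equal(sum(res1$summary$n), 201)
})

test_that("cultivar comparisons respect cluster and cultivar size rules", {
  set.seed(90)
  lab <- c(rep(1, 9), rep(2, 40), rep(3, 40))
  cult <- c(rep("F60", 9),
            rep(c("F60", "F733"), each = 20),
            rep(c("F60", "F733"), each = 20))
  yld <- c(rnorm(9, 6000, 500),
           rnorm(20, 7000, 500), rnorm(20, 5000, 500),   # strong split
           rnorm(40, 6000, 500))                          # identical
  res <- cultivar_within_cluster(lab, yld, cult)
  expect_true("1" %in% attr(res, "skipped"))     # 9 events: not considered
  expect_false("1" %in% names(res))
  l2 <- res[["2"]]$letters
  expect_false(l2[["F60"]] == l2[["F733"]])
  l3 <- res[["3"]]$letters
  expect_equal(l3[["F60"]], l3[["F733"]])
  ## a cluster whose eligible cultivars fall below two is reported as such
  res2 <- cultivar_within_cluster(rep(1, 12), rnorm(12),
                                  c(rep("A", 10), "B", "C"))
  expect_equal(res2[["1"]], "no comparison possible")
})
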