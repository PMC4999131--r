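#' Kruskal-Wallis letter grouping
#'
#' Omnibus Kruskal-Wallis test on the pooled ranks followed by pairwise
#' comparisons of mean rank differences using the normal-approximation
#' criterion (midranks for ties, tie-corrected variance), uncorrected at
#' level `alpha` by default to match the customary 5-percent-level
#' multiple-comparison display; a Bonferroni option is available.  Letters
#' are assigned with the standard insert-and-absorb algorithm over items
#' sorted by decreasing mean rank: two items share a letter iff their
#' pairwise difference is not significant.
#'
#' @param samples named list of numeric vectors (>= 2 items, each with
#'   >= 2 values).
#' @param alpha significance level of the pairwise comparisons.
#' @param p_adjust `"none"` (default) or `"bonferroni"`.
#' @return object of class `letter_grouping`: `letters` (named character),
#'   `p_matrix` (pairwise p-values), `mean_ranks`, `kw_p` (omnibus
#'   p-value), `alpha`.
#' @export
kw_letter_groups <- function(samples, alpha = 0.05,
                             p_adjust = c("none", "bonferroni")) {
  p_adjust <- match.arg(p_adjust)
  k <- length(samples)
  stopifnot(k >= 2, all(vapply(samples, length, 0L) >= 2))
  if (is.null(names(samples)))
    names(samples) <- sprintf("item%d", seq_len(k))
  x <- unlist(samples, use.names = FALSE)
  g <- factor(rep(names(samples), vapply(samples, length, 0L)),
              levels = names(samples))
  N <- length(x)
  r <- rank(x)           # midranks
  mr <- tapply(r, g, mean)
  ni <- tapply(r, g, length)
  ties <- table(x)
  tie_corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  s2 <- N * (N + 1) / 12 * tie_corr
  kw_p <- if (length(unique(x)) == 1) 1 else
    suppressWarnings(kruskal.test(x, g)$p.value)

  pmat <- matrix(1, k, k, dimnames = list(names(samples), names(samples)))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (s2 <= 0) { pmat[i, j] <- pmat[j, i] <- 1; next }
      z <- abs(mr[i] - mr[j]) / sqrt(s2 * (1 / ni[i] + 1 / ni[j]))
      p <- 2 * pnorm(-z)
      if (p_adjust == "bonferroni") p <- min(1, p * k * (k - 1) / 2)
      pmat[i, j] <- pmat[j, i] <- p
    }
  }
  ord <- order(mr, decreasing = TRUE)
  letters <- assign_letters(pmat < alpha, names(samples)[ord])
  structure(list(letters = letters[names(samples)], p_matrix = pmat,
                 mean_ranks = setNames(as.numeric(mr), names(samples)),
                 kw_p = kw_p, alpha = alpha),
            class = "letter_grouping")
}

## insert-and-absorb: start from one group holding every item; for each
## significant pair split every group containing both; drop groups that are
## subsets of others; label groups a, b, c, ... in rank order
assign_letters <- function(signif, items_ordered) {
  groups <- list(items_ordered)
  k <- length(items_ordered)
  for (a in seq_len(k - 1)) {
    for (b in (a + 1):k) {
      i <- items_ordered[a]; j <- items_ordered[b]
      if (!isTRUE(signif[i, j])) next
      new_groups <- list()
      for (grp in groups) {
        if (i %in% grp && j %in% grp)
          new_groups <- c(new_groups, list(setdiff(grp, i)),
                          list(setdiff(grp, j)))
        else new_groups <- c(new_groups, list(grp))
      }
      ## absorb groups contained in another group
      keep <- rep(TRUE, length(new_groups))
      for (u in seq_along(new_groups)) {
        for (v in seq_along(new_groups)) {
          if (u != v && keep[v] &&
              all(new_groups[[u]] %in% new_groups[[v]]) &&
              (length(new_groups[[u]]) < length(new_groups[[v]]) || u > v))
            keep[u] <- FALSE
        }
      }
      groups <- unique(new_groups[keep])
    }
  }
  ## order groups by the position of their best-ranked member
  first_pos <- vapply(groups, function(grp)
    min(match(grp, items_ordered)), 0)
  groups <- groups[order(first_pos)]
  out <- setNames(rep("", length(items_ordered)), items_ordered)
  for (gi in seq_along(groups))
    for (it in groups[[gi]])
      out[it] <- paste0(out[it], letters[gi])
  out
}

#' @export
print.letter_grouping <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis letter grouping (alpha = %g, omnibus p = %.3g)\n",
              x$alpha, x$kw_p))
  df <- data.frame(mean_rank = round(x$mean_ranks, 1),
                   letters = x$letters)
  print(df[order(-df$mean_rank), ])
  invisible(x)
}

#' Ensemble of conditional inference forests for variable importance
#'
#' Trains an ensemble of forests on an indicator table and aggregates
#' conditional permutation importances: each run's raw importance vector is
#' normalized (divided by its sum; a run whose raw sum is non-positive gets
#' the uniform vector and a degenerate flag) and scaled by that run's
#' out-of-bag R-squared, and the final importance of a predictor is the
#' mean of its scaled values over runs.  When the table is larger than
#' `subsample_trigger` rows the ensemble instead trains one forest on each
#' of `subsets` independently drawn subsets of `subset_size` distinct rows.
#' Per-predictor importance distributions over runs are letter-grouped with
#' [kw_letter_groups()].
#'
#' @param table indicator table: `Cultivar` (optional), indicator columns,
#'   `Yield`; an `event_id` column is ignored as predictor.
#' @param control a [cif_control()].
#' @param runs number of forests when not subsampling.
#' @param subsample_trigger row count above which the subsampling protocol
#'   is used.
#' @param subsets,subset_size subsampling protocol (independently re-drawn
#'   subsets without replacement within each subset).
#' @param conditional use conditional (default) or marginal permutation
#'   importance.
#' @param cond_threshold see [cif_importance()].
#' @param exclude character vector of columns to exclude from predictors.
#' @param seed master integer seed; the whole ensemble is reproducible from
#'   it.
#' @return object of class `vi_ensemble`: `scaled` (runs x predictors
#'   matrix), `final_vi` (named, sorted decreasing), `r2` (per run),
#'   `letters` ([kw_letter_groups()] result), `degenerate` (per-run flag),
#'   `subsampled`, `subset_rows` (list, when subsampled).
#' @export
vi_ensemble <- function(table, control = cif_control(), runs = 100,
                        subsample_trigger = 500, subsets = 100,
                        subset_size = 400, conditional = TRUE,
                        cond_threshold = 0.2, exclude = character(),
                        seed = 1L) {
  stopifnot("Yield" %in% names(table))
  n <- nrow(table)
  if (n < 50) stopf("at least 50 rows are required, got %d", n)
  pred_cols <- setdiff(names(table), c("event_id", "Yield", exclude))
  x_all <- table[pred_cols]
  y_all <- table$Yield
  subsampled <- n > subsample_trigger
  nrun <- if (subsampled) subsets else runs
  if (subsampled && subset_size > n) {
    warnf("subset_size %d exceeds n = %d; lowered to n", subset_size, n)
    subset_size <- n
  }
  seeds <- split_seed(seed, 3L * nrun)
  p <- length(pred_cols)
  scaled <- matrix(NA_real_, nrun, p, dimnames = list(NULL, pred_cols))
  raw <- matrix(NA_real_, nrun, p, dimnames = list(NULL, pred_cols))
  r2 <- numeric(nrun)
  degenerate <- logical(nrun)
  subset_rows <- if (subsampled) vector("list", nrun) else NULL
  for (r in seq_len(nrun)) {
    if (subsampled) {
      rows <- with_seed(seeds[[3 * r - 2]],
                        sample.int(n, subset_size, replace = FALSE))
      subset_rows[[r]] <- rows
    } else rows <- seq_len(n)
    fit <- cif_forest(x_all[rows, , drop = FALSE], y_all[rows],
                      control = control, seed = seeds[[3 * r - 1]])
    r2[r] <- oob_r2(fit)
    vi_raw <- cif_importance(fit, conditional = conditional,
                             cond_threshold = cond_threshold,
                             seed = seeds[[3 * r]])
    raw[r, ] <- vi_raw
    s <- sum(vi_raw)
    ## degenerate-model guard: dividing by the sum reads each score as a
    ## share of total importance mass; when positive and negative scores
    ## nearly cancel (sum below the largest single magnitude) that reading
    ## is meaningless and the run gets the uniform vector instead
    if (s <= 0 || s < max(abs(vi_raw))) {
      degenerate[r] <- TRUE
      norm <- rep(1 / p, p)
    } else norm <- vi_raw / s
    scaled[r, ] <- norm * r2[r]
  }
  final_vi <- sort(colMeans(scaled), decreasing = TRUE)
  letters <- if (nrun >= 2)
    kw_letter_groups(lapply(as.data.frame(scaled), identity)) else NULL
  structure(list(scaled = scaled, raw = raw, final_vi = final_vi,
                 r2 = r2, letters = letters, degenerate = degenerate,
                 subsampled = subsampled, subset_rows = subset_rows,
                 control = control, conditional = conditional),
            class = "vi_ensemble")
}

#' @export
print.vi_ensemble <- function(x, n = 10, ...) {
  cat(sprintf(paste0("Variable-importance ensemble: %d runs%s, ",
                     "mean R2 = %.3f (sd %.3f)\n"),
              nrow(x$scaled),
              if (x$subsampled) " (subsampled protocol)" else "",
              mean(x$r2), sd(x$r2)))
  if (any(x$degenerate))
    cat(sprintf("  %d degenerate run(s) (non-positive raw importance sum)\n",
                sum(x$degenerate)))
  top <- head(x$final_vi, n)
  df <- data.frame(final_VI = signif(top, 4),
                   letters = x$letters$letters[names(top)])
  print(df)
  invisible(x)
}

#' @export
summary.vi_ensemble <- function(object, ...) {
  nm <- names(object$final_vi)
  data.frame(predictor = nm,
             final_VI = as.numeric(object$final_vi),
             vi_sd = apply(object$scaled[, nm, drop = FALSE], 2, sd),
             letters = unname(object$letters$letters[nm]),
             row.names = NULL)
}

#' @export
plot.vi_ensemble <- function(x, n = 15, ...) {
  top <- rev(head(x$final_vi, n))
  graphics::barplot(top, horiz = TRUE, las = 1,
                    xlab = "final variable importance (R2-scaled)", ...)
  invisible(x)
}

#' Partial dependence profile of a forest predictor
#'
#' Evaluates the forest on the training rows with one predictor forced to
#' each point of a quantile grid (1st to 99th percentile) and averages the
#' predictions, tracing the partial relationship between the predictor and
#' the modelled response.
#'
#' @param model a [cif_forest()] fit.
#' @param predictor name of a continuous predictor.
#' @param grid_size number of grid points.
#' @return object of class `partial_dependence`: data.frame with `grid` and
#'   `profile`, plus attributes `predictor` and `rug` (observed values).
#' @export
partial_dependence <- function(model, predictor, grid_size = 40) {
  stopifnot(inherits(model, "cif_forest"))
  j <- match(predictor, model$var_names)
  if (is.na(j)) stopf("unknown predictor '%s'", predictor)
  if (model$nlev[j] > 0)
    stopf("partial dependence is defined here for continuous predictors")
  xj <- model$x[, j]
  if (var(xj) == 0) stopf("constant predictor '%s'", predictor)
  grid <- unique(as.numeric(quantile(xj, seq(0.01, 0.99,
                                             length.out = grid_size))))
  prof <- vapply(grid, function(g) {
    M <- model$x
    M[, j] <- g
    mean(.cif_predict_cpp(model$trees, M, model$nlev))
  }, 0.0)
  structure(data.frame(grid = grid, profile = prof),
            predictor = predictor, rug = xj,
            class = c("partial_dependence", "data.frame"))
}

#' @export
plot.partial_dependence <- function(x, ...) {
  plot(x$grid, x$profile, type = "l",
       xlab = attr(x, "predictor"), ylab = "partial prediction", ...)
  graphics::rug(attr(x, "rug"))
  invisible(x)
}

#' Estimate the breakpoint of a partial dependence curve
#'
#' Locates the maximum-curvature point: the grid value with the largest
#' absolute change of local slope between adjacent segments of the profile.
#'
#' @param pd a [partial_dependence()] object.
#' @return the grid value at maximal curvature.
#' @export
pd_breakpoint <- function(pd) {
  g <- pd$grid; f <- pd$profile
  stopifnot(length(g) >= 3)
  slopes <- diff(f) / diff(g)
  curv <- abs(diff(slopes))
  g[which.max(curv) + 1]
}

#' Per-cultivar importance ensembles
#'
#' Runs [vi_ensemble()] on each cultivar subset with strictly more than
#' `min_n` rows, excluding the cultivar column from the predictors; smaller
#' cultivars are reported as skipped.
#'
#' @param table indicator table with a `Cultivar` column.
#' @param min_n minimum observations (strict `>`).
#' @param ... passed to [vi_ensemble()].
#' @return list: `models` (named list of `vi_ensemble`), `skipped` (named
#'   integer vector of row counts).
#' @export
per_cultivar_vi <- function(table, min_n = 100, ...) {
  stopifnot("Cultivar" %in% names(table))
  counts <- table(as.character(table$Cultivar))
  run <- names(counts)[counts > min_n]
  skip <- counts[setdiff(names(counts), run)]
  models <- lapply(setNames(run, run), function(cv)
    vi_ensemble(table[as.character(table$Cultivar) == cv, , drop = FALSE],
                exclude = "Cultivar", ...))
  list(models = models,
       skipped = setNames(as.integer(skip), names(skip)))
}
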