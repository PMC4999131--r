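#' Control parameters for conditional inference forests
#'
#' Defaults follow common practice for explanatory forest analyses of
#' indicator tables: 2,000 trees, mtry = round(p/3) candidate predictors
#' per node (9 when p = 27), split selection by association-test p-value
#' with a Bonferroni-adjusted stop at the 5 percent level, and node-size
#' limits minsplit = 20, minbucket = 7.
#'
#' @param ntree number of trees.
#' @param mtry candidate predictors sampled at each node; `NULL` means
#'   `round(p / 3)`.
#' @param alpha_split significance level of the split stop criterion.
#' @param minsplit minimum node size considered for splitting.
#' @param minbucket minimum terminal node size.
#' @return list of class `cif_control`.
#' @export
cif_control <- function(ntree = 2000, mtry = NULL, alpha_split = 0.05,
                        minsplit = 20, minbucket = 7) {
  stopifnot(ntree >= 1, alpha_split > 0, alpha_split <= 1,
            minsplit >= 2, minbucket >= 1)
  structure(list(ntree = as.integer(ntree), mtry = mtry,
                 alpha_split = alpha_split, minsplit = as.integer(minsplit),
                 minbucket = as.integer(minbucket)),
            class = "cif_control")
}

## encode a predictor data.frame for the C++ core: factors become 1-based
## level codes, numerics pass through; nlev is 0 for numeric columns
encode_predictors <- function(x, levels = NULL) {
  stopifnot(is.data.frame(x))
  p <- ncol(x)
  nlev <- integer(p)
  lev <- levels %||% vector("list", p)
  M <- matrix(0, nrow(x), p, dimnames = list(NULL, names(x)))
  for (j in seq_len(p)) {
    col <- x[[j]]
    if (is.character(col)) col <- factor(col)
    if (is.factor(col)) {
      if (is.null(lev[[j]])) lev[[j]] <- levels(col)
      if (length(lev[[j]]) > 32)
        stopf("categorical predictor '%s' has more than 32 levels",
              names(x)[j])
      code <- match(as.character(col), lev[[j]])
      if (anyNA(code))
        stopf("unseen level in categorical predictor '%s'", names(x)[j])
      M[, j] <- code
      nlev[j] <- length(lev[[j]])
    } else {
      if (anyNA(col) || any(!is.finite(col)))
        stopf("missing or non-finite values in predictor '%s'", names(x)[j])
      M[, j] <- as.numeric(col)
    }
  }
  list(M = M, nlev = nlev, levels = lev)
}

#' Fit a conditional inference regression forest
#'
#' Grows an ensemble of conditional-inference-style regression trees on
#' bootstrap samples.  At each node, `mtry` predictors are sampled without
#' replacement and the one with the smallest p-value of a standardized
#' linear association statistic with the response is selected; the node is
#' not split if the Bonferroni-adjusted minimum p-value exceeds
#' `alpha_split` or the node is smaller than `minsplit`.  The split point
#' maximizes the standardized two-sample mean-difference statistic subject
#' to `minbucket`.  Forest predictions average the tree-wise terminal-node
#' means.  The fit is fully deterministic given `seed`.
#'
#' @param x data.frame of predictors (numeric and/or factor; factors of at
#'   most 32 levels).
#' @param y numeric response (here: yield, kg ha-1); must not be constant.
#' @param control a [cif_control()] object.
#' @param seed integer seed.
#' @return object of class `cif_forest` with elements `trees`, `x`, `y`,
#'   `nlev`, `levels`, `control`.
#' @seealso [oob_r2()], [cif_importance()], [partial_dependence()]
#' @export
cif_forest <- function(x, y, control = cif_control(), seed = NULL) {
  stopifnot(is.numeric(y), nrow(x) == length(y))
  if (var(y) == 0) stopf("the response is constant; nothing to model")
  enc <- encode_predictors(x)
  mtry <- control$mtry %||% max(1L, round(ncol(x) / 3))
  if (mtry < 1 || mtry > ncol(x)) stopf("mtry must lie in [1, p]")
  trees <- with_seed(seed,
    .cif_fit_cpp(enc$M, y, enc$nlev, control$ntree, as.integer(mtry),
                 control$alpha_split, control$minsplit, control$minbucket))
  structure(list(trees = trees, x = enc$M, y = y, nlev = enc$nlev,
                 levels = enc$levels, var_names = names(x),
                 control = control, mtry = as.integer(mtry)),
            class = "cif_forest")
}

#' @export
print.cif_forest <- function(x, ...) {
  cat(sprintf(paste0("Conditional inference regression forest\n",
                     "  %d trees, %d predictors (mtry = %d), n = %d\n"),
              length(x$trees), ncol(x$x), x$mtry, length(x$y)))
  r2 <- tryCatch(oob_r2(x), error = function(e) NA_real_)
  if (!is.na(r2)) cat(sprintf("  out-of-bag R-squared: %.3f\n", r2))
  invisible(x)
}

#' @export
predict.cif_forest <- function(object, newdata = NULL, ...) {
  M <- if (is.null(newdata)) object$x else {
    stopifnot(identical(names(newdata), object$var_names))
    encode_predictors(newdata, levels = object$levels)$M
  }
  .cif_predict_cpp(object$trees, M, object$nlev)
}

#' Out-of-bag predictions of a forest
#'
#' @param model a [cif_forest()] fit.
#' @return numeric vector of OOB predictions (NA for observations that were
#'   in-bag in every tree).
#' @export
oob_predictions <- function(model) {
  stopifnot(inherits(model, "cif_forest"))
  .cif_oob_predict_cpp(model$trees, model$x, model$nlev)
}

#' Out-of-bag coefficient of determination
#'
#' R2 = 1 - sum((y - yhat_oob)^2) / sum((y - ybar)^2), computed over the
#' observations that were out-of-bag in at least one tree.  May be negative
#' (a forest worse than the mean); it is not clipped.
#'
#' @param model a [cif_forest()] fit, or a numeric vector of observed
#'   responses when `yhat` is supplied.
#' @param yhat optional vector of (OOB) predictions aligned with `model`
#'   taken as the observed responses.
#' @return R-squared, unitless.
#' @export
oob_r2 <- function(model, yhat = NULL) {
  if (inherits(model, "cif_forest")) {
    y <- model$y
    yhat <- oob_predictions(model)
  } else y <- model
  ok <- !is.na(yhat)
  y <- y[ok]; yhat <- yhat[ok]
  if (length(y) == 0) stopf("no out-of-bag observations")
  if (var(y) == 0) stopf("zero variance in the response")
  1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
}

#' Permutation variable importance (conditional or marginal)
#'
#' For each predictor the out-of-bag mean squared error after permuting it
#' is compared with the unpermuted baseline, per tree, and averaged.  With
#' `conditional = TRUE` (default) the permutation is performed within the
#' cells of the partition formed by each tree's own split points on the
#' covariates whose absolute Spearman correlation with the permuted
#' predictor exceeds `cond_threshold`, which isolates a predictor's own
#' contribution from that of its correlates.  Negative values are retained.
#'
#' @param model a [cif_forest()] fit.
#' @param conditional permute within conditioning strata (`TRUE`) or freely
#'   (`FALSE`, marginal importance).
#' @param cond_threshold absolute Spearman correlation above which a
#'   covariate joins a predictor's conditioning set.
#' @param seed integer seed for the permutations.
#' @return named numeric vector of raw importance scores (MSE increase,
#'   response units squared).
#' @export
cif_importance <- function(model, conditional = TRUE, cond_threshold = 0.2,
                           seed = NULL) {
  stopifnot(inherits(model, "cif_forest"))
  p <- ncol(model$x)
  cond_sets <- rep(list(integer()), p)
  if (conditional) {
    num <- which(model$nlev == 0)
    if (length(num) > 1) {
      rho <- suppressWarnings(cor(model$x[, num, drop = FALSE],
                                  method = "spearman"))
      rho[!is.finite(rho)] <- 0
      for (a in seq_along(num)) {
        others <- num[abs(rho[a, ]) > cond_threshold & seq_along(num) != a]
        cond_sets[[num[a]]] <- as.integer(others)
      }
    }
  }
  vi <- with_seed(seed,
    .cif_vi_cpp(model$trees, model$x, model$y, model$nlev, cond_sets,
                conditional))
  setNames(vi, model$var_names)
}

#' First split variable of every tree
#'
#' @param model a [cif_forest()] fit.
#' @return character vector (NA for trees that never split).
#' @export
root_split_vars <- function(model) {
  idx <- .cif_root_vars_cpp(model$trees)
  ifelse(idx == 0, NA_character_, model$var_names[pmax(idx, 1)])
}
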