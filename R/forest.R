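# Oblique classification random forest: bagged trees whose node splits are
# linear combinations of a random feature subset, learned by L2-penalised
# least squares on +/-1 coded labels with the split threshold chosen to
# minimise Gini impurity. Features are z-scored with training statistics so
# one ridge penalty is meaningful across heterogeneous units (mm^3 vs
# unitless). The positive class (1) is "conversion"; vote ties go to it.

default_ridge_grid <- function() 10^seq(-3, 2, by = 1)

#' Hyperparameter configuration for the oblique forest
#'
#' @param mtry_grid candidate numbers of features drawn at each node;
#'   `NULL` means the standard grid `{3, floor(sqrt(p)), 7}` (deduplicated,
#'   capped at p) resolved at tuning time.
#' @param ntree_grid candidate forest sizes.
#' @param ridge_grid L2 penalties tried at every node (the node keeps the
#'   penalty/threshold pair with the lowest split impurity).
#' @param min_node_size nodes smaller than this become leaves.
#' @param max_depth maximal tree depth; 0 means unlimited.
#' @return An object of class `orf_config`.
#' @export
orf_config <- function(mtry_grid = NULL, ntree_grid = c(100L, 200L, 300L),
                       ridge_grid = default_ridge_grid(),
                       min_node_size = 2L, max_depth = 0L) {
  if (!length(ntree_grid) || !length(ridge_grid))
    stop("ntree_grid and ridge_grid must be non-empty")
  structure(list(mtry_grid = if (is.null(mtry_grid)) NULL else as.integer(mtry_grid),
                 ntree_grid = as.integer(ntree_grid),
                 ridge_grid = as.numeric(ridge_grid),
                 min_node_size = as.integer(min_node_size),
                 max_depth = as.integer(max_depth)),
            class = "orf_config")
}

resolve_mtry_grid <- function(config, p) {
  g <- if (is.null(config$mtry_grid)) c(3L, as.integer(floor(sqrt(p))), 7L)
       else config$mtry_grid
  sort(unique(pmax(1L, pmin(g, p))))
}

as_feature_matrix <- function(x) {
  if (is.data.frame(x)) {
    x <- x[, setdiff(names(x), "patient_id"), drop = FALSE]
    x <- as.matrix(x)
  }
  storage.mode(x) <- "double"
  x
}

check_labels <- function(y, n) {
  y <- as.integer(y)
  if (length(y) != n) stop("length of y does not match rows of x")
  if (anyNA(y) || !all(y %in% c(0L, 1L)))
    stop("y must be binary 0/1 (1 = conversion)")
  if (length(unique(y)) < 2L)
    stop("y contains a single class; both classes are required")
  y
}

#' Fit an oblique random forest
#'
#' Grows `ntree` trees on independent bootstrap samples (size n, with
#' replacement). At each node `mtry` features are drawn without
#' replacement; for every penalty in `ridge_grid` the +/-1 coded labels are
#' regressed on the subset by ridge least squares (intercept unpenalised)
#' and thresholds at midpoints of the sorted projections are scanned; the
#' penalty/threshold pair with minimal Gini impurity defines the split. A
#' node becomes a leaf when pure, smaller than `min_node_size`, at
#' `max_depth`, or when no split reduces impurity. The out-of-bag error is
#' the misclassification rate of majority votes restricted, per sample, to
#' trees whose bootstrap sample excluded it.
#'
#' @param x numeric matrix or data.frame of features (a `patient_id` column
#'   is dropped automatically).
#' @param y binary labels, 1 = conversion (positive class).
#' @param mtry features drawn per node (default `floor(sqrt(p))`, at least 3).
#' @param ntree number of trees.
#' @param ridge_grid L2 penalties tried per node.
#' @param min_node_size,max_depth stopping rules (0 depth = unlimited).
#' @param seed optional seed (`set.seed` is called when given).
#' @return An object of class `oblique_forest`.
#' @export
orf_fit <- function(x, y, mtry = NULL, ntree = 300L,
                    ridge_grid = default_ridge_grid(),
                    min_node_size = 2L, max_depth = 0L, seed = NULL) {
  x <- as_feature_matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (n < 10L) stop("at least 10 samples are required")
  if (p < 1L) stop("at least one feature is required")
  y <- check_labels(y, n)
  if (is.null(mtry)) mtry <- max(3L, as.integer(floor(sqrt(p))))
  mtry <- min(as.integer(mtry), p)
  if (!is.null(seed)) set.seed(as.integer(seed))

  center <- colMeans(x)
  scale <- apply(x, 2, pop_sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  xs <- sweep(sweep(x, 2, center, "-"), 2, scale, "/")

  fit <- orf_fit_cpp(xs, y, mtry, as.integer(ntree), as.numeric(ridge_grid),
                     as.integer(min_node_size), as.integer(max_depth))
  structure(list(trees = fit$trees,
                 oob_error = fit$oob_error,
                 oob_pred = fit$oob_pred,
                 inbag = fit$inbag,
                 mtry = mtry, ntree = as.integer(ntree),
                 ridge_grid = as.numeric(ridge_grid),
                 min_node_size = as.integer(min_node_size),
                 max_depth = as.integer(max_depth),
                 center = center, scale = scale,
                 feature_names = colnames(x),
                 n_train = n, seed = seed),
            class = "oblique_forest")
}

#' @export
print.oblique_forest <- function(x, ...) {
  cat("<oblique_forest> ", x$ntree, " trees, mtry ", x$mtry, ", ",
      length(x$center), " features; OOB error ",
      formatC(x$oob_error, digits = 4, format = "f"), "\n", sep = "")
  invisible(x)
}

#' Predict from an oblique forest
#'
#' Majority vote over the trees; ties are broken toward the positive class
#' ("conversion", the majority class of the motivating cohort).
#'
#' @param object an `oblique_forest`.
#' @param newdata feature matrix or data.frame with the training columns.
#' @param type `"class"` for 0/1 labels, `"fraction"` for the fraction of
#'   trees voting for conversion.
#' @param ... unused.
#' @export
predict.oblique_forest <- function(object, newdata,
                                   type = c("class", "fraction"), ...) {
  type <- match.arg(type)
  x <- as_feature_matrix(newdata)
  if (!is.null(object$feature_names) && !is.null(colnames(x)))
    x <- x[, object$feature_names, drop = FALSE]
  if (ncol(x) != length(object$center))
    stop("newdata has ", ncol(x), " features; forest was trained on ",
         length(object$center))
  xs <- sweep(sweep(x, 2, object$center, "-"), 2, object$scale, "/")
  frac <- orf_vote_cpp(object$trees, xs)
  if (type == "fraction") return(frac)
  as.integer(frac >= 0.5)
}

#' Tune mtry and ntree on the out-of-bag error
#'
#' Grid search over `mtry_grid x ntree_grid`; every candidate forest is fit
#' on the same data and scored by its OOB error. Ties are broken toward
#' smaller `ntree`, then smaller `mtry`. The winning forest is returned
#' (already fitted).
#'
#' @param x,y as in [orf_fit()].
#' @param config an [orf_config()].
#' @param seed seed for the whole search (one RNG stream across candidates).
#' @return An object of class `orf_tune`: `results` (data.frame of mtry,
#'   ntree, oob_error), `best_mtry`, `best_ntree`, and `forest`.
#' @export
orf_tune <- function(x, y, config = orf_config(), seed = NULL) {
  stopifnot(inherits(config, "orf_config"))
  xm <- as_feature_matrix(x)
  p <- ncol(xm)
  mtry_grid <- resolve_mtry_grid(config, p)
  cand <- expand.grid(mtry = mtry_grid, ntree = sort(config$ntree_grid))
  cand <- cand[order(cand$ntree, cand$mtry), , drop = FALSE]
  if (!is.null(seed)) set.seed(as.integer(seed))
  best <- NULL; best_err <- Inf
  errs <- numeric(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    f <- orf_fit(xm, y, mtry = cand$mtry[i], ntree = cand$ntree[i],
                 ridge_grid = config$ridge_grid,
                 min_node_size = config$min_node_size,
                 max_depth = config$max_depth, seed = NULL)
    errs[i] <- f$oob_error
    if (f$oob_error < best_err) {  # strict: first minimum wins ties
      best_err <- f$oob_error
      best <- f
    }
  }
  results <- data.frame(mtry = cand$mtry, ntree = cand$ntree, oob_error = errs)
  structure(list(results = results,
                 best_mtry = best$mtry, best_ntree = best$ntree,
                 forest = best),
            class = "orf_tune")
}

#' @export
print.orf_tune <- function(x, ...) {
  cat("<orf_tune> best: mtry ", x$best_mtry, ", ntree ", x$best_ntree,
      " (OOB error ", formatC(x$forest$oob_error, digits = 4, format = "f"),
      ") over ", nrow(x$results), " candidates\n", sep = "")
  invisible(x)
}

#' Bootstrapped node-logistic-regression feature importance
#'
#' Repeats `n_bootstrap` times: resample the data with replacement, grow a
#' forest, and at every internal node fit a logistic regression of the node
#' labels on the node's chosen feature subset. Each subset feature scores
#' +1 when its Wald p-value is below `alpha` and -1 otherwise; a node where
#' the logistic fit does not converge (perfect separation) counts +1 for
#' all its subset features and is flagged. Scores are summed over nodes,
#' trees and iterations; the per-iteration mean is reported.
#'
#' @param x,y as in [orf_fit()].
#' @param mtry,ntree,ridge_grid,min_node_size,max_depth forest parameters.
#' @param n_bootstrap bootstrap iterations (default 100).
#' @param alpha node-level significance threshold.
#' @param node_model `"multivariate"` (one logistic model on the whole
#'   subset, the default) or `"univariate"` (one simple logistic per subset
#'   feature).
#' @param seed optional seed.
#' @return An object of class `orf_importance` with a `scores` data.frame
#'   (feature, mean_score, total_score) sorted by decreasing mean score,
#'   and `n_flagged_nodes`.
#' @export
orf_importance <- function(x, y, mtry = NULL, ntree = 100L,
                           ridge_grid = default_ridge_grid(),
                           n_bootstrap = 100L, alpha = 0.05,
                           node_model = c("multivariate", "univariate"),
                           min_node_size = 2L, max_depth = 0L, seed = NULL) {
  node_model <- match.arg(node_model)
  x <- as_feature_matrix(x)
  n <- nrow(x); p <- ncol(x)
  y <- check_labels(y, n)
  if (is.null(mtry)) mtry <- max(3L, as.integer(floor(sqrt(p))))
  mtry <- min(as.integer(mtry), p)
  if (!is.null(seed)) set.seed(as.integer(seed))
  center <- colMeans(x)
  scale <- apply(x, 2, pop_sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  xs <- sweep(sweep(x, 2, center, "-"), 2, scale, "/")
  res <- orf_importance_cpp(xs, y, mtry, as.integer(ntree),
                            as.numeric(ridge_grid), as.integer(n_bootstrap),
                            alpha, node_model == "univariate",
                            as.integer(min_node_size), as.integer(max_depth))
  nm <- colnames(x)
  if (is.null(nm)) nm <- paste0("x", seq_len(p))
  scores <- data.frame(feature = nm,
                       mean_score = as.numeric(res$mean_score),
                       total_score = as.numeric(res$total_score),
                       stringsAsFactors = FALSE)
  scores <- scores[order(-scores$mean_score), , drop = FALSE]
  rownames(scores) <- NULL
  structure(list(scores = scores,
                 n_flagged_nodes = res$n_flagged_nodes,
                 n_bootstrap = as.integer(n_bootstrap), alpha = alpha,
                 node_model = node_model),
            class = "orf_importance")
}

#' @export
print.orf_importance <- function(x, ...) {
  cat("<orf_importance> ", x$n_bootstrap, " bootstrap iterations (",
      x$node_model, " node model)\n", sep = "")
  print(utils::head(x$scores, 10))
  invisible(x)
}

# ---- serialization ---------------------------------------------------------

#' Serialize an oblique forest to JSON
#'
#' The JSON object carries a format tag, the forest hyperparameters, the
#' feature standardisation (center/scale), and per tree the node arrays:
#' `left`/`right` child indices (0-based, -1 for leaves), leaf `class`,
#' node sample count `n`, projection `threshold`, per-node feature
#' `subsets` (0-based) and `weights` (intercept first). Doubles are written
#' with 17 significant digits so a round trip reproduces predictions
#' exactly.
#'
#' @param forest an `oblique_forest`.
#' @param path optional file to write to.
#' @return The JSON string (invisibly when `path` is given).
#' @export
orf_to_json <- function(forest, path = NULL) {
  stopifnot(inherits(forest, "oblique_forest"))
  obj <- list(format = "cisforest-oblique-forest-v1",
              mtry = forest$mtry, ntree = forest$ntree,
              ridge_grid = forest$ridge_grid,
              min_node_size = forest$min_node_size,
              max_depth = forest$max_depth,
              seed = forest$seed,
              oob_error = forest$oob_error,
              feature_names = forest$feature_names,
              center = unname(forest$center), scale = unname(forest$scale),
              trees = lapply(forest$trees, function(tr) {
                list(left = tr$left, right = tr$right, class = tr$class,
                     n = tr$n, threshold = tr$threshold,
                     subsets = tr$subsets, weights = tr$weights)
              }))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17), null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Deserialize an oblique forest written by [orf_to_json()]
#'
#' @param json a JSON string or path to a JSON file.
#' @return An `oblique_forest` (without OOB vote details).
#' @export
orf_from_json <- function(json) {
  if (length(json) == 1L && file.exists(json)) json <- paste(readLines(json), collapse = "\n")
  obj <- jsonlite::fromJSON(json, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  if (!identical(obj$format, "cisforest-oblique-forest-v1"))
    stop("not a cisforest oblique-forest JSON object")
  trees <- lapply(obj$trees, function(tr) {
    k <- length(tr$left)
    list(left = as.integer(tr$left), right = as.integer(tr$right),
         class = as.integer(tr$class), n = as.integer(tr$n),
         threshold = as.numeric(tr$threshold),
         subsets = lapply(tr$subsets, as.integer),
         weights = lapply(tr$weights, as.numeric))
  })
  structure(list(trees = trees, oob_error = obj$oob_error, oob_pred = NULL,
                 inbag = NULL, mtry = as.integer(obj$mtry),
                 ntree = as.integer(obj$ntree),
                 ridge_grid = as.numeric(obj$ridge_grid),
                 min_node_size = as.integer(obj$min_node_size),
                 max_depth = as.integer(obj$max_depth),
                 center = as.numeric(obj$center), scale = as.numeric(obj$scale),
                 feature_names = if (is.null(obj$feature_names)) NULL
                                 else as.character(obj$feature_names),
                 n_train = NA_integer_, seed = obj$seed),
            class = "oblique_forest")
}
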