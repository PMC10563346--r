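#' Default hyperparameter grid
#'
#' Grid over the tuned dimensions of the forest: number of trees, maximum
#' tree depth (NA = unlimited), per-tree bootstrap sample fraction, and
#' number of candidate features per split.
#'
#' @param ntree,max_depth,sample_frac,mtry Vectors of candidate values.
#' @return data.frame, one row per grid point.
#' @export
pdivas_grid <- function(ntree = c(100, 300, 500),
                        max_depth = c(4, 8, 16, NA),
                        sample_frac = c(0.5, 0.8, 1.0),
                        mtry = c(1, 2, 3, length(PDIVAS_FEATURES))) {
  expand.grid(ntree = ntree, max_depth = max_depth,
              sample_frac = sample_frac, mtry = mtry)
}

# reduced grid for smoke-scale runs (documented in the vignette)
#' @rdname pdivas_grid
#' @export
pdivas_grid_small <- function() {
  expand.grid(ntree = c(100, 300), max_depth = c(4, NA),
              sample_frac = c(0.8, 1.0), mtry = c(2, 5))
}

as_label01 <- function(label) {
  if (is.factor(label)) label <- as.character(label)
  if (is.character(label)) {
    ok <- label %in% c("pathogenic", "benign")
    if (!all(ok)) stop("labels must be 'pathogenic'/'benign' (or 0/1)")
    label <- as.integer(label == "pathogenic")
  }
  label <- as.integer(label)
  if (!all(label %in% c(0L, 1L))) stop("labels must be binary")
  label
}

feature_matrix <- function(data, features = PDIVAS_FEATURES) {
  miss <- setdiff(features, names(data))
  if (length(miss)) stop("missing feature columns: ",
                         paste(miss, collapse = ", "))
  m <- as.matrix(data[, features, drop = FALSE])
  storage.mode(m) <- "double"
  m
}

rf_fit <- function(X, y, ntree, max_depth, sample_frac, mtry, seed) {
  if (is.na(max_depth)) max_depth <- 1000000L
  set.seed(seed)
  .rf_train(X, y, as.integer(ntree), as.integer(max_depth),
            as.numeric(sample_frac), as.integer(mtry))
}

stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    i <- which(y == cls)
    fold[i] <- sample(rep_len(seq_len(k), length(i)))
  }
  fold
}

#' Tune forest hyperparameters by cross-validated average precision
#'
#' Stratified k-fold cross-validation over a hyperparameter grid; the
#' selected point maximizes mean cross-validated average precision. Ties are
#' broken toward the smaller model: fewer trees, then shallower depth, then
#' smaller sample fraction, then fewer features per split.
#'
#' @param data data.frame containing the feature columns.
#' @param label Binary labels ("pathogenic"/"benign" or 0/1).
#' @param grid Grid from [pdivas_grid()].
#' @param k Number of folds (default 5).
#' @param seed RNG seed; results are deterministic given the seed.
#' @param features Feature columns to use.
#' @return List: \code{best} (one-row data.frame), \code{cv} (grid with mean
#'   AP per point).
#' @export
tune_hyperparameters <- function(data, label, grid = pdivas_grid(), k = 5,
                                 seed = 1, features = PDIVAS_FEATURES) {
  if (nrow(grid) == 0) stop("empty hyperparameter grid")
  y <- as_label01(label)
  if (min(table(y)) < k)
    stop("need at least k rows of each class for ", k, "-fold CV")
  X <- feature_matrix(data, features)
  fold <- stratified_folds(y, k, child_seed(seed, 11))
  ap <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    hp <- grid[g, ]
    fold_ap <- numeric(k)
    for (f in seq_len(k)) {
      tr <- fold != f
      m <- rf_fit(X[tr, , drop = FALSE], y[tr], hp$ntree, hp$max_depth,
                  hp$sample_frac, min(hp$mtry, ncol(X)),
                  child_seed(seed, 100L + g * k + f))
      s <- .rf_predict(m$trees, X[!tr, , drop = FALSE])
      fold_ap[f] <- average_precision(y[!tr], s)
    }
    ap[g] <- mean(fold_ap)
  }
  depth_key <- ifelse(is.na(grid$max_depth), Inf, grid$max_depth)
  best <- order(-ap, grid$ntree, depth_key, grid$sample_frac, grid$mtry)[1]
  cv <- cbind(grid, mean_ap = ap)
  list(best = grid[best, , drop = FALSE], cv = cv)
}

#' Fit the deep-intronic pathogenicity forest
#'
#' Trains the random-forest ensemble on a labeled five-feature table. The
#' prediction score of a variant is the fraction of trees classifying it as
#' pathogenic, so every score is a multiple of 1/ntree in [0,1]. When
#' \code{hp} is NULL the hyperparameters are first tuned by
#' [tune_hyperparameters()] on \code{grid}.
#'
#' @param data data.frame with the [pdivas_features()] columns (complete rows
#'   only) and, unless \code{label} is given, a \code{label} column.
#' @param label Binary labels; defaults to \code{data$label}.
#' @param hp NULL (tune) or a one-row data.frame / list with \code{ntree},
#'   \code{max_depth}, \code{sample_frac}, \code{mtry}.
#' @param grid Tuning grid when \code{hp} is NULL.
#' @param k CV folds for tuning.
#' @param seed RNG seed (fit is bit-reproducible given the seed).
#' @param features Feature columns.
#' @return Object of class \code{"pdivas_fit"}.
#' @export
pdivas <- function(data, label = data$label, hp = NULL,
                   grid = pdivas_grid(), k = 5, seed = 1,
                   features = PDIVAS_FEATURES) {
  y <- as_label01(label)
  if (length(unique(y)) < 2) stop("training data must contain both classes")
  X <- feature_matrix(data, features)
  if (anyNA(X)) stop("training rows must be complete (no missing features)")
  cv <- NULL
  if (is.null(hp)) {
    tuned <- tune_hyperparameters(data, y, grid, k, seed, features)
    hp <- tuned$best
    cv <- tuned$cv
  }
  hp <- as.data.frame(hp)[1, c("ntree", "max_depth", "sample_frac", "mtry")]
  m <- rf_fit(X, y, hp$ntree, hp$max_depth, hp$sample_frac,
              min(hp$mtry, ncol(X)), child_seed(seed, 1))
  structure(list(forest = m$trees,
                 importance = setNames(as.numeric(m$importance), features),
                 hp = hp, seed = seed, cv = cv, features = features,
                 n = nrow(X), class_counts = table(y)),
            class = "pdivas_fit")
}

#' @export
print.pdivas_fit <- function(x, ...) {
  cat("Deep-intronic splice pathogenicity forest\n")
  cat(sprintf("  trees: %d  max depth: %s  sample frac: %g  mtry: %d\n",
              x$hp$ntree,
              if (is.na(x$hp$max_depth)) "unlimited" else x$hp$max_depth,
              x$hp$sample_frac, x$hp$mtry))
  cat(sprintf("  trained on %d rows (%d pathogenic / %d benign)\n",
              x$n, x$class_counts["1"], x$class_counts["0"]))
  invisible(x)
}

#' @export
summary.pdivas_fit <- function(object, ...) {
  print(object)
  cat("  feature importances (impurity decrease, sum 1):\n")
  imp <- sort(feature_importances(object), decreasing = TRUE)
  for (f in names(imp)) cat(sprintf("    %-24s %.3f\n", f, imp[f]))
  if (!is.null(object$cv))
    cat(sprintf("  tuned over %d grid points; best CV mean AP = %.4f\n",
                nrow(object$cv), max(object$cv$mean_ap)))
  invisible(object)
}

#' Predict pathogenicity scores
#'
#' Returns the fraction-of-trees score for each row. Rows with any missing
#' feature are unscorable and return NA (never a numeric score).
#'
#' @param object A [pdivas()] fit.
#' @param newdata data.frame with the model's feature columns.
#' @param ... Unused.
#' @return Numeric scores in [0,1]; NA for incomplete rows.
#' @export
predict.pdivas_fit <- function(object, newdata, ...) {
  X <- feature_matrix(newdata, object$features)
  ok <- !apply(is.na(X), 1, any)
  out <- rep(NA_real_, nrow(X))
  if (any(ok))
    out[ok] <- .rf_predict(object$forest, X[ok, , drop = FALSE])
  out
}

#' Impurity-decrease feature importances
#'
#' Mean over trees of each tree's normalized accumulated Gini impurity
#' decrease; non-negative and summing to 1.
#'
#' @param model A [pdivas()] fit.
#' @return Named numeric vector over the model's features.
#' @export
feature_importances <- function(model) {
  stopifnot(inherits(model, "pdivas_fit"))
  model$importance
}

#' @export
plot.pdivas_fit <- function(x, ...) {
  imp <- sort(feature_importances(x))
  graphics::barplot(imp, horiz = TRUE, las = 1,
                    xlab = "impurity-decrease importance",
                    main = "Feature importances", ...)
  invisible(x)
}

#' Cumulative-feature training analysis
#'
#' Retrains the forest on growing feature prefixes (first feature alone,
#' first two, ...) with the same train/test split and hyperparameters for
#' every row, reporting held-out average precision and maximum MCC per
#' prefix.
#'
#' @param train,test data.frames with feature columns.
#' @param train_label,test_label Binary labels.
#' @param ordered_features Features in the order they are added.
#' @param hp Hyperparameters (one-row data.frame/list); required so every
#'   prefix uses the same settings.
#' @param seed RNG seed.
#' @return data.frame with columns \code{n_features}, \code{feature_added},
#'   \code{average_precision}, \code{max_mcc}.
#' @export
cumulative_feature_analysis <- function(train, test, train_label, test_label,
                                        ordered_features = PDIVAS_FEATURES,
                                        hp = list(ntree = 300, max_depth = NA,
                                                  sample_frac = 1, mtry = 2),
                                        seed = 1) {
  stopifnot(length(ordered_features) >= 1)
  ytr <- as_label01(train_label); yte <- as_label01(test_label)
  out <- vector("list", length(ordered_features))
  for (i in seq_along(ordered_features)) {
    feats <- ordered_features[seq_len(i)]
    hp_i <- list(ntree = hp$ntree, max_depth = hp$max_depth,
                 sample_frac = hp$sample_frac, mtry = min(hp$mtry, i))
    fit <- pdivas(train, ytr, hp = hp_i, seed = seed, features = feats)
    s <- predict(fit, test)
    out[[i]] <- data.frame(
      n_features = i, feature_added = ordered_features[i],
      average_precision = average_precision(yte, s),
      max_mcc = max_mcc(yte, s)$mcc)
  }
  do.call(rbind, out)
}
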