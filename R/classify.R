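#' Train a Gaussian-kernel SVM on texture feature vectors
#'
#' Soft-margin support vector machine with the radial basis (Gaussian)
#' kernel `k(u, v) = exp(-gamma * ||u - v||^2)`. Features are
#' standardized (zero mean, unit variance; constant features get unit
#' scale) before kernel evaluation, and the same scaling is stored in
#' the model and applied at prediction time. `gamma` defaults to
#' `1 / n_features` on the standardized scale — i.e. one over the
#' number of features times the (unit) feature variance.
#'
#' @param features a numeric matrix / data frame with one row per
#'   sample and named columns, or a list of identically named numeric
#'   vectors (e.g. from [extract_features()]).
#' @param labels a vector with exactly two distinct values (e.g.
#'   `"normal"` / `"abnormal"`); both classes must be present.
#' @param gamma kernel width (> 0); `NULL` for the default above.
#' @param cost soft-margin regularization constant C (> 0).
#' @return an object of class `tumor_svm` wrapping the fitted
#'   [e1071::svm] model together with the feature schema and scaling.
#' @examples
#' x <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 3), 20))
#' colnames(x) <- c("f1", "f2")
#' fit <- train_svm(x, rep(c("normal", "abnormal"), each = 20))
#' predict(fit, x[1:3, ])
#' @export
train_svm <- function(features, labels, gamma = NULL, cost = 1) {
  x <- as_feature_matrix(features)
  if (length(labels) != nrow(x)) {
    stop("one label per feature row is required", call. = FALSE)
  }
  y <- factor(labels)
  if (nlevels(y) != 2L) {
    stop("exactly two classes, both present, are required (got ",
         nlevels(y), ")", call. = FALSE)
  }
  if (!all(is.finite(x))) stop("non-finite feature values", call. = FALSE)
  center <- colMeans(x)
  scale_ <- apply(x, 2, stats::sd)
  scale_[scale_ == 0 | !is.finite(scale_)] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale_, "/")
  if (is.null(gamma)) gamma <- 1 / ncol(xs)
  stopifnot(gamma > 0, cost > 0)
  fit <- e1071::svm(xs, y, kernel = "radial", gamma = gamma, cost = cost,
                    scale = FALSE)
  structure(list(fit = fit, feature_names = colnames(x),
                 center = center, scale = scale_,
                 gamma = gamma, cost = cost, classes = levels(y)),
            class = "tumor_svm")
}

as_feature_matrix <- function(features) {
  if (is.list(features) && !is.data.frame(features)) {
    schema <- names(features[[1]])
    for (fv in features) {
      if (!identical(names(fv), schema)) {
        stop("feature vectors have inconsistent names", call. = FALSE)
      }
    }
    features <- do.call(rbind, lapply(features, as.numeric))
    colnames(features) <- schema
  }
  x <- as.matrix(features)
  if (is.null(colnames(x))) {
    stop("features must have column names (a schema)", call. = FALSE)
  }
  storage.mode(x) <- "double"
  x
}

#' @export
print.tumor_svm <- function(x, ...) {
  cat(sprintf(paste0("<tumor_svm> RBF kernel, gamma %.4g, cost %.3g, ",
                     "%d support vectors, classes %s\n"),
              x$gamma, x$cost, x$fit$tot.nSV,
              paste(x$classes, collapse = "/")))
  invisible(x)
}

#' Predict slice labels from texture features
#'
#' Columns are matched to the training schema by name (any order); a
#' missing or extra feature is an error. The decision value is the
#' signed distance-like score of the SVM decision function; its sign
#' determines the label.
#'
#' @param object a [train_svm()] model.
#' @param features as in [train_svm()]; a single named vector is also
#'   accepted.
#' @param ... unused.
#' @return a data frame with one row per sample: `label` and
#'   `decision_value`.
#' @export
predict.tumor_svm <- function(object, features, ...) {
  if (is.numeric(features) && !is.matrix(features) &&
      !is.null(names(features))) {
    features <- matrix(features, 1, dimnames = list(NULL, names(features)))
  }
  x <- as_feature_matrix(features)
  if (!setequal(colnames(x), object$feature_names)) {
    stop("feature schema mismatch: expected {",
         paste(object$feature_names, collapse = ", "), "}", call. = FALSE)
  }
  x <- x[, object$feature_names, drop = FALSE]
  xs <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  pr <- stats::predict(object$fit, xs, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  # libsvm orients the decision sign by the first label it encounters in
  # the training data; re-orient so positive always favors the first
  # factor level (e.g. "abnormal" before "normal"), making the value a
  # stable, model-independent score
  favored <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
  sign_fix <- if (identical(favored, object$classes[1])) 1 else -1
  data.frame(label = as.character(pr),
             decision_value = sign_fix * as.numeric(dv),
             stringsAsFactors = FALSE)
}

#' Texture features of one slice through the full pipeline
#'
#' Runs contrast enhancement, skull stripping, optional BWT denoising
#' and feature extraction over the resulting brain region — the
#' per-slice computation behind [evaluate_pipeline()].
#'
#' @inheritParams strip_skull
#' @param gain,cutoff sigmoid enhancement parameters
#'   ([enhance_contrast()]).
#' @param use_bwt denoise the stripped slice with [bwt_denoise()]
#'   before feature extraction.
#' @param bwt_levels,keep_fraction passed to [bwt_denoise()].
#' @param glcm_levels GLCM quantization levels.
#' @return a named numeric feature vector (see [extract_features()]).
#' @export
slice_features <- function(img, threshold = 128, gain = 10, cutoff = 0.5,
                           use_bwt = TRUE, bwt_levels = 2,
                           keep_fraction = 0.2, glcm_levels = 8) {
  enh <- enhance_contrast(img, gain = gain, cutoff = cutoff)
  st <- strip_skull(enh, threshold = threshold)
  work <- st$image
  if (use_bwt) work <- bwt_denoise(work, levels = bwt_levels,
                                   keep_fraction = keep_fraction)
  extract_features(work, st$mask, levels = glcm_levels)
}

#' End-to-end evaluation on a labeled phantom cohort
#'
#' Computes pipeline features for every slice, makes a stratified
#' seeded train/test split, trains the Gaussian-kernel SVM on the
#' training slices and scores the held-out slices. Abnormal is the
#' positive class.
#'
#' @param dataset a list of `phantom_truth` objects (see
#'   [make_dataset()]), containing both classes.
#' @param train_fraction fraction of each class used for training.
#' @param seed seed for the stratified split.
#' @param gamma,cost passed to [train_svm()].
#' @param ... passed to [slice_features()].
#' @return a list with `confusion` (a [confusion_matrix()]), `metrics`
#'   (accuracy/sensitivity/specificity in percent), `model`,
#'   `predictions` (per test slice: truth, label, decision value) and
#'   `test_idx`.
#' @export
evaluate_pipeline <- function(dataset, train_fraction = 2 / 3, seed = 1L,
                              gamma = NULL, cost = 1, ...) {
  stopifnot(length(dataset) >= 4L, train_fraction > 0, train_fraction < 1)
  labels <- vapply(dataset, function(p) p$label, character(1))
  if (length(unique(labels)) != 2L) {
    stop("dataset must contain both normal and abnormal slices",
         call. = FALSE)
  }
  feats <- lapply(dataset, function(p) slice_features(p$image, ...))
  train_idx <- with_seed(seed, {
    unlist(lapply(split(seq_along(labels), labels), function(idx) {
      sample(idx, max(1L, round(train_fraction * length(idx))))
    }), use.names = FALSE)
  })
  test_idx <- setdiff(seq_along(labels), train_idx)
  if (length(test_idx) == 0L || length(unique(labels[train_idx])) != 2L) {
    stop("split left an empty test set or a one-class training set",
         call. = FALSE)
  }
  model <- train_svm(feats[train_idx], labels[train_idx],
                     gamma = gamma, cost = cost)
  pred <- predict(model, feats[test_idx])
  truth <- labels[test_idx]
  cm <- confusion_matrix(
    tp = sum(truth == "abnormal" & pred$label == "abnormal"),
    tn = sum(truth == "normal"   & pred$label == "normal"),
    fp = sum(truth == "normal"   & pred$label == "abnormal"),
    fn = sum(truth == "abnormal" & pred$label == "normal"))
  list(confusion = cm,
       metrics = classification_metrics(cm),
       model = model,
       predictions = data.frame(truth = truth, pred,
                                stringsAsFactors = FALSE),
       test_idx = test_idx)
}
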