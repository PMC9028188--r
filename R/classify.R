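#' Train/test splitting of instances or feature tables
#'
#' Block mode (the default) partitions by contiguous time blocks within each
#' recording: the final `test_fraction` of each recording's instances (in
#' start-time order) forms the test set, so overlapping windows never
#' straddle the two partitions. Random mode samples instances uniformly.
#' Errors if any class is missing from either partition.
#'
#' @param x A `gait_instances` tibble or feature table with a `label` column.
#' @param test_fraction Fraction assigned to the test set.
#' @param mode `"block"` or `"random"`.
#' @param seed Integer seed (random mode).
#' @return A list with elements `train`, `test` and `test_fraction_achieved`.
#' @export
split_instances <- function(x, test_fraction = 0.2,
                            mode = c("block", "random"), seed = 1L) {
  mode <- match.arg(mode)
  if (test_fraction <= 0 || test_fraction >= 1) {
    stopf("`test_fraction` must lie in (0, 1)")
  }
  n <- nrow(x)
  if (n < 5) stopf("too few instances (%d) to split", n)
  if (length(unique(as.character(x$label))) < 2) {
    stopf("need at least 2 classes to split for classification")
  }

  if (mode == "block") {
    grp <- if ("recording_id" %in% names(x)) x$recording_id else rep("all", n)
    ord <- if ("start_time" %in% names(x)) {
      order(grp, x$start_time)
    } else {
      order(grp)
    }
    is_test <- logical(n)
    for (g in unique(grp)) {
      rows <- ord[grp[ord] == g]
      k <- round(length(rows) * test_fraction)
      if (k > 0) is_test[tail(rows, k)] <- TRUE
    }
  } else {
    is_test <- logical(n)
    idx <- with_seed_(seed, sample.int(n, round(n * test_fraction)))
    is_test[idx] <- TRUE
  }

  train <- x[!is_test, , drop = FALSE]
  test <- x[is_test, , drop = FALSE]
  missing_train <- setdiff(unique(as.character(x$label)),
                           unique(as.character(train$label)))
  missing_test <- setdiff(unique(as.character(x$label)),
                          unique(as.character(test$label)))
  if (length(missing_train) || length(missing_test)) {
    stopf(paste0("class '%s' absent from the %s partition; ",
                 "try mode = 'random' or more data"),
          c(missing_train, missing_test)[1],
          if (length(missing_train)) "train" else "test")
  }
  for (a in c("window_length", "stride", "channels", "sensor_rate",
              "feature_names")) {
    attr(train, a) <- attr(x, a)
    attr(test, a) <- attr(x, a)
  }
  list(train = train, test = test,
       test_fraction_achieved = nrow(test) / n)
}

#' Deterministic CART decision tree
#'
#' Gini-impurity classification tree on a numeric feature matrix, grown
#' depth-first with deterministic tie-breaking (lowest feature index, then
#' lowest threshold), used as the base learner of the time series forest.
#'
#' @param x Numeric feature matrix (rows = instances).
#' @param y Factor of class labels.
#' @param minsplit Minimum node size eligible for splitting.
#' @param minbucket Minimum samples in a leaf.
#' @param maxdepth Maximum tree depth.
#' @return A `gait_cart` object.
#' @export
fit_decision_tree <- function(x, y, minsplit = 10, minbucket = 3,
                              maxdepth = 20) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stopf("feature matrix must be numeric")
  if (any(!is.finite(x))) stopf("feature matrix contains non-finite values")
  y <- factor(y)
  tree <- .cart_grow(x, as.integer(y) - 1L, nlevels(y),
                     as.integer(minsplit), as.integer(minbucket),
                     as.integer(maxdepth))
  structure(list(tree = tree, levels = levels(y), p = ncol(x)),
            class = "gait_cart")
}

#' @param object A `gait_cart` model.
#' @param newdata Numeric matrix with the same columns as training.
#' @param ... Unused.
#' @rdname fit_decision_tree
#' @export
predict.gait_cart <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$p) {
    stopf("newdata has %d columns; model expects %d", ncol(newdata), object$p)
  }
  factor(object$levels[.cart_predict(object$tree, newdata) + 1L],
         levels = object$levels)
}

#' Time series forest configuration
#'
#' @param n_trees Number of trees.
#' @param n_intervals Random intervals per tree; default
#'   `ceiling(sqrt(window_length)) * 3`.
#' @param min_interval_length Minimum interval length in samples.
#' @param bootstrap Resample instances with replacement per tree.
#' @param rng_seed Integer seed.
#' @return A `tsf_config` list.
#' @export
tsf_config <- function(n_trees = 200, n_intervals = NULL,
                       min_interval_length = 3, bootstrap = TRUE,
                       rng_seed = 1L) {
  if (n_trees < 1) stopf("`n_trees` must be >= 1")
  if (min_interval_length < 2) stopf("`min_interval_length` must be >= 2")
  structure(list(n_trees = as.integer(n_trees), n_intervals = n_intervals,
                 min_interval_length = as.integer(min_interval_length),
                 bootstrap = isTRUE(bootstrap),
                 rng_seed = as.integer(rng_seed)),
            class = "tsf_config")
}

# (mean, sd, slope) of interval [s, e] for every channel; X is the stacked
# n x (w*c) instance matrix with channel-major blocks
interval_features <- function(X, w, n_channels, s, e) {
  len <- e - s + 1
  tt <- seq_len(len) - (len + 1) / 2
  stt <- sum(tt^2)
  out <- matrix(0, nrow(X), 3 * n_channels)
  for (ch in seq_len(n_channels)) {
    block <- X[, (ch - 1) * w + (s:e), drop = FALSE]
    m <- rowMeans(block)
    ss <- rowSums(block^2) - len * m^2
    ss[ss < 0] <- 0
    sdv <- if (len > 1) sqrt(ss / (len - 1)) else rep(0, nrow(X))
    slope <- as.numeric(block %*% tt) / stt
    out[, (ch - 1) * 3 + 1:3] <- cbind(m, sdv, slope)
  }
  out
}

#' Train a time series forest
#'
#' A tree ensemble for fixed-length multichannel windows: each tree draws a
#' bootstrap resample of the instances (sub-sample size equal to the input
#' size, drawn with replacement) and a fresh set of random intervals, maps
#' every instance to the concatenation over intervals and channels of the
#' interval mean, standard deviation and least-squares slope, and fits one
#' deterministic CART on that transform. Prediction is the majority vote over
#' trees, ties broken by the class order of first occurrence in training.
#'
#' @param train A `gait_instances` tibble.
#' @param config A [tsf_config()].
#' @return A `gait_tsf` model.
#' @export
fit_tsf <- function(train, config = tsf_config()) {
  im <- instances_matrix(train)
  w <- im$w
  nch <- length(im$channels)
  if (w < config$min_interval_length) {
    stopf("window length (%d) is shorter than min_interval_length (%d)",
          w, config$min_interval_length)
  }
  n_int <- config$n_intervals %||% (ceiling(sqrt(w)) * 3)
  y <- factor(train$label)
  y <- droplevels(y)
  class_order <- unique(as.character(train$label))

  trees <- with_seed_(config$rng_seed, {
    lapply(seq_len(config$n_trees), function(b) {
      idx <- if (config$bootstrap) {
        sample.int(nrow(im$X), nrow(im$X), replace = TRUE)
      } else {
        seq_len(nrow(im$X))
      }
      starts <- sample.int(w - config$min_interval_length + 1, n_int,
                           replace = TRUE)
      lens <- vapply(starts, function(s) {
        sample.int(w - s - config$min_interval_length + 2, 1) +
          config$min_interval_length - 1L
      }, integer(1))
      ends <- starts + lens - 1L
      Xb <- im$X[idx, , drop = FALSE]
      feats <- .tsf_transform(Xb, w, nch, starts, ends)
      list(cart = fit_decision_tree(feats, y[idx]),
           starts = starts, ends = ends)
    })
  })

  structure(list(trees = trees, window_length = w, channels = im$channels,
                 class_order = class_order, levels = levels(y),
                 config = config),
            class = "gait_tsf")
}

#' @param object A `gait_tsf` model.
#' @param newdata A `gait_instances` tibble.
#' @param ... Unused.
#' @rdname fit_tsf
#' @export
predict.gait_tsf <- function(object, newdata, ...) {
  im <- instances_matrix(newdata)
  if (im$w != object$window_length) {
    stopf("window length mismatch: model %d, newdata %d",
          object$window_length, im$w)
  }
  nch <- length(object$channels)
  votes <- matrix(0L, nrow(im$X), length(object$levels))
  colnames(votes) <- object$levels
  for (tr in object$trees) {
    feats <- .tsf_transform(im$X, im$w, nch, as.integer(tr$starts),
                            as.integer(tr$ends))
    pred <- predict(tr$cart, feats)
    votes[cbind(seq_len(nrow(votes)), as.integer(pred))] <-
      votes[cbind(seq_len(nrow(votes)), as.integer(pred))] + 1L
  }
  # majority vote; ties broken by class order of first occurrence in training
  pref <- match(object$class_order, object$levels)
  pick <- apply(votes[, pref, drop = FALSE], 1, which.max)
  factor(object$class_order[pick], levels = object$levels)
}

#' Train a random forest on a feature table
#'
#' Delegates to the `ranger` implementation with the conventional defaults
#' (500 trees, sqrt(p) candidate features per split), seeded for
#' reproducibility.
#'
#' @param train A `gait_features` table (`label` + numeric features).
#' @param seed Integer seed.
#' @param num_trees Number of trees.
#' @return A `gait_rf` model.
#' @export
fit_random_forest <- function(train, seed = 1L, num_trees = 500) {
  feats <- setdiff(names(train), "label")
  X <- as.matrix(train[, feats, drop = FALSE])
  if (any(!is.finite(X))) stopf("feature table contains non-finite values")
  y <- droplevels(factor(train$label))
  fit <- ranger::ranger(
    x = X, y = y, num.trees = num_trees,
    mtry = max(1, floor(sqrt(length(feats)))),
    seed = seed, num.threads = 1, importance = "impurity"
  )
  structure(list(fit = fit, features = feats),
            class = "gait_rf")
}

#' @param object A `gait_rf` model.
#' @param newdata Feature table containing the training feature columns.
#' @param ... Unused.
#' @rdname fit_random_forest
#' @export
predict.gait_rf <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$features, drop = FALSE])
  pred <- predict(object$fit, data = X, num.threads = 1)$predictions
  factor(as.character(pred), levels = levels(pred))
}

#' Evaluate a fitted classifier on a test set
#'
#' Builds the count confusion matrix (rows = true labels, columns =
#' predictions), per-class precision (true positives over all positive
#' predictions, by column), overall accuracy (trace over total) and
#' macro-averaged precision. Classes never predicted have undefined (`NA`)
#' precision, flagged rather than counted as zero.
#'
#' @param model A `gait_rf`, `gait_tsf` or `gait_cart` model.
#' @param test Test instances (`gait_instances` for TSF/CART) or feature
#'   table (for RF), with a `label` column.
#' @return A `gait_eval` object.
#' @export
evaluate_model <- function(model, test) {
  if (nrow(test) == 0) stopf("test set is empty")
  pred <- predict(model, test)
  truth <- as.character(test$label)
  classes <- union(levels(pred), unique(truth))
  present <- classes[classes %in% c(truth, as.character(pred))]
  confusion <- table(truth = factor(truth, present),
                     predicted = factor(as.character(pred), present))
  tp <- diag(confusion)
  pred_n <- colSums(confusion)
  precision <- ifelse(pred_n > 0, tp / pred_n, NA_real_)
  out <- list(
    confusion = confusion,
    confusion_rownorm = sweep(confusion, 1, pmax(1, rowSums(confusion)), "/"),
    per_class = tibble::tibble(
      class = present,
      precision = as.numeric(precision),
      support = as.integer(rowSums(confusion)),
      defined = pred_n > 0
    ),
    accuracy = sum(tp) / sum(confusion),
    macro_precision = mean(precision, na.rm = TRUE),
    n = length(truth)
  )
  class(out) <- "gait_eval"
  out
}

#' @export
print.gait_eval <- function(x, ...) {
  cat(sprintf("<gait_eval> accuracy %.3f, macro precision %.3f (n = %d)\n",
              x$accuracy, x$macro_precision, x$n))
  print(x$confusion)
  invisible(x)
}

#' @export
tidy.gait_eval <- function(x, ...) x$per_class

#' @export
glance.gait_eval <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, macro_precision = x$macro_precision,
                 n = x$n)
}

#' @export
tidy.gait_rf <- function(x, ...) {
  imp <- x$fit$variable.importance
  tibble::tibble(feature = names(imp), importance = as.numeric(imp)) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' @export
glance.gait_rf <- function(x, ...) {
  tibble::tibble(num_trees = x$fit$num.trees, mtry = x$fit$mtry,
                 oob_error = x$fit$prediction.error,
                 n_features = length(x$features))
}

#' @export
tidy.gait_tsf <- function(x, ...) {
  purrr::map_dfr(seq_along(x$trees), function(i) {
    tibble::tibble(tree = i, interval_start = x$trees[[i]]$starts,
                   interval_end = x$trees[[i]]$ends)
  })
}

#' @export
glance.gait_tsf <- function(x, ...) {
  tibble::tibble(n_trees = length(x$trees),
                 n_intervals = length(x$trees[[1]]$starts),
                 window_length = x$window_length,
                 n_channels = length(x$channels))
}
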