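with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

esec_labels <- function(xs) {
  vapply(xs, function(e) {
    if (is.null(e$action_label)) NA_character_ else e$action_label
  }, character(1))
}

#' Mean class similarity per prefix column
#'
#' For each column index `j` up to the test matrix length, the test eSEC
#' truncated to its first `j` columns is compared against every training
#' eSEC truncated (or last-column padded) to `j` columns; similarities are
#' averaged per action class.
#'
#' @param test An `esec_matrix`.
#' @param training List of labelled `esec_matrix` objects.
#' @return Numeric matrix `n_columns(test) x n_classes`.
#' @export
prefix_class_similarity <- function(test, training) {
  labels <- esec_labels(training)
  if (anyNA(labels)) stop("domain error: unlabelled training eSEC")
  classes <- sort(unique(labels))
  tm <- esec_mat(test)
  jmax <- ncol(tm)
  out <- matrix(NA_real_, jmax, length(classes),
                dimnames = list(NULL, classes))
  for (j in seq_len(jmax)) {
    tp <- tm[, seq_len(j), drop = FALSE]
    sims <- vapply(training,
                   function(tr) esec_similarity(tp, pad_cols(esec_mat(tr), j)),
                   numeric(1))
    out[j, ] <- vapply(classes, function(cl) mean(sims[labels == cl]),
                       numeric(1))
  }
  out
}

#' Progressive classification of an eSEC matrix
#'
#' Scans the eSEC column by column and declares a prediction at the earliest
#' column where a single class's mean prefix similarity is the unique
#' maximum, leads the runner-up by at least `margin` (a fraction of the
#' 0-100 similarity scale), and remains the unique maximum through every
#' later column. If no column satisfies this, the argmax at the final column
#' is returned with the final column as prediction column.
#'
#' @param test An `esec_matrix`.
#' @param training List of labelled `esec_matrix` objects covering at least
#'   two classes (a single class is predicted trivially at column 1).
#' @param margin Required similarity lead as a fraction (0 = any strict lead).
#' @return An `esec_prediction`: list with `label`, `prediction_column`,
#'   `class_similarity` (per-column matrix), `correct` (if the test carries
#'   a label), `predictive_power`.
#' @export
classify_progressive <- function(test, training, margin = 0) {
  if (length(training) == 0L) stop("domain error: empty training set")
  sim <- prefix_class_similarity(test, training)
  jmax <- nrow(sim)
  nclass <- ncol(sim)
  pred_col <- jmax
  label <- colnames(sim)[which.max(sim[jmax, ])]
  if (nclass == 1L) {
    pred_col <- 1L
    label <- colnames(sim)
  } else {
    top <- apply(sim, 1, which.max)
    best <- sim[cbind(seq_len(jmax), top)]
    second <- vapply(seq_len(jmax),
                     function(j) max(sim[j, -top[j]]), numeric(1))
    unique_lead <- best > second & (best - second) / 100 >= margin
    # winner must stay the strict argmax through the final column
    stays <- rev(cumprod(rev(best > second &
                               c(top[-1L] == top[-jmax], TRUE)))) > 0
    ok <- which(unique_lead & stays)
    if (length(ok)) {
      pred_col <- ok[1L]
      label <- colnames(sim)[top[pred_col]]
    }
  }
  truth <- test$action_label
  structure(list(label = label, prediction_column = pred_col,
                 class_similarity = sim,
                 correct = if (!is.null(truth)) identical(label, truth),
                 predictive_power = predictive_power(pred_col, jmax)),
            class = "esec_prediction")
}

#' @export
print.esec_prediction <- function(x, ...) {
  cat(sprintf("Predicted '%s' at column %d of %d (predictive power %.1f%%)%s\n",
              x$label, x$prediction_column, nrow(x$class_similarity),
              x$predictive_power,
              if (isTRUE(x$correct)) " [correct]"
              else if (isFALSE(x$correct)) " [wrong]" else ""))
  invisible(x)
}

#' Train/test evaluation of a labelled eSEC dataset
#'
#' Splits the dataset into training and test samples (stratified by action,
#' seeded), classifies every test eSEC progressively, and summarises
#' accuracy and predictive power per action and overall.
#'
#' @param dataset List of labelled `esec_matrix` objects.
#' @param split Fraction of each class used for training.
#' @param seed Integer seed making the split reproducible.
#' @param margin Passed to [classify_progressive()].
#' @return List with `per_action` (data.frame: n_test, accuracy, mean/min/max
#'   predictive power), `overall` (accuracy, mean predictive power), and the
#'   individual `predictions`.
#' @export
evaluate_dataset <- function(dataset, split = 0.5, seed = 1L, margin = 0) {
  labels <- esec_labels(dataset)
  if (anyNA(labels)) stop("domain error: unlabelled eSEC in dataset")
  classes <- sort(unique(labels))
  train_idx <- integer(0)
  with_seed(seed, {
    for (cl in classes) {
      idx <- which(labels == cl)
      n_tr <- max(1L, floor(length(idx) * split))
      if (length(idx) < 2L)
        stop("class '", cl, "' has fewer than 2 scenarios")
      train_idx <- c(train_idx, sample(idx, n_tr))
    }
  })
  test_idx <- setdiff(seq_along(dataset), train_idx)
  training <- dataset[train_idx]
  preds <- lapply(dataset[test_idx], classify_progressive,
                  training = training, margin = margin)
  truth <- labels[test_idx]
  pp <- vapply(preds, `[[`, numeric(1), "predictive_power")
  correct <- vapply(preds, function(p) isTRUE(p$correct), logical(1))
  per_action <- do.call(rbind, lapply(classes, function(cl) {
    i <- truth == cl
    data.frame(action = cl, n_test = sum(i),
               accuracy = mean(correct[i]),
               mean_pp = mean(pp[i]), min_pp = min(pp[i]),
               max_pp = max(pp[i]), stringsAsFactors = FALSE)
  }))
  list(per_action = per_action,
       overall = list(accuracy = mean(correct), mean_pp = mean(pp),
                      n_test = length(test_idx)),
       predictions = preds)
}
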