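# KNN classification of mutations from (rSASA, EC, PD) features.
#
# The classifier is deliberately plain k-nearest-neighbours: Euclidean
# distance in z-scored feature space (standardization fit on the training
# set), majority vote, ties broken by the single nearest neighbour. The
# optional ddg columns are annotations that can be pulled into the
# feature set to reproduce the with/without-ddg comparison.

FEATURES_DEFAULT <- c("rsasa", "ec", "pd")
LABELS <- c("pathogenic", "non_pathogenic", "unknown")

#' Validate a feature table
#'
#' @param x data.frame with `mutation_id`, feature columns, and `label`.
#' @param feature_set feature column names that must be present and finite.
#' @return the validated data.frame (invisibly usable).
#' @export
validate_features <- function(x, feature_set = FEATURES_DEFAULT) {
  need <- c("mutation_id", feature_set, "label")
  miss <- setdiff(need, names(x))
  check_that(length(miss) == 0L, "feature table missing columns: %s",
             paste(miss, collapse = ", "))
  check_that(all(x$label %in% LABELS), "labels must be one of: %s",
             paste(LABELS, collapse = ", "))
  for (f in feature_set) {
    check_that(all(is.finite(x[[f]])), "non-finite values in feature '%s'", f)
  }
  x
}

#' Random train/test partition of the labelled rows
#'
#' Unknown-labelled rows are excluded; the split is disjoint, exhaustive
#' over the labelled rows, and deterministic given the seed.
#'
#' @param dataset feature data.frame.
#' @param train_n number of training rows.
#' @param seed RNG seed.
#' @return list(train =, test =) of data.frames.
#' @export
partition <- function(dataset, train_n, seed) {
  labelled <- dataset[dataset$label != "unknown", , drop = FALSE]
  n <- nrow(labelled)
  check_that(is_count(train_n) && train_n >= 1 && train_n < n,
             "train_n must be in [1, %d)", n)
  idx <- with_seed(seed, sample.int(n, train_n))
  list(train = labelled[idx, , drop = FALSE],
       test = labelled[-idx, , drop = FALSE])
}

#' Fit standardization parameters on the training features
#' @noRd
fit_scaler <- function(train, feature_set) {
  m <- vapply(feature_set, function(f) mean(train[[f]]), numeric(1))
  s <- vapply(feature_set, function(f) stats::sd(train[[f]]), numeric(1))
  s[!is.finite(s) | s == 0] <- 1  # constant feature: leave centred only
  list(center = m, scale = s)
}

apply_scaler <- function(x, feature_set, scaler) {
  sweep(sweep(as.matrix(x[, feature_set, drop = FALSE]), 2, scaler$center),
        2, scaler$scale, "/")
}

#' Classify query rows by k-nearest neighbours
#'
#' Euclidean distance in (optionally z-scored) feature space; majority
#' vote over the k nearest training rows. A tied vote is resolved by the
#' label of the single nearest neighbour, which also makes even k
#' deterministic. Distance ties are broken by training-row order.
#'
#' @param train labelled feature data.frame (no "unknown" rows).
#' @param query feature data.frame of rows to classify.
#' @param k neighbourhood size (<= nrow(train); odd recommended).
#' @param feature_set feature columns used (default rsasa, ec, pd).
#' @param standardize z-score features using training-set parameters
#'   (default TRUE).
#' @return data.frame with `mutation_id`, `predicted`, per-class vote
#'   counts (`votes_pathogenic`, `votes_non_pathogenic`) and `margin`
#'   (winning minus losing votes).
#' @export
knn_predict <- function(train, query, k = 7,
                        feature_set = FEATURES_DEFAULT, standardize = TRUE) {
  validate_features(train, feature_set)
  check_that(!any(train$label == "unknown"), "training rows must be labelled")
  check_that(is_count(k) && k >= 1 && k <= nrow(train),
             "k must be an integer in [1, %d]", nrow(train))
  scaler <- if (standardize) fit_scaler(train, feature_set) else
    list(center = rep(0, length(feature_set)),
         scale = rep(1, length(feature_set)))
  xt <- apply_scaler(train, feature_set, scaler)
  xq <- apply_scaler(query, feature_set, scaler)
  res <- lapply(seq_len(nrow(xq)), function(i) {
    d <- sqrt(colSums((t(xt) - xq[i, ])^2))
    nn <- order(d)[seq_len(k)]  # order() is stable: row-order tie-break
    votes <- table(factor(train$label[nn],
                          levels = c("pathogenic", "non_pathogenic")))
    top <- names(votes)[votes == max(votes)]
    pred <- if (length(top) == 1L) top else train$label[nn[1L]]
    data.frame(predicted = pred,
               votes_pathogenic = as.integer(votes[["pathogenic"]]),
               votes_non_pathogenic = as.integer(votes[["non_pathogenic"]]),
               margin = as.integer(abs(diff(range(votes)))),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  cbind(data.frame(mutation_id = query$mutation_id,
                   stringsAsFactors = FALSE), out)
}

#' Accuracy over a set of k values, with a recommended k
#'
#' Classification accuracy on the test set for every k in `k_values`;
#' the recommended k is the median of the accuracy-maximizing set (for an
#' even-sized set, the upper-middle element, so the recommendation is
#' always one of the tested values).
#'
#' @param train,test labelled feature data.frames.
#' @param k_values integer vector of k values to try.
#' @param feature_set,standardize passed to [knn_predict()].
#' @return list(accuracy = data.frame(k, accuracy), recommended_k =).
#' @export
k_sweep <- function(train, test, k_values = 1:15,
                    feature_set = FEATURES_DEFAULT, standardize = TRUE) {
  k_values <- sort(unique(as.integer(k_values)))
  acc <- vapply(k_values, function(k) {
    pred <- knn_predict(train, test, k, feature_set, standardize)
    mean(pred$predicted == test$label)
  }, numeric(1))
  best <- k_values[acc == max(acc)]
  recommended <- best[ceiling(length(best) / 2)]
  list(accuracy = data.frame(k = k_values, accuracy = acc),
       recommended_k = recommended)
}

#' Classify unknown-effect mutations, report-style
#'
#' Trains on the labelled rows and predicts every unknown row, returning
#' a per-mutation report with vote margins; optional external-predictor
#' annotation columns (e.g. a PolyPhen call) are passed through verbatim
#' for side-by-side comparison.
#'
#' @param labelled feature data.frame of pathogenic / non_pathogenic rows.
#' @param unknowns feature data.frame of rows to classify.
#' @param k neighbourhood size.
#' @param feature_set,standardize passed to [knn_predict()].
#' @param annotation_cols column names of `unknowns` copied into the report.
#' @return report data.frame; zero rows when `unknowns` is empty.
#' @export
classify_unknowns <- function(labelled, unknowns, k = 7,
                              feature_set = FEATURES_DEFAULT,
                              standardize = TRUE,
                              annotation_cols = character(0)) {
  if (nrow(unknowns) == 0L) {
    return(data.frame(mutation_id = character(0), predicted = character(0),
                      votes_pathogenic = integer(0),
                      votes_non_pathogenic = integer(0),
                      margin = integer(0), stringsAsFactors = FALSE))
  }
  rep_df <- knn_predict(labelled, unknowns, k, feature_set, standardize)
  for (col in annotation_cols) {
    check_that(col %in% names(unknowns),
               "annotation column '%s' absent from unknowns", col)
    rep_df[[col]] <- unknowns[[col]]
  }
  rep_df
}
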