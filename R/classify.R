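#' Train the multiclass behavior SVM
#'
#' Fits a one-vs-one multiclass support vector machine (RBF kernel,
#' pairwise-coupled probability calibration) on the 25 burst predictors of
#' labeled calibration bursts. Predictors are z-scored by training mean/sd;
#' the standardization parameters travel with the model.
#'
#' @param features feature table from [featurize()] (or any table carrying
#'   the 25 predictor columns of [predictor_names()]), without missing
#'   predictor values.
#' @param labels character/factor of true behavior classes, one per row.
#' @param tau default probability gate stored with the model (see
#'   [predict_gated()]).
#' @param cost,gamma SVM hyperparameters; library defaults when `NULL`.
#' @param seed RNG seed for the probability-calibration cross-validation.
#' @return object of class `behavior_model`.
#' @seealso [predict_gated()], [loocv()]
#' @export
train_behavior_model <- function(features, labels, tau = 0.7,
                                 cost = 1, gamma = NULL, seed = 1L) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) {
    stop("training requires at least two behavior classes", call. = FALSE)
  }
  X <- as.matrix(features[, .predictor_cols])
  if (anyNA(X)) {
    stop("training features contain missing predictor values", call. = FALSE)
  }
  stopifnot(nrow(X) == length(labels))
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[scale == 0] <- 1
  Z <- sweep(sweep(X, 2, center), 2, scale, "/")
  if (is.null(gamma)) gamma <- 1 / ncol(Z)
  if (!is.null(seed)) set.seed(seed)
  fit <- e1071::svm(Z, factor(labels), kernel = "radial", cost = cost,
                    gamma = gamma, probability = TRUE, scale = FALSE)
  structure(
    list(svm = fit, center = center, scale = scale,
         classes = sort(unique(labels)), tau = tau,
         predictors = .predictor_cols),
    class = "behavior_model"
  )
}

#' @export
print.behavior_model <- function(x, ...) {
  cat("behavior_model: RBF SVM over", length(x$predictors), "predictors;",
      "classes:", paste(x$classes, collapse = ", "),
      sprintf("; probability gate tau = %g\n", x$tau))
  invisible(x)
}

#' Gate a class-probability matrix
#'
#' The prediction is the highest-probability class when that probability
#' strictly exceeds `tau`; otherwise the burst is assigned to `"other"`
#' (behaviors absent from the training set).
#'
#' @param probs numeric matrix, rows summing to 1, with class column names.
#' @param tau probability threshold (default 0.7; comparison is strict, so
#'   a probability of exactly 0.7 yields `"other"`).
#' @return character vector of labels.
#' @examples
#' gate_probabilities(rbind(c(immobile = 0.8, balling = 0.15, locomotion = 0.05)))
#' @export
gate_probabilities <- function(probs, tau = 0.7) {
  probs <- rbind(probs)
  ix <- max.col(probs, ties.method = "first")
  p <- probs[cbind(seq_len(nrow(probs)), ix)]
  ifelse(p > tau, colnames(probs)[ix], "other")
}

#' Predict gated behavior labels
#'
#' Applies a trained [train_behavior_model()] to new bursts. Bursts with
#' missing predictor values are classified `"other"` with a warning.
#'
#' @param model a `behavior_model`.
#' @param features feature table with the 25 predictor columns (extra
#'   columns such as `individual_id`, `timestamp` are carried through).
#' @param tau probability gate; defaults to the model's stored `tau`.
#' @return tibble with carried identifiers plus `label` (one of the model
#'   classes or `"other"`) and `max_prob`.
#' @export
predict_gated <- function(model, features, tau = model$tau) {
  stopifnot(inherits(model, "behavior_model"))
  X <- as.matrix(features[, model$predictors])
  ok <- stats::complete.cases(X)
  label <- rep("other", nrow(X))
  max_prob <- rep(NA_real_, nrow(X))
  if (any(!ok)) {
    warning(sprintf("%d burst(s) with missing predictors classified as 'other'",
                    sum(!ok)))
  }
  if (any(ok)) {
    Z <- sweep(sweep(X[ok, , drop = FALSE], 2, model$center), 2,
               model$scale, "/")
    pr <- predict(model$svm, Z, probability = TRUE)
    probs <- attr(pr, "probabilities")
    label[ok] <- gate_probabilities(probs, tau)
    max_prob[ok] <- apply(probs, 1, max)
  }
  meta_cols <- intersect(c("individual_id", "burst_id", "timestamp"),
                         names(features))
  out <- tibble::as_tibble(features[, meta_cols, drop = FALSE])
  out$label <- label
  out$max_prob <- max_prob
  out
}

#' Confusion-matrix evaluation of gated predictions
#'
#' @param true true class labels.
#' @param predicted predicted labels (may include `"other"`).
#' @return list of class `evaluation_report`: `confusion` (true x
#'   predicted), per-class `recall` = TP/(TP+FN) and `precision` =
#'   TP/(TP+FP), `other_count` and `other_fraction`.
#' @export
evaluation_report <- function(true, predicted) {
  true <- as.character(true)
  predicted <- as.character(predicted)
  classes <- sort(unique(true))
  lv <- union(classes, "other")
  conf <- table(true = factor(true, levels = classes),
                predicted = factor(predicted, levels = lv))
  recall <- sapply(classes, function(cl) {
    tp <- conf[cl, cl]
    tp / sum(conf[cl, ])
  })
  precision <- sapply(classes, function(cl) {
    tp <- conf[cl, cl]
    fp <- sum(conf[, cl]) - tp
    if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  })
  structure(
    list(confusion = conf, recall = recall, precision = precision,
         other_count = sum(predicted == "other"),
         other_fraction = mean(predicted == "other")),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("per-class recall:   ",
      paste(sprintf("%s %.3f", names(x$recall), x$recall), collapse = "  "), "\n")
  cat("per-class precision:",
      paste(sprintf("%s %.3f", names(x$precision), x$precision), collapse = "  "), "\n")
  cat(sprintf("classified 'other': %d (%.1f%%)\n",
              x$other_count, 100 * x$other_fraction))
  invisible(x)
}

#' Leave-one-out cross-validation of the behavior model
#'
#' Each labeled burst is predicted by a model trained on the remaining
#' n - 1 bursts (per-burst folds). By default the probability gate is
#' applied during evaluation, so bursts below the gate count as `"other"`
#' (a false negative for their true class); `gated = FALSE` evaluates the
#' raw argmax instead.
#'
#' @param features feature table with the 25 predictors.
#' @param labels true classes (n >= 3).
#' @param tau probability gate.
#' @param gated apply the gate during evaluation (default `TRUE`).
#' @param cost,gamma,seed passed to [train_behavior_model()].
#' @return an [evaluation_report()] with an extra element `predicted`.
#' @export
loocv <- function(features, labels, tau = 0.7, gated = TRUE,
                  cost = 1, gamma = NULL, seed = 1L) {
  labels <- as.character(labels)
  n <- length(labels)
  stopifnot(n >= 3, nrow(features) == n)
  predicted <- character(n)
  for (i in seq_len(n)) {
    fit <- train_behavior_model(features[-i, , drop = FALSE], labels[-i],
                                tau = tau, cost = cost, gamma = gamma,
                                seed = seed)
    pr <- predict_gated(fit, features[i, , drop = FALSE],
                        tau = if (gated) tau else -Inf)
    predicted[i] <- pr$label
  }
  rep <- evaluation_report(labels, predicted)
  rep$predicted <- predicted
  rep
}

#' Daily behavior budgets from gated predictions
#'
#' Counts the four behavior labels per individual and calendar day
#' (00:00-23:59 study-local time). Days failing the completeness filter
#' (fewer than `min_bursts` kept bursts) are excluded, so that no day is
#' biased toward behaviors of a particular time of day.
#'
#' @param predictions tibble with `individual_id`, `timestamp`, `label`.
#' @param min_bursts completeness threshold (1430 at the full-size protocol
#'   of 1440 bursts/day).
#' @param tz study-local timezone.
#' @return tibble: `individual_id`, `date`, `n_bursts`, and one count
#'   column per label (`immobile`, `balling`, `locomotion`, `other`).
#' @export
daily_budget <- function(predictions, min_bursts = 1430, tz = .hog_tz) {
  stopifnot(all(c("individual_id", "timestamp", "label") %in% names(predictions)))
  df <- predictions
  df$date <- as.Date(df$timestamp, tz = tz)
  out <- df %>%
    dplyr::count(.data$individual_id, .data$date, .data$label) %>%
    tidyr::pivot_wider(names_from = "label", values_from = "n",
                       values_fill = 0L)
  for (lb in .hog_labels) {
    if (!lb %in% names(out)) out[[lb]] <- 0L
  }
  out$n_bursts <- out$immobile + out$balling + out$locomotion + out$other
  out <- out[out$n_bursts >= min_bursts,
             c("individual_id", "date", "n_bursts", .hog_labels)]
  tibble::as_tibble(out)
}
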