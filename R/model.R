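#' Classifier configuration
#'
#' Bundles the tunable training parameters. The production classifier is a
#' random forest with 1500 trees and unlimited depth; naive Bayes, a CART
#' decision tree, and an RBF-kernel SVM (gamma 0.01, cost 1, scaled inputs)
#' are available behind the same interface for comparison.
#'
#' @param classifier One of `"random_forest"`, `"naive_bayes"`,
#'   `"decision_tree"`, `"svm"`.
#' @param n_trees Number of forest trees (random forest only).
#' @param max_depth Maximum tree depth; `NULL` = unlimited.
#' @param seed Integer seed controlling all training randomness.
#' @param folds Number of cross-validation folds.
#' @param threshold Positive-class probability threshold for the
#'   yes/no call.
#' @param cost_fp,cost_fn Per-error costs used for the cost figure of the
#'   evaluation report.
#' @param pwm_layout `"per_aa"` (default): the PWM value of every amino
#'   acid at each position, as a PWM-scaled one-hot encoding (160
#'   numerics), which preserves residue identity; `"compact"`: only the
#'   observed residue's PWM value per position (8 numerics).
#' @return A `casp_config` list.
#' @export
casp_config <- function(classifier = "random_forest", n_trees = 1500L,
                        max_depth = NULL, seed = 1L, folds = 10L,
                        threshold = 0.5, cost_fp = 1, cost_fn = 1,
                        pwm_layout = c("per_aa", "compact")) {
  classifier <- match.arg(
    classifier, c("random_forest", "naive_bayes", "decision_tree", "svm")
  )
  pwm_layout <- match.arg(pwm_layout)
  if (n_trees < 1L) abort("n_trees must be >= 1")
  if (folds < 2L) abort("folds must be >= 2")
  structure(
    list(
      classifier = classifier, n_trees = as.integer(n_trees),
      max_depth = max_depth, seed = as.integer(seed),
      folds = as.integer(folds), threshold = threshold,
      cost_fp = cost_fp, cost_fn = cost_fn, pwm_layout = pwm_layout
    ),
    class = "casp_config"
  )
}

config_features <- function(windows, pwm, structures, config) {
  encode_windows(
    windows, pwm, structures,
    expand_pwm = identical(config$pwm_layout, "per_aa")
  )
}

fit_classifier <- function(features, y, config) {
  set.seed(config$seed)
  switch(config$classifier,
    random_forest = randomForest::randomForest(
      x = as.data.frame(features), y = y,
      ntree = config$n_trees,
      maxnodes = if (is.null(config$max_depth)) NULL else 2L^config$max_depth
    ),
    naive_bayes = e1071::naiveBayes(as.data.frame(features), y),
    decision_tree = rpart::rpart(
      y ~ .,
      data = cbind(as.data.frame(features), y = y), method = "class"
    ),
    svm = {
      x <- model.matrix(~ . - 1, data = as.data.frame(features))
      e1071::svm(
        x = x, y = y,
        kernel = "radial", gamma = 0.01, cost = 1,
        scale = apply(x, 2L, stats::var) > 0, # constant one-hots unscalable
        probability = TRUE
      )
    }
  )
}

score_classifier <- function(fit, features, config) {
  df <- as.data.frame(features)
  switch(config$classifier,
    random_forest = unname(predict(fit, df, type = "prob")[, "positive"]),
    naive_bayes = unname(predict(fit, df, type = "raw")[, "positive"]),
    decision_tree = unname(predict(fit, df, type = "prob")[, "positive"]),
    svm = {
      p <- predict(fit, model.matrix(~ . - 1, data = df), probability = TRUE)
      unname(attr(p, "probabilities")[, "positive"])
    }
  )
}

#' Train a cleavage-site classifier
#'
#' Encodes every training window as PWM + structure features and fits the
#' configured classifier. The returned model stores the PWM, the structure
#' source and the configuration, so scoring is fully self-contained and
#' reproducible.
#'
#' @param ts Training-set tibble ([build_training_set()]): must contain both
#'   classes in its `label` column.
#' @param pwm A `casp_pwm` computed from the positive windows.
#' @param structures Structure tibble covering the training proteins, or
#'   `NULL` for all-default labels.
#' @param config A [casp_config()].
#' @return A `casp_model` object.
#' @export
casp_train <- function(ts, pwm, structures = NULL, config = casp_config()) {
  stopifnot(inherits(pwm, "casp_pwm"))
  if (length(unique(ts$label)) < 2L) {
    abort("Training set must contain both positive and negative windows")
  }
  features <- config_features(ts, pwm, structures, config)
  y <- factor(ts$label, levels = c("negative", "positive"))
  fit <- fit_classifier(features, y, config)
  structure(
    list(
      fit = fit,
      pwm = pwm,
      config = config,
      feature_names = names(features),
      class_counts = table(y),
      version = as.character(packageVersion("caspcleave"))
    ),
    class = "casp_model"
  )
}

#' @export
print.casp_model <- function(x, ...) {
  cat(
    "Caspase cleavage-site model (", x$config$classifier, ")\n",
    "  training windows: ",
    paste(names(x$class_counts), as.integer(x$class_counts),
      sep = "=", collapse = ", "
    ), "\n",
    "  PWM from ", x$pwm$n_sequences, " positive windows\n",
    sep = ""
  )
  invisible(x)
}

#' Glance at a trained model
#'
#' @param x A `casp_model`.
#' @param ... Unused.
#' @return One-row tibble of model metadata.
#' @export
glance.casp_model <- function(x, ...) {
  tibble(
    classifier = x$config$classifier,
    n_trees = x$config$n_trees,
    n_positive = as.integer(x$class_counts[["positive"]]),
    n_negative = as.integer(x$class_counts[["negative"]]),
    pwm_windows = x$pwm$n_sequences,
    threshold = x$config$threshold
  )
}

#' Score cleavage windows with a trained model
#'
#' @param model A `casp_model`.
#' @param windows Window tibble (`protein_id`, `p1_position`, `window`).
#' @param structures Structure tibble covering the windows' proteins, or
#'   `NULL` for default labels.
#' @return Numeric vector of positive-class probabilities in [0, 1].
#' @export
casp_score <- function(model, windows, structures = NULL) {
  features <- config_features(windows, model$pwm, structures, model$config)
  score_classifier(model$fit, features, model$config)
}

#' Confusion-matrix evaluation metrics
#'
#' Computes the standard quality measures of a binary cleavage classifier
#' from its confusion counts: accuracy, precision and specificity (as
#' percentages), Matthews correlation coefficient, Cohen's kappa, a linear
#' misclassification cost `cost_fp * fp + cost_fn * fn`, and - when paired
#' scores are supplied - the area under the ROC curve. A metric whose
#' denominator is empty (e.g. precision with no positive calls) is reported
#' as `NA`, not 0.
#'
#' @param tp,fn,fp,tn Confusion counts (true/false positives/negatives).
#' @param scores Optional tibble with columns `score` and `label`
#'   (`"positive"`/`"negative"`) for the AUC.
#' @param cost_fp,cost_fn Per-error costs.
#' @return A `casp_eval` object; see [glance.casp_eval()].
#' @examples
#' glance(compute_metrics(191, 6, 5, 788))
#' @export
compute_metrics <- function(tp, fn, fp, tn, scores = NULL,
                            cost_fp = 1, cost_fn = 1) {
  counts <- c(tp, fn, fp, tn)
  if (any(counts < 0) || sum(counts) == 0) {
    abort("Confusion counts must be nonnegative and not all zero")
  }
  total <- tp + fn + fp + tn
  acc <- (tp + tn) / total * 100
  prc <- if (tp + fp > 0) tp / (tp + fp) * 100 else NA_real_
  spc <- if (tn + fp > 0) tn / (tn + fp) * 100 else NA_real_
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den > 0) (tp * tn - fp * fn) / mcc_den else NA_real_
  po <- (tp + tn) / total
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / total^2
  kappa <- if (pe < 1) (po - pe) / (1 - pe) else NA_real_
  auc <- NULL
  if (!is.null(scores)) {
    stopifnot(all(c("score", "label") %in% names(scores)))
    resp <- factor(scores$label, levels = c("negative", "positive"))
    if (nlevels(droplevels(resp)) == 2L) {
      auc <- as.numeric(pROC::auc(pROC::roc(
        response = resp, predictor = scores$score,
        levels = c("negative", "positive"), direction = "<", quiet = TRUE
      )))
    }
  }
  structure(
    list(
      tp = tp, fn = fn, fp = fp, tn = tn,
      kappa = kappa, auc = auc %||% NA_real_,
      acc_percent = acc, prc_percent = prc, spc_percent = spc, mcc = mcc,
      cost = cost_fp * fp + cost_fn * fn,
      scores = scores
    ),
    class = "casp_eval"
  )
}

#' @export
print.casp_eval <- function(x, ...) {
  cat("Cleavage classifier evaluation\n")
  cat(sprintf(
    "  TP %d  FN %d  FP %d  TN %d\n", x$tp, x$fn, x$fp, x$tn
  ))
  cat(sprintf(
    "  ACC %.2f%%  PRC %.1f%%  SPC %.1f%%  MCC %.3f  kappa %.3f  AUC %s  cost %.1f\n",
    x$acc_percent, x$prc_percent, x$spc_percent, x$mcc, x$kappa,
    ifelse(is.na(x$auc), "-", sprintf("%.3f", x$auc)), x$cost
  ))
  invisible(x)
}

#' Tidy / glance methods for evaluation reports
#'
#' `glance()` returns the report as a one-row tibble mirroring the usual
#' summary-table layout (TP, FN, FP, TN, kappa, AUC, cost, ACC, PRC, SPC,
#' MCC); `tidy()` returns the long (metric, value) form.
#'
#' @param x A `casp_eval` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
glance.casp_eval <- function(x, ...) {
  tibble(
    tp = x$tp, fn = x$fn, fp = x$fp, tn = x$tn,
    kappa = x$kappa, auc = x$auc, cost = x$cost,
    acc_percent = x$acc_percent, prc_percent = x$prc_percent,
    spc_percent = x$spc_percent, mcc = x$mcc
  )
}

#' @rdname glance.casp_eval
#' @export
tidy.casp_eval <- function(x, ...) {
  tidyr::pivot_longer(
    glance(x),
    cols = dplyr::everything(),
    names_to = "metric", values_to = "value"
  )
}

#' ROC curve of an evaluation report
#'
#' @param object A `casp_eval` carrying pooled scores.
#' @param ... Unused.
#' @return A ggplot ROC curve.
#' @export
autoplot.casp_eval <- function(object, ...) {
  if (is.null(object$scores)) {
    abort("This evaluation report carries no scores; no ROC to plot")
  }
  sc <- arrange(object$scores, desc(.data$score))
  n_pos <- sum(sc$label == "positive")
  n_neg <- sum(sc$label == "negative")
  df <- tibble(
    fpr = cumsum(sc$label == "negative") / n_neg,
    tpr = cumsum(sc$label == "positive") / n_pos
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::labs(
      x = "False-positive rate", y = "True-positive rate",
      subtitle = sprintf("AUC = %.3f", object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' Evaluate a model on labelled windows
#'
#' Scores the windows, thresholds the probabilities, and assembles the full
#' evaluation report (confusion counts, rates, kappa, MCC, AUC, cost).
#'
#' @param model A `casp_model`.
#' @param ts Labelled window tibble.
#' @param structures Structure tibble or `NULL`.
#' @return A `casp_eval`.
#' @export
casp_evaluate <- function(model, ts, structures = NULL) {
  score <- casp_score(model, ts, structures)
  eval_from_scores(
    tibble(score = score, label = ts$label),
    model$config
  )
}

eval_from_scores <- function(scores, config) {
  pred_pos <- scores$score >= config$threshold
  is_pos <- scores$label == "positive"
  compute_metrics(
    tp = sum(pred_pos & is_pos), fn = sum(!pred_pos & is_pos),
    fp = sum(pred_pos & !is_pos), tn = sum(!pred_pos & !is_pos),
    scores = scores, cost_fp = config$cost_fp, cost_fn = config$cost_fn
  )
}

#' Stratified k-fold cross-validation
#'
#' Splits the training set into `config$folds` class-stratified folds
#' (seeded from `config$seed`), trains on each complement, scores the held
#' out fold, pools the out-of-fold scores, and reports confusion counts at
#' the classification threshold plus AUC over the pooled scores.
#'
#' By default the supplied PWM (usually computed from all positives) is
#' used for every fold, matching the published procedure of encoding the
#' records once before cross-validation. That leaks a little information
#' from held-out positives into the features; `refit_pwm = TRUE` instead
#' recomputes the PWM inside each fold from the fold's training positives
#' only, which is the leak-free variant appropriate for calibration
#' studies (e.g. checking that a null dataset yields AUC near 0.5).
#'
#' @inheritParams casp_train
#' @param refit_pwm Recompute the PWM per fold from training-fold
#'   positives (default `FALSE`: use `pwm` as given for all folds)?
#' @return A `casp_eval` whose `scores` element holds the pooled
#'   out-of-fold (score, label) pairs.
#' @export
cross_validate <- function(ts, pwm, structures = NULL,
                           config = casp_config(), refit_pwm = FALSE) {
  counts <- table(ts$label)
  if (any(counts < config$folds)) {
    abort("Each class must have at least as many windows as folds")
  }
  features <- config_features(ts, pwm, structures, config)
  y <- factor(ts$label, levels = c("negative", "positive"))
  set.seed(config$seed)
  fold <- integer(nrow(ts))
  for (cls in levels(y)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep_len(seq_len(config$folds), length(idx)))
  }
  oof <- numeric(nrow(ts))
  for (k in seq_len(config$folds)) {
    hold <- fold == k
    feats <- features
    if (refit_pwm) {
      fold_pwm <- compute_pwm(
        ts[!hold & y == "positive", , drop = FALSE],
        tibble(aa = AA_STANDARD, freq = unname(pwm$background)),
        pseudocount = pwm$pseudocount
      )
      feats <- config_features(ts, fold_pwm, structures, config)
    }
    fit <- fit_classifier(feats[!hold, ], y[!hold], config)
    oof[hold] <- score_classifier(fit, feats[hold, ], config)
  }
  eval_from_scores(tibble(score = oof, label = as.character(y)), config)
}

#' Save / load a trained model
#'
#' Serializes the model (classifier state, PWM, configuration, package
#' version) so that a reloaded model reproduces scores exactly. Loading a
#' file written by an incompatible package version is refused with both
#' versions named.
#'
#' @param model A `casp_model`.
#' @param path File path (`.rds`).
#' @return `path` invisibly; `load_model()` returns the `casp_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "casp_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- tryCatch(readRDS(path), error = function(e) {
    abort(paste0("Cannot read model file '", path, "': ", conditionMessage(e)))
  })
  if (!inherits(model, "casp_model")) {
    abort(paste0("File '", path, "' does not contain a caspcleave model"))
  }
  here <- as.character(packageVersion("caspcleave"))
  if (strsplit(model$version, "\\.")[[1]][1] != strsplit(here, "\\.")[[1]][1]) {
    abort(paste0(
      "Model was saved by caspcleave ", model$version,
      " and cannot be loaded by ", here
    ))
  }
  model
}
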