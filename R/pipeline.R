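#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end method: forest size, network
#' training schedule, number of selected features, SVM kernel and box
#' constraint, and the evaluation protocol.
#'
#' @param trees forest size p (default 1000).
#' @param epochs network training epochs (default 50).
#' @param lr network learning rate (default 1e-4).
#' @param k_selected number of top-GCW features fed to the SVM
#'   (default 900).
#' @param kernel SVM kernel kind or a full [kernel_spec()] (default
#'   linear).
#' @param C SVM box constraint (default 1).
#' @param cv_folds folds for [cross_validate()] (default 10).
#' @param train_fraction train share for [train_test_split()]
#'   (default 0.7).
#' @param selection_scope `"per_fold"` (refit forest/network/selection
#'   inside each training fold; no leakage) or `"global"` (one selection
#'   pass on the full data before CV).
#' @param hidden dense hidden widths after the masked layer.
#' @param batch_size network mini-batch size.
#' @param seed master seed; every stochastic stage derives its own
#'   stream from it.
#' @return a `pipeline_config` object.
#' @export
pipeline_config <- function(trees = 1000L, epochs = 50L, lr = 1e-4,
                            k_selected = 900L, kernel = "linear", C = 1,
                            cv_folds = 10L, train_fraction = 0.7,
                            selection_scope = c("per_fold", "global"),
                            hidden = c(64L, 16L), batch_size = 32L,
                            seed = 1L) {
  selection_scope <- match.arg(selection_scope)
  if (!inherits(kernel, "kernel_spec")) kernel <- kernel_spec(kernel)
  if (cv_folds < 2L) stop_forgenet("cv_folds must be >= 2", "forgenet_input_error")
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop_forgenet("train_fraction must be in (0,1)", "forgenet_input_error")
  }
  if (k_selected < 1L) stop_forgenet("k_selected must be >= 1", "forgenet_input_error")
  structure(list(trees = as.integer(trees), epochs = as.integer(epochs),
                 lr = lr, k_selected = as.integer(k_selected),
                 kernel = kernel, C = C, cv_folds = as.integer(cv_folds),
                 train_fraction = train_fraction,
                 selection_scope = selection_scope,
                 hidden = as.integer(hidden),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# Sub-seeds derived from the master seed so stages have independent,
# reproducible streams (kept below 2^31).
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% .Machine$integer.max)
}

#' Confusion-matrix metric bundle
#'
#' TPR = TP/(TP+FN), FPR = FP/(FP+TN), Precision = TP/(TP+FP),
#' Specificity = TN/(TN+FP), F1 = 2TP/(2TP+FP+FN). A zero denominator
#' yields NA (rendered blank in reports).
#'
#' @param TP,FP,FN,TN non-negative integer confusion counts.
#' @return an `eval_report` holding the counts and the five rates.
#' @export
compute_metrics <- function(TP, FP, FN, TN) {
  cnt <- c(TP = TP, FP = FP, FN = FN, TN = TN)
  if (any(cnt < 0) || any(cnt != round(cnt))) {
    stop_forgenet("confusion counts must be non-negative integers",
                  "forgenet_input_error")
  }
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  TP <- as.integer(TP); FP <- as.integer(FP)
  FN <- as.integer(FN); TN <- as.integer(TN)
  structure(list(
    TP = TP, FP = FP, FN = FN, TN = TN,
    TPR = rate(TP, TP + FN),
    FPR = rate(FP, FP + TN),
    Precision = rate(TP, TP + FP),
    Specificity = rate(TN, TN + FP),
    F1 = rate(2 * TP, 2 * TP + FP + FN),
    AUC = NA_real_
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "" else sprintf("%.6f", v)
  cat(sprintf("confusion: TP=%d FP=%d FN=%d TN=%d\n", x$TP, x$FP, x$FN, x$TN))
  cat(sprintf("TPR %s  FPR %s  Precision %s  Specificity %s  F1 %s  AUC %s\n",
              fmt(x$TPR), fmt(x$FPR), fmt(x$Precision), fmt(x$Specificity),
              fmt(x$F1), fmt(x$AUC)))
  invisible(x)
}

#' ROC curve and AUC from decision values
#'
#' AUC is the normalized Mann-Whitney rank statistic (ties get half
#' credit); ROC points come from a threshold sweep over the unique
#' decision values.
#'
#' @param decision_values numeric scores, larger = more active.
#' @param labels +1/-1 vector.
#' @return list with `auc` and a data.frame `roc` of (FPR, TPR) points.
#' @export
roc_auc <- function(decision_values, labels) {
  labels <- as.numeric(labels)
  if (length(unique(labels)) < 2L) {
    stop_forgenet("both classes required for ROC", "forgenet_input_error")
  }
  pos <- labels == 1
  P <- sum(pos); N <- sum(!pos)
  r <- rank(decision_values)
  auc <- (sum(r[pos]) - P * (P + 1) / 2) / (P * N)
  th <- c(Inf, sort(unique(decision_values), decreasing = TRUE))
  roc <- t(vapply(th, function(t) {
    pred <- decision_values >= t
    c(FPR = sum(pred & !pos) / N, TPR = sum(pred & pos) / P)
  }, numeric(2)))
  list(auc = auc, roc = as.data.frame(roc))
}

confusion_from_pred <- function(pred, truth) {
  compute_metrics(TP = sum(pred == 1 & truth == 1),
                  FP = sum(pred == 1 & truth == -1),
                  FN = sum(pred == -1 & truth == 1),
                  TN = sum(pred == -1 & truth == -1))
}

# Core of the method on one train set: forest -> graph -> network ->
# GCW -> top-k. Returns the selected column indices and the stage fits.
fit_selector <- function(Xtr, ytr, cfg, seed_off = 0L) {
  forest <- fit_forest(Xtr, ytr, p = cfg$trees,
                       seed = derive_seed(cfg$seed, 1L + seed_off))
  graph <- forest_graph(forest)
  net <- train_gedfn(Xtr, ytr, graph, epochs = cfg$epochs, lr = cfg$lr,
                     seed = derive_seed(cfg$seed, 2L + seed_off),
                     hidden = cfg$hidden, batch_size = cfg$batch_size)
  scores <- gcw_scores(net, graph)
  selected <- select_top_k(scores, cfg$k_selected)
  list(forest = forest, graph = graph, net = net, scores = scores,
       selected = selected)
}

#' Run the full method on a train/test pair
#'
#' Fits the forest on the training matrix, builds the feature graph,
#' trains the masked network, selects the top-k GCW features, trains
#' the SVM on the selected columns and evaluates on the test matrix.
#'
#' @param train,test `fused_features` objects (or plain matrices plus
#'   `train_labels`/`test_labels`) sharing one column space.
#' @param cfg a `pipeline_config`.
#' @param train_labels,test_labels labels when matrices are plain.
#' @return list with `report` (an `eval_report` incl. AUC), `selected`
#'   (feature indices), `selected_names`, `decision` values, and the
#'   fitted `svm`.
#' @export
run_forgenet_svm <- function(train, test, cfg = pipeline_config(),
                             train_labels = NULL, test_labels = NULL) {
  Xtr <- if (inherits(train, "fused_features")) train$matrix else as.matrix(train)
  ytr <- if (inherits(train, "fused_features")) train$labels else train_labels
  Xte <- if (inherits(test, "fused_features")) test$matrix else as.matrix(test)
  yte <- if (inherits(test, "fused_features")) test$labels else test_labels
  if (ncol(Xtr) != ncol(Xte)) {
    stop_forgenet("train and test must share one column space",
                  "forgenet_input_error")
  }
  if (cfg$k_selected > ncol(Xtr)) {
    stop_forgenet(sprintf("k_selected (%d) exceeds feature width (%d)",
                          cfg$k_selected, ncol(Xtr)),
                  "forgenet_input_error")
  }
  sel <- fit_selector(Xtr, ytr, cfg)
  svm <- train_svm(Xtr[, sel$selected, drop = FALSE], ytr,
                   spec = cfg$kernel, C = cfg$C)
  pr <- predict(svm, Xte[, sel$selected, drop = FALSE])
  report <- confusion_from_pred(pr$label, yte)
  if (length(unique(yte)) > 1L) {
    report$AUC <- roc_auc(pr$decision, yte)$auc
  }
  nms <- colnames(Xtr) %||% sprintf("f%06d", seq_len(ncol(Xtr)))
  list(report = report, selected = sel$selected,
       selected_names = nms[sel$selected], decision = pr$decision,
       svm = svm)
}

#' Stratified fold assignment
#' @param y +1/-1 labels.
#' @param k fold count.
#' @param seed integer seed.
#' @return integer fold id per sample; per-class counts differ by <= 1
#'   across folds.
#' @export
stratified_folds <- function(y, k, seed = 1L) {
  fold <- integer(length(y))
  offset <- 0L
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      # stagger each class's remainder so total fold sizes differ by <= 1
      fold[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
      offset <- (offset + length(idx)) %% k
    }
  })
  fold
}

#' Stratified train/test split
#'
#' Per class, `floor((1 - train_fraction) * count)` samples go to the
#' test set (so 94 actives at 70/30 give 28 test positives) and the
#' rest to training.
#'
#' @param fused a `fused_features` object with labels.
#' @param train_fraction train share (default 0.7).
#' @param seed integer seed.
#' @return list of `fused_features`: `train` and `test`.
#' @export
train_test_split <- function(fused, train_fraction = 0.7, seed = 1L) {
  y <- fused$labels
  test_idx <- integer(0)
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      n_test <- floor((1 - train_fraction) * length(idx))
      test_idx <- c(test_idx, sample(idx, n_test))
    }
  })
  subset_fused <- function(rows) {
    structure(list(matrix = fused$matrix[rows, , drop = FALSE],
                   blocks = fused$blocks, labels = fused$labels[rows],
                   rdkit_stats = fused$rdkit_stats),
              class = "fused_features")
  }
  list(train = subset_fused(setdiff(seq_along(y), sort(test_idx))),
       test = subset_fused(sort(test_idx)))
}

#' Stratified k-fold cross-validation of the full method
#'
#' With `selection_scope = "per_fold"` the forest, network and feature
#' selection are refitted inside every training fold; `"global"` runs
#' one selection pass on the full data first (paper-style, leaks the
#' test fold into selection). Headline metrics pool the confusion
#' counts across folds (micro aggregation); the pooled AUC uses the
#' concatenated held-out decision values, and per-fold reports are kept.
#'
#' @param data a `fused_features` object with labels.
#' @param cfg a `pipeline_config`.
#' @return list with `pooled` (an `eval_report`), `per_fold` (list of
#'   `eval_report`s), `fold_mean` (mean of defined per-fold rates),
#'   `decision`/`truth` (pooled, in fold order) and `folds`.
#' @export
cross_validate <- function(data, cfg = pipeline_config()) {
  X <- data$matrix
  y <- data$labels
  if (length(y) < cfg$cv_folds) {
    stop_forgenet("fewer samples than folds", "forgenet_input_error")
  }
  fold <- stratified_folds(y, cfg$cv_folds, derive_seed(cfg$seed, 100L))
  if (min(table(fold, y)) == 0) {
    stop_forgenet("a fold lacks a class; use stratification or fewer folds",
                  "forgenet_input_error")
  }
  global_sel <- NULL
  if (cfg$selection_scope == "global") {
    global_sel <- fit_selector(X, y, cfg)$selected
  }
  per_fold <- vector("list", cfg$cv_folds)
  dec_all <- numeric(0); truth_all <- numeric(0)
  for (f in seq_len(cfg$cv_folds)) {
    tr <- fold != f; te <- fold == f
    selected <- global_sel %||%
      fit_selector(X[tr, , drop = FALSE], y[tr], cfg, seed_off = 10L * f)$selected
    svm <- train_svm(X[tr, selected, drop = FALSE], y[tr],
                     spec = cfg$kernel, C = cfg$C)
    pr <- predict(svm, X[te, selected, drop = FALSE])
    rep_f <- confusion_from_pred(pr$label, y[te])
    if (length(unique(y[te])) > 1L) rep_f$AUC <- roc_auc(pr$decision, y[te])$auc
    per_fold[[f]] <- rep_f
    dec_all <- c(dec_all, pr$decision)
    truth_all <- c(truth_all, y[te])
  }
  pooled <- compute_metrics(
    TP = sum(vapply(per_fold, `[[`, numeric(1), "TP")),
    FP = sum(vapply(per_fold, `[[`, numeric(1), "FP")),
    FN = sum(vapply(per_fold, `[[`, numeric(1), "FN")),
    TN = sum(vapply(per_fold, `[[`, numeric(1), "TN")))
  pooled$AUC <- roc_auc(dec_all, truth_all)$auc
  rates <- c("TPR", "FPR", "Precision", "Specificity", "F1", "AUC")
  fold_mean <- vapply(rates, function(r) {
    v <- vapply(per_fold, `[[`, numeric(1), r)
    mean(v, na.rm = TRUE)
  }, numeric(1))
  list(pooled = pooled, per_fold = per_fold, fold_mean = fold_mean,
       decision = dec_all, truth = truth_all, folds = fold)
}

#' Sweep the number of selected features
#'
#' Repeats [cross_validate()] for each k and tabulates both the pooled
#' (micro) and fold-averaged metrics.
#'
#' @param data a `fused_features` object.
#' @param cfg a `pipeline_config` (its `k_selected` is overridden).
#' @param ks candidate k values.
#' @return data.frame, one row per k with pooled_* and mean_* columns.
#' @export
sweep_k <- function(data, cfg = pipeline_config(),
                    ks = c(50, 100, 200, 500, 600, 700, 800, 900, 1000, 1200)) {
  ks <- ks[ks <= ncol(data$matrix)]
  rows <- lapply(ks, function(k) {
    cfg$k_selected <- as.integer(k)
    cv <- cross_validate(data, cfg)
    data.frame(k = k,
               pooled_TPR = cv$pooled$TPR, pooled_FPR = cv$pooled$FPR,
               pooled_Precision = cv$pooled$Precision,
               pooled_Specificity = cv$pooled$Specificity,
               pooled_F1 = cv$pooled$F1, pooled_AUC = cv$pooled$AUC,
               mean_TPR = cv$fold_mean[["TPR"]],
               mean_FPR = cv$fold_mean[["FPR"]],
               mean_Precision = cv$fold_mean[["Precision"]],
               mean_Specificity = cv$fold_mean[["Specificity"]],
               mean_F1 = cv$fold_mean[["F1"]],
               mean_AUC = cv$fold_mean[["AUC"]])
  })
  do.call(rbind, rows)
}

report_payload <- function(report, cfg = NULL, selected_names = NULL,
                           per_fold = NULL) {
  six <- function(v) if (is.na(v)) NULL else as.numeric(sprintf("%.6f", v))
  payload <- list(
    config = if (!is.null(cfg)) {
      c(unclass(cfg)[setdiff(names(unclass(cfg)), "kernel")],
        list(kernel = unclass(cfg$kernel)))
    },
    confusion = list(TP = report$TP, FP = report$FP, FN = report$FN,
                     TN = report$TN),
    metrics = list(TPR = six(report$TPR), FPR = six(report$FPR),
                   Precision = six(report$Precision),
                   Specificity = six(report$Specificity),
                   F1 = six(report$F1), AUC = six(report$AUC)),
    selected_features = selected_names,
    per_fold = if (!is.null(per_fold)) {
      lapply(per_fold, function(r) {
        list(TP = r$TP, FP = r$FP, FN = r$FN, TN = r$TN,
             TPR = six(r$TPR), FPR = six(r$FPR), Precision = six(r$Precision),
             Specificity = six(r$Specificity), F1 = six(r$F1),
             AUC = six(r$AUC))
      })
    }
  )
  payload[!vapply(payload, is.null, logical(1))]
}

#' Write an evaluation report as JSON
#'
#' Deterministic rendering: rates fixed to six decimals (matching the
#' report tables), undefined rates omitted, stable key order — two runs
#' with identical config and seed produce byte-identical files.
#'
#' @param report an `eval_report`.
#' @param path output path.
#' @param cfg optional `pipeline_config` echoed into the report.
#' @param selected_names optional selected-feature names.
#' @param per_fold optional list of per-fold `eval_report`s.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, cfg = NULL, selected_names = NULL,
                         per_fold = NULL) {
  jsonlite::write_json(report_payload(report, cfg, selected_names, per_fold),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write ROC points as TSV
#' @param roc data.frame of (FPR, TPR) points from [roc_auc()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_roc <- function(roc, path) {
  utils::write.table(roc, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
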