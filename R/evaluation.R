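#' Confusion counts for binary predictions
#'
#' Standard 2x2 counts with death (label 1) as the positive class.
#'
#' @param y_true,y_pred 0/1 vectors of equal length.
#' @return named list TP, FP, TN, FN.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch", call. = FALSE)
  if (!all(y_true %in% c(0, 1)) || !all(y_pred %in% c(0, 1))) {
    stop("inputs must be binary 0/1", call. = FALSE)
  }
  list(TP = sum(y_true == 1 & y_pred == 1),
       FP = sum(y_true == 0 & y_pred == 1),
       TN = sum(y_true == 0 & y_pred == 0),
       FN = sum(y_true == 1 & y_pred == 0))
}

#' Summary classification metrics from confusion counts
#'
#' Accuracy, sensitivity (TP/(TP+FN)), specificity (TN/(TN+FP)), per-class
#' precision/recall with the 0/0 -> 0 convention, macro-precision and
#' macro-recall (unweighted two-class means), and F1 both as macro-F1
#' (headline) and positive-class F1.
#'
#' @param counts as from [confusion()].
#' @return named list of metric scalars plus the counts.
#' @export
summary_metrics <- function(counts) {
  n <- counts$TP + counts$FP + counts$TN + counts$FN
  stopifnot(n > 0)
  div <- function(a, b) if (b == 0) 0 else a / b
  prec1 <- div(counts$TP, counts$TP + counts$FP)
  rec1 <- div(counts$TP, counts$TP + counts$FN)
  prec0 <- div(counts$TN, counts$TN + counts$FN)
  rec0 <- div(counts$TN, counts$TN + counts$FP)
  f1 <- function(p, r) if (p + r == 0) 0 else 2 * p * r / (p + r)
  macro_p <- (prec0 + prec1) / 2
  macro_r <- (rec0 + rec1) / 2
  list(
    TP = counts$TP, FP = counts$FP, TN = counts$TN, FN = counts$FN,
    accuracy = (counts$TP + counts$TN) / n,
    sensitivity = rec1, specificity = rec0,
    precision_pos = prec1, recall_pos = rec1,
    macro_precision = macro_p, macro_recall = macro_r,
    f1_macro = (f1(prec0, rec0) + f1(prec1, rec1)) / 2,
    f1_pos = f1(prec1, rec1)
  )
}

#' ROC curve and rank-statistic AUC
#'
#' The AUC is the probability that a random positive outscores a random
#' negative, ties counting one half (Mann-Whitney rank statistic). ROC points
#' come from a threshold sweep over the unique scores; the trapezoidal area
#' under that curve equals the rank statistic exactly (ties produce diagonal
#' segments).
#'
#' @param y_true 0/1 labels (both classes present).
#' @param scores numeric scores, higher = more death-like.
#' @return list with \code{auc} and \code{roc} (data.frame fpr, tpr ordered
#'   from threshold +Inf down).
#' @export
roc_auc <- function(y_true, scores) {
  stopifnot(length(y_true) == length(scores))
  npos <- sum(y_true == 1)
  nneg <- sum(y_true == 0)
  if (npos == 0 || nneg == 0) {
    stop("both classes must be present", call. = FALSE)
  }
  r <- rank(scores)
  auc <- (sum(r[y_true == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(t) sum(scores >= t & y_true == 1), 0) / npos)
  fpr <- c(0, vapply(thr, function(t) sum(scores >= t & y_true == 0), 0) / nneg)
  list(auc = auc, roc = data.frame(fpr = fpr, tpr = tpr))
}

#' Evaluate predicted probabilities on a node subset
#'
#' Thresholds the death probability at \code{threshold} (default 0.5) for the
#' confusion metrics; AUC is threshold-free.
#'
#' @param prob N x 2 probability matrix (or death-probability vector).
#' @param y 0/1 labels.
#' @param idx node indices to evaluate (e.g. the test mask).
#' @param threshold decision threshold on the death probability.
#' @return a metrics list (see [summary_metrics()]) plus \code{auc} and
#'   \code{roc}.
#' @export
evaluate_predictions <- function(prob, y, idx = seq_along(y), threshold = 0.5) {
  p <- if (is.matrix(prob)) prob[, 2] else prob
  p <- p[idx]; yt <- y[idx]
  m <- summary_metrics(confusion(yt, as.integer(p >= threshold)))
  ra <- roc_auc(yt, p)
  c(m, list(auc = ra$auc, roc = ra$roc))
}

run_one_model <- function(prep, masks, config, model, measures = NULL, k = 6) {
  need_p <- model %in% c("amgcn", "pgcn")
  need_f <- model %in% c("amgcn", "kgcn")
  gp <- if (need_p) {
    population_adjacency(prep$X, prep$raw,
                         measures %||% phenotype_measures(schema = prep$schema))
  }
  gf <- if (need_f) knn_adjacency(cosine_similarity_matrix(prep$X), k)
  if (model == "amgcn") {
    fit <- train_amgcn(prep$X, gp, gf, prep$labels, masks, config)
    prob <- predict(fit, prep$X, gp, gf)
  } else if (model == "pgcn") {
    fit <- train_gcn(prep$X, gp, prep$labels, masks, config)
    prob <- predict(fit, prep$X, gp)
  } else {
    fit <- train_gcn(prep$X, gf, prep$labels, masks, config)
    prob <- predict(fit, prep$X, gf)
  }
  list(fit = fit, prob = prob)
}

#' Phenotype-measure combination sweep
#'
#' For every requested combination of candidate phenotypic measures, builds
#' the population graph, trains the topology-channel GCN, and evaluates on
#' the test set; each combination is repeated over the given seeds and
#' metrics are aggregated as mean and sd.
#'
#' @param prep preprocessed cohort as from [preprocess_cohort()].
#' @param candidates character vector of candidate measures (default the four
#'   clinical variables sex, age, BMI, smoking).
#' @param combos list of character vectors; default all nonempty subsets of
#'   the candidates.
#' @param config a [train_config()]; its seed is offset per repetition.
#' @param seeds integer vector of repetition seeds.
#' @param beta thresholds for quantitative measures.
#' @param train_frac training fraction for the per-seed split.
#' @return data.frame, one row per combination: mean/sd of AUC, accuracy and
#'   macro F1 over seeds.
#' @export
sweep_phenotypes <- function(prep,
                             candidates = c("sex_male", "age", "bmi", "smoking"),
                             combos = NULL,
                             config = train_config(),
                             seeds = 1:5,
                             beta = c(age = 5, bmi = 2),
                             train_frac = 0.60) {
  if (is.null(combos)) {
    combos <- unlist(lapply(seq_along(candidates), function(m) {
      utils::combn(candidates, m, simplify = FALSE)
    }), recursive = FALSE)
  }
  if (length(combos) == 0 || any(lengths(combos) == 0)) {
    stop("combinations must be nonempty", call. = FALSE)
  }
  rows <- lapply(combos, function(cmb) {
    meas <- phenotype_measures(cmb, prep$schema, beta)
    per_seed <- vapply(seeds, function(s) {
      cfg <- config; cfg$seed <- derive_seed(s, "sweep-p")
      masks <- split_masks(nrow(prep$X), train_frac, cfg$seed)
      res <- run_one_model(prep, masks, cfg, "pgcn", measures = meas)
      ev <- evaluate_predictions(res$prob, prep$labels, masks$test)
      c(ev$auc, ev$accuracy, ev$f1_macro)
    }, numeric(3))
    data.frame(combination = paste(cmb, collapse = "+"),
               n_measures = length(cmb),
               auc_mean = mean(per_seed[1, ]), auc_sd = stats::sd(per_seed[1, ]),
               acc_mean = mean(per_seed[2, ]), acc_sd = stats::sd(per_seed[2, ]),
               f1_mean = mean(per_seed[3, ]), f1_sd = stats::sd(per_seed[3, ]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Neighborhood-size (K) sweep for the KNN graph
#'
#' For each K, builds the cosine-similarity KNN graph, trains the
#' feature-channel GCN, and evaluates on the test set over the given seeds.
#'
#' @inheritParams sweep_phenotypes
#' @param k_values integer vector of neighbor counts (default 2:9).
#' @return data.frame, one row per K.
#' @export
sweep_k <- function(prep, k_values = 2:9, config = train_config(),
                    seeds = 1:5, train_frac = 0.60) {
  n <- nrow(prep$X)
  if (any(k_values < 1 | k_values > n - 1)) {
    stop("`k_values` must lie in [1, N-1]", call. = FALSE)
  }
  S <- cosine_similarity_matrix(prep$X)
  rows <- lapply(k_values, function(k) {
    gf <- knn_adjacency(S, k)
    per_seed <- vapply(seeds, function(s) {
      cfg <- config; cfg$seed <- derive_seed(s, "sweep-k")
      masks <- split_masks(n, train_frac, cfg$seed)
      fit <- train_gcn(prep$X, gf, prep$labels, masks, cfg)
      prob <- predict(fit, prep$X, gf)
      ev <- evaluate_predictions(prob, prep$labels, masks$test)
      c(ev$auc, ev$accuracy, ev$f1_macro)
    }, numeric(3))
    data.frame(k = k,
               auc_mean = mean(per_seed[1, ]), auc_sd = stats::sd(per_seed[1, ]),
               acc_mean = mean(per_seed[2, ]), acc_sd = stats::sd(per_seed[2, ]),
               f1_mean = mean(per_seed[3, ]), f1_sd = stats::sd(per_seed[3, ]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Serialize / restore a metrics report as CSV
#'
#' One row per model/combination/K with canonical numeric formatting; ROC
#' points can be exported separately as \code{fpr,tpr} lines. Round-trips
#' losslessly at the written precision.
#'
#' @param report data.frame of metric rows.
#' @param path output path.
#' @return \code{path} / the restored data.frame.
#' @export
write_metrics_csv <- function(report, path) {
  out <- report
  for (nm in names(out)) {
    if (is.numeric(out[[nm]]) && !is.integer(out[[nm]])) {
      out[[nm]] <- format_num(out[[nm]])
    }
  }
  utils::write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metrics_csv
#' @export
read_metrics_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname write_metrics_csv
#' @param roc data.frame with fpr, tpr.
#' @export
write_roc_points <- function(roc, path) {
  utils::write.table(
    data.frame(fpr = format_num(roc$fpr), tpr = format_num(roc$tpr)),
    path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
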