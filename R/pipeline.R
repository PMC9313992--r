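#' Run configuration for the end-to-end pipeline
#'
#' A flat list of settings covering every stage: synthetic-cohort spec
#' overrides, preprocessing thresholds, graph settings, training
#' configuration and evaluation settings, all driven by one global seed.
#'
#' @param out_dir output directory for all artifacts.
#' @param cohort_csv optional path to an existing cohort CSV (with a
#'   \code{.schema} sidecar); when NULL a synthetic cohort is generated.
#' @param n_patients,prevalence,signal_strength synthetic-spec overrides.
#' @param miss_threshold missingness filter threshold.
#' @param measures phenotype measures for the population graph.
#' @param beta quantitative-measure thresholds.
#' @param k KNN neighbor count (default 6).
#' @param train TrainConfig, as from [train_config()].
#' @param train_frac training fraction.
#' @param threshold decision threshold for confusion metrics.
#' @param seed single global seed; every stage derives its own stream from it.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(out_dir,
                       cohort_csv = NULL,
                       n_patients = 600,
                       prevalence = 0.05,
                       signal_strength = 2.5,
                       miss_threshold = 0.80,
                       measures = c("age", "smoking"),
                       beta = c(age = 5, bmi = 2),
                       k = 6,
                       train = train_config(),
                       train_frac = 0.60,
                       threshold = 0.5,
                       seed = 21) {
  structure(list(out_dir = out_dir, cohort_csv = cohort_csv,
                 n_patients = n_patients, prevalence = prevalence,
                 signal_strength = signal_strength,
                 miss_threshold = miss_threshold, measures = measures,
                 beta = beta, k = k, train = train, train_frac = train_frac,
                 threshold = threshold, seed = as.integer(seed)),
            class = "run_config")
}

#' Write / read a run configuration as flat key=value text
#'
#' @param config a \code{run_config}.
#' @param path file path.
#' @return \code{path} / the restored \code{run_config}.
#' @export
write_run_config <- function(config, path) {
  # out_dir is deliberately not serialized: the config travels with its run
  # directory, and embedding the path would make manifests location-dependent
  kv <- c(
    sprintf("cohort_csv=%s", config$cohort_csv %||% ""),
    sprintf("n_patients=%d", as.integer(config$n_patients)),
    sprintf("prevalence=%s", format_num(config$prevalence)),
    sprintf("signal_strength=%s", format_num(config$signal_strength)),
    sprintf("miss_threshold=%s", format_num(config$miss_threshold)),
    sprintf("measures=%s", paste(config$measures, collapse = "+")),
    sprintf("beta=%s", paste(sprintf("%s:%s", names(config$beta),
                                     format_num(config$beta)), collapse = "+")),
    sprintf("k=%d", as.integer(config$k)),
    sprintf("train_frac=%s", format_num(config$train_frac)),
    sprintf("threshold=%s", format_num(config$threshold)),
    sprintf("seed=%d", config$seed),
    sprintf("train.%s=%s",
            c("lr", "weight_decay", "epochs", "patience", "dropout", "nhid1",
              "nhid2", "att_hidden", "beta", "theta", "loss_reduction",
              "class_weights", "seed"),
            c(format_num(config$train$lr), format_num(config$train$weight_decay),
              config$train$epochs, config$train$patience,
              format_num(config$train$dropout), config$train$nhid1,
              config$train$nhid2, config$train$att_hidden,
              format_num(config$train$beta), format_num(config$train$theta),
              config$train$loss_reduction, config$train$class_weights,
              config$train$seed))
  )
  writeLines(kv, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, function(x) paste(x[-1], collapse = "="),
                                 character(1)),
                          vapply(kv, `[[`, character(1), 1L))
  beta_parts <- strsplit(strsplit(vals[["beta"]], "+", fixed = TRUE)[[1]], ":")
  beta <- stats::setNames(as.numeric(vapply(beta_parts, `[[`, character(1), 2L)),
                          vapply(beta_parts, `[[`, character(1), 1L))
  tr <- train_config(
    lr = as.numeric(vals[["train.lr"]]),
    weight_decay = as.numeric(vals[["train.weight_decay"]]),
    epochs = as.integer(vals[["train.epochs"]]),
    patience = as.integer(vals[["train.patience"]]),
    dropout = as.numeric(vals[["train.dropout"]]),
    nhid1 = as.integer(vals[["train.nhid1"]]),
    nhid2 = as.integer(vals[["train.nhid2"]]),
    att_hidden = as.integer(vals[["train.att_hidden"]]),
    beta = as.numeric(vals[["train.beta"]]),
    theta = as.numeric(vals[["train.theta"]]),
    loss_reduction = vals[["train.loss_reduction"]],
    class_weights = as.logical(vals[["train.class_weights"]]),
    seed = as.integer(vals[["train.seed"]]))
  run_config(out_dir = dirname(path),
             cohort_csv = if (nzchar(vals[["cohort_csv"]])) vals[["cohort_csv"]],
             n_patients = as.integer(vals[["n_patients"]]),
             prevalence = as.numeric(vals[["prevalence"]]),
             signal_strength = as.numeric(vals[["signal_strength"]]),
             miss_threshold = as.numeric(vals[["miss_threshold"]]),
             measures = strsplit(vals[["measures"]], "+", fixed = TRUE)[[1]],
             beta = beta, k = as.integer(vals[["k"]]), train = tr,
             train_frac = as.numeric(vals[["train_frac"]]),
             threshold = as.numeric(vals[["threshold"]]),
             seed = as.integer(vals[["seed"]]))
}

manifest_add <- function(manifest, stage, inputs, outputs, seed) {
  hash <- function(files) {
    files <- files[file.exists(files)]
    if (length(files) == 0) return("-")
    paste(unname(tools::md5sum(sort(files))), collapse = "+")
  }
  rbind(manifest, data.frame(stage = stage, input_hash = hash(inputs),
                             output_hash = hash(outputs), seed = seed,
                             stringsAsFactors = FALSE))
}

stage_fresh <- function(old_manifest, stage, inputs, outputs) {
  if (is.null(old_manifest) || !all(file.exists(outputs))) return(FALSE)
  row <- old_manifest[old_manifest$stage == stage, , drop = FALSE]
  if (nrow(row) != 1) return(FALSE)
  files <- inputs[file.exists(inputs)]
  h <- if (length(files) == 0) "-" else
    paste(unname(tools::md5sum(sort(files))), collapse = "+")
  identical(row$input_hash, h)
}

#' Run the full pipeline: simulate, preprocess, graphs, train, evaluate
#'
#' Executes every stage from a single configuration with full seed control,
#' writing all artifacts (cohort CSV, processed matrix, split file, both
#' graph edge lists, training histories, a metrics report with one row per
#' model in \{p-GCN, K-GCN, AM-GCN\}, ROC point files) plus a manifest of
#' stage input/output hashes into \code{config$out_dir}. Stages whose
#' recorded input hashes are unchanged and whose outputs exist are skipped.
#'
#' @param config a [run_config()].
#' @param models character subset of c("pgcn", "kgcn", "amgcn").
#' @return invisibly, a list with the metrics report and the manifest.
#' @export
run_pipeline <- function(config, models = c("pgcn", "kgcn", "amgcn")) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(config$out_dir, f)
  write_run_config(config, pth("config.txt"))
  old_manifest <- if (file.exists(pth("manifest.csv"))) {
    utils::read.csv(pth("manifest.csv"), stringsAsFactors = FALSE)
  }
  manifest <- NULL
  log_stage <- function(stage, t0, skipped = FALSE) {
    message(sprintf("[%s] %s (%.2fs)", stage,
                    if (skipped) "cached" else "done",
                    as.numeric(Sys.time()) - t0))
  }

  # -- simulate -----------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  cohort_path <- config$cohort_csv %||% pth("cohort.csv")
  sim_seed <- derive_seed(config$seed, "simulate")
  if (is.null(config$cohort_csv)) {
    if (stage_fresh(old_manifest, "simulate", pth("config.txt"),
                    c(cohort_path, paste0(cohort_path, ".schema")))) {
      log_stage("simulate", t0, TRUE)
    } else {
      spec <- synthetic_spec(n_patients = config$n_patients,
                             prevalence = config$prevalence,
                             signal_strength = config$signal_strength,
                             seed = sim_seed)
      write_cohort_csv(generate_cohort(spec), chd_schema(spec), cohort_path)
      log_stage("simulate", t0)
    }
  }
  manifest <- manifest_add(manifest, "simulate", pth("config.txt"),
                           c(cohort_path, paste0(cohort_path, ".schema")),
                           sim_seed)

  # -- preprocess ---------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  cohort <- read_cohort_csv(cohort_path)
  schema <- attr(cohort, "schema")
  prep <- preprocess_cohort(cohort, schema, config$miss_threshold)
  split_seed <- derive_seed(config$seed, "split")
  masks <- split_masks(nrow(prep$X), config$train_frac, split_seed)
  Xout <- data.frame(patient_id = prep$patient_ids,
                     label = prep$labels)
  for (j in seq_len(ncol(prep$X))) Xout[[colnames(prep$X)[j]]] <- format_num(prep$X[, j])
  utils::write.table(Xout, pth("features.csv"), sep = ",", quote = FALSE,
                     row.names = FALSE)
  part <- rep("test", nrow(prep$X))
  part[masks$train_fit] <- "train"
  part[masks$val] <- "val"
  writeLines(c("patient_id,partition",
               sprintf("%s,%s", prep$patient_ids, part)), pth("split.csv"))
  manifest <- manifest_add(manifest, "preprocess", cohort_path,
                           c(pth("features.csv"), pth("split.csv")), split_seed)
  log_stage("preprocess", t0)

  # -- graphs -------------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  meas <- phenotype_measures(config$measures, schema, config$beta)
  gp <- population_adjacency(prep$X, prep$raw, meas)
  gf <- knn_adjacency(cosine_similarity_matrix(prep$X), config$k)
  write_edge_list(gp, pth("graph_population.csv"))
  write_edge_list(gf, pth("graph_knn.csv"))
  manifest <- manifest_add(manifest, "graphs", pth("features.csv"),
                           c(pth("graph_population.csv"), pth("graph_knn.csv")),
                           config$seed)
  log_stage("graphs", t0)

  # -- train + evaluate ---------------------------------------------------
  report <- NULL
  for (model in models) {
    t0 <- as.numeric(Sys.time())
    cfg <- config$train
    cfg$seed <- derive_seed(config$seed, paste0("train-", model))
    hist_path <- pth(sprintf("history_%s.csv", model))
    prob_path <- pth(sprintf("prob_%s.csv", model))
    train_inputs <- c(pth("config.txt"), pth("features.csv"), pth("split.csv"),
                      pth("graph_population.csv"), pth("graph_knn.csv"))
    cached <- stage_fresh(old_manifest, paste0("train-", model),
                          train_inputs, c(hist_path, prob_path))
    if (cached) {
      prob <- utils::read.csv(prob_path, stringsAsFactors = FALSE)$p_death
      hist <- utils::read.csv(hist_path, stringsAsFactors = FALSE)
      best_epoch <- hist$epoch[which.min(hist$val_loss)]
    } else {
      res <- switch(model,
        pgcn = {
          fit <- train_gcn(prep$X, gp, prep$labels, masks, cfg)
          list(fit = fit, prob = predict(fit, prep$X, gp))
        },
        kgcn = {
          fit <- train_gcn(prep$X, gf, prep$labels, masks, cfg)
          list(fit = fit, prob = predict(fit, prep$X, gf))
        },
        amgcn = {
          fit <- train_amgcn(prep$X, gp, gf, prep$labels, masks, cfg)
          list(fit = fit, prob = predict(fit, prep$X, gp, gf))
        })
      hist <- res$fit$history
      hist$train_loss <- format_num(hist$train_loss)
      hist$val_loss <- format_num(hist$val_loss)
      utils::write.table(hist, hist_path, sep = ",", quote = FALSE,
                         row.names = FALSE)
      writeLines(c("patient_id,p_death",
                   sprintf("%s,%s", prep$patient_ids,
                           format_num(res$prob[, 2]))), prob_path)
      prob <- res$prob[, 2]
      best_epoch <- res$fit$best_epoch
    }
    ev <- evaluate_predictions(prob, prep$labels, masks$test,
                               config$threshold)
    write_roc_points(ev$roc, pth(sprintf("roc_%s.csv", model)))
    row <- data.frame(model = model, best_epoch = best_epoch,
                      accuracy = ev$accuracy, auc = ev$auc,
                      macro_precision = ev$macro_precision,
                      macro_recall = ev$macro_recall,
                      f1_macro = ev$f1_macro, f1_pos = ev$f1_pos,
                      stringsAsFactors = FALSE)
    report <- rbind(report, row)
    manifest <- manifest_add(manifest, paste0("train-", model),
                             train_inputs,
                             c(hist_path, prob_path), cfg$seed)
    log_stage(paste0("train-", model), t0, cached)
  }
  write_metrics_csv(report, pth("metrics.csv"))
  manifest <- manifest_add(manifest, "evaluate",
                           pth(sprintf("history_%s.csv", models)),
                           pth("metrics.csv"), config$seed)
  utils::write.table(manifest, pth("manifest.csv"), sep = ",", quote = FALSE,
                     row.names = FALSE)
  invisible(list(report = report, manifest = manifest))
}
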