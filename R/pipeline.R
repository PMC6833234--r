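#' Experiment configuration
#'
#' Bundles every knob of the end-to-end experiment: the cohort source, the
#' classifier families with their grids, the cross-validation layout, the
#' feature subset, the clinical thresholds and the global seed. The single
#' seed fans out to per-stage child seeds (cohort, folds, grid search, model
#' fits) so each stage is independently reproducible.
#'
#' @param cohort A [cohort_config()] for synthetic input, or a file path to a
#'   CGM CSV ([read_cgm_csv()] dialect).
#' @param families Character vector among `"rf"`, `"svm_ln"`, `"svm_rbf"`,
#'   `"knn"`, `"lr"`.
#' @param grids Named list of hyperparameter grids (defaults to
#'   [default_grids()], subset to `families`).
#' @param k,inner_k Outer and inner cross-subject fold counts.
#' @param feature_subset `"all"` (CGM, RIG, GRC) or `"cgm_grc"` (the
#'   RIG-ablated set; labels and events are identical across ablations).
#' @param horizon Prediction horizon in 5-min steps (default 6 = 30 min).
#' @param W Prediction steps per meal (default 42 = 3.5 h).
#' @param alert,severe,near Thresholds in mg/dL (defaults 70, 54, 80).
#' @param cost_fn_override `NULL` to use the class-imbalance cost from the
#'   training folds, or a number (e.g. 1 for a cost-insensitive baseline).
#' @param seed Global integer seed.
#' @param out_dir Optional directory where `folds.csv` and `summary.csv` are
#'   written.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(cohort = cohort_config(),
                              families = c("rf", "svm_ln", "svm_rbf",
                                           "knn", "lr"),
                              grids = NULL, k = 5L, inner_k = 3L,
                              feature_subset = "all", horizon = 6L, W = 42L,
                              alert = 70, severe = 54, near = 80,
                              cost_fn_override = NULL, seed = 1L,
                              out_dir = NULL) {
  families <- match.arg(families, c("rf", "svm_ln", "svm_rbf", "knn", "lr"),
                        several.ok = TRUE)
  if (is.null(grids)) grids <- default_grids()
  stopifnot(all(families %in% names(grids)),
            severe < alert, alert < near,
            horizon >= 1L, W >= 1L)
  structure(
    list(cohort = cohort, families = families, grids = grids[families],
         k = as.integer(k), inner_k = as.integer(inner_k),
         feature_subset = feature_subset, horizon = as.integer(horizon),
         W = as.integer(W), alert = alert, severe = severe, near = near,
         cost_fn_override = cost_fn_override, seed = as.integer(seed),
         out_dir = out_dir),
    class = "experiment_config"
  )
}

#' Read an experiment configuration from YAML
#'
#' Recognized keys mirror the [experiment_config()] arguments; `cohort:` may
#' hold [cohort_config()] fields (synthetic input) or a `csv:` path. Grids are
#' given as named lists of vectors and crossed with `expand.grid()`.
#'
#' @param path Path to a YAML file.
#' @return An [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  cohort <- if (!is.null(y$cohort$csv)) {
    y$cohort$csv
  } else {
    do.call(cohort_config, y$cohort %||% list())
  }
  grids <- if (!is.null(y$grids)) {
    # yaml yields mixed-type sequences as lists; flatten each grid axis
    lapply(y$grids, function(g) do.call(expand.grid, lapply(g, unlist)))
  } else NULL
  args <- y[setdiff(names(y), c("cohort", "grids"))]
  do.call(experiment_config,
          c(list(cohort = cohort, grids = grids), args))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full prediction experiment
#'
#' Executes the whole flow: load or simulate the cohort, fill short sensor
#' gaps, filter meal announcements, build the feature samples, split
#' cross-subject folds, and per fold and family compute the false-negative
#' cost, grid-search hyperparameters, train, predict the held-out subjects,
#' and score both sample-level metrics and the event/alarm calculus. Fully
#' deterministic given the configuration seed.
#'
#' @param config An [experiment_config()].
#' @return A list of class `pphypo_experiment` with `folds` (one row per fold
#'   and family), `summary` (mean and SD per family), `data_info` (cohort and
#'   sample statistics) and `config`. When `config$out_dir` is set,
#'   `folds.csv` and `summary.csv` are written there.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  seed <- config$seed

  # --- cohort ---------------------------------------------------------------
  if (inherits(config$cohort, "cohort_config")) {
    cc <- config$cohort
    cc$seed <- seed
    cohort <- simulate_cohort(cc)
    series_list <- cohort$series
  } else {
    series_list <- read_cgm_csv(config$cohort)
  }
  if (!length(series_list)) stop("empty cohort", call. = FALSE)

  # --- preprocessing --------------------------------------------------------
  series_list <- lapply(series_list, interpolate_gaps)
  names(series_list) <- vapply(series_list, function(s) s$series_id, "")
  meals <- do.call(rbind, lapply(series_list, filter_meal_announcements))
  samples <- build_dataset(series_list, meals, W = config$W,
                           horizon = config$horizon, threshold = config$alert)
  g_all <- unlist(lapply(series_list, function(s) s$glucose))
  data_info <- list(
    n_series = length(series_list),
    n_points = length(g_all),
    frac_below_alert = mean(g_all[!is.na(g_all)] < config$alert),
    n_samples = nrow(samples),
    n_pos = sum(samples$label == 1),
    n_neg = sum(samples$label == 0),
    imbalance = sum(samples$label == 0) / max(sum(samples$label == 1), 1L),
    skip_log = attr(samples, "skip_log")
  )

  # --- folds ----------------------------------------------------------------
  series_meta <- data.frame(
    series_id = vapply(series_list, function(s) s$series_id, ""),
    patient_id = vapply(series_list, function(s) s$patient_id, ""),
    stringsAsFactors = FALSE
  )
  folds <- cross_subject_folds(series_meta, k = config$k, seed = seed + 1L)

  events_by_series <- lapply(series_list, function(s) {
    extract_hypo_events(s, meals[meals$series_id == s$series_id, , drop = FALSE],
                        alert = config$alert, severe = config$severe)
  })

  # --- per fold, per family -------------------------------------------------
  rows <- list()
  for (f in folds) {
    train <- samples[samples$series_id %in% f$train_series, , drop = FALSE]
    test <- samples[samples$series_id %in% f$test_series, , drop = FALSE]
    cost <- compute_fn_cost(train$label)
    if (!is.null(config$cost_fn_override)) {
      cost$cost_fn <- config$cost_fn_override
    }
    test_events <- do.call(rbind, events_by_series[f$test_series])
    for (fam in config$families) {
      hyper <- grid_search(fam, train, series_meta, config$grids[[fam]],
                           cost = cost, inner_k = config$inner_k,
                           seed = seed + 2L,
                           feature_subset = config$feature_subset)
      model <- train_model(fam, train, cost, hyper,
                           feature_subset = config$feature_subset,
                           seed = seed + 3L)
      pred <- predict(model, test)
      sm <- sample_metrics(test$label, pred$label, pred$score)

      alarms <- fold_alarms(test, pred$label, meals, events_by_series)
      matched <- match_alarms_events(alarms, test_events)
      nh_frac <- near_hypo_false_alarm_fraction(matched,
                                                series_list[f$test_series],
                                                near = config$near)
      rows[[length(rows) + 1L]] <- data.frame(
        fold = f$fold, family = fam,
        hyper = paste(sprintf("%s=%s", names(hyper), unlist(hyper)),
                      collapse = ";"),
        cost_fn = cost$cost_fn,
        sens = sm$metrics[["sensitivity"]], spec = sm$metrics[["specificity"]],
        precision = sm$metrics[["precision"]], f1 = sm$metrics[["f1"]],
        auc = sm$metrics[["auc"]],
        NH = matched$metrics[["NH"]], TP_e = matched$metrics[["TP_e"]],
        FP_e = matched$metrics[["FP_e"]], FAR = matched$metrics[["FAR"]],
        DT = matched$metrics[["DT"]],
        severe_alarmed = matched$metrics[["severe_alarmed"]],
        severe_missed = matched$metrics[["severe_missed"]],
        near_hypo_fa_frac = nh_frac,
        stringsAsFactors = FALSE
      )
    }
  }
  folds_df <- do.call(rbind, rows)
  summary_df <- summarize_folds(folds_df)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(folds_df, file.path(config$out_dir, "folds.csv"),
                     row.names = FALSE)
    utils::write.csv(summary_df, file.path(config$out_dir, "summary.csv"),
                     row.names = FALSE)
  }
  structure(
    list(folds = folds_df, summary = summary_df, data_info = data_info,
         config = config),
    class = "pphypo_experiment"
  )
}

# Hard predictions of one fold regrouped per (series, meal) into step
# sequences t = 1..W, then run through the alarm detector. Steps with no
# emitted sample count as negative predictions.
fold_alarms <- function(test, hard_labels, meals, events_by_series) {
  test$pred <- hard_labels
  key <- unique(test[, c("series_id", "meal_index")])
  alarms <- vector("list", nrow(key))
  for (r in seq_len(nrow(key))) {
    sel <- test$series_id == key$series_id[r] &
      test$meal_index == key$meal_index[r]
    pv <- integer(max(test$t[sel]))
    pv[test$t[sel]] <- test$pred[sel]
    gi <- meals$grid_index[meals$series_id == key$series_id[r] &
                             meals$meal_index == key$meal_index[r]]
    alarms[[r]] <- detect_alarms(pv, gi, series_id = key$series_id[r],
                                 meal_index = key$meal_index[r],
                                 events = events_by_series[[key$series_id[r]]])
  }
  out <- do.call(rbind, alarms)
  if (is.null(out)) {
    out <- data.frame(series_id = character(), meal_index = integer(),
                      alarm_minute = numeric(), t_first = integer(),
                      run_length = integer(), stringsAsFactors = FALSE)
  }
  out
}

#' Per-family mean and standard deviation across folds
#'
#' `NA` metric values (undefined ratios in a fold) are omitted from that
#' metric's average, and the summary means equal the arithmetic mean of the
#' per-fold values.
#'
#' @param folds_df The `folds` table of a [run_experiment()] result.
#' @return A data.frame with one `mean` and one `sd` column per metric,
#'   one row per family.
#' @export
summarize_folds <- function(folds_df) {
  metrics <- c("sens", "spec", "precision", "f1", "auc", "NH", "TP_e",
               "FP_e", "FAR", "DT", "severe_alarmed", "severe_missed",
               "near_hypo_fa_frac")
  fams <- unique(folds_df$family)
  out <- lapply(fams, function(fam) {
    sub <- folds_df[folds_df$family == fam, , drop = FALSE]
    row <- list(family = fam)
    for (m in metrics) {
      row[[paste0(m, "_mean")]] <- mean(sub[[m]], na.rm = TRUE)
      row[[paste0(m, "_sd")]] <- stats::sd(sub[[m]], na.rm = TRUE)
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @export
print.pphypo_experiment <- function(x, ...) {
  cat(sprintf(
    "<pphypo_experiment: %d series, %d samples (%d positive, %.1f:1), %d folds x %d families>\n",
    x$data_info$n_series, x$data_info$n_samples, x$data_info$n_pos,
    x$data_info$imbalance, max(x$folds$fold), length(unique(x$folds$family))
  ))
  show <- x$summary[, c("family", "auc_mean", "sens_mean", "spec_mean",
                        "f1_mean", "FAR_mean", "DT_mean")]
  print(show, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Paired per-fold comparison of two experiment reports
#'
#' @param a,b Results of [run_experiment()] with the same fold structure
#'   (e.g. a feature ablation on the same cohort and seed).
#' @param family Family to compare (default `"rf"`).
#' @return A list with `per_fold` (fold, metric deltas a - b) and
#'   `mean_delta` (named vector).
#' @export
compare_runs <- function(a, b, family = "rf") {
  fa <- a$folds[a$folds$family == family, , drop = FALSE]
  fb <- b$folds[b$folds$family == family, , drop = FALSE]
  if (!identical(fa$fold, fb$fold)) {
    stop("fold structures differ; compare runs on the same cohort and seed",
         call. = FALSE)
  }
  metrics <- c("sens", "spec", "precision", "f1", "auc", "TP_e", "FP_e",
               "FAR", "DT")
  deltas <- fa[, metrics] - fb[, metrics]
  deltas <- cbind(fold = fa$fold, deltas)
  list(per_fold = deltas, mean_delta = colMeans(deltas[, metrics], na.rm = TRUE))
}
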