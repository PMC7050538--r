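#' The 13 built-in settings of the benchmark grid
#'
#' The full hyperparameter grid of the validation study: the depth series
#' HL4..HL1 at a constant 8000 total hidden neurons, the width series
#' HL1/2..HL1/16 halving a single hidden layer, the mini-batch series
#' HL4//2 and HL4//4 (batch 100/k), and the LOG variants that add a
#' log(1+x) transform of the descriptor counts. The reference setting is
#' HL4: hidden layers 4000, 2000, 1000, 1000 with dropout 25, 25, 25, 10 %,
#' mini-batch 100, no log transform.
#'
#' @return a named list of 13 [dnn_setting()] objects.
#' @export
builtin_settings <- function() {
  hl4 <- c(4000L, 2000L, 1000L, 1000L)
  dr4 <- c(25, 25, 25, 10)
  s <- list(
    dnn_setting("HL4",        hl4,                     dr4,          100L, FALSE),
    dnn_setting("HL3",        c(4000L, 2500L, 1500L),  c(25, 25, 10), 100L, FALSE),
    dnn_setting("HL2",        c(6000L, 2000L),         c(25, 10),     100L, FALSE),
    dnn_setting("HL1",        8000L,                   10,            100L, FALSE),
    dnn_setting("HL1/2",      4000L,                   10,            100L, FALSE),
    dnn_setting("HL1/4",      2000L,                   10,            100L, FALSE),
    dnn_setting("HL1/8",      1000L,                   10,            100L, FALSE),
    dnn_setting("HL1/16",     500L,                    10,            100L, FALSE),
    dnn_setting("HL4//2",     hl4,                     dr4,           50L, FALSE),
    dnn_setting("HL4//4",     hl4,                     dr4,           25L, FALSE),
    dnn_setting("LOG HL4",    hl4,                     dr4,          100L, TRUE),
    dnn_setting("LOG HL4//2", hl4,                     dr4,           50L, TRUE),
    dnn_setting("LOG HL4//4", hl4,                     dr4,           25L, TRUE)
  )
  stats::setNames(s, vapply(s, `[[`, character(1), "name"))
}

# Best value and first-maximizer epoch of an R^2 trace.
trace_best <- function(trace) {
  best_epoch <- which.max(trace)
  list(best_r2 = trace[best_epoch], best_epoch = as.integer(best_epoch))
}

#' One training run under the best-epoch protocol
#'
#' Trains a freshly initialized model on the aligned training split for
#' `config$epochs` epochs. After every epoch the test-set squared Pearson
#' correlation is evaluated with dropout disabled, giving a dense R^2
#' trace; the run's score is the best value in the trace (first maximizer
#' on ties). Selecting the epoch on the test trace is deliberate protocol
#' replication -- it is an oracle-epoch score, not a blind-test estimate --
#' so the final-epoch value is also recorded for honest use.
#'
#' If `setting$log_transform` is set, both splits are log(1+x)-transformed
#' before training. Initialization draws from a stream seeded with `seed`,
#' shuffling and dropout masks from an independent stream seeded with
#' `seed + 1000003`.
#'
#' @param dataset an [align_vocabularies()] result.
#' @param setting a [dnn_setting()].
#' @param config a [train_config()].
#' @param seed integer seed of this run.
#' @return an object of class `run_result`: list with `r2_trace`,
#'   `best_r2`, `best_epoch`, `final_r2`, `train_mse_trace`, `seed`,
#'   `setting_name`.
#' @export
run_single <- function(dataset, setting, config = train_config(), seed = config$base_seed) {
  stopifnot(inherits(dataset, "aligned_dataset"), inherits(setting, "dnn_setting"),
            inherits(config, "train_config"))
  train <- dataset$train
  test <- dataset$test
  if (setting$log_transform) {
    train <- log_transform(train)
    test <- log_transform(test)
  }
  model <- build_model(setting, ncol(train$descriptors), seed = seed)
  shuffle_stream <- rng_stream(seed + 1000003L)
  opt_state <- NULL
  r2_trace <- numeric(config$epochs)
  mse_trace <- numeric(config$epochs)
  for (epoch in seq_len(config$epochs)) {
    step <- train_one_epoch(model, train, setting, config, opt_state, shuffle_stream)
    model <- step$model
    opt_state <- step$opt_state
    pred_test <- dnn_forward(model, test$descriptors, dropout = FALSE)$yhat
    r2_trace[epoch] <- suppressWarnings(r_squared(test$activities, pred_test))
    pred_train <- dnn_forward(model, train$descriptors, dropout = FALSE)$yhat
    mse_trace[epoch] <- mse(train$activities, pred_train)
  }
  best <- trace_best(r2_trace)
  structure(
    list(r2_trace = r2_trace,
         best_r2 = best$best_r2,
         best_epoch = best$best_epoch,
         final_r2 = r2_trace[config$epochs],
         train_mse_trace = mse_trace,
         seed = as.integer(seed),
         setting_name = setting$name),
    class = "run_result"
  )
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf("<run_result %s seed %d: best R2 %.4f @ epoch %d (final %.4f)>\n",
              x$setting_name, x$seed, x$best_r2, x$best_epoch, x$final_r2))
  invisible(x)
}

#' Repeated runs of one setting on one target
#'
#' Performs `config$n_runs` independent [run_single()] runs with seeds
#' `config$base_seed + 0 .. n_runs - 1` and averages their best-epoch R^2
#' values; that mean is the setting's "R^2 performance" on the target.
#'
#' @inheritParams run_single
#' @return an object of class `setting_result`: list with `runs`,
#'   `mean_best_r2`, `mean_final_r2`, `setting_name`.
#' @export
run_setting <- function(dataset, setting, config = train_config()) {
  runs <- lapply(seq_len(config$n_runs) - 1L, function(r) {
    run_single(dataset, setting, config, seed = config$base_seed + r)
  })
  structure(
    list(runs = runs,
         mean_best_r2 = mean(vapply(runs, `[[`, numeric(1), "best_r2")),
         mean_final_r2 = mean(vapply(runs, `[[`, numeric(1), "final_r2")),
         setting_name = setting$name),
    class = "setting_result"
  )
}

#' @export
print.setting_result <- function(x, ...) {
  cat(sprintf("<setting_result %s: mean best R2 %.4f over %d runs>\n",
              x$setting_name, x$mean_best_r2, length(x$runs)))
  invisible(x)
}

#' Run the full settings-by-targets benchmark grid
#'
#' Evaluates every setting on every target dataset with [run_setting()] and
#' assembles the report: a cell matrix of mean best-epoch R^2 values
#' (settings as rows, targets as columns), a per-setting overall average
#' across targets (the "Average" column), and a per-target standard
#' deviation across settings (the "Std. Dev." row). A matching cell matrix
#' of mean final-epoch R^2 values is kept alongside as the leakage-free
#' companion score.
#'
#' @param datasets named list of [align_vocabularies()] results, one per
#'   target.
#' @param settings list of [dnn_setting()] objects (default the built-in
#'   13-setting grid).
#' @param config a [train_config()].
#' @param run_logs if a directory path, per-run JSON logs (seed, setting,
#'   full traces) are written there so every reported mean is auditable.
#' @return an object of class `benchmark_report`; see
#'   [report_table()] for serialization.
#' @export
run_grid <- function(datasets, settings = builtin_settings(),
                     config = train_config(), run_logs = NULL) {
  if (length(datasets) < 1L) stop("need at least one target dataset")
  if (is.null(names(datasets)) || any(!nzchar(names(datasets)))) {
    stop("datasets must be a named list (one name per target)")
  }
  missing <- names(datasets)[!vapply(datasets, inherits, logical(1), "aligned_dataset")]
  if (length(missing) > 0L) {
    stop("not aligned datasets: ", paste(missing, collapse = ", "))
  }
  if (length(settings) < 1L) stop("need at least one setting")
  setting_names <- vapply(settings, `[[`, character(1), "name")
  targets <- names(datasets)

  cells <- matrix(NA_real_, nrow = length(settings), ncol = length(targets),
                  dimnames = list(setting_names, targets))
  final_cells <- cells
  for (tg in targets) {
    for (k in seq_along(settings)) {
      res <- run_setting(datasets[[tg]], settings[[k]], config)
      cells[k, tg] <- res$mean_best_r2
      final_cells[k, tg] <- res$mean_final_r2
      if (!is.null(run_logs)) {
        dir.create(run_logs, recursive = TRUE, showWarnings = FALSE)
        for (run in res$runs) {
          log_path <- file.path(run_logs, sprintf("%s_%s_seed%d.json",
                                                  gsub("[^A-Za-z0-9]+", "-", tg),
                                                  gsub("[^A-Za-z0-9]+", "-", setting_names[k]),
                                                  run$seed))
          jsonlite::write_json(
            list(target = tg, setting = run$setting_name, seed = run$seed,
                 best_r2 = run$best_r2, best_epoch = run$best_epoch,
                 final_r2 = run$final_r2, r2_trace = run$r2_trace,
                 train_mse_trace = run$train_mse_trace),
            log_path, digits = NA, auto_unbox = TRUE)
        }
      }
    }
  }
  structure(
    list(cells = cells,
         final_cells = final_cells,
         setting_average = rowMeans(cells),
         target_sd = apply(cells, 2L, stats::sd),
         config = config),
    class = "benchmark_report"
  )
}

#' Report as a data frame (or TSV / Markdown text)
#'
#' Lays the report out like the study's summary table: one row per setting
#' with the per-target mean best-epoch R^2 cells and the overall Average
#' column, plus a final "Std. Dev." row holding the per-target standard
#' deviation across settings.
#'
#' @param report a [run_grid()] result.
#' @param format `"data.frame"`, `"tsv"` or `"markdown"`.
#' @param digits rounding for the text formats.
#' @return a data.frame, or a single string in the requested text format.
#' @export
report_table <- function(report, format = c("data.frame", "tsv", "markdown"),
                         digits = 4L) {
  stopifnot(inherits(report, "benchmark_report"))
  format <- match.arg(format)
  cells <- report$cells
  df <- data.frame(Setting = rownames(cells), as.data.frame(cells),
                   Average = report$setting_average,
                   check.names = FALSE, row.names = NULL)
  sd_row <- data.frame(Setting = "Std. Dev.",
                       as.data.frame(t(report$target_sd)),
                       Average = NA_real_,
                       check.names = FALSE, row.names = NULL)
  df <- rbind(df, sd_row)
  if (format == "data.frame") return(df)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) ifelse(is.na(x), "", sprintf("%.*f", digits, x)))
  if (format == "tsv") {
    lines <- c(paste(names(df), collapse = "\t"),
               apply(df, 1L, paste, collapse = "\t"))
    return(paste0(paste(lines, collapse = "\n"), "\n"))
  }
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(df, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  paste0(paste(c(header, sep, rows), collapse = "\n"), "\n")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf("<benchmark_report: %d settings x %d targets (oracle-epoch scores)>\n",
              nrow(x$cells), ncol(x$cells)))
  print(report_table(x), digits = 4)
  invisible(x)
}
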