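test_that("the built-in grid reproduces the declared 13 settings", {
  s <- builtin_settings()
  expect_length(s, 13L)
  expect_equal(names(s),
               c("HL4", "HL3", "HL2", "HL1", "HL1/2", "HL1/4", "HL1/8",
                 "HL1/16", "HL4//2", "HL4//4", "LOG HL4", "LOG HL4//2",
                 "LOG HL4//4"))
  expect_equal(s[["HL2"]]$hidden_sizes, c(6000L, 2000L))
  expect_equal(s[["HL2"]]$dropout_percents, c(25, 10))
  expect_equal(s[["HL2"]]$minibatch_size, 100L)
  expect_false(s[["HL2"]]$log_transform)
  expect_equal(s[["LOG HL4//4"]]$hidden_sizes, c(4000L, 2000L, 1000L, 1000L))
  expect_equal(s[["LOG HL4//4"]]$minibatch_size, 25L)
  expect_true(s[["LOG HL4//4"]]$log_transform)
  # depth series totals 8000 hidden neurons
  for (nm in c("HL4", "HL3", "HL2", "HL1")) {
    expect_equal(sum(s[[nm]]$hidden_sizes), 8000L)
  }
  # batch-size series quarters the updates
  expect_equal(s[["HL4//4"]]$minibatch_size, s[["HL4"]]$minibatch_size / 4L)
})

test_that("the best-epoch rule takes the first maximizer", {
  tb <- qsardnn:::trace_best(c(0.1, 0.5, 0.3, 0.5, 0.2))
  expect_equal(tb$best_r2, 0.5)
  expect_equal(tb$best_epoch, 2L)
  tb2 <- qsardnn:::trace_best(0.42)
  expect_equal(tb2$best_epoch, 1L)
})

test_that("run_single traces every epoch and records the best", {
  al <- tiny_aligned(seed = 2)
  s <- dnn_setting("t", 16L, 10, minibatch_size = 40L)
  cfg <- train_config(epochs = 1, n_runs = 1, base_seed = 5)
  rr <- run_single(al, s, cfg, seed = 5)
  expect_length(rr$r2_trace, 1L)
  expect_equal(rr$best_epoch, 1L)
  expect_equal(rr$best_r2, rr$r2_trace[1])
  cfg6 <- train_config(epochs = 6, n_runs = 1, base_seed = 5)
  rr6 <- run_single(al, s, cfg6, seed = 5)
  expect_length(rr6$r2_trace, 6L)
  expect_length(rr6$train_mse_trace, 6L)
  expect_equal(rr6$best_r2, max(rr6$r2_trace))
  expect_equal(rr6$best_epoch, which.max(rr6$r2_trace))
  expect_equal(rr6$final_r2, rr6$r2_trace[6])
  # training reduces the train MSE over epochs
  expect_lt(rr6$train_mse_trace[6], rr6$train_mse_trace[1])
})

test_that("run_setting averages the runs' best values over the seed series", {
  al <- tiny_aligned(seed = 3)
  s <- dnn_setting("t", 8L, 0, minibatch_size = 60L)
  cfg <- train_config(epochs = 3, n_runs = 2, base_seed = 11)
  res <- run_setting(al, s, cfg)
  expect_length(res$runs, 2L)
  expect_equal(vapply(res$runs, `[[`, integer(1), "seed"), c(11L, 12L))
  expect_equal(res$mean_best_r2,
               mean(vapply(res$runs, `[[`, numeric(1), "best_r2")))
  # n_runs = 1: the mean is that run's best
  cfg1 <- train_config(epochs = 3, n_runs = 1, base_seed = 11)
  res1 <- run_setting(al, s, cfg1)
  expect_equal(res1$mean_best_r2, res1$runs[[1]]$best_r2)
  # repeating the whole protocol reproduces it exactly
  res_again <- run_setting(al, s, cfg)
  expect_identical(res$mean_best_r2, res_again$mean_best_r2)
})

test_that("log-transform settings train on transformed descriptors", {
  al <- tiny_aligned(seed = 4)
  cfg <- train_config(epochs = 2, n_runs = 1, base_seed = 2)
  s_raw <- dnn_setting("raw", 8L, 0, 60L, log_transform = FALSE)
  s_log <- dnn_setting("log", 8L, 0, 60L, log_transform = TRUE)
  r_raw <- run_single(al, s_raw, cfg, seed = 2)
  r_log <- run_single(al, s_log, cfg, seed = 2)
  # same seeds, different inputs: trajectories must differ
  expect_false(identical(r_raw$r2_trace, r_log$r2_trace))
})

test_that("grid reports are complete and their aggregates recompute", {
  datasets <- list(T1 = tiny_aligned(seed = 6), T2 = tiny_aligned(seed = 7))
  settings <- list(dnn_setting("A", 8L, 0, 60L),
                   dnn_setting("B", 8L, 0, 30L))
  cfg <- train_config(epochs = 2, n_runs = 2, base_seed = 1)
  logs <- withr::local_tempdir()
  rep <- run_grid(datasets, settings, cfg, run_logs = logs)
  expect_equal(dim(rep$cells), c(2L, 2L))
  expect_false(anyNA(rep$cells))
  expect_equal(rep$setting_average, rowMeans(rep$cells))
  expect_equal(rep$target_sd, apply(rep$cells, 2, sd))
  # every run left an auditable JSON log
  expect_length(list.files(logs, pattern = "\\.json$"), 2 * 2 * 2)
  log1 <- jsonlite::read_json(list.files(logs, full.names = TRUE)[1],
                              simplifyVector = TRUE)
  expect_length(log1$r2_trace, 2L)
  # single cell grid equals run_setting's mean
  rep1 <- run_grid(datasets["T1"], settings[1], cfg)
  expect_equal(unname(rep1$cells[1, 1]),
               run_setting(datasets$T1, settings[[1]], cfg)$mean_best_r2)
  # degenerate std dev: identical rows give zero spread
  repx <- rep
  repx$cells[2, ] <- repx$cells[1, ]
  expect_equal(unname(apply(repx$cells, 2, sd)), c(0, 0))
  expect_error(run_grid(unname(datasets), settings, cfg), "named list")
  expect_error(run_grid(list(T1 = "nope"), settings, cfg), "not aligned")
})

test_that("report serialization mirrors the summary-table layout", {
  datasets <- list(T1 = tiny_aligned(seed = 8))
  settings <- list(dnn_setting("A", 8L, 0, 60L))
  rep <- run_grid(datasets, settings, train_config(epochs = 1, n_runs = 1))
  df <- report_table(rep)
  expect_equal(df$Setting, c("A", "Std. Dev."))
  expect_equal(names(df), c("Setting", "T1", "Average"))
  expect_equal(df$Average[1], unname(rep$setting_average["A"]))
  tsv <- report_table(rep, "tsv")
  expect_match(tsv, "Setting\tT1\tAverage")
  md <- report_table(rep, "markdown")
  expect_match(md, "\\| Setting \\| T1 \\| Average \\|")
})

test_that("quartering the mini-batch quadruples updates, not evaluations", {
  n_train <- 1000L
  expect_equal(updates_per_epoch(n_train, 25L), 4L * updates_per_epoch(n_train, 100L))
  # the evaluation count is one per epoch regardless of batch size
  al <- tiny_aligned(seed = 9)
  cfg <- train_config(epochs = 3, n_runs = 1, base_seed = 1)
  for (bsz in c(120L, 30L)) {
    rr <- run_single(al, dnn_setting("t", 8L, 0, bsz), cfg, seed = 1)
    expect_length(rr$r2_trace, cfg$epochs)
  }
})
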