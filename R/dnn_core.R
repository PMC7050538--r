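#' One hyperparameter setting for the feed-forward QSAR regressor
#'
#' A setting bundles everything that varies across the benchmark grid: the
#' hidden-layer sizes, the per-hidden-layer dropout percentages, the
#' mini-batch size, and whether descriptor counts are log(1+x)-transformed
#' before training. The input layer always has 0 % dropout; the output is a
#' single linear neuron.
#'
#' @param name label used in reports, e.g. `"HL4//4"`.
#' @param hidden_sizes integer vector of hidden-layer widths (>= 1 each).
#' @param dropout_percents dropout rate per hidden layer, in percent,
#'   each in \[0, 100); same length as `hidden_sizes`.
#' @param minibatch_size molecules per parameter update (>= 1).
#' @param log_transform apply [log_transform()] to both splits before
#'   training?
#' @return an object of class `dnn_setting`.
#' @export
dnn_setting <- function(name, hidden_sizes, dropout_percents,
                        minibatch_size = 100L, log_transform = FALSE) {
  hidden_sizes <- as.integer(hidden_sizes)
  dropout_percents <- as.numeric(dropout_percents)
  if (length(hidden_sizes) == 0L || any(hidden_sizes < 1L)) {
    stop("hidden_sizes must be a non-empty vector of positive integers")
  }
  if (length(dropout_percents) != length(hidden_sizes)) {
    stop("dropout_percents must match hidden_sizes in length")
  }
  if (any(dropout_percents < 0 | dropout_percents >= 100)) {
    stop("dropout_percents must lie in [0, 100)")
  }
  minibatch_size <- as.integer(minibatch_size)
  if (is.na(minibatch_size) || minibatch_size < 1L) {
    stop("minibatch_size must be >= 1")
  }
  structure(
    list(name = as.character(name),
         hidden_sizes = hidden_sizes,
         dropout_percents = dropout_percents,
         minibatch_size = minibatch_size,
         log_transform = isTRUE(log_transform)),
    class = "dnn_setting"
  )
}

#' @export
print.dnn_setting <- function(x, ...) {
  cat(sprintf("<dnn_setting %s: hidden [%s], dropout%% [%s], batch %d, log %s>\n",
              x$name,
              paste(x$hidden_sizes, collapse = ", "),
              paste(x$dropout_percents, collapse = ", "),
              x$minibatch_size,
              if (x$log_transform) "yes" else "no"))
  invisible(x)
}

#' Training-protocol configuration
#'
#' Epoch count, number of repeated runs, base seed, and the Adam optimizer
#' constants. Defaults follow the benchmark protocol (1000 epochs, 5 runs)
#' and the customary Adam constants (alpha 0.001, beta1 0.9, beta2 0.999,
#' epsilon 1e-8). Run r uses seed `base_seed + r - 1`; within a run,
#' initialization and data shuffling draw from separate streams derived
#' from that seed.
#'
#' @param epochs training epochs per run (>= 1).
#' @param n_runs independent randomly initialized runs per setting (>= 1).
#' @param base_seed integer seed of the first run.
#' @param adam_alpha,adam_beta1,adam_beta2,adam_epsilon Adam constants.
#' @return an object of class `train_config`.
#' @export
train_config <- function(epochs = 1000L, n_runs = 5L, base_seed = 1L,
                         adam_alpha = 0.001, adam_beta1 = 0.9,
                         adam_beta2 = 0.999, adam_epsilon = 1e-8) {
  epochs <- as.integer(epochs)
  n_runs <- as.integer(n_runs)
  if (is.na(epochs) || epochs < 1L) stop("epochs must be >= 1")
  if (is.na(n_runs) || n_runs < 1L) stop("n_runs must be >= 1")
  structure(
    list(epochs = epochs, n_runs = n_runs, base_seed = as.integer(base_seed),
         adam_alpha = adam_alpha, adam_beta1 = adam_beta1,
         adam_beta2 = adam_beta2, adam_epsilon = adam_epsilon),
    class = "train_config"
  )
}

#' Build a randomly initialized feed-forward regression model
#'
#' Fully connected network: hidden layers of the sizes in `setting`, each
#' with ReLU activation and (inverted) dropout at the setting's rate, then
#' a single linear output neuron. Weights are He-initialized -- normal with
#' standard deviation sqrt(2 / fan_in) -- and biases start at zero; there
#' is no unsupervised pre-training. Initialization draws only from the
#' stream seeded by `seed`, so a model is reproducible independent of any
#' surrounding RNG use.
#'
#' @param setting a [dnn_setting()].
#' @param input_dim number of descriptor columns (>= 1).
#' @param seed integer seed for the initialization stream.
#' @return an object of class `qsar_dnn` holding weight matrices `W`,
#'   bias vectors `b`, and the architecture descriptor.
#' @export
build_model <- function(setting, input_dim, seed) {
  stopifnot(inherits(setting, "dnn_setting"))
  input_dim <- as.integer(input_dim)
  if (is.na(input_dim) || input_dim < 1L) stop("input_dim must be >= 1")
  sizes <- c(input_dim, setting$hidden_sizes, 1L)
  init <- rng_stream(seed)
  W <- vector("list", length(sizes) - 1L)
  b <- vector("list", length(sizes) - 1L)
  with_stream(init, {
    for (l in seq_along(W)) {
      fan_in <- sizes[l]
      W[[l]] <- matrix(stats::rnorm(fan_in * sizes[l + 1L], sd = sqrt(2 / fan_in)),
                       nrow = fan_in, ncol = sizes[l + 1L])
      b[[l]] <- numeric(sizes[l + 1L])
    }
  })
  structure(
    list(W = W, b = b,
         input_dim = input_dim,
         hidden_sizes = setting$hidden_sizes,
         dropout_percents = setting$dropout_percents,
         activation = "relu"),
    class = "qsar_dnn"
  )
}

#' @export
print.qsar_dnn <- function(x, ...) {
  cat(sprintf("<qsar_dnn: %d -> %s -> 1, ReLU, dropout%% [%s]>\n",
              x$input_dim,
              paste(x$hidden_sizes, collapse = " -> "),
              paste(x$dropout_percents, collapse = ", ")))
  invisible(x)
}

#' Number of parameter updates per training epoch
#'
#' The training set is partitioned into mini-batches of `minibatch_size`
#' molecules; one Adam update is performed per mini-batch, so the number of
#' updates per epoch is `n_train / minibatch_size`, taken as a ceiling
#' because the final partial batch is also trained on. Halving the batch
#' size therefore doubles the updates per epoch at a fixed epoch count.
#'
#' @param n_train number of training molecules (>= 1).
#' @param minibatch_size mini-batch size (>= 1).
#' @return an integer count of updates.
#' @examples
#' updates_per_epoch(1000, 100)  # 10
#' updates_per_epoch(1000, 25)   # 40
#' @export
updates_per_epoch <- function(n_train, minibatch_size) {
  n_train <- as.integer(n_train)
  minibatch_size <- as.integer(minibatch_size)
  if (is.na(n_train) || n_train < 1L) stop("n_train must be >= 1")
  if (is.na(minibatch_size) || minibatch_size < 1L) stop("minibatch_size must be >= 1")
  as.integer(ceiling(n_train / minibatch_size))
}

# Forward pass. When `dropout` is TRUE, hidden activations are masked with
# inverted dropout (mask / keep-probability), drawing masks from the
# current RNG state; caller is responsible for stream management. Returns
# the prediction vector and, if `keep_cache`, the per-layer activations
# and masks needed for backpropagation.
dnn_forward <- function(model, X, dropout = FALSE, keep_cache = FALSE) {
  nh <- length(model$hidden_sizes)
  A <- X
  cache <- if (keep_cache) list(A = vector("list", nh + 1L),
                                Z = vector("list", nh),
                                M = vector("list", nh)) else NULL
  if (keep_cache) cache$A[[1L]] <- A
  for (l in seq_len(nh)) {
    Z <- A %*% model$W[[l]]
    Z <- sweep(Z, 2L, model$b[[l]], "+")
    H <- pmax(Z, 0)
    if (dropout && model$dropout_percents[l] > 0) {
      keep <- 1 - model$dropout_percents[l] / 100
      M <- matrix(stats::rbinom(length(H), 1L, keep), nrow = nrow(H)) / keep
      H <- H * M
    } else {
      M <- NULL
    }
    A <- H
    if (keep_cache) {
      cache$Z[[l]] <- Z
      cache$M[l] <- list(M)  # keep the slot even when the mask is NULL
      cache$A[[l + 1L]] <- A
    }
  }
  out_l <- nh + 1L
  yhat <- drop(A %*% model$W[[out_l]] + model$b[[out_l]])
  list(yhat = yhat, cache = cache)
}

# Backpropagation of the MSE loss through the cached forward pass.
# Returns gradients in the same list shapes as model$W / model$b.
dnn_backward <- function(model, cache, yhat, y) {
  nh <- length(model$hidden_sizes)
  bsz <- length(y)
  gW <- vector("list", nh + 1L)
  gb <- vector("list", nh + 1L)
  delta <- matrix(2 * (yhat - y) / bsz, ncol = 1L)
  gW[[nh + 1L]] <- crossprod(cache$A[[nh + 1L]], delta)
  gb[[nh + 1L]] <- colSums(delta)
  up <- delta %*% t(model$W[[nh + 1L]])
  for (l in rev(seq_len(nh))) {
    if (!is.null(cache$M[[l]])) up <- up * cache$M[[l]]
    up <- up * (cache$Z[[l]] > 0)
    gW[[l]] <- crossprod(cache$A[[l]], up)
    gb[[l]] <- colSums(up)
    if (l > 1L) up <- up %*% t(model$W[[l]])
  }
  list(W = gW, b = gb)
}

adam_init <- function(model) {
  zeros_like <- function(p) if (is.matrix(p)) matrix(0, nrow(p), ncol(p)) else numeric(length(p))
  list(t = 0L,
       mW = lapply(model$W, zeros_like), vW = lapply(model$W, zeros_like),
       mb = lapply(model$b, zeros_like), vb = lapply(model$b, zeros_like))
}

adam_step <- function(model, grads, opt, config) {
  a <- config$adam_alpha; b1 <- config$adam_beta1
  b2 <- config$adam_beta2; eps <- config$adam_epsilon
  opt$t <- opt$t + 1L
  corr1 <- 1 - b1^opt$t
  corr2 <- 1 - b2^opt$t
  for (l in seq_along(model$W)) {
    opt$mW[[l]] <- b1 * opt$mW[[l]] + (1 - b1) * grads$W[[l]]
    opt$vW[[l]] <- b2 * opt$vW[[l]] + (1 - b2) * grads$W[[l]]^2
    model$W[[l]] <- model$W[[l]] -
      a * (opt$mW[[l]] / corr1) / (sqrt(opt$vW[[l]] / corr2) + eps)
    opt$mb[[l]] <- b1 * opt$mb[[l]] + (1 - b1) * grads$b[[l]]
    opt$vb[[l]] <- b2 * opt$vb[[l]] + (1 - b2) * grads$b[[l]]^2
    model$b[[l]] <- model$b[[l]] -
      a * (opt$mb[[l]] / corr1) / (sqrt(opt$vb[[l]] / corr2) + eps)
  }
  list(model = model, opt = opt)
}

check_width <- function(model, X) {
  if (ncol(X) != model$input_dim) {
    stop(sprintf("model expects %d descriptor columns, table has %d",
                 model$input_dim, ncol(X)))
  }
}

#' Train a model for one epoch
#'
#' One epoch: the training molecules are reshuffled (from `shuffle_stream`),
#' partitioned into mini-batches of `setting$minibatch_size` (the final
#' batch may be partial and is trained on), and one Adam update of the MSE
#' loss -- with dropout active -- is performed per mini-batch.
#'
#' @param model a [build_model()] result.
#' @param train an [activity_table()] whose descriptor width matches the
#'   model's input width.
#' @param setting the [dnn_setting()] (for the mini-batch size and dropout).
#' @param config a [train_config()] (for the Adam constants).
#' @param opt_state Adam state from a previous epoch, or `NULL` to start.
#' @param shuffle_stream RNG stream (from the internal stream constructor)
#'   driving the shuffle and the dropout masks; pass the same object across
#'   epochs to continue its sequence.
#' @return list with updated `model` and `opt_state`.
#' @export
train_one_epoch <- function(model, train, setting, config = train_config(),
                            opt_state = NULL, shuffle_stream = NULL) {
  stopifnot(inherits(model, "qsar_dnn"), inherits(train, "activity_table"),
            inherits(setting, "dnn_setting"))
  X <- train$descriptors
  y <- train$activities
  check_width(model, X)
  if (is.null(opt_state)) opt_state <- adam_init(model)
  if (is.null(shuffle_stream)) shuffle_stream <- rng_stream(0L)
  n <- nrow(X)
  bsz <- setting$minibatch_size
  with_stream(shuffle_stream, {
    perm <- sample.int(n)
    starts <- seq(1L, n, by = bsz)
    for (s in starts) {
      idx <- perm[s:min(s + bsz - 1L, n)]
      Xb <- X[idx, , drop = FALSE]
      yb <- y[idx]
      fwd <- dnn_forward(model, Xb, dropout = TRUE, keep_cache = TRUE)
      grads <- dnn_backward(model, fwd$cache, fwd$yhat, yb)
      upd <- adam_step(model, grads, opt_state, config)
      model <- upd$model
      opt_state <- upd$opt
    }
  })
  list(model = model, opt_state = opt_state)
}

#' Predict activities for an activity table
#'
#' Deterministic forward pass with dropout disabled (inverted dropout means
#' no rescaling is needed at evaluation time).
#'
#' @param object a `qsar_dnn` model.
#' @param table an [activity_table()] with matching descriptor width.
#' @param ... unused.
#' @return numeric vector, one predicted activity per molecule.
#' @export
predict.qsar_dnn <- function(object, table, ...) {
  stopifnot(inherits(table, "activity_table"))
  check_width(object, table$descriptors)
  dnn_forward(object, table$descriptors, dropout = FALSE)$yhat
}

#' Serialize model weights to a portable JSON file
#'
#' @param model a `qsar_dnn` model.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "qsar_dnn"))
  payload <- list(
    input_dim = model$input_dim,
    hidden_sizes = model$hidden_sizes,
    dropout_percents = model$dropout_percents,
    activation = model$activation,
    W = lapply(model$W, function(w) list(dim = dim(w), data = as.numeric(w))),
    b = model$b
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a model serialized by [write_model()]
#'
#' @param path JSON file written by [write_model()].
#' @return a `qsar_dnn` model.
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  W <- lapply(p$W, function(w) matrix(w$data, nrow = w$dim[1], ncol = w$dim[2]))
  structure(
    list(W = W, b = lapply(p$b, as.numeric),
         input_dim = as.integer(p$input_dim),
         hidden_sizes = as.integer(p$hidden_sizes),
         dropout_percents = as.numeric(p$dropout_percents),
         activation = p$activation),
    class = "qsar_dnn"
  )
}
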