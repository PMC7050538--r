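#' Specification of a synthetic molecular-activity dataset
#'
#' Describes a dataset with the statistical structure the benchmark
#' assumes: a sparse non-negative integer descriptor matrix with
#' heavy-tailed column frequencies (most substructures are rare, a few are
#' common), a train/test descriptor-vocabulary mismatch, a time-split-like
#' covariate shift of the test split, an activity mechanism of controllable
#' complexity, Gaussian measurement noise, and optional floor censoring
#' (assay dynamic range limits reported as a constant).
#'
#' The three mechanisms form a complexity ladder mirroring activity types:
#' `linear_logD_like` (a weighted sum of counts, partition-coefficient-like,
#' learnable without depth), `single_index_nonlinear` (a saturating
#' transform of one latent index, optionally pushed through the
#' Cheng-Prusoff relation with per-molecule substrate-concentration jitter,
#' pIC50-like), and `composed_multimechanism` (a product/ratio composition
#' of several latent sub-responses with heteroscedastic noise,
#' bioavailability-like and intentionally hard).
#'
#' @param n_train,n_test molecules per split.
#' @param n_descriptors descriptor columns per split.
#' @param zero_fraction expected fraction of zero entries, in (0,1).
#' @param count_dispersion negative-binomial overdispersion of the nonzero
#'   counts (0 = Poisson-like; larger = heavier count tail).
#' @param mechanism one of `"linear_logD_like"`, `"single_index_nonlinear"`,
#'   `"composed_multimechanism"`.
#' @param noise_sd standard deviation of the additive Gaussian activity
#'   noise (heteroscedastically scaled for the composed mechanism).
#' @param censor_floor if non-`NULL`, activities below this value are
#'   reported as exactly this value.
#' @param vocab_overlap fraction of the train vocabulary also present in
#'   the test vocabulary, in (0, 1]; the remaining test columns are novel.
#' @param shift_strength log-normal perturbation scale of the test split's
#'   column frequencies (0 = identically distributed splits).
#' @param seed integer seed; the whole dataset is a deterministic function
#'   of the spec.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_train = 1000L, n_test = 300L, n_descriptors = 400L,
                           zero_fraction = 0.9, count_dispersion = 0.6,
                           mechanism = c("linear_logD_like",
                                         "single_index_nonlinear",
                                         "composed_multimechanism"),
                           noise_sd = 0.25, censor_floor = NULL,
                           vocab_overlap = 0.8, shift_strength = 0.1,
                           seed = 1L) {
  mechanism <- match.arg(mechanism)
  n_train <- as.integer(n_train); n_test <- as.integer(n_test)
  n_descriptors <- as.integer(n_descriptors)
  if (n_train < 1L || n_test < 1L || n_descriptors < 1L) {
    stop("n_train, n_test and n_descriptors must all be >= 1")
  }
  if (!(zero_fraction > 0 && zero_fraction < 1)) stop("zero_fraction must be in (0,1)")
  if (count_dispersion < 0) stop("count_dispersion must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!(vocab_overlap > 0 && vocab_overlap <= 1)) stop("vocab_overlap must be in (0,1]")
  if (shift_strength < 0) stop("shift_strength must be >= 0")
  structure(
    list(n_train = n_train, n_test = n_test, n_descriptors = n_descriptors,
         zero_fraction = zero_fraction, count_dispersion = count_dispersion,
         mechanism = mechanism, noise_sd = noise_sd,
         censor_floor = censor_floor, vocab_overlap = vocab_overlap,
         shift_strength = shift_strength, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

# Per-column inclusion probabilities: power-law ranks rescaled so the
# expected zero fraction matches the spec, iterating to absorb clipping
# at 1.
column_frequencies <- function(n_columns, zero_fraction) {
  raw <- (seq_len(n_columns))^(-0.7)
  target <- (1 - zero_fraction) * n_columns
  q <- raw * target / sum(raw)
  for (it in 1:20) {
    over <- q >= 1
    if (!any(over)) break
    q[over] <- 1
    deficit <- target - sum(q[over])
    if (sum(!over) == 0L) break
    q[!over] <- q[!over] * deficit / sum(q[!over])
  }
  pmin(q, 1)
}

draw_count_matrix <- function(n_rows, q, count_dispersion) {
  n_cols <- length(q)
  m <- matrix(0L, n_rows, n_cols)
  size <- if (count_dispersion > 0) 1 / count_dispersion else Inf
  for (j in seq_len(n_cols)) {
    present <- stats::rbinom(n_rows, 1L, q[j]) == 1L
    k <- sum(present)
    if (k > 0L) {
      extra <- if (is.finite(size)) {
        stats::rnbinom(k, size = size, mu = 1)
      } else {
        stats::rpois(k, 1)
      }
      m[present, j] <- 1L + extra
    }
  }
  m
}

# Sparse coefficient vector over a vocabulary: 10 % of columns active,
# standard-normal weights. Active columns are sampled with probability
# proportional to their inclusion frequency: activity-driving
# substructures are common scaffolds, not one-off fragments, and a signal
# carried by a descriptor seen in a handful of training molecules would be
# unlearnable by any method.
sparse_beta <- function(n_columns, freq = rep(1, n_columns)) {
  beta <- numeric(n_columns)
  active <- sample.int(n_columns, size = max(1L, round(0.1 * n_columns)),
                       prob = freq)
  beta[active] <- stats::rnorm(length(active))
  beta
}

# Standardize a latent index on the training split and keep the affine
# map so the identical transformation applies to the test split.
standardizer <- function(train_index) {
  mu <- mean(train_index)
  sigma <- stats::sd(train_index)
  if (!is.finite(sigma) || sigma == 0) sigma <- 1
  list(center = mu, scale = sigma)
}

apply_standardizer <- function(index, st) (index - st$center) / st$scale

#' Noiseless activity of descriptor rows under a generating mechanism
#'
#' Applies the ground-truth count-to-activity map of a synthetic dataset.
#' `params` is the `mechanism_params` element of the [generate_dataset()]
#' ground truth; rows must be ordered like the training vocabulary it was
#' built for (novel test-only descriptors carry no signal and are ignored
#' by passing zero).
#'
#' For `single_index_nonlinear`, the latent pKi-like index is pushed
#' through the Cheng-Prusoff relation with a per-molecule substrate ratio
#' `[S]/Km` supplied via `substrate_ratio` (default 0, which collapses
#' IC50 to Ki and the activity to the pKi-like value).
#'
#' @param counts numeric vector (one molecule) or matrix (molecules in
#'   rows) of descriptor counts in training-vocabulary order.
#' @param mechanism mechanism name, as in [synthetic_spec()].
#' @param params mechanism parameters from the ground truth.
#' @param substrate_ratio `[S]/Km` per molecule (scalar or one per row);
#'   only used by `single_index_nonlinear`.
#' @return numeric vector of noiseless activities, one per row.
#' @export
mechanism_activity <- function(counts, mechanism, params, substrate_ratio = 0) {
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L)
  if (mechanism == "linear_logD_like") {
    drop(params$intercept + counts %*% params$beta)
  } else if (mechanism == "single_index_nonlinear") {
    z <- apply_standardizer(drop(counts %*% params$beta), params$standardize)
    pki <- params$level + params$amplitude * tanh(z)
    # compose through the Cheng-Prusoff relation: Ki = 10^-pKi (M),
    # IC50 = Ki (1 + [S]/Km), activity reported as pIC50 = -log10 IC50
    ic50 <- cheng_prusoff_ic50(10^(-pki), substrate_conc = substrate_ratio, Km = 1)
    -log10(ic50)
  } else if (mechanism == "composed_multimechanism") {
    u <- lapply(1:3, function(k) {
      stats::plogis(apply_standardizer(drop(counts %*% params$betas[[k]]),
                                       params$standardize[[k]]))
    })
    log10(1 + 100 * u[[1]] * u[[2]] * (1 - u[[3]]))
  } else {
    stop("unknown mechanism: ", mechanism)
  }
}

# Heteroscedastic noise scale of the composed mechanism (the third latent
# sub-response inflates the noise, emulating in vivo variability).
composed_noise_scale <- function(counts, params) {
  u3 <- stats::plogis(apply_standardizer(drop(counts %*% params$betas[[3]]),
                                         params$standardize[[3]]))
  0.5 + u3
}

#' Generate a synthetic train/test dataset with known ground truth
#'
#' Draws descriptor counts as negative-binomial values thinned by
#' per-column Bernoulli inclusion, with inclusion probabilities following
#' a power law over column ranks (heavy-tailed substructure frequencies).
#' The test split shares `vocab_overlap` of the training vocabulary, gains
#' novel columns for the remainder (exercising [align_vocabularies()]),
#' and its column frequencies are log-normally perturbed by
#' `shift_strength` to emulate a time-series split's covariate shift.
#' Activities are the mechanism applied to the counts plus Gaussian noise;
#' if `censor_floor` is set, lower activities are reported as the floor.
#'
#' @param spec a [synthetic_spec()].
#' @return a list with `train` and `test` ([activity_table()] objects,
#'   un-aligned vocabularies) and `truth`: a `ground_truth` list holding
#'   `mechanism`, `mechanism_params`, the noiseless activities of both
#'   splits, the drawn substrate ratios (single-index mechanism), and the
#'   train vocabulary. The result is a bit-exact function of the spec.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  stream <- rng_stream(spec$seed)
  with_stream(stream, {
    n_shared <- max(1L, round(spec$vocab_overlap * spec$n_descriptors))
    n_novel <- spec$n_descriptors - n_shared
    width <- max(nchar(as.character(spec$n_descriptors + n_novel)), 4L)
    pool <- sprintf(paste0("D%0", width, "d"), seq_len(spec$n_descriptors + n_novel))
    train_vocab <- pool[seq_len(spec$n_descriptors)]
    test_vocab <- c(pool[seq_len(n_shared)],
                    if (n_novel > 0L) pool[spec$n_descriptors + seq_len(n_novel)])

    q_train <- column_frequencies(spec$n_descriptors, spec$zero_fraction)
    shift <- exp(spec$shift_strength * stats::rnorm(spec$n_descriptors))
    q_test_shared <- pmin(q_train[seq_len(n_shared)] * shift[seq_len(n_shared)], 1)
    q_test_novel <- if (n_novel > 0L) {
      pmin(q_train[n_shared + seq_len(n_novel)] *
             shift[n_shared + seq_len(n_novel)], 1)
    } else numeric(0)

    X_train <- draw_count_matrix(spec$n_train, q_train, spec$count_dispersion)
    colnames(X_train) <- train_vocab
    X_test <- draw_count_matrix(spec$n_test, c(q_test_shared, q_test_novel),
                                spec$count_dispersion)
    colnames(X_test) <- test_vocab

    # mechanism parameters live on the training vocabulary; novel test
    # descriptors carry no signal, and test rows have zero in the
    # train-only columns they genuinely lack
    X_test_on_train_vocab <- matrix(0, spec$n_test, spec$n_descriptors,
                                    dimnames = list(NULL, train_vocab))
    X_test_on_train_vocab[, seq_len(n_shared)] <- X_test[, seq_len(n_shared)]

    params <- switch(
      spec$mechanism,
      linear_logD_like = {
        beta <- sparse_beta(spec$n_descriptors, q_train)
        st <- standardizer(drop(X_train %*% beta))
        # rescale so the training activities sit in a log D-like window
        # (location 2.5, unit signal scale)
        list(beta = beta / st$scale, intercept = 2.5 - st$center / st$scale)
      },
      single_index_nonlinear = {
        beta <- sparse_beta(spec$n_descriptors, q_train)
        list(beta = beta, standardize = standardizer(drop(X_train %*% beta)),
             level = 6.5, amplitude = 1.5)
      },
      composed_multimechanism = {
        betas <- lapply(1:3, function(k) sparse_beta(spec$n_descriptors, q_train))
        list(betas = betas,
             standardize = lapply(betas, function(b) standardizer(drop(X_train %*% b))))
      }
    )

    substrate_ratio_train <- substrate_ratio_test <- 0
    if (spec$mechanism == "single_index_nonlinear") {
      # per-molecule assay-condition jitter: [S]/Km log-normal around 1
      substrate_ratio_train <- stats::rlnorm(spec$n_train, 0, 0.5)
      substrate_ratio_test <- stats::rlnorm(spec$n_test, 0, 0.5)
    }

    clean_train <- mechanism_activity(X_train, spec$mechanism, params,
                                      substrate_ratio_train)
    clean_test <- mechanism_activity(X_test_on_train_vocab, spec$mechanism, params,
                                     substrate_ratio_test)

    noise_scale_train <- noise_scale_test <- 1
    if (spec$mechanism == "composed_multimechanism") {
      noise_scale_train <- composed_noise_scale(X_train, params)
      noise_scale_test <- composed_noise_scale(X_test_on_train_vocab, params)
    }
    act_train <- clean_train +
      spec$noise_sd * noise_scale_train * stats::rnorm(spec$n_train)
    act_test <- clean_test +
      spec$noise_sd * noise_scale_test * stats::rnorm(spec$n_test)

    if (!is.null(spec$censor_floor)) {
      act_train[act_train < spec$censor_floor] <- spec$censor_floor
      act_test[act_test < spec$censor_floor] <- spec$censor_floor
    }

    truth <- structure(
      list(mechanism = spec$mechanism,
           mechanism_params = params,
           train_vocabulary = train_vocab,
           clean_train = clean_train,
           clean_test = clean_test,
           substrate_ratio_train = substrate_ratio_train,
           substrate_ratio_test = substrate_ratio_test),
      class = "ground_truth"
    )

    list(
      train = activity_table(sprintf("TRAIN%05d", seq_len(spec$n_train)),
                             act_train, X_train),
      test = activity_table(sprintf("TEST%05d", seq_len(spec$n_test)),
                            act_test, X_test),
      truth = truth
    )
  })
}

#' Toy molecule fixtures
#'
#' A named list of small hand-built [molecular_graph()] objects used
#' throughout the test suite: methane (a lone heavy atom), propane,
#' ethanol, benzene, and a deliberately disconnected two-fragment graph
#' (ethane plus a free water oxygen). Their hand-enumerated expected AP
#' fingerprints ship as `inst/extdata/toy_expected_ap.json`.
#'
#' @return named list of `molecular_graph` objects.
#' @export
toy_molecules <- function() {
  list(
    methane = molecular_graph(
      atoms = data.frame(element = "C", attached_hydrogens = 4L)
    ),
    propane = molecular_graph(
      atoms = data.frame(element = c("C", "C", "C"),
                         attached_hydrogens = c(3L, 2L, 3L)),
      bonds = data.frame(i = c(1L, 2L), j = c(2L, 3L), order = "single")
    ),
    ethanol = molecular_graph(
      atoms = data.frame(element = c("C", "C", "O"),
                         attached_hydrogens = c(3L, 2L, 1L)),
      bonds = data.frame(i = c(1L, 2L), j = c(2L, 3L), order = "single")
    ),
    benzene = molecular_graph(
      atoms = data.frame(element = rep("C", 6), attached_hydrogens = 1L),
      bonds = data.frame(i = 1:6, j = c(2:6, 1L), order = "aromatic")
    ),
    two_fragments = molecular_graph(
      atoms = data.frame(element = c("C", "C", "O"),
                         attached_hydrogens = c(3L, 3L, 2L)),
      bonds = data.frame(i = 1L, j = 2L, order = "single")
    )
  )
}
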