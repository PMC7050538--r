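#' Squared Pearson correlation between observed and predicted activities
#'
#' The benchmark's prediction-performance metric: the squared Pearson
#' correlation coefficient
#' \deqn{R^2 = \frac{\left[\sum_i (x_i-\bar x)(y_i-\bar y)\right]^2}
#'                  {\sum_i (x_i-\bar x)^2 \sum_i (y_i-\bar y)^2}}
#' where \eqn{x_i} are observed and \eqn{y_i} predicted activity values.
#' It is symmetric in its arguments and invariant under affine maps
#' \eqn{y \mapsto a y + b} with \eqn{a \neq 0}.
#'
#' If either vector has zero variance the correlation is undefined; by
#' convention this returns 0 with a warning, so that a collapsed model
#' (constant predictions) scores worst instead of aborting a long
#' training run.
#'
#' @param observed numeric vector of observed activities.
#' @param predicted numeric vector of predicted activities, same length.
#' @return a single number in \[0, 1\].
#' @examples
#' r_squared(c(1, 2, 3), c(1, 2, 4))  # 27/28
#' @export
r_squared <- function(observed, predicted) {
  x <- as.numeric(observed)
  y <- as.numeric(predicted)
  if (length(x) != length(y)) {
    stop("observed and predicted must have the same length")
  }
  if (length(x) < 2L) {
    stop("r_squared requires at least two observations")
  }
  if (anyNA(x) || anyNA(y)) {
    stop("r_squared does not accept missing values")
  }
  dx <- x - mean(x)
  dy <- y - mean(y)
  sxx <- sum(dx * dx)
  syy <- sum(dy * dy)
  if (sxx == 0 || syy == 0) {
    warning("zero variance in observed or predicted values; returning R^2 = 0")
    return(0)
  }
  sxy <- sum(dx * dy)
  (sxy * sxy) / (sxx * syy)
}

#' Mean square error between observed and predicted activities
#'
#' The training loss of the pipeline:
#' \eqn{\mathrm{MSE} = \sum_i (x_i - y_i)^2 / N}. Unlike \eqn{R^2} it is
#' scale-dependent, so it is used only to optimize a model on its own
#' training set, never to compare targets.
#'
#' @inheritParams r_squared
#' @return a single non-negative number.
#' @export
mse <- function(observed, predicted) {
  x <- as.numeric(observed)
  y <- as.numeric(predicted)
  if (length(x) != length(y)) {
    stop("observed and predicted must have the same length")
  }
  if (length(x) == 0L) {
    stop("mse requires at least one observation")
  }
  if (anyNA(x) || anyNA(y)) {
    stop("mse does not accept missing values")
  }
  mean((x - y)^2)
}

#' IC50 from Ki under competitive single-substrate inhibition
#'
#' Cheng-Prusoff relation \eqn{IC_{50} = K_i (1 + [S]/K_m)}: the measured
#' half-maximal inhibitory concentration depends on the substrate
#' concentration \eqn{[S]} of the assay, while \eqn{K_i} is an intrinsic
#' property of the inhibitor-enzyme pair. The synthetic-data generator
#' uses this to emulate assay-condition jitter in pIC50-type activities.
#'
#' @param Ki dissociation constant of the enzyme-inhibitor complex (M), > 0.
#' @param substrate_conc substrate concentration \eqn{[S]} (M), >= 0.
#'   May be a vector.
#' @param Km Michaelis constant of the substrate (M), > 0.
#' @return IC50 in the same concentration unit as `Ki`.
#' @examples
#' cheng_prusoff_ic50(5e-9, 10e-6, 5e-6)  # 15e-9
#' @export
cheng_prusoff_ic50 <- function(Ki, substrate_conc, Km) {
  if (any(!is.finite(Ki)) || any(Ki <= 0)) {
    stop("Ki must be positive and finite")
  }
  if (any(!is.finite(Km)) || any(Km <= 0)) {
    stop("Km must be positive and finite")
  }
  if (any(!is.finite(substrate_conc)) || any(substrate_conc < 0)) {
    stop("substrate_conc must be non-negative and finite")
  }
  Ki * (1 + substrate_conc / Km)
}
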