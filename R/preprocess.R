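#' Background-correct raw array intensities
#'
#' Two methods, applied per array (column):
#'
#' * `"normexp_moments"` models each array's observed intensity as the
#'   sum of an exponential true-signal component (mean `alpha`) and a
#'   normal background (mean `mu`, sd `sigma`), estimates the three
#'   parameters by the method of moments (third central moment
#'   `2*alpha^3` identifies `alpha`), and replaces each value by the
#'   conditional expectation of the signal given the observation, plus
#'   `offset`. If the moment estimates are infeasible (non-positive
#'   skewness or `sigma^2 <= 0`) the array falls back to
#'   `"subtract_floor"` with a warning.
#' * `"subtract_floor"` subtracts the array's negative-control mean and
#'   floors at 0.5 before adding `offset`: `max(x - mu_hat, 0.5) + offset`.
#'
#' Both are strictly increasing in the observed value, so within-array
#' rank order is preserved; all outputs are strictly positive.
#'
#' @param m an `expr_matrix` at stage `"raw"`, linear scale.
#' @param control_types named integer vector (-1/0/+1) per probe;
#'   required by `subtract_floor` (including as the fallback) to locate
#'   negative controls.
#' @param method background model, see Details.
#' @param offset non-negative constant added after correction to damp
#'   low-intensity variance on the log scale.
#' @return an `expr_matrix` at stage `"background_corrected"`.
#' @export
background_correct <- function(m, control_types = NULL,
                               method = c("normexp_moments", "subtract_floor"),
                               offset = 16) {
  method <- match.arg(method)
  check_matrix_state(m, stage = "raw", scale = "linear")
  stopifnot(offset >= 0)
  x <- m$values
  neg_means <- NULL
  if (!is.null(control_types)) {
    ct <- control_types[rownames(x)]
    if (any(ct == -1L, na.rm = TRUE)) {
      neg_means <- colMeans(x[which(ct == -1L), , drop = FALSE])
    }
  }
  floor_one <- function(col, mu_hat) pmax(col - mu_hat, 0.5) + offset
  need_controls <- function() {
    if (is.null(neg_means)) {
      stop("subtract_floor needs control_types with negative controls")
    }
  }
  out <- x
  for (j in seq_len(ncol(x))) {
    if (method == "subtract_floor") {
      need_controls()
      out[, j] <- floor_one(x[, j], neg_means[j])
    } else {
      fit <- normexp_fit_moments(x[, j])
      if (is.null(fit)) {
        warning(sprintf(
          "array '%s': infeasible normexp moment estimates, falling back to subtract_floor",
          colnames(x)[j]))
        need_controls()
        out[, j] <- floor_one(x[, j], neg_means[j])
      } else {
        out[, j] <- limma::normexp.signal(
          c(fit[["mu"]], log(fit[["sigma"]]), log(fit[["alpha"]])),
          x = x[, j]) + offset
      }
    }
  }
  m$values <- out
  advance_stage(m, "background_corrected")
}

#' Method-of-moments fit of the normexp convolution
#'
#' For observed `x = signal + background` with `signal ~
#' Exponential(mean alpha)` and `background ~ Normal(mu, sigma^2)`:
#' `E[x] = mu + alpha`, `Var[x] = sigma^2 + alpha^2`, and the third
#' central moment is `2 * alpha^3` (the normal part is symmetric).
#'
#' @param x numeric vector of linear-scale intensities from one array.
#' @return named vector `c(alpha, mu, sigma)`, or `NULL` when the
#'   moments are infeasible (skewness <= 0 or implied `sigma^2 <= 0`).
#' @export
normexp_fit_moments <- function(x) {
  mean_x <- mean(x)
  m2 <- mean((x - mean_x)^2)
  m3 <- mean((x - mean_x)^3)
  if (m3 <= 0) return(NULL)
  alpha <- (m3 / 2)^(1 / 3)
  sigma2 <- m2 - alpha^2
  if (sigma2 <= 0) return(NULL)
  c(alpha = alpha, mu = mean_x - alpha, sigma = sqrt(sigma2))
}

#' Quantile-normalize arrays to a common intensity distribution
#'
#' Forces every column to share one empirical distribution: each
#' column's sorted values are replaced by the across-column mean of
#' sorted values; ties within a column receive the mean of the reference
#' values at their tied ranks; within-column rank order is preserved.
#'
#' @param m an `expr_matrix` at stage `"background_corrected"`, linear
#'   scale.
#' @return an `expr_matrix` at stage `"normalized"`.
#' @export
quantile_normalize <- function(m) {
  check_matrix_state(m, stage = "background_corrected", scale = "linear")
  if (ncol(m$values) < 2) {
    warning("single-sample matrix: quantile normalization is a no-op")
  } else if (nrow(m$values) > 0) {
    dn <- dimnames(m$values)
    m$values <- limma::normalizeQuantiles(m$values, ties = TRUE)
    dimnames(m$values) <- dn
  }
  advance_stage(m, "normalized")
}

#' Log2-transform an expression matrix
#'
#' @param m an `expr_matrix` on the linear scale, all values > 0.
#' @return the same-stage matrix on the log2 scale.
#' @export
log2_transform <- function(m) {
  check_matrix_state(m, scale = "linear")
  nonpos <- which(m$values <= 0, arr.ind = TRUE)
  if (nrow(nonpos) > 0) {
    stop(sprintf("non-positive value for probe '%s'; cannot log2-transform",
                 rownames(m$values)[nonpos[1, 1]]))
  }
  m$values <- log2(m$values)
  m$scale <- "log2"
  m
}

#' Filter probes against negative-control background
#'
#' For each array the 95th percentile of its negative-control
#' intensities is computed (linear interpolation between order
#' statistics, i.e. position `1 + (n-1)p` in the sorted sample) and
#' multiplied by `brightness_factor`. A regular probe is kept iff its
#' normalized value reaches that per-array threshold on at least
#' `min_arrays` arrays. Control probes are removed from the output
#' regardless.
#'
#' @param m an `expr_matrix` at stage `"normalized"`, linear scale,
#'   still containing the control probes.
#' @param control_types named integer vector (-1/0/+1) per probe.
#' @param percentile negative-control percentile defining background
#'   (default 95).
#' @param brightness_factor multiplicative margin over the background
#'   percentile; 1.10 = "at least 10% brighter".
#' @param min_arrays number of arrays on which a probe must clear the
#'   threshold (default 3).
#' @return list with `matrix` (the filtered `expr_matrix`, regular kept
#'   probes only), `decisions` (data.frame `probe_id`, `n_bright_arrays`,
#'   `kept` for every regular probe), `bright` (regular-probe x array
#'   logical matrix) and `thresholds` (per-array linear thresholds).
#' @export
negctrl_filter <- function(m, control_types, percentile = 95,
                           brightness_factor = 1.10, min_arrays = 3) {
  check_matrix_state(m, stage = "normalized", scale = "linear")
  ct <- control_types[rownames(m$values)]
  if (anyNA(ct)) {
    stop("control_types must cover every probe in the matrix")
  }
  neg <- m$values[ct == -1L, , drop = FALSE]
  if (nrow(neg) == 0) {
    stop(sprintf("no negative-control probes available for array '%s'",
                 colnames(m$values)[1]))
  }
  thresholds <- brightness_factor *
    apply(neg, 2, stats::quantile, probs = percentile / 100,
          type = 7, names = FALSE)
  regular <- m$values[ct == 0L, , drop = FALSE]
  bright <- sweep(regular, 2, thresholds, ">=")
  n_bright <- rowSums(bright)
  kept <- n_bright >= min_arrays
  decisions <- data.frame(probe_id = rownames(regular),
                          n_bright_arrays = as.integer(n_bright),
                          kept = kept, row.names = NULL,
                          stringsAsFactors = FALSE)
  m$values <- regular[kept, , drop = FALSE]
  m <- advance_stage(m, "filtered")
  list(matrix = m, decisions = decisions, bright = bright,
       thresholds = thresholds)
}
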