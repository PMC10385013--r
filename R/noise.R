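# Gaussian-noise data augmentation: additive perturbation of a feature vector
# during training only. Two schemes are supported:
#   * embedding site — each element is selected with probability `elem_prob`
#     and perturbed by a draw from a Normal(0, std) truncated to `trunc_range`
#     (the word-embedding perturbation scheme, default range [0, 0.3] with
#     selection probability 0.3);
#   * pre_classifier site — plain Normal(0, std) perturbation of the pooled
#     feature vector just before the softmax classifier (the headline
#     configuration, std 0.1 for the convolutional model and 0.3 for the
#     encoder-based one).

#' Configure the Gaussian-noise layer
#'
#' @param std standard deviation of the underlying normal (>= 0; 0 disables).
#' @param elem_prob probability that an element receives a perturbation.
#' @param trunc_range length-2 numeric `c(lo, hi)`: draws are restricted to
#'   this interval. Defaults to `c(0, 0.3)` for the `embedding` site and
#'   `c(-Inf, Inf)` (no truncation) otherwise.
#' @param site where the noise is injected in the forward pass:
#'   `"pre_classifier"` (default), `"embedding"`, or `"both"`.
#' @param train_only if `TRUE` (default) the layer is the identity outside of
#'   training.
#' @return object of class `noise_config`.
#' @export
noise_config <- function(std = 0.1, elem_prob = 1,
                         trunc_range = NULL,
                         site = c("pre_classifier", "embedding", "both"),
                         train_only = TRUE) {
  site <- match.arg(site)
  if (is.null(trunc_range))
    trunc_range <- if (site == "embedding") c(0, 0.3) else c(-Inf, Inf)
  if (std < 0) stopf("noise std must be >= 0, got %g", std)
  if (elem_prob < 0 || elem_prob > 1)
    stopf("elem_prob must be in [0, 1], got %g", elem_prob)
  if (trunc_range[1] > trunc_range[2])
    stopf("truncation range: lo (%g) > hi (%g)", trunc_range[1], trunc_range[2])
  structure(list(std = std, elem_prob = elem_prob,
                 trunc_range = as.numeric(trunc_range[1:2]), site = site,
                 train_only = isTRUE(train_only)),
            class = "noise_config")
}

# Draws from Normal(0, sd) truncated to [lo, hi], by inverse-CDF sampling.
rtruncnorm0 <- function(n, sd, lo, hi) {
  a <- stats::pnorm(lo, 0, sd)
  b <- stats::pnorm(hi, 0, sd)
  stats::qnorm(a + stats::runif(n) * (b - a), 0, sd)
}

#' Mean and variance of a truncated centered normal
#'
#' Closed-form moments of Normal(0, sd) restricted to `[lo, hi]`; the
#' independent reference used to check the sampler.
#'
#' @param sd standard deviation of the parent normal.
#' @param lo,hi truncation bounds.
#' @return list with `mean` and `var`.
#' @export
truncnorm_moments <- function(sd, lo, hi) {
  a <- lo / sd
  b <- hi / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a)
  db <- stats::dnorm(b)
  mu <- sd * (da - db) / z
  a_term <- if (is.finite(a)) a * da else 0
  b_term <- if (is.finite(b)) b * db else 0
  v <- sd^2 * (1 + (a_term - b_term) / z - ((da - db) / z)^2)
  list(mean = mu, var = v)
}

#' Apply Gaussian noise to a numeric vector or matrix
#'
#' During training, each element is independently selected with probability
#' `cfg$elem_prob` and receives an additive draw from Normal(0, `cfg$std`)
#' truncated to `cfg$trunc_range` (an infinite range gives the plain normal).
#' With `training = FALSE` (and `cfg$train_only`) or `std = 0` the input is
#' returned bit-identical. Draws use R's global RNG; seed beforehand for
#' reproducibility.
#'
#' @param v numeric vector or matrix.
#' @param cfg a [noise_config()].
#' @param training logical.
#' @return perturbed object of the same shape.
#' @export
gaussian_noise <- function(v, cfg, training = TRUE) {
  if (cfg$std < 0) stopf("noise std must be >= 0")
  if ((cfg$train_only && !training) || cfg$std == 0 || cfg$elem_prob == 0)
    return(v)
  n <- length(v)
  sel <- if (cfg$elem_prob >= 1) rep(TRUE, n) else stats::runif(n) < cfg$elem_prob
  lo <- cfg$trunc_range[1]
  hi <- cfg$trunc_range[2]
  ns <- sum(sel)
  if (ns == 0) return(v)
  draws <- if (is.finite(lo) || is.finite(hi)) rtruncnorm0(ns, cfg$std, lo, hi)
           else stats::rnorm(ns, 0, cfg$std)
  v[sel] <- v[sel] + draws
  v
}
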