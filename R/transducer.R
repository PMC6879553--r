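#' Perceptual transducer models
#'
#' A transducer is a fixed likelihood p(x|w) mapping the true roundness w to
#' an internal percept x. Two families:
#' \describe{
#'   \item{thurstonian}{x = w + Gaussian noise of sd `sigma`, truncated to
#'     the roundness interval \[0,1\] and discretized on an evenly spaced
#'     percept grid (default 1001 points).}
#'   \item{binomial}{x is the number of successes in `T` Bernoulli trials
#'     with success probability w; T acts as the perceptual resource.}
#' }
#'
#' @param kind `"thurstonian"` or `"binomial"`.
#' @param sigma Perceptual standard deviation (roundness units; thurstonian).
#' @param T_obs Observation length (non-negative integer; binomial).
#' @param n_percepts Thurstonian percept-grid size.
#' @return A list of class `br_transducer`.
#' @export
transducer_model <- function(kind = c("thurstonian", "binomial"),
                             sigma = NULL, T_obs = NULL, n_percepts = 1001L) {
  kind <- match.arg(kind)
  if (kind == "thurstonian") {
    stopifnot(!is.null(sigma), sigma > 0)
  } else {
    stopifnot(!is.null(T_obs), T_obs >= 0, T_obs == round(T_obs))
  }
  structure(list(kind = kind, sigma = sigma, T_obs = T_obs,
                 n_percepts = as.integer(n_percepts)),
            class = "br_transducer")
}

# Likelihood matrix p(x|w): rows = world states, cols = percepts; each row
# sums to 1. Also returns the percept grid.
transducer_likelihood <- function(model, roundness) {
  if (model$kind == "thurstonian") {
    x <- seq(0, 1, length.out = model$n_percepts)
    lik <- do.call(rbind, lapply(roundness, function(w) {
      d <- stats::dnorm(x, mean = w, sd = model$sigma)
      d / sum(d)
    }))
  } else {
    x <- 0:model$T_obs
    lik <- do.call(rbind, lapply(roundness, function(w)
      stats::dbinom(x, size = model$T_obs, prob = w)))
  }
  list(lik = lik, percepts = x)
}

# Truncation constant of the continuous Thurstonian density on [0,1]
thurstonian_truncation <- function(w, sigma) {
  stats::pnorm(1, mean = w, sd = sigma) - stats::pnorm(0, mean = w, sd = sigma)
}

#' Channel induced by a perceptual transducer
#'
#' The decision-maker observes a percept x, forms the Bayes posterior
#' p(w|x) over the twelve discrete roundness values, and picks the action
#' maximizing the posterior-expected utility (ties to the lowest flat index).
#' Averaged over percepts this yields the response channel
#' \deqn{p(a|w) = \sum_x p(x|w)\, \delta_{a, a^*(x)}.}
#'
#' @param model A [transducer_model()].
#' @param task A `br_task`.
#' @return A `br_channel` with attribute `model`.
#' @export
transducer_channel <- function(model, task) {
  tl <- transducer_likelihood(model, task$roundness)
  lik <- tl$lik
  # Bayes over discrete states: p(w|x) prop. p(x|w) p(w), per percept column
  joint <- lik * task$prior
  px <- colSums(joint)
  keep <- px > 1e-300
  post_w <- sweep(joint[, keep, drop = FALSE], 2, px[keep], "/")
  # value of each action per percept, argmax with lowest-index tie-break
  v <- crossprod(post_w, task$utility)      # percepts x actions
  a_star <- max.col(v, ties.method = "first")
  n_a <- ncol(task$utility)
  post <- matrix(0, task$n_states, n_a)
  for (a in unique(a_star)) {
    cols <- which(keep)[a_star == a]
    post[, a] <- rowSums(lik[, cols, drop = FALSE])
  }
  post <- post / rowSums(post)
  ch <- new_channel(post, task$prior)
  attr(ch, "model") <- model
  ch
}

#' Constrained curve of a transducer family
#'
#' Scans the noise parameter (sigma for the Thurstonian family, T for the
#' Binomial family) and reports one (E[U], I, mean level) point per value.
#'
#' @param kind `"thurstonian"` or `"binomial"`.
#' @param param_grid Parameter values to scan.
#' @param task A `br_task`.
#' @param keep_channels Store channels in a list column.
#' @return A `br_curve` with column `param` holding the scanned parameter.
#' @export
transducer_curve <- function(kind = c("thurstonian", "binomial"),
                             param_grid = NULL, task, keep_channels = FALSE) {
  kind <- match.arg(kind)
  if (is.null(param_grid))
    param_grid <- if (kind == "thurstonian") default_sigma_grid() else default_T_grid()
  channels <- lapply(param_grid, function(p) {
    m <- if (kind == "thurstonian") transducer_model("thurstonian", sigma = p)
         else transducer_model("binomial", T_obs = p)
    transducer_channel(m, task)
  })
  curve_from_channels(channels, param = param_grid, task = task,
                      family = kind, keep_channels = keep_channels)
}

#' Analytic Beta posterior for the Binomial transducer
#'
#' Conjugacy oracle: under a continuous Beta(a, b) prior on the roundness,
#' observing x successes out of T gives the Beta(a + x, b + T - x) posterior.
#' Returned as a density evaluated on a grid (normalized to sum to 1), for
#' comparison against brute-force discrete Bayes on the same grid.
#'
#' @param x Successes observed.
#' @param T_obs Number of Bernoulli trials.
#' @param a,b Beta prior parameters (1, 1 = uniform).
#' @param grid Evaluation grid on \[0,1\].
#' @return Numeric vector of normalized posterior masses on `grid`.
#' @export
beta_binomial_posterior <- function(x, T_obs, a = 1, b = 1,
                                    grid = seq(0, 1, length.out = 2001)) {
  d <- stats::dbeta(grid, a + x, b + T_obs - x)
  d[!is.finite(d)] <- 0
  d / sum(d)
}
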