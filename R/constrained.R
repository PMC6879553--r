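#' Fixed action priors over the response hierarchy
#'
#' A level-blocked prior assigns probability `q1` to each coarse button, `q2`
#' to each intermediate and `q3` to each precise button, with
#' 3 q1 + 6 q2 + 12 q3 = 1. Two presets: `"uniform_actions"` (every action
#' 1/21) and `"uniform_levels"` (1/9, 1/18, 1/36 -- each level carries total
#' mass 1/3).
#'
#' @param q1,q2,q3 Per-action probabilities by level (non-negative).
#' @param preset Optional preset name overriding the q's.
#' @return Numeric length-21 prior vector with attribute `q`.
#' @export
#' @examples
#' prior_spec(preset = "uniform_levels")[c(1, 4, 10)]  # 1/9 1/18 1/36
prior_spec <- function(q1 = NULL, q2 = NULL, q3 = NULL, preset = NULL) {
  if (!is.null(preset)) {
    q <- switch(preset,
      uniform_actions = rep(1 / 21, 3),
      uniform_levels  = c(1 / 9, 1 / 18, 1 / 36),
      stop("unknown preset: ", preset)
    )
  } else {
    q <- c(q1, q2, q3)
    if (length(q) != 3) stop("supply q1, q2, q3 or a preset")
  }
  if (any(q < 0)) stop("prior probabilities must be non-negative")
  tot <- 3 * q[1] + 6 * q[2] + 12 * q[3]
  if (abs(tot - 1) > 1e-10) stop("3 q1 + 6 q2 + 12 q3 must equal 1 (got ", tot, ")")
  p0 <- rep(q, times = c(3, 6, 12))
  attr(p0, "q") <- q
  p0
}

#' Distort the task payoffs
#'
#' Replaces the 0.6 and 0.8 payoffs by subjective values `v06` and `v08` with
#' the ordering 0 < v06 < v08 < 1 preserved; 0 and 1.0 cells are unchanged,
#' so the zero pattern of the table is identical.
#'
#' @param utility Utility matrix or `br_task`.
#' @param v06,v08 Subjective values of the 0.6 and 0.8 payoffs.
#' @return Object of the same kind as `utility` with distorted payoffs.
#' @export
distort_utility <- function(utility, v06, v08) {
  if (!(v06 > 0 && v06 < v08 && v08 < 1))
    stop("distortion must satisfy 0 < v06 < v08 < 1")
  apply_u <- function(u) {
    u[abs(u - 0.6) < 1e-12] <- v06
    u[abs(u - 0.8) < 1e-12] <- v08
    u
  }
  if (inherits(utility, "br_task")) {
    utility$utility <- apply_u(utility$utility)
    utility
  } else apply_u(utility)
}

#' Similarity kernel for near-miss generalization
#'
#' Shepard-style decay of utility with within-level button distance:
#' exponential \eqn{k(t) = e^{-\theta |t|}} or Gaussian
#' \eqn{k(t) = e^{-t^2 / (2\theta^2)}}, normalized so k(0) = 1 (a correct
#' response keeps its full payoff).
#'
#' @param family `"exponential"` or `"gaussian"`.
#' @param theta Positive decay parameter, in within-level button units.
#' @return A function of the signed button offset `t`.
#' @export
similarity_kernel <- function(family = c("exponential", "gaussian"), theta) {
  family <- match.arg(family)
  stopifnot(theta > 0)
  switch(family,
    exponential = function(t) exp(-theta * abs(t)),
    gaussian    = function(t) exp(-0.5 * t^2 / theta^2)
  )
}

#' Blur the utility table with a similarity kernel
#'
#' Within each level, the payoff of the correct button leaks to its
#' neighbors: V(w, a) = k(delta) u_l where delta is the signed within-level
#' offset of `a` from the rewarded button of w's level. There is no
#' cross-level blur and the diagonal is preserved (k(0) = 1).
#'
#' @param task A `br_task`.
#' @param kernel A [similarity_kernel()] function.
#' @return A `br_task` with the blurred utility matrix.
#' @export
blur_utility <- function(task, kernel) {
  stopifnot(inherits(task, "br_task"), is.function(kernel))
  h <- task$hierarchy
  v <- matrix(0, task$n_states, h$n_actions, dimnames = dimnames(task$utility))
  for (l in seq_len(h$n_levels)) {
    acts <- level_actions(h, l)
    for (w in seq_len(task$n_states)) {
      star <- button_of_action(h, correct_action(task, w, l))
      v[w, acts] <- kernel(seq_len(h$n_buttons[l]) - star) * h$payoff[l]
    }
  }
  task$utility <- v
  task
}

new_constrained_curve <- function(df, family, frontier_utility = NULL) {
  attr(df, "family") <- family
  class(df) <- c("br_curve", class(df))
  df
}

#' Constrained frontier under a fixed action prior
#'
#' Scans beta with [fixed_prior_solve()] under a fixed prior and reports the
#' actual (E[U], I, mean level) of each induced channel. The curve lies
#' weakly below the unconstrained efficiency frontier.
#'
#' @param task A `br_task`.
#' @param p0 Strictly positive action prior (e.g. from [prior_spec()]).
#' @param beta_grid Increasing positive inverse temperatures.
#' @param keep_channels Store each channel in a list column.
#' @return A tibble of class `br_curve` with columns `param` (beta),
#'   `expected_utility`, `mutual_info_bits`, `mean_level`.
#' @export
frontier_fixed_prior <- function(task, p0, beta_grid = default_beta_grid(),
                                 keep_channels = FALSE) {
  if (any(p0 <= 0)) stop("fixed prior must be strictly positive on every action")
  curve_from_channels(
    lapply(beta_grid, function(b) fixed_prior_solve(task, beta = b, p0 = p0)),
    param = beta_grid, task = task, family = "fixed_prior",
    keep_channels = keep_channels
  )
}

curve_from_channels <- function(channels, param, task, family, keep_channels = FALSE) {
  rows <- purrr::map2_dfr(channels, param, function(ch, p) {
    tibble::tibble(
      param = p,
      expected_utility = expected_utility(ch, task),
      mutual_info_bits = mutual_information_bits(ch),
      mean_level = level_statistics(ch, task$hierarchy)$mean_level
    )
  })
  if (keep_channels) rows$channel <- channels
  new_constrained_curve(rows, family)
}

#' Channel of a Gaussian response profile of width sigma
#'
#' For each world state and each level, the candidate response is a Gaussian
#' over that level's button indices centered at the rewarded button with
#' common standard deviation `sigma` (discretized and renormalized). The
#' state's level is the candidate maximizing expected utility, with ties
#' resolved toward the coarser level; the channel row places all mass on the
#' chosen level's candidate.
#'
#' @param task A `br_task`.
#' @param sigma Positive standard deviation in button units.
#' @return A `br_channel`.
#' @export
gaussian_response_channel <- function(task, sigma) {
  stopifnot(sigma > 0)
  h <- task$hierarchy
  post <- matrix(0, task$n_states, h$n_actions)
  for (w in seq_len(task$n_states)) {
    best_l <- 1L
    best_eu <- -Inf
    best_p <- NULL
    for (l in seq_len(h$n_levels)) {
      acts <- level_actions(h, l)
      star <- button_of_action(h, correct_action(task, w, l))
      dens <- stats::dnorm(seq_len(h$n_buttons[l]), mean = star, sd = sigma)
      if (sum(dens) <= 0) { dens <- rep(0, h$n_buttons[l]); dens[star] <- 1 }
      p <- dens / sum(dens)
      eu <- sum(p * task$utility[w, acts])
      if (eu > best_eu + 1e-12) { best_eu <- eu; best_l <- l; best_p <- p }
    }
    post[w, level_actions(h, best_l)] <- best_p
  }
  new_channel(post, task$prior)
}

#' Constrained curve of Gaussian response profiles
#'
#' Scans the common response standard deviation and reports one
#' (E[U], I, mean level) point per sigma. Mean level is piecewise constant in
#' sigma: a finer level is adopted only when its expected utility overtakes
#' the coarser one's.
#'
#' @param task A `br_task`.
#' @param sigma_grid Positive standard deviations (button units).
#' @param keep_channels Store channels in a list column.
#' @return A `br_curve`.
#' @export
gaussian_response_curve <- function(task, sigma_grid = default_sigma_grid(),
                                    keep_channels = FALSE) {
  stopifnot(all(sigma_grid > 0))
  curve_from_channels(
    lapply(sigma_grid, function(s) gaussian_response_channel(task, s)),
    param = sigma_grid, task = task, family = "gaussian",
    keep_channels = keep_channels
  )
}

#' Default constrained-model scan grids
#'
#' Log-spaced default grids for the resource parameter of each constrained
#' family: response/percept noise `sigma`, Binomial observation length `T`,
#' and similarity decay `theta`.
#'
#' @param n Number of grid points where applicable.
#' @return Numeric grid.
#' @export
default_sigma_grid <- function(n = 50L) exp(seq(log(1e-3), log(1), length.out = n))

#' @rdname default_sigma_grid
#' @export
default_T_grid <- function() c(0L, 1L, 2L, 3L, 5L, 8L, 13L, 21L, 34L, 55L,
                               89L, 144L, 233L, 377L, 610L, 1000L, 2000L)

#' @rdname default_sigma_grid
#' @export
default_theta_grid <- function(n = 50L) exp(seq(log(0.1), log(20), length.out = n))
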