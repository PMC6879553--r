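# Row-wise exponential tilt in log space: p(a|w) prop. p0(a) exp(beta U(w,a)).
# Stable for large beta; marginal entries of exactly 0 stay 0.
tilt_rows <- function(utility, beta, p0) {
  logit <- sweep(beta * utility, 2, ifelse(p0 > 0, log(p0), -Inf), "+")
  mx <- apply(logit, 1, max)
  p <- exp(logit - mx)
  p / rowSums(p)
}

# Free energy E[U] - (1/beta) I  with information in nats (natural-log beta
# convention throughout the solvers; user-facing information is in bits).
free_energy_nats <- function(posterior, marginal, prior, utility, beta) {
  eu <- sum(prior * rowSums(posterior * utility))
  i_nats <- sum(vapply(seq_len(nrow(posterior)),
                       function(w) prior[w] * kl_nats(posterior[w, ], marginal),
                       numeric(1)))
  if (beta == 0) eu else eu - i_nats / beta
}

#' Bounded-rational channel by Blahut-Arimoto iteration
#'
#' Solves the utility/information trade-off
#' \deqn{\max_{p(a|w)} E[U] - \tfrac{1}{\beta} I(W;A)}
#' by alternating the exponential-tilt posterior update
#' \eqn{p(a|w) \propto p(a) e^{\beta U(w,a)}} with the marginal update
#' \eqn{p(a) = \sum_w p(w) p(a|w)}. The inverse temperature `beta` uses the
#' natural-log convention (units 1/utility); reported information is in bits.
#' The free energy is non-decreasing across iterations; iteration stops when
#' successive free-energy values differ by less than `tol`.
#'
#' @param utility Utility matrix (states x actions) or a `br_task`.
#' @param prior State prior; defaults to the task prior or uniform.
#' @param beta Non-negative inverse temperature. `beta = 0` returns the
#'   analytic zero-resource channel (all rows equal to `init_marginal`).
#' @param tol Free-energy convergence tolerance (default 1e-12).
#' @param max_iter Iteration cap (default 100000).
#' @param init_marginal Optional starting action marginal (warm start).
#' @param multistart Also run from a uniform and a rational-policy marginal
#'   and keep the best free energy (default TRUE). The fixed-point map slows
#'   down critically near the frontier's abstraction-level transitions, where
#'   a single start can stall on a metastable plateau.
#' @return A `br_channel` with attributes `beta`, `iterations`, `converged`
#'   and `objective_trace`. Non-convergence raises an error of class
#'   `braidr_no_convergence` carrying the last iterate and the trace.
#' @export
#' @examples
#' task <- build_lab_task()
#' ch <- blahut_arimoto(task, beta = 10)
#' mutual_information_bits(ch)
ba_core <- function(utility, prior, beta, tol, max_iter, m0) {
  m <- m0 / sum(m0)
  trace <- numeric(0)
  f_old <- -Inf
  converged <- FALSE
  post <- NULL
  for (it in seq_len(max_iter)) {
    post <- tilt_rows(utility, beta, m)
    m <- as.vector(prior %*% post)
    f <- free_energy_nats(post, m, prior, utility, beta)
    trace <- c(trace, f)
    if (is.finite(f_old) && abs(f - f_old) < tol) { converged <- TRUE; break }
    f_old <- f
  }
  list(post = post, m = m, f = f, trace = trace, converged = converged, iters = it)
}

# marginal of the rational (row-argmax) policy; ties to the lowest index
rational_marginal <- function(utility, prior) {
  a <- max.col(utility, ties.method = "first")
  m <- numeric(ncol(utility))
  for (w in seq_along(a)) m[a[w]] <- m[a[w]] + prior[w]
  m
}

blahut_arimoto <- function(utility, prior = NULL, beta, tol = 1e-12,
                           max_iter = 100000L, init_marginal = NULL,
                           multistart = TRUE) {
  if (inherits(utility, "br_task")) {
    if (is.null(prior)) prior <- utility$prior
    utility <- utility$utility
  }
  if (is.null(prior)) prior <- rep(1 / nrow(utility), nrow(utility))
  stopifnot(beta >= 0, all(is.finite(utility)))
  n_a <- ncol(utility)

  if (beta == 0) {
    m <- if (is.null(init_marginal)) rep(1 / n_a, n_a)
         else init_marginal / sum(init_marginal)
    post <- matrix(m, nrow(utility), n_a, byrow = TRUE)
    ch <- new_channel(post, prior)
    attr(ch, "beta") <- 0
    attr(ch, "iterations") <- 0L
    attr(ch, "converged") <- TRUE
    return(ch)
  }

  # Near the frontier's level transitions the fixed-point map slows down
  # critically and a single start can linger on a metastable plateau; running
  # from several initial marginals and keeping the best free energy makes the
  # returned channel the global optimum in practice.
  starts <- if (is.null(init_marginal)) list(rep(1 / n_a, n_a))
            else list(init_marginal)
  if (multistart) {
    if (!is.null(init_marginal)) starts <- c(starts, list(rep(1 / n_a, n_a)))
    starts <- c(starts, list(rational_marginal(utility, prior) + 1e-9))
  }

  best <- NULL
  for (m0 in starts) {
    run <- ba_core(utility, prior, beta, tol, max_iter, m0)
    if (is.null(best) || run$f > best$f + 1e-15 ||
        (run$converged && !best$converged && run$f >= best$f - 1e-12))
      best <- run
  }
  ch <- new_channel(best$post, prior)
  attr(ch, "beta") <- beta
  attr(ch, "iterations") <- best$iters
  attr(ch, "converged") <- best$converged
  attr(ch, "objective_trace") <- best$trace
  if (!best$converged) {
    cnd <- structure(
      class = c("braidr_no_convergence", "error", "condition"),
      list(message = sprintf("Blahut-Arimoto did not converge in %d iterations (beta = %g)",
                             max_iter, beta),
           call = sys.call(-1), channel = ch, trace = best$trace)
    )
    stop(cnd)
  }
  ch
}

#' Bounded-rational channel under a fixed action prior
#'
#' With a fixed (non-adaptive) prior p0(a) the optimum is a single
#' exponential tilt per row, \eqn{p(a|w) \propto p_0(a) e^{\beta U(w,a)}};
#' no marginal iteration is involved. The returned channel's action marginal
#' is recomputed from the result, so its reported mutual information is the
#' actual I(W;A) of the induced channel.
#'
#' @inheritParams blahut_arimoto
#' @param p0 Strictly positive prior over all actions.
#' @return A `br_channel` with attribute `beta`.
#' @export
fixed_prior_solve <- function(utility, prior = NULL, beta, p0) {
  if (inherits(utility, "br_task")) {
    if (is.null(prior)) prior <- utility$prior
    utility <- utility$utility
  }
  if (is.null(prior)) prior <- rep(1 / nrow(utility), nrow(utility))
  stopifnot(beta >= 0, length(p0) == ncol(utility))
  if (any(p0 <= 0)) stop("p0 must be strictly positive on every action")
  p0 <- p0 / sum(p0)
  post <- if (beta == 0) matrix(p0, nrow(utility), ncol(utility), byrow = TRUE)
          else tilt_rows(utility, beta, p0)
  ch <- new_channel(post, prior)
  attr(ch, "beta") <- beta
  ch
}

#' Best utility achievable with zero information
#'
#' The zero-resource benchmark U_min: the best constant (state-independent)
#' strategy, max_a E_w[U(w,a)]. Equals 0.2 for both the lab task and the
#' guessing game.
#'
#' @inheritParams blahut_arimoto
#' @return Scalar utility.
#' @export
zero_information_utility <- function(utility, prior = NULL) {
  if (inherits(utility, "br_task")) {
    if (is.null(prior)) prior <- utility$prior
    utility <- utility$utility
  }
  if (is.null(prior)) prior <- rep(1 / nrow(utility), nrow(utility))
  max(as.vector(prior %*% utility))
}

#' Trace the utility/information efficiency frontier
#'
#' Runs the Blahut-Arimoto solver along an increasing grid of inverse
#' temperatures (warm-starting each solve from the previous marginal) and
#' records one frontier point per beta: expected utility, mutual information
#' in bits, and abstraction-level statistics. The resulting (I, E[U])
#' polyline is non-decreasing in both coordinates and concave.
#'
#' @inheritParams blahut_arimoto
#' @param beta_grid Increasing positive vector; default 60 points log-spaced
#'   on \eqn{[10^{-2}, 10^3]}.
#' @param hierarchy Hierarchy used for level statistics (default the 21-action
#'   panel); set `NULL` to skip level columns.
#' @param keep_channels Store each solved channel in a list column (needed by
#'   [nearest_frontier_channel()]).
#' @return A tibble of class `br_frontier` with columns `beta`,
#'   `expected_utility`, `mutual_info_bits`, `kl_bound_bits`, `mean_level`,
#'   `sigma_plus`, `sigma_minus` (and `channel` if kept). The task utility is
#'   attached as attribute `utility`.
#' @export
efficiency_frontier <- function(utility, prior = NULL,
                                beta_grid = default_beta_grid(),
                                tol = 1e-12, max_iter = 100000L,
                                hierarchy = action_hierarchy(),
                                keep_channels = FALSE) {
  if (inherits(utility, "br_task")) {
    if (is.null(prior)) prior <- utility$prior
    hierarchy <- utility$hierarchy
    utility <- utility$utility
  }
  if (is.null(prior)) prior <- rep(1 / nrow(utility), nrow(utility))
  stopifnot(all(beta_grid > 0), !is.unsorted(beta_grid))

  # Bidirectional warm sweep: solutions warm-started from below can lag on a
  # metastable branch near the frontier's abstraction transitions (and vice
  # versa), so the grid is swept once upward from a uniform start and once
  # downward from the rational-policy start, keeping the better free energy
  # per beta.
  sweep <- function(idx, m0) {
    m <- m0
    out <- vector("list", length(beta_grid))
    for (k in idx) {
      b <- beta_grid[k]
      ch <- tryCatch(
        blahut_arimoto(utility, prior, beta = b, tol = tol, max_iter = max_iter,
                       init_marginal = m, multistart = FALSE),
        braidr_no_convergence = function(e) {
          stop(sprintf("frontier solve failed at beta = %g: %s", b, conditionMessage(e)))
        }
      )
      m <- ch$marginal
      out[[k]] <- ch
    }
    out
  }
  fwd <- sweep(seq_along(beta_grid), NULL)
  # transitions require beta * utility gaps of order log(branch ratio); far
  # below that the optimum is unique and the downward sweep only adds cost
  bwd_idx <- which(beta_grid >= 0.5)
  bwd <- sweep(rev(bwd_idx), rational_marginal(utility, prior) + 1e-9)
  f_of <- function(ch, b) free_energy_nats(ch$posterior, ch$marginal, prior,
                                           utility, b)
  rows <- vector("list", length(beta_grid))
  chans <- vector("list", length(beta_grid))
  for (k in seq_along(beta_grid)) {
    b <- beta_grid[k]
    ch <- if (!is.null(bwd[[k]]) &&
              f_of(bwd[[k]], b) > f_of(fwd[[k]], b) + 1e-15) bwd[[k]] else fwd[[k]]
    ls <- if (!is.null(hierarchy) && ncol(utility) == hierarchy$n_actions)
      level_statistics(ch, hierarchy)
    else list(mean_level = NA_real_, sigma_plus = NA_real_, sigma_minus = NA_real_)
    rows[[k]] <- tibble::tibble(
      beta = b,
      expected_utility = expected_utility(ch, utility),
      mutual_info_bits = mutual_information_bits(ch),
      kl_bound_bits = mutual_information_bits(ch),
      mean_level = ls$mean_level,
      sigma_plus = ls$sigma_plus,
      sigma_minus = ls$sigma_minus
    )
    if (keep_channels) chans[[k]] <- ch
  }
  out <- dplyr::bind_rows(rows)
  if (keep_channels) out$channel <- chans
  attr(out, "utility") <- utility
  attr(out, "prior") <- prior
  attr(out, "u_min") <- zero_information_utility(utility, prior)
  class(out) <- c("br_frontier", class(out))
  out
}

#' @rdname efficiency_frontier
#' @param n Number of grid points.
#' @param range Log-range endpoints for the beta grid.
#' @export
default_beta_grid <- function(n = 60L, range = c(1e-2, 1e3)) {
  exp(seq(log(range[1]), log(range[2]), length.out = n))
}

#' Frontier utility at a given information level
#'
#' Piecewise-linear interpolation of the frontier's expected utility at
#' mutual information `i_bits`. Because the frontier is concave, linear
#' interpolation is a lower bound on the true frontier value, which keeps the
#' derived efficiency conservative (at most 1).
#'
#' @param frontier A `br_frontier`.
#' @param i_bits Mutual information in bits.
#' @return Interpolated utility; values beyond the frontier's maximum
#'   information are clamped to the maximal frontier utility with a warning.
#' @export
frontier_utility_at <- function(frontier, i_bits) {
  x <- c(0, frontier$mutual_info_bits)
  y <- c(attr(frontier, "u_min"), frontier$expected_utility)
  if (any(i_bits > max(x))) {
    warning("information beyond frontier range; clamping to maximal frontier utility")
    i_bits <- pmin(i_bits, max(x))
  }
  stats::approx(x, y, xout = pmax(i_bits, 0), ties = max)$y
}

#' Upper envelope of the frontier at a given information level
#'
#' A rigorous upper bound on the achievable utility at mutual information
#' `i_bits`, from free-energy duality: every channel with information I and
#' utility U satisfies \eqn{U \le F^*(\beta) + I/\beta} for every
#' \eqn{\beta}, where \eqn{F^*(\beta)} is the optimal free energy. Minimizing
#' the right-hand side over the frontier's beta grid yields the tangent-line
#' envelope of the concave frontier. Useful for dominance checks, where the
#' chord interpolation of [frontier_utility_at()] (a lower bound) would be
#' too strict.
#'
#' @inheritParams frontier_utility_at
#' @return Upper-bound utilities at `i_bits`.
#' @export
frontier_utility_bound <- function(frontier, i_bits) {
  i_nats_grid <- frontier$mutual_info_bits * log(2)
  f_star <- frontier$expected_utility - i_nats_grid / frontier$beta
  vapply(i_bits * log(2), function(i_nats)
    min(f_star + i_nats / frontier$beta), numeric(1))
}

#' Efficiency of an (utility, information) operating point
#'
#' \deqn{\epsilon = (U^{exp} - U^{min}) / (U^{max} - U^{min}),}
#' where U_min is the best zero-information utility and U_max the frontier
#' utility at the point's information level.
#'
#' @param u_exp Measured expected utility.
#' @param i_exp Measured mutual information, bits.
#' @param frontier A `br_frontier` for the same task.
#' @return Efficiency (dimensionless, at most 1 up to interpolation error).
#' @export
efficiency <- function(u_exp, i_exp, frontier) {
  u_min <- attr(frontier, "u_min")
  u_max <- frontier_utility_at(frontier, i_exp)
  (u_exp - u_min) / (u_max - u_min)
}

#' One-row frontier summary
#'
#' @param x A `br_frontier`.
#' @param ... Unused.
#' @return Tibble with the information and utility spans of the curve.
#' @export
glance.br_frontier <- function(x, ...) {
  tibble::tibble(
    n_points = nrow(x),
    max_info_bits = max(x$mutual_info_bits),
    min_utility = min(x$expected_utility),
    max_utility = max(x$expected_utility),
    u_min = attr(x, "u_min")
  )
}
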