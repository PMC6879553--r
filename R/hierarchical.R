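# log(sum(exp(x))) with -Inf-safe shift
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Effective utility of an abstraction level (closed form)
#'
#' For the crisp task utility, where each level offers exactly one rewarded
#' button of payoff u_l among N_l equally likely buttons, the free-energy
#' value of committing to level l is world-state independent,
#' \deqn{\Delta F(l) = \frac{1}{\beta_2} \log \frac{e^{\beta_2 u_l} + N_l - 1}{N_l}.}
#' In the zero-temperature limit this tends to u_l, and as
#' \eqn{\beta_2 \to 0} to u_l / N_l (the uniform-policy expected utility).
#'
#' @param level Level index 1..3 (vectorized).
#' @param beta2 Within-level inverse temperature (>= 0; 0 handled as limit).
#' @param hierarchy An [action_hierarchy()].
#' @return Effective utility in payoff units.
#' @export
#' @examples
#' delta_F(1, beta2 = 1)  # log((exp(0.6) + 2)/3) ~ 0.2421
delta_F <- function(level, beta2, hierarchy = action_hierarchy()) {
  u <- hierarchy$payoff[level]
  n <- hierarchy$n_buttons[level]
  if (beta2 == 0) return(u / n)
  # log((exp(b u) + n - 1) / n) / b, written to stay finite for large b u
  u + (log1p((n - 1) * exp(-beta2 * u)) - log(n)) / beta2
}

# Numeric Delta F for a general (possibly blurred) utility: per (w, l),
# (1/beta2) log sum_a p(a|l) exp(beta2 U(w, a)). beta2 = 0 falls back to the
# prior-expected utility. `within_priors` is a list of per-level priors
# (default uniform).
delta_F_numeric <- function(utility, hierarchy = action_hierarchy(), beta2,
                            within_priors = NULL) {
  n_w <- nrow(utility)
  out <- matrix(0, n_w, hierarchy$n_levels)
  for (l in seq_len(hierarchy$n_levels)) {
    acts <- level_actions(hierarchy, l)
    p0 <- if (is.null(within_priors)) rep(1 / length(acts), length(acts))
          else within_priors[[l]]
    if (beta2 == 0) {
      out[, l] <- as.vector(utility[, acts, drop = FALSE] %*% p0)
    } else {
      lp0 <- ifelse(p0 > 0, log(p0), -Inf)
      for (w in seq_len(n_w))
        out[w, l] <- logsumexp(beta2 * utility[w, acts] + lp0) / beta2
    }
  }
  out
}

#' Solve the hierarchical (level, within-level) bounded-rational model
#'
#' Solves the two-step trade-off
#' \deqn{\max E[U] - \tfrac{1}{\beta_1} I(W;L) - \tfrac{1}{\beta_2} I(W;A|L)}
#' by alternating fixed-point sweeps: within-level posteriors
#' \eqn{p(a|w,l) \propto p(a|l) e^{\beta_2 U(w,l,a)}}, within-level priors,
#' the level free energies \eqn{\Delta F(w,l)}, the level posterior
#' \eqn{p(l|w) \propto p(l) e^{\beta_1 \Delta F(w,l)}}, and the level prior.
#' For `beta1 == beta2` the induced joint channel over the 21 flat actions
#' coincides with the flat [blahut_arimoto()] solution at the same beta.
#'
#' @param utility Utility matrix (12 x 21) or a `br_task`.
#' @param prior State prior.
#' @param beta1 Inverse temperature of the level-selection step (>= 0).
#' @param beta2 Inverse temperature of the within-level step (>= 0).
#' @param tol Objective convergence tolerance (default 1e-12).
#' @param max_iter Sweep cap.
#' @param hierarchy An [action_hierarchy()].
#' @param multistart Also sweep from level-concentrated starting priors and
#'   keep the best objective (default TRUE); see [blahut_arimoto()].
#' @return A list of class `br_hier_policy` with `level_posterior` (12 x 3),
#'   `level_prior`, `within_posterior` (list of 12 x N_l matrices),
#'   `within_prior` (list), `delta_F` (12 x 3), `beta1`, `beta2`, plus
#'   convergence metadata.
#' @export
solve_hierarchical <- function(utility, prior = NULL, beta1, beta2,
                               tol = 1e-12, max_iter = 100000L,
                               hierarchy = action_hierarchy(),
                               multistart = TRUE) {
  if (inherits(utility, "br_task")) {
    if (is.null(prior)) prior <- utility$prior
    hierarchy <- utility$hierarchy
    utility <- utility$utility
  }
  if (is.null(prior)) prior <- rep(1 / nrow(utility), nrow(utility))
  stopifnot(beta1 >= 0, beta2 >= 0)
  n_w <- nrow(utility)
  n_lev <- hierarchy$n_levels

  objective <- function(p_lw, p_l, p_awl, p_al) {
    eu <- 0
    i_wl <- sum(vapply(seq_len(n_w),
                       function(w) prior[w] * kl_nats(p_lw[w, ], p_l), numeric(1)))
    i_wal <- 0
    for (l in seq_len(n_lev)) {
      acts <- level_actions(hierarchy, l)
      eu <- eu + sum(prior * p_lw[, l] *
                       rowSums(p_awl[[l]] * utility[, acts, drop = FALSE]))
      i_wal <- i_wal + sum(vapply(seq_len(n_w), function(w)
        prior[w] * p_lw[w, l] * kl_nats(p_awl[[l]][w, ], p_al[[l]]), numeric(1)))
    }
    eu - (if (beta1 > 0) i_wl / beta1 else 0) -
      (if (beta2 > 0) i_wal / beta2 else 0)
  }

  sweep_from <- function(p_l0) {
    p_l <- p_l0 / sum(p_l0)
    p_al <- lapply(seq_len(n_lev), function(l) {
      n <- hierarchy$n_buttons[l]
      rep(1 / n, n)
    })
    p_lw <- matrix(p_l, n_w, n_lev, byrow = TRUE)
    p_awl <- vector("list", n_lev)
    f_old <- -Inf
    trace <- numeric(0)
    converged <- FALSE
    dF <- NULL
    for (it in seq_len(max_iter)) {
      # within-level posteriors (tilt of the within-level prior)
      for (l in seq_len(n_lev)) {
        acts <- level_actions(hierarchy, l)
        p_awl[[l]] <- if (beta2 == 0)
          matrix(p_al[[l]], n_w, length(acts), byrow = TRUE)
        else tilt_rows(utility[, acts, drop = FALSE], beta2, p_al[[l]])
      }
      # within-level priors p(a|l) = sum_w p(w|l) p(a|w,l)
      for (l in seq_len(n_lev)) {
        wt <- prior * p_lw[, l]
        p_al[[l]] <- if (sum(wt) > 1e-300) as.vector((wt / sum(wt)) %*% p_awl[[l]])
                     else rep(1 / hierarchy$n_buttons[l], hierarchy$n_buttons[l])
      }
      # refresh posteriors against the updated priors, then level free energies
      for (l in seq_len(n_lev)) {
        acts <- level_actions(hierarchy, l)
        p_awl[[l]] <- if (beta2 == 0)
          matrix(p_al[[l]], n_w, length(acts), byrow = TRUE)
        else tilt_rows(utility[, acts, drop = FALSE], beta2, p_al[[l]])
      }
      dF <- delta_F_numeric(utility, hierarchy, beta2, within_priors = p_al)
      # level posterior and prior
      p_lw <- if (beta1 == 0) matrix(p_l, n_w, n_lev, byrow = TRUE)
              else tilt_rows(dF, beta1, p_l)
      p_l <- as.vector(prior %*% p_lw)

      f <- objective(p_lw, p_l, p_awl, p_al)
      trace <- c(trace, f)
      if (is.finite(f_old) && abs(f - f_old) < tol) { converged <- TRUE; break }
      f_old <- f
    }
    list(p_lw = p_lw, p_l = p_l, p_awl = p_awl, p_al = p_al, dF = dF,
         f = f, trace = trace, converged = converged, iters = it)
  }

  # The level-prior feedback has the same metastable plateaus as the flat
  # solver near abstraction transitions; restarting from level-concentrated
  # priors and keeping the best objective finds the global optimum.
  starts <- list(rep(1 / n_lev, n_lev))
  if (multistart)
    starts <- c(starts, lapply(seq_len(n_lev), function(l) {
      p <- rep(0.01, n_lev)
      p[l] <- 1 - 0.01 * (n_lev - 1)
      p
    }))
  best <- NULL
  for (p_l0 in starts) {
    run <- sweep_from(p_l0)
    if (is.null(best) || run$f > best$f + 1e-15 ||
        (run$converged && !best$converged && run$f >= best$f - 1e-12))
      best <- run
  }
  if (!best$converged)
    stop(structure(
      class = c("braidr_no_convergence", "error", "condition"),
      list(message = sprintf("hierarchical solver did not converge in %d sweeps", max_iter),
           call = sys.call(-1), trace = best$trace)
    ))

  structure(
    list(
      level_posterior = best$p_lw, level_prior = best$p_l,
      within_posterior = best$p_awl, within_prior = best$p_al,
      delta_F = best$dF, beta1 = beta1, beta2 = beta2,
      prior = prior, hierarchy = hierarchy,
      iterations = best$iters, objective_trace = best$trace
    ),
    class = "br_hier_policy"
  )
}

#' Flat channel induced by a hierarchical policy
#'
#' Combines level selection and within-level choice into the joint
#' p(a|w) = p(l(a)|w) p(a|w, l(a)) over the 21 flat actions.
#'
#' @param policy A `br_hier_policy`.
#' @return A `br_channel`.
#' @export
induced_channel <- function(policy) {
  h <- policy$hierarchy
  n_w <- nrow(policy$level_posterior)
  post <- matrix(0, n_w, h$n_actions)
  for (l in seq_len(h$n_levels)) {
    acts <- level_actions(h, l)
    post[, acts] <- policy$level_posterior[, l] * policy$within_posterior[[l]]
  }
  new_channel(post, policy$prior)
}

#' Information decomposition of a hierarchical policy
#'
#' Splits the processed information into the level-selection cost I(W;L) and
#' the within-level cost I(W;A|L). By the chain rule their sum equals
#' I(W; (L,A)) of the induced joint channel.
#'
#' @param policy A `br_hier_policy`.
#' @return Tibble with columns `i_wl_bits` and `i_wa_given_l_bits`.
#' @export
information_decomposition <- function(policy) {
  prior <- policy$prior
  n_w <- length(prior)
  i_wl <- sum(vapply(seq_len(n_w), function(w)
    prior[w] * kl_nats(policy$level_posterior[w, ], policy$level_prior), numeric(1)))
  i_wal <- 0
  for (l in seq_len(policy$hierarchy$n_levels)) {
    i_wal <- i_wal + sum(vapply(seq_len(n_w), function(w)
      prior[w] * policy$level_posterior[w, l] *
        kl_nats(policy$within_posterior[[l]][w, ], policy$within_prior[[l]]),
      numeric(1)))
  }
  tibble::tibble(i_wl_bits = max(i_wl, 0) / log(2),
                 i_wa_given_l_bits = max(i_wal, 0) / log(2))
}

#' @export
print.br_hier_policy <- function(x, ...) {
  dec <- information_decomposition(x)
  cat(sprintf(
    "<br_hier_policy> beta1 = %g, beta2 = %g | I(W;L) = %.3f bits, I(W;A|L) = %.3f bits\n",
    x$beta1, x$beta2, dec$i_wl_bits, dec$i_wa_given_l_bits
  ))
  invisible(x)
}
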