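# Run code under a temporary seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Model families available for fitting
#'
#' @return Character vector of family identifiers.
#' @export
fit_families <- function() {
  c("basic", "fixed_prior", "distorted", "blurred",
    "gaussian", "thurstonian", "binomial", "hierarchical")
}

#' Default parameter grids per model family
#'
#' Modest exhaustive-search grids bracketing the regimes of every family:
#' inverse temperatures log-spaced, perceptual noise log-spaced, Binomial
#' observation lengths Fibonacci-like, utility distortions on a coarse
#' ordered simplex.
#'
#' @param n_beta,n_sigma Grid sizes for the beta and sigma axes.
#' @return Named list of named lists of parameter vectors.
#' @export
default_fit_grids <- function(n_beta = 12L, n_sigma = 12L) {
  betas <- exp(seq(log(0.5), log(500), length.out = n_beta))
  sigmas <- exp(seq(log(0.01), log(0.5), length.out = n_sigma))
  list(
    basic       = list(beta = betas),
    fixed_prior = list(beta = betas, q1 = c(0.05, 1 / 9, 0.2), q2 = c(0.02, 1 / 18, 0.08)),
    distorted   = list(beta = betas, v06 = c(0.2, 0.4, 0.6), v08 = c(0.5, 0.7, 0.8, 0.9)),
    blurred     = list(beta = betas, theta = c(0.5, 1, 2.05, 4, 8)),
    gaussian    = list(sigma = exp(seq(log(0.05), log(6), length.out = n_sigma))),
    thurstonian = list(sigma = sigmas),
    binomial    = list(T_obs = default_T_grid()),
    hierarchical = list(beta1 = exp(seq(log(0.5), log(200), length.out = 6)),
                        beta2 = exp(seq(log(0.5), log(200), length.out = 6)))
  )
}

# Expand a named list of parameter vectors into a lexicographically ordered
# grid data frame (ties in the fit break toward the first row).
expand_param_grid <- function(grid) {
  df <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df[do.call(order, df), , drop = FALSE]
}

#' Predicted channels of a family over a parameter grid
#'
#' Builds the model-predicted response channel at every grid point of a
#' family. Channels do not depend on the data being fit, so the result can be
#' computed once and reused across subjects and cross-validation folds.
#'
#' @param family One of [fit_families()].
#' @param grid Named list of parameter vectors (default from
#'   [default_fit_grids()]).
#' @param task A `br_task`.
#' @param kernel_family Kernel for the blurred family.
#' @return A list with `params` (grid tibble, lexicographic order) and
#'   `channels` (list of `br_channel`, one per row). Invalid grid points
#'   (e.g. unordered distortions) are dropped.
#' @export
family_channels <- function(family, grid = NULL, task = build_lab_task(),
                            kernel_family = "exponential") {
  family <- match.arg(family, fit_families())
  if (is.null(grid)) grid <- default_fit_grids()[[family]]
  params <- expand_param_grid(grid)
  build <- function(p) {
    switch(family,
      basic       = blahut_arimoto(task, beta = p$beta),
      fixed_prior = {
        q3 <- (1 - 3 * p$q1 - 6 * p$q2) / 12
        if (q3 <= 0) return(NULL)
        fixed_prior_solve(task, beta = p$beta, p0 = prior_spec(p$q1, p$q2, q3))
      },
      distorted   = {
        if (!(p$v06 > 0 && p$v06 < p$v08 && p$v08 < 1)) return(NULL)
        blahut_arimoto(distort_utility(task, p$v06, p$v08), beta = p$beta)
      },
      blurred     = blahut_arimoto(
        blur_utility(task, similarity_kernel(kernel_family, p$theta)),
        beta = p$beta),
      gaussian    = gaussian_response_channel(task, p$sigma),
      thurstonian = transducer_channel(transducer_model("thurstonian", sigma = p$sigma), task),
      binomial    = transducer_channel(transducer_model("binomial", T_obs = p$T_obs), task),
      hierarchical = induced_channel(
        solve_hierarchical(task, beta1 = p$beta1, beta2 = p$beta2))
    )
  }
  channels <- lapply(seq_len(nrow(params)), function(i) build(params[i, , drop = FALSE]))
  ok <- !vapply(channels, is.null, logical(1))
  list(params = tibble::as_tibble(params[ok, , drop = FALSE]),
       channels = channels[ok], family = family)
}

# Mean absolute error between a predicted channel and response frequencies,
# over all cells of the states listed in `states`.
channel_mae <- function(pred, freq, states = seq_len(nrow(freq))) {
  mean(abs(pred[states, , drop = FALSE] - freq[states, , drop = FALSE]))
}

#' Fit one model family to an empirical estimate by grid search
#'
#' Exhaustively scans the family's parameter grid and picks the channel
#' minimizing the mean absolute error between predicted choice probabilities
#' and the empirical response frequencies, over all 12 x 21 cells. Ties break
#' to the lexicographically smallest grid point.
#'
#' @param family One of [fit_families()].
#' @param train_est A `br_estimate` to fit.
#' @param task A `br_task`.
#' @param grid Named list of parameter vectors.
#' @param precomputed Optional result of [family_channels()] to reuse.
#' @return A list of class `br_fit` with `family`, `params` (one-row tibble
#'   of the best parameters), `channel`, `mae` and the scanned `grid_mae`.
#' @export
grid_fit <- function(family, train_est, task = build_lab_task(),
                     grid = NULL, precomputed = NULL) {
  fc <- if (is.null(precomputed)) family_channels(family, grid, task) else precomputed
  if (!length(fc$channels)) stop("empty parameter grid for family ", family)
  freq <- train_est$posterior
  maes <- vapply(fc$channels, function(ch) channel_mae(ch$posterior, freq), numeric(1))
  k <- which.min(maes)
  structure(
    list(family = fc$family, params = fc$params[k, , drop = FALSE],
         channel = fc$channels[[k]], mae = maes[k],
         grid_mae = dplyr::mutate(fc$params, mae = maes)),
    class = "br_fit"
  )
}

#' @export
print.br_fit <- function(x, ...) {
  cat(sprintf("<br_fit> family = %s | train MAE = %.5f\n", x$family, x$mae))
  print(x$params)
  invisible(x)
}

#' @export
tidy.br_fit <- function(x, ...) x$grid_mae

#' @export
glance.br_fit <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(family = x$family, mae = x$mae), x$params)
}

# probability the fitted channel assigns to the level containing each
# held-out response, given its world state
level_score <- function(pred, hierarchy, world_state, action) {
  lev <- level_of_action(hierarchy, action)
  mass <- vapply(seq_along(action), function(i)
    sum(pred[world_state[i], level_actions(hierarchy, lev[i])]), numeric(1))
  mean(mass)
}

#' Cross-validated model comparison
#'
#' For each subject x condition cell, trials are partitioned at random into
#' `n_folds` folds of near-equal size (seeded, reproducible). Each family is
#' fit by [grid_fit()] on the training folds' response frequencies and
#' evaluated on the held-out fold by (i) the mean absolute error between
#' held-out response frequencies and predicted probabilities -- states with no
#' held-out trials are excluded from the mean -- and (ii) the mean predicted
#' probability of the level containing each held-out response.
#'
#' @param trials Trial tibble.
#' @param families Character vector of families to compare.
#' @param n_folds Number of folds (default 10).
#' @param seed RNG seed for the fold assignment (default 20191120).
#' @param task A `br_task`.
#' @param grids Optional named list of per-family grids.
#' @return Tibble with one row per subject x condition x family x fold:
#'   `mae`, `level_score` and the best-fit parameters as a packed string.
#' @export
crossval <- function(trials, families = fit_families(), n_folds = 10L,
                     seed = 20191120L, task = build_lab_task(), grids = NULL) {
  validate_trials(trials, task)
  fc_all <- lapply(stats::setNames(families, families), function(f)
    family_channels(f, grid = grids[[f]], task = task))
  groups <- dplyr::distinct(trials, .data$subject, .data$condition)
  out <- purrr::map_dfr(seq_len(nrow(groups)), function(g) {
    subject <- groups$subject[g]
    condition <- groups$condition[g]
    tt <- trials[trials$subject == subject & trials$condition == condition, ]
    n <- nrow(tt)
    if (n < n_folds) stop("fewer trials than folds for ", subject, "/", condition)
    fold <- with_seed(seed + g, sample(rep(seq_len(n_folds), length.out = n)))
    purrr::map_dfr(seq_len(n_folds), function(k) {
      train <- tt[fold != k, ]
      held <- tt[fold == k, ]
      train_est <- estimate_response(train)
      held_counts <- table(factor(held$world_state, levels = 1:12),
                           factor(held$action, levels = 1:21))
      held_n <- rowSums(held_counts)
      held_states <- which(held_n > 0)
      held_freq <- matrix(0, 12, 21)
      held_freq[held_states, ] <- held_counts[held_states, ] / held_n[held_states]
      purrr::map_dfr(families, function(f) {
        fit <- grid_fit(f, train_est, task, precomputed = fc_all[[f]])
        tibble::tibble(
          subject = subject, condition = condition, family = f, fold = k,
          mae = channel_mae(fit$channel$posterior, held_freq, held_states),
          level_score = level_score(fit$channel$posterior, task$hierarchy,
                                    held$world_state, held$action),
          params = paste(names(fit$params), signif(unlist(fit$params), 4),
                         sep = "=", collapse = ", ")
        )
      })
    })
  })
  out
}
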