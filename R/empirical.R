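#' Experimental condition names
#'
#' The six conditions cross three perceptual difficulties (easy, medium,
#' hard) with two response deadlines (slow = 5000 ms, fast = 450 ms).
#'
#' @return Character vector of the six condition names, in the order run.
#' @export
condition_names <- function() {
  c("easySlow", "easyFast", "mediumSlow", "mediumFast", "hardSlow", "hardFast")
}

validate_trials <- function(trials, task = NULL) {
  need <- c("subject", "condition", "trial", "world_state", "action", "correct", "rt_ms")
  miss <- setdiff(need, names(trials))
  if (length(miss)) stop("trial table is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(trials)) {
    stopifnot(all(trials$world_state >= 1), all(trials$world_state <= 12),
              all(trials$action >= 1), all(trials$action <= 21))
    bad <- setdiff(unique(trials$condition), condition_names())
    if (length(bad)) stop("unknown condition(s): ", paste(bad, collapse = ", "))
  }
  invisible(trials)
}

#' Read / write behavioral trial tables
#'
#' Trial tables are tab-separated UTF-8 text with header columns `subject`,
#' `condition`, `trial`, `world_state` (1-12), `action` (1-21), `correct`
#' (0/1) and `rt_ms`.
#'
#' @param path File path.
#' @param trials A trial tibble.
#' @return `read_trials()` returns a tibble; `write_trials()` returns `path`
#'   invisibly.
#' @export
read_trials <- function(path) {
  trials <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_trials(trials)
}

#' @rdname read_trials
#' @export
write_trials <- function(trials, path) {
  validate_trials(trials)
  readr::write_tsv(trials, path)
  invisible(path)
}

#' Empirical response distribution of a subject in a condition
#'
#' Plug-in maximum-likelihood estimate of the response probabilities
#' p_exp(a|w) from trial counts. Every world state must have at least one
#' trial; a missing state is a data defect and raises an error naming it.
#'
#' @param trials Trial tibble (see [read_trials()]).
#' @param subject,condition Optional filters; by default all rows are pooled.
#' @param n_states,n_actions Dimensions of the count matrix.
#' @return A list of class `br_estimate` with `counts` (states x actions),
#'   `posterior` (row frequencies), `n_per_state` and the uniform `prior`.
#' @export
estimate_response <- function(trials, subject = NULL, condition = NULL,
                              n_states = 12L, n_actions = 21L) {
  validate_trials(trials)
  if (!is.null(subject)) trials <- trials[trials$subject %in% subject, ]
  if (!is.null(condition)) trials <- trials[trials$condition %in% condition, ]
  counts <- matrix(0L, n_states, n_actions)
  tab <- table(factor(trials$world_state, levels = seq_len(n_states)),
               factor(trials$action, levels = seq_len(n_actions)))
  counts[] <- as.integer(tab)
  n_w <- rowSums(counts)
  if (any(n_w == 0))
    stop("no trials for world state(s): ", paste(which(n_w == 0), collapse = ", "))
  structure(
    list(counts = counts, posterior = counts / n_w, n_per_state = n_w,
         prior = rep(1 / n_states, n_states)),
    class = "br_estimate"
  )
}

as_channel <- function(est) new_channel(est$posterior, est$prior)

#' Plug-in mutual information of an empirical estimate
#'
#' Evaluates the mutual information of the empirical response frequencies
#' (no bias correction; the plug-in estimator has a known upward
#' finite-sample bias).
#'
#' @param est A `br_estimate`.
#' @param prior State prior (default the estimate's uniform prior).
#' @return Mutual information in bits.
#' @export
empirical_information <- function(est, prior = est$prior) {
  mutual_information_bits(new_channel(est$posterior, prior))
}

#' Empirical expected utility
#'
#' @param est A `br_estimate`.
#' @param utility Utility matrix or `br_task`.
#' @return Expected utility under the empirical response frequencies.
#' @export
empirical_utility <- function(est, utility) {
  expected_utility(as_channel(est), utility)
}

#' Per-condition descriptive statistics of a trial table
#'
#' For each condition: overall hit rate, the share of hits achieved on each
#' abstraction level, each level's contribution to the mean per-trial utility,
#' and the mean selected level.
#'
#' @param trials Trial tibble.
#' @param task A `br_task`.
#' @return Tibble with one row per condition and columns `n_trials`,
#'   `hit_rate`, `hit_share_l1..l3`, `utility_l1..l3` (contributions summing
#'   to `mean_utility`), `mean_utility`, `mean_level`.
#' @export
descriptive_stats <- function(trials, task = build_lab_task()) {
  validate_trials(trials, task)
  h <- task$hierarchy
  trials |>
    dplyr::mutate(
      level = level_of_action(h, .data$action),
      utility = task$utility[cbind(.data$world_state, .data$action)],
      hit = .data$utility > 0
    ) |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      hit_rate = mean(.data$hit),
      hit_share_l1 = sum(.data$hit & .data$level == 1) / max(sum(.data$hit), 1L),
      hit_share_l2 = sum(.data$hit & .data$level == 2) / max(sum(.data$hit), 1L),
      hit_share_l3 = sum(.data$hit & .data$level == 3) / max(sum(.data$hit), 1L),
      utility_l1 = sum(.data$utility[.data$level == 1]) / dplyr::n(),
      utility_l2 = sum(.data$utility[.data$level == 2]) / dplyr::n(),
      utility_l3 = sum(.data$utility[.data$level == 3]) / dplyr::n(),
      mean_utility = mean(.data$utility),
      mean_level = mean(.data$level),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$condition, condition_names()))
}

#' Per-subject-condition efficiency analysis
#'
#' The main empirical pipeline: estimates each subject-condition response
#' distribution, computes its plug-in mutual information, expected utility
#' and efficiency against the supplied frontier.
#'
#' @param trials Trial tibble.
#' @param task A `br_task`.
#' @param frontier A `br_frontier` for the same task (computed if missing).
#' @return Tibble with columns `subject`, `condition`, `n_trials`,
#'   `mutual_info_bits`, `expected_utility`, `efficiency`, `mean_level`.
#' @export
analyze_trials <- function(trials, task = build_lab_task(),
                           frontier = efficiency_frontier(task)) {
  validate_trials(trials, task)
  groups <- dplyr::distinct(trials, .data$subject, .data$condition)
  purrr::pmap_dfr(groups, function(subject, condition) {
    est <- estimate_response(trials, subject = subject, condition = condition)
    i <- empirical_information(est)
    u <- empirical_utility(est, task)
    tibble::tibble(
      subject = subject, condition = condition,
      n_trials = sum(est$counts),
      mutual_info_bits = i,
      expected_utility = u,
      efficiency = efficiency(u, i, frontier),
      mean_level = level_statistics(as_channel(est), task$hierarchy)$mean_level
    )
  })
}

#' Closest theoretical channel on a curve
#'
#' Finds the stored channel on a frontier or constrained curve minimizing the
#' elementwise L2 distance between the empirical conditional matrix
#' p_exp(a|w) and the theoretical p(a|w).
#'
#' @param est A `br_estimate` (or `br_channel`).
#' @param curve A `br_frontier` or `br_curve` built with
#'   `keep_channels = TRUE`.
#' @return A list with `channel`, `index`, `distance` and the curve row.
#' @export
nearest_frontier_channel <- function(est, curve) {
  if (!"channel" %in% names(curve) || nrow(curve) == 0)
    stop("curve must store channels (use keep_channels = TRUE)")
  p <- if (inherits(est, "br_channel")) est$posterior else est$posterior
  d <- vapply(curve$channel, function(ch) sqrt(sum((p - ch$posterior)^2)), numeric(1))
  k <- which.min(d)
  list(channel = curve$channel[[k]], index = k, distance = d[k],
       point = curve[k, setdiff(names(curve), "channel")])
}

#' Alternative 12-action information accounting
#'
#' Re-expresses the 21-action response distribution on the 12 finest buttons
#' by spreading each action's probability uniformly over its top-level
#' descendants (a coarse button counts as 4 precise ones, an intermediate as
#' 2), and returns the plug-in mutual information of the resulting 12 x 12
#' channel. A random coarse-button press then generates log2 3 bits rather
#' than log2 21. Coarsening never increases information.
#'
#' @param est A `br_estimate` (or `br_channel`) over the 21 flat actions.
#' @param hierarchy An [action_hierarchy()].
#' @param prior State prior.
#' @return Mutual information in bits of the 12-action accounting.
#' @export
alternative_information_12 <- function(est, hierarchy = action_hierarchy(),
                                       prior = NULL) {
  p <- if (inherits(est, "br_channel")) est$posterior else est$posterior
  if (is.null(prior)) prior <- rep(1 / nrow(p), nrow(p))
  spread <- matrix(0, hierarchy$n_actions, 12L)
  for (a in seq_len(hierarchy$n_actions)) {
    d <- top_descendants(hierarchy, a)
    spread[a, d] <- 1 / length(d)
  }
  mutual_information_bits(new_channel(p %*% spread, prior))
}
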