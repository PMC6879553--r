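#' Configure a synthetic behavioral cohort
#'
#' Describes a cohort emulating the experiment's structure: `n_subjects`
#' subjects each running the six conditions in order, with
#' `trials_per_condition` trials per condition balanced over the twelve world
#' states (600 = 12 x 50 by default). The default generator is a Thurstonian
#' observer whose perceptual noise grows with condition difficulty, with
#' multiplicative log-normal heterogeneity across subjects (capped at a
#' factor of 2); these generator values are stand-ins chosen to span the
#' task's resource range, not measured quantities.
#'
#' @param n_subjects Number of subjects (default 11).
#' @param trials_per_condition Trials per condition (default 600).
#' @param conditions Condition names (default the six standard ones).
#' @param family Generating family: `"thurstonian"`, `"binomial"` or
#'   `"basic"` (bounded-rational channel at a given beta).
#' @param condition_params Named numeric vector: the family's resource
#'   parameter per condition (sigma, T, or beta).
#' @param subject_sdlog Log-normal sd of the per-subject multiplicative
#'   factor on the resource parameter (0 disables heterogeneity; the factor
#'   is clipped to \[1/2, 2\]).
#' @param seed Base RNG seed.
#' @return A list of class `br_cohort_config`.
#' @export
cohort_config <- function(n_subjects = 11L, trials_per_condition = 600L,
                          conditions = condition_names(),
                          family = "thurstonian",
                          condition_params = NULL,
                          subject_sdlog = 0.25, seed = 20191120L) {
  if (is.null(condition_params)) {
    condition_params <- switch(family,
      thurstonian = c(easySlow = 0.030, easyFast = 0.045, mediumSlow = 0.060,
                      mediumFast = 0.080, hardSlow = 0.110, hardFast = 0.150),
      binomial    = c(easySlow = 800, easyFast = 400, mediumSlow = 200,
                      mediumFast = 100, hardSlow = 50, hardFast = 25),
      basic       = c(easySlow = 200, easyFast = 100, mediumSlow = 50,
                      mediumFast = 25, hardSlow = 12, hardFast = 6),
      stop("no default parameters for family ", family)
    )
  }
  stopifnot(all(conditions %in% names(condition_params)))
  structure(
    list(n_subjects = as.integer(n_subjects),
         trials_per_condition = as.integer(trials_per_condition),
         conditions = conditions, family = family,
         condition_params = condition_params,
         subject_sdlog = subject_sdlog, seed = as.integer(seed)),
    class = "br_cohort_config"
  )
}

#' Read a cohort configuration from a YAML file
#'
#' Accepts keys matching the arguments of [cohort_config()].
#'
#' @param path YAML file path.
#' @return A `br_cohort_config`.
#' @export
read_cohort_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read config files")
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$condition_params)) cfg$condition_params <- unlist(cfg$condition_params)
  do.call(cohort_config, cfg)
}

generator_channel <- function(family, param, task) {
  switch(family,
    thurstonian = transducer_channel(transducer_model("thurstonian", sigma = param), task),
    binomial    = transducer_channel(transducer_model("binomial", T_obs = round(param)), task),
    basic       = blahut_arimoto(task, beta = param),
    stop("unknown generating family ", family)
  )
}

#' Sample trials from a channel
#'
#' Draws (world state, action) pairs from a channel: states either i.i.d.
#' from the prior or on a balanced, shuffled schedule (equal repetitions per
#' state, requiring `n` divisible by the number of states); actions from the
#' channel row. Correctness is derived from the utility table. Response times
#' are not modeled and emitted as `NA`.
#'
#' @param channel A `br_channel`.
#' @param n Number of trials (0 gives an empty table).
#' @param task A `br_task`.
#' @param balanced Use the balanced state schedule (default TRUE).
#' @param seed Optional seed; if `NULL`, uses the current RNG stream.
#' @param subject,condition Label columns for the emitted rows.
#' @return A trial tibble fragment (see [read_trials()] for the dialect).
#' @export
sample_trials <- function(channel, n, task = build_lab_task(), balanced = TRUE,
                          seed = NULL, subject = "S01", condition = "easySlow") {
  if (n < 0) stop("n must be non-negative")
  draw <- function() {
    if (n == 0) return(tibble::tibble(
      subject = character(), condition = character(), trial = integer(),
      world_state = integer(), action = integer(), correct = integer(),
      rt_ms = numeric()
    ))
    n_states <- nrow(channel$posterior)
    w <- if (balanced) {
      if (n %% n_states != 0) stop("balanced schedule needs n divisible by ", n_states)
      sample(rep(seq_len(n_states), each = n %/% n_states))
    } else {
      sample.int(n_states, n, replace = TRUE, prob = channel$prior)
    }
    a <- vapply(w, function(wi)
      sample.int(ncol(channel$posterior), 1L, prob = channel$posterior[wi, ]),
      integer(1))
    tibble::tibble(
      subject = subject, condition = condition, trial = seq_len(n),
      world_state = as.integer(w), action = as.integer(a),
      correct = as.integer(task$utility[cbind(w, a)] > 0),
      rt_ms = NA_real_
    )
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Simulate a synthetic cohort
#'
#' Generates the full trial table of a configured cohort: per subject, a
#' heterogeneity factor scales the per-condition resource parameter; per
#' subject x condition, the generating channel is built and a balanced,
#' shuffled block of trials is sampled. The same seed reproduces the same
#' table exactly.
#'
#' @param config A [cohort_config()].
#' @param task A `br_task`.
#' @return A trial tibble with attribute `generators`: a tibble of the
#'   per-subject-condition generating parameters and channels.
#' @export
simulate_cohort <- function(config = cohort_config(), task = build_lab_task()) {
  stopifnot(inherits(config, "br_cohort_config"))
  subjects <- sprintf("S%02d", seq_len(config$n_subjects))
  factors <- with_seed(config$seed, {
    f <- exp(stats::rnorm(config$n_subjects, 0, config$subject_sdlog))
    pmin(pmax(f, 0.5), 2)
  })
  gen <- list()
  rows <- list()
  k <- 0L
  for (s in seq_along(subjects)) {
    for (cond in config$conditions) {
      k <- k + 1L
      param <- config$condition_params[[cond]] *
        (if (config$family == "binomial") 1 / factors[s] else
           if (config$family == "basic") 1 / factors[s] else factors[s])
      ch <- generator_channel(config$family, param, task)
      rows[[k]] <- sample_trials(
        ch, config$trials_per_condition, task,
        balanced = TRUE, seed = config$seed + 1000L * s + match(cond, condition_names()),
        subject = subjects[s], condition = cond
      )
      gen[[k]] <- tibble::tibble(subject = subjects[s], condition = cond,
                                 family = config$family, param = param,
                                 channel = list(ch))
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "generators") <- dplyr::bind_rows(gen)
  out
}
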