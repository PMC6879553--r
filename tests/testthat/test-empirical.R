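make_trials <- function(task, w, a, subject = "S01", condition = "easySlow") {
  tibble::tibble(
    subject = subject, condition = condition, trial = seq_along(w),
    world_state = as.integer(w), action = as.integer(a),
    correct = as.integer(task$utility[cbind(w, a)] > 0),
    rt_ms = 500
  )
}

test_that("response estimation is the plug-in frequency table", {
  task <- lab_task()
  top <- vapply(1:12, function(w) correct_action(task, w, 3), integer(1))
  tt <- make_trials(task, 1:12, top)
  est <- estimate_response(tt)
  expect_equal(est$posterior, deterministic_level_channel(task, 3)$posterior)
  # duplicating every trial leaves the estimate unchanged
  tt2 <- dplyr::bind_rows(tt, tt)
  expect_equal(estimate_response(tt2)$posterior, est$posterior)
  expect_equal(estimate_response(tt2)$n_per_state, est$n_per_state * 2)
  # a state with no trials is a data defect
  expect_error(estimate_response(tt[-3, ]), "world state")
  expect_error(estimate_response(tt[trunc(0), ]))
})

test_that("sampled estimates stay inside binomial confidence bands", {
  task <- lab_task()
  ch <- transducer_channel(transducer_model("thurstonian", sigma = 0.06), task)
  tt <- sample_trials(ch, 600, task, seed = 99)
  est <- estimate_response(tt)
  # 99% binomial band per cell, against the generating probabilities
  z <- qnorm(0.995)
  n <- est$n_per_state
  ok <- abs(est$posterior - ch$posterior) <=
    z * sqrt(ch$posterior * (1 - ch$posterior) / n) + 1e-12
  expect_gt(mean(ok), 0.98)
})

test_that("plug-in information and utility evaluate canonical responders", {
  task <- lab_task()
  top <- vapply(1:12, function(w) correct_action(task, w, 3), integer(1))
  est_top <- estimate_response(make_trials(task, 1:12, top))
  expect_equal(empirical_information(est_top), log2(12))
  expect_equal(empirical_utility(est_top, task), 1.0)
  # constant responder: no information, the bottom button's base rate
  est_const <- estimate_response(make_trials(task, 1:12, rep(1L, 12)))
  expect_equal(empirical_information(est_const), 0)
  expect_equal(empirical_utility(est_const, task), 0.2, tolerance = 1e-12)
  # 50/50 mix of perfect-top and constant responders
  est_mix <- estimate_response(make_trials(task, rep(1:12, 2), c(top, rep(1L, 12))))
  expect_equal(empirical_utility(est_mix, task), 0.6, tolerance = 1e-12)
  # hand-computed 2x2 plug-in mutual information
  counts <- rbind(c(3, 1), c(1, 3))
  p <- counts / rowSums(counts)
  m <- colMeans(p)
  by_hand <- sum(0.5 * p * log2(p / rep(m, each = 2)))
  est22 <- structure(list(posterior = p, prior = c(0.5, 0.5)), class = "br_estimate")
  expect_equal(empirical_information(est22), by_hand, tolerance = 1e-12)
  expect_lte(empirical_information(est_top), log2(12) + 1e-9)
})

test_that("descriptive statistics partition hits and utility by level", {
  task <- lab_task()
  top <- vapply(1:12, function(w) correct_action(task, w, 3), integer(1))
  bot <- vapply(1:12, function(w) correct_action(task, w, 1), integer(1))
  all_top <- make_trials(task, 1:12, top)
  ds <- descriptive_stats(all_top, task)
  expect_equal(ds$hit_rate, 1)
  expect_equal(ds$mean_level, 3)
  expect_equal(ds$hit_share_l3, 1)
  # alternate correct-bottom and wrong-top responses
  wrong_top <- ifelse(top < 21, top + 1L, 20L)
  mixed <- make_trials(task, rep(1:12, 2), c(bot, wrong_top))
  ds2 <- descriptive_stats(mixed, task)
  expect_equal(ds2$hit_rate, 0.5)
  expect_equal(c(ds2$hit_share_l1, ds2$hit_share_l2, ds2$hit_share_l3), c(1, 0, 0))
  expect_equal(ds2$utility_l1 + ds2$utility_l2 + ds2$utility_l3, ds2$mean_utility,
               tolerance = 1e-12)
  expect_equal(ds2$mean_utility, 0.3, tolerance = 1e-12)
})

test_that("nearest-frontier matching minimizes the matrix L2 distance", {
  task <- lab_task()
  fr <- lab_frontier()
  k <- 30L
  stored <- fr$channel[[k]]
  est <- structure(list(posterior = stored$posterior, prior = task$prior),
                   class = "br_estimate")
  hit <- nearest_frontier_channel(est, fr)
  expect_equal(hit$distance, 0)
  expect_equal(hit$channel$posterior, stored$posterior)
  # a perturbed estimate: the reported distance beats every stored channel
  pert <- stored$posterior * 0.9 + matrix(1 / 21, 12, 21) * 0.1
  est2 <- structure(list(posterior = pert, prior = task$prior), class = "br_estimate")
  hit2 <- nearest_frontier_channel(est2, fr)
  d_all <- vapply(fr$channel, function(ch) sqrt(sum((pert - ch$posterior)^2)),
                  numeric(1))
  expect_equal(hit2$distance, min(d_all))
  expect_error(nearest_frontier_channel(est, fr[, setdiff(names(fr), "channel")]))
})

test_that("the 12-action accounting coarsens information correctly", {
  task <- lab_task()
  h <- task$hierarchy
  # perfect bottom-level play: 4-way spread leaves log2 3 bits
  bot <- deterministic_level_channel(task, 1)
  expect_equal(alternative_information_12(bot), log2(3), tolerance = 1e-12)
  # perfect top-level play is unchanged
  top <- deterministic_level_channel(task, 3)
  expect_equal(alternative_information_12(top), log2(12), tolerance = 1e-12)
  # constant single action carries nothing
  const <- new_channel(matrix(rep(c(1, rep(0, 20)), each = 12), 12, 21))
  expect_equal(alternative_information_12(const), 0)
  # coarsening never increases information (random estimates)
  set.seed(31)
  for (rep in 1:10) {
    p <- matrix(rgamma(12 * 21, 0.5), 12)
    p <- p / rowSums(p)
    ch <- new_channel(p)
    expect_lte(alternative_information_12(ch),
               mutual_information_bits(ch) + 1e-9)
  }
})

test_that("empirical points converge to the generating frontier point", {
  task <- lab_task()
  ch <- blahut_arimoto(task, beta = 6)
  target <- c(mutual_information_bits(ch), expected_utility(ch, task))
  dist_at <- function(n) {
    est <- estimate_response(sample_trials(ch, n, task, seed = 123))
    sqrt(sum((c(empirical_information(est), empirical_utility(est, task)) - target)^2))
  }
  d600 <- dist_at(600)
  d60k <- dist_at(60000)
  expect_lt(d60k, d600)
  expect_lt(d60k, 0.05)
})

test_that("trial tables survive a TSV round trip and reject bad conditions", {
  task <- lab_task()
  tt <- sample_trials(blahut_arimoto(task, beta = 5), 120, task, seed = 3,
                      condition = "hardFast")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trials(tt, path)
  back <- read_trials(path)
  expect_equal(back$action, tt$action)
  expect_equal(back$world_state, tt$world_state)
  bad <- dplyr::mutate(tt, condition = "impossiblyHard")
  expect_error(write_trials(bad, path), "unknown condition")
})

test_that("analyze_trials reports one efficiency row per subject-condition", {
  task <- lab_task()
  fr <- lab_frontier()
  tt <- dplyr::bind_rows(
    sample_trials(blahut_arimoto(task, beta = 20), 240, task, seed = 1,
                  subject = "S01", condition = "easySlow"),
    sample_trials(blahut_arimoto(task, beta = 2), 240, task, seed = 2,
                  subject = "S01", condition = "hardFast")
  )
  res <- analyze_trials(tt, task, fr)
  expect_equal(nrow(res), 2L)
  expect_true(all(res$efficiency <= 1.05))
  easy <- res[res$condition == "easySlow", ]
  hard <- res[res$condition == "hardFast", ]
  expect_gt(easy$mutual_info_bits, hard$mutual_info_bits)
  expect_gt(easy$expected_utility, hard$expected_utility)
})
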