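test_that("prior specifications normalize over the level-blocked actions", {
  p_act <- prior_spec(preset = "uniform_actions")
  expect_equal(as.vector(p_act), rep(1 / 21, 21), ignore_attr = TRUE)
  p_lev <- prior_spec(preset = "uniform_levels")
  expect_equal(unname(p_lev[c(1, 4, 10)]), c(1 / 9, 1 / 18, 1 / 36))
  expect_equal(sum(p_lev), 1, tolerance = 1e-12)
  expect_error(prior_spec(0.2, 0.2, 0.2), "must equal 1")
  expect_error(frontier_fixed_prior(lab_task(), rep(c(1 / 9, 0, 1 / 18), c(3, 6, 12)),
                                    beta_grid = 1), "strictly positive")
})

test_that("utility distortion remaps payoffs and preserves the zero pattern", {
  task <- lab_task()
  d <- distort_utility(task, 0.36, 0.64)   # the alpha = 2 power distortion
  expect_equal(sort(unique(as.vector(d$utility))), c(0, 0.36, 0.64, 1))
  expect_equal(d$utility > 0, task$utility > 0)
  # near-identity distortion changes nothing but the two payoff values
  d2 <- distort_utility(task, 0.6, 0.8)
  expect_equal(d2$utility, task$utility)
  expect_error(distort_utility(task, 0.8, 0.6))
  expect_error(distort_utility(task, 0.5, 1.2))
})

test_that("similarity blur decays within levels and keeps the diagonal", {
  task <- lab_task()
  b <- blur_utility(task, similarity_kernel("exponential", 2.05))
  # correct cells keep their full payoff
  for (w in 1:12) for (l in 1:3)
    expect_equal(b$utility[w, correct_action(task, w, l)], task$hierarchy$payoff[l])
  # one-button near miss on the top level
  expect_equal(b$utility[1, 11], exp(-2.05) * 1.0, tolerance = 1e-12)
  # no cross-level blur: level blocks depend only on their own correct button
  expect_equal(b$utility[1, 4], 0.8)
  expect_equal(b$utility[1, 5], exp(-2.05) * 0.8, tolerance = 1e-12)
  # blur adds mass
  expect_true(all(rowSums(b$utility) > rowSums(task$utility)))
  # a very sharp kernel approaches the crisp utility
  sharp <- blur_utility(task, similarity_kernel("exponential", 20))
  off <- abs(sharp$utility - task$utility)
  expect_lt(max(off), 1e-8)
  # gaussian kernel with k(0) = 1
  g <- blur_utility(task, similarity_kernel("gaussian", 1))
  expect_equal(g$utility[1, 11], exp(-0.5) * 1.0, tolerance = 1e-12)
})

test_that("high-rationality solutions concentrate on the crisp argmax cells", {
  task <- lab_task()
  blurred <- blur_utility(task, similarity_kernel("exponential", 1))
  ch_b <- blahut_arimoto(blurred, beta = 300)
  ch_c <- blahut_arimoto(task, beta = 300)
  argmax_b <- apply(ch_b$posterior, 1, which.max)
  argmax_c <- apply(ch_c$posterior, 1, which.max)
  expect_equal(argmax_b, argmax_c)
})

test_that("fixed-prior curves approach the rational limit and stay dominated", {
  task <- lab_task()
  fr <- lab_frontier()
  curve <- frontier_fixed_prior(task, prior_spec(preset = "uniform_levels"),
                                beta_grid = default_beta_grid(25))
  last <- curve[nrow(curve), ]
  expect_equal(last$expected_utility, 1, tolerance = 1e-3)
  expect_equal(last$mutual_info_bits, log2(12), tolerance = 1e-3)
  u_max <- frontier_utility_bound(fr, curve$mutual_info_bits)
  expect_true(all(curve$expected_utility <= u_max + 1e-6))
})

test_that("gaussian response profiles trade precision for level height", {
  task <- lab_task()
  # degenerate gaussian: perfect top-level play
  ch0 <- gaussian_response_channel(task, 1e-4)
  expect_equal(expected_utility(ch0, task), 1.0, tolerance = 1e-9)
  # very wide gaussian: near-uniform responses on the coarsest level
  chw <- gaussian_response_channel(task, 100)
  expect_equal(level_statistics(chw, task$hierarchy)$mean_level, 1)
  expect_equal(expected_utility(chw, task), 0.2, tolerance = 1e-2)
  # mean level is a step function of sigma: few distinct values, non-increasing
  curve <- gaussian_response_curve(task, exp(seq(log(1e-3), log(20), length.out = 25)))
  expect_true(all(diff(curve$mean_level) <= 1e-9))
  expect_lte(length(unique(round(curve$mean_level, 6))), 8)
})

test_that("transducer channels cover the degenerate limits", {
  task <- lab_task()
  # noiseless thurstonian observer: perfect top-level identification
  ch <- transducer_channel(transducer_model("thurstonian", sigma = 1e-4), task)
  expect_equal(expected_utility(ch, task), 1.0, tolerance = 1e-9)
  expect_equal(mutual_information_bits(ch), log2(12), tolerance = 1e-9)
  # binomial with no observations: a single uninformative percept
  ch0 <- transducer_channel(transducer_model("binomial", T_obs = 0), task)
  expect_equal(mutual_information_bits(ch0), 0)
  expect_equal(expected_utility(ch0, task), 0.2)
  expect_true(all(ch0$posterior[, 1] == 1))   # a coarse button, lowest index
})

test_that("thurstonian channels show the bow effect at moderate noise", {
  task <- lab_task()
  mean_level_by_state <- function(ch) {
    lv <- level_of_action(task$hierarchy, 1:21)
    as.vector(ch$posterior %*% lv)
  }
  ch <- transducer_channel(transducer_model("thurstonian", sigma = 0.2), task)
  ml <- mean_level_by_state(ch)
  expect_gte(ml[1], ml[6])
  expect_gte(ml[12], ml[6])
  # strictly higher boundary levels in the moderate-noise regime
  ch2 <- transducer_channel(transducer_model("thurstonian", sigma = 0.08), task)
  ml2 <- mean_level_by_state(ch2)
  expect_gt(ml2[1], ml2[6])
  expect_gt(ml2[12], ml2[6])
})

test_that("transducer curves are monotone in their resource parameter", {
  task <- lab_task()
  bt <- transducer_curve("binomial", c(0L, 2L, 8L, 34L, 144L, 610L, 2000L), task)
  expect_equal(bt$expected_utility[1], 0.2)
  expect_equal(bt$mutual_info_bits[1], 0)
  expect_equal(bt$expected_utility[nrow(bt)], 1, tolerance = 1e-2)
  expect_true(all(diff(bt$expected_utility) >= -1e-9))
  th <- transducer_curve("thurstonian", c(0.005, 0.02, 0.05, 0.1, 0.2, 0.5), task)
  expect_true(all(diff(th$expected_utility) <= 1e-9))
})

test_that("constrained curves never beat the unconstrained frontier", {
  task <- lab_task()
  fr <- lab_frontier()
  curves <- list(
    frontier_fixed_prior(task, prior_spec(preset = "uniform_actions"),
                         beta_grid = default_beta_grid(15)),
    gaussian_response_curve(task, exp(seq(log(0.01), log(10), length.out = 15))),
    transducer_curve("thurstonian", exp(seq(log(0.01), log(0.5), length.out = 15)), task),
    transducer_curve("binomial", c(0L, 3L, 13L, 55L, 233L, 1000L), task)
  )
  for (cv in curves) {
    u_max <- frontier_utility_bound(fr, cv$mutual_info_bits)
    expect_true(all(cv$expected_utility <= u_max + 1e-6))
  }
})

test_that("binomial Bayes matches the conjugate Beta posterior", {
  grid <- seq(0, 1, length.out = 2001)
  set.seed(23)
  for (rep in 1:20) {
    T_obs <- sample(0:200, 1)
    x <- sample(0:T_obs, 1)
    analytic <- beta_binomial_posterior(x, T_obs, grid = grid)
    # brute-force discrete Bayes under a uniform prior on the same grid
    lik <- stats::dbinom(x, T_obs, grid)
    brute <- lik / sum(lik)
    expect_lt(0.5 * sum(abs(analytic - brute)), 1e-6)
  }
})

test_that("thurstonian truncation constant matches numeric integration", {
  for (w in c(1 / 24, 0.375, 23 / 24)) for (s in c(0.05, 0.2, 0.5)) {
    z <- braidr:::thurstonian_truncation(w, s)
    num <- stats::integrate(function(x) stats::dnorm(x, w, s), 0, 1,
                            rel.tol = 1e-10)$value
    expect_equal(z, num, tolerance = 1e-6)
  }
})
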