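test_that("zero temperature gives a prior-only channel", {
  task <- lab_task()
  ch <- blahut_arimoto(task, beta = 0)
  expect_equal(max(abs(sweep(ch$posterior, 2, ch$marginal))), 0)
  expect_equal(mutual_information_bits(ch), 0)
})

test_that("the rational limit identifies every state at the top level", {
  task <- lab_task()
  ch <- blahut_arimoto(task, beta = 1000)
  expect_equal(expected_utility(ch, task), 1.0, tolerance = 1e-3)
  expect_equal(mutual_information_bits(ch), log2(12), tolerance = 1e-3)
})

test_that("solver matches exhaustive simplex grid search on random utilities", {
  set.seed(41)
  for (rep in 1:3) {
    u2 <- matrix(runif(6), 2, 3)
    p2 <- c(0.5, 0.5)
    ch <- blahut_arimoto(u2, p2, beta = 2)
    f_ba <- ba_objective(ch, u2, 2)
    f_grid <- primal_grid_max_2row(u2, p2, beta = 2, step = 0.01)
    expect_gte(f_ba, f_grid - 1e-9)   # no grid point can beat the optimum
    expect_equal(f_ba, f_grid, tolerance = 1e-3)
  }
  # 3-state problems via the closed-form dual on the marginal simplex
  for (rep in 1:3) {
    u3 <- matrix(runif(9), 3, 3)
    p3 <- rep(1 / 3, 3)
    ch <- blahut_arimoto(u3, p3, beta = 2)
    f_ba <- ba_objective(ch, u3, 2)
    f_grid <- dual_grid_max(u3, p3, beta = 2, step = 0.002)
    expect_equal(f_ba, f_grid, tolerance = 1e-3)
  }
})

test_that("free energy is non-decreasing across iterations", {
  set.seed(7)
  task <- lab_task()
  for (beta in c(0.5, 2, 10, 100)) {
    tr <- attr(blahut_arimoto(task, beta = beta), "objective_trace")
    expect_true(all(diff(tr) >= -1e-12))
  }
  u <- matrix(runif(12), 3, 4)
  tr <- attr(blahut_arimoto(u, beta = 3), "objective_trace")
  expect_true(all(diff(tr) >= -1e-12))
})

test_that("information is reported in bits (nats / ln 2)", {
  post <- rbind(c(0.9, 0.1), c(0.1, 0.9))
  ch <- new_channel(post)
  h2 <- function(p) -p * log2(p) - (1 - p) * log2(1 - p)
  expect_equal(mutual_information_bits(ch), 1 - h2(0.1), tolerance = 1e-12)
  # manual nats computation converts by ln 2
  m <- ch$marginal
  nats <- mean(c(
    sum(post[1, ] * log(post[1, ] / m)),
    sum(post[2, ] * log(post[2, ] / m))
  ))
  expect_equal(mutual_information_bits(ch), nats / log(2), tolerance = 1e-12)
})

test_that("mutual information recognizes identity and uninformative channels", {
  task <- lab_task()
  top <- deterministic_level_channel(task, 3)
  expect_equal(mutual_information_bits(top), log2(12), tolerance = 1e-12)
  flat <- new_channel(matrix(1 / 21, 12, 21))
  expect_equal(mutual_information_bits(flat), 0)
  expect_lte(mutual_information_bits(top), min(log2(12), log2(21)) + 1e-9)
})

test_that("expected utility evaluates deterministic and uniform channels", {
  task <- lab_task()
  expect_equal(expected_utility(deterministic_level_channel(task, 3), task), 1.0)
  expect_equal(expected_utility(deterministic_level_channel(task, 1), task), 0.6)
  expect_equal(expected_utility(new_channel(matrix(1 / 21, 12, 21)), task),
               2.4 / 21, tolerance = 1e-12)
  expect_error(expected_utility(new_channel(matrix(1 / 3, 2, 3)), task))
})

test_that("fixed-prior solve is a single tilt with recomputed marginal", {
  task <- lab_task()
  # beta = 0: rows equal the prior
  ch0 <- fixed_prior_solve(task, beta = 0, p0 = rep(1 / 21, 21))
  expect_equal(max(abs(ch0$posterior - 1 / 21)), 0)
  # fixed-point property: the optimal marginal reproduces the BA solution
  ba <- blahut_arimoto(task, beta = 5)
  fp <- fixed_prior_solve(task, beta = 5, p0 = ba$marginal)
  expect_equal(fp$posterior, ba$posterior, tolerance = 1e-9)
  # level-uniform prior at beta = 0: hand-computed expected utility 5/36
  chl <- fixed_prior_solve(task, beta = 0, p0 = prior_spec(preset = "uniform_levels"))
  expect_equal(mutual_information_bits(chl), 0)
  expect_equal(expected_utility(chl, task), 5 / 36, tolerance = 1e-12)
  expect_error(fixed_prior_solve(task, beta = 1, p0 = c(rep(0, 1), rep(1 / 20, 20))))
})

test_that("the efficiency frontier is monotone, concave and spans the task", {
  fr <- lab_frontier()
  expect_true(all(diff(fr$mutual_info_bits) >= -1e-8))
  expect_true(all(diff(fr$expected_utility) >= -1e-8))
  # concavity: chord slopes non-increasing
  di <- diff(fr$mutual_info_bits)
  keep <- di > 1e-10
  slopes <- diff(fr$expected_utility)[keep] / di[keep]
  expect_true(all(diff(slopes) <= 1e-6))
  # endpoints: zero-information optimum 0.2; rational limit
  expect_equal(fr$expected_utility[1], 0.2, tolerance = 1e-2)
  expect_lt(fr$mutual_info_bits[1], 1e-3)
  expect_equal(fr$expected_utility[nrow(fr)], 1.0, tolerance = 1e-3)
  expect_equal(fr$mutual_info_bits[nrow(fr)], log2(12), tolerance = 1e-3)
  # playing the bottom level perfectly is feasible at log2 3 bits
  expect_gte(frontier_utility_at(fr, log2(3)), 0.6 - 1e-9)
})

test_that("every frontier point has efficiency 1", {
  fr <- lab_frontier()
  eff <- mapply(function(u, i) efficiency(u, i, fr),
                fr$expected_utility, fr$mutual_info_bits)
  expect_true(all(eff >= 1 - 1e-3 & eff <= 1 + 1e-9))
  # the zero-information utility has efficiency 0
  expect_equal(efficiency(0.2, 0.5, fr), 0, tolerance = 1e-9)
  # interpolated denominator for an off-frontier point
  u_max <- frontier_utility_at(fr, log2(3))
  expect_equal(efficiency(0.6, log2(3), fr), (0.6 - 0.2) / (u_max - 0.2))
  expect_warning(frontier_utility_at(fr, 10), "clamping")
})

test_that("level statistics implement the directed variances", {
  task <- lab_task()
  s <- level_statistics(deterministic_level_channel(task, 1), task$hierarchy)
  expect_equal(s$mean_level, 1)
  expect_equal(s$sigma_plus, 0)
  expect_equal(s$sigma_minus, 0)

  mk <- function(p_l) {
    post <- matrix(0, 12, 21)
    post[, 1] <- p_l[1]; post[, 4] <- p_l[2]; post[, 10] <- p_l[3]
    new_channel(post)
  }
  s2 <- level_statistics(mk(c(0.5, 0, 0.5)), task$hierarchy)
  expect_equal(s2$mean_level, 2)
  expect_equal(s2$sigma_plus^2, 1)
  expect_equal(s2$sigma_minus^2, 1)

  s3 <- level_statistics(mk(c(0.25, 0.5, 0.25)), task$hierarchy)
  expect_equal(s3$mean_level, 2)
  expect_equal(s3$sigma_plus^2, 1 / 3, tolerance = 1e-12)
  expect_equal(s3$sigma_minus^2, 1 / 3, tolerance = 1e-12)
})

test_that("guessing-game channels reproduce the worked bit/reward arithmetic", {
  gg <- build_guessing_game()
  # information needed to name a specimen / category / super-category
  expect_equal(mutual_information_bits(deterministic_level_channel(gg, 3)), log2(12))
  expect_equal(mutual_information_bits(deterministic_level_channel(gg, 2)), log2(6))
  expect_equal(mutual_information_bits(deterministic_level_channel(gg, 1)), log2(3))
  # guessing specimens knowing only the category / super-category
  cat2 <- category_guess_channel(gg, 2)
  expect_equal(expected_utility(cat2, gg), 0.5)
  expect_equal(mutual_information_bits(cat2), log2(6), tolerance = 1e-12)
  sup <- category_guess_channel(gg, 1)
  expect_equal(expected_utility(sup, gg), 0.25)
  expect_equal(mutual_information_bits(sup), log2(3), tolerance = 1e-12)
  # guessing categories knowing the super-category
  supcat <- category_guess_channel(gg, 1, guess_level = 2)
  expect_equal(expected_utility(supcat, gg), 0.4)
  expect_equal(mutual_information_bits(supcat), log2(3), tolerance = 1e-12)
})
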