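# Brute-force oracles for the bounded-rational solver, independent of the
# iterative implementation.

# all points of the probability simplex over `k` outcomes with grid step
simplex_grid <- function(k, step) {
  n <- round(1 / step)
  if (k == 2) {
    i <- 0:n
    cbind(i / n, 1 - i / n)
  } else if (k == 3) {
    out <- list()
    r <- 0L
    for (i in 0:n) for (j in 0:(n - i)) {
      r <- r + 1L
      out[[r]] <- c(i, j, n - i - j) / n
    }
    do.call(rbind, out)
  } else stop("unsupported k")
}

# exhaustive primal grid search of the utility/information objective for a
# 2-state problem: candidate channels are all pairs of simplex rows
primal_grid_max_2row <- function(utility, prior, beta, step) {
  G <- simplex_grid(ncol(utility), step)
  xlx <- function(m) ifelse(m > 0, m * log(m), 0)
  s <- rowSums(xlx(G))                       # sum_a g log g per row
  eu <- G %*% t(utility)                     # rows x states
  best <- -Inf
  for (i in seq_len(nrow(G))) {
    m <- prior[1] * matrix(G[i, ], nrow(G), ncol(G), byrow = TRUE) + prior[2] * G
    i_nats <- prior[1] * s[i] + prior[2] * s - rowSums(xlx(m))
    f <- prior[1] * eu[i, 1] + prior[2] * eu[, 2] - i_nats / beta
    best <- max(best, max(f))
  }
  best
}

# exhaustive grid search over the action marginal of the closed-form dual:
# F(m) = (1/beta) sum_w p(w) log sum_a m_a exp(beta U(w,a)). Any fixed m
# bounds the primal objective from below, and the simplex maximum equals the
# primal optimum.
dual_grid_max <- function(utility, prior, beta, step) {
  G <- simplex_grid(ncol(utility), step)
  E <- exp(beta * utility)                   # states x actions
  vals <- log(tcrossprod(E, G)) / beta       # states x grid
  max(as.vector(prior %*% vals))
}

ba_objective <- function(ch, utility, beta) {
  expected_utility(ch, utility) - mutual_information_bits(ch) * log(2) / beta
}
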