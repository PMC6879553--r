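#' Construct a stimulus-response channel
#'
#' A channel is a conditional distribution p(a|w) over actions for each world
#' state, together with the state prior and the induced action marginal
#' p(a) = sum_w p(w) p(a|w). Channels are the common currency of the package:
#' bounded-rational solutions, constrained-model predictions and empirical
#' estimates are all channels.
#'
#' @param posterior Numeric matrix, states x actions, rows summing to 1.
#' @param prior State prior p(w); defaults to uniform.
#' @return An object of class `br_channel` with components `posterior`,
#'   `marginal` and `prior`.
#' @export
new_channel <- function(posterior, prior = NULL) {
  posterior <- unname(as.matrix(posterior))
  if (is.null(prior)) prior <- rep(1 / nrow(posterior), nrow(posterior))
  stopifnot(length(prior) == nrow(posterior), all(posterior >= 0))
  rs <- rowSums(posterior)
  if (any(abs(rs - 1) > 1e-8)) stop("posterior rows must sum to 1")
  structure(
    list(
      posterior = posterior,
      marginal  = as.vector(prior %*% posterior),
      prior     = prior
    ),
    class = "br_channel"
  )
}

#' @export
print.br_channel <- function(x, ...) {
  cat(sprintf(
    "<br_channel> %d states -> %d actions | I = %.3f bits\n",
    nrow(x$posterior), ncol(x$posterior), mutual_information_bits(x)
  ))
  invisible(x)
}

# 0 log 0 = 0 convention; probabilities below .Machine tiny treated as zero
xlogx <- function(p) ifelse(p > 1e-300, p * log(p), 0)

kl_nats <- function(p, q) {
  i <- p > 1e-300
  sum(p[i] * (log(p[i]) - log(q[i])))
}

#' Mutual information of a channel, in bits
#'
#' Computes I(W;A) = E_p(w) D_KL(p(a|w) || p(a)) with the 0 log 0 = 0
#' convention, reported in bits.
#'
#' @param channel A [new_channel()] object.
#' @return Non-negative mutual information in bits; 0 iff all rows are equal.
#' @export
mutual_information_bits <- function(channel) {
  p <- channel$posterior
  m <- channel$marginal
  nats <- sum(vapply(
    seq_len(nrow(p)),
    function(w) channel$prior[w] * kl_nats(p[w, ], m),
    numeric(1)
  ))
  max(nats, 0) / log(2)
}

#' Expected utility of a channel
#'
#' The bilinear form E_{p(w) p(a|w)}[U(w,a)].
#'
#' @param channel A `br_channel`.
#' @param utility Utility matrix (states x actions) or a `br_task`.
#' @return Expected utility in the task's payoff units.
#' @export
expected_utility <- function(channel, utility) {
  u <- if (inherits(utility, "br_task")) utility$utility else utility
  if (!all(dim(u) == dim(channel$posterior))) stop("utility/channel shape mismatch")
  sum(channel$prior * rowSums(channel$posterior * u))
}

#' Abstraction-level statistics of a channel
#'
#' Marginalizes the action distribution onto the three abstraction levels and
#' computes the mean selected level together with directed variances above and
#' below the mean,
#' \deqn{\sigma_+^2 = \sum_{l \ge \bar l} p(l) (l-\bar l)^2 / \sum_{l' \ge \bar l} p(l'),}
#' and symmetrically for \eqn{\sigma_-^2}; the boundary term \eqn{l = \bar l}
#' enters both sums.
#'
#' @param channel A `br_channel` over the 21 flat actions.
#' @param hierarchy An [action_hierarchy()].
#' @return A list with `p_level` (length 3), `mean_level`, `sigma_plus`,
#'   `sigma_minus` (directed standard deviations, in levels).
#' @export
level_statistics <- function(channel, hierarchy = action_hierarchy()) {
  p_a <- channel$marginal
  p_l <- vapply(seq_len(hierarchy$n_levels),
                function(l) sum(p_a[level_actions(hierarchy, l)]), numeric(1))
  lv <- seq_len(hierarchy$n_levels)
  lbar <- sum(lv * p_l)
  up <- lv >= lbar
  dn <- lv <= lbar
  s2p <- if (sum(p_l[up]) > 0) sum(p_l[up] * (lv[up] - lbar)^2) / sum(p_l[up]) else 0
  s2m <- if (sum(p_l[dn]) > 0) sum(p_l[dn] * (lv[dn] - lbar)^2) / sum(p_l[dn]) else 0
  list(
    p_level     = p_l,
    mean_level  = lbar,
    sigma_plus  = sqrt(s2p),
    sigma_minus = sqrt(s2m)
  )
}

#' Tidy a channel into long format
#'
#' @param x A `br_channel`.
#' @param ... Unused.
#' @return Tibble with columns `world_state`, `action`, `prob`.
#' @export
tidy.br_channel <- function(x, ...) {
  tibble::tibble(
    world_state = rep(seq_len(nrow(x$posterior)), times = ncol(x$posterior)),
    action      = rep(seq_len(ncol(x$posterior)), each = nrow(x$posterior)),
    prob        = as.vector(x$posterior)
  )
}

#' One-row summary of a channel
#'
#' @param x A `br_channel`.
#' @param utility Optional utility matrix or `br_task` for expected utility.
#' @param ... Unused.
#' @return One-row tibble with `mutual_info_bits`, `mean_level`, and
#'   `expected_utility` when a utility is supplied.
#' @export
glance.br_channel <- function(x, utility = NULL, ...) {
  out <- tibble::tibble(
    mutual_info_bits = mutual_information_bits(x),
    mean_level = if (ncol(x$posterior) == 21L)
      level_statistics(x)$mean_level else NA_real_
  )
  if (!is.null(out) && !is.null(utility))
    out$expected_utility <- expected_utility(x, utility)
  out
}
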