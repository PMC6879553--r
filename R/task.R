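#' Action hierarchy of the identification task
#'
#' The response panel has three stacked levels of precision: 3 coarse buttons
#' (payoff 0.6 for a correct identification), 6 intermediate buttons (payoff
#' 0.8) and 12 precise buttons (payoff 1.0). Each level partitions the unit
#' roundness scale \eqn{[0,1)} into equal half-open intervals, and every
#' coarser button is the union of exactly two buttons of the next finer level.
#' Flat action indices run bottom-to-top: 1--3 (coarse), 4--9 (intermediate),
#' 10--21 (precise).
#'
#' @return A list of class `br_hierarchy` with components `n_levels`,
#'   `n_buttons` (3, 6, 12), `payoff` (0.6, 0.8, 1.0), `offset` (flat-index
#'   offset per level) and `n_actions` (21).
#' @export
#' @examples
#' h <- action_hierarchy()
#' level_of_action(h, 10)  # first precise button lives on level 3
action_hierarchy <- function() {
  structure(
    list(
      n_levels  = 3L,
      n_buttons = c(3L, 6L, 12L),
      payoff    = c(0.6, 0.8, 1.0),
      offset    = c(0L, 3L, 9L),
      n_actions = 21L
    ),
    class = "br_hierarchy"
  )
}

#' Map between flat action indices and (level, button) pairs
#'
#' @param hierarchy An [action_hierarchy()].
#' @param action Flat action index in 1..21.
#' @param level Level index (1 coarsest .. 3 finest).
#' @param button Within-level button index.
#' @return `level_of_action()` and `button_of_action()` return integers;
#'   `flat_action()` returns the flat index.
#' @export
level_of_action <- function(hierarchy, action) {
  stopifnot(all(action >= 1L), all(action <= hierarchy$n_actions))
  findInterval(action, cumsum(c(1L, hierarchy$n_buttons))[-4], rightmost.closed = FALSE)
}

#' @rdname level_of_action
#' @export
button_of_action <- function(hierarchy, action) {
  l <- level_of_action(hierarchy, action)
  as.integer(action) - hierarchy$offset[l]
}

#' @rdname level_of_action
#' @export
flat_action <- function(hierarchy, level, button) {
  stopifnot(all(level %in% seq_len(hierarchy$n_levels)))
  stopifnot(all(button >= 1L), all(button <= hierarchy$n_buttons[level]))
  hierarchy$offset[level] + as.integer(button)
}

#' @rdname level_of_action
#' @export
level_actions <- function(hierarchy, level) {
  hierarchy$offset[level] + seq_len(hierarchy$n_buttons[level])
}

#' Roundness interval covered by a button
#'
#' Buttons are half-open intervals `[lo, hi)` except the last button of each
#' level, which is closed at 1 so the partition is exhaustive.
#'
#' @inheritParams level_of_action
#' @return Numeric vector `c(lo, hi)`.
#' @export
button_interval <- function(hierarchy, level, button) {
  n <- hierarchy$n_buttons[level]
  c((button - 1) / n, button / n)
}

#' Top-level descendants of a flat action
#'
#' Every button covers 12 / N_l of the finest buttons: a coarse button covers
#' four precise buttons, an intermediate button two, a precise button itself.
#' Used by the alternative 12-action information accounting.
#'
#' @inheritParams level_of_action
#' @return Integer vector of top-level button indices (1..12).
#' @export
top_descendants <- function(hierarchy, action) {
  l <- level_of_action(hierarchy, action)
  j <- button_of_action(hierarchy, action)
  span <- 12L %/% hierarchy$n_buttons[l]
  (j - 1L) * span + seq_len(span)
}

roundness_midpoints <- function(n_states = 12L) (2 * seq_len(n_states) - 1) / (2 * n_states)

build_task <- function(currency, state_labels = NULL) {
  hierarchy <- action_hierarchy()
  n_states <- 12L
  w <- roundness_midpoints(n_states)
  utility <- matrix(0, n_states, hierarchy$n_actions)
  for (l in seq_len(hierarchy$n_levels)) {
    n <- hierarchy$n_buttons[l]
    j <- floor(w * n) + 1L                      # w < 1 always, so j <= n
    utility[cbind(seq_len(n_states), flat_action(hierarchy, l, j))] <- hierarchy$payoff[l]
  }
  colnames(utility) <- as.character(seq_len(hierarchy$n_actions))
  rownames(utility) <- as.character(seq_len(n_states))
  structure(
    list(
      n_states  = n_states,
      roundness = w,
      prior     = rep(1 / n_states, n_states),
      hierarchy = hierarchy,
      utility   = utility,
      currency  = currency,
      state_labels = state_labels
    ),
    class = "br_task"
  )
}

#' Build the ellipse identification task
#'
#' Twelve world states are ellipses of increasing roundness; their roundness
#' values sit at the midpoints of the twelve finest response intervals,
#' \eqn{w_i = (2i-1)/24}. Responses are the 21 hierarchy buttons; the utility
#' \eqn{U(w,a)} pays the level payoff when the state's roundness falls inside
#' the button's interval and 0 otherwise, so every row has exactly three
#' non-zero entries, 0.6, 0.8 and 1.0 points.
#'
#' @return A `br_task`: a list with `roundness`, uniform `prior`, the
#'   `hierarchy`, the 12 x 21 `utility` matrix and the payoff `currency`.
#' @export
#' @examples
#' task <- build_lab_task()
#' task$utility[1, c(1, 4, 10)]  # 0.6 0.8 1.0
build_lab_task <- function() build_task(currency = "points")

#' Build the animal guessing game
#'
#' The introductory example task: twelve specimens grouped into six categories
#' of two and three super-categories of four. Naming the exact specimen pays
#' $1, the category $0.8 and the super-category $0.6. Structurally identical
#' to [build_lab_task()] up to the currency unit and state labels.
#'
#' @return A `br_task` with `currency = "dollars"` and specimen labels.
#' @export
build_guessing_game <- function() {
  labels <- c(
    "Persian", "Siamese", "German Shepherd", "Rottweiler",
    "Ball Python", "Corn Snake", "Chameleon", "Leopard Gecko",
    "Poison Dart Frog", "European Tree Frog", "Axolotl", "Fire Salamander"
  )
  build_task(currency = "dollars", state_labels = labels)
}

#' The unique rewarded action for a state at a level
#'
#' @param task A `br_task`.
#' @param w World-state index in 1..12.
#' @param level Level index in 1..3.
#' @return Flat action index of the single action with non-zero utility for
#'   `w` on `level`.
#' @export
#' @examples
#' correct_action(build_lab_task(), w = 1, level = 3)  # 10
correct_action <- function(task, w, level) {
  stopifnot(all(w >= 1L), all(w <= task$n_states))
  stopifnot(all(level %in% seq_len(task$hierarchy$n_levels)))
  n <- task$hierarchy$n_buttons[level]
  j <- floor(task$roundness[w] * n) + 1L
  flat_action(task$hierarchy, level, j)
}

#' @export
print.br_task <- function(x, ...) {
  cat(sprintf(
    "<br_task> %d states, %d actions (%s levels), payoffs in %s\n",
    x$n_states, x$hierarchy$n_actions,
    paste(x$hierarchy$n_buttons, collapse = "/"), x$currency
  ))
  invisible(x)
}

#' Utility table as a tidy tibble
#'
#' @param x A `br_task`.
#' @param ... Unused.
#' @return A tibble with columns `world_state`, `action`, `level`, `utility`.
#' @export
tidy.br_task <- function(x, ...) {
  h <- x$hierarchy
  tibble::tibble(
    world_state = rep(seq_len(x$n_states), times = h$n_actions),
    action      = rep(seq_len(h$n_actions), each = x$n_states),
    level       = level_of_action(h, .data$action),
    utility     = as.vector(x$utility)
  )
}

#' Write / read a utility table as tab-delimited text
#'
#' The serialization is a 12-row, 21-column tab-separated table with a header
#' row of flat action indices.
#'
#' @param task A `br_task`.
#' @param path File path.
#' @return `write_utility_tsv()` returns `path` invisibly;
#'   `read_utility_tsv()` returns the utility matrix.
#' @export
write_utility_tsv <- function(task, path) {
  utils::write.table(task$utility, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_utility_tsv
#' @export
read_utility_tsv <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE))
  rownames(m) <- as.character(seq_len(nrow(m)))
  m
}
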