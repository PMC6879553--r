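# Lazily computed shared fixtures, built once per test run.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE))
    assign(name, expr, envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

lab_task <- function() cached("lab_task", build_lab_task())

lab_frontier <- function() {
  cached("lab_frontier", efficiency_frontier(lab_task(), keep_channels = TRUE))
}

# deterministic channel playing the correct button of `level` for every state
deterministic_level_channel <- function(task, level) {
  post <- matrix(0, task$n_states, task$hierarchy$n_actions)
  post[cbind(seq_len(task$n_states),
             vapply(seq_len(task$n_states),
                    function(w) correct_action(task, w, level), integer(1)))] <- 1
  new_channel(post, task$prior)
}

# channel spreading each state uniformly over the `guess_level` buttons that
# descend from the state's correct button at `known_level`: the decision-maker
# knows the coarse category and guesses uniformly at the finer level
category_guess_channel <- function(task, known_level, guess_level = 3L) {
  h <- task$hierarchy
  stopifnot(guess_level > known_level)
  span <- h$n_buttons[guess_level] %/% h$n_buttons[known_level]
  post <- matrix(0, task$n_states, h$n_actions)
  for (w in seq_len(task$n_states)) {
    j <- button_of_action(h, correct_action(task, w, known_level))
    kids <- (j - 1L) * span + seq_len(span)
    post[w, flat_action(h, guess_level, kids)] <- 1 / span
  }
  new_channel(post, task$prior)
}
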