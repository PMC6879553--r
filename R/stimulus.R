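#' Stimulus condition parameters
#'
#' Dot-motion parameters of the three perceptual difficulty levels: number
#' of signal dots tracing the ellipse, number of random noise dots, and the
#' per-frame percentage of signal dots replaced by noise.
#'
#' @return Tibble with columns `condition`, `signal_dots`, `random_dots`,
#'   `replacement_rate` (percent), `duration_ms`, `n_frames`.
#' @export
stimulus_conditions <- function() {
  tibble::tibble(
    condition = c("easy", "medium", "hard"),
    signal_dots = c(100L, 75L, 50L),
    random_dots = c(250L, 400L, 450L),
    replacement_rate = c(35, 40, 40),
    duration_ms = 500,
    n_frames = 30L
  )
}

#' Ellipse geometry of the twelve world states
#'
#' Each state i is an ellipse with vertical major semi-axis b = 1/2 and minor
#' semi-axis a_i = (2i - 1)/48, placed at the midpoints of the twelve finest
#' roundness intervals so that 0 < a_i < 1/2 runs from an almost vertical
#' line to an almost perfect circle; the roundness is w = a/b = 2 a_i.
#'
#' @param state World-state index 1..12 (vectorized).
#' @return Tibble with columns `state`, `minor_axis`, `major_axis`,
#'   `roundness`.
#' @export
ellipse_spec <- function(state = 1:12) {
  stopifnot(all(state >= 1), all(state <= 12))
  a <- (2 * state - 1) / 48
  tibble::tibble(state = as.integer(state), minor_axis = a, major_axis = 0.5,
                 roundness = 2 * a)
}

ellipse_point <- function(a, b, phase) {
  cbind(x = 0.5 + a * cos(phase), y = 0.5 + b * sin(phase))
}

reflect01 <- function(z) {
  z <- abs(z)
  i <- z > 1
  z[i] <- 2 - z[i]
  pmin(pmax(z, 0), 1)
}

#' Generate a dot-motion ellipse video
#'
#' Signal dots advance along the (invisible) ellipse boundary at constant
#' angular speed (one revolution per 60 frames) with random starting phases;
#' random dots take uniform random-walk steps (disc of radius 0.02 per
#' frame, reflecting at the unit-square walls). Between consecutive frames,
#' `floor(rate/100 x signal dots)` randomly chosen signal dots are replaced
#' by uniformly placed noise dots while an equal number of noise dots join
#' the boundary at random phases, keeping both dot counts constant. All
#' coordinates are continuous in the unit square with the ellipse centered at
#' (0.5, 0.5); no rasterization is applied.
#'
#' @param state World-state index 1..12.
#' @param condition Condition name from [stimulus_conditions()], or a
#'   one-row list/tibble with `signal_dots`, `random_dots`,
#'   `replacement_rate`.
#' @param seed RNG seed; the same seed reproduces the video exactly.
#' @param n_frames Number of frames (default 30).
#' @return Tibble of class `br_video` with columns `frame`, `dot`, `x`, `y`,
#'   `label` ("signal"/"random") and attributes `state`, `minor_axis`.
#' @export
generate_stimulus <- function(state, condition = "hard", seed = 1L, n_frames = 30L) {
  if (is.character(condition)) {
    tab <- stimulus_conditions()
    row <- tab[tab$condition == condition, ]
    if (nrow(row) != 1) stop("unknown condition: ", condition)
    condition <- row
  }
  n_sig <- as.integer(condition$signal_dots)
  n_rnd <- as.integer(condition$random_dots)
  rate <- as.numeric(condition$replacement_rate)
  spec <- ellipse_spec(state)
  a <- spec$minor_axis
  b <- spec$major_axis
  step_angle <- 2 * pi / 60
  walk_radius <- 0.02

  with_seed(seed, {
    phase <- stats::runif(n_sig, 0, 2 * pi)
    rx <- stats::runif(n_rnd)
    ry <- stats::runif(n_rnd)
    frames <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      if (f > 1) {
        phase <- phase + step_angle
        ang <- stats::runif(n_rnd, 0, 2 * pi)
        rad <- walk_radius * sqrt(stats::runif(n_rnd))
        rx <- reflect01(rx + rad * cos(ang))
        ry <- reflect01(ry + rad * sin(ang))
        # swapping labels needs a noise pool; without one no dot can leave
        m <- min(floor(rate / 100 * n_sig), n_rnd)
        if (m > 0) {
          # m signal dots leave the boundary; m noise dots join it
          leave <- sample.int(n_sig, m)
          phase[leave] <- NA
          new_sig <- stats::runif(m, 0, 2 * pi)
          phase <- c(phase[!is.na(phase)], new_sig)
          join <- sample.int(n_rnd, m)
          rx[join] <- stats::runif(m)
          ry[join] <- stats::runif(m)
        }
      }
      sig <- ellipse_point(a, b, phase)
      frames[[f]] <- tibble::tibble(
        frame = f,
        dot = seq_len(n_sig + n_rnd),
        x = c(sig[, "x"], rx),
        y = c(sig[, "y"], ry),
        label = rep(c("signal", "random"), c(n_sig, n_rnd))
      )
    }
    video <- dplyr::bind_rows(frames)
    attr(video, "state") <- as.integer(state)
    attr(video, "minor_axis") <- a
    class(video) <- c("br_video", class(video))
    video
  })
}

#' Minor-axis estimate of a point
#'
#' Inverts the ellipse equation \eqn{x^2/a^2 + y^2/b^2 = 1} for the minor
#' semi-axis: \eqn{\hat a = |x| b / \sqrt{b^2 - y^2}} with coordinates
#' relative to the ellipse center. For a point on ellipse i the estimate
#' equals a_i exactly; for random points it is broadly spread. Points with
#' \eqn{|y| \ge b} are outside the estimator's validity domain and return
#' `NA`.
#'
#' @param x,y Coordinates relative to the ellipse center.
#' @param b Major semi-axis (default 1/2).
#' @return Minor-axis estimates (NA where undefined).
#' @export
estimate_minor_axis <- function(x, y, b = 0.5) {
  out <- rep(NA_real_, length(x))
  ok <- abs(y) < b
  out[ok] <- abs(x[ok]) * b / sqrt(b^2 - y[ok]^2)
  out
}

# Greedy minimum-distance matching between two point sets (n x 2 matrices):
# repeatedly pair the globally closest unused points. Returns an index matrix
# (i in P, j in Q); no point is used twice.
greedy_match <- function(P, Q) {
  n1 <- nrow(P); n2 <- nrow(Q)
  d2 <- outer(rowSums(P^2), rowSums(Q^2), "+") - 2 * tcrossprod(P, Q)
  o <- order(d2)
  used1 <- logical(n1); used2 <- logical(n2)
  m <- min(n1, n2)
  res <- matrix(0L, m, 2)
  k <- 0L
  for (idx in o) {
    i <- ((idx - 1L) %% n1) + 1L
    j <- ((idx - 1L) %/% n1) + 1L
    if (used1[i] || used2[j]) next
    used1[i] <- TRUE; used2[j] <- TRUE
    k <- k + 1L
    res[k, ] <- c(i, j)
    if (k == m) break
  }
  res
}

#' Recognize the world state of a dot-motion video
#'
#' The automatic recognition algorithm: consecutive frames are paired point
#' by point by greedy minimum distance; each matched pair yields two
#' minor-axis estimates, and only pairs whose estimates are consistent
#' (absolute difference at most `threshold`) survive -- coherent signal dots
#' stay on the ellipse so their estimates agree, while random dots drift.
#' Surviving estimates from all frame pairs are binned to the nearest of the
#' twelve admissible minor-axis values and the modal bin is returned.
#'
#' @param video A `br_video` (or any tibble with `frame`, `x`, `y`).
#' @param threshold Consistency threshold on |a1 - a2| (default 0.1).
#' @param b Major semi-axis (default 1/2).
#' @param center Ellipse center (default c(0.5, 0.5)).
#' @return Estimated world-state index (1..12), with attribute `histogram`
#'   (counts per candidate state).
#' @export
recognize <- function(video, threshold = 0.1, b = 0.5, center = c(0.5, 0.5)) {
  fr <- split(data.frame(x = video$x - center[1], y = video$y - center[2]),
              video$frame)
  if (length(fr) < 2) stop("need at least two frames")
  a_cand <- ellipse_spec()$minor_axis
  counts <- numeric(12)
  for (f in seq_len(length(fr) - 1L)) {
    P <- as.matrix(fr[[f]])
    Q <- as.matrix(fr[[f + 1L]])
    mt <- greedy_match(P, Q)
    a1 <- estimate_minor_axis(P[mt[, 1], 1], P[mt[, 1], 2], b)
    a2 <- estimate_minor_axis(Q[mt[, 2], 1], Q[mt[, 2], 2], b)
    ok <- !is.na(a1) & !is.na(a2) & a1 < b & a2 < b & abs(a1 - a2) <= threshold
    vals <- c(a1[ok], a2[ok])
    if (length(vals)) {
      bins <- vapply(vals, function(v) which.min(abs(v - a_cand)), integer(1))
      counts <- counts + tabulate(bins, nbins = 12L)
    }
  }
  if (sum(counts) == 0) stop("no consistent point pairs survived the threshold")
  est <- which.max(counts)
  attr(est, "histogram") <- counts
  est
}

#' Recognition accuracy over generated stimuli
#'
#' Generates `n_per_state` videos for each of the twelve world states under
#' one condition, runs [recognize()] on each, and returns the fraction of
#' correctly identified states.
#'
#' @param condition Condition name or parameter row (see
#'   [generate_stimulus()]).
#' @param n_per_state Videos per world state.
#' @param seed Base seed; video (state s, replicate r) uses
#'   `seed + 100 * s + r`.
#' @param threshold Consistency threshold passed to [recognize()].
#' @return Accuracy fraction in \[0, 1\], with attribute `results` (tibble of
#'   per-video truth and estimate).
#' @export
accuracy_experiment <- function(condition = "hard", n_per_state = 5L, seed = 1L,
                                threshold = 0.1) {
  stopifnot(n_per_state >= 1)
  res <- purrr::map_dfr(1:12, function(s) {
    purrr::map_dfr(seq_len(n_per_state), function(r) {
      video <- generate_stimulus(s, condition, seed = seed + 100L * s + r)
      tibble::tibble(state = s, replicate = r, estimate = recognize(video, threshold))
    })
  })
  acc <- mean(res$estimate == res$state)
  attr(acc, "results") <- res
  acc
}

#' Write / read a video as tab-delimited text
#'
#' @param video A `br_video`.
#' @param path File path.
#' @return `write_video_tsv()` returns `path` invisibly; `read_video_tsv()`
#'   the video tibble.
#' @export
write_video_tsv <- function(video, path) {
  readr::write_tsv(video, path)
  invisible(path)
}

#' @rdname write_video_tsv
#' @export
read_video_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
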