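#' Construct a locomotion track
#'
#' @param t sampling times in seconds, strictly increasing.
#' @param x,y coordinates in mm.
#' @param id animal identifier.
#' @return a `track`: data.table with columns `t`, `x`, `y` and attribute
#'   `id`.
#' @export
track <- function(t, x, y, id = "fly1") {
  stopifnot(length(t) == length(x), length(t) == length(y))
  if (length(t) < 2L) stop_fmt("track needs at least two samples")
  if (any(diff(t) <= 0)) stop_fmt("track timestamps must be strictly increasing")
  tr <- data.table::data.table(t = as.numeric(t), x = as.numeric(x),
                               y = as.numeric(y))
  data.table::setattr(tr, "id", id)
  data.table::setattr(tr, "class", c("track", class(tr)))
  tr[]
}

#' Read tracks from a TSV file
#'
#' @param path TSV with columns animal, t, x, y.
#' @return named list of `track` objects, one per animal.
#' @export
read_tracks <- function(path) {
  if (!file.exists(path)) stop_fmt("track file not found: %s", path)
  dt <- fread_skip_comments(path, sep = "\t", header = TRUE)
  need <- c("animal", "t", "x", "y")
  if (!all(need %in% names(dt)))
    stop_fmt("track file needs columns: %s", paste(need, collapse = ", "))
  ids <- unique(dt$animal)
  stats::setNames(lapply(ids, function(a) {
    d <- dt[dt$animal == a][order(t)]
    track(d$t, d$x, d$y, id = a)
  }), ids)
}

#' Quantize a track into fixed-width speed quanta
#'
#' The record is divided into quanta of `quantum` seconds starting at the
#' first sample; the mean speed within each quantum is the path length
#' travelled in it divided by the quantum width. Samples straddling a
#' quantum boundary are split by linear interpolation. A partial trailing
#' quantum is discarded. A quantum is `resting` when its mean speed is
#' below `threshold`, otherwise `moving`.
#'
#' @param track a `track`.
#' @param quantum quantum width in seconds (default 1).
#' @param threshold resting/moving speed threshold in mm/s (default 5).
#' @return a `quantized_track`: data.table with columns `quantum` (1-based
#'   index), `path` (mm), `speed` (mm/s), `state`; attributes `quantum`,
#'   `threshold`, `duration` (quantized seconds) and `id`.
#' @export
quantize_track <- function(track, quantum = 1, threshold = 5) {
  stopifnot(inherits(track, "track"), quantum > 0, threshold >= 0)
  rel <- track$t - track$t[1L]
  n_q <- floor(rel[length(rel)] / quantum)
  if (n_q < 1L) stop_fmt("track duration (%.3f s) shorter than one quantum", max(rel))
  horizon <- n_q * quantum
  bnd <- seq(quantum, horizon, by = quantum)
  # inject interpolated samples at each quantum boundary, then every
  # segment lies within exactly one quantum
  xb <- stats::approx(rel, track$x, xout = bnd)$y
  yb <- stats::approx(rel, track$y, xout = bnd)$y
  tt <- c(rel, bnd); xx <- c(track$x, xb); yy <- c(track$y, yb)
  o <- order(tt)
  tt <- tt[o]; xx <- xx[o]; yy <- yy[o]
  dup <- c(FALSE, diff(tt) == 0)
  tt <- tt[!dup]; xx <- xx[!dup]; yy <- yy[!dup]
  keep <- tt <= horizon
  tt <- tt[keep]; xx <- xx[keep]; yy <- yy[keep]
  seg_len <- sqrt(diff(xx)^2 + diff(yy)^2)
  mid <- (tt[-1L] + tt[-length(tt)]) / 2
  qidx <- pmin(floor(mid / quantum) + 1L, n_q)
  path <- numeric(n_q)
  tal <- tapply(seg_len, qidx, sum)
  path[as.integer(names(tal))] <- as.numeric(tal)
  speed <- path / quantum
  out <- data.table::data.table(
    quantum = seq_len(n_q), path = path, speed = speed,
    state = ifelse(speed < threshold, "resting", "moving"))
  data.table::setattr(out, "quantum", quantum)
  data.table::setattr(out, "threshold", threshold)
  data.table::setattr(out, "duration", horizon)
  data.table::setattr(out, "id", attr(track, "id"))
  data.table::setattr(out, "class", c("quantized_track", class(out)))
  out[]
}

#' Merge neighboring quanta of equal state into intervals
#'
#' @param quantized a `quantized_track`, or a character vector of states.
#' @param quantum quantum width in seconds (taken from the quantized track
#'   when one is supplied).
#' @return an `interval_set`: data.table with columns `start`, `end`
#'   (seconds, half-open) and `state`; maximal runs only, so adjacent
#'   intervals always differ in state and the intervals tile the record.
#' @export
merge_intervals <- function(quantized, quantum = 1) {
  if (inherits(quantized, "quantized_track")) {
    states <- quantized$state
    quantum <- attr(quantized, "quantum")
  } else states <- as.character(quantized)
  if (!length(states)) stop_fmt("no quanta to merge")
  r <- rle(states)
  ends <- cumsum(r$lengths) * quantum
  out <- data.table::data.table(start = c(0, ends[-length(ends)]),
                                end = ends, state = r$values)
  data.table::setattr(out, "class", c("interval_set", class(out)))
  out[]
}

#' Locomotion summary statistics
#'
#' Activity index is the percent of (quantized) record time spent moving;
#' run frequency is the number of moving bouts per 100 s; running speed is
#' the mean speed over moving intervals only (total path in moving quanta
#' divided by total moving time), reported as `NA` when the animal never
#' moves.
#'
#' @param quantized a `quantized_track`.
#' @param intervals optional `interval_set` derived from `quantized`
#'   (recomputed when omitted).
#' @return a `locomotion_summary`: list with `id`, `activity_index`
#'   (percent), `run_frequency` (bouts per 100 s), `running_speed` (mm/s or
#'   NA), `moving_time`, `resting_time`, `duration` (seconds).
#' @export
locomotion_summary <- function(quantized, intervals = merge_intervals(quantized)) {
  stopifnot(inherits(quantized, "quantized_track"))
  duration <- attr(quantized, "duration")
  moving <- sum(intervals[state == "moving", end - start])
  resting <- sum(intervals[state == "resting", end - start])
  n_runs <- nrow(intervals[state == "moving"])
  moving_path <- sum(quantized[state == "moving", path])
  res <- list(
    id = attr(quantized, "id"),
    activity_index = 100 * moving / duration,
    run_frequency = 100 * n_runs / duration,
    running_speed = if (moving > 0) moving_path / moving else NA_real_,
    moving_time = moving, resting_time = resting, duration = duration)
  class(res) <- "locomotion_summary"
  res
}

#' @export
print.locomotion_summary <- function(x, ...) {
  cat(sprintf("<%s> activity %.1f%%, %.2f runs/100 s, speed %s mm/s over %.0f s\n",
              x$id %||% "track", x$activity_index, x$run_frequency,
              if (is.na(x$running_speed)) "NA" else sprintf("%.2f", x$running_speed),
              x$duration))
  invisible(x)
}

#' Courtship learning index
#'
#' `LI = 100 * (mean CI_naive - mean CI_trained) / mean CI_naive`, the
#' relative reduction of the courtship index after training with a
#' fertilized female.
#'
#' @param naive,trained numeric vectors of per-male courtship indices
#'   (percent of observation time spent courting, in `[0, 100]`).
#' @return the learning index in percent.
#' @export
learning_index <- function(naive, trained) {
  check_ci <- function(v, lab) {
    if (!length(v)) stop_fmt("%s sample is empty", lab)
    if (any(is.na(v)) || any(v < 0 | v > 100))
      stop_fmt("%s courtship indices must lie in [0, 100]", lab)
  }
  check_ci(naive, "naive"); check_ci(trained, "trained")
  m_na <- mean(naive)
  if (m_na == 0) stop_fmt("learning index undefined: mean naive CI is 0")
  100 * (m_na - mean(trained)) / m_na
}

# LI for permuted samples; permutations can produce a zero naive mean,
# which is scored as maximally extreme (conservative)
li_or_inf <- function(naive, trained) {
  m_na <- mean(naive)
  if (m_na == 0) {
    if (mean(trained) == 0) return(0)
    return(-Inf)
  }
  100 * (m_na - mean(trained)) / m_na
}

#' Randomization test for a learning index
#'
#' Two-sided label-permutation test of `LI != 0`: naive/trained labels are
#' permuted over the pooled courtship indices, the learning index is
#' recomputed for each permutation, and the p-value is
#' `(1 + #{|LI*| >= |LI_obs|}) / (1 + reps)` (add-one estimator, so p is
#' never exactly 0).
#'
#' @param naive,trained courtship-index samples.
#' @param reps number of permutations (>= 1000).
#' @param seed RNG seed.
#' @return list with `LI` (observed), `p_value`, `reps`.
#' @export
randomization_test <- function(naive, trained, reps = 10000L, seed = 0L) {
  stopifnot(reps >= 1000L)
  obs <- learning_index(naive, trained)
  pooled <- c(naive, trained)
  n1 <- length(naive)
  p <- with_seed(seed, {
    extreme <- 0L
    for (i in seq_len(reps)) {
      idx <- sample.int(length(pooled), n1)
      stat <- li_or_inf(pooled[idx], pooled[-idx])
      if (abs(stat) >= abs(obs) - 1e-12) extreme <- extreme + 1L
    }
    (1 + extreme) / (1 + reps)
  })
  list(LI = obs, p_value = p, reps = reps)
}

#' Randomization test for a difference of learning indices
#'
#' Compares the learning indices of two conditions (each a naive/trained
#' pair) by permuting naive/trained labels within each condition
#' independently; the statistic is `LI_1 - LI_2`, two-sided.
#'
#' @param naive1,trained1 condition 1 samples.
#' @param naive2,trained2 condition 2 samples.
#' @param reps number of permutations (>= 1000).
#' @param seed RNG seed.
#' @return list with `LI1`, `LI2`, `diff`, `p_value`, `reps`.
#' @export
li_difference_test <- function(naive1, trained1, naive2, trained2,
                               reps = 10000L, seed = 0L) {
  stopifnot(reps >= 1000L)
  li1 <- learning_index(naive1, trained1)
  li2 <- learning_index(naive2, trained2)
  obs <- li1 - li2
  pool1 <- c(naive1, trained1); k1 <- length(naive1)
  pool2 <- c(naive2, trained2); k2 <- length(naive2)
  p <- with_seed(seed, {
    extreme <- 0L
    for (i in seq_len(reps)) {
      i1 <- sample.int(length(pool1), k1)
      i2 <- sample.int(length(pool2), k2)
      stat <- li_or_inf(pool1[i1], pool1[-i1]) - li_or_inf(pool2[i2], pool2[-i2])
      if (is.nan(stat)) stat <- Inf
      if (abs(stat) >= abs(obs) - 1e-12) extreme <- extreme + 1L
    }
    (1 + extreme) / (1 + reps)
  })
  list(LI1 = li1, LI2 = li2, diff = obs, p_value = p, reps = reps)
}

#' Read courtship-index samples from a TSV file
#'
#' @param path TSV with columns group (`naive`/`trained`), animal, CI.
#' @return list with numeric vectors `naive` and `trained`.
#' @export
read_courtship <- function(path) {
  if (!file.exists(path)) stop_fmt("courtship file not found: %s", path)
  dt <- fread_skip_comments(path, sep = "\t", header = TRUE)
  if (!all(c("group", "CI") %in% names(dt)))
    stop_fmt("courtship file needs columns group and CI")
  grp <- tolower(dt$group)
  if (!all(grp %in% c("naive", "trained")))
    stop_fmt("group must be 'naive' or 'trained'")
  list(naive = dt$CI[grp == "naive"], trained = dt$CI[grp == "trained"])
}
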