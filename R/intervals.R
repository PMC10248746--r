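#' Partition the exposure window into contiguous day intervals
#'
#' Splits the inclusive day window `[window_start, window_end]` (day 0 =
#' transplant day) into `n_intervals` contiguous, non-overlapping intervals.
#' With the defaults (-7, 30, 5) the partition is anchored so that the
#' pre-transplant days form their own interval and post-transplant weeks
#' start at day 0: [-7,-1], [0,6], [7,13], [14,20], [21,30] — approximately
#' one week each, with the final interval absorbing the remainder.
#'
#' For non-default windows the same rule applies: if day -1 and day 0 both
#' lie strictly inside the window and `n_intervals >= 2`, one boundary is
#' pinned at the -1/0 transition and the remaining days are split into
#' near-equal runs; otherwise the window is split into near-equal runs
#' directly, any remainder going to the last interval.
#'
#' @param window_start,window_end Integer days, inclusive.
#' @param n_intervals Number of intervals (>= 1).
#' @return An object of class `interval_scheme`: a data.frame with columns
#'   `interval` (1-based index), `start`, `end`.
#' @export
#' @examples
#' build_interval_scheme()            # canonical 5-interval scheme
#' build_interval_scheme(0, 4, 5)     # five one-day intervals
build_interval_scheme <- function(window_start = -7L, window_end = 30L,
                                  n_intervals = 5L) {
  window_start <- as.integer(window_start)
  window_end <- as.integer(window_end)
  n_intervals <- as.integer(n_intervals)
  ndays <- window_end - window_start + 1L
  if (n_intervals < 1L)
    stop("n_intervals must be >= 1", call. = FALSE)
  if (ndays < n_intervals)
    stop(sprintf("window [%d, %d] has %d days; cannot form %d intervals",
                 window_start, window_end, ndays, n_intervals), call. = FALSE)

  equal_runs <- function(from, to, k) {
    nd <- to - from + 1L
    base <- nd %/% k
    sizes <- rep(base, k)
    sizes[k] <- sizes[k] + nd %% k  # remainder absorbed by the last interval
    ends <- from - 1L + cumsum(sizes)
    starts <- c(from, head(ends, -1L) + 1L)
    data.frame(start = starts, end = ends)
  }

  if (n_intervals >= 2L && window_start <= -1L && window_end >= 0L) {
    # pin one boundary at the transplant day: pre-HCT days are interval 1
    post <- equal_runs(0L, window_end, n_intervals - 1L)
    iv <- rbind(data.frame(start = window_start, end = -1L), post)
  } else {
    iv <- equal_runs(window_start, window_end, n_intervals)
  }
  iv <- data.frame(interval = seq_len(nrow(iv)), iv)
  structure(iv, class = c("interval_scheme", "data.frame"),
            window_start = window_start, window_end = window_end)
}

#' @export
print.interval_scheme <- function(x, ...) {
  cat(sprintf("Interval scheme over days [%d, %d], %d intervals:\n",
              attr(x, "window_start"), attr(x, "window_end"), nrow(x)))
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %d: [%d, %d]\n", x$interval[i], x$start[i], x$end[i]))
  invisible(x)
}

#' Map days to interval indices
#'
#' @param scheme An `interval_scheme`.
#' @param day Integer vector of days.
#' @return Integer vector of interval indices (NA outside the window).
#' @export
interval_of_day <- function(scheme, day) {
  idx <- rep(NA_integer_, length(day))
  for (i in seq_len(nrow(scheme)))
    idx[day >= scheme$start[i] & day <= scheme$end[i]] <- scheme$interval[i]
  idx
}

n_intervals <- function(scheme) nrow(scheme)
scheme_window <- function(scheme) {
  c(attr(scheme, "window_start"), attr(scheme, "window_end"))
}
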