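#' Construct a spike train
#'
#' A spike train holds the ordered spike times of one unit in milliseconds,
#' together with the observation window `[t_start, t_stop)`.
#'
#' @param times numeric vector of spike times in ms, strictly increasing.
#' @param t_start,t_stop observation window in ms; every spike time must
#'   satisfy `t_start <= t < t_stop`.
#' @return an object of class `spike_train`.
#' @export
spike_train <- function(times, t_start = 0, t_stop = NULL) {
  times <- as.numeric(times)
  check_scalar(t_start, "t_start")
  if (is.null(t_stop)) t_stop <- if (length(times)) max(times) + 1e-9 else t_start
  check_scalar(t_stop, "t_stop")
  if (t_stop < t_start) stopf("t_stop < t_start")
  if (length(times)) {
    if (any(!is.finite(times))) stopf("non-finite spike times")
    if (any(diff(times) <= 0)) stopf("spike times must be strictly increasing")
    if (times[1] < t_start || times[length(times)] >= t_stop)
      stopf("spike times outside [t_start, t_stop)")
  }
  structure(list(times = times, t_start = t_start, t_stop = t_stop),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  dur <- (x$t_stop - x$t_start) / 1000
  cat(sprintf("<spike_train> %d spikes on [%g, %g) ms (%.2f s, mean rate %.2f /s)\n",
              length(x$times), x$t_start, x$t_stop, dur,
              if (dur > 0) length(x$times) / dur else NA_real_))
  invisible(x)
}

#' @export
length.spike_train <- function(x) length(x$times)

#' Duration of a spike train in ms
#' @param x a `spike_train`.
#' @return duration `t_stop - t_start` in ms.
#' @export
train_duration <- function(x) x$t_stop - x$t_start

#' Mean firing rate of a spike train in spikes per second
#' @param x a `spike_train`.
#' @return spike count divided by duration, in s^-1.
#' @export
train_rate <- function(x) length(x$times) / (train_duration(x) / 1000)

#' Read spike trains from a two-column text file
#'
#' The format is whitespace-separated `train_id time_ms`, with ascending times
#' within each id (gdf-like). Returns one `spike_train` per id, ordered by id.
#'
#' @param path file path.
#' @param t_start,t_stop observation window applied to every train; when
#'   `t_stop` is `NULL` it is taken as the largest time rounded up to the next
#'   0.1 ms.
#' @return list of `spike_train` objects, named by train id.
#' @export
read_spike_trains <- function(path, t_start = 0, t_stop = NULL) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  if (!any(keep)) return(list())
  idx <- which(keep)
  parts <- strsplit(trimws(lines[keep]), "[[:space:]]+")
  bad <- which(vapply(parts, length, 1L) != 2L)
  if (length(bad))
    stopf("malformed line %d in '%s'", idx[bad[1]], path)
  ids <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1L)))
  tms <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
  bad <- which(is.na(ids) | is.na(tms))
  if (length(bad))
    stopf("malformed line %d in '%s'", idx[bad[1]], path)
  # ascending-within-id contract, reported with the first offending line
  ord_bad <- which(diff(tms) <= 0 & diff(ids) == 0)
  if (length(ord_bad))
    stopf("non-monotone spike times at line %d in '%s'", idx[ord_bad[1] + 1L], path)
  if (is.null(t_stop)) t_stop <- ceiling(max(tms) * 10 + 1) / 10
  out <- lapply(split(tms, ids), spike_train, t_start = t_start, t_stop = t_stop)
  out[order(as.integer(names(out)))]
}

#' Write spike trains to a two-column text file
#'
#' @param trains list of `spike_train` objects.
#' @param path output file path.
#' @param digits decimal digits for times; the default preserves the 0.1 ms
#'   simulation grid losslessly.
#' @return `path`, invisibly.
#' @export
write_spike_trains <- function(trains, path, digits = 4) {
  if (inherits(trains, "spike_train")) trains <- list(trains)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(trains)) {
    tr <- trains[[i]]
    if (length(tr$times))
      writeLines(sprintf("%d %s", i,
                         formatC(tr$times, format = "f", digits = digits)), con)
  }
  invisible(path)
}
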