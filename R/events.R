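#' Detect spiking events by inter-spike interval
#'
#' An event is a maximal run of consecutive spikes in which every adjacent
#' inter-spike interval is strictly less than `iei_threshold_s`; runs with at
#' least `min_spikes` spikes become events spanning first to last spike.
#' The default criterion (at least two spikes with intervals under 500 ms)
#' is the standard definition for neonatal network events.
#'
#' @param train a [spike_train()].
#' @param iei_threshold_s inter-spike-interval criterion (s); intervals of
#'   exactly this value break the run.
#' @param min_spikes minimum spikes per event.
#' @return an object of class `event_set`: list with `events` (data.frame
#'   `start_s`, `stop_s`, `n_spikes`, `duration_s`), `span_s`,
#'   `iei_threshold_s`, `min_spikes`.
#' @export
detect_events <- function(train, iei_threshold_s = 0.5, min_spikes = 2L) {
  stopifnot(iei_threshold_s > 0, min_spikes >= 1L)
  times <- train$times_s
  if (length(times) == 0L) {
    ev <- data.frame(start_s = numeric(), stop_s = numeric(),
                     n_spikes = integer(), duration_s = numeric())
  } else {
    breaks <- which(diff(times) >= iei_threshold_s)
    starts <- c(1L, breaks + 1L)
    stops <- c(breaks, length(times))
    keep <- (stops - starts + 1L) >= min_spikes
    ev <- data.frame(start_s = times[starts[keep]],
                     stop_s = times[stops[keep]],
                     n_spikes = stops[keep] - starts[keep] + 1L)
    ev$duration_s <- ev$stop_s - ev$start_s
  }
  structure(list(events = ev, span_s = train$span_s,
                 iei_threshold_s = iei_threshold_s,
                 min_spikes = as.integer(min_spikes)),
            class = "event_set")
}

#' @export
print.event_set <- function(x, ...) {
  cat(sprintf("<event_set> %d events over %.1f s (continuity %.3f)\n",
              nrow(x$events), diff(x$span_s), compute_continuity(x)$continuity))
  invisible(x)
}

#' Continuity of activity
#'
#' The proportion of total recording time that contains an event; isolated
#' spikes contribute nothing.
#'
#' @param events an `event_set` from [detect_events()].
#' @return list with `continuity` (in \[0, 1\]), `total_event_time_s` and
#'   `span_s`.
#' @export
compute_continuity <- function(events) {
  span <- diff(events$span_s)
  if (!is.finite(span) || span <= 0) stop("event set has zero or unknown span")
  tot <- sum(events$events$duration_s)
  list(continuity = tot / span, total_event_time_s = tot, span_s = span)
}

#' Event-duration distribution
#'
#' Histogram and empirical CDF of event durations. Default edges include
#' bins above 5 s and above 10 s, the ranges in which manipulations of the
#' retino-thalamo-cortical loop reshape the duration distribution.
#'
#' @param events an `event_set`.
#' @param edges_s histogram break points (s); `Inf` allowed as last edge.
#' @return list with `durations_s`, `ecdf` (a [stats::ecdf()] function or
#'   `NULL`), `histogram` (data.frame `lo_s`, `hi_s`, `count`, `proportion`)
#'   and `empty` flag.
#' @export
event_duration_distribution <- function(events,
                                        edges_s = c(0, 0.5, 1, 2, 5, 10, Inf)) {
  d <- events$events$duration_s
  if (!length(d)) {
    return(list(durations_s = numeric(), ecdf = NULL,
                histogram = data.frame(lo_s = utils::head(edges_s, -1),
                                       hi_s = edges_s[-1], count = 0L,
                                       proportion = NaN),
                empty = TRUE))
  }
  cnt <- as.integer(table(cut(d, edges_s, right = FALSE,
                              include.lowest = FALSE)))
  list(durations_s = d, ecdf = stats::ecdf(d),
       histogram = data.frame(lo_s = utils::head(edges_s, -1),
                              hi_s = edges_s[-1], count = cnt,
                              proportion = cnt / length(d)),
       empty = FALSE)
}

#' Signed percent change
#'
#' `100 * (post - pre) / pre`; the pre value must be positive.
#'
#' @param pre_value,post_value numeric scalars (or equal-length vectors).
#' @return percent change, same length as inputs.
#' @export
percent_change <- function(pre_value, post_value) {
  if (any(pre_value <= 0))
    stop("percent_change undefined for non-positive pre value")
  100 * (post_value - pre_value) / pre_value
}
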