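#' Spike train container
#'
#' Ordered spike timestamps from one channel of one region, together with the
#' recording span. Times are seconds from session start; the span is the
#' half-open interval `[t0, t1)`.
#'
#' @param times_s ascending numeric spike times (s).
#' @param region `"LGN"`, `"VC"` or `"other"`.
#' @param channel integer channel id.
#' @param span_s length-2 numeric `(t0, t1)`.
#' @return an object of class `spike_train`.
#' @export
spike_train <- function(times_s, region = c("LGN", "VC", "other"),
                        channel = 1L, span_s) {
  region <- match.arg(region)
  times_s <- as.numeric(times_s)
  stopifnot(length(span_s) == 2L, span_s[2] > span_s[1])
  if (length(times_s)) {
    if (is.unsorted(times_s, strictly = TRUE))
      stop("spike times must be strictly ascending")
    if (times_s[1] < span_s[1] || times_s[length(times_s)] > span_s[2])
      stop("spike times outside recording span")
  }
  structure(list(times_s = times_s, region = region,
                 channel = as.integer(channel),
                 span_s = as.numeric(span_s)),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %s ch%d: %d spikes over %.1f s (%.2f Hz)\n",
              x$region, x$channel, length(x$times_s), diff(x$span_s),
              length(x$times_s) / diff(x$span_s)))
  invisible(x)
}

#' Mean firing rate of a spike train
#'
#' @param train a [spike_train()].
#' @return spikes per second over the recording span.
#' @export
firing_rate <- function(train) length(train$times_s) / diff(train$span_s)

#' LFP trace container
#'
#' @param samples_uv numeric vector, amplitude in microvolts.
#' @param fs_hz sampling rate (Hz).
#' @param region,channel as in [spike_train()].
#' @param t0_s time of the first sample (s).
#' @return an object of class `lfp_trace`.
#' @export
lfp_trace <- function(samples_uv, fs_hz, region = c("VC", "LGN", "other"),
                      channel = 1L, t0_s = 0) {
  region <- match.arg(region)
  stopifnot(fs_hz > 0, all(is.finite(samples_uv)))
  structure(list(samples_uv = as.numeric(samples_uv), fs_hz = fs_hz,
                 region = region, channel = as.integer(channel), t0_s = t0_s),
            class = "lfp_trace")
}

#' Recording session container
#'
#' Bundles multi-region spike trains, optional LFP traces, a stimulus-event
#' table and metadata (age mode, manipulation, seed, generator parameters and
#' the generator's internal logs when the session is synthetic).
#'
#' @param spike_trains list of [spike_train()] objects with equal spans.
#' @param lfp optional list of [lfp_trace()] objects.
#' @param stimuli data.frame with columns `kind`, `onset_s` (and optionally
#'   `trial`, `pulse`); may have zero rows.
#' @param meta named list of metadata.
#' @return an object of class `recording_session`.
#' @export
recording_session <- function(spike_trains, lfp = NULL, stimuli = NULL,
                              meta = list()) {
  stopifnot(length(spike_trains) >= 1L,
            all(vapply(spike_trains, inherits, TRUE, "spike_train")))
  span <- spike_trains[[1]]$span_s
  for (tr in spike_trains)
    if (!isTRUE(all.equal(tr$span_s, span)))
      stop("all spike trains in a session must share one span")
  if (is.null(stimuli))
    stimuli <- data.frame(kind = character(), onset_s = numeric())
  if (nrow(stimuli) && (any(stimuli$onset_s < span[1]) ||
                        any(stimuli$onset_s > span[2])))
    stop("stimulus onsets outside session span")
  structure(list(spike_trains = spike_trains, lfp = lfp, stimuli = stimuli,
                 span_s = span, meta = meta),
            class = "recording_session")
}

#' @export
print.recording_session <- function(x, ...) {
  cat(sprintf("<recording_session> %.1f s, %d train(s), %d LFP trace(s), %d stimuli\n",
              diff(x$span_s), length(x$spike_trains),
              length(x$lfp %||% list()), nrow(x$stimuli)))
  for (tr in x$spike_trains) print(tr)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fetch spike trains of a session by region/channel
#'
#' @param session a [recording_session()].
#' @param region region name, or `NULL` for all.
#' @param channel channel id, or `NULL` for all.
#' @return for `get_train`, a single [spike_train()] (error if not exactly
#'   one match); for `get_trains`, a list.
#' @export
get_trains <- function(session, region = NULL, channel = NULL) {
  keep <- vapply(session$spike_trains, function(tr) {
    (is.null(region) || tr$region == region) &&
      (is.null(channel) || tr$channel == channel)
  }, TRUE)
  session$spike_trains[keep]
}

#' @rdname get_trains
#' @export
get_train <- function(session, region = NULL, channel = NULL) {
  trs <- get_trains(session, region, channel)
  if (length(trs) != 1L)
    stop(sprintf("expected exactly one matching train, found %d", length(trs)))
  trs[[1]]
}

#' Write a session to a directory
#'
#' Produces `spikes.csv` (region, channel, time_s), `stimuli.csv`,
#' `session.json` (metadata) and, when LFP is present, one `lfp_<region>_<ch>.bin`
#' (float32 little-endian) with a JSON sidecar holding the sampling rate.
#' Spike times round-trip at full double precision.
#'
#' @param session a [recording_session()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- data.table::rbindlist(lapply(session$spike_trains, function(tr)
    data.table::data.table(region = tr$region, channel = tr$channel,
                           time_s = tr$times_s)))
  if (!nrow(sp)) sp <- data.table::data.table(region = character(),
                                              channel = integer(),
                                              time_s = numeric())
  data.table::fwrite(sp, file.path(dir, "spikes.csv"))
  data.table::fwrite(session$stimuli, file.path(dir, "stimuli.csv"))
  meta <- session$meta
  meta$span_s <- session$span_s
  meta$trains <- lapply(session$spike_trains, function(tr)
    list(region = tr$region, channel = tr$channel))
  lfp_files <- list()
  for (lf in session$lfp %||% list()) {
    stub <- sprintf("lfp_%s_%d", lf$region, lf$channel)
    con <- file(file.path(dir, paste0(stub, ".bin")), "wb")
    writeBin(as.numeric(lf$samples_uv), con, size = 4L, endian = "little")
    close(con)
    jsonlite::write_json(list(fs_hz = lf$fs_hz, region = lf$region,
                              channel = lf$channel, t0_s = lf$t0_s,
                              n = length(lf$samples_uv), dtype = "float32le"),
                         file.path(dir, paste0(stub, ".json")),
                         auto_unbox = TRUE, digits = NA)
    lfp_files <- c(lfp_files, list(stub))
  }
  meta$lfp_files <- lfp_files
  jsonlite::write_json(serialize_meta(meta), file.path(dir, "session.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

serialize_meta <- function(x) {
  if (is.function(x)) return(NULL)
  if (inherits(x, c("age_profile", "wave_params", "manipulation_spec",
                    "stimulus_protocol", "loop_params")))
    x <- unclass(x)
  if (is.list(x)) lapply(x, serialize_meta) else x
}

#' Read a session written by [write_session()]
#'
#' Also accepts a bare two-column delimited spike file through
#' [read_spike_file()].
#'
#' @param dir directory containing `spikes.csv` and `session.json`.
#' @return a [recording_session()].
#' @export
read_session <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "session.json"),
                              simplifyVector = TRUE)
  span <- as.numeric(meta$span_s)
  sp <- data.table::fread(file.path(dir, "spikes.csv"))
  trains <- list()
  tr_index <- meta$trains
  if (is.data.frame(tr_index)) tr_index <- split(tr_index, seq_len(nrow(tr_index)))
  for (ti in tr_index) {
    sel <- sp[sp$region == ti$region & sp$channel == ti$channel, ]
    trains[[length(trains) + 1L]] <-
      spike_train(sort(sel$time_s), region = ti$region,
                  channel = ti$channel, span_s = span)
  }
  stim_path <- file.path(dir, "stimuli.csv")
  stimuli <- if (file.exists(stim_path)) as.data.frame(data.table::fread(stim_path)) else NULL
  if (!is.null(stimuli) && !nrow(stimuli)) stimuli <- NULL
  lfp <- list()
  for (stub in meta$lfp_files %||% list()) {
    side <- jsonlite::read_json(file.path(dir, paste0(stub, ".json")),
                                simplifyVector = TRUE)
    con <- file(file.path(dir, paste0(stub, ".bin")), "rb")
    x <- readBin(con, numeric(), n = side$n, size = 4L, endian = "little")
    close(con)
    lfp[[length(lfp) + 1L]] <- lfp_trace(x, fs_hz = side$fs_hz,
                                         region = side$region,
                                         channel = side$channel,
                                         t0_s = side$t0_s)
  }
  meta$span_s <- NULL; meta$trains <- NULL; meta$lfp_files <- NULL
  recording_session(trains, lfp = if (length(lfp)) lfp else NULL,
                    stimuli = stimuli, meta = meta)
}

#' Read a plain delimited spike file
#'
#' Accepts a two-column (`channel`, `time_s`) or three-column (`region`,
#' `channel`, `time_s`) delimited file and returns a session spanning
#' `[0, max time]` (or a supplied span).
#'
#' @param path file path.
#' @param region region assigned when the file has no region column.
#' @param span_s optional recording span.
#' @return a [recording_session()].
#' @export
read_spike_file <- function(path, region = "LGN", span_s = NULL) {
  d <- as.data.frame(data.table::fread(path))
  if (!"region" %in% names(d)) d$region <- region
  if (is.null(span_s)) span_s <- c(0, max(d$time_s) + 1e-9)
  groups <- split(d, list(d$region, d$channel), drop = TRUE)
  trains <- lapply(groups, function(g)
    spike_train(sort(g$time_s), region = g$region[1], channel = g$channel[1],
                span_s = span_s))
  recording_session(unname(trains), meta = list(source = path))
}
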