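#' Write a cohort to a plain-text dataset
#'
#' One directory per subject with one channel table (CSV: time column plus
#' one column per channel, input first) and one single-column event file per
#' trial, plus a YAML manifest at the root recording rates, channel roles,
#' units and per-trial exclusion intervals (invalid time ranges).
#'
#' @param cohort Output of [make_cohort()].
#' @param path Target directory (created if missing).
#' @param input_name Column name for the input channel (default `"u"`).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, input_name = "u") {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(format = "phirf-dataset-1", input = input_name,
                   subjects = list())
  for (s in seq_along(cohort)) {
    sid <- sprintf("s%02d", s)
    sdir <- file.path(path, sid)
    dir.create(sdir, showWarnings = FALSE)
    trials <- cohort[[s]]$trials
    tr_entries <- list()
    for (i in seq_along(trials)) {
      tr <- trials[[i]]
      tab <- data.frame(time = ts_times(tr$input), check.names = FALSE)
      tab[[input_name]] <- tr$input$values
      for (nm in names(tr$channels)) tab[[nm]] <- tr$channels[[nm]]$values
      chf <- sprintf("%s/t%02d_channels.csv", sid, i)
      evf <- sprintf("%s/t%02d_events.txt", sid, i)
      utils::write.csv(tab, file.path(path, chf), row.names = FALSE)
      writeLines(formatC(tr$events, format = "g", digits = 15),
                 file.path(path, evf))
      excl <- mask_to_intervals(!tr$input$valid, tr$input$rate, tr$input$start)
      units <- c(stats::setNames(tr$input$units, input_name),
                 vapply(tr$channels, function(ch) ch$units, character(1)))
      tr_entries[[i]] <- list(channels = chf, events = evf,
                              rate = tr$input$rate,
                              units = as.list(units),
                              exclude = excl)
    }
    manifest$subjects[[sid]] <- list(id = sid, trials = tr_entries)
  }
  yaml::write_yaml(manifest, file.path(path, "manifest.yaml"))
  invisible(path)
}

mask_to_intervals <- function(bad, rate, start) {
  runs <- valid_runs(bad)
  if (nrow(runs) == 0L) return(list())
  lapply(seq_len(nrow(runs)), function(i)
    c(start + (runs[i, 1] - 1) / rate, start + (runs[i, 2] - 1) / rate))
}

#' Load a plain-text cohort dataset
#'
#' Reads a dataset written by [write_cohort()] (or assembled by hand in the
#' same layout), applying exclusion intervals from the manifest as validity
#' masks.  Malformed manifests, missing channels and unsorted events are
#' rejected with file context.
#'
#' @param path Dataset directory containing `manifest.yaml`.
#' @return A cohort: list of subjects, each a list with `trials`.
#' @export
load_dataset <- function(path) {
  mf_path <- file.path(path, "manifest.yaml")
  if (!file.exists(mf_path)) stop("no manifest.yaml in ", path)
  mf <- yaml::read_yaml(mf_path)
  if (is.null(mf$subjects)) stop("manifest has no subjects: ", mf_path)
  input_name <- mf$input %||% "u"
  cohort <- list()
  for (sid in names(mf$subjects)) {
    strials <- mf$subjects[[sid]]$trials
    trials <- vector("list", length(strials))
    for (i in seq_along(strials)) {
      ent <- strials[[i]]
      chf <- file.path(path, ent$channels)
      evf <- file.path(path, ent$events)
      if (!file.exists(chf)) stop("missing channel table: ", chf)
      if (!file.exists(evf)) stop("missing event file: ", evf)
      tab <- utils::read.csv(chf, check.names = FALSE)
      if (!"time" %in% names(tab)) stop("no `time` column in ", chf)
      if (!input_name %in% names(tab))
        stop("input channel `", input_name, "` missing in ", chf)
      rate <- ent$rate
      tstep <- diff(tab$time[1:2])
      if (abs(tstep - 1 / rate) > 1e-6 / rate)
        stop("rate mismatch between manifest and table in ", chf)
      events <- as.numeric(readLines(evf))
      if (any(!is.finite(events)) || any(diff(events) <= 0))
        stop("unsorted or malformed events in ", evf)
      valid <- rep(TRUE, nrow(tab))
      tt <- tab$time
      for (iv in ent$exclude)
        valid[tt >= iv[[1]] - 1e-9 & tt <= iv[[2]] + 1e-9] <- FALSE
      units <- ent$units %||% list()
      mk <- function(nm) time_series(tab[[nm]], rate, tab$time[1],
                                     units = units[[nm]] %||% "", valid = valid)
      chans <- setdiff(names(tab), c("time", input_name))
      trials[[i]] <- list(input = mk(input_name),
                          channels = stats::setNames(lapply(chans, mk), chans),
                          events = events)
    }
    cohort[[sid]] <- list(trials = trials)
  }
  cohort
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a phiIRF (or its statistics) as a long-format table
#'
#' Columns: stimulus phase, normalized response time, value; for a
#' `"phirf_stats"` object additionally CI half-width, t, adjusted p and the
#' significance flag.
#'
#' @param x A `"phirf"` or `"phirf_stats"`.
#' @param file Output CSV path, or `NULL` to return the data frame.
#' @return The data frame, invisibly if written.
#' @export
export_phirf <- function(x, file = NULL) {
  if (inherits(x, "phirf")) {
    df <- data.frame(
      stimulus_phase = rep(x$phases, each = length(x$tr)),
      response_time = rep(x$tr, length(x$phases)),
      value = as.vector(x$h))
  } else if (inherits(x, "phirf_stats")) {
    df <- data.frame(
      stimulus_phase = rep(x$phases, each = length(x$tr)),
      response_time = rep(x$tr, length(x$phases)),
      mean = as.vector(x$mean),
      ci_halfwidth = as.vector(x$ci_halfwidth))
    if (!is.null(x$p_adj)) {
      df$t <- as.vector(x$t)
      df$p_adj <- as.vector(x$p_adj)
      df$significant <- as.vector(x$significant)
    }
  } else stop("export_phirf(): unsupported object")
  if (is.null(file)) return(df)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(df)
}

#' Export a phase map as a two-column table
#'
#' @param pm A `"phase_map"`.
#' @param file Output path (CSV with columns `time`, `theta`).
#' @export
export_phase_map <- function(pm, file) {
  stopifnot(inherits(pm, "phase_map"))
  utils::write.csv(data.frame(time = pm$tgrid, theta = pm$theta),
                   file, row.names = FALSE)
  invisible(file)
}

#' Read single-column event times
#'
#' @param file Text file with one event time (seconds) per line.
#' @return Numeric vector.
#' @export
read_events <- function(file) {
  ev <- as.numeric(readLines(file))
  if (any(!is.finite(ev))) stop("malformed event file: ", file)
  ev
}
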