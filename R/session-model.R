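#' Stimulus panel
#'
#' Describes the stimulus battery delivered to the vomeronasal organ. Exactly
#' one stimulus must be designated the solvent control (Ringer's solution in
#' the experiments this package models); responses to the control disqualify
#' a cell from analysis.
#'
#' @param ids character vector of unique stimulus identifiers
#' @param control id of the solvent-control stimulus (must be one of `ids`)
#' @param labels human-readable labels, defaults to `ids`
#' @param tags optional grouping tags (e.g. "urine", "faeces", "bile acid");
#'   recycled, defaults to ""
#' @return an object of class `stimulus_panel`: a list with a `stimuli`
#'   data frame (id, label, tag) and the `control` id
#' @export
stimulus_panel <- function(ids, control, labels = ids, tags = "") {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop_format("duplicate stimulus ids in panel")
  control <- as.character(control)
  if (length(control) != 1L || !control %in% ids)
    stop_format("panel must designate exactly one control stimulus present in ids")
  structure(list(
    stimuli = data.frame(id = ids,
                         label = rep_len(as.character(labels), length(ids)),
                         tag = rep_len(as.character(tags), length(ids)),
                         stringsAsFactors = FALSE),
    control = control
  ), class = "stimulus_panel")
}

#' Trial table
#'
#' One row per stimulus delivery event. Times are seconds from session start.
#'
#' @param stimulus_id character vector of stimulus ids
#' @param onset_s,offset_s stimulus epoch boundaries (s); `offset_s > onset_s`
#' @param repeat_index 1-based repeat counter per stimulus
#' @return data frame of class `trial_table`
#' @export
trial_table <- function(stimulus_id, onset_s, offset_s, repeat_index) {
  df <- data.frame(stimulus_id = as.character(stimulus_id),
                   onset_s = as.numeric(onset_s),
                   offset_s = as.numeric(offset_s),
                   repeat_index = as.integer(repeat_index),
                   stringsAsFactors = FALSE)
  class(df) <- c("trial_table", "data.frame")
  df
}

#' Trial-structured single-unit session
#'
#' The core container: sorted spike trains for one or more cells, the trial
#' table of stimulus events, and the stimulus panel. Empty spike trains are
#' legitimate (a silent cell), so the set of cells is carried explicitly
#' rather than inferred from the spike table.
#'
#' @param spikes data frame with columns `cell_id`, `spike_time_s`
#' @param trials a [trial_table()] (or data frame with its columns)
#' @param panel a [stimulus_panel()]
#' @param cells character vector of cell ids; defaults to the ids present in
#'   `spikes`
#' @param meta named list of metadata (generator config, seed, ground truth
#'   for synthetic sessions, `duration_s`)
#' @param validate run [validate_session()] (default TRUE)
#' @return object of class `aob_session`
#' @export
session <- function(spikes, trials, panel, cells = NULL, meta = list(),
                    validate = TRUE) {
  spikes <- data.frame(cell_id = as.character(spikes$cell_id),
                       spike_time_s = as.numeric(spikes$spike_time_s),
                       stringsAsFactors = FALSE)
  if (is.null(cells)) cells <- unique(spikes$cell_id)
  s <- structure(list(spikes = spikes,
                      trials = as.data.frame(trials),
                      panel = panel,
                      cells = as.character(cells),
                      meta = meta),
                 class = "aob_session")
  if (validate) validate_session(s)
  s
}

#' Validate a session against its structural invariants
#'
#' Checks: panel has a unique control; spike times are non-negative and
#' strictly increasing within each cell; every trial's stimulus id exists in
#' the panel; `offset > onset` and the stimulus epoch duration lies within
#' `duration_bounds`; spike cell ids are all listed in `cells`.
#' The minimum-repeat rule (>= 3 repeats per stimulus) is deliberately
#' enforced at analysis time, not here, so partial sessions stay inspectable.
#'
#' @param s an `aob_session`
#' @param duration_bounds allowed stimulus epoch durations in seconds
#'   (default `c(3, 5)`)
#' @return `s`, invisibly; errors of class `aobtune_validation_error` or
#'   `aobtune_format_error` otherwise
#' @export
validate_session <- function(s, duration_bounds = c(3, 5)) {
  if (!inherits(s$panel, "stimulus_panel"))
    stop_format("session panel is not a stimulus_panel")
  tr <- s$trials
  need <- c("stimulus_id", "onset_s", "offset_s", "repeat_index")
  if (!all(need %in% names(tr)))
    stop_format("trial table missing columns: %s",
                paste(setdiff(need, names(tr)), collapse = ", "))
  unknown <- setdiff(unique(tr$stimulus_id), s$panel$stimuli$id)
  if (length(unknown))
    stop_validation("trials reference stimuli absent from panel: %s",
                    paste(unknown, collapse = ", "))
  if (any(tr$offset_s <= tr$onset_s))
    stop_validation("trial with offset <= onset")
  dur <- tr$offset_s - tr$onset_s
  tol <- 1e-9
  if (any(dur < duration_bounds[1] - tol | dur > duration_bounds[2] + tol))
    stop_validation("stimulus epoch duration outside [%g, %g] s",
                    duration_bounds[1], duration_bounds[2])
  if (any(tr$repeat_index < 1L))
    stop_validation("repeat_index must be >= 1")
  if (any(s$spikes$spike_time_s < 0))
    stop_validation("negative spike times")
  stray <- setdiff(unique(s$spikes$cell_id), s$cells)
  if (length(stray))
    stop_validation("spikes for cells absent from cell index: %s",
                    paste(stray, collapse = ", "))
  for (cid in unique(s$spikes$cell_id)) {
    st <- s$spikes$spike_time_s[s$spikes$cell_id == cid]
    if (any(diff(st) <= 0))
      stop_validation("spike times for cell %s not strictly increasing", cid)
  }
  invisible(s)
}

#' Spike times for one cell
#' @param s an `aob_session`
#' @param cell_id cell identifier
#' @return numeric vector of spike times (possibly empty)
#' @export
spike_times <- function(s, cell_id) {
  if (!cell_id %in% s$cells) stop_validation("unknown cell id: %s", cell_id)
  s$spikes$spike_time_s[s$spikes$cell_id == cell_id]
}

#' Recorded span of a session
#'
#' Uses `meta$duration_s` when present (always set by the simulator),
#' otherwise the latest of: last spike, last trial offset + 15 s.
#' @param s an `aob_session`
#' @return `c(0, end)` in seconds
#' @export
session_span <- function(s) {
  end <- s$meta$duration_s %||%
    max(c(s$spikes$spike_time_s, s$trials$offset_s + 15), na.rm = TRUE)
  c(0, end)
}

#' @export
print.aob_session <- function(x, ...) {
  cat(sprintf("<aob_session> %d cells, %d spikes, %d trials, %d stimuli (control: %s)\n",
              length(x$cells), nrow(x$spikes), nrow(x$trials),
              nrow(x$panel$stimuli), x$panel$control))
  invisible(x)
}

#' Write a session to a directory
#'
#' Plain-text layout: `spikes.csv` (cell_id, spike_time_s), `trials.csv`
#' (stimulus_id, onset_s, offset_s, repeat_index), `cells.csv` (cell index,
#' preserving silent cells), `panel.json`, `meta.json`. Numbers are written
#' with 17 significant digits so [read_session()] reproduces the session
#' exactly.
#'
#' @param s an `aob_session`
#' @param path target directory (created if needed)
#' @return `path`, invisibly
#' @export
write_session <- function(s, path) {
  validate_session(s)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create session directory: ", path)
  sp <- data.frame(cell_id = s$spikes$cell_id,
                   spike_time_s = fmt_num(s$spikes$spike_time_s))
  utils::write.csv(sp, file.path(path, "spikes.csv"), row.names = FALSE,
                   quote = FALSE)
  tr <- data.frame(stimulus_id = s$trials$stimulus_id,
                   onset_s = fmt_num(s$trials$onset_s),
                   offset_s = fmt_num(s$trials$offset_s),
                   repeat_index = s$trials$repeat_index)
  utils::write.csv(tr, file.path(path, "trials.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(data.frame(cell_id = s$cells),
                   file.path(path, "cells.csv"), row.names = FALSE,
                   quote = FALSE)
  jsonlite::write_json(list(stimuli = s$panel$stimuli, control = s$panel$control),
                       file.path(path, "panel.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(s$meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a session from a directory written by [write_session()]
#'
#' @param path session directory
#' @return validated `aob_session`
#' @export
read_session <- function(path) {
  req <- c("spikes.csv", "trials.csv", "panel.json")
  missing <- req[!file.exists(file.path(path, req))]
  if (length(missing))
    stop_format("session directory %s missing: %s", path,
                paste(missing, collapse = ", "))
  pj <- jsonlite::read_json(file.path(path, "panel.json"),
                            simplifyVector = TRUE)
  if (is.null(pj$control) || !length(pj$control))
    stop_format("panel.json lacks a control stimulus")
  panel <- stimulus_panel(pj$stimuli$id, control = pj$control,
                          labels = pj$stimuli$label, tags = pj$stimuli$tag)
  spikes <- utils::read.csv(file.path(path, "spikes.csv"),
                            colClasses = c(cell_id = "character",
                                           spike_time_s = "numeric"))
  trials <- utils::read.csv(file.path(path, "trials.csv"),
                            colClasses = c(stimulus_id = "character",
                                           onset_s = "numeric",
                                           offset_s = "numeric",
                                           repeat_index = "integer"))
  cells <- NULL
  if (file.exists(file.path(path, "cells.csv")))
    cells <- utils::read.csv(file.path(path, "cells.csv"),
                             colClasses = "character")$cell_id
  meta <- list()
  if (file.exists(file.path(path, "meta.json")))
    meta <- jsonlite::read_json(file.path(path, "meta.json"),
                                simplifyVector = TRUE)
  if (!is.null(meta$ground_truth))
    meta$ground_truth <- as.data.frame(meta$ground_truth)
  session(spikes, trial_table(trials$stimulus_id, trials$onset_s,
                              trials$offset_s, trials$repeat_index),
          panel, cells = cells, meta = meta)
}
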