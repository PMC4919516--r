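#' Analysis windows
#'
#' Window definitions, all relative to stimulus onset (seconds):
#' the response window is the 4 s stretch beginning 1 s after onset (the
#' delay allows the stimulus line's dead volume to clear), the baseline
#' window is the 5 s before onset, and the peristimulus window spans 5 s
#' before to 15 s after onset, evaluated in 1 s bins (20 bins).
#'
#' @param response `c(start, end)` of the response window (default `c(1, 5)`)
#' @param baseline `c(start, end)` of the baseline window (default `c(-5, 0)`)
#' @param psth `c(start, end)` of the peristimulus window (default `c(-5, 15)`)
#' @param psth_bin bin width in seconds (default 1)
#' @return list of class `analysis_windows`
#' @export
analysis_windows <- function(response = c(1, 5), baseline = c(-5, 0),
                             psth = c(-5, 15), psth_bin = 1) {
  stopifnot(diff(response) > 0, diff(baseline) > 0, diff(psth) > 0,
            psth_bin > 0)
  nb <- diff(psth) / psth_bin
  if (abs(nb - round(nb)) > 1e-9)
    stop_validation("psth window is not a whole number of bins")
  structure(list(response = response, baseline = baseline, psth = psth,
                 psth_bin = psth_bin), class = "analysis_windows")
}

#' Stimulus-evoked change in firing rate (delta-R)
#'
#' delta-R = (spike count in the response window) / response length -
#' (spike count in the baseline window) / baseline length, both windows
#' anchored at the event onset. Counting is half-open `[a, b)`.
#'
#' @param times spike times of one cell (seconds)
#' @param onset event onset(s); vectorised
#' @param windows an [analysis_windows()]
#' @return delta-R in Hz, one value per onset
#' @export
compute_delta_r <- function(times, onset, windows = analysis_windows()) {
  r <- windows$response; b <- windows$baseline
  vapply(onset, function(o) {
    count_spikes(times, o + r[1], o + r[2]) / diff(r) -
      count_spikes(times, o + b[1], o + b[2]) / diff(b)
  }, numeric(1))
}

#' Peristimulus time histogram
#'
#' Bins spikes around each event onset and averages the per-bin rate across
#' events. Events whose peristimulus window is not fully inside `span` are
#' dropped (their indices returned in `dropped`).
#'
#' @param times spike times of one cell
#' @param onsets event onsets
#' @param windows an [analysis_windows()]
#' @param span recorded span `c(start, end)`; `NULL` disables the check
#' @return object of class `aob_psth`: list with `t_left` (left bin edges,
#'   onset-relative), `rate` (mean Hz per bin), `sem` (across-event s.e.m.),
#'   `n_events`, `dropped`, and the per-event count matrix `counts`
#' @export
compute_psth <- function(times, onsets, windows = analysis_windows(),
                         span = NULL) {
  if (length(onsets) < 1) stop_validation("compute_psth needs >= 1 event")
  w <- windows$psth; bw <- windows$psth_bin
  dropped <- integer(0)
  if (!is.null(span)) {
    ok <- (onsets + w[1]) >= span[1] & (onsets + w[2]) <= span[2]
    dropped <- which(!ok)
    onsets <- onsets[ok]
    if (length(onsets) == 0)
      stop_validation("all events fall outside the recorded span")
  }
  edges <- seq(w[1], w[2], by = bw)
  counts <- t(vapply(onsets, function(o) {
    h <- findInterval(times - o, edges, left.open = FALSE)
    tabulate(h[h >= 1 & h <= length(edges) - 1], nbins = length(edges) - 1)
  }, numeric(length(edges) - 1)))
  rate <- colMeans(counts) / bw
  sem <- if (nrow(counts) > 1) apply(counts / bw, 2, stats::sd) / sqrt(nrow(counts))
         else rep(NA_real_, ncol(counts))
  structure(list(t_left = edges[-length(edges)], rate = rate, sem = sem,
                 n_events = length(onsets), dropped = dropped,
                 counts = counts, bin_s = bw),
            class = "aob_psth")
}

#' @export
print.aob_psth <- function(x, ...) {
  cat(sprintf("<aob_psth> %d bins x %d events; peak %.2f Hz\n",
              length(x$rate), x$n_events, max(x$rate)))
  invisible(x)
}

#' Per-trial responses for every cell x event of a session
#'
#' Events whose baseline or response window falls outside the recorded span
#' are dropped per event (logged in the `dropped_events` attribute).
#'
#' @param s an `aob_session`
#' @param windows an [analysis_windows()]
#' @return data frame (cell_id, stimulus_id, repeat_index, onset_s,
#'   delta_r_hz, response_hz, baseline_hz)
#' @export
session_responses <- function(s, windows = analysis_windows()) {
  span <- session_span(s)
  tr <- s$trials
  lo <- pmin(tr$onset_s + windows$baseline[1], tr$onset_s + windows$response[1])
  hi <- pmax(tr$onset_s + windows$baseline[2], tr$onset_s + windows$response[2])
  ok <- lo >= span[1] & hi <= span[2]
  if (any(!ok))
    message(sprintf("session_responses: %d event(s) outside recorded span dropped",
                    sum(!ok)))
  tr <- tr[ok, , drop = FALSE]
  r <- windows$response; b <- windows$baseline
  res <- lapply(s$cells, function(cid) {
    st <- spike_times(s, cid)
    resp <- vapply(tr$onset_s, function(o)
      count_spikes(st, o + r[1], o + r[2]) / diff(r), numeric(1))
    base <- vapply(tr$onset_s, function(o)
      count_spikes(st, o + b[1], o + b[2]) / diff(b), numeric(1))
    data.frame(cell_id = cid, stimulus_id = tr$stimulus_id,
               repeat_index = tr$repeat_index, onset_s = tr$onset_s,
               delta_r_hz = resp - base, response_hz = resp,
               baseline_hz = base, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "dropped_events") <- which(!ok)
  out
}

#' Significance call for one cell x stimulus
#'
#' A response is significant iff (1) a two-sample Student's t-test of the
#' per-trial delta-R values against the control stimulus trials gives
#' p < `alpha`, and (2) the mean rate increase exceeds `rate_threshold_hz`.
#' The rate criterion reads the mean delta-R by default
#' (`rate_criterion = "delta_r"`); `"absolute"` instead requires the mean
#' response-window rate itself to exceed the threshold (both readings of the
#' published rule are available).
#'
#' @param delta_r per-trial delta-R values for the stimulus
#' @param control_delta_r per-trial delta-R values for the control
#' @param alpha t-test threshold (default 0.05)
#' @param rate_threshold_hz rate floor in Hz (default 1)
#' @param rate_criterion `"delta_r"` (default) or `"absolute"`
#' @param response_hz per-trial response-window rates, required for the
#'   `"absolute"` criterion
#' @param var_equal classical Student's form (default TRUE); FALSE gives the
#'   Welch variant
#' @param min_trials minimum trials per group (default 3); fewer returns an
#'   unanalyzable call (`significant = NA`)
#' @return list: `significant` (logical or NA), `p_value`, `rate_ok`,
#'   `mean_delta_r`, `n_trials`
#' @export
call_response <- function(delta_r, control_delta_r, alpha = 0.05,
                          rate_threshold_hz = 1,
                          rate_criterion = c("delta_r", "absolute"),
                          response_hz = NULL, var_equal = TRUE,
                          min_trials = 3) {
  rate_criterion <- match.arg(rate_criterion)
  n1 <- length(delta_r); n0 <- length(control_delta_r)
  if (n1 < min_trials || n0 < min_trials)
    return(list(significant = NA, p_value = NA_real_, rate_ok = NA,
                mean_delta_r = mean(delta_r), n_trials = n1))
  p <- if (stats::sd(delta_r) == 0 && stats::sd(control_delta_r) == 0) {
    if (mean(delta_r) == mean(control_delta_r)) 1 else 0
  } else {
    stats::t.test(delta_r, control_delta_r, var.equal = var_equal)$p.value
  }
  rate_ok <- if (rate_criterion == "delta_r") {
    mean(delta_r) > rate_threshold_hz
  } else {
    if (is.null(response_hz))
      stop_validation("rate_criterion = 'absolute' needs response_hz")
    mean(response_hz) > rate_threshold_hz
  }
  list(significant = (p < alpha) && rate_ok, p_value = p, rate_ok = rate_ok,
       mean_delta_r = mean(delta_r), n_trials = n1)
}

# one-sample rule for the control stimulus itself: a cell "responds to the
# control" if its control delta-R is significantly above 0 and exceeds the
# rate floor
call_control_response <- function(control_delta_r, alpha = 0.05,
                                  rate_threshold_hz = 1, min_trials = 3) {
  if (length(control_delta_r) < min_trials)
    return(list(significant = NA, p_value = NA_real_))
  p <- if (stats::sd(control_delta_r) == 0) {
    if (mean(control_delta_r) == 0) 1 else 0
  } else {
    stats::t.test(control_delta_r, mu = 0)$p.value
  }
  list(significant = (p < alpha) && mean(control_delta_r) > rate_threshold_hz,
       p_value = p)
}

#' Cell inclusion rule
#'
#' A cell enters the population analyses iff it has at least one significant
#' non-control stimulus, is not control-responsive, and completed at least
#' `min_trials` trials for every tested stimulus.
#'
#' @param stimulus_significant logical vector of non-control significance
#'   calls (NA = unanalyzable)
#' @param control_significant logical control call
#' @param n_trials trial counts per tested stimulus (including control)
#' @param min_trials minimum complete trials (default 3)
#' @return list: `included` (logical), `reason` (one of "included",
#'   "insufficient trials", "control responsive", "no response")
#' @export
include_cell <- function(stimulus_significant, control_significant, n_trials,
                         min_trials = 3) {
  if (any(n_trials < min_trials) || any(is.na(stimulus_significant)) ||
      is.na(control_significant))
    return(list(included = FALSE, reason = "insufficient trials"))
  if (isTRUE(control_significant))
    return(list(included = FALSE, reason = "control responsive"))
  if (!any(stimulus_significant))
    return(list(included = FALSE, reason = "no response"))
  list(included = TRUE, reason = "included")
}

#' Normalize a cell's tuning vector
#'
#' Divides the mean delta-R vector (control excluded by the caller) by the
#' maximum absolute entry, so the strongest response maps to +1 or -1 and
#' inhibitory responses stay within `[-1, 1]`.
#'
#' @param mean_delta_r numeric vector of per-stimulus mean delta-R
#' @return normalized vector; errors on an all-zero input (such a cell
#'   should have been excluded upstream)
#' @export
normalize_tuning <- function(mean_delta_r) {
  m <- max(abs(mean_delta_r))
  if (m == 0) stop_validation("cannot normalize an all-zero tuning vector")
  mean_delta_r / m
}

#' Full tuning table for a session
#'
#' Runs [session_responses()], calls significance per cell x non-control
#' stimulus against the control trials, applies the control-responsiveness
#' and inclusion rules, and normalizes each included cell's mean delta-R
#' vector to its maximum absolute response.
#'
#' @param s an `aob_session`
#' @param windows an [analysis_windows()]
#' @inheritParams call_response
#' @return object of class `tuning_table`: list with `calls` (data frame:
#'   cell_id, stimulus_id, n_trials, mean_delta_r, p_value, significant,
#'   norm_delta_r), `cells` (cell_id, control_significant, included, reason),
#'   `responses` (the per-trial table), `control` (id), `stimuli`
#'   (non-control ids)
#' @export
build_tuning_table <- function(s, windows = analysis_windows(), alpha = 0.05,
                               rate_threshold_hz = 1,
                               rate_criterion = c("delta_r", "absolute"),
                               var_equal = TRUE, min_trials = 3) {
  rate_criterion <- match.arg(rate_criterion)
  resp <- session_responses(s, windows)
  ctrl <- s$panel$control
  stim_ids <- setdiff(s$panel$stimuli$id, ctrl)
  calls <- list(); cells <- list()
  for (cid in s$cells) {
    rc <- resp[resp$cell_id == cid, ]
    dr_ctrl <- rc$delta_r_hz[rc$stimulus_id == ctrl]
    cc <- call_control_response(dr_ctrl, alpha, rate_threshold_hz, min_trials)
    row <- lapply(stim_ids, function(sid) {
      sel <- rc$stimulus_id == sid
      cr <- call_response(rc$delta_r_hz[sel], dr_ctrl, alpha,
                          rate_threshold_hz, rate_criterion,
                          response_hz = rc$response_hz[sel],
                          var_equal = var_equal, min_trials = min_trials)
      data.frame(cell_id = cid, stimulus_id = sid, n_trials = cr$n_trials,
                 mean_delta_r = cr$mean_delta_r, p_value = cr$p_value,
                 significant = cr$significant, stringsAsFactors = FALSE)
    })
    row <- do.call(rbind, row)
    inc <- include_cell(row$significant, cc$significant,
                        c(row$n_trials, length(dr_ctrl)), min_trials)
    row$norm_delta_r <- NA_real_
    if (inc$included)
      row$norm_delta_r <- normalize_tuning(row$mean_delta_r)
    calls[[cid]] <- row
    cells[[cid]] <- data.frame(cell_id = cid,
                               control_significant = cc$significant,
                               included = inc$included, reason = inc$reason,
                               stringsAsFactors = FALSE)
  }
  structure(list(calls = do.call(rbind, c(calls, make.row.names = FALSE)),
                 cells = do.call(rbind, c(cells, make.row.names = FALSE)),
                 responses = resp, control = ctrl, stimuli = stim_ids),
            class = "tuning_table")
}

#' @export
print.tuning_table <- function(x, ...) {
  cat(sprintf("<tuning_table> %d cells (%d included) x %d stimuli + control '%s'\n",
              nrow(x$cells), sum(x$cells$included), length(x$stimuli),
              x$control))
  invisible(x)
}

#' Binary response matrix of a tuning table
#'
#' @param tt a `tuning_table`
#' @param included_only restrict to included cells (default TRUE)
#' @return logical matrix, cells x non-control stimuli
#' @export
response_matrix <- function(tt, included_only = TRUE) {
  cells <- if (included_only) tt$cells$cell_id[tt$cells$included]
           else tt$cells$cell_id
  m <- matrix(FALSE, length(cells), length(tt$stimuli),
              dimnames = list(cells, tt$stimuli))
  cl <- tt$calls[tt$calls$cell_id %in% cells, ]
  m[cbind(cl$cell_id, cl$stimulus_id)] <- !is.na(cl$significant) & cl$significant
  m
}

#' Normalized tuning matrix of included cells
#'
#' @param tt a `tuning_table`
#' @return numeric matrix in `[-1, 1]`, included cells x non-control stimuli
#' @export
tuning_matrix <- function(tt) {
  cells <- tt$cells$cell_id[tt$cells$included]
  m <- matrix(NA_real_, length(cells), length(tt$stimuli),
              dimnames = list(cells, tt$stimuli))
  cl <- tt$calls[tt$calls$cell_id %in% cells, ]
  m[cbind(cl$cell_id, cl$stimulus_id)] <- cl$norm_delta_r
  m
}

#' Fluorescence response ratio (dF/F-style)
#'
#' Mean intensity of the 3 stacks from stimulus onset divided by the mean of
#' the 3 stacks immediately before onset, as used for volumetric calcium
#' imaging of sensory neurons.
#'
#' @param stack_means per-stack mean pixel intensities
#' @param stim_onset_index 1-based index of the first stack at/after onset
#' @param n_stacks stacks averaged on each side (default 3)
#' @return unitless post/pre ratio
#' @export
compute_dff <- function(stack_means, stim_onset_index, n_stacks = 3) {
  if (stim_onset_index - n_stacks < 1 ||
      stim_onset_index + n_stacks - 1 > length(stack_means))
    stop_validation("need %d stacks on each side of the onset", n_stacks)
  pre <- mean(stack_means[(stim_onset_index - n_stacks):(stim_onset_index - 1)])
  post <- mean(stack_means[stim_onset_index:(stim_onset_index + n_stacks - 1)])
  if (pre == 0) stop_validation("baseline intensity is zero")
  post / pre
}
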