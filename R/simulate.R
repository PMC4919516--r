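#' Generator configuration for synthetic sessions
#'
#' Defines a ground-truth tuning experiment: each cell fires as a
#' piecewise-constant-rate Poisson process at its baseline rate `lambda0`,
#' elevated by `delta[cell, stimulus]` Hz during the 4 s response window
#' (1 s after onset) of each matching stimulus event. Stimuli are delivered
#' in randomised interleaved blocks (each stimulus once per block), mirroring
#' the ex vivo delivery protocol the generator emulates.
#'
#' @param n_cells number of cells
#' @param panel a [stimulus_panel()]
#' @param baseline_hz per-cell baseline rate lambda0 (scalar or length
#'   `n_cells`); if `NULL`, drawn uniformly from `baseline_range_hz` at
#'   simulation time
#' @param effect_hz ground-truth effect matrix Delta (Hz), `n_cells` rows,
#'   columns named by stimulus id. Missing stimuli (and always the control)
#'   get Delta = 0. `NULL` means all zero.
#' @param trials_per_stimulus repeats per stimulus (>= 3; default 5)
#' @param stimulus_duration_s epoch length in seconds (default 4; the
#'   delivery protocol allows 3-5)
#' @param inter_onset_s spacing between consecutive onsets (default 20 s,
#'   enough to hold the full 20 s peristimulus window)
#' @param jitter_sd across-trial multiplicative effect jitter: per trial the
#'   effect is scaled by a unit-mean log-normal factor with this log-sd
#'   (default 0.2); 0 disables jitter
#' @param baseline_range_hz range for drawn baselines (default 0.5-3 Hz)
#' @param seed integer seed recorded in the session metadata
#' @return object of class `generator_config`
#' @export
generator_config <- function(n_cells, panel, baseline_hz = NULL,
                             effect_hz = NULL, trials_per_stimulus = 5,
                             stimulus_duration_s = 4, inter_onset_s = 20,
                             jitter_sd = 0.2,
                             baseline_range_hz = c(0.5, 3), seed = 1L) {
  if (!inherits(panel, "stimulus_panel")) stop_format("panel must be a stimulus_panel")
  if (trials_per_stimulus < 3) stop_validation("trials_per_stimulus must be >= 3")
  stim_ids <- panel$stimuli$id
  delta <- matrix(0, n_cells, length(stim_ids),
                  dimnames = list(NULL, stim_ids))
  if (!is.null(effect_hz)) {
    effect_hz <- as.matrix(effect_hz)
    if (nrow(effect_hz) != n_cells)
      stop_validation("effect_hz must have n_cells rows")
    bad <- setdiff(colnames(effect_hz), stim_ids)
    if (length(bad))
      stop_validation("effect_hz columns not in panel: %s",
                      paste(bad, collapse = ", "))
    delta[, colnames(effect_hz)] <- effect_hz
  }
  delta[, panel$control] <- 0  # the generator never plants control responders
  if (!is.null(baseline_hz)) {
    baseline_hz <- rep_len(as.numeric(baseline_hz), n_cells)
    if (any(baseline_hz <= 0)) stop_validation("baseline rates must be > 0")
    if (any(baseline_hz + apply(delta, 1, min) < 0))
      stop_validation("lambda0 + Delta must be >= 0 for every cell x stimulus")
  }
  structure(list(n_cells = n_cells, panel = panel, baseline_hz = baseline_hz,
                 delta = delta, trials_per_stimulus = trials_per_stimulus,
                 stimulus_duration_s = stimulus_duration_s,
                 inter_onset_s = inter_onset_s, jitter_sd = jitter_sd,
                 baseline_range_hz = baseline_range_hz,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Simulate a trial-structured session with known ground truth
#'
#' Spikes are drawn from a piecewise-constant Poisson process: rate
#' `lambda0` everywhere except the 4 s response window
#' `[onset + 1, onset + 5]` of each event, where the rate is
#' `lambda0 + Delta * f_trial` with `f_trial` a unit-mean log-normal jitter
#' factor. Rates that would go negative after jitter (possible for
#' inhibitory Delta) are clipped to 0 and counted in
#' `meta$clipped_rate_segments`. Trial order is a seeded random interleave:
#' within every block each stimulus appears exactly once. The ground-truth
#' effect map, config and seed are stored in the session metadata.
#'
#' @param config a [generator_config()]
#' @return an `aob_session`; deterministic given `config$seed`
#' @export
simulate_session <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  p <- config$panel
  stim_ids <- p$stimuli$id
  n_stim <- length(stim_ids)
  n_events <- n_stim * config$trials_per_stimulus

  order_ids <- unlist(lapply(seq_len(config$trials_per_stimulus),
                             function(b) sample(stim_ids)))
  pre_pad <- 10
  onsets <- pre_pad + (seq_len(n_events) - 1) * config$inter_onset_s
  rep_idx <- stats::ave(seq_along(order_ids), order_ids, FUN = seq_along)
  trials <- trial_table(order_ids, onsets,
                        onsets + config$stimulus_duration_s, rep_idx)
  t_end <- onsets[n_events] + 15

  lambda0 <- config$baseline_hz
  if (is.null(lambda0))
    lambda0 <- stats::runif(config$n_cells, config$baseline_range_hz[1],
                            config$baseline_range_hz[2])

  # per cell x event jitter factors (unit mean log-normal)
  s <- config$jitter_sd
  jit <- if (s > 0)
    matrix(stats::rlnorm(config$n_cells * n_events,
                         meanlog = -s^2 / 2, sdlog = s),
           config$n_cells, n_events)
  else matrix(1, config$n_cells, n_events)

  win_lo <- onsets + 1
  win_hi <- onsets + 5
  clipped <- 0L
  cell_ids <- sprintf("cell_%03d", seq_len(config$n_cells))
  out <- vector("list", config$n_cells)
  for (i in seq_len(config$n_cells)) {
    d_ev <- config$delta[i, order_ids] * jit[i, ]
    # segment breakpoints: baseline stretches interleaved with response windows
    seg_lo <- c(0, win_hi)
    seg_hi <- c(win_lo, t_end)
    base_times <- sample_poisson_segments(seg_lo, seg_hi, rep(lambda0[i], n_events + 1))
    rates <- lambda0[i] + d_ev
    neg <- rates < 0
    if (any(neg)) { clipped <- clipped + sum(neg); rates[neg] <- 0 }
    win_times <- sample_poisson_segments(win_lo, win_hi, rates)
    st <- sort(c(base_times, win_times))
    st <- st[!duplicated(st)]
    out[[i]] <- data.frame(cell_id = cell_ids[i], spike_time_s = st,
                           stringsAsFactors = FALSE)
  }
  spikes <- do.call(rbind, out)
  gt <- data.frame(cell_id = rep(cell_ids, times = n_stim),
                   stimulus_id = rep(stim_ids, each = config$n_cells),
                   delta_hz = as.vector(config$delta),
                   stringsAsFactors = FALSE)
  meta <- list(synthetic = TRUE, seed = config$seed, duration_s = t_end,
               baseline_hz = lambda0, ground_truth = gt,
               clipped_rate_segments = clipped,
               generator = list(n_cells = config$n_cells,
                                trials_per_stimulus = config$trials_per_stimulus,
                                stimulus_duration_s = config$stimulus_duration_s,
                                inter_onset_s = config$inter_onset_s,
                                jitter_sd = config$jitter_sd))
  if (clipped > 0)
    message(sprintf("simulate_session: %d negative rate segment(s) clipped to 0", clipped))
  session(spikes, trials, p, cells = cell_ids, meta = meta)
}

# homogeneous Poisson samples on disjoint segments [lo_k, hi_k) at rate_k
sample_poisson_segments <- function(lo, hi, rate) {
  len <- hi - lo
  n <- stats::rpois(length(lo), rate * len)
  if (sum(n) == 0) return(numeric(0))
  u <- stats::runif(sum(n))
  offs <- rep(lo, n) + u * rep(len, n)
  sort(offs)
}

#' Ground-truth tuning of a synthetic session
#'
#' Binary table of planted responsiveness: TRUE where the planted effect is
#' at or above the detection floor (default 1 Hz, mirroring the rate
#' criterion of the significance caller).
#'
#' @param s a session produced by [simulate_session()]
#' @param floor_hz detection floor (default 1)
#' @return data frame (cell_id, stimulus_id, delta_hz, responsive)
#' @export
ground_truth_tuning <- function(s, floor_hz = 1) {
  if (!isTRUE(s$meta$synthetic) || is.null(s$meta$ground_truth))
    stop_validation("session carries no ground truth (not generator-produced)")
  gt <- s$meta$ground_truth
  gt$responsive <- gt$delta_hz >= floor_hz
  gt
}
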