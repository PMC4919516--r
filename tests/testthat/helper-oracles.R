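# Independent brute-force oracles and small fixture builders shared by the
# suite. The oracles deliberately use naive loops and first-principles
# formulas, never the package's own code paths.

# naive delta-R: count spikes one by one over explicit windows
bf_delta_r <- function(times, onset, resp = c(1, 5), base = c(-5, 0)) {
  nr <- 0; nb <- 0
  for (t in times) {
    if (t >= onset + resp[1] && t < onset + resp[2]) nr <- nr + 1
    if (t >= onset + base[1] && t < onset + base[2]) nb <- nb + 1
  }
  nr / (resp[2] - resp[1]) - nb / (base[2] - base[1])
}

# naive PSTH: per-event, per-bin double loop
bf_psth <- function(times, onsets, win = c(-5, 15), bin = 1) {
  nbins <- (win[2] - win[1]) / bin
  acc <- matrix(0, length(onsets), nbins)
  for (e in seq_along(onsets)) {
    for (b in seq_len(nbins)) {
      lo <- onsets[e] + win[1] + (b - 1) * bin
      hi <- lo + bin
      acc[e, b] <- sum(times >= lo & times < hi)
    }
  }
  colMeans(acc) / bin
}

# d-prime from first principles (explicit sums, n-1 variance)
bf_dprime <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  vx <- sum((x - mx)^2) / (length(x) - 1)
  vy <- sum((y - my)^2) / (length(y) - 1)
  abs(mx - my) / sqrt((vx + vy) / 2)
}

# pairwise overlap by explicit set intersection over cells
bf_pairwise <- function(m, stimuli) {
  out <- matrix(NA_real_, length(stimuli), length(stimuli),
                dimnames = list(stimuli, stimuli))
  for (r in stimuli) {
    resp_r <- rownames(m)[m[, r]]
    if (length(resp_r) == 0) next
    for (c in stimuli) {
      resp_c <- rownames(m)[m[, c]]
      out[r, c] <- 100 * length(intersect(resp_r, resp_c)) / length(resp_r)
    }
  }
  out
}

demo_panel <- function(stims = c("urine", "faeces"), control = "ringers") {
  stimulus_panel(c(control, stims), control = control)
}

# tiny hand-built session: one cell, given spike times, one event per
# stimulus repeat at 20 s spacing starting at onset 10
tiny_session <- function(times, stims = c("urine", "faeces"), repeats = 3,
                         cell = "c1") {
  p <- demo_panel(stims)
  ids <- rep(p$stimuli$id, repeats)
  onsets <- 10 + (seq_along(ids) - 1) * 20
  tr <- trial_table(ids, onsets, onsets + 4,
                    rep(seq_len(repeats), each = nrow(p$stimuli)))
  session(data.frame(cell_id = rep(cell, length(times)),
                     spike_time_s = times),
          tr, p, cells = cell,
          meta = list(duration_s = max(onsets) + 15))
}

# binary response matrix with named region counts, e.g.
# region_matrix(list("urine" = 22, "faeces" = 19, "urine+faeces" = 14,
#                    "other" = 34), stimuli = c("urine","faeces","other_stim"))
region_matrix <- function(counts, stimuli) {
  n <- sum(unlist(counts))
  m <- matrix(FALSE, n, length(stimuli),
              dimnames = list(sprintf("cell%03d", seq_len(n)), stimuli))
  i <- 0
  for (region in names(counts)) {
    k <- counts[[region]]
    cols <- if (region == "other") "other_stim" else strsplit(region, "+", fixed = TRUE)[[1]]
    if (k > 0) m[(i + 1):(i + k), cols] <- TRUE
    i <- i + k
  }
  m
}

# planted-archetype generator session: n_per cells per archetype, effect
# delta_hz on the archetype's stimulus only
archetype_session <- function(n_arch = 4, n_per = 15, delta_hz = 8, seed = 1,
                              baseline_hz = NULL) {
  stims <- paste0("s", seq_len(n_arch))
  p <- stimulus_panel(c("ringers", stims), control = "ringers")
  n <- n_arch * n_per
  truth <- rep(seq_len(n_arch), each = n_per)
  eff <- matrix(0, n, n_arch + 1, dimnames = list(NULL, p$stimuli$id))
  for (i in seq_len(n)) eff[i, stims[truth[i]]] <- delta_hz
  cfg <- generator_config(n, p, baseline_hz = baseline_hz, effect_hz = eff,
                          seed = seed)
  list(session = simulate_session(cfg), truth = truth, panel = p,
       config = cfg)
}
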