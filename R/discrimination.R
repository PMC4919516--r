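#' Discriminability index (d-prime) for one cell
#'
#' The sensitivity index with pooled across-trial variance:
#' `|mean(x) - mean(y)| / sqrt((var(x) + var(y)) / 2)`, sample variances
#' with n - 1 denominator. The absolute value makes d-prime non-negative and
#' symmetric in its arguments.
#'
#' @param x,y per-trial delta-R values for the two stimuli (>= 2 trials each)
#' @return non-negative unitless d-prime; 0 if both variances are zero and
#'   the means agree; error if both variances are zero and the means differ
#'   (undefined)
#' @export
dprime <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop_validation("dprime needs >= 2 trials per stimulus")
  v1 <- stats::var(x); v2 <- stats::var(y)
  num <- abs(mean(x) - mean(y))
  if (v1 + v2 == 0) {
    if (num == 0) return(0)
    stop_validation("d-prime undefined: zero variance with unequal means")
  }
  num / sqrt((v1 + v2) / 2)
}

#' Population shuffle test for d-prime distributions
#'
#' Tests whether the observed per-cell d-prime distribution reflects
#' systematic discrimination rather than random integration of independent
#' response variables. `n_model` model populations of the same size are
#' drawn: in the default `"trial_sets"` mode each model cell pairs a
#' randomly chosen cell's stimulus-1 trial set with an independently chosen
#' cell's stimulus-2 trial set (sampled with replacement), preserving each
#' donor's across-trial variance; in `"values"` mode each model cell's trial
#' sets are rebuilt by sampling individual delta-R values pooled across all
#' cells. Each model population's d-prime distribution is compared with the
#' observed one by a tie-corrected two-group Kruskal-Wallis test; a model
#' population counts as "statistically lower" when p < `alpha` and its
#' median d-prime is below the observed median.
#'
#' @param trials_a,trials_b lists (one element per cell) of per-trial
#'   delta-R vectors for the two compared stimuli; >= 2 cells, >= 2 trials
#'   per set
#' @param n_model number of model populations (default 100000; >= 1)
#' @param seed integer seed
#' @param alpha significance threshold (default 0.05)
#' @param mode `"trial_sets"` (default) or `"values"`
#' @param keep_models return the full model d-prime matrix (cells x
#'   `n_model`); off by default to bound memory at large `n_model`
#' @return object of class `shuffle_test`: `fraction_lower` (fraction of
#'   model populations significantly below the observed), `observed`
#'   (per-cell d-prime), `observed_median`, `model_medians`, `p_values`,
#'   `n_model`, `seed`, `mode`, and `model_dprime` if requested
#' @export
shuffle_test <- function(trials_a, trials_b, n_model = 100000, seed = 1L,
                         alpha = 0.05, mode = c("trial_sets", "values"),
                         keep_models = FALSE) {
  mode <- match.arg(mode)
  n <- length(trials_a)
  if (length(trials_b) != n)
    stop_validation("trials_a and trials_b must have one element per cell")
  if (n < 2)
    stop_validation("shuffle test needs >= 2 cells (rank test degenerate)")
  if (n_model < 1) stop_validation("n_model must be >= 1")
  set.seed(seed)
  observed <- mapply(dprime, trials_a, trials_b)
  obs_med <- stats::median(observed)

  if (mode == "trial_sets") {
    ma <- vapply(trials_a, mean, numeric(1))
    va <- vapply(trials_a, stats::var, numeric(1))
    mb <- vapply(trials_b, mean, numeric(1))
    vb <- vapply(trials_b, stats::var, numeric(1))
    ia <- matrix(sample.int(n, n * n_model, replace = TRUE), n, n_model)
    ib <- matrix(sample.int(n, n * n_model, replace = TRUE), n, n_model)
    num <- abs(ma[ia] - mb[ib])
    den <- sqrt((va[ia] + vb[ib]) / 2)
    dm <- matrix(ifelse(den == 0, ifelse(num == 0, 0, Inf), num / den),
                 n, n_model)
  } else {
    pool_a <- unlist(trials_a)
    pool_b <- unlist(trials_b)
    na <- vapply(trials_a, length, integer(1))
    nb <- vapply(trials_b, length, integer(1))
    grp_a <- rep(seq_len(n), na)
    grp_b <- rep(seq_len(n), nb)
    dm <- matrix(NA_real_, n, n_model)
    chunk <- max(1L, min(n_model, as.integer(2e6 / (sum(na) + sum(nb)) + 1)))
    done <- 0L
    while (done < n_model) {
      m <- min(chunk, n_model - done)
      da <- matrix(pool_a[sample.int(length(pool_a), sum(na) * m,
                                     replace = TRUE)], sum(na), m)
      db <- matrix(pool_b[sample.int(length(pool_b), sum(nb) * m,
                                     replace = TRUE)], sum(nb), m)
      sa <- rowsum(da, grp_a) / na
      sb <- rowsum(db, grp_b) / nb
      va <- (rowsum(da^2, grp_a) - na * sa^2) / (na - 1)
      vb <- (rowsum(db^2, grp_b) - nb * sb^2) / (nb - 1)
      num <- abs(sa - sb)
      den <- sqrt((va + vb) / 2)
      dm[, (done + 1):(done + m)] <-
        ifelse(den == 0, ifelse(num == 0, 0, Inf), num / den)
      done <- done + m
    }
  }

  model_medians <- apply(dm, 2, stats::median)
  p_values <- vapply(seq_len(n_model), function(j)
    kw2_pvalue(observed, dm[, j]), numeric(1))
  lower <- p_values < alpha & model_medians < obs_med
  res <- list(fraction_lower = mean(lower), observed = observed,
              observed_median = obs_med, model_medians = model_medians,
              p_values = p_values, n_model = n_model, seed = seed,
              mode = mode, alpha = alpha)
  if (keep_models) res$model_dprime <- dm
  structure(res, class = "shuffle_test")
}

#' @export
print.shuffle_test <- function(x, ...) {
  cat(sprintf(
    "<shuffle_test> %d cells, %d model populations (%s mode)\n  observed median d' = %.3f; %.1f%% of model populations statistically lower\n",
    length(x$observed), x$n_model, x$mode, x$observed_median,
    100 * x$fraction_lower))
  invisible(x)
}

# tie-corrected Kruskal-Wallis p-value for exactly two groups.
# Equivalent to stats::kruskal.test(list(x, y)) but ~20x faster, which the
# shuffle test needs at 1e4-1e5 model populations.
kw2_pvalue <- function(x, y) {
  nx <- length(x); ny <- length(y); N <- nx + ny
  r <- rank(c(x, y))
  stat <- 12 / (N * (N + 1)) *
    (sum(r[seq_len(nx)])^2 / nx + sum(r[nx + seq_len(ny)])^2 / ny) -
    3 * (N + 1)
  ties <- table(r)
  tie_corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (tie_corr == 0) return(1)  # all values identical
  stats::pchisq(stat / tie_corr, df = 1, lower.tail = FALSE)
}

#' Histogram of observed vs. model d-prime distributions
#'
#' Bins the observed per-cell d-prime values and, when model populations are
#' available, the mean per-bin count across model populations (the "mean of
#' shuffled populations" overlay of the population figures). Counts in every
#' histogram sum to the number of cells.
#'
#' @param observed numeric vector of observed d-prime values, or a
#'   [shuffle_test()] result run with `keep_models = TRUE`
#' @param model optional matrix of model d-prime values (cells x populations)
#' @param bin_width bin width (default 0.25)
#' @return data frame (bin_lo, bin_hi, observed_count, model_mean_count)
#' @export
dprime_histogram <- function(observed, model = NULL, bin_width = 0.25) {
  if (inherits(observed, "shuffle_test")) {
    model <- observed$model_dprime
    observed <- observed$observed
  }
  finite_max <- max(c(observed, if (!is.null(model)) model[is.finite(model)]),
                    na.rm = TRUE)
  top <- max(bin_width, ceiling(finite_max / bin_width + 1e-9) * bin_width)
  edges <- seq(0, top, by = bin_width)
  bin_of <- function(v) {
    b <- findInterval(v, edges, left.open = FALSE, rightmost.closed = TRUE)
    pmin(pmax(b, 1L), length(edges) - 1L)
  }
  obs_count <- tabulate(bin_of(observed), nbins = length(edges) - 1L)
  model_mean <- rep(NA_real_, length(edges) - 1L)
  if (!is.null(model)) {
    cnt <- apply(model, 2, function(col)
      tabulate(bin_of(col), nbins = length(edges) - 1L))
    model_mean <- rowMeans(cnt)
  }
  data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
             observed_count = obs_count, model_mean_count = model_mean)
}

#' Per-cell trial sets for a stimulus pair
#'
#' Extracts, for every included cell of a tuning table, the per-trial
#' delta-R vectors for two stimuli, optionally normalized by the cell's
#' maximum absolute mean response (the same per-cell scale used for the
#' tuning heat maps); input shape required by [shuffle_test()].
#'
#' @param tt a `tuning_table`
#' @param stim_a,stim_b stimulus ids
#' @param normalized divide each cell's trials by its max |mean delta-R|
#'   (default TRUE)
#' @return list with `trials_a`, `trials_b` (named lists per cell)
#' @export
trial_sets <- function(tt, stim_a, stim_b, normalized = TRUE) {
  stopifnot(inherits(tt, "tuning_table"))
  bad <- setdiff(c(stim_a, stim_b), tt$stimuli)
  if (length(bad))
    stop_validation("stimuli absent from tuning table: %s",
                    paste(bad, collapse = ", "))
  cells <- tt$cells$cell_id[tt$cells$included]
  get <- function(cid, sid) {
    v <- tt$responses$delta_r_hz[tt$responses$cell_id == cid &
                                   tt$responses$stimulus_id == sid]
    if (normalized) {
      m <- max(abs(tt$calls$mean_delta_r[tt$calls$cell_id == cid]))
      v <- v / m
    }
    v
  }
  list(trials_a = stats::setNames(lapply(cells, get, stim_a), cells),
       trials_b = stats::setNames(lapply(cells, get, stim_b), cells))
}
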