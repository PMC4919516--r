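#' Pipeline configuration
#'
#' Assembles (or reads from YAML) the configuration for an end-to-end run:
#' synthetic-session generator settings, analysis-window overrides,
#' consensus-clustering parameters, shuffle-test parameters and tuning
#' category definitions. Every random stage derives its seed from the single
#' top-level `seed`, so a config fully determines the outputs.
#'
#' @param path YAML file to read, or `NULL` to build from the arguments
#' @param generator a [generator_config()] (ignored when `path` given)
#' @param windows an [analysis_windows()]
#' @param clustering list: `n_runs`, `k_range`, `quantile`, `bandwidth`
#' @param shuffle list: `stim_a`, `stim_b`, `n_model`, `mode`, `normalized`
#' @param categories named list of stimulus sets for [classify_tuning()]
#'   (`NULL` skips classification)
#' @param seed master seed
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(path = NULL, generator = NULL,
                            windows = analysis_windows(),
                            clustering = list(n_runs = 500, k_range = 2:12,
                                              quantile = 0.3,
                                              bandwidth = NULL),
                            shuffle = NULL, categories = NULL, seed = 1L) {
  if (!is.null(path)) {
    y <- yaml::read_yaml(path)
    if (is.null(y$panel$control))
      stop_format("config panel lacks a control stimulus id")
    panel <- stimulus_panel(vapply(y$panel$stimuli, `[[`, "", "id"),
                            control = y$panel$control,
                            labels = vapply(y$panel$stimuli, function(s)
                              s$label %||% s$id, ""),
                            tags = vapply(y$panel$stimuli, function(s)
                              s$tag %||% "", ""))
    effect <- NULL
    if (!is.null(y$effects)) {
      effect <- matrix(0, y$n_cells, nrow(panel$stimuli),
                       dimnames = list(NULL, panel$stimuli$id))
      for (e in y$effects)
        effect[e$cells[1]:e$cells[2], e$stimulus] <- e$delta_hz
    }
    seed <- y$seed %||% 1L
    generator <- generator_config(
      n_cells = y$n_cells, panel = panel,
      baseline_hz = y$baseline_hz,
      effect_hz = effect,
      trials_per_stimulus = y$trials_per_stimulus %||% 5,
      stimulus_duration_s = y$stimulus_duration_s %||% 4,
      inter_onset_s = y$inter_onset_s %||% 20,
      jitter_sd = y$jitter_sd %||% 0.2,
      seed = seed)
    clustering <- utils::modifyList(clustering, y$clustering %||% list())
    shuffle <- y$shuffle
    categories <- y$categories
  }
  if (is.null(generator)) stop_format("pipeline config needs a generator")
  structure(list(generator = generator, windows = windows,
                 clustering = clustering, shuffle = shuffle,
                 categories = categories, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Simulates (or accepts) a session, computes the tuning table, optional
#' category classification, consensus clustering + MDS of the normalized
#' tuning curves, and the optional d-prime shuffle test; writes all tables
#' plus a manifest to `out_dir`. Identical config + seed produce identical
#' outputs.
#'
#' @param config a [pipeline_config()]
#' @param out_dir output directory
#' @param session optional pre-built `aob_session` (skips simulation)
#' @return (invisibly) list with `session`, `tuning`, `classification`,
#'   `clustering`, `mds`, `shuffle`, `out_dir`
#' @export
run_pipeline <- function(config, out_dir, session = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(session)) session <- simulate_session(config$generator)
  validate_session(session)
  write_session(session, file.path(out_dir, "session"))

  tt <- build_tuning_table(session, config$windows)
  utils::write.csv(tt$responses, file.path(out_dir, "responses.csv"),
                   row.names = FALSE)
  utils::write.csv(tt$calls, file.path(out_dir, "tuning.csv"),
                   row.names = FALSE)
  utils::write.csv(tt$cells, file.path(out_dir, "cells.csv"),
                   row.names = FALSE)

  classification <- NULL
  if (!is.null(config$categories) && sum(tt$cells$included) > 0) {
    classification <- classify_tuning(tt, config$categories)
    utils::write.csv(classification, file.path(out_dir, "categories.csv"),
                     row.names = FALSE)
  }

  clustering <- NULL; mds <- NULL
  tm <- tuning_matrix(tt)
  if (nrow(tm) >= 2) {
    cl <- config$clustering
    clustering <- consensus_cluster(tm, n_runs = cl$n_runs %||% 500,
                                    k_range = cl$k_range %||% 2:12,
                                    bandwidth = cl$bandwidth,
                                    quantile = cl$quantile %||% 0.3,
                                    seed = config$seed + 1L)
    utils::write.csv(data.frame(cell_id = rownames(tm),
                                cluster = clustering$labels),
                     file.path(out_dir, "clusters.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(clustering$similarity),
                     file.path(out_dir, "similarity.csv"), row.names = FALSE)
    mds <- mds_embed(clustering$similarity, dims = 3,
                     seed = config$seed + 2L)
    mdf <- as.data.frame(mds$points)
    names(mdf) <- paste0("dim", seq_len(ncol(mdf)))
    mdf <- cbind(cell_id = rownames(tm), mdf)
    utils::write.csv(mdf, file.path(out_dir, "mds.csv"), row.names = FALSE)
  }

  shuffle <- NULL
  if (!is.null(config$shuffle) && sum(tt$cells$included) >= 2) {
    sh <- config$shuffle
    ts <- trial_sets(tt, sh$stim_a, sh$stim_b,
                     normalized = sh$normalized %||% TRUE)
    shuffle <- shuffle_test(ts$trials_a, ts$trials_b,
                            n_model = sh$n_model %||% 100000,
                            seed = config$seed + 3L,
                            mode = sh$mode %||% "trial_sets")
    utils::write.csv(data.frame(cell_id = names(shuffle$observed),
                                dprime = shuffle$observed),
                     file.path(out_dir, "dprime.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(stim_a = sh$stim_a, stim_b = sh$stim_b,
           n_model = shuffle$n_model, mode = shuffle$mode,
           seed = shuffle$seed,
           observed_median_dprime = shuffle$observed_median,
           fraction_lower = shuffle$fraction_lower),
      file.path(out_dir, "shuffle_summary.json"),
      auto_unbox = TRUE, digits = NA)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("aobtune")),
    seed = config$seed,
    generator_seed = config$generator$seed,
    n_cells = config$generator$n_cells,
    n_included = sum(tt$cells$included),
    stages = c("simulate/ingest", "response_analysis",
               if (!is.null(classification)) "classification",
               if (!is.null(clustering)) "consensus_clustering",
               if (!is.null(shuffle)) "discrimination"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(session = session, tuning = tt,
                 classification = classification, clustering = clustering,
                 mds = mds, shuffle = shuffle, out_dir = out_dir))
}

#' Plot a peristimulus time histogram
#'
#' Base-graphics step plot of the trial-averaged rate with an s.e.m. band
#' and the stimulus onset marked.
#'
#' @param x an `aob_psth`
#' @param main plot title
#' @param ... passed to [plot()]
#' @export
plot.aob_psth <- function(x, main = "PSTH", ...) {
  t_mid <- x$t_left + x$bin_s / 2
  ylim <- c(0, max(x$rate + ifelse(is.na(x$sem), 0, x$sem)) * 1.1 + 1e-9)
  plot(t_mid, x$rate, type = "s", xlab = "time from onset (s)",
       ylab = "rate (Hz)", ylim = ylim, main = main, ...)
  if (!all(is.na(x$sem))) {
    graphics::arrows(t_mid, pmax(0, x$rate - x$sem), t_mid, x$rate + x$sem,
                     angle = 90, code = 3, length = 0.02, col = "grey50")
  }
  graphics::abline(v = 0, lty = 2, col = "red")
  invisible(x)
}
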