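#' Tuning-category classification
#'
#' Partitions cells into categories defined by named stimulus sets: for two
#' sets A and B, the categories are exclusive-A ("A_only": responds to at
#' least one stimulus in A and none in B), exclusive-B, "A+B" (responds to
#' both sets), and "other" (responds to neither, i.e. only to stimuli outside
#' the sets). Generalizes to three or more sets with one category per
#' observed combination. Percentages are reported to one decimal,
#' round-half-away-from-zero.
#'
#' @param responsive logical matrix (cells x stimuli, column names =
#'   stimulus ids) or a `tuning_table` (included cells are used)
#' @param sets named list of character vectors of stimulus ids; sets must be
#'   disjoint and present in the matrix
#' @param other_label label for cells responding to none of the sets
#' @return data frame (category, n, pct); counts partition the cells
#' @export
classify_tuning <- function(responsive, sets, other_label = "other") {
  x <- as_response_matrix(responsive)
  if (nrow(x) == 0) stop_validation("empty response table")
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop_validation("sets must be named")
  all_ids <- unlist(sets)
  if (anyDuplicated(all_ids)) stop_validation("stimulus sets must be disjoint")
  missing <- setdiff(all_ids, colnames(x))
  if (length(missing))
    stop_validation("stimuli absent from table: %s",
                    paste(missing, collapse = ", "))
  hit <- vapply(sets, function(ids)
    apply(x[, ids, drop = FALSE], 1, any), logical(nrow(x)))
  hit <- matrix(hit, nrow = nrow(x), dimnames = list(NULL, names(sets)))
  lab <- apply(hit, 1, function(h) {
    w <- names(sets)[h]
    if (length(w) == 0) other_label
    else if (length(w) == 1) paste0(w, "_only")
    else paste(w, collapse = "+")
  })
  # stable category order: singles, then combos in first-appearance order, other last
  singles <- paste0(names(sets), "_only")
  combos <- setdiff(unique(lab), c(singles, other_label))
  levels <- c(singles, combos, other_label)
  n <- vapply(levels, function(l) sum(lab == l), integer(1))
  data.frame(category = levels, n = as.integer(n),
             pct = round_half_up(100 * n / nrow(x), 1),
             row.names = NULL, stringsAsFactors = FALSE)
}

as_response_matrix <- function(x) {
  if (inherits(x, "tuning_table")) x <- response_matrix(x)
  if (!is.matrix(x) || !is.logical(x))
    stop_validation("expected a logical response matrix or tuning_table")
  x
}

#' Venn-region counts of response overlap
#'
#' Among cells responding to at least one of the listed stimuli, counts
#' every response-pattern region (e.g. for stimuli a, b: "a", "b", "a&b").
#'
#' @param responsive logical matrix or `tuning_table`
#' @param stimuli 2 or 3 stimulus ids
#' @return named integer vector of region counts, plus attribute
#'   `n_responders`
#' @export
overlap_venn <- function(responsive, stimuli) {
  x <- as_response_matrix(responsive)
  if (length(stimuli) < 2 || length(stimuli) > 3)
    stop_validation("overlap_venn takes 2 or 3 stimuli")
  missing <- setdiff(stimuli, colnames(x))
  if (length(missing))
    stop_validation("stimuli absent from table: %s",
                    paste(missing, collapse = ", "))
  sub <- x[, stimuli, drop = FALSE]
  sub <- sub[apply(sub, 1, any), , drop = FALSE]
  regions <- lapply(seq_along(stimuli), function(k)
    utils::combn(stimuli, k, simplify = FALSE))
  regions <- unlist(regions, recursive = FALSE)
  counts <- vapply(regions, function(r) {
    sum(apply(sub, 1, function(row)
      all(row[r]) && !any(row[setdiff(stimuli, r)])))
  }, integer(1))
  names(counts) <- vapply(regions, paste, character(1), collapse = "&")
  attr(counts, "n_responders") <- nrow(sub)
  counts
}

#' Pairwise co-response percentage matrix
#'
#' Entry (r, c) is 100 x (number of cells significantly responding to both
#' r and c) / (number of cells responding to r, the row stimulus). The
#' diagonal is 100 by construction. Rows whose stimulus has zero responders
#' are undefined and reported as NA, not 0.
#'
#' @param responsive logical matrix or `tuning_table`
#' @param stimuli stimulus ids (default: all columns)
#' @return numeric percentage matrix
#' @export
pairwise_overlap <- function(responsive, stimuli = NULL) {
  x <- as_response_matrix(responsive)
  if (is.null(stimuli)) stimuli <- colnames(x)
  missing <- setdiff(stimuli, colnames(x))
  if (length(missing))
    stop_validation("stimuli absent from table: %s",
                    paste(missing, collapse = ", "))
  sub <- x[, stimuli, drop = FALSE]
  both <- crossprod(sub)  # co-responder counts
  n_r <- diag(both)
  out <- 100 * both / n_r  # rows scaled by row-stimulus responders
  out[n_r == 0, ] <- NA_real_
  dimnames(out) <- list(stimuli, stimuli)
  out
}

#' Consensus clustering of tuning curves
#'
#' Builds a cell-by-cell similarity matrix from many non-deterministic base
#' clusterings and extracts the final partition by mean-shift clustering of
#' the similarity-matrix rows. Each base run draws a random subsample of the
#' cells (fraction `subsample`) and clusters it by k-means with random
#' initialization and k drawn uniformly from `k_range`; similarity(i, j) is
#' the fraction of co-sampled runs that co-assign cells i and j. The
#' subsampling perturbation keeps repeated runs from resolving the same
#' noise-level splits deterministically, which would depress within-cluster
#' similarity.
#'
#' @param x numeric matrix, rows = cells (normalized tuning curves in
#'   `[-1, 1]`)
#' @param n_runs number of base clusterings (>= 100 recommended; default 500)
#' @param k_range candidate k values for the base k-means (default 2:12).
#'   Values are additionally capped at `max(2, n/4)` so base clusters keep
#'   a handful of cells each, and at the number of distinct rows.
#' @param subsample fraction of cells entering each base run (default 0.8)
#' @param bandwidth mean-shift bandwidth on similarity rows; `NULL` (default)
#'   estimates it with [estimate_bandwidth()]
#' @param bandwidth_method heuristic for the estimate (default `"gap"`)
#' @param quantile quantile for the `"quantile"` heuristic (default 0.3)
#' @param seed integer seed; the whole procedure is deterministic given it
#' @return object of class `consensus_clustering`: list with `labels`
#'   (integer cluster per cell, 1-based, ordered by decreasing cluster
#'   size), `similarity` (symmetric matrix, unit diagonal), `n_clusters`,
#'   `bandwidth`, `n_runs`, `seed`
#' @export
consensus_cluster <- function(x, n_runs = 500, k_range = 2:12,
                              subsample = 0.8, bandwidth = NULL,
                              bandwidth_method = c("gap", "quantile"),
                              quantile = 0.3, seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2) {
    warning("fewer than 2 cells: returning a single cluster")
    return(structure(list(labels = rep(1L, n),
                          similarity = matrix(1, n, n),
                          n_clusters = min(n, 1L), bandwidth = NA_real_,
                          n_runs = 0L, seed = seed),
                     class = "consensus_clustering"))
  }
  set.seed(seed)
  distinct <- nrow(unique(x))
  co <- matrix(0, n, n)
  inc <- matrix(0, n, n)
  if (distinct < 2) {
    co[] <- 1; inc[] <- 1  # all rows identical: everything co-assigns
  } else {
    kr <- k_range[k_range <= max(2, floor(n / 4))]
    if (!length(kr)) kr <- 2L
    ks <- sample(rep_len(kr, max(length(kr), 2L)), n_runs, replace = TRUE)
    n_sub <- max(3L, min(n, round(subsample * n)))
    for (r in seq_len(n_runs)) {
      idx <- sort(sample.int(n, n_sub))
      xs <- x[idx, , drop = FALSE]
      k <- min(ks[r], nrow(unique(xs)))
      km <- tryCatch(
        stats::kmeans(xs, centers = k, nstart = 1, iter.max = 50),
        error = function(e)
          stats::kmeans(xs, centers = max(1, k - 1), nstart = 1,
                        iter.max = 50))
      inc[idx, idx] <- inc[idx, idx] + 1
      for (g in seq_len(max(km$cluster))) {
        ii <- idx[km$cluster == g]
        co[ii, ii] <- co[ii, ii] + 1
      }
    }
  }
  sim <- ifelse(inc > 0, co / pmax(inc, 1), 0)
  sim <- (sim + t(sim)) / 2  # exact symmetry against float asymmetries
  diag(sim) <- 1
  ms <- mean_shift(sim, bandwidth = bandwidth, method = bandwidth_method,
                   quantile = quantile)
  structure(list(labels = ms$labels, similarity = sim,
                 n_clusters = max(ms$labels), bandwidth = ms$bandwidth,
                 n_runs = n_runs, seed = seed),
            class = "consensus_clustering")
}

#' @export
print.consensus_clustering <- function(x, ...) {
  cat(sprintf("<consensus_clustering> %d cells -> %d clusters (%d runs, bandwidth %.3g)\n",
              length(x$labels), x$n_clusters, x$n_runs, x$bandwidth))
  invisible(x)
}

#' Bandwidth heuristic for mean shift
#'
#' Two estimators. `"gap"` (default) targets the bimodal distance structure
#' of consensus similarity rows — small within-cluster distances, large
#' between-cluster distances — by placing the bandwidth at the midpoint of
#' the largest gap in the sorted pairwise-distance distribution (tails
#' trimmed to the central 5-95% so outliers cannot capture the gap).
#' `"quantile"` is the k-nearest-neighbour heuristic: mean over points of
#' the distance to their k-th nearest neighbour, k =
#' `max(1, floor(quantile * n))`; it assumes a unimodal distance spread and
#' can exceed the between-cluster separation when clusters hold fewer than
#' `quantile * n` points each.
#'
#' @param x numeric matrix of points (rows)
#' @param method `"gap"` (default) or `"quantile"`
#' @param quantile for the k-NN heuristic, in (0, 1], default 0.3
#' @return bandwidth (0 if all points coincide)
#' @export
estimate_bandwidth <- function(x, method = c("gap", "quantile"),
                               quantile = 0.3) {
  method <- match.arg(method)
  n <- nrow(x)
  if (n < 2) return(0)
  d <- stats::dist(x)
  if (max(d) == 0) return(0)
  if (method == "quantile") {
    dm <- as.matrix(d)
    k <- max(1L, min(n - 1L, floor(quantile * n)))
    knd <- apply(dm, 1, function(row) sort(row[-which.min(row)])[k])
    return(mean(knd))
  }
  v <- sort(as.numeric(d))
  m <- length(v)
  if (m == 1) return(v / 2)
  lo <- max(1L, ceiling(0.05 * m))
  hi <- min(m, floor(0.95 * m))
  if (hi <= lo) { lo <- 1L; hi <- m }
  gaps <- diff(v[lo:hi])
  if (!length(gaps) || max(gaps) == 0) return(stats::median(v))
  i <- which.max(gaps)
  (v[lo + i - 1] + v[lo + i]) / 2
}

#' Flat-kernel mean-shift clustering
#'
#' Each point is iteratively shifted to the mean of all points within
#' `bandwidth` of its current position until convergence; converged modes
#' closer than the bandwidth are merged (strongest window first) and points
#' are assigned to the nearest surviving mode. Deterministic.
#'
#' @param x numeric matrix of points (rows)
#' @param bandwidth window radius; `NULL` uses [estimate_bandwidth()]
#' @param method,quantile passed to the bandwidth heuristic
#' @param max_iter,tol iteration controls
#' @return list: `labels` (1-based, ordered by decreasing cluster size),
#'   `modes` (matrix of cluster modes), `bandwidth`
#' @export
mean_shift <- function(x, bandwidth = NULL, method = c("gap", "quantile"),
                       quantile = 0.3, max_iter = 300, tol = 1e-6) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (is.null(bandwidth))
    bandwidth <- estimate_bandwidth(x, method = method, quantile = quantile)
  if (n < 2 || bandwidth <= 0)
    return(list(labels = rep(1L, n), modes = x[1, , drop = FALSE],
                bandwidth = bandwidth))
  h2 <- bandwidth^2
  modes <- x
  for (i in seq_len(n)) {
    m <- x[i, ]
    for (it in seq_len(max_iter)) {
      d2 <- colSums((t(x) - m)^2)
      inside <- d2 <= h2
      new_m <- colMeans(x[inside, , drop = FALSE])
      if (sum((new_m - m)^2) < tol^2) { m <- new_m; break }
      m <- new_m
    }
    modes[i, ] <- m
  }
  # merge modes within one bandwidth, strongest (most populated window) first
  support <- vapply(seq_len(n), function(i)
    sum(colSums((t(x) - modes[i, ])^2) <= h2), integer(1))
  ord <- order(support, decreasing = TRUE)
  kept <- integer(0)
  assign_mode <- integer(n)
  for (i in ord) {
    if (length(kept)) {
      d2k <- vapply(kept, function(j) sum((modes[i, ] - modes[j, ])^2),
                    numeric(1))
      j <- kept[which.min(d2k)]
      if (min(d2k) <= h2) { assign_mode[i] <- j; next }
    }
    kept <- c(kept, i)
    assign_mode[i] <- i
  }
  centers <- modes[kept, , drop = FALSE]
  # assign every point to the nearest surviving mode
  lab <- apply(x, 1, function(p)
    which.min(colSums((t(centers) - p)^2)))
  # relabel by decreasing cluster size (ties: first occurrence)
  sizes <- tabulate(lab, nbins = nrow(centers))
  new_id <- integer(nrow(centers))
  new_id[order(sizes, decreasing = TRUE)] <- seq_len(nrow(centers))
  lab <- new_id[lab]
  used <- sort(unique(lab))
  lab <- match(lab, used)  # contiguous labels
  list(labels = as.integer(lab),
       modes = centers[order(new_id)[used], , drop = FALSE],
       bandwidth = bandwidth)
}

#' Nonmetric MDS embedding of a similarity matrix
#'
#' Embeds cells by nonmetric (Kruskal) multidimensional scaling of the
#' dissimilarity `1 - similarity`, for 3-D visualization of tuning
#' differences between clusters.
#'
#' @param similarity symmetric similarity matrix in `[0, 1]`, unit diagonal
#' @param dims embedding dimension (default 3)
#' @param seed seed (the embedding is deterministic; kept for the interface
#'   contract)
#' @return list: `points` (n x dims coordinates), `stress` (Kruskal stress,
#'   percent)
#' @export
mds_embed <- function(similarity, dims = 3, seed = 1L) {
  s <- as.matrix(similarity)
  n <- nrow(s)
  if (n == 1)
    return(list(points = matrix(0, 1, dims), stress = 0))
  d <- 1 - s
  diag(d) <- 0
  off <- d[upper.tri(d)]
  if (max(off) - min(off) < 1e-12) {
    warning("degenerate (all-equal) dissimilarities: zero-spread embedding")
    return(list(points = matrix(0, n, dims), stress = 0))
  }
  d[d <= 0 & row(d) != col(d)] <- 1e-8  # isoMDS rejects zero off-diagonals
  set.seed(seed)
  init <- stats::cmdscale(d, k = min(dims, n - 1))
  if (ncol(init) < dims)
    init <- cbind(init, matrix(0, n, dims - ncol(init)))
  fit <- MASS::isoMDS(stats::as.dist(d), y = init, k = dims, trace = FALSE)
  list(points = fit$points, stress = fit$stress)
}
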