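test_that("tuning classification reproduces worked compositions", {
  stims <- c("urine", "faeces", "other_stim")
  sets <- list(urine = "urine", faeces = "faeces")

  # 55 responders: 19 faeces-only / 22 urine-only / 14 both
  m <- region_matrix(list(faeces = 19, urine = 22, `urine+faeces` = 14), stims)
  cl <- classify_tuning(m, sets)
  expect_equal(cl$pct[cl$category == "faeces_only"], 34.5)
  expect_equal(cl$pct[cl$category == "urine_only"], 40.0)
  expect_equal(cl$pct[cl$category == "urine+faeces"], 25.5)

  # everyone responds to everything: 100% both
  all_m <- matrix(TRUE, 10, 2, dimnames = list(NULL, c("urine", "faeces")))
  cl <- classify_tuning(all_m, sets)
  expect_equal(cl$pct[cl$category == "urine+faeces"], 100)
  expect_equal(sum(cl$n), 10)

  # 20-cell bile-acid fixture: 7 DCA-only of 20 -> 35.0%
  m <- region_matrix(list(ca = 2, dca = 7, faeces = 7, `ca+dca+faeces` = 3,
                          `ca+faeces` = 1),
                     c("ca", "dca", "faeces", "other_stim"))
  cl <- classify_tuning(m, list(ca = "ca", dca = "dca", faeces = "faeces"))
  expect_equal(cl$pct[cl$category == "dca_only"], 35.0)
  expect_equal(cl$pct[cl$category == "ca_only"], 10.0)
})

test_that("classification partitions cells and percentages sum to 100", {
  for (i in 1:20) {
    set.seed(i)
    m <- matrix(runif(40 * 3) < 0.4, 40, 3,
                dimnames = list(NULL, c("a", "b", "c")))
    cl <- classify_tuning(m, list(a = "a", b = "b"))
    expect_equal(sum(cl$n), 40)
    expect_lt(abs(sum(cl$pct) - 100), 0.2)  # rounding slack
  }
  expect_error(classify_tuning(matrix(TRUE, 0, 2,
                                      dimnames = list(NULL, c("a", "b"))),
                               list(a = "a")),
               class = "aobtune_validation_error")
  m <- matrix(TRUE, 2, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(classify_tuning(m, list(x = "a", y = c("a", "b"))),
               class = "aobtune_validation_error")
})

test_that("venn regions count response patterns among responders", {
  stims <- c("urine", "faeces", "other_stim")
  # disjoint responders: zero intersection
  m <- region_matrix(list(urine = 5, faeces = 4), stims)
  v <- overlap_venn(m, c("urine", "faeces"))
  expect_equal(unname(v["urine&faeces"]), 0L)

  # 29-cell fixture 10/6/13
  m <- region_matrix(list(female_faeces = 10, male_faeces = 6,
                          `female_faeces+male_faeces` = 13),
                     c("female_faeces", "male_faeces", "other_stim"))
  v <- overlap_venn(m, c("female_faeces", "male_faeces"))
  expect_equal(unname(v[c("female_faeces", "male_faeces",
                          "female_faeces&male_faeces")]), c(10L, 6L, 13L))
  expect_equal(attr(v, "n_responders"), 29L)

  # three sets with a single triple responder in the centre
  m <- region_matrix(list(a = 3, b = 2, c = 2, `a+b+c` = 1),
                     c("a", "b", "c", "other_stim"))
  v <- overlap_venn(m, c("a", "b", "c"))
  expect_equal(unname(v["a&b&c"]), 1L)

  expect_error(overlap_venn(m, c("a", "zz")),
               class = "aobtune_validation_error")
})

test_that("pairwise overlap equals brute-force set intersection", {
  m <- region_matrix(list(ca = 4, dca = 3, `ca+dca` = 2),
                     c("ca", "dca", "lca", "other_stim"))
  po <- pairwise_overlap(m, c("ca", "dca", "lca"))
  expect_equal(unname(diag(po)[1:2]), c(100, 100))
  # no cell responds to both ca and lca: mutual exclusivity reads 0%
  expect_equal(unname(po["ca", "dca"]), 100 * 2 / 6)
  expect_equal(unname(po["ca", "lca"]), 0)
  # zero-responder row is missing, not 0
  expect_true(all(is.na(po["lca", ])))

  for (i in 1:100) {
    set.seed(i)
    m <- matrix(runif(30 * 4) < 0.35, 30, 4,
                dimnames = list(sprintf("c%02d", 1:30), c("w", "x", "y", "z")))
    expect_equal(pairwise_overlap(m), bf_pairwise(m, colnames(m)),
                 tolerance = 1e-12)
  }
})

test_that("consensus clustering recovers two planted archetypes exactly", {
  skip_if_not_installed("mclust")
  set.seed(42)
  arch <- rbind(c(1, 0, 0, 0.1), c(0, 1, 0.1, 0))
  truth <- rep(1:2, each = 10)
  x <- arch[truth, ] + matrix(rnorm(20 * 4, sd = 0.05), 20, 4)
  cc <- consensus_cluster(x, n_runs = 200, seed = 9)
  expect_equal(cc$n_clusters, 2)
  expect_equal(mclust::adjustedRandIndex(cc$labels, truth), 1)
})

test_that("consensus clustering handles degenerate and repeated input", {
  x <- matrix(1, 6, 3)
  cc <- consensus_cluster(x, n_runs = 100, seed = 1)
  expect_equal(cc$n_clusters, 1)
  expect_true(all(cc$similarity == 1))

  set.seed(3)
  x <- matrix(rnorm(24), 8, 3)
  c1 <- consensus_cluster(x, n_runs = 150, seed = 5)
  c2 <- consensus_cluster(x, n_runs = 150, seed = 5)
  expect_identical(c1$labels, c2$labels)
  expect_identical(c1$similarity, c2$similarity)

  expect_warning(cc <- consensus_cluster(x[1, , drop = FALSE]),
                 "single cluster")
  expect_equal(cc$labels, 1L)
})

test_that("similarity matrices are symmetric with unit diagonal in [0,1]", {
  for (sd in 1:5) {
    set.seed(sd)
    x <- matrix(rnorm(15 * 3), 15, 3)
    cc <- consensus_cluster(x, n_runs = 120, seed = sd)
    s <- cc$similarity
    expect_equal(s, t(s))
    expect_equal(unname(diag(s)), rep(1, 15))
    expect_true(all(s >= 0 & s <= 1))
    expect_equal(sort(unique(cc$labels)), seq_len(cc$n_clusters))
  }
})

test_that("mean shift finds the modes of well-separated point clouds", {
  set.seed(6)
  x <- rbind(matrix(rnorm(30, mean = 0, sd = 0.1), 15, 2),
             matrix(rnorm(30, mean = 3, sd = 0.1), 15, 2))
  ms <- mean_shift(x)
  expect_equal(max(ms$labels), 2)
  expect_equal(ms$labels[1:15], rep(ms$labels[1], 15))
  expect_equal(ms$labels[16:30], rep(ms$labels[16], 15))
})

test_that("MDS embedding separates planted groups and preserves order", {
  # two tight groups in similarity space
  s <- matrix(0.1, 10, 10)
  s[1:5, 1:5] <- 0.9; s[6:10, 6:10] <- 0.9
  diag(s) <- 1
  e <- mds_embed(s, dims = 3)
  d <- as.matrix(dist(e$points))
  within <- c(d[1:5, 1:5][upper.tri(d[1:5, 1:5])],
              d[6:10, 6:10][upper.tri(d[6:10, 6:10])])
  between <- d[1:5, 6:10]
  expect_gt(min(between), max(within))

  # single cell: a point at the origin
  e1 <- mds_embed(matrix(1, 1, 1))
  expect_equal(e1$points, matrix(0, 1, 3))

  # 4-point toy: embedding distances monotone in dissimilarities
  s4 <- matrix(c(1, .9, .5, .2,
                 .9, 1, .6, .3,
                 .5, .6, 1, .8,
                 .2, .3, .8, 1), 4, 4)
  e4 <- mds_embed(s4, dims = 2)
  d4 <- as.matrix(dist(e4$points))
  ut <- upper.tri(d4)
  rho <- cor(d4[ut], (1 - s4)[ut], method = "spearman")
  expect_gt(rho, 0.9)

  expect_warning(ez <- mds_embed(matrix(0.5, 3, 3) + diag(0.5, 3)),
                 "degenerate")
  expect_equal(ez$points, matrix(0, 3, 3))
})
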