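test_that("kmeans within-dispersion follows the pairwise formula and shrinks with k", {
  set.seed(10)
  pts <- matrix(rnorm(40), 20, 2)

  # k = 1: no partition freedom; W = D / (2n) with D the full (both
  # directions) sum of pairwise squared distances
  w1 <- kmeans_fit(pts, 1)$W
  d2 <- as.matrix(dist(pts))^2
  expect_equal(w1, sum(d2) / (2 * nrow(pts)), tolerance = 1e-9)

  # pairwise form equals the fitted dispersion for any k
  fit3 <- kmeans_fit(pts, 3, seed = 2)
  w_pair <- 0
  for (g in unique(fit3$labels)) {
    idx <- fit3$labels == g
    w_pair <- w_pair + sum(d2[idx, idx]) / (2 * sum(idx))
  }
  expect_equal(fit3$W, w_pair, tolerance = 1e-9)

  # two far-separated pairs are recovered exactly
  far <- rbind(c(0, 0), c(0.1, 0), c(50, 50), c(50.1, 50))
  lab <- kmeans_fit(far, 2, seed = 1)$labels
  expect_identical(lab[1], lab[2])
  expect_identical(lab[3], lab[4])
  expect_false(lab[1] == lab[3])

  # W_k non-increasing in k
  ws <- vapply(1:6, function(k) kmeans_fit(pts, k, n_restarts = 10, seed = 3)$W,
               numeric(1))
  expect_true(all(diff(ws) <= 1e-9))

  expect_error(kmeans_fit(pts, 21), "exceeds")
})

test_that("gap statistic recovers trivial and planted cluster structure", {
  set.seed(20)
  blob <- matrix(rnorm(80, sd = 0.05), 40, 2)
  g1 <- gap_statistic(blob, k_max = 5, B = 50, n_restarts = 10, seed = 1)
  expect_identical(g1$k_hat, 1L)
  expect_equal(g1$gap, g1$E_logW - g1$logW, tolerance = 1e-12)
  expect_true(all(g1$se > 0))

  centers <- rbind(c(0, 0), c(2, 0), c(1, 2))
  pts <- do.call(rbind, lapply(1:3, function(i)
    sweep(matrix(rnorm(60, sd = 0.05), 30, 2), 2, centers[i, ], "+")))
  g3 <- gap_statistic(pts, k_max = 6, B = 50, n_restarts = 10, seed = 2)
  expect_identical(g3$k_hat, 3L)

  flat <- matrix(1, 10, 3)
  expect_warning(gd <- gap_statistic(flat, k_max = 4, B = 20), "degenerate")
  expect_identical(gd$k_hat, 1L)
})

test_that("observed log-dispersion matches clusGap on well-separated data", {
  centers <- rbind(c(0, 0), c(5, 5))
  set.seed(33)
  pts <- do.call(rbind, lapply(1:2, function(i)
    sweep(matrix(rnorm(40, sd = 0.1), 20, 2), 2, centers[i, ], "+")))
  ours <- gap_statistic(pts, k_max = 3, B = 20, n_restarts = 20, seed = 4)
  cg <- cluster::clusGap(pts, kmeans, K.max = 3, B = 20, d.power = 2,
                         nstart = 20, iter.max = 100, verbose = FALSE)
  # clusGap halves the pooled dispersion (single-counted pairs), a constant
  # log(2) offset that cancels in the gap itself
  expect_equal(ours$logW, cg$Tab[, "logW"] + log(2), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("hierarchical clustering matches a naive complete-linkage oracle", {
  d3 <- matrix(c(0, 0.1, 0.9, 0.1, 0, 0.9, 0.9, 0.9, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  hc3 <- hierarchical_cluster(distance_matrix(d3))
  expect_equal(hc3$height, c(0.1, 0.9))
  first_merge <- rownames(d3)[-hc3$merge[1, ]]
  expect_setequal(first_merge, c("A", "B"))

  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  hc2 <- hierarchical_cluster(distance_matrix(d2))
  expect_equal(hc2$height, 0.4)

  set.seed(44)
  for (rep in 1:10) {
    d <- random_distance(6)
    hc <- hierarchical_cluster(distance_matrix(d))
    expect_equal(sort(hc$height), sort(oracle_complete_linkage_heights(d)),
                 tolerance = 1e-12)
  }

  one <- matrix(0, 1, 1, dimnames = list("a", "a"))
  expect_error(hierarchical_cluster(distance_matrix(one)), "at least 2")
})

test_that("dendrograms export as parseable Newick with the sample leaves", {
  d <- random_distance(5, seed = 50)
  hc <- hierarchical_cluster(distance_matrix(d))
  nwk <- dendrogram_newick(hc)
  tre <- ape::read.tree(text = nwk)
  expect_setequal(tre$tip.label, rownames(d))
})

test_that("CST rules map dominant taxa to types and sub-clusters", {
  tab <- cst_fixture_table()
  res <- assign_cst(tab)
  expect_identical(setNames(res$cst, res$sample_id),
                   c(crisp = "I", gasse = "II", iners = "III", jense = "V",
                     strep = "IV", gard = "IV", dive = "IV"))
  expect_identical(setNames(res$subcluster, res$sample_id)[c("strep", "gard", "dive")],
                   c(strep = "IV-Streptococcus", gard = "IV-Gardnerella",
                     dive = "IV-diverse"))
  expect_identical(res$subcluster[res$cst != "IV"], rep("none", 4))

  # dominance is a genus-level call: all Lactobacillus species summed
  expect_true(res$lactobacillus_dominant[res$sample_id == "crisp"])
  expect_false(res$lactobacillus_dominant[res$sample_id == "strep"])  # 0.34 < 0.50
  lac <- rowSums(unclass(tab)[, grepl("^Lactobacillus", colnames(tab))])
  other_max <- apply(unclass(tab)[, !grepl("^Lactobacillus", colnames(tab))], 1, max)
  expect_identical(unname(res$lactobacillus_dominant), unname(lac > other_max))

  # CSTs partition the samples
  expect_identical(sum(table(res$cst)), nrow(tab))

  # scale invariance in counts mode
  cnt <- make_counts_table(rbind(c(10, 1, 2, 1, 3, 1, 2, 1)),
                           taxa = colnames(tab))
  scaled <- make_counts_table(unclass(cnt) * 17, taxa = colnames(tab))
  expect_identical(assign_cst(cnt)$cst, assign_cst(scaled)$cst)

  bad <- make_counts_table(matrix(1:4, 1), taxa = paste0("G", 1:4))
  expect_error(assign_cst(bad), "Lactobacillus_crispatus")
})

test_that("dominance summaries cross-tabulate and test group differences", {
  tab <- cst_fixture_table()
  res <- assign_cst(tab)
  meta <- data.frame(sample_id = res$sample_id,
                     group = c("NSW", "NSW", "NSW", "FSW", "FSW", "FSW", "FSW"))
  out <- dominance_summary(res, meta)
  expect_identical(sum(out$dominance_table), 7L)
  expect_identical(sum(out$cst_table), 7L)
  expect_true(out$dominance_test$p_value >= 0 && out$dominance_test$p_value <= 1)

  # all dominant: proportions 1, p = 1
  all_dom <- res
  all_dom$lactobacillus_dominant <- TRUE
  out2 <- dominance_summary(all_dom, meta)
  expect_true(all(vapply(out2$dominance_proportions, `[[`, 1, "proportion") == 1))
  expect_equal(out2$dominance_test$p_value, 1)
})

test_that("categorical test reproduces the study's dominance contrast", {
  tab <- matrix(c(11, 8, 8, 40), 2, byrow = TRUE)
  res <- categorical_test(tab)
  expect_identical(res$test, "Fisher exact")
  expect_equal(res$p_value, 0.002, tolerance = 0.1)  # prints as 0.002

  big <- matrix(c(30, 40, 35, 45, 50, 20), 2, byrow = TRUE)
  expect_identical(categorical_test(big)$test, "chi-square (Yates)")
  small <- matrix(c(2, 3, 1, 9, 8, 2), 2, byrow = TRUE)
  expect_identical(categorical_test(small)$test, "Fisher exact")
})
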