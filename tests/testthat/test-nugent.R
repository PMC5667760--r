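test_that("nugent rubric scores the canonical slides", {
  expect_equal(nugent_score(4, 0, 0)$score, 0)
  expect_identical(nugent_score(4, 0, 0)$category, "0-3")
  expect_equal(nugent_score(0, 4, 4)$score, 10)
  expect_identical(nugent_score(0, 4, 4)$category, "7-10")
  expect_equal(nugent_score(2, 2, 1)$score, 5)
  expect_identical(nugent_score(2, 2, 1)$category, "4-6")

  expect_error(nugent_score(5, 0, 0), "\\[0, 4\\]")
  expect_error(nugent_score(1, -1, 0), "\\[0, 4\\]")
  expect_error(nugent_score(1, 0.5, 0), "\\[0, 4\\]")
})

test_that("nugent score matches the exhaustive 125-entry rubric table", {
  grid <- oracle_nugent_table()
  res <- nugent_score(grid$lacto, grid$gv, grid$curved)
  expect_identical(res$score, as.integer(grid$score))
  expect_identical(res$score,
                   res$lacto_points + res$gv_points + res$curved_points)
  expect_true(all(res$score >= 0 & res$score <= 10))
  expect_identical(res$category, nugent_category(res$score))
  # category boundaries exactly 0-3 / 4-6 / 7-10
  expect_identical(unique(res$category[res$score <= 3]), "0-3")
  expect_identical(unique(res$category[res$score %in% 4:6]), "4-6")
  expect_identical(unique(res$category[res$score >= 7]), "7-10")
})

test_that("morphotype observation thresholds select the present classes", {
  expect_length(morphotype_classes_observed(0, 0, 0), 0)
  expect_identical(morphotype_classes_observed(4, 2, 0),
                   c("Lactobacillus", "GV_Bacteroides"))
  expect_identical(morphotype_classes_observed(0, 0, 3), "Mobiluncus")
  expect_identical(morphotype_classes_observed(1, 1, 1, threshold = 2),
                   character(0))
  expect_error(morphotype_classes_observed(1, 1, 1, threshold = 0), ">= 1")
})

test_that("complete agreement follows the top-5 coverage rule", {
  # empty observed set: vacuous agreement
  a0 <- agreement(character(0), c("Lactobacillus", "Gardnerella"))
  expect_true(a0$complete_agreement)
  expect_true(a0$vacuous)

  a1 <- agreement(c("Lactobacillus", "GV_Bacteroides"),
                  c("Lactobacillus", "Gardnerella", "Prevotella", "Sneathia",
                    "Atopobium"))
  expect_true(a1$complete_agreement)
  expect_false(a1$vacuous)

  # BVAB1 is not mapped to Mobiluncus by default: curved rods go unmatched
  a2 <- agreement("Mobiluncus",
                  c("BVAB1", "Prevotella", "Sneathia", "Gardnerella",
                    "Megasphaera"))
  expect_false(a2$complete_agreement)

  # ...unless the map is recalibrated to treat BVAB1 as a curved rod
  a3 <- agreement("Mobiluncus", c("BVAB1", "Prevotella"),
                  genus_map = c(default_morphotype_map(), BVAB1 = "Mobiluncus"))
  expect_true(a3$complete_agreement)

  # species calls reduce to their genus before mapping
  a4 <- agreement("Lactobacillus", c("Lactobacillus_iners", "Gardnerella"))
  expect_true(a4$complete_agreement)

  expect_warning(a5 <- agreement("Lactobacillus", character(0)), "empty top-5")
  expect_false(a5$complete_agreement)
  expect_error(agreement("NotAClass", "Lactobacillus"), "unknown morphotype")
})

test_that("agreement is monotone in the top-5 list", {
  set.seed(60)
  genera <- c("Lactobacillus", "Gardnerella", "Prevotella", "Mobiluncus",
              "Sneathia", "BVAB1", "Atopobium", "Streptococcus")
  for (rep in 1:200) {
    obs <- sample(c("Lactobacillus", "GV_Bacteroides", "Mobiluncus"),
                  sample(0:3, 1))
    top <- sample(genera, sample(0:4, 1))
    extra <- sample(setdiff(genera, top), 1)
    before <- suppressWarnings(agreement(obs, top))$complete_agreement
    after <- suppressWarnings(agreement(obs, c(top, extra)))$complete_agreement
    expect_false(before && !after)
  }
})

test_that("cohort concordance rates stratify and conserve denominators", {
  tab <- cst_fixture_table()
  cst <- assign_cst(tab)
  meta <- data.frame(
    sample_id = cst$sample_id,
    group = c("NSW", "NSW", "NSW", "FSW", "FSW", "FSW", "FSW"),
    lacto_q = c(4, 4, 4, 4, 2, 0, 0),
    gv_q = c(0, 0, 1, 0, 1, 4, 3),
    curved_q = c(0, 0, 0, 0, 0, 0, 3),
    stringsAsFactors = FALSE)
  meta$top5_genera <- top_taxa(tab, 5)$per_sample[meta$sample_id]
  out <- suppressWarnings(concordance_summary(meta, cst))  # NSW has no CST IV
  rates <- out$rates

  overall <- rates[rates$stratum == "overall", ]
  expect_identical(overall$n_total, 7L)
  for (g in c("NSW", "FSW")) {
    g_tot <- rates$n_total[rates$stratum == g]
    strata <- rates[grepl(paste0("^", g, "_"), rates$stratum), ]
    expect_identical(sum(strata$n_total), g_tot)
    expect_identical(sum(strata$n_agree), rates$n_agree[rates$stratum == g])
  }
  expect_identical(sum(rates$n_total[rates$stratum %in% c("NSW", "FSW")]), 7L)

  # samples without morphotype data are excluded and counted
  meta2 <- meta
  meta2$lacto_q[1] <- NA
  out2 <- suppressWarnings(concordance_summary(meta2, cst))
  expect_identical(out2$n_excluded, 1L)
  expect_identical(out2$rates$n_total[out2$rates$stratum == "overall"], 6L)

  # fully agreeing records give rate 1 everywhere
  meta3 <- meta
  meta3$lacto_q <- 4; meta3$gv_q <- 0; meta3$curved_q <- 0
  out3 <- suppressWarnings(concordance_summary(meta3, cst))
  lacto_in_top5 <- vapply(meta3$top5_genera,
                          function(t5) any(grepl("^Lactobacillus", t5)),
                          logical(1))
  expect_identical(unname(out3$records$complete_agreement), unname(lacto_in_top5))
})
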