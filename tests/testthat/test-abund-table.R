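test_that("construction validates values, names and relative row sums", {
  m <- matrix(c(1, 2, 3, 4), 2, 2,
              dimnames = list(c("s1", "s2"), c("A", "B")))
  expect_s3_class(abundance_table(m, "counts"), "abund_table")

  m_neg <- m; m_neg[2, 1] <- -1
  expect_error(abundance_table(m_neg, "counts"), "s2.*A|negative")

  m_rel <- matrix(c(0.5, 0.4, 0.5, 0.5), 2, 2,
                  dimnames = list(c("s1", "bad_row"), c("A", "B")))
  expect_error(abundance_table(m_rel, "relative"), "bad_row")

  m_dup <- m; rownames(m_dup) <- c("s1", "s1")
  expect_error(abundance_table(m_dup, "counts"), "duplicated sample")
})

test_that("write/read round trip reproduces the table exactly", {
  set.seed(42)
  tab <- random_counts_table(6, 9)
  path <- tempfile(fileext = ".tsv")
  write_abundance_table(tab, path)
  back <- read_abundance_table(path, "counts")
  expect_identical(rownames(back), rownames(tab))
  expect_identical(colnames(back), colnames(tab))
  expect_lt(max(abs(unclass(back) - unclass(tab))), 1e-9)

  rel <- renormalize(tab)
  path2 <- tempfile(fileext = ".tsv")
  write_abundance_table(rel, path2)
  back2 <- read_abundance_table(path2, "relative")
  expect_lt(max(abs(unclass(back2) - unclass(rel))), 1e-9)
})

test_that("relative-mode reader auto-detects a transposed table", {
  set.seed(7)
  rel <- renormalize(random_counts_table(4, 6))
  path <- tempfile(fileext = ".tsv")
  df <- data.frame(taxon = colnames(rel), t(unclass(rel)), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_abundance_table(path, "relative")
  expect_identical(rownames(back), rownames(rel))
  expect_lt(max(abs(unclass(back) - unclass(rel))), 1e-9)
})

test_that("genus collapse sums OTUs, conserves totals, pools unmapped OTUs", {
  tab <- make_counts_table(rbind(c(3, 5, 2), c(1, 0, 4)),
                           taxa = c("OTU1", "OTU2", "OTU3"))
  tax <- c(OTU1 = "Lactobacillus", OTU2 = "Lactobacillus", OTU3 = "Gardnerella")
  coll <- collapse_to_genus(tab, tax)
  expect_equal(unclass(coll)[, "Lactobacillus"], c(s1 = 8, s2 = 1))
  expect_equal(rowSums(coll), rowSums(tab))

  # identity taxonomy leaves values unchanged
  ident <- setNames(colnames(tab), colnames(tab))
  same <- collapse_to_genus(tab, ident)
  expect_equal(unclass(same)[, colnames(tab)], unclass(tab)[, colnames(tab)])

  # unmapped OTU pooled into "unclassified"; per-sample totals conserved
  expect_warning(un <- collapse_to_genus(tab, tax[-3]), "unclassified")
  expect_true("unclassified" %in% colnames(un))
  expect_equal(unclass(un)[, "unclassified"], unclass(tab)[, "OTU3"])
  expect_equal(rowSums(un), rowSums(tab))

  expect_error(collapse_to_genus(tab, character(0)), "empty taxonomy")
})

test_that("collapse conserves counts-mode totals on random tables", {
  set.seed(99)
  for (rep in 1:20) {
    tab <- random_counts_table(5, 12)
    tax <- setNames(sample(paste0("G", 1:4), 12, replace = TRUE), colnames(tab))
    coll <- collapse_to_genus(tab, tax)
    expect_identical(unname(rowSums(coll)), unname(rowSums(tab)))
  }
})

test_that("relabel renames, merges collisions by summation, rejects cycles", {
  tab <- make_counts_table(rbind(c(4, 6, 2)),
                           taxa = c("Shuttleworthia", "BVAB1", "Prevotella"))
  out <- apply_relabel(tab, c(Shuttleworthia = "BVAB1"))
  expect_false("Shuttleworthia" %in% colnames(out))
  expect_equal(unname(unclass(out)[1, "BVAB1"]), 4 + 6)  # collision merged
  expect_equal(unname(rowSums(out)), unname(rowSums(tab)))

  expect_identical(apply_relabel(tab, setNames(character(0), character(0))), tab)

  solo <- apply_relabel(tab, c(Prevotella = "Prevotella_amnii"))
  expect_equal(unname(unclass(solo)[1, "Prevotella_amnii"]), 2)

  expect_error(apply_relabel(tab, c(A = "B", B = "A")), "cyclic")
})

test_that("top_taxa ranks by abundance with alphabetical tie-break", {
  tab <- abundance_table(matrix(c(0.5, 0.3, 0.2), 1,
                                dimnames = list("s1", c("A", "B", "C"))),
                         "relative")
  expect_identical(top_taxa(tab, 2)$per_sample$s1, c("A", "B"))

  tie <- abundance_table(matrix(c(0.4, 0.3, 0.3), 1,
                                dimnames = list("s1", c("C", "Zeta", "Alpha"))),
                         "relative")
  expect_identical(top_taxa(tie, 3)$per_sample$s1, c("C", "Alpha", "Zeta"))

  # n beyond the number of taxa returns everything
  expect_length(top_taxa(tie, 10)$global, 3)
})

test_that("top-n lists are prefixes of top-(n+1) lists", {
  set.seed(5)
  for (rep in 1:10) {
    tab <- random_counts_table(4, 8)
    for (n in 1:7) {
      a <- top_taxa(tab, n)
      b <- top_taxa(tab, n + 1)
      expect_identical(a$global, b$global[seq_len(n)])
      for (s in names(a$per_sample))
        expect_identical(a$per_sample[[s]], b$per_sample[[s]][seq_len(n)])
    }
  }
})
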