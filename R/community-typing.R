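# Community typing: k-means within-dispersion, gap-statistic estimation of
# the number of clusters, hierarchical clustering of the Bray-Curtis matrix,
# rule-based community state type (CST) assignment with CST IV sub-clusters,
# and Lactobacillus-dominance summaries with categorical tests.

CST_SPECIES <- c(I = "Lactobacillus_crispatus", II = "Lactobacillus_gasseri",
                 III = "Lactobacillus_iners", V = "Lactobacillus_jensenii")

#' K-means fit with restarts and pairwise within-dispersion
#'
#' Runs [stats::kmeans()] with `n_restarts` random starts and returns the best
#' partition together with the pooled within-cluster dispersion
#' `W_k = sum_r D_r / (2 * n_r)` where `D_r` is the sum of pairwise squared
#' Euclidean distances inside cluster r (for Euclidean data this equals the
#' total within-cluster sum of squares).
#'
#' @param points Numeric matrix (observations x features).
#' @param k Number of clusters, `<= nrow(points)`.
#' @param n_restarts Random starts (default 25).
#' @param seed Optional integer seed.
#' @return List: `labels` (integer vector), `W` (within-dispersion),
#'   `centers`.
#' @export
kmeans_fit <- function(points, k, n_restarts = 25, seed = NULL) {
  points <- as.matrix(points)
  stop_if_not_scalar_count(k, "k")
  if (k > nrow(points))
    stop(sprintf("k = %d exceeds the number of points (%d)", k, nrow(points)))
  fit <- with_seed(seed, {
    if (k == 1L) {
      ctr <- matrix(colMeans(points), 1L)
      list(cluster = rep(1L, nrow(points)), centers = ctr,
           tot.withinss = sum(sweep(points, 2L, ctr)^2))
    } else {
      stats::kmeans(points, centers = k, nstart = n_restarts, iter.max = 100L)
    }
  })
  list(labels = fit$cluster, W = fit$tot.withinss, centers = fit$centers)
}

# log of pooled within-dispersion for a labeling (pairwise form).
log_w_from_labels <- function(points, labels) {
  w <- 0
  for (g in unique(labels)) {
    sub <- points[labels == g, , drop = FALSE]
    ng <- nrow(sub)
    if (ng > 1L) w <- w + sum(sweep(sub, 2L, colMeans(sub))^2)
  }
  log(max(w, .Machine$double.xmin))
}

#' Gap statistic for the number of clusters
#'
#' Compares the log within-cluster dispersion of k-means partitions of the
#' data against `B` reference datasets drawn uniformly inside the
#' principal-component-aligned bounding box of the observations (the
#' Tibshirani et al. reference null): `gap(k) = E[log W*_k] - log W_k`, with
#' `se(k) = sd(log W*_k) * sqrt(1 + 1/B)`. `k_hat` reads the "plateau" of the
#' gap curve: with the default `"firstSEmax"` rule, the smallest k whose gap
#' is within one standard error of the first local maximum of the curve.
#' `"Tibs2001SEmax"` (the original one-standard-error rule, smallest k with
#' `gap(k) >= gap(k + 1) - se(k + 1)`) is available but stops prematurely on
#' gap curves that stay flat before jumping at the true k, as sharply
#' separated compositional clusters produce.
#'
#' @param points Numeric matrix (observations x features).
#' @param k_max Largest k considered (`>= 2`).
#' @param B Number of reference datasets (`>= 10`; default 100).
#' @param n_restarts K-means restarts per fit (default 25).
#' @param seed Optional integer seed covering both the k-means starts and the
#'   reference draws.
#' @param rule Plateau rule for `k_hat`: `"firstSEmax"` (default) or
#'   `"Tibs2001SEmax"`.
#' @return List of class `"gap_profile"`: `k_values`, `logW`, `E_logW`,
#'   `gap`, `se`, `k_hat`.
#' @export
gap_statistic <- function(points, k_max = 10, B = 100, n_restarts = 25,
                          seed = NULL, rule = c("firstSEmax", "Tibs2001SEmax")) {
  rule <- match.arg(rule)
  points <- as.matrix(points)
  stop_if_not_scalar_count(k_max, "k_max")
  if (k_max < 2L) stop("k_max must be >= 2")
  if (B < 10L) stop("B must be >= 10")
  n <- nrow(points)
  if (k_max > n) stop("k_max exceeds the number of points")
  if (max(apply(points, 2L, function(col) diff(range(col)))) < 1e-12) {
    warning("degenerate data (all points identical): k_hat = 1")
    return(structure(list(k_values = 1L, logW = NA_real_, E_logW = NA_real_,
                          gap = NA_real_, se = NA_real_, k_hat = 1L),
                     class = "gap_profile"))
  }
  ks <- seq_len(k_max)
  with_seed(seed, {
    logW <- vapply(ks, function(k)
      log(kmeans_fit(points, k, n_restarts = n_restarts)$W), numeric(1L))
    # reference null: uniform in the PCA-aligned bounding box
    ctr <- colMeans(points)
    xc <- sweep(points, 2L, ctr)
    v <- svd(xc, nu = 0L)$v
    xp <- xc %*% v
    lo <- apply(xp, 2L, min)
    hi <- apply(xp, 2L, max)
    logW_ref <- matrix(NA_real_, B, k_max)
    for (b in seq_len(B)) {
      zp <- sapply(seq_along(lo), function(j) stats::runif(n, lo[j], hi[j]))
      z <- zp %*% t(v) + matrix(ctr, n, length(ctr), byrow = TRUE)
      logW_ref[b, ] <- vapply(ks, function(k)
        log(kmeans_fit(z, k, n_restarts = n_restarts)$W), numeric(1L))
    }
    e_logw <- colMeans(logW_ref)
    se <- apply(logW_ref, 2L, stats::sd) * sqrt(1 + 1 / B)
    gap <- e_logw - logW
    if (rule == "Tibs2001SEmax") {
      k_hat <- k_max
      for (k in seq_len(k_max - 1L)) {
        if (gap[k] >= gap[k + 1L] - se[k + 1L]) { k_hat <- k; break }
      }
    } else {
      # first local maximum of the gap curve, then the smallest k within one
      # reference standard error of it
      f <- k_max
      for (k in seq_len(k_max - 1L)) {
        if (gap[k] >= gap[k + 1L]) { f <- k; break }
      }
      k_hat <- which(gap[seq_len(f)] >= gap[f] - se[f])[1L]
    }
    structure(list(k_values = ks, logW = logW, E_logW = e_logw, gap = gap,
                   se = se, k_hat = as.integer(k_hat)),
              class = "gap_profile")
  })
}

#' @export
print.gap_profile <- function(x, ...) {
  cat(sprintf("Gap statistic profile (k = 1..%d): k_hat = %d\n",
              max(x$k_values), x$k_hat))
  if (!anyNA(x$gap))
    print(data.frame(k = x$k_values, logW = round(x$logW, 4),
                     E_logW = round(x$E_logW, 4), gap = round(x$gap, 4),
                     se = round(x$se, 4)), row.names = FALSE)
  invisible(x)
}

#' Hierarchical clustering of a distance matrix
#'
#' Agglomerative clustering via [stats::hclust()] (complete linkage by
#' default, average available). Input sample order is normalized (sorted by
#' sample id) so the merge tree and leaf order are deterministic.
#'
#' @param dm A [distance_matrix()] over `>= 2` samples.
#' @param linkage `"complete"` (default) or `"average"`.
#' @return The `hclust` object (leaves labelled by sample id).
#' @export
hierarchical_cluster <- function(dm, linkage = c("complete", "average")) {
  stopifnot(inherits(dm, "dist_matrix"))
  linkage <- match.arg(linkage)
  if (length(dm$sample_ids) < 2L) stop("need at least 2 samples to cluster")
  ord <- order(dm$sample_ids, method = "radix")
  d <- dm$d[ord, ord]
  stats::hclust(stats::as.dist(d), method = linkage)
}

#' Export a dendrogram in Newick format
#'
#' @param hc An `hclust` object (e.g. from [hierarchical_cluster()]).
#' @param path Optional file path; when `NULL` the Newick string is returned.
#' @return Newick string (invisibly when written to `path`).
#' @export
dendrogram_newick <- function(hc, path = NULL) {
  stopifnot(inherits(hc, "hclust"))
  tre <- ape::as.phylo(hc)
  if (is.null(path)) return(ape::write.tree(tre))
  ape::write.tree(tre, file = path)
  invisible(ape::write.tree(tre))
}

#' Assign community state types from a species-call table
#'
#' Deterministic rule set over the most abundant taxon of each sample
#' (ties by taxon name ascending): *L. crispatus* -> CST I, *L. gasseri* ->
#' CST II, *L. iners* -> CST III, *L. jensenii* -> CST V, anything else ->
#' CST IV. CST IV samples get a sub-cluster from their top taxon's genus —
#' `IV-Streptococcus`, `IV-Gardnerella`, or `IV-diverse`. The
#' Lactobacillus-dominance flag is computed at genus level (all
#' *Lactobacillus* species summed) and is independent of the CST rule.
#'
#' @param table An [abundance_table()] whose taxa include the four
#'   CST-defining species calls (`Lactobacillus_crispatus`, `_gasseri`,
#'   `_iners`, `_jensenii`; other taxa at genus or species level, species
#'   named `Genus_species`).
#' @return `data.frame` with one row per sample: `sample_id`, `cst`,
#'   `subcluster`, `dominant_taxon`, `dominant_fraction`,
#'   `lactobacillus_dominant`.
#' @export
assign_cst <- function(table) {
  stopifnot(inherits(table, "abund_table"))
  missing_sp <- setdiff(unname(CST_SPECIES), colnames(table))
  if (length(missing_sp) > 0L)
    stop("required species-call taxa absent: ", paste(missing_sp, collapse = ", "))
  rel <- if (table_mode(table) == "relative") unclass(table) else
    unclass(renormalize(table))
  taxa <- colnames(rel)
  genus_tot <- t(rowsum(t(rel), group = genus_of(taxa)))
  genera <- colnames(genus_tot)
  out <- lapply(seq_len(nrow(rel)), function(i) {
    ord <- order_by_abundance(rel[i, ], taxa)
    top <- taxa[ord[1L]]
    cst <- names(CST_SPECIES)[match(top, CST_SPECIES)]
    if (is.na(cst)) cst <- "IV"
    sub <- "none"
    if (cst == "IV") {
      g <- genus_of(top)
      sub <- if (g == "Streptococcus") "IV-Streptococcus"
             else if (g == "Gardnerella") "IV-Gardnerella"
             else "IV-diverse"
    }
    gi <- order_by_abundance(genus_tot[i, ], genera)[1L]
    data.frame(sample_id = rownames(rel)[i], cst = cst, subcluster = sub,
               dominant_taxon = top, dominant_fraction = rel[i, ord[1L]],
               lactobacillus_dominant = genera[gi] == "Lactobacillus",
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Categorical association test for a contingency table
#'
#' Fisher's exact test for 2x2 tables; otherwise chi-square with Yates
#' correction, falling back to Fisher's exact test when any expected cell is
#' below 5.
#'
#' @param tab Contingency table (matrix).
#' @return List: `test` (name), `p_value`.
#' @export
categorical_test <- function(tab) {
  tab <- as.matrix(tab)
  if (all(dim(tab) == 2L)) {
    return(list(test = "Fisher exact", p_value = stats::fisher.test(tab)$p.value))
  }
  keep_r <- rowSums(tab) > 0
  keep_c <- colSums(tab) > 0
  tab2 <- tab[keep_r, keep_c, drop = FALSE]
  if (any(dim(tab2) < 2L)) return(list(test = "degenerate", p_value = 1))
  exp_cells <- outer(rowSums(tab2), colSums(tab2)) / sum(tab2)
  if (any(exp_cells < 5)) {
    p <- tryCatch(stats::fisher.test(tab2, workspace = 2e7)$p.value,
                  error = function(e)
                    stats::fisher.test(tab2, simulate.p.value = TRUE, B = 1e5)$p.value)
    return(list(test = "Fisher exact", p_value = p))
  }
  list(test = "chi-square (Yates)",
       p_value = suppressWarnings(stats::chisq.test(tab2, correct = TRUE)$p.value))
}

#' Dominance and CST contingency summaries by group
#'
#' Cross-tabulates Lactobacillus dominance and CST against the sample group
#' and tests each table with [categorical_test()].
#'
#' @param assignments Output of [assign_cst()].
#' @param metadata `data.frame` with `sample_id` and `group` columns covering
#'   the assigned samples.
#' @return List: `dominance_table`, `dominance_test`, `dominance_proportions`
#'   (named by group, with numerators/denominators), `cst_table`, `cst_test`.
#' @export
dominance_summary <- function(assignments, metadata) {
  m <- match(assignments$sample_id, metadata$sample_id)
  if (anyNA(m)) stop("metadata missing sample(s): ",
                     paste(assignments$sample_id[is.na(m)], collapse = ", "))
  grp <- factor(metadata$group[m])
  if (any(table(grp) == 0L)) stop("empty group")
  dom <- factor(assignments$lactobacillus_dominant, levels = c(TRUE, FALSE),
                labels = c("dominant", "not_dominant"))
  dom_tab <- table(group = grp, dominance = dom)
  cst_tab <- table(group = grp, cst = factor(assignments$cst,
                                             levels = c("I", "II", "III", "IV", "V")))
  cst_tab <- cst_tab[, colSums(cst_tab) > 0, drop = FALSE]
  props <- lapply(levels(grp), function(g) {
    n_dom <- sum(dom == "dominant" & grp == g)
    n_tot <- sum(grp == g)
    list(n_dominant = n_dom, n_total = n_tot, proportion = n_dom / n_tot)
  })
  names(props) <- levels(grp)
  list(dominance_table = dom_tab,
       dominance_test = categorical_test(dom_tab),
       dominance_proportions = props,
       cst_table = cst_tab,
       cst_test = categorical_test(cst_tab))
}
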