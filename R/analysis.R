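# Full-pipeline orchestration: one call runs alpha diversity, Bray-Curtis /
# PCoA / PERMANOVA, gap-statistic clustering, CST assignment, dominance and
# concordance summaries, and collects everything (plus a reproducibility
# manifest) in a classed result object.

#' Run the complete vaginal-microbiota analysis
#'
#' Takes a species-call-level count table and per-sample metadata and runs
#' every stage of the pipeline: rarefaction alpha diversity (observed taxa,
#' Chao1, Shannon in bits, evaluated on a depth grid and at a pinned analysis
#' depth), genus-level Bray-Curtis dissimilarity with PCoA and a one-factor
#' PERMANOVA on the group label, gap-statistic estimation of the number of
#' community clusters, hierarchical clustering, rule-based CST assignment
#' with *Lactobacillus*-dominance classification, and — when morphotype
#' quantitation is present — Nugent concordance against each sample's top-5
#' genera. One global `seed` is expanded into fixed per-stage seeds
#' (`seed + 1` alpha, `seed + 2` PERMANOVA, `seed + 3` gap), all recorded in
#' the manifest, so stages can be re-run in isolation.
#'
#' @param counts Species-call-level [abundance_table()] in counts mode
#'   (taxa named `Genus` or `Genus_species`, including the four CST-defining
#'   *Lactobacillus* species).
#' @param metadata `data.frame` with `sample_id` and `group`, optionally
#'   `age`, `cycle_stage`, `lacto_q`/`gv_q`/`curved_q`, `nugent_score`,
#'   `nugent_category`, `top5_genera`; rows must cover all samples.
#' @param depths Rarefaction depth grid; default 9 evenly spaced depths from
#'   10 to the largest sample total.
#' @param analysis_depth Pinned single-depth at which per-sample alpha values
#'   are compared (default 6791, a depth retaining most deeply-sequenced
#'   cohorts).
#' @param n_iterations Rarefaction iterations per depth (default 10).
#' @param permutations PERMANOVA permutations (default 999).
#' @param k_max,B,n_restarts Gap-statistic controls (defaults 10, 100, 25).
#' @param genus_map Genus -> morphotype map for the concordance stage.
#' @param seed Global integer seed.
#' @return Object of class `"vm_analysis"`; see [summary.vm_analysis()] and
#'   [vm_summary_json()].
#' @export
vm_analysis <- function(counts, metadata,
                        depths = NULL, analysis_depth = 6791,
                        n_iterations = 10, permutations = 999,
                        k_max = 10, B = 100, n_restarts = 25,
                        genus_map = default_morphotype_map(),
                        seed = 1L) {
  stopifnot(inherits(counts, "abund_table"))
  if (table_mode(counts) != "counts") stop("stage io: counts-mode table required")
  if (!all(c("sample_id", "group") %in% names(metadata)))
    stop("stage io: metadata needs sample_id and group columns")
  m <- match(rownames(counts), metadata$sample_id)
  if (anyNA(m))
    stop("stage io: metadata missing sample(s): ",
         paste(rownames(counts)[is.na(m)], collapse = ", "))
  metadata <- metadata[m, , drop = FALSE]
  groups <- stats::setNames(as.character(metadata$group), metadata$sample_id)
  seed <- as.integer(seed)
  seeds <- c(alpha = seed + 1L, permanova = seed + 2L, gap = seed + 3L)

  # genus-level relative table feeds all beta/typing stages
  genus_tax <- stats::setNames(genus_of(colnames(counts)), colnames(counts))
  genus_rel <- renormalize(collapse_to_genus(counts, genus_tax))
  species_rel <- renormalize(counts)

  totals <- rowSums(counts)
  if (is.null(depths))
    depths <- unique(round(seq(10, max(totals), length.out = 9)))
  rare <- rarefaction_curves(counts, depths = depths,
                             n_iterations = n_iterations,
                             seed = seeds[["alpha"]], groups = groups)
  pinned <- rarefaction_curves(counts, depths = analysis_depth,
                               n_iterations = n_iterations,
                               seed = seeds[["alpha"]], groups = groups)
  shannon_at_depth <- with(subset(pinned$per_sample, metric == "shannon"),
                           stats::setNames(mean, sample_id))

  dm <- bray_curtis(genus_rel)
  ordin <- pcoa(dm)
  perm <- permanova(dm, groups, n_permutations = permutations,
                    seed = seeds[["permanova"]])

  gap <- gap_statistic(unclass(genus_rel), k_max = k_max, B = B,
                       n_restarts = n_restarts, seed = seeds[["gap"]])
  hc <- hierarchical_cluster(dm)
  cst <- assign_cst(species_rel)
  dom <- dominance_summary(cst, metadata)

  concord <- NULL
  if (all(c("lacto_q", "gv_q", "curved_q") %in% names(metadata))) {
    md <- metadata
    if (!"top5_genera" %in% names(md))
      md$top5_genera <- top_taxa(genus_rel, 5L)$per_sample[md$sample_id]
    concord <- concordance_summary(md, cst, genus_map = genus_map)
  }

  table1 <- summarize_table1(metadata)

  # per-group Shannon at the pinned depth, plus Nugent-stratum comparisons
  shan_meta <- data.frame(sample_id = names(shannon_at_depth),
                          shannon = unname(shannon_at_depth),
                          stringsAsFactors = FALSE)
  shan_meta$group <- groups[shan_meta$sample_id]
  shan_meta$nugent_category <-
    if ("nugent_category" %in% names(metadata))
      metadata$nugent_category[match(shan_meta$sample_id, metadata$sample_id)]
    else NA_character_
  shan_meta$cst <- cst$cst[match(shan_meta$sample_id, cst$sample_id)]

  fit <- structure(list(
    counts = counts, metadata = metadata, genus_rel = genus_rel,
    rarefaction = rare, shannon_at_depth = shan_meta,
    analysis_depth = analysis_depth,
    dm = dm, pcoa = ordin, permanova = perm,
    gap = gap, hclust = hc, cst = cst, dominance = dom,
    concordance = concord, table1 = table1,
    manifest = list(package = "vmcst",
                    version = as.character(utils::packageVersion("vmcst")),
                    seed = seed, stage_seeds = as.list(seeds),
                    depths = depths, analysis_depth = analysis_depth,
                    n_iterations = n_iterations, permutations = permutations,
                    k_max = k_max, B = B, n_restarts = n_restarts)),
    class = "vm_analysis")
  fit
}

#' @export
print.vm_analysis <- function(x, ...) {
  cat("Vaginal microbiota community analysis\n")
  cat(sprintf("  %d samples x %d species-call taxa (%d genera)\n",
              nrow(x$counts), ncol(x$counts), ncol(x$genus_rel)))
  cat(sprintf("  PERMANOVA (group): pseudo-F = %.3f, p = %.4g\n",
              x$permanova$pseudo_F, x$permanova$p_value))
  cat(sprintf("  Gap-statistic clusters: k_hat = %d\n", x$gap$k_hat))
  cst_counts <- table(x$cst$cst)
  cat("  CST counts: ", paste(sprintf("%s=%d", names(cst_counts), cst_counts),
                              collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Summary of a fitted vaginal-microbiota analysis
#'
#' Collapses the per-stage results into the headline quantities: group sizes,
#' *Lactobacillus*-dominance proportions with their categorical test, CST
#' counts by group, PERMANOVA pseudo-F and p, the gap-statistic `k_hat`,
#' mean Shannon (at the pinned depth) by group and by Nugent category, the
#' fraction of low-Nugent samples per group falling in CST IV, and the
#' concordance rates.
#'
#' @param object A [vm_analysis()] result.
#' @param ... Unused.
#' @return A named list of class `"summary.vm_analysis"`.
#' @export
summary.vm_analysis <- function(object, ...) {
  x <- object
  grp <- as.character(x$metadata$group)
  dom_props <- lapply(x$dominance$dominance_proportions, function(p)
    list(n_dominant = p$n_dominant, n_total = p$n_total,
         percent = 100 * p$proportion))
  cst_by_group <- as.data.frame.matrix(x$dominance$cst_table)

  sh <- x$shannon_at_depth
  shannon_by_group <- lapply(split(sh$shannon, sh$group), function(v)
    list(mean = mean(v), sem = stats::sd(v) / sqrt(length(v)), n = length(v)))
  shannon_by_nugent <- NULL
  high_div_low_nugent <- NULL
  if (!all(is.na(sh$nugent_category))) {
    shannon_by_nugent <- lapply(split(sh, sh$group), function(d)
      lapply(split(d$shannon, d$nugent_category), function(v)
        list(mean = mean(v), sem = stats::sd(v) / sqrt(length(v)), n = length(v))))
    low <- sh[!is.na(sh$nugent_category) & sh$nugent_category == "0-3", ]
    high_div_low_nugent <- lapply(split(low, low$group), function(d)
      list(n_cst_iv = sum(d$cst == "IV"), n_low_nugent = nrow(d),
           percent = 100 * mean(d$cst == "IV")))
  }
  conc <- if (!is.null(x$concordance)) x$concordance$rates else NULL

  structure(list(
    group_sizes = as.list(table(grp)),
    dominance = dom_props,
    dominance_p = x$dominance$dominance_test$p_value,
    cst_counts = as.list(table(x$cst$cst)),
    cst_by_group = cst_by_group,
    permanova = list(pseudo_F = x$permanova$pseudo_F,
                     p = x$permanova$p_value,
                     permutations = x$permanova$n_permutations),
    gap_k = x$gap$k_hat,
    analysis_depth = x$analysis_depth,
    shannon_by_group = shannon_by_group,
    shannon_by_nugent = shannon_by_nugent,
    high_diversity_low_nugent = high_div_low_nugent,
    concordance = conc,
    manifest = x$manifest),
    class = "summary.vm_analysis")
}

#' @export
print.summary.vm_analysis <- function(x, ...) {
  cat("Summary of vaginal microbiota analysis\n")
  cat("  Groups:", paste(sprintf("%s n=%d", names(x$group_sizes),
                                 unlist(x$group_sizes)), collapse = ", "), "\n")
  for (g in names(x$dominance)) {
    d <- x$dominance[[g]]
    cat(sprintf("  Lactobacillus dominant, %s: %d/%d (%.0f%%)\n",
                g, d$n_dominant, d$n_total, d$percent))
  }
  cat(sprintf("  Dominance test p = %.4g\n", x$dominance_p))
  cat("  CST counts:", paste(sprintf("%s=%d", names(x$cst_counts),
                                     unlist(x$cst_counts)), collapse = ", "), "\n")
  cat(sprintf("  PERMANOVA: pseudo-F = %.3f, p = %.4g (%d permutations)\n",
              x$permanova$pseudo_F, x$permanova$p, x$permanova$permutations))
  cat(sprintf("  Gap-statistic k_hat = %d\n", x$gap_k))
  for (g in names(x$shannon_by_group)) {
    s <- x$shannon_by_group[[g]]
    cat(sprintf("  Shannon at depth %d, %s: %.3f +/- %.3f (n=%d)\n",
                x$analysis_depth, g, s$mean, s$sem, s$n))
  }
  if (!is.null(x$concordance)) {
    cat("  Concordance rates:\n")
    print(transform(x$concordance, rate = round(rate, 3)), row.names = FALSE)
  }
  invisible(x)
}

#' JSON summary of an analysis
#'
#' Serializes [summary.vm_analysis()] as JSON (percentages always accompanied
#' by numerator and denominator; all seeds in the manifest), suitable for the
#' run record. Re-running [vm_analysis()] with the same inputs and manifest
#' settings reproduces the JSON byte for byte.
#'
#' @param fit A [vm_analysis()] result.
#' @param path Optional output path.
#' @return JSON string (invisibly when written to `path`).
#' @export
vm_summary_json <- function(fit, path = NULL) {
  s <- summary(fit)
  s$concordance <- if (!is.null(s$concordance)) {
    stats::setNames(lapply(seq_len(nrow(s$concordance)), function(i)
      list(n_agree = s$concordance$n_agree[i], n_total = s$concordance$n_total[i],
           rate = s$concordance$rate[i])), s$concordance$stratum)
  }
  s$cst_by_group <- lapply(as.list(as.data.frame(t(s$cst_by_group))),
                           function(v) stats::setNames(as.list(v), colnames(s$cst_by_group)))
  json <- jsonlite::toJSON(unclass(s), auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null")
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(as.character(json)))
  }
  as.character(json)
}

#' Plot method for a fitted analysis
#'
#' Base-graphics panels: group-mean rarefaction curves (per metric), the
#' first two PCoA axes colored by group, and the gap-statistic profile with
#' the selected k.
#'
#' @param x A [vm_analysis()] result.
#' @param which Subset of `c("rarefaction", "pcoa", "gap")`.
#' @param ... Passed to the underlying plot calls.
#' @return `x`, invisibly.
#' @export
plot.vm_analysis <- function(x, which = c("rarefaction", "pcoa", "gap"), ...) {
  which <- match.arg(which, several.ok = TRUE)
  if ("rarefaction" %in% which && !is.null(x$rarefaction$per_group)) {
    pg <- x$rarefaction$per_group
    for (met in unique(pg$metric)) {
      d <- pg[pg$metric == met, ]
      grps <- unique(d$group)
      graphics::plot(range(d$depth), range(d$group_mean), type = "n",
                     xlab = "rarefaction depth", ylab = met,
                     main = paste("Rarefaction:", met), ...)
      for (i in seq_along(grps)) {
        di <- d[d$group == grps[i], ]
        graphics::lines(di$depth, di$group_mean, col = i, type = "b", pch = i)
      }
      graphics::legend("bottomright", legend = grps, col = seq_along(grps),
                       pch = seq_along(grps), bty = "n")
    }
  }
  if ("pcoa" %in% which) {
    co <- x$pcoa$coordinates
    grp <- factor(x$metadata$group[match(rownames(co), x$metadata$sample_id)])
    pe <- 100 * x$pcoa$proportion_explained
    graphics::plot(co[, 1L], co[, 2L], col = as.integer(grp), pch = 19,
                   xlab = sprintf("PCo1 (%.1f%%)", pe[1L]),
                   ylab = sprintf("PCo2 (%.1f%%)", pe[2L]),
                   main = "Bray-Curtis PCoA", ...)
    graphics::legend("topright", legend = levels(grp),
                     col = seq_len(nlevels(grp)), pch = 19, bty = "n")
  }
  if ("gap" %in% which && !anyNA(x$gap$gap)) {
    graphics::plot(x$gap$k_values, x$gap$gap, type = "b", pch = 19,
                   xlab = "k", ylab = "gap statistic",
                   main = sprintf("Gap statistic (k_hat = %d)", x$gap$k_hat), ...)
    graphics::arrows(x$gap$k_values, x$gap$gap - x$gap$se,
                     x$gap$k_values, x$gap$gap + x$gap$se,
                     angle = 90, code = 3, length = 0.03)
    graphics::abline(v = x$gap$k_hat, lty = 2)
  }
  invisible(x)
}

#' Per-group descriptive characteristics table
#'
#' Age mean and range (unknowns counted separately), Nugent-category counts
#' and percentages, and menstrual-cycle-stage counts per group, with
#' between-group tests (age via [compare_groups_continuous()], categorical
#' variables via [categorical_test()]). With a single group only the
#' descriptive columns are produced.
#'
#' @param metadata `data.frame` with `group` and any of `age`,
#'   `nugent_category` (or `nugent_score`), `cycle_stage`.
#' @return List of class `"table1"`: `age`, `nugent`, `cycle_stage` blocks
#'   (each with per-group entries and, for `>= 2` groups, a `p_value`).
#' @export
summarize_table1 <- function(metadata) {
  grp <- factor(as.character(metadata$group))
  multi <- nlevels(grp) >= 2L
  out <- list(group_sizes = as.list(table(grp)))

  if ("age" %in% names(metadata)) {
    age <- suppressWarnings(as.numeric(metadata$age))
    blocks <- lapply(levels(grp), function(g) {
      a <- age[grp == g]
      list(mean = mean(a, na.rm = TRUE),
           range = if (all(is.na(a))) c(NA_real_, NA_real_) else range(a, na.rm = TRUE),
           n_unknown = sum(is.na(a)))
    })
    names(blocks) <- levels(grp)
    out$age <- blocks
    if (multi && sum(!is.na(age)) >= 4L)
      out$age$p_value <- tryCatch(
        compare_groups_continuous(age, grp)$p_value, error = function(e) NA_real_)
  }

  nug <- if ("nugent_category" %in% names(metadata)) metadata$nugent_category
         else if ("nugent_score" %in% names(metadata)) nugent_category(metadata$nugent_score)
         else NULL
  if (!is.null(nug)) {
    nug <- factor(nug, levels = c("0-3", "4-6", "7-10"))
    tab <- table(group = grp, nugent = nug)
    out$nugent <- list(counts = tab,
                       percent = 100 * prop.table(tab, margin = 1L))
    if (multi) out$nugent$p_value <- categorical_test(tab)$p_value
  }

  if ("cycle_stage" %in% names(metadata)) {
    tab <- table(group = grp, cycle_stage = as.character(metadata$cycle_stage))
    out$cycle_stage <- list(counts = tab)
    if (multi) out$cycle_stage$p_value <- categorical_test(tab)$p_value
  }
  structure(out, class = "table1")
}

#' @export
print.table1 <- function(x, ...) {
  cat("Cohort characteristics by group\n")
  cat("  n:", paste(sprintf("%s=%d", names(x$group_sizes), unlist(x$group_sizes)),
                    collapse = ", "), "\n")
  if (!is.null(x$age)) {
    for (g in setdiff(names(x$age), "p_value")) {
      a <- x$age[[g]]
      cat(sprintf("  Age, %s: %.1f (%g-%g), unknown %d\n", g, a$mean,
                  a$range[1L], a$range[2L], a$n_unknown))
    }
    if (!is.null(x$age$p_value)) cat(sprintf("  Age p = %.3g\n", x$age$p_value))
  }
  if (!is.null(x$nugent)) {
    cat("  Nugent categories:\n"); print(x$nugent$counts)
    if (!is.null(x$nugent$p_value)) cat(sprintf("  Nugent p = %.3g\n", x$nugent$p_value))
  }
  if (!is.null(x$cycle_stage)) {
    cat("  Cycle stage:\n"); print(x$cycle_stage$counts)
    if (!is.null(x$cycle_stage$p_value))
      cat(sprintf("  Cycle p = %.3g\n", x$cycle_stage$p_value))
  }
  invisible(x)
}
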