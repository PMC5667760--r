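# Alpha diversity: rarefaction without replacement and the three classic
# metrics (observed taxa, bias-corrected Chao1, Shannon in bits). Conventions
# follow the QIIME-era defaults: singletons retained, Shannon uses log2,
# Chao1 uses the bias-corrected estimator (defined when F2 = 0).

#' Rarefy a count vector to a fixed depth
#'
#' Subsamples reads without replacement (a multivariate hypergeometric draw,
#' realized as a sequential [stats::rhyper()] chain), so the output total is
#' exactly `depth` and no taxon exceeds its original count.
#'
#' @param counts Non-negative integer vector of per-taxon read counts.
#' @param depth Target depth, `>= 1` and `<= sum(counts)`.
#' @param seed Optional integer seed; the caller's RNG state is untouched.
#' @return Integer vector of rarefied counts (names preserved).
#' @examples
#' rarefy(c(A = 10, B = 0), depth = 4)   # always c(4, 0)
#' @export
rarefy <- function(counts, depth, seed = NULL) {
  counts <- check_counts(counts)
  stop_if_not_scalar_count(depth, "depth")
  total <- sum(counts)
  if (total < depth)
    stop(sprintf("depth %d exceeds sample total %d", as.integer(depth), as.integer(total)))
  with_seed(seed, {
    out <- integer(length(counts))
    k <- as.integer(depth)
    rem <- total
    for (i in seq_along(counts)) {
      if (k == 0L) break
      rem <- rem - counts[i]
      x <- stats::rhyper(1L, counts[i], rem, k)
      out[i] <- x
      k <- k - x
    }
    names(out) <- names(counts)
    out
  })
}

check_counts <- function(counts) {
  if (!is.numeric(counts) || length(counts) == 0L)
    stop("counts must be a non-empty numeric vector")
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers")
  if (sum(counts) == 0) stop("all-zero count vector")
  counts
}

#' Shannon diversity (bits)
#'
#' `H = -sum(p_i * log2(p_i))` over taxa with positive counts, `p_i` the
#' within-sample proportion. Base-2 by convention here (values on the scale
#' QIIME reports); `base` switches, with a warning that comparisons against
#' base-2 references then no longer hold.
#'
#' @param counts Non-negative numeric vector with at least one positive entry
#'   (relative abundances are accepted: only proportions enter the formula).
#' @param base Logarithm base, default 2.
#' @return Shannon index, `>= 0` and `<= log2(S_obs)` for base 2.
#' @examples
#' shannon(c(1, 1, 1, 1))  # 2 bits
#' @export
shannon <- function(counts, base = 2) {
  if (!is.numeric(counts) || length(counts) == 0L || any(counts < 0))
    stop("counts must be a non-empty non-negative numeric vector")
  if (sum(counts) == 0) stop("all-zero count vector")
  if (base != 2)
    warning("Shannon base != 2: values are not comparable to base-2 (QIIME-scale) references")
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p, base = base))
}

#' Chao1 richness estimate (bias-corrected)
#'
#' `S_obs + F1 * (F1 - 1) / (2 * (F2 + 1))` with `F1`/`F2` the singleton and
#' doubleton counts; equals `S_obs` when `F1 <= 1` and is always defined
#' (including `F2 = 0`).
#'
#' @param counts Non-negative integer vector with at least one positive entry.
#' @return Estimated richness, `>= S_obs`.
#' @examples
#' chao1(c(5, 1, 1, 2))  # 4.5
#' @export
chao1 <- function(counts) {
  counts <- check_counts(counts)
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

observed_taxa <- function(counts) sum(counts > 0)

alpha_metric_fun <- function(metric) {
  switch(metric,
         observed = observed_taxa,
         chao1 = chao1,
         shannon = shannon,
         stop("unknown metric: ", metric))
}

#' Rarefaction curves for observed taxa, Chao1 and Shannon
#'
#' For every sample, depth and iteration, draws a without-replacement
#' subsample and evaluates the three metrics. Samples whose total is below a
#' depth are excluded at that depth (flagged, not an error). Per-sample means
#' and SEMs are over iterations; group curves summarize per-sample iteration
#' means across samples (mean +/- SEM).
#'
#' @param table An [abundance_table()] in counts mode.
#' @param depths Integer vector of rarefaction depths.
#' @param n_iterations Subsamples per (sample, depth); default 10.
#' @param seed Integer seed; draws are sub-seeded per (sample, depth,
#'   iteration) so the full grid is reproducible.
#' @param groups Optional named factor/character vector (names = sample ids)
#'   for group summary curves.
#' @return List of class `"rarefaction_result"`: `values` (long data.frame of
#'   sample/metric/depth/iteration/value), `per_sample` (mean and SEM per
#'   sample/metric/depth), `per_group` (when `groups` given), and
#'   `excluded` (sample/depth pairs skipped).
#' @export
rarefaction_curves <- function(table, depths, n_iterations = 10, seed = NULL,
                               groups = NULL) {
  stopifnot(inherits(table, "abund_table"))
  if (table_mode(table) != "counts")
    stop("rarefaction requires a counts-mode table; collapse/convert before calling")
  depths <- sort(unique(as.integer(depths)))
  if (any(depths < 1)) stop("depths must be >= 1")
  stop_if_not_scalar_count(n_iterations, "n_iterations")
  totals <- rowSums(table)
  metrics <- c("observed", "chao1", "shannon")

  rows <- vector("list", 0L)
  excluded <- data.frame(sample_id = character(), depth = integer())
  idx <- 0L
  for (si in seq_len(nrow(table))) {
    sid <- rownames(table)[si]
    cnt <- unclass(table)[si, ]
    for (d in depths) {
      if (totals[si] < d) {
        excluded <- rbind(excluded, data.frame(sample_id = sid, depth = d))
        next
      }
      for (it in seq_len(n_iterations)) {
        idx <- idx + 1L
        sub_seed <- if (is.null(seed)) NULL else
          (as.integer(seed) + 7919L * si + 104729L * match(d, depths) + it) %% .Machine$integer.max
        sub <- rarefy(cnt, d, seed = sub_seed)
        rows[[idx]] <- data.frame(
          sample_id = sid, depth = d, iteration = it,
          metric = metrics,
          value = c(observed_taxa(sub), chao1(sub), shannon(sub)),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (idx == 0L)
    stop("no sample reaches any requested depth; nothing to rarefy")
  values <- do.call(rbind, rows)

  per_sample <- stats::aggregate(value ~ sample_id + metric + depth, data = values,
                                 FUN = mean)
  names(per_sample)[names(per_sample) == "value"] <- "mean"
  sem_it <- stats::aggregate(value ~ sample_id + metric + depth, data = values,
                             FUN = function(v) stats::sd(v) / sqrt(length(v)))
  per_sample$sem <- sem_it$value[match(
    paste(per_sample$sample_id, per_sample$metric, per_sample$depth),
    paste(sem_it$sample_id, sem_it$metric, sem_it$depth))]

  per_group <- NULL
  if (!is.null(groups)) {
    per_sample$group <- as.character(groups[per_sample$sample_id])
    per_group <- stats::aggregate(mean ~ group + metric + depth, data = per_sample,
                                  FUN = mean)
    sem_g <- stats::aggregate(mean ~ group + metric + depth, data = per_sample,
                              FUN = function(v) stats::sd(v) / sqrt(length(v)))
    names(per_group)[names(per_group) == "mean"] <- "group_mean"
    per_group$group_sem <- sem_g$mean[match(
      paste(per_group$group, per_group$metric, per_group$depth),
      paste(sem_g$group, sem_g$metric, sem_g$depth))]
  }

  structure(list(values = values, per_sample = per_sample, per_group = per_group,
                 excluded = excluded, depths = depths,
                 n_iterations = as.integer(n_iterations)),
            class = "rarefaction_result")
}

#' Compare a continuous variable between groups
#'
#' Chooses the test the way classic biostatistics workflows do: per-group
#' normality screen (Shapiro-Wilk at alpha = 0.05; any group too small or
#' degenerate for the screen is treated as non-normal), then Student's t-test
#' / one-way ANOVA when all groups pass, otherwise Mann-Whitney /
#' Kruskal-Wallis. The chosen test's name is returned for audit.
#'
#' @param values Numeric vector.
#' @param groups Factor/character vector, same length; `>= 2` non-empty
#'   groups, each with `>= 2` observations.
#' @return List: `test` (name), `statistic`, `p_value`, `n_per_group`.
#' @export
compare_groups_continuous <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- factor(as.character(groups[keep]))
  sizes <- table(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 non-empty groups")
  if (any(sizes < 2L))
    stop("group(s) with fewer than 2 observations: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  normal <- vapply(levels(groups), function(g) {
    v <- values[groups == g]
    if (length(v) < 3L || length(unique(v)) < 2L) return(FALSE)
    ok <- tryCatch(stats::shapiro.test(v)$p.value >= 0.05, error = function(e) FALSE)
    ok
  }, logical(1L))
  two <- nlevels(groups) == 2L
  if (all(normal)) {
    if (two) {
      ht <- stats::t.test(values ~ groups)
      res <- list(test = "t-test", statistic = unname(ht$statistic), p_value = ht$p.value)
    } else {
      ht <- stats::anova(stats::aov(values ~ groups))
      res <- list(test = "one-way ANOVA", statistic = ht$`F value`[1L],
                  p_value = ht$`Pr(>F)`[1L])
    }
  } else {
    if (two) {
      ht <- suppressWarnings(stats::wilcox.test(values ~ groups, exact = FALSE, correct = TRUE))
      res <- list(test = "Mann-Whitney", statistic = unname(ht$statistic), p_value = ht$p.value)
    } else {
      ht <- stats::kruskal.test(values, groups)
      res <- list(test = "Kruskal-Wallis", statistic = unname(ht$statistic), p_value = ht$p.value)
    }
  }
  res$n_per_group <- as.integer(sizes)
  names(res$n_per_group) <- names(sizes)
  res
}
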