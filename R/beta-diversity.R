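# Beta diversity: Bray-Curtis dissimilarity, principal coordinates analysis
# (Gower double-centering, no negative-eigenvalue correction), and a
# one-factor PERMANOVA with a seeded permutation engine that supports
# exhaustive enumeration on small designs.

#' Pairwise distance matrix container
#'
#' @param d Symmetric numeric matrix with zero diagonal and matching
#'   row/column names (sample ids).
#' @return Object of class `"dist_matrix"`.
#' @export
distance_matrix <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-9)
    stop("distance matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix diagonal must be zero")
  if (is.null(rownames(d))) stop("distance matrix needs sample ids as dimnames")
  colnames(d) <- rownames(d)
  structure(list(sample_ids = rownames(d), d = d), class = "dist_matrix")
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("Distance matrix: %d samples, range [%.4f, %.4f]\n",
              length(x$sample_ids), min(x$d[upper.tri(x$d)]), max(x$d)))
  invisible(x)
}

#' Bray-Curtis dissimilarity
#'
#' `d(x, y) = 1 - 2 * sum(min(x_i, y_i)) / (sum(x) + sum(y))`, computed with
#' [vegan::vegdist()]. Works on counts or relative abundances; all-zero
#' samples are rejected by name.
#'
#' @param table An [abundance_table()].
#' @return A [distance_matrix()] with entries in `[0, 1]`.
#' @export
bray_curtis <- function(table) {
  stopifnot(inherits(table, "abund_table"))
  rs <- rowSums(table)
  if (any(rs <= 0))
    stop("all-zero sample(s): ", paste(rownames(table)[rs <= 0], collapse = ", "))
  d <- as.matrix(vegan::vegdist(unclass(table), method = "bray"))
  distance_matrix(d)
}

#' Principal coordinates analysis
#'
#' Gower double-centering of `-d^2 / 2` followed by eigendecomposition.
#' Coordinates are eigenvectors scaled by the square root of their (positive)
#' eigenvalues; negative eigenvalues are reported, not corrected, and the
#' proportion explained is over the positive-eigenvalue total. Axis signs are
#' fixed (largest-magnitude loading positive) for determinism.
#'
#' @param dm A [distance_matrix()].
#' @return List of class `"pcoa_result"`: `coordinates` (samples x positive
#'   axes), `eigenvalues` (all, descending), `proportion_explained`.
#' @export
pcoa <- function(dm) {
  stopifnot(inherits(dm, "dist_matrix"))
  d2 <- dm$d^2
  n <- nrow(d2)
  cj <- diag(n) - matrix(1 / n, n, n)
  b <- -0.5 * cj %*% d2 %*% cj
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  tol <- 1e-9 * max(1, abs(e$values[1L]))
  pos <- which(e$values > tol)
  if (length(pos) == 0L) {
    coords <- matrix(numeric(0), n, 0L, dimnames = list(dm$sample_ids, NULL))
  } else {
    coords <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(e$values[pos]), length(pos))
    for (j in seq_len(ncol(coords))) {
      i_max <- which.max(abs(coords[, j]))
      if (coords[i_max, j] < 0) coords[, j] <- -coords[, j]
    }
    dimnames(coords) <- list(dm$sample_ids, paste0("PCo", seq_len(ncol(coords))))
  }
  structure(list(coordinates = coords,
                 eigenvalues = e$values,
                 proportion_explained = e$values[pos] / sum(e$values[pos])),
            class = "pcoa_result")
}

# Sum-of-squares decomposition from a squared-distance matrix and labels.
permanova_ss <- function(d2, labels) {
  n <- nrow(d2)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (g in unique(labels)) {
    idx <- labels == g
    ng <- sum(idx)
    ss_within <- ss_within + sum(d2[idx, idx]) / (2 * ng)
  }
  c(total = ss_total, within = ss_within)
}

permanova_f <- function(d2, labels, k, n) {
  ss <- permanova_ss(d2, labels)
  ((ss[["total"]] - ss[["within"]]) / (k - 1)) / (ss[["within"]] / (n - k))
}

# All permutations of 1..n as an n! x n matrix (used for exhaustive mode).
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (pos in seq_len(n)) {
    blk <- cbind(sub, n)[, append(seq_len(n - 1L), n, after = pos - 1L), drop = FALSE]
    out[r + seq_len(nrow(sub)), ] <- blk
    r <- r + nrow(sub)
  }
  out
}

#' One-factor PERMANOVA
#'
#' Partitions the variance of a distance matrix between groups:
#' `SS_total = sum_{i<j} d_ij^2 / N`, `SS_within = sum_g sum_{i<j in g}
#' d_ij^2 / n_g`, pseudo-F = `((SS_total - SS_within) / (k - 1)) /
#' (SS_within / (N - k))`. The p-value comes from label permutations:
#' `p = (1 + #{F* >= F}) / (1 + n_permutations)` for sampled permutations
#' (observed configuration included, so `p > 0`), or the exact proportion
#' over all `N!` relabelings when `method = "exhaustive"`.
#'
#' @param dm A [distance_matrix()].
#' @param labels Group labels aligned with `dm$sample_ids` (or named by
#'   sample id); `>= 2` groups with `>= 2` samples each.
#' @param n_permutations Number of sampled permutations (default 999).
#' @param seed Optional integer seed for the permutation stream.
#' @param method `"sampled"` (default) or `"exhaustive"`.
#' @return List of class `"permanova_result"`: `pseudo_F`, `SS_total`,
#'   `SS_within`, `df_between`, `df_within`, `n_permutations`, `p_value`,
#'   `method`.
#' @export
permanova <- function(dm, labels, n_permutations = 999, seed = NULL,
                      method = c("sampled", "exhaustive")) {
  stopifnot(inherits(dm, "dist_matrix"))
  method <- match.arg(method)
  if (!is.null(names(labels))) labels <- labels[dm$sample_ids]
  labels <- as.character(labels)
  n <- length(dm$sample_ids)
  if (length(labels) != n || anyNA(labels))
    stop("labels must align with the distance matrix sample order")
  sizes <- table(labels)
  k <- length(sizes)
  if (k < 2L) stop("need at least 2 groups")
  if (any(sizes < 2L))
    stop("group(s) with fewer than 2 samples: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  d2 <- dm$d^2
  ss <- permanova_ss(d2, labels)
  f_obs <- ((ss[["total"]] - ss[["within"]]) / (k - 1)) / (ss[["within"]] / (n - k))
  eps <- 1e-12 * max(1, abs(f_obs))
  if (method == "exhaustive") {
    if (n > 9L) stop("exhaustive enumeration limited to N <= 9")
    perms <- all_permutations(n)
    f_star <- apply(perms, 1L, function(p) permanova_f(d2, labels[p], k, n))
    p_value <- mean(f_star >= f_obs - eps)
    n_used <- nrow(perms)
  } else {
    stop_if_not_scalar_count(n_permutations, "n_permutations")
    f_star <- with_seed(seed, {
      vapply(seq_len(n_permutations),
             function(b) permanova_f(d2, sample(labels), k, n), numeric(1L))
    })
    p_value <- (1 + sum(f_star >= f_obs - eps)) / (1 + n_permutations)
    n_used <- as.integer(n_permutations)
  }
  structure(list(pseudo_F = unname(f_obs),
                 SS_total = ss[["total"]], SS_within = ss[["within"]],
                 df_between = k - 1L, df_within = n - k,
                 n_permutations = n_used, p_value = p_value, method = method),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4f (df %d, %d), p = %.4g [%s, %d permutations]\n",
              x$pseudo_F, x$df_between, x$df_within, x$p_value, x$method,
              x$n_permutations))
  invisible(x)
}
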