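# Shared fixture builders and independent oracles for the test suite.
# Oracles here are written directly from the formula definitions and stay
# independent of the package's implementation paths.

make_counts_table <- function(values, samples = NULL, taxa = NULL) {
  if (is.null(samples)) samples <- paste0("s", seq_len(nrow(values)))
  if (is.null(taxa)) taxa <- paste0("t", seq_len(ncol(values)))
  dimnames(values) <- list(samples, taxa)
  abundance_table(values, "counts")
}

random_counts_table <- function(n_samples, n_taxa, max_count = 50) {
  make_counts_table(matrix(sample(0:max_count, n_samples * n_taxa, replace = TRUE),
                           n_samples, n_taxa))
}

# --- independent formula oracles -------------------------------------------

oracle_shannon <- function(counts) {
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log2(p))
}

oracle_chao1 <- function(counts) {
  s <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  s + f1 * (f1 - 1) / (2 * (f2 + 1))
}

oracle_bray <- function(x, y) {
  1 - 2 * sum(pmin(x, y)) / (sum(x) + sum(y))
}

# Pseudo-F for a squared-distance matrix and labels, from the definition.
oracle_permanova_f <- function(d, labels) {
  d2 <- d^2
  n <- nrow(d2)
  k <- length(unique(labels))
  ss_t <- sum(d2[upper.tri(d2)]) / n
  ss_w <- 0
  for (g in unique(labels)) {
    i <- which(labels == g)
    ss_w <- ss_w + sum(d2[i, i][upper.tri(matrix(0, length(i), length(i)))]) / length(i)
  }
  ((ss_t - ss_w) / (k - 1)) / (ss_w / (n - k))
}

# Exact two-group permutation p by enumerating group-1 index subsets.
oracle_permanova_exact_p <- function(d, labels) {
  n <- nrow(d)
  g1 <- unique(labels)[1L]
  n1 <- sum(labels == g1)
  f_obs <- oracle_permanova_f(d, labels)
  subsets <- utils::combn(n, n1)
  f_all <- apply(subsets, 2L, function(idx) {
    lab <- rep("b", n)
    lab[idx] <- "a"
    oracle_permanova_f(d, lab)
  })
  mean(f_all >= f_obs - 1e-12)
}

# Naive complete-linkage agglomeration: merge heights only.
oracle_complete_linkage_heights <- function(d) {
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      h <- max(d[clusters[[i]], clusters[[j]]])
      if (h < best[1L]) best <- c(h, i, j)
    }
    heights <- c(heights, best[1L])
    clusters[[best[2L]]] <- c(clusters[[best[2L]]], clusters[[best[3L]]])
    clusters[[best[3L]]] <- NULL
  }
  heights
}

# Exhaustive Nugent rubric table generated straight from the scoring rules.
oracle_nugent_table <- function() {
  grid <- expand.grid(lacto = 0:4, gv = 0:4, curved = 0:4)
  lacto_pts <- c(4, 3, 2, 1, 0)[grid$lacto + 1]
  gv_pts <- grid$gv
  curved_pts <- ifelse(grid$curved == 0, 0, ifelse(grid$curved <= 2, 1, 2))
  grid$score <- lacto_pts + gv_pts + curved_pts
  grid
}

# Random symmetric distance-like matrix with zero diagonal.
random_distance <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- matrix(runif(n * 2), n, 2)
  d <- as.matrix(dist(x))
  dimnames(d) <- list(paste0("s", 1:n), paste0("s", 1:n))
  d
}

# Sharp Dirichlet-mixture point cloud with a planted number of clusters.
planted_dirichlet_points <- function(k, n = 60, n_taxa = 10, seed = 1) {
  set.seed(seed)
  pts <- matrix(0, n, n_taxa)
  assign <- sort(rep_len(seq_len(k), n))
  for (i in seq_len(n)) {
    alpha <- rep(0.3, n_taxa)
    alpha[assign[i]] <- 30
    g <- rgamma(n_taxa, alpha, 1)
    pts[i, ] <- g / sum(g)
  }
  list(points = pts, assignment = assign)
}

# Small species-call table exercising CST rules.
cst_fixture_table <- function() {
  taxa <- c("Lactobacillus_crispatus", "Lactobacillus_gasseri",
            "Lactobacillus_iners", "Lactobacillus_jensenii",
            "Gardnerella", "Streptococcus", "Prevotella", "Sneathia")
  m <- rbind(
    crisp = c(0.90, 0.01, 0.02, 0.01, 0.02, 0.01, 0.02, 0.01),
    gasse = c(0.01, 0.85, 0.05, 0.01, 0.03, 0.02, 0.02, 0.01),
    iners = c(0.02, 0.01, 0.80, 0.01, 0.05, 0.05, 0.04, 0.02),
    jense = c(0.01, 0.01, 0.02, 0.88, 0.03, 0.02, 0.02, 0.01),
    strep = c(0.02, 0.01, 0.30, 0.01, 0.10, 0.50, 0.04, 0.02),
    gard  = c(0.02, 0.01, 0.10, 0.01, 0.60, 0.10, 0.10, 0.06),
    dive  = c(0.02, 0.01, 0.10, 0.01, 0.15, 0.10, 0.35, 0.26))
  colnames(m) <- taxa
  abundance_table(m, "relative")
}
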