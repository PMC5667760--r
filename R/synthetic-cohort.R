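# Seeded Dirichlet-multinomial cohort generator. Each sample gets a planted
# community type (CST I/II/III plus three CST IV sub-types), a composition
# drawn from that type's Dirichlet concentration vector over a fixed 25-taxon
# panel, a multinomial read-count vector at a uniform random depth, and
# Gram-stain morphotype quantitation derived from the composition through
# fixed abundance bands (or, with probability `discordance_rate`, from an
# independent draw — emulating slide misreading).

#' Default taxon panel for synthetic cohorts
#'
#' Four CST-defining *Lactobacillus* species calls plus 21 genera typical of
#' diverse vaginal communities (the top-genera range of 16S surveys).
#'
#' @return Character vector of 25 taxon names.
#' @export
default_taxon_panel <- function() {
  c("Lactobacillus_crispatus", "Lactobacillus_gasseri", "Lactobacillus_iners",
    "Lactobacillus_jensenii",
    "Gardnerella", "Prevotella", "Sneathia", "BVAB1", "Streptococcus",
    "Mobiluncus", "Atopobium", "Megasphaera", "Anaerococcus", "Dialister",
    "Peptoniphilus", "Finegoldia", "Escherichia", "Bifidobacterium",
    "Veillonella", "Mycoplasma", "Ureaplasma", "Corynebacterium",
    "Staphylococcus", "Aerococcus", "Porphyromonas")
}

PLANTED_TYPES <- c("I", "II", "III", "IV-Strep", "IV-Gard", "IV-diverse")

# Dirichlet concentration vectors per planted type. Lactobacillus CSTs are
# sharp (dominant weight 40 vs 0.1-1 elsewhere, i.e. >= 40x), matching the
# near-complete dominance real Lactobacillus communities show; CST IV types
# have a leading taxon over a broad anaerobe background.
default_base_compositions <- function(panel = default_taxon_panel()) {
  base <- function(...) {
    a <- stats::setNames(rep(0.1, length(panel)), panel)
    mods <- list(...)
    a[names(mods)] <- unlist(mods)
    a
  }
  anaerobe_bg <- list(Gardnerella = 2, Prevotella = 2, Sneathia = 1, BVAB1 = 1,
                      Atopobium = 1, Megasphaera = 1, Anaerococcus = 1,
                      Dialister = 1, Peptoniphilus = 0.5, Finegoldia = 0.5,
                      Veillonella = 0.5, Porphyromonas = 0.5, Mobiluncus = 0.3,
                      Lactobacillus_iners = 0.3, Lactobacillus_crispatus = 0.2)
  iv <- function(extra) {
    a <- stats::setNames(rep(0.2, length(panel)), panel)
    a[names(anaerobe_bg)] <- unlist(anaerobe_bg)
    a[names(extra)] <- unlist(extra)
    a
  }
  list(
    "I" = base(Lactobacillus_crispatus = 40, Lactobacillus_iners = 1),
    "II" = base(Lactobacillus_gasseri = 40, Lactobacillus_iners = 1),
    "III" = base(Lactobacillus_iners = 40, Lactobacillus_crispatus = 0.5),
    "V" = base(Lactobacillus_jensenii = 40, Lactobacillus_iners = 1),
    "IV-Strep" = iv(list(Streptococcus = 20)),
    "IV-Gard" = iv(list(Gardnerella = 20)),
    "IV-diverse" = iv(list(Prevotella = 4, Sneathia = 4, BVAB1 = 4,
                           Gardnerella = 1.5, Mobiluncus = 1))
  )
}

# Genera whose cells read as Gardnerella/Bacteroides-type morphotypes on a
# Gram stain; BVAB1 and Mobiluncus read as curved rods.
GV_MORPH_GENERA <- c("Gardnerella", "Prevotella", "Porphyromonas", "Atopobium",
                     "Megasphaera", "Dialister", "Anaerococcus", "Peptoniphilus",
                     "Finegoldia", "Veillonella", "Sneathia")
CURVED_MORPH_TAXA <- c("BVAB1", "Mobiluncus")

band_quantitation <- function(frac, thresholds) {
  sum(frac >= thresholds)  # thresholds descending, length 4 -> q in 0..4
}

LACTO_BANDS <- c(0.75, 0.40, 0.15, 0.02)
GV_BANDS <- c(0.75, 0.40, 0.15, 0.02)
CURVED_BANDS <- c(0.40, 0.20, 0.08, 0.01)

morphotypes_from_composition <- function(p) {
  lacto <- sum(p[genus_of(names(p)) == "Lactobacillus"])
  gv <- sum(p[names(p) %in% GV_MORPH_GENERA])
  curved <- sum(p[names(p) %in% CURVED_MORPH_TAXA])
  c(lacto_q = band_quantitation(lacto, LACTO_BANDS),
    gv_q = band_quantitation(gv, GV_BANDS),
    curved_q = band_quantitation(curved, CURVED_BANDS))
}

#' Specification of a synthetic cohort
#'
#' @param group_sizes Named integer vector, group -> number of samples.
#' @param cst_mixture Named list, group -> probability vector over the six
#'   planted types (`I`, `II`, `III`, `IV-Strep`, `IV-Gard`, `IV-diverse`);
#'   each must sum to 1 within `1e-9`.
#' @param base_compositions Named list, planted type -> Dirichlet
#'   concentration vector over the taxon panel; default
#'   `default_base_compositions()`.
#' @param depth_range Integer `c(min, max)` sequencing depth, `min >= 1`.
#' @param discordance_rate Probability in `[0, 1]` that a sample's morphotype
#'   scores are generated independently of its composition.
#' @param cycle_probs Named list, group -> probability vector over
#'   `proliferative`, `secretory`, `hormonal_contraceptive`, `unknown`.
#' @param seed Default seed used by [generate_cohort()] when none is given.
#' @return List of class `"cohort_spec"`.
#' @export
cohort_spec <- function(group_sizes, cst_mixture,
                        base_compositions = default_base_compositions(),
                        depth_range = c(6791L, 54288L),
                        discordance_rate = 0.15,
                        cycle_probs = NULL, seed = 1L) {
  stopifnot(length(group_sizes) >= 1L, all(group_sizes >= 1L),
            !is.null(names(group_sizes)))
  if (depth_range[1L] < 1L || depth_range[2L] < depth_range[1L])
    stop("invalid depth_range")
  if (discordance_rate < 0 || discordance_rate > 1)
    stop("discordance_rate must be in [0, 1]")
  for (g in names(group_sizes)) {
    mix <- cst_mixture[[g]]
    if (is.null(mix) || abs(sum(mix) - 1) > 1e-9)
      stop("cst_mixture for group '", g, "' must sum to 1")
    if (!all(names(mix) %in% names(base_compositions)))
      stop("cst_mixture for group '", g, "' names types without base compositions")
  }
  panel <- names(base_compositions[[1L]])
  for (ty in names(base_compositions)) {
    a <- base_compositions[[ty]]
    if (!identical(names(a), panel)) stop("base compositions must share one taxon panel")
    dom <- names(a)[which.max(a)]
    if (!dom %in% panel) stop("panel missing dominant taxon for type ", ty)
  }
  if (is.null(cycle_probs))
    cycle_probs <- stats::setNames(rep(list(c(proliferative = 0.05, secretory = 0.25,
                                              hormonal_contraceptive = 0.3,
                                              unknown = 0.4)),
                                       length(group_sizes)), names(group_sizes))
  structure(list(group_sizes = group_sizes, cst_mixture = cst_mixture,
                 base_compositions = base_compositions,
                 depth_range = as.integer(depth_range),
                 discordance_rate = discordance_rate,
                 cycle_probs = cycle_probs, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Paper-scale two-group cohort specification
#'
#' 19 NSW (non-sex workers) and 48 FSW (female sex workers) with CST
#' mixtures taken from the study-population contingency table this generator
#' emulates: NSW 2/1/8/8 across CST I/II/III/IV, FSW 5/1/1/41 (CST IV mass
#' split 20/30/50 across the *Streptococcus*, *Gardnerella* and diverse
#' sub-types). Depth range 6791-54288 reads; menstrual-cycle frequencies per
#' group from the same population.
#'
#' @param discordance_rate Morphotype discordance probability (default 0.15).
#' @param seed Default generation seed.
#' @return A [cohort_spec()].
#' @export
preset_paper_like <- function(discordance_rate = 0.15, seed = 1L) {
  iv_split <- c("IV-Strep" = 0.2, "IV-Gard" = 0.3, "IV-diverse" = 0.5)
  mix <- function(i, ii, iii, iv) {
    c(I = i, II = ii, III = iii, iv * iv_split)
  }
  cohort_spec(
    group_sizes = c(NSW = 19L, FSW = 48L),
    cst_mixture = list(NSW = mix(2 / 19, 1 / 19, 8 / 19, 8 / 19),
                       FSW = mix(5 / 48, 1 / 48, 1 / 48, 41 / 48)),
    depth_range = c(6791L, 54288L),
    discordance_rate = discordance_rate,
    cycle_probs = list(NSW = c(proliferative = 0 / 19, secretory = 1 / 19,
                               hormonal_contraceptive = 8 / 19, unknown = 10 / 19),
                       FSW = c(proliferative = 3 / 48, secretory = 17 / 48,
                               hormonal_contraceptive = 10 / 48, unknown = 18 / 48)),
    seed = seed)
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  stats::setNames(g / sum(g), names(alpha))
}

#' Generate a synthetic cohort
#'
#' Draws, per sample: a planted community type from its group's mixture, a
#' composition from that type's Dirichlet concentrations, a read depth
#' uniform in `depth_range`, multinomial counts, morphotype quantitation from
#' composition bands (independent redraw with probability
#' `discordance_rate`), a Nugent score from the rubric, menstrual-cycle
#' stage, age, and the sample's top-5 genera. Fully reproducible by seed.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed (default `spec$seed`).
#' @return List of class `"vm_cohort"`: `counts` (species-call level
#'   [abundance_table()], counts mode), `relative` (genus-level relative
#'   [abundance_table()]), `metadata` (data.frame: sample_id, group, age,
#'   cycle_stage, lacto_q/gv_q/curved_q, nugent_score, nugent_category,
#'   morphotype_discordant, top5_genera list column), `truth` (data.frame of
#'   planted type and CST per sample).
#' @export
generate_cohort <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  panel <- names(spec$base_compositions[[1L]])
  with_seed(seed, {
    rows <- list(); meta <- list(); truth <- list()
    i_all <- 0L
    for (g in names(spec$group_sizes)) {
      mix <- spec$cst_mixture[[g]]
      for (i in seq_len(spec$group_sizes[[g]])) {
        i_all <- i_all + 1L
        sid <- sprintf("%s_%02d", g, i)
        planted <- sample(names(mix), 1L, prob = mix)
        p <- rdirichlet1(spec$base_compositions[[planted]])
        depth <- sample(seq(spec$depth_range[1L], spec$depth_range[2L]), 1L)
        cnt <- as.integer(stats::rmultinom(1L, depth, p))
        discordant <- stats::runif(1L) < spec$discordance_rate
        q <- if (discordant) {
          alt_type <- sample(names(mix), 1L, prob = mix)
          morphotypes_from_composition(rdirichlet1(spec$base_compositions[[alt_type]]))
        } else {
          morphotypes_from_composition(p)
        }
        ns <- nugent_score(q[["lacto_q"]], q[["gv_q"]], q[["curved_q"]])
        cyc <- sample(names(spec$cycle_probs[[g]]), 1L, prob = spec$cycle_probs[[g]])
        age <- as.integer(round(min(45, max(19, stats::rnorm(1L, 30, 6)))))
        rows[[i_all]] <- cnt
        meta[[i_all]] <- data.frame(
          sample_id = sid, group = g, age = age, cycle_stage = cyc,
          lacto_q = q[["lacto_q"]], gv_q = q[["gv_q"]], curved_q = q[["curved_q"]],
          nugent_score = ns$score, nugent_category = ns$category,
          morphotype_discordant = discordant, stringsAsFactors = FALSE)
        truth[[i_all]] <- data.frame(
          sample_id = sid, group = g, planted_type = planted,
          planted_cst = sub("-.*$", "", planted), stringsAsFactors = FALSE)
      }
    }
    counts <- do.call(rbind, rows)
    dimnames(counts) <- list(vapply(meta, `[[`, "", "sample_id"), panel)
    counts_tab <- abundance_table(counts, "counts")
    genus_tax <- stats::setNames(genus_of(panel), panel)
    genus_rel <- renormalize(collapse_to_genus(counts_tab, genus_tax))
    metadata <- do.call(rbind, meta)
    metadata$top5_genera <- top_taxa(genus_rel, 5L)$per_sample[metadata$sample_id]
    truth <- do.call(rbind, truth)
    rownames(metadata) <- rownames(truth) <- NULL
    structure(list(counts = counts_tab, relative = genus_rel,
                   metadata = metadata, truth = truth, spec = spec,
                   seed = as.integer(seed)),
              class = "vm_cohort")
  })
}

#' @export
print.vm_cohort <- function(x, ...) {
  cat(sprintf("Synthetic vaginal-microbiota cohort: %d samples (%s), %d taxa, seed %d\n",
              nrow(x$counts),
              paste(sprintf("%s n=%d", names(x$spec$group_sizes), x$spec$group_sizes),
                    collapse = ", "),
              ncol(x$counts), x$seed))
  print(table(planted = x$truth$planted_type, group = x$truth$group))
  invisible(x)
}
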