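# Nugent scoring from Gram-stain morphotype quantitation, and the
# concordance rule comparing morphotypes seen under the microscope with the
# top-5 genera from 16S sequencing.
#
# The Nugent rubric converts three 0-4 morphotype quantitation scores to
# points: Lactobacillus morphotypes are scored inversely (abundant
# lactobacilli are healthy), Gardnerella/Bacteroides morphotypes directly,
# and Mobiluncus-type curved rods on a compressed 0-2 scale. The summed
# 0-10 score is categorized 0-3 (normal), 4-6 (intermediate), 7-10 (BV).

MORPHOTYPE_CLASSES <- c("Lactobacillus", "GV_Bacteroides", "Mobiluncus")

#' Default genus-to-morphotype map
#'
#' Maps 16S genera to the Gram-stain morphotype class they would present as:
#' *Lactobacillus* rods; *Gardnerella*/*Bacteroides*-type coccobacilli (here
#' also *Prevotella* and *Porphyromonas*, historically split out of
#' *Bacteroides*); *Mobiluncus* curved rods. All other genera map to no
#' class. BVAB1 is deliberately unmapped by default even though it is a
#' curved rod often scored as a *Mobiluncus* morphotype — the map is a plain
#' named vector so users can recalibrate it against their own slide-reading
#' conventions.
#'
#' @return Named character vector (genus -> morphotype class).
#' @export
default_morphotype_map <- function() {
  c(Lactobacillus = "Lactobacillus",
    Gardnerella = "GV_Bacteroides",
    Bacteroides = "GV_Bacteroides",
    Prevotella = "GV_Bacteroides",
    Porphyromonas = "GV_Bacteroides",
    Mobiluncus = "Mobiluncus")
}

check_quantitation <- function(q, what) {
  if (anyNA(q) || any(q < 0 | q > 4 | q != floor(q)))
    stop(sprintf("`%s` must be integer quantitation in [0, 4]", what))
  as.integer(q)
}

#' Nugent score from morphotype quantitation
#'
#' Vectorized over samples. Points: Lactobacillus 4->0, 3->1, 2->2, 1->3,
#' 0->4; G. vaginalis/Bacteroides identity 0->0 ... 4->4; curved rods 0->0,
#' 1-2 -> 1, 3-4 -> 2.
#'
#' @param lacto_q,gv_q,curved_q Integer quantitation scores in `[0, 4]` for
#'   the three morphotype classes.
#' @return `data.frame`: the inputs, per-class points, `score` (0-10) and
#'   `category` (`"0-3"`, `"4-6"`, `"7-10"`).
#' @examples
#' nugent_score(4, 0, 0)  # score 0, normal
#' nugent_score(0, 4, 4)  # score 10, BV
#' @export
nugent_score <- function(lacto_q, gv_q, curved_q) {
  lacto_q <- check_quantitation(lacto_q, "lacto_q")
  gv_q <- check_quantitation(gv_q, "gv_q")
  curved_q <- check_quantitation(curved_q, "curved_q")
  stopifnot(length(lacto_q) == length(gv_q), length(gv_q) == length(curved_q))
  lacto_points <- 4L - lacto_q
  gv_points <- gv_q
  curved_points <- c(0L, 1L, 1L, 2L, 2L)[curved_q + 1L]
  score <- lacto_points + gv_points + curved_points
  data.frame(lacto_q = lacto_q, gv_q = gv_q, curved_q = curved_q,
             lacto_points = lacto_points, gv_points = gv_points,
             curved_points = curved_points, score = score,
             category = nugent_category(score), stringsAsFactors = FALSE)
}

#' Nugent category from a score
#' @param score Integer Nugent score 0-10.
#' @return Character: `"0-3"`, `"4-6"` or `"7-10"`.
#' @export
nugent_category <- function(score) {
  if (any(score < 0 | score > 10, na.rm = TRUE)) stop("Nugent score must be in [0, 10]")
  as.character(cut(score, breaks = c(-1, 3, 6, 10), labels = c("0-3", "4-6", "7-10")))
}

#' Morphotype classes observed under microscopy
#'
#' A class counts as observed when its quantitation reaches `threshold`
#' (default 1, i.e. any recorded presence).
#'
#' @inheritParams nugent_score
#' @param threshold Minimum quantitation to count as observed (`>= 1`).
#' @return For scalar input, a character vector (subset of
#'   `Lactobacillus`, `GV_Bacteroides`, `Mobiluncus`); for vector input, a
#'   list of such vectors.
#' @export
morphotype_classes_observed <- function(lacto_q, gv_q, curved_q, threshold = 1) {
  if (threshold < 1) stop("threshold must be >= 1")
  lacto_q <- check_quantitation(lacto_q, "lacto_q")
  gv_q <- check_quantitation(gv_q, "gv_q")
  curved_q <- check_quantitation(curved_q, "curved_q")
  res <- lapply(seq_along(lacto_q), function(i)
    MORPHOTYPE_CLASSES[c(lacto_q[i], gv_q[i], curved_q[i]) >= threshold])
  if (length(res) == 1L) res[[1L]] else res
}

#' Morphotype / top-5-genera agreement for one sample
#'
#' "Complete agreement" holds when every morphotype class observed by
#' microscopy is represented by at least one of the sample's top-5 sequenced
#' genera under the genus-to-morphotype map. An empty observed set agrees
#' vacuously (flagged for audit). Adding genera to the top-5 list can only
#' add matches, never remove them.
#'
#' @param observed_morphotypes Character vector (possibly empty), subset of
#'   the three morphotype classes.
#' @param top5_genera Character vector of genus names (species calls of the
#'   form `Genus_species` are reduced to their genus).
#' @param genus_map Named character vector genus -> morphotype class;
#'   default [default_morphotype_map()].
#' @return List of class `"concordance_record"`: `observed_morphotypes`,
#'   `top5_genera`, `matched_morphotypes`, `complete_agreement`, `vacuous`.
#' @export
agreement <- function(observed_morphotypes, top5_genera,
                      genus_map = default_morphotype_map()) {
  observed_morphotypes <- as.character(observed_morphotypes)
  bad <- setdiff(observed_morphotypes, MORPHOTYPE_CLASSES)
  if (length(bad) > 0L) stop("unknown morphotype class(es): ", paste(bad, collapse = ", "))
  vacuous <- length(observed_morphotypes) == 0L
  if (length(top5_genera) == 0L && !vacuous)
    warning("empty top-5 list with observed morphotypes: scored as disagreement")
  present_classes <- unique(unname(genus_map[genus_of(as.character(top5_genera))]))
  matched <- intersect(observed_morphotypes, present_classes)
  structure(list(observed_morphotypes = observed_morphotypes,
                 top5_genera = as.character(top5_genera),
                 matched_morphotypes = matched,
                 complete_agreement = setequal(matched, observed_morphotypes),
                 vacuous = vacuous),
            class = "concordance_record")
}

#' Cohort concordance summary, stratified by group and CST
#'
#' Applies [agreement()] per sample and summarizes the complete-agreement
#' rate overall, per group, and per group within the two CST strata
#' (*Lactobacillus*-dominant CST I-III pooled vs high-diversity CST IV).
#' Samples without morphotype data (any quantitation `NA`) are excluded from
#' denominators and counted separately.
#'
#' @param metadata `data.frame` with `sample_id`, `group`, `lacto_q`, `gv_q`,
#'   `curved_q`, and `top5_genera` (list column of character vectors, or a
#'   `";"`-separated character column).
#' @param cst Output of [assign_cst()] covering the same samples.
#' @param genus_map Genus -> morphotype map; default
#'   [default_morphotype_map()].
#' @param threshold Observation threshold for
#'   [morphotype_classes_observed()].
#' @return List of class `"concordance_summary"`: `records` (per-sample
#'   data.frame with agreement flags), `rates` (data.frame of stratum /
#'   n_agree / n_total / rate), `n_excluded`.
#' @export
concordance_summary <- function(metadata, cst,
                                genus_map = default_morphotype_map(),
                                threshold = 1) {
  need <- c("sample_id", "group", "lacto_q", "gv_q", "curved_q", "top5_genera")
  miss <- setdiff(need, names(metadata))
  if (length(miss) > 0L) stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  top5 <- metadata$top5_genera
  if (!is.list(top5)) top5 <- strsplit(as.character(top5), ";", fixed = TRUE)
  has_morph <- !(is.na(metadata$lacto_q) | is.na(metadata$gv_q) | is.na(metadata$curved_q))
  cst_of <- cst$cst[match(metadata$sample_id, cst$sample_id)]
  stratum <- ifelse(cst_of %in% c("I", "II", "III", "V"), "lacto_dominant_cst",
                    "cst_iv")
  rec <- lapply(which(has_morph), function(i) {
    obs <- morphotype_classes_observed(metadata$lacto_q[i], metadata$gv_q[i],
                                       metadata$curved_q[i], threshold = threshold)
    a <- agreement(obs, top5[[i]], genus_map = genus_map)
    data.frame(sample_id = metadata$sample_id[i],
               group = as.character(metadata$group[i]),
               cst = cst_of[i], stratum = stratum[i],
               observed = paste(a$observed_morphotypes, collapse = ";"),
               matched = paste(a$matched_morphotypes, collapse = ";"),
               complete_agreement = a$complete_agreement,
               vacuous = a$vacuous, stringsAsFactors = FALSE)
  })
  records <- do.call(rbind, rec)
  rate_row <- function(label, flags) {
    data.frame(stratum = label, n_agree = sum(flags), n_total = length(flags),
               rate = if (length(flags) > 0L) mean(flags) else NA_real_,
               stringsAsFactors = FALSE)
  }
  rates <- rate_row("overall", records$complete_agreement)
  for (g in sort(unique(records$group))) {
    in_g <- records$group == g
    rates <- rbind(rates, rate_row(g, records$complete_agreement[in_g]))
    for (s in c("lacto_dominant_cst", "cst_iv")) {
      flags <- records$complete_agreement[in_g & records$stratum == s]
      if (length(flags) == 0L) {
        warning(sprintf("empty stratum %s/%s omitted", g, s))
        next
      }
      rates <- rbind(rates, rate_row(paste(g, s, sep = "_"), flags))
    }
  }
  structure(list(records = records, rates = rates,
                 n_excluded = sum(!has_morph)),
            class = "concordance_summary")
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat(sprintf("Morphotype/16S concordance (%d samples scored, %d excluded):\n",
              nrow(x$records), x$n_excluded))
  print(transform(x$rates, rate = round(rate, 3)), row.names = FALSE)
  invisible(x)
}
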