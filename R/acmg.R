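# A modified ACMG/AMP 2015 rule engine. Criteria are evaluated from
# per-variant evidence (functional category, CADD, SpliceAI, ClinVar
# assertion + review stars, pass-through flags), then combined by the 2015
# table into B < LB < VUS < LP < P.
#
# Modifications mirrored from the automated-platform setup this package
# models: PVS1 fires directly from a loss-of-function functional category;
# PP3 is disabled whenever PVS1 fires; PP3/BP4 use CADD >= 25.3 / < 22.7
# and SpliceAI 0.5; PP5/BP6 strength scales with review stars (two-star:
# moderate/strong, three-or-more: very strong); PS4, PM3, PP4, BP2 and BP5
# are excluded (they need cohort, phasing or gene-disease data).

.PATHOGENIC_DEFAULTS <- c(
  PVS1 = "very_strong",
  PS1 = "strong", PS2 = "strong", PS3 = "strong", PS4 = "strong",
  PM1 = "moderate", PM2 = "moderate", PM3 = "moderate", PM4 = "moderate",
  PM5 = "moderate", PM6 = "moderate",
  PP1 = "supporting", PP2 = "supporting", PP3 = "supporting",
  PP4 = "supporting", PP5 = "supporting")

.BENIGN_DEFAULTS <- c(
  BA1 = "standalone",
  BS1 = "strong", BS2 = "strong", BS3 = "strong", BS4 = "strong",
  BP1 = "supporting", BP2 = "supporting", BP3 = "supporting",
  BP4 = "supporting", BP5 = "supporting", BP6 = "supporting",
  BP7 = "supporting")

.criterion_direction <- function(id) {
  ifelse(id %in% names(.BENIGN_DEFAULTS), "benign", "pathogenic")
}

.criterion_default_strength <- function(id) {
  both <- c(.PATHOGENIC_DEFAULTS, .BENIGN_DEFAULTS)
  out <- unname(both[id])
  if (anyNA(out)) stop("unknown criterion id: ",
                       paste(id[is.na(out)], collapse = ", "))
  out
}

#' ACMG engine configuration
#'
#' @param pp3_cadd_min CADD threshold at or above which PP3 fires.
#' @param bp4_cadd_max CADD threshold below which BP4 fires
#'   (must be below `pp3_cadd_min`).
#' @param spliceai_min SpliceAI delta-score threshold for splice impact.
#' @param pp5_star_map,bp6_star_map named strength per review-star tier;
#'   names are the minimum stars for that tier, applied from the highest
#'   tier down.
#' @param disabled criteria that never fire.
#' @param benign_vs_sufficient treat one benign very-strong criterion as
#'   sufficient for Benign (the 2015 table predates benign very-strong
#'   strengths; this mirrors the pathogenic side's weighting).
#' @return list of class `"acmg_config"`.
#' @export
acmg_config <- function(pp3_cadd_min = 25.3, bp4_cadd_max = 22.7,
                        spliceai_min = 0.5,
                        pp5_star_map = c("2" = "moderate",
                                         "3" = "very_strong"),
                        bp6_star_map = c("2" = "strong",
                                         "3" = "very_strong"),
                        disabled = c("PS4", "PM3", "PP4", "BP2", "BP5"),
                        benign_vs_sufficient = TRUE) {
  stopifnot(pp3_cadd_min > bp4_cadd_max)
  structure(list(pp3_cadd_min = pp3_cadd_min, bp4_cadd_max = bp4_cadd_max,
                 spliceai_min = spliceai_min, pp5_star_map = pp5_star_map,
                 bp6_star_map = bp6_star_map, disabled = disabled,
                 benign_vs_sufficient = isTRUE(benign_vs_sufficient)),
            class = "acmg_config")
}

.star_strength <- function(stars, map) {
  tiers <- sort(as.integer(names(map)), decreasing = TRUE)
  for (t in tiers) if (!is.na(stars) && stars >= t)
    return(unname(map[as.character(t)]))
  NA_character_
}

.applied <- function(criterion = character(0), strength = character(0)) {
  data.frame(criterion = criterion, strength = strength,
             direction = .criterion_direction(criterion),
             stringsAsFactors = FALSE)
}

#' Evaluate the modified ACMG criteria from per-variant evidence
#'
#' PVS1 fires iff the functional category is LoF; PP3 (CADD or SpliceAI
#' above threshold) is suppressed under PVS1; BP4 needs low CADD and no
#' splice signal; PP5/BP6 fire from the ClinVar assertion at star-scaled
#' strength; PM4 from ProteinLengthChange; BP7 from Synonymous without
#' splice signal. External flags (PS1, PM5, PM2, ...) pass through at
#' default strength. Disabled criteria never fire. Absent evidence simply
#' never triggers.
#'
#' @param evidence list or one-row data.frame with `functional_category`,
#'   optional `cadd`, optional `spliceai_max`, `clinvar_class`
#'   (P/LP/B/LB or NA), `stars`, and optionally `external`, a character
#'   vector of externally asserted criterion ids (or a named logical
#'   vector).
#' @param cfg an [acmg_config()].
#' @return data.frame of applied criteria: `criterion`, `strength`,
#'   `direction`.
#' @export
evaluate_criteria <- function(evidence, cfg = acmg_config()) {
  e <- evidence
  num <- function(x) if (is.null(x) || length(x) == 0) NA_real_
                     else suppressWarnings(as.numeric(x))
  cadd <- num(e$cadd); splice <- num(e$spliceai_max)
  if (!is.na(splice) && (splice < 0 || splice > 1))
    stop("spliceai_max outside [0,1]")
  stars <- if (is.null(e$stars)) NA_integer_ else as.integer(e$stars)
  category <- if (is.null(e$functional_category)) NA_character_
              else as.character(e$functional_category)
  cls <- if (is.null(e$clinvar_class)) NA_character_
         else as.character(e$clinvar_class)
  crit <- character(0); strength <- character(0)
  add <- function(id, s = .criterion_default_strength(id)) {
    crit <<- c(crit, id); strength <<- c(strength, s)
  }
  pvs1 <- isTRUE(category == "LoF")
  if (pvs1) add("PVS1")
  splice_hit <- !is.na(splice) && splice >= cfg$spliceai_min
  if (!pvs1 && ((!is.na(cadd) && cadd >= cfg$pp3_cadd_min) || splice_hit))
    add("PP3")
  if (!is.na(cadd) && cadd < cfg$bp4_cadd_max && !splice_hit)
    add("BP4")
  if (!is.na(cls) && cls %in% c("P", "LP")) {
    s <- .star_strength(stars, cfg$pp5_star_map)
    if (!is.na(s)) add("PP5", s)
  }
  if (!is.na(cls) && cls %in% c("B", "LB")) {
    s <- .star_strength(stars, cfg$bp6_star_map)
    if (!is.na(s)) add("BP6", s)
  }
  if (isTRUE(category == "ProteinLengthChange")) add("PM4")
  if (isTRUE(category == "Synonymous") && !splice_hit) add("BP7")
  ext <- e$external
  if (!is.null(ext)) {
    if (is.logical(ext)) ext <- names(ext)[ext]
    ext <- unlist(ext, use.names = FALSE)
    for (id in setdiff(ext, crit)) add(id)
  }
  out <- .applied(crit, strength)
  out <- out[!out$criterion %in% cfg$disabled, , drop = FALSE]
  if (anyDuplicated(out$criterion))
    stop("criterion applied twice: ",
         out$criterion[duplicated(out$criterion)][1])
  rownames(out) <- NULL
  out
}

.CLASS_LEVELS <- c("B", "LB", "VUS", "LP", "P")

#' Combine applied criteria into a five-tier classification
#'
#' Implements the 2015 combining table over strength counts, each side
#' evaluated independently; both sides met, or neither, gives VUS.
#' Pathogenic very-strong criteria beyond the first count as strong
#' (so two very-strongs classify as Pathogenic); one benign very-strong
#' suffices for Benign when the config says so.
#'
#' @param applied data.frame from [evaluate_criteria()].
#' @param cfg an [acmg_config()] (only `benign_vs_sufficient` is used).
#' @return one of `"B"`, `"LB"`, `"VUS"`, `"LP"`, `"P"`.
#' @examples
#' combine_criteria(data.frame(criterion = c("PVS1", "PM2"),
#'                             strength = c("very_strong", "moderate"),
#'                             direction = "pathogenic"))
#' @export
combine_criteria <- function(applied, cfg = acmg_config()) {
  cnt <- function(dir, s) sum(applied$direction == dir &
                                applied$strength == s)
  vs <- cnt("pathogenic", "very_strong")
  s  <- cnt("pathogenic", "strong") + max(0L, vs - 1L)
  m  <- cnt("pathogenic", "moderate")
  p  <- cnt("pathogenic", "supporting")
  vs <- min(vs, 1L)
  ba  <- cnt("benign", "standalone")
  bvs <- cnt("benign", "very_strong")
  bs  <- cnt("benign", "strong")
  bp  <- cnt("benign", "supporting")
  pathogenic <-
    (vs >= 1 && (s >= 1 || m >= 2 || (m >= 1 && p >= 1) || p >= 2)) ||
    s >= 2 ||
    (s >= 1 && (m >= 3 || (m >= 2 && p >= 2) || (m >= 1 && p >= 4)))
  likely_pathogenic <-
    (vs >= 1 && m >= 1) ||
    (s >= 1 && m >= 1) || (s >= 1 && p >= 2) ||
    m >= 3 || (m >= 2 && p >= 2) || (m >= 1 && p >= 4)
  benign <- ba >= 1 || bs >= 2 ||
    (cfg$benign_vs_sufficient && bvs >= 1) ||
    (!cfg$benign_vs_sufficient && bvs + bs >= 2)
  likely_benign <- ((bs + bvs) >= 1 && bp >= 1) || bp >= 2
  path_side <- if (pathogenic) "P" else if (likely_pathogenic) "LP" else NA
  ben_side <- if (benign) "B" else if (likely_benign) "LB" else NA
  if (!is.na(path_side) && !is.na(ben_side)) return("VUS")
  if (!is.na(path_side)) return(path_side)
  if (!is.na(ben_side)) return(ben_side)
  "VUS"
}

#' Classify a variant from evidence
#'
#' `combine_criteria` composed with `evaluate_criteria`; the applied set is
#' returned alongside for audit.
#'
#' @inheritParams evaluate_criteria
#' @return list with `class` (one of B/LB/VUS/LP/P) and `applied`.
#' @export
classify_acmg <- function(evidence, cfg = acmg_config()) {
  applied <- evaluate_criteria(evidence, cfg)
  list(class = combine_criteria(applied, cfg), applied = applied)
}

#' The classification order B < LB < VUS < LP < P as an ordered factor
#' @param x character vector of class labels.
#' @return ordered factor.
#' @export
classification_factor <- function(x) {
  factor(x, levels = .CLASS_LEVELS, ordered = TRUE)
}
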