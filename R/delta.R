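# Delta analysis: how discordant consequence calls move the PVS1 criterion
# (loss / gain) and the final five-tier classification
# (upgraded / unchanged / downgraded) relative to the reference.

#' PVS1 status changes implied by category discordance
#'
#' For each (reference category, tool category) pair: `pvs1_loss` when the
#' reference is LoF and the tool is not, `pvs1_gain` for the converse,
#' `none` otherwise. Within-LoF term changes (e.g. nonsense read as
#' frameshift) keep the category and therefore PVS1.
#'
#' @param reference_category,tool_category character vectors of functional
#'   categories.
#' @return list with `deltas` (per-pair data.frame: status,
#'   `category_changed`) and `summary` counts (`pvs1_loss`, `pvs1_gain`,
#'   `changed_within_none`, `unchanged`).
#' @examples
#' pvs1_delta("LoF", "Missense")$summary
#' @export
pvs1_delta <- function(reference_category, tool_category) {
  stopifnot(length(reference_category) == length(tool_category))
  ref_lof <- reference_category == "LoF"
  tool_lof <- tool_category == "LoF"
  status <- ifelse(ref_lof & !tool_lof, "pvs1_loss",
                   ifelse(!ref_lof & tool_lof, "pvs1_gain", "none"))
  changed <- reference_category != tool_category
  deltas <- data.frame(reference_category = reference_category,
                       tool_category = tool_category,
                       status = status, category_changed = changed,
                       stringsAsFactors = FALSE)
  summary <- c(pvs1_loss = sum(status == "pvs1_loss"),
               pvs1_gain = sum(status == "pvs1_gain"),
               changed_within_none = sum(status == "none" & changed),
               unchanged = sum(!changed))
  stopifnot(sum(summary[c("pvs1_loss", "pvs1_gain")]) +
              sum(status == "none") == length(status))
  list(deltas = deltas, summary = summary)
}

#' Reclassify under the tool's category and compare with the reference call
#'
#' Each variant is classified twice with [classify_acmg()]: once with the
#' reference functional category and once with the tool's, all other
#' evidence held fixed (this mirrors reassessing only the criteria that a
#' consequence change can move). The direction follows the order
#' B < LB < VUS < LP < P.
#'
#' @param evidence data.frame with one row per variant: the
#'   [evaluate_criteria()] evidence columns plus `reference_category` and
#'   `tool_category`.
#' @param cfg an [acmg_config()].
#' @param no_conflict_only keep only variants whose reference-based class
#'   agrees with the recorded ClinVar class (`clinvar_class` column), the
#'   pre-filter used before reassessment; default on.
#' @return data.frame with reference and tool classes and `direction`
#'   (`upgraded` / `unchanged` / `downgraded`), one row per retained
#'   variant.
#' @export
reclassify_delta <- function(evidence, cfg = acmg_config(),
                             no_conflict_only = TRUE) {
  n <- nrow(evidence)
  ref_class <- character(n); tool_class <- character(n)
  for (i in seq_len(n)) {
    e <- as.list(evidence[i, , drop = FALSE])
    e$functional_category <- evidence$reference_category[i]
    ref_class[i] <- classify_acmg(e, cfg)$class
    e$functional_category <- evidence$tool_category[i]
    tool_class[i] <- classify_acmg(e, cfg)$class
  }
  keep <- rep(TRUE, n)
  if (no_conflict_only && "clinvar_class" %in% names(evidence))
    keep <- ref_class == as.character(evidence$clinvar_class)
  ord <- classification_factor(tool_class)
  ref_ord <- classification_factor(ref_class)
  direction <- ifelse(ord > ref_ord, "upgraded",
                      ifelse(ord < ref_ord, "downgraded", "unchanged"))
  out <- data.frame(reference_class = ref_class, tool_class = tool_class,
                    direction = direction,
                    clinvar_class = if ("clinvar_class" %in% names(evidence))
                      as.character(evidence$clinvar_class) else NA_character_,
                    stringsAsFactors = FALSE)
  out[keep, , drop = FALSE]
}

#' Summarize deltas into stacked-bar-ready counts and proportions
#'
#' @param group grouping labels (e.g. the reference ClinVar class, or a
#'   tool name), one per delta.
#' @param outcome outcome labels (e.g. `changed`/`unchanged`, or the
#'   direction), one per delta.
#' @return data.frame of per-group outcome counts and proportions;
#'   proportions sum to 1 within each group. Empty input gives an empty
#'   report.
#' @examples
#' summarize_deltas(rep("annovar", 532),
#'                  rep(c("changed", "unchanged"), c(185, 347)))
#' @export
summarize_deltas <- function(group, outcome) {
  stopifnot(length(group) == length(outcome))
  if (length(group) == 0)
    return(data.frame(group = character(0), outcome = character(0),
                      count = integer(0), proportion = numeric(0)))
  tab <- as.data.frame(table(group = group, outcome = outcome),
                       stringsAsFactors = FALSE)
  names(tab)[3] <- "count"
  tab <- tab[tab$count > 0 | TRUE, ]
  tot <- stats::ave(tab$count, tab$group, FUN = sum)
  tab$proportion <- ifelse(tot > 0, tab$count / tot, NA_real_)
  tab <- tab[tot > 0, ]
  rownames(tab) <- NULL
  tab
}
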