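# Sequence Ontology normalization: per-tool consequence vocabularies are
# mapped to one canonical SO term set carrying a strict severity order
# (most severe first), then binned into the ACMG-facing functional
# categories LoF / Missense / ProteinLengthChange / Synonymous / Other.
#
# Both the severity order and the synonym map ship as editable TSVs under
# inst/extdata/ so an alternative table can be slotted in.

.so_env <- new.env(parent = emptyenv())

#' The canonical SO severity table
#'
#' @param path optional TSV with columns `rank`, `canonical_term` replacing
#'   the shipped table (most severe first, each term exactly once).
#' @return character vector of canonical SO terms, most severe first.
#' @export
severity_table <- function(path = NULL) {
  if (is.null(path)) {
    if (is.null(.so_env$severity)) {
      path <- system.file("extdata", "so_severity.tsv",
                          package = "varconcord", mustWork = TRUE)
      tab <- utils::read.delim(path, stringsAsFactors = FALSE)
      .so_env$severity <- tab$canonical_term[order(tab$rank)]
    }
    return(.so_env$severity)
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  terms <- tab$canonical_term[order(tab$rank)]
  if (anyDuplicated(terms)) stop("severity table has duplicated terms")
  terms
}

#' The per-tool consequence synonym map
#'
#' @param path optional TSV with columns `tool`, `raw_term`,
#'   `canonical_term` replacing the shipped map. Raw terms are matched
#'   case-insensitively with spaces/hyphens read as underscores; canonical
#'   terms pass through unchanged for every tool.
#' @return data.frame with columns `tool`, `raw_term`, `canonical_term`.
#' @export
synonym_map <- function(path = NULL) {
  if (is.null(path)) {
    if (is.null(.so_env$synonyms)) {
      path <- system.file("extdata", "so_synonyms.tsv",
                          package = "varconcord", mustWork = TRUE)
      .so_env$synonyms <- utils::read.delim(path, stringsAsFactors = FALSE)
    }
    return(.so_env$synonyms)
  }
  utils::read.delim(path, stringsAsFactors = FALSE)
}

.norm_key <- function(x) gsub("[ -]", "_", tolower(trimws(x)))

#' Normalize a raw consequence term onto the canonical SO vocabulary
#'
#' Deterministic and case-insensitive; unknown terms map to the sentinel
#' `"unmapped"` rather than being dropped.
#'
#' @param raw character vector of raw tool terms.
#' @param tool one of `"annovar"`, `"snpeff"`, `"vep"`, `"clinvar"`,
#'   `"synthetic"` (selects the synonym dialect).
#' @param map optional synonym map (see [synonym_map()]).
#' @param severity optional severity table (see [severity_table()]).
#' @return character vector of canonical terms (or `"unmapped"`).
#' @examples
#' normalize_term("stopgain", "annovar")
#' @export
normalize_term <- function(raw, tool, map = synonym_map(),
                           severity = severity_table()) {
  key <- .norm_key(raw)
  sub <- map[map$tool == tool, , drop = FALSE]
  out <- sub$canonical_term[match(key, .norm_key(sub$raw_term))]
  canon <- severity[match(key, .norm_key(severity))]
  out[is.na(out)] <- canon[is.na(out)]
  out[is.na(out)] <- "unmapped"
  out
}

#' Pick the most severe of several canonical SO terms
#'
#' @param terms non-empty character vector of canonical terms; the sentinel
#'   `"unmapped"` ranks below every real term.
#' @param severity severity order, most severe first.
#' @return the single most severe term.
#' @examples
#' most_severe(c("intron_variant", "splice_donor_variant"))
#' @export
most_severe <- function(terms, severity = severity_table()) {
  if (length(terms) == 0) stop("missing annotation: no consequence terms")
  r <- match(terms, severity)
  r[is.na(r)] <- length(severity) + 1L  # unmapped: least severe
  terms[which.min(r)]
}

.category_map <- list(
  LoF = c("frameshift_variant", "splice_donor_variant",
          "splice_acceptor_variant", "stop_gained"),
  Missense = "missense_variant",
  ProteinLengthChange = c("inframe_insertion", "inframe_deletion",
                          "protein_altering_variant", "stop_lost",
                          "start_lost"),
  Synonymous = c("synonymous_variant", "stop_retained_variant",
                 "start_retained_variant")
)

#' Bin a canonical SO term into its ACMG-facing functional category
#'
#' LoF (frameshift, splice donor/acceptor, nonsense) is the PVS1 trigger;
#' ProteinLengthChange (inframe indel, stop-loss, initiator codon) maps to
#' PM4; Synonymous to BP7; everything else (UTR, intronic, up/downstream,
#' non-coding, intergenic, unmapped) is Other.
#'
#' @param term character vector of canonical SO terms.
#' @return character vector over
#'   `{"LoF","Missense","ProteinLengthChange","Synonymous","Other"}`.
#' @examples
#' functional_category("stop_gained")
#' @export
functional_category <- function(term) {
  out <- rep("Other", length(term))
  for (cat in names(.category_map))
    out[term %in% .category_map[[cat]]] <- cat
  n_unmapped <- sum(term == "unmapped")
  if (n_unmapped > 0)
    warning(n_unmapped, " unmapped term(s) binned as Other")
  out
}
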