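# Curation: turn a raw ClinVar-style record table into the analysis test
# set. Alleles are made parsimonious (suffix/prefix trimming) and
# left-aligned against an optional reference context; variants are classed
# SNV / Indel / MNV / Other; then the filter chain excludes, in a fixed
# order with first-failing-filter attribution: oversized indels, low review
# stars, unwanted significance classes, excluded chromosomes, records
# without molecular consequence, and records with multiple MC terms for one
# transcript.

#' Curation configuration
#'
#' Defaults reproduce the stringent criteria used for a clinical
#' concordance test set: small variants only (indels under 50 bp), review
#' status of at least two stars, no VUS/conflicting/other significance, no
#' mitochondrial variants, molecular-consequence information required and
#' unambiguous.
#'
#' @param max_indel_len largest retained indel length difference, in bases.
#' @param min_stars minimum ClinVar review stars.
#' @param exclude_clnsig significance classes to drop.
#' @param exclude_chroms chromosomes to drop.
#' @param require_mc drop records lacking molecular-consequence terms.
#' @param exclude_multi_mc_per_transcript drop records listing more than one
#'   MC term for a single transcript.
#' @return list of class `"curation_config"`.
#' @export
curation_config <- function(max_indel_len = 49L, min_stars = 2L,
                            exclude_clnsig = c("VUS", "conflicting", "other"),
                            exclude_chroms = "MT",
                            require_mc = TRUE,
                            exclude_multi_mc_per_transcript = TRUE) {
  stopifnot(max_indel_len >= 1, min_stars >= 0, min_stars <= 4)
  structure(list(max_indel_len = as.integer(max_indel_len),
                 min_stars = as.integer(min_stars),
                 exclude_clnsig = exclude_clnsig,
                 exclude_chroms = exclude_chroms,
                 require_mc = isTRUE(require_mc),
                 exclude_multi_mc_per_transcript =
                   isTRUE(exclude_multi_mc_per_transcript)),
            class = "curation_config")
}

#' Normalize a variant's alleles (parsimony + left alignment)
#'
#' Shared suffix then shared prefix are trimmed, keeping at least one base
#' on each side per VCF convention; with a reference context, indels are
#' left-shifted to the smallest position describing the same edited
#' sequence. Idempotent.
#'
#' @param variant list or one-row data.frame with `pos`, `ref`, `alt`.
#' @param reference_context optional DNA string covering the variant site,
#'   needed only for left-shifting across repeats.
#' @param context_start 1-based genomic position of the first base of
#'   `reference_context`.
#' @return the variant with normalized `pos`, `ref`, `alt`; degenerate
#'   alleles or `ref == alt` raise an error.
#' @export
normalize_allele <- function(variant, reference_context = NULL,
                             context_start = 1L) {
  pos <- as.integer(variant$pos)
  ref <- toupper(variant$ref); alt <- toupper(variant$alt)
  if (grepl("[^ACGT]", ref) || grepl("[^ACGT]", alt))
    stop("degenerate: non-ACGT base in alleles")
  has_ctx <- !is.null(reference_context)
  if (has_ctx) reference_context <- toupper(reference_context)
  ctx_at <- function(p) {
    i <- p - context_start + 1L
    if (i < 1 || i > nchar(reference_context)) NA_character_
    else substr(reference_context, i, i)
  }
  repeat {
    # trim shared suffix (keep >= 1 base each side)
    while (nchar(ref) > 1 && nchar(alt) > 1 &&
           substr(ref, nchar(ref), nchar(ref)) ==
           substr(alt, nchar(alt), nchar(alt))) {
      ref <- substr(ref, 1, nchar(ref) - 1)
      alt <- substr(alt, 1, nchar(alt) - 1)
    }
    # left-extend indels through repeats: when the alleles still share a
    # terminal base but the keep-one-base rule blocks further trimming,
    # prepend the preceding context base and go round again
    if (has_ctx && nchar(ref) != nchar(alt) &&
        substr(ref, nchar(ref), nchar(ref)) ==
          substr(alt, nchar(alt), nchar(alt))) {
      b <- ctx_at(pos - 1L)
      if (!is.na(b)) {
        ref <- paste0(b, substr(ref, 1, nchar(ref) - 1))
        alt <- paste0(b, substr(alt, 1, nchar(alt) - 1))
        pos <- pos - 1L
        next
      }
    }
    break
  }
  # trim shared prefix (keep >= 1 base each side)
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, 1, 1) == substr(alt, 1, 1)) {
    ref <- substr(ref, 2, nchar(ref)); alt <- substr(alt, 2, nchar(alt))
    pos <- pos + 1L
  }
  if (ref == alt) stop("non-variant: ref equals alt after trimming")
  variant$pos <- pos; variant$ref <- ref; variant$alt <- alt
  variant
}

#' Classify normalized alleles as SNV / Indel / MNV / Other
#'
#' @param ref,alt character vectors of normalized alleles.
#' @return character vector of classes; symbolic or empty alleles are fatal
#'   for length-0 and classed `"Other"` for symbolic.
#' @examples
#' classify_variant_class(c("A", "AT", "ATG"), c("G", "GC", "A"))
#' @export
classify_variant_class <- function(ref, alt) {
  if (any(!nzchar(ref)) || any(!nzchar(alt)))
    stop("empty allele: normalization contract breached")
  symbolic <- grepl("[^ACGT]", ref) | grepl("[^ACGT]", alt)
  nr <- nchar(ref); na <- nchar(alt)
  out <- ifelse(nr != na, "Indel",
                ifelse(nr == 1, "SNV", "MNV"))
  out[symbolic] <- "Other"
  out
}

#' Apply the curation filter chain
#'
#' A record is retained iff it passes every filter; each exclusion is
#' attributed to the first failing filter in the fixed order
#' size, stars, clnsig, chrom, MC-present, multi-MC. Records are expected
#' to be normalized and de-duplicated on (chrom, pos, ref, alt) already.
#'
#' @param records a ClinVar record data.frame (see [read_clinvar_vcf()]).
#' @param config a [curation_config()].
#' @return list with `retained` (the surviving records) and `summary`, a
#'   list holding `input_count`, per-filter `exclusions`, `retained_count`,
#'   and `type_composition` / `class_composition` tables over the retained
#'   set.
#' @export
apply_filters <- function(records, config = curation_config()) {
  stopifnot(inherits(config, "curation_config"))
  n <- nrow(records)
  vclass <- classify_variant_class(records$ref, records$alt)
  indel_len <- pmax(nchar(records$ref), nchar(records$alt)) - 1L
  mc_n <- vapply(records$mc, nrow, 0L)
  mc_multi <- vapply(records$mc, function(m) {
    if (nrow(m) < 2) return(any(m$multi))
    any(m$multi) ||
      any(stats::aggregate(term ~ addNA(accession), data = m,
                           FUN = length)$term > 1)
  }, NA)
  fail <- cbind(
    size   = vclass == "Indel" & indel_len > config$max_indel_len,
    stars  = is.na(records$stars) | records$stars < config$min_stars,
    clnsig = records$clnsig %in% config$exclude_clnsig,
    chrom  = records$chrom %in% config$exclude_chroms,
    mc_present = config$require_mc & mc_n == 0L,
    multi_mc   = config$exclude_multi_mc_per_transcript & mc_multi)
  first_fail <- apply(fail, 1, function(x) {
    i <- which(x)
    if (length(i)) colnames(fail)[i[1]] else NA_character_
  })
  keep <- is.na(first_fail)
  retained <- records[keep, , drop = FALSE]
  retained$variant_class <- vclass[keep]
  exclusions <- table(factor(first_fail, levels = colnames(fail)))
  summary <- list(
    input_count = n,
    exclusions = as.list(exclusions),
    retained_count = sum(keep),
    type_composition = table(factor(vclass[keep],
                                    levels = c("SNV", "Indel", "MNV",
                                               "Other"))),
    class_composition = table(factor(retained$clnsig,
                                     levels = c("P", "LP", "B", "LB"))))
  stopifnot(summary$input_count ==
              summary$retained_count + sum(unlist(summary$exclusions)))
  list(retained = retained, summary = summary)
}
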