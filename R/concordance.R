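# Concordance accounting: three-way Venn partitions over
# (variant, transcript, value) tuples, per-tool match fractions against a
# reference with a mismatch-cause breakdown, and stratified fractions.

#' Build (variant, transcript, value) tuple keys
#'
#' @param chrom,pos,ref,alt variant key columns.
#' @param accession transcript accession (compared version-blind: any
#'   `.version` suffix is dropped).
#' @param value canonicalized HGVSc, HGVSp, or most-severe SO term; rows
#'   with `NA` value are dropped (they are counted as missing in fraction
#'   denominators, not in Venn universes).
#' @return character vector of tuple keys.
#' @export
tuple_key <- function(chrom, pos, ref, alt, accession, value) {
  keep <- !is.na(value)
  paste(chrom, pos, ref, alt, sub("\\.\\d+$", "", accession),
        value, sep = "\r")[keep]
}

#' Partition three sets into the seven Venn regions
#'
#' @param setA,setB,setC character vectors (duplicates ignored).
#' @return list of class `"venn_partition"` with the seven region counts
#'   (`A_only`, `B_only`, `C_only`, `AB`, `AC`, `BC`, `ABC`) and the
#'   `union` total.
#' @examples
#' venn_partition(c("x", "y"), "y", c("y", "z"))
#' @export
venn_partition <- function(setA, setB, setC) {
  A <- unique(setA); B <- unique(setB); C <- unique(setC)
  u <- unique(c(A, B, C))
  inA <- u %in% A; inB <- u %in% B; inC <- u %in% C
  out <- list(
    A_only = sum(inA & !inB & !inC),
    B_only = sum(!inA & inB & !inC),
    C_only = sum(!inA & !inB & inC),
    AB = sum(inA & inB & !inC),
    AC = sum(inA & !inB & inC),
    BC = sum(!inA & inB & inC),
    ABC = sum(inA & inB & inC),
    union = length(u))
  stopifnot(out$union == sum(unlist(out[1:7])))
  structure(out, class = "venn_partition")
}

#' Three-way Venn over per-tool transcript accession sets
#'
#' Accessions are compared version-blind.
#'
#' @param setA,setB,setC character vectors of transcript accessions.
#' @return a `"venn_partition"`.
#' @export
transcript_venn <- function(setA, setB, setC) {
  strip <- function(x) sub("\\.\\d+$", "", x)
  venn_partition(strip(setA), strip(setB), strip(setC))
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("Venn partition (union =", x$union, ")\n")
  for (r in c("A_only", "B_only", "C_only", "AB", "AC", "BC", "ABC"))
    cat(sprintf("  %-7s %d\n", r, x[[r]]))
  invisible(x)
}

#' Per-tool match fraction against the reference, with cause breakdown
#'
#' The fraction is matches over all comparable reference entries; missing
#' annotations stay in the denominator (a missing annotation is counted as
#' incorrect). The cause breakdown over non-matches normalizes to 1.
#'
#' @param results data.frame of match results with columns `tool`,
#'   `verdict` (`exact` / `equivalent` / `mismatch` / `missing`) and
#'   `cause`.
#' @param treat_equivalent_as_match count `equivalent` verdicts as matches
#'   (the headline accounting); with `FALSE`, only `exact` matches count
#'   and equivalences surface as `non_preferred` causes.
#' @return data.frame with one row per (tool, cause = NA) carrying the
#'   fraction, plus cause rows; columns `tool`, `n`, `matches`, `fraction`,
#'   `cause`, `cause_share`.
#' @export
match_fraction <- function(results, treat_equivalent_as_match = TRUE) {
  if (nrow(results) == 0) stop("empty reference: no results to aggregate")
  is_match <- results$verdict == "exact" |
    (treat_equivalent_as_match & results$verdict == "equivalent")
  out <- lapply(split(seq_len(nrow(results)), results$tool), function(i) {
    n <- length(i); m <- sum(is_match[i])
    misses <- results[i, ][!is_match[i], , drop = FALSE]
    causes <- table(misses$cause, useNA = "no")
    cause_df <- if (length(causes))
      data.frame(cause = names(causes),
                 cause_share = as.numeric(causes) / sum(causes),
                 stringsAsFactors = FALSE)
    else data.frame(cause = character(0), cause_share = numeric(0))
    list(tool = results$tool[i[1]], n = n, matches = m,
         fraction = m / n, causes = cause_df)
  })
  summary <- do.call(rbind, lapply(out, function(x)
    data.frame(tool = x$tool, n = x$n, matches = x$matches,
               fraction = x$fraction, stringsAsFactors = FALSE)))
  rownames(summary) <- NULL
  attr(summary, "causes") <- lapply(out, `[[`, "causes")
  summary
}

#' Stratified match fractions
#'
#' @param results match-result data.frame also carrying the stratum label
#'   column named in `by`.
#' @param by stratifying column: `variant_class`, `clinvar_type`, or
#'   `functional_category` (any column present in `results` works).
#' @param treat_equivalent_as_match as in [match_fraction()].
#' @return data.frame of per (tool, stratum) fractions; strata with zero
#'   denominator are simply absent. Unknown (NA) labels are grouped as
#'   `"other"`.
#' @export
stratify <- function(results, by, treat_equivalent_as_match = TRUE) {
  if (!by %in% names(results)) stop("no stratum column ", by)
  lab <- as.character(results[[by]])
  lab[is.na(lab)] <- "other"
  parts <- split(seq_len(nrow(results)), lab)
  out <- lapply(names(parts), function(s) {
    f <- match_fraction(results[parts[[s]], , drop = FALSE],
                        treat_equivalent_as_match)
    f$stratum <- s
    f
  })
  res <- do.call(rbind, out)
  res[, c("tool", "stratum", "n", "matches", "fraction")]
}
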