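# End-to-end comparison: pair each reference record with each tool's
# annotation on the same variant and (version-blind) transcript, then judge
# HGVSc, HGVSp and the most-severe coding impact. This is the glue the
# concordance and delta modules consume.

.vkey <- function(df) paste(df$chrom, df$pos, df$ref, df$alt, sep = "\r")

#' Compare tool annotations against a reference, per variant and metric
#'
#' For every reference record and every tool, the tool's annotation on the
#' reference's (version-blind) transcript accession is located; absence —
#' including annotations only on other transcripts — is judged `missing`.
#' HGVSc and HGVSp are compared with [compare_hgvs()]; the coding impact is
#' the equality of most-severe canonical SO terms after per-dialect
#' normalization.
#'
#' @param reference annotation-model data.frame for the reference (e.g. the
#'   `reference` element of [simulate_dataset()], or a parsed ClinVar
#'   table); extra columns `clinvar_class`, `stars`, `variant_class` are
#'   carried through when present.
#' @param tool_annotations named list of annotation-model data.frames.
#' @param transcripts optional named cDNA vector (names = accessions,
#'   versionless or versioned) enabling sequence-aware equivalence.
#' @param level comparison level passed to [compare_hgvs()].
#' @return long data.frame: one row per (tool, reference record, metric in
#'   hgvsc/hgvsp/impact) with `verdict`, `cause`, the reference and tool
#'   canonical terms and functional categories, and carried-through strata.
#' @export
compare_annotations <- function(reference, tool_annotations,
                                transcripts = NULL, level = "full") {
  rkey <- .vkey(reference)
  ref_term <- normalize_term(reference$consequences, "clinvar")
  ref_cat <- functional_category(ref_term)
  n <- nrow(reference)
  tnames <- if (!is.null(transcripts))
    sub("\\.\\d+$", "", names(transcripts)) else character(0)
  tidx <- match(sub("\\.\\d+$", "", reference$accession), tnames)
  out <- list()
  for (tool in names(tool_annotations)) {
    ann <- tool_annotations[[tool]]
    akey <- paste(.vkey(ann), sub("\\.\\d+$", "", ann$accession),
                  sep = "\r")
    want <- paste(rkey, sub("\\.\\d+$", "", reference$accession),
                  sep = "\r")
    hit <- match(want, akey)
    found <- !is.na(hit)
    # tool-side most-severe canonical term, vectorized over "&"-joins
    tool_term <- rep(NA_character_, n)
    raw_cons <- ann$consequences[hit]
    simple <- found & !is.na(raw_cons) & !grepl("&", raw_cons, fixed = TRUE)
    tool_term[simple] <- normalize_term(raw_cons[simple], tool)
    for (i in which(found & !is.na(raw_cons) &
                    grepl("&", raw_cons, fixed = TRUE)))
      tool_term[i] <- most_severe(normalize_term(
        strsplit(raw_cons[i], "&", fixed = TRUE)[[1]], tool))
    tool_cat <- rep(NA_character_, n)
    tool_cat[!is.na(tool_term)] <-
      functional_category(tool_term[!is.na(tool_term)])
    judge <- function(query, ref_val, protein) {
      verdict <- rep("mismatch", n); cause <- rep(NA_character_, n)
      absent <- is.na(query)
      verdict[absent] <- "missing"; cause[absent] <- "missing_na"
      exact <- !absent & query == ref_val
      verdict[exact] <- "exact"
      for (i in which(!absent & !exact)) {
        tm <- if (!protein && !is.null(transcripts) && !is.na(tidx[i]))
          transcript_model(reference$accession[i],
                           transcripts[[tidx[i]]]) else NULL
        r <- compare_hgvs(query[i], ref_val[i], tm = tm,
                          level = if (protein && level == "full")
                            "canonical" else level)
        verdict[i] <- r$verdict; cause[i] <- r$cause
      }
      list(verdict = verdict, cause = cause)
    }
    res_c <- judge(ifelse(found, ann$hgvs_c[hit], NA), reference$hgvs_c,
                   protein = FALSE)
    res_p <- judge(ifelse(found, ann$hgvs_p[hit], NA), reference$hgvs_p,
                   protein = TRUE)
    term_verdict <- ifelse(is.na(tool_term), "missing",
                           ifelse(tool_term == ref_term, "exact",
                                  "mismatch"))
    term_cause <- ifelse(term_verdict == "missing", "missing_na",
                         ifelse(term_verdict == "mismatch",
                                "position_or_type", NA))
    base <- data.frame(
      tool = tool, chrom = reference$chrom, pos = reference$pos,
      ref = reference$ref, alt = reference$alt,
      accession = reference$accession,
      reference_term = ref_term, reference_category = ref_cat,
      tool_term = tool_term, tool_category = tool_cat,
      stringsAsFactors = FALSE)
    for (extra in c("clinvar_class", "stars", "variant_class"))
      base[[extra]] <- if (extra %in% names(reference))
        reference[[extra]] else NA
    has_p <- !is.na(reference$hgvs_p)
    out[[length(out) + 1L]] <- rbind(
      cbind(metric = "hgvsc", verdict = res_c$verdict,
            cause = res_c$cause, base, stringsAsFactors = FALSE),
      cbind(metric = "hgvsp", verdict = res_p$verdict[has_p],
            cause = res_p$cause[has_p], base[has_p, , drop = FALSE],
            stringsAsFactors = FALSE),
      cbind(metric = "impact", verdict = term_verdict,
            cause = term_cause, base, stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run the full concordance accounting on a compared dataset
#'
#' Convenience wrapper producing the headline tables: per-tool per-metric
#' match fractions (equivalence-aware and strict), three-way Venn
#' partitions of (variant, transcript, value) tuples per metric, and the
#' PVS1 delta summary per tool.
#'
#' @param results output of [compare_annotations()].
#' @param tool_annotations the annotation tables (for the Venn universes).
#' @return list with `fractions`, `venn` (per metric), `pvs1` (per tool).
#' @export
concordance_report <- function(results, tool_annotations) {
  fractions <- do.call(rbind, lapply(split(results, results$metric),
    function(r) {
      eq <- match_fraction(r, treat_equivalent_as_match = TRUE)
      st <- match_fraction(r, treat_equivalent_as_match = FALSE)
      data.frame(metric = r$metric[1], tool = eq$tool, n = eq$n,
                 fraction = eq$fraction, fraction_strict = st$fraction,
                 stringsAsFactors = FALSE)
    }))
  rownames(fractions) <- NULL
  tools <- names(tool_annotations)
  venn <- list()
  if (length(tools) == 3) {
    sets_for <- function(value_col) lapply(tool_annotations, function(a) {
      v <- a[[value_col]]
      tuple_key(a$chrom, a$pos, a$ref, a$alt, a$accession, v)
    })
    venn$hgvsc <- do.call(venn_partition, unname(sets_for("hgvs_c")))
    venn$hgvsp <- do.call(venn_partition, unname(sets_for("hgvs_p")))
    venn$transcripts <- transcript_venn(
      tool_annotations[[1]]$accession, tool_annotations[[2]]$accession,
      tool_annotations[[3]]$accession)
  }
  pvs1 <- lapply(split(results, results$tool), function(r) {
    r <- r[r$metric == "impact" & !is.na(r$tool_category), , drop = FALSE]
    pvs1_delta(r$reference_category, r$tool_category)$summary
  })
  list(fractions = fractions, venn = venn, pvs1 = pvs1)
}
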