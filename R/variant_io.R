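# Readers and writers for the annotation dialects the pipeline consumes:
# ClinVar-style VCF INFO (CLNSIG / CLNREVSTAT / MC), SnpEff ANN, VEP CSQ,
# and ANNOVAR tab-delimited multianno tables. The VCF container itself is
# read through vcfR; only the INFO dialects are parsed here.
#
# All parsers meet in one flat annotation data model:
#   tool, chrom, pos, ref, alt, accession, version, protein_accession,
#   hgvs_c, hgvs_p, consequences ("&"-joined raw terms)
# with "absent" uniformly represented as NA. Rejected or malformed entries
# are counted on the result's "flagged" attribute, never silently dropped.

.ACC_RE <- "^(NM_|NR_|ENST)\\d+"

.blank_to_na <- function(x) {
  x <- trimws(x)
  x[x %in% c("", ".", "-", "NA")] <- NA_character_
  x
}

.annotation_df <- function(tool = character(0), chrom = character(0),
                           pos = integer(0), ref = character(0),
                           alt = character(0), accession = character(0),
                           version = integer(0),
                           protein_accession = character(0),
                           hgvs_c = character(0), hgvs_p = character(0),
                           consequences = character(0)) {
  data.frame(tool = tool, chrom = chrom, pos = as.integer(pos), ref = ref,
             alt = alt, accession = accession, version = as.integer(version),
             protein_accession = protein_accession, hgvs_c = hgvs_c,
             hgvs_p = hgvs_p, consequences = consequences,
             stringsAsFactors = FALSE)
}

.split_acc <- function(x) {
  m <- regmatches(x, regexec("^(.*?)(?:\\.(\\d+))?$", x))
  list(acc = vapply(m, `[`, "", 2),
       ver = suppressWarnings(as.integer(vapply(m, `[`, "", 3))))
}

.info_field <- function(info, key) {
  pat <- paste0("(?:^|;)", key, "=([^;]*)")
  m <- regmatches(info, regexec(pat, info))
  vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, "")
}

#' The ClinVar review-status to star map
#'
#' ClinVar's published review-status tiers: practice guideline = 4 stars,
#' expert panel = 3, multiple submitters without conflicts = 2, single
#' submitter or conflicting = 1, no assertion = 0.
#'
#' @return named integer vector keyed by normalized review-status text.
#' @export
clinvar_star_map <- function() {
  c(practice_guideline = 4L,
    reviewed_by_expert_panel = 3L,
    "criteria_provided,_multiple_submitters,_no_conflicts" = 2L,
    "criteria_provided,_conflicting_classifications" = 1L,
    "criteria_provided,_conflicting_interpretations" = 1L,
    "criteria_provided,_single_submitter" = 1L,
    no_assertion_criteria_provided = 0L,
    no_assertion_provided = 0L,
    no_classification_provided = 0L,
    no_classification_for_the_single_variant = 0L,
    no_classifications_from_unflagged_records = 0L)
}

.clnsig_map <- function(x) {
  x <- tolower(.blank_to_na(x))
  out <- rep("other", length(x))
  out[is.na(x)] <- "other"
  out[grepl("^conflicting", x)] <- "conflicting"
  out[x == "uncertain_significance"] <- "VUS"
  out[x == "pathogenic"] <- "P"
  out[x %in% c("likely_pathogenic", "pathogenic/likely_pathogenic")] <- "LP"
  out[x == "benign"] <- "B"
  out[x %in% c("likely_benign", "benign/likely_benign")] <- "LB"
  out
}

.parse_mc <- function(mc) {
  # MC entries are comma-separated "SO:0001575|splice_donor_variant" pairs
  if (is.na(mc)) return(list(data.frame(accession = character(0),
                                        term = character(0),
                                        multi = logical(0))))
  entries <- strsplit(mc, ",", fixed = TRUE)[[1]]
  terms <- vapply(entries, function(e) {
    parts <- strsplit(e, "|", fixed = TRUE)[[1]]
    if (length(parts) >= 2) parts[2] else parts[1]
  }, "", USE.NAMES = FALSE)
  # a single entry naming several "&"-joined terms is flagged, not merged
  multi <- grepl("&", terms, fixed = TRUE)
  list(data.frame(accession = NA_character_, term = terms, multi = multi,
                  stringsAsFactors = FALSE))
}

#' Read a ClinVar-style VCF into curation-ready records
#'
#' One record per line per ALT allele (multi-allelic lines are split).
#' Unparseable INFO values yield flagged records rather than errors; the
#' number of skipped/flagged lines is reported on the `"flagged"` attribute.
#' The optional extension keys `CLNSELTR`, `CLNHGVSC` and `CLNHGVSP`
#' (selected transcript and its coding/protein HGVS, as written by
#' [write_outputs()]) are picked up when present.
#'
#' @param path a VCF 4.x file (plain or bgzipped) with ClinVar INFO keys
#'   `CLNSIG`, `CLNREVSTAT`, `MC`, and optionally `CLNHGVS`.
#' @param star_map named integer vector mapping normalized review-status
#'   text to 0-4 stars (default [clinvar_star_map()]).
#' @return data.frame with one row per record: variant key columns, clnsig
#'   class, review status and stars, the `mc` list-column of
#'   (accession, term) molecular consequences, HGVS fields and the selected
#'   transcript. Attribute `"flagged"`: named counts of oddities seen.
#' @export
read_clinvar_vcf <- function(path, star_map = clinvar_star_map()) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  flagged <- c(multiallelic_split = 0L, unknown_review_status = 0L,
               multi_term_mc_entry = 0L)
  rows <- vector("list", nrow(fix))
  for (k in seq_len(nrow(fix))) {
    alts <- strsplit(fix[k, "ALT"], ",", fixed = TRUE)[[1]]
    if (length(alts) > 1)
      flagged["multiallelic_split"] <- flagged["multiallelic_split"] + 1L
    info <- fix[k, "INFO"]
    revstat <- .blank_to_na(.info_field(info, "CLNREVSTAT"))
    stars <- unname(star_map[.norm_key(revstat)])
    if (!is.na(revstat) && is.na(stars)) {
      flagged["unknown_review_status"] <- flagged["unknown_review_status"] + 1L
      stars <- 0L
    }
    mc <- .parse_mc(.info_field(info, "MC"))
    if (any(mc[[1]]$multi))
      flagged["multi_term_mc_entry"] <- flagged["multi_term_mc_entry"] + 1L
    id <- suppressWarnings(as.integer(fix[k, "ID"]))
    rows[[k]] <- data.frame(
      chrom = sub("^chr", "", fix[k, "CHROM"]),
      pos = as.integer(fix[k, "POS"]),
      ref = toupper(fix[k, "REF"]), alt = toupper(alts),
      clinvar_id = id,
      clnsig = .clnsig_map(.info_field(info, "CLNSIG")),
      review_status_raw = revstat,
      stars = if (is.na(revstat)) NA_integer_ else as.integer(stars),
      hgvs_g = .blank_to_na(.info_field(info, "CLNHGVS")),
      hgvs_c = .blank_to_na(.info_field(info, "CLNHGVSC")),
      hgvs_p = .blank_to_na(.info_field(info, "CLNHGVSP")),
      selected_transcript = .blank_to_na(.info_field(info, "CLNSELTR")),
      row.names = NULL, stringsAsFactors = FALSE)
    rows[[k]]$mc <- rep(mc, length(alts))
  }
  out <- do.call(rbind, rows)
  attr(out, "flagged") <- flagged
  out
}

#' Parse a SnpEff ANN INFO field
#'
#' One annotation per comma-separated ANN entry; `&`-joined consequence
#' terms are split into separate raw terms. Entries with fewer than 11 pipe
#' fields, or transcript accessions outside NM/NR/ENST, are counted on the
#' `"flagged"` attribute.
#'
#' @param ann the raw `ANN=` value (without the key).
#' @param variant list or one-row data.frame with `chrom`, `pos`, `ref`,
#'   `alt`.
#' @return annotation data.frame (see package overview for columns).
#' @export
parse_snpeff_ann <- function(ann, variant) {
  flagged <- c(malformed_entry = 0L, rejected_accession = 0L)
  out <- list()
  if (!is.na(ann)) for (entry in strsplit(ann, ",", fixed = TRUE)[[1]]) {
    f <- strsplit(entry, "|", fixed = TRUE)[[1]]
    if (length(f) < 11) { flagged["malformed_entry"] <-
                            flagged["malformed_entry"] + 1L; next }
    feat <- .split_acc(.blank_to_na(f[7]))
    if (is.na(feat$acc) || !grepl(.ACC_RE, feat$acc)) {
      flagged["rejected_accession"] <- flagged["rejected_accession"] + 1L
      next
    }
    out[[length(out) + 1L]] <- .annotation_df(
      tool = "snpeff", chrom = variant$chrom, pos = variant$pos,
      ref = variant$ref, alt = variant$alt,
      accession = feat$acc, version = feat$ver,
      protein_accession = NA_character_,
      hgvs_c = .blank_to_na(f[10]), hgvs_p = .blank_to_na(f[11]),
      consequences = .blank_to_na(f[2]))
  }
  res <- if (length(out)) do.call(rbind, out) else .annotation_df()
  attr(res, "flagged") <- flagged
  res
}

#' Extract the CSQ field order from a VEP-annotated VCF
#'
#' @param vcf a `vcfR` object (or path to the VCF).
#' @return character vector of CSQ sub-field names, from the header's
#'   `Format:` description.
#' @export
csq_field_order <- function(vcf) {
  if (is.character(vcf)) vcf <- vcfR::read.vcfR(vcf, verbose = FALSE)
  meta <- vcf@meta
  line <- grep("^##INFO=<ID=CSQ", meta, value = TRUE)
  if (length(line) == 0) stop("malformed VCF header: no CSQ INFO definition")
  m <- regmatches(line, regexec("Format: ?([^\"]+)", line))[[1]]
  if (length(m) < 2) stop("malformed CSQ Description: no Format clause")
  strsplit(trimws(m[2]), "|", fixed = TRUE)[[1]]
}

#' Parse a VEP CSQ INFO field
#'
#' Field meanings are taken by name from the header-derived order, so a
#' permuted header parses identically. `%XX` URL-escapes in HGVS fields are
#' decoded (VEP encodes `=` as `%3D`).
#'
#' @param csq raw `CSQ=` value.
#' @param csq_order field names from [csq_field_order()].
#' @param variant list with `chrom`, `pos`, `ref`, `alt`.
#' @return annotation data.frame with a `"flagged"` count attribute.
#' @export
parse_vep_csq <- function(csq, csq_order, variant) {
  flagged <- c(malformed_entry = 0L, rejected_accession = 0L)
  out <- list()
  if (!is.na(csq)) for (entry in strsplit(csq, ",", fixed = TRUE)[[1]]) {
    f <- strsplit(entry, "|", fixed = TRUE)[[1]]
    length(f) <- length(csq_order)     # pad trailing empties
    if (sum(!is.na(f)) == 0 ||
        length(strsplit(entry, "|", fixed = TRUE)[[1]]) > length(csq_order)) {
      flagged["malformed_entry"] <- flagged["malformed_entry"] + 1L; next
    }
    names(f) <- csq_order
    feat <- .split_acc(.blank_to_na(f["Feature"]))
    if (is.na(feat$acc) || !grepl(.ACC_RE, feat$acc)) {
      flagged["rejected_accession"] <- flagged["rejected_accession"] + 1L
      next
    }
    dec <- function(x) if (is.na(x)) x else utils::URLdecode(x)
    hc <- dec(.blank_to_na(f["HGVSc"]))
    hp <- dec(.blank_to_na(f["HGVSp"]))
    pacc <- NA_character_
    if (!is.na(hp) && grepl(":", hp, fixed = TRUE)) {
      pacc <- sub(":.*$", "", hp)
      hp <- sub("^[^:]*:", "", hp)
    }
    if (!is.na(hc)) hc <- sub("^[^:]*:", "", hc)
    out[[length(out) + 1L]] <- .annotation_df(
      tool = "vep", chrom = variant$chrom, pos = variant$pos,
      ref = variant$ref, alt = variant$alt,
      accession = feat$acc, version = feat$ver,
      protein_accession = pacc, hgvs_c = hc, hgvs_p = hp,
      consequences = .blank_to_na(f["Consequence"]))
  }
  res <- if (length(out)) do.call(rbind, out) else .annotation_df()
  attr(res, "flagged") <- flagged
  res
}

.read_tool_vcf <- function(path, tool) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  order <- if (tool == "vep") csq_field_order(v) else NULL
  flagged <- NULL
  out <- lapply(seq_len(nrow(fix)), function(k) {
    var <- list(chrom = sub("^chr", "", fix[k, "CHROM"]),
                pos = as.integer(fix[k, "POS"]),
                ref = toupper(fix[k, "REF"]), alt = toupper(fix[k, "ALT"]))
    val <- .info_field(fix[k, "INFO"], if (tool == "vep") "CSQ" else "ANN")
    if (tool == "vep") parse_vep_csq(val, order, var)
    else parse_snpeff_ann(val, var)
  })
  flagged <- Reduce(`+`, lapply(out, attr, "flagged"))
  res <- do.call(rbind, out)
  attr(res, "flagged") <- flagged
  res
}

#' Read a whole SnpEff- or VEP-annotated VCF into the annotation model
#'
#' @param path path to the annotated VCF.
#' @return annotation data.frame with a `"flagged"` attribute.
#' @export
read_snpeff_vcf <- function(path) .read_tool_vcf(path, "snpeff")

#' @rdname read_snpeff_vcf
#' @export
read_vep_vcf <- function(path) .read_tool_vcf(path, "vep")

.annovar_default_cols <- c(chrom = "Chr", pos = "Start", ref = "Ref",
                           alt = "Alt", func = "Func.refGene",
                           exonic_func = "ExonicFunc.refGene",
                           gene_detail = "GeneDetail.refGene",
                           aa_change = "AAChange.refGene")

#' Read an ANNOVAR tab-delimited multianno table
#'
#' One annotation per transcript sub-entry of the AAChange (exonic) or
#' GeneDetail (non-exonic) cell; sub-fields are `:`-joined as
#' `GENE:NM_x:exonN:c.x:p.x`. ANNOVAR reports no transcript versions and no
#' protein accessions, so both come back `NA`.
#'
#' @param path path to the table.
#' @param column_map named character vector remapping the expected logical
#'   columns (`chrom`, `pos`, `ref`, `alt`, `func`, `exonic_func`,
#'   `gene_detail`, `aa_change`) to this table's column names.
#' @return annotation data.frame with a `"flagged"` attribute; the count
#'   `missing_cell` tallies `.` sentinel cells.
#' @export
read_annovar_table <- function(path, column_map = NULL) {
  cols <- .annovar_default_cols
  if (!is.null(column_map)) cols[names(column_map)] <- column_map
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  missing_cols <- setdiff(unname(cols), names(tab))
  if (length(missing_cols))
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  flagged <- c(missing_cell = 0L, rejected_accession = 0L)
  out <- list()
  for (k in seq_len(nrow(tab))) {
    raw_cons <- .blank_to_na(tab[k, cols["exonic_func"]])
    if (is.na(raw_cons)) raw_cons <- .blank_to_na(tab[k, cols["func"]])
    cell <- .blank_to_na(tab[k, cols["aa_change"]])
    if (is.na(cell)) cell <- .blank_to_na(tab[k, cols["gene_detail"]])
    if (is.na(cell)) { flagged["missing_cell"] <-
                         flagged["missing_cell"] + 1L; next }
    for (entry in strsplit(cell, ",", fixed = TRUE)[[1]]) {
      f <- strsplit(entry, ":", fixed = TRUE)[[1]]
      acc_i <- grep(.ACC_RE, f)[1]
      if (is.na(acc_i)) { flagged["rejected_accession"] <-
                            flagged["rejected_accession"] + 1L; next }
      hc <- f[grepl("^c\\.", f)][1]
      hp <- f[grepl("^p\\.", f)][1]
      out[[length(out) + 1L]] <- .annotation_df(
        tool = "annovar", chrom = as.character(tab[k, cols["chrom"]]),
        pos = as.integer(tab[k, cols["pos"]]),
        ref = toupper(tab[k, cols["ref"]]),
        alt = toupper(tab[k, cols["alt"]]),
        accession = sub("\\.\\d+$", "", f[acc_i]), version = NA_integer_,
        protein_accession = NA_character_,
        hgvs_c = if (length(hc) && !is.na(hc)) hc else NA_character_,
        hgvs_p = if (length(hp) && !is.na(hp)) hp else NA_character_,
        consequences = raw_cons)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else .annotation_df()
  attr(res, "flagged") <- flagged
  res
}

#' Write the normalized annotation table as TSV
#'
#' Fixed column order: tool, chrom, pos, ref, alt, accession, version,
#' hgvs_c, hgvs_p, consequences (protein_accession is carried when present).
#'
#' @param annotations annotation data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(annotations, path) {
  cols <- c("tool", "chrom", "pos", "ref", "alt", "accession", "version",
            "protein_accession", "hgvs_c", "hgvs_p", "consequences")
  utils::write.table(annotations[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  invisible(path)
}

# ---- dialect writers (round-trip partners of the parsers above; the
# ---- simulator uses these to exercise the real parsers end to end)

.vcf_header <- function(info_lines) {
  c("##fileformat=VCFv4.2",
    info_lines,
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
}

.na_dot <- function(x) ifelse(is.na(x), "", x)

#' Serialize annotations back into their tool dialect
#'
#' `write_snpeff_vcf()` emits an ANN-dialect VCF, `write_vep_vcf()` a
#' CSQ-dialect VCF (with the Format clause in the header), and
#' `write_annovar_table()` a multianno-style TSV. Reparsing with the
#' matching reader is the identity on all model fields.
#'
#' @param annotations annotation data.frame (one or more rows per variant).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_snpeff_vcf <- function(annotations, path) {
  key <- paste(annotations$chrom, annotations$pos, annotations$ref,
               annotations$alt, sep = "\r")
  lines <- vapply(unique(key), function(k) {
    a <- annotations[key == k, , drop = FALSE]
    entries <- vapply(seq_len(nrow(a)), function(i) {
      ver <- if (is.na(a$version[i])) "" else paste0(".", a$version[i])
      paste(a$alt[i], .na_dot(a$consequences[i]), "MODIFIER", "GENE",
            "GENE", "transcript", paste0(a$accession[i], ver),
            "protein_coding", "1/1", .na_dot(a$hgvs_c[i]),
            .na_dot(a$hgvs_p[i]), "", "", "", "", "", sep = "|")
    }, "")
    paste(a$chrom[1], a$pos[1], ".", a$ref[1], a$alt[1], ".", ".",
          paste0("ANN=", paste(entries, collapse = ",")), sep = "\t")
  }, "")
  writeLines(c(.vcf_header(
    "##INFO=<ID=ANN,Number=.,Type=String,Description=\"Functional annotations: 'Allele | Annotation | Annotation_Impact | Gene_Name | Gene_ID | Feature_Type | Feature_ID | Transcript_BioType | Rank | HGVS.c | HGVS.p | cDNA.pos / cDNA.length | CDS.pos / CDS.length | AA.pos / AA.length | Distance | ERRORS / WARNINGS / INFO'\">"),
    lines), path)
  invisible(path)
}

.CSQ_ORDER <- c("Allele", "Consequence", "IMPACT", "SYMBOL", "Feature_type",
                "Feature", "HGVSc", "HGVSp")

#' @rdname write_snpeff_vcf
#' @export
write_vep_vcf <- function(annotations, path) {
  enc <- function(x) gsub("=", "%3D", x, fixed = TRUE)
  key <- paste(annotations$chrom, annotations$pos, annotations$ref,
               annotations$alt, sep = "\r")
  lines <- vapply(unique(key), function(k) {
    a <- annotations[key == k, , drop = FALSE]
    entries <- vapply(seq_len(nrow(a)), function(i) {
      ver <- if (is.na(a$version[i])) "" else paste0(".", a$version[i])
      acc <- paste0(a$accession[i], ver)
      hc <- if (is.na(a$hgvs_c[i])) "" else
        enc(paste0(acc, ":", a$hgvs_c[i]))
      hp <- if (is.na(a$hgvs_p[i])) "" else
        enc(paste0(if (is.na(a$protein_accession[i])) acc
                   else a$protein_accession[i], ":", a$hgvs_p[i]))
      paste(a$alt[i], .na_dot(a$consequences[i]), "MODIFIER", "GENE",
            "Transcript", acc, hc, hp, sep = "|")
    }, "")
    paste(a$chrom[1], a$pos[1], ".", a$ref[1], a$alt[1], ".", ".",
          paste0("CSQ=", paste(entries, collapse = ",")), sep = "\t")
  }, "")
  writeLines(c(.vcf_header(paste0(
    "##INFO=<ID=CSQ,Number=.,Type=String,Description=\"Consequence annotations from Ensembl VEP. Format: ",
    paste(.CSQ_ORDER, collapse = "|"), "\">")), lines), path)
  invisible(path)
}

#' @rdname write_snpeff_vcf
#' @export
write_annovar_table <- function(annotations, path) {
  key <- paste(annotations$chrom, annotations$pos, annotations$ref,
               annotations$alt, sep = "\r")
  rows <- lapply(unique(key), function(k) {
    a <- annotations[key == k, , drop = FALSE]
    exonic <- !is.na(a$hgvs_p[1])
    entries <- vapply(seq_len(nrow(a)), function(i) {
      paste(c("GENE", a$accession[i], "exon1",
              .na_dot(a$hgvs_c[i]),
              if (!is.na(a$hgvs_p[i])) a$hgvs_p[i]), collapse = ":")
    }, "")
    data.frame(Chr = a$chrom[1], Start = a$pos[1], End = a$pos[1],
               Ref = a$ref[1], Alt = a$alt[1],
               Func.refGene = if (exonic) "exonic" else
                 .na_dot(a$consequences[1]),
               Gene.refGene = "GENE",
               GeneDetail.refGene = if (exonic) "." else
                 paste(entries, collapse = ","),
               ExonicFunc.refGene = if (exonic)
                 .na_dot(a$consequences[1]) else ".",
               AAChange.refGene = if (exonic)
                 paste(entries, collapse = ",") else ".",
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
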