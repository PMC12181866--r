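# HGVS parsing, canonicalization and equivalence.
#
# Descriptions are held as plain lists of class "hgvs". Coding (c.) and
# non-coding (n.) descriptions carry 1-based positions into a transcript,
# optionally with intron offsets (c.310+3) or UTR zones (c.-12, c.*45).
# Protein (p.) alleles are stored as three-letter codes with "Ter" canonical
# for stops; "=" marks a synonymous (no-change) allele.

.AA3 <- c("Ala","Arg","Asn","Asp","Cys","Gln","Glu","Gly","His","Ile",
          "Leu","Lys","Met","Phe","Pro","Ser","Thr","Trp","Tyr","Val",
          "Sec","Ter")
.AA1 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V",
          "U","*")

.aa1_to_3 <- function(x) {
  out <- .AA3[match(x, .AA1)]
  out[x == "X"] <- "Ter"   # legacy stop code
  out
}

# Tokenize an amino-acid string that may mix one- and three-letter codes
# (three-letter match is tried first at each offset). Returns a character
# vector of three-letter codes, or NULL if the string is not a clean run.
.aa_tokens <- function(s) {
  out <- character(0)
  while (nchar(s) > 0) {
    tri <- substr(s, 1, 3)
    if (tri %in% .AA3) {
      out <- c(out, tri); s <- substr(s, 4, nchar(s)); next
    }
    one <- substr(s, 1, 1)
    if (one %in% c(.AA1, "X")) {
      out <- c(out, .aa1_to_3(one)); s <- substr(s, 2, nchar(s)); next
    }
    return(NULL)
  }
  out
}

.aa_block_re <- paste0("(?:", paste(.AA3, collapse = "|"),
                       "|[ARNDCQEGHILKMFPSTWYVUX*])")

# A transcript-space position: base (1-based), optional intron offset,
# optional UTR zone ("5utr": c.-N, "3utr": c.*N).
hgvs_pos <- function(base, offset = NA_integer_, utr = NA_character_) {
  list(base = as.integer(base), offset = as.integer(offset), utr = utr)
}

.parse_pos <- function(tok) {
  m <- regmatches(tok, regexec("^([*-]?)(\\d+)([+-]\\d+)?$", tok))[[1]]
  if (length(m) == 0) return(NULL)
  utr <- switch(m[2], "-" = "5utr", "*" = "3utr", NA_character_)
  off <- if (nzchar(m[4])) as.integer(m[4]) else NA_integer_
  hgvs_pos(as.integer(m[3]), off, utr)
}

.fmt_pos <- function(p) {
  paste0(switch(as.character(p$utr %in% "5utr"), "TRUE" = "-", ""),
         if (isTRUE(p$utr == "3utr")) "*" else "",
         p$base,
         if (!is.na(p$offset)) sprintf("%+d", p$offset) else "")
}

.pos_equal <- function(a, b) {
  identical(a$base, b$base) &&
    identical(is.na(a$offset), is.na(b$offset)) &&
    (is.na(a$offset) || a$offset == b$offset) &&
    identical(is.na(a$utr), is.na(b$utr)) &&
    (is.na(a$utr) || a$utr == b$utr)
}

.new_hgvs <- function(raw, accession = NA_character_, version = NA_integer_,
                      molecule, start = NULL, end = NULL, edit,
                      ref = NA_character_, alt = NA_character_,
                      fs_new_aa = NA_character_, fs_ter_offset = NA_integer_,
                      repeat_count = NA_integer_, predicted = FALSE) {
  structure(list(raw = raw, accession = accession, version = version,
                 molecule = molecule, start = start, end = end, edit = edit,
                 ref = ref, alt = alt, fs_new_aa = fs_new_aa,
                 fs_ter_offset = fs_ter_offset, repeat_count = repeat_count,
                 predicted = predicted),
            class = "hgvs")
}

#' Parse an HGVS expression
#'
#' Accepts coding/non-coding/genomic nucleotide descriptions
#' (`c.`, `n.`, `g.`: substitution, del, dup, ins, delins, inv, `=`,
#' repeat `unit[N]`) and protein descriptions (`p.`: substitution with one-
#' or three-letter codes and `Ter`/`X`/`*` stops, synonymous `=` forms,
#' short and long frameshifts, ranged del/dup/ins/delins, extensions).
#' An `accession.version:` prefix is split off when present; a gene symbol
#' in parentheses after the accession is discarded.
#'
#' @param text a single HGVS string, e.g. `"NM_000419.5:c.310+3_310+6del"`.
#' @return an object of class `"hgvs"`; unparseable input returns a
#'   `"hgvs_parse_error"` object carrying the offending token (checked with
#'   [is_hgvs()]), so callers can map failures to a mismatch cause instead
#'   of crashing mid-table.
#' @examples
#' parse_hgvs("NM_001009944.3:c.5824dup")
#' parse_hgvs("p.F12Lfs*13")
#' @export
parse_hgvs <- function(text) {
  if (length(text) != 1 || is.na(text) || !nzchar(trimws(text)))
    return(.parse_fail(text, "empty"))
  s <- gsub("[[:space:]]+", "", text)
  acc <- NA_character_; ver <- NA_integer_
  if (grepl(":", s, fixed = TRUE)) {
    i <- regexpr(":", s, fixed = TRUE)
    accpart <- substr(s, 1, i - 1)
    s <- substr(s, i + 1, nchar(s))
    accpart <- sub("\\([^)]*\\)$", "", accpart)
    m <- regmatches(accpart, regexec("^(.*?)(?:\\.(\\d+))?$", accpart))[[1]]
    acc <- m[2]
    ver <- if (nzchar(m[3])) as.integer(m[3]) else NA_integer_
  }
  m <- regmatches(s, regexec("^([cngmp])\\.(.+)$", s))[[1]]
  if (length(m) == 0) return(.parse_fail(text, s))
  mol <- m[2]; body <- m[3]
  out <- if (mol == "p") .parse_protein(body) else .parse_nucleotide(body)
  if (is.null(out)) return(.parse_fail(text, body))
  out$raw <- text; out$accession <- acc; out$version <- ver
  out$molecule <- mol
  out
}

.parse_fail <- function(text, token) {
  structure(list(raw = if (length(text)) text else NA_character_,
                 token = token),
            class = "hgvs_parse_error")
}

#' Test whether an object is a successfully parsed HGVS description
#' @param x any object.
#' @return logical scalar.
#' @export
is_hgvs <- function(x) inherits(x, "hgvs")

.parse_nucleotide <- function(body) {
  pos_re <- "[*-]?\\d+(?:[+-]\\d+)?"
  m <- regmatches(body, regexec(
    paste0("^(", pos_re, ")(?:_(", pos_re, "))?(.*)$"), body))[[1]]
  if (length(m) == 0) return(NULL)
  start <- .parse_pos(m[2])
  end <- if (nzchar(m[3])) .parse_pos(m[3]) else NULL
  tail <- m[4]
  if (is.null(start)) return(NULL)
  mk <- function(...) .new_hgvs(raw = body, molecule = "c",
                                start = start, end = end, ...)
  if (tail == "=") return(mk(edit = "identity"))
  mm <- regmatches(tail, regexec("^([ACGTN]+)>([ACGTN]+)$", tail))[[1]]
  if (length(mm)) {
    if (!is.null(end)) return(NULL)
    return(mk(edit = "sub", ref = mm[2], alt = mm[3]))
  }
  mm <- regmatches(tail, regexec("^del([ACGTN]*)ins([ACGTN]+)$", tail))[[1]]
  if (length(mm))
    return(mk(edit = "delins",
              ref = if (nzchar(mm[2])) mm[2] else NA_character_,
              alt = mm[3]))
  mm <- regmatches(tail, regexec("^del([ACGTN]*)$", tail))[[1]]
  if (length(mm))
    return(mk(edit = "del",
              ref = if (nzchar(mm[2])) mm[2] else NA_character_))
  mm <- regmatches(tail, regexec("^dup([ACGTN]*)$", tail))[[1]]
  if (length(mm))
    return(mk(edit = "dup",
              ref = if (nzchar(mm[2])) mm[2] else NA_character_))
  mm <- regmatches(tail, regexec("^ins([ACGTN]+)$", tail))[[1]]
  if (length(mm)) return(mk(edit = "ins", alt = mm[2]))
  if (tail == "inv") return(mk(edit = "inv"))
  mm <- regmatches(tail, regexec("^([ACGTN]+)\\[(\\d+)\\]$", tail))[[1]]
  if (length(mm))
    return(mk(edit = "repeat", ref = mm[2],
              repeat_count = as.integer(mm[3])))
  NULL
}

.parse_protein <- function(body) {
  predicted <- FALSE
  if (grepl("^\\(.*\\)$", body)) {
    predicted <- TRUE
    body <- substr(body, 2, nchar(body) - 1)
  }
  mk <- function(...) .new_hgvs(raw = body, molecule = "p",
                                predicted = predicted, ...)
  if (body %in% c("=", "?"))
    return(mk(edit = "identity", start = NULL))
  aa <- .aa_block_re
  # frameshift: Aaa123(Bbb)?fs((Ter|*|X)N?)?
  m <- regmatches(body, regexec(paste0(
    "^(", aa, ")(\\d+)(", aa, ")?fs(?:(?:Ter|\\*|X)(\\d+)?)?$"),
    body, perl = TRUE))[[1]]
  if (length(m)) {
    ref <- .aa_tokens(m[2]); new_aa <- if (nzchar(m[4])) .aa_tokens(m[4]) else NULL
    if (!is.null(ref) && length(ref) == 1 &&
        (is.null(new_aa) || length(new_aa) == 1)) {
      has_ter <- grepl("fs(Ter|\\*|X)", body)
      return(mk(edit = "fs", start = hgvs_pos(as.integer(m[3])), ref = ref,
                fs_new_aa = if (is.null(new_aa)) NA_character_ else new_aa,
                fs_ter_offset = if (nzchar(m[5])) as.integer(m[5])
                                else NA_integer_))
    }
  }
  # extension: Ter110GlnextTer17 / Met1extN
  m <- regmatches(body, regexec(paste0(
    "^(", aa, ")(\\d+)(", aa, ")?ext(?:(?:Ter|\\*)?(-?\\d+|\\?)?)?$"),
    body, perl = TRUE))[[1]]
  if (length(m)) {
    ref <- .aa_tokens(m[2])
    if (!is.null(ref) && length(ref) == 1)
      return(mk(edit = "ext", start = hgvs_pos(as.integer(m[3])), ref = ref,
                alt = if (nzchar(m[4])) .aa_tokens(m[4])[1] else NA_character_,
                fs_ter_offset = if (nzchar(m[5]) && m[5] != "?")
                                  as.integer(m[5]) else NA_integer_))
  }
  # ranged del/dup/ins/delins
  m <- regmatches(body, regexec(paste0(
    "^(", aa, ")(\\d+)(?:_(", aa, ")(\\d+))?(del|dup|ins|delins)(.*)$"),
    body, perl = TRUE))[[1]]
  if (length(m)) {
    ref1 <- .aa_tokens(m[2])
    ref2 <- if (nzchar(m[4])) .aa_tokens(m[4]) else NULL
    kind <- m[6]
    alt <- if (nzchar(m[7])) .aa_tokens(m[7]) else NULL
    ok_alt <- (kind %in% c("ins", "delins")) == !is.null(alt)
    if (!is.null(ref1) && length(ref1) == 1 &&
        (is.null(ref2) || length(ref2) == 1) && ok_alt) {
      return(mk(edit = kind,
                start = hgvs_pos(as.integer(m[3])),
                end = if (nzchar(m[5])) hgvs_pos(as.integer(m[5])) else NULL,
                ref = paste0(ref1, if (!is.null(ref2)) paste0("_", ref2) else ""),
                alt = if (is.null(alt)) NA_character_
                      else paste(alt, collapse = "")))
    }
  }
  # substitution / synonymous: Aaa123Bbb, Aaa123=, Q480X, Ter110=
  m <- regmatches(body, regexec(paste0(
    "^(", aa, ")(\\d+)(=|", aa, ")$"), body, perl = TRUE))[[1]]
  if (length(m)) {
    ref <- .aa_tokens(m[2])
    if (!is.null(ref) && length(ref) == 1) {
      alt <- if (m[4] == "=") ref else .aa_tokens(m[4])
      if (!is.null(alt) && length(alt) == 1)
        return(mk(edit = "sub", start = hgvs_pos(as.integer(m[3])),
                  ref = ref, alt = alt))
    }
  }
  NULL
}

#' Canonicalize a protein-level HGVS description
#'
#' Rewrites the description in preferred form: three-letter amino-acid
#' codes, `Ter` for stops, `=` rendering for synonymous substitutions.
#' Short-form frameshifts are left short (expansion would need the protein
#' sequence). Idempotent.
#'
#' @param desc an `"hgvs"` object with `molecule == "p"`.
#' @return the canonicalized `"hgvs"` object; its `raw` field is the
#'   preferred rendering.
#' @examples
#' render_hgvs(canonicalize_protein(parse_hgvs("p.Q480X")))
#' @export
canonicalize_protein <- function(desc) {
  if (!is_hgvs(desc)) stop("not an hgvs object")
  if (desc$molecule != "p") stop("canonicalize_protein needs a p. description")
  # parser already stores three-letter/Ter internally; rendering is canonical
  desc$raw <- render_hgvs(desc, with_accession = FALSE)
  desc$predicted <- FALSE
  desc
}

#' Render an HGVS description in preferred syntax
#'
#' @param desc an `"hgvs"` object.
#' @param with_accession prefix `accession.version:` when available.
#' @return a character scalar.
#' @export
render_hgvs <- function(desc, with_accession = TRUE) {
  if (!is_hgvs(desc)) stop("not an hgvs object")
  pre <- ""
  if (with_accession && !is.na(desc$accession)) {
    pre <- paste0(desc$accession,
                  if (!is.na(desc$version)) paste0(".", desc$version) else "",
                  ":")
  }
  if (desc$molecule == "p") return(paste0(pre, "p.", .render_protein(desc)))
  paste0(pre, desc$molecule, ".", .render_nucleotide(desc))
}

.render_nucleotide <- function(d) {
  span <- .fmt_pos(d$start)
  if (!is.null(d$end)) span <- paste0(span, "_", .fmt_pos(d$end))
  switch(d$edit,
    sub = paste0(span, d$ref, ">", d$alt),
    del = paste0(span, "del"),
    dup = paste0(span, "dup"),
    ins = paste0(span, "ins", d$alt),
    delins = paste0(span, "delins", d$alt),
    inv = paste0(span, "inv"),
    identity = paste0(span, "="),
    "repeat" = paste0(span, d$ref, "[", d$repeat_count, "]"),
    stop("cannot render edit kind ", d$edit))
}

.render_protein <- function(d) {
  if (d$edit == "identity" && is.null(d$start)) return("=")
  p1 <- function() paste0(d$ref, d$start$base)
  switch(d$edit,
    sub = if (identical(d$ref, d$alt)) paste0(p1(), "=")
          else paste0(p1(), d$alt),
    fs = paste0(p1(),
                if (!is.na(d$fs_new_aa)) d$fs_new_aa else "",
                "fs",
                if (!is.na(d$fs_ter_offset)) paste0("Ter", d$fs_ter_offset)
                else ""),
    ext = paste0(p1(), if (!is.na(d$alt)) d$alt else "", "ext",
                 if (!is.na(d$fs_ter_offset)) paste0("Ter", d$fs_ter_offset)
                 else ""),
    del = , dup = {
      refs <- strsplit(d$ref, "_", fixed = TRUE)[[1]]
      span <- paste0(refs[1], d$start$base)
      if (!is.null(d$end)) span <- paste0(span, "_", refs[2], d$end$base)
      paste0(span, d$edit)
    },
    ins = , delins = {
      refs <- strsplit(d$ref, "_", fixed = TRUE)[[1]]
      span <- paste0(refs[1], d$start$base)
      if (!is.null(d$end)) span <- paste0(span, "_", refs[2], d$end$base)
      paste0(span, d$edit, d$alt)
    },
    stop("cannot render protein edit kind ", d$edit))
}

#' A minimal transcript model
#'
#' @param accession transcript accession (e.g. `"NM_000001"`).
#' @param cdna cDNA sequence as an uppercase DNA string.
#' @param version optional integer version.
#' @param cds_start 1-based offset of coding position 1 within `cdna`.
#' @param cds_end 1-based end of the CDS within `cdna`.
#' @param strand `"+"` or `"-"` (informational).
#' @return a list of class `"transcript_model"`.
#' @export
transcript_model <- function(accession, cdna, version = NA_integer_,
                             cds_start = 1L, cds_end = nchar(cdna),
                             strand = "+") {
  cdna <- toupper(cdna)
  stopifnot(nchar(cdna) >= 1, cds_start >= 1, cds_end <= nchar(cdna),
            cds_start <= cds_end)
  structure(list(accession = accession, version = version, cdna = cdna,
                 cds_start = as.integer(cds_start),
                 cds_end = as.integer(cds_end), strand = strand),
            class = "transcript_model")
}

# Map a coding position (no intron offset, no UTR zone for simplicity beyond
# 5'/3' arithmetic) into a 1-based index of the cDNA string.
.pos_index <- function(p, tm) {
  if (!is.na(p$offset)) stop("intron offsets are not representable in cDNA")
  if (isTRUE(p$utr == "5utr")) return(tm$cds_start - p$base)
  if (isTRUE(p$utr == "3utr")) return(tm$cds_end + p$base)
  tm$cds_start - 1L + p$base
}

.index_pos <- function(i, tm) {
  if (i < tm$cds_start) return(hgvs_pos(tm$cds_start - i, utr = "5utr"))
  if (i > tm$cds_end) return(hgvs_pos(i - tm$cds_end, utr = "3utr"))
  hgvs_pos(i - tm$cds_start + 1L)
}

#' Apply a coding HGVS edit to a sequence
#'
#' The independent oracle for equivalence: two descriptions are the same
#' variant iff they edit the transcript into the same sequence.
#'
#' @param seq DNA string, or a [transcript_model()].
#' @param desc an `"hgvs"` object with `molecule` in `c`, `n` and positions
#'   inside the sequence (no intron offsets).
#' @return the edited DNA string.
#' @export
apply_edit <- function(seq, desc) {
  tm <- if (inherits(seq, "transcript_model")) seq
        else transcript_model("seq", seq)
  s <- tm$cdna
  if (!is_hgvs(desc)) stop("not an hgvs object")
  if (!desc$molecule %in% c("c", "n")) stop("apply_edit needs c. or n.")
  i <- .pos_index(desc$start, tm)
  j <- if (!is.null(desc$end)) .pos_index(desc$end, tm) else i
  if (i < 1 || j > nchar(s) || j < i) stop("position out of range")
  seg <- substr(s, i, j)
  if (!is.na(desc$ref) && desc$edit %in% c("sub", "del", "dup", "delins",
                                           "inv") && desc$ref != seg &&
      desc$edit != "sub")
    stop("reference discordant: stated ", desc$ref, " found ", seg)
  left <- substr(s, 1, i - 1)
  right <- substr(s, j + 1, nchar(s))
  switch(desc$edit,
    sub = {
      if (seg != desc$ref)
        stop("reference discordant: stated ", desc$ref, " found ", seg)
      paste0(left, desc$alt, right)
    },
    del = paste0(left, right),
    dup = paste0(left, seg, seg, right),
    ins = {
      if (j != i + 1) stop("ins needs two flanking positions")
      paste0(substr(s, 1, i), desc$alt, substr(s, i + 1, nchar(s)))
    },
    delins = paste0(left, desc$alt, right),
    inv = paste0(left, .revcomp(seg), right),
    identity = s,
    "repeat" = {
      # seg begins a run of the stated unit; rewrite run to N copies
      unit <- desc$ref; k <- 0L
      while (substr(s, i + k * nchar(unit),
                    i + (k + 1) * nchar(unit) - 1) == unit) k <- k + 1L
      if (k == 0L) stop("reference discordant: no ", unit, " run at site")
      paste0(left, strrep(unit, desc$repeat_count),
             substr(s, i + k * nchar(unit), nchar(s)))
    },
    stop("unsupported edit kind ", desc$edit))
}

.revcomp <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

#' Shift a deletion/duplication/insertion maximally 3' (the HGVS 3' rule)
#'
#' Returns the unique most-3' description of the same edit; insertions whose
#' inserted allele equals the immediately 5' reference segment become
#' duplications (HGVS prefers dup over ins). Substitutions and other kinds
#' are returned unchanged. Idempotent, and `apply_edit` output is preserved.
#'
#' @param desc an `"hgvs"` coding description without intron offsets.
#' @param tm a [transcript_model()] (or plain DNA string).
#' @return the shifted `"hgvs"` object (alleles filled in from the sequence).
#' @export
shift3 <- function(desc, tm) {
  if (!inherits(tm, "transcript_model")) tm <- transcript_model("seq", tm)
  s <- tm$cdna
  if (!is_hgvs(desc)) stop("not an hgvs object")
  if (!desc$molecule %in% c("c", "n") ||
      !desc$edit %in% c("del", "dup", "ins")) return(desc)
  i <- .pos_index(desc$start, tm)
  j <- if (!is.null(desc$end)) .pos_index(desc$end, tm) else i
  n <- nchar(s)
  if (desc$edit %in% c("del", "dup")) {
    seg <- substr(s, i, j)
    if (!is.na(desc$ref) && desc$ref != seg)
      stop("reference discordant: stated ", desc$ref, " found ", seg)
    # slide the interval right while the base entering from the right
    # equals the base leaving on the left
    while (j < n && substr(s, j + 1, j + 1) == substr(s, i, i)) {
      i <- i + 1L; j <- j + 1L
    }
    out <- desc
    out$start <- .index_pos(i, tm)
    out$end <- if (j > i) .index_pos(j, tm) else NULL
    out$ref <- substr(s, i, j)
    out$raw <- NA_character_
    return(out)
  }
  # insertion between i and j=i+1: rotate while next right base equals the
  # first base of the inserted allele
  if (j != i + 1) stop("ins needs two flanking positions")
  allele <- desc$alt
  while (i + 1 <= n && substr(s, i + 1, i + 1) == substr(allele, 1, 1)) {
    allele <- paste0(substr(allele, 2, nchar(allele)), substr(allele, 1, 1))
    i <- i + 1L
  }
  L <- nchar(allele)
  if (i - L + 1 >= 1 && substr(s, i - L + 1, i) == allele) {
    out <- desc
    out$edit <- "dup"
    out$start <- .index_pos(i - L + 1L, tm)
    out$end <- if (L > 1) .index_pos(i, tm) else NULL
    out$ref <- allele
    out$alt <- NA_character_
    out$raw <- NA_character_
    return(out)
  }
  out <- desc
  out$start <- .index_pos(i, tm)
  out$end <- .index_pos(i + 1L, tm)
  out$alt <- allele
  out$raw <- NA_character_
  out
}

#' Version-aware transcript accession matching
#'
#' @param query,reference accession strings, with or without a `.version`
#'   suffix (e.g. `"NM_000059"` or `"NM_000059.4"`).
#' @param ignore_version drop versions before comparing (the convention
#'   needed for versionless ANNOVAR output).
#' @return logical scalar.
#' @export
accession_match <- function(query, reference, ignore_version = TRUE) {
  split1 <- function(x) {
    m <- regmatches(x, regexec("^(.*?)(?:\\.(\\d+))?$", x))[[1]]
    list(acc = m[2], ver = if (nzchar(m[3])) as.integer(m[3]) else NA_integer_)
  }
  q <- split1(query); r <- split1(reference)
  if (q$acc != r$acc) return(FALSE)
  if (ignore_version) return(TRUE)
  if (is.na(q$ver) || is.na(r$ver)) return(TRUE)
  q$ver == r$ver
}

.match_result <- function(verdict, cause = NA_character_, detail = "") {
  data.frame(verdict = verdict, cause = cause, detail = detail,
             stringsAsFactors = FALSE)
}

# notation-level equality of two parsed nucleotide descriptions
.nt_canonical_equal <- function(q, r) {
  if (q$edit == r$edit) {
    same <- .pos_equal(q$start, r$start) &&
      identical(is.null(q$end), is.null(r$end)) &&
      (is.null(q$end) || .pos_equal(q$end, r$end))
    if (!same) return(FALSE)
    return(switch(q$edit,
      sub = q$ref == r$ref && q$alt == r$alt,
      ins = , delins = q$alt == r$alt,
      del = , dup = , inv = is.na(q$ref) || is.na(r$ref) || q$ref == r$ref,
      "repeat" = q$ref == r$ref && q$repeat_count == r$repeat_count,
      identity = TRUE,
      FALSE))
  }
  # dup vs ins with stated alleles at the adjacent site
  kinds <- c(q$edit, r$edit)
  if (!("dup" %in% kinds && "ins" %in% kinds)) return(FALSE)
  pair <- list(q, r)
  d <- pair[[which(kinds == "dup")[1]]]
  i <- pair[[which(kinds == "ins")[1]]]
  if (!is.na(d$ref) && !is.na(i$alt) && d$ref == i$alt &&
      is.na(d$start$offset) && is.na(i$start$offset)) {
    dup_end <- if (!is.null(d$end)) d$end$base else d$start$base
    if (identical(i$start$base, dup_end) &&
        !is.null(i$end) && identical(i$end$base, dup_end + 1L))
      return(TRUE)
  }
  FALSE
}

# notation-level equality of two parsed protein descriptions
.p_canonical_equal <- function(q, r) {
  syn <- function(d) d$edit == "sub" && identical(d$ref, d$alt)
  if (syn(q) || syn(r))
    return(syn(q) && syn(r) && .pos_equal(q$start, r$start) &&
             q$ref == r$ref)
  if (q$edit == "fs" && r$edit == "fs") {
    if (!.pos_equal(q$start, r$start) || q$ref != r$ref) return(FALSE)
    short <- function(d) is.na(d$fs_new_aa) && is.na(d$fs_ter_offset)
    if (short(q) || short(r)) return(TRUE)  # short form matches any long form
    return(identical(q$fs_new_aa, r$fs_new_aa) &&
             identical(q$fs_ter_offset, r$fs_ter_offset))
  }
  if (q$edit != r$edit) return(FALSE)
  if (q$edit == "identity") return(TRUE)
  .pos_equal(q$start, r$start) &&
    identical(is.null(q$end), is.null(r$end)) &&
    (is.null(q$end) || .pos_equal(q$end, r$end)) &&
    identical(q$ref, r$ref) && identical(q$alt, r$alt) &&
    identical(q$fs_ter_offset, r$fs_ter_offset)
}

# full-level normal form for coding edits: shift3 against the transcript,
# with del/dup/ins allele text resolved from the sequence
.nt_full_equal <- function(q, r, tm) {
  normal <- function(d) {
    if (d$edit %in% c("del", "dup", "ins")) d <- shift3(d, tm)
    # resolve a dup into its duplicated segment for cross-kind identity
    key <- c(d$edit,
             .fmt_pos(d$start),
             if (!is.null(d$end)) .fmt_pos(d$end) else "",
             if (!is.na(d$ref)) d$ref else "",
             if (!is.na(d$alt)) d$alt else "")
    paste(key, collapse = "|")
  }
  ok <- try(identical(normal(q), normal(r)), silent = TRUE)
  if (!inherits(ok, "try-error") && isTRUE(ok)) return(TRUE)
  # last resort: sequence-level comparison via apply_edit
  sq <- try(apply_edit(tm, q), silent = TRUE)
  sr <- try(apply_edit(tm, r), silent = TRUE)
  !inherits(sq, "try-error") && !inherits(sr, "try-error") &&
    identical(sq, sr)
}

#' Compare two HGVS expressions
#'
#' Judges a query annotation against a reference expression. The verdict is
#' `missing` (no query), `exact` (same string after whitespace removal),
#' `equivalent` (same variant in a different but recognized notation), or
#' `mismatch`. Equivalent-but-not-exact verdicts carry cause
#' `non_preferred`; mismatches carry `position_or_type`, or `unknown` when
#' the query does not parse.
#'
#' @param query query HGVS string, or `NA`/`NULL` when the tool gave none.
#' @param reference reference HGVS string (must parse).
#' @param tm optional [transcript_model()] enabling sequence-aware (`full`)
#'   equivalence.
#' @param level `strict` (string identity), `canonical` (notation rules:
#'   amino-acid codes, Ter/X/*, `p.=`, short-vs-long frameshift, dup-vs-ins
#'   with stated alleles), or `full` (additionally 3'-shifting and sequence
#'   identity against `tm`).
#' @param ignore_version compare accessions version-blind (default, as
#'   required for versionless output).
#' @return one-row data.frame: `verdict`, `cause`, `detail`.
#' @examples
#' compare_hgvs("p.Q480X", "p.Gln480Ter", level = "canonical")
#' @export
compare_hgvs <- function(query, reference, tm = NULL,
                         level = c("canonical", "strict", "full"),
                         ignore_version = TRUE) {
  level <- match.arg(level)
  if (is.null(query) || length(query) == 0 || is.na(query) ||
      !nzchar(trimws(query)))
    return(.match_result("missing", "missing_na"))
  nows <- function(x) gsub("[[:space:]]+", "", x)
  if (nows(query) == nows(reference)) return(.match_result("exact"))
  r <- parse_hgvs(reference)
  if (!is_hgvs(r)) stop("reference does not parse: ", reference)
  q <- parse_hgvs(query)
  if (!is_hgvs(q))
    return(.match_result("mismatch", "unknown",
                         paste0("unparseable: ", q$token)))
  if (!is.na(q$accession) && !is.na(r$accession) &&
      !accession_match(paste0(q$accession,
                              ifelse(is.na(q$version), "",
                                     paste0(".", q$version))),
                       paste0(r$accession,
                              ifelse(is.na(r$version), "",
                                     paste0(".", r$version))),
                       ignore_version = ignore_version))
    return(.match_result("mismatch", "position_or_type",
                         "transcript accession differs"))
  if (q$molecule != r$molecule)
    return(.match_result("mismatch", "position_or_type",
                         "molecule differs"))
  # same-syntax check once accession handled (strict stops here)
  same_body <- identical(sub("^[^:]*:", "", nows(query)),
                         sub("^[^:]*:", "", nows(reference)))
  if (same_body) return(.match_result("equivalent", "non_preferred",
                                      "accession rendering differs"))
  if (level == "strict")
    return(.match_result("mismatch", "position_or_type"))
  eq <- if (q$molecule == "p") .p_canonical_equal(q, r)
        else .nt_canonical_equal(q, r)
  if (!eq && level == "full" && !is.null(tm) && q$molecule %in% c("c", "n")) {
    eq <- tryCatch(.nt_full_equal(q, r, tm), error = function(e) FALSE)
  }
  if (eq) return(.match_result("equivalent", "non_preferred"))
  .match_result("mismatch", "position_or_type")
}
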