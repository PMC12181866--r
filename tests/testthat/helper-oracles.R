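# Shared fixtures and independent oracles, built in code.

# Random transcript with a planted homopolymer run, so indel shifting has
# something to bite on.
random_transcript <- function(len = sample(40:100, 1)) {
  s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
             collapse = "")
  run_len <- sample(3:6, 1)
  start <- sample(5:(len - run_len - 5), 1)
  paste0(substr(s, 1, start - 1),
         strrep(sample(c("A", "C", "G", "T"), 1), run_len),
         substr(s, start + run_len, len))
}

# A random small coding edit on `seq`, as an hgvs object.
random_edit <- function(seq) {
  L <- nchar(seq)
  kind <- sample(c("del", "dup", "ins", "sub"), 1)
  i <- sample(3:(L - 4), 1)
  w <- sample(1:3, 1)
  txt <- switch(kind,
    del = if (w == 1) sprintf("c.%ddel", i)
          else sprintf("c.%d_%ddel", i, i + w - 1),
    dup = if (w == 1) sprintf("c.%ddup", i)
          else sprintf("c.%d_%ddup", i, i + w - 1),
    ins = sprintf("c.%d_%dins%s", i, i + 1,
                  paste(sample(c("A", "C", "G", "T"), w, replace = TRUE),
                        collapse = "")),
    sub = {
      ref <- substr(seq, i, i)
      sprintf("c.%d%s>%s", i, ref,
              sample(setdiff(c("A", "C", "G", "T"), ref), 1))
    })
  parse_hgvs(txt)
}

# All small del/dup/ins candidates near a position, as description strings;
# used to pool equivalent and non-equivalent partners for an edit.
candidate_edits <- function(seq, center, max_w = 3) {
  L <- nchar(seq)
  out <- character(0)
  for (i in max(2, center - 6):min(L - 2, center + 6)) {
    for (w in 1:max_w) {
      if (i + w - 1 <= L - 1) {
        out <- c(out,
                 if (w == 1) c(sprintf("c.%ddel", i), sprintf("c.%ddup", i))
                 else c(sprintf("c.%d_%ddel", i, i + w - 1),
                        sprintf("c.%d_%ddup", i, i + w - 1)),
                 sprintf("c.%d_%dins%s", i, i + 1,
                         substr(seq, i, i + w - 1)))
      }
    }
  }
  unique(out)
}

# Independent brute-force transcription of the 2015 rule-combining table,
# written as a literal rule list over strength counts (deliberately not
# sharing code with combine_criteria()).
oracle_combine <- function(strengths, directions,
                           benign_vs_sufficient = TRUE) {
  n_of <- function(dir, s) sum(directions == dir & strengths == s)
  PVS <- n_of("pathogenic", "very_strong")
  PS <- n_of("pathogenic", "strong")
  PM <- n_of("pathogenic", "moderate")
  PP <- n_of("pathogenic", "supporting")
  # a second very-strong has no 2015 slot; it is weighed as a strong
  if (PVS > 1) { PS <- PS + (PVS - 1); PVS <- 1 }
  BA <- n_of("benign", "standalone")
  BVS <- n_of("benign", "very_strong")
  BS <- n_of("benign", "strong")
  BP <- n_of("benign", "supporting")
  pathogenic <-
    (PVS == 1 && PS >= 1) ||
    (PVS == 1 && PM >= 2) ||
    (PVS == 1 && PM == 1 && PP == 1) ||
    (PVS == 1 && PM >= 1 && PP >= 1) ||
    (PVS == 1 && PP >= 2) ||
    (PS >= 2) ||
    (PS == 1 && PM >= 3) ||
    (PS == 1 && PM >= 2 && PP >= 2) ||
    (PS == 1 && PM >= 1 && PP >= 4) ||
    (PS >= 1 && (PM >= 3 || (PM >= 2 && PP >= 2) || (PM >= 1 && PP >= 4)))
  likely_path <-
    (PVS == 1 && PM >= 1) ||
    (PS >= 1 && PM >= 1) ||
    (PS >= 1 && PP >= 2) ||
    (PM >= 3) ||
    (PM >= 2 && PP >= 2) ||
    (PM >= 1 && PP >= 4)
  benign <- (BA >= 1) || (BS >= 2) ||
    (if (benign_vs_sufficient) BVS >= 1 else (BVS + BS) >= 2)
  likely_ben <- ((BS + BVS) >= 1 && BP >= 1) || (BP >= 2)
  p_side <- if (pathogenic) "P" else if (likely_path) "LP" else NA
  b_side <- if (benign) "B" else if (likely_ben) "LB" else NA
  if (!is.na(p_side) && !is.na(b_side)) return("VUS")
  if (!is.na(p_side)) return(p_side)
  if (!is.na(b_side)) return(b_side)
  "VUS"
}

# Brute-force Venn region counts by direct membership enumeration.
oracle_venn <- function(A, B, C) {
  A <- unique(A); B <- unique(B); C <- unique(C)
  u <- unique(c(A, B, C))
  region <- vapply(u, function(x) {
    paste0(ifelse(x %in% A, "A", ""), ifelse(x %in% B, "B", ""),
           ifelse(x %in% C, "C", ""))
  }, "")
  counts <- table(factor(region,
                         levels = c("A", "B", "C", "AB", "AC", "BC",
                                    "ABC")))
  list(A_only = unname(counts["A"]), B_only = unname(counts["B"]),
       C_only = unname(counts["C"]), AB = unname(counts["AB"]),
       AC = unname(counts["AC"]), BC = unname(counts["BC"]),
       ABC = unname(counts["ABC"]), union = length(u))
}

# Evidence constructor with the engine's expected field names.
make_evidence <- function(category = "Other", cadd = NA, spliceai = NA,
                          clinvar_class = NA, stars = NA,
                          external = NULL) {
  list(functional_category = category, cadd = cadd,
       spliceai_max = spliceai, clinvar_class = clinvar_class,
       stars = stars, external = external)
}
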