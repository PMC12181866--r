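# Ground-truthed simulator. Generates variants on synthetic transcript
# windows (with planted repeat runs so 3'-rule shifting is actually
# exercised), a ClinVar-style reference, three corrupted per-tool
# annotation tables, and an ACMG evidence table. Corruption channels are
# orthogonal by design — consequence confusion never rewrites the HGVS
# strings and non-preferred-syntax corruption never touches the consequence
# term — so every match fraction has an exact closed form
# (see expected_metrics()).

.SIM_TERMS_PLP <- c(
  stop_gained = 0.14, frameshift_variant = 0.16,
  splice_donor_variant = 0.05, splice_acceptor_variant = 0.04,
  missense_variant = 0.33, inframe_insertion = 0.03,
  inframe_deletion = 0.03, stop_lost = 0.01, start_lost = 0.01,
  synonymous_variant = 0.02, splice_region_variant = 0.04,
  intron_variant = 0.08, "5_prime_UTR_variant" = 0.03,
  "3_prime_UTR_variant" = 0.03)

.SIM_TERMS_BLB <- c(
  missense_variant = 0.17, synonymous_variant = 0.33,
  intron_variant = 0.25, "5_prime_UTR_variant" = 0.05,
  "3_prime_UTR_variant" = 0.12, splice_region_variant = 0.05,
  stop_gained = 0.005, frameshift_variant = 0.005,
  inframe_deletion = 0.01, inframe_insertion = 0.01)

# confusion sends a term to one plausible neighbour; note stop_gained's
# neighbour stays inside LoF (nonsense read as frameshift keeps PVS1),
# so category-preserving term swaps occur as they do in real output
.SIM_CONFUSION_NEIGHBOUR <- c(
  stop_gained = "frameshift_variant",
  frameshift_variant = "inframe_deletion",
  splice_donor_variant = "intron_variant",
  splice_acceptor_variant = "intron_variant",
  missense_variant = "synonymous_variant",
  synonymous_variant = "missense_variant",
  inframe_deletion = "frameshift_variant",
  inframe_insertion = "frameshift_variant",
  stop_lost = "missense_variant",
  start_lost = "missense_variant",
  splice_region_variant = "intron_variant",
  intron_variant = "splice_region_variant",
  "5_prime_UTR_variant" = "upstream_gene_variant",
  "3_prime_UTR_variant" = "downstream_gene_variant")

# terms whose preferred HGVSc admits an equivalent non-preferred rewriting
# in this generator (indels planted in repeat runs; dup vs ins)
.SIM_C_ALT_TERMS <- c("frameshift_variant", "inframe_deletion",
                      "inframe_insertion")
# terms that carry a protein-level description
.SIM_P_TERMS <- c("missense_variant", "synonymous_variant", "stop_gained",
                  "stop_lost", "start_lost", "frameshift_variant",
                  "inframe_deletion", "inframe_insertion")

.SO_IDS <- c(
  stop_gained = "SO:0001587", frameshift_variant = "SO:0001589",
  splice_donor_variant = "SO:0001575",
  splice_acceptor_variant = "SO:0001574",
  missense_variant = "SO:0001583", inframe_insertion = "SO:0001821",
  inframe_deletion = "SO:0001822", stop_lost = "SO:0001578",
  start_lost = "SO:0002012", synonymous_variant = "SO:0001819",
  splice_region_variant = "SO:0001630", intron_variant = "SO:0001627",
  "5_prime_UTR_variant" = "SO:0001623",
  "3_prime_UTR_variant" = "SO:0001624")

#' Simulator configuration
#'
#' Defaults emulate the curated clinical test set this pipeline targets:
#' the class mix follows the composition of a curated two-star ClinVar set
#' (23.3% P, 3.7% LP, 34.7% B, 38.4% LB), the PLP term mix is far richer in
#' LoF and indel consequences than the BLB mix, CADD is class-conditionally
#' normal (mean 30 sd 4 for PLP truth, mean 12 sd 5 for BLB, truncated at
#' 0) so both the PP3 and BP4 thresholds are exercised, and SpliceAI is
#' high only for splice-site truth.
#'
#' @param n_variants number of variants.
#' @param seed RNG seed; identical (config, seed) gives identical output.
#' @param class_mix probabilities over P/LP/B/LB.
#' @param term_mix_plp,term_mix_blb per-class probabilities over canonical
#'   SO terms.
#' @param tools per-tool corruption settings: each a list with
#'   `missing_rate`, `nonpreferred_rate`, `transcript_absent_rate`,
#'   `strip_version`, `confusion_off` (probability mass moved from a term
#'   to its designated neighbour).
#' @param cadd_mean,cadd_sd class-conditional CADD parameters
#'   (named PLP/BLB).
#' @param spliceai_splice_range,spliceai_other_range uniform ranges for the
#'   SpliceAI score given splice-site vs other truth.
#' @param stars_mix probabilities over 2/3/4 review stars.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(n_variants = 2000L, seed = 1L,
                       class_mix = c(P = 38278, LP = 6073, B = 57081,
                                     LB = 63117) / 164549,
                       term_mix_plp = .SIM_TERMS_PLP,
                       term_mix_blb = .SIM_TERMS_BLB,
                       tools = list(
                         annovar = list(missing_rate = 0.08,
                                        nonpreferred_rate = 0.15,
                                        transcript_absent_rate = 0.05,
                                        strip_version = TRUE,
                                        confusion_off = 0.02),
                         snpeff = list(missing_rate = 0.02,
                                       nonpreferred_rate = 0.10,
                                       transcript_absent_rate = 0.02,
                                       strip_version = FALSE,
                                       confusion_off = 0.015),
                         vep = list(missing_rate = 0.01,
                                    nonpreferred_rate = 0.05,
                                    transcript_absent_rate = 0.01,
                                    strip_version = FALSE,
                                    confusion_off = 0.01)),
                       cadd_mean = c(PLP = 30, BLB = 12),
                       cadd_sd = c(PLP = 4, BLB = 5),
                       spliceai_splice_range = c(0.6, 1),
                       spliceai_other_range = c(0, 0.2),
                       stars_mix = c("2" = 0.90, "3" = 0.09, "4" = 0.01)) {
  chk <- function(p, what) if (abs(sum(p) - 1) > 1e-9 || any(p < 0))
    stop(what, " must be a probability vector summing to 1")
  if (n_variants < 1) stop("degenerate config: n_variants < 1")
  chk(class_mix, "class_mix"); chk(term_mix_plp, "term_mix_plp")
  chk(term_mix_blb, "term_mix_blb"); chk(stars_mix, "stars_mix")
  for (t in names(tools)) {
    r <- unlist(tools[[t]][c("missing_rate", "nonpreferred_rate",
                             "transcript_absent_rate", "confusion_off")])
    if (any(r < 0 | r > 1)) stop("rates for ", t, " must lie in [0,1]")
  }
  structure(list(n_variants = as.integer(n_variants), seed = as.integer(seed),
                 class_mix = class_mix, term_mix_plp = term_mix_plp,
                 term_mix_blb = term_mix_blb, tools = tools,
                 cadd_mean = cadd_mean, cadd_sd = cadd_sd,
                 spliceai_splice_range = spliceai_splice_range,
                 spliceai_other_range = spliceai_other_range,
                 stars_mix = stars_mix),
            class = "sim_config")
}

.rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

.AA20 <- setdiff(.AA3, c("Ter", "Sec"))
.AA3_TO_1 <- stats::setNames(.AA1, .AA3)

.one_letter <- function(p3) {
  # rewrite the three-letter tokens of a protein body in one-letter code
  out <- p3
  for (aa in .AA3) out <- gsub(aa, .AA3_TO_1[[aa]], out, fixed = TRUE)
  out
}

# Build the truth HGVSc (preferred), its non-preferred alternative (or NA),
# and the VCF-style left-aligned alleles for one variant.
.sim_edit <- function(term, cdna, run_start, run_len) {
  L <- nchar(cdna)
  run_end <- run_start + run_len - 1L
  base_at <- function(i) substr(cdna, i, i)
  other_base <- function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1)
  sub_at <- function(pos_str, i) {
    ref <- base_at(i); alt <- other_base(ref)
    list(hgvs_c = sprintf("c.%s%s>%s", pos_str, ref, alt), alt_c = NA,
         ref = ref, alt = alt, offset_in_window = i)
  }
  exon_pos <- function() sample(setdiff(seq(5, L - 5),
                                        seq(run_start - 1, run_end + 1)), 1)
  switch(term,
    missense_variant = , synonymous_variant = , stop_gained = ,
    stop_lost = , start_lost = {
      i <- exon_pos(); sub_at(as.character(i), i)
    },
    splice_donor_variant = {
      e <- sample(20:(L - 20), 1)
      list(hgvs_c = sprintf("c.%d+1G>A", e), alt_c = NA,
           ref = "G", alt = "A", offset_in_window = NA)
    },
    splice_acceptor_variant = {
      e <- sample(20:(L - 20), 1)
      list(hgvs_c = sprintf("c.%d-2A>G", e), alt_c = NA,
           ref = "A", alt = "G", offset_in_window = NA)
    },
    splice_region_variant = {
      e <- sample(20:(L - 20), 1)
      list(hgvs_c = sprintf("c.%d+5G>A", e), alt_c = NA,
           ref = "G", alt = "A", offset_in_window = NA)
    },
    intron_variant = {
      e <- sample(20:(L - 20), 1)
      list(hgvs_c = sprintf("c.%d+%dA>G", e, sample(8:30, 1)), alt_c = NA,
           ref = "A", alt = "G", offset_in_window = NA)
    },
    "5_prime_UTR_variant" = {
      list(hgvs_c = sprintf("c.-%dA>G", sample(5:200, 1)), alt_c = NA,
           ref = "A", alt = "G", offset_in_window = NA)
    },
    "3_prime_UTR_variant" = {
      list(hgvs_c = sprintf("c.*%dA>G", sample(5:200, 1)), alt_c = NA,
           ref = "A", alt = "G", offset_in_window = NA)
    },
    frameshift_variant = {
      # 1-base deletion inside the planted run; preferred = most 3'
      d <- parse_hgvs(sprintf("c.%ddel", run_start))
      pref <- render_hgvs(shift3(d, cdna), with_accession = FALSE)
      list(hgvs_c = pref,
           alt_c = sprintf("c.%ddel", run_start),
           ref = paste0(base_at(run_start - 1L), base_at(run_start)),
           alt = base_at(run_start - 1L), offset_in_window = NA)
    },
    inframe_deletion = {
      d <- parse_hgvs(sprintf("c.%d_%ddel", run_start, run_start + 2L))
      pref <- render_hgvs(shift3(d, cdna), with_accession = FALSE)
      list(hgvs_c = pref,
           alt_c = sprintf("c.%d_%ddel", run_start, run_start + 2L),
           ref = paste0(base_at(run_start - 1L),
                        substr(cdna, run_start, run_start + 2L)),
           alt = base_at(run_start - 1L), offset_in_window = NA)
    },
    inframe_insertion = {
      # duplication of three run bases; ins form is the alternative
      d <- parse_hgvs(sprintf("c.%d_%ddup", run_start, run_start + 2L))
      sh <- shift3(d, cdna)
      pref <- render_hgvs(sh, with_accession = FALSE)
      b <- sh$end$base
      list(hgvs_c = pref,
           alt_c = sprintf("c.%d_%dins%s", b, b + 1L, sh$ref),
           ref = base_at(run_start - 1L),
           alt = paste0(base_at(run_start - 1L),
                        substr(cdna, run_start, run_start + 2L)),
           offset_in_window = NA)
    },
    stop("no edit recipe for term ", term))
}

.sim_protein <- function(term) {
  k <- sample(10:400, 1)
  aa <- function() sample(.AA20, 1)
  a1 <- aa(); a2 <- aa()
  while (a2 == a1) a2 <- aa()
  switch(term,
    missense_variant = {
      p <- sprintf("p.%s%d%s", a1, k, a2)
      list(hgvs_p = p, alts = c(paste0("p.", .one_letter(substr(p, 3, nchar(p))))))
    },
    synonymous_variant = {
      list(hgvs_p = sprintf("p.%s%d=", a1, k),
           alts = c(sprintf("p.%s%d%s", a1, k, a1),
                    sprintf("p.%s%d%s", .AA3_TO_1[[a1]], k, .AA3_TO_1[[a1]])))
    },
    stop_gained = {
      list(hgvs_p = sprintf("p.%s%dTer", a1, k),
           alts = c(sprintf("p.%s%dX", .AA3_TO_1[[a1]], k),
                    sprintf("p.%s%d*", a1, k)))
    },
    stop_lost = {
      m <- sample(5:60, 1)
      p <- sprintf("p.Ter%d%sextTer%d", k, a1, m)
      list(hgvs_p = p,
           alts = c(sprintf("p.*%d%sext*%d", k, .AA3_TO_1[[a1]], m)))
    },
    start_lost = {
      list(hgvs_p = sprintf("p.Met1%s", a1),
           alts = c(sprintf("p.M1%s", .AA3_TO_1[[a1]])))
    },
    frameshift_variant = {
      m <- sample(2:80, 1)
      list(hgvs_p = sprintf("p.%s%d%sfsTer%d", a1, k, a2, m),
           alts = c(sprintf("p.%s%dfs", a1, k),
                    sprintf("p.%s%d%sfs*%d", .AA3_TO_1[[a1]], k,
                            .AA3_TO_1[[a2]], m)))
    },
    inframe_deletion = {
      p <- sprintf("p.%s%d_%s%ddel", a1, k, a2, k + 2L)
      list(hgvs_p = p,
           alts = c(paste0("p.", .one_letter(substr(p, 3, nchar(p))))))
    },
    inframe_insertion = {
      a3 <- aa()
      p <- sprintf("p.%s%d_%s%dins%s", a1, k, a2, k + 1L, a3)
      list(hgvs_p = p,
           alts = c(paste0("p.", .one_letter(substr(p, 3, nchar(p))))))
    },
    list(hgvs_p = NA_character_, alts = character(0)))
}

#' Simulate a ground-truthed annotation benchmark
#'
#' Draws variants (class, consequence term, synthetic transcript window
#' with a planted repeat run, preferred HGVSc/HGVSp, scores, stars), then
#' corrupts them per tool through four labelled channels: missingness,
#' transcript unavailability (the annotation lands on a different
#' accession), non-preferred-syntax substitution (drawn from the known
#' equivalent-form set: one-letter amino acids, X-for-Ter, Val17Val,
#' short-form frameshifts, left-shifted indel placement, ins-for-dup), and
#' consequence confusion to a neighbouring term. ANNOVAR-style output
#' additionally strips transcript versions.
#'
#' @param cfg a [sim_config()].
#' @return list with `truth` (one row per variant incl. the cDNA window),
#'   `reference` (ClinVar-style records, annotation-model layout plus
#'   clnsig/stars), `tool_annotations` (named list of annotation
#'   data.frames), `labels` (per (tool, variant) corruption labels),
#'   `evidence` (ACMG evidence table) and `transcripts` (named cDNA
#'   vector).
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_variants
  cls <- sample(names(cfg$class_mix), n, replace = TRUE,
                prob = cfg$class_mix)
  grp <- ifelse(cls %in% c("P", "LP"), "PLP", "BLB")
  truth <- vector("list", n)
  transcripts <- character(n)
  for (i in seq_len(n)) {
    mix <- if (grp[i] == "PLP") cfg$term_mix_plp else cfg$term_mix_blb
    term <- sample(names(mix), 1, prob = mix)
    L <- sample(seq(60L, 300L, 3L), 1)
    cdna <- .rand_dna(L)
    run_len <- sample(6:9, 1)
    run_start <- sample(seq(10L, L - 10L - run_len), 1)
    run_base <- sample(c("A", "C", "G", "T"), 1)
    cdna <- paste0(substr(cdna, 1, run_start - 1L),
                   strrep(run_base, run_len),
                   substr(cdna, run_start + run_len, L))
    # guard the run boundary so the planted run is the maximal run
    if (substr(cdna, run_start - 1L, run_start - 1L) == run_base)
      cdna <- paste0(substr(cdna, 1, run_start - 2L),
                     other <- setdiff(c("A", "C", "G", "T"), run_base)[1],
                     substr(cdna, run_start, L))
    if (substr(cdna, run_start + run_len, run_start + run_len) == run_base)
      cdna <- paste0(substr(cdna, 1, run_start + run_len - 1L),
                     setdiff(c("A", "C", "G", "T"), run_base)[1],
                     substr(cdna, run_start + run_len + 1L, L))
    acc <- sprintf("NM_%06d", 100000L + i)
    ver <- sample(1:9, 1)
    ed <- .sim_edit(term, cdna, run_start, run_len)
    pr <- .sim_protein(term)
    stars <- as.integer(sample(names(cfg$stars_mix), 1,
                               prob = cfg$stars_mix))
    splice_truth <- term %in% c("splice_donor_variant",
                                "splice_acceptor_variant")
    cadd <- max(0, stats::rnorm(1, cfg$cadd_mean[grp[i]],
                                cfg$cadd_sd[grp[i]]))
    sar <- if (splice_truth) cfg$spliceai_splice_range
           else cfg$spliceai_other_range
    truth[[i]] <- data.frame(
      chrom = as.character(sample(c(1:22, "X"), 1)), pos = 1000L + i * 97L,
      ref = ed$ref, alt = ed$alt, clinvar_id = i,
      clinvar_class = cls[i], stars = stars,
      term = term, category = functional_category(term),
      accession = acc, version = ver,
      hgvs_c = ed$hgvs_c,
      hgvs_c_alt = if (is.na(ed$alt_c[1])) NA_character_ else ed$alt_c,
      hgvs_p = pr$hgvs_p,
      hgvs_p_alts = paste(pr$alts, collapse = ";"),
      cadd = round(cadd, 2),
      spliceai_max = round(stats::runif(1, sar[1], sar[2]), 3),
      stringsAsFactors = FALSE)
    transcripts[i] <- cdna
  }
  truth <- do.call(rbind, truth)
  names(transcripts) <- truth$accession
  reference <- .annotation_df(
    tool = "clinvar", chrom = truth$chrom, pos = truth$pos,
    ref = truth$ref, alt = truth$alt, accession = truth$accession,
    version = truth$version, protein_accession = NA_character_,
    hgvs_c = truth$hgvs_c, hgvs_p = truth$hgvs_p,
    consequences = truth$term)
  reference$clinvar_id <- truth$clinvar_id
  reference$clinvar_class <- truth$clinvar_class
  reference$stars <- truth$stars
  reference$variant_class <- classify_variant_class(truth$ref, truth$alt)
  tool_annotations <- list(); labels <- list()
  for (tool in names(cfg$tools)) {
    tc <- cfg$tools[[tool]]
    miss <- stats::runif(n) < tc$missing_rate
    tabs <- stats::runif(n) < tc$transcript_absent_rate
    npr <- stats::runif(n) < tc$nonpreferred_rate
    conf <- stats::runif(n) < tc$confusion_off
    term_out <- ifelse(conf, .SIM_CONFUSION_NEIGHBOUR[truth$term],
                       truth$term)
    hc <- truth$hgvs_c; hp <- truth$hgvs_p
    c_eff <- npr & !is.na(truth$hgvs_c_alt)
    hc[c_eff] <- truth$hgvs_c_alt[c_eff]
    p_eff <- npr & nzchar(truth$hgvs_p_alts)
    for (i in which(p_eff)) {
      alts <- strsplit(truth$hgvs_p_alts[i], ";", fixed = TRUE)[[1]]
      hp[i] <- sample(alts, 1)
    }
    acc <- ifelse(tabs, sprintf("NM_9%05d", seq_len(n)), truth$accession)
    ver <- if (isTRUE(tc$strip_version)) rep(NA_integer_, n)
           else truth$version
    ann <- .annotation_df(
      tool = tool, chrom = truth$chrom, pos = truth$pos, ref = truth$ref,
      alt = truth$alt, accession = acc, version = ver,
      protein_accession = NA_character_, hgvs_c = hc, hgvs_p = hp,
      consequences = .tool_raw_term(term_out, tool))
    ann <- ann[!miss, , drop = FALSE]
    rownames(ann) <- NULL
    tool_annotations[[tool]] <- ann
    labels[[tool]] <- data.frame(
      tool = tool, clinvar_id = truth$clinvar_id,
      missing = miss, transcript_dropped = tabs,
      nonpreferred_form_used = npr,
      nonpreferred_c_effective = c_eff, nonpreferred_p_effective = p_eff,
      term_confused = conf, emitted_term = term_out,
      emitted_hgvs_c = hc, emitted_hgvs_p = hp,
      emitted_accession = acc,
      stringsAsFactors = FALSE)
  }
  evidence <- data.frame(
    chrom = truth$chrom, pos = truth$pos, ref = truth$ref,
    alt = truth$alt, clinvar_id = truth$clinvar_id,
    functional_category = truth$category, cadd = truth$cadd,
    spliceai_max = truth$spliceai_max,
    clinvar_class = truth$clinvar_class, stars = truth$stars,
    stringsAsFactors = FALSE)
  list(truth = truth, reference = reference,
       tool_annotations = tool_annotations,
       labels = do.call(rbind, labels), evidence = evidence,
       transcripts = transcripts, config = cfg)
}

# express a canonical term in the tool's own vocabulary; SnpEff splice
# terms come out "&"-joined with intron_variant as real SnpEff output does
.tool_raw_term <- function(term, tool) {
  if (tool == "annovar") {
    map <- c(stop_gained = "stopgain", stop_lost = "stoploss",
             start_lost = "startloss",
             missense_variant = "nonsynonymous_SNV",
             synonymous_variant = "synonymous_SNV",
             frameshift_variant = "frameshift_deletion",
             inframe_deletion = "nonframeshift_deletion",
             inframe_insertion = "nonframeshift_insertion",
             intron_variant = "intronic",
             "5_prime_UTR_variant" = "UTR5",
             "3_prime_UTR_variant" = "UTR3",
             upstream_gene_variant = "upstream",
             downstream_gene_variant = "downstream")
    out <- unname(map[term])
    out[is.na(out)] <- term[is.na(out)]
    return(out)
  }
  if (tool == "snpeff") {
    splice <- term %in% c("splice_donor_variant", "splice_acceptor_variant")
    return(ifelse(splice, paste0(term, "&intron_variant"), term))
  }
  term
}

#' Closed-form expectations for the simulator's pipeline metrics
#'
#' With orthogonal corruption channels every metric factorizes: an
#' annotation is comparable when neither missing nor on an absent
#' transcript, the consequence matches unless confused, and the HGVS string
#' matches exactly unless a non-preferred form was substituted (which
#' equivalence-aware comparison resolves). PVS1 loss/gain rates follow from
#' the truth mass of each term times its confusion mass across the LoF
#' boundary.
#'
#' @param cfg a [sim_config()].
#' @return per-tool data.frame of expected fractions: `hgvsc_equiv`,
#'   `hgvsc_strict`, `hgvsp_equiv`, `hgvsp_strict`, `impact`,
#'   `pvs1_loss_rate`, `pvs1_gain_rate` (the PVS1 rates are conditional on
#'   an observed tool category, over all variants).
#' @export
expected_metrics <- function(cfg = sim_config()) {
  p_term <- function(term_set) {
    plp <- sum(cfg$class_mix[c("P", "LP")])
    sum(cfg$term_mix_plp[names(cfg$term_mix_plp) %in% term_set]) * plp +
      sum(cfg$term_mix_blb[names(cfg$term_mix_blb) %in% term_set]) *
        (1 - plp)
  }
  p_c_alt_overall <- p_term(.SIM_C_ALT_TERMS)
  p_has_p <- p_term(.SIM_P_TERMS)
  p_c_alt_given_p <- p_term(intersect(.SIM_C_ALT_TERMS, .SIM_P_TERMS)) /
    p_has_p
  lof_terms <- .category_map$LoF
  loss_terms <- names(.SIM_CONFUSION_NEIGHBOUR)[
    names(.SIM_CONFUSION_NEIGHBOUR) %in% lof_terms &
      !.SIM_CONFUSION_NEIGHBOUR %in% lof_terms]
  gain_terms <- names(.SIM_CONFUSION_NEIGHBOUR)[
    .SIM_CONFUSION_NEIGHBOUR %in% lof_terms &
      !names(.SIM_CONFUSION_NEIGHBOUR) %in% lof_terms]
  out <- lapply(names(cfg$tools), function(tool) {
    tc <- cfg$tools[[tool]]
    obs <- (1 - tc$missing_rate) * (1 - tc$transcript_absent_rate)
    data.frame(
      tool = tool,
      observable = obs,
      hgvsc_equiv = obs,
      hgvsc_strict = obs * (1 - tc$nonpreferred_rate * p_c_alt_overall),
      hgvsp_equiv = obs,
      hgvsp_strict = obs * (1 - tc$nonpreferred_rate),
      impact = obs * (1 - tc$confusion_off),
      pvs1_loss_rate = p_term(loss_terms) * tc$confusion_off,
      pvs1_gain_rate = p_term(gain_terms) * tc$confusion_off,
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.CLNSIG_OUT <- c(P = "Pathogenic", LP = "Likely_pathogenic",
                 B = "Benign", LB = "Likely_benign")
.REVSTAT_OUT <- c("2" = "criteria_provided,_multiple_submitters,_no_conflicts",
                  "3" = "reviewed_by_expert_panel",
                  "4" = "practice_guideline")

#' Write a simulated dataset as on-disk tool dialects
#'
#' Emits a ClinVar-dialect reference VCF (CLNSIG / CLNREVSTAT / MC plus the
#' extension keys CLNSELTR / CLNHGVSC / CLNHGVSP for the selected
#' transcript and its HGVS), an ANN-dialect VCF, a CSQ-dialect VCF, an
#' ANNOVAR-style multianno TSV, the transcript windows as FASTA, and the
#' truth/evidence tables as TSV — so the package's real parsers can be
#' exercised end to end.
#'
#' @param sim result of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return named vector of the file paths written.
#' @export
write_outputs <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tr <- sim$truth
  ref_lines <- vapply(seq_len(nrow(tr)), function(i) {
    acc <- paste0(tr$accession[i], ".", tr$version[i])
    info <- paste0(
      "CLNSIG=", .CLNSIG_OUT[tr$clinvar_class[i]],
      ";CLNREVSTAT=", .REVSTAT_OUT[as.character(tr$stars[i])],
      ";MC=", .SO_IDS[tr$term[i]], "|", tr$term[i],
      ";CLNSELTR=", acc,
      ";CLNHGVSC=", acc, ":", tr$hgvs_c[i],
      if (!is.na(tr$hgvs_p[i]))
        paste0(";CLNHGVSP=", acc, ":", tr$hgvs_p[i]) else "")
    paste(tr$chrom[i], tr$pos[i], tr$clinvar_id[i], tr$ref[i], tr$alt[i],
          ".", ".", info, sep = "\t")
  }, "")
  paths <- c(reference = file.path(dir, "reference.vcf"),
             snpeff = file.path(dir, "snpeff.vcf"),
             vep = file.path(dir, "vep.vcf"),
             annovar = file.path(dir, "annovar.tsv"),
             transcripts = file.path(dir, "transcripts.fa"),
             truth = file.path(dir, "truth.tsv"),
             evidence = file.path(dir, "evidence.tsv"))
  info_defs <- c(
    "##INFO=<ID=CLNSIG,Number=.,Type=String,Description=\"Clinical significance\">",
    "##INFO=<ID=CLNREVSTAT,Number=.,Type=String,Description=\"Review status\">",
    "##INFO=<ID=MC,Number=.,Type=String,Description=\"Molecular consequence (SO id|term)\">",
    "##INFO=<ID=CLNSELTR,Number=1,Type=String,Description=\"Selected transcript\">",
    "##INFO=<ID=CLNHGVSC,Number=1,Type=String,Description=\"Coding HGVS on the selected transcript\">",
    "##INFO=<ID=CLNHGVSP,Number=1,Type=String,Description=\"Protein HGVS on the selected transcript\">")
  writeLines(c(.vcf_header(info_defs), ref_lines), paths["reference"])
  write_snpeff_vcf(sim$tool_annotations$snpeff, paths["snpeff"])
  write_vep_vcf(sim$tool_annotations$vep, paths["vep"])
  write_annovar_table(sim$tool_annotations$annovar, paths["annovar"])
  writeLines(as.vector(rbind(paste0(">", names(sim$transcripts)),
                             sim$transcripts)), paths["transcripts"])
  utils::write.table(sim$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  utils::write.table(sim$evidence, paths["evidence"], sep = "\t",
                     quote = FALSE, row.names = FALSE, na = ".")
  invisible(paths)
}

#' Read transcript windows written by [write_outputs()]
#'
#' @param path FASTA file of cDNA windows.
#' @return named character vector of sequences.
#' @export
read_transcript_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(seqs)), names(seqs))
}
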