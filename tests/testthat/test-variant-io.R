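# Dialect parsers: ClinVar INFO, SnpEff ANN, VEP CSQ, ANNOVAR tables.

clinvar_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".vcf",
                                .local_envir = parent.frame())
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=CLNSIG,Number=.,Type=String,Description=\"x\">",
               "##INFO=<ID=CLNREVSTAT,Number=.,Type=String,Description=\"x\">",
               "##INFO=<ID=MC,Number=.,Type=String,Description=\"x\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               lines), path)
  path
}

test_that("ClinVar records map review status, significance and MC terms", {
  path <- clinvar_fixture(c(
    "13\t100\t11\tA\tG\t.\t.\tCLNSIG=Pathogenic;CLNREVSTAT=reviewed_by_expert_panel;MC=SO:0001575|splice_donor_variant",
    "2\t200\t12\tC\tT\t.\t.\tCLNSIG=Uncertain_significance;CLNREVSTAT=criteria_provided,_multiple_submitters,_no_conflicts;MC=SO:0001583|missense_variant",
    "3\t300\t13\tG\tGA\t.\t.\tCLNSIG=Benign;CLNREVSTAT=practice_guideline;MC=SO:0001589|frameshift_variant,SO:0001627|intron_variant"))
  rec <- read_clinvar_vcf(path)
  expect_equal(nrow(rec), 3)
  expect_equal(rec$stars, c(3L, 2L, 4L))
  expect_equal(rec$clnsig, c("P", "VUS", "B"))
  expect_equal(rec$mc[[1]]$term, "splice_donor_variant")
  expect_equal(rec$mc[[3]]$term,
               c("frameshift_variant", "intron_variant"))
  expect_error(read_clinvar_vcf(file.path(tempdir(), "nope.vcf")),
               "no such file")
})

test_that("multi-allelic lines split and oddities are counted, not fatal", {
  path <- clinvar_fixture(c(
    "1\t100\t21\tA\tG,T\t.\t.\tCLNSIG=Pathogenic;CLNREVSTAT=reviewed_by_expert_panel;MC=SO:0001583|missense_variant",
    "1\t200\t22\tA\tG\t.\t.\tCLNSIG=Pathogenic;CLNREVSTAT=some_new_status;MC=SO:0001583|missense_variant&synonymous_variant"))
  rec <- read_clinvar_vcf(path)
  expect_equal(nrow(rec), 3)              # one extra row from the split
  expect_equal(rec$alt[1:2], c("G", "T"))
  flagged <- attr(rec, "flagged")
  expect_equal(unname(flagged["multiallelic_split"]), 1L)
  expect_equal(unname(flagged["unknown_review_status"]), 1L)
  expect_equal(unname(flagged["multi_term_mc_entry"]), 1L)
  expect_true(rec$mc[[3]]$multi)
})

test_that("SnpEff ANN entries split on commas and ampersands", {
  var <- list(chrom = "1", pos = 100L, ref = "A", alt = "G")
  ann <- paste0(
    "G|splice_donor_variant&intron_variant|HIGH|X|X|transcript|",
    "NM_001048174.2|protein_coding|1/1|c.1434+2del||||||,",
    "G|missense_variant|MODERATE|X|X|transcript|NM_000001.1|",
    "protein_coding|1/1|c.76A>G|p.Ile26Val|||||")
  a <- parse_snpeff_ann(ann, var)
  expect_equal(nrow(a), 2)
  expect_equal(a$consequences[1], "splice_donor_variant&intron_variant")
  expect_equal(a$accession[1], "NM_001048174")
  expect_equal(a$version[1], 2L)
  expect_true(is.na(a$hgvs_p[1]))       # empty HGVS.p subfield -> absent
  expect_equal(a$hgvs_p[2], "p.Ile26Val")
  # short entries are flagged, non-NM/NR/ENST accessions rejected
  bad <- parse_snpeff_ann("G|x|y", var)
  expect_equal(nrow(bad), 0)
  expect_equal(unname(attr(bad, "flagged")["malformed_entry"]), 1L)
  odd <- parse_snpeff_ann(
    "G|missense_variant|M|X|X|transcript|XR_0001.1|pc|1/1|c.1A>G|p.K1R",
    var)
  expect_equal(unname(attr(odd, "flagged")["rejected_accession"]), 1L)
})

test_that("VEP CSQ parsing is header-driven and decodes URL escapes", {
  var <- list(chrom = "1", pos = 100L, ref = "A", alt = "G")
  order1 <- c("Allele", "Consequence", "Feature", "HGVSc", "HGVSp")
  csq1 <- "G|missense_variant|ENST00000544455.6|ENST00000544455.6:c.68A>G|ENSP00000369497.3:p.Asp23Gly"
  a1 <- parse_vep_csq(csq1, order1, var)
  expect_equal(a1$accession, "ENST00000544455")
  expect_equal(a1$version, 6L)
  expect_equal(a1$hgvs_c, "c.68A>G")
  expect_equal(a1$hgvs_p, "p.Asp23Gly")
  expect_equal(a1$protein_accession, "ENSP00000369497.3")
  # permuted header order parses to the same result
  order2 <- rev(order1)
  csq2 <- paste(rev(strsplit(csq1, "|", fixed = TRUE)[[1]]),
                collapse = "|")
  a2 <- parse_vep_csq(csq2, order2, var)
  expect_equal(a1[, c("accession", "version", "hgvs_c", "hgvs_p")],
               a2[, c("accession", "version", "hgvs_c", "hgvs_p")])
  # %3D decodes to "="
  a3 <- parse_vep_csq("G|synonymous_variant|NM_000001.1|NM_000001.1:c.51G%3DA|NM_000001.1:p.Val17%3D",
                      order1, var)
  expect_equal(a3$hgvs_p, "p.Val17=")
})

test_that("ANNOVAR tables split transcript sub-entries and sentinels", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    paste("Chr", "Start", "End", "Ref", "Alt", "Func.refGene",
          "Gene.refGene", "GeneDetail.refGene", "ExonicFunc.refGene",
          "AAChange.refGene", sep = "\t"),
    "2\t2662\t2662\tG\tA\texonic\tOTOF\t.\tstopgain\tOTOF:NM_194248:exon22:c.2662G>A:p.E888K",
    "3\t100\t100\tC\tT\tintronic\tGENE2\tGENE2:NM_000011:exon2:c.12-5C>T\t.\t.",
    "4\t200\t200\tA\tG\texonic\tGENE3\t.\tsynonymous SNV\tGENE3:NM_1:exon1:c.1A>G:p.K1K,GENE3:NM_2:exon1:c.5A>G:p.Q2Q",
    "5\t300\t300\tT\tC\tintergenic\tNONE\t.\t.\t."), path)
  a <- read_annovar_table(path)
  expect_equal(a$accession[1], "NM_194248")
  expect_true(is.na(a$version[1]))       # ANNOVAR never reports versions
  expect_true(all(is.na(a$protein_accession)))
  expect_equal(a$hgvs_c[1], "c.2662G>A")
  expect_equal(a$hgvs_p[1], "p.E888K")
  expect_equal(a$consequences[2], "intronic")
  expect_equal(sum(a$accession %in% c("NM_1", "NM_2")), 2)  # comma split
  expect_equal(unname(attr(a, "flagged")["missing_cell"]), 1L)
  expect_error(read_annovar_table(path, column_map = c(chrom = "Kr")),
               "missing required columns")
})

test_that("all parsers share one absent state and round-trip their dialect", {
  set.seed(11)
  # fuzzed annotations; ANNOVAR constraints: no version, per-variant terms
  n <- 40
  base <- data.frame(
    tool = "x", chrom = as.character(sample(1:22, n, TRUE)),
    pos = sample.int(1e6, n), ref = sample(c("A", "C", "G", "T"), n, TRUE),
    alt = sample(c("A", "C", "G", "T"), n, TRUE),
    accession = sprintf("NM_%06d", sample.int(999999, n)),
    version = sample(c(NA, 1:9), n, TRUE),
    protein_accession = NA_character_,
    hgvs_c = ifelse(runif(n) < .8,
                    sprintf("c.%d%s>%s", sample.int(5000, n),
                            sample(c("A", "C"), n, TRUE),
                            sample(c("G", "T"), n, TRUE)), NA),
    hgvs_p = ifelse(runif(n) < .6,
                    sprintf("p.Ala%dVal", sample.int(400, n)), NA),
    consequences = sample(c("missense_variant", "synonymous_variant",
                            "stop_gained&splice_region_variant"), n, TRUE),
    stringsAsFactors = FALSE)
  key <- function(df) paste(df$chrom, df$pos, df$ref, df$alt, df$accession)
  roundtrip <- function(writer, reader, ann) {
    path <- withr::local_tempfile(.local_envir = parent.frame())
    writer(ann, path)
    got <- reader(path)
    m <- match(key(ann), key(got))
    expect_false(any(is.na(m)))
    for (col in c("hgvs_c", "hgvs_p", "consequences", "version"))
      expect_equal(got[[col]][m], ann[[col]], label = col)
  }
  sn <- base; sn$tool <- "snpeff"
  roundtrip(write_snpeff_vcf, read_snpeff_vcf, sn)
  vp <- base; vp$tool <- "vep"
  roundtrip(write_vep_vcf, read_vep_vcf, vp)
  av <- base; av$tool <- "annovar"; av$version <- NA_integer_
  # ANNOVAR's table needs HGVSc present for an entry to exist
  av$hgvs_c[is.na(av$hgvs_c)] <- "c.1A>G"
  av$consequences <- sub("&.*", "", av$consequences)
  roundtrip(write_annovar_table, read_annovar_table, av)
  # one shared absent state across dialects
  expect_true(is.na(parse_snpeff_ann(
    "G|missense_variant|M|X|X|transcript|NM_1.1|pc|1/1||p.K1R",
    list(chrom = "1", pos = 1L, ref = "A", alt = "G"))$hgvs_c))
})
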