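# The ground-truthed simulator: determinism, limits, label sufficiency,
# file round trips.

test_that("identical config and seed give identical datasets and files", {
  cfg <- sim_config(n_variants = 40, seed = 99)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$tool_annotations, s2$tool_annotations)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_outputs(s1, d1); p2 <- write_outputs(s2, d2)
  for (f in names(p1))
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]),
                     label = paste("file", f))
  # a different seed changes the draw
  s3 <- simulate_dataset(sim_config(n_variants = 40, seed = 100))
  expect_false(identical(s1$truth, s3$truth))
})

test_that("config validation rejects degenerate settings", {
  expect_error(sim_config(n_variants = 0), "n_variants")
  expect_error(sim_config(class_mix = c(P = 0.5, LP = 0.2, B = 0.2,
                                        LB = 0.2)), "summing to 1")
  bad_tools <- list(annovar = list(missing_rate = 1.2,
                                   nonpreferred_rate = 0,
                                   transcript_absent_rate = 0,
                                   strip_version = TRUE,
                                   confusion_off = 0))
  expect_error(sim_config(tools = bad_tools), "\\[0,1\\]")
})

no_noise_tools <- function() {
  lapply(stats::setNames(nm = c("annovar", "snpeff", "vep")), function(t)
    list(missing_rate = 0, nonpreferred_rate = 0,
         transcript_absent_rate = 0, strip_version = (t == "annovar"),
         confusion_off = 0))
}

test_that("with zero corruption every tool matches and the venn is all-ABC", {
  sim <- simulate_dataset(sim_config(n_variants = 200, seed = 17,
                                     tools = no_noise_tools()))
  res <- compare_annotations(sim$reference, sim$tool_annotations,
                             sim$transcripts)
  rep <- concordance_report(res, sim$tool_annotations)
  expect_true(all(rep$fractions$fraction == 1))
  expect_true(all(rep$fractions$fraction_strict == 1))
  expect_equal(rep$venn$hgvsc$ABC, rep$venn$hgvsc$union)
  expect_equal(rep$venn$hgvsp$ABC, rep$venn$hgvsp$union)
  for (tool in names(rep$pvs1)) {
    expect_equal(unname(rep$pvs1[[tool]]["pvs1_loss"]), 0L)
    expect_equal(unname(rep$pvs1[[tool]]["pvs1_gain"]), 0L)
  }
  em <- expected_metrics(sim$config)
  expect_true(all(em$hgvsc_equiv == 1 & em$impact == 1 &
                    em$pvs1_loss_rate == 0))
})

test_that("an isolated missingness rate is recovered binomially", {
  tools <- no_noise_tools()
  tools$snpeff$missing_rate <- 0.2
  sim <- simulate_dataset(sim_config(n_variants = 2000, seed = 29,
                                     tools = tools))
  res <- compare_annotations(sim$reference, sim$tool_annotations,
                             sim$transcripts)
  fr <- match_fraction(res[res$metric == "hgvsc", ])
  got <- fr$fraction[fr$tool == "snpeff"]
  expect_lt(abs(got - 0.8), 3 * sqrt(0.8 * 0.2 / 2000))
  expect_equal(fr$fraction[fr$tool == "vep"], 1)
  # every snpeff miss is attributed to the missing-annotation cause
  causes <- attr(fr, "causes")$snpeff
  expect_equal(causes$cause, "missing_na")
  expect_equal(causes$cause_share, 1)
})

test_that("corruption labels plus truth regenerate the emitted annotations", {
  sim <- simulate_dataset(sim_config(n_variants = 150, seed = 43))
  for (tool in names(sim$tool_annotations)) {
    lab <- sim$labels[sim$labels$tool == tool, ]
    keep <- !lab$missing
    rebuilt <- data.frame(
      clinvar_id = lab$clinvar_id[keep],
      accession = lab$emitted_accession[keep],
      hgvs_c = lab$emitted_hgvs_c[keep],
      hgvs_p = lab$emitted_hgvs_p[keep],
      consequences = varconcord:::.tool_raw_term(lab$emitted_term[keep],
                                                 tool),
      stringsAsFactors = FALSE)
    ann <- sim$tool_annotations[[tool]]
    expect_identical(rebuilt$accession, ann$accession)
    expect_identical(rebuilt$hgvs_c, ann$hgvs_c)
    expect_identical(rebuilt$hgvs_p, ann$hgvs_p)
    expect_identical(rebuilt$consequences, ann$consequences)
    # labels are consistent with what they claim
    expect_true(all(lab$emitted_hgvs_c[!lab$nonpreferred_c_effective] ==
                      sim$truth$hgvs_c[!lab$nonpreferred_c_effective]))
    expect_true(all(lab$emitted_term[!lab$term_confused] ==
                      sim$truth$term[!lab$term_confused]))
  }
})

test_that("written files form a complete set and reparse to the same tables", {
  sim <- simulate_dataset(sim_config(n_variants = 10, seed = 3))
  dir <- withr::local_tempdir()
  paths <- write_outputs(sim, dir)
  expect_setequal(names(paths),
                  c("reference", "snpeff", "vep", "annovar", "transcripts",
                    "truth", "evidence"))
  expect_true(all(file.exists(paths)))
  ref <- read_clinvar_vcf(paths["reference"])
  expect_equal(nrow(ref), 10)
  expect_equal(ref$clnsig, sim$truth$clinvar_class)
  expect_equal(ref$stars, sim$truth$stars)
  expect_equal(sub("^[^:]*:", "", ref$hgvs_c), sim$truth$hgvs_c)
  expect_equal(vapply(ref$mc, function(m) m$term[1], ""), sim$truth$term)
  # pipeline verdicts from files match the in-memory run exactly
  from_files <- list(annovar = read_annovar_table(paths["annovar"]),
                     snpeff = read_snpeff_vcf(paths["snpeff"]),
                     vep = read_vep_vcf(paths["vep"]))
  fa <- read_transcript_fasta(paths["transcripts"])
  expect_identical(unname(fa), unname(sim$transcripts))
  res_files <- compare_annotations(sim$reference, from_files, fa)
  res_mem <- compare_annotations(sim$reference,
                                 sim$tool_annotations[names(from_files)],
                                 sim$transcripts)
  expect_identical(res_files$verdict, res_mem$verdict)
  expect_identical(res_files$cause, res_mem$cause)
})
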