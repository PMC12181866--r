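# HGVS parsing, canonical protein syntax, edit application and 3' shifting.

test_that("coding and protein descriptions parse into structured fields", {
  d <- parse_hgvs("NM_001009944.3:c.5824dup")
  expect_equal(d$accession, "NM_001009944")
  expect_equal(d$version, 3L)
  expect_equal(d$molecule, "c")
  expect_equal(d$edit, "dup")
  expect_equal(d$start$base, 5824L)

  d <- parse_hgvs("NM_000419.5:c.310+3_310+6del")
  expect_equal(d$start$base, 310L)
  expect_equal(d$start$offset, 3L)
  expect_equal(d$end$base, 310L)
  expect_equal(d$end$offset, 6L)
  expect_equal(d$edit, "del")

  d <- parse_hgvs("p.F12Lfs*13")
  expect_equal(d$ref, "Phe")
  expect_equal(d$start$base, 12L)
  expect_equal(d$fs_new_aa, "Leu")
  expect_equal(d$fs_ter_offset, 13L)

  d <- parse_hgvs("c.-12A>G")
  expect_equal(d$start$utr, "5utr")
  d <- parse_hgvs("c.*45del")
  expect_equal(d$start$utr, "3utr")

  # repeat notation parses (comparison support is deliberately limited)
  d <- parse_hgvs("c.53AGC[23]")
  expect_equal(d$edit, "repeat")
  expect_equal(d$repeat_count, 23L)
})

test_that("unparseable input returns a structured failure, not an error", {
  bad <- parse_hgvs("c.notavariant")
  expect_false(is_hgvs(bad))
  expect_s3_class(bad, "hgvs_parse_error")
  expect_true(nzchar(bad$token))
})

test_that("protein canonicalization prefers three-letter codes, Ter and =", {
  canon <- function(x) render_hgvs(canonicalize_protein(parse_hgvs(x)))
  expect_equal(canon("p.Q480X"), "p.Gln480Ter")
  expect_equal(canon("p.Gln480*"), "p.Gln480Ter")
  expect_equal(canon("p.Val17Val"), "p.Val17=")
  expect_equal(canon("p.V17V"), "p.Val17=")
  # idempotence
  expect_equal(canon("p.Gln480Ter"), "p.Gln480Ter")
  expect_equal(canon(canon("p.Q480X")), canon("p.Q480X"))
  expect_error(canonicalize_protein(parse_hgvs("c.76A>T")), "p\\.")
})

test_that("apply_edit implements HGVS edit semantics", {
  expect_equal(apply_edit("ATGTTTTGC", parse_hgvs("c.4del")), "ATGTTTGC")
  expect_equal(apply_edit("ATGTTTTGC", parse_hgvs("c.7del")), "ATGTTTGC")
  expect_equal(apply_edit("ACGT", parse_hgvs("c.2dup")), "ACCGT")
  expect_equal(apply_edit("ACGT", parse_hgvs("c.2C>G")), "AGGT")
  expect_equal(apply_edit("ACGT", parse_hgvs("c.2_3insTT")), "ACTTGT")
  expect_equal(apply_edit("ACGTAA", parse_hgvs("c.2_4delinsG")), "AGAA")
  expect_equal(apply_edit("ACGTAA", parse_hgvs("c.2_4inv")), "AACGAA")
  expect_error(apply_edit("ACGT", parse_hgvs("c.2A>G")),
               "reference discordant")
  expect_error(apply_edit("ACGT", parse_hgvs("c.9del")), "range")
})

test_that("shift3 right-aligns and prefers duplication over insertion", {
  s <- shift3(parse_hgvs("c.4del"), "ATGTTTTGC")
  expect_equal(s$start$base, 7L)
  # dup preference: inserting C after a C becomes a dup of that C
  seqc <- "AACGG"
  s <- shift3(parse_hgvs("c.3_4insC"), seqc)
  expect_equal(s$edit, "dup")
  expect_equal(s$start$base, 3L)
  # no repeat: fixed point
  s <- shift3(parse_hgvs("c.2del"), "ACGT")
  expect_equal(s$start$base, 2L)
  # idempotence and sequence preservation on a run
  tm <- "ATGTTTTGC"
  d <- parse_hgvs("c.4_5del")
  s1 <- shift3(d, tm); s2 <- shift3(s1, tm)
  expect_equal(render_hgvs(s1), render_hgvs(s2))
  expect_equal(apply_edit(tm, d), apply_edit(tm, s1))
  expect_gte(s1$start$base, d$start$base)
})

test_that("accession matching is version-blind when asked", {
  expect_true(accession_match("NM_000059", "NM_000059.4"))
  expect_true(accession_match("NM_000059.3", "NM_000059.4",
                              ignore_version = TRUE))
  expect_false(accession_match("NM_000059.3", "NM_000059.4",
                               ignore_version = FALSE))
  expect_false(accession_match("NM_000059.4", "ENST00000544455.6"))
  # a versionless side cannot contradict a strict comparison
  expect_true(accession_match("NM_000059", "NM_000059.4",
                              ignore_version = FALSE))
})

test_that("compare_hgvs grades exactness, equivalence and mismatch causes", {
  r <- compare_hgvs("p.Arg1942fs", "p.Arg1942ProfsTer48")
  expect_equal(r$verdict, "equivalent")
  expect_equal(r$cause, "non_preferred")
  # two contradictory long frameshift forms are position/type mismatches
  r <- compare_hgvs("p.Arg1942GlyfsTer10", "p.Arg1942ProfsTer48")
  expect_equal(r$verdict, "mismatch")
  expect_equal(r$cause, "position_or_type")
  r <- compare_hgvs(NA, "c.310+3_310+6del")
  expect_equal(r$verdict, "missing")
  expect_equal(r$cause, "missing_na")
  r <- compare_hgvs("c.76A>T", "c.76A>T")
  expect_equal(r$verdict, "exact")
  r <- compare_hgvs("p.(Gln480Ter)", "p.Gln480Ter")
  expect_equal(r$verdict, "equivalent")
  r <- compare_hgvs("garbage!!", "c.76A>T")
  expect_equal(r$cause, "unknown")
  # accession mismatch decides before syntax
  r <- compare_hgvs("NM_000001.1:c.76A>T", "NM_000002.1:c.76A>T")
  expect_equal(r$verdict, "mismatch")
  # dup-vs-ins without sequence needs the alleles spelled out
  r <- compare_hgvs("c.3_4insC", "c.3dupC", level = "canonical")
  expect_equal(r$verdict, "equivalent")
  r <- compare_hgvs("c.3_4insC", "c.3dup", level = "canonical")
  expect_equal(r$verdict, "mismatch")
  # repeat notation never judges equivalent at canonical level
  r <- compare_hgvs("c.5AG[3]", "c.5_6dup", level = "canonical")
  expect_equal(r$verdict, "mismatch")
})

test_that("sequence-aware comparison resolves shifted and rewritten forms", {
  tm <- transcript_model("t", paste0(strrep("A", 30), "TATATA",
                                     strrep("G", 10)))
  r <- compare_hgvs("c.31_32del", "c.35_36del", tm = tm, level = "full")
  expect_equal(r$verdict, "equivalent")
  # same pair without sequence cannot be resolved
  r <- compare_hgvs("c.31_32del", "c.35_36del", level = "canonical")
  expect_equal(r$verdict, "mismatch")
  seqc <- paste0(strrep("G", 5822), "TC", "AAA")
  tm2 <- transcript_model("t2", seqc)
  r <- compare_hgvs("c.5824_5825insC", "c.5824dup", tm = tm2,
                    level = "full")
  expect_equal(r$verdict, "equivalent")
})

test_that("equivalence relations nest: strict within canonical within full", {
  set.seed(41)
  tm_seq <- random_transcript(60)
  tm <- transcript_model("t", tm_seq)
  for (k in 1:200) {
    d <- random_edit(tm_seq)
    partner <- parse_hgvs(sample(candidate_edits(tm_seq, d$start$base), 1))
    q <- render_hgvs(partner, with_accession = FALSE)
    ref <- render_hgvs(d, with_accession = FALSE)
    v <- function(level) compare_hgvs(q, ref, tm = tm, level = level)$verdict
    ok <- c(strict = v("strict") %in% c("exact", "equivalent"),
            canonical = v("canonical") %in% c("exact", "equivalent"),
            full = v("full") %in% c("exact", "equivalent"))
    expect_true(!ok[["strict"]] || ok[["canonical"]])
    expect_true(!ok[["canonical"]] || ok[["full"]])
    # symmetry at the canonical level
    expect_equal(
      compare_hgvs(q, ref, tm = tm)$verdict %in% c("exact", "equivalent"),
      compare_hgvs(ref, q, tm = tm)$verdict %in% c("exact", "equivalent"))
    # reflexivity
    expect_equal(compare_hgvs(ref, ref)$verdict, "exact")
  }
})
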