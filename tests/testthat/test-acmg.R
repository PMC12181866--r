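# The modified ACMG engine: criterion evaluation, thresholds, combining.

applied_ids <- function(a) sort(a$criterion)

test_that("criterion evaluation follows the modified rules", {
  a <- evaluate_criteria(make_evidence("LoF", cadd = 34,
                                       clinvar_class = "P", stars = 2))
  expect_setequal(a$criterion, c("PVS1", "PP5"))
  expect_equal(a$strength[a$criterion == "PP5"], "moderate")
  expect_false("PP3" %in% a$criterion)   # suppressed under PVS1

  a <- evaluate_criteria(make_evidence("Missense", cadd = 20,
                                       spliceai = 0.1,
                                       clinvar_class = "B", stars = 2))
  expect_setequal(a$criterion, c("BP4", "BP6"))
  expect_equal(a$strength[a$criterion == "BP6"], "strong")

  a <- evaluate_criteria(make_evidence("Synonymous", spliceai = 0.05,
                                       clinvar_class = "B", stars = 3))
  expect_setequal(a$criterion, c("BP7", "BP6"))
  expect_equal(a$strength[a$criterion == "BP6"], "very_strong")

  a <- evaluate_criteria(make_evidence("ProteinLengthChange",
                                       clinvar_class = "P", stars = 4))
  expect_setequal(a$criterion, c("PM4", "PP5"))
  expect_equal(a$strength[a$criterion == "PP5"], "very_strong")

  # splice signal alone triggers PP3 and vetoes BP7
  a <- evaluate_criteria(make_evidence("Synonymous", spliceai = 0.9))
  expect_setequal(a$criterion, "PP3")

  # external flags pass through; excluded criteria never fire
  a <- evaluate_criteria(make_evidence("Other",
                                       external = c("PM2", "PS4", "BP5")))
  expect_setequal(a$criterion, "PM2")
})

test_that("thresholds behave exactly at the boundaries", {
  eps <- 1e-9
  fires <- function(cadd = NA, spliceai = NA, category = "Missense")
    evaluate_criteria(make_evidence(category, cadd = cadd,
                                    spliceai = spliceai))$criterion
  expect_true("PP3" %in% fires(cadd = 25.3))
  expect_false("PP3" %in% fires(cadd = 25.3 - eps))
  expect_false("BP4" %in% fires(cadd = 22.7))
  expect_true("BP4" %in% fires(cadd = 22.7 - eps))
  # between the thresholds: neither PP3 nor BP4
  expect_length(fires(cadd = 24), 0)
  expect_true("PP3" %in% fires(spliceai = 0.5))
  expect_false("PP3" %in% fires(spliceai = 0.5 - eps))
  # BP4 requires the splice signal to be low or absent
  expect_false("BP4" %in% fires(cadd = 10, spliceai = 0.5))
  expect_true("BP4" %in% fires(cadd = 10, spliceai = 0.5 - eps))
  expect_error(evaluate_criteria(make_evidence("Other", spliceai = 1.2)),
               "0,1")
})

test_that("combining reproduces the published rule combinations", {
  comb <- function(ids, strengths = NULL) {
    a <- data.frame(criterion = ids,
                    strength = if (is.null(strengths))
                      varconcord:::.criterion_default_strength(ids)
                    else strengths,
                    direction = varconcord:::.criterion_direction(ids),
                    stringsAsFactors = FALSE)
    combine_criteria(a)
  }
  expect_equal(comb(c("PVS1", "PM2")), "LP")
  expect_equal(comb(character(0)), "VUS")
  expect_equal(comb(c("PVS1", "PS1")), "P")
  expect_equal(comb(c("PVS1", "PM1", "PM2")), "P")
  expect_equal(comb(c("PS1", "PS3")), "P")
  expect_equal(comb(c("PS1", "PM1", "PM2", "PM4")), "P")
  expect_equal(comb(c("PM1", "PM2", "PM4")), "LP")
  expect_equal(comb(c("PS1", "PP1", "PP2")), "LP")
  expect_equal(comb(c("BA1")), "B")
  expect_equal(comb(c("BS1", "BS2")), "B")
  expect_equal(comb(c("BS1", "BP4")), "LB")
  expect_equal(comb(c("BP4", "BP7")), "LB")
  expect_equal(comb(c("BS1")), "VUS")
  # conflicting evidence on both sides lands in VUS
  expect_equal(comb(c("PVS1", "PS1", "BA1")), "VUS")
  # the downgrade mechanism in miniature
  expect_equal(comb(c("PVS1", "PP5"),
                    c("very_strong", "moderate")), "LP")
  expect_equal(comb(c("PP5", "PP3"), c("moderate", "supporting")), "VUS")
  # a promoted benign very-strong suffices for Benign
  expect_equal(comb("BP6", "very_strong"), "B")
})

test_that("every subset of a 12-criterion pool matches the brute-force table", {
  pool <- data.frame(
    criterion = c("PVS1", "PS1", "PS3", "PM1", "PM2", "PM4", "PP1", "PP3",
                  "BA1", "BS1", "BS2", "BP4"),
    stringsAsFactors = FALSE)
  pool$strength <- varconcord:::.criterion_default_strength(pool$criterion)
  pool$direction <- varconcord:::.criterion_direction(pool$criterion)
  res <- vapply(0:(2^12 - 1), function(mask) {
    sel <- pool[bitwAnd(mask, 2^(0:11)) > 0, , drop = FALSE]
    c(engine = combine_criteria(sel),
      oracle = oracle_combine(sel$strength, sel$direction))
  }, c(engine = "", oracle = ""))
  expect_equal(unname(res["engine", ]), unname(res["oracle", ]))
  expect_equal(length(unique(res["engine", ])), 5L)  # all five tiers occur
})

test_that("promoted strengths also match the oracle exhaustively", {
  pool <- data.frame(
    criterion = c("PVS1", "PP5", "PS1", "PM1", "PM4", "PP1", "PP3",
                  "BA1", "BP6", "BS1", "BP4", "BP7"),
    strength = c("very_strong", "very_strong", "strong", "moderate",
                 "moderate", "supporting", "supporting",
                 "standalone", "very_strong", "strong", "supporting",
                 "supporting"),
    stringsAsFactors = FALSE)
  pool$direction <- varconcord:::.criterion_direction(pool$criterion)
  res <- vapply(0:(2^12 - 1), function(mask) {
    sel <- pool[bitwAnd(mask, 2^(0:11)) > 0, , drop = FALSE]
    c(engine = combine_criteria(sel),
      oracle = oracle_combine(sel$strength, sel$direction))
  }, c(engine = "", oracle = ""))
  expect_equal(unname(res["engine", ]), unname(res["oracle", ]))
})

test_that("PVS1 and PP3 never co-fire, and classes compose via classify", {
  set.seed(47)
  for (k in 1:300) {
    e <- make_evidence(
      category = sample(c("LoF", "Missense", "ProteinLengthChange",
                          "Synonymous", "Other"), 1),
      cadd = sample(c(NA, runif(1, 0, 50)), 1),
      spliceai = sample(c(NA, runif(1)), 1),
      clinvar_class = sample(c(NA, "P", "LP", "B", "LB"), 1),
      stars = sample(2:4, 1))
    out <- classify_acmg(e)
    expect_false(all(c("PVS1", "PP3") %in% out$applied$criterion))
    expect_true(out$class %in% c("B", "LB", "VUS", "LP", "P"))
    expect_equal(out$class, combine_criteria(out$applied))
  }
})

test_that("extra pathogenic evidence never demotes the pathogenic side", {
  set.seed(53)
  pool <- c("PVS1", "PS1", "PS3", "PM1", "PM2", "PM4", "PP1", "PP3")
  for (k in 1:200) {
    ids <- sample(pool, sample(0:5, 1))
    extra <- sample(setdiff(pool, ids), 1)
    mk <- function(x) data.frame(
      criterion = x,
      strength = varconcord:::.criterion_default_strength(x),
      direction = varconcord:::.criterion_direction(x),
      stringsAsFactors = FALSE)
    before <- classification_factor(combine_criteria(mk(ids)))
    after <- classification_factor(combine_criteria(mk(c(ids, extra))))
    expect_true(after >= before)
  }
})
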