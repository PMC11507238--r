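make_calls <- function(labels, status, trait = "eye") {
  tibble::tibble(sample_id = sprintf("x%d", seq_along(labels)),
                 trait = trait, labels = labels, status = status)
}

test_that("match classification follows the strict and flexible rules", {
  calls <- make_calls(
    c("brown", "blue", "intermediate/brown", "intermediate/brown", NA),
    c("definitive", "definitive", "undefined", "undefined", "NA"))
  obs <- c("brown", "brown", "brown", "blue", "brown")
  strict <- classify_match(calls, obs, "strict")
  expect_equal(strict$match,
               c("correct", "incorrect", "uncertain", "uncertain", "NA"))
  flex <- classify_match(calls, obs, "flexible")
  expect_equal(flex$match,
               c("correct", "incorrect", "correct", "incorrect", "NA"))
  # unknown observed category errors
  expect_error(classify_match(calls, c("brown", "purple", "brown", "blue", "brown")),
               "purple")
  # skin empty undefined stays undefined in both modes
  skin_calls <- make_calls(NA_character_, "undefined", trait = "skin")
  for (mode in c("strict", "flexible")) {
    expect_equal(classify_match(skin_calls, "pale", mode)$match, "undefined")
  }
})

test_that("compound labels resolve to observed-if-member else leading label", {
  expect_equal(resolve_label("intermediate/brown", "brown"), "brown")
  expect_equal(resolve_label("intermediate/brown", "blue"), "intermediate")
  expect_equal(resolve_label("blue", "brown"), "blue")
  expect_equal(resolve_label(c("intermediate/blue", "black/brown"),
                             c("intermediate", "brown")),
               c("intermediate", "brown"))
})

test_that("confusion cells conserve the scored record count", {
  calls <- make_calls(
    c("blue", "brown", "intermediate/brown", "blue", NA, "intermediate/blue"),
    c("definitive", "definitive", "definitive", "definitive", "NA", "definitive"))
  obs <- c("blue", "brown", "brown", "brown", "blue", "brown")
  m <- classify_match(calls, obs, "flexible")
  cells <- confusion_counts(m)
  n_scored <- sum(!is.na(m$resolved))
  expect_true(all(cells$tp + cells$fp + cells$fn + cells$tn == n_scored))
  expect_equal(cells$n_na[1], 1)
  # single record observed = resolved = blue
  single <- classify_match(make_calls("blue", "definitive"), "blue", "strict")
  c1 <- confusion_counts(single)
  expect_equal(unlist(c1[c1$category == "blue", c("tp", "fp", "fn", "tn")]),
               c(tp = 1, fp = 0, fn = 0, tn = 0))
  expect_equal(unlist(c1[c1$category == "brown", c("tp", "fp", "fn", "tn")]),
               c(tp = 0, fp = 0, fn = 0, tn = 1))
})

test_that("all-correct predictions give zero FP and FN everywhere", {
  obs <- sample(trait_levels("eye"), 30, replace = TRUE)
  calls <- make_calls(obs, rep("definitive", 30))
  cells <- confusion_counts(classify_match(calls, obs, "strict"))
  expect_true(all(cells$fp == 0))
  expect_true(all(cells$fn == 0))
})

test_that("degenerate denominators give NA metrics, never an error", {
  # no predicted positives -> PPV undefined; unobserved category -> no sensitivity
  calls <- make_calls(c("brown", "brown"), rep("definitive", 2))
  mm <- classify_match(calls, c("brown", "blue"), "strict")
  met <- concordance_metrics(mm)
  expect_true(is.na(met$ppv[met$category == "blue"]))
  expect_true(is.na(met$sensitivity[met$category == "intermediate"]))
})

test_that("metrics equal an exhaustive per-pair counting oracle", {
  withr::with_seed(23, {
    levels <- trait_levels("eye")
    for (rep_i in 1:20) {
      n <- sample(10:50, 1)
      obs <- sample(levels, n, replace = TRUE)
      pred <- sample(levels, n, replace = TRUE)
      calls <- make_calls(pred, rep("definitive", n))
      mm <- classify_match(calls, obs, "strict")
      met <- concordance_metrics(mm)
      for (cat in levels) {
        tp <- sum(obs == cat & pred == cat)
        fp <- sum(obs != cat & pred == cat)
        fn <- sum(obs == cat & pred != cat)
        tn <- sum(obs != cat & pred != cat)
        row <- met[met$category == cat, ]
        expect_equal(unlist(row[, c("tp", "fp", "fn", "tn")]),
                     c(tp = tp, fp = fp, fn = fn, tn = tn))
        if (tp + fn > 0) expect_equal(row$sensitivity, tp / (tp + fn))
        if (tn + fp > 0) expect_equal(row$specificity, tn / (tn + fp))
        if (tp + fp > 0) expect_equal(row$ppv, tp / (tp + fp))
        if (tn + fn > 0) expect_equal(row$npv, tn / (tn + fn))
      }
    }
  })
})

test_that("flexible rescoring never loses correct matches and keeps incorrect fixed for eye", {
  records <- expand_breakdown(study_breakdown("eye", "strict"))
  calls <- records[, c("sample_id", "trait", "labels", "status")]
  strict <- classify_match(calls, records$observed, "strict")
  flex <- classify_match(calls, records$observed, "flexible")
  expect_gte(sum(flex$match == "correct"), sum(strict$match == "correct"))
  # eye-specific: incorrect counts per category unchanged except reclassified
  # uncertains; total incorrect for blue grows only from its uncertain pool
  expect_equal(sum(flex$match == "incorrect") - sum(strict$match == "incorrect"),
               sum(strict$match == "uncertain") -
                 (sum(flex$match == "correct") - sum(strict$match == "correct")))
})

test_that("breakdown expansion enforces the integer-count window", {
  # 40% of 7 implies 2.8 -> 3, but 3/7 = 42.86% disagrees beyond 0.5 points
  bd <- tibble::tibble(observed = "blue", n = 7L, outcome = "correct",
                       predicted = "blue", status = "definitive", pct = 40)
  expect_error(expand_breakdown(bd, "eye"), "non-integral")
  bd$n <- 32L
  bd$pct <- 93.75
  rec <- expand_breakdown(bd, "eye")
  expect_equal(nrow(rec), 30)
  # printed rounding inconsistencies within 0.5 points are absorbed
  bd$pct <- 3.33  # 1/32 = 3.125%
  expect_equal(nrow(expand_breakdown(bd, "eye")), 1)
  # zero-count row expands to nothing
  bd0 <- bd; bd0$pct <- 0
  expect_equal(nrow(expand_breakdown(bd0, "eye")), 0)
})
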