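test_that("eye calls follow the threshold band rules", {
  # definitive single calls above 0.7
  expect_equal(call_eye(c(blue = 0.85, intermediate = 0.05, brown = 0.10))$labels,
               "blue")
  expect_equal(call_eye(c(blue = 0.1, intermediate = 0.1, brown = 0.8))$status,
               "definitive")
  # 0.5-0.7 band: compound intermediate-X; strict undefined, flexible definitive
  strict <- call_eye(c(blue = 0.60, intermediate = 0.15, brown = 0.25), "strict")
  expect_equal(strict$labels, "intermediate/blue")
  expect_equal(strict$status, "undefined")
  flex <- call_eye(c(blue = 0.60, intermediate = 0.15, brown = 0.25), "flexible")
  expect_equal(flex$labels, "intermediate/blue")
  expect_equal(flex$status, "definitive")
  # both blue and brown at or below 0.5 -> intermediate
  both_low <- call_eye(c(blue = 0.35, intermediate = 0.25, brown = 0.40))
  expect_equal(both_low$labels, "intermediate")
  expect_equal(both_low$status, "intermediate_rule")
  # dominant intermediate probability -> definitive intermediate
  expect_equal(call_eye(c(blue = 0.1, intermediate = 0.75, brown = 0.15))$status,
               "definitive")
  # boundary values fall to the lower branch
  expect_equal(call_eye(c(blue = 0.5, intermediate = 0.2, brown = 0.3))$status,
               "intermediate_rule")
  expect_equal(call_eye(c(blue = 0.7, intermediate = 0.1, brown = 0.2))$status,
               "undefined")
  # NA probability (missing required marker) -> NA call
  expect_equal(call_eye(c(blue = NA, intermediate = NA, brown = NA))$status, "NA")
  # malformed vector errors
  expect_error(call_eye(c(blue = 0.9, intermediate = 0.4, brown = 0.1)),
               "malformed")
})

test_that("hair calls use argmax with a compound band and vocabulary tie-break", {
  expect_equal(call_hair(c(blond = 0.1, red = 0, brown = 0.8, black = 0.1))$labels,
               "brown")
  comp <- call_hair(c(blond = 0.05, red = 0, brown = 0.46, black = 0.49))
  expect_equal(comp$labels, "black/brown")
  tie <- call_hair(c(blond = 0.25, red = 0.25, brown = 0.25, black = 0.25))
  expect_equal(tie$labels, "blond/red")
  # outside the band: single call
  expect_equal(call_hair(c(blond = 0.05, red = 0, brown = 0.34, black = 0.61))$labels,
               "black")
})

test_that("skin calls require a dominant tone and add flexible secondaries", {
  strict <- call_skin(c(very_pale = 0.01, pale = 0.10, intermediate = 0.70,
                        dark = 0.18, dark_black = 0.01), "strict")
  expect_equal(strict$labels, "intermediate")
  undef <- call_skin(c(very_pale = 0.05, pale = 0.30, intermediate = 0.40,
                       dark = 0.20, dark_black = 0.05), "strict")
  expect_equal(undef$status, "undefined")
  expect_true(is.na(undef$labels))
  # undefined in both modes when nothing exceeds 0.5
  undef2 <- call_skin(c(very_pale = 0.05, pale = 0.30, intermediate = 0.40,
                        dark = 0.20, dark_black = 0.05), "flexible")
  expect_equal(undef2$status, "undefined")
  # flexible secondary only within the gap
  p <- c(very_pale = 0.02, pale = 0.25, intermediate = 0.55, dark = 0.17,
         dark_black = 0.01)
  expect_equal(call_skin(p, "flexible")$labels, "intermediate")  # 0.30 > 0.2
  wide <- calling_thresholds(skin_secondary_gap = 0.35)
  expect_equal(call_skin(p, "flexible", wide)$labels, "intermediate/pale")
  # reduced vocabulary (unobserved categories absent) is accepted
  expect_equal(call_skin(c(pale = 0.2, intermediate = 0.6, dark = 0.2),
                         "strict")$labels, "intermediate")
})

test_that("exactly one branch fires for every valid probability vector", {
  withr::with_seed(7, {
    for (i in 1:300) {
      p3 <- as.vector(rmultinom(1, 1000, runif(3))) / 1000
      eye <- call_eye(setNames(p3, trait_levels("eye")),
                      sample(c("strict", "flexible"), 1))
      expect_true(eye$status %in% c("definitive", "undefined", "intermediate_rule"))
      expect_false(is.na(eye$labels))

      p4 <- as.vector(rmultinom(1, 1000, runif(4))) / 1000
      hair <- call_hair(setNames(p4, trait_levels("hair")))
      expect_equal(hair$status, "definitive")

      p5 <- as.vector(rmultinom(1, 1000, runif(5))) / 1000
      skin <- call_skin(setNames(p5, trait_levels("skin")),
                        sample(c("strict", "flexible"), 1))
      expect_true(xor(skin$status == "undefined", !is.na(skin$labels)))
    }
  })
})

test_that("strict and flexible agree on definitive single-label calls", {
  withr::with_seed(11, {
    for (i in 1:100) {
      p3 <- setNames(as.vector(rmultinom(1, 1000, runif(3))) / 1000,
                     trait_levels("eye"))
      s <- call_eye(p3, "strict"); f <- call_eye(p3, "flexible")
      if (s$status %in% c("definitive", "intermediate_rule")) {
        expect_identical(s, f)
      } else {
        expect_equal(s$labels, f$labels)  # same compound, status differs
      }
      # no intermediate_rule call when blue or brown exceeds 0.5
      if (max(p3["blue"], p3["brown"]) > 0.5) {
        expect_false(s$status == "intermediate_rule")
      }
    }
  })
})

test_that("batch calling maps a probability table to a call table", {
  probs <- tibble::tibble(
    sample_id = c("a", "b", "c"),
    blue = c(0.85, 0.60, NA),
    intermediate = c(0.05, 0.15, NA),
    brown = c(0.10, 0.25, NA)
  )
  calls <- call_phenotypes(probs, "eye", mode = "strict")
  expect_equal(calls$labels, c("blue", "intermediate/blue", NA))
  expect_equal(calls$status, c("definitive", "undefined", "NA"))
  expect_equal(calls$sample_id, probs$sample_id)
})
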