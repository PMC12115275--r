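# Friability, compendial weight variation, and QTPP/CQA batch evaluation.

test_that("friability formula, scale invariance and error handling", {
  expect_equal(sedem_round(friability(6.50, 6.44), 3), 0.923)
  expect_equal(friability(6.5, 6.5), 0)
  expect_error(friability(6.4, 6.5), "impossible-gain")
  set.seed(9)
  for (i in 1:30) {
    w1 <- runif(1, 5, 8)
    w2 <- runif(1, 0.9 * w1, w1)
    k <- runif(1, 0.1, 10)
    fr <- friability(w1, w2)
    expect_true(fr >= 0 && fr < 100)
    expect_equal(friability(k * w1, k * w2), fr, tolerance = 1e-12)
  }
})

test_that("weight variation applies the compendial two-beyond-band rule", {
  ident <- weight_variation(rep(67, 20))
  expect_true(ident$pass)
  expect_true(all(ident$deviation_pct == 0))
  expect_equal(ident$band_pct, 10)  # mean below 80 mg

  one_high <- weight_variation(c(rep(67, 19), 67 * 1.15))
  expect_true(one_high$pass)       # one unit beyond 10%, none beyond 20%

  three_high <- weight_variation(c(rep(67, 17), rep(67 * 1.12, 3)))
  expect_false(three_high$pass)    # three units beyond the band

  extreme <- weight_variation(c(rep(67, 19), 67 * 1.25))
  expect_false(extreme$pass)       # one unit beyond twice the band

  mid <- weight_variation(rep(150, 20))
  expect_equal(mid$band_pct, 7.5)
  heavy <- weight_variation(rep(300, 20))
  expect_equal(heavy$band_pct, 5)

  expect_error(weight_variation(rep(67, 19)), "insufficient-sample")
})

test_that("CQA evaluation reproduces the reference batch verdicts", {
  qc <- sedem_fixture("tablet_qc")

  f13 <- qc[qc$formulation == "F13", ]
  v13 <- evaluate_cqa(tablet_batch("F13", hardness_n = f13$mean_hardness_n,
                                   friability_pct = f13$friability_pct,
                                   disintegration_s = f13$disintegration_s,
                                   diameter_mm = f13$diameter_mm))
  st <- stats::setNames(v13$attributes$status, v13$attributes$attribute)
  expect_identical(st[["disintegration_s"]], "pass")
  expect_identical(st[["friability_pct"]], "pass")
  expect_identical(st[["diameter_mm"]], "pass")
  expect_identical(st[["hardness_n"]], "flag")  # 62.5 N above the 60 N window
  expect_false(v13$overall == "fail")

  f16 <- qc[qc$formulation == "F16", ]
  expect_warning(  # friability printed exactly at the 1% limit
    v16 <- evaluate_cqa(tablet_batch("F16", hardness_n = f16$mean_hardness_n,
                                     friability_pct = f16$friability_pct,
                                     disintegration_s = f16$disintegration_s,
                                     diameter_mm = f16$diameter_mm)),
    "pass-at-limit")
  st16 <- stats::setNames(v16$attributes$status, v16$attributes$attribute)
  expect_identical(st16[["disintegration_s"]], "fail")  # 420 s > 3 min
  expect_identical(st16[["friability_pct"]], "pass")
  expect_identical(v16$overall, "fail")

  # exactly F13 and F14 disintegrate in under a minute; only F16 breaks QTPP
  expect_setequal(qc$formulation[qc$disintegration_s < 60], c("F13", "F14"))
  expect_setequal(qc$formulation[qc$disintegration_s > 180], "F16")
  expect_true(qc$friability_pct[qc$formulation == "F14"] < 1)
})

test_that("missing attributes yield not_assessed and an indeterminate verdict", {
  v <- evaluate_cqa(tablet_batch("partial", disintegration_s = 40,
                                 diameter_mm = 5))
  st <- stats::setNames(v$attributes$status, v$attributes$attribute)
  expect_identical(st[["friability_pct"]], "not_assessed")
  expect_identical(v$overall, "indeterminate")
})

test_that("improving any single attribute never flips a pass to fail", {
  base <- list(hardness = 40, friability = 0.8, disintegration = 150,
               diameter = 6.5)
  verdict_of <- function(b) {
    evaluate_cqa(tablet_batch("x", hardness_n = b$hardness,
                              friability_pct = b$friability,
                              disintegration_s = b$disintegration,
                              diameter_mm = b$diameter))
  }
  set.seed(31)
  for (i in 1:40) {
    b <- list(hardness = runif(1, 10, 80), friability = runif(1, 0.1, 1.6),
              disintegration = runif(1, 20, 400), diameter = runif(1, 4, 9))
    v0 <- verdict_of(b)$attributes
    improved <- b
    pick <- sample(names(b), 1)
    improved[[pick]] <- switch(pick,
      hardness = 42.5,          # center of the window
      friability = b$friability * 0.5,
      disintegration = b$disintegration * 0.5,
      diameter = min(b$diameter, 5))
    v1 <- verdict_of(improved)$attributes
    for (a in v0$attribute) {
      s0 <- v0$status[v0$attribute == a]
      s1 <- v1$status[v1$attribute == a]
      expect_false(s0 == "pass" && s1 == "fail", info = paste(a, pick))
    }
  }
})
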