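# Item settings that fire / do not fire each binary score item.
krs_item_settings <- list(
  platelets = c(off = 250, on = 400),
  leukocytes = c(off = 8, on = 12),
  hemoglobin = c(off = 13, on = 9.5),
  bmi_ge_35 = c(off = FALSE, on = TRUE)
)

test_that("Khorana score equals 1 + number of fired items over all 2^4 combinations", {
  for (mask in 0:15) {
    on <- as.logical(bitwAnd(mask, 2^(0:3)))
    p <- make_patient(
      platelets = if (on[1]) 400 else 250,
      leukocytes = if (on[2]) 12 else 8,
      hemoglobin = if (on[3]) 9.5 else 13,
      bmi_ge_35 = on[4])
    s <- score_khorana(p)
    expect_equal(s$points, 1L + sum(on))
    expect_equal(s$points, sum(unlist(s$fired_items)))
    expect_identical(s$category, classify_risk("KRS", s$points))
  }
})

test_that("Khorana worked examples: all items fire to 5/high; none fire to 1/intermediate", {
  s <- score_khorana(make_patient(platelets = 400, leukocytes = 12,
                                  hemoglobin = 9.5, bmi_ge_35 = TRUE))
  expect_equal(s$points, 5L)
  expect_identical(s$category, "high")

  s0 <- score_khorana(make_patient())
  expect_equal(s0$points, 1L)
  expect_identical(s0$category, "intermediate")
  expect_named(s0$fired_items, "site_lung")

  # just over the platelet and leukocyte thresholds
  s3 <- score_khorana(make_patient(platelets = 351, leukocytes = 11.5))
  expect_equal(s3$points, 3L)
  expect_identical(s3$category, "high")

  # ESA use substitutes for anemia in the hemoglobin item
  expect_equal(score_khorana(make_patient(esa_use = TRUE))$points, 2L)
})

test_that("PROTECHT adds one point each for platinum and gemcitabine", {
  expect_equal(score_protecht(make_patient(platinum_chemo = TRUE))$points, 2L)
  expect_identical(score_protecht(make_patient(platinum_chemo = TRUE))$category,
                   "intermediate")
  s <- score_protecht(make_patient(platinum_chemo = TRUE,
                                   gemcitabine_chemo = TRUE))
  expect_equal(s$points, 3L)
  expect_identical(s$category, "high")
  # with no chemo it coincides with the Khorana score
  expect_equal(score_protecht(make_patient())$points,
               score_khorana(make_patient())$points)
  # exhaustive: 4 KRS items x 2 chemo items
  for (mask in 0:63) {
    on <- as.logical(bitwAnd(mask, 2^(0:5)))
    p <- make_patient(
      platelets = if (on[1]) 400 else 250,
      leukocytes = if (on[2]) 12 else 8,
      hemoglobin = if (on[3]) 9.5 else 13,
      bmi_ge_35 = on[4],
      platinum_chemo = on[5], gemcitabine_chemo = on[6])
    expect_equal(score_protecht(p)$points, 1L + sum(on))
  }
})

test_that("CONKO replaces the BMI item with WHO performance status >= 2", {
  expect_equal(score_conko(make_patient(who_ps = 2))$points, 2L)
  expect_identical(score_conko(make_patient(who_ps = 2))$category,
                   "intermediate")
  # BMI must NOT contribute
  expect_equal(score_conko(make_patient(who_ps = 1, bmi_ge_35 = TRUE))$points,
               1L)
  s <- score_conko(make_patient(who_ps = 2, platelets = 360, leukocytes = 12))
  expect_equal(s$points, 4L)
  expect_identical(s$category, "high")
  for (mask in 0:15) {
    on <- as.logical(bitwAnd(mask, 2^(0:3)))
    p <- make_patient(
      platelets = if (on[1]) 400 else 250,
      leukocytes = if (on[2]) 12 else 8,
      hemoglobin = if (on[3]) 9.5 else 13,
      who_ps = if (on[4]) 3L else 0L)
    expect_equal(score_conko(p)$points, 1L + sum(on))
  }
})

compass_weights <- c(6L, 4L, 3L, 2L, 5L, 5L, 1L, 2L)

compass_patient <- function(on) {
  make_patient(
    anthracycline_chemo = on[1],
    months_since_diagnosis = if (on[2]) 3 else 8,
    central_venous_catheter = on[3],
    tnm_stage = if (on[4]) "IV" else "IIIA",
    hypertension = on[5], diabetes = on[5],  # two predictors => composite
    recent_hospitalization = on[6],
    personal_vte_history = on[7],
    platelets = if (on[8]) 350 else 250)
}

test_that("COMPASS-CAT points equal the dot product with (6,4,3,2,5,5,1,2) over all 2^8 combinations", {
  for (mask in 0:255) {
    on <- as.logical(bitwAnd(mask, 2^(0:7)))
    s <- score_compass_cat(compass_patient(on))
    expect_equal(s$points, as.integer(sum(compass_weights * on)))
    expect_equal(s$points, sum(unlist(s$fired_items)))
    expect_identical(s$category, if (s$points >= 7) "high" else "low")
  }
})

test_that("COMPASS-CAT worked examples and the 28-point maximum", {
  s <- score_compass_cat(make_patient(months_since_diagnosis = 3,
                                      recent_hospitalization = TRUE))
  expect_equal(s$points, 9L)
  expect_identical(s$category, "high")

  s0 <- score_compass_cat(make_patient())
  expect_equal(s0$points, 0L)
  expect_identical(s0$category, "low")

  s_all <- score_compass_cat(compass_patient(rep(TRUE, 8)))
  expect_equal(s_all$points, 28L)

  s5 <- score_compass_cat(make_patient(tnm_stage = "IV",
                                       central_venous_catheter = TRUE))
  expect_equal(s5$points, 5L)
  expect_identical(s5$category, "low")
})

test_that("threshold boundaries are exact", {
  # platelets exactly 350 fires the COMPASS-CAT biomarker (>=) but no KRS item (>)
  p <- make_patient(platelets = 350)
  expect_equal(score_khorana(p)$points, 1L)
  expect_equal(score_compass_cat(p)$points, 2L)
  expect_equal(score_khorana(make_patient(platelets = 350.001))$points, 2L)
  # leukocytes exactly 11 does not fire (strict >)
  expect_equal(score_khorana(make_patient(leukocytes = 11))$points, 1L)
  # hemoglobin exactly 10 does not fire (strict <)
  expect_equal(score_khorana(make_patient(hemoglobin = 10))$points, 1L)
  # months since diagnosis exactly 6 fires the 4-point time item (<=)
  expect_equal(score_compass_cat(make_patient(months_since_diagnosis = 6))$points, 4L)
  expect_equal(score_compass_cat(make_patient(months_since_diagnosis = 6.01))$points, 0L)
})

test_that("risk categories step at the documented thresholds", {
  expect_identical(classify_risk("KRS", 0), "low")
  expect_identical(classify_risk("KRS", 1), "intermediate")
  expect_identical(classify_risk("KRS", 2), "intermediate")
  expect_identical(classify_risk("KRS", 3), "high")
  expect_identical(classify_risk("COMPASS_CAT", 6), "low")
  expect_identical(classify_risk("COMPASS_CAT", 7), "high")
  expect_identical(classify_risk("PROTECHT", 2), "intermediate")
  expect_identical(classify_risk("PROTECHT", 3), "high")
  expect_identical(classify_risk("CONKO", 3), "high")
  expect_error(classify_risk("KRS", -1), "negative")
  # category is non-decreasing in points for every model
  rank_of <- c(low = 1L, intermediate = 2L, high = 3L)
  for (m in c("KRS", "PROTECHT", "CONKO", "COMPASS_CAT")) {
    ranks <- rank_of[classify_risk(m, 0:28)]
    expect_true(all(diff(ranks) >= 0))
  }
})

test_that("setting any single item flag never decreases points or downgrades the category", {
  rank_of <- c(low = 1L, intermediate = 2L, high = 3L)
  scorers <- list(score_khorana, score_protecht, score_conko,
                  score_compass_cat)
  bumps <- list(
    function(p) { p$platelets <- 400; p },
    function(p) { p$leukocytes <- 12; p },
    function(p) { p$hemoglobin <- 9; p },
    function(p) { p$bmi_ge_35 <- TRUE; p$obesity <- TRUE; p },
    function(p) { p$who_ps <- 3L; p },
    function(p) { p$platinum_chemo <- TRUE; p },
    function(p) { p$gemcitabine_chemo <- TRUE; p },
    function(p) { p$anthracycline_chemo <- TRUE; p },
    function(p) { p$months_since_diagnosis <- 2; p },
    function(p) { p$central_venous_catheter <- TRUE; p },
    function(p) { p$tnm_stage <- "IV"; p },
    function(p) { p$recent_hospitalization <- TRUE; p },
    function(p) { p$personal_vte_history <- TRUE; p },
    function(p) { p$hypertension <- TRUE; p$diabetes <- TRUE; p }
  )
  co <- random_cohort(25, seed = 99)
  df <- as.data.frame(co)
  for (i in seq_len(nrow(df))) {
    p <- df[i, , drop = FALSE]
    for (scorer in scorers) {
      base <- scorer(p)
      for (bump in bumps) {
        bumped <- scorer(bump(p))
        expect_gte(bumped$points, base$points)
        expect_gte(rank_of[[bumped$category]], rank_of[[base$category]])
      }
    }
  }
})

test_that("score_all matches the per-record scorers element-wise", {
  co <- random_cohort(200, seed = 17)
  df <- as.data.frame(co)
  tab <- score_all(co)
  expect_equal(nrow(tab), 4L * nrow(df))
  scorers <- list(KRS = score_khorana, PROTECHT = score_protecht,
                  CONKO = score_conko, COMPASS_CAT = score_compass_cat)
  for (m in names(scorers)) {
    sub <- tab[tab$model == m, ]
    expect_identical(sub$patient_id, df$patient_id)
    per_record <- lapply(seq_len(nrow(df)),
                         function(i) scorers[[m]](df[i, , drop = FALSE]))
    expect_equal(sub$points, vapply(per_record, `[[`, 0L, "points"))
    expect_identical(sub$category,
                     vapply(per_record, `[[`, "", "category"))
    # the audit strings reconstruct the point totals
    audit_pts <- vapply(strsplit(sub$fired_items, ";"), function(tok) {
      if (length(tok) == 0L || identical(tok, "")) return(0L)
      sum(as.integer(sub("^.*=", "", tok)))
    }, 0L)
    expect_equal(audit_pts, sub$points)
  }
})

test_that("scoring a single zero-item patient gives the documented minimal totals", {
  co <- make_cohort(make_patient("solo"))
  tab <- score_all(co)
  expect_equal(tab$points[tab$model == "KRS"], 1L)
  expect_identical(tab$category[tab$model == "KRS"], "intermediate")
  expect_equal(tab$points[tab$model == "PROTECHT"], 1L)
  expect_equal(tab$points[tab$model == "CONKO"], 1L)
  expect_equal(tab$points[tab$model == "COMPASS_CAT"], 0L)
  expect_identical(tab$category[tab$model == "COMPASS_CAT"], "low")
})
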