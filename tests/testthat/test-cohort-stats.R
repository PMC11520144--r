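test_that("Clopper-Pearson intervals match the closed form and binom.test", {
  est <- incidence_with_ci(0, 10)
  expect_identical(est$ci_low, 0)
  expect_equal(est$ci_high, 1 - 0.025^(1 / 10))
  est <- incidence_with_ci(10, 10)
  expect_identical(est$ci_high, 1)
  expect_equal(est$ci_low, 0.025^(1 / 10))
  est <- incidence_with_ci(5, 10)
  expect_equal(est$proportion, 0.5)
  expect_equal(est$ci_low + est$ci_high, 1)  # symmetric about 1/2
  # dual-route check against the standard exact test implementation
  for (kn in list(c(3, 17), c(40, 120), c(1, 9))) {
    bt <- stats::binom.test(kn[1], kn[2])$conf.int
    est <- incidence_with_ci(kn[1], kn[2])
    expect_equal(c(est$ci_low, est$ci_high), as.numeric(bt), tolerance = 1e-12)
  }
  expect_error(incidence_with_ci(0, 0), "positive")
})

test_that("higher confidence gives nested, wider intervals", {
  e90 <- incidence_with_ci(12, 40, 0.90)
  e95 <- incidence_with_ci(12, 40, 0.95)
  e99 <- incidence_with_ci(12, 40, 0.99)
  expect_lt(e99$ci_low, e95$ci_low); expect_lt(e95$ci_low, e90$ci_low)
  expect_gt(e99$ci_high, e95$ci_high); expect_gt(e95$ci_high, e90$ci_high)
  w <- incidence_with_ci(12, 40, method = "wilson")
  expect_lt(w$ci_low, 12 / 40); expect_gt(w$ci_high, 12 / 40)
})

test_that("binary SMD follows the pooled-variance closed form", {
  expect_identical(smd_binary(30, 100, 30, 100), 0)
  expect_identical(smd_binary(0, 50, 0, 80), 0)  # degenerate
  # independent in-test evaluation: p1=0.5, p2=0.6
  expected <- abs(0.5 - 0.6) / sqrt((0.5 * 0.5 + 0.6 * 0.4) / 2)
  expect_equal(smd_binary(50, 100, 60, 100), expected)
  expect_equal(round(expected, 3), 0.202)
  expect_equal(smd_binary(50, 100, 60, 100), smd_binary(60, 100, 50, 100))
})

test_that("multicategory SMD reduces to binary and matches the matrix form", {
  m2 <- matrix(c(30, 70, 45, 55), ncol = 2)
  expect_equal(smd_multicategory(m2), smd_binary(30, 100, 45, 100))
  same <- matrix(c(60, 30, 10, 120, 60, 20), ncol = 2)
  expect_equal(smd_multicategory(same), 0)
  m3 <- matrix(c(600, 300, 100, 500, 300, 200), ncol = 2)
  # independent evaluation: T' S^-1 T over the first K-1 proportions
  p1 <- c(0.6, 0.3); p2 <- c(0.5, 0.3)
  S1 <- matrix(c(0.6 * 0.4, -0.6 * 0.3, -0.6 * 0.3, 0.3 * 0.7), 2)
  S2 <- matrix(c(0.5 * 0.5, -0.5 * 0.3, -0.5 * 0.3, 0.3 * 0.7), 2)
  expected <- sqrt(drop(t(p1 - p2) %*% solve((S1 + S2) / 2) %*% (p1 - p2)))
  expect_equal(smd_multicategory(m3), expected)
  # invariant under category permutation, drops empty categories
  perm <- m3[c(3, 1, 2), ]
  expect_equal(smd_multicategory(perm), expected)
  padded <- rbind(m3, c(0, 0))
  expect_equal(smd_multicategory(padded), expected)
})

test_that("reference-group tests are Pearson chi-square without correction", {
  expect_identical(reference_group_test(matrix(c(20, 40, 10, 20), 2)), 1)
  tab <- matrix(c(50, 90, 50, 10), nrow = 2)  # 50/50 vs 90/10
  # independent closed-form statistic
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - E)^2 / E)
  expect_equal(reference_group_test(tab), 1 - stats::pchisq(stat, 1))
  expect_warning(p <- reference_group_test(matrix(c(0, 10, 0, 20), 2)),
                 "degenerate")
  expect_identical(p, 1)
  pf <- reference_group_test(matrix(c(3, 5, 4, 2), 2), method = "fisher")
  expect_gt(pf, 0); expect_lte(pf, 1)
})

test_that("the ICD-limit census counts capped admissions and upgrade overlap", {
  adm <- rbind(
    adm_row("m1", "q1", fc = "Medicare",
            icd = paste(sprintf("Z00.%02d", 1:25), collapse = ";")),
    adm_row("m2", "q2", fc = "Medicare",
            icd = paste(sprintf("Z00.%02d", 1:25), collapse = ";")),
    adm_row("m3", "q3", fc = "Medicare",
            icd = paste(sprintf("Z00.%02d", 1:26), collapse = ";")),
    adm_row("m4", "q4", fc = "Aetna",
            icd = paste(sprintf("Z00.%02d", 1:25), collapse = ";")),
    adm_row("m5", "q5", fc = "Medicare", icd = "Z00.01"))
  co <- ehr_cohort(admissions = adm)
  ups <- data.frame(encounter_id = c("m1", "m5"),
                    upgrade_type = c("base_to_CC", "CC_to_MCC"))
  expect_identical(icd_limit_census(co, ups),
                   list(at_limit = 3L, at_limit_upgrade_eligible = 1L))
  none <- data.frame(encounter_id = character(0),
                     upgrade_type = character(0))
  expect_identical(icd_limit_census(co, none)$at_limit_upgrade_eligible, 0L)
  # limit 1 counts every coded admission
  expect_identical(icd_limit_census(co, ups, limit = 1)$at_limit, 4L)
  empty <- ehr_cohort()
  expect_identical(icd_limit_census(empty, none)$at_limit, 0L)
})

test_that("the audit table tabulates a hand-checked fixture exactly", {
  findings <- data.frame(
    encounter_id = rep(c("a", "b", "c", "d"), each = 2),
    disease_name = rep(c("Hyponatremia", "Delirium"), 4),
    detected    = c(TRUE, TRUE,  TRUE, FALSE, FALSE, FALSE, TRUE, FALSE),
    icd_present = c(TRUE, FALSE, FALSE, TRUE, TRUE,  FALSE, FALSE, FALSE))
  findings$missing_icd <- findings$detected & !findings$icd_present
  ups <- data.frame(encounter_id = c("a", "c"),
                    upgrade_type = c("base_to_CC", "none"),
                    driving_diseases = c("Hyponatremia", ""))
  tab <- build_audit_table(findings, ups)
  hypo <- tab[tab$disease_name == "Hyponatremia", ]
  # hand tabulation: detected a,b,d; missing b,d; driving upgrade a; coded a,c
  expect_identical(hypo$detected, 3L)
  expect_identical(hypo$missing_icd, 2L)
  expect_equal(hypo$missing_icd_pct, 66.7)
  expect_identical(hypo$drg_inadequate, 1L)
  expect_identical(hypo$not_sensitive, 1L)
  expect_equal(hypo$not_sensitive_pct, 50)  # of the coded set {a, c}
  del <- tab[tab$disease_name == "Delirium", ]
  expect_identical(del$detected, 1L)
  expect_identical(del$missing_icd, 1L)
  expect_equal(del$missing_icd_pct, 100)
  tot <- tab[tab$disease_name == "Total", ]
  expect_identical(tot$detected, 4L)
  expect_identical(tot$missing_icd, 3L)
  # per-row coherence: missing never exceeds detected, percentages recompute
  expect_true(all(tab$missing_icd <= tab$detected))
})

test_that("the balance table splits groups and reports per-variable SMDs", {
  gen <- generate_cohort(synth_config(n_admissions = 400, seed = 17))
  aud <- run_audit(gen$cohort, synthetic_drg_catalogue())
  b <- aud$balance
  expect_setequal(unique(b$variable),
                  c("Sex", "Race / Ethnicity", "Payor Group", "Age Group"))
  smds <- b$smd[!is.na(b$smd)]
  expect_length(smds, 4)
  expect_true(all(smds >= 0))
  expect_true(all(is.na(b$p_value[b$reference])))
  # group sizes add up to the cohort
  expect_identical(sum(b$accurate[b$variable == "Sex"]) +
                     sum(b$unbilled[b$variable == "Sex"]), 400L)
  # demographics are independent of coding accuracy by construction, so
  # only sampling noise remains; stay clearly below the medium band
  expect_true(all(smds < 0.6))
})
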