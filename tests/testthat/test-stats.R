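test_that("CV is zero for a constant series and scale-invariant otherwise", {
  expect_equal(coefficient_of_variation(c(5, 5, 5, 5)), 0)
  expect_equal(coefficient_of_variation(c(4, 6)), 100 * sqrt(2) / 5)
  set.seed(5)
  x <- rlnorm(6)
  expect_equal(coefficient_of_variation(2 * x), coefficient_of_variation(x))
  expect_error(coefficient_of_variation(5), "at least two")
  expect_error(coefficient_of_variation(c(-3, 1)), "positive mean")
})

test_that("two_sample_t matches the textbook pooled-variance computation", {
  a <- c(1, 2, 3); b <- c(1, 2, 3, 4)
  # closed-form pooled t computed from first principles
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  p_hand <- 2 * pt(-abs(t_hand), df = length(a) + length(b) - 2)
  got <- two_sample_t(a, b)
  expect_equal(got$statistic, t_hand)
  expect_equal(got$p_value, p_hand)
  expect_equal(got$df, 5)
  # identical samples: t = 0, p = 1; swapping negates t, preserves p
  same <- two_sample_t(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  swapped <- two_sample_t(b, a)
  expect_equal(swapped$statistic, -got$statistic)
  expect_equal(swapped$p_value, got$p_value)
  expect_error(two_sample_t(c(1, 1), c(1, 1)), "degenerate")
  expect_error(two_sample_t(1, c(1, 2)), "at least two")
})

test_that("paired_t reduces to the one-sample t on differences", {
  set.seed(8)
  before <- rnorm(10); after <- before + rnorm(10, 0.3)
  got <- paired_t(before, after)
  one <- t.test(after - before)
  expect_equal(got$statistic, unname(one$statistic))
  expect_equal(got$p_value, one$p.value)
  expect_equal(paired_t(before, before)$p_value, 1)
  expect_error(paired_t(before, after[-1]), "equal length")
  expect_error(paired_t(before, before + 2), "non-zero constant")
})

test_that("count_comparison applies Pearson chi-squared with a Fisher fallback", {
  # identical proportions: no association, p = 1 (expected cells all >= 5)
  same <- count_comparison(5, 50, 5, 50)
  expect_equal(same$method, "chi_squared")
  expect_equal(same$p_value, 1)
  # 3/51 vs 8/54: min expected cell is 11*51/105 = 5.34, so Pearson applies;
  # closed-form oracle N(ad-bc)^2 / ((a+b)(c+d)(a+c)(b+d)) on 1 df
  got <- count_comparison(3, 51, 8, 54)
  expect_equal(got$method, "chi_squared")
  a <- 3; b <- 48; c <- 8; d <- 46; N <- 105
  x2 <- N * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  expect_equal(got$statistic, x2)
  expect_equal(got$p_value, pchisq(x2, df = 1, lower.tail = FALSE))
  # sparse table: expected events cell 6*20/40 = 3 < 5 -> Fisher, checked
  # against direct hypergeometric enumeration of all tables no more likely
  # than the one observed
  sparse <- count_comparison(1, 20, 5, 20)
  expect_equal(sparse$method, "fisher_exact")
  probs <- dhyper(0:6, 20, 20, 6)
  p_enum <- sum(probs[probs <= dhyper(1, 20, 20, 6) * (1 + 1e-7)])
  expect_equal(sparse$p_value, p_enum, tolerance = 1e-10)
  expect_lt(count_comparison(0, 10, 10, 10)$p_value, 0.01)
  expect_error(count_comparison(-1, 10, 2, 10), "non-negative")
})

test_that("two_sample_t p-values are uniform under the null (KS check)", {
  set.seed(303)
  p <- replicate(500, two_sample_t(rnorm(15), rnorm(15))$p_value)
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("compare_groups on mirror-image arms returns p = 1 everywhere", {
  cohort <- tibble::tibble(
    patient_id = sprintf("P%02d", 1:10),
    arm = rep(c("intervention", "control"), each = 5),
    start_date = as.Date("2024-01-01")
  )
  set.seed(17)
  base <- tibble::tibble(patient_id = cohort$patient_id[1:5],
                         period = 1L,
                         dose_taking = runif(5, 95, 100),
                         dose_frequency = runif(5, 90, 100),
                         dose_interval = runif(5, 90, 100),
                         drug_holidays = runif(5, 0, 5))
  mirrored <- base |> dplyr::mutate(patient_id = cohort$patient_id[6:10])
  adh <- dplyr::bind_rows(base, mirrored)
  tr_base <- tidyr::crossing(patient_id = cohort$patient_id[1:5], visit = 1:6) |>
    dplyr::mutate(drug_id = "tacrolimus", level = rnorm(dplyr::n(), 5, 1))
  troughs <- dplyr::bind_rows(
    tr_base,
    tr_base |> dplyr::mutate(patient_id = rep(cohort$patient_id[6:10], each = 6)))
  res <- compare_groups(cohort, adherence = adh, troughs = troughs)
  expect_true(all(abs(res$outcomes$p_value - 1) < 1e-12))
  expect_true(all(res$outcomes$mean_1 == res$outcomes$mean_2))
})

test_that("compare_groups enforces arm sizes and keeps its row structure", {
  cohort <- tibble::tibble(patient_id = c("A", "B", "C"),
                           arm = c("intervention", "control", "control"),
                           start_date = as.Date("2024-01-01"))
  expect_error(compare_groups(cohort), "at least two")
  cohort_ok <- tibble::tibble(patient_id = sprintf("P%d", 1:8),
                              arm = rep(c("intervention", "control"), 4),
                              start_date = as.Date("2024-01-01"))
  set.seed(2)
  adh <- tidyr::crossing(patient_id = cohort_ok$patient_id, period = 1:3) |>
    dplyr::mutate(dose_taking = runif(dplyr::n(), 90, 100),
                  dose_frequency = runif(dplyr::n(), 90, 100),
                  dose_interval = runif(dplyr::n(), 90, 100),
                  drug_holidays = runif(dplyr::n(), 0, 5))
  clinical <- tibble::tibble(patient_id = cohort_ok$patient_id,
                             ev1 = rep(c(TRUE, FALSE), 4),
                             ev2 = FALSE)
  res <- compare_groups(cohort_ok, adherence = adh, clinical = clinical)
  # 4 metrics x 3 periods continuous rows + 2 event rows, whatever the values
  expect_equal(nrow(res$outcomes), 12)
  expect_equal(nrow(res$events), 2)
  expect_true(all(res$outcomes$p_value >= 0 & res$outcomes$p_value <= 1, na.rm = TRUE))
  expect_equal(unname(res$n), c(4, 4))
  td <- tidy(res)
  expect_equal(nrow(td), 14)
  gl <- glance(res)
  expect_equal(gl$n_comparisons, 14)
})

test_that("null compare_groups rejects the trough row at about the nominal rate", {
  set.seed(909)
  n_rep <- 300
  rej <- 0
  cohort <- tibble::tibble(patient_id = sprintf("P%02d", 1:30),
                           arm = rep(c("intervention", "control"), each = 15),
                           start_date = as.Date("2024-01-01"))
  for (r in seq_len(n_rep)) {
    troughs <- tidyr::crossing(patient_id = cohort$patient_id, visit = 1:6) |>
      dplyr::mutate(drug_id = "tacrolimus", level = rnorm(dplyr::n(), 5, 1.2))
    res <- compare_groups(cohort, troughs = troughs)
    p <- res$outcomes$p_value[res$outcomes$outcome == "tacrolimus_trough"]
    if (p < 0.05) rej <- rej + 1
  }
  expect_gt(rej / n_rep, 0.02)
  expect_lt(rej / n_rep, 0.08)
})

test_that("feedback subgroup analysis splits at >= 1 deduplicated occurrence", {
  cohort <- tibble::tibble(patient_id = sprintf("P%02d", 1:51),
                           arm = "intervention",
                           start_date = as.Date("2024-01-01"))
  # 13 patients with one violated slot each (escalations must not double-count)
  fb <- tidyr::crossing(patient_id = sprintf("P%02d", 1:13), escalation_index = 0:2) |>
    dplyr::mutate(timestamp = as.POSIXct("2024-01-01 11:00:00", tz = "UTC") +
                    escalation_index * 1800,
                  kind = "missed_dose", slot_index = 0L)
  set.seed(31)
  troughs <- tidyr::crossing(patient_id = cohort$patient_id, visit = 1:6) |>
    dplyr::mutate(drug_id = "tacrolimus", level = rnorm(dplyr::n(), 5, 1.2))
  res <- feedback_subgroup_analysis(cohort, fb, troughs = troughs)
  expect_equal(unname(res$n), c(13, 38))
  expect_equal(res$groups, c("feedback", "no_feedback"))
  # subgroup means recompute from the partition with the same estimators
  lev <- troughs |> dplyr::group_by(patient_id) |> dplyr::summarise(m = mean(level))
  in_fb <- lev$patient_id %in% sprintf("P%02d", 1:13)
  row <- res$outcomes[res$outcomes$outcome == "tacrolimus_trough", ]
  expect_equal(row$mean_1, mean(lev$m[in_fb]))
  expect_equal(row$mean_2, mean(lev$m[!in_fb]))
  expect_equal(row$p_value, two_sample_t(lev$m[in_fb], lev$m[!in_fb])$p_value)
})

test_that("an empty feedback subgroup is flagged, not an error", {
  cohort <- tibble::tibble(patient_id = sprintf("P%02d", 1:10),
                           arm = "intervention",
                           start_date = as.Date("2024-01-01"))
  no_fb <- tibble::tibble(patient_id = character(), timestamp = as.POSIXct(character(), tz = "UTC"),
                          kind = character(), escalation_index = integer(),
                          slot_index = integer())
  set.seed(12)
  troughs <- tidyr::crossing(patient_id = cohort$patient_id, visit = 1:6) |>
    dplyr::mutate(drug_id = "tacrolimus", level = rnorm(dplyr::n(), 5, 1.2))
  res <- feedback_subgroup_analysis(cohort, no_fb, troughs = troughs)
  expect_equal(unname(res$n), c(0, 10))
  expect_true(all(res$outcomes$method == "not_computable"))
  expect_true(all(is.na(res$outcomes$p_value)))
})
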