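test_that("clean spec yields one complete row per patient", {
  spec <- tiny_spec(n = 80)
  coh <- generate_cohort(spec)
  expect_equal(nrow(coh), 80)
  expect_false(anyDuplicated(coh$patient_id) > 0)
  feats <- coh[, chd_schema(spec)$name]
  expect_false(anyNA(feats))
  qual <- coh[, spec$qual_features$name]
  expect_true(all(unlist(qual) %in% c(0, 1)))
  expect_true(all(coh$label %in% 0:1))
})

test_that("generation is deterministic and byte-identical for a fixed seed", {
  spec <- synthetic_spec(n_patients = 120, prevalence = 0.1, seed = 42)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1, c2)
  f1 <- tempfile(); f2 <- tempfile()
  write_cohort_csv(c1, chd_schema(spec), f1)
  write_cohort_csv(c2, chd_schema(spec), f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("realized prevalence tracks the spec within 20% relative at n >= 1000", {
  for (s in 1:5) {
    spec <- synthetic_spec(n_patients = 1200, prevalence = 0.044,
                           duplicate_rate = 0, missing_rate = 0,
                           outlier_rate = 0, seed = s)
    coh <- generate_cohort(spec)
    realized <- mean(coh$label)
    expect_gt(realized, 0.044 * 0.8)
    expect_lt(realized, 0.044 * 1.2)
  }
})

test_that("emulated registry shape: death count near 120 of 2702 records", {
  spec <- synthetic_spec(n_patients = 2702, prevalence = 0.044,
                         duplicate_rate = 0, missing_rate = 0,
                         outlier_rate = 0, seed = 21)
  coh <- generate_cohort(spec)
  deaths <- sum(coh$label)
  expect_gte(deaths, ceiling(0.8 * 119))
  expect_lte(deaths, floor(1.2 * 119))
})

test_that("quantitative quartiles approach the spec at large n", {
  spec <- synthetic_spec(n_patients = 6000, duplicate_rate = 0,
                         missing_rate = 0, outlier_rate = 0,
                         community_shift = 0, signal_strength = 0, seed = 5)
  coh <- generate_cohort(spec)
  qf <- spec$quant_features
  for (j in seq_len(nrow(qf))) {
    q <- quantile(coh[[qf$name[j]]], c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- qf$q3[j] - qf$q1[j]
    expect_lt(abs(q[2] - qf$median[j]), 0.1 * iqr)
    expect_lt(abs(q[1] - qf$q1[j]), 0.15 * iqr)
    expect_lt(abs(q[3] - qf$q3[j]), 0.15 * iqr)
  }
})

test_that("qualitative prevalences are honored", {
  spec <- synthetic_spec(n_patients = 5000, duplicate_rate = 0,
                         missing_rate = 0, outlier_rate = 0, seed = 9)
  coh <- generate_cohort(spec)
  cf <- spec$qual_features
  for (j in seq_len(nrow(cf))) {
    expect_lt(abs(mean(coh[[cf$name[j]]]) - cf$prevalence[j]), 0.03)
  }
})

test_that("messiness injection follows the stated rates", {
  spec <- synthetic_spec(n_patients = 1000, duplicate_rate = 0.2,
                         missing_rate = 0.05, outlier_rate = 0.01, seed = 3)
  coh <- generate_cohort(spec)
  n_extra <- nrow(coh) - 1000
  expect_equal(n_extra, 200)
  # duplicated ids carry strictly increasing timestamps
  dups <- names(which(table(coh$patient_id) > 1))
  for (id in dups[1:5]) {
    ts <- coh$timestamp[coh$patient_id == id]
    expect_true(all(diff(sort(ts)) > 0))
  }
  qmiss <- mean(is.na(as.matrix(coh[, spec$quant_features$name])))
  expect_gt(qmiss, 0.03); expect_lt(qmiss, 0.07)
  cmiss <- mean(as.matrix(coh[, spec$qual_features$name]) == 0.5)
  expect_gt(cmiss, 0.03); expect_lt(cmiss, 0.07)
})

test_that("ground truth matches its cohort and rejects a mismatched spec", {
  spec <- tiny_spec(n = 50)
  coh <- generate_cohort(spec)
  gt <- ground_truth(spec, coh)
  expect_named(gt, c("latent_prob", "community", "risk_score"))
  expect_length(gt$latent_prob, 50)
  other <- tiny_spec(n = 51)
  expect_error(ground_truth(other, coh), "not generated")
})

test_that("zero signal strength gives equal latent probabilities and no association", {
  spec <- synthetic_spec(n_patients = 400, prevalence = 0.3,
                         signal_strength = 0, duplicate_rate = 0,
                         missing_rate = 0, outlier_rate = 0, seed = 1)
  coh <- generate_cohort(spec)
  gt <- ground_truth(spec, coh)
  expect_lt(diff(range(gt$latent_prob)), 1e-12)
  # label independent of features: single-feature AUC centered at 0.5 over seeds
  aucs <- sapply(1:20, function(s) {
    sp <- synthetic_spec(n_patients = 300, prevalence = 0.3,
                         signal_strength = 0, duplicate_rate = 0,
                         missing_rate = 0, outlier_rate = 0, seed = s)
    ch <- generate_cohort(sp)
    roc_auc(ch$label, ch$age)$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("latent probabilities are monotone in the risk score and oracle AUC grows with strength", {
  spec <- synthetic_spec(n_patients = 500, prevalence = 0.2,
                         duplicate_rate = 0, missing_rate = 0,
                         outlier_rate = 0, seed = 2)
  coh <- generate_cohort(spec)
  gt <- ground_truth(spec, coh)
  ord <- order(gt$risk_score)
  expect_true(all(diff(gt$latent_prob[ord]) >= 0))
  # brute-force pairwise rank statistic of latent prob vs label
  p <- gt$latent_prob; y <- coh$label
  pos <- p[y == 1]; neg <- p[y == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  auc_brute <- mean(cmp)
  expect_equal(auc_brute, roc_auc(y, p)$auc, tolerance = 1e-12)
  strong <- synthetic_spec(n_patients = 500, prevalence = 0.2,
                           signal_strength = 12, duplicate_rate = 0,
                           missing_rate = 0, outlier_rate = 0, seed = 2)
  cs <- generate_cohort(strong)
  gs <- ground_truth(strong, cs)
  expect_gt(roc_auc(cs$label, gs$latent_prob)$auc, 0.97)
  expect_gt(roc_auc(cs$label, gs$latent_prob)$auc,
            roc_auc(y, p)$auc)
})

test_that("cohort CSV round-trips through the sidecar schema", {
  spec <- tiny_spec(n = 40)
  coh <- generate_cohort(spec)
  f <- tempfile(fileext = ".csv")
  write_cohort_csv(coh, chd_schema(spec), f)
  back <- read_cohort_csv(f)
  expect_equal(back$patient_id, coh$patient_id)
  expect_equal(back$age, coh$age, tolerance = 1e-8)
  expect_equal(attr(back, "schema")$kind, chd_schema(spec)$kind)
})

test_that("invalid specs are rejected", {
  expect_error(synthetic_spec(prevalence = 0), "prevalence")
  expect_error(synthetic_spec(missing_rate = 1.2), "missing_rate")
  qf <- chd_quant_features(); qf$q1[1] <- qf$median[1] + 1
  expect_error(synthetic_spec(quant_features = qf), "q1 < median < q3")
  expect_error(synthetic_spec(risk_features = "nope"), "risk_features")
})
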