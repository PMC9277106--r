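ctx300 <- thermal_context(300)

test_that("the thermal context derives kT from the gas constant", {
  expect_equal(ctx300$kT, 0.59616123, tolerance = 1e-7)
  expect_error(thermal_context(-5), class = "ededock_bad_temperature")
})

test_that("a single conformation returns its raw docking score", {
  expect_equal(ensemble_score(-11.2, 0, ctx300)$score, -11.2, tolerance = 1e-12)
})

test_that("equal conformational energies with equal scores return that score", {
  r <- ensemble_score(rep(-7.3, 4), rep(0, 4), ctx300)
  expect_equal(r$score, -7.3, tolerance = 1e-12)
  expect_equal(r$contributions, rep(0.25, 4), tolerance = 1e-12)
})

test_that("the ensemble score matches the brute-force partition-sum oracle", {
  # the worked 4-state case
  dg_conf <- c(0, 0.5108, 1.2040, 2.3026)
  dg_bind <- c(-9.4, -11.2, -8.0, -10.0)
  r <- ensemble_score(dg_bind, dg_conf, ctx300)
  expect_equal(r$score, oracle_ensemble_score(dg_bind, dg_conf, ctx300$kT),
               tolerance = 1e-10)
  expect_equal(sum(r$contributions), 1, tolerance = 1e-10)
  expect_true(all(r$contributions >= 0))

  # random instances, n between 1 and 8
  for (s in 1:300) {
    inst <- with_seed_local(s, {
      n <- sample(1:8, 1)
      list(conf = c(0, stats::runif(n - 1, 0, 6)),
           bind = stats::runif(n, -15, -2))
    })
    got <- ensemble_score(inst$bind, inst$conf, ctx300)$score
    want <- oracle_ensemble_score(inst$bind, inst$conf, ctx300$kT)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("missing poses drop out of the bound partition only", {
  dg_conf <- c(0, 0.7, 1.4)
  dg_bind <- c(-9.5, NA, -8.1)
  r <- ensemble_score(dg_bind, dg_conf, ctx300)
  expect_true(r$missing)
  expect_equal(r$n_used, 2L)
  expect_equal(r$score, oracle_ensemble_score(dg_bind, dg_conf, ctx300$kT),
               tolerance = 1e-12)
  expect_true(is.na(r$contributions[2]))
  expect_equal(sum(r$contributions, na.rm = TRUE), 1, tolerance = 1e-10)
  expect_error(ensemble_score(c(NA, NA), c(0, 1), ctx300),
               class = "ededock_all_missing")
})

test_that("a non-zero or negative reference free energy is rejected", {
  expect_error(ensemble_score(c(-9, -8), c(0.2, 0.5), ctx300),
               class = "ededock_bad_reference")
  expect_error(ensemble_score(c(-9, -8), c(-0.1, 0), ctx300),
               class = "ededock_bad_reference")
})

test_that("equal weighting equals the zero-dG_conf limit and soft-minimum behavior", {
  expect_equal(equal_weight_score(rep(-6.4, 3), ctx300), -6.4, tolerance = 1e-12)
  for (s in 1:200) {
    bind <- with_seed_local(1000 + s, stats::runif(sample(1:8, 1), -15, -2))
    ew <- equal_weight_score(bind, ctx300)
    es <- ensemble_score(bind, rep(0, length(bind)), ctx300)$score
    expect_equal(ew, es, tolerance = 1e-12)
  }
  soft <- equal_weight_score(c(-10, 0), ctx300)
  expect_gt(soft, -10); expect_lt(soft, 0)
  expect_lt(soft, mean(c(-10, 0)))   # closer to the strong score than the mean
})

test_that("scores stay within per-conformation bounds and respond monotonically", {
  for (s in 1:200) {
    inst <- with_seed_local(2000 + s, {
      n <- sample(2:8, 1)
      list(conf = c(0, stats::runif(n - 1, 0, 5)),
           bind = stats::runif(n, -15, -2))
    })
    sc <- ensemble_score(inst$bind, inst$conf, ctx300)$score
    expect_gte(sc, min(inst$bind) - 1e-12)
    expect_lte(sc, max(inst$bind) + 1e-12)
    improved <- inst$bind
    j <- with_seed_local(s, sample(length(improved), 1))
    improved[j] <- improved[j] - 0.5
    expect_lt(ensemble_score(improved, inst$conf, ctx300)$score, sc)
  }
})

test_that("rare high-energy states do not contribute to the score", {
  dg_conf <- c(0, 0.51, 1.20)
  dg_bind <- c(-9.4, -11.2, -8.0)
  base <- ensemble_score(dg_bind, dg_conf, ctx300)$score
  with_rare <- ensemble_score(c(dg_bind, -14), c(dg_conf, 20), ctx300)$score
  expect_lt(abs(with_rare - base), 1e-6)
})

test_that("extreme scores and conformational energies stay finite", {
  r <- ensemble_score(c(-50, 50, -50), c(0, 250, 500), ctx300)
  expect_true(is.finite(r$score))
  expect_true(all(is.finite(r$contributions)))
  expect_true(is.finite(equal_weight_score(c(-50, 50), ctx300)))
})

test_that("triage partitions the reported class means at the -9 kcal/mol cutoff", {
  res <- data.frame(compound_id = c("strong_mean", "medium_mean", "weak_mean"),
                    ensemble_dg_bind = c(-10.4, -9.8, -8.5))
  tr <- triage(res, cutoff = -9)
  expect_equal(tr$active$compound_id, c("strong_mean", "medium_mean"))
  expect_equal(tr$inactive$compound_id, "weak_mean")
  # boundary inclusion and ascending order
  tr2 <- triage(data.frame(compound_id = c("a", "b"),
                           ensemble_dg_bind = c(-9.0, -9.5)), -9)
  expect_equal(tr2$active$compound_id, c("b", "a"))
  empty <- triage(res[0, ], -9)
  expect_equal(nrow(empty$active), 0L)
  expect_equal(nrow(empty$inactive), 0L)
})

test_that("screen evaluation reproduces hand-computed confusion counts", {
  # perfect separation
  res <- data.frame(compound_id = paste0("c", 1:6),
                    ensemble_dg_bind = c(-11, -10, -9.5, -8, -7, -6))
  labels <- data.frame(compound_id = paste0("c", 1:6),
                       class = c("strong", "medium", "strong", "weak", "weak", "weak"))
  ev <- evaluate_screen(res, labels, cutoff = -9)
  expect_equal(ev$accuracy, 1.0)
  expect_equal(ev$fnr, 0); expect_equal(ev$fpr, 0)

  # everything predicted active, half truly active
  res2 <- data.frame(compound_id = paste0("c", 1:4),
                     ensemble_dg_bind = rep(-12, 4))
  labels2 <- data.frame(compound_id = paste0("c", 1:4),
                        class = c("strong", "medium", "weak", "weak"))
  ev2 <- evaluate_screen(res2, labels2, cutoff = -9)
  expect_equal(ev2$accuracy, 0.5)
  expect_equal(ev2$fpr, 1.0); expect_equal(ev2$fnr, 0)

  # seeded 23-compound set vs exhaustive enumeration
  fix <- with_seed_local(99, list(
    score = stats::runif(23, -12, -6),
    class = sample(c("strong", "medium", "weak"), 23, replace = TRUE)))
  res3 <- data.frame(compound_id = sprintf("c%02d", 1:23),
                     ensemble_dg_bind = fix$score)
  labels3 <- data.frame(compound_id = sprintf("c%02d", 1:23), class = fix$class)
  ev3 <- evaluate_screen(res3, labels3, cutoff = -9)
  pred <- fix$score <= -9; truth <- fix$class %in% c("strong", "medium")
  expect_equal(ev3$tp, sum(pred & truth))
  expect_equal(ev3$fp, sum(pred & !truth))
  expect_equal(ev3$tn, sum(!pred & !truth))
  expect_equal(ev3$fn, sum(!pred & truth))
  expect_equal(ev3$accuracy, (ev3$tp + ev3$tn) / 23)

  expect_error(evaluate_screen(res3, labels3[-1, ]),
               class = "ededock_unlabeled_compound")
})

test_that("undefined rates are reported as NA, never zero", {
  res <- data.frame(compound_id = "c1", ensemble_dg_bind = -12)
  labels <- data.frame(compound_id = "c1", class = "strong")
  ev <- evaluate_screen(res, labels, cutoff = -9)
  expect_true(is.na(ev$fpr))   # no true negatives or false positives
  expect_equal(ev$fnr, 0)
})

test_that("top-fraction summaries match a brute-force sort-and-average", {
  res <- data.frame(compound_id = paste0("c", 1:4),
                    ensemble_dg_bind = c(-8, -10, -9, -7))
  s <- screen_summary(res, top_fraction = 1)
  expect_equal(s$n_top, 4L)
  expect_equal(s$mean, mean(res$ensemble_dg_bind))

  big <- with_seed_local(5, data.frame(compound_id = seq_len(1000),
                                       ensemble_dg_bind = stats::rnorm(1000, -7, 2)))
  s2 <- screen_summary(big, 0.025)
  expect_equal(s2$n_top, 25L)
  expect_equal(s2$mean, mean(sort(big$ensemble_dg_bind)[1:25]), tolerance = 1e-12)

  flat <- data.frame(compound_id = 1:5, ensemble_dg_bind = rep(-9.1, 5))
  s3 <- screen_summary(flat, 0.5)
  expect_equal(s3$mean, -9.1); expect_equal(s3$sd, 0)
  expect_error(screen_summary(flat[0, ], 0.5), class = "ededock_empty_results")
})

test_that("score tables round-trip through CSV including missing poses", {
  m <- rbind(c(-9.1, NA, -8.2), c(-10.5, -9.9, -11.0))
  tab <- score_table(c("a", "b"), c("S0", "S1", "S2"), m)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_score_table(tab, csv)
  tab2 <- read_score_table(csv)
  expect_equal(tab2$compound_ids, c("a", "b"))
  expect_equal(tab2$conformation_ids, c("S0", "S1", "S2"))
  expect_equal(tab2$dg_bind, tab$dg_bind, ignore_attr = TRUE, tolerance = 1e-12)
  expect_error(score_table("a", c("S0", "S1"), rbind(c(NA, NA))),
               class = "ededock_all_missing")
})

test_that("table-level scoring orders and flags compounds correctly", {
  m <- rbind(c(-11, -10.5, -10.8, -11.2), c(-7, -6.5, NA, -7.2),
             c(-9.3, -9.1, -9.0, -9.2))
  tab <- score_table(c("hit", "dud", "mid"), paste0("S", 0:3), m)
  res <- score_ensemble(tab, c(0, 0.5, 1.2, 2.3), ctx300, cutoff = -9)
  expect_equal(res$predicted_active, c(TRUE, FALSE, TRUE))
  expect_true(res$missing_pose[2])
  expect_equal(res$n_conformations_used, c(4L, 3L, 4L))
  for (i in 1:3)
    expect_equal(res$ensemble_dg_bind[i],
                 oracle_ensemble_score(m[i, ], c(0, 0.5, 1.2, 2.3), ctx300$kT),
                 tolerance = 1e-10)
})
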