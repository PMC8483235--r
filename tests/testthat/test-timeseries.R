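test_that("PELT finds the exact penalized segmentation", {
  # constant series: no changepoints
  expect_length(pelt_changepoints(rep(2, 10))$changepoints, 0)
  # noiseless level shift: exactly one changepoint at the step
  cp <- pelt_changepoints(c(rep(0, 6), rep(5, 6)))
  expect_equal(cp$changepoints, 7L)
  expect_equal(cp$segments$mean, c(0, 5))
  expect_error(pelt_changepoints(c(1, 2, 3)), "min_seg")

  # oracle equivalence on random series (full 200-series suite runs in the
  # acceptance tests; a fast subset here)
  withr::with_seed(51, {
    for (rep in 1:40) {
      n <- sample(4:12, 1)
      x <- rnorm(n) + rep(c(0, sample(c(0, 3), 1)), each = ceiling(n / 2))[1:n]
      pen <- runif(1, 0.5, 8)
      fit <- pelt_changepoints(x, penalty = pen)
      objs <- vapply(all_segmentations(n, 2), seg_objective, numeric(1),
                     x = x, penalty = pen)
      expect_equal(seg_objective(x, fit$changepoints, pen), min(objs),
                   tolerance = 1e-10)
    }
  })
})

test_that("changepoint count is non-increasing in the penalty", {
  withr::with_seed(52, {
    for (rep in 1:20) {
      x <- rnorm(12) + rep(c(0, 2, -1), each = 4)
      counts <- vapply(c(0.1, 0.5, 1, 2, 4, 8, 16), function(p)
        length(pelt_changepoints(x, penalty = p)$changepoints), numeric(1))
      expect_true(all(diff(counts) <= 0))
    }
  })
})

test_that("cross-covariance scores follow the ccf convention and lag rules", {
  x <- c(1, 3, 2, 5, 4, 6, 2, 7)
  expect_equal(crosscov_score(x, x), 1)
  expect_equal(crosscov_score(x, -x, max_lag = 0), -1)
  # shifted series: high score at lag 1, recovered only when lags are searched
  s <- sin(seq(0, 3 * pi, length.out = 13))
  expect_gt(crosscov_score(s[1:12], s[2:13], max_lag = 1), 0.85)
  expect_lt(crosscov_score(s[1:12], s[2:13], max_lag = 0),
            crosscov_score(s[1:12], s[2:13], max_lag = 1))
  # exact agreement with stats::ccf values
  y <- withr::with_seed(54, rnorm(8))
  cc <- ccf(x, y, lag.max = 1, plot = FALSE)
  expect_equal(crosscov_score(x, y, max_lag = 1), max(cc$acf), tolerance = 1e-10)
  expect_warning(out <- crosscov_score(rep(1, 8), y), "zero-variance")
  expect_true(is.na(out))
  expect_error(crosscov_score(1:4, 1:4), "at least 5")
})

test_that("patients below the visit threshold are excluded from cross-covariance testing", {
  comp <- withr::with_seed(55, matrix(rgamma(22 * 3, 2), 22, 3))
  comp <- comp / rowSums(comp)
  colnames(comp) <- c("Campylobacter", "g2", "g3")
  md <- data.frame(
    sample_id = sprintf("S%02d", 1:22),
    patient_id = rep(c("P1", "P2", "P3", "P4"), c(4, 6, 6, 6)),
    visit_index = c(1:4, 1:6, 1:6, 1:6),
    day_offset = c(seq(0, 90, 30), rep(seq(0, 150, 30), 3)),
    visit_type = "stable",
    eosinophil_pct = withr::with_seed(56, runif(22, 0, 20)),
    stringsAsFactors = FALSE)
  rownames(comp) <- md$sample_id
  ds <- cohort_dataset(genus_table(comp, kind = "relative"), md)
  res <- crosscov_perm_test(ds, "Campylobacter", "eosinophil", B = 50, seed = 1)
  expect_setequal(names(res$scores), c("P2", "P3", "P4"))   # P1 has only 4 visits
  expect_equal(res$cumulative, sum(res$scores))
  expect_error(crosscov_perm_test(ds, "Campylobacter", "eosinophil",
                                  min_visits = 7), "eligible")
})

test_that("coupled genera track eosinophilia against the permutation null", {
  g <- shared_cohort()
  res <- crosscov_perm_test(g$dataset, "Campylobacter", "eosinophil",
                            B = 200, seed = 5)
  expect_gte(length(res$scores), 30)
  expect_true(all(abs(res$scores) <= 1))
  expect_lt(res$p, 0.05)
  # screening adjusts across genera and keeps the coupled pair on top
  scr <- crosscov_screen(g$dataset,
                         c("Campylobacter", "Granulicatella", "Moraxella",
                           "Serratia"),
                         target = "eosinophil", B = 100, seed = 6)
  expect_true(all(scr$q[scr$genus %in% c("Campylobacter", "Granulicatella")] < 0.05))
})

test_that("changepoints co-occurring with events produce significant odds ratios", {
  # ten patients whose marker genus steps up exactly at the one exacerbation
  sim <- withr::with_seed(57, {
    rows <- list(); meta <- list()
    for (p in 1:10) {
      nv <- 8; ex_at <- 5
      marker <- c(rep(0.05, ex_at - 1), rep(0.35, nv - ex_at + 1)) +
        runif(nv, 0, 0.01)
      flat <- rep(0.4, nv)
      ids <- sprintf("P%02d_V%d", p, 1:nv)
      rows[[p]] <- cbind(marker = marker, flat = flat,
                         g3 = 1 - marker - flat)
      meta[[p]] <- data.frame(
        sample_id = ids, patient_id = sprintf("P%02d", p),
        visit_index = 1:nv, day_offset = seq(0, by = 30, length.out = nv),
        visit_type = ifelse(1:nv == ex_at, "exacerbation", "stable"),
        eosinophil_pct = runif(nv, 0, 2), neutrophil_pct = runif(nv, 65, 90),
        stringsAsFactors = FALSE)
    }
    ab <- do.call(rbind, rows)
    md <- do.call(rbind, meta)
    rownames(ab) <- md$sample_id
    cohort_dataset(genus_table(ab, kind = "relative"), md)
  })
  res <- changepoint_event_association(sim, event = "exacerbation")
  mk <- res[res$genus == "marker", ]
  expect_true(mk$significant)
  expect_gt(mk$ci_low, 1)
  # a flat genus has no changepoints anywhere: corrected OR, not significant
  fl <- res[res$genus == "flat", ]
  expect_equal(fl$a + fl$b, 0)
  expect_true(fl$corrected)
  expect_false(fl$significant)
  expect_equal(res$n_transitions[1], 10 * 7)
})

test_that("endotype-switch events are restricted to consecutive stable visits", {
  sim <- withr::with_seed(58, {
    nv <- 8
    eos <- c(1, 1, 1, 8, 8, 1, 1, 8)       # N -> E at visit 4, E -> N at 6, N -> E at 8
    marker <- c(rep(0.05, 3), rep(0.5, 2), rep(0.05, 2), 0.5) + runif(nv, 0, 0.005)
    other <- (1 - marker) / 2
    md <- data.frame(
      sample_id = sprintf("P1_V%d", 1:nv), patient_id = "P1",
      visit_index = 1:nv, day_offset = seq(0, by = 30, length.out = nv),
      visit_type = c(rep("stable", 7), "exacerbation"),
      eosinophil_pct = eos, neutrophil_pct = c(80, 80, 80, 40, 40, 80, 80, 40),
      stringsAsFactors = FALSE)
    ab <- cbind(marker = marker, g2 = other, g3 = other)
    rownames(ab) <- md$sample_id
    cohort_dataset(genus_table(ab, kind = "relative"), md)
  })
  res <- changepoint_event_association(sim, event = "switch_to_E",
                                       penalty = 0.05)
  mk <- res[res$genus == "marker", ]
  # the stable-window N->E switch at visit 4 coincides with a changepoint;
  # the visit-8 switch arrives at an exacerbation and must not count
  expect_equal(mk$a, 1)
  expect_equal(mk$n_transitions, 6)
})
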