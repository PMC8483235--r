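lognormal_counts <- function(n, loads, noise_sd = 0.6, base = 2, depth = 30000,
                             factor_values = NULL) {
  v <- factor_values %||% rnorm(n)
  l <- sapply(seq_along(loads), function(j) base + loads[j] * v +
                noise_sd * rnorm(n))
  fr <- exp(l) / rowSums(exp(l))
  cnt <- t(apply(fr, 1, function(p) rmultinom(1, depth, p)))
  colnames(cnt) <- paste0("g", seq_along(loads))
  cnt
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("the SparCC basis solve matches the 3-genus algebraic solution", {
  # uncorrelated basis: the three-equation system is exact, so the solver
  # must return the generating variances and zero correlations
  withr::with_seed(61, {
    for (rep in 1:5) {
      w <- runif(3, 0.5, 2)
      tm <- outer(w, w, function(a, b) a + b)
      diag(tm) <- 0
      r <- endomix:::sparcc_basis(tm, exclusion_threshold = 10)
      expect_equal(max(abs(r[upper.tri(r)])), 0, tolerance = 1e-10)
    }
    # general variation matrix: solver equals the closed-form solution
    # omega_i = (t_ij + t_ik - t_jk) / 2 of the three-equation system,
    # worked independently of the matrix solve
    for (rep in 1:5) {
      tm <- matrix(0, 3, 3)
      tm[1, 2] <- tm[2, 1] <- runif(1, 1, 3)
      tm[1, 3] <- tm[3, 1] <- runif(1, 1, 3)
      tm[2, 3] <- tm[3, 2] <- runif(1, 1, 3)
      r <- endomix:::sparcc_basis(tm, exclusion_threshold = 10)
      om <- c((tm[1, 2] + tm[1, 3] - tm[2, 3]) / 2,
              (tm[1, 2] + tm[2, 3] - tm[1, 3]) / 2,
              (tm[1, 3] + tm[2, 3] - tm[1, 2]) / 2)
      if (any(om <= 0)) next
      for (i in 1:2) for (j in (i + 1):3) {
        expected <- (om[i] + om[j] - tm[i, j]) / (2 * sqrt(om[i] * om[j]))
        expect_equal(r[i, j], max(min(expected, 1), -1), tolerance = 1e-10)
      }
    }
  })
})

test_that("SparCC is null-calibrated and recovers a strong basis correlation", {
  cnt0 <- withr::with_seed(62, lognormal_counts(2000, rep(0, 8)))
  r0 <- sparcc(cnt0, seed = 1)
  expect_lt(max(abs(r0[upper.tri(r0)])), 0.1)
  expect_equal(r0, t(r0))
  expect_true(all(diag(r0) == 1))
  expect_true(all(abs(r0) <= 1))

  cnt1 <- withr::with_seed(63, {
    z <- rnorm(500)
    l <- cbind(2 + z, 2 + 0.9 * z + sqrt(1 - 0.81) * rnorm(500),
               matrix(2 + rnorm(500 * 4), 500, 4))
    fr <- exp(l) / rowSums(exp(l))
    cnt <- t(apply(fr, 1, function(p) rmultinom(1, 30000, p)))
    colnames(cnt) <- paste0("g", 1:6)
    cnt
  })
  r1 <- sparcc(cnt1, seed = 2)
  expect_gt(r1["g1", "g2"], 0.8)
  expect_lte(r1["g1", "g2"], 1)
  zero <- cnt1; zero[, 3] <- 0
  expect_error(sparcc(zero), "g3")
  expect_warning(sparcc(cnt1[1:50, ] / rowSums(cnt1[1:50, ]), seed = 1),
                 "relative")
})

test_that("edge significance is permutation-based with BH control", {
  cnt <- withr::with_seed(64, {
    z <- rnorm(150)
    l <- cbind(2 + z, 2 + 0.95 * z + 0.3 * rnorm(150),
               matrix(2 + rnorm(150 * 4), 150, 4))
    fr <- exp(l) / rowSums(exp(l))
    cnt <- t(apply(fr, 1, function(p) rmultinom(1, 20000, p)))
    colnames(cnt) <- paste0("g", 1:6)
    cnt
  })
  r <- sparcc(cnt, seed = 3)
  sig <- edge_significance(cnt, r, B = 300, seed = 4)
  expect_equal(min(sig$p, na.rm = TRUE), 1 / 301)   # attainable minimum
  expect_lt(sig$q["g1", "g2"], 0.05)
  expect_warning(edge_significance(cnt, r, B = 10, seed = 1), "resolution")
})

test_that("networks retain capped significant edges and find Louvain modules", {
  # two disconnected 5-cliques
  g <- 10
  r <- diag(g)
  rownames(r) <- colnames(r) <- paste0("g", 1:g)
  for (i in 1:4) for (j in (i + 1):5) r[i, j] <- r[j, i] <- 0.8
  for (i in 6:9) for (j in (i + 1):10) r[i, j] <- r[j, i] <- 0.8
  q <- matrix(1, g, g, dimnames = dimnames(r))
  q[r != 0 & row(r) != col(r)] <- 0.001
  net <- build_network(r, q, seed = 2)
  expect_equal(length(unique(net$nodes$module)), 2)
  expect_equal(nrow(net$edges), 20)            # top_k larger than available
  # node degree equals incident retained edges
  for (i in seq_len(nrow(net$nodes)))
    expect_equal(net$nodes$degree[i],
                 sum(net$edges$genus1 == net$nodes$genus[i]) +
                   sum(net$edges$genus2 == net$nodes$genus[i]))
  # cap: top_k = 3 keeps the 3 largest |r| per sign
  r2 <- r; r2[1, 2] <- r2[2, 1] <- 0.9
  net2 <- build_network(r2, q, top_k = 3, seed = 2)
  expect_equal(nrow(net2$edges), 3)
  expect_true(0.9 %in% net2$edges$r)
  id4 <- diag(4)
  dimnames(id4) <- list(paste0("g", 1:4), paste0("g", 1:4))
  expect_warning(empty <- build_network(id4, matrix(1, 4, 4)), "empty")
  expect_equal(nrow(empty$edges), 0)
})

test_that("residualization removes covariate and patient structure", {
  # empty covariates, no patients: centered values
  m <- withr::with_seed(65, matrix(rnorm(60), 20, 3))
  expect_equal(residualize_features(m), scale(m, scale = FALSE),
               ignore_attr = TRUE)
  # exact linear function of a covariate vanishes
  cov <- data.frame(age = withr::with_seed(66, rnorm(20, 60, 8)))
  m2 <- cbind(f1 = 2 * cov$age + 5, f2 = withr::with_seed(67, rnorm(20)))
  res <- residualize_features(m2, cov)
  expect_lt(sd(res[, "f1"]), 1e-6 * sd(m2[, "f1"]))
  # residual-covariate correlation bound at n = 240 with patient effects
  sim <- withr::with_seed(68, {
    n <- 240
    pats <- rep(sprintf("P%02d", 1:60), each = 4)
    covs <- data.frame(age = rnorm(n, 65, 8), sex = sample(c("F", "M"), n, TRUE),
                       bmi = rnorm(n, 27, 4))
    b <- rep(rnorm(60, 0, 1), each = 4)
    feats <- cbind(f1 = 0.3 * covs$age + b + rnorm(n),
                   f2 = 2 * (covs$sex == "F") + b + rnorm(n))
    list(feats = feats, covs = covs, pats = pats)
  })
  res2 <- residualize_features(sim$feats, sim$covs, sim$pats)
  expect_lt(abs(cor(res2[, "f1"], sim$covs$age)), 0.05)
  expect_lt(abs(cor(res2[, "f2"], as.numeric(sim$covs$sex == "F"))), 0.05)
  bad <- data.frame(a = 1:20, b = 2 * (1:20))
  expect_error(residualize_features(m, bad), "rank-deficient")
})

test_that("genus-mediator correlation finds latent-factor pairs and respects Spearman invariance", {
  sim <- withr::with_seed(69, {
    n <- 120
    z <- rnorm(n)
    genera <- cbind(ga = 0.7 * z + sqrt(1 - 0.49) * rnorm(n),
                    gb = rnorm(n), gc = rnorm(n))
    meds <- cbind(m1 = 0.7 * z + sqrt(1 - 0.49) * rnorm(n),
                  m2 = rnorm(n))
    list(genera = genera, meds = meds)
  })
  mc <- feature_mediator_corr(sim$genera, sim$meds)
  expect_true("ga" %in% mc$retained$genus && "m1" %in% mc$retained$mediator)
  hit <- mc$retained[mc$retained$genus == "ga" & mc$retained$mediator == "m1", ]
  expect_equal(hit$sign, "positive")
  # rank transformation of the inputs leaves coefficients unchanged
  mc2 <- feature_mediator_corr(apply(sim$genera, 2, rank),
                               apply(sim$meds, 2, rank))
  expect_equal(mc2$r, mc$r, tolerance = 1e-10)
  # too few complete pairs: skipped with warning
  g3 <- sim$genera; g3[3:120, "gb"] <- NA
  w <- capture_warnings(feature_mediator_corr(g3, sim$meds))
  expect_true(length(w) >= 1 && all(grepl("skipped", w)))
})

test_that("subgroup networks show the designed co-occurrence structure", {
  g <- shared_cohort(seed = 19, n_patients = 500)
  tr <- g$truth
  cnt <- unclass(g$dataset$abundance)
  r_nh <- sparcc(cnt[tr$sample_id[tr$state == "NH"], ], seed = 7)
  disp <- names(generator_config(n_patients = 2)$displacement)
  expect_lt(mean(r_nh["Haemophilus", disp]), -0.2)
  expect_gte(sum(r_nh["Haemophilus", ] < -0.1), 5)
  r_e <- sparcc(cnt[tr$sample_id[tr$state == "E"], ], seed = 8)
  clique <- c("Campylobacter", "Granulicatella", "Capnocytophaga",
              "Fusobacterium")
  sub <- r_e[clique, clique]
  expect_gt(min(sub[upper.tri(sub)]), 0.2)
})
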