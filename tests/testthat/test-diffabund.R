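make_rel <- function(m) {
  rownames(m) <- paste0("S", seq_len(nrow(m)))
  genus_table(m / rowSums(m), kind = "relative")
}

test_that("LEfSe-style screen calls large, consistent differences and nothing else", {
  # identical class distributions -> no significant genera
  x <- withr::with_seed(1, matrix(rgamma(60 * 5, 2), 60, 5))
  colnames(x) <- paste0("g", 1:5)
  tab <- make_rel(x)
  cls <- rep(c("A", "B"), each = 30)
  res0 <- lefse_effect_size(tab, cls, seed = 2)
  expect_false(any(res0$significant))

  # ~4 decades of separation in one genus -> LDA > 4 and significant
  y <- withr::with_seed(3, {
    m <- matrix(rgamma(100 * 4, 20), 100, 4)
    target <- c(abs(rnorm(50, 1e-5, 2e-6)), abs(rnorm(50, 1e-1, 1e-2)))
    cbind(m / rowSums(m) * (1 - target), marker = target)
  })
  colnames(y) <- c(paste0("g", 1:4), "marker")
  res <- lefse_effect_size(make_rel(y), rep(c("lo", "hi"), each = 50), seed = 4)
  mk <- res[res$genus == "marker", ]
  expect_true(mk$significant)
  expect_gt(mk$lda, 4)
  expect_equal(mk$enriched_class, "hi")
  # direction always matches the larger class mean
  sig <- res[res$significant, ]
  for (i in seq_len(nrow(sig))) {
    mm <- tapply(unclass(make_rel(y))[, sig$genus[i]],
                 rep(c("lo", "hi"), each = 50), mean)
    expect_equal(sig$enriched_class[i], names(mm)[which.max(mm)])
  }
  expect_error(lefse_effect_size(tab, rep("A", 60)), "two classes")
  expect_error(lefse_effect_size(tab, c(rep("A", 58), "B", "B")), "at least 3")
})

test_that("dominant-genus rescaling preserves ratios and row sums", {
  m <- rbind(c(0.8, 0.1, 0.1), c(0.05, 0.475, 0.475), c(0.05, 0.6, 0.35),
             c(0.05, 0.3, 0.65), c(0.05, 0.5, 0.45))
  colnames(m) <- c("Haemophilus", "g2", "g3")
  rownames(m) <- paste0("S", 1:5)
  tab <- genus_table(m, kind = "relative")
  out <- rescale_dominant(tab, "Haemophilus")   # mean Haemophilus = 0.2
  expect_equal(unname(unclass(out)[1, ]), c(0.2, 0.4, 0.4))
  expect_true(all(abs(rowSums(out) - 1) < 1e-9))
  # non-target within-sample ratios unchanged
  expect_equal(unclass(out)[3, "g2"] / unclass(out)[3, "g3"],
               m[3, "g2"] / m[3, "g3"])
  # a sample already at the mean is unchanged
  m2 <- m; m2[1, ] <- c(0.2, 0.4, 0.4); m2[2, ] <- c(0.2, 0.4, 0.4)
  m2[3:5, 1] <- 0.2; m2[3:5, 2:3] <- m2[3:5, 2:3] / rowSums(m2[3:5, 2:3]) * 0.8
  out2 <- rescale_dominant(genus_table(m2, kind = "relative"), "Haemophilus")
  expect_equal(unclass(out2)[1, ], unclass(genus_table(m2, kind = "relative"))[1, ],
               tolerance = 1e-12)
  only <- rbind(c(1, 0, 0), c(0.1, 0.45, 0.45))
  colnames(only) <- colnames(m); rownames(only) <- c("A", "B")
  expect_error(rescale_dominant(genus_table(only, kind = "relative"),
                                "Haemophilus"), "only")
})

test_that("quantile ranks are within-sample percentiles, tie-averaged, monotone-invariant", {
  m <- rbind(c(0.1, 0.2, 0.3, 0.4), c(0.25, 0.25, 0.2, 0.3))
  colnames(m) <- paste0("g", 1:4); rownames(m) <- c("A", "B")
  qr1 <- quantile_rank(genus_table(m, kind = "relative"))
  expect_equal(unname(qr1["A", ]), (1:4) / 4)
  expect_equal(unname(qr1["B", c("g1", "g2")]), c(2.5, 2.5) / 4)
  # squaring the abundances (strictly monotone) leaves the output unchanged
  m2 <- m^2 / rowSums(m^2)
  rownames(m2) <- rownames(m)
  expect_equal(quantile_rank(genus_table(m2, kind = "relative")), qr1)
})

test_that("eosinophilia-coupled genera survive all three normalizations", {
  g <- shared_cohort()
  tr <- g$truth
  sel <- tr$state %in% c("E", "NB")
  cls <- factor(ifelse(tr$state[sel] == "E", "eosinophilic", "neutrophilic"))
  rel <- to_relative(g$dataset$abundance)
  tab <- genus_table(unclass(rel)[sel, ], kind = "relative")
  for (norm in list(raw = function(t) t,
                    rescaled = function(t) rescale_dominant(t, "Haemophilus"),
                    quantile = quantile_rank)) {
    res <- lefse_effect_size(norm(tab), cls, seed = 3)
    hits <- res[res$genus %in% c("Campylobacter", "Granulicatella"), ]
    expect_true(all(hits$significant))
    expect_true(all(hits$enriched_class == "eosinophilic"))
  }
})

test_that("the mixed model recovers the simulated eosinophilia variance partition", {
  sim <- withr::with_seed(31, {
    n_pat <- 100; per <- 5; n <- n_pat * per
    comp <- matrix(rgamma(n * 6, 2), n, 6)
    comp <- comp / rowSums(comp)
    colnames(comp) <- paste0("g", 1:6)
    rownames(comp) <- sprintf("S%03d", 1:n)
    pat <- rep(sprintf("P%03d", 1:n_pat), each = per)
    b <- rep(rnorm(n_pat, 0, 2), each = per)
    xb <- 10 + 30 * comp[, "g1"] + 20 * comp[, "g2"]
    eos <- xb + b + rnorm(n, 0, 2)
    eos <- pmin(pmax(eos, 0), 100)
    md <- data.frame(sample_id = rownames(comp), patient_id = pat,
                     visit_index = rep(1:per, n_pat),
                     day_offset = rep(seq(0, 120, length.out = per), n_pat),
                     visit_type = "stable", eosinophil_pct = eos,
                     neutrophil_pct = 50, stringsAsFactors = FALSE)
    list(ds = cohort_dataset(genus_table(comp, kind = "relative"), md),
         r2_true = var(xb) / (var(xb) + 4 + 4))
  })
  fit <- eos_variance_explained(sim$ds, c("g1", "g2"), covariates = character(0))
  expect_lt(abs(fit$r2_marginal - sim$r2_true), 0.05)
  expect_true(all(c("g1", "g2") %in% fit$coefficients$term))

  # zero-effect simulation: R2 below 0.05
  null_ds <- withr::with_seed(32, {
    ds <- sim$ds
    ds$metadata$eosinophil_pct <-
      pmin(pmax(30 + rep(rnorm(100, 0, 2), each = 5) + rnorm(500, 0, 2), 0), 100)
    ds
  })
  fit0 <- eos_variance_explained(null_ds, c("g1", "g2"), covariates = character(0))
  expect_lt(fit0$r2_marginal, 0.05)
})

test_that("degenerate designs are reported: single visits and collinear genera", {
  comp <- withr::with_seed(33, matrix(rgamma(40 * 4, 2), 40, 4))
  comp <- comp / rowSums(comp)
  colnames(comp) <- paste0("g", 1:4)
  rownames(comp) <- sprintf("S%02d", 1:40)
  md <- data.frame(sample_id = rownames(comp),
                   patient_id = sprintf("P%02d", 1:40), visit_index = 1,
                   day_offset = 0, visit_type = "stable",
                   eosinophil_pct = withr::with_seed(34, runif(40, 0, 30)),
                   neutrophil_pct = 50, stringsAsFactors = FALSE)
  ds <- cohort_dataset(genus_table(comp, kind = "relative"), md)
  expect_warning(eos_variance_explained(ds, c("g1", "g2"),
                                        covariates = character(0)),
                 "single-visit")
  # perfectly collinear pair
  comp2 <- cbind(comp[, 1:2], g3 = comp[, 2], g4 = comp[, 4])
  comp2 <- comp2 / rowSums(comp2)
  rownames(comp2) <- rownames(comp)
  ds2 <- cohort_dataset(genus_table(comp2, kind = "relative"), md)
  expect_error(eos_variance_explained(ds2, c("g2", "g3"),
                                      covariates = character(0)), "collinear")
})
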