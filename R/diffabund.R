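#' LEfSe-style differential abundance
#'
#' Two-stage enrichment screen between sample classes: a per-genus
#' Kruskal-Wallis test with Benjamini-Hochberg correction, followed, for the
#' passing genera, by a bootstrapped linear-discriminant effect size.
#' Relative abundances are rescaled to the 1-1e6 range (the reference
#' algorithm's convention); each of `n_boot` class-stratified subsamples of
#' two thirds of the samples contributes
#' `log10(1 + |difference of class means|)` on that scale, and the effect
#' size is the bootstrap mean.  The enriched class is the one with the
#' larger overall mean.  With more than two classes the discriminant
#' contrast is the range of the class means.
#'
#' @param table relative-abundance [genus_table()].
#' @param classes class label per sample (>= 2 classes, each with >= 3
#'   samples).
#' @param lda_threshold effect-size call threshold on the log10 scale
#'   (default 4.0).
#' @param n_boot bootstrap subsamples.
#' @param seed RNG seed.
#' @param fdr use BH-adjusted q for the significance gate (default); set
#'   `FALSE` for the classic raw-alpha behavior.
#' @param alpha significance level for the (adjusted) Kruskal-Wallis p.
#' @return data frame per genus: `genus`, `enriched_class`, `p`, `q`,
#'   `lda`, `significant`.
#' @export
lefse_effect_size <- function(table, classes, lda_threshold = 4, n_boot = 30,
                              seed = 1L, fdr = TRUE, alpha = 0.05) {
  rel <- if (inherits(table, "genus_table")) unclass(to_relative(table))
         else as.matrix(table)
  classes <- droplevels(as.factor(classes))
  abort_if(nlevels(classes) < 2, "need at least two classes")
  abort_if(any(table(classes) < 3), "every class needs at least 3 samples")
  abort_if(length(classes) != nrow(rel), "classes must match table rows")
  p <- apply(rel, 2, function(v)
    suppressWarnings(stats::kruskal.test(v, classes)$p.value))
  p[is.na(p)] <- 1
  q <- stats::p.adjust(p, "BH")
  gate <- if (fdr) q else p
  scaled <- rel * 1e6
  scaled[scaled < 1] <- 1
  contrast <- function(v, cl) {
    m <- tapply(v, cl, mean)
    max(m) - min(m)
  }
  lda <- rep(NA_real_, ncol(rel))
  enriched <- rep(NA_character_, ncol(rel))
  idx_by_class <- split(seq_along(classes), classes)
  for (g in which(gate < alpha)) {
    es <- with_seed_if(seed + g, vapply(seq_len(n_boot), function(b) {
      take <- unlist(lapply(idx_by_class, function(ix)
        sample(ix, max(1, floor(2 * length(ix) / 3)))))
      log10(1 + contrast(scaled[take, g], classes[take]))
    }, numeric(1)))
    lda[g] <- mean(es)
    m <- tapply(rel[, g], classes, mean)
    enriched[g] <- names(m)[which.max(m)]
  }
  data.frame(genus = colnames(rel), enriched_class = enriched, p = p, q = q,
             lda = lda,
             significant = !is.na(lda) & lda > lda_threshold & gate < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Downscale a dominant genus to its cohort mean
#'
#' Dominance-control normalization: in every sample the target genus is set
#' to its across-sample mean `m` and the remaining genera are rescaled
#' proportionally to total `1 - m`, so rows still sum to one while
#' within-sample ratios among the non-target genera are preserved.
#'
#' @param table relative-abundance [genus_table()].
#' @param genus name of the genus to downscale.
#' @return rescaled relative `genus_table`.
#' @export
rescale_dominant <- function(table, genus) {
  rel <- to_relative(table)
  abort_if(!genus %in% colnames(rel), "genus not in table: ", genus)
  x <- unclass(rel)
  m <- mean(x[, genus])
  abort_if(m >= 1, "mean abundance of ", genus, " is >= 1; nothing left to rescale")
  only <- x[, genus] >= 1 - 1e-12
  abort_if(any(only), "samples contain only ", genus, ": ",
           paste(rownames(x)[only], collapse = ", "))
  scale <- (1 - m) / (1 - x[, genus])
  out <- x * scale
  out[, genus] <- m
  genus_table(out / rowSums(out), kind = "relative")
}

#' Within-sample percentile ranks
#'
#' Replaces each genus value by its within-sample rank divided by the number
#' of genera (ties as average ranks).  The result is invariant to any
#' strictly monotone per-sample transform of the abundances.
#'
#' @param table relative-abundance [genus_table()].
#' @return numeric matrix of percentile ranks in `(0, 1]`.
#' @export
quantile_rank <- function(table) {
  x <- unclass(if (inherits(table, "genus_table")) to_relative(table) else table)
  t(apply(x, 1, function(v) rank(v, ties.method = "average"))) / ncol(x)
}

#' Variance in sputum eosinophilia explained by genus abundances
#'
#' Linear mixed model of sputum eosinophil percentage on the listed genus
#' relative abundances plus covariates, with a per-patient random
#' intercept.  The marginal R-squared is the fixed-effect variance over the
#' total (fixed + random-intercept + residual) variance; coefficient
#' p-values use Satterthwaite degrees of freedom.  When no patient has two
#' visits the random intercept is inestimable and the model degrades to a
#' fixed-effects fit with a warning.
#'
#' @param dataset a [cohort_dataset()] with `eosinophil_pct` metadata.
#' @param genera genus names to include as fixed effects.
#' @param covariates metadata columns used as adjustment covariates.
#' @return list: `r2_marginal`, `coefficients` (term, estimate, p),
#'   `model`.
#' @export
eos_variance_explained <- function(dataset, genera,
                                   covariates = c("age", "sex", "bmi", "smoking")) {
  md <- dataset$metadata
  rel <- unclass(to_relative(dataset$abundance))
  abort_if(!all(genera %in% colnames(rel)), "unknown genera: ",
           paste(setdiff(genera, colnames(rel)), collapse = ", "))
  covariates <- intersect(covariates, names(md))
  df <- data.frame(eos = md$eosinophil_pct, rel[, genera, drop = FALSE],
                   md[, covariates, drop = FALSE],
                   patient = md$patient_id, check.names = FALSE)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  fixed_terms <- c(sprintf("`%s`", genera), covariates)
  fixed_formula <- stats::reformulate(fixed_terms, response = "eos")
  mm <- stats::model.matrix(fixed_formula, df)
  if (qr(mm)$rank < ncol(mm)) {
    cc <- stats::cor(mm[, -1, drop = FALSE])
    diag(cc) <- 0
    bad <- which(abs(cc) > 0.999, arr.ind = TRUE)
    pair <- if (nrow(bad)) paste(rownames(cc)[bad[1, 1]], colnames(cc)[bad[1, 2]],
                                 sep = " ~ ") else "unknown pair"
    stop("collinear fixed effects: ", pair, call. = FALSE)
  }
  multi_visit <- any(table(df$patient) > 1)
  if (!multi_visit) {
    warning("all patients single-visit; fitting fixed effects only", call. = FALSE)
    fit <- stats::lm(fixed_formula, df)
    sm <- summary(fit)
    coefs <- data.frame(term = rownames(sm$coefficients),
                        estimate = sm$coefficients[, 1],
                        p = sm$coefficients[, 4], row.names = NULL)
    return(list(r2_marginal = sm$r.squared, coefficients = coefs, model = fit))
  }
  f <- stats::update(fixed_formula, . ~ . + (1 | patient))
  fit <- lmerTest::lmer(f, data = df, REML = TRUE)
  fe <- lme4::fixef(fit)
  xb <- mm[, names(fe), drop = FALSE] %*% fe
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_f <- stats::var(as.numeric(xb))
  var_tot <- var_f + sum(vc$vcov)
  sm <- stats::coef(summary(fit))
  coefs <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                      p = sm[, "Pr(>|t|)"], row.names = NULL)
  list(r2_marginal = var_f / var_tot, coefficients = coefs, model = fit)
}
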