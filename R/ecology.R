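#' Shannon diversity
#'
#' Shannon entropy (natural log) of one composition or of every row of an
#' abundance matrix; rows are normalized to proportions first.
#'
#' @param x non-negative vector or matrix with positive (row) sums.
#' @return diversity in nats, in `[0, log(richness)]`.
#' @export
shannon <- function(x) {
  if (is.matrix(x) || inherits(x, "genus_table")) {
    abort_if(any(rowSums(x) <= 0), "all-zero sample")
    return(vegan::diversity(unclass(x), index = "shannon"))
  }
  abort_if(any(x < 0), "negative abundances")
  abort_if(sum(x) <= 0, "all-zero composition")
  vegan::diversity(x, index = "shannon")
}

#' Bray-Curtis dissimilarity
#'
#' `BC(x, y) = sum |x_i - y_i| / sum (x_i + y_i)`, in `[0, 1]` for
#' relative abundances.
#'
#' @param table relative-abundance [genus_table()] (or matrix).
#' @return a [stats::dist].
#' @export
bray_curtis <- function(table) {
  if (inherits(table, "genus_table"))
    abort_if(table_kind(table) != "relative", "bray_curtis expects relative abundances")
  vegan::vegdist(unclass(table), method = "bray")
}

#' Principal coordinates analysis
#'
#' Classical (Torgerson) scaling: the squared distance matrix is double
#' centered into the Gower matrix, whose eigendecomposition yields sample
#' coordinates on axes ordered by decreasing eigenvalue.  Negative
#' eigenvalues (non-Euclidean input) are reported and flagged but no
#' correction is applied to the coordinates; proportions explained are
#' relative to the sum of positive eigenvalues.
#'
#' @param dist a [stats::dist] or square symmetric matrix.
#' @return list of class `pcoa_result`: `coordinates` (samples x positive
#'   axes), `eigenvalues` (all), `proportion_explained`,
#'   `negative_eigenvalues` flag.
#' @export
pcoa <- function(dist) {
  d <- as.matrix(dist)
  abort_if(nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-8,
           "distance matrix must be square and symmetric")
  n <- nrow(d)
  j <- diag(n) - matrix(1 / n, n, n)
  g <- -0.5 * j %*% (d^2) %*% j
  e <- eigen((g + t(g)) / 2, symmetric = TRUE)
  pos <- e$values > 1e-8 * max(abs(e$values))
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), nrow = sum(pos))
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("PC", seq_len(ncol(coords)))
  structure(list(coordinates = coords,
                 eigenvalues = e$values,
                 proportion_explained = e$values[pos] / sum(e$values[pos]),
                 negative_eigenvalues = any(e$values < -1e-8 * max(abs(e$values)))),
            class = "pcoa_result")
}

permanova_stats <- function(d2, groups) {
  n <- nrow(d2)
  k <- length(unique(groups))
  sst <- sum(d2) / (2 * n)
  ssw <- sum(vapply(split(seq_len(n), groups), function(idx)
    sum(d2[idx, idx]) / (2 * length(idx)), numeric(1)))
  ssb <- sst - ssw
  c(f = (ssb / (k - 1)) / (ssw / (n - k)), r2 = ssb / sst)
}

#' One-way PERMANOVA
#'
#' Permutational multivariate analysis of variance on a distance matrix:
#' pseudo-F from within- versus between-group sums of squared distances,
#' with the p-value from seeded label permutations,
#' `p = (1 + #permuted F >= observed) / (n_perm + 1)`.
#'
#' @param dist a [stats::dist].
#' @param groups group labels, at least two non-empty groups.
#' @param n_perm number of permutations.
#' @param seed RNG seed for the permutations.
#' @return list of class `permanova_result`: `f`, `r2`, `p`, `n_perm`,
#'   `seed`.
#' @export
permanova <- function(dist, groups, n_perm = 999, seed = 1L) {
  d2 <- as.matrix(dist)^2
  groups <- as.factor(groups)
  abort_if(nlevels(droplevels(groups)) < 2, "need at least two groups")
  obs <- permanova_stats(d2, groups)
  exceed <- with_seed_if(seed, {
    sum(vapply(seq_len(n_perm), function(i)
      permanova_stats(d2, sample(groups))["f"], numeric(1)) >= obs["f"])
  })
  structure(list(f = unname(obs["f"]), r2 = unname(obs["r2"]),
                 p = (1 + exceed) / (n_perm + 1), n_perm = n_perm,
                 seed = seed),
            class = "permanova_result")
}

#' Group dispersion as distance to centroid
#'
#' Per-sample distance to its group centroid in principal-coordinate space
#' with the imaginary-axis correction for non-Euclidean distances
#' (Anderson's method, via [vegan::betadisper()]), followed by pairwise
#' rank-sum comparisons of the dispersions between groups with
#' Benjamini-Hochberg adjustment.
#'
#' @param dist a [stats::dist].
#' @param groups group labels.
#' @return list: `distances` (per sample), `groups`, `comparisons` (data
#'   frame of pairwise Wilcoxon tests with BH-adjusted q).
#' @export
centroid_dispersion <- function(dist, groups) {
  groups <- as.factor(groups)
  if (any(table(groups) == 1))
    warning("group of size 1: its dispersion is 0", call. = FALSE)
  if (all(dist < 1e-12)) {            # degenerate: identical samples
    dd <- rep(0, attr(dist, "Size"))
    names(dd) <- attr(dist, "Labels") %||% seq_along(dd)
  } else {
    bd <- vegan::betadisper(dist, groups, type = "centroid")
    dd <- bd$distances
  }
  pairs <- utils::combn(levels(groups), 2)
  cmp <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    p = apply(pairs, 2, function(gp) {
                      a <- dd[groups == gp[1]]; b <- dd[groups == gp[2]]
                      if (length(a) < 2 || length(b) < 2) return(NA_real_)
                      suppressWarnings(stats::wilcox.test(a, b)$p.value)
                    }))
  cmp$q <- stats::p.adjust(cmp$p, "BH")
  list(distances = dd, groups = groups, comparisons = cmp)
}

#' Paired stability-exacerbation microbiome shifts
#'
#' Pairs each exacerbation sample with the same patient's most recent
#' preceding stable sample and computes their Bray-Curtis dissimilarity.
#' Pairs are grouped by the inflammatory state (NH/NB/E) of the stable
#' sample and the per-group shifts compared pairwise by rank-sum tests with
#' BH adjustment.  Exacerbations with no preceding stable visit are
#' excluded; pairs whose stable state is not NH/NB/E are dropped from the
#' grouped comparison.
#'
#' @param dataset a [cohort_dataset()].
#' @param states data frame `sample_id`, `state` (NH/NB/E/EXCLUDED), e.g.
#'   from [derive_states()].
#' @return list: `pairs` (data frame with stable/exacerbation ids, stable
#'   state, Bray-Curtis shift), `comparisons`.  Empty with a warning when
#'   nothing can be paired.
#' @export
paired_shift <- function(dataset, states) {
  md <- dataset$metadata
  rel <- unclass(to_relative(dataset$abundance))
  st <- stats::setNames(states$state, states$sample_id)
  ord_col <- if ("day_offset" %in% names(md)) "day_offset" else "visit_index"
  rows <- list()
  for (pd in split(md, md$patient_id)) {
    pd <- pd[order(pd[[ord_col]]), ]
    for (i in which(pd$visit_type == "exacerbation")) {
      prev <- which(pd$visit_type == "stable" & seq_len(nrow(pd)) < i)
      if (length(prev) == 0) next
      s_id <- pd$sample_id[max(prev)]; e_id <- pd$sample_id[i]
      bc <- vegan::vegdist(rel[c(s_id, e_id), , drop = FALSE], "bray")[1]
      rows[[length(rows) + 1]] <- data.frame(
        patient_id = pd$patient_id[1], stable_id = s_id, exac_id = e_id,
        stable_state = unname(st[s_id] %||% NA_character_), shift = bc,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    warning("no pairable stability-exacerbation samples", call. = FALSE)
    return(list(pairs = data.frame(), comparisons = data.frame()))
  }
  pairs <- do.call(rbind, rows)
  grp <- pairs[pairs$stable_state %in% c("NH", "NB", "E") &
                 !is.na(pairs$stable_state), ]
  cmp <- data.frame()
  lev <- intersect(c("NH", "NB", "E"), unique(grp$stable_state))
  if (length(lev) >= 2) {
    pr <- utils::combn(lev, 2)
    cmp <- data.frame(group1 = pr[1, ], group2 = pr[2, ],
                      p = apply(pr, 2, function(gp)
                        suppressWarnings(stats::wilcox.test(
                          grp$shift[grp$stable_state == gp[1]],
                          grp$shift[grp$stable_state == gp[2]])$p.value)))
    cmp$q <- stats::p.adjust(cmp$p, "BH")
  }
  list(pairs = pairs, comparisons = cmp)
}
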