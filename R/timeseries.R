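#' PELT changepoint detection for a single trajectory
#'
#' Exact penalized segmentation of a numeric series under the normal
#' mean-change model: the cost of a segment is its sum of squared
#' deviations from the segment mean, and the objective is the total cost
#' plus `penalty` per added segment.  The search is the pruned exact linear
#' time (PELT) recursion, whose pruning never discards an optimal
#' candidate, so the result is the exact minimizer.  The default penalty is
#' BIC-style, `2 * sigma2 * log(n)`, with the noise variance estimated from
#' first differences (`var(diff(x)) / 2`), which is robust to mean shifts.
#'
#' @param series numeric vector without missing values (drop missing visits
#'   before calling and keep your own index map).
#' @param penalty non-negative penalty per additional segment; `NULL` for
#'   the BIC-style default.
#' @param min_seg minimum segment length (default 2).
#' @return list of class `changepoint_set`: `changepoints` (1-based first
#'   index of each new segment, strictly increasing; empty when the series
#'   is homogeneous), `segments` (data frame `start`, `end`, `mean`),
#'   `penalty`, `min_seg`.
#' @export
pelt_changepoints <- function(series, penalty = NULL, min_seg = 2) {
  x <- as.numeric(series)
  abort_if(anyNA(x), "series contains missing values")
  n <- length(x)
  abort_if(n < 2 * min_seg, "series shorter than 2 * min_seg")
  if (is.null(penalty)) {
    sig2 <- stats::var(diff(x)) / 2
    if (!is.finite(sig2) || sig2 <= 0) sig2 <- .Machine$double.eps
    penalty <- 2 * sig2 * log(n)
  }
  abort_if(penalty < 0, "penalty must be non-negative")
  s1 <- c(0, cumsum(x)); s2 <- c(0, cumsum(x^2))
  segcost <- function(i, j) { # cost of x[i..j]
    len <- j - i + 1
    (s2[j + 1] - s2[i]) - (s1[j + 1] - s1[i])^2 / len
  }
  f <- rep(Inf, n + 1)          # f[t+1] = optimal cost of x[1..t]
  f[1] <- -penalty
  last <- integer(n + 1)
  cands <- 0L
  # A candidate s that fails the pruning test at time t is dominated by the
  # candidate t itself -- but only from time t + min_seg on, when t becomes
  # a feasible last changepoint.  Removals are therefore applied with that
  # delay, which preserves exactness under the minimum-segment constraint.
  removals <- vector("list", n + min_seg + 1)
  for (t in min_seg:n) {
    if (!is.null(removals[[t]])) cands <- setdiff(cands, removals[[t]])
    ok <- cands[cands <= t - min_seg]
    vals <- f[ok + 1] + vapply(ok, function(s) segcost(s + 1, t), numeric(1)) +
      penalty
    b <- which.min(vals)
    f[t + 1] <- vals[b]
    last[t + 1] <- ok[b]
    removals[[t + min_seg]] <- ok[vals - penalty > f[t + 1]]  # PELT prune, K = 0
    cands <- c(cands, t)
  }
  cps <- integer(0)
  s <- last[n + 1]
  while (s > 0) {
    cps <- c(s, cps)
    s <- last[s + 1]
  }
  starts <- c(1L, cps + 1L)
  ends <- c(cps, n)
  segs <- data.frame(start = starts, end = ends,
                     mean = vapply(seq_along(starts), function(i)
                       mean(x[starts[i]:ends[i]]), numeric(1)))
  structure(list(changepoints = cps + 1L, segments = segs,
                 penalty = penalty, min_seg = min_seg),
            class = "changepoint_set")
}

#' Changepoints of every genus trajectory in a cohort
#'
#' Orders each eligible patient's visits chronologically, converts
#' abundances to relative, and runs [pelt_changepoints()] per genus.
#'
#' @param dataset a [cohort_dataset()].
#' @param genera genus subset (default all).
#' @param min_visits minimum visits for a patient to be analyzed
#'   (default 5).
#' @param penalty,min_seg passed to [pelt_changepoints()].
#' @return list of class `cohort_changepoints`, one element per eligible
#'   patient: `sample_ids` (chronological), `visit_type`, and `starts`, a
#'   named list per genus of 1-based positions (within the patient's
#'   series) where a new segment starts.
#' @export
cohort_changepoints <- function(dataset, genera = NULL, min_visits = 5,
                                penalty = NULL, min_seg = 2) {
  rel <- unclass(to_relative(dataset$abundance))
  genera <- genera %||% colnames(rel)
  md <- dataset$metadata
  ord_col <- if ("day_offset" %in% names(md)) "day_offset" else "visit_index"
  out <- list()
  for (pd in split(md, md$patient_id)) {
    if (nrow(pd) < min_visits) next
    pd <- pd[order(pd[[ord_col]]), ]
    starts <- lapply(genera, function(g)
      pelt_changepoints(rel[pd$sample_id, g], penalty, min_seg)$changepoints)
    names(starts) <- genera
    out[[pd$patient_id[1]]] <- list(sample_ids = pd$sample_id,
                                    visit_type = pd$visit_type,
                                    starts = starts)
  }
  structure(out, class = "cohort_changepoints", min_visits = min_visits)
}

#' Odds ratio between changepoints and events
#'
#' Scores every inter-visit transition of every eligible patient: a
#' transition "contains" a changepoint for a genus when a new segment
#' starts exactly at the destination visit, and carries an event when the
#' supplied per-visit event indicator is `TRUE` at the destination visit
#' (`NA` removes the transition, e.g. to restrict switch events to
#' consecutive stable visits).  The pooled 2x2 table (changepoint x event)
#' gives a Woolf-CI odds ratio per genus; a genus is called significant
#' when the lower CI limit exceeds 1.
#'
#' @param changepoints a [cohort_changepoints()].
#' @param events list named by patient: logical vector per visit (aligned
#'   with the patient's chronological `sample_ids`), `NA` to drop a
#'   transition.
#' @return data frame per genus: counts `a`, `b`, `c`, `d` (a = changepoint
#'   and event), `or`, `ci_low`, `ci_high`, `p`, `corrected`,
#'   `significant`, and `n_transitions`.
#' @export
changepoint_event_or <- function(changepoints, events) {
  pats <- intersect(names(changepoints), names(events))
  abort_if(length(pats) == 0, "no eligible patients shared by changepoints and events")
  genera <- names(changepoints[[pats[1]]]$starts)
  res <- lapply(genera, function(g) {
    a <- b <- cc <- d <- 0L
    for (p in pats) {
      ev <- events[[p]]
      nv <- length(changepoints[[p]]$sample_ids)
      abort_if(length(ev) != nv, "event vector misaligned for patient ", p)
      cp <- changepoints[[p]]$starts[[g]]
      for (t in 2:nv) {
        if (is.na(ev[t])) next
        has_cp <- t %in% cp
        if (has_cp && ev[t]) a <- a + 1L
        else if (has_cp) b <- b + 1L
        else if (ev[t]) cc <- cc + 1L
        else d <- d + 1L
      }
    }
    abort_if(a + b + cc + d == 0, "zero eligible transitions")
    o <- odds_ratio_2x2(a, b, cc, d)
    data.frame(genus = g, a = a, b = b, c = cc, d = d, or = o$or,
               ci_low = o$ci_low, ci_high = o$ci_high, p = o$p,
               corrected = o$corrected, significant = o$ci_low > 1,
               n_transitions = a + b + cc + d, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Changepoint-event association across a cohort
#'
#' End-to-end wrapper: detects per-genus changepoints for all patients with
#' at least `min_visits` visits and associates them with one of three
#' event definitions: `"exacerbation"` (the destination visit is an
#' exacerbation, all transitions eligible), `"switch_to_E"` /
#' `"switch_to_N"` (endotype switch neutrophilic -> eosinophilic or the
#' reverse between consecutive stable visits; other transitions excluded).
#'
#' @param dataset a [cohort_dataset()].
#' @param event event definition (see above).
#' @param genera,min_visits,penalty,min_seg passed to
#'   [cohort_changepoints()].
#' @param thresholds endotype thresholds for the switch events.
#' @return per-genus association data frame, see [changepoint_event_or()].
#' @export
changepoint_event_association <- function(dataset,
                                          event = c("exacerbation",
                                                    "switch_to_E", "switch_to_N"),
                                          genera = NULL, min_visits = 5,
                                          penalty = NULL, min_seg = 2,
                                          thresholds = endotype_thresholds()) {
  event <- match.arg(event)
  cps <- cohort_changepoints(dataset, genera, min_visits, penalty, min_seg)
  endo <- endotype_samples(dataset, thresholds)
  lab <- stats::setNames(as.character(endo$endotype), endo$sample_id)
  events <- lapply(cps, function(pc) {
    nv <- length(pc$sample_ids)
    ev <- rep(NA, nv)
    if (event == "exacerbation") {
      ev <- pc$visit_type == "exacerbation"
    } else {
      from <- if (event == "switch_to_E") "neutrophilic" else "eosinophilic"
      to <- if (event == "switch_to_E") "eosinophilic" else "neutrophilic"
      for (t in 2:nv) {
        both_stable <- all(pc$visit_type[(t - 1):t] == "stable")
        e0 <- lab[pc$sample_ids[t - 1]]; e1 <- lab[pc$sample_ids[t]]
        if (both_stable && e0 %in% c(from, to) && e1 %in% c(from, to))
          ev[t] <- (e0 == from && e1 == to)
      }
    }
    ev
  })
  changepoint_event_or(cps, events)
}

# normalized cross-correlation at integer lags; identical to the values
# stats::ccf() reports (covariances with 1/n, scaled by full-series sds)
ncc <- function(x, y, lags) {
  n <- length(x)
  xs <- x - mean(x); ys <- y - mean(y)
  den <- sqrt(sum(xs^2) * sum(ys^2))
  vapply(lags, function(l) {
    t <- seq_len(n - abs(l))
    if (l >= 0) sum(xs[t + l] * ys[t]) / den else sum(xs[t] * ys[t - l]) / den
  }, numeric(1))
}

#' Cross-covariance score of two visit series
#'
#' Both series are centered and scaled by their full-series standard
#' deviations and the normalized cross-correlation is computed at integer
#' lags `|l| <= max_lag`; the score is the maximum signed value over those
#' lags, in `[-1, 1]`.  Positive lag means the abundance series leads the
#' cell series.  Visits are sparse, so only short lags are meaningful.
#'
#' @param abundance_series,cell_series equal-length numeric series
#'   (length >= 5) with positive variance.
#' @param max_lag largest lag considered (default 1).
#' @return the score, or `NA` with a warning for a zero-variance series.
#' @export
crosscov_score <- function(abundance_series, cell_series, max_lag = 1) {
  x <- as.numeric(abundance_series); y <- as.numeric(cell_series)
  abort_if(length(x) != length(y), "series must have equal length")
  abort_if(length(x) < 5, "series must have at least 5 visits")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero-variance series: score undefined", call. = FALSE)
    return(NA_real_)
  }
  r <- ncc(x, y, -max_lag:max_lag)
  max(pmin(pmax(r, -1), 1))
}

#' Permutation test for cross-covariance tracking
#'
#' Computes the per-patient cross-covariance score between a genus
#' trajectory and a sputum cell percentage for every patient with at least
#' `min_visits` complete visits, the cumulative score (sum over patients)
#' and its interpatient SD, and a null distribution from `B` within-patient
#' permutations of the abundance series order (the cell series stays
#' fixed).  Significance is a one-sided rank-sum test of the observed
#' per-patient scores against the pooled permuted scores (a paired
#' alternative compares each patient's observed score with the mean of its
#' own null).
#'
#' @param dataset a [cohort_dataset()].
#' @param genus genus to score.
#' @param target `"eosinophil"` or `"neutrophil"` sputum percentage.
#' @param B number of permutations per patient.
#' @param min_visits eligibility threshold (default 5).
#' @param max_lag passed to [crosscov_score()].
#' @param seed RNG seed.
#' @param paired use the paired Wilcoxon variant.
#' @return list of class `crosscov_result`: `genus`, `scores` (per
#'   patient), `cumulative`, `sd`, `p`, `null_scores`, `n_perm`, `seed`.
#' @export
crosscov_perm_test <- function(dataset, genus, target = c("eosinophil", "neutrophil"),
                               B = 1000, min_visits = 5, max_lag = 1,
                               seed = 1L, paired = FALSE) {
  target <- match.arg(target)
  col <- paste0(target, "_pct")
  md <- dataset$metadata
  abort_if(!col %in% names(md), "metadata lacks ", col)
  rel <- unclass(to_relative(dataset$abundance))
  abort_if(!genus %in% colnames(rel), "unknown genus: ", genus)
  ord_col <- if ("day_offset" %in% names(md)) "day_offset" else "visit_index"
  series <- list()
  for (pd in split(md, md$patient_id)) {
    pd <- pd[order(pd[[ord_col]]), ]
    pd <- pd[!is.na(pd[[col]]), ]
    if (nrow(pd) < min_visits) next
    series[[pd$patient_id[1]]] <- list(x = rel[pd$sample_id, genus],
                                       y = pd[[col]])
  }
  abort_if(length(series) == 0, "no eligible patients (>= ", min_visits, " visits)")
  if (length(series) < 3)
    warning("fewer than 3 eligible patients; test is weakly powered", call. = FALSE)
  with_seed_if(seed, {
    obs <- vapply(series, function(s)
      suppressWarnings(crosscov_score(s$x, s$y, max_lag)), numeric(1))
    keep <- !is.na(obs)
    obs <- obs[keep]; series <- series[keep]
    null <- lapply(series, function(s)
      vapply(seq_len(B), function(b)
        suppressWarnings(crosscov_score(sample(s$x), s$y, max_lag)), numeric(1)))
    p <- if (paired) {
      mu <- vapply(null, mean, na.rm = TRUE, numeric(1))
      suppressWarnings(stats::wilcox.test(obs, mu, paired = TRUE,
                                          alternative = "greater")$p.value)
    } else {
      suppressWarnings(stats::wilcox.test(obs, unlist(null),
                                          alternative = "greater")$p.value)
    }
    structure(list(genus = genus, scores = obs, cumulative = sum(obs),
                   sd = stats::sd(obs), p = p, null_scores = null,
                   n_perm = B, seed = seed),
              class = "crosscov_result")
  })
}

#' Screen genera for cross-covariance tracking
#'
#' Runs [crosscov_perm_test()] for several genera and adjusts the p-values
#' across genera by Benjamini-Hochberg.
#'
#' @param dataset a [cohort_dataset()].
#' @param genera genus names (default: all).
#' @param ... passed to [crosscov_perm_test()].
#' @return data frame `genus`, `cumulative`, `sd`, `n_patients`, `p`, `q`.
#' @export
crosscov_screen <- function(dataset, genera = NULL, ...) {
  genera <- genera %||% colnames(dataset$abundance)
  res <- lapply(genera, function(g) crosscov_perm_test(dataset, g, ...))
  out <- data.frame(genus = genera,
                    cumulative = vapply(res, `[[`, numeric(1), "cumulative"),
                    sd = vapply(res, `[[`, numeric(1), "sd"),
                    n_patients = vapply(res, function(r) length(r$scores), numeric(1)),
                    p = vapply(res, `[[`, numeric(1), "p"),
                    stringsAsFactors = FALSE)
  out$q <- stats::p.adjust(out$p, "BH")
  out
}
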