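#' Derive joint inflammatory states
#'
#' Combines the sputum endotype with the microbiome community type into the
#' three states used for transition analysis: NH (neutrophilic with a
#' Haemophilus-predominant community), NB (neutrophilic with a balanced
#' community), E (eosinophilic, any community).  Every other combination
#' (mixed, paucigranulocytic, unassigned, or neutrophilic with another
#' dominant genus) is EXCLUDED.
#'
#' @param endotype factor/character of endotype labels (see
#'   [classify_endotype()]).
#' @param community_type character of community-type names (see
#'   [name_community_types()]); `"balanced"` prefixes count as balanced.
#' @return character vector over `{"NH", "NB", "E", "EXCLUDED"}`.
#' @export
derive_states <- function(endotype, community_type) {
  abort_if(length(endotype) != length(community_type),
           "endotype and community_type must align")
  endo <- as.character(endotype)
  bal <- startsWith(community_type, "balanced")
  haem <- community_type == "Haemophilus-predominant"
  out <- rep("EXCLUDED", length(endo))
  out[endo == "neutrophilic" & haem] <- "NH"
  out[endo == "neutrophilic" & bal] <- "NB"
  out[endo == "eosinophilic"] <- "E"
  out
}

#' State labels for every sample of a cohort
#'
#' Convenience wrapper: endotypes the samples, community-types the cohort,
#' and derives the joint NH/NB/E/EXCLUDED state per sample.
#'
#' @param dataset a [cohort_dataset()].
#' @param typing optional result of [community_typing()] (computed if
#'   missing).
#' @param thresholds an [endotype_thresholds()].
#' @return data frame `sample_id`, `endotype`, `community_type`, `state`.
#' @export
state_samples <- function(dataset, typing = NULL,
                          thresholds = endotype_thresholds()) {
  endo <- endotype_samples(dataset, thresholds)
  if (is.null(typing)) typing <- community_typing(dataset)
  asg <- typing$assignment
  m <- match(endo$sample_id, asg$sample_id)
  data.frame(sample_id = endo$sample_id,
             endotype = as.character(endo$endotype),
             community_type = asg$community_type[m],
             state = derive_states(endo$endotype, asg$community_type[m]),
             stringsAsFactors = FALSE)
}

#' Within-patient state transition tables
#'
#' Builds from-state by to-state counts over consecutive same-patient visit
#' pairs (chronological order), separately for the two analyzed contexts:
#' stable followed by stable, and stable followed by exacerbation.  A pair
#' is dropped when either member's state is EXCLUDED
#' (mixed/paucigranulocytic endotypes or non-NH/NB communities) — pairs are
#' never bridged across an excluded visit, so the recovered persistences
#' estimate the underlying one-step transition probabilities.  Pairs in
#' other contexts (exacerbation first) are also dropped.  Persistence of a
#' state is the fraction of its outgoing transitions that return to it.
#'
#' @param dataset a [cohort_dataset()].
#' @param states data frame `sample_id`, `state` as from [state_samples()]
#'   or [derive_states()].
#' @return list of class `transition_table` with one element per context
#'   (`stable_stable`, `stable_exacerbation`), each holding `counts` (3x3
#'   matrix over NH/NB/E), `persistence`, `n_pairs`; plus a data frame
#'   `pairs` of the contributing transitions and
#'   `adjacency = "consecutive"`.
#' @export
transition_table <- function(dataset, states) {
  md <- dataset$metadata
  st <- stats::setNames(states$state, states$sample_id)
  ord_col <- if ("day_offset" %in% names(md)) "day_offset" else "visit_index"
  keep <- c("NH", "NB", "E")
  rows <- list()
  for (pd in split(md, md$patient_id)) {
    o <- order(pd[[ord_col]])
    abort_if(any(diff(pd$visit_index[o]) <= 0), "unordered visits for patient ",
             pd$patient_id[1])
    pd <- pd[o, ]
    s <- unname(st[pd$sample_id])
    if (nrow(pd) < 2) next
    for (i in seq_len(nrow(pd) - 1)) {
      if (anyNA(s[i:(i + 1)]) || !all(s[i:(i + 1)] %in% keep)) next
      ctx <- if (pd$visit_type[i] == "stable" && pd$visit_type[i + 1] == "stable")
        "stable_stable"
      else if (pd$visit_type[i] == "stable" && pd$visit_type[i + 1] == "exacerbation")
        "stable_exacerbation"
      else NA_character_
      if (is.na(ctx)) next
      rows[[length(rows) + 1]] <- data.frame(
        patient_id = pd$patient_id[1], context = ctx,
        from_sample = pd$sample_id[i], to_sample = pd$sample_id[i + 1],
        from_state = s[i], to_state = s[i + 1], stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(patient_id = character(), context = character(),
               from_sample = character(), to_sample = character(),
               from_state = character(), to_state = character())
  out <- lapply(c(stable_stable = "stable_stable",
                  stable_exacerbation = "stable_exacerbation"), function(ctx) {
    pp <- pairs[pairs$context == ctx, ]
    counts <- table(factor(pp$from_state, keep), factor(pp$to_state, keep))
    counts <- matrix(counts, 3, 3, dimnames = list(keep, keep))
    tot <- rowSums(counts)
    list(counts = counts,
         persistence = ifelse(tot > 0, diag(counts) / tot, NA_real_),
         n_pairs = nrow(pp))
  })
  structure(c(out, list(pairs = pairs, adjacency = "consecutive")),
            class = "transition_table")
}

#' Odds ratio for a 2x2 table
#'
#' `OR = ad / bc` with the Haldane-Anscombe +0.5 correction applied to all
#' cells when any cell is zero (flagged), a Woolf log-normal 95 % CI, and a
#' two-sided p-value from the log-OR z statistic.
#'
#' @param a,b,c,d cell counts: rows = exposure (yes/no), columns = outcome
#'   (yes/no), `a` = exposed with outcome.
#' @return list of class `odds_ratio`: `counts`, `or`, `ci_low`, `ci_high`,
#'   `corrected`, `p`.
#' @export
odds_ratio_2x2 <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  corrected <- any(counts == 0)
  x <- counts + if (corrected) 0.5 else 0
  or <- (x["a"] * x["d"]) / (x["b"] * x["c"])
  se <- sqrt(sum(1 / x))
  ci <- exp(log(or) + c(-1, 1) * stats::qnorm(0.975) * se)
  z <- log(or) / se
  structure(list(counts = counts, or = unname(or), ci_low = unname(ci[1]),
                 ci_high = unname(ci[2]), corrected = corrected,
                 p = 2 * stats::pnorm(-abs(z))),
            class = "odds_ratio")
}

#' Association of a binary covariate with endotype switches
#'
#' Cross-tabulates a per-pair switch indicator (e.g. neutrophilic <->
#' eosinophilic change between the two visits of a transition pair) against
#' a binary covariate indicator (e.g. the pair spans different meteorological
#' seasons, or the patient uses inhaled corticosteroids at baseline) and
#' returns the [odds_ratio_2x2()].
#'
#' @param switch_indicator logical per pair.
#' @param covariate_indicator logical per pair.
#' @return an `odds_ratio` object.
#' @export
covariate_switch_or <- function(switch_indicator, covariate_indicator) {
  s <- as.logical(switch_indicator); v <- as.logical(covariate_indicator)
  abort_if(length(s) != length(v), "indicators must align")
  ok <- !is.na(s) & !is.na(v)
  s <- s[ok]; v <- v[ok]
  abort_if(length(unique(s)) < 2 || length(unique(v)) < 2,
           "constant indicator: odds ratio undefined")
  odds_ratio_2x2(sum(v & s), sum(v & !s), sum(!v & s), sum(!v & !s))
}
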