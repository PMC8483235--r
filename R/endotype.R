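#' Sputum endotype thresholds
#'
#' The established differential cell-count cutoffs: a sample is eosinophil-
#' high at sputum eosinophils >= 3 % and neutrophil-high at sputum
#' neutrophils >= 61 %.
#'
#' @param eosinophil eosinophil percentage cutoff.
#' @param neutrophil neutrophil percentage cutoff.
#' @return list of class `endotype_thresholds`.
#' @export
endotype_thresholds <- function(eosinophil = 3, neutrophil = 61) {
  abort_if(eosinophil <= 0 || neutrophil <= 0, "thresholds must be positive")
  structure(list(eosinophil = eosinophil, neutrophil = neutrophil),
            class = "endotype_thresholds")
}

endotype_levels <- c("neutrophilic", "eosinophilic", "mixed",
                     "paucigranulocytic", "unassigned")

#' Classify sputum inflammatory endotypes from differential cell counts
#'
#' Applies the two-threshold rule to sputum eosinophil and neutrophil
#' percentages: neutrophilic (eos < 3 %, neu >= 61 %), eosinophilic
#' (eos >= 3 %, neu < 61 %), mixed-granulocytic (both high),
#' paucigranulocytic (both low).  Comparisons are made on the unrounded
#' percentages and the cutoffs are inclusive (`>=`).  A missing percentage
#' yields `"unassigned"`; out-of-range values are an error.
#'
#' @param eosinophil_pct,neutrophil_pct numeric vectors of sputum
#'   percentages in `[0, 100]`; `NA` allowed.
#' @param thresholds an [endotype_thresholds()].
#' @return factor with levels neutrophilic, eosinophilic, mixed,
#'   paucigranulocytic, unassigned.
#' @export
classify_endotype <- function(eosinophil_pct, neutrophil_pct,
                              thresholds = endotype_thresholds()) {
  abort_if(length(eosinophil_pct) != length(neutrophil_pct),
           "percentage vectors must have equal length")
  bad <- function(x) any(x < 0 | x > 100, na.rm = TRUE)
  abort_if(bad(eosinophil_pct) || bad(neutrophil_pct),
           "percentages must lie in [0, 100]")
  eos_hi <- eosinophil_pct >= thresholds$eosinophil
  neu_hi <- neutrophil_pct >= thresholds$neutrophil
  lab <- ifelse(eos_hi & neu_hi, "mixed",
         ifelse(eos_hi, "eosinophilic",
         ifelse(neu_hi, "neutrophilic", "paucigranulocytic")))
  lab[is.na(eosinophil_pct) | is.na(neutrophil_pct)] <- "unassigned"
  factor(lab, levels = endotype_levels)
}

#' Endotype every sample of a cohort dataset
#'
#' @param dataset a [cohort_dataset()] whose metadata carries
#'   `eosinophil_pct` and `neutrophil_pct`.
#' @param thresholds an [endotype_thresholds()].
#' @return data frame `sample_id`, `endotype`.
#' @export
endotype_samples <- function(dataset, thresholds = endotype_thresholds()) {
  md <- dataset$metadata
  abort_if(!all(c("eosinophil_pct", "neutrophil_pct") %in% names(md)),
           "metadata lacks sputum cell percentages")
  data.frame(sample_id = md$sample_id,
             endotype = classify_endotype(md$eosinophil_pct, md$neutrophil_pct,
                                          thresholds),
             stringsAsFactors = FALSE)
}
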