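#' Construct a genus abundance table
#'
#' A genus abundance table is a numeric samples-by-genera matrix with unique
#' sample ids as row names, unique genus names as column names, and a `kind`
#' attribute that is either `"counts"` (non-negative integers) or
#' `"relative"` (rows summing to one).  All pipeline stages consume this
#' representation.
#'
#' @param values numeric matrix, samples in rows, genera in columns.
#' @param kind `"counts"` or `"relative"`; if `NULL`, detected from the
#'   values (all integer-valued entries imply counts).
#' @return the validated matrix with class `genus_table` and a `kind`
#'   attribute.
#' @export
genus_table <- function(values, kind = NULL) {
  values <- as.matrix(values)
  abort_if(!is.numeric(values), "abundance values must be numeric")
  abort_if(anyNA(values), "abundance table contains missing values")
  abort_if(any(values < 0), "abundance table contains negative values")
  abort_if(is.null(rownames(values)), "abundance table needs sample ids as row names")
  abort_if(anyDuplicated(rownames(values)) > 0,
           "duplicate sample ids: ",
           paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  abort_if(is.null(colnames(values)), "abundance table needs genus names as column names")
  abort_if(anyDuplicated(colnames(values)) > 0, "duplicate genus names")
  if (is.null(kind)) {
    kind <- if (all(abs(values - round(values)) < 1e-8)) "counts" else "relative"
  }
  kind <- match.arg(kind, c("counts", "relative"))
  if (kind == "relative") {
    rs <- rowSums(values)
    abort_if(any(abs(rs - 1) > 1e-6),
             "relative abundance rows must sum to 1; offending samples: ",
             paste(utils::head(rownames(values)[abs(rs - 1) > 1e-6], 5), collapse = ", "))
  }
  structure(values, kind = kind, class = c("genus_table", class(values)))
}

#' @export
print.genus_table <- function(x, ...) {
  cat(sprintf("<genus_table> %d samples x %d genera (%s)\n",
              nrow(x), ncol(x), attr(x, "kind")))
  invisible(x)
}

#' Kind of a genus abundance table
#' @param x a [genus_table()].
#' @return `"counts"` or `"relative"`.
#' @export
table_kind <- function(x) attr(x, "kind") %||% "counts"

#' Convert counts to relative abundances
#'
#' Divides every row by its total.  Relative input is returned unchanged
#' (idempotent).  A sample whose row sums to zero cannot be normalized and
#' raises an error naming it.
#'
#' @param table a [genus_table()].
#' @return a relative-abundance `genus_table` (rows sum to one).
#' @export
to_relative <- function(table) {
  abort_if(!inherits(table, "genus_table"), "expected a genus_table")
  if (table_kind(table) == "relative") return(table)
  rs <- rowSums(table)
  abort_if(any(rs <= 0), "zero-total samples cannot be normalized: ",
           paste(rownames(table)[rs <= 0], collapse = ", "))
  genus_table(unclass(table) / rs, kind = "relative")
}

#' Rarefy a count table to fixed sequencing depth
#'
#' Each sample is subsampled without replacement to exactly `depth` reads
#' (random subsampling of individual reads, via [vegan::rrarefy()]).
#' Samples with fewer than `depth` total reads are dropped and listed in the
#' `dropped` attribute of the result.  The same seed always yields the same
#' output.
#'
#' @param table a `genus_table` of kind `"counts"`.
#' @param depth target reads per sample; the discovery and validation arms of
#'   the emulated cohorts used 29117 and 2207 (see [rarefaction_presets]).
#' @param seed integer RNG seed.
#' @return rarefied counts `genus_table`; attribute `dropped` holds ids of
#'   removed samples.
#' @export
rarefy <- function(table, depth, seed = 1L) {
  abort_if(!inherits(table, "genus_table"), "expected a genus_table")
  abort_if(table_kind(table) != "counts", "rarefaction requires a count table")
  abort_if(length(depth) != 1 || depth <= 0, "depth must be a positive scalar")
  totals <- rowSums(table)
  keep <- totals >= depth
  dropped <- rownames(table)[!keep]
  abort_if(!any(keep), "no sample reaches the requested depth")
  kept <- unclass(table)[keep, , drop = FALSE]
  # rrarefy emits an advisory note about count magnitudes; inputs are
  # already validated as integer counts above
  out <- with_seed_if(seed, suppressWarnings(vegan::rrarefy(kept, sample = depth)))
  structure(genus_table(out, kind = "counts"), dropped = dropped)
}

#' Rarefaction depth presets
#'
#' Named depths matching the two sequencing arms the synthetic cohorts
#' emulate: a high-depth Illumina arm (29117 reads) and a shallower 454 arm
#' (2207 reads).  No depth is ever applied silently; pass one explicitly to
#' [rarefy()].
#' @export
rarefaction_presets <- c(discovery = 29117L, validation = 2207L)

metadata_required <- c("sample_id", "patient_id", "visit_index", "visit_type")

validate_metadata <- function(metadata) {
  missing <- setdiff(metadata_required, names(metadata))
  abort_if(length(missing) > 0, "metadata lacks required columns: ",
           paste(missing, collapse = ", "))
  abort_if(anyDuplicated(metadata$sample_id) > 0, "duplicate sample ids in metadata: ",
           paste(unique(metadata$sample_id[duplicated(metadata$sample_id)]), collapse = ", "))
  abort_if(!all(metadata$visit_type %in% c("stable", "exacerbation")),
           "visit_type must be 'stable' or 'exacerbation'")
  for (col in intersect(c("neutrophil_pct", "eosinophil_pct", "lymphocyte_pct",
                          "macrophage_pct", "epithelial_pct"), names(metadata))) {
    v <- metadata[[col]]
    abort_if(any(v < 0 | v > 100, na.rm = TRUE), col, " outside [0, 100]")
  }
  if ("day_offset" %in% names(metadata)) {
    ok <- vapply(split(metadata, metadata$patient_id), function(d) {
      d <- d[order(d$visit_index), ]
      all(diff(d$day_offset) > 0) || nrow(d) < 2
    }, logical(1))
    abort_if(!all(ok), "visit_index must increase with day_offset within patient: ",
             paste(names(ok)[!ok], collapse = ", "))
  }
  invisible(metadata)
}

recount_bookkeeping <- function(abundance, metadata) {
  list(
    n_samples = nrow(abundance),
    n_patients = length(unique(metadata$patient_id)),
    n_stable = sum(metadata$visit_type == "stable"),
    n_exacerbation = sum(metadata$visit_type == "exacerbation")
  )
}

#' Assemble a cohort dataset
#'
#' Binds an abundance table to its per-sample metadata, checks that the two
#' agree sample-for-sample, and records conserved bookkeeping counts
#' (samples, patients, visits per type).  Downstream stages never create or
#' destroy samples, so these counts stay valid through the pipeline.
#'
#' @param abundance a [genus_table()].
#' @param metadata data frame with at least `sample_id`, `patient_id`,
#'   `visit_index`, `visit_type` (`"stable"`/`"exacerbation"`); optional
#'   `day_offset`, sputum cell percentages (`neutrophil_pct`,
#'   `eosinophil_pct`, `lymphocyte_pct`, `macrophage_pct`,
#'   `epithelial_pct`), `mediator_*` columns on the log scale, and
#'   covariates (`age`, `sex`, `bmi`, `smoking`, `ics`, `site`).
#' @return an object of class `cohort_dataset`: list with elements
#'   `abundance`, `metadata` (ordered as the table rows) and `bookkeeping`.
#' @export
cohort_dataset <- function(abundance, metadata) {
  abort_if(!inherits(abundance, "genus_table"), "abundance must be a genus_table")
  metadata <- as.data.frame(metadata)
  validate_metadata(metadata)
  ids <- rownames(abundance)
  only_table <- setdiff(ids, metadata$sample_id)
  abort_if(length(only_table) > 0, "samples missing from metadata: ",
           paste(only_table, collapse = ", "))
  metadata <- metadata[match(ids, metadata$sample_id), , drop = FALSE]
  rownames(metadata) <- NULL
  structure(list(abundance = abundance, metadata = metadata,
                 bookkeeping = recount_bookkeeping(abundance, metadata)),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  b <- x$bookkeeping
  cat(sprintf("<cohort_dataset> %d samples / %d patients (%d stable, %d exacerbation), %d genera\n",
              b$n_samples, b$n_patients, b$n_stable, b$n_exacerbation, ncol(x$abundance)))
  invisible(x)
}

#' Check bookkeeping conservation of a cohort dataset
#'
#' Recomputes sample, patient and per-visit-type counts from the members and
#' compares them with the stored bookkeeping.  The per-type counts must also
#' add up to the total.
#' @param dataset a [cohort_dataset()].
#' @return `TRUE` invisibly; errors on any discrepancy.
#' @export
check_bookkeeping <- function(dataset) {
  b <- dataset$bookkeeping
  r <- recount_bookkeeping(dataset$abundance, dataset$metadata)
  abort_if(!identical(b, r), "bookkeeping counts disagree with members")
  abort_if(b$n_stable + b$n_exacerbation != b$n_samples,
           "per-visit-type counts do not add up to the sample total")
  invisible(TRUE)
}

read_abundance_file <- function(path) {
  if (grepl("\\.biom$", path, ignore.case = TRUE)) {
    abort_if(!requireNamespace("biomformat", quietly = TRUE),
             "reading BIOM files requires the biomformat package")
    b <- biomformat::read_biom(path)
    return(t(as.matrix(biomformat::biom_data(b))))  # biom stores taxa x samples
  }
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  m
}

#' Load a cohort from abundance and metadata files
#'
#' Reads a genus abundance TSV (samples as rows, genera as columns, first
#' column the sample id; BIOM files are also accepted) and a metadata TSV,
#' validates their agreement, and returns a [cohort_dataset()].  A table
#' delivered genera-by-samples is detected by comparing row and column names
#' against the metadata sample ids and transposed with a warning.  The table
#' kind is auto-detected: all-integer values are treated as counts.
#'
#' @param abundance_path path to abundance TSV or BIOM file.
#' @param metadata_path path to metadata TSV (columns as in
#'   [cohort_dataset()]).
#' @return a `cohort_dataset`.
#' @export
load_cohort <- function(abundance_path, metadata_path) {
  abort_if(!file.exists(abundance_path), "abundance file not found: ", abundance_path)
  abort_if(!file.exists(metadata_path), "metadata file not found: ", metadata_path)
  m <- read_abundance_file(abundance_path)
  metadata <- utils::read.delim(metadata_path, check.names = FALSE,
                                stringsAsFactors = FALSE)
  ids <- as.character(metadata$sample_id)
  row_hits <- mean(rownames(m) %in% ids)
  col_hits <- mean(colnames(m) %in% ids)
  if (col_hits > row_hits) {
    warning("abundance table appears transposed (genera as rows); transposing",
            call. = FALSE)
    m <- t(m)
  }
  cohort_dataset(genus_table(m), metadata)
}

#' Write a cohort dataset to a directory
#'
#' Emits `abundance.tsv`, `metadata.tsv` and `bookkeeping.json`.  Numeric
#' abundances are written with 17 significant digits so a write/load round
#' trip reproduces the doubles bit-exactly.
#'
#' @param dataset a [cohort_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ab <- dataset$abundance
  fmt <- if (table_kind(ab) == "counts") function(x) format(x, scientific = FALSE, trim = TRUE)
         else function(x) sprintf("%.17g", x)
  df <- data.frame(sample_id = rownames(ab),
                   apply(unclass(ab), 2, fmt),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, file.path(dir, "abundance.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$metadata, file.path(dir, "metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(dataset$bookkeeping, file.path(dir, "bookkeeping.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
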