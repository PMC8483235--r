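# Small fixtures built in code, plus a lazily generated default synthetic
# cohort shared across test files (generation and community typing are the
# expensive steps, so cache them once per test run).

toy_counts <- function() {
  m <- matrix(c(10, 10, 0,
                5, 5, 10,
                0, 2, 18), nrow = 3, byrow = TRUE,
              dimnames = list(c("S1", "S2", "S3"),
                              c("Haemophilus", "Moraxella", "Rothia")))
  genus_table(m)
}

toy_metadata <- function() {
  data.frame(sample_id = c("S1", "S2", "S3"), patient_id = c("P1", "P1", "P2"),
             visit_index = c(1, 2, 1), day_offset = c(0, 30, 0),
             visit_type = c("stable", "exacerbation", "stable"),
             stringsAsFactors = FALSE)
}

# minimal longitudinal dataset from explicit per-patient visit tables
make_longitudinal <- function(visits, abundance) {
  rownames(abundance) <- visits$sample_id
  cohort_dataset(genus_table(abundance), visits)
}

.shared <- new.env()

shared_cohort <- function(seed = 7, n_patients = 200) {
  key <- sprintf("cohort_%d_%d", seed, n_patients)
  if (is.null(.shared[[key]]))
    .shared[[key]] <- generate_cohort(generator_config(n_patients = n_patients,
                                                       seed = seed))
  .shared[[key]]
}

shared_typing <- function(seed = 7, n_patients = 200) {
  key <- sprintf("typing_%d_%d", seed, n_patients)
  if (is.null(.shared[[key]]))
    .shared[[key]] <- community_typing(shared_cohort(seed, n_patients)$dataset)
  .shared[[key]]
}

# brute-force mean silhouette width straight from the definition
brute_silhouette <- function(labels, dist) {
  d <- as.matrix(dist)
  n <- nrow(d)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(labels == labels[i]), i)
    if (length(own) == 0) { s[i] <- 0; next }
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(cl)
      mean(d[i, labels == cl]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# brute-force distance-based Calinski-Harabasz from the definition
brute_ch <- function(labels, dist) {
  d2 <- as.matrix(dist)^2
  n <- nrow(d2)
  k <- length(unique(labels))
  sst <- 0; ssw <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sst <- sst + d2[i, j] / n
    if (labels[i] == labels[j])
      ssw <- ssw + d2[i, j] / sum(labels == labels[i])
  }
  ((sst - ssw) / (k - 1)) / (ssw / (n - k))
}

# all segmentations of 1..n with minimum segment length, as lists of
# segment start indices (excluding 1)
all_segmentations <- function(n, min_seg) {
  res <- list(integer(0))
  grow <- function(starts) {
    last <- if (length(starts)) starts[length(starts)] else 1L
    from <- last + min_seg
    for (s in seq(from, n - min_seg + 1L, length.out = max(0, n - min_seg + 1L - from + 1L)))
      if (n - s + 1L >= min_seg) {
        st <- c(starts, as.integer(s))
        res[[length(res) + 1L]] <<- st
        grow(st)
      }
  }
  grow(integer(0))
  res
}

seg_objective <- function(x, starts, penalty) {
  bounds <- c(1L, starts, length(x) + 1L)
  cost <- 0
  for (i in seq_len(length(bounds) - 1)) {
    seg <- x[bounds[i]:(bounds[i + 1] - 1L)]
    cost <- cost + sum((seg - mean(seg))^2)
  }
  cost + penalty * length(starts)
}
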