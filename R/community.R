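#' Jensen-Shannon distance between samples
#'
#' Pairwise square-root Jensen-Shannon divergence between the rows of a
#' relative abundance table.  The divergence is computed with base-2
#' logarithms (so it lies in `[0, 1]`) as `H(m) - (H(p) + H(q)) / 2` with
#' `m` the midpoint of the two compositions and `H` the Shannon entropy
#' (with the `0 * log 0 = 0` convention); its square root is a metric.
#'
#' @param table a relative-abundance [genus_table()] (or matrix with rows
#'   summing to one).
#' @return a [stats::dist] object of sqrt-JSD values.
#' @export
jsd_distance <- function(table) {
  x <- unclass(table)
  abort_if(any(x < 0), "negative abundances")
  if (inherits(table, "genus_table"))
    abort_if(table_kind(table) != "relative", "jsd_distance requires relative abundances")
  n <- nrow(x)
  h <- function(m) { # rowwise base-2 entropy
    p <- m
    p[p == 0] <- 1          # 0 log 0 := 0
    -rowSums(m * log2(p))
  }
  hx <- h(x)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    m <- (x[rep(i, length(j)), , drop = FALSE] + x[j, , drop = FALSE]) / 2
    jsd <- h(m) - (hx[i] + hx[j]) / 2
    d[i, j] <- d[j, i] <- sqrt(pmax(jsd, 0))
  }
  dimnames(d) <- list(rownames(x), rownames(x))
  stats::as.dist(d)
}

#' Distance-based Calinski-Harabasz index
#'
#' Pseudo-F ratio of between- to within-cluster dispersion computed purely
#' from a distance matrix: within-cluster sums of squared distances divided
#' by cluster size, between = total minus within.
#'
#' @param dist a [stats::dist].
#' @param labels cluster assignment.
#' @return the CH index (undefined and an error for a single cluster).
#' @export
calinski_harabasz <- function(dist, labels) {
  d2 <- as.matrix(dist)^2
  n <- nrow(d2)
  k <- length(unique(labels))
  abort_if(k < 2, "Calinski-Harabasz index is undefined for a single cluster")
  sst <- sum(d2) / (2 * n)
  ssw <- sum(vapply(split(seq_len(n), labels), function(idx)
    sum(d2[idx, idx]) / (2 * length(idx)), numeric(1)))
  ((sst - ssw) / (k - 1)) / (ssw / (n - k))
}

mean_silhouette <- function(labels, dist) {
  mean(cluster::silhouette(as.integer(factor(labels)), dist)[, "sil_width"])
}

# PAM (build + swap) with seeded random restarts: a single swap descent can
# stall in a local optimum, so the best of the build start and `restarts`
# random starts is kept (judged by the PAM objective).
pam_fit <- function(dist, k, restarts = 5, seed = 1L) {
  best <- cluster::pam(dist, k, diss = TRUE)
  n <- attr(dist, "Size")
  for (i in seq_len(restarts)) {
    start <- with_seed_if(seed + i, sample(n, k))
    fit <- cluster::pam(dist, k, diss = TRUE, medoids = start)
    if (fit$objective["swap"] < best$objective["swap"]) best <- fit
  }
  best
}

#' Discover community types by Ward clustering on Jensen-Shannon distances
#'
#' Builds a Ward-linkage dendrogram on the sqrt-JSD matrix, cuts it at every
#' `k` in `k_range`, scores each cut by its mean silhouette width on the
#' same distances, and keeps the `k` with the largest mean silhouette (ties
#' resolved toward the smaller `k`).
#'
#' @param dist sqrt-JSD distances from [jsd_distance()].
#' @param k_range candidate cluster numbers (default 2..10).
#' @return list of class `community_types`: `cluster` (named integer
#'   vector), `k`, `silhouette` (named mean widths per k), `method`
#'   (`"ward"`), and the `hclust` tree.
#' @export
fit_community_types <- function(dist, k_range = 2:10) {
  n <- attr(dist, "Size")
  abort_if(min(k_range) < 2, "k_range must start at 2 or above")
  abort_if(n < max(k_range) + 1, "need at least max(k_range) + 1 samples")
  abort_if(all(dist == 0), "degenerate distance matrix (all zeros)")
  hc <- stats::hclust(dist, method = "ward.D2")
  sil <- vapply(k_range, function(k) mean_silhouette(stats::cutree(hc, k), dist),
                numeric(1))
  names(sil) <- k_range
  k <- k_range[which.max(sil)]   # which.max takes the first (smallest) maximizer
  structure(list(cluster = stats::cutree(hc, k), k = k, silhouette = sil,
                 method = "ward", tree = hc),
            class = "community_types")
}

#' Validate a community typing with k-medoids
#'
#' Runs partitioning-around-medoids (build + swap, [cluster::pam()]) on the
#' same distance matrix for every `k` in `k_range`, selects the `k`
#' maximizing the distance-based Calinski-Harabasz index, and reports the
#' adjusted Rand agreement with a reference labelling (typically the Ward
#' solution).
#'
#' @param dist distances as in [fit_community_types()].
#' @param k_range candidate cluster numbers (k = 1 has no CH index and is
#'   not searched).
#' @param reference_labels optional labelling to compare against.
#' @return list of class `community_types`: `cluster`, `k`, `ch` (index per
#'   k), `method` (`"pam"`), `ari` (adjusted Rand vs the reference, or
#'   `NA`).
#' @export
validate_with_pam <- function(dist, k_range = 2:10, reference_labels = NULL) {
  n <- attr(dist, "Size")
  abort_if(min(k_range) < 2, "k_range must start at 2 or above")
  abort_if(max(k_range) > n, "k cannot exceed the number of samples")
  fits <- lapply(k_range, function(k) pam_fit(dist, k))
  ch <- vapply(seq_along(k_range), function(i)
    calinski_harabasz(dist, fits[[i]]$clustering), numeric(1))
  names(ch) <- k_range
  best <- which.max(ch)
  labels <- fits[[best]]$clustering
  ari <- if (is.null(reference_labels)) NA_real_ else
    mclust::adjustedRandIndex(labels, reference_labels)
  structure(list(cluster = labels, k = k_range[best], ch = ch,
                 method = "pam", medoids = fits[[best]]$medoids, ari = ari),
            class = "community_types")
}

#' Name community types by genus dominance
#'
#' A cluster whose top mean-abundance genus exceeds the dominance threshold
#' is named `"<Genus>-predominant"`; all others are `"balanced"` (suffixed
#' `balanced-1`, `balanced-2`, ... when several clusters are balanced).
#'
#' @param table relative-abundance [genus_table()] (counts are converted).
#' @param assignment per-sample cluster ids, aligned with (or named by) the
#'   table rows.
#' @param dominance mean-abundance threshold for calling a dominant genus
#'   (default 0.3).
#' @return data frame `sample_id`, `cluster`, `community_type`; the
#'   per-cluster names are in attribute `"cluster_names"`.
#' @export
name_community_types <- function(table, assignment, dominance = 0.3) {
  if (inherits(assignment, "community_types")) assignment <- assignment$cluster
  rel <- if (inherits(table, "genus_table")) to_relative(table)
         else genus_table(table, kind = "relative")
  abort_if(length(assignment) != nrow(rel),
           "assignment must cover every sample of the table")
  ids <- if (is.factor(assignment)) levels(assignment) else sort(unique(assignment))
  sizes <- table(factor(assignment, levels = ids))
  abort_if(any(sizes == 0), "empty cluster in assignment: ",
           paste(ids[sizes == 0], collapse = ", "))
  nm <- vapply(ids, function(cl) {
    mu <- colMeans(unclass(rel)[assignment == cl, , drop = FALSE])
    top <- which.max(mu)
    if (mu[top] > dominance) paste0(names(mu)[top], "-predominant") else "balanced"
  }, character(1))
  bal <- nm == "balanced"
  if (sum(bal) > 1) nm[bal] <- paste0("balanced-", seq_len(sum(bal)))
  names(nm) <- ids
  structure(data.frame(sample_id = rownames(rel), cluster = assignment,
                       community_type = nm[as.character(assignment)],
                       stringsAsFactors = FALSE, row.names = NULL),
            cluster_names = nm)
}

#' Community-type a cohort end to end
#'
#' Convenience pipeline: relative abundances, sqrt-JSD distances, Ward
#' clustering with silhouette-selected `k`, PAM/CH validation, and
#' dominance-based naming.
#'
#' @param dataset a [cohort_dataset()].
#' @param k_range candidate cluster numbers.
#' @param dominance naming threshold, see [name_community_types()].
#' @return list: `assignment` (per-sample data frame with community type),
#'   `ward`, `pam` (the two `community_types` fits), `distance`.
#' @export
community_typing <- function(dataset, k_range = 2:10, dominance = 0.3) {
  rel <- to_relative(dataset$abundance)
  d <- jsd_distance(rel)
  ward <- fit_community_types(d, k_range)
  pam <- validate_with_pam(d, k_range, reference_labels = ward$cluster)
  named <- name_community_types(rel, ward$cluster, dominance)
  list(assignment = named, ward = ward, pam = pam, distance = d)
}

#' ROC biomarker threshold for a one-feature classifier
#'
#' AUC by the midrank Mann-Whitney statistic (ties counted one half), with
#' the optimal cutoff chosen to maximize Youden's J = sensitivity +
#' specificity - 1 over the rule "positive when value >= cutoff"; ties in J
#' resolve to the lower cutoff.
#'
#' @param feature_values numeric feature (higher = more indicative of the
#'   positive class).
#' @param binary_labels logical or 0/1 labels; both classes must occur.
#' @param feature optional feature name carried into the result.
#' @return list of class `biomarker_threshold`: `feature`, `auc`, `cutoff`,
#'   `sensitivity`, `specificity`.
#' @export
biomarker_threshold <- function(feature_values, binary_labels, feature = NULL) {
  lab <- as.logical(binary_labels)
  abort_if(anyNA(lab) || anyNA(feature_values), "missing values not allowed")
  n1 <- sum(lab); n0 <- sum(!lab)
  abort_if(n1 == 0 || n0 == 0, "both classes must be present")
  r <- rank(feature_values)
  auc <- (sum(r[lab]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  cuts <- sort(unique(feature_values))
  j <- vapply(cuts, function(cc)
    mean(feature_values[lab] >= cc) + mean(feature_values[!lab] < cc) - 1,
    numeric(1))
  best <- cuts[which.max(j)]    # first maximizer = lowest cutoff
  structure(list(feature = feature, auc = auc, cutoff = best,
                 sensitivity = mean(feature_values[lab] >= best),
                 specificity = mean(feature_values[!lab] < best)),
            class = "biomarker_threshold")
}
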