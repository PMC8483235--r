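#' @keywords internal
# Solve the SparCC basis system for one variation matrix.
# t[i, j] = var(log(x_i / x_j)); under the sparsity approximation the basis
# variances omega solve M omega = rowSums(t) with M = ones(G) + diag(G - 2).
# Strongly correlated pairs are excluded from the system one at a time
# (most extreme first) and the system re-solved, up to max_rounds times.
sparcc_basis <- function(tmat, exclusion_threshold = 0.1, max_rounds = 10) {
  g <- nrow(tmat)
  m <- matrix(1, g, g)
  diag(m) <- g - 1
  t_work <- tmat
  solve_r <- function() {
    omega <- pmax(solve(m, rowSums(t_work)), 1e-10)
    cv <- (outer(omega, omega, "+") - tmat) / 2
    r <- cv / sqrt(outer(omega, omega))
    pmin(pmax(r, -1), 1)
  }
  r <- solve_r()
  excluded <- matrix(FALSE, g, g)
  for (round in seq_len(max_rounds)) {
    cand <- abs(r)
    diag(cand) <- 0
    cand[excluded] <- 0
    mx <- max(cand)
    if (mx <= exclusion_threshold) break
    ij <- which(cand == mx, arr.ind = TRUE)[1, ]
    i <- ij[1]; j <- ij[2]
    excluded[i, j] <- excluded[j, i] <- TRUE
    m[i, i] <- m[i, i] - 1
    m[j, j] <- m[j, j] - 1
    m[i, j] <- m[j, i] <- 0
    t_work[i, j] <- t_work[j, i] <- 0
    if (any(diag(m) < 2)) break   # system no longer solvable for a component
    r <- solve_r()
  }
  dimnames(r) <- dimnames(tmat)
  r
}

#' SparCC compositional correlation
#'
#' Estimates basis (absolute-abundance) correlations from compositional
#' count data.  Per estimation iteration, underlying fractions are drawn
#' from the Dirichlet posterior of each sample (pseudo-count 1), the
#' variation matrix `t_ij = var(log(x_i / x_j))` is computed, the basis
#' variances are solved from the sparse linear approximation, and strongly
#' correlated pairs (|r| above the exclusion threshold, most extreme first)
#' are iteratively excluded from the basis system.  The reported
#' correlation is the elementwise median across iterations, clipped to
#' `[-1, 1]`.
#'
#' @param table counts [genus_table()] or matrix (samples x genera, at
#'   least 4 genera).  Relative input is converted to pseudo-counts at a
#'   nominal depth with a warning.
#' @param n_est_iter estimation iterations (default 20).
#' @param exclusion_threshold correlation magnitude above which a pair is
#'   excluded from the basis system (default 0.1).
#' @param max_exclusion_rounds exclusion iterations per estimation
#'   (default 10).
#' @param seed RNG seed for the posterior draws.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
sparcc <- function(table, n_est_iter = 20, exclusion_threshold = 0.1,
                   max_exclusion_rounds = 10, seed = 1L) {
  x <- unclass(table)
  if (inherits(table, "genus_table") && table_kind(table) == "relative" ||
      max(rowSums(x)) <= 1 + 1e-6) {
    warning("relative input: converting to pseudo-counts at nominal depth 10000",
            call. = FALSE)
    x <- round(x * 10000)
  }
  abort_if(ncol(x) < 4, "SparCC needs at least 4 genera")
  zero <- colSums(x) == 0
  abort_if(any(zero), "all-zero genera: ",
           paste(colnames(x)[zero], collapse = ", "))
  g <- ncol(x)
  with_seed_if(seed, {
    rs <- array(NA_real_, c(g, g, n_est_iter))
    for (it in seq_len(n_est_iter)) {
      gm <- matrix(stats::rgamma(length(x), shape = x + 1), nrow(x), g)
      fr <- gm / rowSums(gm)
      l <- log(fr)
      v <- stats::cov(l)
      tmat <- outer(diag(v), diag(v), "+") - 2 * v
      rs[, , it] <- sparcc_basis(tmat, exclusion_threshold, max_exclusion_rounds)
    }
    r <- apply(rs, c(1, 2), stats::median)
    r <- (r + t(r)) / 2
    diag(r) <- 1
    dimnames(r) <- list(colnames(x), colnames(x))
    r
  })
}

#' Permutation significance of SparCC correlations
#'
#' Builds per-pair null correlation distributions by permuting each genus
#' column independently and re-running SparCC on every permuted table.
#' Two-sided p-values are `(1 + #|r_null| >= |r_obs|) / (B + 1)` per pair,
#' BH-adjusted across all pairs.
#'
#' @param table the count table that produced `observed_r`.
#' @param observed_r correlation matrix from [sparcc()].
#' @param B number of permutations (a warning is issued below 20, where
#'   the attainable resolution `1 / (B + 1)` is coarse).
#' @param seed RNG seed.
#' @param ... passed on to [sparcc()] (iteration/exclusion settings).
#' @return list: `p` and `q` matrices aligned with `observed_r`.
#' @export
edge_significance <- function(table, observed_r, B = 100, seed = 1L, ...) {
  if (B < 20) warning("B < 20: p-value resolution is only 1/(B+1)", call. = FALSE)
  x <- unclass(table)
  g <- ncol(x)
  exceed <- matrix(0, g, g)
  with_seed_if(seed, {
    for (b in seq_len(B)) {
      xp <- apply(x, 2, sample)
      rn <- suppressWarnings(sparcc(xp, seed = NULL, ...))
      exceed <- exceed + (abs(rn) >= abs(observed_r))
    }
  })
  p <- (1 + exceed) / (B + 1)
  diag(p) <- NA
  ut <- upper.tri(p)
  q <- p
  q[ut] <- stats::p.adjust(p[ut], "BH")
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  dimnames(p) <- dimnames(q) <- dimnames(observed_r)
  list(p = p, q = q)
}

#' Build a co-occurrence network from significant correlations
#'
#' Retains edges with `q < q_threshold`, caps them at the `top_k` largest
#' |r| separately for positive (co-occurrence) and negative (co-exclusion)
#' signs, and assigns modules by Louvain community detection on the
#' |r|-weighted graph at the given resolution.  Louvain is order-dependent,
#' so it is run with 10 seeded restarts and the partition with the best
#' modularity is kept.
#'
#' @param correlations symmetric correlation matrix.
#' @param q matching BH-adjusted significance matrix.
#' @param q_threshold edge retention threshold (default 0.05).
#' @param top_k edges kept per sign (default 100).
#' @param louvain_resolution Louvain resolution parameter (default 1.0).
#' @param seed RNG seed for the restarts.
#' @return list of class `cooccurrence_network`: `nodes` (genus, degree,
#'   module), `edges` (genus1, genus2, r, q, sign).
#' @export
build_network <- function(correlations, q, q_threshold = 0.05, top_k = 100,
                          louvain_resolution = 1.0, seed = 1L) {
  abort_if(!all(dim(correlations) == dim(q)), "correlations and q must align")
  if (is.null(rownames(correlations)))
    rownames(correlations) <- colnames(correlations) <-
      paste0("V", seq_len(nrow(correlations)))
  ut <- which(upper.tri(correlations), arr.ind = TRUE)
  ed <- data.frame(genus1 = rownames(correlations)[ut[, 1]],
                   genus2 = colnames(correlations)[ut[, 2]],
                   r = correlations[ut], q = q[ut],
                   stringsAsFactors = FALSE)
  ed <- ed[!is.na(ed$q) & ed$q < q_threshold, ]
  if (nrow(ed) == 0) {
    warning("no significant edges: empty network", call. = FALSE)
    return(structure(list(nodes = data.frame(), edges = data.frame()),
                     class = "cooccurrence_network"))
  }
  keep_top <- function(e, k) e[order(-abs(e$r)), ][seq_len(min(k, nrow(e))), ]
  ed <- rbind(keep_top(ed[ed$r > 0, ], top_k), keep_top(ed[ed$r <= 0, ], top_k))
  ed <- ed[!is.na(ed$r), ]
  ed$sign <- ifelse(ed$r > 0, "cooccurrence", "coexclusion")
  gr <- igraph::graph_from_data_frame(ed[, c("genus1", "genus2")],
                                      directed = FALSE)
  igraph::E(gr)$weight <- abs(ed$r)
  best <- NULL; best_mod <- -Inf
  for (i in 1:10) {
    cm <- with_seed_if(seed + i,
      igraph::cluster_louvain(gr, resolution = louvain_resolution))
    if (igraph::modularity(cm) > best_mod) {
      best_mod <- igraph::modularity(cm)
      best <- cm
    }
  }
  nodes <- data.frame(genus = igraph::V(gr)$name,
                      degree = igraph::degree(gr),
                      module = igraph::membership(best),
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = ed, modularity = best_mod),
            class = "cooccurrence_network")
}

#' Residualize features against demographic covariates
#'
#' Regresses each feature (genus abundance or mediator) on the supplied
#' covariates with a per-patient random intercept and returns the
#' residuals, removing demographic and repeated-measures structure before
#' correlation analysis.  With no covariates and no patient ids the
#' residuals are simply the centered values.
#'
#' @param mat numeric samples x features matrix.
#' @param covariates data frame of covariates (may be `NULL`/empty); must
#'   be complete for the included samples.
#' @param patient_ids optional patient identifier per sample, enabling the
#'   random intercept.
#' @return residual matrix of the same shape.
#' @export
residualize_features <- function(mat, covariates = NULL, patient_ids = NULL) {
  mat <- as.matrix(mat)
  has_cov <- !is.null(covariates) && ncol(as.data.frame(covariates)) > 0
  if (has_cov) {
    covariates <- as.data.frame(covariates)
    abort_if(anyNA(covariates), "covariates must be complete")
    mm <- stats::model.matrix(~., covariates)
    abort_if(qr(mm)$rank < ncol(mm), "rank-deficient covariates")
  }
  if (!has_cov && is.null(patient_ids))
    return(scale(mat, center = TRUE, scale = FALSE))
  out <- mat
  for (j in seq_len(ncol(mat))) {
    df <- data.frame(y = mat[, j])
    rhs <- "1"
    if (has_cov) {
      df <- cbind(df, covariates)
      rhs <- paste(colnames(covariates), collapse = " + ")
    }
    if (is.null(patient_ids)) {
      fit <- stats::lm(stats::as.formula(paste("y ~", rhs)), df)
      out[, j] <- stats::resid(fit)
    } else {
      df$patient <- patient_ids
      fit <- lme4::lmer(stats::as.formula(paste("y ~", rhs, "+ (1 | patient)")),
                        df, REML = TRUE,
                        control = lme4::lmerControl(check.conv.singular = "ignore"))
      out[, j] <- stats::resid(fit)
    }
  }
  out
}

#' All-against-all genus-mediator correlation
#'
#' Spearman correlation for every genus-mediator pair of residualized
#' matrices, BH-adjusted across all pairs, with the retained sets capped at
#' `top_k` per sign among pairs passing `q < q_threshold`.
#'
#' @param residual_genera,residual_mediators row-aligned residual matrices
#'   (see [residualize_features()]).
#' @param q_threshold retention threshold on BH q (default 0.1).
#' @param top_k retained correlations per sign (default 20).
#' @return list of class `mediator_correlation`: `r`, `p`, `q` matrices
#'   (genus x mediator) and `retained` (data frame genus, mediator, r, q,
#'   sign).
#' @export
feature_mediator_corr <- function(residual_genera, residual_mediators,
                                  q_threshold = 0.1, top_k = 20) {
  gx <- as.matrix(residual_genera); mx <- as.matrix(residual_mediators)
  abort_if(nrow(gx) != nrow(mx), "matrices must be row-aligned by sample")
  ng <- ncol(gx); nm <- ncol(mx)
  r <- p <- matrix(NA_real_, ng, nm,
                   dimnames = list(colnames(gx), colnames(mx)))
  for (i in seq_len(ng)) for (j in seq_len(nm)) {
    ok <- stats::complete.cases(gx[, i], mx[, j])
    if (sum(ok) < 3) {
      warning("fewer than 3 complete pairs for ", colnames(gx)[i], " x ",
              colnames(mx)[j], "; skipped", call. = FALSE)
      next
    }
    ct <- suppressWarnings(stats::cor.test(gx[ok, i], mx[ok, j],
                                           method = "spearman", exact = FALSE))
    r[i, j] <- unname(ct$estimate)
    p[i, j] <- ct$p.value
  }
  q <- p
  q[] <- stats::p.adjust(p, "BH")
  idx <- which(!is.na(q) & q < q_threshold, arr.ind = TRUE)
  retained <- data.frame(genus = rownames(r)[idx[, 1]],
                         mediator = colnames(r)[idx[, 2]],
                         r = r[idx], q = q[idx], stringsAsFactors = FALSE)
  if (nrow(retained) > 0) {
    retained$sign <- ifelse(retained$r > 0, "positive", "negative")
    keep <- function(e, k) e[order(-abs(e$r)), ][seq_len(min(k, nrow(e))), ]
    retained <- rbind(keep(retained[retained$sign == "positive", ], top_k),
                      keep(retained[retained$sign == "negative", ], top_k))
    retained <- retained[!is.na(retained$r), ]
    rownames(retained) <- NULL
  }
  structure(list(r = r, p = p, q = q, retained = retained),
            class = "mediator_correlation")
}
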