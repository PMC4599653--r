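#' First-order partial Spearman correlation
#'
#' Ranks x, y and z, then removes the covariate's contribution with the
#' first-order recursion on the rank-scale Pearson correlations:
#' `r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`.
#' A constant (or `NULL`) covariate falls back to plain Spearman with a
#' warning.
#'
#' @param x,y Numeric vectors of equal length >= 4; must be non-constant.
#' @param z Covariate vector of the same length, or `NULL`.
#' @return Partial Spearman coefficient in `[-1, 1]`.
#' @export
partial_spearman <- function(x, y, z = NULL) {
  n <- length(x)
  if (n < 4L || length(y) != n || (!is.null(z) && length(z) != n))
    stop("x, y (and z) must share a length >= 4")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("x and y must be non-constant")
  rx <- rank(x); ry <- rank(y)
  if (is.null(z) || stats::sd(z) == 0) {
    if (!is.null(z)) warning("constant covariate; falling back to plain Spearman")
    return(stats::cor(rx, ry))
  }
  rz <- rank(z)
  r_xy <- stats::cor(rx, ry)
  r_xz <- stats::cor(rx, rz)
  r_yz <- stats::cor(ry, rz)
  if (abs(r_xz) >= 1 - 1e-12 || abs(r_yz) >= 1 - 1e-12)
    stop("degenerate conditioning: covariate is rank-identical to x or y")
  out <- (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
  max(-1, min(1, out))
}

#' Pairwise disease similarity from pathway-level vectors
#'
#' For each unordered disease pair the partial Spearman correlation of
#' their pathway vectors is computed given a background covariate:
#' `"loo-mean"` (default) conditions on the element-wise mean pathway
#' vector over all *other* diseases, `"global-mean"` on the mean over all
#' diseases, `"none"` uses plain Spearman.
#'
#' @param dc_matrix Numeric matrix, pathways x diseases, as produced by
#'   [pathway_dc_matrix()].
#' @param covariate_mode One of `"loo-mean"`, `"global-mean"`, `"none"`.
#' @return Object of class `SimilarityMatrix`: list with `diseases`,
#'   symmetric `rho` (diagonal `NA`), and `covariate_mode`.
#' @export
similarity_matrix <- function(dc_matrix,
                              covariate_mode = c("loo-mean", "global-mean", "none")) {
  covariate_mode <- match.arg(covariate_mode)
  if (!is.matrix(dc_matrix) || ncol(dc_matrix) < 3L)
    stop("dc_matrix must be a pathways x diseases matrix with >= 3 diseases")
  diseases <- colnames(dc_matrix)
  if (is.null(diseases)) stop("dc_matrix must carry disease column names")
  nd <- ncol(dc_matrix)
  rho <- matrix(NA_real_, nd, nd, dimnames = list(diseases, diseases))
  global_mean <- rowMeans(dc_matrix)
  for (i in seq_len(nd - 1L)) {
    for (j in seq(i + 1L, nd)) {
      z <- switch(covariate_mode,
                  "loo-mean" = rowMeans(dc_matrix[, -c(i, j), drop = FALSE]),
                  "global-mean" = global_mean,
                  "none" = NULL)
      r <- partial_spearman(dc_matrix[, i], dc_matrix[, j], z)
      rho[i, j] <- rho[j, i] <- r
    }
  }
  structure(list(diseases = diseases, rho = rho,
                 covariate_mode = covariate_mode),
            class = "SimilarityMatrix")
}

#' Degree-preserving permutation of gene-to-pathway membership
#'
#' Randomizes the bipartite gene/pathway membership structure by repeated
#' checkerboard (2x2) swaps: two membership edges (g1, p1), (g2, p2) with
#' g1 != g2, p1 != p2 and both cross memberships absent are rewired to
#' (g1, p2), (g2, p1). This preserves exactly (1) the number of pathways
#' each gene belongs to, (2) every pathway's size, and (3) the number of
#' pathways. Swap attempts default to 10x the number of memberships.
#'
#' @param pathways A `PathwayCollection` with >= 2 pathways.
#' @param seed Optional seed; when `NULL` the ambient RNG stream is used.
#' @param nswap_factor Attempted swaps per membership edge (default 10).
#' @return A permuted `PathwayCollection` with identical margins.
#' @export
permute_pathway_membership <- function(pathways, seed = NULL, nswap_factor = 10) {
  stopifnot(inherits(pathways, "PathwayCollection"))
  if (length(pathways$sets) < 2L) stop("need >= 2 pathways to permute")
  run <- function() {
    pw_ids <- names(pathways$sets)
    genes <- pathway_universe(pathways)
    gi <- stats::setNames(seq_along(genes), genes)
    eg <- unlist(lapply(pathways$sets, function(s) gi[s]), use.names = FALSE)
    ep <- rep(seq_along(pw_ids), lengths(pathways$sets))
    m <- length(eg)
    inc <- matrix(FALSE, length(genes), length(pw_ids))
    inc[cbind(eg, ep)] <- TRUE
    n_att <- ceiling(nswap_factor * m)
    picks <- matrix(sample.int(m, 2L * n_att, replace = TRUE), ncol = 2L)
    for (t in seq_len(n_att)) {
      i <- picks[t, 1L]; j <- picks[t, 2L]
      g1 <- eg[i]; p1 <- ep[i]; g2 <- eg[j]; p2 <- ep[j]
      if (g1 == g2 || p1 == p2) next
      if (inc[g1, p2] || inc[g2, p1]) next
      inc[g1, p1] <- FALSE; inc[g2, p2] <- FALSE
      inc[g1, p2] <- TRUE;  inc[g2, p1] <- TRUE
      ep[i] <- p2; ep[j] <- p1
    }
    sets <- split(genes[eg], factor(ep, levels = seq_along(pw_ids)))
    names(sets) <- pw_ids
    pathway_collection(lapply(sets, sort),
                       provenance = paste0(pathways$provenance, " (permuted)"))
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Permutation null distribution of disease similarities
#'
#' Each repetition draws one pseudo pathway collection by membership
#' permutation, rebuilds the pathway-level vectors for every disease from
#' the *observed* per-gene profiles, and recomputes the full similarity
#' matrix, yielding per-pair null coefficient vectors.
#'
#' @param profiles Named list (disease id -> `DCProfile` or named numeric
#'   vector of per-gene values).
#' @param pathways The observed `PathwayCollection`.
#' @param reps Number of permutations (>= 100 unless `force = TRUE`;
#'   500 is the conventional depth).
#' @param seed Seed for the permutation stream.
#' @param covariate_mode Passed to [similarity_matrix()].
#' @param min_genes Passed to [pathway_dc_matrix()].
#' @param force Allow `reps < 100` with a warning (for smoke tests).
#' @return Object of class `NullDistribution`: list with `reps`, `pairs`
#'   (2-column character matrix), `null` (pairs x reps matrix), `seed`.
#' @export
null_distribution <- function(profiles, pathways, reps = 500L, seed = 1L,
                              covariate_mode = "loo-mean", min_genes = 1L,
                              force = FALSE) {
  if (reps < 100L) {
    if (!force) stop("reps must be >= 100 (use force = TRUE to override)")
    warning("running with reps < 100; p-values will be coarse")
  }
  diseases <- names(profiles)
  pair_idx <- which(upper.tri(diag(length(diseases))), arr.ind = TRUE)
  pairs <- cbind(diseases[pair_idx[, 1]], diseases[pair_idx[, 2]])
  null <- matrix(NA_real_, nrow(pairs), reps)
  with_seed(seed, {
    for (r in seq_len(reps)) {
      pseudo <- permute_pathway_membership(pathways)
      mat <- pathway_dc_matrix(profiles, pseudo, min_genes = min_genes)
      sim <- similarity_matrix(mat, covariate_mode = covariate_mode)
      null[, r] <- sim$rho[pair_idx]
    }
  })
  structure(list(reps = reps, pairs = pairs, null = null, seed = seed,
                 covariate_mode = covariate_mode),
            class = "NullDistribution")
}

#' Empirical p-values against the permutation null
#'
#' Two-sided on magnitude with +1 smoothing:
#' `p = (1 + #{|rho_null| >= |rho_obs|}) / (reps + 1)` per disease pair,
#' so both strongly positive and strongly negative similarities can be
#' significant; the sign is kept on the network edge.
#'
#' @param observed A `SimilarityMatrix`.
#' @param null A `NullDistribution` covering every observed pair.
#' @return Data frame with columns `disease_a`, `disease_b`, `rho`, `p`.
#' @export
empirical_pvalues <- function(observed, null) {
  stopifnot(inherits(observed, "SimilarityMatrix"),
            inherits(null, "NullDistribution"))
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  null_key <- key(null$pairs[, 1], null$pairs[, 2])
  diseases <- observed$diseases
  pair_idx <- which(upper.tri(diag(length(diseases))), arr.ind = TRUE)
  a <- diseases[pair_idx[, 1]]; b <- diseases[pair_idx[, 2]]
  row_of <- match(key(a, b), null_key)
  if (anyNA(row_of)) stop("null distribution is missing observed pair(s)")
  rho <- observed$rho[pair_idx]
  p <- vapply(seq_along(rho), function(k) {
    (1 + sum(abs(null$null[row_of[k], ]) >= abs(rho[k]))) / (null$reps + 1)
  }, numeric(1))
  flip <- a > b
  tmp <- a[flip]; a[flip] <- b[flip]; b[flip] <- tmp
  out <- data.frame(disease_a = a, disease_b = b, rho = rho, p = p,
                    stringsAsFactors = FALSE)
  out <- out[order(out$disease_a, out$disease_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment; a validated front for
#' `stats::p.adjust(method = "BH")`.
#'
#' @param pvals Numeric vector of p-values in (0, 1].
#' @return Vector of q-values, monotone non-decreasing in p.
#' @export
bh_fdr <- function(pvals) {
  if (!length(pvals)) return(numeric(0))
  if (any(!is.finite(pvals)) || any(pvals <= 0 | pvals > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Build the disease-disease link network
#'
#' Pairs with `p < p_threshold` become signed weighted edges carrying
#' `rho`, `p` and `q`; the overall FDR summary is the largest BH q-value
#' among the included edges (the estimated false-discovery rate at the
#' chosen cutoff).
#'
#' @param pair_stats Data frame from [empirical_pvalues()] (columns
#'   `disease_a`, `disease_b`, `rho`, `p`).
#' @param p_threshold Inclusion threshold on the empirical p (default
#'   0.05).
#' @param nodes Optional full node set; defaults to all diseases in
#'   `pair_stats`.
#' @return A `DiseaseNetwork` with attribute `fdr` (NA when no edges).
#' @export
build_network <- function(pair_stats, p_threshold = 0.05, nodes = NULL) {
  need <- c("disease_a", "disease_b", "rho", "p")
  if (!all(need %in% names(pair_stats)))
    stop("pair_stats must have columns: ", paste(need, collapse = ", "))
  if (is.null(nodes))
    nodes <- sort(unique(c(pair_stats$disease_a, pair_stats$disease_b)))
  pair_stats$q <- bh_fdr(pair_stats$p)
  keep <- pair_stats$p < p_threshold
  net <- disease_network(nodes, pair_stats[keep, , drop = FALSE],
                         p_threshold = p_threshold)
  attr(net, "fdr") <- if (any(keep)) max(net$edges$q) else NA_real_
  net
}
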