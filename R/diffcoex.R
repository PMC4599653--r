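#' Condition-wise Pearson correlation matrix
#'
#' Correlations are computed over the samples of one condition only.
#' Zero-variance genes cannot be correlated; their rows and columns are
#' set to 0 (diagonal kept at 1) and the genes are flagged with a warning.
#'
#' @param dataset An `ExpressionDataset`.
#' @param condition `"disease"` or `"normal"`.
#' @return Symmetric correlation matrix with unit diagonal; attribute
#'   `flagged` lists zero-variance genes.
#' @export
pairwise_correlation <- function(dataset, condition = c("disease", "normal")) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  condition <- match.arg(condition)
  m <- dataset$values[, dataset$condition == condition, drop = FALSE]
  if (ncol(m) < 3L)
    stop(sprintf("condition '%s' has %d samples; >= 3 required", condition, ncol(m)))
  sds <- apply(m, 1, stats::sd)
  flagged <- rownames(m)[sds == 0]
  r <- suppressWarnings(stats::cor(t(m), method = "pearson"))
  if (length(flagged)) {
    warning("zero-variance gene(s) in condition '", condition, "': ",
            paste(flagged, collapse = ", "))
    r[flagged, ] <- 0
    r[, flagged] <- 0
  }
  diag(r) <- 1
  # clamp numerical overshoot
  r[r > 1] <- 1
  r[r < -1] <- -1
  attr(r, "flagged") <- flagged
  r
}

#' Disease/normal coexpression matrices for one dataset
#'
#' @param dataset An `ExpressionDataset`.
#' @return An object of class `CoexpressionPair` holding both symmetric
#'   Pearson matrices in a shared gene order plus the union of
#'   zero-variance flags.
#' @export
coexpression_pair <- function(dataset) {
  rd <- pairwise_correlation(dataset, "disease")
  rn <- pairwise_correlation(dataset, "normal")
  structure(list(gene_ids = rownames(rd), R_disease = rd, R_normal = rn,
                 flagged = union(attr(rd, "flagged"), attr(rn, "flagged"))),
            class = "CoexpressionPair")
}

#' Percentile-based neighbor sets
#'
#' A gene j qualifies as a neighbor of gene i in one condition when
#' `|r_ij|` lies in the top `1 - q` fraction of that condition's
#' off-diagonal `|r|` values; the final neighbor set is the union across
#' the two conditions, so the correlation vectors X (disease) and Y
#' (normal) are read over one common, identically ordered set.
#'
#' @param coex A `CoexpressionPair`.
#' @param q Percentile threshold in (0, 1); default 0.75.
#' @return Named list of character vectors (gene -> neighbors, in gene
#'   order). Genes may have empty sets; downstream profile construction
#'   drops them with a warning.
#' @export
neighbor_sets <- function(coex, q = 0.75) {
  stopifnot(inherits(coex, "CoexpressionPair"))
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q >= 1)
    stop("q must lie in (0, 1)")
  qualify <- function(r) {
    a <- abs(r)
    diag(a) <- NA
    thr <- stats::quantile(a[upper.tri(a)], probs = q, names = FALSE)
    ok <- !is.na(a) & a >= thr
    ok
  }
  ok <- qualify(coex$R_disease) | qualify(coex$R_normal)
  genes <- coex$gene_ids
  out <- lapply(seq_along(genes), function(i) genes[ok[i, ]])
  names(out) <- genes
  out
}

#' Per-gene differential coexpression (dC)
#'
#' For gene i with neighbor set of size n, let X and Y be its Pearson
#' correlations to those neighbors in the disease and normal condition.
#' Then `dC_i = sqrt( sum_k (x_ik - y_ik)^2 / n )`: the root-mean-square
#' change of the gene's coexpression profile, equivalently the Euclidean
#' distance between X and Y divided by `sqrt(n)`. It is bounded in
#' `[0, 2]` and zero iff the profiles agree exactly.
#'
#' @param coex A `CoexpressionPair`.
#' @param neighbors Per-gene neighbor sets (see [neighbor_sets()]).
#' @return An object of class `DCProfile`: data frame with columns `gene`,
#'   `n` (neighbor count) and `dC`, plus the neighbor sets as an
#'   attribute. Genes flagged as zero-variance or with empty neighbor sets
#'   are excluded (with a warning for the latter).
#' @export
compute_dC <- function(coex, neighbors) {
  stopifnot(inherits(coex, "CoexpressionPair"))
  genes <- intersect(coex$gene_ids, names(neighbors))
  empty <- genes[lengths(neighbors[genes]) == 0L]
  if (length(empty))
    warning("gene(s) with empty neighbor sets excluded: ",
            paste(utils::head(empty, 5), collapse = ", "),
            if (length(empty) > 5) ", ...")
  keep <- setdiff(genes, union(empty, coex$flagged))
  dC <- vapply(keep, function(g) {
    nb <- neighbors[[g]]
    if (!all(nb %in% coex$gene_ids)) stop("neighbor(s) of ", g, " not in matrices")
    x <- coex$R_disease[g, nb]
    y <- coex$R_normal[g, nb]
    sqrt(mean((x - y)^2))
  }, numeric(1))
  out <- data.frame(gene = keep, n = lengths(neighbors[keep]), dC = unname(dC),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "neighbors") <- neighbors[keep]
  class(out) <- c("DCProfile", "data.frame")
  out
}

#' Full dC profile of one dataset
#'
#' Convenience chain: [coexpression_pair()] -> [neighbor_sets()] ->
#' [compute_dC()].
#'
#' @param dataset An `ExpressionDataset`.
#' @param q Neighbor percentile threshold, see [neighbor_sets()].
#' @return A `DCProfile`.
#' @export
dc_profile <- function(dataset, q = 0.75) {
  coex <- coexpression_pair(dataset)
  compute_dC(coex, neighbor_sets(coex, q = q))
}

#' Permutation significance of dC (DCG calling)
#'
#' Sample-condition labels are permuted `reps` times; the condition-wise
#' correlations are recomputed under each permutation over the observed
#' neighbor sets, giving a per-gene null dC distribution. The empirical
#' p-value uses +1 smoothing: `p_i = (1 + #{null >= observed}) / (reps + 1)`.
#' Genes with `p < alpha` are the differentially coexpressed genes (DCGs).
#'
#' @param dataset An `ExpressionDataset`.
#' @param q Neighbor percentile threshold.
#' @param reps Number of label permutations (>= 100).
#' @param seed Seed for the permutation stream.
#' @param alpha DCG calling threshold on the permutation p (default 0.05).
#' @return A `DCProfile` with extra columns `p` and `dcg` (logical).
#' @export
dcg_significance <- function(dataset, q = 0.75, reps = 1000L, seed = 1L,
                             alpha = 0.05) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  if (reps < 100L) stop("reps must be >= 100")
  coex <- coexpression_pair(dataset)
  nb <- neighbor_sets(coex, q = q)
  obs <- compute_dC(coex, nb)
  nb_kept <- attr(obs, "neighbors")
  cond <- dataset$condition
  values <- dataset$values
  obs_dc <- stats::setNames(obs$dC, obs$gene)
  exceed <- stats::setNames(numeric(nrow(obs)), obs$gene)
  with_seed(seed, {
    for (r in seq_len(reps)) {
      perm <- sample(cond)
      pd <- suppressWarnings(stats::cor(t(values[, perm == "disease", drop = FALSE])))
      pn <- suppressWarnings(stats::cor(t(values[, perm == "normal", drop = FALSE])))
      pd[is.na(pd)] <- 0; pn[is.na(pn)] <- 0
      null_dc <- vapply(obs$gene, function(g) {
        nbg <- nb_kept[[g]]
        sqrt(mean((pd[g, nbg] - pn[g, nbg])^2))
      }, numeric(1))
      exceed <- exceed + (null_dc >= obs_dc)
    }
  })
  obs$p <- (1 + unname(exceed[obs$gene])) / (reps + 1)
  obs$dcg <- obs$p < alpha
  obs
}

#' Identify differentially coexpressed links (DCLs)
#'
#' A gene pair is a DCL when at least one condition shows a qualified
#' correlation (`max(|r_disease|, |r_normal|) >= rc`) and the correlation
#' change is large (`|r_disease - r_normal| >= dr`). Classes:
#' `reversal` when both correlations qualify with opposite signs; `gain`
#' when only the disease correlation qualifies; `loss` when only the
#' normal correlation qualifies. (Pairs qualified in both conditions with
#' the same sign — possible only for small `dr` — are labelled by which
#' condition is stronger.)
#'
#' @param coex A `CoexpressionPair`.
#' @param rc Qualification threshold on |r|, in (0, 1]; default 0.6.
#' @param dr Change threshold on |r_disease - r_normal|, in (0, 2);
#'   default 0.8.
#' @return Data frame with columns `gene_a`, `gene_b`, `r_disease`,
#'   `r_normal`, `delta`, `class`, lexicographically ordered pairs.
#' @export
identify_dcls <- function(coex, rc = 0.6, dr = 0.8) {
  stopifnot(inherits(coex, "CoexpressionPair"))
  if (rc <= 0 || rc > 1) stop("rc must lie in (0, 1]")
  if (dr <= 0 || dr >= 2) stop("dr must lie in (0, 2)")
  genes <- coex$gene_ids
  ut <- which(upper.tri(coex$R_disease), arr.ind = TRUE)
  rd <- coex$R_disease[ut]
  rn <- coex$R_normal[ut]
  delta <- abs(rd - rn)
  qual_d <- abs(rd) >= rc
  qual_n <- abs(rn) >= rc
  is_dcl <- (qual_d | qual_n) & delta >= dr
  idx <- which(is_dcl)
  cls <- character(length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    if (qual_d[i] && qual_n[i]) {
      cls[k] <- if (sign(rd[i]) != sign(rn[i])) "reversal"
                else if (abs(rd[i]) > abs(rn[i])) "gain" else "loss"
    } else if (qual_d[i]) cls[k] <- "gain" else cls[k] <- "loss"
  }
  a <- genes[ut[idx, 1]]
  b <- genes[ut[idx, 2]]
  flip <- a > b
  tmp <- a[flip]; a[flip] <- b[flip]; b[flip] <- tmp
  out <- data.frame(gene_a = a, gene_b = b, r_disease = rd[idx],
                    r_normal = rn[idx], delta = delta[idx], class = cls,
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-gene log2 fold change between conditions
#'
#' The differential-expression baseline statistic: `log2` of the ratio of
#' mean disease intensity to mean normal intensity, on the linear scale.
#'
#' @param dataset An `ExpressionDataset` with strictly positive condition
#'   means for every gene.
#' @return Named numeric vector of log2 fold changes.
#' @export
log_fold_change <- function(dataset) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  md <- rowMeans(dataset$values[, dataset$condition == "disease", drop = FALSE])
  mn <- rowMeans(dataset$values[, dataset$condition == "normal", drop = FALSE])
  bad <- names(md)[md <= 0 | mn <= 0]
  if (length(bad))
    stop("non-positive condition mean for gene(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  log2(md / mn)
}
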