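#' Exclude pathways under-detected on a platform
#'
#' Under a binomial model, a pathway of size m with d members present on
#' the platform is compared with the global detection fraction
#' `p0 = |platform genes in the universe| / |universe|`; the pathway is
#' excluded when the lower-tail probability `P(X <= d | m, p0)` falls
#' below `alpha`, i.e. when significantly fewer members are detected than
#' platform coverage predicts.
#'
#' @param pathways A `PathwayCollection`.
#' @param platform_genes Character vector of genes measurable on the
#'   platform.
#' @param alpha Significance level in (0, 1); default 0.05.
#' @return The retained `PathwayCollection`.
#' @export
platform_coverage_filter <- function(pathways, platform_genes, alpha = 0.05) {
  stopifnot(inherits(pathways, "PathwayCollection"))
  if (!length(platform_genes)) stop("platform_genes must be non-empty")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  universe <- pathway_universe(pathways)
  p0 <- length(intersect(platform_genes, universe)) / length(universe)
  keep <- vapply(pathways$sets, function(members) {
    m <- length(members)
    d <- sum(members %in% platform_genes)
    stats::pbinom(d, m, p0) >= alpha
  }, logical(1))
  pathway_collection(pathways$sets[keep], provenance = pathways$provenance)
}

#' Aggregate a per-gene statistic to pathway level
#'
#' Each pathway's value is the unweighted mean of the statistic over its
#' member genes that are present in the profile; pathways with fewer than
#' `min_genes` measured members are dropped.
#'
#' @param profile A `DCProfile` or a named numeric vector of per-gene
#'   values (e.g. log fold changes for the differential-expression
#'   baseline).
#' @param pathways A `PathwayCollection`.
#' @param min_genes Minimum measured members per retained pathway
#'   (default 1).
#' @return Named numeric vector of pathway values with attribute
#'   `n_genes_used`.
#' @export
pathway_dc <- function(profile, pathways, min_genes = 1L) {
  stopifnot(inherits(pathways, "PathwayCollection"))
  if (!length(pathways$sets)) stop("empty pathway collection")
  if (inherits(profile, "DCProfile")) {
    values <- stats::setNames(profile$dC, profile$gene)
  } else {
    values <- profile
    if (is.null(names(values))) stop("profile must be named by gene")
  }
  agg <- lapply(pathways$sets, function(members) {
    present <- intersect(members, names(values))
    c(mean = if (length(present)) mean(values[present]) else NA_real_,
      n = length(present))
  })
  n_used <- vapply(agg, `[[`, numeric(1), "n")
  keep <- n_used >= min_genes
  if (!any(keep)) stop("no pathway has >= min_genes measured members")
  out <- vapply(agg[keep], `[[`, numeric(1), "mean")
  attr(out, "n_genes_used") <- as.integer(n_used[keep])
  out
}

#' Aligned pathway-level vectors across diseases
#'
#' Applies [pathway_dc()] per disease, then keeps the intersection of
#' pathways valid in every disease so all vectors share one pathway order
#' (a requirement of the partial-correlation step).
#'
#' @param profiles Named list (disease id -> `DCProfile` or named numeric
#'   vector).
#' @param pathways A `PathwayCollection`.
#' @param min_genes Passed to [pathway_dc()].
#' @return Numeric matrix, pathways x diseases.
#' @export
pathway_dc_matrix <- function(profiles, pathways, min_genes = 1L) {
  stopifnot(is.list(profiles), length(profiles) >= 1L)
  if (is.null(names(profiles))) stop("profiles must be named by disease id")
  per_disease <- lapply(profiles, pathway_dc, pathways = pathways,
                        min_genes = min_genes)
  common <- Reduce(intersect, lapply(per_disease, names))
  if (!length(common)) stop("no pathway valid across all diseases")
  out <- vapply(per_disease, function(v) unname(v[common]),
                numeric(length(common)))
  if (length(common) == 1L)
    out <- matrix(out, nrow = 1L,
                  dimnames = list(common, names(per_disease)))
  else rownames(out) <- common
  out
}
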