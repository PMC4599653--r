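#' Within-network distance (WD) of a disease subset
#'
#' Compactness statistic of a category inside the full network:
#' `WD = sum d(i, j) / k` over all unordered member pairs, where
#' `d(i, j)` is the unweighted shortest-path length in the *full* network
#' and `k` is the number of links with both endpoints in the subset.
#' A complete graph restricted to all of its nodes gives exactly 1; any
#' member pair disconnected in the full network makes WD infinite
#' (flagged).
#'
#' @param network A `DiseaseNetwork`.
#' @param members Character vector of >= 2 member diseases (all must be
#'   network nodes).
#' @return A one-row data frame (class `WDReport` rows): `n_diseases`,
#'   `k`, `wd`, `disconnected`.
#' @export
within_network_distance <- function(network, members) {
  stopifnot(inherits(network, "DiseaseNetwork"))
  members <- unique(as.character(members))
  if (length(members) < 2L) stop("need >= 2 member diseases")
  stray <- setdiff(members, network$nodes)
  if (length(stray)) stop("member(s) not in network: ", paste(stray, collapse = ", "))
  k <- sum(network$edges$disease_a %in% members &
             network$edges$disease_b %in% members)
  if (k == 0L) stop("no link has both endpoints in the member set; WD undefined")
  g <- as_igraph(network)
  d <- igraph::distances(g, v = members, to = members, weights = NA)
  sumd <- sum(d[upper.tri(d)])
  data.frame(n_diseases = length(members), k = k,
             wd = sumd / k, disconnected = is.infinite(sumd))
}

# WD that tolerates undefined cases (used by permutation nulls): k = 0 or
# a disconnected member pair both count as maximally non-compact (Inf)
wd_or_inf <- function(dist_matrix, edges_a, edges_b, members) {
  k <- sum(edges_a %in% members & edges_b %in% members)
  if (k == 0L) return(Inf)
  d <- dist_matrix[members, members]
  sum(d[upper.tri(d)]) / k
}

#' WD table over a category annotation
#'
#' One row per category with at least two member diseases in the network
#' and at least one within-category link, plus a `whole network` row;
#' categories whose WD exceeds the whole-network WD are flagged.
#'
#' @param network A `DiseaseNetwork`.
#' @param annotation A `CategoryAnnotation`; diseases not in the network
#'   are dropped with a warning.
#' @return Data frame with columns `category`, `n_diseases`, `k`, `wd`,
#'   `disconnected`, `above_whole_network`.
#' @export
category_wd_table <- function(network, annotation) {
  stopifnot(inherits(network, "DiseaseNetwork"),
            inherits(annotation, "CategoryAnnotation"))
  unknown <- setdiff(names(annotation$sets), network$nodes)
  if (length(unknown))
    warning("annotated disease(s) not in network dropped: ",
            paste(unknown, collapse = ", "))
  known <- setdiff(names(annotation$sets), unknown)
  by_cat <- split(rep(known, lengths(annotation$sets[known])),
                  unlist(annotation$sets[known], use.names = FALSE))
  whole <- within_network_distance(network, network$nodes)
  rows <- list()
  for (cat in sort(names(by_cat))) {
    members <- unique(by_cat[[cat]])
    if (length(members) < 2L) {
      warning("category '", cat, "' has < 2 diseases in the network; omitted")
      next
    }
    k <- sum(network$edges$disease_a %in% members &
               network$edges$disease_b %in% members)
    if (k == 0L) {
      warning("category '", cat, "' has no internal link; omitted")
      next
    }
    rows[[cat]] <- cbind(category = cat,
                         within_network_distance(network, members))
  }
  out <- rbind(do.call(rbind, unname(rows)),
               cbind(category = "whole network", whole))
  out$above_whole_network <- out$wd > whole$wd
  rownames(out) <- NULL
  out
}

#' Tissue compactness with a label-permutation test
#'
#' For every tissue with at least `min_diseases` diseases the observed WD
#' is compared with `reps` permutations of the disease-to-tissue
#' assignment (per-tissue counts fixed). Two significance summaries are
#' reported: a one-sided Wilcoxon signed-rank test of the null WD vector
#' against the observed value (alternative: null WDs greater, i.e. the
#' tissue is more compact than chance), and the plain empirical fraction
#' of null WDs less than or equal to the observed. Permutations in which
#' a pseudo tissue has no internal link, or spans disconnected components,
#' score an infinite WD; since the signed-rank test only uses ranks these
#' are mapped to a value above the largest finite WD.
#'
#' @param network A `DiseaseNetwork`.
#' @param tissue_map Named character vector (disease id -> tissue).
#' @param reps Number of label permutations (>= 100; 500 conventional).
#' @param seed Permutation seed.
#' @param min_diseases Minimum diseases per analysed tissue (default 3).
#' @return Data frame: `tissue`, `n_diseases`, `k`, `wd`, `p_wilcoxon`,
#'   `p_empirical`.
#' @export
tissue_wd_permutation <- function(network, tissue_map, reps = 500L, seed = 1L,
                                  min_diseases = 3L) {
  stopifnot(inherits(network, "DiseaseNetwork"))
  if (reps < 100L) stop("reps must be >= 100")
  tissue_map <- tissue_map[names(tissue_map) %in% network$nodes]
  counts <- table(tissue_map)
  tissues <- names(counts)[counts >= min_diseases]
  if (length(tissues) < 2L)
    stop("need >= 2 tissues with >= ", min_diseases, " diseases")
  tissue_map <- tissue_map[tissue_map %in% tissues]
  diseases <- names(tissue_map)
  g <- as_igraph(network)
  dist_all <- igraph::distances(g, v = diseases, to = diseases, weights = NA)
  ea <- network$edges$disease_a; eb <- network$edges$disease_b
  observed <- vapply(tissues, function(tt)
    wd_or_inf(dist_all, ea, eb, diseases[tissue_map == tt]), numeric(1))
  null_wd <- matrix(NA_real_, length(tissues), reps,
                    dimnames = list(tissues, NULL))
  with_seed(seed, {
    for (r in seq_len(reps)) {
      perm <- stats::setNames(sample(tissue_map), diseases)
      null_wd[, r] <- vapply(tissues, function(tt)
        wd_or_inf(dist_all, ea, eb, diseases[perm == tt]), numeric(1))
    }
  })
  res <- lapply(tissues, function(tt) {
    nulls <- null_wd[tt, ]
    obs <- observed[[tt]]
    finite_max <- max(c(nulls[is.finite(nulls)], if (is.finite(obs)) obs, 1))
    cap <- finite_max + 1
    nulls_c <- ifelse(is.finite(nulls), nulls, cap)
    obs_c <- if (is.finite(obs)) obs else cap
    pw <- suppressWarnings(stats::wilcox.test(
      nulls_c, mu = obs_c, alternative = "greater", exact = FALSE)$p.value)
    members <- diseases[tissue_map == tt]
    k <- sum(ea %in% members & eb %in% members)
    data.frame(tissue = tt, n_diseases = length(members), k = k, wd = obs,
               p_wilcoxon = pw,
               p_empirical = (1 + sum(nulls_c <= obs_c)) / (reps + 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Average-linkage clustering of the similarity matrix
#'
#' Non-significant coefficients are set to zero, the distance is
#' `1 - rho`, and the tree is cut into `k` groups by average-linkage
#' agglomeration. Diseases are processed in lexicographic label order so
#' ties break deterministically.
#'
#' @param similarity A `SimilarityMatrix`.
#' @param pair_stats Data frame from [empirical_pvalues()] supplying the
#'   per-pair p-values.
#' @param k Number of groups (2 <= k <= number of diseases).
#' @param p_threshold Coefficients with `p >= p_threshold` are zeroed.
#' @return Named integer vector (disease -> group id); the `hclust` tree
#'   is attached as attribute `tree`.
#' @export
hierarchical_cluster <- function(similarity, pair_stats, k, p_threshold = 0.05) {
  stopifnot(inherits(similarity, "SimilarityMatrix"))
  diseases <- sort(similarity$diseases)
  if (k < 2L) stop("k must be >= 2")
  if (k > length(diseases)) stop("k must not exceed the number of diseases")
  rho <- similarity$rho[diseases, diseases]
  keep <- matrix(FALSE, length(diseases), length(diseases),
                 dimnames = list(diseases, diseases))
  sig <- pair_stats[pair_stats$p < p_threshold, , drop = FALSE]
  if (nrow(sig)) {
    keep[cbind(sig$disease_a, sig$disease_b)] <- TRUE
    keep[cbind(sig$disease_b, sig$disease_a)] <- TRUE
  }
  rho[!keep] <- 0
  diag(rho) <- 1
  tree <- stats::hclust(stats::as.dist(1 - rho), method = "average")
  groups <- stats::cutree(tree, k = k)
  attr(groups, "tree") <- tree
  groups
}

#' Hypergeometric test of shared items between two diseases
#'
#' Upper-tail probability of drawing at least the observed overlap when
#' `|items(a)|` items are drawn without replacement from the association
#' universe containing `|items(b)|` successes; symmetric in (a, b).
#'
#' @param assoc An `AssociationTable`.
#' @param a,b Disease ids present in the table.
#' @return One-row data frame: `disease_a`, `disease_b`, `kind`,
#'   `overlap`, `size_a`, `size_b`, `universe`, `p`.
#' @export
pair_sharing_test <- function(assoc, a, b) {
  stopifnot(inherits(assoc, "AssociationTable"))
  for (d in c(a, b)) if (is.null(assoc$sets[[d]]))
    stop("disease '", d, "' absent from the association table")
  sa <- assoc$sets[[a]]; sb <- assoc$sets[[b]]
  n_univ <- length(assoc$universe)
  ov <- length(intersect(sa, sb))
  p <- stats::phyper(ov - 1, length(sb), n_univ - length(sb), length(sa),
                     lower.tail = FALSE)
  data.frame(disease_a = a, disease_b = b, kind = assoc$kind, overlap = ov,
             size_a = length(sa), size_b = length(sb), universe = n_univ,
             p = p, stringsAsFactors = FALSE)
}

#' Contingency table of sharing significance by link status
#'
#' Classifies every unordered pair of diseases that carry associated items
#' as DDL (edge present) or non-DDL, and as significant or non-significant
#' sharer by [pair_sharing_test()] at `alpha`.
#'
#' @param network A `DiseaseNetwork`.
#' @param assoc An `AssociationTable`.
#' @param alpha Sharing-significance threshold (default 0.05).
#' @return 2x2 integer matrix, rows `DDL`/`non-DDL`, columns
#'   `significant`/`non-significant`.
#' @export
sharing_contingency <- function(network, assoc, alpha = 0.05) {
  stopifnot(inherits(network, "DiseaseNetwork"),
            inherits(assoc, "AssociationTable"))
  covered <- intersect(network$nodes,
                       names(assoc$sets)[lengths(assoc$sets) > 0])
  if (length(covered) < 2L) stop("fewer than 2 diseases carry associated items")
  edge_key <- paste(network$edges$disease_a, network$edges$disease_b, sep = "\r")
  tab <- matrix(0L, 2, 2, dimnames = list(c("DDL", "non-DDL"),
                                          c("significant", "non-significant")))
  covered <- sort(covered)
  for (i in seq_len(length(covered) - 1L)) {
    for (j in seq(i + 1L, length(covered))) {
      a <- covered[i]; b <- covered[j]
      is_ddl <- paste(a, b, sep = "\r") %in% edge_key
      sig <- pair_sharing_test(assoc, a, b)$p < alpha
      tab[if (is_ddl) 1L else 2L, if (sig) 1L else 2L] <-
        tab[if (is_ddl) 1L else 2L, if (sig) 1L else 2L] + 1L
    }
  }
  tab
}

#' One-sided Fisher test: do DDLs share items more often?
#'
#' Tests whether significant sharing is enriched among DDLs relative to
#' non-DDL pairs (alternative: odds ratio > 1).
#'
#' @param tab 2x2 matrix with rows (DDL, non-DDL) and columns
#'   (significant, non-significant), e.g. from [sharing_contingency()].
#' @return List with `p` and the input `table`.
#' @export
ddl_vs_nonddl_fisher <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("tab must be 2x2")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("contingency table has an empty margin")
  list(p = stats::fisher.test(tab, alternative = "greater")$p.value,
       table = tab)
}

#' Node-degree histogram over configurable bins
#'
#' @param network A non-empty `DiseaseNetwork`.
#' @param bins List of inclusive integer ranges `c(lo, hi)`; ranges must
#'   not overlap.
#' @return Data frame with `bin`, `count`, `fraction`, plus an `outside`
#'   attribute counting nodes in no bin.
#' @export
degree_distribution <- function(network, bins) {
  stopifnot(inherits(network, "DiseaseNetwork"))
  if (!length(network$nodes)) stop("empty network")
  bins <- lapply(bins, function(b) {
    if (length(b) != 2L || b[1] > b[2]) stop("each bin must be an ordered pair")
    as.numeric(b)
  })
  if (length(bins) > 1L) {
    ord <- order(vapply(bins, `[[`, numeric(1), 1L))
    sb <- bins[ord]
    for (i in seq_len(length(sb) - 1L))
      if (sb[[i]][2] >= sb[[i + 1]][1]) stop("bins overlap")
  }
  deg <- igraph::degree(as_igraph(network))
  counts <- vapply(bins, function(b) sum(deg >= b[1] & deg <= b[2]), numeric(1))
  out <- data.frame(
    bin = vapply(bins, function(b) sprintf("%g-%g", b[1], b[2]), character(1)),
    count = as.integer(counts),
    fraction = counts / length(deg))
  attr(out, "outside") <- as.integer(length(deg) - sum(counts))
  out
}

#' Pathway enrichment of common DCGs with a random-set permutation test
#'
#' Each candidate pathway gets a hypergeometric upper-tail p for its
#' overlap with the common DCG set; the overall statistic is the
#' proportion of pathways with `p < alpha`, and its significance is the
#' (+1-smoothed) fraction of `reps` random gene sets of the same size
#' whose proportion reaches the observed one.
#'
#' @param common_dcgs Character vector of genes (subset of `universe`).
#' @param candidate_pathways A `PathwayCollection`.
#' @param universe Gene universe for both the hypergeometric test and the
#'   random draws.
#' @param reps Number of random sets (>= 100).
#' @param seed Seed for the draws.
#' @param alpha Per-pathway significance level (default 0.05).
#' @return List with `per_pathway` (data frame `pathway`, `overlap`, `p`),
#'   `proportion` (observed fraction of enriched pathways), and
#'   `proportion_p`.
#' @export
common_dcg_enrichment <- function(common_dcgs, candidate_pathways, universe,
                                  reps = 1000L, seed = 1L, alpha = 0.05) {
  stopifnot(inherits(candidate_pathways, "PathwayCollection"))
  if (reps < 100L) stop("reps must be >= 100")
  universe <- unique(as.character(universe))
  common_dcgs <- unique(as.character(common_dcgs))
  if (!all(common_dcgs %in% universe))
    stop("common_dcgs must be a subset of the universe")
  sets <- lapply(candidate_pathways$sets, intersect, universe)
  n_univ <- length(universe)
  n_dcg <- length(common_dcgs)
  prop_enriched <- function(gene_set) {
    p <- vapply(sets, function(members) {
      ov <- length(intersect(members, gene_set))
      stats::phyper(ov - 1, length(members), n_univ - length(members),
                    length(gene_set), lower.tail = FALSE)
    }, numeric(1))
    p
  }
  p_obs <- prop_enriched(common_dcgs)
  obs_prop <- mean(p_obs < alpha)
  exceed <- 0L
  with_seed(seed, {
    for (r in seq_len(reps)) {
      rand <- sample(universe, n_dcg)
      if (mean(prop_enriched(rand) < alpha) >= obs_prop) exceed <- exceed + 1L
    }
  })
  list(per_pathway = data.frame(pathway = names(sets),
                                overlap = vapply(sets, function(m)
                                  length(intersect(m, common_dcgs)), numeric(1)),
                                p = unname(p_obs), stringsAsFactors = FALSE),
       proportion = obs_prop,
       proportion_p = (1 + exceed) / (reps + 1))
}
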