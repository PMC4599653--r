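# Independent oracle implementations used to cross-check the package's
# statistics. These deliberately avoid the code paths they validate.

# Benjamini-Hochberg step-up, written from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  running_min <- Inf
  for (i in m:1) {
    running_min <- min(running_min, p[o[i]] * m / i)
    q[o[i]] <- running_min
  }
  q
}

# upper-tail hypergeometric P(X >= k) by direct summation of combinatorial
# counts: draw n_draw items from a universe of N containing K successes
oracle_hyper_upper <- function(k, K, N, n_draw) {
  upper <- min(K, n_draw)
  if (k > upper) return(0)
  total <- choose(N, n_draw)
  sum(vapply(k:upper, function(x)
    choose(K, x) * choose(N - K, n_draw - x), numeric(1))) / total
}

# one-sided (greater) Fisher exact p for a 2x2 table by enumerating the
# hypergeometric support: tables at least as extreme toward larger [1,1]
oracle_fisher_greater <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  N <- r1 + r2
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(support, function(x)
    choose(r1, x) * choose(r2, c1 - x) / choose(N, c1), numeric(1))
  sum(probs[support >= a])
}

# Spearman rank correlation from the Pearson definition on ranks
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# first-order partial correlation of ranks via residualisation: correlate
# the residuals of rank(x) ~ rank(z) and rank(y) ~ rank(z)
oracle_partial_spearman <- function(x, y, z) {
  rx <- rank(x); ry <- rank(y); rz <- rank(z)
  ex <- stats::resid(stats::lm(rx ~ rz))
  ey <- stats::resid(stats::lm(ry ~ rz))
  sum(ex * ey) / sqrt(sum(ex^2) * sum(ey^2))
}

# brute-force average-linkage agglomeration returning merge heights
oracle_average_linkage_heights <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in seq(i + 1L, length(clusters))) {
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < best_h) { best_h <- h; best <- c(i, j) }
      }
    }
    heights <- c(heights, best_h)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# all 0-1 gene x pathway matrices with the given margins, as canonical
# signature strings (pathway -> sorted members)
enumerate_margin_matrices <- function(gene_degrees, pathway_sizes) {
  ng <- length(gene_degrees); np <- length(pathway_sizes)
  cells <- expand.grid(rep(list(0:1), ng * np))
  sigs <- character(0)
  for (r in seq_len(nrow(cells))) {
    m <- matrix(as.integer(cells[r, ]), ng, np)
    if (all(rowSums(m) == gene_degrees) && all(colSums(m) == pathway_sizes)) {
      sigs <- c(sigs, incidence_signature(m, names(gene_degrees)))
    }
  }
  sort(sigs)
}

incidence_signature <- function(m, gene_names) {
  paste(apply(m, 2, function(col) paste(sort(gene_names[col == 1]),
                                        collapse = ",")),
        collapse = "|")
}

collection_signature <- function(pathways, gene_names) {
  paste(vapply(pathways$sets, function(s) paste(sort(s), collapse = ","),
               character(1)), collapse = "|")
}
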