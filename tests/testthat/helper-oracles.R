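# Independent brute-force oracles used to cross-check the implementation.
# These are deliberately written as plain-formula loops, separate from any
# code path in R/.

oracle_bray <- function(x, y) {
  if (sum(x) + sum(y) == 0) return(0)
  sum(abs(x - y)) / sum(x + y)
}

oracle_jaccard <- function(x, y) {
  a <- x > 0; b <- y > 0
  if (!any(a | b)) return(0)
  1 - sum(a & b) / sum(a | b)
}

# tie-corrected Kruskal-Wallis H via the textbook rank-sum formula
oracle_kw <- function(values, groups) {
  groups <- as.factor(groups)
  N <- length(values)
  r <- rank(values)
  R <- tapply(r, groups, sum)
  n <- tapply(r, groups, length)
  H <- 12 / (N * (N + 1)) * sum(R^2 / n) - 3 * (N + 1)
  ties <- table(values)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# Dunn z for one pair, pooled tie correction
oracle_dunn_z <- function(values, groups, g1, g2) {
  r <- rank(values)
  N <- length(values)
  ties <- table(values)
  s2 <- N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))
  m1 <- mean(r[groups == g1]); m2 <- mean(r[groups == g2])
  n1 <- sum(groups == g1); n2 <- sum(groups == g2)
  (m1 - m2) / sqrt(s2 * (1 / n1 + 1 / n2))
}

# Pearson correlation of midranks, from first principles
oracle_spearman_rho <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  dx <- rx - mean(rx); dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

oracle_chisq <- function(tab) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  out <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      e <- sum(tab[i, ]) * sum(tab[, j]) / n
      out <- out + (tab[i, j] - e)^2 / e
    }
  }
  out
}

# expected richness under without-replacement subsampling (hypergeometric)
oracle_rarefy <- function(counts, n) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  sum(1 - exp(lchoose(N - counts, n) - lchoose(N, n)))
}

oracle_mdo <- function(rel_abund, midpoints) {
  num <- 0; den <- 0
  for (i in seq_along(rel_abund)) {
    if (rel_abund[i] > 0) {
      num <- num + rel_abund[i] * midpoints[i]
      den <- den + rel_abund[i]
    }
  }
  if (den == 0) NA_real_ else num / den
}

# small hand-built survey fixture: 2 provinces x day/night x 4 strata
tiny_meta <- function() {
  design <- survey_design(provinces = c("A", "B"),
                          strata = data.frame(upper_m = c(0, 50, 100, 200),
                                              lower_m = c(50, 100, 200, 400)),
                          reads_per_sample = 1000, seed = 1)
  survey_meta(design)
}

# random counts-mode read_matrix over a given metadata table
random_matrix <- function(meta, n_taxa = 6, reads = 500, marker = "M1") {
  cts <- matrix(rpois(n_taxa * nrow(meta), reads / n_taxa), n_taxa,
                nrow(meta),
                dimnames = list(sprintf("t%02d", seq_len(n_taxa)),
                                meta$sample_id))
  read_matrix(cts, marker = marker, mode = "counts")
}
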