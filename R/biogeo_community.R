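#' Depth zone of each sample
#'
#' Epipelagic for strata wholly above the 200 m boundary (lower bound
#' <= 200 m), mesopelagic otherwise. The default strata abut exactly at
#' 200 m, so no stratum straddles the zones.
#'
#' @param meta Sample metadata.
#' @param boundary_m Zone boundary, default 200 m.
#' @return Character vector along `meta` rows.
#' @export
depth_zone <- function(meta, boundary_m = 200) {
  ifelse(meta$stratum_lower_m <= boundary_m, "epipelagic", "mesopelagic")
}

#' Taxonomic richness, observed or rarefied
#'
#' Presence-based richness per sample, depth zone or province. Grouped
#' richness pools read counts within the group. With `rarefy_to` set,
#' reports the expected richness under without-replacement subsampling to
#' `rarefy_to` reads: the analytic hypergeometric expectation by default
#' (via [vegan::rarefy]), or a seeded Monte-Carlo mean of
#' [vegan::rrarefy] draws. Groups with fewer than `rarefy_to` reads are
#' excluded (NA) and flagged in the `excluded` attribute.
#'
#' @param matrix A counts-mode [read_matrix()] (counts required when
#'   rarefying; presence works for observed richness in either mode).
#' @param meta Sample metadata.
#' @param group_by `"sample"`, `"depth_zone"` or `"province"`.
#' @param rarefy_to Integer read depth to rarefy to, or `NULL` (observed).
#' @param method `"analytic"` or `"montecarlo"`.
#' @param n_mc Monte-Carlo draws.
#' @param seed Seed for the Monte-Carlo option.
#' @return Data frame `group`, `n_reads`, `richness`.
#' @export
richness <- function(matrix, meta,
                     group_by = c("sample", "depth_zone", "province"),
                     rarefy_to = NULL,
                     method = c("analytic", "montecarlo"),
                     n_mc = 1000, seed = 1L) {
  group_by <- match.arg(group_by)
  method <- match.arg(method)
  if (!is.null(rarefy_to) && matrix$mode != "counts") {
    stop("rarefaction requires counts mode")
  }
  cts <- matrix$counts[, meta$sample_id, drop = FALSE]
  groups <- switch(group_by,
                   sample = meta$sample_id,
                   depth_zone = depth_zone(meta),
                   province = meta$province)
  glev <- unique(groups)
  pooled <- vapply(glev, function(g) {
    rowSums(cts[, groups == g, drop = FALSE])
  }, numeric(nrow(cts)))
  if (nrow(cts) == 0) {
    return(data.frame(group = glev, n_reads = 0,
                      richness = 0))
  }
  totals <- colSums(pooled)
  if (is.null(rarefy_to)) {
    rich <- colSums(pooled > 0)
    excluded <- character(0)
  } else {
    ok <- totals >= rarefy_to
    rich <- rep(NA_real_, length(glev))
    if (any(ok)) {
      sub <- t(pooled[, ok, drop = FALSE])
      if (method == "analytic") {
        rich[ok] <- as.numeric(vegan::rarefy(sub, sample = rarefy_to))
      } else {
        set.seed(substream_seed(seed, "rarefy"))
        rich[ok] <- vapply(seq_len(nrow(sub)), function(i) {
          mean(vapply(seq_len(n_mc), function(k) {
            sum(vegan::rrarefy(sub[i, , drop = FALSE], rarefy_to) > 0)
          }, numeric(1)))
        }, numeric(1))
      }
    }
    excluded <- glev[!ok]
  }
  out <- data.frame(group = glev, n_reads = totals, richness = rich)
  attr(out, "excluded") <- excluded
  out
}

#' Province-occupancy partition and endemism
#'
#' For each taxon, the set of provinces in which it was observed (>=
#' `min_reads` reads) within a depth scope, tallied by province subset.
#' Epipelagic scope keeps strata with lower bound <= 200 m, mesopelagic
#' scope strata with upper bound >= 200 m. Endemism per province is the
#' fraction of that province's observed taxa found only there;
#' cosmopolitan taxa occur in every province.
#'
#' @param matrix A [read_matrix()].
#' @param meta Sample metadata.
#' @param depth_scope `"full"`, `"epipelagic"` or `"mesopelagic"`.
#' @param min_reads Presence threshold (>= 1 read by default).
#' @param boundary_m Zone boundary, default 200 m.
#' @return Object of class `occupancy_partition`: list with `counts`
#'   (named integer vector per non-empty province subset, labels
#'   "+"-joined in metadata province order), `endemism_pct`,
#'   `cosmopolitan_pct`, `n_taxa_observed`, `taxa` (per-taxon data frame
#'   with `occupancy` and `n_provinces`), `depth_scope`.
#' @export
occupancy_partition <- function(matrix, meta,
                                depth_scope = c("full", "epipelagic",
                                                "mesopelagic"),
                                min_reads = 1, boundary_m = 200) {
  depth_scope <- match.arg(depth_scope)
  provinces <- unique(meta$province)
  if (length(provinces) < 2) stop("need >= 2 provinces")
  keep <- switch(depth_scope,
                 full = rep(TRUE, nrow(meta)),
                 epipelagic = meta$stratum_lower_m <= boundary_m,
                 mesopelagic = meta$stratum_upper_m >= boundary_m)
  sub <- meta[keep, ]
  cts <- matrix$counts[, sub$sample_id, drop = FALSE]
  occ_mat <- vapply(provinces, function(pv) {
    rowSums(cts[, sub$province == pv, drop = FALSE]) >= min_reads
  }, logical(nrow(cts)))
  if (!is.matrix(occ_mat)) {
    occ_mat <- matrix(occ_mat, nrow = nrow(cts),
                      dimnames = list(rownames(cts), provinces))
  }
  observed <- rowSums(occ_mat) > 0
  occ_lab <- apply(occ_mat, 1, function(o) paste(provinces[o], collapse = "+"))
  taxa <- data.frame(taxon_id = rownames(cts), occupancy = occ_lab,
                     n_provinces = rowSums(occ_mat))[observed, ]
  counts <- table(taxa$occupancy)
  endemism <- vapply(provinces, function(pv) {
    in_pv <- occ_mat[observed, pv]
    if (!sum(in_pv)) return(NA_real_)
    100 * sum(taxa$occupancy == pv) / sum(in_pv)
  }, numeric(1))
  structure(list(
    counts = setNames(as.integer(counts), names(counts)),
    endemism_pct = endemism,
    cosmopolitan_pct = 100 * sum(taxa$n_provinces == length(provinces)) /
      max(1, nrow(taxa)),
    n_taxa_observed = nrow(taxa),
    taxa = taxa, depth_scope = depth_scope
  ), class = "occupancy_partition")
}

#' @export
print.occupancy_partition <- function(x, ...) {
  cat("Occupancy partition (", x$depth_scope, " scope), ",
      x$n_taxa_observed, " taxa observed\n", sep = "")
  print(x$counts)
  cat("endemism %:\n"); print(round(x$endemism_pct, 1))
  cat(sprintf("cosmopolitan: %.1f%%\n", x$cosmopolitan_pct))
  invisible(x)
}

#' Community distance matrix
#'
#' Bray-Curtis on relative abundances, or Jaccard on presence/absence,
#' between samples (via [vegan::vegdist]). Distances between two all-zero
#' samples are defined as 0 and flagged in the `zero_pairs` attribute.
#'
#' @param matrix A [read_matrix()]; Bray-Curtis requires relative mode,
#'   Jaccard uses presence from any mode.
#' @param metric `"bray_curtis"` or `"jaccard"`.
#' @return A `dist` object with attributes `metric` and `zero_pairs`.
#' @export
distance_matrix <- function(matrix, metric = c("bray_curtis", "jaccard")) {
  metric <- match.arg(metric)
  x <- t(matrix$counts)
  if (nrow(x) < 2) stop("need >= 2 samples")
  if (metric == "bray_curtis") {
    if (matrix$mode != "relative") {
      stop("Bray-Curtis requires a relative-mode matrix")
    }
    d <- vegan::vegdist(x, method = "bray")
  } else {
    d <- vegan::vegdist(x > 0, method = "jaccard", binary = TRUE)
  }
  zp <- which(is.na(as.matrix(d)) & upper.tri(as.matrix(d)), arr.ind = TRUE)
  d[is.na(d)] <- 0
  attr(d, "metric") <- metric
  attr(d, "zero_pairs") <- zp
  d
}

#' Non-metric multidimensional scaling
#'
#' Kruskal stress-1 nMDS of a community distance matrix via
#' [vegan::metaMDS] (iterative monotone regression, `n_starts` seeded
#' random starts, best-stress solution kept).
#'
#' @param d A `dist` object.
#' @param k Target dimensionality.
#' @param n_starts Random starts.
#' @param seed Seed.
#' @return List `points` (n x k coordinates), `stress` (Kruskal stress-1,
#'   fraction), `converged`.
#' @export
nmds_ordination <- function(d, k = 2, n_starts = 20, seed = 1L) {
  n <- attr(d, "Size")
  if (n < k + 1) stop("need at least k+1 samples")
  set.seed(substream_seed(seed, "nmds"))
  fit <- vegan::metaMDS(d, k = k, try = n_starts, trymax = n_starts,
                        trace = 0, autotransform = FALSE, wascores = FALSE)
  if (!fit$converged) {
    warning("nMDS did not converge; returning best solution found")
  }
  list(points = fit$points, stress = fit$stress,
       converged = isTRUE(fit$converged))
}

#' Beta-dispersion contrast between depth zones
#'
#' Multivariate homogeneity of group dispersions: principal-coordinate
#' embedding of the distance matrix with the standard imaginary-axis
#' correction, distance of each sample to its group centroid, then a
#' one-way ANOVA on those distances (via [vegan::betadisper]), with an
#' optional seeded permutation test.
#'
#' @param d A `dist` object.
#' @param groups Factor/character of group membership per sample (e.g.
#'   epipelagic vs mesopelagic).
#' @param n_perm Permutations for the permutation p-value (0 to skip).
#' @param seed Seed for permutations.
#' @return List `F`, `df` (c(between, within)), `p_anova`, `p_perm`,
#'   `distances` (named per-sample distance to group centroid),
#'   `group_means`.
#' @export
beta_dispersion <- function(d, groups, n_perm = 999, seed = 1L) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2) stop("need >= 2 groups")
  if (any(table(groups) < 2)) stop("every group needs >= 2 samples")
  bd <- vegan::betadisper(d, groups, type = "centroid")
  an <- anova(bd)
  p_perm <- NA_real_
  if (n_perm > 0) {
    set.seed(substream_seed(seed, "perm"))
    pt <- vegan::permutest(bd, permutations = n_perm)
    p_perm <- pt$tab$`Pr(>F)`[1]
  }
  list(F = an$`F value`[1], df = an$Df, p_anova = an$`Pr(>F)`[1],
       p_perm = p_perm, distances = bd$distances,
       group_means = tapply(bd$distances, groups, mean))
}
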