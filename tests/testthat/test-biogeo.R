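test_that("richness counts presences, overall and by group", {
  meta <- tiny_meta()
  cts <- matrix(0L, 3, nrow(meta),
                dimnames = list(paste0("t", 1:3), meta$sample_id))
  cts[1, 1:4] <- 5L
  cts[2, 1] <- 1L
  m <- read_matrix(cts, "x")
  r <- richness(m, meta, "sample")
  expect_equal(r$richness[r$group == meta$sample_id[1]], 2)
  rp <- richness(m, meta, "province")
  expect_equal(sum(rp$richness), sum(rowSums(cts) > 0) +
                 0 * nrow(rp))  # t3 observed nowhere
  empty <- read_matrix(cts[0, , drop = FALSE], "x")
  re <- richness(empty, meta, "sample")
  expect_true(all(re$richness == 0))
})

test_that("rarefied richness uses the hypergeometric expectation", {
  meta <- tiny_meta()[1, , drop = FALSE]
  counts <- c(10, 5, 3, 1, 1)
  cts <- matrix(as.integer(counts), 5, 1,
                dimnames = list(paste0("t", 1:5), meta$sample_id))
  m <- read_matrix(cts, "x")
  r <- richness(m, meta, "sample", rarefy_to = 10)
  expect_equal(r$richness, oracle_rarefy(counts, 10), tolerance = 1e-10)
  # Monte-Carlo agrees with the analytic expectation within 3 SE
  rmc <- richness(m, meta, "sample", rarefy_to = 10,
                  method = "montecarlo", n_mc = 10000, seed = 7)
  se <- sqrt(5) / sqrt(10000)  # variance of richness bounded by S
  expect_lt(abs(rmc$richness - r$richness), 3 * max(se, 0.05))
  # rarefied richness never exceeds observed richness
  expect_lte(r$richness, sum(counts > 0))
  # samples shallower than the rarefaction depth are flagged out
  r2 <- richness(m, meta, "sample", rarefy_to = 100)
  expect_true(is.na(r2$richness))
  expect_equal(attr(r2, "excluded"), meta$sample_id)
})

test_that("occupancy partition enumerates province subsets exactly", {
  design <- survey_design(provinces = c("A", "B", "C"), seed = 1)
  meta <- survey_meta(design)
  cts <- matrix(0L, 3, nrow(meta),
                dimnames = list(paste0("t", 1:3), meta$sample_id))
  cts[1, meta$province == "A"] <- 1L
  cts[2, meta$province %in% c("A", "B")] <- 1L
  cts[3, ] <- 1L
  part <- occupancy_partition(read_matrix(cts, "x"), meta, "full")
  expect_equal(unname(part$counts[c("A", "A+B", "A+B+C")]), c(1L, 1L, 1L))
  # endemism in A: 1 endemic of 3 taxa observed in A
  expect_equal(unname(part$endemism_pct["A"]), 100 / 3)
  expect_equal(part$cosmopolitan_pct, 100 / 3)
  expect_equal(part$n_taxa_observed, 3)
})

test_that("occupancy partition matches brute-force set enumeration", {
  design <- survey_design(provinces = c("A", "B", "C"), seed = 2)
  meta <- survey_meta(design)
  set.seed(10)
  for (k in 1:10) {
    cts <- matrix(rbinom(8 * nrow(meta), 1, 0.08) * rpois(8 * nrow(meta), 5),
                  8, nrow(meta),
                  dimnames = list(paste0("t", 1:8), meta$sample_id))
    part <- occupancy_partition(read_matrix(cts, "x"), meta, "full")
    brute <- sapply(seq_len(8), function(i) {
      present <- unique(meta$province[cts[i, ] > 0])
      paste(intersect(c("A", "B", "C"), present), collapse = "+")
    })
    brute <- brute[brute != ""]
    expect_equal(sum(part$counts), length(brute))
    expect_equal(part$counts[sort(unique(brute))],
                 table(brute)[sort(unique(brute))],
                 ignore_attr = TRUE)
  }
})

test_that("depth scopes split occupancy at the 200 m stratum boundary", {
  design <- survey_design(provinces = c("A", "B"), seed = 1)
  meta <- survey_meta(design)
  cts <- matrix(0L, 2, nrow(meta),
                dimnames = list(c("shallow", "deep"), meta$sample_id))
  cts["shallow", meta$stratum_lower_m <= 200] <- 1L
  cts["deep", meta$stratum_upper_m >= 200 & meta$province == "A"] <- 1L
  m <- read_matrix(cts, "x")
  epi <- occupancy_partition(m, meta, "epipelagic")
  meso <- occupancy_partition(m, meta, "mesopelagic")
  expect_equal(epi$n_taxa_observed, 1)
  expect_equal(names(meso$counts), "A")
  expect_equal(meso$taxa$taxon_id, "deep")
})

test_that("distance metrics match hand formulas and metric axioms", {
  # worked example: Bray-Curtis of [0.6,0.4] vs [0.2,0.8] is 0.4
  cts <- matrix(c(6, 4, 2, 8, 6, 4), 2, 3,
                dimnames = list(c("a", "b"), c("s1", "s2", "s3")))
  rel <- to_relative(read_matrix(cts, "x"))
  d <- distance_matrix(rel, "bray_curtis")
  dm <- as.matrix(d)
  expect_equal(dm["s1", "s2"], 0.4, tolerance = 1e-12)
  expect_equal(dm["s1", "s3"], 0)   # identical compositions
  # disjoint supports -> 1 under both metrics
  cts2 <- matrix(c(5, 0, 0, 7), 2, 2,
                 dimnames = list(c("a", "b"), c("s1", "s2")))
  rel2 <- to_relative(read_matrix(cts2, "x"))
  expect_equal(as.matrix(distance_matrix(rel2, "bray_curtis"))["s1", "s2"], 1)
  expect_equal(as.matrix(distance_matrix(rel2, "jaccard"))["s1", "s2"], 1)

  # random fixtures against the oracles, plus axioms
  meta <- tiny_meta()
  set.seed(21)
  for (k in 1:10) {
    m <- random_matrix(meta, n_taxa = 7)
    rel <- to_relative(m)
    db <- as.matrix(distance_matrix(rel, "bray_curtis"))
    dj <- as.matrix(distance_matrix(m, "jaccard"))
    i <- sample(nrow(db), 1); j <- sample(nrow(db), 1)
    expect_equal(db[i, j], oracle_bray(rel$counts[, i], rel$counts[, j]),
                 tolerance = 1e-12)
    expect_equal(dj[i, j], oracle_jaccard(m$counts[, i], m$counts[, j]),
                 tolerance = 1e-12)
    expect_true(all(diag(db) == 0) && all(abs(db - t(db)) < 1e-15))
    expect_true(all(db >= 0 & db <= 1) && all(dj >= 0 & dj <= 1))
  }
})

test_that("all-zero sample pairs get distance 0 and a flag", {
  cts <- matrix(c(3, 1, 0, 0, 0, 0), 2, 3,
                dimnames = list(c("a", "b"), c("s1", "s2", "s3")))
  rel <- to_relative(read_matrix(cts, "x"))
  d <- distance_matrix(rel, "bray_curtis")
  dm <- as.matrix(d)
  expect_equal(dm["s2", "s3"], 0)
  expect_gt(nrow(attr(d, "zero_pairs")), 0)
})

test_that("nMDS embeds a genuinely 2-D configuration with near-zero stress", {
  set.seed(14)
  pts <- matrix(rnorm(20 * 2), 20, 2)
  rownames(pts) <- paste0("s", 1:20)
  d <- dist(pts)
  fit <- nmds_ordination(d, k = 2, n_starts = 10, seed = 3)
  expect_lt(fit$stress, 0.01)
  # duplicate samples land on near-identical coordinates
  pts2 <- rbind(pts, s21 = pts[1, ])
  fit2 <- nmds_ordination(dist(pts2), k = 2, n_starts = 10, seed = 3)
  expect_lt(sqrt(sum((fit2$points["s21", ] - fit2$points["s1", ])^2)),
            0.05 * max(dist(fit2$points)))
})

test_that("beta-dispersion matches a hand-computed ANOVA on distances", {
  meta <- tiny_meta()
  set.seed(31)
  m <- random_matrix(meta, n_taxa = 10)
  rel <- to_relative(m)
  d <- distance_matrix(rel, "bray_curtis")
  groups <- depth_zone(meta)
  bd <- beta_dispersion(d, groups, n_perm = 99, seed = 5)
  # one-way ANOVA on the per-sample distances, by hand
  x <- bd$distances; g <- as.factor(groups)
  gm <- tapply(x, g, mean); n <- tapply(x, g, length)
  ssb <- sum(n * (gm - mean(x))^2)
  ssw <- sum((x - gm[g])^2)
  f_hand <- (ssb / (nlevels(g) - 1)) / (ssw / (length(x) - nlevels(g)))
  expect_equal(bd$F, f_hand, tolerance = 1e-10)
  expect_equal(bd$df, c(nlevels(g) - 1, length(x) - nlevels(g)))
  expect_true(bd$p_perm >= 0 && bd$p_perm <= 1)
})

test_that("beta-dispersion flags degenerate groups and detects planted noise", {
  meta <- tiny_meta()
  m <- random_matrix(meta, n_taxa = 6)
  d <- distance_matrix(to_relative(m), "bray_curtis")
  expect_error(beta_dispersion(d, rep("g1", nrow(meta)), 0), ">= 2 groups")
  expect_error(beta_dispersion(d, c("a", rep("b", nrow(meta) - 1)), 0),
               ">= 2 samples")

  # two groups of 12 around distinct compositions, one 5x noisier
  set.seed(77)
  base1 <- runif(15); base2 <- runif(15)
  mk <- function(base, sdev, n, tag) {
    sapply(seq_len(n), function(i) abs(base + rnorm(15, 0, sdev)))
  }
  comp <- cbind(mk(base1, 0.02, 12), mk(base2, 0.10, 12))
  dimnames(comp) <- list(paste0("t", 1:15), paste0("s", 1:24))
  rel <- to_relative(read_matrix(round(comp * 1e4), "x"))
  d2 <- distance_matrix(rel, "bray_curtis")
  g2 <- rep(c("tight", "loose"), each = 12)
  bd2 <- beta_dispersion(d2, g2, n_perm = 199, seed = 11)
  expect_gt(bd2$group_means["loose"], bd2$group_means["tight"])
  expect_lt(bd2$p_anova, 0.05)
})

test_that("identical samples within a group give zero dispersion", {
  cts <- matrix(rep(c(5, 3, 2), 6), 3, 6,
                dimnames = list(paste0("t", 1:3), paste0("s", 1:6)))
  cts2 <- cts; cts2[, 4:6] <- c(1, 1, 8)
  rel <- to_relative(read_matrix(cts2, "x"))
  d <- distance_matrix(rel, "bray_curtis")
  bd <- beta_dispersion(d, rep(c("g1", "g2"), each = 3), n_perm = 0)
  expect_true(all(abs(bd$distances) < 1e-8))
})
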