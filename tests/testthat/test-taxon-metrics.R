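# hand-built two-station fixture for MDO / DVM checks:
# strata as in the survey, counts placed explicitly
dvm_fixture <- function(counts_list) {
  design <- survey_design(seed = 1)
  meta <- survey_meta(design)
  cts <- matrix(0L, length(counts_list), nrow(meta),
                dimnames = list(names(counts_list), meta$sample_id))
  for (tx in names(counts_list)) {
    for (nm in names(counts_list[[tx]])) {
      cts[tx, nm] <- counts_list[[tx]][[nm]]
    }
  }
  # a filler taxon keeps every sample non-empty
  filler <- matrix(1000L, 1, nrow(meta),
                   dimnames = list("filler", meta$sample_id))
  m <- read_matrix(rbind(cts, filler), marker = "M1")
  list(meta = meta, counts = m, rel = to_relative(m))
}

test_that("MDO is the abundance-weighted mean of occupied net midpoints", {
  fx <- dvm_fixture(list(t1 = c("Subarctic_day_100-200m" = 500)))
  expect_equal(mdo(fx$rel, fx$meta, "t1"), 150)

  # equal relative abundance in the 0-25 and 25-50 nets -> mean of midpoints
  fx2 <- dvm_fixture(list(t1 = c("Subarctic_day_0-25m" = 300,
                                 "Subarctic_day_25-50m" = 300)))
  expect_equal(mdo(fx2$rel, fx2$meta, "t1"), 25)

  # hand-computed weighted mean: 0.10 at 150 m and 0.03 at 700 m
  r <- c(0.10, 0.03); mids <- c(150, 700)
  expect_equal(sum(r * mids) / sum(r), 276.9230769, tolerance = 1e-6)
  fx3 <- dvm_fixture(list(t1 = c("Subarctic_day_100-200m" = 111,
                                 "Subarctic_day_600-800m" = 31)))
  rel3 <- fx3$rel$counts["t1", c("Subarctic_day_100-200m",
                                 "Subarctic_day_600-800m")]
  expect_equal(mdo(fx3$rel, fx3$meta, "t1"),
               oracle_mdo(unname(rel3), c(150, 700)))
  expect_error(mdo(fx3$rel, fx3$meta, "nope"), "unknown taxon")
})

test_that("MDO is scale-invariant and bounded by occupied midpoints", {
  meta <- tiny_meta()
  set.seed(5)
  for (k in 1:20) {
    m <- random_matrix(meta, n_taxa = 5)
    rel <- to_relative(m)
    v <- mdo(rel, meta, "t01")
    occ <- m$counts["t01", ] > 0
    mids <- meta$stratum_midpoint_m[match(colnames(m$counts)[occ],
                                          meta$sample_id)]
    expect_gte(v, min(mids)); expect_lte(v, max(mids))
    # rescaling one taxon's relative abundances leaves its MDO unchanged
    scaled <- rel
    scaled$counts["t01", ] <- scaled$counts["t01", ] * 0.37
    r <- scaled$counts["t01", meta$sample_id]
    expect_equal(sum(r * meta$stratum_midpoint_m) / sum(r), v,
                 tolerance = 1e-12)
  }
})

test_that("habitat classification uses a strict 200 m boundary", {
  expect_equal(classify_habitat(c(250, 150, 200, NA)),
               c("mesopelagic", "epipelagic", "epipelagic", NA))
})

test_that("DVM criteria fail individually as designed", {
  # C1: present in only one day net
  fx <- dvm_fixture(list(t1 = c("Subarctic_day_400-600m" = 200,
                                "Subarctic_night_0-25m" = 100,
                                "Subarctic_night_25-50m" = 100)))
  d <- detect_dvm(fx$rel, fx$counts, fx$meta, "t1", default_strata())
  expect_equal(d$dvm, "no")
  expect_false(d$stations$c1[d$stations$station == "Subarctic"])

  # C2: day/night tow abundances threefold different
  fx2 <- dvm_fixture(list(t1 = c("Subarctic_day_400-600m" = 300,
                                 "Subarctic_day_600-800m" = 300,
                                 "Subarctic_night_0-25m" = 100,
                                 "Subarctic_night_25-50m" = 100)))
  d2 <- detect_dvm(fx2$rel, fx2$counts, fx2$meta, "t1", default_strata())
  st2 <- d2$stations[d2$stations$station == "Subarctic", ]
  expect_true(st2$c1); expect_false(st2$c2)
  expect_equal(d2$dvm, "no")

  # C3: rare taxon below 0.01% of the study reads (4 of ~48,000)
  fx3 <- dvm_fixture(list(t1 = c("Subarctic_day_400-600m" = 1,
                                 "Subarctic_day_600-800m" = 1,
                                 "Subarctic_night_0-25m" = 1,
                                 "Subarctic_night_25-50m" = 1)))
  d3 <- detect_dvm(fx3$rel, fx3$counts, fx3$meta, "t1", default_strata())
  expect_false(d3$stations$c3[1])

  # C4: shift of one stratum only (day WMD 225 -> index 4,
  # night WMD 112.5 -> index 3)
  fx4 <- dvm_fixture(list(t1 = c("Subarctic_day_100-200m" = 150,
                                 "Subarctic_day_200-400m" = 150,
                                 "Subarctic_night_50-100m" = 150,
                                 "Subarctic_night_100-200m" = 150)))
  d4 <- detect_dvm(fx4$rel, fx4$counts, fx4$meta, "t1", default_strata())
  st4 <- d4$stations[d4$stations$station == "Subarctic", ]
  expect_true(st4$c1 && st4$c2 && st4$c3)
  expect_false(st4$c4)
})

test_that("a planted migrator passes all four criteria, checked by hand", {
  fx <- dvm_fixture(list(t1 = c("Subarctic_day_400-600m" = 400,
                                "Subarctic_day_600-800m" = 100,
                                "Subarctic_night_25-50m" = 350,
                                "Subarctic_night_50-100m" = 100)))
  d <- detect_dvm(fx$rel, fx$counts, fx$meta, "t1", default_strata())
  st <- d$stations[d$stations$station == "Subarctic", ]
  # C1 by hand: 2 day nets, 2 night nets
  expect_true(st$c1)
  # C2 by hand: tow totals both 500/(tow reads); ratio ~ 1.07
  a_day <- 500 / (500 + 8 * 1000 - 0)  # filler contributes 1000 per net
  a_night <- 450 / (450 + 8 * 1000)
  expect_lt(max(a_day, a_night) / min(a_day, a_night), 2)
  expect_true(st$c2)
  # C3 by hand: 950 reads of 48*1000 + 950 total > 1e-4
  expect_true(st$c3)
  # C4 by hand: WMD_day in 400-600 (index 5), WMD_night in 25-50/50-100
  wd <- (400 / 1400 * 500 + 100 / 1100 * 700) / (400 / 1400 + 100 / 1100)
  expect_equal(st$wmd_day_m, wd, tolerance = 1e-9)
  expect_true(st$c4)
  expect_equal(d$dvm, "yes")
})

test_that("DVM day/night relabelling flips nothing but the shift sign", {
  fx <- dvm_fixture(list(t1 = c("Subarctic_day_400-600m" = 400,
                                "Subarctic_day_600-800m" = 100,
                                "Subarctic_night_25-50m" = 350,
                                "Subarctic_night_50-100m" = 100)))
  meta_sw <- fx$meta
  meta_sw$tow_period <- ifelse(meta_sw$tow_period == "day", "night", "day")
  d <- detect_dvm(fx$rel, fx$counts, fx$meta, "t1", default_strata())
  dsw <- detect_dvm(fx$rel, fx$counts, meta_sw, "t1", default_strata())
  s1 <- d$stations[d$stations$station == "Subarctic", ]
  s2 <- dsw$stations[dsw$stations$station == "Subarctic", ]
  expect_equal(s1[, c("c1", "c2", "c3", "c4", "pass")],
               s2[, c("c1", "c2", "c3", "c4", "pass")],
               ignore_attr = TRUE)
  expect_equal(s2$wmd_day_m, s1$wmd_night_m)
  expect_equal(s2$wmd_night_m, s1$wmd_day_m)
})

test_that("detect_dvm requires a station with paired tows", {
  fx <- dvm_fixture(list(t1 = c("Subarctic_day_400-600m" = 100)))
  meta_day <- fx$meta[fx$meta$tow_period == "day", ]
  expect_error(detect_dvm(fx$rel, fx$counts, meta_day, "t1",
                          default_strata()),
               "paired")
})

test_that("recovered MDO lands within one stratum of the planted truth", {
  design <- survey_design(seed = 31)
  pl <- planting_config(migrator_fraction = 0, depth_sd_epi_m = 50,
                        depth_sd_meso_m = 50)
  sim <- simulate_survey(design = design, planting = pl, n_taxa = 60)
  rel <- to_relative(sim$matrices$M1)
  m <- mdo_all(rel, sim$meta)
  big <- sim$taxa$global_share >= 0.001
  idx_est <- stratum_index_of_depth(m$mdo_overall_m, design$strata)
  # estimator vs the noiseless expected MDO, for all abundant taxa
  idx_truth <- stratum_index_of_depth(sim$taxa$mdo_expected_m,
                                      design$strata)
  expect_true(all(abs(idx_est - idx_truth)[big] <= 1, na.rm = TRUE))
  # for deep taxa, whose strata are wider than the 50 m spread, the
  # estimate also sits within one stratum of the planted centre itself
  deep <- big & sim$taxa$depth_center_day_m > 200
  idx_ctr <- stratum_index_of_depth(sim$taxa$depth_center_day_m,
                                    design$strata)
  expect_true(all(abs(idx_est - idx_ctr)[deep] <= 1, na.rm = TRUE))
})

test_that("size-depth correlation recovers monotone relationships", {
  md <- data.frame(taxon_id = paste0("t", 1:10), station = "A",
                   tow_period = "day", mdo_m = seq(50, 500, length.out = 10))
  tr <- data.frame(name = paste0("t", 1:10),
                   body_size_mm = seq(1, 10))
  r <- size_depth_correlation(md, tr, "A", "day")
  expect_equal(r$rho, 1)
  tr$body_size_mm <- rev(tr$body_size_mm)
  expect_equal(size_depth_correlation(md, tr, "A", "day")$rho, -1)
  # too few pairs is flagged, not an error
  r2 <- size_depth_correlation(md[1:2, ], tr, "A", "day")
  expect_true(r2$insufficient)
})
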