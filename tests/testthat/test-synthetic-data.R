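test_that("survey design validates strata and defaults to the eight nets", {
  d <- survey_design()
  expect_equal(nrow(d$strata), 8)
  expect_equal(d$strata$upper_m[1], 0)
  expect_equal(d$strata$lower_m[8], 1000)
  expect_error(survey_design(strata = data.frame(upper_m = c(0, 30),
                                                 lower_m = c(50, 100))),
               "contiguous")
  expect_error(survey_design(reads_per_sample = 0), "positive")
})

test_that("stratum indexing is half-open with a closed deepest stratum", {
  st <- default_strata()
  expect_equal(stratum_index_of_depth(c(0, 24.9, 25, 200, 399.9, 1000), st),
               c(0L, 0L, 1L, 4L, 4L, 7L))
  expect_true(is.na(stratum_index_of_depth(1001, st)))
})

test_that("profiles follow the parametric curves exactly at zero noise", {
  spec <- env_field_spec(noise_sd = c(temperature = 0, oxygen = 0, chla = 0))
  design <- survey_design(seed = 3)
  prof <- generate_profiles(spec, design)
  expect_equal(nrow(prof), 3 * 1001)
  sub <- prof[prof$province == "Subtropical", ]
  p <- spec$provinces$Subtropical
  # analytic evaluation of the stated curves
  expect_equal(sub$temperature_C, env_temperature(0:1000, p$temperature))
  expect_equal(sub$oxygen, env_oxygen(0:1000, p$oxygen))
  expect_equal(sub$chla, env_chla(0:1000, p$chla))
  # temperature never increases with depth; Chl-a ~ 0 below 200 m
  expect_true(all(diff(sub$temperature_C) <= 1e-12))
  expect_true(all(sub$chla[sub$depth_m > 200] < 0.05))
})

test_that("profiles are seeded and reproducible", {
  design <- survey_design(seed = 11)
  p1 <- generate_profiles(env_field_spec(), design)
  p2 <- generate_profiles(env_field_spec(), design)
  expect_identical(p1, p2)
  p3 <- generate_profiles(env_field_spec(), survey_design(seed = 12))
  expect_false(identical(p1, p3))
})

test_that("undefined province is a configuration error", {
  spec <- env_field_spec(provinces = list(OnlyOne = env_field_spec()$provinces[[1]]))
  expect_error(generate_profiles(spec, survey_design()), "Subarctic")
})

test_that("depth-preference mass matches numeric integration of the Gaussian", {
  st <- default_strata()
  m <- depth_mass(900, 50, st)
  expect_equal(sum(m), 1, tolerance = 1e-12)
  # independent oracle: integrate the truncated Gaussian over each interval
  norm <- integrate(dnorm, 0, 1000, mean = 900, sd = 50)$value
  for (i in c(1, 6, 8)) {
    ref <- integrate(dnorm, st$upper_m[i], st$lower_m[i], mean = 900,
                     sd = 50)$value / norm
    expect_equal(m[i], ref, tolerance = 1e-3)
  }
  # a deep taxon has far less mass in the surface net than at depth
  expect_lt(m[1], m[8])
})

test_that("migrator assignment replays the documented seeded draw", {
  design <- survey_design(seed = 21)
  taxa <- generate_taxa(100, design,
                        planting_config(migrator_fraction = 0.5))
  set.seed(substream_seed(21, "taxa"))
  expect_identical(taxa$is_migrator, rbinom(100, 1, 0.5) == 1)
})

test_that("planting parameters force the advertised structure", {
  design <- survey_design(seed = 5)
  none <- generate_taxa(40, design, planting_config(migrator_fraction = 0))
  expect_true(all(!none$is_migrator))
  expect_equal(none$depth_center_day_m, none$depth_center_night_m)
  allp <- generate_taxa(40, design,
                        planting_config(occupancy_probs_epi = c(0, 0, 1),
                                        occupancy_probs_meso = c(0, 0, 1)))
  expect_true(all(allp$n_provinces == 3))
  # migrators sit >= 2 strata apart between day and night
  mig <- generate_taxa(60, design, planting_config(migrator_fraction = 1))
  sep <- abs(stratum_index_of_depth(mig$depth_center_day_m, design$strata) -
               stratum_index_of_depth(mig$depth_center_night_m,
                                      design$strata))
  expect_true(all(sep >= 2))
})

test_that("sampled reads are multinomial per sample with exact column sums", {
  design <- survey_design(seed = 9, reads_per_sample = 2000)
  taxa <- generate_taxa(30, design)
  reads <- sample_reads(taxa, design)
  cs <- colSums(reads$matrices$M1$counts)
  expect_true(all(cs == 2000 | cs == 0))
  expect_false(any(reads$meta$all_zero))
})

test_that("occupancy indicator zeroes counts outside occupied provinces", {
  design <- survey_design(seed = 13)
  taxa <- generate_taxa(25, design)
  reads <- sample_reads(taxa, design)
  cts <- reads$matrices$M1$counts
  for (i in seq_len(nrow(taxa))) {
    occ <- strsplit(taxa$occupancy[i], "+", fixed = TRUE)[[1]]
    outside <- reads$meta$sample_id[!reads$meta$province %in% occ]
    expect_true(all(cts[taxa$taxon_id[i], outside] == 0))
  }
})

test_that("a single taxon takes every read in its occupied samples", {
  design <- survey_design(seed = 2, reads_per_sample = 500)
  taxa <- generate_taxa(1, design)
  reads <- sample_reads(taxa, design)
  cts <- reads$matrices$M1$counts
  occ <- strsplit(taxa$occupancy[1], "+", fixed = TRUE)[[1]]
  inside <- reads$meta$sample_id[reads$meta$province %in% occ]
  expect_true(all(cts[1, inside] == 500))
})

test_that("with vanishing depth spread all reads land in the home stratum", {
  design <- survey_design(seed = 4, reads_per_sample = 1000)
  taxa <- generate_taxa(5, design,
                        planting_config(migrator_fraction = 0,
                                        depth_sd_epi_m = 1e-3,
                                        depth_sd_meso_m = 1e-3))
  reads <- sample_reads(taxa, design)
  cts <- reads$matrices$M1$counts
  meta <- reads$meta
  for (i in seq_len(5)) {
    home <- stratum_index_of_depth(taxa$depth_center_day_m[i], design$strata)
    off <- meta$sample_id[meta$stratum_index != home]
    expect_true(all(cts[taxa$taxon_id[i], off] == 0))
  }
})

test_that("expected counts order follows the Gaussian mass over strata", {
  design <- survey_design(seed = 8)
  taxa <- generate_taxa(10, design)
  taxa$depth_center_day_m <- taxa$depth_center_night_m <- 900
  taxa$depth_sd_day_m <- taxa$depth_sd_night_m <- 50
  taxa$occupancy <- "Subarctic+Transition+Subtropical"
  w <- expected_weights(taxa, design)
  meta <- survey_meta(design)
  shallow <- meta$sample_id[meta$stratum_index == 0]
  deep <- meta$sample_id[meta$stratum_index == 7]
  expect_true(all(rowSums(w[, shallow]) < rowSums(w[, deep])))
})

test_that("seeded simulations are bit-reproducible end to end", {
  s1 <- simulate_survey(design = survey_design(seed = 33), n_taxa = 20)
  s2 <- simulate_survey(design = survey_design(seed = 33), n_taxa = 20)
  expect_identical(s1$matrices$M1$counts, s2$matrices$M1$counts)
  expect_identical(s1$taxa, s2$taxa)
  expect_identical(s1$profiles, s2$profiles)
})

test_that("multi-marker simulation splits taxa with configured overlap", {
  design <- survey_design(seed = 17, n_markers = 2, marker_overlap = 0.3)
  taxa <- generate_taxa(50, design)
  reads <- sample_reads(taxa, design)
  expect_named(reads$matrices, c("M1", "M2"))
  det <- reads$detected
  expect_true(all(rowSums(det) >= 1))
  shared <- rowSums(det) == 2
  # non-shared taxa appear in exactly one marker's matrix
  for (i in which(!shared)) {
    m_off <- which(!det[i, ])
    expect_true(all(reads$matrices[[m_off]]$counts[i, ] == 0))
  }
})
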