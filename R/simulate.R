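#' Planting parameters for the synthetic community
#'
#' Controls the ground-truth structure planted in a simulated survey:
#' vertical preferences, diel vertical migration (DVM), province occupancy,
#' read-share distribution and trait assignment.
#'
#' Defaults plant the structure the survey design is meant to recover:
#' distinct epipelagic and mesopelagic resident pools; migrators resident
#' deep by day and shallow by night with planted day/night weighted mean
#' depths at least `migration_min_strata` strata apart; province-specific
#' epipelagic pools (most epipelagic residents endemic to one province)
#' against a broadly shared mesopelagic pool (most mesopelagic residents
#' cosmopolitan). Migrators are a minority of taxa but are abundant
#' (`migrator_share_boost`), so their read-weighted prevalence is well
#' above their taxon-weighted one. Mesopelagic vertical niche breadth
#' grows with depth (`depth_sd_meso_frac` of the daytime centre),
#' reflecting the weakening of environmental gradients below the
#' permanent thermocline.
#'
#' Depth centres are drawn stratified: each taxon is assigned a home
#' stratum (uniform over its zone's strata, per tow period for
#' migrators) and a centre uniform within that stratum, clipped to the
#' configured depth range. This spreads community biomass roughly evenly
#' over the sampled strata in both tow periods — thin surface strata
#' carry surface-intensified per-metre biomass, as in real epipelagic
#' communities — so no net sample is dominated by sparse-community
#' renormalisation artefacts.
#'
#' @param migrator_fraction Probability that a taxon performs DVM.
#' @param migration_min_strata Minimum separation, in strata, between the
#'   strata containing a migrator's planted (noiseless) day and night
#'   weighted mean depths.
#' @param p_mesopelagic Probability that a non-migrating taxon is a
#'   mesopelagic resident.
#' @param epi_depth_range,meso_depth_range Clip bounds (m) for resident
#'   day(=night) depth centres.
#' @param day_depth_range,night_depth_range Clip bounds (m) for migrator
#'   daytime and nighttime depth centres.
#' @param depth_sd_epi_m SD (m) of the Gaussian vertical preference of
#'   epipelagic residents.
#' @param depth_sd_meso_frac Mesopelagic resident SD as a fraction of the
#'   depth centre (overridden by `depth_sd_meso_m` when set).
#' @param depth_sd_meso_m Optional flat mesopelagic resident SD (m).
#' @param migrator_day_sd_m,migrator_night_sd_m Migrator vertical SDs (m)
#'   by tow period.
#' @param migrator_share_boost Multiplier on migrators' raw read shares
#'   before normalisation (migrators are abundant taxa).
#' @param epi_share_boost Multiplier on epipelagic residents' raw shares:
#'   epipelagic standing stock exceeds mesopelagic standing stock, and
#'   the boost offsets the endemism of epipelagic pools so that every net
#'   sample carries comparable community weight in both tow periods.
#' @param province_sdlog_epi,province_sdlog_meso Log-normal SD of
#'   per-province abundance multipliers for epipelagic residents and for
#'   mesopelagic residents/migrators. Environmental selection acts more
#'   strongly on epipelagic communities, so shared epipelagic taxa vary
#'   in abundance among provinces much more than deep-living taxa.
#' @param occupancy_probs_epi,occupancy_probs_meso Probabilities that a
#'   taxon of each planted habitat occupies 1, 2, ... provinces.
#' @param share_meanlog,share_sdlog Log-normal parameters for raw global
#'   read shares (normalised to sum to 1 across taxa).
#' @param p_asexual Probability that a taxon is capable of asexual
#'   reproduction.
#' @param asexual_wide_occupancy If `TRUE`, taxa with asexual reproduction
#'   get the mesopelagic (wide) occupancy distribution regardless of
#'   habitat, planting a recoverable trait effect on distributional range.
#' @return An object of class `planting_config`.
#' @export
planting_config <- function(migrator_fraction = 0.15,
                            migration_min_strata = 2L,
                            p_mesopelagic = 0.5,
                            epi_depth_range = c(5, 195),
                            meso_depth_range = c(500, 850),
                            day_depth_range = c(300, 700),
                            night_depth_range = c(5, 150),
                            depth_sd_epi_m = 40,
                            depth_sd_meso_frac = 0.22,
                            depth_sd_meso_m = NULL,
                            migrator_day_sd_m = 60,
                            migrator_night_sd_m = 30,
                            migrator_share_boost = 1.5,
                            epi_share_boost = 3,
                            province_sdlog_epi = 1,
                            province_sdlog_meso = 0.3,
                            occupancy_probs_epi = c(0.7, 0.2, 0.1),
                            occupancy_probs_meso = c(0.1, 0.2, 0.7),
                            share_meanlog = 0,
                            share_sdlog = 1,
                            p_asexual = 0.2,
                            asexual_wide_occupancy = FALSE) {
  stopifnot(migrator_fraction >= 0, migrator_fraction <= 1,
            depth_sd_epi_m > 0, migrator_day_sd_m > 0,
            migrator_night_sd_m > 0, migrator_share_boost > 0)
  structure(as.list(environment()), class = "planting_config")
}

#' Gaussian depth-preference mass per stratum
#'
#' Mass of a truncated Gaussian vertical distribution within each stratum,
#' computed by numeric integration at 1-m resolution (density evaluated at
#' 1-m bin centres over [0, 1000) and normalised), consistent with the
#' half-open `[upper, lower)` stratum convention.
#'
#' @param center_m,sd_m Gaussian centre and SD (m).
#' @param strata Strata data frame.
#' @return Numeric vector of per-stratum masses summing to 1.
#' @export
depth_mass <- function(center_m, sd_m, strata) {
  zc <- seq(0.5, 999.5, by = 1)
  dens <- dnorm(zc, center_m, sd_m)
  tot <- sum(dens)
  if (tot == 0) { # numerically degenerate: all mass in containing stratum
    idx <- stratum_index_of_depth(center_m, strata)
    out <- numeric(nrow(strata))
    out[idx + 1L] <- 1
    return(out)
  }
  vapply(seq_len(nrow(strata)), function(i) {
    inbin <- zc > strata$upper_m[i] & zc < strata$lower_m[i]
    sum(dens[inbin]) / tot
  }, numeric(1))
}

#' Generate planted taxa with ground-truth labels
#'
#' Draws, deterministically for the design seed, a community of taxa with
#' known vertical distributions, DVM behaviour, province occupancy, global
#' read shares and traits. The first random draw is the vectorised binomial
#' migrator assignment, so it can be replayed to audit the generator.
#'
#' Ground-truth habitat is the habitat implied by the planted depth
#' centres: the noiseless (infinite-read) mean depth of occurrence of the
#' taxon under this design and community, thresholded at 200 m. Ground
#' truth also records, per occupied province, the maximum expected read
#' count over that province's net samples (`min_expected_peak`, minimised
#' over occupied provinces), which bounds how detectable the taxon is.
#'
#' @param n_taxa Number of taxa.
#' @param design A [survey_design()].
#' @param planting A [planting_config()].
#' @return Data frame (one row per taxon): `taxon_id`, `is_migrator`,
#'   `depth_center_day_m`, `depth_center_night_m`, `depth_sd_day_m`,
#'   `depth_sd_night_m`,
#'   `global_share`, `occupancy` ("+"-joined province labels in design
#'   order), `n_provinces`, `habitat` (ground truth), `mdo_expected_m`,
#'   `min_expected_peak`, and trait columns (`body_size_mm`, `diet`,
#'   `feeding`, `spawning`, `asexual`, `composition`).
#' @export
generate_taxa <- function(n_taxa, design, planting = planting_config()) {
  stopifnot(n_taxa >= 1, inherits(design, "survey_design"),
            inherits(planting, "planting_config"))
  pl <- planting
  set.seed(substream_seed(design$seed, "taxa"))

  is_migrator <- rbinom(n_taxa, 1, pl$migrator_fraction) == 1

  # stratified centre draw: a home stratum uniform over the zone's
  # strata, then a centre uniform within it (clipped to the bounds)
  st <- design$strata
  epi_strata <- which(st$lower_m <= 200)
  deep_strata <- which(st$upper_m >= 200)
  stratified_draw <- function(strata_idx, bounds) {
    repeat {
      h <- strata_idx[sample.int(length(strata_idx), 1)]
      lo <- max(st$upper_m[h], bounds[1])
      hi <- min(st$lower_m[h], bounds[2])
      if (lo < hi) return(runif(1, lo, hi))
    }
  }
  # noiseless single-taxon WMD: depth-preference mass-weighted stratum
  # midpoints, the deterministic limit of the per-tow MDO estimator
  mids <- (st$upper_m + st$lower_m) / 2
  wmd0 <- function(center, sd) {
    sum(depth_mass(center, sd, st) * mids)
  }
  day_c <- night_c <- sd_day <- sd_night <- numeric(n_taxa)
  epi_resident <- logical(n_taxa)
  for (i in seq_len(n_taxa)) {
    if (is_migrator[i]) {
      # redraw until the planted day/night WMDs sit >= min_strata apart,
      # so the migration amplitude is expressed in the detector's units
      repeat {
        day_c[i] <- stratified_draw(deep_strata, pl$day_depth_range)
        night_c[i] <- stratified_draw(epi_strata, pl$night_depth_range)
        sep <- abs(
          stratum_index_of_depth(wmd0(day_c[i], pl$migrator_day_sd_m),
                                 st) -
            stratum_index_of_depth(wmd0(night_c[i], pl$migrator_night_sd_m),
                                   st))
        if (sep >= pl$migration_min_strata) break
      }
      sd_day[i] <- pl$migrator_day_sd_m
      sd_night[i] <- pl$migrator_night_sd_m
    } else {
      meso <- runif(1) < pl$p_mesopelagic
      if (meso) {
        day_c[i] <- night_c[i] <- stratified_draw(deep_strata,
                                                  pl$meso_depth_range)
        sd_day[i] <- sd_night[i] <-
          if (is.null(pl$depth_sd_meso_m)) pl$depth_sd_meso_frac * day_c[i]
          else pl$depth_sd_meso_m
      } else {
        day_c[i] <- night_c[i] <- stratified_draw(epi_strata,
                                                  pl$epi_depth_range)
        sd_day[i] <- sd_night[i] <- pl$depth_sd_epi_m
        epi_resident[i] <- TRUE
      }
    }
  }

  raw_share <- rlnorm(n_taxa, pl$share_meanlog, pl$share_sdlog)
  raw_share[is_migrator] <- raw_share[is_migrator] * pl$migrator_share_boost
  raw_share[epi_resident] <- raw_share[epi_resident] * pl$epi_share_boost
  global_share <- raw_share / sum(raw_share)

  # per-province abundance multipliers (stronger provincial structure in
  # the epipelagic than in the deep community)
  P <- length(design$provinces)
  prov_sdlog <- ifelse(epi_resident, pl$province_sdlog_epi,
                       pl$province_sdlog_meso)
  prov_mult <- matrix(rlnorm(n_taxa * P, 0, rep(prov_sdlog, P)),
                      n_taxa, P,
                      dimnames = list(NULL, design$provinces))

  # traits (drawn before occupancy so occupancy can depend on them)
  traits <- data.frame(
    body_size_mm = round(rlnorm(n_taxa, log(2), 1), 2),
    diet = sample(c("carnivore", "omnivore", "herbivore"), n_taxa,
                  replace = TRUE, prob = c(0.25, 0.5, 0.25)),
    feeding = sample(c("ambush", "cruise", "parasitoid", "suspension"),
                     n_taxa, replace = TRUE, prob = c(0.2, 0.3, 0.1, 0.4)),
    spawning = sample(c("broadcast", "brooding"), n_taxa, replace = TRUE,
                      prob = c(0.8, 0.2)),
    asexual = sample(c("yes", "no"), n_taxa, replace = TRUE,
                     prob = c(pl$p_asexual, 1 - pl$p_asexual)),
    composition = sample(c("gelatinous", "intermediate", "non-gelatinous"),
                         n_taxa, replace = TRUE, prob = c(0.15, 0.15, 0.7))
  )

  # provisional habitat from planted centres decides the occupancy pool;
  # migrators use both zones and get the wide (mesopelagic) distribution
  centre_mid <- (day_c + night_c) / 2
  wide_pool <- is_migrator | centre_mid > 200
  if (pl$asexual_wide_occupancy) wide_pool <- wide_pool | traits$asexual == "yes"

  P <- length(design$provinces)
  occupancy <- character(n_taxa)
  n_prov <- integer(n_taxa)
  for (i in seq_len(n_taxa)) {
    probs <- if (wide_pool[i]) pl$occupancy_probs_meso else pl$occupancy_probs_epi
    probs <- probs[seq_len(min(length(probs), P))]
    k <- sample.int(length(probs), 1, prob = probs)
    occ <- sort(sample.int(P, k))
    occupancy[i] <- paste(design$provinces[occ], collapse = "+")
    n_prov[i] <- k
  }

  taxa <- data.frame(
    taxon_id = sprintf("t%04d", seq_len(n_taxa)),
    is_migrator = is_migrator,
    depth_center_day_m = day_c,
    depth_center_night_m = night_c,
    depth_sd_day_m = sd_day,
    depth_sd_night_m = sd_night,
    global_share = global_share,
    occupancy = occupancy,
    n_provinces = n_prov
  )
  taxa <- cbind(taxa, traits)
  colnames(prov_mult) <- paste0("share_mult_", design$provinces)
  taxa <- cbind(taxa, prov_mult)

  # noiseless ground truth under this design and community
  ew <- expected_weights(taxa, design)
  meta <- survey_meta(design)
  rel <- sweep(ew, 2, pmax(colSums(ew), .Machine$double.xmin), "/")
  taxa$mdo_expected_m <- vapply(seq_len(n_taxa), function(i) {
    w <- rel[i, ]
    occ <- w > 0
    if (!any(occ)) return(NA_real_)
    sum(w[occ] * meta$stratum_midpoint_m[occ]) / sum(w[occ])
  }, numeric(1))
  taxa$habitat <- classify_habitat(taxa$mdo_expected_m)
  exp_counts <- rel * design$reads_per_sample
  taxa$min_expected_peak <- vapply(seq_len(n_taxa), function(i) {
    provs <- strsplit(taxa$occupancy[i], "+", fixed = TRUE)[[1]]
    min(vapply(provs, function(pv) {
      max(exp_counts[i, meta$province == pv])
    }, numeric(1)))
  }, numeric(1))
  taxa
}

#' Expected (pre-multinomial) taxon weights per sample
#'
#' Expected weight of each taxon in each net sample: global share times the
#' Gaussian depth-preference mass over the stratum (day centres for day
#' tows, night centres for night tows) times the province-occupancy
#' indicator. Columns are proportional to expected community composition.
#'
#' @param taxa Data frame from [generate_taxa()].
#' @param design A [survey_design()].
#' @return Matrix taxa x samples of non-negative weights.
#' @export
expected_weights <- function(taxa, design) {
  meta <- survey_meta(design)
  n <- nrow(taxa)
  w <- matrix(0, n, nrow(meta),
              dimnames = list(taxa$taxon_id, meta$sample_id))
  mass_day <- t(vapply(seq_len(n), function(i)
    depth_mass(taxa$depth_center_day_m[i], taxa$depth_sd_day_m[i],
               design$strata),
    numeric(nrow(design$strata))))
  mass_night <- t(vapply(seq_len(n), function(i)
    depth_mass(taxa$depth_center_night_m[i], taxa$depth_sd_night_m[i],
               design$strata),
    numeric(nrow(design$strata))))
  occ_sets <- strsplit(taxa$occupancy, "+", fixed = TRUE)
  for (j in seq_len(nrow(meta))) {
    mass <- if (meta$tow_period[j] == "day") mass_day else mass_night
    sidx <- meta$stratum_index[j] + 1L
    occ <- vapply(occ_sets, function(s) meta$province[j] %in% s, logical(1))
    mult_col <- paste0("share_mult_", meta$province[j])
    mult <- if (mult_col %in% names(taxa)) taxa[[mult_col]] else 1
    w[, j] <- taxa$global_share * mass[, sidx] * occ * mult
  }
  w
}

#' Draw read-count matrices for a planted community
#'
#' One sample per (province, tow period, stratum). Counts are multinomial
#' with `reads_per_sample` trials over the expected taxon weights of
#' [expected_weights()]; samples whose weights are all zero stay all-zero
#' and are flagged in the metadata. With `n_markers > 1`, taxa are split
#' into marker detection sets (a seeded fraction `marker_overlap` detected
#' by all markers, the rest by exactly one) and reads are drawn
#' independently per marker over its detected taxa.
#'
#' @param taxa Data frame from [generate_taxa()].
#' @param design A [survey_design()].
#' @return List with `matrices` (named list of counts-mode [read_matrix()]
#'   objects, one per marker), `meta` (sample metadata with an `all_zero`
#'   logical column: all-zero in every marker), and `detected` (logical
#'   taxa x markers matrix).
#' @export
sample_reads <- function(taxa, design) {
  stopifnot(nrow(taxa) >= 1)
  meta <- survey_meta(design)
  w <- expected_weights(taxa, design)
  n <- nrow(taxa)
  markers <- paste0("M", seq_len(design$n_markers))

  set.seed(substream_seed(design$seed, "markers"))
  detected <- matrix(TRUE, n, design$n_markers,
                     dimnames = list(taxa$taxon_id, markers))
  if (design$n_markers > 1) {
    shared <- runif(n) < design$marker_overlap
    assigned <- sample.int(design$n_markers, n, replace = TRUE)
    for (m in seq_len(design$n_markers)) {
      detected[, m] <- shared | assigned == m
    }
  }

  set.seed(substream_seed(design$seed, "reads"))
  matrices <- lapply(seq_along(markers), function(m) {
    counts <- matrix(0L, n, nrow(meta),
                     dimnames = list(taxa$taxon_id, meta$sample_id))
    wm <- w * detected[, m]
    for (j in seq_len(nrow(meta))) {
      if (sum(wm[, j]) > 0) {
        counts[, j] <- rmultinom(1, design$reads_per_sample, wm[, j])[, 1]
      }
    }
    read_matrix(counts, marker = markers[m], mode = "counts")
  })
  names(matrices) <- markers
  meta$all_zero <- Reduce(`&`, lapply(matrices,
                                      function(mt) colSums(mt$counts) == 0))
  list(matrices = matrices, meta = meta, detected = detected)
}

#' Simulate a complete depth-stratified metabarcoding survey
#'
#' Convenience wrapper: generates CTD profiles, planted taxa, read-count
#' matrices and the trait table for one survey, all reproducible from the
#' design seed.
#'
#' @param design A [survey_design()].
#' @param env An [env_field_spec()].
#' @param planting A [planting_config()].
#' @param n_taxa Number of taxa to plant.
#' @return List with `design`, `profiles`, `taxa` (ground truth),
#'   `traits` (trait table keyed by taxonomic name), `matrices`, `meta`,
#'   `detected`.
#' @export
simulate_survey <- function(design = survey_design(),
                            env = env_field_spec(),
                            planting = planting_config(),
                            n_taxa = 100) {
  profiles <- generate_profiles(env, design)
  taxa <- generate_taxa(n_taxa, design, planting)
  reads <- sample_reads(taxa, design)
  traits <- data.frame(
    name = taxa$taxon_id,
    taxa[, c("body_size_mm", "diet", "feeding", "spawning", "asexual",
             "composition")]
  )
  list(design = design, profiles = profiles, taxa = taxa, traits = traits,
       matrices = reads$matrices, meta = reads$meta,
       detected = reads$detected)
}
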