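#' Full run configuration
#'
#' Bundles the survey (simulated by default), the analysis thresholds
#' (all defaulting to the standard values: 200 m habitat boundary; DVM
#' rule of >= 2 nets per tow, <= 2-fold day/night abundance ratio,
#' >= 0.01% of study reads, >= 2 strata WMD shift), ordination and
#' permutation settings, and the master seed.
#'
#' @param n_taxa Taxa to plant when simulating.
#' @param design A [survey_design()] (its seed is overridden by `seed`).
#' @param env An [env_field_spec()].
#' @param planting A [planting_config()].
#' @param input Optional list of paths for real inputs instead of
#'   simulation: `matrices` (named by marker), `meta`, `ctd`, `traits`.
#' @param habitat_boundary_m Epipelagic/mesopelagic boundary (m).
#' @param dvm [dvm_criteria()] thresholds.
#' @param rarefy_to Optional rarefaction depth for richness tables.
#' @param nmds_starts Random starts for nMDS.
#' @param n_perm Permutations for the beta-dispersion permutation test.
#' @param seed Master seed.
#' @param out_dir Optional directory to write all report tables (TSV).
#' @return List of class `run_config`.
#' @export
run_config <- function(n_taxa = 100,
                       design = survey_design(),
                       env = env_field_spec(),
                       planting = planting_config(),
                       input = NULL,
                       habitat_boundary_m = 200,
                       dvm = dvm_criteria(),
                       rarefy_to = NULL,
                       nmds_starts = 20,
                       n_perm = 999,
                       seed = 1L,
                       out_dir = NULL) {
  stopifnot(habitat_boundary_m > 0)
  design$seed <- as.integer(seed)
  structure(as.list(environment()), class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Reads a flat YAML document whose keys mirror the [run_config()],
#' [survey_design()], [planting_config()] and [dvm_criteria()] arguments
#' (e.g. `n_taxa`, `seed`, `reads_per_sample`, `n_markers`,
#' `migrator_fraction`, `min_study_share`, `rarefy_to`, `out_dir`).
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  take <- function(f, keys) do.call(f, y[intersect(keys, names(y))])
  design <- take(survey_design,
                 c("provinces", "reads_per_sample", "n_markers",
                   "marker_overlap"))
  planting <- take(planting_config,
                   c("migrator_fraction", "depth_sd_m",
                     "migration_min_strata", "p_mesopelagic",
                     "share_meanlog", "share_sdlog",
                     "asexual_wide_occupancy"))
  dvm <- take(dvm_criteria, c("min_nets", "max_fold", "min_study_share",
                              "min_strata_shift"))
  args <- y[intersect(c("n_taxa", "habitat_boundary_m", "rarefy_to",
                        "nmds_starts", "n_perm", "seed", "out_dir"),
                      names(y))]
  do.call(run_config, c(args, list(design = design, planting = planting,
                                   dvm = dvm)))
}

#' Per-taxon metrics table
#'
#' Assembles, for every taxon of one marker (or the combined matrix), the
#' overall MDO, habitat class, DVM label, province occupancy, observed
#' global read share and environmental ranges.
#'
#' @param matrix_counts Counts-mode [read_matrix()].
#' @param meta Sample metadata.
#' @param envs Net environments from [net_environment()].
#' @param criteria [dvm_criteria()].
#' @param boundary_m Habitat boundary (m).
#' @return Data frame, one row per taxon.
#' @export
taxon_metrics_table <- function(matrix_counts, meta, envs,
                                criteria = dvm_criteria(),
                                boundary_m = 200) {
  rel <- to_relative(matrix_counts)
  strata <- unique(meta[order(meta$stratum_index),
                        c("stratum_upper_m", "stratum_lower_m")])
  names(strata) <- c("upper_m", "lower_m")
  m <- mdo_all(rel, meta)
  m$habitat <- classify_habitat(m$mdo_overall_m, boundary_m)
  dvm <- dvm_table(rel, matrix_counts, meta, strata, criteria)
  m$dvm <- dvm$dvm[match(m$taxon_id, dvm$taxon_id)]
  occ <- occupancy_partition(matrix_counts, meta, "full")
  m$occupancy <- occ$taxa$occupancy[match(m$taxon_id, occ$taxa$taxon_id)]
  m$n_provinces <- occ$taxa$n_provinces[match(m$taxon_id, occ$taxa$taxon_id)]
  er <- env_range_table(matrix_counts, meta, envs)
  m <- merge(m, er, by = "taxon_id", sort = FALSE)
  m$global_share <- rowSums(matrix_counts$counts[m$taxon_id, meta$sample_id,
                                                 drop = FALSE]) /
    sum(matrix_counts$counts)
  m
}

#' Habitat vs number-of-provinces association
#'
#' Chi-square test of independence between habitat class (epipelagic /
#' mesopelagic) and the number of provinces in which each taxon was
#' observed.
#'
#' @param metrics A [taxon_metrics_table()].
#' @return A `test_result` (see [chi_square_independence()]).
#' @export
habitat_occupancy_chisq <- function(metrics) {
  ok <- !is.na(metrics$habitat) & !is.na(metrics$n_provinces)
  chi_square_independence(table(metrics$habitat[ok],
                                metrics$n_provinces[ok]))
}

#' Environmental-range vs occupancy-class contrasts
#'
#' Within one habitat class, Kruskal-Wallis of each environmental range
#' (temperature, Chl-a, oxygen) across taxa observed in 1, 2, ...
#' provinces, with Dunn's Bonferroni-adjusted pairwise comparisons when
#' more than two occupancy classes are present.
#'
#' @param metrics A [taxon_metrics_table()].
#' @param habitat `"epipelagic"` or `"mesopelagic"`.
#' @return List `tests` (data frame) and `pairwise` (data frame).
#' @export
env_occupancy_contrasts <- function(metrics,
                                    habitat = c("epipelagic",
                                                "mesopelagic")) {
  habitat <- match.arg(habitat)
  sub <- metrics[!is.na(metrics$habitat) & metrics$habitat == habitat, ]
  contrast_battery(sub, group_col = "n_provinces",
                   variables = c("range_temperature", "range_chla",
                                 "range_oxygen"),
                   label = paste0(habitat, ":occupancy"))
}

#' Trait-state contrasts of environmental and distributional ranges
#'
#' For each trait and each of temperature range, Chl-a range, oxygen range
#' and number of provinces: Kruskal-Wallis across trait states (Dunn's
#' pairwise when more than two states). Epipelagic and mesopelagic scopes
#' filter taxa by habitat; the DVM trait is contrasted across the full
#' water column (migrators use both zones), which is the `"all"` scope.
#'
#' @param metrics A [taxon_metrics_table()].
#' @param traits Trait table keyed by `name`.
#' @param scope `"epipelagic"`, `"mesopelagic"` or `"all"`.
#' @param trait_cols Traits to contrast; defaults to the categorical
#'   traits for habitat scopes and `"dvm"` for the full-column scope.
#' @return List `tests` and `pairwise` data frames.
#' @export
trait_contrasts <- function(metrics, traits,
                            scope = c("epipelagic", "mesopelagic", "all"),
                            trait_cols = NULL) {
  scope <- match.arg(scope)
  if (is.null(trait_cols)) {
    trait_cols <- if (scope == "all") "dvm" else
      c("diet", "feeding", "spawning", "asexual", "composition")
  }
  sub <- if (scope == "all") metrics else
    metrics[!is.na(metrics$habitat) & metrics$habitat == scope, ]
  # join traits on the taxonomic name (marker prefixes stripped)
  plain_id <- sub("^[^:]+:", "", sub$taxon_id)
  for (tc in setdiff(trait_cols, names(sub))) {
    sub[[tc]] <- traits[[tc]][match(plain_id, traits$name)]
  }
  vars <- c("range_temperature", "range_chla", "range_oxygen",
            "n_provinces")
  tests <- list(); pairwise <- list()
  for (tc in trait_cols) {
    res <- contrast_battery(sub, group_col = tc, variables = vars,
                            label = paste0(scope, ":", tc))
    tests[[tc]] <- res$tests
    pairwise[[tc]] <- res$pairwise
  }
  list(tests = do.call(rbind, c(tests, list(make.row.names = FALSE))),
       pairwise = do.call(rbind, c(pairwise,
                                   list(make.row.names = FALSE))))
}

# Kruskal-Wallis (+ Dunn when > 2 states) of each variable across the
# states of one grouping column; states with no data are dropped with a
# warning, single-state cases are flagged untested.
contrast_battery <- function(df, group_col, variables, label) {
  tests <- list(); pairwise <- list()
  for (v in variables) {
    ok <- !is.na(df[[group_col]]) & !is.na(df[[v]])
    g <- droplevels(as.factor(df[[group_col]][ok]))
    x <- df[[v]][ok]
    row <- data.frame(contrast = label, group_by = group_col,
                      variable = v, n = length(x),
                      n_states = nlevels(g), statistic = NA_real_,
                      df = NA_real_, p = NA_real_, note = "")
    if (nlevels(g) < 2 || length(x) < 3) {
      row$note <- "untested: <2 states or n<3"
      warning(label, " / ", v, ": ", row$note)
    } else {
      kw <- kruskal_wallis(x, g)
      row$statistic <- kw$statistic; row$df <- kw$df; row$p <- kw$p
      if (kw$degenerate) row$note <- "degenerate: all values identical"
      if (nlevels(g) > 2 && !kw$degenerate) {
        pw <- dunn_posthoc(x, g)
        pw <- cbind(data.frame(contrast = label, variable = v), pw)
        pairwise[[paste(label, v)]] <- pw
      }
    }
    tests[[v]] <- row
  }
  list(tests = do.call(rbind, c(tests, list(make.row.names = FALSE))),
       pairwise = if (length(pairwise))
         do.call(rbind, c(pairwise, list(make.row.names = FALSE)))
       else data.frame())
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) a survey, then produces, deterministically for the
#' configured seed and per dataset (each marker plus the marker-combined
#' matrix when several markers are present): the per-taxon metrics table,
#' occupancy partitions for the full column, epipelagic and mesopelagic
#' scopes, richness tables (observed and, if configured, rarefied),
#' Bray-Curtis and Jaccard distance matrices, nMDS coordinates,
#' epipelagic-vs-mesopelagic beta-dispersion, the habitat x occupancy
#' chi-square, environmental-range x occupancy contrasts per habitat, and
#' trait contrasts (including the full-column DVM contrast).
#'
#' @param config A [run_config()].
#' @return List with `data` (simulation/ingest products), `datasets`
#'   (named list of per-dataset result bundles) and `manifest`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  warnings_log <- character(0)
  note <- function(...) {
    msg <- paste0(...)
    warnings_log <<- c(warnings_log, msg)
    message("[zoopvert] ", msg)
  }

  if (is.null(config$input)) {
    note("stage simulate: ", config$n_taxa, " taxa, ",
         length(config$design$provinces), " provinces, seed ",
         config$seed)
    sim <- simulate_survey(config$design, config$env, config$planting,
                           config$n_taxa)
  } else {
    note("stage ingest: reading input tables")
    mats <- lapply(names(config$input$matrices), function(mk) {
      read_read_matrix(config$input$matrices[[mk]], marker = mk)
    })
    names(mats) <- names(config$input$matrices)
    sim <- list(design = config$design,
                profiles = read_ctd_profiles(config$input$ctd),
                taxa = NULL,
                traits = read_trait_table(config$input$traits),
                matrices = mats,
                meta = read_sample_meta(config$input$meta))
  }

  envs <- net_environment(sim$profiles, sim$meta)

  mats <- sim$matrices
  if (length(mats) > 1) {
    mats <- c(mats, list(combined = combine_markers(unname(mats))))
  }

  datasets <- lapply(names(mats), function(nm) {
    note("stage analyze [", nm, "]: ", nrow(mats[[nm]]$counts), " taxa x ",
         ncol(mats[[nm]]$counts), " samples")
    analyze_dataset(mats[[nm]], sim$meta, envs, sim$traits, config)
  })
  names(datasets) <- names(mats)

  manifest <- list(
    seed = config$seed,
    config_hash = config_hash(config),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("zoopvert")),
    datasets = names(datasets),
    tables = c(metrics = "taxon_metrics_table",
               occupancy_full = "occupancy_partition",
               occupancy_epipelagic = "occupancy_partition",
               occupancy_mesopelagic = "occupancy_partition",
               richness_sample = "richness",
               richness_zone = "richness",
               bray_curtis = "distance_matrix",
               jaccard = "distance_matrix",
               nmds = "nmds_ordination",
               beta_dispersion_bray = "beta_dispersion",
               beta_dispersion_jaccard = "beta_dispersion",
               habitat_occupancy_chisq = "habitat_occupancy_chisq",
               env_occupancy = "env_occupancy_contrasts",
               trait_contrasts = "trait_contrasts"),
    log = warnings_log
  )
  out <- list(data = sim, envs = envs, datasets = datasets,
              manifest = manifest)
  if (!is.null(config$out_dir)) write_report(out, config$out_dir)
  out
}

analyze_dataset <- function(mat_counts, meta, envs, traits, config) {
  rel <- to_relative(mat_counts)
  metrics <- taxon_metrics_table(mat_counts, meta, envs, config$dvm,
                                 config$habitat_boundary_m)
  occ <- lapply(c(full = "full", epipelagic = "epipelagic",
                  mesopelagic = "mesopelagic"), function(sc) {
    occupancy_partition(mat_counts, meta, sc,
                        boundary_m = config$habitat_boundary_m)
  })
  rich <- list(
    sample = richness(mat_counts, meta, "sample",
                      rarefy_to = config$rarefy_to, seed = config$seed),
    zone = richness(mat_counts, meta, "depth_zone",
                    rarefy_to = config$rarefy_to, seed = config$seed),
    province = richness(mat_counts, meta, "province",
                        rarefy_to = config$rarefy_to, seed = config$seed)
  )
  d_bray <- distance_matrix(rel, "bray_curtis")
  d_jac <- distance_matrix(mat_counts, "jaccard")
  zones <- depth_zone(meta, config$habitat_boundary_m)
  ord <- nmds_ordination(d_bray, k = 2, n_starts = config$nmds_starts,
                         seed = config$seed)
  bd <- list(
    bray_curtis = beta_dispersion(d_bray, zones, config$n_perm,
                                  config$seed),
    jaccard = beta_dispersion(d_jac, zones, config$n_perm, config$seed)
  )
  contrasts <- withCallingHandlers({
    list(
      habitat_occupancy = habitat_occupancy_chisq(metrics),
      env_occupancy_epi = env_occupancy_contrasts(metrics, "epipelagic"),
      env_occupancy_meso = env_occupancy_contrasts(metrics, "mesopelagic"),
      traits_epi = trait_contrasts(metrics, traits, "epipelagic"),
      traits_meso = trait_contrasts(metrics, traits, "mesopelagic"),
      dvm_full = trait_contrasts(metrics, traits, "all")
    )
  }, warning = function(w) invokeRestart("muffleWarning"))
  list(metrics = metrics, occupancy = occ, richness = rich,
       distances = list(bray_curtis = d_bray, jaccard = d_jac),
       nmds = ord, beta_dispersion = bd, contrasts = contrasts)
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f, version = 2)
  unname(tools::md5sum(f))
}

write_report <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) {
    write.table(df, file.path(out_dir, paste0(name, ".tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  for (nm in names(result$datasets)) {
    ds <- result$datasets[[nm]]
    tsv(ds$metrics, paste0(nm, "_taxon_metrics"))
    for (sc in names(ds$occupancy)) {
      oc <- ds$occupancy[[sc]]
      tsv(data.frame(subset = names(oc$counts), n_taxa = oc$counts),
          paste0(nm, "_occupancy_", sc))
    }
    for (g in names(ds$richness)) {
      tsv(ds$richness[[g]], paste0(nm, "_richness_", g))
    }
    for (m in names(ds$distances)) {
      dm <- as.matrix(ds$distances[[m]])
      write.csv(dm, file.path(out_dir, paste0(nm, "_", m, ".csv")))
    }
    tsv(data.frame(sample_id = rownames(ds$nmds$points), ds$nmds$points,
                   stress = ds$nmds$stress), paste0(nm, "_nmds"))
    tsv(ds$contrasts$env_occupancy_epi$tests,
        paste0(nm, "_env_occupancy_epipelagic"))
    tsv(ds$contrasts$env_occupancy_meso$tests,
        paste0(nm, "_env_occupancy_mesopelagic"))
    tsv(ds$contrasts$traits_epi$tests, paste0(nm, "_traits_epipelagic"))
    tsv(ds$contrasts$traits_meso$tests, paste0(nm, "_traits_mesopelagic"))
    tsv(ds$contrasts$dvm_full$tests, paste0(nm, "_dvm_contrasts"))
  }
  manifest <- result$manifest
  manifest$tables <- as.list(manifest$tables)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yml"))
  invisible(out_dir)
}
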