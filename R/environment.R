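#' Mean environmental conditions per net depth range
#'
#' Averages the 1-m binned CTD values of each province's profile over every
#' stratum interval to give the mean conditions experienced by that
#' province-stratum's samples. Intervals are half-open `[upper, lower)`
#' against integer-depth bins; the deepest stratum is closed at its lower
#' bound (so 800-1000 m averages 201 bins). Day and night tows at a
#' station share one CTD environment.
#'
#' @param profiles CTD profiles data frame (see [read_ctd_profiles()]).
#' @param meta Sample metadata (provinces and strata are taken from it).
#' @return Data frame, one row per (province, stratum): `province`,
#'   `stratum_index`, `stratum_upper_m`, `stratum_lower_m`,
#'   `mean_temperature_C`, `mean_oxygen`, `mean_chla`.
#' @export
net_environment <- function(profiles, meta) {
  cells <- unique(meta[, c("province", "stratum_index", "stratum_upper_m",
                           "stratum_lower_m")])
  cells <- cells[order(cells$province, cells$stratum_index), ]
  deepest <- max(meta$stratum_lower_m)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    pv <- cells$province[i]
    upper <- cells$stratum_upper_m[i]
    lower <- cells$stratum_lower_m[i]
    prof <- profiles[profiles$province == pv, ]
    if (!nrow(prof)) stop("no CTD profile for province ", pv)
    bins <- if (lower == deepest) upper:lower else upper:(lower - 1)
    sel <- match(bins, prof$depth_m)
    if (anyNA(sel)) {
      stop(sprintf("CTD profile for %s has a gap in [%g, %g] m (first at %g m)",
                   pv, upper, lower, bins[which(is.na(sel))[1]]))
    }
    data.frame(province = pv, stratum_index = cells$stratum_index[i],
               stratum_upper_m = upper, stratum_lower_m = lower,
               mean_temperature_C = mean(prof$temperature_C[sel]),
               mean_oxygen = mean(prof$oxygen[sel]),
               mean_chla = mean(prof$chla[sel]))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Environmental range inhabited by one taxon
#'
#' Collects the net-mean value of a variable for every (province, stratum)
#' cell in which the taxon occurred (>= 1 read, day and night tows
#' pooled), and returns the difference between the maximum and minimum.
#'
#' @param matrix A [read_matrix()] (any mode; occurrence is > 0).
#' @param meta Sample metadata.
#' @param envs Net environments from [net_environment()].
#' @param taxon_id Taxon to evaluate.
#' @param variable `"temperature"`, `"oxygen"` or `"chla"`.
#' @return List `range` (max - min, >= 0; 0 when a single cell is
#'   occupied) and `n_cells`.
#' @export
taxon_env_range <- function(matrix, meta, envs, taxon_id,
                            variable = c("temperature", "oxygen", "chla")) {
  variable <- match.arg(variable)
  if (!taxon_id %in% rownames(matrix$counts)) {
    stop("unknown taxon: ", taxon_id)
  }
  x <- matrix$counts[taxon_id, meta$sample_id]
  occ <- meta[x > 0, c("province", "stratum_index")]
  if (!nrow(occ)) stop("taxon ", taxon_id, " occurs in no sample")
  occ <- unique(occ)
  col <- paste0("mean_", sub("temperature", "temperature_C", variable))
  key_env <- paste(envs$province, envs$stratum_index)
  vals <- envs[[col]][match(paste(occ$province, occ$stratum_index), key_env)]
  if (anyNA(vals)) stop("missing net environment for an occupied cell")
  list(range = max(vals) - min(vals), n_cells = nrow(occ))
}

#' Environmental ranges for all taxa
#'
#' @inheritParams taxon_env_range
#' @return Data frame `taxon_id`, `range_temperature`, `range_oxygen`,
#'   `range_chla`, `n_cells` (NA rows for taxa observed nowhere).
#' @export
env_range_table <- function(matrix, meta, envs) {
  taxa <- rownames(matrix$counts)
  rows <- lapply(taxa, function(tx) {
    if (all(matrix$counts[tx, meta$sample_id] == 0)) {
      return(data.frame(taxon_id = tx, range_temperature = NA_real_,
                        range_oxygen = NA_real_, range_chla = NA_real_,
                        n_cells = 0L))
    }
    rt <- taxon_env_range(matrix, meta, envs, tx, "temperature")
    ro <- taxon_env_range(matrix, meta, envs, tx, "oxygen")
    rc <- taxon_env_range(matrix, meta, envs, tx, "chla")
    data.frame(taxon_id = tx, range_temperature = rt$range,
               range_oxygen = ro$range, range_chla = rc$range,
               n_cells = rt$n_cells)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
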