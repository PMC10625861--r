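#' Mean depth of occurrence (MDO)
#'
#' Relative-read-abundance-weighted mean of stratum midpoints over the nets
#' in which a taxon was observed (count > 0 after replicate merging):
#' `MDO = sum(r_i * mid_i) / sum(r_i)` over occupied nets `i`, where `r_i`
#' is the taxon's relative abundance within net `i`. The overall scope
#' pools all nets from all stations and tows into a single weighted mean;
#' the per-tow scope restricts to one (station, tow period).
#'
#' @param matrix A relative-mode [read_matrix()].
#' @param meta Sample metadata (see [survey_meta()]).
#' @param taxon_id Taxon to evaluate.
#' @param scope `"overall"` or `"per_tow"`.
#' @param station,tow_period Required for `scope = "per_tow"`.
#' @return MDO in metres, or `NA` when the taxon occurs in no net in scope.
#' @export
mdo <- function(matrix, meta, taxon_id, scope = c("overall", "per_tow"),
                station = NULL, tow_period = NULL) {
  scope <- match.arg(scope)
  stopifnot(inherits(matrix, "read_matrix"), matrix$mode == "relative")
  if (!taxon_id %in% rownames(matrix$counts)) {
    stop("unknown taxon: ", taxon_id)
  }
  keep <- rep(TRUE, nrow(meta))
  if (scope == "per_tow") {
    stopifnot(!is.null(station), !is.null(tow_period))
    keep <- meta$station == station & meta$tow_period == tow_period
  }
  r <- matrix$counts[taxon_id, meta$sample_id[keep]]
  mid <- meta$stratum_midpoint_m[keep]
  occ <- r > 0
  if (!any(occ)) return(NA_real_)
  sum(r[occ] * mid[occ]) / sum(r[occ])
}

#' Overall and per-tow MDO for every taxon
#'
#' @inheritParams mdo
#' @return `mdo_all()`: data frame `taxon_id`, `mdo_overall_m`.
#'   `mdo_by_tow()`: long data frame `taxon_id`, `station`, `tow_period`,
#'   `mdo_m` (NA when unobserved in that tow).
#' @export
mdo_all <- function(matrix, meta) {
  stopifnot(matrix$mode == "relative")
  r <- matrix$counts[, meta$sample_id, drop = FALSE]
  mid <- meta$stratum_midpoint_m
  w <- rowSums(r)
  m <- as.vector(r %*% mid) / ifelse(w == 0, NA_real_, w)
  data.frame(taxon_id = rownames(r), mdo_overall_m = m)
}

#' @rdname mdo_all
#' @export
mdo_by_tow <- function(matrix, meta) {
  stopifnot(matrix$mode == "relative")
  tows <- unique(meta[, c("station", "tow_period")])
  out <- lapply(seq_len(nrow(tows)), function(i) {
    keep <- meta$station == tows$station[i] &
      meta$tow_period == tows$tow_period[i]
    r <- matrix$counts[, meta$sample_id[keep], drop = FALSE]
    mid <- meta$stratum_midpoint_m[keep]
    w <- rowSums(r)
    data.frame(taxon_id = rownames(r), station = tows$station[i],
               tow_period = tows$tow_period[i],
               mdo_m = as.vector(r %*% mid) / ifelse(w == 0, NA_real_, w))
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Classify vertical habitat from overall MDO
#'
#' Mesopelagic iff MDO strictly exceeds the habitat boundary (200 m);
#' an MDO of exactly 200 m is epipelagic. `NA` MDO gives `NA` (taxon
#' excluded from habitat analyses).
#'
#' @param mdo_overall_m Numeric vector of overall MDO values (m).
#' @param boundary_m Habitat boundary depth, default 200 m.
#' @return Character vector, `"epipelagic"` or `"mesopelagic"`.
#' @export
classify_habitat <- function(mdo_overall_m, boundary_m = 200) {
  ifelse(is.na(mdo_overall_m), NA_character_,
         ifelse(mdo_overall_m > boundary_m, "mesopelagic", "epipelagic"))
}

#' Thresholds for the four-criterion DVM rule
#'
#' @param min_nets Minimum occupied nets in each of the day and the night
#'   tow (criterion 1).
#' @param max_fold Maximum fold difference between day and night tow-level
#'   relative abundances (criterion 2).
#' @param min_study_share Minimum share of the study's total reads for the
#'   marker (criterion 3); 1e-4 is 0.01%.
#' @param min_strata_shift Minimum day/night shift of the weighted mean
#'   depth, counted in sampling strata (criterion 4).
#' @return List of thresholds.
#' @export
dvm_criteria <- function(min_nets = 2L, max_fold = 2,
                         min_study_share = 1e-4, min_strata_shift = 2L) {
  stopifnot(min_nets > 0, max_fold > 0, min_study_share > 0,
            min_strata_shift > 0)
  list(min_nets = as.integer(min_nets), max_fold = max_fold,
       min_study_share = min_study_share,
       min_strata_shift = as.integer(min_strata_shift))
}

#' Detect diel vertical migration for one taxon
#'
#' At every station with paired day and night tows, evaluates the four
#' criteria for DVM behaviour:
#' \describe{
#'   \item{C1}{observed in at least `min_nets` nets in the day tow and in
#'     the night tow;}
#'   \item{C2}{day and night tow-level relative abundances (taxon reads /
#'     tow total reads) no more than `max_fold` different (symmetric
#'     ratio);}
#'   \item{C3}{taxon reads are at least `min_study_share` of the study's
#'     total reads for the marker;}
#'   \item{C4}{the weighted mean depth of occurrence (per-tow MDO) shifted
#'     by at least `min_strata_shift` sampling strata between day and
#'     night, measured as the difference of the indices of the strata
#'     containing each WMD.}
#' }
#' The taxon is labelled DVM when all four hold at one or more stations
#' (configurable via `require_all_stations`).
#'
#' @param matrix_rel Relative-mode [read_matrix()] (for C4 weights).
#' @param matrix_counts Counts-mode [read_matrix()] of the same marker and
#'   samples (for C1-C3).
#' @param meta Sample metadata.
#' @param taxon_id Taxon to evaluate.
#' @param strata Strata data frame (for stratum indices).
#' @param criteria Thresholds from [dvm_criteria()].
#' @param require_all_stations If `TRUE`, all paired stations must qualify.
#' @return List with `dvm` (`"yes"`/`"no"`) and `stations`, a per-station
#'   diagnostics data frame (columns `station`, `c1`..`c4`, `pass`,
#'   `wmd_day_m`, `wmd_night_m`).
#' @export
detect_dvm <- function(matrix_rel, matrix_counts, meta, taxon_id, strata,
                       criteria = dvm_criteria(),
                       require_all_stations = FALSE) {
  stopifnot(matrix_rel$mode == "relative", matrix_counts$mode == "counts")
  if (!taxon_id %in% rownames(matrix_counts$counts)) {
    stop("unknown taxon: ", taxon_id)
  }
  stations <- unique(meta$station)
  paired <- stations[vapply(stations, function(s) {
    all(c("day", "night") %in% meta$tow_period[meta$station == s])
  }, logical(1))]
  if (!length(paired)) stop("no station with paired day and night tows")

  cts <- matrix_counts$counts
  study_total <- sum(cts)
  taxon_total <- sum(cts[taxon_id, meta$sample_id])
  c3 <- taxon_total / study_total >= criteria$min_study_share

  rows <- lapply(paired, function(s) {
    sel <- function(period) meta$station == s & meta$tow_period == period
    ids_d <- meta$sample_id[sel("day")]
    ids_n <- meta$sample_id[sel("night")]
    c1 <- sum(cts[taxon_id, ids_d] > 0) >= criteria$min_nets &&
      sum(cts[taxon_id, ids_n] > 0) >= criteria$min_nets
    a_day <- sum(cts[taxon_id, ids_d]) / sum(cts[, ids_d])
    a_night <- sum(cts[taxon_id, ids_n]) / sum(cts[, ids_n])
    c2 <- if (a_day == 0 || a_night == 0) FALSE else
      max(a_day, a_night) / min(a_day, a_night) <= criteria$max_fold
    wmd_d <- mdo(matrix_rel, meta, taxon_id, "per_tow", s, "day")
    wmd_n <- mdo(matrix_rel, meta, taxon_id, "per_tow", s, "night")
    c4 <- if (is.na(wmd_d) || is.na(wmd_n)) FALSE else
      abs(stratum_index_of_depth(wmd_d, strata) -
            stratum_index_of_depth(wmd_n, strata)) >=
        criteria$min_strata_shift
    data.frame(station = s, c1 = c1, c2 = c2, c3 = c3, c4 = c4,
               pass = c1 && c2 && c3 && c4,
               wmd_day_m = wmd_d, wmd_night_m = wmd_n)
  })
  diag <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  qualifies <- if (require_all_stations) all(diag$pass) else any(diag$pass)
  list(dvm = if (qualifies) "yes" else "no", stations = diag)
}

#' DVM labels for every taxon
#'
#' @inheritParams detect_dvm
#' @return Data frame `taxon_id`, `dvm`, `n_stations_pass`.
#' @export
dvm_table <- function(matrix_rel, matrix_counts, meta, strata,
                      criteria = dvm_criteria(),
                      require_all_stations = FALSE) {
  taxa <- rownames(matrix_counts$counts)
  res <- lapply(taxa, function(tx) {
    d <- detect_dvm(matrix_rel, matrix_counts, meta, tx, strata, criteria,
                    require_all_stations)
    data.frame(taxon_id = tx, dvm = d$dvm,
               n_stations_pass = sum(d$stations$pass))
  })
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}

#' Body size vs depth correlation within one tow
#'
#' Ties-corrected Spearman rank correlation between maximum reported body
#' size and per-tow MDO for taxa observed in the given (station, tow
#' period). Requires at least 3 complete pairs; otherwise returns `NA`
#' with a flag.
#'
#' @param mdo_tow Data frame from [mdo_by_tow()].
#' @param traits Trait table with `name` and `body_size_mm`.
#' @param station,tow_period Scope.
#' @return List `rho`, `p`, `n`, `insufficient` (logical).
#' @export
size_depth_correlation <- function(mdo_tow, traits, station, tow_period) {
  sub <- mdo_tow[mdo_tow$station == station &
                   mdo_tow$tow_period == tow_period, ]
  sz <- traits$body_size_mm[match(sub$taxon_id, traits$name)]
  ok <- complete.cases(sz, sub$mdo_m)
  if (sum(ok) < 3) {
    return(list(rho = NA_real_, p = NA_real_, n = sum(ok),
                insufficient = TRUE))
  }
  r <- spearman_cor(sz[ok], sub$mdo_m[ok])
  list(rho = r$rho, p = r$p, n = r$n, insufficient = FALSE)
}
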