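#' Default MOCNESS depth strata
#'
#' The eight discrete depth strata sampled by each tow, listed shallow to
#' deep: 0-25, 25-50, 50-100, 100-200, 200-400, 400-600, 600-800 and
#' 800-1000 m. Strata abut exactly at 200 m, so the epipelagic (0-200 m)
#' and mesopelagic (200-1000 m) zones are unions of whole strata.
#'
#' @return A data frame with columns `upper_m` and `lower_m`, one row per
#'   stratum, sorted shallow to deep.
#' @export
default_strata <- function() {
  data.frame(
    upper_m = c(0, 25, 50, 100, 200, 400, 600, 800),
    lower_m = c(25, 50, 100, 200, 400, 600, 800, 1000)
  )
}

#' Describe a depth-stratified paired day/night tow survey
#'
#' Captures the sampling design: the biogeochemical provinces surveyed (one
#' station each), the discrete depth strata sampled by each MOCNESS tow, the
#' paired day/night tow at every station, the sequencing depth per sample,
#' and the number of metabarcoding markers.
#'
#' @param provinces Ordered character vector of province labels.
#' @param strata Data frame with `upper_m`/`lower_m` columns, sorted shallow
#'   to deep, contiguous and non-overlapping. Default [default_strata()].
#' @param reads_per_sample Sequencing depth (reads) per net sample. The
#'   default, 5e4, matches typical per-sample read counts after quality
#'   control in depth-stratified metabarcoding surveys.
#' @param n_markers Number of metabarcoding markers simulated.
#' @param marker_overlap Fraction of taxa detected by every marker; the rest
#'   are detected by exactly one marker (marker-specific detection).
#' @param seed Master seed for all randomness in the simulation.
#' @return An object of class `survey_design`.
#' @export
survey_design <- function(provinces = c("Subarctic", "Transition", "Subtropical"),
                          strata = default_strata(),
                          reads_per_sample = 50000L,
                          n_markers = 1L,
                          marker_overlap = 0.2,
                          seed = 1L) {
  stopifnot(is.character(provinces), length(provinces) >= 1,
            !anyDuplicated(provinces))
  strata <- as.data.frame(strata)
  stopifnot(all(c("upper_m", "lower_m") %in% names(strata)))
  if (any(strata$upper_m >= strata$lower_m)) {
    stop("each stratum must have upper_m < lower_m")
  }
  if (is.unsorted(strata$upper_m, strictly = TRUE)) {
    stop("strata must be sorted shallow to deep")
  }
  n <- nrow(strata)
  if (n > 1 && any(strata$lower_m[-n] != strata$upper_m[-1])) {
    stop("strata must be contiguous and non-overlapping")
  }
  if (reads_per_sample <= 0) stop("reads_per_sample must be positive")
  if (n_markers < 1) stop("n_markers must be >= 1")
  structure(
    list(provinces = provinces, strata = strata,
         tow_periods = c("day", "night"),
         reads_per_sample = as.integer(reads_per_sample),
         n_markers = as.integer(n_markers),
         marker_overlap = marker_overlap,
         seed = as.integer(seed)),
    class = "survey_design"
  )
}

#' @export
print.survey_design <- function(x, ...) {
  cat("Survey design:", length(x$provinces), "provinces x 2 tow periods x",
      nrow(x$strata), "strata;", x$reads_per_sample, "reads/sample;",
      x$n_markers, "marker(s); seed", x$seed, "\n")
  invisible(x)
}

#' Index of the stratum containing a depth
#'
#' Strata are half-open intervals `[upper, lower)` except the deepest, which
#' is closed at its lower bound. Indices are 0-based with 0 the shallowest
#' stratum, so index differences count strata crossed.
#'
#' @param depth_m Numeric vector of depths (m).
#' @param strata Strata data frame as in [survey_design()].
#' @return Integer vector of 0-based stratum indices (`NA` outside range).
#' @export
stratum_index_of_depth <- function(depth_m, strata) {
  n <- nrow(strata)
  idx <- findInterval(depth_m, c(strata$upper_m, strata$lower_m[n]),
                      rightmost.closed = TRUE) - 1L
  idx[idx < 0 | idx >= n] <- NA_integer_
  idx
}

#' Sample metadata implied by a survey design
#'
#' One net sample per (province, tow period, stratum), one station per
#' province. Rows are ordered province-major, then day before night, then
#' shallow to deep.
#'
#' @param design A [survey_design()].
#' @return Data frame with columns `sample_id`, `province`, `station`,
#'   `tow_period`, `stratum_upper_m`, `stratum_lower_m`, `stratum_index`
#'   (0 = shallowest) and `stratum_midpoint_m`.
#' @export
survey_meta <- function(design) {
  stopifnot(inherits(design, "survey_design"))
  st <- design$strata
  grid <- expand.grid(stratum = seq_len(nrow(st)) - 1L,
                      tow_period = design$tow_periods,
                      province = design$provinces,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  upper <- st$upper_m[grid$stratum + 1L]
  lower <- st$lower_m[grid$stratum + 1L]
  data.frame(
    sample_id = sprintf("%s_%s_%d-%dm", grid$province, grid$tow_period,
                        upper, lower),
    province = grid$province,
    station = grid$province,
    tow_period = grid$tow_period,
    stratum_upper_m = upper,
    stratum_lower_m = lower,
    stratum_index = grid$stratum,
    stratum_midpoint_m = (upper + lower) / 2
  )
}
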