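#' Read / write sample metadata
#'
#' TSV with columns `sample_id`, `province`, `station`, `tow_period`,
#' `stratum_upper_m`, `stratum_lower_m`, `stratum_index`,
#' `stratum_midpoint_m`. Validates midpoints, tow periods and uniqueness of
#' (province, station, tow_period, stratum).
#'
#' @param path File path.
#' @return Sample metadata data frame.
#' @export
read_sample_meta <- function(path) {
  meta <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "province", "station", "tow_period",
            "stratum_upper_m", "stratum_lower_m", "stratum_index",
            "stratum_midpoint_m")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("metadata missing column(s): ",
                         paste(miss, collapse = ", "))
  validate_sample_meta(meta)
  meta
}

validate_sample_meta <- function(meta) {
  if (any(!meta$tow_period %in% c("day", "night"))) {
    stop("tow_period must be 'day' or 'night'")
  }
  if (any(meta$stratum_upper_m < 0 |
          meta$stratum_upper_m >= meta$stratum_lower_m)) {
    stop("strata need 0 <= upper < lower")
  }
  mid <- (meta$stratum_upper_m + meta$stratum_lower_m) / 2
  if (any(abs(mid - meta$stratum_midpoint_m) > 1e-9)) {
    stop("stratum_midpoint_m inconsistent with bounds")
  }
  key <- paste(meta$province, meta$station, meta$tow_period,
               meta$stratum_index)
  if (anyDuplicated(key)) {
    stop("duplicate (province, station, tow_period, stratum) sample: ",
         key[duplicated(key)][1])
  }
  invisible(meta)
}

#' @rdname read_sample_meta
#' @param meta Sample metadata data frame.
#' @export
write_sample_meta <- function(meta, path) {
  validate_sample_meta(meta)
  write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write 1-m binned CTD profiles
#'
#' CSV with columns `province`, `depth_m`, `temperature_C`, `oxygen`,
#' `chla`. Depths must be strictly increasing at 1-m spacing within each
#' province.
#'
#' @param path File path.
#' @return Profiles data frame.
#' @export
read_ctd_profiles <- function(path) {
  prof <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("province", "depth_m", "temperature_C", "oxygen", "chla")
  miss <- setdiff(need, names(prof))
  if (length(miss)) stop("CTD table missing column(s): ",
                         paste(miss, collapse = ", "))
  for (pv in unique(prof$province)) {
    z <- prof$depth_m[prof$province == pv]
    if (any(diff(z) != 1)) {
      stop("CTD profile for ", pv, " is not on a strictly increasing ",
           "1-m grid")
    }
  }
  prof
}

#' @rdname read_ctd_profiles
#' @param profiles Profiles data frame.
#' @export
write_ctd_profiles <- function(profiles, path) {
  write.csv(profiles, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

trait_vocab <- list(
  diet = c("carnivore", "omnivore", "herbivore"),
  feeding = c("ambush", "cruise", "parasitoid", "suspension"),
  spawning = c("broadcast", "brooding"),
  asexual = c("yes", "no"),
  composition = c("gelatinous", "intermediate", "non-gelatinous"),
  dvm = c("yes", "no")
)

#' Read / write a trait table
#'
#' TSV keyed by taxonomic `name` with trait columns `body_size_mm` (mm,
#' maximum reported for the species), `diet`, `feeding`, `spawning`,
#' `asexual` and `composition`. Missing values are empty strings or "NA".
#' Every non-missing categorical value must be in its vocabulary.
#'
#' @param path File path.
#' @return Trait table data frame.
#' @export
read_trait_table <- function(path) {
  tr <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  if (!"name" %in% names(tr)) stop("trait table needs a 'name' column")
  validate_trait_table(tr)
  tr
}

validate_trait_table <- function(tr) {
  for (col in intersect(names(trait_vocab), names(tr))) {
    bad <- !is.na(tr[[col]]) & !tr[[col]] %in% trait_vocab[[col]]
    if (any(bad)) {
      stop(sprintf("invalid %s value '%s' for '%s'", col,
                   tr[[col]][bad][1], tr$name[bad][1]))
    }
  }
  if ("body_size_mm" %in% names(tr) &&
      any(!is.na(tr$body_size_mm) & tr$body_size_mm <= 0)) {
    stop("body_size_mm must be positive")
  }
  invisible(tr)
}

#' @rdname read_trait_table
#' @param traits Trait table data frame.
#' @export
write_trait_table <- function(traits, path) {
  validate_trait_table(traits)
  write.table(traits, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Look up traits for a taxonomy string
#'
#' Matches a semicolon-delimited ranked taxonomy string against the trait
#' table's `name` column at the most specific rank present: the last rank
#' with a match wins. Group-level (genus/family) entries should only be
#' present in the table when the trait is uniform within the group; the
#' lookup matches by name only.
#'
#' @param taxonomy Semicolon-delimited taxonomy string (coarse to fine).
#' @param traits Trait table (see [read_trait_table()]).
#' @return One-row data frame of traits, or `NULL` when no rank matches.
#' @export
trait_lookup <- function(taxonomy, traits) {
  ranks <- trimws(strsplit(taxonomy, ";", fixed = TRUE)[[1]])
  ranks <- ranks[nzchar(ranks)]
  for (r in rev(ranks)) {
    hit <- which(traits$name == r)
    if (length(hit)) return(traits[hit[1], , drop = FALSE])
  }
  NULL
}
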