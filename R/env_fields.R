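#' Parametric environmental depth fields per province
#'
#' Describes, for every province, smooth parametric depth curves for
#' temperature, dissolved oxygen and chlorophyll-a fluorescence on
#' 0-1000 m, plus Gaussian sensor noise. Temperature holds a mixed-layer
#' plateau at its surface value then declines exponentially below the
#' thermocline towards its deep value; oxygen holds its surface value
#' above the oxycline then declines towards a deep minimum reached by
#' about its minimum depth; Chl-a is a Gaussian subsurface peak
#' (effectively zero below 200 m).
#'
#' The defaults emulate an eastern North Pacific latitudinal gradient:
#' a warm, oligotrophic subtropical station with a deep chlorophyll maximum
#' and a deep, mild oxycline; a cool, productive subarctic station with a
#' shallow chlorophyll peak and a sharp, shallow oxycline reaching a strong
#' oxygen minimum; the transition station intermediate. Temperature and
#' Chl-a gradients (vertical and among provinces) are concentrated in the
#' epipelagic, while the oxygen gradient sits in the mesopelagic.
#'
#' @param provinces Named list of per-province parameter lists; see the
#'   function body for the expected structure (`temperature`, `oxygen`,
#'   `chla` sub-lists).
#' @param noise_sd Named numeric: sensor noise SD for `temperature`
#'   (degrees C), `oxygen` (ml/l) and `chla` (mg/m^3).
#' @return An object of class `env_field_spec`.
#' @export
env_field_spec <- function(provinces = NULL,
                           noise_sd = c(temperature = 0.05, oxygen = 0.05,
                                        chla = 0.02)) {
  if (is.null(provinces)) {
    provinces <- list(
      Subarctic = list(
        temperature = list(surface = 11, thermocline_m = 30, deep = 2.5,
                           width_m = 35),
        oxygen = list(surface = 6.8, oxycline_m = 150, minimum = 0.4,
                      minimum_depth_m = 600),
        chla = list(peak = 2.5, peak_depth_m = 20, width_m = 20)
      ),
      Transition = list(
        temperature = list(surface = 16, thermocline_m = 45, deep = 3,
                           width_m = 45),
        oxygen = list(surface = 6.2, oxycline_m = 300, minimum = 0.8,
                      minimum_depth_m = 700),
        chla = list(peak = 1.2, peak_depth_m = 50, width_m = 25)
      ),
      Subtropical = list(
        temperature = list(surface = 24, thermocline_m = 70, deep = 3.5,
                           width_m = 55),
        oxygen = list(surface = 5.3, oxycline_m = 450, minimum = 1.5,
                      minimum_depth_m = 800),
        chla = list(peak = 0.4, peak_depth_m = 110, width_m = 30)
      )
    )
  }
  stopifnot(is.list(provinces), length(provinces) >= 1,
            !is.null(names(provinces)))
  structure(list(provinces = provinces, noise_sd = noise_sd),
            class = "env_field_spec")
}

env_temperature <- function(z, p) {
  # mixed-layer plateau at the surface value, exponential decline below
  # the thermocline towards the deep value (non-increasing with depth)
  p$deep + (p$surface - p$deep) *
    pmin(1, exp(-(z - p$thermocline_m) / p$width_m))
}

env_oxygen <- function(z, p) {
  # plateau at the surface value above the oxycline, exponential decline
  # towards the deep minimum reached by about minimum_depth
  width <- (p$minimum_depth_m - p$oxycline_m) / 3
  p$minimum + (p$surface - p$minimum) *
    pmin(1, exp(-(z - p$oxycline_m) / width))
}

env_chla <- function(z, p) {
  p$peak * exp(-(z - p$peak_depth_m)^2 / (2 * p$width_m^2))
}

#' Generate 1-m binned CTD profiles for every province
#'
#' Evaluates the parametric depth curves at integer depths 0..1000 m and
#' adds seeded Gaussian sensor noise. Oxygen and Chl-a are floored at zero.
#'
#' @param spec An [env_field_spec()].
#' @param design A [survey_design()]; every design province must be defined
#'   in `spec`, otherwise a configuration error is raised.
#' @return Data frame with columns `province`, `depth_m` (0..1000),
#'   `temperature_C`, `oxygen`, `chla`.
#' @export
generate_profiles <- function(spec, design) {
  stopifnot(inherits(spec, "env_field_spec"), inherits(design, "survey_design"))
  missing_p <- setdiff(design$provinces, names(spec$provinces))
  if (length(missing_p)) {
    stop("no environmental field defined for province(s): ",
         paste(missing_p, collapse = ", "))
  }
  set.seed(substream_seed(design$seed, "profiles"))
  z <- 0:1000
  out <- lapply(design$provinces, function(pv) {
    p <- spec$provinces[[pv]]
    n <- length(z)
    noise <- spec$noise_sd
    data.frame(
      province = pv,
      depth_m = z,
      temperature_C = env_temperature(z, p$temperature) +
        rnorm(n, 0, noise[["temperature"]]),
      oxygen = pmax(0, env_oxygen(z, p$oxygen) + rnorm(n, 0, noise[["oxygen"]])),
      chla = pmax(0, env_chla(z, p$chla) + rnorm(n, 0, noise[["chla"]]))
    )
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
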