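#' Excitation light source
#'
#' Describes one LED excitation source of the imaging head. Only one light is
#' active per acquired channel; the others are off. Relative intensity is the
#' 8-bit drive level of the LED controller.
#'
#' @param name Light name, one of `"red"`, `"green"`, `"blue"`.
#' @param center_wavelength Emission center of the LED in nm (380-780).
#' @param relative_intensity Integer drive level in \[0, 255\]; operationally
#'   50-255. Lower values are used when the LED wavelength sits close to the
#'   detection filter, to avoid overexposing the sensor.
#' @param bandwidth Full width at half maximum of the LED spectrum in nm.
#' @return An object of class `excitation_light`.
#' @export
excitation_light <- function(name, center_wavelength, relative_intensity,
                             bandwidth = 20) {
  name <- match.arg(name, c("red", "green", "blue"))
  if (!is.numeric(center_wavelength) || length(center_wavelength) != 1 ||
      center_wavelength < 380 || center_wavelength > 780) {
    stop("center_wavelength must be a single value in [380, 780] nm",
         call. = FALSE)
  }
  if (!is.numeric(relative_intensity) || length(relative_intensity) != 1 ||
      relative_intensity < 0 || relative_intensity > 255 ||
      relative_intensity != round(relative_intensity)) {
    stop("relative_intensity must be an integer in [0, 255]", call. = FALSE)
  }
  if (!is.numeric(bandwidth) || bandwidth <= 0) {
    stop("bandwidth must be positive", call. = FALSE)
  }
  structure(
    list(name = name,
         center_wavelength = as.numeric(center_wavelength),
         relative_intensity = as.integer(relative_intensity),
         bandwidth = as.numeric(bandwidth)),
    class = "excitation_light"
  )
}

#' Bandpass detection filter
#'
#' @param center_wavelength Passband center in nm.
#' @param passband_fwhm Full width at half maximum of the (Gaussian-modeled)
#'   transmission curve, nm. Default 10 nm, typical of tunable filters.
#' @return An object of class `bandpass_filter`.
#' @export
bandpass_filter <- function(center_wavelength, passband_fwhm = 10) {
  if (!is.numeric(center_wavelength) || length(center_wavelength) != 1 ||
      center_wavelength <= 0) {
    stop("center_wavelength must be a single positive value", call. = FALSE)
  }
  if (!is.numeric(passband_fwhm) || passband_fwhm <= 0) {
    stop("passband_fwhm must be positive", call. = FALSE)
  }
  structure(
    list(center_wavelength = as.numeric(center_wavelength),
         passband_fwhm = as.numeric(passband_fwhm)),
    class = "bandpass_filter"
  )
}

#' Default red/green/blue excitation set
#'
#' Green 525 nm at drive level 50 and red 625 nm at 255 follow the worked
#' armrest example; the blue LED center is taken as 460 nm at 50 (kept low,
#' like green, because it sits inside the 420-720 nm filter sweep).
#'
#' @param green_irel,red_irel,blue_irel Drive levels per light.
#' @return List of three `excitation_light` objects.
#' @export
default_lights <- function(green_irel = 50, red_irel = 255, blue_irel = 50) {
  list(
    excitation_light("red", 625, red_irel),
    excitation_light("green", 525, green_irel),
    excitation_light("blue", 460, blue_irel)
  )
}

#' Build a full-grid acquisition protocol
#'
#' Enumerates every (light, filter) pair over a filter sweep. The default
#' sweep, 420 to 720 nm in 20 nm increments with three lights, yields the
#' standard 48-channel acquisition of 1393 x 1040 px frames.
#'
#' @param light_specs List of [excitation_light()] objects.
#' @param filter_min,filter_max Sweep bounds in nm.
#' @param increment Sweep step in nm; must be positive.
#' @param frame_width,frame_height Sensor frame size in px.
#' @param passband_fwhm Filter passband FWHM passed to [bandpass_filter()].
#' @return An `acquisition_protocol`: list with `lights`, `filters`,
#'   `channels` (data frame: light, light_nm, i_rel, filter_nm, in
#'   light-major order), `frame_height`, `frame_width`.
#' @examples
#' p <- make_protocol(default_lights())
#' nrow(p$channels)  # 48
#' @export
make_protocol <- function(light_specs,
                          filter_min = 420, filter_max = 720, increment = 20,
                          frame_width = 1393, frame_height = 1040,
                          passband_fwhm = 10) {
  if (!is.list(light_specs) || length(light_specs) == 0 ||
      !all(vapply(light_specs, inherits, logical(1), "excitation_light"))) {
    stop("light_specs must be a non-empty list of excitation_light objects",
         call. = FALSE)
  }
  if (!is.numeric(increment) || increment <= 0) {
    stop("invalid protocol: increment must be positive", call. = FALSE)
  }
  if (filter_min > filter_max) {
    stop("invalid protocol: filter_min must not exceed filter_max",
         call. = FALSE)
  }
  centers <- seq(filter_min, filter_max, by = increment)
  filters <- lapply(centers, bandpass_filter, passband_fwhm = passband_fwhm)
  channels <- do.call(rbind, lapply(light_specs, function(l) {
    data.frame(light = l$name,
               light_nm = l$center_wavelength,
               i_rel = l$relative_intensity,
               filter_nm = centers)
  }))
  rownames(channels) <- NULL
  if (anyDuplicated(channels[, c("light", "i_rel", "filter_nm")])) {
    stop("invalid protocol: duplicate (light, intensity, filter) channels",
         call. = FALSE)
  }
  structure(
    list(lights = light_specs, filters = filters, channels = channels,
         frame_height = as.integer(frame_height),
         frame_width = as.integer(frame_width)),
    class = "acquisition_protocol"
  )
}

#' @export
print.acquisition_protocol <- function(x, ...) {
  cat(sprintf("acquisition protocol: %d lights x %d filters = %d channels, %d x %d px frames\n",
              length(x$lights), length(x$filters), nrow(x$channels),
              x$frame_width, x$frame_height))
  invisible(x)
}

#' Fluorophore with Gaussian excitation/emission spectra
#'
#' First-order fluorescence model: unimodal Gaussian excitation and emission
#' bands with a non-negative Stokes shift. Widths are Gaussian standard
#' deviations in nm. The default parameters emulate a flavin-like
#' (riboflavin-type) stain that emits near 500 nm under green and blue
#' excitation but barely responds to red.
#'
#' @param name Label.
#' @param excitation_peak,excitation_width Excitation band center / sd, nm.
#' @param emission_peak,emission_width Emission band center / sd, nm.
#' @param quantum_scale Non-negative brightness scale (dimensionless).
#' @return An object of class `fluorophore`.
#' @export
fluorophore <- function(name = "flavin-like",
                        excitation_peak = 450, excitation_width = 60,
                        emission_peak = 500, emission_width = 25,
                        quantum_scale = 30) {
  if (emission_peak < excitation_peak) {
    stop("emission_peak must be >= excitation_peak (non-negative Stokes shift)",
         call. = FALSE)
  }
  if (quantum_scale < 0 || excitation_width <= 0 || emission_width <= 0) {
    stop("spectral widths must be positive and quantum_scale >= 0",
         call. = FALSE)
  }
  structure(
    list(name = name,
         excitation_peak = excitation_peak,
         excitation_width = excitation_width,
         emission_peak = emission_peak,
         emission_width = emission_width,
         quantum_scale = quantum_scale),
    class = "fluorophore"
  )
}

fwhm_to_sd <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' Fluorescence contribution of a fluorophore in one channel
#'
#' Forward model for one (light, filter) channel: the excitation spectrum
#' evaluated at the LED center, scaled by the drive level over 255, times the
#' emission band's overlap integral with the Gaussian filter passband
#' (normalized so a filter centered on the emission peak with a narrow
#' passband gives the factor `passband_sd / sqrt(emission_sd^2 +
#' passband_sd^2)`). The response is exactly zero when the LED is more than
#' five excitation widths from the excitation peak, or the filter more than
#' five combined widths from the emission peak.
#'
#' @param fluor A [fluorophore()].
#' @param light An [excitation_light()].
#' @param filter A [bandpass_filter()].
#' @return Dimensionless non-negative intensity contribution. Linear in
#'   `relative_intensity` and in `quantum_scale`.
#' @export
channel_response <- function(fluor, light, filter) {
  stopifnot(inherits(fluor, "fluorophore"),
            inherits(light, "excitation_light"),
            inherits(filter, "bandpass_filter"))
  sd_f <- fwhm_to_sd(filter$passband_fwhm)
  d_exc <- abs(light$center_wavelength - fluor$excitation_peak)
  sd_em <- fluor$emission_width
  d_em <- abs(filter$center_wavelength - fluor$emission_peak)
  if (d_exc > 5 * fluor$excitation_width ||
      d_em > 5 * sqrt(sd_em^2 + sd_f^2)) {
    return(0)
  }
  exc <- exp(-d_exc^2 / (2 * fluor$excitation_width^2))
  # Gaussian-Gaussian overlap of emission band and filter transmission,
  # normalized to the narrow-filter limit
  overlap <- sd_f / sqrt(sd_em^2 + sd_f^2) *
    exp(-d_em^2 / (2 * (sd_em^2 + sd_f^2)))
  resp <- fluor$quantum_scale * exc * (light$relative_intensity / 255) * overlap
  if (resp < .Machine$double.eps) 0 else resp
}

#' Specular/stray-light leakage of the excitation LED through the filter
#'
#' Background term that makes channels whose filter sits on top of the LED
#' wavelength bright, emulating the overexposure that forces drive levels
#' down when light and filter wavelengths coincide.
#'
#' @inheritParams channel_response
#' @return Non-negative leakage factor, 1 at zero light-filter separation and
#'   full drive.
#' @keywords internal
leakage_response <- function(light, filter) {
  sd_l <- fwhm_to_sd(light$bandwidth)
  sd_f <- fwhm_to_sd(filter$passband_fwhm)
  d <- light$center_wavelength - filter$center_wavelength
  (light$relative_intensity / 255) * exp(-d^2 / (2 * (sd_l^2 + sd_f^2)))
}
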