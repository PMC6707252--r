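# Synthetic TEM coat-profile phantoms.
#
# Each phantom image is a straight stereociliary membrane seen edge-on:
# moving from extracellular space (left) into the cilium (right) the gray
# value drops through a surface-coat band, a membrane band and the actin
# core, plus Gaussian pixel noise. Tannic acid stain darkens the image, so
# bands are modeled as negative gray offsets from a bright background. The
# inner leaflet sits at a known position so a profile box with the inner
# leaflet on its midline can be placed exactly.

#' Specification of a coat phantom
#'
#' Band geometry (nm, measured along the profile from the extracellular
#' end): the coat occupies `[coat_start_nm, membrane_outer_nm]`, the
#' membrane `[membrane_outer_nm, membrane_outer_nm + membrane_thickness_nm]`
#' (inner leaflet at the latter edge, 100 nm by default so it falls on the
#' midline of a 200-nm box), and actin everything deeper. Gray amplitudes
#' are subtractive: staining amplitude A means the band is A gray levels
#' darker than background.
#'
#' @param pixel_size_nm pixel size; the acquisition magnifications gave
#'   0.77, 0.94, 1.26 or 1.92 nm
#' @param background_gray bright background gray value
#' @param membrane_depth_gray membrane band staining amplitude
#' @param coat_amplitude_gray coat band staining amplitude (control value)
#' @param actin_amplitude_gray actin core staining amplitude
#' @param coat_start_nm,membrane_outer_nm,membrane_thickness_nm band
#'   geometry, nm
#' @param coat_gap_nm electron-lucent cleft between the coat band and the
#'   outer leaflet (default 4 nm); keeps the membrane measurement free of
#'   coat signal, as in the real images where membrane staining is an
#'   internal control independent of the coat
#' @param noise_sd_gray Gaussian pixel noise SD
#' @param n_sections_per_group sections (images) per group
#' @param mutant_coat_scale multiplier on the coat amplitude in the mutant
#'   group
#' @param image_size_nm square image side, nm
#' @param rng_seed integer seed
#' @return object of class `coat_phantom_spec`
#' @export
coat_phantom_spec <- function(pixel_size_nm = 1.92,
                              background_gray = 200,
                              membrane_depth_gray = 120,
                              coat_amplitude_gray = 80,
                              actin_amplitude_gray = 100,
                              coat_start_nm = 30,
                              membrane_outer_nm = 85,
                              membrane_thickness_nm = 15,
                              coat_gap_nm = 4,
                              noise_sd_gray = 8,
                              n_sections_per_group = 14L,
                              mutant_coat_scale = 0.3,
                              image_size_nm = 240,
                              rng_seed = 1L) {
  if (pixel_size_nm <= 0) stop("pixel_size_nm must be > 0")
  if (image_size_nm <= 0) stop("image_size_nm must be > 0")
  amps <- c(membrane_depth_gray, coat_amplitude_gray, actin_amplitude_gray)
  if (any(amps < 0)) stop("staining amplitudes must be >= 0")
  if (noise_sd_gray < 0) stop("noise_sd_gray must be >= 0")
  if (n_sections_per_group < 1) stop("n_sections_per_group must be >= 1")
  if (mutant_coat_scale < 0) stop("mutant_coat_scale must be >= 0")
  if (!(coat_start_nm >= 0 && coat_start_nm < membrane_outer_nm - coat_gap_nm))
    stop("need 0 <= coat_start_nm < membrane_outer_nm - coat_gap_nm")
  if (coat_gap_nm < 0) stop("coat_gap_nm must be >= 0")
  structure(as.list(environment())[c(
    "pixel_size_nm", "background_gray", "membrane_depth_gray",
    "coat_amplitude_gray", "actin_amplitude_gray", "coat_start_nm",
    "membrane_outer_nm", "membrane_thickness_nm", "coat_gap_nm",
    "noise_sd_gray", "n_sections_per_group", "mutant_coat_scale",
    "image_size_nm", "rng_seed")], class = "coat_phantom_spec")
}

# noise-free staining amplitude (gray levels below background) at depth x nm
coat_band_staining <- function(x_nm, spec, coat_scale = 1) {
  inner <- spec$membrane_outer_nm + spec$membrane_thickness_nm
  s <- numeric(length(x_nm))
  s[x_nm >= spec$coat_start_nm &
      x_nm < spec$membrane_outer_nm - spec$coat_gap_nm] <-
    spec$coat_amplitude_gray * coat_scale
  s[x_nm >= spec$membrane_outer_nm & x_nm < inner] <- spec$membrane_depth_gray
  s[x_nm >= inner] <- spec$actin_amplitude_gray
  s
}

#' Generate coat phantom images for two groups, with ground truth
#'
#' @param spec a [coat_phantom_spec()]
#' @return list with `control` and `mutant` (lists of image matrices `[y, x]`
#'   with attribute `pixel_size_nm`) and `truth`: the noise-free normalized
#'   profile per group on a 1-nm grid and the true coat/actin amplitude
#'   ratios
#' @export
generate_coat_phantom <- function(spec) {
  stopifnot(inherits(spec, "coat_phantom_spec"))
  n_px <- floor(spec$image_size_nm / spec$pixel_size_nm) + 1L
  x_nm <- (seq_len(n_px) - 1L) * spec$pixel_size_nm

  make_group <- function(coat_scale, seed_offset) {
    row_profile <- spec$background_gray - coat_band_staining(x_nm, spec,
                                                             coat_scale)
    base <- matrix(row_profile, nrow = n_px, ncol = n_px, byrow = TRUE)
    with_seed(spec$rng_seed + seed_offset, {
      lapply(seq_len(spec$n_sections_per_group), function(i) {
        img <- base + matrix(stats::rnorm(n_px * n_px, 0, spec$noise_sd_gray),
                             n_px, n_px)
        attr(img, "pixel_size_nm") <- spec$pixel_size_nm
        img
      })
    })
  }

  grid <- 0:floor(spec$image_size_nm)
  truth_norm <- function(coat_scale) {
    s <- coat_band_staining(grid, spec, coat_scale)
    if (spec$actin_amplitude_gray <= 0) return(rep(NA_real_, length(grid)))
    s / spec$actin_amplitude_gray
  }
  list(control = make_group(1, 100L),
       mutant = make_group(spec$mutant_coat_scale, 200L),
       truth = list(
         position_nm = grid,
         control_profile = truth_norm(1),
         mutant_profile = truth_norm(spec$mutant_coat_scale),
         coat_actin_ratio_control = if (spec$actin_amplitude_gray > 0)
           spec$coat_amplitude_gray / spec$actin_amplitude_gray else NA_real_,
         coat_actin_ratio_mutant = if (spec$actin_amplitude_gray > 0)
           spec$coat_amplitude_gray * spec$mutant_coat_scale /
             spec$actin_amplitude_gray else NA_real_,
         inner_leaflet_nm = spec$membrane_outer_nm +
           spec$membrane_thickness_nm))
}

#' Run the coat pipeline on a generated phantom
#'
#' Places the standard box (axis along +x, inner leaflet on the midline) in
#' every image, extracts and normalizes profiles, and compares the groups.
#'
#' @param phantom result of [generate_coat_phantom()]
#' @param spec the [coat_phantom_spec()] used to generate it
#' @param length_nm profile/box length (default 200; the inner leaflet then
#'   sits at 100 nm = length/2)
#' @param width_nm box width (default 200)
#' @param ... passed to [compare_groups()]
#' @return a `coat_comparison`
#' @export
analyze_coat_phantom <- function(phantom, spec, length_nm = 200,
                                 width_nm = 200, ...) {
  inner <- spec$membrane_outer_nm + spec$membrane_thickness_nm
  x0 <- inner - length_nm / 2
  if (x0 < 0) stop("box extends beyond the extracellular edge")
  y_mid <- spec$image_size_nm / 2
  box <- profile_box(x0, y_mid, x0 + length_nm, y_mid,
                     width_nm = min(width_nm, spec$image_size_nm - 10))
  run <- function(img) {
    normalize_profile(extract_profile(img, box, spec$pixel_size_nm),
                      pixel_size_nm = spec$pixel_size_nm)
  }
  compare_groups(lapply(phantom$control, run), lapply(phantom$mutant, run),
                 ...)
}
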