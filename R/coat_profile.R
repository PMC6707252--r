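# Stereocilia surface-coat densitometry from TEM images.
#
# A ~200 x 200 nm box is placed perpendicular to the stereociliary membrane
# with the inner leaflet on its midline; intensity is averaged across the
# box width, background-subtracted, regridded to 1 nm by linear
# interpolation and normalized to the actin staining (mean over 140-200 nm
# of the profile). Staining is defined as B - I (tannic acid darkens the
# image), so cell-free regions sit near 0 and the actin core near 1.

#' Define a profile box on a TEM image
#'
#' @param x0_nm,y0_nm extracellular end of the box axis (position 0 of the
#'   profile)
#' @param x1_nm,y1_nm intracellular end of the box axis
#' @param width_nm box width perpendicular to the axis (default 200)
#' @return object of class `profile_box`
#' @export
profile_box <- function(x0_nm, y0_nm, x1_nm, y1_nm, width_nm = 200) {
  if (width_nm <= 0) stop("width_nm must be > 0")
  len <- sqrt((x1_nm - x0_nm)^2 + (y1_nm - y0_nm)^2)
  if (len <= 0) stop("box axis endpoints must be distinct")
  structure(list(x0_nm = x0_nm, y0_nm = y0_nm, x1_nm = x1_nm, y1_nm = y1_nm,
                 width_nm = width_nm, length_nm = len),
            class = "profile_box")
}

# bilinear sampling of image (matrix [y, x], pixel centers at 0-based
# index * pixel_size) at arbitrary (x, y) nm positions
bilinear_sample <- function(image, x_nm, y_nm, pixel_size_nm) {
  xi <- x_nm / pixel_size_nm
  yi <- y_nm / pixel_size_nm
  nx <- ncol(image); ny <- nrow(image)
  if (any(xi < 0 | xi > nx - 1 | yi < 0 | yi > ny - 1))
    stop("sampling position outside image bounds")
  x0 <- pmin(floor(xi), nx - 2); x1 <- x0 + 1
  y0 <- pmin(floor(yi), ny - 2); y1 <- y0 + 1
  fx <- xi - x0; fy <- yi - y0
  idx <- function(r, c) image[cbind(r + 1, c + 1)]
  (1 - fx) * (1 - fy) * idx(y0, x0) + fx * (1 - fy) * idx(y0, x1) +
    (1 - fx) * fy * idx(y1, x0) + fx * fy * idx(y1, x1)
}

#' Extract a raw intensity profile along a box
#'
#' Samples the image along the box axis at the native pixel pitch,
#' averaging bilinear samples across the box width (also at native pitch).
#' Position 0 is the extracellular end.
#'
#' @param image numeric matrix `[y, x]` of gray values
#' @param box a [profile_box()]
#' @param pixel_size_nm image pixel size in nm
#' @return data.frame `position_nm, intensity`
#' @export
extract_profile <- function(image, box, pixel_size_nm) {
  stopifnot(inherits(box, "profile_box"), pixel_size_nm > 0)
  u <- c(box$x1_nm - box$x0_nm, box$y1_nm - box$y0_nm) / box$length_nm
  v <- c(-u[2], u[1])
  positions <- seq(0, box$length_nm, by = pixel_size_nm)
  w_off <- seq(-box$width_nm / 2, box$width_nm / 2, by = pixel_size_nm)
  tw <- expand.grid(t = positions, w = w_off)
  vals <- bilinear_sample(image,
                          box$x0_nm + tw$t * u[1] + tw$w * v[1],
                          box$y0_nm + tw$t * u[2] + tw$w * v[2],
                          pixel_size_nm)
  prof <- rowMeans(matrix(vals, nrow = length(positions)))
  data.frame(position_nm = positions, intensity = prof)
}

#' Background-subtract, regrid to 1 nm and actin-normalize a profile
#'
#' Staining is s(x) = B - I(x), with B the background gray value (mean of a
#' cell-free ROI if given, else the mean raw intensity over the first
#' `background_window_nm` of the profile). The staining trace is regridded
#' to a 1-nm grid by linear interpolation between native samples and divided
#' by its mean over the actin window.
#'
#' @param profile data.frame `position_nm, intensity` from
#'   [extract_profile()]
#' @param pixel_size_nm native pixel size (provenance only; the profile
#'   carries its own positions)
#' @param background value: a single gray value (e.g. a cell-free ROI mean),
#'   or NULL to use the leading-window rule
#' @param background_window_nm leading window for the background estimate
#'   (default 20)
#' @param actin_window normalization window in nm, default `c(140, 200)`
#' @return object of class `intensity_profile`: data.frame `position_nm,
#'   value` on the 1-nm grid with attributes `background`, `actin_value`,
#'   `pixel_size_nm`
#' @export
normalize_profile <- function(profile, pixel_size_nm = NA_real_,
                              background = NULL, background_window_nm = 20,
                              actin_window = c(140, 200)) {
  pos <- profile$position_nm
  # a 200-nm box sampled at native pitch ends just short of 200 nm; the
  # actin window is clipped to the covered grid rather than rejected
  if (max(pos) < actin_window[1] + 1)
    stop("profile (", max(pos), " nm) does not reach the actin window [",
         actin_window[1], ", ", actin_window[2], "] nm")
  B <- if (!is.null(background)) background
       else mean(profile$intensity[pos <= background_window_nm])
  s <- B - profile$intensity
  grid <- seq(0, floor(max(pos)), by = 1)
  s1 <- stats::approx(pos, s, xout = grid, rule = 2)$y
  in_actin <- grid >= actin_window[1] & grid <= actin_window[2]
  actin <- mean(s1[in_actin])
  if (!is.finite(actin) || actin <= 0)
    stop("actin-window mean staining is not positive; cannot normalize")
  out <- data.frame(position_nm = grid, value = s1 / actin)
  structure(out, class = c("intensity_profile", "data.frame"),
            background = B, actin_value = actin,
            pixel_size_nm = pixel_size_nm, actin_window = actin_window)
}

#' Pointwise mean and s.e.m. of a group of profiles
#'
#' @param profiles list of `intensity_profile` on a common 1-nm grid
#' @return data.frame `position_nm, mean, sem, n`
#' @export
average_profiles <- function(profiles) {
  if (length(profiles) < 2) stop("need at least 2 profiles")
  grid <- profiles[[1]]$position_nm
  for (p in profiles)
    if (!isTRUE(all.equal(p$position_nm, grid)))
      stop("profiles are not on a common grid")
  mat <- vapply(profiles, function(p) p$value, numeric(length(grid)))
  data.frame(position_nm = grid,
             mean = rowMeans(mat),
             sem = apply(mat, 1, stats::sd) / sqrt(ncol(mat)),
             n = ncol(mat))
}

#' Compare coat and membrane staining between two groups
#'
#' Per section, the coat summary is the mean normalized staining inside
#' `coat_window` and the membrane summary the mean inside `membrane_window`.
#' Each summary is compared between groups with a two-sample two-tailed
#' Student's t test (equal variances by default; set `welch = TRUE` for the
#' unequal-variance form). The difference trace is control mean minus mutant
#' mean, pointwise.
#'
#' @param control,mutant lists of `intensity_profile` (>= 2 sections each)
#' @param coat_window,membrane_window summary windows in nm; defaults
#'   `c(30, 85)` and `c(85, 105)` (inner leaflet at 100 nm by the box rule)
#' @param welch use Welch's t test instead of the equal-variance Student form
#' @return object of class `coat_comparison`: group mean traces, difference
#'   trace, per-section summaries, and a `tests` data.frame with t, df, p
#'   per summary window
#' @export
compare_groups <- function(control, mutant, coat_window = c(30, 85),
                           membrane_window = c(85, 105), welch = FALSE) {
  if (length(control) < 2 || length(mutant) < 2)
    stop("each group needs at least 2 sections")
  if (diff(coat_window) <= 0 || diff(membrane_window) <= 0)
    stop("summary windows must have positive extent")
  avg_c <- average_profiles(control)
  avg_m <- average_profiles(mutant)
  if (!isTRUE(all.equal(avg_c$position_nm, avg_m$position_nm)))
    stop("groups are not on a common grid")

  window_mean <- function(p, w)
    mean(p$value[p$position_nm >= w[1] & p$position_nm <= w[2]])
  summaries <- data.frame(
    group = c(rep("control", length(control)), rep("mutant", length(mutant))),
    coat = c(vapply(control, window_mean, numeric(1), w = coat_window),
             vapply(mutant, window_mean, numeric(1), w = coat_window)),
    membrane = c(vapply(control, window_mean, numeric(1), w = membrane_window),
                 vapply(mutant, window_mean, numeric(1), w = membrane_window)))

  run_t <- function(vals) {
    a <- vals[summaries$group == "control"]
    b <- vals[summaries$group == "mutant"]
    if (stats::sd(c(a - mean(a), b - mean(b))) == 0) {
      # degenerate: identical within groups; t test undefined or trivial
      same <- isTRUE(all.equal(mean(a), mean(b)))
      return(list(statistic = if (same) 0 else Inf,
                  parameter = length(a) + length(b) - 2,
                  p.value = if (same) 1 else 0))
    }
    tt <- stats::t.test(a, b, var.equal = !welch)
    list(statistic = unname(tt$statistic), parameter = unname(tt$parameter),
         p.value = tt$p.value)
  }
  t_coat <- run_t(summaries$coat)
  t_mem <- run_t(summaries$membrane)

  structure(list(
    control_mean = avg_c, mutant_mean = avg_m,
    difference = data.frame(position_nm = avg_c$position_nm,
                            value = avg_c$mean - avg_m$mean),
    summaries = summaries,
    tests = data.frame(window = c("coat", "membrane"),
                       lo_nm = c(coat_window[1], membrane_window[1]),
                       hi_nm = c(coat_window[2], membrane_window[2]),
                       t = c(t_coat$statistic, t_mem$statistic),
                       df = c(t_coat$parameter, t_mem$parameter),
                       p = c(t_coat$p.value, t_mem$p.value)),
    n_control = length(control), n_mutant = length(mutant),
    welch = welch),
    class = "coat_comparison")
}

#' @export
print.coat_comparison <- function(x, ...) {
  cat(sprintf("coat comparison: %d control vs %d mutant sections (%s t test)\n",
              x$n_control, x$n_mutant,
              if (x$welch) "Welch" else "Student equal-variance"))
  print(x$tests, row.names = FALSE)
  invisible(x)
}
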