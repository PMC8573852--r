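# Screen geometry, visual-angle arithmetic and AOI layout.

#' Screen geometry of the stimulus display
#'
#' Physical layout of the notated melody on screen. Defaults reproduce the
#' experimental display: a 27.3 cm staff (1.3 cm clef/meter block followed by
#' four 6.5 cm bars) centred on a 49.92 x 28.08 cm (1920 x 1080 px) image
#' viewed from 60 cm, 2.24 x 2.11 cm AOIs, and a 32.23 x 5.98 cm valid area
#' centred on the staff.
#'
#' @param staff_width_cm Width of the whole staff.
#' @param clef_block_cm Width of the clef and meter annotation.
#' @param bar_width_cm Width of one bar.
#' @param staff_height_cm Height of the five-line staff.
#' @param aoi_width_cm,aoi_height_cm AOI rectangle size.
#' @param valid_width_cm,valid_height_cm Valid-area rectangle size.
#' @param image_width_px,image_height_px Stimulus image size in pixels.
#' @param image_width_cm,image_height_cm Stimulus image size in centimetres.
#' @param viewing_distance_cm Eye-to-screen distance.
#' @param min_aoi_deg Minimum admissible AOI size in degrees of visual angle.
#' @return An object of class `screen_geometry`.
#' @export
screen_geometry <- function(staff_width_cm = 27.3,
                            clef_block_cm = 1.3,
                            bar_width_cm = 6.5,
                            staff_height_cm = 0.78,
                            aoi_width_cm = 2.24,
                            aoi_height_cm = 2.11,
                            valid_width_cm = 32.23,
                            valid_height_cm = 5.98,
                            image_width_px = 1920,
                            image_height_px = 1080,
                            image_width_cm = 49.92,
                            image_height_cm = 28.08,
                            viewing_distance_cm = 60,
                            min_aoi_deg = 1.5) {
  geom <- structure(
    list(
      staff_width_cm = staff_width_cm,
      clef_block_cm = clef_block_cm,
      bar_width_cm = bar_width_cm,
      staff_height_cm = staff_height_cm,
      aoi_width_cm = aoi_width_cm,
      aoi_height_cm = aoi_height_cm,
      valid_width_cm = valid_width_cm,
      valid_height_cm = valid_height_cm,
      image_width_px = image_width_px,
      image_height_px = image_height_px,
      image_width_cm = image_width_cm,
      image_height_cm = image_height_cm,
      viewing_distance_cm = viewing_distance_cm,
      min_aoi_deg = min_aoi_deg
    ),
    class = "screen_geometry"
  )
  min_cm <- visual_angle_to_cm(min_aoi_deg, viewing_distance_cm)
  if (aoi_width_cm < min_cm || aoi_height_cm < min_cm) {
    stop(sprintf(
      "AOI size %.2f x %.2f cm is below the %.2f cm minimum (%g deg at %g cm)",
      aoi_width_cm, aoi_height_cm, min_cm, min_aoi_deg, viewing_distance_cm
    ))
  }
  geom
}

#' Convert a visual angle to extent on screen
#'
#' Uses the standard chord formula `2 * d * tan(angle / 2)`. At 60 cm
#' viewing distance, 2 degrees subtend 2.1 cm and 1.5 degrees 1.57 cm.
#'
#' @param angle_deg Visual angle in degrees, in `[0, 180)`.
#' @param distance_cm Viewing distance in centimetres, positive.
#' @return Extent on screen in centimetres.
#' @export
#' @examples
#' round(visual_angle_to_cm(2, 60), 1)    # 2.1
#' round(visual_angle_to_cm(1.5, 60), 2)  # 1.57
visual_angle_to_cm <- function(angle_deg, distance_cm) {
  if (any(distance_cm <= 0)) stop("distance_cm must be positive")
  if (any(angle_deg < 0 | angle_deg >= 180)) {
    stop("angle_deg must lie in [0, 180)")
  }
  2 * distance_cm * tan(angle_deg * pi / 360)
}

#' Convert an on-screen extent to visual angle
#'
#' Inverse of [visual_angle_to_cm()].
#'
#' @param size_cm Extent on screen in centimetres, non-negative.
#' @param distance_cm Viewing distance in centimetres, positive.
#' @return Visual angle in degrees.
#' @export
cm_to_visual_angle <- function(size_cm, distance_cm) {
  if (any(distance_cm <= 0)) stop("distance_cm must be positive")
  if (any(size_cm < 0)) stop("size_cm must be non-negative")
  2 * atan(size_cm / (2 * distance_cm)) * 180 / pi
}

#' Convert between pixel and centimetre screen coordinates
#'
#' The stimulus image maps 1920 px to 49.92 cm (and 1080 px to 28.08 cm), so
#' both axes share one scale. Conversion uses the horizontal scale and
#' errors if the vertical scale disagrees by more than 0.1%.
#'
#' @param px,cm Numeric coordinate vectors.
#' @param geometry A [screen_geometry()].
#' @return The converted coordinates.
#' @export
px_to_cm <- function(px, geometry = screen_geometry()) {
  px * .px_scale(geometry)
}

#' @rdname px_to_cm
#' @export
cm_to_px <- function(cm, geometry = screen_geometry()) {
  cm / .px_scale(geometry)
}

.px_scale <- function(geometry) {
  sx <- geometry$image_width_cm / geometry$image_width_px
  sy <- geometry$image_height_cm / geometry$image_height_px
  if (abs(sx - sy) / sx > 1e-3) {
    stop("anisotropic pixel scale: image px and cm sizes disagree across axes")
  }
  sx
}

#' Valid-area rectangle in image coordinates
#'
#' The valid area is centred on the staff, which itself is centred on the
#' image; fixations outside it are discarded by the trial exclusion rules.
#'
#' @param geometry A [screen_geometry()].
#' @return A named numeric vector `c(x0, x1, y0, y1)` in cm, origin at the
#'   image's top-left corner.
#' @export
valid_area_rect <- function(geometry = screen_geometry()) {
  cx <- geometry$image_width_cm / 2
  cy <- geometry$image_height_cm / 2
  c(
    x0 = cx - geometry$valid_width_cm / 2,
    x1 = cx + geometry$valid_width_cm / 2,
    y0 = cy - geometry$valid_height_cm / 2,
    y1 = cy + geometry$valid_height_cm / 2
  )
}

#' AOI rectangles for the note pairs of bars 2-4
#'
#' Each AOI starts at its bar's barline (the note pair of interest appears
#' directly after the barline) and is centred vertically on the staff. There
#' is no AOI on bar 1, whose content is previewed during the count-in.
#'
#' @param geometry A [screen_geometry()].
#' @param bars Integer vector of bar numbers carrying AOIs (default 2:4).
#' @return A tibble with columns `aoi_index`, `bar`, `x0`, `x1`, `y0`, `y1`
#'   (cm, origin top-left of image).
#' @export
aoi_rects <- function(geometry = screen_geometry(), bars = 2:4) {
  staff_x0 <- (geometry$image_width_cm - geometry$staff_width_cm) / 2
  bar_x0 <- staff_x0 + geometry$clef_block_cm +
    (bars - 1) * geometry$bar_width_cm
  cy <- geometry$image_height_cm / 2
  out <- tibble::tibble(
    aoi_index = seq_along(bars),
    bar = as.integer(bars),
    x0 = bar_x0,
    x1 = bar_x0 + geometry$aoi_width_cm,
    y0 = cy - geometry$aoi_height_cm / 2,
    y1 = cy + geometry$aoi_height_cm / 2
  )
  .check_aoi_overlap(out)
  out
}

.check_aoi_overlap <- function(aois) {
  n <- nrow(aois)
  if (n < 2) return(invisible(aois))
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      overlap_x <- aois$x0[i] < aois$x1[j] && aois$x0[j] < aois$x1[i]
      overlap_y <- aois$y0[i] < aois$y1[j] && aois$y0[j] < aois$y1[i]
      if (overlap_x && overlap_y) {
        stop(sprintf("AOIs %d and %d overlap", aois$aoi_index[i],
                     aois$aoi_index[j]))
      }
    }
  }
  invisible(aois)
}
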