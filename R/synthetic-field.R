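#' Specify one synthetic microcolony
#'
#' A colony is modelled as a compact blob whose area grows exponentially:
#' \code{area(t) = initial_area * exp(growth_rate * t)}, with
#' \code{growth_rate} the specific growth rate (natural-log area change per
#' hour). Fluorescence, when rendered, is uniform over the colony footprint.
#'
#' @param colony_id Identifier (character or integer).
#' @param center Numeric length-2, (x, y) pixel coordinates of the colony
#'   center (x = column, y = row, 1-based).
#' @param initial_area Footprint area at time 0, in pixels; must be > 0.
#' @param growth_rate Specific growth rate, per hour; must be finite.
#' @param fluorescence_level Per-pixel fluorescence intensity (arbitrary
#'   units, >= 0) used for the optional fluorescence channel.
#' @param survives_shock Logical; whether the colony resumes growth after a
#'   heat shock (see [simulate_heat_shock_series()]).
#' @param post_shock_rate Specific growth rate after the shock, per hour;
#'   only used when \code{survives_shock} is \code{TRUE}.
#' @return A \code{colony_spec} list.
#' @export
colony_spec <- function(colony_id, center, initial_area, growth_rate,
                        fluorescence_level = 0, survives_shock = TRUE,
                        post_shock_rate = growth_rate) {
  if (length(center) != 2 || !all(is.finite(center)))
    stopf("colony '%s': center must be finite (x, y)", colony_id)
  if (!is.finite(initial_area) || initial_area <= 0)
    stopf("colony '%s': initial_area must be > 0", colony_id)
  if (!is.finite(growth_rate))
    stopf("colony '%s': growth_rate must be finite", colony_id)
  if (!is.finite(fluorescence_level) || fluorescence_level < 0)
    stopf("colony '%s': fluorescence_level must be >= 0", colony_id)
  structure(list(colony_id = as.character(colony_id),
                 center = as.numeric(center),
                 initial_area = initial_area,
                 growth_rate = growth_rate,
                 fluorescence_level = fluorescence_level,
                 survives_shock = isTRUE(survives_shock),
                 post_shock_rate = post_shock_rate),
            class = "colony_spec")
}

#' Specify a synthetic imaging field
#'
#' Encodes the optical contract of low-magnification bright-field yeast
#' imaging: colony interiors are the brightest pixels in the field and the
#' 1--2 px colony perimeter the darkest, on an intermediate background. The
#' default intensities (background 0.50, interior 0.80, rim 0.15,
#' noise sd 0.02 on a [0, 1] scale) separate cleanly under the default
#' robust dual thresholds.
#'
#' @param width,height Field size in pixels.
#' @param colonies List of [colony_spec()] objects.
#' @param pixel_pitch Physical pixel size, micrometres per pixel. The default
#'   0.6708 corresponds to an area scale of 0.45 um^2 per pixel.
#' @param background_level,interior_level,rim_level Intensities on [0, 1];
#'   must satisfy \code{rim_level < background_level < interior_level}.
#' @param noise_sd Additive Gaussian pixel noise standard deviation.
#' @param fluor_background Background intensity of the fluorescence channel.
#' @param rim_width Width of the dark perimeter band, pixels (drawn inside
#'   the colony footprint so the footprint area stays analytic).
#' @param boundary_amp Relative amplitude of the seeded lobed perturbation of
#'   the colony boundary (0 gives perfect disks).
#' @param seed Integer seed; fixes all pixel noise and per-colony shapes.
#' @return A \code{field_spec} list.
#' @export
field_spec <- function(width, height, colonies = list(),
                       pixel_pitch = 0.6708,
                       background_level = 0.50, interior_level = 0.80,
                       rim_level = 0.15, noise_sd = 0.02,
                       fluor_background = 0.05,
                       rim_width = 1.5, boundary_amp = 0.04, seed = 1L) {
  if (width <= 0 || height <= 0) stopf("field dimensions must be positive")
  if (!(rim_level < background_level && background_level < interior_level))
    stopf("need rim_level < background_level < interior_level")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  if (!all(vapply(colonies, inherits, logical(1), "colony_spec")))
    stopf("colonies must be a list of colony_spec objects")
  structure(list(width = as.integer(width), height = as.integer(height),
                 colonies = colonies, pixel_pitch = pixel_pitch,
                 background_level = background_level,
                 interior_level = interior_level, rim_level = rim_level,
                 noise_sd = noise_sd, fluor_background = fluor_background,
                 rim_width = rim_width, boundary_amp = boundary_amp,
                 seed = as.integer(seed)),
            class = "field_spec")
}

# Deterministic per-colony boundary-shape parameters (no RNG involvement so
# shapes persist across frames and channels).
colony_shape <- function(spec, i) {
  h <- (abs(spec$seed) * 131L + i * 7919L) %% 100003L
  list(lobes = 3L + (h %% 4L),
       phase = (h %% 360L) * pi / 180,
       amp = spec$boundary_amp)
}

#' Render one synthetic frame and its ground-truth mask
#'
#' Draws every colony of a field at the given time as a filled, slightly
#' lobed disk of area \code{round(initial_area * exp(mu * t))} pixels with a
#' bright interior and a dark 1--2 px inner rim, adds Gaussian pixel noise,
#' and returns the image together with the ground-truth label mask.
#'
#' @param spec A [field_spec()].
#' @param time Acquisition time, hours (>= 0).
#' @param channel \code{"bright"} (default) or \code{"fluor"}; the
#'   fluorescence channel renders each footprint at the colony's uniform
#'   \code{fluorescence_level} with no rim.
#' @param well,field Optional identifiers attached to the frame.
#' @param saturate Internal: render colonies "large and white" (footprint
#'   inflated, interior at saturation), emulating the appearance ~10 um below
#'   the true focal plane; used by [simulate_defocus_stack()].
#' @return A list of class \code{mc_frame}: \code{pixels} (height x width
#'   matrix, values clamped to [0, 1]), \code{mask} (integer label matrix,
#'   0 = background, i = i-th colony), \code{time}, \code{channel},
#'   \code{well}, \code{field}.
#' @export
render_colony_field <- function(spec, time, channel = c("bright", "fluor"),
                                well = "A1", field = 1L, saturate = FALSE) {
  stopifnot(inherits(spec, "field_spec"))
  channel <- match.arg(channel)
  if (!is.finite(time) || time < 0) stopf("time must be >= 0")
  w <- spec$width; h <- spec$height
  bg <- if (channel == "bright") spec$background_level else spec$fluor_background
  px <- matrix(bg, nrow = h, ncol = w)
  mask <- matrix(0L, nrow = h, ncol = w)
  inflate <- if (saturate) 1.3 else 1.0
  for (i in seq_along(spec$colonies)) {
    co <- spec$colonies[[i]]
    area <- co$initial_area * exp(co$growth_rate * time)
    r <- sqrt(area / pi) * inflate
    sh <- colony_shape(spec, i)
    rmax <- r * (1 + sh$amp) * 1.06 + 2   # head-room for radius calibration
    cx <- co$center[1]; cy <- co$center[2]
    if (cx - rmax < 1 || cx + rmax > w || cy - rmax < 1 || cy + rmax > h)
      stopf("colony '%s' exceeds field bounds at t = %g h", co$colony_id, time)
    xs <- floor(cx - rmax):ceiling(cx + rmax)
    ys <- floor(cy - rmax):ceiling(cy + rmax)
    dxm <- matrix(xs - cx, nrow = length(ys), ncol = length(xs), byrow = TRUE)
    dym <- matrix(ys - cy, nrow = length(ys), ncol = length(xs))
    d <- sqrt(dxm * dxm + dym * dym)
    shape <- 1 + sh$amp * cos(sh$lobes * atan2(dym, dxm) + sh$phase)
    # calibrate the radius so the rasterized pixel count equals the rounded
    # analytic area: take the k-th smallest shape-normalized distance
    u <- d / shape + seq_along(d) * 1e-9   # epsilon breaks symmetry ties
    k <- max(1L, min(round(area), length(u)))
    r <- sort(u, partial = k)[k]
    inside <- u <= r
    rb <- r * shape
    sub <- px[ys, xs, drop = FALSE]
    if (channel == "bright") {
      lev <- if (saturate) 1.0 else spec$interior_level
      sub[inside] <- lev
      if (!saturate) {
        rim <- inside & d > (rb - spec$rim_width)
        sub[rim] <- spec$rim_level
      }
    } else {
      sub[inside] <- co$fluorescence_level
    }
    px[ys, xs] <- sub
    msub <- mask[ys, xs, drop = FALSE]
    msub[inside] <- i
    mask[ys, xs] <- msub
  }
  if (spec$noise_sd > 0)
    px <- px + with_seed(frame_seed(spec$seed, time, channel),
                         matrix(stats::rnorm(h * w, 0, spec$noise_sd), h, w))
  px[px < 0] <- 0
  px[px > 1] <- 1
  structure(list(pixels = px, mask = mask, time = time, channel = channel,
                 well = well, field = field),
            class = "mc_frame")
}

#' @export
print.mc_frame <- function(x, ...) {
  cat(sprintf("<mc_frame> %dx%d px, t = %g h, channel = %s, well %s field %s\n",
              nrow(x$pixels), ncol(x$pixels), x$time, x$channel,
              x$well, x$field))
  invisible(x)
}
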