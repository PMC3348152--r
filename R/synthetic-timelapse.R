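#' Simulate a bright-field time-lapse with ground truth
#'
#' Renders one frame per requested time (optionally plus a fluorescence
#' frame) and records the exact analytic ground truth per colony and
#' timepoint. Manifest areas follow \code{area(t) = initial_area * exp(mu t)}
#' exactly; the rasterized pixel count is recorded alongside. A fixed field
#' seed makes the pixel output bit-identical across calls.
#'
#' @param spec A [field_spec()].
#' @param times Strictly increasing acquisition times, hours.
#' @param fluorescence Also render a fluorescence frame per timepoint?
#' @param well,field Identifiers attached to the frames and manifest.
#' @return A list of class \code{mc_timelapse}: \code{frames} (list of
#'   bright-field [render_colony_field()] frames), \code{fluor_frames}
#'   (list or \code{NULL}), \code{manifest} (data.frame: colony_id, label,
#'   time, area (analytic), raster_px, x, y, growth_rate), \code{spec}.
#' @export
simulate_timelapse <- function(spec, times, fluorescence = FALSE,
                               well = "A1", field = 1L) {
  stopifnot(inherits(spec, "field_spec"))
  if (length(times) < 1 || any(!is.finite(times)))
    stopf("times must be finite")
  if (any(diff(times) <= 0)) stopf("times must be strictly increasing")
  frames <- lapply(times, render_colony_field, spec = spec,
                   channel = "bright", well = well, field = field)
  fluor <- if (fluorescence)
    lapply(times, render_colony_field, spec = spec, channel = "fluor",
           well = well, field = field)
  man <- do.call(rbind, lapply(seq_along(times), function(k) {
    fr <- frames[[k]]
    raster <- tabulate(fr$mask[fr$mask > 0L],
                       nbins = length(spec$colonies))
    do.call(rbind, lapply(seq_along(spec$colonies), function(i) {
      co <- spec$colonies[[i]]
      data.frame(colony_id = co$colony_id, label = i, time = times[k],
                 area = co$initial_area * exp(co$growth_rate * times[k]),
                 raster_px = raster[i],
                 x = co$center[1], y = co$center[2],
                 growth_rate = co$growth_rate,
                 stringsAsFactors = FALSE)
    }))
  }))
  structure(list(frames = frames, fluor_frames = fluor,
                 manifest = man, spec = spec, well = well, field = field),
            class = "mc_timelapse")
}

#' Simulate a heat-shock experiment (pre/post series with a plate shift)
#'
#' Removing and replacing the plate for the shock shifts every colony
#' rigidly by the same vector. Pre-shock frames follow
#' [simulate_timelapse()]; in the post-shock series every colony center is
#' translated by \code{shift}, non-survivors keep the area they had at the
#' end of the pre-shock series, and survivors grow at their
#' \code{post_shock_rate} from the first post-shock frame onwards.
#'
#' @param spec A [field_spec()].
#' @param pre_times,post_times Strictly increasing times, hours. Post-shock
#'   times are expressed on their own clock (growth is measured from
#'   \code{post_times[1]}).
#' @param shift Numeric length-2 (dx, dy), pixels.
#' @param fluorescence Render fluorescence frames for the pre-shock series?
#' @param well,field Identifiers.
#' @return List of class \code{mc_shock_series}: \code{pre}, \code{post}
#'   (both \code{mc_timelapse}), \code{shift}, and \code{survival}
#'   (data.frame: colony_id, label, survives, area_at_shock,
#'   true_delta_px over the post window).
#' @export
simulate_heat_shock_series <- function(spec, pre_times, post_times,
                                       shift = c(0, 0), fluorescence = FALSE,
                                       well = "A1", field = 1L) {
  stopifnot(inherits(spec, "field_spec"))
  if (length(shift) != 2 || !all(is.finite(shift)))
    stopf("shift must be finite (dx, dy)")
  pre <- simulate_timelapse(spec, pre_times, fluorescence = fluorescence,
                            well = well, field = field)
  t_shock <- max(pre_times)
  post_colonies <- lapply(spec$colonies, function(co) {
    colony_spec(co$colony_id,
                center = co$center + shift,
                initial_area = co$initial_area * exp(co$growth_rate * t_shock),
                growth_rate = if (co$survives_shock) co$post_shock_rate else 0,
                fluorescence_level = co$fluorescence_level,
                survives_shock = co$survives_shock,
                post_shock_rate = co$post_shock_rate)
  })
  post_spec <- spec
  post_spec$colonies <- post_colonies
  post_spec$seed <- spec$seed + 104729L
  post <- simulate_timelapse(post_spec, post_times - post_times[1],
                             well = well, field = field)
  # report post manifest on the caller's post clock
  post$manifest$time <- post$manifest$time + post_times[1]
  for (k in seq_along(post$frames)) post$frames[[k]]$time <- post_times[k]
  window <- max(post_times) - post_times[1]
  surv <- do.call(rbind, lapply(seq_along(spec$colonies), function(i) {
    co <- spec$colonies[[i]]
    a0 <- co$initial_area * exp(co$growth_rate * t_shock)
    rate <- if (co$survives_shock) co$post_shock_rate else 0
    data.frame(colony_id = co$colony_id, label = i,
               survives = co$survives_shock,
               area_at_shock = a0,
               true_delta_px = a0 * (exp(rate * window) - 1),
               stringsAsFactors = FALSE)
  }))
  structure(list(pre = pre, post = post, shift = as.numeric(shift),
                 survival = surv),
            class = "mc_shock_series")
}

#' Simulate a focusing stack of defocus offsets
#'
#' Emulates the idiosyncratic optics used by the plate-focusing routine:
#' roughly 10 um below the ideal focal plane, yeast appear large and white,
#' producing a sharp peak of saturated pixels. The frame at
#' \code{focal_index} is rendered in that state (inflated footprints,
#' interior at full saturation), so the offset-selection rule
#' ([select_focus_offset()]) should return \code{offsets[focal_index] + 10}.
#'
#' @param spec A [field_spec()] with at least one colony.
#' @param offsets Distinct focus offsets, micrometres (>= 2 values).
#' @param focal_index Index into \code{offsets} of the below-focus frame.
#' @return List of frames; each frame carries an \code{offset} element.
#' @export
simulate_defocus_stack <- function(spec, offsets, focal_index) {
  stopifnot(inherits(spec, "field_spec"))
  if (length(offsets) < 2) stopf("need at least 2 offsets")
  if (anyDuplicated(offsets)) stopf("offsets must be distinct")
  if (focal_index < 1 || focal_index > length(offsets))
    stopf("focal_index out of range")
  if (length(spec$colonies) == 0)
    stopf("field has no colonies: nothing to saturate")
  lapply(seq_along(offsets), function(k) {
    fr <- render_colony_field(spec, time = 0, channel = "bright",
                              saturate = (k == focal_index))
    fr$offset <- offsets[k]
    fr
  })
}
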