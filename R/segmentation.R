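#' Segmentation parameters
#'
#' The assay gives no absolute threshold values, so the defaults are
#' scale-free robust estimates per frame: high = median + k * MAD,
#' low = median - k * MAD (k = 5). Absolute overrides are available for
#' calibrated setups.
#'
#' @param high,low Either \code{"auto"} (robust per-frame estimate) or an
#'   absolute intensity.
#' @param k_mad Multiplier for the robust thresholds.
#' @param morph_rounds Rounds of dilation, then the same number of rounds of
#'   erosion, applied to each threshold mask ("several rounds"); default 3
#'   closes 1--2 px rim gaps without bridging neighbouring colonies.
#' @param struct_element \code{"cross"} (3x3 diamond) or \code{"square"}.
#' @param min_object_px Minimum object area kept, pixels.
#' @param saturation_level Intensity at or above which a pixel counts as
#'   saturated (focusing rule).
#' @return A \code{segmentation_params} list.
#' @export
segmentation_params <- function(high = "auto", low = "auto", k_mad = 5,
                                morph_rounds = 3,
                                struct_element = c("cross", "square"),
                                min_object_px = 20, saturation_level = 1.0) {
  struct_element <- match.arg(struct_element)
  if (morph_rounds < 0) stopf("morph_rounds must be >= 0")
  if (min_object_px < 0) stopf("min_object_px must be >= 0")
  structure(list(high = high, low = low, k_mad = k_mad,
                 morph_rounds = morph_rounds,
                 struct_element = struct_element,
                 min_object_px = min_object_px,
                 saturation_level = saturation_level),
            class = "segmentation_params")
}

#' Choose the focus offset from a defocus stack
#'
#' Implements the plate-focusing rule: yeast about 10 um below the ideal
#' focal plane appear large and white, so the ideal plane lies 10 um above
#' the offset whose image carries the most saturated pixels. Ties are broken
#' toward the lowest offset.
#'
#' @param stack List of frames, each with \code{pixels} and \code{offset}
#'   (micrometres), e.g. from [simulate_defocus_stack()].
#' @param saturation_level Saturation intensity threshold.
#' @return Chosen focus offset, micrometres.
#' @export
select_focus_offset <- function(stack, saturation_level = 1.0) {
  if (length(stack) < 2) stopf("need at least 2 frames to focus")
  offsets <- vapply(stack, function(f) f$offset %||% NA_real_, numeric(1))
  if (any(is.na(offsets)) || anyDuplicated(offsets))
    stopf("frames must carry distinct offsets")
  counts <- vapply(stack, function(f) sum(f$pixels >= saturation_level),
                   numeric(1))
  if (all(counts == 0)) stopf("cannot focus: no frame contains saturated pixels")
  best <- which(counts == max(counts))
  offsets[best[which.min(offsets[best])]] + 10
}

struct_kernel <- function(struct_element) {
  EBImage::makeBrush(3, shape = if (struct_element == "cross") "diamond"
                     else "box")
}

# morph_rounds of dilation followed by morph_rounds of erosion (a closing
# that spans gaps up to ~2*rounds px with a 3x3 element).
morph_cleanup <- function(mask, rounds, kern) {
  m <- mask
  if (rounds > 0) {
    for (i in seq_len(rounds)) m <- EBImage::dilate(m, kern)
    for (i in seq_len(rounds)) m <- EBImage::erode(m, kern)
  }
  m
}

#' Segment microcolonies by the dual-threshold AND rule
#'
#' Microcolonies are both the brightest objects in a bright-field frame
#' (cell centers) and the dimmest (cell perimeters). Two binary masks are
#' built -- pixels above the high threshold and pixels below the low
#' threshold -- and each is subjected to several rounds of dilation then
#' erosion to form continuous objects. Connected components of the union
#' are kept only if they intersect \emph{both} cleaned masks: debris that is
#' only bright or only dark never carries the paired signature and is
#' discarded. Components smaller than \code{min_object_px} are dropped.
#'
#' @param frame A bright-field frame (list with \code{pixels}; see
#'   [render_colony_field()]).
#' @param params A [segmentation_params()].
#' @return A list of class \code{mc_objects}: \code{labels} (integer matrix,
#'   0 background), \code{table} (data.frame: label, area_px, x, y,
#'   feret_px, touches_edge), \code{time}, \code{well}, \code{field},
#'   \code{thresholds}.
#' @export
dual_threshold_segment <- function(frame, params = segmentation_params()) {
  if (!is.null(frame$channel) && frame$channel != "bright")
    stopf("dual_threshold_segment expects a bright-field frame")
  px <- frame$pixels
  if (!is.matrix(px) || length(px) == 0) stopf("frame has no pixel grid")
  if (any(!is.finite(px))) stopf("frame contains non-finite intensities")
  med <- stats::median(px)
  s <- stats::mad(px)
  hi <- if (identical(params$high, "auto")) med + params$k_mad * s else params$high
  lo <- if (identical(params$low, "auto")) med - params$k_mad * s else params$low
  if (hi < lo) stopf("degenerate thresholds: high (%g) below low (%g)", hi, lo)
  kern <- struct_kernel(params$struct_element)
  hi_m <- morph_cleanup((px > hi) * 1, params$morph_rounds, kern)
  lo_m <- morph_cleanup((px < lo) * 1, params$morph_rounds, kern)
  lab <- EBImage::bwlabel(pmax(hi_m, lo_m))
  keep <- integer(0)
  if (max(lab) > 0) {
    n <- max(lab)
    idx <- lab > 0
    labs <- lab[idx]
    in_hi <- tabulate(labs[hi_m[idx] > 0], nbins = n)
    in_lo <- tabulate(labs[lo_m[idx] > 0], nbins = n)
    area <- tabulate(labs, nbins = n)
    keep <- which(in_hi > 0 & in_lo > 0 & area >= params$min_object_px)
  }
  relab <- matrix(0L, nrow(lab), ncol(lab))
  if (length(keep)) {
    map <- integer(max(lab))
    map[keep] <- seq_along(keep)
    pos <- lab > 0
    relab[pos] <- map[lab[pos]]
  }
  structure(list(labels = relab,
                 table = label_table(relab),
                 time = frame$time %||% NA_real_,
                 well = frame$well %||% NA_character_,
                 field = frame$field %||% NA,
                 thresholds = c(high = hi, low = lo)),
            class = "mc_objects")
}

# Per-label area, centroid, Feret diameter and edge contact.
label_table <- function(labels) {
  n <- max(labels)
  if (n == 0)
    return(data.frame(label = integer(0), area_px = numeric(0),
                      x = numeric(0), y = numeric(0), feret_px = numeric(0),
                      touches_edge = logical(0)))
  idx <- which(labels > 0, arr.ind = TRUE)
  labs <- labels[labels > 0]
  area <- tabulate(labs, nbins = n)
  cx <- tapply(idx[, "col"], labs, mean)
  cy <- tapply(idx[, "row"], labs, mean)
  h <- nrow(labels); w <- ncol(labels)
  edge <- tapply(idx[, "row"] == 1 | idx[, "row"] == h |
                   idx[, "col"] == 1 | idx[, "col"] == w, labs, any)
  feret <- vapply(seq_len(n), function(k) {
    pts <- idx[labs == k, , drop = FALSE]
    feret_diameter(pts[, "col"], pts[, "row"])
  }, numeric(1))
  data.frame(label = seq_len(n), area_px = as.numeric(area),
             x = as.numeric(cx), y = as.numeric(cy), feret_px = feret,
             touches_edge = as.logical(edge))
}

# Maximum Feret diameter: largest pairwise distance between object pixel
# centers; reduced to the convex hull first, so only extreme (boundary)
# points enter the O(b^2) scan.
feret_diameter <- function(xs, ys) {
  if (length(xs) == 1) return(0)
  pts <- cbind(xs, ys)
  if (nrow(pts) > 3) {
    hull <- grDevices::chull(pts)
    pts <- pts[hull, , drop = FALSE]
  }
  d <- cross_dist(pts[, 1], pts[, 2], pts[, 1], pts[, 2])
  max(d)
}

#' Measure labeled objects, optionally with fluorescence density
#'
#' Area is the labeled pixel count, the centroid the mean pixel coordinate,
#' the Feret diameter the longest straight-line span, and -- when a
#' co-registered fluorescence frame is supplied -- fluorescence density the
#' mean fluorescence intensity over all pixels within the object.
#'
#' @param objects An \code{mc_objects} result from [dual_threshold_segment()].
#' @param fluor_frame Optional fluorescence frame whose pixel grid matches
#'   the segmented frame.
#' @return The object table, with a \code{fluor_density} column when a
#'   fluorescence frame is given.
#' @export
measure_objects <- function(objects, fluor_frame = NULL) {
  stopifnot(inherits(objects, "mc_objects"))
  tab <- objects$table
  if (!is.null(fluor_frame)) {
    fp <- fluor_frame$pixels
    if (!identical(dim(fp), dim(objects$labels)))
      stopf("fluorescence frame shape %s does not match bright frame %s",
            paste(dim(fp), collapse = "x"),
            paste(dim(objects$labels), collapse = "x"))
    labs <- objects$labels[objects$labels > 0]
    vals <- fp[objects$labels > 0]
    dens <- tapply(vals, labs, mean)
    tab$fluor_density <- as.numeric(dens[as.character(tab$label)])
  }
  tab
}
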