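#' Fit the specific growth rate of one colony track
#'
#' The specific growth rate is the ordinary least-squares slope of
#' \code{log(area)} (natural log, pixels) against time (hours) over all
#' recorded points, and the fit quality is the Pearson correlation of that
#' relationship. Tracks with fewer than \code{min_timepoints} recorded
#' points are flagged excluded. A colony counts as having divided when its
#' fitted rate exceeds 0.1 per hour.
#'
#' @param track_points data.frame with columns \code{time} and
#'   \code{area_px} (and optionally \code{track_id},
#'   \code{fluor_density}); all areas must be positive.
#' @param min_timepoints Minimum points for inclusion (default 5).
#' @return One-row data.frame: track_id, mu (per hour), r, n_timepoints,
#'   mean_fluor, divided, degenerate_fit, included, exclusion_reason.
#' @export
fit_specific_growth_rate <- function(track_points, min_timepoints = 5) {
  tp <- track_points[order(track_points$time), ]
  if (nrow(tp) < 1) stopf("track has no points")
  if (any(tp$area_px <= 0)) stopf("non-positive colony area")
  la <- log(tp$area_px)
  n <- nrow(tp)
  degenerate <- FALSE
  if (n < 2) {
    mu <- NA_real_; r <- NA_real_
  } else if (stats::sd(la) == 0) {
    mu <- 0; r <- 0; degenerate <- TRUE
  } else {
    mu <- stats::cov(tp$time, la) / stats::var(tp$time)
    r <- stats::cor(tp$time, la)
  }
  included <- n >= min_timepoints
  data.frame(track_id = tp$track_id[1] %||% NA,
             mu = mu, r = r, n_timepoints = n,
             mean_fluor = if (!is.null(tp$fluor_density))
               mean(tp$fluor_density) else NA_real_,
             divided = isTRUE(mu > 0.1),
             degenerate_fit = degenerate,
             included = included,
             exclusion_reason = if (included) "" else "too_few_timepoints",
             stringsAsFactors = FALSE)
}

#' Fit growth rates for all tracks
#'
#' @param tracks An \code{mc_tracks} result from [link_frames()], or a
#'   points data.frame with \code{track_id}, \code{time}, \code{area_px}.
#' @param min_timepoints Minimum points for inclusion.
#' @return data.frame of [fit_specific_growth_rate()] rows, one per track.
#' @export
fit_growth_rates <- function(tracks, min_timepoints = 5) {
  pts <- if (inherits(tracks, "mc_tracks")) tracks$points else tracks
  out <- do.call(rbind, lapply(split(pts, pts$track_id),
                               fit_specific_growth_rate,
                               min_timepoints = min_timepoints))
  rownames(out) <- NULL
  out
}

#' Spatial quality-control filters
#'
#' Computes, for each track, the time-averaged centroid, the distance to
#' its nearest neighbouring colony and to the field edge (micrometres), and
#' flags exclusions: colonies with a nearest neighbour closer than
#' \code{neighbor_min_um} (close neighbours bias rates: fast-growing pairs
#' merge before five timepoints accrue) or within \code{edge_min_um} of the
#' field edge. The two filters commute; reasons are reported sorted so the
#' flags are order-independent.
#'
#' @param records Growth-record data.frame (must carry \code{track_id}).
#' @param tracks \code{mc_tracks} (or points data.frame) used for the
#'   time-averaged centroids.
#' @param field_px Numeric length-2 (width, height) of the field, pixels.
#' @param pixel_pitch Micrometres per pixel.
#' @param neighbor_min_um,edge_min_um Exclusion radii, micrometres.
#' @return \code{records} with added columns nearest_neighbor_um,
#'   edge_um, and updated included/exclusion_reason.
#' @export
compute_spatial_qc <- function(records, tracks, field_px,
                               pixel_pitch = 0.6708,
                               neighbor_min_um = 35, edge_min_um = 55) {
  if (pixel_pitch <= 0) stopf("pixel_pitch must be > 0")
  pts <- if (inherits(tracks, "mc_tracks")) tracks$points else tracks
  cen <- do.call(rbind, lapply(split(pts, pts$track_id), function(tp)
    data.frame(track_id = tp$track_id[1], x = mean(tp$x), y = mean(tp$y))))
  m <- match(records$track_id, cen$track_id)
  x <- cen$x[m]; y <- cen$y[m]
  nn_um <- nn_dist(cen$x, cen$y)[m] * pixel_pitch
  edge_um <- pmin(x - 1, field_px[1] - x, y - 1, field_px[2] - y) * pixel_pitch
  records$nearest_neighbor_um <- nn_um
  records$edge_um <- edge_um
  for (i in seq_len(nrow(records))) {
    reasons <- character(0)
    if (nzchar(records$exclusion_reason[i]))
      reasons <- strsplit(records$exclusion_reason[i], ";")[[1]]
    if (is.finite(edge_um[i]) && edge_um[i] < edge_min_um)
      reasons <- c(reasons, "edge")
    if (is.finite(nn_um[i]) && nn_um[i] < neighbor_min_um)
      reasons <- c(reasons, "proximity")
    reasons <- sort(unique(reasons))
    records$exclusion_reason[i] <- paste(reasons, collapse = ";")
    records$included[i] <- length(reasons) == 0
  }
  records
}

#' Normalize growth rates against per-well reference colonies
#'
#' Each rate is divided by the mean rate of the reference-strain colonies
#' measured in the same well; optionally all values are then rescaled so
#' that the grand mean of the control-strain records equals one.
#'
#' @param records data.frame with \code{mu} and \code{well}.
#' @param reference data.frame of reference-strain records (\code{mu},
#'   \code{well}); must be non-empty for every well in \code{records}.
#' @param controls Optional data.frame of control records (\code{mu},
#'   \code{well}) put through the same per-well normalization; their grand
#'   mean is then set to one.
#' @return \code{records} with an added \code{mu_norm} column.
#' @export
normalize_rates <- function(records, reference, controls = NULL) {
  ref_means <- tapply(reference$mu, reference$well, mean)
  wells <- unique(records$well)
  missing <- setdiff(wells, names(ref_means))
  if (length(missing))
    stopf("no reference colonies in well(s): %s",
          paste(missing, collapse = ", "))
  records$mu_norm <- records$mu / as.numeric(ref_means[records$well])
  if (!is.null(controls)) {
    miss2 <- setdiff(unique(controls$well), names(ref_means))
    if (length(miss2))
      stopf("no reference colonies in well(s): %s",
            paste(miss2, collapse = ", "))
    ctrl <- controls$mu / as.numeric(ref_means[controls$well])
    records$mu_norm <- records$mu_norm / mean(ctrl)
  }
  records
}

#' Summarize a growth-rate distribution
#'
#' Slow growers are operationally defined as colonies growing at less than
#' half the population median rate.
#'
#' @param rates Numeric vector of specific growth rates (n >= 1).
#' @return List of class \code{mc_distribution}: n, mean, sd, median,
#'   half_median, fraction_slow, and \code{cdf} (data.frame: rate,
#'   quantile -- the empirical cumulative distribution).
#' @export
summarize_distribution <- function(rates) {
  rates <- rates[is.finite(rates)]
  if (length(rates) < 1) stopf("need at least one finite rate")
  med <- stats::median(rates)
  s <- sort(rates)
  structure(list(n = length(rates), mean = mean(rates),
                 sd = stats::sd(rates), median = med,
                 half_median = med / 2,
                 fraction_slow = mean(rates < med / 2),
                 cdf = data.frame(rate = s,
                                  quantile = seq_along(s) / length(s))),
            class = "mc_distribution")
}

#' @export
print.mc_distribution <- function(x, ...) {
  cat(sprintf(paste0("<growth-rate distribution> n = %d, mean = %.4g,",
                     " median = %.4g, fraction below half-median = %.3g\n"),
              x$n, x$mean, x$median, x$fraction_slow))
  invisible(x)
}

# Rank-sum comparison: exact enumeration (via the exact null distribution)
# for small untied samples, normal approximation with tie correction
# otherwise -- stats::wilcox.test implements exactly this policy.
rank_sum_p <- function(x, y, exact_max = 20) {
  suppressWarnings(stats::wilcox.test(
    x, y, exact = (length(x) <= exact_max && length(y) <= exact_max &&
                     !anyDuplicated(c(x, y))))$p.value)
}

#' Binned comparison of a measured value
#'
#' Bins records by one variable and, for each bin, reports the mean and
#' standard error of a second value plus a two-sided rank-sum p-value
#' contrasting the bin with the remaining records.
#'
#' @param records data.frame.
#' @param value Column name of the value summarized per bin.
#' @param by Column name of the binning variable.
#' @param edges Numeric bin edges (length >= 3, giving >= 2 bins).
#' @return data.frame per bin: bin, lo, hi, n, mean, sem, p, degenerate.
#'   Empty bins are skipped with a warning; a bin holding every record is
#'   flagged degenerate (no complement to compare against).
#' @export
bin_and_compare <- function(records, value, by, edges) {
  if (length(edges) < 3) stopf("need at least 2 bins")
  v <- records[[value]]; b <- records[[by]]
  ok <- is.finite(v) & is.finite(b)
  v <- v[ok]; b <- b[ok]
  bins <- cut(b, edges, include.lowest = TRUE)
  if (sum(table(bins) > 0) < 2) stopf("need >= 2 non-empty bins")
  out <- lapply(seq_along(levels(bins)), function(i) {
    inb <- which(as.integer(bins) == i)
    if (length(inb) == 0) {
      warning(sprintf("empty bin %s skipped", levels(bins)[i]), call. = FALSE)
      return(NULL)
    }
    degenerate <- length(inb) == length(v)
    p <- if (degenerate) NA_real_ else rank_sum_p(v[inb], v[-inb])
    data.frame(bin = levels(bins)[i], lo = edges[i], hi = edges[i + 1],
               n = length(inb), mean = mean(v[inb]),
               sem = stats::sd(v[inb]) / sqrt(length(inb)),
               p = p, degenerate = degenerate, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Calibrate automated colony area against manual cell counts
#'
#' Least-squares line of manual count on automated area, with Bland-Altman
#' agreement statistics of (area-predicted count - manual count).
#'
#' @param areas,counts Paired numeric vectors (>= 3 pairs).
#' @return List: slope, intercept, r_squared, slope_se, intercept_se,
#'   ba_mean (mean difference), ba_lo, ba_hi (mean +/- 1.96 sd).
#' @export
calibrate_area_to_count <- function(areas, counts) {
  if (length(areas) != length(counts)) stopf("areas and counts differ in length")
  if (length(areas) < 3) stopf("need at least 3 area/count pairs")
  fit <- stats::lm(counts ~ areas)
  pred <- stats::fitted(fit)
  diffs <- pred - counts
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       slope_se = sm$coefficients[2, 2],
       intercept_se = sm$coefficients[1, 2],
       r_squared = sm$r.squared,
       ba_mean = mean(diffs),
       ba_lo = mean(diffs) - 1.96 * stats::sd(diffs),
       ba_hi = mean(diffs) + 1.96 * stats::sd(diffs))
}
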