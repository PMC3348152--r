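#' Tracking parameters
#'
#' @param max_displacement Maximal centroid displacement matched between
#'   consecutive frames, micrometres per frame. Colonies are near-immobile
#'   at hourly framing, so the default is tight.
#' @param area_drop_abort_fraction Relative area decrease between
#'   consecutive frames above which tracking is aborted (large drops
#'   indicate an image-analysis failure).
#' @param denovo_factor De-novo objects are merged into the nearest active
#'   track if their centroid lies within \code{denovo_factor} times that
#'   track's longest straight-line span (Feret diameter); 0.65 by
#'   convention.
#' @param min_timepoints Minimum recorded timepoints for a track to enter
#'   growth fitting.
#' @param isolation_threshold Minimal nearest-neighbour distance
#'   (micrometres) for a colony to be used in plate-shift estimation.
#' @param pixel_pitch Micrometres per pixel.
#' @return A \code{tracking_params} list.
#' @export
tracking_params <- function(max_displacement = 15,
                            area_drop_abort_fraction = 0.25,
                            denovo_factor = 0.65, min_timepoints = 5,
                            isolation_threshold = 100,
                            pixel_pitch = 0.6708) {
  if (area_drop_abort_fraction <= 0 || area_drop_abort_fraction >= 1)
    stopf("area_drop_abort_fraction must be in (0, 1)")
  if (min_timepoints < 2) stopf("min_timepoints must be >= 2")
  if (pixel_pitch <= 0) stopf("pixel_pitch must be > 0")
  structure(list(max_displacement = max_displacement,
                 area_drop_abort_fraction = area_drop_abort_fraction,
                 denovo_factor = denovo_factor,
                 min_timepoints = min_timepoints,
                 isolation_threshold = isolation_threshold,
                 pixel_pitch = pixel_pitch),
            class = "tracking_params")
}

# Label pairs whose masks lie within `gap` px of each other (Chebyshev),
# found by comparing the label grid against shifted copies of itself.
adjacent_label_pairs <- function(labels, gap = 1) {
  offs <- list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  if (gap >= 1)
    offs <- c(offs, list(c(0, 2), c(2, 0), c(1, 2), c(2, 1),
                         c(1, -2), c(2, -1), c(2, 2), c(2, -2)))
  h <- nrow(labels); w <- ncol(labels)
  pairs <- matrix(integer(0), ncol = 2)
  for (o in offs) {
    dr <- o[1]; dc <- o[2]
    r1 <- max(1, 1 - dr):min(h, h - dr)
    c1 <- max(1, 1 - dc):min(w, w - dc)
    a <- labels[r1, c1, drop = FALSE]
    b <- labels[r1 + dr, c1 + dc, drop = FALSE]
    hit <- a > 0 & b > 0 & a != b
    if (any(hit))
      pairs <- rbind(pairs, cbind(pmin(a[hit], b[hit]), pmax(a[hit], b[hit])))
  }
  unique(pairs)
}

# Greedy assignment of tracks to objects by ascending centroid distance
# within max_dist; ties broken by the area ratio closest to 1.
greedy_match <- function(tx, ty, ta, ox, oy, oa, max_dist) {
  nt <- length(tx); no <- length(ox)
  if (nt == 0 || no == 0)
    return(data.frame(track = integer(0), object = integer(0)))
  d <- cross_dist(tx, ty, ox, oy)
  cand <- which(d <= max_dist, arr.ind = TRUE)
  if (nrow(cand) == 0)
    return(data.frame(track = integer(0), object = integer(0)))
  ratio <- abs(oa[cand[, 2]] / ta[cand[, 1]] - 1)
  ord <- order(d[cand], ratio)
  cand <- cand[ord, , drop = FALSE]
  used_t <- logical(nt); used_o <- logical(no)
  res <- list()
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (!used_t[i] && !used_o[j]) {
      used_t[i] <- TRUE; used_o[j] <- TRUE
      res[[length(res) + 1]] <- c(i, j)
    }
  }
  m <- do.call(rbind, res)
  data.frame(track = m[, 1], object = m[, 2])
}

#' Link per-frame objects into colony tracks
#'
#' Aligns microcolonies through time by centroid proximity (greedy
#' nearest-centroid matching within \code{max_displacement}). A track stops
#' being recorded when its object touches a neighbouring object (both
#' tracks terminate, \code{touched_neighbor}) or the field edge
#' (\code{touched_edge}; the touching point is recorded). A decrease in
#' area exceeding \code{area_drop_abort_fraction} between consecutive
#' frames aborts the track (\code{area_drop_abort}) without recording the
#' aberrant point. Objects appearing de novo in later frames are merged
#' into the nearest active track when within 0.65 x that track's Feret
#' diameter, otherwise ignored (see [absorb_de_novo()]).
#'
#' @param objects_list Time-ordered list of \code{mc_objects} (from
#'   [dual_threshold_segment()]); each may carry a \code{fluor_density}
#'   column in its table (see [measure_objects()]).
#' @param params A [tracking_params()].
#' @return A list of class \code{mc_tracks}: \code{points} (data.frame:
#'   track_id, time, area_px, x, y, feret_px, fluor_density, absorbed_px),
#'   \code{tracks} (data.frame: track_id, n_points, termination,
#'   first_time, last_time, absorbed_px), \code{ignored} (data.frame of
#'   unabsorbed de-novo objects), \code{accounting} (per-frame pixel
#'   bookkeeping).
#' @export
link_frames <- function(objects_list, params = tracking_params()) {
  times <- vapply(objects_list, function(o) o$time, numeric(1))
  if (anyDuplicated(times)) stopf("duplicate frame timestamps")
  if (is.unsorted(times, strictly = TRUE)) stopf("frames must be time-ordered")
  max_dist <- params$max_displacement / params$pixel_pitch

  tabs <- lapply(objects_list, function(o) {
    tab <- o$table
    if (is.null(tab$fluor_density)) tab$fluor_density <- NA_real_
    tab
  })
  n_tracks <- 0L
  state <- list()    # per track: id, active, x, y, area, feret, termination
  points <- list(); ignored <- list(); acct <- list()

  record <- function(id, time, obj, absorbed = 0) {
    points[[length(points) + 1]] <<- data.frame(
      track_id = id, time = time, area_px = obj$area_px + absorbed,
      x = obj$x, y = obj$y, feret_px = obj$feret_px,
      fluor_density = obj$fluor_density, absorbed_px = absorbed)
  }

  for (k in seq_along(objects_list)) {
    tab <- tabs[[k]]
    tnow <- times[k]
    touching <- adjacent_label_pairs(objects_list[[k]]$labels, gap = 1)
    touch_lab <- unique(as.vector(touching))
    px_tracked <- 0; px_ignored <- 0; px_dropped <- 0

    if (k == 1L) {
      for (j in seq_len(nrow(tab))) {
        n_tracks <- n_tracks + 1L
        id <- n_tracks
        record(id, tnow, tab[j, ])
        px_tracked <- px_tracked + tab$area_px[j]
        term <- if (tab$label[j] %in% touch_lab) "touched_neighbor"
                else if (tab$touches_edge[j]) "touched_edge" else NA
        state[[id]] <- list(id = id, active = is.na(term),
                            x = tab$x[j], y = tab$y[j],
                            area = tab$area_px[j], feret = tab$feret_px[j],
                            termination = if (is.na(term)) "none" else term,
                            absorbed = 0)
      }
    } else {
      act <- which(vapply(state, function(s) s$active, logical(1)))
      m <- greedy_match(vapply(state[act], `[[`, numeric(1), "x"),
                        vapply(state[act], `[[`, numeric(1), "y"),
                        vapply(state[act], `[[`, numeric(1), "area"),
                        tab$x, tab$y, tab$area_px, max_dist)
      matched_obj <- rep(NA_integer_, nrow(tab))
      if (nrow(m)) matched_obj[m$object] <- act[m$track]

      # aberrant area drops: abort before recording
      dropped <- integer(0)
      for (r in seq_len(nrow(m))) {
        id <- act[m$track[r]]; j <- m$object[r]
        s <- state[[id]]
        if (tab$area_px[j] < (1 - params$area_drop_abort_fraction) * s$area) {
          state[[id]]$active <- FALSE
          state[[id]]$termination <- "area_drop_abort"
          matched_obj[j] <- NA_integer_
          dropped <- c(dropped, j)
          px_dropped <- px_dropped + tab$area_px[j]
        }
      }

      # de-novo objects: absorb into the nearest active track or ignore
      denovo <- setdiff(which(is.na(matched_obj)), dropped)
      absorbed_into <- rep(0, length(state))
      for (j in denovo) {
        act2 <- which(vapply(state, function(s) s$active, logical(1)))
        act2 <- act2[act2 %in% matched_obj[!is.na(matched_obj)]]
        dec <- absorb_decision(tab$x[j], tab$y[j],
                               vapply(state[act2], `[[`, numeric(1), "x"),
                               vapply(state[act2], `[[`, numeric(1), "y"),
                               vapply(state[act2], `[[`, numeric(1), "feret"),
                               params$denovo_factor)
        if (is.na(dec)) {
          ignored[[length(ignored) + 1]] <- data.frame(
            time = tnow, label = tab$label[j], area_px = tab$area_px[j],
            x = tab$x[j], y = tab$y[j])
          px_ignored <- px_ignored + tab$area_px[j]
        } else {
          id <- act2[dec]
          absorbed_into[id] <- absorbed_into[id] + tab$area_px[j]
        }
      }

      # record matched points, then apply touch terminations
      for (r in seq_len(nrow(m))) {
        id <- act[m$track[r]]; j <- m$object[r]
        if (!state[[id]]$active) next
        extra <- absorbed_into[id]
        record(id, tnow, tab[j, ], absorbed = extra)
        px_tracked <- px_tracked + tab$area_px[j] + extra
        state[[id]]$x <- tab$x[j]; state[[id]]$y <- tab$y[j]
        state[[id]]$area <- tab$area_px[j] + extra
        state[[id]]$feret <- tab$feret_px[j]
        state[[id]]$absorbed <- state[[id]]$absorbed + extra
        if (tab$label[j] %in% touch_lab) {
          state[[id]]$active <- FALSE
          state[[id]]$termination <- "touched_neighbor"
        } else if (tab$touches_edge[j]) {
          state[[id]]$active <- FALSE
          state[[id]]$termination <- "touched_edge"
        }
      }
    }
    acct[[length(acct) + 1]] <- data.frame(
      time = tnow, total_object_px = sum(tab$area_px),
      tracked_px = px_tracked, ignored_px = px_ignored,
      dropped_px = px_dropped)
  }

  points <- if (length(points)) do.call(rbind, points) else
    data.frame(track_id = integer(0), time = numeric(0),
               area_px = numeric(0), x = numeric(0), y = numeric(0),
               feret_px = numeric(0), fluor_density = numeric(0),
               absorbed_px = numeric(0))
  tracks <- do.call(rbind, lapply(state, function(s) {
    tp <- points[points$track_id == s$id, ]
    data.frame(track_id = s$id, n_points = nrow(tp),
               termination = s$termination,
               first_time = min(tp$time), last_time = max(tp$time),
               absorbed_px = s$absorbed)
  })) %||% data.frame()
  ignored <- if (length(ignored)) do.call(rbind, ignored) else
    data.frame(time = numeric(0), label = integer(0), area_px = numeric(0),
               x = numeric(0), y = numeric(0))
  structure(list(points = points, tracks = tracks, ignored = ignored,
                 accounting = do.call(rbind, acct), params = params),
            class = "mc_tracks")
}

absorb_decision <- function(x, y, tx, ty, tferet, factor) {
  if (length(tx) == 0) return(NA_integer_)
  d <- sqrt((tx - x)^2 + (ty - y)^2)
  i <- which.min(d)
  if (d[i] <= factor * tferet[i]) i else NA_integer_
}

#' Decide absorption of de-novo objects into existing tracks
#'
#' An object with no match in prior frames (typically a single cell that
#' drifted away from a nearby microcolony) is merged into the nearest
#' active track if its centroid lies within
#' \code{denovo_factor x (that track's Feret diameter)}; otherwise it is
#' ignored. This is the standalone decision surface used inside
#' [link_frames()].
#'
#' @param new_objects data.frame with columns \code{x}, \code{y} (and
#'   optionally \code{label}, \code{area_px}).
#' @param tracks data.frame of active tracks with columns \code{track_id},
#'   \code{x}, \code{y}, \code{feret_px} (current frame state).
#' @param params A [tracking_params()].
#' @return \code{new_objects} with added columns \code{action}
#'   ("merged"/"ignored") and \code{track_id} (NA when ignored).
#' @export
absorb_de_novo <- function(new_objects, tracks, params = tracking_params()) {
  out <- new_objects
  out$action <- "ignored"
  out$track_id <- NA_integer_
  for (j in seq_len(nrow(out))) {
    dec <- absorb_decision(out$x[j], out$y[j], tracks$x, tracks$y,
                           tracks$feret_px, params$denovo_factor)
    if (!is.na(dec)) {
      out$action[j] <- "merged"
      out$track_id[j] <- tracks$track_id[dec]
    }
  }
  out
}

#' Estimate the rigid plate shift across a heat shock
#'
#' Selects colonies whose nearest pre-shock neighbour is farther than
#' \code{isolation_threshold} (micrometres), matches each to the nearest
#' post-shock object, and returns the mean centroid displacement, which is
#' then used to realign all remaining microcolonies.
#'
#' @param pre_objects,post_objects Object tables (data.frames with
#'   \code{x}, \code{y} in pixels), e.g. \code{$table} of
#'   [dual_threshold_segment()] results for the last pre-shock and first
#'   post-shock frames.
#' @param params A [tracking_params()].
#' @return Numeric (dx, dy) in pixels, with attribute \code{n_isolated}.
#' @export
estimate_plate_shift <- function(pre_objects, post_objects,
                                 params = tracking_params()) {
  iso_px <- params$isolation_threshold / params$pixel_pitch
  nn <- nn_dist(pre_objects$x, pre_objects$y)
  iso <- which(nn > iso_px)
  if (length(iso) < 3)
    stopf("unreliable alignment: only %d isolated colonies (need >= 3)",
          length(iso))
  d <- cross_dist(pre_objects$x[iso], pre_objects$y[iso],
                  post_objects$x, post_objects$y)
  j <- apply(d, 1, which.min)
  dx <- post_objects$x[j] - pre_objects$x[iso]
  dy <- post_objects$y[j] - pre_objects$y[iso]
  structure(c(mean(dx), mean(dy)), n_isolated = length(iso))
}

#' Realign post-shock objects to pre-shock tracks
#'
#' Translates post-shock centroids by \code{-shift} and matches them to the
#' last recorded centroid of each pre-shock track by greedy nearest
#' centroid within \code{max_displacement}. Unmatched tracks and objects
#' are reported, not errors.
#'
#' @param pre_tracks An \code{mc_tracks} result for the pre-shock series.
#' @param post_objects Object table of the first post-shock frame.
#' @param shift Numeric (dx, dy) pixels, from [estimate_plate_shift()].
#' @param params A [tracking_params()].
#' @return List: \code{pairs} (data.frame: track_id, post_label, dist_px),
#'   \code{unmatched_tracks}, \code{unmatched_objects}.
#' @export
realign_series <- function(pre_tracks, post_objects, shift,
                           params = tracking_params()) {
  last_pt <- do.call(rbind, lapply(split(pre_tracks$points,
                                         pre_tracks$points$track_id),
                                   function(tp) tp[which.max(tp$time), ]))
  px <- post_objects$x - shift[1]
  py <- post_objects$y - shift[2]
  max_dist <- params$max_displacement / params$pixel_pitch
  m <- greedy_match(last_pt$x, last_pt$y, last_pt$area_px,
                    px, py, post_objects$area_px, max_dist)
  pairs <- data.frame(track_id = last_pt$track_id[m$track],
                      post_label = post_objects$label[m$object],
                      dist_px = sqrt((last_pt$x[m$track] - px[m$object])^2 +
                                       (last_pt$y[m$track] - py[m$object])^2))
  list(pairs = pairs,
       unmatched_tracks = setdiff(last_pt$track_id, pairs$track_id),
       unmatched_objects = setdiff(post_objects$label, pairs$post_label))
}
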