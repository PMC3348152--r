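#' Run the growth pipeline on synthetic fields
#'
#' Convenience wrapper running simulation, segmentation, tracking,
#' growth-rate fitting and spatial QC for a list of field specifications,
#' returning combined growth records with ground-truth matches.
#'
#' @param fields List of [field_spec()] objects (e.g. from
#'   [default_scenario()]).
#' @param times Acquisition times, hours.
#' @param seg_params A [segmentation_params()].
#' @param track_params A [tracking_params()].
#' @param fluorescence Render and measure a fluorescence channel?
#' @param keep_images Keep per-field simulations and objects in the result
#'   (memory-heavy; off by default).
#' @return List: \code{records} (growth records with spatial QC and, via
#'   [match_tracks_to_truth()], true_mu/colony_id columns and a field
#'   index), \code{tracks} (per-field \code{mc_tracks}), \code{manifests}
#'   (per-field manifest), and when \code{keep_images}, \code{sims} and
#'   \code{objects}.
#' @export
run_growth_pipeline <- function(fields, times = 0:8,
                                seg_params = segmentation_params(),
                                track_params = tracking_params(),
                                fluorescence = FALSE,
                                keep_images = FALSE) {
  all_records <- list(); all_tracks <- list(); manifests <- list()
  sims <- list(); objects_kept <- list()
  for (f in seq_along(fields)) {
    sim <- simulate_timelapse(fields[[f]], times, fluorescence = fluorescence,
                              field = f)
    objs <- lapply(seq_along(sim$frames), function(k) {
      o <- dual_threshold_segment(sim$frames[[k]], seg_params)
      if (fluorescence)
        o$table <- measure_objects(o, sim$fluor_frames[[k]])
      o
    })
    tracks <- link_frames(objs, track_params)
    rec <- fit_growth_rates(tracks, track_params$min_timepoints)
    rec <- compute_spatial_qc(rec, tracks,
                              c(fields[[f]]$width, fields[[f]]$height),
                              track_params$pixel_pitch)
    truth <- match_tracks_to_truth(tracks, sim$manifest)
    m <- match(rec$track_id, truth$track_id)
    rec$colony_id <- truth$colony_id[m]
    rec$true_mu <- sim$manifest$growth_rate[
      match(truth$label[m], sim$manifest$label)]
    rec$field <- f
    all_records[[f]] <- rec
    all_tracks[[f]] <- tracks
    manifests[[f]] <- sim$manifest
    if (keep_images) {
      sims[[f]] <- sim
      objects_kept[[f]] <- objs
    }
  }
  out <- list(records = do.call(rbind, all_records),
              tracks = all_tracks, manifests = manifests)
  if (keep_images) {
    out$sims <- sims
    out$objects <- objects_kept
  }
  out
}

#' Run the heat-shock survival pipeline on synthetic fields
#'
#' For each field: simulate a shocked series, segment both series, track
#' the pre-shock series, estimate the plate shift from isolated colonies,
#' realign, track the post-shock series, and call survival.
#'
#' @param fields List of [field_spec()] (e.g. from [shock_scenario()]).
#' @param pre_times,post_times Acquisition times, hours (post on its own
#'   clock).
#' @param shift True rigid plate shift applied at the shock, pixels.
#' @param seg_params,track_params,surv_params Parameter objects.
#' @return List: \code{records} (survival records + field, plus manifest
#'   truth columns true_survives), \code{shift_estimates} (per-field
#'   data.frame: field, dx, dy, n_isolated).
#' @export
run_survival_pipeline <- function(fields, pre_times = 0:5,
                                  post_times = 0:16,
                                  shift = c(3.2, -1.7),
                                  seg_params = segmentation_params(),
                                  track_params = tracking_params(),
                                  surv_params = survival_params()) {
  recs <- list(); shifts <- list()
  for (f in seq_along(fields)) {
    ser <- simulate_heat_shock_series(fields[[f]], pre_times, post_times,
                                      shift = shift, field = f)
    pre_objs <- lapply(ser$pre$frames, dual_threshold_segment, seg_params)
    post_objs <- lapply(ser$post$frames, dual_threshold_segment, seg_params)
    pre_tracks <- link_frames(pre_objs, track_params)
    est <- estimate_plate_shift(pre_objs[[length(pre_objs)]]$table,
                                post_objs[[1]]$table, track_params)
    shifts[[f]] <- data.frame(field = f, dx = est[1], dy = est[2],
                              n_isolated = attr(est, "n_isolated"))
    re <- realign_series(pre_tracks, post_objs[[1]]$table, est, track_params)
    post_tracks <- link_frames(post_objs, track_params)
    # a post track is identified by its first recorded object centroid
    first_pt <- do.call(rbind, lapply(
      split(post_tracks$points, post_tracks$points$track_id),
      function(tp) tp[which.min(tp$time), ]))
    lab0 <- post_objs[[1]]$table
    post_id_by_label <- first_pt$track_id[
      vapply(seq_len(nrow(lab0)), function(j)
        which.min((first_pt$x - lab0$x[j])^2 + (first_pt$y - lab0$y[j])^2),
        integer(1))]
    pairs <- data.frame(track_id = re$pairs$track_id,
                        post_track_id = post_id_by_label[
                          match(re$pairs$post_label, lab0$label)])
    rec <- call_survival_all(pre_tracks, post_tracks, pairs, surv_params)
    truth <- match_tracks_to_truth(pre_tracks, ser$pre$manifest)
    m <- match(rec$track_id, truth$track_id)
    rec$colony_id <- truth$colony_id[m]
    rec$true_survives <- ser$survival$survives[
      match(truth$label[m], ser$survival$label)]
    rec$field <- f
    recs[[f]] <- rec
  }
  list(records = do.call(rbind, recs),
       shift_estimates = do.call(rbind, shifts))
}
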