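#' Draw specific growth rates from the bulk + slow-tail mixture
#'
#' Population model used by the demo scenarios: a Gaussian bulk of normal
#' growers plus a small uniform slow tail, echoing the continuous growth-rate
#' distribution with a slow-growing minority seen in clonal yeast
#' populations. Draws are truncated to \code{[0, rate_cap]} so rendered
#' colonies stay within field bounds over a 9-h series.
#'
#' @param n Number of draws.
#' @param bulk_mean,bulk_sd Mean and sd of the bulk component, per hour.
#' @param slow_weight Mixture weight of the slow tail.
#' @param slow_max Upper bound of the uniform slow tail, per hour.
#' @param rate_cap Truncation bound, per hour.
#' @return Numeric vector of specific growth rates.
#' @export
sample_growth_rates <- function(n, bulk_mean = 0.38, bulk_sd = 0.05,
                                slow_weight = 0.05, slow_max = 0.15,
                                rate_cap = 0.50) {
  slow <- stats::runif(n) < slow_weight
  mu <- stats::rnorm(n, bulk_mean, bulk_sd)
  mu[slow] <- stats::runif(sum(slow), 0, slow_max)
  pmin(pmax(mu, 0), rate_cap)
}

# Growth-anticorrelated marker fluorescence (Tsl1-like): slow colonies bright.
marker_fluorescence <- function(mu, base = 0.9, k = 4) base * exp(-k * mu)

#' Build the default synthetic plate scenario
#'
#' Lays out \code{grid x grid} colonies per field on a jittered lattice with
#' enough spacing that colonies stay mutually disjoint and clear of the
#' spatial-QC margins over 9 h of growth. Growth rates come from
#' [sample_growth_rates()]; marker fluorescence is anticorrelated with
#' growth rate.
#'
#' @param n_fields Number of fields.
#' @param grid Colonies per side of the lattice.
#' @param field_px Field width and height, pixels.
#' @param spacing Lattice pitch, pixels.
#' @param jitter Maximal uniform jitter applied to each center, pixels.
#' @param area_range Range of initial colony areas, pixels.
#' @param seed Integer seed (drives layout, rates and pixel noise).
#' @param ... Passed to [sample_growth_rates()].
#' @return List of [field_spec()] objects, one per field.
#' @export
default_scenario <- function(n_fields = 8, grid = 8, field_px = 1024,
                             spacing = 120, jitter = 8,
                             area_range = c(60, 120), seed = 1L, ...) {
  margin <- (field_px - (grid - 1) * spacing) / 2
  if (margin < 90) stopf("lattice does not fit the field with a safe margin")
  centers <- expand.grid(x = margin + spacing * (0:(grid - 1)),
                         y = margin + spacing * (0:(grid - 1)))
  n <- nrow(centers)
  lapply(seq_len(n_fields), function(f) {
    with_seed(seed + 1000L * f, {
      mu <- sample_growth_rates(n, ...)
      a0 <- stats::runif(n, area_range[1], area_range[2])
      jx <- stats::runif(n, -jitter, jitter)
      jy <- stats::runif(n, -jitter, jitter)
      cols <- lapply(seq_len(n), function(i)
        colony_spec(sprintf("f%02d_c%03d", f, i),
                    center = c(centers$x[i] + jx[i], centers$y[i] + jy[i]),
                    initial_area = a0[i], growth_rate = mu[i],
                    fluorescence_level = marker_fluorescence(mu[i])))
      field_spec(field_px, field_px, colonies = cols, seed = seed + f)
    })
  })
}

#' Build a low-density heat-shock scenario
#'
#' Heat-shock workflows plate at low density (around eight colonies per
#' field) so that isolated colonies are available for plate realignment.
#' Survival is drawn with probability decreasing in the pre-shock growth
#' rate (slow growers persist), via a logistic link.
#'
#' @param n_fields Number of fields.
#' @param per_field Colonies per field.
#' @param field_px Field size, pixels.
#' @param surv_intercept,surv_slope Logistic coefficients of survival on the
#'   pre-shock rate; the default slope (-8 per unit rate) makes slow growers
#'   markedly more likely to survive.
#' @param post_rate Specific growth rate of surviving colonies after the
#'   shock, per hour.
#' @param seed Integer seed.
#' @param ... Passed to [sample_growth_rates()].
#' @return List of [field_spec()] objects.
#' @export
shock_scenario <- function(n_fields = 4, per_field = 8, field_px = 768,
                           surv_intercept = 2.5, surv_slope = -8,
                           post_rate = 0.2, seed = 1L, ...) {
  pitch <- 230
  centers <- expand.grid(x = pitch * (0:2), y = pitch * (0:2))
  centers <- centers[-5, ]                       # drop the middle cell
  off <- (field_px - 2 * pitch) / 2
  lapply(seq_len(n_fields), function(f) {
    with_seed(seed + 777L * f, {
      idx <- seq_len(min(per_field, nrow(centers)))
      mu <- sample_growth_rates(length(idx), ...)
      surv <- stats::runif(length(idx)) <
        stats::plogis(surv_intercept + surv_slope * mu)
      cols <- lapply(seq_along(idx), function(i)
        colony_spec(sprintf("f%02d_s%02d", f, i),
                    center = c(off + centers$x[idx[i]] +
                                 stats::runif(1, -15, 15),
                               off + centers$y[idx[i]] +
                                 stats::runif(1, -15, 15)),
                    initial_area = stats::runif(1, 70, 120),
                    growth_rate = mu[i],
                    fluorescence_level = marker_fluorescence(mu[i]),
                    survives_shock = surv[i],
                    post_shock_rate = post_rate))
      field_spec(field_px, field_px, colonies = cols, seed = seed + 31L * f)
    })
  })
}

#' Simulate a tabular survival cohort for model checking
#'
#' Draws growth rates from the mixture model, assigns genotypes, and
#' generates survival outcomes from a logistic model with known
#' coefficients; used to validate [logistic_survival_model()] recovery.
#'
#' @param n Cohort size.
#' @param beta0,beta_mu,beta_genotype,beta_interaction True coefficients on
#'   the logit scale (genotype coded 0/1).
#' @param p_genotype Probability of genotype 1.
#' @param seed Integer seed.
#' @return data.frame: mu, genotype (factor "g0"/"g1"), survived (logical).
#' @export
simulate_survival_cohort <- function(n, beta0 = 2.5, beta_mu = -8,
                                     beta_genotype = 0.7,
                                     beta_interaction = 0,
                                     p_genotype = 0.5, seed = 1L) {
  with_seed(seed, {
    mu <- sample_growth_rates(n)
    g <- stats::rbinom(n, 1, p_genotype)
    eta <- beta0 + beta_mu * mu + beta_genotype * g + beta_interaction * mu * g
    data.frame(mu = mu,
               genotype = factor(ifelse(g == 1, "g1", "g0"),
                                 levels = c("g0", "g1")),
               survived = stats::runif(n) < stats::plogis(eta))
  })
}

#' Simulate a gene table for the slow-growth marker screen
#'
#' Generates a table of genes with growth-rate regression slopes, DM
#' expression noise, and young/old expression intensities. Exactly
#' \code{planted_candidates} rows are placed inside the screen margins
#' (slope < slope_max and DM > dm_min); all other rows are pushed outside at
#' least one margin. Optionally imposes a target correlation \code{rho}
#' between |log AER| and DM (AER = young/old expression ratio).
#'
#' @param n_genes Number of rows.
#' @param planted_candidates Number of guaranteed screen hits.
#' @param effect_params List: \code{slope_max} (-2), \code{dm_min} (5),
#'   \code{rho} (0), \code{slope_mean} (-0.5), \code{slope_sd} (1.2),
#'   \code{dm_mean} (2), \code{dm_sd} (2), \code{log_aer_sd} (0.8),
#'   \code{missing_frac} (0.05).
#' @param seed Integer seed.
#' @return data.frame: gene, slope, dm, young_expr, old_expr.
#' @export
simulate_gene_table <- function(n_genes, planted_candidates = 0,
                                effect_params = list(), seed = 1L) {
  p <- utils::modifyList(list(slope_max = -2, dm_min = 5, rho = 0,
                              slope_mean = -0.5, slope_sd = 1.2,
                              dm_mean = 2, dm_sd = 2, log_aer_sd = 0.8,
                              missing_frac = 0.05), effect_params)
  if (planted_candidates > n_genes)
    stopf("planted_candidates (%d) exceeds n_genes (%d)",
          planted_candidates, n_genes)
  if (abs(p$rho) >= 1) stopf("impossible margin configuration: |rho| >= 1")
  with_seed(seed, {
    log_aer <- stats::rnorm(n_genes, 0, p$log_aer_sd)
    a <- abs(log_aer)
    a_std <- if (stats::sd(a) > 0) (a - mean(a)) / stats::sd(a) else a * 0
    dm <- p$dm_mean + p$dm_sd * (p$rho * a_std +
                                   sqrt(1 - p$rho^2) * stats::rnorm(n_genes))
    slope <- stats::rnorm(n_genes, p$slope_mean, p$slope_sd)
    planted <- seq_len(planted_candidates)
    if (planted_candidates > 0) {
      slope[planted] <- p$slope_max - abs(stats::rnorm(planted_candidates, 1, 0.3))
      dm[planted] <- p$dm_min + abs(stats::rnorm(planted_candidates, 2, 0.5))
    }
    # push accidental qualifiers among the non-planted rows outside the DM margin
    spoil <- setdiff(which(slope < p$slope_max & dm > p$dm_min), planted)
    dm[spoil] <- p$dm_min - stats::runif(length(spoil), 0.1, 1)
    young <- exp(stats::rnorm(n_genes, 6, 1))
    old <- young / exp(log_aer)
    tab <- data.frame(gene = sprintf("GENE%04d", seq_len(n_genes)),
                      slope = slope, dm = dm,
                      young_expr = young, old_expr = old,
                      stringsAsFactors = FALSE)
    if (p$missing_frac > 0 && n_genes > planted_candidates) {
      pool <- setdiff(seq_len(n_genes), planted)
      n_miss <- round(p$missing_frac * length(pool))
      if (n_miss > 0) {
        miss <- sample(pool, n_miss)
        half <- seq_len(ceiling(n_miss / 2))
        tab$slope[miss[half]] <- NA
        tab$dm[miss[-half]] <- NA
      }
    }
    tab
  })
}

#' Match tracked colonies to ground-truth manifest identities
#'
#' Assigns each track to the manifest colony whose true centroid is nearest
#' the track's first recorded centroid, and reports per-timepoint agreement;
#' used to benchmark segmentation and tracking against a generator's truth.
#'
#' @param tracks Result of [link_frames()].
#' @param manifest Manifest data.frame from [simulate_timelapse()].
#' @param max_dist Maximal allowed match distance, pixels.
#' @return data.frame per track: track_id, colony_id, label,
#'   n_points, n_time_matched (timepoints where the track centroid lies
#'   within \code{max_dist} of the true centroid), mean_area_rel_err.
#' @export
match_tracks_to_truth <- function(tracks, manifest, max_dist = 10) {
  pts <- tracks$points
  t0 <- min(manifest$time)
  man0 <- manifest[manifest$time == t0, ]
  out <- lapply(split(pts, pts$track_id), function(tp) {
    tp <- tp[order(tp$time), ]
    d0 <- sqrt((man0$x - tp$x[1])^2 + (man0$y - tp$y[1])^2)
    j <- which.min(d0)
    if (d0[j] > max_dist)
      return(data.frame(track_id = tp$track_id[1], colony_id = NA,
                        label = NA, n_points = nrow(tp),
                        n_time_matched = 0, mean_area_rel_err = NA))
    man_c <- manifest[manifest$label == man0$label[j], ]
    m <- match(tp$time, man_c$time)
    ok <- !is.na(m)
    dd <- sqrt((man_c$x[m[ok]] - tp$x[ok])^2 + (man_c$y[m[ok]] - tp$y[ok])^2)
    rel <- abs(tp$area_px[ok] - man_c$area[m[ok]]) / man_c$area[m[ok]]
    data.frame(track_id = tp$track_id[1], colony_id = man0$colony_id[j],
               label = man0$label[j], n_points = nrow(tp),
               n_time_matched = sum(dd <= max_dist),
               mean_area_rel_err = mean(rel))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
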