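#' Survival-calling parameters
#'
#' A colony is a survivor if it grows by at least \code{survivor_px} pixels
#' (default 400 px, 180 um^2, ~eight cells) over \code{window} hours after
#' heat shock, a non-survivor if it grows by less than
#' \code{nonsurvivor_px} (300 px, 135 um^2, ~six cells), and is otherwise
#' ignored. Alternative cut-offs are accepted; the defaults are the
#' conventional ones.
#'
#' @param survivor_px,nonsurvivor_px Area-change thresholds, pixels
#'   (\code{nonsurvivor_px < survivor_px}).
#' @param window Post-shock observation window, hours.
#' @param baseline \code{"first_post"} (default): growth measured from the
#'   first post-shock frame; \code{"last_pre"}: from the last pre-shock
#'   area (conflates shock-time shrinkage into the change).
#' @return A \code{survival_params} list.
#' @export
survival_params <- function(survivor_px = 400, nonsurvivor_px = 300,
                            window = 16,
                            baseline = c("first_post", "last_pre")) {
  if (nonsurvivor_px >= survivor_px)
    stopf("nonsurvivor_px must be < survivor_px")
  if (window <= 0) stopf("window must be > 0")
  structure(list(survivor_px = survivor_px, nonsurvivor_px = nonsurvivor_px,
                 window = window, baseline = match.arg(baseline)),
            class = "survival_params")
}

#' Call heat-shock survival for one realigned colony
#'
#' The area change is the post-shock area at the end of the observation
#' window minus the baseline area (by default the first post-shock frame).
#' Changes of at least \code{survivor_px} call a survivor, below
#' \code{nonsurvivor_px} a non-survivor; the band in between is ignored.
#'
#' @param pre_track data.frame of pre-shock points (needs \code{time},
#'   \code{area_px}; optionally \code{track_id}, \code{fluor_density}).
#' @param post_track data.frame of post-shock points for the matched
#'   colony; must span at least \code{window} hours.
#' @param params A [survival_params()].
#' @return One-row data.frame: track_id, pre_mu, pre_fluor, delta_px, call
#'   ("survivor"/"non_survivor"/"ignored").
#' @export
call_survival <- function(pre_track, post_track,
                          params = survival_params()) {
  post <- post_track[order(post_track$time), ]
  if (nrow(post) < 2) stopf("post-shock series has fewer than 2 points")
  span <- max(post$time) - min(post$time)
  if (span < params$window)
    stopf("post-shock series spans %.3g h, shorter than the %.3g h window",
          span, params$window)
  t_end <- min(post$time) + params$window
  a_end <- post$area_px[max(which(post$time <= t_end))]
  base <- if (params$baseline == "first_post") post$area_px[1]
          else pre_track$area_px[which.max(pre_track$time)]
  delta <- a_end - base
  call <- if (delta >= params$survivor_px) "survivor"
          else if (delta < params$nonsurvivor_px) "non_survivor"
          else "ignored"
  fit <- fit_specific_growth_rate(pre_track, min_timepoints = 2)
  data.frame(track_id = fit$track_id, pre_mu = fit$mu,
             pre_fluor = fit$mean_fluor, delta_px = delta, call = call,
             stringsAsFactors = FALSE)
}

#' Call survival for every realigned pre/post pair
#'
#' @param pre_tracks \code{mc_tracks} for the pre-shock series.
#' @param post_tracks \code{mc_tracks} for the post-shock series.
#' @param pairs data.frame mapping \code{track_id} (pre) to
#'   \code{post_track_id}.
#' @param params A [survival_params()].
#' @return data.frame of [call_survival()] rows plus \code{post_track_id}.
#' @export
call_survival_all <- function(pre_tracks, post_tracks, pairs,
                              params = survival_params()) {
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    pre <- pre_tracks$points[pre_tracks$points$track_id == pairs$track_id[i], ]
    post <- post_tracks$points[
      post_tracks$points$track_id == pairs$post_track_id[i], ]
    rec <- call_survival(pre, post, params)
    rec$track_id <- pairs$track_id[i]
    rec$post_track_id <- pairs$post_track_id[i]
    rec
  })
  do.call(rbind, out)
}

#' Survival frequency by bin with Fisher tests
#'
#' Drops ignored records, bins the remainder by a chosen variable, and for
#' each bin reports the percentage of surviving colonies and a two-sided
#' Fisher exact p-value of the bin's survivor/non-survivor counts against
#' the remaining records (two-sided by summing table probabilities no
#' larger than the observed table's).
#'
#' @param records Survival records (needs \code{call} plus the binning
#'   column).
#' @param by Column name to bin on (e.g. \code{"pre_mu"} or
#'   \code{"pre_fluor"}).
#' @param edges Numeric bin edges.
#' @return data.frame per bin: bin, lo, hi, n, n_survivor, pct_survival,
#'   p, degenerate. Empty bins are skipped with a warning.
#' @export
survival_by_bin <- function(records, by, edges) {
  rec <- records[records$call != "ignored", ]
  surv <- rec$call == "survivor"
  b <- rec[[by]]
  bins <- cut(b, edges, include.lowest = TRUE)
  out <- lapply(seq_along(levels(bins)), function(i) {
    inb <- which(as.integer(bins) == i)
    if (length(inb) == 0) {
      warning(sprintf("empty bin %s skipped", levels(bins)[i]), call. = FALSE)
      return(NULL)
    }
    degenerate <- length(inb) == nrow(rec)
    p <- if (degenerate) NA_real_ else
      stats::fisher.test(matrix(c(sum(surv[inb]), sum(!surv[inb]),
                                  sum(surv[-inb]), sum(!surv[-inb])),
                                nrow = 2))$p.value
    data.frame(bin = levels(bins)[i], lo = edges[i], hi = edges[i + 1],
               n = length(inb), n_survivor = sum(surv[inb]),
               pct_survival = 100 * mean(surv[inb]),
               p = p, degenerate = degenerate, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# explicit complete-separation checks so failures carry the covariate name
check_separation <- function(mu, genotype, survived) {
  if (all(survived) || !any(survived))
    stopf("complete separation: outcome is constant (all %s)",
          if (all(survived)) "survivors" else "non-survivors")
  if (max(mu[!survived]) < min(mu[survived]) ||
      max(mu[survived]) < min(mu[!survived]))
    stopf("complete separation on covariate 'mu'")
  tabs <- table(genotype, survived)
  if (all(apply(tabs, 1, function(r) any(r == 0))))
    stopf("complete separation on covariate 'genotype'")
}

#' Multiple logistic regression of survival on growth rate and genotype
#'
#' Survival is a binary outcome, so its dependence on the pre-shock
#' specific growth rate and genotype is modelled by logistic regression.
#' The full model (main effects + interaction) is compared with the
#' main-effects model and the two single-effect models by AIC; models
#' within \code{aic_margin} of the best are treated as equivalent and the
#' most parsimonious of them is selected (so an interaction must earn its
#' keep by a clear AIC improvement, mirroring "not significantly better").
#' Reported coefficient p-values come from the selected model.
#'
#' @param records data.frame with \code{mu}, \code{genotype} (factor or
#'   character, 2 levels; the first level is the reference), and
#'   \code{survived} (logical) or \code{call} ("survivor"/"non_survivor").
#' @param aic_margin AIC units within which a simpler model wins (default 2).
#' @return List of class \code{mc_logistic}: \code{selected} (model name),
#'   \code{fit} (the selected \code{glm}), \code{coefficients}
#'   (data.frame: term, estimate, se, p), \code{aic} (named vector).
#' @export
logistic_survival_model <- function(records, aic_margin = 2) {
  if (is.null(records$survived)) {
    rec <- records[records$call != "ignored", ]
    rec$survived <- rec$call == "survivor"
  } else rec <- records
  rec$genotype <- factor(rec$genotype)
  if (nlevels(rec$genotype) != 2)
    stopf("need exactly 2 genotypes (got %d)", nlevels(rec$genotype))
  check_separation(rec$mu, rec$genotype, rec$survived)
  forms <- list(full = survived ~ mu * genotype,
                main_effects = survived ~ mu + genotype,
                mu_only = survived ~ mu,
                genotype_only = survived ~ genotype)
  fits <- lapply(forms, function(f)
    stats::glm(f, family = stats::binomial(), data = rec))
  aics <- vapply(fits, stats::AIC, numeric(1))
  npar <- vapply(fits, function(f) length(stats::coef(f)), numeric(1))
  tied <- which(aics <= min(aics) + aic_margin)
  selected <- names(tied)[which.min(npar[tied])]
  fit <- fits[[selected]]
  cf <- summary(fit)$coefficients
  list2 <- list(selected = selected, fit = fit,
                coefficients = data.frame(term = rownames(cf),
                                          estimate = cf[, 1], se = cf[, 2],
                                          p = cf[, 4], row.names = NULL,
                                          stringsAsFactors = FALSE),
                aic = aics)
  class(list2) <- "mc_logistic"
  list2
}

#' @export
print.mc_logistic <- function(x, ...) {
  cat(sprintf("<logistic survival model> selected: %s\n", x$selected))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Plating survival test on arcsine square-root transformed proportions
#'
#' Replicate survival proportions are variance-stabilized by
#' \code{asin(sqrt(p))} and the two strains compared by a Student's t test.
#'
#' @param proportions Numeric survival proportions in [0, 1].
#' @param strain Strain label per replicate (2 levels, >= 2 replicates
#'   each).
#' @return List: transformed_means (named), t, df, p.
#' @export
plating_survival_test <- function(proportions, strain) {
  if (any(!is.finite(proportions) | proportions < 0 | proportions > 1))
    stopf("proportions must lie in [0, 1]")
  strain <- factor(strain)
  if (nlevels(strain) != 2) stopf("need exactly 2 strains")
  if (any(table(strain) < 2)) stopf("need >= 2 replicates per strain")
  z <- asin(sqrt(proportions))
  tt <- stats::t.test(z ~ strain, var.equal = TRUE)
  list(transformed_means = tapply(z, strain, mean),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}
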