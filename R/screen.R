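#' Screen thresholds for slow-growth markers
#'
#' Candidate markers of cell-to-cell growth variation must both
#' anti-correlate with the bulk growth rate (chemostat regression slope
#' strictly below \code{slope_max}) and be noisy across cells (DM,
#' distance-to-median expression noise in synthetic dextrose medium,
#' strictly above \code{dm_min}).
#'
#' @param slope_max Strict upper bound on the growth-rate slope (default -2).
#' @param dm_min Strict lower bound on DM noise (default 5).
#' @return A \code{screen_params} list.
#' @export
screen_params <- function(slope_max = -2, dm_min = 5) {
  if (!is.finite(slope_max) || !is.finite(dm_min))
    stopf("thresholds must be finite")
  structure(list(slope_max = slope_max, dm_min = dm_min),
            class = "screen_params")
}

#' Screen a gene table for slow-growth markers
#'
#' The background set consists of genes with a reported value for both the
#' growth-rate slope and DM noise; candidates are background genes with
#' slope strictly below \code{slope_max} and DM strictly above
#' \code{dm_min}, returned sorted by DM descending. Gene identifiers are
#' matched case-insensitively; duplicates keep the first occurrence with a
#' warning.
#'
#' @param records data.frame with columns \code{gene}, \code{slope},
#'   \code{dm} (extra columns are carried through).
#' @param params A [screen_params()].
#' @return List of class \code{mc_screen}: \code{candidates} (data.frame),
#'   \code{n_background}, \code{n_total}, \code{params}.
#' @export
apply_screen <- function(records, params = screen_params()) {
  rec <- records
  key <- toupper(trimws(as.character(rec$gene)))
  if (anyDuplicated(key)) {
    warning(sprintf("%d duplicate gene id(s); keeping first occurrence",
                    sum(duplicated(key))), call. = FALSE)
    rec <- rec[!duplicated(key), ]
  }
  background <- rec[!is.na(rec$slope) & !is.na(rec$dm), ]
  cand <- background[background$slope < params$slope_max &
                       background$dm > params$dm_min, ]
  cand <- cand[order(-cand$dm), ]
  rownames(cand) <- NULL
  structure(list(candidates = cand, n_background = nrow(background),
                 n_total = nrow(records), params = params),
            class = "mc_screen")
}

#' @export
print.mc_screen <- function(x, ...) {
  cat(sprintf(
    "<marker screen> %d candidate(s) (slope < %g, DM > %g) of %d background genes\n",
    nrow(x$candidates), x$params$slope_max, x$params$dm_min, x$n_background))
  invisible(x)
}

#' Replicative-age contribution to expression noise
#'
#' Bins genes by the logarithm of their age expression ratio (AER, the mean
#' expression in young cells over the mean expression in old cells) and
#' reports per-bin DM noise with a rank-sum comparison of each bin against
#' the remaining genes, plus the fraction of DM variance explained by
#' |log AER| (R-squared of a linear regression).
#'
#' @param records data.frame with \code{dm}, \code{young_expr},
#'   \code{old_expr} (or a precomputed \code{aer} column).
#' @param edges Bin edges on the log2 AER scale.
#' @return List of class \code{mc_aer}: \code{bins} (data.frame: bin, lo,
#'   hi, n, mean_dm, sem, p), \code{variance_explained}, \code{n_used},
#'   \code{n_dropped}.
#' @export
aer_noise_analysis <- function(records, edges) {
  if (length(edges) < 3) stopf("need at least 2 bins")
  aer <- records$aer %||% (records$young_expr / records$old_expr)
  ok <- !is.na(aer) & aer > 0 & !is.na(records$dm)
  n_dropped <- sum(!is.na(records$dm)) - sum(ok)
  if (any(!is.na(aer) & aer <= 0))
    warning(sprintf("%d record(s) with non-positive AER dropped",
                    sum(!is.na(aer) & aer <= 0)), call. = FALSE)
  la <- log2(aer[ok])
  dm <- records$dm[ok]
  cuts <- cut(la, edges, include.lowest = TRUE)
  bins <- do.call(rbind, lapply(seq_along(levels(cuts)), function(i) {
    inb <- which(as.integer(cuts) == i)
    if (length(inb) == 0) {
      warning(sprintf("empty bin %s skipped", levels(cuts)[i]), call. = FALSE)
      return(NULL)
    }
    degenerate <- length(inb) == length(dm)
    data.frame(bin = levels(cuts)[i], lo = edges[i], hi = edges[i + 1],
               n = length(inb), mean_dm = mean(dm[inb]),
               sem = stats::sd(dm[inb]) / sqrt(length(inb)),
               p = if (degenerate) NA_real_ else
                 rank_sum_p(dm[inb], dm[-inb]),
               degenerate = degenerate, stringsAsFactors = FALSE)
  }))
  r2 <- if (stats::sd(abs(la)) == 0 || stats::sd(dm) == 0) 0 else
    summary(stats::lm(dm ~ abs(la)))$r.squared
  structure(list(bins = bins, variance_explained = r2,
                 n_used = sum(ok), n_dropped = n_dropped),
            class = "mc_aer")
}

#' @export
print.mc_aer <- function(x, ...) {
  cat(sprintf(
    "<age-expression-ratio analysis> n = %d, variance explained = %.3g\n",
    x$n_used, x$variance_explained))
  print(x$bins, digits = 3)
  invisible(x)
}

#' Read / write gene tables
#'
#' Tab-separated tables with a header line; expected columns \code{gene},
#' \code{slope}, \code{dm}, \code{young_expr}, \code{old_expr} (any subset
#' beyond \code{gene} is accepted).
#'
#' @param path File path.
#' @rdname gene_table_io
#' @export
read_gene_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @param records data.frame to write.
#' @rdname gene_table_io
#' @export
write_gene_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
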