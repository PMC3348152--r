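#' Write a time-lapse to disk as TIFF frames plus a manifest
#'
#' One 32-bit float grayscale TIFF per field, timepoint and channel, named
#' \code{well_{W}_field_{F}_t{T}_{channel}.tif}, with the ground-truth
#' manifest as a TSV beside them.
#'
#' @param sim An \code{mc_timelapse} from [simulate_timelapse()].
#' @param dir Output directory (created if needed).
#' @return Character vector of written frame paths (invisible).
#' @export
write_timelapse <- function(sim, dir) {
  stopifnot(inherits(sim, "mc_timelapse"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wr <- function(frame) {
    p <- file.path(dir, sprintf("well_%s_field_%s_t%03d_%s.tif",
                                frame$well, frame$field,
                                as.integer(round(frame$time)),
                                frame$channel))
    tiff::writeTIFF(frame$pixels, p, bits.per.sample = 32L)
    p
  }
  for (fr in sim$frames) paths <- c(paths, wr(fr))
  if (!is.null(sim$fluor_frames))
    for (fr in sim$fluor_frames) paths <- c(paths, wr(fr))
  utils::write.table(sim$manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Read frames from a directory by the plate-layout filename pattern
#'
#' Parses \code{well_{W}_field_{F}_t{T}_{channel}.(tif|png)} filenames and
#' returns frames ordered by well, field and time.
#'
#' @param dir Directory of frame files.
#' @param channel Channel to load ("bright" or "fluor").
#' @return List of frame lists (\code{pixels}, \code{time}, \code{well},
#'   \code{field}, \code{channel}).
#' @export
read_frames <- function(dir, channel = "bright") {
  rx <- "^well_(.+)_field_(.+)_t([0-9]+)_([a-z]+)\\.(tif|tiff|png)$"
  files <- list.files(dir, full.names = FALSE)
  files <- files[grepl(rx, files)]
  info <- regmatches(files, regexec(rx, files))
  keep <- vapply(info, function(m) m[5] == channel, logical(1))
  files <- files[keep]; info <- info[keep]
  if (length(files) == 0) stopf("no '%s' frames found in %s", channel, dir)
  ord <- order(vapply(info, `[`, character(1), 2),
               vapply(info, `[`, character(1), 3),
               as.integer(vapply(info, `[`, character(1), 4)))
  lapply(ord, function(i) {
    m <- info[[i]]
    px <- if (grepl("png$", files[i])) {
      if (!requireNamespace("png", quietly = TRUE))
        stopf("reading PNG frames requires the 'png' package")
      png::readPNG(file.path(dir, files[i]))
    } else tiff::readTIFF(file.path(dir, files[i]))
    if (length(dim(px)) == 3) px <- px[, , 1]
    list(pixels = px, time = as.numeric(m[4]), well = m[2],
         field = m[3], channel = m[5])
  })
}

#' Read a flat key=value configuration file
#'
#' Lines of the form \code{key = value}; blank lines and \code{#} comments
#' are skipped; values that parse as numbers become numeric.
#'
#' @param path File path.
#' @return Named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stopf("malformed config line: '%s'", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' Write object or track tables as TSV
#'
#' @param x data.frame.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) utils::read.delim(path, stringsAsFactors = FALSE)
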