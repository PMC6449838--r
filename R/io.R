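#' Read a multi-page TIFF as a time-series stack
#'
#' @param path Path to a multi-page grayscale TIFF (one page per frame).
#' @param frame_interval Seconds per frame.
#' @param protocol A [stimulus_protocol()].
#' @param max_value Full-scale value the pixel data were stored against
#'   (default 65535 for 16-bit).
#' @return A [time_series_stack()] in camera counts.
#' @export
read_stack_tiff <- function(path, frame_interval, protocol,
                            max_value = 65535) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- array(0, dim = c(length(pages), nrow(pages[[1]]),
                             ncol(pages[[1]])))
  for (i in seq_along(pages)) frames[i, , ] <- pages[[i]] * max_value
  time_series_stack(frames, frame_interval, protocol)
}

#' Write a time-series stack as a multi-page TIFF
#'
#' Pixel values are scaled by `max_value` into the unit range and stored as
#' 16-bit samples, one page per frame.
#'
#' @param stack A [time_series_stack()].
#' @param path Output path.
#' @param max_value Full-scale camera value (default 65535).
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path, max_value = 65535) {
  stopifnot(inherits(stack, "time_series_stack"))
  pages <- lapply(seq_len(dim(stack$frames)[1]), function(f) {
    pmin(pmax(stack$frames[f, , ] / max_value, 0), 1)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

# write.csv with fixed options so reruns are byte-identical
write_csv_stable <- function(df, path) {
  utils::write.csv(format(df, trim = TRUE, digits = 12, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records the configuration, seed and package version of a pipeline run so
#' every reported number is reproducible from the manifest plus the inputs.
#'
#' @param config Named list of configuration values.
#' @param path Output JSON path.
#' @param counts Optional named list of filter-stage counts (ROIs detected,
#'   events censored, incomplete tracks, ...).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, path, counts = NULL) {
  manifest <- list(
    package = "smcquant",
    version = as.character(utils::packageVersion("smcquant")),
    config = config,
    counts = counts
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
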