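# Plain-text / TIFF interchange: traces CSV (molecule_id, frame, time_s,
# intensity_green[, intensity_red]), 16-bit multi-frame grayscale TIFF
# stacks (one file per channel, frame index = time order) and JSON event
# logs keyed by molecule.

#' Write a TraceSet to CSV
#'
#' @param traces a \linkS4class{TraceSet}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeTraces <- function(traces, path) {
  chans <- channelNames(traces)
  nF <- length(frameTimes(traces))
  dfs <- lapply(seq_len(nrow(traces)), function(m) {
    df <- data.frame(molecule_id = m, frame = seq_len(nF) - 1L,
                     time_s = frameTimes(traces))
    for (ch in chans)
      df[[paste0("intensity_", ch)]] <- as.numeric(traceMatrix(traces, ch)[m, ])
    df
  })
  utils::write.csv(do.call(rbind, dfs), path, row.names = FALSE)
  invisible(path)
}

#' Read a traces CSV into a TraceSet
#'
#' @param path CSV written by \code{\link{writeTraces}} (columns
#'   molecule_id, frame, time_s and one intensity_* column per channel).
#' @return a \linkS4class{TraceSet}.
#' @export
readTraces <- function(path) {
  df <- utils::read.csv(path)
  chans <- sub("^intensity_", "", grep("^intensity_", names(df), value = TRUE))
  if (!length(chans)) stop("no intensity_* columns in ", path)
  mols <- sort(unique(df$molecule_id))
  frames <- sort(unique(df$frame))
  dt <- if (length(frames) > 1L)
    stats::median(diff(sort(unique(df$time_s)))) else 1
  channels <- lapply(chans, function(ch) {
    m <- matrix(NA_real_, length(mols), length(frames))
    idx <- cbind(match(df$molecule_id, mols), match(df$frame, frames))
    m[idx] <- df[[paste0("intensity_", ch)]]
    m
  })
  names(channels) <- chans
  TraceSet(channels, frameIntervalS = dt)
}

#' Write a ground-truth event log as JSON
#'
#' @param trajectories a \linkS4class{ClampTrajectorySet} (or anything with
#'   an \code{eventLog}).
#' @param path output JSON file, keyed by molecule_id.
#' @return \code{path}, invisibly.
#' @export
writeEventLog <- function(trajectories, path) {
  ev <- eventLog(trajectories)
  byMol <- split(ev[, c("channel", "frame", "kind")], ev$molecule_id)
  jsonlite::write_json(byMol, path, dataframe = "rows", auto_unbox = TRUE)
  invisible(path)
}

#' Write an image stack as 16-bit multi-frame TIFF
#'
#' @param stack [row, col, frame] numeric array; values are clipped to
#'   [0, 65535].
#' @param path output .tif file.
#' @return \code{path}, invisibly.
#' @export
writeImageStack <- function(stack, path) {
  frames <- lapply(seq_len(dim(stack)[3L]), function(f)
    pmin(pmax(stack[, , f], 0), 65535) / 65535)
  tiff::writeTIFF(frames, path, bits.per.sample = 16L, reduce = FALSE)
  invisible(path)
}

#' Read a multi-frame TIFF stack
#'
#' @param path .tif file written by \code{\link{writeImageStack}} (or any
#'   grayscale multi-frame TIFF).
#' @return [row, col, frame] numeric array in raw count units.
#' @export
readImageStack <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  arr <- array(0, dim = c(dim(frames[[1L]])[1:2], length(frames)))
  for (f in seq_along(frames)) {
    m <- frames[[f]]
    if (length(dim(m)) == 3L) m <- m[, , 1L]
    arr[, , f] <- m * 65535
  }
  arr
}

#' Write / read a channel transform as JSON
#'
#' @param transform a \linkS4class{ChannelTransform}.
#' @param path JSON file.
#' @return \code{path} (write) or a \linkS4class{ChannelTransform} (read).
#' @export
writeTransform <- function(transform, path) {
  jsonlite::write_json(list(linear = transform@linear,
                            offset = transform@offset,
                            residual_rms_px = transform@residualRms,
                            n_beads = transform@nBeads),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeTransform
#' @export
readTransform <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("ChannelTransform", linear = matrix(unlist(x$linear), 2L, 2L),
      offset = as.numeric(x$offset), residualRms = as.numeric(x$residual_rms_px),
      nBeads = as.integer(x$n_beads))
}
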