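#' Calibrated, timestamped image stack of one immersed tablet
#'
#' Container for a time-lapse sequence of RGB rasters of a single tablet
#' replicate immersed in dyed medium, together with the acquisition
#' calibration. The canonical acquisition is 31 frames taken once per minute
#' for 30 minutes.
#'
#' @param frames list of numeric `H x W x 3` arrays with intensities in
#'   `[0, 1]`, all with identical dimensions.
#' @param timestamps numeric vector of minutes since immersion, strictly
#'   increasing, starting at 0; one per frame.
#' @param pixel_size millimetres per pixel (> 0).
#' @param replicate_id label for the replicate.
#' @param medium label for the immersion medium (e.g. `"water"`,
#'   `"HCl_pH1.2"`).
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(frames, timestamps, pixel_size,
                        replicate_id = "rep1", medium = "water") {
  if (!is.list(frames) || length(frames) < 2L)
    stop("image_stack: need at least 2 frames")
  dims <- dim(frames[[1]])
  if (length(dims) != 3L || dims[3] != 3L)
    stop("image_stack: frames must be H x W x 3 arrays")
  ok <- vapply(frames, function(f) identical(dim(f), dims), logical(1))
  if (!all(ok)) stop("image_stack: all frames must share dimensions")
  timestamps <- as.numeric(timestamps)
  if (length(timestamps) != length(frames))
    stop("image_stack: one timestamp per frame required")
  if (timestamps[1] != 0 || any(diff(timestamps) <= 0))
    stop("image_stack: timestamps must be strictly increasing with timestamps[0] = 0")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("image_stack: pixel_size must be a positive scalar")
  structure(list(frames = frames, timestamps = timestamps,
                 pixel_size = pixel_size, replicate_id = replicate_id,
                 medium = medium),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("image_stack: %d frames %dx%d px, %.4g mm/px, t = %g..%g min, replicate '%s' in '%s'\n",
              length(x$frames), d[1], d[2], x$pixel_size,
              min(x$timestamps), max(x$timestamps), x$replicate_id, x$medium))
  invisible(x)
}

#' @export
length.image_stack <- function(x) length(x$frames)

#' Write an RGB array as a PPM image
#'
#' Portable pixmap, ASCII (`P3`) or binary (`P6`). ASCII PPM is the only
#' raster format in this package's IO surface that is plain text end to end.
#'
#' @param img numeric `H x W x 3` array in `[0, 1]`.
#' @param path output file path.
#' @param ascii write ASCII `P3` (default) rather than binary `P6`.
#' @param maxval maximum sample value (default 255).
#' @export
write_ppm <- function(img, path, ascii = TRUE, maxval = 255L) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
  h <- dim(img)[1]; w <- dim(img)[2]
  q <- round(clamp(img, 0, 1) * maxval)
  ## interleave channels row-major: R G B per pixel, pixels left-to-right,
  ## rows top-to-bottom
  px <- aperm(q, c(3, 2, 1))  # channel, col, row
  vals <- as.integer(px)
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P3", paste(w, h), as.character(maxval)), con)
    ## 15 samples per line keeps lines short per the PPM convention
    pad <- (-length(vals)) %% 15L
    m <- matrix(c(as.character(vals), rep("", pad)), nrow = 15L)
    writeLines(trimws(apply(m, 2, paste, collapse = " ")), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(sprintf("P6\n%d %d\n%d\n", w, h, maxval), con, eos = NULL)
    writeBin(as.raw(vals), con)
  }
  invisible(path)
}

#' Read a PPM image (`P3` or `P6`) as an RGB array in `[0, 1]`
#'
#' @param path file path.
#' @return numeric `H x W x 3` array.
#' @export
read_ppm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2L)
  if (!magic %in% c("P3", "P6")) stop("read_ppm: not a PPM file: ", path)
  ## read header tokens (width, height, maxval), skipping comments/whitespace
  toks <- character(0)
  buf <- character(0)
  while (length(toks) < 3L) {
    ch <- readChar(con, 1L)
    if (!length(ch)) stop("read_ppm: truncated header")
    if (ch == "#") { repeat { c2 <- readChar(con, 1L); if (!length(c2) || c2 == "\n") break } ; ch <- " " }
    if (grepl("[[:space:]]", ch)) {
      if (length(buf)) { toks <- c(toks, paste(buf, collapse = "")); buf <- character(0) }
    } else buf <- c(buf, ch)
  }
  w <- as.integer(toks[1]); h <- as.integer(toks[2]); maxval <- as.integer(toks[3])
  n <- 3L * w * h
  if (magic == "P6") {
    vals <- as.integer(readBin(con, "raw", n))
  } else {
    vals <- scan(con, what = integer(), n = n, quiet = TRUE)
  }
  if (length(vals) != n) stop("read_ppm: truncated pixel data")
  px <- array(vals, dim = c(3L, w, h))
  aperm(px, c(3, 2, 1)) / maxval
}

#' Write an image stack to a directory of PPM frames with a JSON sidecar
#'
#' Frames go to `frame_000.ppm`, `frame_001.ppm`, ... and the calibration
#' (pixel size, timestamps, replicate and medium labels) to `stack.json`.
#'
#' @param stack an [image_stack].
#' @param dir output directory (created if needed).
#' @param ascii write ASCII `P3` frames (text-only deliverables) or binary `P6`.
#' @return `dir`, invisibly.
#' @export
write_image_stack <- function(stack, dir, ascii = FALSE) {
  stopifnot(inherits(stack, "image_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(stack$frames))
    write_ppm(stack$frames[[i]],
              file.path(dir, sprintf("frame_%03d.ppm", i - 1L)), ascii = ascii)
  meta <- list(pixel_size_mm = stack$pixel_size,
               timestamps_min = stack$timestamps,
               replicate_id = stack$replicate_id,
               medium = stack$medium)
  jsonlite::write_json(meta, file.path(dir, "stack.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read an image stack from a directory of PPM frames plus `stack.json`
#'
#' The sidecar must give `pixel_size_mm` and either `timestamps_min` or
#' `frame_interval_min`, and may give `replicate_id` and `medium`.
#'
#' @param dir directory containing `frame_*.ppm` and `stack.json`.
#' @return an [image_stack].
#' @export
read_image_stack <- function(dir) {
  meta_path <- file.path(dir, "stack.json")
  if (!file.exists(meta_path)) stop("read_image_stack: missing sidecar ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.ppm$", full.names = TRUE))
  if (length(files) < 2L) stop("read_image_stack: need at least 2 frames in ", dir)
  frames <- lapply(files, read_ppm)
  ts <- meta$timestamps_min
  if (is.null(ts)) {
    if (is.null(meta$frame_interval_min))
      stop("read_image_stack: sidecar needs timestamps_min or frame_interval_min")
    ts <- (seq_along(frames) - 1) * meta$frame_interval_min
  }
  image_stack(frames, ts, meta$pixel_size_mm,
              replicate_id = meta$replicate_id %||% basename(dir),
              medium = meta$medium %||% "unknown")
}
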