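#' Read a TIFF file as a frame or stack
#'
#' Reads single- or multi-page grayscale TIFF. Integer pages (8/16-bit) are
#' promoted to float without value change; 32-bit float pages are read
#' as stored (including values outside `[0, 1]`). Multi-page files return an
#' [image_stack()] in page order.
#'
#' @param path path to a TIFF file.
#' @param pixel_size optional pixel size (nm/px) to attach as metadata.
#' @return An [image_frame()] (one page) or [image_stack()] (several).
#' @export
read_tiff <- function(path, pixel_size = NA_real_) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE),
                    error = function(e)
                      stop("unreadable TIFF '", path, "': ",
                           conditionMessage(e), call. = FALSE))
  is_float <- vapply(pages, function(p) {
    fmt <- attr(p, "sample.format")
    identical(fmt, "float")
  }, logical(1))
  if (!all(is_float))  # integer data: re-read unscaled
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  frames <- lapply(seq_along(pages), function(i) {
    p <- pages[[i]]
    if (length(dim(p)) == 3L) p <- p[, , 1L]   # first channel of RGB input
    if (any(!is.finite(p)))
      stop(sprintf("non-finite pixel values in page %d of '%s'", i, path),
           call. = FALSE)
    image_frame(matrix(as.numeric(p), nrow(p), ncol(p)), pixel_size)
  })
  if (length(frames) == 1L) frames[[1]] else image_stack(frames)
}

#' Write frames as 32-bit float TIFF
#'
#' Writes one page per frame, uncompressed little-endian IEEE float, so that
#' MSSR outputs (which are not integer counts and need not lie in `[0, 1]`)
#' round-trip exactly at 32-bit precision.
#'
#' @param frames an [image_frame()], matrix, or [image_stack()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_tiff <- function(frames, path) {
  if (inherits(frames, "image_stack")) {
    pages <- lapply(frames, as_pixel_matrix)
  } else {
    pages <- list(as_pixel_matrix(as_image_frame(frames)))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(v) writeBin(as.integer(v), con, size = 2, endian = "little")
  w32 <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  # header
  writeBin(charToRaw("II"), con)
  w16(42L)
  n <- length(pages)
  data_len <- vapply(pages, function(p) 4L * length(p), integer(1))
  ifd_len <- 2L + 10L * 12L + 4L
  # layout: header | data1 ifd1 | data2 ifd2 | ...
  data_off <- integer(n); ifd_off <- integer(n)
  pos <- 8L
  for (i in seq_len(n)) {
    data_off[i] <- pos
    ifd_off[i] <- pos + data_len[i]
    pos <- ifd_off[i] + ifd_len
  }
  w32(ifd_off[1])
  tag_short <- function(code, value) { w16(code); w16(3L); w32(1L); w16(value); w16(0L) }
  tag_long <- function(code, value) { w16(code); w16(4L); w32(1L); w32(value) }
  for (i in seq_len(n)) {
    p <- pages[[i]]
    writeBin(as.numeric(t(p)), con, size = 4, endian = "little")  # scanlines
    w16(10L)                                 # tag count
    tag_long(256L, ncol(p))                  # ImageWidth
    tag_long(257L, nrow(p))                  # ImageLength
    tag_short(258L, 32L)                     # BitsPerSample
    tag_short(259L, 1L)                      # no compression
    tag_short(262L, 1L)                      # BlackIsZero
    tag_long(273L, data_off[i])              # StripOffsets
    tag_short(277L, 1L)                      # SamplesPerPixel
    tag_long(278L, nrow(p))                  # RowsPerStrip
    tag_long(279L, data_len[i])              # StripByteCounts
    tag_short(339L, 3L)                      # SampleFormat: IEEE float
    w32(if (i < n) ifd_off[i + 1] else 0L)   # next IFD
  }
  invisible(path)
}

#' Run configuration
#'
#' Serializable description of a complete processing run: input/output paths,
#' MSSR parameters, the temporal mode, a seed and a log level. Round-trips
#' through JSON unchanged (`write_config()` / `read_config()`).
#'
#' @param input input TIFF path.
#' @param output output TIFF path.
#' @param params an [mssr_params()].
#' @param ptf `NULL` for single-frame analysis, or a PTF name
#'   (see [apply_ptf()]) for temporal analysis.
#' @param seed integer seed recorded in the provenance (the MSSR pipeline is
#'   deterministic; the seed covers any stochastic simulation inputs).
#' @param log_level one of `"quiet"`, `"info"`.
#' @return A `run_config` object.
#' @export
run_config <- function(input, output, params, ptf = NULL, seed = 1L,
                       log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  if (!inherits(params, "mssr_params"))
    stop("`params` must be an mssr_params object", call. = FALSE)
  structure(list(input = input, output = output, params = params,
                 ptf = ptf, seed = as.integer(seed), log_level = log_level),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path JSON path.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$params <- unclass(x$params)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- x$params
  params <- mssr_params(amp = p$amp, psf_fwhm = p$psf_fwhm, order = p$order,
                        interpolation = p$interpolation,
                        boundary = p$boundary,
                        mesh_minimization = isTRUE(p$mesh_minimization))
  params$interp_given <- isTRUE(p$interp_given)
  run_config(input = x$input, output = x$output, params = params,
             ptf = if (is.null(x$ptf)) NULL else x$ptf,
             seed = x$seed, log_level = x$log_level)
}

#' Run the full processing pipeline from a configuration
#'
#' Reads the input TIFF, runs single-frame ([sf_mssr()]) or temporal
#' ([t_mssr()]) analysis according to the configuration, and writes the
#' output as 32-bit float TIFF together with a JSON provenance file
#' (parameters, seed, package version, per-stage timings) next to it.
#' Reruns with the same configuration produce byte-identical outputs.
#'
#' @param config a [run_config()] or path to its JSON serialization.
#' @return Invisibly, a list with the output frame, the output path and the
#'   provenance path.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  if (!inherits(config, "run_config"))
    stop("`config` must be a run_config or a path to one", call. = FALSE)
  say <- function(...) if (config$log_level != "quiet") message(...)
  timings <- list()
  tic <- function(expr, stage) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    val
  }
  say("reading ", config$input)
  input <- tic(read_tiff(config$input), "read")
  single <- is.null(config$ptf)
  out <- if (single) {
    fr <- if (inherits(input, "image_stack")) input[[1]] else input
    say("sf-MSSR order ", config$params$order)
    tic(sf_mssr(fr, config$params), "mssr")
  } else {
    stack <- if (inherits(input, "image_stack")) input
             else image_stack(list(input))
    say("t-MSSR order ", config$params$order, ", PTF ", config$ptf)
    tic(t_mssr(stack, config$params, config$ptf), "mssr")
  }
  tic(write_tiff(out, config$output), "write")
  prov <- list(
    software = "mssr", version = as.character(packageVersion("mssr")),
    parameters = unclass(config$params), ptf = config$ptf,
    seed = config$seed, input = config$input, output = config$output,
    timings_s = timings)
  prov_path <- paste0(tools::file_path_sans_ext(config$output), "_provenance.json")
  jsonlite::write_json(prov, prov_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  say("wrote ", config$output)
  invisible(list(frame = out, output = config$output, provenance = prov_path))
}
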