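#' Write a pressure trace to a WAV file
#'
#' Mono RIFF/WAVE writer. `float32` (IEEE float, format code 3) stores the
#' pressure samples in pascals verbatim and is the preferred format, since
#' millipascal-scale signals would lose precision under 16-bit quantization.
#' `pcm16` divides by `scale_pa` (default: the max absolute sample) before
#' quantizing; the scale is returned invisibly and stored in a `.scale.txt`
#' sidecar so the pressure calibration survives the round trip.
#'
#' @param trace a `pressure_trace` (or numeric vector with `sample_rate`).
#' @param path output file path.
#' @param format `"float32"` or `"pcm16"`.
#' @param sample_rate required when `trace` is a bare vector.
#' @param scale_pa full-scale pressure for `pcm16`, Pa.
#' @return Invisibly, the scale factor used (1 for float32).
#' @export
write_wav <- function(trace, path, format = c("float32", "pcm16"),
                      sample_rate = NULL, scale_pa = NULL) {
  format <- match.arg(format)
  if (inherits(trace, "pressure_trace")) {
    x <- trace$samples; fs <- trace$sample_rate
  } else {
    x <- as.numeric(trace); fs <- sample_rate
    if (is.null(fs)) stop("sample_rate required for a bare vector")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  nch <- 1L
  if (format == "float32") {
    bits <- 32L; fmt_code <- 3L; data_len <- 4L * length(x)
  } else {
    bits <- 16L; fmt_code <- 1L; data_len <- 2L * length(x)
    if (is.null(scale_pa)) scale_pa <- max(abs(x), 1e-12)
  }
  block <- nch * bits / 8L
  fmt_len <- if (fmt_code == 3L) 18L else 16L
  fact_len <- if (fmt_code == 3L) 12L else 0L
  riff_len <- 4L + (8L + fmt_len) + fact_len + (8L + data_len)
  wr_int <- function(v, size) writeBin(as.integer(v), con, size = size,
                                       endian = "little")
  writeChar("RIFF", con, eos = NULL); wr_int(riff_len, 4)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); wr_int(fmt_len, 4)
  wr_int(fmt_code, 2); wr_int(nch, 2); wr_int(fs, 4)
  wr_int(fs * block, 4); wr_int(block, 2); wr_int(bits, 2)
  if (fmt_code == 3L) {
    wr_int(0, 2)  # cbSize
    writeChar("fact", con, eos = NULL); wr_int(4, 4); wr_int(length(x), 4)
  }
  writeChar("data", con, eos = NULL); wr_int(data_len, 4)
  if (format == "float32") {
    writeBin(as.numeric(x), con, size = 4, endian = "little")
    invisible(1)
  } else {
    q <- as.integer(round(pmax(-1, pmin(1, x / scale_pa)) * 32767))
    writeBin(q, con, size = 2, endian = "little")
    writeLines(format(scale_pa, digits = 17),
               paste0(path, ".scale.txt"))
    invisible(scale_pa)
  }
}

#' Read a WAV file into a pressure trace
#'
#' Reads mono float32 or PCM16 RIFF/WAVE files. For PCM16 a `.scale.txt`
#' sidecar written by [write_wav()] restores the pressure calibration;
#' otherwise `scale_pa` applies.
#'
#' @param path file path.
#' @param channel sensor label for the returned trace.
#' @param scale_pa full-scale pressure for PCM16 without a sidecar, Pa.
#' @return A `pressure_trace`.
#' @export
read_wav <- function(path, channel = "microphone", scale_pa = 1) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd_int <- function(size, signed = TRUE)
    readBin(con, "integer", n = 1, size = size, endian = "little",
            signed = signed)
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file")
  rd_int(4)
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file")
  fmt_code <- NA; fs <- NA; bits <- NA; nch <- NA; x <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    len <- rd_int(4)
    if (id == "fmt ") {
      fmt_code <- rd_int(2); nch <- rd_int(2); fs <- rd_int(4)
      rd_int(4); rd_int(2); bits <- rd_int(2)
      if (len > 16) readBin(con, "raw", n = len - 16)
    } else if (id == "data") {
      if (fmt_code == 3 && bits == 32)
        x <- readBin(con, "numeric", n = len / 4, size = 4,
                     endian = "little")
      else if (fmt_code == 1 && bits == 16)
        x <- readBin(con, "integer", n = len / 2, size = 2,
                     endian = "little", signed = TRUE)
      else stop("unsupported WAV encoding (format ", fmt_code, ", ",
                bits, " bit)")
      if (len %% 2 == 1) readBin(con, "raw", n = 1)
    } else {
      readBin(con, "raw", n = len + len %% 2)
    }
    if (!is.null(x) && !is.na(fmt_code)) break
  }
  if (is.null(x)) stop("no data chunk found")
  if (nch != 1) stop("only mono WAV supported")
  if (fmt_code == 1) {
    sidecar <- paste0(path, ".scale.txt")
    if (file.exists(sidecar))
      scale_pa <- as.numeric(readLines(sidecar, n = 1))
    x <- x / 32767 * scale_pa
  }
  pressure_trace(x, fs, channel)
}

#' Write a frame stack as a multi-page TIFF
#'
#' Float 32-bit pages; intensities are clamped to `[0, 1]`. Frame rate,
#' pixel size and origin are stored in a `.meta.yml` sidecar so the stack
#' round-trips through [read_frame_stack()].
#'
#' @param stack a `frame_stack`.
#' @param path output TIFF path.
#' @return Invisibly, `path`.
#' @export
write_frame_stack <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  n <- dim(stack$frames)[3]
  pages <- lapply(seq_len(n), function(i) {
    f <- stack$frames[, , i]
    f[f < 0] <- 0; f[f > 1] <- 1
    f
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  yaml::write_yaml(list(frame_rate = stack$frame_rate,
                        px_size_um = stack$px_size_um,
                        origin_um = as.numeric(stack$origin_um)),
                   paste0(path, ".meta.yml"))
  invisible(path)
}

#' Read a multi-page TIFF into a frame stack
#'
#' @param path TIFF path; frame rate and calibration come from the
#'   `.meta.yml` sidecar when present, else from the arguments.
#' @param frame_rate,px_size_um,origin_um metadata fallbacks.
#' @return A `frame_stack`.
#' @export
read_frame_stack <- function(path, frame_rate = NULL, px_size_um = NULL,
                             origin_um = c(0, 0)) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta_path <- paste0(path, ".meta.yml")
  if (file.exists(meta_path)) {
    meta <- yaml::read_yaml(meta_path)
    frame_rate <- meta$frame_rate
    px_size_um <- meta$px_size_um
    origin_um <- as.numeric(meta$origin_um)
  }
  if (is.null(frame_rate) || is.null(px_size_um))
    stop("frame_rate and px_size_um required (no metadata sidecar)")
  d <- dim(pages[[1]])
  frames <- array(unlist(pages), dim = c(d[1], d[2], length(pages)))
  structure(list(frames = frames, frame_rate = frame_rate,
                 px_size_um = px_size_um, origin_um = origin_um),
            class = "frame_stack")
}

#' Write / read an analysis configuration
#'
#' YAML round trip of a [run_config()] list, used to echo the full parameter
#' set into every output directory for provenance.
#'
#' @param config a `run_config` list.
#' @param path YAML file path.
#' @return `write_config` returns `path` invisibly; `read_config` returns
#'   the configuration list.
#' @export
write_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$interval_candidates <- as.list(cfg$interval_candidates)
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$interval_candidates <- unlist(cfg$interval_candidates)
  cfg$cavitation_ref_pa <- as.numeric(unlist(cfg$cavitation_ref_pa))
  structure(cfg, class = "run_config")
}
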