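# File I/O: 8-bit grayscale PNG/BMP frames, flat key-value config files,
# template masks with sidecar records, and tab-separated result logs.

#' Read and write thermographic frames
#'
#' Frames are stored as 8-bit grayscale images.  PNG is handled through the
#' png package; BMP (the snapshot format of the acquisition system) by a
#' minimal built-in reader/writer for uncompressed 8-bit palette bitmaps,
#' since no available package reads BMP.  Writing then reading a frame
#' reproduces the pixel matrix exactly.
#'
#' @param path file path ending in `.png` or `.bmp`.
#' @param calib the [temperature_calibration()] to attach.
#' @param timestamp optional acquisition time, seconds.
#' @param frame a [thermal_frame()] (or intensity matrix) to write.
#' @return `read_frame()` returns a [thermal_frame()]; `write_frame()`
#'   returns `path` invisibly.
#' @export
read_frame <- function(path, calib = temperature_calibration(),
                       timestamp = NA_real_) {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
               png = read_png_gray(path),
               bmp = read_bmp_gray(path),
               stop_format("unsupported image format: .", ext))
  thermal_frame(px, calib, timestamp)
}

#' @rdname read_frame
#' @export
write_frame <- function(frame, path) {
  px <- as_pixel_matrix(frame)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG(px / 255, path),
         bmp = write_bmp_gray(px, path),
         stop_format("unsupported image format: .", ext))
  invisible(path)
}

read_png_gray <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] == 2L) {
      img <- img[, , 1]  # gray + alpha
    } else {
      stop_format("non-grayscale PNG: ", path)
    }
  }
  matrix(as.integer(round_half_up(img * 255)), nrow = nrow(img))
}

# Minimal uncompressed 8-bit palette BMP support (BITMAPINFOHEADER, BI_RGB,
# grayscale palette, bottom-up rows padded to 4 bytes).

write_bmp_gray <- function(px, path) {
  h <- nrow(px); w <- ncol(px)
  row_bytes <- ((w + 3L) %/% 4L) * 4L
  data_size <- row_bytes * h
  offset <- 14L + 40L + 256L * 4L
  con <- file(path, "wb")
  on.exit(close(con))
  u16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeBin(charToRaw("BM"), con)
  u32(offset + data_size); u16(0); u16(0); u32(offset)
  u32(40); u32(w); u32(h); u16(1); u16(8); u32(0); u32(data_size)
  u32(2835); u32(2835); u32(256); u32(0)
  pal <- as.raw(rep(0:255, each = 4) * c(1, 1, 1, 0))  # B, G, R, reserved
  writeBin(pal, con)
  rows <- matrix(as.raw(0), nrow = row_bytes, ncol = h)
  rows[seq_len(w), ] <- as.raw(t(px[h:1, , drop = FALSE]))
  writeBin(as.vector(rows), con)
  invisible(path)
}

read_bmp_gray <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  u16 <- function(at) sum(as.integer(raw[at + 0:1]) * c(1, 256))
  u32 <- function(at) sum(as.integer(raw[at + 0:3]) * 256^(0:3))
  if (rawToChar(raw[1:2]) != "BM") stop_format("not a BMP file: ", path)
  offset <- u32(11L)
  header_size <- u32(15L)
  if (header_size < 40L) stop_format("unsupported BMP header in ", path)
  w <- u32(19L); h <- u32(23L)
  bpp <- u16(29L); compression <- u32(31L)
  if (bpp != 8L || compression != 0L) {
    stop_format("only uncompressed 8-bit BMP supported: ", path)
  }
  n_colors <- u32(47L); if (n_colors == 0L) n_colors <- 256L
  pal_at <- 14L + header_size
  pal <- matrix(as.integer(raw[pal_at + seq_len(n_colors * 4L)]), nrow = 4L)
  if (any(pal[1, ] != pal[2, ] | pal[2, ] != pal[3, ])) {
    stop_format("non-grayscale BMP palette: ", path)
  }
  gray <- pal[1, ]  # palette index -> gray level
  row_bytes <- ((w + 3L) %/% 4L) * 4L
  rows <- matrix(as.integer(raw[offset + seq_len(row_bytes * h)]),
                 nrow = row_bytes)
  px <- t(rows[seq_len(w), h:1, drop = FALSE])
  matrix(gray[px + 1L], nrow = h)
}

#' Load a sensor configuration from a flat key-value file
#'
#' The config format is one `key = value` pair per line (`#` comments and
#' blank lines ignored).  Recognized keys: `shift`, `mnot`,
#' `min_particle_area`, `match_threshold`, `rotation_step`, `max_hens`,
#' `temp_at_0`, `temp_at_255`, `template_shape`, `template_height`,
#' `template_base`, `template` (path to a template PNG written by
#' [write_template()]).  Missing keys fall back to the [sensor_config()]
#' defaults; unknown keys are configuration errors.  The preset
#' `"paper2018"` is the deployed field parameter set (shift 5 degC, MNOT
#' 796 px, triangle 43 x 33).
#'
#' @param path config file path, or `NULL` for pure defaults/preset.
#' @param preset optional preset name (`"paper2018"`).
#' @return A [sensor_config()].
#' @export
load_config <- function(path = NULL, preset = NULL) {
  kv <- list()
  if (!is.null(preset)) {
    if (!identical(preset, "paper2018")) stop_config("unknown preset: ", preset)
    # deployed field values; identical to the package defaults
    kv <- list(shift = 5, mnot = 796, template_shape = "triangle",
               template_height = 43, template_base = 33)
  }
  if (!is.null(path)) {
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      m <- regmatches(ln, regexec("^([A-Za-z0-9_]+)[[:space:]]*=[[:space:]]*(.*)$", ln))[[1]]
      if (length(m) != 3L) stop_config("malformed config line: '", ln, "'")
      kv[[m[2]]] <- trimws(m[3])
    }
  }
  known <- c("shift", "mnot", "min_particle_area", "match_threshold",
             "rotation_step", "max_hens", "temp_at_0", "temp_at_255",
             "template_shape", "template_height", "template_base", "template")
  unknown <- setdiff(names(kv), known)
  if (length(unknown) > 0L) {
    stop_config("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  num <- function(key, default) {
    if (is.null(kv[[key]])) return(default)
    v <- suppressWarnings(as.numeric(kv[[key]]))
    if (is.na(v)) stop_config("key '", key, "' must be numeric, got '", kv[[key]], "'")
    v
  }
  calib <- temperature_calibration(num("temp_at_0", 0), num("temp_at_255", 51))
  template <- if (!is.null(kv$template)) {
    read_template(kv$template)
  } else {
    shape <- if (is.null(kv$template_shape)) "triangle" else kv$template_shape
    render_template(shape, num("template_height", 43), num("template_base", 33))
  }
  sensor_config(shift = num("shift", 5),
                mnot = num("mnot", 796),
                min_particle_area = num("min_particle_area", 50),
                template = template,
                match_threshold = num("match_threshold", 0.5),
                rotation_step = num("rotation_step", 30),
                max_hens = num("max_hens", 5),
                calibration = calib)
}

#' @rdname load_config
#' @param config a [sensor_config()] to write.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "sensor_config"))
  lines <- c(
    sprintf("shift = %g", config$shift),
    sprintf("mnot = %d", config$mnot),
    sprintf("min_particle_area = %d", config$min_particle_area),
    sprintf("match_threshold = %g", config$match_threshold),
    sprintf("rotation_step = %g", config$rotation_step),
    sprintf("max_hens = %d", config$max_hens),
    sprintf("temp_at_0 = %g", config$calibration$temp_at_0),
    sprintf("temp_at_255 = %g", config$calibration$temp_at_255),
    sprintf("template_shape = %s", config$template$shape_kind),
    sprintf("template_height = %d", config$template$height),
    sprintf("template_base = %d", config$template$base))
  writeLines(lines, path)
  invisible(path)
}

#' Serialize templates as PNG masks with a sidecar text record
#'
#' @param template a `hen_template`.
#' @param path PNG path; the sidecar record (`shape_kind`, `height`, `base`)
#'   goes to `path` with a `.txt` extension.
#' @return `read_template()` returns the `hen_template`; `write_template()`
#'   returns `path` invisibly.
#' @export
write_template <- function(template, path) {
  stopifnot(inherits(template, "hen_template"))
  png::writePNG(template$mask + 0, path)  # writePNG wants doubles in [0, 1]
  side <- paste0(tools::file_path_sans_ext(path), ".txt")
  writeLines(c(paste("shape_kind =", template$shape_kind),
               paste("height =", template$height),
               paste("base =", template$base)), side)
  invisible(path)
}

#' @rdname write_template
#' @export
read_template <- function(path) {
  side <- paste0(tools::file_path_sans_ext(path), ".txt")
  if (!file.exists(side)) stop_format("missing template sidecar: ", side)
  kv <- list()
  for (ln in readLines(side, warn = FALSE)) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) == 2L) kv[[trimws(parts[1])]] <- trimws(parts[2])
  }
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  mask <- matrix(as.integer(img > 0.5), nrow = nrow(img))
  structure(list(mask = mask, shape_kind = kv$shape_kind,
                 height = as.integer(kv$height), base = as.integer(kv$base)),
            class = "hen_template")
}

#' Write and read per-frame sensor results
#'
#' One tab-separated row per frame: `timestamp`, `cp`, `mno`, `hen_count`,
#' `background_temp`.
#'
#' @param results list of `occupancy_result` (see [process_sequence()]) or a
#'   data.frame from [occupancy_table()].
#' @param path file path.
#' @export
write_results <- function(results, path) {
  df <- if (is.data.frame(results)) results else occupancy_table(results)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  read.delim(path, colClasses = c("numeric", "numeric", "integer",
                                  "integer", "numeric"))
}
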