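#' Construct a film scan
#'
#' A `film_scan` holds the raw, un-calibrated pixel grid of a scanned
#' radiochromic film together with the scanner metadata needed to convert it
#' to a dose plane.
#'
#' @param pixels integer matrix of pixel values, rows = inplane, columns =
#'   crossplane.
#' @param bit_depth bits per sample of the data (default 12; 12-bit data in
#'   a 16-bit container is the usual digitizer output).
#' @param dpi scan resolution in dots per inch (default 75).
#' @param roi rectangular crop in pixel indices `c(row1, row2, col1, col2)`;
#'   default the full grid.
#' @param sdd source-to-detector distance at which the film was irradiated,
#'   in cm (default 56.8, the tray position in the accessory holder).
#' @param steps character vector of provenance notes.
#' @return an object of class `film_scan`.
#' @export
film_scan <- function(pixels, bit_depth = 12, dpi = 75, roi = NULL,
                      sdd = 56.8, steps = character()) {
  pixels <- as.matrix(pixels)
  if (!is.numeric(pixels) || length(pixels) == 0L)
    stop("'pixels' must be a non-empty numeric matrix")
  if (any(pixels != round(pixels), na.rm = TRUE))
    stop("'pixels' must be integer-valued")
  if (!is.finite(bit_depth) || bit_depth <= 0 || bit_depth > 32)
    stop("'bit_depth' must be in 1..32")
  if (any(pixels < 0 | pixels >= 2^bit_depth, na.rm = TRUE))
    stop(sprintf("pixel values must lie in [0, %d) for bit depth %d",
                 2^bit_depth, bit_depth))
  if (!is.finite(dpi) || dpi <= 0) stop("'dpi' must be > 0")
  if (!is.finite(sdd) || sdd <= 0) stop("'sdd' must be > 0 (cm)")
  d <- dim(pixels)
  if (is.null(roi)) roi <- c(1L, d[1], 1L, d[2])
  roi <- as.integer(roi)
  if (length(roi) != 4L || roi[1] < 1L || roi[2] > d[1] || roi[3] < 1L ||
      roi[4] > d[2] || roi[1] > roi[2] || roi[3] > roi[4])
    stop("'roi' must be c(row1, row2, col1, col2) inside the pixel grid")
  structure(list(pixels = pixels, bit_depth = as.integer(bit_depth),
                 dpi = as.numeric(dpi), roi = roi, sdd = as.numeric(sdd),
                 steps = as.character(steps)),
            class = "film_scan")
}

#' @export
print.film_scan <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("film scan: %d x %d px, %d-bit, %g dpi (%.4f mm/px), SDD %.1f cm\n",
              d[1], d[2], x$bit_depth, x$dpi, scan_pixel_spacing(x), x$sdd))
  cat(sprintf("  ROI rows %d..%d, cols %d..%d; pixel range [%d, %d]\n",
              x$roi[1], x$roi[2], x$roi[3], x$roi[4],
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Pixel spacing of a film scan
#'
#' @param scan a `film_scan`.
#' @return pixel pitch in mm (25.4 / dpi).
#' @export
scan_pixel_spacing <- function(scan) {
  stopifnot(inherits(scan, "film_scan"))
  25.4 / scan$dpi
}

#' Read a scanned film TIFF
#'
#' Reads a grayscale or RGB TIFF into a `film_scan`.  RGB images are reduced
#' to their red channel (the most dose-sensitive channel of EBT-type film);
#' this is logged in the scan's `steps`.  The dpi is taken from the TIFF
#' resolution metadata when present, otherwise `default_dpi` is used and the
#' fallback logged.  12-bit data stored in a 16-bit container is the
#' expected digitizer output: when the sample depth reads 16 but every pixel
#' fits in 12 bits, the scan is recorded as 12-bit.
#'
#' @param path TIFF file path.
#' @param roi optional crop `c(row1, row2, col1, col2)` applied after
#'   reading (the returned pixel grid is the cropped region).
#' @param default_dpi resolution assumed when the file carries none
#'   (default 75).
#' @param sdd irradiation distance in cm (default 56.8).
#' @return a `film_scan`.
#' @export
read_film_tiff <- function(path, roi = NULL, default_dpi = 75, sdd = 56.8) {
  if (!file.exists(path)) stop(sprintf("film TIFF not found: '%s'", path))
  img <- tryCatch(tiff::readTIFF(path, info = TRUE, as.is = TRUE),
                  error = function(e)
                    stop(sprintf("cannot read TIFF '%s': %s", path,
                                 conditionMessage(e))))
  steps <- sprintf("read_film_tiff: '%s'", path)
  if (length(dim(img)) == 3L) {
    nch <- dim(img)[3]
    if (nch < 3L)
      stop(sprintf("unsupported sample format in '%s': %d channels", path, nch))
    img2 <- img[, , 1]
    attributes(img2) <- c(attributes(img2), attributes(img)[
      setdiff(names(attributes(img)), c("dim", "dimnames"))])
    img <- img2
    steps <- c(steps, "channel: RGB input reduced to red channel")
  } else if (length(dim(img)) != 2L) {
    stop(sprintf("unsupported TIFF layout in '%s'", path))
  }
  info <- attributes(img)
  bits <- info$bits.per.sample
  if (is.null(bits)) bits <- 16L
  # readTIFF(as.is = TRUE) yields native integers for grayscale but
  # normalized [0, 1] values for multi-channel images
  px <- matrix(as.numeric(img), nrow = nrow(img))
  if (any(px != round(px)) && max(px) <= 1)
    px <- round(px * (2^bits - 1))
  if (any(px != round(px)))
    stop(sprintf("unsupported sample format in '%s': non-integer samples", path))
  if (bits == 16L && max(px) < 4096) {
    bits <- 12L
    steps <- c(steps, "bit depth: 12-bit data detected in 16-bit container")
  }
  dpi <- NULL
  if (!is.null(info$x.resolution) && is.finite(info$x.resolution) &&
      info$x.resolution > 0) {
    dpi <- info$x.resolution
    unit <- info$resolution.unit
    if (!is.null(unit) && identical(unit, "cm")) dpi <- dpi * 2.54
    steps <- c(steps, sprintf("dpi: %g from TIFF metadata", dpi))
  } else {
    dpi <- default_dpi
    steps <- c(steps, sprintf("dpi: metadata absent, fallback %g", dpi))
  }
  scan <- film_scan(px, bit_depth = bits, dpi = dpi, sdd = sdd, steps = steps)
  if (!is.null(roi)) {
    roi <- as.integer(roi)
    if (length(roi) != 4L || roi[1] > roi[2] || roi[3] > roi[4])
      stop(sprintf("zero-size or malformed ROI for '%s'", path))
    if (roi[1] < 1L || roi[2] > nrow(px) || roi[3] < 1L || roi[4] > ncol(px))
      stop(sprintf("ROI outside pixel grid of '%s'", path))
    scan <- film_scan(px[roi[1]:roi[2], roi[3]:roi[4], drop = FALSE],
                      bit_depth = bits, dpi = dpi, sdd = sdd,
                      steps = c(steps, sprintf("roi: rows %d..%d cols %d..%d",
                                               roi[1], roi[2], roi[3], roi[4])))
  }
  scan
}

#' Write a film scan as a 16-bit grayscale TIFF
#'
#' Fixture/export helper; the written file round-trips losslessly through
#' [read_film_tiff()] (resolution metadata is not embedded, so reading
#' relies on the dpi fallback).
#'
#' @param scan a `film_scan`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_film_tiff <- function(scan, path) {
  stopifnot(inherits(scan, "film_scan"))
  tiff::writeTIFF(scan$pixels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Mean pixel value over a patch
#'
#' Statistic used to tie a calibration irradiation to a single pixel value:
#' the arithmetic mean over a rectangular patch, with its standard deviation
#' for quality control.
#'
#' @param scan a `film_scan`.
#' @param patch `c(row1, row2, col1, col2)` in pixel indices, inside the
#'   scan's ROI; default the whole ROI.
#' @return list with `mean`, `sd` and `n`.
#' @export
roi_mean_pixel <- function(scan, patch = NULL) {
  stopifnot(inherits(scan, "film_scan"))
  if (is.null(patch)) patch <- scan$roi
  patch <- as.integer(patch)
  if (length(patch) != 4L || patch[1] > patch[2] || patch[3] > patch[4])
    stop("empty or malformed patch")
  if (patch[1] < scan$roi[1] || patch[2] > scan$roi[2] ||
      patch[3] < scan$roi[3] || patch[4] > scan$roi[4])
    stop("patch must lie inside the scan ROI")
  v <- scan$pixels[patch[1]:patch[2], patch[3]:patch[4]]
  list(mean = mean(v), sd = stats::sd(as.numeric(v)), n = length(v))
}

# ---------------------------------------------------------------------------
# ascii_grid dose-plane format: plain-text, self-describing header then
# ny rows of nx doses.  Versioned so readers can refuse future layouts.

#' Read a dose plane from disk
#'
#' Supported formats: `"ascii_grid"`, a self-describing plain-text format
#' (header: nx, ny, spacing_mm, origin_mm, sdd_cm, unit; then ny rows of nx
#' doses), and `"dicom_rt_dose"`, a single-frame DICOM RT Dose file
#' (Explicit VR little endian, uncompressed).  DICOM doses in Gy are
#' converted to cGy via DoseGridScaling.
#'
#' @param path file path.
#' @param format `"ascii_grid"` (default) or `"dicom_rt_dose"`.
#' @return a `dose_plane` in cGy.
#' @export
read_dose_grid <- function(path, format = c("ascii_grid", "dicom_rt_dose")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("dose grid not found: '%s'", path))
  switch(format,
         ascii_grid = read_ascii_grid(path),
         dicom_rt_dose = read_dicom_rt_dose(path))
}

read_ascii_grid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L || !startsWith(lines[1], "rcfqa_dose_grid"))
    stop(sprintf("'%s' is not an rcfqa ascii_grid file", path))
  ver <- trimws(sub("^rcfqa_dose_grid", "", lines[1]))
  if (!identical(ver, "v1"))
    stop(sprintf("unsupported ascii_grid version '%s' in '%s'", ver, path))
  hdr <- list(); i <- 2L
  while (i <= length(lines) && !startsWith(lines[i], "data")) {
    kv <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (length(kv) >= 2L) hdr[[kv[1]]] <- kv[-1]
    i <- i + 1L
  }
  need <- c("nx", "ny", "spacing_mm", "origin_mm", "sdd_cm", "unit")
  miss <- setdiff(need, names(hdr))
  if (length(miss))
    stop(sprintf("ascii_grid '%s' header missing: %s", path,
                 paste(miss, collapse = ", ")))
  nx <- as.integer(hdr$nx[1]); ny <- as.integer(hdr$ny[1])
  unit <- hdr$unit[1]
  if (!unit %in% c("cGy", "Gy"))
    stop(sprintf("ascii_grid '%s': unknown dose unit '%s'", path, unit))
  if (i >= length(lines))
    stop(sprintf("ascii_grid '%s': no data section", path))
  toks <- unlist(strsplit(trimws(lines[(i + 1L):length(lines)]), "[[:space:]]+"))
  toks <- toks[nzchar(toks)]
  vals <- suppressWarnings(as.numeric(toks))  # "NA" tokens stay NA
  if (length(vals) != nx * ny)
    stop(sprintf("ascii_grid '%s': header promises %d values, found %d",
                 path, nx * ny, length(vals)))
  m <- matrix(vals, nrow = ny, ncol = nx, byrow = TRUE)
  if (unit == "Gy") m <- m * 100
  lbl <- if (!is.null(hdr$label)) paste(hdr$label, collapse = " ") else ""
  dose_plane(m, spacing = as.numeric(hdr$spacing_mm[1:2]),
             origin = as.numeric(hdr$origin_mm[1:2]),
             sdd = as.numeric(hdr$sdd_cm[1]), label = lbl)
}

#' Write a dose plane in the ascii_grid format
#'
#' @param plane a `dose_plane`.
#' @param path output path.
#' @param digits significant digits to keep (default 10; the write/read
#'   round trip is lossless at default settings for doses of clinical
#'   magnitude).
#' @return `path`, invisibly.
#' @export
write_dose_grid <- function(plane, path, digits = 10) {
  stopifnot(inherits(plane, "dose_plane"))
  d <- dim(plane$values)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("rcfqa_dose_grid v1",
               sprintf("nx %d", d[2]),
               sprintf("ny %d", d[1]),
               sprintf("spacing_mm %.12g %.12g", plane$spacing[1], plane$spacing[2]),
               sprintf("origin_mm %.12g %.12g", plane$origin[1], plane$origin[2]),
               sprintf("sdd_cm %.12g", plane$sdd),
               "unit cGy",
               if (nzchar(plane$label)) sprintf("label %s", plane$label),
               "data"), con)
  apply(plane$values, 1, function(row)
    writeLines(paste(formatC(row, digits = digits, format = "g"),
                     collapse = " "), con))
  invisible(path)
}

# ---------------------------------------------------------------------------
# Minimal DICOM RT Dose support (Explicit VR little endian, single frame,
# uncompressed).  No installed R package reads DICOM, so the small subset
# needed here is implemented directly.

.u16 <- function(raw2) as.integer(raw2[1]) + 256L * as.integer(raw2[2])
.u32 <- function(raw4) sum(as.numeric(raw4) * c(1, 256, 65536, 16777216))

read_dicom_rt_dose <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    stop(sprintf("'%s' is not a DICOM file (missing DICM magic)", path))
  pos <- 133L
  elems <- list()
  ts <- NULL
  repeat {
    if (pos + 7L > length(raw)) break
    group <- .u16(raw[pos:(pos + 1L)])
    elem <- .u16(raw[(pos + 2L):(pos + 3L)])
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      len <- .u32(raw[(pos + 8L):(pos + 11L)])
      hdr <- 12L
    } else if (grepl("^[A-Z]{2}$", vr)) {
      len <- .u16(raw[(pos + 6L):(pos + 7L)])
      hdr <- 8L
    } else {
      stop(sprintf("'%s': implicit-VR or corrupt element at offset %d; only Explicit VR little endian is supported",
                   path, pos - 1L))
    }
    if (len == 4294967295) stop(sprintf("'%s': undefined-length elements are not supported", path))
    if (pos + hdr + len - 1L > length(raw))
      stop(sprintf("'%s': truncated DICOM element (%04x,%04x)", path, group, elem))
    body <- if (len > 0) raw[(pos + hdr):(pos + hdr + len - 1L)] else raw(0)
    key <- sprintf("%04x,%04x", group, elem)
    elems[[key]] <- list(vr = vr, body = body)
    if (key == "0002,0010") ts <- trimws(rawToChar(body))
    pos <- pos + hdr + len
  }
  if (!is.null(ts) && ts != "1.2.840.10008.1.2.1")
    stop(sprintf("'%s': transfer syntax %s not supported (Explicit VR little endian only)", path, ts))
  getstr <- function(key) {
    e <- elems[[key]]
    if (is.null(e)) return(NULL)
    trimws(rawToChar(e$body))
  }
  getus <- function(key) {
    e <- elems[[key]]
    if (is.null(e)) return(NULL)
    .u16(e$body[1:2])
  }
  modality <- getstr("0008,0060")
  if (!is.null(modality) && modality != "RTDOSE")
    stop(sprintf("'%s': modality '%s' is not RTDOSE", path, modality))
  nrows <- getus("0028,0010"); ncols <- getus("0028,0011")
  bits <- getus("0028,0100")
  if (is.null(nrows) || is.null(ncols) || is.null(bits))
    stop(sprintf("'%s': missing Rows/Columns/BitsAllocated", path))
  nframes <- getstr("0028,0008")
  if (!is.null(nframes) && as.integer(nframes) > 1L)
    stop(sprintf("'%s': multi-frame RT Dose not supported; export a single coronal slice", path))
  scaling <- getstr("3004,000e")
  if (is.null(scaling))
    stop(sprintf("'%s': DoseGridScaling (3004,000E) missing", path))
  scaling <- as.numeric(scaling)
  units <- getstr("3004,0002")
  if (!is.null(units) && !toupper(units) %in% c("GY", "RELATIVE"))
    stop(sprintf("'%s': unsupported dose units '%s'", path, units))
  iop <- getstr("0020,0037")
  if (!is.null(iop)) {
    v <- as.numeric(strsplit(iop, "\\\\")[[1]])
    # coronal slice: rows and columns both orthogonal to the patient A-P axis
    if (length(v) == 6L && (abs(v[2]) > 1e-3 || abs(v[5]) > 1e-3))
      stop(sprintf("'%s': non-coronal orientation; this tool compares coronal dose planes", path))
  }
  ps <- getstr("0028,0030")
  spacing <- if (is.null(ps)) c(1, 1) else rev(as.numeric(strsplit(ps, "\\\\")[[1]]))
  ipp <- getstr("0020,0032")
  origin <- if (is.null(ipp)) NULL else {
    v <- as.numeric(strsplit(ipp, "\\\\")[[1]])
    c(v[1], v[3])  # coronal: x (crossplane), z (inplane)
  }
  pd <- elems[["7fe0,0010"]]
  if (is.null(pd)) stop(sprintf("'%s': PixelData missing", path))
  if (bits == 16L) {
    n <- length(pd$body) %/% 2L
    vals <- readBin(pd$body, "integer", n = n, size = 2, signed = FALSE,
                    endian = "little")
  } else if (bits == 32L) {
    n <- length(pd$body) %/% 4L
    vals <- readBin(pd$body, "integer", n = n, size = 4, endian = "little")
    vals <- ifelse(vals < 0, vals + 4294967296, vals)
  } else stop(sprintf("'%s': BitsAllocated %d not supported", path, bits))
  if (n != nrows * ncols)
    stop(sprintf("'%s': PixelData holds %d samples, header promises %d",
                 path, n, nrows * ncols))
  m <- matrix(vals, nrow = nrows, ncol = ncols, byrow = TRUE)
  dose_plane(m * scaling * 100, spacing = spacing, origin = origin,
             sdd = 100, label = basename(path))
}

# Internal fixture writer: emits a minimal single-frame Explicit-VR-LE RT
# Dose file.  Used by the test suite to exercise read_dose_grid().
write_dicom_rt_dose <- function(plane, path, scaling = 1e-4) {
  stopifnot(inherits(plane, "dose_plane"))
  d <- dim(plane$values)
  stored <- round(plane$values / 100 / scaling)  # cGy -> Gy -> stored
  if (any(stored < 0 | stored > 65535, na.rm = TRUE))
    stop("doses out of range for 16-bit storage at this scaling")
  stored[is.na(stored)] <- 0
  pad <- function(s) if (nchar(s) %% 2 == 1) paste0(s, " ") else s
  el <- function(group, elem, vr, body) {
    if (is.character(body)) body <- charToRaw(pad(body))
    stopifnot(length(body) %% 2 == 0)
    tag <- writeBin(c(group, elem), raw(), size = 2, endian = "little")
    if (vr %in% c("OB", "OW")) {
      c(tag, charToRaw(vr), as.raw(c(0, 0)),
        writeBin(length(body), raw(), size = 4, endian = "little"), body)
    } else {
      c(tag, charToRaw(vr),
        writeBin(length(body), raw(), size = 2, endian = "little"), body)
    }
  }
  us <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
  meta <- c(el(0x0002L, 0x0002L, "UI", "1.2.840.10008.5.1.4.1.1.481.2"),
            el(0x0002L, 0x0003L, "UI", "1.2.826.0.1.3680043.9999.1"),
            el(0x0002L, 0x0010L, "UI", "1.2.840.10008.1.2.1"))
  grouplen <- el(0x0002L, 0x0000L, "UL",
                 writeBin(length(meta), raw(), size = 4, endian = "little"))
  px <- writeBin(as.integer(t(stored)), raw(), size = 2, endian = "little")
  body <- c(
    el(0x0008L, 0x0060L, "CS", "RTDOSE"),
    el(0x0020L, 0x0032L, "DS", sprintf("%g\\0\\%g", plane$origin[1], plane$origin[2])),
    el(0x0020L, 0x0037L, "DS", "1\\0\\0\\0\\0\\1"),
    el(0x0028L, 0x0008L, "IS", "1"),
    el(0x0028L, 0x0010L, "US", us(d[1])),
    el(0x0028L, 0x0011L, "US", us(d[2])),
    el(0x0028L, 0x0030L, "DS", sprintf("%g\\%g", plane$spacing[2], plane$spacing[1])),
    el(0x0028L, 0x0100L, "US", us(16L)),
    el(0x0028L, 0x0101L, "US", us(16L)),
    el(0x0028L, 0x0102L, "US", us(15L)),
    el(0x0028L, 0x0103L, "US", us(0L)),
    el(0x3004L, 0x0002L, "CS", "GY"),
    el(0x3004L, 0x000eL, "DS", sprintf("%.10g", scaling)),
    el(0x7fe0L, 0x0010L, "OW", px))
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), grouplen, meta, body), con)
  invisible(path)
}
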