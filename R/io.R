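## Image stack container and TIFF/MRC2014 IO.
##
## Axis convention throughout the package: voxels are indexed (z, y, x),
## y increasing downward in image row order. Intensities are held as doubles;
## the original sample type is recorded in `dtype` for write-back.

#' Image stack with physical metadata
#'
#' The universal carrier for image data in fibsemqc: a 3D voxel array in
#' (z, y, x) order together with the lateral pixel size and the slice
#' (milling) step. Single images are represented as 1-slice stacks.
#'
#' @param voxels numeric array; a 2D matrix is promoted to a 1-slice stack.
#' @param pixel_nm lateral pixel size in nm per pixel (x and y), > 0.
#' @param step_nm slice step in nm (distance milled between consecutive
#'   slices); may be `NA` for single images.
#' @param dtype storage type for write-back: `"uint8"`, `"uint16"`,
#'   `"int16"`, `"int8"` or `"float"`.
#' @return an object of class `image_stack` with fields `voxels`,
#'   `pixel_nm`, `step_nm`, `dtype`.
#' @examples
#' s <- image_stack(array(0, c(2, 8, 8)), pixel_nm = 5, step_nm = 50)
#' dim(s$voxels)
#' @export
image_stack <- function(voxels, pixel_nm, step_nm = NA_real_,
                        dtype = "float") {
  if (is.matrix(voxels)) voxels <- array(voxels, c(1L, dim(voxels)))
  if (length(dim(voxels)) != 3L)
    stop("voxels must be a 2D matrix or 3D array (z, y, x)")
  if (!is.numeric(pixel_nm) || length(pixel_nm) != 1L ||
      !is.finite(pixel_nm) || pixel_nm <= 0)
    stop("pixel_nm must be a single positive number")
  if (!is.na(step_nm) && step_nm <= 0)
    stop("step_nm must be positive (or NA for single images)")
  if (!all(is.finite(voxels))) stop("voxels must be finite")
  dtype <- match.arg(dtype, c("float", "uint8", "uint16", "int16", "int8"))
  structure(list(voxels = voxels * 1.0, pixel_nm = as.numeric(pixel_nm),
                 step_nm = as.numeric(step_nm), dtype = dtype),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "image_stack: %d slice(s) of %d x %d px, pixel %.4g nm, step %s nm, dtype %s\n",
    d[1], d[2], d[3], x$pixel_nm,
    if (is.na(x$step_nm)) "NA" else format(x$step_nm), x$dtype))
  invisible(x)
}

#' Extract one slice of a stack as a matrix
#'
#' @param stack an [image_stack()] (a plain matrix passes through).
#' @param z 1-based slice index.
#' @return a numeric matrix (y, x).
#' @export
stack_slice <- function(stack, z = 1L) {
  if (is.matrix(stack)) return(stack)
  if (inherits(stack, "image_stack")) stack <- stack$voxels
  stack[z, , , drop = TRUE]
}

.as_image_matrix <- function(image) {
  if (inherits(stack <- image, "image_stack")) image <- stack_slice(stack, 1L)
  if (!is.matrix(image)) stop("expected a 2D image (matrix or 1-slice stack)")
  image
}

## ---- MRC2014 ----------------------------------------------------------

.mrc_modes <- c(`0` = "int8", `1` = "int16", `2` = "float", `6` = "uint16")

.read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_int <- readBin(con, "integer", n = 10L, size = 4L, endian = "little")
  cella <- readBin(con, "numeric", n = 3L, size = 4L, endian = "little")
  cellb <- readBin(con, "numeric", n = 3L, size = 4L, endian = "little")
  mapcrs <- readBin(con, "integer", n = 3L, size = 4L, endian = "little")
  dstats <- readBin(con, "numeric", n = 3L, size = 4L, endian = "little")
  ispg_nsym <- readBin(con, "integer", n = 2L, size = 4L, endian = "little")
  seek(con, 1024L)
  nx <- hdr_int[1]; ny <- hdr_int[2]; nz <- hdr_int[3]; mode <- hdr_int[4]
  mx <- hdr_int[8]; my <- hdr_int[9]; mz <- hdr_int[10]
  if (!as.character(mode) %in% names(.mrc_modes))
    stop("unsupported MRC mode: ", mode)
  n <- nx * ny * nz
  vals <- switch(as.character(mode),
    `0` = readBin(con, "integer", n = n, size = 1L, signed = TRUE,
                  endian = "little"),
    `1` = readBin(con, "integer", n = n, size = 2L, signed = TRUE,
                  endian = "little"),
    `2` = readBin(con, "numeric", n = n, size = 4L, endian = "little"),
    `6` = {
      v <- readBin(con, "integer", n = n, size = 2L, signed = FALSE,
                   endian = "little")
      v
    })
  if (length(vals) != n) stop("truncated MRC data in ", path)
  # file stores x fastest, then y, then z; reorder to (z, y, x)
  a <- array(as.numeric(vals), c(nx, ny, nz))
  voxels <- aperm(a, c(3L, 2L, 1L))
  pixel_nm <- if (mx > 0 && cella[1] > 0) cella[1] / mx / 10 else NA_real_
  step_nm <- if (mz > 0 && cella[3] > 0) cella[3] / mz / 10 else NA_real_
  list(voxels = voxels, pixel_nm = pixel_nm, step_nm = step_nm,
       dtype = .mrc_modes[[as.character(mode)]])
}

.write_mrc <- function(stack, path) {
  d <- dim(stack$voxels)
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  mode <- switch(stack$dtype, int8 = 0L, int16 = 1L, uint16 = 6L, 2L)
  step <- if (is.na(stack$step_nm)) stack$pixel_nm else stack$step_nm
  con <- file(path, "wb")
  on.exit(close(con))
  wInt <- function(x) writeBin(as.integer(x), con, size = 4L,
                               endian = "little")
  wFlt <- function(x) writeBin(as.numeric(x), con, size = 4L,
                               endian = "little")
  v <- stack$voxels
  wInt(c(nx, ny, nz, mode, 0L, 0L, 0L, nx, ny, nz))
  wFlt(c(nx * stack$pixel_nm * 10, ny * stack$pixel_nm * 10, nz * step * 10))
  wFlt(c(90, 90, 90))
  wInt(c(1L, 2L, 3L))
  wFlt(c(min(v), max(v), mean(v)))
  wInt(c(1L, 0L))                       # ispg, nsymbt
  wInt(rep(0L, 25L))                    # extra
  wFlt(c(0, 0, 0))                      # origin
  writeChar("MAP ", con, 4L, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wFlt(sd(as.numeric(v)))
  wInt(0L)                              # nlabl
  writeBin(raw(800L), con)              # labels
  a <- aperm(v, c(3L, 2L, 1L))          # back to x-fastest order
  vals <- as.numeric(a)
  if (mode == 2L) {
    writeBin(vals, con, size = 4L, endian = "little")
  } else if (mode == 6L) {
    # writeBin has no unsigned 16-bit: wrap to signed representation
    iv <- as.integer(round(vals))
    iv[iv > 32767L] <- iv[iv > 32767L] - 65536L
    writeBin(iv, con, size = 2L, endian = "little")
  } else {
    writeBin(as.integer(round(vals)), con, size = ifelse(mode == 0L, 1L, 2L),
             endian = "little")
  }
  invisible(path)
}

## ---- TIFF -------------------------------------------------------------

.tiff_sidecar <- function(path) paste0(path, ".meta.json")

.read_tiff_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  shapes <- vapply(pages, function(p) dim(p)[1:2], integer(2))
  if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1]))
    stop("inconsistent slice shapes in ", path)
  drop_channel <- function(p) if (length(dim(p)) == 3L) p[, , 1L] else p
  voxels <- array(0, c(length(pages), shapes[1, 1], shapes[2, 1]))
  for (i in seq_along(pages)) voxels[i, , ] <- drop_channel(pages[[i]])
  meta <- list(pixel_nm = NA_real_, step_nm = NA_real_, dtype = NA_character_)
  sc <- .tiff_sidecar(path)
  if (file.exists(sc)) meta <- utils::modifyList(meta, jsonlite::read_json(sc))
  scalar <- function(x, na) if (length(x) != 1L || is.na(x)) na else x
  list(voxels = voxels,
       pixel_nm = as.numeric(scalar(meta$pixel_nm, NA_real_)),
       step_nm = as.numeric(scalar(meta$step_nm, NA_real_)),
       dtype = as.character(scalar(meta$dtype, NA_character_)))
}

.write_tiff_stack <- function(stack, path) {
  v <- stack$voxels
  dtype <- stack$dtype
  if (dtype == "float") {
    rng <- range(v)
    if (rng[1] < 0 || rng[2] > 1)
      stop("TIFF output supports integer dtypes or floats in [0,1]; ",
           "use an .mrc path for general float stacks")
    scale <- 1; bits <- 32L
  } else if (dtype %in% c("uint8", "int8")) {
    scale <- 255; bits <- 8L
  } else {
    scale <- 65535; bits <- 16L
  }
  pages <- lapply(seq_len(dim(v)[1]), function(z) v[z, , ] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  jsonlite::write_json(
    list(pixel_nm = stack$pixel_nm, step_nm = stack$step_nm,
         dtype = stack$dtype),
    .tiff_sidecar(path), auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

## ---- public API -------------------------------------------------------

#' Read an image stack or mask from TIFF or MRC
#'
#' Multi-page TIFF (with an optional JSON metadata sidecar written by
#' [write_stack()]) and MRC2014 volumes are supported. TIFF carries no
#' reliable physical units, so `pixel_nm`/`step_nm` should be supplied; for
#' MRC the voxel-size header is honored but an explicit override wins.
#'
#' @param path file path ending in `.tif`/`.tiff` or `.mrc`/`.rec`.
#' @param pixel_nm,step_nm physical metadata overrides in nm.
#' @return an [image_stack()].
#' @export
read_stack <- function(path, pixel_nm = NULL, step_nm = NULL) {
  if (!file.exists(path)) stop("cannot read ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("tif", "tiff")) .read_tiff_stack(path)
         else if (ext %in% c("mrc", "rec", "map")) .read_mrc(path)
         else stop("unsupported stack format: .", ext)
  px <- if (!is.null(pixel_nm)) pixel_nm else raw$pixel_nm
  st <- if (!is.null(step_nm)) step_nm else raw$step_nm
  if (is.na(px)) stop("pixel_nm not stored in file; supply it explicitly")
  image_stack(raw$voxels, pixel_nm = px, step_nm = st,
              dtype = if (is.na(raw$dtype)) "float" else raw$dtype)
}

#' Write an image stack to TIFF or MRC
#'
#' The format follows the file extension. MRC stores the metadata in the
#' MRC2014 voxel-size header; TIFF gets a small JSON sidecar
#' (`<path>.meta.json`) so that [read_stack()] round-trips metadata.
#' Integer dtypes round-trip bit-exactly; `"float"` data are stored as
#' 32-bit floats (use MRC).
#'
#' @param stack an [image_stack()].
#' @param path destination path (`.tif`/`.tiff` or `.mrc`).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  if (!dir.exists(dirname(path))) stop("directory does not exist: ",
                                       dirname(path))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) .write_tiff_stack(stack, path)
  else if (ext %in% c("mrc", "rec", "map")) .write_mrc(stack, path)
  else stop("unsupported stack format: .", ext)
  invisible(path)
}

#' Label mask helper
#'
#' Validates a non-negative integer label array against its parent stack
#' (0 = background, k > 0 = component k) and returns it as an integer array.
#'
#' @param labels integer array (2D or 3D).
#' @param parent optional [image_stack()] or array whose shape must match.
#' @return integer array of labels.
#' @export
label_mask <- function(labels, parent = NULL) {
  if (is.logical(labels)) labels <- labels * 1L
  if (any(labels < 0) || any(labels != round(labels)))
    stop("labels must be non-negative integers")
  if (!is.null(parent)) {
    pd <- if (inherits(parent, "image_stack")) dim(parent$voxels)
          else dim(parent)
    ld <- dim(labels)
    if (length(ld) == 2L && length(pd) == 3L) pd <- pd[2:3]
    if (!identical(as.integer(ld), as.integer(pd)))
      stop("mask shape does not match parent stack")
  }
  storage.mode(labels) <- "integer"
  labels
}

#' Imaging parameter record
#'
#' Per-image SEM acquisition parameters used by [electron_dose()].
#'
#' @param voltage_kV SEM acceleration voltage (kV).
#' @param current_pA beam current (pA), ideally the Faraday-cup measurement.
#' @param dwell_ns per-pixel dwell time (ns).
#' @param line_integration number of repeated line scans averaged per row.
#' @param pixel_nm pixel size (nm).
#' @return a list of class `imaging_params`.
#' @export
imaging_params <- function(voltage_kV, current_pA, dwell_ns,
                           line_integration, pixel_nm) {
  vals <- c(voltage_kV, current_pA, dwell_ns, line_integration, pixel_nm)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all imaging parameters must be strictly positive")
  structure(list(voltage_kV = voltage_kV, current_pA = current_pA,
                 dwell_ns = dwell_ns, line_integration = line_integration,
                 pixel_nm = pixel_nm), class = "imaging_params")
}

## shared internal logging: ISO timestamps on stderr, never in reports
.log <- function(fmt, ...) {
  message(format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"), " fibsemqc: ",
          sprintf(fmt, ...))
}
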