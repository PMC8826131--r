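# Stack I/O: multipage TIFF, directories of numbered single-page TIFFs, and
# raw binary volumes with a plain-text sidecar.
#
# 16-bit unsigned TIFFs go through the 'tiff' package in both directions.
# 32-bit float TIFFs are read through 'tiff' (libtiff handles the float
# sample format) but written by a small built-in writer, because writeTIFF()
# only stores integer sample formats; the writer emits plain uncompressed
# baseline TIFF (little-endian, one strip per page, SampleFormat = IEEE
# float), which both libtiff and Python's tifffile read back bit-exactly.

#' Read an image stack from TIFF
#'
#' Reads either a multipage TIFF file or a directory of single-page TIFFs.
#' Directory entries are ordered by natural numeric sort on the integer
#' embedded in each filename (`s2.tif` sorts before `s10.tif`), so zero
#' padding in filenames does not matter.
#'
#' @param path Path to a multipage TIFF file or a directory of single-page
#'   TIFFs.
#' @param meta Optional [acquisition_meta()]; when supplied, its slice count
#'   must agree with the file and the voxel size argument wins over TIFF
#'   resolution tags.
#' @param voxel_size_um Voxel size to record in the returned stack. When
#'   `NULL`, an x-resolution tag in the file is used if present (interpreted
#'   as pixels per centimetre), else 1.
#' @param on_nonfinite What to do with NaN/Inf pixels: `"error"` (default)
#'   or `"repair"`, which replaces them with the finite minimum of the slice
#'   and emits a warning.
#'
#' @return An [image_stack()] with slices in ascending slice order and
#'   `dtype` inferred from the pixel type (`"uint16"` or `"float32"`).
#' @export
read_stack <- function(path, meta = NULL, voxel_size_um = NULL,
                       on_nonfinite = c("error", "repair")) {
  on_nonfinite <- match.arg(on_nonfinite)
  if (!file.exists(path)) stop("input path does not exist: ", path)
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                        full.names = TRUE)
    if (length(files) == 0L)
      stop("no TIFF files found in directory: ", path)
    files <- files[natural_order(basename(files))]
    pages <- lapply(files, function(f) {
      p <- tiff::readTIFF(f, all = TRUE, info = TRUE)
      if (length(p) != 1L)
        stop("expected single-page TIFFs in directory mode, but '",
             basename(f), "' has ", length(p), " pages")
      p[[1]]
    })
  } else {
    pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  }
  shapes <- vapply(pages, function(p) paste(dim(p), collapse = "x"), "")
  if (length(unique(shapes)) != 1L)
    stop("mixed slice shapes in ", path, ": ",
         paste(unique(shapes), collapse = ", "))
  if (length(dim(pages[[1]])) != 2L)
    stop("only single-channel grayscale TIFFs are supported: ", path)

  fmt <- tiff_page_dtype(pages[[1]], path)
  d <- dim(pages[[1]])
  arr <- array(0, c(d[1], d[2], length(pages)))
  for (i in seq_along(pages)) {
    pg <- pages[[i]]
    if (fmt == "uint16") pg <- round(pg * 65535)
    arr[, , i] <- pg
  }
  if (fmt == "uint16") storage.mode(arr) <- "integer"

  if (any(!is.finite(arr))) {
    if (on_nonfinite == "error")
      stop("non-finite pixel values in ", path,
           " (use on_nonfinite = \"repair\" to replace them)")
    for (i in seq_len(dim(arr)[3])) {
      sl <- arr[, , i]
      bad <- !is.finite(sl)
      if (any(bad)) {
        sl[bad] <- min(sl[!bad])
        arr[, , i] <- sl
      }
    }
    warning("replaced non-finite pixels with the finite slice minimum in ",
            path)
  }

  vs <- voxel_size_um
  if (is.null(vs)) {
    xres <- attr(pages[[1]], "x.resolution")
    resu <- attr(pages[[1]], "resolution.unit")
    vs <- if (!is.null(xres) && is.numeric(xres) && xres > 0 &&
              identical(resu, "cm")) 10000 / xres else 1
  }
  if (!is.null(meta)) {
    stopifnot(inherits(meta, "AcquisitionMeta"))
    if (meta$n_slices != dim(arr)[3])
      stop("metadata declares ", meta$n_slices, " slices but ", path,
           " holds ", dim(arr)[3])
    vs <- meta$slice_spacing_mm * 1000
  }
  image_stack(arr, dtype = fmt, voxel_size_um = vs)
}

tiff_page_dtype <- function(page, path) {
  bps <- attr(page, "bits.per.sample")
  sf <- attr(page, "sample.format")
  if (identical(sf, "float") && identical(bps, 32L)) return("float32")
  if ((is.null(sf) || identical(sf, "unsigned integer")) &&
      identical(bps, 16L)) return("uint16")
  stop("unsupported TIFF pixel type in ", path, " (bits=", bps,
       ", format=", if (is.null(sf)) "unsigned integer" else sf,
       "); only 16-bit unsigned and 32-bit float grayscale are supported")
}

#' Write an image stack to TIFF
#'
#' @param stack An [image_stack()].
#' @param path Output file (multipage layout) or directory (per-slice
#'   layout). Parent directories are created as needed.
#' @param layout `"per-slice"` (default; one numbered file per slice,
#'   `slice_000.tif`, `slice_001.tif`, ... zero-padded to a fixed width) or
#'   `"multipage"` (one file).
#'
#' @return Invisibly, the vector of files written.
#' @export
write_stack <- function(stack, path, layout = c("per-slice", "multipage")) {
  layout <- match.arg(layout)
  validate_image_stack(stack)
  nz <- n_slices(stack)
  if (layout == "multipage") {
    dir_create_for(path)
    write_tiff_pages(lapply(seq_len(nz), function(i) stack$data[, , i]),
                     path, stack$dtype)
    return(invisible(path))
  }
  if (!dir.exists(path) && !dir.create(path, recursive = TRUE))
    stop("cannot create output directory: ", path)
  width <- max(3L, nchar(as.character(nz - 1L)))
  files <- file.path(path, sprintf("slice_%0*d.tif", width, seq_len(nz) - 1L))
  for (i in seq_len(nz))
    write_tiff_pages(list(stack$data[, , i]), files[i], stack$dtype)
  invisible(files)
}

write_tiff_pages <- function(pages, path, dtype) {
  if (dtype == "uint16") {
    ok <- try(tiff::writeTIFF(lapply(pages, function(p) p / 65535), path,
                              bits.per.sample = 16L, compression = "none"),
              silent = TRUE)
    if (inherits(ok, "try-error"))
      stop("failed to write TIFF '", path, "': ", attr(ok, "condition")$message)
  } else {
    write_float32_tiff(pages, path)
  }
  invisible(path)
}

# Minimal multipage 32-bit float TIFF writer: little-endian, uncompressed,
# one strip per page, SampleFormat = 3 (IEEE float). Values are stored as
# float32, so doubles are quantised to float32 precision on write.
write_float32_tiff <- function(pages, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  n <- length(pages)
  npix <- vapply(pages, length, 1L)
  data_off <- 8 + c(0, cumsum(4 * as.numeric(npix)))[seq_len(n)]
  n_entries <- 11L
  ifd_size <- 2 + 12 * n_entries + 4
  ifd_off <- 8 + sum(4 * as.numeric(npix)) + (seq_len(n) - 1) * ifd_size
  writeBin(as.integer(ifd_off[1]), con, size = 4, endian = "little")
  for (p in pages)  # row-major pixel order
    writeBin(as.vector(t(p)), con, size = 4, endian = "little")
  entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == 3L) {  # SHORT padded to 4 bytes
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  for (i in seq_len(n)) {
    h <- nrow(pages[[i]]); w <- ncol(pages[[i]])
    writeBin(n_entries, con, size = 2, endian = "little")
    entry(256, 3, 1, w)              # ImageWidth
    entry(257, 3, 1, h)              # ImageLength
    entry(258, 3, 1, 32)             # BitsPerSample
    entry(259, 3, 1, 1)              # Compression = none
    entry(262, 3, 1, 1)              # Photometric = BlackIsZero
    entry(273, 4, 1, data_off[i])    # StripOffsets
    entry(277, 3, 1, 1)              # SamplesPerPixel
    entry(278, 3, 1, h)              # RowsPerStrip
    entry(279, 4, 1, 4 * h * w)      # StripByteCounts
    entry(284, 3, 1, 1)              # PlanarConfig = contiguous
    entry(339, 3, 1, 3)              # SampleFormat = IEEE float
    writeBin(as.integer(if (i < n) ifd_off[i + 1] else 0L), con,
             size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a raw binary volume with a plain-text sidecar
#'
#' Reads volumes stored as headerless binary (the direct 16-bit export path
#' of some reconstructions). Geometry and pixel type come from a sidecar
#' text file of `key: value` lines with required keys `nz`, `ny`, `nx`,
#' `dtype` (`uint16` or `float32`), `endianness` (`little` or `big`) and
#' `voxel_size_um`. The file size on disk must equal
#' `nz * ny * nx * bytes-per-voxel` exactly.
#'
#' @param path Path to the raw binary volume.
#' @param sidecar Path to the sidecar text file.
#' @return An [image_stack()] with `nz` slices of shape `ny x nx`.
#' @export
read_raw_volume <- function(path, sidecar) {
  if (!file.exists(path)) stop("raw volume not found: ", path)
  if (!file.exists(sidecar)) stop("sidecar not found: ", sidecar)
  sc <- read_sidecar(sidecar)
  for (k in c("nz", "ny", "nx", "dtype", "endianness", "voxel_size_um"))
    if (is.null(sc[[k]]))
      stop("sidecar ", sidecar, " is missing required key '", k, "'")
  nz <- as.integer(sc$nz); ny <- as.integer(sc$ny); nx <- as.integer(sc$nx)
  if (any(is.na(c(nz, ny, nx))) || nz < 1 || ny < 1 || nx < 1)
    stop("sidecar dims must be positive integers")
  dtype <- match.arg(sc$dtype, c("uint16", "float32"))
  endian <- match.arg(sc$endianness, c("little", "big"))
  bpv <- if (dtype == "uint16") 2L else 4L
  expected <- as.numeric(nz) * ny * nx * bpv
  actual <- file.info(path)$size
  if (actual != expected)
    stop("corrupt volume: ", path, " has ", actual, " bytes but sidecar ",
         "dims imply ", expected)
  con <- file(path, "rb")
  on.exit(close(con))
  nvox <- nz * ny * nx
  if (dtype == "uint16") {
    v <- readBin(con, "integer", n = nvox, size = 2, signed = FALSE,
                 endian = endian)
  } else {
    v <- readBin(con, "double", n = nvox, size = 4, endian = endian)
  }
  # raw volumes are stored x-fastest, then y, then z
  arr <- aperm(array(v, c(nx, ny, nz)), c(2, 1, 3))
  if (dtype == "uint16") storage.mode(arr) <- "integer"
  image_stack(arr, dtype = dtype,
              voxel_size_um = as.numeric(sc$voxel_size_um))
}

#' Write a raw binary volume with a plain-text sidecar
#'
#' Inverse of [read_raw_volume()]: round-trips are value-exact (float32
#' stacks are quantised to float32 precision, as on any 32-bit write path).
#'
#' @param stack An [image_stack()].
#' @param path Output path for the binary volume.
#' @param sidecar Output path for the sidecar; default `<path>.meta`.
#' @param endianness Byte order, `"little"` (default) or `"big"`.
#' @return Invisibly, `path`.
#' @export
write_raw_volume <- function(stack, path, sidecar = paste0(path, ".meta"),
                             endianness = c("little", "big")) {
  endianness <- match.arg(endianness)
  validate_image_stack(stack)
  dir_create_for(path)
  d <- dim(stack$data)
  con <- file(path, "wb")
  on.exit(close(con))
  v <- as.vector(aperm(stack$data, c(2, 1, 3)))  # x-fastest order
  if (stack$dtype == "uint16") {
    writeBin(as.integer(v), con, size = 2, endian = endianness)
  } else {
    writeBin(as.numeric(v), con, size = 4, endian = endianness)
  }
  writeLines(c(sprintf("nz: %d", d[3]), sprintf("ny: %d", d[1]),
               sprintf("nx: %d", d[2]), sprintf("dtype: %s", stack$dtype),
               sprintf("endianness: %s", endianness),
               sprintf("voxel_size_um: %.10g", stack$voxel_size_um)),
             sidecar)
  invisible(path)
}

read_sidecar <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) == 3L) out[[m[2]]] <- trimws(m[3])
  }
  out
}

# Natural numeric ordering of filenames: order primarily by the last integer
# run embedded in the name, so s1 < s2 < s10 regardless of zero padding;
# names without digits fall back to their lexicographic position.
natural_order <- function(names) {
  stripped <- tools::file_path_sans_ext(names)
  nums <- suppressWarnings(as.numeric(vapply(stripped, function(s) {
    m <- regmatches(s, gregexpr("[0-9]+", s))[[1]]
    if (length(m) == 0L) NA_character_ else m[length(m)]
  }, "")))
  order(is.na(nums), nums, stripped)
}

dir_create_for <- function(path) {
  d <- dirname(path)
  if (!dir.exists(d) && !dir.create(d, recursive = TRUE))
    stop("cannot create directory for output: ", d)
  invisible(d)
}
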