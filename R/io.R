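# Volume I/O: uncompressed MetaImage (.mha, LOCAL data) and NIfTI-1
# (.nii / .nii.gz). Both formats are written natively with writeBin since
# no pre-installed R package reads them; only the fields this pipeline
# needs are handled (3D scalar grids, spacing, datatype).
#
# Conventions: files store spacing in millimetres (the common convention
# for both formats); in-memory objects carry micrometres. Images are
# written as signed 16-bit HU, label maps as unsigned 16-bit, masks as
# unsigned 8-bit; reading restores the matching class via `as`.

#' Read / write volumetric images
#'
#' `write_volume()` writes a [voxel_image()] (int16), [label_map()]
#' (uint16), or [binary_mask()] (uint8) as MetaImage (`.mha`) or NIfTI-1
#' (`.nii`, `.nii.gz`) by file extension; `read_volume()` reads it back
#' losslessly (grid, spacing, integer values). Anisotropic spacing in a
#' header is accepted with a warning and carried through to volume
#' computations.
#'
#' @param obj volume object to write.
#' @param path file path; extension selects the format.
#' @param as on read: `"auto"` (from stored datatype: integer types become
#'   label maps, floats images), `"image"`, `"label_map"`, or `"mask"`.
#' @return `read_volume()` returns the volume object; `write_volume()`
#'   returns `path` invisibly.
#' @export
write_volume <- function(obj, path) {
  stopifnot(inherits(obj, c("voxel_image", "label_map", "binary_mask")))
  ext <- volume_format(path)
  if (inherits(obj, "voxel_image")) {
    vals <- round(obj$values)
    if (any(vals < -32768 | vals > 32767)) {
      stop("HU values out of int16 range")
    }
    type <- "int16"
  } else if (inherits(obj, "label_map")) {
    if (any(obj$values > 65535L)) stop("labels out of uint16 range")
    vals <- obj$values
    type <- "uint16"
  } else {
    vals <- obj$values + 0L
    type <- "uint8"
  }
  if (ext == "mha") {
    write_mha(vals, dim(obj$values), obj$spacing / 1000, type, path)
  } else {
    write_nifti(vals, dim(obj$values), obj$spacing / 1000, type, path,
                gz = grepl("\\.gz$", path))
  }
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path, as = c("auto", "image", "label_map", "mask")) {
  as <- match.arg(as)
  ext <- volume_format(path)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  parsed <- if (ext == "mha") read_mha(path) else read_nifti(path)
  spacing_um <- parsed$spacing_mm * 1000
  if (diff(range(spacing_um)) > 1e-9) {
    warning(sprintf("anisotropic spacing in %s: %s um", basename(path),
                    paste(signif(spacing_um, 6), collapse = " x ")))
  }
  vals <- array(parsed$data, parsed$dim)
  if (as == "auto") {
    as <- if (parsed$type %in% c("uint8", "uint16")) "label_map" else "image"
  }
  switch(as,
    image = voxel_image(vals, spacing_um),
    label_map = label_map(vals, spacing_um),
    mask = binary_mask(vals != 0, spacing_um))
}

volume_format <- function(path) {
  if (grepl("\\.mha$", path, ignore.case = TRUE)) return("mha")
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) return("nii")
  stop(sprintf("unsupported volume extension: %s (use .mha, .nii, .nii.gz)",
               basename(path)))
}

.vol_types <- data.frame(
  type = c("uint8", "int16", "uint16", "float32"),
  met = c("MET_UCHAR", "MET_SHORT", "MET_USHORT", "MET_FLOAT"),
  nifti = c(2L, 4L, 512L, 16L),
  size = c(1L, 2L, 2L, 4L),
  signed = c(FALSE, TRUE, FALSE, TRUE),
  stringsAsFactors = FALSE)

write_mha <- function(vals, dm, spacing_mm, type, path) {
  ti <- .vol_types[.vol_types$type == type, ]
  hdr <- paste0(
    "ObjectType = Image\n",
    "NDims = 3\n",
    "BinaryData = True\n",
    "BinaryDataByteOrderMSB = False\n",
    "CompressedData = False\n",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1\n",
    "Offset = 0 0 0\n",
    sprintf("ElementSpacing = %.9g %.9g %.9g\n",
            spacing_mm[1], spacing_mm[2], spacing_mm[3]),
    sprintf("DimSize = %d %d %d\n", dm[1], dm[2], dm[3]),
    sprintf("ElementType = %s\n", ti$met),
    "ElementDataFile = LOCAL\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(hdr, con, eos = NULL)
  write_pixels(con, vals, ti)
  invisible(path)
}

read_mha <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- read_bin_line(con)
    if (is.null(line)) stop(sprintf("corrupt MetaImage header: %s", path))
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop(sprintf("corrupt MetaImage header: %s", path))
    key <- trimws(kv[1])
    hdr[[key]] <- trimws(kv[2])
    if (key == "ElementDataFile") break
  }
  if (!identical(hdr$ElementDataFile, "LOCAL")) {
    stop(sprintf("only ElementDataFile = LOCAL supported: %s", path))
  }
  if (is.null(hdr$DimSize) || is.null(hdr$ElementType)) {
    stop(sprintf("corrupt MetaImage header (missing DimSize/ElementType): %s",
                 path))
  }
  dm <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  if (is.null(hdr$ElementSpacing)) {
    stop(sprintf("spacing missing in header: %s", path))
  }
  spacing_mm <- as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]])
  ti <- .vol_types[.vol_types$met == hdr$ElementType, ]
  if (nrow(ti) != 1L) {
    stop(sprintf("unsupported ElementType %s in %s", hdr$ElementType, path))
  }
  data <- read_pixels(con, prod(dm), ti, path)
  list(data = data, dim = dm, spacing_mm = spacing_mm, type = ti$type)
}

read_bin_line <- function(con) {
  out <- raw(0)
  repeat {
    ch <- readBin(con, "raw", 1L)
    if (length(ch) == 0L) return(NULL)
    if (ch == as.raw(10L)) break
    out <- c(out, ch)
    if (length(out) > 4096L) return(NULL)
  }
  rawToChar(out)
}

write_nifti <- function(vals, dm, spacing_mm, type, path, gz = FALSE) {
  ti <- .vol_types[.vol_types$type == type, ]
  con <- if (gz) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(348L, 4)                       # sizeof_hdr
  writeBin(raw(36L), con)           # unused
  wi(c(3L, dm, 1L, 1L, 1L, 1L), 2)  # dim[8]
  writeBin(raw(14L), con)           # intent params etc.
  wi(ti$nifti, 2)                   # datatype
  wi(8L * ti$size, 2)               # bitpix
  wi(0L, 2)                         # slice_start
  wf(c(1, spacing_mm, 0, 0, 0, 0))  # pixdim[8]
  wf(352)                           # vox_offset
  wf(c(1, 0))                       # scl_slope, scl_inter
  wi(0L, 2)                         # slice_end
  writeBin(raw(1L), con)            # slice_code
  writeBin(as.raw(10L), con)        # xyzt_units: mm | sec
  wf(c(0, 0, 0))                    # cal_max/min, slice_duration
  wf(0)                             # toffset
  wi(c(0L, 0L), 4)                  # glmax, glmin
  writeBin(raw(80L + 24L), con)     # descrip, aux_file
  wi(c(0L, 1L), 2)                  # qform_code, sform_code
  wf(rep(0, 6))                     # quatern b,c,d, qoffset x,y,z
  wf(c(spacing_mm[1], 0, 0, 0))     # srow_x
  wf(c(0, spacing_mm[2], 0, 0))     # srow_y
  wf(c(0, 0, spacing_mm[3], 0))     # srow_z
  writeBin(raw(16L), con)           # intent_name
  writeChar("n+1", con, nchars = 3, eos = NULL)
  writeBin(raw(1L), con)
  writeBin(raw(4L), con)            # extension flag
  write_pixels(con, vals, ti)
  invisible(path)
}

read_nifti <- function(path) {
  con <- gzfile(path, "rb")  # gzfile transparently reads plain files too
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348L)
  if (length(hdr) < 348L) stop(sprintf("corrupt NIfTI file: %s", path))
  ri <- function(off, size, n = 1L) {
    readBin(hdr[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = "little")
  }
  rf <- function(off, n = 1L) {
    readBin(hdr[(off + 1):(off + 4L * n)], "numeric", n = n, size = 4,
            endian = "little")
  }
  if (ri(0, 4) != 348L) stop(sprintf("corrupt NIfTI file: %s", path))
  dims <- ri(40, 2, 8L)
  if (dims[1] < 3L) stop(sprintf("expected a 3D NIfTI volume: %s", path))
  dm <- dims[2:4]
  datatype <- ri(70, 2)
  ti <- .vol_types[.vol_types$nifti == datatype, ]
  if (nrow(ti) != 1L) {
    stop(sprintf("unsupported NIfTI datatype %d in %s", datatype, path))
  }
  pixdim <- rf(76, 8L)
  spacing_mm <- pixdim[2:4]
  if (any(spacing_mm <= 0)) stop(sprintf("spacing missing in header: %s",
                                         path))
  vox_offset <- rf(108)
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0L) readBin(con, "raw", skip)
  data <- read_pixels(con, prod(dm), ti, path)
  list(data = data, dim = dm, spacing_mm = spacing_mm, type = ti$type)
}

write_pixels <- function(con, vals, ti) {
  v <- if (ti$type == "float32") as.numeric(vals) else as.integer(round(vals))
  if (!ti$signed && ti$size == 2L) {
    v <- ifelse(v > 32767L, v - 65536L, v)  # store uint16 via int16 bits
  }
  if (ti$type == "float32") {
    writeBin(v, con, size = 4L, endian = "little")
  } else {
    writeBin(v, con, size = ti$size, endian = "little")
  }
}

read_pixels <- function(con, n, ti, path) {
  if (ti$type == "float32") {
    out <- readBin(con, "numeric", n = n, size = 4L, endian = "little")
  } else {
    out <- readBin(con, "integer", n = n, size = ti$size,
                   signed = ti$signed || ti$size > 2L, endian = "little")
    if (!ti$signed && ti$size == 2L) {
      out <- ifelse(out < 0L, out + 65536L, out)
    }
  }
  if (length(out) != n) stop(sprintf("truncated volume data: %s", path))
  out
}
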