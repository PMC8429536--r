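#' CT volume container
#'
#' A minimal container for a 3-D grid of Hounsfield units with physical voxel
#' spacing. Axis convention: `i`/`j` are the in-plane (x/y) axes, `k` is the
#' cranio-caudal axis, so an axial slice is `values[, , k]`. Spacing is in
#' millimetres per axis; with the clinical reconstructions this package
#' targets the z component is the slice increment (e.g. 0.7 mm), which is
#' what defines the grid geometry.
#'
#' @param values Numeric 3-D array of HU values (finite).
#' @param spacing Numeric length-3 vector of voxel sizes in mm, all positive.
#' @return An object of class `ct_volume` with elements `values`, `spacing`
#'   and an `axes` tag.
#' @export
ct_volume <- function(values, spacing) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    abort("`values` must be a 3-D array.", class = "voinoise_invalid_parameter")
  }
  if (any(dim(values) < 1L)) {
    abort("Each axis must have at least one voxel.",
          class = "voinoise_invalid_parameter")
  }
  if (!all(is.finite(values))) {
    abort("HU values must all be finite.", class = "voinoise_invalid_parameter")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0)) {
    abort("`spacing` must be three positive voxel sizes in mm.",
          class = "voinoise_invalid_spacing")
  }
  structure(list(values = values, spacing = spacing, axes = "ijk=xyz, k cranial+"),
            class = "ct_volume")
}

#' @export
dim.ct_volume <- function(x) dim(x$values)

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<ct_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  HU range [%.1f, %.1f]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' Convert stored integer values to Hounsfield units
#'
#' Applies the linear calibration `HU = slope * stored + intercept` used by
#' CT exports (e.g. DICOM RescaleSlope/RescaleIntercept).
#'
#' @param stored Numeric stored values.
#' @param slope,intercept Calibration coefficients.
#' @return Numeric HU values.
#' @examples
#' rescale_to_hu(24, slope = 1, intercept = -1024)  # -1000 HU
#' @export
rescale_to_hu <- function(stored, slope = 1, intercept = 0) {
  slope * stored + intercept
}

#' Read a CT volume from disk
#'
#' Supports NIfTI (`.nii`, `.nii.gz`) and MetaImage (`.mhd`, `.mha`). Voxel
#' spacing is always taken from the file header; a missing or non-positive
#' spacing is a hard error, never silently defaulted.
#'
#' @param path Path to a NIfTI or MetaImage file.
#' @return A [ct_volume()].
#' @export
read_ct_volume <- function(path) {
  if (dir.exists(path)) {
    abort(paste0("Directory input (DICOM series) is not supported; convert ",
                 "the series to NIfTI or MetaImage first (HU calibration via ",
                 "rescale_to_hu() if needed)."),
          class = "voinoise_unsupported_format")
  }
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "voinoise_io_error")
  }
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) {
    img <- RNifti::readNifti(path)
    vals <- as.array(img)
    if (length(dim(vals)) == 4L && dim(vals)[4] == 1L) {
      vals <- array(vals, dim(vals)[1:3])
    }
    if (length(dim(vals)) != 3L) {
      abort("Expected a 3-D NIfTI volume.", class = "voinoise_io_error")
    }
    sp <- RNifti::pixdim(img)[1:3]
    if (length(sp) != 3L || !all(is.finite(sp)) || any(sp <= 0)) {
      abort("NIfTI header has missing or non-positive voxel spacing.",
            class = "voinoise_invalid_spacing")
    }
    return(ct_volume(vals, sp))
  }
  if (grepl("\\.(mhd|mha)$", lp)) {
    return(read_metaimage(path))
  }
  abort(sprintf("Unrecognised volume format: %s", path),
        class = "voinoise_unsupported_format")
}

#' Write a CT volume to disk
#'
#' @param volume A [ct_volume()].
#' @param path Output path; format chosen by extension (`.nii`/`.nii.gz` or
#'   `.mhd`/`.mha`).
#' @return `path`, invisibly.
#' @export
write_ct_volume <- function(volume, path) {
  stopifnot(inherits(volume, "ct_volume"))
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) {
    img <- RNifti::asNifti(volume$values)
    RNifti::pixdim(img) <- volume$spacing
    RNifti::writeNifti(img, path)
  } else if (grepl("\\.(mhd|mha)$", lp)) {
    write_metaimage(volume, path)
  } else {
    abort(sprintf("Unrecognised output format: %s", path),
          class = "voinoise_unsupported_format")
  }
  invisible(path)
}

# --- MetaImage (ITK .mhd/.mha) ------------------------------------------
# Plain-text key = value header; raw voxel block either appended (.mha,
# ElementDataFile = LOCAL) or in a sibling file (.mhd).

.met_types <- list(
  MET_CHAR   = list(what = "integer", size = 1L, signed = TRUE),
  MET_UCHAR  = list(what = "integer", size = 1L, signed = FALSE),
  MET_SHORT  = list(what = "integer", size = 2L, signed = TRUE),
  MET_USHORT = list(what = "integer", size = 2L, signed = FALSE),
  MET_INT    = list(what = "integer", size = 4L, signed = TRUE),
  MET_UINT   = list(what = "integer", size = 4L, signed = FALSE),
  MET_FLOAT  = list(what = "double",  size = 4L, signed = TRUE),
  MET_DOUBLE = list(what = "double",  size = 8L, signed = TRUE)
)

read_metaimage <- function(path) {
  raw_all <- readBin(path, "raw", n = file.size(path))
  # decode header line by line (raw data follows the ElementDataFile line
  # and must never be passed through character conversion)
  newlines <- which(raw_all == as.raw(10L))
  hdr_lines <- character()
  header_end <- NA_integer_
  pos <- 1L
  for (e in newlines) {
    line <- tryCatch(rawToChar(raw_all[seq.int(pos, e - 1L)]),
                     error = function(err) NULL)
    if (is.null(line)) break
    hdr_lines <- c(hdr_lines, sub("\r$", "", line))
    pos <- e + 1L
    if (grepl("^\\s*ElementDataFile", line)) {
      header_end <- e
      break
    }
  }
  if (is.na(header_end)) {
    abort("MetaImage header has no ElementDataFile entry.",
          class = "voinoise_io_error")
  }
  kv <- list()
  for (ln in hdr_lines) {
    p <- regmatches(ln, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*?)\\s*$", ln))[[1]]
    if (length(p) == 3L) kv[[p[2]]] <- p[3]
  }
  if (!is.null(kv$CompressedData) && toupper(kv$CompressedData) == "TRUE") {
    abort("Compressed MetaImage data is not supported.",
          class = "voinoise_unsupported_format")
  }
  if (!identical(kv$NDims, "3")) {
    abort("MetaImage must be 3-D.", class = "voinoise_io_error")
  }
  d <- as.integer(strsplit(kv$DimSize, "\\s+")[[1]])
  sp_str <- kv$ElementSpacing %||% kv$ElementSize
  if (is.null(sp_str)) {
    abort("MetaImage header has no ElementSpacing; refusing to default.",
          class = "voinoise_invalid_spacing")
  }
  sp <- as.numeric(strsplit(sp_str, "\\s+")[[1]])
  tp <- .met_types[[kv$ElementType %||% ""]]
  if (is.null(tp)) {
    abort(sprintf("Unsupported MetaImage ElementType: %s", kv$ElementType),
          class = "voinoise_unsupported_format")
  }
  msb <- toupper(kv$BinaryDataByteOrderMSB %||% kv$ElementByteOrderMSB %||% "FALSE")
  endian <- if (msb == "TRUE") "big" else "little"
  n <- prod(d)
  datafile <- kv$ElementDataFile
  if (identical(toupper(datafile), "LOCAL")) {
    data_raw <- raw_all[(header_end + 1L):length(raw_all)]
  } else {
    dpath <- file.path(dirname(path), datafile)
    if (!file.exists(dpath)) {
      abort(sprintf("MetaImage data file not found: %s", dpath),
            class = "voinoise_io_error")
    }
    data_raw <- readBin(dpath, "raw", n = file.size(dpath))
  }
  if (length(data_raw) < n * tp$size) {
    abort("MetaImage data block shorter than DimSize implies.",
          class = "voinoise_io_error")
  }
  vals <- readBin(data_raw, tp$what, n = n, size = tp$size,
                  signed = tp$signed, endian = endian)
  ct_volume(array(as.numeric(vals), dim = d), sp)
}

write_metaimage <- function(volume, path) {
  d <- dim(volume$values)
  local <- grepl("\\.mha$", tolower(path))
  datafile <- if (local) "LOCAL" else paste0(sub("\\.mhd$", "", basename(path),
                                                ignore.case = TRUE), ".raw")
  hdr <- paste0(
    "ObjectType = Image\n",
    "NDims = 3\n",
    "BinaryData = True\n",
    "BinaryDataByteOrderMSB = False\n",
    "CompressedData = False\n",
    sprintf("DimSize = %d %d %d\n", d[1], d[2], d[3]),
    sprintf("ElementSpacing = %.10g %.10g %.10g\n",
            volume$spacing[1], volume$spacing[2], volume$spacing[3]),
    "ElementType = MET_DOUBLE\n",
    sprintf("ElementDataFile = %s\n", datafile)
  )
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(charToRaw(hdr), con)
  if (local) {
    writeBin(as.vector(volume$values), con, size = 8L, endian = "little")
  } else {
    rawcon <- file(file.path(dirname(path), datafile), "wb")
    on.exit(close(rawcon), add = TRUE)
    writeBin(as.vector(volume$values), rawcon, size = 8L, endian = "little")
  }
  invisible(path)
}
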