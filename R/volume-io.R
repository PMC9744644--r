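#' OCT volume container
#'
#' A 3-D reflectivity array with explicit physical voxel spacing. The array is
#' indexed `[x, y, z]` where `x` is the fast transverse axis, `y` the slow
#' (B-scan) axis, and `z` depth, increasing from the vitreous (ILM side)
#' towards the choroid (RPE side). Indices are 1-based throughout the package;
#' depth maps refer to this same 1-based voxel grid. Intensities are stored as
#' doubles; integer input (8/16-bit vendor exports) is promoted to `[0, 1]` by
#' dividing by the dtype maximum.
#'
#' The default spacing corresponds to a 6 mm x 6 mm x 2 mm macular cube
#' sampled at 512 x 128 x 1024 voxels: (11.72, 46.88, 1.953) um.
#'
#' @param data numeric 3-D array, indexed `[x, y, z]`.
#' @param spacing_um numeric length-3, per-axis voxel size in micrometres.
#' @param meta free-form named list of acquisition tags.
#' @return An object of class `oct_volume`.
#' @export
oct_volume <- function(data, spacing_um = c(6000 / 512, 6000 / 128, 2000 / 1024),
                       meta = list()) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (is.integer(data) || max(data, na.rm = TRUE) > 1 + 1e-9) {
    mx <- if (is.integer(data)) {
      if (max(data) > 255) 65535 else 255
    } else max(data)
    data <- data / mx
  }
  storage.mode(data) <- "double"
  if (!all(is.finite(data))) stop("volume contains non-finite voxels", call. = FALSE)
  spacing_um <- as.numeric(spacing_um)
  if (length(spacing_um) != 3 || any(spacing_um <= 0))
    stop("spacing_um must be 3 positive values", call. = FALSE)
  structure(list(data = data, spacing_um = spacing_um, origin = c(0, 0), meta = meta),
            class = "oct_volume")
}

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<oct_volume> %d x %d x %d voxels, spacing (%.2f, %.2f, %.3f) um\n",
              d[1], d[2], d[3], x$spacing_um[1], x$spacing_um[2], x$spacing_um[3]))
  invisible(x)
}

#' @export
dim.oct_volume <- function(x) dim(x$data)

#' En-face image container
#'
#' A 2-D scalar image on the `(x, y)` transverse grid of a source volume,
#' produced by depth projection between two retinal surfaces.
#'
#' @param data numeric matrix indexed `[x, y]`.
#' @param spacing_um length-2 pixel size in micrometres.
#' @param provenance named list (projection band, reducer, source id, ...).
#' @return An object of class `enface_image`.
#' @export
enface_image <- function(data, spacing_um, provenance = list()) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!all(is.finite(data))) stop("en-face image contains non-finite pixels", call. = FALSE)
  structure(list(data = data, spacing_um = as.numeric(spacing_um), provenance = provenance),
            class = "enface_image")
}

#' @export
print.enface_image <- function(x, ...) {
  cat(sprintf("<enface_image> %d x %d px, spacing (%.2f, %.2f) um\n",
              nrow(x$data), ncol(x$data), x$spacing_um[1], x$spacing_um[2]))
  invisible(x)
}

#' Binary vessel mask
#'
#' Strictly binary en-face mask of vessel pixels, with the threshold and
#' parameters that produced it kept as provenance.
#'
#' @param data logical matrix (or coercible 0/1 matrix).
#' @param provenance named list; typically `threshold` and upstream params.
#' @return An object of class `vessel_mask`.
#' @export
vessel_mask <- function(data, provenance = list()) {
  data <- as.matrix(data)
  if (is.numeric(data)) {
    if (!all(data %in% c(0, 1))) stop("mask must be strictly binary", call. = FALSE)
    data <- data > 0.5
  }
  stopifnot(is.logical(data))
  structure(list(data = data, provenance = provenance), class = "vessel_mask")
}

# ---- volume file I/O --------------------------------------------------------

#' Read and write OCT volumes
#'
#' Format is inferred from the extension: `.nrrd` (raw little-endian NRRD,
#' lossless), `.nii`/`.nii.gz` (NIfTI via RNifti, lossless), or `.tif`/`.tiff`
#' (multi-page TIFF, one page per depth slice, stored as 32-bit unsigned
#' samples of the `[0, 1]` range, so round-trips are exact only to 2^-32).
#' Spacing metadata round-trips to at least 6 significant figures in all
#' formats; for TIFF it is carried in a JSON description tag.
#'
#' @param path file path with one of the recognised extensions.
#' @param volume an [oct_volume()].
#' @return `read_volume()` returns an [oct_volume()]; `write_volume()` returns
#'   `path` invisibly.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  ext <- volume_ext(path)
  switch(ext,
    nrrd = read_nrrd_volume(path),
    nii = {
      img <- RNifti::readNifti(path)
      oct_volume(array(as.numeric(img), dim = dim(img)),
                 spacing_um = RNifti::pixdim(img) * 1000)
    },
    tif = {
      pages <- tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE),
                        error = function(e) stop(sprintf(
                          "cannot read TIFF '%s': %s", path, conditionMessage(e)), call. = FALSE))
      meta <- tiff_meta(pages[[1]])
      arr <- array(0, c(dim(pages[[1]])[1], dim(pages[[1]])[2], length(pages)))
      for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
      oct_volume(arr, spacing_um = meta$spacing_um %||% c(6000 / 512, 6000 / 128, 2000 / 1024))
    },
    stop(sprintf("unknown volume extension for '%s'", path), call. = FALSE)
  )
}

#' @rdname read_volume
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "oct_volume"))
  ext <- volume_ext(path)
  switch(ext,
    nrrd = write_nrrd_volume(volume, path),
    nii = {
      img <- RNifti::asNifti(volume$data)
      RNifti::pixdim(img) <- volume$spacing_um / 1000
      RNifti::writeNifti(img, path)
    },
    tif = {
      d <- volume$data
      if (min(d) < 0 || max(d) > 1) stop("TIFF export requires data in [0, 1]", call. = FALSE)
      desc <- jsonlite::toJSON(list(spacing_um = volume$spacing_um), auto_unbox = TRUE, digits = NA)
      pages <- lapply(seq_len(dim(d)[3]), function(k) d[, , k])
      attr(pages[[1]], "description") <- as.character(desc)
      tiff::writeTIFF(pages, path, bits.per.sample = 32L)
    },
    stop(sprintf("unknown volume extension for '%s'", path), call. = FALSE)
  )
  invisible(path)
}

volume_ext <- function(path) {
  p <- tolower(path)
  if (grepl("\\.nrrd$", p)) "nrrd"
  else if (grepl("\\.nii(\\.gz)?$", p)) "nii"
  else if (grepl("\\.tiff?$", p)) "tif"
  else "unknown"
}

tiff_meta <- function(page) {
  desc <- attr(page, "description")
  if (is.null(desc)) return(list())
  tryCatch(jsonlite::fromJSON(desc), error = function(e) list())
}

# Minimal NRRD0004 reader/writer: attached header, raw little-endian doubles.
# No NRRD package exists in the R stack used here; the format is a plain text
# header followed by raw sample data, which is all the pipeline needs for a
# lossless native format.
read_nrrd_volume <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!grepl("^NRRD", magic)) stop(sprintf("'%s' is not an NRRD file", path), call. = FALSE)
  fields <- list()
  repeat {
    ln <- readLines(con, n = 1)
    if (length(ln) == 0) stop(sprintf("truncated NRRD header in '%s'", path), call. = FALSE)
    if (ln == "") break
    if (grepl("^#", ln)) next
    kv <- strsplit(ln, ": ", fixed = TRUE)[[1]]
    fields[[tolower(kv[1])]] <- kv[2]
  }
  sizes <- as.integer(strsplit(fields[["sizes"]], " ")[[1]])
  if (length(sizes) != 3) stop(sprintf("'%s': expected a 3-D NRRD", path), call. = FALSE)
  if (!identical(fields[["type"]], "double"))
    stop(sprintf("'%s': unsupported NRRD type '%s'", path, fields[["type"]]), call. = FALSE)
  n <- prod(sizes)
  raw_vals <- readBin(con, "double", n = n, size = 8, endian = "little")
  if (length(raw_vals) < n) stop(sprintf("truncated NRRD data in '%s'", path), call. = FALSE)
  spacing <- c(6000 / 512, 6000 / 128, 2000 / 1024)
  if (!is.null(fields[["spacings"]]))
    spacing <- as.numeric(strsplit(fields[["spacings"]], " ")[[1]]) * 1000
  oct_volume(array(raw_vals, dim = sizes), spacing_um = spacing)
}

write_nrrd_volume <- function(volume, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c(
    "NRRD0004",
    "type: double",
    "dimension: 3",
    sprintf("sizes: %s", paste(dim(volume$data), collapse = " ")),
    sprintf("spacings: %s", paste(format(volume$spacing_um / 1000, digits = 10), collapse = " ")),
    "endian: little",
    "encoding: raw",
    ""
  )
  writeLines(hdr, con)
  writeBin(as.numeric(volume$data), con, size = 8, endian = "little")
  invisible(path)
}

# ---- 2-D image / mask I/O ---------------------------------------------------

#' Write an en-face image or mask as PNG
#'
#' Images are rescaled to `[0, 1]` for display; masks are written as 0/1.
#'
#' @param x an [enface_image()] or [vessel_mask()].
#' @param path output `.png` path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(x, path) {
  m <- if (inherits(x, "vessel_mask")) x$data * 1 else {
    d <- x$data
    rng <- range(d)
    if (diff(rng) > 0) (d - rng[1]) / diff(rng) else d * 0
  }
  # png() expects row-major display orientation: transpose (x, y) -> (row, col)
  png::writePNG(t(m), path)
  invisible(path)
}

# ---- tabular I/O ------------------------------------------------------------

physio_schema <- c(
  subject = "character", day = "character", variable = "character", value = "numeric"
)

#' Read and write physiology tables
#'
#' Long-format physiology tables have mandatory columns `subject`, `day`,
#' `variable`, `value`. Missing cells are preserved as `NA` (the study design
#' allows missing arterial draws). Extra columns are kept with a warning.
#'
#' @param path CSV path.
#' @param results a data frame to write.
#' @return `read_table()` returns a tibble; `write_results()` returns `path`
#'   invisibly. `write_results_json()` serializes any list or tibble to JSON.
#' @export
read_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(names(physio_schema), names(tbl))
  if (length(missing_cols) > 0)
    stop(sprintf("physiology table is missing mandatory column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  extra <- setdiff(names(tbl), names(physio_schema))
  if (length(extra) > 0)
    warning(sprintf("extra column(s) preserved: %s", paste(extra, collapse = ", ")), call. = FALSE)
  tbl$subject <- as.character(tbl$subject)
  tbl$day <- as.character(tbl$day)
  tbl$variable <- as.character(tbl$variable)
  tbl$value <- as.numeric(tbl$value)
  tibble::as_tibble(tbl)
}

#' @rdname read_table
#' @export
write_results <- function(results, path) {
  readr::write_csv(results, path, na = "")
  invisible(path)
}

#' @rdname read_table
#' @export
write_results_json <- function(results, path) {
  jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(path)
}
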