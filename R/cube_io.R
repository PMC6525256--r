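#' Read a multispectral cube from disk
#'
#' Two container formats are supported:
#' \describe{
#'   \item{`tiff_stack`}{multi-page TIFF, one page per band, written by
#'     [write_cube()]. A JSON sidecar (`<path>.json`) carries wavelengths,
#'     the intensity scaling, the processing history and (if any pixel is
#'     invalid) marks the final page as the validity mask. Integer data
#'     round-trip bit-exactly (16-bit storage); float data are stored as
#'     scaled 32-bit float pages.}
#'   \item{`array_container`}{R serialization of a
#'     `list(data, wavelengths_nm, valid_mask, meta)`; exact for any
#'     numeric type.}
#' }
#' A plain multi-page TIFF without sidecar is also readable: intensities are
#' taken as stored and wavelengths default to the 400-650 nm grid.
#'
#' @param path file path
#' @param format `"auto"` (by extension: `.rds` = array container, otherwise
#'   TIFF), `"tiff_stack"` or `"array_container"`
#' @return a [spectral_cube()]
#' @export
read_cube <- function(path, format = c("auto", "tiff_stack", "array_container")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort_io("cannot read cube: no such file '%s'", path)
  if (format == "auto")
    format <- if (grepl("\\.rds$", path, ignore.case = TRUE))
      "array_container" else "tiff_stack"

  if (format == "array_container") {
    obj <- tryCatch(readRDS(path),
                    error = function(e) abort_io("unreadable array container '%s': %s",
                                                 path, conditionMessage(e)))
    if (!all(c("data", "wavelengths_nm") %in% names(obj)))
      abort_format("array container '%s' lacks data/wavelengths_nm keys", path)
    return(spectral_cube(obj$data, obj$wavelengths_nm, obj$valid_mask,
                         obj$meta %||% list()))
  }

  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, info = FALSE),
                    error = function(e) abort_io("unreadable TIFF '%s': %s",
                                                 path, conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3L) p[, , 1L] else p)
  dims <- vapply(pages, dim, integer(2L))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L]))
    abort_format("TIFF '%s': page sizes differ across bands", path)

  side <- read_sidecar(path)
  valid_mask <- NULL
  if (isTRUE(side$mask_page)) {
    valid_mask <- pages[[length(pages)]] > 0.5
    pages <- pages[-length(pages)]
  }
  if (length(pages) < 2L)
    abort_format("'%s' has %d band(s); a cube needs at least 2", path,
                 length(pages))
  arr <- array(unlist(pages, use.names = FALSE),
               dim = c(dim(pages[[1L]]), length(pages)))
  scale <- side$scale %||% 1
  offset <- side$offset %||% 0
  arr <- arr * scale + offset
  if (isTRUE(side$integer)) {
    arr <- round(arr)
    if (identical(side$storage, "integer")) storage.mode(arr) <- "integer"
  }
  spectral_cube(arr,
                wavelengths_nm = side$wavelengths_nm,
                valid_mask = valid_mask,
                meta = side$meta %||% list())
}

#' Write a multispectral cube to disk
#'
#' See [read_cube()] for the container formats. `read_cube(write_cube(c))`
#' returns `c` bit-exactly for integer-valued cubes and within 32-bit float
#' representation precision otherwise.
#'
#' @param cube a [spectral_cube()]
#' @param path destination file path; a JSON sidecar `<path>.json` is written
#'   alongside TIFF output
#' @param format `"auto"`, `"tiff_stack"` or `"array_container"`
#' @return `path`, invisibly
#' @export
write_cube <- function(cube, path, format = c("auto", "tiff_stack", "array_container")) {
  format <- match.arg(format)
  if (!dir.exists(dirname(path)))
    abort_io("cannot write cube: directory '%s' does not exist", dirname(path))
  if (format == "auto")
    format <- if (grepl("\\.rds$", path, ignore.case = TRUE))
      "array_container" else "tiff_stack"

  if (format == "array_container") {
    saveRDS(list(data = cube$data, wavelengths_nm = cube$wavelengths_nm,
                 valid_mask = cube$valid_mask, meta = cube$meta), path)
    return(invisible(path))
  }

  x <- cube$data
  is_int <- all(x == round(x)) && min(x) >= 0 && max(x) <= 65535
  if (is_int) {
    scale <- 65535
    offset <- 0
    pages01 <- lapply(seq_len(dim(x)[3L]), function(k) x[, , k] / 65535)
    bits <- 16L
  } else {
    offset <- min(x)
    scale <- max(x) - offset
    if (scale == 0) scale <- 1
    pages01 <- lapply(seq_len(dim(x)[3L]),
                      function(k) (x[, , k] - offset) / scale)
    bits <- 32L
  }
  mask_page <- !all(cube$valid_mask)
  if (mask_page) pages01 <- c(pages01, list(cube$valid_mask * 1))
  ok <- tryCatch(tiff::writeTIFF(pages01, path, bits.per.sample = bits),
                 error = function(e) abort_io("cannot write TIFF '%s': %s",
                                              path, conditionMessage(e)))
  # large numeric payloads (e.g. a phantom's noise-free composite) stay out
  # of the JSON sidecar; only compact provenance is serialized
  meta <- Filter(function(v) length(unlist(v, use.names = FALSE)) <= 256L,
                 cube$meta)
  side <- list(wavelengths_nm = cube$wavelengths_nm,
               integer = is_int, storage = storage.mode(cube$data),
               scale = scale, offset = offset,
               mask_page = mask_page, meta = meta)
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".json")

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) return(list())
  side <- jsonlite::read_json(sp, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
  side$wavelengths_nm <- as.numeric(side$wavelengths_nm)
  side
}

#' Read / write a label mask image
#'
#' Masks are single-page 8-bit PNG (or TIFF) images with pixel values
#' 0 = healthy, 255 = carcinoma, 128 = ignore.
#'
#' @param path image file path
#' @param patient_id,image_id identifiers attached to the mask
#' @return a [label_mask()]
#' @export
read_mask <- function(path, patient_id = "", image_id = "") {
  if (!file.exists(path)) abort_io("cannot read mask: no such file '%s'", path)
  img <- if (grepl("\\.png$", path, ignore.case = TRUE))
    png::readPNG(path) else tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  v <- round(img * 255)
  labels <- matrix(NA_integer_, nrow(v), ncol(v))
  labels[v <= 64] <- 0L
  labels[v >= 192] <- 1L
  label_mask(labels, patient_id, image_id)
}

#' @rdname read_mask
#' @param mask a [label_mask()]
#' @export
write_mask <- function(mask, path) {
  if (!dir.exists(dirname(path)))
    abort_io("cannot write mask: directory '%s' does not exist", dirname(path))
  v <- mask$labels
  img <- matrix(128 / 255, nrow(v), ncol(v))
  img[!is.na(v) & v == 0L] <- 0
  img[!is.na(v) & v == 1L] <- 1
  png::writePNG(img, path)
  invisible(path)
}

#' Read a dataset manifest
#'
#' A manifest is a CSV with header `cube,mask,patient_id,image_id`; paths are
#' resolved relative to the manifest's directory unless absolute. Referenced
#' files are checked for existence.
#'
#' @param path CSV file path
#' @param check_files verify that every referenced cube/mask exists
#' @return a `dataset_manifest`: data frame of entries with attribute
#'   `n_patients`
#' @export
read_manifest <- function(path, check_files = TRUE) {
  if (!file.exists(path)) abort_io("no such manifest '%s'", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cube", "mask", "patient_id", "image_id")
  if (!all(need %in% names(df)))
    abort_format("manifest '%s' must have columns %s", path,
                 paste(need, collapse = ", "))
  if (any(!nzchar(df$patient_id)))
    abort_data("manifest '%s': empty patient_id in row(s) %s", path,
               paste(which(!nzchar(df$patient_id)), collapse = ", "))
  base <- dirname(path)
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  df$cube <- resolve(df$cube)
  df$mask <- resolve(df$mask)
  if (check_files) {
    bad <- which(!file.exists(df$cube) | !file.exists(df$mask))
    if (length(bad))
      abort_data("manifest '%s': missing files referenced in row(s) %s", path,
                 paste(bad, collapse = ", "))
  }
  structure(df, class = c("dataset_manifest", "data.frame"),
            n_patients = length(unique(df$patient_id)))
}

#' @export
print.dataset_manifest <- function(x, ...) {
  cat(sprintf("dataset_manifest: %d entries, %d patients\n",
              nrow(x), attr(x, "n_patients")))
  NextMethod()
}
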