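#' Read a hyperspectral cube from an ENVI header + binary pair
#'
#' Supports BSQ and BIL interleaves, little- and big-endian byte order, and
#' ENVI data types 1 (uint8), 2 (int16), 3 (int32), 4 (float32), 5 (float64)
#' and 12 (uint16). The header must declare `samples`, `lines`, `bands`,
#' `interleave`, `data type` and a `wavelength` list; the cube kind is
#' recovered from the `cube kind` header entry when present.
#'
#' @param header_path Path to the `.hdr` text header. The binary file is the
#'   same path without the `.hdr` extension (or with `.img` / `.dat`
#'   appended, whichever exists).
#' @return A [hyper_cube()].
#' @seealso [write_envi()]
#' @export
read_envi <- function(header_path) {
  if (!file.exists(header_path)) {
    stop(sprintf("ENVI header not found: %s", header_path), call. = FALSE)
  }
  hdr <- parse_envi_header(header_path)
  for (key in c("samples", "lines", "bands", "interleave", "data type")) {
    if (is.null(hdr[[key]])) {
      stop(sprintf("ENVI header is missing required key '%s'", key), call. = FALSE)
    }
  }
  if (is.null(hdr[["wavelength"]])) {
    stop("ENVI header is missing the 'wavelength' list", call. = FALSE)
  }
  samples <- as.integer(hdr[["samples"]])
  lines <- as.integer(hdr[["lines"]])
  bands <- as.integer(hdr[["bands"]])
  wavelengths <- as.numeric(strsplit(hdr[["wavelength"]], ",")[[1]])
  if (length(wavelengths) != bands) {
    stop(sprintf("header declares %d bands but %d wavelengths",
                 bands, length(wavelengths)), call. = FALSE)
  }
  interleave <- tolower(hdr[["interleave"]])
  if (!interleave %in% c("bsq", "bil")) {
    stop(sprintf("unsupported ENVI interleave '%s' (supported: bsq, bil)",
                 interleave), call. = FALSE)
  }
  dtype <- as.integer(hdr[["data type"]])
  spec <- envi_dtype_spec(dtype)
  endian <- if (!is.null(hdr[["byte order"]]) && as.integer(hdr[["byte order"]]) == 1)
    "big" else "little"

  bin_path <- envi_binary_path(header_path)
  n <- samples * lines * bands
  con <- file(bin_path, "rb")
  on.exit(close(con))
  v <- readBin(con, what = spec$what, n = n, size = spec$size,
               signed = spec$signed, endian = endian)
  if (length(v) != n) {
    stop(sprintf("ENVI binary %s holds %d values, expected %d",
                 bin_path, length(v), n), call. = FALSE)
  }
  values <- switch(interleave,
    # BSQ: sample fastest, then line, then band
    bsq = aperm(array(v, dim = c(samples, lines, bands)), c(2, 1, 3)),
    # BIL: sample fastest, then band, then line
    bil = aperm(array(v, dim = c(samples, bands, lines)), c(3, 1, 2))
  )
  kind <- hdr[["cube kind"]] %||% "raw"
  if (!kind %in% c("raw", "reflectance", "normalized")) kind <- "raw"
  hyper_cube(values, wavelengths, kind = kind)
}

#' Write a hyperspectral cube as ENVI header + BSQ binary
#'
#' Emits a text `.hdr` (with the wavelength list and the cube kind recorded)
#' and a flat little-endian float64 BSQ binary, so the round trip through
#' [read_envi()] is lossless.
#'
#' @param cube A [hyper_cube()].
#' @param path Output path without extension; `<path>.hdr` and `<path>` are
#'   written.
#' @return Invisibly, the header path.
#' @export
write_envi <- function(cube, path) {
  stopifnot(inherits(cube, "hyper_cube"))
  d <- dim(cube$values)
  hdr_path <- paste0(path, ".hdr")
  hdr <- c(
    "ENVI",
    "description = { hsoximetry hyperspectral cube }",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 5",
    "interleave = bsq",
    "byte order = 0",
    "wavelength units = Nanometers",
    sprintf("cube kind = %s", cube$kind),
    sprintf("wavelength = { %s }",
            paste(format(cube$wavelengths, trim = TRUE, digits = 15),
                  collapse = ", "))
  )
  writeLines(hdr, hdr_path)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(aperm(cube$values, c(2, 1, 3))), con,
           size = 8, endian = "little")
  invisible(hdr_path)
}

# key = value parser tolerant of { multi-line } lists
parse_envi_header <- function(header_path) {
  lines <- readLines(header_path, warn = FALSE)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    line <- lines[i]
    if (!grepl("=", line, fixed = TRUE)) { i <- i + 1L; next }
    key <- tolower(trimws(sub("=.*$", "", line)))
    val <- trimws(sub("^[^=]*=", "", line))
    if (startsWith(val, "{")) {
      while (!grepl("\\}", val) && i < length(lines)) {
        i <- i + 1L
        val <- paste(val, trimws(lines[i]))
      }
      val <- trimws(gsub("[{}]", "", val))
    }
    out[[key]] <- val
    i <- i + 1L
  }
  out
}

envi_dtype_spec <- function(dtype) {
  switch(as.character(dtype),
    "1" = list(what = "integer", size = 1, signed = FALSE),
    "2" = list(what = "integer", size = 2, signed = TRUE),
    "3" = list(what = "integer", size = 4, signed = TRUE),
    "4" = list(what = "numeric", size = 4, signed = TRUE),
    "5" = list(what = "numeric", size = 8, signed = TRUE),
    "12" = list(what = "integer", size = 2, signed = FALSE),
    stop(sprintf("unsupported ENVI data type %s", dtype), call. = FALSE)
  )
}

envi_binary_path <- function(header_path) {
  base <- sub("\\.hdr$", "", header_path)
  for (cand in c(base, paste0(base, ".img"), paste0(base, ".dat"))) {
    if (file.exists(cand)) return(cand)
  }
  stop(sprintf("no binary cube found next to %s", header_path), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
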