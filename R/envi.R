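# ENVI cube I/O. One fixed dialect: BIL interleave, 32-bit IEEE float
# (data type 4), little-endian (byte order 0), wavelength list in the header.
# The header is an ASCII key = value file; list values are brace-delimited
# and may span lines.

parse_envi_header <- function(header_path) {
  lines <- readLines(header_path, warn = FALSE)
  if (length(lines) == 0L || trimws(lines[1]) != "ENVI")
    stop("not an ENVI header: first line must be 'ENVI'", call. = FALSE)
  # merge brace-delimited list values that span physical lines
  fields <- list()
  buf <- character(0)
  depth <- 0L
  logical_lines <- character(0)
  for (ln in lines[-1]) {
    buf <- c(buf, ln)
    depth <- depth +
      nchar(gsub("[^{]", "", ln)) - nchar(gsub("[^}]", "", ln))
    if (depth <= 0L) {
      logical_lines <- c(logical_lines, paste(buf, collapse = " "))
      buf <- character(0)
      depth <- 0L
    }
  }
  for (ln in logical_lines) {
    ln <- trimws(ln)
    if (ln == "" || !grepl("=", ln, fixed = TRUE)) next
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    fields[[tolower(key)]] <- val
  }
  fields
}

envi_field_num <- function(fields, key) {
  if (is.null(fields[[key]]))
    stop(sprintf("ENVI header missing required field '%s'", key), call. = FALSE)
  as.numeric(fields[[key]])
}

#' Read an ENVI hyperspectral cube
#'
#' Reads the BIL / float32 / little-endian dialect written by [write_envi()].
#' The header must declare `samples`, `lines`, `bands`, `interleave = bil`,
#' `data type = 4`, `byte order = 0` and a `wavelength` list, which defines
#' the cube's [wavelength_grid()].
#'
#' @param header_path Path to the ASCII `.hdr` file.
#' @param data_path Path to the binary cube; defaults to `header_path` with
#'   the extension replaced by `.raw`.
#' @return A [hypercube()].
#' @export
read_envi <- function(header_path, data_path = sub("\\.hdr$", ".raw", header_path)) {
  f <- parse_envi_header(header_path)
  samples <- as.integer(envi_field_num(f, "samples"))
  lines_n <- as.integer(envi_field_num(f, "lines"))
  bands <- as.integer(envi_field_num(f, "bands"))
  interleave <- tolower(f[["interleave"]] %||% "")
  if (interleave != "bil")
    stop(sprintf("unsupported ENVI field 'interleave' = '%s' (only 'bil' is supported)",
                 interleave), call. = FALSE)
  dtype <- as.integer(envi_field_num(f, "data type"))
  if (dtype != 4L)
    stop(sprintf("unsupported ENVI field 'data type' = %d (only 4, float32)", dtype),
         call. = FALSE)
  border <- as.integer(envi_field_num(f, "byte order"))
  if (border != 0L)
    stop(sprintf("unsupported ENVI field 'byte order' = %d (only 0, little-endian)",
                 border), call. = FALSE)
  wl_raw <- f[["wavelength"]]
  if (is.null(wl_raw))
    stop("ENVI header missing required field 'wavelength'", call. = FALSE)
  wl <- as.numeric(strsplit(gsub("[{}]", "", wl_raw), ",")[[1]])
  if (length(wl) != bands)
    stop(sprintf("wavelength list has %d entries for %d bands", length(wl), bands),
         call. = FALSE)
  n <- samples * lines_n * bands
  con <- file(data_path, "rb")
  on.exit(close(con))
  v <- readBin(con, what = "numeric", n = n, size = 4L, endian = "little")
  if (length(v) != n)
    stop(sprintf("cube file truncated: expected %d values, read %d", n, length(v)),
         call. = FALSE)
  # BIL: value index = ((line-1)*bands + (band-1))*samples + sample
  arr <- aperm(array(v, dim = c(samples, bands, lines_n)), c(3L, 1L, 2L))
  grid <- wavelength_grid(bands, min(wl), max(wl))
  hypercube(arr, grid)
}

#' Write an ENVI hyperspectral cube
#'
#' Writes the one dialect [read_envi()] accepts (BIL, float32,
#' little-endian), so that a write-read cycle is stable: values already
#' representable in 32-bit floats round-trip bit-exactly.
#'
#' @param cube A [hypercube()].
#' @param header_path Output path for the `.hdr` file.
#' @param data_path Output path for the binary cube; defaults to
#'   `header_path` with the extension replaced by `.raw`.
#' @return Invisibly, `c(header_path, data_path)`.
#' @export
write_envi <- function(cube, header_path,
                       data_path = sub("\\.hdr$", ".raw", header_path)) {
  stopifnot(inherits(cube, "hypercube"))
  d <- dim(cube$data)
  wl <- paste(sprintf("%.6f", cube$grid$centers), collapse = ", ")
  hdr <- c(
    "ENVI",
    "description = {hsibruise reflectance cube}",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 4",
    "interleave = bil",
    "byte order = 0",
    "wavelength units = Nanometers",
    sprintf("wavelength = {%s}", wl)
  )
  writeLines(hdr, header_path)
  v <- as.vector(aperm(cube$data, c(2L, 3L, 1L)))  # sample fastest, then band, then line
  con <- file(data_path, "wb")
  on.exit(close(con))
  writeBin(v, con, size = 4L, endian = "little")
  invisible(c(header_path, data_path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
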