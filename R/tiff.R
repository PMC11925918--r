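# Minimal single-band GeoTIFF codec.
#
# No raster I/O package is assumed: this reads and writes baseline TIFF 6.0
# with the three georeferencing tags the pipeline needs (ModelPixelScale,
# ModelTiepoint, GDAL_NODATA). Writer: little-endian, uncompressed, one
# float32 sample per pixel, one strip. Reader: either byte order,
# uncompressed, single-sample, int/uint/float samples, any strip layout.

TIFF_TAG <- c(width = 256L, height = 257L, bits = 258L, compression = 259L,
              photometric = 262L, description = 270L, strip_offsets = 273L,
              samples = 277L, rows_per_strip = 278L, strip_bytes = 279L,
              planar = 284L, sample_format = 339L,
              pixel_scale = 33550L, tiepoint = 33922L, gdal_nodata = 42113L)

write_tiff_grid <- function(grid, path) {
  v <- grid$values
  nr <- nrow(v); nc <- ncol(v)
  finite <- v[!is.na(v)]
  nodata <- -9999
  if (length(finite) && any(abs(finite - nodata) < 1e-6)) nodata <- -3.0e38
  flat <- as.numeric(t(v))                       # row-major, north-up
  flat[is.na(flat)] <- nodata

  desc <- grid$crs_tag
  desc_raw <- if (nzchar(desc)) c(charToRaw(desc), as.raw(0)) else raw(0)
  nodata_raw <- c(charToRaw(sprintf("%.10g", nodata)), as.raw(0))

  data_offset <- 8L
  data_bytes <- 4L * nr * nc
  ifd_offset <- data_offset + data_bytes

  entries <- list(
    list(TIFF_TAG[["width"]], 4L, 1L, nc),
    list(TIFF_TAG[["height"]], 4L, 1L, nr),
    list(TIFF_TAG[["bits"]], 3L, 1L, 32L),
    list(TIFF_TAG[["compression"]], 3L, 1L, 1L),
    list(TIFF_TAG[["photometric"]], 3L, 1L, 1L))
  if (length(desc_raw))
    entries <- c(entries, list(list(TIFF_TAG[["description"]], 2L,
                                    length(desc_raw), desc_raw)))
  entries <- c(entries, list(
    list(TIFF_TAG[["strip_offsets"]], 4L, 1L, data_offset),
    list(TIFF_TAG[["samples"]], 3L, 1L, 1L),
    list(TIFF_TAG[["rows_per_strip"]], 4L, 1L, nr),
    list(TIFF_TAG[["strip_bytes"]], 4L, 1L, data_bytes),
    list(TIFF_TAG[["planar"]], 3L, 1L, 1L),
    list(TIFF_TAG[["sample_format"]], 3L, 1L, 3L),
    list(TIFF_TAG[["pixel_scale"]], 12L, 3L,
         c(grid$cell_size, grid$cell_size, 0)),
    list(TIFF_TAG[["tiepoint"]], 12L, 6L,
         c(0, 0, 0, grid$origin[1], grid$origin[2], 0)),
    list(TIFF_TAG[["gdal_nodata"]], 2L, length(nodata_raw), nodata_raw)))

  type_size <- c(`2` = 1L, `3` = 2L, `4` = 4L, `12` = 8L)
  n_entries <- length(entries)
  extra_offset <- ifd_offset + 2L + 12L * n_entries + 4L

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(as.integer(ifd_offset), con, size = 4, endian = "little")
  writeBin(flat, con, size = 4, endian = "little")

  extras <- raw(0)
  writeBin(as.integer(n_entries), con, size = 2, endian = "little")
  for (e in entries) {
    writeBin(as.integer(e[[1]]), con, size = 2, endian = "little")
    writeBin(as.integer(e[[2]]), con, size = 2, endian = "little")
    writeBin(as.integer(e[[3]]), con, size = 4, endian = "little")
    nbytes <- type_size[[as.character(e[[2]])]] * e[[3]]
    val <- e[[4]]
    if (nbytes <= 4L) {
      payload <- if (is.raw(val)) c(val, raw(4L - length(val)))
      else {
        rc <- rawConnection(raw(0), "wb")
        writeBin(as.integer(val), rc,
                 size = type_size[[as.character(e[[2]])]], endian = "little")
        out <- rawConnectionValue(rc); close(rc)
        c(out, raw(4L - length(out)))
      }
      writeBin(payload, con)
    } else {
      writeBin(as.integer(extra_offset + length(extras)), con, size = 4,
               endian = "little")
      rc <- rawConnection(raw(0), "wb")
      if (is.raw(val)) writeBin(val, rc)
      else if (e[[2]] == 12L) writeBin(as.numeric(val), rc, size = 8,
                                       endian = "little")
      else writeBin(as.integer(val), rc,
                    size = type_size[[as.character(e[[2]])]], endian = "little")
      extras <- c(extras, rawConnectionValue(rc)); close(rc)
    }
  }
  writeBin(0L, con, size = 4, endian = "little")  # no next IFD
  if (length(extras)) writeBin(extras, con)
  invisible(path)
}

read_tiff_grid <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  if (length(bytes) < 8L) stop("not a TIFF file: ", path)
  order_tag <- rawToChar(bytes[1:2])
  endian <- switch(order_tag, II = "little", MM = "big",
                   stop("not a TIFF file (bad byte order mark): ", path))
  rint <- function(off, size, n = 1L, signed = FALSE)
    readBin(bytes[(off + 1L):(off + size * n)], "integer", n = n, size = size,
            endian = endian, signed = signed || size == 4L)
  rdbl <- function(off, n = 1L, size = 8L)
    readBin(bytes[(off + 1L):(off + size * n)], "double", n = n, size = size,
            endian = endian)
  if (rint(2L, 2L) != 42L) stop("not a TIFF file (bad magic): ", path)
  ifd <- rint(4L, 4L)
  n_entries <- rint(ifd, 2L)
  type_size <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `6` = 1L, `8` = 2L,
                 `9` = 4L, `11` = 4L, `12` = 8L)

  tags <- list()
  for (k in seq_len(n_entries)) {
    off <- ifd + 2L + 12L * (k - 1L)
    tag <- rint(off, 2L); type <- rint(off + 2L, 2L); count <- rint(off + 4L, 4L)
    ts <- type_size[as.character(type)]
    if (is.na(ts)) next                           # rational etc.: unused here
    nbytes <- ts * count
    voff <- if (nbytes <= 4L) off + 8L else rint(off + 8L, 4L)
    val <- switch(as.character(type),
      `1` = rint(voff, 1L, count),
      `2` = {
        s <- bytes[(voff + 1L):(voff + count)]
        rawToChar(s[s != as.raw(0)])
      },
      `3` = rint(voff, 2L, count),
      `4` = rint(voff, 4L, count),
      `6` = rint(voff, 1L, count, signed = TRUE),
      `8` = rint(voff, 2L, count, signed = TRUE),
      `9` = rint(voff, 4L, count, signed = TRUE),
      `11` = rdbl(voff, count, size = 4L),
      `12` = rdbl(voff, count))
    tags[[as.character(tag)]] <- val
  }
  gettag <- function(name, default = NULL) {
    v <- tags[[as.character(TIFF_TAG[[name]])]]
    if (is.null(v)) default else v
  }

  nc <- gettag("width"); nr <- gettag("height")
  if (is.null(nc) || is.null(nr)) stop("TIFF missing image dimensions: ", path)
  if (gettag("compression", 1L) != 1L)
    stop("unsupported compressed TIFF: ", path)
  if (gettag("samples", 1L) != 1L)
    stop("only single-band TIFF supported: ", path)
  bits <- gettag("bits", 1L)[1]
  fmt <- gettag("sample_format", 1L)[1]

  offsets <- gettag("strip_offsets")
  if (is.null(offsets)) stop("TIFF missing strip offsets: ", path)
  counts <- gettag("strip_bytes", (bits / 8) * nr * nc)
  sample_bytes <- bits / 8L
  vals <- numeric(0)
  for (s in seq_along(offsets)) {
    n_samp <- counts[s] / sample_bytes
    chunk <- bytes[(offsets[s] + 1L):(offsets[s] + counts[s])]
    vals <- c(vals, switch(as.character(fmt),
      `1` = , `2` = readBin(chunk, "integer", n = n_samp, size = sample_bytes,
                            endian = endian, signed = (fmt == 2L || sample_bytes == 4L)),
      `3` = readBin(chunk, "double", n = n_samp, size = sample_bytes,
                    endian = endian),
      stop("unsupported TIFF sample format ", fmt, ": ", path)))
  }
  if (length(vals) != nr * nc)
    stop("TIFF pixel count mismatch in ", path)

  scale <- gettag("pixel_scale"); tie <- gettag("tiepoint")
  if (is.null(scale) || is.null(tie))
    stop("TIFF has no georeference (missing pixel scale / tiepoint): ", path)
  if (abs(scale[1] - scale[2]) > 1e-6 * scale[1])
    stop("non-square cells unsupported: ", path)
  origin <- c(tie[4] - tie[1] * scale[1], tie[5] + tie[2] * scale[2])

  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  nd <- gettag("gdal_nodata")
  if (!is.null(nd)) {
    ndv <- suppressWarnings(as.numeric(nd))
    if (is.finite(ndv)) {
      tol <- 1e-6 * max(1, abs(ndv))
      m[abs(m - ndv) <= tol] <- NA
    } else if (is.nan(ndv)) m[is.nan(m)] <- NA
  }
  hr_grid(m, cell_size = scale[1], origin = origin,
          crs_tag = gettag("description", ""))
}
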