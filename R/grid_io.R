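# Raster I/O and geometric plumbing: ESRI ASCII grid + minimal GeoTIFF,
# alignment onto a common extent/resolution, boundary clipping, and
# rasterization of admin-unit tables.

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) return("geotiff")
  if (ext %in% c("asc", "txt", "grd")) return("ascii_grid")
  magic <- tryCatch(readBin(path, "raw", n = 2L), error = function(e) raw(0))
  if (length(magic) == 2L && rawToChar(magic) %in% c("II", "MM")) "geotiff"
  else "ascii_grid"
}

#' Read a single-band raster
#'
#' Reads GeoTIFF (single band, uncompressed) or ESRI ASCII grid into an
#' [hr_grid]. Cells equal to the file's nodata value come back as `NA`. For
#' ASCII grids, a sidecar `.prj` file (free text) is picked up as the crs tag
#' when present.
#'
#' @param path file path.
#' @param format `"geotiff"`, `"ascii_grid"`, or `"auto"` (by extension, then
#'   content sniffing).
#' @return an [hr_grid].
#' @seealso [write_raster()]
#' @export
read_raster <- function(path, format = c("auto", "geotiff", "ascii_grid")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("raster file does not exist: ", path)
  if (format == "auto") format <- guess_format(path)
  switch(format,
         geotiff = read_tiff_grid(path),
         ascii_grid = read_ascii_grid(path))
}

#' Write a single-band raster
#'
#' Writes an [hr_grid] as GeoTIFF (float32, uncompressed, nodata-tagged) or
#' ESRI ASCII grid. Round-trips through [read_raster()] preserve the nodata
#' mask exactly and values to float32 precision (GeoTIFF) or 9 significant
#' digits (ASCII). A non-empty `crs_tag` is stored in the TIFF description
#' tag, or in a `.prj` sidecar for ASCII grids.
#'
#' @param grid an [hr_grid].
#' @param path output path; parent directory must exist.
#' @param format `"geotiff"` or `"ascii_grid"`.
#' @return `path`, invisibly.
#' @export
write_raster <- function(grid, path, format = c("geotiff", "ascii_grid")) {
  stopifnot(is_hr_grid(grid))
  format <- match.arg(format)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir)
  switch(format,
         geotiff = write_tiff_grid(grid, path),
         ascii_grid = write_ascii_grid(grid, path))
  invisible(path)
}

read_ascii_grid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 6L) stop("not an ESRI ASCII grid: ", path)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) && grepl("^\\s*[A-Za-z_]+\\s+\\S", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("ESRI ASCII header incomplete in ", path, " (need ncols/nrows/cellsize)")
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner
  else if (!is.null(hdr$xllcenter)) hdr$xllcenter - hdr$cellsize / 2
  else stop("ESRI ASCII header missing xllcorner in ", path)
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner
  else if (!is.null(hdr$yllcenter)) hdr$yllcenter - hdr$cellsize / 2
  else stop("ESRI ASCII header missing yllcorner in ", path)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != nr * nc)
    stop("ESRI ASCII grid has ", length(vals), " values, expected ",
         nr * nc, ": ", path)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  prj <- paste0(tools::file_path_sans_ext(path), ".prj")
  crs <- if (file.exists(prj)) paste(readLines(prj, warn = FALSE),
                                     collapse = "\n") else ""
  hr_grid(m, cell_size = hdr$cellsize,
          origin = c(xll, yll + nr * hdr$cellsize), crs_tag = crs)
}

write_ascii_grid <- function(grid, path) {
  v <- grid$values
  nodata <- -9999
  if (any(!is.na(v) & abs(v - nodata) < 1e-9)) nodata <- -3.0e38
  out <- v
  out[is.na(out)] <- nodata
  hdr <- c(paste("ncols", ncol(v)),
           paste("nrows", nrow(v)),
           paste("xllcorner", sprintf("%.10g", grid$origin[1])),
           paste("yllcorner",
                 sprintf("%.10g", grid$origin[2] - nrow(v) * grid$cell_size)),
           paste("cellsize", sprintf("%.10g", grid$cell_size)),
           paste("NODATA_value", sprintf("%.10g", nodata)))
  body <- apply(out, 1, function(r) paste(sprintf("%.9g", r), collapse = " "))
  writeLines(c(hdr, body), path)
  if (nzchar(grid$crs_tag))
    writeLines(grid$crs_tag, paste0(tools::file_path_sans_ext(path), ".prj"))
  invisible(path)
}

#' Align rasters onto a common grid
#'
#' Snaps a set of overlapping rasters onto their common intersection extent at
#' a target resolution using nearest-neighbour resampling, and stacks them
#' with their indicator metadata. Nodata is propagated as the union of the
#' input masks: the composite index is only defined where every indicator is
#' valid.
#'
#' @param grids list of [hr_grid], one per spec, all in the same crs.
#' @param specs list of [indicator_spec] or the [canonical_indicators()] frame.
#' @param target_cell_size output resolution in metres (default 1000).
#' @param year year label for the stack.
#' @return an [hr_stack] on the intersection extent.
#' @export
align_stack <- function(grids, specs, target_cell_size = 1000,
                        year = NA_integer_) {
  if (is.data.frame(specs)) specs <- specs_from_frame(specs)
  stopifnot(length(grids) >= 1L, target_cell_size > 0)
  crs <- unique(vapply(grids, `[[`, "", "crs_tag"))
  if (length(crs) > 1L)
    stop("grids declare different crs tags (", paste(crs, collapse = " / "),
         "); reproject before stacking")
  ext <- vapply(grids, grid_extent, numeric(4))
  xmin <- max(ext["xmin", ]); xmax <- min(ext["xmax", ])
  ymin <- max(ext["ymin", ]); ymax <- min(ext["ymax", ])
  eps <- 1e-9 * target_cell_size
  nc <- floor((xmax - xmin) / target_cell_size + eps)
  nr <- floor((ymax - ymin) / target_cell_size + eps)
  if (xmax - xmin <= eps || ymax - ymin <= eps || nc < 1L || nr < 1L)
    stop("rasters have no spatial intersection at ", target_cell_size, " m")
  xc <- xmin + (seq_len(nc) - 0.5) * target_cell_size
  yc <- ymax - (seq_len(nr) - 0.5) * target_cell_size
  resampled <- lapply(grids, function(g) {
    jj <- pmin(pmax(ceiling((xc - g$origin[1]) / g$cell_size - 1e-9), 1L),
               ncol(g$values))
    ii <- pmin(pmax(ceiling((g$origin[2] - yc) / g$cell_size - 1e-9), 1L),
               nrow(g$values))
    hr_grid(g$values[ii, jj, drop = FALSE], cell_size = target_cell_size,
            origin = c(xmin, ymax), crs_tag = g$crs_tag)
  })
  union_mask <- Reduce(`|`, lapply(resampled, function(g) is.na(g$values)))
  resampled <- lapply(resampled, function(g) {
    g$values[union_mask] <- NA
    g
  })
  hr_stack(resampled, specs, year = year)
}

#' Clip a grid to a study boundary
#'
#' Masks every cell outside the boundary; cells inside keep their value.
#'
#' @param grid an [hr_grid].
#' @param boundary an aligned [hr_grid] whose values are 1 (inside) / 0 or
#'   `NA` (outside), or a logical matrix of the same shape.
#' @return the clipped [hr_grid].
#' @export
clip_to_boundary <- function(grid, boundary) {
  stopifnot(is_hr_grid(grid))
  if (is_hr_grid(boundary)) {
    stop_if_misaligned(grid, boundary, "grid and boundary")
    inside <- !is.na(boundary$values) & boundary$values != 0
  } else if (is.matrix(boundary)) {
    if (!identical(dim(boundary), dim(grid$values)))
      stop("boundary matrix shape ", paste(dim(boundary), collapse = "x"),
           " does not match grid ", paste(dim(grid$values), collapse = "x"))
    inside <- !is.na(boundary) & boundary != 0
  } else stop("boundary must be an hr_grid or a matrix")
  grid$values[!inside] <- NA
  grid
}

#' Rasterize an admin-unit statistic onto a zone grid
#'
#' Distributes yearbook-style per-unit values uniformly over each unit's
#' cells: every cell of zone `k` receives the table value for `unit_id = k`.
#' Zone id 0 (and nodata zones) are masked. The table may be a data.frame or
#' a CSV path with header `unit_id,value`.
#'
#' @param table data.frame with columns `unit_id`, `value`, or a CSV path.
#' @param zones [hr_grid] of integer unit ids, aligned with `template`.
#' @param template [hr_grid] supplying the output georeference and mask.
#' @return an [hr_grid] of per-cell values.
#' @export
rasterize_admin_table <- function(table, zones, template) {
  if (is.character(table)) table <- utils::read.csv(table)
  if (!all(c("unit_id", "value") %in% names(table)))
    stop("admin table must have columns unit_id, value")
  stopifnot(is_hr_grid(zones), is_hr_grid(template))
  stop_if_misaligned(zones, template, "zones and template")
  z <- zones$values
  ids <- unique(z[!is.na(z) & z != 0])
  missing_ids <- setdiff(ids, table$unit_id)
  if (length(missing_ids))
    stop("zone id(s) missing from admin table: ",
         paste(sort(missing_ids), collapse = ", "))
  lut <- stats::setNames(table$value, as.character(table$unit_id))
  out <- matrix(NA_real_, nrow(z), ncol(z))
  sel <- !is.na(z) & z != 0
  out[sel] <- lut[as.character(z[sel])]
  out[is.na(template$values)] <- NA
  hr_grid(out, cell_size = template$cell_size, origin = template$origin,
          crs_tag = template$crs_tag)
}
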