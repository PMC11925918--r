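#' Single-band raster grid
#'
#' The elementary spatial container of the package: a north-up value matrix
#' with a nodata mask, a square cell size in metres and the projected
#' coordinates of its upper-left corner. Row 1 is the northern edge; the
#' centre of cell `(i, j)` sits at
#' `origin + ((j - 0.5) * cell_size, -(i - 0.5) * cell_size)`.
#'
#' Nodata cells are stored as `NA` in `values`; every statistic in the
#' package excludes them.
#'
#' @param values numeric matrix (north-up, row-major); `NA` marks nodata.
#' @param cell_size cell edge length in metres (> 0), default 1000.
#' @param origin length-2 numeric, projected `(x, y)` of the upper-left
#'   corner. Defaults to `(0, nrow(values) * cell_size)` so that the lower
#'   left corner is the projection origin.
#' @param crs_tag opaque coordinate-system identifier string. The pipeline
#'   never reprojects; it only refuses to combine grids whose tags differ.
#' @return an object of class `hr_grid`.
#' @examples
#' g <- hr_grid(matrix(1:12, 3, 4), cell_size = 500)
#' dim(g)
#' @export
hr_grid <- function(values, cell_size = 1000, origin = NULL, crs_tag = "") {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(cell_size) || length(cell_size) != 1L || !is.finite(cell_size) ||
      cell_size <= 0)
    stop("cell_size must be a single positive number")
  if (is.null(origin)) origin <- c(0, nrow(values) * cell_size)
  if (length(origin) != 2L || !all(is.finite(origin)))
    stop("origin must be a finite (x, y) pair")
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin), crs_tag = as.character(crs_tag)),
    class = "hr_grid")
}

#' @export
dim.hr_grid <- function(x) dim(x$values)

#' Nodata mask of a grid
#'
#' @param grid an [hr_grid].
#' @return logical matrix, `TRUE` where the cell is nodata.
#' @export
nodata_mask <- function(grid) {
  stopifnot(is_hr_grid(grid))
  is.na(grid$values)
}

#' Test for the grid class
#' @param x object.
#' @return `TRUE` for [hr_grid] objects.
#' @export
is_hr_grid <- function(x) inherits(x, "hr_grid")

#' @export
print.hr_grid <- function(x, ...) {
  d <- dim(x$values)
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<hr_grid> %d x %d cells, %g m, origin (%g, %g)%s\n",
              d[1], d[2], x$cell_size, x$origin[1], x$origin[2],
              if (nzchar(x$crs_tag)) paste0(", crs '", x$crs_tag, "'") else ""))
  if (length(v))
    cat(sprintf("  values: [%g, %g], mean %g; %d nodata cells\n",
                min(v), max(v), mean(v), sum(is.na(x$values))))
  else cat("  all cells nodata\n")
  invisible(x)
}

# extent as (xmin, xmax, ymin, ymax) in projection units
grid_extent <- function(g) {
  d <- dim(g$values)
  c(xmin = g$origin[1], xmax = g$origin[1] + d[2] * g$cell_size,
    ymin = g$origin[2] - d[1] * g$cell_size, ymax = g$origin[2])
}

# TRUE when two grids cover the same cells in the same crs
grids_aligned <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$cell_size - b$cell_size) <= tol * a$cell_size &&
    all(abs(a$origin - b$origin) <= tol * a$cell_size) &&
    identical(a$crs_tag, b$crs_tag)
}

stop_if_misaligned <- function(a, b, what = "grids") {
  if (!grids_aligned(a, b))
    stop(what, " are not aligned: shapes ",
         paste(dim(a$values), collapse = "x"), " vs ",
         paste(dim(b$values), collapse = "x"),
         ", origins (", paste(signif(a$origin, 10), collapse = ", "), ") vs (",
         paste(signif(b$origin, 10), collapse = ", "), ")")
  invisible(TRUE)
}

#' Indicator metadata
#'
#' Describes one assessment indicator: its category in the risk triangle
#' (hazard, social vulnerability or exposure) and its direction — `"positive"`
#' when larger raw values mean more risk (e.g. land surface temperature,
#' population density), `"negative"` when larger values mean less risk
#' (e.g. NDVI, GDP, physicians per capita).
#'
#' @param name indicator name.
#' @param category one of `"hazard"`, `"social_vulnerability"`, `"exposure"`.
#' @param direction one of `"positive"`, `"negative"`.
#' @param units free-text unit string.
#' @return an object of class `hr_indicator_spec`.
#' @seealso [canonical_indicators()] for the standard 13-indicator set.
#' @export
indicator_spec <- function(name, category, direction, units = "") {
  category <- match.arg(category,
                        c("hazard", "social_vulnerability", "exposure"))
  direction <- match.arg(direction, c("positive", "negative"))
  structure(list(name = as.character(name), category = category,
                 direction = direction, units = as.character(units)),
            class = "hr_indicator_spec")
}

#' The canonical 13-indicator set
#'
#' The standard indicator battery for composite heat health risk: one thermal
#' hazard layer (nighttime land surface temperature), seven social-vulnerability
#' indicators and five exposure indicators, each with its risk direction.
#' Socio-economic capacity and health-resource indicators (GDP, income,
#' physicians, beds) and the exposure buffers (NDVI, water resources) are
#' negative — more of them lowers risk; demographic vulnerability, density and
#' outdoor-occupation shares are positive.
#'
#' @return a data.frame with columns `name`, `category`, `direction`, `units`.
#' @examples
#' canonical_indicators()
#' @export
canonical_indicators <- function() {
  data.frame(
    name = c("lst",
             "gdp", "income", "physicians", "hospital_beds",
             "older_adults", "female", "unemployment",
             "ndvi", "pop_density", "water_resources",
             "agricultural_practitioners", "construction_practitioners"),
    category = c("hazard",
                 rep("social_vulnerability", 7),
                 rep("exposure", 5)),
    direction = c("positive",
                  "negative", "negative", "negative", "negative",
                  "positive", "positive", "positive",
                  "negative", "positive", "negative",
                  "positive", "positive"),
    units = c("degC",
              "yuan", "yuan", "persons", "beds", "%", "%", "%",
              "index", "persons/km2", "m3", "%", "%"),
    stringsAsFactors = FALSE)
}

specs_from_frame <- function(df) {
  lapply(seq_len(nrow(df)), function(i)
    indicator_spec(df$name[i], df$category[i], df$direction[i], df$units[i]))
}

#' Aligned multi-indicator stack
#'
#' A named set of mutually aligned [hr_grid]s, one per indicator, with the
#' indicator metadata and a year label. All grids must share shape, cell size,
#' origin and crs tag; the union of their nodata masks defines where the
#' composite index is computable.
#'
#' @param grids named list of [hr_grid], one per spec, in spec order.
#' @param specs list of [indicator_spec] (or the data.frame from
#'   [canonical_indicators()]).
#' @param year integer year label.
#' @return an object of class `hr_stack`.
#' @export
hr_stack <- function(grids, specs, year = NA_integer_) {
  if (is.data.frame(specs)) specs <- specs_from_frame(specs)
  if (length(grids) != length(specs))
    stop("need exactly one grid per indicator spec (",
         length(grids), " grids, ", length(specs), " specs)")
  names(grids) <- vapply(specs, `[[`, "", "name")
  ref <- grids[[1]]
  for (nm in names(grids)) {
    if (!is_hr_grid(grids[[nm]])) stop("grid '", nm, "' is not an hr_grid")
    stop_if_misaligned(ref, grids[[nm]], paste0("stack grids ('", nm, "')"))
  }
  structure(list(grids = grids, specs = specs, year = as.integer(year)),
            class = "hr_stack")
}

#' @export
print.hr_stack <- function(x, ...) {
  d <- dim(x$grids[[1]]$values)
  cat(sprintf("<hr_stack> %d indicators, %d x %d cells, year %s\n",
              length(x$grids), d[1], d[2], x$year))
  for (s in x$specs)
    cat(sprintf("  %-28s %-20s %s\n", s$name, s$category, s$direction))
  invisible(x)
}

#' Union nodata mask of a stack
#'
#' A cell is unusable for the composite index when any indicator is nodata
#' there: the multiplicative index is undefined with a missing factor.
#'
#' @param stack an [hr_stack].
#' @return logical matrix, `TRUE` where any layer is nodata.
#' @export
stack_mask <- function(stack) {
  stopifnot(inherits(stack, "hr_stack"))
  Reduce(`|`, lapply(stack$grids, function(g) is.na(g$values)))
}

# restore RNG state on exit so seeded helpers do not perturb the session
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}
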