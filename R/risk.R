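# Composite risk surface, five-level classification and the area /
# transition / dominance accounting derived from the class maps.

risk_levels <- c("lowest", "low", "medium", "high", "highest")

#' Compute the composite heat health risk surface
#'
#' Multiplies the hazard, social-vulnerability and exposure surfaces cellwise
#' (`raw = H * S * E`) and min-max rescales the product to `[0, 1]` over the
#' unmasked cells. The multiplicative form means a cell is only high-risk
#' when all three components are elevated; the strictly positive `[0.01,
#' 1.01]` normalization of the inputs keeps the product well behaved.
#'
#' @param h,s,e aligned [hr_grid]s: hazard, social vulnerability, exposure,
#'   on the normalized `[0.01, 1.01]` scale.
#' @param year year label.
#' @return an object of class `hr_riskmap` with the rescaled `hhr` grid and
#'   the three component grids.
#' @export
compute_hhr <- function(h, s, e, year = NA_integer_) {
  stopifnot(is_hr_grid(h), is_hr_grid(s), is_hr_grid(e))
  stop_if_misaligned(h, s, "hazard and social-vulnerability grids")
  stop_if_misaligned(h, e, "hazard and exposure grids")
  raw <- h$values * s$values * e$values
  hhr <- hr_grid(rescale01(raw), cell_size = h$cell_size, origin = h$origin,
                 crs_tag = h$crs_tag)
  structure(list(hhr = hhr, h = h, s = s, e = e, year = as.integer(year)),
            class = "hr_riskmap")
}

#' @export
print.hr_riskmap <- function(x, ...) {
  cat(sprintf("<hr_riskmap> year %s\n", x$year))
  print(x$hhr)
  invisible(x)
}

#' Exact Jenks natural breaks
#'
#' Finds the partition of the values into `n_classes` contiguous classes that
#' minimizes the total within-class sum of squared deviations, by exact
#' dynamic programming over the sorted values (the global optimum, not the
#' common heuristic). The returned thresholds are the minima of classes
#' 2..n: a value belongs to class `k` when `thresholds[k-1] <= value <
#' thresholds[k]` (see [classify_risk()]).
#'
#' @param values numeric vector (an [hr_grid] is accepted; its unmasked cells
#'   are used).
#' @param n_classes number of classes (needs at least that many distinct
#'   values).
#' @return numeric vector of `n_classes - 1` ascending thresholds, with the
#'   achieved within-class SSD as attribute `"ssd"`.
#' @export
jenks_breaks <- function(values, n_classes = 5L) {
  if (is_hr_grid(values)) values <- values$values
  v <- sort(as.numeric(values[!is.na(values)]))
  if (n_classes < 1L) stop("n_classes must be >= 1")
  if (length(unique(v)) < n_classes)
    stop("need at least ", n_classes, " distinct values, got ",
         length(unique(v)))
  res <- .jenks_dp(v, as.integer(n_classes))
  thresholds <- v[res$starts[-1]]
  attr(thresholds, "ssd") <- res$ssd
  thresholds
}

#' Classify a risk surface into five levels
#'
#' Bins the `[0, 1]` risk surface into the levels lowest / low / medium /
#' high / highest using half-open intervals: values below the first
#' threshold are `lowest`, values at or above the last are `highest`, and
#' each boundary value belongs to the upper class.
#'
#' @param risk an `hr_riskmap` (its `hhr` grid is used) or an [hr_grid].
#' @param thresholds 4 strictly ascending break values; by default the exact
#'   Jenks breaks of the surface itself. The conventional fixed standard
#'   `c(0.2, 0.4, 0.5, 0.58)` may be supplied for replication.
#' @param year year label (defaults to the risk map's).
#' @return an object of class `hr_classmap`: integer class grid (1..5),
#'   level names, thresholds, year.
#' @export
classify_risk <- function(risk, thresholds = NULL, year = NULL) {
  g <- if (inherits(risk, "hr_riskmap")) risk$hhr
  else if (is_hr_grid(risk)) risk
  else stop("risk must be an hr_riskmap or hr_grid")
  if (is.null(year))
    year <- if (inherits(risk, "hr_riskmap")) risk$year else NA_integer_
  if (is.null(thresholds)) thresholds <- jenks_breaks(g, 5L)
  thresholds <- as.numeric(thresholds)
  if (length(thresholds) != 4L || any(diff(thresholds) <= 0))
    stop("thresholds must be 4 strictly ascending break values")
  v <- g$values
  cls <- matrix(NA_real_, nrow(v), ncol(v))
  ok <- !is.na(v)
  cls[ok] <- findInterval(v[ok], thresholds) + 1
  classes <- hr_grid(cls, cell_size = g$cell_size, origin = g$origin,
                     crs_tag = g$crs_tag)
  structure(list(classes = classes, levels = risk_levels,
                 thresholds = thresholds, year = as.integer(year)),
            class = "hr_classmap")
}

#' Construct a class map from an integer grid
#'
#' Wraps an already-categorical grid (e.g. from [gen_markov_series()]) as an
#' `hr_classmap` without thresholds.
#'
#' @param grid [hr_grid] of integer classes in `1..length(levels)`.
#' @param levels class labels.
#' @param year year label.
#' @return an `hr_classmap`.
#' @export
as_classmap <- function(grid, levels = risk_levels, year = NA_integer_) {
  stopifnot(is_hr_grid(grid))
  v <- grid$values[!is.na(grid$values)]
  if (length(v) && (any(v != round(v)) || any(v < 1) || any(v > length(levels))))
    stop("grid values must be integer classes in 1..", length(levels))
  structure(list(classes = grid, levels = levels, thresholds = NULL,
                 year = as.integer(year)),
            class = "hr_classmap")
}

#' @export
print.hr_classmap <- function(x, ...) {
  cat(sprintf("<hr_classmap> year %s, levels %s\n", x$year,
              paste(x$levels, collapse = "/")))
  if (!is.null(x$thresholds))
    cat("  thresholds:", paste(signif(x$thresholds, 5), collapse = ", "), "\n")
  print(round(area_proportions(x), 2))
  invisible(x)
}

class_counts <- function(classmap) {
  v <- classmap$classes$values
  counts <- vapply(seq_along(classmap$levels),
                   function(k) sum(v == k, na.rm = TRUE), numeric(1))
  stats::setNames(counts, classmap$levels)
}

#' Per-level area shares
#'
#' Share of each risk level among the unmasked cells, as percentages summing
#' to 100.
#'
#' @param classmap an `hr_classmap`.
#' @return named numeric vector of percentages.
#' @export
area_proportions <- function(classmap) {
  stopifnot(inherits(classmap, "hr_classmap"))
  counts <- class_counts(classmap)
  total <- sum(counts)
  if (total == 0) stop("class map has no unmasked cells")
  100 * counts / total
}

#' Cross-date class-transition accounting
#'
#' Cross-tabulates cell classes at two dates: `counts[r, c]` is the number of
#' cells at level `r` on the first date and level `c` on the second. The row
#' and column marginals reproduce the two dates' class counts exactly, and
#' the proportions (shares of all compared cells) sum to 1.
#'
#' @param map1,map2 aligned `hr_classmap`s with identical masks.
#' @return an object of class `hr_transitions` with `counts`, `proportions`,
#'   `levels`, `years`.
#' @export
transition_accounting <- function(map1, map2) {
  stopifnot(inherits(map1, "hr_classmap"), inherits(map2, "hr_classmap"))
  stop_if_misaligned(map1$classes, map2$classes, "class maps")
  a <- map1$classes$values; b <- map2$classes$values
  if (!identical(is.na(a), is.na(b)))
    stop("class maps have different nodata masks; transitions undefined")
  ok <- !is.na(a)
  if (!any(ok)) stop("class maps have no unmasked cells")
  k <- length(map1$levels)
  counts <- table(factor(a[ok], levels = seq_len(k)),
                  factor(b[ok], levels = seq_len(k)))
  counts <- matrix(as.numeric(counts), k, k,
                   dimnames = list(from = map1$levels, to = map2$levels))
  structure(list(counts = counts, proportions = counts / sum(counts),
                 levels = map1$levels, years = c(map1$year, map2$year)),
            class = "hr_transitions")
}

#' @export
print.hr_transitions <- function(x, ...) {
  cat(sprintf("<hr_transitions> %s -> %s (cell counts)\n",
              x$years[1], x$years[2]))
  print(x$counts)
  invisible(x)
}

# min-max rescale over a logical domain; a constant component rescales to 0
# (no variation means it can never dominate on its own)
rescale_on_domain <- function(values, domain) {
  out <- rep(NA_real_, length(values))
  v <- values[domain]
  r <- range(v, na.rm = TRUE)
  out[domain] <- if (r[2] - r[1] > 0) (v - r[1]) / (r[2] - r[1]) else 0
  out
}

#' Dominant-factor subzones of the high-risk area
#'
#' Within the high + highest risk cells, attributes each cell to the
#' component — hazard, social vulnerability or exposure — with the largest
#' min-max-rescaled value (rescaling done over the high+highest domain so
#' the three components are comparable). Ties go to hazard, then social
#' vulnerability, then exposure. The reported proportions are shares of the
#' high+highest domain and sum to 100.
#'
#' @param risk an `hr_riskmap` (components `h`, `s`, `e` are used).
#' @param classmap the matching `hr_classmap`.
#' @return an object of class `hr_dominance`: `zones` ([hr_grid] coded 1 =
#'   hazard, 2 = social vulnerability, 3 = exposure, `NA` elsewhere) and
#'   `proportions` (named percentages).
#' @export
dominant_factor_subzones <- function(risk, classmap) {
  stopifnot(inherits(risk, "hr_riskmap"), inherits(classmap, "hr_classmap"))
  stop_if_misaligned(risk$hhr, classmap$classes, "risk map and class map")
  cl <- classmap$classes$values
  domain <- !is.na(cl) & cl >= 4
  if (!any(domain))
    stop("no high or highest risk cells; dominance subzones undefined")
  comp <- cbind(hazard = rescale_on_domain(as.numeric(risk$h$values), domain),
                social_vulnerability =
                  rescale_on_domain(as.numeric(risk$s$values), domain),
                exposure = rescale_on_domain(as.numeric(risk$e$values), domain))
  zones <- matrix(NA_real_, nrow(cl), ncol(cl))
  zones[domain] <- max.col(comp[domain, , drop = FALSE], ties.method = "first")
  prop <- vapply(1:3, function(k) sum(zones == k, na.rm = TRUE), numeric(1))
  prop <- 100 * prop / sum(prop)
  names(prop) <- colnames(comp)
  g <- risk$hhr
  structure(list(zones = hr_grid(zones, cell_size = g$cell_size,
                                 origin = g$origin, crs_tag = g$crs_tag),
                 proportions = prop, year = risk$year),
            class = "hr_dominance")
}

#' @export
print.hr_dominance <- function(x, ...) {
  cat(sprintf("<hr_dominance> year %s, shares of high+highest cells (%%):\n",
              x$year))
  print(round(x$proportions, 2))
  invisible(x)
}
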