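# Seeded synthetic study regions and indicator stacks.
#
# Emulates the structure the assessment pipeline expects from real 1-km
# rasters: an elliptical study boundary with nodata outside, urban cores with
# radially decaying development intensity, mountain/water low-risk fringes,
# spatially autocorrelated indicator fields sharing a common urbanization
# factor (so PCA weighting is meaningful), and a mild multi-year drift that
# moves cells between adjacent risk levels. No attempt is made to imitate a
# real geography.

#' Synthetic scenario parameters
#'
#' Bundles every knob of the generator. Defaults describe a 128 x 128 cell
#' (~128 km) region with three urban cores, a quarter of the land
#' mountainous, a lake/wetland share of 8%, three assessment years a
#' half-decade apart and a per-year urban-intensification drift of 2% on the
#' heat and population-density gradients — enough to move cells between
#' adjacent risk levels over a decade without reshuffling the map.
#'
#' @param shape `(rows, cols)`, at least 32 x 32.
#' @param seed integer master seed; every derived field is a pure function of
#'   it.
#' @param n_urban_cores number of urban centres; the first is placed at the
#'   region centre.
#' @param urban_radius e-folding radius of each core, in cells.
#' @param mountain_fraction,water_fraction target shares of the study area
#'   (must sum to < 1).
#' @param years integer year labels, ascending.
#' @param trend_per_year per-year relative amplification of the urbanization
#'   loading of LST and population density (normalized units).
#' @param noise_sd standard deviation of per-cell white noise on each
#'   indicator (latent units; the common factor has unit variance).
#' @param smoothing_scale Gaussian smoothing radius of the latent fields, in
#'   cells.
#' @return an object of class `hr_scenario`.
#' @export
synthetic_scenario <- function(shape = c(128, 128), seed = 42,
                               n_urban_cores = 3, urban_radius = 10,
                               mountain_fraction = 0.25, water_fraction = 0.08,
                               years = c(2010L, 2015L, 2019L),
                               trend_per_year = 0.02, noise_sd = 0.15,
                               smoothing_scale = 6) {
  if (length(shape) != 2L || any(shape < 32))
    stop("shape must be at least 32 x 32 for meaningful spatial statistics")
  if (mountain_fraction < 0 || water_fraction < 0 ||
      mountain_fraction + water_fraction >= 1)
    stop("landform fractions must be nonnegative and sum to < 1")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  structure(list(shape = as.integer(shape), seed = as.integer(seed),
                 n_urban_cores = as.integer(n_urban_cores),
                 urban_radius = urban_radius,
                 mountain_fraction = mountain_fraction,
                 water_fraction = water_fraction,
                 years = as.integer(years),
                 trend_per_year = trend_per_year, noise_sd = noise_sd,
                 smoothing_scale = smoothing_scale),
            class = "hr_scenario")
}

# Seeded stationary Gaussian random field: white noise convolved with an
# isotropic Gaussian kernel, standardized to zero mean / unit sd.
smooth_field <- function(nr, nc, scale, seed) {
  with_seed(seed, {
    h <- max(1L, ceiling(2 * scale))
    pad_r <- nr + 2L * h
    pad_c <- nc + 2L * h
    noise <- matrix(stats::rnorm(pad_r * pad_c), pad_r, pad_c)
    kern1 <- stats::dnorm(seq(-h, h), sd = scale)
    kern1 <- kern1 / sum(kern1)
    # separable convolution, valid region only
    tmp <- matrix(0, nr, pad_c)
    for (a in seq_len(2L * h + 1L))
      tmp <- tmp + kern1[a] * noise[(a):(a + nr - 1L), , drop = FALSE]
    out <- matrix(0, nr, nc)
    for (b in seq_len(2L * h + 1L))
      out <- out + kern1[b] * tmp[, (b):(b + nc - 1L), drop = FALSE]
    (out - mean(out)) / stats::sd(out)
  })
}

landform_levels <- c("urban", "rural", "mountain", "water")

#' Generate the synthetic study region
#'
#' Builds the static geography of a scenario: an elliptical study boundary
#' (cells outside are nodata for the whole pipeline), a `[0, 1]` urbanization
#' intensity surface peaking at the urban cores and decaying radially, and a
#' categorical landform map (urban / rural / mountain / water) whose mountain
#' and water shares match the requested fractions to within rounding.
#'
#' @param scenario an [synthetic_scenario()].
#' @return a list with elements `boundary` (0/1 [hr_grid]), `landform`
#'   (integer-coded [hr_grid]; levels in `attr(, "levels")`), and
#'   `urbanization` ([hr_grid] in `[0, 1]`, nodata outside the boundary).
#' @export
make_study_region <- function(scenario) {
  stopifnot(inherits(scenario, "hr_scenario"))
  nr <- scenario$shape[1]; nc <- scenario$shape[2]
  ii <- row(matrix(0, nr, nc)); jj <- col(matrix(0, nr, nc))
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  inside <- ((ii - cy) / (0.48 * nr))^2 + ((jj - cx) / (0.48 * nc))^2 <= 1

  # urban cores: first at the centre, the rest seeded inside the boundary
  cores <- with_seed(scenario$seed + 1L, {
    k <- scenario$n_urban_cores
    pos <- matrix(c(cy, cx), 1, 2)
    if (k > 1L) {
      extra <- cbind(stats::runif(k - 1L, 0.25 * nr, 0.75 * nr),
                     stats::runif(k - 1L, 0.25 * nc, 0.75 * nc))
      pos <- rbind(pos, extra)
    }
    pos
  })
  amp <- c(1, rep(0.85, max(0L, scenario$n_urban_cores - 1L)))
  bump <- matrix(0, nr, nc)
  for (k in seq_len(nrow(cores))) {
    d2 <- (ii - cores[k, 1])^2 + (jj - cores[k, 2])^2
    bump <- pmax(bump, amp[k] * exp(-d2 / (2 * scenario$urban_radius^2)))
  }
  texture <- smooth_field(nr, nc, scenario$smoothing_scale, scenario$seed + 2L)
  urb <- bump + 0.08 * texture
  urb <- (urb - min(urb)) / (max(urb) - min(urb))

  wfield <- smooth_field(nr, nc, 1.5 * scenario$smoothing_scale,
                         scenario$seed + 3L)
  mfield <- smooth_field(nr, nc, 1.5 * scenario$smoothing_scale,
                         scenario$seed + 4L)
  land <- matrix(NA_integer_, nr, nc)
  n_in <- sum(inside)
  land[inside] <- 2L                              # rural default
  if (scenario$water_fraction > 0) {
    thr <- stats::quantile(wfield[inside], scenario$water_fraction)
    land[inside & wfield <= thr] <- 4L
  }
  rest <- inside & land != 4L
  if (scenario$mountain_fraction > 0) {
    p_mnt <- scenario$mountain_fraction * n_in / sum(rest)
    thr <- stats::quantile(mfield[rest], 1 - p_mnt)
    land[rest & mfield > thr] <- 3L
  }
  land[inside & land == 2L & urb > 0.55] <- 1L    # urban

  gr <- function(m) hr_grid(m, cell_size = 1000, crs_tag = "synthetic")
  boundary <- gr(matrix(as.numeric(inside), nr, nc))
  urb_g <- urb; urb_g[!inside] <- NA
  landform <- gr(land * 1.0)
  attr(landform, "levels") <- landform_levels
  list(boundary = boundary, landform = landform, urbanization = gr(urb_g))
}

# Ground-truth factor structure of the 13 canonical indicators.
# loading_urb: loading on the standardized urbanization field, with the sign
# of the indicator's risk direction so that direction is recoverable as the
# sign of the correlation with urbanization. group/loading_grp: one of three
# shared secondary fields (socio-economic, demographic, environmental) that
# give the correlation matrix a multi-component structure.
indicator_truth <- function() {
  df <- canonical_indicators()
  df$loading_urb <- c(0.90,                                  # lst
                      0.80, 0.75, 0.85, 0.70,                # gdp..beds
                      0.55, 0.45, 0.40,                      # older..unemp
                      0.85, 0.90, 0.70, 0.35, 0.80)          # ndvi..constr
  df$loading_urb <- ifelse(df$direction == "negative",
                           -df$loading_urb, df$loading_urb)
  df$group <- c(3L, 1L, 1L, 1L, 1L, 2L, 2L, 2L, 3L, 1L, 3L, 3L, 2L)
  df$loading_grp <- c(0.20, 0.40, 0.45, 0.35, 0.45, 0.60, 0.60, 0.65,
                      0.40, 0.30, 0.55, 0.70, 0.45)
  df$drifts <- df$name %in% c("lst", "pop_density")
  df
}

#' Generate one year's indicator stack
#'
#' Produces all 13 canonical indicators as latent-factor fields over the
#' study region:
#' `indicator = loading_urb * z(urbanization) + loading_grp * group_field + noise`.
#' The urbanization loading carries the indicator's risk-direction sign; three
#' shared secondary fields (socio-economic, demographic, environmental) give
#' the indicator battery a multi-component correlation structure suited to
#' PCA. For years after the first, the urbanization loading of LST and
#' population density is amplified by `trend_per_year` per elapsed year —
#' urban heat and densification intensify, which is what moves cells across
#' adjacent risk-class boundaries. Per-year measurement noise is drawn
#' independently; the geography and secondary fields are fixed by the
#' scenario seed.
#'
#' @param scenario an [synthetic_scenario()].
#' @param region output of [make_study_region()] for the same scenario.
#' @param year one of `scenario$years`.
#' @param secondary keep the shared secondary fields? Setting `FALSE` zeroes
#'   their loadings, leaving a pure one-factor structure (useful for
#'   recovery tests).
#' @return an [hr_stack] with `attr(, "truth")`: the per-indicator
#'   ground-truth loadings actually applied.
#' @export
gen_indicator_stack <- function(scenario, region, year, secondary = TRUE) {
  stopifnot(inherits(scenario, "hr_scenario"))
  if (!year %in% scenario$years)
    stop("unknown year label ", year, "; scenario years are ",
         paste(scenario$years, collapse = ", "))
  nr <- scenario$shape[1]; nc <- scenario$shape[2]
  inside <- region$boundary$values != 0
  u <- region$urbanization$values
  uz <- u
  uz[inside] <- (u[inside] - mean(u[inside])) / stats::sd(u[inside])

  truth <- indicator_truth()
  if (!secondary) truth$loading_grp <- 0
  elapsed <- year - scenario$years[1]
  truth$loading_applied <- truth$loading_urb *
    ifelse(truth$drifts, 1 + scenario$trend_per_year * elapsed, 1)

  grp_fields <- lapply(1:3, function(g)
    smooth_field(nr, nc, scenario$smoothing_scale, scenario$seed + 10L + g))

  grids <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    noise <- with_seed(scenario$seed + 1000L * (year %% 1000L) + i,
                       matrix(stats::rnorm(nr * nc), nr, nc))
    v <- truth$loading_applied[i] * uz +
      truth$loading_grp[i] * grp_fields[[truth$group[i]]] +
      scenario$noise_sd * noise
    v[!inside] <- NA
    grids[[i]] <- hr_grid(v, cell_size = 1000, crs_tag = "synthetic")
  }
  st <- hr_stack(grids, specs_from_frame(truth[, 1:4]), year = year)
  attr(st, "truth") <- truth
  st
}

#' Evolve a categorical map by a Markov chain with optional spatial mixing
#'
#' Each unmasked cell transitions independently according to the
#' row-stochastic matrix `P`; afterwards, each cell adopts the modal class of
#' its 5 x 5 neighbourhood with probability `spatial_mixing`, which injects
#' the spatial autocorrelation a cellular automaton expects. With
#' `spatial_mixing = 0` the empirical one-step transition frequencies converge
#' to `P` as the cell count grows.
#'
#' @param P k x k row-stochastic matrix (rows sum to 1 within 1e-9).
#' @param init [hr_grid] of integer classes in `1..k` (`NA` = nodata).
#' @param steps number of steps to simulate.
#' @param seed integer seed.
#' @param spatial_mixing probability in `[0, 1]` of the neighbourhood-mode
#'   override.
#' @return list of `steps` class [hr_grid]s (the initial map is not included).
#' @export
gen_markov_series <- function(P, init, steps, seed = 1L, spatial_mixing = 0) {
  P <- as.matrix(P)
  k <- nrow(P)
  if (ncol(P) != k) stop("P must be square")
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-9))
    stop("P must be row-stochastic (rows summing to 1)")
  stopifnot(is_hr_grid(init), steps >= 1, spatial_mixing >= 0,
            spatial_mixing <= 1)
  cls <- init$values
  present <- unique(cls[!is.na(cls)])
  if (length(present) && (any(present < 1) || any(present > k) ||
                          any(present != round(present))))
    stop("init classes must be integers in 1..", k)
  cumP <- t(apply(P, 1, cumsum))
  valid <- !is.na(cls)
  out <- vector("list", steps)
  with_seed(seed, {
    for (s in seq_len(steps)) {
      u <- matrix(stats::runif(length(cls)), nrow(cls), ncol(cls))
      nxt <- cls
      for (c in seq_len(k)) {
        sel <- valid & cls == c
        if (any(sel))
          nxt[sel] <- findInterval(u[sel], cumP[c, ], left.open = TRUE) + 1L
      }
      if (spatial_mixing > 0) {
        counts <- lapply(seq_len(k), function(c) {
          m <- matrix(0, nrow(cls), ncol(cls))
          m[valid & nxt == c] <- 1
          box_sum(m, 2L)
        })
        best <- counts[[1]]; modal <- matrix(1L, nrow(cls), ncol(cls))
        for (c in seq_len(k)[-1]) {
          better <- counts[[c]] > best
          modal[better] <- c
          best[better] <- counts[[c]][better]
        }
        mix <- valid & matrix(stats::runif(length(cls)), nrow(cls),
                              ncol(cls)) < spatial_mixing
        nxt[mix] <- modal[mix]
      }
      cls <- nxt
      g <- hr_grid(cls * 1.0, cell_size = init$cell_size,
                   origin = init$origin, crs_tag = init$crs_tag)
      out[[s]] <- g
    }
  })
  out
}
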