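# Shared test fixtures, all built in code.

ref_csv <- function(name)
  utils::read.csv(system.file("extdata", "reference", name,
                              package = "heatrisk"))

# small random grid with a few nodata holes
random_grid <- function(nr = 16, nc = 12, seed = 1, cell_size = 1000,
                        origin = NULL, crs = "test", holes = 3) {
  set.seed(seed)
  m <- matrix(runif(nr * nc, -5, 20), nr, nc)
  if (holes > 0) m[sample(length(m), holes)] <- NA
  hr_grid(m, cell_size = cell_size, origin = origin, crs_tag = crs)
}

# class map on an nr x nc grid from an integer matrix (NA allowed)
classmap_from <- function(m, year = NA_integer_) {
  as_classmap(hr_grid(m * 1.0, cell_size = 1000), year = year)
}

# small coherent multi-year class-map series: classify a synthetic risk
# surface, then evolve it under a known adjacent-level transition matrix
coherent_series <- function(seed, shape = c(96, 96), steps = 2,
                            spatial_mixing = 0.3) {
  sc <- synthetic_scenario(shape = shape, seed = seed)
  reg <- make_study_region(sc)
  st <- normalize_stack(gen_indicator_stack(sc, reg, 2010))
  w <- pca_weights(stack_observations(st), canonical_indicators())
  rm0 <- compute_hhr(st$grids[["lst"]],
                     composite_score(st, w, "social_vulnerability"),
                     composite_score(st, w, "exposure"), 2010)
  cm0 <- classify_risk(rm0)
  P <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5) if (abs(i - j) == 1) P[i, j] <- 0.08
  P[abs(row(P) - col(P)) > 1] <- 0.005
  diag(P) <- 1 - rowSums(P)
  ser <- gen_markov_series(P, cm0$classes, steps, seed = seed + 99,
                           spatial_mixing = spatial_mixing)
  maps <- c(list(cm0), lapply(ser, as_classmap))
  for (i in seq_along(maps)) maps[[i]]$year <- 2010L + 5L * (i - 1L)
  list(maps = maps, P = P)
}

# independent shuffled-map kappa baseline: same marginals, random locations
shuffled_kappa <- function(truth, seed) {
  v <- truth$classes$values
  ok <- !is.na(v)
  set.seed(seed)
  v2 <- v
  v2[ok] <- sample(v[ok])
  shuf <- truth
  shuf$classes$values <- v2
  kappa_agreement(shuf, truth)$kappa
}

# brute-force Jenks oracle: enumerate all contiguous partitions of the
# sorted values into k classes and return the minimal total within-class SSD
jenks_bruteforce <- function(values, k) {
  v <- sort(values)
  n <- length(v)
  ssd <- function(x) sum((x - mean(x))^2)
  best <- Inf
  best_breaks <- NULL
  cuts <- utils::combn(n - 1, k - 1, simplify = FALSE)
  if (k == 1) cuts <- list(integer(0))
  for (cut in cuts) {
    bounds <- c(0, cut, n)
    tot <- 0
    for (c in seq_len(k))
      tot <- tot + ssd(v[(bounds[c] + 1):bounds[c + 1]])
    if (tot < best - 1e-12) {
      best <- tot
      best_breaks <- if (k > 1) v[cut + 1] else numeric(0)
    }
  }
  list(ssd = best, thresholds = best_breaks)
}
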