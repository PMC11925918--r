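# From-scratch CA-Markov: transition-probability estimation between two
# dated class maps, neighbourhood suitability surfaces, and iterative
# demand-driven allocation of the projected class areas.

#' Estimate a class transition model from two dated maps
#'
#' Cross-tabulates the two maps and row-normalizes the counts into the
#' transition probability matrix `P` (`P[i, j]` = probability that a cell at
#' level `i` on the first date is at level `j` on the second). A class absent
#' at the first date gets an identity row: it is assumed to stay itself.
#'
#' @param map1,map2 aligned `hr_classmap`s sharing the level set.
#' @return an object of class `hr_transition_model`: `states`, `counts`, `P`,
#'   `period` (years between the maps, when both carry year labels).
#' @export
estimate_transition <- function(map1, map2) {
  acc <- transition_accounting(map1, map2)
  counts <- acc$counts
  k <- nrow(counts)
  P <- counts / pmax(rowSums(counts), 1)
  empty <- rowSums(counts) == 0
  if (any(empty)) P[empty, ] <- diag(k)[empty, , drop = FALSE]
  period <- if (!is.na(map1$year) && !is.na(map2$year))
    map2$year - map1$year else NA_integer_
  structure(list(states = acc$levels, counts = counts, P = P,
                 period = period),
            class = "hr_transition_model")
}

#' @export
print.hr_transition_model <- function(x, ...) {
  cat(sprintf("<hr_transition_model> %d states, period %s\n",
              length(x$states), x$period))
  print(round(x$P, 3))
  invisible(x)
}

#' Markov projection of class areas
#'
#' Projects the aggregate class composition forward: `S_{t+n} = S_t P^n`.
#' The total area is conserved because `P` is row-stochastic.
#'
#' @param areas per-class cell counts (length = number of states).
#' @param model an `hr_transition_model` (or a row-stochastic matrix).
#' @param steps number of applications of `P`.
#' @return named numeric vector of expected per-class counts.
#' @export
project_markov <- function(areas, model, steps = 1L) {
  P <- if (inherits(model, "hr_transition_model")) model$P else as.matrix(model)
  areas <- as.numeric(areas)
  if (length(areas) != nrow(P))
    stop("areas length ", length(areas), " does not match ", nrow(P), " states")
  if (any(areas < 0)) stop("areas must be nonnegative")
  out <- matrix(areas, 1)
  for (s in seq_len(steps)) out <- out %*% P
  stats::setNames(as.numeric(out), rownames(P))
}

#' Neighbourhood suitability atlas
#'
#' For each class, the suitability of a cell is the fraction of valid cells
#' in the (default 5 x 5) Moore window around it — centre included, windows
#' truncated at edges, nodata excluded from numerator and denominator —
#' currently holding that class. Per cell the suitabilities across classes
#' sum to 1: they partition the window.
#'
#' @param classmap an `hr_classmap`.
#' @param filter_size odd window edge length (default 5).
#' @return an object of class `hr_suitability`: list of per-class [hr_grid]s
#'   in `[0, 1]` plus the filter size.
#' @export
build_suitability <- function(classmap, filter_size = 5L) {
  stopifnot(inherits(classmap, "hr_classmap"))
  if (filter_size %% 2 != 1 || filter_size < 3)
    stop("filter_size must be an odd integer >= 3")
  half <- (filter_size - 1L) %/% 2L
  cl <- classmap$classes$values
  valid <- !is.na(cl)
  denom <- box_count(valid, half)
  g <- classmap$classes
  surfaces <- lapply(seq_along(classmap$levels), function(k) {
    m <- matrix(0, nrow(cl), ncol(cl))
    m[valid & cl == k] <- 1
    s <- box_sum(m, half) / pmax(denom, 1)
    s[!valid] <- NA
    hr_grid(s, cell_size = g$cell_size, origin = g$origin, crs_tag = g$crs_tag)
  })
  names(surfaces) <- classmap$levels
  structure(list(surfaces = surfaces, filter_size = as.integer(filter_size)),
            class = "hr_suitability")
}

#' CA-Markov simulation settings
#'
#' @param iterations number of annual allocation cycles (default 10).
#' @param filter_size odd Moore-window edge for the suitability filter
#'   (default 5).
#' @param seed integer seed for tie-breaking jitter.
#' @param base_year,target_year optional labels recorded on the output.
#' @return an object of class `hr_sim_config`.
#' @export
simulation_config <- function(iterations = 10L, filter_size = 5L, seed = 1L,
                              base_year = NA_integer_,
                              target_year = NA_integer_) {
  if (iterations < 1) stop("iterations must be >= 1")
  if (filter_size %% 2 != 1 || filter_size < 3)
    stop("filter_size must be an odd integer >= 3")
  structure(list(iterations = as.integer(iterations),
                 filter_size = as.integer(filter_size),
                 seed = as.integer(seed),
                 base_year = as.integer(base_year),
                 target_year = as.integer(target_year)),
            class = "hr_sim_config")
}

#' Simulate one full CA-Markov transition
#'
#' Allocates the Markov-projected class demand spatially, in
#' `config$iterations` annual cycles. Each cycle: (a) the cumulative demand
#' after cycle `m` of `M` is `S_0 ((1 - m/M) I + (m/M) P)` — a linear
#' interpolation from the identity to the full one-period matrix `P`, whose
#' last cycle enforces the exact terminal Markov demand (fractional matrix
#' powers are ill-defined for some `P`); (b) the suitability atlas is rebuilt
#' from the current map with the configured Moore filter; (c) every
#' cell-class pair is scored `suitability_k(cell) * P[current_class, k]`;
#' (d) cells are greedily assigned in descending score order until every
#' class meets its demand, ties broken by a seeded uniform jitter. Masked
#' cells never change and carry no demand; the unmasked cell count is
#' conserved exactly.
#'
#' @param base the starting `hr_classmap`.
#' @param model `hr_transition_model` for one full period.
#' @param config an [simulation_config()].
#' @return the simulated `hr_classmap` (thresholds inherited from `base`).
#' @export
simulate_ca_markov <- function(base, model, config = simulation_config()) {
  stopifnot(inherits(base, "hr_classmap"),
            inherits(model, "hr_transition_model"),
            inherits(config, "hr_sim_config"))
  k <- length(model$states)
  if (length(base$levels) != k)
    stop("base map levels do not match the transition model states")
  P <- model$P
  cl <- base$classes$values
  valid <- !is.na(cl)
  n <- sum(valid)
  if (n == 0) stop("base map has no unmasked cells")
  areas0 <- vapply(seq_len(k), function(c) sum(cl[valid] == c), numeric(1))
  M <- config$iterations

  with_seed(config$seed, {
    for (m in seq_len(M)) {
      t <- m / M
      Pm <- (1 - t) * diag(k) + t * P
      demand <- round_preserving_sum(as.numeric(areas0 %*% Pm), n)
      if (sum(demand) != n)
        stop("infeasible class demand: ", sum(demand), " cells for ", n)

      # rebuild suitability from the *current* map
      cur_map <- base
      cur_map$classes$values <- cl
      suit <- build_suitability(cur_map, config$filter_size)

      idx <- which(valid)
      cur <- cl[idx]
      scores <- matrix(0, length(idx), k)
      for (c in seq_len(k))
        scores[, c] <- suit$surfaces[[c]]$values[idx] * P[cur, c]
      scores <- scores + matrix(stats::runif(length(scores), 0, 1e-9),
                                nrow(scores), ncol(scores))

      ord <- order(scores, decreasing = TRUE)     # over the cell x class grid
      cand_cell <- ((ord - 1L) %% length(idx)) + 1L
      cand_class <- ((ord - 1L) %/% length(idx)) + 1L
      newcls <- integer(length(idx))
      left <- demand
      assigned <- 0L
      for (q in seq_along(ord)) {
        cell <- cand_cell[q]; cc <- cand_class[q]
        if (newcls[cell] == 0L && left[cc] > 0L) {
          newcls[cell] <- cc
          left[cc] <- left[cc] - 1L
          assigned <- assigned + 1L
          if (assigned == length(idx)) break
        }
      }
      cl[idx] <- newcls
    }
  })
  out <- base
  out$classes$values[] <- cl
  out$year <- config$target_year
  out
}

#' End-to-end prediction from two observed maps
#'
#' Estimates the transition model between two dated class maps and applies it
#' once forward from the later map with [simulate_ca_markov()], assuming the
#' transition regime is stationary.
#'
#' @param map_t0,map_t1 aligned `hr_classmap`s (earlier, later).
#' @param config an [simulation_config()].
#' @return the predicted `hr_classmap`.
#' @export
predict_risk <- function(map_t0, map_t1, config = simulation_config()) {
  model <- estimate_transition(map_t0, map_t1)
  simulate_ca_markov(map_t1, model, config)
}
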