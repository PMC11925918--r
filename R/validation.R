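# Map-agreement validation: Cohen's kappa with a large-sample significance
# test, and the iteration-count robustness sweep.

#' Cohen's kappa between two class maps
#'
#' Chance-corrected agreement between two aligned categorical maps:
#' `kappa = (p_o - p_e) / (1 - p_e)` with `p_o` the observed diagonal share
#' of the confusion matrix and `p_e` the agreement expected from the
#' marginals alone. Significance uses the large-sample normal deviate of
#' kappa under the independence null (the standard test that the agreement
#' exceeds chance). Cells masked in either map are excluded pairwise.
#'
#' @param map_a,map_b aligned `hr_classmap`s (or integer [hr_grid]s /
#'   matrices with matching shapes).
#' @return an object of class `hr_kappa`: `kappa`, `z`, `p_value`,
#'   `confusion`, `observed_agreement`, `expected_agreement`, `n`.
#' @export
kappa_agreement <- function(map_a, map_b) {
  get_vals <- function(m) {
    if (inherits(m, "hr_classmap")) m$classes$values
    else if (is_hr_grid(m)) m$values
    else if (is.matrix(m)) m
    else stop("maps must be hr_classmap, hr_grid or matrix")
  }
  a <- get_vals(map_a); b <- get_vals(map_b)
  if (!identical(dim(a), dim(b)))
    stop("maps have different shapes: ", paste(dim(a), collapse = "x"),
         " vs ", paste(dim(b), collapse = "x"))
  if (inherits(map_a, "hr_classmap") && inherits(map_b, "hr_classmap"))
    stop_if_misaligned(map_a$classes, map_b$classes, "class maps")
  ok <- !is.na(a) & !is.na(b)
  n <- sum(ok)
  if (n == 0) stop("maps have no jointly unmasked cells")
  states <- sort(unique(c(a[ok], b[ok])))
  conf <- table(factor(a[ok], levels = states), factor(b[ok], levels = states))
  conf <- matrix(as.numeric(conf), length(states), length(states),
                 dimnames = list(a = states, b = states))
  p_o <- sum(diag(conf)) / n
  pr <- rowSums(conf) / n
  pc <- colSums(conf) / n
  p_e <- sum(pr * pc)
  if (p_e >= 1)
    stop("expected agreement is 1 (both maps constant); kappa undefined")
  kappa <- (p_o - p_e) / (1 - p_e)
  # large-sample variance under the independence null (Fleiss)
  var0 <- (p_e + p_e^2 - sum(pr * pc * (pr + pc))) / (n * (1 - p_e)^2)
  z <- if (var0 > 0) kappa / sqrt(var0) else NA_real_
  p_value <- if (is.na(z)) NA_real_ else 2 * stats::pnorm(-abs(z))
  structure(list(kappa = kappa, z = z, p_value = p_value, confusion = conf,
                 observed_agreement = p_o, expected_agreement = p_e, n = n),
            class = "hr_kappa")
}

#' @export
print.hr_kappa <- function(x, ...) {
  cat(sprintf("<hr_kappa> kappa %.3f (p_o %.3f, p_e %.3f, n %d), z %.2f, p %.3g\n",
              x$kappa, x$observed_agreement, x$expected_agreement, x$n,
              x$z, x$p_value))
  invisible(x)
}

#' Robustness of the prediction to the iteration count
#'
#' Re-runs the CA-Markov hindcast for each iteration count and scores each
#' prediction against the observed truth map with Cohen's kappa. A stable
#' model shows nearly identical kappa across nearby iteration counts.
#'
#' @param map_t0,map_t1 the two calibration `hr_classmap`s.
#' @param truth the observed `hr_classmap` the hindcasts are scored against.
#' @param iteration_counts integer vector of iteration settings (may be
#'   empty).
#' @param filter_size,seed forwarded to [simulation_config()].
#' @return data.frame with columns `iterations`, `kappa`, `p_value`, sorted
#'   by `iterations`.
#' @export
robustness_sweep <- function(map_t0, map_t1, truth, iteration_counts,
                             filter_size = 5L, seed = 1L) {
  iteration_counts <- sort(as.integer(iteration_counts))
  rows <- lapply(iteration_counts, function(it) {
    pred <- predict_risk(map_t0, map_t1,
                         simulation_config(iterations = it,
                                           filter_size = filter_size,
                                           seed = seed))
    k <- kappa_agreement(pred, truth)
    data.frame(iterations = it, kappa = k$kappa, p_value = k$p_value)
  })
  if (!length(rows))
    return(data.frame(iterations = integer(0), kappa = numeric(0),
                      p_value = numeric(0)))
  do.call(rbind, rows)
}
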