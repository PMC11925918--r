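# Indicator normalization, sampling-adequacy diagnostics and PCA-based
# weighting of the social-vulnerability and exposure batteries.

#' Min-max normalize an indicator grid
#'
#' Rescales an indicator onto `[0.01, 1.01]` over its unmasked cells:
#' positive-direction indicators map their minimum to 0.01 and maximum to
#' 1.01 (`(X - MIN)/(MAX - MIN) + 0.01`); negative-direction indicators are
#' reversed (`(MAX - X)/(MAX - MIN) + 0.01`), so that after normalization a
#' larger value always means more risk. The 0.01 offset keeps every
#' normalized indicator strictly positive, which matters because the
#' composite index is a product.
#'
#' @param grid an [hr_grid].
#' @param direction `"positive"` or `"negative"` (see [indicator_spec()]).
#' @return the normalized [hr_grid], range `[0.01, 1.01]`.
#' @export
normalize_indicator <- function(grid, direction = c("positive", "negative")) {
  stopifnot(is_hr_grid(grid))
  direction <- match.arg(direction)
  v <- grid$values
  r <- range(v, na.rm = TRUE)
  if (!is.finite(r[1]) || r[2] - r[1] <= 0)
    stop("cannot normalize a constant grid (no spread between MIN and MAX)")
  out <- if (direction == "positive") (v - r[1]) / (r[2] - r[1]) + 0.01
  else (r[2] - v) / (r[2] - r[1]) + 0.01
  grid$values <- out
  grid
}

#' Normalize every layer of a stack
#'
#' Applies [normalize_indicator()] per layer using each spec's direction.
#'
#' @param stack an [hr_stack].
#' @return the normalized [hr_stack].
#' @export
normalize_stack <- function(stack) {
  stopifnot(inherits(stack, "hr_stack"))
  for (i in seq_along(stack$grids))
    stack$grids[[i]] <- normalize_indicator(stack$grids[[i]],
                                            stack$specs[[i]]$direction)
  stack
}

#' Sample a stack into an observation matrix
#'
#' Extracts unmasked cells as rows of an observation x indicator matrix for
#' the multivariate diagnostics and PCA. When the number of valid cells
#' exceeds `cap`, cells are thinned on a regular grid (every k-th valid cell
#' in row-major order) for tractability.
#'
#' @param stack an [hr_stack] (or list of stacks, pooled over years).
#' @param categories indicator categories to keep (default: social
#'   vulnerability and exposure, the weighted batteries).
#' @param cap maximum number of rows (default 50000).
#' @return numeric matrix with one column per kept indicator.
#' @export
stack_observations <- function(stack,
                               categories = c("social_vulnerability",
                                              "exposure"),
                               cap = 50000L) {
  stacks <- if (inherits(stack, "hr_stack")) list(stack) else stack
  mats <- lapply(stacks, function(st) {
    keep <- vapply(st$specs, function(s) s$category %in% categories,
                   logical(1))
    mask <- stack_mask(st)
    m <- vapply(st$grids[keep], function(g) g$values[!mask],
                numeric(sum(!mask)))
    colnames(m) <- names(st$grids)[keep]
    m
  })
  out <- do.call(rbind, mats)
  if (nrow(out) > cap) {
    idx <- unique(round(seq(1L, nrow(out), length.out = cap)))
    out <- out[idx, , drop = FALSE]
  }
  out
}

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' `KMO = sum(r^2) / (sum(r^2) + sum(u^2))` over off-diagonal pairs, where
#' `r` are the simple correlations and `u` the anti-image (partial)
#' correlations obtained from the inverse correlation matrix. Values above
#' 0.7 indicate the indicator battery shares enough common variance for PCA
#' to be meaningful; a battery of mutually independent indicators scores
#' around 0.5.
#'
#' @param data observation x indicator matrix (at least 2 columns).
#' @return list with elements `kmo`, `n_obs`, `n_vars`.
#' @export
kmo_test <- function(data) {
  data <- as.matrix(data)
  p <- ncol(data)
  if (p < 2L) stop("KMO needs at least 2 indicators")
  R <- stats::cor(data)
  Rinv <- tryCatch(solve(R), error = function(e)
    stop("correlation matrix is singular; KMO undefined"))
  d <- 1 / sqrt(diag(Rinv))
  U <- -Rinv * outer(d, d)                        # partial correlations
  off <- upper.tri(R)
  kmo <- sum(R[off]^2) / (sum(R[off]^2) + sum(U[off]^2))
  list(kmo = kmo, n_obs = nrow(data), n_vars = p)
}

#' Bartlett's test of sphericity
#'
#' Tests the null that the indicator correlation matrix is the identity:
#' `chi2 = -((n - 1) - (2p + 5)/6) * ln det(R)` on `p(p-1)/2` degrees of
#' freedom. A significant result licenses factoring the battery.
#'
#' @param data observation x indicator matrix with more rows than columns.
#' @return list with `chi2`, `df`, `p_value`, `n_obs`, `n_vars`.
#' @export
bartlett_sphericity <- function(data) {
  data <- as.matrix(data)
  n <- nrow(data); p <- ncol(data)
  if (n <= p) stop("Bartlett's test needs more observations than indicators")
  R <- stats::cor(data)
  detR <- det(R)
  if (detR <= 0)
    stop("correlation matrix is not positive definite; sphericity test undefined")
  chi2 <- -((n - 1) - (2 * p + 5) / 6) * log(detR)
  df <- p * (p - 1) / 2
  list(chi2 = chi2, df = df,
       p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
       n_obs = n, n_vars = p)
}

#' PCA-based indicator weights
#'
#' Derives one weight per social-vulnerability / exposure indicator from a
#' correlation-matrix PCA of the observation matrix. Components are retained
#' by the eigenvalue-greater-than-1 rule (or a fixed count); each retained
#' loading `a_ij` is converted to a score coefficient
#' `b_ij = |a_ij| / sqrt(X_j)` (eigenvalue `X_j`), the coefficients are
#' averaged with the components' variance-contribution rates `PC_j` as
#' weights, and the result is renormalized to sum to 1 *within each
#' category*, so the vulnerability battery and the exposure battery each
#' carry unit total weight. Absolute loadings are used because the sign of an
#' indicator's risk contribution is already carried by its normalization
#' direction.
#'
#' The hazard layer is never weighted: a single-indicator battery needs no
#' weights, and the composite index multiplies hazard in directly.
#'
#' @param data observation x indicator matrix (columns named as in `specs`).
#' @param specs list of [indicator_spec] (or [canonical_indicators()] frame)
#'   covering the columns of `data`; hazard entries are dropped.
#' @param retention `"eigenvalue_gt_1"` (default) or an integer number of
#'   components.
#' @param b_formula `"abs_a_over_sqrt_x"` (default, `|a_ij|/sqrt(X_j)`) or
#'   `"a_over_x"` (`|a_ij|/X_j`).
#' @return an object of class `hr_pca_weights`: eigenvalues, loadings,
#'   per-component contribution percentages, cumulative contributions, score
#'   coefficients, per-indicator weights and the retained-component count.
#' @export
pca_weights <- function(data, specs, retention = "eigenvalue_gt_1",
                        b_formula = c("abs_a_over_sqrt_x", "a_over_x")) {
  b_formula <- match.arg(b_formula)
  if (is.data.frame(specs)) specs <- specs_from_frame(specs)
  specs <- Filter(function(s) s$category != "hazard", specs)
  nm <- vapply(specs, `[[`, "", "name")
  data <- as.matrix(data)
  if (!all(nm %in% colnames(data)))
    stop("observation matrix is missing indicator column(s): ",
         paste(setdiff(nm, colnames(data)), collapse = ", "))
  X <- data[, nm, drop = FALSE]
  p <- ncol(X)

  R <- stats::cor(X)
  eig <- eigen(R, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  contribution <- 100 * ev / p
  cumulative <- cumsum(contribution)

  n_retained <- if (identical(retention, "eigenvalue_gt_1")) sum(ev > 1)
  else as.integer(retention)
  if (is.na(n_retained) || n_retained < 1L)
    stop("component retention selected fewer than 1 component")
  n_retained <- min(n_retained, p)

  # loadings: eigenvector scaled by sqrt(eigenvalue)
  loadings <- sweep(eig$vectors, 2, sqrt(ev), `*`)
  dimnames(loadings) <- list(nm, paste0("PC", seq_len(p)))

  ret <- seq_len(n_retained)
  b <- switch(b_formula,
    abs_a_over_sqrt_x = sweep(abs(loadings[, ret, drop = FALSE]), 2,
                              sqrt(ev[ret]), `/`),
    a_over_x = sweep(abs(loadings[, ret, drop = FALSE]), 2, ev[ret], `/`))
  w_raw <- as.numeric(b %*% contribution[ret]) / sum(contribution[ret])

  category <- vapply(specs, `[[`, "", "category")
  weights <- w_raw
  for (cat in unique(category)) {
    sel <- category == cat
    weights[sel] <- w_raw[sel] / sum(w_raw[sel])
  }
  names(weights) <- nm

  structure(list(eigenvalues = ev, loadings = loadings,
                 contribution = contribution, cumulative = cumulative,
                 score_coefficients = b, weights = weights,
                 category = stats::setNames(category, nm),
                 n_retained = n_retained, b_formula = b_formula),
            class = "hr_pca_weights")
}

#' @export
print.hr_pca_weights <- function(x, ...) {
  cat(sprintf("<hr_pca_weights> %d indicators, %d retained components (%.1f%% of variance)\n",
              length(x$weights), x$n_retained, x$cumulative[x$n_retained]))
  df <- data.frame(category = x$category, weight = round(x$weights, 4))
  print(df)
  invisible(x)
}

#' Weighted category score surface
#'
#' Collapses the normalized indicators of one category into a single surface
#' by the cellwise weighted sum `sum_i W_i * x_i`. Because the weights within
#' a category sum to 1 and each normalized indicator lies in `[0.01, 1.01]`,
#' the score does too.
#'
#' @param stack a *normalized* [hr_stack].
#' @param weights an `hr_pca_weights` from [pca_weights()] (or a named
#'   numeric vector of weights).
#' @param category `"social_vulnerability"` or `"exposure"`.
#' @return an [hr_grid] score surface.
#' @export
composite_score <- function(stack, weights,
                            category = c("social_vulnerability", "exposure")) {
  stopifnot(inherits(stack, "hr_stack"))
  category <- match.arg(category)
  w <- if (inherits(weights, "hr_pca_weights")) weights$weights else weights
  nm <- vapply(stack$specs, `[[`, "", "name")
  cats <- vapply(stack$specs, `[[`, "", "category")
  need <- nm[cats == category]
  miss <- setdiff(need, names(w))
  if (length(miss))
    stop("weights missing for indicator(s): ", paste(miss, collapse = ", "))
  ref <- stack$grids[[which(cats == category)[1]]]
  acc <- matrix(0, nrow(ref$values), ncol(ref$values))
  for (ind in need) acc <- acc + w[[ind]] * stack$grids[[ind]]$values
  mask <- stack_mask(stack)
  acc[mask] <- NA
  hr_grid(acc, cell_size = ref$cell_size, origin = ref$origin,
          crs_tag = ref$crs_tag)
}
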