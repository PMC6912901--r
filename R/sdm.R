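#' Uniform random background points
#'
#' @param grid An [sdm_grid()] landscape (missing cells excluded).
#' @param n Number of background points (default 10000).
#' @param seed Optional integer seed.
#' @return A `background_set`: list with `points` (x, y matrix), `method`,
#'   `n`, `seed`.
#' @export
uniform_background <- function(grid, n = 10000, seed = NULL) {
  design <- random_points(grid, n = n, seed = seed)
  structure(list(points = design$points, method = "uniform", n = n,
                 seed = seed),
            class = "background_set")
}

#' Targeted background points along survey trajectories
#'
#' Draws background points with the same spatial bias as the observation
#' process: a position uniform by length along the trajectories, a
#' perpendicular offset distance drawn from the detection model's density
#' `g`, and a side drawn uniformly. Points falling outside the landscape
#' extent are redrawn, so the empirical distance distribution of the set
#' matches `g` (up to edge effects).
#'
#' @param design A trajectory-bearing [survey_design()].
#' @param model A `detection_model` supplying the offset density.
#' @param grid An [sdm_grid()] defining the extent.
#' @param n Number of background points (default 10000).
#' @param seed Optional integer seed.
#' @return A `background_set` with `method = "targeted"`.
#' @export
targeted_background <- function(design, model, grid, n = 10000, seed = NULL) {
  stopifnot(inherits(design, "survey_design"),
            inherits(model, "detection_model"),
            inherits(grid, "sdm_grid"))
  if (is.null(design$trajectories))
    stop("targeted background needs a trajectory design")
  seg <- trajectory_segments(design$trajectories)
  len <- sqrt((seg[, 3] - seg[, 1])^2 + (seg[, 4] - seg[, 2])^2)
  if (sum(len) <= 0) stop("trajectories have zero length")
  if (!is.null(seed)) set.seed(seed)
  ext <- grid_extent(grid)
  pts <- matrix(NA_real_, 0, 2)
  while (nrow(pts) < n) {
    m <- n - nrow(pts)
    k <- sample.int(nrow(seg), m, replace = TRUE, prob = len)
    t <- stats::runif(m)
    bx <- seg[k, 1] + t * (seg[k, 3] - seg[k, 1])
    by <- seg[k, 2] + t * (seg[k, 4] - seg[k, 2])
    ux <- (seg[k, 3] - seg[k, 1]) / len[k]
    uy <- (seg[k, 4] - seg[k, 2]) / len[k]
    side <- sample(c(-1, 1), m, replace = TRUE)
    off <- sample_detection_distance(model, m)
    x <- bx - side * uy * off
    y <- by + side * ux * off
    inside <- x >= ext["xmin"] & x <= ext["xmax"] &
      y >= ext["ymin"] & y <= ext["ymax"]
    pts <- rbind(pts, cbind(x[inside], y[inside]))
  }
  structure(list(points = pts[seq_len(n), , drop = FALSE],
                 method = "targeted", n = n, seed = seed),
            class = "background_set")
}

#' @export
print.background_set <- function(x, ...) {
  cat(sprintf("<background_set> %s, %d points\n", x$method, nrow(x$points)))
  invisible(x)
}

#' Fit a presence-only SDM by weighted logistic regression
#'
#' Fits the Maxent-equivalent model: a logistic regression contrasting
#' presence records (response 1, weight 1) against background points
#' (response 0, weight `background_weight`). With a large background weight
#' the slope estimates converge to those of the inhomogeneous Poisson point
#' process likelihood with the background points as quadrature nodes
#' (infinitely weighted logistic regression). Features are linear in the
#' standardized covariates; optionally the cell's distance to the survey
#' trajectories enters as one extra linear predictor (the
#' distance-to-trajectories bias correction), internally scaled to units of
#' 100 m for conditioning and reported back per meter.
#'
#' @param presences Data frame of presence records with columns `x`, `y`
#'   (and optionally `sex`).
#' @param background A `background_set`.
#' @param stack A standardized [covariate_stack()].
#' @param distance Optional distance grid from [distance_to_trajectories()];
#'   supplying it switches on the distance-covariate correction.
#' @param correction Correction label stored on the fit: `"none"`,
#'   `"targeted"` or `"distance"`. Defaults to `"distance"` when a distance
#'   grid is supplied, else to the background set's method (`"targeted"`
#'   background implies the targeted correction).
#' @param background_weight Weight of each background point in the logistic
#'   likelihood (default 1000).
#' @return An `sdm_fit` with elements `coefficients` (per covariate),
#'   `distance_coefficient` (per meter; `NULL` unless correcting by
#'   distance), `intercept`, `correction`, `log_likelihood`, `n_presence`,
#'   `n_background`, `converged`.
#' @export
fit_sdm <- function(presences, background, stack, distance = NULL,
                    correction = NULL, background_weight = 1000) {
  stopifnot(inherits(background, "background_set"),
            inherits(stack, "covariate_stack"))
  if (!all(c("x", "y") %in% names(presences)))
    stop("`presences` must have columns x and y")
  if (nrow(presences) < 5)
    stop("need at least 5 presence records")
  if (!stack$standardized)
    stop("covariates must be standardized before fitting")
  if (is.null(correction))
    correction <- if (!is.null(distance)) "distance"
                  else if (background$method == "targeted") "targeted"
                  else "none"
  correction <- match.arg(correction, c("none", "targeted", "distance"))
  if (correction == "distance" && is.null(distance))
    stop("the distance correction needs a distance grid")

  pxy <- as_xy_matrix(presences)
  bxy <- background$points
  xy <- rbind(pxy, bxy)
  X <- vapply(stack$grids, function(g) extract_values(g, xy),
              numeric(nrow(xy)))
  vars <- colnames(X)
  if (correction == "distance") {
    X <- cbind(X, .dist100 = extract_values(distance, xy) / 100)
  }
  y <- c(rep(1L, nrow(pxy)), rep(0L, nrow(bxy)))
  w <- c(rep(1, nrow(pxy)), rep(background_weight, nrow(bxy)))
  ok <- stats::complete.cases(X)
  X <- X[ok, , drop = FALSE]; y <- y[ok]; w <- w[ok]
  if (sum(y) < ncol(X) + 1)
    stop("fewer presences than coefficients: model is unidentifiable")

  Xd <- cbind("(Intercept)" = 1, X)
  fit <- suppressWarnings(
    stats::glm.fit(Xd, y, weights = w, family = stats::binomial())
  )
  if (!fit$converged)
    warning("weighted logistic fit did not converge (possible separation); ",
            "coefficients may be unreliable")
  cf <- fit$coefficients
  coefs <- cf[vars]
  bad <- is.na(coefs)
  if (any(bad))
    warning("coefficient(s) not estimable (collinearity): ",
            paste(vars[bad], collapse = ", "))
  mu_hat <- pmin(1 - 1e-12, pmax(1e-12, fit$fitted.values))
  ll <- sum(w * (y * log(mu_hat) + (1 - y) * log(1 - mu_hat)))
  dist_coef <- if (correction == "distance")
    unname(cf[".dist100"]) / 100 else NULL
  structure(list(
    coefficients = coefs,
    distance_coefficient = dist_coef,
    intercept = unname(cf["(Intercept)"]),
    correction = correction,
    background_method = background$method,
    background_weight = background_weight,
    log_likelihood = ll,
    n_presence = sum(y), n_background = sum(1 - y),
    converged = fit$converged
  ), class = "sdm_fit")
}

#' @export
print.sdm_fit <- function(x, ...) {
  cat(sprintf("<sdm_fit> correction: %s; %d presences vs %d background\n",
              x$correction, x$n_presence, x$n_background))
  cat("  coefficients:",
      paste(sprintf("%s=%.3f", names(x$coefficients), x$coefficients),
            collapse = ", "), "\n")
  if (!is.null(x$distance_coefficient))
    cat(sprintf("  distance coefficient: %.5f per m\n",
                x$distance_coefficient))
  invisible(x)
}

#' Predicted relative abundance map
#'
#' Evaluates the fitted model's raw (exponential) output on every cell and
#' divides by its landscape sum, giving per-cell relative abundances
#' \eqn{\mu_j} that sum to one. For distance-corrected fits the distance term
#' is set to zero by default (`zero_distance = TRUE`), i.e. the habitat-only
#' prediction.
#'
#' @param fit An `sdm_fit`.
#' @param stack The standardized [covariate_stack()] to predict on.
#' @param distance Distance grid, only needed when `zero_distance = FALSE`
#'   for a distance-corrected fit.
#' @param zero_distance Set the distance covariate to zero across the
#'   landscape (default `TRUE`).
#' @return An [sdm_grid()] of relative abundances summing to 1 over
#'   non-missing cells.
#' @export
predict_relative_abundance <- function(fit, stack, distance = NULL,
                                       zero_distance = TRUE) {
  stopifnot(inherits(fit, "sdm_fit"), inherits(stack, "covariate_stack"))
  missing_cov <- setdiff(names(fit$coefficients), names(stack$grids))
  if (length(missing_cov))
    stop("stack lacks covariate(s): ", paste(missing_cov, collapse = ", "))
  ref <- stack$grids[[1]]
  eta <- matrix(0, nrow(ref$values), ncol(ref$values))
  for (nm in names(fit$coefficients))
    eta <- eta + stack$grids[[nm]]$values * fit$coefficients[[nm]]
  if (!is.null(fit$distance_coefficient) && !zero_distance) {
    if (is.null(distance))
      stop("need a distance grid when zero_distance = FALSE")
    eta <- eta + distance$values * fit$distance_coefficient
  }
  raw <- exp(eta - max(eta, na.rm = TRUE))  # intercept-free; constant cancels
  mu <- raw / sum(raw, na.rm = TRUE)
  sdm_grid(mu, cell_size = ref$cell_size, origin = ref$origin)
}
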