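#' Survey design container
#'
#' @param kind `"random"`, `"systematic"` or `"subjective"`.
#' @param points For the random design: two-column matrix of sample points.
#' @param trajectories For transect/subjective designs: list of
#'   [trajectory()] objects.
#' @return An object of class `survey_design`.
#' @export
survey_design <- function(kind = c("random", "systematic", "subjective"),
                          points = NULL, trajectories = NULL) {
  kind <- match.arg(kind)
  if (kind == "random") {
    if (is.null(points) || !is.null(trajectories))
      stop("random designs carry `points` only")
    points <- as_xy_matrix(points)
  } else {
    if (is.null(trajectories) || !is.null(points))
      stop(sprintf("%s designs carry `trajectories` only", kind))
    if (inherits(trajectories, "trajectory"))
      trajectories <- list(trajectories)
    for (tr in trajectories) stopifnot(inherits(tr, "trajectory"))
  }
  structure(list(kind = kind, points = points, trajectories = trajectories),
            class = "survey_design")
}

#' @export
print.survey_design <- function(x, ...) {
  if (x$kind == "random")
    cat(sprintf("<survey_design> random, %d points\n", nrow(x$points)))
  else
    cat(sprintf("<survey_design> %s, %d trajectories, total length %.1f m\n",
                x$kind, length(x$trajectories),
                trajectory_length(x$trajectories)))
  invisible(x)
}

#' Systematic parallel transects over an extent
#'
#' Lays parallel transect lines across the landscape at a fixed spacing, with
#' the offset of the first line drawn uniformly in `[0, spacing)` and each
#' line clipped to the rectangular extent.
#'
#' @param extent Either an [sdm_grid()] or a numeric
#'   `c(xmin, xmax, ymin, ymax)`.
#' @param spacing Perpendicular distance between transects in meters
#'   (default 400).
#' @param orientation Transect direction in degrees from the x axis
#'   (default 0 = east--west lines).
#' @param offset Optional fixed offset of the first line in meters; if `NULL`
#'   it is drawn uniformly in `[0, spacing)` under `seed`.
#' @param seed Optional integer seed for the offset draw.
#' @return A systematic [survey_design()] (one trajectory per transect).
#' @export
systematic_transects <- function(extent, spacing = 400, orientation = 0,
                                 offset = NULL, seed = NULL) {
  if (inherits(extent, "sdm_grid")) extent <- grid_extent(extent)
  stopifnot(length(extent) == 4)
  names(extent) <- c("xmin", "xmax", "ymin", "ymax")
  if (spacing <= 0) stop("`spacing` must be positive")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(offset)) offset <- stats::runif(1, 0, spacing)

  th <- orientation * pi / 180
  u <- c(cos(th), sin(th))      # along-transect direction
  nvec <- c(-sin(th), cos(th))  # normal
  corners <- rbind(c(extent["xmin"], extent["ymin"]),
                   c(extent["xmax"], extent["ymin"]),
                   c(extent["xmin"], extent["ymax"]),
                   c(extent["xmax"], extent["ymax"]))
  proj <- corners %*% nvec
  start <- min(proj) + offset %% spacing
  levels <- if (start > max(proj)) numeric(0)
            else seq(start, max(proj), by = spacing)
  if (length(levels) == 0) {
    warning("spacing larger than extent: single central transect")
    levels <- mean(range(proj))
  }
  trajs <- list()
  for (lv in levels) {
    p0 <- lv * nvec
    tr <- clip_line_to_rect(p0, u, extent)
    if (!is.null(tr)) trajs[[length(trajs) + 1]] <- trajectory(tr)
  }
  if (length(trajs) == 0)
    stop("no transect intersects the extent")
  survey_design("systematic", trajectories = trajs)
}

# clip the infinite line p0 + t*u to the rectangle; returns 2x2 vertex matrix
clip_line_to_rect <- function(p0, u, ext) {
  tmin <- -Inf; tmax <- Inf
  for (dimn in 1:2) {
    lo <- ext[[if (dimn == 1) "xmin" else "ymin"]]
    hi <- ext[[if (dimn == 1) "xmax" else "ymax"]]
    if (abs(u[dimn]) < 1e-12) {
      if (p0[dimn] < lo || p0[dimn] > hi) return(NULL)
    } else {
      t1 <- (lo - p0[dimn]) / u[dimn]
      t2 <- (hi - p0[dimn]) / u[dimn]
      tmin <- max(tmin, min(t1, t2))
      tmax <- min(tmax, max(t1, t2))
    }
  }
  if (!(tmax > tmin)) return(NULL)
  rbind(p0 + tmin * u, p0 + tmax * u)
}

#' Uniform random survey points
#'
#' Samples point locations uniformly over the non-missing cells of the
#' landscape (cell drawn uniformly among non-missing cells, position uniform
#' within the cell).
#'
#' @param grid An [sdm_grid()] defining the landscape (missing cells are
#'   excluded).
#' @param n Number of points (default 2000).
#' @param seed Optional integer seed.
#' @return A random [survey_design()].
#' @export
random_points <- function(grid, n = 2000, seed = NULL) {
  stopifnot(inherits(grid, "sdm_grid"))
  if (n < 1) stop("`n` must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  ok <- which(!is.na(grid$values))
  if (length(ok) == 0) stop("landscape has no non-missing cells")
  centers <- cell_centers(grid)
  cells <- ok[sample.int(length(ok), n, replace = TRUE)]
  cs <- grid$cell_size
  pts <- centers[cells, , drop = FALSE] +
    cbind(stats::runif(n, -cs / 2, cs / 2), stats::runif(n, -cs / 2, cs / 2))
  survey_design("random", points = pts)
}

#' Distance from every cell center to the nearest trajectory
#'
#' Exact minimum Euclidean point-to-segment distance over all trajectory
#' segments of the design.
#'
#' @param grid An [sdm_grid()] giving the cells.
#' @param design A trajectory-bearing [survey_design()].
#' @return An [sdm_grid()] of distances in meters (0 on cells whose center
#'   lies on a trajectory).
#' @export
distance_to_trajectories <- function(grid, design) {
  stopifnot(inherits(grid, "sdm_grid"), inherits(design, "survey_design"))
  if (is.null(design$trajectories))
    stop("distance to trajectories is undefined for a point design")
  seg <- trajectory_segments(design$trajectories)
  ctr <- cell_centers(grid)
  d2 <- rep(Inf, nrow(ctr))
  px <- ctr[, 1]; py <- ctr[, 2]
  for (k in seq_len(nrow(seg))) {
    ax <- seg[k, 1]; ay <- seg[k, 2]; bx <- seg[k, 3]; by <- seg[k, 4]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx * vx + vy * vy
    if (L2 == 0) {
      dx <- px - ax; dy <- py - ay
    } else {
      t <- pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / L2))
      dx <- px - (ax + t * vx); dy <- py - (ay + t * vy)
    }
    d2 <- pmin(d2, dx * dx + dy * dy)
  }
  sdm_grid(matrix(sqrt(d2), nrow(grid$values), ncol(grid$values)),
           cell_size = grid$cell_size, origin = grid$origin)
}

# ---- detection models -------------------------------------------------------

#' Distance-decay detection model
#'
#' Represents the decay of sign detectability with distance `d` from the
#' observer's path through a density `g(d)` on `[0, truncation]`; the
#' detection probability is the normalized density `p(d) = g(d) / g(0)`
#' (1 on the path, 0 beyond the truncation distance).
#'
#' `detection_model()` builds a parametric model directly;
#' [fit_detection_model()] estimates one from a sample of observed
#' sign-to-trajectory distances.
#'
#' @param form `"exponential"` (rate parameter), `"half-normal"` (sigma), or
#'   `"empirical-spline"` (log-density spline; only via
#'   [fit_detection_model()]).
#' @param par Named parameter: `rate` for exponential, `sigma` for
#'   half-normal.
#' @param truncation Truncation distance in meters (default 300); signs
#'   farther than this are never observed.
#' @return An object of class `detection_model`.
#' @export
#' @examples
#' m <- detection_model("exponential", c(rate = 1/50))
#' detection_probability(m, c(0, 50, 1000))
detection_model <- function(form = c("exponential", "half-normal"),
                            par, truncation = 300) {
  form <- match.arg(form)
  if (truncation <= 0) stop("`truncation` must be positive")
  par <- unlist(par)
  need <- if (form == "exponential") "rate" else "sigma"
  if (!need %in% names(par) || par[[need]] <= 0)
    stop(sprintf("form '%s' needs a positive parameter '%s'", form, need))
  structure(list(form = form, par = par, truncation = truncation),
            class = "detection_model")
}

#' Fit a distance-decay detection model to observed distances
#'
#' Parametric forms are fitted by closed-form maximum likelihood; the
#' `"empirical-spline"` form fits a smooth log-density by Poisson regression
#' of binned distance counts on a natural-spline basis (a log-spline density
#' estimate).
#'
#' @param distances Sample of observed sign-to-trajectory distances (m).
#' @param form `"empirical-spline"`, `"exponential"` or `"half-normal"`.
#' @param truncation Truncation distance (m); observations beyond it are
#'   dropped with a warning.
#' @param df Spline degrees of freedom for the empirical form (default 4).
#' @param n_bins Histogram bins for the empirical form (default 30).
#' @return A `detection_model`.
#' @export
fit_detection_model <- function(distances,
                                form = c("empirical-spline", "exponential",
                                         "half-normal"),
                                truncation = 300, df = 4, n_bins = 30) {
  form <- match.arg(form)
  if (truncation <= 0) stop("`truncation` must be positive")
  d <- distances[is.finite(distances) & distances >= 0]
  if (any(d > truncation)) {
    warning(sprintf("%d distance(s) beyond the truncation distance dropped",
                    sum(d > truncation)))
    d <- d[d <= truncation]
  }
  if (form == "exponential") {
    if (length(d) < 2 || mean(d) <= 0) stop("need positive distances")
    return(detection_model("exponential", c(rate = 1 / mean(d)), truncation))
  }
  if (form == "half-normal") {
    if (length(d) < 2 || mean(d^2) <= 0) stop("need positive distances")
    return(detection_model("half-normal", c(sigma = sqrt(mean(d^2))),
                           truncation))
  }
  # empirical log-density spline
  if (length(d) < 20)
    stop("empirical-spline form needs at least 20 distances")
  if (stats::sd(d) == 0)
    stop("all distances identical: cannot fit a spline density")
  breaks <- seq(0, truncation, length.out = n_bins + 1)
  counts <- tabulate(findInterval(d, breaks, rightmost.closed = TRUE),
                     nbins = n_bins)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  basis <- splines::ns(mids, df = df)
  fit <- stats::glm(counts ~ basis, family = stats::poisson())
  pred_grid <- seq(0, truncation, length.out = 512)
  bg <- splines::ns(pred_grid, df = df,
                    knots = attr(basis, "knots"),
                    Boundary.knots = attr(basis, "Boundary.knots"))
  log_g <- cbind(1, bg) %*% stats::coef(fit)
  g <- exp(log_g - max(log_g))
  structure(list(form = "empirical-spline",
                 par = NULL, truncation = truncation,
                 spline = list(x = pred_grid, g = as.vector(g))),
            class = "detection_model")
}

#' @export
print.detection_model <- function(x, ...) {
  cat(sprintf("<detection_model> %s, truncation %g m", x$form, x$truncation))
  if (!is.null(x$par))
    cat(sprintf(" (%s)", paste(sprintf("%s=%.4g", names(x$par), x$par),
                               collapse = ", ")))
  cat("\n")
  invisible(x)
}

# un-normalized density g(d) of a detection model
detection_density <- function(model, d) {
  stopifnot(inherits(model, "detection_model"))
  g <- switch(model$form,
    "exponential" = model$par[["rate"]] * exp(-model$par[["rate"]] * d),
    "half-normal" = exp(-d^2 / (2 * model$par[["sigma"]]^2)),
    "empirical-spline" = stats::approx(model$spline$x, model$spline$g,
                                       xout = d, rule = 2)$y
  )
  g[d > model$truncation] <- 0
  g
}

#' Detection probability at a distance
#'
#' `p(d) = g(d) / g(0)`, so p(0) = 1 and p = 0 beyond the truncation
#' distance.
#'
#' @param model A `detection_model`.
#' @param d Distances in meters (vectorized, all >= 0).
#' @return Detection probabilities in `[0, 1]`.
#' @export
detection_probability <- function(model, d) {
  if (any(d < 0, na.rm = TRUE)) stop("distances must be non-negative")
  g0 <- detection_density(model, 0)
  pmin(1, detection_density(model, d) / g0)
}

# draw n distances from the detection density g on [0, truncation]
# (inverse-CDF on a fine grid; exact enough at 1e4 support points)
sample_detection_distance <- function(model, n) {
  xs <- seq(0, model$truncation, length.out = 10001)
  g <- detection_density(model, xs)
  cdf <- cumsum(g)
  cdf <- cdf / cdf[length(cdf)]
  stats::approx(cdf, xs, xout = stats::runif(n), rule = 2, ties = "ordered")$y
}

# ---- thinning ---------------------------------------------------------------

#' Thin simulated sign counts into presence-only records
#'
#' Applies the observation process to a realized count grid: each sign in a
#' cell is observed independently with the cell's detection probability
#' (binomial thinning), cells with zero observed signs are dropped, and each
#' observed sign becomes one presence record at its cell center (duplicate
#' records are kept, one row per sign).
#'
#' For trajectory designs the detection probability is
#' `detection_probability(model, d_j)` with `d_j` the cell's distance to the
#' nearest trajectory; for the random design it is 1 in every sampled cell
#' (a cell containing at least one survey point) and 0 elsewhere.
#'
#' @param counts A `count_grid` from [realize_counts()].
#' @param design A [survey_design()].
#' @param model A `detection_model` (required for trajectory designs).
#' @param distance Optional precomputed distance grid from
#'   [distance_to_trajectories()] (computed on the fly if omitted).
#' @param seed Optional integer seed.
#' @return A data frame of presence records with columns `x`, `y`, `sex`.
#' @export
thin_to_presences <- function(counts, design, model = NULL, distance = NULL,
                              seed = NULL) {
  stopifnot(inherits(counts, "sdm_grid"), inherits(design, "survey_design"))
  if (design$kind == "random") {
    p <- sampled_cell_indicator(counts, design)
  } else {
    if (is.null(model))
      stop("a detection model is required for trajectory designs")
    if (is.null(distance)) distance <- distance_to_trajectories(counts, design)
    if (!same_geometry(counts, distance))
      stop("`distance` grid is not aligned with `counts`")
    p <- detection_probability(model, as.vector(distance$values))
  }
  if (!is.null(seed)) set.seed(seed)
  nvec <- as.vector(counts$values)
  nvec[is.na(nvec)] <- 0
  obs <- stats::rbinom(length(nvec), nvec, p)
  ctr <- cell_centers(counts)
  keep <- which(obs > 0)
  xs <- rep(ctr[keep, 1], obs[keep])
  out <- data.frame(
    x = xs,
    y = rep(ctr[keep, 2], obs[keep]),
    sex = rep(if (is.null(counts$sex)) NA_character_ else counts$sex,
              length(xs))
  )
  rownames(out) <- NULL
  out
}

# 0/1 vector (cell order) marking cells containing at least one survey point
sampled_cell_indicator <- function(grid, design) {
  stopifnot(design$kind == "random")
  idx <- cell_index(grid, design$points)
  p <- numeric(length(grid$values))
  ok <- !is.na(idx[, 1])
  p[(idx[ok, 2] - 1L) * nrow(grid$values) + idx[ok, 1]] <- 1
  p
}
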