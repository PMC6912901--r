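#' Create a survey trajectory
#'
#' @param vertices Two-column matrix or data frame of ordered `(x, y)` vertex
#'   coordinates in meters.
#' @return An object of class `trajectory` (a vertex matrix with a length
#'   attribute).
#' @export
trajectory <- function(vertices) {
  v <- as_xy_matrix(vertices)
  if (nrow(v) < 2) stop("a trajectory needs at least 2 vertices")
  if (any(!is.finite(v))) stop("trajectory vertices must be finite")
  structure(list(vertices = v), class = "trajectory")
}

#' Total length of a trajectory (or list of trajectories)
#'
#' @param x A `trajectory` or a list of them.
#' @return Length in meters (sum of segment lengths).
#' @export
trajectory_length <- function(x) {
  if (inherits(x, "trajectory")) {
    v <- x$vertices
    sum(sqrt(rowSums((v[-1, , drop = FALSE] -
                        v[-nrow(v), , drop = FALSE])^2)))
  } else if (is.list(x)) {
    sum(vapply(x, trajectory_length, numeric(1)))
  } else stop("not a trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d vertices, length %.1f m\n",
              nrow(x$vertices), trajectory_length(x)))
  invisible(x)
}

# all segments of a list of trajectories as one matrix (x1, y1, x2, y2)
trajectory_segments <- function(trajectories) {
  if (inherits(trajectories, "trajectory")) trajectories <- list(trajectories)
  do.call(rbind, lapply(trajectories, function(tr) {
    v <- tr$vertices
    n <- nrow(v)
    cbind(v[-n, 1], v[-n, 2], v[-1, 1], v[-1, 2])
  }))
}

#' Generate habitat-biased observer trajectories
#'
#' Emulates "subjective" (opportunistic) survey routes: a correlated random
#' walk on the landscape whose step directions are up-weighted toward cells
#' with higher values of a preference surface. At every step the walker
#' considers a fan of candidate headings within +/-120 degrees of its current
#' heading and picks one with probability proportional to
#' `exp(bias_strength * preference)` at the candidate endpoint; candidates
#' outside the landscape extent are discarded. Walk start locations are also
#' habitat-biased (cell drawn with probability proportional to
#' `exp(bias_strength * preference)`), mimicking observers who first choose
#' a favorable area and then wander through it. With `bias_strength = 0` the
#' walk is a plain correlated random walk with uniform starts, independent
#' of the preference surface.
#'
#' @param preference An [sdm_grid()] of preference values (any finite scale;
#'   typically a standardized log-intensity surface).
#' @param total_length Total trajectory length to generate, in meters.
#' @param step Step length in meters (must be < `total_length` and smaller
#'   than the landscape extent).
#' @param bias_strength Non-negative selectivity of the walker; 0 = unbiased.
#' @param n_paths Number of separate walks over which `total_length` is split
#'   (emulating several survey days).
#' @param seed Optional integer seed.
#' @return A list of [trajectory()] objects whose summed length is within one
#'   step of `total_length`.
#' @export
generate_subjective_trajectory <- function(preference, total_length,
                                           step = 25, bias_strength = 1,
                                           n_paths = 1, seed = NULL) {
  stopifnot(inherits(preference, "sdm_grid"))
  if (any(!is.finite(preference$values)))
    stop("`preference` must be finite everywhere")
  if (!(total_length > step && step > 0))
    stop("need total_length > step > 0")
  if (bias_strength < 0) stop("`bias_strength` must be >= 0")
  ext <- grid_extent(preference)
  if (step >= min(ext["xmax"] - ext["xmin"], ext["ymax"] - ext["ymin"]))
    stop("`step` is larger than the landscape extent")
  if (!is.null(seed)) set.seed(seed)

  n_steps_total <- round(total_length / step)
  steps_per_path <- diff(round(seq(0, n_steps_total, length.out = n_paths + 1)))
  fan <- seq(-120, 120, by = 30) * pi / 180
  pv <- as.vector(preference$values)
  start_w <- exp(bias_strength * (pv - max(pv)))
  centers <- cell_centers(preference)

  lapply(steps_per_path, function(n_steps) {
    pos <- centers[sample.int(length(start_w), 1, prob = start_w), ]
    # nudge border starts inward so the first steps are unconstrained
    pos <- pmin(pmax(pos, c(ext["xmin"], ext["ymin"]) + step),
                c(ext["xmax"], ext["ymax"]) - step)
    heading <- stats::runif(1, 0, 2 * pi)
    verts <- matrix(NA_real_, n_steps + 1, 2)
    verts[1, ] <- pos
    for (s in seq_len(n_steps)) {
      repeat {
        ang <- heading + fan
        cand <- cbind(pos[1] + step * cos(ang), pos[2] + step * sin(ang))
        inside <- cand[, 1] > ext["xmin"] & cand[, 1] < ext["xmax"] &
          cand[, 2] > ext["ymin"] & cand[, 2] < ext["ymax"]
        if (any(inside)) break
        heading <- heading + pi  # cornered: turn around
      }
      w <- rep(0, length(ang))
      pref <- extract_values(preference, cand[inside, , drop = FALSE])
      w[inside] <- exp(bias_strength * (pref - max(pref)))
      pick <- sample.int(length(ang), 1, prob = w)
      heading <- ang[pick]
      pos <- cand[pick, ]
      verts[s + 1, ] <- pos
    }
    trajectory(verts)
  })
}

# ---- trajectory I/O ---------------------------------------------------------

#' Write trajectories to a vertex CSV
#'
#' Columns: `trajectory_id`, `vertex_index`, `x`, `y`.
#'
#' @param trajectories A `trajectory` or list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectories, path) {
  if (inherits(trajectories, "trajectory")) trajectories <- list(trajectories)
  rows <- do.call(rbind, lapply(seq_along(trajectories), function(i) {
    v <- trajectories[[i]]$vertices
    data.frame(trajectory_id = i, vertex_index = seq_len(nrow(v)),
               x = v[, 1], y = v[, 2])
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read trajectories from a vertex CSV
#'
#' @param path CSV with columns `trajectory_id`, `vertex_index`, `x`, `y`.
#' @return A list of [trajectory()] objects.
#' @export
read_trajectory_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("trajectory_id", "vertex_index", "x", "y")
  if (!all(need %in% names(d)))
    stop(sprintf("'%s': missing columns %s", path,
                 paste(setdiff(need, names(d)), collapse = ", ")))
  lapply(split(d, d$trajectory_id), function(g) {
    g <- g[order(g$vertex_index), ]
    trajectory(cbind(g$x, g$y))
  })
}

#' Write trajectories as a GeoJSON FeatureCollection of LineStrings
#'
#' @param trajectories A `trajectory` or list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_geojson <- function(trajectories, path) {
  if (inherits(trajectories, "trajectory")) trajectories <- list(trajectories)
  features <- lapply(seq_along(trajectories), function(i) {
    list(
      type = "Feature",
      properties = list(trajectory_id = i),
      geometry = list(
        type = "LineString",
        coordinates = unname(apply(trajectories[[i]]$vertices, 1, as.list,
                                   simplify = FALSE))
      )
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read trajectories from a GeoJSON FeatureCollection of LineStrings
#'
#' @param path GeoJSON file with one LineString feature per trajectory.
#' @return A list of [trajectory()] objects.
#' @export
read_trajectory_geojson <- function(path) {
  j <- jsonlite::read_json(path)
  if (is.null(j$type) || j$type != "FeatureCollection")
    stop(sprintf("'%s': not a GeoJSON FeatureCollection", path))
  lapply(j$features, function(f) {
    if (is.null(f$geometry$type) || f$geometry$type != "LineString")
      stop(sprintf("'%s': only LineString features are supported", path))
    coords <- f$geometry$coordinates
    trajectory(do.call(rbind, lapply(coords, function(p)
      c(as.numeric(p[[1]]), as.numeric(p[[2]])))))
  })
}
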