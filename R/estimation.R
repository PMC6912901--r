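#' Per-cell detection probability surface
#'
#' Builds the detection-probability grid \eqn{p_{obs,j}} used in
#' total-sign estimation, by one of three methods:
#' \describe{
#'   \item{`"detection-density"`}{`p = g(d_j) / g(0)` from a distance-decay
#'     detection model (used with uncorrected and targeted-background
#'     models).}
#'   \item{`"distance-model"`}{`p = exp(beta_d * d_j)` from the fitted
#'     distance-to-trajectories coefficient, capped at 1 (a positive
#'     `beta_d` signals a fitting problem and triggers a warning).}
#'   \item{`"sampled-cells"`}{1 in cells containing at least one survey
#'     point, 0 elsewhere (random point designs).}
#' }
#'
#' @param method One of `"detection-density"`, `"distance-model"`,
#'   `"sampled-cells"`.
#' @param distance Distance grid (first two methods).
#' @param fit An `sdm_fit` with a distance coefficient (`"distance-model"`).
#' @param model A `detection_model` (`"detection-density"`).
#' @param design A random-point [survey_design()] (`"sampled-cells"`).
#' @param grid Landscape grid (`"sampled-cells"`).
#' @return An [sdm_grid()] with values in `[0, 1]`.
#' @export
detection_grid <- function(method = c("detection-density", "distance-model",
                                      "sampled-cells"),
                           distance = NULL, fit = NULL, model = NULL,
                           design = NULL, grid = NULL) {
  method <- match.arg(method)
  if (method == "detection-density") {
    if (is.null(model) || is.null(distance))
      stop("detection-density needs `model` and `distance`")
    p <- detection_probability(model, as.vector(distance$values))
    ref <- distance
  } else if (method == "distance-model") {
    if (is.null(fit) || is.null(distance))
      stop("distance-model needs `fit` and `distance`")
    if (is.null(fit$distance_coefficient))
      stop("fit has no distance coefficient (not a distance-corrected model)")
    bd <- fit$distance_coefficient
    if (bd > 0)
      warning("positive distance coefficient: detection would increase with ",
              "distance; capping p at 1")
    p <- pmin(1, exp(bd * as.vector(distance$values)))
    ref <- distance
  } else {
    if (is.null(design) || is.null(grid))
      stop("sampled-cells needs `design` and `grid`")
    p <- sampled_cell_indicator(grid, design)
    ref <- grid
  }
  sdm_grid(matrix(p, nrow(ref$values), ncol(ref$values)),
           cell_size = ref$cell_size, origin = ref$origin)
}

#' Expected total number of signs under complete sampling
#'
#' Scales the observed sign count up to the whole landscape:
#' \deqn{N_{tot} = \frac{N_{obs}}{\sum_j \mu_j \, p_{obs,j}}}
#' where \eqn{\mu_j} are predicted relative abundances (summing to 1) and
#' \eqn{p_{obs,j}} per-cell detection probabilities. Under complete sampling
#' (`p = 1` everywhere) this reduces to `N_obs`.
#'
#' @param n_obs Observed number of signs.
#' @param mu Relative-abundance grid from [predict_relative_abundance()].
#' @param p_obs Detection grid from [detection_grid()].
#' @return The scalar estimate `N_tot >= 0`.
#' @export
estimate_total_signs <- function(n_obs, mu, p_obs) {
  stopifnot(inherits(mu, "sdm_grid"), inherits(p_obs, "sdm_grid"))
  if (!same_geometry(mu, p_obs)) stop("`mu` and `p_obs` are not aligned")
  s <- sum(mu$values * p_obs$values, na.rm = TRUE)
  if (s <= 0)
    stop("sum of mu * p is zero: no detectable mass under this design")
  n_obs / s
}

#' Sign-density map in signs per hectare
#'
#' \eqn{\lambda_j = \mu_j N_{tot} / a_j} with \eqn{a_j} the cell area in ha,
#' so that \eqn{\sum_j \lambda_j a_j = N_{tot}}.
#'
#' @param mu Relative-abundance grid.
#' @param n_tot Estimated total signs (from [estimate_total_signs()]).
#' @param cell_area Cell area in ha; defaults to the grid's own cell area.
#' @return An [sdm_grid()] of densities (signs/ha).
#' @export
sign_density <- function(mu, n_tot, cell_area = NULL) {
  stopifnot(inherits(mu, "sdm_grid"), n_tot >= 0)
  if (is.null(cell_area)) cell_area <- cell_area_ha(mu)
  if (cell_area <= 0) stop("`cell_area` must be positive")
  sdm_grid(mu$values * n_tot / cell_area,
           cell_size = mu$cell_size, origin = mu$origin)
}

#' Sex ratio from raw observation counts
#'
#' The proportion of females among sexed records,
#' `N_f / (N_f + N_m)`.
#'
#' @param records Presence records with a `sex` column (values `"female"` /
#'   `"male"`); rows with other labels are ignored.
#' @return A `sex_ratio_estimate`: list with `ratio`, `n_obs` (named
#'   per-sex counts), `method = "observations"`.
#' @export
#' @examples
#' recs <- data.frame(x = 0, y = 0,
#'                    sex = rep(c("male", "female"), c(17, 12)))
#' sex_ratio_from_observations(recs)$ratio  # 12/29
sex_ratio_from_observations <- function(records) {
  if (!"sex" %in% names(records)) stop("`records` must have a sex column")
  nf <- sum(records$sex == "female", na.rm = TRUE)
  nm <- sum(records$sex == "male", na.rm = TRUE)
  if (nf + nm == 0) stop("no sexed records")
  structure(list(ratio = nf / (nf + nm),
                 n_obs = c(female = nf, male = nm),
                 n_tot = NULL, method = "observations"),
            class = "sex_ratio_estimate")
}

#' Sex ratio from model-based total-sign estimates
#'
#' Estimates each sex's expected total sign count under complete sampling
#' ([estimate_total_signs()]) and returns the female share
#' `N_tot,f / (N_tot,f + N_tot,m)`. With perfect detection for both sexes
#' this reduces to the observation ratio.
#'
#' @param n_obs_f,n_obs_m Observed sign counts per sex.
#' @param mu_f,mu_m Relative-abundance grids per sex.
#' @param p_obs_f,p_obs_m Detection grids per sex.
#' @param method Label recorded on the estimate (e.g. `"model-targeted"`).
#' @return A `sex_ratio_estimate` with `ratio`, `n_obs`, `n_tot`.
#' @export
sex_ratio_from_models <- function(n_obs_f, n_obs_m, mu_f, mu_m,
                                  p_obs_f, p_obs_m, method = "model") {
  ntf <- estimate_total_signs(n_obs_f, mu_f, p_obs_f)
  ntm <- estimate_total_signs(n_obs_m, mu_m, p_obs_m)
  structure(list(ratio = ntf / (ntf + ntm),
                 n_obs = c(female = n_obs_f, male = n_obs_m),
                 n_tot = c(female = ntf, male = ntm),
                 method = method),
            class = "sex_ratio_estimate")
}

#' @export
print.sex_ratio_estimate <- function(x, ...) {
  cat(sprintf("<sex_ratio_estimate> %s: proportion female %.3f\n",
              x$method, x$ratio))
  cat(sprintf("  N_obs: %d female, %d male\n", x$n_obs["female"],
              x$n_obs["male"]))
  if (!is.null(x$n_tot))
    cat(sprintf("  N_tot: %.1f female, %.1f male\n", x$n_tot["female"],
                x$n_tot["male"]))
  invisible(x)
}
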