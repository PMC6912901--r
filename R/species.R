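#' Per-sex intensity model parameters
#'
#' Holds the intercept and per-covariate slopes of the log-linear intensity
#' model \eqn{\ln \lambda(s) = \beta_0 + \sum_i x_i(s)\,\beta_i} for one sex.
#'
#' @param sex Label, `"female"` or `"male"` (other group labels are allowed).
#' @param intercept Intercept \eqn{\beta_0} on the log scale.
#' @param slopes Named numeric vector of slopes \eqn{\beta_i}; names must
#'   match covariate layer names.
#' @return An object of class `sex_params`.
#' @export
sex_params <- function(sex, intercept, slopes) {
  if (is.null(names(slopes)) || any(names(slopes) == ""))
    stop("`slopes` must be a named numeric vector")
  stopifnot(is.numeric(intercept), length(intercept) == 1,
            is.numeric(slopes))
  structure(list(sex = as.character(sex), intercept = as.numeric(intercept),
                 slopes = slopes),
            class = "sex_params")
}

#' @export
print.sex_params <- function(x, ...) {
  cat(sprintf("<sex_params> %s: intercept %.4g; slopes %s\n", x$sex,
              x$intercept,
              paste(sprintf("%s=%.4g", names(x$slopes), x$slopes),
                    collapse = ", ")))
  invisible(x)
}

#' Reference virtual-species parameterizations
#'
#' The shipped female/male parameter sets for the three standard layers
#' (`slope`, `canopy`, `simpson`): female slopes (-0.9, -0.8, 1) with
#' intercept -4; male slopes (-0.2, 0.9, -0.9) with intercept -3.55. The male
#' intercept was tuned for one particular landscape so that the expected sex
#' ratio is 0.5 there; on other landscapes use
#' [calibrate_male_intercept()] instead of the stored constant.
#'
#' @param sex `"female"` or `"male"`.
#' @return A [sex_params()] object.
#' @export
#' @examples
#' reference_params("female")
reference_params <- function(sex = c("female", "male")) {
  sex <- match.arg(sex)
  if (sex == "female")
    sex_params("female", -4,
               c(slope = -0.9, canopy = -0.8, simpson = 1))
  else
    sex_params("male", -3.55,
               c(slope = -0.2, canopy = 0.9, simpson = -0.9))
}

#' Compute the intensity surface of one sex
#'
#' Evaluates \eqn{\lambda(s) = \exp(\beta_0 + \sum_i x_i(s)\beta_i)} on every
#' cell. Cells with any missing covariate get a missing intensity.
#'
#' @param stack A standardized [covariate_stack()].
#' @param params A [sex_params()] whose slope names are all present in the
#'   stack.
#' @return An `intensity_grid`: an [sdm_grid()] with attributes `sex`.
#' @export
compute_intensity <- function(stack, params) {
  stopifnot(inherits(stack, "covariate_stack"), inherits(params, "sex_params"))
  unknown <- setdiff(names(params$slopes), names(stack$grids))
  if (length(unknown))
    stop("unknown covariate(s) in params: ", paste(unknown, collapse = ", "))
  ref <- stack$grids[[1]]
  eta <- matrix(params$intercept, nrow(ref$values), ncol(ref$values))
  for (nm in names(params$slopes))
    eta <- eta + stack$grids[[nm]]$values * params$slopes[[nm]]
  g <- sdm_grid(exp(eta), cell_size = ref$cell_size, origin = ref$origin)
  g$sex <- params$sex
  class(g) <- c("intensity_grid", class(g))
  g
}

#' Calibrate the male intercept to a target expected sex ratio
#'
#' Closed-form calibration: given the female intensity surface and the male
#' slopes, sets the male intercept so that the expected proportion of female
#' signs, \eqn{\sum_s \lambda_f(s) / (\sum_s \lambda_f(s) + \sum_s
#' \lambda_m(s))}, equals `target_ratio` exactly:
#' \deqn{\beta_{0,m} = \ln\sum_s \lambda_f(s) -
#'   \ln\sum_s e^{\sum_i x_i(s)\beta_{i,m}} +
#'   \ln\frac{1 - r}{r}.}
#'
#' @param stack A standardized [covariate_stack()].
#' @param female Female [sex_params()].
#' @param male_slopes Named numeric vector of male slopes.
#' @param target_ratio Target expected female share, in (0, 1); default 0.5.
#' @return Male [sex_params()] with the calibrated intercept.
#' @export
calibrate_male_intercept <- function(stack, female, male_slopes,
                                     target_ratio = 0.5) {
  stopifnot(inherits(stack, "covariate_stack"))
  if (!(target_ratio > 0 && target_ratio < 1))
    stop("`target_ratio` must be in (0, 1)")
  lam_f <- compute_intensity(stack, female)$values
  if (all(is.na(lam_f))) stop("landscape is empty (all-missing cells)")
  male0 <- sex_params("male", 0, male_slopes)
  em <- compute_intensity(stack, male0)$values
  ok <- !is.na(lam_f) & !is.na(em)
  b0m <- log(sum(lam_f[ok])) - log(sum(em[ok])) +
    log((1 - target_ratio) / target_ratio)
  sex_params("male", b0m, male_slopes)
}

#' Draw a Poisson sign-count realization of an intensity surface
#'
#' Draws the number of signs in each cell independently from
#' Poisson(\eqn{\lambda_j}).
#'
#' @param intensity An `intensity_grid` from [compute_intensity()].
#' @param seed Optional integer seed.
#' @return A `count_grid`: an [sdm_grid()] of integer counts with the sex
#'   label carried over.
#' @export
realize_counts <- function(intensity, seed = NULL) {
  stopifnot(inherits(intensity, "sdm_grid"))
  lam <- intensity$values
  if (any(!is.na(lam) & (lam < 0 | !is.finite(lam))))
    stop("intensity must be finite and non-negative")
  if (!is.null(seed)) set.seed(seed)
  counts <- matrix(NA_real_, nrow(lam), ncol(lam))
  ok <- !is.na(lam)
  counts[ok] <- stats::rpois(sum(ok), lam[ok])
  g <- sdm_grid(counts, cell_size = intensity$cell_size,
                origin = intensity$origin)
  g$sex <- intensity$sex
  class(g) <- c("count_grid", class(g))
  g
}
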