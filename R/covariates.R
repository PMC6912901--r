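#' Generate spatially autocorrelated covariate rasters
#'
#' Simulates `n_layers` stationary Gaussian random fields with an exponential
#' correlogram `C(h) = exp(-h / spatial_range)` by circulant embedding
#' (FFT on a doubled torus, negative embedding eigenvalues clamped to zero),
#' then mixes the fields linearly so the realized pairwise Pearson
#' correlations over cells match `target_correlation`: the independent fields
#' are empirically whitened (Cholesky of their sample correlation) and
#' re-colored with the Cholesky factor of the target matrix. The result is
#' returned standardized (each layer mean 0, sd 1 over cells).
#'
#' @param n_rows,n_cols Grid dimensions (cells).
#' @param n_layers Number of covariate layers (>= 1).
#' @param spatial_range Correlation range of the exponential correlogram, in
#'   meters; `0` gives spatially independent (white-noise) layers.
#' @param target_correlation Symmetric positive-definite matrix with unit
#'   diagonal giving the wanted between-layer correlations; default identity.
#' @param cell_size Cell edge length in meters.
#' @param layer_names Optional layer names; defaults to `slope`, `canopy`,
#'   `simpson` for three layers, else `V1..Vk`.
#' @param seed Optional integer seed; fixing it makes the stack reproducible
#'   bit for bit.
#'
#' @return A standardized [covariate_stack()].
#' @export
#' @examples
#' st <- generate_covariates(50, 50, 3, spatial_range = 100, seed = 1)
#' round(cor(stack_as_matrix(st)), 3)
generate_covariates <- function(n_rows, n_cols, n_layers = 3,
                                spatial_range = 200,
                                target_correlation = NULL,
                                cell_size = 25,
                                layer_names = NULL,
                                seed = NULL) {
  if (n_layers < 1) stop("`n_layers` must be at least 1")
  if (spatial_range < 0) stop("`spatial_range` must be non-negative")
  if (is.null(target_correlation)) target_correlation <- diag(n_layers)
  target_correlation <- as.matrix(target_correlation)
  if (!isTRUE(all.equal(dim(target_correlation), c(n_layers, n_layers))))
    stop("`target_correlation` must be n_layers x n_layers")
  if (max(abs(target_correlation - t(target_correlation))) > 1e-8)
    stop("`target_correlation` must be symmetric")
  if (max(abs(diag(target_correlation) - 1)) > 1e-8)
    stop("`target_correlation` must have unit diagonal")
  Lt <- tryCatch(chol(target_correlation), error = function(e)
    stop("`target_correlation` is not positive definite: ",
         conditionMessage(e)))
  if (is.null(layer_names))
    layer_names <- if (n_layers == 3) c("slope", "canopy", "simpson")
                   else paste0("V", seq_len(n_layers))
  if (length(layer_names) != n_layers) stop("wrong number of layer names")

  if (!is.null(seed)) set.seed(seed)
  S <- n_rows * n_cols
  X <- matrix(0, S, n_layers)
  if (spatial_range > 0) {
    emb <- grf_embedding(n_rows, n_cols, cell_size, spatial_range)
    for (k in seq_len(n_layers))
      X[, k] <- as.vector(grf_draw(emb, n_rows, n_cols))
  } else {
    X[] <- stats::rnorm(S * n_layers)
  }
  # center, whiten by the empirical covariance, re-color with the target:
  # realized correlations then equal the target to machine precision
  X <- scale(X, center = TRUE, scale = FALSE)
  if (n_layers > 1) {
    Se <- crossprod(X) / (S - 1)
    X <- X %*% solve(chol(Se)) %*% Lt
  }
  X <- scale(X, center = FALSE, scale = apply(X, 2, stats::sd))

  grids <- lapply(seq_len(n_layers), function(k)
    sdm_grid(matrix(X[, k], n_rows, n_cols), cell_size = cell_size))
  names(grids) <- layer_names
  constants <- lapply(grids, function(g) c(mean = 0, sd = 1))
  covariate_stack(grids, standardized = TRUE, constants = constants)
}

# circulant-embedding spectrum of an exponential covariance on a doubled torus
grf_embedding <- function(n_rows, n_cols, cell_size, range_m) {
  m1 <- 2L * n_rows
  m2 <- 2L * n_cols
  i <- 0:(m1 - 1); i <- pmin(i, m1 - i)
  j <- 0:(m2 - 1); j <- pmin(j, m2 - j)
  h <- sqrt(outer(i^2, j^2, "+")) * cell_size
  cc <- exp(-h / range_m)
  lam <- Re(stats::fft(cc))
  lam[lam < 0] <- 0  # approximate embedding: clamp negative eigenvalues
  list(lam = lam, m1 = m1, m2 = m2)
}

grf_draw <- function(emb, n_rows, n_cols) {
  m1 <- emb$m1; m2 <- emb$m2
  eps <- matrix(stats::rnorm(m1 * m2), m1, m2) +
    1i * matrix(stats::rnorm(m1 * m2), m1, m2)
  f <- stats::fft(sqrt(emb$lam / (m1 * m2)) * eps)
  Re(f)[seq_len(n_rows), seq_len(n_cols)]
}
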