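# shared in-code fixtures for the test suite

# small standardized synthetic landscape
tiny_stack <- function(n = 40, seed = 1, range_m = 100) {
  generate_covariates(n, n, 3, spatial_range = range_m, seed = seed)
}

# stack built from explicit matrices (marked standardized for model code
# that requires the flag; values are whatever the test needs)
manual_stack <- function(..., cell_size = 25, standardized = TRUE) {
  mats <- list(...)
  covariate_stack(lapply(mats, sdm_grid, cell_size = cell_size),
                  standardized = standardized)
}

# single horizontal two-vertex trajectory design
horizontal_design <- function(y = 0, x0 = 0, x1 = 1000,
                              kind = "subjective") {
  survey_design(kind, trajectories = list(trajectory(rbind(c(x0, y),
                                                           c(x1, y)))))
}

expect_grid_equal <- function(a, b, tol = 1e-9) {
  expect_s3_class(a, "sdm_grid")
  expect_equal(dim(a$values), dim(b$values))
  expect_equal(a$cell_size, b$cell_size, tolerance = tol)
  expect_equal(a$origin, b$origin, tolerance = tol)
  expect_equal(a$values, b$values, tolerance = tol)
}
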