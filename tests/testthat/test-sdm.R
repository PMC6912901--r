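test_that("uniform background is reproducible and inside the extent", {
  g <- sdm_grid(matrix(0, 30, 30), cell_size = 25)
  a <- uniform_background(g, 500, seed = 4)
  b <- uniform_background(g, 500, seed = 4)
  expect_identical(a$points, b$points)
  expect_true(all(a$points >= 0 & a$points <= 750))
  expect_equal(nrow(a$points), 500)
})

test_that("targeted background reproduces the detection-distance law", {
  g <- sdm_grid(matrix(0, 145, 145), cell_size = 25)
  des <- systematic_transects(g, spacing = 400, offset = 200)
  model <- detection_model("exponential", c(rate = 1 / 25),
                           truncation = 300)
  bg <- targeted_background(des, model, g, n = 10000, seed = 8)
  expect_equal(nrow(bg$points), 10000)
  dist_grid <- distance_to_trajectories(g, des)
  # exact point-to-trajectory distances of the background points
  seg <- sdmbias:::trajectory_segments(des$trajectories)
  d <- rep(Inf, nrow(bg$points))
  for (k in seq_len(nrow(seg))) {
    t <- pmin(1, pmax(0, ((bg$points[, 1] - seg[k, 1]) *
                            (seg[k, 3] - seg[k, 1]) +
                            (bg$points[, 2] - seg[k, 2]) *
                            (seg[k, 4] - seg[k, 2])) /
                       sum((seg[k, 3:4] - seg[k, 1:2])^2)))
    d <- pmin(d, sqrt((bg$points[, 1] - (seg[k, 1] +
                                           t * (seg[k, 3] - seg[k, 1])))^2 +
                        (bg$points[, 2] - (seg[k, 2] +
                                             t * (seg[k, 4] - seg[k, 2])))^2))
  }
  ks <- suppressWarnings(stats::ks.test(d, function(q)
    stats::pexp(q, 1 / 25) / stats::pexp(300, 1 / 25)))
  expect_lte(unname(ks$statistic), 0.05)
  expect_error(targeted_background(random_points(g, 5, seed = 1), model, g),
               "trajectory")
})

test_that("weighted-logistic slopes match the Poisson point-process oracle", {
  st <- tiny_stack(80, seed = 14)
  truth <- sex_params("f", -2.5, c(slope = -0.9, canopy = -0.8,
                                   simpson = 1))
  counts <- realize_counts(compute_intensity(st, truth), seed = 15)
  ctr <- cell_centers(counts)
  keep <- which(counts$values > 0)
  pres <- data.frame(x = rep(ctr[keep, 1], counts$values[keep]),
                     y = rep(ctr[keep, 2], counts$values[keep]))
  bg <- uniform_background(st$grids[[1]], 10000, seed = 16)
  fit <- fit_sdm(pres, bg, st)
  # independent oracle: down-weighted Poisson regression on the same points
  xy <- rbind(as.matrix(pres), bg$points)
  X <- vapply(st$grids, function(g) extract_values(g, xy),
              numeric(nrow(xy)))
  y <- rep(1:0, c(nrow(pres), 10000))
  wq <- ifelse(y == 1, 1e-8, nrow(ctr) / 10000)
  oracle <- stats::glm.fit(cbind(1, X), y / wq, weights = wq,
                           family = stats::poisson())
  expect_lt(max(abs(fit$coefficients - oracle$coefficients[-1])), 1e-3)
  # large-sample consistency against the generating slopes
  expect_lt(max(abs(fit$coefficients - truth$slopes)), 0.1)
})

test_that("null covariates get near-zero coefficients", {
  st <- tiny_stack(60, seed = 24)
  # intensity depends on slope only; canopy and simpson are null
  truth <- sex_params("f", -1, c(slope = 0.8, canopy = 0, simpson = 0))
  counts <- realize_counts(compute_intensity(st, truth), seed = 25)
  ctr <- cell_centers(counts)
  keep <- which(counts$values > 0)
  pres <- data.frame(x = rep(ctr[keep, 1], counts$values[keep]),
                     y = rep(ctr[keep, 2], counts$values[keep]))
  bg <- uniform_background(st$grids[[1]], 5000, seed = 26)
  fit <- fit_sdm(pres, bg, st)
  # standard errors from an independent refit of the same weighted logistic
  xy <- rbind(as.matrix(pres), bg$points)
  dat <- as.data.frame(vapply(st$grids, function(g) extract_values(g, xy),
                              numeric(nrow(xy))))
  dat$y <- rep(1:0, c(nrow(pres), 5000))
  dat$w <- ifelse(dat$y == 1, 1, 1000)
  ref <- suppressWarnings(
    stats::glm(y ~ slope + canopy + simpson, stats::binomial(), dat,
               weights = w))
  se <- summary(ref)$coefficients[c("canopy", "simpson"), "Std. Error"]
  # the glm SE conditions on the background sample; Monte-Carlo quadrature
  # noise inflates the total sd by ~sqrt(1 + n_presence/n_background), so a
  # 3-total-SE check corresponds to about 4 conditional SEs here
  expect_lt(abs(fit$coefficients["canopy"]), 4 * se["canopy"])
  expect_lt(abs(fit$coefficients["simpson"]), 4 * se["simpson"])
})

test_that("distance-corrected fits recover a negative distance coefficient", {
  st <- tiny_stack(60, seed = 34)
  truth <- sex_params("f", -0.8, c(slope = -0.5, canopy = 0.4,
                                   simpson = 0.6))
  counts <- realize_counts(compute_intensity(st, truth), seed = 35)
  des <- systematic_transects(st$grids[[1]], spacing = 250, offset = 100)
  dg <- distance_to_trajectories(st$grids[[1]], des)
  model <- detection_model("exponential", c(rate = 1 / 30),
                           truncation = 300)
  recs <- thin_to_presences(counts, des, model, distance = dg, seed = 36)
  fit <- fit_sdm(recs, uniform_background(st$grids[[1]], 5000, seed = 37),
                 st, distance = dg)
  expect_equal(fit$correction, "distance")
  expect_lt(fit$distance_coefficient, 0)
  # the true thinning is exp(-d/30): the fitted per-meter coefficient should
  # be in that neighbourhood
  expect_lt(abs(fit$distance_coefficient - (-1 / 30)), 0.02)
  expect_error(fit_sdm(recs, uniform_background(st$grids[[1]], 100,
                                                seed = 1),
                       st, correction = "distance"),
               "distance grid")
})

test_that("fit input contracts are enforced", {
  st <- tiny_stack(20, seed = 44)
  bg <- uniform_background(st$grids[[1]], 200, seed = 45)
  expect_error(fit_sdm(data.frame(x = 1:3, y = 1:3), bg, st), "at least 5")
  raw <- covariate_stack(st$grids, standardized = FALSE)
  pres <- data.frame(x = runif(10, 0, 500), y = runif(10, 0, 500))
  expect_error(fit_sdm(pres, bg, raw), "standardized")
})

test_that("relative-abundance maps normalize, rank by linear predictor and
           ignore intercept shifts", {
  st <- tiny_stack(30, seed = 54)
  truth <- sex_params("f", -2, c(slope = 0.7, canopy = -0.3, simpson = 0.2))
  counts <- realize_counts(compute_intensity(st, truth), seed = 55)
  ctr <- cell_centers(counts)
  keep <- which(counts$values > 0)
  pres <- data.frame(x = rep(ctr[keep, 1], counts$values[keep]),
                     y = rep(ctr[keep, 2], counts$values[keep]))
  fit <- fit_sdm(pres, uniform_background(st$grids[[1]], 2000, seed = 56),
                 st)
  mu <- predict_relative_abundance(fit, st)
  expect_equal(sum(mu$values), 1, tolerance = 1e-9)
  expect_true(all(mu$values > 0))
  # ranking equals ranking of the linear predictor
  eta <- Reduce(`+`, Map(function(g, b) g$values * b,
                         st$grids[names(fit$coefficients)],
                         fit$coefficients))
  expect_equal(rank(as.vector(mu$values)), rank(as.vector(eta)))
  # intercept shifts cancel in the normalization
  fit2 <- fit
  fit2$intercept <- fit$intercept + 5
  mu2 <- predict_relative_abundance(fit2, st)
  expect_equal(mu2$values, mu$values, tolerance = 1e-12)
})

test_that("targeted fit on unbiased data approaches the uniform fit", {
  st <- tiny_stack(80, seed = 64)
  truth <- sex_params("f", -1.6, c(slope = -0.9, canopy = -0.8,
                                   simpson = 1))
  counts <- realize_counts(compute_intensity(st, truth), seed = 65)
  ctr <- cell_centers(counts)
  keep <- which(counts$values > 0)
  pres <- data.frame(x = rep(ctr[keep, 1], counts$values[keep]),
                     y = rep(ctr[keep, 2], counts$values[keep]))
  # a dense transect grid with near-uniform offsets covers the extent, so
  # the targeted background is nearly uniform and the fits should agree
  des <- systematic_transects(st$grids[[1]], spacing = 100, offset = 50)
  cover <- detection_model("half-normal", c(sigma = 300), truncation = 600)
  fit_u <- fit_sdm(pres, uniform_background(st$grids[[1]], 8000, seed = 66),
                   st)
  fit_t <- fit_sdm(pres, targeted_background(des, cover, st$grids[[1]],
                                             8000, seed = 67), st)
  expect_lt(max(abs(fit_u$coefficients - fit_t$coefficients)), 0.1)
})
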