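test_that("systematic transects tile a square extent with the right length", {
  ext <- c(0, 2000, 0, 2000)
  des <- systematic_transects(ext, spacing = 400, orientation = 0,
                              offset = 200)
  expect_equal(length(des$trajectories), 5)
  expect_equal(trajectory_length(des$trajectories), 10000)
  ys <- vapply(des$trajectories, function(tr) tr$vertices[1, 2], numeric(1))
  expect_equal(sort(ys), c(200, 600, 1000, 1400, 1800))
  # every transect fully inside the extent, any orientation
  for (ang in c(0, 30, 90, 135)) {
    d2 <- systematic_transects(ext, spacing = 300, orientation = ang,
                               seed = 5)
    for (tr in d2$trajectories) {
      v <- tr$vertices
      expect_true(all(v[, 1] >= -1e-9 & v[, 1] <= 2000 + 1e-9 &
                        v[, 2] >= -1e-9 & v[, 2] <= 2000 + 1e-9))
    }
  }
  # the reference configuration: 400 m spacing over a ~13 km2 extent gives
  # about 32 km of transects
  g <- sdm_grid(matrix(0, 145, 145), cell_size = 25)
  d3 <- systematic_transects(g, spacing = 400, seed = 1)
  expect_true(abs(trajectory_length(d3$trajectories) - 32000) < 4000)
  expect_warning(systematic_transects(c(0, 100, 0, 100), spacing = 500),
                 "single")
})

test_that("random survey points are uniform over the landscape", {
  g <- sdm_grid(matrix(0, 40, 40), cell_size = 25)
  pvals <- vapply(1:20, function(s) {
    des <- random_points(g, 2000, seed = s)
    expect_true(all(des$points >= 0 & des$points <= 1000))
    qx <- des$points[, 1] > 500
    qy <- des$points[, 2] > 500
    stats::chisq.test(table(qx, qy))$p.value
  }, numeric(1))
  expect_true(all(pvals > 0.001))
  # missing cells are never sampled
  vals <- matrix(0, 10, 10); vals[, 1:5] <- NA
  g2 <- sdm_grid(vals, cell_size = 25)
  des2 <- random_points(g2, 500, seed = 3)
  expect_true(all(des2$points[, 1] > 125))
})

test_that("distance to trajectories matches geometry and a densified oracle", {
  g <- sdm_grid(matrix(0, 30, 30), cell_size = 25)
  # single horizontal segment through y = 387.5 (a row of cell centers)
  des <- horizontal_design(y = 387.5, x0 = 0, x1 = 750)
  dg <- distance_to_trajectories(g, des)
  idx <- cell_index(g, cbind(400, 387.5))
  expect_equal(dg$values[idx], 0)
  expect_equal(dg$values[cell_index(g, cbind(400, 487.5))], 100)
  # brute-force oracle: minimum distance to segments densified at 0.1 m
  set.seed(42)
  trs <- list(trajectory(matrix(runif(8, 0, 750), 4, 2)),
              trajectory(matrix(runif(6, 0, 750), 3, 2)))
  des2 <- survey_design("subjective", trajectories = trs)
  dg2 <- distance_to_trajectories(g, des2)
  dense <- do.call(rbind, lapply(trs, function(tr) {
    v <- tr$vertices
    do.call(rbind, lapply(seq_len(nrow(v) - 1), function(i) {
      n <- max(2, ceiling(sqrt(sum((v[i + 1, ] - v[i, ])^2)) / 0.1))
      cbind(seq(v[i, 1], v[i + 1, 1], length.out = n),
            seq(v[i, 2], v[i + 1, 2], length.out = n))
    }))
  }))
  ctr <- cell_centers(g)
  sub <- sample(nrow(ctr), 50)
  for (i in sub) {
    oracle <- sqrt(min((dense[, 1] - ctr[i, 1])^2 +
                         (dense[, 2] - ctr[i, 2])^2))
    expect_lt(abs(as.vector(dg2$values)[i] - oracle), 0.2)
  }
  # reversal invariance
  rev_trs <- lapply(trs, function(tr)
    trajectory(tr$vertices[nrow(tr$vertices):1, ]))
  dg3 <- distance_to_trajectories(g, survey_design("subjective",
                                                   trajectories = rev_trs))
  expect_equal(dg2$values, dg3$values, tolerance = 1e-9)
  expect_error(distance_to_trajectories(g, random_points(g, 10, seed = 1)),
               "point design")
})

test_that("parametric detection models fit by closed-form MLE and normalize", {
  set.seed(7)
  d <- rexp(1000, 1 / 50)
  d <- d[d <= 300]
  fit <- fit_detection_model(d, "exponential", truncation = 300)
  expect_equal(unname(fit$par["rate"]), 1 / mean(d))
  expect_lt(abs(fit$par["rate"] - 1 / 50), 0.1 * (1 / 50))
  expect_equal(detection_probability(fit, 0), 1)
  expect_equal(detection_probability(fit, 100),
               exp(-unname(fit$par["rate"]) * 100))
  hn <- fit_detection_model(abs(rnorm(1000, 0, 40)), "half-normal",
                            truncation = 300)
  expect_equal(detection_probability(hn, 0), 1)
  expect_lt(abs(hn$par["sigma"] - 40), 4)
  # beyond-truncation distances dropped with warning; p is 0 there
  expect_warning(fit_detection_model(c(rexp(500, 1 / 30), 400),
                                     "exponential", truncation = 300),
                 "truncation")
  m <- detection_model("exponential", c(rate = 0.01), truncation = 300)
  expect_equal(detection_probability(m, 100), exp(-1), tolerance = 1e-12)
  expect_equal(detection_probability(m, 400), 0)
  expect_error(detection_probability(m, -5), "non-negative")
})

test_that("spline detection fit recovers a flat density within 0.15", {
  set.seed(13)
  D <- 200
  d <- runif(2000, 0, D)
  fit <- fit_detection_model(d, "empirical-spline", truncation = D)
  xs <- seq(0, 0.8 * D, length.out = 50)
  p <- detection_probability(fit, xs)
  expect_true(all(abs(p - 1) <= 0.15))
  expect_equal(detection_probability(fit, 0), 1)
  expect_error(fit_detection_model(rep(5, 30), "empirical-spline"),
               "identical")
  expect_error(fit_detection_model(runif(10), "empirical-spline"),
               "at least 20")
})

test_that("detection probability is monotone for parametric forms", {
  d <- sort(runif(100, 0, 290))
  for (m in list(detection_model("exponential", c(rate = 1 / 40)),
                 detection_model("half-normal", c(sigma = 60)))) {
    p <- detection_probability(m, d)
    expect_true(all(diff(p) <= 1e-12))
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("thinning keeps expectation and never creates signs", {
  st <- tiny_stack(20, seed = 2)
  lam <- compute_intensity(st, sex_params("female", -1.5,
                                          c(slope = 0.5, canopy = -0.5,
                                            simpson = 0.3)))
  counts <- realize_counts(lam, seed = 3)
  des <- horizontal_design(y = 250, x0 = 0, x1 = 500)
  model <- detection_model("exponential", c(rate = 1 / 50))
  dg <- distance_to_trajectories(st$grids[[1]], des)
  p <- detection_probability(model, as.vector(dg$values))
  cnt <- as.vector(counts$values)
  expected <- sum(cnt * p)
  se <- sqrt(sum(cnt * p * (1 - p)))
  set.seed(11)
  n_obs <- vapply(1:1000, function(i)
    nrow(thin_to_presences(counts, des, model, distance = dg)), numeric(1))
  expect_lt(abs(mean(n_obs) - expected), 4 * se / sqrt(1000))
  # thinning never creates signs in any cell
  for (s in 1:10) {
    recs <- thin_to_presences(counts, des, model, distance = dg, seed = s)
    if (nrow(recs) == 0) next
    tab <- table(cell_index(counts, recs)[, 1],
                 cell_index(counts, recs)[, 2])
    for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
      r <- as.integer(rownames(tab))[i]; c <- as.integer(colnames(tab))[j]
      expect_lte(tab[i, j], counts$values[r, c])
    }
    expect_true(all(recs$sex == "female"))
  }
})

test_that("thinning limits: perfect detection keeps all, zero keeps none", {
  st <- tiny_stack(15, seed = 5)
  lam <- compute_intensity(st, sex_params("m", -0.5, c(slope = 0.3,
                                                       canopy = 0,
                                                       simpson = 0)))
  counts <- realize_counts(lam, seed = 6)
  des <- horizontal_design(y = 187.5, x0 = 0, x1 = 375)
  # a detection model that is ~1 everywhere within the landscape
  all_see <- detection_model("half-normal", c(sigma = 1e9),
                             truncation = 1e9)
  recs <- thin_to_presences(counts, des, all_see, seed = 1)
  expect_equal(nrow(recs), sum(counts$values))
  # an off-center trajectory with a sub-cell truncation: p = 0 everywhere
  des_off <- horizontal_design(y = 190, x0 = 0, x1 = 375)
  none <- detection_model("exponential", c(rate = 100), truncation = 1e-6)
  expect_equal(nrow(thin_to_presences(counts, des_off, none, seed = 1)), 0)
  # random design: all signs in sampled cells are kept
  des_r <- random_points(st$grids[[1]], 50, seed = 9)
  recs_r <- thin_to_presences(counts, des_r, seed = 2)
  p <- sdmbias:::sampled_cell_indicator(counts, des_r)
  expect_equal(nrow(recs_r), sum(as.vector(counts$values) * p))
})
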