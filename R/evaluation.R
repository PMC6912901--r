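#' Signed estimation bias of fitted habitat coefficients
#'
#' @param fit An `sdm_fit`.
#' @param truth The generating [sex_params()].
#' @return Named vector `estimate - truth` per covariate.
#' @export
parameter_bias <- function(fit, truth) {
  stopifnot(inherits(fit, "sdm_fit"), inherits(truth, "sex_params"))
  if (!setequal(names(fit$coefficients), names(truth$slopes)))
    stop("fit and truth do not share the same coefficient names")
  fit$coefficients[names(truth$slopes)] - truth$slopes
}

#' Spearman rank correlation between two maps
#'
#' Rank correlation over the jointly non-missing cells, with average-rank tie
#' handling. A constant map has no defined rank correlation; `NA` is
#' returned with a warning.
#'
#' @param predicted,truth Aligned [sdm_grid()] objects.
#' @return Spearman's rho in `[-1, 1]`, or `NA`.
#' @export
spearman_map_correlation <- function(predicted, truth) {
  stopifnot(inherits(predicted, "sdm_grid"), inherits(truth, "sdm_grid"))
  if (!same_geometry(predicted, truth)) stop("maps are not aligned")
  a <- as.vector(predicted$values); b <- as.vector(truth$values)
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 3) stop("need at least 3 jointly non-missing cells")
  if (stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) {
    warning("constant map: Spearman correlation undefined")
    return(NA_real_)
  }
  stats::cor(a[ok], b[ok], method = "spearman")
}

#' Ranking AUC of presence vs background scores
#'
#' Area under the ROC curve computed by the Mann--Whitney rank formula
#' (ties counted one half).
#'
#' @param scores_presence,scores_background Numeric score vectors.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores_presence, scores_background) {
  n1 <- length(scores_presence); n0 <- length(scores_background)
  if (n1 == 0 || n0 == 0) stop("both score sets must be non-empty")
  r <- rank(c(scores_presence, scores_background))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cross-validated AUC of a fitted SDM
#'
#' Scores presences and an independent evaluation background set with the
#' fitted model's habitat linear predictor, splits both sets into `k`
#' stratified folds, computes the ranking AUC within each fold, and returns
#' the fold mean and between-fold variance (the cross-validated-AUC
#' convention). Folds without presences are skipped with a warning.
#'
#' @param presences Presence records (`x`, `y`).
#' @param eval_background A `background_set` drawn independently of the one
#'   used for fitting.
#' @param fit An `sdm_fit`.
#' @param stack The standardized [covariate_stack()].
#' @param k Number of folds (default 10).
#' @param seed Optional integer seed for fold assignment.
#' @return List with `auc_mean`, `auc_variance`, `fold_auc`.
#' @export
cv_auc <- function(presences, eval_background, fit, stack, k = 10,
                   seed = NULL) {
  stopifnot(inherits(fit, "sdm_fit"), inherits(stack, "covariate_stack"),
            inherits(eval_background, "background_set"))
  if (k < 2) stop("`k` must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  sp <- sdm_scores(fit, stack, as_xy_matrix(presences))
  sb <- sdm_scores(fit, stack, eval_background$points)
  fp <- sample(rep_len(seq_len(k), length(sp)))
  fb <- sample(rep_len(seq_len(k), length(sb)))
  fold_auc <- rep(NA_real_, k)
  for (i in seq_len(k)) {
    p <- sp[fp == i]; b <- sb[fb == i]
    if (length(p) == 0 || length(b) == 0) {
      warning(sprintf("fold %d has no presences (or background): skipped", i))
      next
    }
    fold_auc[i] <- auc_score(p, b)
  }
  ok <- !is.na(fold_auc)
  list(auc_mean = mean(fold_auc[ok]),
       auc_variance = if (sum(ok) > 1) stats::var(fold_auc[ok]) else NA_real_,
       fold_auc = fold_auc)
}

# habitat-only linear predictor of a fit at point locations
sdm_scores <- function(fit, stack, xy) {
  X <- vapply(stack$grids[names(fit$coefficients)],
              function(g) extract_values(g, xy), numeric(nrow(xy)))
  drop(X %*% fit$coefficients)
}

# ---- experiment driver ------------------------------------------------------

#' Configuration of the virtual-species experiment
#'
#' Defaults mirror the reference study conditions: a 145 x 145 landscape of
#' 25 m cells (about 13 km2) with three weakly correlated covariates
#' (`slope`, `canopy`, `simpson`; pairwise correlations 0.21, 0.18, 0.12),
#' the shipped female parameters with the male intercept calibrated to an
#' expected sex ratio of 0.5, three survey designs (2000 random points,
#' systematic transects 400 m apart, and habitat-biased subjective walks of
#' 31.2 km total length), an exponential distance-decay detection model with
#' mean detection distance 10 m truncated at 300 m, 10000 background points,
#' and 100 replicates.
#'
#' @param n_rows,n_cols,cell_size Landscape geometry.
#' @param spatial_range Covariate autocorrelation range (m).
#' @param target_correlation Between-covariate correlation matrix.
#' @param female Female [sex_params()].
#' @param male_slopes Male slope vector (intercept is calibrated).
#' @param target_ratio Expected female share the male intercept is calibrated
#'   to.
#' @param designs Subset of `c("random", "systematic", "subjective")`.
#' @param corrections Subset of `c("none", "targeted", "distance")` (the
#'   random design always uses `"none"` only).
#' @param n_random_points,transect_spacing,subjective_length,trajectory_step
#'   Survey-design parameters (m where applicable).
#' @param subjective_bias Bias strength of the subjective walker toward the
#'   male habitat surface.
#' @param subjective_paths Number of separate subjective walks.
#' @param detection A `detection_model` used both to thin counts and as the
#'   known decay in the corrections.
#' @param background_n,background_weight Background size and logistic weight.
#' @param eval_background_n Evaluation background size for AUC.
#' @param n_replicates Number of replicate simulations (default 100).
#' @param include_generic Also fit pooled-sex (generic) models.
#' @param include_auc Compute cross-validated AUC per fit.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(n_rows = 145, n_cols = 145, cell_size = 25,
                              spatial_range = 200,
                              target_correlation = NULL,
                              female = reference_params("female"),
                              male_slopes = reference_params("male")$slopes,
                              target_ratio = 0.5,
                              designs = c("random", "systematic",
                                          "subjective"),
                              corrections = c("none", "targeted", "distance"),
                              n_random_points = 2000,
                              transect_spacing = 400,
                              subjective_length = 31200,
                              trajectory_step = 25,
                              subjective_bias = 0.7,
                              subjective_paths = 12,
                              detection = detection_model(
                                "exponential", c(rate = 1 / 10),
                                truncation = 300),
                              background_n = 10000,
                              background_weight = 1000,
                              eval_background_n = 10000,
                              n_replicates = 100,
                              include_generic = TRUE,
                              include_auc = TRUE) {
  if (is.null(target_correlation)) {
    target_correlation <- diag(3)
    dimnames(target_correlation) <- list(c("slope", "canopy", "simpson"),
                                         c("slope", "canopy", "simpson"))
    target_correlation["slope", "canopy"] <-
      target_correlation["canopy", "slope"] <- 0.21
    target_correlation["slope", "simpson"] <-
      target_correlation["simpson", "slope"] <- 0.18
    target_correlation["canopy", "simpson"] <-
      target_correlation["simpson", "canopy"] <- 0.12
  }
  designs <- match.arg(designs, several.ok = TRUE)
  corrections <- match.arg(corrections, several.ok = TRUE)
  if (n_replicates < 1) stop("`n_replicates` must be at least 1")
  structure(as.list(environment()), class = "experiment_config")
}

#' Run the replicated virtual-species experiment
#'
#' Builds one synthetic landscape and fixed survey designs and backgrounds,
#' then for each replicate realizes Poisson sign counts per sex, thins them
#' through each survey design, fits presence-only SDMs per correction (and
#' per sex, plus pooled generic models), and records habitat-coefficient
#' bias, Spearman map correlations against the true intensity surfaces,
#' cross-validated AUC, and observation- and model-based sex-ratio
#' estimates. Background point locations are fixed across replicates within
#' each scenario; the whole run is reproducible from `(config, seed)`.
#'
#' @param config An [experiment_config()].
#' @param seed Integer master seed.
#' @return An object of class `sdm_experiment`: list with `coefs`,
#'   `spearman`, `auc`, `ratios`, `failures` (long data frames), the fixed
#'   `truth` parameters, `config` and `seed`. Use [summarize_experiment()]
#'   for the aggregated tables.
#' @export
run_experiment <- function(config = experiment_config(), seed = 1) {
  stopifnot(inherits(config, "experiment_config"))
  set.seed(seed)
  seeds <- as.list(sample.int(.Machine$integer.max - 1,
                              8 + config$n_replicates))
  rep_seeds <- unlist(seeds[-(1:8)])

  stack <- generate_covariates(config$n_rows, config$n_cols, 3,
                               spatial_range = config$spatial_range,
                               target_correlation = config$target_correlation,
                               cell_size = config$cell_size,
                               layer_names = rownames(config$target_correlation),
                               seed = seeds[[1]])
  ref <- stack$grids[[1]]
  female <- config$female
  male <- calibrate_male_intercept(stack, female, config$male_slopes,
                                   config$target_ratio)
  lam_f <- compute_intensity(stack, female)
  lam_m <- compute_intensity(stack, male)
  truth <- list(female = female, male = male,
                intensity = list(female = lam_f, male = lam_m))

  # fixed trajectory designs, distance grids, backgrounds --------------------
  # (the random survey points are redrawn each replicate: they emulate
  # independent surveys, unlike the fixed real-world trajectories; the
  # entry here only fixes the scenario structure)
  designs <- list()
  if ("random" %in% config$designs)
    designs$random <- random_points(ref, config$n_random_points,
                                    seed = seeds[[2]])
  if ("systematic" %in% config$designs)
    designs$systematic <- systematic_transects(ref, config$transect_spacing,
                                               seed = seeds[[3]])
  if ("subjective" %in% config$designs) {
    pref <- sdm_grid(log(lam_m$values) - male$intercept,
                     cell_size = ref$cell_size, origin = ref$origin)
    designs$subjective <- survey_design(
      "subjective",
      trajectories = generate_subjective_trajectory(
        pref, config$subjective_length, config$trajectory_step,
        bias_strength = config$subjective_bias,
        n_paths = config$subjective_paths, seed = seeds[[4]]))
  }
  dist_grids <- lapply(designs, function(d)
    if (d$kind == "random") NULL else distance_to_trajectories(ref, d))

  bg_uniform <- uniform_background(ref, config$background_n, seed = seeds[[5]])
  bg_targeted <- lapply(designs, function(d)
    if (d$kind == "random") NULL
    else targeted_background(d, config$detection, ref, config$background_n,
                             seed = seeds[[6]]))
  eval_bg <- lapply(designs, function(d)
    if (d$kind == "random")
      uniform_background(ref, config$eval_background_n, seed = seeds[[7]])
    else targeted_background(d, config$detection, ref,
                             config$eval_background_n, seed = seeds[[7]]))

  models <- c("female", "male", if (config$include_generic) "generic")
  coefs <- list(); spear <- list(); aucs <- list(); ratios <- list()
  failures <- list()

  for (r in seq_len(config$n_replicates)) {
    set.seed(rep_seeds[r])
    counts <- list(female = realize_counts(lam_f),
                   male = realize_counts(lam_m))
    for (dn in names(designs)) {
      des <- if (dn == "random")
        random_points(ref, config$n_random_points)
      else designs[[dn]]
      dg <- dist_grids[[dn]]
      recs <- lapply(counts, thin_to_presences, design = des,
                     model = config$detection, distance = dg)
      recs$generic <- rbind(recs$female, recs$male)
      nf <- nrow(recs$female); nm <- nrow(recs$male)
      if (nf + nm > 0)
        ratios[[length(ratios) + 1]] <- data.frame(
          replicate = r, design = dn, method = "observations",
          ratio = nf / (nf + nm), n_obs_f = nf, n_obs_m = nm,
          n_tot_f = NA_real_, n_tot_m = NA_real_)
      corr_set <- if (des$kind == "random") "none" else config$corrections
      for (cr in corr_set) {
        res <- tryCatch(
          run_scenario(r, dn, cr, des, dg, recs, stack, truth, config,
                       bg_uniform, bg_targeted[[dn]], eval_bg[[dn]], models),
          error = function(e) e)
        if (inherits(res, "error")) {
          failures[[length(failures) + 1]] <- data.frame(
            replicate = r, design = dn, correction = cr,
            message = conditionMessage(res))
          next
        }
        coefs[[length(coefs) + 1]] <- res$coefs
        spear[[length(spear) + 1]] <- res$spearman
        if (!is.null(res$auc)) aucs[[length(aucs) + 1]] <- res$auc
        if (!is.null(res$ratio)) ratios[[length(ratios) + 1]] <- res$ratio
      }
    }
  }
  structure(list(
    coefs = do.call(rbind, coefs),
    spearman = do.call(rbind, spear),
    auc = if (length(aucs)) do.call(rbind, aucs) else NULL,
    ratios = do.call(rbind, ratios),
    failures = if (length(failures)) do.call(rbind, failures) else NULL,
    truth = truth, designs = designs, config = config, seed = seed
  ), class = "sdm_experiment")
}

# one replicate x design x correction cell of the experiment
run_scenario <- function(r, dn, cr, des, dg, recs, stack, truth, config,
                         bg_uniform, bg_targeted, eval_bg, models) {
  bg <- if (cr == "targeted") bg_targeted else bg_uniform
  dist_arg <- if (cr == "distance") dg else NULL
  fits <- lapply(models, function(mdl)
    fit_sdm(recs[[mdl]], bg, stack, distance = dist_arg, correction = cr,
            background_weight = config$background_weight))
  names(fits) <- models
  mus <- lapply(fits, predict_relative_abundance, stack = stack)

  coefs <- do.call(rbind, lapply(models, function(mdl) {
    est <- fits[[mdl]]$coefficients
    tr <- if (mdl == "generic") rep(NA_real_, length(est))
          else truth[[mdl]]$slopes[names(est)]
    data.frame(replicate = r, design = dn, correction = cr, model = mdl,
               term = names(est), estimate = unname(est),
               truth = unname(tr), bias = unname(est - tr))
  }))

  spear_rows <- list()
  for (mdl in models) {
    targets <- if (mdl == "generic") c("female", "male") else mdl
    for (tg in targets)
      spear_rows[[length(spear_rows) + 1]] <- data.frame(
        replicate = r, design = dn, correction = cr, model = mdl,
        compare_sex = tg,
        rho = spearman_map_correlation(mus[[mdl]],
                                       truth$intensity[[tg]]))
  }

  auc_rows <- NULL
  if (config$include_auc) {
    auc_rows <- do.call(rbind, lapply(models, function(mdl) {
      a <- cv_auc(recs[[mdl]], eval_bg, fits[[mdl]], stack)
      data.frame(replicate = r, design = dn, correction = cr, model = mdl,
                 auc_mean = a$auc_mean, auc_variance = a$auc_variance)
    }))
  }

  ratio_row <- NULL
  if (all(c("female", "male") %in% models)) {
    p_obs <- lapply(c(female = "female", male = "male"), function(sx) {
      if (des$kind == "random")
        detection_grid("sampled-cells", design = des,
                       grid = stack$grids[[1]])
      else if (cr == "distance")
        detection_grid("distance-model", distance = dg, fit = fits[[sx]])
      else
        detection_grid("detection-density", distance = dg,
                       model = config$detection)
    })
    est <- sex_ratio_from_models(nrow(recs$female), nrow(recs$male),
                                 mus$female, mus$male,
                                 p_obs$female, p_obs$male,
                                 method = paste0("model-", cr))
    ratio_row <- data.frame(
      replicate = r, design = dn, method = paste0("model-", cr),
      ratio = est$ratio, n_obs_f = est$n_obs[["female"]],
      n_obs_m = est$n_obs[["male"]],
      n_tot_f = est$n_tot[["female"]], n_tot_m = est$n_tot[["male"]])
  }

  list(coefs = coefs, spearman = do.call(rbind, spear_rows),
       auc = auc_rows, ratio = ratio_row)
}

#' @export
print.sdm_experiment <- function(x, ...) {
  cat(sprintf("<sdm_experiment> %d replicate(s), designs: %s\n",
              x$config$n_replicates,
              paste(names(x$designs), collapse = ", ")))
  if (!is.null(x$failures))
    cat(sprintf("  %d failed scenario cell(s)\n", nrow(x$failures)))
  invisible(x)
}

#' Aggregate experiment results
#'
#' Produces the summary tables of the experiment: mean and sd of the
#' habitat-coefficient estimates and their bias per scenario, mean and sd of
#' the Spearman map correlations, and median/quartiles of the sex-ratio
#' estimates per design and estimation method.
#'
#' @param experiment An `sdm_experiment` from [run_experiment()].
#' @return List of data frames `bias`, `spearman`, `ratios` (and `auc` when
#'   present).
#' @export
summarize_experiment <- function(experiment) {
  stopifnot(inherits(experiment, "sdm_experiment"))
  cf <- experiment$coefs
  bias <- do.call(rbind, lapply(
    split(cf, list(cf$design, cf$correction, cf$model, cf$term),
          drop = TRUE),
    function(g) data.frame(
      design = g$design[1], correction = g$correction[1], model = g$model[1],
      term = g$term[1], mean_estimate = mean(g$estimate),
      sd_estimate = stats::sd(g$estimate), truth = g$truth[1],
      mean_bias = mean(g$bias), mean_abs_bias = mean(abs(g$bias)))))
  sp <- experiment$spearman
  spearman <- do.call(rbind, lapply(
    split(sp, list(sp$design, sp$correction, sp$model, sp$compare_sex),
          drop = TRUE),
    function(g) data.frame(
      design = g$design[1], correction = g$correction[1], model = g$model[1],
      compare_sex = g$compare_sex[1],
      mean_rho = mean(g$rho, na.rm = TRUE),
      sd_rho = stats::sd(g$rho, na.rm = TRUE))))
  rt <- experiment$ratios
  ratios <- do.call(rbind, lapply(
    split(rt, list(rt$design, rt$method), drop = TRUE),
    function(g) data.frame(
      design = g$design[1], method = g$method[1],
      median_ratio = stats::median(g$ratio),
      q1_ratio = unname(stats::quantile(g$ratio, 0.25)),
      q3_ratio = unname(stats::quantile(g$ratio, 0.75)),
      sd_ratio = stats::sd(g$ratio),
      mean_n_obs_f = mean(g$n_obs_f), mean_n_obs_m = mean(g$n_obs_m))))
  out <- list(bias = bias, spearman = spearman, ratios = ratios)
  if (!is.null(experiment$auc)) {
    au <- experiment$auc
    out$auc <- do.call(rbind, lapply(
      split(au, list(au$design, au$correction, au$model), drop = TRUE),
      function(g) data.frame(
        design = g$design[1], correction = g$correction[1],
        model = g$model[1], mean_auc = mean(g$auc_mean),
        sd_auc = stats::sd(g$auc_mean))))
  }
  lapply(out, function(d) { rownames(d) <- NULL; d })
}
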