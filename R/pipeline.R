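# Pipeline orchestration: simulate -> fit-surface -> train -> predict ->
# report, driven by a single validated JSON config with one seed propagated
# to every stochastic stage. Reruns with the same config are bit-identical.

.config_schema <- list(
  output_dir = "character", seed = "numeric", log_level = "character",
  phantom = list(n_train = "numeric", n_test = "numeric",
                 age_range = "numeric", voxel_size = "numeric",
                 speckle_level = "numeric", hemisphere = "character"),
  fit = list(enabled = "logical", lambda1 = "numeric", lambda2 = "numeric",
             lambda3 = "numeric", lambda4 = "numeric",
             fa_threshold = "numeric", max_alternations = "numeric",
             inflate = "numeric"),
  forest = list(n_trees = "numeric", max_depth = "numeric",
                m_candidates = "numeric", min_samples = "numeric",
                min_gain = "numeric", sigma_max2 = "numeric",
                bag_fraction = "numeric", banks = "character"),
  report = list(maturation_depth = "numeric")
)

#' Default pipeline configuration
#' @export
default_config <- function(output_dir = tempfile("cranioage_run_"),
                           seed = 1L) {
  list(output_dir = output_dir, seed = as.integer(seed), log_level = "info",
       phantom = list(n_train = 30, n_test = 10, age_range = c(18, 34),
                      voxel_size = 1.5, speckle_level = 0.4,
                      hemisphere = "right"),
       fit = list(enabled = FALSE, lambda1 = 1.0, lambda2 = 0.1,
                  lambda3 = 0.01, lambda4 = 0.1, fa_threshold = 0.4,
                  max_alternations = 10, inflate = 1.08),
       forest = list(n_trees = 8, max_depth = 12, m_candidates = 50,
                     min_samples = 5, min_gain = 1e-3, sigma_max2 = 1.0,
                     bag_fraction = 0.67,
                     banks = c("haar3d", "unary", "binary_context",
                               "size_euclid", "size_ortho", "inner_hc")),
       report = list(maturation_depth = 3))
}

#' Validate a pipeline configuration
#'
#' Unknown keys (at either level) are rejected; types are checked against
#' the schema. Returns the config merged over defaults.
#' @export
validate_config <- function(config) {
  def <- default_config()
  unknown <- setdiff(names(config), names(.config_schema))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (sec in names(config)) {
    spec <- .config_schema[[sec]]
    if (is.list(spec)) {
      unknown <- setdiff(names(config[[sec]]), names(spec))
      if (length(unknown))
        stop("unknown config key(s) in '", sec, "': ",
             paste(unknown, collapse = ", "))
      for (k in names(config[[sec]])) {
        if (!inherits(config[[sec]][[k]], spec[[k]]) &&
            !(spec[[k]] == "numeric" && is.numeric(config[[sec]][[k]])))
          stop("config '", sec, ".", k, "' must be ", spec[[k]])
        def[[sec]][[k]] <- config[[sec]][[k]]
      }
    } else {
      def[[sec]] <- config[[sec]]
    }
  }
  def
}

#' Read a pipeline configuration from JSON
#' @export
read_config <- function(path) {
  validate_config(jsonlite::read_json(path, simplifyVector = TRUE))
}

log_msg <- function(cfg, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                  paste0(...)))
}

#' Run the pipeline
#'
#' Stages: `simulate` (phantom cohorts + cohort tables), `fit` (surface
#' fitting per phantom; with `fit$enabled = FALSE` the known ground-truth
#' placement is used instead), `train` (per-hemisphere forest ->
#' model.json), `predict` (predictions.csv on the test cohort) and
#' `report` (RMSE/correlation summary, feature profiles, error-margin and
#' maturation-map artifacts). A manifest records the config, seeds and
#' output hashes.
#'
#' @param config config list (see [default_config()]); validated first.
#' @param stages subset of stages to run (dependencies are checked).
#' @return invisibly, a list of produced artifact paths.
#' @export
run_pipeline <- function(config = default_config(),
                         stages = c("simulate", "fit", "train", "predict",
                                    "report")) {
  cfg <- validate_config(config)
  all_stages <- c("simulate", "fit", "train", "predict", "report")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  out <- cfg$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  art <- list()
  state_path <- function(nm) file.path(out, nm)

  need <- function(path, stage_hint) {
    if (!file.exists(path))
      stop("missing dependency artifact ", path, "; run the '", stage_hint,
           "' stage first")
    path
  }

  if ("simulate" %in% stages) {
    log_msg(cfg, "simulate: generating ", cfg$phantom$n_train, "+",
            cfg$phantom$n_test, " phantoms")
    tr_dir <- state_path("train_volumes")
    te_dir <- state_path("test_volumes")
    co_tr <- make_cohort(cfg$phantom$n_train, cfg$phantom$age_range,
                         seed = cfg$seed, hemisphere = cfg$phantom$hemisphere,
                         write_dir = tr_dir,
                         voxel_size = cfg$phantom$voxel_size,
                         speckle_level = cfg$phantom$speckle_level)
    co_te <- make_cohort(cfg$phantom$n_test, cfg$phantom$age_range,
                         seed = cfg$seed + 1L,
                         hemisphere = cfg$phantom$hemisphere,
                         write_dir = te_dir,
                         voxel_size = cfg$phantom$voxel_size,
                         speckle_level = cfg$phantom$speckle_level)
    art$train_cohort <- file.path(tr_dir, "cohort.csv")
    art$test_cohort <- file.path(te_dir, "cohort.csv")
  }

  load_cohort <- function(dir_nm) {
    tab <- utils::read.csv(need(file.path(state_path(dir_nm), "cohort.csv"),
                                "simulate"), stringsAsFactors = FALSE)
    n <- nrow(tab)
    seed0 <- if (dir_nm == "train_volumes") cfg$seed else cfg$seed + 1L
    ages <- with_seed(seed0, stats::runif(n, cfg$phantom$age_range[1],
                                          cfg$phantom$age_range[2]))
    lapply(seq_len(n), function(i) {
      sp <- phantom_spec(age = ages[i],
                         occluded_side = if (tab$hemisphere[i] == "left")
                           "right" else "left",
                         seed = child_seed(seed0, i),
                         voxel_size = cfg$phantom$voxel_size,
                         speckle_level = cfg$phantom$speckle_level)
      make_phantom(sp)
    })
  }

  build_examples <- function(phs, fitted_dir = NULL) {
    lapply(seq_along(phs), function(i) {
      ph <- phs[[i]]
      X <- NULL
      if (!is.null(fitted_dir)) {
        fp <- file.path(fitted_dir, sprintf("fitted_%03d.csv", i))
        if (file.exists(fp)) X <- as.matrix(utils::read.csv(fp))
      }
      phantom_example(ph, X = X)
    })
  }

  if ("fit" %in% stages && isTRUE(cfg$fit$enabled)) {
    log_msg(cfg, "fit: deformable surface fitting")
    fit_dir <- state_path("fitted")
    dir.create(fit_dir, showWarnings = FALSE)
    params <- energy_params(cfg$fit$lambda1, cfg$fit$lambda2,
                            cfg$fit$lambda3, cfg$fit$lambda4)
    phs <- load_cohort("train_volumes")
    for (i in seq_along(phs)) {
      ph <- phs[[i]]
      X0 <- phantom_initialization(ph, inflate = cfg$fit$inflate)
      ft <- fit_cranial_surface(volume = ph$volume, X0 = X0,
                                surface = default_surface(),
                                params = params,
                                fa_threshold = cfg$fit$fa_threshold,
                                max_alternations = cfg$fit$max_alternations)
      utils::write.csv(as.data.frame(ft$X),
                       file.path(fit_dir, sprintf("fitted_%03d.csv", i)),
                       row.names = FALSE)
      utils::write.csv(ft$trace,
                       file.path(fit_dir, sprintf("trace_%03d.csv", i)),
                       row.names = FALSE)
    }
    art$fitted_dir <- fit_dir
  }

  if ("train" %in% stages) {
    log_msg(cfg, "train: growing the regression forest")
    phs <- load_cohort("train_volumes")
    exs <- build_examples(phs, if (isTRUE(cfg$fit$enabled))
      state_path("fitted") else NULL)
    hp <- forest_hyperparams(n_trees = cfg$forest$n_trees,
                             max_depth = cfg$forest$max_depth,
                             m_candidates = cfg$forest$m_candidates,
                             min_samples = cfg$forest$min_samples,
                             min_gain = cfg$forest$min_gain,
                             sigma_max2 = cfg$forest$sigma_max2,
                             bag_fraction = cfg$forest$bag_fraction,
                             seed = cfg$seed + 2L)
    fo <- train_forest(exs, hp, banks = cfg$forest$banks)
    art$model <- state_path("model.json")
    write_forest(fo, art$model)
  }

  if ("predict" %in% stages) {
    log_msg(cfg, "predict: applying the model to the test cohort")
    fo <- read_forest(need(state_path("model.json"), "train"))
    phs <- load_cohort("test_volumes")
    exs <- build_examples(phs)
    pr <- lapply(exs, function(e) predict_age(fo, e))
    tab <- data.frame(id = sprintf("phantom_%03d", seq_along(exs)),
                      true_age = vapply(exs, function(e) e$age, numeric(1)),
                      pred_age = vapply(pr, function(p) p$age, numeric(1)),
                      used_leaves = vapply(pr, function(p) p$used_leaves,
                                           numeric(1)),
                      fallback = vapply(pr, function(p) p$fallback_used,
                                        logical(1)))
    art$predictions <- state_path("predictions.csv")
    utils::write.csv(tab, art$predictions, row.names = FALSE)
  }

  if ("report" %in% stages) {
    log_msg(cfg, "report: summaries and diagnostics")
    tab <- utils::read.csv(need(state_path("predictions.csv"), "predict"))
    fo <- read_forest(need(state_path("model.json"), "train"))
    rm_ <- rmse_ga(tab$pred_age, tab$true_age)
    summ <- list(rmse_gw = rm_$gw, rmse_days = rm_$days,
                 pearson_r = stats::cor(tab$pred_age, tab$true_age),
                 n_test = nrow(tab))
    art$summary <- state_path("report_summary.json")
    jsonlite::write_json(summ, art$summary, auto_unbox = TRUE, digits = NA)
    dg <- forest_diagnostics(fo)
    art$profile <- state_path("feature_profile.csv")
    utils::write.csv(dg$profile, art$profile, row.names = FALSE)
    em <- tryCatch(error_margin(tab$pred_age, tab$true_age,
                                age_grid = seq(cfg$phantom$age_range[1],
                                               cfg$phantom$age_range[2], 0.5)),
                   error = function(e) NULL)
    if (!is.null(em)) {
      art$delta_w <- state_path("delta_w.csv")
      utils::write.csv(em$delta_w, art$delta_w, row.names = FALSE)
    }
    phs <- load_cohort("test_volumes")
    ref <- phantom_example(phs[[1]])
    mm <- maturation_map(fo, cfg$report$maturation_depth, ref)
    art$maturation <- state_path("maturation_map.nii.gz")
    write_volume(mm, art$maturation)
  }

  # manifest: config, seed and artifact hashes
  ver <- tryCatch(as.character(utils::packageVersion("cranioage")),
                  error = function(e) "dev")
  manifest <- list(package_version = ver,
                   seed = cfg$seed, config = cfg,
                   artifacts = lapply(Filter(function(p) is.character(p) &&
                                               file.exists(p), art),
                                      function(p) unname(tools::md5sum(p))))
  jsonlite::write_json(manifest, state_path("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(art)
}
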