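# End-to-end driver: phantoms -> paired simulation -> patch datasets ->
# training -> correction -> evaluation, with a manifest capturing every
# resolved parameter and seed.

#' Desk-scale configuration plan
#'
#' A reduced plan for single-CPU runs: five brain surrogates (one per
#' deformation), three five-rod phantoms (TBR 0, 5, 10), the cold-sphere
#' and the twenty-rod phantom.  The phantom-level split rules still apply:
#' brains 4 train / 1 test, rod5 TBR 0 and 5 train, TBR 10 test.
#'
#' @return A `configuration_plan` tibble.
#' @export
desk_configuration_plan <- function() {
  entries <- tibble::tibble(
    family = c(rep("brain", 5), rep("rod5", 3), "sphere1", "rod20"),
    config_id = c(sprintf("brain_t0.0_r0_d%d", 0:4),
                  sprintf("rod5_tbr%g", c(0, 5, 10)), "sphere1", "rod20"),
    tbr = c(rep(NA_real_, 5), 0, 5, 10, NA_real_, NA_real_),
    translation_x = c(rep(0, 5), rep(NA_real_, 5)),
    translation_y = c(rep(0, 5), rep(NA_real_, 5)),
    rotation_deg = c(rep(0, 5), rep(NA_real_, 5)),
    deformation = c(0:4, rep(NA_integer_, 5)))
  structure(entries, class = c("configuration_plan", class(entries)))
}

#' Pipeline run configuration
#'
#' The `"desk"` preset (default) runs the whole pipeline on one CPU in
#' minutes: 128 x 128 in-plane grids at 0.8 mm voxels (60 slices for the
#' cylindrical phantoms, 150 for the brain), the reduced
#' [desk_configuration_plan()], and a 2000-iteration training budget.
#' The `"full"` preset uses the complete 30-configuration plan on
#' 250 x 250 grids at 0.4 mm with a 50000-iteration budget.
#'
#' @param out_dir Output directory for all run artifacts.
#' @param seed Global seed; every stage derives its own sub-seed from it.
#' @param preset `"desk"` or `"full"`.
#' @param architectures Architectures to train (subset of CNN1/CNN2/CNN3).
#' @param iterations Training iterations (overrides the preset budget).
#' @param plan Optional plan override (a `configuration_plan` tibble).
#' @param grid,brain_grid Optional grid overrides.
#' @param acq Named list of [acq_config()] overrides (e.g.
#'   `list(psf_fwhm_mm = 1)`).
#' @param train Named list of [train_config()] overrides.
#' @return A `run_config` list of resolved parameters.
#' @export
run_config <- function(out_dir, seed = 1L, preset = c("desk", "full"),
                       architectures = "CNN1", iterations = NULL,
                       plan = NULL, grid = NULL, brain_grid = NULL,
                       acq = list(), train = list()) {
  preset <- match.arg(preset)
  stopifnot(all(architectures %in% c("CNN1", "CNN2", "CNN3")))
  if (preset == "desk") {
    grid <- grid %||% phantom_grid(128L, 60L, 0.8)
    brain_grid <- brain_grid %||% phantom_grid(128L, 150L, 0.8)
    plan <- plan %||% desk_configuration_plan()
    iterations <- iterations %||% 2000L
  } else {
    grid <- grid %||% phantom_grid(250L, 200L, 0.4)
    brain_grid <- brain_grid %||% phantom_grid(250L, 290L, 0.4)
    plan <- plan %||% default_configuration_plan()
    iterations <- iterations %||% 50000L
  }
  acq_args <- modifyList(list(seed = derive_seed(seed, "acq")), acq)
  structure(list(out_dir = out_dir, seed = as.integer(seed), preset = preset,
                 architectures = architectures,
                 iterations = as.integer(iterations), plan = plan,
                 grid = grid, brain_grid = brain_grid,
                 acq = do.call(acq_config, acq_args),
                 train_overrides = train),
            class = "run_config")
}

stage_msg <- function(log, stage, ...) {
  msg <- sprintf(...)
  message(sprintf("[%s] %s", stage, msg))
  c(log, sprintf("[%s] %s", stage, msg))
}

label_size_for <- function(arch) if (arch == "CNN1") 20L else 18L

#' Run the full correction pipeline
#'
#' Executes all stages — phantom generation, paired gamma/Ga-68
#' simulation, patch-dataset construction, network training, whole-volume
#' correction of the held-out and evaluation phantoms, and metric
#' computation — writing phantoms, volumes, patch stores, checkpoints, a
#' metrics report and a JSON manifest under `cfg$out_dir`.
#'
#' @param cfg A [run_config()].
#' @param write_volumes Write NIfTI volumes for all stages (disable to
#'   keep only metrics, checkpoints and the manifest).
#' @return Invisibly, the manifest list; its `metrics` element is the
#'   comparison table (one row per phantom family x variant x metric).
#' @export
run_pipeline <- function(cfg, write_volumes = TRUE) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- character(0)
  t0 <- Sys.time()

  # --- stage 1: phantoms ---------------------------------------------------
  log <- stage_msg(log, "phantoms", "materializing %d configurations",
                   nrow(cfg$plan))
  phantoms <- enumerate_configurations(cfg$plan, grid = cfg$grid,
                                       brain_grid = cfg$brain_grid,
                                       seed = derive_seed(cfg$seed, "phantoms"))
  if (write_volumes)
    for (ph in phantoms) write_phantom(ph, file.path(cfg$out_dir, "phantoms"))

  # --- stage 2: paired simulation -----------------------------------------
  log <- stage_msg(log, "simulate", "simulating %d gamma/ga68 pairs",
                   length(phantoms))
  kernels <- list()
  pairs <- list()
  for (ph in phantoms) {
    vx <- as.character(ph$voxel_size_mm)
    if (is.null(kernels[[vx]]))
      kernels[[vx]] <- build_range_kernel(cfg$acq$range_mean_mm,
                                          ph$voxel_size_mm,
                                          law = cfg$acq$range_law,
                                          params = cfg$acq$range_params)
    pr <- simulate_pair(ph, cfg$acq, kernel = kernels[[vx]])
    pairs[[ph$config_id]] <- list(gamma = pr$gamma, ga68 = pr$ga68,
                                  family = ph$family, tbr = ph$tbr)
    if (write_volumes) {
      write_image_volume(pr$gamma, file.path(cfg$out_dir, "images"))
      write_image_volume(pr$ga68, file.path(cfg$out_dir, "images"))
    }
  }

  # --- stage 3: patch datasets --------------------------------------------
  label_sizes <- unique(vapply(cfg$architectures, label_size_for, integer(1)))
  splits <- list()
  for (ls in label_sizes) {
    splits[[as.character(ls)]] <- make_splits(pairs, label_size = ls)
    if (write_volumes) {
      write_patch_set(splits[[as.character(ls)]]$train,
                      file.path(cfg$out_dir, "patches",
                                sprintf("train_label%d", ls)))
      write_patch_set(splits[[as.character(ls)]]$test,
                      file.path(cfg$out_dir, "patches",
                                sprintf("test_label%d", ls)))
    }
    log <- stage_msg(log, "dataset",
                     "label %d: %d training / %d testing patches", ls,
                     dim(splits[[as.character(ls)]]$train$inputs)[3],
                     dim(splits[[as.character(ls)]]$test$inputs)[3])
  }

  # --- stage 4: training ---------------------------------------------------
  models <- list()
  for (arch in cfg$architectures) {
    sp <- splits[[as.character(label_size_for(arch))]]
    tc_args <- modifyList(
      list(iterations = cfg$iterations,
           seed = derive_seed(cfg$seed, paste0("train:", arch))),
      cfg$train_overrides)
    tc <- do.call(train_config, tc_args)
    model <- init_weights(build_model(arch),
                          seed = derive_seed(cfg$seed, paste0("init:", arch)))
    log <- stage_msg(log, "train", "%s: %d iterations on %d patches", arch,
                     tc$iterations, dim(sp$train$inputs)[3])
    model <- train(model, sp$train, tc, test_data = sp$test)
    models[[arch]] <- model
    save_model(model, file.path(cfg$out_dir, "models", arch))
  }

  # --- stage 5: correction -------------------------------------------------
  fam <- vapply(pairs, function(p) p$family, character(1))
  tbr <- vapply(pairs, function(p) p$tbr %||% NA_real_, numeric(1))
  ids <- names(pairs)
  brain_ids <- ids[fam == "brain"]
  n_test_brain <- if (length(brain_ids)) max(1L, floor(length(brain_ids) / 5)) else 0L
  eval_ids <- c(tail(brain_ids, n_test_brain),
                ids[fam == "rod5" & tbr %in% TEST_ROD5_TBRS],
                ids[fam %in% c("sphere1", "rod20")])
  corrected <- list()
  for (arch in cfg$architectures) {
    corrected[[arch]] <- list()
    for (id in eval_ids) {
      corrected[[arch]][[id]] <- apply_correction(models[[arch]],
                                                  pairs[[id]]$ga68)
      if (write_volumes)
        write_image_volume(corrected[[arch]][[id]],
                           file.path(cfg$out_dir, "corrected"))
    }
    log <- stage_msg(log, "correct", "%s: corrected %d evaluation volumes",
                     arch, length(eval_ids))
  }

  # --- stage 6: evaluation -------------------------------------------------
  metrics <- evaluate_run(pairs, corrected, phantoms, eval_ids)
  write_metrics_report(metrics, file.path(cfg$out_dir, "metrics", "report"))
  log <- stage_msg(log, "evaluate", "%d metric rows", nrow(metrics))

  manifest <- list(
    preset = cfg$preset, seed = cfg$seed,
    architectures = cfg$architectures, iterations = cfg$iterations,
    acq = unclass(cfg$acq),
    grid = unclass(cfg$grid), brain_grid = unclass(cfg$brain_grid),
    plan = as.data.frame(cfg$plan),
    evaluation_ids = eval_ids,
    patch_counts = lapply(splits, function(s)
      list(train = dim(s$train$inputs)[3], test = dim(s$test$inputs)[3])),
    checkpoints = as.list(file.path("models", paste0(cfg$architectures, ".rds"))),
    log = log,
    timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  write_json_file(manifest, file.path(cfg$out_dir, "manifest.json"))
  manifest$metrics <- metrics
  invisible(manifest)
}

# Metric comparison table across image variants (gamma reference, raw
# ga68, and each architecture's correction).
evaluate_run <- function(pairs, corrected, phantoms, eval_ids) {
  fam <- vapply(pairs, function(p) p$family, character(1))
  rows <- list()
  add <- function(tbl, family, config_id) {
    tbl$family <- family
    tbl$config_id <- config_id
    rows[[length(rows) + 1]] <<- tbl
  }
  # whole-image RMSE/PSNR on held-out volumes
  for (id in eval_ids[fam[eval_ids] %in% c("brain", "rod5")]) {
    gamma <- pairs[[id]]$gamma
    add(metrics_table(compute_pair_stats(gamma, pairs[[id]]$ga68)),
        fam[id], id)
    for (arch in names(corrected))
      add(metrics_table(compute_pair_stats(gamma, corrected[[arch]][[id]])),
          fam[id], id)
  }
  # RC from the held-out rod5 + sphere1, SOR from sphere1
  rod5_id <- eval_ids[fam[eval_ids] == "rod5"][1]
  sph_id <- eval_ids[fam[eval_ids] == "sphere1"][1]
  if (!is.na(rod5_id) && !is.na(sph_id)) {
    rod5_ph <- phantoms[[rod5_id]]
    sph_ph <- phantoms[[sph_id]]
    variants <- c(list(gamma = list(rod5 = pairs[[rod5_id]]$gamma,
                                    sph = pairs[[sph_id]]$gamma),
                       ga68 = list(rod5 = pairs[[rod5_id]]$ga68,
                                   sph = pairs[[sph_id]]$ga68)),
                  lapply(corrected, function(cc)
                    list(rod5 = cc[[rod5_id]], sph = cc[[sph_id]])))
    for (v in names(variants)) {
      add(metrics_table(compute_rc(variants[[v]]$rod5, rod5_ph,
                                   variants[[v]]$sph)),
          "rod5", rod5_id)
      add(metrics_table(compute_sor(variants[[v]]$sph, sph_ph)),
          "sphere1", sph_id)
    }
  }
  out <- do.call(rbind, rows)
  out[, c("family", "config_id", "variant", "metric", "diameter_mm", "value")]
}

#' Generate tiny analytic fixtures
#'
#' Small (at most 64^3) phantom/image bundles with closed-form metric
#' values in their sidecar, for unit testing and demonstrations:
#' `"point_source"` (one hot voxel), `"uniform_cylinder"` (RC = 1 by
#' construction), `"rod5_const"` (a reduced five-rod phantom) and
#' `"cold_sphere"` (SOR = 0 without blur or noise).
#'
#' @param kind Fixture kind.
#' @param seed Seed recorded in the bundle.
#' @return A list with `phantom`, noise-free `gamma`/`ga68` expectation
#'   images (for the image-bearing kinds) and a `sidecar` of closed-form
#'   values.
#' @export
fixture_generator <- function(kind = c("point_source", "uniform_cylinder",
                                       "rod5_const", "cold_sphere"),
                              seed = 1L) {
  kind <- match.arg(kind)
  grid <- phantom_grid(64L, 24L, 0.8)
  acq <- acq_config(seed = seed)
  if (kind == "point_source") {
    act <- array(0, c(33, 33, 33))
    act[17, 17, 17] <- 1e6
    lab <- array(0L, dim(act))
    lab[17, 17, 17] <- 1L
    ph <- new_voxel_phantom(act, lab, phantom_grid(33L, 33L, 0.4), "rod5",
                            sprintf("fixture_point_%d", seed))
    side <- list(kind = kind, seed = seed, nonzero_voxels = 1,
                 center_index = c(17, 17, 17))
    return(list(phantom = ph, sidecar = side))
  }
  if (kind == "uniform_cylinder") {
    ph <- make_rod5_phantom(1, grid = grid,
                            config_id = sprintf("fixture_unif_%d", seed))
    # TBR 1: rods and background share one concentration -> RC = 1
    side <- list(kind = kind, seed = seed, rc = 1,
                 activity_bq_ml = ROD_ACTIVITY_BQ_ML)
    return(list(phantom = ph, sidecar = side))
  }
  if (kind == "rod5_const") {
    ph <- make_rod5_phantom(0, grid = grid,
                            config_id = sprintf("fixture_rod5_%d", seed))
    pair <- simulate_pair(ph, acq, noise = FALSE)
    side <- list(kind = kind, seed = seed, tbr = 0,
                 rod_activity_bq_ml = ROD_ACTIVITY_BQ_ML)
    return(list(phantom = ph, gamma = pair$gamma, ga68 = pair$ga68,
                sidecar = side))
  }
  ph <- make_sphere1_phantom(grid = grid,
                             config_id = sprintf("fixture_sphere_%d", seed))
  img <- simulate_image(ph, acq_config(psf_fwhm_mm = 1e-6, seed = seed),
                        "gamma", noise = FALSE)
  side <- list(kind = kind, seed = seed, sor = 0,
               note = "no blur, no noise: the cold sphere stays exactly cold")
  list(phantom = ph, gamma = img, sidecar = side)
}
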