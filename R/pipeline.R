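# End-to-end pipeline driver: simulate -> preprocess -> train -> predict ->
# quantify -> evaluate, each stage writing its artifacts plus a JSON
# provenance sidecar (stage, package version, seed, config hash) so any
# artifact can be re-created from its sidecar plus the config file.

PIPELINE_STAGES <- c("simulate", "preprocess", "train", "predict",
                     "quantify", "evaluate")

#' Read and validate a pipeline configuration
#'
#' The YAML file holds one block per stage (`scene`, `preprocess`, `train`,
#' `tile`, `quantify`, `evaluate`), an optional `io` block with input paths,
#' and a global `seed`. Missing blocks fall back to package defaults.
#'
#' @param path YAML file.
#' @return a `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  as_pipeline_config(cfg)
}

#' @rdname read_pipeline_config
#' @param cfg a raw config list (as from [yaml::read_yaml()]).
#' @export
as_pipeline_config <- function(cfg = list()) {
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$scene <- cfg$scene %||% list()
  cfg$preprocess <- cfg$preprocess %||% list()
  cfg$train <- cfg$train %||% list()
  cfg$tile <- cfg$tile %||% list()
  cfg$quantify <- cfg$quantify %||% list()
  cfg$evaluate <- cfg$evaluate %||% list()
  cfg$io <- cfg$io %||% list()
  structure(cfg, class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_hash <- function(cfg) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(unclass(cfg), f)
  unname(tools::md5sum(f))
}

write_provenance <- function(artifact_path, stage, cfg, seed, extra = list()) {
  side <- paste0(artifact_path, ".provenance.json")
  jsonlite::write_json(c(list(
    artifact = basename(artifact_path),
    stage = stage,
    package = "capiwide",
    version = as.character(utils::packageVersion("capiwide")),
    seed = seed,
    config_md5 = config_hash(cfg)
  ), extra), side, auto_unbox = TRUE, digits = NA)
  invisible(side)
}

# quantile-based green-channel threshold: the classical (non-learned)
# capillary extraction used when no trained model/predicted mask exists;
# pixels in the darkest-green `q` fraction become foreground.
threshold_green_mask <- function(still, q = 0.08) {
  g <- still[, , 2]
  cut <- stats::quantile(g, q, names = FALSE, type = 1)
  mask <- matrix(0L, nrow(g), ncol(g))
  mask[g <= cut] <- 255L
  mask
}

#' Run the capillaroscopy analysis pipeline
#'
#' Executes the requested stages in canonical order
#' (simulate, preprocess, train, predict, quantify, evaluate), passing
#' results between stages in memory and writing every artifact with a
#' provenance sidecar under `out_dir/<stage>/`. Stages whose inputs were not
#' produced by an earlier stage read them from the paths in `config$io`
#' (`frames`, `still`, `model`, `mask`, `gt_mask`, `pairs`). Deterministic
#' stages re-run with the same config and seed reproduce identical artifacts.
#'
#' If `quantify` runs without a predicted mask (no `predict` stage, no
#' `io$mask`), the still's green channel is thresholded at the darkest
#' `quantify$threshold_quantile` fraction (default 0.08) — the classical
#' non-learned extraction — so the short simulate/preprocess/quantify chain
#' is self-contained.
#'
#' @param config a `pipeline_config` (see [read_pipeline_config()]).
#' @param stages subset of the six stage names.
#' @param out_dir artifact directory.
#' @return (invisibly) a list of in-memory stage results.
#' @export
run_pipeline <- function(config, stages = PIPELINE_STAGES, out_dir = "capiwide_out") {
  config <- as_pipeline_config(unclass(config))
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  state <- list()

  for (stage in stages) {
    sdir <- file.path(out_dir, stage)
    dir.create(sdir, showWarnings = FALSE)
    t0 <- proc.time()[["elapsed"]]

    if (stage == "simulate") {
      scfg <- do.call(scene_config, c(config$scene,
                                      if (is.null(config$scene$seed)) list(seed = seed)))
      sim <- generate_scene(scfg)
      state$stack <- sim$stack
      state$gt_mask <- sim$ground_truth$capillary_mask
      state$sim <- sim
      write_frames(sim$stack, file.path(sdir, "frames"))
      write_mask(sim$ground_truth$capillary_mask, file.path(sdir, "gt_mask.png"))
      write_offsets_csv(sim$ground_truth$jitter_offsets,
                        file.path(sdir, "jitter_offsets.csv"))
      yaml::write_yaml(unclass(scfg), file.path(sdir, "scene_config.yaml"))
      write_provenance(file.path(sdir, "gt_mask.png"), stage, config, seed,
                       list(region_count = sim$ground_truth$region_count))

    } else if (stage == "preprocess") {
      stack <- state$stack %||% {
        if (is.null(config$io$frames)) stop("preprocess: no frames (run simulate or set io$frames)")
        read_frames(config$io$frames,
                    um_per_px = config$io$um_per_px %||% NA_real_,
                    fps = config$io$fps %||% NA_real_)
      }
      pp <- config$preprocess
      res <- preprocess_video(
        stack,
        template_margin_px = pp$template_margin_px %||% 50,
        flat = do.call(flat_field_config, pp$flat %||% list()),
        con = do.call(contrast_config, pp$contrast %||% list()))
      state$still <- res$still
      state$margin <- res$stabilization$margin_px
      if (!is.null(state$gt_mask))
        state$gt_still_mask <- crop_margin(state$gt_mask, state$margin)
      write_still(res$still, file.path(sdir, "still.png"))
      write_offsets_csv(res$stabilization$offsets, file.path(sdir, "offsets.csv"))
      write_provenance(file.path(sdir, "still.png"), stage, config, seed)

    } else if (stage == "train") {
      tr <- config$train
      pairs <- if (!is.null(config$io$pairs)) {
        lapply(config$io$pairs, function(p)
          list(image = read_still(p$image), mask = read_mask(p$mask)))
      } else {
        if (is.null(state$still) || is.null(state$gt_still_mask))
          stop("train: no annotation pairs (run simulate+preprocess or set io$pairs)")
        list(list(image = state$still, mask = state$gt_still_mask))
      }
      tcfg <- do.call(train_config, c(tr, if (is.null(tr$seed)) list(seed = seed)))
      patches <- sample_patches(pairs, tcfg)
      model <- train_segmenter(patches, tcfg)
      state$model <- model
      save_segmenter(model, file.path(sdir, "model.rds"))
      write.csv(model$train_log, file.path(sdir, "train_log.csv"), row.names = FALSE)
      write_provenance(file.path(sdir, "model.rds"), stage, config, seed,
                       list(final_loss = utils::tail(model$train_log$loss, 1)))

    } else if (stage == "predict") {
      model <- state$model %||% {
        if (is.null(config$io$model)) stop("predict: no model (run train or set io$model)")
        load_segmenter(config$io$model)
      }
      still <- state$still %||% {
        if (is.null(config$io$still)) stop("predict: no still (run preprocess or set io$still)")
        read_still(config$io$still)
      }
      tcfg <- do.call(tile_config, config$tile)
      pred <- predict_tiled(model, still, tcfg)
      state$pred_mask <- pred$mask
      state$probability <- pred$probability
      write_mask(pred$mask, file.path(sdir, "mask.png"))
      tiff::writeTIFF(pred$probability, file.path(sdir, "probability.tif"),
                      bits.per.sample = 32L)
      write_provenance(file.path(sdir, "mask.png"), stage, config, seed,
                       list(window_px = tcfg$window_px, stride_px = tcfg$stride_px,
                            threshold = tcfg$threshold))

    } else if (stage == "quantify") {
      qc <- config$quantify
      mask <- state$pred_mask %||% {
        if (!is.null(config$io$mask)) read_mask(config$io$mask)
        else if (!is.null(state$still))
          threshold_green_mask(state$still, qc$threshold_quantile %||% 0.08)
        else stop("quantify: no mask (run predict, set io$mask, or run preprocess)")
      }
      tab <- label_regions(mask, qc$connectivity %||% 8, qc$min_region_px %||% 0)
      vars <- capillary_variables(tab, um_per_px = config$io$um_per_px %||% NULL)
      out <- unclass(vars)
      if (isTRUE(qc$calibrate)) {
        cal <- default_calibration()
        out$number_calibrated <- apply_calibration(vars$number, cal$number)
        out$total_area_calibrated <- apply_calibration(vars$total_area_px, cal$total_area)
        if (!is.na(vars$average_area_px))
          out$average_area_calibrated <-
            apply_calibration(vars$average_area_px, cal$average_area)
      }
      state$region_table <- tab
      state$variables <- vars
      write_region_table_csv(tab, file.path(sdir, "regions.csv"))
      jsonlite::write_json(out, file.path(sdir, "variables.json"),
                           auto_unbox = TRUE, digits = NA)
      write_provenance(file.path(sdir, "variables.json"), stage, config, seed)

    } else if (stage == "evaluate") {
      pred <- state$pred_mask %||% {
        if (is.null(config$io$mask)) stop("evaluate: no predicted mask")
        read_mask(config$io$mask)
      }
      gt <- state$gt_still_mask %||% {
        if (is.null(config$io$gt_mask)) stop("evaluate: no ground-truth mask")
        read_mask(config$io$gt_mask)
      }
      ev <- evaluate_masks(list(pred), list(gt),
                           connectivity = config$evaluate$connectivity %||% 8)
      state$evaluation <- ev
      write.csv(ev$per_image, file.path(sdir, "per_image.csv"), row.names = FALSE)
      jsonlite::write_json(as.list(ev$mean), file.path(sdir, "report.json"),
                           auto_unbox = TRUE, digits = NA)
      write_provenance(file.path(sdir, "report.json"), stage, config, seed)
    }

    message(sprintf("[capiwide] %-10s %6.1f s", stage,
                    proc.time()[["elapsed"]] - t0))
  }
  invisible(state)
}
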