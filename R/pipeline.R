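#' Simulate a paired LDCT/NDCT dataset
#'
#' Runs the full physics chain for a set of random phantoms: draw a phantom
#' from `spec`, Siddon-project it, reconstruct the noiseless sinogram (the
#' normal-dose image), corrupt the counts at a blank-scan level drawn from
#' `b0` (one level per image, so mixed-noise training sets are a vector),
#' and reconstruct the low-dose image. Train / validation / test roles are
#' assigned at image level with disjoint phantom seeds, so no test slice
#' shares a source with training.
#'
#' Images are finally rescaled to `[0, 1]` by one affine map per dataset
#' (the min/max of the normal-dose set), the convention all training and
#' metrics code assumes.
#'
#' @param spec a [phantom_spec()], typically [random_phantom_spec()].
#' @param geom a [fan_geometry()].
#' @param n_train,n_val,n_test images per role.
#' @param b0 blank-scan photon level(s); a vector is sampled per image.
#' @param r_mean electronic noise mean (counts).
#' @param filter FBP apodization for both members of each pair; the default
#'   keeps the classic unapodized ramp so the pairs retain the full streak
#'   and noise texture the denoiser must learn.
#' @param seed master seed; phantoms, noise draws and noise-level
#'   assignment all derive from it.
#' @return an `ldct_dataset`: list of records (id, role, b0, nd, ld
#'   matrices in unit range) plus the normalization map (`lo`, `hi`).
#' @export
simulate_dataset <- function(spec, geom, n_train = 12L, n_val = 2L,
                             n_test = 3L, b0 = 1e5, r_mean = 0,
                             filter = "ram-lak", seed = 1L) {
  n <- n_train + n_val + n_test
  roles <- rep(c("train", "val", "test"), c(n_train, n_val, n_test))
  seeds <- derive_seeds(seed, 2L * n + 1L)
  levels <- with_seed(seeds[2L * n + 1L],
                      b0[sample.int(length(b0), n, replace = TRUE)])
  grid_n <- spec$grid_n
  recs <- lapply(seq_len(n), function(i) {
    ph <- generate_phantom(spec, seed = seeds[i])
    sino <- siddon_project(ph, geom)
    nd <- fbp_reconstruct(sino, grid_n, spec$fov_mm, filter = filter)
    meas <- simulate_counts(sino, b0 = levels[i], r_mean = r_mean,
                            seed = seeds[n + i])
    ld <- fbp_reconstruct(counts_to_sinogram(meas), grid_n, spec$fov_mm,
                          filter = filter)
    list(id = sprintf("%s%03d", roles[i], i), role = roles[i],
         b0 = levels[i], phantom_seed = seeds[i],
         nd = nd$values, ld = ld$values)
  })
  lo <- min(vapply(recs, function(r) min(r$nd), numeric(1)))
  hi <- max(vapply(recs, function(r) max(r$nd), numeric(1)))
  if (hi <= lo) stopf("degenerate dataset: constant normal-dose images")
  for (i in seq_len(n)) {
    recs[[i]]$nd <- (recs[[i]]$nd - lo) / (hi - lo)
    recs[[i]]$ld <- (recs[[i]]$ld - lo) / (hi - lo)
  }
  structure(list(records = recs, norm = c(lo = lo, hi = hi),
                 geometry = geom, spec = spec, seed = seed),
            class = "ldct_dataset")
}

#' @export
print.ldct_dataset <- function(x, ...) {
  r <- x$records
  cat(sprintf("ldct_dataset: %d images (%d train / %d val / %d test), b0 in {%s}\n",
              length(r), sum(vapply(r, function(z) z$role == "train", logical(1))),
              sum(vapply(r, function(z) z$role == "val", logical(1))),
              sum(vapply(r, function(z) z$role == "test", logical(1))),
              paste(format(unique(vapply(r, `[[`, numeric(1), "b0")),
                           scientific = TRUE), collapse = ", ")))
  invisible(x)
}

dataset_role <- function(ds, role) {
  Filter(function(r) r$role == role, ds$records)
}

#' Experiment configuration
#'
#' Bundles everything one end-to-end run needs: the phantom family, the
#' acquisition geometry, the noise levels, the architecture variant and the
#' training configuration. Variant tags fix the kernel scale set
#' (see [variant_scales()]); `"custom"` takes `scales` as given.
#'
#' @param variant architecture tag: `"cnn3"`, `"cnn5"`, `"scn2"`,
#'   `"scn3"`, `"scn4"` or `"custom"`.
#' @param scales kernel sizes, used only when `variant = "custom"`.
#' @param depth competitive blocks in the stack.
#' @param filters filters per hidden block.
#' @param spec phantom family, a [phantom_spec()].
#' @param geom a [fan_geometry()].
#' @param b0 blank-scan level(s) for the dataset.
#' @param n_train,n_val,n_test dataset sizes (images).
#' @param train a [train_config()].
#' @param seed master seed for the run.
#' @return a list of class `experiment_config`.
#' @export
experiment_config <- function(variant = "scn3", scales = NULL, depth = 3L,
                              filters = 16L,
                              spec = random_phantom_spec(grid_n = 64L),
                              geom = toy_geometry(), b0 = 1e5,
                              n_train = 12L, n_val = 2L, n_test = 3L,
                              train = toy_train_config(), seed = 1L) {
  sc <- if (identical(variant, "custom")) {
    if (is.null(scales)) stopf("'scales' required for variant = \"custom\"")
    as.integer(scales)
  } else variant_scales(variant)
  structure(list(variant = variant, scales = sc, depth = as.integer(depth),
                 filters = as.integer(filters), spec = spec, geom = geom,
                 b0 = b0, n_train = as.integer(n_train),
                 n_val = as.integer(n_val), n_test = as.integer(n_test),
                 train = train, seed = as.integer(seed)),
            class = "experiment_config")
}

#' Scaled-down geometry for 64-pixel slices
#'
#' Same source/detector distances and detector length as the default
#' [fan_geometry()], with the bin and view counts reduced in proportion to
#' the coarser grid.
#'
#' @param n_bins,n_views sampling of the scaled acquisition.
#' @export
toy_geometry <- function(n_bins = 128L, n_views = 256L) {
  fan_geometry(n_bins = n_bins, n_views = n_views)
}

#' Run one end-to-end denoising experiment
#'
#' simulate -> reconstruct -> split -> patch -> (pretrain) -> fine-tune ->
#' evaluate. Returns the held-out evaluation of both the low-dose input and
#' the network output against the normal-dose reference, the trained model
#' and the training log. When `out_dir` is given, every stage's artifacts
#' (resolved config echo, dataset previews, checkpoint, training log CSV,
#' report CSV) are persisted there.
#'
#' @param cfg an [experiment_config()].
#' @param dataset optionally a pre-simulated [simulate_dataset()] result to
#'   reuse across variants (the ablation harness does this so every variant
#'   sees identical data).
#' @param out_dir optional output directory.
#' @return list with `report` (network), `report_ldct` (input baseline),
#'   `model`, `log`, `dataset`, and `psnr_gain_db` (mean held-out PSNR
#'   improvement of the network over the low-dose input).
#' @export
run_experiment <- function(cfg, dataset = NULL, out_dir = NULL) {
  if (!inherits(cfg, "experiment_config"))
    stopf("'cfg' must be an experiment_config")
  if (is.null(dataset))
    dataset <- simulate_dataset(cfg$spec, cfg$geom, cfg$n_train, cfg$n_val,
                                cfg$n_test, b0 = cfg$b0, seed = cfg$seed)
  tr <- dataset_role(dataset, "train")
  va <- dataset_role(dataset, "val")
  te <- dataset_role(dataset, "test")
  stopifnot(length(intersect(vapply(tr, `[[`, character(1), "id"),
                             vapply(te, `[[`, character(1), "id"))) == 0L)

  patches <- combine_patch_sets(lapply(tr, function(r)
    extract_patches(r$ld, r$nd, cfg$train, source_id = r$id)))

  desc <- scn_descriptor(depth = cfg$depth, scales = cfg$scales,
                         filters = cfg$filters)
  model <- init_scn(desc, init_std = cfg$train$init_std,
                    seed = cfg$train$seed + 31L)
  if (cfg$train$pretrain == "greedy")
    model <- pretrain_blocks(patches, model, cfg$train)
  ft <- fine_tune(patches, model, cfg$train,
                  val_pairs = lapply(va, function(r)
                    list(ld = r$ld, nd = r$nd)))

  ids <- vapply(te, `[[`, character(1), "id")
  refs <- lapply(te, `[[`, "nd")
  lds <- lapply(te, `[[`, "ld")
  outs <- lapply(lds, scn_forward, model = ft$model)
  rep_net <- eval_report(outs, refs, ids = ids)
  rep_ld <- eval_report(lds, refs, ids = ids)
  gain <- mean(rep_net$per_image$psnr_db - rep_ld$per_image$psnr_db)

  res <- list(report = rep_net, report_ldct = rep_ld, model = ft$model,
              log = ft$log, best_epoch = ft$best_epoch, dataset = dataset,
              psnr_gain_db = gain, config = cfg)
  if (!is.null(out_dir)) persist_experiment(res, out_dir)
  res
}

persist_experiment <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- res$config
  echo <- list(variant = cfg$variant, scales = cfg$scales,
               depth = cfg$depth, filters = cfg$filters, b0 = cfg$b0,
               n_train = cfg$n_train, n_val = cfg$n_val,
               n_test = cfg$n_test, seed = cfg$seed,
               train = unclass(cfg$train),
               geometry = unclass(cfg$geom),
               phantom_spec = unclass(cfg$spec),
               dataset_norm = as.list(res$dataset$norm),
               best_epoch = res$best_epoch)
  writeLines(jsonlite::toJSON(echo, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, null = "null"),
             file.path(out_dir, "config_echo.json"))
  write.csv(res$log, file.path(out_dir, "training_log.csv"),
            row.names = FALSE)
  save_scn(res$model, file.path(out_dir, "model.ckpt"))
  write_eval_report(res$report, file.path(out_dir, "report_scn.csv"))
  write_eval_report(res$report_ldct, file.path(out_dir, "report_ldct.csv"))
  te <- dataset_role(res$dataset, "test")
  if (length(te)) {
    w <- c(0, 1)
    write_png_preview(te[[1]]$nd, file.path(out_dir, "test1_ndct.png"), w)
    write_png_preview(te[[1]]$ld, file.path(out_dir, "test1_ldct.png"), w)
    write_png_preview(scn_forward(te[[1]]$ld, res$model),
                      file.path(out_dir, "test1_scn.png"), w)
  }
  invisible(out_dir)
}

#' Ablation sweep over architecture variants
#'
#' Runs [run_experiment()] for each variant on the identical dataset (one
#' simulation, shared), so any score difference is attributable to the
#' architecture.
#'
#' @param cfg base [experiment_config()]; its `variant` field is replaced.
#' @param variants character vector of variant tags.
#' @param out_dir optional root directory (one subdirectory per variant).
#' @return named list of [run_experiment()] results.
#' @export
run_ablation <- function(cfg, variants = c("cnn3", "scn3"),
                         out_dir = NULL) {
  dataset <- simulate_dataset(cfg$spec, cfg$geom, cfg$n_train, cfg$n_val,
                              cfg$n_test, b0 = cfg$b0, seed = cfg$seed)
  res <- lapply(variants, function(v) {
    cv <- cfg
    cv$variant <- v
    cv$scales <- variant_scales(v)
    run_experiment(cv, dataset = dataset,
                   out_dir = if (is.null(out_dir)) NULL
                             else file.path(out_dir, v))
  })
  names(res) <- variants
  res
}
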