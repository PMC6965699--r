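#' Pipeline configuration
#'
#' End-to-end study configuration: simulate phantoms, pseudo-label them
#' with the HMRF stage, train a network on a seeded train split, predict
#' the held-out split, and score predictions against ground truth by
#' three-axis MIP comparison.
#'
#' @param workdir working directory for artifacts (created if missing).
#' @param n_cases number of phantom cases to simulate.
#' @param n_train training cases; the remaining cases form the test split
#'   (seeded random disjoint selection).
#' @param phantom a [phantom_spec()].
#' @param hmrf an [hmrf_config()].
#' @param train a [train_config()].
#' @param arch `"segnet2d"` (three-axis ensemble) or `"unet3d"`.
#' @param net_size network input side (slices are resized to
#'   `net_size` x `net_size`; U-Net patches are `net_size`^3).
#' @param filters convolution channels (SegNet) / base channels (U-Net).
#' @param patch_stride U-Net patch stride at training and inference.
#' @param postprocess optional minimum component size for
#'   [largest_components()] applied to predicted vessel masks.
#' @param p_stroke fraction of stroke-like phantoms.
#' @param seed global seed; per-stage seeds are derived from it.
#' @param save_nifti write volumes/labels/predictions under `workdir`.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(workdir = tempfile("vesselseg"), n_cases = 10L,
                            n_train = 7L, phantom = phantom_spec(),
                            hmrf = hmrf_config(), train = train_config(),
                            arch = c("segnet2d", "unet3d"), net_size = 64L,
                            filters = 16L, patch_stride = NULL,
                            postprocess = NULL, p_stroke = 0,
                            seed = 1L, save_nifti = FALSE) {
  arch <- match.arg(arch)
  stopifnot(n_cases >= 2L, n_train >= 1L, n_train < n_cases)
  structure(list(workdir = workdir, n_cases = as.integer(n_cases),
                 n_train = as.integer(n_train), phantom = phantom,
                 hmrf = hmrf, train = train, arch = arch,
                 net_size = as.integer(net_size),
                 filters = as.integer(filters),
                 patch_stride = patch_stride, postprocess = postprocess,
                 p_stroke = p_stroke, seed = as.integer(seed),
                 save_nifti = save_nifti),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipeline_config()] arguments; `phantom`,
#' `hmrf` and `train` are nested maps passed to their constructors.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sub <- function(name, ctor) {
    if (is.null(y[[name]])) ctor() else do.call(ctor, y[[name]])
  }
  args <- y[setdiff(names(y), c("phantom", "hmrf", "train"))]
  args$phantom <- sub("phantom", phantom_spec)
  args$hmrf <- sub("hmrf", hmrf_config)
  args$train <- sub("train", train_config)
  do.call(pipeline_config, args)
}

pipeline_log <- function(stage, msg, t0 = NULL) {
  el <- if (is.null(t0)) "" else
    sprintf(" [%.1fs]", as.numeric(Sys.time()) - t0)
  message(sprintf("[%s] %s%s", stage, msg, el))
}

#' Run the full unsupervised segmentation study
#'
#' Stages: simulate phantoms -> HMRF pseudo-labels per case -> train the
#' chosen architecture on the training split's pseudo-labels -> predict
#' the held-out split -> evaluate vessel masks against ground truth by
#' three-axis MIP metrics. The train/test split is seeded and disjoint.
#' Every stage logs its parameters; intermediates are written under
#' `config$workdir` when `save_nifti` is set, and a JSON manifest
#' recording the seed, split, and summary metrics is always written.
#'
#' @param config a [pipeline_config()].
#' @param cases optional pre-generated list of `phantom_case` objects
#'   (skips simulation).
#' @return list with `report` (from [evaluate_dataset()], the network),
#'   `report_hmrf` (same, for the raw HMRF pseudo-labels on the test
#'   split), `split`, `models`, `loss`, `cases`, `pseudo`, `manifest`.
#' @export
run_pipeline <- function(config, cases = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$workdir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(config$seed, 4L)
  t0 <- as.numeric(Sys.time())

  # -- simulate ---------------------------------------------------------
  if (is.null(cases)) {
    pipeline_log("simulate", sprintf("%d cases, seed %d", config$n_cases,
                                     seeds[1]))
    cases <- generate_dataset(config$phantom, config$n_cases,
                              seed = seeds[1], p_stroke = config$p_stroke)
  }
  n <- length(cases)
  if (config$n_train >= n) stop("run_pipeline: no test cases left")

  # -- HMRF pseudo-labels ----------------------------------------------
  pipeline_log("label", sprintf("HMRF pseudo-labels (beta=%.2g, %d-neighborhood)",
                                config$hmrf$beta, config$hmrf$neighborhood))
  pseudo <- lapply(cases, function(cs)
    make_pseudo_labels(cs$intensity, config$hmrf))

  # -- split ------------------------------------------------------------
  split_train <- sort(with_seed(seeds[2], sample(n, config$n_train)))
  split_test <- setdiff(seq_len(n), split_train)
  pipeline_log("split", sprintf("train {%s} / test {%s}",
                                paste(split_train, collapse = ","),
                                paste(split_test, collapse = ",")))

  train_pairs <- lapply(split_train, function(i)
    list(volume = cases[[i]]$intensity, labels = pseudo[[i]]))

  # -- train ------------------------------------------------------------
  tc <- config$train
  tc$seed <- seeds[3]
  if (config$arch == "segnet2d") {
    models <- list()
    loss <- list()
    for (a in mip_axes) {
      pipeline_log("train", sprintf("SegNet2D %s axis: %d filters, %d epochs",
                                    a, config$filters, tc$epochs))
      dat <- slice_dataset(train_pairs, a, out_size = config$net_size)
      mdl <- build_segnet2d(in_size = config$net_size, n_classes = 3L,
                            filters = config$filters, seed = seeds[4])
      tr <- train_model(mdl, dat, tc)
      attr(tr$model, "axis") <- a
      models[[a]] <- tr$model
      loss[[a]] <- tr$loss
    }
  } else {
    stride <- if (is.null(config$patch_stride)) config$net_size
              else config$patch_stride
    pipeline_log("train", sprintf("U-Net3D: %d base filters, %d epochs",
                                  config$filters, tc$epochs))
    dat <- patch_dataset(train_pairs, patch = config$net_size,
                         stride = stride)
    mdl <- build_unet3d(in_size = config$net_size, n_classes = 3L,
                        filters = config$filters, seed = seeds[4])
    tr <- train_model(mdl, dat, tc)
    models <- list(unet3d = tr$model)
    loss <- list(unet3d = tr$loss)
  }

  # -- predict + evaluate ----------------------------------------------
  reports <- list()
  reports_hmrf <- list()
  for (i in split_test) {
    pipeline_log("predict", sprintf("case %d", i))
    pm <- if (config$arch == "segnet2d") {
      predict_segnet_ensemble(models, cases[[i]]$intensity)
    } else {
      stride <- if (is.null(config$patch_stride)) config$net_size %/% 2L
                else config$patch_stride
      predict_unet3d(models$unet3d, cases[[i]]$intensity, stride = stride)
    }
    pred <- probs_to_labels(pm)
    reports[[length(reports) + 1L]] <-
      evaluate_case(pred, cases[[i]]$truth, postprocess = config$postprocess)
    reports_hmrf[[length(reports_hmrf) + 1L]] <-
      evaluate_case(pseudo[[i]], cases[[i]]$truth,
                    postprocess = config$postprocess)
    if (config$save_nifti) {
      write_volume(pred, file.path(config$workdir,
                                   sprintf("case_%04d_pred.nii.gz", i)))
    }
  }
  report <- evaluate_dataset(reports)
  report_hmrf <- evaluate_dataset(reports_hmrf)

  if (config$save_nifti) {
    for (i in seq_len(n)) {
      write_volume(cases[[i]]$intensity,
                   file.path(config$workdir,
                             sprintf("case_%04d_img.nii.gz", i)))
      write_volume(cases[[i]]$truth,
                   file.path(config$workdir,
                             sprintf("case_%04d_truth.nii.gz", i)))
      write_volume(pseudo[[i]],
                   file.path(config$workdir,
                             sprintf("case_%04d_pseudo.nii.gz", i)))
    }
  }

  manifest <- list(seed = config$seed, arch = config$arch,
                   n_cases = n, split_train = split_train,
                   split_test = split_test,
                   net = list(size = config$net_size,
                              filters = config$filters,
                              epochs = config$train$epochs),
                   dnn_mean = as.list(report$per_case),
                   hmrf_mean = as.list(report_hmrf$per_case),
                   wall_seconds = as.numeric(Sys.time()) - t0)
  jsonlite::write_json(manifest,
                       file.path(config$workdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  pipeline_log("done", sprintf("DNN mean DSC %.3f vs HMRF %.3f",
                               report$per_case[["dsc"]],
                               report_hmrf$per_case[["dsc"]]), t0)

  list(report = report, report_hmrf = report_hmrf,
       split = list(train = split_train, test = split_test),
       models = models, loss = loss, cases = cases, pseudo = pseudo,
       manifest = manifest)
}
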