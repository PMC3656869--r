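#' Configuration for the marker-guided training pipeline
#'
#' One nested list drives every stage; a single global `seed` fans out to
#' stage-specific seeds through a fixed derivation so stages stay
#' independent but the whole run is reproducible.
#'
#' @param stain_matrix a `stain_matrix`.
#' @param segmentation list from [segmentation_params()].
#' @param catalog a [feature_catalog()].
#' @param masking list with `min_cluster_area`, `grow_radius`.
#' @param min_overlap marker-overlap fraction for [assign_labels()].
#' @param train_fraction balanced-set split fraction (default 0.665).
#' @param standardize_method `"minmax"` or `"zscore"`.
#' @param select `NULL` to skip feature selection, or a list with
#'   `subsample_fraction` and `step` for ranked backward elimination with a
#'   cubic-fit optimum.
#' @param algorithm classifier trained at the end.
#' @param holdout integer indices of input images held out as the external
#'   (ground-truth evaluated) set; `NULL` keeps everything for training.
#' @param background_intensity,eps see [rgb_to_od()].
#' @param seed global integer seed.
#' @return a named list.
#' @export
pipeline_config <- function(stain_matrix = default_stain_matrix(),
                            segmentation = segmentation_params(),
                            catalog = feature_catalog(),
                            masking = list(min_cluster_area = 400,
                                           grow_radius = 4),
                            min_overlap = 0.5,
                            train_fraction = 0.665,
                            standardize_method = "minmax",
                            select = NULL,
                            algorithm = "svm",
                            holdout = NULL,
                            background_intensity = 255, eps = 1,
                            seed = 1) {
  as.list(environment())
}

# Deconvolve one image, segment it, auto-label from the marker mask, and
# extract features. `image` may be an RGB array or a synthetic_scene (whose
# truth labels, when present, ride along for evaluation only).
process_core_image <- function(image, config, image_id = "image") {
  truth <- NULL
  if (inherits(image, "synthetic_scene")) {
    truth <- image$nuclei
    image <- image$image
  }
  od <- rgb_to_od(image, config$background_intensity, config$eps)
  dens <- deconvolve(od, config$stain_matrix)
  marker <- segment_marker_mask(dens$dab,
                                min_cluster_area = config$masking$min_cluster_area,
                                grow_radius = config$masking$grow_radius)
  tissue <- segment_tissue_mask(dens$hematoxylin)
  labels <- segment_nuclei(dens$hematoxylin, config$segmentation)
  auto <- assign_labels(labels, marker, config$min_overlap)
  ft <- extract_features(labels, dens$hematoxylin, config$catalog,
                         classes = auto, image_id = image_id)
  # attach ground-truth class by nearest truth nucleus (evaluation only)
  if (!is.null(truth) && nrow(ft) > 0 && nrow(truth) > 0) {
    nt <- nuclei_table(labels)
    truth_class <- vapply(seq_len(nrow(nt)), function(i) {
      d <- sqrt((truth$x - nt$x[i])^2 + (truth$y - nt$y[i])^2)
      j <- which.min(d)
      if (d[j] <= 5) as.character(truth$class[j]) else NA_character_
    }, character(1))
    ft$truth_class <- truth_class
  }
  list(features = ft, labels = labels, marker_mask = marker,
       tissue_mask = tissue, densities = dens,
       qc = list(clip_fraction = dens$clip_fraction,
                 n_objects = max(labels),
                 marker_area = sum(marker), tissue_area = sum(tissue)))
}

#' Run the full marker-guided training pipeline
#'
#' Executes, per image: deconvolution, marker/tissue masking, nucleus
#' segmentation, marker-overlap auto-labelling and feature extraction;
#' then pools the training images, balances classes, splits into training
#' and internal validation, standardizes (fit on train only), optionally
#' runs ranked backward feature elimination with a cubic-fit optimum, and
#' trains the classifier. Held-out images form the external set. Class
#' labels used for training always come from the marker mask, never from
#' synthetic ground truth; when scenes carry truth, an additional
#' truth-label evaluation of the held-out set is reported.
#'
#' @param images list of RGB arrays or `synthetic_scene`s.
#' @param config list from [pipeline_config()].
#' @return list with `model`, `reports` (internal / external /
#'   external_truth eval reports), `selection` (ranking, trace, optimum, or
#'   NULL), `datasets`, `per_image` QC, `manifest`.
#' @export
run_training_pipeline <- function(images, config = pipeline_config()) {
  if (length(images) == 0) stop("no input images")
  ids <- sprintf("img%02d", seq_along(images))
  per <- lapply(seq_along(images), function(i) {
    process_core_image(images[[i]], config, ids[i])
  })
  names(per) <- ids
  holdout <- config$holdout %||% integer(0)
  train_imgs <- setdiff(seq_along(images), holdout)
  ft_train <- do.call(rbind, lapply(per[train_imgs],
                                    function(p) p$features))
  ds_full <- dataset_from_features(ft_train)
  ds_bal <- balance_classes(ds_full, derive_seed(config$seed, "balance"))
  sp <- split_dataset(ds_bal, config$train_fraction,
                      derive_seed(config$seed, "split"))
  ds_ext <- ds_ext_truth <- NULL
  if (length(holdout) > 0) {
    ft_ext <- do.call(rbind, lapply(per[holdout], function(p) p$features))
    ds_ext <- dataset_from_features(ft_ext)
    if (!is.null(ft_ext$truth_class)) {
      keep <- !is.na(ft_ext$truth_class)
      fx <- ft_ext[keep, , drop = FALSE]
      fx$class <- factor(fx$truth_class, levels = c("melanoma", "other"))
      ds_ext_truth <- dataset_from_features(fx)
    }
  }
  std <- standardize(sp$train, test = sp$test,
                     method = config$standardize_method)
  tr <- std$train; te <- std$test
  ext <- if (!is.null(ds_ext)) apply_standardization(std$transform, ds_ext)
  ext_truth <- if (!is.null(ds_ext_truth)) {
    apply_standardization(std$transform, ds_ext_truth)
  }
  selection <- NULL
  if (!is.null(config$select)) {
    ranking <- rank_features(ds_bal,
                             config$select$subsample_fraction %||% 0.05,
                             derive_seed(config$seed, "rank"))
    ext_for_trace <- ext %||% te
    trace <- backward_elimination(tr, te, ext_for_trace, ranking,
                                  step = config$select$step %||% 1L)
    opt <- fit_optimum(trace)
    keep_feats <- ranking$feature[seq_len(opt$n_features)]
    tr <- ds_subset(tr, features = keep_feats)
    te <- ds_subset(te, features = keep_feats)
    if (!is.null(ext)) ext <- ds_subset(ext, features = keep_feats)
    if (!is.null(ext_truth)) {
      ext_truth <- ds_subset(ext_truth, features = keep_feats)
    }
    selection <- list(ranking = ranking, trace = trace, optimum = opt,
                      features = keep_feats)
  }
  subset_transform <- std$transform
  if (!is.null(selection)) {
    keep <- match(colnames(tr$x), names(subset_transform$center))
    subset_transform$center <- subset_transform$center[keep]
    subset_transform$scale <- subset_transform$scale[keep]
    subset_transform$constant <- subset_transform$constant[keep]
  }
  model <- train_classifier(tr, config$algorithm,
                            seed = derive_seed(config$seed, "train"),
                            transform = subset_transform)
  reports <- list(internal = evaluate_classifier(model, te))
  if (!is.null(ext)) reports$external <- evaluate_classifier(model, ext)
  if (!is.null(ext_truth)) {
    reports$external_truth <- evaluate_classifier(model, ext_truth)
  }
  manifest <- list(
    n_images = length(images), holdout = holdout, seed = config$seed,
    algorithm = config$algorithm,
    counts = list(full = as.list(table(ds_full$y)),
                  balanced = as.list(table(ds_bal$y)),
                  train = nrow(tr$x), internal_test = nrow(te$x),
                  external = if (!is.null(ext)) nrow(ext$x) else 0L),
    features = colnames(tr$x),
    package_version = as.character(utils::packageVersion("melmark"))
  )
  list(model = model, reports = reports, selection = selection,
       datasets = list(train = tr, internal_test = te, external = ext,
                       external_truth = ext_truth),
       per_image = lapply(per, function(p) p$qc),
       manifest = manifest)
}

#' Run the biomarker quantification pipeline over a batch of images
#'
#' Applies [quantify_image()] to each image; per-image failures are
#' recorded and the run continues unless `fail_fast`.
#'
#' @param images list of RGB arrays or `synthetic_scene`s.
#' @param model a `cell_classifier`.
#' @param config list from [quantification_config()].
#' @param fail_fast abort on the first per-image error.
#' @return list with `scores` (per successful image), `failures` (named
#'   error messages), and `summary` data frame (one row per image).
#' @export
run_quantification_pipeline <- function(images, model,
                                        config = quantification_config(),
                                        fail_fast = FALSE) {
  ids <- sprintf("img%02d", seq_along(images))
  scores <- list()
  failures <- list()
  for (i in seq_along(images)) {
    cfg <- config
    cfg$image_id <- ids[i]
    res <- tryCatch(quantify_image(images[[i]], model, cfg),
                    error = function(e) e)
    if (inherits(res, "error")) {
      if (fail_fast) stop(res)
      failures[[ids[i]]] <- conditionMessage(res)
    } else {
      scores[[ids[i]]] <- res
    }
  }
  summary <- do.call(rbind, lapply(names(scores), function(id) {
    s <- scores[[id]]
    data.frame(image_id = id, melanoma_count = s$melanoma_count,
               positive_count = s$positive_count, ratio = s$ratio)
  }))
  list(scores = scores, failures = failures,
       summary = summary %||% data.frame())
}
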