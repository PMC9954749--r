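# Pipeline driver: chains synth -> normalize -> patch -> split -> train ->
# evaluate with a single config and seed, writing every artifact plus a run
# record that lists them.

#' Run the patch-classification pipeline
#'
#' Executes the enabled stages in order on a shared output directory.
#' Stages:
#' \describe{
#'   \item{synth}{generate a synthetic cohort tree (\code{\link{generate_cohort}})}
#'   \item{normalize}{Macenko-normalize every manifest image
#'     (\code{\link{normalize_image}})}
#'   \item{patch}{budgeted patch extraction
#'     (\code{\link{extract_cohort_patches}})}
#'   \item{split}{patient-level train/test split
#'     (\code{\link{make_patient_split}})}
#'   \item{train}{fit the network on training-side patches
#'     (\code{\link{fabnet}})}
#'   \item{evaluate}{predict test-side patches and write the metrics report
#'     (\code{\link{evaluate_predictions}})}
#' }
#' A failure in any stage halts the run with an error naming the stage; a
#' stage whose upstream artifact is missing raises a dependency error. All
#' stochastic stages derive their seeds from \code{config$seed}, so two
#' identical runs produce identical artifacts.
#'
#' @param config named list (or path to a YAML file) with elements
#'   \code{out} (output directory), \code{seed}, \code{stages} (character
#'   vector), and per-stage option lists \code{synth} (classes,
#'   patients_per_class, images_per_patient, image_size, style),
#'   \code{patch} (beta, size), \code{split} (ratio), \code{arch} (n_pairs,
#'   base_filters, reduce_cap) and \code{train} (epochs, learning_rate,
#'   batch_size, optimizer).
#' @param manifest optional pre-existing sample manifest (data frame) used
#'   when the synth stage is disabled.
#' @return List with the artifacts produced (manifests, split, fit,
#'   metrics), invisibly; a \code{run_record.json} in \code{config$out}
#'   lists every file written.
#' @export
run_pipeline <- function(config, manifest = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$out)) stop("config error: 'out' directory is required")
  if (is.null(config$seed)) stop("config error: 'seed' is required")
  seed <- as.integer(config$seed)
  out <- config$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages %||% c("synth", "patch", "split", "train",
                                 "evaluate")
  artifacts <- character()
  note <- function(path) artifacts <<- c(artifacts, path)
  result <- list()

  if ("synth" %in% stages) {
    sy <- config$synth %||% list()
    classes <- sy$classes %||% list(
      list(name = "benign_like", nucleus_density = 6, category = "benign"),
      list(name = "malignant_like", nucleus_density = 50,
           category = "malignant"))
    class_specs <- lapply(classes, function(cl)
      synthetic_class_spec(cl$name, cl$nucleus_density,
                           radius_range = cl$radius_range %||% c(3, 6),
                           eosin_level = cl$eosin_level %||% 0.4,
                           category = cl$category %||% "benign"))
    cohort_cfg <- synthetic_cohort_config(
      class_specs,
      patients_per_class = sy$patients_per_class %||% 6L,
      images_per_patient = sy$images_per_patient %||% 3L,
      magnifications = sy$magnifications %||% "none",
      image_size = sy$image_size %||% 64L,
      seed = seed)
    manifest <- generate_cohort(cohort_cfg, file.path(out, "cohort"),
                                style = sy$style %||% "breakhis")
    note(file.path(out, "cohort", "manifest.csv"))
  }
  if (is.null(manifest))
    stop("dependency error in stage '", setdiff(stages, "synth")[1],
         "': no sample manifest (enable the synth stage or pass one)")
  result$manifest <- manifest

  if ("normalize" %in% stages) {
    ndir <- file.path(out, "normalized")
    dir.create(ndir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(nrow(manifest))) {
      img <- read_image(manifest$path[i])
      norm <- normalize_image(img)
      npath <- file.path(ndir, paste0(manifest$image_id[i], ".png"))
      write_image(norm, npath)
      manifest$path[i] <- npath
    }
    write_manifest(manifest, file.path(out, "manifest_normalized.csv"))
    note(file.path(out, "manifest_normalized.csv"))
    result$manifest <- manifest
  }

  patch_manifest <- NULL
  if ("patch" %in% stages) {
    pc <- config$patch %||% list()
    patch_manifest <- extract_cohort_patches(
      manifest, file.path(out, "patches"),
      beta = pc$beta %||% 32L, size = pc$size %||% 32L, seed = seed)
    write_manifest(patch_manifest, file.path(out, "patch_manifest.csv"))
    note(file.path(out, "patch_manifest.csv"))
    result$patch_manifest <- patch_manifest
  }

  plan <- NULL
  if ("split" %in% stages) {
    sp <- config$split %||% list()
    plan <- make_patient_split(manifest, ratio = sp$ratio %||% 0.7,
                               seed = seed)
    write_split(plan, file.path(out, "split.json"))
    note(file.path(out, "split.json"))
    result$split <- plan
  }

  fit <- NULL
  if ("train" %in% stages) {
    if (is.null(patch_manifest))
      stop("dependency error in stage 'train': no patch manifest ",
           "(enable the patch stage)")
    ar <- config$arch %||% list()
    tr <- config$train %||% list()
    pc <- config$patch %||% list()
    spec <- tiny_fabnet_spec(
      head_classes = length(unique(patch_manifest$class_label)),
      n_pairs = ar$n_pairs %||% 1L,
      base_filters = ar$base_filters %||% 8L,
      reduce_cap = ar$reduce_cap %||% 8L,
      input_size = pc$size %||% 32L)
    cfg <- train_config(epochs = tr$epochs %||% 10L,
                        learning_rate = tr$learning_rate %||% 1e-3,
                        batch_size = tr$batch_size %||% 16L,
                        optimizer = tr$optimizer %||% "adam",
                        seed = seed)
    fit <- fabnet(patch_manifest, spec = spec, config = cfg, split = plan)
    utils::write.csv(fit$history, file.path(out, "history.csv"),
                     row.names = FALSE)
    note(file.path(out, "history.csv"))
    result$fit <- fit
  }

  if ("evaluate" %in% stages) {
    if (is.null(fit))
      stop("dependency error in stage 'evaluate': no trained model ",
           "(enable the train stage)")
    test_manifest <- if (!is.null(plan))
      split_side(patch_manifest, plan, "test") else patch_manifest
    if (!nrow(test_manifest))
      stop("dependency error in stage 'evaluate': empty test side")
    records <- predict_patches(fit, test_manifest)
    utils::write.csv(records, file.path(out, "predictions.csv"),
                     row.names = FALSE)
    note(file.path(out, "predictions.csv"))
    metrics <- evaluate_predictions(records, file.path(out, "metrics"))
    note(file.path(out, "metrics", "metrics.json"))
    result$records <- records
    result$metrics <- metrics
  }

  jsonlite::write_json(list(seed = seed, stages = stages,
                            artifacts = artifacts),
                       file.path(out, "run_record.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
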