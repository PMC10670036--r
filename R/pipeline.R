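#' Run the end-to-end classification pipeline
#'
#' Orchestrates phantom cohort generation (or an existing manifest), the
#' subject-level split, normalization, slice/mean-image generation, model
#' training and evaluation, writing all artefacts (provenance CSVs, history
#' CSV, evaluation report JSON) under `out_dir`.
#'
#' The configuration is a named list (or a YAML file path) with entries:
#' \describe{
#'   \item{modality}{`"fMRI"` (temporal-mean 3D samples + 3D-CNN) or
#'     `"sMRI"` (whole normalized volumes + 3D-CNN).}
#'   \item{phantom}{list(n_asd, n_tc, shape, n_timepoints, ...) passed to
#'     [phantom_params]/[make_cohort]; omit and give `manifest` to use
#'     existing data.}
#'   \item{manifest}{path to a manifest CSV (alternative to `phantom`).}
#'   \item{split}{list(fraction = 0.8, seed = 1).}
#'   \item{window}{list(strategy = "mid_n", n = 50) for fMRI.}
#'   \item{input_shape}{CNN input resolution (default c(32, 32, 32)).}
#'   \item{train}{list(epochs, learning_rate, batch_size, augment, seed)
#'     passed to [train_config].}
#'   \item{seed}{master seed, used where a stage seed is not given.}
#' }
#'
#' @param config Named list or path to a YAML file.
#' @param out_dir Output directory.
#' @return List with `report` (an [eval_report]), `history`, `model`, and
#'   the `split`.
#' @export
run_pipeline <- function(config, out_dir) {
    if (is.character(config) && length(config) == 1L)
        config <- yaml::read_yaml(config)
    stopifnot(is.list(config))
    seed <- config$seed %||% 1L
    modality <- match.arg(config$modality %||% "fMRI", c("fMRI", "sMRI"))
    if (!dir.exists(out_dir))
        dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

    log_stage <- function(fmt, ...)
        message(sprintf(paste0("[neuroslice] ", fmt), ...))

    if (!is.null(config$phantom)) {
        ph <- config$phantom
        pp_args <- ph[setdiff(names(ph), c("n_asd", "n_tc", "compress"))]
        pp_args$seed <- pp_args$seed %||% seed
        params <- do.call(phantom_params, pp_args)
        log_stage("generating %d ASD + %d TC %s phantoms (shape %s)",
                  ph$n_asd, ph$n_tc, modality,
                  paste(params$shape, collapse = "x"))
        cohort <- make_cohort(ph$n_asd, ph$n_tc, params,
                              file.path(out_dir, "cohort"),
                              modality = modality,
                              compress = ph$compress %||% TRUE)
    } else if (!is.null(config$manifest)) {
        cohort <- read_manifest(config$manifest)
    } else {
        stop_ns("config needs either `phantom` or `manifest`",
                "neuroslice_validation_error")
    }

    sp <- config$split %||% list()
    split <- split_subjects(cohort, fraction = sp$fraction %||% 0.8,
                            seed = sp$seed %||% seed)
    if (nrow(split$train) == 0L || nrow(split$test) == 0L)
        stop_ns("degenerate split: train and test must both be nonempty",
                "neuroslice_validation_error")
    log_stage("split: %d train / %d test subjects",
              nrow(split$train), nrow(split$test))

    input_shape <- as.integer(config$input_shape %||% c(32L, 32L, 32L))
    data_dir <- file.path(out_dir, "dataset")
    if (modality == "fMRI") {
        w <- config$window %||% list(strategy = "mid_n", n = 50L)
        log_stage("fMRI temporal strategy %s (n=%s) + normalization",
                  w$strategy, w$n %||% "-")
        ds <- generate_fmri_dataset(split, strategy = w$strategy, n = w$n,
                                    out_dir = data_dir)
    } else {
        log_stage("sMRI normalization of whole volumes")
        norm <- normalize_cohort(cohort, file.path(out_dir, "normalized"))
        split3 <- split
        for (part in c("train", "test")) {
            ids <- split[[part]]$subject_id
            split3[[part]] <- norm[norm$subject_id %in% ids, , drop = FALSE]
        }
        ds <- volume_dataset_from_split(split3, data_dir)
    }

    train_set <- load_volume_samples(ds, "train", shape = input_shape)
    test_set <- load_volume_samples(ds, "test", shape = input_shape)
    leak <- intersect(train_set$subject_id, test_set$subject_id)
    stopifnot(length(leak) == 0L)

    tc_args <- config$train %||% list()
    tc_args$seed <- tc_args$seed %||% seed
    cfg <- do.call(train_config, tc_args)
    log_stage("training 3D-CNN: %d epochs, lr %g, batch %d",
              cfg$epochs, cfg$learning_rate, cfg$batch_size)
    model <- build_cnn3d(input_shape, seed = cfg$seed)
    fit <- train_model(model, train_set$x, train_set$y,
                       test_set$x, test_set$y, cfg)
    write.csv(fit$history, file.path(out_dir, "history.csv"),
              row.names = FALSE)

    probs <- predict(fit$model, test_set$x)
    report <- eval_report(probs, test_set$y)
    jsonlite::write_json(unclass(report),
                         file.path(out_dir, "eval_report.json"),
                         auto_unbox = TRUE, digits = NA)
    log_stage("test accuracy %.4f, F1 %.4f, loss %.4f",
              report$accuracy, report$f1, report$cross_entropy)
    list(report = report, history = fit$history, model = fit$model,
         split = split, dataset = ds)
}

# wrap a pre-normalized 3D cohort split as a slice_dataset (one whole-volume
# sample per subject) with a provenance CSV
volume_dataset_from_split <- function(split, out_dir) {
    rows <- list()
    for (partition in c("train", "test")) {
        m <- split[[partition]]
        for (i in seq_len(nrow(m)))
            rows[[length(rows) + 1L]] <- data.frame(
                subject_id = m$subject_id[i], label = m$label[i],
                partition = partition, plane = "3d",
                slice_index = NA_integer_, path = m$path[i],
                stringsAsFactors = FALSE)
    }
    samples <- do.call(rbind, rows)
    if (!dir.exists(out_dir))
        dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(samples, file.path(out_dir, "provenance.csv"),
              row.names = FALSE)
    structure(list(samples = samples, modality = "sMRI-3D"),
              class = "slice_dataset")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
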