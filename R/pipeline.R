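#' Assemble a full pipeline configuration
#'
#' One object drives the whole pipeline: phantom generation, train/test
#' split, autoencoder training, radiomic extraction, spectral reduction
#' and the classifier grid.  All randomness descends from `seed`.
#'
#' @param phantom a [phantom_config()]; its `image_size` should match the
#'   model preset.
#' @param model a [model_config()].
#' @param train a [train_config()].
#' @param radiomics a [radiomics_config()].
#' @param n_train,n_test split sizes (defaults follow the cohort size).
#' @param masks `"ground_truth"` to extract radiomics on the reference
#'   masks, `"predicted"` to use the autoencoder's segmentations.
#' @param n_components,k_neighbors spectral-reduction settings.
#' @param k_latent deep latent features to keep.
#' @param grid classifier grid (list of [rf_hyperparams()]).
#' @param n_boot bootstrap replicates in the metric panel.
#' @param seed global seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(phantom = phantom_config(image_size = 64L,
                                                     n_benign = 30L,
                                                     n_malignant = 30L,
                                                     n_normal = 10L),
                            model = model_config("desk"),
                            train = train_config(epochs = 20L,
                                                 lr_start = 3e-3,
                                                 lr_end = 1e-4),
                            radiomics = radiomics_config(),
                            n_train = NULL, n_test = NULL,
                            masks = c("ground_truth", "predicted"),
                            n_components = 12L, k_neighbors = 10L,
                            k_latent = 4L,
                            grid = default_rf_grid(),
                            n_boot = 1000L, seed = 1L) {
  masks <- match.arg(masks)
  total <- phantom$n_benign + phantom$n_malignant + phantom$n_normal
  if (is.null(n_test)) n_test <- max(2L, round(total * 145 / 780))
  if (is.null(n_train)) n_train <- total - n_test
  if (phantom$image_size != model$input_size)
    stop("pipeline_config: phantom image_size must equal model input_size")
  structure(list(phantom = phantom, model = model, train = train,
                 radiomics = radiomics, n_train = n_train, n_test = n_test,
                 masks = masks, n_components = as.integer(n_components),
                 k_neighbors = as.integer(k_neighbors),
                 k_latent = as.integer(k_latent), grid = grid,
                 n_boot = as.integer(n_boot), seed = as.integer(seed)),
            class = "pipeline_config")
}

config_hash <- function(cfg) {
  txt <- paste(deparse(unclass(cfg)), collapse = "")
  f <- tempfile()
  writeLines(txt, f)
  on.exit(unlink(f))
  unname(tools::md5sum(f))
}

write_stamped_csv <- function(df, path, stamp) {
  con <- file(path, "w")
  writeLines(paste0("# dualrad ",
                    as.character(utils::packageVersion("dualrad")),
                    " config ", stamp), con)
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
}

#' Save / load a fitted autoencoder checkpoint
#' @param model a fitted `dual_ae`.
#' @param path checkpoint path (RDS).
#' @export
save_dual_ae <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_dual_ae
#' @export
load_dual_ae <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "dual_ae")) stop("load_dual_ae: not a dual_ae checkpoint")
  m
}

#' Run the full phantom-to-diagnosis pipeline
#'
#' Stages: generate the phantom cohort, write it out, split, train the
#' dual-output autoencoder on abnormal training cases, extract deep latent
#' and conventional radiomics for all abnormal cases, reduce the
#' conventional panel by Laplacian eigenmaps, and evaluate the classifier
#' grid with LOOCV.  Every CSV written carries a header comment naming the
#' package version and the configuration hash; rerunning with the same
#' configuration reproduces the CSVs bit-identically.
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir run directory (created).
#' @param verbose log progress to the run log and console.
#' @return list with the results table (`results`), the stage artifact
#'   paths, the fitted model, and the test-set Dice scores.
#' @export
run_pipeline <- function(cfg, out_dir = tempfile("dualrad_run_"),
                         verbose = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "log.txt")
  say <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...))
    cat(msg, "\n", file = logf, append = TRUE)
    if (verbose) message(msg)
  }
  stamp <- config_hash(cfg)
  stage <- "phantom"
  result <- tryCatch({
    say("stage phantom: generating %d samples",
        cfg$phantom$n_benign + cfg$phantom$n_malignant + cfg$phantom$n_normal)
    cohort <- generate_cohort(cfg$phantom)
    write_cohort(cohort, file.path(out_dir, "cohort"))
    write_stamped_csv(cohort$manifest, file.path(out_dir, "manifest.csv"),
                      stamp)

    stage <- "split"
    sp <- split_dataset(cohort$samples, cfg$n_train, cfg$n_test,
                        seed = cfg$seed, stratify = TRUE)
    split_df <- data.frame(
      id = c(vapply(sp$train, `[[`, "", "id"),
             vapply(sp$test, `[[`, "", "id")),
      partition = rep(c("train", "test"),
                      c(length(sp$train), length(sp$test))))
    write_stamped_csv(split_df, file.path(out_dir, "split.csv"), stamp)

    stage <- "train"
    say("stage train: fitting autoencoder (%d epochs)", cfg$train$epochs)
    abn_test <- Filter(function(s) s$label != "normal", sp$test)
    fit <- dual_autoencoder(sp$train, model = cfg$model, train = cfg$train,
                            val = abn_test)
    save_dual_ae(fit, file.path(out_dir, "model.rds"))
    write_stamped_csv(fit$history, file.path(out_dir, "history.csv"), stamp)

    stage <- "segment"
    test_dice <- vapply(abn_test, function(s) {
      dice_coefficient(binarize(predict(fit, s)$prob_map), s$mask)
    }, 0)

    stage <- "radiomics"
    abn <- Filter(function(s) s$label != "normal", cohort$samples)
    say("stage radiomics: %d abnormal cases", length(abn))
    if (cfg$masks == "predicted") {
      abn <- lapply(abn, function(s) {
        s$mask <- binarize(predict(fit, s)$prob_map)
        s
      })
      empty <- vapply(abn, function(s) sum(s$mask) == 0, TRUE)
      if (any(empty))
        say("stage radiomics: %d predicted masks empty; falling back to such cases' reference masks",
            sum(empty))
      for (i in which(empty))
        abn[[i]]$mask <- Filter(function(s) s$id == abn[[i]]$id,
                                cohort$samples)[[1]]$mask
    }
    Xconv <- extract_feature_matrix(abn, cfg$radiomics)
    write_stamped_csv(data.frame(id = rownames(Xconv), Xconv,
                                 check.names = FALSE),
                      file.path(out_dir, "features.csv"), stamp)
    latents <- t(vapply(abn, function(s) predict(fit, s)$latent,
                        numeric(cfg$model$latent_dim)))
    rownames(latents) <- rownames(Xconv)
    write_stamped_csv(data.frame(id = rownames(latents), latents),
                      file.path(out_dir, "latent.csv"), stamp)

    stage <- "reduce"
    emb <- spectral_embed(Xconv, cfg$n_components, cfg$k_neighbors)
    E <- emb$embedding
    rownames(E) <- rownames(Xconv)
    write_stamped_csv(data.frame(id = rownames(E), E),
                      file.path(out_dir, "embedded.csv"), stamp)

    stage <- "classify"
    y <- as.integer(vapply(abn, `[[`, "", "label") == "malignant")
    if (length(unique(y)) < 2L)
      stop("single-class cohort: need both benign and malignant cases")
    fl <- suppressWarnings(filter_latent(latents, cfg$k_latent))
    say("stage classify: grid of %d settings", length(cfg$grid))
    results <- grid_evaluate(E, fl$reduced, y, grid = cfg$grid,
                             n_boot = cfg$n_boot)
    write_stamped_csv(results, file.path(out_dir, "results.csv"), stamp)

    say("pipeline complete")
    list(results = results, out_dir = out_dir, model = fit,
         test_dice = test_dice,
         paths = file.path(out_dir,
                           c("manifest.csv", "split.csv", "history.csv",
                             "features.csv", "latent.csv", "embedded.csv",
                             "results.csv")))
  }, error = function(e) {
    cat(sprintf("FAILED at stage %s: %s\n", stage, conditionMessage(e)),
        file = logf, append = TRUE)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  result
}
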