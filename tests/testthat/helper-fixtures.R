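# Memoised fixtures shared across test files (built once per test run).
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, maker) {
  if (is.null(.fixture_env[[name]])) assign(name, maker(), .fixture_env)
  .fixture_env[[name]]
}

# 75 easy benign phantoms at desk scale: the segmentation benchmark cohort.
easy_cohort <- function() fixture("easy_cohort", function() {
  generate_cohort(phantom_config(image_size = 64L, n_benign = 75L,
                                 n_malignant = 0L, n_normal = 0L,
                                 seed = 11L, preset = "easy"))
})

desk_train_config <- function(seed = 1L) {
  train_config(epochs = 30L, batch_size = 8L, lr_start = 1e-3,
               lr_end = 1e-4, seed = seed)
}

# Autoencoder trained 30 epochs on the first 60 easy phantoms.
easy_ae <- function(seed = 1L) {
  fixture(sprintf("easy_ae_%d", seed), function() {
    dual_autoencoder(easy_cohort()$samples[1:60],
                     model = model_config("desk"),
                     train = desk_train_config(seed))
  })
}

hard_dice <- function(fit, samples) {
  vapply(samples, function(s)
    dice_coefficient(binarize(predict(fit, s)$prob_map), s$mask), 0)
}

# Full pipeline run on a 200-phantom benign/malignant cohort.
accept_run <- function() fixture("accept_run", function() {
  cfg <- pipeline_config(
    phantom = phantom_config(image_size = 64L, n_benign = 100L,
                             n_malignant = 100L, n_normal = 0L, seed = 29L),
    model = model_config("desk"),
    train = train_config(epochs = 20L, batch_size = 8L, lr_start = 1e-3,
                         lr_end = 1e-4, seed = 5L),
    seed = 29L)
  run_pipeline(cfg, out_dir = file.path(tempdir(), "dualrad_accept_run"))
})

read_stamped_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", check.names = FALSE)
}

# Conventional feature matrix and labels from the pipeline run.
accept_features <- function() fixture("accept_features", function() {
  run <- accept_run()
  ft <- read_stamped_csv(file.path(run$out_dir, "features.csv"))
  X <- as.matrix(ft[, -1])
  rownames(X) <- ft$id
  lat <- read_stamped_csv(file.path(run$out_dir, "latent.csv"))
  L <- as.matrix(lat[, -1])
  rownames(L) <- lat$id
  list(X = X, latent = L,
       y = as.integer(grepl("^malignant", ft$id)))
})
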