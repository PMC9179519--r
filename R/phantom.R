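#' Configuration for the synthetic ultrasound phantom generator
#'
#' The phantom generator emulates the statistical structure of a breast
#' ultrasound screening cohort: speckled grayscale images with hypoechoic
#' lesions whose morphology depends on class.  Benign lesions are smooth
#' ellipses; malignant lesions carry a spiculated (radially sinusoidal)
#' boundary and a faint posterior shadow; normal images have no lesion and
#' an all-zero mask.
#'
#' @param image_size pixels per side (square images), at least 32.
#' @param n_benign,n_malignant,n_normal nonnegative class counts.  Defaults
#'   mirror a 780-image screening cohort (437 benign, 210 malignant,
#'   133 normal).
#' @param speckle_scale positive scale of the multiplicative Rayleigh
#'   speckle component (0 disables speckle).
#' @param lesion_area_range interval of lesion area as a fraction of the
#'   image, within (0, 1).
#' @param spiculation_amplitude nonnegative relative amplitude of the
#'   radial boundary perturbation applied to malignant lesions only.
#' @param center_jitter maximum offset of the lesion centre from the image
#'   centre, as a fraction of the image side.
#' @param seed integer seed; together with the per-case index it fully
#'   determines every sample.
#' @param preset `"cohort"` for the defaults above, `"easy"` for a
#'   deliberately learnable segmentation benchmark (large centred smooth
#'   lesions, mild speckle) used by the desk-scale training demos.
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(image_size = 512L,
                           n_benign = 437L, n_malignant = 210L,
                           n_normal = 133L,
                           speckle_scale = 0.35,
                           lesion_area_range = c(0.02, 0.20),
                           spiculation_amplitude = 0.25,
                           center_jitter = 0.2,
                           seed = 1L,
                           preset = c("cohort", "easy")) {
  preset <- match.arg(preset)
  if (preset == "easy") {
    if (missing(lesion_area_range)) lesion_area_range <- c(0.08, 0.18)
    if (missing(speckle_scale)) speckle_scale <- 0.2
    if (missing(center_jitter)) center_jitter <- 0.1
    if (missing(spiculation_amplitude)) spiculation_amplitude <- 0.2
  }
  cfg <- list(image_size = as.integer(image_size),
              n_benign = as.integer(n_benign),
              n_malignant = as.integer(n_malignant),
              n_normal = as.integer(n_normal),
              speckle_scale = speckle_scale,
              lesion_area_range = lesion_area_range,
              spiculation_amplitude = spiculation_amplitude,
              center_jitter = center_jitter,
              seed = as.integer(seed),
              preset = preset)
  class(cfg) <- "phantom_config"
  validate_phantom_config(cfg)
  cfg
}

validate_phantom_config <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  if (cfg$image_size < 32L)
    stop("phantom_config: image_size must be at least 32")
  if (any(c(cfg$n_benign, cfg$n_malignant, cfg$n_normal) < 0L))
    stop("phantom_config: class counts must be nonnegative")
  r <- cfg$lesion_area_range
  if (length(r) != 2L || r[1] <= 0 || r[2] >= 1 || r[1] > r[2])
    stop("phantom_config: lesion_area_range must be an ordered interval within (0, 1)")
  if (cfg$speckle_scale < 0) stop("phantom_config: speckle_scale must be >= 0")
  if (cfg$spiculation_amplitude < 0)
    stop("phantom_config: spiculation_amplitude must be >= 0")
  invisible(cfg)
}

phantom_labels <- c("benign", "malignant", "normal")

# Deterministic per-case seed: mixes cohort seed, case index and label.
case_seed <- function(seed, case_index, label) {
  code <- match(label, phantom_labels)
  (as.double(seed) * 100003 + as.double(case_index) * 1009 + code * 7) %%
    2147483647
}

# Separable Gaussian blur with replicated edges (kernel radius 3 sigma).
blur_gauss <- function(m, sigma) {
  r <- ceiling(3 * sigma)
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  pad <- function(idx, n) pmin(pmax(idx, 1L), n)
  sweep1 <- function(x) { # along rows
    out <- x * k[r + 1]
    for (d in seq_len(r)) {
      out <- out + k[r + 1 + d] * x[pad(seq_len(nrow(x)) + d, nrow(x)), ,
                                    drop = FALSE]
      out <- out + k[r + 1 - d] * x[pad(seq_len(nrow(x)) - d, nrow(x)), ,
                                    drop = FALSE]
    }
    out
  }
  t(sweep1(t(sweep1(m))))
}

# Smooth low-frequency base intensity: a few Gaussian blobs on a gradient.
phantom_base <- function(n) {
  g <- seq(0, 1, length.out = n)
  base <- outer(0.55 + 0.25 * g, rep(1, n)) # mild depth gradient
  xs <- matrix(stats::runif(6, 0.1, 0.9), ncol = 2)
  amp <- stats::runif(3, -0.15, 0.15)
  wid <- stats::runif(3, 0.15, 0.4)
  gr <- seq(0, 1, length.out = n)
  for (k in 1:3) {
    bl <- outer(exp(-(gr - xs[k, 1])^2 / (2 * wid[k]^2)),
                exp(-(gr - xs[k, 2])^2 / (2 * wid[k]^2)))
    base <- base + amp[k] * bl
  }
  base
}

# Radial lesion support: ellipse, optionally perturbed by a sum of
# sinusoids in polar angle (spiculation).  Star-convex, hence connected.
lesion_mask <- function(n, center, axes, theta0, spic_amp, spic_lobes) {
  xs <- (seq_len(n) - 0.5) / n
  X <- outer(xs, rep(1, n)) - center[1]
  Y <- outer(rep(1, n), xs) - center[2]
  ct <- cos(theta0); st <- sin(theta0)
  U <- ct * X + st * Y
  V <- -st * X + ct * Y
  r <- sqrt((U / axes[1])^2 + (V / axes[2])^2) # =1 on the ellipse boundary
  if (spic_amp > 0) {
    ang <- atan2(V, U)
    pert <- 1
    for (k in seq_along(spic_lobes))
      pert <- pert + (spic_amp / length(spic_lobes)) *
        sin(spic_lobes[k] * ang + k)
    mask <- r <= pert
  } else {
    mask <- r <= 1
  }
  mask * 1L
}

#' Generate one synthetic ultrasound sample
#'
#' Fully determined by `(cfg$seed, case_index, label)`: the same triple
#' always yields a bit-identical image and mask.
#'
#' @param label one of `"benign"`, `"malignant"`, `"normal"`.
#' @param cfg a [phantom_config()].
#' @param case_index integer case index within the cohort.
#' @return an `ultrasound_sample`: list with `id`, `image` (matrix in
#'   \[0,1\]), `mask` (0/1 matrix of the same shape), `label`.
#' @export
generate_phantom <- function(label, cfg, case_index = 0L) {
  validate_phantom_config(cfg)
  if (!label %in% phantom_labels)
    stop("generate_phantom: invalid label '", label, "'")
  n <- cfg$image_size
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(case_seed(cfg$seed, case_index, label))

  base <- phantom_base(n)
  mask <- matrix(0L, n, n)
  if (label != "normal") {
    area_fr <- stats::runif(1, cfg$lesion_area_range[1], cfg$lesion_area_range[2])
    # ellipse semi-axes (in image-fraction units), aspect ratio in [1, 2]
    aspect <- stats::runif(1, 1, 2)
    a <- sqrt(area_fr * aspect / pi)
    b <- a / aspect
    cj <- cfg$center_jitter
    center <- 0.5 + stats::runif(2, -cj, cj)
    theta0 <- stats::runif(1, 0, pi)
    spic_amp <- if (label == "malignant") cfg$spiculation_amplitude else 0
    lobes <- if (label == "malignant") sample(7:12, 3) else integer(0)
    mask <- lesion_mask(n, center, c(a, b), theta0, spic_amp, lobes)
    if (sum(mask) == 0) { # degenerate draw: force a minimal central lesion
      mask[ceiling(n / 2), ceiling(n / 2)] <- 1L
    }
    # hypoechoic interior at half intensity, with a partial-volume rim:
    # the imaging point-spread function blurs lesion edges, so boundary
    # pixels attenuate only partially.  Spiculated boundaries have a larger
    # rim fraction, which carries into in-ROI texture.
    sm <- blur_gauss(mask, sigma = max(1, n / 64))
    het <- 0
    if (label == "malignant") {
      # malignant lesions carry heterogeneous internal echotexture
      # (coarse-grained intensity variation), unlike homogeneously
      # hypoechoic benign nodules
      h <- blur_gauss(matrix(stats::rnorm(n * n), n, n), sigma = n / 32)
      het <- 0.3 * h / stats::sd(h)
    }
    base <- base * pmax(1 - 0.5 * sm * (1 + het), 0.1)
    if (label == "malignant") {
      # faint posterior shadowing below the lesion
      shadow <- apply(mask, 2, function(col) {
        w <- which(col > 0)
        s <- numeric(length(col))
        if (length(w)) s[seq_len(length(col)) > max(w)] <- 1
        s
      })
      base <- base * (1 - 0.2 * shadow)
    }
  }
  # multiplicative Rayleigh speckle, mean-normalised to 1
  if (cfg$speckle_scale > 0) {
    ray <- sqrt(-2 * log(stats::runif(n * n)))   # Rayleigh(1) deviates
    spk <- 1 + cfg$speckle_scale * (matrix(ray, n, n) / sqrt(pi / 2) - 1)
    img <- base * pmax(spk, 0)
  } else {
    img <- base
  }
  img <- img - min(img)
  img <- img / max(img)
  structure(list(id = sprintf("%s_%04d", label, case_index),
                 image = img, mask = mask, label = label),
            class = "ultrasound_sample")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Generate a full phantom cohort
#'
#' @param cfg a [phantom_config()]; class counts give the cohort makeup.
#' @return list with `samples` (list of `ultrasound_sample`) and `manifest`
#'   (data.frame: id, label, area_fraction).
#' @export
generate_cohort <- function(cfg) {
  validate_phantom_config(cfg)
  total <- cfg$n_benign + cfg$n_malignant + cfg$n_normal
  if (total == 0L) stop("generate_cohort: all class counts are zero")
  labels <- rep(phantom_labels, c(cfg$n_benign, cfg$n_malignant, cfg$n_normal))
  samples <- vector("list", total)
  for (i in seq_len(total))
    samples[[i]] <- generate_phantom(labels[i], cfg, case_index = i)
  manifest <- data.frame(
    id = vapply(samples, `[[`, "", "id"),
    label = labels,
    area_fraction = vapply(samples, function(s) mean(s$mask), 0),
    stringsAsFactors = FALSE)
  list(samples = samples, manifest = manifest)
}

#' Write a cohort to a BUSI-style directory layout
#'
#' Creates per-class folders with 8-bit grayscale `<id>.png` and
#' `<id>_mask.png` pairs (no mask file for normal cases) and a
#' `manifest.csv`.
#'
#' @param cohort result of [generate_cohort()], or a list of samples.
#' @param root output directory (created if missing).
#' @return `root`, invisibly.
#' @export
write_cohort <- function(cohort, root) {
  samples <- if (!is.null(cohort$samples)) cohort$samples else cohort
  for (lab in unique(vapply(samples, `[[`, "", "label")))
    dir.create(file.path(root, lab), recursive = TRUE, showWarnings = FALSE)
  for (s in samples) {
    png::writePNG(t(s$image), file.path(root, s$label, paste0(s$id, ".png")))
    if (s$label != "normal")
      png::writePNG(t(s$mask * 1.0),
                    file.path(root, s$label, paste0(s$id, "_mask.png")))
  }
  if (!is.null(cohort$manifest))
    utils::write.csv(cohort$manifest, file.path(root, "manifest.csv"),
                     row.names = FALSE)
  invisible(root)
}
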