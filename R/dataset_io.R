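#' Load a BUSI-style image/mask directory into memory
#'
#' Expects per-class folders (`benign/`, `malignant/`, `normal/`) containing
#' grayscale PNGs with the `<name>_mask.png` pairing convention.  Images are
#' resized to `target_size` (bilinear) and min-max normalised to \[0,1\];
#' masks are resized nearest-neighbour and re-binarised at 0.5.  Several
#' `_mask_1.png`-style masks for one image are merged by pixelwise OR.
#' Normal-class images may lack a mask file; an all-zero mask is
#' substituted.  A missing mask for an abnormal image is an error.
#'
#' @param root dataset directory.
#' @param target_size output side length in pixels.
#' @return list of `ultrasound_sample`.
#' @export
load_dataset <- function(root, target_size = 512L) {
  if (!dir.exists(root)) stop("load_dataset: no such directory: ", root)
  labs <- intersect(phantom_labels, list.dirs(root, recursive = FALSE,
                                              full.names = FALSE))
  if (!length(labs)) stop("load_dataset: no class folders under ", root)
  samples <- list()
  for (lab in labs) {
    files <- list.files(file.path(root, lab), pattern = "\\.png$")
    imgs <- files[!grepl("_mask", files)]
    for (f in sort(imgs)) {
      id <- sub("\\.png$", "", f)
      img <- read_gray_png(file.path(root, lab, f))
      maskfiles <- files[grepl(paste0("^", id, "_mask"), files)]
      if (length(maskfiles) == 0L) {
        if (lab != "normal")
          stop("load_dataset: missing mask for abnormal case '", id, "'")
        mask <- matrix(0L, nrow(img), ncol(img))
      } else {
        mask <- Reduce(`|`, lapply(maskfiles, function(mf)
          read_gray_png(file.path(root, lab, mf)) >= 0.5)) * 1L
      }
      if (!all(dim(mask) == dim(img)))
        stop("load_dataset: image/mask shape mismatch for '", id, "'")
      img <- resize_image(img, target_size, method = "bilinear")
      rng <- range(img)
      img <- if (diff(rng) > 0) (img - rng[1]) / diff(rng) else img * 0
      mask <- (resize_image(mask, target_size, method = "nearest") >= 0.5) * 1L
      samples[[length(samples) + 1L]] <-
        structure(list(id = id, image = img, mask = mask, label = lab),
                  class = "ultrasound_sample")
    }
  }
  samples
}

read_gray_png <- function(path) {
  a <- tryCatch(png::readPNG(path),
                error = function(e) stop("unreadable PNG: ", path))
  if (length(dim(a)) == 3L) a <- a[, , 1]
  t(a) # undo the row/col transpose used when writing
}

resize_image <- function(img, target, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  if (nrow(img) == target && ncol(img) == target) return(img)
  if (method == "bilinear") {
    as.matrix(EBImage::resize(EBImage::Image(img), w = target, h = target,
                              filter = "bilinear"))
  } else {
    idx <- function(n) pmin(n, pmax(1L, ceiling(seq_len(target) * n / target)))
    img[idx(nrow(img)), idx(ncol(img)), drop = FALSE]
  }
}

#' Reproducible train/test split
#'
#' @param samples list of `ultrasound_sample`.
#' @param n_train,n_test requested sizes; their sum must not exceed the
#'   cohort size.  The full-cohort presets from the source protocol are
#'   635/145 (cohort of 780) and 550/100.
#' @param seed integer seed controlling the permutation.
#' @param stratify preserve per-class proportions within rounding.
#' @return list with disjoint `train` and `test` sample lists.
#' @export
split_dataset <- function(samples, n_train, n_test, seed = 1L,
                          stratify = FALSE) {
  n <- length(samples)
  if (n_train + n_test > n)
    stop("split_dataset: requested sizes exceed cohort size")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  labels <- vapply(samples, `[[`, "", "label")
  if (stratify) {
    tr_idx <- integer(0); te_idx <- integer(0)
    classes <- unique(labels)
    # largest-remainder apportionment of the requested sizes across classes
    alloc <- function(total) {
      raw <- total * table(labels)[classes] / n
      base <- floor(raw)
      rem <- total - sum(base)
      if (rem > 0) {
        extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
        base[extra] <- base[extra] + 1
      }
      base
    }
    a_tr <- alloc(n_train); a_te <- alloc(n_test)
    for (k in seq_along(classes)) {
      pool <- sample(which(labels == classes[k]))
      tr_idx <- c(tr_idx, pool[seq_len(a_tr[k])])
      te_idx <- c(te_idx, pool[a_tr[k] + seq_len(a_te[k])])
    }
  } else {
    perm <- sample(n)
    tr_idx <- perm[seq_len(n_train)]
    te_idx <- perm[n_train + seq_len(n_test)]
  }
  list(train = samples[sort(tr_idx)], test = samples[sort(te_idx)])
}

#' Build a manifest data frame from loaded samples
#' @param samples list of `ultrasound_sample`.
#' @return data.frame with id, label and mask area fraction.
#' @export
dataset_manifest <- function(samples) {
  data.frame(id = vapply(samples, `[[`, "", "id"),
             label = vapply(samples, `[[`, "", "label"),
             area_fraction = vapply(samples, function(s) mean(s$mask), 0),
             stringsAsFactors = FALSE)
}
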