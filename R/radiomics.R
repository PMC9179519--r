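#' Configuration for conventional radiomic extraction
#'
#' @param n_gray_levels fixed number of discretisation bins inside the ROI
#'   (fixed-bin-count discretisation, so features are invariant to affine
#'   intensity rescaling).
#' @param log_sigmas standard deviations (pixels) of the
#'   Laplacian-of-Gaussian derived images.
#' @param wavelet_levels stationary (undecimated) Haar wavelet levels; each
#'   level contributes LL/LH/HL/HH sub-bands at full image resolution.
#' @return object of class `radiomics_config`.
#' @export
radiomics_config <- function(n_gray_levels = 32L, log_sigmas = c(1, 3),
                             wavelet_levels = 3L) {
  if (n_gray_levels < 2L) stop("radiomics_config: n_gray_levels must be >= 2")
  if (wavelet_levels < 1L) stop("radiomics_config: wavelet_levels must be >= 1")
  structure(list(n_gray_levels = as.integer(n_gray_levels),
                 log_sigmas = log_sigmas,
                 wavelet_levels = as.integer(wavelet_levels)),
            class = "radiomics_config")
}

# ---- gray-level discretisation -------------------------------------------

#' Quantise ROI intensities to a fixed number of gray levels
#' @param vals numeric values (ROI intensities) or matrix with NA outside
#'   the ROI.
#' @param n_levels number of bins; a constant input maps to level 1.
#' @return integer levels in 1..n_levels (NA preserved).
#' @export
quantize_roi <- function(vals, n_levels = 32L) {
  rng <- range(vals, na.rm = TRUE)
  if (diff(rng) == 0) {
    q <- vals
    q[!is.na(q)] <- 1L
    return(q)
  }
  q <- floor((vals - rng[1]) / diff(rng) * n_levels) + 1
  q[q > n_levels] <- n_levels
  q
}

shift_mat <- function(m, dr, dc) {
  n <- nrow(m); p <- ncol(m)
  out <- matrix(NA_real_, n, p)
  rs <- max(1, 1 + dr):min(n, n + dr)
  cs <- max(1, 1 + dc):min(p, p + dc)
  out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

# ---- first-order statistics (18) -----------------------------------------

first_order_features <- function(vals, n_levels = 32L) {
  v <- vals[!is.na(vals)]
  n <- length(v)
  m <- mean(v)
  va <- mean((v - m)^2)          # population variance
  sdv <- sqrt(va)
  q <- stats::quantile(v, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE,
                       type = 7)
  inner <- v[v >= q[1] & v <= q[5]]
  hist_p <- tabulate(quantize_roi(v, n_levels), n_levels) / n
  hp <- hist_p[hist_p > 0]
  skew <- if (sdv > 0) mean((v - m)^3) / sdv^3 else 0
  kurt <- if (sdv > 0) mean((v - m)^4) / sdv^4 else 0
  c(Energy = sum(v^2),
    TotalEnergy = sum(v^2),      # unit pixel spacing
    Entropy = -sum(hp * log2(hp)),
    Minimum = min(v),
    P10 = q[1], P90 = q[5],
    Maximum = max(v),
    Mean = m,
    Median = q[3],
    InterquartileRange = q[4] - q[2],
    Range = max(v) - min(v),
    MeanAbsoluteDeviation = mean(abs(v - m)),
    RobustMeanAbsoluteDeviation =
      if (length(inner)) mean(abs(inner - mean(inner))) else 0,
    RootMeanSquared = sqrt(mean(v^2)),
    Skewness = skew,
    Kurtosis = kurt,
    Variance = va,
    Uniformity = sum(hp^2))
}

# ---- GLCM (24) ------------------------------------------------------------

glcm_offsets <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))

#' Gray-level co-occurrence matrix for one offset
#'
#' Pools the offset with its negation (symmetric matrix) and normalises to
#' sum 1.  Pixel pairs where either member lies outside the ROI are
#' ignored.
#'
#' @param q quantised ROI matrix (levels 1..n, NA outside the ROI).
#' @param offset integer `c(dr, dc)` displacement at distance 1.
#' @param n_levels number of gray levels.
#' @return `n_levels` x `n_levels` matrix summing to 1 (all zero if the
#'   ROI admits no valid pairs).
#' @export
glcm_matrix <- function(q, offset, n_levels = max(q, na.rm = TRUE)) {
  s <- shift_mat(q, offset[1], offset[2])
  ok <- !is.na(q) & !is.na(s)
  P <- matrix(0, n_levels, n_levels)
  if (any(ok)) {
    tab <- table(factor(q[ok], levels = 1:n_levels),
                 factor(s[ok], levels = 1:n_levels))
    P <- unclass(tab) + t(unclass(tab))   # symmetrise
    P <- P / sum(P)
  }
  P
}

glcm_features_one <- function(P) {
  Ng <- nrow(P)
  i <- row(P); j <- col(P)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum((1:Ng) * px); muy <- sum((1:Ng) * py)
  sx <- sqrt(sum(((1:Ng) - mux)^2 * px)); sy <- sqrt(sum(((1:Ng) - muy)^2 * py))
  # diagonal / cross-diagonal marginals
  pxmy <- vapply(0:(Ng - 1), function(k) sum(P[abs(i - j) == k]), 0)
  pxpy <- vapply(2:(2 * Ng), function(k) sum(P[(i + j) == k]), 0)
  k_d <- 0:(Ng - 1); k_s <- 2:(2 * Ng)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  HX <- ent(px); HY <- ent(py); HXY <- ent(P)
  pp <- outer(px, py)
  sel <- P > 0 & pp > 0
  HXY1 <- -sum(P[sel] * log2(pp[sel]))
  HXY2 <- ent(pp)
  DA <- sum(k_d * pxmy)
  corr <- if (sx > 0 && sy > 0) (sum(i * j * P) - mux * muy) / (sx * sy) else 1
  imc1 <- if (max(HX, HY) > 0) (HXY - HXY1) / max(HX, HY) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (HXY2 - HXY))))
  # maximal correlation coefficient via the Q matrix (restricted to
  # occupied gray levels)
  occ <- which(px > 0)
  mcc <- 1
  if (length(occ) > 1) {
    Psub <- P[occ, occ, drop = FALSE]
    Q <- (Psub / px[occ]) %*% t(Psub / matrix(py[occ], length(occ),
                                              length(occ), byrow = TRUE))
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    mcc <- sqrt(max(0, ev[2]))
  }
  c(Autocorrelation = sum(i * j * P),
    ClusterProminence = sum((i + j - mux - muy)^4 * P),
    ClusterShade = sum((i + j - mux - muy)^3 * P),
    ClusterTendency = sum((i + j - mux - muy)^2 * P),
    Contrast = sum((i - j)^2 * P),
    Correlation = corr,
    DifferenceAverage = DA,
    DifferenceEntropy = ent(pxmy),
    DifferenceVariance = sum((k_d - DA)^2 * pxmy),
    Id = sum(pxmy / (1 + k_d)),
    Idm = sum(pxmy / (1 + k_d^2)),
    Idmn = sum(pxmy / (1 + k_d^2 / Ng^2)),
    Idn = sum(pxmy / (1 + k_d / Ng)),
    Imc1 = imc1, Imc2 = imc2,
    InverseVariance = sum(pxmy[-1] / k_d[-1]^2),
    JointAverage = mux,
    JointEnergy = sum(P^2),
    JointEntropy = HXY,
    MCC = mcc,
    MaximumProbability = max(P),
    SumAverage = sum(k_s * pxpy),
    SumEntropy = ent(pxpy),
    SumSquares = sx^2)
}

glcm_features <- function(q, n_levels) {
  mats <- lapply(glcm_offsets, function(o) glcm_matrix(q, o, n_levels))
  feats <- vapply(mats, glcm_features_one, numeric(24))
  rowMeans(feats)
}

# ---- GLDM (14) -------------------------------------------------------------

neighbor_shifts8 <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1),
                          c(1, -1), c(1, 0), c(1, 1))

gldm_features <- function(q, n_levels, alpha = 0) {
  inroi <- !is.na(q)
  dep <- matrix(0L, nrow(q), ncol(q))
  for (k in seq_len(nrow(neighbor_shifts8))) {
    s <- shift_mat(q, neighbor_shifts8[k, 1], neighbor_shifts8[k, 2])
    dep <- dep + (!is.na(s) & inroi & abs(q - s) <= alpha)
  }
  g <- q[inroi]; d <- dep[inroi] + 1L  # dependence index j = count + 1
  Nd <- max(d)
  P <- unclass(table(factor(g, levels = 1:n_levels), factor(d, levels = 1:Nd)))
  size_zone_style_features(P, Np = sum(P), prefix = "", flavor = "gldm")
}

# ---- GLRLM (16) ------------------------------------------------------------

glrlm_lines <- function(q) {
  n <- nrow(q); p <- ncol(q)
  list(h = split(q, row(q)),
       v = split(q, col(q)),
       d1 = split(q, row(q) - col(q)),
       d2 = split(q, row(q) + col(q)))
}

glrlm_matrix_dir <- function(lines, n_levels) {
  max_r <- max(vapply(lines, length, 0L))
  P <- matrix(0, n_levels, max_r)
  for (ln in lines) {
    r <- rle(as.numeric(ln))
    keep <- !is.na(r$values)
    if (any(keep))
      for (k in which(keep))
        P[r$values[k], r$lengths[k]] <- P[r$values[k], r$lengths[k]] + 1
  }
  P
}

glrlm_features <- function(q, n_levels) {
  Np <- sum(!is.na(q))
  ls <- glrlm_lines(q)
  feats <- vapply(ls, function(lines) {
    P <- glrlm_matrix_dir(lines, n_levels)
    size_zone_style_features(P, Np = Np, flavor = "glrlm")
  }, numeric(16))
  rowMeans(feats)
}

# Shared run-length / size-zone / dependence feature family.  P is a
# (gray level x size) count matrix; names differ per family.
size_zone_style_features <- function(P, Np, prefix = "", flavor) {
  Nz <- sum(P)
  if (Nz == 0) P1 <- P else P1 <- P / Nz
  i <- row(P); j <- col(P)
  pi_g <- rowSums(P1); pj <- colSums(P1)
  mu_i <- sum(row(P1)[, 1] * pi_g); mu_j <- sum(seq_len(ncol(P1)) * pj)
  pp <- P1[P1 > 0]
  small <- sum(P1 / j^2); large <- sum(P1 * j^2)
  gln <- sum(rowSums(P)^2) / max(Nz, 1)
  sn <- sum(colSums(P)^2) / max(Nz, 1)
  lowg <- sum(P1 / i^2); highg <- sum(P1 * i^2)
  glv <- sum(P1 * (i - mu_i)^2)
  jv <- sum(P1 * (j - mu_j)^2)
  entr <- if (length(pp)) -sum(pp * log2(pp)) else 0
  slg <- sum(P1 / (i^2 * j^2)); shg <- sum(P1 * i^2 / j^2)
  llg <- sum(P1 * j^2 / i^2); lhg <- sum(P1 * i^2 * j^2)
  if (flavor == "glrlm") {
    c(ShortRunEmphasis = small, LongRunEmphasis = large,
      GrayLevelNonUniformity = gln,
      GrayLevelNonUniformityNormalized = gln / max(Nz, 1),
      RunLengthNonUniformity = sn,
      RunLengthNonUniformityNormalized = sn / max(Nz, 1),
      RunPercentage = Nz / max(Np, 1),
      GrayLevelVariance = glv, RunVariance = jv, RunEntropy = entr,
      LowGrayLevelRunEmphasis = lowg, HighGrayLevelRunEmphasis = highg,
      ShortRunLowGrayLevelEmphasis = slg,
      ShortRunHighGrayLevelEmphasis = shg,
      LongRunLowGrayLevelEmphasis = llg,
      LongRunHighGrayLevelEmphasis = lhg)
  } else if (flavor == "glszm") {
    c(SmallAreaEmphasis = small, LargeAreaEmphasis = large,
      GrayLevelNonUniformity = gln,
      GrayLevelNonUniformityNormalized = gln / max(Nz, 1),
      SizeZoneNonUniformity = sn,
      SizeZoneNonUniformityNormalized = sn / max(Nz, 1),
      ZonePercentage = Nz / max(Np, 1),
      GrayLevelVariance = glv, ZoneVariance = jv, ZoneEntropy = entr,
      LowGrayLevelZoneEmphasis = lowg, HighGrayLevelZoneEmphasis = highg,
      SmallAreaLowGrayLevelEmphasis = slg,
      SmallAreaHighGrayLevelEmphasis = shg,
      LargeAreaLowGrayLevelEmphasis = llg,
      LargeAreaHighGrayLevelEmphasis = lhg)
  } else { # gldm
    c(SmallDependenceEmphasis = small, LargeDependenceEmphasis = large,
      GrayLevelNonUniformity = gln,
      DependenceNonUniformity = sn,
      DependenceNonUniformityNormalized = sn / max(Nz, 1),
      GrayLevelVariance = glv, DependenceVariance = jv,
      DependenceEntropy = entr,
      LowGrayLevelEmphasis = lowg, HighGrayLevelEmphasis = highg,
      SmallDependenceLowGrayLevelEmphasis = slg,
      SmallDependenceHighGrayLevelEmphasis = shg,
      LargeDependenceLowGrayLevelEmphasis = llg,
      LargeDependenceHighGrayLevelEmphasis = lhg)
  }
}

# ---- GLSZM (16) ------------------------------------------------------------

#' 8-connected component labelling
#'
#' Labels connected regions of a binary mask using 8-connectivity
#' (4-connected labelling refined by merging components that touch
#' diagonally).
#'
#' @param mask binary matrix.
#' @return integer matrix of component labels (0 = background).
#' @export
label_components <- function(mask) {
  l4 <- as.matrix(EBImage::bwlabel(EBImage::Image((mask > 0) * 1)))
  nl <- max(l4)
  if (nl <= 1) return(l4)
  parent <- seq_len(nl)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (d in list(c(1, 1), c(1, -1))) {
    s <- shift_mat(l4, d[1], d[2])
    ok <- l4 > 0 & !is.na(s) & s > 0 & l4 != s
    if (any(ok)) {
      pairs <- unique(cbind(l4[ok], s[ok]))
      for (k in seq_len(nrow(pairs))) {
        a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
        if (a != b) parent[max(a, b)] <- min(a, b)
      }
    }
  }
  roots <- vapply(seq_len(nl), function(x) as.integer(find(x)), 0L)
  relab <- match(roots, sort(unique(roots)))
  out <- l4
  out[l4 > 0] <- relab[l4[l4 > 0]]
  out
}

glszm_features <- function(q, n_levels) {
  Np <- sum(!is.na(q))
  zones_g <- integer(0); zones_s <- integer(0)
  for (g in seq_len(n_levels)) {
    bw <- !is.na(q) & q == g
    if (!any(bw)) next
    lab <- label_components(bw)
    sizes <- tabulate(lab[lab > 0])
    zones_g <- c(zones_g, rep(g, length(sizes)))
    zones_s <- c(zones_s, sizes)
  }
  P <- unclass(table(factor(zones_g, levels = 1:n_levels),
                     factor(zones_s, levels = seq_len(max(zones_s)))))
  size_zone_style_features(P, Np = Np, flavor = "glszm")
}

# ---- NGTDM (5) -------------------------------------------------------------

ngtdm_features <- function(q, n_levels) {
  inroi <- !is.na(q)
  nb_sum <- matrix(0, nrow(q), ncol(q))
  nb_cnt <- matrix(0, nrow(q), ncol(q))
  for (k in seq_len(nrow(neighbor_shifts8))) {
    s <- shift_mat(q, neighbor_shifts8[k, 1], neighbor_shifts8[k, 2])
    ok <- !is.na(s)
    nb_sum[ok] <- nb_sum[ok] + s[ok]
    nb_cnt <- nb_cnt + ok
  }
  use <- inroi & nb_cnt > 0
  g <- q[use]
  abar <- nb_sum[use] / nb_cnt[use]
  N <- length(g)
  s_i <- vapply(1:n_levels, function(l) sum(abs(g[g == l] - abar[g == l])), 0)
  n_i <- tabulate(g, n_levels)
  p_i <- n_i / N
  pos <- which(p_i > 0)
  Ngp <- length(pos)
  coarse_den <- sum(p_i * s_i)
  coarseness <- if (coarse_den > 0) 1 / coarse_den else 1e6
  contrast <- 0
  if (Ngp > 1) {
    iv <- pos
    pm <- outer(p_i[pos], p_i[pos])
    dm <- outer(iv, iv, `-`)^2
    contrast <- sum(pm * dm) / (Ngp * (Ngp - 1)) * sum(s_i) / N
  }
  busy_den <- 0; complexity <- 0; strength_num <- 0
  if (Ngp >= 1) {
    for (a in pos) for (b in pos) {
      busy_den <- busy_den + abs(a * p_i[a] - b * p_i[b])
      complexity <- complexity +
        abs(a - b) * (p_i[a] * s_i[a] + p_i[b] * s_i[b]) / (p_i[a] + p_i[b])
      strength_num <- strength_num + (p_i[a] + p_i[b]) * (a - b)^2
    }
  }
  busyness <- if (busy_den > 0) sum(p_i * s_i) / busy_den else 0
  complexity <- complexity / N
  strength <- if (sum(s_i) > 0) strength_num / sum(s_i) else 0
  c(Coarseness = coarseness, Contrast = contrast, Busyness = busyness,
    Complexity = complexity, Strength = strength)
}

# ---- 2-D shape (9) ---------------------------------------------------------

# Marching-squares perimeter and mesh area at the 0.5 iso-level, with
# midpoint vertex interpolation; mask padded so the contour always closes.
marching_squares <- function(mask) {
  m <- matrix(0L, nrow(mask) + 2L, ncol(mask) + 2L)
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- (mask > 0) * 1L
  a <- m[-nrow(m), -ncol(m)]   # (r, c)
  b <- m[-1, -ncol(m)]         # (r+1, c)
  cc <- m[-nrow(m), -1]        # (r, c+1)
  d <- m[-1, -1]               # (r+1, c+1)
  case <- a + 2L * b + 4L * cc + 8L * d
  s2 <- sqrt(2) / 2
  # perimeter and inside-area per marching-squares case (unit cell)
  perim_tab <- c(0, s2, s2, 1, s2, 1, 2 * s2, s2,
                 s2, 2 * s2, 1, s2, 1, s2, s2, 0)
  area_tab <- c(0, 1 / 8, 1 / 8, 1 / 2, 1 / 8, 1 / 2, 1 / 4, 7 / 8,
                1 / 8, 1 / 4, 1 / 2, 7 / 8, 1 / 2, 7 / 8, 7 / 8, 1)
  counts <- tabulate(case + 1L, 16L)
  list(perimeter = sum(counts * perim_tab),
       mesh_area = sum(counts * area_tab))
}

#' Two-dimensional shape features of a lesion mask
#'
#' Nine descriptors: pixel area, mesh (contour-polygon) area, perimeter,
#' perimeter-to-area ratio, sphericity (circle-normalised compactness),
#' maximum diameter, major/minor principal axis lengths and elongation.
#' Perimeter and mesh area come from a marching-squares contour at the
#' 0.5 level, so they approximate the continuous outline rather than the
#' blocky pixel boundary.
#'
#' @param mask binary matrix with at least one positive pixel.
#' @return named numeric vector of 9 features.
#' @export
shape_features_2d <- function(mask) {
  if (sum(mask) == 0) stop("shape_features_2d: empty mask")
  ms <- marching_squares(mask)
  area_pix <- sum(mask > 0)
  idx <- which(mask > 0, arr.ind = TRUE)
  ctr <- colMeans(idx)
  X <- sweep(idx, 2, ctr)
  cv <- crossprod(X) / nrow(X)
  ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ev[ev < 0] <- 0
  maxdiam <- 0
  hull <- idx[grDevices::chull(idx[, 1], idx[, 2]), , drop = FALSE]
  if (nrow(hull) >= 2) maxdiam <- sqrt(max(stats::dist(hull)^2))
  perim <- ms$perimeter
  c(PixelSurface = area_pix,
    MeshSurface = ms$mesh_area,
    Perimeter = perim,
    PerimeterSurfaceRatio = perim / max(ms$mesh_area, .Machine$double.eps),
    Sphericity = if (perim > 0) 2 * sqrt(pi * ms$mesh_area) / perim else 1,
    MaximumDiameter = maxdiam,
    MajorAxisLength = 4 * sqrt(ev[1]),
    MinorAxisLength = 4 * sqrt(ev[2]),
    Elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 1)
}

# ---- derived images --------------------------------------------------------

log_kernel <- function(sigma) {
  r <- ceiling(4 * sigma)
  xs <- -r:r
  X <- outer(xs^2, rep(1, length(xs))) + outer(rep(1, length(xs)), xs^2)
  k <- -1 / (pi * sigma^4) * (1 - X / (2 * sigma^2)) * exp(-X / (2 * sigma^2))
  k - mean(k) # zero-sum so constant regions respond exactly 0
}

swt_pair <- function(x, s, margin) {
  # periodic shift along rows (margin 1) or columns (margin 2)
  n <- dim(x)[margin]
  idx <- ((seq_len(n) - 1 + s) %% n) + 1
  shifted <- if (margin == 1) x[idx, , drop = FALSE] else x[, idx, drop = FALSE]
  list(lo = (x + shifted) / 2, hi = (x - shifted) / 2)
}

#' Derived images for texture analysis
#'
#' Produces `length(log_sigmas)` Laplacian-of-Gaussian responses plus
#' `4 * wavelet_levels` stationary (a-trous, undecimated) Haar wavelet
#' sub-bands (LL/LH/HL/HH per level; first letter = row filter).  Every
#' derived raster keeps the input shape, so the original ROI mask applies
#' directly.
#'
#' @param image 2-D numeric matrix.
#' @param cfg a [radiomics_config()].
#' @return named list of matrices (14 under the defaults).
#' @export
derive_images <- function(image, cfg = radiomics_config()) {
  out <- list()
  for (s in cfg$log_sigmas) {
    k <- log_kernel(s)
    rad <- (nrow(k) - 1L) %/% 2L
    # replicate-pad so the kernel never exceeds the raster, then crop back
    ri <- c(rep(1L, rad), seq_len(nrow(image)), rep(nrow(image), rad))
    ci <- c(rep(1L, rad), seq_len(ncol(image)), rep(ncol(image), rad))
    padded <- image[ri, ci]
    r <- as.matrix(EBImage::filter2(EBImage::Image(padded), k,
                                    boundary = "circular"))
    r <- r[rad + seq_len(nrow(image)), rad + seq_len(ncol(image))]
    out[[sprintf("log_sigma_%s", gsub("\\.", "_", format(s, nsmall = 1)))]] <- r
  }
  ll <- image
  for (lev in seq_len(cfg$wavelet_levels)) {
    s <- 2L^(lev - 1L)
    rowp <- swt_pair(ll, s, 1)
    LL <- swt_pair(rowp$lo, s, 2); LH <- LL$hi; LLb <- LL$lo
    HL <- swt_pair(rowp$hi, s, 2)
    out[[sprintf("wavelet_L%d_LL", lev)]] <- LLb
    out[[sprintf("wavelet_L%d_LH", lev)]] <- LH
    out[[sprintf("wavelet_L%d_HL", lev)]] <- HL$lo
    out[[sprintf("wavelet_L%d_HH", lev)]] <- HL$hi
    ll <- LLb
  }
  out
}

# ---- assembly --------------------------------------------------------------

fo_names <- c("Energy", "TotalEnergy", "Entropy", "Minimum", "P10", "P90",
              "Maximum", "Mean", "Median", "InterquartileRange", "Range",
              "MeanAbsoluteDeviation", "RobustMeanAbsoluteDeviation",
              "RootMeanSquared", "Skewness", "Kurtosis", "Variance",
              "Uniformity")

#' Names of the full conventional radiomic feature panel
#'
#' Frozen, versioned list of the 354 feature names in extraction order:
#' 102 on the original image (18 first-order, 9 shape, 24 GLCM, 14 GLDM,
#' 16 GLRLM, 16 GLSZM, 5 NGTDM) plus 18 first-order features on each of
#' the 14 derived images.
#'
#' @param cfg a [radiomics_config()].
#' @return character vector of length 354 under the defaults.
#' @export
radiomics_feature_names <- function(cfg = radiomics_config()) {
  derived <- c(vapply(cfg$log_sigmas, function(s)
    sprintf("log_sigma_%s", gsub("\\.", "_", format(s, nsmall = 1))), ""),
    as.vector(t(outer(sprintf("wavelet_L%d", seq_len(cfg$wavelet_levels)),
                      c("LL", "LH", "HL", "HH"), paste, sep = "_"))))
  probe <- matrix(c(0, 1, 2, 3), 2, 2)
  c(paste0("original_firstorder_", fo_names),
    paste0("original_shape2D_", names(shape_features_2d(matrix(1, 2, 2)))),
    paste0("original_glcm_", names(glcm_features_one(diag(2) / 2))),
    paste0("original_gldm_",
           names(size_zone_style_features(matrix(1, 1, 1), 1, flavor = "gldm"))),
    paste0("original_glrlm_",
           names(size_zone_style_features(matrix(1, 1, 1), 1, flavor = "glrlm"))),
    paste0("original_glszm_",
           names(size_zone_style_features(matrix(1, 1, 1), 1, flavor = "glszm"))),
    paste0("original_ngtdm_", c("Coarseness", "Contrast", "Busyness",
                                "Complexity", "Strength")),
    as.vector(t(outer(derived, paste0("firstorder_", fo_names),
                      paste, sep = "_"))))
}

#' Extract the conventional radiomic feature vector for one lesion ROI
#'
#' Computes all features on the masked region only.  Texture matrices use
#' fixed-bin-count discretisation inside the ROI; a constant ROI yields
#' the documented limiting values (entropies 0, ratios at their limits),
#' never NaN.
#'
#' @param sample an `ultrasound_sample`, or an image matrix (then `mask`
#'   must be given).
#' @param mask binary matrix when `sample` is a plain image.
#' @param cfg a [radiomics_config()].
#' @return named numeric vector of length 354 (under the defaults).
#' @export
extract_features <- function(sample, mask = NULL, cfg = radiomics_config()) {
  if (inherits(sample, "ultrasound_sample") ||
      (is.list(sample) && !is.null(sample$image))) {
    image <- sample$image; mask <- sample$mask
  } else image <- sample
  if (is.null(mask) || sum(mask) == 0)
    stop("extract_features: empty or missing mask")
  if (!all(dim(image) == dim(mask)))
    stop("extract_features: image/mask shape mismatch")
  nl <- cfg$n_gray_levels
  roi_na <- image
  roi_na[mask == 0] <- NA_real_
  q <- quantize_roi(roi_na, nl)
  out <- c(first_order_features(roi_na[!is.na(roi_na)], nl),
           shape_features_2d(mask),
           glcm_features(q, nl),
           gldm_features(q, nl),
           glrlm_features(q, nl),
           glszm_features(q, nl),
           ngtdm_features(q, nl))
  for (dimg in derive_images(image, cfg)) {
    v <- dimg
    v[mask == 0] <- NA_real_
    out <- c(out, first_order_features(v[!is.na(v)], nl))
  }
  names(out) <- radiomics_feature_names(cfg)
  out
}

#' Radiomic feature matrix for a cohort
#'
#' @param samples list of `ultrasound_sample` (abnormal cases; samples
#'   with empty masks are skipped with a message).
#' @param cfg a [radiomics_config()].
#' @return matrix cases x 354 with sample ids as rownames.
#' @export
extract_feature_matrix <- function(samples, cfg = radiomics_config()) {
  keep <- vapply(samples, function(s) sum(s$mask) > 0, TRUE)
  if (!all(keep))
    message("extract_feature_matrix: skipping ", sum(!keep),
            " empty-mask samples")
  samples <- samples[keep]
  X <- t(vapply(samples, function(s) extract_features(s, cfg = cfg),
                numeric(length(radiomics_feature_names(cfg)))))
  rownames(X) <- vapply(samples, `[[`, "", "id")
  X
}
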