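# Independent oracles used across test files.  Deliberately brute-force and
# separate from the package implementation.

# Flood-fill connected-component count (8-connectivity).
oracle_n_components <- function(mask, conn8 = TRUE) {
  todo <- which(mask > 0, arr.ind = TRUE)
  if (nrow(todo) == 0) return(0L)
  seen <- matrix(FALSE, nrow(mask), ncol(mask))
  nb <- if (conn8) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  ncomp <- 0L
  for (k in seq_len(nrow(todo))) {
    r0 <- todo[k, 1]; c0 <- todo[k, 2]
    if (seen[r0, c0]) next
    ncomp <- ncomp + 1L
    stack <- list(c(r0, c0)); seen[r0, c0] <- TRUE
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (j in seq_len(nrow(nb))) {
        r <- p[1] + nb[j, 1]; cc <- p[2] + nb[j, 2]
        if (r >= 1 && r <= nrow(mask) && cc >= 1 && cc <= ncol(mask) &&
            mask[r, cc] > 0 && !seen[r, cc]) {
          seen[r, cc] <- TRUE
          stack[[length(stack) + 1L]] <- c(r, cc)
        }
      }
    }
  }
  ncomp
}

# Brute-force Dice by explicit elementwise summation.
oracle_dice <- function(p, g) {
  num <- 0; d1 <- 0; d2 <- 0
  for (i in seq_along(p)) {
    num <- num + 2 * p[i] * g[i]
    d1 <- d1 + p[i]^2
    d2 <- d2 + g[i]^2
  }
  if (d1 + d2 == 0) return(1)
  num / (d1 + d2)
}

# Exhaustive symmetric co-occurrence counting for one offset.
oracle_glcm <- function(q, dr, dc, n_levels) {
  P <- matrix(0, n_levels, n_levels)
  for (r in seq_len(nrow(q))) for (cc in seq_len(ncol(q))) {
    r2 <- r + dr; c2 <- cc + dc
    if (r2 >= 1 && r2 <= nrow(q) && c2 >= 1 && c2 <= ncol(q) &&
        !is.na(q[r, cc]) && !is.na(q[r2, c2])) {
      P[q[r, cc], q[r2, c2]] <- P[q[r, cc], q[r2, c2]] + 1
      P[q[r2, c2], q[r, cc]] <- P[q[r2, c2], q[r, cc]] + 1
    }
  }
  P / sum(P)
}

# Average precision by explicit enumeration of all score thresholds.
oracle_ap <- function(scores, y) {
  th <- sort(unique(scores), decreasing = TRUE)
  prevR <- 0; ap <- 0
  for (t in th) {
    sel <- scores >= t
    P <- sum(y[sel]) / sum(sel)
    R <- sum(y[sel]) / sum(y)
    ap <- ap + (R - prevR) * P
    prevR <- R
  }
  ap
}
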