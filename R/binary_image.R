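# Binary-image primitives: exact Euclidean distance transform and
# morphological thinning. These back the width-based decomposition of a
# vessel mask into thin and thick compartments; no raster package in the
# dependency stack provides them, so they are implemented here.

#' Squared Euclidean distance transform
#'
#' Computes, for every pixel, the squared Euclidean distance to the nearest
#' pixel of the feature set, using the exact two-pass lower-envelope
#' algorithm (1-D parabola sweep applied to columns then rows).
#'
#' @param feature logical or 0/1 matrix; `TRUE`/1 marks the feature set.
#' @return numeric matrix of squared distances; `Inf` if the feature set is
#'   empty.
#' @export
distance_transform_sq <- function(feature) {
  f <- matrix(ifelse(as.logical(feature), 0, Inf),
              nrow = nrow(feature), ncol = ncol(feature))
  f <- apply(f, 2, dt_1d)
  f <- t(apply(f, 1, dt_1d))
  f
}

# 1-D squared distance transform (Felzenszwalb & Huttenlocher lower
# envelope of parabolas). f: vector of initial costs.
dt_1d <- function(f) {
  n <- length(f)
  if (all(is.infinite(f))) return(f)
  d <- numeric(n)
  v <- integer(n)  # locations of parabolas in the envelope
  z <- numeric(n + 1)  # boundaries between parabolas
  k <- 1L
  v[1] <- 1L
  z[1] <- -Inf
  z[2] <- Inf
  for (q in 2:n) {
    if (is.infinite(f[q])) next
    repeat {
      p <- v[k]
      if (is.infinite(f[p])) {
        s <- -Inf
      } else {
        s <- ((f[q] + q^2) - (f[p] + p^2)) / (2 * q - 2 * p)
      }
      if (s <= z[k]) {
        k <- k - 1L
        if (k == 0L) { k <- 1L; v[1] <- q; z[1] <- -Inf; z[2] <- Inf; break }
      } else {
        k <- k + 1L
        v[k] <- q
        z[k] <- s
        z[k + 1] <- Inf
        break
      }
    }
  }
  k <- 1L
  for (q in 1:n) {
    while (z[k + 1] < q) k <- k + 1L
    p <- v[k]
    d[q] <- (q - p)^2 + f[p]
  }
  d
}

# Shift a matrix by (dy, dx) with zero fill; used by the thinning kernel.
shift_mat <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  ys <- seq_len(h) - dy
  xs <- seq_len(w) - dx
  ok_y <- ys >= 1 & ys <= h
  ok_x <- xs >= 1 & xs <= w
  out[ok_y, ok_x] <- m[ys[ok_y], xs[ok_x]]
  out
}

#' Morphological thinning (Zhang-Suen)
#'
#' Reduces a binary mask to an (approximately) one-pixel-wide skeleton.
#' If thinning would remove every foreground pixel of a tiny blob, the
#' original blob pixels are retained so that a non-empty mask always yields
#' a non-empty skeleton.
#'
#' @param mask 0/1 matrix.
#' @return 0/1 matrix of the same shape.
#' @export
skeletonize <- function(mask) {
  check_binary(mask, "mask")
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  if (sum(m) == 0) return(m)
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      # neighbours clockwise from north: P2..P9
      p2 <- shift_mat(m, -1, 0); p3 <- shift_mat(m, -1, 1)
      p4 <- shift_mat(m, 0, 1);  p5 <- shift_mat(m, 1, 1)
      p6 <- shift_mat(m, 1, 0);  p7 <- shift_mat(m, 1, -1)
      p8 <- shift_mat(m, 0, -1); p9 <- shift_mat(m, -1, -1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      seqs <- list(p2, p3, p4, p5, p6, p7, p8, p9, p2)
      a <- 0
      for (i in 1:8) a <- a + (seqs[[i]] == 0 & seqs[[i + 1]] == 1)
      if (step == 1) {
        cond <- p2 * p4 * p6 == 0 & p4 * p6 * p8 == 0
      } else {
        cond <- p2 * p4 * p8 == 0 & p2 * p6 * p8 == 0
      }
      del <- m == 1 & b >= 2 & b <= 6 & a == 1 & cond
      if (any(del)) {
        m[del] <- 0
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (sum(m) == 0) m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  m
}
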