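# Synthetic vascular phantoms: branching random-walk vessel trees rendered
# onto a textured background with radial vignetting, plus decomposition of
# the ground truth into thin and thick compartments by local calibre.
# Emulates manually annotated dataset triplets (image, gt, thin, thick).

#' Parameters of a synthetic vascular scene
#'
#' @param image_height,image_width image dimensions in pixels (each >= 32).
#' @param n_trees number of vascular root branches (>= 0).
#' @param thin_width_range integer vector (min, max) of thin-vessel widths
#'   in pixels; default `c(1, 2)`.
#' @param thick_width_range integer vector (min, max) of thick-vessel widths
#'   in pixels; default `c(3, 8)`. Must lie strictly above the thin range.
#' @param branch_depth number of branching levels per tree (>= 1).
#' @param vessel_contrast relative intensity offset of vessel pixels over
#'   local background, in `[0, 1]`.
#' @param background_noise_sd standard deviation of additive pixel noise in
#'   intensity units (image intensities live in `[0, 1]`).
#' @param seed integer seed; the scene is a deterministic function of the
#'   full parameter set.
#' @return an object of class `scene_params`.
#' @export
scene_params <- function(image_height = 64, image_width = 64, n_trees = 2,
                         thin_width_range = c(1, 2),
                         thick_width_range = c(3, 8),
                         branch_depth = 3, vessel_contrast = 0.6,
                         background_noise_sd = 0.03, seed = 1L) {
  if (image_height < 32 || image_width < 32) {
    stop("image dimensions must be at least 32 pixels in each axis", call. = FALSE)
  }
  if (thin_width_range[1] > thin_width_range[2] ||
      thick_width_range[1] > thick_width_range[2]) {
    stop("degenerate width range: min exceeds max", call. = FALSE)
  }
  if (thin_width_range[2] >= thick_width_range[1]) {
    stop("thin_width_range max must be below thick_width_range min", call. = FALSE)
  }
  if (n_trees < 0 || branch_depth < 1) {
    stop("n_trees must be >= 0 and branch_depth >= 1", call. = FALSE)
  }
  structure(list(
    image_height = as.integer(image_height),
    image_width = as.integer(image_width),
    n_trees = as.integer(n_trees),
    thin_width_range = as.numeric(thin_width_range),
    thick_width_range = as.numeric(thick_width_range),
    branch_depth = as.integer(branch_depth),
    vessel_contrast = as.numeric(vessel_contrast),
    background_noise_sd = as.numeric(background_noise_sd),
    seed = as.integer(seed)
  ), class = "scene_params")
}

# Stamp a disk of radius r (in pixels) centred at (y, x) into mask.
stamp_disk <- function(mask, y, x, r) {
  h <- nrow(mask); w <- ncol(mask)
  y0 <- max(1L, floor(y - r)); y1 <- min(h, ceiling(y + r))
  x0 <- max(1L, floor(x - r)); x1 <- min(w, ceiling(x + r))
  if (y0 > y1 || x0 > x1) return(mask)
  ys <- y0:y1; xs <- x0:x1
  dd <- outer((ys - y)^2, (xs - x)^2, "+")
  sub <- mask[ys, xs, drop = FALSE]
  sub[dd <= r^2] <- 1
  mask[ys, xs] <- sub
  mask
}

# Trace one branch as a correlated random walk, stamping a constant-calibre
# stroke along the way; the walk reflects at the image border so branches
# stay inside the frame. Calibres below 2 px are snapped to single-pixel
# stamps so thin vessels render at true 1-px width. Returns the updated
# mask and the walk's end state.
trace_branch <- function(mask, y, x, theta, width, len) {
  h <- nrow(mask); w <- ncol(mask)
  r <- max(width / 2, 0.5)
  step <- 0.7
  for (i in seq_len(ceiling(len / step))) {
    if (r < 1) {
      mask[max(1, min(h, round(y))), max(1, min(w, round(x)))] <- 1
    } else {
      mask <- stamp_disk(mask, y, x, r)
    }
    theta <- theta + stats::rnorm(1, 0, 0.18)
    yn <- y + step * sin(theta)
    xn <- x + step * cos(theta)
    if (yn < 1 || yn > h) { theta <- -theta; yn <- y + step * sin(theta) }
    if (xn < 1 || xn > w) { theta <- pi - theta; xn <- x + step * cos(theta) }
    y <- min(max(yn, 1), h)
    x <- min(max(xn, 1), w)
  }
  list(mask = mask, y = y, x = x, theta = theta)
}

# Recursively grow a tree: the root levels carry thick calibres, deeper
# levels thin ones, so every scene with branch_depth >= 2 exercises both
# calibre regimes.
grow_tree <- function(mask, y, x, theta, level, params) {
  h <- params$image_height; w <- params$image_width
  thick_level <- level <= ceiling(params$branch_depth / 2)
  rng <- if (thick_level) params$thick_width_range else params$thin_width_range
  width <- stats::runif(1, rng[1], rng[2])
  len <- stats::runif(1, 0.35, 0.6) * min(h, w) / level
  tr <- trace_branch(mask, y, x, theta, width, len)
  mask <- tr$mask
  if (level < params$branch_depth) {
    for (s in c(-1, 1)) {
      ang <- tr$theta + s * stats::runif(1, 0.3, 0.9)
      mask <- grow_tree(mask, tr$y, tr$x, ang, level + 1L, params)
    }
  }
  mask
}

#' Generate a synthetic vessel scene
#'
#' Draws `n_trees` branching vessel trees (per-branch constant calibre,
#' thick near the root, thin at the leaves), renders them over a smoothed
#' noise background with a radial illumination falloff imitating fundus
#' vignetting, and decomposes the ground truth into thin and thick masks
#' with [decompose_by_width()].
#'
#' @param params a [scene_params()] object.
#' @param width_threshold calibre cut-off (full width, pixels) separating
#'   thin from thick; default 2, aligned with the thin width range.
#' @return a list with elements `image` (matrix in `[0, 1]`), `gt`, `thin`,
#'   `thick` (0/1 matrices of the same shape).
#' @export
generate_scene <- function(params, width_threshold = 2) {
  stopifnot(inherits(params, "scene_params"))
  h <- params$image_height; w <- params$image_width
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(params$seed)

  gt <- matrix(0, h, w)
  if (params$n_trees > 0) {
    for (t in seq_len(params$n_trees)) {
      # roots on the image border, heading inwards
      side <- sample(4, 1)
      if (side == 1) { y <- 1; x <- stats::runif(1, 0.2, 0.8) * w; theta <- pi / 2 }
      else if (side == 2) { y <- h; x <- stats::runif(1, 0.2, 0.8) * w; theta <- -pi / 2 }
      else if (side == 3) { y <- stats::runif(1, 0.2, 0.8) * h; x <- 1; theta <- 0 }
      else { y <- stats::runif(1, 0.2, 0.8) * h; x <- w; theta <- pi }
      theta <- theta + stats::rnorm(1, 0, 0.3)
      gt <- grow_tree(gt, y, x, theta, 1L, params)
    }
  }

  # background: low-frequency texture + radial vignetting
  base <- matrix(stats::rnorm(h * w, 0, 1), h, w)
  base <- box_blur(base, 5)
  base <- 0.45 + 0.05 * base / max(abs(base), 1e-8)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  rad <- sqrt(outer(((1:h) - cy)^2, ((1:w) - cx)^2, "+")) / sqrt(cy^2 + cx^2)
  base <- base * (1 - 0.25 * rad^2)

  img <- base + params$vessel_contrast * gt
  if (params$background_noise_sd > 0) {
    img <- img + matrix(stats::rnorm(h * w, 0, params$background_noise_sd), h, w)
  }
  img <- pmin(pmax(img, 0), 1)

  dec <- decompose_by_width(gt, width_threshold)
  list(image = img, gt = gt, thin = dec$thin, thick = dec$thick)
}

# Save/restore the global RNG state so generators are pure functions of
# their seed without disturbing the caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# Separable box blur with edge replication; k = half-width.
box_blur <- function(m, k) {
  h <- nrow(m); w <- ncol(m)
  pad <- function(v, n) c(rep(v[1], n), v, rep(v[length(v)], n))
  blur1 <- function(v) {
    vp <- pad(v, k)
    cs <- cumsum(c(0, vp))
    (cs[(2 * k + 2):(length(vp) + 1)] - cs[1:(length(vp) - 2 * k)]) / (2 * k + 1)
  }
  m <- apply(m, 2, blur1)
  t(apply(m, 1, blur1))
}

#' Decompose a vessel mask by local calibre
#'
#' Skeletonizes the mask, reads the local vessel radius at each skeleton
#' pixel from the Euclidean distance transform, labels a skeleton pixel
#' thin when its estimated full width (2 x radius) does not exceed
#' `width_threshold` and thick otherwise, then assigns every foreground
#' pixel the label of its nearest skeleton pixel. Pixels equidistant to a
#' thin and a thick skeleton pixel go to thick, keeping the partition
#' deterministic.
#'
#' @param gt 0/1 matrix.
#' @param width_threshold positive calibre cut-off in pixels (full width).
#' @return list with 0/1 matrices `thin` and `thick` forming an exact
#'   partition of `gt`.
#' @export
decompose_by_width <- function(gt, width_threshold = 2) {
  if (width_threshold <= 0) stop("width_threshold must be positive", call. = FALSE)
  check_binary(gt, "gt")
  gt <- matrix(as.numeric(gt), nrow(gt), ncol(gt))
  empty <- matrix(0, nrow(gt), ncol(gt))
  if (sum(gt) == 0) return(list(thin = empty, thick = empty))

  skel <- skeletonize(gt)
  # radius at each pixel: distance to the nearest background pixel
  rad <- sqrt(distance_transform_sq(gt == 0))
  thin_skel <- skel == 1 & 2 * rad <= width_threshold
  thick_skel <- skel == 1 & !thin_skel

  d_thin <- distance_transform_sq(thin_skel)
  d_thick <- distance_transform_sq(thick_skel)
  fg <- gt == 1
  thin <- empty; thick <- empty
  is_thin <- fg & (d_thin < d_thick)   # ties -> thick
  thin[is_thin] <- 1
  thick[fg & !is_thin] <- 1
  list(thin = thin, thick = thick)
}
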