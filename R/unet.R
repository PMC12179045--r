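# The U-Net family used for both teachers and student: two same-padded 3x3
# convolutions per block with channel-wise normalization before ReLU, 2x2
# max-pool downsampling, 2x2 stride-2 transposed-convolution upsampling
# with skip concatenation, and a final 1x1 convolution emitting logits.
# The "Lite" variant divides every channel width by width_divisor = 8.

#' U-Net configuration
#'
#' @param in_channels input channels (1 grayscale, 3 RGB).
#' @param out_channels output channels (1 for binary segmentation).
#' @param base_width channels at the first encoder level (64 in the
#'   standard network). Must be divisible by `width_divisor`.
#' @param depth number of pooling stages (4 in the standard network).
#' @param width_divisor positive integer dividing every channel width;
#'   1 gives the standard network, 8 the Lite variant.
#' @param batch_norm whether blocks carry a normalization layer with
#'   affine scale/shift before each activation.
#' @return an object of class `unet_config`.
#' @export
unet_config <- function(in_channels = 1, out_channels = 1, base_width = 64,
                        depth = 4, width_divisor = 1, batch_norm = TRUE) {
  if (depth < 1) stop("depth must be >= 1", call. = FALSE)
  if (width_divisor < 1 || base_width %% width_divisor != 0) {
    stop("base_width must be divisible by width_divisor", call. = FALSE)
  }
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 base_width = as.integer(base_width),
                 depth = as.integer(depth),
                 width_divisor = as.integer(width_divisor),
                 batch_norm = isTRUE(batch_norm)),
            class = "unet_config")
}

# channel widths at encoder levels 1..depth plus the bottleneck
channel_schedule <- function(cfg) {
  cfg$base_width * 2^(0:cfg$depth) / cfg$width_divisor
}

#' Closed-form trainable-parameter count
#'
#' Sums weights and biases of every convolution and transposed convolution
#' plus the per-channel scale/shift of each normalization layer. The count
#' is independent of input size and equals the instantiated network's
#' trainable-parameter total.
#'
#' @param cfg a [unet_config()].
#' @return integer parameter count.
#' @export
count_parameters <- function(cfg) {
  stopifnot(inherits(cfg, "unet_config"))
  ch <- channel_schedule(cfg)
  bn <- function(c) if (cfg$batch_norm) 2 * c else 0
  conv <- function(cin, cout, k = 3) (k * k * cin + 1) * cout
  blk <- function(cin, cout) conv(cin, cout) + bn(cout) + conv(cout, cout) + bn(cout)
  total <- 0
  cin <- cfg$in_channels
  for (c in ch) {            # encoder levels + bottleneck
    total <- total + blk(cin, c)
    cin <- c
  }
  for (c in rev(ch[seq_len(cfg$depth)])) {   # decoder
    total <- total + (4 * (2 * c) + 1) * c   # 2x2 transposed conv with bias
    total <- total + blk(2 * c, c)           # after skip concatenation
  }
  total <- total + conv(ch[1], cfg$out_channels, k = 1)
  as.integer(total)
}

#' Multiply-accumulate count at a given input shape
#'
#' Per layer: `out_H * out_W * C_in * C_out * kernel_area`, summed over all
#' convolution and transposed-convolution layers (pooling, normalization
#' and activations excluded). Linear in the padded pixel count.
#'
#' @param cfg a [unet_config()].
#' @param input_shape integer `(height, width)`, each divisible by
#'   `2^depth`.
#' @return MAC count (numeric; may exceed integer range).
#' @export
count_macs <- function(cfg, input_shape) {
  stopifnot(inherits(cfg, "unet_config"))
  h <- input_shape[1]; w <- input_shape[2]
  if (h %% 2^cfg$depth != 0 || w %% 2^cfg$depth != 0) {
    stop(sprintf("input shape %dx%d not divisible by 2^depth = %d; pad first",
                 h, w, 2^cfg$depth), call. = FALSE)
  }
  ch <- channel_schedule(cfg)
  total <- 0
  cin <- cfg$in_channels
  for (i in seq_along(ch)) {
    total <- total + h * w * 9 * cin * ch[i] + h * w * 9 * ch[i] * ch[i]
    cin <- ch[i]
    if (i <= cfg$depth) { h <- h / 2; w <- w / 2 }
  }
  for (c in rev(ch[seq_len(cfg$depth)])) {
    h <- h * 2; w <- w * 2
    total <- total + h * w * (2 * c) * c * 4          # transposed conv
    total <- total + h * w * 9 * (2 * c) * c + h * w * 9 * c * c
  }
  total + h * w * ch[1] * cfg$out_channels
}

#' Parameter size in megabytes
#'
#' @param param_count parameter count (>= 0).
#' @param bytes_per_param storage bytes per parameter (4 for float32).
#' @return size in MB using 10^6 bytes per MB.
#' @export
parameter_size_mb <- function(param_count, bytes_per_param = 4) {
  if (param_count < 0) stop("param_count must be >= 0", call. = FALSE)
  param_count * bytes_per_param / 1e6
}

#' Accounting report for a set of configurations
#'
#' @param configs named list of [unet_config()] objects.
#' @param input_shape `(height, width)` at which MACs are evaluated.
#' @return data.frame with params (M), MACs (G) and parameter size (MB).
#' @export
accounting_report <- function(configs, input_shape) {
  rows <- lapply(names(configs), function(nm) {
    p <- count_parameters(configs[[nm]])
    data.frame(model = nm,
               params_M = round(p / 1e6, 3),
               flops_G = round(count_macs(configs[[nm]], input_shape) / 1e9, 2),
               size_MB = round(parameter_size_mb(p), 2))
  })
  do.call(rbind, rows)
}

# ---- padding ----

#' Padding specification
#'
#' Zero padding appended on the bottom and right only, following the
#' bottom/right convention used for the public vessel benchmarks.
#'
#' @param pad_bottom,pad_right non-negative pixel counts.
#' @return an object of class `padding_spec`.
#' @export
padding_spec <- function(pad_bottom = 0, pad_right = 0) {
  if (pad_bottom < 0 || pad_right < 0) stop("pads must be >= 0", call. = FALSE)
  structure(list(pad_bottom = as.integer(pad_bottom),
                 pad_right = as.integer(pad_right)),
            class = "padding_spec")
}

#' Per-dataset padding overrides
#'
#' DRIVE (584x565) pads to 592x576, CHASEDB1 (960x999) to 1008x1008,
#' DCA1 (300x300) to 320x320; CHUAC (512x512) needs none.
#'
#' @param name dataset name.
#' @return a `padding_spec`.
#' @export
dataset_padding <- function(name) {
  switch(tolower(name),
         drive = padding_spec(8, 11),
         chasedb1 = padding_spec(48, 9),
         dca1 = padding_spec(20, 20),
         chuac = padding_spec(0, 0),
         stop(sprintf("no padding override for dataset '%s'", name), call. = FALSE))
}

#' Pad an image on the bottom and right
#'
#' @param image matrix or `[H, W, C]` array.
#' @param spec a [padding_spec()], or `"auto16"` to pad each axis to the
#'   next multiple of 16.
#' @return list with the padded `image` and the `spec` used (pass the spec
#'   to [unpad()] to crop back).
#' @export
pad_to_spec <- function(image, spec = "auto16") {
  d <- dim(image)
  h <- d[1]; w <- d[2]
  if (identical(spec, "auto16")) {
    spec <- padding_spec(ceiling(h / 16) * 16 - h, ceiling(w / 16) * 16 - w)
  }
  stopifnot(inherits(spec, "padding_spec"))
  nh <- h + spec$pad_bottom; nw <- w + spec$pad_right
  if (length(d) == 2) {
    out <- matrix(0, nh, nw)
    out[1:h, 1:w] <- image
  } else {
    out <- array(0, c(nh, nw, d[3]))
    out[1:h, 1:w, ] <- image
  }
  list(image = out, spec = spec, orig_shape = c(h, w))
}

#' Crop a padded output back to the original shape
#'
#' @param output matrix or array produced at the padded shape.
#' @param padded the list returned by [pad_to_spec()].
#' @return the output cropped to the original spatial shape.
#' @export
unpad <- function(output, padded) {
  h <- padded$orig_shape[1]; w <- padded$orig_shape[2]
  if (length(dim(output)) == 2) output[1:h, 1:w, drop = FALSE]
  else output[1:h, 1:w, , drop = FALSE]
}

# ---- network construction and differentiation ----

#' Instantiate a U-Net
#'
#' Weights use He-normal initialization from the current RNG stream; seed
#' with `set.seed()` for reproducible builds.
#'
#' @param cfg a [unet_config()].
#' @return an object of class `unet` holding the configuration and the
#'   nested parameter list.
#' @export
build_unet <- function(cfg) {
  stopifnot(inherits(cfg, "unet_config"))
  ch <- channel_schedule(cfg)
  mk_block <- function(cin, cout) {
    b <- list(conv1 = conv3_init(cin, cout))
    if (cfg$batch_norm) b$norm1 <- norm_init(cout)
    b$conv2 <- conv3_init(cout, cout)
    if (cfg$batch_norm) b$norm2 <- norm_init(cout)
    b
  }
  params <- list(enc = list(), bottleneck = NULL, dec = list(), final = NULL)
  cin <- cfg$in_channels
  for (i in seq_len(cfg$depth)) {
    params$enc[[i]] <- mk_block(cin, ch[i])
    cin <- ch[i]
  }
  params$bottleneck <- mk_block(cin, ch[cfg$depth + 1])
  for (i in seq_len(cfg$depth)) {
    lev <- cfg$depth + 1 - i          # decode from the deepest level up
    cdec <- ch[lev]
    params$dec[[i]] <- list(up = tconv_init(2 * cdec, cdec),
                            block = mk_block(2 * cdec, cdec))
  }
  params$final <- conv1_init(ch[1], cfg$out_channels)
  structure(list(config = cfg, params = params), class = "unet")
}

#' Number of trainable parameters of an instantiated network
#' @param net a `unet`.
#' @return integer total over all parameter arrays.
#' @export
n_parameters <- function(net) {
  sum(vapply(flatten_params(net$params), length, integer(1)))
}

block_fwd <- function(p, x) {
  caches <- list()
  r <- conv3_fwd(p$conv1, x); caches$conv1 <- r$cache; x <- r$out
  if (!is.null(p$norm1)) { r <- norm_fwd(p$norm1, x); caches$norm1 <- r$cache; x <- r$out }
  r <- relu_fwd(x); caches$relu1 <- r$cache; x <- r$out
  r <- conv3_fwd(p$conv2, x); caches$conv2 <- r$cache; x <- r$out
  if (!is.null(p$norm2)) { r <- norm_fwd(p$norm2, x); caches$norm2 <- r$cache; x <- r$out }
  r <- relu_fwd(x); caches$relu2 <- r$cache; x <- r$out
  list(out = x, cache = caches)
}

block_bwd <- function(p, cache, dout) {
  g <- list()
  dout <- relu_bwd(cache$relu2, dout)
  if (!is.null(p$norm2)) { r <- norm_bwd(p$norm2, cache$norm2, dout); g$norm2 <- r$grads; dout <- r$dx }
  r <- conv3_bwd(p$conv2, cache$conv2, dout); g$conv2 <- r$grads; dout <- r$dx
  dout <- relu_bwd(cache$relu1, dout)
  if (!is.null(p$norm1)) { r <- norm_bwd(p$norm1, cache$norm1, dout); g$norm1 <- r$grads; dout <- r$dx }
  r <- conv3_bwd(p$conv1, cache$conv1, dout); g$conv1 <- r$grads; dout <- r$dx
  # reorder grads to match parameter creation order
  gg <- list(conv1 = g$conv1)
  if (!is.null(p$norm1)) gg$norm1 <- g$norm1
  gg$conv2 <- g$conv2
  if (!is.null(p$norm2)) gg$norm2 <- g$norm2
  list(grads = gg, dx = dout)
}

#' Forward pass
#'
#' @param net a `unet`.
#' @param x input: matrix or `[H, W, C]` array with spatial dims divisible
#'   by `2^depth`.
#' @param want_cache keep intermediate activations for [unet_backward()].
#' @return with `want_cache = FALSE` (default) the logit map as an
#'   `[H, W, out_channels]` array; otherwise a list `(logits, cache)`.
#' @export
unet_forward <- function(net, x, want_cache = FALSE) {
  cfg <- net$config
  if (is.matrix(x)) x <- array(x, c(dim(x), 1))
  d <- dim(x)
  if (d[1] %% 2^cfg$depth != 0 || d[2] %% 2^cfg$depth != 0) {
    stop(sprintf(paste0("input %dx%d is not divisible by 2^depth = %d; ",
                        "use pad_to_spec() first"), d[1], d[2], 2^cfg$depth),
         call. = FALSE)
  }
  if (d[3] != cfg$in_channels) {
    stop(sprintf("input has %d channels, config expects %d", d[3], cfg$in_channels),
         call. = FALSE)
  }
  p <- net$params
  cache <- list(enc = list(), pool = list(), dec = list())
  skips <- list()
  for (i in seq_len(cfg$depth)) {
    r <- block_fwd(p$enc[[i]], x); cache$enc[[i]] <- r$cache
    skips[[i]] <- r$out
    r <- maxpool_fwd(r$out); cache$pool[[i]] <- r$cache
    x <- r$out
  }
  r <- block_fwd(p$bottleneck, x); cache$bottleneck <- r$cache
  x <- r$out
  for (i in seq_len(cfg$depth)) {
    lev <- cfg$depth + 1 - i
    r <- tconv_fwd(p$dec[[i]]$up, x)
    cache$dec[[i]] <- list(up = r$cache)
    skip <- skips[[lev]]
    x <- array(c(skip, r$out), c(dim(skip)[1], dim(skip)[2],
                                 dim(skip)[3] + dim(r$out)[3]))
    cache$dec[[i]]$nskip <- dim(skip)[3]
    r <- block_fwd(p$dec[[i]]$block, x)
    cache$dec[[i]]$block <- r$cache
    x <- r$out
  }
  r <- conv1_fwd(p$final, x); cache$final <- r$cache
  if (want_cache) list(logits = r$out, cache = cache) else r$out
}

#' Backward pass
#'
#' @param net a `unet`.
#' @param cache the cache from `unet_forward(..., want_cache = TRUE)`.
#' @param dlogits gradient of the scalar loss with respect to the logits.
#' @return nested gradient list matching `net$params`.
#' @export
unet_backward <- function(net, cache, dlogits) {
  cfg <- net$config
  p <- net$params
  if (is.matrix(dlogits)) dlogits <- array(dlogits, c(dim(dlogits), 1))
  g <- list(enc = vector("list", cfg$depth), bottleneck = NULL,
            dec = vector("list", cfg$depth), final = NULL)
  r <- conv1_bwd(p$final, cache$final, dlogits)
  g$final <- r$grads; dx <- r$dx
  dskips <- vector("list", cfg$depth)
  for (i in rev(seq_len(cfg$depth))) {
    lev <- cfg$depth + 1 - i
    r <- block_bwd(p$dec[[i]]$block, cache$dec[[i]]$block, dx)
    gb <- r$grads; dx <- r$dx
    ns <- cache$dec[[i]]$nskip
    dskips[[lev]] <- dx[, , seq_len(ns), drop = FALSE]
    dup <- dx[, , ns + seq_len(dim(dx)[3] - ns), drop = FALSE]
    r <- tconv_bwd(p$dec[[i]]$up, cache$dec[[i]]$up, dup)
    g$dec[[i]] <- list(up = r$grads, block = gb)
    dx <- r$dx
  }
  r <- block_bwd(p$bottleneck, cache$bottleneck, dx)
  g$bottleneck <- r$grads; dx <- r$dx
  for (i in rev(seq_len(cfg$depth))) {
    dx <- maxpool_bwd(cache$pool[[i]], dx)
    dx <- dx + dskips[[i]]
    r <- block_bwd(p$enc[[i]], cache$enc[[i]], dx)
    g$enc[[i]] <- r$grads; dx <- r$dx
  }
  g
}

#' @export
print.unet <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<unet> in=%d out=%d base=%d depth=%d divisor=%d norm=%s  (%s parameters)\n",
              cfg$in_channels, cfg$out_channels, cfg$base_width, cfg$depth,
              cfg$width_divisor, cfg$batch_norm,
              format(n_parameters(x), big.mark = ",")))
  invisible(x)
}
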