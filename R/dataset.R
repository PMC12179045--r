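# On-disk dataset layout:
#   <root>/<split>/images/*.png   grayscale (or RGB) rasters in [0, 1]
#   <root>/<split>/gt/*.png       binary masks {0, 255}
#   <root>/<split>/thin/*.png     binary masks {0, 255}
#   <root>/<split>/thick/*.png    binary masks {0, 255}
#   <root>/manifest.yaml          generation parameters and seeds
# Readers also accept PGM (P2/P5) rasters laid out the same way.

#' Read a raster image as a numeric matrix in [0, 1]
#'
#' Supports PNG (via the png package) and PGM (plain P2 and raw P5).
#' Multi-channel PNGs are converted to luminance.
#'
#' @param path image file path.
#' @return numeric matrix in `[0, 1]`.
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop(sprintf("missing image file: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path)
    if (length(dim(a)) == 3) {
      ch <- dim(a)[3]
      if (ch >= 3) {
        a <- 0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
      } else {
        a <- a[, , 1]
      }
    }
    return(a)
  }
  if (ext == "pgm") return(read_pgm(path))
  stop(sprintf("unsupported raster format '%s' (supported: png, pgm): %s",
               ext, path), call. = FALSE)
}

#' Write a numeric matrix in [0, 1] as an 8-bit grayscale PNG
#' @param img numeric matrix in `[0, 1]`.
#' @param path output path.
#' @export
write_raster <- function(img, path) {
  img <- pmin(pmax(img, 0), 1)
  # quantize to 8 bits so write/read round-trips are exact
  img <- round(img * 255) / 255
  png::writePNG(img, path)
  invisible(path)
}

#' Read/write a binary mask ({0, 255} 8-bit convention on disk)
#' @param path mask file path.
#' @return 0/1 matrix.
#' @export
read_mask <- function(path) {
  m <- read_raster(path)
  out <- matrix(0, nrow(m), ncol(m))
  out[m >= 0.5] <- 1
  out
}

#' @rdname read_mask
#' @param mask 0/1 matrix.
#' @export
write_mask <- function(mask, path) {
  check_binary(mask, "mask")
  write_raster(mask, path)
}

read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2)
  if (!magic %in% c("P2", "P5")) stop("not a PGM file: ", path, call. = FALSE)
  tok <- pgm_tokens(con, 3)
  w <- as.integer(tok[1]); h <- as.integer(tok[2]); mx <- as.numeric(tok[3])
  if (magic == "P5") {
    v <- as.numeric(readBin(con, "integer", n = w * h, size = 1, signed = FALSE))
  } else {
    v <- numeric(0)
    while (length(v) < w * h) {
      ln <- readLines(con, 1)
      if (length(ln) == 0) break
      ln <- sub("#.*", "", ln)
      v <- c(v, as.numeric(strsplit(trimws(ln), "\\s+")[[1]]))
    }
  }
  matrix(v / mx, nrow = h, ncol = w, byrow = TRUE)
}

# read whitespace-separated header tokens, skipping comments
pgm_tokens <- function(con, n) {
  tok <- character(0)
  buf <- ""
  while (length(tok) < n) {
    ch <- readChar(con, 1)
    if (length(ch) == 0 || ch == "") break
    if (ch == "#") { repeat { c2 <- readChar(con, 1); if (c2 %in% c("\n", "")) break } ; ch <- " " }
    if (grepl("\\s", ch)) {
      if (nzchar(buf)) { tok <- c(tok, buf); buf <- "" }
    } else buf <- paste0(buf, ch)
  }
  tok
}

#' Generate a synthetic dataset on disk
#'
#' Writes `n_train + n_val + n_test` scene triplets under `root` using the
#' standard layout, with per-sample seeds derived deterministically from
#' `params$seed` and the split name so splits are disjoint by construction.
#'
#' @param root output directory (created if needed).
#' @param n_train,n_val,n_test non-negative sample counts per split.
#' @param params a [scene_params()] object; its `seed` seeds the whole
#'   dataset.
#' @param width_threshold calibre cut-off passed to [generate_scene()].
#' @return the dataset handle from [load_dataset()].
#' @export
make_dataset <- function(root, n_train, n_val, n_test, params,
                         width_threshold = 2) {
  stopifnot(inherits(params, "scene_params"))
  counts <- c(train = n_train, val = n_val, test = n_test)
  if (any(counts < 0)) stop("split counts must be >= 0", call. = FALSE)
  for (split in names(counts)) {
    for (sub in c("images", "gt", "thin", "thick")) {
      dir.create(file.path(root, split, sub), recursive = TRUE, showWarnings = FALSE)
    }
    n <- counts[[split]]
    if (n == 0) next
    for (i in seq_len(n)) {
      p <- params
      p$seed <- derive_seed(params$seed, paste0(split, "_", i))
      scn <- generate_scene(p, width_threshold)
      id <- sprintf("%s_%03d", split, i)
      write_raster(scn$image, file.path(root, split, "images", paste0(id, ".png")))
      write_mask(scn$gt, file.path(root, split, "gt", paste0(id, ".png")))
      write_mask(scn$thin, file.path(root, split, "thin", paste0(id, ".png")))
      write_mask(scn$thick, file.path(root, split, "thick", paste0(id, ".png")))
    }
  }
  manifest <- list(
    params = unclass(params),
    width_threshold = width_threshold,
    counts = as.list(counts)
  )
  yaml::write_yaml(manifest, file.path(root, "manifest.yaml"))
  load_dataset(root)
}

#' Load a dataset laid out on disk
#'
#' Expects the standard `<root>/<split>/{images,gt,thin,thick}` layout
#' (thin/thick folders optional). Every image must have a ground-truth mask
#' of the same spatial shape; a missing or mismatched mask is an error
#' naming the offending file.
#'
#' @param root dataset directory.
#' @param splits split names to look for.
#' @return an object of class `vessel_dataset`: per split, a list of
#'   samples with elements `id`, `image`, `gt` and (when present) `thin`,
#'   `thick`.
#' @export
load_dataset <- function(root, splits = c("train", "val", "test")) {
  if (!dir.exists(root)) stop(sprintf("dataset root does not exist: %s", root), call. = FALSE)
  out <- list()
  for (split in splits) {
    img_dir <- file.path(root, split, "images")
    samples <- list()
    if (dir.exists(img_dir)) {
      files <- sort(list.files(img_dir, pattern = "\\.(png|pgm)$", ignore.case = TRUE))
      for (f in files) {
        id <- tools::file_path_sans_ext(f)
        img <- read_raster(file.path(img_dir, f))
        smp <- list(id = id, image = img)
        for (m in c("gt", "thin", "thick")) {
          mp <- mask_path(file.path(root, split, m), id)
          if (is.null(mp)) {
            if (m == "gt") {
              stop(sprintf("missing ground-truth mask for %s (expected under %s)",
                           f, file.path(root, split, m)), call. = FALSE)
            }
            next
          }
          msk <- read_mask(mp)
          check_same_shape(img, msk, sprintf("image %s and its %s mask", f, m))
          smp[[m]] <- msk
        }
        samples[[id]] <- smp
      }
    }
    out[[split]] <- samples
  }
  structure(list(root = root, splits = out), class = "vessel_dataset")
}

mask_path <- function(dir, id) {
  for (ext in c(".png", ".pgm")) {
    p <- file.path(dir, paste0(id, ext))
    if (file.exists(p)) return(p)
  }
  NULL
}

#' @export
print.vessel_dataset <- function(x, ...) {
  cat("<vessel_dataset>", x$root, "\n")
  for (s in names(x$splits)) {
    cat(sprintf("  %-5s %d samples\n", s, length(x$splits[[s]])))
  }
  invisible(x)
}

#' Load a real dataset with the split conventions of the four public
#' vessel benchmarks
#'
#' For a known `name` (`drive`, `chasedb1`, `chuac`, `dca1`) images found
#' under `root/{images,gt,thin,thick}` are ordered by filename and split
#' into the conventional train/val/test counts (DRIVE 18/2/20,
#' CHASEDB1 18/2/8, CHUAC 16/4/10, DCA1 80/20/34). Otherwise `root` must
#' already use the `<split>/` layout.
#'
#' @param root dataset directory.
#' @param name optional benchmark name controlling the split.
#' @return a `vessel_dataset`.
#' @export
load_real_dataset <- function(root, name = NULL) {
  if (is.null(name)) return(load_dataset(root))
  name <- tolower(name)
  conv <- list(drive = c(18, 2, 20), chasedb1 = c(18, 2, 8),
               chuac = c(16, 4, 10), dca1 = c(80, 20, 34))
  if (!name %in% names(conv)) {
    stop(sprintf("unknown dataset name '%s' (known: %s)", name,
                 paste(names(conv), collapse = ", ")), call. = FALSE)
  }
  img_dir <- file.path(root, "images")
  if (!dir.exists(img_dir)) stop(sprintf("missing images folder under %s", root), call. = FALSE)
  files <- sort(list.files(img_dir, pattern = "\\.(png|pgm)$", ignore.case = TRUE))
  n <- conv[[name]]
  if (length(files) < sum(n)) {
    stop(sprintf("%s layout expects %d images, found %d", name, sum(n), length(files)),
         call. = FALSE)
  }
  idx <- list(train = seq_len(n[1]), val = n[1] + seq_len(n[2]),
              test = n[1] + n[2] + seq_len(n[3]))
  splits <- list()
  for (s in names(idx)) {
    samples <- list()
    for (f in files[idx[[s]]]) {
      id <- tools::file_path_sans_ext(f)
      img <- read_raster(file.path(img_dir, f))
      smp <- list(id = id, image = img)
      for (m in c("gt", "thin", "thick")) {
        mp <- mask_path(file.path(root, m), id)
        if (is.null(mp)) {
          if (m == "gt") stop(sprintf("missing ground-truth mask for %s", f), call. = FALSE)
          next
        }
        msk <- read_mask(mp)
        check_same_shape(img, msk, sprintf("image %s and its %s mask", f, m))
        smp[[m]] <- msk
      }
      samples[[id]] <- smp
    }
    splits[[s]] <- samples
  }
  structure(list(root = root, splits = splits), class = "vessel_dataset")
}
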