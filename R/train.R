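# Training pipeline. Teachers are plain supervised U-Nets, one per ground
# truth variant (original / thick / thin). The student minimizes the
# weighted sum of the mean per-teacher distillation loss and a hard-label
# loss against the original ground truth. One shared loop drives both: a
# teacher is simply a run with no teachers and alpha = 0, which also makes
# the alpha = 0 student trajectory bit-identical to supervised training.

#' Training configuration
#'
#' Adam with learning rate 1e-3, batch size 8, 250 epochs, no early
#' stopping; after every epoch the model is scored on the validation split
#' and the weights with minimum validation loss are retained.
#'
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size (>= 1).
#' @param epochs training epochs (>= 1).
#' @param seed integer seed driving weight initialization and shuffling.
#' @param spec padding passed to [pad_to_spec()] for every sample.
#' @param verbose print one line per epoch.
#' @return an object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, batch_size = 8, epochs = 250,
                         seed = 1L, spec = "auto16", verbose = FALSE) {
  if (epochs < 1) stop("epochs must be >= 1", call. = FALSE)
  if (batch_size < 1) stop("batch_size must be >= 1", call. = FALSE)
  structure(list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 spec = spec, verbose = isTRUE(verbose)),
            class = "train_config")
}

role_target <- function(role) {
  switch(role, original = "gt", thick = "thick", thin = "thin",
         stop(sprintf("unknown teacher role '%s'", role), call. = FALSE))
}

# Pad every sample once up front; returns list of (x [H,W,C], y matrix).
prep_samples <- function(samples, target, cfg, spec) {
  lapply(samples, function(smp) {
    y <- smp[[target]]
    if (is.null(y)) {
      stop(sprintf("sample %s lacks the '%s' mask required for this role",
                   smp$id, target), call. = FALSE)
    }
    pad <- pad_to_spec(smp$image, spec)
    ypad <- pad_to_spec(y, pad$spec)
    x <- pad$image
    if (is.matrix(x)) x <- array(x, c(dim(x), 1))
    if (dim(x)[3] != cfg$in_channels) {
      stop(sprintf("sample %s has %d channels, config expects %d",
                   smp$id, dim(x)[3], cfg$in_channels), call. = FALSE)
    }
    list(x = x, y = ypad$image)
  })
}

# Loss and student-logit gradient for one sample under the full objective.
# z_teachers: list of precomputed logit maps from the frozen teachers
# (teachers never move and there is no augmentation, so computing their
# logits once per sample is exact).
sample_loss_grad <- function(net, x, y, hard, dcfg, z_teachers, want_grad = TRUE) {
  fwd <- unet_forward(net, x, want_cache = want_grad)
  z <- if (want_grad) fwd$logits[, , 1] else fwd[, , 1]
  p <- sigmoid(z)
  hard_val <- hard$fn(p, y)
  per_teacher <- NULL
  avg <- 0
  dz <- NULL
  if (length(z_teachers) > 0 && dcfg$alpha > 0) {
    per_teacher <- numeric(length(z_teachers))
    dsum <- 0
    for (k in seq_along(z_teachers)) {
      zt <- z_teachers[[k]]
      per_teacher[k] <- distillation_loss(zt, z, dcfg)
      if (want_grad) dsum <- dsum + distillation_grad(zt, z, dcfg)
    }
    avg <- avg_distillation_loss(per_teacher)
    if (want_grad) dz <- dcfg$alpha * dsum / length(z_teachers)
  }
  bd <- total_student_loss(avg, hard_val, dcfg, per_teacher)
  if (want_grad) {
    dhard_dz <- hard$grad(p, y) * p * (1 - p)
    dz <- (dz %||% 0) + (1 - dcfg$alpha) * dcfg$penalty * dhard_dz
    grads <- unet_backward(net, fwd$cache, dz)
    list(breakdown = bd, grads = grads)
  } else {
    list(breakdown = bd)
  }
}

# The shared training loop.
train_loop <- function(dataset, target, unet_cfg, train_cfg, dcfg,
                       teachers = list()) {
  tr <- dataset$splits$train
  va <- dataset$splits$val
  if (length(tr) == 0) stop("empty training split", call. = FALSE)
  if (length(va) == 0) stop("empty validation split", call. = FALSE)
  hard <- make_loss(dcfg$hard_loss)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(train_cfg$seed)

  net <- build_unet(unet_cfg)
  flat <- flatten_params(net$params)
  opt <- adam_init(flat)

  trs <- prep_samples(tr, target, unet_cfg, train_cfg$spec)
  vas <- prep_samples(va, target, unet_cfg, train_cfg$spec)

  # frozen-teacher soft targets, computed once per sample
  teacher_logits <- function(s) {
    lapply(teachers, function(t) unet_forward(t$net, s$x)[, , 1])
  }
  if (length(teachers) > 0 && dcfg$alpha > 0) {
    ztr <- lapply(trs, teacher_logits)
    zva <- lapply(vas, teacher_logits)
  } else {
    ztr <- rep(list(list()), length(trs))
    zva <- rep(list(list()), length(vas))
  }

  best_val <- Inf
  best_flat <- flat
  history <- data.frame()
  n <- length(trs)
  for (epoch in seq_len(train_cfg$epochs)) {
    ord <- sample(n)
    batches <- split(ord, ceiling(seq_along(ord) / train_cfg$batch_size))
    ep_loss <- 0
    for (b in batches) {
      gacc <- NULL
      bloss <- 0
      for (i in b) {
        r <- sample_loss_grad(net, trs[[i]]$x, trs[[i]]$y, hard, dcfg, ztr[[i]])
        bloss <- bloss + r$breakdown$total
        gflat <- flatten_params(r$grads)
        gacc <- if (is.null(gacc)) gflat else Map(`+`, gacc, gflat)
      }
      gacc <- lapply(gacc, function(g) g / length(b))
      st <- adam_step(flat, gacc, opt, lr = train_cfg$learning_rate)
      flat <- st$params; opt <- st$state
      net$params <- unflatten_params(net$params, flat)
      ep_loss <- ep_loss + bloss
    }
    val_loss <- mean(vapply(seq_along(vas), function(i) {
      sample_loss_grad(net, vas[[i]]$x, vas[[i]]$y, hard, dcfg, zva[[i]],
                       want_grad = FALSE)$breakdown$total
    }, numeric(1)))
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = ep_loss / n,
                                         val_loss = val_loss))
    if (val_loss < best_val) {
      best_val <- val_loss
      best_flat <- flat
    }
    if (train_cfg$verbose) {
      message(sprintf("epoch %3d  train %.4f  val %.4f", epoch,
                      ep_loss / n, val_loss))
    }
  }
  net$params <- unflatten_params(net$params, best_flat)
  list(net = net, best_val = best_val, history = history)
}

#' Train a specialist teacher
#'
#' Supervised training of a U-Net on the mask variant matching `role`
#' (`"original"` -> full ground truth, `"thick"`, `"thin"`), with the
#' configured hard loss (default DiceBCELoss) and best-by-validation-loss
#' checkpointing.
#'
#' @param role `"original"`, `"thick"` or `"thin"`.
#' @param dataset a `vessel_dataset` with train and val splits carrying the
#'   mask folder for the role.
#' @param unet_cfg a [unet_config()].
#' @param train_cfg a [train_config()].
#' @param hard_loss a [loss_config()] for the supervised loss.
#' @return a `teacher_spec` list: `role`, `net`, `best_val`, `history`.
#' @export
train_teacher <- function(role, dataset, unet_cfg, train_cfg,
                          hard_loss = loss_config("DiceBCELoss")) {
  target <- role_target(role)
  dcfg <- distill_config(alpha = 0, penalty = 1, hard_loss = hard_loss,
                         teacher_roles = role)
  fit <- train_loop(dataset, target, unet_cfg, train_cfg, dcfg, teachers = list())
  structure(list(role = role, net = fit$net, best_val = fit$best_val,
                 history = fit$history), class = "teacher_spec")
}

#' Train a student by multi-teacher distillation
#'
#' Each step computes the per-teacher distillation losses, their mean, the
#' hard loss against the original ground truth, and the total
#' `alpha * avg + (1 - alpha) * penalty * hard`. Teachers stay frozen in
#' inference mode; the checkpoint with the lowest validation total loss is
#' returned. With `alpha = 0` the trajectory is identical to plain
#' supervised training with the same seed.
#'
#' @param teachers list of `teacher_spec` objects (length >= 1).
#' @param dataset a `vessel_dataset`.
#' @param unet_cfg student [unet_config()].
#' @param train_cfg a [train_config()].
#' @param distill_cfg a [distill_config()].
#' @return list: `net`, `best_val`, `history`, `teachers` (roles used).
#' @export
train_student <- function(teachers, dataset, unet_cfg, train_cfg,
                          distill_cfg = distill_config()) {
  if (distill_cfg$alpha > 0 && length(teachers) < 1) {
    stop("need at least one trained teacher (or set alpha = 0)", call. = FALSE)
  }
  for (t in teachers) stopifnot(inherits(t, "teacher_spec"))
  fit <- train_loop(dataset, "gt", unet_cfg, train_cfg, distill_cfg, teachers)
  list(net = fit$net, best_val = fit$best_val, history = fit$history,
       teachers = vapply(teachers, function(t) t$role, character(1)))
}

#' Save / load a checkpoint
#'
#' Checkpoints carry the weights together with the network configuration.
#'
#' @param net a `unet` (or `teacher_spec`).
#' @param path file path (`.rds`).
#' @export
save_checkpoint <- function(net, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(net, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("checkpoint not found: %s (train a model first)", path),
         call. = FALSE)
  }
  readRDS(path)
}

#' Ablation sweep
#'
#' Trains and evaluates one student per grid point, holding everything else
#' (including the seed) fixed, and returns one row per point.
#'
#' @param kind `"temperature"`, `"penalty"`, `"loss"`, `"teachers"` or
#'   `"lite"`.
#' @param grid vector/list of grid values: numbers for temperature and
#'   penalty, loss names for loss, character vectors of roles for teachers,
#'   width divisors for lite.
#' @param base list with `dataset`, `teachers`, `unet_cfg`, `train_cfg`,
#'   `distill_cfg`.
#' @param target evaluation target mask.
#' @return data.frame: kind, value, best_val and test metrics (percent).
#' @export
run_sweep <- function(kind, grid, base, target = "gt") {
  kinds <- c("temperature", "penalty", "loss", "teachers", "lite")
  if (!kind %in% kinds) {
    stop(sprintf("unknown sweep kind '%s' (valid: %s)", kind,
                 paste(kinds, collapse = ", ")), call. = FALSE)
  }
  if (length(grid) == 0) stop("empty sweep grid", call. = FALSE)
  rows <- list()
  for (i in seq_along(grid)) {
    g <- if (is.list(grid)) grid[[i]] else grid[i]
    dcfg <- base$distill_cfg
    ucfg <- base$unet_cfg
    teachers <- base$teachers
    label <- as.character(paste(g, collapse = "+"))
    if (kind == "temperature") dcfg$temperature <- g
    if (kind == "penalty") dcfg$penalty <- g
    if (kind == "loss") dcfg$hard_loss <- if (is.character(g)) loss_config(g) else g
    if (kind == "teachers") {
      roles <- vapply(teachers, function(t) t$role, character(1))
      teachers <- teachers[roles %in% g]
      if (length(teachers) == 0) stop("no teacher matches roles in grid point", call. = FALSE)
    }
    if (kind == "lite") {
      ucfg$width_divisor <- as.integer(g)
      if (ucfg$base_width %% ucfg$width_divisor != 0) {
        stop("base_width not divisible by sweep divisor", call. = FALSE)
      }
    }
    fit <- train_student(teachers, base$dataset, ucfg, base$train_cfg, dcfg)
    ev <- evaluate_set(fit$net, base$dataset$splits$test, target = target,
                       spec = base$train_cfg$spec)
    rows[[i]] <- data.frame(kind = kind, value = label,
                            best_val = fit$best_val,
                            t(round(ev$metrics * 100, 2)))
  }
  do.call(rbind, rows)
}
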