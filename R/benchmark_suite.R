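# The packaged desk-scale benchmark: a small, easy synthetic regime
# (64x64, high vessel contrast, no background noise) on which teachers
# train to high F1 within ~30 epochs on a CPU, and on which the
# multi-teacher student can be compared against single-teacher students.
# All sizes are fixed here so tests, the acceptance script and the README
# exercise one and the same world.

#' Desk-scale benchmark definitions
#'
#' `desk_scene_params()` fixes the easy synthetic regime; `desk_dataset()`
#' materializes its 6/2/4 train/val/test split on disk;
#' `desk_unet_config()` and `desk_train_config()` fix the small network
#' (base width 8, depth 2) and the short training schedule (30 epochs,
#' batch 4, Adam 1e-3) used at this scale.
#'
#' @param seed integer seed.
#' @return the respective configuration object.
#' @export
desk_scene_params <- function(seed = 1L) {
  scene_params(image_height = 64, image_width = 64, n_trees = 2,
               branch_depth = 3, vessel_contrast = 0.7,
               background_noise_sd = 0, seed = seed)
}

#' @rdname desk_scene_params
#' @param root output directory.
#' @export
desk_dataset <- function(root, seed = 1L) {
  make_dataset(root, n_train = 6, n_val = 2, n_test = 4,
               desk_scene_params(seed))
}

#' @rdname desk_scene_params
#' @export
desk_unet_config <- function() {
  unet_config(in_channels = 1, out_channels = 1, base_width = 8, depth = 2)
}

#' @rdname desk_scene_params
#' @param epochs training epochs.
#' @export
desk_train_config <- function(seed = 1L, epochs = 30) {
  train_config(learning_rate = 1e-3, batch_size = 4, epochs = epochs,
               seed = seed)
}

#' Run the desk-scale distillation benchmark
#'
#' For one seed: generates the benchmark dataset, trains the three
#' specialist teachers, distills one student per single teacher and one
#' from all three, and evaluates everything on the test split against the
#' full ground truth.
#'
#' @param seed integer seed driving data generation and every training run.
#' @param root dataset directory (a fresh temporary directory by default).
#' @param epochs training epochs for teachers and students.
#' @param distill_cfg a [distill_config()] shared by all students.
#' @return list with `teacher_val_f1` (validation F1 of each teacher
#'   against its own target), `student_f1` (named test F1 of students
#'   `T1`, `T2`, `T3`, `multi`), and the fitted objects.
#' @export
run_desk_benchmark <- function(seed = 1L, root = tempfile("deskbench"),
                               epochs = 30,
                               distill_cfg = distill_config()) {
  ds <- desk_dataset(root, seed)
  ucfg <- desk_unet_config()
  tcfg <- desk_train_config(seed, epochs)

  roles <- c(original = "T1", thick = "T2", thin = "T3")
  teachers <- list()
  teacher_val_f1 <- numeric(0)
  for (role in names(roles)) {
    tch <- train_teacher(role, ds, ucfg, tcfg)
    ev <- evaluate_set(tch$net, ds$splits$val, target = role_target(role))
    teachers[[role]] <- tch
    teacher_val_f1[[roles[[role]]]] <- ev$metrics[["F1"]]
  }

  student_f1 <- numeric(0)
  students <- list()
  for (role in names(roles)) {
    fit <- train_student(teachers[role], ds, ucfg, tcfg, distill_cfg)
    ev <- evaluate_set(fit$net, ds$splits$test, target = "gt")
    student_f1[[paste0(roles[[role]], "+S")]] <- ev$metrics[["F1"]]
    students[[roles[[role]]]] <- fit
  }
  fit <- train_student(teachers, ds, ucfg, tcfg, distill_cfg)
  ev <- evaluate_set(fit$net, ds$splits$test, target = "gt")
  student_f1[["multi"]] <- ev$metrics[["F1"]]
  students[["multi"]] <- fit

  list(teacher_val_f1 = teacher_val_f1, student_f1 = student_f1,
       teachers = teachers, students = students, dataset = ds)
}
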