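# Response-based multi-teacher distillation mathematics. Teacher logits are
# temperature-softened through the sigmoid, both probability maps are
# clamped away from {0, 1}, their per-pixel binary KL divergence is averaged
# over pixels to give one scalar per teacher, the per-teacher scalars are
# averaged, and the total student objective mixes that average with a
# (optionally penalized) hard-label loss.

#' Distillation configuration
#'
#' @param temperature softening temperature `T > 0` applied to teacher
#'   logits (default 3, the value that consistently balances soft-label
#'   transfer and student learning).
#' @param alpha weight of the distillation term in `[0, 1]` (default 0.5,
#'   equal weighting of distillation and hard-label terms).
#' @param epsilon probability clamp in `(0, 0.5)` (default `1e-7`).
#' @param penalty multiplier `>= 1` on the hard-label loss term
#'   (default 1 = off; 5-20 in the penalized variant).
#' @param hard_loss a [loss_config()] for the hard-label slot (default
#'   DiceBCELoss).
#' @param teacher_roles subset of `c("original", "thick", "thin")`.
#' @param scale_student if `TRUE`, the student logits are also divided by
#'   the temperature (conventional distillation); the default `FALSE`
#'   softens teacher logits only.
#' @return an object of class `distill_config`.
#' @export
distill_config <- function(temperature = 3, alpha = 0.5, epsilon = 1e-7,
                           penalty = 1, hard_loss = loss_config("DiceBCELoss"),
                           teacher_roles = c("original", "thick", "thin"),
                           scale_student = FALSE) {
  if (temperature <= 0) stop("temperature must be > 0", call. = FALSE)
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]", call. = FALSE)
  if (epsilon <= 0 || epsilon >= 0.5) stop("epsilon must lie in (0, 0.5)", call. = FALSE)
  if (penalty < 1) stop("penalty must be >= 1", call. = FALSE)
  if (is.character(hard_loss)) hard_loss <- loss_config(hard_loss)
  stopifnot(inherits(hard_loss, "loss_config"))
  if (length(teacher_roles) < 1) stop("need at least one teacher role", call. = FALSE)
  teacher_roles <- match.arg(teacher_roles, c("original", "thick", "thin"),
                             several.ok = TRUE)
  structure(list(temperature = temperature, alpha = alpha, epsilon = epsilon,
                 penalty = penalty, hard_loss = hard_loss,
                 teacher_roles = teacher_roles,
                 scale_student = isTRUE(scale_student)),
            class = "distill_config")
}

#' Temperature-soften logits into probabilities
#'
#' Teacher logits are divided by the temperature before the sigmoid;
#' student logits pass through the plain sigmoid (teacher-only softening).
#'
#' @param z logit map.
#' @param temperature `T > 0`.
#' @param scale `"teacher"` (apply `T`) or `"student"` (no `T`).
#' @return probability map in `(0, 1)`.
#' @export
soften <- function(z, temperature, scale = c("teacher", "student")) {
  scale <- match.arg(scale)
  if (temperature <= 0) stop("temperature must be > 0", call. = FALSE)
  if (scale == "teacher") sigmoid(z / temperature) else sigmoid(z)
}

#' Clamp probabilities away from 0 and 1
#'
#' @param p probability map.
#' @param eps clamp in `(0, 0.5)`; every value is forced into
#'   `[eps, 1 - eps]`.
#' @return clamped map.
#' @export
clamp_probs <- function(p, eps = 1e-7) {
  pmin(pmax(p, eps), 1 - eps)
}

#' Per-pixel binary Kullback-Leibler divergence
#'
#' `p_t log(p_t / p_s) + (1 - p_t) log((1 - p_t) / (1 - p_s))` (natural
#' log), computed pixel-wise. Both maps must already be clamped.
#'
#' @param p_teacher,p_student probability maps of identical shape.
#' @return per-pixel divergence map (nats).
#' @export
kl_binary <- function(p_teacher, p_student) {
  check_same_shape(p_teacher, p_student, "teacher and student maps")
  p_teacher * log(p_teacher / p_student) +
    (1 - p_teacher) * log((1 - p_teacher) / (1 - p_student))
}

#' Distillation loss for one teacher
#'
#' Mean over all pixels of the binary KL divergence between the clamped,
#' temperature-softened teacher probabilities and the student
#' probabilities.
#'
#' @param z_teacher,z_student logit maps of identical shape.
#' @param cfg a [distill_config()].
#' @return non-negative scalar (nats per pixel).
#' @export
distillation_loss <- function(z_teacher, z_student, cfg = distill_config()) {
  check_same_shape(z_teacher, z_student, "teacher and student logits")
  p_t <- clamp_probs(soften(z_teacher, cfg$temperature, "teacher"), cfg$epsilon)
  p_s <- if (cfg$scale_student) {
    clamp_probs(soften(z_student, cfg$temperature, "teacher"), cfg$epsilon)
  } else {
    clamp_probs(soften(z_student, cfg$temperature, "student"), cfg$epsilon)
  }
  mean(kl_binary(p_t, p_s))
}

# Gradient of distillation_loss with respect to the student logits. The
# clamp is treated as pass-through (its measure-zero kinks are irrelevant
# at the default epsilon), giving the classic (p_s - p_t) / n form; when
# the student is also temperature-scaled the chain rule contributes 1/T.
distillation_grad <- function(z_teacher, z_student, cfg = distill_config()) {
  p_t <- clamp_probs(soften(z_teacher, cfg$temperature, "teacher"), cfg$epsilon)
  if (cfg$scale_student) {
    p_s <- sigmoid(z_student / cfg$temperature)
    (p_s - p_t) / (length(z_student) * cfg$temperature)
  } else {
    p_s <- sigmoid(z_student)
    (p_s - p_t) / length(z_student)
  }
}

#' Average distillation loss across teachers
#'
#' @param losses numeric vector of per-teacher scalar losses (length >= 1).
#' @return their arithmetic mean.
#' @export
avg_distillation_loss <- function(losses) {
  if (length(losses) < 1) stop("need at least one teacher loss", call. = FALSE)
  mean(losses)
}

#' Total student loss
#'
#' `alpha * avg_distillation + (1 - alpha) * penalty * hard`: the penalty
#' multiplies only the hard-label term, emphasizing ground-truth fidelity.
#'
#' @param avg_distillation scalar mean distillation loss.
#' @param hard scalar hard-label loss.
#' @param cfg a [distill_config()].
#' @param per_teacher optional vector of per-teacher losses to carry in
#'   the breakdown.
#' @return a `distill_breakdown` list with `per_teacher`, `average`,
#'   `hard`, `total`.
#' @export
total_student_loss <- function(avg_distillation, hard, cfg = distill_config(),
                               per_teacher = NULL) {
  stopifnot(is.finite(avg_distillation), is.finite(hard))
  total <- cfg$alpha * avg_distillation + (1 - cfg$alpha) * cfg$penalty * hard
  structure(list(per_teacher = per_teacher, average = avg_distillation,
                 hard = hard, total = total), class = "distill_breakdown")
}
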