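#' @keywords internal
#' @useDynLib vesselkd, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

# Numerical helpers shared across modules. Probability clamping lives in
# distill.R because its epsilon is part of the distillation contract.

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Stop unless masks/maps share a spatial shape
#' @noRd
check_same_shape <- function(a, b, what = "inputs") {
  da <- dim(a) %||% length(a)
  db <- dim(b) %||% length(b)
  if (!identical(as.integer(da), as.integer(db))) {
    stop(sprintf("shape mismatch between %s: %s vs %s", what,
                 paste(da, collapse = "x"), paste(db, collapse = "x")),
         call. = FALSE)
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_binary <- function(x, what = "mask") {
  v <- unique(as.vector(x))
  if (!all(v %in% c(0, 1))) {
    stop(sprintf("%s must be binary (0/1); found other values", what),
         call. = FALSE)
  }
  invisible(TRUE)
}

# Derive a child seed from a parent seed and a label, staying within the
# 32-bit signed integer range R requires for set.seed().
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483587L) + 1L
}
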