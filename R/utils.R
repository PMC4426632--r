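`%||%` <- function(x, y) if (is.null(x)) y else x

stop2 <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "pollscape_error")))
}

warn2 <- function(..., class) {
  warning(warningCondition(paste0(...), class = c(class, "pollscape_warning")))
}

assert_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x > max) {
    stop2(sprintf("`%s` must be a finite number in [%s, %s]", name, min, max),
          class = "pollscape_domain_error")
  }
  invisible(x)
}

#' Derive a reproducible child seed from a master seed
#'
#' Stages of the pipeline draw their own random numbers; to keep every stage
#' individually re-runnable each one receives a seed derived deterministically
#' from the master seed and a stage label. Derived seeds stay below 2^31.
#'
#' @param seed master integer seed.
#' @param label character stage label.
#' @return an integer seed.
#' @keywords internal
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h * 2654435) %% 2147483629) + 1L
}
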