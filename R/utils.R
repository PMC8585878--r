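`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child seed from a root seed
#'
#' All stochastic stages draw their seed from one root seed plus a fixed
#' per-stage offset, so an entire run is a pure function of the root seed
#' while stages remain individually reproducible.
#'
#' @param seed Integer root seed.
#' @param offset Integer stage offset.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) %% 2147483647 * 48271 + offset) %% 2147483647)
}

stop_if_not_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a single number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  }
  invisible(x)
}

# sample SD / mean; the denominator guard mirrors gaze_cv()
cv_of <- function(x) sd(x) / mean(x)
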