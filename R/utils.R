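# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_seizdg <- function(..., class) {
  stop(structure(
    class = c(class, "seizdg_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

assert_finite <- function(x, what = "input") {
  if (!all(is.finite(x))) {
    stop_seizdg(what, " contains non-finite values (NaN/Inf)",
                class = "seizdg_validation_error")
  }
  invisible(x)
}

#' Derive a named sub-seed from a master seed
#'
#' Deterministically fans one master seed out into independent named
#' substreams (parameter init, cohort structure, noise, ...) while keeping
#' every derived seed inside the 32-bit integer range.
#'
#' @param seed master seed (integer).
#' @param stream character stream name.
#' @return an integer seed.
#' @keywords internal
derive_seed <- function(seed, stream) {
  codes <- utf8ToInt(stream)
  h <- sum(codes * seq_along(codes))
  as.integer((as.numeric(seed) %% 100003) * 21001 + (h %% 9973) * 101)
}
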