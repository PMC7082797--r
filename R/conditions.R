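#' @title Classed error conditions
#' @description Internal helper raising classed conditions so callers can
#'   `tryCatch()` on specific failure modes (e.g. `AlphabetError`,
#'   `KeyParseError`).
#' @noRd
rflpStop <- function(class, msg, ...) {
  stop(structure(
    list(message = msg, call = sys.call(-1), ...),
    class = c(class, "rflpError", "error", "condition")
  ))
}
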