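# internal helpers: classed error conditions and numeric utilities

# All user-facing validation failures raise classed conditions so callers (and
# the CLI) can distinguish bad input (exit 2) from I/O failure (exit 3).
.segStop <- function(subclass, msg, category = "validation", call. = FALSE) {
  stop(errorCondition(
    msg,
    class = c(paste0("segatlas_", subclass),
              paste0("segatlas_", category),
              "segatlas_error")
  ))
}

# round half away from zero, so channel midpoints (127.5) land on 128
# reproducibly; base round() is banker's rounding.
.roundHalfAway <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

.assertScalarString <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x))
    .segStop("badArgument", sprintf("'%s' must be a single non-empty string", what))
  invisible(x)
}

#' Validate a view mode
#'
#' Expression values can be rendered in one of two view modes: `"normalized"`
#' (per-gene min-max scaling across segments, emphasising the spatial pattern)
#' or `"absolute"` (scaling against a dataset-wide range, preserving cross-gene
#' magnitude differences).
#'
#' @param mode Character scalar, `"normalized"` or `"absolute"`.
#' @return The validated mode string.
#' @examples
#' viewMode("normalized")
#' @export
viewMode <- function(mode = c("normalized", "absolute")) {
  if (length(mode) == 1L && !mode %in% c("normalized", "absolute"))
    .segStop("badViewMode",
             sprintf("view mode must be 'normalized' or 'absolute', got '%s'", mode))
  match.arg(mode)
}

# min-max scale to [0,1]; constant vectors map to 0.5 (flagged by caller)
.minMax <- function(v) {
  rng <- range(v)
  if (rng[1] == rng[2]) return(rep(0.5, length(v)))
  (v - rng[1]) / (rng[2] - rng[1])
}

.isConstant <- function(v) {
  max(v) == min(v)
}
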