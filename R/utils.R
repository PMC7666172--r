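# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_if <- function(cond, msg) {
  if (isTRUE(cond)) stop(msg, call. = FALSE)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' @importFrom rlang .data
NULL

# Wrap ZT hours into [0, 24).
wrap_zt <- function(zt) zt %% 24

# Hours covered by a ZT window [from, to); windows crossing ZT 24 allowed.
zt_in_window <- function(zt, from, to) {
  zt <- wrap_zt(zt)
  from <- wrap_zt(from)
  to <- wrap_zt(to)
  if (from < to) zt >= from & zt < to else zt >= from | zt < to
}
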