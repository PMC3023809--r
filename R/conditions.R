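# Structured error conditions. Every user-facing failure carries a subclass
# (atk_validation, atk_not_found, ...) so callers and the CLI can map errors
# to distinct exit codes without parsing messages.

atkStop <- function(class, fmt, ...) {
  msg <- if (length(list(...))) sprintf(fmt, ...) else fmt
  stop(structure(
    class = c(paste0("atk_", class), "atkError", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Map an atlaskit error condition to a CLI exit code
#'
#' @param cond a condition object.
#' @return integer exit code; 1 for errors with no specific class.
#' @keywords internal
atkExitCode <- function(cond) {
  codes <- c(
    atk_validation = 2L, atk_config = 2L, atk_key = 2L,
    atk_not_found = 3L, atk_format = 4L, atk_bounds = 5L,
    atk_state = 6L, atk_singular = 6L, atk_degenerate = 6L,
    atk_backend = 7L, atk_registration = 7L, atk_io = 8L
  )
  hit <- intersect(names(codes), class(cond))
  if (length(hit)) codes[[hit[1L]]] else 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
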