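# Condition classes used across the package. Three families map onto the
# distinct CLI exit codes: I/O (missing/unwritable files), validation (bad
# user data), contract (programming errors / violated preconditions).

ousio_error <- function(message, class, ..., call = sys.call(-1)) {
  structure(
    class = c(class, "ousio_error", "error", "condition"),
    list(message = message, call = call, ...)
  )
}

stop_io <- function(message, ...) {
  stop(ousio_error(message, "ousio_io_error", ...))
}

stop_validation <- function(message, ...) {
  stop(ousio_error(message, "ousio_validation_error", ...))
}

stop_contract <- function(message, ...) {
  stop(ousio_error(message, "ousio_contract_error", ...))
}

#' Exit codes used by the command-line interface
#'
#' A named integer vector mapping error families to stable process exit
#' codes: `ok` (0), `io` (10), `validation` (11), `contract` (12),
#' `other` (13).
#'
#' @return Named integer vector.
#' @export
#' @examples
#' ousio_exit_codes()["io"]
ousio_exit_codes <- function() {
  c(ok = 0L, io = 10L, validation = 11L, contract = 12L, other = 13L)
}
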