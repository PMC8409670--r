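# Typed error conditions. Model-fitting failures carry a reason drawn from a
# fixed vocabulary so callers (select_ggmm, the CLI) can record them as
# failure records instead of crashing a whole model-selection sweep.

FAILURE_REASONS <- c("not_positive_definite", "empty_component", "no_convergence")

#' Signal a model-fitting failure
#'
#' @param reason one of `"not_positive_definite"`, `"empty_component"`,
#'   `"no_convergence"`.
#' @param detail human-readable diagnostic.
#' @param K component count being attempted, if known.
#' @keywords internal
#' @noRd
ggmm_fail <- function(reason, detail, K = NA_integer_) {
  reason <- match.arg(reason, FAILURE_REASONS)
  abort(
    message = sprintf("GGMM fit failed (%s): %s", reason, detail),
    class = c(paste0("ggmnet_", reason), "ggmnet_failure"),
    reason = reason,
    detail = detail,
    K = as.integer(K)
  )
}

# generic invalid-input error with a stable class for tests
ggmnet_abort <- function(what, detail) {
  abort(message = detail, class = c(paste0("ggmnet_", what), "ggmnet_error"))
}

#' Convert a caught failure condition into a one-row failure record
#' @keywords internal
#' @noRd
failure_record <- function(cond, K) {
  tibble::tibble(
    K = as.integer(if (!is.null(cond$K) && !is.na(cond$K)) cond$K else K),
    reason = cond$reason %||% "no_convergence",
    detail = cond$detail %||% conditionMessage(cond)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
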