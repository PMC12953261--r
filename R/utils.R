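# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_arg <- function(msg) rlang::abort(msg, class = "depscreen_argument_error")
abort_schema <- function(msg) rlang::abort(msg, class = "depscreen_schema_error")
abort_validation <- function(msg) rlang::abort(msg, class = "depscreen_validation_error")

#' Derive a stage seed from a run seed
#'
#' One global seed fans out to per-stage seeds through a fixed integer hash,
#' so individual stages of a study can be rerun in isolation and still agree
#' with the full run.
#'
#' @param seed Integer run seed.
#' @param salt Character stage label.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, salt) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(salt))
  h <- sum(utf8ToInt(salt) * seq_along(utf8ToInt(salt)))
  as.integer((abs(seed) * 69069 + h * 97 + 13) %% 2147483587)
}

# round to one decimal, printed like the study tables
pct1 <- function(x) round(100 * x, 1)

is_binary01 <- function(x) all(x %in% c(0, 1))

check_labels <- function(y, arg = "labels") {
  y <- as.integer(y)
  if (length(y) == 0) abort_arg(sprintf("`%s` is empty", arg))
  if (anyNA(y) || !is_binary01(y)) {
    abort_arg(sprintf("`%s` must be a 0/1 vector without missing values", arg))
  }
  y
}
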