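#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor cor.test coef dist ecdf lm median pchisq pf pt qexp
#'   rmultinom rnorm runif sd shapiro.test smooth.spline predict t.test var
#'   var.test wilcox.test setNames quantile
#' @importFrom utils read.delim write.table head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds with `seed`, evaluates `expr`, and
#' restores the state on exit. With `seed = NULL` the expression runs under
#' the current RNG stream.
#'
#' @param seed integer seed or NULL.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# stable per-stage sub-seed, kept below 2^31
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + index * 7919) %% 2147483647L)
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("menet_config_error", "error")))
}

stop_format <- function(...) {
  stop(errorCondition(paste0(...), class = c("menet_format_error", "error")))
}
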