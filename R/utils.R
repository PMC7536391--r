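#' @importFrom rlang abort warn .data :=
#' @importFrom stats rnorm runif rbeta rlnorm quantile sd var coef lm qnorm
#'   dnorm setNames acf median complete.cases
#' @importFrom utils head read.delim write.table
NULL

# consistent error signalling with a package-specific class
cs_abort <- function(msg, class = "cropshift_error", ...) {
  abort(msg, class = c(class, "cropshift_error"), ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# check a data frame has the named columns
check_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    cs_abort(sprintf("%s is missing required column(s): %s",
                     what, paste(missing, collapse = ", ")),
             class = "cropshift_missing_columns")
  }
  invisible(df)
}

# deterministic per-stage seed expansion from one root seed (kept < 2^31)
derive_seed <- function(root_seed, stage) {
  stopifnot(is.numeric(root_seed), length(root_seed) == 1)
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((abs(root_seed) * 7919 + h * 104729 + 17) %% 2147483629)
}

# run an expression with a temporary RNG seed, restoring the caller's stream
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
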