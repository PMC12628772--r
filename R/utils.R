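# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded internals do not perturb the
#' caller's RNG stream. Used by every stochastic operation in the package.
#'
#' @param seed integer seed (must be < 2^31).
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
      get(".Random.seed", envir = .GlobalEnv)
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
          rm(".Random.seed", envir = .GlobalEnv)
        }
      } else {
        assign(".Random.seed", old, envir = .GlobalEnv)
      }
    })
    set.seed(as.integer(seed %% 2147483647L))
  }
  force(code)
}

# stop()/warning() wrappers carrying a condition class so callers and the CLI
# can distinguish user-input problems from internal faults
nl_stop <- function(msg, class = "nitrilink_error", call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "nitrilink_error")))
}

nl_warn <- function(msg) warning(msg, call. = FALSE)

# message to stderr with a timestamp; all pipeline logging funnels here
nl_log <- function(...) {
  message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), ...)
}

assert_count_matrix <- function(x, what = "count table") {
  if (!is.matrix(x) || !is.numeric(x)) {
    nl_stop(sprintf("%s must be a numeric matrix (samples x taxa)", what),
            "nitrilink_format_error")
  }
  if (any(x < 0)) {
    nl_stop(sprintf("%s contains negative values", what),
            "nitrilink_format_error")
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    nl_stop(sprintf("%s must carry sample rownames and taxon colnames", what),
            "nitrilink_format_error")
  }
  if (anyDuplicated(rownames(x))) {
    nl_stop(sprintf("%s has duplicate sample ids", what),
            "nitrilink_format_error")
  }
  if (anyDuplicated(colnames(x))) {
    nl_stop(sprintf("%s has duplicate taxon ids", what),
            "nitrilink_format_error")
  }
  invisible(x)
}

softmax_rows <- function(z) {
  m <- apply(z, 1L, max)
  e <- exp(z - m)
  e / rowSums(e)
}

# standardize a vector to mean 0, sd 1 (constant input -> zeros)
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}
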