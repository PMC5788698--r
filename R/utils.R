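# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state, so
#' seeded generators do not disturb the global random stream.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

stop_cm <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "cristamorph_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

warn_cm <- function(msg, class) {
  warning(structure(
    class = c(class, "cristamorph_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop_cm(sprintf("`%s` must be positive and finite", name),
            "cristamorph_argument_error")
  }
  invisible(x)
}

# conversion constants: lengths are nm internally, densities/areas are
# reported in micrometre units at the boundary
NM2_PER_UM2 <- 1e6
NM3_PER_UM3 <- 1e9
NM_PER_UM <- 1e3
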