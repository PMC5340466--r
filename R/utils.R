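# Internal helpers shared across modules.

# Run code with a temporary RNG seed, restoring global RNG state afterwards.
# All stochastic operations take an explicit seed; none touch hidden state.
.withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Evaluate an expression row-wise over one Taxmap table, with computed
# columns available as if they were real columns (user columns shadow
# computed ones, with a warning). `env` supplies free variables.
.evalInTable <- function(tm, table, expr, env) {
  df <- .materialize(tm, table)
  tryCatch(
    eval(expr, envir = df, enclos = env),
    error = function(e) {
      m <- regmatches(conditionMessage(e),
                      regexec("object '([^']+)' not found", conditionMessage(e)))[[1]]
      if (length(m) == 2L) {
        stop("unknown column: '", m[2], "' is not a column, computed column, ",
             "or visible variable", call. = FALSE)
      }
      stop(e)
    })
}

# Recycle a scalar predicate/key result to table length, or validate length.
.recycleToRows <- function(x, n, what) {
  if (length(x) == 1L) x <- rep(x, n)
  if (length(x) != n) {
    stop(what, " must have length 1 or ", n, ", got ", length(x), call. = FALSE)
  }
  x
}

.fmtIds <- function(ids, max = 5L) {
  shown <- utils::head(ids, max)
  out <- paste(shown, collapse = ", ")
  if (length(ids) > max) out <- paste0(out, ", ...")
  out
}
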