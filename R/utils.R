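# internal helpers shared across modules

# Evaluate `expr` under a temporary R RNG state seeded with `seed`, restoring
# the caller's state afterwards. Keeps package functions from clobbering the
# session RNG while staying reproducible.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

# Load a packaged constant table once per session.
extdata_table <- function(name) {
  if (is.null(the[[name]])) {
    path <- system.file("extdata", name, package = "orfvec", mustWork = TRUE)
    the[[name]] <- utils::read.delim(path, comment.char = "#",
                                     stringsAsFactors = FALSE)
  }
  the[[name]]
}

assert_scalar_string <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single non-NA string.", what))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
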