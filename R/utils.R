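#' @keywords internal
"_PACKAGE"

# Stage-scoped seeding: one user seed per run, each pipeline stage draws from
# its own deterministic substream so reordering or skipping stages cannot
# silently change another stage's numbers. Substream seeds stay < 2^31.
stage_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 69069 + h * 101) %% 2147483587) + 1L
}

with_stage_seed <- function(seed, stage, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(stage_seed(seed, stage))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_prob <- function(x, what = deparse(substitute(x))) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(what, " must lie in [0, 1]", call. = FALSE)
  }
  invisible(x)
}
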