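# internal helpers shared across modules

# run code with a temporarily seeded RNG, restoring the caller's state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

axis_index <- function(axis) {
  if (is.character(axis)) {
    i <- match(tolower(axis), c("x", "y", "z"))
    if (is.na(i)) stop("axis must be one of 'x', 'y', 'z'")
    return(i)
  }
  axis <- as.integer(axis)
  if (!axis %in% 1:3) stop("axis must be 1, 2 or 3 (or 'x','y','z')")
  axis
}

`%||%` <- function(a, b) if (is.null(a)) b else a
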