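#' Deterministic named substreams from one root seed
#'
#' All randomness in the synthetic-data generator flows from a single root
#' seed; every record (blank, standard, spot, transect) draws from its own
#' named substream so that any individual record is reproducible in isolation
#' and insertion or removal of records does not reshuffle the others.
#'
#' @param root integer root seed.
#' @param name character label of the substream (e.g. a record id).
#' @return integer seed in [0, 2^31 - 2], a deterministic function of
#'   `root` and `name`.
#' @keywords internal
substream_seed <- function(root, name) {
  stopifnot(length(root) == 1L, is.finite(root), length(name) == 1L)
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(root) %% m
  for (b in utf8ToInt(as.character(name))) {
    h <- (h * 31 + b) %% m
  }
  as.integer(h)
}

#' Evaluate an expression under a named substream, restoring RNG state
#' @keywords internal
with_substream <- function(root, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(root, name))
  expr
}
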