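`%||%` <- function(x, y) if (is.null(x)) y else x

#' @noRd
abort_if <- function(cond, ...) {
  if (isTRUE(cond)) stop(..., call. = FALSE)
  invisible(NULL)
}

# INFO-level progress notes; suppressed unless option avpcm.verbose is TRUE
vlog <- function(...) {
  if (isTRUE(getOption("avpcm.verbose", FALSE))) {
    message(format(Sys.time(), "[%H:%M:%S] "), sprintf(...))
  }
  invisible(NULL)
}

assert_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  abort_if(length(missing) > 0,
           sprintf("%s is missing required column(s): %s",
                   what, paste(missing, collapse = ", ")))
  invisible(df)
}

MARKERS <- c("TP53", "RB1", "PTEN")

assert_marker <- function(marker) {
  abort_if(!all(marker %in% MARKERS),
           sprintf("unknown marker(s): %s (expected %s)",
                   paste(setdiff(marker, MARKERS), collapse = ", "),
                   paste(MARKERS, collapse = "/")))
  invisible(marker)
}

# deterministic per-stage substream: run code under a seed derived from
# (seed, stage), restoring the caller's RNG state afterwards
with_stage_seed <- function(seed, stage, code) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  offsets <- c(truth = 11L, ihc = 23L, expression = 37L, genomics = 53L,
               misc = 71L)
  off <- offsets[[stage]] %||% 97L
  derived <- (as.integer(seed) %% 1000000L) * 1000L + off
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(derived)
  force(code)
}
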