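# Seeded RNG helpers.

# Run `expr` under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a child seed from a master seed and a stream label
#'
#' Deterministic integer hash used to give every subject / modality /
#' observer / session combination its own independent, reproducible RNG
#' stream. All arithmetic stays below 2^53 so the result is exact in doubles;
#' the returned seed is in `[0, 2^31 - 2]`.
#'
#' @param master Integer master seed.
#' @param ... Character or integer stream labels.
#' @return A single integer seed.
#' @export
child_seed <- function(master, ...) {
  mod <- 2147483629  # large prime < 2^31
  h <- as.numeric(master) %% mod
  for (part in list(...)) {
    codes <- if (is.character(part)) utf8ToInt(paste(part, collapse = "/"))
             else as.numeric(part)
    h <- (h * 69069 + 1) %% mod
    for (v in codes) h <- (h * 40503 + (v %% mod) + 97) %% mod
  }
  as.integer(h)
}
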