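#' Derive a reproducible sub-seed from a master seed and labels
#'
#' Maps a master seed plus an arbitrary set of labels (state id, replicate
#' index, stage name, ...) to an integer seed in `[1, 2^31 - 2]` by a stable
#' polynomial string hash. Distinct labels give distinct, effectively
#' independent RNG streams; the mapping is platform-independent and does not
#' depend on R's RNG state.
#'
#' @param master_seed Integer master seed.
#' @param ... Labels (coerced to character) identifying the sub-stream.
#' @return A single integer seed.
#' @export
#' @examples
#' sub_seed(42, "CA", "pm25", 7)
sub_seed <- function(master_seed, ...) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L, is.finite(master_seed))
  key <- paste(c(format(master_seed, scientific = FALSE), vapply(list(...), as.character, "")),
               collapse = "\r")
  # 31-bit polynomial rolling hash; exact in double arithmetic (31 * 2^31 < 2^53)
  p <- 2147483629
  h <- abs(master_seed) %% p
  for (code in utf8ToInt(key)) h <- (h * 31 + code) %% p
  as.integer(h + 1)
}

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
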