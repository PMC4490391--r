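# shared internal helpers

`%||%` <- function(x, y) if (is.null(x)) y else x

# Run `code` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

complement_bases <- function(x) {
  out <- x
  ok <- !is.na(x)
  out[ok] <- chartr("ACGT", "TGCA", x[ok])
  out
}

# format floats at 9 significant digits, "." for NA (on-disk null token)
fmt_num <- function(x) {
  out <- rep(".", length(x))
  ok <- !is.na(x)
  out[ok] <- sprintf("%.9g", x[ok])
  out
}

fmt_int <- function(x) {
  out <- rep(".", length(x))
  ok <- !is.na(x)
  out[ok] <- as.character(as.integer(x[ok]))
  out
}

fmt_chr <- function(x) {
  out <- as.character(x)
  out[is.na(out)] <- "."
  out
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 0 && x == floor(x)
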