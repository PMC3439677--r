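# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Sets the seed, runs `expr`, and restores the caller's `.Random.seed`, so
#' seeded operations inside the package never perturb the user's RNG stream.
#'
#' @param seed Integer seed, or `NULL` to use the current stream untouched.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single integer", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse-complement a DNA string
#'
#' Plain-character implementation over the `{A,C,G,T,N}` alphabet used
#' throughout the package (windows are already extracted as character
#' strings).
#'
#' @param seq A single DNA string.
#' @return The reverse complement, same alphabet.
#' @keywords internal
#' @noRd
revcomp_chr <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  x <- chartr("ACGTN", "TGCAN", seq)
  paste(rev(strsplit(x, "", fixed = TRUE)[[1L]]), collapse = "")
}

# Encode a DNA string as integer codes A=1 C=2 G=3 T=4, anything else NA.
dna_codes <- function(seq) {
  raw <- utf8ToInt(seq)
  code <- rep(NA_integer_, length(raw))
  code[raw == 65L] <- 1L  # A
  code[raw == 67L] <- 2L  # C
  code[raw == 71L] <- 3L  # G
  code[raw == 84L] <- 4L  # T
  code
}

round2 <- function(x) round(x, 2L)
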