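# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse-complement DNA strings
#'
#' Vectorised over a character vector; IUPAC letters are handled by
#' [Biostrings::reverseComplement()].
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Run `expr` under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, expr) {
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
  set.seed(seed)
  force(expr)
}

# Locale-independent ordering for chromosome names plus numeric keys.
order_radix <- function(...) order(..., method = "radix")

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
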