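`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so generator calls are pure functions of
#' their arguments (including `seed`) and do not disturb the caller's RNG
#' stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param code expression to evaluate.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Reverse complement of a DNA string
#'
#' @param x a single DNA string over A/C/G/T/N.
#' @return the reverse complement, as a character scalar.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' @keywords internal
random_dna <- function(n, gc = 0.42) {
  if (n <= 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Round half away from zero
#'
#' Percentage formatting in the report tables: values exactly half-way round
#' up (`round()` in R rounds half to even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' @keywords internal
pct_of <- function(n, total, digits = 1) {
  if (total <= 0) return(rep(0, length(n)))
  round_half_up(100 * n / total, digits)
}

#' @keywords internal
is_dna_string <- function(x) {
  is.character(x) & !is.na(x) & grepl("^[ACGTN]*$", x)
}

#' @keywords internal
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# uniform integers in [lo, hi]; safe when lo == hi (unlike sample(x, 1))
#' @keywords internal
rint <- function(lo, hi, n = 1L) {
  as.integer(lo) + sample.int(as.integer(hi) - as.integer(lo) + 1L, n,
                              replace = TRUE) - 1L
}
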