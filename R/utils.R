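#' @importFrom stats pbinom runif setNames median sd
#' @importFrom utils combn head read.table write.table packageVersion
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; the activity-window tables use
#' conventional half-up rounding (e.g. 0.14458/0.01909 = 7.57... -> 7.6).
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

## --- internal sequence helpers -------------------------------------------

VALID_BASES <- c("A", "C", "G", "T", "N")

# uppercase, T for U, IUPAC ambiguity codes to N; errors on anything else
normalize_seq <- function(x, what = "sequence") {
  x <- toupper(x)
  x <- chartr("U", "T", x)
  x <- gsub("[RYSWKMBDHV]", "N", x)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop(sprintf("invalid characters in %s %s", what,
                 paste(which(bad), collapse = ", ")), call. = FALSE)
  }
  x
}

revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

# accept a named character vector or a Biostrings XStringSet
as_seq_vector <- function(x, what = "sequences") {
  if (methods::is(x, "XStringSet")) {
    out <- as.character(x)
  } else if (is.character(x)) {
    out <- x
  } else {
    stop(sprintf("%s must be a named character vector or an XStringSet", what),
         call. = FALSE)
  }
  if (length(out) > 0 && is.null(names(out))) {
    names(out) <- paste0("seq", seq_along(out))
  }
  normalize_seq(out, what)
}

seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

#' Generate a random DNA sequence
#'
#' Draws i.i.d. bases at the requested GC content using the current RNG
#' state (set a seed beforehand for reproducibility).
#'
#' @param n sequence length in bases
#' @param gc GC content in `[0,1]`
#' @return a single character string over A/C/G/T
#' @export
random_dna <- function(n, gc = 0.5) {
  stopifnot(n >= 0, gc >= 0, gc <= 1)
  if (n == 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}
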