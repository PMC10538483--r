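#' @keywords internal
BASES <- c("A", "C", "G", "T")

# ASCII lookup: A/a=0, C/c=1, G/g=2, T/t=3, anything else NA
.DIGIT_LUT <- local({
  lut <- rep(NA_integer_, 128L)
  lut[utf8ToInt("A")] <- 0L; lut[utf8ToInt("a")] <- 0L
  lut[utf8ToInt("C")] <- 1L; lut[utf8ToInt("c")] <- 1L
  lut[utf8ToInt("G")] <- 2L; lut[utf8ToInt("g")] <- 2L
  lut[utf8ToInt("T")] <- 3L; lut[utf8ToInt("t")] <- 3L
  lut
})

# Digit vector of a sequence string; non-ACGT characters become NA.
# Soft-masked (lowercase) bases are accepted.
seq_to_digits <- function(s) {
  v <- utf8ToInt(s)
  d <- rep(NA_integer_, length(v))
  ok <- v >= 1L & v <= 128L
  d[ok] <- .DIGIT_LUT[v[ok]]
  d
}

digits_to_string <- function(d) {
  paste(BASES[d + 1L], collapse = "")
}

new_kmer <- function(digits) {
  structure(list(k = length(digits), digits = digits), class = "kmer")
}

#' Encode a DNA string as a k-mer
#'
#' A k-mer is stored as its exact base-4 digit vector with A=0, C=1, G=2,
#' T=3, leftmost character most significant. The representation is exact for
#' any k (no integer-width ceiling). Lowercase (soft-masked) bases are
#' uppercased before validation.
#'
#' @param s A non-empty string over A/C/G/T (case-insensitive).
#' @return An object of class `"kmer"` with fields `k` and `digits`.
#' @examples
#' x <- encode_kmer("ACGT")
#' kmer_code(x)  # 27
#' @export
encode_kmer <- function(s) {
  if (!is.character(s) || length(s) != 1L || is.na(s))
    stop("k-mer must be a single character string")
  if (nchar(s) == 0L)
    stop("k-mer must be non-empty")
  d <- seq_to_digits(s)
  if (anyNA(d)) {
    pos <- which(is.na(d))[1L]
    stop(sprintf("invalid character '%s' at position %d (expected A/C/G/T)",
                 substr(s, pos, pos), pos))
  }
  new_kmer(d)
}

#' Coerce to a k-mer
#'
#' @param x A `"kmer"` object or a DNA string.
#' @return A `"kmer"` object.
#' @export
as_kmer <- function(x) {
  if (inherits(x, "kmer")) x else encode_kmer(x)
}

#' Decode a k-mer back to its DNA string
#'
#' @param x A `"kmer"` object or DNA string.
#' @return An uppercase ACGT string.
#' @export
kmer_string <- function(x) {
  digits_to_string(as_kmer(x)$digits)
}

#' Numeric base-4 code of a k-mer
#'
#' The integer in `[0, 4^k)` whose base-4 big-endian digits are the encoded
#' characters. Exact only while `4^k` fits a double mantissa, so restricted
#' to `k <= 26`; larger k-mers are handled throughout the package by their
#' digit vectors and never need the scalar code.
#'
#' @param x A `"kmer"` object or DNA string.
#' @return A numeric scalar.
#' @export
kmer_code <- function(x) {
  x <- as_kmer(x)
  if (x$k > 26L)
    stop("scalar codes are only exact for k <= 26; use the digit representation")
  sum(x$digits * 4^((x$k - 1L):0L))
}

#' @export
print.kmer <- function(x, ...) {
  cat(sprintf("<kmer k=%d> %s\n", x$k, kmer_string(x)))
  invisible(x)
}

#' @export
format.kmer <- function(x, ...) kmer_string(x)

# rotate helpers keep the class of their input: string in, string out
.rot_wrap <- function(x, f) {
  was_chr <- is.character(x)
  x <- as_kmer(x)
  out <- new_kmer(f(x$digits))
  if (was_chr) kmer_string(out) else out
}

#' One-letter rotations of a k-mer
#'
#' `rotate_ccw()` is the counterclockwise (left) rotation
#' `x_1 .. x_{k-1} x_0`; `rotate_cw()` is the clockwise (right) rotation
#' `x_{k-1} x_0 .. x_{k-2}`. They are mutually inverse and generate the
#' conjugacy class (pure cycle) of the k-mer.
#'
#' @param x A `"kmer"` object or DNA string (a string input returns a string).
#' @return The rotated k-mer, same type as the input.
#' @examples
#' rotate_cw("ACTAC")   # "CACTA"
#' rotate_ccw("ACGT")   # "CGTA"
#' @export
rotate_ccw <- function(x) {
  .rot_wrap(x, function(d) c(d[-1L], d[1L]))
}

#' @rdname rotate_ccw
#' @export
rotate_cw <- function(x) {
  .rot_wrap(x, function(d) {
    k <- length(d)
    c(d[k], d[-k])
  })
}

#' Is a k-mer the lexicographically smallest of its rotations?
#'
#' True iff no cyclic rotation of `x` is lexicographically smaller than `x`
#' (equal rotations are allowed, so periodic k-mers qualify). Runs in O(k)
#' with a single scan of at most 2k - 1 character comparisons.
#'
#' @param x A `"kmer"` object or DNA string.
#' @return Logical scalar.
#' @examples
#' is_smallest_rotation("AAAAA")  # TRUE
#' is_smallest_rotation("CA")     # FALSE ("AC" is smaller)
#' @export
is_smallest_rotation <- function(x) {
  smallest_rotation_cpp(as_kmer(x)$digits)
}

# Run `code` with the global RNG state restored afterwards.
with_preserved_rng <- function(code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  force(code)
}
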