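# Total k-mer orders. Every order is partition-compatible: an ordered
# partition of the 4^k k-mers decides between classes (smaller rank first)
# and an XOR hash of the 2k-bit encoding decides within a class. With the
# all-zero mask the within-class order is lexicographic.

ORDER_KINDS <- c("random", "lex", "decycling", "double_decycling",
                 "set_file", "miniception")

#' Derive the 2k-bit XOR mask from a user seed
#'
#' Seed 0 is reserved for the all-zero mask (identity hash, i.e.
#' lexicographic within-class order). Any other seed seeds R's
#' Mersenne-Twister, which draws the mask as k independent uniform base-4
#' digits (big-endian fill: digit for character 0 first). The mask, not the
#' user seed, defines the order; the derivation is pinned so identical seeds
#' reproduce identical orders across runs. The caller's RNG state is
#' preserved.
#'
#' @param k k-mer length.
#' @param seed Non-negative integer user seed.
#' @return Integer vector of k base-4 digits.
#' @export
derive_xor_mask <- function(k, seed) {
  k <- as.integer(k)
  stopifnot(k >= 1L, is.numeric(seed), length(seed) == 1L, seed >= 0)
  if (seed == 0) return(integer(k))
  with_preserved_rng({
    set.seed(as.integer(seed))
    sample(0:3, k, replace = TRUE)
  })
}

#' Construct a minimizer order
#'
#' Builds the total k-mer order used by [select_minimizers()] and the density
#' harness. Kinds:
#' \describe{
#'   \item{`random`}{single class; XOR-hash order.}
#'   \item{`lex`}{single class; plain lexicographic order (seed ignored).}
#'   \item{`decycling`}{members of the minimum decycling set D_k precede all
#'     other k-mers; XOR hash within classes.}
#'   \item{`double_decycling`}{three classes: D_k, then the symmetric
#'     decycling set minus D_k, then the rest.}
#'   \item{`set_file`}{k-mers of a user-supplied set (e.g. a DOCKS/PASHA UHS
#'     file) precede the rest.}
#'   \item{`miniception`}{k-mers whose minimal k0-mer (under an inner random
#'     order) is their first or last k0-mer precede the rest.}
#' }
#'
#' @param kind Order kind, one of
#'   `"random"`, `"lex"`, `"decycling"`, `"double_decycling"`, `"set_file"`,
#'   `"miniception"`.
#' @param k k-mer length.
#' @param seed User seed for the XOR mask (see [derive_xor_mask()]); 0 gives
#'   the lexicographic within-class order.
#' @param epsilon Zero tolerance for the embedding tests, default `1e-9 * k`.
#' @param set Character vector of k-mers (for `set_file`), alternative to
#'   `set_file`.
#' @param set_file Path to a k-mer set file (one k-mer per line).
#' @param k0 Inner k-mer length for `miniception`, `0 < k0 < k`.
#' @param inner_seed Seed of the Miniception inner order; default `seed + 1`.
#' @return An object of class `"minimizer_order"`.
#' @examples
#' o <- minimizer_order("decycling", k = 5, seed = 0)
#' order_key("ACTAC", o)$rank  # 0: in D_5
#' @export
minimizer_order <- function(kind, k, seed = 1, epsilon = NULL,
                            set = NULL, set_file = NULL,
                            k0 = NULL, inner_seed = NULL) {
  kind <- match.arg(kind, ORDER_KINDS)
  k <- as.integer(k)
  stopifnot(k >= 1L)
  mask <- if (kind == "lex") integer(k) else derive_xor_mask(k, seed)
  o <- list(kind = kind, k = k, seed = seed, mask = mask,
            epsilon = decycling_epsilon(k, epsilon))
  if (kind == "set_file") {
    if (is.null(set) && is.null(set_file))
      stop("set_file order requires `set` or `set_file`")
    if (is.null(set)) set <- read_kmer_set(set_file, k = k)
    if (length(set) > 0L && any(nchar(set) != k))
      stop("set k-mers must have length k")
    o$set <- toupper(set)
  }
  if (kind == "miniception") {
    if (is.null(k0)) stop("miniception order requires k0 (0 < k0 < k)")
    k0 <- as.integer(k0)
    if (k0 <= 0L || k0 >= k) stop("k0 must satisfy 0 < k0 < k")
    if (is.null(inner_seed)) inner_seed <- seed + 1
    o$k0 <- k0
    o$inner_seed <- inner_seed
    o$inner_mask <- derive_xor_mask(k0, inner_seed)
  }
  structure(o, class = "minimizer_order")
}

#' @export
print.minimizer_order <- function(x, ...) {
  extra <- switch(x$kind,
    set_file = sprintf(", |set|=%d", length(x$set)),
    miniception = sprintf(", k0=%d, inner_seed=%s", x$k0,
                          format(x$inner_seed)),
    "")
  cat(sprintf("<minimizer_order %s k=%d seed=%s%s>\n",
              x$kind, x$k, format(x$seed), extra))
  invisible(x)
}

# partition ranks of every k-mer position of a digit sequence (no NAs)
.seq_ranks <- function(digits, order) {
  n <- length(digits) - order$k + 1L
  if (n < 1L) return(integer(0))
  switch(order$kind,
    random = ,
    lex = integer(n),
    decycling = seq_partition_ranks_cpp(digits, order$k, order$epsilon, FALSE),
    double_decycling = seq_partition_ranks_cpp(digits, order$k, order$epsilon,
                                               TRUE),
    set_file = {
      s <- digits_to_string(digits)
      km <- substring(s, seq_len(n), seq_len(n) + order$k - 1L)
      as.integer(!(km %in% order$set))
    },
    miniception = {
      flags <- miniception_flags_cpp(digits, order$k, order$k0, order$inner_mask)
      as.integer(!flags)
    })
}

#' XOR-hashed value of a k-mer under an order
#'
#' Returns `code(x) XOR mask` as a numeric code — a bijection on `[0, 4^k)`
#' for any fixed mask, so distinct k-mers never collide. Exact only for
#' `k <= 26` (see [kmer_code()]); larger k is handled internally by digit
#' vectors.
#'
#' @param x A `"kmer"` object or DNA string.
#' @param order A [minimizer_order()].
#' @return Numeric scalar in `[0, 4^k)`.
#' @export
hash_kmer <- function(x, order) {
  x <- as_kmer(x)
  if (x$k != order$k) stop("k-mer length does not match the order's k")
  hashed <- bitwXor(x$digits, order$mask)
  sum(hashed * 4^((x$k - 1L):0L))
}

#' Order key of a k-mer
#'
#' The pair (partition rank, XOR-hashed value) whose lexicographic comparison
#' realizes the partition-compatible order: rank 0 sorts before rank 1 before
#' rank 2; within a rank the hashed value decides.
#'
#' @inheritParams hash_kmer
#' @return List with `rank` (integer), `hashed_digits` (base-4 digits of the
#'   hashed value) and `hashed` (numeric code, `NA` when `k > 26`).
#' @export
order_key <- function(x, order) {
  x <- as_kmer(x)
  if (x$k != order$k) stop("k-mer length does not match the order's k")
  rank <- .seq_ranks(x$digits, order)
  hashed_digits <- bitwXor(x$digits, order$mask)
  hashed <- if (x$k <= 26L) sum(hashed_digits * 4^((x$k - 1L):0L)) else NA_real_
  list(rank = rank, hashed_digits = hashed_digits, hashed = hashed)
}

#' Compare two k-mers under an order
#'
#' @param x1,x2 `"kmer"` objects or DNA strings of the same length.
#' @inheritParams hash_kmer
#' @return `-1L` if `x1` is smaller, `0L` if identical, `1L` if larger. Hash
#'   bijectivity guarantees a strict total order on distinct k-mers.
#' @export
compare_kmers <- function(x1, x2, order) {
  x1 <- as_kmer(x1); x2 <- as_kmer(x2)
  if (x1$k != x2$k) stop("k-mers must have the same length")
  k1 <- order_key(x1, order)
  k2 <- order_key(x2, order)
  if (k1$rank != k2$rank) return(if (k1$rank < k2$rank) -1L else 1L)
  d <- k1$hashed_digits - k2$hashed_digits
  nz <- which(d != 0L)
  if (length(nz) == 0L) return(0L)
  if (d[nz[1L]] < 0L) -1L else 1L
}

#' Miniception set membership of a k-mer
#'
#' A k-mer belongs to the Miniception universal hitting set iff the minimum
#' of its `k - k0 + 1` constituent k0-mers — under the inner XOR-hash order,
#' leftmost on ties — sits at offset 0 or offset `k - k0`.
#'
#' @param x A `"kmer"` object or DNA string.
#' @param k0 Inner k-mer length, `0 < k0 < k`.
#' @param inner_seed Seed of the inner order (see [derive_xor_mask()]).
#' @param inner_mask Optional explicit mask of k0 base-4 digits, overriding
#'   `inner_seed`.
#' @return Logical scalar.
#' @examples
#' miniception_member("CAAG", k0 = 2, inner_seed = 0)  # FALSE: min "AA" interior
#' @export
miniception_member <- function(x, k0, inner_seed = 1, inner_mask = NULL) {
  x <- as_kmer(x)
  k0 <- as.integer(k0)
  if (k0 <= 0L || k0 >= x$k) stop("k0 must satisfy 0 < k0 < k")
  if (is.null(inner_mask)) inner_mask <- derive_xor_mask(k0, inner_seed)
  miniception_flags_cpp(x$digits, x$k, k0, as.integer(inner_mask))[1L]
}
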