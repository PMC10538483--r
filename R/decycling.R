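# Mykkeltveit embedding and decycling-set membership.
#
# The embedding places character i of a k-mer, weighted by its numeric value,
# at the k-th root of unity exp(2*pi*i*sqrt(-1)/k); M(x) = (R(x), I(x)) is the
# resulting sum. A conjugacy class (pure cycle of the complete de Bruijn
# graph) contributes to the decycling set D_k its first counterclockwise
# rotation with positive imaginary part; classes whose rotations all embed at
# the origin contribute their lexicographically smallest rotation. The
# symmetric set mirrors "positive" to "negative".

# Zero tolerance on I(x): exact arithmetic would test I(x) == 0, floating
# point needs a band. Scales with k since I is a sum of k terms.
decycling_epsilon <- function(k, epsilon = NULL) {
  if (is.null(epsilon)) return(1e-9 * k)
  stopifnot(is.numeric(epsilon), length(epsilon) == 1L, epsilon > 0)
  epsilon
}

#' Mykkeltveit embedding of a k-mer
#'
#' Computes `M(x) = (R(x), I(x))` with
#' `R(x) = sum_i x_i cos(2 pi i / k)` and `I(x) = sum_i x_i sin(2 pi i / k)`,
#' where `x_i` is the numeric encoding (A=0, C=1, G=2, T=3) of character `i`.
#' The sign of `I(x)` classifies rotations as positive or negative; summation
#' order is fixed (i = 0..k-1) for run-to-run determinism.
#'
#' @param x A `"kmer"` object or DNA string.
#' @return Named numeric vector `c(R = , I = )`.
#' @examples
#' mykkeltveit_embed("AAAAA")["I"]  # exactly 0
#' @export
mykkeltveit_embed <- function(x) {
  embed_kmer_cpp(as_kmer(x)$digits)
}

#' Membership in the Mykkeltveit minimum decycling set
#'
#' `in_decycling_set()` tests in O(k) whether a k-mer belongs to the minimum
#' decycling set D_k: it is a member iff `I(x) > epsilon` while its clockwise
#' rotation `x'` has `I(x') <= epsilon` (the first positive counterclockwise
#' rotation of its pure cycle), or the whole cycle embeds at the origin
#' (`|I(x)| <= epsilon` and `|I(x')| <= epsilon`) and `x` is the
#' lexicographically smallest rotation. `in_symmetric_decycling_set()` is the
#' mirror test (first *negative* counterclockwise rotation); origin-embedded
#' cycles share the same lexicographic representative in both sets, so the
#' ordered partition `{D_k, symmetric \ D_k, rest}` is well defined.
#'
#' @param x A `"kmer"` object, DNA string, or character vector of k-mers.
#' @param epsilon Zero tolerance for `I(x)`; default `1e-9 * k`.
#' @return Logical, one value per input k-mer.
#' @examples
#' in_decycling_set("ACTAC")  # TRUE
#' in_decycling_set("ACACT")  # FALSE (another rotation represents the class)
#' @export
in_decycling_set <- function(x, epsilon = NULL) {
  .mds_apply(x, epsilon, symmetric = FALSE)
}

#' @rdname in_decycling_set
#' @export
in_symmetric_decycling_set <- function(x, epsilon = NULL) {
  .mds_apply(x, epsilon, symmetric = TRUE)
}

.mds_apply <- function(x, epsilon, symmetric) {
  if (is.character(x) && length(x) > 1L) {
    return(vapply(x, function(s) {
      d <- as_kmer(s)$digits
      mds_member_cpp(d, decycling_epsilon(length(d), epsilon), symmetric)
    }, logical(1L), USE.NAMES = FALSE))
  }
  d <- as_kmer(x)$digits
  mds_member_cpp(d, decycling_epsilon(length(d), epsilon), symmetric)
}

#' Enumerate a decycling set explicitly (small k)
#'
#' Filters all `4^k` k-mers through the O(k) membership test. Intended for
#' verification and for writing set files at small k; the on-the-fly
#' membership test makes enumeration unnecessary for sketching.
#'
#' @param k k-mer length, at most `max_k`.
#' @param variant `"positive"` for D_k, `"symmetric"` for the mirror set.
#' @param epsilon Zero tolerance, default `1e-9 * k`.
#' @param max_k Refusal ceiling (memory/time guard), default 12.
#' @return Character vector of member k-mers in lexicographic order; its
#'   length equals the necklace count [necklace_count()].
#' @examples
#' length(enumerate_decycling_set(5))  # 208
#' @export
enumerate_decycling_set <- function(k, variant = c("positive", "symmetric"),
                                    epsilon = NULL, max_k = 12L) {
  variant <- match.arg(variant)
  k <- as.integer(k)
  stopifnot(k >= 1L)
  if (k > max_k)
    stop(sprintf(paste0("k = %d exceeds the enumeration ceiling (%d); use the ",
                        "on-the-fly membership test in_decycling_set() instead"),
                 k, max_k))
  enumerate_mds_cpp(k, decycling_epsilon(k, epsilon), variant == "symmetric")
}

#' Number of conjugacy classes (necklaces) of k-mers
#'
#' Burnside count `(1/k) * sum_{d | k} phi(d) * 4^(k/d)` of cyclic rotation
#' classes over the 4-letter alphabet. A minimum decycling set has exactly
#' one member per class, so this is its size.
#'
#' @param k k-mer length (kept in the exact-double range).
#' @return Numeric count.
#' @examples
#' necklace_count(5)  # 208
#' @export
necklace_count <- function(k) {
  k <- as.integer(k)
  stopifnot(k >= 1L, k <= 26L)
  divs <- which(k %% seq_len(k) == 0L)
  phi <- vapply(divs, euler_phi, numeric(1L))
  sum(phi * 4^(k / divs)) / k
}

euler_phi <- function(n) {
  res <- n
  m <- n
  p <- 2
  while (p * p <= m) {
    if (m %% p == 0) {
      res <- res / p * (p - 1)
      while (m %% p == 0) m <- m / p
    }
    p <- p + 1
  }
  if (m > 1) res <- res / m * (m - 1)
  res
}

#' Verify that a k-mer set decycles the complete de Bruijn graph
#'
#' Builds the complete de Bruijn graph on all `4^k` nodes, removes the given
#' k-mers, and reports whether the remainder is acyclic (self-loops count as
#' cycles). Test-scale oracle; refuses k > 8.
#'
#' @param k k-mer length, at most 8.
#' @param removed Character vector of k-mers to delete.
#' @return Logical scalar.
#' @export
verify_decycling <- function(k, removed) {
  k <- as.integer(k)
  stopifnot(k >= 1L, k <= 8L)
  n <- 4^k
  codes <- 0:(n - 1)
  # edge u -> v iff v = (u mod 4^(k-1)) * 4 + b
  u <- rep(codes, each = 4L)
  v <- (u %% 4^(k - 1)) * 4 + rep(0:3, times = n)
  g <- igraph::graph_from_edgelist(cbind(u, v) + 1L, directed = TRUE)
  if (length(removed) > 0L) {
    rem <- vapply(removed, function(s) {
      x <- as_kmer(s)
      if (x$k != k) stop("removed k-mer has wrong length")
      kmer_code(x)
    }, numeric(1L), USE.NAMES = FALSE)
    g <- igraph::delete_vertices(g, rem + 1L)
  }
  igraph::is_dag(g)
}

#' Read and write k-mer set files
#'
#' Plain-text set files with one uppercase k-mer per line (LF-terminated),
#' the format produced by UHS tools such as DOCKS and PASHA. `write_kmer_set`
#' sorts lexicographically before writing; `read_kmer_set` validates every
#' line, deduplicates, and warns on an empty file (an order built from an
#' empty set degenerates to the plain random order).
#'
#' @param kmers Character vector of equal-length ACGT k-mers.
#' @param path File path.
#' @param k Expected k-mer length; inferred from the first line when `NULL`.
#' @return `read_kmer_set` returns a character vector of unique k-mers;
#'   `write_kmer_set` returns `path` invisibly.
#' @export
write_kmer_set <- function(kmers, path) {
  if (length(kmers) > 0L) {
    lens <- nchar(kmers)
    if (length(unique(lens)) != 1L) stop("k-mers must all have the same length")
    bad <- grepl("[^ACGT]", toupper(kmers))
    if (any(bad)) stop(sprintf("non-ACGT k-mer at entry %d", which(bad)[1L]))
  }
  writeLines(sort(toupper(kmers)), path)
  invisible(path)
}

#' @rdname write_kmer_set
#' @export
read_kmer_set <- function(path, k = NULL) {
  if (!file.exists(path)) stop(sprintf("set file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    warning("empty k-mer set file; the derived order degenerates to random")
    return(character(0))
  }
  lines <- toupper(lines)
  if (is.null(k)) k <- nchar(lines[1L])
  bad <- which(nchar(lines) != k)
  if (length(bad) > 0L)
    stop(sprintf("line %d: k-mer length %d, expected %d",
                 bad[1L], nchar(lines[bad[1L]]), k))
  badc <- grep("[^ACGT]", lines)
  if (length(badc) > 0L)
    stop(sprintf("line %d: non-ACGT character", badc[1L]))
  unique(lines)
}
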