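# Independent oracles, deliberately decoupled from the package's code paths:
# string/arithmetic re-derivations of the embedding, class representatives
# and per-window argmin used to cross-check the O(k) and streaming routes.

ORACLE_BASES <- c("A", "C", "G", "T")

# all 4^k k-mers in lexicographic order (string construction, not codes)
all_kmers <- function(k) {
  g <- do.call(expand.grid,
               c(rep(list(ORACLE_BASES), k), KEEP.OUT.ATTRS = FALSE,
                 stringsAsFactors = FALSE))
  # expand.grid varies the first column fastest; putting it last in the
  # paste makes the result come out in lexicographic order already
  do.call(paste0, g[, rev(seq_len(k)), drop = FALSE])
}

o_digits <- function(s) {
  match(strsplit(s, "")[[1]], ORACLE_BASES) - 1L
}

o_rotations <- function(s) {
  k <- nchar(s)
  vapply(0:(k - 1L), function(i) paste0(substr(s, i + 1L, k), substr(s, 1L, i)),
         character(1L))
}

o_embed_I <- function(s) {
  d <- o_digits(s)
  k <- length(d)
  sum(d * sin(2 * pi * (0:(k - 1L)) / k))
}

# rotate-and-pick brute force: the class member is the first positive
# (negative) rotation whose clockwise predecessor is nonpositive
# (non-negative); all-zero classes take the lexicographically smallest.
o_mds_member <- function(s, symmetric = FALSE, tol = NULL) {
  k <- nchar(s)
  if (is.null(tol)) tol <- 1e-9 * k
  rots <- o_rotations(s)
  I <- vapply(rots, o_embed_I, numeric(1L), USE.NAMES = FALSE)
  if (all(abs(I) <= tol)) return(s == min(rots))
  prev <- I[c(k, seq_len(k - 1L))]  # I of the clockwise rotation
  sel <- if (!symmetric) which(I > tol & prev <= tol)
         else which(I < -tol & prev >= -tol)
  any(rots[sel] == s)
}

o_smallest_rotation <- function(s) s == min(o_rotations(s))

# Vectorized code-arithmetic oracle: decycling-set membership for ALL 4^k
# k-mers at once (k <= 13 or so). Independent of the C++ scan: works on
# numeric codes, matrix trig and rotation-code arithmetic.
o_mds_all <- function(k, symmetric = FALSE, tol = NULL) {
  if (is.null(tol)) tol <- 1e-9 * k
  codes <- 0:(4^k - 1)
  dig <- sapply(0:(k - 1L), function(j) (codes %/% 4^(k - 1L - j)) %% 4)
  I <- as.numeric(dig %*% sin(2 * pi * (0:(k - 1L)) / k))
  cw <- (codes %% 4) * 4^(k - 1L) + codes %/% 4
  Icw <- I[cw + 1]
  zero <- abs(I) <= tol & abs(Icw) <= tol
  # lexicographically smallest rotation: min code over the rotation orbit
  minrot <- codes
  r <- codes
  for (j in seq_len(k - 1L)) {
    r <- (r %% 4^(k - 1L)) * 4 + r %/% 4^(k - 1L)  # ccw rotation
    minrot <- pmin(minrot, r)
  }
  ismin <- codes == minrot
  if (!symmetric) (I > tol & Icw <= tol) | (zero & ismin)
  else            (I < -tol & Icw >= -tol) | (zero & ismin)
}

# memoized variant: the k = 11 table is expensive to rebuild per instance
.o_mds_cache <- new.env(parent = emptyenv())
o_mds_all_cached <- function(k, symmetric = FALSE) {
  key <- paste0(k, if (symmetric) "s" else "p")
  if (is.null(.o_mds_cache[[key]]))
    .o_mds_cache[[key]] <- o_mds_all(k, symmetric)
  .o_mds_cache[[key]]
}

# partition ranks of all k-mer positions of a sequence, oracle-side
o_ranks <- function(s, k, kind) {
  if (kind == "random") return(NULL)
  codes <- o_seq_codes(s, k)
  if (kind == "decycling")
    return(as.numeric(!o_mds_all_cached(k)[codes + 1]))
  inD <- o_mds_all_cached(k)
  inS <- o_mds_all_cached(k, symmetric = TRUE)
  (2 - 2 * inD - 1 * (inS & !inD))[codes + 1]
}

# digits of a sequence string, oracle-side
o_seq_digits <- function(s) {
  match(strsplit(s, "")[[1]], ORACLE_BASES) - 1L
}

# rolling numeric codes of all k-mers of a sequence (k <= 26)
o_seq_codes <- function(s, k) {
  d <- o_seq_digits(s)
  n <- length(d) - k + 1L
  code <- numeric(n)
  c0 <- sum(d[1:k] * 4^((k - 1L):0L))
  code[1L] <- c0
  p4 <- 4^(k - 1L)
  for (p in seq_len(n - 1L)) {
    c0 <- (c0 %% p4) * 4 + d[p + k]
    code[p + 1L] <- c0
  }
  code
}

# naive per-window argmin selection (leftmost ties via which.min), with
# partition ranks supplied by the caller; the independent windowing oracle
o_select <- function(s, k, w, mask_digits, ranks = NULL) {
  code <- o_seq_codes(s, k)
  n <- length(code)
  mask_code <- sum(mask_digits * 4^((k - 1L):0L))
  key <- bitwXor(as.integer(code), as.integer(mask_code))
  if (is.null(ranks)) ranks <- numeric(n)
  key <- ranks * 4^k + key
  nw <- n - w + 1L
  sel <- vapply(seq_len(nw), function(j) j - 1L + which.min(key[j:(j + w - 1L)]) - 1L,
                integer(1L))
  sort(unique(sel))
}

# window-guarantee check on a SelectionResult
covers_all_windows <- function(positions, n_kmers, w) {
  nw <- n_kmers - w + 1L
  if (nw < 1L) return(TRUE)
  all(vapply(seq_len(nw) - 1L,
             function(j) any(positions >= j & positions <= j + w - 1L),
             logical(1L)))
}
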