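# Windowed minimizer selection and density evaluation.
#
# Conventions (used in every output): 0-based k-mer start offsets; a window
# of w overlapping k-mers spans L = w + k - 1 bases; density = selected
# positions / all k-mer start positions; density factor = density * (w + 1).

resolve_w <- function(k, w = NULL, L = NULL) {
  if (is.null(w) && is.null(L)) stop("provide w or L")
  if (!is.null(w) && !is.null(L) && L != w + k - 1)
    stop(sprintf("inconsistent parameters: L must equal w + k - 1 (got L=%d, w+k-1=%d)",
                 L, w + k - 1))
  if (is.null(w)) w <- L - k + 1
  w <- as.integer(w)
  if (w < 1L) stop("w must be >= 1 (i.e. L >= k)")
  w
}

#' Minimizer position of a single window
#'
#' Returns the 0-based offset (in `[0, w - 1]`) of the order-minimal k-mer in
#' an `L = w + k - 1` nt window, leftmost on ties.
#'
#' @param window ACGT string of length `w + k - 1`.
#' @param order A [minimizer_order()].
#' @param w Window size in k-mers; inferred from `nchar(window)` when `NULL`.
#' @return Integer offset.
#' @examples
#' o <- minimizer_order("lex", k = 2)
#' window_minimizer("AAA", o)  # 0: identical k-mers, leftmost wins
#' @export
window_minimizer <- function(window, order, w = NULL) {
  k <- order$k
  if (is.null(w)) w <- nchar(window) - k + 1L
  if (nchar(window) != w + k - 1L)
    stop(sprintf("window must have length w + k - 1 = %d", w + k - 1L))
  d <- seq_to_digits(window)
  if (anyNA(d)) {
    pos <- which(is.na(d))[1L]
    stop(sprintf("non-ACGT character at position %d", pos))
  }
  ranks <- .seq_ranks(d, order)
  select_minimizers_cpp(d, k, as.integer(w), ranks, order$mask)[1L]
}

#' Select the minimizers of a sequence
#'
#' Applies the scheme to every overlapping `L`-long window and returns the
#' distinct, sorted 0-based k-mer start positions selected. Every window
#' contains at least one selected position (window guarantee), and the
#' per-window selections never move backwards as the window slides (forward
#' property). The streaming implementation is bit-exact with the naive
#' per-window argmin with leftmost ties.
#'
#' @param seq ACGT string (use [particular_density()] for sequences with
#'   non-ACGT characters).
#' @param order A [minimizer_order()].
#' @param w Window size in k-mers (`L = w + k - 1`); give `w` or `L`.
#' @param L Window length in bases.
#' @return List with `positions` (strictly increasing integer vector) and
#'   `n_windows`. A sequence shorter than `L` yields no windows: empty
#'   result with a warning.
#' @export
select_minimizers <- function(seq, order, w = NULL, L = NULL) {
  k <- order$k
  w <- resolve_w(k, w, L)
  d <- seq_to_digits(seq)
  if (anyNA(d)) {
    pos <- which(is.na(d))[1L]
    stop(sprintf("non-ACGT character at position %d; split the sequence or use particular_density()",
                 pos))
  }
  if (length(d) < w + k - 1L) {
    warning("sequence shorter than L = w + k - 1; no window exists")
    return(list(positions = integer(0), n_windows = 0L))
  }
  ranks <- .seq_ranks(d, order)
  pos <- select_minimizers_cpp(d, k, w, ranks, order$mask)
  list(positions = pos, n_windows = length(d) - k + 1L - w + 1L)
}

# ACGT runs of a digit vector: data.frame(start (0-based), length)
.acgt_runs <- function(d) {
  r <- rle(!is.na(d))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(start = starts[r$values], length = r$lengths[r$values])
}

#' Particular density of a minimizer scheme on given sequences
#'
#' Splits each sequence at non-ACGT characters, runs minimizer selection on
#' every run long enough to contain a window, and aggregates. Runs shorter
#' than `L` admit no window and are excluded from both numerator and
#' denominator, so density remains a property of the scheme rather than of
#' sequence fragmentation; their count is reported.
#'
#' @param x Character vector of sequences (e.g. from [read_fasta()]), or a
#'   single string.
#' @param order A [minimizer_order()].
#' @param w,L Window size in k-mers / window length in bases (give one).
#' @return Object of class `"density_report"`: a list with `n_selected`,
#'   `n_positions` (total k-mer start positions over eligible runs),
#'   `density`, `density_factor`, `k`, `w`, `L`, `n_runs_used`,
#'   `n_runs_skipped`.
#' @export
particular_density <- function(x, order, w = NULL, L = NULL) {
  k <- order$k
  w <- resolve_w(k, w, L)
  Lb <- w + k - 1L
  n_sel <- 0; n_pos <- 0; used <- 0L; skipped <- 0L
  for (s in x) {
    d <- seq_to_digits(s)
    runs <- .acgt_runs(d)
    for (i in seq_len(nrow(runs))) {
      len <- runs$length[i]
      if (len < Lb) { skipped <- skipped + 1L; next }
      rd <- d[(runs$start[i] + 1L):(runs$start[i] + len)]
      ranks <- .seq_ranks(rd, order)
      pos <- select_minimizers_cpp(rd, k, w, ranks, order$mask)
      n_sel <- n_sel + length(pos)
      n_pos <- n_pos + (len - k + 1L)
      used <- used + 1L
    }
  }
  if (used == 0L)
    stop(sprintf("no ACGT run of length >= L = %d; cannot compute density", Lb))
  density <- n_sel / n_pos
  structure(list(n_selected = n_sel, n_positions = n_pos,
                 density = density, density_factor = density * (w + 1),
                 k = k, w = w, L = Lb,
                 n_runs_used = used, n_runs_skipped = skipped),
            class = "density_report")
}

#' @export
print.density_report <- function(x, ...) {
  cat(sprintf("<density_report k=%d w=%d L=%d>\n", x$k, x$w, x$L))
  cat(sprintf("  selected %d of %d k-mer positions (runs used %d, skipped %d)\n",
              x$n_selected, x$n_positions, x$n_runs_used, x$n_runs_skipped))
  cat(sprintf("  density %.6f   density factor %.4f\n",
              x$density, x$density_factor))
  invisible(x)
}

#' Generate a uniform i.i.d. ACGT sequence
#'
#' Each base is drawn independently and uniformly from A/C/G/T using R's
#' Mersenne-Twister seeded with `seed`; identical `(length, seed)` pairs give
#' identical sequences. The caller's RNG state is preserved.
#'
#' @param length Sequence length in nt.
#' @param seed Integer seed.
#' @return An ACGT string.
#' @export
generate_iid_sequence <- function(length, seed) {
  stopifnot(length >= 1)
  with_preserved_rng({
    set.seed(as.integer(seed))
    paste(sample(BASES, length, replace = TRUE), collapse = "")
  })
}

# replicate seeds derived from a base seed: one sequence seed and one order
# seed per replicate, all below 2^31 and reproducible from base_seed alone
.replicate_seeds <- function(base_seed, n_reps) {
  with_preserved_rng({
    set.seed(as.integer(base_seed))
    list(seq = sample.int(2147483646L, n_reps),
         ord = sample.int(2147483646L, n_reps))
  })
}

#' Expected density of a minimizer order on i.i.d. sequences
#'
#' Estimates expected density by running [particular_density()] on `n_reps`
#' random i.i.d. sequences, each with its own sequence seed and order seed
#' derived deterministically from `base_seed`. Different order kinds called
#' with the same `base_seed` see identical sequences and order seeds, so
#' comparisons between kinds are paired.
#'
#' @param kind Order kind (see [minimizer_order()]).
#' @param k k-mer length.
#' @param w,L Window size in k-mers / window length in bases (give one).
#' @param n_reps Number of replicates (default 5).
#' @param seq_len Length of each i.i.d. sequence (default 1e6 nt).
#' @param base_seed Master seed for the replicate seeds.
#' @param epsilon,set,set_file,k0 Passed to [minimizer_order()]; for
#'   `miniception`, `k0 = NULL` defaults to `max(k - w, 3)`.
#' @return A one-row `data.frame` with columns `kind, k, w, L, n_reps,
#'   seq_len, mean_density, mean_density_factor, stderr_density_factor,
#'   lower_bound_factor`; per-replicate factors are in
#'   `attr(, "replicates")`. The standard error is `NA` for a single
#'   replicate.
#' @examples
#' \donttest{
#' expected_density("random", k = 11, w = 90, n_reps = 2, seq_len = 1e5,
#'                  base_seed = 1)
#' }
#' @export
expected_density <- function(kind, k, w = NULL, L = NULL, n_reps = 5,
                             seq_len = 1e6, base_seed = 1, epsilon = NULL,
                             set = NULL, set_file = NULL, k0 = NULL) {
  kind <- match.arg(kind, ORDER_KINDS)
  w <- resolve_w(k, w, L)
  stopifnot(n_reps >= 1)
  if (kind == "miniception" && is.null(k0)) k0 <- max(k - w, 3L)
  seeds <- .replicate_seeds(base_seed, n_reps)
  facs <- numeric(n_reps)
  dens <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    s <- generate_iid_sequence(seq_len, seeds$seq[r])
    o <- minimizer_order(kind, k, seed = seeds$ord[r], epsilon = epsilon,
                         set = set, set_file = set_file, k0 = k0)
    pd <- particular_density(s, o, w = w)
    facs[r] <- pd$density_factor
    dens[r] <- pd$density
  }
  out <- data.frame(
    kind = kind, k = as.integer(k), w = w, L = w + k - 1L,
    n_reps = as.integer(n_reps), seq_len = seq_len,
    mean_density = mean(dens),
    mean_density_factor = mean(facs),
    stderr_density_factor = if (n_reps > 1) sd(facs) / sqrt(n_reps) else NA_real_,
    lower_bound_factor = lower_bound_density_factor(k, w),
    stringsAsFactors = FALSE)
  attr(out, "replicates") <- data.frame(rep = seq_len(n_reps),
                                        seq_seed = seeds$seq,
                                        order_seed = seeds$ord,
                                        density = dens,
                                        density_factor = facs)
  out
}

#' Forward-scheme density-factor lower bound
#'
#' The proven lower bound on the density of any forward sketching scheme
#' (minimizers included),
#' `(1.5 + max(0, ceiling((k - w) / w)) + 1 / (2w)) / (w + k)`,
#' reported as a density factor (multiplied by `w + 1`). For fixed `k` it
#' converges to 1.5 as the window grows.
#'
#' @param k,w Scheme parameters.
#' @return Numeric density factor.
#' @examples
#' lower_bound_density_factor(1, 1)  # 2
#' @export
lower_bound_density_factor <- function(k, w) {
  stopifnot(k >= 1, w >= 1)
  (1.5 + pmax(0, ceiling((k - w) / w)) + 1 / (2 * w)) / (w + k) * (w + 1)
}

#' Density-factor sweep over a parameter grid
#'
#' Runs [expected_density()] for every combination of `k`, `L` and order
#' kind, with replicate seeds shared across kinds (paired comparisons).
#'
#' @param k_values,L_values Integer vectors (`L > k` required).
#' @param orders Character vector of order kinds.
#' @param n_reps,seq_len,base_seed,epsilon,k0,set,set_file As in
#'   [expected_density()].
#' @return A `data.frame` with one row per (k, L, order) combination.
#' @export
density_sweep <- function(k_values, L_values, orders, n_reps = 5,
                          seq_len = 1e6, base_seed = 1, epsilon = NULL,
                          k0 = NULL, set = NULL, set_file = NULL) {
  rows <- list()
  for (k in k_values) for (L in L_values) {
    if (L <= k) stop(sprintf("L must exceed k (got k=%d, L=%d)", k, L))
    for (kind in orders) {
      rows[[length(rows) + 1L]] <-
        expected_density(kind, k, L = L, n_reps = n_reps, seq_len = seq_len,
                         base_seed = base_seed, epsilon = epsilon,
                         set = set, set_file = set_file, k0 = k0)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(kind = character(0), k = integer(0), w = integer(0),
                      L = integer(0), n_reps = integer(0),
                      seq_len = numeric(0), mean_density = numeric(0),
                      mean_density_factor = numeric(0),
                      stderr_density_factor = numeric(0),
                      lower_bound_factor = numeric(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, lapply(rows, function(r) { attr(r, "replicates") <- NULL; r }))
  rownames(out) <- NULL
  out
}
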