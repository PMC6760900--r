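#' Jukes-Cantor distance from an observed mismatch proportion
#'
#' `d = -(3/4) * ln(1 - 4p/3)`: the substitutions-per-site estimate that
#' corrects the observed proportion of differing sites `p` for multiple
#' hits under the one-parameter substitution model. Defined for
#' `0 <= p < 0.75`; the transform saturates at p = 0.75.
#'
#' @param p Proportion(s) of differing compared sites.
#' @return Jukes-Cantor distance(s).
#' @examples
#' jc_distance(0.1)  # 0.1073256
#' @export
jc_distance <- function(p) {
  if (any(p < 0)) stop("p must be >= 0")
  if (any(p >= 0.75)) stop("saturation: p must be < 0.75")
  -0.75 * log(1 - 4 * p / 3)
}

#' Jukes-Cantor distances over random non-overlapping windows
#'
#' Emulates the genome-wide neutral-rate estimate: the coordinate-aligned
#' consensus sequences of two populations are tiled into non-overlapping
#' windows of `window_len` sites, `n_windows` tiles are sampled without
#' replacement with a seeded generator, and the per-window mismatch
#' proportion (excluding positions where either sequence has N or a gap)
#' is transformed with [jc_distance()]. The published scheme used 10,000
#' random non-overlapping 25 kbp autosomal windows; tests use scaled-down
#' window sets with the same machinery.
#'
#' @param seq_a,seq_b Equal-length sequence strings (A,C,G,T,N,-).
#' @param n_windows Number of windows to sample.
#' @param window_len Window length in sites.
#' @param seed Integer seed; the same seed yields the same window set.
#' @return List with `starts` (1-based window starts), `distances` (per
#'   window; NA when a window has no comparable site) and `mean`
#'   (over non-NA windows).
#' @export
window_distances <- function(seq_a, seq_b, n_windows, window_len, seed) {
  a <- chars(toupper(seq_a)); b <- chars(toupper(seq_b))
  if (length(a) != length(b)) stop("sequences must be coordinate-aligned")
  n_tiles <- length(a) %/% window_len
  if (n_windows > n_tiles) {
    stop("insufficient length: at most ", n_tiles, " non-overlapping ",
         "windows of ", window_len, " sites are available")
  }
  tiles <- with_seed(seed, sample.int(n_tiles, n_windows))
  starts <- (tiles - 1) * window_len + 1
  d <- vapply(starts, function(s) {
    ia <- a[s:(s + window_len - 1)]; ib <- b[s:(s + window_len - 1)]
    ok <- ia %in% DNA_STATES & ib %in% DNA_STATES
    if (!any(ok)) return(NA_real_)
    jc_distance(sum(ia[ok] != ib[ok]) / sum(ok))
  }, numeric(1))
  list(starts = sort(starts), distances = d[order(starts)],
       mean = mean(d, na.rm = TRUE))
}

#' Neutral expectation for the number of substitutions
#'
#' Multiplies the gap-free length of a focal alignment by the genome-wide
#' mean per-site distance, giving the approximately neutral number of
#' substitutions expected for the comparison: `E = L * d_bar`.
#'
#' @param L Gap-free alignment length (sites, >= 0).
#' @param d_bar Mean per-site distance (>= 0).
#' @return List (class `neutral_expectation`): `L`, `d_bar`, `expected`.
#' @examples
#' expected_substitutions(500, 0.013)$expected  # 6.5
#' @export
expected_substitutions <- function(L, d_bar) {
  stopifnot(L >= 0, d_bar >= 0)
  structure(list(L = L, d_bar = d_bar, expected = L * d_bar),
            class = "neutral_expectation")
}
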