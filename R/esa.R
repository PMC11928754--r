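#' Enhanced generalized suffix array over m sequences
#'
#' Builds the suffix array (within-document, 1-based), document array,
#' LCP array and BWT over `m` sentinel-terminated symbol sequences. The
#' per-document sentinels satisfy `#1 < #2 < ... < #m` and are smaller
#' than every alphabet symbol, so equal suffixes from different documents
#' sort by document index, and the suffix consisting only of the sentinel
#' is the smallest suffix of its document. The same construction serves
#' the base level (character sequences) and the parse level (integer rank
#' sequences).
#'
#' @param seqs Either a character vector (each element one sequence) or a
#'   list of positive integer vectors. All sequences must be non-empty.
#' @return An object of class `pm_gsa`: a list with
#'   * `SA`: within-document suffix start positions (1-based; position
#'     `n_j + 1` is the sentinel-only suffix of document j);
#'   * `DA`: document index per suffix-array row;
#'   * `LCP`: longest-common-prefix lengths, `LCP[1] = -1`; a virtual
#'     `LCP[n + 1] = -1` is implied;
#'   * `BWT`: coded preceding symbol per row (codes `1..m` are the
#'     sentinels `#j`, larger codes are alphabet symbols);
#'   * `n`: total number of suffixes, `m + sum(n_j)`;
#'   * `m`, `doc_len` (lengths without sentinel) and the coded
#'     concatenation `concat` used internally.
#' @export
build_gsa <- function(seqs) {
  if (is.character(seqs)) seqs <- lapply(seqs, utf8ToInt)
  stopifnot(is.list(seqs), length(seqs) >= 1L)
  m <- length(seqs)
  seqs <- unname(seqs)
  lens <- vapply(seqs, length, integer(1))
  if (any(lens == 0L)) stop("all sequences must be non-empty")
  if (any(vapply(seqs, function(s) anyNA(s) || any(s < 1L), logical(1))))
    stop("symbol codes must be positive integers")
  # sentinel #j -> code j; alphabet symbol x -> code x + m
  coded <- vector("list", m)
  for (j in seq_len(m)) coded[[j]] <- c(seqs[[j]] + m, j)
  s <- unlist(coded, use.names = FALSE)
  n <- length(s)
  sa_global <- suffix_array_doubling(s)
  doc_start <- cumsum(c(1L, lens[-m] + 1L))     # global start of each doc
  da <- findInterval(sa_global, doc_start)
  sa <- sa_global - doc_start[da] + 1L
  lcp <- .pm_kasai(s, sa_global)
  bwt <- s[pmax(sa_global - 1L, 1L)]
  bwt[sa == 1L] <- da[sa == 1L]
  structure(list(SA = sa, DA = da, LCP = lcp, BWT = as.integer(bwt),
                 n = n, m = m, doc_len = lens, concat = s,
                 doc_start = doc_start),
            class = "pm_gsa")
}

# Prefix-doubling suffix sort (Manber-Myers) driven by order(); the
# distinct sentinels guarantee all ranks become unique. O(n log^2 n) but
# each pass is a radix sort in C, which is fast enough up to a few
# million symbols.
suffix_array_doubling <- function(s) {
  n <- length(s)
  if (n == 1L) return(1L)
  rk <- match(s, sort.int(unique(s), method = "radix"))
  k <- 1L
  while (max(rk) < n) {
    key2 <- if (k < n) c(rk[-seq_len(k)], integer(k)) else integer(n)
    o <- order(rk, key2, method = "radix")
    r1 <- rk[o]; r2 <- key2[o]
    changed <- c(TRUE, r1[-1L] != r1[-n] | r2[-1L] != r2[-n])
    rk[o] <- cumsum(changed)
    k <- k * 2L
  }
  order(rk, method = "radix")
}

#' Enumerate all lcp-intervals of an enhanced GSA
#'
#' An lcp-interval of value `ell` is a maximal run `[lb..rb]` (`lb < rb`)
#' with `LCP[k] >= ell` for `lb < k <= rb`, equality for at least one such
#' `k`, and `LCP[lb] < ell`, `LCP[rb + 1] < ell`. These are exactly the
#' internal nodes of the generalized suffix tree, so there are at most
#' `n - 1` of them; they are enumerated in linear time with the classic
#' stack algorithm.
#'
#' @param gsa A [build_gsa()] result.
#' @param min_ell Smallest lcp-value to report (default 1; pass 0 to also
#'   get the root interval when it qualifies).
#' @return A data frame with columns `ell`, `lb`, `rb`, `width`.
#' @export
enumerate_lcp_intervals <- function(gsa, min_ell = 1L) {
  stopifnot(inherits(gsa, "pm_gsa"))
  m <- .pm_lcp_intervals(gsa$LCP, as.integer(min_ell))
  data.frame(ell = m[, 1L], lb = m[, 2L], rb = m[, 3L],
             width = m[, 3L] - m[, 2L] + 1L)
}

# String (coded symbols, without the +m offset) spelled by the first
# `ell` symbols of the suffix at GSA row i.
gsa_row_prefix <- function(gsa, i, ell) {
  g <- gsa$doc_start[gsa$DA[i]] + gsa$SA[i] - 1L
  gsa$concat[g:(g + ell - 1L)] - gsa$m
}
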