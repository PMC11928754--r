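#' Fragment sets
#'
#' A fragment is a (possibly partial) multiMUM together with a chaining
#' weight. Fragment sets are stored column-wise: `len[i]` is the match
#' length in symbols, `pos[i, k]` the 1-based start in sequence `k` (`NA`
#' where the fragment is absent), `weight[i]` the chaining weight.
#'
#' @param len Integer vector of match lengths.
#' @param pos Integer matrix, one row per fragment, one column per
#'   sequence; `NA` marks absence.
#' @param weight Numeric weights (defaults to `len`).
#' @param level `"parse"` or `"base"`.
#' @return An object of class `pm_fragments`.
#' @export
pm_fragments <- function(len, pos, weight = len, level = "base") {
  if (is.null(dim(pos))) pos <- matrix(pos, nrow = length(len))
  stopifnot(length(len) == nrow(pos), length(weight) == length(len))
  structure(list(len = as.integer(len), pos = pos,
                 weight = as.numeric(weight), level = level),
            class = "pm_fragments")
}

#' @export
length.pm_fragments <- function(x) length(x$len)

frag_subset <- function(f, idx) {
  pm_fragments(f$len[idx], f$pos[idx, , drop = FALSE], f$weight[idx],
               f$level)
}

# occurrence count per fragment
frag_occ <- function(f) rowSums(!is.na(f$pos))

#' Find multiMUMs via the lcp-interval test
#'
#' A multiMUM is a substring occurring exactly once in each of the m
#' sequences that cannot be extended simultaneously left or right without
#' a mismatch in some pair. multiMUMs correspond one-to-one to
#' lcp-intervals of width exactly m whose document-array entries are
#' pairwise distinct and whose BWT entries are not all equal (the latter
#' is left-maximality; right-maximality is implied by lcp-interval-hood).
#'
#' @param gsa A [build_gsa()] result over the m sequences.
#' @param min_length Discard multiMUMs shorter than this many symbols
#'   (default 1 keeps everything).
#' @return A [pm_fragments()] object; positions are 1-based starts.
#' @examples
#' g <- build_gsa(c("ABCA", "BCAC", "ABCD"))
#' f <- find_multimums(g)   # the single multiMUM "BC": length 2 at 2,1,2
#' @export
find_multimums <- function(gsa, min_length = 1L) {
  collect_mums(gsa, min_width = gsa$m, min_length = min_length)
}

#' Find partial multiMUMs
#'
#' A partial multiMUM is a multiMUM of a subset of the sequences; absent
#' sequences are marked `NA`. The detection test is the same as in
#' [find_multimums()] with the width condition relaxed to
#' `min_occ <= width <= m`. The default `min_occ` of `floor(m/2) + 1`
#' (occurrence in more than half of the sequences) is what guarantees
#' that any two compatible partial fragments are comparable, so chains
#' can be totally ordered.
#'
#' @inheritParams find_multimums
#' @param min_occ Minimum number of sequences a partial multiMUM must
#'   occur in.
#' @return A [pm_fragments()] object with `NA` positions for absent
#'   sequences.
#' @export
find_partial_multimums <- function(gsa, min_occ = floor(gsa$m / 2) + 1L,
                                   min_length = 1L) {
  collect_mums(gsa, min_width = max(2L, as.integer(min_occ)),
               min_length = min_length)
}

collect_mums <- function(gsa, min_width, min_length) {
  m <- gsa$m
  iv <- enumerate_lcp_intervals(gsa, min_ell = max(1L, as.integer(min_length)))
  iv <- iv[iv$width >= min_width & iv$width <= m, , drop = FALSE]
  keep_len <- integer(0)
  keep_pos <- list()
  for (r in seq_len(nrow(iv))) {
    lb <- iv$lb[r]; rb <- iv$rb[r]
    da <- gsa$DA[lb:rb]
    if (anyDuplicated(da)) next
    bwt <- gsa$BWT[lb:rb]
    if (all(bwt == bwt[1L])) next     # left-extendable in every sequence
    p <- rep(NA_integer_, m)
    p[da] <- gsa$SA[lb:rb]
    keep_len <- c(keep_len, iv$ell[r])
    keep_pos[[length(keep_pos) + 1L]] <- p
  }
  pos <- if (length(keep_pos)) do.call(rbind, keep_pos) else
    matrix(integer(0), nrow = 0L, ncol = m)
  pm_fragments(keep_len, pos)
}
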