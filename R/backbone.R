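#' Anchor sets
#'
#' An anchor is a region fixed into the alignment: per-sequence 1-based
#' start positions (`NA` for absent sequences), a common length, and the
#' column offsets (1-based, within the anchor) where not all sequences
#' agree -- these arise from extension across isolated mismatches and are
#' candidate SNPs.
#'
#' @param start Integer matrix (anchors x sequences) of 1-based starts.
#' @param len Integer vector of anchor lengths.
#' @param mism List of integer vectors of mismatch column offsets.
#' @return An object of class `pm_anchors`.
#' @export
pm_anchors <- function(start, len, mism = rep(list(integer(0)), length(len))) {
  if (is.null(dim(start))) start <- matrix(start, nrow = length(len))
  stopifnot(nrow(start) == length(len), length(mism) == length(len))
  structure(list(start = start, len = as.integer(len), mism = mism),
            class = "pm_anchors")
}

#' @export
length.pm_anchors <- function(x) length(x$len)

#' Lift a parse-level chain to base-level anchors
#'
#' Replaces each meta-symbol span of a parse-level fragment with its
#' phrases: the fragment becomes an exact base-level match whose length
#' is the summed phrase length and whose start in sequence `k` is the
#' base offset of the first phrase. Because equal meta-symbols expand to
#' identical phrases, the lifted substrings are base-identical across
#' sequences.
#'
#' @param chain A `pm_chain` of parse-level fragments.
#' @param pfp The [pfp_parse()] result the fragments were found on.
#' @return A [pm_anchors()] object.
#' @export
lift_to_base <- function(chain, pfp) {
  f <- chain$frags
  k <- length(f)
  m <- ncol(f$pos)
  if (k == 0L)
    return(pm_anchors(matrix(integer(0), 0L, m), integer(0), list()))
  start <- matrix(NA_integer_, k, m)
  len <- integer(k)
  for (i in seq_len(k)) {
    for (s in seq_len(m)) {
      p <- f$pos[i, s]
      if (is.na(p)) next
      parse <- pfp$parses[[s]]
      start[i, s] <- parse$starts[p]
      w <- pfp_base_weight(parse, pfp$dict, p, p + f$len[i] - 1L)
      if (len[i] == 0L) len[i] <- w
      else if (len[i] != w) stop("inconsistent base weight across sequences")
    }
  }
  pm_anchors(start, len)
}

# Length of the run of columns immediately left of `starts` (exclusive)
# on which all sequences agree; bounded by `maxr`. Chunked vectorised scan.
run_left <- function(seqs, cols, starts, maxr) {
  if (maxr <= 0L) return(0L)
  r <- 0L
  chunk <- 1024L
  while (r < maxr) {
    b <- min(chunk, maxr - r)
    M <- vapply(seq_along(cols), function(ii) {
      k <- cols[ii]
      seqs[[k]][(starts[ii] - r - b):(starts[ii] - r - 1L)]
    }, integer(b))
    M <- matrix(M, nrow = b)
    agree <- rowSums(M == M[, 1L]) == ncol(M)
    bad <- which(!rev(agree))           # scan from the right end backwards
    if (length(bad)) return(r + bad[1L] - 1L)
    r <- r + b
  }
  r
}

run_right <- function(seqs, cols, ends, maxr) {
  if (maxr <= 0L) return(0L)
  r <- 0L
  chunk <- 1024L
  while (r < maxr) {
    b <- min(chunk, maxr - r)
    M <- vapply(seq_along(cols), function(ii) {
      k <- cols[ii]
      seqs[[k]][(ends[ii] + r + 1L):(ends[ii] + r + b)]
    }, integer(b))
    M <- matrix(M, nrow = b)
    agree <- rowSums(M == M[, 1L]) == ncol(M)
    bad <- which(!agree)
    if (length(bad)) return(r + bad[1L] - 1L)
    r <- r + b
  }
  r
}

#' Extend an anchor across isolated mismatches
#'
#' Starting from an exact match, the anchor is extended base-by-base,
#' simultaneously in all sequences it occurs in: first fully to the left,
#' then fully to the right. When a mismatch is hit, it is crossed (and
#' recorded as a mismatch column) only if at least `min_match` bases then
#' match exactly in all sequences before the next mismatch or a bound --
#' an isolated mismatch is most likely a SNP. Only substitution-style
#' crossings are made: every sequence advances exactly one base.
#' Extension never crosses sequence ends or the given bounds.
#'
#' @param seqs_int List of integer-coded sequences.
#' @param start Per-sequence 1-based anchor starts (`NA` = absent).
#' @param len Anchor length.
#' @param min_match Matching run required to cross a mismatch
#'   (default 10).
#' @param lo,hi Per-sequence inclusive bounds the extension must stay
#'   within (e.g. neighbouring anchors); default whole sequence.
#' @return A list `start`, `len`, `mism` (1-based mismatch column
#'   offsets within the extended anchor).
#' @export
extend_anchor <- function(seqs_int, start, len, min_match = 10L,
                          lo = NULL, hi = NULL) {
  cols <- which(!is.na(start))
  if (is.null(lo)) lo <- rep(1L, length(start))
  if (is.null(hi)) hi <- vapply(seqs_int, length, integer(1))
  st <- start[cols]
  lo <- lo[cols]; hi <- hi[cols]
  en <- st + len - 1L
  mism_left <- integer(0)    # distance d: mismatch at st - d (pre-extension)
  # --- left ---
  repeat {
    r <- run_left(seqs_int, cols, st, min(st - lo))
    st <- st - r
    if (min(st - lo) == 0L) break
    # mismatch at st - 1; cross iff min_match further bases match
    if (min(st - 1L - lo) < min_match) break
    r2 <- run_left(seqs_int, cols, st - 1L, min(st - 1L - lo))
    if (r2 < min_match) break
    mism_left <- c(mism_left, start[cols][1L] - (st[1L] - 1L))
    st <- st - 1L
  }
  # --- right ---
  mism_right <- integer(0)
  repeat {
    r <- run_right(seqs_int, cols, en, min(hi - en))
    en <- en + r
    if (min(hi - en) == 0L) break
    if (min(hi - (en + 1L)) < min_match) break
    r2 <- run_right(seqs_int, cols, en + 1L, min(hi - en - 1L))
    if (r2 < min_match) break
    mism_right <- c(mism_right, (en[1L] + 1L) - start[cols][1L] + 1L)
    en <- en + 1L
  }
  new_len <- en[1L] - st[1L] + 1L
  left_ext <- start[cols][1L] - st[1L]
  # convert mismatch records to offsets within the extended anchor
  mism <- sort(c(left_ext - mism_left + 1L, left_ext + mism_right))
  out_start <- start
  out_start[cols] <- st
  list(start = out_start, len = new_len, mism = mism)
}

#' Compute the alignment backbone of a sequence set
#'
#' Runs phases 1-2 of the pipeline: prefix-free parse all sequences with
#' a shared dictionary, build the parse-level enhanced GSA, find
#' multiMUMs, chain them (exact DP up to `dp_threshold` fragments, the
#' sorted-by-score heuristic above), lift the chain to the base level and
#' extend each anchor across isolated mismatches. Anchors are processed
#' left to right; each anchor's extension is bounded by its (already
#' extended) left neighbour and its unextended right neighbour.
#'
#' @param seqs Named character vector of sequences.
#' @param params A [pm_config()] list (see [run_pipeline()]).
#' @return List with `anchors` (a [pm_anchors()]), `gaps` (see
#'   [gaps_between()]), `pfp`, and counters `n_mums`, `n_extensions`.
#' @export
build_backbone <- function(seqs, params = pm_config()) {
  m <- length(seqs)
  stopifnot(m >= 2L)
  pfp <- pfp_parse(seqs, pfp_params(params$window, params$modulus))
  gsa <- build_gsa(lapply(pfp$parses, `[[`, "symbols"))
  mums <- find_multimums(gsa)
  seqs_int <- lapply(seqs, utf8ToInt)
  lens <- vapply(seqs_int, length, integer(1))
  if (length(mums) == 0L) {
    empty <- pm_anchors(matrix(integer(0), 0L, m), integer(0), list())
    return(list(anchors = empty, anchors_raw = empty,
                gaps = gaps_between(NULL, lens), pfp = pfp,
                n_mums = 0L, n_extensions = 0L))
  }
  # weight = expanded base count of the symbol span
  mums$weight <- vapply(seq_len(length(mums)), function(i) {
    s <- which(!is.na(mums$pos[i, ]))[1L]
    p <- mums$pos[i, s]
    as.numeric(pfp_base_weight(pfp$parses[[s]], pfp$dict, p,
                               p + mums$len[i] - 1L))
  }, numeric(1))
  mums$level <- "parse"
  mums <- frag_subset(mums, which(mums$len >= params$min_mum_symbols))
  chain <- if (length(mums) <= params$dp_threshold) chain_dp(mums) else
    chain_heuristic(mums)
  anchors_raw <- lift_to_base(chain, pfp)
  ext <- extend_anchors(seqs_int, anchors_raw, params$extension_min_match)
  gaps <- gaps_between(ext$anchors, lens)
  list(anchors = ext$anchors, anchors_raw = anchors_raw, gaps = gaps,
       pfp = pfp, n_mums = length(chain$idx),
       n_extensions = ext$n_extensions)
}

# Extend every anchor of a backbone, left to right, with first-come
# bounds: the left bound is the previous anchor's extended end, the right
# bound the next anchor's current (unextended) start.
extend_anchors <- function(seqs_int, anchors, min_match) {
  k <- length(anchors)
  m <- ncol(anchors$start)
  lens <- vapply(seqs_int, length, integer(1))
  if (k == 0L) return(list(anchors = anchors, n_extensions = 0L))
  prev_end <- rep(0L, m)
  n_ext <- 0L
  for (i in seq_len(k)) {
    lo <- prev_end + 1L
    hi <- if (i < k) {
      nx <- anchors$start[i + 1L, ]
      ifelse(is.na(nx), lens, nx - 1L)
    } else lens
    e <- extend_anchor(seqs_int, anchors$start[i, ], anchors$len[i],
                       min_match, lo, hi)
    anchors$start[i, ] <- e$start
    anchors$len[i] <- e$len
    anchors$mism[[i]] <- e$mism
    n_ext <- n_ext + length(e$mism)
    occ <- !is.na(e$start)
    prev_end[occ] <- e$start[occ] + e$len - 1L
  }
  list(anchors = anchors, n_extensions = n_ext)
}

#' Per-sequence gaps between consecutive anchors
#'
#' @param anchors A [pm_anchors()] object (all-present anchors), or
#'   `NULL` for an empty backbone.
#' @param lens Integer vector of sequence lengths.
#' @return List of gaps; each gap is a list with `start`, `end`
#'   (per-sequence 1-based inclusive bounds; `end < start` means the gap
#'   is empty in that sequence) and `left`, `right` anchor indices (0 =
#'   backbone end).
#' @export
gaps_between <- function(anchors, lens) {
  m <- length(lens)
  if (is.null(anchors) || length(anchors) == 0L) {
    return(list(list(start = rep(1L, m), end = lens, left = 0L, right = 0L)))
  }
  k <- length(anchors)
  gaps <- vector("list", k + 1L)
  prev_end <- rep(0L, m)
  for (i in seq_len(k)) {
    st <- anchors$start[i, ]
    cur <- ifelse(is.na(st), prev_end, st - 1L)
    gaps[[i]] <- list(start = prev_end + 1L, end = as.integer(cur),
                      left = i - 1L, right = i)
    occ <- !is.na(st)
    prev_end[occ] <- st[occ] + anchors$len[i] - 1L
  }
  gaps[[k + 1L]] <- list(start = prev_end + 1L, end = lens,
                         left = k, right = 0L)
  gaps
}
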