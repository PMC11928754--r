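#' Does one fragment precede another?
#'
#' `f` precedes `g` (written `f` \eqn{\ll} `g`) when the two fragments are
#' colinear and non-overlapping: `f` ends strictly before `g` starts in
#' every sequence on which both are compared. For partial fragments the
#' comparison runs over the sequences where both occur; two fragments
#' sharing no sequence are incomparable (`FALSE` both ways).
#'
#' @param frags A [pm_fragments()] object.
#' @param i,j Fragment indices.
#' @return `TRUE` iff fragment `i` precedes fragment `j`.
#' @export
precedes <- function(frags, i, j) {
  if (i == j) return(FALSE)
  fi <- frags$pos[i, ]; fj <- frags$pos[j, ]
  common <- !is.na(fi) & !is.na(fj)
  if (!any(common)) return(FALSE)
  all(fi[common] + frags$len[i] - 1L < fj[common])
}

# Vectorised predecessor test: which of the fragments in `idx` precede
# fragment j? ends/pos are the fragment matrices.
precedes_which <- function(ends, pos, idx, j) {
  if (length(idx) == 0L) return(logical(0))
  pj <- pos[j, ]
  e <- ends[idx, , drop = FALSE]
  cmp <- sweep(e, 2L, pj, `<`)                 # NA where either absent
  common <- !is.na(cmp)
  ok <- rowSums(cmp & common) == rowSums(common) & rowSums(common) > 0L
  ok
}

chain_result <- function(frags, idx, score) {
  structure(list(frags = frag_subset(frags, idx), idx = idx,
                 score = score), class = "pm_chain")
}

#' Optimal global fragment chain by dynamic programming
#'
#' Maximises the summed weight of a chain `0` \eqn{\ll f_1 \ll \dots \ll
#' f_j \ll} `t` under the recurrence
#' `score(f') = weight(f') + max(0, score(f) : f` \eqn{\ll} `f')`.
#' Quadratic in the number of fragments; intended for fragment sets where
#' every fragment occurs in the sequence used for the processing order
#' (the first sequence with no absences). Ties between equal-score
#' predecessors are broken deterministically: smaller end position in the
#' ordering sequence, then smaller fragment index.
#'
#' @param frags A [pm_fragments()] object.
#' @return A `pm_chain`: `frags` (the chain in \eqn{\ll} order), `idx`
#'   (indices into the input) and `score`. Empty input gives an empty
#'   chain of score 0.
#' @export
chain_dp <- function(frags) {
  k <- length(frags)
  if (k == 0L) return(chain_result(frags, integer(0), 0))
  full_col <- which(colSums(is.na(frags$pos)) == 0L)
  if (length(full_col) == 0L)
    stop("chain_dp needs at least one sequence in which every fragment occurs")
  oc <- full_col[1L]
  ends <- frags$pos + frags$len - 1L
  ord <- order(frags$pos[, oc], seq_len(k))
  score <- numeric(k); pred <- integer(k)
  for (jj in seq_len(k)) {
    j <- ord[jj]
    prev <- ord[seq_len(jj - 1L)]
    ok <- precedes_which(ends, frags$pos, prev, j)
    best <- 0; bp <- 0L
    if (any(ok)) {
      cand <- prev[ok]
      sc <- score[cand]
      top <- which(sc == max(sc))
      cand <- cand[top]
      # deterministic tie-break: smaller end in ordering sequence, then id
      cand <- cand[order(ends[cand, oc], cand)]
      bp <- cand[1L]
      best <- score[bp]
    }
    score[j] <- frags$weight[j] + best
    pred[j] <- bp
  }
  top <- which(score == max(score))
  top <- top[order(ends[top, oc], top)]
  at <- top[1L]
  path <- integer(0)
  while (at != 0L) { path <- c(at, path); at <- pred[at] }
  chain_result(frags, path, score[top[1L]])
}

#' Sorted-by-score chaining heuristic
#'
#' Processes fragments by increasing position in the ordering sequence
#' and, for each, scans the already-processed fragments in decreasing
#' score, taking the first valid predecessor. Expected near-linear when
#' an optimal chain contains almost all fragments; always returns a valid
#' chain, but the score can be suboptimal on adversarial inputs.
#'
#' @inheritParams chain_dp
#' @return A `pm_chain` (see [chain_dp()]).
#' @export
chain_heuristic <- function(frags) {
  k <- length(frags)
  if (k == 0L) return(chain_result(frags, integer(0), 0))
  full_col <- which(colSums(is.na(frags$pos)) == 0L)
  if (length(full_col) == 0L)
    stop("chain_heuristic needs a sequence in which every fragment occurs")
  oc <- full_col[1L]
  ends <- frags$pos + frags$len - 1L
  ord <- order(frags$pos[, oc], seq_len(k))
  score <- numeric(k); pred <- integer(k)
  proc <- integer(0)          # processed ids, kept sorted by score desc
  for (jj in seq_len(k)) {
    j <- ord[jj]
    best <- 0; bp <- 0L
    for (i in proc) {
      if (precedes(frags, i, j)) { bp <- i; best <- score[i]; break }
    }
    score[j] <- frags$weight[j] + best
    pred[j] <- bp
    proc <- c(proc, j)
    proc <- proc[order(-score[proc], ends[proc, oc], proc)]
  }
  top <- which(score == max(score))
  top <- top[order(ends[top, oc], top)]
  at <- top[1L]
  path <- integer(0)
  while (at != 0L) { path <- c(at, path); at <- pred[at] }
  chain_result(frags, path, score[top[1L]])
}

#' Chain partial fragments via the k-sequence subset heuristic
#'
#' Chaining partial fragments directly is hard because \eqn{\ll} loses
#' transitivity; instead, for each `k` from `floor(m/2) + 1` to `m`, the
#' `k` sequences with the most fragment bases are selected (ties: lower
#' sequence index) and only the fragments occurring in *all* of them are
#' chained, each weighted by the total bases it covers (length times
#' occurrence count). The chain covering the most bases over all `k`
#' wins.
#'
#' @param partials A [pm_fragments()] object; every fragment must occur
#'   in more than half of the eligible sequences.
#' @param m Number of sequences eligible for chaining (defaults to the
#'   number of columns of `partials$pos`).
#' @param seqs Indices of the eligible sequences themselves; useful when
#'   some sequences of the set cannot host fragments (e.g. empty gap
#'   intervals). Defaults to all.
#' @param use_dp Use [chain_dp()] (default) or [chain_heuristic()].
#' @return A `pm_chain` over the original fragment set (indices refer to
#'   `partials`); attribute `"k_seqs"` records the selected sequences.
#' @export
select_subset_chain <- function(partials, m = ncol(partials$pos),
                                seqs = NULL, use_dp = TRUE) {
  if (is.null(seqs)) seqs <- seq_len(m)
  m <- length(seqs)
  if (length(partials) == 0L)
    return(chain_result(partials, integer(0), 0))
  occ <- !is.na(partials$pos)
  base_per_seq <- colSums(occ[, seqs, drop = FALSE] * partials$len)
  kmin <- floor(m / 2) + 1L
  best <- NULL; best_cov <- -1; best_seqs <- integer(0)
  for (k in kmin:m) {
    sel <- seqs[order(-base_per_seq, seq_len(m))[seq_len(k)]]
    in_all <- rowSums(occ[, sel, drop = FALSE]) == k
    if (!any(in_all)) next
    idx <- which(in_all)
    sub <- frag_subset(partials, idx)
    sub$pos <- sub$pos[, sel, drop = FALSE]
    sub$weight <- sub$len * frag_occ(frag_subset(partials, idx))
    ch <- if (use_dp) chain_dp(sub) else chain_heuristic(sub)
    cov <- ch$score                       # score == bases covered here
    if (cov > best_cov) {
      best_cov <- cov
      best <- chain_result(partials, idx[ch$idx], ch$score)
      best_seqs <- sel
    }
  }
  if (is.null(best)) return(chain_result(partials, integer(0), 0))
  attr(best, "k_seqs") <- sort(best_seqs)
  best
}

#' Re-add fragment occurrences per sequence (heaviest increasing subsequence)
#'
#' Given a chain whose fragment order is fixed, candidate occurrences for
#' absent `(fragment, sequence)` slots are selected per sequence
#' independently: a maximum-weight subset whose positions are strictly
#' increasing (and non-overlapping) consistently with the chain order and
#' with the fragments already placed in that sequence. Candidates for
#' slots that already have a position, or that cannot fit between the
#' surrounding placed fragments, are discarded.
#'
#' @param chain A `pm_chain`.
#' @param candidates Data frame with columns `seq` (sequence index),
#'   `frag` (position of the fragment in the chain order), `pos` (1-based
#'   candidate start), `len` (match length) and `weight`.
#' @return The chain with accepted candidates filled into `frags$pos`.
#' @export
his_augment <- function(chain, candidates) {
  if (is.null(candidates) || nrow(candidates) == 0L) return(chain)
  f <- chain$frags
  K <- length(f)
  for (s in unique(candidates$seq)) {
    cand <- candidates[candidates$seq == s, , drop = FALSE]
    fixed <- which(!is.na(f$pos[, s]))
    cand <- cand[is.na(f$pos[cand$frag, s]), , drop = FALSE]
    if (nrow(cand) == 0L) next
    # window each candidate between the surrounding placed fragments
    lo <- vapply(cand$frag, function(t) {
      pr <- fixed[fixed < t]
      if (length(pr)) max(f$pos[pr, s] + f$len[pr]) else 1L
    }, numeric(1))
    hi <- vapply(cand$frag, function(t) {
      nx <- fixed[fixed > t]
      if (length(nx)) min(f$pos[nx, s]) - 1L else Inf
    }, numeric(1))
    ok <- cand$pos >= lo & cand$pos + cand$len - 1L <= hi
    cand <- cand[ok, , drop = FALSE]
    if (nrow(cand) == 0L) next
    # independent segments between consecutive fixed fragments
    seg <- findInterval(cand$frag, fixed + 0.5)
    for (g in unique(seg)) {
      cc <- cand[seg == g, , drop = FALSE]
      pick <- his_select(cc)
      if (length(pick)) {
        cc <- cc[pick, , drop = FALSE]
        f$pos[cbind(cc$frag, rep(s, nrow(cc)))] <- as.integer(cc$pos)
      }
    }
  }
  chain$frags <- f
  chain
}

# Max-weight subset of candidates with strictly increasing fragment order
# and non-overlapping increasing positions; at most one candidate per
# fragment slot. Quadratic DP. Returns row indices.
his_select <- function(cand) {
  nc <- nrow(cand)
  if (nc == 0L) return(integer(0))
  o <- order(cand$frag, cand$pos)
  cand <- cand[o, , drop = FALSE]
  best <- cand$weight; pred <- integer(nc)
  for (j in seq_len(nc)) {
    for (i in seq_len(j - 1L)) {
      compat <- cand$frag[i] < cand$frag[j] &&
        cand$pos[i] + cand$len[i] - 1L < cand$pos[j]
      if (compat && best[i] + cand$weight[j] > best[j]) {
        best[j] <- best[i] + cand$weight[j]
        pred[j] <- i
      }
    }
  }
  at <- which.max(best)
  path <- integer(0)
  while (at != 0L) { path <- c(at, path); at <- pred[at] }
  o[path]
}

#' Check that fragments admit a linear order under \eqn{\ll}
#'
#' Fragments occurring in more than half of the sequences are pairwise
#' either incompatible or comparable; this verifies comparability and
#' returns the linear order. Fragments involved in violations (crossing
#' pairs) are excluded greedily, lightest first.
#'
#' @param frags A [pm_fragments()] object.
#' @return List with `order` (fragment indices in \eqn{\ll} order) and
#'   `excluded` (indices dropped because of violations).
#' @export
order_check <- function(frags) {
  k <- length(frags)
  excluded <- integer(0)
  active <- seq_len(k)
  repeat {
    na <- length(active)
    if (na <= 1L) break
    P <- matrix(FALSE, na, na)
    for (a in seq_len(na)) for (b in seq_len(na)) {
      if (a != b) P[a, b] <- precedes(frags, active[a], active[b])
    }
    viol <- which(!P & !t(P) & upper.tri(P), arr.ind = TRUE)
    if (nrow(viol) == 0L) {
      ord <- order(-rowSums(P), active)
      # a non-transitive tournament (cycle) can survive the pairwise
      # check; verify the produced order and keep excluding if needed
      bad <- NULL
      for (t in seq_len(na - 1L)) {
        if (!P[ord[t], ord[t + 1L]]) { bad <- c(ord[t], ord[t + 1L]); break }
      }
      if (is.null(bad))
        return(list(order = active[ord], excluded = excluded))
      viol <- matrix(bad, nrow = 1L)
    }
    pair <- active[c(viol[1L, 1L], viol[1L, 2L])]
    drop <- pair[order(frags$weight[pair], pair)][1L]
    excluded <- c(excluded, drop)
    active <- setdiff(active, drop)
  }
  list(order = active, excluded = excluded)
}
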