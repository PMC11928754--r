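# Independent reference implementations used to verify the package's
# algorithms on small inputs. They are deliberately naive: direct
# transcriptions of the definitions, with no shared code paths.

rnd_str <- function(n, alphabet = c("A", "B", "C")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

rnd_dna <- function(n) rnd_str(n, c("A", "C", "G", "T"))

# --- enhanced GSA oracle: sort all sentinel-terminated suffixes ---------

oracle_gsa <- function(seqs) {
  m <- length(seqs)
  # sentinels: control characters 1..m, smaller than any printable symbol
  full <- paste0(seqs, vapply(seq_len(m), intToUtf8, character(1)))
  suf <- list()
  for (j in seq_len(m)) {
    nj <- nchar(full[j])
    for (k in seq_len(nj))
      suf[[length(suf) + 1L]] <- list(doc = j, pos = k,
                                      txt = substring(full[j], k))
  }
  txts <- vapply(suf, `[[`, character(1), "txt")
  o <- order(txts, method = "radix")
  sa <- vapply(suf, `[[`, integer(1), "pos")[o]
  da <- vapply(suf, `[[`, integer(1), "doc")[o]
  n <- length(o)
  lcp <- integer(n)
  lcp[1] <- -1L
  lcp_pair <- function(a, b) {
    la <- nchar(a); lb <- nchar(b); l <- 0L
    while (l < min(la, lb) &&
           substr(a, l + 1L, l + 1L) == substr(b, l + 1L, l + 1L)) l <- l + 1L
    l
  }
  st <- txts[o]
  for (i in seq_len(n - 1L)) lcp[i + 1L] <- lcp_pair(st[i], st[i + 1L])
  list(SA = sa, DA = da, LCP = lcp, n = n)
}

# --- lcp-interval oracle: check the four defining conditions ------------

oracle_lcp_intervals <- function(lcp, min_ell = 1L) {
  n <- length(lcp)
  out <- list()
  lcp_ext <- c(lcp, -1L)                 # virtual LCP[n+1]
  for (lb in seq_len(n - 1L)) {
    for (rb in (lb + 1L):n) {
      inner <- lcp_ext[(lb + 1L):rb]
      ell <- min(inner)
      if (ell < min_ell) next
      if (lcp_ext[lb] < ell && lcp_ext[rb + 1L] < ell)
        out[[length(out) + 1L]] <- c(ell = ell, lb = lb, rb = rb)
    }
  }
  if (length(out) == 0L)
    return(data.frame(ell = integer(0), lb = integer(0), rb = integer(0)))
  df <- as.data.frame(do.call(rbind, out))
  df[order(df$lb, df$rb), , drop = FALSE]
}

# --- multiMUM oracle: enumerate substrings, check the definition --------

# all (possibly overlapping) occurrence start positions
count_occurrences <- function(pattern, s) {
  l <- nchar(pattern); n <- nchar(s)
  if (l > n) return(integer(0))
  i <- seq_len(n - l + 1L)
  i[substring(s, i, i + l - 1L) == pattern]
}

# All (partial) multiMUMs with occurrence in >= min_occ sequences and in
# no others (absence elsewhere mirrors the interval method's width
# semantics). Sentinel convention: position 0 / past-the-end count as
# per-sequence distinct characters for maximality.
oracle_multimums <- function(seqs, min_occ = length(seqs)) {
  m <- length(seqs)
  subs <- unique(unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    unlist(lapply(seq_len(n), function(i)
      substring(s, i, i:n)))
  })))
  res <- list()
  for (w in subs) {
    ell <- nchar(w)
    occ <- lapply(seqs, count_occurrences, pattern = w)
    cnt <- lengths(occ)
    if (any(cnt > 1L)) next
    S <- which(cnt == 1L)
    if (length(S) < min_occ) next
    pos <- vapply(occ[S], `[[`, integer(1), 1L)
    # left-maximal: some pair of preceding characters differs (position 1
    # precedes with a per-sequence sentinel, always distinct)
    prevc <- ifelse(pos == 1L, paste0("#", S),
                    substring(seqs[S], pos - 1L, pos - 1L))
    nextc <- ifelse(pos + ell - 1L == nchar(seqs[S]), paste0("$", S),
                    substring(seqs[S], pos + ell, pos + ell))
    if (length(unique(prevc)) <= 1L) next
    if (length(unique(nextc)) <= 1L) next
    p <- rep(NA_integer_, m)
    p[S] <- pos
    res[[length(res) + 1L]] <- list(len = ell, pos = p)
  }
  res
}

# canonical string form of a fragment set, for set comparison
mum_key <- function(len, pos) {
  if (length(len) == 0L) return(character(0))
  sort(paste(len, apply(pos, 1L, paste, collapse = ","), sep = ":"))
}

# --- chaining oracle: exhaustive subset enumeration ---------------------

# For full-occupancy fragments the precedes relation is transitive, so a
# subset is a chain iff, sorted by start in sequence 1, consecutive
# fragments satisfy precedes.
oracle_best_chain <- function(frags) {
  k <- length(frags)
  if (k == 0L) return(0)
  best <- 0
  for (mask in seq_len(2^k) - 1L) {
    idx <- which(bitwAnd(mask, 2^(seq_len(k) - 1L)) > 0L)
    if (length(idx) == 0L) next
    idx <- idx[order(frags$pos[idx, 1L])]
    ok <- TRUE
    if (length(idx) > 1L) {
      for (t in seq_len(length(idx) - 1L)) {
        if (!precedes(frags, idx[t], idx[t + 1L])) { ok <- FALSE; break }
      }
      # transitivity check across all pairs, to be safe
      if (ok && length(idx) > 2L) {
        for (a in seq_along(idx)) for (b in seq_along(idx)) {
          if (a < b && !precedes(frags, idx[a], idx[b])) ok <- FALSE
        }
      }
    }
    if (ok) best <- max(best, sum(frags$weight[idx]))
  }
  best
}

# --- HIS oracle: exhaustive subset enumeration --------------------------

# candidates: data.frame(frag, pos, len, weight); fixed: data.frame(frag,
# pos, len) already placed in the same sequence. Returns the maximum
# total candidate weight over subsets consistent with the fixed anchors
# and the chain order.
oracle_his <- function(candidates, fixed) {
  # a candidate for an already-placed slot is discarded by contract
  candidates <- candidates[!candidates$frag %in% fixed$frag, , drop = FALSE]
  nc <- nrow(candidates)
  best <- 0
  for (mask in seq_len(2^nc) - 1L) {
    idx <- which(bitwAnd(mask, 2^(seq_len(nc) - 1L)) > 0L)
    sel <- candidates[idx, , drop = FALSE]
    if (anyDuplicated(sel$frag)) next
    all_items <- rbind(
      data.frame(frag = fixed$frag, pos = fixed$pos, len = fixed$len),
      data.frame(frag = sel$frag, pos = sel$pos, len = sel$len))
    all_items <- all_items[order(all_items$frag), , drop = FALSE]
    ok <- TRUE
    if (nrow(all_items) > 1L) {
      for (t in seq_len(nrow(all_items) - 1L)) {
        if (all_items$pos[t] + all_items$len[t] - 1L >= all_items$pos[t + 1L])
          ok <- FALSE
      }
    }
    if (ok) best <- max(best, sum(sel$weight))
  }
  best
}

unaligned_block_public <- function(texts) panmum:::unaligned_block(texts)

frag_subset_public <- function(f, idx) {
  pm_fragments(f$len[idx], f$pos[idx, , drop = FALSE], f$weight[idx],
               f$level)
}

# --- small random fragment instances ------------------------------------

# Random full-occupancy fragment set over m sequences: place k intervals,
# mostly colinear, some shuffled.
rnd_fragments <- function(k, m, shuffle_prob = 0.3) {
  len <- sample(1:5, k, replace = TRUE)
  pos <- matrix(0L, k, m)
  cur <- rep(1L, m)
  for (i in seq_len(k)) {
    for (s in seq_len(m)) {
      cur[s] <- cur[s] + sample(0:3, 1L)
      pos[i, s] <- cur[s]
      cur[s] <- cur[s] + len[i]
    }
  }
  # randomly displace some fragments to create overlaps/crossings
  for (i in seq_len(k)) {
    if (runif(1) < shuffle_prob) {
      s <- sample(m, 1L)
      pos[i, s] <- sample(seq_len(max(cur)), 1L)
    }
  }
  pm_fragments(len, pos, weight = sample(1:10, k, replace = TRUE))
}

# --- exact 3-sequence sum-of-pairs alignment (tiny inputs) --------------

oracle_sp3 <- function(a, b, c) {
  A <- utf8ToInt(a); B <- utf8ToInt(b); C <- utf8ToInt(c)
  na <- length(A); nb <- length(B); nc <- length(C)
  D <- array(Inf, dim = c(na + 1L, nb + 1L, nc + 1L))
  D[1, 1, 1] <- 0
  sub <- function(x, y) if (x == y) 0L else 1L
  for (i in 0:na) for (j in 0:nb) for (k in 0:nc) {
    if (i + j + k == 0L) next
    best <- Inf
    if (i > 0 && j > 0 && k > 0)
      best <- min(best, D[i, j, k] + sub(A[i], B[j]) + sub(A[i], C[k]) +
                    sub(B[j], C[k]))
    if (i > 0 && j > 0) best <- min(best, D[i, j, k + 1] +
                                      sub(A[i], B[j]) + 2L)
    if (i > 0 && k > 0) best <- min(best, D[i, j + 1, k] +
                                      sub(A[i], C[k]) + 2L)
    if (j > 0 && k > 0) best <- min(best, D[i + 1, j, k] +
                                      sub(B[j], C[k]) + 2L)
    if (i > 0) best <- min(best, D[i, j + 1, k + 1] + 2L)
    if (j > 0) best <- min(best, D[i + 1, j, k + 1] + 2L)
    if (k > 0) best <- min(best, D[i + 1, j + 1, k] + 2L)
    D[i + 1, j + 1, k + 1] <- best
  }
  D[na + 1, nb + 1, nc + 1]
}

# sum-of-pairs cost of a set of gapped rows under unit costs
sp_cost_rows <- function(rows) {
  m <- length(rows)
  tot <- 0L
  ch <- lapply(rows, utf8ToInt)
  gap <- utf8ToInt("-")
  for (i in seq_len(m - 1L)) for (j in (i + 1L):m)
    tot <- tot + sum(ch[[i]] != ch[[j]] & !(ch[[i]] == gap & ch[[j]] == gap))
  tot
}
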