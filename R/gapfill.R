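#' Map a fragment into a gap region (built-in mapper)
#'
#' Seed-and-extend placement of a fragment text inside a target region:
#' exact seeds (21-mers from the fragment ends and middle; the whole
#' fragment when shorter) locate candidate offsets, which are scored with
#' a banded unit-cost alignment of the fragment against the same-length
#' target window. The quality score is MAPQ-like: unique near-exact hits
#' score far above 30, ambiguous placements (two candidates of similar
#' cost) score near 0. An external mapper can stand in for this via the
#' `mapper` entry of [pm_config()] (any function with this signature,
#' e.g. one built by [paf_mapper()]).
#'
#' @param fragment_text Fragment to place.
#' @param region_text Target region (the gap interval in the sequence the
#'   fragment is absent from).
#' @param params A [pm_config()] list (uses `seed_len`, `band_max`).
#' @return Data frame with columns `target_start` (1-based offset in the
#'   region), `len`, `cost`, `quality`; zero rows when nothing places.
#' @export
map_fragment <- function(fragment_text, region_text, params = pm_config()) {
  empty <- data.frame(target_start = integer(0), len = integer(0),
                      cost = integer(0), quality = numeric(0))
  qlen <- nchar(fragment_text)
  tlen <- nchar(region_text)
  if (qlen == 0L || tlen == 0L || tlen < qlen %/% 2L) return(empty)
  seed_len <- min(params$seed_len, qlen)
  seed_off <- unique(c(1L, max(1L, (qlen - seed_len) %/% 2L + 1L),
                       qlen - seed_len + 1L))
  cand <- integer(0)
  for (so in seed_off) {
    seed <- substr(fragment_text, so, so + seed_len - 1L)
    hits <- gregexpr(seed, region_text, fixed = TRUE)[[1L]]
    if (hits[1L] == -1L) next
    cand <- c(cand, as.integer(hits) - so + 1L)
  }
  cand <- sort(unique(cand))
  # merge near-duplicate offsets (within half a seed)
  if (length(cand) > 1L)
    cand <- cand[c(TRUE, diff(cand) > seed_len %/% 2L)]
  if (length(cand) == 0L) return(empty)
  qi <- utf8ToInt(fragment_text)
  ti <- utf8ToInt(region_text)
  res <- lapply(cand, function(o) {
    if (o < 1L || o + qlen - 1L > tlen) return(NULL)
    win <- ti[o:(o + qlen - 1L)]
    cost <- .pm_edit_cost(qi, win, max(32L, qlen %/% 4L))
    if (cost < 0L) return(NULL)
    data.frame(target_start = o, len = qlen, cost = cost)
  })
  res <- do.call(rbind, res)
  if (is.null(res) || nrow(res) == 0L) return(empty)
  base_q <- pmax(0, 60 * (1 - 3 * res$cost / qlen))
  if (nrow(res) >= 2L) {
    o <- order(res$cost)
    gap2 <- res$cost[o[2L]] - res$cost[o[1L]]
    amb <- pmin(60, 6 * gap2)
    q <- pmin(base_q, amb)
    q[o[-1L]] <- pmin(q[o[-1L]], 3)        # secondary placements
    res$quality <- q
  } else res$quality <- base_q
  res
}

#' Read mappings in PAF format
#'
#' Parses the first 12 standard PAF columns as produced by long-read
#' mappers; column 12 is the MAPQ.
#'
#' @param path Path to a PAF file.
#' @return Data frame with columns `qname`, `qlen`, `qstart`, `qend`,
#'   `strand`, `tname`, `tlen`, `tstart`, `tend`, `nmatch`, `alen`,
#'   `mapq` (start/end 0-based half-open, as in the format).
#' @export
read_paf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(data.frame(qname = character(0), qlen = integer(0),
                      qstart = integer(0), qend = integer(0),
                      strand = character(0), tname = character(0),
                      tlen = integer(0), tstart = integer(0),
                      tend = integer(0), nmatch = integer(0),
                      alen = integer(0), mapq = integer(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) < 12L)
  if (length(bad))
    stop("PAF line ", bad[1L], " has fewer than 12 columns")
  g <- function(i) vapply(parts, `[[`, character(1), i)
  data.frame(qname = g(1), qlen = as.integer(g(2)),
             qstart = as.integer(g(3)), qend = as.integer(g(4)),
             strand = g(5), tname = g(6), tlen = as.integer(g(7)),
             tstart = as.integer(g(8)), tend = as.integer(g(9)),
             nmatch = as.integer(g(10)), alen = as.integer(g(11)),
             mapq = as.integer(g(12)))
}

#' Build a mapper function from an external PAF-emitting command
#'
#' Returns a function with the [map_fragment()] signature that writes the
#' fragment and region to temporary FASTA files, runs `cmd` (a template
#' with placeholders `{query}`, `{target}`), reads the resulting PAF from
#' stdout and converts it to the built-in match table. Matches are later
#' filtered at `mapq_min` like built-in ones; failures yield zero
#' matches.
#'
#' @param cmd Command template, e.g.
#'   `"minimap2 -c {target} {query}"`.
#' @return A function `(fragment_text, region_text, params)`.
#' @export
paf_mapper <- function(cmd) {
  force(cmd)
  function(fragment_text, region_text, params = pm_config()) {
    qf <- tempfile(fileext = ".fa"); tf <- tempfile(fileext = ".fa")
    on.exit(unlink(c(qf, tf)), add = TRUE)
    writeLines(c(">q", fragment_text), qf)
    writeLines(c(">t", region_text), tf)
    full <- gsub("{query}", qf, gsub("{target}", tf, cmd, fixed = TRUE),
                 fixed = TRUE)
    out <- tryCatch(system(full, intern = TRUE, ignore.stderr = TRUE),
                    error = function(e) character(0), warning = function(w) character(0))
    if (length(out) == 0L)
      return(data.frame(target_start = integer(0), len = integer(0),
                        cost = integer(0), quality = numeric(0)))
    pf <- tempfile(); on.exit(unlink(pf), add = TRUE)
    writeLines(out, pf)
    paf <- read_paf(pf)
    paf <- paf[paf$strand == "+", , drop = FALSE]
    data.frame(target_start = paf$tstart + 1L - paf$qstart,
               len = paf$qlen, cost = paf$alen - paf$nmatch,
               quality = paf$mapq)
  }
}

# Find partial multiMUM fragments inside a gap, in slice-local base
# coordinates. `level` is "parse" or "base"; empty slices get NA columns.
gap_fragments <- function(slices, level, params) {
  m <- length(slices)
  ne <- which(nchar(slices) > 0L)
  if (length(ne) < 2L)
    return(pm_fragments(integer(0), matrix(integer(0), 0L, m)))
  min_occ <- floor(length(ne) / 2) + 1L
  if (level == "parse") {
    pfp <- pfp_parse(slices[ne], pfp_params(params$window,
                                            params$gap_modulus))
    gsa <- build_gsa(lapply(pfp$parses, `[[`, "symbols"))
    mums <- find_partial_multimums(gsa, min_occ = min_occ)
    if (length(mums) == 0L)
      return(pm_fragments(integer(0), matrix(integer(0), 0L, m)))
    # lift symbol spans to slice-local base coordinates
    k <- length(mums)
    pos <- matrix(NA_integer_, k, m)
    len <- integer(k)
    drop <- logical(k)
    for (i in seq_len(k)) {
      for (jj in seq_along(ne)) {
        p <- mums$pos[i, jj]
        if (is.na(p)) next
        parse <- pfp$parses[[jj]]
        pos[i, ne[jj]] <- parse$starts[p]
        w <- pfp_base_weight(parse, pfp$dict, p, p + mums$len[i] - 1L)
        if (len[i] == 0L) len[i] <- w else if (len[i] != w) drop[i] <- TRUE
      }
    }
    keep <- which(!drop & len >= params$min_mum_bases)
    pm_fragments(len[keep], pos[keep, , drop = FALSE],
                 weight = len[keep], level = "base")
  } else {
    gsa <- build_gsa(as.character(slices[ne]))
    mums <- find_partial_multimums(gsa, min_occ = min_occ,
                                   min_length = params$min_mum_bases)
    if (length(mums) == 0L)
      return(pm_fragments(integer(0), matrix(integer(0), 0L, m)))
    pos <- matrix(NA_integer_, length(mums), m)
    pos[, ne] <- mums$pos
    pm_fragments(mums$len, pos, weight = mums$len, level = "base")
  }
}

# Try to extend absent (fragment, sequence) slots of a chain via the
# mapper, then accept consistent matches with the HIS variant.
mapper_extend <- function(chain, slices, params) {
  f <- chain$frags
  K <- length(f)
  if (K == 0L) return(chain)
  mapper <- if (is.function(params$mapper)) params$mapper else map_fragment
  cand <- list()
  for (s in seq_along(slices)) {
    if (nchar(slices[s]) == 0L) next
    absent <- which(is.na(f$pos[, s]))
    if (length(absent) == 0L) next
    placed <- which(!is.na(f$pos[, s]))
    for (t in absent) {
      pr <- placed[placed < t]
      nx <- placed[placed > t]
      lo <- if (length(pr)) max(f$pos[pr, s] + f$len[pr]) else 1L
      hi <- if (length(nx)) min(f$pos[nx, s]) - 1L else nchar(slices[s])
      if (hi - lo + 1L < f$len[t] %/% 2L) next
      src <- which(!is.na(f$pos[t, ]))[1L]
      ftext <- substr(slices[src], f$pos[t, src],
                      f$pos[t, src] + f$len[t] - 1L)
      region <- substr(slices[s], lo, hi)
      mm <- mapper(ftext, region, params)
      mm <- mm[mm$quality >= params$mapq_min, , drop = FALSE]
      if (nrow(mm) == 0L) next
      cand[[length(cand) + 1L]] <-
        data.frame(seq = s, frag = t, pos = lo + mm$target_start - 1L,
                   len = mm$len, weight = mm$len)
    }
  }
  if (length(cand) == 0L) return(chain)
  his_augment(chain, do.call(rbind, cand))
}

#' Recursively close a gap between two anchors
#'
#' Implements the gap-completion phase. Small gaps (every sequence's
#' interval at most `small_gap_threshold`) go straight to the center-star
#' aligner. Larger gaps are split: partial multiMUMs are found (on the
#' parse level for very large gaps, base level otherwise, falling back to
#' the base level when the parse level finds nothing), chained with the
#' k-sequence subset heuristic, completed by the mapper, and anchors
#' occurring in all non-empty sequences split the gap into sub-gaps that
#' are filled recursively. Partial anchors that do not split are passed
#' down as residual constraints. A sequence that cannot be anchored at
#' all while the others share long anchors is removed and laid out
#' unaligned after the gap, so no residue is ever lost.
#'
#' @param slices Character vector: the gap interval of every sequence
#'   (empty string where the gap is empty).
#' @param params A [pm_config()] list.
#' @param depth Recursion depth (the cap is `params$depth_cap`).
#' @param residual Optional [pm_fragments()] of anchors inherited from
#'   the level above (slice-local coordinates); lower-level chains are
#'   kept consistent with them by giving them overriding weight.
#' @return List of alignment blocks (see [merge_blocks()]).
#' @export
fill_gap <- function(slices, params = pm_config(), depth = 1L,
                     residual = NULL) {
  m <- length(slices)
  w <- nchar(slices)
  if (all(w == 0L)) return(list())
  ne <- which(w > 0L)
  if (length(ne) == 1L || max(w) <= params$small_gap_threshold ||
      depth > params$depth_cap)
    return(list(small_align(slices, params)))
  levels_to_try <- if (max(w) >= params$parse_gap_factor *
                         params$small_gap_threshold)
    c("parse", "base") else "base"
  for (level in levels_to_try) {
    frags <- gap_fragments(slices, level, params)
    if (!is.null(residual) && length(residual) > 0L) {
      frags <- pm_fragments(c(residual$len, frags$len),
                            rbind(residual$pos, frags$pos),
                            c(rep(sum(frags$weight) + 1, length(residual)),
                              frags$weight))
    }
    if (length(frags) == 0L) next
    chain <- select_subset_chain(frags, seqs = ne)
    if (length(chain$idx) == 0L) next
    # re-add occurrences outside the selected sequences via HIS
    ksel <- attr(chain, "k_seqs")
    orig_pos <- chain$frags$pos
    outside <- setdiff(seq_len(m), ksel)
    chain$frags$pos[, outside] <- NA_integer_
    cand <- list()
    for (s in outside) {
      hasp <- which(!is.na(orig_pos[, s]))
      if (length(hasp))
        cand[[length(cand) + 1L]] <-
          data.frame(seq = s, frag = hasp, pos = orig_pos[hasp, s],
                     len = chain$frags$len[hasp],
                     weight = chain$frags$len[hasp])
    }
    if (length(cand)) chain <- his_augment(chain, do.call(rbind, cand))
    chain <- mapper_extend(chain, slices, params)
    f <- chain$frags
    full <- which(rowSums(!is.na(f$pos[, ne, drop = FALSE])) == length(ne))
    if (length(full) == 0L) {
      res <- remove_unalignable(slices, f, params, depth)
      if (!is.null(res)) return(res)
      next
    }
    return(split_and_recurse(slices, f, full, params, depth))
  }
  # nothing splits the gap: last resort is the small-gap aligner
  if (max(w) > 10L * params$small_gap_threshold)
    warning("gap of size ", max(w),
            " could not be split; delegating to the small-gap aligner")
  list(small_align(slices, params))
}

small_align <- function(slices, params) {
  if (is.function(params$aligner)) {
    blk <- tryCatch(params$aligner(slices), error = function(e) NULL)
    if (!is.null(blk) &&
        identical(gsub(GAP_CHAR, "", blk$rows, fixed = TRUE),
                  unname(slices)))
      return(list(rows = blk$rows, width = nchar(blk$rows[1L]),
                  aligned = TRUE))
  }
  align_small(as.character(slices), params$band_max)
}

# Split around the full anchors (kept in chain order) and recurse; partial
# anchors between split points become residual constraints below.
split_and_recurse <- function(slices, f, full, params, depth) {
  m <- length(slices)
  w <- nchar(slices)
  ord <- order(f$pos[full, which(colSums(is.na(f$pos[full, , drop = FALSE]))
                                 == 0L)[1L]])
  full <- full[ord]
  blocks <- list()
  prev_end <- rep(0L, m)
  prev_chain_idx <- 0L
  for (ii in seq_along(full)) {
    t <- full[ii]
    st <- f$pos[t, ]
    sub_lo <- prev_end + 1L
    sub_hi <- ifelse(is.na(st), prev_end, st - 1L)
    sub_hi[w == 0L] <- 0L
    sub <- substr_vec(slices, sub_lo, sub_hi)
    res <- residual_in(f, setdiff(seq_len(length(f)), full),
                       prev_chain_idx, t, sub_lo)
    blocks <- c(blocks, fill_gap(sub, params, depth + 1L, res))
    blocks <- c(blocks, list(anchor_block(slices, st, f$len[t])))
    occ <- !is.na(st)
    prev_end[occ] <- st[occ] + f$len[t] - 1L
    prev_chain_idx <- t
  }
  sub <- substr_vec(slices, prev_end + 1L, nchar(slices))
  res <- residual_in(f, setdiff(seq_len(length(f)), full),
                     prev_chain_idx, length(f) + 1L, prev_end + 1L)
  c(blocks, fill_gap(sub, params, depth + 1L, res))
}

substr_vec <- function(slices, lo, hi) {
  out <- character(length(slices))
  for (k in seq_along(slices))
    out[k] <- if (hi[k] >= lo[k]) substr(slices[k], lo[k], hi[k]) else ""
  out
}

# Residual partial anchors that fall strictly between chain positions
# `after` and `before`, re-based to sub-gap coordinates.
residual_in <- function(f, partial_idx, after, before, sub_lo) {
  sel <- partial_idx[partial_idx > after & partial_idx < before]
  if (length(sel) == 0L) return(NULL)
  pos <- f$pos[sel, , drop = FALSE]
  pos <- sweep(pos, 2L, as.integer(sub_lo - 1L), `-`)
  keep <- rowSums(pos < 1L, na.rm = TRUE) == 0L
  if (!any(keep)) return(NULL)
  pm_fragments(f$len[sel][keep], pos[keep, , drop = FALSE])
}

# The unalignable-sequence rule: a sequence with no anchor occurrence at
# all is removed (laid out unaligned after the gap) when the remaining
# sequences share anchors exceeding the removal length.
remove_unalignable <- function(slices, f, params, depth) {
  m <- length(slices)
  ne <- which(nchar(slices) > 0L)
  if (length(f) == 0L) return(NULL)
  occ <- !is.na(f$pos)
  dead <- ne[colSums(occ[, ne, drop = FALSE]) == 0L]
  if (length(dead) == 0L || length(dead) >= length(ne) - 1L) return(NULL)
  long <- f$len >= params$removal_min_len
  span <- rowSums(occ[, setdiff(ne, dead), drop = FALSE]) ==
    length(ne) - length(dead)
  if (!any(long & span)) return(NULL)
  kept <- slices
  kept[dead] <- ""
  blocks <- fill_gap(kept, params, depth + 1L)
  for (s in dead) {
    txt <- rep("", m)
    txt[s] <- slices[s]
    blocks <- c(blocks, list(unaligned_block(txt)))
  }
  blocks
}
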