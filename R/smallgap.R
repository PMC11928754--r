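GAP_CHAR <- "-"

# Band-doubling unit-cost alignment wrapper. Returns a_idx/b_idx (source
# positions per column, 0 = gap) and cost; when no optimum is certified
# within band_max, falls back to the trivial unaligned layout (a's
# residues, then b's) and reports exact = FALSE.
edit_align <- function(a_int, b_int, band_max = .Machine$integer.max) {
  r <- .pm_edit_align(a_int, b_int, band_max)
  if (r$cost < 0L) {
    n <- length(a_int); m <- length(b_int)
    return(list(cost = n + m, a_idx = c(seq_len(n), integer(m)),
                b_idx = c(integer(n), seq_len(m)), exact = FALSE))
  }
  r$exact <- TRUE
  r
}

#' Optimal pairwise alignment under unit edit costs
#'
#' Needleman-Wunsch with match 0, mismatch 1, indel 1, computed within an
#' adaptive diagonal band (the band doubles until the cost is certified
#' optimal), so the cost equals the Levenshtein distance.
#'
#' @param a,b Character scalars.
#' @return List with `a`, `b` (gapped texts of equal length) and `cost`.
#' @examples
#' pairwise_edit_align("kitten", "sitting")$cost   # 3
#' @export
pairwise_edit_align <- function(a, b) {
  ai <- utf8ToInt(a); bi <- utf8ToInt(b)
  r <- edit_align(ai, bi)
  ac <- strsplit(a, "", fixed = TRUE)[[1L]]
  bc <- strsplit(b, "", fixed = TRUE)[[1L]]
  list(a = paste(ifelse(r$a_idx == 0L, GAP_CHAR, ac[pmax(r$a_idx, 1L)]),
                 collapse = ""),
       b = paste(ifelse(r$b_idx == 0L, GAP_CHAR, bc[pmax(r$b_idx, 1L)]),
                 collapse = ""),
       cost = r$cost)
}

# Merge a new pairwise (star vs other) alignment into the running
# multi-alignment; "once a gap, always a gap". cur_star / rows are
# integer vectors of source positions per column (0 = gap).
merge_into_star <- function(cur_star, rows, a_idx, b_idx) {
  nc <- length(cur_star); np <- length(a_idx)
  i <- 1L; j <- 1L
  # columns of the merged alignment are described by pairs (old col or 0,
  # pair col or 0)
  old_of <- integer(nc + np); pair_of <- integer(nc + np)
  nout <- 0L
  while (i <= nc || j <= np) {
    nout <- nout + 1L
    if (i <= nc && cur_star[i] == 0L) {
      old_of[nout] <- i; i <- i + 1L
    } else if (j <= np && a_idx[j] == 0L) {
      pair_of[nout] <- j; j <- j + 1L
    } else if (i <= nc && j <= np) {
      stopifnot(cur_star[i] == a_idx[j])   # both consume the same star base
      old_of[nout] <- i; pair_of[nout] <- j
      i <- i + 1L; j <- j + 1L
    } else stop("pairwise alignment inconsistent with star row")
  }
  old_of <- old_of[seq_len(nout)]; pair_of <- pair_of[seq_len(nout)]
  star_new <- ifelse(old_of > 0L, cur_star[pmax(old_of, 1L)],
                     a_idx[pmax(pair_of, 1L)])
  star_new[old_of == 0L & pair_of == 0L] <- 0L
  rows_new <- lapply(rows, function(rv) {
    v <- integer(length(old_of))
    v[old_of > 0L] <- rv[old_of[old_of > 0L]]
    v
  })
  new_row <- integer(length(old_of))
  new_row[pair_of > 0L] <- b_idx[pair_of[pair_of > 0L]]
  list(star = as.integer(star_new), rows = rows_new, new_row = new_row)
}

#' Align a small gap with the center-star method
#'
#' Progressive multiple alignment under unit edit costs: the star is the
#' slice minimising the total pairwise distance (all pairs for up to 8
#' non-empty slices, a deterministic subsample above that); every other
#' slice is aligned optimally against the star and the pairwise
#' alignments are merged column-wise ("once a gap, always a gap"). Empty
#' slices become all-gap rows.
#'
#' @param slices Character vector, one (possibly empty) text per
#'   sequence.
#' @param band_max Band limit for the pairwise aligner; slices whose
#'   alignment to the star cannot be certified within this band are laid
#'   out unaligned (their residues in their own columns).
#' @return An alignment block: list with `rows` (gapped texts of equal
#'   length), `width`, `aligned = TRUE`.
#' @export
align_small <- function(slices, band_max = 4096L) {
  m <- length(slices)
  nonempty <- which(nchar(slices) > 0L)
  if (length(nonempty) == 0L)
    return(list(rows = rep("", m), width = 0L, aligned = TRUE))
  ints <- lapply(slices, utf8ToInt)
  if (length(nonempty) == 1L) {
    w <- nchar(slices[nonempty])
    rows <- rep(strrep(GAP_CHAR, w), m)
    rows[nonempty] <- slices[nonempty]
    return(list(rows = rows, width = w, aligned = TRUE))
  }
  # choose the star
  ne <- nonempty
  star <- if (length(ne) <= 8L) {
    tot <- vapply(ne, function(a) {
      sum(vapply(setdiff(ne, a), function(b)
        edit_align(ints[[a]], ints[[b]], band_max)$cost, numeric(1)))
    }, numeric(1))
    ne[which.min(tot)]
  } else {
    tot <- vapply(ne, function(a) {
      others <- setdiff(ne, a)
      probe <- others[unique(round(seq(1L, length(others), length.out = 5L)))]
      sum(vapply(probe, function(b)
        edit_align(ints[[a]], ints[[b]], band_max)$cost, numeric(1)))
    }, numeric(1))
    ne[which.min(tot)]
  }
  cur_star <- seq_along(ints[[star]])
  rows <- list()
  row_ids <- integer(0)
  for (s in setdiff(ne, star)) {
    pa <- edit_align(ints[[star]], ints[[s]], band_max)
    mg <- merge_into_star(cur_star, rows, pa$a_idx, pa$b_idx)
    cur_star <- mg$star
    rows <- mg$rows
    rows[[length(rows) + 1L]] <- mg$new_row
    row_ids <- c(row_ids, s)
  }
  width <- length(cur_star)
  out <- rep(strrep(GAP_CHAR, width), m)
  render <- function(v, text) {
    ch <- strsplit(text, "", fixed = TRUE)[[1L]]
    paste(ifelse(v == 0L, GAP_CHAR, ch[pmax(v, 1L)]), collapse = "")
  }
  out[star] <- render(cur_star, slices[star])
  for (ii in seq_along(row_ids))
    out[row_ids[ii]] <- render(rows[[ii]], slices[row_ids[ii]])
  list(rows = out, width = width, aligned = TRUE)
}

# Render an anchor as an alignment block: the covered residues verbatim
# (they agree outside the mismatch columns); absent sequences get all-gap
# rows.
anchor_block <- function(seqs, anchor_start, anchor_len) {
  m <- length(seqs)
  rows <- character(m)
  for (k in seq_len(m)) {
    rows[k] <- if (is.na(anchor_start[k])) strrep(GAP_CHAR, anchor_len)
      else substr(seqs[k], anchor_start[k], anchor_start[k] + anchor_len - 1L)
  }
  list(rows = rows, width = anchor_len, aligned = TRUE)
}

# Unaligned layout: each listed sequence's text in its own column range.
unaligned_block <- function(texts) {
  m <- length(texts)
  w <- nchar(texts)
  width <- sum(w)
  offs <- cumsum(c(0L, w[-m]))
  rows <- vapply(seq_len(m), function(k) {
    paste0(strrep(GAP_CHAR, offs[k]), texts[k],
           strrep(GAP_CHAR, width - offs[k] - w[k]))
  }, character(1))
  list(rows = rows, width = width, aligned = FALSE)
}

#' Concatenate alignment blocks into an MSA
#'
#' @param blocks List of alignment blocks (each with `rows`, `width` and
#'   an `aligned` flag), in backbone order.
#' @param ids Sequence ids (row names).
#' @return An object of class `pm_msa`: `rows` (named gapped texts of
#'   equal length), `boundaries` (cumulative end column of each block)
#'   and `aligned` (per-block flag).
#' @export
merge_blocks <- function(blocks, ids) {
  blocks <- Filter(function(b) b$width > 0L, blocks)
  m <- length(ids)
  if (length(blocks) == 0L) {
    return(structure(list(rows = stats::setNames(rep("", m), ids),
                          boundaries = integer(0), aligned = logical(0)),
                     class = "pm_msa"))
  }
  for (b in blocks) {
    if (length(b$rows) != m || any(nchar(b$rows) != b$width))
      stop("malformed block: row count or width mismatch")
  }
  rows <- vapply(seq_len(m), function(k)
    paste(vapply(blocks, function(b) b$rows[k], character(1)),
          collapse = ""), character(1))
  structure(list(rows = stats::setNames(rows, ids),
                 boundaries = cumsum(vapply(blocks, `[[`, integer(1),
                                            "width")),
                 aligned = vapply(blocks, `[[`, logical(1), "aligned")),
            class = "pm_msa")
}

#' @export
print.pm_msa <- function(x, ...) {
  nc <- if (length(x$rows)) nchar(x$rows[[1L]]) else 0L
  cat("pm_msa: ", length(x$rows), " sequences, ", nc, " columns, ",
      length(x$boundaries), " blocks\n", sep = "")
  invisible(x)
}

# Ungapped residues of each MSA row; the projection property demands this
# equals the input sequence.
msa_ungap <- function(msa) {
  vapply(msa$rows, function(r) gsub(GAP_CHAR, "", r, fixed = TRUE),
         character(1))
}

#' Verify the projection property of an MSA
#'
#' Removing gap symbols from row `j` must reproduce input sequence `j`
#' exactly.
#'
#' @param msa A `pm_msa`.
#' @param seqs The input sequences (named character vector).
#' @return `TRUE` invisibly, or an error naming the offending sequence.
#' @export
check_projection <- function(msa, seqs) {
  ug <- msa_ungap(msa)
  for (k in seq_along(seqs)) {
    if (!identical(unname(ug[k]), unname(seqs[k])))
      stop("projection violated for sequence ", names(seqs)[k])
  }
  invisible(TRUE)
}
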