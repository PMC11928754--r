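#' Percent coverage of an alignment
#'
#' The number of bases included in aligned blocks relative to the total
#' number of input bases, in percent. Accepts either a backbone
#' ([pm_anchors()]; bases inside anchors count) or a final MSA
#' ([merge_blocks()]; bases in blocks flagged `aligned` count, so
#' sequences laid out unaligned do not inflate coverage).
#'
#' @param x A `pm_anchors` or `pm_msa` object.
#' @param seqs The input sequences (named character vector).
#' @return Percentage in \[0, 100\].
#' @export
coverage_percent <- function(x, seqs) {
  total <- sum(nchar(seqs))
  if (total == 0L) return(0)
  if (inherits(x, "pm_anchors")) {
    covered <- sum(vapply(seq_len(length(x)), function(i)
      sum(!is.na(x$start[i, ])) * x$len[i], numeric(1)))
  } else if (inherits(x, "pm_msa")) {
    if (length(x$boundaries) == 0L) return(0)
    starts <- c(1L, head(x$boundaries, -1L) + 1L)
    covered <- 0
    for (b in which(x$aligned)) {
      seg <- substring(x$rows, starts[b], x$boundaries[b])
      covered <- covered + sum(nchar(gsub(GAP_CHAR, "", seg, fixed = TRUE)))
    }
  } else stop("x must be pm_anchors or pm_msa")
  100 * covered / total
}

#' Percent identity of an MSA
#'
#' The fraction of alignment columns that contain no gap symbol and a
#' single distinct residue, in percent. An optional column interval
#' (e.g. a centromeric region) can be excluded from both numerator and
#' denominator.
#'
#' @param msa A `pm_msa`.
#' @param excluded_region Optional `c(from, to)` columns (1-based,
#'   inclusive) to omit.
#' @return Percentage, or `NA` if no columns remain.
#' @export
identity_percent <- function(msa, excluded_region = NULL) {
  nc <- if (length(msa$rows)) nchar(msa$rows[[1L]]) else 0L
  if (nc == 0L) return(NA_real_)
  M <- do.call(rbind, strsplit(unname(msa$rows), "", fixed = TRUE))
  keep <- rep(TRUE, nc)
  if (!is.null(excluded_region))
    keep[excluded_region[1L]:excluded_region[2L]] <- FALSE
  if (!any(keep)) return(NA_real_)
  M <- M[, keep, drop = FALSE]
  no_gap <- colSums(M == GAP_CHAR) == 0L
  ident <- no_gap & vapply(seq_len(ncol(M)), function(j)
    all(M[, j] == M[1L, j]), logical(1))
  100 * sum(ident) / ncol(M)
}

#' Sum-of-pairs value of an alignment
#'
#' The sum of pairwise distances over all unordered row pairs, divided by
#' the number of sequences (lower is better). Two modes: `"induced"`
#' scores each gapped row pair column-wise (gap-vs-residue and mismatch
#' cost 1, gap-vs-gap 0); `"exact"` recomputes the true Levenshtein
#' distance of the ungapped rows, so `exact <= induced` always.
#'
#' @param msa A `pm_msa` (or, for `mode = "exact"`, plain sequences).
#' @param mode `"induced"` or `"exact"`.
#' @param remove_nonbase Strip characters outside `A`,`C`,`G`,`T` before
#'   comparing (the convention used when comparing against aligners that
#'   treat ambiguity codes differently). Only meaningful for `"exact"`.
#' @param scale Multiply the result (e.g. `1e-5` for display at the
#'   conventional reporting scale).
#' @return Non-negative number.
#' @export
sp_value <- function(msa, mode = c("induced", "exact"),
                     remove_nonbase = FALSE, scale = 1) {
  mode <- match.arg(mode)
  rows <- if (inherits(msa, "pm_msa")) unname(msa$rows) else unname(msa)
  m <- length(rows)
  stopifnot(m >= 2L)
  total <- 0
  if (mode == "induced") {
    chars <- lapply(rows, function(r) utf8ToInt(r))
    gap <- utf8ToInt(GAP_CHAR)
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      a <- chars[[i]]; b <- chars[[j]]
      total <- total + sum(a != b & !(a == gap & b == gap))
    }
  } else {
    ug <- gsub(GAP_CHAR, "", rows, fixed = TRUE)
    if (remove_nonbase) ug <- gsub("[^ACGT]", "", ug)
    ints <- lapply(ug, utf8ToInt)
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      d <- .pm_edit_cost(ints[[i]], ints[[j]],
                         max(length(ints[[i]]), length(ints[[j]])))
      total <- total + d
    }
  }
  scale * total / m
}

#' Alignment metrics report
#'
#' @param msa A `pm_msa`.
#' @param seqs The input sequences.
#' @param excluded_region Optional column interval excluded from the
#'   identity (see [identity_percent()]).
#' @return Data frame with one row per metric (`coverage_percent`,
#'   `identity_percent`, `sp_induced`).
#' @export
metrics_report <- function(msa, seqs, excluded_region = NULL) {
  data.frame(metric = c("coverage_percent", "identity_percent",
                        "sp_induced"),
             value = c(coverage_percent(msa, seqs),
                       identity_percent(msa, excluded_region),
                       sp_value(msa, "induced")))
}
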