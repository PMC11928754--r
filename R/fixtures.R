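#' Parameters for the synthetic pangenome generator
#'
#' The generator emulates the structure of a set of same-chromosome
#' assemblies from one species: a common ancestor with independent
#' per-individual substitutions and short indels, optional missing
#' segments (emulating incomplete contig coverage, up to the ~20%
#' missing data seen in real assembly sets) and optional inversions
#' (which a colinear aligner is expected to fail on -- they exist to
#' demonstrate that failure mode, not to be handled).
#'
#' @param ancestor_length Length of the ancestral sequence in bases.
#' @param m Number of derived sequences.
#' @param snp_rate Per-base substitution probability.
#' @param indel_rate Per-base probability of starting an indel.
#' @param indel_geom Geometric length parameter for indels (mean length
#'   `1/indel_geom`).
#' @param missing_fraction Fraction of each sequence deleted as larger
#'   segments (leading, trailing and internal).
#' @param inversion_count,inversion_length Number and length of planted
#'   inversions.
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#' @return A list of class `fixture_params`.
#' @export
fixture_params <- function(ancestor_length = 10000L, m = 3L,
                           snp_rate = 1e-3, indel_rate = 0,
                           indel_geom = 0.5, missing_fraction = 0,
                           inversion_count = 0L, inversion_length = 1000L,
                           seed = 1L) {
  stopifnot(snp_rate >= 0, snp_rate <= 1, indel_rate >= 0, indel_rate <= 1,
            missing_fraction >= 0, missing_fraction <= 1, m >= 1,
            ancestor_length >= 1)
  structure(as.list(environment()), class = "fixture_params")
}

BASES <- c("A", "C", "G", "T")

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic pangenome with a variant truth record
#'
#' Draws an i.i.d. uniform ACGT ancestor and derives `m` sequences by
#' applying substitutions, indels, missing segments and inversions
#' independently per sequence. Every variant is recorded with its
#' ancestor position, so the truth record replayed against the ancestor
#' reproduces each sequence exactly (see [apply_truth()]).
#'
#' @param params A [fixture_params()] object.
#' @return List with `ancestor`, `seqs` (named character vector
#'   `s1..sm`) and `truth` (data frame: `seq`, `type` of
#'   `snp`/`ins`/`del`/`inv`, `anc_pos` -- 1-based ancestor position the
#'   variant applies at (insertions insert before it) -- `len`, `alt`).
#' @export
generate_pangenome <- function(params = fixture_params()) {
  stopifnot(inherits(params, "fixture_params"))
  with_seed(params$seed, {
    anc <- paste(sample(BASES, params$ancestor_length, replace = TRUE),
                 collapse = "")
    truth <- list()
    seqs <- character(params$m)
    for (k in seq_len(params$m)) {
      tr <- draw_variants(params, anc)
      seqs[k] <- apply_variants(anc, tr)
      if (nrow(tr)) tr$seq <- paste0("s", k)
      truth[[k]] <- tr
    }
    names(seqs) <- paste0("s", seq_len(params$m))
    truth <- do.call(rbind, truth)
    list(ancestor = anc, seqs = seqs,
         truth = truth[, c("seq", "type", "anc_pos", "len", "alt")])
  })
}

draw_variants <- function(params, anc) {
  n <- params$ancestor_length
  out <- list()
  # substitutions: the alternative base always differs from the reference
  npos <- which(runif(n) < params$snp_rate)
  if (length(npos)) {
    ref <- substring(anc, npos, npos)
    alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1L),
                  character(1), USE.NAMES = FALSE)
    out$snp <- data.frame(type = "snp", anc_pos = npos, len = 1L,
                          alt = alt, stringsAsFactors = FALSE)
  }
  # short indels
  if (params$indel_rate > 0) {
    ipos <- which(runif(n) < params$indel_rate)
    if (length(ipos)) {
      ilen <- 1L + rgeom(length(ipos), params$indel_geom)
      ins <- runif(length(ipos)) < 0.5
      out$ind <- data.frame(
        type = ifelse(ins, "ins", "del"), anc_pos = ipos, len = ilen,
        alt = ifelse(ins,
                     vapply(ilen, function(l)
                       paste(sample(BASES, l, replace = TRUE),
                             collapse = ""), character(1)),
                     ""),
        stringsAsFactors = FALSE)
    }
  }
  # larger missing segments
  if (params$missing_fraction > 0) {
    total_miss <- round(params$missing_fraction * n)
    pieces <- pmax(1L, round(total_miss * c(0.4, 0.3, 0.3)))
    lead <- pieces[1L]
    trail <- pieces[2L]
    internal <- pieces[3L]
    ipos <- sample(seq(lead + 2L, max(lead + 2L, n - trail - internal - 1L)),
                   1L)
    out$miss <- data.frame(
      type = "del",
      anc_pos = c(1L, ipos, n - trail + 1L),
      len = c(lead, internal, trail), alt = "",
      stringsAsFactors = FALSE)
  }
  if (params$inversion_count > 0) {
    L <- min(params$inversion_length, n %/% 2L)
    st <- sample(seq_len(max(1L, n - L)), params$inversion_count)
    out$inv <- data.frame(type = "inv", anc_pos = st, len = L, alt = "",
                          stringsAsFactors = FALSE)
  }
  tr <- if (length(out)) do.call(rbind, out) else
    data.frame(type = character(0), anc_pos = integer(0), len = integer(0),
               alt = character(0), stringsAsFactors = FALSE)
  tr <- tr[order(tr$anc_pos), , drop = FALSE]
  # drop variants overlapping an earlier del/inv footprint, so replay is
  # unambiguous
  if (nrow(tr) > 1L) {
    keep <- logical(nrow(tr))
    covered_to <- 0L
    for (i in seq_len(nrow(tr))) {
      if (tr$anc_pos[i] > covered_to) {
        keep[i] <- TRUE
        foot <- if (tr$type[i] == "ins") 0L else tr$len[i]
        covered_to <- max(covered_to, tr$anc_pos[i] + foot - 1L)
      }
    }
    tr <- tr[keep, , drop = FALSE]
  }
  tr$seq <- rep(NA_character_, nrow(tr))
  rownames(tr) <- NULL
  tr
}

#' Replay a truth record against the ancestor
#'
#' @param ancestor Ancestor sequence.
#' @param truth Truth rows for one derived sequence (see
#'   [generate_pangenome()]).
#' @return The reconstructed sequence; equals the generated one.
#' @export
apply_truth <- function(ancestor, truth) apply_variants(ancestor, truth)

apply_variants <- function(anc, tr) {
  if (nrow(tr) == 0L) return(anc)
  tr <- tr[order(tr$anc_pos), , drop = FALSE]
  n <- nchar(anc)
  out <- character(0)
  cur <- 1L
  revcomp <- function(x) {
    chartr("ACGT", "TGCA",
           paste(rev(strsplit(x, "", fixed = TRUE)[[1L]]), collapse = ""))
  }
  for (i in seq_len(nrow(tr))) {
    p <- tr$anc_pos[i]
    if (p > cur) out <- c(out, substr(anc, cur, p - 1L))
    switch(tr$type[i],
      snp = { out <- c(out, tr$alt[i]); cur <- p + 1L },
      ins = { out <- c(out, tr$alt[i], substr(anc, p, p)); cur <- p + 1L },
      del = { cur <- p + tr$len[i] },
      inv = {
        out <- c(out, revcomp(substr(anc, p, p + tr$len[i] - 1L)))
        cur <- p + tr$len[i]
      })
  }
  if (cur <= n) out <- c(out, substr(anc, cur, n))
  paste(out, collapse = "")
}

#' The four-sequence worked-example instance
#'
#' Three length-4 sequences over a four-symbol alphabet whose generalized
#' suffix array has 15 rows and whose unique multiMUM is the substring
#' `"BC"` of length 2 at 1-based positions 2, 1, 2.
#'
#' @return Named character vector `c(S1 = "ABCA", S2 = "BCAC",
#'   S3 = "ABCD")`.
#' @export
fig_instance <- function() c(S1 = "ABCA", S2 = "BCAC", S3 = "ABCD")
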