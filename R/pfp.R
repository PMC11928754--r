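#' Prefix-free parsing parameters
#'
#' A length-`window` window of the input is a *trigger string* when its
#' Karp-Rabin rolling hash is divisible by `modulus`; the parse breaks the
#' sequence after every trigger window. Larger moduli make triggers rarer
#' and phrases longer (expected phrase length grows roughly linearly with
#' the modulus), which trades anchor resolution for speed.
#'
#' @param window Window size in characters (default 10). The first
#'   `window - 1` positions of a sequence can never close a phrase.
#' @param modulus Hash modulus; a window triggers iff its hash is 0 mod
#'   `modulus`. Default 100; 20 is the conventional choice inside large
#'   gaps, where finer phrases help.
#' @param trigger Optional character vector of window strings that are
#'   declared triggers directly, bypassing the hash. Intended for worked
#'   examples and tests (e.g. `window = 1`, `trigger = "t"`).
#' @return An object of class `pfp_params`.
#' @export
pfp_params <- function(window = 10L, modulus = 100L, trigger = NULL) {
  window <- as.integer(window)
  modulus <- as.integer(modulus)
  stopifnot(length(window) == 1L, window >= 1L,
            length(modulus) == 1L, modulus >= 1L)
  structure(list(window = window, modulus = modulus, trigger = trigger),
            class = "pfp_params")
}

trigger_end_positions <- function(text, params) {
  n <- nchar(text)
  w <- params$window
  if (n < w) return(integer(0))
  if (!is.null(params$trigger)) {
    wins <- substring(text, seq_len(n - w + 1L), seq_len(n - w + 1L) + w - 1L)
    return(which(wins %in% params$trigger) + w - 1L)
  }
  .pm_trigger_ends(utf8ToInt(text), w, params$modulus)
}

#' Prefix-free parse a set of sequences with a shared dictionary
#'
#' Each sequence is scanned left to right; a phrase ends at every trigger
#' window (see [pfp_params()]) and the final phrase runs to the end of the
#' sequence whether or not it ends with a trigger. The phrase dictionary is
#' built jointly over all sequences and sorted lexicographically (byte
#' order), so two parse symbols are equal if and only if their phrases are
#' identical on the base level -- the property that makes parse-level
#' matches meaningful across sequences.
#'
#' @param seqs Named character vector of sequences (one element per
#'   sequence, names are ids).
#' @param params A [pfp_params()] object.
#' @return An object of class `pm_pfp`: a list with elements
#'   * `dict`: character vector of distinct phrases, sorted ascending;
#'     a phrase's rank (index) is its meta-symbol;
#'   * `parses`: named list, one per input sequence, each with `symbols`
#'     (integer ranks), `starts` (1-based base offset of each phrase) and
#'     `total` (total base length);
#'   * `params`: the parameters used.
#' @examples
#' p <- pfp_parse(c(s = "gattacat"), pfp_params(window = 1, trigger = "t"))
#' p$dict                 # "acat" "gat" "t"
#' p$parses$s$symbols     # 2 3 1
#' @export
pfp_parse <- function(seqs, params = pfp_params()) {
  stopifnot(is.character(seqs), length(seqs) >= 1L, all(nchar(seqs) >= 1L))
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  pieces <- lapply(seqs, function(s) {
    n <- nchar(s)
    ends <- trigger_end_positions(s, params)
    ends <- ends[ends < n]            # last phrase always runs to the end
    ends <- c(ends, n)
    starts <- c(1L, head(ends, -1L) + 1L)
    list(phrases = substring(s, starts, ends), starts = starts, total = n)
  })
  dict <- sort(unique(unlist(lapply(pieces, `[[`, "phrases"),
                             use.names = FALSE)), method = "radix")
  parses <- lapply(pieces, function(pc) {
    list(symbols = match(pc$phrases, dict), starts = pc$starts,
         total = pc$total)
  })
  structure(list(dict = dict, parses = parses, params = params),
            class = "pm_pfp")
}

#' Expand a parse back to its source text
#'
#' @param parse One element of `pm_pfp$parses` (or any list with a
#'   `symbols` integer vector).
#' @param dict The phrase dictionary (character vector, rank-indexed).
#' @return The expanded text; the identity `pfp_expand(parse, dict) == S`
#'   holds for every parsed sequence `S`.
#' @export
pfp_expand <- function(parse, dict) {
  sym <- parse$symbols
  if (length(sym) == 0L) return("")
  if (anyNA(sym) || any(sym < 1L) || any(sym > length(dict)))
    stop("parse refers to unknown dictionary ranks")
  paste(dict[sym], collapse = "")
}

#' Base-level weight of a parse symbol range
#'
#' Total number of bases obtained by replacing the parse symbols in
#' positions `from..to` (1-based, inclusive) with their phrases. An empty
#' range (`to < from`) weighs 0.
#'
#' @param parse One element of `pm_pfp$parses`.
#' @param dict The phrase dictionary.
#' @param from,to Symbol positions, 1-based inclusive.
#' @return Integer base count.
#' @export
pfp_base_weight <- function(parse, dict, from, to) {
  k <- length(parse$symbols)
  if (from < 1L || to > k || from > to + 1L)
    stop("symbol range [", from, ", ", to, "] out of bounds for parse of length ", k)
  if (to < from) return(0L)
  sum(nchar(dict[parse$symbols[from:to]]))
}
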