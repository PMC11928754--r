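#' Read sequences from a FASTA file
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercased residues, in file order;
#'   an empty file yields an empty vector.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L ||
      all(!nzchar(trimws(readLines(path, warn = FALSE)))))
    return(stats::setNames(character(0), character(0)))
  set <- Biostrings::readBStringSet(path)
  if (any(Biostrings::width(set) == 0L))
    stop("empty record in ", path, ": ", names(set)[Biostrings::width(set) == 0L][1L])
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate sequence id in ", path, ": ", ids[duplicated(ids)][1L])
  stats::setNames(toupper(as.character(set)), ids)
}

write_fasta <- function(seqs, path, width = 80L) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Write a multiple alignment to MAF and/or gapped FASTA
#'
#' MAF output has one alignment block per MSA block; each block carries
#' one `s` line per sequence with 0-based ungapped start, residue count,
#' strand (always `+`) and source size. Rows contributing no residue to a
#' block are emitted with size 0, so every block has one row per
#' sequence. The non-standard `a`-line attribute `panmum_aligned`
#' records whether a block is an aligned block or an unaligned layout;
#' other MAF consumers ignore it, and it makes `write -> read` the
#' identity.
#'
#' @param msa A `pm_msa`.
#' @param path Output path (without extension when `format = "both"`;
#'   `.maf` / `.fa` are appended).
#' @param format `"maf"`, `"fasta"` or `"both"`.
#' @return Invisibly, the paths written.
#' @export
write_alignment <- function(msa, path, format = c("maf", "fasta", "both")) {
  format <- match.arg(format)
  stopifnot(inherits(msa, "pm_msa"))
  paths <- character(0)
  if (format %in% c("maf", "both")) {
    p <- if (format == "both") paste0(path, ".maf") else path
    write_maf(msa, p)
    paths <- c(paths, p)
  }
  if (format %in% c("fasta", "both")) {
    p <- if (format == "both") paste0(path, ".fa") else path
    write_fasta(msa$rows, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

write_maf <- function(msa, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1 program=panmum", con)
  ids <- names(msa$rows)
  src_size <- nchar(gsub(GAP_CHAR, "", msa$rows, fixed = TRUE))
  offs <- stats::setNames(rep(0L, length(ids)), ids)
  starts <- c(1L, head(msa$boundaries, -1L) + 1L)
  for (b in seq_along(msa$boundaries)) {
    writeLines(sprintf("a score=0 panmum_aligned=%d",
                       as.integer(msa$aligned[b])), con)
    seg <- substring(msa$rows, starts[b], msa$boundaries[b])
    sz <- nchar(gsub(GAP_CHAR, "", seg, fixed = TRUE))
    writeLines(sprintf("s %s %d %d + %d %s", ids, offs, sz,
                       src_size, seg), con)
    writeLines("", con)
    offs <- offs + sz
  }
  invisible(path)
}

#' Read a multiple alignment from MAF
#'
#' Inverse of the MAF dialect written by [write_alignment()]: blocks are
#' concatenated in file order, rows matched by source name.
#'
#' @param path Path to a MAF file.
#' @return A `pm_msa`.
#' @export
read_maf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  ids <- NULL
  rows <- NULL
  widths <- integer(0)
  aligned <- logical(0)
  i <- 1L
  while (i <= length(lines)) {
    ln <- lines[i]
    if (startsWith(ln, "a")) {
      al <- !grepl("panmum_aligned=0", ln, fixed = TRUE)
      j <- i + 1L
      bids <- character(0); btxt <- character(0)
      while (j <= length(lines) && startsWith(lines[j], "s ")) {
        f <- strsplit(lines[j], "[ \t]+")[[1L]]
        if (length(f) < 7L) stop("malformed s line at line ", j)
        bids <- c(bids, f[2L]); btxt <- c(btxt, f[7L])
        j <- j + 1L
      }
      if (is.null(ids)) {
        ids <- bids
        rows <- stats::setNames(rep("", length(ids)), ids)
      }
      if (!setequal(bids, ids)) stop("block rows do not match sequence set")
      rows[bids] <- paste0(rows[bids], btxt)
      widths <- c(widths, nchar(btxt[1L]))
      aligned <- c(aligned, al)
      i <- j
    } else i <- i + 1L
  }
  structure(list(rows = rows, boundaries = cumsum(widths),
                 aligned = aligned), class = "pm_msa")
}

#' Read a gapped FASTA alignment
#'
#' @param path Path to a gapped FASTA file.
#' @return A `pm_msa` with a single block.
#' @export
read_alignment_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  rows <- stats::setNames(as.character(set), sub("\\s.*$", "", names(set)))
  if (length(unique(nchar(rows))) > 1L)
    stop("alignment rows differ in length")
  nc <- if (length(rows)) nchar(rows[[1L]]) else 0L
  structure(list(rows = rows,
                 boundaries = if (nc > 0L) nc else integer(0),
                 aligned = if (nc > 0L) TRUE else logical(0)),
            class = "pm_msa")
}
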