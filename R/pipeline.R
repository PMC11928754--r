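#' Pipeline configuration
#'
#' Collects every tunable of the aligner with its default. Values of
#' note: `modulus` controls expected phrase length on the backbone
#' (larger = longer phrases = fewer, coarser anchors); `gap_modulus`
#' is the finer modulus used when re-parsing inside large gaps;
#' `small_gap_threshold` is the largest per-sequence gap the center-star
#' aligner takes directly; `extension_min_match` is the run of exact
#' matches required to cross a mismatch during anchor extension.
#'
#' @param ... Overrides of the defaults, by name.
#' @return A named list of class `pm_config`.
#' @export
pm_config <- function(...) {
  cfg <- list(
    window = 10L,              # PFP window size (bases)
    modulus = 100L,            # PFP modulus on the backbone
    gap_modulus = 20L,         # PFP modulus inside large gaps
    small_gap_threshold = 10000L,  # bases; larger gaps are split first
    parse_gap_factor = 10L,    # gaps >= factor*threshold use parse level
    extension_min_match = 10L, # exact-match run needed to cross a SNP
    mapq_min = 30,             # minimum mapper quality accepted
    min_mum_symbols = 1L,      # parse-level multiMUM length filter
    min_mum_bases = 20L,       # base-level multiMUM length filter
    dp_threshold = 2000L,      # fragments; above this chain heuristically
    removal_min_len = 500L,    # anchor length that licenses removal
    depth_cap = 10L,           # gap recursion depth cap
    band_max = 4096L,          # band limit of the unit-cost aligner
    seed_len = 21L,            # exact seed length of the built-in mapper
    mapper = NULL,             # function(fragment, region, params) or NULL
    aligner = NULL,            # function(slices) -> block, or NULL
    verbose = FALSE)
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown configuration option(s): ",
                          paste(bad, collapse = ", "))
    cfg <- modifyList(cfg, over)
  }
  structure(cfg, class = "pm_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' The file holds any subset of the [pm_config()] fields by name.
#'
#' @param path YAML file path.
#' @return A `pm_config` list.
#' @export
read_config <- function(path) {
  do.call(pm_config, yaml::read_yaml(path))
}

pm_log <- function(cfg, ...) {
  if (isTRUE(cfg$verbose)) message(format(Sys.time(), "%H:%M:%S "), ...)
}

#' Align a set of sequences end to end
#'
#' Runs the three phases of the aligner: (1) prefix-free parse all
#' sequences with a shared phrase dictionary; (2) compute the backbone --
#' parse-level enhanced GSA, multiMUM detection, colinear chaining,
#' lifting to the base level, extension across isolated mismatches; (3)
#' close every gap between anchors recursively with partial multiMUMs,
#' the mapper and the small-gap aligner. The result is a colinear MSA
#' whose rows project exactly onto the input sequences (no residue is
#' dropped or reordered); sequences that could not be aligned inside a
#' gap are laid out in unaligned blocks, which are flagged as such.
#'
#' @param seqs Named character vector of at least two sequences (see
#'   [read_fasta()]).
#' @param config A [pm_config()] list.
#' @return A `pm_msa` with attribute `stats`: a list with `n_mums`
#'   (anchors in the backbone chain), `n_extensions` (mismatch columns
#'   crossed), `coverage_chain` and `coverage_backbone` (percent
#'   coverage after chaining resp. extension), `n_gaps`.
#' @examples
#' px <- generate_pangenome(fixture_params(ancestor_length = 2000, m = 3,
#'                                         snp_rate = 1e-3, seed = 7))
#' msa <- run_pipeline(px$seqs)
#' attr(msa, "stats")$coverage_backbone
#' @export
run_pipeline <- function(seqs, config = pm_config()) {
  if (length(seqs) < 2L)
    stop("at least two sequences are required")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must carry unique names")
  if (any(nchar(seqs) == 0L)) stop("empty sequence in input")
  seqs <- toupper(seqs)
  pm_log(config, "phase 1+2: backbone (", length(seqs), " sequences, ",
         sum(nchar(seqs)), " bases)")
  bb <- build_backbone(seqs, config)
  pm_log(config, "backbone: ", length(bb$anchors), " anchors, ",
         bb$n_extensions, " extensions, ", length(bb$gaps), " gaps")
  anchors <- bb$anchors
  blocks <- list()
  k <- length(anchors)
  for (i in seq_along(bb$gaps)) {
    g <- bb$gaps[[i]]
    slices <- substr_vec(seqs, g$start, g$end)
    if (any(nchar(slices) > 0L))
      blocks <- c(blocks, fill_gap(slices, config))
    if (g$right >= 1L)
      blocks <- c(blocks,
                  list(anchor_block(seqs, anchors$start[g$right, ],
                                    anchors$len[g$right])))
  }
  msa <- merge_blocks(blocks, names(seqs))
  check_projection(msa, seqs)
  attr(msa, "stats") <- list(
    n_mums = bb$n_mums,
    n_extensions = bb$n_extensions,
    n_anchors = k,
    coverage_chain = if (is.null(bb$anchors_raw)) NA_real_ else
      coverage_percent(bb$anchors_raw, seqs),
    coverage_backbone = coverage_percent(anchors, seqs),
    n_gaps = sum(vapply(bb$gaps, function(g) any(g$end >= g$start),
                        logical(1))))
  pm_log(config, "done: ", nchar(msa$rows[[1L]]), " columns")
  msa
}
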