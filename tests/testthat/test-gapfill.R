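test_that("the built-in mapper places exact and near-exact fragments", {
  set.seed(123)
  region <- rnd_dna(2000)
  frag <- substr(region, 801, 1000)
  # exact, unique occurrence
  mm <- map_fragment(frag, region)
  expect_identical(nrow(mm), 1L)
  expect_identical(mm$target_start, 801L)
  expect_gte(mm$quality, 30)
  # nothing similar at all
  expect_identical(nrow(map_fragment(strrep("A", 100), region)), 0L)
  # 2% substitutions: still recovered at the planted offset
  fv <- strsplit(frag, "")[[1L]]
  idx <- sample(length(fv), 4L)
  fv[idx] <- vapply(fv[idx], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
  mm2 <- map_fragment(paste(fv, collapse = ""), region)
  expect_identical(mm2$target_start[which.max(mm2$quality)], 801L)
  expect_gte(max(mm2$quality), 30)
  # an ambiguous fragment (two identical placements) scores low
  region2 <- paste0(frag, rnd_dna(50), frag)
  mm3 <- map_fragment(frag, region2)
  expect_true(all(mm3$quality < 30))
})

test_that("PAF round-trips through the reader and malformed lines error", {
  p <- tempfile(fileext = ".paf")
  writeLines(c("q1\t100\t0\t100\t+\tt1\t5000\t200\t300\t95\t100\t60",
               "q2\t80\t0\t80\t-\tt1\t5000\t10\t90\t70\t80\t12"), p)
  paf <- read_paf(p)
  expect_identical(nrow(paf), 2L)
  expect_identical(paf$mapq, c(60L, 12L))
  expect_identical(paf$tstart[1L], 200L)
  writeLines("q1\t100\t0", p)
  expect_error(read_paf(p), "fewer than 12")
  writeLines(character(0), p)
  expect_identical(nrow(read_paf(p)), 0L)
})

test_that("a planted common substring splits a large gap", {
  set.seed(321)
  core <- rnd_dna(300)
  slices <- vapply(1:3, function(i)
    paste0(rnd_dna(400), core, rnd_dna(400)), character(1))
  cfg <- pm_config(small_gap_threshold = 200L, min_mum_bases = 50L,
                   band_max = 512L)
  blocks <- fill_gap(slices, cfg)
  expect_gte(length(blocks), 3L)       # sub-gap, anchor, sub-gap at least
  msa <- merge_blocks(blocks, c("a", "b", "c"))
  expect_true(check_projection(msa, c(a = slices[1L], b = slices[2L],
                                      c = slices[3L])))
  # the anchor block keeps the planted core aligned
  expect_gte(identity_percent(msa), 20)
})

test_that("gap filling is exercised end to end on fragmented fixtures", {
  px <- generate_pangenome(fixture_params(ancestor_length = 30000, m = 4,
                                          snp_rate = 1e-3,
                                          missing_fraction = 0.15,
                                          seed = 31))
  cfg <- pm_config(small_gap_threshold = 1000L)
  msa <- run_pipeline(px$seqs, cfg)
  expect_true(check_projection(msa, px$seqs))
  expect_gte(identity_percent(msa), 50)
})

test_that("an unalignable sequence is removed and re-inserted unaligned", {
  set.seed(213)
  shared <- rnd_dna(3000)
  sA <- paste0(rnd_dna(50), shared, rnd_dna(50))
  sB <- paste0(rnd_dna(60), shared, rnd_dna(40))
  sC <- paste0(rnd_dna(55), shared, rnd_dna(45))
  junk <- paste(sample(c("A", "C", "G", "T"),
                       3100, replace = TRUE, prob = c(0.7, 0.1, 0.1, 0.1)),
                collapse = "")
  slices <- c(sA, sB, sC, junk)
  cfg <- pm_config(small_gap_threshold = 500L, removal_min_len = 500L,
                   band_max = 256L)
  blocks <- fill_gap(slices, cfg)
  msa <- merge_blocks(blocks, c("a", "b", "c", "d"))
  expect_true(check_projection(msa, c(a = sA, b = sB, c = sC, d = junk)))
  # the junk sequence's residues appear exactly once, in unaligned blocks
  expect_true(any(!msa$aligned))
})

test_that("the documented failure mode: inversions collapse coverage", {
  px <- generate_pangenome(fixture_params(ancestor_length = 20000, m = 3,
                                          snp_rate = 1e-3,
                                          inversion_count = 4L,
                                          inversion_length = 2500L,
                                          seed = 41))
  bb_inv <- build_backbone(px$seqs, pm_config())
  px0 <- generate_pangenome(fixture_params(ancestor_length = 20000, m = 3,
                                           snp_rate = 1e-3, seed = 41))
  bb0 <- build_backbone(px0$seqs, pm_config())
  expect_lt(coverage_percent(bb_inv$anchors, px$seqs),
            coverage_percent(bb0$anchors, px0$seqs))
})

test_that("an empty gap produces no blocks", {
  expect_identical(fill_gap(c("", "", "")), list())
})
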