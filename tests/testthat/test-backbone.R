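test_that("lifting a parse-level chain gives base-level exact matches", {
  seqs <- c(a = "gattacatgg", b = "ccgattacat")
  p <- pfp_parse(seqs, pfp_params(window = 1, trigger = "t"))
  g <- build_gsa(lapply(p$parses, `[[`, "symbols"))
  f <- find_multimums(g)
  ch <- chain_dp(f)
  an <- lift_to_base(ch, p)
  expect_gte(length(an), 1L)
  for (i in seq_len(length(an))) {
    sub_a <- substr(seqs[["a"]], an$start[i, 1L], an$start[i, 1L] + an$len[i] - 1L)
    sub_b <- substr(seqs[["b"]], an$start[i, 2L], an$start[i, 2L] + an$len[i] - 1L)
    expect_identical(sub_a, sub_b)
  }
  # empty chain lifts to an empty anchor set
  ch0 <- chain_dp(pm_fragments(integer(0), matrix(integer(0), 0L, 2L)))
  expect_identical(length(lift_to_base(ch0, p)), 0L)
})

test_that("extension crosses one isolated mismatch but respects the stop rule", {
  # left context, reading outward from the anchor: a SNP, 12 identical
  # bases, a second SNP, then only 5 identical bases to the sequence
  # start -- so the first SNP is crossed (+13 columns including the SNP)
  # and the extension stops before the second (5 < 10)
  left1 <- paste0("AAAAA", "G", strrep("C", 12), "G")   # positions 1..19
  left2 <- paste0("AAAAA", "T", strrep("C", 12), "C")
  core <- strrep("ACGT", 5)
  s1 <- paste0(left1, core); s2 <- paste0(left2, core)
  si <- lapply(c(s1, s2), utf8ToInt)
  st <- rep(nchar(left1) + 1L, 2L)                      # anchor at 20
  e <- extend_anchor(si, st, nchar(core), min_match = 10L)
  expect_identical(e$start, rep(7L, 2L))
  expect_identical(e$len, nchar(core) + 13L)
  expect_identical(e$mism, 13L)       # the crossed SNP, column 13
  # with an unattainable min_match the extension stops at the first
  # mismatch
  e2 <- extend_anchor(si, st, nchar(core), min_match = .Machine$integer.max)
  expect_identical(e2$start, st)
  expect_identical(e2$mism, integer(0))
})

test_that("extension is bounded by sequence ends and neighbours", {
  s <- strrep("ACGT", 10)
  si <- lapply(c(s, s), utf8ToInt)
  # anchor at position 1: no left extension possible
  e <- extend_anchor(si, c(1L, 1L), 4L)
  expect_identical(e$start, c(1L, 1L))
  expect_identical(e$len, nchar(s))   # identical sequences: full extension
  expect_identical(e$mism, integer(0))
  # explicit bounds are honoured
  e2 <- extend_anchor(si, c(11L, 11L), 4L, lo = c(5L, 5L), hi = c(20L, 20L))
  expect_identical(e2$start, c(5L, 5L))
  expect_identical(e2$start + e2$len - 1L, c(20L, 20L))
})

test_that("every recorded mismatch column has at least two distinct residues", {
  set.seed(444)
  px <- generate_pangenome(fixture_params(ancestor_length = 8000, m = 4,
                                          snp_rate = 2e-3, seed = 17))
  bb <- build_backbone(px$seqs, pm_config())
  an <- bb$anchors
  chars <- lapply(px$seqs, function(s) strsplit(s, "")[[1L]])
  for (i in seq_len(length(an))) {
    for (cc in an$mism[[i]]) {
      col <- vapply(seq_along(chars), function(k)
        chars[[k]][an$start[i, k] + cc - 1L], character(1))
      expect_gte(length(unique(col)), 2L)
    }
    # outside mismatch columns all residues agree
    ok_cols <- setdiff(seq_len(an$len[i]), an$mism[[i]])
    probe <- ok_cols[unique(round(seq(1L, length(ok_cols),
                                      length.out = 25L)))]
    for (cc in probe) {
      col <- vapply(seq_along(chars), function(k)
        chars[[k]][an$start[i, k] + cc - 1L], character(1))
      expect_identical(length(unique(col)), 1L)
    }
  }
})

test_that("anchors stay non-overlapping and ordered after extension", {
  set.seed(555)
  px <- generate_pangenome(fixture_params(ancestor_length = 20000, m = 5,
                                          snp_rate = 1e-3, indel_rate = 1e-4,
                                          seed = 23))
  bb <- build_backbone(px$seqs, pm_config())
  an <- bb$anchors
  expect_gte(length(an), 1L)
  for (k in seq_len(ncol(an$start))) {
    st <- an$start[, k]
    en <- st + an$len - 1L
    expect_true(all(diff(st) > 0L))
    expect_true(all(head(en, -1L) < tail(st, -1L)))
  }
})

test_that("two identical sequences give one all-covering anchor and no gaps", {
  s <- strrep("GATTACA", 300)
  bb <- build_backbone(c(a = s, b = s), pm_config())
  expect_identical(length(bb$anchors), 1L)
  expect_identical(unname(bb$anchors$start[1L, ]), c(1L, 1L))
  expect_identical(bb$anchors$len[1L], nchar(s))
  expect_true(all(vapply(bb$gaps, function(g) all(g$end < g$start),
                         logical(1))))
})

test_that("an anchorless input yields an empty backbone with one spanning gap", {
  # two unrelated random sequences at a coarse modulus rarely share
  # phrases; construct explicitly disjoint alphabets to force it
  seqs <- c(a = strrep("AC", 200), b = strrep("GT", 200))
  bb <- build_backbone(seqs, pm_config())
  expect_identical(length(bb$anchors), 0L)
  expect_identical(length(bb$gaps), 1L)
  expect_identical(bb$gaps[[1L]]$start, c(1L, 1L))
  expect_identical(unname(bb$gaps[[1L]]$end), unname(nchar(seqs)))
})

test_that("finer parsing yields at least as many anchors and coverage", {
  px <- generate_pangenome(fixture_params(ancestor_length = 30000, m = 4,
                                          snp_rate = 1e-3, seed = 29))
  st <- lapply(c(20L, 100L), function(mod) {
    bb <- build_backbone(px$seqs, pm_config(modulus = mod))
    list(n = length(bb$anchors),
         cov = coverage_percent(bb$anchors_raw, px$seqs))
  })
  expect_gte(st[[1L]]$n, st[[2L]]$n)
  expect_gte(st[[1L]]$cov, st[[2L]]$cov)
})
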