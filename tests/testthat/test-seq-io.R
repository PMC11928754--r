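test_that("FASTA reading uppercases, preserves order and handles CRLF", {
  f <- tempfile(fileext = ".fa")
  writeLines(c(">one", "ACGT", ">two desc", "nn"), f)
  got <- read_fasta(f)
  expect_identical(got, c(one = "ACGT", two = "NN"))
  # Windows line endings give the same residues
  writeBin(charToRaw(">one\r\nAC\r\nGT\r\n>two\r\nnn\r\n"), f)
  expect_identical(read_fasta(f), c(one = "ACGT", two = "NN"))
  # empty file -> empty set
  writeLines(character(0), f)
  expect_identical(length(read_fasta(f)), 0L)
  # duplicate ids are an error
  writeLines(c(">x", "AA", ">x", "CC"), f)
  expect_error(read_fasta(f), "duplicate")
  expect_error(read_fasta(tempfile()), "no such file")
})

test_that("MAF write -> read is the identity, including size-0 rows", {
  px <- generate_pangenome(fixture_params(ancestor_length = 3000, m = 3,
                                          snp_rate = 2e-3, indel_rate = 1e-3,
                                          seed = 8))
  msa <- run_pipeline(px$seqs)
  f <- tempfile(fileext = ".maf")
  write_alignment(msa, f, "maf")
  back <- read_maf(f)
  expect_identical(back$rows, msa$rows)
  expect_identical(back$boundaries, msa$boundaries)
  expect_identical(back$aligned, msa$aligned)
  # a block where one sequence contributes nothing still has m rows
  msa2 <- merge_blocks(list(list(rows = c("AC", "AC", "--"), width = 2L,
                                 aligned = TRUE),
                            list(rows = c("G", "G", "T"), width = 1L,
                                 aligned = TRUE)),
                       c("a", "b", "c"))
  f2 <- tempfile(fileext = ".maf")
  write_alignment(msa2, f2, "maf")
  lines <- readLines(f2)
  s_lines <- grep("^s ", lines, value = TRUE)
  expect_identical(length(s_lines), 6L)          # 2 blocks x 3 rows
  expect_true(any(grepl("^s c 0 0 \\+", s_lines)))  # size-0 row emitted
  back2 <- read_maf(f2)
  expect_identical(back2$rows, msa2$rows)
})

test_that("MAF start/size/srcSize fields are consistent", {
  msa <- merge_blocks(list(list(rows = c("AC-", "ACG"), width = 3L,
                                aligned = TRUE),
                           list(rows = c("TT", "-T"), width = 2L,
                                aligned = TRUE)),
                      c("x", "y"))
  f <- tempfile(fileext = ".maf")
  write_alignment(msa, f, "maf")
  s <- read.table(text = grep("^s ", readLines(f), value = TRUE))
  names(s) <- c("tag", "src", "start", "size", "strand", "srcSize", "text")
  expect_identical(s$strand, rep("+", 4L))
  expect_identical(s$srcSize[s$src == "x"], c(4L, 4L))
  # starts accumulate the ungapped sizes
  expect_identical(s$start[s$src == "x"], c(0L, 2L))
  expect_identical(s$start[s$src == "y"], c(0L, 3L))
  expect_identical(s$size[s$src == "y"], c(3L, 1L))
})

test_that("gapped FASTA round-trips rows", {
  px <- generate_pangenome(fixture_params(ancestor_length = 1000, m = 3,
                                          snp_rate = 2e-3, seed = 9))
  msa <- run_pipeline(px$seqs)
  f <- tempfile(fileext = ".fa")
  write_alignment(msa, f, "fasta")
  back <- read_alignment_fasta(f)
  expect_identical(back$rows, msa$rows)
  # "both" writes two files with the given prefix
  pre <- tempfile()
  paths <- write_alignment(msa, pre, "both")
  expect_true(all(file.exists(paste0(pre, c(".maf", ".fa")))))
})

test_that("configuration files mirror the option list", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("modulus: 20", "small_gap_threshold: 500"), f)
  cfg <- read_config(f)
  expect_equal(cfg$modulus, 20)
  expect_equal(cfg$small_gap_threshold, 500)
  expect_identical(cfg$window, 10L)      # untouched default
  expect_error(pm_config(bogus = 1), "unknown configuration")
})
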