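mk_pair <- function(s1, s2) {
  list(r1 = seq_record("p/1", s1, rep(35, nchar(s1))),
       r2 = seq_record("p/2", s2, rep(35, nchar(s2))))
}

test_that("a perfect full-length overlap is an insert equal to the read length", {
  set.seed(41)
  s <- random_seqs(1, 50)
  res <- find_overlap(mk_pair(s, revcomp(s)))
  expect_equal(res$insert_size, 50L)
  expect_equal(res$overlap_len, 50L)
  expect_equal(res$mismatches, 0L)
  expect_true(is.na(res$adapter_start_r1))
  expect_true(is.na(res$adapter_start_r2))
})

test_that("read-through pairs expose the adapter at the insert size", {
  set.seed(42)
  insert <- random_seqs(1, 30)
  adapter <- "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA"
  r1 <- substr(paste0(insert, adapter), 1, 40)
  r2 <- substr(paste0(revcomp(insert), adapter), 1, 40)
  res <- find_overlap(mk_pair(r1, r2))
  expect_equal(res$insert_size, 30L)
  expect_equal(res$adapter_start_r1, 30L)
  expect_equal(res$adapter_start_r2, 30L)
})

test_that("overlap geometry is recovered exactly on error-free fixtures", {
  spec <- library_spec(n_reads = 400L, read_len = 100L, paired = TRUE,
                       insert_mean = 150, insert_sd = 15,
                       error_rate = 0, seed = 9)
  lib <- generate_library(spec)
  cfg <- qc_config()
  r1 <- read_fastq(lib$files[1]); r2 <- read_fastq(lib$files[2])
  pairs <- pair_reads(r1, r2)
  detectable <- 2L * 100L - lib$manifest$insert_size >= cfg$min_overlap
  res <- lapply(pairs, find_overlap, cfg = cfg)
  got <- vapply(res, `[[`, integer(1), "insert_size")
  expect_true(all(!is.na(got[detectable])))
  expect_equal(got[detectable], lib$manifest$insert_size[detectable])
  # short inserts imply read-through adapters at the insert position
  short <- detectable & lib$manifest$insert_size < 100L
  a1 <- vapply(res, `[[`, integer(1), "adapter_start_r1")
  expect_equal(a1[short], lib$manifest$insert_size[short])
})

test_that("overlap-derived adapter positions agree with probe hits", {
  spec <- library_spec(n_reads = 300L, read_len = 100L, paired = TRUE,
                       insert_mean = 80, insert_sd = 10,
                       adapter_seq = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA",
                       error_rate = 0, seed = 27)
  lib <- generate_library(spec)
  r1 <- read_fastq(lib$files[1]); r2 <- read_fastq(lib$files[2])
  pairs <- pair_reads(r1, r2)
  m <- build_matcher(default_probe_set("illumina"))
  cfg <- qc_config()
  agree <- 0L; both <- 0L
  for (i in seq_along(pairs)) {
    ov <- find_overlap(pairs[[i]], cfg)
    if (is.na(ov$adapter_start_r1)) next
    hits <- scan_read(m, pairs[[i]]$r1)
    hits <- hits[hits$label == "Illumina TruSeq adapter", ]
    if (nrow(hits) == 0L) next
    both <- both + 1L
    if (hits$position[1] == ov$adapter_start_r1) agree <- agree + 1L
  }
  expect_gt(both, 100L)
  expect_equal(agree, both)
})

test_that("random pairs rarely produce a chance overlap", {
  set.seed(55)
  n <- 2000L
  c1 <- seqscope:::new_read_chunk(paste0("a", 1:n), rep("", n),
                                  random_seqs(n, 50),
                                  rep(strrep("I", 50), n))
  c2 <- seqscope:::new_read_chunk(paste0("a", 1:n), rep("", n),
                                  random_seqs(n, 50),
                                  rep(strrep("I", 50), n))
  res <- seqscope:::find_overlaps_chunk(c1, c2, qc_config())
  fp <- mean(!is.na(vapply(res, `[[`, integer(1), "insert_size")))
  expect_lt(fp, 0.01)
})

test_that("insert histograms conserve pairs and locate the fixture mode", {
  spec <- library_spec(n_reads = 500L, read_len = 150L, paired = TRUE,
                       insert_mean = 200, insert_sd = 0.1,
                       error_rate = 0, seed = 8)
  lib <- generate_library(spec)
  rep <- run_qc(lib$files)
  ins <- rep$insert_sizes
  expect_equal(sum(ins$histogram$count) + ins$undetermined, 500L)
  expect_equal(ins$histogram$insert_size[which.max(ins$histogram$count)], 200L)

  expect_equal(insert_size_histogram(list())$n_pairs, 0L)
})

test_that("overlap recovery stays high at a 2% base error rate", {
  spec <- library_spec(n_reads = 500L, read_len = 100L, paired = TRUE,
                       insert_mean = 150, insert_sd = 15,
                       error_rate = 0.02, seed = 13)
  lib <- generate_library(spec)
  cfg <- qc_config()
  r1 <- read_fastq(lib$files[1]); r2 <- read_fastq(lib$files[2])
  chunk1 <- seqscope:::records_to_chunk(r1)
  chunk2 <- seqscope:::records_to_chunk(r2)
  res <- seqscope:::find_overlaps_chunk(chunk1, chunk2, cfg)
  got <- vapply(res, `[[`, integer(1), "insert_size")
  detectable <- 2L * 100L - lib$manifest$insert_size >= cfg$min_overlap
  recovered <- mean(got[detectable] == lib$manifest$insert_size[detectable],
                    na.rm = FALSE)
  recovered[is.na(recovered)] <- 0
  expect_gt(mean(!is.na(got[detectable]) &
                 got[detectable] == lib$manifest$insert_size[detectable]),
            0.95)
})
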