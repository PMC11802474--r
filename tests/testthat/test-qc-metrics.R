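test_that("Phred conversions follow the closed forms", {
  expect_equal(phred_to_error(c(0, 10, 20)), c(1, 0.1, 0.01))
  expect_error(phred_to_error(-1), "negative")
  expect_equal(read_mean_quality_expected_error(c(10, 10, 10)), 10)
  expect_equal(read_mean_quality_expected_error(0), 0)
  expect_equal(read_mean_quality_expected_error(c(10, 20)),
               -10 * log10(0.055), tolerance = 1e-12)
  expect_equal(read_mean_quality_arithmetic(c(10, 20)), 15)
  expect_error(read_mean_quality_expected_error(integer(0)), "empty")
  expect_error(read_mean_quality_arithmetic(integer(0)), "empty")
})

test_that("arithmetic mean quality dominates expected-error mean (Jensen)", {
  set.seed(101)
  for (i in 1:200) {
    q <- sample(0:60, sample(1:120, 1), replace = TRUE)
    a <- read_mean_quality_arithmetic(q)
    e <- read_mean_quality_expected_error(q)
    expect_gte(a, e - 1e-9)
    if (length(unique(q)) == 1L) expect_equal(a, e, tolerance = 1e-9)
    else expect_gt(a, e)
  }
})

test_that("GC percent excludes N and marks undefined reads", {
  expect_equal(gc_percent(c("ATGC", "AAAA", "GCNGC")), c(50, 0, 100))
  expect_true(is.na(gc_percent("NNN")))
  expect_true(is.na(gc_percent("")))
})

test_that("accumulation counts every read exactly once into every histogram", {
  profile <- new_position_profile()
  summaries <- new_read_summaries()
  accumulate(seq_record("r1", "ACGT", rep(40, 4)), profile, summaries)
  tab <- profile_table(profile)
  expect_equal(tab$A[1], 1)
  expect_equal(tab$observed[1], 1)
  expect_equal(tab$mean_phred[1], 40)

  for (i in 1:99) accumulate(seq_record(paste0("r", i), "ACGT", rep(40, 4)),
                             profile, summaries)
  s <- summaries_table(summaries)
  expect_equal(s$n_reads, 100L)
  expect_equal(s$length_histogram$count[s$length_histogram$length == 4], 100L)
  expect_equal(sum(s$gc_histogram$count), 100L)
  expect_equal(sum(s$mean_quality_expected_error$count), 100L)
  expect_equal(sum(s$mean_quality_arithmetic$count), 100L)
  expect_equal(s$mean_quality_expected_error$count[41], 100L)  # all at Q40
})

test_that("per-read histograms conserve reads on a mixed fixture library", {
  spec <- library_spec(n_reads = 1500L, read_len = 120L,
                       duplicate_fraction = 0.3, seed = 17)
  lib <- generate_library(spec)
  rep <- run_qc(lib$files)
  s <- rep$summary
  expect_equal(sum(s$length_histogram$count), 1500L)
  expect_equal(sum(s$gc_histogram$count), 1500L)
  expect_equal(sum(s$mean_quality_expected_error$count), 1500L)
  expect_equal(sum(s$mean_quality_arithmetic$count), 1500L)
})

test_that("position profile columns are non-increasing and lengths bin correctly", {
  set.seed(33)
  lens <- sample(c(20L, 50L, 90L), 400L, replace = TRUE)
  seqs <- vapply(lens, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
  quals <- vapply(lens, function(L)
    intToUtf8(rep(35L + 33L, L)), character(1))
  path <- write_tmp_fastq(paste0("r", seq_along(lens)), seqs, quals)
  rep <- run_qc(path)
  obs <- rep$positions$observed
  expect_true(all(diff(obs) <= 0))
  expect_equal(obs[1], 400)
  expect_equal(obs[21], sum(lens >= 21))
})

test_that("ultra-long reads fall into geometric position bins past 500", {
  long <- paste(rep("ACGT", 2000), collapse = "")  # 8000 bp
  path <- write_tmp_fastq("long1", long, intToUtf8(rep(68L, 8000)))
  rep <- run_qc(path)
  tab <- rep$positions
  expect_equal(tab$end[nrow(tab)], 8000L)
  expect_true(all(tab$end[tab$start <= 500] == tab$start[tab$start <= 500]))
  widths <- tab$end - tab$start + 1L
  expect_true(any(widths[tab$start > 500] > 1L))
  # every base of the read lands in exactly one bin
  expect_equal(tab$observed, as.numeric(widths))
  expect_equal(sum(widths), 8000L)
})
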