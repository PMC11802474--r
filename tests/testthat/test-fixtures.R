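test_that("generation is deterministic: same seed, byte-identical files", {
  spec <- library_spec(n_reads = 300L, read_len = 80L,
                       duplicate_fraction = 0.3, adapter_spike_fraction = 0.1,
                       seed = 123)
  lib1 <- generate_library(spec, dir = tempfile())
  lib2 <- generate_library(spec, dir = tempfile())
  expect_identical(readLines(lib1$files), readLines(lib2$files))
  expect_identical(lib1$manifest, lib2$manifest)
})

test_that("duplicate structure is exact by construction", {
  spec <- library_spec(n_reads = 10000L, read_len = 50L,
                       duplicate_fraction = 0.5, error_rate = 0, seed = 2)
  lib <- generate_library(spec)
  expect_equal(lib$truth$dedup_fraction, 0.5)
  recs <- read_fastq(lib$files)
  seqs <- vapply(recs, `[[`, character(1), "sequence")
  # distinct sequences equal the manifest's distinct groups (up to the
  # vanishing chance of random 50-mer collisions)
  expect_equal(length(unique(seqs)),
               length(unique(lib$manifest$duplicate_group)))
  # reads in the same duplicate group are byte-identical at zero error
  grp <- split(seqs, lib$manifest$duplicate_group)
  expect_true(all(vapply(grp, function(g) length(unique(g)) == 1L,
                         logical(1))))
})

test_that("paired geometry places read-through adapters at the insert size", {
  spec <- library_spec(n_reads = 200L, read_len = 250L, paired = TRUE,
                       insert_mean = 200, insert_sd = 10, error_rate = 0,
                       seed = 14)
  lib <- generate_library(spec)
  short <- lib$manifest$insert_size < 250L
  expect_true(all(lib$manifest$adapter_start[short] ==
                  lib$manifest$insert_size[short]))
  r1 <- read_fastq(lib$files[1])
  i <- which(short)[1]
  ins <- lib$manifest$insert_size[i]
  expect_equal(substr(r1[[i]]$sequence, ins + 1,
                      min(250, ins + nchar(spec$adapter_seq))),
               substr(spec$adapter_seq, 1, min(250 - ins,
                                               nchar(spec$adapter_seq))))
})

test_that("manifest totals stay self-consistent with the emitted files", {
  spec <- library_spec(n_reads = 500L, read_len = 100L,
                       adapter_spike_fraction = 0.2,
                       contaminant_seq = strrep("ACGTT", 9),
                       contaminant_fraction = 0.1, seed = 15)
  lib <- generate_library(spec)
  expect_equal(nrow(lib$manifest), 500L)
  expect_equal(lib$truth$n_adapter, sum(!is.na(lib$manifest$adapter_start)))
  expect_equal(lib$truth$n_contaminant, sum(lib$manifest$contaminant))
  recs <- read_fastq(lib$files)
  expect_length(recs, 500L)
  # spiked adapters really sit at the recorded positions
  spiked <- which(!is.na(lib$manifest$adapter_start))[1:5]
  for (i in spiked) {
    at <- lib$manifest$adapter_start[i]
    expect_equal(substr(recs[[i]]$sequence, at + 1,
                        at + nchar(spec$adapter_seq)), spec$adapter_seq)
  }
})

test_that("a contradictory spec is rejected", {
  expect_error(library_spec(read_len = 20L, adapter_spike_fraction = 0.1,
                            adapter_seq = strrep("A", 33)),
               "adapter longer")
  expect_error(library_spec(duplicate_fraction = 1.5), "fractions")
})

test_that("the two-state quality model separates the averaging modes", {
  spec <- library_spec(n_reads = 2000L, read_len = 150L, seed = 99)
  lib <- generate_library(spec)
  recs <- read_fastq(lib$files)
  arith <- vapply(recs, function(r)
    read_mean_quality_arithmetic(r$qualities), numeric(1))
  ee <- vapply(recs, function(r)
    read_mean_quality_expected_error(r$qualities), numeric(1))
  expect_true(all(arith >= ee - 1e-9))
  expect_gt(mean(arith) - mean(ee), 5)  # modes diverge strongly
  expect_equal(mean(arith), 24, tolerance = 0.1)
})
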