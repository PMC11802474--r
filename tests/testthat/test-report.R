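test_that("an empty FASTQ produces a valid zero-read report", {
  empty <- tempfile(fileext = ".fastq")
  file.create(empty)
  rep <- run_qc(empty)
  expect_s3_class(rep, "qc_report")
  expect_equal(rep$summary$n_reads, 0L)
  expect_equal(sum(rep$summary$length_histogram$count), 0L)
  expect_equal(rep$duplication$total_reads, 0)
  expect_equal(rep$overrepresented$sampled_reads, 0)
  expect_equal(nrow(rep$overrepresented$table), 0L)
  json <- tempfile(fileext = ".json")
  html <- tempfile(fileext = ".html")
  write_json(rep, json)
  write_html(rep, html)
  expect_true(jsonlite::validate(paste(readLines(json), collapse = "\n")))
  expect_true(any(grepl("<h2>", readLines(html))))
})

test_that("identical inputs give identical reports (determinism)", {
  spec <- library_spec(n_reads = 400L, read_len = 90L,
                       duplicate_fraction = 0.2, seed = 3)
  lib <- generate_library(spec)
  r1 <- run_qc(lib$files)
  r2 <- run_qc(lib$files)
  j1 <- jsonlite::toJSON(report_fingerprint(r1), auto_unbox = TRUE,
                         digits = NA, na = "null")
  j2 <- jsonlite::toJSON(report_fingerprint(r2), auto_unbox = TRUE,
                         digits = NA, na = "null")
  expect_identical(as.character(j1), as.character(j2))
})

test_that("JSON serialization round-trips and carries the schema version", {
  spec <- library_spec(n_reads = 200L, read_len = 60L, seed = 4)
  lib <- generate_library(spec)
  rep <- run_qc(lib$files)
  path <- tempfile(fileext = ".json")
  write_json(rep, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$metadata$schema_version, "1.0")
  expect_equal(back$summary$n_reads, rep$summary$n_reads)
  expect_equal(back$duplication$dedup_fraction,
               rep$duplication$dedup_fraction, tolerance = 1e-12)
  expect_equal(back$summary$mean_quality_expected_error$count,
               rep$summary$mean_quality_expected_error$count)
  # keys survive a serialize/deserialize/serialize cycle unchanged
  j1 <- as.character(jsonlite::toJSON(jsonlite::read_json(path),
                                      auto_unbox = TRUE, digits = NA))
  j2 <- as.character(jsonlite::toJSON(jsonlite::read_json(path),
                                      auto_unbox = TRUE, digits = NA))
  expect_identical(j1, j2)
})

test_that("HTML is self-contained and mirrors the JSON tables", {
  cfg <- qc_config()
  db <- build_contaminant_index(
    system.file("extdata", "contaminants_synthetic.fasta",
                package = "seqscope"), cfg)
  spec <- library_spec(n_reads = 8000L, read_len = 150L,
                       contaminant_seq = substr(db$sequence[2], 1, 42),
                       contaminant_fraction = 0.05, seed = 6)
  lib <- generate_library(spec)
  rep <- run_qc(lib$files)
  html_path <- tempfile(fileext = ".html")
  write_html(rep, html_path)
  html <- paste(readLines(html_path), collapse = "\n")
  expect_false(grepl("https?://", html))
  expect_false(grepl("src=", html))
  for (frag in rep$overrepresented$table$fragment)
    expect_true(grepl(frag, html, fixed = TRUE))
})

test_that("read totals agree across report sections (conservation)", {
  spec <- library_spec(n_reads = 1200L, read_len = 100L, ont_meta = TRUE,
                       duplicate_fraction = 0.4, seed = 44)
  lib <- generate_library(spec)
  rep <- run_qc(lib$files)
  n <- rep$summary$n_reads
  expect_equal(n, 1200L)
  expect_equal(sum(rep$summary$length_histogram$count), n)
  expect_equal(sum(rep$summary$gc_histogram$count), n)
  expect_equal(sum(rep$summary$mean_quality_expected_error$count), n)
  expect_equal(rep$adapters$total_reads, n)
  expect_equal(rep$duplication$total_reads + rep$duplication$empty_reads, n)
  expect_equal(rep$ont$n_with_channel, n)
  expect_equal(rep$positions$observed[1], n)
})

test_that("input errors are raised before processing", {
  expect_error(run_qc("no/such/file.fastq"), "not found")
  junk <- tempfile()
  writeBin(as.raw(c(0x00, 0x01, 0x02, 0x03, 0x04)), junk)
  expect_error(run_qc(junk), "detect")
})
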