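db_path <- function() system.file("extdata", "contaminants_synthetic.fasta",
                                  package = "seqscope")

test_that("read sampling and fragment windows follow the 1-in-8 scheme", {
  cfg <- qc_config()
  set.seed(61)
  r <- random_seqs(1, 42)
  expect_length(sample_fragments(r, read_index = 1L, cfg), 0L)
  frags <- sample_fragments(r, read_index = 0L, cfg)
  expect_equal(frags, c(substr(r, 1, 21), substr(r, 22, 42)))
  # fragments with N are skipped
  rn <- paste0(substr(r, 1, 20), "N", substring(r, 22))
  expect_equal(sample_fragments(rn, 0L, cfg), substr(r, 22, 42))
  # long reads are capped at 8 evenly spaced fragments
  long <- random_seqs(1, 21 * 40)
  expect_length(sample_fragments(long, 0L, cfg), 8L)
  # sampled-read count over a stream
  idx <- 0:9999
  expect_equal(sum(idx %% cfg$sample_rate_denom == 0), ceiling(10000 / 8))
})

test_that("the fragment table caps distinct keys but keeps counting", {
  tab <- fragment_table(distinct_cap = 2L)
  table_update(tab, c("AAA", "BBB", "CCC", "AAA"), n_sampled_reads = 4L)
  expect_true(tab$saturated)
  expect_equal(tab$n_distinct, 2L)
  expect_equal(tab$counts[["AAA"]], 2L)
  expect_equal(tab$counts[["BBB"]], 1L)
  expect_null(tab$counts[["CCC"]])

  tab2 <- fragment_table(distinct_cap = 100L)
  table_update(tab2, as.character(1:100))
  expect_equal(tab2$n_distinct, 100L)
  expect_false(tab2$saturated)
})

test_that("flagging uses a strict threshold over sampled reads", {
  cfg <- qc_config()
  tab <- fragment_table()
  tab$sampled_reads <- 10000
  tab$counts[["AAAAAAAAAAAAAAAAAAAAA"]] <- 11L   # 0.11% > 0.1%
  tab$counts[["CCCCCCCCCCCCCCCCCCCCC"]] <- 10L   # exactly 0.1%: not flagged
  tab$n_distinct <- 2L
  flagged <- flag_overrepresented(tab, cfg)
  expect_equal(flagged$fragment, "AAAAAAAAAAAAAAAAAAAAA")
  expect_equal(flagged$count, 11L)
  expect_equal(flagged$fraction, 0.0011)
})

test_that("canonical k-mers are involutive and strand-insensitive", {
  set.seed(62)
  for (k in c(3L, 5L, 6L)) {
    kmers <- random_seqs(200, k)
    canon <- canonical_kmer(kmers)
    expect_equal(canonical_kmer(canon), canon)
    expect_equal(canonical_kmer(revcomp(kmers)), canon)
  }
  expect_equal(canonical_kmer("TTTT"), "AAAA")
  expect_equal(canonical_kmer("ACGT"), "ACGT")  # its own reverse complement
})

test_that("the contaminant index finds spiked fragments in both orientations", {
  cfg <- qc_config()
  db <- build_contaminant_index(db_path(), cfg)
  expect_gt(length(db$id), 10L)
  entry <- db$sequence[1]
  frag <- substr(entry, 10, 30)          # 21 bp substring of entry 1
  hit <- identify_fragment(frag, db, cfg)
  expect_equal(hit$target_id, db$id[1])
  expect_equal(hit$identity, 1.0)
  expect_equal(hit$score, 42L)           # 21 matches at +2
  hit_rc <- identify_fragment(revcomp(frag), db, cfg)
  expect_equal(hit_rc$target_id, db$id[1])
  expect_equal(hit_rc$identity, 1.0)
  # one mismatch: identity 20/21
  # mismatch near the fragment end so at least one 16-mer window stays clean
  frag_mm <- paste0(substr(frag, 1, 2),
                    chartr("ACGT", "CATG", substr(frag, 3, 3)),
                    substring(frag, 4))
  hit_mm <- identify_fragment(frag_mm, db, cfg)
  expect_equal(hit_mm$target_id, db$id[1])
  expect_equal(hit_mm$identity, 20 / 21, tolerance = 1e-12)
})

test_that("random fragments almost never hit the database", {
  set.seed(63)
  cfg <- qc_config()
  db <- build_contaminant_index(db_path(), cfg)
  frags <- random_seqs(1000, 21)
  hits <- sum(vapply(frags, function(f)
    !is.null(identify_fragment(f, db, cfg)), logical(1)))
  expect_lt(hits / 1000, 0.01)
})

test_that("an empty FASTA is rejected", {
  empty <- tempfile(fileext = ".fasta")
  file.create(empty)
  expect_error(build_contaminant_index(empty), "empty")
})

test_that("Smith-Waterman matches its closed-form and boundary examples", {
  al <- smith_waterman(strrep("ACGTG", 4), strrep("ACGTG", 4))
  expect_equal(al$score, 40L)  # 20 bases at +2
  expect_equal(al$identity, 1.0)
  none <- smith_waterman("AAAA", "GGGG")
  expect_equal(none$score, 0L)
  expect_true(is.na(none$identity))
  expect_true(all(is.na(none$query_span)))
  expect_error(smith_waterman("", "ACGT"), "non-empty")
})

test_that("Smith-Waterman equals brute-force enumeration on tiny strings", {
  set.seed(64)
  for (i in 1:60) {
    a <- random_seqs(1, sample(1:8, 1))
    b <- random_seqs(1, sample(1:8, 1))
    expect_equal(smith_waterman(a, b)$score, bf_local_score(a, b),
                 info = paste(a, b))
  }
})

test_that("Smith-Waterman agrees with an independent aligner on random pairs", {
  set.seed(65)
  for (i in 1:200) {
    a <- random_seqs(1, sample(4:12, 1))
    b <- random_seqs(1, sample(4:12, 1))
    expect_equal(smith_waterman(a, b)$score,
                 biostrings_local_score(a, b), info = paste(a, b))
  }
})

test_that("Smith-Waterman score is symmetric under symmetric scoring", {
  set.seed(66)
  for (i in 1:50) {
    a <- random_seqs(1, sample(5:15, 1))
    b <- random_seqs(1, sample(5:15, 1))
    expect_equal(smith_waterman(a, b)$score, smith_waterman(b, a)$score)
  }
})

test_that("spiked contaminants are flagged and identified end to end", {
  cfg <- qc_config()
  db <- build_contaminant_index(db_path(), cfg)
  vec <- unname(substr(db$sequence[3], 1, 42))
  spec <- library_spec(n_reads = 20000L, read_len = 150L,
                       contaminant_seq = vec, contaminant_fraction = 0.02,
                       seed = 19)
  lib <- generate_library(spec)
  rep <- run_qc(lib$files)
  tab <- rep$overrepresented$table
  spike_frag <- substr(vec, 1, 21)
  expect_true(spike_frag %in% tab$fragment)
  row <- tab[tab$fragment == spike_frag, ]
  expect_equal(row$best_match_id, db$id[3])
  expect_gte(row$identity, 0.95)
  # and it is the top-ranked fragment
  expect_equal(tab$fragment[1], spike_frag)
})
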