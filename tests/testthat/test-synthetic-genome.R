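test_that("telomere emitter follows the TG1-3 grammar exactly", {
  tm <- telomere_model()
  expect_identical(gen_telomere_repeats(tm, 0), "")
  s <- gen_telomere_repeats(tm, 10000, seed = 3)
  expect_equal(nchar(s), 10000)
  expect_true(telomere_grammar_ok(s))
  # maximal G runs are 1-3, T never doubled
  runs <- rle(strsplit(s, "")[[1]])
  expect_true(all(runs$lengths[runs$values == "G"] <= 3))
  expect_true(all(runs$lengths[runs$values == "T"] == 1))
  # determinism
  expect_identical(s, gen_telomere_repeats(tm, 10000, seed = 3))
  expect_false(identical(s, gen_telomere_repeats(tm, 10000, seed = 4)))
})

test_that("independently emitted 50 bp telomere windows are effectively unique", {
  tm <- telomere_model()
  tracts <- vapply(1:40, function(i) gen_telomere_repeats(tm, 500, seed = 100 + i), "")
  wins <- unlist(lapply(tracts, function(s) {
    substring(s, seq(1, nchar(s) - 49, by = 50), seq(50, nchar(s), by = 50))
  }))
  n <- length(wins)
  n_pairs <- n * (n - 1) / 2
  dup <- n - length(unique(wins))
  expect_lt(dup / n_pairs, 1e-4)
})

test_that("reference genome matches its declared structure and ledger", {
  ref <- fixture_reference()
  lg <- ref$ledger
  expect_equal(length(ref$genome), 16)
  f <- lg$features
  expect_equal(sum(f$feature == "yprime"), 34)
  expect_equal(length(unique(f$extremity[f$feature == "yprime"])), 20)
  expect_equal(sum(f$feature == "x_element"), 32)
  counts <- table(f$extremity[f$feature == "yprime"])
  expect_true(max(counts) == 6)
  # ledger self-check: every planted interval re-extracts identically
  expect_true(verify_ledger(ref$genome, lg))
  # determinism: identical (config, seed) give byte-identical FASTA content
  ref2 <- build_reference_genome(seed = 1)
  expect_identical(unclass(ref2$genome), unclass(build_reference_genome(seed = 1)$genome))
  # interstitial seeds and telomeres satisfy the grammar
  st <- lg$structures[[f$extremity[f$feature == "yprime"][1]]]
  expect_true(all(vapply(st$slots$seed_seq, telomere_grammar_ok, logical(1))))
  expect_true(telomere_grammar_ok(st$tel))
})

test_that("library families sit in their declared length bands", {
  lib <- fixture_reference()$ledger$library
  expect_equal(nrow(lib), 20)
  expect_true(all(lib$length[lib$family == "short"] > 4900 &
                    lib$length[lib$family == "short"] < 5700))
  expect_true(all(lib$length[lib$family == "long"] > 6400 &
                    lib$length[lib$family == "long"] < 7000))
  expect_equal(lib$length[lib$family == "intermediate"], 5981)
})

test_that("inconsistent generator configuration errors out", {
  expect_error(synthetic_config(occupancy = rep(1, 40)), "extremities")
  cfg <- small_config()
  cfg$extremity_cap <- 1000
  expect_error(build_reference_genome(cfg, seed = 1), "window")
})

test_that("roll_circle produces rotated perfect arrays", {
  expect_identical(roll_circle("ACGTGT", 3, 0), "ACGTGTACGTGTACGTGT")
  r2 <- roll_circle("ACGTGT", 3, 2)
  expect_identical(r2, strrep("GTGTAC", 3))
  expect_equal(nchar(r2), 18)
  expect_identical(roll_circle("ACGTGT", 4, 1, cap_length = 10), "CGTGTACGTG")
  expect_error(roll_circle("", 3, 0), "empty")
  # a planted unit is recovered by the tandem scanner with its unit length
  # and copy number
  tm <- telomere_model()
  unit <- gen_telomere_repeats(tm, 139, seed = 9)
  tel <- paste0(gen_telomere_repeats(tm, 400, seed = 10),
                roll_circle(unit, 9, 37),
                gen_telomere_repeats(tm, 300, seed = 11))
  arr <- find_perfect_tandem_arrays(tel, 50, 2)
  expect_true(any(arr$unit_len == 139 & arr$copies == 9))
})

test_that("planted losses shorten the arm by the element plus its seed", {
  ref <- fixture_reference()
  lg <- ref$ledger
  e <- "chr01_L"
  st <- lg$structures[[e]]
  skip_if(nrow(st$slots) == 0)
  s <- plant_rearrangements(lg, tibble::tibble(kind = "loss", extremity = e,
                                               slot = 1L),
                            clone = "x", seed = 1)
  before <- nchar(telorearr:::render_arm(st)$seq)
  after <- nchar(telorearr:::render_arm(s$ledger$structures[[e]])$seq)
  expect_equal(before - after,
               nchar(st$slots$seq[1]) + nchar(st$slots$seed_seq[1]))
  # unspecified chromosomes are byte-identical to the control
  other <- setdiff(names(ref$genome), "chr01")
  expect_identical(unclass(s$genome[other]), unclass(ref$genome[other]))
})

test_that("planted mosaics decompose into exactly their two donors", {
  lg <- fixture_reference()$ledger
  ev <- tibble::tibble(kind = "new_variant", extremity = "chr01_R",
                       donors = list(c("Y01", "Y12")), position = 0L)
  s <- plant_rearrangements(lg, ev, clone = "m", seed = 2)
  newseq <- s$ledger$novel_seqs[[1]]
  dec <- explain_mosaic(newseq, setNames(lg$library$seq, lg$library$variant_id))
  expect_true(dec$mosaic)
  expect_equal(dec$coverage, 1)
  expect_setequal(dec$donors, c("Y01", "Y12"))
})

test_that("simulated reads are exact substrings at error rate zero", {
  ref <- fixture_reference()
  g <- as_genome(ref$genome[c("chr01", "chr02")])
  rd <- simulate_reads(g, coverage = 2, seed = 11)
  # coverage within 10% of target
  expect_lt(abs(sum(rd$length) / (2 * sum(nchar(g))) - 1), 0.1)
  for (i in seq_len(min(20, nrow(rd)))) {
    sq <- if (rd$strand[i] == "-") telorearr:::revcomp(rd$seq[i]) else rd$seq[i]
    expect_identical(sq, substr(g[[rd$chrom[i]]], rd$start[i],
                                rd$start[i] + nchar(sq) - 1L))
  }
  # determinism and FASTQ round trip
  rd2 <- simulate_reads(g, coverage = 2, seed = 11)
  expect_identical(rd$seq, rd2$seq)
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_reads_fastq(rd, fq)
  back <- read_reads_fastq(fq)
  expect_identical(back$seq, rd$seq)
})

test_that("homopolymer-only noise is neutralized by condensation", {
  ref <- fixture_reference()
  src <- substr(ref$genome[["chr03"]], 1, 50000)
  noisy <- telorearr:::apply_read_errors(src, sub_rate = 0,
                                         hp_indel_rate = 0.6, hp_min_run = 5)
  expect_false(identical(src, noisy))
  expect_identical(condense_homopolymers(src), condense_homopolymers(noisy))
})
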