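test_that("telomere tract detection is accurate on planted tracts", {
  ref <- fixture_reference()
  planted <- vapply(ref$ledger$structures, function(s) nchar(s$tel), 0L)
  measured <- measure_assembly_telomere_lengths(ref$genome)
  m <- setNames(measured$length, measured$extremity)
  # recall and accuracy: every planted tract >= 100 bp found within 20 bp
  big <- names(planted)[planted >= 100]
  expect_true(all(m[big] > 0))
  expect_true(all(abs(m[big] - planted[big]) <= 20))
  # control-like per-extremity means sit in the expected 300-400 bp band
  expect_gt(mean(m), 280)
  expect_lt(mean(m), 420)
})

test_that("non-telomeric sequence yields no tract", {
  set.seed(5)
  rnd <- paste(sample(c("A", "C", "G", "T"), 4000, TRUE), collapse = "")
  expect_equal(nrow(detect_telomere_tract(rnd)), 0)
  # telomere-free end measures 0
  g <- as_genome(c(chrX = rnd))
  tl <- measure_assembly_telomere_lengths(g)
  expect_equal(tl$length, c(0L, 0L))
})

test_that("Y' detection equals planted truth exactly on the control", {
  ref <- fixture_reference()
  ctrl <- fixture_control()
  m <- ctrl$maps[ctrl$maps$feature == "yprime", ]
  expect_equal(nrow(m), 34)
  expect_equal(length(unique(m$extremity)), 20)
  fy <- ref$ledger$features[ref$ledger$features$feature == "yprime", ]
  win <- setNames(ctrl$maps$window, ctrl$maps$extremity)
  for (e in unique(fy$extremity)) {
    arm_len <- fy$arm_len[fy$extremity == e][1]
    planted <- sort(win[[e]] - arm_len + fy$start[fy$extremity == e])
    detected <- sort(m$start[m$extremity == e])
    expect_identical(as.integer(detected), as.integer(planted))
  }
  # zero-Y' extremities yield no instances
  none <- setdiff(unique(ctrl$maps$extremity), unique(fy$extremity))
  expect_equal(sum(m$extremity %in% none), 0)
})

test_that("alignments at or below 200 bp are not reported", {
  ref <- fixture_reference()
  lib <- setNames(ref$ledger$library$seq, ref$ledger$library$variant_id)
  tm <- telomere_model()
  frag <- substr(lib[[1]], 1000, 1199) # 200 bp: not > 200
  ext <- paste0(telorearr:::random_dna(3000), frag,
                gen_telomere_repeats(tm, 350, seed = 2))
  expect_equal(nrow(detect_yprime_instances(ext, lib)), 0)
  # a 400 bp fragment of the same variant is reported
  ext2 <- paste0(telorearr:::random_dna(3000), substr(lib[[1]], 1000, 1399),
                 gen_telomere_repeats(tm, 350, seed = 2))
  expect_equal(nrow(detect_yprime_instances(ext2, lib)), 1)
})

test_that("adding a redundant overlapping library variant never changes intervals", {
  ref <- fixture_reference()
  lib <- setNames(ref$ledger$library$seq, ref$ledger$library$variant_id)
  ext <- extremities(ref$genome, 150000)
  ys <- unique(ref$ledger$features$extremity[
    ref$ledger$features$feature == "yprime"])
  for (e in ys[1:4]) {
    sq <- ext$seq[ext$extremity == e]
    base <- detect_yprime_instances(sq, lib)
    aug <- c(lib, redundant = substr(lib[[3]], 500, 4500))
    again <- detect_yprime_instances(sq, aug)
    expect_identical(base[, c("start", "end")], again[, c("start", "end")])
  }
})

test_that("X elements are located within 10 bp of the planted interval", {
  ref <- fixture_reference()
  ctrl <- fixture_control()
  mx <- ctrl$maps[ctrl$maps$feature == "x_element", ]
  expect_equal(nrow(mx), 32)
  fx <- ref$ledger$features[ref$ledger$features$feature == "x_element", ]
  win <- setNames(ctrl$maps$window, ctrl$maps$extremity)
  for (i in seq_len(nrow(fx))) {
    e <- fx$extremity[i]
    planted <- win[[e]] - fx$arm_len[i] + fx$start[i]
    detected <- mx$start[mx$extremity == e]
    expect_lte(abs(detected - planted), 10)
  }
  # absent X yields no call
  tm <- telomere_model()
  sq <- paste0(telorearr:::random_dna(5000), gen_telomere_repeats(tm, 300, seed = 1))
  expect_equal(nrow(detect_x_element(sq, ref$ledger$x_ancestor)), 0)
})

test_that("map features are ordered core < X < Y' < telomere at every end", {
  ctrl <- fixture_control()
  for (e in unique(ctrl$maps$extremity)) {
    f <- ctrl$maps[ctrl$maps$extremity == e, ]
    f <- f[order(f$start), ]
    ord <- match(f$feature, c("x_element", "yprime", "telomere"))
    expect_true(!is.unsorted(ord))
    expect_equal(f$feature[nrow(f)], "telomere")
  }
})

test_that("extremities with >5 Y' and adjacent duplicates are undetermined", {
  labelled <- tibble::tibble(
    extremity = c(rep("e1", 6), rep("e2", 6), rep("e3", 3)),
    index = c(0:5, 0:5, 0:2),
    label = c("A", "B", "C", "D", "E", "F",   # 6 distinct: resolved
              "A", "A", "B", "C", "D", "E",   # 6 with adjacent dup
              "A", "A", "B"))                 # adjacent dup but only 3
  st <- flag_undetermined(labelled)
  expect_equal(st$status[st$extremity == "e1"], "resolved")
  expect_equal(st$status[st$extremity == "e2"], "undetermined")
  expect_equal(st$status[st$extremity == "e3"], "resolved")
  # default control is fully resolved
  expect_true(all(fixture_control()$status$status == "resolved"))
})

test_that("read-based lengths recover planted means within 10%", {
  ref <- fixture_reference()
  anchors <- anchor_library(ref$genome)
  expect_equal(nrow(anchors), 32)
  rd <- simulate_reads(ref$genome, coverage = 12, seed = 21)
  rl <- read_length_distribution(rd, anchors)
  planted <- vapply(ref$ledger$structures, function(s) nchar(s$tel), 0L)
  agg <- dplyr::summarise(dplyr::group_by(tibble::as_tibble(rl), extremity),
                          m = mean(length), n = dplyr::n())
  solid <- agg[agg$n >= 4, ]
  expect_gt(nrow(solid), 20)
  expect_true(all(abs(solid$m / planted[solid$extremity] - 1) <= 0.1))
  # reads with no anchors give an empty distribution
  empty <- read_length_distribution(rd[0, ], anchors)
  expect_equal(nrow(empty), 0)
})

test_that("length summaries use the Q1/Q3 and 1.5 IQR whisker convention", {
  x <- tibble::tibble(extremity = "e", length = c(1, 2, 3, 4, 100))
  s <- length_summary(x)
  q1 <- quantile(x$length, 0.25, names = FALSE)
  q3 <- quantile(x$length, 0.75, names = FALSE)
  expect_equal(s$q1, q1)
  expect_equal(s$q3, q3)
  expect_equal(s$whisker_lo, q1 - 1.5 * (q3 - q1))
  expect_equal(s$whisker_hi, q3 + 1.5 * (q3 - q1))
  expect_equal(s$median, 3)
})
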