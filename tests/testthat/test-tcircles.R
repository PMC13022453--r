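test_that("tandem scanner equals the brute-force reference on random tracts", {
  tm <- telomere_model()
  for (i in 1:30) {
    set.seed(i)
    s <- gen_telomere_repeats(tm, sample(300:3000, 1), seed = 400 + i)
    if (runif(1) < 0.7) {
      u <- gen_telomere_repeats(tm, sample(30:250, 1), seed = 500 + i)
      p <- sample(nchar(s) - 1, 1)
      s <- paste0(substr(s, 1, p), strrep(u, sample(2:6, 1)),
                  substr(s, p + 1, nchar(s)))
    }
    a <- find_perfect_tandem_arrays(s, 30, 2)[, c("start", "unit_len", "copies")]
    b <- scan_tandem_bruteforce(s, 30, 2)
    a <- a[order(a$start, a$unit_len), ]
    b <- b[order(b$start, b$unit_len), ]
    expect_equal(as.data.frame(a), as.data.frame(b), ignore_attr = TRUE)
  }
})

test_that("array intervals are exact unit concatenations within the tract", {
  tm <- telomere_model()
  s <- gen_telomere_repeats(tm, 1200, seed = 7)
  u <- gen_telomere_repeats(tm, 61, seed = 8)
  tel <- paste0(substr(s, 1, 600), strrep(u, 4), substr(s, 601, 1200))
  arr <- find_perfect_tandem_arrays(tel, 30, 2)
  expect_true(all(arr$end - arr$start == arr$unit_len * arr$copies))
  expect_true(all(arr$start >= 0 & arr$end <= nchar(tel)))
  hit <- arr[arr$unit_len == 61, ]
  expect_equal(hit$copies, 4)
  expect_identical(substr(tel, hit$start + 1, hit$end),
                   strrep(hit$unit, hit$copies))
  expect_equal(nrow(find_perfect_tandem_arrays("", 30, 2)), 0)
})

test_that("pure telomerase tracts carry no >= 50 bp arrays", {
  tm <- telomere_model()
  for (i in 1:10) {
    s <- gen_telomere_repeats(tm, 4000, seed = 600 + i)
    expect_equal(nrow(find_perfect_tandem_arrays(s, 50, 2)), 0)
  }
})

test_that("consolidation applies the unit-size and copy-number gates", {
  tm <- telomere_model()
  u40 <- gen_telomere_repeats(tm, 40, seed = 1)
  u80 <- gen_telomere_repeats(tm, 80, seed = 2)
  u90 <- gen_telomere_repeats(tm, 90, seed = 3)
  arrays <- tibble::tibble(
    extremity = "e1",
    start = c(0L, 500L, 1500L), unit_len = c(40L, 80L, 90L),
    copies = c(5L, 3L, 4L),
    unit = c(u40, u80, u90))
  arrays$end <- arrays$start + arrays$unit_len * arrays$copies
  cons <- consolidate_circles(arrays)
  # the 40 bp unit is below the use threshold; two unrelated units remain
  expect_equal(nrow(cons), 2)
  expect_setequal(cons$circle_id, c("Circle_80", "Circle_90"))
  # fewer than three copies is not circle evidence
  arrays2 <- arrays[2, ]; arrays2$copies <- 2L
  arrays2$end <- arrays2$start + arrays2$unit_len * arrays2$copies
  expect_equal(nrow(consolidate_circles(arrays2)), 0)
})

test_that("two arrays of one unit at different phases give one named circle", {
  tm <- telomere_model()
  unit <- gen_telomere_repeats(tm, 139, seed = 12)
  rot <- function(u, r) paste0(substr(u, r + 1, nchar(u)), substr(u, 1, r))
  arrays <- tibble::tibble(
    extremity = c("e1", "e2"),
    start = c(0L, 0L), unit_len = 139L, copies = c(4L, 3L),
    unit = c(unit, rot(unit, 57)))
  arrays$end <- arrays$start + arrays$unit_len * arrays$copies
  cons <- consolidate_circles(arrays)
  expect_equal(nrow(cons), 1)
  expect_equal(cons$circle_id, "Circle_139")
  expect_equal(cons$total_copies, 7L)
})

test_that("circle matching recovers planted copies, phase and rotation invariance", {
  tm <- telomere_model()
  unit <- gen_telomere_repeats(tm, 120, seed = 13)
  tel <- paste0(gen_telomere_repeats(tm, 500, seed = 14),
                roll_circle(unit, 6, 37),
                gen_telomere_repeats(tm, 400, seed = 15))
  m <- match_circle(unit, tel)
  expect_equal(nrow(m), 1)
  expect_equal(m$copies, 6)
  # start and phase agree with the planted array up to lattice equivalence
  expect_equal((m$phase - 37) %% 120, (m$start - 500) %% 120)
  expect_lt(abs(m$start - 500), 120)
  # rotating the query leaves the match set invariant (phases shift)
  rotu <- paste0(substr(unit, 61, 120), substr(unit, 1, 60))
  m2 <- match_circle(rotu, tel)
  expect_equal(m2$start, m$start)
  expect_equal(m2$copies, m$copies)
  expect_equal((m2$phase + 60) %% 120, m$phase %% 120)
  # unrelated telomere: no matches
  expect_equal(nrow(match_circle(unit, gen_telomere_repeats(tm, 3000, seed = 16))), 0)
})

test_that("specificity filter discards multi-copy hits elsewhere and traces origins", {
  tm <- telomere_model()
  unit <- gen_telomere_repeats(tm, 52, seed = 17)
  circle <- tibble::tibble(circle_id = "Circle_52", unit = unit,
                           unit_len = 52L, n_arrays = 1L, total_copies = 4L)
  own <- tibble::tibble(extremity = "own_e",
                        seq = paste0(roll_circle(unit, 4, 0),
                                     gen_telomere_repeats(tm, 200, seed = 18)))
  control <- tibble::tibble(extremity = "chr05_L",
                            seq = paste0(gen_telomere_repeats(tm, 100, seed = 19),
                                         unit,
                                         gen_telomere_repeats(tm, 150, seed = 20)))
  clean <- tibble::tibble(extremity = "z",
                          seq = gen_telomere_repeats(tm, 400, seed = 21))
  # two copies in another clone's telomeres: discarded
  other2 <- tibble::tibble(extremity = "o", seq = paste0(
    gen_telomere_repeats(tm, 80, seed = 22), unit,
    gen_telomere_repeats(tm, 90, seed = 23), unit,
    gen_telomere_repeats(tm, 60, seed = 24)))
  res <- specificity_filter_and_origin(circle, own, list(a = other2), control)
  expect_false(res$kept)
  # specific circle with a single-copy control hit: origin recorded
  res2 <- specificity_filter_and_origin(circle, own, list(a = clean), control)
  expect_true(res2$kept)
  expect_equal(res2$origin_extremity, "chr05_L")
  # the locus can shift by a few bases when the flanking telomere happens to
  # extend the periodic match
  expect_lt(abs(res2$origin_start - 100), 10)
  # no control hit: kept with unknown origin
  res3 <- specificity_filter_and_origin(circle, own, list(a = clean), clean)
  expect_true(res3$kept)
  expect_true(is.na(res3$origin_extremity))
})

test_that("containment relations hold for planted nested circles only", {
  tm <- telomere_model()
  inner <- gen_telomere_repeats(tm, 139, seed = 25)
  outer <- paste0(inner, gen_telomere_repeats(tm, 193, seed = 26))
  other <- gen_telomere_repeats(tm, 200, seed = 27)
  circles <- tibble::tibble(
    circle_id = c("Circle_139", "Circle_332", "Circle_200"),
    unit = c(inner, outer, other),
    unit_len = c(139L, 332L, 200L))
  rel <- nested_circle_relations(circles)
  expect_equal(nrow(rel), 1)
  expect_equal(rel$inner, "Circle_139")
  expect_equal(rel$outer, "Circle_332")
  # a rotated inner is still contained (circles have no fixed origin)
  circles$unit[1] <- paste0(substr(inner, 71, 139), substr(inner, 1, 70))
  rel2 <- nested_circle_relations(circles)
  expect_true(any(rel2$inner == "Circle_139" & rel2$outer == "Circle_332"))
})

test_that("tandem fractions are well-ordered and NA without telomeric DNA", {
  tm <- telomere_model()
  unit <- gen_telomere_repeats(tm, 100, seed = 28)
  tracts <- tibble::tibble(
    extremity = c("e1", "e2"),
    seq = c(paste0(gen_telomere_repeats(tm, 300, seed = 29),
                   roll_circle(unit, 4, 0),
                   gen_telomere_repeats(tm, 300, seed = 30)),
            paste0(gen_telomere_repeats(tm, 200, seed = 31), unit,
                   gen_telomere_repeats(tm, 200, seed = 32))))
  arrays <- find_perfect_tandem_arrays(tracts$seq[1], 30, 2)
  arrays$extremity <- "e1"
  circles <- tibble::tibble(circle_id = "Circle_100", unit = unit,
                            unit_len = 100L)
  fr <- tandem_fraction(tracts, arrays, circles)
  expect_gte(fr$extended_fraction, fr$perfect_fraction)
  expect_true(fr$perfect_fraction >= 0 && fr$extended_fraction <= 1)
  # the single unplanted occurrence on e2 only counts in the extended set
  expect_gte(fr$extended_bp - fr$perfect_bp, 100)
  fr0 <- tandem_fraction(tracts[0, ], arrays[0, ], circles[0, ])
  expect_true(is.na(fr0$perfect_fraction))
})
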