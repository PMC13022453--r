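test_that("diff_extremity is a fixed point on identical maps", {
  expect_equal(nrow(diff_extremity(c("A", "B"), c("A", "B"), "e")), 0)
  for (i in 1:20) {
    set.seed(i)
    labs <- sample(LETTERS[1:6], sample(0:6, 1), replace = TRUE)
    expect_equal(nrow(diff_extremity(labs, labs, "e")), 0)
  }
})

test_that("diff_extremity classifies losses, gains, tandems and new variants", {
  cat_labels <- LETTERS[1:6]
  # survivor missing the middle of three: exactly one loss
  d <- diff_extremity(c("A", "B", "C"), c("A", "C"), "e", cat_labels)
  expect_equal(nrow(d), 1)
  expect_equal(d$kind, "loss")
  expect_equal(d$label, "B")
  # a gained copy adjacent to its twin is also a tandem amplification
  d2 <- diff_extremity(c("A", "B"), c("A", "B", "B"), "e", cat_labels)
  expect_setequal(d2$kind, c("gain", "tandem_amplification"))
  expect_true(all(d2$label == "B"))
  # a gained label absent from the catalog is also a new variant
  d3 <- diff_extremity(c("A"), c("A", "zz"), "e", cat_labels)
  expect_setequal(d3$kind, c("gain", "new_variant"))
  # a replaced label yields one loss plus one gain
  d4 <- diff_extremity(c("A", "B"), c("A", "C"), "e", cat_labels)
  expect_setequal(d4$kind, c("loss", "gain"))
  expect_equal(sort(d4$label), c("B", "C"))
})

test_that("mosaic explanation covers constructed mosaics and rejects noise", {
  set.seed(4)
  lib <- c(A = paste(sample(c("A", "C", "G", "T"), 6000, TRUE), collapse = ""),
           B = paste(sample(c("A", "C", "G", "T"), 6000, TRUE), collapse = ""))
  new <- paste0(substr(lib["A"], 1, 3000), substr(lib["B"], 3001, 6000))
  dec <- explain_mosaic(new, lib)
  expect_true(dec$mosaic)
  expect_equal(dec$coverage, 1)
  expect_setequal(dec$donors, c("A", "B"))
  # random sequence: no exact matches at all
  rnd <- paste(sample(c("A", "C", "G", "T"), 5000, TRUE), collapse = "")
  expect_null(explain_mosaic(rnd, lib))
  # monotone: adding donors never turns an explained sequence unexplained
  lib2 <- c(lib, C = paste(sample(c("A", "C", "G", "T"), 6000, TRUE),
                           collapse = ""))
  dec2 <- explain_mosaic(new, lib2)
  expect_true(dec2$mosaic)
  # a single donor with rearranged segment order still counts as explained
  re <- paste0(substr(lib["A"], 3001, 6000), substr(lib["A"], 1, 3000))
  dec3 <- explain_mosaic(re, lib["A"])
  expect_true(dec3$mosaic)
})

test_that("terminal duplications report donor, span and exact junction homology", {
  ref <- fixture_reference()
  ctrl <- fixture_control()
  cass <- ref$ledger$cassettes
  ev <- tibble::tibble(kind = "terminal_duplication",
                       extremity = cass$arm1[cass$cassette_id == "C1"],
                       cassette = "C1")
  s <- plant_rearrangements(ref$ledger, ev, clone = "d", seed = 3)
  cl <- analyze_survivor(s$genome, ctrl, clone = "d")
  d <- cl$calls[cl$calls$kind == "terminal_duplication", ]
  expect_equal(nrow(d), 1)
  expect_equal(d$donor, cass$arm2[cass$cassette_id == "C1"])
  expect_equal(d$homology, cass$h[cass$cassette_id == "C1"])
  planted <- s$ledger$events[s$ledger$events$kind == "terminal_duplication", ]
  expect_equal(d$seg_len, planted$seg_len)
  # no duplication planted: no calls
  cl0 <- detect_terminal_duplications(ref$genome, ref$genome, ctrl$maps,
                                      ctrl$maps)
  expect_equal(nrow(cl0), 0)
})

test_that("nested duplications yield two events at one extremity", {
  ref <- fixture_reference()
  ctrl <- fixture_control()
  ev <- tibble::tibble(kind = "nested_duplication", extremity = "chr04_R",
                       cassettes = list(c("C2", "C3")))
  s <- plant_rearrangements(ref$ledger, ev, clone = "n", seed = 4)
  cl <- analyze_survivor(s$genome, ctrl, clone = "n")
  d <- cl$calls[cl$calls$kind == "terminal_duplication", ]
  expect_equal(nrow(d), 2)
  expect_setequal(d$donor, c("chr09_L", "chr11_R"))
  expect_setequal(d$homology, c(800, 400))
  expect_true(all(d$extremity == "chr04_R"))
})

test_that("circularized chromosomes are called; single missing ends are anomalies", {
  ref <- fixture_reference()
  ctrl <- fixture_control()
  s <- plant_rearrangements(ref$ledger,
                            tibble::tibble(kind = "circularization",
                                           chrom = "chr03"),
                            clone = "circ", seed = 6)
  cl <- analyze_survivor(s$genome, ctrl, clone = "circ")
  cc <- cl$calls[cl$calls$kind == "circularization", ]
  expect_equal(nrow(cc), 1)
  expect_setequal(c(cc$extremity, cc$extremity2), c("chr03_L", "chr03_R"))
  # normal survivor: no circularization
  cl0 <- detect_circularization(ref$genome, ref$genome, ctrl$maps)
  expect_equal(sum(cl0$kind == "circularization"), 0)
  # one telomere-free end only: anomaly, not a call
  g2 <- unclass(ref$genome)
  g2[["chr05"]] <- substr(g2[["chr05"]], 1, nchar(g2[["chr05"]]) - 2000)
  g2 <- as_genome(g2)
  maps2 <- build_extremity_maps(g2, ref$ledger$library, ref$ledger$x_ancestor)
  an <- detect_circularization(g2, ref$genome, maps2)
  expect_equal(sum(an$kind == "circularization"), 0)
  expect_true(any(an$kind == "anomaly" & an$chrom == "chr05"))
})

test_that("clone summaries count events and respect exclusions", {
  classes <- tibble::tibble(extremity = paste0("e", 1:6),
                            class = c(rep("yprime", 3), rep("x_only", 3)))
  empty <- summarize_clone(tibble::tibble(kind = character(0),
                                          extremity = character(0)),
                           classes, clone = "z")
  expect_equal(empty$n_loss + empty$n_gain + empty$n_extremities_affected, 0)
  calls <- tibble::tibble(kind = rep("loss", 5),
                          extremity = c("e1", "e1", "e2", "e3", "e3"))
  s <- summarize_clone(calls, classes, clone = "c")
  expect_equal(s$n_loss, 5)
  expect_equal(s$n_extremities_affected, 3)
  expect_equal(s$freq_y, 1)
  expect_equal(s$freq_x, 0)
  # excluded (undetermined) extremities leave the denominators
  s2 <- summarize_clone(calls, classes, excluded = "e3", clone = "c")
  expect_equal(s2$n_extremities_affected, 2)
  expect_equal(s2$n_extremities, 5)
})

test_that("Fisher's exact test equals hypergeometric enumeration", {
  tab <- matrix(c(18, 12, 5, 21), 2, byrow = TRUE)
  res <- compare_groups(tibble::tibble(group = c("a", "a"), freq_x = c(0, 0),
                                       freq_y = c(0, 0),
                                       frac_altered = c(0, 0)),
                        type_counts = tab)
  p_pkg <- res$p_value[res$test == "fisher_type_counts"]
  # enumeration oracle: sum hypergeometric probabilities <= P(observed)
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  xs <- max(0, k - n):min(k, m)
  probs <- dhyper(xs, m, n, k)
  p_oracle <- sum(probs[probs <= dhyper(tab[1, 1], m, n, k) * (1 + 1e-7)])
  expect_lt(abs(p_pkg - p_oracle), 1e-10)
})

test_that("Mann-Whitney on small samples equals permutation enumeration", {
  x <- c(0.31, 0.12, 0.55, 0.47, 0.20)
  y <- c(0.62, 0.81, 0.44, 0.77)
  res <- compare_groups(tibble::tibble(group = "g", freq_x = c(x, NA, NA, NA, NA),
                                       freq_y = c(y, NA, NA, NA, NA, NA),
                                       frac_altered = 0)[1:9, ])
  p_pkg <- res$p_value[res$test == "mann_whitney_class_freq"]
  # full enumeration of the rank-sum distribution
  pooled <- c(y, x)
  n1 <- length(y)
  combs <- utils::combn(length(pooled), n1)
  obs <- sum(rank(pooled)[seq_len(n1)])
  stats <- apply(combs, 2, function(idx) sum(rank(pooled)[idx]))
  mu <- n1 * (length(pooled) + 1) / 2
  p_oracle <- mean(abs(stats - mu) >= abs(obs - mu) - 1e-12)
  expect_equal(p_pkg, p_oracle, tolerance = 1e-12)
  # identical groups give p = 1
  res2 <- compare_groups(tibble::tibble(group = "g",
                                        freq_x = c(0.1, 0.2, 0.3),
                                        freq_y = c(0.1, 0.2, 0.3),
                                        frac_altered = 0))
  expect_equal(res2$p_value[res2$test == "mann_whitney_class_freq"], 1)
  # degenerate group reports NA rather than erroring
  res3 <- compare_groups(tibble::tibble(group = "g", freq_x = 0.1,
                                        freq_y = 0.5, frac_altered = 0))
  expect_true(is.na(res3$p_value[res3$test == "mann_whitney_class_freq"]))
})
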