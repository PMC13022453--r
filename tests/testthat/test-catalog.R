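test_that("homopolymer condensation follows the >4 -> 4 rule and is idempotent", {
  expect_identical(condense_homopolymers("AAAAAA"), "AAAA")
  expect_identical(condense_homopolymers("ACGT"), "ACGT")
  expect_identical(condense_homopolymers("AAAACCCCCGGGGGGT"), "AAAACCCCGGGGT")
  set.seed(8)
  for (i in 1:200) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(10:200, 1),
                      replace = TRUE, prob = c(.4, .1, .1, .4)), collapse = "")
    c1 <- condense_homopolymers(s)
    expect_identical(condense_homopolymers(c1), c1)
    expect_false(grepl("A{5}|C{5}|G{5}|T{5}", c1))
  }
})

test_that("pairwise similarity matches a full dynamic-programming oracle", {
  set.seed(2)
  a <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
  b <- a
  for (p in sample(100:1900, 5)) {
    substr(b, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                      substr(a, p, p)), 1)
  }
  expect_equal(pairwise_similarity(a, a), 100)
  sim <- pairwise_similarity(a, b)
  # independent oracle: Biostrings local alignment under the same scoring
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  al <- Biostrings::pairwiseAlignment(Biostrings::DNAString(a),
                                      Biostrings::DNAString(b),
                                      type = "local",
                                      substitutionMatrix = mat,
                                      gapOpening = 0.1, gapExtension = 0.9)
  cols <- Biostrings::nchar(al)
  pid <- 100 * Biostrings::nmatch(al) / cols
  flanks <- (Biostrings::start(Biostrings::pattern(al)) - 1) +
    (nchar(a) - Biostrings::end(Biostrings::pattern(al))) +
    (Biostrings::start(Biostrings::subject(al)) - 1) +
    (nchar(b) - Biostrings::end(Biostrings::subject(al)))
  oracle <- pid * cols / (cols + flanks)
  expect_lt(abs(sim - oracle), 0.01)
  expect_equal(sim, pairwise_similarity(b, a))
  expect_error(pairwise_similarity("", "ACGT"), "empty")
})

test_that("unrelated random sequences score well below the label threshold", {
  set.seed(9)
  for (i in 1:8) {
    a <- paste(sample(c("A", "C", "G", "T"), 5000, TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), 5000, TRUE), collapse = "")
    expect_lt(pairwise_similarity(a, b), 50)
  }
})

test_that("similarity matrices are symmetric with a 100 diagonal", {
  s <- c(x = "ACGTACGTACGT", y = "ACGTACGTACGT", z = "ACGTACGTACGT")
  m <- similarity_matrix(s)
  expect_true(all(m == 100))
  ref <- fixture_control()
  m2 <- ref$catalog$matrix
  expect_identical(m2, t(m2))
  expect_true(all(diag(m2) == 100))
  expect_true(all(m2 >= 0 & m2 <= 100))
  expect_error(similarity_matrix(s[1]), "at least 2")
})

test_that("within-family similarity exceeds cross-family similarity", {
  ctrl <- fixture_control()
  lib <- fixture_reference()$ledger$library
  map <- fixture_label_map()
  inst <- ctrl$catalog$instances
  fam <- lib$family[match(map$variant_id[match(inst$label, map$label)],
                          lib$variant_id)]
  m <- ctrl$catalog$matrix
  same <- outer(fam, fam, "==") & fam != "intermediate"
  ut <- upper.tri(m)
  within <- m[ut & same]
  cross <- m[ut & !same & outer(fam != "intermediate", fam != "intermediate", "&")]
  grid <- expand.grid(w = within, c = cross)[seq(1, length(within) * length(cross),
                                                 length.out = 2000), ]
  expect_gt(mean(grid$w > grid$c), 0.95)
})

test_that("label assignment respects the 99.9 threshold and its closure", {
  m <- matrix(100, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_equal(length(unique(assign_labels(m)$label)), 1)
  # strictly-greater threshold: a pair at exactly the threshold splits
  m2 <- matrix(c(100, 99.9, 99.9, 100), 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(length(unique(assign_labels(m2, 99.9)$label)), 2)
  # non-transitive chain collapses by single linkage and is flagged fragile
  m3 <- matrix(c(100, 99.95, 99.0,
                 99.95, 100, 99.95,
                 99.0, 99.95, 100), 3, byrow = TRUE,
               dimnames = list(letters[1:3], letters[1:3]))
  lab3 <- assign_labels(m3, 99.9)
  expect_equal(length(unique(lab3$label)), 1)
  expect_true(all(lab3$fragile))
  # control catalog recovers the 20 planted variants from 34 instances
  ctrl <- fixture_control()
  expect_equal(nrow(ctrl$catalog$variants), 20)
  expect_equal(nrow(ctrl$catalog$instances), 34)
})

test_that("clustering recovers planted block structure and is order-invariant", {
  # two planted families with a large gap
  ids <- paste0("v", 1:8)
  m <- matrix(85, 8, 8, dimnames = list(ids, ids))
  m[1:4, 1:4] <- 99
  m[5:8, 5:8] <- 99
  diag(m) <- 100
  cl <- cluster_variants(m)
  expect_equal(cl$k, 2)
  grp <- cl$assignment$cluster
  expect_equal(length(unique(grp[1:4])), 1)
  expect_equal(length(unique(grp[5:8])), 1)
  expect_false(grp[1] == grp[5])
  # permuting the input leaves the partition unchanged
  perm <- c(3, 7, 1, 5, 2, 8, 4, 6)
  cl2 <- cluster_variants(m[perm, perm])
  a1 <- setNames(cl$assignment$cluster, cl$assignment$variant)
  a2 <- setNames(cl2$assignment$cluster, cl2$assignment$variant)
  expect_true(all(outer(a1[ids], a1[ids], "==") ==
                    outer(a2[ids], a2[ids], "==")))
  expect_error(cluster_variants(m[1:2, 1:2]), "at least 3")
  expect_s3_class(tidy(cl), "tbl_df")
  expect_equal(glance(cl)$k, 2)
})

test_that("the default catalog groups its 20 variants into 11 clusters", {
  ctrl <- fixture_control()
  reps <- setNames(ctrl$catalog$variants$representative,
                   ctrl$catalog$variants$label)
  vm <- similarity_matrix(reps)
  cl <- cluster_variants(vm)
  expect_equal(cl$k, 11)
  # clusters coincide with the planted subfamilies (founders + intermediate)
  lib <- fixture_reference()$ledger$library
  map <- fixture_label_map()
  founder <- lib$founder[match(map$variant_id, lib$variant_id)]
  founder[lib$family[match(map$variant_id, lib$variant_id)] == "intermediate"] <-
    "intermediate"
  cluster_of <- cl$assignment$cluster[match(map$label, cl$assignment$variant)]
  expect_equal(length(unique(paste(founder, cluster_of))), 11)
})

test_that("variant length statistics summarise families and flag outliers", {
  v <- tibble::tibble(label = c("a", "b", "c"),
                      length = c(5470, 5470, 5470), family = "short")
  s <- variant_length_stats(v)
  expect_equal(s$stats$min, s$stats$max)
  expect_equal(s$stats$mean, 5470)
  lib <- fixture_reference()$ledger$library
  s2 <- variant_length_stats(dplyr::rename(lib, label = "variant_id"))
  short <- s2$stats[s2$stats$family == "short", ]
  expect_equal(short$mean, mean(lib$length[lib$family == "short"]))
  expect_equal(nrow(s2$intermediates), 1)
  expect_equal(s2$intermediates$length, 5981)
})

test_that("replicate assemblies with homopolymer noise keep identical catalogs", {
  ref <- fixture_reference()
  g1 <- replicate_assembly_noise(ref$genome, seed = 31)
  ctrl0 <- fixture_control()
  maps1 <- build_extremity_maps(g1, ref$ledger$library, ref$ledger$x_ancestor)
  cat1 <- build_catalog(maps1)
  expect_equal(nrow(cat1$variants), nrow(ctrl0$catalog$variants))
  expect_equal(nrow(cat1$instances), nrow(ctrl0$catalog$instances))
  # homologous instances (same extremity and index) score sim >= 99.98
  j <- dplyr::inner_join(ctrl0$catalog$instances, cat1$instances,
                         by = c("extremity", "index"),
                         suffix = c("_a", "_b"))
  sims <- purrr::map2_dbl(j$condensed_a, j$condensed_b, pairwise_similarity)
  expect_equal(nrow(j), 34)
  expect_true(all(sims >= 99.98))
})
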