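#' Compare control and survivor Y' label strings at one extremity
#'
#' The two centromere-to-telomere label vectors are aligned by minimum edit
#' distance with matches free, indels costing 1 and label substitution
#' disallowed (equivalently: a longest-common-subsequence alignment, so no
#' surviving label is ever paired with a different control label only to be
#' reported as a phantom loss-plus-gain pair). Control labels left unmatched
#' are losses, survivor labels left unmatched are gains; a replaced label
#' therefore yields one loss plus one gain. A gained label identical to an
#' adjacent survivor label is additionally reported as a tandem
#' amplification; a gained label absent from the control catalog is
#' additionally reported as a new variant.
#'
#' @param control_labels,survivor_labels Character vectors of labels ordered
#'   centromere to telomere.
#' @param extremity Extremity id carried into the calls.
#' @param catalog_labels All labels present in the control catalog.
#' @return Tibble of calls (kind, extremity, label, position).
#' @export
diff_extremity <- function(control_labels, survivor_labels, extremity = NA,
                           catalog_labels = unique(control_labels)) {
  a <- control_labels
  b <- survivor_labels
  n <- length(a); m <- length(b)
  D <- matrix(0, n + 1, m + 1)
  D[, 1] <- 0:n
  D[1, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      D[i + 1, j + 1] <- min(D[i, j] + if (a[i] == b[j]) 0 else Inf,
                             D[i, j + 1] + 1,
                             D[i + 1, j] + 1)
    }
  }
  # traceback, preferring matches, then deletion, then insertion
  i <- n; j <- m
  losses <- integer(0); gains <- integer(0)
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 && a[i] == b[j] && D[i + 1, j + 1] == D[i, j]) {
      i <- i - 1; j <- j - 1
    } else if (i > 0 && D[i + 1, j + 1] == D[i, j + 1] + 1) {
      losses <- c(losses, i)
      i <- i - 1
    } else {
      gains <- c(gains, j)
      j <- j - 1
    }
  }
  calls <- list()
  for (p in rev(losses)) {
    calls[[length(calls) + 1L]] <- tibble::tibble(
      kind = "loss", extremity = extremity, label = a[p], position = p - 1L)
  }
  for (p in rev(gains)) {
    lab <- b[p]
    calls[[length(calls) + 1L]] <- tibble::tibble(
      kind = "gain", extremity = extremity, label = lab, position = p - 1L)
    neighbours <- c(if (p > 1) b[p - 1], if (p < m) b[p + 1])
    if (lab %in% neighbours) {
      calls[[length(calls) + 1L]] <- tibble::tibble(
        kind = "tandem_amplification", extremity = extremity, label = lab,
        position = p - 1L)
    }
    if (!lab %in% catalog_labels) {
      calls[[length(calls) + 1L]] <- tibble::tibble(
        kind = "new_variant", extremity = extremity, label = lab,
        position = p - 1L)
    }
  }
  if (!length(calls)) {
    return(tibble::tibble(kind = character(0), extremity = character(0),
                          label = character(0), position = integer(0)))
  }
  dplyr::bind_rows(calls)
}

#' Explain a new Y' sequence as a mosaic of known elements
#'
#' Enumerates maximal perfect matches of at least `mosaic_min_exact` bp
#' between the new sequence and every catalog variant (both orientations).
#' The sequence is mosaic when the union of such matches covers it entirely;
#' the reported decomposition is greedy (longest match first, leftmost on
#' ties).
#'
#' @param new_sequence The new Y' sequence.
#' @param catalog_seqs Named character vector of known Y' sequences.
#' @param config A [telo_config()].
#' @return A list of class `mosaic_decomposition` (`segments` tibble,
#'   `coverage` fraction, `donors`, `mosaic` flag), or `NULL` when no match
#'   at all explains any part of the sequence.
#' @export
explain_mosaic <- function(new_sequence, catalog_seqs,
                           config = telo_config()) {
  min_len <- config$mosaic_min_exact
  n <- nchar(new_sequence)
  segs <- purrr::imap_dfr(catalog_seqs, function(v, id) {
    fwd <- cpp_mems(new_sequence, v, k = 21L, min_len = min_len,
                    max_bucket = 64L)
    rev <- cpp_mems(new_sequence, revcomp(v), k = 21L, min_len = min_len,
                    max_bucket = 64L)
    out <- list()
    if (nrow(fwd)) out$f <- tibble::tibble(donor = id, strand = "+",
                                           start = fwd$qstart,
                                           end = fwd$qstart + fwd$length,
                                           donor_start = fwd$tstart,
                                           length = fwd$length)
    if (nrow(rev)) out$r <- tibble::tibble(donor = id, strand = "-",
                                           start = rev$qstart,
                                           end = rev$qstart + rev$length,
                                           donor_start = rev$tstart,
                                           length = rev$length)
    dplyr::bind_rows(out)
  })
  if (!nrow(segs)) return(NULL)
  # coverage of the union of all matches
  iv <- segs[order(segs$start), c("start", "end")]
  cov <- 0; cur_s <- iv$start[1]; cur_e <- iv$end[1]
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv$start[i] <= cur_e) cur_e <- max(cur_e, iv$end[i])
    else { cov <- cov + cur_e - cur_s; cur_s <- iv$start[i]; cur_e <- iv$end[i] }
  }
  cov <- cov + cur_e - cur_s
  coverage <- cov / n
  # greedy decomposition: longest first, leftmost tie-break
  pool <- segs[order(-segs$length, segs$start), ]
  covered <- logical(n)
  chosen <- list()
  for (i in seq_len(nrow(pool))) {
    idx <- pool$start[i]:(pool$end[i] - 1L)
    if (any(!covered[idx])) {
      chosen[[length(chosen) + 1L]] <- pool[i, ]
      covered[idx] <- TRUE
    }
    if (all(covered)) break
  }
  chosen <- dplyr::bind_rows(chosen)
  donors <- unique(chosen$donor)
  rearranged <- length(donors) == 1 &&
    nrow(chosen) > 1 && is.unsorted(chosen$donor_start[order(chosen$start)])
  structure(list(segments = chosen[order(chosen$start), ],
                 coverage = coverage, donors = donors,
                 mosaic = coverage >= 1 && (length(donors) >= 2 || rearranged)),
            class = "mosaic_decomposition")
}

#' Detect BIR-like terminal duplications
#'
#' For every extremity with an X element in both genomes, the region
#' upstream of the X element is compared with its control counterpart over
#' `upstream_window` bp. On deviation, the divergent terminal segment is
#' mapped against all control extremities and decomposed into a chain of
#' donor-arm segments; the junction homology is the longest exact match
#' spanning each junction (the donor match extends back into the shared
#' recipient sequence).
#'
#' @param survivor_genome,control_genome `telo_genome`s.
#' @param survivor_maps,control_maps Annotations from
#'   [build_extremity_maps()].
#' @param config A [telo_config()].
#' @return Tibble of calls (kind = terminal_duplication, extremity, donor,
#'   junction position in canonical coordinates, homology, seg_len); one row
#'   per donor segment, so nested duplications yield several rows at one
#'   extremity.
#' @export
detect_terminal_duplications <- function(survivor_genome, control_genome,
                                         survivor_maps, control_maps,
                                         config = telo_config()) {
  s_ext <- extremities(survivor_genome, config$extremity_window)
  c_ext <- extremities(control_genome, config$extremity_window)
  shared <- intersect(s_ext$extremity, c_ext$extremity)
  out <- list()
  for (e in shared) {
    xs <- survivor_maps[survivor_maps$extremity == e &
                          survivor_maps$feature == "x_element", ]
    xc <- control_maps[control_maps$extremity == e &
                         control_maps$feature == "x_element", ]
    if (!nrow(xs) || !nrow(xc)) next
    ss <- s_ext$seq[s_ext$extremity == e]
    cs <- c_ext$seq[c_ext$extremity == e]
    up_s <- substr(ss, max(1L, xs$start[1] - config$upstream_window + 1L),
                   xs$start[1])
    up_c <- substr(cs, max(1L, xc$start[1] - config$upstream_window + 1L),
                   xc$start[1])
    if (identical(up_s, up_c)) next
    # locate the divergence point of the survivor arm from its own control:
    # the centromere-proximal chain (smallest survivor start; the two
    # canonical windows begin at different depths of the shared core when
    # chromosome lengths differ, so no fixed offset is assumed)
    anchor <- chain_mems(cpp_mems(cs, ss, k = 31L, min_len = 200L,
                                  max_bucket = 16L), max_gap = 50)
    if (!nrow(anchor)) next
    anchor <- anchor[which.min(anchor$tstart), ]
    p <- anchor$tend - 1L # 0-based divergence point on survivor
    if (p >= nchar(ss) - 5) next
    # map the divergent tail against every other control arm
    mems_all <- purrr::map_dfr(seq_len(nrow(c_ext)), function(k) {
      if (c_ext$extremity[k] == e) return(tibble::tibble())
      m <- chain_mems(cpp_mems(c_ext$seq[k], ss, k = 31L, min_len = 300L,
                               max_bucket = 16L), max_gap = 50)
      if (!nrow(m)) return(tibble::tibble())
      m$donor <- c_ext$extremity[k]
      m
    })
    cur <- p
    guard <- 0L
    while (cur < nchar(ss) - 5 && guard < 8L) {
      guard <- guard + 1L
      cand <- mems_all[mems_all$tstart - 1L <= cur & mems_all$tend - 1L > cur + 200, ]
      if (!nrow(cand)) break
      bi <- which.max(cand$tend)
      hom <- cur - (cand$tstart[bi] - 1L)
      out[[length(out) + 1L]] <- tibble::tibble(
        kind = "terminal_duplication", extremity = e,
        donor = cand$donor[bi], junction = cur, homology = hom,
        seg_len = cand$tend[bi] - 1L - cur)
      cur <- cand$tend[bi] - 1L
    }
  }
  if (!length(out)) {
    return(tibble::tibble(kind = character(0), extremity = character(0),
                          donor = character(0), junction = integer(0),
                          homology = numeric(0), seg_len = numeric(0)))
  }
  dplyr::bind_rows(out)
}

#' Detect chromosome circularization
#'
#' Flags chromosomes whose two extremities both lack a terminal telomere
#' tract and whose two terminal `upstream_window` segments map to the same
#' control chromosome (the emitted contig is the circle linearized at an
#' arbitrary point). A chromosome missing a tract at only one end is
#' reported as an anomaly, not called.
#'
#' @inheritParams detect_terminal_duplications
#' @return Tibble (kind = circularization | anomaly, chrom, extremity,
#'   extremity2 = the matched control chromosome's two arms for calls).
#' @export
detect_circularization <- function(survivor_genome, control_genome,
                                   survivor_maps, config = telo_config()) {
  out <- list()
  for (ch in names(survivor_genome)) {
    ids <- paste0(ch, c("_L", "_R"))
    has_tel <- vapply(ids, function(e) {
      any(survivor_maps$extremity == e & survivor_maps$feature == "telomere")
    }, logical(1))
    if (all(has_tel)) next
    if (sum(has_tel) == 1) {
      out[[length(out) + 1L]] <- tibble::tibble(
        kind = "anomaly", chrom = ch, extremity = ids[!has_tel][1],
        extremity2 = NA_character_)
      next
    }
    len <- nchar(survivor_genome[[ch]])
    w <- min(config$upstream_window, len %/% 2)
    seg1 <- substr(survivor_genome[[ch]], 1L, w)
    seg2 <- substr(survivor_genome[[ch]], len - w + 1L, len)
    # the circle is mostly chromosome core, so segments are mapped against
    # the full control chromosomes (both strands), not extremity windows
    hit_chrom <- function(seg) {
      best_cov <- 0; best_chrom <- NA_character_
      for (cn in names(control_genome)) {
        for (sq in c(seg, revcomp(seg))) {
          m <- chain_mems(cpp_mems(sq, control_genome[[cn]], k = 31L,
                                   min_len = 500L, max_bucket = 16L),
                          max_gap = 100)
          if (!nrow(m)) next
          # union of chain spans on the segment: a segment crossing the
          # circle junction maps in two chains to the same chromosome
          iv <- m[order(m$qstart), c("qstart", "qend")]
          cov <- 0; cs <- iv$qstart[1]; ce <- iv$qend[1]
          for (ii in seq_len(nrow(iv))[-1]) {
            if (iv$qstart[ii] <= ce) ce <- max(ce, iv$qend[ii])
            else { cov <- cov + ce - cs; cs <- iv$qstart[ii]; ce <- iv$qend[ii] }
          }
          cov <- cov + ce - cs
          if (cov > best_cov) { best_cov <- cov; best_chrom <- cn }
        }
      }
      if (best_cov >= 0.8 * w) best_chrom else NA_character_
    }
    h1 <- hit_chrom(seg1); h2 <- hit_chrom(seg2)
    if (!is.na(h1) && identical(h1, h2)) {
      out[[length(out) + 1L]] <- tibble::tibble(
        kind = "circularization", chrom = ch,
        extremity = paste0(h1, "_L"), extremity2 = paste0(h1, "_R"))
    } else {
      out[[length(out) + 1L]] <- tibble::tibble(
        kind = "anomaly", chrom = ch, extremity = ids[1],
        extremity2 = NA_character_)
    }
  }
  if (!length(out)) {
    return(tibble::tibble(kind = character(0), chrom = character(0),
                          extremity = character(0), extremity2 = character(0)))
  }
  dplyr::bind_rows(out)
}

#' Summarise the rearrangement calls of one clone
#'
#' Counts calls per kind, the number of affected extremities, and per-class
#' (X-only versus Y'-bearing, classes taken from the control map) alteration
#' frequencies. Undetermined extremities are excluded from all denominators.
#'
#' @param calls Call tibble (columns kind, extremity).
#' @param control_classes Tibble (extremity, class) with class `x_only` or
#'   `yprime`, from [extremity_classes()].
#' @param excluded Extremities excluded from denominators (undetermined or
#'   skipped).
#' @param clone Clone name.
#' @return One-row tibble of class counts and frequencies.
#' @export
summarize_clone <- function(calls, control_classes, excluded = character(0),
                            clone = NA_character_) {
  yk <- c("loss", "gain", "tandem_amplification", "new_variant")
  cc <- control_classes[!control_classes$extremity %in% excluded, ]
  y_events <- calls[calls$kind %in% yk, ]
  affected_y <- unique(y_events$extremity)
  affected_any <- unique(calls$extremity[calls$kind %in%
                                           c(yk, "terminal_duplication",
                                             "circularization")])
  cls <- function(klass) {
    ext <- cc$extremity[cc$class == klass]
    if (!length(ext)) return(NA_real_)
    mean(ext %in% affected_any)
  }
  tibble::tibble(
    clone = clone,
    n_loss = sum(calls$kind == "loss"),
    n_gain = sum(calls$kind == "gain"),
    n_tandem_amplification = sum(calls$kind == "tandem_amplification"),
    n_new_variant = sum(calls$kind == "new_variant"),
    n_terminal_duplication = sum(calls$kind == "terminal_duplication"),
    n_circularization = sum(calls$kind == "circularization"),
    n_extremities_affected = length(intersect(affected_y, cc$extremity)),
    n_extremities = nrow(cc),
    frac_altered = length(intersect(affected_any, cc$extremity)) /
      max(1L, nrow(cc)),
    freq_x = cls("x_only"),
    freq_y = cls("yprime")
  )
}

#' Extremity classes of a control genome
#'
#' @param control_maps Control annotation.
#' @return Tibble (extremity, class) where class is `yprime` when at least
#'   one Y' element is annotated and `x_only` otherwise.
#' @export
extremity_classes <- function(control_maps) {
  ext <- unique(control_maps$extremity)
  has_y <- vapply(ext, function(e) {
    any(control_maps$extremity == e & control_maps$feature == "yprime")
  }, logical(1))
  tibble::tibble(extremity = ext,
                 class = ifelse(has_y, "yprime", "x_only"))
}

#' Group comparison statistics
#'
#' Reproduces the study's statistical toolkit on clone summaries: per-group
#' two-sided Mann-Whitney comparison of alteration frequencies at Y'-bearing
#' versus X-only extremities, pairwise two-sided Student's t-tests of the
#' fraction of altered extremities between groups, and, when a 2x2 count
#' table is supplied, a two-sided Fisher's exact test of survivor-type
#' proportions. P-values are not adjusted for multiplicity. Degenerate
#' inputs (fewer than two observations in a group) yield NA rows rather than
#' errors.
#'
#' @param summaries Tibble of clone summaries (from [summarize_clone()])
#'   with a `group` column.
#' @param type_counts Optional 2x2 matrix of survivor-type counts for
#'   Fisher's exact test.
#' @return Tidy tibble (test, group1, group2, estimate1, estimate2,
#'   statistic, p_value).
#' @export
compare_groups <- function(summaries, type_counts = NULL) {
  s <- tibble::as_tibble(summaries)
  if (!"group" %in% names(s)) s$group <- "all"
  rows <- list()
  safe <- function(expr) tryCatch(suppressWarnings(expr),
                                  error = function(e) NULL)
  for (g in unique(s$group)) {
    sg <- s[s$group == g, ]
    x <- sg$freq_x[!is.na(sg$freq_x)]
    y <- sg$freq_y[!is.na(sg$freq_y)]
    ht <- if (length(x) >= 2 && length(y) >= 2) {
      safe(stats::wilcox.test(y, x, alternative = "two.sided", exact = TRUE))
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      test = "mann_whitney_class_freq", group1 = g, group2 = g,
      estimate1 = mean(y), estimate2 = mean(x),
      statistic = if (!is.null(ht)) unname(ht$statistic) else NA_real_,
      p_value = if (!is.null(ht)) ht$p.value else NA_real_)
  }
  gs <- unique(s$group)
  if (length(gs) > 1) {
    for (i in seq_along(gs)[-length(gs)]) {
      for (j in (i + 1):length(gs)) {
        a <- s$frac_altered[s$group == gs[i]]
        b <- s$frac_altered[s$group == gs[j]]
        ht <- if (length(a) >= 2 && length(b) >= 2) {
          safe(stats::t.test(a, b, alternative = "two.sided"))
        }
        rows[[length(rows) + 1L]] <- tibble::tibble(
          test = "t_frac_altered", group1 = gs[i], group2 = gs[j],
          estimate1 = mean(a), estimate2 = mean(b),
          statistic = if (!is.null(ht)) unname(ht$statistic) else NA_real_,
          p_value = if (!is.null(ht)) ht$p.value else NA_real_)
      }
    }
  }
  if (!is.null(type_counts)) {
    ht <- safe(stats::fisher.test(type_counts, alternative = "two.sided"))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      test = "fisher_type_counts", group1 = rownames(type_counts)[1] %||% "r1",
      group2 = rownames(type_counts)[2] %||% "r2",
      estimate1 = type_counts[1, 1] / sum(type_counts[1, ]),
      estimate2 = type_counts[2, 1] / sum(type_counts[2, ]),
      statistic = if (!is.null(ht)) unname(ht$estimate) else NA_real_,
      p_value = if (!is.null(ht)) ht$p.value else NA_real_)
  }
  dplyr::bind_rows(rows)
}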