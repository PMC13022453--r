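#' Find perfect tandem repeat arrays in a telomere tract
#'
#' Reports every maximal perfect tandem array with a primitive unit of at
#' least `min_unit` bp and at least `min_copies` full copies. An array is
#' anchored at the leftmost start of its maximal periodic region (exactly
#' one report per region and period), is not extendable by a further full
#' unit on either side, and its interval is an exact concatenation of the
#' unit (interval length = unit length x copies).
#'
#' @param seq Telomere tract (canonical frame).
#' @param min_unit Minimum unit length (bp).
#' @param min_copies Minimum copy number.
#' @return Tibble (start, unit_len, copies, end, unit); `start` 0-based,
#'   `end = start + unit_len * copies`.
#' @export
find_perfect_tandem_arrays <- function(seq, min_unit = 30, min_copies = 2) {
  none <- tibble::tibble(start = integer(0), unit_len = integer(0),
                         copies = integer(0), end = integer(0),
                         unit = character(0))
  n <- nchar(seq)
  if (n < 2 * min_unit) return(none)
  res <- cpp_tandem_scan(seq, min_unit, min_copies)
  if (!nrow(res)) return(none)
  out <- tibble::tibble(
    start = as.integer(res$start) - 1L,
    unit_len = as.integer(res$unit_len),
    copies = as.integer(res$copies)
  )
  out$end <- out$start + out$unit_len * out$copies
  out$unit <- substring(seq, out$start + 1L, out$start + out$unit_len)
  out
}

is_primitive <- function(unit) {
  L <- nchar(unit)
  for (d in seq_len(L %/% 2)) {
    if (L %% d != 0) next
    if (identical(unit, strrep(substr(unit, 1L, d), L %/% d))) return(FALSE)
  }
  TRUE
}

#' Reference brute-force tandem array scanner
#'
#' Direct per-start, per-unit-length enumeration with the same array
#' definition as [find_perfect_tandem_arrays()]; used as an independent
#' check of the production scanner.
#'
#' @inheritParams find_perfect_tandem_arrays
#' @return Tibble (start, unit_len, copies), 0-based starts.
#' @export
scan_tandem_bruteforce <- function(seq, min_unit = 30, min_copies = 2) {
  res <- cpp_tandem_brute(seq, min_unit, min_copies)
  tibble::tibble(start = as.integer(res$start) - 1L,
                 unit_len = as.integer(res$unit_len),
                 copies = as.integer(res$copies))
}

rotations_min <- function(unit) {
  d <- paste0(unit, unit)
  rots <- substring(d, seq_len(nchar(unit)), seq_len(nchar(unit)) + nchar(unit) - 1L)
  min(rots)
}

# Circular-permutation-aware normalized alignment score between two units:
# the doubled first unit is locally aligned against the second; the score is
# normalized by the longer unit length so only same-length (rotated,
# near-identical) units can exceed ~1.
circle_unit_score <- function(a, b, config = telo_config()) {
  al <- cpp_local_align(paste0(a, a), b, config$align_match,
                        config$align_mismatch, config$align_gap_open,
                        config$align_gap_ext)
  al$score / max(nchar(a), nchar(b))
}

#' Consolidate tandem arrays into candidate t-circles
#'
#' Drops units shorter than `tandem_use_min_unit`, keeps arrays with at
#' least `tandem_min_copies_circle` copies, groups units whose
#' circular-permutation-aware normalized alignment score exceeds
#' `circle_merge_score`, and represents each group by its most common unit
#' (largest total copy support; ties broken by length, then by the
#' lexicographically smallest rotation). Circle ids are
#' `Circle_<unit length>`.
#'
#' @param arrays Array tibble for one clone ([find_perfect_tandem_arrays()]
#'   output plus an `extremity` column).
#' @param config A [telo_config()].
#' @return Tibble (circle_id, unit, unit_len, n_arrays, total_copies).
#' @export
consolidate_circles <- function(arrays, config = telo_config()) {
  none <- tibble::tibble(circle_id = character(0), unit = character(0),
                         unit_len = integer(0), n_arrays = integer(0),
                         total_copies = integer(0))
  a <- arrays[arrays$unit_len >= config$tandem_use_min_unit &
                arrays$copies >= config$tandem_min_copies_circle, ]
  if (!nrow(a)) return(none)
  # group by exact unit (any rotation) first
  a$rot_key <- vapply(a$unit, rotations_min, "")
  by_unit <- dplyr::summarise(dplyr::group_by(a, .data$rot_key),
                              unit = .data$unit[1],
                              unit_len = .data$unit_len[1],
                              n_arrays = dplyr::n(),
                              total_copies = sum(.data$copies),
                              .groups = "drop")
  # then merge highly similar units
  k <- nrow(by_unit)
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (k > 1) {
    for (i in 1:(k - 1)) {
      for (j in (i + 1):k) {
        sc <- max(circle_unit_score(by_unit$unit[i], by_unit$unit[j], config),
                  circle_unit_score(by_unit$unit[j], by_unit$unit[i], config))
        if (sc > config$circle_merge_score) parent[find(j)] <- find(i)
      }
    }
  }
  comp <- vapply(seq_len(k), find, 0L)
  out <- purrr::map_dfr(unique(comp), function(cmp) {
    g <- by_unit[comp == cmp, ]
    g <- g[order(-g$total_copies, -g$unit_len, vapply(g$unit, rotations_min, "")), ]
    tibble::tibble(circle_id = paste0("Circle_", g$unit_len[1]),
                   unit = g$unit[1], unit_len = g$unit_len[1],
                   n_arrays = sum(g$n_arrays),
                   total_copies = sum(g$total_copies))
  })
  out[order(-out$unit_len), ]
}

#' Match a circle unit across a telomere
#'
#' Slides a window of the unit length (step 1) along the sequence and calls
#' a match when the normalized local alignment score of the doubled unit
#' against the window exceeds `circle_match_score` (exact rotations are
#' recognized directly). Non-overlapping matches are reported with the
#' phase (starting rotation of the unit) and merged into runs of contiguous
#' copies.
#'
#' @param unit Circle unit sequence.
#' @param seq Telomere sequence to scan.
#' @param config A [telo_config()].
#' @return Tibble (start, end, phase, copies, min_score); `start` 0-based,
#'   contiguous matches merged.
#' @export
match_circle <- function(unit, seq, config = telo_config()) {
  none <- tibble::tibble(start = integer(0), end = integer(0),
                         phase = integer(0), copies = integer(0),
                         min_score = numeric(0))
  if (is.na(seq) || !nchar(seq)) return(none)
  m <- cpp_circle_scan(unit, seq, config$circle_match_score,
                       config$align_match, config$align_mismatch,
                       config$align_gap_open, config$align_gap_ext)
  if (!nrow(m)) return(none)
  u <- nchar(unit)
  # merge contiguous windows into runs; the run phase is anchored on the
  # best-scoring (ideally exact) window of the run, because the alignment
  # phase estimate of an imperfect boundary window can be off by a gap
  run_id <- cumsum(c(1L, (m$start[-1] - m$start[-nrow(m)]) != u))
  purrr::map_dfr(split(seq_len(nrow(m)), run_id), function(idx) {
    st <- m$start[idx] - 1L
    best <- idx[which.max(m$score[idx])]
    phase0 <- (m$phase[m$start == m$start[best]][1] -
                 (m$start[best] - m$start[idx[1]])) %% u
    tibble::tibble(start = st[1], end = st[1] + length(idx) * u,
                   phase = as.integer(phase0), copies = length(idx),
                   min_score = min(m$score[idx]))
  })
}

#' Specificity filter and origin tracing for a circle
#'
#' Counts unit occurrences in the telomeres of every other assembly: more
#' than one copy in any other assembly discards the circle (its sequence is
#' not specific enough); exactly one copy in the control records that locus
#' as the circle's origin.
#'
#' @param circle One row of [consolidate_circles()] output.
#' @param own_tracts Telomere tract tibble (extremity, seq) of the clone the
#'   circle was found in.
#' @param other_tracts Named list of tract tibbles for the other survivor
#'   assemblies.
#' @param control_tracts Tract tibble of the control assembly.
#' @param config A [telo_config()].
#' @return The circle row annotated with `kept`, `origin_extremity`,
#'   `origin_start` (NA when unknown).
#' @export
specificity_filter_and_origin <- function(circle, own_tracts, other_tracts,
                                          control_tracts,
                                          config = telo_config()) {
  count_in <- function(tracts) {
    hits <- purrr::map_dfr(seq_len(nrow(tracts)), function(i) {
      m <- match_circle(circle$unit, tracts$seq[i], config)
      if (!nrow(m)) return(tibble::tibble())
      m$extremity <- tracts$extremity[i]
      m
    })
    hits
  }
  n_copies <- function(h) if (nrow(h) && "copies" %in% names(h)) sum(h$copies) else 0
  kept <- TRUE
  for (tr in other_tracts) {
    h <- count_in(tr)
    if (n_copies(h) > 1) { kept <- FALSE; break }
  }
  origin_e <- NA_character_; origin_s <- NA_integer_
  if (kept) {
    hc <- count_in(control_tracts)
    if (n_copies(hc) == 1) {
      origin_e <- hc$extremity[1]
      origin_s <- hc$start[1]
    }
  }
  dplyr::mutate(circle, kept = kept, origin_extremity = origin_e,
                origin_start = origin_s)
}

#' Containment relations between circles of one clone
#'
#' Reports ordered pairs where the smaller unit matches inside the larger
#' one (circular-permutation-aware, normalized by the smaller unit length).
#'
#' @param circles Circle tibble of one clone.
#' @param config A [telo_config()].
#' @return Tibble (inner, outer, score).
#' @export
nested_circle_relations <- function(circles, config = telo_config()) {
  none <- tibble::tibble(inner = character(0), outer = character(0),
                         score = numeric(0))
  if (nrow(circles) < 2) return(none)
  rows <- list()
  for (i in seq_len(nrow(circles))) {
    for (j in seq_len(nrow(circles))) {
      if (i == j) next
      if (circles$unit_len[i] >= circles$unit_len[j]) next
      # rotation-aware containment: scan the inner unit (any rotation, via
      # its doubled form inside cpp_circle_scan) across the doubled outer
      # unit, which exposes all linearizations of the outer circle
      m <- match_circle(circles$unit[i],
                        paste0(circles$unit[j], circles$unit[j]), config)
      if (nrow(m)) {
        sc <- max(m$min_score)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          inner = circles$circle_id[i], outer = circles$circle_id[j],
          score = sc)
      }
    }
  }
  if (!length(rows)) return(none)
  dplyr::bind_rows(rows)
}

#' Fraction of telomeric DNA in tandem arrays
#'
#' Perfect fraction: union of perfect tandem array intervals (units of at
#' least `tandem_use_min_unit` bp) over total telomeric bp. Extended
#' fraction: additionally counts single or imperfect circle-unit matches
#' (normalized score above `circle_match_score`, any copy count).
#'
#' @param tracts Tract tibble (extremity, seq) of one clone.
#' @param arrays Array tibble of the clone (with `extremity`).
#' @param circles Consolidated circle tibble of the clone.
#' @param config A [telo_config()].
#' @return One-row tibble (total_bp, perfect_bp, extended_bp,
#'   perfect_fraction, extended_fraction); fractions NA when there is no
#'   telomeric DNA.
#' @export
tandem_fraction <- function(tracts, arrays, circles, config = telo_config()) {
  total <- sum(nchar(tracts$seq))
  if (total == 0) {
    return(tibble::tibble(total_bp = 0, perfect_bp = NA_real_,
                          extended_bp = NA_real_,
                          perfect_fraction = NA_real_,
                          extended_fraction = NA_real_))
  }
  iv_union <- function(df) {
    if (!nrow(df) || !all(c("extremity", "start", "end") %in% names(df))) {
      return(0)
    }
    tot <- 0
    for (e in unique(df$extremity)) {
      d <- df[df$extremity == e, c("start", "end")]
      d <- d[order(d$start), ]
      cs <- d$start[1]; ce <- d$end[1]
      for (i in seq_len(nrow(d))[-1]) {
        if (d$start[i] <= ce) ce <- max(ce, d$end[i])
        else { tot <- tot + ce - cs; cs <- d$start[i]; ce <- d$end[i] }
      }
      tot <- tot + ce - cs
    }
    tot
  }
  perf <- if (nrow(arrays) && "unit_len" %in% names(arrays)) {
    arrays[arrays$unit_len >= config$tandem_use_min_unit,
           c("extremity", "start", "end")]
  } else {
    tibble::tibble(extremity = character(0), start = integer(0),
                   end = integer(0))
  }
  perfect_bp <- iv_union(perf)
  extra <- purrr::map_dfr(seq_len(nrow(circles)), function(ci) {
    purrr::map_dfr(seq_len(nrow(tracts)), function(ti) {
      m <- match_circle(circles$unit[ci], tracts$seq[ti], config)
      if (!nrow(m)) return(tibble::tibble())
      tibble::tibble(extremity = tracts$extremity[ti], start = m$start,
                     end = m$end)
    })
  })
  ext_bp <- iv_union(dplyr::bind_rows(perf, extra))
  tibble::tibble(total_bp = total, perfect_bp = perfect_bp,
                 extended_bp = ext_bp,
                 perfect_fraction = perfect_bp / total,
                 extended_fraction = ext_bp / total)
}
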