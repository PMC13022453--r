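#' Detect the terminal telomere tract of a canonical extremity
#'
#' Slides a 20 bp window (step 1) along the canonical sequence, scores each
#' window by the fraction of its 6-mers generable by the degenerate TG1-3
#' grammar, keeps windows scoring at least `tel_score`, bridges gaps up to
#' `tel_bridge` bp, and reports the maximal terminal run reaching the
#' sequence end. Runs shorter than `min_tract` are not reported.
#'
#' @param seq Canonical extremity sequence (telomere rightward).
#' @param config A [telo_config()].
#' @return A one-row tibble (start, end, length; 0-based half-open canonical
#'   coordinates) or a zero-row tibble when no terminal tract is found.
#' @export
detect_telomere_tract <- function(seq, config = telo_config()) {
  none <- tibble::tibble(start = integer(0), end = integer(0),
                         length = integer(0))
  n <- nchar(seq)
  w <- config$tel_window
  if (n < max(w, 6)) return(none)
  # scan only the terminal region, growing it while the tract fills it
  scan <- min(n, 16000L)
  repeat {
    res <- scan_terminal_tract(substr(seq, n - scan + 1L, n), config)
    if (!nrow(res)) return(none)
    if (res$start > 0L || scan == n) {
      res$start <- res$start + (n - scan)
      res$end <- res$end + (n - scan)
      if (res$length < config$min_tract) return(none)
      return(res)
    }
    scan <- min(n, scan * 2L)
  }
}

scan_terminal_tract <- function(seq, config) {
  none <- tibble::tibble(start = integer(0), end = integer(0),
                         length = integer(0))
  n <- nchar(seq)
  w <- config$tel_window
  if (n < max(w, 6)) return(none)
  prof <- telomericity_profile(seq, window = w)
  ok <- which(prof >= config$tel_score)
  if (!length(ok)) return(none)
  # covered intervals (0-based half-open), merged across bridgeable gaps
  iv_start <- ok - 1L
  iv_end <- ok - 1L + w
  keep_start <- iv_start[1]
  merged <- list()
  cur_end <- iv_end[1]
  for (i in seq_along(iv_start)[-1]) {
    if (iv_start[i] - cur_end <= config$tel_bridge) {
      cur_end <- max(cur_end, iv_end[i])
    } else {
      merged[[length(merged) + 1L]] <- c(keep_start, cur_end)
      keep_start <- iv_start[i]
      cur_end <- iv_end[i]
    }
  }
  merged[[length(merged) + 1L]] <- c(keep_start, cur_end)
  last <- merged[[length(merged)]]
  if (last[2] < n - config$tel_bridge) return(none)
  len <- n - last[1]
  if (len < config$min_tract) return(none)
  tibble::tibble(start = as.integer(last[1]), end = as.integer(n),
                 length = as.integer(len))
}

# Chain maximal exact matches into alignment-like blocks: MEMs sorted by
# target start are grouped while the target gap and the diagonal shift stay
# small. Returns one row per chain with target/query spans.
chain_mems <- function(mems, max_gap = 150, max_shift = 50) {
  if (!nrow(mems)) {
    return(tibble::tibble(tstart = integer(0), tend = integer(0),
                          qstart = integer(0), qend = integer(0)))
  }
  m <- mems[order(mems$tstart), ]
  diag <- m$tstart - m$qstart
  chain_id <- integer(nrow(m))
  cur <- 1L
  chain_id[1] <- cur
  cur_end <- m$tstart[1] + m$length[1]
  cur_diag <- diag[1]
  for (i in seq_len(nrow(m))[-1]) {
    if (m$tstart[i] - cur_end <= max_gap && abs(diag[i] - cur_diag) <= max_shift) {
      chain_id[i] <- cur
      cur_end <- max(cur_end, m$tstart[i] + m$length[i])
      cur_diag <- diag[i]
    } else {
      cur <- cur + 1L
      chain_id[i] <- cur
      cur_end <- m$tstart[i] + m$length[i]
      cur_diag <- diag[i]
    }
  }
  # chains are contiguous blocks of rows (ids assigned in sorted order)
  i_end <- c(which(diff(chain_id) != 0L), nrow(m))
  i_start <- c(1L, head(i_end, -1L) + 1L)
  te <- m$tstart + m$length
  qe <- m$qstart + m$length
  tibble::tibble(
    chain = chain_id[i_start],
    tstart = m$tstart[i_start],
    tend = vapply(seq_along(i_start),
                  function(j) max(te[i_start[j]:i_end[j]]), 0),
    qstart = vapply(seq_along(i_start),
                    function(j) min(m$qstart[i_start[j]:i_end[j]]), 0),
    qend = vapply(seq_along(i_start),
                  function(j) max(qe[i_start[j]:i_end[j]]), 0)
  )
}

#' Detect Y' element instances on a canonical extremity
#'
#' Every library variant is matched against the extremity (seeded maximal
#' exact matches chained into local-alignment blocks); blocks longer than
#' `yprime_min_aln_len` are kept, their union is taken, and the union is
#' split into instances at interstitial telomeric seeds (gaps of at least
#' 30 bp with telomericity >= `tel_score`). Instances are indexed from the
#' centromere toward the telomere.
#'
#' @param seq Canonical extremity sequence.
#' @param yprime_lib Named character vector (or tibble with `variant_id`,
#'   `seq`) of known Y' sequences.
#' @param config A [telo_config()].
#' @return Tibble (index, start, end, length, seq), 0-based half-open
#'   canonical coordinates.
#' @export
detect_yprime_instances <- function(seq, yprime_lib, config = telo_config()) {
  lib <- yprime_lib_seqs(yprime_lib)
  if (!length(lib)) stop("empty Y' library")
  # one seeded-MEM pass over the concatenated library, split back per variant
  spacer <- strrep("N", 30)
  concat <- paste(lib, collapse = spacer)
  offsets <- cumsum(c(0, head(nchar(lib) + 30, -1)))
  mems <- cpp_mems(concat, seq, k = 21L, min_len = 30L, max_bucket = 128L,
                   stride = 4L)
  spans <- tibble::tibble(tstart = integer(0), tend = integer(0))
  if (nrow(mems)) {
    mems$variant <- findInterval(mems$qstart, offsets + 1)
    spans <- purrr::map_dfr(split(mems, mems$variant), function(mv) {
      ch <- chain_mems(mv)
      ch[ch$tend - ch$tstart > config$yprime_min_aln_len, ]
    })
  }
  none <- tibble::tibble(index = integer(0), start = integer(0),
                         end = integer(0), length = integer(0),
                         seq = character(0))
  if (!nrow(spans)) return(none)
  iv <- spans[order(spans$tstart), c("tstart", "tend")]
  merged <- list(c(iv$tstart[1], iv$tend[1]))
  for (i in seq_len(nrow(iv))[-1]) {
    cur <- merged[[length(merged)]]
    gap <- iv$tstart[i] - cur[2]
    telomeric_gap <- FALSE
    if (gap >= 30) {
      # split when the gap contains an interstitial telomeric seed anywhere
      # (ragged instance boundaries can leave non-telomeric margins)
      gseq <- substr(seq, cur[2], iv$tstart[i] - 1L)
      prof <- telomericity_profile(gseq, window = 30)
      telomeric_gap <- length(prof) > 0 && any(prof >= config$tel_score)
    }
    if (gap <= 1000 && !telomeric_gap) {
      merged[[length(merged)]] <- c(cur[1], max(cur[2], iv$tend[i]))
    } else {
      merged[[length(merged) + 1L]] <- c(iv$tstart[i], iv$tend[i])
    }
  }
  out <- purrr::map_dfr(merged, function(m) {
    tibble::tibble(start = m[1] - 1L, end = m[2] - 1L)
  })
  out$length <- out$end - out$start
  out <- out[out$length > config$yprime_min_aln_len, ]
  if (!nrow(out)) return(none)
  out <- out[order(out$start), ]
  out$index <- seq_len(nrow(out)) - 1L
  out$seq <- substring(seq, out$start + 1L, out$end)
  out[, c("index", "start", "end", "length", "seq")]
}

yprime_lib_seqs <- function(yprime_lib) {
  if (is.data.frame(yprime_lib)) {
    setNames(yprime_lib$seq, yprime_lib$variant_id)
  } else {
    yprime_lib
  }
}

#' Detect the X element on a canonical extremity
#'
#' Best chained match of the X reference against the extremity; a call
#' requires at least `x_min_cov` of the reference length to be covered.
#'
#' @param seq Canonical extremity sequence.
#' @param x_ref X element reference sequence.
#' @param config A [telo_config()].
#' @return One-row tibble (start, end, length) or a zero-row tibble.
#' @export
detect_x_element <- function(seq, x_ref, config = telo_config()) {
  none <- tibble::tibble(start = integer(0), end = integer(0),
                         length = integer(0))
  ch <- chain_mems(cpp_mems(x_ref, seq, k = 21L, min_len = 25L,
                            max_bucket = 64L))
  if (!nrow(ch)) return(none)
  ch$qcov <- ch$qend - ch$qstart
  best <- ch[which.max(ch$qcov), ]
  if (best$qcov < config$x_min_cov * nchar(x_ref)) return(none)
  tibble::tibble(start = as.integer(best$tstart - 1L),
                 end = as.integer(best$tend - 1L),
                 length = as.integer(best$tend - best$tstart))
}

#' Annotate every extremity of a genome
#'
#' Runs the telomere, X and Y' detectors on the canonical frame of all
#' 2N extremities.
#'
#' @param genome A `telo_genome`.
#' @param yprime_lib Known Y' sequences (named vector or tibble).
#' @param x_ref X element reference sequence.
#' @param config A [telo_config()].
#' @return A feature tibble (extremity, chrom, side, chrom_len, window,
#'   feature, start, end, length, index, seq) in canonical coordinates;
#'   features ordered centromere to telomere within each extremity.
#' @export
build_extremity_maps <- function(genome, yprime_lib, x_ref,
                                 config = telo_config()) {
  exts <- extremities(genome, window = config$extremity_window)
  purrr::map_dfr(seq_len(nrow(exts)), function(i) {
    e <- exts[i, ]
    feats <- list()
    x <- detect_x_element(e$seq, x_ref, config)
    if (nrow(x)) {
      feats$x <- dplyr::mutate(x, feature = "x_element", index = NA_integer_,
                               seq = NA_character_)
    }
    yp <- detect_yprime_instances(e$seq, yprime_lib, config)
    if (nrow(yp)) {
      feats$y <- dplyr::mutate(yp, feature = "yprime")
    }
    tr <- detect_telomere_tract(e$seq, config)
    if (nrow(tr)) {
      feats$t <- dplyr::mutate(tr, feature = "telomere", index = NA_integer_,
                               seq = NA_character_)
    }
    f <- dplyr::bind_rows(feats)
    if (!nrow(f)) {
      return(tibble::tibble())
    }
    dplyr::bind_cols(
      e[rep(1, nrow(f)), c("extremity", "chrom", "side", "chrom_len", "window")],
      f[order(f$start), c("feature", "start", "end", "length", "index", "seq")]
    )
  })
}

#' Assembly-level telomere length per extremity
#'
#' @param genome A `telo_genome`.
#' @param config A [telo_config()].
#' @return A tibble (extremity, length) with one row per extremity (0 when no
#'   terminal tract is detected), of class `telo_lengths`.
#' @export
measure_assembly_telomere_lengths <- function(genome, config = telo_config()) {
  exts <- extremities(genome, window = config$extremity_window)
  out <- purrr::map_dfr(seq_len(nrow(exts)), function(i) {
    tr <- detect_telomere_tract(exts$seq[i], config)
    tibble::tibble(extremity = exts$extremity[i],
                   length = if (nrow(tr)) tr$length else 0L)
  })
  structure(out, class = c("telo_lengths", class(out)), kind = "assembly")
}

#' Summarise a telomere length distribution
#'
#' Per-extremity summary with box-plot statistics; whiskers follow the
#' Q1 - 1.5 IQR / Q3 + 1.5 IQR convention.
#'
#' @param lengths A `telo_lengths` tibble (columns extremity, length).
#' @return Tibble (extremity, n, mean, q1, median, q3, whisker_lo,
#'   whisker_hi).
#' @export
length_summary <- function(lengths) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(lengths), .data$extremity),
    n = dplyr::n(),
    mean = mean(.data$length),
    q1 = quantile(.data$length, 0.25, names = FALSE),
    median = median(.data$length),
    q3 = quantile(.data$length, 0.75, names = FALSE),
    .groups = "drop"
  ) |>
    dplyr::mutate(iqr = .data$q3 - .data$q1,
                  whisker_lo = .data$q1 - 1.5 * .data$iqr,
                  whisker_hi = .data$q3 + 1.5 * .data$iqr) |>
    dplyr::select(-"iqr")
}

#' Extract per-extremity subtelomeric read anchors
#'
#' One unique ~1 kb anchor per extremity, taken immediately
#' centromere-proximal to the control terminal telomere tract.
#'
#' @param genome Control `telo_genome`.
#' @param config A [telo_config()].
#' @param anchor_len Anchor length (bp).
#' @return Tibble (extremity, seq).
#' @export
anchor_library <- function(genome, config = telo_config(), anchor_len = 1000) {
  exts <- extremities(genome, window = config$extremity_window)
  purrr::map_dfr(seq_len(nrow(exts)), function(i) {
    tr <- detect_telomere_tract(exts$seq[i], config)
    if (!nrow(tr) || tr$start < anchor_len) return(tibble::tibble())
    tibble::tibble(extremity = exts$extremity[i],
                   seq = substr(exts$seq[i], tr$start - anchor_len + 1L,
                                tr$start))
  })
}

#' Read-based telomere length distribution
#'
#' Each read is assigned to the extremity whose anchor it matches (>= 90%
#' of `min_span` anchor bases recovered in exact matches); reads matching
#' several anchors go to the unique best one and are dropped on exact ties.
#' An assigned read contributes its terminal telomere tract length when the
#' tract reaches the read end and starts within 100 bp of the anchor match.
#'
#' @param reads Tibble with `read_id` and `seq` (see [simulate_reads()]).
#' @param anchors Tibble from [anchor_library()].
#' @param config A [telo_config()].
#' @param min_span Minimum anchored span (bp).
#' @param min_identity Minimum fraction of the span recovered exactly.
#' @param drop_truncated Exclude reads whose terminal tract is shorter than
#'   60% of the longest tract observed at the same extremity. Such reads come
#'   from molecules sheared inside the telomere and only underestimate the
#'   length; the filter assumes one underlying length per extremity and
#'   should be disabled for clones with strong intraclonal heterogeneity.
#' @return A `telo_lengths` tibble (extremity, read_id, length).
#' @export
read_length_distribution <- function(reads, anchors, config = telo_config(),
                                     min_span = 800, min_identity = 0.9,
                                     drop_truncated = TRUE) {
  if (!nrow(reads) || !nrow(anchors)) {
    return(structure(tibble::tibble(extremity = character(0),
                                    read_id = character(0),
                                    length = integer(0)),
                     class = c("telo_lengths", "tbl_df", "tbl", "data.frame"),
                     kind = "reads"))
  }
  concat <- paste(anchors$seq, collapse = strrep("N", 25))
  offsets <- cumsum(c(0, head(nchar(anchors$seq) + 25, -1)))
  map_anchor <- function(qpos) findInterval(qpos, offsets + 1)
  score_orient <- function(sq) {
    m <- cpp_mems(concat, sq, k = 21L, min_len = 40L, max_bucket = 64L)
    if (!nrow(m)) return(NULL)
    m$anchor <- map_anchor(m$qstart)
    agg <- dplyr::summarise(dplyr::group_by(m, .data$anchor),
                            matched = sum(.data$length),
                            tend = max(.data$tstart + .data$length - 1L),
                            .groups = "drop")
    agg[agg$matched >= min_identity * min_span, ]
  }
  # a telomere-measuring read must end in telomeric sequence in one
  # orientation; this cheap vectorized check skips the bulk of the reads
  nch <- nchar(reads$seq)
  tails <- substr(reads$seq, pmax(1L, nch - 23L), nch)
  heads_rc <- revcomp(substr(reads$seq, 1L, pmin(nch, 24L)))
  sc <- function(x) vapply(x, telomericity, 0)
  fwd_ok <- sc(tails) >= config$tel_score
  rev_ok <- sc(heads_rc) >= config$tel_score
  rc_full <- rep(NA_character_, nrow(reads))
  if (any(rev_ok)) rc_full[rev_ok] <- revcomp(reads$seq[rev_ok])
  rows <- purrr::map_dfr(which(fwd_ok | rev_ok), function(i) {
    cands <- character(0)
    if (fwd_ok[i]) cands <- reads$seq[i]
    if (rev_ok[i]) cands <- c(cands, rc_full[i])
    best <- NULL
    for (sq in cands) {
      agg <- score_orient(sq)
      if (is.null(agg) || !nrow(agg)) next
      agg <- agg[order(-agg$matched), ]
      if (nrow(agg) > 1 && agg$matched[1] == agg$matched[2]) next # ambiguous
      cand <- list(anchor = agg$anchor[1], tend = agg$tend[1],
                   matched = agg$matched[1], seq = sq)
      if (is.null(best) || cand$matched > best$matched) best <- cand
    }
    if (is.null(best)) return(tibble::tibble())
    tr <- detect_telomere_tract(best$seq, config)
    if (!nrow(tr)) return(tibble::tibble())
    if (tr$start > best$tend + 100) return(tibble::tibble())
    tibble::tibble(extremity = anchors$extremity[best$anchor],
                   read_id = reads$read_id[i], length = tr$length)
  })
  if (!nrow(rows)) {
    rows <- tibble::tibble(extremity = character(0), read_id = character(0),
                           length = integer(0))
  } else if (drop_truncated) {
    rows <- dplyr::group_by(rows, .data$extremity) |>
      dplyr::filter(.data$length >= 0.6 * max(.data$length)) |>
      dplyr::ungroup()
  }
  structure(rows, class = c("telo_lengths", class(tibble::tibble())),
            kind = "reads")
}
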