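#' Roll a circular unit into a linear tandem array
#'
#' Rotates the unit by `phase`, then concatenates `n_copies` of the rotation,
#' optionally truncating to `cap_length`. Appending the result into a
#' telomere yields a perfect tandem array whose phase records where in the
#' circle copying started.
#'
#' @param circle_unit Unit sequence (non-empty).
#' @param n_copies Number of copies (>= 1).
#' @param phase Starting rotation, `0 <= phase < nchar(circle_unit)`.
#' @param cap_length Optional maximum output length (bp).
#' @return A character scalar.
#' @export
roll_circle <- function(circle_unit, n_copies, phase = 0, cap_length = NULL) {
  u <- nchar(circle_unit)
  if (u == 0) stop("empty circle unit")
  stopifnot(n_copies >= 1, phase >= 0, phase < u)
  rot <- paste0(substr(circle_unit, phase + 1L, u),
                substr(circle_unit, 1L, phase))
  out <- strrep(rot, n_copies)
  if (!is.null(cap_length)) out <- substr(out, 1L, cap_length)
  out
}

# ---- reference genome ------------------------------------------------------

default_cassettes <- function() {
  tibble::tribble(
    ~cassette_id, ~h, ~arm1, ~pos1, ~arm2, ~pos2,
    "C1", 1000L, "chr02_R", 4000L, "chr07_L", 5000L,
    "C2", 800L, "chr04_R", 3000L, "chr09_L", 4000L,
    "C3", 400L, "chr09_L", 7000L, "chr11_R", 5000L,
    "C4", 600L, "chr13_R", 6000L, "chr15_L", 3500L,
    "CC", 700L, "chr03_L", 5000L, "chr03_R", 5000L
  )
}

# Render one arm structure into its canonical sequence plus arm-frame
# feature intervals (0-based half-open; 0 = centromere-proximal arm start).
render_arm <- function(struct) {
  parts <- c(struct$flank, struct$x)
  feats <- tibble::tibble(feature = "x_element",
                          start = nchar(struct$flank),
                          end = nchar(struct$flank) + nchar(struct$x),
                          label = NA_character_)
  pos <- feats$end[1]
  if (nrow(struct$slots)) {
    for (i in seq_len(nrow(struct$slots))) {
      sd <- struct$slots$seed_seq[i]
      vs <- struct$slots$seq[i]
      parts <- c(parts, sd, vs)
      feats <- dplyr::bind_rows(
        feats,
        tibble::tibble(feature = "seed", start = pos, end = pos + nchar(sd),
                       label = NA_character_),
        tibble::tibble(feature = "yprime", start = pos + nchar(sd),
                       end = pos + nchar(sd) + nchar(vs),
                       label = struct$slots$variant_id[i])
      )
      pos <- pos + nchar(sd) + nchar(vs)
    }
  }
  parts <- c(parts, struct$tel)
  feats <- dplyr::bind_rows(
    feats,
    tibble::tibble(feature = "telomere", start = pos,
                   end = pos + nchar(struct$tel), label = NA_character_)
  )
  list(seq = paste(parts, collapse = ""), features = feats)
}

render_genome <- function(ledger) {
  chroms <- names(ledger$centers)
  seqs <- vapply(chroms, function(ch) {
    eL <- paste0(ch, "_L"); eR <- paste0(ch, "_R")
    armL <- ledger$arm_overrides[[eL]] %||% render_arm(ledger$structures[[eL]])$seq
    armR <- ledger$arm_overrides[[eR]] %||% render_arm(ledger$structures[[eR]])$seq
    paste0(revcomp(armL), ledger$centers[[ch]], armR)
  }, "")
  if (length(ledger$drop_chroms)) seqs <- seqs[setdiff(chroms, ledger$drop_chroms)]
  if (length(ledger$extra_chroms)) {
    seqs <- c(seqs, unlist(ledger$extra_chroms))
  }
  as_genome(seqs)
}

ledger_features <- function(ledger) {
  purrr::map_dfr(names(ledger$structures), function(e) {
    if (e %in% names(ledger$arm_overrides)) return(tibble::tibble())
    r <- render_arm(ledger$structures[[e]])
    f <- r$features
    f$extremity <- e
    f$arm_len <- nchar(r$seq)
    f$chrom <- sub("_[LR]$", "", e)
    f$side <- sub("^.*_", "", e)
    f
  })
}

#' Build the synthetic control genome and its truth ledger
#'
#' Each extremity is assembled as flank + X element + (interstitial telomeric
#' seed + Y') repeats + terminal TG1-3 tract, in the canonical frame; left
#' arms are reverse-complemented into the chromosome. Shared homology
#' cassettes are planted in selected subtelomeric flanks (donor/recipient
#' pairs for BIR-like duplications; a mating-type-like cassette on both
#' chromosome III flanks for circularization). The most telomere-distal Y'
#' slot of every Y'-bearing end carries a distinct variant; duplicate
#' placements sit in interior slots and never adjacent to a same-label copy,
#' so the control maps fully resolve.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed; identical (config, seed) give byte-identical
#'   output.
#' @return A list with elements `genome` (a `telo_genome`) and `ledger` (a
#'   `truth_ledger`: library, structures, per-feature intervals, planted
#'   events and circles).
#' @export
build_reference_genome <- function(config = synthetic_config(), seed = 1L) {
  lib <- yprime_library(config$n_variants, seed = seed)
  if (max(nchar(lib$seq)) + config$flank_len > config$extremity_cap %||% Inf) {
    stop("Y' longer than the extremity window allows")
  }
  with_seed(child_seed(seed, "reference_genome"), {
    chroms <- paste0("chr", sprintf("%02d", seq_len(config$n_chrom)))
    exts <- as.vector(t(outer(chroms, c("_L", "_R"), paste0)))
    x_anc <- cap_edges(random_dna(config$x_len))

    # occupancy: which ends carry Y', how many, and which variants
    ends_y <- sample(exts, length(config$occupancy))
    counts <- setNames(sample(config$occupancy), ends_y)
    distal <- setNames(sample(lib$variant_id, length(ends_y)), ends_y)

    structures <- list()
    for (e in exts) {
      k <- if (e %in% ends_y) counts[[e]] else 0L
      ids <- character(0)
      if (k > 0) {
        ids <- distal[[e]]
        while (length(ids) < k) {
          cand <- sample(lib$variant_id, 1)
          if (cand != ids[1]) ids <- c(cand, ids) # prepend centromere-side
        }
      }
      slots <- tibble::tibble(
        variant_id = ids,
        seed_seq = vapply(seq_along(ids), function(i) {
          gen_telomere_repeats(config$tel_model,
                               sample(config$seed_len_range[1]:config$seed_len_range[2], 1))
        }, ""),
        seq = lib$seq[match(ids, lib$variant_id)]
      )
      tel_len <- max(60L, round(rnorm(1, config$tel_model$mean_len,
                                      config$tel_model$sd_len)))
      structures[[e]] <- list(
        flank = random_dna(config$flank_len),
        x = mutate_seq(x_anc, config$x_divergence, protect_edges = 32),
        slots = slots,
        tel = gen_telomere_repeats(config$tel_model, tel_len)
      )
    }

    # plant homology cassettes into flanks, with distinct boundary bases so
    # the junction homology length is exactly the cassette length
    cassettes <- default_cassettes()
    cassettes <- cassettes[cassettes$arm1 %in% exts & cassettes$arm2 %in% exts, ]
    cassettes$seq <- vapply(cassettes$h, random_dna, "")
    for (i in seq_len(nrow(cassettes))) {
      for (side in 1:2) {
        arm <- cassettes[[paste0("arm", side)]][i]
        pos <- cassettes[[paste0("pos", side)]][i]
        h <- cassettes$h[i]
        fl <- structures[[arm]]$flank
        guard <- if (side == 1) c("A", "A") else c("C", "C")
        fl <- paste0(substr(fl, 1, pos - 1), guard[1], cassettes$seq[i],
                     guard[2], substr(fl, pos + h + 2, nchar(fl)))
        structures[[arm]]$flank <- fl
        # record the cassette interval (after the 1-base guard)
        cassettes[[paste0("at", side)]][i] <- pos
      }
    }

    centers <- setNames(lapply(chroms, function(ch) random_dna(config$core_len)),
                        chroms)
    ledger <- structure(list(
      clone = "control",
      config = config, seed = seed,
      library = lib, x_ancestor = x_anc,
      cassettes = cassettes,
      structures = structures, centers = centers,
      arm_overrides = list(), drop_chroms = character(0), extra_chroms = list(),
      novel_seqs = list(),
      events = empty_events(),
      circles = tibble::tibble()
    ), class = "truth_ledger")
    ledger$features <- ledger_features(ledger)
    list(genome = render_genome(ledger), ledger = ledger)
  })
}

empty_events <- function() {
  tibble::tibble(clone = character(0), kind = character(0),
                 extremity = character(0), label = character(0),
                 donor = character(0), homology = numeric(0),
                 seg_len = numeric(0), unit_id = character(0),
                 copies = numeric(0), phase = numeric(0))
}

#' Verify that a truth ledger describes its genome exactly
#'
#' Re-extracts every recorded feature interval from the rendered genome and
#' compares it with the recorded sequence content; also re-extracts planted
#' circle arrays.
#'
#' @param genome The genome emitted for `ledger`.
#' @param ledger A `truth_ledger`.
#' @return TRUE (invisibly) or an error describing the first mismatch.
#' @export
verify_ledger <- function(genome, ledger) {
  for (e in setdiff(names(ledger$structures), names(ledger$arm_overrides))) {
    chrom <- sub("_[LR]$", "", e)
    if (chrom %in% ledger$drop_chroms) next
    side <- sub("^.*_", "", e)
    r <- render_arm(ledger$structures[[e]])
    arm_len <- nchar(r$seq)
    chrseq <- genome[[chrom]]
    arm_in_genome <- if (side == "R") {
      substr(chrseq, nchar(chrseq) - arm_len + 1L, nchar(chrseq))
    } else {
      revcomp(substr(chrseq, 1L, arm_len))
    }
    if (!identical(arm_in_genome, r$seq)) {
      stop("ledger mismatch at ", e)
    }
    f <- r$features
    for (i in seq_len(nrow(f))) {
      got <- substr(r$seq, f$start[i] + 1L, f$end[i])
      want <- switch(f$feature[i],
                     x_element = ledger$structures[[e]]$x,
                     telomere = ledger$structures[[e]]$tel,
                     NULL)
      if (!is.null(want) && !identical(got, want)) {
        stop("feature re-extraction mismatch at ", e, " ", f$feature[i])
      }
    }
  }
  invisible(TRUE)
}
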