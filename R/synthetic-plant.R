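normalize_events <- function(events) {
  defaults <- list(kind = NA_character_, extremity = NA_character_,
                   slot = NA_integer_, variant = NA_character_,
                   position = NA_integer_, donors = list(NULL),
                   novel = FALSE, cassette = NA_character_,
                   cassettes = list(NULL), chrom = NA_character_,
                   tel_len = NA_real_, segments = list(NULL))
  for (nm in names(defaults)) {
    if (!nm %in% names(events)) {
      events[[nm]] <- if (is.list(defaults[[nm]])) {
        rep(defaults[[nm]], nrow(events))
      } else rep(defaults[[nm]], nrow(events))
    }
  }
  events
}

# Valid insertion position for label v into the slot label vector: never
# adjacent to an existing copy of v and never between two identical adjacent
# labels (which would break up a tandem pair). NA when no position qualifies.
pick_insert_position <- function(labels, v) {
  n <- length(labels)
  ok <- vapply(0:n, function(p) {
    left <- if (p >= 1) labels[p] else ""
    right <- if (p < n) labels[p + 1] else ""
    v != left && v != right && !(nzchar(left) && left == right)
  }, logical(1))
  if (!any(ok)) return(NA_integer_)
  cand <- (0:n)[ok]
  if (length(cand) > 1) sample(cand, 1) else cand
}

rand_seed_seq <- function(ledger) {
  rng <- ledger$config$seed_len_range
  gen_telomere_repeats(ledger$config$tel_model, sample(rng[1]:rng[2], 1))
}

#' Plant rearrangements into a survivor genome
#'
#' Applies a typed event specification to a copy of the control ledger and
#' re-emits the genome, extending the ledger with the realised events.
#' Supported kinds: `loss`, `gain`, `tandem_amplification`, `new_variant`
#' (mosaic of two donors, or a heavily mutated novel when `novel = TRUE`),
#' `set_telomere`, `telomere_build` (explicit telomere composition including
#' rolling-circle arrays), `terminal_duplication` and `nested_duplication`
#' (via planted homology cassettes) and `circularization`. Extremities not
#' named in any event remain byte-identical to the control.
#'
#' @param ledger Control `truth_ledger` from [build_reference_genome()].
#' @param events Event tibble; see the fields used by each kind in the
#'   source and the samplers [sample_yas_events()] / [sample_t2l_events()].
#' @param clone Clone name recorded in the ledger.
#' @param seed Integer seed for apply-time choices (which slot is lost, which
#'   variant gained, ...), all of which are recorded in the returned ledger.
#' @return A list with `genome` and `ledger` for the survivor.
#' @export
plant_rearrangements <- function(ledger, events, clone = "survivor", seed = 1L) {
  stopifnot(inherits(ledger, "truth_ledger"))
  ev <- normalize_events(events)
  lg <- ledger
  lg$clone <- clone
  out_events <- list()
  # plant-time guards against self-cancelling event pairs: a label lost at an
  # end is not re-gained there, and amplified/gained labels are not lost
  lost_at <- list()
  gained_at <- list()
  # gains and mosaic donors recombine material already present in the
  # control genome, so they draw from the instantiated variants only
  present <- unique(unlist(lapply(ledger$structures,
                                  function(s) s$slots$variant_id)))
  with_seed(child_seed(seed, paste0("plant_", clone)), {
    for (i in seq_len(nrow(ev))) {
      kind <- ev$kind[i]
      e <- ev$extremity[i]
      if (!is.na(e) && !e %in% names(lg$structures)) {
        stop("event references unknown extremity: ", e)
      }
      rec <- tibble::tibble(clone = clone, kind = kind, extremity = e,
                            label = NA_character_, donor = NA_character_,
                            homology = NA_real_, seg_len = NA_real_,
                            unit_id = NA_character_, copies = NA_real_,
                            phase = NA_real_)
      if (kind %in% c("loss", "gain", "tandem_amplification", "new_variant")) {
        st <- lg$structures[[e]]
        n <- nrow(st$slots)
        if (kind == "loss") {
          if (n == 0) stop("loss planted at Y'-free extremity ", e)
          s <- ev$slot[i]
          if (is.na(s)) {
            ok <- which(!st$slots$variant_id %in% gained_at[[e]])
            if (!length(ok)) ok <- seq_len(n)
            s <- if (length(ok) > 1) sample(ok, 1) else ok
          }
          rec$label <- st$slots$variant_id[s]
          lost_at[[e]] <- c(lost_at[[e]], rec$label)
          st$slots <- st$slots[-s, ]
        } else if (kind == "gain") {
          v <- ev$variant[i]
          if (is.na(v)) {
            # sampled gains introduce a label new to this extremity; adjacent
            # duplications of a resident label are tandem amplifications
            pool <- setdiff(present,
                            c(lost_at[[e]], gained_at[[e]],
                              st$slots$variant_id))
            if (!length(pool)) pool <- present
            v <- if (length(pool) > 1) sample(pool, 1) else pool
          }
          if (!v %in% lg$library$variant_id) stop("unknown variant: ", v)
          p <- ev$position[i]
          if (is.na(p)) {
            p <- pick_insert_position(st$slots$variant_id, v)
            if (is.na(p)) next # no position keeps the end unambiguous
          }
          new_row <- tibble::tibble(variant_id = v, seed_seq = rand_seed_seq(lg),
                                    seq = lg$library$seq[lg$library$variant_id == v])
          st$slots <- dplyr::bind_rows(utils::head(st$slots, p), new_row,
                                       utils::tail(st$slots, n - p))
          rec$label <- v
          gained_at[[e]] <- c(gained_at[[e]], v)
        } else if (kind == "tandem_amplification") {
          if (n == 0) stop("tandem amplification at Y'-free extremity ", e)
          s <- ev$slot[i]
          if (is.na(s)) {
            # never re-amplify a label gained at this end in this clone: the
            # two gained copies would be indistinguishable from one event
            ok <- which(!st$slots$variant_id %in% gained_at[[e]])
            if (!length(ok)) next
            s <- if (length(ok) > 1) sample(ok, 1) else ok
          }
          dup <- st$slots[s, ]
          dup$seed_seq <- rand_seed_seq(lg)
          st$slots <- dplyr::bind_rows(utils::head(st$slots, s), dup,
                                       utils::tail(st$slots, n - s))
          rec$label <- dup$variant_id
          gained_at[[e]] <- c(gained_at[[e]], dup$variant_id)
        } else { # new_variant
          donors <- ev$donors[[i]]
          if (is.null(donors)) donors <- sample(present, 2)
          a <- lg$library$seq[lg$library$variant_id == donors[1]]
          newid <- paste0("new_", clone, "_", i)
          if (isTRUE(ev$novel[i])) {
            newseq <- mutate_seq(a, 0.05, protect_edges = 12)
            rec$donor <- "novel"
          } else {
            b <- lg$library$seq[lg$library$variant_id == donors[2]]
            cut_a <- round(nchar(a) * runif(1, 0.4, 0.6))
            cut_b <- round(nchar(b) * runif(1, 0.4, 0.6))
            newseq <- paste0(substr(a, 1, cut_a),
                             substr(b, cut_b + 1, nchar(b)))
            rec$donor <- paste(donors, collapse = "+")
          }
          p <- ev$position[i]
          if (is.na(p)) {
            p <- pick_insert_position(st$slots$variant_id, newid)
            if (is.na(p)) next
          }
          new_row <- tibble::tibble(variant_id = newid,
                                    seed_seq = rand_seed_seq(lg), seq = newseq)
          st$slots <- dplyr::bind_rows(utils::head(st$slots, p), new_row,
                                       utils::tail(st$slots, n - p))
          lg$novel_seqs[[newid]] <- newseq
          rec$label <- newid
        }
        lg$structures[[e]] <- st
      } else if (kind == "set_telomere") {
        lg$structures[[e]]$tel <-
          gen_telomere_repeats(lg$config$tel_model, ev$tel_len[i])
        rec$seg_len <- ev$tel_len[i]
      } else if (kind == "telomere_build") {
        segs <- ev$segments[[i]]
        parts <- character(0)
        offset <- 0
        for (sg in segs) {
          if (sg$type == "orig") {
            parts <- c(parts, lg$structures[[e]]$tel)
            offset <- offset + nchar(lg$structures[[e]]$tel)
          } else if (sg$type == "fresh") {
            parts <- c(parts, gen_telomere_repeats(lg$config$tel_model, sg$len))
            offset <- offset + sg$len
          } else if (sg$type == "array") {
            cir <- lg$circles[lg$circles$unit_id == sg$unit_id, ]
            if (nrow(cir) != 1) stop("unknown circle unit: ", sg$unit_id)
            arr <- roll_circle(cir$unit, sg$copies, sg$phase)
            out_events[[length(out_events) + 1L]] <-
              tibble::tibble(clone = clone, kind = "telomere_array",
                             extremity = e, label = NA_character_,
                             donor = NA_character_, homology = NA_real_,
                             seg_len = offset, unit_id = sg$unit_id,
                             copies = sg$copies, phase = sg$phase)
            parts <- c(parts, arr)
            offset <- offset + nchar(arr)
          }
        }
        lg$structures[[e]]$tel <- paste(parts, collapse = "")
        rec <- NULL
      } else if (kind %in% c("terminal_duplication", "nested_duplication")) {
        cass <- lg$cassettes
        surgery <- function(arm_seq, donor_seq, pr, pd, h) {
          paste0(substr(arm_seq, 1, pr + h), substr(donor_seq, pd + h + 1,
                                                    nchar(donor_seq)))
        }
        site <- function(id, arm) {
          r <- cass[cass$cassette_id == id, ]
          if (nrow(r) != 1) stop("unknown cassette: ", id)
          if (r$arm1 == arm) list(pos = r$pos1, other = r$arm2,
                                  other_pos = r$pos2, h = r$h)
          else if (r$arm2 == arm) list(pos = r$pos2, other = r$arm1,
                                       other_pos = r$pos1, h = r$h)
          else stop("cassette ", id, " not planted on ", arm)
        }
        rec_arm <- lg$arm_overrides[[e]] %||% render_arm(lg$structures[[e]])$seq
        if (kind == "terminal_duplication") {
          s1 <- site(ev$cassette[i], e)
          donor_arm <- render_arm(lg$structures[[s1$other]])$seq
          lg$arm_overrides[[e]] <- surgery(rec_arm, donor_arm, s1$pos,
                                           s1$other_pos, s1$h)
          rec$donor <- s1$other
          rec$homology <- s1$h
          rec$seg_len <- nchar(donor_arm) - (s1$other_pos + s1$h)
        } else {
          ids <- ev$cassettes[[i]]
          s_out <- site(ids[1], e)
          armA <- render_arm(lg$structures[[s_out$other]])$seq
          s_in <- site(ids[2], s_out$other)
          armB <- render_arm(lg$structures[[s_in$other]])$seq
          mid <- substr(armA, s_out$other_pos + s_out$h + 1, s_in$pos + s_in$h)
          lg$arm_overrides[[e]] <- paste0(
            substr(rec_arm, 1, s_out$pos + s_out$h), mid,
            substr(armB, s_in$other_pos + s_in$h + 1, nchar(armB)))
          rec <- dplyr::bind_rows(
            tibble::tibble(clone = clone, kind = "terminal_duplication",
                           extremity = e, label = NA_character_,
                           donor = s_out$other, homology = s_out$h,
                           seg_len = nchar(mid), unit_id = NA_character_,
                           copies = NA_real_, phase = NA_real_),
            tibble::tibble(clone = clone, kind = "terminal_duplication",
                           extremity = e, label = NA_character_,
                           donor = s_in$other, homology = s_in$h,
                           seg_len = nchar(armB) - (s_in$other_pos + s_in$h),
                           unit_id = NA_character_,
                           copies = NA_real_, phase = NA_real_))
        }
      } else if (kind == "circularization") {
        ch <- ev$chrom[i]
        cid <- if (is.na(ev$cassette[i])) "CC" else ev$cassette[i]
        cass <- lg$cassettes[lg$cassettes$cassette_id == cid, ]
        if (is.na(cass$cassette_id[1])) stop("circularization cassette missing")
        eL <- paste0(ch, "_L"); eR <- paste0(ch, "_R")
        pL <- if (cass$arm1 == eL) cass$pos1 else cass$pos2
        pR <- if (cass$arm1 == eR) cass$pos1 else cass$pos2
        armL <- render_arm(lg$structures[[eL]])$seq
        armR <- render_arm(lg$structures[[eR]])$seq
        circle <- paste0(revcomp(substr(armL, 1, pL + cass$h)),
                         lg$centers[[ch]], substr(armR, 1, pR - 1))
        r <- sample.int(nchar(circle), 1)
        contig <- paste0(substr(circle, r, nchar(circle)),
                         substr(circle, 1, r - 1))
        lg$drop_chroms <- c(lg$drop_chroms, ch)
        lg$extra_chroms[[paste0(ch, "_circ")]] <- contig
        rec$extremity <- eL
        rec$donor <- eR
      } else {
        stop("unknown event kind: ", kind)
      }
      if (!is.null(rec)) out_events[[length(out_events) + 1L]] <- rec
    }
  })
  lg$events <- dplyr::bind_rows(lg$events, dplyr::bind_rows(out_events))
  lg$features <- ledger_features(lg)
  list(genome = render_genome(lg), ledger = lg)
}

#' Expected detectable events for a planted survivor
#'
#' Translates planted events into the calls the comparison stage should
#' report: a tandem amplification is also a gain, a new variant is also a
#' gain, and extremities rewritten by a terminal duplication or lost to
#' circularization contribute only those calls.
#'
#' @param ledger Survivor `truth_ledger`.
#' @return Tibble of expected calls (kind, extremity, label, donor, homology).
#' @export
expected_events <- function(ledger) {
  ev <- ledger$events
  skip <- unique(ev$extremity[ev$kind %in% c("terminal_duplication",
                                             "circularization")])
  rows <- list()
  for (i in seq_len(nrow(ev))) {
    k <- ev$kind[i]
    if (k %in% c("loss", "gain", "tandem_amplification", "new_variant") &&
        !ev$extremity[i] %in% skip) {
      lab <- ev$label[i]
      if (k == "loss") {
        rows[[length(rows) + 1L]] <- tibble::tibble(kind = "loss",
          extremity = ev$extremity[i], label = lab)
      } else if (k == "gain") {
        rows[[length(rows) + 1L]] <- tibble::tibble(kind = "gain",
          extremity = ev$extremity[i], label = lab)
      } else if (k == "tandem_amplification") {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          kind = c("tandem_amplification", "gain"),
          extremity = ev$extremity[i], label = lab)
      } else {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          kind = c("new_variant", "gain"),
          extremity = ev$extremity[i], label = NA_character_)
      }
    } else if (k == "terminal_duplication") {
      rows[[length(rows) + 1L]] <- tibble::tibble(kind = k,
        extremity = ev$extremity[i], label = NA_character_,
        donor = ev$donor[i], homology = ev$homology[i])
    } else if (k == "circularization") {
      rows[[length(rows) + 1L]] <- tibble::tibble(kind = k,
        extremity = ev$extremity[i], label = NA_character_,
        donor = ev$donor[i], homology = NA_real_)
    }
  }
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) out <- tibble::tibble(kind = character(0),
                                        extremity = character(0),
                                        label = character(0))
  out
}
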