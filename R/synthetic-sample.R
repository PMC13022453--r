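#' Sample a Y'-associated-survivor event specification
#'
#' Draws per-clone event counts matching the rearrangement load observed in
#' uncapping survivors — losses ~ Normal(8.3, 3.7) and total gains ~
#' Normal(18, 8.9), split between plain gains, tandem amplifications and new
#' variants — and concentrates them on a per-clone set of affected
#' extremities: each Y'-bearing end is affected with probability
#' `p_affect_y` (0.28) and each X-only end with probability `p_affect_x`
#' (0.15), the class-specific alteration frequencies of the study. 0-2
#' BIR-like terminal duplications are drawn from the planted cassette
#' registry. Events respect the map-resolution cap (no end is pushed beyond
#' 5 Y' copies) and never touch a duplication recipient or donor arm twice.
#'
#' @param ledger Control `truth_ledger`.
#' @param seed Integer seed.
#' @param mean_loss,sd_loss,mean_gain,sd_gain Per-clone count distributions.
#' @param p_tandem,p_new Fraction of gains realised as tandem amplifications
#'   and as new (mosaic) variants.
#' @param p_novel Fraction of new variants that are heavily mutated novels
#'   rather than mosaics of two donors.
#' @param p_affect_y,p_affect_x Per-extremity alteration probabilities for
#'   Y'-bearing and X-only ends.
#' @param n_dup Candidate numbers of terminal duplications (one is drawn).
#' @return An event tibble for [plant_rearrangements()].
#' @export
sample_yas_events <- function(ledger, seed = 1L,
                              mean_loss = 8.3, sd_loss = 3.7,
                              mean_gain = 18, sd_gain = 8.9,
                              p_tandem = 0.3, p_new = 0.12, p_novel = 0.15,
                              p_affect_y = 0.28, p_affect_x = 0.15,
                              n_dup = 0:2) {
  with_seed(child_seed(seed, "sample_yas"), {
    counts <- vapply(ledger$structures, function(s) nrow(s$slots), 0L)
    dup_cass <- ledger$cassettes$cassette_id[ledger$cassettes$cassette_id != "CC"]
    k_dup <- min(sample(n_dup, 1), length(dup_cass))
    used <- character(0)
    dup_rows <- list()
    if (k_dup > 0) {
      for (cid in sample(dup_cass, k_dup)) {
        row <- ledger$cassettes[ledger$cassettes$cassette_id == cid, ]
        if (row$arm1 %in% used || row$arm2 %in% used) next
        used <- c(used, row$arm1, row$arm2)
        dup_rows[[length(dup_rows) + 1L]] <-
          tibble::tibble(kind = "terminal_duplication", extremity = row$arm1,
                         cassette = cid)
      }
    }
    free <- setdiff(names(counts), used)
    y_ends <- free[counts[free] >= 1]
    x_ends <- free[counts[free] == 0]
    affected <- c(y_ends[runif(length(y_ends)) < p_affect_y],
                  x_ends[runif(length(x_ends)) < p_affect_x])
    if (!length(intersect(affected, y_ends))) {
      affected <- c(affected, sample(y_ends, 1))
    }
    n_loss <- max(0L, round(rnorm(1, mean_loss, sd_loss)))
    n_gain <- max(0L, round(rnorm(1, mean_gain, sd_gain)))
    n_tandem <- rbinom(1, n_gain, p_tandem)
    n_new <- rbinom(1, n_gain - n_tandem, p_new)
    n_plain <- n_gain - n_tandem - n_new
    rows <- list()
    pick <- function(pool) if (length(pool) > 1) sample(pool, 1) else pool
    for (i in seq_len(n_loss)) {
      pool <- affected[counts[affected] >= 1]
      if (!length(pool)) break
      e <- pick(pool)
      counts[e] <- counts[e] - 1L
      rows[[length(rows) + 1L]] <- tibble::tibble(kind = "loss", extremity = e)
    }
    tandem_labels_used <- character(0)
    add_gain <- function(kind, need_existing) {
      pool <- affected[counts[affected] <= 4 &
                         (!need_existing | counts[affected] >= 1)]
      if (!length(pool)) return(NULL)
      e <- pick(pool)
      counts[e] <<- counts[e] + 1L
      tibble::tibble(kind = kind, extremity = e)
    }
    for (i in seq_len(n_tandem)) {
      r <- add_gain("tandem_amplification", TRUE)
      if (!is.null(r)) rows[[length(rows) + 1L]] <- r
    }
    for (i in seq_len(n_new)) {
      r <- add_gain("new_variant", FALSE)
      if (!is.null(r)) { r$novel <- runif(1) < p_novel; rows[[length(rows) + 1L]] <- r }
    }
    for (i in seq_len(n_plain)) {
      r <- add_gain("gain", FALSE)
      if (!is.null(r)) rows[[length(rows) + 1L]] <- r
    }
    dplyr::bind_rows(c(rows, dup_rows))
  })
}

#' Build the t-circle unit panel from a control ledger
#'
#' Excises circle units from control telomere tracts (so each has a unique,
#' traceable locus of origin) and adds one longer unit that contains the
#' first as a subsequence, mirroring the observed nested circle pair. Units
#' are checked to occur exactly once across all control telomere tracts.
#'
#' @param ledger Control `truth_ledger`.
#' @param seed Integer seed.
#' @param unit_lens Lengths of the excised units (bp); the nested unit adds
#'   `nested_extra` fresh telomeric bases to the first unit.
#' @param nested_extra Extra length of the nested containing unit (bp).
#' @return The ledger with a populated `circles` table (unit_id, unit,
#'   origin_extremity, origin_offset).
#' @export
make_tcircle_panel <- function(ledger, seed = 1L, unit_lens = c(139, 58),
                               nested_extra = 193) {
  with_seed(child_seed(seed, "tcircle_panel"), {
    tracts <- vapply(ledger$structures, function(s) s$tel, "")
    pool <- names(tracts)[nchar(tracts) >= max(unit_lens) + 120]
    origins <- sample(pool, length(unit_lens))
    rows <- purrr::map2_dfr(unit_lens, origins, function(L, e) {
      off <- sample(40:(nchar(tracts[[e]]) - L - 40), 1)
      tibble::tibble(unit_id = paste0("u", L), unit = substr(tracts[[e]],
                     off + 1, off + L),
                     origin_extremity = e, origin_offset = off)
    })
    nested <- tibble::tibble(
      unit_id = paste0("u", unit_lens[1] + nested_extra),
      unit = paste0(rows$unit[1],
                    gen_telomere_repeats(ledger$config$tel_model, nested_extra)),
      origin_extremity = NA_character_, origin_offset = NA_real_)
    circles <- dplyr::bind_rows(rows, nested)
    # units must be unique across all control tracts
    all_tel <- paste(tracts, collapse = "NNNN")
    n_occ <- vapply(circles$unit, function(u) {
      length(gregexpr(u, all_tel, fixed = TRUE)[[1]][
        gregexpr(u, all_tel, fixed = TRUE)[[1]] > 0])
    }, 0L)
    expect_occ <- ifelse(is.na(circles$origin_extremity), 0L, 1L)
    if (!all(n_occ == expect_occ)) stop("circle unit not unique in control")
    ledger$circles <- circles
    ledger
  })
}

#' Sample a type-II-like survivor event specification
#'
#' Keeps `n_short` extremities at their control telomere length and
#' heterogeneously elongates the rest up to ~10 kb, planting rolling-circle
#' tandem arrays (3-9 copies, arbitrary phase) from the ledger's circle
#' panel into a subset of the elongated telomeres, interleaved with fresh
#' telomerase-like emission. Y' rearrangements are drawn at the same rates
#' as for Y'-associated survivors.
#'
#' @param ledger Control ledger carrying a circle panel
#'   (see [make_tcircle_panel()]).
#' @param seed Integer seed.
#' @param n_short Number of non-elongated extremities.
#' @param elong_range Range of added telomere length (bp).
#' @param array_target Fraction of telomeric bp targeted by perfect arrays.
#' @param yas_args Arguments forwarded to [sample_yas_events()].
#' @return An event tibble for [plant_rearrangements()].
#' @export
sample_t2l_events <- function(ledger, seed = 1L, n_short = 5,
                              elong_range = c(1000, 9500),
                              array_target = 0.27,
                              yas_args = list(n_dup = 0)) {
  stopifnot(nrow(ledger$circles) > 0)
  yas <- do.call(sample_yas_events,
                 c(list(ledger = ledger, seed = child_seed(seed, "t2l_yas")),
                   yas_args))
  with_seed(child_seed(seed, "sample_t2l"), {
    exts <- names(ledger$structures)
    skip <- unique(yas$extremity[yas$kind == "terminal_duplication"])
    short_ends <- sample(setdiff(exts, skip), n_short)
    long_ends <- setdiff(exts, c(short_ends, skip))
    circles <- ledger$circles
    rows <- list()
    for (e in long_ends) {
      extra <- round(runif(1, elong_range[1], elong_range[2]))
      arr_bp_target <- array_target * (nchar(ledger$structures[[e]]$tel) + extra)
      segs <- list(list(type = "orig"))
      arr_bp <- 0
      # plant arrays until the per-end budget is spent
      while (arr_bp < arr_bp_target && extra > 300) {
        ci <- sample.int(nrow(circles), 1)
        u <- nchar(circles$unit[ci])
        cp <- sample(3:9, 1)
        # keep the planted fraction near its target: cap copies by both the
        # remaining elongation budget and the remaining array budget, and
        # stop rather than overshoot when neither fits 3 more copies
        cp <- min(cp, (extra - 100) %/% u,
                  round((arr_bp_target - arr_bp) / u))
        if (cp < 3) break
        gap <- sample(80:250, 1)
        segs <- c(segs, list(list(type = "fresh", len = gap),
                             list(type = "array", unit_id = circles$unit_id[ci],
                                  copies = cp, phase = sample.int(u, 1) - 1L)))
        arr_bp <- arr_bp + u * cp
        extra <- extra - u * cp - gap
      }
      if (extra > 0) segs <- c(segs, list(list(type = "fresh", len = extra)))
      rows[[length(rows) + 1L]] <-
        tibble::tibble(kind = "telomere_build", extremity = e,
                       segments = list(segs))
    }
    dplyr::bind_rows(c(list(yas), rows))
  })
}
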