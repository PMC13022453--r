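#' Map planted variant ids to catalog labels
#'
#' Joins the control ledger's planted Y' features with the detected catalog
#' instances by extremity and centromere-to-telomere index.
#'
#' @param catalog Control `yprime_catalog`.
#' @param ledger Control `truth_ledger`.
#' @return Tibble (variant_id, label).
#' @export
ledger_label_map <- function(catalog, ledger) {
  fy <- ledger$features[ledger$features$feature == "yprime", ]
  fy <- dplyr::group_by(fy, .data$extremity) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::mutate(index = dplyr::row_number() - 1L) |>
    dplyr::ungroup()
  j <- dplyr::inner_join(
    fy[, c("extremity", "index", "label")],
    catalog$instances[, c("extremity", "index", "label")],
    by = c("extremity", "index"), suffix = c("_planted", "_detected"))
  unique(j[, c("label_planted", "label_detected")]) |>
    dplyr::rename(variant_id = "label_planted", label = "label_detected")
}

normalize_call_set <- function(calls, label_map = NULL) {
  k_y <- c("loss", "gain", "tandem_amplification")
  rows <- list()
  y <- calls[calls$kind %in% k_y, ]
  if (nrow(y)) {
    lab <- y$label
    if (!is.null(label_map)) {
      hit <- match(lab, label_map$variant_id)
      lab[!is.na(hit)] <- label_map$label[hit[!is.na(hit)]]
    }
    lab[grepl("^new_", lab)] <- NA_character_ # novel labels have no shared id
    rows$y <- tibble::tibble(kind = y$kind, extremity = y$extremity,
                             key = lab)
  }
  nv <- calls[calls$kind == "new_variant", ]
  if (nrow(nv)) {
    rows$nv <- tibble::tibble(kind = "new_variant", extremity = nv$extremity,
                              key = NA_character_)
  }
  td <- calls[calls$kind == "terminal_duplication", ]
  if (nrow(td)) {
    rows$td <- tibble::tibble(kind = "terminal_duplication",
                              extremity = td$extremity,
                              key = paste0(td$donor, ":", td$homology))
  }
  cc <- calls[calls$kind == "circularization", ]
  if (nrow(cc)) {
    rows$cc <- tibble::tibble(kind = "circularization",
                              extremity = cc$extremity, key = cc$donor)
  }
  out <- dplyr::bind_rows(rows)
  if (is.null(out) || !nrow(out)) {
    return(tibble::tibble(kind = character(0), extremity = character(0),
                          key = character(0), n = integer(0)))
  }
  dplyr::count(out, .data$kind, .data$extremity, .data$key)
}

#' Score detected calls against planted truth
#'
#' Compares the multiset of detected calls with the calls expected from the
#' survivor ledger ([expected_events()]): Y' events by (kind, extremity,
#' label), new variants by (extremity), terminal duplications by (extremity,
#' donor, junction homology), circularizations by the extremity pair.
#'
#' @param detected Call tibble from [analyze_survivor()] (`$calls`).
#' @param survivor_ledger The survivor's `truth_ledger`.
#' @param label_map From [ledger_label_map()].
#' @return One-row tibble (n_expected, n_detected, true_positive, precision,
#'   recall).
#' @export
score_against_ledger <- function(detected, survivor_ledger, label_map) {
  exp_n <- normalize_call_set(expected_events(survivor_ledger), label_map)
  det <- detected
  # circularization detection reports donor as extremity2; align payloads
  if ("extremity2" %in% names(det) && any(det$kind == "circularization")) {
    det$donor[det$kind == "circularization"] <-
      det$extremity2[det$kind == "circularization"]
  }
  det_n <- normalize_call_set(det)
  j <- dplyr::full_join(exp_n, det_n, by = c("kind", "extremity", "key"),
                        suffix = c("_exp", "_det"))
  j$n_exp[is.na(j$n_exp)] <- 0L
  j$n_det[is.na(j$n_det)] <- 0L
  tp <- sum(pmin(j$n_exp, j$n_det))
  tibble::tibble(n_expected = sum(j$n_exp), n_detected = sum(j$n_det),
                 true_positive = tp,
                 precision = ifelse(sum(j$n_det) > 0, tp / sum(j$n_det), NA),
                 recall = ifelse(sum(j$n_exp) > 0, tp / sum(j$n_exp), NA))
}
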