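#' Analysis configuration
#'
#' Bundles every threshold used across the pipeline. Defaults follow the
#' published analysis of transient-uncapping survivors: Y' alignments are kept
#' when longer than 200 bp, two Y' elements share a label when their
#' homopolymer-condensed similarity exceeds 99.9, homopolymers longer than 4
#' are condensed to 4, mosaic explanations require perfect matches of more
#' than 50 bp, telomere tandem scans consider units of at least 30 bp but use
#' only units of at least 50 bp with three or more copies as circle
#' candidates, circle merging/matching uses a 0.98 normalized score, and
#' terminal duplications are screened over the 15 kb upstream of the X
#' element.
#'
#' @param yprime_min_aln_len Minimum Y' alignment length kept (bp, exclusive
#'   bound: alignments must be longer than this).
#' @param label_sim_threshold Similarity (0-100) above which two Y' elements
#'   receive the same label.
#' @param condensation_max_run Maximum homopolymer run length after
#'   condensation.
#' @param mosaic_min_exact Minimum length of a perfect match used in mosaic
#'   decomposition (bp; "size > 50" means 51 and up).
#' @param tandem_min_unit Minimum tandem repeat unit length scanned (bp).
#' @param tandem_use_min_unit Minimum unit length retained for circle
#'   candidacy (bp).
#' @param tandem_min_copies Minimum copies for a reported tandem array.
#' @param tandem_min_copies_circle Minimum copies for circle candidacy.
#' @param circle_merge_score Normalized alignment score above which two
#'   candidate units are considered the same circle.
#' @param circle_match_score Normalized score above which a sliding window is
#'   called a circle match.
#' @param upstream_window Window upstream of the X element compared between
#'   control and survivor (bp).
#' @param extremity_window Extremity window analysed per chromosome end (bp);
#'   capped at half the chromosome length.
#' @param min_tract Minimum terminal telomere tract length reported (bp).
#' @param tel_window,tel_score,tel_bridge Telomere detector: sliding window
#'   size (bp), minimum TG1-3 6-mer dictionary score per window, and maximum
#'   non-telomeric gap bridged (bp).
#' @param x_min_cov Minimum fraction of the X reference covered for an X call.
#' @param align_match,align_mismatch,align_gap_open,align_gap_ext Local
#'   alignment scoring (first gap base costs `align_gap_open`, each further
#'   base `align_gap_ext`).
#' @param seed Integer seed driving all stochastic operations.
#'
#' @return A list of class `telo_config`.
#' @export
telo_config <- function(yprime_min_aln_len = 200,
                        label_sim_threshold = 99.9,
                        condensation_max_run = 4,
                        mosaic_min_exact = 51,
                        tandem_min_unit = 30,
                        tandem_use_min_unit = 50,
                        tandem_min_copies = 2,
                        tandem_min_copies_circle = 3,
                        circle_merge_score = 0.98,
                        circle_match_score = 0.98,
                        upstream_window = 15000,
                        extremity_window = 150000,
                        min_tract = 40,
                        tel_window = 20,
                        tel_score = 0.8,
                        tel_bridge = 10,
                        x_min_cov = 0.6,
                        align_match = 1,
                        align_mismatch = -1,
                        align_gap_open = 1,
                        align_gap_ext = 0.9,
                        seed = 1L) {
  cfg <- list(yprime_min_aln_len = yprime_min_aln_len,
              label_sim_threshold = label_sim_threshold,
              condensation_max_run = condensation_max_run,
              mosaic_min_exact = mosaic_min_exact,
              tandem_min_unit = tandem_min_unit,
              tandem_use_min_unit = tandem_use_min_unit,
              tandem_min_copies = tandem_min_copies,
              tandem_min_copies_circle = tandem_min_copies_circle,
              circle_merge_score = circle_merge_score,
              circle_match_score = circle_match_score,
              upstream_window = upstream_window,
              extremity_window = extremity_window,
              min_tract = min_tract,
              tel_window = tel_window,
              tel_score = tel_score,
              tel_bridge = tel_bridge,
              x_min_cov = x_min_cov,
              align_match = align_match,
              align_mismatch = align_mismatch,
              align_gap_open = align_gap_open,
              align_gap_ext = align_gap_ext,
              seed = as.integer(seed))
  num <- cfg[setdiff(names(cfg), c("align_mismatch", "seed"))]
  if (any(vapply(num, function(x) !is.numeric(x) || x <= 0, logical(1)))) {
    stop("all thresholds in telo_config() must be strictly positive")
  }
  structure(cfg, class = "telo_config")
}

#' Read or write a configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_config()` returns a `telo_config`; `write_config()` the path,
#'   invisibly.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(telo_config, vals)
}

#' @rdname read_config
#' @param config A `telo_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
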