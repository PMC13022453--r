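# Shared fixtures, built once per test run. Everything is generated in code
# from fixed seeds; no data files are read.

.fixtures <- new.env(parent = emptyenv())

fixture_reference <- function() {
  if (is.null(.fixtures$ref)) {
    ref <- build_reference_genome(seed = 1)
    ref$ledger <- make_tcircle_panel(ref$ledger, seed = 1)
    .fixtures$ref <- ref
  }
  .fixtures$ref
}

fixture_control <- function() {
  if (is.null(.fixtures$control)) {
    ref <- fixture_reference()
    .fixtures$control <- analyze_control(ref$genome, ref$ledger$library,
                                         ref$ledger$x_ancestor)
  }
  .fixtures$control
}

fixture_label_map <- function() {
  if (is.null(.fixtures$map)) {
    .fixtures$map <- ledger_label_map(fixture_control()$catalog,
                                      fixture_reference()$ledger)
  }
  .fixtures$map
}

# Small genome for pipeline mechanics (not the study-scale conditions).
small_config <- function() {
  synthetic_config(n_chrom = 6, core_len = 12000, flank_len = 9000,
                   occupancy = c(3, 2, 2, 1, 1, 1))
}

# Consistency of a detected circle match with a planted array: there must be
# a match run whose (phase, start) agree with the planted (phase, offset)
# modulo the unit length, allowing for the representative being a rotation of
# the planted unit and for the detected tract starting a few bases earlier.
phase_consistent <- function(planted_row, matches, planted_unit, rep_unit,
                             tract_delta) {
  L <- nchar(planted_unit)
  r0 <- regexpr(rep_unit, paste0(planted_unit, planted_unit),
                fixed = TRUE)[[1]] - 1L
  if (r0 < 0) return(FALSE)
  s0 <- planted_row$seg_len + tract_delta
  for (j in seq_len(nrow(matches))) {
    lhs <- (matches$phase[j] + r0 - planted_row$phase) %% L
    rhs <- (matches$start[j] - s0) %% L
    if (lhs == rhs && abs(matches$start[j] - s0) < L) return(TRUE)
  }
  FALSE
}
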