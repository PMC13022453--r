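#' Degenerate TG1-3 telomere repeat model
#'
#' Budding-yeast telomeres are ~350 bp of degenerate TG1-3 repeats on the
#' G-rich strand. The emitter writes "TG" blocks and appends an extra G with
#' probability `p_extra_g`, redrawing while a G-run would exceed 3, so emitted
#' tracts contain only T and G, G-runs of length 1-3, and never two
#' consecutive T's.
#'
#' @param p_extra_g Probability of appending an extra G to a block (applied
#'   once for a second G and again for a third).
#' @param mean_len,sd_len Target terminal tract length distribution (bp) for
#'   control-like telomeres.
#' @return A list of class `telomere_model`.
#' @export
telomere_model <- function(p_extra_g = 0.5, mean_len = 350, sd_len = 50) {
  structure(list(p_extra_g = p_extra_g, mean_len = mean_len, sd_len = sd_len),
            class = "telomere_model")
}

#' Emit a degenerate TG1-3 telomere tract
#'
#' @param model A [telomere_model()].
#' @param length Exact tract length to emit (bp); 0 gives "".
#' @param seed Optional integer seed; identical seed and parameters give
#'   identical output.
#' @return A character scalar in the canonical (G-rich, telomere-rightward)
#'   frame.
#' @export
gen_telomere_repeats <- function(model = telomere_model(), length, seed = NULL) {
  stopifnot(length >= 0)
  if (length == 0) return("")
  with_seed(seed, {
    n_blocks <- ceiling(length / 2) + 8L
    # block = T followed by 1-3 G's; extra G's drawn independently, capped at 3
    g1 <- runif(n_blocks) < model$p_extra_g
    g2 <- g1 & (runif(n_blocks) < model$p_extra_g)
    blocks <- paste0("TG", ifelse(g1, "G", ""), ifelse(g2, "G", ""))
    s <- paste(blocks, collapse = "")
    while (nchar(s) < length) {
      s <- paste0(s, paste(rep("TG", length), collapse = ""))
    }
    substr(s, 1L, length)
  })
}

#' Check a sequence against the TG1-3 grammar
#'
#' @param seq Character scalar (canonical frame).
#' @return TRUE when `seq` contains only T/G, no G-run longer than 3 and no
#'   TT dinucleotide.
#' @export
telomere_grammar_ok <- function(seq) {
  !grepl("[^TG]", seq) && !grepl("GGGG", seq, fixed = TRUE) &&
    !grepl("TT", seq, fixed = TRUE)
}

# Dictionary of all 6-mers generable by the TG1-3 grammar (any phase).
telomere_kmer_dict <- local({
  dict <- NULL
  function() {
    if (is.null(dict)) {
      blocks <- c("TG", "TGG", "TGGG")
      strings <- ""
      for (i in 1:5) {
        strings <- as.vector(outer(strings, blocks, paste0))
        strings <- unique(substr(strings, 1, 16))
      }
      long <- strings[nchar(strings) >= 6]
      kmers <- unique(unlist(lapply(long, function(s) {
        n <- nchar(s)
        substring(s, 1:(n - 5), 6:n)
      })))
      dict <<- kmers
    }
    dict
  }
})

# Telomericity profile: for each window start i (1-based), the fraction of
# overlapping 6-mers of seq[i .. i+window-1] present in the TG1-3 dictionary.
telomericity_profile <- function(seq, window = 20) {
  n <- nchar(seq)
  if (n < window) return(numeric(0))
  kmers <- substring(seq, 1:(n - 5), 6:n)
  ok <- as.integer(kmers %in% telomere_kmer_dict())
  per_win <- window - 5L
  cs <- cumsum(c(0L, ok))
  starts <- 1:(n - window + 1L)
  (cs[starts + per_win] - cs[starts]) / per_win
}

#' Telomericity score of a window
#'
#' Fraction of the overlapping 6-mers of `seq` found in the dictionary of
#' 6-mers generable by the TG1-3 grammar.
#'
#' @param seq Character scalar.
#' @return A score in `[0, 1]` (NA for sequences shorter than 6 bp).
#' @export
telomericity <- function(seq) {
  n <- nchar(seq)
  if (n < 6) return(NA_real_)
  kmers <- substring(seq, 1:(n - 5), 6:n)
  mean(kmers %in% telomere_kmer_dict())
}
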