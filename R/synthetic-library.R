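#' Synthetic genome configuration
#'
#' Study-condition defaults for the synthetic control genome: 16 chromosomes,
#' an X element at every extremity, 34 Y' elements distributed over 20 of the
#' 32 extremities with 0-6 tandem copies per end, ~350 bp degenerate TG1-3
#' terminal tracts, short interstitial telomeric seeds (50-150 bp) between
#' tandem Y' copies, and a panel of shared homology cassettes planted in
#' subtelomeric flanks to support BIR-like terminal duplications and
#' chromosome III circularization.
#'
#' @param n_chrom Number of chromosomes.
#' @param core_len Length of the unique chromosome core between the two
#'   subtelomeric flanks (bp).
#' @param flank_len Length of the unique subtelomeric flank upstream of the X
#'   element on each arm (bp).
#' @param x_len X element length (bp); per-arm copies diverge by
#'   `x_divergence` substitutions from a common ancestor.
#' @param x_divergence Per-base substitution rate between the X ancestor and
#'   each planted copy.
#' @param n_variants Number of distinct Y' sequence variants in the library.
#' @param occupancy Integer vector of per-end Y' copy numbers for the ends
#'   that carry Y' (the remaining ends carry none); its length is the number
#'   of Y'-bearing ends and its sum the total instance count.
#' @param seed_len_range Range of interstitial telomeric seed lengths (bp).
#' @param tel_model A [telomere_model()].
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_chrom = 16,
                             core_len = 30000,
                             flank_len = 12000,
                             x_len = 1000,
                             x_divergence = 0.01,
                             n_variants = 20,
                             occupancy = c(6, 4, 3, 2, 2, 2, 2, rep(1, 13)),
                             seed_len_range = c(50, 150),
                             tel_model = telomere_model()) {
  if (length(occupancy) > 2 * n_chrom) stop("more Y' ends than extremities")
  if (max(occupancy) < 1) stop("occupancy lists Y'-bearing ends only")
  structure(list(n_chrom = n_chrom, core_len = core_len, flank_len = flank_len,
                 x_len = x_len, x_divergence = x_divergence,
                 n_variants = n_variants, occupancy = occupancy,
                 seed_len_range = seed_len_range, tel_model = tel_model),
            class = "synthetic_config")
}

# Overwrite the edges of an element with fixed low-complexity-free caps so
# element boundaries never blur into flanking homopolymers or telomeric seeds.
cap_edges <- function(seq, left = "CATCAGTACGAT", right = "ACGATCATGCTA") {
  n <- nchar(seq)
  paste0(left, substr(seq, nchar(left) + 1L, n - nchar(right)), right)
}

#' Generate a Y' element variant library
#'
#' Two family ancestors (short ~5.5 kb and long ~6.7 kb; the long ancestor is
#' the short one with an extra internal block) are diversified into subfamily
#' founders (1.5% divergence, family-band target lengths) and then into
#' sequence variants (0.15% divergence plus occasional small indels). One
#' variant is an intermediate-size truncation of a long founder, mirroring
#' the observed outlier between the two size classes.
#'
#' @param n_variants Number of variants (>= 12).
#' @param seed Integer seed.
#' @return A tibble with columns `variant_id`, `family` (short/long/
#'   intermediate), `founder`, `length`, `seq`.
#' @export
yprime_library <- function(n_variants = 20, seed = 1L) {
  stopifnot(n_variants >= 12)
  with_seed(child_seed(seed, "yprime_library"), {
    short_anc <- cap_edges(random_dna(5470))
    long_anc <- cap_edges(paste0(substr(short_anc, 1, 3000), random_dna(1200),
                                 substr(short_anc, 3001, 5470)))
    founders <- tibble::tibble(
      founder = paste0("f", sprintf("%02d", 1:10)),
      family = c(rep("short", 4), rep("long", 6)),
      target = c(5062, 5320, 5470, 5592, 6484, 6580, 6670, 6760, 6850, 6933)
    )
    founders$seq <- purrr::map2_chr(founders$family, founders$target,
                                    function(fam, tgt) {
      anc <- if (fam == "short") short_anc else long_anc
      s <- mutate_seq(anc, 0.015, protect_edges = 12)
      delta <- tgt - nchar(s)
      mid <- nchar(s) %/% 2
      if (delta < 0) {
        s <- paste0(substr(s, 1, mid), substr(s, mid + 1 - delta, nchar(s)))
      } else if (delta > 0) {
        s <- paste0(substr(s, 1, mid), random_dna(delta),
                    substr(s, mid + 1, nchar(s)))
      }
      s
    })
    # variants per founder (the last slot is the intermediate-size outlier)
    per_founder <- c(3, 2, 2, 1, 3, 2, 2, 2, 1, 1)
    idx <- rep(seq_len(10), per_founder)
    extra <- n_variants - 1L - length(idx)
    if (extra > 0) idx <- c(idx, sample(10, extra, replace = TRUE))
    idx <- idx[seq_len(n_variants - 1L)]
    lib <- tibble::tibble(
      variant_id = paste0("Y", sprintf("%02d", seq_len(n_variants))),
      family = c(founders$family[idx], "intermediate"),
      founder = c(founders$founder[idx], "f07")
    )
    # variant-indexed base-4 stamp written near the distal end: distinct
    # variants always differ within their terminal kilobase, the region read
    # anchors are drawn from
    stamp <- function(s, v) {
      n <- nchar(s)
      pos <- n - c(450L, 400L, 350L, 300L)
      dig <- (v %/% c(1L, 4L, 16L, 64L)) %% 4L
      for (j in seq_along(pos)) {
        substr(s, pos[j], pos[j]) <- DNA_BASES[dig[j] + 1L]
      }
      s
    }
    lib$seq <- c(
      purrr::map_chr(idx, function(i) {
        s <- mutate_seq(founders$seq[i], 0.0015, protect_edges = 12)
        if (runif(1) < 0.3) { # occasional small indel
          mid <- sample(2000:4000, 1)
          k <- sample(3:10, 1)
          if (runif(1) < 0.5) {
            s <- paste0(substr(s, 1, mid), substr(s, mid + 1 + k, nchar(s)))
          } else {
            s <- paste0(substr(s, 1, mid), random_dna(k),
                        substr(s, mid + 1, nchar(s)))
          }
        }
        s
      }),
      { # intermediate: truncate a long founder to 5981 bp
        f <- founders$seq[founders$founder == "f07"]
        cut <- nchar(f) - 5981
        mid <- nchar(f) %/% 2
        mutate_seq(paste0(substr(f, 1, mid), substr(f, mid + 1 + cut, nchar(f))),
                   0.0015, protect_edges = 12)
      }
    )
    lib$seq <- purrr::map2_chr(lib$seq, seq_len(n_variants), stamp)
    lib$length <- nchar(lib$seq)
    lib
  })
}
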