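apply_read_errors <- function(seq, sub_rate = 0, hp_indel_rate = 0,
                              hp_min_run = 5) {
  if (sub_rate <= 0 && hp_indel_rate <= 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (hp_indel_rate > 0) {
    r <- rle(ch)
    idx <- which(r$lengths >= hp_min_run)
    if (length(idx)) {
      flip <- idx[runif(length(idx)) < hp_indel_rate]
      r$lengths[flip] <- pmax(1L, r$lengths[flip] +
                                sample(c(-1L, 1L), length(flip), replace = TRUE))
    }
    ch <- inverse.rle(r)
  }
  if (sub_rate > 0) {
    k <- rbinom(1, length(ch), sub_rate)
    if (k > 0) {
      pos <- sample(length(ch), k)
      ch[pos] <- vapply(ch[pos], function(b) {
        sample(setdiff(DNA_BASES, b), 1)
      }, "")
    }
  }
  paste(ch, collapse = "")
}

#' Simulate long reads from a genome
#'
#' Reads are sampled uniformly across the genome with random strand flips and
#' log-normal lengths, truncated at chromosome ends (a molecule cannot extend
#' past a telomere). Errors follow a simple nanopore-like model:
#' substitutions at `sub_rate` and +-1 length errors in homopolymers of at
#' least `hp_min_run` bases at `hp_indel_rate` per run. Sampling continues
#' until the realised (post-truncation) base count reaches
#' `coverage * genome size`.
#'
#' @param genome A `telo_genome`.
#' @param coverage Target coverage.
#' @param meanlog,sdlog,min_len Read length distribution (log-normal,
#'   truncated below at `min_len`).
#' @param sub_rate,hp_indel_rate,hp_min_run Error model.
#' @param seed Integer seed.
#' @param path Optional FASTQ output path.
#' @return A tibble (read_id, chrom, start, strand, length, seq); written as
#'   FASTQ too when `path` is given.
#' @export
simulate_reads <- function(genome, coverage = 30, meanlog = log(15000),
                           sdlog = 0.4, min_len = 1000,
                           sub_rate = 0, hp_indel_rate = 0, hp_min_run = 5,
                           seed = 1L, path = NULL) {
  stopifnot(coverage > 0)
  with_seed(child_seed(seed, "simulate_reads"), {
    lens <- nchar(genome)
    target <- coverage * sum(lens)
    rows <- list()
    total <- 0
    i <- 0L
    while (total < target) {
      n <- max(64L, ceiling((target - total) / exp(meanlog + sdlog^2 / 2)))
      chrom <- sample(names(genome), n, replace = TRUE, prob = lens)
      rl <- pmax(min_len, round(rlnorm(n, meanlog, sdlog)))
      # molecule placed uniformly over [1 - rl + 1, chrom length]; clipping at
      # both ends yields reads terminating exactly at either chromosome end
      start <- floor(runif(n) * (lens[chrom] + rl - 1)) - rl + 2L
      end <- pmin(start + rl - 1L, lens[chrom])
      start <- pmax(start, 1L)
      strand <- sample(c("+", "-"), n, replace = TRUE)
      sq <- unname(substr(genome[chrom], start, end))
      keep <- nchar(sq) >= min_len / 2
      sq <- sq[keep]; chrom <- chrom[keep]; start <- start[keep]
      strand <- strand[keep]
      flip <- strand == "-"
      if (any(flip)) sq[flip] <- revcomp(sq[flip])
      if (sub_rate > 0 || hp_indel_rate > 0) {
        sq <- vapply(sq, apply_read_errors, "", sub_rate = sub_rate,
                     hp_indel_rate = hp_indel_rate, hp_min_run = hp_min_run,
                     USE.NAMES = FALSE)
      }
      rows[[length(rows) + 1L]] <-
        tibble::tibble(chrom = chrom, start = as.integer(start),
                       strand = strand, length = nchar(sq), seq = sq)
      total <- total + sum(nchar(sq))
      i <- i + 1L
      if (i > 10000L) stop("read sampling failed to reach target coverage")
    }
    reads <- dplyr::bind_rows(rows)
    # trim overshoot so total bases track the requested coverage
    cum <- cumsum(reads$length)
    reads <- reads[seq_len(which(cum >= target)[1]), ]
    reads$read_id <- sprintf("read_%06d", seq_len(nrow(reads)))
    reads <- reads[c("read_id", "chrom", "start", "strand", "length", "seq")]
    if (!is.null(path)) write_reads_fastq(reads, path)
    reads
  })
}

#' Write or read simulated reads as FASTQ
#'
#' Records are written as plain four-line FASTQ with constant qualities
#' (reads beyond ~20 kb overflow the line buffer of the usual XStringSet
#' FASTQ writer, so the records are emitted directly).
#'
#' @param reads Tibble from [simulate_reads()].
#' @param path FASTQ path.
#' @return `write_reads_fastq()` returns `path` invisibly;
#'   `read_reads_fastq()` a tibble (read_id, length, seq).
#' @export
write_reads_fastq <- function(reads, path) {
  lines <- as.vector(rbind(paste0("@", reads$read_id),
                           reads$seq,
                           "+",
                           strrep("I", nchar(reads$seq))))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_reads_fastq
#' @export
read_reads_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4 != 0) stop("malformed FASTQ: ", path)
  ids <- sub("\\s.*$", "", sub("^@", "", lines[seq(1, length(lines), 4)]))
  seqs <- toupper(lines[seq(2, length(lines), 4)])
  tibble::tibble(read_id = ids, length = nchar(seqs), seq = seqs)
}

#' Apply replicate-assembly homopolymer noise
#'
#' Emulates the residual differences between two independent assemblies of
#' the same strain: +-1 length errors confined to homopolymer runs of at
#' least `min_run` bases, the error mode that dominates polished nanopore
#' assemblies and exactly the regime neutralized by homopolymer condensation.
#'
#' @param genome A `telo_genome`.
#' @param p Per-run perturbation probability.
#' @param min_run Minimum run length perturbed (bp).
#' @param seed Integer seed.
#' @return A perturbed `telo_genome`.
#' @export
replicate_assembly_noise <- function(genome, p = 0.5, min_run = 5, seed = 1L) {
  with_seed(child_seed(seed, "assembly_noise"), {
    out <- vapply(unclass(genome), function(s) {
      apply_read_errors(s, sub_rate = 0, hp_indel_rate = p,
                        hp_min_run = min_run)
    }, "")
    as_genome(out)
  })
}

#' Write a self-contained synthetic demo data set
#'
#' Emits a control genome, a Y'-associated survivor (Y' events only; telomere
#' length distribution unchanged) and a type-II-like survivor (elongated
#' telomeres with planted rolling-circle arrays), together with the planted
#' truth as JSON.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param config A [synthetic_config()].
#' @return Invisibly, a list with file paths and the three ledgers.
#' @export
make_demo <- function(dir = tempfile("telodemo"), seed = 1L,
                      config = synthetic_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref <- build_reference_genome(config, seed = seed)
  ref$ledger <- make_tcircle_panel(ref$ledger, seed = seed)
  yas <- plant_rearrangements(ref$ledger, sample_yas_events(ref$ledger, seed = child_seed(seed, "yas")),
                              clone = "yas1", seed = child_seed(seed, "yas"))
  t2l <- plant_rearrangements(ref$ledger,
                              sample_t2l_events(ref$ledger, seed = child_seed(seed, "t2l")),
                              clone = "t2l1", seed = child_seed(seed, "t2l"))
  paths <- list(control = file.path(dir, "control.fasta"),
                yas = file.path(dir, "survivor_yas.fasta"),
                t2l = file.path(dir, "survivor_t2l.fasta"),
                truth = file.path(dir, "truth.json"))
  write_genome_fasta(ref$genome, paths$control)
  write_genome_fasta(yas$genome, paths$yas)
  write_genome_fasta(t2l$genome, paths$t2l)
  truth <- list(
    control_features = ref$ledger$features,
    circles = ref$ledger$circles,
    events = dplyr::bind_rows(yas$ledger$events, t2l$ledger$events)
  )
  jsonlite::write_json(truth, paths$truth, dataframe = "rows", na = "null")
  invisible(c(paths, list(control_ledger = ref$ledger, yas_ledger = yas$ledger,
                          t2l_ledger = t2l$ledger)))
}
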