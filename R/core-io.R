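#' Read a genome assembly from FASTA
#'
#' Sequences are uppercased and any IUPAC ambiguity code other than A/C/G/T is
#' converted to N; record order is preserved. Chromosome names must be unique
#' and sequences non-empty.
#'
#' @param path FASTA file.
#' @return A named character vector (one element per chromosome) of class
#'   `telo_genome`.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) {
                    stop("malformed FASTA in ", path, ": ", conditionMessage(e),
                         call. = FALSE)
                  })
  if (length(set) == 0) stop("no FASTA records in ", path)
  seqs <- toupper(as.character(set))
  seqs <- gsub("[^ACGTN]", "N", seqs)
  nm <- sub("\\s.*$", "", names(set))
  as_genome(setNames(seqs, nm))
}

#' Construct a genome object from named sequences
#'
#' @param seqs Named character vector of chromosome sequences (A/C/G/T/N).
#' @return A `telo_genome`.
#' @export
as_genome <- function(seqs) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("chromosome names must be present and unique")
  }
  if (any(nchar(seqs) == 0)) {
    stop("empty chromosome sequence: ",
         paste(names(seqs)[nchar(seqs) == 0], collapse = ", "))
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("non-ACGTN characters in: ", paste(names(seqs)[bad], collapse = ", "))
  }
  structure(seqs, class = "telo_genome")
}

#' @export
print.telo_genome <- function(x, ...) {
  cat("<telo_genome> ", length(x), " chromosomes, ",
      format(sum(nchar(x)), big.mark = ","), " bp\n", sep = "")
  invisible(x)
}

#' Write a genome to FASTA
#'
#' @param genome A `telo_genome` (or named character vector).
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  set <- Biostrings::DNAStringSet(unclass(genome))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Canonical chromosome extremities
#'
#' Every chromosome contributes two extremities, L and R. Each is reported in
#' the canonical frame: the G-rich strand read 5' to 3' toward the chromosome
#' end, so the telomere always sits at the right-hand end of the returned
#' sequence. The R side is the terminal window as-is; the L side is the
#' reverse complement of the initial window. The window is capped at half the
#' chromosome length so the two frames never overlap.
#'
#' @param genome A `telo_genome`.
#' @param window Window size in bp (see [telo_config()]).
#' @return A tibble with columns `extremity`, `chrom`, `side`, `chrom_len`,
#'   `window` (the realised window size) and `seq` (canonical sequence).
#' @export
extremities <- function(genome, window = 150000) {
  purrr::map_dfr(names(genome), function(ch) {
    len <- nchar(genome[[ch]])
    w <- min(window, len %/% 2)
    seqs <- c(revcomp(substr(genome[[ch]], 1L, w)),
              substr(genome[[ch]], len - w + 1L, len))
    tibble::tibble(
      extremity = paste0(ch, "_", c("L", "R")),
      chrom = ch,
      side = c("L", "R"),
      chrom_len = len,
      window = w,
      seq = seqs
    )
  })
}

#' Canonical frame for one extremity
#'
#' @inheritParams extremities
#' @param chrom Chromosome name.
#' @param side `"L"` or `"R"`.
#' @return One row of the [extremities()] tibble.
#' @export
canonical_extremity <- function(genome, chrom, side, window = 150000) {
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  len <- nchar(genome[[chrom]])
  if (window > len) stop("window exceeds chromosome length")
  sq <- if (side == "R") {
    substr(genome[[chrom]], len - window + 1L, len)
  } else {
    revcomp(substr(genome[[chrom]], 1L, window))
  }
  tibble::tibble(extremity = paste0(chrom, "_", side), chrom = chrom,
                 side = side, chrom_len = len, window = window, seq = sq)
}

# Map a 0-based half-open interval [start, end) in the canonical frame of an
# extremity back to 0-based half-open original chromosome coordinates.
canonical_to_original <- function(start, end, side, chrom_len, window) {
  if (side == "R") {
    off <- chrom_len - window
    c(off + start, off + end)
  } else {
    c(window - end, window - start)
  }
}

#' Write extremity annotations to BED and TSV
#'
#' Intervals held in canonical extremity coordinates are de-canonicalized to
#' original chromosome coordinates (0-based half-open, BED convention). The
#' BED file has columns chrom, start, end, feature, label, side; the TSV
#' report carries the full annotation table. Output is bit-stable for
#' identical input.
#'
#' @param maps Annotation tibble as produced by [build_extremity_maps()]
#'   (columns `extremity`, `chrom`, `side`, `chrom_len`, `window`, `feature`,
#'   `start`, `end`, and optionally `label`).
#' @param bed_path,tsv_path Output paths (`NULL` to skip one of them).
#' @return Invisibly, the de-canonicalized annotation tibble.
#' @export
write_annotations <- function(maps, bed_path = NULL, tsv_path = NULL) {
  cols <- c("extremity", "chrom", "side", "chrom_len", "window",
            "feature", "start", "end")
  stopifnot(all(cols %in% names(maps)))
  out <- maps
  if (!"label" %in% names(out)) out$label <- NA_character_
  if (nrow(out)) {
    oc <- purrr::pmap(out[c("start", "end", "side", "chrom_len", "window")],
                      function(start, end, side, chrom_len, window) {
                        canonical_to_original(start, end, side, chrom_len, window)
                      })
    out$orig_start <- purrr::map_dbl(oc, 1)
    out$orig_end <- purrr::map_dbl(oc, 2)
  } else {
    out$orig_start <- numeric(0)
    out$orig_end <- numeric(0)
  }
  out <- dplyr::arrange(out, .data$chrom, .data$orig_start, .data$feature)
  if (!is.null(bed_path)) {
    bed <- dplyr::transmute(out, .data$chrom, start = .data$orig_start,
                            end = .data$orig_end, .data$feature,
                            label = dplyr::coalesce(.data$label, "."),
                            .data$side)
    readr::write_tsv(bed, bed_path, col_names = FALSE, progress = FALSE)
  }
  if (!is.null(tsv_path)) {
    readr::write_tsv(out, tsv_path, progress = FALSE)
  }
  invisible(out)
}

#' Read back an annotation TSV report
#'
#' @param tsv_path Path written by [write_annotations()].
#' @return The annotation tibble.
#' @export
read_annotations <- function(tsv_path) {
  readr::read_tsv(tsv_path, show_col_types = FALSE, progress = FALSE)
}
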