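#' Condense homopolymers
#'
#' Collapses every homopolymer run longer than `max_run` to exactly
#' `max_run` bases, neutralizing the dominant nanopore assembly error mode
#' before sequence comparison. Idempotent.
#'
#' @param seq Character vector of DNA sequences.
#' @param max_run Maximum run length retained.
#' @return Character vector of condensed sequences.
#' @export
condense_homopolymers <- function(seq, max_run = 4) {
  vapply(seq, function(s) {
    r <- rle(strsplit(s, "", fixed = TRUE)[[1]])
    r$lengths <- pmin(r$lengths, max_run)
    paste(inverse.rle(r), collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Pairwise Y' similarity
#'
#' Best local alignment of two (condensed) sequences, summarised as
#' `sim = %identity * alignment_length / alignment_span`, where
#' `%identity` is matches over alignment columns, `alignment_length` the
#' number of alignment columns, and the span adds the unaligned flanking
#' bases of both sequences to the alignment length. Identical sequences
#' score exactly 100; the measure is symmetric.
#'
#' @param a,b DNA sequences (non-empty).
#' @param config A [telo_config()] (alignment scoring).
#' @return Similarity in `[0, 100]`.
#' @export
pairwise_similarity <- function(a, b, config = telo_config()) {
  if (!nchar(a) || !nchar(b)) stop("empty sequence")
  if (identical(a, b)) return(100)
  st <- anchored_align_stats(a, b, config)
  if (st$columns == 0) return(0)
  pid <- 100 * st$matches / st$columns
  span <- st$columns + st$flanks
  pid * st$columns / span
}

# Seed-and-extend alignment statistics: maximal exact matches are chained
# colinearly (dynamic programming over anchors, overlaps trimmed) and the
# divergent gaps between consecutive anchors are resolved by affine global
# alignment (gaps larger than `gap_cap` on both sequences are counted as
# unmatched columns). Sequences whose whole lengths are moderate are aligned
# by full local dynamic programming directly.
anchored_align_stats <- function(a, b, config = telo_config(),
                                 gap_cap = 3000) {
  na <- nchar(a); nb <- nchar(b)
  if (as.double(na) * nb <= 4e6) {
    al <- cpp_local_align(a, b, config$align_match, config$align_mismatch,
                          config$align_gap_open, config$align_gap_ext)
    return(list(matches = al$matches, columns = al$columns,
                flanks = (al$a_start - 1) + (na - al$a_end) +
                  (al$b_start - 1) + (nb - al$b_end)))
  }
  m <- cpp_mems(a, b, k = 15L, min_len = 20L, max_bucket = 64L)
  if (!nrow(m)) return(list(matches = 0, columns = 0, flanks = na + nb))
  m <- m[order(m$qstart, m$tstart), ]
  k <- nrow(m)
  qe <- m$qstart + m$length - 1L
  te <- m$tstart + m$length - 1L
  best <- m$length
  prev <- rep(0L, k)
  for (i in seq_len(k)) {
    for (j in seq_len(i - 1L)) {
      if (m$qstart[j] >= m$qstart[i] || m$tstart[j] >= m$tstart[i]) next
      ov <- max(0L, qe[j] - m$qstart[i] + 1L, te[j] - m$tstart[i] + 1L)
      gain <- best[j] + m$length[i] - ov
      if (gain > best[i]) { best[i] <- gain; prev[i] <- j }
    }
  }
  # reconstruct the best chain
  i <- which.max(best)
  chain <- integer(0)
  while (i != 0L) { chain <- c(i, chain); i <- prev[i] }
  matches <- 0; columns <- 0
  last_q <- m$qstart[chain[1]] - 1L
  last_t <- m$tstart[chain[1]] - 1L
  flanks <- (m$qstart[chain[1]] - 1L) + (m$tstart[chain[1]] - 1L)
  for (ci in chain) {
    # trim any overlap with the previous block
    ov <- max(0L, last_q - m$qstart[ci] + 1L, last_t - m$tstart[ci] + 1L)
    qs <- m$qstart[ci] + ov; ts <- m$tstart[ci] + ov
    ga <- qs - last_q - 1L; gb <- ts - last_t - 1L
    if (ga > 0 || gb > 0) {
      if (min(ga, gb) == 0 || max(ga, gb) > gap_cap) {
        columns <- columns + max(ga, gb)
      } else {
        g <- cpp_global_align(substr(a, last_q + 1L, qs - 1L),
                              substr(b, last_t + 1L, ts - 1L),
                              config$align_match, config$align_mismatch,
                              config$align_gap_open, config$align_gap_ext)
        matches <- matches + g$matches
        columns <- columns + g$columns
      }
    }
    blk <- qe[ci] - qs + 1L
    if (blk > 0) { matches <- matches + blk; columns <- columns + blk }
    last_q <- max(last_q, qe[ci]); last_t <- max(last_t, te[ci])
  }
  flanks <- flanks + (na - last_q) + (nb - last_t)
  list(matches = matches, columns = columns, flanks = flanks)
}

#' Similarity matrix over Y' instances
#'
#' Computes all pairwise similarities once (identical sequences are
#' deduplicated first) and fills a symmetric matrix with a 100 diagonal.
#'
#' @param seqs Named character vector of condensed sequences (>= 2).
#' @param config A [telo_config()].
#' @return A symmetric numeric matrix with dimnames.
#' @export
similarity_matrix <- function(seqs, config = telo_config()) {
  n <- length(seqs)
  if (n < 2) stop("need at least 2 sequences")
  ids <- names(seqs) %||% as.character(seq_len(n))
  uniq <- unique(unname(seqs))
  ui <- match(seqs, uniq)
  m_u <- diag(100, length(uniq))
  if (length(uniq) > 1) {
    for (i in 1:(length(uniq) - 1)) {
      for (j in (i + 1):length(uniq)) {
        m_u[i, j] <- m_u[j, i] <- pairwise_similarity(uniq[i], uniq[j], config)
      }
    }
  }
  m <- m_u[ui, ui, drop = FALSE]
  diag(m) <- 100
  dimnames(m) <- list(ids, ids)
  m
}

#' Assign variant labels from a similarity matrix
#'
#' Two or more instances share a label when their similarity exceeds
#' `threshold`; since that relation is not transitive, labels are the
#' connected components of the above-threshold graph (single-linkage
#' closure). Components whose minimum internal similarity falls below the
#' threshold are flagged `fragile`. Label ids are deterministic (ordered by
#' smallest member).
#'
#' @param mat Similarity matrix from [similarity_matrix()].
#' @param threshold Label threshold (percent; strictly greater-than).
#' @return Tibble (instance, label, fragile).
#' @export
assign_labels <- function(mat, threshold = 99.9) {
  n <- nrow(mat)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j > i && mat[i, j] > threshold) {
        parent[find(j)] <- find(i)
      }
    }
  }
  comp <- vapply(seq_len(n), find, 0L)
  first <- match(unique(comp), comp)
  lab_of_comp <- setNames(paste0("L", sprintf("%03d", seq_along(first))),
                          comp[first])
  labels <- lab_of_comp[as.character(comp)]
  fragile <- vapply(seq_len(n), function(i) {
    members <- which(comp == comp[i])
    if (length(members) < 2) return(FALSE)
    min(mat[members, members]) <= threshold
  }, logical(1))
  tibble::tibble(instance = rownames(mat) %||% as.character(seq_len(n)),
                 label = unname(labels), fragile = fragile)
}

#' Build the Y' variant catalog of a control genome
#'
#' Extracts all Y' instance sequences from the control extremity maps,
#' condenses homopolymers, computes the similarity matrix, assigns labels at
#' the configured threshold and picks the longest member of each label as its
#' representative.
#'
#' @param maps Control annotation from [build_extremity_maps()].
#' @param config A [telo_config()].
#' @return A list of class `yprime_catalog`: `instances` (tibble: instance,
#'   extremity, index, length, seq, condensed, label), `variants` (tibble:
#'   label, n_members, length, family, representative condensed sequence),
#'   `matrix` (instance similarity matrix).
#' @export
build_catalog <- function(maps, config = telo_config()) {
  inst <- maps[maps$feature == "yprime", ]
  if (!nrow(inst)) stop("no Y' instances in maps")
  instances <- tibble::tibble(
    instance = paste0(inst$extremity, ".", inst$index),
    extremity = inst$extremity,
    index = inst$index,
    length = inst$length,
    seq = inst$seq,
    condensed = condense_homopolymers(inst$seq, config$condensation_max_run)
  )
  mat <- similarity_matrix(setNames(instances$condensed, instances$instance),
                           config)
  labs <- assign_labels(mat, config$label_sim_threshold)
  instances$label <- labs$label[match(instances$instance, labs$instance)]
  variants <- dplyr::group_by(instances, .data$label) |>
    dplyr::summarise(n_members = dplyr::n(),
                     length = max(.data$length),
                     representative = .data$condensed[which.max(.data$length)],
                     .groups = "drop")
  variants$family <- guess_family(variants$length)
  structure(list(instances = instances, variants = variants, matrix = mat,
                 fragile = labs$fragile[match(instances$instance, labs$instance)],
                 config = config),
            class = "yprime_catalog")
}

guess_family <- function(len, short_band = c(5000, 5700),
                         long_band = c(6300, 7100)) {
  dplyr::case_when(
    len >= short_band[1] & len <= short_band[2] ~ "short",
    len >= long_band[1] & len <= long_band[2] ~ "long",
    TRUE ~ "intermediate"
  )
}

#' @export
print.yprime_catalog <- function(x, ...) {
  cat("<yprime_catalog> ", nrow(x$instances), " instances, ",
      nrow(x$variants), " variants\n", sep = "")
  invisible(x)
}

#' Hierarchical clustering of Y' variants
#'
#' Agglomerative clustering (average linkage) on distance `100 - sim` over
#' the variant representatives. The mean silhouette is profiled over
#' `k = 2 .. n-1`; the chosen `k` maximizes the silhouette (ties go to the
#' smaller `k`). A curvature-based elbow of the same profile (maximum
#' discrete second difference) is also computed and reported: on curves with
#' several local bumps it can lock onto an early bump, so it is exposed for
#' inspection rather than used for the choice.
#'
#' @param mat Similarity matrix over variants (>= 3 rows).
#' @return An object of class `yprime_clusters`: assignment tibble, chosen
#'   `k`, the curvature elbow `elbow_k`, silhouette profile, and the
#'   `hclust` tree.
#' @export
cluster_variants <- function(mat) {
  n <- nrow(mat)
  if (n < 3) stop("need at least 3 variants to cluster")
  d <- stats::as.dist(100 - mat)
  hc <- stats::hclust(d, method = "average")
  ks <- 2:(n - 1)
  sil <- vapply(ks, function(k) {
    cl <- stats::cutree(hc, k = k)
    mean(cluster::silhouette(cl, d)[, "sil_width"])
  }, 0)
  k <- ks[which.max(sil)]
  elbow_k <- NA_integer_
  if (length(ks) >= 3) {
    curv <- 2 * sil[2:(length(ks) - 1)] - sil[1:(length(ks) - 2)] -
      sil[3:length(ks)]
    if (any(curv > 0)) elbow_k <- ks[which.max(curv) + 1L]
  }
  assignment <- tibble::tibble(variant = rownames(mat),
                               cluster = unname(stats::cutree(hc, k = k)))
  structure(list(assignment = assignment, k = k, elbow_k = elbow_k,
                 argmax_k = k,
                 silhouette = tibble::tibble(k = ks, silhouette = sil),
                 hclust = hc),
            class = "yprime_clusters")
}

#' @export
print.yprime_clusters <- function(x, ...) {
  cat("<yprime_clusters> k =", x$k, "(silhouette argmax:", x$argmax_k, ")\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname cluster_variants
#' @param x A `yprime_clusters` object.
#' @param ... Unused.
#' @export
tidy.yprime_clusters <- function(x, ...) x$assignment

#' @rdname cluster_variants
#' @export
glance.yprime_clusters <- function(x, ...) {
  tibble::tibble(k = x$k, argmax_k = x$argmax_k,
                 silhouette_at_k = x$silhouette$silhouette[x$silhouette$k == x$k])
}

#' Export a variant dendrogram as Newick
#'
#' @param clusters A `yprime_clusters` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(clusters, path) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    stop("the ape package is required for Newick export")
  }
  ape::write.tree(ape::as.phylo(clusters$hclust), file = path)
  invisible(path)
}

#' Per-family Y' length statistics
#'
#' @param variants Tibble with `label` (or `variant_id`), `length` and
#'   optionally `family` columns (guessed from length otherwise).
#' @return A list with `stats` (per-family min/max/mean/n) and
#'   `intermediates` (variants outside both family bands).
#' @export
variant_length_stats <- function(variants) {
  v <- tibble::as_tibble(variants)
  if (!"family" %in% names(v)) v$family <- guess_family(v$length)
  stats <- dplyr::group_by(v, .data$family) |>
    dplyr::summarise(n = dplyr::n(), min = min(.data$length),
                     max = max(.data$length), mean = mean(.data$length),
                     .groups = "drop")
  list(stats = stats, intermediates = v[v$family == "intermediate", ])
}

#' Label survivor Y' instances against a control catalog
#'
#' Condensed survivor instances identical to a catalog member inherit its
#' label directly; the rest are aligned against length-compatible catalog
#' representatives and take the best label scoring above the threshold, or a
#' fresh `new_*` label otherwise.
#'
#' @param maps Survivor annotation from [build_extremity_maps()].
#' @param catalog Control `yprime_catalog`.
#' @param config A [telo_config()].
#' @return Tibble (instance, extremity, index, length, seq, condensed,
#'   label, novel).
#' @export
label_against_catalog <- function(maps, catalog, config = telo_config()) {
  inst <- maps[maps$feature == "yprime", ]
  out <- tibble::tibble(
    instance = paste0(inst$extremity, ".", inst$index),
    extremity = inst$extremity, index = inst$index, length = inst$length,
    seq = inst$seq,
    condensed = condense_homopolymers(inst$seq, config$condensation_max_run)
  )
  by_seq <- setNames(catalog$instances$label, catalog$instances$condensed)
  labels <- character(nrow(out))
  novel <- logical(nrow(out))
  new_i <- 0L
  for (i in seq_len(nrow(out))) {
    hit <- by_seq[out$condensed[i]]
    if (!is.na(hit)) { labels[i] <- hit; next }
    cand <- catalog$variants
    lenr <- nchar(out$condensed[i]) / nchar(cand$representative)
    cand <- cand[lenr > 0.995 & lenr < 1.005, ]
    best <- 0; best_lab <- NA_character_
    for (j in seq_len(nrow(cand))) {
      s <- pairwise_similarity(out$condensed[i], cand$representative[j], config)
      if (s > best) { best <- s; best_lab <- cand$label[j] }
    }
    if (best > config$label_sim_threshold) {
      labels[i] <- best_lab
    } else {
      new_i <- new_i + 1L
      labels[i] <- paste0("new_", out$extremity[i], "_", new_i)
      novel[i] <- TRUE
    }
  }
  out$label <- labels
  out$novel <- novel
  out
}

#' Flag unresolved extremity maps
#'
#' An extremity is `undetermined` when it carries more than 5 Y' elements and
#' any two adjacent instances share a label (tandem-repeat resolution
#' ambiguity); all other extremities are `resolved`.
#'
#' @param labelled Labelled instance tibble (columns extremity, index,
#'   label).
#' @return Tibble (extremity, n_yprime, status).
#' @export
flag_undetermined <- function(labelled) {
  dplyr::group_by(tibble::as_tibble(labelled), .data$extremity) |>
    dplyr::arrange(.data$index, .by_group = TRUE) |>
    dplyr::summarise(
      n_yprime = dplyr::n(),
      adjacent_dup = any(.data$label == dplyr::lag(.data$label), na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(status = ifelse(.data$n_yprime > 5 & .data$adjacent_dup,
                                  "undetermined", "resolved")) |>
    dplyr::select("extremity", "n_yprime", "status")
}
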