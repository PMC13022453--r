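#' Extract annotated telomere tracts
#'
#' @param genome A `telo_genome`.
#' @param maps Annotation from [build_extremity_maps()].
#' @param config A [telo_config()].
#' @return Tibble (extremity, seq) of terminal tract sequences.
#' @export
telomere_tracts <- function(genome, maps, config = telo_config()) {
  ext <- extremities(genome, config$extremity_window)
  tr <- maps[maps$feature == "telomere", ]
  purrr::map_dfr(seq_len(nrow(tr)), function(i) {
    e <- ext[ext$extremity == tr$extremity[i], ]
    tibble::tibble(extremity = tr$extremity[i],
                   seq = substr(e$seq, tr$start[i] + 1L, tr$end[i]))
  })
}

#' Annotate and catalogue a control genome
#'
#' @param genome Control `telo_genome`.
#' @param yprime_ref Known Y' reference sequences (named vector or tibble).
#' @param x_ref X element reference sequence.
#' @param config A [telo_config()].
#' @return A list of class `telo_control`: maps, catalog, per-extremity
#'   classes and resolution status, telomere tracts, and the inputs.
#' @export
analyze_control <- function(genome, yprime_ref, x_ref,
                            config = telo_config()) {
  maps <- build_extremity_maps(genome, yprime_ref, x_ref, config)
  catalog <- build_catalog(maps, config)
  status <- flag_undetermined(catalog$instances)
  all_ext <- unique(extremities(genome, config$extremity_window)$extremity)
  status <- dplyr::bind_rows(
    status,
    tibble::tibble(extremity = setdiff(all_ext, status$extremity),
                   n_yprime = 0L, status = "resolved"))
  structure(list(genome = genome, maps = maps, catalog = catalog,
                 classes = extremity_classes(maps), status = status,
                 tracts = telomere_tracts(genome, maps, config),
                 yprime_ref = yprime_ref, x_ref = x_ref, config = config),
            class = "telo_control")
}

#' Call rearrangements in one survivor against a control
#'
#' Annotates the survivor, labels its Y' instances against the control
#' catalog, detects terminal duplications and circularization first, then
#' diffs the Y' label strings of every extremity that is resolved in both
#' genomes and not rewritten by a duplication or circularization (such
#' extremities would otherwise produce spurious loss/gain calls for the
#' donor arm's Y' complement), and explains new variants as mosaics.
#'
#' @param survivor_genome Survivor `telo_genome`.
#' @param control A `telo_control` from [analyze_control()].
#' @param clone Clone name.
#' @param config A [telo_config()].
#' @return A list of class `telo_clone`: maps, labelled instances, status,
#'   calls tibble, mosaic explanations, skipped extremities, summary row,
#'   and telomere tracts.
#' @export
analyze_survivor <- function(survivor_genome, control, clone = "survivor",
                             config = control$config) {
  maps <- build_extremity_maps(survivor_genome, control$yprime_ref,
                               control$x_ref, config)
  labelled <- label_against_catalog(maps, control$catalog, config)
  status <- flag_undetermined(labelled)
  dup_calls <- detect_terminal_duplications(survivor_genome, control$genome,
                                            maps, control$maps, config)
  circ_calls <- detect_circularization(survivor_genome, control$genome,
                                       maps, config)
  s_ext <- unique(extremities(survivor_genome, config$extremity_window)$extremity)
  c_ext <- control$status$extremity
  undet <- union(status$extremity[status$status == "undetermined"],
                 control$status$extremity[control$status$status == "undetermined"])
  rewritten <- unique(dup_calls$extremity)
  circ_ext <- unique(c(circ_calls$extremity[circ_calls$kind == "circularization"],
                       circ_calls$extremity2[circ_calls$kind == "circularization"]))
  absent <- setdiff(c_ext, s_ext)
  skipped <- tibble::tibble(
    extremity = c(undet, rewritten, intersect(absent, c_ext)),
    reason = c(rep("undetermined", length(undet)),
               rep("terminal_duplication", length(rewritten)),
               rep("absent_in_survivor", length(intersect(absent, c_ext)))))
  diff_ext <- setdiff(intersect(c_ext, s_ext), skipped$extremity)
  ctrl_inst <- control$catalog$instances
  cat_labels <- unique(ctrl_inst$label)
  y_calls <- purrr::map_dfr(diff_ext, function(e) {
    cl <- ctrl_inst[ctrl_inst$extremity == e, ]
    sl <- labelled[labelled$extremity == e, ]
    diff_extremity(cl$label[order(cl$index)], sl$label[order(sl$index)],
                   extremity = e, catalog_labels = cat_labels)
  })
  calls <- dplyr::bind_rows(
    y_calls,
    dup_calls,
    circ_calls[circ_calls$kind == "circularization", ]
  )
  # mosaic explanation of new variants against the raw control catalog
  cat_seqs <- setNames(ctrl_inst$seq, ctrl_inst$instance)
  cat_seqs <- cat_seqs[!duplicated(ctrl_inst$label)]
  new_labs <- unique(calls$label[calls$kind == "new_variant"])
  mosaics <- purrr::map(setNames(new_labs, new_labs), function(lab) {
    sq <- labelled$seq[labelled$label == lab][1]
    if (is.na(sq)) return(NULL)
    explain_mosaic(sq, cat_seqs, config)
  })
  summary <- summarize_clone(calls, control$classes,
                             excluded = skipped$extremity, clone = clone)
  structure(list(clone = clone, maps = maps, labelled = labelled,
                 status = status, calls = calls, mosaics = mosaics,
                 skipped = skipped, summary = summary,
                 tracts = telomere_tracts(survivor_genome, maps, config)),
            class = "telo_clone")
}

#' @export
print.telo_clone <- function(x, ...) {
  cat("<telo_clone> ", x$clone, ": ", nrow(x$calls), " calls\n", sep = "")
  invisible(x)
}

#' T-circle analysis across clones
#'
#' Scans the telomere tracts of every clone for perfect tandem arrays,
#' consolidates candidate circles per clone, applies the cross-assembly
#' specificity filter, traces origins in the control, reports containment
#' relations and per-clone tandem fractions, and matches every kept circle
#' across all telomeres of all assemblies.
#'
#' @param clones Named list of `telo_clone` objects.
#' @param control A `telo_control`.
#' @param config A [telo_config()].
#' @return A list of class `tcircle_report`: `arrays`, `circles`,
#'   `matches`, `nested`, `fractions` tibbles.
#' @export
tcircle_analysis <- function(clones, control, config = control$config) {
  empty_arrays <- tibble::tibble(start = integer(0), unit_len = integer(0),
                                 copies = integer(0), end = integer(0),
                                 unit = character(0), extremity = character(0),
                                 clone = character(0))
  arrays <- dplyr::bind_rows(empty_arrays,
                             purrr::imap_dfr(clones, function(cl, nm) {
    purrr::map_dfr(seq_len(nrow(cl$tracts)), function(i) {
      a <- find_perfect_tandem_arrays(cl$tracts$seq[i],
                                      config$tandem_min_unit,
                                      config$tandem_min_copies)
      if (!nrow(a)) return(tibble::tibble())
      a$extremity <- cl$tracts$extremity[i]
      a$clone <- nm
      a
    })
  }))
  all_tracts <- c(list(control = control$tracts),
                  purrr::map(clones, "tracts"))
  empty_circles <- tibble::tibble(circle_id = character(0),
                                  unit = character(0), unit_len = integer(0),
                                  n_arrays = integer(0),
                                  total_copies = integer(0),
                                  kept = logical(0),
                                  origin_extremity = character(0),
                                  origin_start = integer(0),
                                  clone = character(0))
  circles <- dplyr::bind_rows(empty_circles,
                              purrr::imap_dfr(clones, function(cl, nm) {
    ca <- arrays[arrays$clone == nm, ]
    if (!nrow(ca)) return(tibble::tibble())
    cons <- consolidate_circles(ca, config)
    if (!nrow(cons)) return(tibble::tibble())
    out <- purrr::map_dfr(seq_len(nrow(cons)), function(i) {
      others <- all_tracts[setdiff(names(all_tracts), c(nm, "control"))]
      specificity_filter_and_origin(cons[i, ], all_tracts[[nm]], others,
                                    control$tracts, config)
    })
    out$clone <- nm
    out
  }))
  kept <- circles[isTRUE_vec(circles$kept), ]
  matches <- purrr::map_dfr(seq_len(nrow(kept)), function(i) {
    purrr::imap_dfr(all_tracts, function(tr, gnm) {
      purrr::map_dfr(seq_len(nrow(tr)), function(ti) {
        m <- match_circle(kept$unit[i], tr$seq[ti], config)
        if (!nrow(m)) return(tibble::tibble())
        m$genome <- gnm
        m$extremity <- tr$extremity[ti]
        m$circle_id <- kept$circle_id[i]
        m$clone <- kept$clone[i]
        m
      })
    })
  })
  nested <- purrr::map_dfr(unique(kept$clone), function(nm) {
    nr <- nested_circle_relations(kept[kept$clone == nm, ], config)
    if (nrow(nr)) nr$clone <- nm
    nr
  })
  fractions <- purrr::imap_dfr(clones, function(cl, nm) {
    fr <- tandem_fraction(cl$tracts, arrays[arrays$clone == nm, ],
                          kept[kept$clone == nm, ], config)
    fr$clone <- nm
    fr
  })
  structure(list(arrays = arrays, circles = circles, matches = matches,
                 nested = nested, fractions = fractions),
            class = "tcircle_report")
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Run the full comparison pipeline
#'
#' Reads the control and survivor assemblies, annotates them, builds the Y'
#' catalog, calls rearrangements per survivor, runs the t-circle analysis,
#' and (optionally) writes the result tables plus a reproducibility manifest
#' to `outdir`.
#'
#' @param control_path Control assembly FASTA (or a `telo_genome`).
#' @param survivor_paths Named character vector of survivor FASTAs (or a
#'   named list of `telo_genome`s).
#' @param yprime_ref,x_ref Reference element sequences (FASTA paths, named
#'   vectors, or tibble for Y').
#' @param outdir Output directory (`NULL` to skip writing).
#' @param config A [telo_config()].
#' @return A list of class `telo_pipeline`: `control`, `clones`, `summaries`,
#'   `events`, `tcircles`, `lengths`.
#' @export
run_pipeline <- function(control_path, survivor_paths, yprime_ref, x_ref,
                         outdir = NULL, config = telo_config()) {
  as_gen <- function(x) if (inherits(x, "telo_genome")) x else read_genome_fasta(x)
  as_seqs <- function(x) {
    if (is.character(x) && length(x) == 1 && file.exists(x)) {
      unclass(read_genome_fasta(x))
    } else x
  }
  control_genome <- as_gen(control_path)
  control <- analyze_control(control_genome, as_seqs(yprime_ref),
                             as_seqs(x_ref), config)
  if (is.null(names(survivor_paths))) {
    names(survivor_paths) <- paste0("clone", seq_along(survivor_paths))
  }
  clones <- purrr::imap(as.list(survivor_paths), function(p, nm) {
    analyze_survivor(as_gen(p), control, clone = nm, config)
  })
  summaries <- purrr::map_dfr(clones, "summary")
  events <- purrr::imap_dfr(clones, function(cl, nm) {
    ev <- cl$calls
    if (nrow(ev)) ev <- dplyr::mutate(ev, clone = nm, .before = 1)
    ev
  })
  tc <- tcircle_analysis(clones, control, config)
  lengths <- dplyr::bind_rows(
    dplyr::mutate(tibble::as_tibble(
      measure_assembly_telomere_lengths(control_genome, config)),
      clone = "control"),
    purrr::imap_dfr(clones, function(cl, nm) {
      tr <- cl$tracts
      tibble::tibble(extremity = tr$extremity, length = nchar(tr$seq),
                     clone = nm)
    })
  )
  res <- structure(list(control = control, clones = clones,
                        summaries = summaries, events = events,
                        tcircles = tc, lengths = lengths, config = config),
                   class = "telo_pipeline")
  if (!is.null(outdir)) write_pipeline_outputs(res, outdir)
  res
}

write_pipeline_outputs <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    readr::write_tsv(tibble::as_tibble(df), file.path(outdir, name),
                     progress = FALSE)
  }
  w(res$events, "events.tsv")
  w(res$summaries, "clone_summaries.tsv")
  w(res$control$catalog$instances[, c("instance", "extremity", "index",
                                      "length", "label")],
    "control_yprime_instances.tsv")
  w(res$control$catalog$variants[, c("label", "n_members", "length", "family")],
    "control_yprime_variants.tsv")
  mat <- res$control$catalog$matrix
  w(dplyr::bind_cols(tibble::tibble(instance = rownames(mat)),
                     tibble::as_tibble(mat)),
    "control_similarity_matrix.tsv")
  w(res$tcircles$arrays[, setdiff(names(res$tcircles$arrays), "unit")],
    "tandem_arrays.tsv")
  if (nrow(res$tcircles$circles)) w(res$tcircles$circles, "circles.tsv")
  if (nrow(res$tcircles$matches)) w(res$tcircles$matches, "circle_matches.tsv")
  w(res$tcircles$fractions, "tandem_fractions.tsv")
  w(res$lengths, "telomere_lengths.tsv")
  write_annotations(res$control$maps,
                    bed_path = file.path(outdir, "control_annotations.bed"),
                    tsv_path = file.path(outdir, "control_annotations.tsv"))
  manifest <- list(package_version = as.character(utils::packageVersion("telorearr")),
                   config = unclass(res$config),
                   clones = names(res$clones),
                   written = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(outdir)
}

#' @export
print.telo_pipeline <- function(x, ...) {
  cat("<telo_pipeline> ", length(x$clones), " survivor clone(s), ",
      nrow(x$events), " calls\n", sep = "")
  invisible(x)
}
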