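# End-to-end orchestration: alignments -> recoding -> diagnostics -> panels
# -> networks -> phasing -> per-locus combination calls -> multilocus
# classification -> chloroplast maternal assignment -> reports.

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("stage %s: %s", stage, conditionMessage(e)),
          class = c("hybridID_stage_error", class(e)[1]))
  })
}

# individual id of a row id following the <ind>_h1/_h2/_c/_cp convention
individual_id <- function(x) sub("_(h[12]|c|cp)$", "", x)

# Phase an individual from cloned haplotype-role rows (the
# cloning-sequencing fallback) rather than from its consensus read.
phased_from_hap_rows <- function(cm, ind, panel) {
  ids <- paste0(ind, c("_h1", "_h2"))
  h1 <- unname(cm$states[ids[1], ])
  h2 <- unname(cm$states[ids[2], ])
  panel_keys <- vapply(panel$haplotypes$states, hap_key, character(1))
  nm <- panel$haplotypes$name[match(c(hap_key(h1), hap_key(h2)), panel_keys)]
  novel_i <- 0L
  if (is.na(nm[1])) { novel_i <- novel_i + 1L; nm[1] <- paste0("UN-", novel_i) }
  if (is.na(nm[2])) { novel_i <- novel_i + 1L; nm[2] <- paste0("UN-", novel_i) }
  sp <- panel$haplotypes$species[match(nm, panel$haplotypes$name)]
  if (!is.na(sp[2]) && sp[2] == "species_A" && (is.na(sp[1]) || sp[1] != "species_A")) {
    tmp <- h1; h1 <- h2; h2 <- tmp; nm <- rev(nm)
  }
  tibble(sample_id = ind, hap1_name = nm[1], hap2_name = nm[2],
         method = "cloned", confidence = 1, tie = FALSE,
         n_resolutions = 1L, hap1 = list(h1), hap2 = list(h2))
}

analyse_locus <- function(aln, locus_letter, epsilon = 0, max_het = 20) {
  locus <- aln_locus(aln)
  cm <- recode_matrix(aln)
  dtable <- diagnostic_sites(cm)
  panel_a <- collapse_haplotypes(cm, "species_A", locus_letter = locus_letter)
  panel_b <- collapse_haplotypes(cm, "species_B", locus_letter = locus_letter)
  panel <- combine_panels(panel_a, panel_b)
  networks <- list(
    species_A = median_joining(panel_a, epsilon = epsilon),
    species_B = median_joining(panel_b, epsilon = epsilon),
    combined = median_joining(panel, epsilon = epsilon)
  )

  smp <- cm$samples
  cons <- smp[smp$role == "diploid_consensus", , drop = FALSE]
  cons$ind <- individual_id(cons$sample_id)
  hap_row_ids <- smp$sample_id[smp$role == "haplotype"]
  cons$cloned <- paste0(cons$ind, "_h1") %in% hap_row_ids &
    paste0(cons$ind, "_h2") %in% hap_row_ids

  freqs <- NULL
  g_all <- genotypes_from_matrix(cm)
  em_ok <- is.na(cons$readable_prefix) & g_all$n_het <= max_het
  if (any(em_ok)) {
    freqs <- em_haplotype_frequencies(g_all[em_ok, ], cm$characters,
                                      panel = panel, max_het = max_het)$freqs
  }

  # identical genotypes phase (and score) identically: compute once per
  # distinct state vector, then fan results back out to individuals
  gkey <- vapply(g_all$states, hap_key, character(1))
  phase_cache <- new.env(parent = emptyenv())
  phased <- purrr::map_dfr(seq_len(nrow(cons)), function(i) {
    if (cons$cloned[i]) {
      return(phased_from_hap_rows(cm, cons$ind[i], panel))
    }
    hit <- phase_cache[[gkey[i]]]
    if (is.null(hit)) {
      hit <- phase_genotype(g_all$states[[i]], panel, freqs = freqs,
                            sample_id = cons$ind[i], max_het = max_het)
      phase_cache[[gkey[i]]] <- hit
    }
    hit$sample_id <- cons$ind[i]
    hit
  })

  call_cache <- new.env(parent = emptyenv())
  calls <- purrr::map_dfr(seq_len(nrow(phased)), function(i) {
    ck <- paste(phased$hap1_name[i], phased$hap2_name[i],
                hap_key(phased$hap1[[i]]), hap_key(phased$hap2[[i]]))
    hit <- call_cache[[ck]]
    if (is.null(hit)) {
      hit <- locus_combination(phased[i, ], panel_a, panel_b)
      call_cache[[ck]] <- hit
    }
    hit$sample_id <- phased$sample_id[i]
    hit
  })
  calls$locus <- locus
  calls$taxon <- cons$taxon[match(calls$sample_id, cons$ind)]
  calls$population <- cons$population[match(calls$sample_id, cons$ind)]

  add_cache <- new.env(parent = emptyenv())
  additivity <- purrr::map_dfr(seq_len(nrow(cons)), function(i) {
    hit <- add_cache[[gkey[i]]]
    if (is.null(hit)) {
      hit <- glance(additivity_profile(g_all$states[[i]], dtable,
                                       sample_id = cons$ind[i]))
      add_cache[[gkey[i]]] <- hit
    }
    hit$sample_id <- cons$ind[i]
    hit
  })
  additivity$locus <- locus
  additivity$taxon <- cons$taxon[match(additivity$sample_id, cons$ind)]

  list(locus = locus, character_matrix = cm, diagnostics = dtable,
       n_diag_substitutions = sum(dtable$kind == "substitution"),
       n_diag_indels = sum(dtable$kind == "indel"),
       panel_a = panel_a, panel_b = panel_b, networks = networks,
       em_freqs = freqs, phased = phased, calls = calls,
       additivity = additivity)
}

#' Run the full hybrid-diagnosis pipeline
#'
#' Accepts a [sim_config()] (the synthetic study is generated first), a
#' `sim_dataset`, or a named list of [site_alignment()]s in which one element
#' (named by `cp_locus`) is the chloroplast locus.  Analyses every nuclear
#' locus independently (diagnostic characters, haplotype panels and networks,
#' EM + panel phasing, combination calls), joins loci only at generation
#' classification, assigns the maternal parent from the chloroplast locus,
#' and summarises germination when counts are available.
#'
#' @param x Input (see above).
#' @param cp_locus Name of the chloroplast element of the alignment list.
#' @param epsilon Median-joining relaxation parameter.
#' @param priors Class priors for [classify_individual()].
#' @param germination Optional germination record data frame (overrides the
#'   dataset's own, if any).
#' @param max_het Per-genotype heterozygosity bound for phasing.
#' @param out_dir When given, all product tables, networks and a run log are
#'   written there as deterministic TSV.
#' @return A `hybrid_report` list; see [print.hybrid_report()].
#' @export
run_pipeline <- function(x, cp_locus = "cp", epsilon = 0, priors = NULL,
                         germination = NULL, max_het = 20, out_dir = NULL) {
  germ <- germination
  if (inherits(x, "sim_config")) x <- with_stage("simulate", simulate_individuals(x))
  if (inherits(x, "sim_dataset")) {
    germ <- germ %||% x$germination
    alignments <- x$alignments
  } else if (is.list(x) && all(vapply(x, inherits, logical(1), "site_alignment"))) {
    alignments <- x
  } else if (is.list(x) && !is.null(x$fasta)) {
    alignments <- with_stage("seqio", {
      out <- lapply(names(x$fasta), function(lc) {
        read_fasta_alignment(x$fasta[[lc]], x$sample_sheets[[lc]],
                             taxon_map = x$taxon_map, locus = lc)
      })
      setNames(out, names(x$fasta))
    })
    if (!is.null(x$germination)) {
      germ <- if (is.character(x$germination)) {
        readr::read_tsv(x$germination, col_types = readr::cols())
      } else x$germination
    }
  } else {
    abort("run_pipeline() needs a sim_config, sim_dataset, alignment list, or path config",
          class = "hybridID_usage_error")
  }

  nuclear <- setdiff(names(alignments), cp_locus)
  loci <- lapply(seq_along(nuclear), function(i) {
    with_stage(paste0("locus ", nuclear[i]),
               analyse_locus(alignments[[nuclear[i]]], LETTERS[i],
                             epsilon = epsilon, max_het = max_het))
  })
  names(loci) <- nuclear

  calls <- dplyr::bind_rows(lapply(loci, `[[`, "calls"))
  classification <- with_stage("classify", {
    calls |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::group_map(function(d, key) {
        cl <- classify_individual(dplyr::mutate(d, sample_id = key$sample_id),
                                  priors = priors)
        cl$taxon <- d$taxon[1]
        cl
      }) |>
      dplyr::bind_rows()
  })

  maternal <- NULL
  direction <- NULL
  cp_divergence <- NULL
  if (cp_locus %in% names(alignments)) {
    cp_res <- with_stage("chloroplast", {
      cm_cp <- recode_matrix(alignments[[cp_locus]])
      dt_cp <- diagnostic_sites(cm_cp)
      pa <- collapse_haplotypes(cm_cp, "species_A", locus_letter = "P")
      pb <- collapse_haplotypes(cm_cp, "species_B", locus_letter = "P")
      hyb_ids <- cm_cp$samples$sample_id[cm_cp$samples$taxon == "hybrid" &
                                           cm_cp$samples$role == "haplotype"]
      asn <- purrr::map_dfr(hyb_ids, function(id) {
        maternal_assignment(unname(cm_cp$states[id, ]), pa, pb,
                            sample_id = individual_id(id))
      })
      list(divergence = tibble(
             n_substitutions = sum(dt_cp$kind == "substitution"),
             n_indels = sum(dt_cp$kind == "indel")),
           assignments = asn,
           direction = if (nrow(asn) > 0) direction_summary(asn) else NULL)
    })
    maternal <- cp_res$assignments
    direction <- cp_res$direction
    cp_divergence <- cp_res$divergence
  }

  germ_summary <- if (!is.null(germ) && nrow(germ) > 0) {
    with_stage("germination", germination_summary(germ))
  }

  hyb_class <- classification[classification$taxon == "hybrid", , drop = FALSE]
  report <- structure(
    list(loci = loci, calls = calls, classification = classification,
         n_hybrids = nrow(hyb_class),
         n_f1_consistent = sum(hyb_class$f1_consistent),
         maternal = maternal, direction = direction,
         cp_divergence = cp_divergence,
         germination = germ_summary,
         params = list(cp_locus = cp_locus, epsilon = epsilon,
                       max_het = max_het)),
    class = "hybrid_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.hybrid_report <- function(x, ...) {
  cat("<hybrid_report>\n")
  for (lc in names(x$loci)) {
    l <- x$loci[[lc]]
    cat(sprintf("  %s: %d diagnostic substitution(s) + %d diagnostic indel(s); panels %d (A) / %d (B) haplotypes\n",
                lc, l$n_diag_substitutions, l$n_diag_indels,
                nrow(l$panel_a$haplotypes), nrow(l$panel_b$haplotypes)))
  }
  if (!is.null(x$cp_divergence)) {
    cat(sprintf("  chloroplast divergence: %d substitution(s) + %d indel(s)\n",
                x$cp_divergence$n_substitutions, x$cp_divergence$n_indels))
  }
  cat(sprintf("  hybrids: %d, F1-consistent: %d\n", x$n_hybrids, x$n_f1_consistent))
  if (!is.null(x$direction)) {
    cat(sprintf("  maternal parent: %d/%d species_B (p = %.3g)\n",
                x$direction$n_B, x$direction$n, x$direction$p_value))
  }
  invisible(x)
}

#' Summary tables of a pipeline report
#' @param x A `hybrid_report`.
#' @param ... Unused.
#' @return `tidy()`: the per-individual per-locus combination calls.
#'   `glance()`: one row per locus with diagnostic and panel counts.
#' @export
tidy.hybrid_report <- function(x, ...) as_tibble(x$calls)

#' @rdname tidy.hybrid_report
#' @export
glance.hybrid_report <- function(x, ...) {
  purrr::imap_dfr(x$loci, function(l, nm) {
    tibble(locus = nm,
           n_diag_substitutions = l$n_diag_substitutions,
           n_diag_indels = l$n_diag_indels,
           n_hap_A = nrow(l$panel_a$haplotypes),
           n_hap_B = nrow(l$panel_b$haplotypes))
  })
}

#' Count haplotype combinations per locus and population
#'
#' The per-location tally of hybrid combination labels (the package's
#' analogue of a haplotype-combination table).
#'
#' @param report A `hybrid_report`.
#' @param taxa Which taxa to tabulate (default hybrids only).
#' @return A tibble `locus`, `combination`, `population`, `n`.
#' @export
combination_counts <- function(report, taxa = "hybrid") {
  report$calls |>
    dplyr::filter(.data$taxon %in% taxa) |>
    dplyr::count(.data$locus, .data$combination, .data$population, name = "n")
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  drop_lists <- function(d) d[, !vapply(d, is.list, logical(1)), drop = FALSE]
  tables <- list(
    locus_summary = glance(report),
    combination_calls = drop_lists(report$calls),
    classification = report$classification,
    combination_counts = combination_counts(report)
  )
  for (lc in names(report$loci)) {
    l <- report$loci[[lc]]
    tables[[paste0("diagnostics_", lc)]] <- as_tibble(l$diagnostics)
    tables[[paste0("phased_", lc)]] <- drop_lists(l$phased)
    tables[[paste0("additivity_", lc)]] <- l$additivity
    tables[[paste0("panel_", lc)]] <- tidy(combine_panels(l$panel_a, l$panel_b))
    export_network(l$networks$combined,
                   file.path(out_dir, paste0("network_", lc, ".tsv")),
                   format = "edge_tsv")
  }
  if (!is.null(report$maternal)) tables$maternal_assignments <- report$maternal
  if (!is.null(report$direction)) tables$direction <- report$direction
  if (!is.null(report$germination)) {
    tables$germination_rates <- report$germination$rates
    if (!is.null(report$germination$tests)) {
      tables$germination_tests <- report$germination$tests
    }
  }
  write_tables(tables, out_dir)
  log_lines <- c(
    sprintf("hybridID %s", as.character(utils::packageVersion("hybridID"))),
    sprintf("parameters: cp_locus=%s epsilon=%d max_het=%d",
            report$params$cp_locus, report$params$epsilon, report$params$max_het),
    sprintf("hybrids=%d f1_consistent=%d", report$n_hybrids, report$n_f1_consistent)
  )
  readr::write_lines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}
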