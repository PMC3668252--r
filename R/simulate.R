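# Synthetic-data generator emulating a two-species hybrid-zone study.
#
# The default configuration reproduces the statistical structure of the
# motivating study design: three nuclear loci of 453/601/490 aligned bp with
# 9 / 11 (+ one fixed 5-bp indel) / 7 fixed interspecific substitutions and
# 2&2 / 6&2 / 6&3 within-species haplotypes, a 975-bp chloroplast spacer
# diverged by 11 substitutions plus 3 indels with no within-species
# variation, parental samples across the populations of the sampling table
# (157 + 70 individuals), 22 F1 hybrids (10 + 12 by location), strictly
# species-B-maternal chloroplast transmission, and per-taxon spore
# germination rates 0.798 / 0.654 / 0.203 on > 200 spores.

#' Build a simulation configuration
#'
#' @param seed Integer seed driving every random choice downstream.
#' @param loci List of locus specifications (see [locus_spec()]); default is
#'   the three-nuclear-gene design described above.
#' @param cp Chloroplast spec: `length`, `n_sub`, `indel_lengths`.
#' @param pops_a,pops_b Named integer vectors of parental individuals per
#'   population.
#' @param hybrids Tibble with columns `population`, `class`
#'   (`F1`/`F2`/`BC_A`/`BC_B`), `n`.
#' @param maternal_rule `always_B`, `always_A`, or `random`.
#' @param error_rate Per-base miscall probability applied to consensus reads.
#' @param core_freq Frequency of each species' core haplotype; the remaining
#'   mass is split evenly among minor haplotypes (star-like variation).
#' @param germination Tibble `taxon`, `rate`, `total` of true germination
#'   rates and spore counts.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       loci = NULL,
                       cp = list(length = 975L, n_sub = 11L,
                                 indel_lengths = c(4L, 5L, 6L)),
                       pops_a = c(Wenchang = 21L, Sanya = 21L, Qionghai = 15L,
                                  Haikou = 21L, Danzhou = 23L, Huizhou = 22L,
                                  Guangzhou = 21L, Suixi = 13L),
                       pops_b = c(Gaoqiao = 21L, Wenchang = 25L, Suixi = 24L),
                       hybrids = tibble(population = c("Wenchang", "Suixi"),
                                        class = c("F1", "F1"),
                                        n = c(10L, 12L)),
                       maternal_rule = c("always_B", "always_A", "random"),
                       error_rate = 0,
                       core_freq = 0.75,
                       germination = tibble(
                         taxon = c("species_A", "species_B", "hybrid"),
                         rate = c(0.798, 0.654, 0.203),
                         total = c(204L, 205L, 202L))) {
  loci <- loci %||% list(
    locus_spec("cam",    length = 453L, letter = "A", n_sub = 9L,
               indel_lengths = integer(0), n_hap_a = 2L, n_hap_b = 2L),
    locus_spec("gapCp1", length = 601L, letter = "B", n_sub = 11L,
               indel_lengths = 5L, n_hap_a = 6L, n_hap_b = 2L),
    locus_spec("gapCp2", length = 490L, letter = "C", n_sub = 7L,
               indel_lengths = integer(0), n_hap_a = 6L, n_hap_b = 3L)
  )
  names(loci) <- vapply(loci, `[[`, character(1), "name")
  structure(
    list(seed = as.integer(seed), loci = loci, cp = cp,
         pops_a = pops_a, pops_b = pops_b, hybrids = as_tibble(hybrids),
         maternal_rule = match.arg(maternal_rule),
         error_rate = error_rate, core_freq = core_freq,
         germination = as_tibble(germination)),
    class = "sim_config"
  )
}

#' @rdname sim_config
#' @param name,length,letter,n_sub,indel_lengths,n_hap_a,n_hap_b Locus name,
#'   aligned length (bp), locus letter used in haplotype names, number of
#'   fixed interspecific substitutions, lengths of fixed indel events, and
#'   the number of haplotypes per species (core + one-step minors).
#' @export
locus_spec <- function(name, length, letter, n_sub, indel_lengths = integer(0),
                       n_hap_a = 1L, n_hap_b = 1L) {
  need <- n_sub + sum(indel_lengths) + (n_hap_a - 1L) + (n_hap_b - 1L)
  if (length < need + 2L) {
    abort(sprintf("locus %s: length %d cannot host %d mutations without collision",
                  name, length, need), class = "hybridID_config_error")
  }
  list(name = name, length = as.integer(length), letter = letter,
       n_sub = as.integer(n_sub), indel_lengths = as.integer(indel_lengths),
       n_hap_a = as.integer(n_hap_a), n_hap_b = as.integer(n_hap_b))
}

other_base <- function(b) vapply(b, function(x) sample(setdiff(BASES, x), 1), character(1))

# One locus of the species pair: ancestral sequence, fixed differences,
# star-like within-species haplotypes.  All coordinates 0-based.
build_locus <- function(spec, core_freq) {
  L <- spec$length
  anc <- sample(BASES, L, replace = TRUE)
  # place fixed indel events in the second half so a heterozygous indel still
  # leaves diagnostic substitutions readable upstream
  indels <- tibble(start = integer(), end = integer())
  occupied <- rep(FALSE, L)
  for (len in spec$indel_lengths) {
    repeat {
      s <- sample(seq(floor(L * 0.55), L - len - 2L), 1)
      if (!any(occupied[(s + 1):(s + len + 2)])) break   # keep events non-adjacent
    }
    occupied[(s + 1):(s + len)] <- TRUE
    indels <- dplyr::bind_rows(indels, tibble(start = s, end = s + len))
  }
  indels <- dplyr::arrange(indels, .data$start)
  free <- which(!occupied) - 1L                          # 0-based columns
  # pad around events so runs of gap columns never touch
  near_event <- unique(unlist(lapply(seq_len(nrow(indels)), function(i) {
    c(indels$start[i] - 1L, indels$end[i])
  })))
  free <- setdiff(free, near_event)
  diag_pos <- sort(sample(free, spec$n_sub))
  if (nrow(indels) > 0 && !any(diag_pos < indels$start[1])) {
    # guarantee at least one readable diagnostic site upstream of the first indel
    up <- free[free < indels$start[1]]
    diag_pos <- sort(c(sample(up, 1), diag_pos[-1]))
  }
  free <- setdiff(free, diag_pos)

  core_a <- anc
  core_b <- anc
  core_b[diag_pos + 1L] <- other_base(anc[diag_pos + 1L])
  # species B carries the deletion state at every fixed indel
  for (i in seq_len(nrow(indels))) {
    core_b[(indels$start[i] + 1L):indels$end[i]] <- "-"
  }
  make_minors <- function(core, k) {
    haps <- list(core)
    if (k > 1) {
      pos <- sample(free, k - 1L)
      free <<- setdiff(free, pos)
      for (p in pos) {
        h <- core
        h[p + 1L] <- other_base(core[p + 1L])
        haps <- c(haps, list(h))
      }
    }
    haps
  }
  haps_a <- make_minors(core_a, spec$n_hap_a)
  haps_b <- make_minors(core_b, spec$n_hap_b)
  freqs <- function(k) if (k == 1) 1 else c(core_freq, rep((1 - core_freq) / (k - 1), k - 1))
  list(
    spec = spec,
    diag_pos = diag_pos,
    indels = indels,
    haps_a = tibble(hap_id = paste0(spec$name, "_A", seq_along(haps_a)),
                    seq = vapply(haps_a, paste, character(1), collapse = ""),
                    freq = freqs(spec$n_hap_a)),
    haps_b = tibble(hap_id = paste0(spec$name, "_B", seq_along(haps_b)),
                    seq = vapply(haps_b, paste, character(1), collapse = ""),
                    freq = freqs(spec$n_hap_b))
  )
}

#' Build the diverged species pair for every locus
#'
#' Draws a random ancestral sequence per locus and derives the two species'
#' core haplotypes, differing at exactly the configured fixed substitution
#' positions and indel events, plus star-like within-species minor haplotypes
#' (one private mutation each) at non-diagnostic positions.  Deterministic
#' given `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return A `species_pair` list: `$loci` (per-locus truth), `$cp`
#'   (chloroplast truth with single haplotypes per species).
#' @export
build_species_pair <- function(cfg) {
  set.seed(cfg$seed)
  loci <- lapply(cfg$loci, build_locus, core_freq = cfg$core_freq)
  cp_spec <- locus_spec("trnV-trnM", length = cfg$cp$length, letter = "P",
                        n_sub = cfg$cp$n_sub,
                        indel_lengths = cfg$cp$indel_lengths)
  cp <- build_locus(cp_spec, core_freq = 1)
  structure(list(loci = loci, cp = cp), class = "species_pair")
}

# A base-calling error replaces the observed call (a base or a two-base
# ambiguity code) with a uniformly random different call, so any single
# miscall at a diagnostic site destroys additivity with probability `rate`.
apply_read_error <- function(chars, rate) {
  if (rate <= 0) return(chars)
  call_chars <- c(BASES, names(AMBIG2))
  hit <- which(runif(length(chars)) < rate & chars %in% call_chars)
  if (length(hit) > 0) {
    chars[hit] <- vapply(chars[hit],
                         function(x) sample(setdiff(call_chars, x), 1),
                         character(1))
  }
  chars
}

# Direct-sequencing consensus of two gapped haplotype sequences.  Outside
# indel intervals bases combine by IUPAC union; a shared deletion stays a
# gap; a heterozygous indel truncates the read: everything from the event
# start onwards becomes N and readable_prefix records the cut.
consensus_sequence <- function(seq1, seq2, indels, error_rate = 0) {
  a <- strsplit(seq1, "", fixed = TRUE)[[1]]
  b <- strsplit(seq2, "", fixed = TRUE)[[1]]
  out <- character(length(a))
  both_base <- a != "-" & b != "-"
  out[both_base] <- iupac_union(a[both_base], b[both_base])
  out[a == "-" & b == "-"] <- "-"
  out[xor(a == "-", b == "-")] <- "N"
  rp <- NA_integer_
  for (i in seq_len(nrow(indels))) {
    block_a <- a[(indels$start[i] + 1L):indels$end[i]]
    block_b <- b[(indels$start[i] + 1L):indels$end[i]]
    if (any((block_a == "-") != (block_b == "-"))) {
      rp <- indels$start[i]
      break
    }
  }
  out <- apply_read_error(out, error_rate)
  if (!is.na(rp)) out[(rp + 1L):length(out)] <- "N"
  list(sequence = paste(out, collapse = ""), readable_prefix = rp)
}

draw_hap <- function(haps, n = 1) haps$hap_id[sample.int(nrow(haps), n, replace = TRUE, prob = haps$freq)]

#' Simulate the full study dataset
#'
#' Parental individuals draw two haplotypes per locus from their species'
#' frequency distribution (Hardy-Weinberg); F1s draw one haplotype from each
#' species; F2s draw two independent F1 gametes; backcrosses one F1 gamete
#' plus one parental draw (free recombination between loci, none within).
#' Every individual gets a direct-sequencing consensus row; individuals whose
#' consensus is truncated by a heterozygous indel additionally get cloned
#' haplotype-role rows (the cloning-sequencing fallback).  Parental
#' individuals always carry cloned/phased haplotype rows, mirroring the
#' deposited per-species haplotypes.  The chloroplast sequence is copied from
#' the maternal species; germination counts are binomial draws from the true
#' rates.
#'
#' @param cfg A [sim_config()].
#' @param pair A `species_pair` from [build_species_pair()]; built on the fly
#'   when `NULL`.
#' @return A `sim_dataset`: `$alignments` (named list of [site_alignment()],
#'   nuclear loci plus `"cp"`), `$truth` (`$individuals`, `$haplotypes`,
#'   `$diagnostics`), `$germination`, `$config`.
#' @export
simulate_individuals <- function(cfg, pair = NULL) {
  pair <- pair %||% build_species_pair(cfg)
  set.seed(cfg$seed + 1L)

  inds <- dplyr::bind_rows(
    purrr::imap_dfr(as.list(cfg$pops_a), function(n, pop) {
      tibble(taxon = "species_A", population = pop, class = "pure_A", n = n)
    }),
    purrr::imap_dfr(as.list(cfg$pops_b), function(n, pop) {
      tibble(taxon = "species_B", population = pop, class = "pure_B", n = n)
    }),
    dplyr::mutate(cfg$hybrids, taxon = "hybrid")
  ) |> tidyr::uncount(.data$n)
  prefix <- c(species_A = "aur", species_B = "spe", hybrid = "hyb")
  inds$sample_id <- stats::ave(seq_len(nrow(inds)), inds$taxon,
                               FUN = seq_along)
  inds$sample_id <- sprintf("%s%03d", prefix[inds$taxon], inds$sample_id)
  if (any(inds$taxon == "hybrid") &&
      (nrow(pair$loci[[1]]$haps_a) == 0 || nrow(pair$loci[[1]]$haps_b) == 0)) {
    abort("hybrid classes requested with an empty parental panel",
          class = "hybridID_config_error")
  }

  # maternal species per individual
  inds$maternal <- dplyr::case_when(
    inds$taxon == "species_A" ~ "species_A",
    inds$taxon == "species_B" ~ "species_B",
    cfg$maternal_rule == "always_B" ~ "species_B",
    cfg$maternal_rule == "always_A" ~ "species_A",
    TRUE ~ sample(c("species_A", "species_B"), nrow(inds), replace = TRUE)
  )

  # draw the true haplotype pair of one individual at one locus
  draw_pair <- function(class, locus) {
    A <- locus$haps_a; B <- locus$haps_b
    f1_gamete <- function() if (runif(1) < 0.5) draw_hap(A) else draw_hap(B)
    switch(class,
      pure_A = draw_hap(A, 2),
      pure_B = draw_hap(B, 2),
      F1 = c(draw_hap(A), draw_hap(B)),
      F2 = c(f1_gamete(), f1_gamete()),
      BC_A = c(f1_gamete(), draw_hap(A)),
      BC_B = c(f1_gamete(), draw_hap(B)),
      abort(sprintf("unknown class '%s'", class), class = "hybridID_config_error")
    )
  }

  truth_haps <- list()
  alignments <- list()
  for (lc in names(pair$loci)) {
    locus <- pair$loci[[lc]]
    seqs <- setNames(c(locus$haps_a$seq, locus$haps_b$seq),
                     c(locus$haps_a$hap_id, locus$haps_b$hap_id))
    rows <- list()
    for (i in seq_len(nrow(inds))) {
      ind <- inds[i, ]
      hp <- draw_pair(ind$class, locus)
      truth_haps[[length(truth_haps) + 1L]] <-
        tibble(locus = lc, sample_id = ind$sample_id,
               hap1_id = hp[1], hap2_id = hp[2])
      cons <- consensus_sequence(seqs[[hp[1]]], seqs[[hp[2]]], locus$indels,
                                 error_rate = cfg$error_rate)
      cloned <- ind$taxon != "hybrid" || !is.na(cons$readable_prefix)
      if (cloned) {
        rows[[length(rows) + 1L]] <- tibble(
          sample_id = paste0(ind$sample_id, c("_h1", "_h2")),
          taxon = ind$taxon, population = ind$population, role = "haplotype",
          readable_prefix = NA_integer_, sequence = unname(seqs[hp])
        )
      }
      rows[[length(rows) + 1L]] <- tibble(
        sample_id = paste0(ind$sample_id, "_c"), taxon = ind$taxon,
        population = ind$population, role = "diploid_consensus",
        readable_prefix = cons$readable_prefix, sequence = cons$sequence
      )
    }
    alignments[[lc]] <- site_alignment(dplyr::bind_rows(rows), locus = lc)
  }

  # chloroplast: uniparental, one row per individual, copied from the
  # maternal species core
  cp_seqs <- c(species_A = pair$cp$haps_a$seq[1], species_B = pair$cp$haps_b$seq[1])
  alignments[["cp"]] <- site_alignment(
    tibble(sample_id = paste0(inds$sample_id, "_cp"), taxon = inds$taxon,
           population = inds$population, role = "haplotype",
           readable_prefix = NA_integer_,
           sequence = unname(cp_seqs[inds$maternal])),
    locus = "trnV-trnM"
  )

  germ <- dplyr::mutate(cfg$germination,
                        germinated = rbinom(dplyr::n(), .data$total, .data$rate))

  diagnostics <- dplyr::bind_rows(
    purrr::imap_dfr(pair$loci, function(l, nm) {
      tibble(locus = nm, n_fixed_substitutions = length(l$diag_pos),
             n_fixed_indels = nrow(l$indels))
    }),
    tibble(locus = "cp", n_fixed_substitutions = length(pair$cp$diag_pos),
           n_fixed_indels = nrow(pair$cp$indels))
  )

  structure(
    list(alignments = alignments,
         truth = list(
           individuals = as_tibble(inds[, c("sample_id", "taxon", "population",
                                            "class", "maternal")]),
           haplotypes = dplyr::bind_rows(truth_haps),
           diagnostics = diagnostics),
         germination = germ[, c("taxon", "germinated", "total")],
         config = cfg, pair = pair),
    class = "sim_dataset"
  )
}

#' @rdname simulate_individuals
#' @param ... Passed to [sim_config()].
#' @export
simulate_dataset <- function(seed = 1, ...) {
  simulate_individuals(sim_config(seed = seed, ...))
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("<sim_dataset> %d individuals, %d nuclear loci + cp, seed %d\n",
              nrow(x$truth$individuals), length(x$alignments) - 1L,
              x$config$seed))
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' One FASTA + sample-sheet TSV per locus, plus truth tables and the
#' germination table; everything re-readable with [read_fasta_alignment()].
#'
#' @param ds A `sim_dataset`.
#' @param out_dir Output directory.
#' @return Invisibly, `out_dir`.
#' @export
write_dataset <- function(ds, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (lc in names(ds$alignments)) {
    write_fasta_alignment(ds$alignments[[lc]],
                          file.path(out_dir, paste0(lc, ".fasta")),
                          sample_sheet = file.path(out_dir, paste0(lc, ".samples.tsv")))
  }
  write_tables(list(truth_individuals = ds$truth$individuals,
                    truth_haplotypes = ds$truth$haplotypes,
                    truth_diagnostics = ds$truth$diagnostics,
                    germination = ds$germination),
               out_dir)
  invisible(out_dir)
}
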