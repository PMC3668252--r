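test_that("indel events are maximal same-pattern gap runs", {
  aln <- make_aln(c(a = "AC-----T", b = "ACGGGGGT"))
  ev <- detect_indel_events(aln)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$start, 2L)
  expect_equal(ev$end, 7L)
  expect_equal(ev$length, 5L)

  expect_equal(nrow(detect_indel_events(make_aln(c(a = "ACGT", b = "ACGA")))), 0L)

  # adjacent gap columns with different presence patterns split into events
  ev2 <- detect_indel_events(make_aln(c(a = "A--T", b = "AG-T", c = "A-CT")))
  expect_equal(nrow(ev2), 2L)
  expect_equal(ev2$start, c(1L, 2L))
  expect_equal(ev2$end, c(2L, 3L))

  expect_error(detect_indel_events(make_aln(c(a = "A-T", b = "A-T"))),
               class = "hybridID_alignment_error")
})

test_that("recoding replaces event columns by one binary character", {
  aln <- make_aln(c(a = "AC-----T", b = "ACGGGGGT"))
  cm <- recode_matrix(aln)
  expect_equal(sum(cm$characters$kind == "substitution"), 3L)  # cols 0,1,7
  expect_equal(sum(cm$characters$kind == "indel"), 1L)
  expect_identical(unname(cm$states["a", cm$characters$kind == "indel"]), "0")
  expect_identical(unname(cm$states["b", cm$characters$kind == "indel"]), "1")

  # no events: one character per column
  aln2 <- make_aln(c(a = "ACGT", b = "ACGA"))
  cm2 <- recode_matrix(aln2)
  expect_equal(nrow(cm2$characters), aln_ncol(aln2))
  expect_true(all(cm2$characters$kind == "substitution"))
  expect_identical(cm2$characters$variable, c(FALSE, FALSE, FALSE, TRUE))
})

test_that("consensus rows are truncated at their readable prefix", {
  aln <- make_aln(
    c(a = "ACGTTTTA", b = "ACGTTTTA", con = "ACGTTTTA"),
    role = c("haplotype", "haplotype", "diploid_consensus"),
    readable_prefix = c(NA, NA, 4L)
  )
  cm <- recode_matrix(aln)
  expect_identical(unname(cm$states["con", ]),
                   c("A", "C", "G", "T", "N", "N", "N", "N"))
})

test_that("diagnostic calling matches the definition and its invariances", {
  aln <- make_aln(c(a1 = "ACG", a2 = "ACG", b1 = "ATG", b2 = "ATG"),
                  taxon = c("species_A", "species_A", "species_B", "species_B"))
  cm <- recode_matrix(aln)
  dt <- diagnostic_sites(cm)
  expect_equal(nrow(dt), 1L)
  expect_identical(dt$char_id, "S0001")
  expect_identical(dt$allele_A, "C")
  expect_identical(dt$allele_B, "T")

  # a within-species polymorphism kills the site
  aln2 <- make_aln(c(a1 = "ACG", a2 = "ATG", b1 = "ATG"),
                   taxon = c("species_A", "species_A", "species_B"))
  expect_equal(nrow(diagnostic_sites(recode_matrix(aln2))), 0L)
})

test_that("diagnostic calling equals the per-character brute-force oracle", {
  set.seed(42)
  for (rep in 1:40) {
    aln <- random_species_aln(n_a = 5, n_b = 5, n_col = 30)
    cm <- recode_matrix(aln)
    dt <- diagnostic_sites(cm)
    sa <- cm$states[aln$sample_id[aln$taxon == "species_A"], , drop = FALSE]
    sb <- cm$states[aln$sample_id[aln$taxon == "species_B"], , drop = FALSE]
    oracle <- brute_force_diagnostics(sa, sb)
    expect_identical(dt$char_id, cm$characters$char_id[oracle])

    # symmetry: swapping groups swaps alleles
    dt_sw <- diagnostic_sites(cm,
                              group_a = aln$sample_id[aln$taxon == "species_B"],
                              group_b = aln$sample_id[aln$taxon == "species_A"])
    expect_identical(dt_sw$char_id, dt$char_id)
    expect_identical(dt_sw$allele_A, dt$allele_B)
    expect_identical(dt_sw$allele_B, dt$allele_A)
  }
})

test_that("fixed differences are invariant to duplicating a haplotype", {
  set.seed(7)
  aln <- random_species_aln(n_a = 4, n_b = 4, n_col = 25)
  cm <- recode_matrix(aln)
  dt <- diagnostic_sites(cm)
  dup <- tibble::as_tibble(aln)[1, ]
  dup$sample_id <- "dup1"
  aln2 <- site_alignment(dplyr::bind_rows(tibble::as_tibble(aln), dup), "loc")
  dt2 <- diagnostic_sites(recode_matrix(aln2))
  expect_identical(as.data.frame(dt2), as.data.frame(dt))
})

test_that("every diagnostic character is segregating in the pooled matrix", {
  set.seed(99)
  for (rep in 1:10) {
    aln <- random_species_aln(n_a = 4, n_b = 6, n_col = 20)
    cm <- recode_matrix(aln)
    dt <- diagnostic_sites(cm)
    seg <- cm$characters$char_id[cm$characters$variable]
    expect_true(all(dt$char_id %in% seg))
    expect_lte(nrow(dt), length(seg))
  }
})

test_that("haplotype collapsing names by abundance and tallies populations", {
  aln <- make_aln(c(h1 = "ACG", h2 = "ACG", h3 = "ACG", h4 = "ACG"))
  p <- collapse_haplotypes(recode_matrix(aln), "species_A", locus_letter = "A")
  expect_equal(nrow(p$haplotypes), 1L)
  expect_equal(p$haplotypes$total, 4L)
  expect_identical(p$haplotypes$name, "aA1")

  aln2 <- make_aln(c(x1 = "ACG", x2 = "ACG", y1 = "ATG"),
                   population = c("P1", "P1", "P2"))
  p2 <- collapse_haplotypes(recode_matrix(aln2), "species_A", locus_letter = "B")
  expect_identical(p2$haplotypes$name, c("aB1", "aB2"))
  expect_equal(p2$counts$count[p2$counts$name == "aB1" & p2$counts$population == "P1"], 2L)
  expect_equal(p2$counts$count[p2$counts$name == "aB2" & p2$counts$population == "P2"], 1L)

  # a one-mutation minor haplotype sits one step from the core
  w <- cam_world()
  expect_equal(mutation_distance(
    w$pa$haplotypes$states[[which(w$pa$haplotypes$name == "aA1")]],
    w$pa$haplotypes$states[[which(w$pa$haplotypes$name == "aA2")]]), 1L)
})

test_that("polymorphism summaries count haplotypes, frequencies, segregating sites", {
  aln <- make_aln(setNames(rep("ACG", 10), paste0("h", 1:10)))
  s <- polymorphism_summary(collapse_haplotypes(recode_matrix(aln), "species_A"))
  expect_equal(s$n_haplotypes[s$population == "TOTAL"], 1L)
  expect_equal(s$n_segregating[s$population == "TOTAL"], 0L)

  aln2 <- make_aln(setNames(c(rep("ACG", 7), rep("ATG", 3)), paste0("h", 1:10)))
  pan2 <- collapse_haplotypes(recode_matrix(aln2), "species_A")
  f <- haplotype_frequencies(pan2)
  expect_equal(sort(f$freq), c(0.3, 0.7))
  expect_equal(polymorphism_summary(pan2)$n_segregating[2], 1L)
})

test_that("the simulated gapCp1-like species panel carries six haplotypes", {
  pair <- build_species_pair(sim_config(seed = 5))
  hap <- pair$loci$gapCp1$haps_a
  aln <- make_aln(setNames(hap$seq, paste0("h", seq_len(nrow(hap)))))
  pan <- collapse_haplotypes(recode_matrix(aln), "species_A", locus_letter = "B")
  expect_equal(nrow(pan$haplotypes), 6L)
  expect_equal(polymorphism_summary(pan)$n_haplotypes[2], 6L)
})
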