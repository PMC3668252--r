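test_that("F1 consensus reads are additive at every diagnostic site", {
  w <- cam_world()
  f1 <- unname(mapply(iupac_union, w$haps$aA1, w$haps$sA1))
  prof <- additivity_profile(f1, w$dtable, sample_id = "f1")
  expect_equal(nrow(prof), 9L)
  expect_true(all(prof$verdict == "additive"))
  expect_equal(attr(prof, "additivity_index"), 1.0)

  pure <- additivity_profile(w$haps$aA1, w$dtable)
  expect_true(all(pure$verdict == "allele_A_only"))
  expect_equal(attr(pure, "additivity_index"), 0)

  pure_b <- additivity_profile(w$haps$sA2, w$dtable)
  expect_true(all(pure_b$verdict == "allele_B_only"))
})

test_that("truncated consensus is scored over readable characters only", {
  w <- cam_world()
  f1 <- unname(mapply(iupac_union, w$haps$aA1, w$haps$sA1))
  f1[6:11] <- "N"                       # readable prefix of 5 diagnostic sites
  prof <- additivity_profile(f1, w$dtable)
  expect_equal(attr(prof, "n_readable"), 5L)
  expect_equal(attr(prof, "additivity_index"), 1.0)
  expect_equal(sum(prof$verdict == "unreadable"), 4L)
  # nothing readable: index undefined
  all_n <- rep("N", 11)
  expect_true(is.na(attr(additivity_profile(all_n, w$dtable),
                         "additivity_index")))
  expect_error(additivity_profile(rep("A", 3), w$dtable),
               class = "hybridID_schema_error")
})

test_that("haplotypes are assigned to the strictly nearer species cluster", {
  w <- cam_world()
  exact <- assign_haplotype(w$haps$sA1, w$pa, w$pb)
  expect_identical(exact$cluster, "B")
  expect_identical(exact$nearest_name, "sA1")
  expect_equal(exact$distance, 0L)

  novel <- w$haps$aA1
  novel[11] <- "C"                      # one private step off aA1
  near_a <- assign_haplotype(novel, w$pa, w$pb)
  expect_identical(near_a$cluster, "A")
  expect_identical(near_a$nearest_name, "aA1")
  expect_equal(near_a$distance, 1L)
  expect_false(near_a$exact)

  # equidistant between the clusters: unassigned
  p_a <- manual_panel(list(c("A", "A", "A", "A")), "a1", "species_A")
  p_b <- manual_panel(list(c("G", "G", "G", "G")), "b1", "species_B")
  tie <- assign_haplotype(c("A", "A", "G", "G"), p_a, p_b)
  expect_identical(tie$cluster, "unassigned")
})

test_that("combination labels put the species-A side first and use UN for novels", {
  w <- cam_world()
  pg <- phase_genotype(unname(mapply(iupac_union, w$haps$aA1, w$haps$sA2)),
                       w$panel)
  call <- locus_combination(pg, w$pa, w$pb)
  expect_identical(call$combination, "aA1/sA2")
  expect_identical(call$pattern, "AS")

  hom <- phase_genotype(w$haps$aA1, w$panel)
  call2 <- locus_combination(hom, w$pa, w$pb)
  expect_identical(call2$combination, "aA1/aA1")
  expect_identical(call2$pattern, "AA")

  # novel haplotype one step from the species-A core, paired with sA1
  novel <- w$haps$aA1
  novel[11] <- "C"
  pg3 <- tibble::tibble(sample_id = "x", hap1_name = "UN-1", hap2_name = "sA1",
                        method = "cloned", confidence = 1, tie = FALSE,
                        n_resolutions = 1L,
                        hap1 = list(novel), hap2 = list(w$haps$sA1))
  call3 <- locus_combination(pg3, w$pa, w$pb)
  expect_identical(call3$combination, "UN/sA1")
  expect_identical(call3$pattern, "AS")
})

test_that("generation posteriors follow the Mendelian closed forms", {
  calls <- tibble::tibble(sample_id = "x", pattern = c("AS", "AS", "AS"))
  cl <- classify_individual(calls)
  expect_equal(cl$post_F1, 1 / 1.375, tolerance = 1e-9)   # = 8/11
  expect_true(cl$f1_consistent)
  expect_equal(sum(dplyr::select(cl, dplyr::starts_with("post_"))), 1,
               tolerance = 1e-9)

  # all-homozygous-A: posterior 1 / (1 + (1/4)^3 + (1/2)^3) = 64/73
  cl2 <- classify_individual(tibble::tibble(sample_id = "x",
                                            pattern = c("AA", "AA", "AA")))
  expect_identical(cl2$top_class, "pure_A")
  expect_equal(cl2$post_pure_A, 64 / 73, tolerance = 1e-9)
  expect_false(cl2$f1_consistent)

  # one AA locus excludes F1; backcross to A beats F2
  cl3 <- classify_individual(tibble::tibble(sample_id = "x",
                                            pattern = c("AS", "AS", "AA")))
  expect_equal(cl3$post_F1, 0)
  expect_identical(cl3$top_class, "BC_A")
  expect_gt(cl3$post_BC_A, cl3$post_F2)

  # F1 posterior increases with the number of AS loci
  post_f1 <- vapply(1:4, function(k) {
    classify_individual(tibble::tibble(sample_id = "x",
                                       pattern = rep("AS", k)))$post_F1
  }, numeric(1))
  expect_true(all(diff(post_f1) > 0))

  expect_error(classify_individual(tibble::tibble(sample_id = "x",
                                                  pattern = "UNKNOWN")),
               class = "hybridID_classification_error")
})

test_that("chloroplast distance identifies the maternal species", {
  pair <- build_species_pair(sim_config(seed = 8))
  cp_a <- pair$cp$haps_a$seq[1]
  cp_b <- pair$cp$haps_b$seq[1]
  aln <- make_aln(c(pa = cp_a, pb = cp_b, hyb = cp_b),
                  taxon = c("species_A", "species_B", "hybrid"))
  cm <- recode_matrix(aln)
  p_a <- collapse_haplotypes(cm, "species_A", locus_letter = "P")
  p_b <- collapse_haplotypes(cm, "species_B", locus_letter = "P")
  m <- maternal_assignment(unname(cm$states["hyb", ]), p_a, p_b, "hyb")
  expect_identical(m$assigned, "species_B")
  expect_equal(m$distance_to_B, 0L)
  expect_equal(m$distance_to_A, 14L)    # 11 substitutions + 3 indel events

  m2 <- maternal_assignment(unname(cm$states["pa", ]), p_a, p_b)
  expect_identical(m2$assigned, "species_A")

  p1 <- manual_panel(list(c("A", "A", "A", "A")), "a1", "species_A")
  p2 <- manual_panel(list(c("G", "G", "G", "G")), "b1", "species_B")
  expect_identical(maternal_assignment(c("A", "A", "G", "G"), p1, p2)$assigned,
                   "ambiguous")
})

test_that("the direction test matches the exact binomial", {
  asn <- tibble::tibble(sample_id = paste0("h", 1:22), assigned = "species_B",
                        distance_to_A = 14L, distance_to_B = 0L)
  d <- direction_summary(asn)
  expect_equal(d$prop_B_maternal, 1)
  expect_equal(d$p_value, 2 * 0.5^22, tolerance = 1e-12)

  one <- direction_summary(asn[1, ])
  expect_equal(one$p_value, 1)

  half <- asn
  half$assigned[1:11] <- "species_A"
  expect_equal(direction_summary(half)$p_value, 1)
  expect_equal(direction_summary(half)$prop_B_maternal, 0.5)
})

test_that("germination rates carry Wilson intervals and Fisher comparisons", {
  g <- germination_summary(tibble::tibble(taxon = "t", germinated = 50,
                                          total = 100))
  expect_equal(g$rates$rate, 0.5)
  expect_equal(g$rates$conf_low, 0.404, tolerance = 1e-3)
  expect_equal(g$rates$conf_high, 0.596, tolerance = 1e-3)

  g0 <- germination_summary(tibble::tibble(taxon = "t", germinated = 0,
                                           total = 10))
  expect_equal(g0$rates$rate, 0)
  expect_equal(g0$rates$conf_low, 0)

  g2 <- germination_summary(tibble::tibble(
    taxon = c("species_A", "hybrid"),
    germinated = c(163L, 41L), total = c(204L, 202L)))
  expect_equal(g2$rates$rate, c(0.799, 0.203), tolerance = 1e-3)
  expect_lt(g2$tests$p_value, 1e-10)
  expect_equal(g2$tests$p_adjusted, g2$tests$p_value)  # single comparison

  expect_error(germination_summary(tibble::tibble(taxon = "t", germinated = 0,
                                                  total = 0)),
               class = "hybridID_data_error")
})
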