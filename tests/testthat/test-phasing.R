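one_char_schema <- tibble::tibble(char_id = "S0000", kind = "substitution",
                                  start = 0L, end = 1L, variable = TRUE)

make_genotypes <- function(state_vectors) {
  tibble::tibble(
    sample_id = paste0("g", seq_along(state_vectors)),
    taxon = "hybrid",
    states = state_vectors,
    n_het = vapply(state_vectors, function(s) sum(is_ambiguity_code(s)), integer(1))
  )
}

test_that("EM equals direct counting when phase is unambiguous", {
  # 50 A/A homozygotes + 50 A/G heterozygotes at a single site
  g <- make_genotypes(c(rep(list("A"), 50), rep(list("R"), 50)))
  fit <- em_haplotype_frequencies(g, one_char_schema)
  expect_equal(unname(fit$freqs["A"]), 0.75, tolerance = 1e-9)
  expect_equal(unname(fit$freqs["G"]), 0.25, tolerance = 1e-9)

  # identical homozygotes collapse to one haplotype immediately
  g2 <- make_genotypes(rep(list(c("A", "C")), 8))
  schema2 <- tibble::tibble(char_id = c("S0000", "S0001"), kind = "substitution",
                            start = 0:1, end = 1:2, variable = FALSE)
  fit2 <- em_haplotype_frequencies(g2, schema2)
  expect_equal(length(fit2$freqs), 1L)
  expect_equal(unname(fit2$freqs), 1)
  expect_equal(fit2$n_iter, 1L)
  expect_true(fit2$converged)
})

test_that("EM equals allele counting on multi-site phase-unambiguous data", {
  # haplotypes AA and AG differ at one site only, so every genotype has at
  # most one heterozygous site and phase is forced
  schema2 <- tibble::tibble(char_id = c("S0000", "S0001"), kind = "substitution",
                            start = 0:1, end = 1:2, variable = TRUE)
  set.seed(21)
  pool <- list(c("A", "A"), c("A", "G"))
  truth <- c(0.7, 0.3)
  draws <- replicate(120, sample(1:2, 2, replace = TRUE, prob = truth))
  gvec <- apply(draws, 2, function(p) {
    mapply(iupac_union, pool[[p[1]]], pool[[p[2]]])
  })
  g <- make_genotypes(lapply(seq_len(ncol(gvec)), function(j) unname(gvec[, j])))
  fit <- em_haplotype_frequencies(g, schema2)
  counted <- table(factor(draws, levels = 1:2)) / length(draws)
  expect_equal(unname(fit$freqs["AA"]), unname(counted[1]), tolerance = 1e-7)
  expect_equal(unname(fit$freqs["AG"]), unname(counted[2]), tolerance = 1e-7)
})

test_that("EM recovers simulation truth frequencies and increases likelihood", {
  schema2 <- tibble::tibble(char_id = c("S0000", "S0001"), kind = "substitution",
                            start = 0:1, end = 1:2, variable = TRUE)
  set.seed(31)
  pool <- list(c("A", "A"), c("A", "G"), c("G", "A"))
  truth <- c(0.6, 0.3, 0.1)
  draws <- replicate(500, sample(1:3, 2, replace = TRUE, prob = truth))
  g <- make_genotypes(lapply(seq_len(ncol(draws)), function(j) {
    unname(mapply(iupac_union, pool[[draws[1, j]]], pool[[draws[2, j]]]))
  }))
  fit <- em_haplotype_frequencies(g, schema2)
  expect_true(fit$converged)
  expect_true(all(diff(fit$trace) > -1e-9))          # monotone log-likelihood
  expect_equal(sum(fit$freqs), 1, tolerance = 1e-9)
  expect_lt(abs(fit$freqs[["AA"]] - 0.6), 0.05)
  expect_lt(abs(fit$freqs[["AG"]] - 0.3), 0.05)
  expect_lt(abs(fit$freqs[["GA"]] - 0.1), 0.05)
})

test_that("heterozygosity beyond the bound raises a complexity error", {
  states <- rep("R", 25)
  schema <- tibble::tibble(char_id = sprintf("S%04d", 0:24), kind = "substitution",
                           start = 0:24, end = 1:25, variable = TRUE)
  g <- make_genotypes(list(states))
  expect_error(em_haplotype_frequencies(g, schema),
               class = "hybridID_complexity_error")
})

test_that("phasing resolves hybrids to one named haplotype from each species", {
  w <- cam_world()
  gt <- unname(mapply(iupac_union, w$haps$aA1, w$haps$sA1))
  pg <- phase_genotype(gt, w$panel, sample_id = "hyb")
  expect_identical(sort(c(pg$hap1_name, pg$hap2_name)), c("aA1", "sA1"))
  expect_identical(pg$hap1_name, "aA1")     # species-A side listed first
  expect_false(pg$tie)

  # fully homozygous: unambiguous with confidence 1
  pg2 <- phase_genotype(w$haps$aA1, w$panel)
  expect_identical(pg2$method, "unambiguous")
  expect_equal(pg2$confidence, 1)
  expect_identical(pg2$hap1_name, "aA1")
  expect_identical(pg2$hap2_name, "aA1")

  # one heterozygous site: a single resolution up to order
  gt3 <- unname(mapply(iupac_union, w$haps$aA1, w$haps$aA2))
  pg3 <- phase_genotype(gt3, w$panel)
  expect_equal(pg3$n_resolutions, 1L)
  expect_equal(pg3$confidence, 1)
  expect_setequal(c(pg3$hap1_name, pg3$hap2_name), c("aA1", "aA2"))
})

test_that("phased pairs reproduce their genotype and round-trip through consensus", {
  w <- cam_world()
  hap_names <- names(w$haps)
  set.seed(13)
  for (i in 1:20) {
    pick <- sample(hap_names, 2, replace = TRUE)
    cons <- consensus_from_pair(w$haps[[pick[1]]], w$haps[[pick[2]]],
                                w$cm$characters)
    expect_true(is.na(cons$readable_prefix))
    pg <- phase_genotype(cons$states, w$panel)
    expect_setequal(c(pg$hap1_name, pg$hap2_name), unique(pick))
    # the resolved pair reproduces the genotype at every character
    rebuilt <- mapply(iupac_union, pg$hap1[[1]], pg$hap2[[1]])
    expect_identical(unname(rebuilt), cons$states)
  }
})

test_that("a heterozygous indel truncates the predicted consensus", {
  # 10 columns with a 3-bp event at [4,7); diagnostic substitutions at 1 and 8
  aln <- make_aln(c(a1 = "AAGTCCCTAA", b1 = "ATGT---TCA"),
                  taxon = c("species_A", "species_B"))
  cm <- recode_matrix(aln)
  a <- unname(cm$states["a1", ]); b <- unname(cm$states["b1", ])
  cons <- consensus_from_pair(a, b, cm$characters)
  expect_equal(cons$readable_prefix, 4L)
  keep <- cm$characters$start < 4L
  expect_identical(cons$states[!keep], rep("N", sum(!keep)))
  expect_identical(cons$states[cm$characters$char_id == "S0001"], "W")  # A/T
  # identical pair: consensus equals the haplotype, fully readable
  cons2 <- consensus_from_pair(a, a, cm$characters)
  expect_identical(cons2$states, a)
  expect_true(is.na(cons2$readable_prefix))
})
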