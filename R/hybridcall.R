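# Hybrid diagnosis: additivity scoring at diagnostic characters, per-locus
# haplotype-combination labelling, multilocus generation classification,
# chloroplast maternal-parent assignment, and spore-germination statistics.

HYBRID_CLASSES <- c("pure_A", "pure_B", "F1", "F2", "BC_A", "BC_B")

# Per-class probability of each per-locus cluster pattern under independent
# Mendelian loci: a locus pattern is AA (two species-A haplotypes),
# AS (one of each) or SS.
PATTERN_LIK <- rbind(
  pure_A = c(AA = 1,   AS = 0,   SS = 0),
  pure_B = c(AA = 0,   AS = 0,   SS = 1),
  F1     = c(AA = 0,   AS = 1,   SS = 0),
  F2     = c(AA = 1/4, AS = 1/2, SS = 1/4),
  BC_A   = c(AA = 1/2, AS = 1/2, SS = 0),
  BC_B   = c(AA = 0,   AS = 1/2, SS = 1/2)
)

#' Score chromatogram additivity at the diagnostic characters
#'
#' For each diagnostic character the consensus state is classified as
#' `additive` (equal to the IUPAC union of the two species alleles — both
#' parental bases superimposed), `allele_A_only`, `allele_B_only`, `other`,
#' or `unreadable` (`N`, e.g. beyond the readable prefix of a heterozygous
#' indel).  The additivity index is the fraction additive among readable
#' characters (`NA` when none is readable).
#'
#' @param states Consensus genotype state vector (or one-row genotype tibble
#'   from [genotypes_from_matrix()]).
#' @param dtable A `diagnostic_table` from [diagnostic_sites()].
#' @param sample_id Sample label for the output.
#' @return An `additivity_profile` tibble with one row per diagnostic
#'   character (`char_id`, `verdict`) and attributes summarised by
#'   [glance()]: `additivity_index`, `n_readable`.
#' @export
additivity_profile <- function(states, dtable, sample_id = "sample") {
  if (is.data.frame(states)) {
    sample_id <- states$sample_id[1]
    states <- states$states[[1]]
  }
  abort_if <- function(cond, msg) if (cond) abort(msg, class = "hybridID_schema_error")
  verdicts <- character(nrow(dtable))
  # states are full-schema vectors; the table carries each character's
  # position in that schema
  pos <- attr(dtable, "char_pos", exact = TRUE) %||%
    match(dtable$char_id, dtable$char_id)
  n_schema <- attr(dtable, "n_characters", exact = TRUE)
  abort_if(!is.null(n_schema) && length(states) != n_schema,
           "diagnostic table and genotype use different character schemas")
  for (r in seq_len(nrow(dtable))) {
    k <- pos[r]
    abort_if(is.na(k) || k > length(states),
             "diagnostic table and genotype use different character schemas")
    s <- states[k]
    aA <- dtable$allele_A[r]; aB <- dtable$allele_B[r]
    verdicts[r] <- if (s == "N") {
      "unreadable"
    } else if (dtable$kind[r] == "substitution" && s == iupac_union(aA, aB)) {
      "additive"
    } else if (s == aA) {
      "allele_A_only"
    } else if (s == aB) {
      "allele_B_only"
    } else {
      "other"
    }
  }
  readable <- verdicts != "unreadable"
  out <- tibble(sample_id = sample_id, char_id = dtable$char_id,
                kind = dtable$kind, verdict = verdicts)
  structure(out,
            additivity_index = if (any(readable)) mean(verdicts[readable] == "additive") else NA_real_,
            n_readable = sum(readable),
            class = c("additivity_profile", class(out)))
}

#' @export
glance.additivity_profile <- function(x, ...) {
  tibble(sample_id = x$sample_id[1],
         additivity_index = attr(x, "additivity_index", exact = TRUE),
         n_readable = attr(x, "n_readable", exact = TRUE),
         n_diagnostic = nrow(x))
}

#' @rdname additivity_profile
#' @details `additivity_index()` returns just the index.
#' @export
additivity_index <- function(states, dtable, sample_id = "sample") {
  attr(additivity_profile(states, dtable, sample_id), "additivity_index",
       exact = TRUE)
}

#' Assign a haplotype to a species cluster
#'
#' Exact panel matches take that haplotype's cluster at distance 0; otherwise
#' the nearest named haplotype (by [mutation_distance()]) wins, and an exact
#' tie between the two species' minima leaves the haplotype `unassigned`.
#'
#' @param h Haplotype state vector.
#' @param panel_a,panel_b The two species' `haplotype_panel`s.
#' @return A one-row tibble: `cluster` (`A`/`B`/`unassigned`),
#'   `nearest_name`, `distance`, `exact`.
#' @export
assign_haplotype <- function(h, panel_a, panel_b) {
  d_a <- vapply(panel_a$haplotypes$states, mutation_distance, integer(1), y = h)
  d_b <- vapply(panel_b$haplotypes$states, mutation_distance, integer(1), y = h)
  min_a <- min(d_a); min_b <- min(d_b)
  if (min_a < min_b) {
    i <- which.min(d_a)
    tibble(cluster = "A", nearest_name = panel_a$haplotypes$name[i],
           distance = min_a, exact = min_a == 0L)
  } else if (min_b < min_a) {
    i <- which.min(d_b)
    tibble(cluster = "B", nearest_name = panel_b$haplotypes$name[i],
           distance = min_b, exact = min_b == 0L)
  } else {
    tibble(cluster = "unassigned",
           nearest_name = NA_character_, distance = min_a, exact = FALSE)
  }
}

#' Label the haplotype combination of a phased genotype at one locus
#'
#' Each haplotype of the pair is assigned to a species cluster with
#' [assign_haplotype()]; exact panel matches keep their names, novel
#' haplotypes are labelled `UN` but count as their nearest cluster for the
#' pattern (a haplotype one step from a species-A haplotype is evidence of
#' species-A ancestry).  The combination label lists the species-A-side
#' haplotype first, e.g. `"aA1/sA1"` or `"UN/sB1"`.
#'
#' @param pg A one-row `phased_genotype` (from [phase_genotype()]).
#' @param panel_a,panel_b The two species' panels.
#' @return A one-row `locus_call` tibble: `sample_id`, `locus`,
#'   `combination`, `pattern` (`AA`, `AS`, `SS`, `AN`, `SN`, `NN`,
#'   `UNKNOWN`), plus per-haplotype assignment details.
#' @export
locus_combination <- function(pg, panel_a, panel_b) {
  a1 <- assign_haplotype(pg$hap1[[1]], panel_a, panel_b)
  a2 <- assign_haplotype(pg$hap2[[1]], panel_a, panel_b)
  lab <- function(asn) if (asn$exact) asn$nearest_name else "UN"
  cl <- c(a1$cluster, a2$cluster)
  labs <- c(lab(a1), lab(a2))
  # species-A side first; unassigned last
  ord <- order(match(cl, c("A", "B", "unassigned")))
  cl <- cl[ord]; labs <- labs[ord]
  pattern <- if (all(cl == "unassigned")) {
    "UNKNOWN"
  } else {
    paste0(c(A = "A", B = "S", unassigned = "N")[[cl[1]]],
           c(A = "A", B = "S", unassigned = "N")[[cl[2]]])
  }
  tibble(sample_id = pg$sample_id[1],
         locus = attr(pg, "locus", exact = TRUE) %||% NA_character_,
         combination = paste(labs, collapse = "/"),
         pattern = pattern,
         hap1_cluster = cl[1], hap2_cluster = cl[2],
         hap1_label = labs[1], hap2_label = labs[2],
         hap1_distance = c(a1$distance, a2$distance)[ord][1],
         hap2_distance = c(a1$distance, a2$distance)[ord][2])
}

#' Classify an individual's hybrid generation from its multilocus pattern
#'
#' Under independent Mendelian loci the per-locus cluster-pattern
#' probabilities are: pure A `{AA:1}`; pure B `{SS:1}`; F1 `{AS:1}`;
#' F2 `{AA:1/4, AS:1/2, SS:1/4}`; backcross to A `{AA:1/2, AS:1/2}`;
#' backcross to B `{SS:1/2, AS:1/2}`.  The multilocus likelihood is the
#' product over loci; posteriors are prior-weighted and normalised.  Loci
#' whose pattern is not `AA`/`AS`/`SS` carry no information under this model
#' and are dropped from the product.
#'
#' @param calls A `locus_call` tibble (one row per locus) for one individual.
#' @param priors Named prior over `pure_A`, `pure_B`, `F1`, `F2`, `BC_A`,
#'   `BC_B`; uniform by default.
#' @return A `hybrid_classification`: one-row tibble with `sample_id`,
#'   `n_loci_used`, `f1_consistent`, `top_class`, `top_posterior` and one
#'   `post_*` column per class.
#' @export
classify_individual <- function(calls, priors = NULL) {
  priors <- priors %||% setNames(rep(1 / 6, 6), HYBRID_CLASSES)
  priors <- priors[HYBRID_CLASSES] / sum(priors[HYBRID_CLASSES])
  usable <- calls$pattern %in% colnames(PATTERN_LIK)
  if (!any(usable)) {
    abort("no locus with an informative (AA/AS/SS) pattern",
          class = "hybridID_classification_error")
  }
  pat <- calls$pattern[usable]
  lik <- apply(PATTERN_LIK[, pat, drop = FALSE], 1, prod)
  post <- priors * lik
  if (sum(post) == 0) {
    abort("all classes have zero likelihood", class = "hybridID_classification_error")
  }
  post <- post / sum(post)
  out <- tibble(
    sample_id = calls$sample_id[1],
    n_loci_used = sum(usable),
    f1_consistent = all(calls$pattern == "AS"),
    top_class = HYBRID_CLASSES[which.max(post)],
    top_posterior = max(post)
  )
  for (cl in HYBRID_CLASSES) out[[paste0("post_", cl)]] <- unname(post[cl])
  structure(out, class = c("hybrid_classification", class(out)))
}

#' @export
tidy.hybrid_classification <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x), dplyr::starts_with("post_"),
                      names_to = "class", values_to = "posterior",
                      names_prefix = "post_")
}

#' Assign the maternal parent from a chloroplast sequence
#'
#' Chloroplast DNA is uniparentally (maternally) inherited in ferns, so a
#' hybrid's chloroplast haplotype identifies its maternal species.  Distance
#' is mutational steps on the recoded chloroplast characters (indel events
#' count 1); the closer species wins, an exact tie is `ambiguous`.
#'
#' @param cp Chloroplast state vector of one individual.
#' @param cp_panel_a,cp_panel_b Chloroplast panels of the two species.
#' @param sample_id Sample label.
#' @return A one-row tibble: `sample_id`, `assigned`, `distance_to_A`,
#'   `distance_to_B`.
#' @export
maternal_assignment <- function(cp, cp_panel_a, cp_panel_b,
                                sample_id = "sample") {
  d_a <- min(vapply(cp_panel_a$haplotypes$states, mutation_distance, integer(1), y = cp))
  d_b <- min(vapply(cp_panel_b$haplotypes$states, mutation_distance, integer(1), y = cp))
  tibble(sample_id = sample_id,
         assigned = if (d_a < d_b) "species_A" else if (d_b < d_a) "species_B" else "ambiguous",
         distance_to_A = d_a, distance_to_B = d_b)
}

#' Summarise the direction of hybridization
#'
#' Counts maternal assignments per species and tests the proportion of
#' species-B-maternal hybrids against 0.5 with an exact two-sided binomial
#' test (ambiguous assignments excluded).  The binomial test is an addition
#' of this package; the motivating study reported no test.
#'
#' @param assignments Tibble of [maternal_assignment()] rows.
#' @return A one-row tibble: `n`, `n_A`, `n_B`, `n_ambiguous`,
#'   `prop_B_maternal`, `p_value`.
#' @export
direction_summary <- function(assignments) {
  if (nrow(assignments) == 0) {
    abort("no assignments", class = "hybridID_usage_error")
  }
  n_a <- sum(assignments$assigned == "species_A")
  n_b <- sum(assignments$assigned == "species_B")
  n_amb <- sum(assignments$assigned == "ambiguous")
  n <- n_a + n_b
  p <- if (n > 0) binom.test(n_b, n, p = 0.5)$p.value else NA_real_
  tibble(n = nrow(assignments), n_A = n_a, n_B = n_b, n_ambiguous = n_amb,
         prop_B_maternal = if (n > 0) n_b / n else NA_real_,
         p_value = p)
}

# Wilson score interval for a binomial proportion.
wilson_interval <- function(x, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Compare spore germination rates between taxa
#'
#' Per-taxon germination rate with a 95% Wilson score interval, plus pairwise
#' Fisher exact tests with Holm correction (an addition of this package; the
#' motivating study reported rates only).
#'
#' @param records Data frame with columns `taxon`, `germinated`, `total`.
#' @return A list of two tibbles: `$rates` (taxon, germinated, total, rate,
#'   conf_low, conf_high) and `$tests` (taxon1, taxon2, odds_ratio, p_value,
#'   p_adjusted).
#' @export
germination_summary <- function(records) {
  records <- as_tibble(records)
  if (nrow(records) == 0 || any(records$total <= 0)) {
    abort("each germination record needs total > 0", class = "hybridID_data_error")
  }
  if (any(records$germinated < 0 | records$germinated > records$total)) {
    abort("germinated must lie in [0, total]", class = "hybridID_data_error")
  }
  ci <- t(mapply(wilson_interval, records$germinated, records$total))
  rates <- dplyr::mutate(records,
                         rate = .data$germinated / .data$total,
                         conf_low = unname(ci[, "lower"]),
                         conf_high = unname(ci[, "upper"]))
  tests <- NULL
  if (nrow(records) >= 2) {
    pairs <- utils::combn(nrow(records), 2)
    tests <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
      i1 <- pairs[1, j]; i2 <- pairs[2, j]
      m <- matrix(c(records$germinated[i1], records$total[i1] - records$germinated[i1],
                    records$germinated[i2], records$total[i2] - records$germinated[i2]),
                  nrow = 2, byrow = TRUE)
      ft <- fisher.test(m)
      tibble(taxon1 = records$taxon[i1], taxon2 = records$taxon[i2],
             odds_ratio = unname(ft$estimate), p_value = ft$p.value)
    })
    tests$p_adjusted <- p.adjust(tests$p_value, method = "holm")
  }
  list(rates = rates, tests = tests)
}
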