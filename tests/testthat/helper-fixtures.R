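`%||%` <- function(x, y) if (is.null(x)) y else x

# quick alignment builder
make_aln <- function(seqs, taxon = "species_A", role = "haplotype",
                     population = "P1", readable_prefix = NA_integer_,
                     locus = "loc") {
  n <- length(seqs)
  site_alignment(tibble::tibble(
    sample_id = names(seqs) %||% paste0("s", seq_len(n)),
    taxon = rep_len(taxon, n),
    population = rep_len(population, n),
    role = rep_len(role, n),
    readable_prefix = rep_len(readable_prefix, n),
    sequence = unname(seqs)
  ), locus = locus)
}

# gapless random alignment split into two species groups
random_species_aln <- function(n_a = 5, n_b = 5, n_col = 30, n_miss = 3) {
  bases <- c("A", "C", "G", "T")
  m <- matrix(sample(bases, (n_a + n_b) * n_col, replace = TRUE),
              nrow = n_a + n_b)
  # make a few columns fixed between groups so some diagnostics exist
  for (k in sample(n_col, 4)) {
    m[seq_len(n_a), k] <- sample(bases, 1)
    m[n_a + seq_len(n_b), k] <- sample(setdiff(bases, m[1, k]), 1)
  }
  if (n_miss > 0) m[sample(length(m), n_miss)] <- "N"
  seqs <- apply(m, 1, paste, collapse = "")
  make_aln(setNames(seqs, paste0(c(rep("a", n_a), rep("b", n_b)),
                                 seq_len(n_a + n_b))),
           taxon = c(rep("species_A", n_a), rep("species_B", n_b)))
}

# exhaustive per-character fixed-difference oracle on raw state matrices
brute_force_diagnostics <- function(states_a, states_b) {
  vapply(seq_len(ncol(states_a)), function(k) {
    a <- unique(states_a[, k][states_a[, k] != "N"])
    b <- unique(states_b[, k][states_b[, k] != "N"])
    length(a) == 1 && length(b) == 1 && a != b
  }, logical(1))
}

# ---- exhaustive Steiner-tree oracle (independent of the package) ----

oracle_dist <- function(x, y) sum(x != y)

oracle_mst <- function(d) {
  n <- nrow(d)
  if (n <= 1) return(0)
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  best <- d[1, ]
  total <- 0
  for (s in seq_len(n - 1)) {
    j <- which(!in_tree)[which.min(best[!in_tree])]
    total <- total + best[j]
    in_tree[j] <- TRUE
    best <- pmin(best, d[j, ])
  }
  total
}

# minimum cost of a tree connecting the terminals, allowing any state
# combination over the observed per-character alphabets as Steiner points
steiner_oracle <- function(states, max_steiner = 3) {
  n <- length(states)
  per_char <- lapply(seq_along(states[[1]]),
                     function(k) unique(vapply(states, `[`, character(1), k)))
  cand <- expand.grid(per_char, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  cand <- lapply(seq_len(nrow(cand)), function(i) as.character(cand[i, ]))
  obs_keys <- vapply(states, paste, character(1), collapse = "")
  cand <- cand[!(vapply(cand, paste, character(1), collapse = "") %in% obs_keys)]
  pts <- c(states, cand)
  np <- length(pts)
  D <- matrix(0, np, np)
  for (i in seq_len(np - 1)) {
    for (j in (i + 1):np) D[i, j] <- D[j, i] <- oracle_dist(pts[[i]], pts[[j]])
  }
  best <- oracle_mst(D[seq_len(n), seq_len(n), drop = FALSE])
  m <- length(cand)
  for (size in seq_len(min(max_steiner, m, max(0, n - 2)))) {
    for (comb in utils::combn(m, size, simplify = FALSE)) {
      idx <- c(seq_len(n), n + comb)
      best <- min(best, oracle_mst(D[idx, idx, drop = FALSE]))
    }
  }
  best
}

# manual haplotype panel over an explicit character schema
manual_panel <- function(states, names, species, locus = "loc") {
  nc <- length(states[[1]])
  chars <- tibble::tibble(char_id = sprintf("S%04d", seq_len(nc) - 1L),
                          kind = "substitution",
                          start = seq_len(nc) - 1L, end = seq_len(nc),
                          variable = TRUE)
  structure(list(
    locus = locus, species = species[1],
    haplotypes = tibble::tibble(name = names, species = species,
                                total = rep(1L, length(names)),
                                states = states),
    counts = tibble::tibble(name = names, population = "P1",
                            count = rep(1L, length(names))),
    characters = chars
  ), class = "haplotype_panel")
}

# A small two-species world at one locus, used across the phasing and
# hybrid-call tests.  11 columns: columns 0-8 fixed between the species
# (A vs G), column 9 a species-A private polymorphism (aA2 carries T),
# column 10 a species-B private polymorphism (sA2 carries C).
cam_world <- function(n_core_a = 3, n_core_b = 3) {
  aA1 <- paste0(strrep("A", 9), "A", "A")
  aA2 <- paste0(strrep("A", 9), "T", "A")
  sA1 <- paste0(strrep("G", 9), "A", "A")
  sA2 <- paste0(strrep("G", 9), "A", "C")
  seqs <- c(rep(aA1, n_core_a), aA2, rep(sA1, n_core_b), sA2)
  names(seqs) <- paste0("h", seq_along(seqs))
  taxa <- c(rep("species_A", n_core_a + 1), rep("species_B", n_core_b + 1))
  aln <- make_aln(seqs, taxon = taxa, locus = "cam")
  cm <- recode_matrix(aln)
  pa <- collapse_haplotypes(cm, "species_A", locus_letter = "A")
  pb <- collapse_haplotypes(cm, "species_B", locus_letter = "A")
  list(cm = cm, dtable = diagnostic_sites(cm), pa = pa, pb = pb,
       panel = combine_panels(pa, pb),
       haps = list(aA1 = strsplit(aA1, "")[[1]], aA2 = strsplit(aA2, "")[[1]],
                   sA1 = strsplit(sA1, "")[[1]], sA2 = strsplit(sA2, "")[[1]]))
}

# desk-scale study configuration for fast end-to-end tests
small_config <- function(seed = 1,
                         hybrids = tibble::tibble(population = "P1",
                                                  class = "F1", n = 4L),
                         ...) {
  sim_config(
    seed = seed,
    loci = list(
      locus_spec("locA", 80L, "A", n_sub = 5L, n_hap_a = 2L, n_hap_b = 2L),
      locus_spec("locB", 90L, "B", n_sub = 4L, indel_lengths = 4L,
                 n_hap_a = 2L, n_hap_b = 1L),
      locus_spec("locC", 70L, "C", n_sub = 3L, n_hap_a = 1L, n_hap_b = 2L)
    ),
    cp = list(length = 120L, n_sub = 6L, indel_lengths = c(3L, 4L)),
    pops_a = c(P1 = 6L, P2 = 6L), pops_b = c(P1 = 6L, P2 = 6L),
    hybrids = hybrids,
    ...
  )
}

# memoised paper-configuration pipeline run shared by pipeline and
# acceptance tests
.fixture_env <- new.env(parent = emptyenv())
paper_report <- function(seed = 101) {
  key <- paste0("report_", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- run_pipeline(sim_config(seed = seed))
  }
  .fixture_env[[key]]
}
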