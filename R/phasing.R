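# Resolution of diploid IUPAC genotypes into haplotype pairs.
#
# Direct sequencing of a diploid yields one consensus read per individual in
# which heterozygous sites appear as two-base IUPAC codes.  The package
# resolves these into haplotype pairs with an Excoffier-Slatkin-style EM over
# haplotype frequencies, followed by maximum-posterior resolution constrained
# to the named parental haplotype panel.  A genotype heterozygous at k
# characters has 2^(k-1) possible resolutions.

hap_key <- function(states) paste(states, collapse = "")

#' Extract diploid genotypes from a character matrix
#'
#' @param cm A `character_matrix`.
#' @param sample_ids Which samples; defaults to all `diploid_consensus` rows.
#' @return A tibble `sample_id`, `taxon`, `states` (list-column), `n_het`
#'   (heterozygous character count).
#' @export
genotypes_from_matrix <- function(cm, sample_ids = NULL) {
  ids <- sample_ids %||%
    cm$samples$sample_id[cm$samples$role == "diploid_consensus"]
  tibble(
    sample_id = ids,
    taxon = cm$samples$taxon[match(ids, cm$samples$sample_id)],
    states = lapply(ids, function(i) unname(cm$states[i, ])),
    n_het = vapply(ids, function(i) sum(cm$states[i, ] %in% names(AMBIG2)), integer(1))
  )
}

# Allowed states per character, used to expand N during resolution.  Pools the
# unambiguous and split-ambiguity states seen across genotypes, plus panel
# haplotype states when a panel is given.
allowed_states <- function(genotypes, characters, panel = NULL) {
  ncr <- nrow(characters)
  seen <- vector("list", ncr)
  add <- function(vecs) {
    for (v in vecs) {
      for (k in seq_len(ncr)) {
        s <- v[k]
        if (s == "N") next
        seen[[k]] <<- union(seen[[k]], if (s %in% names(AMBIG2)) iupac_split(s) else s)
      }
    }
  }
  add(genotypes$states)
  if (!is.null(panel)) add(panel$haplotypes$states)
  for (k in seq_len(ncr)) {
    if (length(seen[[k]]) == 0) {
      seen[[k]] <- if (characters$kind[k] == "indel") c("0", "1") else BASES
    }
  }
  seen
}

# All unordered haplotype-pair resolutions compatible with a genotype.
# Returns list(h1 = matrix, h2 = matrix) with one row per resolution.
enumerate_resolutions <- function(states, allowed, max_het = 20,
                                  max_resolutions = 2^20) {
  n_het <- sum(states %in% names(AMBIG2))
  if (n_het > max_het) {
    abort(sprintf("genotype heterozygous at %d characters (> %d): %s resolutions",
                  n_het, max_het, format(2^(n_het - 1), big.mark = ",")),
          class = "hybridID_complexity_error")
  }
  opts <- vector("list", length(states))
  for (k in seq_along(states)) {
    s <- states[k]
    opts[[k]] <- if (s %in% names(AMBIG2)) {
      ab <- iupac_split(s)
      list(c(ab[1], ab[2]), c(ab[2], ab[1]))
    } else if (s == "N") {
      a <- allowed[[k]]
      unlist(lapply(a, function(x) lapply(a, function(y) c(x, y))),
             recursive = FALSE)
    } else {
      list(c(s, s))
    }
  }
  total <- prod(vapply(opts, length, numeric(1)))
  if (total > max_resolutions) {
    abort(sprintf("genotype admits %g resolutions (> %g)", total, max_resolutions),
          class = "hybridID_complexity_error")
  }
  h1 <- matrix(states, nrow = 1)
  h2 <- matrix(states, nrow = 1)
  for (k in seq_along(opts)) {
    o <- opts[[k]]
    if (length(o) == 1) {
      h1[, k] <- o[[1]][1]; h2[, k] <- o[[1]][2]
      next
    }
    reps <- length(o)
    h1 <- h1[rep(seq_len(nrow(h1)), each = reps), , drop = FALSE]
    h2 <- h2[rep(seq_len(nrow(h2)), each = reps), , drop = FALSE]
    h1[, k] <- rep(vapply(o, `[`, character(1), 1), length.out = nrow(h1))
    h2[, k] <- rep(vapply(o, `[`, character(1), 2), length.out = nrow(h2))
  }
  # dedupe unordered pairs
  k1 <- apply(h1, 1, paste, collapse = "")
  k2 <- apply(h2, 1, paste, collapse = "")
  pair_key <- ifelse(k1 <= k2, paste(k1, k2), paste(k2, k1))
  keep <- !duplicated(pair_key)
  list(h1 = h1[keep, , drop = FALSE], h2 = h2[keep, , drop = FALSE],
       key1 = k1[keep], key2 = k2[keep])
}

#' Estimate haplotype frequencies by expectation-maximisation
#'
#' Excoffier-Slatkin-style EM over all haplotype-pair resolutions compatible
#' with each diploid genotype.  The log-likelihood is non-decreasing across
#' iterations; convergence is declared when the largest frequency change falls
#' below `tol`.
#'
#' @param genotypes A genotype tibble from [genotypes_from_matrix()].
#' @param characters Character schema tibble (needed to expand missing
#'   states); taken from `attr(genotypes, "characters")` or supplied.
#' @param panel Optional `haplotype_panel` whose haplotypes seed the state
#'   space for `N` expansion.
#' @param tol Convergence threshold on max |change in frequency|.
#' @param max_iter Iteration cap.
#' @param max_het Per-genotype heterozygosity bound (resolution count grows as
#'   `2^(k-1)`).
#' @return An `em_haplotypes` object with `$freqs` (named, sums to 1),
#'   `$loglik`, `$n_iter`, `$converged`, `$trace` (per-iteration
#'   log-likelihood), and `$haplotypes` tibble.
#' @export
em_haplotype_frequencies <- function(genotypes, characters, panel = NULL,
                                     tol = 1e-8, max_iter = 10000,
                                     max_het = 20) {
  if (nrow(genotypes) == 0) {
    abort("no genotypes", class = "hybridID_usage_error")
  }
  allowed <- allowed_states(genotypes, characters, panel)
  res <- lapply(genotypes$states, enumerate_resolutions,
                allowed = allowed, max_het = max_het)
  keys <- unique(unlist(lapply(res, function(r) c(r$key1, r$key2))))
  H <- length(keys)
  # flat resolution table: haplotype indices, genotype index, pair multiplicity
  i1 <- unlist(lapply(res, function(r) match(r$key1, keys)))
  i2 <- unlist(lapply(res, function(r) match(r$key2, keys)))
  gi <- rep(seq_along(res), vapply(res, function(r) length(r$key1), integer(1)))
  mult <- ifelse(i1 == i2, 1, 2)
  f <- rep(1 / H, H)
  n <- nrow(genotypes)
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  loglik_of <- function(f) {
    w <- f[i1] * f[i2] * mult
    tw <- as.numeric(rowsum(w, gi))
    list(w = w, tw = tw, ll = sum(log(pmax(tw, .Machine$double.xmin))))
  }
  while (it < max_iter) {
    it <- it + 1L
    e <- loglik_of(f)
    tw_g <- e$tw[gi]
    pw <- ifelse(tw_g > 0, e$w / tw_g, 1 / tabulate(gi)[gi])
    counts <- as.numeric(rowsum(c(pw, pw), factor(c(i1, i2), levels = seq_len(H))))
    f_new <- counts / (2 * n)
    trace <- c(trace, e$ll)
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol) { converged <- TRUE; break }
  }
  ll <- loglik_of(f)$ll
  trace <- c(trace, ll)
  loglik <- ll
  structure(
    list(freqs = setNames(f, keys), loglik = ll, n_iter = it,
         converged = converged, trace = trace,
         haplotypes = tibble(key = keys, freq = f)),
    class = "em_haplotypes"
  )
}

#' @export
print.em_haplotypes <- function(x, ...) {
  cat(sprintf("<em_haplotypes> %d haplotypes, logLik %.4f after %d iteration(s)%s\n",
              length(x$freqs), x$loglik, x$n_iter,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' @export
tidy.em_haplotypes <- function(x, ...) {
  dplyr::arrange(x$haplotypes, dplyr::desc(.data$freq))
}

#' @export
glance.em_haplotypes <- function(x, ...) {
  tibble(n_haplotypes = length(x$freqs), logLik = x$loglik,
         n_iter = x$n_iter, converged = x$converged)
}

#' Phase one diploid genotype against a haplotype panel
#'
#' Chooses, among all haplotype pairs compatible with the genotype, the one
#' with maximum posterior probability (product of haplotype frequencies,
#' doubled for heterokaryotypic pairs).  Ties are broken in favour of pairs
#' naming two panel haplotypes, then by frequency product, then
#' lexicographically.  Haplotypes absent from the panel are labelled
#' `UN-1`, `UN-2`, ... and reported as novel.
#'
#' @param states Genotype state vector (or a one-row genotype tibble).
#' @param panel Combined species panel (see [combine_panels()]).
#' @param freqs Named frequency vector from [em_haplotype_frequencies()];
#'   `NULL` for panel-only resolution.
#' @param sample_id Sample label carried into the output.
#' @param max_het Heterozygosity bound, as in [em_haplotype_frequencies()].
#' @return A one-row `phased_genotype` tibble: `sample_id`, `hap1_name`,
#'   `hap2_name`, `method` (`unambiguous`/`panel`/`em`), `confidence`, `tie`,
#'   `n_resolutions`, plus `hap1`/`hap2` state list-columns.
#' @export
phase_genotype <- function(states, panel, freqs = NULL, sample_id = "sample",
                           max_het = 20) {
  if (is.data.frame(states)) {
    sample_id <- states$sample_id[1]
    states <- states$states[[1]]
  }
  allowed <- allowed_states(tibble(states = list(states)), panel$characters, panel)
  res <- enumerate_resolutions(states, allowed, max_het = max_het)
  nres <- nrow(res$h1)
  if (nres == 0) {
    abort("no compatible resolution", class = "hybridID_data_error")
  }
  panel_keys <- vapply(panel$haplotypes$states, hap_key, character(1))
  n_panel <- (res$key1 %in% panel_keys) + (res$key2 %in% panel_keys)
  if (!is.null(freqs)) {
    g1 <- unname(freqs[res$key1]); g1[is.na(g1)] <- 0
    g2 <- unname(freqs[res$key2]); g2[is.na(g2)] <- 0
    w <- g1 * g2 * ifelse(res$key1 == res$key2, 1, 2)
  } else {
    w <- rep(1, nres)
  }
  if (sum(w) == 0) w <- rep(1, nres)       # all-zero EM support: fall back
  post <- w / sum(w)
  lex <- ifelse(res$key1 <= res$key2, paste(res$key1, res$key2),
                paste(res$key2, res$key1))
  ord <- order(-n_panel, -post, lex)
  best <- ord[1]
  # tie: another resolution with identical panel support and posterior
  tie <- nres > 1 &&
    any(n_panel[ord[-1]] == n_panel[best] & abs(post[ord[-1]] - post[best]) < 1e-12)
  h1 <- res$h1[best, ]; h2 <- res$h2[best, ]
  nm1 <- panel$haplotypes$name[match(res$key1[best], panel_keys)]
  nm2 <- panel$haplotypes$name[match(res$key2[best], panel_keys)]
  novel_i <- 0L
  if (is.na(nm1)) { novel_i <- novel_i + 1L; nm1 <- paste0("UN-", novel_i) }
  if (is.na(nm2)) { novel_i <- novel_i + 1L; nm2 <- paste0("UN-", novel_i) }
  # species_A haplotype listed first where determinable
  sp <- panel$haplotypes$species[match(c(nm1, nm2), panel$haplotypes$name)]
  if (!is.na(sp[2]) && sp[2] == "species_A" && (is.na(sp[1]) || sp[1] != "species_A")) {
    tmp <- h1; h1 <- h2; h2 <- tmp
    tmn <- nm1; nm1 <- nm2; nm2 <- tmn
  }
  method <- if (nres == 1) "unambiguous" else if (!is.null(freqs)) "em" else "panel"
  out <- tibble(
    sample_id = sample_id, hap1_name = nm1, hap2_name = nm2,
    method = method, confidence = post[best], tie = tie,
    n_resolutions = nres, hap1 = list(unname(h1)), hap2 = list(unname(h2))
  )
  structure(out, class = c("phased_genotype", class(out)))
}

#' Phase every diploid consensus genotype at a locus
#'
#' Convenience wrapper: runs [em_haplotype_frequencies()] over the pooled
#' consensus genotypes (parental and hybrid alike), then resolves each with
#' [phase_genotype()] against the combined panel.
#'
#' @param cm A `character_matrix`.
#' @param panel Combined species `haplotype_panel`.
#' @param use_em Estimate frequencies by EM first (default) or phase against
#'   the panel alone.
#' @inheritParams phase_genotype
#' @return A `phased_genotype` tibble with one row per consensus genotype.
#' @export
phase_genotypes <- function(cm, panel, use_em = TRUE, max_het = 20) {
  g <- genotypes_from_matrix(cm)
  if (nrow(g) == 0) {
    return(tibble(sample_id = character(), hap1_name = character(),
                  hap2_name = character(), method = character(),
                  confidence = numeric(), tie = logical(),
                  n_resolutions = integer(), hap1 = list(), hap2 = list()))
  }
  freqs <- NULL
  if (use_em) {
    freqs <- em_haplotype_frequencies(g, cm$characters, panel = panel,
                                      max_het = max_het)$freqs
  }
  purrr::map_dfr(seq_len(nrow(g)), function(i) {
    phase_genotype(g$states[[i]], panel, freqs = freqs,
                   sample_id = g$sample_id[i], max_het = max_het)
  })
}

#' Predict the direct-sequencing consensus of a haplotype pair
#'
#' Substitution characters combine by [iupac_union()].  If the pair differs at
#' any indel character the trace is readable only up to the first differing
#' indel event: `readable_prefix` is set to that event's start column and all
#' characters from there on are `N` (intra-individual length polymorphism
#' causes direct sequencing to fail downstream of the frame shift).
#'
#' @param h1,h2 Haplotype state vectors over the same character schema.
#' @param characters Character schema tibble (with `kind`, `start`, `end`).
#' @return A list: `states` (consensus state vector) and `readable_prefix`
#'   (`NA` when the full length is readable).
#' @export
consensus_from_pair <- function(h1, h2, characters) {
  if (length(h1) != length(h2) || length(h1) != nrow(characters)) {
    abort("haplotypes and schema disagree in length", class = "hybridID_schema_error")
  }
  states <- character(length(h1))
  for (k in seq_along(h1)) {
    a <- h1[k]; b <- h2[k]
    states[k] <- if (a == "N" || b == "N") {
      "N"
    } else if (characters$kind[k] == "indel") {
      if (a == b) a else "het"            # placeholder, truncated below
    } else {
      iupac_union(a, b)
    }
  }
  rp <- NA_integer_
  het_indel <- which(states == "het")
  if (length(het_indel) > 0) {
    rp <- min(characters$start[het_indel])
    states[characters$start >= rp | characters$end > rp] <- "N"
  }
  list(states = states, readable_prefix = rp)
}
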