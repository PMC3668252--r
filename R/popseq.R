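# Indel-event recoding, fixed-difference (diagnostic) site calling, haplotype
# collapsing and polymorphism summaries.
#
# Alignments are recoded into a character matrix before any comparison: each
# contiguous insertion/deletion event becomes ONE binary character regardless
# of its length in base pairs (an indel is a single mutational step), and the
# remaining columns become substitution characters.

#' Detect indel events in an alignment
#'
#' Scans the haplotype-role rows for maximal runs of gap-containing columns
#' that share an identical per-sample presence pattern; each run is one indel
#' event.  Consensus rows are ignored (a heterozygous indel is not directly
#' observable in a direct-sequencing trace).
#'
#' @param aln A [site_alignment()].
#' @return A tibble with one row per event: `event_id`, `start`, `end`
#'   (0-based, half-open), `length`, and `presence` (named logical list-column:
#'   which haplotype rows carry bases in the interval), sorted by `start`.
#' @export
detect_indel_events <- function(aln) {
  hap <- aln[aln$role == "haplotype", , drop = FALSE]
  if (nrow(hap) == 0) {
    return(tibble(event_id = character(), start = integer(), end = integer(),
                  length = integer(), presence = list()))
  }
  m <- aln_matrix(hap)
  all_gap <- which(colSums(m == "-") == nrow(m))
  if (length(all_gap) > 0) {
    abort(sprintf("column(s) %s are gaps in every haplotype row (uninformative)",
                  paste(all_gap - 1L, collapse = ", ")),
          class = "hybridID_alignment_error")
  }
  gap_cols <- which(colSums(m == "-") > 0)
  if (length(gap_cols) == 0) {
    return(tibble(event_id = character(), start = integer(), end = integer(),
                  length = integer(), presence = list()))
  }
  pat <- apply(m[, gap_cols, drop = FALSE] != "-", 2, paste, collapse = "")
  # maximal runs of adjacent gap columns with identical presence pattern
  new_event <- c(TRUE, diff(gap_cols) != 1L | pat[-1] != pat[-length(pat)])
  grp <- cumsum(new_event)
  events <- lapply(split(seq_along(gap_cols), grp), function(idx) {
    cols <- gap_cols[idx]
    start <- cols[1] - 1L                      # 0-based
    end <- cols[length(cols)]                  # half-open
    presence <- m[, cols[1]] != "-"
    list(start = start, end = end, presence = presence)
  })
  tibble(
    event_id = unname(vapply(events, function(e) sprintf("I%04d_%04d", e$start, e$end), character(1))),
    start = unname(vapply(events, function(e) e$start, integer(1))),
    end = unname(vapply(events, function(e) e$end, integer(1))),
    length = unname(vapply(events, function(e) e$end - e$start, integer(1))),
    presence = unname(lapply(events, function(e) e$presence))
  ) |> dplyr::arrange(.data$start)
}

#' Recode an alignment into a character matrix
#'
#' Columns inside indel events are replaced by one binary character per event
#' (`"1"` = bases present, `"0"` = deleted); all other columns become
#' substitution characters.  Invariant columns are retained but flagged
#' (`variable = FALSE`).  Diploid-consensus rows keep their IUPAC states at
#' substitution characters; characters at or beyond a row's `readable_prefix`
#' are set to `N` (a heterozygous indel makes the downstream trace unreadable,
#' so `het` is not a legal indel state).
#'
#' @param aln A [site_alignment()].
#' @param events Indel events from [detect_indel_events()] on the same
#'   alignment; detected automatically when `NULL`.
#' @return A `character_matrix` object: `$characters` (schema tibble with
#'   `char_id`, `kind`, `start`, `end`, `variable`), `$states` (samples x
#'   characters character matrix), `$samples` (metadata tibble).
#' @export
recode_matrix <- function(aln, events = NULL) {
  if (is.null(events)) events <- detect_indel_events(aln)
  if (nrow(events) > 1) {
    o <- order(events$start)
    if (any(events$start[o][-1] < events$end[o][-nrow(events)])) {
      abort("overlapping indel events", class = "hybridID_internal_error")
    }
  }
  m <- aln_matrix(aln)
  nc <- ncol(m)
  in_event <- rep(FALSE, nc)
  for (i in seq_len(nrow(events))) {
    in_event[(events$start[i] + 1L):events$end[i]] <- TRUE
  }
  sub_cols <- which(!in_event)            # 1-based
  chars <- tibble(
    char_id = c(sprintf("S%04d", sub_cols - 1L), events$event_id),
    kind = c(rep("substitution", length(sub_cols)), rep("indel", nrow(events))),
    start = c(sub_cols - 1L, events$start),
    end = c(sub_cols, events$end)
  ) |> dplyr::arrange(.data$start)

  states <- matrix("N", nrow = nrow(aln), ncol = nrow(chars),
                   dimnames = list(aln$sample_id, chars$char_id))
  for (k in seq_len(nrow(chars))) {
    if (chars$kind[k] == "substitution") {
      s <- m[, chars$start[k] + 1L]
      s[s == "-"] <- "N"                  # stray gap outside any event
      states[, k] <- s
    } else {
      block <- m[, (chars$start[k] + 1L):chars$end[k], drop = FALSE]
      gaps <- rowSums(block == "-")
      ns <- rowSums(block == "N")
      st <- rep("N", nrow(block))
      st[gaps == ncol(block)] <- "0"
      st[gaps == 0 & ns == 0] <- "1"
      states[, k] <- st
    }
  }
  # truncate consensus rows at their readable prefix
  rp <- aln$readable_prefix
  for (i in which(aln$role == "diploid_consensus" & !is.na(rp))) {
    states[i, chars$start >= rp[i] | chars$end > rp[i]] <- "N"
  }
  hap_states <- states[aln$role == "haplotype", , drop = FALSE]
  variable <- apply(hap_states, 2, function(s) {
    length(unique(s[s != "N"])) > 1
  })
  chars$variable <- if (nrow(hap_states) > 0) unname(variable) else FALSE

  structure(
    list(locus = aln_locus(aln), characters = chars, states = states,
         samples = as_tibble(aln)[, c("sample_id", "taxon", "population",
                                      "role", "readable_prefix")]),
    class = "character_matrix"
  )
}

#' @export
print.character_matrix <- function(x, ...) {
  cat(sprintf("<character_matrix> locus %s: %d samples x %d characters (%d substitution, %d indel)\n",
              x$locus, nrow(x$states), nrow(x$characters),
              sum(x$characters$kind == "substitution"),
              sum(x$characters$kind == "indel")))
  invisible(x)
}

#' @export
tidy.character_matrix <- function(x, ...) {
  long <- as_tibble(x$states, rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "char_id", values_to = "state")
  dplyr::left_join(long, x$characters, by = "char_id") |>
    dplyr::left_join(x$samples, by = "sample_id")
}

# sample_ids of haplotype-role rows of one taxon
hap_ids <- function(cm, taxon) {
  cm$samples$sample_id[cm$samples$role == "haplotype" & cm$samples$taxon == taxon]
}

#' Call diagnostic (fixed-difference) characters between two species
#'
#' A character is diagnostic when every non-missing state within group A is
#' identical, every non-missing state within group B is identical, and the two
#' states differ.  Missing states (`N`) are ignored but flagged; a character
#' at which a group is entirely missing is skipped with a warning.  Only
#' haplotype-role rows define species alleles — diploid consensus rows never
#' contribute.
#'
#' @param cm A `character_matrix` from [recode_matrix()].
#' @param group_a,group_b Sample ids of the two species' haplotype rows;
#'   default to all haplotype rows with taxon `species_A` / `species_B`.
#' @return A `diagnostic_table` tibble: `char_id`, `kind`, `allele_A`,
#'   `allele_B`, `had_missing`, sorted by alignment position.
#' @export
diagnostic_sites <- function(cm, group_a = NULL, group_b = NULL) {
  group_a <- group_a %||% hap_ids(cm, "species_A")
  group_b <- group_b %||% hap_ids(cm, "species_B")
  hap_all <- cm$samples$sample_id[cm$samples$role == "haplotype"]
  group_a <- intersect(group_a, hap_all)
  group_b <- intersect(group_b, hap_all)
  if (length(group_a) == 0 || length(group_b) == 0) {
    abort("both groups need at least one haplotype-role row",
          class = "hybridID_usage_error")
  }
  sa <- cm$states[group_a, , drop = FALSE]
  sb <- cm$states[group_b, , drop = FALSE]
  rows <- lapply(seq_len(nrow(cm$characters)), function(k) {
    a <- sa[, k]; b <- sb[, k]
    a_obs <- unique(a[a != "N"]); b_obs <- unique(b[b != "N"])
    if (length(a_obs) == 0 || length(b_obs) == 0) return("skip")
    if (length(a_obs) == 1 && length(b_obs) == 1 && a_obs != b_obs) {
      tibble(char_id = cm$characters$char_id[k], kind = cm$characters$kind[k],
             allele_A = a_obs, allele_B = b_obs,
             had_missing = any(a == "N") || any(b == "N"))
    } else NULL
  })
  skipped <- cm$characters$char_id[vapply(rows, identical, logical(1), "skip")]
  if (length(skipped) > 0) {
    warn(sprintf("character(s) %s skipped: a group is entirely missing there",
                 paste(skipped, collapse = ", ")))
  }
  out <- dplyr::bind_rows(rows[!vapply(rows, function(r) is.null(r) || identical(r, "skip"), logical(1))])
  if (nrow(out) == 0) {
    out <- tibble(char_id = character(), kind = character(),
                  allele_A = character(), allele_B = character(),
                  had_missing = logical())
  }
  structure(out, locus = cm$locus,
            char_pos = match(out$char_id, cm$characters$char_id),
            n_characters = nrow(cm$characters),
            class = c("diagnostic_table", class(out)))
}

#' Collapse haplotype rows of one taxon into a named haplotype panel
#'
#' Identical state vectors are merged; haplotypes are named
#' `<species-prefix><locus_letter><rank>` (e.g. `aA1`, `sB2`) by descending
#' total count, ties broken by first occurrence, unless explicit `hap_names`
#' are supplied.  Per-population counts are tallied.
#'
#' @param cm A `character_matrix`.
#' @param taxon Which taxon's haplotype rows to collapse (`species_A`,
#'   `species_B`, or `hybrid`).
#' @param locus_letter Single letter identifying the locus in haplotype names
#'   (the three nuclear genes of the motivating study are `A`, `B`, `C`).
#' @param hap_names Optional character vector of names, one per distinct
#'   haplotype in rank order.
#' @return A `haplotype_panel`: `$haplotypes` tibble (`name`, `species`,
#'   `total`, `states` list-column), `$counts` tibble (`name`, `population`,
#'   `count`), `$characters` schema.
#' @export
collapse_haplotypes <- function(cm, taxon, locus_letter = "A", hap_names = NULL) {
  ids <- hap_ids(cm, taxon)
  if (length(ids) == 0) {
    abort(sprintf("no haplotype-role rows for taxon %s", taxon),
          class = "hybridID_usage_error")
  }
  st <- cm$states[ids, , drop = FALSE]
  if (any(st %in% names(AMBIG2))) {
    abort("haplotype rows may not contain ambiguity codes",
          class = "hybridID_role_error")
  }
  key <- apply(st, 1, paste, collapse = "")
  first_seen <- match(unique(key), key)
  tab <- tibble(key = key,
                population = cm$samples$population[match(ids, cm$samples$sample_id)])
  totals <- dplyr::count(tab, .data$key, name = "total")
  totals$first <- match(totals$key, key)
  totals <- dplyr::arrange(totals, dplyr::desc(.data$total), .data$first)
  prefix <- c(species_A = "a", species_B = "s", hybrid = "h", unknown = "u")[[taxon]]
  nm <- hap_names %||% paste0(prefix, locus_letter, seq_len(nrow(totals)))
  if (length(nm) != nrow(totals)) {
    abort("hap_names length must equal the number of distinct haplotypes",
          class = "hybridID_usage_error")
  }
  totals$name <- nm
  counts <- dplyr::count(tab, .data$key, .data$population, name = "count")
  counts$name <- totals$name[match(counts$key, totals$key)]
  structure(
    list(locus = cm$locus, species = taxon,
         haplotypes = tibble(
           name = totals$name, species = taxon, total = totals$total,
           states = lapply(totals$first, function(i) unname(st[i, ]))
         ),
         counts = counts[order(match(counts$name, totals$name), counts$population),
                         c("name", "population", "count")],
         characters = cm$characters),
    class = "haplotype_panel"
  )
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("<haplotype_panel> locus %s, %s: %d haplotypes, %d sequences\n",
              x$locus, paste(unique(x$haplotypes$species), collapse = "+"),
              nrow(x$haplotypes), sum(x$haplotypes$total)))
  invisible(x)
}

#' @export
tidy.haplotype_panel <- function(x, ...) {
  dplyr::left_join(x$counts,
                   x$haplotypes[, c("name", "species", "total")],
                   by = "name") |>
    dplyr::mutate(locus = x$locus, .before = 1)
}

#' Merge the panels of the two species at one locus
#' @param a,b `haplotype_panel` objects sharing a character schema.
#' @return A combined `haplotype_panel`.
#' @export
combine_panels <- function(a, b) {
  if (!identical(a$characters$char_id, b$characters$char_id)) {
    abort("panels have different character schemas", class = "hybridID_schema_error")
  }
  structure(
    list(locus = a$locus, species = "both",
         haplotypes = dplyr::bind_rows(a$haplotypes, b$haplotypes),
         counts = dplyr::bind_rows(a$counts, b$counts),
         characters = a$characters),
    class = "haplotype_panel"
  )
}

#' Per-population polymorphism summary of a haplotype panel
#'
#' @param panel A `haplotype_panel`.
#' @return A tibble with one row per population plus a `TOTAL` row per
#'   species: sample count `n`, `n_haplotypes`, `n_segregating` characters
#'   (characters with more than one state among the haplotypes present).
#' @export
polymorphism_summary <- function(panel) {
  if (nrow(panel$haplotypes) == 0) {
    abort("empty panel", class = "hybridID_usage_error")
  }
  seg_among <- function(hnames) {
    sts <- panel$haplotypes$states[match(hnames, panel$haplotypes$name)]
    if (length(sts) < 2) return(0L)
    m <- do.call(rbind, sts)
    sum(apply(m, 2, function(s) length(unique(s[s != "N"])) > 1))
  }
  pops <- split(panel$counts, panel$counts$population)
  per_pop <- purrr::map2_dfr(pops, names(pops), function(d, p) {
    present <- d$name[d$count > 0]
    tibble(population = p, n = sum(d$count),
           n_haplotypes = length(present),
           n_segregating = seg_among(present))
  })
  total <- tibble(population = "TOTAL", n = sum(panel$haplotypes$total),
                  n_haplotypes = nrow(panel$haplotypes),
                  n_segregating = seg_among(panel$haplotypes$name))
  dplyr::bind_rows(per_pop, total)
}

#' Haplotype frequencies by population
#' @param panel A `haplotype_panel`.
#' @return A tibble `name`, `population`, `count`, `freq`.
#' @export
haplotype_frequencies <- function(panel) {
  panel$counts |>
    dplyr::group_by(.data$population) |>
    dplyr::mutate(freq = .data$count / sum(.data$count)) |>
    dplyr::ungroup()
}
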