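# Alignment input/output.
#
# A site alignment is a tibble with one row per sequence (class
# "site_alignment"): sample metadata columns plus the aligned sequence string,
# and the locus name stored as an attribute.  Columns are 0-based and
# intervals half-open [start, end) throughout the package.

TAXA <- c("species_A", "species_B", "hybrid", "unknown")
ROLES <- c("haplotype", "diploid_consensus")

#' Construct a site alignment from a metadata tibble
#'
#' @param samples A data frame with columns `sample_id`, `taxon` (one of
#'   `species_A`, `species_B`, `hybrid`, `unknown`), `population`, `role`
#'   (`haplotype` or `diploid_consensus`), optional `readable_prefix`
#'   (number of columns readable before a heterozygous-indel frame shift),
#'   and `sequence` (aligned, gapped).
#' @param locus Locus name.
#' @return A `site_alignment` tibble.
#' @export
site_alignment <- function(samples, locus = "locus") {
  samples <- as_tibble(samples)
  required <- c("sample_id", "taxon", "population", "role", "sequence")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols) > 0) {
    abort(paste0("sample table lacks column(s): ", paste(missing_cols, collapse = ", ")),
          class = "hybridID_metadata_error")
  }
  if (!"readable_prefix" %in% names(samples)) samples$readable_prefix <- NA_integer_
  samples$readable_prefix <- as.integer(samples$readable_prefix)
  samples$sequence <- toupper(gsub("U", "T", toupper(samples$sequence), fixed = TRUE))

  if (nrow(samples) == 0 || any(!nzchar(samples$sequence))) {
    abort("alignment must contain at least one non-empty sequence",
          class = "hybridID_alignment_error")
  }
  widths <- nchar(samples$sequence)
  if (length(unique(widths)) != 1L) {
    abort(sprintf("ragged alignment: sequence lengths %s",
                  paste(sort(unique(widths)), collapse = ", ")),
          class = "hybridID_alignment_error")
  }
  if (anyDuplicated(samples$sample_id)) {
    abort("duplicated sample_id within locus", class = "hybridID_metadata_error")
  }
  bad_taxon <- setdiff(unique(samples$taxon), TAXA)
  if (length(bad_taxon) > 0) {
    abort(sprintf("unknown taxon label(s) %s (map user labels via taxon_map)",
                  paste(sQuote(bad_taxon), collapse = ", ")),
          class = "hybridID_metadata_error")
  }
  bad_role <- setdiff(unique(samples$role), ROLES)
  if (length(bad_role) > 0) {
    abort(sprintf("unknown role(s) %s", paste(sQuote(bad_role), collapse = ", ")),
          class = "hybridID_metadata_error")
  }
  for (i in seq_len(nrow(samples))) {
    check_alphabet(
      strsplit(samples$sequence[i], "", fixed = TRUE)[[1]],
      allow_ambiguity = samples$role[i] == "diploid_consensus",
      context = samples$sample_id[i]
    )
  }
  ncol <- widths[1]
  rp <- samples$readable_prefix
  if (any(!is.na(rp) & (rp < 0L | rp > ncol))) {
    abort("readable_prefix outside [0, columns]", class = "hybridID_metadata_error")
  }
  structure(samples, locus = locus,
            class = c("site_alignment", class(samples)))
}

#' @export
print.site_alignment <- function(x, ...) {
  cat(sprintf("<site_alignment> locus %s: %d sequences x %d columns\n",
              aln_locus(x), nrow(x), aln_ncol(x)))
  NextMethod()
}

#' Locus name and column count of a site alignment
#' @param aln A `site_alignment`.
#' @export
aln_locus <- function(aln) attr(aln, "locus", exact = TRUE) %||% "locus"

#' @rdname aln_locus
#' @export
aln_ncol <- function(aln) nchar(aln$sequence[1])

# alignment as a character matrix (rows = samples, 0-based column names)
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$sequence, "", fixed = TRUE))
  rownames(m) <- aln$sample_id
  m
}

#' Read an aligned FASTA plus its sample sheet
#'
#' The sample sheet is a TSV with columns `sample_id`, `taxon`, `population`,
#' `role` and optionally `readable_prefix`.  Raw taxon labels (e.g. species
#' binomials) are mapped to the internal labels `species_A` / `species_B` /
#' `hybrid` via `taxon_map`.
#'
#' @param path Path to a gapped FASTA file in which all records have equal
#'   length (a multiple sequence alignment).
#' @param sample_sheet Path to the sample sheet TSV.
#' @param taxon_map Optional named character vector mapping sheet taxon labels
#'   to `species_A`/`species_B`/`hybrid`/`unknown`.
#' @param locus Locus name; defaults to the FASTA file name without extension.
#' @return A [site_alignment()].
#' @export
read_fasta_alignment <- function(path, sample_sheet, taxon_map = NULL,
                                 locus = NULL) {
  seqs <- read_fasta(path)
  sheet <- read_sample_sheet(sample_sheet, taxon_map = taxon_map)
  missing_ids <- setdiff(names(seqs), sheet$sample_id)
  if (length(missing_ids) > 0) {
    abort(sprintf("FASTA id(s) missing from sample sheet: %s",
                  paste(missing_ids, collapse = ", ")),
          class = "hybridID_metadata_error")
  }
  sheet <- sheet[match(names(seqs), sheet$sample_id), ]
  sheet$sequence <- unname(seqs)
  site_alignment(sheet, locus = locus %||% sub("\\.[^.]*$", "", basename(path)))
}

#' @rdname read_fasta_alignment
#' @export
read_sample_sheet <- function(sample_sheet, taxon_map = NULL) {
  sheet <- readr::read_tsv(sample_sheet, col_types = readr::cols(.default = "c"))
  required <- c("sample_id", "taxon", "population", "role")
  missing_cols <- setdiff(required, names(sheet))
  if (length(missing_cols) > 0) {
    abort(paste0("sample sheet lacks column(s): ", paste(missing_cols, collapse = ", ")),
          class = "hybridID_metadata_error")
  }
  if (!is.null(taxon_map)) {
    mapped <- unname(taxon_map[sheet$taxon])
    sheet$taxon <- ifelse(is.na(mapped), sheet$taxon, mapped)
  }
  if ("readable_prefix" %in% names(sheet)) {
    sheet$readable_prefix <- as.integer(sheet$readable_prefix)
  }
  sheet
}

# FASTA records as named strings; parsing is delegated to ape, which handles
# gapped and IUPAC-coded alignments.
read_fasta <- function(path) {
  recs <- tryCatch(suppressWarnings(ape::read.FASTA(path)),
                   error = function(e) {
                     abort(sprintf("cannot parse '%s' as FASTA: %s",
                                   path, conditionMessage(e)),
                           class = "hybridID_alignment_error")
                   })
  if (length(recs) == 0) {
    abort(sprintf("'%s' contains no FASTA records", path),
          class = "hybridID_alignment_error")
  }
  chars <- as.character(recs)
  seqs <- vapply(chars, function(x) paste(toupper(x), collapse = ""), character(1))
  if (any(!nzchar(seqs))) {
    abort(sprintf("'%s' contains a FASTA record with no sequence", path),
          class = "hybridID_alignment_error")
  }
  ids <- sub("\\s.*$", "", names(seqs))
  setNames(unname(seqs), ids)
}

#' Write a site alignment back to FASTA (and optionally its sample sheet)
#'
#' @param aln A `site_alignment`.
#' @param path Output FASTA path.
#' @param sample_sheet Optional path for the matching sample sheet TSV.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(aln, path, sample_sheet = NULL) {
  out <- character(2L * nrow(aln))
  out[c(TRUE, FALSE)] <- paste0(">", aln$sample_id)
  out[c(FALSE, TRUE)] <- aln$sequence
  readr::write_lines(out, path)
  if (!is.null(sample_sheet)) {
    sheet <- as_tibble(aln)[, c("sample_id", "taxon", "population", "role",
                                "readable_prefix")]
    write_tsv_stable(sheet, sample_sheet)
  }
  invisible(path)
}

# Deterministic TSV writer: fixed column order (as given), fixed numeric
# format, LF endings, "NA" for missing.  Guarantees byte-identical output for
# identical input objects.
write_tsv_stable <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.list(df[[j]])) {
      df[[j]] <- vapply(df[[j]], function(x) paste(x, collapse = ","), character(1))
    } else if (is.double(df[[j]])) {
      df[[j]] <- ifelse(is.na(df[[j]]), "NA", sprintf("%.10g", df[[j]]))
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA", eol = "\n")
  invisible(path)
}

#' Write pipeline products as deterministic TSV files
#'
#' Accepts a named list of data frames (or objects with a [tidy()] method) and
#' writes one `<name>.tsv` per element.  Output is byte-stable: fixed column
#' order, fixed float format, LF line endings.
#'
#' @param objects Named list of data frames / tidy-able objects.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the vector of file paths written.
#' @export
write_tables <- function(objects, out_dir) {
  if (is.data.frame(objects)) objects <- list(table = objects)
  if (is.null(names(objects)) || any(!nzchar(names(objects)))) {
    abort("write_tables() needs a named list", class = "hybridID_usage_error")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2) != 0) {
    abort(sprintf("'%s' is not writable", out_dir), class = "hybridID_io_error")
  }
  paths <- character(0)
  for (nm in names(objects)) {
    obj <- objects[[nm]]
    if (!is.data.frame(obj)) obj <- tidy(obj)
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    write_tsv_stable(obj, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
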