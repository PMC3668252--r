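# Character alphabet and IUPAC semantics shared by every other module.
#
# The working alphabet is {A,C,G,T,-,N} plus the six two-fold IUPAC ambiguity
# codes {R,Y,S,W,K,M}.  Two-fold codes stand for a diploid individual whose two
# alleles are superimposed in a direct-sequencing chromatogram; three- and
# four-fold codes (B,D,H,V) are rejected on input because a diploid can
# superimpose at most two bases.

BASES <- c("A", "C", "G", "T")
AMBIG2 <- c(R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC")
ALPHABET <- c(BASES, "-", "N", names(AMBIG2))

#' Combine two unambiguous bases into one IUPAC code
#'
#' Models chromatogram additivity: a heterozygote carrying `base1` and `base2`
#' at a site reads as the two-base IUPAC ambiguity code.  Equal bases return
#' the base itself.  Vectorised over both arguments.
#'
#' @param base1,base2 Character vectors of unambiguous bases (`A`, `C`, `G`,
#'   `T`).
#' @return A character vector of IUPAC codes (or plain bases where equal).
#' @examples
#' iupac_union("A", "G")  # "R"
#' iupac_union(c("C", "T"), c("C", "G"))  # "C" "K"
#' @export
iupac_union <- function(base1, base2) {
  base1 <- toupper(base1)
  base2 <- toupper(base2)
  bad <- !(base1 %in% BASES) | !(base2 %in% BASES)
  if (any(bad)) {
    abort(
      sprintf(
        "iupac_union() requires unambiguous bases; got %s",
        paste(unique(c(base1[bad], base2[bad])), collapse = ", ")
      ),
      class = "hybridID_alphabet_error"
    )
  }
  lo <- pmin(base1, base2)
  hi <- pmax(base1, base2)
  key <- paste0(lo, hi)
  code <- names(AMBIG2)[match(key, AMBIG2)]
  ifelse(base1 == base2, base1, code)
}

#' Split an IUPAC code into its constituent bases
#'
#' Inverse of [iupac_union()] for two-base codes; `N` expands to all four
#' bases and a plain base returns itself.
#'
#' @param code A single character in `{A,C,G,T,R,Y,S,W,K,M,N}`.
#' @return A character vector of unambiguous bases.
#' @export
iupac_split <- function(code) {
  code <- toupper(code)
  stopifnot(length(code) == 1L)
  if (code %in% BASES) return(code)
  if (code == "N") return(BASES)
  if (code %in% names(AMBIG2)) {
    return(strsplit(AMBIG2[[code]], "", fixed = TRUE)[[1]])
  }
  abort(
    sprintf("'%s' is not a supported IUPAC code", code),
    class = "hybridID_alphabet_error"
  )
}

#' @rdname iupac_split
#' @details `is_ambiguity_code()` tests membership in the two-fold codes.
#' @export
is_ambiguity_code <- function(code) toupper(code) %in% names(AMBIG2)

# Validate a vector of single characters against the working alphabet.
# `allow_ambiguity` is FALSE for haplotype-role rows.
check_alphabet <- function(chars, allow_ambiguity, context = "sequence") {
  bad <- setdiff(unique(chars), ALPHABET)
  if (length(bad) > 0) {
    abort(
      sprintf("illegal character(s) %s in %s (three/four-fold IUPAC codes are not accepted)",
              paste(sQuote(bad), collapse = ", "), context),
      class = "hybridID_alphabet_error"
    )
  }
  if (!allow_ambiguity) {
    amb <- intersect(unique(chars), names(AMBIG2))
    if (length(amb) > 0) {
      abort(
        sprintf("ambiguity code(s) %s in %s, but ambiguity is only permitted in diploid_consensus rows",
                paste(sQuote(amb), collapse = ", "), context),
        class = "hybridID_role_error"
      )
    }
  }
  invisible(chars)
}
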