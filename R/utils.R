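# Shared sequence helpers. All sequences are held internally as upper-case RNA
# (alphabet A, C, G, U); DNA is accepted on input and T is normalized to U.

RNA_BASES <- c("A", "C", "G", "U")

#' Normalize a nucleotide string to internal RNA form
#'
#' Strips whitespace, upper-cases, and converts T to U.
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector in the internal RNA alphabet.
#' @export
as_rna <- function(x) {
  nm <- names(x)
  x <- gsub("[[:space:]]", "", as.character(x))
  x <- chartr("tT", "uU", toupper(chartr("T", "U", x)))
  names(x) <- nm
  x
}

#' Reverse complement of an RNA sequence
#'
#' @param x character vector of RNA sequences (A/C/G/U).
#' @return character vector of reverse complements.
#' @export
rna_revcomp <- function(x) {
  comp <- chartr("ACGU", "UGCA", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

rna_complement_base <- function(b) {
  c(A = "U", C = "G", G = "C", U = "A")[[b]]
}

#' Pair state of one miRNA base against one transcript base
#'
#' Watson-Crick pairs are A:U, U:A, G:C, C:G; G:U and U:G are wobble pairs.
#'
#' @param mirna_base,target_base single upper-case RNA bases.
#' @return one of `"WC"`, `"GU"`, `"MISMATCH"`.
#' @export
pair_state <- function(mirna_base, target_base) {
  wc <- (mirna_base == "A" & target_base == "U") |
        (mirna_base == "U" & target_base == "A") |
        (mirna_base == "G" & target_base == "C") |
        (mirna_base == "C" & target_base == "G")
  gu <- (mirna_base == "G" & target_base == "U") |
        (mirna_base == "U" & target_base == "G")
  ifelse(wc, "WC", ifelse(gu, "GU", "MISMATCH"))
}

check_rna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGU]", x)
  if (any(bad))
    stop(sprintf("%s contains non-RNA characters: %s", what,
                 paste(head(x[bad], 3), collapse = ", ")), call. = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
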