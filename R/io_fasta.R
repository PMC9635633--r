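#' Read a FASTA file of genomic sequences
#'
#' Sequences are returned as a named character vector (one element per record,
#' names are the full header word up to the first whitespace). Residues are
#' upper-cased and validated against the alphabet `{A,C,G,T,N}`; record order
#' is preserved.
#'
#' @param path path to a FASTA file
#' @return named character vector of DNA sequences (possibly length 0)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_hk("FASTA file not found: %s", path)
  if (file.size(path) == 0) return(setNames(character(0), character(0)))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop_hk("malformed FASTA '%s': %s",
                                              path, conditionMessage(e)))
  seqs <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop_hk("duplicate sequence ids in %s: %s", path,
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    ## locate the first offending line for the error message
    lines <- readLines(path, warn = FALSE)
    ln <- which(!startsWith(lines, ">") &
                  grepl("[^ACGTNacgtn]", lines))[1]
    stop_hk("illegal residue characters in %s (record '%s', line %s)",
            path, ids[bad][1], ifelse(is.na(ln), "?", ln))
  }
  setNames(seqs, ids)
}

#' Write genomic sequences to FASTA
#'
#' @param seqs named character vector of sequences
#' @param path output path
#' @param width line wrap width (default 60 columns)
#' @return `path`, invisibly
#' @export
write_fasta <- function(seqs, path, width = 60) {
  set <- Biostrings::BStringSet(seqs)
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Translate a coding sequence
#'
#' Standard genetic code; stop codons are rendered `*` and translation runs to
#' the end of the string (internal stops are preserved so that disrupted
#' reading frames remain visible for pseudogene detection). Codons containing
#' characters outside `{A,C,G,T}` translate to `X`.
#'
#' @param dna a single DNA string, length divisible by 3
#' @return amino-acid string of length `nchar(dna)/3`
#' @export
translate_cds <- function(dna) {
  if (length(dna) != 1 || !is.character(dna)) stop_hk("'dna' must be a single string")
  dna <- toupper(dna)
  n <- nchar(dna)
  if (n %% 3 != 0) stop_hk("CDS length %d is not divisible by 3", n)
  if (n == 0) return("")
  codons <- substring(dna, seq(1, n, 3), seq(3, n, 3))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}
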