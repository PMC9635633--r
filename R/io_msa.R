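#' Construct a multiple sequence alignment object
#'
#' A thin container: equal-length rows of aligned residues (amino acids for
#' `mode = "protein"`, nucleotide triplets for `mode = "codon"`), row ids, and
#' an optional per-row group label used by cross-family comparisons.
#'
#' @param ids character vector of row ids (unique)
#' @param rows character vector of aligned rows (equal widths; gap `-`)
#' @param mode `"protein"` or `"codon"`
#' @param group optional character vector of per-row group labels
#' @return object of class `msa`
#' @export
msa_alignment <- function(ids, rows, mode = c("protein", "codon"),
                          group = NULL) {
  mode <- match.arg(mode)
  if (length(ids) != length(rows)) stop_hk("ids and rows differ in length")
  w <- unique(nchar(rows))
  if (length(w) > 1)
    stop_hk("ragged alignment: row widths %s", paste(w, collapse = ", "))
  if (mode == "codon" && length(w) == 1 && w %% 3 != 0)
    stop_hk("codon-mode alignment width %d not divisible by 3", w)
  if (anyDuplicated(ids)) stop_hk("duplicate row ids in alignment")
  if (!is.null(group) && length(group) != length(ids))
    stop_hk("group labels must match rows")
  structure(list(ids = as.character(ids), rows = toupper(as.character(rows)),
                 mode = mode, group = group),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa> %d rows x %d columns (%s mode)\n",
              length(x$ids), if (length(x$rows)) nchar(x$rows[1]) else 0L,
              x$mode))
  invisible(x)
}

n_rows <- function(msa) length(msa$ids)
n_cols <- function(msa) if (length(msa$rows)) nchar(msa$rows[1]) else 0L

## rows as a character matrix (rows x columns)
msa_matrix <- function(msa) {
  if (n_rows(msa) == 0) return(matrix(character(0), 0, 0))
  do.call(rbind, strsplit(msa$rows, "", fixed = TRUE))
}

#' Read an aligned FASTA file
#'
#' Headers of the form `>id|group=LABEL` populate the per-row group label.
#'
#' @param path aligned FASTA path
#' @param mode `"protein"` or `"codon"`
#' @return an [msa_alignment] object
#' @export
read_msa <- function(path, mode = c("protein", "codon")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop_hk("alignment file not found: %s", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop_hk("malformed aligned FASTA '%s': %s",
                                              path, conditionMessage(e)))
  hdr <- names(set)
  ids <- sub("\\|.*$", "", sub("\\s.*$", "", hdr))
  grp <- ifelse(grepl("group=", hdr),
                sub("^.*group=([^|[:space:]]+).*$", "\\1", hdr), NA_character_)
  group <- if (all(is.na(grp))) NULL else grp
  msa_alignment(ids, as.character(set), mode = mode, group = group)
}

#' Write an alignment to aligned FASTA
#'
#' @param msa an [msa_alignment] object
#' @param path output path
#' @return `path`, invisibly
#' @export
write_msa <- function(msa, path) {
  hdr <- if (is.null(msa$group)) msa$ids else
    ifelse(is.na(msa$group), msa$ids,
           paste0(msa$ids, "|group=", msa$group))
  write_fasta(setNames(msa$rows, hdr), path)
}
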