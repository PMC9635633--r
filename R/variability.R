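## Wu-Kabat variability index: for an alignment column, VI = k / (n_max / N)
## where k is the number of distinct residues, n_max the count of the most
## common residue and N the number of residues observed at the column.  Gaps
## are excluded from all three tallies, as in the classical application to
## immunoglobulin alignments.

#' Wu-Kabat variability profile of a protein alignment
#'
#' Computes per-column k (distinct non-gap residues), `n_max` (count of the
#' most common residue), `N_col` (non-gap rows) and
#' `VI = k * N_col / n_max`, and calls a column polymorphic when
#' `VI >= threshold` (inclusive).  Columns with no residues (`N_col = 0`) are
#' marked undefined (`NA`).
#'
#' @param msa an [msa_alignment] in protein mode with at least 2 rows
#' @param threshold polymorphism call threshold on VI (default 6, inclusive)
#' @return data.frame of class `variability_profile` with columns `column`,
#'   `k`, `n_max`, `N_col`, `VI`, `polymorphic`
#' @export
compute_vi <- function(msa, threshold = 6) {
  if (!inherits(msa, "msa")) stop_hk("'msa' must be an msa_alignment")
  if (msa$mode != "protein") stop_hk("compute_vi requires a protein alignment")
  if (n_rows(msa) < 2) stop_hk("at least 2 rows required")
  m <- msa_matrix(msa)
  stats_col <- function(col) {
    res <- col[col != "-" & col != "."]
    if (length(res) == 0) return(c(NA_real_, NA_real_, 0))
    tb <- table(res)
    c(length(tb), max(tb), length(res))
  }
  s <- apply(m, 2, stats_col)
  k <- s[1, ]; n_max <- s[2, ]; N_col <- s[3, ]
  if (all(N_col == 0)) stop_hk("all-gap alignment: profile undefined")
  vi <- k * N_col / n_max
  out <- data.frame(column = seq_len(ncol(m)), k = as.integer(k),
                    n_max = as.integer(n_max), N_col = as.integer(N_col),
                    VI = vi, polymorphic = !is.na(vi) & vi >= threshold)
  out$polymorphic[N_col == 0] <- NA
  attr(out, "threshold") <- threshold
  attr(out, "alignment_id") <- attr(msa, "id")
  class(out) <- c("variability_profile", "data.frame")
  out
}

## Map alignment columns to reference-sequence residue numbering: columns
## where the reference row has a gap get NA.
reference_numbering <- function(msa, ref_id) {
  i <- match(ref_id, msa$ids)
  if (is.na(i)) stop_hk("reference row '%s' not in alignment", ref_id)
  ch <- strsplit(msa$rows[i], "", fixed = TRUE)[[1]]
  num <- cumsum(ch != "-" & ch != ".")
  num[ch == "-" | ch == "."] <- NA
  num
}

#' Compare polymorphic position sets between two groups in a joint alignment
#'
#' VI is computed within each group separately over the joint alignment's
#' columns; a column is shared when it is polymorphic in both groups.
#' Positions are reported both as joint-alignment columns and in each group's
#' declared reference-row numbering (columns gapped in that reference carry
#' no number).
#'
#' @param msa a protein [msa_alignment] whose `group` labels contain both
#'   `group_a` and `group_b`
#' @param group_a,group_b group labels to compare
#' @param ref_a,ref_b reference row ids (must belong to their group) used for
#'   position numbering; default: the group's first row
#' @param threshold VI polymorphism threshold (inclusive)
#' @return list of class `polymorphism_comparison` with `shared_columns`,
#'   per-group `specific_columns`, `positions` (a data.frame mapping columns
#'   to reference numbering) and the per-group profiles
#' @export
compare_polymorphic_sets <- function(msa, group_a, group_b,
                                     ref_a = NULL, ref_b = NULL,
                                     threshold = 6) {
  if (is.null(msa$group)) stop_hk("alignment carries no group labels")
  sub_group <- function(g) {
    sel <- which(msa$group == g)
    if (length(sel) < 2) stop_hk("group '%s' has fewer than 2 rows", g)
    msa_alignment(msa$ids[sel], msa$rows[sel], mode = "protein")
  }
  ma <- sub_group(group_a); mb <- sub_group(group_b)
  ref_a <- ref_a %||% ma$ids[1]
  ref_b <- ref_b %||% mb$ids[1]
  pa <- compute_vi(ma, threshold); pb <- compute_vi(mb, threshold)
  poly_a <- which(!is.na(pa$polymorphic) & pa$polymorphic)
  poly_b <- which(!is.na(pb$polymorphic) & pb$polymorphic)
  shared <- intersect(poly_a, poly_b)
  num_a <- reference_numbering(ma, ref_a)
  num_b <- reference_numbering(mb, ref_b)
  positions <- data.frame(column = seq_len(n_cols(msa)),
                          pos_a = num_a, pos_b = num_b)
  structure(list(shared_columns = shared,
                 specific_columns = list(setdiff(poly_a, shared),
                                         setdiff(poly_b, shared)) |>
                   setNames(c(group_a, group_b)),
                 positions = positions,
                 shared_positions = list(pos_a = num_a[shared],
                                         pos_b = num_b[shared]),
                 profiles = setNames(list(pa, pb), c(group_a, group_b)),
                 threshold = threshold),
            class = "polymorphism_comparison")
}

#' Write a variability profile as TSV
#'
#' One row per alignment column: `position`, `k`, `n_max`, `N_col`, `VI`,
#' `call` (`polymorphic` / `conserved`; undefined columns render `NA`).
#'
#' @param profile a [compute_vi()] result
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
profile_report <- function(profile, path) {
  out <- data.frame(position = profile$column, k = profile$k,
                    n_max = profile$n_max, N_col = profile$N_col,
                    VI = profile$VI,
                    call = ifelse(is.na(profile$polymorphic), NA,
                                  ifelse(profile$polymorphic, "polymorphic",
                                         "conserved")))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a variability profile written by [profile_report()]
#'
#' @param path TSV path
#' @return data.frame with the profile columns
#' @export
read_profile_report <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  d$polymorphic <- ifelse(is.na(d$call), NA, d$call == "polymorphic")
  d
}
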