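#' Locus census by contig and gene family
#'
#' Tabulates loci (and pseudogene subtotals) per contig and gene family, with
#' margin totals, mirroring the haplotype-wide bookkeeping used for
#' gene-block MHC regions.
#'
#' @param features a [feature_records] data.frame
#' @param contigs character vector of contig ids defining the column order;
#'   features on contigs outside this set raise an error
#' @return list of class `census_report` with integer matrices `counts` and
#'   `pseudogenes` (families x contigs, with `Total` margins), and scalars
#'   `total_loci`, `total_pseudogenes`
#' @export
count_loci <- function(features, contigs) {
  unknown <- setdiff(unique(features$seq_id), contigs)
  if (length(unknown))
    stop_hk("features on unknown contig(s): %s",
            paste(features$locus_id[features$seq_id %in% unknown], collapse = ", "))
  fams <- unique(c(intersect(FEATURE_FAMILIES, features$family),
                   setdiff(unique(features$family), FEATURE_FAMILIES)))
  if (length(fams) == 0) fams <- character(0)
  tab <- function(sel) {
    m <- matrix(0L, nrow = length(fams), ncol = length(contigs),
                dimnames = list(fams, contigs))
    if (any(sel)) {
      t0 <- table(factor(features$family[sel], levels = fams),
                  factor(features$seq_id[sel], levels = contigs))
      m[] <- as.integer(t0)
    }
    m <- cbind(m, Total = rowSums(m))
    rbind(m, Total = colSums(m))
  }
  counts <- tab(rep(TRUE, nrow(features)))
  pseudo <- tab(features$pseudogene)
  structure(list(counts = counts, pseudogenes = pseudo,
                 total_loci = counts["Total", "Total"],
                 total_pseudogenes = pseudo["Total", "Total"]),
            class = "census_report")
}

#' @export
print.census_report <- function(x, ...) {
  cat(sprintf("<census_report> %d loci (%d pseudogenes)\n",
              x$total_loci, x$total_pseudogenes))
  disp <- matrix(sprintf("%d (%dP)", x$counts, x$pseudogenes),
                 nrow = nrow(x$counts), dimnames = dimnames(x$counts))
  print(disp, quote = FALSE)
  invisible(x)
}

#' Gene density in loci per megabase
#'
#' `round(n_loci / region_length_mb)` with halves rounded away from zero, the
#' convention under which 107 loci over 0.639 Mb gives 167 loci/Mb.
#'
#' @param n_loci locus count
#' @param region_length_mb region length in Mb (> 0)
#' @return integer loci per Mb
#' @export
gene_density <- function(n_loci, region_length_mb) {
  assert_scalar_num(n_loci, "n_loci")
  assert_scalar_num(region_length_mb, "region_length_mb")
  if (region_length_mb <= 0) stop_hk("region_length_mb must be positive")
  as.integer(round_half_up(n_loci / region_length_mb))
}

#' Summarize repeat content over a region
#'
#' Per repeat class: element count, total masked bp, and percent of the
#' region.  Percentages are computed from the unrounded bp sums and rounded
#' half-up to 2 decimals.  Grouped rows (transposable elements = LTR + LINE +
#' DNA transposons; tandem repeats; other repeats = small RNA + satellite +
#' simple + low complexity) carry two percent columns: `percent` recomputed
#' from the grouped bp total, and `percent_table`, the sum of the rounded
#' member-class rows as printed in conventional RepeatMasker summary tables
#' (the two differ when member rounding accumulates).
#'
#' @param repeats a [repeat_records] data.frame; class `"other"` records are
#'   excluded from the summary (their count is reported separately)
#' @param region_length_bp region length in bp (> 0)
#' @return list of class `repeat_summary` with data.frames `classes` and
#'   `groups`, and `n_other_excluded`
#' @export
summarize_repeats <- function(repeats, region_length_bp) {
  assert_scalar_num(region_length_bp, "region_length_bp")
  if (region_length_bp <= 0) stop_hk("region_length_bp must be positive")
  ## a bp bound can only be enforced when all records lie on one contig
  if (nrow(repeats) && length(unique(repeats$seq_id)) == 1 &&
      any(repeats$end > region_length_bp))
    stop_hk("repeat record(s) extend beyond the %d bp region", region_length_bp)
  other <- repeats$repeat_class == "other"
  reps <- repeats[!other, , drop = FALSE]
  len <- if (nrow(reps)) reps$end - reps$start + 1L else integer(0)
  cls <- factor(reps$repeat_class, levels = REPEAT_CLASSES)
  classes <- data.frame(
    repeat_class = REPEAT_CLASSES,
    count = as.integer(table(cls)),
    total_bp = as.numeric(tapply(c(len, 0), c(as.character(cls), NA),
                                 sum)[REPEAT_CLASSES]),
    stringsAsFactors = FALSE)
  classes$total_bp[is.na(classes$total_bp)] <- 0
  classes$percent <- round_half_up(100 * classes$total_bp / region_length_bp, 2)
  grp_members <- list(
    transposable_elements = c("LTR", "LINE", "DNA_transposon"),
    tandem_repeats = "tandem",
    other_repeats = c("small_RNA", "satellite", "simple", "low_complexity"))
  groups <- do.call(rbind, lapply(names(grp_members), function(g) {
    sel <- classes$repeat_class %in% grp_members[[g]]
    data.frame(group = g,
               count = sum(classes$count[sel]),
               total_bp = sum(classes$total_bp[sel]),
               percent = round_half_up(100 * sum(classes$total_bp[sel]) /
                                         region_length_bp, 2),
               percent_table = sum(classes$percent[sel]),
               stringsAsFactors = FALSE)
  }))
  structure(list(classes = classes, groups = groups,
                 region_length_bp = region_length_bp,
                 n_other_excluded = sum(other)),
            class = "repeat_summary")
}

#' Gap between two adjacent, non-overlapping features
#'
#' Defined as `start(downstream) - end(upstream)` (not minus one): the
#' convention under which a feature ending at 103,436 followed by one starting
#' at 106,161 sit 2,725 bp apart.
#'
#' @param upstream,downstream single-row [feature_records] (or lists with
#'   `seq_id`, `start`, `end`)
#' @return integer gap in bp
#' @export
boundary_gap <- function(upstream, downstream) {
  if (upstream$seq_id[1] != downstream$seq_id[1])
    stop_hk("features lie on different contigs")
  if (upstream$end[1] >= downstream$start[1])
    stop_hk("features overlap or are mis-ordered (upstream end %d >= downstream start %d)",
            upstream$end[1], downstream$start[1])
  as.integer(downstream$start[1] - upstream$end[1])
}

#' Group full-length loci into types by predicted-protein identity
#'
#' Each full-length locus's CDS is extracted from its contig (strand aware)
#' and translated; loci with byte-identical predicted proteins share a type.
#' Type labels restart per gene family and are assigned `"a"`, `"b"`, ... in
#' order of first genomic occurrence (contig id, then start).  Loci whose CDS
#' is untranslatable (length not divisible by 3) are excluded with a warning
#' and listed in the result.
#'
#' @param features a [feature_records] data.frame; only rows with
#'   `full_length = TRUE` are typed
#' @param sequences named character vector of contig sequences
#' @return list of class `type_clustering`: data.frame `assignments`
#'   (`locus_id`, `family`, `type_label`, `protein`), data.frame `types`
#'   (`family`, `type_label`, `copies`), `n_types` per family, and
#'   `excluded` locus ids
#' @export
cluster_types <- function(features, sequences) {
  f <- features[features$full_length, , drop = FALSE]
  f <- f[order(f$seq_id, f$start), , drop = FALSE]
  if (nrow(f) == 0)
    return(structure(list(assignments = data.frame(), types = data.frame(),
                          n_types = integer(0), excluded = character(0)),
                     class = "type_clustering"))
  missing <- setdiff(unique(f$seq_id), names(sequences))
  if (length(missing)) stop_hk("no sequence for contig(s): %s",
                               paste(missing, collapse = ", "))
  cds <- substring(sequences[f$seq_id], f$start, f$end)
  cds <- ifelse(f$strand == "-", revcomp(cds), cds)
  ok <- nchar(cds) %% 3 == 0
  if (any(!ok))
    warning(sprintf("excluded %d locus/loci with untranslatable CDS: %s",
                    sum(!ok), paste(f$locus_id[!ok], collapse = ", ")),
            call. = FALSE)
  excluded <- f$locus_id[!ok]
  f <- f[ok, , drop = FALSE]
  prot <- vapply(cds[ok], translate_cds, "", USE.NAMES = FALSE)
  ## rows are in genomic order, so unique() ranks proteins by first occurrence
  type_letter <- function(i) {
    ifelse(i <= 26L, letters[i],
           paste0(letters[(i - 1L) %/% 26L], letters[(i - 1L) %% 26L + 1L]))
  }
  label <- character(nrow(f))
  for (fam in unique(f$family)) {
    sel <- which(f$family == fam)
    label[sel] <- type_letter(match(prot[sel], unique(prot[sel])))
  }
  assignments <- data.frame(locus_id = f$locus_id, family = f$family,
                            type_label = label, protein = prot,
                            stringsAsFactors = FALSE)
  types <- do.call(rbind, lapply(split(assignments, assignments$family),
                                 function(d) {
    data.frame(family = d$family[1],
               type_label = sort(unique(d$type_label)),
               copies = as.integer(table(d$type_label)),
               stringsAsFactors = FALSE)
  }))
  rownames(types) <- NULL
  n_types <- vapply(split(assignments$type_label, assignments$family),
                    function(x) length(unique(x)), 1L)
  structure(list(assignments = assignments, types = types,
                 n_types = n_types, excluded = excluded),
            class = "type_clustering")
}

#' Contig size arithmetic for a haplotype abutting an rRNA gene array
#'
#' Splits the summed contig lengths into the haplotype portion and the
#' adjacent nucleolus-organizer (rRNA repeat) portion carried on the first
#' contig.
#'
#' @param contig_lengths positive contig lengths in bp; the first contig is
#'   the one carrying the rRNA array
#' @param nor_length_bp bp of the first contig occupied by the rRNA array
#' @return list with `overall_bp`, `mhc_bp` (overall minus NOR), and
#'   `per_contig_mhc_bp`
#' @export
contig_arithmetic <- function(contig_lengths, nor_length_bp) {
  if (any(contig_lengths <= 0)) stop_hk("contig lengths must be positive")
  assert_scalar_num(nor_length_bp, "nor_length_bp")
  if (nor_length_bp < 0 || nor_length_bp > contig_lengths[1])
    stop_hk("NOR length %s exceeds its contig (%s bp)", nor_length_bp,
            contig_lengths[1])
  per <- contig_lengths
  per[1] <- per[1] - nor_length_bp
  list(overall_bp = sum(contig_lengths),
       mhc_bp = sum(contig_lengths) - nor_length_bp,
       per_contig_mhc_bp = per)
}
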