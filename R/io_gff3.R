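## Locus annotations travel as plain data.frames ("feature records") with the
## columns below; GFF3 is the on-disk form.  The attribute dialect is this
## package's own: ID, family, pseudogene, type_label, full_length.

FEATURE_FAMILIES <- c("MHCY_classI", "YLEC", "MHCY2B", "LENG9L", "ZNFY",
                      "OZFL", "rRNA", "other")

#' Construct a validated table of locus feature records
#'
#' @param seq_id contig id per locus
#' @param family gene family; unknown values are mapped to `"other"` with a
#'   warning
#' @param locus_id unique locus identifier
#' @param start,end 1-based inclusive coordinates
#' @param strand `"+"` or `"-"`
#' @param pseudogene logical pseudogene flag
#' @param type_label optional predicted-protein type label (`"a"`, `"b"`, ...)
#' @param full_length logical; whether the locus carries a full-length gene
#' @param seq_lengths optional named vector of contig lengths used to bound-check
#'   coordinates
#' @return data.frame of class `feature_records`
#' @export
feature_records <- function(seq_id, family, locus_id, start, end,
                            strand = "+", pseudogene = FALSE,
                            type_label = NA_character_, full_length = !pseudogene,
                            seq_lengths = NULL) {
  n <- length(seq_id)
  df <- data.frame(seq_id = as.character(seq_id),
                   family = rep_len(as.character(family), n),
                   locus_id = as.character(locus_id),
                   start = as.integer(start), end = as.integer(end),
                   strand = rep_len(as.character(strand), n),
                   pseudogene = rep_len(as.logical(pseudogene), n),
                   type_label = rep_len(as.character(type_label), n),
                   full_length = rep_len(as.logical(full_length), n),
                   stringsAsFactors = FALSE)
  unknown <- !(df$family %in% FEATURE_FAMILIES)
  if (any(unknown)) {
    warning(sprintf("unknown families mapped to 'other': %s",
                    paste(unique(df$family[unknown]), collapse = ", ")),
            call. = FALSE)
    df$family[unknown] <- "other"
  }
  bad <- df$start < 1L | df$start > df$end
  if (any(bad))
    stop_hk("rejected feature record(s) with start < 1 or start > end: %s",
            paste(df$locus_id[bad], collapse = ", "))
  if (anyDuplicated(df$locus_id))
    stop_hk("duplicate locus_id: %s",
            paste(unique(df$locus_id[duplicated(df$locus_id)]), collapse = ", "))
  if (!all(df$strand %in% c("+", "-")))
    stop_hk("strand must be '+' or '-'")
  if (!is.null(seq_lengths)) {
    len <- seq_lengths[df$seq_id]
    over <- is.na(len) | df$end > len
    if (any(over))
      stop_hk("feature(s) outside their contig: %s",
              paste(df$locus_id[over], collapse = ", "))
  }
  class(df) <- c("feature_records", "data.frame")
  df
}

gff3_escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  gsub("=", "%3D", x, fixed = TRUE)
}

parse_gff3_attributes <- function(attr) {
  lapply(strsplit(attr, ";", fixed = TRUE), function(kv) {
    kv <- kv[nzchar(kv)]
    parts <- regmatches(kv, regexpr("=", kv, fixed = TRUE), invert = TRUE)
    vals <- vapply(parts, function(p) if (length(p) == 2) p[2] else "", "")
    names(vals) <- vapply(parts, `[`, "", 1)
    vals
  })
}

#' Read locus annotations from GFF3
#'
#' Coordinates are kept 1-based inclusive exactly as stored.  The attribute
#' keys `ID` (locus id), `family`, `pseudogene`, `type_label` and
#' `full_length` carry the locus metadata; unknown families are mapped to
#' `"other"` with a warning and records with `start > end` raise an error.
#'
#' @param path path to a GFF3 file
#' @return a [feature_records] data.frame (zero rows for a header-only file)
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop_hk("GFF3 file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0)
    return(feature_records(character(0), character(0), character(0),
                           integer(0), integer(0), character(0), logical(0),
                           character(0), logical(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9))
    stop_hk("GFF3 format error in %s: line %d has %d columns (9 required)",
            path, which(nf < 9)[1], min(nf))
  m <- do.call(rbind, fields)
  start <- suppressWarnings(as.integer(m[, 4]))
  end <- suppressWarnings(as.integer(m[, 5]))
  if (anyNA(start) || anyNA(end))
    stop_hk("GFF3 format error in %s: non-numeric start/end", path)
  at <- parse_gff3_attributes(m[, 9])
  get_at <- function(key, default) {
    vapply(at, function(a) if (key %in% names(a)) a[[key]] else default, "")
  }
  truthy <- function(x) tolower(x) %in% c("true", "1", "yes")
  pseudo <- truthy(get_at("pseudogene", "false"))
  fl_raw <- get_at("full_length", "")
  feature_records(
    seq_id = m[, 1],
    family = get_at("family", "other"),
    locus_id = get_at("ID", paste0("feature_", seq_along(at))),
    start = start, end = end,
    strand = ifelse(m[, 7] %in% c("+", "-"), m[, 7], "+"),
    pseudogene = pseudo,
    type_label = ifelse(nzchar(get_at("type_label", "")),
                        get_at("type_label", ""), NA_character_),
    full_length = ifelse(nzchar(fl_raw), truthy(fl_raw), !pseudo)
  )
}

#' Write locus annotations to GFF3
#'
#' @param features a [feature_records] data.frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_gff3 <- function(features, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(features)) {
    attrs <- sprintf("ID=%s;family=%s;pseudogene=%s;full_length=%s%s",
                     gff3_escape(features$locus_id), features$family,
                     tolower(features$pseudogene), tolower(features$full_length),
                     ifelse(is.na(features$type_label), "",
                            paste0(";type_label=", gff3_escape(features$type_label))))
    writeLines(sprintf("%s\thaplokit\tgene\t%d\t%d\t.\t%s\t.\t%s",
                       features$seq_id, features$start, features$end,
                       features$strand, attrs), con)
  }
  invisible(path)
}
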