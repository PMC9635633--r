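REPEAT_CLASSES <- c("LTR", "LINE", "DNA_transposon", "tandem", "small_RNA",
                    "satellite", "simple", "low_complexity")

#' Construct a validated table of repeat records
#'
#' @param seq_id contig id
#' @param repeat_class one of `r paste(REPEAT_CLASSES, collapse=", ")` (or
#'   `"other"` for classes outside the vocabulary)
#' @param repeat_family family string (e.g. `"ERV1"`, `"CR1-F"`)
#' @param start,end 1-based inclusive coordinates
#' @param strand `"+"` or `"-"`
#' @return data.frame of class `repeat_records`
#' @export
repeat_records <- function(seq_id, repeat_class, repeat_family, start, end,
                           strand = "+") {
  n <- length(seq_id)
  df <- data.frame(seq_id = as.character(seq_id),
                   repeat_class = rep_len(as.character(repeat_class), n),
                   repeat_family = rep_len(as.character(repeat_family), n),
                   start = as.integer(start), end = as.integer(end),
                   strand = rep_len(as.character(strand), n),
                   stringsAsFactors = FALSE)
  if (any(df$start > df$end)) stop_hk("repeat record with start > end")
  if (!all(df$repeat_class %in% c(REPEAT_CLASSES, "other")))
    stop_hk("repeat_class outside vocabulary: %s",
            paste(setdiff(unique(df$repeat_class), c(REPEAT_CLASSES, "other")),
                  collapse = ", "))
  class(df) <- c("repeat_records", "data.frame")
  df
}

## Map a RepeatMasker class/family string onto the package vocabulary.
map_repeat_class <- function(cls) {
  top <- sub("/.*$", "", cls)
  out <- rep("other", length(cls))
  out[top %in% c("LTR", "ERV1", "ERV", "ERVL", "ERVK")] <- "LTR"
  out[top == "LINE"] <- "LINE"
  out[top %in% c("DNA", "RC")] <- "DNA_transposon"
  out[top == "Simple_repeat"] <- "simple"
  out[top == "Low_complexity"] <- "low_complexity"
  out[startsWith(top, "Satellite")] <- "satellite"
  out[top %in% c("tRNA", "rRNA", "snRNA", "scRNA", "srpRNA", "Small_RNA")] <- "small_RNA"
  out[top %in% c("Tandem", "Tandem_repeat", "TRF")] <- "tandem"
  out
}

#' Read a RepeatMasker .out table
#'
#' Expects the standard layout (3 header lines, then whitespace-delimited
#' rows).  The class/family column is mapped by prefix onto the package
#' vocabulary (`LTR/*` to `LTR`, `LINE/*` to `LINE`, `DNA/*` to
#' `DNA_transposon`, `Simple_repeat` to `simple`, ...); unknown class strings
#' are kept in an `"other"` bucket and flagged with a warning so that summary
#' tables can exclude them.
#'
#' @param path path to a RepeatMasker `.out` file
#' @return a [repeat_records] data.frame (zero rows for a header-only file)
#' @export
read_repeatmasker_out <- function(path) {
  if (!file.exists(path)) stop_hk(".out file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  ## standard files carry 2 header lines + 1 blank; tolerate any leading block
  ## whose rows do not start with a numeric score
  body <- grepl("^\\s*\\d", lines)
  rows <- lines[body]
  if (length(rows) == 0)
    return(repeat_records(character(0), character(0), character(0),
                          integer(0), integer(0), character(0)))
  fields <- strsplit(trimws(rows), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 11))
    stop_hk("unparseable RepeatMasker row at line %d of %s",
            which(body)[nf < 11][1], path)
  m <- do.call(rbind, lapply(fields, `[`, 1:11))
  start <- suppressWarnings(as.integer(m[, 6]))
  end <- suppressWarnings(as.integer(m[, 7]))
  if (anyNA(start) || anyNA(end))
    stop_hk("unparseable coordinates in RepeatMasker row of %s", path)
  cls <- map_repeat_class(m[, 11])
  if (any(cls == "other"))
    warning(sprintf("%d repeat row(s) with unrecognized class kept as 'other': %s",
                    sum(cls == "other"),
                    paste(unique(m[cls == "other", 11]), collapse = ", ")),
            call. = FALSE)
  repeat_records(seq_id = m[, 5], repeat_class = cls, repeat_family = m[, 10],
                 start = start, end = end,
                 strand = ifelse(m[, 9] == "C", "-", "+"))
}

#' Expand a per-class repeat census into individual repeat records
#'
#' Given summary rows (`repeat_class`, `repeat_family`, `count`, `total_bp`),
#' emits `count` non-overlapping records per row whose lengths sum exactly to
#' `total_bp` (base length plus spread remainder), placed sequentially along
#' one region.  Useful for reconstructing a record-level table from a printed
#' census so that summaries can be recomputed from first principles.
#'
#' @param census data.frame with columns `repeat_class`, `repeat_family`,
#'   `count`, `total_bp`
#' @param seq_id contig id for the emitted records
#' @param gap_bp spacing between consecutive records (default 10)
#' @return a [repeat_records] data.frame
#' @export
expand_repeat_census <- function(census, seq_id = "region", gap_bp = 10) {
  rows <- list()
  pos <- 1L
  for (i in seq_len(nrow(census))) {
    n <- census$count[i]
    if (n == 0) next
    base <- census$total_bp[i] %/% n
    len <- rep(base, n)
    extra <- census$total_bp[i] - base * n
    if (extra > 0) len[seq_len(extra)] <- len[seq_len(extra)] + 1L
    start <- pos + cumsum(c(0L, head(len, -1L) + gap_bp))
    rows[[length(rows) + 1L]] <- data.frame(
      seq_id = seq_id, repeat_class = census$repeat_class[i],
      repeat_family = census$repeat_family[i],
      start = start, end = start + len - 1L, strand = "+",
      stringsAsFactors = FALSE)
    pos <- max(start + len - 1L) + gap_bp + 1L
  }
  d <- do.call(rbind, rows)
  repeat_records(d$seq_id, d$repeat_class, d$repeat_family, d$start, d$end,
                 d$strand)
}

#' Write repeat records as a RepeatMasker-style .out table
#'
#' Emits the standard 3 header lines and one whitespace-delimited row per
#' record, with a class/family string that [read_repeatmasker_out()] maps back
#' onto the same `repeat_class`.
#'
#' @param repeats a [repeat_records] data.frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_repeatmasker_out <- function(repeats, path) {
  class_str <- c(LTR = "LTR/ERV1", LINE = "LINE/CR1", DNA_transposon = "DNA/hAT",
                 tandem = "Tandem", small_RNA = "tRNA", satellite = "Satellite",
                 simple = "Simple_repeat", low_complexity = "Low_complexity",
                 other = "Unknown")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "   SW   perc perc perc  query     position in query      matching repeat        position in repeat",
    "score   div. del. ins.  sequence  begin   end   (left)   repeat   class/family  begin  end (left) ID",
    ""), con)
  if (nrow(repeats)) {
    len <- repeats$end - repeats$start + 1L
    writeLines(sprintf("%5d %4.1f %4.1f %4.1f %s %d %d (0) %s %s %s 1 %d (0) %d",
                       1000L, 10.0, 0.0, 0.0, repeats$seq_id, repeats$start,
                       repeats$end, ifelse(repeats$strand == "-", "C", "+"),
                       repeats$repeat_family, class_str[repeats$repeat_class],
                       len, seq_len(nrow(repeats))), con)
  }
  invisible(path)
}
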