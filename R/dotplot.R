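## K-mer anchored dot plots.  Exact shared k-mers (both orientations) replace
## inexact alignment seeds; tolerance to divergence between duplicated
## segments comes from chaining anchors across gaps, not from fuzzy matching.

## k-mer starts, skipping windows containing N and low-complexity windows
## (fewer than 3 distinct bases over the window, a DUST-like filter matching
## what megablast's default masking removes from seeding)
kmer_starts <- function(seq, k) {
  n <- nchar(seq) - k + 1L
  if (n < 1L) stop_hk("k = %d exceeds sequence length %d", k, nchar(seq))
  km <- substring(seq, 1:n, k:(n + k - 1L))
  keep <- !grepl("N", km, fixed = TRUE) &
    (grepl("A", km, fixed = TRUE) + grepl("C", km, fixed = TRUE) +
       grepl("G", km, fixed = TRUE) + grepl("T", km, fixed = TRUE)) >= 3L
  list(kmers = km[keep], pos = which(keep))
}

cross_positions <- function(ka, kb) {
  da <- data.table::data.table(kmer = ka$kmers, pos_a = ka$pos)
  db <- data.table::data.table(kmer = kb$kmers, pos_b = kb$pos)
  m <- merge(da, db, by = "kmer", allow.cartesian = TRUE)
  list(pos_a = m$pos_a, pos_b = m$pos_b)
}

#' Find exact k-mer anchors between two sequences
#'
#' Reports every pair of positions whose k-mers are equal (`forward`) or
#' reverse complements (`inverted`).  K-mers containing `N` are skipped.  In
#' a self comparison (`seq_b` missing or identical id) the trivial identity
#' diagonal (`pos_a == pos_b`, forward) is excluded.
#'
#' @param seq_a,seq_b single DNA strings (named or not); omit `seq_b` for a
#'   self comparison
#' @param k k-mer size (default 21, minimum 8)
#' @return data.frame of class `anchor_set` with `pos_a`, `pos_b` (1-based
#'   k-mer starts on the forward strands) and `orientation`; attribute `k`
#' @export
find_anchors <- function(seq_a, seq_b = NULL, k = 21) {
  if (k < 8) stop_hk("k must be at least 8")
  self <- is.null(seq_b)
  if (self) seq_b <- seq_a
  a <- toupper(unname(seq_a)); b <- toupper(unname(seq_b))
  ka <- kmer_starts(a, k)
  kb <- kmer_starts(b, k)
  fw <- cross_positions(ka, kb)
  ## inverted: k-mers of revcomp(b); start i there maps to forward start
  ## nchar(b) - i - k + 2 on b
  rb <- revcomp(b)
  krb <- kmer_starts(rb, k)
  inv <- cross_positions(ka, krb)
  inv_pos_b <- nchar(b) - inv$pos_b - k + 2L
  out <- data.frame(
    pos_a = c(fw$pos_a, inv$pos_a),
    pos_b = c(fw$pos_b, inv_pos_b),
    orientation = rep(c("forward", "inverted"),
                      c(length(fw$pos_a), length(inv$pos_a))),
    stringsAsFactors = FALSE)
  if (self)
    out <- out[!(out$orientation == "forward" & out$pos_a == out$pos_b), ,
               drop = FALSE]
  out <- out[order(out$orientation, out$pos_a, out$pos_b), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "k") <- k
  class(out) <- c("anchor_set", "data.frame")
  out
}

#' Chain collinear anchors into dot-plot segments
#'
#' Same-orientation anchors are grouped by single-linkage along their
#' diagonal (forward: `pos_b - pos_a`; inverted: `pos_b + pos_a`) with
#' diagonal offsets allowed to drift by at most `max_gap_bp`, then split
#' where consecutive anchor positions jump by more than `max_gap_bp`.
#' Chains spanning less than `min_span_bp` are discarded.
#'
#' @param anchors a [find_anchors()] result
#' @param max_gap_bp maximum diagonal drift and positional gap within a chain
#'   (default 2000)
#' @param min_span_bp minimum chain span kept (default 300)
#' @return data.frame of class `segment_chains` with `start_a`, `end_a`,
#'   `start_b`, `end_b`, `orientation`, `n_anchors`, `span_bp`
#' @export
chain_anchors <- function(anchors, max_gap_bp = 2000, min_span_bp = 300) {
  k <- attr(anchors, "k") %||% 21L
  empty <- data.frame(start_a = integer(0), end_a = integer(0),
                      start_b = integer(0), end_b = integer(0),
                      orientation = character(0), n_anchors = integer(0),
                      span_bp = integer(0), stringsAsFactors = FALSE)
  class(empty) <- c("segment_chains", "data.frame")
  attr(empty, "k") <- k
  if (nrow(anchors) == 0) return(empty)
  dt <- data.table::as.data.table(anchors)
  dt[, diagv := ifelse(orientation == "forward", pos_b - pos_a,
                       pos_b + pos_a)]
  data.table::setorder(dt, orientation, diagv, pos_a)
  dt[, band := cumsum(c(TRUE, diff(diagv) > max_gap_bp)),
     by = "orientation"]
  data.table::setorder(dt, orientation, band, pos_a)
  dt[, part := cumsum(c(TRUE, diff(pos_a) > max_gap_bp)),
     by = c("orientation", "band")]
  ch <- dt[, list(start_a = min(pos_a), end_a = max(pos_a) + k - 1L,
                  start_b = min(pos_b), end_b = max(pos_b) + k - 1L,
                  n_anchors = .N),
           by = c("orientation", "band", "part")]
  ch[, span_bp := pmax(end_a - start_a, end_b - start_b) + 1L]
  out <- as.data.frame(ch[, c("start_a", "end_a", "start_b", "end_b",
                              "orientation", "n_anchors", "span_bp")])
  out <- out[out$span_bp >= min_span_bp, , drop = FALSE]
  out <- out[order(out$start_a, out$start_b), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "k") <- k
  class(out) <- c("segment_chains", "data.frame")
  out
}

## reciprocal overlap of two intervals (fraction of the longer and shorter)
reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- pmin(e1, e2) - pmax(s1, s2) + 1
  ifelse(ov <= 0, 0, pmin(ov / (e1 - s1 + 1), ov / (e2 - s2 + 1)))
}

#' Call duplicated genomic blocks from chained dot-plot segments
#'
#' Chains whose two intervals BOTH span at least `min_block_bp` (computed
#' over all sequence pairs, self comparisons included) and whose anchor
#' density reaches `min_anchor_density` contribute their intervals as
#' duplicate copy candidates.  The density floor separates genuine
#' near-identical duplications (pairwise divergence of 4% still leaves
#' about 0.18 exact 21-mer anchors per bp) from diffuse chains glued
#' together out of scattered repeat-family matches (density well below
#' 0.01).  Candidates are merged by single-linkage at reciprocal interval
#' overlap of at least 50% into copies; copies linked by chains form a
#' block.  The archetype is the longest copy; per-copy orientation is
#' propagated from the archetype (taken as `direct`) through the chain
#' orientations, and completeness is the copy span over the archetype span.
#'
#' @param chain_list list of elements `list(seq_a =, seq_b =, chains =)`
#'   covering all pairwise comparisons (use [chain_all()] to build it)
#' @param min_block_bp minimum chain span treated as a segmental block
#'   (default 20000, separating multi-gene blocks from single-gene repeats)
#' @param full_threshold completeness at or above which a copy is called full
#'   (default 0.90)
#' @param min_anchor_density minimum `n_anchors / span_bp` for a block-scale
#'   chain (default 0.02)
#' @return data.frame of class `duplication_blocks`: one row per copy with
#'   `block_id`, `archetype_bp`, `seq_id`, `start`, `end`, `orientation`,
#'   `completeness`, `full`
#' @export
call_blocks <- function(chain_list, min_block_bp = 20000,
                        full_threshold = 0.90, min_anchor_density = 0.02) {
  empty <- data.frame(block_id = character(0), archetype_bp = integer(0),
                      seq_id = character(0), start = integer(0),
                      end = integer(0), orientation = character(0),
                      completeness = numeric(0), full = logical(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("duplication_blocks", "data.frame")
  ## collect copy candidates from both sides of every long chain
  cand <- list(); links <- list()
  for (cmp in chain_list) {
    ch <- cmp$chains
    min_side <- pmin(ch$end_a - ch$start_a, ch$end_b - ch$start_b) + 1L
    ch <- ch[min_side >= min_block_bp &
               ch$n_anchors / ch$span_bp >= min_anchor_density, , drop = FALSE]
    if (nrow(ch) == 0) next
    for (i in seq_len(nrow(ch))) {
      ia <- length(cand) + 1L
      cand[[ia]] <- data.frame(seq_id = cmp$seq_a, start = ch$start_a[i],
                               end = ch$end_a[i], stringsAsFactors = FALSE)
      ib <- length(cand) + 1L
      cand[[ib]] <- data.frame(seq_id = cmp$seq_b, start = ch$start_b[i],
                               end = ch$end_b[i], stringsAsFactors = FALSE)
      links[[length(links) + 1L]] <- c(ia, ib, ch$orientation[i] == "inverted")
    }
  }
  if (length(cand) == 0) return(empty)
  cand <- do.call(rbind, cand)
  n <- nrow(cand)
  ## single-linkage clustering of candidate intervals into copies
  copy_of <- seq_len(n)
  find_root <- function(i) { while (copy_of[i] != i) i <- copy_of[i]; i }
  for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
    if (cand$seq_id[i] != cand$seq_id[j]) next
    if (reciprocal_overlap(cand$start[i], cand$end[i],
                           cand$start[j], cand$end[j]) >= 0.5) {
      ri <- find_root(i); rj <- find_root(j)
      if (ri != rj) copy_of[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find_root, 1L)
  copy_id <- match(roots, unique(roots))
  n_copies <- max(copy_id)
  copies <- do.call(rbind, lapply(seq_len(n_copies), function(cid) {
    sel <- copy_id == cid
    data.frame(seq_id = cand$seq_id[sel][1],
               start = min(cand$start[sel]), end = max(cand$end[sel]),
               stringsAsFactors = FALSE)
  }))
  ## block = connected component of copies over chain links; edge parity
  ## (inverted = TRUE) carries relative orientation
  adj <- lapply(seq_len(n_copies), function(i) integer(0))
  inv_edge <- list()
  for (l in links) {
    u <- copy_id[l[1]]; v <- copy_id[l[2]]
    if (u == v) next   # a self chain fully merged into one copy
    adj[[u]] <- c(adj[[u]], v); adj[[v]] <- c(adj[[v]], u)
    inv_edge[[paste(min(u, v), max(u, v))]] <- as.logical(l[3])
  }
  comp <- rep(NA_integer_, n_copies)
  inverted <- rep(NA, n_copies)
  ncomp <- 0L
  for (s in order(copies$seq_id, copies$start)) {
    if (!is.na(comp[s])) next
    ncomp <- ncomp + 1L
    ## BFS from the longest copy of this component for orientation anchoring
    stack <- s; members <- integer(0)
    comp[s] <- ncomp
    while (length(stack)) {
      u <- stack[1]; stack <- stack[-1]
      members <- c(members, u)
      for (v in adj[[u]]) if (is.na(comp[v])) { comp[v] <- ncomp; stack <- c(stack, v) }
    }
    arch <- members[which.max(copies$end[members] - copies$start[members])]
    inverted[arch] <- FALSE
    stack <- arch
    while (length(stack)) {
      u <- stack[1]; stack <- stack[-1]
      for (v in adj[[u]]) {
        if (!is.na(inverted[v])) next
        flip <- inv_edge[[paste(min(u, v), max(u, v))]]
        inverted[v] <- xor(inverted[u], flip)
        stack <- c(stack, v)
      }
    }
  }
  ## keep components with >= 2 copies; stable ids in genomic order
  keep <- which(table(comp)[as.character(comp)] >= 2)
  if (length(keep) == 0) return(empty)
  res <- copies[keep, , drop = FALSE]
  res$comp <- comp[keep]
  res$inverted <- inverted[keep]
  comp_ids <- sort(unique(res$comp))
  first_key <- t(vapply(comp_ids, function(cc) {
    ix <- which(res$comp == cc)
    i <- ix[order(res$seq_id[ix], res$start[ix])][1]
    c(res$seq_id[i], sprintf("%012d", res$start[i]))
  }, c("", "")))
  ord <- order(first_key[, 1], first_key[, 2])
  bid_of <- setNames(paste0("B", seq_along(comp_ids)),
                     as.character(comp_ids[ord]))
  res$block_id <- bid_of[as.character(res$comp)]
  arch_bp <- tapply(res$end - res$start + 1L, res$block_id, max)
  res$archetype_bp <- as.integer(arch_bp[res$block_id])
  res$orientation <- ifelse(res$inverted, "inverted", "direct")
  res$completeness <- pmin(1, (res$end - res$start + 1) / res$archetype_bp)
  res$full <- res$completeness >= full_threshold
  res <- res[order(res$block_id, res$seq_id, res$start),
             c("block_id", "archetype_bp", "seq_id", "start", "end",
               "orientation", "completeness", "full")]
  rownames(res) <- NULL
  class(res) <- c("duplication_blocks", "data.frame")
  res
}

#' Chain anchors for every sequence pair (self pairs included)
#'
#' @param sequences named character vector of contigs
#' @param k k-mer size
#' @param max_gap_bp,min_span_bp see [chain_anchors()]
#' @return list of `list(seq_a, seq_b, chains)` suitable for [call_blocks()]
#' @export
chain_all <- function(sequences, k = 21, max_gap_bp = 2000,
                      min_span_bp = 300) {
  ids <- names(sequences)
  out <- list()
  for (i in seq_along(ids)) for (j in i:length(ids)) {
    anc <- if (i == j) find_anchors(sequences[[i]], k = k)
           else find_anchors(sequences[[i]], sequences[[j]], k = k)
    out[[length(out) + 1L]] <- list(
      seq_a = ids[i], seq_b = ids[j],
      chains = chain_anchors(anc, max_gap_bp = max_gap_bp,
                             min_span_bp = min_span_bp))
  }
  out
}

#' Export a dot plot and its chain coordinates
#'
#' Writes chain coordinates as TSV and, when `plot_path` is given, renders a
#' dot plot (forward traces rise, inverted traces fall; a self plot draws the
#' main diagonal as a reference line).
#'
#' @param chains a [chain_anchors()] result
#' @param tsv_path output TSV path
#' @param plot_path optional plot path (`.pdf` or `.png`)
#' @param seq_a_len,seq_b_len axis extents in bp (defaults: chain maxima)
#' @param self logical; draw the identity diagonal
#' @param main plot title
#' @return `tsv_path`, invisibly
#' @export
export_dotplot <- function(chains, tsv_path, plot_path = NULL,
                           seq_a_len = NULL, seq_b_len = NULL,
                           self = FALSE, main = "dot plot") {
  write.table(as.data.frame(chains), tsv_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(plot_path)) {
    xmax <- seq_a_len %||% max(c(chains$end_a, 1))
    ymax <- seq_b_len %||% max(c(chains$end_b, 1))
    if (grepl("\\.png$", plot_path)) {
      grDevices::png(plot_path, width = 900, height = 900)
    } else {
      grDevices::pdf(plot_path, width = 7, height = 7)
    }
    on.exit(grDevices::dev.off())
    graphics::plot(NA, xlim = c(1, xmax), ylim = c(1, ymax),
                   xlab = "sequence A (bp)", ylab = "sequence B (bp)",
                   main = main)
    if (self) graphics::abline(0, 1, col = "grey70", lty = 2)
    if (nrow(chains)) {
      fw <- chains$orientation == "forward"
      graphics::segments(chains$start_a[fw], chains$start_b[fw],
                         chains$end_a[fw], chains$end_b[fw], col = "black")
      graphics::segments(chains$start_a[!fw], chains$end_b[!fw],
                         chains$end_a[!fw], chains$start_b[!fw], col = "red")
    }
  }
  invisible(tsv_path)
}

#' Read chains written by [export_dotplot()]
#'
#' @param path TSV path
#' @return `segment_chains` data.frame
#' @export
read_chains_tsv <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  class(d) <- c("segment_chains", "data.frame")
  d
}
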