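#' Define a restriction enzyme recognition site
#'
#' @param name enzyme name, e.g. `"TaqI"`
#' @param site recognition sequence over `{A,C,G,T}`, e.g. `"TCGA"`
#' @param cut_offset bases after the site start (top strand) at which the cut
#'   falls; TaqI (`T^CGA`) cuts at offset 1
#' @return list of class `recognition_site`
#' @export
recognition_site <- function(name, site, cut_offset) {
  site <- toupper(site)
  if (grepl("[^ACGT]", site) || nchar(site) == 0)
    stop_hk("recognition site must be a non-empty string over {A,C,G,T}")
  if (cut_offset < 0 || cut_offset > nchar(site))
    stop_hk("cut_offset must lie in [0, %d]", nchar(site))
  structure(list(name = name, site = site, cut_offset = as.integer(cut_offset),
                 palindromic = identical(site, revcomp(site))),
            class = "recognition_site")
}

#' TaqI (`T^CGA`)
#' @export
TAQ1 <- function() recognition_site("TaqI", "TCGA", 1L)

## All between-base cut coordinates (number of bases left of the cut) on a
## linear sequence.  Palindromic sites need only the top strand; otherwise the
## bottom strand is scanned with the reverse-complement site.
cut_positions <- function(seq, enzyme) {
  find <- function(pat) {
    hits <- gregexpr(paste0("(?=", pat, ")"), seq, perl = TRUE)[[1]]
    if (hits[1] == -1) integer(0) else as.integer(hits)
  }
  cuts <- find(enzyme$site) + enzyme$cut_offset - 1L
  if (!enzyme$palindromic) {
    w <- nchar(enzyme$site)
    rc_starts <- find(revcomp(enzyme$site))
    ## a bottom-strand site at top positions [s, s+w-1] cuts w-offset bases
    ## into the site measured from its top-strand left end
    cuts <- c(cuts, rc_starts + (w - enzyme$cut_offset) - 1L)
  }
  cuts <- sort(unique(cuts))
  cuts[cuts >= 1L & cuts < nchar(seq)]
}

#' In-silico restriction digest of a linear sequence
#'
#' Cuts at every exact occurrence of the recognition site (overlapping
#' occurrences included; windows containing `N` never match and so are never
#' cut).  Fragment coordinates are 1-based inclusive; lengths always sum to
#' the sequence length and the fragment count is the cut count plus one.
#'
#' @param seq a single named or unnamed DNA string
#' @param enzyme a [recognition_site]
#' @param seq_id id recorded in the result (defaults to `names(seq)`)
#' @return list of class `digest_result` with `seq_id`, `cut_positions`
#'   (between-base coordinates) and data.frame `fragments`
#'   (`fragment_id`, `start`, `end`, `length_bp`)
#' @export
digest <- function(seq, enzyme, seq_id = NULL) {
  seq_id <- seq_id %||% names(seq) %||% "seq"
  seq <- toupper(unname(seq))
  if (!nzchar(seq)) stop_hk("cannot digest an empty sequence")
  cuts <- cut_positions(seq, enzyme)
  bounds <- c(0L, cuts, nchar(seq))
  frags <- data.frame(
    fragment_id = paste0(seq_id, "_f", seq_len(length(bounds) - 1L)),
    start = head(bounds, -1L) + 1L,
    end = tail(bounds, -1L),
    stringsAsFactors = FALSE)
  frags$length_bp <- frags$end - frags$start + 1L
  structure(list(seq_id = seq_id, cut_positions = cuts, fragments = frags),
            class = "digest_result")
}

## Smith-Waterman score under BLASTN-like scoring: match +1, mismatch -2,
## affine gaps (open 5, extend 2); N mismatches everything.  The strong
## mismatch/gap penalties keep random-sequence scores near zero so that a
## score threshold separates genuine duplex-forming homology cleanly.
sw_matrix <- local({
  mat <- NULL
  function() {
    if (is.null(mat)) {
      bases <- c("A", "C", "G", "T", "N")
      m <- matrix(-2, 5, 5, dimnames = list(bases, bases))
      diag(m) <- 1
      m["N", "N"] <- -2
      mat <<- m
    }
    mat
  }
})

local_align_score <- function(subject, probe) {
  Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(probe),
    subject = Biostrings::DNAString(subject),
    type = "local", substitutionMatrix = sw_matrix(),
    gapOpening = 5, gapExtension = 2, scoreOnly = TRUE)
}

#' Flag digest fragments that would hybridize with a probe
#'
#' A fragment is probe-positive when the optimal Smith-Waterman local
#' alignment between the fragment (either strand) and the probe, under
#' BLASTN-like scoring (match +1, mismatch -2, gap open 5 / extend 2),
#' reaches the score a `min_identity` ungapped match over `min_overlap_bp`
#' would earn: `min_overlap_bp * (3 * min_identity - 2)`.  The default 0.80
#' identity over 60 bp models stringent Southern hybridization conditions.
#'
#' @param dig a [digest()] result
#' @param seq the digested sequence (to extract fragment sequences)
#' @param probe a single DNA probe string (at least `min_overlap_bp` long)
#' @param min_identity minimum alignment identity (default 0.80)
#' @param min_overlap_bp minimum duplex length in bp (default 60)
#' @return the digest's `fragments` data.frame with logical `probe_hit` and
#'   numeric `sw_score` columns
#' @export
hybridize <- function(dig, seq, probe, min_identity = 0.80,
                      min_overlap_bp = 60) {
  probe <- toupper(unname(probe))
  if (!nzchar(probe)) stop_hk("probe must be non-empty")
  if (nchar(probe) < min_overlap_bp)
    stop_hk("probe (%d bp) is shorter than min_overlap_bp (%d)",
            nchar(probe), min_overlap_bp)
  seq <- toupper(unname(seq))
  frags <- dig$fragments
  threshold <- min_overlap_bp * (3 * min_identity - 2)
  sub <- substring(seq, frags$start, frags$end)
  ## strand symmetry: align the probe and its reverse complement
  probe_rc <- revcomp(probe)
  score <- vapply(sub, function(s) {
    max(local_align_score(s, probe), local_align_score(s, probe_rc))
  }, 0, USE.NAMES = FALSE)
  frags$sw_score <- score
  frags$probe_hit <- score >= threshold
  frags
}

#' Collapse fragment sizes into gel bands by co-migration
#'
#' Single-linkage merge of sizes whose pairwise relative difference (relative
#' to the smaller) is at most `tolerance`; a band's size is the mean of its
#' member sizes.  Bands are reported largest first, as on a gel.
#'
#' @param sizes numeric fragment or band sizes in bp (positive); may carry
#'   names used as member ids
#' @param tolerance relative co-migration window (default 0.05)
#' @return list of class `band_pattern` with data.frame `bands`
#'   (`size_bp`, `n_members`, `members`) and the tolerance
#' @export
to_band_pattern <- function(sizes, tolerance = 0.05) {
  if (length(sizes) == 0)
    return(structure(list(bands = data.frame(size_bp = numeric(0),
                                             n_members = integer(0),
                                             members = character(0)),
                          tolerance = tolerance),
                     class = "band_pattern"))
  if (any(sizes <= 0)) stop_hk("band sizes must be positive")
  ids <- names(sizes) %||% as.character(seq_along(sizes))
  o <- order(sizes)
  s <- as.numeric(sizes)[o]; ids <- ids[o]
  ## adjacent-link single linkage on sorted sizes
  newband <- c(TRUE, diff(s) / head(s, -1) > tolerance)
  grp <- cumsum(newband)
  bands <- data.frame(
    size_bp = as.numeric(tapply(s, grp, mean)),
    n_members = as.integer(tapply(s, grp, length)),
    members = as.character(tapply(ids, grp, paste, collapse = ",")),
    stringsAsFactors = FALSE)
  bands <- bands[order(-bands$size_bp), , drop = FALSE]
  rownames(bands) <- NULL
  structure(list(bands = bands, tolerance = tolerance),
            class = "band_pattern")
}

#' Match predicted to observed band patterns
#'
#' Greedy best-first one-to-one matching by smallest relative size error
#' (relative to the observed band), accepting pairs with error at most
#' `tolerance`; ties break toward the larger band.  Leftovers on either side
#' are reported unmatched.
#'
#' @param predicted,observed [to_band_pattern()] results (or plain numeric
#'   size vectors, which are wrapped at the same tolerance)
#' @param tolerance maximum relative size error for a match (default 0.05)
#' @return list of class `match_report` with data.frame `matches`
#'   (`predicted_bp`, `observed_bp`, `relative_error`),
#'   `unmatched_predicted`, `unmatched_observed`
#' @export
match_bands <- function(predicted, observed, tolerance = 0.05) {
  as_sizes <- function(x) {
    if (inherits(x, "band_pattern")) x$bands$size_bp else as.numeric(x)
  }
  p <- sort(as_sizes(predicted), decreasing = TRUE)
  o <- sort(as_sizes(observed), decreasing = TRUE)
  if (length(p) == 0 || length(o) == 0) {
    return(structure(list(matches = data.frame(predicted_bp = numeric(0),
                                               observed_bp = numeric(0),
                                               relative_error = numeric(0)),
                          unmatched_predicted = p, unmatched_observed = o),
                     class = "match_report"))
  }
  err <- abs(outer(p, o, "-")) / matrix(o, length(p), length(o), byrow = TRUE)
  used_p <- logical(length(p)); used_o <- logical(length(o))
  matches <- list()
  repeat {
    err_live <- err
    err_live[used_p, ] <- Inf
    err_live[, used_o] <- Inf
    best <- min(err_live)
    if (!is.finite(best) || best > tolerance) break
    cand <- which(err_live == best, arr.ind = TRUE)
    ## ties break toward the larger band (sizes sorted descending)
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]
    used_p[i] <- TRUE; used_o[j] <- TRUE
    matches[[length(matches) + 1L]] <-
      data.frame(predicted_bp = p[i], observed_bp = o[j],
                 relative_error = err[i, j])
  }
  matches <- if (length(matches)) do.call(rbind, matches) else
    data.frame(predicted_bp = numeric(0), observed_bp = numeric(0),
               relative_error = numeric(0))
  structure(list(matches = matches,
                 unmatched_predicted = p[!used_p],
                 unmatched_observed = o[!used_o]),
            class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf("<match_report> %d matched, %d unmatched predicted, %d unmatched observed\n",
              nrow(x$matches), length(x$unmatched_predicted),
              length(x$unmatched_observed)))
  invisible(x)
}

#' End-to-end virtual Southern over a set of contigs
#'
#' Digest each contig, flag probe-positive fragments, and collapse their
#' sizes into a predicted band pattern.
#'
#' @param sequences named character vector of contigs
#' @param probe DNA probe string
#' @param enzyme a [recognition_site] (default TaqI)
#' @param tolerance co-migration tolerance
#' @param min_identity,min_overlap_bp hybridization thresholds, see
#'   [hybridize()]
#' @return list with `fragments` (all flagged fragments across contigs) and
#'   `pattern` (the probe-positive [to_band_pattern()])
#' @export
predict_southern <- function(sequences, probe, enzyme = TAQ1(),
                             tolerance = 0.05, min_identity = 0.80,
                             min_overlap_bp = 60) {
  frags <- do.call(rbind, lapply(names(sequences), function(id) {
    d <- digest(sequences[[id]], enzyme, seq_id = id)
    f <- hybridize(d, sequences[[id]], probe,
                   min_identity = min_identity,
                   min_overlap_bp = min_overlap_bp)
    f$seq_id <- id
    f
  }))
  pos <- frags[frags$probe_hit, , drop = FALSE]
  pattern <- to_band_pattern(setNames(pos$length_bp, pos$fragment_id),
                             tolerance = tolerance)
  list(fragments = frags, pattern = pattern)
}
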