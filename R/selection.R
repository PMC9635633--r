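## Nei-Gojobori (1986) counting estimator of dN/dS with Jukes-Cantor
## correction, applied per structural segment of a codon alignment, and a
## Saitou-Nei neighbor-joining tree for grouping putative alleles.

.ng86 <- new.env(parent = emptyenv())

codon_split <- function(x) {
  n <- nchar(x)
  substring(x, seq(1, n, 3), seq(3, n, 3))
}

## per-codon count of potential synonymous sites (each position contributes
## the fraction of its 3 possible changes that preserve the amino acid;
## changes to stop codons count as nonsynonymous, so sites always sum to 3)
ng86_tables <- function() {
  if (!is.null(.ng86$syn_sites)) return(invisible())
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)
  bases <- c("A", "C", "G", "T")
  syn_sites <- setNames(numeric(64), codons)
  for (cd in codons) {
    s <- 0
    for (p in 1:3) {
      for (b in setdiff(bases, substr(cd, p, p))) {
        alt <- cd
        substr(alt, p, p) <- b
        if (gc[[alt]] == gc[[cd]]) s <- s + 1
      }
    }
    syn_sites[cd] <- s / 3
  }
  ## pathway-averaged synonymous / nonsynonymous difference counts for every
  ## ordered codon pair; minimal substitution pathways through stop codons
  ## are dropped from the average (unless every pathway is blocked)
  perms <- list(`1` = list(1L),
                `2` = list(c(1L, 2L), c(2L, 1L)),
                `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                           c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
  sd <- matrix(0, 64, 64, dimnames = list(codons, codons))
  nd <- matrix(0, 64, 64, dimnames = list(codons, codons))
  for (i in seq_len(64)) for (j in seq_len(64)) {
    c1 <- codons[i]; c2 <- codons[j]
    if (c1 == c2) next
    diff_pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    res <- matrix(0, 0, 2)   # rows: (syn, nonsyn) per pathway
    blocked <- matrix(0, 0, 2)
    for (ord in perms[[as.character(length(diff_pos))]]) {
      cur <- c1; s <- 0; n <- 0; hit_stop <- FALSE
      for (step in seq_along(ord)) {
        p <- diff_pos[ord[step]]
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        if (gc[[nxt]] == gc[[cur]]) s <- s + 1 else n <- n + 1
        if (step < length(ord) && gc[[nxt]] == "*") hit_stop <- TRUE
        cur <- nxt
      }
      if (hit_stop) blocked <- rbind(blocked, c(s, n))
      else res <- rbind(res, c(s, n))
    }
    if (nrow(res) == 0) res <- blocked
    sd[i, j] <- mean(res[, 1])
    nd[i, j] <- mean(res[, 2])
  }
  .ng86$syn_sites <- syn_sites
  .ng86$sd <- sd
  .ng86$nd <- nd
  invisible()
}

jc_correct <- function(p) {
  if (4 * p / 3 >= 1) return(NA_real_)    # saturated
  -0.75 * log(1 - 4 * p / 3)
}

#' Pairwise NG86 dN/dS over (a segment of) a codon alignment
#'
#' Potential synonymous/nonsynonymous sites are counted per codon from the
#' standard code (changes to stop codons count as nonsynonymous, so
#' `N_sites + S_sites = 3 * codons compared`) and averaged over the pair;
#' observed differences are averaged over all minimal substitution pathways,
#' excluding pathways through stop codons.  Proportions are Jukes-Cantor
#' corrected.  Ratio conventions: `dN = 0` gives ratio 0; `dS = 0` with
#' `dN > 0` is `undefined_dS`; `4p/3 >= 1` on either proportion is
#' `saturated` (both excluded from medians).
#'
#' @param codons_i,codons_j aligned codon strings (equal length, multiple of
#'   3); codon pairs containing gaps, ambiguous bases or stop codons are
#'   skipped and counted
#' @param mask optional integer vector of codon indices (1-based) to compare
#' @return list of class `dnds_estimate`: `n_codons_compared`, `n_skipped`,
#'   `N_sites`, `S_sites`, `Nd`, `Sd`, `pN`, `pS`, `dN`, `dS`, `ratio`,
#'   `status` (`"ok"`, `"zero_dN"`, `"undefined_dS"`, `"saturated"`,
#'   `"no_data"`)
#' @export
ng86_pair <- function(codons_i, codons_j, mask = NULL) {
  ng86_tables()
  if (nchar(codons_i) != nchar(codons_j))
    stop_hk("aligned sequences differ in length (%d vs %d)",
            nchar(codons_i), nchar(codons_j))
  if (nchar(codons_i) %% 3 != 0)
    stop_hk("sequence length %d is not a multiple of 3", nchar(codons_i))
  ci <- codon_split(toupper(codons_i))
  cj <- codon_split(toupper(codons_j))
  if (!is.null(mask)) {
    if (any(mask < 1 | mask > length(ci)))
      stop_hk("segment mask outside the %d-codon alignment", length(ci))
    ci <- ci[mask]; cj <- cj[mask]
  }
  gc <- Biostrings::GENETIC_CODE
  clean <- function(x) grepl("^[ACGT]{3}$", x) & gc[x] != "*"
  ok <- clean(ci) & clean(cj)
  ok[is.na(ok)] <- FALSE
  ncomp <- sum(ok)
  est <- list(n_codons_compared = ncomp, n_skipped = sum(!ok))
  if (ncomp == 0) {
    est <- c(est, list(N_sites = 0, S_sites = 0, Nd = 0, Sd = 0,
                       pN = NA_real_, pS = NA_real_, dN = NA_real_,
                       dS = NA_real_, ratio = NA_real_, status = "no_data"))
    class(est) <- "dnds_estimate"
    return(est)
  }
  ci <- ci[ok]; cj <- cj[ok]
  S <- (sum(.ng86$syn_sites[ci]) + sum(.ng86$syn_sites[cj])) / 2
  N <- 3 * ncomp - S
  Sd <- sum(.ng86$sd[cbind(ci, cj)])
  Nd <- sum(.ng86$nd[cbind(ci, cj)])
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  dN <- jc_correct(pN); dS <- jc_correct(pS)
  ## precedence: a pair with no nonsynonymous change is ratio 0 even when the
  ## synonymous proportion is saturated (tiny comparisons saturate easily)
  if (!is.na(dN) && dN == 0) {
    ratio <- 0; status <- "zero_dN"
  } else if (is.na(dN) || is.na(dS)) {
    ratio <- NA_real_; status <- "saturated"
  } else if (dS == 0) {
    ratio <- NA_real_; status <- "undefined_dS"
  } else {
    ratio <- dN / dS; status <- "ok"
  }
  est <- c(est, list(N_sites = N, S_sites = S, Nd = Nd, Sd = Sd,
                     pN = pN, pS = pS, dN = dN, dS = dS,
                     ratio = ratio, status = status))
  class(est) <- "dnds_estimate"
  est
}

#' Define a named partition of codon positions into structural segments
#'
#' @param segments named list; each element a list/matrix of 1-based
#'   inclusive codon ranges, e.g.
#'   `list(alpha1_helix = list(c(50, 86)), remainder = list(c(1, 49)))`
#' @param n_codons total codons in the target alignment (for bound checks)
#' @return list of class `segment_partition` mapping segment name to the
#'   integer codon indices it covers
#' @export
segment_partition <- function(segments, n_codons = NULL) {
  idx <- lapply(segments, function(rr) {
    unique(unlist(lapply(rr, function(r) seq.int(r[1], r[2]))))
  })
  all_idx <- unlist(idx)
  if (anyDuplicated(all_idx))
    stop_hk("segment ranges overlap at codon(s) %s",
            paste(unique(all_idx[duplicated(all_idx)]), collapse = ", "))
  if (!is.null(n_codons) && any(all_idx > n_codons))
    stop_hk("segment ranges exceed the %d-codon alignment", n_codons)
  structure(idx, class = "segment_partition")
}

#' Median dN/dS per structural segment over all sequence pairs
#'
#' Every unordered pair of alignment rows is evaluated with [ng86_pair()]
#' restricted to each segment's codons.  The median is taken over pairs with
#' a defined ratio (`ok`) or with `dN = 0` (ratio 0); `undefined_dS` and
#' `saturated` pairs are excluded and counted.
#'
#' @param msa a codon-mode [msa_alignment] with at least 2 rows
#' @param partition a [segment_partition]
#' @return data.frame of class `segment_summary` with `segment`,
#'   `median_dnds`, `n_pairs_used`, `n_pairs_excluded`
#' @export
segment_medians <- function(msa, partition) {
  if (msa$mode != "codon") stop_hk("segment_medians requires a codon alignment")
  if (n_rows(msa) < 2) stop_hk("at least 2 sequences required")
  pairs <- utils::combn(n_rows(msa), 2)
  out <- lapply(names(partition), function(seg) {
    mask <- partition[[seg]]
    ratios <- numeric(0); excluded <- 0L; usable <- 0L
    for (p in seq_len(ncol(pairs))) {
      e <- ng86_pair(msa$rows[pairs[1, p]], msa$rows[pairs[2, p]], mask = mask)
      if (e$status %in% c("ok", "zero_dN")) {
        ratios <- c(ratios, e$ratio)
      } else {
        excluded <- excluded + 1L
      }
      if (e$n_codons_compared > 0) usable <- usable + 1L
    }
    data.frame(segment = seg,
               median_dnds = if (length(ratios)) median(ratios) else NA_real_,
               n_pairs_used = length(ratios),
               n_pairs_excluded = excluded,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  class(res) <- c("segment_summary", "data.frame")
  res
}

#' Pairwise p-distance matrix of an alignment
#'
#' Proportion of differing residues over mutually non-gap columns.
#'
#' @param msa an [msa_alignment] with at least 2 rows
#' @return symmetric numeric matrix with zero diagonal
#' @export
p_distance_matrix <- function(msa) {
  if (n_rows(msa) < 2) stop_hk("at least 2 rows required")
  m <- msa_matrix(msa)
  gap <- m == "-" | m == "."
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(msa$ids, msa$ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    comp <- !gap[i, ] & !gap[j, ]
    if (!any(comp))
      stop_hk("no comparable columns between '%s' and '%s'",
              msa$ids[i], msa$ids[j])
    D[i, j] <- D[j, i] <- mean(m[i, comp] != m[j, comp])
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining with the Studier-Keppler Q criterion.  Ties in
#' Q are broken toward the lexicographically smallest taxon pair, making the
#' tree reproducible; negative branch-length estimates are clamped to zero
#' and flagged in the `"clamped"` attribute.  Additive matrices are recovered
#' exactly (topology and branch lengths).
#'
#' @param D symmetric distance matrix with zero diagonal and `n >= 3` labeled
#'   taxa
#' @return an unrooted `ape::phylo` tree
#' @export
nj_tree <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop_hk("'D' must be a square matrix")
  n <- nrow(D)
  if (n < 3) stop_hk("at least 3 taxa required")
  if (is.null(rownames(D))) rownames(D) <- colnames(D) <- paste0("t", seq_len(n))
  if (max(abs(D - t(D))) > 1e-9) stop_hk("distance matrix is not symmetric")
  if (any(diag(D) != 0)) stop_hk("distance matrix diagonal must be zero")
  if (any(D < 0)) stop_hk("negative distances are not allowed")
  labs <- rownames(D)
  node <- labs                 # newick subtree strings
  clamped <- FALSE
  br <- function(v) {
    if (v < 0) { clamped <<- TRUE; v <- 0 }
    sprintf("%.12g", v)
  }
  d <- D
  while (n > 3) {
    r <- rowSums(d)
    Q <- (n - 2) * d - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- apply(cand, 1, function(ij) paste(sort(labs[ij]), collapse = "\r"))
    pick <- cand[order(key)[1], ]
    i <- pick[1]; j <- pick[2]
    dij <- d[i, j]
    vi <- dij / 2 + (r[i] - r[j]) / (2 * (n - 2))
    vj <- dij - vi
    new_str <- sprintf("(%s:%s,%s:%s)", node[i], br(vi), node[j], br(vj))
    dk <- (d[i, ] + d[j, ] - dij) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    labs <- c(labs[keep], paste0("\x01", length(labs)))  # internal marker
    node <- c(node[keep], new_str)
    rownames(d2) <- colnames(d2) <- labs
    d <- d2
    n <- n - 1
  }
  v1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  v2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  v3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 node[1], br(v1), node[2], br(v2), node[3], br(v3))
  tree <- ape::read.tree(text = nwk)
  attr(tree, "clamped") <- clamped
  tree
}

#' Read a JSON segment-partition file
#'
#' Format: `{"alpha1_helix": [[50, 86]], "alpha2_helix": [[140, 176]],
#' "remainder": [[1, 49], [87, 139]]}` with 1-based inclusive codon indices.
#'
#' @param path JSON path
#' @param n_codons optional bound check
#' @return a [segment_partition]
#' @export
read_partition_json <- function(path, n_codons = NULL) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  segs <- lapply(raw, function(m) {
    m <- rbind(m)
    lapply(seq_len(nrow(m)), function(i) as.integer(m[i, ]))
  })
  segment_partition(segs, n_codons = n_codons)
}
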