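## Independent oracles used across the suite.  Each is written against the
## definition it checks, not against the implementation path.

## exhaustive codon-table lookup for translation
oracle_translate <- function(dna) {
  gc <- Biostrings::GENETIC_CODE
  n <- nchar(dna)
  out <- character(n / 3)
  for (i in seq_along(out)) {
    cod <- substr(dna, 3 * (i - 1) + 1, 3 * i)
    out[i] <- if (cod %in% names(gc)) gc[[cod]] else "X"
  }
  paste(out, collapse = "")
}

## brute-force Wu-Kabat tally of one alignment (rows = character vector)
oracle_vi <- function(rows) {
  m <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    col <- col[col != "-" & col != "."]
    if (length(col) == 0) return(NA_real_)
    tb <- table(col)
    length(tb) / (max(tb) / length(col))
  }, 0)
}

## quadratic-time Smith-Waterman (Gotoh) score: match +1, mismatch -2,
## affine gaps (open 5, extend 2) -- same scoring as hybridize()
oracle_sw_score <- function(a, b) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  H_prev <- numeric(m + 1)          # best ending anywhere
  E_prev <- rep(NEG, m + 1)         # gap in a (vertical)
  best <- 0
  for (i in seq_len(n)) {
    H <- numeric(m + 1)
    E <- rep(NEG, m + 1)
    Fg <- NEG                       # gap in b (horizontal), per row
    for (j in seq_len(m)) {
      E[j + 1] <- max(H_prev[j + 1] - 7, E_prev[j + 1] - 2)
      Fg <- max(H[j] - 7, Fg - 2)
      sub <- H_prev[j] + if (a[i] == b[j]) 1 else -2
      H[j + 1] <- max(0, sub, E[j + 1], Fg)
    }
    best <- max(best, max(H))
    H_prev <- H; E_prev <- E
  }
  best
}

## brute-force all-pairs k-mer comparison (both orientations)
oracle_anchors <- function(a, b, k, self = FALSE) {
  na <- nchar(a) - k + 1; nb <- nchar(b) - k + 1
  ka <- substring(a, 1:na, k:(na + k - 1))
  kb <- substring(b, 1:nb, k:(nb + k - 1))
  kb_rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(kb)))
  lowc <- function(km) {
    vapply(km, function(x) length(unique(strsplit(x, "")[[1]])) < 3, TRUE)
  }
  drop_a <- grepl("N", ka) | lowc(ka)
  drop_b <- grepl("N", kb) | lowc(kb)
  out <- list()
  for (i in which(!drop_a)) for (j in which(!drop_b)) {
    if (ka[i] == kb[j] && !(self && i == j))
      out[[length(out) + 1L]] <- c(i, j, 0L)
    if (ka[i] == kb_rc[j])
      out[[length(out) + 1L]] <- c(i, j, 1L)
  }
  if (length(out) == 0)
    return(data.frame(pos_a = integer(0), pos_b = integer(0),
                      orientation = character(0)))
  m <- do.call(rbind, out)
  d <- data.frame(pos_a = m[, 1], pos_b = m[, 2],
                  orientation = ifelse(m[, 3] == 1, "inverted", "forward"))
  d[order(d$orientation, d$pos_a, d$pos_b), ]
}

## independent NG86 oracle for a single codon pair: recursive pathway
## enumeration plus direct neighbor counting for sites
oracle_ng86_codon <- function(c1, c2) {
  gc <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  sites <- function(cod) {
    syn <- 0
    for (p in 1:3) for (b in bases[bases != substr(cod, p, p)]) {
      alt <- cod; substr(alt, p, p) <- b
      if (gc[[alt]] == gc[[cod]]) syn <- syn + 1
    }
    c(syn = syn / 3, nonsyn = 3 - syn / 3)
  }
  walk <- function(cur, target) {
    ## returns matrix of (syn, nonsyn, blocked) per complete pathway
    dp <- which(strsplit(cur, "")[[1]] != strsplit(target, "")[[1]])
    if (length(dp) == 0) return(matrix(c(0, 0, 0), 1))
    do.call(rbind, lapply(dp, function(p) {
      nxt <- cur
      substr(nxt, p, p) <- substr(target, p, p)
      step_syn <- as.numeric(gc[[nxt]] == gc[[cur]])
      blocked <- as.numeric(gc[[nxt]] == "*" && nxt != target)
      rest <- walk(nxt, target)
      cbind(rest[, 1] + step_syn, rest[, 2] + (1 - step_syn),
            pmax(rest[, 3], blocked))
    }))
  }
  pw <- walk(c1, c2)
  open <- pw[pw[, 3] == 0, , drop = FALSE]
  if (nrow(open) == 0) open <- pw
  list(sites_1 = sites(c1), sites_2 = sites(c2),
       sd = mean(open[, 1]), nd = mean(open[, 2]))
}

random_codon <- function(n, exclude_stops = TRUE) {
  gc <- Biostrings::GENETIC_CODE
  pool <- if (exclude_stops) names(gc)[gc != "*"] else names(gc)
  sample(pool, n, replace = TRUE)
}

## evolve a codon alignment: `mode` is "neutral" (accept any non-stop
## mutation) or "synonymous" (accept only amino-acid-preserving mutations at
## third codon positions, so that pairwise codon differences are single-site
## and unambiguously synonymous -- two-hit codons would otherwise pick up
## fractional nonsynonymous counts through pathway averaging)
evolve_codon_msa <- function(n_seq, n_codons, n_subs, mode = "neutral") {
  gc <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  anc <- paste(random_codon(n_codons), collapse = "")
  rows <- vapply(seq_len(n_seq), function(i) {
    s <- anc
    done <- 0
    while (done < n_subs) {
      p <- if (mode == "synonymous") 3 * sample.int(n_codons, 1)
           else sample.int(nchar(s), 1)
      b <- sample(bases[bases != substr(s, p, p)], 1)
      cand <- s
      substr(cand, p, p) <- b
      ci <- 3 * ((p - 1) %/% 3) + 1
      old_cod <- substr(s, ci, ci + 2); new_cod <- substr(cand, ci, ci + 2)
      if (gc[[new_cod]] == "*") next
      if (mode == "synonymous" && gc[[new_cod]] != gc[[old_cod]]) next
      s <- cand
      done <- done + 1
    }
    s
  }, "")
  msa_alignment(sprintf("s%02d", seq_len(n_seq)), rows, mode = "codon")
}

## random unrooted tree with branch lengths and its additive distance matrix
random_additive_matrix <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, rooted = FALSE)
  tr$edge.length <- round(runif(length(tr$edge.length), 0.05, 1), 4)
  D <- ape::cophenetic.phylo(tr)
  D <- D[sort(rownames(D)), sort(colnames(D))]
  list(tree = tr, D = D)
}

## vectorized reciprocal overlap of one interval against many
reciprocal_overlap_vec <- function(s1, e1, s2, e2) {
  ov <- pmin(e1, e2) - pmax(s1, s2) + 1
  ifelse(ov <= 0, 0, pmin(ov / (e1 - s1 + 1), ov / (e2 - s2 + 1)))
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## random DNA guaranteed to lack a given site
random_dna_without <- function(n, site) {
  s <- random_dna_str(n)
  while (grepl(site, s, fixed = TRUE))
    s <- sub(site, random_dna_str(nchar(site)), s, fixed = TRUE)
  s
}
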