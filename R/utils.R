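#' @importFrom stats median setNames runif rnorm rbinom
#' @importFrom utils read.delim write.table head tail combn
#' @importFrom data.table data.table as.data.table setorder := .N
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Base [round()] rounds half to even; tabulated genomic summaries in this
#' package use conventional "half-up" rounding instead.
#'
#' @param x numeric vector
#' @param digits decimal places to keep
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Reverse complement of a DNA string
#'
#' @param x character vector of DNA strings over {A,C,G,T,N}
#' @return character vector of reverse complements
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Run `code` with the RNG seeded to `seed`, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## Random DNA of length n (no Ns), vector-free scalar string.
random_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## Substitute a fraction `rate` of positions i.i.d. with a different base.
mutate_dna <- function(seq, rate) {
  if (rate <= 0 || nchar(seq) == 0) return(seq)
  n <- nchar(seq)
  k <- rbinom(1, n, rate)
  if (k == 0) return(seq)
  pos <- sample.int(n, k)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  for (p in pos) {
    alt <- setdiff(bases, ch[p])
    ch[p] <- alt[sample.int(length(alt), 1)]
  }
  paste(ch, collapse = "")
}

## Overwrite seq[start..end] with `piece` (1-based inclusive); lengths must match.
splice_into <- function(seq, start, piece) {
  stopifnot(start >= 1, start + nchar(piece) - 1 <= nchar(seq))
  substr(seq, start, start + nchar(piece) - 1) <- piece
  seq
}

stop_hk <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_scalar_num <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x))
    stop_hk("'%s' must be a single number", name)
}
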