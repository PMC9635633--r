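## Deterministic generator of MHCY-like haplotypes with ground truth: gene
## loci spaced roughly every 10 kb, ~40% interspersed-repeat occupancy,
## implanted segmental duplication blocks (direct/inverted, full/partial),
## a class I probe, and a virtual Southern "observed" band ladder.

.synth <- new.env(parent = emptyenv())

#' Fixed gene-template CDS sequences used by the generator
#'
#' Templates are fixed literals shipped with the package so that
#' predicted-protein type clustering of generated haplotypes is
#' deterministic.  Class I templates t02..t10 are point variants of t01 (a
#' few nonsynonymous codon substitutions each), mimicking protein types
#' defined by variable amino acids.
#'
#' @return data.frame with `family`, `template_id`, `seq`
#' @export
gene_templates <- function() {
  if (is.null(.synth$templates)) {
    path <- system.file("extdata", "gene_templates.fa", package = "haplokit")
    seqs <- read_fasta(path)
    parts <- strsplit(names(seqs), "|", fixed = TRUE)
    .synth$templates <- data.frame(
      family = vapply(parts, `[`, "", 1),
      template_id = vapply(parts, `[`, "", 2),
      seq = unname(seqs), stringsAsFactors = FALSE)
  }
  .synth$templates
}

## Small library of interspersed-repeat archetypes (deterministic literals;
## instances placed on a haplotype are mutated copies of these).
repeat_library <- function() {
  if (is.null(.synth$replib)) {
    .synth$replib <- with_seed(607451, {
      spec <- list(
        list("LTR", "GGLTR7-int", 1500), list("LTR", "ERV1-GG", 2200),
        list("LTR", "ERVL-GG", 900), list("LINE", "CR1-F", 2600),
        list("LINE", "CR1-B", 1200), list("DNA_transposon", "hAT-Charlie", 600),
        list("simple", "(TA)n", 120), list("low_complexity", "A-rich", 150),
        list("tandem", "CCCTC-sat", 200))
      data.frame(
        repeat_class = vapply(spec, function(s) s[[1]], ""),
        repeat_family = vapply(spec, function(s) s[[2]], ""),
        seq = vapply(spec, function(s) {
          cls <- s[[1]]; len <- s[[3]]
          if (cls == "simple") strrep("TA", len / 2)
          else if (cls == "low_complexity")
            paste(sample(c("A", "A", "A", "G"), len, replace = TRUE), collapse = "")
          else if (cls == "tandem") strrep("CCCTC", len / 5)
          else random_dna(len)
        }, ""), stringsAsFactors = FALSE)
    })
  }
  .synth$replib
}

#' Configuration for the synthetic haplotype generator
#'
#' Defaults state the emulated world: gene loci spaced ~10 kb with a family
#' mix proportional to the 45:41:8:8:4:1 census of a block-structured MHC-like
#' haplotype, 40% of bp in interspersed repeats, ~35% of loci pseudogenized,
#' and block copies diverging by 0.5% substitutions.
#'
#' @param contig_length_bp integer vector of contig lengths (one per contig)
#' @param gene_spacing_bp mean center-to-center gene spacing (default 10000)
#' @param family_mix named integer vector: exact locus count per family for
#'   the whole haplotype; default scales the 45:41:8:8:4:1 mix to one locus
#'   per ~6 kb of contig
#' @param class1_templates how many distinct class I templates (protein
#'   types) to cycle through (1..10, default 10)
#' @param pseudogene_fraction probability a placed locus is pseudogenized
#'   (premature stop injected; default 0.35)
#' @param repeat_fraction target fraction of total bp inside repeat
#'   elements (default 0.40)
#' @param block_specs list of duplication-block specs, each a list with
#'   `length_bp`, `n_copies`, `orientations` (`"direct"`/`"inverted"` per
#'   copy), `completeness` (fraction in (0,1] per copy), optional `ends`
#'   (`"5p"`/`"3p"` per copy, default `"5p"`) and optional `contigs`
#'   (contig index per copy, default round-robin)
#' @param divergence per-copy substitution rate applied to block copies
#'   (default 0.005)
#' @param repeat_divergence substitution rate applied to each placed repeat
#'   instance (default 0.15, so aged repeat copies do not masquerade as
#'   segmental duplications)
#' @param dropout optional data.frame (`seq_id`, `start`, `end`) of regions
#'   to treat as unclonable when deriving released contigs
#' @param observed_bands logical; also run the virtual Southern to emit an
#'   observed band ladder (default TRUE)
#' @param seed integer RNG seed; a fixed seed gives byte-identical output
#' @return validated list of class `haplotype_config`
#' @export
haplotype_config <- function(contig_length_bp = 200000,
                             gene_spacing_bp = 10000,
                             family_mix = NULL,
                             class1_templates = 10,
                             pseudogene_fraction = 0.35,
                             repeat_fraction = 0.40,
                             block_specs = list(),
                             divergence = 0.005,
                             repeat_divergence = 0.15,
                             dropout = NULL,
                             observed_bands = TRUE,
                             seed = 1) {
  total <- sum(contig_length_bp)
  if (is.null(family_mix)) {
    base <- c(MHCY_classI = 45, YLEC = 41, MHCY2B = 8, LENG9L = 8,
              ZNFY = 4, OZFL = 1)
    family_mix <- setNames(pmax(0L, as.integer(round(base * total / 639000))),
                           names(base))
    family_mix["OZFL"] <- 1L
  }
  if (repeat_fraction < 0 || repeat_fraction > 1)
    stop_hk("repeat_fraction must lie in [0, 1]")
  if (divergence < 0 || divergence > 0.2)
    stop_hk("divergence must lie in [0, 0.2]")
  for (bs in block_specs) {
    if (bs$length_bp >= min(contig_length_bp))
      stop_hk("block length %d is not smaller than the smallest contig",
              bs$length_bp)
    if (length(bs$orientations) != bs$n_copies ||
        length(bs$completeness) != bs$n_copies)
      stop_hk("block spec needs one orientation and completeness per copy")
    if (any(!bs$orientations %in% c("direct", "inverted")))
      stop_hk("orientations must be 'direct' or 'inverted'")
    if (any(bs$completeness <= 0 | bs$completeness > 1))
      stop_hk("completeness must lie in (0, 1]")
  }
  structure(list(contig_length_bp = as.integer(contig_length_bp),
                 gene_spacing_bp = gene_spacing_bp,
                 family_mix = family_mix,
                 class1_templates = as.integer(class1_templates),
                 pseudogene_fraction = pseudogene_fraction,
                 repeat_fraction = repeat_fraction,
                 block_specs = block_specs,
                 divergence = divergence,
                 repeat_divergence = repeat_divergence,
                 dropout = dropout,
                 observed_bands = isTRUE(observed_bands),
                 seed = as.integer(seed)),
            class = "haplotype_config")
}

## Inject a premature stop at ~40% of the CDS (keeps length and frame).
pseudogenize <- function(cds) {
  n_cod <- nchar(cds) / 3
  p <- max(2L, floor(0.4 * n_cod))
  substr(cds, 3 * (p - 1) + 1, 3 * p) <- "TAA"
  cds
}

#' Generate a synthetic haplotype with ground truth
#'
#' Contigs are assembled from random background DNA into which duplication
#' blocks (random-sequence archetypes containing their own repeat content)
#' are implanted per `block_specs`, gene loci are placed at roughly
#' `gene_spacing_bp` intervals on random strands in the inter-block space
#' (exact `family_mix` counts), and repeat elements are interspersed until
#' `repeat_fraction` of total bp is covered.  All placements are recorded as
#' ground truth.
#'
#' @param config a [haplotype_config]
#' @return list with `sequences` (named character vector) and `truth`, a
#'   list holding [feature_records] `features`, [repeat_records] `repeats`,
#'   data.frame `blocks` (one row per block copy), `probe`,
#'   `observed_bands` (sizes, descending; NULL unless requested),
#'   `dropped_regions`, and the `config`
#' @export
generate_haplotype <- function(config) {
  stopifnot(inherits(config, "haplotype_config"))
  with_seed(config$seed, generate_haplotype_impl(config))
}

generate_haplotype_impl <- function(cfg) {
  L <- cfg$contig_length_bp
  n_contig <- length(L)
  ids <- paste0("Contig", seq_len(n_contig))

  ## ---- plan block copies -------------------------------------------------
  copies <- list()   # per copy: block, len, width, orientation, end, contig
  for (b in seq_along(cfg$block_specs)) {
    bs <- cfg$block_specs[[b]]
    ends <- bs$ends %||% rep("5p", bs$n_copies)
    tigs <- bs$contigs %||% (((seq_len(bs$n_copies) - 1L) %% n_contig) + 1L)
    for (cc in seq_len(bs$n_copies)) {
      copies[[length(copies) + 1L]] <- list(
        block = b, len = bs$length_bp,
        width = as.integer(round(bs$length_bp * bs$completeness[cc])),
        orientation = bs$orientations[cc], end = ends[cc],
        completeness = bs$completeness[cc], contig = tigs[cc])
    }
  }
  ## capacity check before any output
  for (t in seq_len(n_contig)) {
    w <- sum(vapply(copies, function(cp) if (cp$contig == t) cp$width else 0L, 0L))
    slots <- sum(vapply(copies, function(cp) cp$contig == t, TRUE))
    if (w + (slots + 1L) * 3000L > L[t])
      stop_hk("capacity error: blocks (%d bp) do not fit contig %d (%d bp)",
              w, t, L[t])
  }

  ## ---- archetypes (random DNA + internal repeat content) -----------------
  archetypes <- lapply(cfg$block_specs, function(bs) {
    build_repeat_region(bs$length_bp, cfg$repeat_fraction,
                        cfg$repeat_divergence)
  })

  ## ---- place block slots per contig --------------------------------------
  seqs <- vapply(L, random_dna, "")
  names(seqs) <- ids
  slot_tab <- vector("list", n_contig)  # per contig: start/end/copy index
  for (t in seq_len(n_contig)) {
    idx <- which(vapply(copies, function(cp) cp$contig == t, TRUE))
    if (length(idx) == 0) next
    widths <- vapply(copies[idx], `[[`, 0L, "width")
    ngap <- length(idx) + 1L
    ## every inter-block gap gets >= 3 kb so neighboring blocks cannot fuse
    free <- L[t] - sum(widths) - ngap * 3000L
    gaps <- 3000L + tabulate(sample.int(ngap, free, replace = TRUE), ngap)
    starts <- integer(length(idx))
    pos <- 1L
    for (s in seq_along(idx)) {
      pos <- pos + gaps[s]
      starts[s] <- pos
      pos <- pos + widths[s]
    }
    slot_tab[[t]] <- data.frame(start = starts, end = starts + widths - 1L,
                                copy = idx)
  }

  ## ---- write copies into contigs, lift repeat truth ----------------------
  rep_truth <- list()
  blk_truth <- list()
  for (t in seq_len(n_contig)) {
    st <- slot_tab[[t]]
    if (is.null(st)) next
    for (r in seq_len(nrow(st))) {
      cp <- copies[[st$copy[r]]]
      arch <- archetypes[[cp$block]]
      w <- cp$width
      off0 <- if (cp$end == "5p") 0L else cp$len - w
      piece <- substr(arch$seq, off0 + 1L, off0 + w)
      reps <- arch$repeats[arch$repeats$start > off0 &
                             arch$repeats$end <= off0 + w, , drop = FALSE]
      reps$start <- reps$start - off0; reps$end <- reps$end - off0
      if (cp$orientation == "inverted") {
        piece <- revcomp(piece)
        ns <- w - reps$end + 1L; ne <- w - reps$start + 1L
        reps$start <- ns; reps$end <- ne
        reps$strand <- ifelse(reps$strand == "+", "-", "+")
      }
      piece <- mutate_dna(piece, cfg$divergence)
      seqs[t] <- splice_into(seqs[t], st$start[r], piece)
      if (nrow(reps)) {
        reps$seq_id <- ids[t]
        reps$start <- reps$start + st$start[r] - 1L
        reps$end <- reps$end + st$start[r] - 1L
        rep_truth[[length(rep_truth) + 1L]] <- reps
      }
      blk_truth[[length(blk_truth) + 1L]] <- data.frame(
        block_id = paste0("B", cp$block), archetype_bp = cp$len,
        seq_id = ids[t], start = st$start[r], end = st$end[r],
        orientation = cp$orientation, completeness = cp$completeness,
        full = cp$completeness >= 0.90, stringsAsFactors = FALSE)
    }
  }

  ## ---- background free intervals (outside blocks) ------------------------
  free_iv <- lapply(seq_len(n_contig), function(t) {
    st <- slot_tab[[t]]
    if (is.null(st)) return(data.frame(start = 1L, end = L[t]))
    occ <- st[order(st$start), , drop = FALSE]
    s <- c(1L, occ$end + 1L); e <- c(occ$start - 1L, L[t])
    keep <- s <= e
    data.frame(start = s[keep], end = e[keep])
  })

  ## ---- place genes at ~gene_spacing in background ------------------------
  tpl <- gene_templates()
  ci <- which(tpl$family == "MHCY_classI")
  drop <- ci[-seq_len(min(cfg$class1_templates, length(ci)))]
  if (length(drop)) tpl <- tpl[-drop, , drop = FALSE]
  gene_plan <- unlist(mapply(function(fam, k) {
    if (k <= 0) return(character(0))
    t_ids <- tpl$template_id[tpl$family == fam]
    if (length(t_ids) == 0) stop_hk("no template for family %s", fam)
    paste(fam, rep_len(t_ids, k), sep = "\r")
  }, names(cfg$family_mix), cfg$family_mix, SIMPLIFY = FALSE), use.names = FALSE)
  gene_plan <- sample(gene_plan)   # shuffle genomic order of families
  ## center-to-center step: the configured spacing, tightened when the
  ## family mix needs more loci than the inter-block background can hold at
  ## that spacing (density, not spacing, is the contract for exact counts)
  bg_total <- sum(vapply(free_iv, function(iv) sum(iv$end - iv$start + 1L), 0L))
  step_mean <- min(cfg$gene_spacing_bp,
                   floor(0.85 * bg_total / (length(gene_plan) + 1L)))
  step_sd <- step_mean / 6
  feat_truth <- list()
  occupied <- lapply(seq_len(n_contig), function(t) list())  # gene+repeat ivs
  gi <- 0L
  fam_counter <- setNames(integer(length(unique(tpl$family))), unique(tpl$family))
  for (t in seq_len(n_contig)) {
    for (iv in seq_len(nrow(free_iv[[t]]))) {
      lo <- free_iv[[t]]$start[iv]; hi <- free_iv[[t]]$end[iv]
      pos <- lo + max(100L, round(abs(rnorm(1, step_mean / 2,
                                            step_sd))))
      while (gi < length(gene_plan)) {
        parts <- strsplit(gene_plan[gi + 1L], "\r", fixed = TRUE)[[1]]
        fam <- parts[1]; tid <- parts[2]
        cds <- tpl$seq[tpl$family == fam & tpl$template_id == tid]
        glen <- nchar(cds)
        if (pos + glen - 1L > hi) break
        gi <- gi + 1L
        pseudo <- runif(1) < cfg$pseudogene_fraction
        if (pseudo) cds <- pseudogenize(cds)
        strand <- sample(c("+", "-"), 1)
        insert <- if (strand == "-") revcomp(cds) else cds
        seqs[t] <- splice_into(seqs[t], pos, insert)
        fam_counter[fam] <- fam_counter[fam] + 1L
        feat_truth[[length(feat_truth) + 1L]] <- data.frame(
          seq_id = ids[t], family = fam,
          locus_id = sprintf("%s_%02d", fam, fam_counter[fam]),
          start = pos, end = pos + glen - 1L, strand = strand,
          pseudogene = pseudo, type_label = NA_character_,
          full_length = !pseudo, template_id = tid, stringsAsFactors = FALSE)
        occupied[[t]][[length(occupied[[t]]) + 1L]] <- c(pos, pos + glen - 1L)
        step <- max(glen + 200L, round(rnorm(1, step_mean, step_sd)))
        pos <- pos + step
      }
    }
  }
  if (gi < length(gene_plan))
    stop_hk("capacity error: %d of %d genes do not fit the background space",
            length(gene_plan) - gi, length(gene_plan))

  ## ---- intersperse repeats up to repeat_fraction -------------------------
  target_bp <- round(cfg$repeat_fraction * sum(L))
  placed_bp <- sum(vapply(rep_truth,
                          function(d) sum(as.numeric(d$end - d$start + 1L)), 0))
  bg <- place_background_repeats(seqs, free_iv, occupied,
                                 target_bp - placed_bp,
                                 cfg$repeat_divergence)
  seqs <- bg$seqs
  repeats <- do.call(rbind, c(rep_truth, list(bg$repeats)))
  if (is.null(repeats))
    repeats <- data.frame(seq_id = character(0), repeat_class = character(0),
                          repeat_family = character(0), start = integer(0),
                          end = integer(0), strand = character(0))
  repeats <- repeats[order(repeats$seq_id, repeats$start), , drop = FALSE]
  rownames(repeats) <- NULL
  repeats <- repeat_records(repeats$seq_id, repeats$repeat_class,
                            repeats$repeat_family, repeats$start,
                            repeats$end, repeats$strand)

  feats <- do.call(rbind, feat_truth)
  features <- feature_records(feats$seq_id, feats$family, feats$locus_id,
                              feats$start, feats$end, feats$strand,
                              feats$pseudogene, feats$type_label,
                              feats$full_length,
                              seq_lengths = setNames(nchar(seqs), ids))
  features$template_id <- feats$template_id

  blocks <- if (length(blk_truth)) do.call(rbind, blk_truth) else
    data.frame(block_id = character(0), archetype_bp = integer(0),
               seq_id = character(0), start = integer(0), end = integer(0),
               orientation = character(0), completeness = numeric(0),
               full = logical(0))

  probe <- substr(tpl$seq[tpl$family == "MHCY_classI"][1], 61, 460)
  observed <- NULL
  if (cfg$observed_bands)
    observed <- generate_observed_bands(seqs, probe, TAQ1(), cfg$dropout)

  list(sequences = seqs,
       truth = list(features = features, repeats = repeats, blocks = blocks,
                    probe = probe, observed_bands = observed,
                    dropped_regions = cfg$dropout, config = cfg))
}

## Random region of `len` bp containing repeat elements covering
## ~`fraction` of it; returns seq plus repeat records in region offsets.
build_repeat_region <- function(len, fraction, repeat_divergence) {
  seq <- random_dna(len)
  free <- data.frame(start = 1L, end = len)
  occ <- list()
  bg <- place_background_repeats(setNames(seq, "r"), list(free), list(occ),
                                 round(fraction * len), repeat_divergence)
  reps <- bg$repeats
  reps$seq_id <- NULL
  list(seq = unname(bg$seqs), repeats = reps)
}

## Fill background intervals with mutated copies of repeat-library elements
## until `need_bp` additional bp are covered.  `occupied` holds per-contig
## gene intervals to avoid.  Returns updated sequences and repeat records.
place_background_repeats <- function(seqs, free_iv, occupied, need_bp,
                                     divergence) {
  lib <- repeat_library()
  te <- which(lib$repeat_class %in% c("LTR", "LINE", "DNA_transposon"))
  te_w <- c(2, 4, 1, 2, 1, 0.5)[seq_along(te)]
  small <- which(!(lib$repeat_class %in% c("LTR", "LINE", "DNA_transposon")))
  ids <- names(seqs)
  out <- list()
  ## free slots = background minus occupied gene intervals, maintained as a
  ## shrinking pool per contig
  pool <- lapply(seq_along(ids), function(t) {
    iv <- free_iv[[t]]
    slots <- Map(function(s, e) c(s, e), iv$start, iv$end)
    for (g in occupied[[t]]) {
      slots <- unlist(lapply(slots, function(sl) {
        if (g[2] < sl[1] || g[1] > sl[2]) return(list(sl))
        res <- list()
        if (g[1] > sl[1]) res <- c(res, list(c(sl[1], g[1] - 1L)))
        if (g[2] < sl[2]) res <- c(res, list(c(g[2] + 1L, sl[2])))
        res
      }), recursive = FALSE)
    }
    slots
  })
  placed <- 0L
  ## a light scatter of small repeats first (~1% of the need), then TEs
  small_quota <- max(0L, round(0.03 * need_bp))
  draw <- function(kind) {
    if (kind == "small") small[sample.int(length(small), 1)]
    else sample(te, 1, prob = te_w)
  }
  while (placed < need_bp) {
    kind <- if (placed < small_quota) "small" else "te"
    li <- draw(kind)
    el <- lib$seq[li]
    el_len <- nchar(el)
    ## pick a contig/slot able to hold at least 80 bp
    cand <- list()
    for (t in seq_along(pool)) for (s in seq_along(pool[[t]])) {
      sl <- pool[[t]][[s]]
      if (sl[2] - sl[1] + 1L >= 80L)
        cand[[length(cand) + 1L]] <- c(t, s, sl[2] - sl[1] + 1L)
    }
    if (length(cand) == 0) break     # background exhausted
    wts <- vapply(cand, `[`, 0, 3)
    pick <- cand[[sample.int(length(cand), 1, prob = wts)]]
    t <- pick[1]; s <- pick[2]
    sl <- pool[[t]][[s]]
    w <- min(el_len, sl[2] - sl[1] + 1L, need_bp - placed + 49L)
    w <- max(w, 50L)
    w <- min(w, sl[2] - sl[1] + 1L)
    off <- sample.int(sl[2] - sl[1] + 2L - w, 1) + sl[1] - 1L
    piece <- mutate_dna(substr(el, 1, w), divergence)
    strand <- sample(c("+", "-"), 1)
    if (strand == "-") piece <- revcomp(piece)
    seqs[t] <- splice_into(seqs[t], off, piece)
    out[[length(out) + 1L]] <- data.frame(
      seq_id = ids[t], repeat_class = lib$repeat_class[li],
      repeat_family = lib$repeat_family[li], start = off,
      end = off + w - 1L, strand = strand, stringsAsFactors = FALSE)
    placed <- placed + w
    ## shrink the slot
    repl <- list()
    if (off - 1L >= sl[1]) repl <- c(repl, list(c(sl[1], off - 1L)))
    if (off + w <= sl[2]) repl <- c(repl, list(c(off + w, sl[2])))
    pool[[t]] <- c(pool[[t]][-s], repl)
  }
  reps <- if (length(out)) do.call(rbind, out) else
    data.frame(seq_id = character(0), repeat_class = character(0),
               repeat_family = character(0), start = integer(0),
               end = integer(0), strand = character(0),
               stringsAsFactors = FALSE)
  list(seqs = seqs, repeats = reps)
}

#' Excise dropout regions from contigs
#'
#' Models the part of a haplotype not captured in clones: the returned
#' contigs are the released (truncated) sequences on which predictions are
#' made, while the full sequences remain the physical truth.
#'
#' @param sequences named character vector of contigs
#' @param dropout data.frame (`seq_id`, `start`, `end`) or NULL
#' @return named character vector with the regions removed
#' @export
apply_dropout <- function(sequences, dropout) {
  if (is.null(dropout) || nrow(dropout) == 0) return(sequences)
  for (i in seq_len(nrow(dropout))) {
    id <- dropout$seq_id[i]
    s <- sequences[[id]]
    sequences[[id]] <- paste0(substr(s, 1, dropout$start[i] - 1L),
                              substr(s, dropout$end[i] + 1L, nchar(s)))
  }
  sequences
}

#' Generate the observed Southern band ladder for a haplotype
#'
#' Runs the in-silico digest and probe hybridization on the FULL sequences
#' (dropout regions included, as genomic DNA on a blot would contain them)
#' and returns the band sizes, largest first.  Bands arising only from
#' dropout regions are thereby observed downstream but absent from
#' predictions made on the truncated contigs.
#'
#' @param sequences full-length named contig sequences
#' @param probe DNA probe string
#' @param enzyme a [recognition_site] (default TaqI)
#' @param dropout ignored except for documentation symmetry: observed bands
#'   always come from the full sequences
#' @param tolerance gel co-migration tolerance (default 0.05)
#' @return numeric band sizes, sorted descending (possibly length 0)
#' @export
generate_observed_bands <- function(sequences, probe, enzyme = TAQ1(),
                                    dropout = NULL, tolerance = 0.05) {
  ps <- predict_southern(sequences, probe, enzyme, tolerance = tolerance)
  sort(ps$pattern$bands$size_bp, decreasing = TRUE)
}

#' Generate a protein alignment with controlled per-column polymorphism
#'
#' Non-listed columns are invariant (a fixed residue per column);
#' listed columns receive residues at exact deterministic counts derived
#' from the requested frequencies (largest-remainder apportionment), then
#' shuffled across rows under the seed.  The expected Wu-Kabat VI of each
#' engineered column is therefore computable in closed form.
#'
#' @param n_rows number of sequences
#' @param width alignment width in columns
#' @param polymorphic_cols named list: `list("12" = c(A = 10/15, S = 5/15))`
#'   mapping column index to residue frequencies (must sum to 1)
#' @param seed RNG seed
#' @return a protein-mode [msa_alignment]
#' @export
generate_class1_alignment <- function(n_rows, width, polymorphic_cols = list(),
                                      seed = 1) {
  cols <- as.integer(names(polymorphic_cols))
  if (length(cols) && any(is.na(cols) | cols < 1 | cols > width))
    stop_hk("polymorphic column index outside alignment width %d", width)
  with_seed(seed, {
    aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    m <- matrix(rep(sample(aas, width, replace = TRUE), each = n_rows),
                nrow = n_rows)
    for (ci in seq_along(cols)) {
      freq <- polymorphic_cols[[ci]]
      if (abs(sum(freq) - 1) > 1e-6)
        stop_hk("frequencies for column %d sum to %.3f, not 1",
                cols[ci], sum(freq))
      raw <- freq * n_rows
      cnt <- floor(raw)
      rem <- n_rows - sum(cnt)
      if (rem > 0) {
        o <- order(raw - cnt, decreasing = TRUE)
        cnt[o[seq_len(rem)]] <- cnt[o[seq_len(rem)]] + 1
      }
      m[, cols[ci]] <- sample(rep(names(freq), times = cnt))
    }
    msa_alignment(sprintf("seq%02d", seq_len(n_rows)),
                  apply(m, 1, paste, collapse = ""), mode = "protein")
  })
}

#' Write a generated haplotype and its truth to disk
#'
#' Emits contig FASTA, probe FASTA, feature GFF3, RepeatMasker-style .out,
#' a JSON truth file (blocks, dropped regions, config echo) and a TSV
#' observed-band list.
#'
#' @param hap a [generate_haplotype()] result
#' @param outdir output directory (created if needed)
#' @return named vector of written paths, invisibly
#' @export
write_haplotype <- function(hap, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(contigs = file.path(outdir, "contigs.fa"),
             probe = file.path(outdir, "probe.fa"),
             features = file.path(outdir, "features.gff3"),
             repeats = file.path(outdir, "repeats.out"),
             truth = file.path(outdir, "truth.json"),
             bands = file.path(outdir, "observed_bands.tsv"))
  write_fasta(hap$sequences, paths["contigs"])
  write_fasta(c(probe = hap$truth$probe), paths["probe"])
  write_gff3(hap$truth$features, paths["features"])
  write_repeatmasker_out(hap$truth$repeats, paths["repeats"])
  jsonlite::write_json(
    list(blocks = hap$truth$blocks,
         dropped_regions = hap$truth$dropped_regions,
         config = hap$truth$config[setdiff(names(hap$truth$config),
                                           c("dropout"))]),
    paths["truth"], auto_unbox = TRUE, digits = NA, null = "null")
  bands <- hap$truth$observed_bands %||% numeric(0)
  writeLines(c("size_bp", format(bands, scientific = FALSE, trim = TRUE)),
             paths["bands"])
  invisible(paths)
}
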