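test_that("a sequence vs its reverse complement gives the inverted anti-diagonal", {
  withr::with_seed(61, {
    s <- random_dna_str(300)
    anc <- find_anchors(s, revcomp(s), k = 21)
    inv <- anc[anc$orientation == "inverted", ]
    expect_gt(nrow(inv), 200)
    ## anti-diagonal: pos_a + pos_b constant = L - k + 2
    expect_true(all(inv$pos_a + inv$pos_b == 300 - 21 + 2))
  })
})

test_that("random self-comparison yields no off-diagonal anchors", {
  withr::with_seed(62, {
    s <- random_dna_str(10000)
    anc <- find_anchors(s, k = 21)
    expect_equal(nrow(anc[anc$orientation == "forward", ]), 0)
  })
})

test_that("X + spacer + X produces forward anchors at the implant offset", {
  withr::with_seed(63, {
    x <- random_dna_str(1000)
    spacer <- random_dna_str(500)
    s <- paste0(x, spacer, x)
    anc <- find_anchors(s, k = 21)
    fw <- anc[anc$orientation == "forward" & anc$pos_b > anc$pos_a, ]
    expect_true(all(fw$pos_b - fw$pos_a == 1500))
    expect_gte(nrow(fw), 1000 - 21 + 1 - 50)  # minus low-complexity skips
  })
})

test_that("find_anchors equals the brute-force all-pairs scan", {
  withr::with_seed(64, {
    x <- random_dna_str(120)
    a <- paste0(random_dna_str(200), x, random_dna_str(100))
    b <- paste0(random_dna_str(50), revcomp(x), random_dna_str(250),
                substr(x, 10, 80))
    got <- find_anchors(a, b, k = 12)
    want <- oracle_anchors(a, b, 12)
    expect_equal(got$pos_a, want$pos_a)
    expect_equal(got$pos_b, want$pos_b)
    expect_equal(got$orientation, want$orientation)
    ## self comparison excludes the identity diagonal
    gs <- find_anchors(a, k = 12)
    ws <- oracle_anchors(a, a, 12, self = TRUE)
    expect_equal(nrow(gs), nrow(ws))
  })
})

test_that("anchor symmetry: swapping inputs swaps coordinates", {
  withr::with_seed(65, {
    x <- random_dna_str(200)
    a <- paste0(random_dna_str(100), x)
    b <- paste0(x, random_dna_str(150))
    ab <- find_anchors(a, b, k = 15)
    ba <- find_anchors(b, a, k = 15)
    swapped <- ba[order(ba$orientation, ba$pos_b, ba$pos_a), ]
    expect_equal(ab$pos_a, swapped$pos_b)
    expect_equal(ab$pos_b, swapped$pos_a)
    expect_equal(ab$orientation, swapped$orientation)
  })
})

test_that("chaining merges collinear anchors and splits across gaps", {
  withr::with_seed(66, {
    x <- random_dna_str(1000)
    y <- random_dna_str(800)
    spine <- random_dna_str(6000)
    ## two implants separated by > max_gap on both axes
    a <- paste0(x, spine, y)
    b <- paste0(random_dna_str(300), x, random_dna_str(5000), y)
    ch <- chain_anchors(find_anchors(a, b, k = 21), max_gap_bp = 2000,
                        min_span_bp = 300)
    fw <- ch[ch$orientation == "forward", ]
    expect_equal(nrow(fw), 2)
    expect_gte(max(fw$span_bp), 800 - 21 + 1)

    ## single exact implant: one forward chain spanning >= L - k + 1
    one <- chain_anchors(find_anchors(paste0(x, spine), paste0(spine, x),
                                      k = 21))
    ## keep the x-derived chain (spine matches itself too)
    expect_true(any(one$span_bp >= 1000 - 21 + 1))

    expect_equal(nrow(chain_anchors(find_anchors(random_dna_str(500),
                                                 random_dna_str(500)))), 0)
  })
})

test_that("reverse-complementing one input flips chain orientations", {
  withr::with_seed(67, {
    x <- random_dna_str(2000)
    a <- paste0(random_dna_str(500), x, random_dna_str(400))
    b <- paste0(random_dna_str(200), x, random_dna_str(300))
    ch1 <- chain_anchors(find_anchors(a, b, k = 21))
    ch2 <- chain_anchors(find_anchors(a, revcomp(b), k = 21))
    expect_equal(sort(unique(ch1$orientation)), "forward")
    expect_equal(sort(unique(ch2$orientation)), "inverted")
    ## intervals map: start_b' = L - end_b + 1
    L <- nchar(b)
    expect_equal(sort(L - ch2$end_b + 1), sort(ch1$start_b))
    expect_equal(ch1$start_a, ch2$start_a)
  })
})

test_that("call_blocks recovers implanted duplication blocks exactly", {
  cfg <- haplotype_config(
    contig_length_bp = c(120000, 90000),
    family_mix = c(MHCY_classI = 4, YLEC = 2),
    repeat_fraction = 0.35, divergence = 0,
    block_specs = list(list(length_bp = 30000, n_copies = 2,
                            orientations = c("direct", "inverted"),
                            completeness = c(1, 1))),
    observed_bands = FALSE, seed = 68)
  hap <- generate_haplotype(cfg)
  ## zero divergence: the inverted copy is an exact reverse complement
  tb <- hap$truth$blocks
  s1 <- substr(hap$sequences[tb$seq_id[1]], tb$start[1], tb$end[1])
  s2 <- substr(hap$sequences[tb$seq_id[2]], tb$start[2], tb$end[2])
  expect_identical(unname(s2), unname(revcomp(s1)))

  blocks <- call_blocks(chain_all(hap$sequences))
  expect_equal(length(unique(blocks$block_id)), 1)
  expect_equal(nrow(blocks), 2)
  expect_setequal(blocks$orientation, c("direct", "inverted"))
  expect_true(all(blocks$full))
  ## intervals match truth within k-mer edge effects
  m <- merge(blocks, tb, by = "seq_id")
  expect_true(all(abs(m$start.x - m$start.y) <= 100))
  expect_true(all(abs(m$end.x - m$end.y) <= 100))
})

test_that("partial copies are flagged partial with correct completeness", {
  ## two full copies fix the archetype span; the 5' half copy is partial
  ## (with a lone full+partial pair only the shared segment is observable,
  ## so completeness is measured against the longest detected copy)
  cfg <- haplotype_config(
    contig_length_bp = 160000,
    family_mix = c(MHCY_classI = 3),
    repeat_fraction = 0.3, divergence = 0,
    block_specs = list(list(length_bp = 40000, n_copies = 3,
                            orientations = c("direct", "direct", "direct"),
                            completeness = c(1, 1, 0.5))),
    observed_bands = FALSE, seed = 69)
  hap <- generate_haplotype(cfg)
  blocks <- call_blocks(chain_all(hap$sequences))
  expect_equal(nrow(blocks), 3)
  expect_equal(sort(blocks$full), c(FALSE, TRUE, TRUE))
  expect_equal(min(blocks$completeness), 0.5, tolerance = 0.02)

  ## nothing above min_block_bp: empty call set
  expect_equal(nrow(call_blocks(chain_all(c(x = random_dna_str(5000))))), 0)
})

test_that("dot-plot export round-trips chains and renders a plot", {
  withr::with_seed(70, {
    x <- random_dna_str(1500)
    a <- paste0(x, random_dna_str(2000), revcomp(x))
    ch <- chain_anchors(find_anchors(a, k = 21))
    tsv <- withr::local_tempfile(fileext = ".tsv")
    pdf <- withr::local_tempfile(fileext = ".pdf")
    export_dotplot(ch, tsv, plot_path = pdf, seq_a_len = nchar(a),
                   seq_b_len = nchar(a), self = TRUE)
    expect_true(file.size(pdf) > 0)
    back <- read_chains_tsv(tsv)
    expect_equal(as.data.frame(back), as.data.frame(ch), ignore_attr = TRUE)
    ## empty input does not fail
    empty <- chain_anchors(find_anchors(random_dna_str(200),
                                        random_dna_str(200)))
    tsv2 <- withr::local_tempfile(fileext = ".tsv")
    expect_silent(export_dotplot(empty, tsv2))
  })
})
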