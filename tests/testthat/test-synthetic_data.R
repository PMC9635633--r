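test_that("identical config and seed give byte-identical outputs", {
  cfg <- haplotype_config(contig_length_bp = 80000,
                          family_mix = c(MHCY_classI = 4, YLEC = 3),
                          observed_bands = FALSE, seed = 101)
  h1 <- generate_haplotype(cfg)
  h2 <- generate_haplotype(cfg)
  expect_identical(h1, h2)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_haplotype(h1, d1); write_haplotype(h2, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
  ## and a different seed changes the sequences
  h3 <- generate_haplotype(haplotype_config(
    contig_length_bp = 80000, family_mix = c(MHCY_classI = 4, YLEC = 3),
    observed_bands = FALSE, seed = 102))
  expect_false(identical(h1$sequences, h3$sequences))
})

test_that("truth features match the family mix and lie within contigs", {
  mix <- c(MHCY_classI = 12, YLEC = 5, MHCY2B = 2, OZFL = 1)
  cfg <- haplotype_config(contig_length_bp = c(120000, 60000),
                          family_mix = mix,
                          observed_bands = FALSE, seed = 103)
  hap <- generate_haplotype(cfg)
  f <- hap$truth$features
  expect_equal(sum(f$family == "MHCY_classI"), 12)
  expect_equal(nrow(f), sum(mix))
  lens <- nchar(hap$sequences)
  expect_true(all(f$end <= lens[f$seq_id]))
  expect_true(all(f$start >= 1))
  ## placed CDS is recoverable: full-length loci translate without stops
  full <- f[f$full_length, ][1, ]
  cds <- substr(hap$sequences[[full$seq_id]], full$start, full$end)
  if (full$strand == "-") cds <- revcomp(cds)
  prot <- translate_cds(cds)
  expect_false(grepl("*", substr(prot, 1, nchar(prot) - 1), fixed = TRUE))
  expect_equal(substr(prot, nchar(prot), nchar(prot)), "*")
  ## pseudogenes carry an internal stop
  pseudo <- f[f$pseudogene, ][1, ]
  cdsp <- substr(hap$sequences[[pseudo$seq_id]], pseudo$start, pseudo$end)
  if (pseudo$strand == "-") cdsp <- revcomp(cdsp)
  expect_true(grepl("*", substr(translate_cds(cdsp), 1,
                                nchar(cdsp) / 3 - 1), fixed = TRUE))
})

test_that("repeat occupancy hits the configured fraction within 2 points", {
  cfg <- haplotype_config(contig_length_bp = 200000, repeat_fraction = 0.40,
                          observed_bands = FALSE, seed = 104)
  hap <- generate_haplotype(cfg)
  r <- hap$truth$repeats
  expect_true(all(r$end <= nchar(hap$sequences[r$seq_id])))
  masked <- sum(r$end - r$start + 1)
  expect_lt(abs(masked / 200000 - 0.40), 0.02)
})

test_that("zero-divergence block copies are recorded and exact", {
  cfg <- haplotype_config(contig_length_bp = 120000,
                          family_mix = c(MHCY_classI = 2),
                          divergence = 0,
                          block_specs = list(list(
                            length_bp = 30000, n_copies = 2,
                            orientations = c("direct", "inverted"),
                            completeness = c(1, 1), contigs = c(1, 1))),
                          observed_bands = FALSE, seed = 105)
  hap <- generate_haplotype(cfg)
  tb <- hap$truth$blocks
  expect_equal(nrow(tb), 2)
  s1 <- substr(hap$sequences[[tb$seq_id[1]]], tb$start[1], tb$end[1])
  s2 <- substr(hap$sequences[[tb$seq_id[2]]], tb$start[2], tb$end[2])
  expect_identical(s2, revcomp(s1))
})

test_that("infeasible packing raises a capacity error before output", {
  expect_error(generate_haplotype(haplotype_config(
    contig_length_bp = 50000,
    block_specs = list(list(length_bp = 30000, n_copies = 2,
                            orientations = c("direct", "direct"),
                            completeness = c(1, 1), contigs = c(1, 1))),
    observed_bands = FALSE, seed = 1)), "capacity")
  expect_error(generate_haplotype(haplotype_config(
    contig_length_bp = 30000, family_mix = c(MHCY_classI = 40),
    observed_bands = FALSE, seed = 1)), "capacity")
})

test_that("observed bands equal predicted bands when nothing is dropped", {
  cfg <- haplotype_config(contig_length_bp = 50000,
                          family_mix = c(MHCY_classI = 3),
                          repeat_fraction = 0.3, seed = 106)
  hap <- generate_haplotype(cfg)
  ps <- predict_southern(hap$sequences, hap$truth$probe)
  expect_equal(sort(ps$pattern$bands$size_bp, decreasing = TRUE),
               hap$truth$observed_bands)
})

test_that("a probe with no homology yields an empty band list", {
  withr::with_seed(107, {
    seqs <- c(c1 = random_dna_str(20000))
    probe <- random_dna_str(300)
    expect_length(generate_observed_bands(seqs, probe), 0)
  })
})

test_that("dropout makes exactly the covered probe-positive band unpredictable", {
  cfg <- haplotype_config(contig_length_bp = 60000,
                          family_mix = c(MHCY_classI = 3, YLEC = 2),
                          repeat_fraction = 0.3, seed = 108)
  hap <- generate_haplotype(cfg)
  ## drop the region around one class I locus (covers its probe-positive
  ## fragment entirely, with margin beyond the flanking TaqI sites)
  f <- hap$truth$features
  target <- f[f$family == "MHCY_classI", ][2, ]
  dropout <- data.frame(seq_id = target$seq_id,
                        start = max(1, target$start - 2000),
                        end = min(nchar(hap$sequences[[target$seq_id]]),
                                  target$end + 2000))
  observed <- generate_observed_bands(hap$sequences, hap$truth$probe,
                                      dropout = dropout)
  released <- apply_dropout(hap$sequences, dropout)
  ps <- predict_southern(released, hap$truth$probe)
  mr <- match_bands(ps$pattern, to_band_pattern(observed))
  expect_length(mr$unmatched_predicted, 0)
  expect_gte(length(mr$unmatched_observed), 1)
})

test_that("engineered alignment columns have closed-form VI", {
  ## no polymorphic columns: VI = 1 everywhere
  a0 <- generate_class1_alignment(15, 20, seed = 109)
  expect_equal(compute_vi(a0)$VI, rep(1, 20))

  ## exact counts 10/15 and 5/15: VI = 2 / (10/15) = 3
  a1 <- generate_class1_alignment(
    15, 30, list("7" = c(A = 10 / 15, S = 5 / 15)), seed = 110)
  p1 <- compute_vi(a1)
  expect_equal(p1$VI[7], 3)
  expect_equal(sort(unique(substr(a1$rows, 7, 7))), c("A", "S"))
  expect_equal(sum(substr(a1$rows, 7, 7) == "A"), 10)

  ## 15 distinct residues over 15 rows: VI = 15 / (1/15) = 225
  freqs <- setNames(rep(1 / 15, 15), strsplit("ACDEFGHIKLMNPQR", "")[[1]])
  a2 <- generate_class1_alignment(15, 10, list("3" = freqs), seed = 111)
  expect_equal(compute_vi(a2)$VI[3], 225)

  expect_error(generate_class1_alignment(10, 5, list("9" = c(A = 1))),
               "outside")
  expect_error(generate_class1_alignment(10, 5, list("2" = c(A = 0.5))),
               "sum")
})
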