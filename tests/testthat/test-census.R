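census_gff <- system.file("extdata", "mhcy_census_synthetic.gff3",
                          package = "haplokit")
repeat_tsv <- system.file("extdata", "mhcy_repeat_census_synthetic.tsv",
                          package = "haplokit")

test_that("locus census reproduces the published totals from the fixture", {
  feats <- read_gff3(census_gff)
  rep <- count_loci(feats, paste0("Contig", 1:4))
  expect_equal(rep$total_loci, 107)
  expect_equal(rep$total_pseudogenes, 37)
  expect_equal(unname(rep$counts["MHCY_classI", "Total"]), 45)
  expect_equal(unname(rep$counts["YLEC", "Total"]), 41)
  expect_equal(unname(rep$pseudogenes["MHCY_classI", "Total"]), 4)
  expect_equal(unname(rep$counts["Total", "Contig1"]), 49)
  ## totals equal column and row sums, both ways
  inner <- rep$counts[-nrow(rep$counts), -ncol(rep$counts), drop = FALSE]
  expect_equal(unname(rep$counts["Total", -ncol(rep$counts)]),
               unname(colSums(inner)))
  expect_equal(unname(rep$counts[-nrow(rep$counts), "Total"]),
               unname(rowSums(inner)))
})

test_that("count_loci handles empty input and unknown contigs", {
  empty <- feature_records(character(0), character(0), character(0),
                           integer(0), integer(0))
  rep <- count_loci(empty, c("c1", "c2"))
  expect_equal(rep$total_loci, 0)
  feats <- feature_records("c9", "YLEC", "y1", 1, 10)
  expect_error(count_loci(feats, c("c1")), "unknown contig")
})

test_that("gene_density reproduces the published densities", {
  expect_equal(gene_density(107, 0.639), 167)
  expect_equal(gene_density(46, 0.242), 190)
  expect_equal(gene_density(253, 3.78), 67)
  expect_equal(gene_density(0, 1), 0)
  expect_error(gene_density(10, 0), "positive")
  ## arithmetic oracle on random inputs
  withr::with_seed(1, {
    for (i in 1:20) {
      n <- sample(1:500, 1); l <- runif(1, 0.1, 5)
      expect_equal(gene_density(n, l), as.integer(floor(n / l + 0.5)))
    }
  })
})

test_that("summarize_repeats reproduces the published percentages", {
  census <- read.delim(repeat_tsv)
  reps <- expand_repeat_census(census)
  rs <- summarize_repeats(reps, 638645)
  cls <- function(k, col) rs$classes[rs$classes$repeat_class == k, col]
  expect_equal(cls("LTR", "count"), 349)
  expect_equal(cls("LTR", "total_bp"), 167577)
  expect_equal(cls("LTR", "percent"), 26.24)
  expect_equal(cls("LINE", "percent"), 13.79)
  expect_equal(cls("tandem", "percent"), 1.15)
  grp <- function(g, col) rs$groups[rs$groups$group == g, col]
  expect_equal(grp("transposable_elements", "count"), 597)
  expect_equal(grp("transposable_elements", "total_bp"), 256395)
  ## the printed total percent is the sum of rounded member rows
  expect_equal(grp("transposable_elements", "percent_table"), 40.14)
  expect_equal(grp("transposable_elements", "percent"), 40.15)
  expect_equal(grp("tandem_repeats", "percent"), 1.15)
  expect_equal(grp("other_repeats", "total_bp"), 7053)
})

test_that("summarize_repeats invariants hold on random record sets", {
  withr::with_seed(7, {
    for (i in 1:10) {
      n <- sample(5:40, 1)
      start <- sort(sample.int(50000, n))
      len <- sample(50:900, n, replace = TRUE)
      reps <- repeat_records("r", sample(c("LTR", "LINE", "simple", "tandem"),
                                        n, replace = TRUE),
                             "fam", start, start + len - 1)
      rs <- summarize_repeats(reps, 60000)
      expect_equal(sum(rs$classes$total_bp), sum(len))
      ## percent recomputes from bp within rounding
      expect_true(all(abs(rs$classes$percent -
                            100 * rs$classes$total_bp / 60000) <= 0.005 + 1e-9))
      ## group totals equal sums of member classes
      expect_equal(sum(rs$groups$total_bp), sum(rs$classes$total_bp))
    }
  })
  rs0 <- summarize_repeats(
    repeat_records(character(0), character(0), character(0), integer(0),
                   integer(0)), 1000)
  expect_true(all(rs0$classes$percent == 0))
  expect_true(all(rs0$classes$count == 0))
})

test_that("boundary_gap uses the start2 - end1 convention", {
  up <- feature_records("Contig1", "rRNA", "ETS3", 103101, 103436)
  dn <- feature_records("Contig1", "other", "LTR1", 106161, 106385)
  expect_equal(boundary_gap(up, dn), 2725)
  a <- feature_records("c", "YLEC", "a", 1, 10)
  b <- feature_records("c", "YLEC", "b", 11, 20)
  expect_equal(boundary_gap(a, b), 1)
  expect_error(boundary_gap(b, a), "overlap|mis-ordered")
  expect_error(boundary_gap(
    feature_records("c1", "YLEC", "x", 1, 10),
    feature_records("c2", "YLEC", "y", 50, 60)), "different contigs")
  withr::with_seed(3, {
    for (i in 1:20) {
      e1 <- sample.int(10000, 1); s2 <- e1 + sample.int(5000, 1)
      u <- feature_records("c", "YLEC", "u", max(1, e1 - 100), e1)
      d <- feature_records("c", "YLEC", "d", s2, s2 + 10)
      expect_equal(boundary_gap(u, d), s2 - e1)
    }
  })
})

test_that("contig_arithmetic reproduces the published totals", {
  res <- contig_arithmetic(c(412370, 148501, 138921, 45013), 106160)
  expect_equal(res$overall_bp, 744805)
  expect_equal(res$mhc_bp, 638645)
  expect_equal(res$per_contig_mhc_bp[1], 306210)
  expect_equal(sum(res$per_contig_mhc_bp[-1]), 332435)
  single <- contig_arithmetic(5000, 0)
  expect_equal(single$mhc_bp, 5000)
  expect_error(contig_arithmetic(c(100, 50), 200), "exceeds")
  withr::with_seed(5, {
    lens <- sample.int(1e6, 4); nor <- sample.int(lens[1], 1)
    r <- contig_arithmetic(lens, nor)
    expect_equal(r$overall_bp, Reduce(`+`, as.list(lens)))
    expect_equal(r$mhc_bp, r$overall_bp - nor)
  })
})

test_that("cluster_types groups by exact predicted-protein identity", {
  tpl <- gene_templates()
  cds_a <- tpl$seq[tpl$family == "MHCY_classI"][1]
  cds_b <- tpl$seq[tpl$family == "MHCY_classI"][2]
  seqs <- c(ctg = paste0(cds_a, strrep("T", 30), cds_a, strrep("G", 30),
                         revcomp(cds_a), strrep("C", 30), cds_b))
  n <- nchar(cds_a)
  feats <- feature_records(
    rep("ctg", 4), rep("MHCY_classI", 4), paste0("L", 1:4),
    start = c(1, n + 31, 2 * n + 61, 3 * n + 91),
    end = c(n, 2 * n + 30, 3 * n + 60, 4 * n + 90),
    strand = c("+", "+", "-", "+"))
  cl <- cluster_types(feats, seqs)
  expect_equal(unname(cl$n_types["MHCY_classI"]), 2L)
  expect_identical(cl$assignments$type_label, c("a", "a", "a", "b"))
  expect_equal(sort(cl$types$copies), c(1L, 3L))
})

test_that("one residue difference separates types; order only permutes labels", {
  p1 <- "ATGAAAGAATAA"
  p2 <- "ATGAAAGAGTAA"   # synonymous change: same protein
  p3 <- "ATGAAAGTATAA"   # nonsynonymous: different protein
  seqs <- c(c1 = paste0(p1, p2, p3))
  feats <- feature_records(rep("c1", 3), rep("YLEC", 3), c("y1", "y2", "y3"),
                           start = c(1, 13, 25), end = c(12, 24, 36))
  cl <- cluster_types(feats, seqs)
  expect_identical(cl$assignments$type_label, c("a", "a", "b"))
  ## reversing input order cannot change the partition
  cl2 <- cluster_types(feats[3:1, ], seqs)
  expect_identical(cl2$assignments$type_label, c("a", "a", "b"))
})

test_that("untranslatable CDS is excluded with a warning", {
  seqs <- c(c1 = strrep("A", 100))
  feats <- feature_records("c1", "YLEC", "y1", 1, 10)  # width 10, not %3
  expect_warning(cl <- cluster_types(feats, seqs), "untranslatable")
  expect_identical(cl$excluded, "y1")
})

test_that("type clustering of generated haplotypes matches implanted templates", {
  cfg <- haplotype_config(contig_length_bp = 150000,
                          family_mix = c(MHCY_classI = 17),
                          class1_templates = 10,
                          pseudogene_fraction = 0,
                          repeat_fraction = 0.2,
                          observed_bands = FALSE, seed = 91)
  hap <- generate_haplotype(cfg)
  cl <- cluster_types(hap$truth$features, hap$sequences)
  expect_equal(unname(cl$n_types["MHCY_classI"]), 10L)
  ## copies per type match the implanted template multiplicity
  truth_copies <- sort(as.integer(table(hap$truth$features$template_id)))
  expect_equal(sort(cl$types$copies), truth_copies)
  expect_equal(sum(cl$types$copies), 17L)
})
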