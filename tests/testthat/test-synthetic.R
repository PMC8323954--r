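test_that("generators are deterministic under a fixed seed", {
  p1 <- generate_cr_panel(cr_panel_config(seed = 99))
  p2 <- generate_cr_panel(cr_panel_config(seed = 99))
  expect_identical(p1$msa$seqs, p2$msa$seqs)
  expect_identical(p1$truth, p2$truth)
  p3 <- generate_cr_panel(cr_panel_config(seed = 100))
  expect_false(identical(p1$msa$seqs, p3$msa$seqs))

  q1 <- generate_genome_quartet(quartet_config(seed = 7))
  q2 <- generate_genome_quartet(quartet_config(seed = 7))
  expect_identical(q1$msa$seqs, q2$msa$seqs)

  h1 <- generate_het_pileup(het_sim_config(
    gene_table = het_gene_reference()[1:3, ], genome_length = 1500, seed = 7))
  h2 <- generate_het_pileup(het_sim_config(
    gene_table = het_gene_reference()[1:3, ], genome_length = 1500, seed = 7))
  expect_identical(h1$pileup$bases, h2$pileup$bases)
  expect_identical(h1$truth, h2$truth)
})

test_that("planted panel frequencies are exact census ratios", {
  cfg <- cr_panel_config(n_haplotypes = 45, cs_lengths = c(40, 25),
                         vs_lengths = c(30, 40), vs_variant_counts = c(3, 5),
                         type_counts = c(transition = 8),
                         bin_site_counts = c(4, 2, 1, 1), seed = 6)
  p <- generate_cr_panel(cfg)
  sites <- polymorphic_sites(p$msa)
  expect_equal(nrow(sites), 8)
  # recovered frequencies equal planted count ratios exactly
  truth_freq <- as.numeric(unlist(strsplit(p$truth$sites$freq_pct, ",")))
  rec_freq <- unlist(sites$variant_freq_pct)
  expect_equal(sort(rec_freq), sort(truth_freq), tolerance = 1e-6)
  # a planted 5/45 variant reads back as 11.1%
  one <- generate_cr_panel(cr_panel_config(
    n_haplotypes = 45, cs_lengths = 20, vs_lengths = 21,
    vs_variant_counts = 1, type_counts = c(transition = 1),
    bin_site_counts = c(0, 1), seed = 3))
  s1 <- polymorphic_sites(one$msa)
  k <- as.integer(one$truth$sites$counts)
  expect_equal(round(s1$variant_freq_pct[[1]], 1), round(100 * k / 45, 1))
})

test_that("a minimal planted panel drives scan and segment detection exactly", {
  cfg <- cr_panel_config(n_haplotypes = 10, cs_lengths = 40, vs_lengths = 10,
                         vs_variant_counts = 2,
                         type_counts = c(transition = 2),
                         bin_site_counts = c(2), seed = 5)
  p <- generate_cr_panel(cfg)
  sites <- polymorphic_sites(p$msa)
  expect_equal(nrow(sites), 2)
  cs <- find_conserved_segments(p$msa, sites = sites)
  expect_equal(nrow(cs), 1)
  expect_equal(cs$length, 40L)
})

test_that("quartet generator plants exactly the configured variant classes", {
  genes <- data.frame(gene = c("g1", "g2"), group = c("ND", "COX"),
                      fi25 = c(3L, 0L), fi50 = c(1L, 2L),
                      length_bp = c(200L, 150L))
  q <- generate_genome_quartet(quartet_config(genes = genes,
                                              genome_length = 400, seed = 2))
  sites <- polymorphic_sites(q$msa)
  expect_equal(nrow(sites), 6)   # 3 + 1 singletons/doubletons in g1, 2 in g2
  pg <- per_gene_variant_table(sites, q$annotations, L = 400)
  expect_equal(pg$`25%`[match(c("g1", "g2"), pg$gene)], c(3L, 0L))
  expect_equal(pg$`50%`[match(c("g1", "g2"), pg$gene)], c(1L, 2L))
  # a 2v2 split site is a single 50% variant (not two)
  expect_true(all(sites$n_variants == 1))

  # zero planted variants: nothing to scan
  none <- generate_genome_quartet(quartet_config(
    genes = data.frame(gene = "g", group = "ND", fi25 = 0L, fi50 = 0L,
                       length_bp = 100L),
    genome_length = 150, seed = 1))
  expect_equal(nrow(scan_sites(none$msa)), 0)
})

test_that("pileup generator recovery: planted fractions and composition", {
  # binomial support: recovered frequency within binomial noise of planted
  h <- generate_het_pileup(het_sim_config(depth_sd = 0, seed = 13))
  tmp <- tempfile(); write_pileup(h$pileup, tmp)
  v <- call_variants(read_pileup(tmp))
  key <- paste(v$position)
  tr <- h$truth[match(key, paste(h$truth$position)), ]
  dev <- abs(v$frequency - tr$fraction)
  tol <- 3 * sqrt(tr$fraction * (1 - tr$fraction) / tr$depth)
  expect_gt(mean(dev <= tol), 0.98)

  # noise off: composition recovered exactly
  h0 <- generate_het_pileup(het_sim_config(depth_sd = 0,
                                           sample_support = FALSE, seed = 3))
  tmp0 <- tempfile(); write_pileup(h0$pileup, tmp0)
  v0 <- call_variants(read_pileup(tmp0))
  comp <- indel_composition(v0)
  expect_equal(comp$n_insertions, 112)
  expect_equal(comp$n_deletions, 72)
  expect_equal(comp$n_substitutions, 2)
  expect_equal(comp$single_base["insertion", "T"], 66L)
  expect_equal(comp$single_base["insertion", "A"], 44L)

  # zero planted variants, zero error rate: caller emits nothing
  gt0 <- het_gene_reference()[1, ]
  gt0[, grep("^\\(", names(gt0))] <- 0
  quiet <- generate_het_pileup(het_sim_config(gene_table = gt0,
                                              genome_length = 500, seed = 1))
  tmpq <- tempfile(); write_pileup(quiet$pileup, tmpq)
  expect_equal(nrow(call_variants(read_pileup(tmpq))), 0)
})

test_that("truth serialization writes valid JSON and VCF", {
  p <- generate_cr_panel(cr_panel_config(
    n_haplotypes = 8, cs_lengths = 20, vs_lengths = 12,
    vs_variant_counts = 2, type_counts = c(transition = 2),
    bin_site_counts = c(2), seed = 4))
  jpath <- tempfile(fileext = ".json")
  write_truth_json(p$truth, jpath)
  back <- jsonlite::read_json(jpath, simplifyVector = TRUE)
  expect_equal(back$sites$msa_column, p$truth$sites$msa_column)

  h <- generate_het_pileup(het_sim_config(
    gene_table = het_gene_reference()[1:2, ], genome_length = 800,
    depth_sd = 0, sample_support = FALSE, seed = 4))
  vpath <- tempfile(fileext = ".vcf")
  write_truth_vcf(h$truth, h$genome, vpath)
  tv <- read_het_vcf(vpath)
  expect_equal(nrow(tv), nrow(h$truth))
  expect_equal(tv$position, h$truth$position)
})
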