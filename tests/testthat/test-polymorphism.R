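test_that("site scan reports segregating columns, gaps as alleles, N as missing", {
  x <- make_msa("AAGT-", "AAGTA", "ACGTA", "ANGTA", reference_id = "s1")
  sites <- scan_sites(x)
  # col 1 monomorphic, col 2 A/C (N dropped), col 3-4 monomorphic, col 5 gap allele
  expect_equal(sites$msa_column, c(2L, 5L))
  expect_equal(sites$alleles[[1]], c(A = 2L, C = 1L))
  expect_equal(sites$n_eff[1], 3L)  # N excluded from the denominator
  expect_equal(sort(names(sites$alleles[[2]])), c("-", "A"))

  # gaps droppable from the denominator via the config switch
  sites2 <- scan_sites(x, gaps_as_alleles = FALSE)
  expect_equal(sites2$msa_column, 2L)

  # all-N columns are skipped
  y <- make_msa("NA", "NC", "NG")
  expect_equal(scan_sites(y)$msa_column, 2L)
})

test_that("reference designation follows the majority / tie / multiallelic rules", {
  mk_site <- function(counts, n = sum(counts)) {
    s <- data.frame(msa_column = 1L)
    s$alleles <- list(counts)
    s$n_eff <- n
    class(s) <- c("site_table", "data.frame")
    s
  }
  # frequency above 50% -> reference
  s <- designate_reference(mk_site(c(A = 27L, G = 18L)))
  expect_equal(s$reference_allele, "A")
  expect_equal(s$variants[[1]], "G")
  expect_equal(s$variant_freq_pct[[1]], 40)

  # bi-allelic 50/50: a single variant; tie to the reference record's base
  s <- designate_reference(mk_site(c(G = 22L, A = 22L)), ref_chars = "G")
  expect_equal(s$reference_allele, "G")
  expect_equal(s$variants[[1]], "A")
  expect_equal(s$n_variants, 1L)
  # ... falling back to the lexicographically smaller allele
  s <- designate_reference(mk_site(c(G = 22L, T = 22L)))
  expect_equal(s$reference_allele, "G")

  # tri-allelic: most frequent is reference, the rest variants
  s <- designate_reference(mk_site(c(A = 22L, G = 14L, T = 8L)))
  expect_equal(s$reference_allele, "A")
  expect_setequal(s$variants[[1]], c("G", "T"))

  # property: no designated variant ever exceeds 50%
  set.seed(9)
  for (rep in 1:200) {
    x <- random_panel(sample(4:12, 1), 25)
    sites <- designate_reference(scan_sites(x))
    freqs <- unlist(sites$variant_freq_pct)
    if (length(freqs)) expect_lte(max(freqs), 50 + 1e-9)
  }
})

test_that("site classification assigns transition/transversion/indel flags", {
  x <- make_msa("AACCC", "GTTC-", "AACCC", reference_id = "s1")
  sites <- polymorphic_sites(x)
  expect_equal(sites$type_label,
               c("transition", "transversion", "transition", "indel"))
  # tri-allelic C/T/G: transition and transversion combined
  y <- make_msa("C", "C", "T", "G", "C", reference_id = "s1")
  st <- polymorphic_sites(y)
  expect_true(st$transition && st$transversion)
  expect_equal(st$type_label, "transition+transversion")
  # every polymorphic site carries at least one flag (exhaustive partition)
  set.seed(10)
  for (rep in 1:50) {
    sites <- polymorphic_sites(random_panel(6, 30))
    expect_true(all(nchar(sites$type_label) > 0))
  }
})

test_that("variability index is the percentage of polymorphic sites per length", {
  expect_equal(round(variability_index(95, 354)$vi, 1), 26.8)
  expect_equal(round(variability_index(3, 11)$vi, 1), 27.3)
  expect_equal(variability_index(0, 100)$vi, 0)
  expect_error(variability_index(3, 0), class = "mito_validation_error")
  expect_error(variability_index(12, 10), class = "mito_validation_error")
})

test_that("weighted bin distribution splits unit site weight across variants", {
  mk <- function(freqs_list) {
    s <- data.frame(msa_column = seq_along(freqs_list))
    s$alleles <- replicate(length(freqs_list), c(A = 1L), simplify = FALSE)
    s$n_eff <- 10L
    s$variant_freq_pct <- freqs_list
    class(s) <- c("site_table", "data.frame")
    s
  }
  # one site, variants at 5% and 15% -> half weight in each bin
  tbl <- weighted_bin_distribution(mk(list(c(5, 15))))
  expect_equal(tbl$`(0,10]`, 0.5)
  expect_equal(tbl$`(10,20]`, 0.5)
  # bi-allelic site at 40% -> unit weight in (30,40]
  tbl <- weighted_bin_distribution(mk(list(40)))
  expect_equal(tbl$`(30,40]`, 1)
  # exact bin edge belongs to the lower (left-open right-closed) bin
  tbl <- weighted_bin_distribution(mk(list(10)))
  expect_equal(tbl$`(0,10]`, 1)
  # frequency above 50% after designation is an internal inconsistency
  expect_error(weighted_bin_distribution(mk(list(60))),
               class = "mito_consistency_error")

  # conservation: grand total equals the site count on random panels
  set.seed(11)
  for (rep in 1:100) {
    x <- random_panel(sample(4:10, 1), 30)
    sites <- designate_reference(scan_sites(x))
    if (nrow(sites) == 0) next
    tot <- freq_bin_totals(weighted_bin_distribution(sites))
    expect_equal(sum(tot$bin_totals), nrow(sites), tolerance = 1e-9)
    expect_equal(tot$grand_total, nrow(sites))
  }
})

test_that("per-gene variant table recovers planted quartet structure", {
  q <- generate_genome_quartet(quartet_config(seed = 5))
  sites <- polymorphic_sites(q$msa)
  expect_equal(nrow(sites), sum(q$truth$genes$fi25) + sum(q$truth$genes$fi50))

  # 1-of-4 -> 25% class; 2v2 -> a single 50% variant
  expect_setequal(unique(round(unlist(sites$variant_freq_pct))), c(25, 50))
  expect_true(all(sites$n_variants == 1))

  pg <- per_gene_variant_table(sites, q$annotations, L = q$msa$n_cols)
  cox1 <- pg[pg$gene == "COX1", ]
  expect_equal(cox1$`25%`, 92)
  expect_equal(cox1$total_variants, 92)
  expect_equal(round(cox1$vi, 2), 6.00)
  expect_equal(sum(pg$`25%`), sum(q$truth$genes$fi25))
  expect_equal(sum(pg$`50%`), sum(q$truth$genes$fi50))
  # per-gene totals match the planted configuration
  merged <- merge(as.data.frame(pg), q$truth$genes, by = "gene")
  expect_true(all(merged$total_variants == merged$fi25 + merged$fi50))
})

test_that("VI is invariant under sequence reordering and column permutation", {
  set.seed(12)
  x <- random_panel(8, 40)
  n1 <- nrow(polymorphic_sites(x))
  perm_rows <- msa(x$ids, x$seqs[sample(x$n_seqs)])
  expect_equal(nrow(polymorphic_sites(perm_rows)), n1)
  m <- as.matrix(x)[, sample(x$n_cols)]
  perm_cols <- msa(x$ids, apply(m, 1, paste, collapse = ""))
  expect_equal(nrow(polymorphic_sites(perm_cols)), n1)
})
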