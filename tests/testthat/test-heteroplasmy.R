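test_that("pileup parsing handles match, mismatch, indel and marker symbols", {
  path <- write_pileup_lines(c(
    "chrM\t5\tA\t10\t....,,..T,\tIIIIIIIIII",
    "chrM\t6\tC\t4\t..+2AT..\tIIII",
    "chrM\t7\tG\t5\t.,-1A.^I..$\tIIIII",
    "chrM\t8\tA\t6\t..**..\tIIIIII"))
  p <- read_pileup(path)
  expect_equal(p$calls[[1]][["ref"]], 9L)
  expect_equal(p$calls[[1]][["T"]], 1L)
  expect_equal(p$calls[[2]][["+AT"]], 1L)
  expect_equal(p$calls[[2]][["ref"]], 4L)
  expect_equal(p$calls[[3]][["-A"]], 1L)
  expect_equal(p$calls[[3]][["ref"]], 5L)
  expect_equal(p$calls[[4]][["*"]], 2L)  # deletion placeholders, not calls

  expect_error(read_pileup(write_pileup_lines("chrM\t1\tA\t2\t.+9A\tII")),
               class = "mito_parse_error")

  # round-trip of a generated pileup preserves planted counts
  h <- generate_het_pileup(het_sim_config(
    gene_table = het_gene_reference()[1:3, ], genome_length = 1500,
    depth_sd = 0, sample_support = FALSE, seed = 8))
  tmp <- tempfile()
  write_pileup(h$pileup, tmp)
  pu <- read_pileup(tmp)
  expect_equal(nrow(pu), 1500)
  expect_equal(pu$coverage, h$pileup$coverage)
  for (i in seq_len(nrow(h$truth))) {
    tr <- h$truth[i, ]
    calls <- pu$calls[[match(tr$position, pu$pos)]]
    key <- switch(tr$type, insertion = paste0("+", tr$seq),
                  deletion = paste0("-", tr$seq), tr$seq)
    expect_equal(calls[[key]], tr$support)
  }
})

test_that("variant calling enforces read-support and consensus thresholds", {
  lines <- c(
    sprintf("chrM\t1\tC\t100\t%s\t%s", paste0(strrep(".", 70), strrep(".+1T", 30)),
            strrep("I", 100)),
    sprintf("chrM\t2\tA\t100\t%sGGG\t%s", strrep(".", 97), strrep("I", 100)),
    sprintf("chrM\t3\tC\t100\t%s\t%s", paste0(strrep(".", 40), strrep(".-1A", 60)),
            strrep("I", 100)))
  p <- read_pileup(write_pileup_lines(lines))
  v <- call_variants(p)
  # 30/100 insertion: heteroplasmic, anchored notation C -> CT
  ins <- v[v$position == 1, ]
  expect_equal(ins$var_type, "insertion")
  expect_equal(ins$frequency, 0.30)
  expect_equal(ins$zygosity, "heteroplasmic")
  expect_equal(ins$alt_allele, "CT")
  # 3 supporting reads: below min_var_reads, no call at position 2
  expect_false(2 %in% v$position)
  # 60/100 deletion: consensus zygosity, CA -> C
  del <- v[v$position == 3, ]
  expect_equal(del$zygosity, "consensus")
  expect_equal(del$ref_allele, "CA")
  expect_equal(del$alt_allele, "C")

  # threshold contract over random pileups
  set.seed(31)
  for (rep in 1:20) {
    d <- sample(20:150, 1)
    k <- sample(0:15, 1)
    ln <- sprintf("chrM\t1\tA\t%d\t%s\t%s", d,
                  paste0(strrep(".", d - k), strrep("T", k)), strrep("I", d))
    vv <- call_variants(read_pileup(write_pileup_lines(ln)))
    if (k >= 4) {
      expect_equal(vv$supporting_reads, k)
      expect_true(all(vv$supporting_reads >= 4))
    } else {
      expect_equal(nrow(vv), 0)
    }
  }
})

test_that("binomial p-value is monotone and gates the called flag", {
  d <- 100
  ks <- 4:40
  ps <- stats::pbinom(ks - 1, d, 0.01, lower.tail = FALSE)
  lines <- sprintf("chrM\t%d\tA\t%d\t%s\t%s", seq_along(ks), d,
                   paste0(strrep(".", d - ks), strrep("G", ks)), strrep("I", d))
  v <- call_variants(read_pileup(write_pileup_lines(lines)))
  expect_equal(v$p_value, ps, tolerance = 1e-12)
  expect_true(all(diff(v$p_value) <= 0))   # monotone decreasing in support
  expect_true(all(v$called == (v$p_value < 0.05)))
})

test_that("per-gene summary bins called variants and sorts by VI", {
  h <- generate_het_pileup(het_sim_config(depth_sd = 0,
                                          sample_support = FALSE, seed = 4))
  tmp <- tempfile(); write_pileup(h$pileup, tmp)
  v <- call_variants(read_pileup(tmp), genome = h$genome$sequence)
  expect_equal(nrow(v), nrow(h$truth))  # exact recovery with noise off
  tbl <- summarize_by_gene(v, h$annotations, L = 15989)
  expect_true(all(diff(tbl$vi) <= 1e-12))
  # row sums equal per-gene totals; grand total equals in-gene call count
  bins <- grep("^\\(", names(tbl), value = TRUE)
  expect_equal(unname(rowSums(tbl[, bins])), as.numeric(tbl$total_variants))
  expect_equal(sum(tbl$total_variants), nrow(h$truth))
  # a 352 bp gene with 13 planted variants: VI 3.69%
  nd3_like <- tbl[tbl$gene == "ND3", ]
  expect_equal(nd3_like$total_variants, 13)
  expect_equal(round(nd3_like$vi, 2), 3.69)
  # planted bins are recovered exactly under deterministic support
  truth_bins <- table(h$truth$gene)
  expect_equal(unname(truth_bins[tbl$gene]), tbl$total_variants,
               ignore_attr = TRUE)
})

test_that("indel composition reports per-base counts and deletion shares", {
  mk <- function(type, seq, n) data.frame(
    position = seq_len(n), ref_allele = "A", alt_allele = "A",
    var_type = type, indel_seq = seq, supporting_reads = 10L, coverage = 100L,
    frequency = 0.1, p_value = 1e-6, zygosity = "heteroplasmic",
    called = TRUE, homopolymer_run = NA_integer_)
  v <- rbind(mk("insertion", "T", 2), mk("deletion", "A", 1))
  class(v) <- c("het_calls", "data.frame")
  comp <- indel_composition(v)
  expect_equal(comp$single_base["insertion", "T"], 2L)
  expect_equal(comp$single_base["deletion", "A"], 1L)

  # the default planted composition: 112 insertions, 72 deletions,
  # C+G deletions ~21%
  pool <- default_het_composition()
  v2 <- do.call(rbind, lapply(seq_len(nrow(pool)), function(i) {
    mk(ifelse(pool$type[i] == "substitution", "substitution-transition",
              pool$type[i]),
       ifelse(pool$type[i] == "substitution", NA, pool$seq[i]), 1)
  }))
  class(v2) <- c("het_calls", "data.frame")
  comp2 <- indel_composition(v2)
  expect_equal(comp2$n_insertions, 112)
  expect_equal(comp2$n_deletions, 72)
  expect_equal(comp2$n_substitutions, 2)
  expect_equal(comp2$single_base["insertion", "T"], 66L)
  expect_equal(comp2$single_base["insertion", "A"], 44L)
  expect_equal(round(sum(comp2$deletion_base_pct[c("C", "G")]), 1), 20.8)
  expect_equal(comp2$max_indel_length, 2L)
})

test_that("invariable regions report circular gaps between variants", {
  r <- invariable_regions(c(100, 700), 1000)
  expect_equal(sort(r$regions$gap), c(400, 600))
  expect_equal(r$max_gap, 600)
  r1 <- invariable_regions(500, 1000)
  expect_equal(r1$max_gap, 1000)
  # planted variant-free stretch is recovered
  set.seed(33)
  pos <- sort(c(sample(1:1000, 30), sample(1549:5000, 20)))
  r2 <- invariable_regions(pos, 5000, circular = FALSE)
  expect_gte(r2$max_gap, 548)
  expect_true(any(r2$regions$gap == max(r2$regions$gap)))
})

test_that("frequency-gap patterns distinguish progressive, gapped and lone-high", {
  expect_equal(frequency_gap_pattern(c(5, 7, 1, 0, 0, 0)), "progressive")
  expect_equal(frequency_gap_pattern(c(5, 4, 2, 0, 0, 1)), "gapped")
  expect_equal(frequency_gap_pattern(c(0, 0, 1, 0, 0, 0)), "lone_high")
  expect_equal(frequency_gap_pattern(c(3, 0, 0, 0, 0, 0)), "progressive")
  expect_error(frequency_gap_pattern(c(0, 0, 0)), class = "mito_validation_error")
})

test_that("VCF round-trip preserves calls", {
  h <- generate_het_pileup(het_sim_config(
    gene_table = het_gene_reference()[1:3, ], genome_length = 1500,
    depth_sd = 0, sample_support = FALSE, seed = 2))
  tmp <- tempfile(); write_pileup(h$pileup, tmp)
  v <- call_variants(read_pileup(tmp))
  vcf <- tempfile(fileext = ".vcf")
  write_het_vcf(v, vcf)
  back <- read_het_vcf(vcf)
  expect_equal(back$position, v$position)
  expect_equal(back$ref_allele, v$ref_allele)
  expect_equal(back$alt_allele, v$alt_allele)
  expect_equal(back$var_type, v$var_type)
  expect_equal(back$frequency, v$frequency, tolerance = 1e-5)
})
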