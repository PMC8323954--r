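test_that("window p-value matches exhaustive enumeration", {
  expect_equal(conserved_run_pvalue(2, 1, 4), 0.5)
  expect_equal(conserved_run_pvalue(10, 3, 10), 0)   # no room for variants
  expect_equal(conserved_run_pvalue(5, 0, 10), 1)    # certain without variants
  for (L in c(4, 6, 9)) {
    for (S in 0:L) {
      for (w in 1:L) {
        expect_equal(conserved_run_pvalue(w, S, L), enum_window_pvalue(w, S, L),
                     tolerance = 1e-12,
                     info = sprintf("L=%d S=%d w=%d", L, S, w))
      }
    }
  }
  # monotone decreasing in w and in S
  expect_true(all(diff(conserved_run_pvalue(1:20, 5, 40)) <= 1e-12))
  ps <- vapply(0:10, function(S) conserved_run_pvalue(8, S, 40), 0)
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("conserved-segment detection finds planted runs", {
  set.seed(21)
  n <- 45
  base <- sample(c("A", "C", "G", "T"), 120, replace = TRUE)
  mat <- matrix(rep(base, each = n), nrow = n)
  # variants everywhere except a planted run at columns 10-60
  for (j in setdiff(seq(2, 120, by = 6), 10:60)) {
    mat[2:4, j] <- setdiff(c("A", "C", "G", "T"), base[j])[1]
  }
  x <- msa(sprintf("h%d", 1:n), apply(mat, 1, paste, collapse = ""))
  cs <- find_conserved_segments(x, conservation_params())
  run <- cs[cs$start_col <= 10 & cs$end_col >= 60, ]
  expect_equal(nrow(run), 1)

  # fully identical alignment: one segment spanning everything (the window
  # null is vacuous at S = 0, so no alpha filtering applies)
  y <- make_msa(strrep("ACGT", 10), strrep("ACGT", 10))
  cs2 <- find_conserved_segments(y, conservation_params())
  expect_equal(nrow(cs2), 1)
  expect_equal(cs2$length, 40)

  # a variant every 10 columns: no run reaches the minimum window
  mat3 <- matrix(rep(base, each = 4), nrow = 4)
  for (j in seq(5, 120, by = 10)) mat3[2, j] <- setdiff(c("A", "C", "G", "T"), base[j])[1]
  z <- msa(sprintf("h%d", 1:4), apply(mat3, 1, paste, collapse = ""))
  expect_equal(nrow(find_conserved_segments(z, conservation_params())), 0)
})

test_that("variable segments are the exact complement of conserved ones", {
  cs <- mitodiv:::new_segment_table(data.frame(
    label = c("CS1", "CS2"), kind = "conserved",
    start_col = c(1L, 61L), end_col = c(40L, 80L),
    length = c(40L, 20L), stringsAsFactors = FALSE))
  vs <- derive_variable_segments(cs, span = c(1L, 100L))
  expect_equal(vs$start_col, c(41L, 81L))
  expect_equal(vs$end_col, c(60L, 100L))
  expect_equal(vs$label, c("VS1", "VS2"))

  # zero CS -> a single VS spanning everything
  empty <- cs[0, ]
  vs0 <- derive_variable_segments(empty, span = c(1L, 50L))
  expect_equal(nrow(vs0), 1)
  expect_equal(vs0$length, 50L)

  # CS covering the whole span -> no VS
  whole <- mitodiv:::new_segment_table(data.frame(
    label = "CS1", kind = "conserved", start_col = 1L, end_col = 100L,
    length = 100L, stringsAsFactors = FALSE))
  expect_equal(nrow(derive_variable_segments(whole, span = c(1L, 100L))), 0)

  # overlapping CS rejected
  bad <- mitodiv:::new_segment_table(data.frame(
    label = c("CS1", "CS2"), kind = "conserved",
    start_col = c(1L, 30L), end_col = c(40L, 50L), length = c(40L, 21L),
    stringsAsFactors = FALSE))
  expect_error(derive_variable_segments(bad, span = c(1L, 100L)),
               class = "mito_validation_error")

  # tiling property on generated panels: CS + VS lengths sum to the span
  for (seed in 1:5) {
    p <- generate_cr_panel(cr_panel_config(seed = seed))
    sites <- polymorphic_sites(p$msa)
    cs <- find_conserved_segments(p$msa, sites = sites)
    vs <- derive_variable_segments(cs, c(1L, p$msa$n_cols))
    expect_equal(sum(cs$length) + sum(vs$length), p$msa$n_cols)
  }
})

test_that("segment statistics compute GC, conserved and polymorphic counts", {
  p <- generate_cr_panel(cr_panel_config(seed = 2))
  sites <- polymorphic_sites(p$msa, ref_start = 14996)
  cs <- find_conserved_segments(p$msa, sites = sites)
  vs <- derive_variable_segments(cs, c(1L, p$msa$n_cols))
  vs <- segment_stats(vs, p$msa, sites, ref_start = 14996)
  vs3 <- vs[vs$label == "VS3", ]
  expect_equal(vs3$length, 354L)
  expect_equal(vs3$n_polymorphic, 95L)
  expect_equal(round(vs3$vi, 1), 26.8)
  # conserved + polymorphic counts never exceed length
  expect_true(all(vs$n_conserved + vs$n_polymorphic <= vs$length))
  # every conserved segment is free of polymorphic columns at C = 100
  cs <- segment_stats(cs, p$msa, sites, ref_start = 14996)
  expect_true(all(cs$n_polymorphic == 0))
  expect_true(all(cs$n_conserved == cs$length))

  # GC edge cases
  allgc <- make_msa("GCGCG", "GCGCG", "GCGCG")
  seg <- mitodiv:::new_segment_table(data.frame(
    label = "CS1", kind = "conserved", start_col = 1L, end_col = 5L,
    length = 5L, stringsAsFactors = FALSE))
  st <- segment_stats(seg, allgc, polymorphic_sites(allgc)[0, ])
  expect_equal(st$gc_content, 100)
  at <- make_msa("AT-AT", "AT-AT")
  st2 <- segment_stats(seg, at, scan_sites(at)[0, ])
  expect_equal(st2$gc_content, 0)  # gaps ignored in GC
})

test_that("hypervariable grouping splits at the valley between the two peaks", {
  mk_vs <- function(counts) {
    mitodiv:::new_segment_table(data.frame(
      label = sprintf("VS%d", seq_along(counts)), kind = "variable",
      start_col = seq_along(counts), end_col = seq_along(counts),
      length = 1L, stringsAsFactors = FALSE))
  }
  vs <- group_hypervariable(mk_vs(1:7), counts = c(7, 19, 95, 18, 3, 26, 14))
  expect_equal(vs$hvs, c(rep("HVS1", 4), rep("HVS2", 3)))
  expect_equal(attr(vs, "peaks"), c(3L, 6L))

  vs2 <- group_hypervariable(mk_vs(1:3), counts = c(10, 1, 10))
  expect_equal(vs2$hvs, c("HVS1", "HVS2", "HVS2"))

  expect_warning(vs3 <- group_hypervariable(mk_vs(1:3), counts = c(5, 4, 3)),
                 "unimodal")
  expect_equal(vs3$hvs, rep("HVS1", 3))

  # explicit split override
  vs4 <- group_hypervariable(mk_vs(1:4), counts = c(1, 2, 3, 4),
                             split_after = 2)
  expect_equal(vs4$hvs, c("HVS1", "HVS1", "HVS2", "HVS2"))
})

test_that("planted segment boundaries are recovered exactly", {
  for (seed in c(1, 7, 13)) {
    cfg <- cr_panel_config(seed = seed)
    p <- generate_cr_panel(cfg)
    sites <- polymorphic_sites(p$msa)
    cs <- find_conserved_segments(p$msa, sites = sites)
    planted <- p$truth$segments[p$truth$segments$kind == "conserved", ]
    expect_equal(cs$start_col, planted$start_col)
    expect_equal(cs$end_col, planted$end_col)
    expect_equal(cs$length, planted$length)
    expect_equal(sum(cs$length), sum(cfg$cs_lengths))
  }
})
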