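# End-to-end commands. Each command reads files, runs the corresponding
# module chain, and writes TSV reports with a provenance header, so stages
# compose via files and every intermediate is auditable.

#' Control-region segmentation report
#'
#' Runs the full segment chain on a gapped control-region alignment:
#' polymorphic-site scan, conserved-segment detection, variable-segment
#' derivation, per-segment statistics and hypervariable grouping. Writes
#' `segments.tsv` (segment, kind, length, coordinates, GC, conserved and
#' polymorphic counts, VI, HVS group) and `segments.bed`.
#'
#' @param alignment Path to a gapped FASTA, or an [msa()].
#' @param out_dir Output directory (created if needed).
#' @param params [conservation_params()].
#' @param ref_start Reference coordinate of the first reference base.
#' @param seed Seed recorded in report headers (no randomness in this
#'   command).
#' @return Invisibly, a list with `segments` (a `segment_table` of CS and
#'   VS in 5'->3' order) and `sites`.
#' @export
run_segments <- function(alignment, out_dir = ".",
                         params = conservation_params(), ref_start = 1L,
                         seed = NULL) {
  x <- if (inherits(alignment, "msa")) alignment else read_alignment(alignment)
  if (x$n_seqs < 2) mito_stop("need >= 2 sequences", "mito_input_error")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sites <- polymorphic_sites(x, ref_start = ref_start)
  message(sprintf("scanned %d columns: %d polymorphic sites", x$n_cols,
                  nrow(sites)))
  cs <- find_conserved_segments(x, params, sites = sites)
  message(sprintf("%d conserved segments (p < %g)", nrow(cs), params$alpha))
  vs <- derive_variable_segments(cs, span = c(1L, x$n_cols))
  cs <- segment_stats(cs, x, sites, ref_start = ref_start)
  vs <- segment_stats(vs, x, sites, ref_start = ref_start)
  if (nrow(vs) >= 2) {
    vs <- tryCatch(group_hypervariable(vs), warning = function(w) {
      message(conditionMessage(w)); suppressWarnings(group_hypervariable(vs))
    })
  }
  all_seg <- rbind(as.data.frame(cs)[, names(cs) != "hvs"],
                   as.data.frame(vs)[, names(vs) != "hvs"])
  all_seg$hvs <- c(rep(NA, nrow(cs)), if (!is.null(vs$hvs)) vs$hvs else
    rep(NA, nrow(vs)))
  all_seg <- all_seg[order(all_seg$start_col), , drop = FALSE]
  write_report(all_seg, file.path(out_dir, "segments.tsv"), seed = seed)
  bed <- data.frame(chrom = "CR", start = all_seg$start_col - 1L,
                    end = all_seg$end_col, name = all_seg$label)
  utils::write.table(bed, file.path(out_dir, "segments.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(list(segments = all_seg, cs = cs, vs = vs, sites = sites))
}

#' Inter-individual variability report
#'
#' Scans an alignment for polymorphic sites and writes: the per-site table
#' (`sites.tsv`), the weighted frequency-bin table (`freq_bins.tsv`, grouped
#' by segment when a segment table is supplied), the site-type tabulation
#' (`site_types.tsv`) and, when annotations are given, the per-gene variant
#' table (`per_gene.tsv`).
#'
#' @param alignment Path to gapped FASTA, or [msa()].
#' @param out_dir Output directory.
#' @param annotations Optional annotation file path or [gene_annotation()].
#' @param L Genome length (required with annotations).
#' @param segments Optional `segment_table` used to group the bin table.
#' @param ref_start Reference coordinate of the first reference base.
#' @param seed Recorded in headers.
#' @return Invisibly: list with `sites`, `bins`, `types`, and `per_gene`
#'   (NULL without annotations).
#' @export
run_interdiv <- function(alignment, out_dir = ".", annotations = NULL,
                         L = NULL, segments = NULL, ref_start = 1L,
                         seed = NULL) {
  x <- if (inherits(alignment, "msa")) alignment else read_alignment(alignment)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sites <- polymorphic_sites(x, ref_start = ref_start)
  message(sprintf("%d polymorphic sites", nrow(sites)))
  flat <- data.frame(msa_column = sites$msa_column,
                     reference_position = sites$reference_position,
                     reference_allele = sites$reference_allele,
                     variants = vapply(sites$variants, paste, "", collapse = ","),
                     variant_freq_pct = vapply(sites$variant_freq_pct, function(f)
                       paste(sprintf("%.2f", f), collapse = ","), ""),
                     type = sites$type_label)
  write_report(flat, file.path(out_dir, "sites.tsv"), seed = seed)
  groups <- NULL
  if (!is.null(segments)) {
    groups <- vapply(sites$msa_column, function(cc) {
      hit <- which(segments$start_col <= cc & segments$end_col >= cc)
      if (length(hit)) segments$label[hit[1]] else "outside"
    }, "")
  }
  bins <- weighted_bin_distribution(sites, groups = groups)
  tot <- freq_bin_totals(bins)
  write_report(bins, file.path(out_dir, "freq_bins.tsv"), seed = seed,
               extra = sprintf("grand_total=%g (site count conserved)",
                               tot$grand_total))
  types <- site_type_summary(sites)
  write_report(types, file.path(out_dir, "site_types.tsv"), seed = seed)
  per_gene <- NULL
  if (!is.null(annotations)) {
    ann <- if (inherits(annotations, "gene_annotation")) annotations else
      read_annotations(annotations)
    if (is.null(L)) mito_stop("L required with annotations", "mito_input_error")
    if (max(ann$start, ann$end) > L) {
      mito_stop("annotation exceeds genome length", "mito_input_error")
    }
    per_gene <- per_gene_variant_table(sites, ann, L = L)
    write_report(as.data.frame(per_gene), file.path(out_dir, "per_gene.tsv"),
                 seed = seed)
  }
  invisible(list(sites = sites, bins = bins, types = types,
                 per_gene = per_gene))
}

#' Heteroplasmy report
#'
#' Calls intra-individual variants from a text pileup (or re-loads a VCF),
#' then writes the call VCF (`het_calls.vcf`), the per-gene frequency-bin
#' summary (`het_per_gene.tsv`, with a `pattern` column classifying each
#' gene's bin occupancy), the indel composition (`indel_composition.tsv`)
#' and the invariable regions (`invariable_regions.tsv`).
#'
#' @param pileup Path to a samtools-style text pileup (or `.vcf`), or a
#'   `pileup` table.
#' @param annotations Annotation path or [gene_annotation()].
#' @param out_dir Output directory.
#' @param L Genome length.
#' @param params [het_caller_params()].
#' @param genome Optional reference sequence string (homopolymer context).
#' @param comma_decimal Render VI with a decimal comma (default FALSE).
#' @param seed Recorded in headers.
#' @return Invisibly: list with `variants`, `per_gene`, `composition`,
#'   `invariable`.
#' @export
run_hetero <- function(pileup, annotations, out_dir = ".", L = NULL,
                       params = het_caller_params(), genome = NULL,
                       comma_decimal = FALSE, seed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(pileup) && grepl("\\.vcf$", pileup, ignore.case = TRUE)) {
    variants <- read_het_vcf(pileup)
  } else {
    pu <- if (inherits(pileup, "pileup")) pileup else read_pileup(pileup)
    variants <- call_variants(pu, params = params, genome = genome)
    if (is.null(L)) L <- max(pu$pos)
  }
  if (is.null(L)) L <- max(variants$position, 1L)
  ann <- if (inherits(annotations, "gene_annotation")) annotations else
    read_annotations(annotations)
  message(sprintf("%d variants (%d called)", nrow(variants),
                  sum(variants$called)))
  write_het_vcf(variants, file.path(out_dir, "het_calls.vcf"))
  per_gene <- if (sum(variants$called) > 0) {
    summarize_by_gene(variants, ann, L = L)
  } else NULL
  if (!is.null(per_gene)) {
    out_pg <- as.data.frame(per_gene)
    if (comma_decimal) {
      out_pg$vi <- sub(".", ",", sprintf("%.2f%%", out_pg$vi), fixed = TRUE)
    }
    write_report(out_pg, file.path(out_dir, "het_per_gene.tsv"), seed = seed)
  } else {
    write_report(data.frame(), file.path(out_dir, "het_per_gene.tsv"),
                 seed = seed)
  }
  comp <- indel_composition(variants)
  write_report(comp$by_event, file.path(out_dir, "indel_composition.tsv"),
               seed = seed,
               extra = sprintf("insertions=%d; deletions=%d; substitutions=%d; max_indel=%d",
                               comp$n_insertions, comp$n_deletions,
                               comp$n_substitutions, comp$max_indel_length))
  inv <- if (sum(variants$called) > 0) {
    invariable_regions(variants$position[variants$called], L = L)
  } else list(max_gap = NA, regions = data.frame())
  write_report(inv$regions, file.path(out_dir, "invariable_regions.tsv"),
               seed = seed, extra = sprintf("max_gap=%s", inv$max_gap))
  invisible(list(variants = variants, per_gene = per_gene,
                 composition = comp, invariable = inv))
}

#' Inter- vs intra-individual comparison report
#'
#' Joins per-gene VI tables from the inter-individual and heteroplasmy
#' analyses over a shared name universe and writes `comparison.tsv`
#' together with the variable-segment polymorphism profile
#' (`vs_profile.tsv`).
#'
#' @param inter Named VI vector, `gene_variant_table`, or path to a
#'   `per_gene.tsv` report.
#' @param intra Named VI vector, `het_gene_table`, or path to a
#'   `het_per_gene.tsv` report.
#' @param out_dir Output directory.
#' @param universe Region-name universe; default is the union of the two
#'   tables' names.
#' @param vs_counts Optional per-VS polymorphic counts for the profile.
#' @param seed Recorded in headers.
#' @return Invisibly: list with `comparison` and `profile`.
#' @export
run_compare <- function(inter, intra, out_dir = ".", universe = NULL,
                        vs_counts = NULL, seed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  as_vi <- function(obj) {
    if (is.character(obj) && length(obj) == 1) obj <- read_report(obj)
    if (is.data.frame(obj)) return(stats::setNames(obj$vi, obj$gene))
    obj
  }
  vi_inter <- as_vi(inter)
  vi_intra <- as_vi(intra)
  if (is.null(universe)) {
    universe <- union(normalize_region_name(names(vi_inter)),
                      normalize_region_name(names(vi_intra)))
  }
  cmp <- join_vi_tables(vi_inter, vi_intra, universe)
  write_report(as.data.frame(cmp), file.path(out_dir, "comparison.tsv"),
               seed = seed,
               extra = sprintf("inter_only=%d; intra_only=%d; both=%d; neither=%d",
                               sum(cmp$category == "inter_only"),
                               sum(cmp$category == "intra_only"),
                               sum(cmp$category == "both"),
                               sum(cmp$category == "neither")))
  profile <- NULL
  if (!is.null(vs_counts)) {
    profile <- vs_profile(vs_counts)
    write_report(data.frame(segment = names(profile$profile),
                            n_polymorphic = as.numeric(profile$profile),
                            is_peak = seq_along(profile$profile) %in%
                              profile$peaks),
                 file.path(out_dir, "vs_profile.tsv"), seed = seed)
  }
  invisible(list(comparison = cmp, profile = profile))
}

#' Distance + UPGMA tree command
#'
#' Computes the pairwise distance matrix under the requested model, builds
#' the UPGMA tree with bootstrap support, and writes the Newick tree
#' (`tree.nwk`) and the distance matrix in square PHYLIP format
#' (`distances.phy`).
#'
#' @param alignment Path to gapped FASTA, or [msa()].
#' @param out_dir Output directory.
#' @param model Distance model (`"p"`, `"TN93"`, `"T92"`).
#' @param gamma Optional gamma shape (e.g. 0.18 for a control region).
#' @param n_boot Bootstrap replicates (default 100; 0 disables).
#' @param seed Seed for the bootstrap resampling.
#' @return Invisibly: list with `tree` and `dist`.
#' @export
run_tree <- function(alignment, out_dir = ".", model = "p", gamma = NULL,
                     n_boot = 100, seed = 1) {
  x <- if (inherits(alignment, "msa")) alignment else read_alignment(alignment)
  if (x$n_seqs < 3) warning("fewer than 3 taxa: degenerate tree")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  d <- pairwise_distance(x, model = model, gamma = gamma)
  tree <- if (n_boot > 0) {
    bootstrap_support(x, model = model, gamma = gamma, n_reps = n_boot,
                      seed = seed)
  } else {
    upgma(d)
  }
  ape::write.tree(tree, file.path(out_dir, "tree.nwk"))
  write_phylip_dist(d, file.path(out_dir, "distances.phy"))
  invisible(list(tree = tree, dist = d))
}

#' Generate and write a full synthetic dataset
#'
#' Writes the three synthetic inputs with their ground truth to `out_dir`:
#' the control-region haplotype panel (`cr_panel.fasta`,
#' `cr_truth.json`), the mitogenome quartet (`quartet.fasta`,
#' `quartet_annotations.tsv`, `quartet_truth.json`) and the heteroplasmy
#' pileup (`het.pileup`, `het_annotations.tsv`, `het_truth.vcf`).
#'
#' @param out_dir Output directory.
#' @param seed Integer seed used for all three generators.
#' @param full Generate the full-size defaults (`TRUE`) or small fast
#'   variants for smoke testing (`FALSE`).
#' @return Invisibly: list of the three generator outputs.
#' @export
run_simulate <- function(out_dir = ".", seed = 1, full = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  panel_cfg <- if (full) cr_panel_config(seed = seed) else
    cr_panel_config(n_haplotypes = 10,
                    cs_lengths = c(25, 30), vs_lengths = c(40, 60),
                    vs_variant_counts = c(4, 6),
                    type_counts = c(transition = 8, transversion = 2),
                    bin_site_counts = c(6, 4), seed = seed)
  panel <- generate_cr_panel(panel_cfg)
  write_alignment(panel$msa, file.path(out_dir, "cr_panel.fasta"))
  write_truth_json(panel$truth, file.path(out_dir, "cr_truth.json"))
  quart <- generate_genome_quartet(quartet_config(seed = seed))
  write_alignment(quart$msa, file.path(out_dir, "quartet.fasta"))
  write_annotations(quart$annotations,
                    file.path(out_dir, "quartet_annotations.tsv"))
  write_truth_json(quart$truth, file.path(out_dir, "quartet_truth.json"))
  het_cfg <- if (full) het_sim_config(seed = seed) else
    het_sim_config(gene_table = het_gene_reference()[1:4, ],
                   genome_length = 2000, seed = seed)
  het <- generate_het_pileup(het_cfg)
  write_pileup(het$pileup, file.path(out_dir, "het.pileup"))
  write_annotations(het$annotations, file.path(out_dir, "het_annotations.tsv"))
  write_truth_vcf(het$truth, het$genome, file.path(out_dir, "het_truth.vcf"))
  invisible(list(panel = panel, quartet = quart, het = het))
}
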