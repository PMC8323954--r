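#' Evaluate code under a temporary RNG seed
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Configuration for the synthetic control-region haplotype panel
#'
#' Defaults emulate the published 45-haplotype control-region panel: seven
#' conserved segments (lengths 40, 27, 23, 20, 27, 35, 24 bp — 196 bp in
#' total) alternating with seven variable segments (lengths 55, 89, 354,
#' 110, 11, 130, 56 bp) that carry 7, 19, 95, 18, 3, 26 and 14 planted
#' polymorphic columns respectively (182 sites). Site types are planted
#' with the panel's composition (143 transition-only, 16 transversion-only,
#' 11 transition+transversion, 9 indel-only, 3 indel+transition) and
#' primary-variant frequencies are drawn so the five 10% frequency bins
#' receive 111, 27, 13, 13 and 18 sites (most variants at low frequency).
#'
#' @param n_haplotypes Number of aligned haplotypes (default 45).
#' @param cs_lengths Planted conserved-segment lengths (5'->3').
#' @param vs_lengths Planted variable-segment lengths.
#' @param vs_variant_counts Polymorphic columns planted per VS.
#' @param type_counts Named counts over site-type categories
#'   (`transition`, `transversion`, `both`, `indel`, `indel_transition`);
#'   recycled/truncated to the total site count.
#' @param bin_site_counts Sites per 10% primary-variant frequency bin.
#' @param ref_start Reference coordinate of the first alignment column.
#' @param seed Integer seed; identical config + seed gives byte-identical
#'   output.
#' @return list of class `cr_panel_config`.
#' @export
cr_panel_config <- function(n_haplotypes = 45,
                            cs_lengths = c(40, 27, 23, 20, 27, 35, 24),
                            vs_lengths = c(55, 89, 354, 110, 11, 130, 56),
                            vs_variant_counts = c(7, 19, 95, 18, 3, 26, 14),
                            type_counts = c(transition = 143,
                                            transversion = 16, both = 11,
                                            indel = 9, indel_transition = 3),
                            bin_site_counts = c(111, 27, 13, 13, 18),
                            ref_start = 14996,
                            seed = 1) {
  stopifnot(length(cs_lengths) == length(vs_lengths),
            length(vs_lengths) == length(vs_variant_counts),
            all(vs_variant_counts >= 1), all(vs_variant_counts <= vs_lengths),
            n_haplotypes >= 2)
  structure(list(n_haplotypes = as.integer(n_haplotypes),
                 cs_lengths = as.integer(cs_lengths),
                 vs_lengths = as.integer(vs_lengths),
                 vs_variant_counts = as.integer(vs_variant_counts),
                 type_counts = type_counts,
                 bin_site_counts = bin_site_counts,
                 ref_start = as.integer(ref_start),
                 seed = as.integer(seed)),
            class = "cr_panel_config")
}

#' @noRd
transition_partner <- function(b) c(A = "G", G = "A", C = "T", T = "C")[[b]]

#' @noRd
transversion_partner <- function(b) {
  if (b %in% PURINES) sample(PYRIMIDINES, 1) else sample(PURINES, 1)
}

#' Generate a synthetic control-region haplotype panel
#'
#' Builds a gapped alignment with planted conserved runs (identical across
#' all haplotypes) and planted polymorphic columns realized at exact allele
#' counts (frequencies are census ratios, not samples). Variant columns
#' within each variable segment include its first and last columns and are
#' spread evenly, so no monomorphic run inside a VS reaches the conserved
#' window length and planted segment boundaries are recovered exactly.
#' Indel variants are realized as gap characters. The first haplotype never
#' carries a variant and serves as the coordinate-reference record.
#'
#' @param config A [cr_panel_config()].
#' @return list with `msa` (the [msa()] panel) and `truth`: `segments`
#'   (planted layout: label, kind, start/end columns, length, n planted
#'   variants) and `sites` (per planted column: segment, reference allele,
#'   variant alleles, counts, frequencies, type category).
#' @export
generate_cr_panel <- function(config = cr_panel_config()) {
  stopifnot(inherits(config, "cr_panel_config"))
  with_seed(config$seed, generate_cr_panel_impl(config))
}

#' @noRd
generate_cr_panel_impl <- function(config) {
  n <- config$n_haplotypes
  nseg <- length(config$cs_lengths)
  # layout: CS1 VS1 CS2 VS2 ... (alternating, conserved first)
  lens <- as.vector(rbind(config$cs_lengths, config$vs_lengths))
  kinds <- rep(c("conserved", "variable"), nseg)
  labels <- as.vector(rbind(sprintf("CS%d", seq_len(nseg)),
                            sprintf("VS%d", seq_len(nseg))))
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  L <- ends[length(ends)]
  segments <- data.frame(label = labels, kind = kinds, start_col = starts,
                         end_col = ends, length = lens,
                         n_planted = as.vector(rbind(rep(NA, nseg),
                                                     config$vs_variant_counts)),
                         stringsAsFactors = FALSE)
  base_seq <- sample(DNA_BASES, L, replace = TRUE)
  mat <- matrix(rep(base_seq, each = n), nrow = n)

  # planted variant columns per VS: endpoints included, evenly spread
  vs_rows <- which(segments$kind == "variable")
  site_cols <- integer(0)
  site_seg <- character(0)
  for (r in vs_rows) {
    len <- segments$length[r]
    k <- segments$n_planted[r]
    off <- if (k == 1) round(len / 2) else unique(round(seq(1, len, length.out = k)))
    while (length(off) < k) {            # fill collisions from rounding
      off <- sort(union(off, setdiff(seq_len(len), off)[1]))
    }
    site_cols <- c(site_cols, segments$start_col[r] + off - 1L)
    site_seg <- c(site_seg, rep(segments$label[r], k))
  }
  S <- length(site_cols)

  # site type categories at exact planted counts
  tc <- config$type_counts
  types <- rep(names(tc), times = tc)
  if (length(types) < S) {
    types <- c(types, rep("transition", S - length(types)))
  }
  types <- sample(types)[seq_len(S)]

  # primary-variant allele counts per frequency bin (k/n in (b-1)*10..b*10 %)
  bins <- rep(seq_along(config$bin_site_counts), times = config$bin_site_counts)
  if (length(bins) < S) bins <- c(bins, rep(1L, S - length(bins)))
  bins <- sample(bins)[seq_len(S)]
  k_range <- function(b) {
    ks <- seq_len(floor(n / 2))
    ks[100 * ks / n > (b - 1) * 10 & 100 * ks / n <= b * 10]
  }
  multi <- types %in% c("both", "indel_transition")
  k1 <- vapply(seq_len(S), function(i) {
    ks <- k_range(bins[i])
    if (multi[i]) ks <- ks[n - 2 * ks - 1 >= 1]  # room for a second variant
    if (length(ks) == 0) ks <- 1L
    ks[sample.int(length(ks), 1)]
  }, 0L)

  truth_sites <- vector("list", S)
  for (i in seq_len(S)) {
    col <- site_cols[i]
    ref <- base_seq[col]
    v1 <- switch(types[i],
                 transition = transition_partner(ref),
                 transversion = transversion_partner(ref),
                 both = transition_partner(ref),
                 indel = GAP,
                 indel_transition = GAP)
    v2 <- switch(types[i],
                 both = transversion_partner(ref),
                 indel_transition = transition_partner(ref),
                 NULL)
    kk1 <- k1[i]
    kk2 <- if (!is.null(v2)) max(1L, min(kk1, n - 2L * kk1 - 1L)) else 0L
    carriers <- sample(2:n, kk1 + kk2)   # haplotype 1 is the reference record
    mat[carriers[seq_len(kk1)], col] <- v1
    if (kk2 > 0) mat[carriers[kk1 + seq_len(kk2)], col] <- v2
    truth_sites[[i]] <- data.frame(
      msa_column = col, segment = site_seg[i], reference_allele = ref,
      variants = paste(c(v1, v2), collapse = ","),
      counts = paste(c(kk1, if (kk2 > 0) kk2), collapse = ","),
      freq_pct = paste(sprintf("%.12g", 100 * c(kk1, if (kk2 > 0) kk2) / n),
                       collapse = ","),
      type = types[i], stringsAsFactors = FALSE)
  }
  seqs <- apply(mat, 1, paste, collapse = "")
  ids <- sprintf("hap%02d", seq_len(n))
  panel <- msa(ids, seqs, reference_id = ids[1])
  truth <- list(segments = segments,
                sites = do.call(rbind, truth_sites),
                ref_start = config$ref_start,
                n_haplotypes = n, seed = config$seed)
  list(msa = panel, truth = truth)
}

#' Configuration for the synthetic mitogenome quartet
#'
#' Defaults emulate an inter-individual comparison of four complete
#' mitogenomes: per-gene planted counts of singleton (25% frequency) and
#' doubleton (2v2 split, 50% frequency) substitution sites following the
#' published per-gene tallies (212 sites over 27 genes/regions).
#'
#' @param genes data.frame with `gene`, `group`, `fi25`, `fi50`,
#'   `length_bp` (default [mitogenome_gene_reference()]).
#' @param genome_length Total genome length (genes are laid out
#'   consecutively from position 1; the remainder is intergenic).
#' @param transversion_prob Probability that a planted substitution is a
#'   transversion rather than a transition (default 0.18).
#' @param seed Integer seed.
#' @return list of class `quartet_config`.
#' @export
quartet_config <- function(genes = mitogenome_gene_reference(),
                           genome_length = 15989,
                           transversion_prob = 0.18,
                           seed = 1) {
  stopifnot(all(c("gene", "group", "fi25", "fi50", "length_bp") %in% names(genes)))
  total <- sum(genes$length_bp)
  if (total > genome_length) {
    mito_stop("genes do not fit in genome_length", "mito_validation_error")
  }
  structure(list(genes = genes, genome_length = as.integer(genome_length),
                 transversion_prob = transversion_prob,
                 seed = as.integer(seed)),
            class = "quartet_config")
}

#' Generate a synthetic mitogenome quartet
#'
#' Mutates a random ancestor genome into four descendants, planting in each
#' gene the configured number of singleton sites (one genome carries the
#' variant: frequency 1/4) and doubleton sites (a 2v2 split: two genomes
#' carry each allele, which after reference designation counts as a single
#' 50% variant). No indels are planted, so the four genomes align
#' column-wise. Genome 1 is never mutated and serves as the reference
#' record.
#'
#' @param config A [quartet_config()].
#' @return list with `genomes` (4 [circular_genome()]s), `msa` (their
#'   trivial alignment), `annotations` ([gene_annotation()]), and `truth`
#'   (planted per-gene counts and per-site records).
#' @export
generate_genome_quartet <- function(config = quartet_config()) {
  stopifnot(inherits(config, "quartet_config"))
  with_seed(config$seed, generate_genome_quartet_impl(config))
}

#' @noRd
generate_genome_quartet_impl <- function(config) {
  genes <- config$genes
  L <- config$genome_length
  ends <- cumsum(genes$length_bp)
  starts <- ends - genes$length_bp + 1L
  ann <- gene_annotation(genes$gene, genes$group, starts, ends)
  anc <- sample(DNA_BASES, L, replace = TRUE)
  mat <- matrix(rep(anc, each = 4), nrow = 4)
  sites <- list()
  for (g in seq_len(nrow(genes))) {
    n25 <- genes$fi25[g]; n50 <- genes$fi50[g]
    npos <- n25 + n50
    if (npos == 0) next
    if (npos > genes$length_bp[g]) {
      mito_stop(sprintf("gene %s too short for planted sites", genes$gene[g]),
                "mito_validation_error")
    }
    pos <- sort(sample(starts[g]:ends[g], npos))
    cls <- sample(c(rep("25", n25), rep("50", n50)))
    for (s in seq_len(npos)) {
      ref <- anc[pos[s]]
      alt <- if (stats::runif(1) < config$transversion_prob) {
        transversion_partner(ref)
      } else transition_partner(ref)
      if (cls[s] == "25") {
        who <- sample(2:4, 1)             # genome 1 stays reference-like
      } else {
        who <- c(3L, 4L)                  # 2v2 split
      }
      mat[who, pos[s]] <- alt
      sites[[length(sites) + 1L]] <- data.frame(
        position = pos[s], gene = genes$gene[g], reference_allele = ref,
        variant_allele = alt, freq_class = cls[s], stringsAsFactors = FALSE)
    }
  }
  seqs <- apply(mat, 1, paste, collapse = "")
  ids <- sprintf("genome%d", 1:4)
  genomes <- lapply(1:4, function(i) circular_genome(ids[i], seqs[i]))
  names(genomes) <- ids
  truth_sites <- if (length(sites)) do.call(rbind, sites) else
    data.frame(position = integer(0), gene = character(0),
               reference_allele = character(0), variant_allele = character(0),
               freq_class = character(0))
  list(genomes = genomes,
       msa = msa(ids, seqs, reference_id = ids[1]),
       annotations = ann,
       truth = list(genes = genes, sites = truth_sites, seed = config$seed))
}

#' Default planted heteroplasmy event pool
#'
#' The event pool emulating the published intra-individual composition:
#' 112 insertions (66 single T, 44 single A, one AT, one CT), 72 deletions
#' (36 T, 20 A, 9 C, 6 G, one AA) and 2 transition substitutions — 186
#' events, largest indel 2 bp, C+G involved in 15/72 deletions (~21%).
#'
#' @return data.frame `type`, `seq` (one row per event).
#' @export
default_het_composition <- function() {
  rbind(
    data.frame(type = "insertion",
               seq = c(rep("T", 66), rep("A", 44), "AT", "CT")),
    data.frame(type = "deletion",
               seq = c(rep("T", 36), rep("A", 20), rep("C", 9), rep("G", 6),
                       "AA")),
    data.frame(type = "substitution", seq = c("ts", "ts"))
  )
}

#' Configuration for the synthetic heteroplasmy pileup
#'
#' Defaults emulate a single-individual mitogenome read pileup: per-site
#' coverage drawn from a negative binomial with mean 128.4 and standard
#' deviation 51.3, and 186 planted variants distributed over the annotated
#' genes following the published per-gene, per-frequency-interval tallies,
#' with event types drawn from [default_het_composition()] (predominantly
#' single-base A/T indels at sub-50% frequencies).
#'
#' @param gene_table data.frame as returned by [het_gene_reference()]
#'   (per-gene bin counts and lengths) driving where and at what frequency
#'   variants are planted; fractional lengths are floored.
#' @param genome_length Genome length in bp.
#' @param depth_mean,depth_sd Coverage model (negative binomial); a zero
#'   `depth_sd` gives constant coverage.
#' @param composition Event pool (data.frame `type`, `seq`); defaults to
#'   [default_het_composition()], truncated/recycled to the number of
#'   planted variants.
#' @param error_rate Background per-read error rate at non-planted sites
#'   (default 0: noise off).
#' @param sample_support Draw supporting reads binomially at the planted
#'   fraction (`TRUE`, the realistic default) or fix them at
#'   `round(f * depth)` for exact recovery checks (`FALSE`).
#' @param min_fraction Lower bound applied to planted fractions so variants
#'   stay detectable at the configured depth.
#' @param seed Integer seed.
#' @return list of class `het_sim_config`.
#' @export
het_sim_config <- function(gene_table = het_gene_reference(),
                           genome_length = 15989,
                           depth_mean = 128.4, depth_sd = 51.3,
                           composition = default_het_composition(),
                           error_rate = 0,
                           sample_support = TRUE,
                           min_fraction = 0.04,
                           seed = 1) {
  stopifnot(depth_mean > 0, depth_sd >= 0)
  structure(list(gene_table = gene_table,
                 genome_length = as.integer(genome_length),
                 depth_mean = depth_mean, depth_sd = depth_sd,
                 composition = composition, error_rate = error_rate,
                 sample_support = isTRUE(sample_support),
                 min_fraction = min_fraction,
                 seed = as.integer(seed)),
            class = "het_sim_config")
}

#' Generate a synthetic heteroplasmy pileup
#'
#' Lays the genes of `gene_table` consecutively on a random genome, plants
#' one variant per configured gene/frequency-bin count (fraction drawn
#' uniformly inside the bin, bounded below by `min_fraction`), draws
#' per-site coverage from the negative-binomial depth model, and writes
#' supporting reads either binomially at the planted fraction or exactly.
#' Non-planted sites are pure reference calls, plus optional error-rate
#' noise. Planted positions are spaced at least 4 bp apart so anchored
#' indel representations never collide.
#'
#' @param config A [het_sim_config()].
#' @return list with `pileup` (a [read_pileup()]-style table), `genome`
#'   (the reference [circular_genome()]), `annotations`, and `truth`
#'   (data.frame of planted variants: position, type, seq, fraction, gene,
#'   bin).
#' @export
generate_het_pileup <- function(config = het_sim_config()) {
  stopifnot(inherits(config, "het_sim_config"))
  with_seed(config$seed, generate_het_pileup_impl(config))
}

#' @noRd
generate_het_pileup_impl <- function(config) {
  gt <- config$gene_table
  L <- config$genome_length
  glens <- as.integer(floor(gt$length_bp))
  ends <- cumsum(glens)
  if (ends[length(ends)] > L) {
    mito_stop("genes do not fit in genome_length", "mito_validation_error")
  }
  starts <- ends - glens + 1L
  ann <- gene_annotation(gt$gene, gt$group, starts, ends)
  genome_chars <- sample(DNA_BASES, L, replace = TRUE)

  bins <- grep("^\\(", names(gt), value = TRUE)
  # planted slots: gene x bin counts
  slots <- list()
  for (g in seq_len(nrow(gt))) {
    for (b in seq_along(bins)) {
      cnt <- gt[[bins[b]]][g]
      if (cnt > 0) {
        slots[[length(slots) + 1L]] <- data.frame(
          gene = gt$gene[g], gi = g, bin = b, n = cnt,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(slots)) {
    slots <- do.call(rbind, slots)
    slots <- slots[rep(seq_len(nrow(slots)), slots$n), c("gene", "gi", "bin")]
  } else {
    slots <- data.frame(gene = character(0), gi = integer(0), bin = integer(0))
  }
  nvar <- nrow(slots)

  comp <- config$composition
  if (nrow(comp) < nvar) {
    comp <- comp[rep(seq_len(nrow(comp)), length.out = nvar), , drop = FALSE]
  }
  comp <- comp[sample.int(nrow(comp))[seq_len(nvar)], , drop = FALSE]

  # positions: within the slot's gene, spaced >= 4 bp apart genome-wide
  taken <- integer(0)
  pos <- integer(nvar)
  for (i in seq_len(nvar)) {
    gi <- slots$gi[i]
    cand <- setdiff(starts[gi]:(ends[gi] - 3L), unlist(lapply(taken, function(p) (p - 3L):(p + 3L))))
    if (length(cand) == 0) {
      mito_stop(sprintf("cannot place planted variant in gene %s", slots$gene[i]),
                "mito_validation_error")
    }
    pos[i] <- if (length(cand) == 1) cand else sample(cand, 1)
    taken <- c(taken, pos[i])
  }
  frac <- numeric(nvar)
  for (i in seq_len(nvar)) {
    lo <- (slots$bin[i] - 1) / 10
    hi <- slots$bin[i] / 10
    frac[i] <- stats::runif(1, max(lo, config$min_fraction), hi)
  }
  # deletions consume the bases after the anchor: make the genome agree
  for (i in seq_len(nvar)) {
    if (comp$type[i] == "deletion") {
      s <- strsplit(comp$seq[i], "", fixed = TRUE)[[1]]
      genome_chars[pos[i] + seq_along(s)] <- s
    }
  }
  # substitutions: transition partner of the reference base
  alt_seq <- comp$seq
  for (i in seq_len(nvar)) {
    if (comp$type[i] == "substitution") {
      alt_seq[i] <- transition_partner(genome_chars[pos[i]])
    }
  }

  # coverage model
  mu <- config$depth_mean
  if (config$depth_sd > 0 && config$depth_sd^2 > mu) {
    size <- mu^2 / (config$depth_sd^2 - mu)
    depth <- stats::rnbinom(L, size = size, mu = mu)
  } else {
    depth <- rep(round(mu), L)
  }
  depth <- pmax(depth, 1L)

  planted_at <- integer(L)
  planted_at[pos] <- seq_len(nvar)
  star_extra <- integer(L)   # deletion placeholders at downstream positions

  bases_col <- character(L)
  support <- integer(nvar)
  for (p in seq_len(L)) {
    d <- depth[p]
    i <- planted_at[p]
    if (i > 0) {
      f <- frac[i]
      sup <- if (config$sample_support) stats::rbinom(1, d, f) else
        as.integer(round(f * d))
      sup <- max(0L, min(sup, d))
      support[i] <- sup
      ty <- comp$type[i]
      sq <- alt_seq[i]
      if (ty == "insertion") {
        bases_col[p] <- paste0(strrep(".", d - sup),
                               strrep(sprintf(".+%d%s", nchar(sq), sq), sup))
      } else if (ty == "deletion") {
        bases_col[p] <- paste0(strrep(".", d - sup),
                               strrep(sprintf(".-%d%s", nchar(sq), sq), sup))
        star_extra[p + seq_len(nchar(sq))] <- sup
      } else {
        bases_col[p] <- paste0(strrep(".", d - sup), strrep(sq, sup))
      }
    } else {
      nerr <- if (config$error_rate > 0) stats::rbinom(1, d, config$error_rate) else 0L
      if (nerr > 0) {
        errs <- sample(setdiff(DNA_BASES, genome_chars[p]), nerr, replace = TRUE)
        bases_col[p] <- paste0(strrep(".", d - nerr), paste(errs, collapse = ""))
      } else {
        bases_col[p] <- strrep(".", d)
      }
    }
    if (star_extra[p] > 0 && i == 0) {
      bases_col[p] <- paste0(bases_col[p], strrep("*", star_extra[p]))
    }
  }
  pile <- data.frame(chrom = "chrM", pos = seq_len(L), ref = genome_chars,
                     coverage = depth, stringsAsFactors = FALSE)
  pile$bases <- bases_col
  truth <- data.frame(position = pos, type = comp$type, seq = alt_seq,
                      fraction = frac, gene = slots$gene, bin = slots$bin,
                      support = support, depth = depth[pos],
                      stringsAsFactors = FALSE)
  truth <- truth[order(truth$position), , drop = FALSE]
  rownames(truth) <- NULL
  list(pileup = pile, genome = circular_genome("chrM",
                                               paste(genome_chars, collapse = "")),
       annotations = ann,
       truth = truth)
}

#' Write a generated pileup to a samtools-style text file
#'
#' @param pileup The `pileup` element of [generate_het_pileup()] output
#'   (columns `chrom`, `pos`, `ref`, `coverage`, `bases`).
#' @param path Output path.
#' @export
write_pileup <- function(pileup, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%s\t%d\t%s\t%d\t%s\t%s", pileup$chrom, pileup$pos,
                     pileup$ref, pileup$coverage, pileup$bases,
                     strrep("I", pileup$coverage)), con)
  invisible(path)
}

#' Write a planted-variant truth table as VCF
#'
#' @param truth The `truth` element of [generate_het_pileup()] output.
#' @param genome The reference [circular_genome()].
#' @param path Output path.
#' @export
write_truth_vcf <- function(truth, genome, path) {
  chars <- strsplit(genome$sequence, "", fixed = TRUE)[[1]]
  ref <- alt <- character(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    p <- truth$position[i]
    if (truth$type[i] == "insertion") {
      ref[i] <- chars[p]; alt[i] <- paste0(chars[p], truth$seq[i])
    } else if (truth$type[i] == "deletion") {
      ref[i] <- paste0(chars[p], truth$seq[i]); alt[i] <- chars[p]
    } else {
      ref[i] <- chars[p]; alt[i] <- truth$seq[i]
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=mitodiv synthetic truth",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tAF=%.6f", genome$id,
                     truth$position, ref, alt, truth$fraction), con)
  invisible(path)
}

#' Serialize a generator truth object to JSON
#'
#' @param truth Truth list/data.frame from any generator.
#' @param path Output path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, dataframe = "columns", auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
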