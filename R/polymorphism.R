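#' Scan an alignment for polymorphic sites
#'
#' A polymorphic site is an alignment column with at least two distinct
#' observed alleles, where the gap character counts as an allele (indel
#' column) and `N` is treated as missing data: `N` calls are excluded from
#' both the allele counts and the frequency denominator, and all-`N` columns
#' are skipped.
#'
#' @param x An [msa()] object.
#' @param gaps_as_alleles If `FALSE`, gap calls are dropped from the
#'   denominator like `N` (so pure indel columns are not reported). The
#'   default `TRUE` treats gaps as segregating alleles.
#' @return A data.frame of class `site_table` with one row per polymorphic
#'   column: `msa_column`, list-column `alleles` (named counts) and `n_eff`
#'   (frequency denominator at that column).
#' @seealso [designate_reference()], [classify_sites()], [polymorphic_sites()]
#' @export
scan_sites <- function(x, gaps_as_alleles = TRUE) {
  stopifnot(inherits(x, "msa"))
  m <- as.matrix(x)
  allowed <- if (gaps_as_alleles) c(DNA_BASES, GAP) else DNA_BASES
  cols <- vector("list", x$n_cols)
  keep <- logical(x$n_cols)
  for (j in seq_len(x$n_cols)) {
    col <- m[, j]
    counts <- vapply(allowed, function(a) sum(col == a), 0L)
    counts <- counts[counts > 0]
    if (length(counts) >= 2) {
      keep[j] <- TRUE
      cols[[j]] <- counts
    }
  }
  out <- data.frame(msa_column = which(keep))
  out$alleles <- cols[keep]
  out$n_eff <- vapply(out$alleles, sum, 0L)
  class(out) <- c("site_table", "data.frame")
  out
}

#' Designate reference and variant alleles at each polymorphic site
#'
#' Variant tables produced by naive SNP callers list the reference allele
#' among the variants, inflating variant counts. The designation rules used
#' here are: (1) an allele with frequency above 50% is the reference;
#' (2) at bi-allelic sites where both alleles sit at exactly 50%, one is the
#' reference and the site carries a single variant — the tie is broken in
#' favour of the allele carried by the alignment's coordinate-reference
#' record, falling back to the lexicographically smaller allele;
#' (3) at tri- and tetra-allelic sites the most frequent allele is the
#' reference and the rest are variants.
#'
#' @param sites A `site_table` from [scan_sites()].
#' @param ref_chars Optional character vector giving, per alignment column,
#'   the base carried by the designated reference record (used for 50/50
#'   tie-breaking). Usually supplied by [polymorphic_sites()].
#' @return The `site_table` with columns `reference_allele`, list-columns
#'   `variants`, `variant_counts`, `variant_freq_pct`, and `n_variants`.
#'   Variant frequencies are percentages of `n_eff` and never exceed 50.
#' @export
designate_reference <- function(sites, ref_chars = NULL) {
  stopifnot(inherits(sites, "site_table"))
  n <- nrow(sites)
  ref <- character(n)
  vars <- vector("list", n)
  vcounts <- vector("list", n)
  for (i in seq_len(n)) {
    counts <- sites$alleles[[i]]
    counts <- sort(counts, decreasing = TRUE)
    top <- names(counts)[counts == counts[1]]
    if (length(top) > 1) {
      # tie at the top (e.g. bi-allelic 50/50): prefer the reference record's
      # base at this column, else the lexicographically smaller allele
      pick <- NULL
      if (!is.null(ref_chars)) {
        rb <- ref_chars[sites$msa_column[i]]
        if (rb %in% top) pick <- rb
      }
      if (is.null(pick)) pick <- sort(top)[1]
      ref[i] <- pick
    } else {
      ref[i] <- top[1]
    }
    v <- counts[names(counts) != ref[i]]
    vars[[i]] <- names(v)
    vcounts[[i]] <- as.integer(v)
  }
  sites$reference_allele <- ref
  sites$variants <- vars
  sites$variant_counts <- vcounts
  sites$variant_freq_pct <- Map(function(vc, ne) 100 * vc / ne,
                                vcounts, sites$n_eff)
  sites$n_variants <- lengths(vars)
  sites
}

#' @noRd
pair_is_transition <- function(a, b) {
  (a %in% PURINES & b %in% PURINES) | (a %in% PYRIMIDINES & b %in% PYRIMIDINES)
}

#' @noRd
pair_is_transversion <- function(a, b) {
  (a %in% PURINES & b %in% PYRIMIDINES) | (a %in% PYRIMIDINES & b %in% PURINES)
}

#' Classify polymorphic sites by substitution/indel content
#'
#' Each site receives flags for the reference/variant allele pairs it
#' contains: `transition` if some pair is A<->G or C<->T, `transversion` if
#' some pair crosses the purine/pyrimidine divide, `indel` if the gap
#' character is among the alleles. Flags combine at multi-allelic sites
#' (e.g. a site segregating C/T/G contains both a transition and a
#' transversion). Every polymorphic site carries at least one flag.
#'
#' @param sites A `site_table` with designated references
#'   ([designate_reference()]).
#' @return The table with logical columns `transition`, `transversion`,
#'   `indel` and a combined `type_label`.
#' @export
classify_sites <- function(sites) {
  stopifnot(inherits(sites, "site_table"),
            !is.null(sites$reference_allele))
  n <- nrow(sites)
  ts <- tv <- ind <- logical(n)
  for (i in seq_len(n)) {
    r <- sites$reference_allele[i]
    vs <- sites$variants[[i]]
    ind[i] <- r == GAP || any(vs == GAP)
    vb <- vs[vs != GAP]
    if (r != GAP && length(vb) > 0) {
      ts[i] <- any(pair_is_transition(r, vb))
      tv[i] <- any(pair_is_transversion(r, vb))
    }
  }
  sites$transition <- ts
  sites$transversion <- tv
  sites$indel <- ind
  lab <- character(n)
  for (i in seq_len(n)) {
    parts <- c(if (ts[i]) "transition", if (tv[i]) "transversion",
               if (ind[i]) "indel")
    lab[i] <- paste(parts, collapse = "+")
  }
  sites$type_label <- lab
  sites
}

#' Full polymorphic-site scan with reference designation and typing
#'
#' Convenience wrapper chaining [scan_sites()], [designate_reference()] and
#' [classify_sites()], and attaching reference coordinates via
#' [coordinate_map()].
#'
#' @inheritParams scan_sites
#' @param ref_start Reference position of the first base of the coordinate
#'   reference record (see [coordinate_map()]).
#' @return A fully annotated `site_table` with `reference_position`.
#' @export
polymorphic_sites <- function(x, ref_start = 1L, gaps_as_alleles = TRUE) {
  sites <- scan_sites(x, gaps_as_alleles = gaps_as_alleles)
  ref_chars <- NULL
  if (!is.null(x$reference_id)) {
    ref_chars <- strsplit(x$seqs[match(x$reference_id, x$ids)], "",
                          fixed = TRUE)[[1]]
  }
  sites <- designate_reference(sites, ref_chars = ref_chars)
  sites <- classify_sites(sites)
  if (!is.null(x$reference_id)) {
    cm <- coordinate_map(x, ref_start = ref_start)
    sites$reference_position <- cm[sites$msa_column]
  } else {
    sites$reference_position <- sites$msa_column
  }
  sites
}

#' Tabulate site-type categories
#'
#' Counts polymorphic sites by exclusive type category (transition-only,
#' transversion-only, transition+transversion, indel-only, combined
#' indel categories) with percentages of the total.
#'
#' @param sites A classified `site_table`.
#' @return data.frame with `category`, `n_sites`, `pct`.
#' @export
site_type_summary <- function(sites) {
  stopifnot(!is.null(sites$type_label))
  tab <- table(sites$type_label)
  out <- data.frame(category = names(tab), n_sites = as.integer(tab),
                    stringsAsFactors = FALSE)
  out$pct <- 100 * out$n_sites / sum(out$n_sites)
  out[order(-out$n_sites), , drop = FALSE]
}

#' Variability index
#'
#' The variability index expresses polymorphism density as a percentage:
#' `VI = 100 * n_polymorphic / length`. Longer genes accumulate more
#' polymorphic sites by chance alone; VI normalizes for length.
#'
#' @param n_polymorphic Number of polymorphic sites (vectorized).
#' @param length Region length in bp (> 0).
#' @return data.frame with `n_polymorphic`, `length`, `vi` (percentage).
#' @examples
#' variability_index(95, 354)$vi  # 26.8 (1 d.p.)
#' @export
variability_index <- function(n_polymorphic, length) {
  if (any(length <= 0)) mito_stop("length must be > 0", "mito_validation_error")
  if (any(n_polymorphic < 0 | n_polymorphic > length)) {
    mito_stop("n_polymorphic must lie in [0, length]", "mito_validation_error")
  }
  data.frame(n_polymorphic = n_polymorphic, length = length,
             vi = 100 * n_polymorphic / length)
}

#' @noRd
bin_labels <- function(bin_width, max_pct) {
  lo <- seq(0, max_pct - bin_width, by = bin_width)
  sprintf("(%g,%g]", lo, lo + bin_width)
}

#' Weighted allele-frequency bin distribution
#'
#' Distributes polymorphic sites over variant-frequency intervals. Each site
#' contributes a total weight of 1, split equally among its variant alleles
#' (1/k for a site with k variants), and each share is added to the
#' left-open right-closed percentage bin containing that variant's
#' frequency. The split prevents multi-allelic sites from being counted more
#' than once, while still recording every variant's frequency; it is what
#' produces fractional table entries of the form m/2, m/3.
#'
#' @param sites A designated `site_table`.
#' @param groups Optional character vector (length `nrow(sites)`) assigning
#'   each site to a row of the output (e.g. its variable segment or gene);
#'   default is a single row `"all"`.
#' @param bin_width Bin width in percent (default 10).
#' @param max_pct Upper bound of the last bin (default 50; after reference
#'   designation no variant can exceed 50%).
#' @return A data.frame of class `freq_bin_table`: one row per group, one
#'   numeric column per bin, plus `total_variants` (unit-weight site count
#'   per row).
#' @export
weighted_bin_distribution <- function(sites, groups = NULL, bin_width = 10,
                                      max_pct = 50) {
  stopifnot(inherits(sites, "site_table"), !is.null(sites$variant_freq_pct))
  if (is.null(groups)) groups <- rep("all", nrow(sites))
  stopifnot(length(groups) == nrow(sites))
  labs <- bin_labels(bin_width, max_pct)
  glev <- unique(groups)
  w <- matrix(0, nrow = length(glev), ncol = length(labs),
              dimnames = list(glev, labs))
  nsite <- stats::setNames(integer(length(glev)), glev)
  for (i in seq_len(nrow(sites))) {
    f <- sites$variant_freq_pct[[i]]
    if (any(f > max_pct + 1e-9)) {
      mito_stop(sprintf(
        "variant frequency %.1f%% exceeds %g%% after reference designation",
        max(f), max_pct), "mito_consistency_error")
    }
    k <- length(f)
    bins <- pmin(pmax(ceiling(f / bin_width - 1e-12), 1L), length(labs))
    g <- groups[i]
    for (b in bins) w[g, b] <- w[g, b] + 1 / k
    nsite[g] <- nsite[g] + 1L
  }
  out <- data.frame(region = glev, stringsAsFactors = FALSE)
  for (j in seq_along(labs)) out[[labs[j]]] <- unname(w[, j])
  out$total_variants <- as.integer(nsite)
  attr(out, "bin_width") <- bin_width
  class(out) <- c("freq_bin_table", "data.frame")
  out
}

#' Column-wise totals and shares of a frequency-bin table
#'
#' @param tbl A `freq_bin_table`.
#' @return list with `bin_totals`, `grand_total` (sum of unit site weights),
#'   `shares_pct` (per-bin percentage of the grand total).
#' @export
freq_bin_totals <- function(tbl) {
  stopifnot(inherits(tbl, "freq_bin_table"))
  bins <- grep("^\\(", names(tbl), value = TRUE)
  bt <- colSums(as.data.frame(tbl)[, bins, drop = FALSE])
  gt <- sum(tbl$total_variants)
  list(bin_totals = bt, grand_total = gt, shares_pct = 100 * bt / sum(bt))
}

#' @export
print.freq_bin_table <- function(x, ...) {
  cat("<freq_bin_table>\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  tot <- freq_bin_totals(x)
  cat(sprintf("Grand total: %g sites; lowest-bin share: %.1f%%\n",
              tot$grand_total, tot$shares_pct[1]))
  invisible(x)
}

#' Per-gene variant table from an alignment scan
#'
#' Assigns polymorphic sites to genes by reference position (sites inside no
#' annotation are grouped as `intergenic`), counts variants per attainable
#' frequency class (for a 4-sequence alignment these are exactly 25% —
#' singleton — and 50% — a 2v2 split, which counts as a single variant),
#' and computes each gene's variability index.
#'
#' @param sites Designated, classified `site_table` with
#'   `reference_position`.
#' @param annotations A [gene_annotation()] table.
#' @param L Genome length in bp.
#' @param keep_intergenic Keep the `intergenic` row (default `TRUE`).
#' @return A data.frame of class `gene_variant_table`: `gene`, `group`, one
#'   count column per frequency class, `total_variants`, `length_bp`, `vi`,
#'   sorted by `vi` descending.
#' @export
per_gene_variant_table <- function(sites, annotations, L,
                                   keep_intergenic = TRUE) {
  stopifnot(inherits(sites, "site_table"), !is.null(sites$variant_freq_pct))
  df <- as.data.frame(annotations)
  lens <- gene_length(annotations, L)
  hit <- genes_at(sites$reference_position, annotations)
  if (any(lengths(hit) > 1)) {
    warning("some sites overlap multiple genes; counted in each")
  }
  # frequency classes: distinct rounded variant percentages observed
  all_pct <- round_half_up(unlist(sites$variant_freq_pct), 1)
  classes <- sort(unique(all_pct))
  class_lab <- sprintf("%g%%", classes)
  genes <- c(unique(df$gene), "intergenic")
  counts <- matrix(0L, nrow = length(genes), ncol = length(classes),
                   dimnames = list(genes, class_lab))
  nsites <- stats::setNames(integer(length(genes)), genes)
  for (i in seq_len(nrow(sites))) {
    gs <- hit[[i]]
    if (length(gs) == 0) gs <- "intergenic"
    pct <- round_half_up(sites$variant_freq_pct[[i]], 1)
    for (g in gs) {
      for (p in pct) {
        counts[g, match(p, classes)] <- counts[g, match(p, classes)] + 1L
      }
      nsites[g] <- nsites[g] + 1L
    }
  }
  out <- data.frame(gene = genes,
                    group = c(df$group[match(unique(df$gene), df$gene)], "-"),
                    stringsAsFactors = FALSE)
  for (j in seq_along(class_lab)) out[[class_lab[j]]] <- counts[, j]
  out$total_variants <- as.integer(rowSums(counts))
  out$length_bp <- c(unname(lens[unique(df$gene)]), NA_integer_)
  out$vi <- ifelse(is.na(out$length_bp), NA_real_,
                   100 * out$total_variants / out$length_bp)
  if (!keep_intergenic) out <- out[out$gene != "intergenic", , drop = FALSE]
  out <- out[out$total_variants > 0, , drop = FALSE]  # genes without variants are absent
  out <- out[order(-ifelse(is.na(out$vi), -Inf, out$vi)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gene_variant_table", "data.frame")
  out
}
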