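#' Heteroplasmy caller parameters
#'
#' Thresholds for calling intra-individual (heteroplasmic) variants from a
#' read pileup, following the VarScan-style contract: a variant needs at
#' least `min_var_reads` supporting reads and frequency at least
#' `min_var_freq`; calls at or above `min_freq_for_hom` are consensus
#' (homozygous-style) rather than heteroplasmic. The p-value is a one-sided
#' binomial tail of the supporting reads against the sequencing error rate
#' `error_rate`; calls with `p >= p_threshold` are retained but flagged
#' not-called and excluded from summaries.
#'
#' @param min_var_reads Minimum supporting reads (default 4).
#' @param min_freq_for_hom Consensus frequency threshold (default 0.5).
#' @param min_var_freq Minimum variant frequency (default 0).
#' @param error_rate Per-base sequencing error rate for the binomial null
#'   (default 0.01).
#' @param p_threshold Significance threshold for the call flag
#'   (default 0.05).
#' @return list of class `het_caller_params`.
#' @export
het_caller_params <- function(min_var_reads = 4, min_freq_for_hom = 0.5,
                              min_var_freq = 0, error_rate = 0.01,
                              p_threshold = 0.05) {
  stopifnot(min_var_reads >= 0, min_freq_for_hom > 0, min_freq_for_hom <= 1,
            min_var_freq >= 0, min_var_freq < 1,
            error_rate > 0, error_rate < 1, p_threshold > 0, p_threshold <= 1)
  structure(list(min_var_reads = as.integer(min_var_reads),
                 min_freq_for_hom = min_freq_for_hom,
                 min_var_freq = min_var_freq, error_rate = error_rate,
                 p_threshold = p_threshold),
            class = "het_caller_params")
}

#' Parse one pileup base string into call counts
#' @noRd
parse_pileup_bases <- function(s, ref, line_no = NA) {
  s <- gsub("\\^.", "", s)       # read-start marker carries a quality char
  s <- gsub("\\$", "", s, fixed = FALSE)
  counts <- new.env(parent = emptyenv())
  bump <- function(key) {
    assign(key, (if (exists(key, counts)) get(key, counts) else 0L) + 1L, counts)
  }
  i <- 1L
  n <- nchar(s)
  while (i <= n) {
    ch <- substr(s, i, i)
    if (ch == "." || ch == ",") {
      # indel events are attached to the preceding read base
      nxt <- if (i < n) substr(s, i + 1L, i + 1L) else ""
      if (nxt == "+" || nxt == "-") {
        m <- regmatches(substr(s, i + 1L, n),
                        regexpr("^[+-][0-9]+", substr(s, i + 1L, n)))
        if (length(m) == 0) {
          mito_stop(sprintf("malformed indel at line %s", line_no),
                    "mito_parse_error")
        }
        len <- as.integer(substr(m, 2L, nchar(m)))
        seq_start <- i + 1L + nchar(m)
        seq_end <- seq_start + len - 1L
        if (seq_end > n) {
          mito_stop(sprintf("indel length overruns line %s", line_no),
                    "mito_parse_error")
        }
        bump(paste0(substr(m, 1L, 1L), toupper(substr(s, seq_start, seq_end))))
        bump("ref")
        i <- seq_end + 1L
      } else {
        bump("ref")
        i <- i + 1L
      }
    } else if (ch %in% c("A", "C", "G", "T", "N", "a", "c", "g", "t", "n")) {
      bump(toupper(ch))
      i <- i + 1L
    } else if (ch == "*") {
      bump("*")                  # placeholder for a base deleted upstream
      i <- i + 1L
    } else if (ch == ">" || ch == "<") {
      i <- i + 1L                # reference skip
    } else if (ch == "+" || ch == "-") {
      # indel not anchored to a visible read base (tolerated dialect)
      m <- regmatches(substr(s, i, n), regexpr("^[+-][0-9]+", substr(s, i, n)))
      if (length(m) == 0) {
        mito_stop(sprintf("malformed indel at line %s", line_no),
                  "mito_parse_error")
      }
      len <- as.integer(substr(m, 2L, nchar(m)))
      seq_start <- i + nchar(m)
      seq_end <- seq_start + len - 1L
      if (seq_end > n) {
        mito_stop(sprintf("indel length overruns line %s", line_no),
                  "mito_parse_error")
      }
      bump(paste0(substr(m, 1L, 1L), toupper(substr(s, seq_start, seq_end))))
      i <- seq_end + 1L
    } else {
      mito_stop(sprintf("unexpected pileup character '%s' at line %s", ch, line_no),
                "mito_parse_error")
    }
  }
  out <- mget(ls(counts), counts)
  vapply(out, identity, 0L)
}

#' Read a samtools-style text pileup
#'
#' Parses the 6-column text pileup dialect: `chrom pos ref depth bases
#' quals`. Match symbols `.`/`,` count toward the reference; `ACGTacgt` are
#' substitution calls; `+n<seq>`/`-n<seq>` are insertion/deletion events
#' anchored at the position; `^q`/`$` read start/end markers are stripped;
#' `*` marks a base deleted by an upstream deletion and is not a call.
#'
#' @param path Pileup file.
#' @return data.frame of class `pileup`: `chrom`, `pos`, `ref`, `coverage`
#'   and list-column `calls` (named counts; key `ref` for reference calls,
#'   `+SEQ`/`-SEQ` for indels).
#' @export
read_pileup <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) mito_stop("empty pileup", "mito_format_error")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 5)
  if (length(bad)) {
    mito_stop(sprintf("pileup line %d has fewer than 5 columns", bad[1]),
              "mito_parse_error")
  }
  chrom <- vapply(parts, `[[`, "", 1L)
  pos <- as.integer(vapply(parts, `[[`, "", 2L))
  ref <- toupper(vapply(parts, `[[`, "", 3L))
  depth <- as.integer(vapply(parts, `[[`, "", 4L))
  calls <- lapply(seq_along(parts), function(i) {
    s <- parts[[i]][5L]
    # fast paths for the overwhelmingly common simple lines
    if (grepl("^[.,]*$", s)) return(c(ref = nchar(s)))
    if (!grepl("[+^$*><,.-]", s)) {
      tab <- table(toupper(strsplit(s, "", fixed = TRUE)[[1]]))
      return(stats::setNames(as.integer(tab), names(tab)))
    }
    if (!grepl("[+^$*><-]", s)) {
      chars <- toupper(strsplit(s, "", fixed = TRUE)[[1]])
      chars[chars %in% c(".", ",")] <- "ref"
      tab <- table(chars)
      return(stats::setNames(as.integer(tab), names(tab)))
    }
    parse_pileup_bases(s, ref[i], line_no = i)
  })
  out <- data.frame(chrom = chrom, pos = pos, ref = ref, coverage = depth,
                    stringsAsFactors = FALSE)
  out$calls <- calls
  class(out) <- c("pileup", "data.frame")
  out
}

#' Call heteroplasmic variants from a pileup
#'
#' Emits every non-reference call satisfying the thresholds in `params`
#' (see [het_caller_params()]). Indels are reported as anchored ref/alt
#' strings: an insertion of `T` after reference base `C` is `C -> CT`; a
#' deletion of `A` after `C` is `CA -> C`. Substitutions are typed as
#' transitions or transversions. Each variant carries a one-sided binomial
#' p-value of its supporting reads against the error rate; variants failing
#' `p_threshold` are kept in the output but `called = FALSE` so summaries
#' can exclude them. Sites with zero coverage are skipped.
#'
#' @param pileup A [read_pileup()] table.
#' @param params [het_caller_params()].
#' @param genome Optional reference sequence string for homopolymer-context
#'   annotation of indels (length of the base run surrounding the event).
#' @return data.frame of class `het_calls`: `position`, `ref_allele`,
#'   `alt_allele`, `var_type`, `supporting_reads`, `coverage`, `frequency`,
#'   `p_value`, `zygosity`, `called`, `homopolymer_run`.
#' @export
call_variants <- function(pileup, params = het_caller_params(),
                          genome = NULL) {
  stopifnot(inherits(pileup, "pileup"), inherits(params, "het_caller_params"))
  rows <- list()
  for (i in seq_len(nrow(pileup))) {
    cov <- pileup$coverage[i]
    if (cov <= 0) next
    ref <- pileup$ref[i]
    calls <- pileup$calls[[i]]
    for (key in names(calls)) {
      if (key %in% c("ref", "N", "*") || key == ref) next
      support <- calls[[key]]
      freq <- support / cov
      if (support < params$min_var_reads || freq < params$min_var_freq) next
      first <- substr(key, 1L, 1L)
      if (first == "+") {
        seq <- substr(key, 2L, nchar(key))
        ref_a <- ref; alt_a <- paste0(ref, seq); type <- "insertion"
      } else if (first == "-") {
        seq <- substr(key, 2L, nchar(key))
        ref_a <- paste0(ref, seq); alt_a <- ref; type <- "deletion"
      } else {
        seq <- NA_character_
        ref_a <- ref; alt_a <- key
        type <- if (pair_is_transition(ref, key)) "substitution-transition"
                else "substitution-transversion"
      }
      p <- stats::pbinom(support - 1L, cov, params$error_rate,
                         lower.tail = FALSE)
      hrun <- NA_integer_
      if (!is.null(genome) && first %in% c("+", "-")) {
        hrun <- homopolymer_run(genome, pileup$pos[i], substr(seq, 1L, 1L))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        position = pileup$pos[i], ref_allele = ref_a, alt_allele = alt_a,
        var_type = type, indel_seq = seq, supporting_reads = support,
        coverage = cov, frequency = freq, p_value = p,
        zygosity = if (freq >= params$min_freq_for_hom) "consensus" else "heteroplasmic",
        called = p < params$p_threshold, homopolymer_run = hrun,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(position = integer(0), ref_allele = character(0),
               alt_allele = character(0), var_type = character(0),
               indel_seq = character(0), supporting_reads = integer(0),
               coverage = integer(0), frequency = numeric(0),
               p_value = numeric(0), zygosity = character(0),
               called = logical(0), homopolymer_run = integer(0))
  class(out) <- c("het_calls", "data.frame")
  out
}

#' Length of the homopolymer run of `base` around position `pos`
#' @noRd
homopolymer_run <- function(genome, pos, base) {
  chars <- strsplit(genome, "", fixed = TRUE)[[1]]
  L <- length(chars)
  run <- 0L
  j <- pos
  while (j <= L && chars[j] == base) { run <- run + 1L; j <- j + 1L }
  j <- pos - 1L
  while (j >= 1 && chars[j] == base) { run <- run + 1L; j <- j - 1L }
  run
}

#' Per-gene heteroplasmy summary with frequency bins
#'
#' Assigns called variants to genes by position, counts them per 10%
#' frequency interval, and computes each gene's intra-individual
#' variability index. Variants outside every annotation (intergenic) and
#' genes without variants are absent from the table, which is sorted by VI
#' descending.
#'
#' @param variants A `het_calls` table ([call_variants()]); only rows with
#'   `called == TRUE` contribute.
#' @param annotations A [gene_annotation()] table.
#' @param L Genome length in bp.
#' @param bin_width Bin width in percent (default 10).
#' @param max_pct Upper bound of the last bin; default covers the largest
#'   observed frequency (at least 60).
#' @return data.frame of class `het_gene_table`: `gene`, `group`, one column
#'   per bin, `total_variants`, `length_bp`, `vi`, `pattern` (see
#'   [frequency_gap_pattern()]).
#' @export
summarize_by_gene <- function(variants, annotations, L, bin_width = 10,
                              max_pct = NULL) {
  stopifnot(inherits(variants, "het_calls"))
  v <- variants[variants$called, , drop = FALSE]
  pct <- 100 * v$frequency
  if (is.null(max_pct)) {
    max_pct <- max(60, bin_width * ceiling(max(pct, 0) / bin_width))
  }
  labs <- bin_labels(bin_width, max_pct)
  df <- as.data.frame(annotations)
  lens <- gene_length(annotations, L)
  hit <- genes_at(v$position, annotations)
  genes <- unique(df$gene)
  counts <- matrix(0L, nrow = length(genes), ncol = length(labs),
                   dimnames = list(genes, labs))
  for (i in seq_len(nrow(v))) {
    gs <- hit[[i]]
    if (length(gs) == 0) next   # intergenic variants excluded
    b <- min(max(ceiling(pct[i] / bin_width - 1e-12), 1L), length(labs))
    for (g in gs) counts[g, b] <- counts[g, b] + 1L
  }
  out <- data.frame(gene = genes, group = df$group[match(genes, df$gene)],
                    stringsAsFactors = FALSE)
  for (j in seq_along(labs)) out[[labs[j]]] <- counts[, j]
  out$total_variants <- as.integer(rowSums(counts))
  out$length_bp <- unname(lens[genes])
  out$vi <- 100 * out$total_variants / out$length_bp
  out <- out[out$total_variants > 0, , drop = FALSE]
  out$pattern <- apply(out[, labs, drop = FALSE], 1, frequency_gap_pattern)
  out <- out[order(-out$vi), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("het_gene_table", "data.frame")
  out
}

#' Classify a gene's frequency-bin occupancy pattern
#'
#' Distinguishes how a gene's variants populate the frequency intervals:
#' `progressive` if the occupied bins form an unbroken prefix starting at
#' the lowest interval (variants fill a frequency interval before occupying
#' the next — the pattern typical of protein-coding genes);
#' `lone_high` if exactly one bin is occupied and it is not the lowest
#' (a single higher-frequency variant); `gapped` otherwise (occupied bins
#' with holes, e.g. a gene with low-frequency variants plus an isolated
#' high-frequency one).
#'
#' @param bin_counts Numeric vector of per-bin variant counts, lowest bin
#'   first.
#' @return One of `"progressive"`, `"gapped"`, `"lone_high"`.
#' @export
frequency_gap_pattern <- function(bin_counts) {
  occ <- which(bin_counts > 0)
  if (length(occ) == 0) mito_stop("no occupied bins", "mito_validation_error")
  if (length(occ) == 1 && occ != 1) return("lone_high")
  if (identical(occ, seq_len(length(occ)))) return("progressive")
  "gapped"
}

#' Indel composition report
#'
#' Tabulates called indels by type (insertion/deletion), inserted/deleted
#' sequence and length; reports the share of deletions involving each base
#' and the largest indel.
#'
#' @param variants A `het_calls` table; only `called` rows contribute.
#' @return list with `by_event` (type x sequence counts), `n_insertions`,
#'   `n_deletions`, `n_substitutions`, `single_base` (type x base counts
#'   for 1-bp indels), `deletion_base_pct` (percentage of deletions whose
#'   sequence contains each base), `max_indel_length`.
#' @export
indel_composition <- function(variants) {
  stopifnot(inherits(variants, "het_calls"))
  v <- variants[variants$called, , drop = FALSE]
  ins <- v[v$var_type == "insertion", , drop = FALSE]
  del <- v[v$var_type == "deletion", , drop = FALSE]
  subs <- v[startsWith(v$var_type, "substitution"), , drop = FALSE]
  ev <- rbind(
    if (nrow(ins)) data.frame(type = "insertion", seq = ins$indel_seq),
    if (nrow(del)) data.frame(type = "deletion", seq = del$indel_seq)
  )
  by_event <- if (!is.null(ev)) {
    agg <- stats::aggregate(list(n = rep(1L, nrow(ev))), ev, sum)
    agg$length <- nchar(agg$seq)
    agg[order(agg$type, -agg$n), , drop = FALSE]
  } else data.frame(type = character(0), seq = character(0), n = integer(0),
                    length = integer(0))
  single <- by_event[by_event$length == 1, , drop = FALSE]
  sb <- matrix(0L, nrow = 2, ncol = 4,
               dimnames = list(c("insertion", "deletion"), DNA_BASES))
  for (i in seq_len(nrow(single))) {
    sb[single$type[i], single$seq[i]] <- single$n[i]
  }
  del_pct <- vapply(DNA_BASES, function(b) {
    if (nrow(del) == 0) return(0)
    100 * sum(grepl(b, del$indel_seq, fixed = TRUE)) / nrow(del)
  }, 0)
  list(by_event = by_event,
       n_insertions = nrow(ins), n_deletions = nrow(del),
       n_substitutions = nrow(subs),
       single_base = sb, deletion_base_pct = del_pct,
       max_indel_length = if (nrow(by_event)) max(by_event$length) else 0L)
}

#' Invariable regions between variant positions
#'
#' Computes the maximal gaps between consecutive variant positions on a
#' (circular) genome; long gaps reveal invariable regions, candidate loci
#' under strong selective constraint.
#'
#' @param positions Variant positions (>= 1 required).
#' @param L Genome length.
#' @param circular Include the wrap-around gap (default `TRUE`).
#' @param min_gap Report only gaps of at least this length (default 0).
#' @return list with `max_gap` and `regions` (data.frame `from`, `to`,
#'   `gap` where `gap` is the distance from one variant to the next).
#' @export
invariable_regions <- function(positions, L, circular = TRUE, min_gap = 0) {
  positions <- sort(unique(as.integer(positions)))
  if (length(positions) == 0) mito_stop(">= 1 variant required", "mito_validation_error")
  if (length(positions) == 1) {
    gap <- if (circular) L else NA_integer_
    regions <- data.frame(from = positions, to = positions, gap = gap)
    return(list(max_gap = gap, regions = regions[regions$gap >= min_gap, ]))
  }
  from <- positions
  to <- c(positions[-1], positions[1])
  gap <- c(diff(positions), L - positions[length(positions)] + positions[1])
  if (!circular) { from <- from[-length(from)]; to <- to[-length(to)]; gap <- gap[-length(gap)] }
  regions <- data.frame(from = from, to = to, gap = gap)
  list(max_gap = max(gap), regions = regions[regions$gap >= min_gap, , drop = FALSE])
}

#' Write heteroplasmic calls as a minimal VCF
#'
#' @param variants `het_calls` table.
#' @param path Output path.
#' @param chrom Contig name (default `"chrM"`).
#' @export
write_het_vcf <- function(variants, path, chrom = "chrM") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##source=mitodiv %s",
                       as.character(utils::packageVersion("mitodiv"))),
               '##INFO=<ID=DP,Number=1,Type=Integer,Description="Coverage">',
               '##INFO=<ID=AD,Number=1,Type=Integer,Description="Supporting reads">',
               '##INFO=<ID=AF,Number=1,Type=Float,Description="Variant frequency">',
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(variants)) {
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\tDP=%d;AD=%d;AF=%.6f",
                       chrom, variants$position, variants$ref_allele,
                       variants$alt_allele,
                       ifelse(variants$called, "PASS", "not_called"),
                       variants$coverage, variants$supporting_reads,
                       variants$frequency), con)
  }
  invisible(path)
}

#' Read a VCF of variants into a het_calls-style table
#'
#' Minimal VCF (v4.x) reader for variant tables with `DP`/`AD` style depths
#' in INFO; intended for re-loading calls written by [write_het_vcf()] or
#' simple caller output.
#'
#' @param path VCF file.
#' @return data.frame of class `het_calls`.
#' @export
read_het_vcf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0) {
    out <- data.frame(position = integer(0), ref_allele = character(0),
                      alt_allele = character(0), var_type = character(0),
                      indel_seq = character(0), supporting_reads = integer(0),
                      coverage = integer(0), frequency = numeric(0),
                      p_value = numeric(0), zygosity = character(0),
                      called = logical(0), homopolymer_run = integer(0))
    class(out) <- c("het_calls", "data.frame")
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  get_info <- function(info, key) {
    m <- regmatches(info, regexpr(sprintf("%s=[^;]+", key), info))
    if (length(m) == 0) return(NA_character_)
    sub(sprintf("%s=", key), "", m)
  }
  pos <- as.integer(vapply(parts, `[[`, "", 2L))
  ref <- vapply(parts, `[[`, "", 4L)
  alt <- vapply(parts, `[[`, "", 5L)
  filt <- vapply(parts, `[[`, "", 7L)
  info <- vapply(parts, `[[`, "", 8L)
  dp <- as.integer(vapply(info, get_info, "", "DP"))
  ad <- as.integer(vapply(info, get_info, "", "AD"))
  af <- as.numeric(vapply(info, get_info, "", "AF"))
  type <- ifelse(nchar(ref) > nchar(alt), "deletion",
          ifelse(nchar(alt) > nchar(ref), "insertion",
          ifelse(pair_is_transition(ref, alt), "substitution-transition",
                 "substitution-transversion")))
  iseq <- ifelse(type == "deletion", substr(ref, 2L, nchar(ref)),
          ifelse(type == "insertion", substr(alt, 2L, nchar(alt)),
                 NA_character_))
  freq <- ifelse(is.na(af), ad / dp, af)
  out <- data.frame(position = pos, ref_allele = ref, alt_allele = alt,
                    var_type = type, indel_seq = iseq,
                    supporting_reads = ad, coverage = dp, frequency = freq,
                    p_value = NA_real_, zygosity = ifelse(freq >= 0.5,
                                                          "consensus",
                                                          "heteroplasmic"),
                    called = filt %in% c("PASS", "."),
                    homopolymer_run = NA_integer_, stringsAsFactors = FALSE)
  class(out) <- c("het_calls", "data.frame")
  out
}
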