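#' Circular genome object
#'
#' A lightweight container for a (usually circular) DNA sequence such as a
#' mitochondrial genome. The sequence is stored uppercase over the alphabet
#' `{A,C,G,T,N}`.
#'
#' @param id Sequence identifier.
#' @param sequence DNA string; lowercase input is uppercased.
#' @param circular Logical; `TRUE` for circular topology (the default, as for
#'   mitochondrial genomes).
#' @return An object of class `circular_genome` with fields `id`, `sequence`,
#'   `length` and `circular`.
#' @examples
#' g <- circular_genome("mt", "ACGTACGT")
#' g$length
#' @export
circular_genome <- function(id, sequence, circular = TRUE) {
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0) mito_stop("empty sequence", "mito_format_error")
  check_alphabet(sequence, c(DNA_BASES, "N"), sprintf("genome '%s'", id))
  structure(
    list(id = as.character(id), sequence = sequence,
         length = nchar(sequence), circular = isTRUE(circular)),
    class = "circular_genome"
  )
}

#' @export
print.circular_genome <- function(x, ...) {
  cat(sprintf("<circular_genome> %s: %d bp (%s)\n", x$id, x$length,
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' Read genomes from a FASTA file
#'
#' @param path FASTA file with one or more ungapped records.
#' @param circular Logical topology flag applied to every record.
#' @return A list of [circular_genome()] objects, named by record id.
#' @export
read_genomes <- function(path, circular = TRUE) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) mito_stop("no FASTA records found", "mito_format_error")
  ids <- sub("\\s.*$", "", names(set))
  out <- lapply(seq_along(set), function(i) {
    circular_genome(ids[i], as.character(set[[i]]), circular = circular)
  })
  names(out) <- ids
  out
}

#' Write genomes to a FASTA file
#'
#' @param genomes A `circular_genome` or list of them.
#' @param path Output path.
#' @export
write_genomes <- function(genomes, path) {
  if (inherits(genomes, "circular_genome")) genomes <- list(genomes)
  seqs <- Biostrings::BStringSet(vapply(genomes, `[[`, "", "sequence"))
  names(seqs) <- vapply(genomes, `[[`, "", "id")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Rotate a circular genome to a common start anchor
#'
#' Circular genomes deposited in databases start at arbitrary points; before
#' alignment they must be rotated to a common origin. The returned sequence
#' starts at the first occurrence of `anchor` (searched on the forward strand
#' first, then on the reverse complement, in which case the genome is
#' reverse-complemented before rotation).
#'
#' @param genome A [circular_genome()].
#' @param anchor DNA motif expected to occur in the genome; the default
#'   `nchar` recommendation is ~20-30 bp so the anchor is effectively unique.
#' @return The rotated `circular_genome`; the rotation offset (0-based) is
#'   attached as attribute `rotation` and reported via `message()`.
#' @examples
#' rotate_to_anchor(circular_genome("g", "CCAAT"), "AAT")$sequence  # "AATCC"
#' @export
rotate_to_anchor <- function(genome, anchor) {
  stopifnot(inherits(genome, "circular_genome"))
  anchor <- toupper(anchor)
  if (!genome$circular) mito_stop("genome is not circular", "mito_validation_error")
  L <- genome$length
  if (nchar(anchor) > L) mito_stop("anchor longer than genome", "mito_anchor_error")
  # search in the doubled sequence so anchors spanning the origin are found
  find_in <- function(s) {
    doubled <- paste0(s, substr(s, 1, nchar(anchor) - 1))
    hits <- gregexpr(anchor, doubled, fixed = TRUE)[[1]]
    hits[hits > 0 & hits <= L]
  }
  seq <- genome$sequence
  hits <- find_in(seq)
  if (length(hits) == 0) {
    seq <- revcomp(seq)
    hits <- find_in(seq)
    if (length(hits) == 0) {
      mito_stop(sprintf("anchor '%s' not found in genome '%s' or its reverse complement",
                        anchor, genome$id), "mito_anchor_error")
    }
  }
  if (length(hits) > 1) {
    warning(sprintf("anchor occurs %d times in '%s'; using first occurrence",
                    length(hits), genome$id))
  }
  k <- hits[1] - 1L  # 0-based rotation offset
  rotated <- if (k == 0) seq else {
    paste0(substr(seq, k + 1L, L), substr(seq, 1L, k))
  }
  out <- circular_genome(genome$id, rotated, circular = TRUE)
  attr(out, "rotation") <- k
  message(sprintf("rotated '%s' by %d bp to anchor", genome$id, k))
  out
}

#' Spacing statistics of positions on a (circular) sequence
#'
#' Computes the mean and population standard deviation of the gaps between
#' consecutive sorted positions. On a circular sequence the wrap-around gap
#' from the last position back to the first is included, in which case the
#' mean gap equals `L/n` exactly.
#'
#' @param positions Distinct 1-based integer positions.
#' @param L Sequence length in bp.
#' @param circular Include the wrap-around gap (default `TRUE`).
#' @return A list with `mean_gap`, `sd_gap`, `n`, `gaps`.
#' @examples
#' circular_spacing_stats(c(1, 26, 51, 76), 100)  # mean 25, sd 0
#' @export
circular_spacing_stats <- function(positions, L, circular = TRUE) {
  positions <- as.integer(positions)
  if (anyDuplicated(positions)) {
    mito_stop("duplicate positions", "mito_validation_error")
  }
  if (length(positions) < 2) mito_stop("need >= 2 positions", "mito_validation_error")
  if (any(positions < 1 | positions > L)) {
    mito_stop("positions outside [1, L]", "mito_validation_error")
  }
  p <- sort(positions)
  gaps <- diff(p)
  if (circular) gaps <- c(gaps, L - p[length(p)] + p[1])
  m <- mean(gaps)
  s <- sqrt(mean((gaps - m)^2))  # population SD
  list(mean_gap = m, sd_gap = s, n = length(p), gaps = gaps)
}

#' Gene annotation table
#'
#' Builds or validates an annotation table for a circular genome. Genes are
#' rows with 1-based inclusive coordinates; a gene wrapping the origin is
#' written with `start > end`. A gene split into several intervals (for
#' example a duplicated tRNA) occupies several rows sharing the same name.
#'
#' @param gene Gene/region names.
#' @param group Gene group, one of `ND`, `COX`, `ATP`, `tRNA`, `rRNA`, `CR`.
#' @param start,end 1-based inclusive interval bounds.
#' @param strand `"+"` or `"-"`.
#' @return A `data.frame` of class `gene_annotation`.
#' @export
gene_annotation <- function(gene, group, start, end, strand = "+") {
  df <- data.frame(gene = as.character(gene), group = as.character(group),
                   start = as.integer(start), end = as.integer(end),
                   strand = strand, stringsAsFactors = FALSE)
  if (nrow(df) == 0) mito_stop("empty annotation", "mito_validation_error")
  if (any(df$start < 1 | df$end < 1)) {
    mito_stop("annotation coordinates must be >= 1", "mito_validation_error")
  }
  if (!all(df$strand %in% c("+", "-"))) {
    mito_stop("strand must be '+' or '-'", "mito_validation_error")
  }
  class(df) <- c("gene_annotation", "data.frame")
  df
}

#' Read gene annotations from TSV or GFF3
#'
#' The TSV dialect has five columns `gene, group, start, end, strand` with a
#' header row. GFF3 files (detected by extension or `##gff` preamble) are read
#' through \pkg{rtracklayer}; the gene name is taken from the `Name` (or `ID`)
#' attribute and the group from the `gene_group` attribute when present,
#' otherwise guessed from the name.
#'
#' @param path Annotation file.
#' @return A [gene_annotation()] table.
#' @export
read_annotations <- function(path) {
  is_gff <- grepl("\\.gff3?$", path, ignore.case = TRUE) ||
    startsWith(readLines(path, n = 1), "##gff")
  if (is_gff) {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      mito_stop("reading GFF3 requires the rtracklayer package",
                "mito_format_error")
    }
    gr <- rtracklayer::import(path)
    md <- S4Vectors::mcols(gr)
    nm <- if (!is.null(md$Name)) as.character(md$Name) else as.character(md$ID)
    grp <- if (!is.null(md$gene_group)) as.character(md$gene_group) else guess_gene_group(nm)
    return(gene_annotation(nm, grp, BiocGenerics::start(gr),
                           BiocGenerics::end(gr),
                           as.character(BiocGenerics::strand(gr))))
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("gene", "group", "start", "end", "strand")
  if (!all(need %in% names(df))) {
    mito_stop(sprintf("annotation TSV must have columns: %s",
                      paste(need, collapse = ", ")), "mito_format_error")
  }
  gene_annotation(df$gene, df$group, df$start, df$end, df$strand)
}

#' Write annotations as 5-column TSV
#' @param annotations A [gene_annotation()] table.
#' @param path Output path.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.table(as.data.frame(annotations)[, c("gene", "group", "start",
                                                    "end", "strand")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @noRd
guess_gene_group <- function(nm) {
  out <- rep("CR", length(nm))
  out[grepl("^ND", nm, ignore.case = TRUE)] <- "ND"
  out[grepl("^(COX|CYTB)", nm, ignore.case = TRUE)] <- "COX"
  out[grepl("^ATP", nm, ignore.case = TRUE)] <- "ATP"
  out[grepl("tRNA", nm, ignore.case = TRUE)] <- "tRNA"
  out[grepl("rRNA", nm, ignore.case = TRUE)] <- "rRNA"
  out
}

#' Length of one annotation interval on a circular genome
#' @noRd
interval_length <- function(start, end, L) {
  ifelse(start <= end, end - start + 1L, (L - start + 1L) + end)
}

#' Total gene length in bp
#'
#' Sums the interval lengths of all rows matching `gene`; intervals written
#' with `start > end` wrap the origin of the circular genome.
#'
#' @param annotations A [gene_annotation()] table.
#' @param L Genome length in bp (needed to resolve wrapping intervals).
#' @param gene Optional gene name(s); default all genes in the table.
#' @return Named integer vector of lengths.
#' @examples
#' a <- gene_annotation("CR", "CR", 15900, 50)
#' gene_length(a, L = 16000)  # 151
#' @export
gene_length <- function(annotations, L, gene = NULL) {
  stopifnot(inherits(annotations, "gene_annotation"))
  df <- as.data.frame(annotations)
  if (!is.null(gene)) df <- df[df$gene %in% gene, , drop = FALSE]
  if (any(df$start > L | df$end > L)) {
    mito_stop("annotation interval outside [1, L]", "mito_validation_error")
  }
  lens <- interval_length(df$start, df$end, L)
  out <- tapply(lens, factor(df$gene, levels = unique(df$gene)), sum)
  stats::setNames(as.integer(out), names(out))
}

#' Does a position fall inside an annotation interval (with wrap)?
#' @noRd
pos_in_interval <- function(pos, start, end) {
  ifelse(start <= end, pos >= start & pos <= end, pos >= start | pos <= end)
}

#' Genes overlapping each position
#'
#' @param positions Integer genome positions.
#' @param annotations A [gene_annotation()] table.
#' @return A list, per position, of the gene names whose intervals contain it
#'   (possibly several for overlapping genes; empty for intergenic positions).
#' @export
genes_at <- function(positions, annotations) {
  df <- as.data.frame(annotations)
  lapply(positions, function(p) {
    unique(df$gene[pos_in_interval(p, df$start, df$end)])
  })
}
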