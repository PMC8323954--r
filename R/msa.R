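#' Multiple sequence alignment container
#'
#' Stores a gapped alignment as equal-length uppercase strings over
#' `{A,C,G,T,N,-}` together with an optional coordinate-reference record.
#' All inter-individual analyses operate on this container; alignment
#' computation itself (e.g. MAFFT) is upstream of the package.
#'
#' @param ids Record identifiers (unique).
#' @param seqs Gapped sequences, same order as `ids`.
#' @param reference_id Optional id of the record whose ungapped coordinates
#'   anchor user-facing positions (see [coordinate_map()]).
#' @return An object of class `msa` with fields `ids`, `seqs`, `n_seqs`,
#'   `n_cols`, `reference_id`.
#' @export
msa <- function(ids, seqs, reference_id = NULL) {
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  if (length(ids) != length(seqs)) {
    mito_stop("ids and seqs differ in length", "mito_validation_error")
  }
  if (length(seqs) < 2) {
    mito_stop("an alignment needs >= 2 records", "mito_format_error")
  }
  if (anyDuplicated(ids)) mito_stop("duplicate record ids", "mito_validation_error")
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1) {
    mito_stop(sprintf("ragged alignment: record lengths %s",
                      paste(unique(widths), collapse = ", ")),
              "mito_alignment_shape_error")
  }
  for (i in seq_along(seqs)) {
    check_alphabet(seqs[i], c(DNA_BASES, "N", GAP), sprintf("record '%s'", ids[i]))
  }
  if (!is.null(reference_id) && !reference_id %in% ids) {
    mito_stop(sprintf("reference_id '%s' is not a record id", reference_id),
              "mito_validation_error")
  }
  structure(
    list(ids = ids, seqs = seqs, n_seqs = length(ids),
         n_cols = widths[1], reference_id = reference_id),
    class = "msa"
  )
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa> %d sequences x %d columns%s\n", x$n_seqs, x$n_cols,
              if (!is.null(x$reference_id))
                sprintf(" (reference: %s)", x$reference_id) else ""))
  invisible(x)
}

#' @export
as.matrix.msa <- function(x, ...) {
  m <- do.call(rbind, strsplit(x$seqs, "", fixed = TRUE))
  rownames(m) <- x$ids
  m
}

#' Read a gapped FASTA alignment
#'
#' @param path FASTA file with >= 2 records of identical gapped length.
#' @param reference_id Optional coordinate-reference record id; defaults to
#'   the first record.
#' @return An [msa()] object.
#' @export
read_alignment <- function(path, reference_id = NULL) {
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) mito_stop(
                    sprintf("cannot read FASTA '%s': %s", path, conditionMessage(e)),
                    "mito_format_error"))
  if (length(set) == 0) mito_stop("empty FASTA file", "mito_format_error")
  ids <- sub("\\s.*$", "", names(set))
  if (is.null(reference_id)) reference_id <- ids[1]
  msa(ids, as.character(set), reference_id = reference_id)
}

#' Write an alignment to gapped FASTA
#'
#' Sequences are written unwrapped (one line per record) so that
#' read/write round-trips are byte-identical.
#'
#' @param x An [msa()] object.
#' @param path Output path.
#' @export
write_alignment <- function(x, path) {
  stopifnot(inherits(x, "msa"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", x$ids, "\n", x$seqs), con, sep = "\n")
  invisible(path)
}

#' Map alignment columns to reference positions
#'
#' User-facing coordinates are 1-based positions in the ungapped reference
#' record (optionally offset so they match genome coordinates, e.g. the
#' control region embedded in a mitogenome). Columns where the reference
#' carries a gap map to the preceding reference position (0 before the first
#' reference base).
#'
#' @param x An [msa()] with `reference_id` set (or `reference_id` supplied).
#' @param ref_start Reference position of the first reference base
#'   (default 1).
#' @param reference_id Override the alignment's reference record.
#' @return Integer vector of length `n_cols`: reference position per column.
#' @export
coordinate_map <- function(x, ref_start = 1L, reference_id = NULL) {
  stopifnot(inherits(x, "msa"))
  rid <- if (!is.null(reference_id)) reference_id else x$reference_id
  if (is.null(rid)) mito_stop("no reference_id set", "mito_validation_error")
  if (!rid %in% x$ids) {
    mito_stop(sprintf("reference_id '%s' not in alignment", rid),
              "mito_validation_error")
  }
  refseq <- strsplit(x$seqs[match(rid, x$ids)], "", fixed = TRUE)[[1]]
  ungapped <- cumsum(refseq != GAP)
  pos <- ifelse(ungapped == 0, 0L, ungapped + as.integer(ref_start) - 1L)
  as.integer(pos)
}

#' Extract a column range as a sub-alignment
#' @noRd
msa_slice <- function(x, from, to) {
  msa(x$ids, substr(x$seqs, from, to),
      reference_id = x$reference_id)
}
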