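#' @keywords internal
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")
PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")
GAP <- "-"

#' Stop with a classed condition
#' @noRd
mito_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "mito_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Validate a DNA string over a restricted alphabet
#' @noRd
check_alphabet <- function(x, allowed, what = "sequence") {
  chars <- unique(strsplit(x, "", fixed = TRUE)[[1]])
  bad <- setdiff(chars, allowed)
  if (length(bad) > 0) {
    mito_stop(
      sprintf("%s contains characters outside {%s}: %s",
              what, paste(allowed, collapse = ","), paste(bad, collapse = ",")),
      "mito_alphabet_error"
    )
  }
  invisible(TRUE)
}

#' Reverse complement of a DNA string (gaps and N preserved)
#' @noRd
revcomp <- function(x) {
  chartr("ACGTN-", "TGCAN-", paste(rev(strsplit(x, "", fixed = TRUE)[[1]]),
                                   collapse = ""))
}

#' Round half away from zero, matching how the tabulated values are printed
#' @noRd
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Write a TSV report with a provenance header
#'
#' All tabular outputs share this writer so that every report carries the
#' package version and the seed (when one governed the run).
#' @noRd
write_report <- function(df, path, seed = NULL, extra = NULL) {
  version <- as.character(utils::packageVersion("mitodiv"))
  hdr <- sprintf("# mitodiv %s", version)
  if (!is.null(seed)) hdr <- paste0(hdr, sprintf("; seed=%d", as.integer(seed)))
  if (!is.null(extra)) hdr <- paste0(hdr, "; ", extra)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  if (ncol(df) > 0) {
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a TSV report written by write_report()
#' @noRd
read_report <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}
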