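#' Normalize gene / segment names to a shared vocabulary
#'
#' Published variability tables spell the same region inconsistently
#' ("VS 3" vs "VS3", "COX1 gene" vs "COX1", "s-rRNA" casing). This
#' normalizer maps all spellings onto one canonical form so that
#' inter- and intra-individual tables can be joined by name.
#'
#' @param x Character vector of names.
#' @return Canonical names: segments as `VS3`/`CS6`/`HVS1`; rRNAs as
#'   `s-rRNA`/`l-rRNA`; tRNAs as `tRNA-Xxx`; everything else uppercased
#'   with `" gene"` suffixes and spaces removed.
#' @export
normalize_region_name <- function(x) {
  out <- trimws(x)
  out <- sub("\\s+gene$", "", out, ignore.case = TRUE)
  out <- gsub("\\s+", " ", out)
  vapply(out, function(nm) {
    if (grepl("^(VS|CS|HVS)\\s?[0-9]+$", nm, ignore.case = TRUE)) {
      return(toupper(gsub(" ", "", nm)))
    }
    if (grepl("^s[- ]?rRNA$", nm, ignore.case = TRUE)) return("s-rRNA")
    if (grepl("^l[- ]?rRNA$", nm, ignore.case = TRUE)) return("l-rRNA")
    if (grepl("^tRNA", nm, ignore.case = TRUE)) {
      aa <- sub("^tRNA[- ]?", "", nm, ignore.case = TRUE)
      aa <- paste0(toupper(substr(aa, 1, 1)), tolower(substr(aa, 2, nchar(aa))))
      return(paste0("tRNA-", aa))
    }
    toupper(gsub(" ", "", nm))
  }, "", USE.NAMES = FALSE)
}

#' Join inter- and intra-individual variability tables
#'
#' Produces one row per region of the analysis universe, categorizing each
#' as showing only inter-individual variation, only intra-individual
#' variation, both, or neither, and ranking regions by the sum of the two
#' variability indices.
#'
#' @param inter Named numeric vector: inter-individual VI (percent) per
#'   region with inter-individual variation.
#' @param intra Named numeric vector: intra-individual (heteroplasmy) VI.
#' @param universe Character vector of all analyzed region names.
#' @param normalize Normalize all names via [normalize_region_name()]
#'   (default `TRUE`).
#' @return data.frame of class `vi_comparison`: `name`, `vi_inter`,
#'   `vi_intra`, `category`, `vi_sum`, sorted by `vi_sum` descending.
#' @export
join_vi_tables <- function(inter, intra, universe, normalize = TRUE) {
  if (length(inter) == 0) inter <- stats::setNames(numeric(0), character(0))
  if (length(intra) == 0) intra <- stats::setNames(numeric(0), character(0))
  if (normalize) {
    names(inter) <- normalize_region_name(names(inter))
    names(intra) <- normalize_region_name(names(intra))
    universe <- normalize_region_name(universe)
  }
  if (anyDuplicated(universe)) {
    mito_stop("duplicate names in universe", "mito_validation_error")
  }
  extra <- setdiff(c(names(inter), names(intra)), universe)
  if (length(extra)) {
    mito_stop(sprintf("names outside the universe: %s",
                      paste(extra, collapse = ", ")), "mito_validation_error")
  }
  vi_inter <- unname(inter[match(universe, names(inter))])
  vi_intra <- unname(intra[match(universe, names(intra))])
  has_inter <- !is.na(vi_inter) & vi_inter > 0
  has_intra <- !is.na(vi_intra) & vi_intra > 0
  category <- ifelse(has_inter & has_intra, "both",
              ifelse(has_inter, "inter_only",
              ifelse(has_intra, "intra_only", "neither")))
  vi_sum <- ifelse(is.na(vi_inter), 0, vi_inter) +
    ifelse(is.na(vi_intra), 0, vi_intra)
  out <- data.frame(name = universe, vi_inter = vi_inter, vi_intra = vi_intra,
                    category = category, vi_sum = vi_sum,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$vi_sum), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("vi_comparison", "data.frame")
  out
}

#' @export
print.vi_comparison <- function(x, ...) {
  cat("<vi_comparison>\n")
  print.data.frame(x, row.names = FALSE, digits = 3)
  tab <- table(factor(x$category,
                      levels = c("inter_only", "intra_only", "both", "neither")))
  cat(sprintf("inter-only: %d; intra-only: %d; both: %d; neither: %d\n",
              tab["inter_only"], tab["intra_only"], tab["both"], tab["neither"]))
  invisible(x)
}

#' Polymorphic-count profile over variable segments
#'
#' Returns the ordered per-VS polymorphic-site counts together with the
#' detected local maxima; two well-separated peaks indicate a bimodal
#' profile, i.e. two distinct hypervariable regions.
#'
#' @param segments A `segment_table` of variable segments (5'->3' order), or
#'   a numeric count vector.
#' @return list with `profile` (named counts), `peaks` (indices of local
#'   maxima).
#' @export
vs_profile <- function(segments) {
  if (inherits(segments, "segment_table")) {
    counts <- stats::setNames(segments$n_polymorphic, segments$label)
  } else {
    counts <- segments
    if (is.null(names(counts))) {
      names(counts) <- sprintf("VS%d", seq_along(counts))
    }
  }
  peaks <- local_maxima(as.numeric(counts))
  if (length(peaks) == 0) warning("flat profile: no strict peak")
  list(profile = counts, peaks = peaks)
}

#' Plot the variable-segment polymorphism profile
#'
#' Barplot of per-VS polymorphic counts with peak segments highlighted.
#'
#' @param segments As in [vs_profile()].
#' @param ... Passed to [graphics::barplot()].
#' @export
plot_vs_profile <- function(segments, ...) {
  pr <- vs_profile(segments)
  cols <- rep("grey70", length(pr$profile))
  cols[pr$peaks] <- "steelblue"
  graphics::barplot(pr$profile, col = cols,
                    ylab = "Polymorphic sites", xlab = "Variable segment", ...)
  invisible(pr)
}
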