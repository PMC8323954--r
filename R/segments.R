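#' Conservation-scan parameters
#'
#' @param min_window Minimum length (alignment columns) of a conserved run
#'   (default 20).
#' @param threshold Conservation threshold C in percent (default 100: every
#'   sequence must carry the same A/C/G/T base; gaps and N count as
#'   mismatches).
#' @param alpha Significance level for the window p-value (default 0.05).
#' @param bonferroni Multiply each run's p-value by the number of window
#'   placements (off by default).
#' @return list of class `conservation_params`.
#' @export
conservation_params <- function(min_window = 20, threshold = 100,
                                alpha = 0.05, bonferroni = FALSE) {
  stopifnot(min_window >= 1, threshold > 0, threshold <= 100,
            alpha > 0, alpha < 1)
  structure(list(min_window = as.integer(min_window), threshold = threshold,
                 alpha = alpha, bonferroni = isTRUE(bonferroni)),
            class = "conservation_params")
}

#' Per-column conservation of an alignment
#'
#' Conservation of a column is the percentage of sequences carrying the
#' modal A/C/G/T base; gaps and N reduce it. At threshold 100 a column is
#' conserved only if all sequences carry the same unambiguous base.
#'
#' @param x An [msa()].
#' @return Numeric vector (percent) of length `n_cols`.
#' @export
column_conservation <- function(x) {
  m <- as.matrix(x)
  apply(m, 2, function(col) {
    counts <- vapply(DNA_BASES, function(a) sum(col == a), 0L)
    100 * max(counts) / length(col)
  })
}

#' Exact p-value for a variant-free window
#'
#' Probability that a fixed window of `w` columns contains none of `S`
#' polymorphic columns placed uniformly without replacement among `L`
#' columns: `choose(L - w, S) / choose(L, S)`. This hypergeometric null is
#' exact, monotonically decreasing in both `w` and `S`, and verifiable by
#' enumeration. It is `0` when `S > L - w` (no room for the variants) and
#' `1` when `S = 0`.
#'
#' @param w Window (run) length in columns.
#' @param S Number of polymorphic columns in the whole alignment.
#' @param L Total alignment columns.
#' @return p-value in `[0, 1]`; vectorized over `w`.
#' @examples
#' conserved_run_pvalue(2, 1, 4)  # 0.5
#' @export
conserved_run_pvalue <- function(w, S, L) {
  stopifnot(S >= 0, S <= L, all(w >= 1), all(w <= L))
  vapply(w, function(wi) {
    if (S == 0) return(1)
    if (S > L - wi) return(0)
    exp(lchoose(L - wi, S) - lchoose(L, S))
  }, 0)
}

#' @noRd
new_segment_table <- function(df) {
  cols <- c("label", "kind", "start_col", "end_col", "length", "ref_start",
            "ref_end", "gc_content", "n_conserved", "n_polymorphic", "vi",
            "p_value")
  for (cc in setdiff(cols, names(df))) df[[cc]] <- rep(NA, nrow(df))
  df <- df[, cols, drop = FALSE]
  class(df) <- c("segment_table", "data.frame")
  df
}

#' Detect conserved segments in an alignment
#'
#' Finds maximal runs of columns whose conservation is at least
#' `params$threshold` and whose length is at least `params$min_window`,
#' assigns each run the exact window p-value of [conserved_run_pvalue()]
#' (with `S` = number of polymorphic columns in the alignment), and
#' discards runs with `p >= alpha`. Segments are numbered CS1, CS2, ... in
#' 5'->3' order.
#'
#' @param x An [msa()].
#' @param params A [conservation_params()] object.
#' @param sites Optional precomputed `site_table` (to avoid rescanning).
#' @return A `segment_table` of conserved segments with alignment-column
#'   coordinates and p-values.
#' @export
find_conserved_segments <- function(x, params = conservation_params(),
                                    sites = NULL) {
  stopifnot(inherits(x, "msa"), inherits(params, "conservation_params"))
  cons <- column_conservation(x) >= params$threshold - 1e-9
  if (is.null(sites)) sites <- scan_sites(x)
  S <- nrow(sites)
  L <- x$n_cols
  r <- rle(cons)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= params$min_window
  if (!any(keep)) {
    return(new_segment_table(data.frame(label = character(0), kind = character(0),
                                        start_col = integer(0), end_col = integer(0),
                                        length = integer(0))))
  }
  st <- starts[keep]; en <- ends[keep]; w <- en - st + 1L
  p <- conserved_run_pvalue(w, S, L)
  if (params$bonferroni) p <- pmin(1, p * (L - w + 1))
  # with no polymorphic columns anywhere the window null is vacuous (p = 1);
  # a fully conserved alignment still reports its single segment
  ok <- if (S == 0) rep(TRUE, length(p)) else p < params$alpha
  st <- st[ok]; en <- en[ok]; w <- w[ok]; p <- p[ok]
  if (length(st) == 0) {
    return(new_segment_table(data.frame(label = character(0), kind = character(0),
                                        start_col = integer(0), end_col = integer(0),
                                        length = integer(0))))
  }
  df <- data.frame(label = sprintf("CS%d", seq_along(st)), kind = "conserved",
                   start_col = st, end_col = en, length = w,
                   stringsAsFactors = FALSE)
  df$p_value <- p
  new_segment_table(df)
}

#' Derive variable segments as the complement of conserved segments
#'
#' Everything in the analyzed span that is not part of a conserved segment
#' is a variable segment; leading and trailing non-conserved stretches are
#' included. Conserved and variable segments tile the span without overlap.
#'
#' @param cs A `segment_table` of conserved segments (sorted,
#'   non-overlapping).
#' @param span Integer vector `c(first_col, last_col)` of the analyzed
#'   region (e.g. `c(1, n_cols)`).
#' @return A `segment_table` of variable segments numbered VS1, ... in
#'   5'->3' order.
#' @export
derive_variable_segments <- function(cs, span) {
  stopifnot(length(span) == 2, span[1] <= span[2])
  cs <- cs[order(cs$start_col), , drop = FALSE]
  if (nrow(cs) > 1 && any(cs$start_col[-1] <= cs$end_col[-nrow(cs)])) {
    mito_stop("conserved segments overlap", "mito_validation_error")
  }
  if (nrow(cs) > 0 && (cs$start_col[1] < span[1] || cs$end_col[nrow(cs)] > span[2])) {
    mito_stop("conserved segments outside span", "mito_validation_error")
  }
  bounds_lo <- c(span[1], cs$end_col + 1L)
  bounds_hi <- c(cs$start_col - 1L, span[2])
  keep <- bounds_lo <= bounds_hi
  st <- bounds_lo[keep]; en <- bounds_hi[keep]
  df <- data.frame(label = if (length(st)) sprintf("VS%d", seq_along(st)) else character(0),
                   kind = rep("variable", length(st)),
                   start_col = st, end_col = en, length = en - st + 1L,
                   stringsAsFactors = FALSE)
  new_segment_table(df)
}

#' Fill per-segment statistics
#'
#' For each segment computes: length (columns), GC content (percentage of
#' G+C among non-gap, non-N characters of columns that are not
#' indel-containing polymorphic sites, pooled across sequences), conserved-
#' and polymorphic-column counts, the variability index, and reference
#' coordinates via [coordinate_map()] when the alignment has a reference
#' record.
#'
#' @param segments A `segment_table`.
#' @param x The [msa()] the segments were derived from.
#' @param sites A classified `site_table` for `x` (from
#'   [polymorphic_sites()]).
#' @param ref_start Reference position of the first reference base (for
#'   reporting segment coordinates).
#' @return The `segment_table` with statistics filled in.
#' @export
segment_stats <- function(segments, x, sites, ref_start = 1L) {
  stopifnot(inherits(segments, "segment_table"), inherits(x, "msa"))
  if (nrow(segments) == 0) return(segments)
  m <- as.matrix(x)
  cons <- column_conservation(x) >= 100 - 1e-9
  poly_cols <- sites$msa_column
  indel_cols <- if (!is.null(sites$indel)) sites$msa_column[sites$indel] else integer(0)
  cm <- if (!is.null(x$reference_id)) coordinate_map(x, ref_start = ref_start) else NULL
  for (i in seq_len(nrow(segments))) {
    colr <- segments$start_col[i]:segments$end_col[i]
    gc_cols <- setdiff(colr, indel_cols)
    chars <- m[, gc_cols, drop = FALSE]
    chars <- chars[chars %in% DNA_BASES]
    segments$gc_content[i] <- if (length(chars)) 100 * mean(chars %in% c("G", "C")) else NA_real_
    segments$n_conserved[i] <- sum(cons[colr])
    np <- sum(poly_cols %in% colr)
    segments$n_polymorphic[i] <- np
    segments$vi[i] <- 100 * np / segments$length[i]
    if (!is.null(cm)) {
      segments$ref_start[i] <- max(cm[colr[1]], ref_start)
      segments$ref_end[i] <- cm[colr[length(colr)]]
    }
  }
  segments
}

#' Group variable segments into hypervariable regions
#'
#' The per-VS polymorphic-count profile of a control region is typically
#' bimodal; the two peaks delimit two hypervariable regions (HVS). The
#' profile (optionally smoothed by a centered moving average) is searched
#' for local maxima; with two or more peaks, the VS are split into two
#' contiguous groups at the valley (minimum) between the two largest peaks,
#' the valley segment opening the second group. A unimodal profile yields a
#' single group with a warning. An explicit `split_after` index overrides
#' detection.
#'
#' @param vs A `segment_table` of variable segments in 5'->3' order.
#' @param counts Per-VS polymorphic counts (default taken from
#'   `vs$n_polymorphic`).
#' @param smooth_window Odd moving-average window (default 1 = none).
#' @param split_after Optional index: group 1 is VS 1..split_after.
#' @return The `segment_table` with an `hvs` column (HVS1/HVS2) and
#'   attribute `peaks` (indices of detected local maxima).
#' @examples
#' # counts 7,19,95,18,3,26,14 -> peaks at VS3 and VS6, split before VS5
#' @export
group_hypervariable <- function(vs, counts = NULL, smooth_window = 1,
                                split_after = NULL) {
  stopifnot(inherits(vs, "segment_table"))
  if (is.null(counts)) counts <- vs$n_polymorphic
  n <- length(counts)
  if (n < 2) mito_stop("need >= 2 variable segments", "mito_validation_error")
  prof <- counts
  if (smooth_window > 1) {
    k <- smooth_window %/% 2
    prof <- vapply(seq_len(n), function(i) {
      mean(counts[max(1, i - k):min(n, i + k)])
    }, 0)
  }
  peaks <- local_maxima(prof)
  attr(vs, "peaks") <- peaks
  if (is.null(split_after)) {
    if (length(peaks) < 2) {
      warning("unimodal polymorphic-count profile; single hypervariable group")
      vs$hvs <- "HVS1"
      return(vs)
    }
    top2 <- peaks[order(-prof[peaks])][1:2]
    top2 <- sort(top2)
    between <- (top2[1] + 1):(top2[2] - 1)
    valley <- between[which.min(prof[between])]
    split_after <- valley - 1L
  }
  vs$hvs <- ifelse(seq_len(nrow(vs)) <= split_after, "HVS1", "HVS2")
  vs
}

#' Indices of local maxima (boundaries count with one neighbour)
#' @noRd
local_maxima <- function(v) {
  n <- length(v)
  if (n == 1) return(1L)
  is_peak <- logical(n)
  is_peak[1] <- v[1] > v[2]
  is_peak[n] <- v[n] > v[n - 1]
  if (n > 2) {
    for (i in 2:(n - 1)) {
      is_peak[i] <- v[i] >= v[i - 1] && v[i] >= v[i + 1] &&
        (v[i] > v[i - 1] || v[i] > v[i + 1])
    }
  }
  which(is_peak)
}

#' @export
print.segment_table <- function(x, ...) {
  cat(sprintf("<segment_table> %d segments\n", nrow(x)))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
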