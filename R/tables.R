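# Reference layouts for the Penaeus vannamei mitogenome (NC_009626-style
# coordinates). These tabulations describe the published characterization of
# the ~16 kb shrimp mitochondrial genome: its control-region segmentation and
# the per-gene variant tallies. They serve two purposes: worked-example
# inputs for the arithmetic helpers, and default parameters for the
# synthetic-data generators, which emulate data with this structure.

#' Control-region segment layout
#'
#' The alternating conserved/variable segmentation of the shrimp
#' mitochondrial control region: 7 conserved segments (CS, 196 bp in total)
#' interleaved with 7 variable segments (VS, 805 bp) carrying 182
#' polymorphic sites among 45 haplotypes. Coordinates are 1-based reference
#' genome positions; the layout tiles the CR exactly (one deposited CS start
#' coordinate was inconsistent with tiling and is corrected here).
#'
#' @return data.frame: `label`, `kind`, `start`, `end`, `length`,
#'   `n_polymorphic` (NA for conserved segments), `gc_content`.
#' @export
cr_segment_layout <- function() {
  df <- data.frame(
    label = c("CS1", "VS1", "CS2", "VS2", "CS3", "VS3", "CS4", "VS4",
              "CS5", "VS5", "CS6", "VS6", "CS7", "VS7"),
    kind = rep(c("conserved", "variable"), 7),
    start = c(14996, 15036, 15090, 15117, 15205, 15228, 15580, 15600,
              15709, 15736, 15747, 15782, 15911, 15935),
    end = c(15035, 15089, 15116, 15204, 15227, 15579, 15599, 15708,
            15735, 15746, 15781, 15910, 15934, 15990),
    length = c(40, 55, 27, 89, 23, 354, 20, 110, 27, 11, 35, 130, 24, 56),
    n_polymorphic = c(NA, 7, NA, 19, NA, 95, NA, 18, NA, 3, NA, 26, NA, 14),
    gc_content = c(12.5, 8.3, 14.8, 22.9, 17.4, 9.7, 25, 13, 29.6, 25,
                   22.9, 10.6, 16.7, 14.3),
    stringsAsFactors = FALSE
  )
  df
}

#' Weighted frequency-bin reference for the control-region haplotype panel
#'
#' Per-variable-segment weighted variant counts over 10% frequency
#' intervals for the 45-haplotype control-region panel (182 polymorphic
#' sites in total; fractional entries arise from the 1/k weighting of
#' multi-allelic sites).
#'
#' @return A `freq_bin_table` with one row per variable segment.
#' @export
cr_bin_reference <- function() {
  out <- data.frame(
    region = sprintf("VS%d", 1:7),
    `(0,10]` = c(7.0, 11.0, 54.8, 10.0, 2.0, 14.5, 11.0),
    `(10,20]` = c(0.0, 4.0, 14.8, 1.5, 0.0, 5.5, 2.0),
    `(20,30]` = c(0.0, 1.0, 8.3, 1.0, 1.0, 2.0, 0.0),
    `(30,40]` = c(0.0, 0.0, 9.5, 1.5, 0.0, 1.0, 1.0),
    `(40,50]` = c(0.0, 3.0, 7.5, 4.0, 0.0, 3.0, 0.0),
    total_variants = c(7L, 19L, 95L, 18L, 3L, 26L, 14L),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  attr(out, "bin_width") <- 10
  class(out) <- c("freq_bin_table", "data.frame")
  out
}

#' Per-gene inter-individual variant reference (4-genome comparison)
#'
#' Variant tallies per gene/region for the comparison of four complete
#' mitogenomes: counts of 25%-frequency (singleton) and 50%-frequency
#' (2v2 split) polymorphic sites, region length and variability index.
#' 212 polymorphic sites in total.
#'
#' @return data.frame: `gene`, `group`, `fi25`, `fi50`, `total`, `length_bp`.
#' @export
mitogenome_gene_reference <- function() {
  data.frame(
    gene = c("VS3", "VS5", "VS2", "VS4", "COX1", "VS6", "tRNA-Tyr", "VS1",
             "tRNA-Glu", "VS7", "tRNA-Ile", "tRNA-Phe", "tRNA-Trp",
             "tRNA-Val", "COX2", "ND1", "ND2", "ND5", "CYTB", "s-rRNA",
             "ND4L", "ND4", "ATP6", "l-rRNA", "ND3", "ND6", "COX3"),
    group = c("CR", "CR", "CR", "CR", "COX", "CR", "tRNA", "CR", "tRNA",
              "CR", "tRNA", "tRNA", "tRNA", "tRNA", "COX", "ND", "ND", "ND",
              "COX", "rRNA", "ND", "ND", "ATP", "rRNA", "ND", "ND", "COX"),
    fi25 = c(18, 0, 6, 0, 92, 4, 3, 2, 0, 0, 1, 1, 1, 1, 4, 5, 7, 6, 4, 3,
             0, 3, 2, 2, 1, 1, 1),
    fi50 = c(17, 1, 1, 7, 0, 3, 0, 0, 2, 1, 0, 0, 0, 0, 3, 2, 0, 3, 0, 0,
             1, 1, 0, 2, 0, 0, 0),
    length_bp = c(352, 11, 87, 109, 1534, 129, 66, 55, 70, 56, 67, 67, 69,
                  72, 688, 938, 1000, 1723, 1136, 856, 300, 1341, 675, 1370,
                  352, 516, 790),
    stringsAsFactors = FALSE
  )
}

#' Per-gene heteroplasmy reference (single-genome read pileup)
#'
#' Called heteroplasmic variant counts per gene over 10% frequency
#' intervals for the intra-individual analysis of a single assembled
#' mitogenome (186 variants: 112 insertions, 72 deletions, 2 transitions).
#' One tRNA length is the average of the two serine tRNA genes as deposited.
#'
#' @return data.frame: `gene`, `group`, six bin columns, `total`,
#'   `length_bp`.
#' @export
het_gene_reference <- function() {
  df <- data.frame(
    gene = c("ND3", "tRNA-Ala", "tRNA-Arg", "tRNA-Lys", "CS6", "ND1",
             "ATP8", "VS7", "ND6", "tRNA-Gly", "tRNA-Pro", "tRNA-Thr",
             "tRNA-Ser", "ND5", "tRNA-Asp", "tRNA-Glu", "CYTB", "ATP6",
             "COX1", "COX3", "VS2", "ND2", "l-rRNA", "ND4", "s-rRNA",
             "COX2", "ND4L", "VS3"),
    group = c("ND", "tRNA", "tRNA", "tRNA", "CR", "ND", "ATP", "CR", "ND",
              "tRNA", "tRNA", "tRNA", "tRNA", "ND", "tRNA", "tRNA", "COX",
              "ATP", "COX", "COX", "CR", "ND", "rRNA", "ND", "rRNA", "COX",
              "ND", "CR"),
    `(0,10]` = c(5, 2, 2, 1, 0, 11, 1, 0, 1, 0, 0, 0, 0, 19, 1, 1, 12, 8,
                 15, 5, 0, 6, 5, 5, 3, 1, 0, 0),
    `(10,20]` = c(7, 0, 0, 1, 0, 9, 1, 0, 4, 1, 1, 0, 1, 5, 0, 0, 3, 1, 5,
                  3, 0, 4, 4, 4, 2, 2, 0, 0),
    `(20,30]` = c(1, 0, 0, 0, 0, 1, 1, 1, 3, 0, 0, 0, 0, 1, 0, 0, 1, 0, 0,
                  2, 0, 1, 2, 1, 0, 1, 1, 0),
    `(30,40]` = c(0, 0, 0, 0, 0, 1, 0, 0, 0, 0, 0, 1, 0, 0, 0, 0, 0, 0, 0,
                  0, 1, 0, 0, 0, 0, 0, 0, 1),
    `(40,50]` = c(0, 0, 0, 0, 1, 1, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0,
                  0, 0, 0, 0, 0, 0, 0, 0, 0),
    `(50,60]` = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0,
                  0, 0, 0, 1, 0, 0, 0, 0, 0),
    length_bp = c(352, 65, 65, 69, 35, 938, 159, 56, 516, 66, 67, 68, 68.5,
                  1723, 70, 70, 1136, 675, 1534, 790, 87, 1000, 1370, 1341,
                  856, 688, 300, 352),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  bins <- grep("^\\(", names(df), value = TRUE)
  df$total <- as.integer(rowSums(df[, bins]))
  df
}
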