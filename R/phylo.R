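#' Pairwise distances from an alignment
#'
#' Computes a symmetric distance matrix under one of three models, with
#' pairwise deletion: for each pair of sequences, columns where either
#' carries a gap or `N` are removed before counting.
#'
#' Models: `"p"` — proportion of mismatching compared columns;
#' `"TN93"` — Tamura-Nei 1993, separating the two transition classes
#' (A<->G, C<->T) with unequal base frequencies; `"T92"` — Tamura 1992,
#' using the GC content of the pair. For `TN93` and `T92` a gamma rate
#' correction with shape `gamma` replaces each `log(x)` term by
#' `a * (x^(-1/a) - 1)`, the standard continuous-gamma form (shape 0.18 is
#' typical for a hypervariable control region).
#'
#' Saturated pairs (a logarithm argument <= 0) get distance `ceiling` with
#' a warning.
#'
#' @param x An [msa()].
#' @param model `"p"`, `"TN93"` or `"T92"`.
#' @param gamma Gamma shape parameter, or `NULL` for uniform rates.
#' @param ceiling Distance assigned to saturated pairs (default 5).
#' @return Symmetric numeric matrix with zero diagonal, taxa as dimnames;
#'   attribute `model` records the settings.
#' @export
pairwise_distance <- function(x, model = c("p", "TN93", "T92"),
                              gamma = NULL, ceiling = 5) {
  stopifnot(inherits(x, "msa"))
  model <- match.arg(model)
  m <- as.matrix(x)
  n <- x$n_seqs
  d <- matrix(0, n, n, dimnames = list(x$ids, x$ids))
  ok_base <- matrix(m %in% DNA_BASES, nrow = n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      use <- ok_base[i, ] & ok_base[j, ]           # pairwise deletion
      a <- m[i, use]; b <- m[j, use]
      dij <- dist_one_pair(a, b, model, gamma)
      if (!is.finite(dij)) {
        warning(sprintf("saturated pair (%s, %s); distance set to %g",
                        x$ids[i], x$ids[j], ceiling))
        dij <- ceiling
      }
      d[i, j] <- d[j, i] <- dij
    }
  }
  attr(d, "model") <- list(model = model, gamma = gamma)
  d
}

#' @noRd
gamma_log <- function(x, a) {
  # -log(x) under uniform rates; a*(x^(-1/a)-1) under gamma shape a
  if (is.null(a)) -log(x) else a * (x^(-1 / a) - 1)
}

#' @noRd
dist_one_pair <- function(a, b, model, gamma) {
  nc <- length(a)
  if (nc == 0) return(NA_real_)
  if (model == "p") return(sum(a != b) / nc)
  diff <- a != b
  ts1 <- sum((a == "A" & b == "G") | (a == "G" & b == "A")) / nc  # purine transitions
  ts2 <- sum((a == "C" & b == "T") | (a == "T" & b == "C")) / nc  # pyrimidine transitions
  Q <- sum(diff) / nc - ts1 - ts2                                  # transversions
  if (model == "T92") {
    theta <- mean(c(a, b) %in% c("G", "C"))
    h <- 2 * theta * (1 - theta)
    P <- ts1 + ts2
    x1 <- 1 - P / h - Q
    x2 <- 1 - 2 * Q
    if (h <= 0 || x1 <= 0 || x2 <= 0) return(NA_real_)
    return(h * gamma_log(x1, gamma) + 0.5 * (1 - h) * gamma_log(x2, gamma))
  }
  # TN93
  f <- function(base) (sum(a == base) + sum(b == base)) / (2 * nc)
  pA <- f("A"); pC <- f("C"); pG <- f("G"); pT <- f("T")
  pR <- pA + pG; pY <- pC + pT
  k1 <- 2 * pA * pG / pR
  k2 <- 2 * pT * pC / pY
  k3 <- 2 * (pR * pY - pA * pG * pY / pR - pT * pC * pR / pY)
  x1 <- 1 - ts1 / k1 - Q / (2 * pR)
  x2 <- 1 - ts2 / k2 - Q / (2 * pY)
  x3 <- 1 - Q / (2 * pR * pY)
  if (any(c(k1, k2) <= 0) || x1 <= 0 || x2 <= 0 || x3 <= 0) return(NA_real_)
  k1 * gamma_log(x1, gamma) + k2 * gamma_log(x2, gamma) + k3 * gamma_log(x3, gamma)
}

#' UPGMA clustering of a distance matrix
#'
#' Average-linkage agglomeration producing a rooted ultrametric tree: the
#' closest pair of clusters joins at height `d/2`, branch lengths are
#' height differences, and the distance from a merged cluster to the others
#' is the size-weighted average. Ties are broken deterministically in
#' favour of the smallest `(i, j)` index pair.
#'
#' @param d Symmetric distance matrix with taxa dimnames (or a `dist`).
#' @return An \pkg{ape} `phylo` tree (rooted, ultrametric) with attribute
#'   `heights` (join height per merge, root last).
#' @export
upgma <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d), nrow(d) >= 2)
  if (max(abs(d - t(d))) > 1e-12) mito_stop("matrix not symmetric", "mito_validation_error")
  taxa <- rownames(d)
  if (is.null(taxa)) taxa <- paste0("t", seq_len(nrow(d)))
  n <- nrow(d)
  active <- seq_len(n)
  newick <- taxa
  heights <- rep(0, n)
  sizes <- rep(1L, n)
  dd <- d
  merge_heights <- numeric(0)
  while (length(active) > 1) {
    k <- length(active)
    best <- c(NA, NA); bmin <- Inf
    for (ii in 1:(k - 1)) {
      for (jj in (ii + 1):k) {
        v <- dd[active[ii], active[jj]]
        if (v < bmin - 1e-15) { bmin <- v; best <- c(ii, jj) }
      }
    }
    i <- active[best[1]]; j <- active[best[2]]
    h <- bmin / 2
    merge_heights <- c(merge_heights, h)
    bi <- h - heights[i]; bj <- h - heights[j]
    new_nwk <- sprintf("(%s:%.10g,%s:%.10g)", newick[i], bi, newick[j], bj)
    # weighted average distance of the merged cluster to the rest
    for (o in setdiff(active, c(i, j))) {
      v <- (sizes[i] * dd[i, o] + sizes[j] * dd[j, o]) / (sizes[i] + sizes[j])
      dd[i, o] <- dd[o, i] <- v
    }
    newick[i] <- new_nwk
    heights[i] <- h
    sizes[i] <- sizes[i] + sizes[j]
    active <- setdiff(active, j)
  }
  tree <- ape::read.tree(text = paste0(newick[active], ";"))
  attr(tree, "heights") <- merge_heights
  tree
}

#' UPGMA tree with bootstrap support
#'
#' Builds the UPGMA tree from the full alignment, then resamples alignment
#' columns with replacement `n_reps` times, rebuilding the tree each time;
#' the support of each internal node is the fraction of replicate trees
#' containing the same bipartition (clade). Reproducible under a fixed
#' seed.
#'
#' @inheritParams pairwise_distance
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param seed Integer seed for the column resampling.
#' @return The `phylo` tree with `node.label` set to support fractions in
#'   `[0, 1]`.
#' @export
bootstrap_support <- function(x, model = "p", gamma = NULL, n_reps = 100,
                              seed = 1) {
  stopifnot(inherits(x, "msa"), n_reps >= 1)
  base_tree <- upgma(pairwise_distance(x, model = model, gamma = gamma))
  m <- as.matrix(x)
  set.seed(as.integer(seed))
  reps <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cols <- sample.int(x$n_cols, x$n_cols, replace = TRUE)
    xr <- msa(x$ids, apply(m[, cols, drop = FALSE], 1, paste, collapse = ""),
              reference_id = x$reference_id)
    reps[[r]] <- suppressWarnings(
      upgma(pairwise_distance(xr, model = model, gamma = gamma)))
  }
  class(reps) <- "multiPhylo"
  cl <- ape::prop.clades(base_tree, reps, rooted = TRUE)
  cl[is.na(cl)] <- 0
  base_tree$node.label <- cl / n_reps
  base_tree
}

#' Leaf-to-root distances of a rooted tree
#' @noRd
root_to_tip <- function(tree) {
  nt <- ape::Ntip(tree)
  dm <- ape::dist.nodes(tree)
  root <- nt + 1L
  dm[root, seq_len(nt)]
}

#' Write a distance matrix in square PHYLIP format
#'
#' @param d Symmetric distance matrix.
#' @param path Output path.
#' @export
write_phylip_dist <- function(d, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(d)), con)
  for (i in seq_len(nrow(d))) {
    writeLines(paste(c(sprintf("%-10s", rownames(d)[i]),
                       sprintf("%.6f", d[i, ])), collapse = " "), con)
  }
  invisible(path)
}
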