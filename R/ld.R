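#' Number of locus pairs
#'
#' @param n number of polymorphic loci.
#' @return `n * (n - 1) / 2`.
#' @export
#' @examples
#' n_pairs(4)  # 6
n_pairs <- function(n) {
  stopifnot(n >= 0)
  as.integer(n * (n - 1) / 2)
}

#' Pairwise linkage disequilibrium over phased haplotypes
#'
#' Computes, for every pair of loci, the classical haplotype-frequency
#' LD statistics D, D', r and r2, the chi-square statistic `2N * r2`,
#' and a two-tailed Fisher exact p-value from the 2x2 haplotype-count
#' table, with Bonferroni-corrected significance flags over all pairs.
#'
#' Alleles enter as major/minor per locus (ties broken toward the first
#' allele seen): with major alleles A and B,
#' `D = p_AB - p_A * p_B`; `D' = D / D_max` where
#' `D_max = min(p_A p_b, p_a p_B)` for positive D and
#' `min(p_A p_B, p_a p_b)` otherwise; `r = D / sqrt(p_A p_a p_B p_b)`.
#' Pairs involving a monomorphic locus are returned with `NA` statistics
#' and flagged not applicable rather than zero.
#'
#' @param x a `phased_cohort` (e.g. from [em_phase()]), or a character
#'   matrix of haplotype allele vectors.
#' @param counts when `x` is a matrix: observation count per row
#'   (default 1 each).
#' @param alpha family-wise error rate for the Bonferroni flag.
#' @return data frame of class `ld_table`, one row per locus pair:
#'   `locus_a`, `locus_b`, `D`, `D_prime`, `r`, `r2`, `chi2`,
#'   `fisher_p`, `bonferroni_significant`, `applicable`.
#' @export
pairwise_ld <- function(x, counts = NULL, alpha = 0.05) {
  if (inherits(x, "phased_cohort")) {
    idx <- as.vector(x$pairs)
    haps <- x$haplotypes[idx, , drop = FALSE]
    counts <- rep(1, nrow(haps))
  } else {
    haps <- as.matrix(x)
    if (is.null(counts)) counts <- rep(1, nrow(haps))
  }
  L <- ncol(haps)
  if (L < 2L) stop("at least two loci are required")
  loci <- colnames(haps)
  if (is.null(loci)) loci <- paste0("L", seq_len(L))
  N2 <- sum(counts)
  rows <- list()
  for (i in seq_len(L - 1L)) {
    for (j in seq((i + 1L), L)) {
      res <- .ld_pair(haps[, i], haps[, j], counts)
      rows[[length(rows) + 1L]] <- data.frame(
        locus_a = loci[i], locus_b = loci[j],
        D = res$D, D_prime = res$D_prime, r = res$r, r2 = res$r2,
        chi2 = if (is.na(res$r2)) NA_real_ else N2 * res$r2,
        fisher_p = res$fisher_p, applicable = res$applicable,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$bonferroni_significant <- FALSE
  app <- out$applicable
  if (any(app))
    out$bonferroni_significant[app] <-
      bonferroni(out$fisher_p[app], alpha)
  rownames(out) <- NULL
  class(out) <- c("ld_table", "data.frame")
  out
}

.ld_pair <- function(ai, aj, counts) {
  na_res <- list(D = NA_real_, D_prime = NA_real_, r = NA_real_,
                 r2 = NA_real_, fisher_p = NA_real_, applicable = FALSE)
  ti <- rowsum(counts, ai)
  tj <- rowsum(counts, aj)
  if (nrow(ti) != 2L || nrow(tj) != 2L) return(na_res)
  # major allele first; ties keep the sorted (alphabetical) first allele
  Ai <- rownames(ti)[order(-ti[, 1])][1]
  Bj <- rownames(tj)[order(-tj[, 1])][1]
  n <- sum(counts)
  pA <- sum(counts[ai == Ai]) / n
  pB <- sum(counts[aj == Bj]) / n
  pAB <- sum(counts[ai == Ai & aj == Bj]) / n
  D <- pAB - pA * pB
  pa <- 1 - pA; pb <- 1 - pB
  Dmax <- if (D > 0) min(pA * pb, pa * pB) else min(pA * pB, pa * pb)
  D_prime <- if (Dmax == 0) 0 else D / Dmax
  denom <- sqrt(pA * pa * pB * pb)
  r <- D / denom
  tab <- matrix(round(c(pAB, pA - pAB, pB - pAB,
                        1 - pA - pB + pAB) * n), 2L, 2L)
  fisher_p <- stats::fisher.test(tab)$p.value
  list(D = D, D_prime = D_prime, r = r, r2 = r^2,
       fisher_p = fisher_p, applicable = TRUE)
}

#' @export
print.ld_table <- function(x, digits = 4, ...) {
  cat("Pairwise linkage disequilibrium (", nrow(x), "locus pair(s) )\n")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], round, digits = digits)
  print(df, row.names = FALSE)
  invisible(x)
}
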