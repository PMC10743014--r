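#' Hamming distances of haplotypes from a reference
#'
#' The per-haplotype mutation count relative to a designated reference
#' haplotype (e.g. the wild type, or the most frequent haplotype).
#'
#' @param haps character matrix of haplotype allele vectors.
#' @param reference reference allele vector, or the row label of a row
#'   of `haps`.
#' @return named integer vector of distances.
#' @export
#' @examples
#' burden_distances(atg16l1_haplotypes(), "hap1")
burden_distances <- function(haps, reference) {
  haps <- as.matrix(haps)
  reference <- .resolve_reference(haps, reference)
  stats::setNames(as.integer(colSums(t(haps) != reference)),
                  rownames(haps))
}

.resolve_reference <- function(haps, reference) {
  if (is.character(reference) && length(reference) == 1L &&
      !is.null(rownames(haps)) && reference %in% rownames(haps))
    reference <- haps[reference, ]
  if (length(reference) != ncol(haps))
    stop("reference must have one allele per locus of the haplotype set")
  reference
}

#' Per-genotype cumulative mutation burden
#'
#' The burden of a diploid genotype is the sum over its two haplotypes
#' of Hamming distances to the reference haplotype.
#'
#' @param x a `phased_cohort`.
#' @param reference as in [burden_distances()].
#' @return named integer vector, one burden per individual.
#' @export
genotype_burden <- function(x, reference) {
  stopifnot(inherits(x, "phased_cohort"))
  d <- burden_distances(x$haplotypes, reference)
  stats::setNames(d[x$pairs[, 1]] + d[x$pairs[, 2]], x$sample_id)
}

#' Group comparison of cumulative mutation burden
#'
#' Compares per-genotype cumulative mutation counts between controls and
#' patients under a named reference design. Homogeneity of variances is
#' checked with Levene's test (mean-centred); when Levene's p < 0.05 the
#' two-sided t-test assumes unequal variances (Welch-Satterthwaite
#' degrees of freedom), otherwise the pooled-variance t is used, and the
#' branch taken is recorded. When the pooled within-group variance is
#' zero the t statistic degenerates; equal group means then give t = 0,
#' p = 1, and unequal means are handled by the exact permutation
#' distribution of the mean difference over all group-label
#' reassignments.
#'
#' @param x a `phased_cohort` with both groups present.
#' @param reference as in [burden_distances()]; typically `"hap1"` (wild
#'   type) or `"hap2"` (most frequent haplotype).
#' @param design optional design name recorded on the result (defaults
#'   to the reference label when one was given).
#' @return object of class `burden_result`: per-individual burdens,
#'   group means and variances, `levene_p`, `t`, `df`, `p`,
#'   `variance_assumption`, `method`.
#' @export
burden_test <- function(x, reference, design = NULL) {
  stopifnot(inherits(x, "phased_cohort"))
  if (is.null(design))
    design <- if (is.character(reference) && length(reference) == 1L)
      paste0(reference, "_reference") else "custom_reference"
  burden <- genotype_burden(x, reference)
  grp <- factor(x$group, levels = c("control", "patient"))
  if (any(table(grp) < 2L))
    stop("both groups need at least 2 individuals")
  m <- tapply(burden, grp, mean)
  v <- tapply(burden, grp, stats::var)
  res <- list(design = design, burden = burden, group = x$group,
              group_means = m, group_vars = v)
  if (all(v == 0)) {
    if (m[1] == m[2]) {
      res <- c(res, list(levene_p = NA_real_, t = 0, df = NA_real_,
                         p = 1, variance_assumption = "degenerate",
                         method = "degenerate: zero variance, equal means"))
    } else {
      p <- .exact_mean_perm_p(burden, grp)
      res <- c(res, list(levene_p = NA_real_, t = Inf, df = NA_real_,
                         p = p, variance_assumption = "degenerate",
                         method = "exact permutation of group labels"))
    }
    return(structure(res, class = "burden_result"))
  }
  lev <- tryCatch(
    car::leveneTest(burden ~ grp, center = mean)[1, "Pr(>F)"],
    error = function(e) NA_real_)
  welch <- is.na(lev) || lev < 0.05
  tt <- stats::t.test(burden ~ grp, var.equal = !welch)
  res <- c(res, list(
    levene_p = lev, t = unname(tt$statistic),
    df = unname(tt$parameter), p = tt$p.value,
    variance_assumption = if (welch) "unequal (Welch)" else "pooled",
    method = tt$method))
  structure(res, class = "burden_result")
}

# exact (or large-sample Monte-Carlo) permutation p for |mean difference|
.exact_mean_perm_p <- function(y, grp) {
  n <- length(y)
  n1 <- sum(grp == levels(grp)[1])
  obs <- abs(mean(y[grp == levels(grp)[1]]) -
               mean(y[grp != levels(grp)[1]]))
  if (choose(n, n1) <= 2e5) {
    combs <- utils::combn(n, n1)
    tot <- sum(y)
    stats <- abs(colSums(matrix(y[combs], nrow = n1)) / n1 -
                   (tot - colSums(matrix(y[combs], nrow = n1))) / (n - n1))
    mean(stats >= obs - 1e-12)
  } else {
    B <- 100000L
    hits <- 0L
    for (b in seq_len(B)) {
      idx <- sample.int(n, n1)
      s <- abs(mean(y[idx]) - mean(y[-idx]))
      if (s >= obs - 1e-12) hits <- hits + 1L
    }
    (hits + 1) / (B + 1)
  }
}

#' @export
print.burden_result <- function(x, ...) {
  cat("Cumulative mutation burden,", x$design, "design\n")
  cat(sprintf("  control mean %.4f (var %.4f), patient mean %.4f (var %.4f)\n",
              x$group_means[["control"]], x$group_vars[["control"]],
              x$group_means[["patient"]], x$group_vars[["patient"]]))
  cat(sprintf("  Levene p = %s; %s\n",
              format(x$levene_p, digits = 4), x$variance_assumption))
  cat(sprintf("  t = %.4f, df = %.2f, two-sided p = %.5g\n",
              x$t, if (is.na(x$df)) NA else x$df, x$p))
  invisible(x)
}
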