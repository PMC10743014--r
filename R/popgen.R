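#' Per-locus allele frequencies
#'
#' Tallies alleles over the non-missing diploid genotypes of a cohort,
#' optionally restricted to one group.
#'
#' @param x a `cohort`.
#' @param locus rs identifier of a panel locus, or `NULL` for all loci.
#' @param group `"control"`, `"patient"` or `NULL` (both groups pooled).
#' @return data frame with columns `rs_id`, `allele`, `count`, `freq`,
#'   `n` (non-missing diploids).
#' @export
allele_freqs <- function(x, locus = NULL, group = NULL) {
  stopifnot(inherits(x, "cohort"))
  keep <- if (is.null(group)) rep(TRUE, n_individuals(x))
          else x$group == group
  if (!any(keep)) stop("no individuals in the requested scope")
  rs <- if (is.null(locus)) x$panel$loci$rs_id else locus
  out <- list()
  for (r in rs) {
    j <- match(r, x$panel$loci$rs_id)
    if (is.na(j)) stop("unknown locus: ", r)
    al <- c(x$a1[keep, j], x$a2[keep, j])
    al <- al[!is.na(al)]
    if (length(al) == 0L) stop("no non-missing genotypes at ", r)
    lev <- c(x$panel$loci$ref[j], x$panel$loci$alt[j])
    cnt <- table(factor(al, levels = lev))
    out[[r]] <- data.frame(
      rs_id = r, allele = lev, count = as.integer(cnt),
      freq = as.numeric(cnt) / length(al),
      n = length(al) %/% 2L, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-locus genotype counts
#'
#' @param x a `cohort`.
#' @param locus rs identifier.
#' @param group optional group filter.
#' @return integer vector `c(n_rr, n_ra, n_aa)` (hom-ref, het, hom-alt).
#' @export
genotype_counts <- function(x, locus, group = NULL) {
  stopifnot(inherits(x, "cohort"))
  j <- match(locus, x$panel$loci$rs_id)
  if (is.na(j)) stop("unknown locus: ", locus)
  keep <- if (is.null(group)) rep(TRUE, n_individuals(x))
          else x$group == group
  a1 <- x$a1[keep, j]; a2 <- x$a2[keep, j]
  ok <- !is.na(a1)
  alt <- x$panel$loci$alt[j]
  code <- (a1[ok] == alt) + (a2[ok] == alt)
  c(n_rr = sum(code == 0L), n_ra = sum(code == 1L),
    n_aa = sum(code == 2L))
}

#' Hardy-Weinberg exact test
#'
#' Exact two-sided test of Hardy-Weinberg proportions for one biallelic
#' locus, by full enumeration of Levene's conditional distribution of the
#' heterozygote count given the allele counts. The p-value is the sum of
#' the probabilities of all configurations no more probable than the
#' observed one (ties included).
#'
#' @param n_rr,n_ra,n_aa genotype counts (hom-ref, het, hom-alt); a
#'   length-3 vector may be given as `n_rr`.
#' @return p-value in `[0, 1]`.
#' @export
#' @examples
#' hwe_exact(1, 0, 1)  # 1/3
hwe_exact <- function(n_rr, n_ra = NULL, n_aa = NULL) {
  if (is.null(n_ra)) {
    stopifnot(length(n_rr) == 3L)
    n_aa <- n_rr[3]; n_ra <- n_rr[2]; n_rr <- n_rr[1]
  }
  if (any(c(n_rr, n_ra, n_aa) < 0)) stop("negative genotype count")
  n <- n_rr + n_ra + n_aa
  if (n == 0) stop("empty genotype table")
  nA <- 2 * n_rr + n_ra
  na <- 2 * n_aa + n_ra
  if (nA == 0 || na == 0) return(1)
  hets <- seq(nA %% 2, min(nA, na), by = 2)
  # log P(het = h | nA, na) = log n! - log nRR! - log h! - log naa!
  #   + h log2 + log nA! + log na! - log (2n)!
  logp <- vapply(hets, function(h) {
    nrr <- (nA - h) / 2; naa2 <- (na - h) / 2
    lgamma(n + 1) - lgamma(nrr + 1) - lgamma(h + 1) - lgamma(naa2 + 1) +
      h * log(2) + lgamma(nA + 1) + lgamma(na + 1) - lgamma(2 * n + 1)
  }, 0)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_ra, hets)]
  sum(p[p <= obs + 1e-12])
}

#' Exact/Monte-Carlo group differentiation test at a locus
#'
#' Tests whether allele (or genotype) composition differs between the
#' control and patient groups at one locus. The observed group-by-allele
#' (or group-by-genotype) contingency table is compared against tables
#' obtained by permuting group labels across individuals, using the
#' table's conditional (multivariate hypergeometric) probability as the
#' ordering statistic; the p-value is the proportion of permuted tables
#' no more probable than the observed one, with Monte-Carlo standard
#' error `sqrt(p(1-p)/n_mc)`. For the 2x2 allelic table the exact
#' two-sided Fisher probability is returned directly (SE = 0).
#'
#' @param x a `cohort`.
#' @param locus rs identifier.
#' @param mode `"allelic"` or `"genotypic"`.
#' @param n_mc number of Monte-Carlo permutations.
#' @param seed integer seed.
#' @return list with `p`, `se`, `mode`, `table` (the observed table) and
#'   `method`.
#' @export
diff_test <- function(x, locus, mode = c("allelic", "genotypic"),
                      n_mc = 100000L, seed = 1L) {
  stopifnot(inherits(x, "cohort"))
  mode <- match.arg(mode)
  j <- match(locus, x$panel$loci$rs_id)
  if (is.na(j)) stop("unknown locus: ", locus)
  ok <- !is.na(x$a1[, j])
  grp <- x$group[ok]
  if (!all(c("control", "patient") %in% grp))
    stop("both groups must be represented at the locus")
  alt <- x$panel$loci$alt[j]
  if (mode == "allelic") {
    # one observation per chromosome; labels permute per individual
    item <- (x$a1[ok, j] == alt) + (x$a2[ok, j] == alt)  # alt count 0..2
    tab <- rbind(control = c(2 * sum(grp == "control") -
                               sum(item[grp == "control"]),
                             sum(item[grp == "control"])),
                 patient = c(2 * sum(grp == "patient") -
                               sum(item[grp == "patient"]),
                             sum(item[grp == "patient"])))
    colnames(tab) <- c(x$panel$loci$ref[j], alt)
    if (any(colSums(tab) == 0))
      return(list(p = 1, se = 0, mode = mode, table = tab,
                  method = "degenerate (monomorphic)"))
    p <- stats::fisher.test(tab)$p.value
    return(list(p = p, se = 0, mode = mode, table = tab,
                method = "Fisher exact (2x2)"))
  }
  code <- (x$a1[ok, j] == alt) + (x$a2[ok, j] == alt)
  lev <- 0:2
  tab <- rbind(control = tabulate(code[grp == "control"] + 1L, 3L),
               patient = tabulate(code[grp == "patient"] + 1L, 3L))
  colnames(tab) <- c("ref/ref", "ref/alt", "alt/alt")
  nz <- colSums(tab) > 0
  if (sum(nz) <= 1L)
    return(list(p = 1, se = 0, mode = mode, table = tab,
                method = "degenerate (single genotype class)"))
  obs_lp <- .table_logprob(tab[, nz, drop = FALSE])
  n_ctrl <- sum(grp == "control")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  hits <- 0L
  n_tot <- length(code)
  for (b in seq_len(n_mc)) {
    idx <- sample.int(n_tot, n_ctrl)
    t1 <- tabulate(code[idx] + 1L, 3L)
    pt <- rbind(t1, colSums(tab) - t1)[, nz, drop = FALSE]
    if (.table_logprob(pt) <= obs_lp + 1e-9) hits <- hits + 1L
  }
  p <- hits / n_mc
  list(p = p, se = sqrt(p * (1 - p) / n_mc), mode = mode, table = tab,
       method = sprintf("Monte-Carlo permutation (%d draws)", n_mc))
}

# log conditional probability of a contingency table given its margins
.table_logprob <- function(tab) {
  sum(lgamma(rowSums(tab) + 1)) + sum(lgamma(colSums(tab) + 1)) -
    lgamma(sum(tab) + 1) - sum(lgamma(tab + 1))
}

#' Pearson chi-square test on a 2x2 allele-count table
#'
#' Chi-square homogeneity test without continuity correction (df = 1).
#'
#' @param tab 2x2 matrix of allele counts (groups x alleles).
#' @return list with `statistic`, `p`, `df`.
#' @export
allele_chisq <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("a 2x2 table is required")
  if (any(tab < 0)) stop("negative counts")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero margin in allele table")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), p = ct$p.value, df = 1L)
}

#' Bonferroni significance flags
#'
#' Flags test `i` as significant iff `p_i < alpha / m`, where `m` is the
#' number of tests performed.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param alpha family-wise error rate.
#' @return logical vector of the same length as `p`.
#' @export
bonferroni <- function(p, alpha = 0.05) {
  if (length(p) == 0L) return(logical(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0,1]")
  p < alpha / length(p)
}

#' Locus-by-locus summary of a cohort
#'
#' Convenience wrapper producing per-locus allele frequencies, genotype
#' counts and Hardy-Weinberg exact p-values for each scope (control,
#' patient, global), mirroring the per-SNP table of a case-control
#' promoter study.
#'
#' @param x a `cohort`.
#' @return data frame with one row per locus and scope.
#' @export
locus_summary <- function(x) {
  stopifnot(inherits(x, "cohort"))
  scopes <- list(control = "control", patient = "patient",
                 global = NULL)
  rows <- list()
  for (r in x$panel$loci$rs_id) {
    j <- match(r, x$panel$loci$rs_id)
    for (s in names(scopes)) {
      gc <- genotype_counts(x, r, scopes[[s]])
      n <- sum(gc)
      alt_freq <- (gc[["n_ra"]] + 2 * gc[["n_aa"]]) / (2 * n)
      rows[[length(rows) + 1L]] <- data.frame(
        rs_id = r, scope = s,
        ref = x$panel$loci$ref[j], alt = x$panel$loci$alt[j],
        n = n, n_rr = gc[["n_rr"]], n_ra = gc[["n_ra"]],
        n_aa = gc[["n_aa"]],
        ref_freq = 1 - alt_freq, alt_freq = alt_freq,
        hwe_p = hwe_exact(gc), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
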