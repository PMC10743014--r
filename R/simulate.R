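#' Specify a two-group cohort simulation
#'
#' A cohort spec fixes the haplotype pool and the per-group haplotype
#' frequency vectors, sample sizes and missing-data rate from which
#' [generate_cohort()] draws synthetic diploid individuals under
#' Hardy-Weinberg random union of haplotypes.
#'
#' @param panel a `locus_panel`.
#' @param haplotypes character matrix of haplotype allele vectors (see
#'   [haplotype_set()]).
#' @param freqs named list with elements `control` and `patient`, each a
#'   non-negative frequency vector over the haplotypes summing to 1.
#' @param n named integer vector `c(control = ..., patient = ...)` of
#'   diploid sample sizes.
#' @param missing_rate probability that a genotype cell is masked as
#'   missing, in `[0, 1]`.
#' @param seed integer seed governing all draws.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(panel, haplotypes, freqs, n,
                        missing_rate = 0, seed = 1L) {
  stopifnot(inherits(panel, "locus_panel"))
  haplotypes <- haplotype_set(panel, haplotypes,
                              labels = rownames(haplotypes))
  K <- nrow(haplotypes)
  if (K < 1L) stop("haplotype set is empty")
  for (g in c("control", "patient")) {
    f <- freqs[[g]]
    if (is.null(f) || length(f) != K)
      stop("freqs$", g, " must have one entry per haplotype")
    if (any(f < 0) || abs(sum(f) - 1) > 1e-9)
      stop("freqs$", g, " must be non-negative and sum to 1")
  }
  if (!all(c("control", "patient") %in% names(n)) || any(n <= 0))
    stop("n must be positive counts named 'control' and 'patient'")
  if (missing_rate < 0 || missing_rate > 1)
    stop("missing_rate must lie in [0, 1]")
  structure(list(panel = panel, haplotypes = haplotypes,
                 freqs = freqs[c("control", "patient")],
                 n = c(control = as.integer(n[["control"]]),
                       patient = as.integer(n[["patient"]])),
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Cohort spec on panel", x$panel$name, "\n")
  cat(sprintf("  n = %d control / %d patient, missing rate %.3f, seed %d\n",
              x$n[["control"]], x$n[["patient"]], x$missing_rate, x$seed))
  tab <- cbind(control = x$freqs$control, patient = x$freqs$patient)
  rownames(tab) <- rownames(x$haplotypes)
  print(round(tab, 4))
  invisible(x)
}

#' Bundled case-control cohort specifications
#'
#' Returns the simulation spec emulating the sporadic Parkinson's disease
#' case-control study of the ATG16L1 and ATG5 promoters: 28 controls and
#' 56 patients.
#'
#' For ATG16L1 the seven haplotypes of [atg16l1_haplotypes()] segregate.
#' The control frequency vector (0.250, 0.625, 0.125, 0, 0, 0, 0) is the
#' unique solution of the observed control allele frequencies; hap4-hap7
#' (the carriers of T at rs77820970) are absent from controls. The
#' patient allele frequencies (T at rs1816753: 0.232; C at rs12476635:
#' 0.146; T at rs74599577: 0.024; T at rs77820970: 0.220) constrain but
#' do not determine the seven patient haplotype frequencies; the bundled
#' vector (0.142, 0.537, 0.101, 0.106, 0.024, 0.045, 0.045) satisfies all
#' four constraints exactly while keeping every patient-only haplotype's
#' expected count at n = 56 at two copies or more.
#'
#' For ATG5 exactly two haplotypes, TG and CA, segregate in complete
#' linkage at frequencies 0.518/0.482 (controls) and 0.536/0.464
#' (patients).
#'
#' @param gene `"ATG16L1"` or `"ATG5"`.
#' @param seed integer seed stored on the spec.
#' @param missing_rate missing-genotype rate stored on the spec.
#' @return a `cohort_spec`.
#' @export
#' @examples
#' promoter_cohort_spec("ATG16L1")
promoter_cohort_spec <- function(gene = c("ATG16L1", "ATG5"), seed = 1L,
                                 missing_rate = 0) {
  gene <- match.arg(gene)
  if (gene == "ATG16L1") {
    cohort_spec(
      panel = atg16l1_panel(),
      haplotypes = atg16l1_haplotypes(),
      freqs = list(
        control = c(0.250, 0.625, 0.125, 0, 0, 0, 0),
        patient = c(0.142, 0.537, 0.101, 0.106, 0.024, 0.045, 0.045)),
      n = c(control = 28L, patient = 56L),
      missing_rate = missing_rate, seed = seed)
  } else {
    cohort_spec(
      panel = atg5_panel(),
      haplotypes = atg5_haplotypes(),
      freqs = list(control = c(0.518, 0.482),
                   patient = c(0.536, 0.464)),
      n = c(control = 28L, patient = 56L),
      missing_rate = missing_rate, seed = seed)
  }
}

#' Generate a synthetic cohort
#'
#' For every individual, two haplotypes are drawn independently from the
#' group's frequency vector (Hardy-Weinberg random union); the unordered
#' per-locus allele pairs are recorded and phase is discarded. Missing
#' cells are then injected independently at the spec's `missing_rate`.
#' The draw is fully reproducible from the seed.
#'
#' @param spec a `cohort_spec`.
#' @param seed integer seed; defaults to the seed stored on the spec.
#' @return a `cohort`; the simulated true haplotype pair indices are
#'   attached as attribute `"true_pairs"` (an n x 2 integer matrix).
#' @export
generate_cohort <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  K <- nrow(spec$haplotypes)
  L <- n_loci(spec$panel)
  groups <- rep(c("control", "patient"), spec$n)
  n <- length(groups)
  pairs <- matrix(0L, n, 2L)
  for (g in c("control", "patient")) {
    idx <- which(groups == g)
    pairs[idx, ] <- sample.int(K, 2L * length(idx), replace = TRUE,
                               prob = spec$freqs[[g]])
  }
  a1 <- spec$haplotypes[pairs[, 1], , drop = FALSE]
  a2 <- spec$haplotypes[pairs[, 2], , drop = FALSE]
  if (spec$missing_rate > 0) {
    mask <- matrix(stats::runif(n * L) < spec$missing_rate, n, L)
    a1[mask] <- NA_character_; a2[mask] <- NA_character_
  }
  ids <- sprintf("%s%03d", ifelse(groups == "control", "C", "P"),
                 stats::ave(seq_len(n), groups, FUN = seq_along))
  out <- cohort(spec$panel, ids, groups, a1, a2)
  attr(out, "true_pairs") <- pairs
  out
}

#' Expected cumulative mutation burden under a reference design
#'
#' Closed-form per-group expectation of the genotype mutation burden (the
#' sum over an individual's two haplotypes of Hamming distances to a
#' designated reference haplotype) under the spec's frequency vectors:
#' `2 * sum_i f_i * d(hap_i, reference)` per group. Used to validate
#' [burden_test()] on simulated cohorts.
#'
#' @param spec a `cohort_spec`.
#' @param reference a haplotype allele vector on the spec's panel, or the
#'   row label of a spec haplotype.
#' @return named numeric vector with elements `control` and `patient`.
#' @export
#' @examples
#' expected_burden(promoter_cohort_spec("ATG16L1"), "hap1")
expected_burden <- function(spec, reference) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.character(reference) && length(reference) == 1L &&
      reference %in% rownames(spec$haplotypes))
    reference <- spec$haplotypes[reference, ]
  if (length(reference) != n_loci(spec$panel))
    stop("reference must have one allele per panel locus")
  d <- colSums(t(spec$haplotypes) != reference)
  c(control = 2 * sum(spec$freqs$control * d),
    patient = 2 * sum(spec$freqs$patient * d))
}

#' Synthetic promoter reference fragment
#'
#' Builds a random reference sequence of the panel's amplicon length with
#' the reference allele placed at every locus offset; a stand-in for the
#' real promoter fragment when scoring transcription-factor motifs on
#' synthetic data.
#'
#' @param panel a `locus_panel`.
#' @param length fragment length; defaults to the largest offset plus 60.
#' @param seed integer seed.
#' @return single character string over A/C/G/T.
#' @export
synthetic_promoter <- function(panel, length = NULL, seed = 1L) {
  if (is.null(length)) length <- max(panel$loci$offset) + 60L
  if (length < max(panel$loci$offset))
    stop("fragment length must cover all amplicon offsets")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  s <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
  s[panel$loci$offset] <- panel$loci$ref
  paste(s, collapse = "")
}
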