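#' Pairwise Hamming distances between haplotypes
#'
#' @param haps character matrix of haplotype allele vectors (rows are
#'   haplotypes on a common panel).
#' @return symmetric integer matrix of site differences.
#' @export
#' @examples
#' hamming_matrix(atg16l1_haplotypes())
hamming_matrix <- function(haps) {
  haps <- as.matrix(haps)
  K <- nrow(haps)
  d <- matrix(0L, K, K, dimnames = list(rownames(haps), rownames(haps)))
  for (i in seq_len(K)) {
    for (j in seq_len(K)) {
      if (j > i) d[i, j] <- d[j, i] <- sum(haps[i, ] != haps[j, ])
    }
  }
  d
}

# variance components of a two-group AMOVA on 2N haplotype observations;
# dd is the (2N x 2N) matrix of squared distances between observations
.amova_components <- function(dd, group) {
  groups <- unique(group)
  if (length(groups) != 2L) stop("exactly two groups are required")
  n_g <- vapply(groups, function(g) sum(group == g), 0)
  if (any(n_g < 2)) stop("each group needs at least 2 haplotype observations")
  n_tot <- sum(n_g)
  ssd_total <- sum(dd) / (2 * n_tot)
  ssd_within <- 0
  for (g in groups) {
    sel <- group == g
    ssd_within <- ssd_within + sum(dd[sel, sel]) / (2 * sum(sel))
  }
  ssd_among <- ssd_total - ssd_within
  df_among <- 1
  df_within <- n_tot - 2
  msd_within <- ssd_within / df_within
  msd_among <- ssd_among / df_among
  n_c <- (n_tot - sum(n_g^2) / n_tot) / df_among
  sigma_a <- (msd_among - msd_within) / n_c
  sigma_w <- msd_within
  list(sigma_a = sigma_a, sigma_w = sigma_w,
       fst = sigma_a / (sigma_a + sigma_w),
       ssd_total = ssd_total, ssd_within = ssd_within,
       ssd_among = ssd_among)
}

.fst_distance <- function(x, distance) {
  K <- nrow(x$haplotypes)
  if (is.matrix(distance)) {
    if (!all(dim(distance) == K)) stop("distance matrix does not match")
    distance
  } else {
    distance <- match.arg(distance, c("identity", "hamming"))
    if (distance == "identity") {
      d <- matrix(1, K, K); diag(d) <- 0; d
    } else hamming_matrix(x$haplotypes)
  }
}

#' AMOVA-style Fst between the two groups of a phased cohort
#'
#' Decomposes the variance of the `2N` haplotype observations into
#' among-group and within-group components using sums of squared
#' inter-haplotype distances and returns
#' `Fst = sigma2_among / (sigma2_among + sigma2_within)`.
#' With the identity distance (all distinct haplotypes one unit apart)
#' this is the conventional frequency-only Fst; with the Hamming matrix
#' it is the distance-weighted PhiST built on the mean number of
#' pairwise nucleotide differences. Negative variance components are
#' reported as computed, not truncated at zero.
#'
#' @param x a `phased_cohort`.
#' @param distance `"identity"`, `"hamming"`, or a K x K matrix whose
#'   entries are treated as squared inter-haplotype distances.
#' @return list with `fst`, `sigma_a`, `sigma_w`, the SSD decomposition
#'   and a `negative_component` flag.
#' @export
amova_fst <- function(x, distance = c("identity", "hamming")) {
  stopifnot(inherits(x, "phased_cohort"))
  d2 <- .fst_distance(x, distance)
  obs_idx <- as.vector(t(x$pairs))
  comp <- .amova_components(d2[obs_idx, obs_idx, drop = FALSE],
                            rep(x$group, each = 2L))
  comp$negative_component <- comp$sigma_a < 0 || comp$sigma_w < 0
  comp
}

#' Permutation test of group differentiation by Fst
#'
#' Permutes whole individuals (keeping their two haplotypes together)
#' between the control and patient groups and recomputes [amova_fst()]
#' for each arrangement. The p-value is the proportion of arrangements,
#' the observed one included, whose statistic is at least the observed
#' one: `p = (1 + #{perm >= obs}) / (1 + n_perm)`, with standard error
#' `sqrt(p(1-p)/n_perm)`.
#'
#' @param x a `phased_cohort`.
#' @param distance as in [amova_fst()].
#' @param n_perm number of permutations (at least 100).
#' @param seed integer seed.
#' @return object of class `fst_result`.
#' @export
fst_test <- function(x, distance = c("identity", "hamming"),
                     n_perm = 10000L, seed = 1L) {
  stopifnot(inherits(x, "phased_cohort"))
  if (n_perm < 100L) stop("use at least 100 permutations")
  d2 <- .fst_distance(x, distance)
  flavor <- if (is.matrix(distance)) "custom"
            else match.arg(distance, c("identity", "hamming"))
  obs_idx <- as.vector(t(x$pairs))
  dd <- d2[obs_idx, obs_idx, drop = FALSE]
  obs <- .amova_components(dd, rep(x$group, each = 2L))$fst
  n <- length(x$group)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    pg <- x$group[sample.int(n)]
    stat <- .amova_components(dd, rep(pg, each = 2L))$fst
    if (stat >= obs - 1e-12) hits <- hits + 1L
  }
  p <- (1 + hits) / (1 + n_perm)
  structure(list(
    flavor = if (flavor == "identity") "conventional"
             else if (flavor == "hamming") "nei_distance" else flavor,
    statistic = obs, p = p, se = sqrt(p * (1 - p) / n_perm),
    n_perm = n_perm, seed = seed),
    class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("%s Fst = %.5f; permutation p = %.5f +/- %.5f (%d perms)\n",
              x$flavor, x$statistic, x$p, x$se, x$n_perm))
  invisible(x)
}
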