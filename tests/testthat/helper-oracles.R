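# Independent brute-force oracles used across the suite. These
# deliberately re-derive each quantity by enumeration or first
# principles, never by calling the code paths they check.

# ---- Hardy-Weinberg: exact distribution by counting perfect matchings
# of the 2n allele copies into n unordered pairs.
double_factorial <- function(m) {
  if (m <= 0) return(1)
  prod(seq(m, 1, by = -2))
}

oracle_hwe_p <- function(nrr, nra, naa) {
  n <- nrr + nra + naa
  nA <- 2 * nrr + nra
  na <- 2 * naa + nra
  if (nA == 0 || na == 0) return(1)
  hets <- seq(nA %% 2, min(nA, na), by = 2)
  counts <- vapply(hets, function(h) {
    choose(nA, h) * choose(na, h) * factorial(h) *
      double_factorial(nA - h - 1) * double_factorial(na - h - 1)
  }, 0)
  probs <- counts / sum(counts)
  obs <- probs[match(nra, hets)]
  sum(probs[probs <= obs + 1e-12])
}

# ---- Fisher 2x2 by direct hypergeometric enumeration.
oracle_fisher_2x2 <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- vapply(ks, function(k)
    choose(c1, k) * choose(n - c1, r1 - k) / choose(n, r1), 0)
  obs <- probs[match(tab[1, 1], ks)]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# ---- Pearson chi-square from expected counts, written out.
oracle_pearson_chi2 <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# ---- All spanning trees of a small complete graph via Pruefer
# sequences; returns the list of minimum-weight trees (edge matrices).
oracle_min_spanning_trees <- function(d) {
  n <- nrow(d)
  stopifnot(n >= 3, n <= 6)
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2)))
  decode <- function(pruefer) {
    degree <- rep(1L, n)
    for (v in pruefer) degree[v] <- degree[v] + 1L
    edges <- matrix(0L, n - 1, 2)
    for (k in seq_along(pruefer)) {
      leaf <- min(which(degree == 1L))
      edges[k, ] <- c(leaf, pruefer[k])
      degree[leaf] <- degree[leaf] - 1L
      degree[pruefer[k]] <- degree[pruefer[k]] - 1L
    }
    edges[n - 1, ] <- which(degree == 1L)
    edges
  }
  trees <- lapply(seq_len(nrow(seqs)), function(i) decode(seqs[i, ]))
  w <- vapply(trees, function(e) sum(d[e]), 0)
  trees[w <= min(w) + 1e-9]
}

canonical_edges <- function(edges) {
  e <- t(apply(edges, 1, sort))
  e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  paste(e[, 1], e[, 2], sep = "-", collapse = ";")
}

# ---- Classical frequency-based Fst from haplotype indicator variables:
# per-haplotype one-way ANOVA sums of squares (via lm), combined into
# the two-level variance components.
oracle_identity_fst <- function(hap_idx, group) {
  g <- factor(group)
  K <- max(hap_idx)
  ss_within <- 0; ss_total <- 0
  for (k in seq_len(K)) {
    x <- as.numeric(hap_idx == k)
    fit <- stats::anova(stats::lm(x ~ g))
    ss_within <- ss_within + fit["Residuals", "Sum Sq"]
    ss_total <- ss_total + sum((x - mean(x))^2)
  }
  n_g <- table(g); n_tot <- sum(n_g)
  msd_within <- ss_within / (n_tot - length(n_g))
  msd_among <- (ss_total - ss_within) / (length(n_g) - 1)
  n_c <- (n_tot - sum(n_g^2) / n_tot) / (length(n_g) - 1)
  sigma_a <- (msd_among - msd_within) / n_c
  sigma_a / (sigma_a + msd_within)
}

# ---- Observed-data log-likelihood of a phasing frequency vector, and
# its maximum over all joint phase assignments (empirical-frequency
# candidates). Haplotypes are 0/1 strings; genotype codes 0/1/2.
oracle_pair_resolutions <- function(gv) {
  het <- which(gv == 1L)
  base <- as.integer(gv == 2L)
  if (length(het) == 0L) {
    k <- paste(base, collapse = "")
    return(list(matrix(c(k, k), 1, 2)))
  }
  m <- length(het) - 1L
  out <- list()
  for (r in seq_len(2L^m)) {
    hA <- base
    if (m > 0L)
      hA[het[-1L]] <- as.integer(intToBits(r - 1L))[seq_len(m)]
    hA[het[1L]] <- 0L
    hB <- hA; hB[het] <- 1L - hA[het]
    out[[r]] <- matrix(c(paste(hA, collapse = ""),
                         paste(hB, collapse = "")), 1, 2)
  }
  out
}

oracle_loglik <- function(gmat, freqs) {
  ll <- 0
  for (i in seq_len(nrow(gmat))) {
    res <- oracle_pair_resolutions(gmat[i, ])
    tot <- 0
    for (p in res) {
      fa <- freqs[p[1]]; fb <- freqs[p[2]]
      if (is.na(fa)) fa <- 0
      if (is.na(fb)) fb <- 0
      tot <- tot + (if (p[1] == p[2]) 1 else 2) * fa * fb
    }
    ll <- ll + log(tot)
  }
  ll
}

oracle_best_phasing_loglik <- function(gmat) {
  res_by_ind <- lapply(seq_len(nrow(gmat)), function(i)
    oracle_pair_resolutions(gmat[i, ]))
  choices <- lengths(res_by_ind)
  grid <- as.matrix(expand.grid(lapply(choices, seq_len)))
  best <- -Inf
  for (r in seq_len(nrow(grid))) {
    haps <- unlist(lapply(seq_len(nrow(gmat)), function(i)
      res_by_ind[[i]][[grid[r, i]]]))
    f <- table(haps) / length(haps)
    ll <- oracle_loglik(gmat, f)
    if (ll > best) best <- ll
  }
  unname(best)
}

# genotype-code matrix of a cohort (0 hom-ref / 1 het / 2 hom-alt)
cohort_gcodes <- function(cc) {
  L <- n_loci(cc$panel)
  g <- matrix(NA_integer_, length(cc$sample_id), L)
  for (j in seq_len(L)) {
    alt <- cc$panel$loci$alt[j]
    g[, j] <- (cc$a1[, j] == alt) + (cc$a2[, j] == alt)
  }
  g
}

# small cohort built directly from explicit genotype strings
make_cohort <- function(panel, group, geno) {
  # geno: character matrix like "T/C" (individuals x loci)
  a1 <- apply(geno, 1:2, function(s) strsplit(s, "/")[[1]][1])
  a2 <- apply(geno, 1:2, function(s) strsplit(s, "/")[[1]][2])
  cohort(panel, sprintf("S%02d", seq_along(group)), group, a1, a2)
}

# two-locus toy panel used by several modules
toy_panel <- function() {
  locus_panel("toy", data.frame(
    rs_id = c("rsA", "rsB"), chrom = "1",
    position = c(100L, 200L), ref = c("A", "A"), alt = c("G", "G"),
    offset = c(10L, 20L)), c(-50L, 50L))
}
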