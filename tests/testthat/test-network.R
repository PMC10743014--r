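test_that("two haplotypes one step apart give the minimal network", {
  haps <- rbind(a = c("A", "A"), b = c("A", "G"))
  net <- median_joining(haps)
  expect_equal(nrow(net$nodes), 2)
  expect_equal(igraph::ecount(net$graph), 1)
  expect_true(all(net$nodes$observed))
  expect_length(reticulations(net), 0)
})

test_that("a 1-1-2 distance chain yields the unique path graph", {
  haps <- rbind(a = c("A", "A"), b = c("A", "G"), c = c("G", "G"))
  # unique MST: a-b, b-c (verified by spanning-tree enumeration)
  d <- hamming_matrix(haps)
  mts <- oracle_min_spanning_trees(d)
  expect_length(mts, 1)
  expect_equal(canonical_edges(mts[[1]]), "1-2;2-3")
  net <- median_joining(haps)
  expect_equal(igraph::ecount(net$graph), 2)
  expect_length(reticulations(net), 0)
  ends <- apply(igraph::ends(net$graph, igraph::E(net$graph)), 1,
                function(e) paste(sort(e), collapse = "-"))
  expect_setequal(ends, c("a-b", "b-c"))
})

test_that("epsilon-zero networks reproduce unique minimum spanning trees", {
  set.seed(71)
  tried <- 0L
  while (tried < 4L) {
    haps <- matrix(sample(c("A", "G"), 5 * 6, TRUE), 5, 6)
    rownames(haps) <- paste0("h", 1:5)
    if (anyDuplicated(apply(haps, 1, paste, collapse = ""))) next
    d <- hamming_matrix(haps)
    mts <- oracle_min_spanning_trees(d)
    if (length(mts) != 1L) next  # only unique-MST instances qualify
    tried <- tried + 1L
    net <- median_joining(haps, epsilon = 0)
    expect_true(all(net$nodes$observed))  # no median vectors
    ends <- igraph::ends(net$graph, igraph::E(net$graph))
    idx <- cbind(match(ends[, 1], rownames(haps)),
                 match(ends[, 2], rownames(haps)))
    expect_equal(canonical_edges(idx), canonical_edges(mts[[1]]))
    expect_length(reticulations(net), 0)
  }
})

test_that("all four two-site combinations form one square cycle", {
  haps <- rbind(h00 = c("A", "A"), h01 = c("A", "G"),
                h10 = c("G", "A"), h11 = c("G", "G"))
  net <- median_joining(haps)
  expect_equal(igraph::ecount(net$graph), 4)
  cyc <- reticulations(net)
  expect_length(cyc, 1)
  expect_length(cyc[[1]]$nodes, 4)
})

test_that("the seven-haplotype fixture contains the hap1-hap2-hap4-hap6 loop", {
  spec <- promoter_cohort_spec("ATG16L1")
  freq <- data.frame(control = spec$freqs$control,
                     patient = spec$freqs$patient,
                     row.names = rownames(spec$haplotypes))
  net <- median_joining(spec$haplotypes, freq = freq)
  cyc <- reticulations(net)
  expect_gte(length(cyc), 1)
  hit <- Filter(function(cy)
    setequal(cy$nodes, c("hap1", "hap2", "hap4", "hap6")), cyc)
  expect_length(hit, 1)
  # the loop alternates between the two outermost SNPs
  expect_setequal(hit[[1]]$alternating_loci,
                  c("rs1816753", "rs77820970"))
  # patient-only haplotypes carry zero control frequency on their nodes
  nd <- net$nodes
  expect_true(all(nd$control_freq[nd$label %in%
                                    paste0("hap", 4:7)] == 0))
})

test_that("duplicated haplotypes merge without changing the edge set", {
  haps <- atg16l1_haplotypes()
  dup <- rbind(haps, hap1b = haps["hap1", ])
  net1 <- median_joining(haps)
  net2 <- median_joining(dup)
  e1 <- apply(igraph::ends(net1$graph, igraph::E(net1$graph)), 1,
              function(e) paste(sort(e), collapse = "-"))
  e2 <- apply(igraph::ends(net2$graph, igraph::E(net2$graph)), 1,
              function(e) paste(sort(e), collapse = "-"))
  expect_setequal(e1, e2)
})

test_that("every edge's step count is the endpoint Hamming distance", {
  net <- median_joining(atg16l1_haplotypes())
  ends <- igraph::ends(net$graph, igraph::E(net$graph))
  for (k in seq_len(nrow(ends))) {
    d <- sum(net$haplotypes[ends[k, 1], ] != net$haplotypes[ends[k, 2], ])
    expect_equal(igraph::E(net$graph)$steps[k], d)
  }
  expect_true(igraph::is_connected(net$graph))
})

test_that("median vectors appear for a star triple and are unobserved", {
  # three haplotypes mutually two apart share an unobserved centre
  haps <- rbind(a = c("G", "A", "A"), b = c("A", "G", "A"),
                c = c("A", "A", "G"))
  net <- median_joining(haps)
  expect_equal(sum(!net$nodes$observed), 1)
  mv <- net$nodes$label[!net$nodes$observed]
  expect_equal(unname(net$haplotypes[mv, ]), c("A", "A", "A"))
  expect_length(reticulations(net), 0)
})

test_that("network export round-trips GML and writes edge lists", {
  spec <- promoter_cohort_spec("ATG16L1")
  freq <- data.frame(control = spec$freqs$control,
                     patient = spec$freqs$patient,
                     row.names = rownames(spec$haplotypes))
  net <- median_joining(spec$haplotypes, freq = freq)
  gml <- tempfile(fileext = ".gml")
  export_network(net, gml, "gml")
  back <- igraph::read_graph(gml, format = "gml")
  expect_true(igraph::isomorphic(net$graph, back))
  edg <- tempfile(fileext = ".tsv")
  export_network(net, edg, "edgelist")
  tab <- utils::read.delim(edg)
  expect_equal(nrow(tab), igraph::ecount(net$graph))
  expect_true(all(c("from", "to", "steps", "loci") %in% names(tab)))
  two <- median_joining(rbind(a = c("A", "A"), b = c("A", "G")))
  edg2 <- tempfile(fileext = ".tsv")
  export_network(two, edg2, "edgelist")
  expect_equal(nrow(utils::read.delim(edg2)), 1)
  expect_error(export_network(net, tempfile(), "png"))
})
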