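make_gra_stub <- function(grd) {
  structure(list(rho = 0.5, grd = grd,
                 ranking = names(sort(-grd))),
            class = "gra_result")
}
make_pearson_stub <- function(peaks, r) {
  ord <- order(-abs(r), peaks)
  structure(list(table = data.frame(peak = peaks[ord], r = r[ord],
                                    p = NA_real_,
                                    rank = seq_along(peaks)),
                 top = peaks[ord], n = 4L, rank_by = "abs"),
            class = "correlation_result")
}

test_that("method sets apply the three screening rules", {
  pe <- make_pearson_stub(c("p1", "p2", "p3"), c(0.9, -0.95, 0.2))
  gr <- make_gra_stub(c(p1 = 0.85, p2 = 0.7, p3 = 0.9))
  vi <- c(p1 = 1.2, p2 = 0.9, p3 = 1.0)
  ms <- method_sets(pe, gr, vi, pearson_k = 2)
  expect_equal(ms$pearson, c("p2", "p1"))
  expect_setequal(ms$gra, c("p1", "p3"))       # GRD > 0.8
  expect_setequal(ms$opls, c("p1", "p3"))      # VIP >= 1 inclusive
  expect_error(method_sets(pe, gr), "required")

  # an empty GRA survivor set propagates
  ms2 <- method_sets(pe, make_gra_stub(c(p1 = 0.1, p2 = 0.2, p3 = 0.3)),
                     vi)
  expect_length(ms2$gra, 0L)
  expect_length(intersect_sets(list(i = ms2))$sets$i, 0L)
})

test_that("three-way intersection behaves like plain set algebra", {
  ms <- list(i1 = list(pearson = c("A", "B", "C"),
                       gra = c("B", "C", "D"),
                       opls = c("C", "B")),
             i2 = list(pearson = "A", gra = "B", opls = "C"))
  tab <- intersect_sets(ms)
  expect_equal(tab$sets$i1, c("B", "C"))
  expect_length(tab$sets$i2, 0L)
  expect_error(intersect_sets(list(i = list(pearson = "A", gra = "B"))),
               "needs")
})

test_that("the published per-method top lists intersect as printed", {
  # neutrophil-count lists as printed for the Pearson and grey screens;
  # the OPLS set is the published consensus row (a superset of the
  # intersection by construction)
  ms <- list(`Neutrophils in BALF` = list(
    pearson = c("A24", "A26", "A30", "A34", "A17"),
    gra = c("A24", "A23", "A26", "A34", "A17"),
    opls = c("A24", "A26", "A30", "A34", "A17", "B11", "A11", "A27")))
  tab <- intersect_sets(ms)
  expect_true(all(c("A24", "A26", "A34", "A17") %in%
                    tab$sets[["Neutrophils in BALF"]]))
})

test_that("union-dedup counts distinct compounds with multiplicity", {
  tab <- consensus_table(list(i1 = c("A", "B"), i2 = c("B", "C"),
                              i3 = character()))
  u <- union_dedup(tab)
  expect_equal(u$peaks, c("A", "B", "C"))
  expect_equal(unname(u$multiplicity), c(1L, 2L, 1L))
  expect_equal(union_dedup(consensus_table(list(i = character())))$peaks,
               character())
})

test_that("network degrees equal indicator memberships plus one herb edge", {
  t8 <- load_fixture("table8")
  hm <- load_fixture("herb_map")
  net <- build_network(t8, hm)
  memb <- table(unlist(t8$sets, use.names = FALSE))
  for (cmp in net$centrality$peak_id)
    expect_equal(net$centrality$degree[net$centrality$peak_id == cmp],
                 unname(memb[cmp]) + 1, ignore_attr = TRUE)

  # degree is invariant to which herb a compound attaches to
  hm_alt <- data.frame(peak_id = hm$peak_id, herb = hm$herb_alt)
  net_alt <- build_network(t8, hm_alt)
  expect_equal(net_alt$centrality$degree, net$centrality$degree)

  expect_error(build_network(t8, hm[1:3, ]), "without a herb")
})

test_that("a single compound-indicator-herb path has the expected shape", {
  tab <- consensus_table(list(ind = "C1"))
  net <- build_network(tab, data.frame(peak_id = "C1", herb = "H"))
  expect_equal(igraph::vcount(net$graph), 3L)
  expect_equal(net$centrality$degree, 2L)
  expect_equal(net$centrality$betweenness, 1)   # middle of a 3-path
})

test_that("betweenness and closeness agree with the brute-force oracle", {
  t8 <- load_fixture("table8")
  hm <- load_fixture("herb_map")
  net <- build_network(t8, hm)
  el <- igraph::as_edgelist(net$graph)
  oracle <- brute_centrality(el)
  expect_equal(net$centrality$betweenness,
               unname(oracle$betweenness[net$centrality$peak_id]),
               tolerance = 1e-9)
  expect_equal(net$centrality$closeness,
               unname(oracle$closeness[net$centrality$peak_id]),
               tolerance = 1e-9)
  expect_equal(net$centrality$degree,
               unname(oracle$degree[net$centrality$peak_id]),
               ignore_attr = TRUE)

  # random bipartite-ish graphs, <= 30 nodes
  set.seed(17)
  for (i in 1:3) {
    n_c <- sample(4:8, 1)
    sets <- lapply(seq_len(sample(3:5, 1)), function(j)
      sample(sprintf("C%02d", seq_len(n_c)), sample(2:n_c, 1)))
    names(sets) <- paste0("ind", seq_along(sets))
    tab <- consensus_table(sets)
    cmp <- sort(unique(unlist(sets)))
    hm2 <- data.frame(peak_id = cmp,
                      herb = sample(c("H1", "H2"), length(cmp),
                                    replace = TRUE))
    net2 <- build_network(tab, hm2)
    o2 <- brute_centrality(igraph::as_edgelist(net2$graph))
    expect_equal(net2$centrality$betweenness,
                 unname(o2$betweenness[net2$centrality$peak_id]),
                 tolerance = 1e-9)
    expect_equal(net2$centrality$closeness,
                 unname(o2$closeness[net2$centrality$peak_id]),
                 tolerance = 1e-9)
  }
})

test_that("median filter applies the strict k-of-3 rule", {
  cent <- data.frame(peak_id = c("a", "b", "c", "d"),
                     betweenness = c(0.9, 0.5, 0.1, 0.2),
                     closeness = c(0.9, 0.8, 0.1, 0.2),
                     degree = c(5, 1, 4, 1))
  # medians: 0.35, 0.5, 2.5 -> a exceeds all three, b two, c one, d none
  expect_equal(median_filter(cent, k_of_3 = 3), "a")
  expect_equal(median_filter(cent, k_of_3 = 2), c("a", "b"))
  expect_equal(median_filter(cent, k_of_3 = 1), c("a", "b", "c"))

  # identical centralities: nothing strictly exceeds the median
  flat <- data.frame(peak_id = c("a", "b"), betweenness = 1,
                     closeness = 1, degree = 2)
  expect_length(median_filter(flat), 0L)
  expect_error(median_filter(flat, k_of_3 = 0), "k_of_3")
})

test_that("median-filter flags are monotone in the rule strictness", {
  set.seed(19)
  for (i in 1:5) {
    cent <- data.frame(peak_id = sprintf("p%02d", 1:12),
                       betweenness = runif(12),
                       closeness = runif(12),
                       degree = sample(1:6, 12, replace = TRUE))
    f1 <- median_filter(cent, 1); f2 <- median_filter(cent, 2)
    f3 <- median_filter(cent, 3)
    expect_true(all(f3 %in% f2))
    expect_true(all(f2 %in% f1))
  }
})

test_that("network exports are written in interchange formats", {
  tab <- consensus_table(list(ind = c("C1", "C2")))
  net <- build_network(tab, data.frame(peak_id = c("C1", "C2"),
                                       herb = "H"))
  g <- withr::local_tempfile(fileext = ".graphml")
  s <- withr::local_tempfile(fileext = ".sif")
  write_network_graphml(net, g)
  write_network_sif(net, s)
  expect_true(file.size(g) > 0)
  sif <- read.table(s, sep = "\t")
  expect_equal(nrow(sif), igraph::ecount(net$graph))
  expect_true(all(grepl("compound-", sif$V2)))
})
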