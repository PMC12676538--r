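# Splice-graph construction, the immediately-joint predicate, the three
# pruning rules (against the packaged example and an independent
# brute-force evaluator), and phasing-path extraction.

simple_locus <- function(frags) {
  umisplice:::new_locus(frags$chrom[1], "+", min(frags$start),
                        max(frags$end), frags)
}

test_that("single covered exon yields one vertex with mean coverage", {
  # ten unspliced 100 bp fragments tiling a 300 bp exon
  starts <- seq(0L, 200L, length.out = 10)
  f <- make_fragments("chr1", lapply(starts, function(s)
    cbind(as.integer(s), as.integer(s + 100))),
    dedup_key = sprintf("k%d", 1:10))
  G <- build_graph(simple_locus(f))
  expect_equal(nrow(G$vertices), 1)
  expect_equal(G$vertices$wv, 10 * 100 / 300, tolerance = 1e-9)
  expect_equal(G$edges$from, c(0L, 1L))
  expect_equal(G$edges$to, c(1L, 2L))
})

test_that("a zero-fragment locus is an error", {
  f <- make_fragments("chr1", cbind(0L, 10L))[0, , drop = FALSE]
  l <- umisplice:::new_locus("chr1", "+", 0L, 10L, f)
  expect_error(build_graph(l), "zero fragments")
})

test_that("junctions sharing a donor give two out-edges with per-junction counts", {
  mk <- function(n, b) {
    make_fragments("chr1", rep(list(b), n),
                   dedup_key = sprintf("%d-%d-%d", b[1, 1], b[nrow(b), 2],
                                       1:n))
  }
  f <- rbind(mk(5, rbind(c(0L, 100L), c(200L, 300L))),
             mk(3, rbind(c(0L, 100L), c(400L, 500L))),
             mk(2, cbind(200L, 300L)), mk(2, cbind(400L, 500L)))
  G <- build_graph(simple_locus(umisplice:::sort_fragments(f)))
  expect_equal(nrow(G$vertices), 3)
  j <- G$edges[G$edges$type == "junction", ]
  expect_equal(j$we[j$from == 1 & j$to == 2], 5)
  expect_equal(j$we[j$from == 1 & j$to == 3], 3)
})

test_that("UMI vertex support counts UMI fragments overlapping the vertex", {
  f <- make_fragments("chr1",
                      list(rbind(c(0L, 100L), c(200L, 300L)),
                           cbind(0L, 90L), cbind(210L, 300L)),
                      umi = c("AA", "CC", NA),
                      dedup_key = c("a", "b", "c"))
  G <- build_graph(simple_locus(f))
  expect_equal(G$vertices$wm, c(2L, 1L))
})

test_that("immediately joint means exactly abutting intervals", {
  G <- make_graph_fixture(c("vertex 1 10 20 wv=1 wm=0",
                            "vertex 2 20 35 wv=1 wm=0",
                            "vertex 3 40 50 wv=1 wm=0",
                            "edge s 1 we=1", "edge 1 2 we=1",
                            "edge 2 3 we=1", "edge 3 t we=1"))
  expect_true(immediately_joint(G, 1, 2))
  expect_false(immediately_joint(G, 2, 3))
})

test_that("the packaged example graph prunes exactly its three artifacts", {
  G <- example_graph()
  p <- ir_params()

  G1 <- prune_full_intron_retention(G, p)
  expect_equal(removed_ids(G1), 3L)

  G2 <- prune_partial_intron_retention(G1, p)
  expect_equal(removed_ids(G2, "partial_ir"), 5L)

  G3 <- prune_isolated_vertices(G2, p)
  expect_equal(removed_ids(G3, "isolated"), 7L)

  expect_setequal(G3$vertices$id, c(1L, 2L, 4L, 6L, 8L))
  # one-shot wrapper agrees
  expect_equal(removed_ids(prune_graph(G, p)), c(3L, 5L, 7L))
})

test_that("UMI support blocks full-retention removal; the lariat rule overrides", {
  G <- example_graph()
  p <- ir_params()
  # give the retention vertex UMI support above a4: kept
  G$vertices$wm[G$vertices$id == 3] <- p$a4 + 1
  G1 <- prune_full_intron_retention(G, p)
  expect_false(3L %in% removed_ids(G1))
  # but a lariat-like coverage spike removes it regardless of UMI support
  G$vertices$wv[G$vertices$id == 3] <- p$a5 * 2 + 1
  G2 <- prune_full_intron_retention(G, p)
  expect_true(3L %in% removed_ids(G2))
})

test_that("true spliced first exons are not partial retentions", {
  G <- example_graph()
  Gp <- prune_graph(G, ir_params())
  expect_true(1L %in% Gp$vertices$id)  # spliced, not immediately joint
})

test_that("isolated vertices survive at the UMI threshold", {
  G <- example_graph()
  p <- ir_params()
  G$vertices$wm[G$vertices$id == 7] <- p$single_exon_min_umi
  Gp <- prune_isolated_vertices(G, p)
  expect_false(7L %in% removed_ids(Gp))
  # a vertex adjacent to s, t and another vertex is no candidate
  expect_false(5L %in% removed_ids(prune_isolated_vertices(G, p)))
})

test_that("pruning matches the brute-force evaluator on random graphs", {
  set.seed(2024)
  p <- ir_params()
  for (i in 1:200) {
    G <- random_splice_graph()
    want <- oracle_prune_all(G, p)
    got <- prune_graph(G, p)
    expect_equal(removed_ids(got, "full_ir"), sort(want$full_ir),
                 info = sprintf("full IR, graph %d", i))
    expect_equal(removed_ids(got, "partial_ir"), sort(want$partial_ir),
                 info = sprintf("partial IR, graph %d", i))
    expect_equal(removed_ids(got, "isolated"), sort(want$isolated),
                 info = sprintf("isolated, graph %d", i))
  }
})

test_that("pruning preserves untouched weights, s/t, and acyclicity", {
  set.seed(99)
  for (i in 1:50) {
    G <- random_splice_graph()
    Gp <- prune_graph(G, ir_params())
    keep <- Gp$vertices$id
    expect_equal(Gp$vertices,
                 G$vertices[G$vertices$id %in% keep, , drop = FALSE])
    ek <- function(e) paste(e$from, e$to)
    common <- ek(Gp$edges)
    orig <- G$edges[match(common, ek(G$edges)), ]
    expect_equal(Gp$edges$we, orig$we)
    # edges still run left to right (acyclic by coordinates)
    inner <- Gp$edges$from != Gp$s & Gp$edges$to != Gp$t
    vs <- Gp$vertices$start[match(Gp$edges$to[inner], Gp$vertices$id)]
    ve <- Gp$vertices$end[match(Gp$edges$from[inner], Gp$vertices$id)]
    expect_true(all(vs >= ve))
  }
})

test_that("per-pass removal is monotone in the thresholds", {
  set.seed(123)
  for (i in 1:40) {
    G <- random_splice_graph()
    lo <- umisplice:::full_ir_candidates(G, ir_params())
    hi <- umisplice:::full_ir_candidates(
      G, ir_params(a1 = 0.5, a2 = 0.5, a3 = 0.5, a4 = 2, a5 = 3))
    expect_true(all(lo %in% hi))
    plo <- umisplice:::partial_ir_candidates(G, ir_params())
    phi <- umisplice:::partial_ir_candidates(
      G, ir_params(b1 = 0.5, b2 = 0.5, b3 = 2))
    expect_true(all(plo %in% phi))
  }
})

test_that("graph construction is independent of fragment input order", {
  set.seed(5)
  f <- make_fragments("chr1",
                      c(lapply(1:8, function(i)
                        rbind(c(i * 10L, 200L), c(400L, 400L + i * 10L))),
                        lapply(1:5, function(i) cbind(i * 20L, i * 20L + 150L))),
                      umi = c(rep("AA", 4), rep(NA, 9)),
                      dedup_key = sprintf("k%d", 1:13))
  f1 <- umisplice:::sort_fragments(f)
  l1 <- simple_locus(f1)
  G1 <- build_graph(l1)
  f2 <- umisplice:::sort_fragments(f[sample(nrow(f)), , drop = FALSE])
  G2 <- build_graph(simple_locus(f2))
  expect_equal(G1$vertices, G2$vertices)
  expect_equal(G1$edges, G2$edges)
})

test_that("phasing paths map fragments onto surviving vertices", {
  G <- example_graph()
  # fragments over the example topology
  f <- make_fragments("chr1",
                      list(rbind(c(350L, 400L), c(500L, 550L)),   # skip junction
                           rbind(c(150L, 200L), c(300L, 360L)),
                           rbind(c(150L, 200L), c(300L, 360L)),
                           cbind(320L, 380L),
                           cbind(420L, 480L)),                    # inside removed v3
                      umi = c(NA, "AA", "CC", NA, NA),
                      dedup_key = sprintf("k%d", 1:5))
  l <- umisplice:::new_locus("chr1", "+", 100L, 1100L, f)
  Gp <- prune_graph(G, ir_params())
  pp <- extract_phasing_paths(l, Gp)
  keys <- vapply(pp$path, paste, character(1), collapse = ",")
  expect_setequal(keys, c("2,4", "1,2", "2"))
  expect_equal(pp$multiplicity[keys == "1,2"], 2)
  expect_equal(pp$umi_multiplicity[keys == "1,2"], 2)
  expect_equal(pp$multiplicity[keys == "2"], 1)
})

test_that("graph fixtures round-trip through their text form", {
  G <- example_graph()
  G2 <- make_graph_fixture(dump_graph(G))
  expect_equal(G2$vertices, G$vertices)
  expect_equal(G2$edges[order(G2$edges$from, G2$edges$to), c("from", "to", "we")],
               G$edges[order(G$edges$from, G$edges$to), c("from", "to", "we")],
               ignore_attr = TRUE)
  expect_error(make_graph_fixture("edge s 1 we=1"), "no vertices")
  expect_error(make_graph_fixture(c("vertex 1 0 10 wv=1", "")), "line 1")
})
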