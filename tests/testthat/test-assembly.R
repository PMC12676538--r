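# Graph decomposition, first-exon anchoring, and the end-to-end single-cell
# pipeline.

chain_graph <- function() {
  make_graph_fixture(c("vertex 1 0 100 wv=5 wm=2",
                       "vertex 2 200 300 wv=5 wm=0",
                       "edge s 1 we=8", "edge 1 2 we=5", "edge 2 t we=9"))
}

diamond_graph <- function(top = 10, bottom = 3) {
  make_graph_fixture(c("vertex 1 0 100 wv=10 wm=3",
                       "vertex 2 200 300 wv=10 wm=0",
                       "vertex 3 400 500 wv=3 wm=0",
                       "vertex 4 600 700 wv=13 wm=0",
                       sprintf("edge s 1 we=%d", top + bottom),
                       sprintf("edge 1 2 we=%d", top),
                       sprintf("edge 1 3 we=%d", bottom),
                       sprintf("edge 2 4 we=%d", top),
                       sprintf("edge 3 4 we=%d", bottom),
                       sprintf("edge 4 t we=%d", top + bottom)))
}

path_keys <- function(cands) {
  vapply(cands$path, paste, character(1), collapse = ",")
}

test_that("a linear chain decomposes into its single bottleneck path", {
  cands <- decompose_graph(chain_graph())
  expect_equal(nrow(cands), 1)
  expect_equal(cands$path[[1]], c(1L, 2L))
  expect_equal(cands$abundance, 5)
})

test_that("parallel paths split flow by their edge weights", {
  cands <- decompose_graph(diamond_graph(10, 3))
  keys <- path_keys(cands)
  expect_setequal(keys, c("1,2,4", "1,3,4"))
  expect_equal(cands$abundance[keys == "1,2,4"], 10)
  expect_equal(cands$abundance[keys == "1,3,4"], 3)
})

test_that("phasing pairs entries and exits, excluding crossing combinations", {
  # double diamond: two entries, shared middle, two exits; phasing links
  # entry 1 with exit 1 and entry 2 with exit 2
  G <- make_graph_fixture(c("vertex 1 0 100 wv=6 wm=2",
                            "vertex 2 120 220 wv=4 wm=2",
                            "vertex 3 300 400 wv=10 wm=0",
                            "vertex 4 500 600 wv=6 wm=0",
                            "vertex 5 620 720 wv=4 wm=0",
                            "edge s 1 we=6", "edge s 2 we=4",
                            "edge 1 3 we=6", "edge 2 3 we=4",
                            "edge 3 4 we=6", "edge 3 5 we=4",
                            "edge 4 t we=6", "edge 5 t we=4"))
  phasing <- data.frame(multiplicity = c(6L, 4L),
                        umi_multiplicity = c(2L, 2L))
  phasing$path <- list(c(1L, 3L, 4L), c(2L, 3L, 5L))
  cands <- decompose_graph(G, phasing)
  expect_setequal(path_keys(cands), c("1,3,4", "2,3,5"))
})

test_that("every supported phasing path survives residual exhaustion", {
  # 5'-biased weights: downstream junction weights exceed the shared
  # upstream edge, so naive peeling would starve the second variant
  G <- make_graph_fixture(c("vertex 1 0 100 wv=6 wm=0",
                            "vertex 2 200 300 wv=10 wm=0",
                            "vertex 3 400 500 wv=8 wm=4",
                            "vertex 4 600 700 wv=9 wm=5",
                            "edge s 1 we=4", "edge 1 2 we=5",
                            "edge 2 3 we=12", "edge 2 4 we=9",
                            "edge 3 t we=12", "edge 4 t we=9"))
  phasing <- data.frame(multiplicity = c(12L, 9L),
                        umi_multiplicity = c(4L, 5L))
  phasing$path <- list(c(2L, 3L), c(2L, 4L))
  cands <- decompose_graph(G, phasing)
  keys <- path_keys(cands)
  expect_true(all(c("1,2,3", "1,2,4") %in% keys))
  expect_true(all(cands$abundance[keys %in% c("1,2,3", "1,2,4")] > 0))
})

test_that("an s-t disconnected graph decomposes to nothing, with a warning", {
  G <- chain_graph()
  G$edges <- G$edges[G$edges$type != "sink", , drop = FALSE]
  expect_warning(res <- decompose_graph(G), "no s-t path")
  expect_equal(nrow(res), 0)
})

test_that("first-exon anchoring keeps 5'-supported candidates only", {
  G <- diamond_graph()
  cands <- decompose_graph(G)
  # plus strand: vertex 1 (wm = 3) is the first exon of both paths
  kept <- anchor_first_exon(cands, G, assembly_params(first_exon_min_umi = 1))
  expect_equal(nrow(kept), 2)
  expect_equal(nrow(anchor_first_exon(
    cands, G, assembly_params(first_exon_min_umi = 4))), 0)

  # minus strand: the filter moves to the genomically last exon (wm = 0)
  expect_equal(nrow(anchor_first_exon(
    cands, G, assembly_params(first_exon_min_umi = 1), strand = "-")), 0)
  G$vertices$wm[G$vertices$id == 4] <- 2
  expect_equal(nrow(anchor_first_exon(
    cands, G, assembly_params(first_exon_min_umi = 1), strand = "-")), 2)
})

test_that("raising the anchoring threshold never adds transcripts", {
  G <- example_graph()
  cands <- decompose_graph(G)
  sizes <- vapply(0:4, function(k) nrow(anchor_first_exon(
    cands, G, assembly_params(first_exon_min_umi = k))), integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("assemble_cell recovers a clean synthetic cell exactly", {
  sim <- simulate_dataset(sim_config(seed = 11, n_loci = 6,
                                     intronic_contamination_rate = 0))
  tx <- assemble_cell(sim$sam[[1]])
  truth <- read_gtf(sim$truth_gtf)
  tk <- chain_key(truth)
  expect_true(all(stats::na.omit(tk) %in% chain_key(tx)))
  expect_equal(evaluate_assembly(tx, truth)$precision, 1.0)
  # emitted junctions all exist in the data
  ft <- sim$fragments
  for (i in which(!is.na(chain_key(tx)))) {
    e <- tx$exons[[i]]
    j <- cbind(e[-nrow(e), 2], e[-1, 1])
    for (k in seq_len(nrow(j))) {
      expect_true(any(grepl(sprintf("-%d,%d-", j[k, 1], j[k, 2]),
                            ft$blocks)))
    }
  }
})

test_that("a cell without UMI reads assembles to nothing under defaults", {
  sim <- simulate_dataset(sim_config(seed = 12, n_loci = 3,
                                     pcr_duplicate_rate = 0))
  lines <- readLines(sim$sam[[1]])
  keep <- !grepl("UB:Z:", lines, fixed = TRUE)
  path <- tempfile(fileext = ".sam")
  writeLines(lines[keep], path)
  tx <- assemble_cell(path)
  expect_equal(nrow(tx), 0)
  expect_true(length(attr(tx, "purged")) > 0)
})

test_that("repeated runs write byte-identical GTF", {
  sim <- simulate_dataset(sim_config(seed = 13, n_loci = 4))
  f1 <- tempfile(fileext = ".gtf"); f2 <- tempfile(fileext = ".gtf")
  write_gtf(assemble_cell(sim$sam[[1]]), f1)
  write_gtf(assemble_cell(sim$sam[[1]]), f2)
  expect_identical(readLines(f1), readLines(f2))
})
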