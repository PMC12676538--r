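# Meta-assembly: pooling, exon-support assignment, and the per-cell union.

test_that("pooling a single cell reproduces its single-cell assembly", {
  sim <- simulate_dataset(sim_config(seed = 21, n_loci = 4))
  meta <- meta_assemble(list(cellA = sim$sam[[1]]))
  sc <- assemble_cell(sim$sam[[1]])
  expect_identical(sort(transcript_union_key(meta$super)),
                   sort(transcript_union_key(sc)))
})

test_that("jointly covered transcripts appear only in the super-cell", {
  # split one cell's reads in half by locus position so that neither half
  # alone passes the locus UMI filter everywhere
  sim <- simulate_dataset(sim_config(seed = 22, n_loci = 1,
                                     transcripts_per_locus = c(1, 1),
                                     exons_per_transcript = c(3, 3),
                                     intronic_contamination_rate = 0,
                                     pcr_duplicate_rate = 0))
  lines <- readLines(sim$sam[[1]])
  hdr <- grepl("^@", lines)
  body <- lines[!hdr]
  qn <- sub("\t.*", "", body)
  umi_q <- unique(qn[grepl("UB:Z:", body)])
  # cell A keeps one UMI fragment (below min_umi_count), cell B the rest
  qa <- c(umi_q[1], setdiff(unique(qn), umi_q))
  a <- tempfile(fileext = ".sam"); b <- tempfile(fileext = ".sam")
  writeLines(c(lines[hdr], body[qn %in% qa]), a)
  writeLines(c(lines[hdr], body[!qn %in% qa]), b)

  scA <- assemble_cell(a); scB <- assemble_cell(b)
  res <- meta_assemble_cells(list(cellA = a, cellB = b))
  truthk <- stats::na.omit(chain_key(read_gtf(sim$truth_gtf)))
  expect_false(any(truthk %in% chain_key(scA)))
  expect_true(all(truthk %in% chain_key(res$super)))
  expect_true(all(truthk %in% chain_key(res$cells$cellA)))
})

test_that("identical alignments in different cells are not cross-deduplicated", {
  f <- make_fragments("chr1",
                      list(cbind(0L, 100L), cbind(0L, 100L)),
                      umi = c("AA", "AA"))
  meta <- meta_assemble(list(c1 = f[1, , drop = FALSE],
                             c2 = f[2, , drop = FALSE]),
                        locus_params = locus_filter_params(min_umi_count = 0,
                                                           min_umi_ratio = 0))
  pooled <- do.call(rbind, meta$cell_fragments)
  expect_equal(nrow(pooled), 2)
  expect_equal(nrow(dedup_fragments(f)), 1)  # same cell: collapsed
})

test_that("exon-support assignment respects the 30% default exactly", {
  exons <- lapply(0:9, function(i) c(i * 1000L, i * 1000L + 100L))
  tx <- umisplice:::new_transcripts(
    chrom = "chr1", strand = "+",
    exons = list(do.call(rbind, exons)), coverage = 1,
    cell_id = "x", source = "single_cell", gene_id = "g",
    transcript_id = "t")
  cover <- function(k) {
    make_fragments("chr1", lapply(seq_len(k), function(i)
      cbind(exons[[i]][1] + 10L, exons[[i]][1] + 60L)),
      dedup_key = sprintf("c%d", seq_len(k)))
  }
  expect_true(assign_transcript_to_cell(tx, cover(3)))   # 0.30 >= 0.30
  expect_false(assign_transcript_to_cell(tx, cover(2)))  # 0.20 < 0.30
  expect_true(assign_transcript_to_cell(tx, cover(2), frac = 0.2))

  single <- tx
  single$exons <- list(cbind(0L, 100L))
  expect_true(assign_transcript_to_cell(single, cover(1)))  # 1/1

  # base-resolution mode: 3 exons covered 50/100 bp each = 15% of bases
  expect_false(assign_transcript_to_cell(tx, cover(3), mode = "bases"))
  expect_true(assign_transcript_to_cell(tx, cover(3), frac = 0.15,
                                        mode = "bases"))

  # monotone in frac
  hits <- vapply(c(0.1, 0.3, 0.5, 0.9), function(fr)
    assign_transcript_to_cell(tx, cover(3), frac = fr), logical(1))
  expect_true(all(diff(hits) <= 0))
})

test_that("the union keeps single-cell records on key collisions", {
  mk <- function(exons, cov, id) {
    umisplice:::new_transcripts(chrom = "chr1", strand = "+",
                                exons = list(exons), coverage = cov,
                                cell_id = "c", source = "single_cell",
                                gene_id = "g", transcript_id = id)
  }
  sc <- rbind(mk(rbind(c(0L, 100L), c(200L, 300L)), 5, "sc1"),
              mk(cbind(1000L, 1200L), 2, "sc2"))
  # same intron chain, different terminal exon lengths: collides
  assigned <- rbind(mk(rbind(c(10L, 100L), c(200L, 280L)), 9, "m1"),
                    mk(rbind(c(5000L, 5100L), c(5200L, 5300L)), 3, "m2"))
  u <- union_transcripts(sc, assigned)
  expect_equal(nrow(u), 3)
  k <- transcript_union_key(u)
  i <- which(k == transcript_union_key(sc)[1])
  expect_equal(u$coverage[i], 5)  # single-cell version kept
  expect_equal(u$source[i], "single_cell")

  expect_equal(nrow(union_transcripts(sc[0, , drop = FALSE], assigned)), 2)
  expect_equal(nrow(union_transcripts(sc, assigned[0, , drop = FALSE])), 2)
})

test_that("meta output contains every cell's single-cell chains (5 cells)", {
  sim <- simulate_dataset(sim_config(seed = 23, n_loci = 4, n_cells = 5))
  res <- meta_assemble_cells(as.list(sim$sam))
  for (nm in names(sim$sam)) {
    sck <- transcript_union_key(assemble_cell(sim$sam[[nm]]))
    expect_true(all(sck %in% transcript_union_key(res$cells[[nm]])),
                info = nm)
  }
})

test_that("super-cell assembly ignores cell input order", {
  sim <- simulate_dataset(sim_config(seed = 24, n_loci = 3, n_cells = 3))
  r1 <- meta_assemble(as.list(sim$sam))
  r2 <- meta_assemble(as.list(rev(sim$sam)))
  expect_identical(sort(transcript_union_key(r1$super)),
                   sort(transcript_union_key(r2$super)))
})
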