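test_that("EIP formula handles canonical and degenerate counts", {
  expect_equal(computeEIP(10, 0), 1)
  expect_equal(computeEIP(0, 5), 0)
  expect_equal(computeEIP(10, 5), 0.5)
  expect_true(is.na(computeEIP(0, 0)))
  expect_error(computeEIP(-1, 2), "non-negative")
  set.seed(3)
  I <- rpois(500, 10); E <- rpois(500, 10)
  v <- computeEIP(I, E)
  expect_true(all(v[!is.na(v)] >= 0 & v[!is.na(v)] <= 1))
  expect_true(all(computeEIP(1:50, 0) == 1))
  expect_true(all(computeEIP(0, 1:50) == 0))
})

test_that("variant EIPs are mutually exclusive", {
  expect_equal(computeVariantEIP(5, 5, 0), cbind(a = 0.5, b = 0.5))
  expect_equal(computeVariantEIP(0, 0, 10), cbind(a = 0, b = 0))
  expect_equal(computeVariantEIP(6, 2, 1), cbind(a = 6 / 9, b = 2 / 9))
  expect_true(all(is.na(computeVariantEIP(0, 0, 0))))
  set.seed(4)
  Ia <- rpois(300, 5); Ib <- rpois(300, 5); E <- rpois(300, 5)
  v <- computeVariantEIP(Ia, Ib, E)
  s <- rowSums(v)
  expect_true(all(s[!is.na(s)] <= 1 + 1e-9))
  v0 <- computeVariantEIP(Ia + 1, Ib, 0)   # E = 0, Ia+Ib > 0
  expect_equal(rowSums(v0), rep(1, 300), tolerance = 1e-9)
})

test_that("detection gate is strict at the CPM boundary", {
  total <- 1e6
  jc <- JunctionCounts(I = matrix(c(0, 1, 4), 3, 1),
                       E = matrix(0, 3, 1),
                       gene = rep("g", 3), event = c("a", "b", "c"),
                       total = total)
  g <- detectionGate(jc)
  ## I=0 fails; CPM(I)=1 gives log2(2)=1, not >1, fails; CPM 4 passes
  expect_equal(as.vector(g), c(FALSE, FALSE, TRUE))
})

test_that("SJ.out.tab ingestion matches coordinates exactly", {
  ann <- data.frame(gene = "Adgrl2", event = "9", variantGroup = NA,
                    chrom = "chr3", strand = "+",
                    inc1Start = 100, inc1End = 199,
                    inc2Start = 300, inc2End = 399,
                    excStart = 100, excEnd = 399)
  f <- withr::local_tempfile()
  writeLines(c("chr3\t100\t199\t1\t1\t1\t5\t0\t30",
               "chr3\t300\t399\t1\t1\t1\t5\t0\t30",
               "chr3\t9000\t9999\t1\t1\t1\t7\t2\t30"), f)
  jc <- readSJTab(f, ann)
  expect_equal(as.vector(SummarizedExperiment::assay(jc, "I")), 10)
  expect_equal(as.vector(SummarizedExperiment::assay(jc, "E")), 0)
  side <- S4Vectors::metadata(jc)$unmatched
  expect_equal(side$start, 9000)

  empty <- withr::local_tempfile()
  writeLines(character(0), empty)
  jc0 <- readSJTab(empty, ann)
  expect_true(all(SummarizedExperiment::assay(jc0, "I") == 0))

  bad <- withr::local_tempfile()
  writeLines(c("chr3\t100\t199\t1\t1\t1\t5\t0\t30",
               "chr3\t100\t199"), bad)
  expect_error(readSJTab(bad, ann), "line 2")
})

test_that("strand-aware matching can be relaxed", {
  ann <- data.frame(gene = "g", event = "e", variantGroup = NA,
                    chrom = "chr1", strand = "-",
                    inc1Start = 10, inc1End = 20,
                    inc2Start = NA, inc2End = NA,
                    excStart = 10, excEnd = 50)
  f <- withr::local_tempfile()
  writeLines("chr1\t10\t20\t1\t1\t1\t6\t0\t30", f)  # plus-strand read
  strict <- readSJTab(f, ann)
  relaxed <- readSJTab(f, ann, ignoreStrand = TRUE)
  expect_equal(as.vector(SummarizedExperiment::assay(strict, "I")), 0)
  expect_equal(as.vector(SummarizedExperiment::assay(relaxed, "I")), 6)
})

test_that("subclass aggregation enforces the cell-count gate", {
  jc <- JunctionCounts(I = matrix(5, 1, 160), E = matrix(0, 1, 160),
                       gene = "g", event = "e",
                       subclass = rep(c("big", "small"), c(110, 50)),
                       total = rep(1e6, 160))
  expect_warning(ag <- aggregateBySubclass(jc, minCells = 100),
                 NA)
  expect_equal(colnames(eipValues(ag)), "big")
  expect_equal(unname(eipValues(ag)[1, "big"]), 1)
})

test_that("subclass EIP recovers simulated psi within 3 SE", {
  psi <- matrix(c(0.2, 0.7, 0.5, 0.95), 2, 2,
                dimnames = list(c("e1", "e2"), c("A", "B")))
  sim <- simulateJunctionReads(SplicingTruth(psi, cellsPerSubclass = 150,
                                             meanDepth = 40, seed = 13))
  gate <- detectionGate(sim$junctions)
  ag <- aggregateBySubclass(sim$junctions, minCells = 100,
                            mode = "pooled", gate = gate)
  I <- SummarizedExperiment::assay(sim$junctions, "I")
  E <- SummarizedExperiment::assay(sim$junctions, "E")
  lab <- subclassLabels(sim$junctions)
  for (s in colnames(psi)) for (ev in rownames(psi)) {
    i <- match(ev, rownames(psi))
    sI <- sum(I[i, lab == s]); sE <- sum(E[i, lab == s])
    se <- pooledEIPSE(sI, sE)
    expect_lt(abs(eipValues(ag)[i, s] - psi[i, s]), 3 * se + 1e-12)
  }
})

test_that("splicing variation partitions family variance", {
  m <- rbind("Adgrl1.7b" = c(0.5, 0.5, 0.5),
             "Adgrl2.9"  = c(0, 1, 0.5),
             "Adgrl2.14" = c(0.2, 0.8, 0.5),
             "Adgrl3.6"  = c(0.4, 0.6, 0.5))
  v <- splicingVariation(m)
  expect_equal(v$perEvent$variance[v$perEvent$event == "Adgrl1.7b"], 0)
  expect_true(all(v$perEvent$variance >= 0))
  expect_equal(sum(v$familyFraction), 1)
  ## two-point population variance: EIPs (0,1) -> 0.25
  v2 <- splicingVariation(matrix(c(0, 1), 1, 2,
                                 dimnames = list("Adgrl2.9", NULL)))
  expect_equal(v2$perEvent$variance, 0.25)
  expect_equal(unname(v2$familyFraction["Adgrl2"]), 1)
  expect_warning(
    splicingVariation(rbind(ok = c(0.1, 0.9), solo = c(0.5, NA))),
    "<2 subclasses")
})

test_that("PCA embedding is centered, unscaled and reconstructable", {
  set.seed(21)
  m <- rbind(matrix(0.9 + rnorm(12, 0, 0.02), 3),
             matrix(0.1 + rnorm(12, 0, 0.02), 3))
  rownames(m) <- paste0("s", 1:6)
  emb <- pcaEmbed(m)
  expect_true(all(diff(emb$explained) <= 1e-12))
  expect_true(all(sign(emb$scores[1:3, 1]) != sign(emb$scores[4:6, 1])))
  rec <- emb$scores %*% t(emb$loadings) +
    matrix(emb$center, 6, 4, byrow = TRUE)
  expect_lt(max(abs(rec - m)), 1e-8)
  ## largest loading of each component is positive (fixed sign)
  expect_true(all(apply(emb$loadings, 2,
                        function(l) l[which.max(abs(l))] > 0)))
  expect_error(pcaEmbed(rbind(c(1, NA), c(0, 1))), "missing")
  expect_warning(d <- pcaEmbed(matrix(0.5, 4, 3)), "degenerate")
  expect_true(d$degenerate)
})

test_that("exon coding arithmetic flags in-frame cassettes", {
  imp <- exonCodingImpact(c("ATGATG", "ATGA"))
  expect_equal(imp$length, c(6, 4))
  expect_equal(imp$divisibleBy3, c(TRUE, FALSE))
  expect_equal(imp$aminoAcids, c(2L, NA))
  expect_error(exonCodingImpact("ATGN"), "A/C/G/T")
  expect_error(exonCodingImpact(""), "non-empty")
})

test_that("packaged Adgrl2 mini-exon encodes 4 amino acids", {
  seqs <- adgrlExonSequences()
  imp <- exonCodingImpact(seqs)
  expect_equal(imp["Adgrl2_exon9", "aminoAcids"], 4L)
  ## splice-site variant pairs differ while sharing a gene
  expect_true(all(c("Adgrl2_exon11a", "Adgrl2_exon11b") %in%
                    rownames(imp)))
})
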