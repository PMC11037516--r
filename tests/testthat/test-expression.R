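# small on-disk fixture: 3 probes x 4 samples (2 subjects? no - one subject,
# days 0/7 with 2 replicates each)
write_toy_expression <- function(dir = tempfile()) {
  dir.create(dir)
  mpath <- file.path(dir, "m.tsv"); spath <- file.path(dir, "s.tsv")
  writeLines(c("probe_id\ts1\ts2\ts3\ts4",
               "p1\t4\t6\t8\t12",
               "p2\t6\t4\t10\t14",
               "p3\t5\t5\t9\t13"), mpath)
  writeLines(c("sample_id\tsubject_id\tday\treplicate",
               "s1\tA\t0\t1", "s2\tA\t0\t2",
               "s3\tA\t7\t1", "s4\tA\t7\t2"), spath)
  c(matrix = mpath, meta = spath)
}

test_that("readExpression parses a toy matrix and validates metadata", {
  p <- write_toy_expression()
  se <- readExpression(p["matrix"], p["meta"])
  expect_identical(dim(SummarizedExperiment::assay(se)), c(3L, 4L))
  expect_identical(SummarizedExperiment::colData(se)$day, c(0L, 0L, 7L, 7L))

  # metadata missing one sample column -> error naming the orphan
  short <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tsubject_id\tday\treplicate",
               "s1\tA\t0\t1", "s2\tA\t0\t2", "s3\tA\t7\t1"), short)
  expect_error(readExpression(p["matrix"], short), "s4")

  # non-positive linear intensity -> error naming the cell
  badm <- tempfile(fileext = ".tsv")
  writeLines(c("probe_id\ts1\ts2\ts3\ts4",
               "p1\t4\t6\t8\t12", "p2\t6\t-1\t10\t14", "p3\t5\t5\t9\t13"), badm)
  expect_error(readExpression(badm, p["meta"]), "p2.*s2")
})

test_that("writeExpression/readExpression round-trips simulator output value for value", {
  sim <- simulateExpression(defaultPahScenario(seed = 3))
  mpath <- tempfile(fileext = ".tsv"); spath <- tempfile(fileext = ".tsv")
  writeExpression(sim$se, mpath, spath)
  se2 <- readExpression(mpath, spath)
  a1 <- SummarizedExperiment::assay(sim$se); a2 <- SummarizedExperiment::assay(se2)
  expect_identical(dimnames(a1), dimnames(a2))
  expect_equal(a2, a1, tolerance = 1e-12)
  expect_identical(as.data.frame(SummarizedExperiment::colData(se2)),
                   as.data.frame(SummarizedExperiment::colData(sim$se)))
})

test_that("aggregation combines probes within sample, then replicates within day", {
  p <- write_toy_expression()
  se <- readExpression(p["matrix"], p["meta"])
  map <- data.frame(probe_id = c("p1", "p2"), gene_symbol = c("G", "G"))
  tbl <- suppressMessages(aggregateToGene(se, map))
  # s1: mean(4,6)=5; s2: mean(6,4)=5; day 0 = 5. s3: 9, s4: 13 -> day 7 = 11
  expect_equal(exprValues(tbl)["G", "0"], 5.0)
  expect_equal(exprValues(tbl)["G", "7"], 11.0)
  # two replicates with gene-level values 8 and 10 average to 9
  map1 <- data.frame(probe_id = "p1", gene_symbol = "H")
  tbl1 <- suppressMessages(aggregateToGene(se, map1))
  expect_equal(exprValues(tbl1)["H", "7"], mean(c(8, 12)))
  # median probe method
  map3 <- data.frame(probe_id = c("p1", "p2", "p3"), gene_symbol = "G")
  tblm <- aggregateToGene(se, map3, probeMethod = "median")
  expect_equal(exprValues(tblm)["G", "0"], mean(c(5, 5)))
  # unmapped probes dropped with a message; disjoint map is an error
  expect_message(aggregateToGene(se, map), "1 unmapped probe")
  expect_error(aggregateToGene(se, data.frame(probe_id = "q9",
                                              gene_symbol = "G")),
               "no probe")
})

test_that("log2-scale input is linearized before aggregation", {
  x <- matrix(c(2, 4, 3, 5), 1, 4,
              dimnames = list("p1", c("s1", "s2", "s3", "s4")))
  meta <- data.frame(sample_id = paste0("s", 1:4), subject_id = "A",
                     day = c(0, 0, 7, 7), replicate = c(1, 2, 1, 2))
  se <- makeExpressionSE(x, meta, scale = "log2")
  tbl <- aggregateToGene(se, data.frame(probe_id = "p1", gene_symbol = "G"))
  expect_equal(exprValues(tbl)["G", "0"], mean(c(4, 16)))
  expect_equal(exprValues(tbl)["G", "7"], mean(c(8, 32)))
})

test_that("fold changes follow the ratio and signed conventions", {
  v <- matrix(c(2, 4, 1, 6, 10, 2.5), 3, 2,
              dimnames = list(c("G1", "G2", "G3"), c("0", "7")))
  tbl <- new("GeneExpressionTable", values = v, days = c(0, 7),
             probeMethod = "mean")
  fc <- computeFoldChange(tbl)
  expect_equal(fcValues(fc)["G1", "7"], 3.0)     # 6/2
  expect_equal(fcValues(fc)["G2", "7"], 2.5)     # 10/4
  expect_equal(fcValues(fc)["G3", "7"], 2.5)
  sg <- computeFoldChange(tbl, convention = "signed")
  expect_equal(fcValues(sg)["G1", "7"], 3.0)     # unchanged when r >= 1

  v2 <- matrix(c(8, 4, 2, 4), 2, 2, dimnames = list(c("G1", "G2"), c("0", "7")))
  tbl2 <- new("GeneExpressionTable", values = v2, days = c(0, 7),
              probeMethod = "mean")
  sg2 <- computeFoldChange(tbl2, convention = "signed")
  expect_equal(fcValues(sg2)["G1", "7"], -4.0)   # ratio 0.25 -> -1/0.25
  expect_equal(fcValues(sg2)["G2", "7"], 1.0)    # no change -> 1 either way

  expect_error(computeFoldChange(tbl, baselineDay = 21), "baseline day 21")
  expect_error(computeFoldChange(tbl, epsilon = 0), "epsilon")
})

test_that("fold change is scale-invariant and aggregation order-invariant", {
  sim <- simulateExpression(defaultPahScenario(seed = 11))
  fc1 <- computeFoldChange(suppressMessages(aggregateToGene(sim$se, sim$map)))
  se_scaled <- sim$se
  SummarizedExperiment::assay(se_scaled) <-
    SummarizedExperiment::assay(sim$se) * 37.5
  fc2 <- computeFoldChange(suppressMessages(aggregateToGene(se_scaled, sim$map)))
  expect_equal(fcValues(fc2), fcValues(fc1), tolerance = 1e-12)

  set.seed(1)
  perm_r <- sample(nrow(sim$se)); perm_c <- sample(ncol(sim$se))
  se_perm <- sim$se[perm_r, perm_c]
  fc3 <- computeFoldChange(suppressMessages(aggregateToGene(se_perm, sim$map)))
  expect_equal(fcValues(fc3)[rownames(fcValues(fc1)), ], fcValues(fc1),
               tolerance = 1e-12)
})

test_that("signed and ratio conventions are mutual inverses", {
  set.seed(42)
  r <- matrix(exp(rnorm(40)), 20, 2, dimnames = list(sprintf("G%02d", 1:20),
                                                     c("7", "21")))
  fc <- foldChangeTable(r, "ratio")
  back <- convertConvention(convertConvention(fc, "signed"), "ratio")
  expect_equal(fcValues(back), fcValues(fc), tolerance = 1e-15)
  sg <- fcValues(convertConvention(fc, "signed"))
  expect_true(all(abs(sg) >= 1 | sg == 1))
})

test_that("fold-change TSV round-trips with its convention", {
  sim <- simulateExpression(defaultPahScenario(seed = 5))
  fc <- computeFoldChange(suppressMessages(aggregateToGene(sim$se, sim$map)),
                          convention = "signed")
  path <- tempfile(fileext = ".tsv")
  writeFoldChange(fc, path)
  fc2 <- readFoldChange(path)
  expect_identical(fcConvention(fc2), "signed")
  expect_equal(fcValues(fc2), fcValues(fc), tolerance = 1e-9)
})
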