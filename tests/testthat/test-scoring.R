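test_that("scoreDrug computes the alignment-weighted mean with audit trail", {
  kb <- loadKnowledgeBase(write_kb_tsv(c(
    "D\tother\tA\ta\tinhibitor\tpathological\tr",   # m = +1
    "D\tother\tB\tb\tinducer\tpathological\tr",     # m = -1
    "D\tother\tC\tc\tinhibitor\tpathological\tr"))) # m = +1
  fc <- foldChangeTable(matrix(c(3, 2, 1), 3, 1, dimnames = list(c("A", "B", "C"), "7")))
  ds <- scoreDrug(kb, fc, "D", 7)
  expect_equal(ds@score, (3 - 2 + 1) / 3, tolerance = 1e-12)  # 0.6667
  expect_identical(ds@n, 3L)
  expect_equal(ds@contributions$contribution,
               ds@contributions$m * ds@contributions$f)
  expect_equal(ds@score, oracle_score(kb, fc, "D", 7), tolerance = 1e-12)

  # all fold changes 1 with all m = +1 -> mean of ones
  fc1 <- foldChangeTable(matrix(1, 3, 1, dimnames = list(c("A", "B", "C"), "7")))
  kb1 <- loadKnowledgeBase(write_kb_tsv(c(
    "D\tother\tA\ta\tinhibitor\tpathological\tr",
    "D\tother\tB\tb\tinhibitor\tpathological\tr",
    "D\tother\tC\tc\tinhibitor\tpathological\tr")))
  expect_equal(scoreDrug(kb1, fc1, "D", 7)@score, 1.0)

  # single gene, m = -1, f = 2 -> -2
  kbneg <- loadKnowledgeBase(write_kb_tsv("D\tother\tA\ta\tinducer\tpathological\tr"))
  fcneg <- foldChangeTable(matrix(2, 1, 1, dimnames = list("A", "7")))
  expect_equal(scoreDrug(kbneg, fcneg, "D", 7)@score, -2.0)
})

test_that("scoring errors are explicit: unknown day, n = 0 never a silent zero", {
  kb <- tiny_kb()
  fc <- foldChangeTable(matrix(2, 1, 1, dimnames = list("G1", "7")))
  expect_error(scoreDrug(kb, fc, "DrugA", 21), "day 21")
  # DrugB's genes (G2, G4) have no data at day 7
  expect_error(scoreDrug(kb, fc, "DrugB", 7), "n = 0")
})

test_that("n counts only genes with available data", {
  kb <- tiny_kb()  # DrugA affects G1, G2, G3
  f <- matrix(c(2, NA, 4), 3, 1, dimnames = list(c("G1", "G2", "G3"), "7"))
  ds <- scoreDrug(kb, foldChangeTable(f), "DrugA", 7)
  expect_identical(ds@n, 2L)
  expect_identical(ds@contributions$gene, c("G1", "G3"))
  # G1 inhibitor/pathological (+1)*2; G3 inducer/compensatory (+1)*4
  expect_equal(ds@score, 3.0, tolerance = 1e-12)
})

test_that("scoreDrug matches the brute-force oracle on random instances", {
  for (seed in 1:150) {
    inst <- random_instance(seed)
    day <- sample(fcDays(inst$fc), 1L)
    for (drug in kbDrugNames(inst$kb)) {
      expected <- oracle_score(inst$kb, inst$fc, drug, day)
      if (is.na(expected)) {
        expect_error(scoreDrug(inst$kb, inst$fc, drug, day), "n = 0")
      } else {
        ds <- scoreDrug(inst$kb, inst$fc, drug, day)
        expect_equal(ds@score, expected, tolerance = 1e-12)
        expect_lte(ds@n, sum(kbInteractions(inst$kb)$drug == drug))
      }
    }
  }
})

test_that("scores are linear in fold change, order-invariant, and bounded by extremes", {
  inst <- random_instance(999)
  kb <- inst$kb; fc <- inst$fc
  for (drug in kbDrugNames(kb)) {
    ds <- tryCatch(scoreDrug(kb, fc, drug, 7), error = function(e) NULL)
    if (is.null(ds)) next
    # linearity: scaling every fold change by c scales S by c
    fc_scaled <- foldChangeTable(fcValues(fc) * 2.5)
    expect_equal(scoreDrug(kb, fc_scaled, drug, 7)@score, 2.5 * ds@score,
                 tolerance = 1e-12)
    # permutation invariance in gene order
    perm <- sample(nrow(fcValues(fc)))
    fc_perm <- foldChangeTable(fcValues(fc)[perm, , drop = FALSE])
    expect_equal(scoreDrug(kb, fc_perm, drug, 7)@score, ds@score,
                 tolerance = 1e-12)
    # bounds by extreme aligned contributions
    expect_gte(ds@score, min(ds@contributions$contribution) - 1e-12)
    expect_lte(ds@score, max(ds@contributions$contribution) + 1e-12)
  }
})

test_that("scoreMatrix isolates missingness and reduces to scoreDrug", {
  kb <- defaultKnowledgeBase()
  sim <- simulateExpression(defaultPahScenario(seed = 2))
  fc <- computeFoldChange(suppressMessages(aggregateToGene(sim$se, sim$map)))
  sm <- scoreMatrix(kb, fc)
  expect_identical(dim(scoreValues(sm)), c(6L, 4L))
  expect_false(anyNA(scoreValues(sm)))

  # drop every macitentan gene: its row is missing, the others intact
  maci <- interactionsForDrug(kb, "Macitentan")$gene
  keep <- setdiff(rownames(fcValues(fc)), maci)
  fc2 <- foldChangeTable(fcValues(fc)[keep, ], baselineDay = 0)
  expect_warning(sm2 <- scoreMatrix(kb, fc2), "Macitentan")
  expect_true(all(is.na(scoreValues(sm2)["Macitentan", ])))
  expect_false(anyNA(scoreValues(sm2)[setdiff(rownames(scoreValues(sm2)),
                                              "Macitentan"), ]))
  expect_true(all(scoreN(sm2)["Macitentan", ] == 0L))

  sm1 <- scoreMatrix(kb, fc, drugs = "Bosentan", days = 21)
  expect_identical(dim(scoreValues(sm1)), c(1L, 1L))
  expect_equal(scoreValues(sm1)[1, 1], scoreDrug(kb, fc, "Bosentan", 21)@score)

  expect_error(scoreMatrix(kb, fc, drugs = character(0)), "empty drug")
  expect_error(scoreMatrix(kb, fc, days = numeric(0)), "empty day")
})

test_that("ranking sorts by descending score with alphabetical ties and lists excluded drugs", {
  ref <- referenceScoreMatrix()
  r180 <- rankDrugs(ref, 180)
  expect_identical(r180$drug, c("Sildenafil", "Ambrisentan", "Bosentan",
                                "Macitentan", "Treprostinil", "Iloprost"))
  expect_equal(r180$score, c(19.30, 9.25, 4.78, 1.58, 1.27, 0.68))
  expect_true(all(diff(r180$score) <= 0))
  expect_setequal(r180$drug, scoreDrugs(ref))  # a permutation of scored drugs

  tie <- new("ScoreMatrix",
             scores = matrix(c(1, 2, 2), 3, 1,
                             dimnames = list(c("Zeta", "Beta", "Alpha"), "7")),
             n = matrix(1L, 3, 1), days = 7)
  expect_identical(rankDrugs(tie, 7)$drug, c("Alpha", "Beta", "Zeta"))

  one <- new("ScoreMatrix",
             scores = matrix(c(1, NA), 2, 1,
                             dimnames = list(c("Only", "NoData"), "7")),
             n = matrix(c(1L, 0L), 2, 1), days = 7)
  rk <- rankDrugs(one, 7)
  expect_identical(rk$drug, "Only")
  expect_identical(attr(rk, "excluded"), "NoData")
  expect_error(rankDrugs(one, 21), "day 21")
})

test_that("score matrix TSV round-trips, with optional presentation rounding", {
  kb <- defaultKnowledgeBase()
  sim <- simulateExpression(defaultPahScenario(seed = 4))
  fc <- computeFoldChange(suppressMessages(aggregateToGene(sim$se, sim$map)))
  sm <- scoreMatrix(kb, fc)
  path <- tempfile(fileext = ".tsv")
  writeScoreMatrix(sm, path, kb = kb)
  sm2 <- readScoreMatrix(path)
  expect_equal(scoreValues(sm2), scoreValues(sm), tolerance = 1e-9)
  writeScoreMatrix(sm, path, round = 2)
  sm3 <- readScoreMatrix(path)
  expect_equal(scoreValues(sm3), round(scoreValues(sm), 2), tolerance = 1e-12)
})
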