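# Programmatic fixtures: tiny knowledge bases, random problem instances and
# the brute-force scoring oracle used for cross-checks.

kb_header <- "drug\tdrug_class\tgene_symbol\tgene_name\tmechanism\tpathology_role\trefs"

write_kb_tsv <- function(rows, path = tempfile(fileext = ".tsv")) {
  writeLines(c(kb_header, rows), path)
  path
}

# three drugs / four genes, one compensatory gene, one inducer edge
tiny_kb <- function() {
  loadKnowledgeBase(write_kb_tsv(c(
    "DrugA\tera\tG1\tgene one\tinhibitor\tpathological\tr1",
    "DrugA\tera\tG2\tgene two\tinhibitor\tpathological\tr1",
    "DrugA\tera\tG3\tgene three\tinducer\tcompensatory\tr2",
    "DrugB\tprostacyclin\tG2\tgene two\tinducer\tpathological\tr3",
    "DrugB\tprostacyclin\tG4\tgene four\tinhibitor\tcompensatory\tr3",
    "DrugC\tpde5_inhibitor\tG1\tgene one\tinhibitor\tpathological\tr4")))
}

# random KB (<= 10 drugs, <= 20 genes) + random ratio fold-change table with
# missing entries; built directly so thousands of instances stay cheap
random_instance <- function(seed) {
  set.seed(seed)
  n_genes <- sample(2:20, 1L)
  n_drugs <- sample(1:10, 1L)
  gsym <- sprintf("G%02d", seq_len(n_genes))
  genes <- data.frame(
    symbol = gsym, name = gsym,
    pathology_role = sample(c("pathological", "compensatory"), n_genes, TRUE),
    refs = "x", stringsAsFactors = FALSE)
  drugs <- data.frame(
    name = sprintf("drug%02d", seq_len(n_drugs)),
    drug_class = sample(c("era", "pde5_inhibitor", "prostacyclin", "other"),
                        n_drugs, TRUE),
    stringsAsFactors = FALSE)
  inter <- do.call(rbind, lapply(seq_len(n_drugs), function(i) {
    gs <- sample(gsym, sample.int(n_genes, 1L))
    data.frame(drug = drugs$name[i], gene = sort(gs),
               mechanism = sample(c("inhibitor", "inducer"), length(gs), TRUE),
               refs = "x", stringsAsFactors = FALSE)
  }))
  kb <- new("DrugGeneKB", genes = genes, drugs = drugs, interactions = inter)
  days <- c(7, 21)
  f <- matrix(exp(rnorm(n_genes * length(days))), n_genes,
              dimnames = list(gsym, as.character(days)))
  f[sample.int(length(f), floor(length(f) * 0.2))] <- NA
  list(kb = kb, fc = foldChangeTable(f, convention = "ratio"))
}

# independent scoring oracle: plain loop, alignment rule restated from the
# definition rather than calling deriveAlignment(); NA when no gene has data
oracle_score <- function(kb, fc, drug, day) {
  inter <- kbInteractions(kb)
  genes <- kbGenes(kb)
  fv <- fcValues(fc)
  tot <- 0; n <- 0L
  for (r in which(inter$drug == drug)) {
    g <- inter$gene[r]
    role <- genes$pathology_role[genes$symbol == g]
    counteracts <- (inter$mechanism[r] == "inhibitor") == (role == "pathological")
    m <- if (counteracts) 1 else -1
    f <- if (g %in% rownames(fv)) fv[g, as.character(day)] else NA_real_
    if (!is.na(f)) { tot <- tot + m * f; n <- n + 1L }
  }
  if (n == 0L) NA_real_ else tot / n
}

# expected regimen of the packaged reference score table
reference_regimen <- data.frame(
  day = rep(c(7, 21, 60, 180), each = 3),
  drug_class = rep(c("prostacyclin", "pde5_inhibitor", "era"), 4),
  drug = c("Treprostinil", "Sildenafil", "Macitentan",
           "Treprostinil", "Sildenafil", "Macitentan",
           "Iloprost", "Sildenafil", "Ambrisentan",
           "Treprostinil", "Sildenafil", "Ambrisentan"),
  stringsAsFactors = FALSE)
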