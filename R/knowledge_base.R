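## Knowledge-base module: load/validate/query the drug-gene interaction KB
## and derive +/-1 alignment factors.

.KB_COLS <- c("drug", "drug_class", "gene_symbol", "gene_name", "mechanism",
              "pathology_role", "refs")

.read_tsv <- function(path, what = "file") {
  if (!file.exists(path)) stop(sprintf("%s not found: %s", what, path), call. = FALSE)
  utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    quote = "", stringsAsFactors = FALSE, check.names = FALSE)
}

#' Load a drug-gene interaction knowledge base from TSV
#'
#' Reads a tab-separated knowledge-base file (UTF-8, header required, lines
#' starting with `#` ignored) with columns `drug`, `drug_class`,
#' `gene_symbol`, `gene_name`, `mechanism`, `pathology_role`, `refs` (a
#' semicolon-joined citation list), one row per drug-gene interaction, and
#' assembles a validated [DrugGeneKB-class].
#'
#' Row-level problems are: an unknown mechanism, pathology role or drug
#' class; an empty drug name or gene symbol; a duplicated (drug, gene) pair;
#' a gene whose role or a drug whose class conflicts with an earlier row.
#' With `strict = TRUE` (default) any such row aborts the load; with
#' `strict = FALSE` offending rows are dropped with a warning stating the
#' count.
#'
#' @param path path to the TSV file.
#' @param strict abort on any invalid row (default) instead of dropping it.
#' @return A [DrugGeneKB-class].
#' @examples
#' kb <- defaultKnowledgeBase()
#' kb
#' @seealso [defaultKnowledgeBase()], [writeKnowledgeBase()],
#'   [interactionsForDrug()]
#' @export
loadKnowledgeBase <- function(path, strict = TRUE) {
  df <- .read_tsv(path, "knowledge-base file")
  miss <- setdiff(.KB_COLS, colnames(df))
  if (length(miss))
    stop(sprintf("knowledge-base file %s is missing column(s): %s",
                 path, paste(miss, collapse = ", ")), call. = FALSE)
  df <- df[, .KB_COLS]
  for (cc in .KB_COLS) df[[cc]] <- trimws(as.character(df[[cc]]))
  df$mechanism <- tolower(df$mechanism)
  df$pathology_role <- tolower(df$pathology_role)
  df$drug_class <- tolower(df$drug_class)
  df$gene_symbol <- toupper(df$gene_symbol)

  bad <- !nzchar(df$drug) | !nzchar(df$gene_symbol) |
    !(df$mechanism %in% .MECHANISMS) |
    !(df$pathology_role %in% .ROLES) |
    !(df$drug_class %in% .DRUG_CLASSES) |
    duplicated(df[, c("drug", "gene_symbol")])
  ## a gene symbol must carry one role; a drug one class — later conflicting
  ## rows are offenders
  role1 <- tapply(df$pathology_role, df$gene_symbol, `[`, 1L)
  class1 <- tapply(df$drug_class, df$drug, `[`, 1L)
  bad <- bad | df$pathology_role != role1[df$gene_symbol] |
    df$drug_class != class1[df$drug]
  if (any(bad)) {
    if (strict)
      stop(sprintf("knowledge-base file %s: %d invalid row(s) (first at data row %d); use strict = FALSE to drop them",
                   path, sum(bad), which(bad)[1L]), call. = FALSE)
    warning(sprintf("dropped %d invalid knowledge-base row(s)", sum(bad)),
            call. = FALSE)
    df <- df[!bad, , drop = FALSE]
  }
  if (nrow(df) == 0L)
    warning("knowledge base contains no interactions", call. = FALSE)

  genes <- unique(df[, c("gene_symbol", "gene_name", "pathology_role")])
  genes <- genes[!duplicated(genes$gene_symbol), , drop = FALSE]
  gene_refs <- vapply(split(df$refs, df$gene_symbol), function(r)
    paste(sort(unique(unlist(strsplit(r, ";", fixed = TRUE)))), collapse = ";"), "")
  genes <- data.frame(symbol = genes$gene_symbol, name = genes$gene_name,
                      pathology_role = genes$pathology_role,
                      refs = unname(gene_refs[genes$gene_symbol]),
                      stringsAsFactors = FALSE)
  genes <- genes[order(genes$symbol), , drop = FALSE]
  drugs <- unique(df[, c("drug", "drug_class")])
  drugs <- data.frame(name = drugs$drug, drug_class = drugs$drug_class,
                      stringsAsFactors = FALSE)
  drugs <- drugs[order(drugs$name), , drop = FALSE]
  inter <- data.frame(drug = df$drug, gene = df$gene_symbol,
                      mechanism = df$mechanism, refs = df$refs,
                      stringsAsFactors = FALSE)
  inter <- inter[order(inter$drug, inter$gene), , drop = FALSE]
  rownames(genes) <- rownames(drugs) <- rownames(inter) <- NULL
  new("DrugGeneKB", genes = genes, drugs = drugs, interactions = inter)
}

#' The packaged PAH knowledge base
#'
#' Loads the knowledge base distributed with the package: 65 curated
#' interactions between six approved PAH drugs (ambrisentan, bosentan,
#' macitentan: endothelin receptor antagonists; sildenafil: PDE5 inhibitor;
#' iloprost, treprostinil: prostacyclins) and 34 PAH-relevant genes.
#'
#' The `pathology_role` column is a curation default, not an experimental
#' fact: every gene is annotated `pathological` except prostaglandin I2
#' synthase (PGIS), an explicitly compensatory enzyme, and the genes the
#' packaged drugs induce as a beneficial response (NOS3, ID1, PPARA, PPARD,
#' PPARG), which are annotated `compensatory`. Users who disagree can edit
#' the TSV — the role column is ordinary input, and changing a role flips
#' the sign of every alignment factor involving that gene.
#'
#' @return A [DrugGeneKB-class].
#' @export
defaultKnowledgeBase <- function() {
  loadKnowledgeBase(system.file("extdata", "pah_kb.tsv", package = "pahscore",
                                mustWork = TRUE))
}

#' Write a knowledge base to TSV
#'
#' Serializes a [DrugGeneKB-class] back to the one-row-per-interaction TSV
#' format read by [loadKnowledgeBase()]. Loading the written file yields a
#' knowledge base with identical gene, drug and interaction sets, except
#' that per-gene reference lists are pooled across that gene's rows.
#'
#' @param kb a [DrugGeneKB-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeKnowledgeBase <- function(kb, path) {
  stopifnot(is(kb, "DrugGeneKB"))
  i <- kb@interactions
  g <- kb@genes[match(i$gene, kb@genes$symbol), ]
  d <- kb@drugs[match(i$drug, kb@drugs$name), ]
  out <- data.frame(drug = i$drug, drug_class = d$drug_class,
                    gene_symbol = i$gene, gene_name = g$name,
                    mechanism = i$mechanism, pathology_role = g$pathology_role,
                    refs = i$refs, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Derive the alignment factor of a drug-gene interaction
#'
#' The alignment factor m encodes whether a drug's effect on a gene works
#' against the expression change expected in disease. It is +1 when the
#' interaction counteracts pathological gene expression (inhibiting a
#' pathological gene) or supports a compensatory response (inducing a
#' compensatory gene), and -1 when the interaction follows pathology
#' (inducing a pathological gene) or suppresses a compensatory gene
#' (inhibiting it, e.g. inhibiting prostaglandin I2 synthase).
#'
#' | mechanism  | pathological | compensatory |
#' |------------|:---:|:---:|
#' | inhibitor  | +1  | -1  |
#' | inducer    | -1  | +1  |
#'
#' @param mechanism character vector, each "inhibitor" or "inducer".
#' @param pathology_role character vector, each "pathological" or
#'   "compensatory"; recycled against `mechanism`.
#' @return Integer vector of +1/-1 alignment factors.
#' @examples
#' deriveAlignment("inhibitor", "pathological")  # +1
#' deriveAlignment("inhibitor", "compensatory")  # -1
#' @export
deriveAlignment <- function(mechanism, pathology_role) {
  if (!all(mechanism %in% .MECHANISMS))
    stop(sprintf("mechanism must be one of: %s",
                 paste(.MECHANISMS, collapse = ", ")), call. = FALSE)
  if (!all(pathology_role %in% .ROLES))
    stop(sprintf("pathology_role must be one of: %s",
                 paste(.ROLES, collapse = ", ")), call. = FALSE)
  ifelse(xor(mechanism == "inhibitor", pathology_role == "pathological"),
         -1L, 1L)
}

#' List a drug's interactions with derived alignment factors
#'
#' @param kb a [DrugGeneKB-class].
#' @param drug a drug name present in `kb`.
#' @return data.frame with one row per interaction of the drug, ordered by
#'   gene symbol: columns `drug`, `gene`, `mechanism`, `pathology_role`,
#'   `alignment` (+1/-1), `refs`. Zero rows if the drug has no interactions.
#' @examples
#' kb <- defaultKnowledgeBase()
#' interactionsForDrug(kb, "Ambrisentan")
#' @export
interactionsForDrug <- function(kb, drug) {
  stopifnot(is(kb, "DrugGeneKB"), is.character(drug), length(drug) == 1L)
  if (!drug %in% kb@drugs$name)
    stop(sprintf("unknown drug '%s'; knowledge base contains: %s", drug,
                 paste(kb@drugs$name, collapse = ", ")), call. = FALSE)
  i <- kb@interactions[kb@interactions$drug == drug, , drop = FALSE]
  i <- i[order(i$gene), , drop = FALSE]
  role <- kb@genes$pathology_role[match(i$gene, kb@genes$symbol)]
  out <- data.frame(drug = i$drug, gene = i$gene, mechanism = i$mechanism,
                    pathology_role = role,
                    alignment = if (nrow(i)) deriveAlignment(i$mechanism, role)
                                else integer(0),
                    refs = i$refs, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' @rdname accessors
setMethod("kbGenes", "DrugGeneKB", function(x) x@genes)
#' @rdname accessors
setMethod("kbDrugs", "DrugGeneKB", function(x) x@drugs)
#' @rdname accessors
setMethod("kbInteractions", "DrugGeneKB", function(x) x@interactions)
#' @rdname accessors
setMethod("kbDrugNames", "DrugGeneKB", function(x) x@drugs$name)

setMethod("show", "DrugGeneKB", function(object) {
  cat(sprintf("DrugGeneKB: %d drugs, %d genes, %d interactions\n",
              nrow(object@drugs), nrow(object@genes),
              nrow(object@interactions)))
  n <- table(factor(object@interactions$drug, levels = object@drugs$name))
  for (d in object@drugs$name)
    cat(sprintf("  %-14s %-15s %2d gene(s)\n", d,
                object@drugs$drug_class[object@drugs$name == d], n[[d]]))
})
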