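# Mutation catalogs: parsing, frequencies, seed genes, residue profiles.

#' Construct a mutation catalog from a data frame
#'
#' A catalog holds per-sample point-mutation records for one cohort. Protein
#' changes are short protein-HGVS strings such as `"R130Q"` or `"R130*"`
#' (an optional `"p."` prefix is stripped). Gene symbols are uppercased and
#' whitespace-stripped; no alias resolution is attempted.
#'
#' @param records data frame with columns `sample_id`, `gene`,
#'   `protein_change` and optionally `phenotype` and `pathogenicity`.
#' @param cohort_name label for the cohort.
#' @param point_only drop records whose `protein_change` does not parse as a
#'   single amino-acid substitution or nonsense change.
#' @return an object of class `mutation_catalog`: the cleaned record table
#'   plus derived unique-mutation and mutated-gene sets and a parse report.
#' @export
mutation_catalog <- function(records, cohort_name, point_only = TRUE) {
  stopifnot(is.data.frame(records))
  need <- c("sample_id", "gene", "protein_change")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0)
    stop_cohortnet(paste0("missing mandatory column(s): ",
                          paste(miss, collapse = ", ")),
                   "cohortnet_config_error")
  if (nrow(records) == 0)
    stop_cohortnet(paste0("empty catalog for cohort '", cohort_name, "'"),
                   "cohortnet_empty_catalog")
  rec <- records
  rec$sample_id <- as.character(rec$sample_id)
  rec$gene <- toupper(gsub("\\s+", "", as.character(rec$gene)))
  rec$protein_change <- sub("^p\\.", "", trimws(as.character(rec$protein_change)))
  if (!"phenotype" %in% names(rec)) rec$phenotype <- NA_character_
  if (!"pathogenicity" %in% names(rec)) rec$pathogenicity <- NA_real_
  rec$pathogenicity <- as.numeric(rec$pathogenicity)
  bad_path <- !is.na(rec$pathogenicity) &
    (rec$pathogenicity < 0 | rec$pathogenicity > 1)
  if (any(bad_path))
    stop_cohortnet("pathogenicity scores must lie in [0, 1]",
                   "cohortnet_config_error")

  ok <- is_point_change(rec$protein_change)
  n_dropped <- 0L
  if (point_only) {
    n_dropped <- sum(!ok)
    rec <- rec[ok, , drop = FALSE]
    if (nrow(rec) == 0)
      stop_cohortnet(paste0("no parseable point mutations in cohort '",
                            cohort_name, "'"),
                     "cohortnet_empty_catalog")
  }
  dup <- duplicated(rec[, c("sample_id", "gene", "protein_change")])
  n_dup <- sum(dup)
  rec <- rec[!dup, , drop = FALSE]
  rownames(rec) <- NULL

  structure(list(
    cohort_name = cohort_name,
    records = rec,
    unique_mutations = unique(paste(rec$gene, rec$protein_change, sep = ":")),
    mutated_genes = sort(unique(rec$gene)),
    parse_report = list(n_input = nrow(records), n_kept = nrow(rec),
                        n_dropped_nonpoint = n_dropped,
                        n_collapsed_duplicates = n_dup,
                        point_only = point_only)
  ), class = "mutation_catalog")
}

# grammar for a single amino-acid substitution or nonsense change
is_point_change <- function(x) grepl("^[A-Z][0-9]+([A-Z]|\\*)$", x)

#' Parse a tabular mutation catalog file
#'
#' Reads a TSV of per-sample mutations into a [mutation_catalog()]. Column
#' names are configurable so MAF-like exports and driver-catalog tables can
#' be consumed directly; `columns = "maf"` is a preset mapping
#' `Tumor_Sample_Barcode`/`Hugo_Symbol`/`HGVSp_Short`.
#'
#' @param path TSV file with a header row.
#' @param cohort_name label for the cohort.
#' @param columns named character vector mapping the canonical names
#'   (`sample_id`, `gene`, `protein_change`, optionally `phenotype`,
#'   `pathogenicity`) to the file's column names, or the string `"maf"`.
#' @param point_only drop non-point protein changes (default `TRUE`).
#' @return a `mutation_catalog`.
#' @export
parse_catalog <- function(path, cohort_name,
                          columns = c(sample_id = "sample_id", gene = "gene",
                                      protein_change = "protein_change"),
                          point_only = TRUE) {
  if (identical(columns, "maf"))
    columns <- c(sample_id = "Tumor_Sample_Barcode", gene = "Hugo_Symbol",
                 protein_change = "HGVSp_Short")
  tab <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (nrow(tab) == 0)
    stop_cohortnet(paste0("empty catalog file: ", path),
                   "cohortnet_empty_catalog")
  miss <- setdiff(unname(columns), names(tab))
  if (length(miss) > 0)
    stop_cohortnet(paste0("column(s) not found in ", path, ": ",
                          paste(miss, collapse = ", ")),
                   "cohortnet_config_error")
  rec <- tab[, unname(columns), drop = FALSE]
  names(rec) <- names(columns)
  for (opt in c("phenotype", "pathogenicity"))
    if (!opt %in% names(rec) && opt %in% names(tab)) rec[[opt]] <- tab[[opt]]
  mutation_catalog(rec, cohort_name, point_only = point_only)
}

#' @export
print.mutation_catalog <- function(x, ...) {
  cat("Mutation catalog:", x$cohort_name, "\n")
  cat("  records:         ", nrow(x$records), "\n")
  cat("  unique mutations:", length(x$unique_mutations), "\n")
  cat("  mutated genes:   ", length(x$mutated_genes), "\n")
  cat("  samples:         ", length(unique(x$records$sample_id)), "\n")
  if (x$parse_report$n_dropped_nonpoint > 0)
    cat("  dropped non-point records:", x$parse_report$n_dropped_nonpoint, "\n")
  invisible(x)
}

# distinct carriers of one (gene, protein_change) mutation
carrier_count <- function(catalog, gene, protein_change) {
  r <- catalog$records
  hit <- r$gene == gene & r$protein_change == protein_change
  length(unique(r$sample_id[hit]))
}

#' Per-patient mutation frequency on a log scale
#'
#' `log10(N + 1)` where `N` is the number of distinct samples carrying the
#' mutation in the catalog. Absent mutations score 0.
#'
#' @param catalog a `mutation_catalog`.
#' @param mutations character vector of `"GENE:CHANGE"` keys, or a
#'   two-column data frame `(gene, protein_change)`.
#' @return numeric vector of `log10(N + 1)` values.
#' @export
mutation_frequency <- function(catalog, mutations) {
  keys <- as_mutation_keys(mutations)
  r <- catalog$records
  rk <- paste(r$gene, r$protein_change, sep = ":")
  n <- vapply(keys, function(k)
    length(unique(r$sample_id[rk == k])), integer(1))
  unname(log10(n + 1))
}

as_mutation_keys <- function(mutations) {
  if (is.data.frame(mutations))
    return(paste(toupper(mutations[[1]]), mutations[[2]], sep = ":"))
  as.character(mutations)
}

#' Select seed genes by recurrence
#'
#' Genes mutated in at least `min_patients` distinct samples, the anchor set
#' for disease-network inference (the recurrence analogue of "seen in at
#' least 3 patients"). Output is ordered by descending carrier count, ties
#' broken lexicographically, so the list is invariant to record order.
#'
#' @param catalog a `mutation_catalog`.
#' @param min_patients minimum number of distinct mutated samples (>= 1).
#' @return character vector of gene symbols (possibly empty).
#' @export
select_seed_genes <- function(catalog, min_patients = 3) {
  stopifnot(min_patients >= 1)
  r <- catalog$records
  per_gene <- tapply(r$sample_id, r$gene, function(s) length(unique(s)))
  per_gene <- per_gene[per_gene >= min_patients]
  if (length(per_gene) == 0) return(character(0))
  ord <- order(-per_gene, names(per_gene))
  names(per_gene)[ord]
}

#' Summarize mutated genes by functional class
#'
#' Counts mutated genes falling in each annotation class (transcription
#' factor, tumor suppressor, oncogene) plus an upset-style table of all
#' class combinations. A gene may belong to several classes; unannotated
#' genes are counted under the empty combination `"none"`.
#'
#' @param catalog a `mutation_catalog`.
#' @param annotation data frame with columns `gene`, `is_tf`, `is_tsg`,
#'   `is_oncogene` (logical flags).
#' @return list with `marginal` (named counts `tf`, `tsg`, `oncogene`,
#'   `none`), `combinations` (data frame of combination counts) and
#'   `n_mutated_genes`.
#' @export
annotate_gene_classes <- function(catalog, annotation) {
  stopifnot(all(c("gene", "is_tf", "is_tsg", "is_oncogene") %in%
                  names(annotation)))
  ann <- annotation
  ann$gene <- toupper(gsub("\\s+", "", as.character(ann$gene)))
  genes <- catalog$mutated_genes
  idx <- match(genes, ann$gene)
  flag <- function(col) !is.na(idx) & ann[[col]][idx] %in% TRUE
  tf <- flag("is_tf"); tsg <- flag("is_tsg"); og <- flag("is_oncogene")
  combo <- ifelse(!tf & !tsg & !og, "none",
                  paste0(ifelse(tf, "TF+", ""), ifelse(tsg, "TSG+", ""),
                         ifelse(og, "OG+", "")))
  combo <- sub("\\+$", "", combo)
  comb_tab <- as.data.frame(table(combo), stringsAsFactors = FALSE)
  names(comb_tab) <- c("classes", "n_genes")
  comb_tab <- comb_tab[order(-comb_tab$n_genes, comb_tab$classes), ]
  rownames(comb_tab) <- NULL
  list(marginal = c(tf = sum(tf), tsg = sum(tsg), oncogene = sum(og),
                    none = sum(combo == "none")),
       combinations = comb_tab,
       n_mutated_genes = length(genes))
}

#' Phenotype-overlap network of a multi-phenotype catalog
#'
#' Builds a weighted graph over the catalog's phenotypes: two phenotypes are
#' connected when they share at least one commonly mutated gene, with edge
#' weight equal to the number of shared mutated genes. Each node carries its
#' sample, mutated-gene and unique-mutation counts.
#'
#' @param catalog a `mutation_catalog` whose records carry phenotypes.
#' @return list with `nodes` (data frame: phenotype, n_samples,
#'   n_mutated_genes, n_mutations) and `edges` (data frame: phenotype_a,
#'   phenotype_b, shared_genes), plus an `igraph` graph in `$graph`.
#' @export
phenotype_overlap_network <- function(catalog) {
  r <- catalog$records
  r <- r[!is.na(r$phenotype), , drop = FALSE]
  if (nrow(r) == 0)
    stop_cohortnet("catalog has no phenotype annotations",
                   "cohortnet_config_error")
  phenos <- sort(unique(r$phenotype))
  gene_sets <- lapply(phenos, function(p) unique(r$gene[r$phenotype == p]))
  names(gene_sets) <- phenos
  nodes <- data.frame(
    phenotype = phenos,
    n_samples = vapply(phenos, function(p)
      length(unique(r$sample_id[r$phenotype == p])), integer(1)),
    n_mutated_genes = lengths(gene_sets),
    n_mutations = vapply(phenos, function(p)
      length(unique(paste(r$gene, r$protein_change)[r$phenotype == p])),
      integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  edges <- data.frame(phenotype_a = character(0), phenotype_b = character(0),
                      shared_genes = integer(0), stringsAsFactors = FALSE)
  if (length(phenos) >= 2) {
    pairs <- combn(phenos, 2)
    w <- apply(pairs, 2, function(pr)
      length(intersect(gene_sets[[pr[1]]], gene_sets[[pr[2]]])))
    keep <- w > 0
    edges <- data.frame(phenotype_a = pairs[1, keep],
                        phenotype_b = pairs[2, keep],
                        shared_genes = as.integer(w[keep]),
                        stringsAsFactors = FALSE)
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  list(nodes = nodes, edges = edges, graph = g)
}

#' Per-residue mutation profile of one gene across two cohorts
#'
#' Tabulates, for every mutated (position, alternate residue) pair of a
#' gene, the number of carriers in each cohort and whether the exact change
#' is shared by both cohorts — the data behind lollipop-style comparisons of
#' germline versus somatic hotspots. Nonsense changes keep `"*"` as the
#' alternate residue.
#'
#' @param a,b `mutation_catalog` objects.
#' @param gene gene symbol.
#' @return data frame with columns `position`, `ref`, `alt`,
#'   `n_a`, `n_b`, `shared`, sorted by position then alt.
#' @export
residue_profile <- function(a, b, gene) {
  gene <- toupper(gsub("\\s+", "", gene))
  grab <- function(cat) {
    r <- cat$records[cat$records$gene == gene, , drop = FALSE]
    if (nrow(r) == 0) return(r)
    r
  }
  ra <- grab(a); rb <- grab(b)
  if (nrow(ra) == 0 && nrow(rb) == 0) {
    warning("gene ", gene, " absent from both catalogs; empty profile")
    return(data.frame(position = integer(0), ref = character(0),
                      alt = character(0), n_a = integer(0), n_b = integer(0),
                      shared = logical(0)))
  }
  changes <- sort(unique(c(ra$protein_change, rb$protein_change)))
  count_in <- function(r, ch)
    if (nrow(r) == 0) 0L else
      length(unique(r$sample_id[r$protein_change == ch]))
  prof <- data.frame(
    position = as.integer(sub("^[A-Z]([0-9]+).*$", "\\1", changes)),
    ref = sub("^([A-Z]).*$", "\\1", changes),
    alt = sub("^[A-Z][0-9]+", "", changes),
    n_a = vapply(changes, function(ch) count_in(ra, ch), integer(1)),
    n_b = vapply(changes, function(ch) count_in(rb, ch), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  prof$shared <- prof$n_a > 0 & prof$n_b > 0
  prof <- prof[order(prof$position, prof$alt), , drop = FALSE]
  rownames(prof) <- NULL
  prof
}
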