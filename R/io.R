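# Readers and writers for the tabular formats the pipeline consumes:
# weighted edge lists, TF->target maps, GMT gene sets, z-score tables.

#' Build a weighted interactome graph
#'
#' The reference network is an undirected protein-protein interaction graph
#' whose edges carry experimental confidence weights in `(0, 1]`.
#' Self-loops are removed and duplicate edges collapse to their maximum
#' weight.
#'
#' @param edges data frame with columns `node_a`, `node_b`, `weight`.
#' @return an undirected `igraph` graph with a `weight` edge attribute.
#' @export
interactome <- function(edges) {
  stopifnot(is.data.frame(edges), ncol(edges) >= 3)
  names(edges)[1:3] <- c("node_a", "node_b", "weight")
  edges$node_a <- toupper(gsub("\\s+", "", as.character(edges$node_a)))
  edges$node_b <- toupper(gsub("\\s+", "", as.character(edges$node_b)))
  edges$weight <- as.numeric(edges$weight)
  if (any(is.na(edges$weight)) || any(edges$weight <= 0))
    stop_cohortnet("interactome weights must be positive",
                   "cohortnet_config_error")
  edges <- edges[edges$node_a != edges$node_b, , drop = FALSE]
  g <- igraph::graph_from_data_frame(edges[, c("node_a", "node_b", "weight")],
                                     directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                   edge.attr.comb = list(weight = "max"))
}

#' Read a weighted edge-list TSV as an interactome
#'
#' Expects three columns (interactor A, interactor B, confidence weight).
#' `dialect = "hippie"` reads the columns named `ID Interactor A`,
#' `ID Interactor B` and `Confidence Value` from a HIPPIE-style export.
#'
#' @param path TSV file.
#' @param dialect `"edgelist"` (default, first three columns used) or
#'   `"hippie"`.
#' @return an undirected weighted `igraph` graph.
#' @export
read_interactome <- function(path, dialect = c("edgelist", "hippie")) {
  dialect <- match.arg(dialect)
  tab <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (dialect == "hippie") {
    cols <- c("ID Interactor A", "ID Interactor B", "Confidence Value")
    miss <- setdiff(cols, names(tab))
    if (length(miss) > 0)
      stop_cohortnet(paste0("missing HIPPIE column(s): ",
                            paste(miss, collapse = ", ")),
                     "cohortnet_config_error")
    tab <- tab[, cols]
  }
  interactome(tab)
}

#' Read a TF-to-target regulatory map
#'
#' Two-or-more-column TSV of directed TF -> target pairs; extra columns
#' (regulation mode, references) are ignored, as in a TRRUST-style export.
#' Duplicate pairs collapse.
#'
#' @param path TSV file; a header row is optional (detected by whether the
#'   first row repeats in the body -- pass `header` explicitly to override).
#' @param header logical; does the file carry a header row?
#' @return object of class `regulatory_map`: data frame `pairs` with columns
#'   `tf`, `target`, plus derived `tf_set` and `target_set`.
#' @export
read_regulatory_map <- function(path, header = TRUE) {
  tab <- read.delim(path, sep = "\t", header = header,
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 2)
    stop_cohortnet("regulatory map needs at least 2 columns (TF, target)",
                   "cohortnet_config_error")
  regulatory_map(tab[[1]], tab[[2]])
}

#' Construct a regulatory map from TF and target vectors
#'
#' @param tf,target character vectors of equal length.
#' @return a `regulatory_map` (see [read_regulatory_map()]).
#' @export
regulatory_map <- function(tf, target) {
  tf <- toupper(gsub("\\s+", "", as.character(tf)))
  target <- toupper(gsub("\\s+", "", as.character(target)))
  pairs <- unique(data.frame(tf = tf, target = target,
                             stringsAsFactors = FALSE))
  pairs <- pairs[order(pairs$tf, pairs$target), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs,
                 tf_set = sort(unique(pairs$tf)),
                 target_set = sort(unique(pairs$target))),
            class = "regulatory_map")
}

#' @export
print.regulatory_map <- function(x, ...) {
  cat("Regulatory map:", nrow(x$pairs), "TF->target pairs,",
      length(x$tf_set), "TFs,", length(x$target_set), "targets\n")
  invisible(x)
}

#' Read gene sets in GMT format
#'
#' Standard tab-separated GMT: set name, description, then member genes.
#' Duplicate genes within a set collapse; empty sets are rejected.
#'
#' @param path GMT file.
#' @return named list of character vectors (class `gene_set_collection`).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0)
    stop_cohortnet(paste0("empty GMT file: ", path),
                   "cohortnet_config_error")
  sets <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop_cohortnet("malformed GMT line (need name, description, genes)",
                     "cohortnet_config_error")
    unique(toupper(gsub("\\s+", "", f[-(1:2)])))
  })
  names(sets) <- vapply(lines, function(ln)
    strsplit(ln, "\t", fixed = TRUE)[[1]][1], character(1))
  if (anyDuplicated(names(sets)))
    stop_cohortnet("duplicate pathway ids in GMT file",
                   "cohortnet_config_error")
  if (any(lengths(sets) == 0))
    stop_cohortnet("empty gene set in GMT file", "cohortnet_config_error")
  structure(sets, class = "gene_set_collection")
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors.
#' @param path output file.
#' @param description optional per-set description (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], description, sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a disease-by-gene z-score table
#'
#' Accepts long format (columns `disease`, `gene`, `z`) or wide format
#' (first column `gene`, one column per disease). Returns a disease x gene
#' numeric matrix with `NA` for unmeasured genes.
#'
#' @param path TSV file.
#' @param format `"long"` or `"wide"`.
#' @return numeric matrix, rows = diseases, columns = genes.
#' @export
read_expression_table <- function(path, format = c("long", "wide")) {
  format <- match.arg(format)
  tab <- read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  if (format == "long") {
    stopifnot(all(c("disease", "gene", "z") %in% names(tab)))
    expression_table(tab$disease, tab$gene, tab$z)
  } else {
    genes <- toupper(gsub("\\s+", "", tab[[1]]))
    m <- t(as.matrix(tab[, -1, drop = FALSE]))
    colnames(m) <- genes
    storage.mode(m) <- "double"
    m
  }
}

#' Assemble an expression z-score matrix from long vectors
#' @param disease,gene,z equal-length vectors of observations.
#' @return numeric matrix, rows = diseases, columns = genes, `NA` where a
#'   (disease, gene) pair was not measured.
#' @export
expression_table <- function(disease, gene, z) {
  gene <- toupper(gsub("\\s+", "", as.character(gene)))
  disease <- as.character(disease)
  if (anyDuplicated(paste(disease, gene, sep = "\r")))
    stop_cohortnet("duplicate (disease, gene) z-score entries",
                   "cohortnet_config_error")
  ds <- sort(unique(disease)); gs <- sort(unique(gene))
  m <- matrix(NA_real_, length(ds), length(gs), dimnames = list(ds, gs))
  m[cbind(match(disease, ds), match(gene, gs))] <- as.numeric(z)
  m
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
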