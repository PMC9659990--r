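# Readers and writers for the pipeline's tabular and FASTA interfaces.

#' Read a protein FASTA into a named character vector
#' @param path FASTA file.
#' @return named character vector (ids are the first whitespace-delimited
#'   token of each description).
#' @export
read_proteins <- function(path) {
  s <- Biostrings::readAAStringSet(path)
  setNames(as.character(s), sub("\\s.*", "", names(s)))
}

#' Read a labeled reference panel FASTA
#'
#' Labels are encoded in the description as `id|subgroup`.
#' @param path FASTA file.
#' @return a [reference_panel()].
#' @export
read_reference_panel <- function(path) {
  s <- Biostrings::readAAStringSet(path)
  desc <- sub("\\s.*", "", names(s))
  parts <- strsplit(desc, "|", fixed = TRUE)
  if (any(lengths(parts) != 2))
    stop("panel descriptions must be 'id|subgroup'")
  reference_panel(vapply(parts, `[`, character(1), 1),
                  as.character(s),
                  vapply(parts, `[`, character(1), 2))
}

#' Write a reference panel to FASTA with `id|subgroup` descriptions
#' @param panel a [reference_panel()].
#' @param path output file.
#' @export
write_reference_panel <- function(panel, path) {
  writeLines(paste0(">", panel$ids, "|", panel$subgroups, "\n",
                    panel$sequences), path, sep = "\n")
  invisible(path)
}

#' Write named sequences to FASTA
#' @param sequences named character vector.
#' @param path output file.
#' @export
write_fasta <- function(sequences, path) {
  writeLines(paste0(">", names(sequences), "\n", unname(sequences)), path,
             sep = "\n")
  invisible(path)
}

#' Read a domain-hit table
#'
#' Tab-separated with header columns protein_id, domain, start, end, score
#' (domtblout-compatible summary).
#' @param path TSV file.
#' @return data.frame.
#' @export
read_domain_hits <- function(path) {
  h <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("protein_id", "domain", "start", "end", "score") %in% names(h)))
  h
}

#' Write a domain-hit table
#' @param hits data.frame.
#' @param path output TSV.
#' @export
write_domain_hits <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix TSV (genes in rows, samples in columns)
#' @param path TSV file; first column gene ids.
#' @param unit unit to record.
#' @param lengths optional named gene lengths.
#' @return an [expr_matrix()].
#' @export
read_expression_tsv <- function(path, unit = "counts", lengths = NULL) {
  d <- read.delim(path, row.names = 1, check.names = FALSE)
  expr_matrix(as.matrix(d), unit = unit, lengths = lengths)
}

#' Write an expression matrix TSV
#' @param x matrix or `expr_matrix`.
#' @param path output TSV.
#' @export
write_expression_tsv <- function(x, path) {
  v <- as.data.frame(unclass(x))
  write.table(cbind(gene = rownames(v), v), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a sample-design table
#' @param path TSV with sample_id, dataset, tissue, stage, treatment, day,
#'   replicate columns (extra columns pass through).
#' @return data.frame.
#' @export
read_design <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot("sample_id" %in% names(d))
  d
}

#' Read gene lengths
#' @param path TSV with columns gene, length.
#' @return named numeric vector.
#' @export
read_lengths <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  setNames(d$length, d$gene)
}

#' Read a collinear-block table
#' @param path TSV with columns block_id, species_a, gene_a, species_b,
#'   gene_b.
#' @return data.frame.
#' @export
read_blocks <- function(path) {
  b <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("block_id", "species_a", "gene_a", "species_b", "gene_b")
                %in% names(b)))
  b
}
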