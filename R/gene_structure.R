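# Gene models from GFF3: exon/intron counts and intron-richness classes.

#' Read gene models from a GFF3 file
#'
#' Parses gene, mRNA, exon and CDS features (ID/Parent attributes) into a
#' list of gene models. Genes without an mRNA child but with direct exon
#' children are accepted as a single implicit transcript. Coordinates stay
#' 1-based inclusive as in GFF3.
#'
#' @param path GFF3 file.
#' @return named list of gene models; each is a list with `gene_id`,
#'   `chromosome`, `strand`, `transcripts` (named list of data.frames with
#'   `start`, `end`, sorted, non-overlapping) and `cds_start` (chromosomal
#'   position of the start codon's first base, NA if no CDS).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- data.frame(
    seqnames = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr), end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    type = as.character(gr$type),
    ID = if (is.null(gr$ID)) NA_character_ else as.character(gr$ID),
    Parent = vapply(as.list(gr$Parent %||% rep(list(character()), length(gr))),
                    function(p) if (length(p)) p[[1]] else NA_character_,
                    character(1)),
    stringsAsFactors = FALSE)
  genes <- df[df$type == "gene", , drop = FALSE]
  mrnas <- df[df$type == "mRNA", , drop = FALSE]
  exons <- df[df$type == "exon", , drop = FALSE]
  cdss  <- df[df$type == "CDS",  , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(genes))) {
    gid <- genes$ID[i]
    tx_ids <- mrnas$ID[mrnas$Parent == gid]
    transcripts <- list()
    if (length(tx_ids)) {
      for (tid in tx_ids) {
        ex <- exons[exons$Parent == tid, c("start", "end"), drop = FALSE]
        transcripts[[tid]] <- ex[order(ex$start), , drop = FALSE]
      }
      cds <- cdss[cdss$Parent %in% tx_ids, , drop = FALSE]
    } else {
      ex <- exons[exons$Parent == gid, c("start", "end"), drop = FALSE]
      if (nrow(ex))
        transcripts[[paste0(gid, ".t1")]] <- ex[order(ex$start), , drop = FALSE]
      cds <- cdss[cdss$Parent == gid, , drop = FALSE]
    }
    cds_start <- NA_integer_
    if (nrow(cds))
      cds_start <- if (genes$strand[i] == "-") max(cds$end) else min(cds$start)
    out[[gid]] <- gene_model(gid, genes$seqnames[i], genes$strand[i],
                             transcripts, cds_start)
  }
  out
}

#' Construct a gene model
#'
#' @param gene_id,chromosome,strand scalars; strand "+" or "-".
#' @param transcripts named list of exon tables (`start`, `end`), each sorted
#'   by start and non-overlapping.
#' @param cds_start chromosomal position of the start codon's first base.
#' @return list of class `gene_model`.
#' @export
gene_model <- function(gene_id, chromosome, strand, transcripts,
                       cds_start = NA_integer_) {
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  for (tid in names(transcripts)) {
    ex <- transcripts[[tid]]
    if (any(ex$start > ex$end)) stop("exon with start > end in ", tid)
    if (nrow(ex) > 1 && any(ex$start[-1] <= ex$end[-nrow(ex)]))
      stop("overlapping or unsorted exons in ", tid)
  }
  structure(list(gene_id = gene_id, chromosome = chromosome, strand = strand,
                 transcripts = transcripts, cds_start = cds_start),
            class = "gene_model")
}

select_transcript <- function(model, transcript_policy = "longest",
                              transcript_id = NULL) {
  tx <- model$transcripts
  if (!length(tx)) stop("gene ", model$gene_id, " has no transcripts")
  if (transcript_policy == "named") {
    if (is.null(transcript_id) || !transcript_id %in% names(tx))
      stop("named transcript not found for ", model$gene_id)
    return(transcript_id)
  }
  len <- vapply(tx, function(ex) sum(ex$end - ex$start + 1L), numeric(1))
  cand <- names(tx)[len == max(len)]
  sort(cand)[1L]
}

#' Count introns of a gene model
#'
#' Introns are exon count minus one on the selected transcript. The default
#' policy selects the transcript with greatest summed exon length (ties go to
#' the lexicographically smallest transcript id).
#'
#' @param model a [gene_model()].
#' @param transcript_policy "longest" (default) or "named".
#' @param transcript_id transcript to use when `transcript_policy = "named"`.
#' @return integer intron count.
#' @export
count_introns <- function(model, transcript_policy = c("longest", "named"),
                          transcript_id = NULL) {
  transcript_policy <- match.arg(transcript_policy)
  tid <- select_transcript(model, transcript_policy, transcript_id)
  nrow(model$transcripts[[tid]]) - 1L
}

#' Intron-richness class
#'
#' Genes are intron-less (no introns), intron-poor (one to three introns) or
#' intron-rich (more than three introns).
#'
#' @param intron_count non-negative integer (vectorised).
#' @return character vector: "intron-less", "intron-poor" or "intron-rich".
#' @export
#' @examples
#' intron_class(c(0, 3, 4))
intron_class <- function(intron_count) {
  if (any(is.na(intron_count)) || any(intron_count < 0))
    stop("intron counts must be non-negative")
  ifelse(intron_count == 0, "intron-less",
         ifelse(intron_count <= 3, "intron-poor", "intron-rich"))
}

#' Intron table for a set of gene models
#' @param models list of gene models (as from [read_gene_models()]).
#' @inheritParams count_introns
#' @return data.frame: gene_id, intron_count, klass.
#' @export
intron_table <- function(models, transcript_policy = "longest") {
  counts <- vapply(models, count_introns,
                   transcript_policy = transcript_policy, integer(1))
  data.frame(gene_id = names(models), intron_count = as.integer(counts),
             klass = intron_class(counts), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Write gene models to GFF3
#'
#' Minimal writer (gene/mRNA/exon/CDS rows with ID/Parent attributes) used by
#' the synthetic generators; output round-trips through
#' [read_gene_models()].
#'
#' @param models list of gene models.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_models_gff3 <- function(models, path) {
  lines <- "##gff-version 3"
  for (m in models) {
    gspan <- range(unlist(lapply(m$transcripts, function(ex) c(ex$start, ex$end))))
    lines <- c(lines, paste(m$chromosome, "erfminer", "gene", gspan[1], gspan[2],
                            ".", m$strand, ".", paste0("ID=", m$gene_id),
                            sep = "\t"))
    for (tid in names(m$transcripts)) {
      ex <- m$transcripts[[tid]]
      lines <- c(lines,
        paste(m$chromosome, "erfminer", "mRNA", min(ex$start), max(ex$end),
              ".", m$strand, ".", paste0("ID=", tid, ";Parent=", m$gene_id),
              sep = "\t"),
        paste(m$chromosome, "erfminer", "exon", ex$start, ex$end,
              ".", m$strand, ".", paste0("Parent=", tid), sep = "\t"),
        paste(m$chromosome, "erfminer", "CDS", ex$start, ex$end,
              ".", m$strand, "0", paste0("Parent=", tid), sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
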