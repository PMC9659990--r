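# Promoter extraction upstream of start codons (strand-aware) and IUPAC
# cis-regulatory element scanning.

IUPAC_EXPAND <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

# IUPAC -> regex character class. Genome N never matches any code except N
# itself, so only the N class includes the literal N.
iupac_to_regex <- function(pattern) {
  letters <- strsplit(toupper(pattern), "")[[1]]
  bad <- setdiff(letters, names(IUPAC_EXPAND))
  if (length(bad))
    stop("invalid IUPAC code(s) in pattern '", pattern, "': ",
         paste(unique(bad), collapse = ""))
  paste(vapply(letters, function(l) {
    set <- IUPAC_EXPAND[[l]]
    if (l == "N") set <- paste0(set, "N")
    if (nchar(set) == 1) set else paste0("[", set, "]")
  }, character(1)), collapse = "")
}

revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

#' Extract promoter regions upstream of start codons
#'
#' For a plus-strand gene the promoter is the `length` bases immediately
#' upstream of the start codon on the forward strand,
#' [cds_start - length, cds_start - 1]; for a minus-strand gene it is
#' [cds_start + 1, cds_start + length] reverse-complemented. Windows clipped
#' at contig edges are flagged `truncated`.
#'
#' @param genome named character vector or `DNAStringSet` of chromosome
#'   sequences, or a FASTA path.
#' @param models list of gene models with `cds_start` set.
#' @param length promoter length in bp (default 2000).
#' @return data.frame: gene_id, chromosome, strand, start, end (1-based
#'   inclusive genomic interval), sequence (promoter-oriented, 5'->3'
#'   towards the gene), truncated.
#' @export
extract_promoters <- function(genome, models, length = 2000) {
  if (is.character(genome) && is.null(names(genome)) && length(genome) == 1 &&
      file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  if (inherits(genome, "DNAStringSet")) {
    nm <- sub("\\s.*", "", names(genome))
    genome <- setNames(as.character(genome), nm)
  }
  rows <- lapply(models, function(m) {
    if (is.na(m$cds_start)) return(NULL)
    if (!m$chromosome %in% names(genome))
      stop("chromosome missing from genome: ", m$chromosome)
    chr_seq <- genome[[m$chromosome]]
    clen <- nchar(chr_seq)
    if (m$strand == "+") {
      start <- m$cds_start - length
      end <- m$cds_start - 1L
      truncated <- start < 1 || end < 1
      start <- max(start, 1L)
      seq <- if (end >= start) substring(chr_seq, start, end) else ""
    } else {
      start <- m$cds_start + 1L
      end <- m$cds_start + length
      truncated <- end > clen || start > clen
      end <- min(end, clen)
      seq <- if (end >= start) revcomp(substring(chr_seq, start, end)) else ""
    }
    data.frame(gene_id = m$gene_id, chromosome = m$chromosome,
               strand = m$strand, start = start, end = end,
               sequence = seq, truncated = truncated,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Built-in illustrative cis-element catalog
#'
#' A small set of common plant cis-regulatory elements (ABRE, ERE, DRE/CRT,
#' GCC-box, G-box, MeJA- and SA-response motifs, ...) with IUPAC patterns.
#' Illustrative defaults for promoter scans, not an exhaustive registry.
#'
#' @return data.frame: element, category, pattern.
#' @export
default_cis_catalog <- function() {
  read_cis_catalog(system.file("extdata", "cis_elements.tsv",
                               package = "erfminer", mustWork = TRUE))
}

#' Read a cis-element catalog
#' @param path TSV with columns element, category, pattern (IUPAC).
#' @return validated data.frame.
#' @export
read_cis_catalog <- function(path) {
  cat <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("element", "category", "pattern") %in% names(cat)))
  for (p in cat$pattern) iupac_to_regex(p)  # validate
  cat
}

match_starts <- function(regex, sequence) {
  # overlapping matches via zero-width lookahead
  m <- gregexpr(paste0("(?=", regex, ")"), sequence, perl = TRUE)[[1]]
  if (m[1] == -1) integer() else as.integer(m)
}

#' Scan promoters for cis-regulatory elements
#'
#' Finds all (possibly overlapping) matches of each IUPAC catalog pattern in
#' each promoter sequence, on the plus strand and, when `both_strands`, the
#' reverse complement (minus-strand positions reported on the promoter's
#' coordinates). An N base in the sequence matches only the pattern code N.
#'
#' @param promoters data.frame from [extract_promoters()] (needs gene_id and
#'   sequence), or a named character vector of sequences.
#' @param catalog data.frame with element, category, pattern columns.
#' @param both_strands scan the reverse complement too (default TRUE).
#' @return list with `hits` (gene_id, element, category, position, strand)
#'   and `counts` (gene x category count table as data.frame).
#' @export
scan_cis_elements <- function(promoters, catalog, both_strands = TRUE) {
  if (is.character(promoters))
    promoters <- data.frame(gene_id = names(promoters),
                            sequence = unname(promoters),
                            stringsAsFactors = FALSE)
  if (nrow(catalog) == 0 || nrow(promoters) == 0) {
    hits <- data.frame(gene_id = character(), element = character(),
                       category = character(), position = integer(),
                       strand = character(), stringsAsFactors = FALSE)
    return(list(hits = hits, counts = data.frame(gene_id = character(),
                                                 stringsAsFactors = FALSE)))
  }
  regexes <- vapply(catalog$pattern, iupac_to_regex, character(1))
  rows <- list()
  for (i in seq_len(nrow(promoters))) {
    seq <- toupper(promoters$sequence[i])
    L <- nchar(seq)
    for (j in seq_len(nrow(catalog))) {
      w <- nchar(catalog$pattern[j])
      st <- match_starts(regexes[j], seq)
      if (length(st))
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = promoters$gene_id[i], element = catalog$element[j],
          category = catalog$category[j], position = st, strand = "+",
          stringsAsFactors = FALSE)
      if (both_strands) {
        st <- match_starts(regexes[j], revcomp(seq))
        if (length(st))
          rows[[length(rows) + 1L]] <- data.frame(
            gene_id = promoters$gene_id[i], element = catalog$element[j],
            category = catalog$category[j],
            position = L - (st + w - 1L) + 1L,  # start on the plus strand
            strand = "-", stringsAsFactors = FALSE)
      }
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(), element = character(),
               category = character(), position = integer(),
               strand = character(), stringsAsFactors = FALSE)
  counts <- as.data.frame.matrix(table(
    factor(hits$gene_id, levels = promoters$gene_id),
    factor(hits$category, levels = unique(catalog$category))))
  counts <- cbind(gene_id = rownames(counts), counts,
                  stringsAsFactors = FALSE)
  rownames(counts) <- NULL
  list(hits = hits, counts = counts)
}
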