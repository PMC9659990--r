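# Subfamily and subgroup classification of AP2/ERF candidates from domain
# architecture and nearest labeled reference, plus C-terminal motif detection
# and basic protein properties.

#' Merge homology- and domain-based candidate sets
#'
#' Combines the two screening routes (homolog alignment and profile-domain
#' search), removes redundancy, and keeps only candidates whose domain
#' content was confirmed by an independent check.
#'
#' @param homology_ids character vector of protein ids found by homology.
#' @param domain_ids character vector of protein ids found by domain search.
#' @param confirmed character vector of ids that passed domain confirmation.
#' @return character vector of unique confirmed candidate ids, sorted.
#' @export
#' @examples
#' merge_candidates(c("a", "b"), c("b", "c"), c("a", "b", "c"))
merge_candidates <- function(homology_ids, domain_ids, confirmed) {
  sort(intersect(union(as.character(homology_ids), as.character(domain_ids)),
                 as.character(confirmed)))
}

#' Reference panel of labeled AP2/ERF exemplars
#'
#' A small container pairing exemplar protein sequences with their subgroup
#' labels (the 15 ERF subclasses Ia..Xb plus AP2, RAV and soloist). Stands in
#' for the labeled homolog set that defines the family's subclades.
#'
#' @param ids character vector of reference ids.
#' @param sequences character vector of amino-acid sequences.
#' @param subgroups character vector of labels, one per entry.
#' @return object of class `reference_panel`.
#' @export
reference_panel <- function(ids, sequences, subgroups) {
  stopifnot(length(ids) == length(sequences),
            length(ids) == length(subgroups),
            !anyDuplicated(ids))
  bad <- setdiff(subgroups, erf_subgroup_labels())
  if (length(bad))
    stop("unknown subgroup label(s): ", paste(bad, collapse = ", "))
  structure(list(ids = as.character(ids),
                 sequences = toupper(as.character(sequences)),
                 subgroups = as.character(subgroups)),
            class = "reference_panel")
}

#' @export
print.reference_panel <- function(x, ...) {
  cat("Reference panel:", length(x$ids), "labeled entries (",
      length(unique(x$subgroups)), "subgroups )\n")
  invisible(x)
}

#' Valid subgroup labels
#'
#' The 15 ERF subclasses plus the AP2, RAV and soloist subfamily labels.
#' @return character vector.
#' @export
erf_subgroup_labels <- function() {
  c("Ia", "Ib", "II", "III", "IV", "Va", "Vb", "VIa", "VIb",
    "VIIa", "VIIb", "VIII", "IX", "Xa", "Xb", "AP2", "RAV", "soloist")
}

subgroup_to_subfamily <- function(label) {
  ifelse(label %in% c("AP2", "RAV", "soloist"), label, "ERF")
}

#' Global alignment score against a reference panel
#'
#' Needleman-Wunsch global alignment (BLOSUM62, affine gaps) of one protein
#' against every panel entry; returns the label of the best-scoring entry.
#' Ties are broken by the lexicographically smallest reference id, so the
#' result is invariant to panel order.
#'
#' @param sequence amino-acid sequence (character scalar).
#' @param panel a [reference_panel()].
#' @param gap_open,gap_extend positive gap penalties (defaults 10 and 1).
#' @param substitution_matrix name of a Biostrings substitution matrix or a
#'   matrix; default `"BLOSUM62"`.
#' @return list with `subgroup`, `nearest_reference`, `score`.
#' @export
assign_subgroup <- function(sequence, panel, gap_open = 10, gap_extend = 1,
                            substitution_matrix = "BLOSUM62") {
  if (!inherits(panel, "reference_panel") || length(panel$ids) == 0L)
    stop("assign_subgroup() requires a non-empty reference_panel")
  # X has no BLOSUM62 row in some builds; score it as the wildcard '*'? No:
  # BLOSUM62 shipped with Biostrings includes X, so pass sequences through.
  scores <- vapply(panel$sequences, function(ref) {
    Biostrings::pairwiseAlignment(
      Biostrings::AAString(sequence), Biostrings::AAString(ref),
      type = "global", substitutionMatrix = substitution_matrix,
      gapOpening = gap_open, gapExtension = gap_extend,
      scoreOnly = TRUE)
  }, numeric(1), USE.NAMES = FALSE)
  best <- which(scores == max(scores))
  best <- best[order(panel$ids[best])][1L]
  list(subgroup = panel$subgroups[best],
       nearest_reference = panel$ids[best],
       score = scores[best])
}

#' Classify one protein into an AP2/ERF subfamily
#'
#' Architecture rules: at least one AP2 and at least one B3 domain gives RAV;
#' two or more AP2 domains (without B3) gives AP2; exactly one AP2 domain is
#' resolved by the nearest labeled reference (some AP2-subfamily members
#' carry a single domain, and the soloist is only distinguishable by
#' sequence). The subgroup always comes from the nearest reference.
#'
#' @param hits data.frame of domain hits for one protein with columns
#'   `protein_id`, `domain` ("AP2"/"B3"), `start`, `end`, `score`.
#' @param panel a [reference_panel()].
#' @param sequence the protein's amino-acid sequence.
#' @param protein_id id (defaults to the one in `hits`).
#' @return data.frame row: protein_id, subfamily, subgroup,
#'   nearest_reference, alignment_score, n_ap2, n_b3.
#' @export
classify_subfamily <- function(hits, panel, sequence,
                               protein_id = unique(hits$protein_id)) {
  n_ap2 <- sum(hits$domain == "AP2")
  n_b3  <- sum(hits$domain == "B3")
  if (n_ap2 < 1L)
    stop("protein ", protein_id,
         " has no AP2 domain hit: not an AP2/ERF family member")
  nn <- assign_subgroup(sequence, panel)
  if (n_b3 >= 1L) {
    subfamily <- "RAV"
    subgroup <- "RAV"
  } else if (n_ap2 >= 2L) {
    subfamily <- "AP2"
    subgroup <- "AP2"
  } else {
    # single AP2 domain: the nearest reference decides the subfamily
    subfamily <- subgroup_to_subfamily(nn$subgroup)
    subgroup <- nn$subgroup
  }
  data.frame(protein_id = protein_id, subfamily = subfamily,
             subgroup = subgroup, nearest_reference = nn$nearest_reference,
             alignment_score = nn$score, n_ap2 = n_ap2, n_b3 = n_b3,
             stringsAsFactors = FALSE)
}

#' Classify a whole protein collection
#'
#' @param proteins named character vector of sequences (names are ids).
#' @param hits data.frame of domain hits for the collection.
#' @param panel a [reference_panel()].
#' @return data.frame, one row per protein carrying at least one AP2 hit.
#' @export
classify_family <- function(proteins, hits, panel) {
  ids <- intersect(names(proteins), unique(hits$protein_id[hits$domain == "AP2"]))
  out <- lapply(ids, function(id)
    classify_subfamily(hits[hits$protein_id == id, , drop = FALSE],
                       panel, proteins[[id]], protein_id = id))
  do.call(rbind, out)
}

# ---- motif detection -------------------------------------------------------

# Default motif patterns. 'x' positions match any canonical residue but never
# the ambiguity letter X.
canon_class <- function() paste0("[", paste(AA20, collapse = ""), "]")

default_motif_patterns <- function(ear_lxlxl = FALSE) {
  pats <- c(
    EAR    = paste0("[LF]DLN[LF]", canon_class(), "P"),
    RKLFGV = "[RK]LFGV",
    EDLL   = "EDLL")
  if (ear_lxlxl)
    pats <- c(pats, EAR_LxLxL = paste0("L", canon_class(), "L", canon_class(), "L"))
  pats
}

#' Detect C-terminal activation/repression motifs
#'
#' Scans a protein for the EAR repression motif (L/F)DLN(L/F)(x)P, the
#' R/K-LFGV repression motif, and the EDLL acidic activation motif. The whole
#' sequence is scanned; each hit is annotated with the sequence third
#' (N-terminal, middle, C-terminal) containing its start, since repression
#' activity is associated with middle/C-terminal copies. Matches of one
#' pattern are non-overlapping; `X` never satisfies a motif class.
#'
#' @param sequence amino-acid sequence.
#' @param protein_id id attached to the output rows.
#' @param patterns named character vector of regular expressions; defaults to
#'   [default_motif_patterns()].
#' @return data.frame: protein_id, motif, start, end, matched_text, region.
#' @export
#' @examples
#' detect_cterm_motifs("MAAALDLNLAP")
detect_cterm_motifs <- function(sequence, protein_id = "protein",
                                patterns = default_motif_patterns()) {
  if (is.null(names(patterns)) || any(!nzchar(names(patterns))))
    stop("motif patterns must be a named character vector")
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  rows <- lapply(names(patterns), function(m) {
    pat <- patterns[[m]]
    ok <- tryCatch({grepl(pat, ""); TRUE}, error = function(e) FALSE,
                   warning = function(w) FALSE)
    if (!ok) stop("malformed motif pattern for ", m, ": ", pat)
    hit <- gregexpr(pat, sequence, perl = TRUE)[[1]]
    if (hit[1] == -1) return(NULL)
    st <- as.integer(hit)
    en <- st + attr(hit, "match.length") - 1L
    data.frame(protein_id = protein_id, motif = m, start = st, end = en,
               matched_text = substring(sequence, st, en),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(protein_id = character(), motif = character(),
                      start = integer(), end = integer(),
                      matched_text = character(), region = character(),
                      stringsAsFactors = FALSE))
  out$region <- ifelse(out$start > 2 * n / 3, "C-terminal",
                       ifelse(out$start > n / 3, "middle", "N-terminal"))
  out[order(out$start, out$motif), , drop = FALSE]
}

#' Scan a protein collection for motifs
#' @param proteins named character vector of sequences.
#' @inheritParams detect_cterm_motifs
#' @return data.frame of all hits.
#' @export
scan_motifs <- function(proteins, patterns = default_motif_patterns()) {
  do.call(rbind, c(lapply(names(proteins), function(id)
    detect_cterm_motifs(proteins[[id]], id, patterns)),
    make.row.names = FALSE))
}

# ---- protein properties ----------------------------------------------------

# Average (isotope-averaged) residue masses, Da; the free protein adds one
# water. X contributes zero mass.
AA_RESIDUE_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326,
  X = 0)
WATER_MASS <- 18.0153

# EMBOSS-style pKa values used for the net-charge equation.
PKA <- list(
  nterm = 8.6, cterm = 3.6,
  pos = c(K = 10.8, R = 12.5, H = 6.5),
  neg = c(D = 3.9, E = 4.1, C = 8.5, Y = 10.1))

protein_net_charge <- function(counts, pH, pka = PKA) {
  cnt <- function(a) if (is.na(counts[a])) 0 else as.numeric(counts[a])
  pos <- 1 / (1 + 10^(pH - pka$nterm)) +
    sum(vapply(names(pka$pos), function(a)
      cnt(a) / (1 + 10^(pH - pka$pos[[a]])), numeric(1)))
  neg <- 1 / (1 + 10^(pka$cterm - pH)) +
    sum(vapply(names(pka$neg), function(a)
      cnt(a) / (1 + 10^(pka$neg[[a]] - pH)), numeric(1)))
  pos - neg
}

#' Basic protein properties: length, molecular weight, isoelectric point
#'
#' Length is the residue count (X included). Molecular weight sums average
#' residue masses plus one water (18.0153 Da); X adds zero mass. The
#' isoelectric point is the pH at which the Henderson-Hasselbalch net charge
#' (EMBOSS-style pKa values; X carries no charge) crosses zero, found by
#' bisection on [0, 14] to 0.01 pH.
#'
#' @param sequence amino-acid sequence (20 canonical letters plus X).
#' @return list with `length`, `molecular_weight` (Da), `pI`.
#' @export
#' @examples
#' protein_properties("G")$molecular_weight  # 75.07
protein_properties <- function(sequence) {
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("empty protein sequence")
  aa <- strsplit(sequence, "")[[1]]
  bad <- setdiff(aa, c(AA20, "X"))
  if (length(bad))
    stop("invalid amino-acid letter(s): ", paste(unique(bad), collapse = ""))
  counts <- table(factor(aa, levels = c(AA20, "X")))
  mw <- sum(AA_RESIDUE_MASS[names(counts)] * as.integer(counts)) + WATER_MASS
  lo <- 0; hi <- 14
  # net charge is monotone decreasing in pH
  while (hi - lo > 0.005) {
    mid <- (lo + hi) / 2
    if (protein_net_charge(counts, mid) > 0) lo <- mid else hi <- mid
  }
  list(length = length(aa), molecular_weight = mw,
       pI = round((lo + hi) / 2, 2))
}

#' Properties table for a protein collection
#' @param proteins named character vector of sequences.
#' @return data.frame: protein_id, length, molecular_weight, pI.
#' @export
protein_properties_table <- function(proteins) {
  do.call(rbind, lapply(names(proteins), function(id) {
    p <- protein_properties(proteins[[id]])
    data.frame(protein_id = id, length = p$length,
               molecular_weight = p$molecular_weight, pI = p$pI,
               stringsAsFactors = FALSE)
  }))
}

# ---- minimal consensus-domain scanner --------------------------------------

#' Locate planted consensus domain blocks (fallback scanner)
#'
#' A minimal substitute for a profile-HMM search so that synthetic fixtures
#' can be analysed end-to-end without external scanners: finds approximate
#' occurrences of fixed consensus strings, allowing a fraction of mismatches.
#' Not a general domain finder.
#'
#' @param proteins named character vector of sequences.
#' @param consensus named character vector of consensus blocks
#'   (names are domain names, e.g. AP2, B3).
#' @param max_mismatch_frac maximum mismatch fraction (default 0.25).
#' @return data.frame like a domain-hit table: protein_id, domain, start,
#'   end, score (matches minus mismatches).
#' @export
scan_consensus_domains <- function(proteins, consensus = domain_consensus(),
                                   max_mismatch_frac = 0.25) {
  rows <- list()
  for (id in names(proteins)) {
    subj <- Biostrings::AAString(proteins[[id]])
    for (dom in names(consensus)) {
      pat <- consensus[[dom]]
      mm <- as.integer(floor(nchar(pat) * max_mismatch_frac))
      m <- Biostrings::matchPattern(pat, subj, max.mismatch = mm)
      if (length(m) == 0) next
      nmm <- Biostrings::neditAt(pat, subj, at = BiocGenerics::start(m))
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = id, domain = dom,
        start = BiocGenerics::start(m), end = BiocGenerics::end(m),
        score = nchar(pat) - 2L * nmm, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(protein_id = character(), domain = character(),
                      start = integer(), end = integer(), score = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
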