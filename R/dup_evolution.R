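# Paralog discovery, duplication-type classification, Nei-Gojobori (1986)
# Ka/Ks with Jukes-Cantor correction, divergence dating, and cross-species
# syntenic intersection.

BASES <- c("A", "C", "G", "T")

codon_table <- function() Biostrings::GENETIC_CODE

split_codons <- function(cds) {
  n <- nchar(cds)
  substring(cds, seq(1, n, 3), seq(3, n, 3))
}

validate_cds_pair <- function(cds_a, cds_b) {
  cds_a <- toupper(cds_a); cds_b <- toupper(cds_b)
  if (nchar(cds_a) != nchar(cds_b)) stop("CDS pair lengths differ")
  if (nchar(cds_a) %% 3 != 0) stop("CDS length not divisible by 3")
  if (nchar(cds_a) == 0) stop("empty CDS")
  if (grepl("[^ACGT]", cds_a) || grepl("[^ACGT]", cds_b))
    stop("CDS must contain only A/C/G/T (remove gap columns first)")
  gc <- codon_table()
  for (s in list(cds_a, cds_b))
    if (any(gc[split_codons(s)] == "*"))
      stop("internal stop codon in CDS")
  list(a = cds_a, b = cds_b)
}

# Synonymous site fraction at each position of a codon: the fraction of the
# three possible single-base changes at that position that preserve the amino
# acid. Changes to stop codons count as nonsynonymous, so S + N is exactly 3
# per codon.
codon_syn_fractions <- function(codon, gc = codon_table()) {
  aa <- gc[[codon]]
  vapply(1:3, function(pos) {
    alts <- setdiff(BASES, substr(codon, pos, pos))
    sum(vapply(alts, function(b) {
      mut <- codon
      substr(mut, pos, pos) <- b
      gc[[mut]] == aa && gc[[mut]] != "*"
    }, logical(1))) / 3
  }, numeric(1))
}

# cache: per-codon synonymous site totals and pairwise pathway-averaged
# (Sd, Nd), computed once per session
.ng86_cache <- new.env(parent = emptyenv())

# 3 x 61 matrix of per-position synonymous site fractions for sense codons
ng86_frac_matrix <- function() {
  if (is.null(.ng86_cache$frac)) {
    gc <- codon_table()
    sense <- names(gc)[gc != "*"]
    .ng86_cache$frac <- vapply(setNames(sense, sense), codon_syn_fractions,
                               numeric(3))
  }
  .ng86_cache$frac
}

# per sense codon and position, the synonymous and nonsynonymous (non-stop)
# single-base replacement codons
ng86_mutation_sets <- function() {
  if (is.null(.ng86_cache$muts)) {
    gc <- codon_table()
    sense <- names(gc)[gc != "*"]
    .ng86_cache$muts <- lapply(setNames(sense, sense), function(cd) {
      lapply(1:3, function(pos) {
        alts <- setdiff(BASES, substr(cd, pos, pos))
        muts <- vapply(alts, function(b) {
          m <- cd; substr(m, pos, pos) <- b; m
        }, character(1), USE.NAMES = FALSE)
        list(syn = muts[gc[muts] == gc[[cd]] & gc[muts] != "*"],
             non = muts[gc[muts] != gc[[cd]] & gc[muts] != "*"])
      })
    })
  }
  .ng86_cache$muts
}

ng86_syn_sites <- function() {
  if (is.null(.ng86_cache$syn_sites)) {
    gc <- codon_table()
    sense <- names(gc)[gc != "*"]
    .ng86_cache$syn_sites <-
      vapply(sense, function(cd) sum(codon_syn_fractions(cd, gc)), numeric(1))
  }
  .ng86_cache$syn_sites
}

# Pathway-averaged synonymous/nonsynonymous differences between two sense
# codons: enumerate all orderings of the differing positions, drop pathways
# passing through a stop codon, average the per-step synonymous counts. If
# every pathway is blocked, split the raw differences in proportion to the
# mean synonymous site fraction at the differing positions.
codon_pair_diffs <- function(codon_a, codon_b, gc = codon_table()) {
  if (codon_a == codon_b) return(c(sd = 0, nd = 0))
  key <- paste0(codon_a, codon_b)
  if (is.null(.ng86_cache$pair)) .ng86_cache$pair <- new.env(parent = emptyenv())
  hit <- .ng86_cache$pair[[key]]
  if (!is.null(hit)) return(hit)
  pos <- which(strsplit(codon_a, "")[[1]] != strsplit(codon_b, "")[[1]])
  k <- length(pos)
  orders <- if (k == 1) list(pos) else
    lapply(asplit(permutations_of(k), 1), function(ix) pos[ix])
  sd_tot <- 0; nd_tot <- 0; n_valid <- 0L
  for (ord in orders) {
    cur <- codon_a
    sd <- 0; nd <- 0; valid <- TRUE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(codon_b, p, p)
      if (gc[[nxt]] == "*" && nxt != codon_b) { valid <- FALSE; break }
      if (gc[[nxt]] == gc[[cur]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (valid) { sd_tot <- sd_tot + sd; nd_tot <- nd_tot + nd
                 n_valid <- n_valid + 1L }
  }
  res <- if (n_valid > 0) {
    c(sd = sd_tot / n_valid, nd = nd_tot / n_valid)
  } else {
    fa <- codon_syn_fractions(codon_a, gc)
    fb <- codon_syn_fractions(codon_b, gc)
    f <- mean((fa[pos] + fb[pos]) / 2)
    c(sd = k * f, nd = k * (1 - f))
  }
  .ng86_cache$pair[[key]] <- res
  res
}

permutations_of <- function(k) {
  if (k == 1) return(matrix(1L))
  sub <- permutations_of(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i)
    cbind(i, ifelse(sub >= i, sub + 1L, sub))))
}

#' Nei-Gojobori (1986) Ka/Ks for an aligned codon pair
#'
#' Counts synonymous (S) and nonsynonymous (N) sites per sequence from the
#' standard genetic code (averaged over the two sequences; mutations to stop
#' codons count as nonsynonymous, so S + N equals three times the codon
#' count), averages synonymous/nonsynonymous differences (Sd, Nd) over all
#' orderings of single-step mutational pathways excluding those passing
#' through stop codons, and applies the Jukes-Cantor correction
#' Ks = -(3/4) log(1 - (4/3) pS) (same for Ka). A correction argument <= 0
#' (saturation) yields NA; the Ka/Ks ratio is NA when Ks is 0 or NA.
#'
#' @param cds_a,cds_b in-frame aligned coding sequences (A/C/G/T, equal
#'   length, multiple of 3, no internal stops; gap columns removed).
#' @param lambda clock rate (substitutions/site/year) used for the divergence
#'   time, default 6.1e-9.
#' @return list of class `rate_estimate`: S, N, Sd, Nd, pS, pN, Ka, Ks,
#'   ratio, T (Mya).
#' @export
#' @examples
#' ng86_kaks("TTTGGGGGG", "TTCGGGGGG")$Ks  # ~0.6355
ng86_kaks <- function(cds_a, cds_b, lambda = 6.1e-9) {
  v <- validate_cds_pair(cds_a, cds_b)
  gc <- codon_table()
  ca <- split_codons(v$a); cb <- split_codons(v$b)
  syn <- ng86_syn_sites()
  S <- (sum(syn[ca]) + sum(syn[cb])) / 2
  N <- 3 * length(ca) - S
  d <- vapply(seq_along(ca), function(i) codon_pair_diffs(ca[i], cb[i], gc),
              numeric(2))
  Sd <- sum(d["sd", ]); Nd <- sum(d["nd", ])
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  jc <- function(p) {
    arg <- 1 - 4 * p / 3
    if (arg <= 0) NA_real_ else -3 / 4 * log(arg)
  }
  Ks <- jc(pS); Ka <- jc(pN)
  ratio <- if (is.na(Ks) || is.na(Ka) || Ks == 0) NA_real_ else Ka / Ks
  structure(list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
                 Ka = Ka, Ks = Ks, ratio = ratio,
                 T = divergence_time(Ks, lambda)),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("NG86 rate estimate: S=%.3f N=%.3f Sd=%.3f Nd=%.3f\n",
              x$S, x$N, x$Sd, x$Nd))
  cat(sprintf("  Ka=%s Ks=%s Ka/Ks=%s T=%s Mya\n",
              format(x$Ka), format(x$Ks), format(x$ratio),
              if (is.na(x$T)) "NA" else sprintf("%.2f", x$T)))
  invisible(x)
}

#' Divergence time from Ks
#'
#' T = Ks / (2 * lambda) * 1e-6, in millions of years, with the default
#' plant clock rate lambda = 6.1e-9 substitutions per site per year.
#'
#' @param ks synonymous substitution rate (vectorised); NA propagates.
#' @param lambda substitutions/site/year.
#' @return divergence time(s) in Mya.
#' @export
#' @examples
#' divergence_time(0.0122)  # 1 Mya
divergence_time <- function(ks, lambda = 6.1e-9) {
  out <- ks / (2 * lambda) * 1e-6
  out[!is.na(ks) & ks < 0] <- NA_real_
  out
}

#' Find paralog pairs by global-alignment identity
#'
#' All unordered protein pairs whose global-alignment identity (matches over
#' alignment length, BLOSUM62, gap open 10 / extend 1) and mutual length
#' coverage (shorter over longer sequence length) reach the thresholds.
#'
#' @param proteins named character vector of sequences (>= 2).
#' @param min_identity minimum identity fraction (default 0.70).
#' @param min_coverage minimum mutual coverage fraction (default 0.75).
#' @return data.frame: gene_a, gene_b (a < b by id), identity, coverage.
#' @export
find_paralog_pairs <- function(proteins, min_identity = 0.70,
                               min_coverage = 0.75) {
  if (length(proteins) < 2) stop("need at least two proteins")
  ids <- sort(names(proteins))
  cmb <- combn(ids, 2)
  rows <- lapply(seq_len(ncol(cmb)), function(j) {
    a <- cmb[1, j]; b <- cmb[2, j]
    la <- nchar(proteins[[a]]); lb <- nchar(proteins[[b]])
    cov <- min(la, lb) / max(la, lb)
    if (cov < min_coverage) return(NULL)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(proteins[[a]]), Biostrings::AAString(proteins[[b]]),
      type = "global", substitutionMatrix = "BLOSUM62",
      gapOpening = 10, gapExtension = 1)
    ident <- Biostrings::nmatch(aln) / Biostrings::nchar(aln)
    if (ident < min_identity) return(NULL)
    data.frame(gene_a = a, gene_b = b, identity = ident, coverage = cov,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_a = character(), gene_b = character(),
                      identity = numeric(), coverage = numeric(),
                      stringsAsFactors = FALSE)
  out
}

#' Classify a duplication event as tandem, segmental or dispersed
#'
#' A pair inside any within-species collinear block is segmental; otherwise a
#' pair on one chromosome separated by at most `max_gap` intervening gene
#' models is tandem; anything else (including unplaced genes) is dispersed.
#'
#' @param gene_a,gene_b gene ids.
#' @param gene_order named list: chromosome -> character vector of gene ids
#'   in chromosomal order. Genes absent from every chromosome are treated as
#'   unplaced only if listed in `unplaced`.
#' @param blocks data.frame with columns block_id, species_a, gene_a,
#'   species_b, gene_b (within-species rows have species_a == species_b).
#' @param max_gap maximum intervening gene models for a tandem call
#'   (default 5).
#' @param unplaced character vector of genes known but not placed.
#' @return data.frame row: gene_a, gene_b, type, evidence.
#' @export
classify_duplication <- function(gene_a, gene_b, gene_order, blocks = NULL,
                                 max_gap = 5, unplaced = character()) {
  all_genes <- c(unlist(gene_order, use.names = FALSE), unplaced)
  for (g in c(gene_a, gene_b))
    if (!g %in% all_genes) stop("gene absent from annotation: ", g)
  pair <- sort(c(gene_a, gene_b))
  if (!is.null(blocks) && nrow(blocks)) {
    within <- blocks[blocks$species_a == blocks$species_b, , drop = FALSE]
    inblock <- apply(within, 1, function(r)
      setequal(c(r[["gene_a"]], r[["gene_b"]]), pair))
    if (any(inblock)) {
      bid <- within$block_id[which(inblock)[1]]
      return(data.frame(gene_a = pair[1], gene_b = pair[2],
                        type = "segmental",
                        evidence = paste0("block:", bid),
                        stringsAsFactors = FALSE))
    }
  }
  loc <- function(g) {
    for (chr in names(gene_order)) {
      i <- match(g, gene_order[[chr]])
      if (!is.na(i)) return(list(chr = chr, i = i))
    }
    NULL
  }
  la <- loc(gene_a); lb <- loc(gene_b)
  if (is.null(la) || is.null(lb))
    return(data.frame(gene_a = pair[1], gene_b = pair[2], type = "dispersed",
                      evidence = "unplaced", stringsAsFactors = FALSE))
  if (la$chr == lb$chr && abs(la$i - lb$i) - 1 <= max_gap)
    return(data.frame(gene_a = pair[1], gene_b = pair[2], type = "tandem",
                      evidence = paste0(la$chr, ":gap=", abs(la$i - lb$i) - 1),
                      stringsAsFactors = FALSE))
  data.frame(gene_a = pair[1], gene_b = pair[2], type = "dispersed",
             evidence = if (la$chr == lb$chr)
               paste0(la$chr, ":gap=", abs(la$i - lb$i) - 1)
             else paste0(la$chr, "/", lb$chr),
             stringsAsFactors = FALSE)
}

#' Gene order per chromosome from gene models
#' @param models list of gene models.
#' @return named list: chromosome -> gene ids ordered by transcript start.
#' @export
gene_order_from_models <- function(models) {
  starts <- vapply(models, function(m)
    min(unlist(lapply(m$transcripts, function(ex) ex$start))), numeric(1))
  chrs <- vapply(models, function(m) m$chromosome, character(1))
  ids <- names(models)
  out <- list()
  for (chr in sort(unique(chrs))) {
    sel <- chrs == chr
    out[[chr]] <- ids[sel][order(starts[sel])]
  }
  out
}

#' Genes conserved across all species' syntenic tables
#'
#' Intersects, over species, the sets of focal-species genes participating in
#' syntenic pairs with that species.
#'
#' @param ortholog_tables named list: species -> character vector of focal
#'   genes in syntenic pairs with that species.
#' @return sorted character vector of genes present in every table.
#' @export
conserved_across <- function(ortholog_tables) {
  if (!length(ortholog_tables)) stop("need at least one species table")
  sort(Reduce(intersect, lapply(ortholog_tables, unique)))
}
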