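# Normalisation, expression thresholds and ratio classifications, DEG
# calling, the three-dataset intersection screen, 2^-ddCT and Spearman
# co-expression.

#' Construct an expression matrix with recorded unit
#'
#' @param values numeric matrix, genes in rows (rownames), samples in
#'   columns (colnames); no negative entries.
#' @param unit "counts", "FPKM" or "TPM".
#' @param lengths named numeric vector of gene lengths (bp); required for
#'   counts that will be normalised.
#' @return object of class `expr_matrix` (the matrix with `unit` and
#'   `lengths` attributes).
#' @export
expr_matrix <- function(values, unit = c("counts", "FPKM", "TPM"),
                        lengths = NULL) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  if (any(values < 0)) stop("expression values must be non-negative")
  if (is.null(rownames(values))) stop("gene rownames required")
  if (!is.null(lengths)) {
    if (any(lengths <= 0)) stop("gene lengths must be positive")
    lengths <- lengths[rownames(values)]
    if (any(is.na(lengths))) stop("missing gene length(s)")
  }
  structure(values, unit = unit, lengths = lengths, class = "expr_matrix")
}

expr_unit <- function(x) attr(x, "unit")

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("%d genes x %d samples [%s]\n", nrow(x), ncol(x), expr_unit(x)))
  invisible(x)
}

#' Normalise a count matrix to TPM or FPKM
#'
#' FPKM_gs = count_gs * 1e9 / (length_g * colsum_s);
#' TPM_gs = rate_gs * 1e6 / sum_g rate_gs with rate = count/length.
#' An all-zero sample column stays zero, with a warning.
#'
#' @param counts `expr_matrix` with unit "counts" (or plain matrix) with
#'   gene lengths.
#' @param lengths named gene lengths (bp), taken from `counts` if absent.
#' @return `expr_matrix` in the requested unit.
#' @export
compute_tpm <- function(counts, lengths = attr(counts, "lengths")) {
  m <- normalise_input(counts, lengths)
  rate <- m$values / m$lengths
  tot <- colSums(rate)
  if (any(tot == 0)) {
    warning("all-zero sample column(s): ",
            paste(colnames(m$values)[tot == 0], collapse = ", "))
    tot[tot == 0] <- 1
  }
  expr_matrix(sweep(rate, 2, tot, "/") * 1e6, "TPM", m$lengths)
}

#' @rdname compute_tpm
#' @export
compute_fpkm <- function(counts, lengths = attr(counts, "lengths")) {
  m <- normalise_input(counts, lengths)
  tot <- colSums(m$values)
  if (any(tot == 0)) {
    warning("all-zero sample column(s): ",
            paste(colnames(m$values)[tot == 0], collapse = ", "))
    tot[tot == 0] <- 1
  }
  expr_matrix(sweep(m$values * 1e9 / m$lengths, 2, tot, "/"), "FPKM",
              m$lengths)
}

normalise_input <- function(counts, lengths) {
  if (inherits(counts, "expr_matrix") && expr_unit(counts) != "counts")
    stop("normalisation expects a counts matrix")
  values <- unclass(counts)
  attr(values, "unit") <- NULL; attr(values, "lengths") <- NULL
  if (is.null(lengths)) stop("gene lengths required for normalisation")
  lengths <- lengths[rownames(values)]
  if (any(is.na(lengths))) stop("missing gene length(s)")
  list(values = as.matrix(values), lengths = lengths)
}

#' Genes expressed above a threshold in at least one sample
#'
#' The inclusive rule: a gene passes when its maximum over samples is
#' greater than or equal to `threshold` (default 20 FPKM/TPM).
#'
#' @param x `expr_matrix` in FPKM or TPM.
#' @param threshold inclusive abundance threshold.
#' @return character vector of gene ids.
#' @export
filter_expressed <- function(x, threshold = 20) {
  if (expr_unit(x) == "counts")
    stop("filter_expressed() needs FPKM or TPM, not raw counts")
  rownames(x)[apply(unclass(x), 1, max) >= threshold]
}

#' Expression-level groups A/B/C
#'
#' Partition by maximum FPKM with half-open bins: C = [0, 20),
#' B = [20, 300), A = [300, Inf).
#'
#' @param x `expr_matrix` in FPKM.
#' @param genes genes to classify (default all rows).
#' @return named character vector of "A"/"B"/"C".
#' @export
group_by_level <- function(x, genes = rownames(x)) {
  if (expr_unit(x) != "FPKM") stop("group_by_level() expects FPKM")
  mx <- apply(unclass(x)[genes, , drop = FALSE], 1, max)
  setNames(ifelse(mx >= 300, "A", ifelse(mx >= 20, "B", "C")), genes)
}

design_samples <- function(design, ...) {
  sel <- rep(TRUE, nrow(design))
  crit <- list(...)
  for (f in names(crit)) sel <- sel & design[[f]] %in% crit[[f]]
  design$sample_id[sel]
}

#' Tissue-dominance classification
#'
#' Ratio of the summed abundance over all flesh samples to the sum over all
#' peel samples; strictly greater than `hi` (default 5) is flesh-dominant,
#' strictly less than `lo` (default 0.2) peel-dominant, otherwise none. A
#' zero peel sum with positive flesh sum is flesh-dominant; both zero is
#' none.
#'
#' @param x `expr_matrix` (FPKM or TPM).
#' @param design data.frame with sample_id and tissue columns.
#' @param tissues the two tissue labels compared, numerator first
#'   (default flesh vs peel).
#' @param hi,lo strict ratio thresholds.
#' @return data.frame: gene, ratio, dominance.
#' @export
classify_dominance <- function(x, design, tissues = c("flesh", "peel"),
                               hi = 5, lo = 0.2) {
  s1 <- design_samples(design, tissue = tissues[1])
  s2 <- design_samples(design, tissue = tissues[2])
  if (!length(s1) || !length(s2))
    stop("both tissues must be present in the design")
  v <- unclass(x)
  sum1 <- rowSums(v[, s1, drop = FALSE])
  sum2 <- rowSums(v[, s2, drop = FALSE])
  ratio <- ifelse(sum2 == 0, ifelse(sum1 > 0, Inf, NA_real_), sum1 / sum2)
  lab <- ifelse(is.na(ratio), "none",
                ifelse(ratio > hi, tissues[1],
                       ifelse(ratio < lo, tissues[2], "none")))
  data.frame(gene = rownames(v), ratio = ratio, dominance = lab,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Ripening-correlation classification
#'
#' Per tissue, the ratio of summed abundance over late stages (default 4-6)
#' to the sum over early stages (1-3); strictly greater than 2 is positively
#' and strictly less than 0.5 negatively correlated with ripening. A zero
#' early sum with positive late sum is positive; both zero is none.
#'
#' @param x `expr_matrix`.
#' @param design data.frame with sample_id, tissue and stage columns.
#' @param late,early integer stage sets.
#' @param hi,lo strict ratio thresholds (defaults 2 and 0.5).
#' @return data.frame: gene, tissue, ratio, correlation.
#' @export
classify_ripening_correlation <- function(x, design, late = 4:6, early = 1:3,
                                          hi = 2, lo = 0.5) {
  stages <- design$stage
  if (!all(c(late, early) %in% stages))
    stop("design is missing required stages")
  v <- unclass(x)
  rows <- lapply(sort(unique(design$tissue)), function(tis) {
    sl <- design_samples(design, tissue = tis, stage = late)
    se <- design_samples(design, tissue = tis, stage = early)
    lsum <- rowSums(v[, sl, drop = FALSE])
    esum <- rowSums(v[, se, drop = FALSE])
    ratio <- ifelse(esum == 0, ifelse(lsum > 0, Inf, NA_real_), lsum / esum)
    lab <- ifelse(is.na(ratio), "none",
                  ifelse(ratio > hi, "positive",
                         ifelse(ratio < lo, "negative", "none")))
    data.frame(gene = rownames(v), tissue = tis, ratio = ratio,
               correlation = lab, row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Call differentially expressed genes between two sample sets
#'
#' log2 fold change of pseudocounted means:
#' log2((mean_case + pc) / (mean_control + pc)). With `test = "welch"` a
#' Welch t-test on log2(x + pc) is added and BH-adjusted across genes;
#' significance then requires |log2FC| >= `lfc` and p_adjust < `alpha`.
#' With `test = "none"` (the fold-change-only rule) significance is
#' |log2FC| >= `lfc` alone.
#'
#' @param case,control abundance matrices (genes x replicate samples) on the
#'   same genes.
#' @param comparison_id label attached to the rows.
#' @param pseudocount added to means (default 1).
#' @param test "none" or "welch".
#' @param lfc absolute log2 fold-change threshold (inclusive, default 1).
#' @param alpha adjusted-p threshold (strict, default 0.05).
#' @return data.frame: comparison_id, gene, log2fc, p, p_adjust,
#'   significant, direction.
#' @export
call_degs <- function(case, control, comparison_id = "case_vs_control",
                      pseudocount = 1, test = c("none", "welch"),
                      lfc = 1, alpha = 0.05) {
  test <- match.arg(test)
  case <- as.matrix(case); control <- as.matrix(control)
  if (ncol(case) < 1 || ncol(control) < 1)
    stop("each side needs at least one replicate")
  if (!identical(rownames(case), rownames(control)))
    stop("case and control must share the same genes in the same order")
  mc <- rowMeans(case); mk <- rowMeans(control)
  log2fc <- log2((mc + pseudocount) / (mk + pseudocount))
  if (test == "welch") {
    if (ncol(case) < 2 || ncol(control) < 2)
      stop("welch test needs >= 2 replicates per side")
    p <- vapply(seq_len(nrow(case)), function(i) {
      a <- log2(case[i, ] + pseudocount); b <- log2(control[i, ] + pseudocount)
      if (stats::sd(a) == 0 && stats::sd(b) == 0)
        return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
      t.test(a, b)$p.value
    }, numeric(1))
    padj <- bh_adjust(p)
    sig <- abs(log2fc) >= lfc & padj < alpha
  } else {
    p <- NA_real_; padj <- NA_real_
    sig <- abs(log2fc) >= lfc
  }
  data.frame(comparison_id = comparison_id, gene = rownames(case),
             log2fc = log2fc, p = p, p_adjust = padj, significant = sig,
             direction = ifelse(log2fc >= 0, "up", "down"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' capped at 1.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Intersection screen for key ripening genes
#'
#' A gene is a key candidate when it is differentially regulated (either
#' direction) in at least one comparison of every comparison group, with
#' every group represented.
#'
#' @param deg_tables named list of [call_degs()] tables, names are
#'   comparison ids.
#' @param groups named list: group name -> character vector of comparison
#'   ids that belong to it; every group must be non-empty and refer to
#'   supplied tables.
#' @return list with `key_genes` (sorted) and `directions` (data.frame of
#'   per-comparison direction for the key genes, NA where not significant).
#' @export
intersect_screen <- function(deg_tables, groups) {
  if (!length(groups) || any(!lengths(groups)))
    stop("every comparison group must be non-empty")
  missing <- setdiff(unlist(groups), names(deg_tables))
  if (length(missing))
    stop("comparison table(s) missing: ", paste(missing, collapse = ", "))
  sig_genes <- function(cmp) {
    t <- deg_tables[[cmp]]
    t$gene[t$significant]
  }
  per_group <- lapply(groups, function(cmps)
    sort(unique(unlist(lapply(cmps, sig_genes)))))
  key <- sort(Reduce(intersect, per_group))
  dirs <- NULL
  if (length(key)) {
    dirs <- data.frame(gene = key, stringsAsFactors = FALSE)
    for (cmp in names(deg_tables)) {
      t <- deg_tables[[cmp]]
      i <- match(key, t$gene)
      dirs[[cmp]] <- ifelse(!is.na(i) & t$significant[i], t$direction[i],
                            NA_character_)
    }
  }
  list(key_genes = key, directions = dirs)
}

#' Relative expression by the 2^-ddCT method
#'
#' 2^-((ct_target - ct_reference) - (calibrator_ct_target -
#' calibrator_ct_reference)), with the reference an internal-control gene
#' and the calibrator a baseline sample. Vectorised over samples.
#'
#' @param ct_target,ct_reference CT values in the sample of interest.
#' @param calibrator_ct_target,calibrator_ct_reference CT values in the
#'   calibrator sample.
#' @return relative expression (1 for the calibrator itself).
#' @export
#' @examples
#' delta_delta_ct(24, 20, 26, 20)  # 4
delta_delta_ct <- function(ct_target, ct_reference,
                           calibrator_ct_target, calibrator_ct_reference) {
  ddct <- (ct_target - ct_reference) -
    (calibrator_ct_target - calibrator_ct_reference)
  2^(-ddct)
}

#' Spearman co-expression matrix
#'
#' Rank correlation (average ranks for ties) between gene expression
#' profiles. A constant gene yields an NA row and column.
#'
#' @param x `expr_matrix` or plain matrix (genes x samples, >= 3 samples).
#' @param genes subset of genes (default all).
#' @return gene x gene correlation matrix.
#' @export
spearman_coexpression <- function(x, genes = rownames(x)) {
  v <- unclass(x)[genes, , drop = FALSE]
  if (ncol(v) < 3) stop("need at least three samples")
  rho <- suppressWarnings(cor(t(v), method = "spearman"))
  const <- apply(v, 1, function(r) max(r) == min(r))
  rho[const, ] <- NA_real_
  rho[, const] <- NA_real_
  rho
}
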