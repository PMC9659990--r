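# The three-dataset screen: thresholds, ratio labels, per-comparison DEGs
# and the cross-dataset intersection, bundled into one report.

#' Default ripening comparisons for the three-dataset screen
#'
#' The riper member of each comparison is the case. Stage dataset: stage 6
#' vs stage 5 per tissue. Ethephon dataset: treated vs control at days 4 and
#' 6 per tissue. Pollination dataset: 100% vs 60% ripeness per treatment and
#' tissue.
#'
#' @param designs named list of design data.frames (stages, ethephon,
#'   pollination), each with sample_id, tissue, stage, treatment, day,
#'   replicate columns as applicable.
#' @return list with `comparisons` (id -> list(dataset, case, control)) and
#'   `groups` (group -> comparison ids).
#' @export
default_screen_comparisons <- function(designs) {
  comp <- list()
  d <- designs$stages
  for (tis in sort(unique(d$tissue))) {
    id <- paste0(toupper(substr(tis, 1, 1)), "6_", toupper(substr(tis, 1, 1)), "5")
    comp[[id]] <- list(dataset = "stages",
                       case = design_samples(d, tissue = tis, stage = 6),
                       control = design_samples(d, tissue = tis, stage = 5))
  }
  d <- designs$ethephon
  for (tis in sort(unique(d$tissue))) for (day in c(2, 4, 6)) {
    cs <- design_samples(d, tissue = tis, day = day, treatment = "ethephon")
    ct <- design_samples(d, tissue = tis, day = day, treatment = "control")
    if (day == 2) next  # the screen uses days 4 and 6
    comp[[paste0("E", day, "_W", day, "_", tis)]] <-
      list(dataset = "ethephon", case = cs, control = ct)
  }
  d <- designs$pollination
  for (trt in sort(unique(d$treatment))) for (tis in sort(unique(d$tissue))) {
    id <- paste0(ifelse(trt == "parthenocarpic", "Par", "Pol"),
                 "100_60_", tis)
    comp[[id]] <- list(dataset = "pollination",
                       case = design_samples(d, tissue = tis, stage = 100,
                                             treatment = trt),
                       control = design_samples(d, tissue = tis, stage = 60,
                                                treatment = trt))
  }
  groups <- list(
    stages = grep("^[FPR]6_", names(comp), value = TRUE),
    ethephon = grep("^E[46]_", names(comp), value = TRUE),
    pollination = grep("^(Par|Pol)100_", names(comp), value = TRUE))
  list(comparisons = comp, groups = groups)
}

#' Run the full three-dataset expression screen
#'
#' Applies the abundance filter (>= 20 FPKM/TPM in at least one sample) per
#' dataset, assigns A/B/C expression groups, tissue dominance and ripening
#' correlation on the developmental dataset, calls DEGs for every ripening
#' comparison, and intersects across comparison groups to nominate key
#' genes.
#'
#' @param stages,ethephon,pollination lists with elements `x` (an
#'   [expr_matrix()]: FPKM for stages, TPM for the other two) and `design`.
#' @param comparisons as from [default_screen_comparisons()]; built
#'   automatically when NULL.
#' @param test DEG test passed to [call_degs()] ("none" reproduces the
#'   fold-change-only rule).
#' @param threshold expression filter (default 20).
#' @return object of class `screen_report`: expressed gene sets, groups,
#'   dominance and correlation tables, DEG tables, key genes with
#'   per-comparison directions.
#' @export
run_screen <- function(stages, ethephon, pollination, comparisons = NULL,
                       test = "none", threshold = 20) {
  datasets <- list(stages = stages, ethephon = ethephon,
                   pollination = pollination)
  if (is.null(comparisons))
    comparisons <- default_screen_comparisons(
      lapply(datasets, function(d) d$design))
  expressed <- lapply(datasets, function(d)
    filter_expressed(d$x, threshold = threshold))
  deg_tables <- list()
  for (id in names(comparisons$comparisons)) {
    cm <- comparisons$comparisons[[id]]
    x <- datasets[[cm$dataset]]$x
    keep <- expressed[[cm$dataset]]
    v <- unclass(x)[keep, , drop = FALSE]
    deg_tables[[id]] <- call_degs(v[, cm$case, drop = FALSE],
                                  v[, cm$control, drop = FALSE],
                                  comparison_id = id, test = test)
  }
  screen <- intersect_screen(deg_tables, comparisons$groups)
  st_expr <- expressed$stages
  structure(list(
    expressed = expressed,
    # level groups cover the whole matrix: group C is exactly the
    # below-filter stratum
    groups = group_by_level(stages$x),
    dominance = {
      d <- classify_dominance(stages$x, stages$design)
      d[d$gene %in% st_expr, , drop = FALSE]
    },
    correlation = {
      d <- classify_ripening_correlation(stages$x, stages$design)
      d[d$gene %in% st_expr, , drop = FALSE]
    },
    deg_tables = deg_tables,
    comparison_groups = comparisons$groups,
    key_genes = screen$key_genes,
    directions = screen$directions), class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat("Three-dataset ripening screen\n")
  for (ds in names(x$expressed))
    cat(sprintf("  %-11s %3d expressed genes\n", ds, length(x$expressed[[ds]])))
  cat("  expression groups:",
      paste(names(table(x$groups)), table(x$groups), sep = "=", collapse = " "),
      "\n")
  dom <- table(x$dominance$dominance)
  cat("  dominance:",
      paste(names(dom), dom, sep = "=", collapse = " "), "\n")
  cor <- table(x$correlation$correlation)
  cat("  ripening correlation (gene x tissue):",
      paste(names(cor), cor, sep = "=", collapse = " "), "\n")
  nsig <- vapply(x$deg_tables, function(t) sum(t$significant), integer(1))
  cat("  DEGs per comparison:",
      paste(names(nsig), nsig, sep = "=", collapse = " "), "\n")
  cat("  key genes (", length(x$key_genes), "):",
      paste(x$key_genes, collapse = ", "), "\n")
  invisible(x)
}

#' Write a screen report to TSV plus a JSON summary
#'
#' @param report a `screen_report`.
#' @param tsv_path per-gene table output (gene, group, dominance,
#'   correlation per tissue, per-comparison direction, key flag).
#' @param json_path summary output (label counts and the key-gene list).
#' @return invisible list of written paths.
#' @export
write_screen_report <- function(report, tsv_path, json_path = NULL) {
  genes <- sort(unique(c(names(report$groups), report$dominance$gene)))
  tab <- data.frame(gene = genes,
                    group = report$groups[genes],
                    stringsAsFactors = FALSE)
  i <- match(genes, report$dominance$gene)
  tab$dominance <- report$dominance$dominance[i]
  for (tis in unique(report$correlation$tissue)) {
    sub <- report$correlation[report$correlation$tissue == tis, ]
    tab[[paste0("correlation_", tis)]] <- sub$correlation[match(genes, sub$gene)]
  }
  for (cmp in names(report$deg_tables)) {
    t <- report$deg_tables[[cmp]]
    j <- match(genes, t$gene)
    tab[[paste0("deg_", cmp)]] <-
      ifelse(!is.na(j) & t$significant[j], t$direction[j], NA_character_)
  }
  tab$key <- tab$gene %in% report$key_genes
  write.table(tab, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(json_path)) {
    summ <- list(
      expressed = lapply(report$expressed, length),
      groups = as.list(table(report$groups)),
      dominance = as.list(table(report$dominance$dominance)),
      correlation = as.list(table(report$correlation$correlation)),
      degs_per_comparison = lapply(report$deg_tables,
                                   function(t) sum(t$significant)),
      key_genes = report$key_genes)
    jsonlite::write_json(summ, json_path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(list(tsv = tsv_path, json = json_path))
}
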