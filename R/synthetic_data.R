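# Deterministic synthetic-data generators with planted ground truth for
# every pipeline stage: protein families with planted domain architectures,
# annotated toy genomes, codon pairs with controlled divergence, and
# replicate count matrices for the three experimental designs.

# Fixed consensus domain blocks. Family members carry mutated copies of
# these, so the domain-hit tables and the fallback consensus scanner agree.
DOMAIN_CONSENSUS <- c(
  AP2 = paste0("SKYRGVRQRPWGKWVAEIRDPKKAARVWLGTFDTAEEAARAYDRAAIEFRG",
               "PRAKLNFPELLI"),  # 63 aa, AP2/ERF DNA-binding block
  B3  = paste0("FEKVLTPSDVGKLNRLVIPKQHAERYFPLDSSNNQNGVLLNFEDRTGKQWRF",
               "RYSYWNSS"))     # 60 aa, B3 block

#' Consensus domain blocks used by the generators and fallback scanner
#' @return named character vector (AP2, B3).
#' @export
domain_consensus <- function() DOMAIN_CONSENSUS

#' Simulation configuration
#'
#' Bundles the seed and every generator parameter with defaults matching the
#' study conditions: 95/20/3/1 subfamily counts (six of the 20 AP2s carrying
#' a single domain), the 6-stage x 2-tissue, ethephon x day x tissue and
#' pollination x ripeness x tissue expression designs with three replicates,
#' and planted dominance (6x), ripening-correlation (3x) and DEG (6x)
#' effects with seven key genes.
#'
#' @param seed integer master seed; fully determines every output.
#' @param family,annotation,kaks,expression named lists overriding the
#'   defaults below.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, family = list(), annotation = list(),
                       kaks = list(), expression = list()) {
  merge_opts <- function(defaults, user) {
    for (k in names(user)) defaults[[k]] <- user[[k]]
    defaults
  }
  structure(list(
    seed = as.integer(seed),
    family = merge_opts(list(
      counts = c(ERF = 95, AP2 = 20, RAV = 3, soloist = 1),
      ap2_single = 6,          # AP2-subfamily members with one domain
      mutation_rate = 0.08,    # substitutions per site vs the exemplar
      backbone = 40,           # residues before the first domain block
      b3_dropout = 0,          # fraction of B3 hits dropped from the TSV
      boundary_jitter = 0,     # +/- residues of domain-boundary noise
      n_motif_ear = 6, n_motif_edll = 4), family),
    annotation = merge_opts(list(
      n_chromosomes = 4, chr_len = 60000L,
      exon_counts = c(1, 1, 12, 2, 1, 4, 1, 3, 1, 2, 1, 5),
      exon_width = 150L, intron_width = 100L), annotation),
    kaks = merge_opts(list(
      n_codons = 300L, target_ks = 0.1, target_ka = 0, n_pairs = 1L), kaks),
    expression = merge_opts(list(
      n_genes = 200L, n_filler = 300L, replicates = 3L,
      nb_size = 50,            # NB size parameter (1/dispersion)
      base_level = 60,         # abundance of an ordinary expressed gene
      level_high = 600, level_low = 5,
      n_high = 30, n_low = 70,
      effect_dominance = 6, effect_correlation = 3, effect_deg = 6,
      n_flesh_dom = 3, n_peel_dom = 9,
      n_pos_cor = 9, n_neg_cor = 27,
      n_stage_deg = c(up = 3, down = 3),
      n_ethephon_deg = c(up = 3, down = 1),
      n_pollination_deg = c(up = 3, down = 0),
      n_key = c(up = 5, down = 2),
      lib_scale = 5), expression)), class = "sim_config")
}

random_aa <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

mutate_aa <- function(seq, rate) {
  aa <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(aa)) < rate)
  for (i in hit) aa[i] <- sample(setdiff(AA20, aa[i]), 1)
  paste(aa, collapse = "")
}

replace_at <- function(seq, start, text) {
  paste0(substring(seq, 1, start - 1), text,
         substring(seq, start + nchar(text)))
}

#' Generate the synthetic protein-family fixture
#'
#' Builds a labeled reference panel (one exemplar per ERF subgroup plus AP2,
#' RAV and soloist), then family members as mutated exemplar copies with
#' planted domain architectures: ERFs with one AP2 block, AP2s with two
#' tandem blocks (a configurable number carry only one), RAVs with AP2 + B3,
#' and one divergent soloist. EAR, R/K-LFGV and EDLL motifs are planted into
#' designated members (one ERF carries EAR in both the middle and the
#' C-terminal region). Domain hits are emitted at the recorded coordinates,
#' optionally with boundary jitter and B3 dropout.
#'
#' @param config a [sim_config()].
#' @param outdir optional directory; writes proteins.faa, domains.tsv,
#'   panel.faa and truth.json.
#' @return list: `proteins` (named vector), `hits` (data.frame), `panel`
#'   ([reference_panel()]), `truth` (subfamily and motif tables).
#' @export
make_family_fixture <- function(config = sim_config(), outdir = NULL) {
  set.seed(config$seed + 101L)
  fc <- config$family
  bb <- fc$backbone
  ap2 <- DOMAIN_CONSENSUS[["AP2"]]; b3 <- DOMAIN_CONSENSUS[["B3"]]
  wa <- nchar(ap2); wb <- nchar(b3)
  erf_groups <- setdiff(erf_subgroup_labels(), c("AP2", "RAV", "soloist"))

  build_exemplar <- function(label) {
    if (label == "AP2") {
      seq <- paste0(random_aa(bb), ap2, random_aa(45), ap2, random_aa(60))
      dom <- data.frame(domain = c("AP2", "AP2"),
                        start = c(bb + 1, bb + wa + 45 + 1),
                        end = c(bb + wa, bb + wa + 45 + wa))
    } else if (label == "RAV") {
      seq <- paste0(random_aa(bb), ap2, random_aa(45), b3, random_aa(50))
      dom <- data.frame(domain = c("AP2", "B3"),
                        start = c(bb + 1, bb + wa + 45 + 1),
                        end = c(bb + wa, bb + wa + 45 + wb))
    } else if (label == "soloist") {
      seq <- paste0(random_aa(bb), mutate_aa(ap2, 0.3), random_aa(105))
      dom <- data.frame(domain = "AP2", start = bb + 1, end = bb + wa)
    } else {
      seq <- paste0(random_aa(bb), ap2, random_aa(105))
      dom <- data.frame(domain = "AP2", start = bb + 1, end = bb + wa)
    }
    list(seq = seq, dom = dom)
  }
  labels <- c(erf_groups, "AP2", "RAV", "soloist")
  exemplars <- lapply(setNames(labels, labels), build_exemplar)
  panel <- reference_panel(paste0("AT_", labels),
                           vapply(exemplars, `[[`, character(1), "seq"),
                           labels)

  n_total <- sum(fc$counts)
  ids <- sprintf("FCD_%08d", seq_len(n_total))
  member_groups <- c(
    rep(erf_groups, length.out = fc$counts[["ERF"]]),
    rep("AP2", fc$counts[["AP2"]]),
    rep("RAV", fc$counts[["RAV"]]),
    rep("soloist", fc$counts[["soloist"]]))
  proteins <- character(n_total)
  hit_rows <- list(); truth_rows <- list()
  ap2_members <- which(member_groups == "AP2")
  single_ap2 <- utils::tail(ap2_members, fc$ap2_single)
  for (i in seq_len(n_total)) {
    g <- member_groups[i]
    ex <- exemplars[[g]]
    seq <- ex$seq; dom <- ex$dom
    if (i %in% single_ap2) {
      # strip the second AP2 block: genuinely single-domain AP2 member
      seq <- replace_at(seq, dom$start[2], random_aa(wa))
      dom <- dom[1, , drop = FALSE]
    }
    seq <- mutate_aa(seq, fc$mutation_rate)
    # restore exact consensus nowhere: hits are planted coordinates
    proteins[i] <- seq
    hit_rows[[i]] <- data.frame(protein_id = ids[i], domain = dom$domain,
                                start = as.integer(dom$start),
                                end = as.integer(dom$end),
                                score = round(runif(nrow(dom), 80, 120), 1),
                                stringsAsFactors = FALSE)
    truth_rows[[i]] <- data.frame(
      protein_id = ids[i], subfamily = subgroup_to_subfamily(g),
      subgroup = g, n_ap2 = sum(dom$domain == "AP2"),
      n_b3 = sum(dom$domain == "B3"), stringsAsFactors = FALSE)
  }
  names(proteins) <- ids

  # plant motifs into C-terminal tails (after the last domain block)
  erf_idx <- which(member_groups %in% erf_groups)
  rav_idx <- which(member_groups == "RAV")
  n_ear <- min(fc$n_motif_ear, length(erf_idx))
  n_edll <- min(fc$n_motif_edll, length(erf_idx) - n_ear)
  ear_targets <- erf_idx[seq_len(n_ear)]
  edll_targets <- erf_idx[n_ear + seq_len(n_edll)]
  motif_rows <- list()
  plant <- function(i, motif, text, start) {
    proteins[i] <<- replace_at(proteins[[i]], start, text)
    motif_rows[[length(motif_rows) + 1L]] <<- data.frame(
      protein_id = ids[i], motif = motif, start = start,
      end = start + nchar(text) - 1L, matched_text = text,
      stringsAsFactors = FALSE)
  }
  for (i in ear_targets)
    plant(i, "EAR", "LDLNLAP", nchar(proteins[[i]]) - 12L)
  # one ERF with EAR in both the middle and the C-terminal region
  if (length(ear_targets)) {
    dual <- ear_targets[1]
    plant(dual, "EAR", "FDLNFSP",
          as.integer(floor(nchar(proteins[[dual]]) / 2)))
  }
  for (i in edll_targets)
    plant(i, "EDLL", "EDLL", nchar(proteins[[i]]) - 20L)
  for (i in rav_idx[seq_len(min(2, length(rav_idx)))])
    plant(i, "RKLFGV", "RLFGV", nchar(proteins[[i]]) - 8L)

  hits <- do.call(rbind, hit_rows)
  if (fc$boundary_jitter > 0) {
    j <- fc$boundary_jitter
    hits$start <- pmax(1L, hits$start +
                         sample(-j:j, nrow(hits), replace = TRUE))
    hits$end <- hits$end + sample(-j:j, nrow(hits), replace = TRUE)
  }
  if (fc$b3_dropout > 0) {
    drop <- hits$domain == "B3" & runif(nrow(hits)) < fc$b3_dropout
    hits <- hits[!drop, , drop = FALSE]
  }
  truth <- list(subfamily = do.call(rbind, truth_rows),
                motifs = do.call(rbind, motif_rows))
  out <- list(proteins = proteins, hits = hits, panel = panel, truth = truth)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(proteins, file.path(outdir, "proteins.faa"))
    write_domain_hits(hits, file.path(outdir, "domains.tsv"))
    write_reference_panel(panel, file.path(outdir, "panel.faa"))
    jsonlite::write_json(truth, file.path(outdir, "truth_family.json"))
  }
  out
}

#' Generate the synthetic annotated-genome fixture
#'
#' A toy multi-chromosome genome with gene models of controlled exon counts
#' (including one 12-exon gene), a planted adjacent tandem pair, a planted
#' collinear-block (segmental) pair spanning two chromosomes, mixed strands,
#' and one gene close to the contig edge so promoter truncation is
#' exercised.
#'
#' @param config a [sim_config()].
#' @param outdir optional directory; writes genome.fna, genes.gff3,
#'   blocks.tsv and truth.json.
#' @return list: `genome` (named character), `models`, `blocks`, `truth`.
#' @export
make_annotation_fixture <- function(config = sim_config(), outdir = NULL) {
  set.seed(config$seed + 202L)
  ac <- config$annotation
  chrs <- paste0("chr", seq_len(ac$n_chromosomes))
  genome <- setNames(vapply(chrs, function(chr) random_dna(ac$chr_len),
                            character(1)), chrs)
  models <- list(); truth_introns <- list()
  gi <- 0L
  plan <- split(ac$exon_counts,
                rep(chrs, length.out = length(ac$exon_counts)))
  for (chr in chrs) {
    pos <- 3000L
    for (nx in plan[[chr]]) {
      gi <- gi + 1L
      gid <- sprintf("FCG_%05d", gi)
      strand <- if (gi %% 3 == 0) "-" else "+"
      starts <- pos + (seq_len(nx) - 1L) * (ac$exon_width + ac$intron_width)
      ex <- data.frame(start = starts, end = starts + ac$exon_width - 1L)
      cds_start <- if (strand == "+") ex$start[1] else ex$end[nx]
      models[[gid]] <- gene_model(gid, chr, strand,
                                  setNames(list(ex), paste0(gid, ".t1")),
                                  cds_start)
      truth_introns[[gid]] <- nx - 1L
      pos <- max(ex$end) + 2500L
    }
  }
  # tandem pair: adjacent genes on one chromosome (0 intervening)
  tandem <- names(models)[vapply(models, function(m)
    m$chromosome == chrs[1], logical(1))][1:2]
  # segmental pair: registered in a within-species collinear block across
  # two chromosomes
  seg_a <- names(models)[vapply(models, function(m)
    m$chromosome == chrs[1], logical(1))][3]
  seg_b <- names(models)[vapply(models, function(m)
    m$chromosome == chrs[2], logical(1))][1]
  blocks <- data.frame(block_id = "b001", species_a = "focal",
                       gene_a = seg_a, species_b = "focal", gene_b = seg_b,
                       stringsAsFactors = FALSE)
  # near-edge gene on the last chromosome: promoter must truncate
  gi <- gi + 1L
  gid <- sprintf("FCG_%05d", gi)
  ex <- data.frame(start = 500L, end = 949L)
  models[[gid]] <- gene_model(gid, chrs[length(chrs)], "+",
                              setNames(list(ex), paste0(gid, ".t1")), 500L)
  truth_introns[[gid]] <- 0L
  truth <- list(introns = data.frame(gene_id = names(truth_introns),
                                     intron_count = unlist(truth_introns),
                                     row.names = NULL,
                                     stringsAsFactors = FALSE),
                tandem_pair = tandem,
                segmental_pair = c(seg_a, seg_b),
                truncated_gene = gid)
  out <- list(genome = genome, models = models, blocks = blocks,
              truth = truth)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(genome, file.path(outdir, "genome.fna"))
    write_gene_models_gff3(models, file.path(outdir, "genes.gff3"))
    write.table(blocks, file.path(outdir, "blocks.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(truth, file.path(outdir, "truth_annotation.json"))
  }
  out
}

#' Generate codon-sequence pairs with controlled divergence
#'
#' Starts from a random stop-free ancestor CDS and plants substitutions per
#' position: a synonymous change with probability pS* x f_i and a
#' nonsynonymous change with probability pN* x (1 - f_i), where f_i is the
#' position's synonymous site fraction and pS*, pN* are the Jukes-Cantor
#' expected difference proportions for the target Ks and Ka. No stop codons
#' are ever introduced.
#'
#' @param config a [sim_config()]; `config$kaks` holds `n_codons`,
#'   `target_ks`, `target_ka` and `n_pairs`.
#' @param outdir optional directory; writes pairs.fna and truth.json.
#' @return list: `ancestor`, `derived` (character vector of length
#'   `n_pairs`), `truth` (targets).
#' @export
make_codon_fixture <- function(config = sim_config(), outdir = NULL) {
  set.seed(config$seed + 303L)
  kc <- config$kaks
  if (kc$target_ks < 0 || kc$target_ka < 0) stop("targets must be >= 0")
  jc_p <- function(k) 3 / 4 * (1 - exp(-4 * k / 3))
  ps <- jc_p(kc$target_ks); pn <- jc_p(kc$target_ka)
  gc <- codon_table()
  sense <- names(gc)[gc != "*"]
  ancestor_codons <- sample(sense, kc$n_codons, replace = TRUE)
  frac <- ng86_frac_matrix()
  muts <- ng86_mutation_sets()
  if (kc$target_ks > 0 && sum(frac[, ancestor_codons]) == 0)
    stop("no synonymous sites available: sequence too short/degenerate")
  mutate_once <- function() {
    codons <- ancestor_codons
    for (ci in seq_along(codons)) {
      for (pos in 1:3) {
        f <- frac[pos, codons[ci]]
        u <- runif(1)
        alt <- muts[[codons[ci]]][[pos]]
        if (u < ps * f && length(alt$syn)) {
          codons[ci] <- alt$syn[sample.int(length(alt$syn), 1)]
        } else if (u < ps * f + pn * (1 - f) && length(alt$non)) {
          codons[ci] <- alt$non[sample.int(length(alt$non), 1)]
        }
      }
    }
    paste(codons, collapse = "")
  }
  derived <- vapply(seq_len(kc$n_pairs), function(i) mutate_once(),
                    character(1))
  ancestor <- paste(ancestor_codons, collapse = "")
  out <- list(ancestor = ancestor, derived = derived,
              truth = list(target_ks = kc$target_ks,
                           target_ka = kc$target_ka))
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    seqs <- c(setNames(ancestor, "ancestor"),
              setNames(derived, paste0("derived_", seq_along(derived))))
    write_fasta(seqs, file.path(outdir, "pairs.fna"))
    jsonlite::write_json(out$truth, file.path(outdir, "truth_codon.json"))
  }
  out
}

#' Generate the three-dataset expression fixture with planted truth
#'
#' Negative-binomial count matrices for the developmental (6 stages x flesh/
#' peel), ethephon (treated vs control x days 2/4/6 x flesh/receptacle) and
#' pollination (parthenocarpic vs pollinated x 60/100% ripeness x flesh/
#' receptacle) designs, sharing one gene universe. Planted, multiplicative
#' effects give analytically known ratio labels: tissue-dominant genes (6x),
#' ripening-correlated genes (3x on late stages), per-comparison DEGs (6x)
#' and a key-gene set differentially regulated in every comparison group
#' (five up, two down by default). Filler genes carry the remaining library
#' mass so realized FPKM/TPM values sit near their targets.
#'
#' @param config a [sim_config()].
#' @param outdir optional directory; writes counts/design/lengths TSVs per
#'   dataset and truth.json.
#' @return list: per dataset a list(counts [expr_matrix], design, unit);
#'   `lengths`; `truth` (dominance, correlation, groups, degs, key_genes,
#'   expressed).
#' @export
make_expression_fixture <- function(config = sim_config(), outdir = NULL) {
  set.seed(config$seed + 404L)
  ec <- config$expression
  ng <- ec$n_genes
  genes <- sprintf("g%03d", seq_len(ng))
  filler <- sprintf("bg%03d", seq_len(ec$n_filler))
  all_genes <- c(genes, filler)
  lengths <- setNames(sample(800:3000, length(all_genes), replace = TRUE),
                      all_genes)

  # baseline abundance targets (FPKM/TPM-scale)
  level <- setNames(rep(ec$base_level, ng), genes)
  level[seq_len(ec$n_high)] <- ec$level_high
  level[(ng - ec$n_low + 1):ng] <- ec$level_low

  # planted gene roles, drawn from the ordinary expressed range
  take <- local({
    pool <- genes[(ec$n_high + 1):(ng - ec$n_low)]
    function(n) {
      stopifnot(n <= length(pool))
      out <- pool[seq_len(n)]; pool <<- pool[-seq_len(n)]; out
    }
  })
  flesh_dom <- take(ec$n_flesh_dom)
  peel_dom <- take(ec$n_peel_dom)
  pos_cor <- take(ec$n_pos_cor)
  neg_cor <- take(ec$n_neg_cor)
  stage_up <- take(ec$n_stage_deg[["up"]])
  stage_dn <- take(ec$n_stage_deg[["down"]])
  eth_up <- take(ec$n_ethephon_deg[["up"]])
  eth_dn <- take(ec$n_ethephon_deg[["down"]])
  pol_up <- take(ec$n_pollination_deg[["up"]])
  pol_dn <- if (ec$n_pollination_deg[["down"]] > 0)
    take(ec$n_pollination_deg[["down"]]) else character()
  key_up <- take(ec$n_key[["up"]])
  key_dn <- take(ec$n_key[["down"]])
  key <- c(key_up, key_dn)

  designs <- list(
    stages = expand.grid(tissue = c("flesh", "peel"), stage = 1:6,
                         replicate = seq_len(ec$replicates),
                         stringsAsFactors = FALSE),
    ethephon = expand.grid(tissue = c("flesh", "receptacle"), day = c(2, 4, 6),
                           treatment = c("ethephon", "control"),
                           replicate = seq_len(ec$replicates),
                           stringsAsFactors = FALSE),
    pollination = expand.grid(tissue = c("flesh", "receptacle"),
                              stage = c(60, 100),
                              treatment = c("parthenocarpic", "pollinated"),
                              replicate = seq_len(ec$replicates),
                              stringsAsFactors = FALSE))
  designs$stages$sample_id <- with(designs$stages, paste0(
    toupper(substr(tissue, 1, 1)), stage, "_r", replicate))
  designs$ethephon$sample_id <- with(designs$ethephon, paste0(
    ifelse(treatment == "ethephon", "E", "W"), day, "_", tissue,
    "_r", replicate))
  designs$pollination$sample_id <- with(designs$pollination, paste0(
    ifelse(treatment == "parthenocarpic", "Par", "Pol"), stage, "_", tissue,
    "_r", replicate))
  designs$stages$dataset <- "stages"
  designs$ethephon$dataset <- "ethephon"
  designs$pollination$dataset <- "pollination"
  designs$stages$treatment <- "none"
  designs$stages$day <- NA; designs$pollination$day <- NA
  designs$ethephon$stage <- NA

  ef <- ec$effect_deg; cf <- ec$effect_correlation; df <- ec$effect_dominance

  effect_matrix <- function(design) {
    e <- matrix(1, nrow = length(all_genes), ncol = nrow(design),
                dimnames = list(all_genes, design$sample_id))
    e
  }
  effects <- lapply(designs, effect_matrix)

  d <- designs$stages
  effects$stages[flesh_dom, d$tissue == "flesh"] <- df
  effects$stages[peel_dom, d$tissue == "peel"] <- df
  effects$stages[pos_cor, d$stage >= 4] <- cf
  effects$stages[neg_cor, d$stage >= 4] <- 1 / cf
  effects$stages[c(stage_up, key_up), d$stage == 6] <- ef
  effects$stages[c(stage_dn, key_dn), d$stage == 6] <- 1 / ef
  d <- designs$ethephon
  eth_sel <- d$treatment == "ethephon" & d$day %in% c(4, 6)
  effects$ethephon[c(eth_up, key_up), eth_sel] <- ef
  effects$ethephon[c(eth_dn, key_dn), eth_sel] <- 1 / ef
  d <- designs$pollination
  ripe_sel <- d$stage == 100
  effects$pollination[c(pol_up, key_up), ripe_sel] <- ef
  effects$pollination[c(pol_dn, key_dn), ripe_sel] <- 1 / ef

  units <- c(stages = "FPKM", ethephon = "TPM", pollination = "TPM")
  datasets <- list()
  for (ds in names(designs)) {
    lev <- c(level, setNames(rep(0, ec$n_filler), filler))
    # filler absorbs the remaining library mass so realized units match the
    # targets: FPKM needs sum(level * length) = 1e9, TPM needs
    # sum(level) = 1e6
    if (units[[ds]] == "FPKM") {
      rem <- 1e9 - sum(lev[genes] * lengths[genes])
      lev[filler] <- rem / sum(lengths[filler])
    } else {
      rem <- 1e6 - sum(lev[genes])
      lev[filler] <- rem / length(filler)
    }
    mu <- lev * lengths / 1000 * ec$lib_scale
    mu_mat <- mu * effects[[ds]]
    counts <- matrix(
      rnbinom(length(mu_mat), mu = mu_mat, size = ec$nb_size),
      nrow = nrow(mu_mat), dimnames = dimnames(mu_mat))
    datasets[[ds]] <- list(
      counts = expr_matrix(counts, "counts", lengths),
      design = designs[[ds]], unit = units[[ds]])
  }

  # analytic truth from the planted multiplicative effects
  dominance <- setNames(rep("none", ng), genes)
  dominance[flesh_dom] <- "flesh"; dominance[peel_dom] <- "peel"
  cor_ratio_up <- (2 + ef) / 3        # one late stage shifted by ef
  lab_from_ratio <- function(r) ifelse(r > 2, "positive",
                                       ifelse(r < 0.5, "negative", "none"))
  correlation <- setNames(rep("none", ng), genes)
  correlation[pos_cor] <- "positive"; correlation[neg_cor] <- "negative"
  correlation[c(stage_up, key_up)] <- lab_from_ratio(cor_ratio_up)
  correlation[c(stage_dn, key_dn)] <- lab_from_ratio((2 + 1 / ef) / 3)

  max_effect <- apply(effects$stages[genes, , drop = FALSE], 1, max)
  exp_max_fpkm <- level * max_effect
  groups <- setNames(ifelse(exp_max_fpkm >= 300, "A",
                            ifelse(exp_max_fpkm >= 20, "B", "C")), genes)

  expressed <- lapply(names(designs), function(ds) {
    mx <- apply(effects[[ds]][genes, , drop = FALSE], 1, max) * level
    genes[mx >= 20]
  })
  names(expressed) <- names(designs)

  degs <- list(
    F6_F5 = c(stage_up, stage_dn, key),
    P6_P5 = c(stage_up, stage_dn, key),
    E4_W4_flesh = c(eth_up, eth_dn, key),
    E4_W4_receptacle = c(eth_up, eth_dn, key),
    E6_W6_flesh = c(eth_up, eth_dn, key),
    E6_W6_receptacle = c(eth_up, eth_dn, key),
    Par100_60_flesh = c(pol_up, pol_dn, key),
    Par100_60_receptacle = c(pol_up, pol_dn, key),
    Pol100_60_flesh = c(pol_up, pol_dn, key),
    Pol100_60_receptacle = c(pol_up, pol_dn, key))
  degs <- lapply(degs, sort)

  truth <- list(genes = genes, dominance = dominance,
                correlation = correlation, groups = groups,
                expressed = expressed, degs = degs,
                key_genes = sort(key),
                roles = list(flesh_dom = flesh_dom, peel_dom = peel_dom,
                             pos_cor = pos_cor, neg_cor = neg_cor,
                             stage_up = stage_up, stage_dn = stage_dn,
                             eth_up = eth_up, eth_dn = eth_dn,
                             pol_up = pol_up, pol_dn = pol_dn,
                             key_up = key_up, key_dn = key_dn))
  out <- list(stages = datasets$stages, ethephon = datasets$ethephon,
              pollination = datasets$pollination, lengths = lengths,
              truth = truth)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    for (ds in names(designs)) {
      write_expression_tsv(datasets[[ds]]$counts,
                           file.path(outdir, paste0(ds, "_counts.tsv")))
      write.table(datasets[[ds]]$design,
                  file.path(outdir, paste0(ds, "_design.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write.table(data.frame(gene = names(lengths), length = lengths),
                file.path(outdir, "lengths.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(truth, file.path(outdir, "truth_expression.json"))
  }
  out
}

#' Run the full screen on a synthetic expression fixture
#'
#' Normalises each dataset's counts to its declared unit and runs
#' [run_screen()].
#'
#' @param fixture result of [make_expression_fixture()].
#' @param ... passed to [run_screen()].
#' @return a `screen_report`.
#' @export
screen_fixture <- function(fixture, ...) {
  norm <- function(ds) {
    x <- if (ds$unit == "FPKM") compute_fpkm(ds$counts)
         else compute_tpm(ds$counts)
    list(x = x, design = ds$design)
  }
  run_screen(norm(fixture$stages), norm(fixture$ethephon),
             norm(fixture$pollination), ...)
}
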