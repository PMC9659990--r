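test_that("candidate merging is the confirmed union of both screens", {
  expect_equal(merge_candidates(c("a", "b"), c("b", "c"), c("a", "b", "c")),
               c("a", "b", "c"))
  expect_equal(merge_candidates("a", "b", "a"), "a")
  expect_equal(merge_candidates(character(), character(), character()),
               character())
  # order-free
  expect_equal(merge_candidates(c("b", "a"), c("c", "b"), c("c", "b", "a")),
               merge_candidates(c("a", "b"), c("b", "c"), c("a", "b", "c")))
})

make_tiny_panel <- function() {
  set.seed(42)
  reference_panel(
    ids = c("AT_III", "AT_IX", "AT_AP2", "AT_RAV", "AT_solo"),
    sequences = vapply(1:5, function(i) random_protein(80), character(1)),
    subgroups = c("III", "IX", "AP2", "RAV", "soloist"))
}

test_that("domain architecture decides the subfamily", {
  panel <- make_tiny_panel()
  hit <- function(dom, s, e) data.frame(protein_id = "p", domain = dom,
                                        start = s, end = e, score = 100)
  seq_ix <- panel$sequences[2]  # nearest reference will be AT_IX
  two_ap2 <- rbind(hit("AP2", 10, 75), hit("AP2", 110, 175))
  expect_equal(classify_subfamily(two_ap2, panel, seq_ix)$subfamily, "AP2")
  ap2_b3 <- rbind(hit("AP2", 10, 75), hit("B3", 120, 190))
  expect_equal(classify_subfamily(ap2_b3, panel, seq_ix)$subfamily, "RAV")
  one <- hit("AP2", 10, 75)
  call <- classify_subfamily(one, panel, seq_ix)
  expect_equal(call$subfamily, "ERF")
  expect_equal(call$subgroup, "IX")
  solo <- classify_subfamily(one, panel, panel$sequences[5])
  expect_equal(solo$subfamily, "soloist")
  # single AP2 domain nearest to an AP2-labeled reference is AP2 subfamily
  ap2_like <- classify_subfamily(one, panel, panel$sequences[3])
  expect_equal(ap2_like$subfamily, "AP2")
  expect_error(classify_subfamily(hit("B3", 5, 60), panel, seq_ix),
               "no AP2 domain")
})

test_that("subgroup assignment picks the best global alignment with a
           deterministic tie rule", {
  panel <- make_tiny_panel()
  for (i in seq_along(panel$ids)) {
    r <- assign_subgroup(panel$sequences[i], panel)
    expect_equal(r$subgroup, panel$subgroups[i])
  }
  # exact tie between duplicated entries goes to the smallest reference id
  dup <- reference_panel(c("AT2", "AT1"), rep(panel$sequences[1], 2),
                         c("IX", "III"))
  expect_equal(assign_subgroup(panel$sequences[1], dup)$nearest_reference,
               "AT1")
  expect_error(assign_subgroup("MKV", reference_panel(character(),
                                                      character(),
                                                      character())))
})

test_that("alignment scores agree with an independent affine-gap DP", {
  data(BLOSUM62, package = "Biostrings", envir = environment())
  set.seed(7)
  for (rep in 1:6) {
    a <- random_protein(sample(8:14, 1))
    b <- random_protein(sample(8:14, 1))
    panel <- reference_panel("R1", b, "III")
    got <- assign_subgroup(a, panel)$score
    expect_equal(got, gotoh_score(a, b, BLOSUM62), tolerance = 1e-9)
  }
  # and the assignment follows the higher DP score
  set.seed(8)
  target <- random_protein(30)
  near <- target
  substr(near, 3, 3) <- "W"
  far <- random_protein(30)
  panel <- reference_panel(c("near", "far"), c(near, far), c("Va", "Xb"))
  expect_equal(assign_subgroup(target, panel)$subgroup, "Va")
})

test_that("panel order does not change the assignment", {
  set.seed(11)
  panel <- make_tiny_panel()
  q <- panel$sequences[4]
  perm <- sample(seq_along(panel$ids))
  shuffled <- reference_panel(panel$ids[perm], panel$sequences[perm],
                              panel$subgroups[perm])
  expect_equal(assign_subgroup(q, panel), assign_subgroup(q, shuffled))
})

test_that("C-terminal motif detection matches the documented patterns", {
  m <- detect_cterm_motifs("MAAALDLNLAP")
  expect_equal(nrow(m), 1L)
  expect_equal(m$motif, "EAR")
  expect_equal(m$matched_text, "LDLNLAP")
  m <- detect_cterm_motifs("MKRKLFGVQ")
  expect_equal(m$motif, "RKLFGV")
  expect_equal(m$matched_text, "KLFGV")
  expect_equal(nrow(detect_cterm_motifs("MFDLNF")), 0L)  # no x-P tail
  m <- detect_cterm_motifs("MEDLLHD")
  expect_equal(m$motif, "EDLL")
  # X never satisfies a motif class, including the wildcard position
  expect_equal(nrow(detect_cterm_motifs("MAAXLDLNLXP")), 0L)
  expect_error(detect_cterm_motifs("MKV", patterns = c("[ML")),
               "named")
})

test_that("motif hit positions re-slice to the matched text", {
  fx <- make_family_fixture(sim_config(3, family = list(
    counts = c(ERF = 20, AP2 = 4, RAV = 2, soloist = 1), ap2_single = 1)))
  hits <- scan_motifs(fx$proteins)
  expect_gt(nrow(hits), 0)
  for (i in seq_len(nrow(hits)))
    expect_equal(substring(fx$proteins[[hits$protein_id[i]]],
                           hits$start[i], hits$end[i]),
                 hits$matched_text[i])
  # every planted motif is recovered at its planted coordinates
  planted <- fx$truth$motifs
  found <- paste(hits$protein_id, hits$motif, hits$start)
  expect_true(all(paste(planted$protein_id, planted$motif, planted$start)
                  %in% found))
})

test_that("protein properties follow the residue-mass and charge models", {
  g <- protein_properties("G")
  expect_equal(g$length, 1L)
  expect_equal(g$molecular_weight, 57.0519 + 18.0153, tolerance = 1e-6)
  expect_equal(protein_properties("ACDEFGHIKLMNPQRSTVWY")$length, 20L)
  expect_lt(protein_properties("DDDD")$pI, protein_properties("KKKK")$pI)
  expect_error(protein_properties(""), "empty")
  expect_error(protein_properties("GZ"), "invalid")
  # X contributes length but no mass
  expect_equal(protein_properties("GXG")$molecular_weight,
               2 * 57.0519 + 18.0153, tolerance = 1e-6)
  expect_equal(protein_properties("GXG")$length, 3L)
})

test_that("molecular weight is additive up to one water", {
  set.seed(5)
  for (i in 1:5) {
    s1 <- random_protein(sample(5:30, 1))
    s2 <- random_protein(sample(5:30, 1))
    expect_equal(protein_properties(paste0(s1, s2))$molecular_weight,
                 protein_properties(s1)$molecular_weight +
                   protein_properties(s2)$molecular_weight - 18.0153,
                 tolerance = 1e-6)
  }
})

test_that("pI agrees with a root-finding oracle on the charge equation", {
  # independent root via uniroot on the same documented pKa model
  charge <- function(seq, pH) {
    counts <- table(strsplit(seq, "")[[1]])
    n_of <- function(a) if (a %in% names(counts)) as.numeric(counts[[a]]) else 0
    pos <- 1 / (1 + 10^(pH - 8.6)) +
      n_of("K") / (1 + 10^(pH - 10.8)) +
      n_of("R") / (1 + 10^(pH - 12.5)) +
      n_of("H") / (1 + 10^(pH - 6.5))
    neg <- 1 / (1 + 10^(3.6 - pH)) +
      n_of("D") / (1 + 10^(3.9 - pH)) +
      n_of("E") / (1 + 10^(4.1 - pH)) +
      n_of("C") / (1 + 10^(8.5 - pH)) +
      n_of("Y") / (1 + 10^(10.1 - pH))
    pos - neg
  }
  set.seed(12)
  for (i in 1:5) {
    s <- random_protein(40)
    root <- stats::uniroot(function(p) charge(s, p), c(0, 14))$root
    expect_equal(protein_properties(s)$pI, root, tolerance = 0.011)
  }
})

test_that("every protein with an AP2 hit gets exactly one subfamily", {
  fx <- make_family_fixture(sim_config(2, family = list(
    counts = c(ERF = 15, AP2 = 6, RAV = 2, soloist = 1), ap2_single = 2)))
  calls <- classify_family(fx$proteins, fx$hits, fx$panel)
  expect_equal(nrow(calls), length(fx$proteins))
  expect_true(all(calls$subfamily %in% c("ERF", "AP2", "RAV", "soloist")))
  expect_false(anyDuplicated(calls$protein_id) > 0)
})

test_that("dropped B3 hits degrade RAV recall without mislabeling as AP2", {
  fx <- make_family_fixture(sim_config(4, family = list(
    counts = c(ERF = 6, AP2 = 3, RAV = 4, soloist = 1), ap2_single = 1,
    b3_dropout = 1)))  # every B3 hit dropped
  expect_false(any(fx$hits$domain == "B3"))
  calls <- classify_family(fx$proteins, fx$hits, fx$panel)
  rav_truth <- fx$truth$subfamily$protein_id[
    fx$truth$subfamily$subfamily == "RAV"]
  got <- calls$subfamily[match(rav_truth, calls$protein_id)]
  # nearest-reference evidence still recovers them; never "AP2 with 2 domains"
  expect_false(any(got == "AP2"))
  expect_true(all(got == "RAV"))
})

test_that("the consensus fallback scanner finds planted domain blocks", {
  fx <- make_family_fixture(sim_config(6, family = list(
    counts = c(ERF = 3, AP2 = 1, RAV = 1, soloist = 0), ap2_single = 0,
    mutation_rate = 0.05)))
  found <- scan_consensus_domains(fx$proteins)
  # every planted hit is rediscovered at its coordinates
  planted <- fx$hits
  key <- paste(found$protein_id, found$domain, found$start, found$end)
  expect_true(all(paste(planted$protein_id, planted$domain, planted$start,
                        planted$end) %in% key))
})
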