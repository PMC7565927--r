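fx <- wif1_fixtures()

test_that("cysteine-anchored alignment pads loops against the next anchor", {
  d1 <- domain_from_string("CAACAGTGTCAAACVCAAAAAAAAC", id = "a")
  aln <- align_domains_by_cysteines(list(d1, d1))
  expect_equal(aln$rows$gapped[1], aln$rows$gapped[2])
  expect_false(grepl("-", aln$rows$gapped[1], fixed = TRUE))
  # C2-C3 loops of length 5 vs 6: the shorter row gets exactly one gap,
  # immediately before the C3 anchor column.
  d2 <- domain_from_string("CAACAGGTGTCAAACVCAAAAAAAAC", id = "b")
  aln2 <- align_domains_by_cysteines(list(d1, d2))
  g1 <- strsplit(aln2$rows$gapped[1], "")[[1]]
  expect_equal(sum(g1 == "-"), 1L)
  expect_equal(which(g1 == "-"), aln2$anchor_columns[3] - 1L)
  expect_error(align_domains_by_cysteines(list()),
               class = "egfofuc_empty_input_error")
})

test_that("alignment anchors are all-cysteine, degapping round-trips, order is stable", {
  set.seed(41)
  doms <- lapply(1:20, function(k) {
    domain_from_string(random_domain_string(), id = paste0("d", k))
  })
  aln <- align_domains_by_cysteines(doms)
  mat <- do.call(rbind, strsplit(aln$rows$gapped, ""))
  for (col in aln$anchor_columns) {
    expect_true(all(mat[, col] == "C"))
  }
  expect_equal(degap(aln$rows$gapped),
               vapply(doms, `[[`, character(1), "sequence"))
  # Permutation stability: shuffling the input only permutes the rows.
  perm <- sample(length(doms))
  aln_p <- align_domains_by_cysteines(doms[perm])
  expect_equal(aln_p$rows$gapped, aln$rows$gapped[perm])
  expect_equal(aln_p$anchor_columns, aln$anchor_columns)
})

test_that("site matrix encodes the mouse and platypus configurations", {
  flank <- function(n) strrep("G", n)
  mouse_domains <- paste0(
    flank(5), "CTTVCAGGGACNDGKCVCNSGYSGDAC",                     # I, no site
    flank(4), "CTTVCAGGGNCNDGKCVCNSGYSGDAC",                     # II, no site
    flank(4), fx$synthetic_domains[["egf3_synthetic"]],           # III, site
    flank(4), "CTTVCAGGGQCNDGKCVCNSGYSGDAC",                     # IV, no site
    flank(4), fx$synthetic_domains[["egf5_synthetic"]],           # V, site
    flank(5))
  mouse <- protein_record("wif1_mouse", mouse_domains,
                          species = "Mus_musculus")
  m_doms <- detect_egf_domains(mouse)
  expect_length(m_doms, 5)
  for (k in 1:5) m_doms[[k]]$slot <- c("I", "II", "III", "IV", "V")[k]
  platypus_domains <- paste0(
    flank(5), fx$synthetic_domains[["platypus_egf1_synthetic"]],  # I, site
    flank(4), "CTTVCAGGGNCNDGKCVCNSGYSGDAC",                     # II
    flank(4), fx$synthetic_domains[["platypus_egf3_synthetic"]],  # III, no site
    flank(4), "CTTVCAGGGQCNDGKCVCNSGYSGDAC",                     # IV
    flank(4), fx$synthetic_domains[["egf5_synthetic"]],           # V, site
    flank(5))
  platypus <- protein_record("wif1_platypus", platypus_domains,
                             species = "Ornithorhynchus_anatinus")
  p_doms <- detect_egf_domains(platypus)
  expect_length(p_doms, 5)
  for (k in 1:5) p_doms[[k]]$slot <- c("I", "II", "III", "IV", "V")[k]
  m <- build_site_matrix(list(Mus_musculus = m_doms,
                              Ornithorhynchus_anatinus = p_doms))
  expect_equal(unname(m["Mus_musculus", ]),
               c("absent", "absent", "present", "absent", "present"))
  expect_equal(m["Ornithorhynchus_anatinus", "I"], c(I = "present"),
               ignore_attr = TRUE)
  expect_equal(unname(m["Ornithorhynchus_anatinus", "III"]), "absent")
  # Duplicate slot labels are refused.
  dup <- m_doms; dup[[2]]$slot <- "I"
  expect_error(build_site_matrix(list(sp = dup)),
               class = "egfofuc_duplicate_slot_error")
})

test_that("site matrix of a simulated family matches the generator's truth", {
  cfg <- simulation_config(seed = 404, n_leaves = 10)
  sim <- simulate_ortholog_family(cfg)
  domain_sets <- lapply(sim$proteins, detect_egf_domains)
  m <- build_site_matrix(domain_sets)
  expect_equal(unclass(m)[rownames(sim$truth$site_matrix), ],
               unclass(sim$truth$site_matrix))
  # Zero-mutation family: constant across species.
  cfg0 <- simulation_config(seed = 405, n_leaves = 8, gain_prob = 0,
                            loss_prob = 0, sub_rate = 0)
  sim0 <- simulate_ortholog_family(cfg0)
  m0 <- sim0$truth$site_matrix
  expect_true(all(apply(m0, 2, function(col) length(unique(col)) == 1)))
})

test_that("logo classes follow the uppercase/lowercase/dot thresholds", {
  col_of <- function(chars) {
    logo <- compute_logo(vapply(chars, identity, character(1)))
    logo[1, ]
  }
  expect_equal(col_of(rep("G", 10))$class, "upper")
  expect_equal(col_of(rep("G", 10))$dominant_freq, 1.0)
  expect_equal(col_of(c(rep("T", 6), "A", "G", "K", "V"))$class, "lower")
  expect_equal(col_of(c(rep("K", 4), "A", "G", "T", "V", "S", "N"))$class, "dot")
  # Boundaries are inclusive at exactly 0.80 and 0.50.
  expect_equal(col_of(c(rep("G", 8), "A", "T"))$class, "upper")
  expect_equal(col_of(c(rep("G", 5), "A", "T", "V", "K", "N"))$class, "lower")
  # Frequencies sum to one over non-gap entries.
  set.seed(5)
  rows <- vapply(1:12, function(k) {
    paste(sample(c(AA_POOL, "-"), 30, replace = TRUE), collapse = "")
  }, character(1))
  logo <- compute_logo(rows)
  freq <- attr(logo, "frequencies")
  sums <- colSums(freq)[logo$n > 0]
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("subfamily comparison flags dominant-residue switches above threshold", {
  a <- compute_logo(rep("CFNGGTC", 10))
  expect_false(any(compare_subfamily_logos(a, a)$deviation))
  # The T-in-deuterostomes vs K-in-protostomes column is flagged.
  b <- compute_logo(rep("CFNGGKC", 10))
  cmp <- compare_subfamily_logos(a, b)
  expect_equal(which(cmp$deviation), 6L)
  # Dominant residues differ but A's dominant barely drops: unflagged.
  a2 <- compute_logo(c(rep("T", 6), rep("K", 4)))   # T dominant, freq 0.6
  b2 <- compute_logo(c(rep("K", 6), rep("T", 4)))   # K dominant, T freq 0.4
  cmp2 <- compare_subfamily_logos(a2, b2, threshold = 0.5)
  expect_false(any(cmp2$deviation))
  expect_error(compare_subfamily_logos(a, compute_logo(rep("CFNGGTCA", 4))),
               class = "egfofuc_length_mismatch_error")
})

test_that("pairwise identity and similarity behave like the ident_sim convention", {
  expect_equal(pairwise_identity_similarity("CFNGGTC", "CFNGGTC"),
               c(identity = 100, similarity = 100))
  # No identical and no similar residues anywhere.
  expect_equal(pairwise_identity_similarity("GGGG", "DDDD"),
               c(identity = 0, similarity = 0))
  # S/T are in the same similarity group: similar but not identical.
  r <- pairwise_identity_similarity("CFNGGTC", "CFNGGSC")
  expect_equal(unname(r["identity"]), 100 * 6 / 7)
  expect_equal(unname(r["similarity"]), 100)
  # Columns where either row is a gap leave the denominator.
  r2 <- pairwise_identity_similarity("AC-T", "ACG-")
  expect_equal(unname(r2["identity"]), 100)
  expect_error(pairwise_identity_similarity("ACT", "AC"),
               class = "egfofuc_length_mismatch_error")
  # identity <= similarity <= 100 on random pairs.
  set.seed(9)
  for (rep in 1:200) {
    a <- paste(sample(AA_POOL, 25, replace = TRUE), collapse = "")
    b <- paste(sample(AA_POOL, 25, replace = TRUE), collapse = "")
    r <- pairwise_identity_similarity(a, b)
    expect_lte(r[["identity"]], r[["similarity"]])
    expect_lte(r[["similarity"]], 100)
  }
})
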