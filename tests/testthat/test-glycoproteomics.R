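fx <- wif1_fixtures()

test_that("digestion reproduces the published WIF1 peptides", {
  # Trypsin on the EGF-LD III context releases the 18-residue peptide.
  tryp <- digest(fx$contexts[["egf3_context"]], trypsin())
  expect_true("ANCSTTCFNGGTCFYPGK" %in% tryp$sequence)
  expect_equal(nchar("ANCSTTCFNGGTCFYPGK"), 18L)
  # Trypsin + thermolysin co-digestion of the 18-mer yields FNGGTC.
  co <- digest(fx$peptides[["egf3_tryptic"]], list(trypsin(), thermolysin()))
  expect_true("FNGGTC" %in% co$sequence)
  # The EGF-LD V co-digestion peptide requires one missed thermolysin
  # cleavage.
  co5 <- digest(fx$peptides[["egf5_tryptic"]], list(trypsin(), thermolysin()),
                max_missed = 1)
  hit <- co5[co5$sequence == "VCEPGCGAHGTCHEPNK", ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$missed_cleavages, 1L)
  # ...and is absent at zero missed cleavages.
  co5_0 <- digest(fx$peptides[["egf5_tryptic"]], list(trypsin(), thermolysin()))
  expect_false("VCEPGCGAHGTCHEPNK" %in% co5_0$sequence)
})

test_that("cleavage exceptions: trypsin not before proline, thermolysin P2' rule", {
  # KP survives trypsin.
  expect_equal(digest("AKPGGR", trypsin())$sequence, c("AKPGGR"))
  expect_equal(digest("AKGGR", trypsin())$sequence, c("AK", "GGR"))
  # Thermolysin cuts before V, but not when the residue after V is proline.
  expect_true("VGG" %in% digest("GGVGG", thermolysin())$sequence)
  expect_equal(digest("GGVPG", thermolysin())$sequence, "GGVPG")
})

test_that("level-0 peptides tile the substrate and level-k are adjacent concatenations", {
  set.seed(31)
  for (rules in list(list(trypsin()), list(thermolysin()),
                     list(trypsin(), thermolysin()))) {
    for (rep in 1:20) {
      s <- paste(sample(rownames(as.matrix(residue_masses())),
                        sample(20:60, 1), replace = TRUE), collapse = "")
      d0 <- digest(s, rules, max_missed = 0)
      expect_equal(paste(d0$sequence, collapse = ""), s)
      d2 <- digest(s, rules, max_missed = 2)
      level0 <- d0$sequence
      for (k in seq_len(nrow(d2))) {
        mc <- d2$missed_cleavages[k]
        i <- which(d0$start == d2$start[k])
        expect_equal(d2$sequence[k],
                     paste(level0[i:(i + mc)], collapse = ""))
      }
    }
  }
  # Coordinate offsets shift reported spans into full-protein numbering.
  d <- digest(fx$peptides[["egf3_tryptic"]], list(trypsin(), thermolysin()),
              offset = 243L)
  expect_equal(d$start[d$sequence == "FNGGTC"], 251L)
})

test_that("peptide masses match the elemental-composition oracle", {
  expect_equal(peptide_mass("G", fixed_mods = NULL), 75.03203,
               tolerance = 1e-7)
  # Carbamidomethylation adds exactly one C2H3NO per cysteine.
  delta <- peptide_mass("FNGGTC") - peptide_mass("FNGGTC", fixed_mods = NULL)
  expect_equal(delta, 57.02146, tolerance = 1e-5)
  expect_equal(delta, oracle_formula_mass("C2H3NO"), tolerance = 1e-6)
  # Structural identity: mass(GG) = 2 * residue(G) + water.
  expect_equal(peptide_mass("GG", fixed_mods = NULL),
               2 * residue_masses()[["G"]] + oracle_water(),
               tolerance = 1e-6)
  expect_error(peptide_mass("GXG"), class = "egfofuc_unknown_residue_error")
  # 1000 random peptides against the oracle, within 1e-6 Da.
  set.seed(13)
  aas <- names(ORACLE_RESIDUES)
  for (rep in 1:1000) {
    s <- paste(sample(aas, sample(5:30, 1), replace = TRUE), collapse = "")
    expect_equal(peptide_mass(s), oracle_peptide_mass(s), tolerance = 1e-6)
  }
})

test_that("glycoform series is the O-fucose extension ladder", {
  none <- enumerate_glycoforms(FALSE)
  expect_equal(nrow(none), 1)
  expect_equal(none$delta_mass, 0)
  series <- enumerate_glycoforms(TRUE)
  expect_equal(nrow(series), 5)
  expect_true(all(diff(series$delta_mass) > 0))
  expect_equal(series$delta_mass[2], 146.05791, tolerance = 1e-5)
  expect_equal(series$delta_mass[2], oracle_formula_mass("C6H10O4"),
               tolerance = 1e-6)
  expect_equal(series$delta_mass[3], 349.13728, tolerance = 1e-5)
  expect_equal(series$delta_mass[3],
               oracle_formula_mass("C6H10O4") + oracle_formula_mass("C8H13NO5"),
               tolerance = 1e-6)
  # Delta masses are additive under composition merge.
  merged <- series[3, c("dHex", "HexNAc", "Hex", "NeuAc")] +
    series[2, c("dHex", "HexNAc", "Hex", "NeuAc")]
  expect_equal(glyco_delta_mass(merged),
               series$delta_mass[3] + series$delta_mass[2])
})

test_that("precursor m/z and neutral mass round-trip exactly", {
  m <- peptide_mass("FNGGTC")
  expect_equal(precursor_mz(m, 1), m + 1.007276, tolerance = 1e-6)
  for (z in 1:5) {
    expect_equal(neutral_mass(precursor_mz(m, z), z), m, tolerance = 1e-9)
  }
})

test_that("fragment ions match a sum-of-residues oracle and are glycan-labile", {
  fr <- fragment_ions("FNGGTC")
  y2 <- fr$mz[fr$series == "y" & fr$index == 2 & fr$charge == 1]
  expect_equal(y2, oracle_y_ion("FNGGTC", 2), tolerance = 1e-6)
  for (idx in 1:5) {
    yi <- fr$mz[fr$series == "y" & fr$index == idx]
    expect_equal(yi, oracle_y_ion("FNGGTC", idx), tolerance = 1e-6)
  }
  # b_i + y_(n-i) neutral masses reassemble the peptide.
  n <- nchar("FNGGTC")
  m <- peptide_mass("FNGGTC")
  for (i in 1:(n - 1)) {
    b <- fr$mz[fr$series == "b" & fr$index == i] - 1.00727646688
    y <- fr$mz[fr$series == "y" & fr$index == n - i] - 1.00727646688
    expect_equal(b + y, m, tolerance = 1e-9)
  }
  # Labile convention: the glycan never shifts fragment m/z...
  fr_labile <- fragment_ions("FNGGTC", glyco_delta = 146.0579,
                             site_index = 5)
  expect_equal(fr_labile$mz, fr$mz)
  # ...unless glycan retention is requested, which shifts exactly the
  # site-spanning fragments.
  fr_keep <- fragment_ions("FNGGTC", retain_glycan = TRUE,
                           glyco_delta = 146.0579, site_index = 5)
  shifted <- abs(fr_keep$mz - fr$mz) > 1
  expect_equal(fr_keep$index[shifted & fr_keep$series == "b"], 5L)
  expect_equal(fr_keep$index[shifted & fr_keep$series == "y"], c(2L, 3L, 4L, 5L))
})

test_that("ppm matching implements the strict 10 ppm rule", {
  expect_true(match_ppm(1000, 1000))
  expect_false(match_ppm(1000.0, 1000.011)) # 11 ppm
  expect_true(match_ppm(1000.0, 1000.009))  # 9 ppm
  set.seed(3)
  for (rep in 1:200) {
    theo <- runif(1, 300, 2000)
    obs <- theo * (1 + runif(1, -2e-5, 2e-5))
    expect_identical(match_ppm(theo, obs),
                     1e6 * abs(obs - theo) / theo < 10)
  }
})

test_that("MRM method emits shared fragments across the glycoform ladder", {
  peptides <- data.frame(sequence = "ANCSTTCFNGGTCFYPGK", site_present = TRUE,
                         stringsAsFactors = FALSE)
  method <- build_mrm_method(peptides, charges = c(2, 3), top_n = 6)
  precursors <- unique(method[, c("glycoform", "z", "precursor_mz")])
  expect_equal(nrow(precursors), 10) # 5 glycoforms x 2 charges
  counts <- table(paste(method$glycoform, method$z))
  expect_true(all(counts <= 6))
  # Identical fragment m/z lists between modified and unmodified forms.
  frag_key <- function(g) {
    sel <- method[method$glycoform == g & method$z == 2, ]
    paste(sel$fragment_series, sel$fragment_index, round(sel$fragment_mz, 6))
  }
  expect_equal(frag_key("O-Fuc"), frag_key("unmodified"))
  expect_equal(frag_key("O-Fuc+HexNAc+Hex+NeuAc"), frag_key("unmodified"))
  # Precursor m/z strictly increases along the extension ladder.
  lad <- precursors[precursors$z == 2, ]
  lad <- lad[match(enumerate_glycoforms(TRUE)$glycoform, lad$glycoform), ]
  expect_true(all(diff(lad$precursor_mz) > 0))
  # Export/import round-trip is lossless.
  path <- tempfile(fileext = ".csv")
  write_transitions(method, path)
  back <- read_transitions(path)
  expect_equal(back$transition_id, method$transition_id)
  expect_equal(back$precursor_mz, method$precursor_mz, tolerance = 1e-12)
  expect_equal(back$fragment_mz, method$fragment_mz, tolerance = 1e-12)
})

test_that("occupancy quantitation uses the shared most-abundant fragment", {
  peptides <- data.frame(sequence = "FNGGTC", site_present = TRUE,
                         stringsAsFactors = FALSE)
  method <- build_mrm_method(peptides, charges = 2, top_n = 3)
  mk_peaks <- function(unmod, mod) {
    u <- method[method$glycoform == "unmodified", ]
    m <- method[method$glycoform == "O-Fuc", ]
    data.frame(transition_id = c(u$transition_id, m$transition_id),
               area = c(unmod, mod), stringsAsFactors = FALSE)
  }
  # Equal areas on every fragment: 50%.
  q <- quantify_site_occupancy(mk_peaks(c(10, 5, 2), c(10, 5, 2)), method)
  expect_equal(q$percent_modified, 50)
  # No unmodified signal: 100%.
  q100 <- quantify_site_occupancy(mk_peaks(c(0, 0, 0), c(7, 1, 1)), method)
  expect_equal(q100$percent_modified, 100)
  # The most abundant unmodified fragment is the one used.
  q2 <- quantify_site_occupancy(mk_peaks(c(2, 90, 8), c(1, 30, 100)), method)
  expect_equal(unname(q2$areas), c(90, 30))
  expect_equal(q2$percent_modified, 100 * 30 / 120)
  # Strictly increasing in A_mod with A_unmod fixed.
  pcts <- vapply(c(1, 5, 20, 80), function(a) {
    quantify_site_occupancy(mk_peaks(c(50, 1, 1), c(a, 0, 0)),
                            method)$percent_modified
  }, numeric(1))
  expect_true(all(diff(pcts) > 0))
  # All-zero signal is an error, not a silent 0/0.
  expect_error(quantify_site_occupancy(mk_peaks(c(0, 0, 0), c(0, 0, 0)), method),
               class = "egfofuc_missing_signal_error")
  # Area ties resolve to the lowest fragment m/z.
  tie <- mk_peaks(c(10, 10, 10), c(3, 6, 9))
  qt <- quantify_site_occupancy(tie, method)
  u <- method[method$glycoform == "unmodified", ]
  expect_equal(qt$fragment,
               paste0(u$fragment_series[which.min(u$fragment_mz)],
                      u$fragment_index[which.min(u$fragment_mz)],
                      "^1 (z=2)"))
  # Extended glycoforms can be pulled into the denominator on demand.
  x <- method[method$glycoform == "O-Fuc+HexNAc", ]
  peaks_ext <- rbind(mk_peaks(c(10, 0, 0), c(10, 0, 0)),
                     data.frame(transition_id = x$transition_id,
                                area = c(20, 0, 0)))
  q_ext <- quantify_site_occupancy(peaks_ext, method, include_extended = TRUE)
  expect_equal(q_ext$percent_modified, 100 * 30 / 40)
})
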