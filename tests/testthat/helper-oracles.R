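## Independent oracles used across the suite. These deliberately re-derive
## quantities by a different route than the package (different element mass
## source, different formula encoding, brute-force enumeration) so they can
## catch implementation errors.

# --- Elemental-composition mass oracle ------------------------------------

ORACLE_ELEMENTS <- c(C = 12.0, H = 1.00782503207, N = 14.0030740048,
                     O = 15.9949146196, S = 31.97207117)
ORACLE_PROTON <- 1.007276466879

ORACLE_RESIDUES <- c(
  A = "C3H5NO", R = "C6H12N4O", N = "C4H6N2O2", D = "C4H5NO3",
  C = "C3H5NOS", E = "C5H7NO3", Q = "C5H8N2O2", G = "C2H3NO",
  H = "C6H7N3O", I = "C6H11NO", L = "C6H11NO", K = "C6H12N2O",
  M = "C5H9NOS", F = "C9H9NO", P = "C5H7NO", S = "C3H5NO2",
  T = "C4H7NO2", W = "C11H10N2O", Y = "C9H9NO2", V = "C5H9NO")

ORACLE_GLYCANS <- c(dHex = "C6H10O4", HexNAc = "C8H13NO5",
                    Hex = "C6H10O5", NeuAc = "C11H17NO8")

oracle_formula_mass <- function(formula) {
  m <- regmatches(formula, gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
  total <- 0
  for (tok in m) {
    el <- gsub("[0-9]", "", tok)
    n <- gsub("[A-Za-z]", "", tok)
    n <- if (nzchar(n)) as.integer(n) else 1L
    total <- total + ORACLE_ELEMENTS[[el]] * n
  }
  total
}

oracle_water <- function() oracle_formula_mass("H2O")

oracle_peptide_mass <- function(sequence, cam = TRUE) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  m <- sum(vapply(ORACLE_RESIDUES[chars], oracle_formula_mass, numeric(1))) +
    oracle_water()
  if (cam) m <- m + sum(chars == "C") * oracle_formula_mass("C2H3NO")
  m
}

# y-ion m/z from first principles: sum of the last `index` residues + water,
# protonated.
oracle_y_ion <- function(sequence, index, z = 1, cam = TRUE) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  suffix <- paste(chars[(length(chars) - index + 1):length(chars)],
                  collapse = "")
  (oracle_peptide_mass(suffix, cam = cam) + z * ORACLE_PROTON) / z
}

# --- Exhaustive parsimony oracle ------------------------------------------

# Minimum change count of a binary character on a rooted tree by brute-force
# enumeration of every internal labeling (and every resolution of '?' leaves).
oracle_fitch_min <- function(tree, states) {
  n_tip <- length(tree$tip.label)
  internal <- (n_tip + 1):max(tree$edge)
  amb <- which(states[tree$tip.label] == "?")
  fixed <- ifelse(states[tree$tip.label] == "1", 1L, 0L)
  n_free <- length(internal) + length(amb)
  best <- Inf
  for (code in 0:(2^n_free - 1)) {
    bits <- as.integer(intToBits(code))[seq_len(n_free)]
    lab <- integer(max(tree$edge))
    lab[seq_len(n_tip)] <- fixed
    if (length(amb) > 0) lab[amb] <- bits[seq_along(amb)]
    lab[internal] <- bits[(length(amb) + 1):n_free]
    changes <- sum(lab[tree$edge[, 1]] != lab[tree$edge[, 2]])
    if (changes < best) best <- changes
  }
  best
}

# --- Random EGF-like domain generator for property tests -------------------

AA_POOL <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "C")

random_domain_string <- function(loop2_site = NA) {
  lens <- c(sample(2:10, 1), 5L, sample(3:10, 1), sample(1:3, 1),
            sample(5:12, 1))
  loops <- vapply(lens, function(n) {
    paste(sample(AA_POOL, n, replace = TRUE), collapse = "")
  }, character(1))
  if (!is.na(loop2_site)) {
    acceptor <- if (loop2_site) sample(c("S", "T"), 1) else
      sample(setdiff(AA_POOL, c("S", "T")), 1)
    loops[2] <- paste0(substr(loops[2], 1, 4), acceptor)
  }
  paste0("C", loops[1], "C", loops[2], "C", loops[3], "C", loops[4],
         "C", loops[5], "C")
}

domain_from_string <- function(s, id = "dom") {
  p <- protein_record(id, s)
  egf_domain(p, 1, nchar(s))
}

# Regular-expression consensus oracle on the C2..C3 substring.
oracle_consensus <- function(domain) {
  seg <- substr(domain$sequence,
                domain$cys[2] - domain$start + 1L,
                domain$cys[3] - domain$start + 1L)
  grepl("^C....[ST]C$", seg)
}
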