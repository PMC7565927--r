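## In silico glycoproteomics: protease digestion (trypsin, thermolysin,
## co-digestion, missed cleavages), monoisotopic peptide and glycoform masses,
## precursor/fragment m/z, MRM transition lists, ppm matching and site
## occupancy from peak areas.

#' Define a protease cleavage rule
#'
#' @param name Rule name.
#' @param side `"C"` for C-terminal cleavage (cut after a residue in
#'   `residues`) or `"N"` for N-terminal cleavage (cut before a residue in
#'   `residues`).
#' @param residues Specificity residue set (non-empty).
#' @param exception Optional predicate `function(chars, i)` returning `TRUE`
#'   when the cut after position `i` (between `i` and `i + 1`) must be
#'   suppressed; `chars` is the residue character vector.
#' @return An object of class `protease_rule`.
#' @export
protease_rule <- function(name, side = c("C", "N"), residues,
                          exception = NULL) {
  side <- match.arg(side)
  if (length(residues) == 0) {
    abort_egfofuc("protease residue set must be non-empty", "config_error")
  }
  structure(list(name = name, side = side, residues = toupper(residues),
                 exception = exception),
            class = "protease_rule")
}

#' Built-in proteases
#'
#' `trypsin()`: cleaves C-terminal to K or R, not when the next residue is
#' proline. `thermolysin()`: cleaves N-terminal to I, L, V, A, M or F, not
#' when the residue following that hydrophobic residue is proline.
#'
#' @return A [protease_rule()].
#' @export
trypsin <- function() {
  protease_rule("trypsin", side = "C", residues = c("K", "R"),
                exception = function(chars, i) {
                  i + 1 <= length(chars) && chars[i + 1] == "P"
                })
}

#' @rdname trypsin
#' @export
thermolysin <- function() {
  protease_rule("thermolysin", side = "N",
                residues = c("I", "L", "V", "A", "M", "F"),
                exception = function(chars, i) {
                  i + 2 <= length(chars) && chars[i + 2] == "P"
                })
}

# Cut positions: i means a cut between residues i and i+1. Co-digestion uses
# the union of all rules' sites.
cut_sites <- function(chars, rules) {
  n <- length(chars)
  if (n < 2) return(integer(0))
  sites <- integer(0)
  for (rule in rules) {
    cand <- if (rule$side == "C") {
      which(chars[-n] %in% rule$residues)
    } else {
      which(chars[-1] %in% rule$residues)
    }
    if (!is.null(rule$exception) && length(cand) > 0) {
      keep <- !vapply(cand, function(i) isTRUE(rule$exception(chars, i)),
                      logical(1))
      cand <- cand[keep]
    }
    sites <- union(sites, cand)
  }
  sort(sites)
}

#' In silico protease digestion
#'
#' Digests a sequence with one or more protease rules. For co-digestion the
#' cut-site set is the union of all proteases' sites, and the missed-cleavage
#' count of a peptide is the number of skipped sites from that union set.
#' Zero-missed-cleavage peptides tile the substrate exactly; a peptide with
#' `k` missed cleavages is the concatenation of `k + 1` adjacent level-0
#' peptides.
#'
#' @param sequence Amino-acid string.
#' @param rules A [protease_rule()] or list of rules (default: trypsin).
#' @param max_missed Maximum number of missed cleavages (default 0).
#' @param offset Coordinate offset: reported `start`/`end` are
#'   `offset + local` (use the substrate's full-protein start minus one).
#' @return `data.frame` with columns `sequence`, `start`, `end` (1-based
#'   inclusive), `missed_cleavages` and `proteases`.
#' @export
#' @examples
#' digest("ANCSTTCFNGGTCFYPGK", list(trypsin(), thermolysin()))
digest <- function(sequence, rules = trypsin(), max_missed = 0L, offset = 0L) {
  if (inherits(rules, "protease_rule")) rules <- list(rules)
  chars <- aa_chars(sequence)
  if (length(chars) == 0) {
    abort_egfofuc("empty substrate sequence", "empty_input_error")
  }
  sites <- cut_sites(chars, rules)
  bounds <- c(0L, sites, length(chars))
  n_pep <- length(bounds) - 1L
  rows <- list()
  prot <- paste(vapply(rules, `[[`, character(1), "name"), collapse = "+")
  for (a in seq_len(n_pep)) {
    for (b in a:min(n_pep, a + max_missed)) {
      from <- bounds[a] + 1L
      to <- bounds[b + 1L]
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = paste(chars[from:to], collapse = ""),
        start = from + offset, end = to + offset,
        missed_cleavages = b - a,
        proteases = prot, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$end), , drop = FALSE]
}

#' Monoisotopic peptide mass
#'
#' Sum of residue monoisotopic masses plus one water, plus fixed
#' modifications. The default fixed modification is carbamidomethylation of
#' cysteines (iodoacetamide alkylation, +57.02146 Da), matching standard
#' reduced/alkylated digests.
#'
#' @param sequence Peptide sequence over the 20 standard residues.
#' @param fixed_mods Named numeric vector: per-residue mass additions, applied
#'   to every occurrence (default `c(C = carbamidomethyl)`). Use `NULL` or an
#'   empty vector for no modification.
#' @return Monoisotopic mass in Da. Signals `egfofuc_unknown_residue_error`
#'   for non-standard residues.
#' @export
#' @examples
#' peptide_mass("G", fixed_mods = NULL) # 75.03203
peptide_mass <- function(sequence, fixed_mods = c(C = CARBAMIDOMETHYL_MASS)) {
  chars <- aa_chars(sequence)
  unknown <- setdiff(unique(chars), names(RESIDUE_MASS))
  if (length(unknown) > 0) {
    abort_egfofuc(
      paste0("unknown residue(s): ", paste(unknown, collapse = ", ")),
      "unknown_residue_error")
  }
  m <- sum(RESIDUE_MASS[chars]) + WATER_MASS
  if (length(fixed_mods) > 0) {
    for (res in names(fixed_mods)) {
      m <- m + fixed_mods[[res]] * sum(chars == res)
    }
  }
  unname(m)
}

#' Enumerate O-fucosylglycan compositions
#'
#' The O-fucose extension series observed on EGF-like domains: unmodified,
#' O-Fuc (dHex), the disaccharide GlcNAc-Fuc (dHex + HexNAc), the
#' trisaccharide with an added hexose, and the sialylated tetrasaccharide
#' (dHex + HexNAc + Hex + NeuAc). A peptide without an acceptor site carries
#' only the unmodified form.
#'
#' @param site_present Logical: does the peptide carry a consensus acceptor?
#' @return `data.frame` with columns `glycoform`, `dHex`, `HexNAc`, `Hex`,
#'   `NeuAc` and `delta_mass` (Da, strictly increasing).
#' @export
enumerate_glycoforms <- function(site_present = TRUE) {
  comp <- data.frame(
    glycoform = c("unmodified", "O-Fuc", "O-Fuc+HexNAc", "O-Fuc+HexNAc+Hex",
                  "O-Fuc+HexNAc+Hex+NeuAc"),
    dHex = c(0, 1, 1, 1, 1),
    HexNAc = c(0, 0, 1, 1, 1),
    Hex = c(0, 0, 0, 1, 1),
    NeuAc = c(0, 0, 0, 0, 1),
    stringsAsFactors = FALSE)
  if (!isTRUE(site_present)) comp <- comp[1, , drop = FALSE]
  comp$delta_mass <- glyco_delta_mass(comp)
  comp
}

#' Glycan delta mass of a composition
#'
#' @param composition `data.frame` (or single named vector) with counts of
#'   `dHex`, `HexNAc`, `Hex`, `NeuAc`. Delta masses are additive under
#'   composition merge.
#' @return Numeric vector of monoisotopic delta masses in Da.
#' @export
glyco_delta_mass <- function(composition) {
  if (is.null(dim(composition))) {
    composition <- as.data.frame(as.list(composition))
  }
  out <- numeric(nrow(composition))
  for (g in names(GLYCAN_MASS)) {
    if (g %in% names(composition)) {
      out <- out + composition[[g]] * GLYCAN_MASS[[g]]
    }
  }
  out
}

#' m/z of a precursor ion
#'
#' @param neutral_mass Neutral monoisotopic mass in Da (glycan delta
#'   included for glycopeptides).
#' @param z Positive charge state.
#' @return `(neutral_mass + z * proton) / z`.
#' @export
precursor_mz <- function(neutral_mass, z) {
  stopifnot(all(z >= 1))
  (neutral_mass + z * PROTON_MASS) / z
}

#' Neutral mass from an observed m/z
#'
#' @param mz Observed m/z.
#' @param z Charge state.
#' @return Neutral mass in Da (exact inverse of [precursor_mz()]).
#' @export
neutral_mass <- function(mz, z) mz * z - z * PROTON_MASS

#' b/y fragment ions of a peptide
#'
#' Full b and y series (indices 1..n-1). By default the O-glycan is treated
#' as labile: fragment m/z are computed without the glycan delta, so modified
#' and unmodified forms of a peptide share identical fragment lists (the
#' convention under which shared-fragment occupancy quantitation is valid).
#' Set `retain_glycan = TRUE` (with `glyco_delta` and `site_index`) for
#' chemistries where fragments keep the glycan.
#'
#' @param sequence Peptide sequence.
#' @param fixed_mods Passed to the residue mass sums (default
#'   carbamidomethyl-C).
#' @param max_charge Fragment charges 1..`max_charge` are emitted.
#' @param retain_glycan Keep the glycan on fragments spanning the site?
#' @param glyco_delta Glycan delta mass (Da), used only when
#'   `retain_glycan = TRUE`.
#' @param site_index 1-based position of the glycosylated residue within the
#'   peptide, used only when `retain_glycan = TRUE`.
#' @return `data.frame` with columns `series` (`"b"`/`"y"`), `index`,
#'   `charge`, `mz`.
#' @export
fragment_ions <- function(sequence, fixed_mods = c(C = CARBAMIDOMETHYL_MASS),
                          max_charge = 1L, retain_glycan = FALSE,
                          glyco_delta = 0, site_index = NA_integer_) {
  chars <- aa_chars(sequence)
  n <- length(chars)
  stopifnot(n >= 2)
  res_m <- RESIDUE_MASS[chars]
  if (length(fixed_mods) > 0) {
    for (res in names(fixed_mods)) {
      res_m[chars == res] <- res_m[chars == res] + fixed_mods[[res]]
    }
  }
  b_neutral <- cumsum(res_m)[seq_len(n - 1)]
  suffix <- rev(cumsum(rev(res_m))) # suffix[k] = sum of residues k..n
  y_neutral <- rev(suffix[2:n]) + WATER_MASS # y_i = last i residues + water
  idx <- seq_len(n - 1)
  if (isTRUE(retain_glycan) && !is.na(site_index) && glyco_delta != 0) {
    b_neutral <- b_neutral + ifelse(idx >= site_index, glyco_delta, 0)
    y_neutral <- y_neutral + ifelse(n - idx + 1 <= site_index, glyco_delta, 0)
  }
  rows <- list()
  for (z in seq_len(max_charge)) {
    rows[[length(rows) + 1]] <- data.frame(
      series = "b", index = idx, charge = z,
      mz = (b_neutral + z * PROTON_MASS) / z, stringsAsFactors = FALSE)
    rows[[length(rows) + 1]] <- data.frame(
      series = "y", index = idx, charge = z,
      mz = (y_neutral + z * PROTON_MASS) / z, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Match theoretical and observed m/z at a ppm tolerance
#'
#' @param theoretical,observed Positive m/z values (vectorized).
#' @param tol_ppm Tolerance in parts per million (default 10).
#' @return Logical: `TRUE` iff `1e6 * |observed - theoretical| / theoretical`
#'   is strictly less than `tol_ppm`.
#' @export
#' @examples
#' match_ppm(1000.0, 1000.011) # 11 ppm: FALSE at the default 10
match_ppm <- function(theoretical, observed, tol_ppm = 10) {
  stopifnot(all(theoretical > 0), all(observed > 0))
  1e6 * abs(observed - theoretical) / theoretical < tol_ppm
}

#' Build an MRM transition table
#'
#' For every peptide, every glycoform of its extension series and every
#' precursor charge, emits at most `top_n` transitions. The fragment list is
#' ranked by the supplied intensity order or, by default, deterministically
#' y-series-first (y ions by decreasing index, then b ions by decreasing
#' index), and the identical fragment list is shared between the modified and
#' unmodified forms of a peptide (labile glycan).
#'
#' @param peptides `data.frame` with columns `sequence` and `site_present`
#'   (logical); an optional `peptide_id` column names peptides (defaults to
#'   the sequence).
#' @param charges Precursor charge states (default `c(2, 3)`).
#' @param top_n Transitions per precursor (default 6).
#' @param fixed_mods Fixed modifications for mass computation.
#' @param rank_fragments Optional `function(fragments)` returning the row
#'   order of the fragment table (most intense first); default: y-first.
#' @return `data.frame` of class `mrm_method` with columns `transition_id`,
#'   `peptide_id`, `sequence`, `glycoform`, `z`, `precursor_mz`,
#'   `fragment_series`, `fragment_index`, `fragment_charge`, `fragment_mz`.
#' @export
build_mrm_method <- function(peptides, charges = c(2L, 3L), top_n = 6L,
                             fixed_mods = c(C = CARBAMIDOMETHYL_MASS),
                             rank_fragments = NULL) {
  stopifnot(is.data.frame(peptides),
            all(c("sequence", "site_present") %in% names(peptides)))
  if (is.null(peptides$peptide_id)) peptides$peptide_id <- peptides$sequence
  if (is.null(rank_fragments)) {
    rank_fragments <- function(fr) {
      order(match(fr$series, c("y", "b")), -fr$index, fr$charge)
    }
  }
  rows <- list()
  for (k in seq_len(nrow(peptides))) {
    seq_k <- peptides$sequence[k]
    pid <- peptides$peptide_id[k]
    base_mass <- peptide_mass(seq_k, fixed_mods = fixed_mods)
    frags <- fragment_ions(seq_k, fixed_mods = fixed_mods, max_charge = 1L)
    frags <- frags[rank_fragments(frags), , drop = FALSE]
    frags <- frags[seq_len(min(top_n, nrow(frags))), , drop = FALSE]
    glyco <- enumerate_glycoforms(peptides$site_present[k])
    for (g in seq_len(nrow(glyco))) {
      for (z in charges) {
        pre <- precursor_mz(base_mass + glyco$delta_mass[g], z)
        rows[[length(rows) + 1]] <- data.frame(
          transition_id = paste(pid, glyco$glycoform[g], z,
                                paste0(frags$series, frags$index,
                                       "^", frags$charge),
                                sep = "|"),
          peptide_id = pid, sequence = seq_k,
          glycoform = glyco$glycoform[g], z = z, precursor_mz = pre,
          fragment_series = frags$series, fragment_index = frags$index,
          fragment_charge = frags$charge, fragment_mz = frags$mz,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("mrm_method", class(out))
  out
}

#' Quantify O-fucosylation site occupancy from peak areas
#'
#' Implements shared-fragment occupancy quantitation: the most abundant
#' fragment of the unmodified form of a peptide is selected (ties broken by
#' lowest fragment m/z), the areas of that same fragment (same precursor
#' charge, series, index and fragment charge) are collected for the
#' unmodified and O-fucosylated forms, and percent modification is
#' `100 * A_mod / (A_mod + A_unmod)`.
#'
#' By default the denominator excludes the extended glycoforms (di-, tri-,
#' tetra-saccharide); `include_extended = TRUE` adds their areas on the same
#' fragment to the modified side and the denominator.
#'
#' @param peak_table `data.frame` with columns `transition_id` and `area`.
#' @param transitions An [build_mrm_method()] table.
#' @param peptide_id Peptide to quantify (default: the single peptide in
#'   `transitions`).
#' @param include_extended Include extended glycoforms in the modified areas?
#' @return An object of class `quant_result`: `percent_modified` in
#'   \[0, 100\], `fragment` (the selected fragment descriptor), `areas`
#'   (named numeric) and `peptide_id`. Signals
#'   `egfofuc_missing_signal_error` when both areas are zero or absent.
#' @export
quantify_site_occupancy <- function(peak_table, transitions,
                                    peptide_id = NULL,
                                    include_extended = FALSE) {
  stopifnot(all(c("transition_id", "area") %in% names(peak_table)))
  if (is.null(peptide_id)) {
    ids <- unique(transitions$peptide_id)
    if (length(ids) != 1) {
      abort_egfofuc("peptide_id must be given when the method holds several peptides",
                    "config_error")
    }
    peptide_id <- ids
  }
  tr <- transitions[transitions$peptide_id == peptide_id, , drop = FALSE]
  if (nrow(tr) == 0) {
    abort_egfofuc(paste0("no transitions for peptide '", peptide_id, "'"),
                  "missing_signal_error")
  }
  areas <- setNames(peak_table$area, peak_table$transition_id)
  tr$area <- unname(areas[tr$transition_id])
  tr$area[is.na(tr$area)] <- 0
  unmod <- tr[tr$glycoform == "unmodified", , drop = FALSE]
  if (nrow(unmod) == 0) {
    abort_egfofuc("no unmodified-form transitions in the method",
                  "missing_signal_error")
  }
  # Most abundant fragment of the unmodified form; ties -> lowest fragment m/z.
  sel <- unmod[order(-unmod$area, unmod$fragment_mz), , drop = FALSE][1, ]
  same_frag <- tr$z == sel$z & tr$fragment_series == sel$fragment_series &
    tr$fragment_index == sel$fragment_index &
    tr$fragment_charge == sel$fragment_charge
  a_unmod <- sum(tr$area[same_frag & tr$glycoform == "unmodified"])
  mod_forms <- if (include_extended) {
    c("O-Fuc", "O-Fuc+HexNAc", "O-Fuc+HexNAc+Hex", "O-Fuc+HexNAc+Hex+NeuAc")
  } else "O-Fuc"
  a_mod <- sum(tr$area[same_frag & tr$glycoform %in% mod_forms])
  if (a_mod + a_unmod <= 0) {
    abort_egfofuc(
      paste0("no signal for peptide '", peptide_id, "' on fragment ",
             sel$fragment_series, sel$fragment_index),
      "missing_signal_error")
  }
  structure(
    list(percent_modified = 100 * a_mod / (a_mod + a_unmod),
         fragment = paste0(sel$fragment_series, sel$fragment_index,
                           "^", sel$fragment_charge, " (z=", sel$z, ")"),
         areas = c(unmodified = a_unmod, modified = a_mod),
         peptide_id = peptide_id,
         include_extended = include_extended),
    class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  cat("<quant_result> ", x$peptide_id, ": ",
      formatC(x$percent_modified, digits = 2, format = "f"),
      "% O-fucosylated on fragment ", x$fragment, "\n", sep = "")
  invisible(x)
}
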