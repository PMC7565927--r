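## Cross-species conservation: cysteine-anchored domain alignment, site
## presence/absence matrices, conservation-class logos, subfamily deviations
## and pairwise identity/similarity.

#' Align EGF-like domains on their cysteine framework
#'
#' Deterministic alignment of homologous EGF-like domains: the six cysteines
#' are anchored column-wise and each inter-cysteine loop (plus the regions
#' before C1 and after C6) is padded to the maximum length observed in the
#' set. Loop residues are left-aligned, with trailing gaps inserted
#' immediately before the next anchor column; the pre-C1 region is
#' right-aligned against the C1 anchor.
#'
#' @param domains A list of [egf_domain()] objects.
#' @return An object of class `domain_alignment`: a list with `rows`
#'   (`data.frame` with `protein_id`, `species`, `slot`, `gapped`),
#'   `anchor_columns` (six column indices, all-cysteine) and `width`.
#'   Signals `egfofuc_empty_input_error` on an empty input.
#' @export
align_domains_by_cysteines <- function(domains) {
  if (length(domains) == 0) {
    abort_egfofuc("no domains to align", "empty_input_error")
  }
  stopifnot(all(vapply(domains, inherits, logical(1), "egf_domain")))
  # Nine variable segments: pre-C1, loops 1..5, post-C6 (anchors in between).
  segs <- lapply(domains, function(d) {
    local_cys <- d$cys - d$start + 1L
    n <- nchar(d$sequence)
    pieces <- character(7)
    pieces[1] <- substr(d$sequence, 1L, local_cys[1] - 1L)
    for (k in 1:5) {
      pieces[k + 1] <- substr(d$sequence, local_cys[k] + 1L,
                              local_cys[k + 1] - 1L)
    }
    pieces[7] <- substr(d$sequence, local_cys[6] + 1L, n)
    pieces
  })
  seg_len <- vapply(segs, nchar, integer(7))
  if (is.null(dim(seg_len))) seg_len <- matrix(seg_len, nrow = 7)
  max_len <- apply(seg_len, 1, max)
  pad_right <- function(s, w) paste0(s, strrep("-", w - nchar(s)))
  pad_left <- function(s, w) paste0(strrep("-", w - nchar(s)), s)
  gapped <- vapply(segs, function(p) {
    paste0(pad_left(p[1], max_len[1]), "C",
           pad_right(p[2], max_len[2]), "C",
           pad_right(p[3], max_len[3]), "C",
           pad_right(p[4], max_len[4]), "C",
           pad_right(p[5], max_len[5]), "C",
           pad_right(p[6], max_len[6]), "C",
           pad_right(p[7], max_len[7]))
  }, character(1))
  anchors <- cumsum(c(max_len[1] + 1,
                      max_len[2] + 1, max_len[3] + 1,
                      max_len[4] + 1, max_len[5] + 1,
                      max_len[6] + 1))
  rows <- data.frame(
    protein_id = vapply(domains, `[[`, character(1), "protein_id"),
    species = vapply(domains, function(d) as.character(d$species), character(1)),
    slot = vapply(domains, function(d) as.character(d$slot), character(1)),
    gapped = gapped, stringsAsFactors = FALSE)
  structure(list(rows = rows, anchor_columns = as.integer(anchors),
                 width = nchar(gapped[1])),
            class = "domain_alignment")
}

#' @export
print.domain_alignment <- function(x, ...) {
  cat("<domain_alignment> ", nrow(x$rows), " rows x ", x$width,
      " columns; anchors at ", paste(x$anchor_columns, collapse = ","),
      "\n", sep = "")
  invisible(x)
}

#' Remove gaps from an aligned row
#'
#' @param gapped A gapped sequence string.
#' @return The ungapped sequence.
#' @export
degap <- function(gapped) gsub("-", "", gapped, fixed = TRUE)

SITE_STATES <- c("present", "absent", "domain_missing", "unknown")

#' Build a species-by-slot site presence matrix
#'
#' For every species and domain slot, records whether the O-fucosylation
#' consensus is `present` or `absent`, whether the domain itself is missing
#' from that species (`domain_missing`), or whether the state cannot be called
#' because the underlying sequence is partial (`unknown`).
#'
#' @param domain_sets Named list (species -> list of [egf_domain()] with slot
#'   labels).
#' @param slots Character vector of slot labels defining the columns
#'   (default `I`..`V`).
#' @param unknown Optional named list (species -> character vector of slots
#'   whose state is unknown, e.g. truncated by a partial sequence).
#' @return A character matrix (species x slot) over the states above, of class
#'   `site_matrix`. Signals `egfofuc_duplicate_slot_error` if a species has
#'   two domains with the same slot.
#' @export
build_site_matrix <- function(domain_sets, slots = c("I", "II", "III", "IV", "V"),
                              unknown = NULL) {
  stopifnot(is.list(domain_sets), !is.null(names(domain_sets)))
  m <- matrix("domain_missing", nrow = length(domain_sets), ncol = length(slots),
              dimnames = list(names(domain_sets), slots))
  for (sp in names(domain_sets)) {
    doms <- domain_sets[[sp]]
    dom_slots <- vapply(doms, function(d) as.character(d$slot), character(1))
    if (anyDuplicated(dom_slots)) {
      abort_egfofuc(
        paste0("species '", sp, "' has duplicated slot label(s): ",
               paste(unique(dom_slots[duplicated(dom_slots)]), collapse = ", ")),
        "duplicate_slot_error")
    }
    for (k in seq_along(doms)) {
      if (!dom_slots[k] %in% slots) next
      site <- find_ofuc_consensus(doms[[k]])
      m[sp, dom_slots[k]] <- if (is.null(site)) "absent" else "present"
    }
    if (!is.null(unknown) && sp %in% names(unknown)) {
      m[sp, intersect(unknown[[sp]], slots)] <- "unknown"
    }
  }
  structure(m, class = c("site_matrix", class(m)))
}

#' Per-column conservation logo of a domain alignment
#'
#' Computes, for every alignment column, the residue frequency distribution
#' over non-gap entries, the dominant residue, and a conservation class
#' following the uppercase/lowercase/dot convention: `upper` when the dominant
#' frequency is >= 0.80, `lower` when it is in \[0.50, 0.80), `dot` when
#' < 0.50.
#'
#' @param alignment A `domain_alignment`, or a character vector of equal-length
#'   gapped sequences.
#' @return A `data.frame` with columns `column`, `dominant`, `dominant_freq`,
#'   `class` and `n` (non-gap count), carrying the full residue-by-column
#'   frequency matrix as attribute `"frequencies"`. Frequencies in each column
#'   sum to 1 over non-gap entries.
#' @export
compute_logo <- function(alignment) {
  gapped <- if (inherits(alignment, "domain_alignment")) {
    alignment$rows$gapped
  } else {
    as.character(alignment)
  }
  stopifnot(length(gapped) > 0, length(unique(nchar(gapped))) == 1)
  mat <- do.call(rbind, strsplit(gapped, "", fixed = TRUE))
  width <- ncol(mat)
  residues <- sort(unique(as.vector(mat[mat != "-"])))
  freq <- matrix(0, nrow = length(residues), ncol = width,
                 dimnames = list(residues, NULL))
  dominant <- character(width)
  dominant_freq <- rep(NA_real_, width)
  n_nongap <- integer(width)
  for (j in seq_len(width)) {
    col <- mat[, j]
    col <- col[col != "-"]
    n_nongap[j] <- length(col)
    if (length(col) == 0) { dominant[j] <- NA_character_; next }
    tab <- table(col) / length(col)
    freq[names(tab), j] <- as.numeric(tab)
    # Deterministic tie-break: alphabetically first among the most frequent.
    top <- names(tab)[tab == max(tab)]
    dominant[j] <- sort(top)[1]
    dominant_freq[j] <- max(tab)
  }
  cls <- ifelse(is.na(dominant_freq), NA_character_,
                ifelse(dominant_freq >= 0.80, "upper",
                       ifelse(dominant_freq >= 0.50, "lower", "dot")))
  out <- data.frame(column = seq_len(width), dominant = dominant,
                    dominant_freq = dominant_freq, class = cls, n = n_nongap,
                    stringsAsFactors = FALSE)
  attr(out, "frequencies") <- freq
  class(out) <- c("logo_table", class(out))
  out
}

# Frequency of residue `res` in column `j` of a logo table (0 when unseen).
logo_freq <- function(logo, res, j) {
  freq <- attr(logo, "frequencies")
  if (!res %in% rownames(freq)) return(0)
  freq[res, j]
}

#' Compare two subfamily logos
#'
#' Flags alignment columns where two subfamilies (e.g. gnathostomes vs
#' protostomes) deviate: a column is flagged iff the dominant residues differ
#' AND the frequency of subfamily A's dominant residue drops by at least
#' `threshold` between the two subfamilies.
#'
#' @param logoA,logoB Logo tables from [compute_logo()] with equal column
#'   counts.
#' @param threshold Minimum dominant-frequency difference (default 0.5).
#' @return A `data.frame` with one row per column: dominant residues and
#'   frequencies in both subfamilies, the frequency of A's dominant residue in
#'   B, and logical `deviation`. Signals `egfofuc_length_mismatch_error` on
#'   unequal column counts.
#' @export
compare_subfamily_logos <- function(logoA, logoB, threshold = 0.5) {
  if (nrow(logoA) != nrow(logoB)) {
    abort_egfofuc(
      paste0("logo column counts differ (", nrow(logoA), " vs ", nrow(logoB), ")"),
      "length_mismatch_error")
  }
  n <- nrow(logoA)
  freqA_dom <- logoA$dominant_freq
  freqB_of_domA <- vapply(seq_len(n), function(j) {
    if (is.na(logoA$dominant[j])) return(NA_real_)
    logo_freq(logoB, logoA$dominant[j], j)
  }, numeric(1))
  deviation <- !is.na(logoA$dominant) & !is.na(logoB$dominant) &
    logoA$dominant != logoB$dominant &
    abs(freqA_dom - freqB_of_domA) >= threshold
  data.frame(
    column = logoA$column,
    dominant_a = logoA$dominant, freq_a = logoA$dominant_freq,
    dominant_b = logoB$dominant, freq_b = logoB$dominant_freq,
    freq_a_dominant_in_b = freqB_of_domA,
    deviation = deviation, stringsAsFactors = FALSE)
}

# Residue similarity groups as used by the SMS2 ident_sim tool.
SIMILARITY_GROUPS <- list(
  c("G", "A", "V", "L", "I"),
  c("F", "Y", "W"),
  c("C", "M"),
  c("S", "T"),
  c("K", "R", "H"),
  c("D", "E", "N", "Q"),
  "P")

#' Pairwise percent identity and similarity of two aligned sequences
#'
#' Columns where either sequence has a gap are excluded from the denominator.
#' Identity counts exact matches; similarity additionally counts matches
#' within residue groups `{GAVLI} {FYW} {CM} {ST} {KRH} {DENQ} {P}`.
#'
#' @param a,b Gapped sequences of equal length.
#' @param groups Similarity groups (list of character vectors); the default
#'   follows the SMS2 ident_sim convention.
#' @return Named numeric vector `c(identity = , similarity = )` in percent.
#'   Signals `egfofuc_length_mismatch_error` on unequal lengths.
#' @export
#' @examples
#' pairwise_identity_similarity("CFNGGTC", "CFNGGSC")
pairwise_identity_similarity <- function(a, b, groups = SIMILARITY_GROUPS) {
  ca <- aa_chars(a); cb <- aa_chars(b)
  if (length(ca) != length(cb)) {
    abort_egfofuc(
      paste0("aligned sequence lengths differ (", length(ca), " vs ",
             length(cb), ")"),
      "length_mismatch_error")
  }
  keep <- ca != "-" & cb != "-"
  ca <- ca[keep]; cb <- cb[keep]
  if (length(ca) == 0) {
    return(c(identity = NA_real_, similarity = NA_real_))
  }
  group_of <- setNames(rep(seq_along(groups), lengths(groups)),
                       unlist(groups))
  ident <- ca == cb
  simil <- ident | (!is.na(group_of[ca]) & !is.na(group_of[cb]) &
                      group_of[ca] == group_of[cb])
  c(identity = 100 * mean(ident), similarity = 100 * mean(simil))
}
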