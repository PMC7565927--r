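## EGF-like domain architecture: cysteine framework, hEGF classification,
## O-fucosylation consensus scanning, POFUT1 compatibility rules.
##
## Coordinate convention throughout: 1-based, inclusive spans, full-precursor
## numbering counted from the initiator methionine, so printed positions such
## as T255 map directly onto `acceptor_pos`.

#' Create a protein record
#'
#' Container for a protein sequence with optional EGF-like domain annotations.
#'
#' @param id Protein identifier.
#' @param sequence Amino-acid sequence (string over the 20 standard residues
#'   plus `X` for unknown).
#' @param species Species name (optional).
#' @param taxon_group One of `"deuterostome"`, `"protostome"`, `"unknown"`.
#' @param annotations Optional `data.frame` with columns `slot`, `start`,
#'   `end` giving known domain spans in 1-based inclusive full-protein
#'   coordinates.
#'
#' @return An object of class `protein_record`.
#' @export
#' @examples
#' protein_record("toy", "MKKCAACNGGTCAACAKCAAAAAAAC")
protein_record <- function(id, sequence, species = NA_character_,
                           taxon_group = c("unknown", "deuterostome", "protostome"),
                           annotations = NULL) {
  taxon_group <- match.arg(taxon_group)
  sequence <- toupper(as.character(sequence))
  chars <- aa_chars(sequence)
  bad <- setdiff(unique(chars), c(AA_STANDARD, "X"))
  if (length(bad) > 0) {
    abort_egfofuc(
      paste0("protein '", id, "' contains non-standard residue(s): ",
             paste(bad, collapse = ", ")),
      "unknown_residue_error")
  }
  if (!is.null(annotations)) {
    stopifnot(all(c("slot", "start", "end") %in% names(annotations)))
    ok <- annotations$start >= 1 & annotations$start <= annotations$end &
      annotations$end <= nchar(sequence)
    if (!all(ok)) {
      abort_egfofuc(
        paste0("protein '", id, "' has annotation span(s) outside 1..length"),
        "annotation_mismatch_error")
    }
  }
  structure(
    list(id = as.character(id), species = species, taxon_group = taxon_group,
         sequence = sequence, annotations = annotations),
    class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat("<protein_record> ", x$id, " (", nchar(x$sequence), " aa",
      if (!is.na(x$species)) paste0(", ", x$species), ")\n", sep = "")
  invisible(x)
}

#' Locate the six-cysteine framework of an EGF-like domain
#'
#' Finds the positions of the six cysteines (C1..C6) within a sequence window
#' assumed to contain exactly one complete EGF-like domain.
#'
#' @param window Amino-acid string covering the candidate domain.
#' @param offset Coordinate offset: the window starts at full-protein position
#'   `offset + 1`, and returned positions are full-protein coordinates.
#'
#' @return Integer vector of six strictly increasing cysteine positions.
#'   Signals a condition of class `egfofuc_cysteine_count_error` if the window
#'   does not contain exactly six cysteines.
#' @export
#' @examples
#' locate_cysteine_framework("ACAACAAAACAACACAAAAC", offset = 100)
locate_cysteine_framework <- function(window, offset = 0L) {
  chars <- aa_chars(window)
  if (length(chars) == 0) {
    abort_egfofuc("empty sequence window", "empty_input_error")
  }
  pos <- which(chars == "C")
  if (length(pos) != 6L) {
    abort_egfofuc(
      paste0("window contains ", length(pos),
             " cysteines (expected 6): not a single complete EGF-like domain"),
      "cysteine_count_error")
  }
  as.integer(pos + offset)
}

#' Construct an EGF-like domain
#'
#' Builds an `egf_domain` from a protein record and an inclusive span, locating
#' the six-cysteine framework and classifying the hEGF subtype (C5-C6 loop of
#' 8 or 9 residues). The disulfide pairing convention recorded for all domains
#' is (C1-C3, C2-C4, C5-C6).
#'
#' @param protein A [protein_record()].
#' @param start,end Inclusive 1-based full-protein coordinates of the domain.
#' @param slot Optional slot label (e.g. `"I"`..`"V"`).
#'
#' @return An object of class `egf_domain` with fields `protein_id`,
#'   `species`, `slot`, `start`, `end`, `sequence`, `cys` (six full-protein
#'   cysteine positions) and `is_hegf`.
#' @export
egf_domain <- function(protein, start, end, slot = NA_character_) {
  stopifnot(inherits(protein, "protein_record"))
  start <- as.integer(start); end <- as.integer(end)
  if (start < 1 || end > nchar(protein$sequence) || start > end) {
    abort_egfofuc(
      paste0("domain span ", start, "..", end, " outside protein '",
             protein$id, "'"),
      "annotation_mismatch_error")
  }
  window <- substr(protein$sequence, start, end)
  cys <- locate_cysteine_framework(window, offset = start - 1L)
  dom <- structure(
    list(protein_id = protein$id, species = protein$species,
         taxon_group = protein$taxon_group,
         slot = as.character(slot), start = start, end = end,
         sequence = window, cys = cys,
         disulfides = c("C1-C3", "C2-C4", "C5-C6"),
         is_hegf = NA),
    class = "egf_domain")
  dom$is_hegf <- classify_hegf(dom)
  dom
}

#' @export
print.egf_domain <- function(x, ...) {
  cat("<egf_domain> ", x$protein_id,
      if (!is.na(x$slot)) paste0(" slot ", x$slot),
      " [", x$start, "-", x$end, "] cys: ",
      paste(x$cys, collapse = ","),
      if (isTRUE(x$is_hegf)) " (hEGF)", "\n", sep = "")
  invisible(x)
}

# Residue at an absolute full-protein position of a domain's parent sequence
# (only positions inside the domain span are addressable).
domain_residue <- function(domain, pos) {
  if (pos < domain$start || pos > domain$end) return(NA_character_)
  substr(domain$sequence, pos - domain$start + 1L, pos - domain$start + 1L)
}

#' Inter-cysteine loop sequence and length
#'
#' Residues strictly between cysteines Ci and Cj of an EGF-like domain.
#' "Loop" always means the residues strictly between the flanking cysteines.
#'
#' @param domain An [egf_domain()].
#' @param i,j Cysteine indices in 1..6 with `i < j`.
#' @return `loop_seq`: the loop as a string; `loop_len`: its length.
#' @export
loop_seq <- function(domain, i, j) {
  stopifnot(inherits(domain, "egf_domain"), i >= 1, j <= 6, i < j)
  from <- domain$cys[i] + 1L
  to <- domain$cys[j] - 1L
  if (from > to) return("")
  substr(domain$sequence, from - domain$start + 1L, to - domain$start + 1L)
}

#' @rdname loop_seq
#' @export
loop_len <- function(domain, i, j) nchar(loop_seq(domain, i, j))

#' Classify the hEGF subtype
#'
#' An EGF-like domain is of the hEGF type -- the class POFUT1 modifies -- when
#' its C5-C6 loop contains eight or nine residues.
#'
#' @param domain An [egf_domain()].
#' @return `TRUE` iff the C5-C6 loop length is 8 or 9.
#' @export
classify_hegf <- function(domain) {
  loop_len(domain, 5, 6) %in% c(8L, 9L)
}

#' Default inter-cysteine spacing configuration for domain detection
#'
#' Allowed lengths of the five inter-cysteine loops when scanning a protein
#' for EGF-like domains: C-x(2,14)-C-x(3,12)-C-x(3,12)-C-x(1,3)-C-x(5,12)-C.
#'
#' @param loop_min,loop_max Integer vectors of length 5 with per-loop bounds.
#' @return A list with `loop_min` and `loop_max`.
#' @export
egf_spacing <- function(loop_min = c(2L, 3L, 3L, 1L, 5L),
                        loop_max = c(14L, 12L, 12L, 3L, 12L)) {
  stopifnot(length(loop_min) == 5, length(loop_max) == 5,
            all(loop_min >= 0), all(loop_min <= loop_max))
  list(loop_min = as.integer(loop_min), loop_max = as.integer(loop_max))
}

#' Detect EGF-like domains in a protein
#'
#' Scans a protein for runs of six cysteines whose inter-cysteine spacings fit
#' the configured loop-length ranges, greedily left to right and without
#' overlap. When the protein carries domain annotations these take precedence:
#' each annotated span is validated against the six-cysteine invariant instead
#' of being re-detected.
#'
#' @param protein A [protein_record()].
#' @param spacing Spacing configuration from [egf_spacing()].
#' @return A list of [egf_domain()] objects (empty when nothing matches).
#'   Signals `egfofuc_annotation_mismatch_error` if an annotated span does not
#'   contain exactly six cysteines.
#' @export
detect_egf_domains <- function(protein, spacing = egf_spacing()) {
  stopifnot(inherits(protein, "protein_record"))
  if (!is.null(protein$annotations)) {
    ann <- protein$annotations
    doms <- lapply(seq_len(nrow(ann)), function(k) {
      tryCatch(
        egf_domain(protein, ann$start[k], ann$end[k], slot = ann$slot[k]),
        egfofuc_cysteine_count_error = function(e) {
          abort_egfofuc(
            paste0("annotated span ", ann$start[k], "..", ann$end[k],
                   " of protein '", protein$id, "' (slot ", ann$slot[k],
                   ") fails the six-cysteine invariant: ",
                   conditionMessage(e)),
            "annotation_mismatch_error")
        })
    })
    return(doms)
  }
  chars <- aa_chars(protein$sequence)
  cpos <- which(chars == "C")
  doms <- list()
  last_end <- 0L
  i <- 1L
  while (i + 5L <= length(cpos)) {
    six <- cpos[i:(i + 5L)]
    gaps <- diff(six) - 1L
    if (six[1] > last_end &&
        all(gaps >= spacing$loop_min) && all(gaps <= spacing$loop_max)) {
      slot_idx <- length(doms) + 1L
      doms[[slot_idx]] <- egf_domain(protein, six[1], six[6],
                                     slot = as.character(slot_idx))
      last_end <- six[6]
      i <- i + 6L
    } else {
      i <- i + 1L
    }
  }
  doms
}

#' Find the O-fucosylation consensus site of a domain
#'
#' Scans the C2-C3 segment of an EGF-like domain for the O-fucosylation
#' consensus C2-X-X-X-X-(S/T)-C3: exactly five residues between C2 and C3 with
#' a serine or threonine immediately before C3. The S/T is the fucose acceptor.
#' `X` in a sequence is accepted at the four wildcard positions but never as
#' the S/T acceptor.
#'
#' @param domain An [egf_domain()].
#' @return An object of class `consensus_site` (fields `protein_id`, `slot`,
#'   `acceptor_pos` in full-protein coordinates, `acceptor_res`, `motif` --
#'   the 7-character C2..C3 segment), or `NULL` when the domain has no site.
#' @export
find_ofuc_consensus <- function(domain) {
  stopifnot(inherits(domain, "egf_domain"))
  if (loop_len(domain, 2, 3) != 5L) return(NULL)
  acceptor_pos <- domain$cys[3] - 1L
  acceptor_res <- domain_residue(domain, acceptor_pos)
  if (!acceptor_res %in% c("S", "T")) return(NULL)
  motif <- substr(domain$sequence,
                  domain$cys[2] - domain$start + 1L,
                  domain$cys[3] - domain$start + 1L)
  structure(
    list(protein_id = domain$protein_id, slot = domain$slot,
         acceptor_pos = acceptor_pos, acceptor_res = acceptor_res,
         motif = motif),
    class = "consensus_site")
}

#' @export
print.consensus_site <- function(x, ...) {
  cat("<consensus_site> ", x$protein_id,
      if (!is.na(x$slot)) paste0(" slot ", x$slot),
      ": ", x$motif, " acceptor ", x$acceptor_res, x$acceptor_pos, "\n",
      sep = "")
  invisible(x)
}

#' Assess POFUT1 substrate compatibility of an EGF-like domain
#'
#' Applies sequence-level rules distilled from the POFUT1/EGF-LD interaction
#' to predict whether a domain can be positioned in the POFUT1 binding groove
#' for fucose transfer:
#'
#' * `bulky_c2plus3` -- a bulky or acidic residue at position C2+3 (default
#'   set `{H, Y, D}`) causes a major steric clash in the C2-C3 loop;
#' * `basic_c5plus1` -- a basic residue (R, K, H) at C5+1 causes steric clash
#'   and/or charge repulsion;
#' * `proline_c1c2` -- a proline in the C1-C2 loop reduces binding affinity;
#' * `gln_c4plus1` -- a glutamine at C4+1 (the single residue between C4 and
#'   C5 in canonical domains) reduces binding affinity.
#'
#' Verdict rule (total and deterministic): no consensus site -> incompatible;
#' consensus with `bulky_c2plus3` or `basic_c5plus1` -> incompatible;
#' consensus with only `proline_c1c2` and/or `gln_c4plus1` -> weakened;
#' consensus with no flags -> favorable.
#'
#' @param domain An [egf_domain()].
#' @param bulky_set Residues treated as blocking at C2+3; default `{H, Y, D}`,
#'   extendable (e.g. with `W`, `F`).
#' @return An object of class `compatibility_report` with the four logical
#'   flags, `has_consensus`, `site` (or `NULL`) and `verdict`.
#' @export
assess_pofut1_compatibility <- function(domain, bulky_set = c("H", "Y", "D")) {
  stopifnot(inherits(domain, "egf_domain"))
  site <- find_ofuc_consensus(domain)
  res_at <- function(pos, upper) {
    if (pos >= upper) NA_character_ else domain_residue(domain, pos)
  }
  r_c2p3 <- res_at(domain$cys[2] + 3L, domain$cys[3])
  r_c5p1 <- res_at(domain$cys[5] + 1L, domain$cys[6])
  r_c4p1 <- res_at(domain$cys[4] + 1L, domain$cys[5])
  flags <- c(
    bulky_c2plus3 = !is.na(r_c2p3) && r_c2p3 %in% bulky_set,
    basic_c5plus1 = !is.na(r_c5p1) && r_c5p1 %in% c("R", "K", "H"),
    proline_c1c2 = grepl("P", loop_seq(domain, 1, 2), fixed = TRUE),
    gln_c4plus1 = !is.na(r_c4p1) && r_c4p1 == "Q"
  )
  verdict <- compatibility_verdict(flags, has_consensus = !is.null(site))
  structure(
    list(protein_id = domain$protein_id, slot = domain$slot,
         flags = flags, has_consensus = !is.null(site), site = site,
         verdict = verdict),
    class = "compatibility_report")
}

# The documented verdict rule as a pure function of the flag vector.
compatibility_verdict <- function(flags, has_consensus) {
  if (!has_consensus) return("incompatible")
  if (flags[["bulky_c2plus3"]] || flags[["basic_c5plus1"]]) return("incompatible")
  if (flags[["proline_c1c2"]] || flags[["gln_c4plus1"]]) return("weakened")
  "favorable"
}

#' @export
print.compatibility_report <- function(x, ...) {
  on <- names(x$flags)[x$flags]
  cat("<compatibility_report> ", x$protein_id,
      if (!is.na(x$slot)) paste0(" slot ", x$slot),
      ": ", x$verdict,
      if (length(on) > 0) paste0(" [", paste(on, collapse = ", "), "]"),
      "\n", sep = "")
  invisible(x)
}

#' Tabulate domains, consensus sites and compatibility for a protein
#'
#' Convenience wrapper running [detect_egf_domains()], [find_ofuc_consensus()]
#' and [assess_pofut1_compatibility()] and returning one row per domain.
#'
#' @param protein A [protein_record()].
#' @param spacing Spacing configuration from [egf_spacing()].
#' @param bulky_set Passed to [assess_pofut1_compatibility()].
#' @return A `data.frame` with columns `protein_id`, `species`, `slot`,
#'   `start`, `end`, `c1`..`c6`, `is_hegf`, `motif`, `acceptor_pos`,
#'   `acceptor_res`, the four flag columns and `verdict`.
#' @export
scan_protein <- function(protein, spacing = egf_spacing(),
                         bulky_set = c("H", "Y", "D")) {
  doms <- detect_egf_domains(protein, spacing = spacing)
  if (length(doms) == 0) {
    return(data.frame(
      protein_id = character(), species = character(), slot = character(),
      start = integer(), end = integer(),
      c1 = integer(), c2 = integer(), c3 = integer(),
      c4 = integer(), c5 = integer(), c6 = integer(),
      is_hegf = logical(), motif = character(), acceptor_pos = integer(),
      acceptor_res = character(), bulky_c2plus3 = logical(),
      basic_c5plus1 = logical(), proline_c1c2 = logical(),
      gln_c4plus1 = logical(), verdict = character(),
      stringsAsFactors = FALSE))
  }
  rows <- lapply(doms, function(d) {
    site <- find_ofuc_consensus(d)
    rep <- assess_pofut1_compatibility(d, bulky_set = bulky_set)
    data.frame(
      protein_id = d$protein_id, species = d$species, slot = d$slot,
      start = d$start, end = d$end,
      c1 = d$cys[1], c2 = d$cys[2], c3 = d$cys[3],
      c4 = d$cys[4], c5 = d$cys[5], c6 = d$cys[6],
      is_hegf = d$is_hegf,
      motif = if (is.null(site)) NA_character_ else site$motif,
      acceptor_pos = if (is.null(site)) NA_integer_ else site$acceptor_pos,
      acceptor_res = if (is.null(site)) NA_character_ else site$acceptor_res,
      bulky_c2plus3 = rep$flags[["bulky_c2plus3"]],
      basic_c5plus1 = rep$flags[["basic_c5plus1"]],
      proline_c1c2 = rep$flags[["proline_c1c2"]],
      gln_c4plus1 = rep$flags[["gln_c4plus1"]],
      verdict = rep$verdict,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
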