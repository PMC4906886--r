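#' Identity and stretch statistics of a duplex layout
#'
#' `identity_bp` counts complementary (pair) columns; `stretch_bp` is the
#' longest run of consecutive pair columns. Identity does not order duplex
#' stability -- probes with identical identity and stretch can differ by
#' tens of degrees in nontarget melting temperature -- which is why audits
#' rank nontargets by Tm.
#'
#' @param layout a [duplex_layout()].
#' @return a one-row tibble with `identity_bp` and `stretch_bp`.
#' @export
duplex_stats <- function(layout) {
  is_pair <- layout$kind == "pair"
  r <- rle(is_pair)
  tibble(
    identity_bp = sum(is_pair),
    stretch_bp = max(r$lengths[r$values], 0L)
  )
}

#' Parse a case-encoded probe/nontarget duplex string
#'
#' The input is an even-length string whose first half is the probe top
#' strand 5'->3' and whose second half is the nontarget counter strand
#' 3'->5', column-aligned; uppercase columns are complementary base pairs
#' and lowercase columns are mismatches. The case masks of the two halves
#' must agree and uppercase columns must actually be complementary.
#'
#' @param row_string the case-encoded duplex string.
#' @return a gapless [duplex_layout()].
#' @export
#' @examples
#' parse_case_encoded_duplex("ACGTTGCA")   # 4 pairs, no mismatch
parse_case_encoded_duplex <- function(row_string) {
  n <- nchar(row_string)
  if (n == 0L || n %% 2L != 0L) {
    abort("case-encoded duplex string must have even, non-zero length")
  }
  half <- n %/% 2L
  p <- seq_chars(substr(row_string, 1L, half))
  cc <- seq_chars(substr(row_string, half + 1L, n))
  up_p <- p %in% LETTERS
  up_c <- cc %in% LETTERS
  if (!identical(up_p, up_c)) {
    abort(sprintf(
      "case masks of the two halves disagree at column %d", which(up_p != up_c)[1]
    ))
  }
  p_up <- toupper(p)
  c_up <- toupper(cc)
  if (any(!p_up %in% DNA_BASES) || any(!c_up %in% DNA_BASES)) {
    abort("case-encoded duplex contains non-ACGT characters")
  }
  comp <- c_up == dna_complement(p_up)
  if (any(up_p & !comp)) {
    abort(sprintf(
      "uppercase column %d is not a complementary base pair", which(up_p & !comp)[1]
    ))
  }
  if (any(!up_p & comp)) {
    abort(sprintf(
      "lowercase column %d is complementary (must be uppercase)", which(!up_p & comp)[1]
    ))
  }
  duplex_layout(p_up, c_up, ifelse(up_p, "pair", "mismatch"))
}

#' Audit a probe set against a genome for cross-hybridization potential
#'
#' For each probe, enumerates all exact-match seeds of at least `min_match`
#' bp against both strands of the genome, extends each into a duplex layout
#' and reports the closest nontarget -- the layout with the highest melting
#' temperature. A probe is flagged when its target-vs-nontarget Tm
#' separation falls below `audit_delta_tm`. Probes without coordinates are
#' located by exact top-strand search first: a unique hit becomes the
#' target locus; multiple hits are reported as `multi_locus`; no hit is
#' reported as `no_target_locus` and every match is audited as a nontarget
#' with the target Tm undefined.
#'
#' @param probes probe tibble ([read_probe_table()] or a design's probes).
#' @param genomes sequence tibble the probes are audited against.
#' @param params a [design_params()] object (supplies `min_match`,
#'   `min_similarity`, `audit_delta_tm` and the hybridization conditions).
#' @return an object of class `probe_audit` with per-probe records and a
#'   summary; see [tidy.probe_audit()] and [glance.probe_audit()].
#' @export
audit_probe_set <- function(probes, genomes, params = design_params()) {
  index <- build_index(tibble(id = genomes$id, sequence = genomes$sequence),
                       min_match = params$min_match)
  records <- purrr::map_dfr(seq_len(nrow(probes)), function(i) {
    audit_one(probes[i, ], genomes, index, params)
  })
  flagged <- records$flagged %in% TRUE
  summary <- tibble(
    n_probes = nrow(records),
    n_flagged = sum(flagged),
    flagged_fraction_pct = if (nrow(records)) 100 * mean(flagged) else NA_real_,
    audit_delta_tm = params$audit_delta_tm
  )
  structure(list(records = records, summary = summary, params = params),
            class = "probe_audit")
}

audit_one <- function(probe, genomes, index, params) {
  seq <- toupper(probe$sequence)
  verdict <- "ok"
  locus <- NULL
  if (!is.na(probe$start) && !is.na(probe$genome_id)) {
    locus <- list(genome_id = probe$genome_id, start = probe$start, end = probe$end)
  } else {
    hits <- locate_exact(seq, genomes)
    if (nrow(hits) == 1L) {
      locus <- list(genome_id = hits$genome_id, start = hits$start, end = hits$end)
    } else if (nrow(hits) > 1L) {
      verdict <- "multi_locus"
    } else {
      verdict <- "no_target_locus"
    }
  }
  tm_t <- if (verdict == "ok") tm_perfect(seq, conditions = params$conditions) else NA_real_
  seeds <- raw_seeds(seq, index)
  if (!is.null(locus)) {
    seeds <- drop_self_raw(seeds, index, locus)
  }
  base <- tibble(
    probe_id = probe$probe_id, probe_length = nchar(seq),
    identity_bp = NA_integer_, stretch_bp = NA_integer_,
    tm_target = tm_t, tm_nontarget = NA_real_, delta_tm = NA_real_,
    nontarget_id = NA_character_, nontarget_start = NA_integer_,
    nontarget_end = NA_integer_, nontarget_strand = NA_character_,
    verdict = verdict, flagged = NA
  )
  if (n_seeds(seeds) == 0L) {
    base$flagged <- if (verdict == "ok") FALSE else NA
    return(base)
  }
  layouts <- candidate_layouts(seq, index, seeds, params$min_similarity)
  tms <- vapply(layouts, tm_duplex, numeric(1), conditions = params$conditions)
  if (all(is.na(tms))) {
    base$flagged <- if (verdict == "ok") FALSE else NA
    return(base)
  }
  best <- which.max(tms)
  lay <- layouts[[best]]
  st <- duplex_stats(lay)
  span <- attr(lay, "subject_span")
  base$identity_bp <- st$identity_bp
  base$stretch_bp <- st$stretch_bp
  base$tm_nontarget <- tms[best]
  base$delta_tm <- if (is.na(tm_t)) NA_real_ else tm_t - tms[best]
  base$nontarget_id <- attr(lay, "subject_id")
  base$nontarget_start <- span[1L]
  base$nontarget_end <- span[2L]
  base$nontarget_strand <- attr(lay, "strand")
  base$flagged <- if (verdict == "ok") base$delta_tm < params$audit_delta_tm else NA
  base
}

locate_exact <- function(seq, genomes) {
  purrr::map_dfr(seq_len(nrow(genomes)), function(i) {
    m <- stringi::stri_locate_all_fixed(genomes$sequence[i], seq)[[1]]
    if (all(is.na(m[, 1]))) {
      return(tibble(genome_id = character(), start = integer(), end = integer()))
    }
    tibble(genome_id = genomes$id[i], start = m[, 1] - 1L, end = m[, 2])
  })
}

#' @export
print.probe_audit <- function(x, ...) {
  cat("<probe_audit>\n")
  cat(sprintf("  %d probe(s), %d flagged (%.2f%%) at delta-Tm < %.1f C\n",
              x$summary$n_probes, x$summary$n_flagged,
              x$summary$flagged_fraction_pct, x$summary$audit_delta_tm))
  invisible(x)
}

#' Fragment-based coverage statistics of a probe set
#'
#' A fragment counts as covered when at least one probe lies fully inside
#' it. Coverage is fragment-based, not base-pair-based, so the covered and
#' uncovered percentages are exact complements.
#'
#' @param probes probe tibble.
#' @param target_fragments target fragment tibble the probes tile.
#' @return a one-row tibble: `probe_count`, `mean_probe_length`,
#'   `pct_fragments_without_probes`, `pct_genome_covered`.
#' @export
coverage_stats <- function(probes, target_fragments) {
  covered <- if (nrow(probes)) {
    unique(probe_fragment_assignment(probes, target_fragments))
  } else {
    integer(0)
  }
  pct_without <- 100 * (nrow(target_fragments) - length(covered)) / nrow(target_fragments)
  tibble(
    probe_count = nrow(probes),
    mean_probe_length = if (nrow(probes)) mean(probes$length) else NA_real_,
    pct_fragments_without_probes = pct_without,
    pct_genome_covered = 100 - pct_without
  )
}
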