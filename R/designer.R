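#' Tiling design parameters
#'
#' The complete parameter set of the two-pass tiling design. Defaults follow
#' the screening thresholds of the published method: candidates with an
#' exact nontarget match of `max_match` (18) bp or longer are ruled out;
#' exact matches of `min_match` (8) bp or longer are extended up to the
#' `min_similarity` (66 %) identity floor and scored thermodynamically; a
#' candidate is selected only if its target melting temperature exceeds its
#' closest nontarget's by at least `min_delta_tm` (5 C). Probe lengths
#' default to 36-46 bp so that around two non-overlapping probes of ~40 bp
#' fit a 100-bp fragment, and probes costing more than `max_cycles` (148)
#' synthesis cycles are removed from the merged design.
#'
#' @param fragment_size target fragment width, bp.
#' @param boundary_width_pass1,boundary_width_pass2 boundary-avoidance
#'   window widths for the two passes, bp.
#' @param max_match inclusive exact-match rule-out length, bp.
#' @param min_match minimum screened exact-match length, bp.
#' @param min_similarity identity floor for seed extension, fraction.
#' @param min_delta_tm minimum target-vs-nontarget Tm separation, degC.
#' @param probe_len_min,probe_len_max candidate probe length range, bp.
#' @param max_probes_per_fragment probes selectable per fragment.
#' @param max_cycles synthesis-cycle budget per probe.
#' @param audit_delta_tm Tm-separation threshold used when flagging probes
#'   in audit mode; defaults to `min_delta_tm`.
#' @param conditions a [thermo_conditions()] object.
#' @param seed integer seed reserved for randomized tie-breaking (the
#'   default selection rule is fully deterministic and ignores it).
#' @return an object of class `design_params`.
#' @export
design_params <- function(fragment_size = 100L,
                          boundary_width_pass1 = 50L,
                          boundary_width_pass2 = 40L,
                          max_match = 18L,
                          min_match = 8L,
                          min_similarity = 0.66,
                          min_delta_tm = 5,
                          probe_len_min = 36L,
                          probe_len_max = 46L,
                          max_probes_per_fragment = 2L,
                          max_cycles = 148L,
                          audit_delta_tm = min_delta_tm,
                          conditions = thermo_conditions(),
                          seed = 1L) {
  p <- list(
    fragment_size = as.integer(fragment_size),
    boundary_width_pass1 = as.integer(boundary_width_pass1),
    boundary_width_pass2 = as.integer(boundary_width_pass2),
    max_match = as.integer(max_match),
    min_match = as.integer(min_match),
    min_similarity = min_similarity,
    min_delta_tm = min_delta_tm,
    probe_len_min = as.integer(probe_len_min),
    probe_len_max = as.integer(probe_len_max),
    max_probes_per_fragment = as.integer(max_probes_per_fragment),
    max_cycles = as.integer(max_cycles),
    audit_delta_tm = audit_delta_tm,
    conditions = conditions,
    seed = as.integer(seed)
  )
  if (p$min_match > p$max_match) abort("`min_match` must be <= `max_match`")
  if (p$probe_len_min > p$probe_len_max) abort("`probe_len_min` must be <= `probe_len_max`")
  if (p$probe_len_max > p$fragment_size) abort("`probe_len_max` must be <= `fragment_size`")
  if (p$min_similarity <= 0 || p$min_similarity > 1) abort("`min_similarity` must be in (0, 1]")
  if (p$min_delta_tm <= 0) abort("`min_delta_tm` must be > 0")
  structure(p, class = "design_params")
}

#' Read design parameters from a flat YAML config
#'
#' Every field of [design_params()] may appear as a top-level key;
#' hybridization conditions use the keys `sodium_molar`,
#' `strand_conc_molar` and `symmetry_factor`. Unknown keys are an error.
#'
#' @param path YAML file path.
#' @return a [design_params()] object.
#' @export
read_design_config <- function(path) {
  cfg <- yaml::read_yaml(path) %||% list()
  cond_keys <- c("sodium_molar", "strand_conc_molar", "symmetry_factor")
  par_keys <- setdiff(names(formals(design_params)), "conditions")
  unknown <- setdiff(names(cfg), c(par_keys, cond_keys))
  if (length(unknown)) {
    abort(paste0("unknown config keys: ", paste(unknown, collapse = ", ")))
  }
  cond <- do.call(thermo_conditions, cfg[intersect(names(cfg), cond_keys)])
  do.call(design_params, c(cfg[intersect(names(cfg), par_keys)], list(conditions = cond)))
}

#' Enumerate probe candidates of a target fragment
#'
#' Every substring of the fragment with length in the configured probe
#' range, fully inside the fragment; candidates containing `N` are
#' rejected. Ordered by start, then length.
#'
#' @param fragment one row of a fragment tibble (role `target`).
#' @param params a [design_params()] object.
#' @return a candidate tibble (`genome_id`, `start`, `end`, `length`,
#'   `sequence`), coordinates absolute on the genome top strand.
#' @export
enumerate_candidates <- function(fragment, params = design_params()) {
  flen <- fragment$end - fragment$start
  lens <- params$probe_len_min:params$probe_len_max
  lens <- lens[lens <= flen]
  if (length(lens) == 0L) {
    return(tibble(genome_id = character(), start = integer(), end = integer(),
                  length = integer(), sequence = character()))
  }
  out <- purrr::map_dfr(lens, function(l) {
    rel <- 0:(flen - l)
    tibble(
      genome_id = fragment$genome_id,
      start = fragment$start + rel,
      end = fragment$start + rel + l,
      length = l,
      sequence = substring(fragment$sequence, rel + 1L, rel + l)
    )
  })
  out <- out[!stringi::stri_detect_fixed(out$sequence, "N"), , drop = FALSE]
  arrange(out, .data$start, .data$length)
}

#' Thermodynamic screen of a single probe candidate
#'
#' Applies the three-rule screen in order: (1) rule out any candidate with
#' an exact nontarget match of `max_match` bp or longer; (2) extend every
#' remaining seed into a duplex layout and compute its melting temperature;
#' (3) accept the candidate only when no screenable nontarget exists or
#' when the target-vs-closest-nontarget Tm separation is at least
#' `min_delta_tm`. The closest nontarget is the layout with the highest
#' melting temperature, not the highest identity.
#'
#' @param candidate one candidate row ([enumerate_candidates()]); a plain
#'   list with `genome_id`, `start`, `end`, `sequence` also works.
#' @param index [build_index()] over the genome records plus the current
#'   avoidance fragments.
#' @param params a [design_params()] object.
#' @return a one-row screen tibble with `verdict` in `accepted`,
#'   `rejected_long_match`, `rejected_delta_tm`, `rejected_alphabet`, plus
#'   `tm_target`, `tm_nontarget`, `delta_tm` and the best nontarget locus.
#' @export
screen_candidate <- function(candidate, index, params = design_params()) {
  res <- screen_core(
    list(genome_id = candidate$genome_id, start = candidate$start,
         end = candidate$end, sequence = candidate$sequence),
    NULL, index, params
  )
  screen_tbl_from_lists(list(res))
}

drop_self_raw <- function(seeds, index, candidate) {
  if (n_seeds(seeds) == 0L) {
    return(seeds)
  }
  os0 <- seeds$os - 1L
  # plus-strand oriented coordinates are already top-strand coordinates
  self <- seeds$strand == 1L &
    index$records$id[seeds$rec] == candidate$genome_id &
    interval_overlap(os0, os0 + seeds$len, candidate$start, candidate$end) > 0L
  subset_seeds(seeds, !self)
}

# screen one candidate (plain list with genome_id/start/end/sequence);
# `seeds` may be precomputed raw seeds (already self-excluded) or NULL
screen_core <- function(cand, seeds, index, params) {
  if (stringi::stri_detect_fixed(cand$sequence, "N")) {
    return(screen_result(cand, "rejected_alphabet", NA_real_, NA_real_, NULL))
  }
  if (is.null(seeds)) {
    seeds <- drop_self_raw(raw_seeds(cand$sequence, index), index, cand)
  }
  if (n_seeds(seeds) > 0L && any(seeds$len >= params$max_match)) {
    return(screen_result(cand, "rejected_long_match", NA_real_, NA_real_, NULL))
  }
  tm_t <- tm_perfect(cand$sequence, conditions = params$conditions)
  if (n_seeds(seeds) == 0L) {
    return(screen_result(cand, "accepted", tm_t, NA_real_, NULL))
  }
  layouts <- candidate_layouts(cand$sequence, index, seeds, params$min_similarity)
  tms <- vapply(layouts, tm_duplex, numeric(1), conditions = params$conditions)
  if (all(is.na(tms))) {
    return(screen_result(cand, "accepted", tm_t, NA_real_, NULL))
  }
  best <- which.max(tms)
  tm_nt <- tms[best]
  verdict <- if (tm_t - tm_nt >= params$min_delta_tm) "accepted" else "rejected_delta_tm"
  screen_result(cand, verdict, tm_t, tm_nt, layouts[[best]])
}

screen_result <- function(cand, verdict, tm_t, tm_nt, best_layout) {
  span <- if (is.null(best_layout)) c(NA_integer_, NA_integer_) else attr(best_layout, "subject_span")
  list(
    genome_id = cand$genome_id, start = cand$start, end = cand$end,
    sequence = cand$sequence, verdict = verdict,
    tm_target = tm_t, tm_nontarget = tm_nt,
    delta_tm = if (is.na(tm_nt)) NA_real_ else tm_t - tm_nt,
    nontarget_id = if (is.null(best_layout)) NA_character_ else attr(best_layout, "subject_id"),
    nontarget_start = as.integer(span[1L]), nontarget_end = as.integer(span[2L]),
    nontarget_strand = if (is.null(best_layout)) NA_character_ else attr(best_layout, "strand")
  )
}

screen_tbl_from_lists <- function(rows) {
  pick <- function(f, mode) vapply(rows, `[[`, vector(mode, 1L), f)
  tibble(
    genome_id = pick("genome_id", "character"),
    start = pick("start", "integer"),
    end = pick("end", "integer"),
    length = pick("end", "integer") - pick("start", "integer"),
    sequence = pick("sequence", "character"),
    verdict = pick("verdict", "character"),
    tm_target = pick("tm_target", "numeric"),
    tm_nontarget = pick("tm_nontarget", "numeric"),
    delta_tm = pick("delta_tm", "numeric"),
    nontarget_id = pick("nontarget_id", "character"),
    nontarget_start = pick("nontarget_start", "integer"),
    nontarget_end = pick("nontarget_end", "integer"),
    nontarget_strand = pick("nontarget_strand", "character")
  )
}

# screen all candidates of one fragment, reusing a single fragment-level
# seed enumeration: a candidate's maximal seeds are the fragment's maximal
# seeds clipped to the candidate window (clipping preserves exactness and
# maximality within the window)
screen_fragment <- function(fragment, index, params) {
  cands <- enumerate_candidates(fragment, params)
  if (nrow(cands) == 0L) {
    return(screen_tbl_from_lists(list()))
  }
  fseeds <- raw_seeds(fragment$sequence, index)
  frag_start <- fragment$start
  rows <- vector("list", nrow(cands))
  for (i in seq_len(nrow(cands))) {
    cand <- list(
      genome_id = cands$genome_id[i], start = cands$start[i],
      end = cands$end[i], sequence = cands$sequence[i]
    )
    rel_cs <- cand$start - frag_start + 1L   # 1-based fragment-relative
    rel_ce <- cand$end - frag_start
    qs2 <- pmax(fseeds$qs, rel_cs)
    qe2 <- pmin(fseeds$qs + fseeds$len - 1L, rel_ce)
    keep <- (qe2 - qs2 + 1L) >= params$min_match
    seeds <- list(
      rec = fseeds$rec[keep], strand = fseeds$strand[keep],
      qs = qs2[keep] - rel_cs + 1L,
      os = fseeds$os[keep] + (qs2[keep] - fseeds$qs[keep]),
      len = qe2[keep] - qs2[keep] + 1L
    )
    seeds <- drop_self_raw(seeds, index, cand)
    rows[[i]] <- screen_core(cand, seeds, index, params)
  }
  screen_tbl_from_lists(rows)
}

#' Select probes for one fragment from its screened candidates
#'
#' From the accepted candidates, greedily chooses up to
#' `max_probes_per_fragment` mutually non-overlapping probes, ranked by
#' larger Tm separation (candidates with no screenable nontarget rank above
#' any finite separation), then by target Tm closest to `tm_anchor`
#' (genome-wide Tm uniformity), then by smaller start. Deterministic.
#'
#' @param fragment the fragment the candidates came from.
#' @param screened screen tibble for this fragment's candidates.
#' @param params a [design_params()] object.
#' @param tm_anchor target-Tm anchor; by default the median target Tm of
#'   the accepted candidates passed in.
#' @return a probe tibble (possibly empty when no candidate was accepted).
#' @export
select_probes <- function(fragment, screened, params = design_params(),
                          tm_anchor = NULL) {
  acc <- screened[screened$verdict == "accepted", , drop = FALSE]
  if (nrow(acc) == 0L) {
    return(empty_probe_tbl())
  }
  anchor <- tm_anchor %||% median(acc$tm_target)
  key_delta <- ifelse(is.na(acc$delta_tm), Inf, acc$delta_tm)
  o <- order(-key_delta, abs(acc$tm_target - anchor), acc$start)
  acc <- acc[o, , drop = FALSE]
  chosen <- integer(0)
  for (i in seq_len(nrow(acc))) {
    if (length(chosen) >= params$max_probes_per_fragment) break
    ok <- all(interval_overlap(acc$start[i], acc$end[i],
                               acc$start[chosen], acc$end[chosen]) == 0L)
    if (ok) chosen <- c(chosen, i)
  }
  sel <- acc[sort(chosen), , drop = FALSE]
  tibble(
    probe_id = sprintf("%s:%d-%d", sel$genome_id, sel$start, sel$end),
    genome_id = sel$genome_id,
    start = sel$start, end = sel$end, length = sel$length,
    sequence = sel$sequence,
    tm_target = sel$tm_target, tm_nontarget = sel$tm_nontarget,
    delta_tm = sel$delta_tm,
    design_pass = fragment$pass_label,
    cycles = NA_integer_
  )
}

empty_probe_tbl <- function() {
  tibble(
    probe_id = character(), genome_id = character(),
    start = integer(), end = integer(), length = integer(),
    sequence = character(), tm_target = numeric(),
    tm_nontarget = numeric(), delta_tm = numeric(),
    design_pass = integer(), cycles = integer()
  )
}

#' Synthesis-cycle cost of a probe
#'
#' Simulates cyclic in-situ synthesis with the fixed dispense schedule
#' A, C, G, T repeating. The probe is synthesized 3'->5', i.e. over the
#' reversed sequence; each base consumes dispenses until the schedule
#' pointer reaches it. Vectorised over probes.
#'
#' @param seq character vector of probe sequences over `{A,C,G,T}`.
#' @return integer vector of total dispense counts.
#' @export
#' @examples
#' synthesis_cycles(c("A", "AAAA", "ACGT"))
synthesis_cycles <- function(seq) {
  vapply(seq, function(s) {
    s <- toupper(s)
    if (stringi::stri_detect_regex(s, "[^ACGT]")) {
      abort("synthesis_cycles: sequence must contain only A/C/G/T")
    }
    idx <- match(rev(seq_chars(s)), DNA_BASES) - 1L
    ptr <- c(0L, (idx[-length(idx)] + 1L) %% 4L)
    sum((idx - ptr) %% 4L + 1L)
  }, integer(1), USE.NAMES = FALSE)
}

run_design_pass <- function(targets, avoid, genomes, params, pass_label) {
  avoid_records <- if (nrow(avoid)) {
    tibble(
      id = sprintf("%s:%d-%d:%s", avoid$genome_id, avoid$start, avoid$end, avoid$role),
      sequence = avoid$sequence
    )
  } else {
    tibble(id = character(), sequence = character())
  }
  index <- build_index(
    bind_rows(tibble(id = genomes$id, sequence = genomes$sequence), avoid_records),
    min_match = params$min_match
  )
  screened <- purrr::map(seq_len(nrow(targets)), function(i) {
    screen_fragment(targets[i, ], index, params)
  })
  all_screened <- bind_rows(screened)
  acc <- all_screened[all_screened$verdict == "accepted", , drop = FALSE]
  anchor <- if (nrow(acc)) median(acc$tm_target) else NA_real_
  probes <- purrr::map_dfr(seq_len(nrow(targets)), function(i) {
    select_probes(targets[i, ], screened[[i]], params, tm_anchor = anchor)
  })
  counts <- table(factor(all_screened$verdict, levels = c(
    "accepted", "rejected_long_match", "rejected_delta_tm", "rejected_alphabet"
  )))
  list(
    probes = probes, index = index,
    counts = tibble(
      pass = pass_label,
      candidates = nrow(all_screened),
      rejected_long_match = unname(counts[["rejected_long_match"]]),
      rejected_delta_tm = unname(counts[["rejected_delta_tm"]]),
      rejected_alphabet = unname(counts[["rejected_alphabet"]]),
      accepted = unname(counts[["accepted"]]),
      selected = nrow(probes)
    )
  )
}

#' Design a whole-genome tiling probe set
#'
#' The full two-pass design: pass 1 tiles each genome into
#' `fragment_size`-bp target fragments, screens every candidate against the
#' whole genome (both strands) plus 50-bp boundary-avoidance fragments, and
#' selects probes per fragment. Fragments left without probes become the
#' pass-2 target set, screened against the genome, the fragments already
#' covered, and narrower 40-bp boundary fragments; the shortened boundary
#' windows let borderline probes near fragment junctions through. Probes
#' from both passes are merged and probes exceeding the synthesis-cycle
#' budget are removed (the count is reported).
#'
#' @param genomes sequence tibble from [read_fasta()] (one record per
#'   replicon/plasmid; specificity is screened jointly across records).
#' @param params a [design_params()] object.
#' @param controls optional sequence tibble of control probes appended
#'   unscreened (their count is logged; they bypass every filter except
#'   the cycle budget, which is reported but not applied to them).
#' @param verbose emit per-stage progress messages.
#' @return an object of class `tiling_design`; see [tidy.tiling_design()]
#'   and [glance.tiling_design()].
#' @export
design_tiling <- function(genomes, params = design_params(), controls = NULL,
                          verbose = FALSE) {
  if (!is.data.frame(genomes) || nrow(genomes) == 0L) {
    abort("`genomes` must contain at least one sequence record")
  }
  say <- function(...) if (verbose) message(sprintf(...))
  targets <- make_target_fragments(genomes, params$fragment_size, pass_label = 1L)
  boundaries <- make_boundary_fragments(
    genomes, params$fragment_size, params$boundary_width_pass1, pass_label = 1L
  )
  say("pass 1: %d target fragments, %d boundary fragments", nrow(targets), nrow(boundaries))
  p1 <- run_design_pass(targets, boundaries, genomes, params, pass_label = 1L)
  say("pass 1: %d candidates, %d selected probes", p1$counts$candidates, p1$counts$selected)

  sp <- make_second_pass_inputs(targets, p1$probes, genomes,
                                fragment_size = params$fragment_size,
                                boundary_width_pass2 = params$boundary_width_pass2)
  counts <- p1$counts
  probes <- p1$probes
  if (nrow(sp$new_targets) > 0L) {
    say("pass 2: %d uncovered fragments re-targeted", nrow(sp$new_targets))
    p2 <- run_design_pass(sp$new_targets, sp$avoid_set, genomes, params, pass_label = 2L)
    say("pass 2: %d candidates, %d selected probes", p2$counts$candidates, p2$counts$selected)
    probes <- bind_rows(probes, p2$probes)
    counts <- bind_rows(counts, p2$counts)
  }
  probes <- arrange(probes, .data$genome_id, .data$start, .data$end)
  probes$cycles <- if (nrow(probes)) synthesis_cycles(probes$sequence) else integer(0)
  over <- probes$cycles > params$max_cycles
  removed_cycles <- sum(over)
  if (removed_cycles) {
    say("removed %d probe(s) exceeding the %d-cycle budget", removed_cycles, params$max_cycles)
  }
  probes <- probes[!over, , drop = FALSE]
  n_controls <- 0L
  if (!is.null(controls) && nrow(controls)) {
    n_controls <- nrow(controls)
    say("appending %d unscreened control probe(s)", n_controls)
    ctl <- tibble(
      probe_id = controls$id, genome_id = NA_character_,
      start = NA_integer_, end = NA_integer_,
      length = nchar(controls$sequence), sequence = toupper(controls$sequence),
      tm_target = NA_real_, tm_nontarget = NA_real_, delta_tm = NA_real_,
      design_pass = NA_integer_, cycles = synthesis_cycles(controls$sequence)
    )
    probes <- bind_rows(probes, ctl)
  }
  designed <- probes[!is.na(probes$design_pass), , drop = FALSE]
  structure(
    list(
      probes = probes,
      fragments = targets,
      params = params,
      counts = counts,
      removed_cycles = removed_cycles,
      n_controls = n_controls,
      coverage = coverage_stats(designed, targets)
    ),
    class = "tiling_design"
  )
}

#' @export
print.tiling_design <- function(x, ...) {
  cat("<tiling_design>\n")
  cat(sprintf("  %d probe(s) over %d target fragment(s)\n",
              nrow(x$probes), nrow(x$fragments)))
  cat(sprintf("  genome covered: %.2f%% (fragments without probes: %.2f%%)\n",
              x$coverage$pct_genome_covered, x$coverage$pct_fragments_without_probes))
  cat(sprintf("  mean probe length: %.1f bp; removed over cycle budget: %d\n",
              x$coverage$mean_probe_length, x$removed_cycles))
  print(x$counts)
  invisible(x)
}
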