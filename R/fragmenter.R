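#' Partition genomes into non-overlapping target fragments
#'
#' Tiles each genome record with consecutive fragments of `fragment_size`
#' base pairs; the terminal fragment of a record may be shorter and is kept
#' as a design target. Coordinates are 0-based, half-open, on the top strand.
#' Genomes are treated as linear; no fragment wraps a sequence end.
#'
#' @param genomes sequence tibble (see [read_fasta()]); one or more records.
#' @param fragment_size target fragment width in bp (default 100).
#' @param pass_label design-pass label recorded on the fragments.
#' @return a fragment tibble with columns `genome_id`, `start`, `end`,
#'   `role`, `pass_label`, `sequence`; concatenating `sequence` per genome
#'   reproduces the genome exactly.
#' @export
#' @examples
#' g <- tibble::tibble(id = "g1", description = "", sequence = strrep("ACGT", 60))
#' make_target_fragments(g, fragment_size = 100)
make_target_fragments <- function(genomes, fragment_size = 100L, pass_label = 1L) {
  assert_scalar_number(fragment_size, "fragment_size", lower = 1)
  if (!is.data.frame(genomes) || nrow(genomes) == 0L) {
    abort("`genomes` must contain at least one sequence record")
  }
  if (any(!nzchar(genomes$sequence))) {
    abort("empty genome sequence cannot be fragmented")
  }
  purrr::map_dfr(seq_len(nrow(genomes)), function(i) {
    L <- nchar(genomes$sequence[i])
    starts <- seq.int(0L, L - 1L, by = fragment_size)
    ends <- pmin(starts + fragment_size, L)
    tibble(
      genome_id = genomes$id[i],
      start = as.integer(starts), end = as.integer(ends),
      role = "target", pass_label = as.integer(pass_label),
      sequence = substring(genomes$sequence[i], starts + 1L, ends)
    )
  })
}

#' Extract boundary-centered avoidance fragments
#'
#' One fragment per internal boundary between adjacent target fragments,
#' centered on the boundary (`boundary_width / 2` bp on either side) and
#' clipped at sequence ends. These are screened as nontargets so that no
#' selected probe straddles a fragment junction.
#'
#' @inheritParams make_target_fragments
#' @param boundary_width even width of the avoidance window (50 for the
#'   first design pass, 40 for the second).
#' @return a fragment tibble with role `boundary_avoid`.
#' @export
make_boundary_fragments <- function(genomes, fragment_size = 100L,
                                    boundary_width = 50L, pass_label = 1L) {
  assert_scalar_number(boundary_width, "boundary_width", lower = 2)
  if (boundary_width %% 2 != 0) {
    abort("`boundary_width` must be even (the window is centered on a boundary)")
  }
  if (boundary_width >= 2 * fragment_size) {
    abort("`boundary_width` must be < 2 * fragment_size")
  }
  purrr::map_dfr(seq_len(nrow(genomes)), function(i) {
    L <- nchar(genomes$sequence[i])
    b <- seq.int(fragment_size, by = fragment_size,
                 length.out = max(0L, ceiling(L / fragment_size) - 1L))
    b <- b[b < L]
    if (length(b) == 0L) {
      return(tibble(
        genome_id = character(), start = integer(), end = integer(),
        role = character(), pass_label = integer(), sequence = character()
      ))
    }
    half <- boundary_width %/% 2
    starts <- pmax(0L, b - half)
    ends <- pmin(L, b + half)
    tibble(
      genome_id = genomes$id[i],
      start = as.integer(starts), end = as.integer(ends),
      role = "boundary_avoid", pass_label = as.integer(pass_label),
      sequence = substring(genomes$sequence[i], starts + 1L, ends)
    )
  })
}

#' Build the input sets for the second design pass
#'
#' Target fragments that received no first-pass probe become the new target
#' set; fragments that were covered become avoidance fragments, combined
#' with a narrower boundary-fragment set (40 bp by default). The narrower
#' boundary windows are what allow borderline probes near fragment
#' junctions to be selected on the second pass.
#'
#' @param targets first-pass target fragment tibble.
#' @param pass1_probes probe tibble from the first pass.
#' @param genomes sequence tibble the fragments came from.
#' @param fragment_size target fragment width used for `targets`.
#' @param boundary_width_pass2 boundary window width for the second pass.
#' @return a list with `new_targets` (pass-2 target fragments) and
#'   `avoid_set` (covered fragments plus pass-2 boundary fragments).
#' @export
make_second_pass_inputs <- function(targets, pass1_probes, genomes,
                                    fragment_size = 100L,
                                    boundary_width_pass2 = 40L) {
  cover <- probe_fragment_assignment(pass1_probes, targets)
  covered_idx <- sort(unique(cover))
  new_targets <- targets[setdiff(seq_len(nrow(targets)), covered_idx), , drop = FALSE]
  new_targets$pass_label <- 2L
  covered <- targets[covered_idx, , drop = FALSE]
  if (nrow(covered)) {
    covered$role <- "covered_avoid"
    covered$pass_label <- 2L
  }
  boundaries <- make_boundary_fragments(
    genomes, fragment_size = fragment_size,
    boundary_width = boundary_width_pass2, pass_label = 2L
  )
  list(new_targets = new_targets, avoid_set = bind_rows(covered, boundaries))
}

# map each probe to the index of the target fragment that fully contains it;
# errors if a probe is not contained in exactly one fragment
probe_fragment_assignment <- function(probes, targets) {
  if (nrow(probes) == 0L) {
    return(integer(0))
  }
  vapply(seq_len(nrow(probes)), function(i) {
    j <- which(
      targets$genome_id == probes$genome_id[i] &
        targets$start <= probes$start[i] &
        targets$end >= probes$end[i]
    )
    if (length(j) != 1L) {
      abort(sprintf(
        "probe %s [%d,%d) is not contained in exactly one target fragment",
        probes$probe_id[i], probes$start[i], probes$end[i]
      ))
    }
    j
  }, integer(1))
}
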