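#' Deterministic random genome
#'
#' Draws an i.i.d. DNA sequence with the requested GC fraction. Generation
#' is reproducible for a fixed seed and leaves the caller's RNG state
#' untouched.
#'
#' @param length sequence length, bp.
#' @param gc_fraction expected fraction of G+C in (0, 1).
#' @param seed integer seed.
#' @param id record id (defaults to a descriptive synthetic id).
#' @return a one-row sequence tibble.
#' @export
#' @examples
#' random_genome(100, gc_fraction = 0.5, seed = 7)
random_genome <- function(length, gc_fraction = 0.5, seed = 1L,
                          id = sprintf("synth_L%d_s%d", length, seed)) {
  assert_scalar_number(length, "length", lower = 1)
  assert_scalar_number(gc_fraction, "gc_fraction", lower = 0, upper = 1)
  seq <- with_seed(seed, {
    probs <- c((1 - gc_fraction) / 2, gc_fraction / 2,
               gc_fraction / 2, (1 - gc_fraction) / 2)
    paste(sample(DNA_BASES, length, replace = TRUE, prob = probs), collapse = "")
  })
  tibble(id = id, description = "synthetic genome", sequence = seq)
}

#' Random genome with no repeated k-mer on either strand
#'
#' Greedy construction (with backtracking) of a sequence in which every
#' k-mer, together with its reverse complement, occurs exactly once. Such a
#' genome contains no exact self-match of length >= k anywhere off-locus,
#' so every probe candidate passes the match screen by construction --
#' useful as a positive control for the designer.
#'
#' @param length sequence length, bp (must be feasible for the chosen k).
#' @param k repeat-free word size (default 8, the screening `min_match`).
#' @param seed integer seed.
#' @param id record id.
#' @return a one-row sequence tibble.
#' @export
random_unique_genome <- function(length, k = 8L, seed = 1L,
                                 id = sprintf("uniq_L%d_s%d", length, seed)) {
  assert_scalar_number(length, "length", lower = k)
  seq <- with_seed(seed, {
    repeat {
      seen <- new.env(parent = emptyenv())
      chars <- character(length)
      chars[1:k] <- sample(DNA_BASES, k, replace = TRUE)
      w <- paste(chars[1:k], collapse = "")
      if (w == dna_revcomp(w)) next
      assign(w, TRUE, seen)
      assign(dna_revcomp(w), TRUE, seen)
      i <- k
      stuck <- FALSE
      while (i < length) {
        ok <- FALSE
        for (b in sample(DNA_BASES)) {
          w <- paste(c(chars[(i - k + 2L):i], b), collapse = "")
          if (!exists(w, seen, inherits = FALSE) &&
              !exists(dna_revcomp(w), seen, inherits = FALSE) &&
              w != dna_revcomp(w)) {
            chars[i + 1L] <- b
            assign(w, TRUE, seen)
            assign(dna_revcomp(w), TRUE, seen)
            i <- i + 1L
            ok <- TRUE
            break
          }
        }
        if (!ok) {
          stuck <- TRUE
          break
        }
      }
      if (!stuck) break
    }
    paste(chars, collapse = "")
  })
  tibble(id = id, description = "repeat-free synthetic genome", sequence = seq)
}

#' Plant an exact repeat or near-duplicate into a genome
#'
#' Copies the source interval onto the destination interval (same length,
#' in place); for `near_duplicate`, each copied base is then mutated
#' independently at `mutation_rate` to one of the three other bases
#' (seeded). The returned annotation records the ground-truth intervals and
#' the realized identity of the planted copy.
#'
#' @param genome a one-row sequence tibble.
#' @param kind `"exact_repeat"` or `"near_duplicate"`.
#' @param source_start,source_end source interval, 0-based half-open.
#' @param dest destination start (0-based); the copy replaces
#'   `[dest, dest + length)`.
#' @param mutation_rate per-base mutation probability for near-duplicates.
#' @param seed integer seed for the mutation draws.
#' @return a list with `genome` (modified sequence tibble) and `features`
#'   (one-row annotation tibble).
#' @export
plant_feature <- function(genome, kind = c("exact_repeat", "near_duplicate"),
                          source_start, source_end, dest,
                          mutation_rate = 0, seed = 1L) {
  kind <- match.arg(kind)
  L <- nchar(genome$sequence)
  len <- source_end - source_start
  if (len < 1L || source_start < 0L || source_end > L) {
    abort("source interval out of range")
  }
  if (dest < 0L || dest + len > L) {
    abort("destination interval out of range")
  }
  if (interval_overlap(source_start, source_end, dest, dest + len) > 0L) {
    abort("planted feature destination overlaps its source")
  }
  src <- substr(genome$sequence, source_start + 1L, source_end)
  copy <- src
  if (kind == "near_duplicate" && mutation_rate > 0) {
    copy <- with_seed(seed, {
      ch <- seq_chars(src)
      hit <- which(stats::runif(len) < mutation_rate)
      for (i in hit) {
        ch[i] <- sample(setdiff(DNA_BASES, ch[i]), 1L)
      }
      paste(ch, collapse = "")
    })
  }
  realized <- mean(seq_chars(copy) == seq_chars(src))
  s <- genome$sequence
  substr(s, dest + 1L, dest + len) <- copy
  genome$sequence <- s
  list(
    genome = genome,
    features = tibble(
      kind = kind, source_start = source_start, source_end = source_end,
      dest_start = dest, dest_end = dest + len,
      mutation_rate = mutation_rate, realized_identity = realized
    )
  )
}

#' Labeled candidate probes with known screening ground truth
#'
#' From a fixture (genome plus planted-feature annotations), emits
#' candidate probes whose correct screening verdict is known by
#' construction: candidates lying inside a planted exact repeat of at
#' least `max_match` bp must be ruled out by the long-match rule;
#' candidates inside a near-duplicate have a melting-temperature-dependent
#' verdict; candidates overlapping no feature (and no feature source) are
#' expected to be accepted.
#'
#' @param fixture list with `genome` and `features` (see
#'   [plant_feature()]).
#' @param params a [design_params()] object.
#' @param probe_len length of the emitted candidates.
#' @param step start offset between consecutive candidates.
#' @return a candidate tibble with a `label` column in
#'   `{ruled_out, delta_dependent, unique_accept}`.
#' @export
make_screening_truth <- function(fixture, params = design_params(),
                                 probe_len = 40L, step = 7L) {
  genome <- fixture$genome
  feats <- fixture$features
  L <- nchar(genome$sequence)
  cand_in <- function(from, to, label) {
    starts <- seq.int(from, by = step, length.out = max(0L, (to - from - probe_len) %/% step + 1L))
    starts <- starts[starts + probe_len <= to]
    if (length(starts) == 0L) {
      return(tibble(genome_id = character(), start = integer(), end = integer(),
                    length = integer(), sequence = character(), label = character()))
    }
    tibble(
      genome_id = genome$id,
      start = as.integer(starts), end = as.integer(starts + probe_len),
      length = probe_len,
      sequence = substring(genome$sequence, starts + 1L, starts + probe_len),
      label = label
    )
  }
  out <- purrr::map_dfr(seq_len(nrow(feats)), function(i) {
    f <- feats[i, ]
    label <- if (f$kind == "exact_repeat" &&
                 f$dest_end - f$dest_start >= params$max_match) {
      "ruled_out"
    } else {
      "delta_dependent"
    }
    cand_in(f$dest_start, f$dest_end, label)
  })
  # unique-region candidates: away from all features and their sources
  occupied <- bind_rows(
    tibble(s = feats$source_start, e = feats$source_end),
    tibble(s = feats$dest_start, e = feats$dest_end)
  )
  uniq <- cand_in(0L, L, "unique_accept")
  if (nrow(uniq) && nrow(occupied)) {
    clear <- vapply(seq_len(nrow(uniq)), function(i) {
      all(interval_overlap(uniq$start[i], uniq$end[i], occupied$s, occupied$e) == 0L)
    }, logical(1))
    uniq <- uniq[clear, , drop = FALSE]
  }
  bind_rows(out, uniq)
}

#' Serialise / load a synthetic fixture
#'
#' The genome is written as FASTA and the ground-truth annotation as a JSON
#' sidecar, so fixtures round-trip exactly and can be regenerated from a
#' seed at any time.
#'
#' @param fixture list with `genome` and `features`.
#' @param prefix output path prefix; writes `<prefix>.fasta` and
#'   `<prefix>.json`.
#' @return `prefix`, invisibly.
#' @export
write_fixture <- function(fixture, prefix) {
  write_fasta(fixture$genome, paste0(prefix, ".fasta"))
  jsonlite::write_json(fixture$features, paste0(prefix, ".json"), digits = NA)
  invisible(prefix)
}

#' @rdname write_fixture
#' @export
read_fixture <- function(prefix) {
  list(
    genome = read_fasta(paste0(prefix, ".fasta")),
    features = as_tibble(jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE))
  )
}
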