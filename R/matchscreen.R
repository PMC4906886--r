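#' Exact-match k-mer index over both strands
#'
#' Indexes every `min_match`-mer of every record, on the given strand and
#' its reverse complement, so that all exact matches of length >=
#' `min_match` between a probe candidate and any indexed sequence can be
#' enumerated. Occurrence positions are stored in the oriented coordinate
#' space of each strand and converted to top-strand coordinates when seeds
#' are reported.
#'
#' @param records sequence tibble (`id`, `sequence`); typically the genome
#'   records plus the current avoidance fragments.
#' @param min_match seed k-mer size in bp (>= 4).
#' @return an object of class `match_index`.
#' @export
build_index <- function(records, min_match = 8L) {
  assert_scalar_number(min_match, "min_match", lower = 4)
  min_match <- as.integer(min_match)
  env <- new.env(parent = emptyenv(), size = max(16L, 2L * sum(nchar(records$sequence))))
  n <- nrow(records)
  chars <- vector("list", n)
  lens <- integer(n)
  for (i in seq_len(n)) {
    s <- records$sequence[i]
    L <- nchar(s)
    lens[i] <- L
    rc <- dna_revcomp(s)
    chars[[i]] <- list(`+` = seq_chars(s), `-` = seq_chars(rc))
    for (strand in 1:2) {
      ss <- if (strand == 1L) s else rc
      if (L < min_match) next
      kmers <- substring(ss, 1:(L - min_match + 1L), min_match:L)
      keep <- !stringi::stri_detect_fixed(kmers, "N")
      pos <- which(keep)
      for (j in pos) {
        km <- kmers[j]
        env[[km]] <- rbind(env[[km]], c(i, strand, j))
      }
    }
  }
  structure(
    list(
      k = min_match,
      records = tibble(id = records$id, length = lens),
      chars = chars,
      env = env
    ),
    class = "match_index"
  )
}

#' @export
print.match_index <- function(x, ...) {
  cat(sprintf(
    "<match_index> k=%d over %d record(s), %s indexed positions\n",
    x$k, nrow(x$records), format(sum(pmax(0L, x$records$length - x$k + 1L)) * 2L)
  ))
  invisible(x)
}

# all maximal exact matches between `seq` and the index, in oriented
# coordinates. Returns a plain list of parallel vectors (rec, strand
# (1=+,2=-), qs, os, len; qs/os 1-based) -- the hot path avoids tibbles.
raw_seeds <- function(seq, index) {
  k <- index$k
  L <- nchar(seq)
  empty <- list(rec = integer(), strand = integer(), qs = integer(),
                os = integer(), len = integer())
  if (L < k) {
    return(empty)
  }
  kmers <- substring(seq, 1:(L - k + 1L), k:L)
  occ_list <- lapply(kmers, function(km) index$env[[km]])
  nh <- vapply(occ_list, function(m) if (is.null(m)) 0L else nrow(m), integer(1))
  if (sum(nh) == 0L) {
    return(empty)
  }
  qpos <- rep.int(seq_along(kmers), nh)
  occ <- do.call(rbind, occ_list[nh > 0L])
  rec <- occ[, 1L]
  strand <- occ[, 2L]
  spos <- occ[, 3L]
  diag <- spos - qpos
  o <- order(rec, strand, diag, qpos)
  rec <- rec[o]; strand <- strand[o]; diag <- diag[o]; qpos <- qpos[o]
  new_run <- c(TRUE, diff(rec) != 0L | diff(strand) != 0L |
                 diff(diag) != 0L | diff(qpos) != 1L)
  run_id <- cumsum(new_run)
  qs <- qpos[new_run]
  run_last <- c(new_run[-1L], TRUE)
  qe <- qpos[run_last]
  list(
    rec = rec[new_run], strand = strand[new_run],
    qs = qs, os = qs + diag[new_run], len = qe - qs + k
  )
}

n_seeds <- function(seeds) length(seeds$rec)

subset_seeds <- function(seeds, keep) {
  lapply(seeds, `[`, keep)
}

# oriented -> top-strand subject coordinates (0-based half-open)
seeds_to_public <- function(seeds, index, q_offset = 0L) {
  L <- index$records$length[seeds$rec]
  os0 <- seeds$os - 1L
  oe0 <- os0 + seeds$len
  minus <- seeds$strand == 2L
  sstart <- ifelse(minus, L - oe0, os0)
  send <- ifelse(minus, L - os0, oe0)
  tibble(
    query_start = seeds$qs - 1L + q_offset,
    query_end = seeds$qs - 1L + seeds$len + q_offset,
    subject_id = index$records$id[seeds$rec],
    subject_start = as.integer(sstart),
    subject_end = as.integer(send),
    strand = c("+", "-")[seeds$strand],
    length = seeds$len
  )
}

#' Enumerate maximal exact-match seeds for a probe candidate
#'
#' Finds every maximal exact match of length >= the index k between the
#' candidate and all indexed sequence, on both strands; maximal means not
#' extendable by one base on either side. Hits overlapping the candidate's
#' own locus on the same (top) strand are excluded -- a second verbatim copy
#' elsewhere is a genuine nontarget and is kept.
#'
#' @param candidate candidate probe sequence.
#' @param index a [build_index()] object.
#' @param self_locus optional list/row with `genome_id`, `start`, `end`
#'   (0-based half-open) giving the candidate's own locus.
#' @return a seed tibble: `query_start`, `query_end`, `subject_id`,
#'   `subject_start`, `subject_end`, `strand`, `length` (coordinates
#'   0-based half-open on the subject top strand).
#' @export
find_maximal_seeds <- function(candidate, index, self_locus = NULL) {
  candidate <- toupper(candidate)
  if (nchar(candidate) < index$k) {
    abort("candidate is shorter than the index k-mer size")
  }
  out <- seeds_to_public(raw_seeds(candidate, index), index)
  drop_self_hits(out, self_locus)
}

drop_self_hits <- function(seeds, self_locus) {
  if (is.null(self_locus) || nrow(seeds) == 0L) {
    return(seeds)
  }
  self <- seeds$strand == "+" &
    seeds$subject_id == self_locus$genome_id &
    interval_overlap(seeds$subject_start, seeds$subject_end,
                     self_locus$start, self_locus$end) > 0L
  seeds[!self, , drop = FALSE]
}

#' Long-match rule-out
#'
#' A candidate with any exact nontarget match of at least `max_match` bp
#' (18 by default, boundary inclusive) is ruled out without thermodynamic
#' screening.
#'
#' @param seeds seed tibble from [find_maximal_seeds()].
#' @param max_match rule-out length in bp.
#' @return `TRUE` if any seed is at least `max_match` long.
#' @export
has_ruling_out_match <- function(seeds, max_match = 18L) {
  nrow(seeds) > 0L && any(seeds$length >= max_match)
}

subject_view <- function(subjects, subject_id, strand) {
  if (inherits(subjects, "match_index")) {
    i <- match(subject_id, subjects$records$id)
    if (is.na(i)) abort(sprintf("unknown subject '%s'", subject_id))
    return(subjects$chars[[i]][[strand]])
  }
  i <- match(subject_id, subjects$id)
  if (is.na(i)) abort(sprintf("unknown subject '%s'", subject_id))
  s <- subjects$sequence[i]
  seq_chars(if (strand == "+") s else dna_revcomp(s))
}

# symmetric greedy ungapped extension of a seed/bridged core.
# qch/sch: candidate and oriented-subject character vectors; the core spans
# candidate [qs,qe] and subject [ss,se] (1-based inclusive, oriented) and
# contributes `pairs0` pair columns and `core` layout columns.
# Extension proceeds in rounds: in each round both open sides propose their
# next column, matching bases are always added, and mismatch admissibility
# is decided against the same round-start identity snapshot -- when only one
# of two simultaneous mismatches would fit under the floor, both sides stop.
# This makes the result invariant under flipping the duplex end-for-end,
# which keeps screening strand symmetric.
extend_core <- function(qch, sch, core, qs, ss, qe, se, pairs0, min_similarity) {
  pairs <- pairs0
  mism <- 0L
  lp <- character(0); lc <- character(0); lk <- character(0)
  rp <- character(0); rc <- character(0); rk <- character(0)
  ql <- qs - 1L; sl <- ss - 1L
  qr <- qe + 1L; sr <- se + 1L
  left_open <- TRUE
  right_open <- TRUE
  nq <- length(qch)
  ns <- length(sch)
  while (left_open || right_open) {
    l_kind <- if (!left_open || ql < 1L || sl < 1L) {
      "end"
    } else if (qch[ql] == sch[sl] && qch[ql] != "N") {
      "pair"
    } else if (qch[ql] != "N" && sch[sl] != "N") {
      "mismatch"
    } else {
      "end"
    }
    r_kind <- if (!right_open || qr > nq || sr > ns) {
      "end"
    } else if (qch[qr] == sch[sr] && qch[qr] != "N") {
      "pair"
    } else if (qch[qr] != "N" && sch[sr] != "N") {
      "mismatch"
    } else {
      "end"
    }
    if (l_kind == "end") left_open <- FALSE
    if (r_kind == "end") right_open <- FALSE
    if (l_kind == "pair") {
      lp <- c(qch[ql], lp); lc <- c(COMP[[sch[sl]]], lc); lk <- c("pair", lk)
      pairs <- pairs + 1L; ql <- ql - 1L; sl <- sl - 1L
    }
    if (r_kind == "pair") {
      rp <- c(rp, qch[qr]); rc <- c(rc, COMP[[sch[sr]]]); rk <- c(rk, "pair")
      pairs <- pairs + 1L; qr <- qr + 1L; sr <- sr + 1L
    }
    n_new <- (l_kind == "mismatch") + (r_kind == "mismatch")
    if (n_new > 0L) {
      if (pairs / (pairs + mism + n_new) >= min_similarity) {
        if (l_kind == "mismatch") {
          lp <- c(qch[ql], lp); lc <- c(COMP[[sch[sl]]], lc); lk <- c("mismatch", lk)
          ql <- ql - 1L; sl <- sl - 1L
        }
        if (r_kind == "mismatch") {
          rp <- c(rp, qch[qr]); rc <- c(rc, COMP[[sch[sr]]]); rk <- c(rk, "mismatch")
          qr <- qr + 1L; sr <- sr + 1L
        }
        mism <- mism + n_new
      } else {
        if (l_kind == "mismatch") left_open <- FALSE
        if (r_kind == "mismatch") right_open <- FALSE
      }
    }
  }
  probe <- c(lp, core$probe, rp)
  counter <- c(lc, core$counter, rc)
  kind <- c(lk, core$kind, rk)
  # single dangling-end columns for unhybridized subject (or probe) bases
  # adjacent to a terminal pair
  if (kind[1L] == "pair") {
    if (sl >= 1L && sch[sl] != "N") {
      probe <- c("-", probe); counter <- c(COMP[[sch[sl]]], counter)
      kind <- c("dangle_counter", kind)
    } else if (sl < 1L && ql >= 1L && qch[ql] != "N") {
      probe <- c(qch[ql], probe); counter <- c("-", counter)
      kind <- c("dangle_probe", kind)
    }
  }
  nlast <- length(kind)
  if (kind[nlast] == "pair") {
    if (sr <= ns && sch[sr] != "N") {
      probe <- c(probe, "-"); counter <- c(counter, COMP[[sch[sr]]])
      kind <- c(kind, "dangle_counter")
    } else if (sr > ns && qr <= nq && qch[qr] != "N") {
      probe <- c(probe, qch[qr]); counter <- c(counter, "-")
      kind <- c(kind, "dangle_probe")
    }
  }
  list(probe = probe, counter = counter, kind = kind,
       s_from = sl + 1L, s_to = sr - 1L, pairs = pairs, mismatches = mism)
}

#' Extend an exact-match seed into a duplex layout
#'
#' Grows the seed outward symmetrically, one ungapped column at a time and
#' alternating sides; a side stops at a sequence end or when adding a
#' mismatch would drop the layout-wide identity (pair columns over
#' pair-plus-mismatch columns) below `min_similarity`. Remaining
#' unhybridized subject bases adjacent to a terminal pair contribute single
#' dangling-end columns. The returned layout always satisfies the identity
#' floor and contains the seed's columns as pairs.
#'
#' @param candidate candidate probe sequence.
#' @param subjects a [build_index()] object or the sequence tibble that was
#'   indexed.
#' @param hit one seed row from [find_maximal_seeds()].
#' @param min_similarity identity floor in (0, 1].
#' @param min_match minimum legal seed length.
#' @return a [duplex_layout()] with attributes `subject_id`, `strand`,
#'   `subject_span` (0-based half-open top-strand coordinates of the
#'   counter-strand region) and `identity`.
#' @export
extend_seed <- function(candidate, subjects, hit, min_similarity = 0.66,
                        min_match = 8L) {
  if (min_similarity <= 0 || min_similarity > 1) {
    abort("`min_similarity` must be in (0, 1]")
  }
  if (hit$length < min_match) {
    abort("seed is shorter than `min_match`")
  }
  candidate <- toupper(candidate)
  qch <- seq_chars(candidate)
  sch <- subject_view(subjects, hit$subject_id, hit$strand)
  L <- length(sch)
  qs <- hit$query_start + 1L
  qe <- hit$query_end
  if (hit$strand == "+") {
    ss <- hit$subject_start + 1L
  } else {
    ss <- L - hit$subject_end + 1L
  }
  se <- ss + hit$length - 1L
  seed_p <- qch[qs:qe]
  core <- list(probe = seed_p, counter = dna_complement(seed_p),
               kind = rep("pair", hit$length))
  ext <- extend_core(qch, sch, core, qs, ss, qe, se, hit$length, min_similarity)
  finish_layout(ext, hit$strand, L, hit$subject_id)
}

finish_layout <- function(ext, strand, subject_len, subject_id) {
  layout <- duplex_layout(ext$probe, ext$counter, ext$kind, validate = FALSE)
  span0 <- c(ext$s_from - 1L, ext$s_to)
  if (strand == "-") {
    span0 <- c(subject_len - span0[2L], subject_len - span0[1L])
  }
  attr(layout, "subject_id") <- subject_id
  attr(layout, "strand") <- strand
  attr(layout, "subject_span") <- span0
  attr(layout, "identity") <- ext$pairs / (ext$pairs + ext$mismatches)
  layout
}

# bridge two same-diagonal-neighborhood seeds (oriented coordinates) with a
# bulge run, then extend the merged core outward. Returns NULL when the
# seed pair is not bridgeable.
bridge_seeds <- function(qch, sch, s1, s2, min_similarity) {
  q1e <- s1$qs + s1$len - 1L
  s1e <- s1$os + s1$len - 1L
  gq <- s2$qs - q1e - 1L
  gs <- s2$os - s1e - 1L
  bridge <- NULL
  if (gq == 0L && gs >= 1L && gs <= 3L) {
    bases <- sch[(s1e + 1L):(s1e + gs)]
    if (any(bases == "N")) return(NULL)
    bridge <- list(probe = rep("-", gs), counter = COMP[bases],
                   kind = rep("bulge_counter", gs))
  } else if (gs == 0L && gq >= 1L && gq <= 3L) {
    bases <- qch[(q1e + 1L):(q1e + gq)]
    if (any(bases == "N")) return(NULL)
    bridge <- list(probe = bases, counter = rep("-", gq),
                   kind = rep("bulge_probe", gq))
  } else {
    return(NULL)
  }
  p1 <- qch[s1$qs:q1e]
  p2 <- qch[s2$qs:(s2$qs + s2$len - 1L)]
  core <- list(
    probe = c(p1, bridge$probe, p2),
    counter = c(COMP[p1], bridge$counter, COMP[p2]),
    kind = c(rep("pair", s1$len), bridge$kind, rep("pair", s2$len))
  )
  extend_core(qch, sch, core, s1$qs, s1$os,
              s2$qs + s2$len - 1L, s2$os + s2$len - 1L,
              s1$len + s2$len, min_similarity)
}

# every nontarget layout for a candidate given its oriented seeds:
# one extension per seed plus one bridged extension per eligible adjacent
# seed pair on the same subject/strand
candidate_layouts <- function(candidate, index, seeds, min_similarity) {
  qch <- seq_chars(toupper(candidate))
  n <- n_seeds(seeds)
  layouts <- vector("list", 0L)
  if (n == 0L) {
    return(layouts)
  }
  o <- order(seeds$rec, seeds$strand, seeds$qs)
  seeds <- subset_seeds(seeds, o)
  for (i in seq_len(n)) {
    rec <- seeds$rec[i]
    strand <- if (seeds$strand[i] == 1L) "+" else "-"
    sch <- index$chars[[rec]][[strand]]
    qs <- seeds$qs[i]; os <- seeds$os[i]; len <- seeds$len[i]
    seed_p <- qch[qs:(qs + len - 1L)]
    core <- list(probe = seed_p, counter = COMP[seed_p],
                 kind = rep("pair", len))
    ext <- extend_core(qch, sch, core, qs, os,
                       qs + len - 1L, os + len - 1L, len, min_similarity)
    layouts[[length(layouts) + 1L]] <-
      finish_layout(ext, strand, length(sch), index$records$id[rec])
    if (i < n && seeds$rec[i + 1L] == rec && seeds$strand[i + 1L] == seeds$strand[i]) {
      br <- bridge_seeds(
        qch, sch,
        list(qs = qs, os = os, len = len),
        list(qs = seeds$qs[i + 1L], os = seeds$os[i + 1L], len = seeds$len[i + 1L]),
        min_similarity
      )
      if (!is.null(br)) {
        layouts[[length(layouts) + 1L]] <-
          finish_layout(br, strand, length(sch), index$records$id[rec])
      }
    }
  }
  layouts
}
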