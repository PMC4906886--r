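#' Read a FASTA file into a sequence table
#'
#' Sequences are uppercased on input and validated against the DNA alphabet
#' `{A, C, G, T, N}`; anything else is a hard error naming the record and the
#' offending position. Record order is preserved and ids (the first
#' whitespace-delimited token of each header) must be non-empty and unique.
#'
#' @param path path to a FASTA file (wrapped or unwrapped).
#' @return a tibble with columns `id`, `description`, `sequence`.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">g1 a toy record", "acgt", "ACGT"), fa)
#' read_fasta(fa)
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("FASTA file not found: %s", path))
  }
  first <- readLines(path, n = 50L, warn = FALSE)
  nonblank <- which(nzchar(trimws(first)))
  if (length(nonblank) > 0 && !startsWith(trimws(first[nonblank[1]]), ">")) {
    abort(sprintf(
      "malformed FASTA: line %d of %s does not start a record ('>' expected)",
      nonblank[1], path
    ))
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    return(tibble(id = character(), description = character(), sequence = character()))
  }
  headers <- names(set) %||% rep("", length(set))
  id <- sub("\\s.*$", "", headers)
  description <- trimws(sub("^\\S*\\s*", "", headers))
  if (any(!nzchar(id))) {
    abort(sprintf("FASTA record %d has an empty id", which(!nzchar(id))[1]))
  }
  if (anyDuplicated(id)) {
    abort(sprintf("duplicate FASTA id: %s", id[duplicated(id)][1]))
  }
  sequence <- unname(toupper(as.character(set)))
  bad <- stringi::stri_locate_first_regex(sequence, "[^ACGTN]")[, "start"]
  if (any(!is.na(bad))) {
    i <- which(!is.na(bad))[1]
    abort(sprintf(
      "illegal character '%s' at position %d of record '%s' (alphabet is A/C/G/T/N)",
      substr(sequence[i], bad[i], bad[i]), bad[i], id[i]
    ))
  }
  tibble(id = id, description = description, sequence = sequence)
}

#' Write a sequence table to FASTA
#'
#' @param seqs tibble with columns `id`, `sequence` and optionally
#'   `description`.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(all(c("id", "sequence") %in% names(seqs)))
  desc <- if ("description" %in% names(seqs)) seqs$description else rep("", nrow(seqs))
  nm <- ifelse(nzchar(desc), paste(seqs$id, desc), seqs$id)
  set <- Biostrings::BStringSet(seqs$sequence)
  names(set) <- nm
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

probe_table_cols <- c(
  "probe_id", "genome_id", "start", "end", "length", "sequence",
  "tm_target", "tm_nontarget", "delta_tm", "design_pass", "cycles"
)

#' Write a probe table
#'
#' Serialises probes as a tab-separated table with a fixed header. Melting
#' temperatures are rendered with two decimal places; absent values (for
#' example `tm_nontarget` when no screenable nontarget exists) become empty
#' fields. Full numeric precision is a property of the in-memory table, not
#' of this interchange format.
#'
#' @param probes probe tibble (see [design_tiling()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_probe_table <- function(probes, path) {
  validate_probe_tbl(probes)
  fmt_tm <- function(x) ifelse(is.na(x), "", sprintf("%.2f", x))
  fmt_int <- function(x) ifelse(is.na(x), "", format(x, scientific = FALSE, trim = TRUE))
  out <- data.frame(
    probe_id = probes$probe_id,
    genome_id = probes$genome_id,
    start = fmt_int(probes$start),
    end = fmt_int(probes$end),
    length = fmt_int(probes$length),
    sequence = probes$sequence,
    tm_target = fmt_tm(probes$tm_target),
    tm_nontarget = fmt_tm(probes$tm_nontarget),
    delta_tm = fmt_tm(probes$delta_tm),
    design_pass = fmt_int(probes$design_pass),
    cycles = fmt_int(probes$cycles),
    check.names = FALSE
  )
  con <- tryCatch(file(path, "w"), error = function(e) {
    abort(sprintf("cannot open '%s' for writing: %s", path, conditionMessage(e)))
  })
  on.exit(close(con))
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe table (or a FASTA of probe sequences)
#'
#' Accepts the tab dialect written by [write_probe_table()] or a plain FASTA
#' of probe sequences; FASTA input yields probes with coordinates and Tm
#' fields unset, which is the typical starting point for
#' [audit_probe_set()] on a foreign probe set.
#'
#' @param path input path.
#' @return a probe tibble.
#' @export
read_probe_table <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("probe table not found: %s", path))
  }
  head1 <- readLines(path, n = 1L, warn = FALSE)
  if (startsWith(trimws(head1), ">")) {
    fa <- read_fasta(path)
    probes <- tibble(
      probe_id = fa$id, genome_id = NA_character_,
      start = NA_integer_, end = NA_integer_,
      length = nchar(fa$sequence), sequence = fa$sequence,
      tm_target = NA_real_, tm_nontarget = NA_real_, delta_tm = NA_real_,
      design_pass = NA_integer_, cycles = NA_integer_
    )
    return(probes)
  }
  raw <- read.delim(path, colClasses = "character", check.names = FALSE)
  if (!identical(names(raw), probe_table_cols)) {
    abort(paste0(
      "probe table header mismatch; expected columns: ",
      paste(probe_table_cols, collapse = ", ")
    ))
  }
  num <- function(x) ifelse(nzchar(x), suppressWarnings(as.numeric(x)), NA_real_)
  int <- function(x) ifelse(nzchar(x), suppressWarnings(as.integer(x)), NA_integer_)
  probes <- tibble(
    probe_id = raw$probe_id, genome_id = raw$genome_id,
    start = int(raw$start), end = int(raw$end), length = int(raw$length),
    sequence = toupper(raw$sequence),
    tm_target = num(raw$tm_target), tm_nontarget = num(raw$tm_nontarget),
    delta_tm = num(raw$delta_tm),
    design_pass = int(raw$design_pass), cycles = int(raw$cycles)
  )
  validate_probe_tbl(probes)
  probes
}

# invariant checks shared by the probe-table reader/writer and the designer;
# `genomes` (optional) additionally checks that each probe sequence equals
# the genome substring at its coordinates
validate_probe_tbl <- function(probes, genomes = NULL) {
  missing_cols <- setdiff(probe_table_cols, names(probes))
  if (length(missing_cols)) {
    abort(paste0("probe table lacks columns: ", paste(missing_cols, collapse = ", ")))
  }
  located <- !is.na(probes$start) & !is.na(probes$end)
  if (any(located & probes$end <= probes$start)) {
    abort("probe with end <= start (coordinates are 0-based half-open)")
  }
  if (any(located & (probes$end - probes$start) != probes$length)) {
    abort("probe with end - start != length")
  }
  if (any(probes$length != nchar(probes$sequence))) {
    abort("probe with length != nchar(sequence)")
  }
  dtm <- probes$delta_tm
  have <- !is.na(dtm) & !is.na(probes$tm_nontarget) & !is.na(probes$tm_target)
  if (any(abs(dtm[have] - (probes$tm_target[have] - probes$tm_nontarget[have])) > 0.011)) {
    abort("probe with delta_tm != tm_target - tm_nontarget")
  }
  if (!is.null(genomes)) {
    for (i in which(located)) {
      gs <- genomes$sequence[match(probes$genome_id[i], genomes$id)]
      sub <- substr(gs, probes$start[i] + 1L, probes$end[i])
      if (!identical(sub, probes$sequence[i])) {
        abort(sprintf("probe %s does not match its genome coordinates", probes$probe_id[i]))
      }
    }
  }
  invisible(probes)
}
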