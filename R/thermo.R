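#' Explicit probe/counter-strand duplex layouts
#'
#' A duplex layout is the column-by-column alignment the thermodynamic
#' engine consumes: the probe strand 5'->3' against the counter strand
#' written 3'->5', one column per position. Column kinds are `pair`
#' (Watson-Crick complementary bases), `mismatch` (two non-complementary
#' bases), `bulge_probe` / `bulge_counter` (an unpaired base on one strand,
#' gap `-` on the other), and `dangle_probe` / `dangle_counter` (a single
#' unpaired terminal base adjacent to a duplex end).
#'
#' @param probe,counter character vectors of single characters over
#'   `{A,C,G,T,-}`; a column never has two gaps.
#' @param kind character vector of column kinds.
#' @param validate check structural invariants (disable only on hot paths
#'   that construct layouts by rule).
#' @return an object of class `duplex_layout`.
#' @export
#' @examples
#' duplex_layout(c("A", "C"), c("T", "G"), c("pair", "pair"))
duplex_layout <- function(probe, counter, kind, validate = TRUE) {
  layout <- structure(
    list(probe = toupper(probe), counter = toupper(counter), kind = kind),
    class = "duplex_layout"
  )
  if (validate) validate_layout(layout)
  layout
}

layout_kinds <- c(
  "pair", "mismatch", "bulge_probe", "bulge_counter",
  "dangle_probe", "dangle_counter"
)

validate_layout <- function(layout) {
  p <- layout$probe
  cc <- layout$counter
  k <- layout$kind
  n <- length(k)
  if (n == 0L || length(p) != n || length(cc) != n) {
    abort("layout strands and kinds must be non-empty and of equal length")
  }
  if (!all(k %in% layout_kinds)) {
    abort(sprintf("unknown layout column kind '%s'", setdiff(k, layout_kinds)[1]))
  }
  if (any(p == "-" & cc == "-")) {
    abort("layout column with gaps on both strands")
  }
  comp_ok <- cc == dna_complement(p) & p != "-" & cc != "-"
  if (any(k == "pair" & !comp_ok)) {
    abort("'pair' column whose bases are not Watson-Crick complementary")
  }
  if (any(k == "mismatch" & (p == "-" | cc == "-"))) {
    abort("'mismatch' column must have bases on both strands")
  }
  if (any(k == "mismatch" & comp_ok)) {
    abort("'mismatch' column with complementary bases (should be 'pair')")
  }
  if (any(k == "bulge_probe" & !(p != "-" & cc == "-")) ||
      any(k == "bulge_counter" & !(p == "-" & cc != "-"))) {
    abort("bulge column must have exactly one gap, on the non-bulged strand")
  }
  if (!any(k == "pair")) {
    abort("layout must contain at least one 'pair' column")
  }
  dang <- which(k %in% c("dangle_probe", "dangle_counter"))
  for (i in dang) {
    at_start <- i == 1L
    at_end <- i == n
    if (!at_start && !at_end) {
      abort("dangling-end columns may occur only at layout ends")
    }
    nb <- if (at_start) i + 1L else i - 1L
    if (k[nb] != "pair") {
      abort("a dangling end must be adjacent to a 'pair' column")
    }
  }
  # bulge runs must be flanked by pair columns (seed-bridging construction)
  r <- rle(k %in% c("bulge_probe", "bulge_counter"))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (j in which(r$values)) {
    if (starts[j] == 1L || ends[j] == n ||
        k[starts[j] - 1L] != "pair" || k[ends[j] + 1L] != "pair") {
      abort("bulge runs must be flanked by 'pair' columns")
    }
  }
  invisible(layout)
}

#' @export
format.duplex_layout <- function(x, ...) {
  paste0(
    "5'-", paste(x$probe, collapse = ""), "-3' (probe)\n",
    "3'-", paste(x$counter, collapse = ""), "-5' (counter)\n",
    "    ", paste(substr(x$kind, 1, 1), collapse = ""), " (p=pair m=mismatch b=bulge d=dangle)"
  )
}

#' @export
print.duplex_layout <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @method as_tibble duplex_layout
#' @export
as_tibble.duplex_layout <- function(x, ...) {
  tibble(column = seq_along(x$kind), probe = x$probe, counter = x$counter, kind = x$kind)
}

# all-pair layout of a sequence against its perfect complement
perfect_layout <- function(seq) {
  p <- seq_chars(toupper(seq))
  duplex_layout(p, dna_complement(p), rep("pair", length(p)), validate = FALSE)
}

lookup_stack <- function(keys, dh_tab, ds_tab) {
  dh <- unname(dh_tab[keys])
  miss <- is.na(dh)
  if (any(miss)) {
    fk <- flip_key(keys[miss])
    dh[miss] <- unname(dh_tab[fk])
    keys[miss] <- fk
  }
  list(dh = dh, ds = unname(ds_tab[keys]), missing = is.na(dh))
}

#' Nearest-neighbor enthalpy and entropy of a duplex layout
#'
#' Sums, over the layout: Watson-Crick stack terms for adjacent pair
#' columns; single-mismatch stack terms for adjacencies of a pair column
#' with an isolated mismatch; an internal-loop entropy penalty (and no
#' stacking credit) for each column of a mismatch run of length two or
#' more; bulge-loop penalties per bulge run, with a single-base bulge
#' keeping the Watson-Crick stack of its flanking pairs; dangling-end terms
#' at layout ends; plus duplex initiation and a penalty per terminal A-T
#' pair. An adjacency with no table entry falls back to the tandem-mismatch
#' policy -- it is never silently zero.
#'
#' @param layout a [duplex_layout()].
#' @param params an [nn_params()] set.
#' @return named numeric vector `c(dh = kcal/mol, ds = cal/(mol*K))`.
#' @export
delta_h_s <- function(layout, params = default_nn_params()) {
  p <- layout$probe
  cc <- layout$counter
  k <- layout$kind
  n <- length(k)
  dh <- params$init_dh
  ds <- params$init_ds

  pair_pos <- which(k == "pair")
  for (i in c(pair_pos[1L], pair_pos[length(pair_pos)])) {
    if (p[i] %in% c("A", "T")) {
      dh <- dh + params$term_at_dh
      ds <- ds + params$term_at_ds
    }
  }

  r <- rle(k)
  run_len <- rep(r$lengths, r$lengths)
  in_tandem <- k == "mismatch" & run_len >= 2L
  ds <- ds + params$tandem_mismatch_ds * sum(in_tandem)

  # stacking adjacencies between consecutive pair/isolated-mismatch columns
  if (n >= 2L) {
    a <- seq_len(n - 1L)
    stackable <- k %in% c("pair", "mismatch") & !in_tandem
    el <- a[stackable[a] & stackable[a + 1L]]
    if (length(el)) {
      keys <- paste0(p[el], p[el + 1L], "/", cc[el], cc[el + 1L])
      got <- lookup_stack(keys, params$stack_dh, params$stack_ds)
      if (any(got$missing)) {
        # e.g. a mismatch orientation outside table coverage: internal-loop policy
        ds <- ds + params$tandem_mismatch_ds * sum(got$missing)
      }
      dh <- dh + sum(got$dh[!got$missing])
      ds <- ds + sum(got$ds[!got$missing])
    }
  }

  # bulge runs
  bulge <- r$values %in% c("bulge_probe", "bulge_counter")
  if (any(bulge)) {
    run_end <- cumsum(r$lengths)
    run_start <- run_end - r$lengths + 1L
    for (j in which(bulge)) {
      L <- r$lengths[j]
      ds <- ds + params$bulge_ds[min(L, length(params$bulge_ds))]
      if (L == 1L) {
        i <- run_start[j]
        key <- paste0(p[i - 1L], p[i + 1L], "/", cc[i - 1L], cc[i + 1L])
        got <- lookup_stack(key, params$wc_dh, params$wc_ds)
        if (got$missing) {
          abort(sprintf("no Watson-Crick closing stack for bulge at column %d", i))
        }
        dh <- dh + got$dh
        ds <- ds + got$ds
      }
    }
  }

  # dangling ends
  for (i in which(k %in% c("dangle_probe", "dangle_counter"))) {
    nb <- if (i == 1L) i + 1L else i - 1L
    lo <- min(i, nb)
    hi <- max(i, nb)
    key <- chartr("-", ".", paste0(p[lo], p[hi], "/", cc[lo], cc[hi]))
    got <- lookup_stack(key, params$dangle_dh, params$dangle_ds)
    if (got$missing) {
      abort(sprintf("no dangling-end parameters for '%s'", key))
    }
    dh <- dh + got$dh
    ds <- ds + got$ds
  }

  c(dh = dh, ds = ds)
}

#' Two-state melting temperature
#'
#' `Tm(degC) = 1000 * dH / (dS_salt + R * ln(C_T / x)) - 273.15` with
#' `R = 1.987 cal/(mol*K)` and the entropic salt correction
#' `dS_salt = dS + 0.368 * n_stacks * ln([Na+])`. Non-duplex-forming inputs
#' (non-negative enthalpy or non-negative corrected denominator) yield `NA`,
#' which callers treat as "no stable duplex".
#'
#' @param dh enthalpy, kcal/mol.
#' @param ds entropy, cal/(mol*K).
#' @param conditions a [thermo_conditions()] object.
#' @param n_stacks number of phosphates contributing to the salt
#'   correction, taken as (pair columns - 1).
#' @return melting temperature in degrees Celsius, or `NA_real_`.
#' @export
melting_temperature <- function(dh, ds, conditions = thermo_conditions(),
                                n_stacks = 0L) {
  R <- 1.987
  ds_salt <- ds + 0.368 * n_stacks * log(conditions$sodium_molar)
  denom <- ds_salt + R * log(conditions$strand_conc_molar / conditions$symmetry_factor)
  tm <- 1000 * dh / denom - 273.15
  tm[!(dh < 0) | !(denom < 0)] <- NA_real_
  tm
}

#' Melting temperature of an arbitrary duplex layout
#'
#' Composes [delta_h_s()] with [melting_temperature()]; the salt-correction
#' stack count is the number of pair columns minus one.
#'
#' @inheritParams delta_h_s
#' @inheritParams melting_temperature
#' @return Tm in degrees Celsius, or `NA_real_` for a non-forming duplex.
#' @export
tm_duplex <- function(layout, params = default_nn_params(),
                      conditions = thermo_conditions()) {
  hs <- delta_h_s(layout, params)
  melting_temperature(hs[["dh"]], hs[["ds"]], conditions,
                      n_stacks = sum(layout$kind == "pair") - 1L)
}

#' Melting temperature of a probe with its perfect-match target
#'
#' @param seq probe sequence over `{A,C,G,T}`, length >= 2.
#' @inheritParams tm_duplex
#' @return Tm in degrees Celsius.
#' @export
#' @examples
#' tm_perfect("ACGTACGTACGTACGTACGT")
tm_perfect <- function(seq, params = default_nn_params(),
                       conditions = thermo_conditions()) {
  seq <- toupper(seq)
  if (nchar(seq) < 2L) {
    abort("`seq` must have length >= 2")
  }
  if (stringi::stri_detect_regex(seq, "[^ACGT]")) {
    abort("`seq` must contain only A/C/G/T (no N) for a perfect duplex")
  }
  tm_duplex(perfect_layout(seq), params, conditions)
}
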