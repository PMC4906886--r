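#' Hybridization condition constants
#'
#' Conditions entering the two-state melting-temperature equation. Defaults
#' are typical array-hybridization assumptions: 50 mM monovalent cation,
#' 1 uM total single-strand concentration, symmetry factor 4 for
#' non-self-complementary duplexes. Screening decisions in this package
#' depend on melting-temperature differences, which softens their
#' sensitivity to the absolute condition choice.
#'
#' @param sodium_molar monovalent cation concentration, mol/L.
#' @param strand_conc_molar total single-strand concentration C_T, mol/L.
#' @param symmetry_factor 4 for non-self-complementary duplexes, 1 for
#'   self-complementary.
#' @return an object of class `thermo_conditions`.
#' @export
thermo_conditions <- function(sodium_molar = 0.05,
                              strand_conc_molar = 1e-6,
                              symmetry_factor = 4) {
  assert_scalar_number(sodium_molar, "sodium_molar", lower = 1e-12)
  assert_scalar_number(strand_conc_molar, "strand_conc_molar", lower = 1e-15)
  if (!symmetry_factor %in% c(1, 4)) {
    abort("`symmetry_factor` must be 1 (self-complementary) or 4")
  }
  structure(
    list(
      sodium_molar = sodium_molar,
      strand_conc_molar = strand_conc_molar,
      symmetry_factor = symmetry_factor
    ),
    class = "thermo_conditions"
  )
}

read_nn_table <- function(file) {
  path <- system.file("extdata", "nn", file, package = "thermotile", mustWork = TRUE)
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

# flip a stack key to the equivalent reading from the other strand:
# top 5'->3' / bottom 3'->5'  ==  rev(bottom) / rev(top)
flip_key <- function(key) {
  parts <- stringi::stri_split_fixed(key, "/", simplify = TRUE)
  paste0(stringi::stri_reverse(parts[, 2]), "/", stringi::stri_reverse(parts[, 1]))
}

# build named dh/ds vectors containing each key and its strand-flipped image
symmetrise <- function(step, dh, ds) {
  flipped <- flip_key(step)
  new <- !(flipped %in% step)
  list(
    dh = stats::setNames(c(dh, dh[new]), c(step, flipped[new])),
    ds = stats::setNames(c(ds, ds[new]), c(step, flipped[new]))
  )
}

#' Nearest-neighbor parameter set
#'
#' Loads the embedded nearest-neighbor tables (Watson-Crick stacks and
#' initiation from the unified oligonucleotide set, single internal
#' mismatches, single dangling ends, and length-dependent bulge-loop
#' penalties; sources are cited in the data files) and assembles the lookup
#' structures used by [delta_h_s()]. The set is swappable: any table can be
#' overridden with a data frame of the same shape.
#'
#' @param wc_stacks,mismatch_stacks,dangling_ends data frames with columns
#'   `step`, `dh`, `ds` overriding the embedded tables.
#' @param initiation data frame with columns `term`, `dh`, `ds` containing
#'   rows `initiation` and `terminal_AT`.
#' @param bulge_loops data frame with columns `length`, `dg37`.
#' @param tandem_mismatch_ds entropy penalty, cal/(mol*K), applied per
#'   column of a mismatch run of length >= 2 (internal-loop fallback; runs
#'   get no stacking credit). The default is deliberately mild so nontarget
#'   stability is not underestimated.
#' @return an object of class `nn_params`.
#' @export
nn_params <- function(wc_stacks = NULL, mismatch_stacks = NULL,
                      dangling_ends = NULL, initiation = NULL,
                      bulge_loops = NULL, tandem_mismatch_ds = -3.0) {
  wc <- wc_stacks %||% read_nn_table("wc_stacks.tsv")
  mm <- mismatch_stacks %||% read_nn_table("mismatch_stacks.tsv")
  de <- dangling_ends %||% read_nn_table("dangling_ends.tsv")
  init <- initiation %||% read_nn_table("initiation.tsv")
  bl <- bulge_loops %||% read_nn_table("bulge_loops.tsv")

  wc_tab <- symmetrise(wc$step, wc$dh, wc$ds)
  stack_tab <- symmetrise(c(wc$step, mm$step), c(wc$dh, mm$dh), c(wc$ds, mm$ds))
  de_tab <- symmetrise(de$step, de$dh, de$ds)

  # dense per-length bulge entropy, linear interpolation between tabulated
  # loop lengths, dh contribution zero
  lens <- seq_len(max(bl$length))
  dg <- stats::approx(bl$length, bl$dg37, xout = lens, rule = 2)$y
  bulge_ds <- -dg * 1000 / 310.15

  structure(
    list(
      wc_dh = wc_tab$dh, wc_ds = wc_tab$ds,
      stack_dh = stack_tab$dh, stack_ds = stack_tab$ds,
      dangle_dh = de_tab$dh, dangle_ds = de_tab$ds,
      init_dh = init$dh[init$term == "initiation"],
      init_ds = init$ds[init$term == "initiation"],
      term_at_dh = init$dh[init$term == "terminal_AT"],
      term_at_ds = init$ds[init$term == "terminal_AT"],
      bulge_ds = bulge_ds,
      tandem_mismatch_ds = tandem_mismatch_ds
    ),
    class = "nn_params"
  )
}

# session-cached default parameter set
default_nn_params <- function() {
  if (is.null(the$nn_params)) {
    the$nn_params <- nn_params()
  }
  the$nn_params
}
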