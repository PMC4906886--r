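#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a tiling design into its probe table
#'
#' @param x a [design_tiling()] result.
#' @param ... unused.
#' @return the probe tibble.
#' @method tidy tiling_design
#' @export
tidy.tiling_design <- function(x, ...) {
  x$probes
}

#' One-row design summary
#'
#' @param x a [design_tiling()] result.
#' @param ... unused.
#' @return a one-row tibble with probe count, mean probe length, coverage
#'   percentages, per-pass probe counts and the cycle-budget removals.
#' @method glance tiling_design
#' @export
glance.tiling_design <- function(x, ...) {
  designed <- x$probes[!is.na(x$probes$design_pass), , drop = FALSE]
  tibble(
    probe_count = x$coverage$probe_count,
    mean_probe_length = x$coverage$mean_probe_length,
    pct_fragments_without_probes = x$coverage$pct_fragments_without_probes,
    pct_genome_covered = x$coverage$pct_genome_covered,
    probes_pass1 = sum(designed$design_pass == 1L),
    probes_pass2 = sum(designed$design_pass == 2L),
    removed_cycles = x$removed_cycles,
    control_probes = x$n_controls
  )
}

#' Plot a tiling design
#'
#' Target and nontarget melting temperatures of the selected probes along
#' the genome; the vertical gap at each probe is the specificity margin
#' the design guarantees.
#'
#' @param object a [design_tiling()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot tiling_design
#' @export
autoplot.tiling_design <- function(object, ...) {
  d <- tidy(object)
  d <- d[!is.na(d$design_pass), , drop = FALSE]
  long <- tidyr::pivot_longer(
    d, c("tm_target", "tm_nontarget"),
    names_to = "duplex", values_to = "tm"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$start, y = .data$tm,
                                     colour = .data$duplex)) +
    ggplot2::geom_point(alpha = 0.7, na.rm = TRUE) +
    ggplot2::facet_wrap(~genome_id, scales = "free_x") +
    ggplot2::labs(
      x = "probe start (bp)", y = "melting temperature (°C)",
      colour = NULL,
      title = "Tiling design: probe target vs closest-nontarget Tm"
    )
}

#' Tidy a probe audit into its per-probe records
#'
#' @param x an [audit_probe_set()] result.
#' @param ... unused.
#' @return the audit record tibble.
#' @method tidy probe_audit
#' @export
tidy.probe_audit <- function(x, ...) {
  x$records
}

#' One-row audit summary
#'
#' @param x an [audit_probe_set()] result.
#' @param ... unused.
#' @return a one-row tibble with probe and flagged counts and the flagged
#'   fraction (percent).
#' @method glance probe_audit
#' @export
glance.probe_audit <- function(x, ...) {
  x$summary
}

#' Plot a probe audit
#'
#' Nontarget identity against nontarget melting temperature: identity does
#' not order thermodynamic stability, which is the reason audits flag by
#' Tm separation rather than by match statistics.
#'
#' @param object an [audit_probe_set()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot probe_audit
#' @export
autoplot.probe_audit <- function(object, ...) {
  d <- tidy(object)
  d <- d[!is.na(d$tm_nontarget), , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$identity_bp, y = .data$tm_nontarget,
                                  colour = .data$flagged)) +
    ggplot2::geom_point(alpha = 0.8, na.rm = TRUE) +
    ggplot2::labs(
      x = "nontarget match identity (bp)",
      y = "nontarget melting temperature (°C)",
      colour = "flagged",
      title = "Probe audit: identity does not order nontarget stability"
    )
}
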