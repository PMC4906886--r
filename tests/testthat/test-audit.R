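params <- design_params()

examples_path <- function() {
  system.file("extdata", "crosshyb_examples.tsv", package = "thermotile")
}

test_that("duplex statistics count pair columns and runs", {
  lay <- thermotile:::perfect_layout("ACGTACGTAC")
  expect_equal(duplex_stats(lay), tibble::tibble(identity_bp = 10L, stretch_bp = 10L))

  p <- thermotile:::seq_chars("ACGTACGTAC")
  cc <- dna_complement(p)
  cc[c(2, 4, 6, 8, 10)] <- vapply(p[c(2, 4, 6, 8, 10)], function(b) {
    setdiff(BASES, dna_complement(b))[1]
  }, character(1))
  k <- rep(c("pair", "mismatch"), 5)
  alt <- duplex_layout(p, cc, k)
  expect_equal(duplex_stats(alt), tibble::tibble(identity_bp = 5L, stretch_bp = 1L))
})

test_that("the published case-encoded duplex rows parse to 50/24/14", {
  rows <- utils::read.delim(examples_path(), comment.char = "#")
  expect_equal(nrow(rows), 7L)
  for (i in seq_len(nrow(rows))) {
    lay <- parse_case_encoded_duplex(rows$duplex[i])
    expect_length(lay$kind, 50L)
    st <- duplex_stats(lay)
    expect_equal(st$identity_bp, 24L)
    expect_equal(st$stretch_bp, 14L)
  }
})

test_that("case-encoded parsing enforces the legend semantics", {
  # fully complementary, all uppercase
  lay <- parse_case_encoded_duplex(paste0("ACGT", "TGCA"))
  expect_true(all(lay$kind == "pair"))

  # case masks disagreeing between halves
  expect_error(parse_case_encoded_duplex(paste0("ACGT", "tGCA")), "disagree")
  # uppercase over a non-complementary pair
  expect_error(parse_case_encoded_duplex(paste0("ACGT", "TGCC")), "not a complementary")
  # lowercase over a complementary pair
  expect_error(parse_case_encoded_duplex(paste0("aCGT", "tGCA")), "must be uppercase")
  expect_error(parse_case_encoded_duplex("ACG"), "even")
})

test_that("probes designed on a genome re-audit clean", {
  g <- random_genome(900, seed = 23)
  d <- design_tiling(g, params)
  aud <- audit_probe_set(tidy(d), g, params)
  expect_equal(glance(aud)$flagged_fraction_pct, 0)
  recs <- tidy(aud)
  ok <- recs$verdict == "ok"
  expect_true(all(is.na(recs$delta_tm[ok]) |
                    recs$delta_tm[ok] >= params$audit_delta_tm))
})

test_that("a probe planted twice is flagged with zero separation", {
  g <- random_unique_genome(500, k = 8, seed = 31)
  fx <- plant_feature(g, "exact_repeat", source_start = 60L, source_end = 120L,
                      dest = 320L)
  probe <- tibble::tibble(
    probe_id = "dup", genome_id = fx$genome$id, start = 70L, end = 110L,
    length = 40L, sequence = substr(fx$genome$sequence, 71L, 110L),
    tm_target = NA_real_, tm_nontarget = NA_real_, delta_tm = NA_real_,
    design_pass = 1L, cycles = NA_integer_
  )
  aud <- audit_probe_set(probe, fx$genome, params)
  rec <- tidy(aud)
  expect_true(rec$flagged)
  # the verbatim copy leaves essentially no separation; surrounding context
  # (dangling ends, chance matches) may even make the nontarget the more
  # stable duplex, so the separation can dip slightly below zero
  expect_lt(rec$delta_tm, 1)
  expect_gt(rec$delta_tm, -5)
  expect_gte(rec$identity_bp, 40L)
  expect_equal(rec$stretch_bp, 40L)
})

test_that("coordinate-free probes are located, ambiguous ones reported", {
  g <- random_unique_genome(500, k = 8, seed = 37)
  fx <- plant_feature(g, "exact_repeat", source_start = 100L, source_end = 150L,
                      dest = 300L)
  probes <- tibble::tibble(
    probe_id = c("unique", "twice", "foreign"),
    genome_id = NA_character_, start = NA_integer_, end = NA_integer_,
    length = 40L,
    sequence = c(
      substr(fx$genome$sequence, 201L, 240L),
      substr(fx$genome$sequence, 105L, 144L),
      strrep("ACCGGTTA", 5)
    ),
    tm_target = NA_real_, tm_nontarget = NA_real_, delta_tm = NA_real_,
    design_pass = NA_integer_, cycles = NA_integer_
  )
  aud <- tidy(audit_probe_set(probes, fx$genome, params))
  expect_equal(aud$verdict, c("ok", "multi_locus", "no_target_locus"))
  expect_false(aud$flagged[1])
  expect_true(is.na(aud$tm_target[2]))
})

test_that("planted near-duplicates produce the expected flagged fraction", {
  g <- random_genome(4000, seed = 43, id = "g")
  # ten probes whose loci are near-duplicated elsewhere at very low
  # divergence, so the copies stay within the flagging separation
  fx <- list(genome = g, features = NULL)
  dests <- seq(2200L, 3550L, by = 150L)
  for (i in seq_along(dests)) {
    fx <- plant_feature(fx$genome, "near_duplicate",
                        source_start = 100L + (i - 1L) * 150L,
                        source_end = 145L + (i - 1L) * 150L,
                        dest = dests[i], mutation_rate = 0.02, seed = i)
  }
  probe_at <- function(s) substr(fx$genome$sequence, s + 1L, s + 40L)
  flagged_starts <- 100L + (seq_along(dests) - 1L) * 150L
  # clean probes from regions free of planted sources and destinations
  clean_starts <- c(seq(1505L, 2150L, by = 8L), seq(3600L, 3950L, by = 10L))[1:90]
  probes <- tibble::tibble(
    probe_id = sprintf("p%03d", seq_len(100L)),
    genome_id = "g",
    start = c(flagged_starts, clean_starts),
    end = c(flagged_starts, clean_starts) + 40L,
    length = 40L,
    sequence = vapply(c(flagged_starts, clean_starts), probe_at, character(1)),
    tm_target = NA_real_, tm_nontarget = NA_real_, delta_tm = NA_real_,
    design_pass = NA_integer_, cycles = NA_integer_
  )
  aud <- audit_probe_set(probes, fx$genome, params)
  recs <- tidy(aud)
  # all ten near-duplicated probes flagged, no clean probe flagged
  expect_true(all(recs$flagged[1:10]))
  expect_false(any(recs$flagged[11:100]))
  expect_equal(glance(aud)$flagged_fraction_pct, 10)
})

test_that("coverage statistics are fragment based and complementary", {
  frags <- tibble::tibble(
    genome_id = "g", start = seq(0L, 990L, 100L), end = seq(100L, 1000L, 100L),
    role = "target", pass_label = 1L, sequence = strrep("A", 100)
  )
  probes <- tibble::tibble(
    probe_id = c("a", "b", "c"), genome_id = "g",
    start = c(10L, 115L, 130L), end = c(50L, 155L, 170L), length = 40L,
    sequence = strrep("A", 40), tm_target = 70, tm_nontarget = NA_real_,
    delta_tm = NA_real_, design_pass = 1L, cycles = NA_integer_
  )
  cov <- coverage_stats(probes, frags)
  expect_equal(cov$probe_count, 3L)
  expect_equal(cov$mean_probe_length, 40)
  expect_equal(cov$pct_fragments_without_probes, 80)
  expect_equal(cov$pct_genome_covered, 20)

  expect_equal(coverage_stats(probes[0, ], frags)$pct_genome_covered, 0)
  full <- purrr::map_dfr(seq(0L, 900L, 100L), function(s) {
    tibble::tibble(probe_id = paste0("p", s), genome_id = "g", start = s + 5L,
                   end = s + 45L, length = 40L, sequence = strrep("A", 40),
                   tm_target = 70, tm_nontarget = NA_real_, delta_tm = NA_real_,
                   design_pass = 1L, cycles = NA_integer_)
  })
  expect_equal(coverage_stats(full, frags)$pct_fragments_without_probes, 0)

  set.seed(8)
  for (i in 1:20) {
    n <- sample(1:10, 1)
    keep <- sort(sample(10L, n))
    cov_i <- coverage_stats(full[keep, ], frags)
    expect_equal(cov_i$pct_genome_covered + cov_i$pct_fragments_without_probes,
                 100, tolerance = 1e-9)
  }
})
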