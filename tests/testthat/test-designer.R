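params <- design_params()

test_that("candidate enumeration counts follow the length range", {
  g <- random_genome(100, seed = 1, id = "g")
  frag <- make_target_fragments(g, 100)[1, ]
  cands <- enumerate_candidates(frag, params)
  expect_equal(nrow(cands), sum(100 - (36:46) + 1))  # 649
  expect_equal(cands$start[1], 0L)

  g40 <- random_genome(40, seed = 2, id = "g")
  frag40 <- make_target_fragments(g40, 100)[1, ]
  expect_equal(nrow(enumerate_candidates(frag40, params)), sum(40 - (36:40) + 1))

  # a single N excludes every candidate spanning it
  gN <- g
  substr(gN$sequence, 51, 51) <- "N"
  fragN <- make_target_fragments(gN, 100)[1, ]
  candsN <- enumerate_candidates(fragN, params)
  expect_true(all(candsN$end <= 50L | candsN$start >= 51L))
})

test_that("the three-rule screen issues the right verdicts", {
  g <- random_unique_genome(500, k = 8, seed = 9)
  fx <- plant_feature(g, "exact_repeat", source_start = 100L, source_end = 160L,
                      dest = 350L)
  idx <- build_index(fx$genome, 8)

  # verbatim duplicate elsewhere: ruled out by the 18-bp rule
  dup <- list(genome_id = fx$genome$id, start = 110L, end = 150L,
              sequence = substr(fx$genome$sequence, 111L, 150L))
  expect_equal(screen_candidate(dup, idx, params)$verdict, "rejected_long_match")

  # no off-locus seed at all: accepted with no nontarget Tm
  uniq <- list(genome_id = fx$genome$id, start = 200L, end = 240L,
               sequence = substr(fx$genome$sequence, 201L, 240L))
  res <- screen_candidate(uniq, idx, params)
  expect_equal(res$verdict, "accepted")
  expect_true(is.na(res$tm_nontarget))

  # candidate with N never reaches the thermodynamic stage
  resN <- screen_candidate(
    list(genome_id = "g", start = 0L, end = 40L,
         sequence = paste0(strrep("A", 20), "N", strrep("C", 19))), idx, params
  )
  expect_equal(resN$verdict, "rejected_alphabet")
})

test_that("the delta-Tm acceptance inequality decides near-duplicate candidates", {
  base <- random_genome(1200, seed = 42)
  found <- c(rejected = FALSE, accepted = FALSE)
  for (rate in c(0.06, 0.25)) {
    fx <- plant_feature(base, "near_duplicate", source_start = 200L,
                        source_end = 400L, dest = 700L, mutation_rate = rate,
                        seed = 99)
    idx <- build_index(fx$genome, 8)
    for (s in seq(700L, 760L, by = 20L)) {
      cand <- list(genome_id = fx$genome$id, start = s, end = s + 40L,
                   sequence = substr(fx$genome$sequence, s + 1L, s + 40L))
      res <- screen_candidate(cand, idx, params)
      if (res$verdict %in% c("accepted", "rejected_delta_tm")) {
        # verdict must equal the inequality on the reported temperatures
        expect_equal(
          res$verdict == "accepted",
          is.na(res$delta_tm) || res$delta_tm >= params$min_delta_tm
        )
        if (!is.na(res$delta_tm)) {
          found[if (res$verdict == "accepted") "accepted" else "rejected"] <- TRUE
        }
      }
    }
  }
  expect_true(all(found))
})

test_that("probe selection ranks by separation, anchors Tm, forbids overlap", {
  g <- random_genome(300, seed = 3)
  frag <- make_target_fragments(g, 100)[1, ]
  mk <- function(start, len, delta, tmt) tibble::tibble(
    genome_id = "g", start = start, end = start + len, length = len,
    sequence = substring(g$sequence, start + 1, start + len),
    verdict = "accepted", tm_target = tmt,
    tm_nontarget = ifelse(is.na(delta), NA_real_, tmt - delta),
    delta_tm = delta, nontarget_id = NA_character_,
    nontarget_start = NA_integer_, nontarget_end = NA_integer_,
    nontarget_strand = NA_character_
  )
  one <- mk(10L, 40L, 12, 70)
  expect_equal(select_probes(frag, one, params)$start, 10L)

  overlapping <- dplyr::bind_rows(mk(10L, 40L, 10, 70), mk(30L, 40L, 7, 70))
  sel <- select_probes(frag, overlapping, params)
  expect_equal(nrow(sel), 1L)
  expect_equal(sel$delta_tm, 10)

  disjoint <- dplyr::bind_rows(mk(5L, 40L, 10, 70), mk(55L, 40L, 7, 70))
  expect_equal(nrow(select_probes(frag, disjoint, params)), 2L)

  # an absent nontarget outranks any finite separation
  pair <- dplyr::bind_rows(mk(10L, 40L, NA_real_, 70), mk(20L, 40L, 30, 70))
  expect_true(is.na(select_probes(frag, pair, params)$delta_tm[1]))

  expect_equal(nrow(select_probes(frag, one[0, ], params)), 0L)
})

test_that("synthesis cycles follow the cyclic A,C,G,T dispense schedule", {
  expect_equal(synthesis_cycles("A"), 1L)
  expect_equal(synthesis_cycles("AAAA"), 13L)   # 1 + 4 + 4 + 4
  expect_equal(synthesis_cycles("ACGT"), 13L)   # over TGCA: 4 + 3 + 3 + 3
  expect_equal(synthesis_cycles(c("A", "AAAA")), c(1L, 13L))
  expect_error(synthesis_cycles("ACGN"), "only A/C/G/T")
})

test_that("a repeat-free genome is fully covered and a duplicated one is empty", {
  g <- random_unique_genome(240, k = 8, seed = 3)
  d <- design_tiling(g, params)
  expect_equal(glance(d)$pct_genome_covered, 100)
  expect_gte(glance(d)$probe_count, nrow(d$fragments))

  h <- random_genome(500, seed = 5)
  dup <- tibble::tibble(id = "dup", description = "",
                        sequence = strrep(h$sequence, 2))
  expect_equal(nrow(tidy(design_tiling(dup, params))), 0L)
})

test_that("designs are deterministic and satisfy their structural invariants", {
  g <- random_genome(900, seed = 17)
  d1 <- design_tiling(g, params)
  d2 <- design_tiling(g, params)
  expect_identical(tidy(d1), tidy(d2))

  probes <- tidy(d1)
  expect_gt(nrow(probes), 0L)
  # no probe crosses a fragment boundary; within a fragment probes are disjoint
  expect_true(all(probes$start %/% 100 == (probes$end - 1L) %/% 100))
  by_frag <- split(probes, probes$start %/% 100)
  for (pf in by_frag) {
    if (nrow(pf) > 1L) {
      o <- order(pf$start)
      expect_true(all(pf$end[o][-nrow(pf)] <= pf$start[o][-1]))
    }
  }
  # probe sequences equal their genome substrings, delta is consistent
  expect_silent(thermotile:::validate_probe_tbl(probes, genomes = g))
  expect_true(all(probes$cycles <= params$max_cycles))
})

test_that("every emitted probe passes a from-scratch re-screen (idempotent audit)", {
  g <- random_genome(900, seed = 23)
  d <- design_tiling(g, params)
  probes <- tidy(d)
  expect_gt(nrow(probes), 0L)
  idx <- build_index(g, params$min_match)
  for (i in seq_len(nrow(probes))) {
    res <- screen_candidate(
      list(genome_id = probes$genome_id[i], start = probes$start[i],
           end = probes$end[i], sequence = probes$sequence[i]), idx, params
    )
    expect_equal(res$verdict, "accepted")
  }
})

test_that("tightening thresholds never loosens the design", {
  fx <- two_pass_fixture()
  n5 <- nrow(tidy(design_tiling(fx$genome, design_params(min_delta_tm = 5))))
  n12 <- nrow(tidy(design_tiling(fx$genome, design_params(min_delta_tm = 12))))
  expect_lte(n12, n5)

  # narrower boundary windows never lose probes
  wide <- design_params(boundary_width_pass1 = 50, boundary_width_pass2 = 50)
  narrow <- design_params(boundary_width_pass1 = 40, boundary_width_pass2 = 40)
  nw <- nrow(tidy(design_tiling(fx$genome, wide)))
  nn <- nrow(tidy(design_tiling(fx$genome, narrow)))
  expect_gte(nn, nw)
})

test_that("the second pass recovers fragments the 50-bp boundaries blocked", {
  fx <- two_pass_fixture()
  d <- design_tiling(fx$genome, params)
  probes <- tidy(d)
  expect_gte(sum(probes$design_pass == 2L), 1L)
  # the blocked fragments are exactly the repeat-carrying ones
  pass2_frags <- unique(probes$start[probes$design_pass == 2L] %/% 100)
  expect_true(all(pass2_frags %in% c(1L, 4L)))
  expect_equal(glance(d)$pct_genome_covered, 100)
})

test_that("design parameters validate and read from YAML config", {
  expect_error(design_params(min_match = 20, max_match = 18), "min_match")
  expect_error(design_params(probe_len_max = 120), "fragment_size")
  expect_error(design_params(min_delta_tm = 0), "min_delta_tm")

  cfg <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("min_delta_tm: 7.5", "probe_len_min: 30", "sodium_molar: 0.1"), cfg)
  p <- read_design_config(cfg)
  expect_equal(p$min_delta_tm, 7.5)
  expect_equal(p$probe_len_min, 30L)
  expect_equal(p$conditions$sodium_molar, 0.1)
  writeLines("not_a_key: 1", cfg)
  expect_error(read_design_config(cfg), "unknown config keys")
})
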