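# Independent oracles and fixture builders used across the suite.

BASES <- c("A", "C", "G", "T")

# --- naive nearest-neighbor term enumeration ---------------------------------
# Deliberately scalar, column-by-column transliteration of the energy rules,
# written before and kept independent of the run-based engine.
naive_delta_h_s <- function(layout, params = thermotile:::default_nn_params()) {
  p <- layout$probe
  cc <- layout$counter
  k <- layout$kind
  n <- length(k)
  look <- function(dh_tab, ds_tab, key) {
    if (!is.na(dh_tab[key])) {
      return(c(dh_tab[[key]], ds_tab[[key]]))
    }
    fk <- thermotile:::flip_key(key)
    if (!is.na(dh_tab[fk])) {
      return(c(dh_tab[[fk]], ds_tab[[fk]]))
    }
    NULL
  }
  dh <- params$init_dh
  ds <- params$init_ds
  pair_idx <- which(k == "pair")
  for (i in c(pair_idx[1], pair_idx[length(pair_idx)])) {
    if (p[i] %in% c("A", "T")) {
      dh <- dh + params$term_at_dh
      ds <- ds + params$term_at_ds
    }
  }
  tandem <- logical(n)
  i <- 1L
  while (i <= n) {
    if (k[i] == "mismatch") {
      j <- i
      while (j < n && k[j + 1L] == "mismatch") j <- j + 1L
      if (j > i) tandem[i:j] <- TRUE
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  for (i in which(tandem)) {
    ds <- ds + params$tandem_mismatch_ds
  }
  for (i in seq_len(n - 1L)) {
    if (k[i] %in% c("pair", "mismatch") && k[i + 1L] %in% c("pair", "mismatch") &&
        !tandem[i] && !tandem[i + 1L]) {
      v <- look(params$stack_dh, params$stack_ds,
                paste0(p[i], p[i + 1L], "/", cc[i], cc[i + 1L]))
      if (is.null(v)) {
        ds <- ds + params$tandem_mismatch_ds
      } else {
        dh <- dh + v[1]
        ds <- ds + v[2]
      }
    }
  }
  i <- 1L
  while (i <= n) {
    if (k[i] %in% c("bulge_probe", "bulge_counter")) {
      j <- i
      while (j < n && k[j + 1L] %in% c("bulge_probe", "bulge_counter")) j <- j + 1L
      len <- j - i + 1L
      ds <- ds + params$bulge_ds[min(len, length(params$bulge_ds))]
      if (len == 1L) {
        v <- look(params$wc_dh, params$wc_ds,
                  paste0(p[i - 1L], p[i + 1L], "/", cc[i - 1L], cc[i + 1L]))
        dh <- dh + v[1]
        ds <- ds + v[2]
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  for (i in which(k %in% c("dangle_probe", "dangle_counter"))) {
    nb <- if (i == 1L) 2L else i - 1L
    lo <- min(i, nb)
    hi <- max(i, nb)
    v <- look(params$dangle_dh, params$dangle_ds,
              chartr("-", ".", paste0(p[lo], p[hi], "/", cc[lo], cc[hi])))
    dh <- dh + v[1]
    ds <- ds + v[2]
  }
  c(dh = dh, ds = ds)
}

# --- random valid duplex layouts ---------------------------------------------
random_layout <- function(min_len = 8L, max_len = 60L) {
  len <- sample(min_len:max_len, 1L)
  p <- sample(BASES, len, replace = TRUE)
  cc <- dna_complement(p)
  k <- rep("pair", len)
  for (i in sample_safe(2:(len - 1L), sample(0:4, 1L))) {
    cc[i] <- sample(setdiff(BASES, dna_complement(p[i])), 1L)
    k[i] <- "mismatch"
  }
  for (b in seq_len(sample(0:2, 1L))) {
    at <- which(k[-length(k)] == "pair" & k[-1L] == "pair")
    if (length(at) == 0L) break
    i <- at[sample.int(length(at), 1L)]
    blen <- sample(1:3, 1L)
    if (stats::runif(1) < 0.5) {
      np <- sample(BASES, blen, replace = TRUE)
      nc <- rep("-", blen)
      nk <- rep("bulge_probe", blen)
    } else {
      np <- rep("-", blen)
      nc <- sample(BASES, blen, replace = TRUE)
      nk <- rep("bulge_counter", blen)
    }
    p <- append(p, np, after = i)
    cc <- append(cc, nc, after = i)
    k <- append(k, nk, after = i)
  }
  if (k[1L] == "pair" && stats::runif(1) < 0.5) {
    if (stats::runif(1) < 0.5) {
      p <- c(sample(BASES, 1L), p); cc <- c("-", cc); k <- c("dangle_probe", k)
    } else {
      p <- c("-", p); cc <- c(sample(BASES, 1L), cc); k <- c("dangle_counter", k)
    }
  }
  n <- length(k)
  if (k[n] == "pair" && stats::runif(1) < 0.5) {
    if (stats::runif(1) < 0.5) {
      p <- c(p, sample(BASES, 1L)); cc <- c(cc, "-"); k <- c(k, "dangle_probe")
    } else {
      p <- c(p, "-"); cc <- c(cc, sample(BASES, 1L)); k <- c(k, "dangle_counter")
    }
  }
  duplex_layout(p, cc, k)
}

sample_safe <- function(x, n) {
  if (n == 0L || length(x) == 0L) return(integer(0))
  x[sample.int(length(x), min(n, length(x)))]
}

# flip a layout to the counter strand's point of view (reverse columns,
# swap strands); physical duplex is unchanged
flip_layout <- function(layout) {
  swap <- c(
    pair = "pair", mismatch = "mismatch",
    bulge_probe = "bulge_counter", bulge_counter = "bulge_probe",
    dangle_probe = "dangle_counter", dangle_counter = "dangle_probe"
  )
  duplex_layout(
    rev(layout$counter), rev(layout$probe), unname(swap[rev(layout$kind)])
  )
}

# --- brute-force maximal exact-match enumeration -----------------------------
# Dynamic programming over all candidate x subject alignments; independent of
# the k-mer index implementation.
brute_seeds <- function(candidate, records, k) {
  qch <- thermotile:::seq_chars(candidate)
  m <- length(qch)
  rows <- list()
  for (g in seq_len(nrow(records))) {
    L <- nchar(records$sequence[g])
    for (strand in c("+", "-")) {
      s <- records$sequence[g]
      if (strand == "-") s <- dna_revcomp(s)
      sch <- thermotile:::seq_chars(s)
      n <- length(sch)
      d_prev <- integer(n)
      for (i in seq_len(m)) {
        match_i <- (qch[i] == sch) & (qch[i] != "N")
        d <- integer(n)
        d[1L] <- as.integer(match_i[1L])
        if (n > 1L) d[2:n] <- (d_prev[1:(n - 1L)] + 1L) * match_i[2:n]
        for (j in which(d >= k)) {
          extendable <- i < m && j < n && qch[i + 1L] == sch[j + 1L] && qch[i + 1L] != "N"
          if (!extendable) {
            len <- d[j]
            os0 <- j - len       # 0-based oriented start
            ss <- if (strand == "+") os0 else L - (os0 + len)
            rows[[length(rows) + 1L]] <- c(i - len, i, g, ss, ss + len, strand == "-", len)
          }
        }
        d_prev <- d
      }
    }
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(
      query_start = integer(), query_end = integer(), subject_id = character(),
      subject_start = integer(), subject_end = integer(), strand = character(),
      length = integer()
    ))
  }
  mtx <- do.call(rbind, rows)
  tibble::tibble(
    query_start = as.integer(mtx[, 1]), query_end = as.integer(mtx[, 2]),
    subject_id = records$id[mtx[, 3]],
    subject_start = as.integer(mtx[, 4]), subject_end = as.integer(mtx[, 5]),
    strand = ifelse(mtx[, 6] == 1, "-", "+"),
    length = as.integer(mtx[, 7])
  )
}

sort_seeds <- function(seeds) {
  seeds[order(seeds$subject_id, seeds$strand, seeds$subject_start,
              seeds$query_start, seeds$length), , drop = FALSE]
}

# borderline two-pass fixture: one fragment whose candidates are all blocked
# in pass 1 (by a planted 75-bp repeat plus the 50-bp boundary window) but
# recoverable with the 40-bp pass-2 window
two_pass_fixture <- function(seed = 7L) {
  g <- random_genome(600, seed = seed)
  plant_feature(g, "exact_repeat", source_start = 100L, source_end = 175L,
                dest = 400L)
}
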