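# Independent brute-force oracles. Each one re-derives the quantity it checks
# by direct enumeration, sharing no code with the implementation paths.

# All ungapped contiguous matches >= min_match between revcomp(probe) and the
# transcript plus strand, by scanning every (probe offset, transcript offset,
# length) window. Returns the single best hit per pair (max length, leftmost
# transcript start) or NULL.
oracle_align_pair <- function(probe, transcript, min_match = 22L) {
  rc <- probeRank:::revcomp(probe)
  np <- nchar(rc); nt <- nchar(transcript)
  best_len <- 0L; best_start <- NA_integer_
  for (len in seq(min(np, nt), min_match)) {
    for (q in seq_len(np - len + 1L)) {
      sub <- substr(rc, q, q + len - 1L)
      for (t in seq_len(nt - len + 1L)) {
        if (substr(transcript, t, t + len - 1L) == sub) {
          if (len > best_len || (len == best_len && t < best_start)) {
            best_len <- len; best_start <- t
          }
        }
      }
    }
    if (best_len > 0L) break  # lengths scanned descending: first found is max
  }
  if (best_len == 0L) return(NULL)
  data.frame(t_start = best_start, t_end = best_start + best_len - 1L,
             match_len = best_len)
}

# Longest contiguous shared substring between revcomp(probe) and transcript.
oracle_longest_match <- function(probe, transcript) {
  rc <- probeRank:::revcomp(probe)
  np <- nchar(rc)
  for (len in np:1) {
    for (q in seq_len(np - len + 1L)) {
      if (grepl(substr(rc, q, q + len - 1L), transcript, fixed = TRUE)) {
        return(len)
      }
    }
  }
  0L
}

# Exact Mann-Whitney tails by direct enumeration with explicit loops.
oracle_mw <- function(x, y) {
  n <- length(x) + length(y)
  r <- rank(c(x, y), ties.method = "average")
  obs <- sum(r[seq_along(x)])
  sets <- combn(n, length(x))
  ge <- 0L; le <- 0L
  for (j in seq_len(ncol(sets))) {
    w <- sum(r[sets[, j]])
    if (w >= obs) ge <- ge + 1L
    if (w <= obs) le <- le + 1L
  }
  c(p_upper = ge / ncol(sets), p_lower = le / ncol(sets))
}

# Hypergeometric upper tail by enumerating every A_size-subset of a T-element
# universe whose first X_T elements are "transcript" probes.
oracle_hyper_tail <- function(X_A, A_size, X_T, T_total) {
  if (A_size == 0L) return(if (X_A == 0L) 1 else stop("invalid"))
  sets <- combn(T_total, A_size)
  hits <- colSums(sets <= X_T)
  mean(hits >= X_A)
}

# Enrichment tail by enumerating every Q-subset of the universe whose first
# Tt elements are targets.
oracle_enrich <- function(QT, Q, Tt, Auniv) {
  if (Q == 0L) return(if (QT == 0L) 1 else stop("invalid"))
  sets <- combn(Auniv, Q)
  inter <- colSums(sets <= Tt)
  mean(inter >= QT)
}

# Benjamini-Hochberg step-up, written from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  if (m > 1L) for (i in (m - 1L):1L) adj[i] <- min(adj[i], adj[i + 1L])
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Small simulated experiment used by several tests.
small_sim <- function(seed = 42L, planted = NULL, noise_sd = 0.25,
                      n_transcripts = 12L, n_decoys = 0L, n_multimap = 0L) {
  cfg <- sim_config(n_transcripts = n_transcripts, seed = seed,
                    n_decoy_probes = n_decoys, n_multimap_probes = n_multimap,
                    noise_sd = noise_sd, planted_effects = planted)
  simulate_experiment(cfg)
}

random_dna <- function(n, len, seed) {
  probeRank:::with_seed(seed, vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1)))
}
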