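#' Configuration for the synthetic-data generator
#'
#' Bundles all tunables of the simulator. Intensities follow a log-additive
#' model: each probe has an affinity intercept drawn once, planted effects add
#' `ln(2) * log2_fc` on the arrays of the affected comparison's experimental
#' group, and Gaussian noise is added on the log scale, so all fluorescence
#' values are positive and effects are multiplicative — only the ordering
#' matters to the rank-based method under test.
#'
#' @param n_transcripts number of transcripts to simulate.
#' @param seed integer seed; mandatory, all randomness is local to it.
#' @param transcript_length transcript length in nt (default 500).
#' @param probes_per_transcript probes tiled per transcript (default 9, the
#'   per-transcript probe count of the Gene ST design's denser targets).
#' @param probe_length probe length in nt; fixed at 25.
#' @param n_decoy_probes number of unmappable decoy probes (no 22-nt match to
#'   any transcript minus strand).
#' @param n_multimap_probes number of probe windows duplicated verbatim into a
#'   second transcript, producing multi-mapping probes.
#' @param baseline_log_mean,baseline_log_sd mean and sd of the per-probe
#'   log-intensity affinity intercept.
#' @param noise_sd sd of the per-measurement log-scale noise (>= 0).
#' @param planted_effects `NULL` or a data frame with columns `transcript_id`,
#'   `position` (comparison position, 1-7 under [default_plan()]) and
#'   `log2_fc`.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_transcripts, seed,
                       transcript_length = 500L,
                       probes_per_transcript = 9L,
                       probe_length = 25L,
                       n_decoy_probes = 0L,
                       n_multimap_probes = 0L,
                       baseline_log_mean = 6,
                       baseline_log_sd = 1,
                       noise_sd = 0.25,
                       planted_effects = NULL) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (probe_length != 25L) stop("probe_length is fixed at 25", call. = FALSE)
  if (n_transcripts < 0L) stop("n_transcripts must be >= 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (abs(seed) > 2^31 - 10) stop("seed out of integer range", call. = FALSE)
  if (n_transcripts > 0L &&
      transcript_length < probe_length + probes_per_transcript - 1L) {
    stop("transcript_length too short for requested probe tiling", call. = FALSE)
  }
  if (!is.null(planted_effects)) {
    req <- c("transcript_id", "position", "log2_fc")
    if (!is.data.frame(planted_effects) || !all(req %in% names(planted_effects))) {
      stop("planted_effects needs columns transcript_id, position, log2_fc",
           call. = FALSE)
    }
  }
  structure(list(
    n_transcripts = as.integer(n_transcripts),
    transcript_length = as.integer(transcript_length),
    probes_per_transcript = as.integer(probes_per_transcript),
    probe_length = 25L,
    n_decoy_probes = as.integer(n_decoy_probes),
    n_multimap_probes = as.integer(n_multimap_probes),
    baseline_log_mean = baseline_log_mean,
    baseline_log_sd = baseline_log_sd,
    noise_sd = noise_sd,
    planted_effects = planted_effects,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Deterministic probe-window start positions: evenly spaced distinct starts.
window_starts <- function(config) {
  L <- config$transcript_length
  p <- config$probe_length
  k <- config$probes_per_transcript
  if (k == 0L) return(integer(0))
  starts <- unique(as.integer(round(seq(1L, L - p + 1L, length.out = k))))
  if (length(starts) != k) {
    stop("cannot place non-overlapping-start windows: transcript too short",
         call. = FALSE)
  }
  starts
}

random_seq <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

#' Simulate a transcriptome
#'
#' Generates `n_transcripts` random sequences (named `tx1`, `tx2`, ...). Probe
#' windows are guaranteed unique across the transcriptome, except that
#' `n_multimap_probes` windows are copied verbatim into a second transcript
#' (into the gap between two probe windows) to create multi-mapping probes.
#' Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return named character vector of transcript sequences.
#' @export
simulate_transcriptome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_transcripts
  if (n == 0L) return(setNames(character(0), character(0)))
  L <- config$transcript_length
  p <- config$probe_length
  starts <- window_starts(config)
  with_seed(config$seed, {
    seqs <- random_seq(n, L)
    names(seqs) <- paste0("tx", seq_len(n))
    # ensure designed probe windows are unique transcriptome-wide
    for (attempt in 1:25) {
      wins <- unlist(lapply(seqs, function(s) substring(s, starts, starts + p - 1L)),
                     use.names = FALSE)
      dup <- duplicated(wins)
      if (!any(dup)) break
      redo <- unique((which(dup) - 1L) %/% length(starts) + 1L)
      seqs[redo] <- random_seq(length(redo), L)
    }
    if (config$n_multimap_probes > 0L) {
      if (n < 2L) stop("n_multimap_probes requires >= 2 transcripts", call. = FALSE)
      gaps <- which(diff(starts) >= 2L * p)  # gap after window i fits a copy
      if (length(gaps) == 0L) {
        stop("probe tiling too dense to host duplicated windows", call. = FALSE)
      }
      for (i in seq_len(config$n_multimap_probes)) {
        src <- ((i - 1L) %% n) + 1L
        tgt <- (src %% n) + 1L
        w_idx <- ((i - 1L) %/% n) %% length(starts) + 1L
        g <- gaps[((i - 1L) %% length(gaps)) + 1L]
        ins <- starts[g] + p  # inside the gap, clear of both flanking windows
        win <- substr(seqs[[src]], starts[w_idx], starts[w_idx] + p - 1L)
        substr(seqs[[tgt]], ins, ins + p - 1L) <- win
      }
    }
    seqs
  })
}

#' Design probes for a simulated transcriptome
#'
#' Tiles `probes_per_transcript` probes per transcript, each the reverse
#' complement of a distinct 25-nt window (so the minus-strand alignment rule
#' finds them), and appends `n_decoy_probes` random 25-mers rejection-sampled
#' to share no 22-nt ungapped match with any transcript (checked with
#' [align_probes()] itself).
#'
#' @param transcripts named character vector from [simulate_transcriptome()].
#' @param config the same [sim_config()].
#' @return list with `probes` (named character vector, ids `txN_probeM` and
#'   `decoyK`) and `origin` (probe id -> source transcript id or `"decoy"`).
#' @export
design_probes <- function(transcripts, config) {
  stopifnot(inherits(config, "sim_config"))
  p <- config$probe_length
  probes <- character(0)
  origin <- character(0)
  if (length(transcripts) > 0L && config$probes_per_transcript > 0L) {
    starts <- window_starts(config)
    for (tx in names(transcripts)) {
      wins <- substring(transcripts[[tx]], starts, starts + p - 1L)
      pr <- revcomp(wins)
      names(pr) <- sprintf("%s_probe%d", tx, seq_along(starts))
      probes <- c(probes, pr)
      origin <- c(origin, setNames(rep(tx, length(pr)), names(pr)))
    }
  }
  if (config$n_decoy_probes > 0L) {
    decoys <- with_seed(config$seed + 1L, {
      found <- character(0)
      for (round in 1:50) {
        need <- config$n_decoy_probes - length(found)
        if (need == 0L) break
        cand <- random_seq(2L * need, p)
        names(cand) <- sprintf("cand%d", seq_along(cand))
        if (length(transcripts) > 0L) {
          hits <- align_probes(cand, transcripts, min_match = 22L)
          ok <- setdiff(names(cand), hits$probe_id)
        } else {
          ok <- names(cand)
        }
        found <- c(found, unname(cand[ok])[seq_len(min(need, length(ok)))])
      }
      if (length(found) < config$n_decoy_probes) {
        stop("failed to sample decoy probes", call. = FALSE)
      }
      found
    })
    names(decoys) <- sprintf("decoy%d", seq_along(decoys))
    probes <- c(probes, decoys)
    origin <- c(origin, setNames(rep("decoy", length(decoys)), names(decoys)))
  }
  list(probes = probes, origin = origin)
}

#' Ground truth for a simulated experiment
#'
#' @param origin probe id -> transcript id (or `"decoy"`), from
#'   [design_probes()].
#' @param config the [sim_config()] (its `planted_effects` define profiles).
#' @param n_positions number of comparisons in the plan (default 7).
#' @return list of class `ground_truth` with `probe_origin`, `true_profile`
#'   (transcript -> H/L/E string; `H` iff planted log2 fold > 0 at that
#'   position, `L` iff < 0, `E` otherwise) and `planted_effects`.
#' @export
ground_truth <- function(origin, config, n_positions = 7L) {
  txs <- setdiff(unique(origin), "decoy")
  prof <- setNames(rep(strrep("E", n_positions), length(txs)), txs)
  pe <- config$planted_effects
  if (!is.null(pe)) {
    for (i in seq_len(nrow(pe))) {
      tx <- as.character(pe$transcript_id[i])
      pos <- as.integer(pe$position[i])
      if (!tx %in% txs) stop(sprintf("planted transcript unknown: %s", tx),
                             call. = FALSE)
      if (pos < 1L || pos > n_positions) stop("planted position outside plan",
                                              call. = FALSE)
      letter <- if (pe$log2_fc[i] > 0) "H" else if (pe$log2_fc[i] < 0) "L" else "E"
      substr(prof[[tx]], pos, pos) <- letter
    }
  }
  structure(list(probe_origin = origin, true_profile = prof,
                 planted_effects = pe), class = "ground_truth")
}

#' Simulate a probe-by-array intensity matrix
#'
#' `intensity(p, a) = exp(b_p + sum(ln2 * log2_fc) + eps)` where `b_p` is a
#' per-probe affinity intercept, the sum runs over planted effects whose
#' experimental group contains array `a` and whose transcript is probe `p`'s
#' origin, and `eps ~ N(0, noise_sd)`. Deterministic given `config$seed`.
#'
#' @param design experiment design ([default_design()]).
#' @param probes named character vector of probe sequences.
#' @param truth [ground_truth()] object.
#' @param config the [sim_config()].
#' @param plan comparison plan, default [default_plan()].
#' @return positive numeric matrix, rows probes, columns arrays.
#' @export
simulate_intensities <- function(design, probes, truth, config,
                                 plan = default_plan()) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "ground_truth"))
  validate_design(design)
  P <- length(probes)
  N <- nrow(design)
  shift <- matrix(0, P, N, dimnames = list(names(probes), design$array_id))
  pe <- config$planted_effects
  if (!is.null(pe) && nrow(pe) > 0L) {
    arrs <- comparison_arrays(plan, design)
    for (i in seq_len(nrow(pe))) {
      tx <- as.character(pe$transcript_id[i])
      if (!tx %in% truth$probe_origin) {
        stop(sprintf("planted transcript unknown: %s", tx), call. = FALSE)
      }
      rows <- names(truth$probe_origin)[truth$probe_origin == tx]
      rows <- intersect(rows, names(probes))
      cols <- arrs[[as.integer(pe$position[i])]]$exp
      shift[rows, cols] <- shift[rows, cols] + log(2) * pe$log2_fc[i]
    }
  }
  with_seed(config$seed + 2L, {
    b <- rnorm(P, config$baseline_log_mean, config$baseline_log_sd)
    eps <- matrix(rnorm(P * N, 0, config$noise_sd), P, N)
    mat <- exp(b + shift + eps)
    dimnames(mat) <- list(names(probes), design$array_id)
    mat
  })
}

#' Simulate a complete experiment bundle
#'
#' Convenience wrapper: transcriptome, probes, ground truth and intensity
#' matrix in one call.
#'
#' @inheritParams simulate_intensities
#' @param config a [sim_config()].
#' @return list with `transcripts`, `probes`, `origin`, `truth`,
#'   `intensities`, `design`, `plan`, `config`.
#' @export
simulate_experiment <- function(config, design = default_design(),
                                plan = default_plan()) {
  transcripts <- simulate_transcriptome(config)
  pd <- design_probes(transcripts, config)
  truth <- ground_truth(pd$origin, config, n_positions = nrow(plan))
  mat <- simulate_intensities(design, pd$probes, truth, config, plan)
  list(transcripts = transcripts, probes = pd$probes, origin = pd$origin,
       truth = truth, intensities = mat, design = design, plan = plan,
       config = config)
}

#' Standard planted-effect panel for validation runs
#'
#' A fixed panel of planted effects cycling over four profile shapes:
#' down-regulated in hypoxic wild-type (positions 4-5), up-regulated in
#' hypoxic wild-type, up in the knockout genotype contrast during hypoxia
#' (positions 2-3), and up in hypoxic knockouts (positions 6-7), all at
#' |log2 fold change| = 2.
#'
#' @param n_planted number of planted transcripts (default 20).
#' @return `planted_effects` data frame for [sim_config()].
#' @export
planted_panel <- function(n_planted = 20L) {
  do.call(rbind, lapply(seq_len(n_planted), function(i) {
    tx <- paste0("tx", i)
    switch((i %% 4L) + 1L,
      data.frame(transcript_id = tx, position = c(4L, 5L), log2_fc = -2),
      data.frame(transcript_id = tx, position = c(4L, 5L), log2_fc = 2),
      data.frame(transcript_id = tx, position = c(2L, 3L), log2_fc = 2),
      data.frame(transcript_id = tx, position = c(6L, 7L), log2_fc = 2))
  }))
}
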