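#' Align probes to a transcriptome (ungapped exact match, minus strand)
#'
#' A hit is reported for a (probe, transcript) pair iff a contiguous exact
#' match of length >= `min_match` exists between the reverse complement of
#' the probe and the transcript plus strand — equivalently, between the probe
#' and the transcript minus strand. One hit per pair is reported, at the
#' maximal match length (leftmost transcript position on ties). A probe may
#' hit multiple transcripts.
#'
#' Implementation is k-mer seed (k = `min_match`) and ungapped extension; the
#' contract is defined by a brute-force window scan, which the seed-and-extend
#' search provably equals because any match of length >= k contains a k-mer
#' seed on the same diagonal.
#'
#' @param probes named character vector of probe sequences (ACGT).
#' @param transcripts named character vector of transcript sequences (ACGT).
#' @param min_match minimal ungapped match length in nt (default 22).
#' @return data frame with columns `probe_id`, `transcript_id`, `t_start`,
#'   `t_end` (1-based inclusive, transcript plus strand), `match_len`.
#' @examples
#' tx <- c(tx1 = paste(rep("ACGTA", 20), collapse = ""))
#' pr <- c(p1 = probeRank:::revcomp(substr(tx, 10, 34)))
#' align_probes(pr, tx)
#' @export
align_probes <- function(probes, transcripts, min_match = 22L) {
  if (length(probes) == 0L || length(transcripts) == 0L) {
    return(empty_hits())
  }
  if (is.null(names(probes)) || is.null(names(transcripts))) {
    stop("probes and transcripts must be named", call. = FALSE)
  }
  check_acgt(probes, "probe")
  check_acgt(transcripts, "transcript")
  k <- as.integer(min_match)
  if (any(nchar(probes) < k)) {
    stop("min_match exceeds probe length", call. = FALSE)
  }
  rc <- revcomp(probes)

  # transcriptome k-mer index
  tx_tab <- do.call(rbind, lapply(names(transcripts), function(id) {
    s <- transcripts[[id]]
    n <- nchar(s) - k + 1L
    if (n < 1L) return(NULL)
    data.frame(kmer = substring(s, 1:n, k:nchar(s)), tx = id, tpos = 1:n,
               stringsAsFactors = FALSE)
  }))
  pr_tab <- do.call(rbind, lapply(names(rc), function(id) {
    s <- rc[[id]]
    n <- nchar(s) - k + 1L
    data.frame(kmer = substring(s, 1:n, k:nchar(s)), probe = id, qpos = 1:n,
               stringsAsFactors = FALSE)
  }))
  if (is.null(tx_tab) || nrow(tx_tab) == 0L) return(empty_hits())
  cand <- merge(pr_tab, tx_tab, by = "kmer")
  if (nrow(cand) == 0L) return(empty_hits())
  cand$diag <- cand$tpos - cand$qpos
  cand <- unique(cand[, c("probe", "tx", "diag")])

  pr_chars <- strsplit(rc, "")
  tx_chars <- strsplit(transcripts, "")
  hits <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    pc <- pr_chars[[cand$probe[i]]]
    tc <- tx_chars[[cand$tx[i]]]
    d <- cand$diag[i]
    qs <- max(1L, 1L - d):min(length(pc), length(tc) - d)
    eq <- pc[qs] == tc[qs + d]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    ok <- which(r$values & r$lengths >= k)
    if (length(ok) == 0L) next
    best <- ok[which.max(r$lengths[ok])]  # leftmost among maxima (which.max)
    len <- r$lengths[best]
    q0 <- qs[1L] + ends[best] - len       # probe-side start of the run
    hits[[i]] <- data.frame(
      probe_id = cand$probe[i], transcript_id = cand$tx[i],
      t_start = q0 + d, t_end = q0 + d + len - 1L, match_len = len,
      stringsAsFactors = FALSE
    )
  }
  hits <- do.call(rbind, hits)
  if (is.null(hits)) return(empty_hits())
  # one hit per (probe, transcript): maximal length, leftmost t_start on ties
  hits <- hits[order(hits$probe_id, hits$transcript_id,
                     -hits$match_len, hits$t_start), ]
  hits <- hits[!duplicated(hits[, c("probe_id", "transcript_id")]), ]
  rownames(hits) <- NULL
  hits
}

empty_hits <- function() {
  data.frame(probe_id = character(0), transcript_id = character(0),
             t_start = integer(0), t_end = integer(0), match_len = integer(0),
             stringsAsFactors = FALSE)
}

#' Build the probe-to-transcript index, discarding unaligned probes
#'
#' Probes without any alignment hit are discarded from the analysis; `T` is
#' the number of retained probes and `targets` tallies, per transcript, the
#' number of distinct probes hitting it (a multi-mapping probe counts once per
#' transcript it hits).
#'
#' @param hits data frame from [align_probes()].
#' @param all_probe_ids character vector of every probe on the array.
#' @return object of class `probe_index`: list with `hits` (probe id ->
#'   character vector of transcript ids), `T` (retained probe count),
#'   `targets` (named integer vector, per-transcript probe counts),
#'   `discarded` (ids of unaligned probes).
#' @export
build_probe_index <- function(hits, all_probe_ids) {
  pairs <- unique(hits[, c("probe_id", "transcript_id")])
  hit_map <- split(pairs$transcript_id, pairs$probe_id)
  retained <- names(hit_map)
  unknown <- setdiff(retained, all_probe_ids)
  if (length(unknown) > 0L) {
    stop("hits reference probes absent from all_probe_ids", call. = FALSE)
  }
  discarded <- setdiff(all_probe_ids, retained)
  targets <- table(pairs$transcript_id)
  targets <- setNames(as.integer(targets), names(targets))
  message(sprintf("probe index: %d retained, %d discarded",
                  length(retained), length(discarded)))
  structure(list(hits = hit_map, T = length(retained), targets = targets,
                 discarded = discarded), class = "probe_index")
}

#' @export
print.probe_index <- function(x, ...) {
  cat(sprintf("probe_index: %d retained probes, %d transcripts, %d discarded\n",
              x$T, length(x$targets), length(x$discarded)))
  invisible(x)
}
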