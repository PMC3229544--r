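#' Hypergeometric attribution tail (pAX)
#'
#' The probability of being mistaken when attributing expression profile A to
#' transcript X: the upper tail, including the observed count, of drawing at
#' least `X_A` of transcript X's probes when `A_size` probes (the profile
#' cluster) are drawn without replacement from the `T` retained probes, of
#' which `X_T` hit X:
#' `p = sum_{i = X_A}^{min(A_size, X_T)} dhyper(i, X_T, T - X_T, A_size)`.
#'
#' @param X_A probes with profile A hitting X (vectorized).
#' @param A_size probes with profile A (cluster size).
#' @param X_T probes hitting X.
#' @param T_total total retained probes (T).
#' @return numeric vector of upper-tail probabilities in (0, 1].
#' @examples
#' hypergeom_tail(4, 5, 9, 20)  # 1512/15504
#' @export
hypergeom_tail <- function(X_A, A_size, X_T, T_total) {
  n <- max(length(X_A), length(A_size), length(X_T), length(T_total))
  X_A <- rep_len(as.numeric(X_A), n); A_size <- rep_len(as.numeric(A_size), n)
  X_T <- rep_len(as.numeric(X_T), n); T_total <- rep_len(as.numeric(T_total), n)
  bad <- X_A < 0 | A_size < 0 | X_T < 0 | T_total < 0 |
    X_A > pmin(A_size, X_T) | X_T > T_total | A_size > T_total
  if (any(bad)) {
    stop("invalid counts: need 0 <= X_A <= min(A_size, X_T), X_T <= T, A_size <= T",
         call. = FALSE)
  }
  vapply(seq_len(n), function(i) {
    hi <- min(A_size[i], X_T[i])
    sum(dhyper(X_A[i]:hi, X_T[i], T_total[i] - X_T[i], A_size[i]))
  }, numeric(1))
}

#' Attribute expression profiles to transcripts
#'
#' For every (transcript, profile) pair with at least one supporting probe —
#' excluding the all-`E` profile, which encodes "no differential expression" —
#' assembles the attribution counts and the raw pAX upper tail. A
#' multi-mapping probe contributes to the record of every transcript it hits.
#'
#' @param clusters profile clusters from [cluster_probes()].
#' @param index [build_probe_index()] over the same retained-probe universe.
#' @return data frame with columns `transcript`, `profile`, `X_A`, `A_size`,
#'   `X_T`, `T`, `p_raw`, ordered by transcript then profile.
#' @export
attribute <- function(clusters, index) {
  stopifnot(inherits(index, "probe_index"))
  cluster_probes_all <- unlist(clusters, use.names = FALSE)
  if (!setequal(cluster_probes_all, names(index$hits)) ||
      length(cluster_probes_all) != length(index$hits)) {
    stop("clusters and probe index cover different probe universes",
         call. = FALSE)
  }
  profile_of <- setNames(rep(names(clusters), lengths(clusters)),
                         cluster_probes_all)
  long <- data.frame(
    probe = rep(names(index$hits), lengths(index$hits)),
    transcript = unlist(index$hits, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  long$profile <- unname(profile_of[long$probe])
  long <- long[!grepl("^E+$", long$profile), , drop = FALSE]
  if (nrow(long) == 0L) {
    return(data.frame(transcript = character(0), profile = character(0),
                      X_A = integer(0), A_size = integer(0), X_T = integer(0),
                      T = integer(0), p_raw = numeric(0),
                      stringsAsFactors = FALSE))
  }
  agg <- aggregate(list(X_A = long$probe),
                   by = list(transcript = long$transcript,
                             profile = long$profile),
                   FUN = length)
  agg$A_size <- unname(lengths(clusters)[agg$profile])
  agg$X_T <- unname(index$targets[agg$transcript])
  agg$T <- index$T
  agg$p_raw <- hypergeom_tail(agg$X_A, agg$A_size, agg$X_T, agg$T)
  agg <- agg[order(agg$transcript, agg$profile), ]
  rownames(agg) <- NULL
  agg
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of the raw attribution p-values;
#' all emitted (transcript, profile) records form one adjustment family.
#'
#' @param p numeric vector of raw p-values in (0, 1].
#' @return adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}

# Resolve, per transcript, the significant direction letter at one comparison
# position: among significant records whose profile is non-E at `position`,
# the minimal-p_adj record wins (ties broken by profile string). Returns a
# data frame (transcript, letter, profile, p_adj, ambiguous); `ambiguous`
# flags transcripts with significant records of both letters at the position.
resolve_position <- function(records, position, alpha = 0.05) {
  if (!"p_adj" %in% names(records)) stop("records lack p_adj", call. = FALSE)
  if (position < 1L || nrow(records) > 0L &&
      position > nchar(records$profile[1L])) {
    stop("position outside the comparison plan", call. = FALSE)
  }
  sig <- records[records$p_adj < alpha, , drop = FALSE]
  if (nrow(sig) == 0L) {
    return(data.frame(transcript = character(0), letter = character(0),
                      profile = character(0), p_adj = numeric(0),
                      ambiguous = logical(0), stringsAsFactors = FALSE))
  }
  sig$letter <- substr(sig$profile, position, position)
  sig <- sig[sig$letter != "E", , drop = FALSE]
  if (nrow(sig) == 0L) {
    return(data.frame(transcript = character(0), letter = character(0),
                      profile = character(0), p_adj = numeric(0),
                      ambiguous = logical(0), stringsAsFactors = FALSE))
  }
  sig <- sig[order(sig$transcript, sig$p_adj, sig$profile), , drop = FALSE]
  amb <- tapply(sig$letter, sig$transcript,
                function(l) length(unique(l)) > 1L)
  best <- sig[!duplicated(sig$transcript), , drop = FALSE]
  best$ambiguous <- unname(amb[best$transcript])
  best[, c("transcript", "letter", "profile", "p_adj", "ambiguous")]
}

#' Call differentially expressed transcripts at one comparison position
#'
#' A transcript is called DE in direction `letter` at `position` if it has at
#' least one attribution record with adjusted p strictly below `alpha` whose
#' profile carries that letter at that position, and its minimal-p_adj
#' significant record at the position agrees with the letter. Transcripts
#' with significant records of conflicting letters at the position are
#' flagged `ambiguous` and resolved to the minimal-p_adj record.
#'
#' @param records attribution data frame carrying a `p_adj` column.
#' @param position comparison position (1-based, plan order).
#' @param letter `"H"` or `"L"`.
#' @param alpha strict threshold on adjusted p (default 0.05).
#' @return data frame `transcript`, `profile`, `p_adj`, `ambiguous`, sorted
#'   by `p_adj` then transcript.
#' @export
call_de <- function(records, position, letter, alpha = 0.05) {
  stopifnot(letter %in% c("H", "L"))
  best <- resolve_position(records, position, alpha)
  out <- best[best$letter == letter, c("transcript", "profile", "p_adj",
                                       "ambiguous"), drop = FALSE]
  out <- out[order(out$p_adj, out$transcript), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Effect size: mean relative-rank difference
#'
#' For an attributed (transcript, profile) pair and one comparison position,
#' the mean over the supporting probes (probes with that profile hitting the
#' transcript) of the difference between the probe's mean relative rank on the
#' comparison's experimental arrays and on its control arrays. Bounded in
#' (-1, 1); its sign agrees with the profile letter at the position.
#'
#' @param transcript transcript id.
#' @param profile attributed profile string (letter at `position` must not
#'   be `E`).
#' @param position comparison position.
#' @param ranks relative-rank matrix.
#' @param plan,design comparison plan and experiment design.
#' @param index probe index.
#' @param clusters profile clusters.
#' @return single numeric effect size.
#' @export
effect_size <- function(transcript, profile, position, ranks, plan, design,
                        index, clusters) {
  if (substr(profile, position, position) == "E") {
    stop("effect size undefined for letter E at the requested position",
         call. = FALSE)
  }
  members <- clusters[[profile]]
  if (is.null(members)) stop("profile has no cluster", call. = FALSE)
  support <- members[vapply(members, function(p) transcript %in% index$hits[[p]],
                            logical(1))]
  if (length(support) == 0L) {
    stop("no supporting probes for this (transcript, profile)", call. = FALSE)
  }
  arrs <- comparison_arrays(plan, design)[[position]]
  d <- rowMeans(ranks[support, arrs$exp, drop = FALSE]) -
    rowMeans(ranks[support, arrs$ctrl, drop = FALSE])
  mean(d)
}

#' Rank transcripts by the product of adjusted p-values in two genotypes
#'
#' Orders transcripts differentially expressed in both genotypes at a matched
#' timepoint by the ascending product of their adjusted p-values (most
#' reliable differential expression first). Transcripts DE in only one
#' genotype are excluded; ties are broken by transcript id.
#'
#' @param de_a,de_b DE-call data frames from [call_de()] for the two
#'   genotypes at the matched timepoint (columns `transcript`, `p_adj`).
#' @return data frame `transcript`, `p_adj_a`, `p_adj_b`, `p_product`,
#'   ordered by ascending product.
#' @export
p_product_ranking <- function(de_a, de_b) {
  m <- merge(de_a[, c("transcript", "p_adj")],
             de_b[, c("transcript", "p_adj")],
             by = "transcript", suffixes = c("_a", "_b"))
  m$p_product <- m$p_adj_a * m$p_adj_b
  m <- m[order(m$p_product, m$transcript), ]
  rownames(m) <- NULL
  m
}

#' Genotype-contrast transcript sets
#'
#' Partitions significant transcripts by when they differ between the two
#' genotypes, using the resolved direction letters at the three genotype
#' comparisons (positions `naive`, `t90`, `t24` of the plan):
#' * `naive_diff` — DE already between naive genotypes;
#' * `consistent` — not DE in naive animals but DE with the same letter at
#'   both hypoxia timepoints;
#' * `only_90` / `only_24` — DE between genotypes at exactly one timepoint.
#'
#' @param records attribution data frame with `p_adj`.
#' @param alpha strict DE threshold (default 0.05).
#' @param positions named integer vector with entries `naive`, `t90`, `t24`
#'   (defaults 1, 2, 3: the canonical plan's genotype comparisons).
#' @return list of four character vectors of transcript ids.
#' @export
contrast_sets <- function(records, alpha = 0.05,
                          positions = c(naive = 1L, t90 = 2L, t24 = 3L)) {
  if (!all(c("naive", "t90", "t24") %in% names(positions))) {
    stop("positions must name naive, t90 and t24 comparisons", call. = FALSE)
  }
  r1 <- resolve_position(records, positions[["naive"]], alpha)
  r2 <- resolve_position(records, positions[["t90"]], alpha)
  r3 <- resolve_position(records, positions[["t24"]], alpha)
  l2 <- setNames(r2$letter, r2$transcript)
  l3 <- setNames(r3$letter, r3$transcript)
  both <- intersect(names(l2), names(l3))
  same <- both[l2[both] == l3[both]]
  list(
    naive_diff = sort(r1$transcript),
    consistent = sort(setdiff(same, r1$transcript)),
    only_90 = sort(setdiff(names(l2), union(r1$transcript, names(l3)))),
    only_24 = sort(setdiff(names(l3), union(r1$transcript, names(l2))))
  )
}
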