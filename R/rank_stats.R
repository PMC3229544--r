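#' Rank-normalize an intensity matrix
#'
#' Each array (column) is replaced by relative ranks: ascending ranks with
#' mid-ranks for ties, divided by the number of probes P, so values lie in
#' (0, 1] and every array has the identical signal distribution. The per-array
#' sum of relative ranks is (P + 1) / 2 exactly, ties or not.
#'
#' @param mat positive numeric matrix, rows probes, columns arrays.
#' @return matrix of relative ranks with the same dimnames.
#' @examples
#' rank_normalize(matrix(c(5, 2, 9), ncol = 1))
#' @export
rank_normalize <- function(mat) {
  mat <- as.matrix(mat)
  if (length(mat) == 0L) stop("empty intensity matrix", call. = FALSE)
  if (anyNA(mat) || any(!is.finite(mat)) || any(mat <= 0)) {
    bad <- which(is.na(mat) | !is.finite(mat) | mat <= 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-positive or missing intensity at row %d, column %d",
                 bad[1L], bad[2L]), call. = FALSE)
  }
  apply(mat, 2L, function(col) rank(col, ties.method = "average")) / nrow(mat)
}

# Cache of assignment-enumeration matrices: for group sizes (nx, ny), an
# (nx+ny) x C(nx+ny, nx) 0/1 indicator of which pooled positions fall in the
# experimental group, one column per equally likely assignment.
.mw_cache <- new.env(parent = emptyenv())

assignment_matrix <- function(nx, ny) {
  key <- paste(nx, ny, sep = "_")
  if (!is.null(.mw_cache[[key]])) return(.mw_cache[[key]])
  n <- nx + ny
  combs <- combn(n, nx)
  A <- matrix(0L, n, ncol(combs))
  A[cbind(as.vector(combs), rep(seq_len(ncol(combs)), each = nx))] <- 1L
  .mw_cache[[key]] <- A
  A
}

#' Exact Mann-Whitney tail probabilities for two small groups
#'
#' Computes the exact one-sided tail probabilities of the rank-sum statistic
#' over all `choose(nx + ny, nx)` equally likely assignments of the pooled
#' mid-ranked values, each tail including the observed statistic. Ties are
#' handled by enumeration over the mid-ranks, where the classical null tables
#' (and `wilcox.test`'s exact mode) do not apply. Mid-ranks are half-integers,
#' so all comparisons are exact in floating point.
#'
#' @param x numeric values of the experimental group (>= 2 values).
#' @param y numeric values of the control group (>= 2 values).
#' @return named numeric vector `c(p_upper, p_lower)`: `p_upper` tests
#'   "experimental higher", `p_lower` "experimental lower".
#' @examples
#' mw_exact(c(0.4, 0.5, 0.6, 0.7, 0.8), c(0.1, 0.2, 0.3))  # 1/56 upper
#' @export
mw_exact <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  r <- rank(c(x, y), ties.method = "average")
  A <- assignment_matrix(nx, ny)
  W <- as.vector(r %*% A)
  obs <- sum(r[seq_len(nx)])
  c(p_upper = mean(W >= obs), p_lower = mean(W <= obs))
}

# Vectorized exact Mann-Whitney over the rows of a relative-rank matrix.
# R: probes x arrays; exp_ids / ctrl_ids: array id vectors. Returns a list
# with p_upper and p_lower vectors (one entry per probe).
mw_exact_matrix <- function(R, exp_ids, ctrl_ids) {
  nx <- length(exp_ids); ny <- length(ctrl_ids)
  pool <- R[, c(exp_ids, ctrl_ids), drop = FALSE]
  rr <- t(apply(pool, 1L, rank, ties.method = "average"))
  A <- assignment_matrix(nx, ny)
  W <- rr %*% A                      # probes x assignments
  obs <- rowSums(rr[, seq_len(nx), drop = FALSE])
  list(p_upper = rowMeans(W >= obs), p_lower = rowMeans(W <= obs))
}

#' Assign an H/L/E letter from exact one-sided tails
#'
#' `H` (higher in the experimental group) if `p_upper <= alpha`; `L` if
#' `p_lower <= alpha`; `E` otherwise. The threshold is inclusive. With exact
#' tails that both include the observed point, `p_upper + p_lower >= 1`, so H
#' and L can never co-fire for `alpha < 0.5`.
#'
#' @param p_upper,p_lower exact tails from [mw_exact()] (vectorized).
#' @param alpha significance threshold in (0, 0.5); default 0.05.
#' @return character vector over `{H, L, E}`.
#' @export
assign_letter <- function(p_upper, p_lower, alpha = 0.05) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 0.5) {
    stop("alpha must lie in (0, 0.5)", call. = FALSE)
  }
  ifelse(p_upper <= alpha, "H", ifelse(p_lower <= alpha, "L", "E"))
}

#' Build per-probe expression strings
#'
#' For every probe, runs the exact Mann-Whitney test on its relative ranks in
#' each planned comparison and concatenates the resulting H/L/E letters in
#' plan order into an expression string describing the probe's
#' differential-expression dynamics.
#'
#' @param ranks relative-rank matrix from [rank_normalize()] (rows probes,
#'   columns arrays), restricted to retained probes.
#' @param design experiment design.
#' @param plan comparison plan (default [default_plan()]).
#' @param alpha letter threshold (default 0.05).
#' @return list with `strings` (named character vector, one string per
#'   probe), `letters` (probes x comparisons character matrix), `p_upper`
#'   and `p_lower` (probes x comparisons numeric matrices).
#' @export
build_expression_strings <- function(ranks, design, plan = default_plan(),
                                     alpha = 0.05) {
  arrs <- comparison_arrays(plan, design)
  missing_arr <- setdiff(unlist(lapply(arrs, unlist)), colnames(ranks))
  if (length(missing_arr) > 0L) {
    stop(sprintf("arrays missing from rank matrix: %s",
                 paste(head(missing_arr, 5L), collapse = ", ")), call. = FALSE)
  }
  ncomp <- length(arrs)
  P <- nrow(ranks)
  p_up <- p_lo <- matrix(NA_real_, P, ncomp,
                         dimnames = list(rownames(ranks), names(arrs)))
  letters <- matrix(NA_character_, P, ncomp,
                    dimnames = list(rownames(ranks), names(arrs)))
  for (j in seq_len(ncomp)) {
    res <- mw_exact_matrix(ranks, arrs[[j]]$exp, arrs[[j]]$ctrl)
    p_up[, j] <- res$p_upper
    p_lo[, j] <- res$p_lower
    letters[, j] <- assign_letter(res$p_upper, res$p_lower, alpha)
  }
  strings <- setNames(do.call(paste0, as.data.frame(letters)), rownames(ranks))
  list(strings = strings, letters = letters, p_upper = p_up, p_lower = p_lo)
}

#' Cluster probes by identical expression strings
#'
#' @param strings named character vector (probe id -> expression string).
#' @return named list: profile string -> character vector of probe ids. The
#'   clusters partition the probes; cluster sizes are the `A` counts of the
#'   attribution statistic.
#' @export
cluster_probes <- function(strings) {
  if (length(strings) == 0L) return(structure(list(), names = character(0)))
  split(names(strings), strings)
}
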