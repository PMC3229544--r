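#' Run the full probe-level differential-expression pipeline
#'
#' Executes the complete workflow on in-memory objects: align probes to the
#' transcriptome and discard unaligned probes; rank-normalize each array over
#' the retained probes; run the exact Mann-Whitney test per probe and
#' comparison; build H/L/E expression strings and cluster probes by string
#' identity; attribute profiles to transcripts with the hypergeometric upper
#' tail; adjust with Benjamini-Hochberg; derive per-comparison DE lists with
#' effect sizes, reliability rankings by p-value products, and
#' genotype-contrast sets. Per-stage counts are logged via `message()`.
#'
#' @param probes named character vector of probe sequences.
#' @param transcripts named character vector of transcript sequences.
#' @param intensities positive probe-by-array matrix covering all probes.
#' @param design experiment design data frame.
#' @param plan comparison plan (default [default_plan()]).
#' @param alpha significance threshold for letters and DE calls
#'   (default 0.05).
#' @param min_match minimal ungapped alignment length (default 22).
#' @param out_dir if non-`NULL`, all result tables are written there as TSV.
#' @return list of class `probe_de_result` with elements `hits`, `index`,
#'   `ranks`, `strings` (the [build_expression_strings()] bundle), `clusters`,
#'   `records` (attribution table with `p_adj`), `de` (per comparison and
#'   direction, with effect sizes), `rankings`, `contrasts`, `stage_counts`.
#' @export
run_pipeline <- function(probes, transcripts, intensities, design,
                         plan = default_plan(), alpha = 0.05,
                         min_match = 22L, out_dir = NULL) {
  validate_design(design)
  stage <- function(fmt, ...) message(sprintf(paste0("[pipeline] ", fmt), ...))

  hits <- align_probes(probes, transcripts, min_match)
  index <- build_probe_index(hits, names(probes))
  if (index$T == 0L) stop("alignment: 0 probes retained", call. = FALSE)
  stage("align: %d/%d probes retained, %d discarded",
        index$T, length(probes), length(index$discarded))

  missing_pr <- setdiff(names(index$hits), rownames(intensities))
  if (length(missing_pr) > 0L) {
    stop("intensity matrix lacks retained probes", call. = FALSE)
  }
  ranks <- rank_normalize(intensities[names(index$hits), design$array_id,
                                      drop = FALSE])
  stage("rank-normalize: %d probes x %d arrays", nrow(ranks), ncol(ranks))

  strings <- build_expression_strings(ranks, design, plan, alpha)
  clusters <- cluster_probes(strings$strings)
  stage("strings: %d profile clusters over %d probes",
        length(clusters), length(strings$strings))

  records <- attribute(clusters, index)
  records$p_adj <- bh_adjust(records$p_raw)
  n_sig <- sum(records$p_adj < alpha)
  stage("attribution: %d records tested, %d significant at adjusted p < %g",
        nrow(records), n_sig, alpha)

  de <- list()
  for (pos in seq_len(nrow(plan))) {
    for (letter in c("H", "L")) {
      calls <- call_de(records, pos, letter, alpha)
      if (nrow(calls) > 0L) {
        calls$effect <- vapply(seq_len(nrow(calls)), function(i) {
          effect_size(calls$transcript[i], calls$profile[i], pos, ranks,
                      plan, design, index, clusters)
        }, numeric(1))
      } else {
        calls$effect <- numeric(0)
      }
      de[[sprintf("%s_%s", plan$label[pos], letter)]] <- calls
    }
  }

  # reliability rankings: transcripts DE in both genotypes at a matched
  # hypoxia timepoint (plan positions 4/6 = 90 min, 5/7 = 24 h)
  rankings <- list()
  if (nrow(plan) >= 7L) {
    for (tp in list(c("90min", 4L, 6L), c("24h", 5L, 7L))) {
      for (letter in c("H", "L")) {
        a <- call_de(records, as.integer(tp[2L]), letter, alpha)
        b <- call_de(records, as.integer(tp[3L]), letter, alpha)
        rankings[[sprintf("%s_%s", tp[1L], letter)]] <- p_product_ranking(a, b)
      }
    }
  }
  contrasts <- if (nrow(plan) >= 3L) contrast_sets(records, alpha) else NULL

  result <- structure(list(
    hits = hits, index = index, ranks = ranks, strings = strings,
    clusters = clusters, records = records, de = de, rankings = rankings,
    contrasts = contrasts,
    stage_counts = c(n_probes = length(probes), retained = index$T,
                     discarded = length(index$discarded),
                     clusters = length(clusters), records = nrow(records),
                     significant = n_sig)
  ), class = "probe_de_result")

  if (!is.null(out_dir)) write_result_bundle(result, out_dir)
  result
}

#' @export
print.probe_de_result <- function(x, ...) {
  cat("probe-level differential-expression result\n")
  print(x$stage_counts)
  invisible(x)
}

#' Write every pipeline result table as TSV
#'
#' @param result a `probe_de_result` from [run_pipeline()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_result_bundle <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv_formatted(result$hits, file.path(dir, "hits.tsv"))

  st <- data.frame(probe_id = names(result$strings$strings),
                   expression_string = unname(result$strings$strings),
                   stringsAsFactors = FALSE)
  pu <- result$strings$p_upper
  pl <- result$strings$p_lower
  for (j in seq_len(ncol(pu))) {
    st[[paste0("p_upper_", colnames(pu)[j])]] <- pu[, j]
    st[[paste0("p_lower_", colnames(pl)[j])]] <- pl[, j]
  }
  write_tsv_formatted(st, file.path(dir, "strings.tsv"))

  write_tsv_formatted(result$records, file.path(dir, "attributions.tsv"))

  for (nm in names(result$de)) {
    write_tsv_formatted(result$de[[nm]],
                        file.path(dir, sprintf("de_%s.tsv", nm)))
  }
  for (nm in names(result$rankings)) {
    write_tsv_formatted(result$rankings[[nm]],
                        file.path(dir, sprintf("ranking_%s.tsv", nm)))
  }
  if (!is.null(result$contrasts)) {
    cs <- result$contrasts
    df <- data.frame(
      set = rep(names(cs), lengths(cs)),
      transcript = unlist(cs, use.names = FALSE),
      stringsAsFactors = FALSE
    )
    write_tsv_formatted(df, file.path(dir, "contrast_sets.tsv"))
  }
  invisible(dir)
}

#' Run the pipeline from files
#'
#' Thin wrapper over [run_pipeline()] reading FASTA/TSV inputs, used by the
#' command-line script.
#'
#' @param probes_fasta,transcripts_fasta FASTA paths.
#' @param intensity_tsv,design_tsv TSV paths.
#' @param out_dir output directory for the result tables.
#' @param alpha,min_match see [run_pipeline()].
#' @return the `probe_de_result`, invisibly.
#' @export
run_pipeline_files <- function(probes_fasta, transcripts_fasta, intensity_tsv,
                               design_tsv, out_dir, alpha = 0.05,
                               min_match = 22L) {
  design <- read_design_tsv(design_tsv)
  probes <- read_fasta(probes_fasta)
  transcripts <- read_fasta(transcripts_fasta)
  intensities <- read_intensity_tsv(intensity_tsv, design)
  invisible(run_pipeline(probes, transcripts, intensities, design,
                         alpha = alpha, min_match = min_match,
                         out_dir = out_dir))
}
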