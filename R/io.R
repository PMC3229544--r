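#' Read a FASTA file
#'
#' Sequences are upper-cased; record ids are the first whitespace-delimited
#' token of the header. Duplicate ids are rejected by name.
#'
#' @param path FASTA file path.
#' @return named character vector of sequences, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate FASTA id: %s", ids[duplicated(ids)][1L]),
         call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs))) {
    stop(sprintf("empty sequence for record %s", ids[!nzchar(seqs)][1L]),
         call. = FALSE)
  }
  setNames(seqs, ids)
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read an experiment-design TSV
#'
#' Columns `array_id`, `genotype`, `timepoint`.
#'
#' @param path TSV file path.
#' @return design data frame.
#' @export
read_design_tsv <- function(path) {
  d <- as.data.frame(data.table::fread(path, sep = "\t", colClasses = "character"))
  validate_design(d)
  d
}

#' @rdname read_design_tsv
#' @param design design data frame.
#' @export
write_design_tsv <- function(design, path) {
  validate_design(design)
  data.table::fwrite(design, path, sep = "\t")
  invisible(path)
}

#' Read a probe-by-array intensity TSV
#'
#' First column `probe_id`, remaining columns one per array. Array membership
#' is cross-checked against the design; non-numeric or non-positive cells are
#' rejected with their coordinates.
#'
#' @param path TSV file path.
#' @param design experiment design the arrays must match.
#' @return positive numeric matrix, rows probes (file order), columns the
#'   design's arrays.
#' @export
read_intensity_tsv <- function(path, design) {
  validate_design(design)
  d <- as.data.frame(data.table::fread(path, sep = "\t"))
  if (names(d)[1L] != "probe_id") {
    stop("intensity TSV must start with a probe_id column", call. = FALSE)
  }
  missing_arr <- setdiff(design$array_id, names(d))
  if (length(missing_arr) > 0L) {
    stop(sprintf("design arrays missing from intensity header: %s",
                 paste(head(missing_arr, 5L), collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(d$probe_id)) {
    stop("duplicate probe_id in intensity TSV", call. = FALSE)
  }
  mat <- as.matrix(d[, design$array_id, drop = FALSE])
  if (!is.numeric(mat)) {
    stop("non-numeric intensity values", call. = FALSE)
  }
  rownames(mat) <- d$probe_id
  bad <- which(is.na(mat) | !is.finite(mat) | mat <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-positive or missing intensity for probe %s, array %s",
                 rownames(mat)[bad[1L, 1L]], colnames(mat)[bad[1L, 2L]]),
         call. = FALSE)
  }
  mat
}

#' @rdname read_intensity_tsv
#' @param mat probe-by-array matrix.
#' @export
write_intensity_tsv <- function(mat, path) {
  d <- data.table::data.table(probe_id = rownames(mat))
  for (cn in colnames(mat)) d[[cn]] <- fmt_num(mat[, cn])
  data.table::fwrite(d, path, sep = "\t")
  invisible(path)
}

# 6 significant digits for floats, plain integers for counts: bit-stable
# output across runs.
fmt_num <- function(x) {
  if (is.numeric(x) && all(x == round(x)) && all(abs(x) < 2^31)) {
    format(as.integer(x), scientific = FALSE, trim = TRUE)
  } else {
    formatC(signif(x, 6L), format = "g", digits = 6L)
  }
}

write_tsv_formatted <- function(df, path) {
  out <- df
  for (cn in names(out)) {
    if (is.numeric(out[[cn]])) out[[cn]] <- fmt_num(out[[cn]])
    if (is.logical(out[[cn]])) out[[cn]] <- ifelse(out[[cn]], "TRUE", "FALSE")
  }
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Write the simulated bundle to disk
#'
#' Writes transcripts and probes as FASTA, intensities, design and ground
#' truth as TSV, in the layout the pipeline reads back.
#'
#' @param sim bundle from [simulate_experiment()].
#' @param dir output directory (created if absent).
#' @return named character vector of the written paths, invisibly.
#' @export
write_sim_bundle <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    transcripts = file.path(dir, "transcripts.fasta"),
    probes = file.path(dir, "probes.fasta"),
    intensities = file.path(dir, "intensities.tsv"),
    design = file.path(dir, "design.tsv"),
    truth = file.path(dir, "ground_truth.tsv")
  )
  write_fasta(sim$transcripts, paths[["transcripts"]])
  write_fasta(sim$probes, paths[["probes"]])
  write_intensity_tsv(sim$intensities, paths[["intensities"]])
  write_design_tsv(sim$design, paths[["design"]])
  gt <- data.frame(probe_id = names(sim$truth$probe_origin),
                   origin = unname(sim$truth$probe_origin),
                   stringsAsFactors = FALSE)
  gt$true_profile <- unname(sim$truth$true_profile[gt$origin])
  gt$true_profile[is.na(gt$true_profile)] <- ""
  write_tsv_formatted(gt, paths[["truth"]])
  invisible(paths)
}

#' Read a run configuration from YAML or JSON
#'
#' Recognized keys: `probes_fasta`, `transcripts_fasta`, `intensity_tsv`,
#' `design_tsv`, `out_dir`, `alpha`, `min_match`.
#'
#' @param path YAML (or JSON, a YAML subset) file.
#' @return named list of configuration values.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$alpha) && (cfg$alpha <= 0 || cfg$alpha >= 0.5)) {
    stop("alpha must lie in (0, 0.5)", call. = FALSE)
  }
  if (!is.null(cfg$min_match) && (cfg$min_match < 15 || cfg$min_match > 25)) {
    stop("min_match must lie in [15, 25]", call. = FALSE)
  }
  cfg
}
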