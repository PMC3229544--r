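#' Experiment design: arrays and their (genotype, timepoint) groups
#'
#' An experiment design is a data frame with columns `array_id`, `genotype`
#' (`"wt"` or `"null"`) and `timepoint` (`"0"`, `"90min"` or `"24h"`).
#' `default_design()` reproduces the study layout: 3 naive wild-type, 5 naive
#' knockout, 5 wild-type and 5 knockout arrays at 90 minutes of hypoxia, and
#' 5 wild-type and 4 knockout arrays at 24 hours.
#'
#' @param sizes integer vector of 6 group sizes in the order naive wt,
#'   naive null, 90-min wt, 90-min null, 24-h wt, 24-h null.
#' @return data frame with columns `array_id`, `genotype`, `timepoint`.
#' @examples
#' d <- default_design()
#' table(d$genotype, d$timepoint)
#' @export
default_design <- function(sizes = c(3L, 5L, 5L, 5L, 5L, 4L)) {
  stopifnot(length(sizes) == 6L, all(sizes >= 2L))
  grp <- data.frame(
    genotype  = c("wt", "null", "wt", "null", "wt", "null"),
    timepoint = c("0", "0", "90min", "90min", "24h", "24h"),
    n         = as.integer(sizes),
    stringsAsFactors = FALSE
  )
  out <- do.call(rbind, lapply(seq_len(nrow(grp)), function(i) {
    data.frame(
      array_id  = sprintf("%s_%s_%d", grp$genotype[i], grp$timepoint[i],
                          seq_len(grp$n[i])),
      genotype  = grp$genotype[i],
      timepoint = grp$timepoint[i],
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  validate_design(out)
  out
}

validate_design <- function(design) {
  req <- c("array_id", "genotype", "timepoint")
  if (!is.data.frame(design) || !all(req %in% names(design))) {
    stop("design must be a data frame with columns array_id, genotype, timepoint",
         call. = FALSE)
  }
  if (anyDuplicated(design$array_id)) {
    stop("duplicate array_id in design", call. = FALSE)
  }
  if (!all(design$genotype %in% c("wt", "null"))) {
    stop("genotype must be 'wt' or 'null'", call. = FALSE)
  }
  if (!all(design$timepoint %in% c("0", "90min", "24h"))) {
    stop("timepoint must be '0', '90min' or '24h'", call. = FALSE)
  }
  invisible(design)
}

#' The canonical seven-comparison plan
#'
#' Positions 1-3 compare knockout to wild-type at matched timepoints (naive,
#' 90 min, 24 h); positions 4-5 compare hypoxic wild-type (90 min, 24 h) to
#' naive wild-type; positions 6-7 do the same within the knockout genotype.
#' In every comparison `H` means higher expression in the experimental member
#' of the pair (the knockout, or the hypoxic group).
#'
#' @return data frame with columns `position`, `label`, `exp_genotype`,
#'   `exp_timepoint`, `ctrl_genotype`, `ctrl_timepoint`.
#' @export
default_plan <- function() {
  data.frame(
    position       = 1:7,
    label          = c("null_vs_wt_0", "null_vs_wt_90min", "null_vs_wt_24h",
                       "wt_90min_vs_0", "wt_24h_vs_0",
                       "null_90min_vs_0", "null_24h_vs_0"),
    exp_genotype   = c("null", "null", "null", "wt", "wt", "null", "null"),
    exp_timepoint  = c("0", "90min", "24h", "90min", "24h", "90min", "24h"),
    ctrl_genotype  = c("wt", "wt", "wt", "wt", "wt", "null", "null"),
    ctrl_timepoint = c("0", "90min", "24h", "0", "0", "0", "0"),
    stringsAsFactors = FALSE
  )
}

#' Resolve a comparison plan against a design
#'
#' @param plan comparison plan ([default_plan()]).
#' @param design experiment design ([default_design()]).
#' @return list, one element per comparison, each with character vectors
#'   `exp` and `ctrl` of array ids.
#' @export
comparison_arrays <- function(plan, design) {
  validate_design(design)
  pick <- function(g, t) design$array_id[design$genotype == g & design$timepoint == t]
  out <- lapply(seq_len(nrow(plan)), function(i) {
    e <- pick(plan$exp_genotype[i], plan$exp_timepoint[i])
    c_ <- pick(plan$ctrl_genotype[i], plan$ctrl_timepoint[i])
    if (length(e) < 2L || length(c_) < 2L) {
      stop(sprintf("comparison '%s': each group needs >= 2 arrays (got %d vs %d)",
                   plan$label[i], length(e), length(c_)), call. = FALSE)
    }
    list(exp = e, ctrl = c_)
  })
  names(out) <- plan$label
  out
}
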