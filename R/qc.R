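# Correlation-based cohort homogeneity QC.

#' Homogeneity quality check of preprocessed surface maps
#'
#' Computes all pairwise Pearson correlations between subjects'
#' preprocessed maps (per tracer) over the included vertices.  Each
#' subject's statistic is the mean of its correlations with all other
#' subjects; a subject is flagged when that statistic falls below the
#' cohort mean minus two standard deviations.
#'
#' @param maps V x n matrix (n >= 3 subjects)
#' @param include logical vertex mask (default: all vertices)
#' @return a `qc_report` data frame: subject, mean_correlation, flagged;
#'   with attribute `correlations` (the full n x n matrix)
#' @export
homogeneity_qc <- function(maps, include = NULL) {
  n <- ncol(maps)
  if (n < 3) stop("need at least 3 subjects")
  if (is.null(include)) include <- rep(TRUE, nrow(maps))
  cc <- cor(maps[include, , drop = FALSE])
  stat <- (rowSums(cc) - 1) / (n - 1)   # mean off-diagonal per subject
  thr <- mean(stat) - 2 * sd(stat)
  out <- data.frame(subject = colnames(maps) %||% seq_len(n),
                    mean_correlation = unname(stat),
                    flagged = unname(stat < thr),
                    stringsAsFactors = FALSE)
  attr(out, "correlations") <- cc
  attr(out, "threshold") <- thr
  class(out) <- c("qc_report", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
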