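# Friedman omnibus test, Nemenyi post-hoc critical difference, and
# critical-difference grouping, used to rank time windows, reference
# regions and classifier configurations.

#' Friedman test with Nemenyi critical-difference grouping
#'
#' Ranks conditions within each block (mid-ranks for ties; with
#' `direction = "higher"` larger scores get larger ranks, so a larger mean
#' rank means a better condition), computes the tie-corrected Friedman
#' chi-square
#' `(k-1) * sum_j (R_j - N(k+1)/2)^2 / sum_ij (r_ij - (k+1)/2)^2`
#' with a chi-square p-value on k-1 degrees of freedom, and the Nemenyi
#' critical difference `CD = q_{alpha,k} * sqrt(k(k+1)/(6N))` where
#' `q_{alpha,k}` is the Studentized-range quantile at infinite degrees of
#' freedom divided by sqrt(2).  Conditions whose mean ranks lie within CD
#' of a local best are chained into groups (the bars of a CD diagram).
#'
#' @param scores N x k matrix or data frame: blocks (rows) x conditions
#'   (columns); no missing cells (rows with any NA are dropped with a
#'   message)
#' @param direction `"higher"` if larger scores are better, `"lower"`
#'   otherwise
#' @param alpha significance level for the critical difference
#' @return a `ranking_result`: condition names, `n_blocks`, `mean_ranks`,
#'   `statistic`, `df`, `p_value`, `cd`, `groups` (list of condition-name
#'   vectors, best first)
#' @export
friedman_rank <- function(scores, direction = c("higher", "lower"),
                          alpha = 0.05) {
  direction <- match.arg(direction)
  scores <- as.matrix(scores)
  k <- ncol(scores)
  if (k < 2) stop("need at least 2 conditions")
  drop_rows <- rowSums(is.na(scores)) > 0
  if (any(drop_rows)) {
    message(sum(drop_rows), " block(s) with missing cells dropped")
    scores <- scores[!drop_rows, , drop = FALSE]
  }
  n <- nrow(scores)
  if (n < 2) stop("need at least 2 complete blocks")
  if (is.null(colnames(scores))) colnames(scores) <- paste0("C", seq_len(k))

  sgn <- if (direction == "higher") 1 else -1
  ranks <- t(apply(sgn * scores, 1, rank))  # mid-ranks for ties
  mean_ranks <- colMeans(ranks)
  centered_col <- n * (mean_ranks - (k + 1) / 2)
  ss_total <- sum((ranks - (k + 1) / 2)^2)
  if (ss_total == 0) {
    stat <- 0; p <- 1
  } else {
    stat <- (k - 1) * sum(centered_col^2) / n / (ss_total / n)
    p <- stats::pchisq(stat, df = k - 1, lower.tail = FALSE)
  }
  cd <- stats::qtukey(1 - alpha, k, Inf) / sqrt(2) * sqrt(k * (k + 1) / (6 * n))

  ord <- order(mean_ranks, decreasing = TRUE)
  groups <- list()
  i <- 1
  while (i <= k) {
    j <- i
    while (j < k && mean_ranks[ord[i]] - mean_ranks[ord[j + 1]] <= cd) j <- j + 1
    seg <- colnames(scores)[ord[i:j]]
    if (length(groups) == 0 || !all(seg %in% groups[[length(groups)]]))
      groups[[length(groups) + 1]] <- seg
    i <- i + 1
  }
  structure(list(conditions = colnames(scores), n_blocks = n,
                 mean_ranks = mean_ranks, statistic = stat, df = k - 1,
                 p_value = p, cd = cd, alpha = alpha, groups = groups,
                 direction = direction),
            class = "ranking_result")
}

#' @exportS3Method base::print
print.ranking_result <- function(x, ...) {
  cat(sprintf("Friedman chi^2(%d) = %.3f, p = %.3g over %d blocks; CD = %.3f\n",
              x$df, x$statistic, x$p_value, x$n_blocks, x$cd))
  ord <- order(x$mean_ranks, decreasing = TRUE)
  for (i in ord)
    cat(sprintf("  %-22s mean rank %.2f\n", x$conditions[i], x$mean_ranks[i]))
  cat(length(x$groups), "CD group(s)\n")
  invisible(x)
}

#' Plot-ready data for a critical-difference diagram
#'
#' @param result a `ranking_result` from [friedman_rank()]
#' @return list with `conditions` (data frame: condition, mean_rank, in
#'   descending-rank order) and `segments` (data frame: group, from_rank,
#'   to_rank for each CD bar)
#' @export
cd_diagram_data <- function(result) {
  stopifnot(inherits(result, "ranking_result"))
  ord <- order(result$mean_ranks, decreasing = TRUE)
  conds <- data.frame(condition = result$conditions[ord],
                      mean_rank = unname(result$mean_ranks[ord]),
                      stringsAsFactors = FALSE)
  segs <- do.call(rbind, lapply(seq_along(result$groups), function(i) {
    g <- result$groups[[i]]
    r <- result$mean_ranks[g]
    data.frame(group = i, from_rank = max(r), to_rank = min(r))
  }))
  list(conditions = conds, segments = segs, cd = result$cd)
}

#' Draw a simple critical-difference diagram
#' @param x a `ranking_result`
#' @param ... ignored
#' @exportS3Method graphics::plot
plot.ranking_result <- function(x, ...) {
  d <- cd_diagram_data(x)
  k <- nrow(d$conditions)
  graphics::plot(d$conditions$mean_rank, seq_len(k), yaxt = "n",
                 xlab = "mean rank", ylab = "", pch = 19,
                 xlim = range(c(d$conditions$mean_rank,
                                d$conditions$mean_rank - x$cd)))
  graphics::axis(2, at = seq_len(k), labels = d$conditions$condition,
                 las = 2, cex.axis = 0.7)
  for (i in seq_len(nrow(d$segments)))
    graphics::segments(d$segments$from_rank[i], i + 0.3,
                       d$segments$to_rank[i], i + 0.3, lwd = 3,
                       col = "brown")
  invisible(d)
}
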