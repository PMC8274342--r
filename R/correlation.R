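# Vertex-wise within- and inter-subject correlations, the t-to-r
# conversion, and optimal-window selection.

#' Within-subject Pearson correlation of two surface maps
#'
#' @param map_a,map_b numeric vectors on the same mesh
#' @param include logical mask of vertices entering the correlation (at
#'   least 3 must be included)
#' @return Pearson r, or `NA` with attribute `reason` when either map has
#'   zero variance over the included vertices
#' @export
within_subject_corr <- function(map_a, map_b, include = NULL) {
  if (is.null(include)) include <- rep(TRUE, length(map_a))
  a <- map_a[include]; b <- map_b[include]
  if (length(a) < 3) stop("need at least 3 included vertices")
  if (sd(a) == 0 || sd(b) == 0)
    return(structure(NA_real_, reason = "zero variance"))
  cor(a, b)
}

#' Convert a Student t statistic to a correlation coefficient
#'
#' `r = sign(t) * sqrt(t^2 / (N - rank(M) + t^2))`, where N is the number
#' of observations and rank(M) the rank of the design matrix.  For a simple
#' regression (intercept plus one regressor, rank 2) this reproduces the
#' Pearson correlation of the two variables exactly.
#'
#' @param t Student t statistic (vectorized)
#' @param n number of observations
#' @param rank_m rank of the design matrix; must satisfy `n > rank_m`
#' @return correlation coefficient(s) in (-1, 1) for finite t
#' @export
t_to_r <- function(t, n, rank_m) {
  if (n <= rank_m) stop("need n > rank_m")
  sign(t) * sqrt(t^2 / (n - rank_m + t^2))
}

#' Vertex-wise inter-subject correlation between two modalities
#'
#' For each vertex, regresses modality B on modality A across subjects
#' (intercept plus slope), converts the slope's t statistic to r via
#' [t_to_r()], and optionally attaches a two-sided permutation p-value
#' obtained by permuting the subject pairing (the same permutation at
#' every vertex, preserving the spatial structure of each modality).
#'
#' @param maps_a,maps_b V x N matrices (columns = the same N subjects)
#' @param include logical vertex mask (default: all)
#' @param n_perm number of pairing permutations (0 = no p-values)
#' @param seed seed for the permutations
#' @return list with per-vertex `r`, `t`, `p` (or `NULL`), `n`, `rank_m`;
#'   vertices with a constant regressor get `NA` and a reason flag
#' @export
inter_subject_corr <- function(maps_a, maps_b, include = NULL,
                               n_perm = 0, seed = 1) {
  stopifnot(ncol(maps_a) == ncol(maps_b), nrow(maps_a) == nrow(maps_b))
  n <- ncol(maps_a)
  if (n < 4) stop("need at least 4 subjects")
  if (is.null(include)) include <- rep(TRUE, nrow(maps_a))
  V <- nrow(maps_a)
  row_r <- function(A, B) {
    A <- A - rowMeans(A); B <- B - rowMeans(B)
    sa <- rowSums(A^2); sb <- rowSums(B^2)
    r <- rowSums(A * B) / sqrt(sa * sb)
    r[sa == 0 | sb == 0] <- NA_real_
    r
  }
  r <- rep(NA_real_, V)
  r[include] <- row_r(maps_a[include, , drop = FALSE],
                      maps_b[include, , drop = FALSE])
  t <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- NULL
  if (n_perm > 0) {
    set.seed(seed)
    cnt <- rep(0L, V)
    robs <- abs(r)
    Ai <- maps_a[include, , drop = FALSE]
    for (b in seq_len(n_perm)) {
      perm <- sample.int(n)
      rp <- abs(row_r(Ai, maps_b[include, perm, drop = FALSE]))
      cnt[include] <- cnt[include] + (!is.na(rp) & rp >= robs[include])
    }
    p <- rep(NA_real_, V)
    p[include] <- (1 + cnt[include]) / (n_perm + 1)
  }
  flagged <- which(include & is.na(r))
  list(r = r, t = t, p = p, n = n, rank_m = 2L, constant_vertices = flagged)
}

#' Select the optimal early time-frame window
#'
#' For each cortical vertex, finds the candidate window with the highest
#' inter-subject correlation with FDG and the one with the lowest
#' inter-subject correlation with the late-phase acquisition, and
#' accumulates vertex areas per window (ties split equally).  The selected
#' window maximizes the FDG-criterion area among the candidates whose
#' late-phase-criterion area is within `tolerance` of the best, mirroring
#' the joint rule "maximize correlation with FDG while minimizing
#' correlation with the late phase".
#'
#' @param candidates list of [frame_window()]s (>= 1)
#' @param r_fdg,r_late V x k matrices of per-vertex inter-subject r for each
#'   candidate (columns follow `candidates`)
#' @param area per-vertex areas (mm^2)
#' @param include logical vertex mask
#' @param tolerance admissible shortfall (area-fraction units) on the
#'   late-phase criterion
#' @param late_criterion `"signed"` picks the per-vertex minimum signed r
#'   (the literal reading of "lowest correlation"); `"absolute"` minimizes
#'   |r|
#' @return a `window_selection` list: `selected`, per-window
#'   `fdg_area_fraction` and `late_area_fraction`, `candidates`, `tie`
#' @export
select_optimal_window <- function(candidates, r_fdg, r_late, area,
                                  include = NULL, tolerance = 0.1,
                                  late_criterion = c("signed", "absolute")) {
  late_criterion <- match.arg(late_criterion)
  k <- length(candidates)
  stopifnot(k >= 1, ncol(r_fdg) == k, ncol(r_late) == k)
  if (is.null(include)) include <- rep(TRUE, nrow(r_fdg))
  idx <- which(include & rowSums(is.na(r_fdg)) == 0 & rowSums(is.na(r_late)) == 0)
  a <- area[idx]
  tot <- sum(a)
  share <- function(values, best_fun) {
    fr <- numeric(k)
    best <- apply(values, 1, best_fun)
    for (v in seq_along(idx)) {
      win <- which(abs(values[v, ] - best[v]) < 1e-12)
      fr[win] <- fr[win] + a[v] / length(win)
    }
    fr / tot
  }
  fdg_fr <- share(r_fdg[idx, , drop = FALSE], max)
  lv <- r_late[idx, , drop = FALSE]
  if (late_criterion == "absolute") lv <- abs(lv)
  late_fr <- share(lv, min)
  ok <- late_fr >= max(late_fr) - tolerance
  pool <- which(ok)
  best_fdg <- max(fdg_fr[pool])
  winners <- pool[abs(fdg_fr[pool] - best_fdg) < 1e-12]
  tie <- length(winners) > 1
  if (tie) warning("tied optimal windows; selecting the lexicographically earliest")
  sel <- winners[1]
  nm <- vapply(candidates, format, character(1))
  structure(list(selected = candidates[[sel]],
                 selected_name = nm[sel],
                 fdg_area_fraction = stats::setNames(fdg_fr, nm),
                 late_area_fraction = stats::setNames(late_fr, nm),
                 candidates = candidates, tolerance = tolerance,
                 tie = tie),
            class = "window_selection")
}
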