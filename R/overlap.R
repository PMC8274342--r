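# Permutation GLM with nuisance covariates, threshold-free cluster
# enhancement on the mesh, max-statistic FWE correction, and
# balanced-accuracy pattern overlap swept over a grid of thresholds.

#' TFCE parameters
#'
#' @param extent_exp,height_exp TFCE exponents E and H; defaults E = 1,
#'   H = 2 (the standard surface recommendation)
#' @param dh height step; `NULL` means 1/100 of the map maximum
#' @return a `tfce_params` list
#' @export
tfce_params <- function(extent_exp = 1, height_exp = 2, dh = NULL) {
  stopifnot(extent_exp >= 0, height_exp >= 0, is.null(dh) || dh > 0)
  structure(list(E = extent_exp, H = height_exp, dh = dh),
            class = "tfce_params")
}

#' Threshold-free cluster enhancement of a statistic map on a mesh
#'
#' `TFCE(v) = sum_h (area of the suprathreshold component containing v)^E
#' * h^H * dh`, with components defined by mesh edge connectivity
#' restricted to the included vertices and extent measured in vertex area
#' (mm^2).  Only positive statistic values contribute (one-sided
#' contrasts); `NA` values are treated as never suprathreshold.
#'
#' @param stat per-vertex statistic
#' @param mesh a `pet_mesh`
#' @param params a [tfce_params()]
#' @param include logical vertex mask (default `mesh$cortex`)
#' @return per-vertex TFCE map (0 outside `include`)
#' @export
tfce_transform <- function(stat, mesh, params = tfce_params(),
                           include = NULL) {
  if (is.null(include)) include <- if (!is.null(mesh$cortex)) mesh$cortex else
    rep(TRUE, n_vertices(mesh))
  s <- stat
  s[!include] <- 0
  s[is.na(s)] <- 0
  mx <- max(s)
  if (mx <= 0) return(numeric(length(s)))
  dh <- if (is.null(params$dh)) mx / 100 else params$dh
  keep <- include[mesh$edges[, 1]] & include[mesh$edges[, 2]]
  e <- mesh$edges[keep, , drop = FALSE]
  .tfce_cpp(s, as.integer(e[, 1] - 1), as.integer(e[, 2] - 1),
            mesh$area, dh, params$E, params$H)
}

# OLS t statistics for the first column of design M, for every column of Y.
# Returns list(t, df); vertices with zero residual variance get NA.
glm_t <- function(Y, M) {
  n <- nrow(M); p <- qr(M)$rank
  if (p < ncol(M)) stop("rank-deficient design")
  MtM <- crossprod(M)
  MtMi <- solve(MtM)
  Cmat <- crossprod(M, Y)            # p x V
  B <- MtMi %*% Cmat
  yss <- colSums(Y^2)
  rss <- pmax(yss - colSums(Cmat * B), 0)
  zero_var <- rss <= 1e-12 * (yss + 1e-300)
  sigma2 <- rss / (n - p)
  se <- sqrt(sigma2 * MtMi[1, 1])
  t <- as.numeric(B[1, ]) / se
  t[zero_var | se == 0 | !is.finite(t)] <- NA_real_
  list(t = t, df = n - p)
}

#' Permutation GLM with TFCE and max-statistic FWE correction
#'
#' Fits, at every included vertex, the model `y ~ x + nuisance` and tests
#' the coefficient of `x` one-sided (positive) after TFCE enhancement.
#' Inference uses Freedman-Lane permutation: responses are residualized
#' against the nuisance covariates, residual rows are permuted, the full
#' model is refitted, and the familywise-corrected p-value at vertex v is
#' `(1 + #\{permutation max TFCE >= TFCE(v)\}) / (P + 1)`.
#'
#' @param response subjects x vertices matrix of maps
#' @param x predictor of interest (length N); e.g. a group indicator coded
#'   so that positive effects are the tested direction, or a cognition
#'   score
#' @param nuisance N x q matrix/data frame of nuisance covariates (sex,
#'   age, education); an intercept is always added
#' @param mesh a `pet_mesh`
#' @param n_perm number of permutations
#' @param seed permutation seed
#' @param tfce a [tfce_params()]
#' @param include logical vertex mask (default `mesh$cortex`)
#' @return list: per-vertex `t`, `tfce`, `p_fwe` (NA outside `include`),
#'   `max_dist` (permutation distribution of the map-wide max TFCE), `df`
#' @export
permutation_glm_tfce <- function(response, x, nuisance = NULL, mesh,
                                 n_perm = 1000, seed = 1,
                                 tfce = tfce_params(), include = NULL) {
  if (is.null(include)) include <- if (!is.null(mesh$cortex)) mesh$cortex else
    rep(TRUE, n_vertices(mesh))
  n <- nrow(response)
  Z <- cbind(intercept = rep(1, n),
             if (!is.null(nuisance)) as.matrix(nuisance))
  storage.mode(Z) <- "double"
  M <- cbind(x = x, Z)
  qrM <- qr(M)
  if (qrM$rank < ncol(M)) {
    cc <- colnames(M)[qrM$pivot[(qrM$rank + 1):ncol(M)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(cc, collapse = ", "))
  }
  Yi <- response[, include, drop = FALSE]
  obs <- glm_t(Yi, M)
  tmap <- rep(NA_real_, n_vertices(mesh))
  tmap[include] <- obs$t
  # fix dh from the observed map so permutation maxima are comparable
  if (is.null(tfce$dh)) {
    mx <- suppressWarnings(max(tmap[include], na.rm = TRUE))
    tfce$dh <- if (is.finite(mx) && mx > 0) mx / 100 else 1
  }
  tf <- tfce_transform(tmap, mesh, tfce, include)

  # Freedman-Lane: permute nuisance-only residual rows
  Rz <- diag(n) - Z %*% solve(crossprod(Z), t(Z))
  E <- Rz %*% Yi
  set.seed(seed)
  max_dist <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    perm <- sample.int(n)
    tp <- glm_t(E[perm, , drop = FALSE], M)$t
    tpm <- rep(NA_real_, n_vertices(mesh))
    tpm[include] <- tp
    max_dist[b] <- max(tfce_transform(tpm, mesh, tfce, include), 0)
  }
  p <- rep(NA_real_, n_vertices(mesh))
  vi <- which(include)
  p[vi] <- vapply(tf[vi], function(v)
    (1 + sum(max_dist >= v)) / (n_perm + 1), numeric(1))
  p[vi][is.na(tmap[vi])] <- NA_real_
  list(t = tmap, tfce = tf, p_fwe = p, max_dist = max_dist, df = obs$df)
}

#' Balanced-accuracy overlap of two binarized significance patterns
#'
#' Binarizes both familywise-corrected p-maps at `p < threshold` and scores
#' the predicted pattern against the true pattern over the included
#' vertices: `BACC = (sensitivity + specificity) / 2`.
#'
#' @param p_true,p_pred per-vertex FWE-corrected p-values (true pattern:
#'   e.g. FDG; predicted: e.g. the early-phase surrogate)
#' @param threshold significance threshold
#' @param include logical vertex mask
#' @return an `overlap_result` list: threshold, TP/FP/TN/FN, sensitivity,
#'   specificity, `bacc`; when the true pattern is empty the result carries
#'   `NA`s and `reason = "empty true pattern"`
#' @export
pattern_overlap <- function(p_true, p_pred, threshold, include = NULL) {
  if (is.null(include)) include <- !is.na(p_true) & !is.na(p_pred)
  idx <- which(include & !is.na(p_true) & !is.na(p_pred))
  tr <- p_true[idx] < threshold
  pr <- p_pred[idx] < threshold
  tp <- sum(tr & pr); fn <- sum(tr & !pr)
  fp <- sum(!tr & pr); tn <- sum(!tr & !pr)
  if (tp + fn == 0)
    return(structure(list(threshold = threshold, tp = tp, fp = fp, tn = tn,
                          fn = fn, sensitivity = NA_real_,
                          specificity = NA_real_, bacc = NA_real_,
                          reason = "empty true pattern"),
                     class = "overlap_result"))
  sens <- tp / (tp + fn)
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  structure(list(threshold = threshold, tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = sens, specificity = spec,
                 bacc = mean(c(sens, spec))),
            class = "overlap_result")
}

#' The standard sweep of 91 FWE thresholds
#'
#' @param from,to,n endpoints (inclusive) and count; defaults give 91
#'   p-values evenly spaced from 0.05 down to 0.001
#' @return strictly decreasing numeric vector
#' @export
threshold_sweep <- function(from = 0.05, to = 0.001, n = 91) {
  stopifnot(from > to, n >= 2)
  seq(from, to, length.out = n)
}

#' Sweep BACC over thresholds and rank reference regions
#'
#' For each reference region, computes the balanced accuracy of the
#' predicted pattern against the true pattern at every threshold of the
#' sweep, then runs a Friedman/Nemenyi ranking with thresholds as blocks
#' (higher BACC better).  Thresholds at which any region's true pattern is
#' empty are excluded with a warning.
#'
#' @param p_true_list,p_pred_list named lists (one entry per reference
#'   region) of FWE-corrected p-maps
#' @param thresholds from [threshold_sweep()]
#' @param include logical vertex mask
#' @return list: `bacc` (threshold x region matrix), `ranking` (a
#'   `ranking_result`), `excluded_thresholds`
#' @export
sweep_and_rank <- function(p_true_list, p_pred_list,
                           thresholds = threshold_sweep(), include = NULL) {
  stopifnot(length(p_true_list) >= 2,
            identical(names(p_true_list), names(p_pred_list)))
  regions <- names(p_true_list)
  bacc <- matrix(NA_real_, length(thresholds), length(regions),
                 dimnames = list(NULL, regions))
  for (j in seq_along(regions)) {
    for (i in seq_along(thresholds)) {
      ov <- pattern_overlap(p_true_list[[j]], p_pred_list[[j]],
                            thresholds[i], include)
      bacc[i, j] <- ov$bacc
    }
  }
  bad <- rowSums(is.na(bacc)) > 0
  if (any(bad))
    warning(sum(bad), " threshold(s) excluded (empty true pattern)")
  if (sum(!bad) < 2) stop("fewer than 2 usable thresholds in the sweep")
  ranking <- friedman_rank(bacc[!bad, , drop = FALSE], direction = "higher")
  list(bacc = bacc, ranking = ranking,
       excluded_thresholds = thresholds[bad])
}
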