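#' Singular spectrum embedding
#'
#' Embeds a series of length N into its L x K trajectory (Hankel) matrix,
#' `K = N - L + 1`, with `X[i, j] = x[i + j - 1]`, and computes its SVD.
#' The squared singular values partition the trajectory energy
#' (`sum(d^2) = ||X||_F^2`).
#'
#' @param values Numeric series (finite).
#' @param L Window length, `2 <= L <= N - 1`.
#' @return A list of class `ssa_model`: `series`, `N`, `L`, `K`, `d`
#'   (singular values, non-increasing), `U` (L x r), `V` (K x r).
#' @export
ssa_embed <- function(values, L) {
  N <- length(values)
  L <- as.integer(L)
  if (any(!is.finite(values))) stop("series must be finite")
  if (L < 2L || L > N - 1L) {
    stop("window length L must satisfy 2 <= L <= N - 1 (N = ", N, ")")
  }
  K <- N - L + 1L
  X <- outer(seq_len(L), seq_len(K), function(i, j) values[i + j - 1L])
  sv <- svd(X)
  structure(list(series = values, N = N, L = L, K = K,
                 d = sv$d, U = sv$u, V = sv$v),
            class = "ssa_model")
}

#' Reconstruct a series from selected eigentriples
#'
#' Sums the chosen rank-1 matrices `d_i u_i v_i'` and maps the result back
#' to a length-N series by anti-diagonal (Hankel) averaging. Computed via
#' the convolution identity: the anti-diagonal sums of `u v'` are the
#' polynomial convolution of `u` and `v`.
#'
#' @param model An [ssa_embed()] result.
#' @param components Integer indices of eigentriples (empty: zero series).
#' @return Numeric series of length `model$N`.
#' @export
ssa_reconstruct <- function(model, components) {
  stopifnot(inherits(model, "ssa_model"))
  N <- model$N
  if (!length(components)) return(numeric(N))
  components <- as.integer(components)
  if (any(components < 1L | components > length(model$d))) {
    stop("component indices out of range")
  }
  counts <- pmin(seq_len(N), model$L, model$K, N - seq_len(N) + 1L)
  acc <- numeric(N)
  for (i in components) {
    acc <- acc + model$d[i] *
      convolve(model$U[, i], rev(model$V[, i]), type = "open")
  }
  acc / counts
}

#' Two-stage singular spectrum decomposition of a weekly series
#'
#' Stage 1 runs a basic SSA with window `L1` (default 52, one year of
#' weeks) and extracts the dominant trend as the reconstruction of the
#' leading eigentriple group. Stage 2 re-embeds the stage-1 residual with
#' the maximal window `L = floor(N/2)` and reports the top `k` oscillatory
#' components `F1..Fk` ordered by singular value. The headline
#' reconstruction is `trend + F1 + F2`. Variance shares are squared
#' singular values over their stage's total (`share_method = "singular"`),
#' or ratios of reconstructed-series variances (`"variance"`).
#'
#' @param values Weekly series, length at least `2 * L1`.
#' @param L1 Stage-1 window (default 52).
#' @param k Number of stage-2 components to report (default 25).
#' @param trend_components Eigentriple indices forming the trend group
#'   (default 1).
#' @param share_method `"singular"` or `"variance"`.
#' @return A list of class `ssa_decomposition`: `trend`, `residual1`,
#'   `components` (N x k matrix, columns `F1..Fk`), `remainder`
#'   (stage-1 residual minus the k components), `reconstruction`
#'   (trend + F1 + F2), `variance_shares` (`data.table`: component,
#'   share; `"trend"` is the stage-1 trend share), `L1`, `L2`,
#'   `stage1`, `stage2` (the two `ssa_model`s).
#' @export
two_stage_ssa <- function(values, L1 = 52L, k = 25L,
                          trend_components = 1L,
                          share_method = c("singular", "variance")) {
  share_method <- match.arg(share_method)
  N <- length(values)
  if (N < 2L * L1) {
    stop("series too short for two-stage SSA: need at least ", 2L * L1,
         " points (got ", N, ")")
  }
  stage1 <- ssa_embed(values, L1)
  trend <- ssa_reconstruct(stage1, trend_components)
  residual1 <- values - trend

  L2 <- N %/% 2L
  stage2 <- ssa_embed(residual1, L2)
  k <- min(as.integer(k), length(stage2$d))
  comp <- vapply(seq_len(k), function(i) ssa_reconstruct(stage2, i),
                 numeric(N))
  colnames(comp) <- paste0("F", seq_len(k))
  remainder <- residual1 - rowSums(comp)

  if (share_method == "singular") {
    tot1 <- sum(stage1$d^2)
    trend_share <- if (tot1 > 0) {
      sum(stage1$d[trend_components]^2) / tot1
    } else 0
    tot2 <- sum(stage2$d^2)
    comp_share <- if (tot2 > 0) stage2$d[seq_len(k)]^2 / tot2 else
      rep(0, k)
  } else {
    v0 <- var(values)
    trend_share <- if (v0 > 0) var(trend) / v0 else 0
    v1 <- var(residual1)
    comp_share <- if (v1 > 0) apply(comp, 2L, var) / v1 else rep(0, k)
  }
  shares <- data.table(component = c("trend", colnames(comp)),
                       share = c(trend_share, comp_share))

  reconstruction <- trend +
    (if (k >= 1L) comp[, 1L] else 0) + (if (k >= 2L) comp[, 2L] else 0)

  structure(list(trend = trend, residual1 = residual1, components = comp,
                 remainder = remainder, reconstruction = reconstruction,
                 variance_shares = shares, L1 = as.integer(L1), L2 = L2,
                 trend_components = as.integer(trend_components),
                 share_method = share_method,
                 stage1 = stage1, stage2 = stage2),
            class = "ssa_decomposition")
}

#' Mann-Kendall trend test
#'
#' Non-parametric monotone-trend test on the pairwise sign statistic
#' `S = sum_{i<j} sign(x_j - x_i)`, with the tie-corrected variance
#' `var(S) = [n(n-1)(2n+5) - sum_t t(t-1)(2t+5)] / 18` (sum over tie-group
#' sizes t), continuity-corrected normal statistic
#' `z = (S -/+ 1)/sqrt(var(S))` (0 when S = 0) and two-sided p-value.
#'
#' @param values Numeric series, length >= 4.
#' @param alpha Significance level for the reported direction
#'   (default 0.05).
#' @return A list of class `mann_kendall`: `S`, `var_S`, `z`, `p`,
#'   `direction` (`"increasing"`, `"decreasing"` or `"none"`), `n`.
#' @export
#' @examples
#' mann_kendall(1:10)$S  # 45 = 10*9/2, all pairs increasing
mann_kendall <- function(values, alpha = 0.05) {
  n <- length(values)
  if (n < 4L) stop("Mann-Kendall test needs at least 4 observations")
  if (any(!is.finite(values))) stop("series must be finite")
  sgn <- sign(outer(values, values, "-"))  # sgn[j, i] = sign(x_j - x_i)
  S <- sum(sgn[lower.tri(sgn)])
  ties <- table(values)
  ties <- ties[ties > 1L]
  var_S <- (n * (n - 1) * (2 * n + 5) -
              sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  z <- if (S == 0 || var_S == 0) 0 else (S - sign(S)) / sqrt(var_S)
  p <- if (var_S == 0) 1 else min(1, 2 * pnorm(-abs(z)))
  direction <- if (p < alpha && S > 0) "increasing" else
    if (p < alpha && S < 0) "decreasing" else "none"
  structure(list(S = S, var_S = var_S, z = z, p = p,
                 direction = direction, n = n),
            class = "mann_kendall")
}
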