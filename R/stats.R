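# Statistical stage: method error, paired side comparison, correlation
# tables, principal components with varimax rotation, and paired-design
# noncentral-t power / sample-size analysis.

#' Dahlberg method error
#'
#' Method error for duplicate measurements:
#' `sqrt( sum( (first - second)^2 ) / (2 n) )`, in the units of the input.
#'
#' @param first,second numeric vectors of paired repeated measurements.
#' @return method error (scalar).
#' @export
dahlberg_error <- function(first, second) {
  if (length(first) != length(second))
    aj_stop("length_mismatch", "repeated measurement vectors differ in length")
  if (length(first) < 2) aj_stop("length_mismatch", "need at least 2 pairs")
  d <- first - second
  sqrt(sum(d^2) / (2 * length(d)))
}

#' Paired deviated- vs non-deviated-side comparison
#'
#' For each variable, reports per-side mean and SD, the Shapiro-Wilk
#' normality p-value on the paired differences (reported, not gating), and
#' the paired t statistic with its two-sided p-value.
#'
#' @param cohort a cohort table as returned by [cohort_table()]: a data frame
#'   with columns `<var>_DS` and `<var>_NDS`.
#' @param variables character vector of variable names; default: every
#'   variable with a complete DS/NDS pair.
#' @return data frame with one row per variable: `variable`, `mean_DS`,
#'   `sd_DS`, `mean_NDS`, `sd_NDS`, `t`, `df`, `p`, `normality_p`.
#' @export
paired_compare <- function(cohort, variables = NULL) {
  if (is.null(variables)) variables <- cohort_variables(cohort)
  rows <- lapply(variables, function(v) {
    x <- cohort[[paste0(v, "_DS")]]
    y <- cohort[[paste0(v, "_NDS")]]
    if (is.null(x) || is.null(y))
      aj_stop("schema_error", sprintf("variable '%s' lacks a DS/NDS pair", v))
    d <- x - y
    if (stats::sd(d) < 1e-12) {
      # identical columns: no evidence of a difference (t = 0, p = 1);
      # a constant nonzero difference has no estimable variance
      if (max(abs(d)) > 1e-12)
        aj_stop("degenerate_variance",
                sprintf("differences for '%s' are constant", v))
      tt <- list(statistic = 0, parameter = length(d) - 1, p.value = 1)
    } else {
      tt <- stats::t.test(x, y, paired = TRUE)
    }
    sw <- tryCatch(stats::shapiro.test(d)$p.value, error = function(e) NA_real_)
    data.frame(variable = v,
               mean_DS = mean(x), sd_DS = stats::sd(x),
               mean_NDS = mean(y), sd_NDS = stats::sd(y),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, normality_p = sw)
  })
  do.call(rbind, rows)
}

#' Pearson correlation table between two variable sets on one side
#'
#' @param cohort cohort table (see [paired_compare()]).
#' @param row_vars,col_vars character vectors of variable names.
#' @param side `"DS"` or `"NDS"`.
#' @return list with matrices `r` and `p` (rows = `row_vars`,
#'   cols = `col_vars`) and the sample size `n`.
#' @export
correlation_table <- function(cohort, row_vars, col_vars, side = c("DS", "NDS")) {
  side <- match.arg(side)
  get <- function(v) {
    x <- cohort[[paste0(v, "_", side)]]
    if (is.null(x)) aj_stop("schema_error", sprintf("no column for '%s' (%s)", v, side))
    if (stats::sd(x) < 1e-12)
      aj_stop("constant_column", sprintf("column '%s' (%s) is constant", v, side))
    x
  }
  r <- matrix(NA_real_, length(row_vars), length(col_vars),
              dimnames = list(row_vars, col_vars))
  p <- r
  for (i in seq_along(row_vars)) for (j in seq_along(col_vars)) {
    ct <- stats::cor.test(get(row_vars[i]), get(col_vars[j]), method = "pearson")
    r[i, j] <- unname(ct$estimate); p[i, j] <- ct$p.value
  }
  list(r = r, p = p, n = nrow(cohort))
}

#' Principal-component loadings of a standardized cohort submatrix
#'
#' Loadings are correlation-matrix eigenvectors scaled by the square root of
#' their eigenvalues; the first `k` components by descending eigenvalue are
#' returned. The number of eigenvalues above 1 is reported alongside, but the
#' component count is fixed (no automatic scree detection).
#'
#' @param X numeric matrix (subjects x variables).
#' @param k number of components to keep (default 4).
#' @return object of class `factor_model`: list with `loadings`
#'   (variables x k), `eigenvalues` (all), `k`, `n_eigen_gt1`, `rotation`
#'   (`"none"`), `kaiser_normalized` (FALSE).
#' @export
pca_loadings <- function(X, k = 4) {
  X <- as.matrix(X)
  if (any(apply(X, 2, stats::sd) < 1e-12))
    aj_stop("constant_column", "constant column in PCA input")
  R <- stats::cor(X)
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) < -1e-8)
    aj_stop("rank_deficient", "correlation matrix not positive semidefinite")
  k <- min(k, ncol(X))
  L <- e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(pmax(e$values[seq_len(k)], 0)), k)
  rownames(L) <- colnames(X)
  L <- fix_loading_signs(L)
  structure(list(loadings = L, eigenvalues = e$values, k = k,
                 n_eigen_gt1 = sum(e$values > 1),
                 rotation = "none", kaiser_normalized = FALSE),
            class = "factor_model")
}

# sign convention: each component's largest-magnitude loading is positive
fix_loading_signs <- function(L) {
  for (j in seq_len(ncol(L))) {
    s <- sign(L[which.max(abs(L[, j])), j])
    if (s < 0) L[, j] <- -L[, j]
  }
  L
}

#' Varimax criterion value
#'
#' `sum_j [ mean(L^4_.j) - mean(L^2_.j)^2 ]` over columns.
#'
#' @param L loading matrix.
#' @return criterion value.
#' @export
varimax_criterion <- function(L) {
  sum(apply(L, 2, function(l) mean(l^4) - mean(l^2)^2))
}

#' Varimax rotation with optional Kaiser normalization
#'
#' Classical pairwise (Jacobi) maximization of the varimax criterion. With
#' `kaiser_normalize = TRUE` rows are scaled to unit communality before
#' rotation and rescaled after. Communalities are preserved exactly
#' (orthogonal rotation) and asserted on every call.
#'
#' @param loadings variables x k loading matrix (or a `factor_model`).
#' @param kaiser_normalize logical, default TRUE.
#' @param tol convergence tolerance on the relative criterion increase.
#' @param max_iter maximum number of sweeps.
#' @return list with `loadings` (rotated, sign/order normalized), `rotmat`
#'   (orthogonal k x k), `criterion`, `iterations`.
#' @export
varimax_rotate <- function(loadings, kaiser_normalize = TRUE,
                           tol = 1e-8, max_iter = 1000) {
  L0 <- if (inherits(loadings, "factor_model")) loadings$loadings else as.matrix(loadings)
  k <- ncol(L0)
  h <- sqrt(rowSums(L0^2))
  if (kaiser_normalize && any(h < 1e-12))
    aj_stop("degenerate_geometry", "zero-communality row with Kaiser normalization")
  W <- if (kaiser_normalize) L0 / h else L0
  p <- nrow(W)
  Rot <- diag(k)
  if (k >= 2) {
    crit_old <- varimax_criterion(W)
    it <- 0
    repeat {
      it <- it + 1
      for (a in seq_len(k - 1)) for (b in (a + 1):k) {
        x <- W[, a]; y <- W[, b]
        u <- x^2 - y^2; v <- 2 * x * y
        A <- sum(u); B <- sum(v)
        C <- sum(u^2 - v^2); D <- sum(2 * u * v)
        num <- D - 2 * A * B / p
        den <- C - (A^2 - B^2) / p
        phi <- atan2(num, den) / 4
        if (abs(phi) > 1e-14) {
          cs <- cos(phi); sn <- sin(phi)
          W[, a] <- cs * x + sn * y
          W[, b] <- -sn * x + cs * y
          G <- diag(k); G[a, a] <- cs; G[b, b] <- cs; G[a, b] <- -sn; G[b, a] <- sn
          Rot <- Rot %*% G
        }
      }
      crit_new <- varimax_criterion(W)
      if (crit_new - crit_old <= tol * max(crit_old, 1e-12)) break
      crit_old <- crit_new
      if (it >= max_iter)
        aj_stop("non_convergence", "varimax did not converge")
    }
  }
  L <- if (kaiser_normalize) W * h else W
  # orthogonality => communalities preserved; assert on every call
  stopifnot(max(abs(rowSums(L^2) - rowSums(L0^2))) < 1e-9)
  # deterministic presentation: order by explained variance, fix signs
  ord <- order(colSums(L^2), decreasing = TRUE)
  L <- L[, ord, drop = FALSE]
  Rot <- Rot[, ord, drop = FALSE]
  sg <- vapply(seq_len(ncol(L)), function(j) {
    s <- sign(L[which.max(abs(L[, j])), j]); if (s == 0) 1 else s
  }, numeric(1))
  L <- sweep(L, 2, sg, `*`)
  Rot <- sweep(Rot, 2, sg, `*`)
  colnames(L) <- paste0("PC", seq_len(ncol(L)))
  list(loadings = L, rotmat = Rot,
       criterion = varimax_criterion(if (kaiser_normalize) L / h else L),
       iterations = if (k >= 2) it else 0L)
}

#' Factor analysis of a cohort side (PCA + varimax)
#'
#' @param cohort cohort table.
#' @param variables variables to include.
#' @param side `"DS"` or `"NDS"`.
#' @param k number of components (default 4).
#' @param kaiser_normalize logical, default TRUE.
#' @return `factor_model` with rotated loadings.
#' @export
factor_analysis <- function(cohort, variables, side = c("DS", "NDS"), k = 4,
                            kaiser_normalize = TRUE) {
  side <- match.arg(side)
  X <- sapply(variables, function(v) cohort[[paste0(v, "_", side)]])
  fm <- pca_loadings(scale(X), k = k)
  vr <- varimax_rotate(fm$loadings, kaiser_normalize = kaiser_normalize)
  fm$loadings <- vr$loadings
  fm$rotation <- "varimax"
  fm$kaiser_normalized <- kaiser_normalize
  fm$rotmat <- vr$rotmat
  fm
}

#' Power of the paired t-test (noncentral t)
#'
#' Two-sided paired-design power:
#' `P(|T'| > t_{1-alpha/2, n-1})` where `T'` is noncentral t with `n - 1`
#' degrees of freedom and noncentrality `dz * sqrt(n)`; both tails included.
#'
#' @param dz paired effect size (mean of differences / SD of differences).
#' @param n number of pairs (>= 2).
#' @param alpha two-sided significance level (default 0.05).
#' @return power in (0, 1).
#' @export
power_paired_t <- function(dz, n, alpha = 0.05) {
  if (any(n < 2)) aj_stop("invalid_spec", "need n >= 2")
  df <- n - 1
  tc <- stats::qt(1 - alpha / 2, df)
  ncp <- dz * sqrt(n)
  stats::pt(-tc, df, ncp) + 1 - stats::pt(tc, df, ncp)
}

#' Minimal paired sample size for target power
#'
#' Smallest `n >= 2` with `power_paired_t(dz, n) >= target_power`, by exact
#' unit-increment search.
#'
#' @param dz paired effect size (> 0).
#' @param target_power target power (default 0.80).
#' @param alpha two-sided significance level (default 0.05).
#' @return integer sample size.
#' @export
min_n_paired_t <- function(dz, target_power = 0.80, alpha = 0.05) {
  if (dz <= 0) aj_stop("invalid_spec", "effect size must be positive")
  n <- 2L
  while (power_paired_t(dz, n, alpha) < target_power) {
    n <- n + 1L
    if (n > 1e6) aj_stop("invalid_spec", "sample size search did not terminate")
  }
  n
}
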