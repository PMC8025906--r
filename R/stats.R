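# Statistical screening of formulation attributes against predicted
# performance: Pearson correlation matrices and two-way ANOVA without
# replication. Raw correlation coefficients are reported as a screening
# heatmap; no multiple-testing correction is applied.

#' Pearson correlation matrix between property and outcome tables
#'
#' Product-moment correlation for every (property, outcome) column pair over
#' matched rows (materials). Constant columns give an undefined correlation
#' and are reported as `NA`, never as zero; pairs with fewer than three
#' complete observations are likewise `NA`.
#'
#' @param props Data frame of material properties (rows = materials).
#' @param outcomes Data frame of performance/PK outcomes, same row set.
#' @return Matrix of r values, properties in rows, outcomes in columns.
#' @export
pearson_matrix <- function(props, outcomes) {
  stopifnot(nrow(props) == nrow(outcomes))
  p <- as.matrix(props[vapply(props, is.numeric, logical(1))])
  o <- as.matrix(outcomes[vapply(outcomes, is.numeric, logical(1))])
  out <- matrix(NA_real_, ncol(p), ncol(o),
                dimnames = list(colnames(p), colnames(o)))
  for (i in seq_len(ncol(p))) for (j in seq_len(ncol(o))) {
    x <- p[, i]; y <- o[, j]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) >= 3L && stats::sd(x[ok]) > 0 && stats::sd(y[ok]) > 0)
      out[i, j] <- stats::cor(x[ok], y[ok])
  }
  out
}

#' Two-way ANOVA without replication
#'
#' Decomposes a complete rows x columns matrix of single observations into
#' row, column and residual sums of squares and tests each factor against the
#' residual mean square.
#'
#' @param m Numeric matrix (>= 2 rows, >= 2 columns, no missing cells).
#' @return List with `F_rows`, `p_rows`, `F_cols`, `p_cols`, the `ss` vector
#'   (rows, cols, residual, total) and the degrees of freedom.
#' @export
anova_two_way_noreplication <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2L || ncol(m) < 2L) stop("need at least a 2 x 2 matrix")
  if (any(!is.finite(m))) stop("no missing cells allowed")
  r <- nrow(m); c <- ncol(m)
  grand <- mean(m)
  ss_rows <- c * sum((rowMeans(m) - grand)^2)
  ss_cols <- r * sum((colMeans(m) - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_res <- ss_tot - ss_rows - ss_cols
  df_rows <- r - 1L; df_cols <- c - 1L; df_res <- df_rows * df_cols
  ms_res <- ss_res / df_res
  eps <- .Machine$double.eps * max(1, ss_tot)
  degenerate <- ms_res <= eps
  if (degenerate)
    warning("zero residual sum of squares: F is unbounded for any factor ",
            "with nonzero sum of squares")
  fstat <- function(ss_fac, df_fac) {
    if (!degenerate) return((ss_fac / df_fac) / ms_res)
    if (ss_fac <= eps) 0 else Inf   # 0/0 resolved in favour of the null
  }
  F_rows <- fstat(ss_rows, df_rows)
  F_cols <- fstat(ss_cols, df_cols)
  list(F_rows = F_rows,
       p_rows = stats::pf(F_rows, df_rows, df_res, lower.tail = FALSE),
       F_cols = F_cols,
       p_cols = stats::pf(F_cols, df_cols, df_res, lower.tail = FALSE),
       ss = c(rows = ss_rows, cols = ss_cols, residual = ss_res, total = ss_tot),
       df = c(rows = df_rows, cols = df_cols, residual = df_res))
}
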