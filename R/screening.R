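#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation; the p-value comes from the t transform
#' `t = r * sqrt(df) / sqrt(1 - r^2)` with the conventional `df = n - 2`.
#'
#' @param x,y Numeric vectors of equal length >= 3, non-constant.
#' @return List with `r`, `p`, `n`, `df`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input; correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
       df = unname(ct$parameter))
}

#' Critical correlation coefficient for a two-sided test
#'
#' `r_crit = t_crit / sqrt(t_crit^2 + df)` with `t_crit` the two-sided
#' `alpha` critical value of Student's t with `df` degrees of freedom --
#' the smallest |r| reaching significance at level `alpha` for that df.
#' At `alpha = 0.05, df = 50` this evaluates to 0.273 (3 d.p.); with the
#' conventional `df = n - 2 = 48` for a 50-subject cohort it is 0.279.
#'
#' @param alpha Two-sided significance level in (0, 1).
#' @param df Degrees of freedom (>= 1).
#' @return The critical |r| in (0, 1).
#' @export
critical_r <- function(alpha = 0.05, df = 50) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  if (df < 1) stop("df must be >= 1")
  t_crit <- stats::qt(1 - alpha / 2, df)
  t_crit / sqrt(t_crit^2 + df)
}

#' Screen network properties against adaptability scores
#'
#' Correlates every network-property column with every adaptability-method
#' column across subjects, and flags property-method cells significant
#' under the conjunctive rule `p < alpha` AND `|r| > r_min`. Negative
#' correlations are eligible (the absolute value is compared to `r_min`).
#' No multiple-testing correction is applied by default; set `fdr = TRUE`
#' to append Benjamini-Hochberg adjusted p-values as an extension column.
#'
#' @param properties subjects x properties numeric matrix / data.frame.
#' @param scores subjects x methods numeric matrix / data.frame (same row
#'   order as `properties`).
#' @param alpha Significance level (default 0.05).
#' @param r_min Minimum |r| (default 0.273, the df = 50 critical value).
#' @param fdr Append BH-adjusted p-values? Default `FALSE`.
#' @return `data.frame` of class `correlation_table` with columns
#'   `property`, `method`, `r`, `p`, `significant` (and `p_fdr` if
#'   requested).
#' @export
screen <- function(properties, scores, alpha = 0.05, r_min = 0.273,
                   fdr = FALSE) {
  properties <- as.matrix(properties)
  scores <- as.matrix(scores)
  if (nrow(properties) != nrow(scores))
    stop("properties and scores must cover the same subjects (",
         nrow(properties), " vs ", nrow(scores), " rows)")
  if (is.null(colnames(properties)))
    colnames(properties) <- paste0("prop", seq_len(ncol(properties)))
  if (is.null(colnames(scores)))
    colnames(scores) <- paste0("method", seq_len(ncol(scores)))
  grid <- expand.grid(property = colnames(properties),
                      method = colnames(scores),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res <- t(apply(grid, 1, function(gr) {
    ct <- pearson_cor(properties[, gr[["property"]]], scores[, gr[["method"]]])
    c(r = ct$r, p = ct$p)
  }))
  out <- cbind(grid, as.data.frame(res))
  out$significant <- out$p < alpha & abs(out$r) > r_min
  if (fdr) out$p_fdr <- stats::p.adjust(out$p, method = "BH")
  class(out) <- c("correlation_table", class(out))
  attr(out, "alpha") <- alpha
  attr(out, "r_min") <- r_min
  out
}

#' Reshape a correlation table into the wide tables-style layout
#'
#' One row per property, one (p, r) column pair per method, significant
#' cells starred.
#'
#' @param tab A [screen()] result.
#' @return Wide `data.frame` with character columns `p_<method>`,
#'   `r_<method>`.
#' @export
correlation_table_wide <- function(tab) {
  props <- unique(tab$property)
  methods <- unique(tab$method)
  out <- data.frame(property = props, stringsAsFactors = FALSE)
  for (m in methods) {
    sub <- tab[tab$method == m, ]
    sub <- sub[match(props, sub$property), ]
    star <- ifelse(sub$significant, " *", "")
    out[[paste0("p_", m)]] <- paste0(sprintf("%.3f", sub$p), star)
    out[[paste0("r_", m)]] <- paste0(sprintf("%.3f", sub$r), star)
  }
  out
}
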