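## Antioxidant-panel statistics: enzyme PCA, Student's t-tests on PC1,
## MDA and GSH/GSSG comparisons.

#' Reduced-to-oxidised glutathione ratio
#'
#' GSH/GSSG: higher values indicate better non-enzymatic antioxidant
#' capacity.
#'
#' @param gsh,gssg Concentrations (same units); `gssg` must be > 0.
#' @return The ratio (vectorised).
#' @export
gsh_ratio <- function(gsh, gssg) {
  if (any(gssg <= 0)) stop("GSSG must be > 0", call. = FALSE)
  gsh / gssg
}

#' Two-tailed Student's t-test (pooled variance)
#'
#' The classical equal-variance form, implemented directly:
#' `t = (mean(x) - mean(y)) / sqrt(sp2 (1/n1 + 1/n2))` with the pooled
#' variance `sp2` and `df = n1 + n2 - 2`.
#'
#' @param x,y Numeric samples, each of length >= 2.
#' @return List with `t`, `df`, `p` (two-tailed).
#' @export
ttest_student <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("each sample needs >= 2 values", call. = FALSE)
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  dm <- mean(x) - mean(y)
  if (sp2 == 0) {
    if (dm == 0) return(list(t = 0, df = n1 + n2 - 2L, p = 1))
    stop("zero pooled variance with unequal means: t undefined", call. = FALSE)
  }
  tval <- dm / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2L
  list(t = tval, df = df, p = 2 * stats::pt(abs(tval), df, lower.tail = FALSE))
}

#' Antioxidant-panel analysis
#'
#' PCA on the four enzyme activities (SOD, CAT, GR, GPx; centred and, by
#' default, unit-variance scaled since the assays are on heterogeneous
#' scales), followed by Student's t-tests comparing the groups on the PC1
#' scores, on MDA, and on the GSH/GSSG ratio.
#'
#' @param panel `data.frame` with columns `group` and `SOD`, `CAT`, `GR`,
#'   `GPx`, `MDA`, `GSH`, `GSSG` (see [gen_panel()]).
#' @param scale. Unit-variance scale the enzyme PCA.
#' @return List with `enzyme_pca` ([fit_pca()] model), `pc1_test`,
#'   `mda_test`, `ratio_test` (each a [ttest_student()] result), and
#'   `groups` (the two group labels in test order).
#' @export
analyze_panel <- function(panel, scale. = TRUE) {
  enz <- c("SOD", "CAT", "GR", "GPx")
  assert_columns(panel, c("group", enz, "MDA", "GSH", "GSSG"),
                 "antioxidant panel")
  groups <- sort(unique(panel$group))
  if (length(groups) != 2)
    stop("panel must contain exactly 2 groups", call. = FALSE)
  if (any(table(panel$group) < 2))
    stop("each group needs >= 2 individuals", call. = FALSE)
  pca <- fit_pca(as.matrix(panel[, enz]), center = TRUE, scale. = scale.)
  pc1 <- pca$scores[, 1]
  sel <- function(v, g) v[panel$group == g]
  ratio <- gsh_ratio(panel$GSH, panel$GSSG)
  list(enzyme_pca = pca,
       pc1_test = ttest_student(sel(pc1, groups[1]), sel(pc1, groups[2])),
       mda_test = ttest_student(sel(panel$MDA, groups[1]),
                                sel(panel$MDA, groups[2])),
       ratio_test = ttest_student(sel(ratio, groups[1]),
                                  sel(ratio, groups[2])),
       groups = groups)
}
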