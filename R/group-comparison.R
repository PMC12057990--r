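#' @include AllClasses.R
NULL

#' One-way ANOVA with Tukey HSD across individuals
#'
#' Compares per-individual isotope (or derived-elevation) values with a
#' one-way ANOVA and Tukey's honest-significant-difference post-hoc test
#' at alpha = 0.05, the standard inter-individual comparison for
#' intra-tooth series. Groups contributing a single value are excluded
#' with a warning (no within-group variance).
#'
#' @param values Numeric vector of observations, or a named list of
#'   numeric vectors (one element per individual).
#' @param groups Factor/character of group labels (ignored when `values`
#'   is a list).
#' @param alpha Significance threshold for flagging pairs (default 0.05).
#' @return List with `F` (statistic), `df` (length-2), `p`, `anova` (the
#'   aov summary table), `tukey` (data.frame of pairwise differences,
#'   adjusted p-values and a `significant` flag) and `excluded` (dropped
#'   group labels).
#' @export
#' @examples
#' compareGroups(list(a = c(1, 2, 3), b = c(4, 5, 6)))
compareGroups <- function(values, groups = NULL, alpha = 0.05) {
  if (is.list(values)) {
    groups <- rep(names(values), lengths(values))
    values <- unlist(values, use.names = FALSE)
  }
  stopifnot(length(values) == length(groups))
  groups <- as.character(groups)
  sizes <- table(groups)
  excluded <- names(sizes)[sizes < 2]
  if (length(excluded)) {
    warning("excluding group(s) with a single value: ",
            paste(excluded, collapse = ", "))
    keep <- !groups %in% excluded
    values <- values[keep]; groups <- groups[keep]
  }
  if (length(unique(groups)) < 2)
    stop("need at least 2 groups with >= 2 values each")
  dat <- data.frame(y = values, g = factor(groups))
  fit <- stats::aov(y ~ g, data = dat)
  tab <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
  tukey <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"],
                      significant = tk[, "p adj"] < alpha,
                      row.names = NULL)
  list(F = tab[1, "F value"],
       df = c(tab[1, "Df"], tab[2, "Df"]),
       p = tab[1, "Pr(>F)"],
       anova = tab, tukey = tukey, excluded = excluded)
}
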