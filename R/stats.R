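#' One-way ANOVA
#'
#' Standard between-groups sums-of-squares decomposition, reported as a
#' tidy one-row table. With two groups the F statistic equals the square of
#' the pooled two-sample t statistic.
#'
#' @param values Numeric response.
#' @param group Grouping factor (>= 2 levels, >= 2 observations each).
#' @return data.frame of class `anova_result`: `term`, `df1`, `df2`,
#'   `statistic` (F), `p`, `n`, `method`.
#' @export
one_way_anova <- function(values, group) {
  group <- factor(group)
  check_groups(values, group)
  fit <- stats::lm(values ~ group)
  a <- stats::anova(fit)
  structure(data.frame(
    term = "group", df1 = a$Df[1], df2 = a$Df[2],
    statistic = a$`F value`[1], p = a$`Pr(>F)`[1],
    n = length(values), method = "one_way_anova"
  ), class = c("anova_result", "data.frame"))
}

check_groups <- function(values, group) {
  stopifnot(length(values) == length(group))
  tab <- table(group)
  if (length(tab) < 2L) stop("at least two groups are required")
  if (any(tab < 2L)) stop("each group needs at least two observations")
  if (all(tapply(values, group, stats::var) == 0) &&
      stats::var(tapply(values, group, mean)) == 0)
    stop("degenerate data: zero variance everywhere")
  invisible(TRUE)
}

#' Two-way ANOVA, optionally with repeated measures
#'
#' Without repetition, fits `values ~ f1 * f2` and reports Type II sums of
#' squares by default (Type I/III selectable), which is well defined for
#' the unbalanced cell counts typical of by-cell physiological data. With
#' `repeated = TRUE`, `f1` is treated as the within-subject factor (e.g.
#' pre / early-post / late-post), `f2` as between-subjects, and the
#' balanced within-subject error partition is used; unbalanced
#' within-subject designs are rejected.
#'
#' @param values Numeric response.
#' @param f1,f2 Factors. For the repeated-measures variant `f1` is the
#'   within-subject factor.
#' @param repeated Use the repeated-measures error partition?
#' @param subject Subject identifier, required when `repeated = TRUE`.
#' @param type Sum-of-squares type for the non-repeated fit: `"II"`
#'   (default), `"I"` or `"III"`.
#' @return data.frame of class `anova_result` with one row per term.
#' @export
two_way_anova <- function(values, f1, f2, repeated = FALSE, subject = NULL,
                          type = c("II", "I", "III")) {
  type <- match.arg(type)
  f1 <- factor(f1); f2 <- factor(f2)
  stopifnot(length(values) == length(f1), length(values) == length(f2))
  if (!repeated) {
    fit <- stats::lm(values ~ f1 * f2)
    tab <- if (type == "I") stats::anova(fit)
           else car::Anova(fit, type = type)
    rows <- rownames(tab)
    keep <- !rows %in% c("Residuals", "(Intercept)")
    res_df <- tab$Df[rows == "Residuals"]
    out <- data.frame(
      term = rows[keep], df1 = tab$Df[keep], df2 = res_df,
      statistic = tab$`F value`[keep], p = tab$`Pr(>F)`[keep],
      n = length(values), method = paste0("two_way_anova_type", type)
    )
  } else {
    if (is.null(subject)) stop("repeated = TRUE requires subject ids")
    subject <- factor(subject)
    counts <- table(subject, f1)
    if (any(counts != 1L))
      stop("repeated-measures design must be balanced: exactly one ",
           "observation per subject and within-subject level")
    df <- data.frame(y = values, w = f1, b = f2, s = subject)
    fit <- stats::aov(y ~ w * b + Error(s / w), data = df)
    sm <- summary(fit)
    out <- do.call(rbind, lapply(sm, function(stratum) {
      tt <- stratum[[1]]
      rows <- trimws(rownames(tt))
      keep <- rows != "Residuals"
      if (!any(keep)) return(NULL)
      data.frame(term = rows[keep], df1 = tt$Df[keep],
                 df2 = tt$Df[rows == "Residuals"],
                 statistic = tt$`F value`[keep], p = tt$`Pr(>F)`[keep],
                 n = length(values), method = "two_way_repeated_anova")
    }))
    rownames(out) <- NULL
    out <- out[!is.na(out$statistic), ]
  }
  structure(out, class = c("anova_result", "data.frame"))
}

#' Tukey HSD post-hoc comparisons
#'
#' All pairwise group comparisons on the studentized range distribution,
#' with the Tukey-Kramer harmonic-mean adjustment for unequal group sizes
#' (as provided by [stats::TukeyHSD()]).
#'
#' @inheritParams one_way_anova
#' @return data.frame of class `posthoc_result`: `pair`, `diff`, `p_adj`,
#'   `method`.
#' @export
tukey_hsd <- function(values, group) {
  group <- factor(group)
  check_groups(values, group)
  tk <- stats::TukeyHSD(stats::aov(values ~ group))$group
  structure(data.frame(
    pair = rownames(tk), diff = tk[, "diff"], p_adj = tk[, "p adj"],
    method = "tukey_hsd", row.names = NULL
  ), class = c("posthoc_result", "data.frame"))
}

#' Kruskal-Wallis rank test
#'
#' Non-parametric omnibus comparison of group distributions, with midrank
#' tie correction (via [stats::kruskal.test()]).
#'
#' @inheritParams one_way_anova
#' @return List with `H`, `df`, `p`, `n`.
#' @export
kruskal_wallis <- function(values, group) {
  group <- factor(group)
  if (any(table(group) == 0L)) stop("empty group")
  kt <- stats::kruskal.test(values, group)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value, n = length(values))
}

#' Dunn pairwise rank comparisons with Sidak adjustment
#'
#' Post hoc to Kruskal-Wallis: for each pair of groups, Dunn's z statistic
#' compares mean ranks computed on the pooled sample (with the standard tie
#' correction), and the two-sided normal p-value is Sidak-adjusted for the
#' number of pairs: `p_adj = 1 - (1 - p)^m`.
#'
#' @inheritParams one_way_anova
#' @return data.frame of class `posthoc_result`: `pair`, `z`, `p_raw`,
#'   `p_adj`, `method`.
#' @export
dunn_sidak <- function(values, group) {
  group <- factor(group)
  tab <- table(group)
  if (any(tab == 0L)) stop("empty group")
  n <- length(values)
  rk <- rank(values)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  mean_rank <- tapply(rk, group, mean)
  lev <- levels(group)
  pairs <- utils::combn(lev, 2)
  m <- ncol(pairs)
  out <- lapply(seq_len(m), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    se <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / tab[[a]] + 1 / tab[[b]]))
    z <- (mean_rank[[a]] - mean_rank[[b]]) / se
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(pair = paste(a, b, sep = "-"), z = z, p_raw = p,
               p_adj = min(1, 1 - (1 - p)^m), method = "dunn_sidak")
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  structure(out, class = c("posthoc_result", "data.frame"))
}

#' Correlate compartment amplitudes across cells
#'
#' Pearson correlation (and test) of per-cell maximum response amplitudes:
#' dendrite versus soma and dendrite versus axon initial segment. The
#' amplitudes are max-in-window values of trial-averaged traces — no event
#' detection is involved.
#'
#' @param data data.frame with numeric columns `dendrite`, `soma`, `ais`
#'   (one row per cell; >= 3 cells).
#' @return data.frame of class `correlation_result`: `pair`, `r`, `p`, `n`.
#' @export
compartment_correlation <- function(data) {
  stopifnot(all(c("dendrite", "soma", "ais") %in% names(data)))
  if (nrow(data) < 3L) stop("at least 3 cells are required")
  one <- function(other) {
    ct <- stats::cor.test(data$dendrite, data[[other]], method = "pearson")
    data.frame(pair = paste0("dendrite-", other),
               r = unname(ct$estimate), p = ct$p.value, n = nrow(data))
  }
  structure(rbind(one("soma"), one("ais")),
            class = c("correlation_result", "data.frame"))
}
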