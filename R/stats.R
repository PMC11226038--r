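# Two-way ANOVA decomposition, effect sizes, biomarker ranking, and robust
# outlier flagging.

#' Two-way ANOVA sum-of-squares decomposition
#'
#' Cell-means decomposition of a two-factor design (typically treatment x
#' time on bone volume or percent change), producing the sums of squares
#' feeding the effect-size measures. The `SS_effect` reported for ranking
#' is the A:B interaction ("Effect" = the condition analyzed, treatment x
#' time); main effects are computed and reported but not ranked on.
#'
#' Balanced designs use the classical weighted decomposition and satisfy
#' `SS_total = SS_A + SS_B + SS_effect + SS_error` to numerical precision.
#' Unbalanced designs (deaths, exclusions) fall back to the unweighted-means
#' analysis (harmonic-mean cell size), with `balanced = FALSE` recorded;
#' the exact partition identity is then not guaranteed.
#'
#' @param design_table data.frame with one row per observation.
#' @param response,factor_a,factor_b column names (defaults `"response"`,
#'   `"group"`, `"timepoint"`).
#' @return list of class `anova_decomposition`: `SS_A`, `SS_B`,
#'   `SS_effect`, `SS_error`, `SS_total`, `DF_A`, `DF_B`, `DF_effect`,
#'   `DF_error`, `MS_error`, `n`, `balanced`, `single_replicate`.
#' @examples
#' d <- expand.grid(group = c("placebo", "antiTNF"), timepoint = c(0, 3, 6),
#'                  rep = 1:4)
#' d$response <- rnorm(nrow(d))
#' two_way_anova(d)
#' @export
two_way_anova <- function(design_table, response = "response",
                          factor_a = "group", factor_b = "timepoint") {
  stopifnot(all(c(response, factor_a, factor_b) %in% names(design_table)))
  y <- as.numeric(design_table[[response]])
  A <- factor(design_table[[factor_a]])
  B <- factor(design_table[[factor_b]])
  if (any(is.na(y))) stop("response contains NA")
  a <- nlevels(A)
  b <- nlevels(B)
  if (a < 2L || b < 2L) stop("each factor needs >= 2 levels")
  n_ab <- table(A, B)
  if (any(n_ab == 0L)) {
    empty <- which(n_ab == 0L, arr.ind = TRUE)[1, ]
    stop(sprintf("empty cell: %s = %s, %s = %s", factor_a,
                 levels(A)[empty[1]], factor_b, levels(B)[empty[2]]))
  }
  N <- length(y)
  grand <- mean(y)
  SS_total <- sum((y - grand)^2)
  cell_mean <- tapply(y, list(A, B), mean)
  SS_error <- sum((y - cell_mean[cbind(A, B)])^2)
  DF_error <- N - a * b
  balanced <- length(unique(as.integer(n_ab))) == 1L
  if (balanced) {
    n_a <- as.integer(table(A))
    n_b <- as.integer(table(B))
    mean_a <- tapply(y, A, mean)
    mean_b <- tapply(y, B, mean)
    SS_A <- sum(n_a * (mean_a - grand)^2)
    SS_B <- sum(n_b * (mean_b - grand)^2)
    SS_cells <- sum(as.integer(n_ab) * (as.numeric(cell_mean) - grand)^2)
    SS_AB <- SS_cells - SS_A - SS_B
  } else {
    # unweighted-means analysis on cell means, harmonic-mean cell size
    nh <- 1 / mean(1 / as.numeric(n_ab))
    m_a <- rowMeans(cell_mean)
    m_b <- colMeans(cell_mean)
    m_g <- mean(cell_mean)
    SS_A <- nh * b * sum((m_a - m_g)^2)
    SS_B <- nh * a * sum((m_b - m_g)^2)
    SS_AB <- nh * sum((sweep(sweep(cell_mean, 1, m_a), 2, m_b) + m_g)^2)
  }
  SS_AB <- max(SS_AB, 0)
  single_replicate <- DF_error == 0L
  if (single_replicate) {
    warning("single replicate per cell: SS_error = 0, omega-squared undefined")
  }
  structure(list(SS_A = SS_A, SS_B = SS_B, SS_effect = SS_AB,
                 SS_error = SS_error, SS_total = SS_total,
                 DF_A = a - 1L, DF_B = b - 1L,
                 DF_effect = (a - 1L) * (b - 1L), DF_error = DF_error,
                 MS_error = if (DF_error > 0L) SS_error / DF_error else
                   NA_real_,
                 n = N, balanced = balanced,
                 single_replicate = single_replicate),
            class = "anova_decomposition")
}

#' @export
print.anova_decomposition <- function(x, ...) {
  cat(sprintf(
    "<anova_decomposition> n=%d%s  SS: A=%.4g B=%.4g effect=%.4g error=%.4g total=%.4g\n",
    x$n, if (x$balanced) " (balanced)" else " (UNBALANCED)",
    x$SS_A, x$SS_B, x$SS_effect, x$SS_error, x$SS_total))
  invisible(x)
}

#' Effect sizes for the treatment-by-time effect
#'
#' Applies the three printed effect-size equations to an ANOVA
#' decomposition:
#' \deqn{\eta^2 = SS_{effect} / SS_{total}}
#' \deqn{partial\ \eta^2 = SS_{effect} / (SS_{total} + SS_{error})}
#' \deqn{\omega^2 = (SS_{effect} - DF_{effect} \cdot MS_{error}) /
#'                  (SS_{total} + MS_{error})}
#'
#' Note the partial eta-squared denominator: this follows the source
#' equations verbatim (their printed values, e.g. talus partial
#' eta^2 = 0.20 < eta^2 = 0.21, confirm the `SS_total + SS_error`
#' denominator), so here `partial_eta2 <= eta2` always. The textbook
#' variant `SS_effect / (SS_effect + SS_error)` is also returned as
#' `partial_eta2_classical`. `omega2` is reported raw and may be negative;
#' `eta2` is bounded between 0 and 1 algebraically, never clamped.
#'
#' An effect is flagged "large" when the measure exceeds
#' `large_effect_threshold` (default 0.138).
#'
#' @param decomposition a [two_way_anova()] result.
#' @param large_effect_threshold default 0.138.
#' @return list of class `effect_sizes`: `eta2`, `partial_eta2`,
#'   `partial_eta2_classical`, `omega2`, logical flags `large_eta2`,
#'   `large_partial_eta2`, `large_omega2`, and the threshold.
#' @examples
#' d <- list(SS_effect = 20, SS_error = 60, SS_total = 100,
#'           DF_effect = 2L, DF_error = 12L, MS_error = 5)
#' class(d) <- "anova_decomposition"
#' es <- effect_sizes(d)
#' es$eta2                     # 0.2
#' es$partial_eta2_classical   # 0.25
#' round(es$omega2, 4)         # (20 - 2*5) / 105 = 0.0952
#' @export
effect_sizes <- function(decomposition, large_effect_threshold = 0.138) {
  stopifnot(inherits(decomposition, "anova_decomposition"))
  d <- decomposition
  if (!is.finite(d$SS_total) || d$SS_total <= 0) {
    stop("SS_total must be > 0: effect sizes undefined for a constant response")
  }
  eta2 <- d$SS_effect / d$SS_total
  partial_eta2 <- d$SS_effect / (d$SS_total + d$SS_error)
  partial_eta2_classical <- if (d$SS_effect + d$SS_error > 0) {
    d$SS_effect / (d$SS_effect + d$SS_error)
  } else {
    NA_real_
  }
  omega2 <- if (!is.na(d$MS_error)) {
    (d$SS_effect - d$DF_effect * d$MS_error) / (d$SS_total + d$MS_error)
  } else {
    NA_real_
  }
  structure(list(eta2 = eta2, partial_eta2 = partial_eta2,
                 partial_eta2_classical = partial_eta2_classical,
                 omega2 = omega2,
                 large_eta2 = eta2 > large_effect_threshold,
                 large_partial_eta2 = partial_eta2 > large_effect_threshold,
                 large_omega2 = !is.na(omega2) &&
                   omega2 > large_effect_threshold,
                 large_effect_threshold = large_effect_threshold),
            class = "effect_sizes")
}

#' @export
print.effect_sizes <- function(x, ...) {
  cat(sprintf(
    "<effect_sizes> eta2=%.3f partial_eta2=%.3f omega2=%.3f (large > %.3f)\n",
    x$eta2, x$partial_eta2, x$omega2, x$large_effect_threshold))
  invisible(x)
}

#' Rank bones as treatment-response biomarkers
#'
#' Runs [two_way_anova()] and [effect_sizes()] per bone and ranks bones by
#' descending eta-squared of the treatment-by-time interaction; partial
#' eta-squared and omega-squared are reported as validation columns. Ties
#' are broken by catalog order and recorded.
#'
#' @param per_bone_design data.frame with a `bone` column plus the design
#'   columns of [two_way_anova()].
#' @param response,factor_a,factor_b passed to [two_way_anova()].
#' @param large_effect_threshold passed to [effect_sizes()].
#' @return data.frame: `bone`, `eta2`, `partial_eta2`, `omega2`,
#'   `large_eta2`, `large_partial_eta2`, `large_omega2`, `rank`.
#' @export
rank_biomarkers <- function(per_bone_design, response = "response",
                            factor_a = "group", factor_b = "timepoint",
                            large_effect_threshold = 0.138) {
  stopifnot("bone" %in% names(per_bone_design))
  bones <- unique(per_bone_design$bone)
  if (length(bones) < 2L) stop("need >= 2 bones to rank")
  rows <- lapply(bones, function(b) {
    d <- per_bone_design[per_bone_design$bone == b, , drop = FALSE]
    es <- effect_sizes(two_way_anova(d, response, factor_a, factor_b),
                       large_effect_threshold)
    data.frame(bone = b, eta2 = es$eta2, partial_eta2 = es$partial_eta2,
               omega2 = es$omega2, large_eta2 = es$large_eta2,
               large_partial_eta2 = es$large_partial_eta2,
               large_omega2 = es$large_omega2, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  cat_order <- match(out$bone, unique(full_catalog_lookup()$report_unit))
  cat_order[is.na(cat_order)] <- length(cat_order) + seq_len(sum(is.na(cat_order)))
  ord <- order(-out$eta2, cat_order)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Robust outlier flagging (ROUT-like)
#'
#' A documented stand-in for the proprietary ROUT procedure: robust
#' z-scores from the median and MAD, two-sided normal tail probabilities,
#' Benjamini-Hochberg adjustment, and flagging at the Q-like false-positive
#' target (default Q = 1%). Deterministic given the data; explicitly NOT
#' bit-compatible with ROUT (recorded in the `method` attribute).
#'
#' @param values numeric vector, at least 4 observations.
#' @param q_target false-discovery target in (0, 1), default 0.01.
#' @return data.frame `value`, `robust_z`, `p`, `p_adj`, `outlier`. A zero
#'   MAD falls back to the scaled mean absolute deviation (so an isolated
#'   spike among identical values is still flagged); fully constant data
#'   yields no flags with a warning. Attribute `method` documents the
#'   approximation.
#' @export
flag_outliers <- function(values, q_target = 0.01) {
  if (length(values) < 4L) stop("need >= 4 observations")
  stopifnot(q_target > 0, q_target < 1)
  med <- median(values)
  s <- mad(values)
  if (s == 0) {
    # an isolated extreme among otherwise identical values zeroes the MAD;
    # fall back to the scaled mean absolute deviation so such a spike is
    # still scored (fully constant data then warns and flags nothing)
    s <- 1.4826 * mean(abs(values - med))
  }
  if (s == 0) {
    warning("MAD is zero; no outliers flagged")
    z <- rep(0, length(values))
  } else {
    z <- (values - med) / s
  }
  p <- 2 * pnorm(-abs(z))
  p_adj <- p.adjust(p, method = "BH")
  out <- data.frame(value = values, robust_z = z, p = p, p_adj = p_adj,
                    outlier = s != 0 & p_adj < q_target)
  attr(out, "method") <-
    "median/MAD robust z + BH FDR; ROUT-like target, not bit-compatible"
  attr(out, "q_target") <- q_target
  out
}
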