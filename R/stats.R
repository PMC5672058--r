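# Group-level statistics: fixed-effects two-way ANOVA and Tukey-Kramer
# post hoc comparisons.

#' Fixed-effects two-way ANOVA
#'
#' Balanced designs use the classical sequential decomposition (which is
#' unique when balanced); unbalanced designs use hierarchical Type II sums
#' of squares.  The interaction is included whenever every cell holds at
#' least two observations, otherwise an additive model is fitted.
#'
#' @param values Numeric observations.
#' @param factor_a,factor_b Factor levels (coerced to factor), same length
#'   as `values`.
#' @param interaction Include the A:B interaction (default: automatic).
#' @return An `anova_result`: data frame with one row per term (sum of
#'   squares, df, F, p) plus attributes `design` and `balanced`.
#' @export
two_way_anova <- function(values, factor_a, factor_b, interaction = NULL) {
  a <- factor(factor_a); b <- factor(factor_b)
  stopifnot(length(values) == length(a), length(values) == length(b))
  if (nlevels(a) < 2 || nlevels(b) < 2) {
    stop("need at least two levels per factor", call. = FALSE)
  }
  cells <- table(a, b)
  if (any(cells == 0)) stop("empty factor cell", call. = FALSE)
  if (is.null(interaction)) interaction <- all(cells >= 2)
  balanced <- length(unique(as.vector(cells))) == 1
  dat <- data.frame(y = values, A = a, B = b)
  form <- if (interaction) y ~ A * B else y ~ A + B
  fit <- stats::lm(form, data = dat)
  tab <- withCallingHandlers(
    if (balanced) stats::anova(fit) else car::Anova(fit, type = 2),
    warning = function(w) {
      # constant data triggers a harmless perfect-fit warning; the F/p
      # values are repaired below
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  rn <- rownames(tab)
  out <- data.frame(
    term = sub("^A$", "factor_a", sub("^B$", "factor_b",
               sub("^A:B$", "interaction", rn))),
    sum_sq = tab[["Sum Sq"]],
    df = tab[["Df"]],
    F = tab[["F value"]],
    p = tab[["Pr(>F)"]],
    stringsAsFactors = FALSE)
  # guard against (near-)constant data, where F is numerically 0/0
  scale <- sum(values^2) / length(values) + 1e-300
  tiny <- out$sum_sq < 1e-20 * scale
  degenerate <- out$term != "Residuals" &
    (is.nan(out$F) | is.na(out$F) | (tiny & tiny[out$term == "Residuals"]))
  out$F[degenerate] <- 0
  out$p[degenerate] <- 1
  attr(out, "design") <- paste(deparse(form), if (balanced) "(balanced)"
                               else "(Type II)")
  attr(out, "balanced") <- balanced
  class(out) <- c("anova_result", "data.frame")
  out
}

#' Tukey-Kramer pairwise comparisons
#'
#' Studentized-range based pairwise tests of group means with the unequal-n
#' (Kramer) correction.  With equal group sizes this reduces to the
#' classical Tukey HSD.  Quantiles of the studentized range are evaluated
#' numerically via R's `ptukey`, valid for arbitrary error df.
#'
#' @param group_means Named numeric vector of group means.
#' @param group_ns Group sizes (same order).
#' @param mse Mean squared error from the ANOVA (> 0).
#' @param df Error degrees of freedom (> 0).
#' @return Data frame with one row per pair: difference, standard error,
#'   studentized-range statistic `q`, adjusted p-value.
#' @export
tukey_kramer <- function(group_means, group_ns, mse, df) {
  stopifnot(length(group_means) == length(group_ns), mse > 0)
  if (df <= 0) stop("error df must be positive", call. = FALSE)
  g <- length(group_means)
  if (g < 2) stop("need at least two groups", call. = FALSE)
  nm <- names(group_means) %||% paste0("g", seq_len(g))
  pairs <- utils::combn(g, 2)
  out <- data.frame(group1 = nm[pairs[1, ]], group2 = nm[pairs[2, ]],
                    diff = NA_real_, se = NA_real_, q = NA_real_,
                    p_adj = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(ncol(pairs))) {
    a <- pairs[1, i]; b <- pairs[2, i]
    d <- group_means[a] - group_means[b]
    se <- sqrt(mse / 2 * (1 / group_ns[a] + 1 / group_ns[b]))
    q <- abs(d) / se
    out$diff[i] <- d
    out$se[i] <- se
    out$q[i] <- q
    out$p_adj[i] <- stats::ptukey(q, nmeans = g, df = df, lower.tail = FALSE)
  }
  out
}

#' Tukey-Kramer comparisons from raw observations
#'
#' Convenience wrapper: one-way decomposition of `values` by `group`,
#' then [tukey_kramer()] with the one-way MSE.
#'
#' @param values Numeric observations.
#' @param group Group labels.
#' @return See [tukey_kramer()].
#' @export
tukey_kramer_groups <- function(values, group) {
  group <- factor(group)
  means <- tapply(values, group, mean)
  ns <- tapply(values, group, length)
  fit <- stats::lm(values ~ group)
  mse <- sum(stats::residuals(fit)^2) / fit$df.residual
  tukey_kramer(means, ns, mse, fit$df.residual)
}
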