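# Group-level inference: repeated-measures mixed models with AIC-selected
# residual covariance, factorial ANOVA, Tukey-Kramer post hocs, and
# one-sample tests against chance.

sum_coded <- function(x) {
  f <- factor(x)
  stats::contrasts(f) <- stats::contr.sum(nlevels(f))
  f
}

new_srt_anova <- function(table, structure = NA_character_, aic = NULL) {
  structure(
    list(table = table, structure = structure, aic = aic),
    class = "srt_anova"
  )
}

#' Repeated-measures ANOVA via a mixed model with AIC-selected covariance
#'
#' Fits the fully crossed fixed-effects model `response ~ within * between`
#' by generalized least squares with the participant as the clustering
#' unit, under each candidate residual covariance structure -- compound
#' symmetry (`"cs"`), first-order autoregressive (`"ar1"`) and unstructured
#' (`"un"`) -- selects the structure with the smallest (REML) AIC, and
#' returns marginal (type-III) F tests. Denominator degrees of freedom use
#' the between-within method: terms involving a within-participant factor
#' are tested against the within-participant error stratum, the rest
#' against the between-participant stratum. Candidates that fail to
#' converge are dropped with a message; if the best-AIC candidate is
#' unavailable the next-best converged structure is used.
#'
#' @param data Long-format data frame, one response per participant x
#'   within-cell.
#' @param response,subject Column names (strings) of the response and the
#'   participant identifier.
#' @param within Character vector of within-participant factor columns.
#' @param between Character vector of between-participant factor columns
#'   (may be empty).
#' @param structures Candidate covariance structures, a subset of
#'   `c("cs", "ar1", "un")`.
#' @return An object of class `srt_anova`; `tidy()` gives the F table
#'   (`term`, `df1`, `df2`, `statistic`, `p.value`), `glance()` the selected
#'   structure and its AIC.
#' @export
rm_anova <- function(data, response, subject, within, between = character(0),
                     structures = c("cs", "ar1", "un")) {
  structures <- match.arg(structures, several.ok = TRUE)
  data <- dplyr::as_tibble(data)
  factors <- c(within, between)
  d <- data.frame(
    .y = as.numeric(data[[response]]),
    .subject = factor(data[[subject]])
  )
  for (f in factors) d[[f]] <- sum_coded(data[[f]])
  if (anyNA(d)) abort("Missing values in response or factors.")
  # observation order within subject, for serial correlation structures
  d <- d[order(d$.subject), , drop = FALSE]
  d$.obs <- stats::ave(seq_len(nrow(d)), d$.subject, FUN = seq_along)

  fixed <- as.formula(paste(".y ~", paste(factors, collapse = " * ")))
  within_levels <- interaction(d[within], drop = TRUE)
  fits <- lapply(structures, function(s) {
    args <- list(
      model = fixed, data = d, method = "REML",
      control = nlme::glsControl(
        maxIter = 100, msMaxIter = 500, tolerance = 1e-10,
        msTol = 1e-12, opt = "optim"
      ),
      correlation = switch(s,
        cs = nlme::corCompSymm(form = ~ 1 | .subject),
        ar1 = nlme::corAR1(form = ~ .obs | .subject),
        un = nlme::corSymm(form = ~ .obs | .subject)
      )
    )
    if (s == "un") {
      d$.wlev <- within_levels
      args$data <- d
      args$weights <- nlme::varIdent(form = ~ 1 | .wlev)
    }
    try(do.call(nlme::gls, args), silent = TRUE)
  })
  names(fits) <- structures
  ok <- !vapply(fits, inherits, logical(1), "try-error")
  if (!any(ok)) abort("No candidate covariance structure converged.")
  if (any(!ok)) {
    inform(paste(
      "Covariance structure(s) failed to converge and were dropped:",
      paste(structures[!ok], collapse = ", ")
    ))
  }
  aics <- vapply(fits[ok], AIC, numeric(1))
  best <- names(aics)[which.min(aics)]
  fit <- fits[[best]]

  at <- anova(fit, type = "marginal")
  at <- at[rownames(at) != "(Intercept)", , drop = FALSE]
  n_obs <- nrow(d)
  n_sub <- nlevels(d$.subject)
  g <- if (length(between) > 0) {
    nlevels(interaction(d[between], drop = TRUE))
  } else {
    1L
  }
  p_rank <- length(coef(fit))
  den_between <- n_sub - g
  den_within <- n_obs - n_sub - (p_rank - g)
  term <- rownames(at)
  is_within <- vapply(term, function(tm) {
    any(within %in% strsplit(tm, ":", fixed = TRUE)[[1]])
  }, logical(1))
  df2 <- ifelse(is_within, den_within, den_between)
  table <- tibble::tibble(
    term = term,
    df1 = as.integer(at$numDF),
    df2 = as.integer(df2),
    statistic = as.numeric(at$`F-value`),
    p.value = pf(as.numeric(at$`F-value`), at$numDF, df2, lower.tail = FALSE)
  )
  aic_vals <- vapply(seq_along(fits), function(i) {
    if (ok[i]) AIC(fits[[i]]) else NA_real_
  }, numeric(1))
  new_srt_anova(
    table,
    structure = best,
    aic = tibble::tibble(
      structure = structures, aic = aic_vals, converged = unname(ok)
    )
  )
}

#' Between-subjects factorial ANOVA (type-III)
#'
#' Fits `response ~ f1 * f2 * ...` with sum-to-zero contrasts and returns
#' type-III F tests (via `car::Anova`), the convention of SAS-style
#' factorial analyses.
#'
#' @param data Data frame with one value per participant.
#' @param response Response column name (string).
#' @param factors Character vector of (between-subject) factor columns.
#' @return An `srt_anova` object.
#' @export
two_way_anova <- function(data, response, factors) {
  data <- dplyr::as_tibble(data)
  d <- data.frame(.y = as.numeric(data[[response]]))
  for (f in factors) d[[f]] <- sum_coded(data[[f]])
  cells <- table(interaction(d[factors], drop = FALSE))
  if (any(cells == 0)) abort("Empty design cell(s): factorial ANOVA undefined.")
  fml <- as.formula(paste(".y ~", paste(factors, collapse = " * ")))
  mod <- lm(fml, data = d)
  if (var(d$.y) == 0) { # constant response: all effect SS are zero
    k <- length(attr(terms(mod), "term.labels"))
    return(new_srt_anova(tibble::tibble(
      term = attr(terms(mod), "term.labels"),
      df1 = NA_integer_, df2 = as.integer(mod$df.residual),
      statistic = rep(0, k), p.value = rep(1, k)
    )))
  }
  at <- car::Anova(mod, type = 3)
  keep <- !rownames(at) %in% c("(Intercept)", "Residuals")
  df_res <- at["Residuals", "Df"]
  new_srt_anova(tibble::tibble(
    term = rownames(at)[keep],
    df1 = as.integer(at$Df[keep]),
    df2 = as.integer(df_res),
    statistic = as.numeric(at$`F value`[keep]),
    p.value = as.numeric(at$`Pr(>F)`[keep])
  ))
}

#' Tukey-Kramer pairwise comparisons
#'
#' Studentized-range comparisons of cell means with the Kramer adjustment
#' for unequal cell sizes: for cells i and j the statistic is
#' `q = |m_i - m_j| / sqrt((s2 / 2) * (1/n_i + 1/n_j))`, referred to the
#' studentized range distribution with `k` groups and `df` error degrees of
#' freedom. With equal `n` this is the ordinary Tukey HSD.
#'
#' @param means Named numeric vector of cell means.
#' @param n Cell sizes (scalar or vector aligned with `means`).
#' @param s2 Pooled error variance (mean square error).
#' @param df Error degrees of freedom.
#' @return A tibble with one row per pair: `pair`, `diff`, `se`,
#'   `statistic` (q), `p.adj`.
#' @export
tukey_kramer <- function(means, n, s2, df) {
  k <- length(means)
  if (k < 2) abort("Need at least two cells.")
  if (is.null(names(means))) names(means) <- paste0("cell", seq_len(k))
  n <- rep_len(n, k)
  degenerate <- s2 <= 0
  if (degenerate) warn("Zero error variance: comparisons are degenerate.")
  idx <- utils::combn(k, 2)
  purrr::map_dfr(seq_len(ncol(idx)), function(c2) {
    i <- idx[1, c2]
    j <- idx[2, c2]
    diff <- means[i] - means[j]
    se <- sqrt((s2 / 2) * (1 / n[i] + 1 / n[j]))
    q <- unname(if (degenerate) {
      if (diff == 0) 0 else Inf
    } else {
      abs(diff) / se
    })
    tibble::tibble(
      pair = paste(names(means)[i], names(means)[j], sep = "-"),
      diff = unname(diff), se = se, statistic = q,
      p.adj = ptukey(q, k, df, lower.tail = FALSE)
    )
  })
}

#' Test group scores against their chance level
#'
#' One-sample Student t or Wilcoxon signed-rank tests of each group's scores
#' against the group-specific chance value, with a Bonferroni-adjusted
#' significance threshold `alpha / k` for the `k` simultaneous tests
#' (`0.05 / 4 = 0.0125` in the standard four-group design).
#'
#' @param data Data frame of per-participant scores.
#' @param score,group Column names (strings) of the score and grouping.
#' @param chance A single chance level, or a named vector keyed by group.
#' @param method `"t"` or `"wilcoxon"`.
#' @param alpha Familywise significance level (default 0.05).
#' @param k Number of simultaneous tests (default: number of groups).
#' @return A tibble with one row per group: `group`, `n`, `mean`, `chance`,
#'   `statistic`, `p.value`, `alpha_adj`, `significant`.
#' @export
test_against_chance <- function(data, score, group, chance,
                                method = c("t", "wilcoxon"),
                                alpha = 0.05, k = NULL) {
  method <- match.arg(method)
  data <- dplyr::as_tibble(data)
  groups <- unique(as.character(data[[group]]))
  k <- k %||% length(groups)
  alpha_adj <- alpha / k
  purrr::map_dfr(groups, function(gname) {
    x <- as.numeric(data[[score]][data[[group]] == gname])
    if (length(x) < 2) abort("Need at least 2 scores per group.")
    mu <- if (length(chance) > 1) unname(chance[[gname]]) else chance
    if (sd(x) == 0) {
      stat <- if (x[1] == mu) 0 else Inf
      p <- if (x[1] == mu) 1 else 0
    } else if (method == "t") {
      ht <- t.test(x, mu = mu)
      stat <- unname(ht$statistic)
      p <- ht$p.value
    } else {
      ht <- suppressWarnings(wilcox.test(x, mu = mu))
      stat <- unname(ht$statistic)
      p <- ht$p.value
    }
    tibble::tibble(
      group = gname, n = length(x), mean = mean(x), chance = mu,
      statistic = stat, p.value = p, alpha_adj = alpha_adj,
      significant = p < alpha_adj
    )
  })
}

#' @export
print.srt_anova <- function(x, ...) {
  cat("<srt_anova>")
  if (!is.na(x$structure)) cat(" covariance:", x$structure)
  cat("\n")
  print(as.data.frame(x$table), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @rdname srtlearn-tidiers
#' @export
tidy.srt_anova <- function(x, ...) x$table

#' @rdname srtlearn-tidiers
#' @export
glance.srt_anova <- function(x, ...) {
  tibble::tibble(
    structure = x$structure,
    aic = if (!is.null(x$aic)) min(x$aic$aic, na.rm = TRUE) else NA_real_,
    n_candidates = if (!is.null(x$aic)) nrow(x$aic) else NA_integer_,
    n_converged = if (!is.null(x$aic)) sum(x$aic$converged) else NA_integer_
  )
}
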