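# Scheirer-Ray-Hare: the rank-based nonparametric analogue of two-way ANOVA.

#' Scheirer-Ray-Hare rank test for a two-factor design
#'
#' Ranks all responses jointly (mid-ranks for ties), computes the two-way
#' ANOVA sums of squares on the ranks, and forms for each term
#' `H = SS_term / MS_total` with `MS_total = SS_total / (N - 1)`. `H` is
#' divided by the tie correction `D = 1 - sum(t^3 - t) / (N^3 - N)` (over
#' tie groups of size `t`) and referred to a chi-square distribution with
#' the term's degrees of freedom. For unbalanced data the sums of squares
#' are type II.
#'
#' @param data Data frame, one response per row.
#' @param response Response column name (string).
#' @param factors Character vector of the two factor columns.
#' @return An object of class `srt_rank_test`; `tidy()` gives `term`, `df`,
#'   `statistic` (H), `p.value`.
#' @examples
#' d <- expand.grid(a = c("l", "h"), b = c("x", "y"), rep = 1:3)
#' d$y <- seq_len(nrow(d))
#' tidy(scheirer_ray_hare(d, "y", c("a", "b")))
#' @export
scheirer_ray_hare <- function(data, response, factors) {
  if (length(factors) != 2) abort("Exactly two factors are required.")
  data <- dplyr::as_tibble(data)
  y <- as.numeric(data[[response]])
  n <- length(y)
  d <- data.frame(.r = rank(y, ties.method = "average"))
  for (f in factors) d[[f]] <- sum_coded(data[[f]])
  cells <- table(interaction(d[factors], drop = FALSE))
  if (any(cells < 2)) abort("Need at least 2 observations per cell.")
  terms_out <- c(factors, paste(factors, collapse = ":"))
  df_terms <- c(
    nlevels(d[[factors[1]]]) - 1L,
    nlevels(d[[factors[2]]]) - 1L,
    (nlevels(d[[factors[1]]]) - 1L) * (nlevels(d[[factors[2]]]) - 1L)
  )
  ss_total <- sum((d$.r - mean(d$.r))^2)
  if (ss_total == 0) { # every response tied
    return(structure(
      list(table = tibble::tibble(
        term = terms_out, df = df_terms,
        statistic = 0, p.value = 1
      )),
      class = "srt_rank_test"
    ))
  }
  fml <- as.formula(paste(".r ~", paste(factors, collapse = " * ")))
  at <- car::Anova(lm(fml, data = d), type = 2)
  ss <- setNames(at$`Sum Sq`, rownames(at))[terms_out]
  ms_total <- ss_total / (n - 1)
  tie_sizes <- table(d$.r)
  tie_d <- 1 - sum(tie_sizes^3 - tie_sizes) / (n^3 - n)
  h <- (ss / ms_total) / tie_d
  structure(
    list(table = tibble::tibble(
      term = terms_out,
      df = as.integer(df_terms),
      statistic = unname(h),
      p.value = pchisq(unname(h), df_terms, lower.tail = FALSE)
    )),
    class = "srt_rank_test"
  )
}

#' @export
print.srt_rank_test <- function(x, ...) {
  cat("<srt_rank_test> Scheirer-Ray-Hare\n")
  print(as.data.frame(x$table), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Tidiers for srtlearn result objects
#'
#' `tidy()` returns the term-level table of a fitted test object;
#' `glance()` returns a one-row model-level summary.
#'
#' @param x An `srt_anova` or `srt_rank_test` object.
#' @param ... Unused.
#' @name srtlearn-tidiers
NULL

#' @rdname srtlearn-tidiers
#' @export
tidy.srt_rank_test <- function(x, ...) x$table

#' @rdname srtlearn-tidiers
#' @export
glance.srt_rank_test <- function(x, ...) {
  tibble::tibble(method = "Scheirer-Ray-Hare", n_terms = nrow(x$table))
}
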