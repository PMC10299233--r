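#' Significance stars
#'
#' Maps p-values to the conventional legend: `ns` for p > 0.05, `*` for
#' p < 0.05, `**` for p < 0.01, `***` for p < 0.001.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Character vector.
#' @export
significance_stars <- function(p) {
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

#' Factorial ANOVA for group comparisons
#'
#' Fits a factorial analysis of variance of a numeric response on any number
#' of categorical factors, with interactions up to `max_order` -- the layer
#' used to compare pore metrics (three factors), mechanical features (two)
#' and viability readouts (four) across compositions and conditions. Balanced
#' and unbalanced designs are both accepted; for unbalanced designs the
#' sum-of-squares convention (Type II by default, Type I or III selectable)
#' is recorded in the result.
#'
#' @param data Data frame in tidy form: one row per observation.
#' @param response Name of the numeric response column.
#' @param factors Character vector of factor column names (each must have at
#'   least two observed levels).
#' @param max_order Maximum interaction order (default: all interactions).
#' @param ss_type `"II"` (default), `"I"` or `"III"` sum of squares.
#' @return An object of class `"factorial_anova"`; `tidy()` returns the term
#'   table (term, df, sumsq, statistic, p_value, stars), `glance()` the
#'   design summary.
#' @examples
#' d <- expand.grid(a = c("x", "y"), b = c("u", "v"), rep = 1:5)
#' d$y <- rnorm(nrow(d)) + (d$a == "x")
#' tidy(anova_factorial(d, "y", c("a", "b")))
#' @export
anova_factorial <- function(data, response, factors,
                            max_order = length(factors),
                            ss_type = c("II", "I", "III")) {
  ss_type <- match.arg(ss_type)
  stopifnot(is.data.frame(data), response %in% names(data),
            all(factors %in% names(data)), length(factors) >= 1,
            max_order >= 1)
  df <- as.data.frame(data)[c(response, factors)]
  df[factors] <- lapply(df[factors], factor)
  for (f in factors) {
    if (nlevels(droplevels(df[[f]])) < 2) {
      abort(sprintf("factor '%s' has a single observed level", f))
    }
  }
  max_order <- min(max_order, length(factors))
  rhs <- paste0("(", paste(factors, collapse = " + "), ")",
                if (max_order > 1) paste0("^", max_order) else "")
  fml <- stats::as.formula(paste(response, "~", rhs))
  cells <- table(df[factors])
  balanced <- length(unique(as.vector(cells))) == 1L && all(cells > 0)
  fit <- if (ss_type == "III") {
    contr <- lapply(df[factors], function(x) "contr.sum")
    names(contr) <- factors
    stats::lm(fml, data = df, contrasts = contr)
  } else {
    stats::lm(fml, data = df)
  }
  if (stats::df.residual(fit) < 1) abort("zero residual degrees of freedom")
  tab <- switch(
    ss_type,
    I = {
      a <- stats::anova(fit)
      tibble(
        term = rownames(a), df = a$Df, sumsq = a$`Sum Sq`,
        statistic = a$`F value`, p_value = a$`Pr(>F)`
      )
    },
    II = {
      a <- car::Anova(fit, type = 2)
      tibble(
        term = rownames(a), df = a$Df, sumsq = a$`Sum Sq`,
        statistic = a$`F value`, p_value = a$`Pr(>F)`
      )
    },
    III = {
      a <- car::Anova(fit, type = 3)
      tibble(
        term = rownames(a), df = a$Df, sumsq = a$`Sum Sq`,
        statistic = a$`F value`, p_value = a$`Pr(>F)`
      )[rownames(a) != "(Intercept)", ]
    }
  )
  tab <- tab |>
    dplyr::mutate(
      stars = significance_stars(.data$p_value),
      term = sub("^Residuals\\s*$", "Residuals", .data$term)
    )
  resid_row <- tab$term == "Residuals"
  structure(
    list(
      table = tab[!resid_row, ],
      residuals = tab[resid_row, c("term", "df", "sumsq")],
      model = fit, ss_type = ss_type, balanced = balanced,
      response = response, factors = factors, max_order = max_order,
      n = nrow(df)
    ),
    class = "factorial_anova"
  )
}

#' @export
print.factorial_anova <- function(x, ...) {
  cat(sprintf(
    "<factorial_anova> %s ~ %s (order <= %d), n = %d, Type %s SS%s\n",
    x$response, paste(x$factors, collapse = " * "), x$max_order, x$n,
    x$ss_type, if (x$balanced) " (balanced)" else " (unbalanced)"
  ))
  print(x$table)
  invisible(x)
}

#' @export
tidy.factorial_anova <- function(x, ...) x$table

#' @export
glance.factorial_anova <- function(x, ...) {
  s <- summary(x$model)
  tibble(
    n = x$n, ss_type = x$ss_type, balanced = x$balanced,
    r_squared = s$r.squared, df_residual = stats::df.residual(x$model),
    sigma = s$sigma
  )
}

#' Tukey--Kramer all-pairs comparisons
#'
#' Pairwise mean comparisons for one factor, with family-wise adjustment from
#' the studentized range distribution and the Kramer correction for unequal
#' group sizes, as implemented by [stats::TukeyHSD()]. Significance stars use
#' the conventional legend (see [significance_stars()]).
#'
#' @param data Data frame, one row per observation.
#' @param response Name of the numeric response column.
#' @param factor Name of the grouping column (>= 2 levels, each with at least
#'   2 observations).
#' @param conf_level Confidence level for the interval columns.
#' @return Tibble with one row per pair: `level_a`, `level_b`, `mean_diff`
#'   (mean of `level_b` minus mean of `level_a`), `conf_low`, `conf_high`,
#'   `adj_p`, `stars`, `significant` (at 0.05).
#' @export
tukey_kramer <- function(data, response, factor, conf_level = 0.95) {
  stopifnot(is.data.frame(data), response %in% names(data),
            factor %in% names(data))
  df <- data.frame(
    y = as.numeric(data[[response]]),
    g = droplevels(base::factor(data[[factor]]))
  )
  if (nlevels(df$g) < 2) abort("factor must have at least 2 levels")
  if (any(table(df$g) < 2)) {
    abort("every level needs at least 2 observations for Tukey-Kramer")
  }
  fit <- stats::aov(y ~ g, data = df)
  tk <- stats::TukeyHSD(fit, conf.level = conf_level)$g
  pairs <- utils::combn(levels(df$g), 2)
  out <- tibble(
    level_a = pairs[1, ], level_b = pairs[2, ],
    mean_diff = unname(tk[, "diff"]), conf_low = unname(tk[, "lwr"]),
    conf_high = unname(tk[, "upr"]), adj_p = unname(tk[, "p adj"])
  ) |>
    dplyr::mutate(
      stars = significance_stars(.data$adj_p),
      significant = .data$adj_p < 0.05
    )
  attr(out, "response") <- response
  attr(out, "factor") <- factor
  out
}

#' Log-normal distribution summary
#'
#' Fits a log-normal distribution to positive values (pore areas are the
#' canonical use: their distribution across a scaffold section is log-normal)
#' and tests goodness of fit with an Anderson--Darling normality test on the
#' log values.
#'
#' @param values Positive numeric vector.
#' @return One-row tibble: `n`, `log_mean`, `log_sd`, `se_log_mean`,
#'   `geometric_mean`, `geometric_sd`, `gof_p` (Anderson--Darling p-value on
#'   log values; `NA` when n < 8 or the fit is degenerate), `degenerate`
#'   (all values equal).
#' @examples
#' lognormal_summary(exp(rnorm(500)))
#' @export
lognormal_summary <- function(values) {
  stopifnot(is.numeric(values), length(values) >= 1)
  if (any(!is.finite(values)) || any(values <= 0)) {
    abort("lognormal_summary requires finite positive values")
  }
  lx <- log(values)
  n <- length(lx)
  m <- mean(lx)
  s <- if (n > 1) stats::sd(lx) else 0
  degenerate <- !is.finite(s) || s < .Machine$double.eps^0.5 * max(1, abs(m))
  gof <- if (!degenerate && n >= 8) nortest::ad.test(lx)$p.value else NA_real_
  tibble(
    n = n, log_mean = m, log_sd = s,
    se_log_mean = if (n > 1) s / sqrt(n) else NA_real_,
    geometric_mean = exp(m), geometric_sd = exp(s),
    gof_p = gof, degenerate = degenerate
  )
}
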