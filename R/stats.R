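#' Choose a distribution family by goodness of fit
#'
#' Fits normal, log-normal and gamma distributions by maximum likelihood
#' (all two-parameter, so the maximised log-likelihood ranks them
#' directly; AIC breaks ties) and returns the best-fitting family.
#' Non-positive values restrict the choice to normal, with a note in the
#' result.
#'
#' @param values Numeric vector, `n >= 8`.
#' @return List: `family` (`"normal"`, `"log-normal"` or `"gamma"`),
#'   `loglik` named vector, `note`.
#' @export
select_family <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 8) stop("need at least 8 values", call. = FALSE)
  if (stats::sd(values) == 0)
    stop("values are constant; distribution fit is degenerate",
         call. = FALSE)
  if (any(values <= 0)) {
    return(list(family = "normal",
                loglik = c(normal =
                  stats::logLik(suppressWarnings(
                    fitdistrplus::fitdist(values, "norm")))),
                note = "non-positive values: only the normal family fitted"))
  }
  fits <- suppressWarnings(list(
    normal = fitdistrplus::fitdist(values, "norm"),
    `log-normal` = fitdistrplus::fitdist(values, "lnorm"),
    gamma = fitdistrplus::fitdist(values, "gamma")))
  ll <- vapply(fits, function(f) as.numeric(stats::logLik(f)), numeric(1))
  aic <- vapply(fits, function(f) f$aic, numeric(1))
  best <- names(ll)[order(-ll, aic)][1]
  list(family = best, loglik = ll, note = NULL)
}

#' Nested genotype comparison with mixed-effects models
#'
#' Fits a (generalised) linear mixed model of `value` on genotype (and
#' optionally drug and their interaction) with random intercepts for
#' litter, animal and slice, and tests the genotype effect by a
#' likelihood-ratio test against the model with genotype dropped. The
#' response family follows `family` (`"log-normal"` models log(value)
#' with a Gaussian LMM; `"gamma"` uses a log-link GLMM; `"binomial"`
#' expects `value` as successes with a `trials` column). Random terms
#' with fewer than 2 levels are dropped up front; a singular fit is
#' refitted with a simplified random structure (drop slice, then litter,
#' never animal), recorded in the metadata.
#'
#' @param data Data frame with columns `value`, `genotype`, `animal`, and
#'   optionally `litter`, `slice`, `drug`, `trials`.
#' @param family `"normal"`, `"log-normal"`, `"gamma"` or `"binomial"`
#'   (`"auto"` runs [select_family()]).
#' @param include_drug Add drug and genotype:drug fixed effects.
#' @return A `spq_comparison` object.
#' @export
hierarchical_compare <- function(data, family = "auto",
                                 include_drug = FALSE) {
  data <- tibble::as_tibble(data)
  stopifnot(all(c("value", "genotype", "animal") %in% names(data)))
  data$genotype <- factor(data$genotype)
  if ("WT" %in% levels(data$genotype))
    data$genotype <- stats::relevel(data$genotype, "WT")
  if (nlevels(data$genotype) != 2)
    stop("genotype must have exactly two levels", call. = FALSE)
  for (g in levels(data$genotype))
    if (length(unique(data$animal[data$genotype == g])) < 2)
      stop("need >= 2 animals per genotype", call. = FALSE)
  if (identical(family, "auto")) family <- select_family(data$value)$family

  re_terms <- c("litter", "animal", "slice")
  re_terms <- re_terms[re_terms %in% names(data)]
  # a random intercept needs >= 2 levels and fewer levels than observations
  re_terms <- re_terms[vapply(re_terms, function(v) {
    k <- length(unique(data[[v]]))
    k >= 2 && k < nrow(data)
  }, logical(1))]
  dropped <- character()

  fx <- if (include_drug && "drug" %in% names(data))
    "genotype * drug" else "genotype"
  fx0 <- if (include_drug && "drug" %in% names(data)) "drug" else "1"

  resp <- "value"
  if (family == "log-normal") {
    if (any(data$value <= 0))
      stop("log-normal family needs positive values", call. = FALSE)
    data$.logvalue <- log(data$value)
    resp <- ".logvalue"
  }
  if (family == "binomial") {
    stopifnot("trials" %in% names(data))
    resp <- "cbind(value, trials - value)"
  }

  fit_pair <- function(terms) {
    re <- paste(sprintf("(1 | %s)", terms), collapse = " + ")
    ff <- stats::as.formula(paste(resp, "~", fx, "+", re))
    ff0 <- stats::as.formula(paste(resp, "~", fx0, "+", re))
    if (family %in% c("normal", "log-normal")) {
      full <- lme4::lmer(ff, data = data, REML = FALSE)
      red <- lme4::lmer(ff0, data = data, REML = FALSE)
    } else if (family == "gamma") {
      full <- lme4::glmer(ff, data = data, family = stats::Gamma("log"))
      red <- lme4::glmer(ff0, data = data, family = stats::Gamma("log"))
    } else {
      full <- lme4::glmer(ff, data = data, family = stats::binomial())
      red <- lme4::glmer(ff0, data = data, family = stats::binomial())
    }
    list(full = full, red = red)
  }

  terms <- re_terms
  repeat {
    fits <- suppressWarnings(suppressMessages(fit_pair(terms)))
    if (!lme4::isSingular(fits$full, tol = 1e-5) || length(terms) <= 1)
      break
    # simplification order: slice first, then litter, never animal
    cand <- intersect(c("slice", "litter"), terms)
    if (!length(cand)) break
    dropped <- c(dropped, cand[1])
    terms <- setdiff(terms, cand[1])
  }
  lrt <- stats::anova(fits$red, fits$full)
  chi <- lrt$Chisq[2]; df <- lrt$Df[2]; p <- lrt$`Pr(>Chisq)`[2]
  co <- lme4::fixef(fits$full)
  eff_name <- grep("^genotype", names(co), value = TRUE)[1]
  new_comparison(
    method = sprintf("%s mixed model, likelihood-ratio test",
                     if (family %in% c("normal", "log-normal"))
                       "linear" else "generalized linear"),
    statistic = chi, df = df, p_value = p,
    effect = unname(co[eff_name]),
    meta = list(family = family, random_effects = terms,
                dropped_singular = dropped,
                effect_term = eff_name, model = fits$full))
}

#' Sum-of-squares F-test comparing regressions between groups
#'
#' Fits a shared model (one parameter set pooled over groups) and
#' separate per-group models, and tests the improvement by
#' \eqn{F = ((SS_{sh} - SS_{sep})/(df_{sh} - df_{sep})) /
#' (SS_{sep}/df_{sep})}. Supported models: `"linear"`
#' (slope + intercept), `"linear_origin"` (slope through the origin) and
#' `"boltzmann"` (variable-slope sigmoid as in [fit_activation()]).
#'
#' @param data Data frame in long form.
#' @param y,x,group Column names.
#' @param model Model family to fit.
#' @return A `spq_comparison` with fields `F`, df pair and p-value.
#' @export
curve_compare_ftest <- function(data, y, x, group,
                                model = c("linear", "linear_origin",
                                          "boltzmann")) {
  model <- match.arg(model)
  df <- tibble::tibble(y = data[[y]], x = data[[x]],
                       g = factor(data[[group]]))
  df <- df[stats::complete.cases(df), ]
  fit_ss <- function(d) {
    if (model == "linear") {
      f <- stats::lm(y ~ x, data = d)
      c(ss = sum(stats::resid(f)^2), k = 2)
    } else if (model == "linear_origin") {
      f <- stats::lm(y ~ 0 + x, data = d)
      c(ss = sum(stats::resid(f)^2), k = 1)
    } else {
      f <- fit_activation(tibble::tibble(step_v = d$x, ih_amp = d$y),
                          response = "current")
      c(ss = stats::deviance(f$fit), k = 3)
    }
  }
  sh <- fit_ss(df)
  sep <- lapply(split(df, df$g), fit_ss)
  ss_sep <- sum(vapply(sep, `[[`, numeric(1), "ss"))
  k_sep <- sum(vapply(sep, `[[`, numeric(1), "k"))
  df_sh <- nrow(df) - sh[["k"]]
  df_sep <- nrow(df) - k_sep
  if (ss_sep <= 0 || df_sep <= 0 || df_sh <= df_sep)
    stop("degenerate F-test (zero residual or no extra parameters)",
         call. = FALSE)
  Fv <- ((sh[["ss"]] - ss_sep) / (df_sh - df_sep)) / (ss_sep / df_sep)
  Fv <- max(Fv, 0)
  p <- stats::pf(Fv, df_sh - df_sep, df_sep, lower.tail = FALSE)
  new_comparison(method = sprintf("sum-of-squares F-test (%s)", model),
                 statistic = Fv, df = c(df_sh - df_sep, df_sep),
                 p_value = p, effect = NA_real_,
                 meta = list(model = model, ss_shared = unname(sh[["ss"]]),
                             ss_separate = ss_sep))
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the D'Agostino skewness and Anscombe-Glynn kurtosis
#' z-statistics into the K-squared omnibus statistic (chi-squared, 2 df).
#'
#' @param x Numeric vector, `n >= 8`.
#' @return List: `statistic` (K2), `p_value`, `z_skew`, `z_kurt`.
#' @export
dagostino_pearson <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 8) stop("need n >= 8 for the omnibus test", call. = FALSE)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  g1 <- mean((x - m)^3) / s2^1.5
  g2 <- mean((x - m)^4) / s2^2 - 3
  # skewness: D'Agostino (1970) transformation
  Y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  z1 <- delta * log(Y / alpha + sqrt((Y / alpha)^2 + 1))
  # kurtosis: Anscombe & Glynn (1983)
  Eb2 <- 3 * (n - 1) / (n + 1)
  Vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  X <- (g2 + 3 - Eb2) / sqrt(Vb2)
  B <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / B * (2 / B + sqrt(1 + 4 / B^2))
  z2 <- ((1 - 2 / (9 * A)) -
           ((1 - 2 / A) / (1 + X * sqrt(2 / (A - 4))))^(1 / 3)) /
    sqrt(2 / (9 * A))
  K2 <- z1^2 + z2^2
  list(statistic = K2, p_value = stats::pchisq(K2, 2, lower.tail = FALSE),
       z_skew = z1, z_kurt = z2)
}

#' Normality-gated two-sample, paired and contingency tests
#'
#' For `"unpaired"` and `"paired"` designs both samples are first tested
#' for normality (D'Agostino-Pearson omnibus test at alpha = 0.05); if
#' both pass, Student's t-test (paired where appropriate) is used,
#' otherwise the Mann-Whitney U-test (unpaired) or Wilcoxon signed-rank
#' test (paired). `"contingency"` expects a 2x2 count matrix in `x` and
#' runs Fisher's exact test (two-sided by the point-probability rule:
#' the p-value sums the probabilities of all tables no more likely than
#' the observed one).
#'
#' @param x,y Numeric samples, or a 2x2 matrix for contingency designs.
#' @param design `"unpaired"`, `"paired"` or `"contingency"`.
#' @param alpha Normality-gate significance level.
#' @return A `spq_comparison`.
#' @export
exact_and_rank_tests <- function(x, y = NULL,
                                 design = c("unpaired", "paired",
                                            "contingency"),
                                 alpha = 0.05) {
  design <- match.arg(design)
  if (design == "contingency") {
    if (!is.matrix(x) || !all(dim(x) == c(2, 2)))
      stop("contingency design needs a 2x2 count matrix", call. = FALSE)
    ft <- stats::fisher.test(x)
    return(new_comparison(method = "Fisher's exact test",
                          statistic = unname(ft$estimate),
                          df = NA_real_, p_value = ft$p.value,
                          effect = unname(ft$estimate),
                          meta = list(table = x)))
  }
  stopifnot(is.numeric(x), is.numeric(y))
  normal <- tryCatch(
    dagostino_pearson(x)$p_value > alpha &&
      dagostino_pearson(y)$p_value > alpha,
    error = function(e) FALSE)   # tiny n: fall back to rank tests
  if (design == "unpaired") {
    if (normal) {
      tt <- stats::t.test(x, y, var.equal = TRUE)
      new_comparison("Student's t-test", unname(tt$statistic),
                     unname(tt$parameter), tt$p.value,
                     effect = mean(x) - mean(y),
                     meta = list(gate = "normal"))
    } else {
      wt <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
      new_comparison("Mann-Whitney U-test", unname(wt$statistic),
                     NA_real_, wt$p.value,
                     effect = stats::median(x) - stats::median(y),
                     meta = list(gate = "non-normal"))
    }
  } else {
    stopifnot(length(x) == length(y))
    if (normal) {
      tt <- stats::t.test(x, y, paired = TRUE)
      new_comparison("paired t-test", unname(tt$statistic),
                     unname(tt$parameter), tt$p.value,
                     effect = mean(x - y), meta = list(gate = "normal"))
    } else {
      wt <- stats::wilcox.test(x, y, paired = TRUE, exact = FALSE)
      new_comparison("Wilcoxon signed-rank test", unname(wt$statistic),
                     NA_real_, wt$p.value,
                     effect = stats::median(x - y),
                     meta = list(gate = "non-normal"))
    }
  }
}

## ---- comparison-result container ---------------------------------------

new_comparison <- function(method, statistic, df, p_value, effect,
                           meta = list()) {
  stopifnot(is.na(p_value) || (p_value >= 0 && p_value <= 1))
  structure(list(method = method, statistic = statistic, df = df,
                 p_value = p_value, effect = effect, meta = meta),
            class = "spq_comparison")
}

#' @export
print.spq_comparison <- function(x, ...) {
  dfs <- paste(signif(x$df, 4), collapse = ", ")
  cat(sprintf("<comparison> %s: statistic = %.4g (df %s), p = %.4g\n",
              x$method, x$statistic, dfs, x$p_value))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.spq_comparison <- function(x, ...) {
  tibble::tibble(method = x$method, statistic = x$statistic,
                 df1 = x$df[1], df2 = if (length(x$df) > 1) x$df[2] else
                   NA_real_,
                 p.value = x$p_value, estimate = x$effect)
}

#' @exportS3Method generics::glance
glance.spq_comparison <- function(x, ...) tidy.spq_comparison(x)
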