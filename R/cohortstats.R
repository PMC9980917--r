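#' @importFrom survival coxph survfit survdiff Surv cox.zph
NULL

stat_result <- function(method, statistic, effect, p_raw, n_used,
                        p_corrected = p_raw, two_sided = TRUE, extra = list()) {
  structure(c(list(method = method, statistic = statistic, effect = effect,
                   p_raw = p_raw, p_corrected = p_corrected,
                   n_used = n_used, two_sided = two_sided), extra),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<%s: stat %.4g, effect %.4g, p %.4g (corrected %.4g), n %d>\n",
              x$method, x$statistic, x$effect, x$p_raw, x$p_corrected,
              x$n_used))
  invisible(x)
}

#' Bonferroni correction capped at 1
#'
#' @param p raw p-values.
#' @param family_size number of tests in the family.
#' @return corrected p-values, monotone in the input and capped at 1.
#' @export
bonferroni <- function(p, family_size) pmin(1, p * family_size)

is_normalish <- function(v, alpha = 0.05) {
  if (sd(v) == 0) return(FALSE)
  p <- if (length(v) >= 5) nortest::lillie.test(v)$p.value
       else stats::shapiro.test(v)$p.value
  p > alpha
}

#' Two-group comparison with normality-driven test choice
#'
#' Lilliefors-corrected Kolmogorov-Smirnov normality on each group decides
#' between Student's t test and the Mann-Whitney U test (asymptotic,
#' tie-corrected); both two-sided. The chosen test is recorded.
#'
#' @param x,y numeric samples (paired by position when \code{paired}).
#' @param paired compare within pairs.
#' @param normality_alpha significance level of the normality pre-test.
#' @return a \code{stat_result}; \code{method} is "t" or "mann_whitney".
#' @export
compare_groups <- function(x, y, paired = FALSE, normality_alpha = 0.05) {
  if (paired) {
    keep <- !is.na(x) & !is.na(y)
    x <- x[keep]; y <- y[keep]
  } else {
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
  }
  if (length(x) < 3 || length(y) < 3)
    stopf("compare_groups: insufficient data (need >= 3 values per group)")
  use_t <- is_normalish(x, normality_alpha) && is_normalish(y, normality_alpha)
  if (use_t) {
    tt <- t.test(x, y, paired = paired)
    stat_result("t", unname(tt$statistic),
                if (paired) mean(x - y) else mean(x) - mean(y),
                tt$p.value, length(x) + length(y))
  } else {
    wt <- suppressWarnings(wilcox.test(x, y, paired = paired, exact = FALSE,
                                       correct = TRUE))
    stat_result("mann_whitney", unname(wt$statistic),
                median(x) - median(y), wt$p.value, length(x) + length(y))
  }
}

#' Pearson or Spearman correlation with two-sided p
#'
#' @param x,y numeric vectors (pairwise complete).
#' @param method "pearson" or "spearman".
#' @return a \code{stat_result} with the coefficient as \code{effect}, or a
#'   missing result (NA effect) with a warning when either vector is constant.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stopf("correlate: need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    warning("correlate: constant input, correlation undefined")
    return(stat_result(method, NA_real_, NA_real_, NA_real_, length(x)))
  }
  ct <- suppressWarnings(cor.test(x, y, method = method))
  stat_result(method, unname(ct$statistic), unname(ct$estimate),
              ct$p.value, length(x))
}

#' Dichotomize a biomarker
#'
#' "High" means strictly above the cutoff for the median and fixed rules.
#' The decile rules mark exactly the top (or bottom) 10% of the analysis set,
#' with ties broken by stable input order.
#'
#' @param values numeric vector (NAs stay NA in the labels).
#' @param rule "median", "fixed", "top_decile" or "bottom_decile".
#' @param cutoff required for \code{rule = "fixed"}.
#' @return list: \code{high} (logical), \code{cutoff}, \code{rule},
#'   \code{n_high}, \code{n_low}.
#' @export
dichotomize <- function(values,
                        rule = c("median", "fixed", "top_decile",
                                 "bottom_decile"),
                        cutoff = NULL) {
  rule <- match.arg(rule)
  ok <- which(!is.na(values))
  v <- values[ok]
  if (length(v) < 2) stopf("dichotomize: need >= 2 non-missing values")
  if (rule != "fixed" && length(unique(v)) < 2)
    stopf("dichotomize: degenerate input, all values equal")
  high <- rep(NA, length(values))
  if (rule == "median") {
    cutoff <- median(v)
    high[ok] <- v > cutoff
  } else if (rule == "fixed") {
    if (is.null(cutoff)) stopf("dichotomize: fixed rule needs a cutoff")
    high[ok] <- v > cutoff
  } else {
    k <- max(1L, round(0.10 * length(v)))
    if (rule == "top_decile") {
      sel <- order(v, decreasing = TRUE)[seq_len(k)]
      cutoff <- min(v[sel])
      high[ok] <- FALSE; high[ok[sel]] <- TRUE
    } else {
      sel <- order(v, decreasing = FALSE)[seq_len(k)]
      cutoff <- max(v[sel])
      high[ok] <- TRUE; high[ok[sel]] <- FALSE
    }
  }
  list(high = high, cutoff = cutoff, rule = rule,
       n_high = sum(high, na.rm = TRUE),
       n_low = sum(!high, na.rm = TRUE))
}

#' Cross-tabulate a clinical variable against a dichotomized marker
#'
#' Counts and row percentages, with Fisher's exact test where applicable
#' (2x2 tables) and the Pearson chi-square test otherwise.
#'
#' @param row categorical vector (rows of the table).
#' @param col binary/categorical vector (columns).
#' @param fisher_2x2 use Fisher's exact test for 2x2 tables (default TRUE;
#'   set FALSE to force chi-square everywhere).
#' @return list of class \code{crosstab}: \code{counts}, \code{row_pct},
#'   \code{test} ("fisher" or "chisq"), \code{p}, \code{n_used}.
#' @export
crosstab <- function(row, col, fisher_2x2 = TRUE) {
  keep <- !is.na(row) & !is.na(col)
  tab <- table(row[keep], col[keep])
  if (any(dim(tab) < 2)) stopf("crosstab: a variable has fewer than 2 levels")
  use_fisher <- all(dim(tab) == 2) && fisher_2x2
  p <- if (use_fisher) fisher.test(tab)$p.value
       else suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
  structure(list(counts = unclass(tab),
                 row_pct = round(100 * prop.table(tab, 1)),
                 test = if (use_fisher) "fisher" else "chisq",
                 p = p, n_used = sum(tab)),
            class = "crosstab")
}

#' @export
print.crosstab <- function(x, ...) {
  cat(sprintf("<crosstab (%s, p = %.4g, n = %d)>\n", x$test, x$p, x$n_used))
  print(x$counts)
  invisible(x)
}

fit_cox_quietly <- function(formula, data) {
  warn <- character()
  fit <- withCallingHandlers(
    tryCatch(coxph(formula, data = data, ties = "efron", x = TRUE, y = TRUE),
             error = function(e) NULL),
    warning = function(w) {
      warn <<- c(warn, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  converged <- !is.null(fit) && all(is.finite(coef(fit))) &&
    !any(grepl("converge|infinite|beta may be infinite", warn))
  list(fit = fit, converged = converged, warnings = warn)
}

#' Univariable Cox screen with Bonferroni correction
#'
#' Fits one univariable Cox model per variable (continuous values as given)
#' and corrects the Wald p-values for the size of the screened family
#' (p_corrected = min(1, p * family_size)). Non-converging fits are flagged
#' and excluded from the corrected ranking.
#'
#' @param data data.frame holding outcome and variables.
#' @param variables character vector of column names to screen.
#' @param time_col,event_col outcome column names.
#' @param family_size Bonferroni family size; defaults to the number of
#'   screened variables.
#' @return data.frame: variable, n_used, beta, hr, p_raw, p_corrected,
#'   converged.
#' @export
univariable_screen <- function(data, variables, time_col = "time_months",
                               event_col = "event",
                               family_size = length(variables)) {
  rows <- lapply(variables, function(v) {
    d <- data.frame(time = data[[time_col]], event = data[[event_col]],
                    x = as.numeric(data[[v]]))
    d <- d[complete.cases(d), , drop = FALSE]
    res <- data.frame(variable = v, n_used = nrow(d), beta = NA_real_,
                      hr = NA_real_, p_raw = NA_real_, p_corrected = NA_real_,
                      converged = FALSE, stringsAsFactors = FALSE)
    if (nrow(d) < 3 || sum(d$event) < 2 || sd(d$x) == 0) return(res)
    f <- fit_cox_quietly(Surv(time, event) ~ x, d)
    if (is.null(f$fit)) return(res)
    s <- summary(f$fit)
    res$beta <- unname(coef(f$fit))
    res$hr <- unname(exp(coef(f$fit)))
    res$p_raw <- s$coefficients[1, "Pr(>|z|)"]
    res$converged <- f$converged
    if (f$converged) res$p_corrected <- bonferroni(res$p_raw, family_size)
    res
  })
  do.call(rbind, rows)
}

#' Kaplan-Meier curves and log-rank comparison
#'
#' Product-limit survival per group with the log-rank test; for two groups a
#' univariable Cox fit of the group indicator supplies the hazard ratio shown
#' alongside the curves.
#'
#' @param time,event follow-up time and event indicator (0/1).
#' @param group grouping vector (>= 2 non-empty groups).
#' @return list of class \code{survival_fit}: \code{curves} (group, time,
#'   n_risk, surv; right-continuous steps starting at 1), \code{logrank_chisq},
#'   \code{df}, \code{p}, and \code{cox} (for two groups).
#' @export
km_logrank <- function(time, event, group) {
  keep <- !is.na(time) & !is.na(event) & !is.na(group)
  d <- data.frame(time = time[keep], event = event[keep],
                  group = factor(group[keep]))
  if (nlevels(d$group) < 2 || any(table(d$group) == 0))
    stopf("km_logrank: need at least two non-empty groups")
  if (sum(d$event) < 1) stopf("km_logrank: no events")
  sf <- survfit(Surv(time, event) ~ group, data = d)
  strata_lab <- rep(sub("^group=", "", names(sf$strata)), sf$strata)
  curves <- rbind(
    data.frame(group = levels(d$group), time = 0,
               n_risk = as.vector(table(d$group)), surv = 1),
    data.frame(group = strata_lab, time = sf$time, n_risk = sf$n.risk,
               surv = sf$surv))
  curves <- curves[order(curves$group, curves$time), ]
  sd_ <- survdiff(Surv(time, event) ~ group, data = d)
  df <- length(sd_$n) - 1
  p <- stats::pchisq(sd_$chisq, df, lower.tail = FALSE)
  cox <- if (nlevels(d$group) == 2) {
    cov <- data.frame(as.numeric(d$group == levels(d$group)[2]))
    names(cov) <- paste0(levels(d$group)[2], "_vs_", levels(d$group)[1])
    cox_fit(d$time, d$event, cov)
  } else NULL
  structure(list(type = "km", curves = curves,
                 logrank_chisq = unname(sd_$chisq), df = df, p = p,
                 n_used = nrow(d), cox = cox),
            class = "survival_fit")
}

#' Cox proportional-hazards fit with Wald inference
#'
#' Partial-likelihood estimation with Efron tie handling; reports per-
#' covariate hazard ratios, Wald 95% confidence intervals and p-values, and a
#' convergence flag (monotone-likelihood/separation fits are flagged).
#'
#' @param time,event outcome.
#' @param covariates data.frame of numeric covariates.
#' @return list of class \code{survival_fit} with a per-covariate \code{table}
#'   (beta, hr, ci_lo, ci_hi, p_wald), \code{converged}, \code{n_used},
#'   \code{n_events} and the underlying \code{fit}.
#' @export
cox_fit <- function(time, event, covariates) {
  covariates <- as.data.frame(covariates)
  d <- cbind(data.frame(time = time, event = event), covariates)
  d <- d[complete.cases(d), , drop = FALSE]
  if (sum(d$event) < ncol(covariates) + 1)
    stopf("cox_fit: need more events than covariates")
  f <- fit_cox_quietly(
    stats::as.formula(paste("Surv(time, event) ~",
                            paste(names(covariates), collapse = " + "))), d)
  if (is.null(f$fit)) stopf("cox_fit: model could not be fitted")
  s <- summary(f$fit)
  tab <- data.frame(
    covariate = rownames(s$coefficients),
    beta = s$coefficients[, "coef"],
    hr = s$coefficients[, "exp(coef)"],
    ci_lo = s$conf.int[, "lower .95"],
    ci_hi = s$conf.int[, "upper .95"],
    p_wald = s$coefficients[, "Pr(>|z|)"],
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(type = "cox", table = tab, converged = f$converged,
                 n_used = nrow(d), n_events = sum(d$event), fit = f$fit),
            class = "survival_fit")
}

#' @export
print.survival_fit <- function(x, ...) {
  if (x$type == "km") {
    cat(sprintf("<KM/log-rank: chisq %.3f (df %d), p = %.4g, n = %d>\n",
                x$logrank_chisq, x$df, x$p, x$n_used))
  } else {
    cat(sprintf("<Cox fit: n = %d, events = %d, converged: %s>\n",
                x$n_used, x$n_events, x$converged))
    print(x$table, digits = 3)
  }
  invisible(x)
}

#' Proportional-hazards check via scaled Schoenfeld residuals
#'
#' Per-covariate test of correlation between scaled Schoenfeld residuals and
#' time. Zero-variance covariates are reported as missing rather than fitted.
#'
#' @param time,event outcome.
#' @param covariates data.frame of numeric covariates.
#' @param fit optional existing [cox_fit()] result to diagnose.
#' @return data.frame: covariate, p_ph (NA for degenerate covariates).
#' @export
ph_check <- function(time, event, covariates, fit = NULL) {
  covariates <- as.data.frame(covariates)
  d <- cbind(data.frame(time = time, event = event), covariates)
  d <- d[complete.cases(d), , drop = FALSE]
  if (sum(d$event) < 3) stopf("ph_check: insufficient events (need >= 3)")
  sds <- vapply(covariates, function(v) sd(v, na.rm = TRUE), numeric(1))
  usable <- names(covariates)[sds > 0]
  out <- data.frame(covariate = names(covariates), p_ph = NA_real_,
                    stringsAsFactors = FALSE)
  if (length(usable)) {
    if (is.null(fit)) fit <- cox_fit(d$time, d$event, d[usable])
    z <- cox.zph(fit$fit)
    ztab <- z$table[setdiff(rownames(z$table), "GLOBAL"), , drop = FALSE]
    out$p_ph[match(rownames(ztab), out$covariate)] <- ztab[, "p"]
  }
  out
}

auc_placements <- function(score, y) {
  cases <- score[y == 1]; controls <- score[y == 0]
  v10 <- vapply(cases, function(s)
    (sum(controls < s) + 0.5 * sum(controls == s)) / length(controls),
    numeric(1))
  v01 <- vapply(controls, function(s)
    (sum(cases > s) + 0.5 * sum(cases == s)) / length(cases),
    numeric(1))
  list(auc = mean(v10), v10 = v10, v01 = v01)
}

#' DeLong comparison of two correlated ROC curves
#'
#' AUCs via placement values and the DeLong variance of the AUC difference on
#' paired scores; two-sided asymptotic p.
#'
#' @param outcome binary outcome (0/1), both classes present.
#' @param score_a,score_b two scores on the same subjects.
#' @return a \code{stat_result} with \code{effect} = AUC(a) - AUC(b) and
#'   extras \code{auc_a}, \code{auc_b}.
#' @export
delong_compare <- function(outcome, score_a, score_b) {
  keep <- !is.na(outcome) & !is.na(score_a) & !is.na(score_b)
  y <- as.integer(outcome[keep]); a <- score_a[keep]; b <- score_b[keep]
  if (length(unique(y)) < 2)
    stopf("delong_compare: both outcome classes must be present")
  pa <- auc_placements(a, y); pb <- auc_placements(b, y)
  m <- sum(y == 1); n0 <- sum(y == 0)
  vd <- var(pa$v10 - pb$v10) / m + var(pa$v01 - pb$v01) / n0
  delta <- pa$auc - pb$auc
  if (vd <= 0) {
    p <- if (abs(delta) < 1e-12) 1 else 0
    z <- if (abs(delta) < 1e-12) 0 else Inf
  } else {
    z <- delta / sqrt(vd)
    p <- 2 * pnorm(-abs(z))
  }
  stat_result("delong", z, delta, p, length(y),
              extra = list(auc_a = pa$auc, auc_b = pb$auc))
}
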