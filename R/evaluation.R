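#' Kaplan-Meier curves and log-rank test between risk groups
#'
#' Product-limit survival estimate per group and the two-sample (or k-sample)
#' log-rank chi-square comparing the groups.
#'
#' @param time,event follow-up times and 0/1 event indicators.
#' @param groups group membership per patient (e.g. `"high"`/`"low"`); every
#'   group must be non-empty.
#' @return an object of class `"km_estimate"`: list with `curves` (data.frame
#'   `group`, `time`, `surv`, `n_risk`, `n_event`), `chisq`, `df`, `p`.
#' @export
km_logrank <- function(time, event, groups) {
  stopifnot(length(time) == length(event), length(time) == length(groups))
  groups <- as.factor(groups)
  if (any(table(groups) == 0L) || nlevels(groups) < 2L)
    stop("every group must be non-empty and at least two groups are required")
  fit <- survfit(Surv(time, event) ~ groups)
  strata_id <- rep(names(fit$strata), fit$strata)
  curves <- data.frame(group = sub("^groups=", "", strata_id),
                       time = fit$time, surv = fit$surv,
                       n_risk = fit$n.risk, n_event = fit$n.event,
                       stringsAsFactors = FALSE)
  sd_ <- survdiff(Surv(time, event) ~ groups)
  df <- nlevels(groups) - 1L
  structure(list(curves = curves, chisq = sd_$chisq, df = df,
                 p = pchisq(sd_$chisq, df = df, lower.tail = FALSE)),
            class = "km_estimate")
}

#' @export
print.km_estimate <- function(x, ...) {
  cat(sprintf("Kaplan-Meier estimate, %d groups; log-rank chisq = %.3f (df %d), p = %.3g\n",
              length(unique(x$curves$group)), x$chisq, x$df, x$p))
  invisible(x)
}

#' Ordinal encoding of T/N/M stage codes
#'
#' Maps stage codes to ordinal integers (`T0 < T1 < ... < T4`,
#' `N0 < ... < N3`, `M0 < M1`). Unknown codes (`TX`, `NX`, `MX`, `NA`, empty)
#' become `NA` and are excluded from models using that covariate.
#'
#' @param codes character vector of stage codes.
#' @return integer vector with `NA` for unknown codes.
#' @export
encode_stage <- function(codes) {
  codes <- as.character(codes)
  num <- suppressWarnings(as.integer(sub("^[TNM]", "", codes)))
  num
}

#' Univariate and multivariate Cox proportional-hazards reports
#'
#' `cox_model` fits either one univariate Cox model per covariate column or a
#' single multivariate model on all columns (Efron ties; rows with missing
#' covariate values excluded per model). `cox_report` produces the combined
#' report: every covariate is screened univariately, and the multivariate
#' model includes the univariately significant covariates (default) or all
#' of them.
#'
#' @param time,event follow-up times and 0/1 event indicators.
#' @param covariates data.frame of numeric covariate columns (encode stage
#'   codes with [encode_stage()] first), one row per patient.
#' @param type `"univariate"` or `"multivariate"`.
#' @return data.frame per covariate: `covariate`, `hr`, `ci_lower`,
#'   `ci_upper`, `p`, `model`, `n`.
#' @export
cox_model <- function(time, event, covariates,
                      type = c("univariate", "multivariate")) {
  type <- match.arg(type)
  stopifnot(is.data.frame(covariates), nrow(covariates) == length(time))
  constant <- vapply(covariates, function(v) length(unique(v[!is.na(v)])) < 2L,
                     logical(1L))
  if (any(constant))
    stop("constant covariates: ",
         paste(names(covariates)[constant], collapse = ", "))
  one_fit <- function(covs) {
    keep <- complete.cases(covs)
    if (sum(event[keep]) < ncol(covs))
      stop("fewer events than covariates after removing missing rows")
    fit <- coxph(Surv(time[keep], event[keep]) ~ ., data = covs[keep, ,
                                                                drop = FALSE],
                 ties = "efron")
    s <- summary(fit)
    data.frame(covariate = rownames(s$coefficients),
               hr = unname(s$coefficients[, "exp(coef)"]),
               ci_lower = unname(s$conf.int[, "lower .95"]),
               ci_upper = unname(s$conf.int[, "upper .95"]),
               p = unname(s$coefficients[, "Pr(>|z|)"]),
               model = type, n = sum(keep),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  if (type == "multivariate") return(one_fit(covariates))
  do.call(rbind, lapply(names(covariates), function(nm)
    one_fit(covariates[nm])))
}

#' @rdname cox_model
#' @param alpha univariate significance level gating entry to the
#'   multivariate model.
#' @param multivariate `"significant"` (default) or `"all"`.
#' @return `cox_report`: the univariate rows followed by the multivariate
#'   rows (covariates not entering the multivariate model are absent there).
#' @export
cox_report <- function(time, event, covariates, alpha = 0.05,
                       multivariate = c("significant", "all")) {
  multivariate <- match.arg(multivariate)
  uni <- cox_model(time, event, covariates, type = "univariate")
  selected <- if (multivariate == "all") names(covariates)
              else uni$covariate[uni$p < alpha]
  multi <- if (length(selected) >= 1L)
    cox_model(time, event, covariates[selected], type = "multivariate")
  else NULL
  rbind(uni, multi)
}

#' Time-dependent ROC AUC for censored outcomes
#'
#' Cumulative-cases / dynamic-controls AUC with inverse-probability-of-
#' censoring weights (IPCW) from the Kaplan-Meier estimate of the censoring
#' distribution. At horizon t, cases are patients with an observed event by
#' t (weighted by 1/G(T-)), controls are patients still at risk beyond t
#' (weighted by 1/G(t)); the AUC is the weighted probability that a random
#' case outscores a random control, ties counting one half. Without
#' censoring the estimator reduces exactly to the empirical case/control
#' concordance.
#'
#' @param scores per-patient risk scores (higher = worse prognosis).
#' @param time,event follow-up times and 0/1 event indicators.
#' @param eval_times evaluation horizons, in the units of `time` (or in
#'   years when `eval_in_years = TRUE`, converted at 365.25 days/year).
#' @param eval_in_years interpret `eval_times` as years with `time` in days.
#' @return data.frame with one row per usable horizon: `eval_time` (as
#'   supplied), `auc`, `n_cases`, `n_controls`; horizons with no cases or no
#'   controls are omitted with a warning. Attribute `estimator` names the
#'   method.
#' @export
time_dependent_auc <- function(scores, time, event, eval_times,
                               eval_in_years = FALSE) {
  stopifnot(length(scores) == length(time), length(time) == length(event))
  horizons <- if (eval_in_years) eval_times * 365.25 else eval_times
  cens_fit <- survfit(Surv(time, 1 - event) ~ 1)
  G_at <- function(u, left = FALSE) {
    idx <- findInterval(u, cens_fit$time, left.open = left)
    c(1, cens_fit$surv)[idx + 1L]
  }
  rows <- lapply(seq_along(horizons), function(h) {
    t0 <- horizons[h]
    case <- time <= t0 & event == 1
    control <- time > t0
    if (!any(case) || !any(control)) {
      warning("horizon ", eval_times[h],
              " omitted: no cases or no controls")
      return(NULL)
    }
    w_case <- 1 / G_at(time[case], left = TRUE)
    w_control <- rep(1 / G_at(t0), sum(control))
    ok <- is.finite(w_case)
    if (!all(ok)) {
      warning("cases with zero censoring-survival weight dropped at horizon ",
              eval_times[h])
      case[case][!ok] <- FALSE
      w_case <- w_case[ok]
    }
    s_case <- scores[case]
    s_control <- scores[control]
    comp <- outer(s_case, s_control, ">") + 0.5 * outer(s_case, s_control,
                                                        "==")
    wmat <- outer(w_case, w_control)
    data.frame(eval_time = eval_times[h],
               auc = sum(wmat * comp) / sum(wmat),
               n_cases = length(s_case), n_controls = length(s_control))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(eval_time = numeric(), auc = numeric(),
                      n_cases = integer(), n_controls = integer())
  attr(out, "estimator") <- "IPCW cumulative/dynamic"
  out
}

#' Discretise copy-number segment means into loss/neutral/gain calls
#'
#' Segment means below `-threshold` are called -1 (copy loss), above
#' `threshold` +1 (copy gain), and the closed interval
#' `[-threshold, threshold]` 0 (wild type). Default threshold 0.2.
#'
#' @param x finite numeric segment means.
#' @param threshold positive boundary (default 0.2); the boundary values
#'   themselves are wild type.
#' @return integer vector of calls in \{-1, 0, 1\}.
#' @export
discretize_segment_mean <- function(x, threshold = 0.2) {
  if (!all(is.finite(x))) stop("segment means must be finite")
  stopifnot(threshold > 0)
  as.integer(sign(x) * (abs(x) > threshold))
}

#' Compare per-gene CNV frequencies between risk groups
#'
#' For every gene, builds the 2x2 contingency of altered (call != 0) versus
#' wild type by risk group and tests it (chi-square when expected counts
#' allow, Fisher otherwise, as in the differential screen). Genes with no
#' variation anywhere, or absent from one group, are skipped with a warning.
#'
#' @param calls data.frame with columns `gene`, `sample` and either `call`
#'   (in \{-1,0,1\}) or `segment_mean` (discretised on the fly).
#' @param groups named vector sample id -> `"high"`/`"low"`.
#' @param alpha significance level for the `different` flag.
#' @param test `"auto"`, `"chisq"` or `"fisher"` (see [differential_pairs()]).
#' @return data.frame per tested gene: alteration frequencies per group,
#'   `p`, `test_used`, logical `different`.
#' @export
cnv_frequency_compare <- function(calls, groups, alpha = 0.05,
                                  test = c("auto", "chisq", "fisher")) {
  test <- match.arg(test)
  stopifnot(is.data.frame(calls), all(c("gene", "sample") %in% names(calls)))
  if (is.null(calls$call)) {
    if (is.null(calls$segment_mean))
      stop("`calls` needs a `call` or `segment_mean` column")
    calls$call <- discretize_segment_mean(calls$segment_mean)
  }
  missing <- setdiff(unique(calls$sample), names(groups))
  if (length(missing))
    stop("ungrouped samples: ", paste(missing, collapse = ", "))
  calls$group <- unname(groups[calls$sample])
  rows <- lapply(split(calls, calls$gene), function(df) {
    tab <- table(factor(df$group, c("high", "low")),
                 factor(df$call != 0, c(TRUE, FALSE)))
    if (any(rowSums(tab) == 0L)) {
      warning("gene ", df$gene[1L], " absent from one group; skipped")
      return(NULL)
    }
    if (sum(tab[, "TRUE"]) == 0L) {
      warning("gene ", df$gene[1L], " has no variation; skipped")
      return(NULL)
    }
    res <- assoc_p_2x2(tab["high", "TRUE"], tab["low", "TRUE"],
                       sum(tab["high", ]), sum(tab["low", ]), test = test)
    data.frame(gene = df$gene[1L],
               freq_high = tab["high", "TRUE"] / sum(tab["high", ]),
               freq_low = tab["low", "TRUE"] / sum(tab["low", ]),
               n_high = sum(tab["high", ]), n_low = sum(tab["low", ]),
               p = unname(res["p"]),
               test_used = c("chisq", "fisher")[res["fisher"] + 1L],
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(NULL)
  out$different <- out$p < alpha
  rownames(out) <- NULL
  out
}

#' Two-group comparison of a continuous measure
#'
#' Two-sided Wilcoxon rank-sum test: exact when the combined sample size is
#' at most 20 and there are no ties, normal approximation with continuity
#' and tie correction otherwise. If every value is tied across both groups
#' the comparison is vacuous and p = 1 is returned with a warning.
#'
#' @param values numeric measurements.
#' @param groups two-level group membership per value.
#' @return list with `statistic` (rank-sum W), `p_value`, `method`.
#' @export
group_difference <- function(values, groups) {
  groups <- as.factor(groups)
  stopifnot(nlevels(groups) == 2L, length(values) == length(groups))
  if (any(table(groups) == 0L)) stop("both groups must be non-empty")
  if (length(unique(values)) == 1L) {
    warning("all values tied across both groups; p = 1")
    return(list(statistic = NA_real_, p_value = 1,
                method = "degenerate (all tied)"))
  }
  x <- values[groups == levels(groups)[1L]]
  y <- values[groups == levels(groups)[2L]]
  exact <- length(values) <= 20L && !anyDuplicated(values)
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       method = wt$method)
}
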