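#' Per-pair 2x2 tumor/normal frequency tables
#'
#' Counts, for every pair, how many tumor and normal samples carry
#' indicator 1.
#'
#' @param irgp an `irgp_matrix` whose samples are labelled tumor/normal
#'   (either via its own `sample_labels` or the `labels` argument).
#' @param labels optional named character vector sample id -> tumor/normal,
#'   overriding the labels stored in `irgp`.
#' @return data.frame with one row per pair: `pair_id`, `ones_tumor`,
#'   `ones_normal`, `n_tumor`, `n_normal`.
#' @export
pair_group_counts <- function(irgp, labels = NULL) {
  stopifnot(inherits(irgp, "irgp_matrix"))
  labels <- labels %||% irgp$sample_labels
  if (is.null(labels)) stop("no tumor/normal labels available")
  samples <- colnames(irgp$values)
  missing <- setdiff(samples, names(labels))
  if (length(missing))
    stop("unlabelled samples: ", paste(missing, collapse = ", "))
  labels <- labels[samples]
  tumor <- labels == "tumor"
  data.frame(pair_id = rownames(irgp$values),
             ones_tumor = rowSums(irgp$values[, tumor, drop = FALSE]),
             ones_normal = rowSums(irgp$values[, !tumor, drop = FALSE]),
             n_tumor = sum(tumor), n_normal = sum(!tumor),
             stringsAsFactors = FALSE, row.names = NULL)
}

# Association p for one 2x2 table. Chi-square (Pearson, no continuity
# correction) when all expected counts are >= 5, Fisher's exact two-sided
# otherwise; a table with a zero margin carries no evidence and scores p = 1.
assoc_p_2x2 <- function(a, b, n1, n2, test = "auto") {
  tab <- matrix(c(a, n1 - a, b, n2 - b), nrow = 2L)
  if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L))
    return(c(p = 1, fisher = NA))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  use_fisher <- switch(test,
                       auto = any(expected < 5),
                       fisher = TRUE,
                       chisq = FALSE)
  if (use_fisher)
    c(p = fisher.test(tab)$p.value, fisher = 1)
  else
    c(p = suppressWarnings(chisq.test(tab, correct = FALSE)$p.value),
      fisher = 0)
}

#' Screen pairs for differential tumor/normal frequency
#'
#' Tests each pair's 2x2 indicator-by-group table. By default a Pearson
#' chi-square test (no continuity correction) is used when all expected
#' counts are at least 5 and Fisher's exact test otherwise; either test can
#' be forced. A pair is flagged differential when its (optionally
#' BH-adjusted) p-value falls below `alpha`.
#'
#' @param counts per-pair count table from [pair_group_counts()].
#' @param alpha significance level (default 0.05).
#' @param test `"auto"`, `"chisq"`, or `"fisher"`.
#' @param fdr apply Benjamini-Hochberg correction before flagging.
#' @return `counts` augmented with `assoc_p`, `test_used`
#'   (`"chisq"`/`"fisher"`/`NA` for zero-margin tables) and logical
#'   `differential`.
#' @export
differential_pairs <- function(counts, alpha = 0.05,
                               test = c("auto", "chisq", "fisher"),
                               fdr = FALSE) {
  test <- match.arg(test)
  stopifnot(alpha > 0, alpha < 1)
  if (counts$n_tumor[1L] == 0L || counts$n_normal[1L] == 0L)
    stop("both tumor and normal groups must be non-empty")
  res <- mapply(assoc_p_2x2, counts$ones_tumor, counts$ones_normal,
                counts$n_tumor, counts$n_normal,
                MoreArgs = list(test = test))
  counts$assoc_p <- res["p", ]
  counts$test_used <- c("chisq", "fisher")[res["fisher", ] + 1L]
  p_flag <- if (isTRUE(fdr)) p.adjust(counts$assoc_p, "BH") else counts$assoc_p
  counts$differential <- p_flag < alpha
  counts
}

#' Pairs differential in both cohorts
#'
#' @param results_cohort1,results_cohort2 screen tables from
#'   [differential_pairs()] computed over the same pair universe.
#' @return character vector of pair ids flagged differential in both.
#' @export
shared_differential <- function(results_cohort1, results_cohort2) {
  if (!setequal(results_cohort1$pair_id, results_cohort2$pair_id))
    stop("the two cohorts were screened over different pair universes")
  intersect(results_cohort1$pair_id[results_cohort1$differential],
            results_cohort2$pair_id[results_cohort2$differential])
}

#' Screen pairs for prognostic association
#'
#' For each pair, fits a univariate Cox proportional-hazards model (Efron
#' ties) on the binary indicator and runs a log-rank test between the
#' indicator-defined groups. A pair is flagged prognostic when the Wald Cox
#' p-value and the log-rank p-value both (rule `"and"`, the default) or
#' either (rule `"or"`) fall below `alpha`. Pairs with a constant indicator
#' among the analysed patients, or whose Cox fit has a monotone likelihood
#' (indicator perfectly separating the risk sets), are skipped with the
#' reason recorded.
#'
#' @param irgp an `irgp_matrix`.
#' @param clinical clinical table; only its samples are analysed and they
#'   must all be columns of `irgp`. Apply [filter_patients()] first.
#' @param alpha significance level.
#' @param rule `"and"` or `"or"` combination of the two tests.
#' @param fdr apply Benjamini-Hochberg correction to each test's p-values
#'   before flagging.
#' @return data.frame per pair: `pair_id`, `cox_hr`, `cox_p`, `logrank_p`,
#'   logical `prognostic` (NA when skipped), `skip_reason`.
#' @export
prognostic_pairs <- function(irgp, clinical, alpha = 0.05,
                             rule = c("and", "or"), fdr = FALSE) {
  stopifnot(inherits(irgp, "irgp_matrix"))
  rule <- match.arg(rule)
  validate_clinical(clinical)
  missing <- setdiff(clinical$sample_id, colnames(irgp$values))
  if (length(missing))
    stop("clinical samples absent from irgp matrix: ",
         paste(missing, collapse = ", "))
  vals <- irgp$values[, clinical$sample_id, drop = FALSE]
  y <- Surv(clinical$time_days, clinical$event)
  n <- nrow(vals)
  cox_hr <- cox_p <- logrank_p <- rep(NA_real_, n)
  reason <- rep(NA_character_, n)
  for (k in seq_len(n)) {
    ind <- vals[k, ]
    if (all(ind == ind[1L])) {
      reason[k] <- "constant indicator"
      next
    }
    fit <- tryCatch(
      withCallingHandlers(
        coxph(y ~ ind, ties = "efron"),
        warning = function(w) {
          if (grepl("infinite|converge", conditionMessage(w)))
            stop("monotone likelihood") else invokeRestart("muffleWarning")
        }),
      error = function(e) NULL)
    if (is.null(fit)) {
      reason[k] <- "non-convergent Cox fit (monotone likelihood)"
      next
    }
    s <- summary(fit)
    cox_hr[k] <- unname(s$coefficients[1L, "exp(coef)"])
    cox_p[k] <- unname(s$coefficients[1L, "Pr(>|z|)"])
    sd_ <- survdiff(y ~ ind)
    logrank_p[k] <- pchisq(sd_$chisq, df = 1L, lower.tail = FALSE)
  }
  pc <- if (isTRUE(fdr)) p.adjust(cox_p, "BH") else cox_p
  pl <- if (isTRUE(fdr)) p.adjust(logrank_p, "BH") else logrank_p
  prognostic <- if (rule == "and") pc < alpha & pl < alpha
                else pc < alpha | pl < alpha
  data.frame(pair_id = rownames(vals), cox_hr = cox_hr, cox_p = cox_p,
             logrank_p = logrank_p, prognostic = prognostic,
             skip_reason = reason, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Two-stage candidate screen across two cohorts
#'
#' Convenience orchestration of the full screen: flag pairs with differential
#' tumor/normal frequency in each cohort, intersect the two flagged sets, and
#' test the shared pairs for prognostic association in the first cohort's
#' filtered patients.
#'
#' @param irgp1,irgp2 labelled `irgp_matrix` objects over the same pair
#'   universe (one per cohort).
#' @param clinical1 clinical table for cohort 1 patients (pre-filtered with
#'   [filter_patients()]).
#' @param config a [pipeline_config()].
#' @return list with elements `screen1`, `screen2` (differential tables),
#'   `shared` (pair ids), `prognostic` (per-pair table over the shared set)
#'   and `candidates` (pair ids flagged prognostic).
#' @export
run_screen <- function(irgp1, irgp2, clinical1, config = pipeline_config()) {
  s1 <- differential_pairs(pair_group_counts(irgp1),
                           alpha = config$alpha_screen,
                           test = config$screen_test, fdr = config$fdr)
  s2 <- differential_pairs(pair_group_counts(irgp2),
                           alpha = config$alpha_screen,
                           test = config$screen_test, fdr = config$fdr)
  shared <- shared_differential(s1, s2)
  if (length(shared) == 0L)
    return(list(screen1 = s1, screen2 = s2, shared = character(),
                prognostic = NULL, candidates = character()))
  prog <- prognostic_pairs(subset_pairs(irgp1, shared), clinical1,
                           alpha = config$alpha_screen,
                           rule = config$prognostic_rule, fdr = config$fdr)
  list(screen1 = s1, screen2 = s2, shared = shared, prognostic = prog,
       candidates = prog$pair_id[which(prog$prognostic)])
}
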