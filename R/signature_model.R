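#' Fit an L1-penalised Cox signature on candidate pairs
#'
#' Maximises the L1-penalised Cox partial log-likelihood over the candidate
#' pair indicators. The penalty is chosen by k-fold cross-validated partial-
#' likelihood deviance at its minimum, with seeded fold assignment; folds are
#' redrawn (with a message) until every fold contains at least one event.
#' Indicators enter the fit unstandardised so the returned coefficients apply
#' directly to raw 0/1 indicators. Pairs with zero coefficient at the chosen
#' penalty are dropped from the returned model.
#'
#' @param irgp an `irgp_matrix` restricted to candidate (non-constant) pairs.
#' @param clinical clinical table of the patients to fit on.
#' @param config a [pipeline_config()] (folds and seed).
#' @param lambda optional fixed penalty (skips cross-validation); `0` gives
#'   the unpenalised partial-likelihood maximiser.
#' @return list with `model` (a [signature_model()] without cutoff) and
#'   `diagnostics`: `lambda` path, mean cross-validated deviance `cvm` with
#'   spread `cvsd`, `nzero` per penalty, `lambda_chosen`, `foldid`.
#' @export
fit_l1_cox <- function(irgp, clinical, config = pipeline_config(),
                       lambda = NULL) {
  stopifnot(inherits(irgp, "irgp_matrix"))
  validate_clinical(clinical)
  x <- t(irgp$values[, clinical$sample_id, drop = FALSE])
  y <- Surv(clinical$time_days, clinical$event)
  # glmnet needs >= 2 columns; pad single-pair fits with an inert zero column
  padded <- ncol(x) == 1L
  if (padded) x <- cbind(x, `..pad` = 0)
  if (!is.null(lambda)) {
    fit <- glmnet::glmnet(x, y, family = "cox", standardize = FALSE,
                          thresh = 1e-12)
    beta <- as.numeric(glmnet::coef.glmnet(fit, s = lambda, exact = TRUE,
                                           x = x, y = y))
    diagnostics <- list(lambda = lambda, lambda_chosen = lambda,
                        nzero = sum(beta != 0), foldid = NULL,
                        cvm = NULL, cvsd = NULL)
  } else {
    nfolds <- config$nfolds
    if (nrow(x) <= 2L * nfolds)
      stop("too few patients for ", nfolds, "-fold cross-validation")
    foldid <- NULL
    for (attempt in seq_len(20L)) {
      foldid <- with_seed(config$random_seed + attempt - 1L,
                          sample(rep_len(seq_len(nfolds), nrow(x))))
      if (all(vapply(split(clinical$event, foldid), sum, 0) > 0)) break
      message("fold without events; redrawing fold assignment")
      foldid <- NULL
    }
    if (is.null(foldid)) stop("could not form folds with events throughout")
    cv <- glmnet::cv.glmnet(x, y, family = "cox", foldid = foldid,
                            standardize = FALSE)
    beta <- as.numeric(glmnet::coef.glmnet(cv, s = "lambda.min"))
    diagnostics <- list(lambda = cv$lambda, cvm = cv$cvm, cvsd = cv$cvsd,
                        nzero = cv$nzero, lambda_chosen = cv$lambda.min,
                        foldid = foldid)
    if (all(beta == 0))
      stop("all coefficients shrink to zero along the entire penalty path; ",
           "extend the grid toward smaller penalties")
  }
  if (padded) beta <- beta[1L]
  keep <- which(beta != 0)
  model <- signature_model(irgp$pairs[keep, , drop = FALSE], beta[keep])
  list(model = model, diagnostics = diagnostics)
}

#' Risk score of indicator profiles
#'
#' The risk score is the linear predictor `sum_k coefficient_k * I_k` over
#' the model's pairs.
#'
#' @param indicators either a 0/1 vector aligned with the model's pair order,
#'   or a 0/1 matrix with one row per model pair (pairs x samples).
#' @param model a [signature_model()].
#' @return a numeric score (or one per sample column).
#' @export
compute_risk_score <- function(indicators, model) {
  stopifnot(inherits(model, "signature_model"))
  if (is.matrix(indicators)) {
    if (nrow(indicators) != length(model))
      stop("indicator matrix has ", nrow(indicators),
           " rows but the model has ", length(model), " pairs")
    drop(crossprod(indicators, model$coefficients))[seq_len(ncol(indicators))]
  } else {
    if (length(indicators) != length(model))
      stop("indicator vector has length ", length(indicators),
           " but the model has ", length(model), " pairs")
    sum(model$coefficients * indicators)
  }
}

#' Score every sample of an expression matrix with a signature
#'
#' Builds the model's pair indicators from the expression values and returns
#' the per-sample risk scores. Invariant to strictly monotone per-sample
#' transforms of the expression values.
#'
#' @param x an [expression_matrix()] containing all signature genes.
#' @param model a [signature_model()].
#' @return named numeric vector of risk scores (one per sample).
#' @export
signature_scores <- function(x, model) {
  stopifnot(inherits(x, "expression_matrix"),
            inherits(model, "signature_model"))
  missing <- setdiff(unique(c(model$pairs$gene_a, model$pairs$gene_b)),
                     rownames(x$values))
  if (length(missing))
    stop("signature genes absent from the matrix: ",
         paste(missing, collapse = ", "))
  irgp <- build_irgp_matrix(x, model$pairs)
  scores <- compute_risk_score(irgp$values, model)
  names(scores) <- colnames(x$values)
  scores
}

# Log-rank chi-square for a given high/low split (internal).
logrank_chisq <- function(time, event, high) {
  survdiff(Surv(time, event) ~ high)$chisq
}

#' Optimal risk-score cutoff by log-rank maximisation
#'
#' Scans the midpoints of adjacent sorted unique scores and returns the
#' candidate maximising the two-sample log-rank statistic between the induced
#' high/low groups, subject to each group holding at least
#' `min_group_frac` of the patients (maximally selected rank statistic). On
#' ties the smallest maximising cutoff is returned.
#'
#' @param scores per-patient risk scores (at least two distinct values).
#' @param time,event follow-up times and 0/1 event indicators.
#' @param min_group_frac smallest admissible group fraction (default 0.1).
#' @return the selected cutoff (a real number strictly between two observed
#'   scores).
#' @export
find_optimal_cutoff <- function(scores, time, event, min_group_frac = 0.1) {
  stopifnot(length(scores) == length(time), length(time) == length(event))
  if (sum(event) == 0L) stop("no events; cutoff search undefined")
  u <- sort(unique(scores))
  if (length(u) < 2L) stop("need at least two distinct scores")
  candidates <- (u[-1L] + u[-length(u)]) / 2
  n <- length(scores)
  feasible <- vapply(candidates, function(cut) {
    n_high <- sum(scores > cut)
    min(n_high, n - n_high) >= min_group_frac * n
  }, logical(1L))
  if (!any(feasible))
    stop("no cutoff satisfies the minimum group-size constraint")
  candidates <- candidates[feasible]
  stat <- vapply(candidates, function(cut)
    logrank_chisq(time, event, scores > cut), numeric(1L))
  candidates[which.max(stat)]
}

#' Classify patients into high/low risk
#'
#' `group` is `"high"` exactly when `risk_score > cutoff`; scores equal to
#' the cutoff are assigned to the low-risk group.
#'
#' @param scores named (or unnamed) numeric risk scores.
#' @param cutoff finite risk-score threshold.
#' @return data.frame with `sample_id`, `risk_score`, and `group`
#'   (`"high"`/`"low"`).
#' @export
classify_patients <- function(scores, cutoff) {
  stopifnot(is.finite(cutoff), length(cutoff) == 1L)
  data.frame(sample_id = names(scores) %||% as.character(seq_along(scores)),
             risk_score = unname(scores),
             group = ifelse(scores > cutoff, "high", "low"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Apply the published 37-pair signature to an expression matrix
#'
#' Builds the 37 published pair indicators, scores each sample with the
#' published coefficients, and classifies at the published cutoff of -0.13.
#' Because the signature depends only on within-sample orderings, the
#' assignment is identical under any strictly monotone per-sample transform
#' of the expression values (so RNA-seq and microarray inputs need no joint
#' normalisation).
#'
#' @param x an [expression_matrix()] containing all 2 x 37 signature genes
#'   (missing genes raise an error listing them).
#' @return data.frame with `sample_id`, `risk_score`, `group`.
#' @export
apply_published_signature <- function(x) {
  model <- load_signature_fixture()
  classify_patients(signature_scores(x, model), model$cutoff)
}
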