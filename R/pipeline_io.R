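#' Expression matrix container
#'
#' Bundles a numeric gene-by-sample matrix with per-sample tumor/normal labels
#' and a cohort identifier. Gene and sample identifiers are the matrix
#' dimnames and must be unique; values must be finite.
#'
#' @param values numeric matrix, genes in rows and samples in columns, with
#'   complete `rownames` and `colnames`.
#' @param sample_labels optional named character vector mapping sample ids to
#'   `"tumor"` or `"normal"`.
#' @param cohort_id cohort name carried through the pipeline.
#' @return an object of class `"expression_matrix"`: a list with elements
#'   `values`, `sample_labels`, `cohort_id`.
#' @export
expression_matrix <- function(values, sample_labels = NULL,
                              cohort_id = "cohort") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (nrow(values) == 0L || ncol(values) == 0L)
    stop("expression matrix is empty")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry gene rownames and sample colnames")
  dup <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup))
    stop("duplicate gene ids: ", paste(dup, collapse = ", "),
         "; collapse probes to genes with collapse_probes()")
  dup <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup))
    stop("duplicate sample ids: ", paste(dup, collapse = ", "))
  if (!all(is.finite(values)))
    stop("expression values must be finite")
  if (!is.null(sample_labels)) {
    if (is.null(names(sample_labels)))
      stop("`sample_labels` must be named by sample id")
    bad <- setdiff(sample_labels, c("tumor", "normal"))
    if (length(bad))
      stop("sample labels must be 'tumor' or 'normal'; found: ",
           paste(unique(bad), collapse = ", "))
    missing <- setdiff(colnames(values), names(sample_labels))
    if (length(missing))
      stop("unlabelled samples: ", paste(missing, collapse = ", "))
    sample_labels <- sample_labels[colnames(values)]
  }
  structure(list(values = values, sample_labels = sample_labels,
                 cohort_id = as.character(cohort_id)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix '%s': %d genes x %d samples\n",
              x$cohort_id, nrow(x$values), ncol(x$values)))
  if (!is.null(x$sample_labels)) {
    tab <- table(x$sample_labels)
    cat("  labels:", paste(sprintf("%s=%d", names(tab), tab),
                           collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

sniff_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

#' Read a gene-by-sample expression matrix from delimited text
#'
#' The file must have a header row of sample ids and gene ids in the first
#' column; tab or comma delimited (detected from the header line). Rows
#' containing any non-numeric value are dropped with a warning. Duplicate gene
#' ids are an error directing the caller to [collapse_probes()].
#'
#' @param path file path.
#' @param cohort_id cohort name to attach.
#' @param label_map optional named character vector sample id -> tumor/normal.
#' @return an [expression_matrix()].
#' @export
read_expression_matrix <- function(path, cohort_id = "cohort",
                                   label_map = NULL) {
  raw <- read.delim(path, sep = sniff_sep(path), check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(raw) < 2L || nrow(raw) == 0L)
    stop("empty expression matrix in ", path)
  ids <- as.character(raw[[1L]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate gene ids in ", path, ": ", paste(dup, collapse = ", "),
         "; collapse probes to genes with collapse_probes()")
  num <- raw[-1L]
  num[] <- lapply(num, function(col) {
    if (is.numeric(col)) col else suppressWarnings(as.numeric(col))
  })
  ok <- complete.cases(num)
  if (!all(ok)) {
    warning(sum(!ok), " row(s) with non-numeric values dropped: ",
            paste(head(ids[!ok], 5L), collapse = ", "))
    num <- num[ok, , drop = FALSE]
    ids <- ids[ok]
  }
  if (nrow(num) == 0L) stop("no numeric rows in ", path)
  values <- as.matrix(num)
  rownames(values) <- ids
  expression_matrix(values, sample_labels = label_map, cohort_id = cohort_id)
}

#' Write an expression matrix as tab-separated text
#'
#' @param x an [expression_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(inherits(x, "expression_matrix"))
  df <- data.frame(gene_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Collapse probe-level rows to gene level
#'
#' For genes measured by several probes, retains the probe with the largest
#' mean expression across samples; ties keep the probe occurring earlier in
#' the input row order. Probes absent from the mapping are dropped.
#'
#' @param x an [expression_matrix()] whose rows are probe ids.
#' @param probe_to_gene named character vector: names are probe ids, values
#'   gene ids.
#' @return an [expression_matrix()] with one row per mapped gene.
#' @export
collapse_probes <- function(x, probe_to_gene) {
  stopifnot(inherits(x, "expression_matrix"))
  if (length(probe_to_gene) == 0L) stop("`probe_to_gene` mapping is empty")
  if (is.null(names(probe_to_gene)))
    stop("`probe_to_gene` must be named by probe id")
  present <- intersect(rownames(x$values), names(probe_to_gene))
  if (length(present) == 0L)
    stop("no probes in the matrix are covered by the mapping")
  means <- rowMeans(x$values[present, , drop = FALSE])
  genes <- probe_to_gene[present]
  # first-occurrence order of genes; within gene, which.max keeps the
  # earliest probe on ties
  keep <- vapply(unique(unname(genes)), function(g) {
    probes <- present[genes == g]
    probes[which.max(means[probes])]
  }, character(1L))
  values <- x$values[keep, , drop = FALSE]
  rownames(values) <- names(keep)
  expression_matrix(values, sample_labels = x$sample_labels,
                    cohort_id = x$cohort_id)
}

#' Log-transform non-negative expression values
#'
#' Replaces every value `v` by `log2(v + 1)`, the usual compression applied to
#' TPM/FPKM abundances. Strictly monotone, so all within-sample orderings
#' (and hence every gene-pair indicator) are preserved.
#'
#' @param x an [expression_matrix()] with non-negative values.
#' @return the transformed [expression_matrix()].
#' @export
log_transform_tpm <- function(x) {
  stopifnot(inherits(x, "expression_matrix"))
  if (any(x$values < 0))
    stop("log_transform_tpm requires non-negative values")
  x$values <- log2(x$values + 1)
  x
}

#' Pipeline configuration
#'
#' Collects the tunable policy knobs of the pipeline with the defaults used
#' throughout: screen significance 0.05, a strict >30-day follow-up filter,
#' a 7:3 stratified split, the full ordered pair convention, chi-square with
#' Fisher fallback, and an AND combination of the two prognostic tests.
#'
#' @param alpha_screen significance level for both screening stages.
#' @param min_followup_days patients must have survival time strictly greater
#'   than this to enter prognostic screening.
#' @param split_ratio training fraction for the stratified cohort split.
#' @param pair_convention `"paper"` (full ordered product with self-pairs,
#'   n^2 pairs) or `"unordered"` (i < j, n(n-1)/2 pairs).
#' @param screen_test `"auto"` (chi-square when all expected counts >= 5,
#'   Fisher otherwise), `"chisq"`, or `"fisher"`.
#' @param prognostic_rule `"and"` requires both Cox and log-rank p below
#'   `alpha_screen`; `"or"` requires either.
#' @param fdr apply Benjamini-Hochberg correction to screen p-values before
#'   flagging (off by default; the screens use raw p-values).
#' @param cutoff_min_group_frac smallest fraction of patients allowed in
#'   either risk group during the optimal-cutoff search.
#' @param nfolds cross-validation folds for the penalised Cox fit.
#' @param random_seed integer seed for the split and fold assignment.
#' @return a list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(alpha_screen = 0.05, min_followup_days = 30,
                            split_ratio = 0.7,
                            pair_convention = c("paper", "unordered"),
                            screen_test = c("auto", "chisq", "fisher"),
                            prognostic_rule = c("and", "or"),
                            fdr = FALSE,
                            cutoff_min_group_frac = 0.1,
                            nfolds = 10L, random_seed = 1L) {
  stopifnot(alpha_screen > 0, alpha_screen < 1,
            split_ratio > 0, split_ratio < 1,
            min_followup_days >= 0,
            cutoff_min_group_frac >= 0, cutoff_min_group_frac < 0.5)
  structure(list(alpha_screen = alpha_screen,
                 min_followup_days = min_followup_days,
                 split_ratio = split_ratio,
                 pair_convention = match.arg(pair_convention),
                 screen_test = match.arg(screen_test),
                 prognostic_rule = match.arg(prognostic_rule),
                 fdr = isTRUE(fdr),
                 cutoff_min_group_frac = cutoff_min_group_frac,
                 nfolds = as.integer(nfolds),
                 random_seed = as.integer(random_seed)),
            class = "pipeline_config")
}

clinical_columns <- c("sample_id", "time_days", "event", "endpoint",
                      "age", "sex", "stage_t", "stage_n", "stage_m")

#' Validate a clinical table
#'
#' Checks the column contract shared by the pipeline: one row per sample with
#' follow-up time in days, an event indicator in \{0, 1\} (NA allowed and
#' treated as unknown status), an endpoint label (`"OS"` or `"DSS"`), age,
#' sex, and T/N/M stage codes. Unknown stage codes (TX/NX/MX/NA) are kept as
#' their own levels, never dropped.
#'
#' @param clinical a data.frame.
#' @return the validated data.frame, invisibly usable downstream.
#' @export
validate_clinical <- function(clinical) {
  missing <- setdiff(clinical_columns, names(clinical))
  if (length(missing))
    stop("clinical table lacks columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(clinical$sample_id))
    stop("duplicate sample ids in clinical table")
  if (any(is.na(clinical$time_days)) || any(clinical$time_days < 0))
    stop("survival times must be present and >= 0")
  ev <- clinical$event
  if (!all(ev[!is.na(ev)] %in% c(0, 1)))
    stop("event must be 0 (censored), 1 (event) or NA (unknown)")
  if (!all(clinical$endpoint %in% c("OS", "DSS")))
    stop("endpoint must be 'OS' or 'DSS'")
  clinical
}

#' Read / write the clinical table
#'
#' Tab-separated with the columns `sample_id, time_days, event, endpoint,
#' age, sex, stage_t, stage_n, stage_m`.
#'
#' @param path file path.
#' @return `read_clinical_table`: the validated data.frame.
#' @export
read_clinical_table <- function(path) {
  df <- read.delim(path, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE,
                   colClasses = c(stage_t = "character",
                                  stage_n = "character",
                                  stage_m = "character"))
  validate_clinical(df)
}

#' @rdname read_clinical_table
#' @param clinical a validated clinical data.frame.
#' @export
write_clinical_table <- function(clinical, path) {
  validate_clinical(clinical)
  write.table(clinical[clinical_columns], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Filter patients for prognostic analysis
#'
#' Retains patients with follow-up strictly greater than
#' `config$min_followup_days` (default 30 days) and a known event status.
#'
#' @param clinical a clinical data.frame (see [validate_clinical()]).
#' @param config a [pipeline_config()].
#' @return the filtered clinical table (possibly empty, with a warning).
#' @export
filter_patients <- function(clinical, config = pipeline_config()) {
  validate_clinical(clinical)
  keep <- clinical$time_days > config$min_followup_days &
    !is.na(clinical$event)
  out <- clinical[keep, , drop = FALSE]
  if (nrow(out) == 0L)
    warning("no patients pass the follow-up/event filter")
  rownames(out) <- NULL
  out
}

#' Stratified training/testing split
#'
#' Randomly partitions patients into training and testing sets at
#' `config$split_ratio`, stratified by T stage so the stage composition of
#' both parts matches the cohort. Unknown stage codes form their own stratum.
#' Within each stratum `ceiling(ratio * n)` patients go to training, so a
#' singleton stratum is always assigned to training. Deterministic given
#' `config$random_seed`.
#'
#' @param clinical a clinical data.frame.
#' @param config a [pipeline_config()].
#' @return list with character vectors `training` and `testing` of sample
#'   ids (a partition of `clinical$sample_id`).
#' @export
split_cohort <- function(clinical, config = pipeline_config()) {
  validate_clinical(clinical)
  stage <- as.character(clinical$stage_t)
  stage[is.na(stage) | stage == ""] <- "NA"
  ids_by_stratum <- split(clinical$sample_id, stage)
  with_seed(config$random_seed, {
    train <- unlist(lapply(ids_by_stratum, function(ids) {
      n_train <- ceiling(config$split_ratio * length(ids))
      if (length(ids) == 1L) {
        message("stratum of size 1 assigned to training")
        return(ids)
      }
      sample(ids, n_train)
    }), use.names = FALSE)
  })
  list(training = sort(train),
       testing = sort(setdiff(clinical$sample_id, train)))
}

#' Gene-pair signature model
#'
#' An ordered list of gene pairs with one coefficient per pair and an
#' optional risk-score cutoff dichotomising patients into high/low risk.
#'
#' @param pairs data.frame with character columns `gene_a`, `gene_b`.
#' @param coefficients numeric vector, one finite value per pair.
#' @param cutoff optional risk-score threshold (`NULL` until chosen).
#' @return an object of class `"signature_model"`.
#' @export
signature_model <- function(pairs, coefficients, cutoff = NULL) {
  stopifnot(is.data.frame(pairs), all(c("gene_a", "gene_b") %in% names(pairs)))
  pairs <- data.frame(gene_a = as.character(pairs$gene_a),
                      gene_b = as.character(pairs$gene_b),
                      stringsAsFactors = FALSE)
  if (nrow(pairs) != length(coefficients))
    stop("one coefficient per pair required")
  if (!all(is.finite(coefficients)))
    stop("coefficients must be finite")
  if (anyDuplicated(pair_ids(pairs)))
    stop("duplicate pairs in signature")
  if (!is.null(cutoff)) stopifnot(is.finite(cutoff), length(cutoff) == 1L)
  structure(list(pairs = pairs, coefficients = as.numeric(coefficients),
                 cutoff = cutoff),
            class = "signature_model")
}

#' @export
print.signature_model <- function(x, ...) {
  cat(sprintf("signature_model: %d gene pairs, cutoff %s\n",
              nrow(x$pairs),
              if (is.null(x$cutoff)) "unset" else format(x$cutoff)))
  invisible(x)
}

#' @export
length.signature_model <- function(x) nrow(x$pairs)

#' Read / write a signature model file
#'
#' Tab-separated with columns `gene_a, gene_b, coefficient` and an optional
#' leading comment line `# cutoff: <value>`.
#'
#' @param path file path.
#' @return `read_signature_model`: a [signature_model()].
#' @export
read_signature_model <- function(path) {
  lines <- readLines(path)
  cutoff <- NULL
  cut_line <- grep("^#\\s*cutoff:", lines)
  if (length(cut_line))
    cutoff <- as.numeric(sub("^#\\s*cutoff:\\s*", "", lines[cut_line[1L]]))
  df <- read.delim(text = lines[!grepl("^#", lines)], sep = "\t",
                   stringsAsFactors = FALSE)
  signature_model(df[c("gene_a", "gene_b")], df$coefficient, cutoff = cutoff)
}

#' @rdname read_signature_model
#' @param model a [signature_model()].
#' @export
write_signature_model <- function(model, path) {
  stopifnot(inherits(model, "signature_model"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(model$cutoff))
    writeLines(sprintf("# cutoff: %s", format(model$cutoff)), con)
  df <- data.frame(model$pairs, coefficient = model$coefficients)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# md5 of the bundled 37-pair signature file; guards against silent edits.
.table2_md5 <- "7837c105b7c8bb8545a6bfb762dfea2f"

#' Load the published 37-pair bladder-cancer signature
#'
#' Returns the bundled prognostic model: 37 immune gene pairs with their
#' L1-penalised Cox coefficients and the published risk-score cutoff of
#' -0.13. The fixture file is checksummed at load.
#'
#' @return a [signature_model()] with 37 pairs and cutoff -0.13.
#' @export
load_signature_fixture <- function() {
  path <- system.file("extdata", "table2_signature.tsv", package = "irgpsig",
                      mustWork = TRUE)
  md5 <- unname(md5sum(path))
  if (!identical(md5, .table2_md5))
    stop("signature fixture checksum mismatch (expected ", .table2_md5,
         ", got ", md5, "); the bundled file is corrupted")
  model <- read_signature_model(path)
  if (length(model) != 37L || is.null(model$cutoff))
    stop("signature fixture malformed")
  model
}
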