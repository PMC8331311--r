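# Shared fixtures and oracles built in code.

# Small labelled expression matrix with reproducible random values.
rand_expr <- function(n_genes = 6, n_samples = 4, seed = 1, genes = NULL,
                      labels = NULL, cohort = "test") {
  set.seed(seed)
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(n_genes))
  samples <- sprintf("s%02d", seq_len(n_samples))
  values <- matrix(runif(length(genes) * n_samples, 0, 10),
                   length(genes), n_samples,
                   dimnames = list(genes, samples))
  expression_matrix(values, sample_labels = labels, cohort_id = cohort)
}

# Minimal clinical table around supplied survival data.
make_clinical <- function(time, event, ids = NULL, stage_t = "T2",
                          age = 65, sex = "male") {
  n <- length(time)
  data.frame(sample_id = ids %||% sprintf("s%03d", seq_len(n)),
             time_days = time, event = event, endpoint = "OS",
             age = rep_len(age, n), sex = rep_len(sex, n),
             stage_t = rep_len(stage_t, n), stage_n = "N0", stage_m = "M0",
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Hand-rolled irgp_matrix from a raw 0/1 matrix (rownames "a|b").
make_irgp <- function(values, labels = NULL) {
  parts <- strsplit(rownames(values), "|", fixed = TRUE)
  structure(list(pairs = data.frame(gene_a = vapply(parts, `[`, "", 1L),
                                    gene_b = vapply(parts, `[`, "", 2L),
                                    stringsAsFactors = FALSE),
                 values = values, sample_labels = labels,
                 cohort_id = "test"),
            class = "irgp_matrix")
}

# Expression values satisfying "gene_a < gene_b for every signature pair
# except those listed in `reversed`", solved by longest-path layering of the
# pairwise ordering constraints.
signature_consistent_expr <- function(model, reversed = character()) {
  pairs <- model$pairs
  lo <- ifelse(pair_ids(pairs) %in% reversed, pairs$gene_b, pairs$gene_a)
  hi <- ifelse(pair_ids(pairs) %in% reversed, pairs$gene_a, pairs$gene_b)
  genes <- unique(c(pairs$gene_a, pairs$gene_b))
  val <- setNames(rep(0, length(genes)), genes)
  for (iter in seq_len(length(genes) + 1L)) {
    changed <- FALSE
    for (e in seq_along(lo)) {
      if (val[lo[e]] >= val[hi[e]]) {
        val[hi[e]] <- val[lo[e]] + 1
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  stopifnot(!changed)  # the ordering constraints must be acyclic
  matrix(val, ncol = 1, dimnames = list(genes, "s01"))
}

# Independent log-rank chi-square: direct observed-minus-expected sums over
# event times (two groups), no survival-package code.
logrank_oracle <- function(time, event, group) {
  group <- as.integer(as.factor(group)) - 1L
  o_minus_e <- 0
  v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == 1L)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == 1L)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o_minus_e)^2 / v
}

# Two-sided Fisher p by explicit hypergeometric enumeration (the same
# probability-ordering rule as the classical exact test).
fisher_oracle <- function(a, b, c_, d) {
  m <- a + b          # row 1 total
  n <- c_ + d         # row 2 total
  k <- a + c_         # column 1 total
  if (k == 0L || k == m + n || m == 0L || n == 0L) return(1)
  support <- max(0L, k - n):min(m, k)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# End-to-end pipeline on one simulated study: enumerate, screen in both
# cohorts, fit the penalised signature on cohort 1.
simulate_and_fit <- function(seed, params = simulation_params(seed = seed)) {
  st <- simulate_study(params)
  pairs <- enumerate_pairs(rownames(st$cohort1$expr$values))
  i1 <- drop_degenerate_pairs(build_irgp_matrix(st$cohort1$expr, pairs))
  i2 <- drop_degenerate_pairs(build_irgp_matrix(st$cohort2$expr, pairs))
  common <- intersect(rownames(i1$values), rownames(i2$values))
  i1 <- subset_pairs(i1, common)
  i2 <- subset_pairs(i2, common)
  cl <- filter_patients(st$cohort1$clinical)
  sc <- run_screen(i1, i2, cl)
  fit <- fit_l1_cox(subset_pairs(i1, sc$candidates), cl,
                    pipeline_config(random_seed = seed))
  list(study = st, clinical = cl, irgp = i1, screen = sc, fit = fit)
}

# Fraction of planted pairs present (in either orientation) in a selected
# pair-id set.
recovered_fraction <- function(signal_pairs, selected_ids) {
  fwd <- pair_ids(signal_pairs)
  rev <- paste(signal_pairs$gene_b, signal_pairs$gene_a, sep = "|")
  mean(fwd %in% selected_ids | rev %in% selected_ids)
}
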