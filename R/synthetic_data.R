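# Registry of named strictly increasing transforms used to emulate
# platform-specific monotone distortions (RNA-seq vs microarray scales).
.platform_transforms <- list(
  identity = function(v) v,
  affine = function(v) 2 * v + 3,
  log1p = function(v) log1p(v),
  sqrt = function(v) sqrt(v),
  exp = function(v) exp(v / 4),
  rank_preserving_power = function(v) v^1.5
)

resolve_transform <- function(transform, values = NULL) {
  if (is.character(transform)) {
    f <- .platform_transforms[[transform]]
    if (is.null(f))
      stop("unknown platform transform '", transform, "'; known monotone ",
           "transforms: ", paste(names(.platform_transforms), collapse = ", "))
    return(f)
  }
  stopifnot(is.function(transform))
  if (!is.null(values)) {
    probe <- sort(unique(as.numeric(values)))
    if (length(probe) > 1L && any(diff(transform(probe)) <= 0))
      stop("transform is not strictly increasing on the value range")
  }
  transform
}

#' Apply a monotone platform transform to an expression matrix
#'
#' Applies a strictly increasing map elementwise, emulating a platform's
#' monotone distortion of the measurement scale. Within-sample rank order is
#' unchanged, so every gene-pair indicator derived from the matrix is
#' invariant.
#'
#' @param x an [expression_matrix()].
#' @param transform a name from the built-in registry (`"identity"`,
#'   `"affine"`, `"log1p"`, `"sqrt"`, `"exp"`, `"rank_preserving_power"`) or
#'   a function, which is verified to be strictly increasing on the observed
#'   value range.
#' @return the transformed [expression_matrix()].
#' @export
apply_platform_transform <- function(x, transform) {
  stopifnot(inherits(x, "expression_matrix"))
  f <- resolve_transform(transform, values = x$values)
  out <- f(x$values)
  if (!all(is.finite(out)))
    stop("transform produced non-finite values")
  x$values[] <- out
  x
}

#' Parameters of the synthetic dual-cohort study
#'
#' Defines the generative model the pipeline is tested against: two cohorts
#' sharing gene-level latent means (so within-sample orderings agree) but
#' observed through different monotone platform distortions; tumor/normal
#' labels; signal pairs whose within-sample ordering is flipped in a random
#' subset of tumors; exponential proportional-hazards survival driven by the
#' pair indicators and clinical covariates; and independent uniform
#' censoring.
#'
#' @param n_genes number of genes per cohort.
#' @param n_tumor,n_normal samples per cohort.
#' @param n_signal_pairs planted prognostic pairs (each uses two dedicated
#'   genes, so `2 * n_signal_pairs <= n_genes`).
#' @param pair_effect_sizes log-hazard weight per planted pair; default
#'   alternates +0.8 / -0.8.
#' @param flip_prob_tumor marginal probability a tumor sample flips a signal
#'   pair's ordering (normals keep the reference ordering up to noise).
#' @param flip_correlation SD (logit scale) of a per-sample aggressiveness
#'   latent shared by all signal pairs: a tumor's flip probability is
#'   `plogis(qlogis(flip_prob_tumor) + flip_correlation * a)` with
#'   `a ~ N(0, 1)`, with the sign of each pair's effect orienting the shift
#'   so hazard-raising orderings co-occur in aggressive tumors. Zero gives
#'   independent flips; positive values reproduce the correlated block
#'   structure real prognostic features show along a disease aggressiveness
#'   axis.
#' @param signal_gap separation (log2 units) between the two genes of a
#'   signal pair; large relative to `noise_sd` so the ordering is reliable.
#' @param noise_sd per-value Gaussian noise SD (log2 units).
#' @param baseline_hazard events/day at linear predictor 0.
#' @param censor_window censoring drawn uniformly on (0, `censor_window`)
#'   days; `Inf` disables censoring.
#' @param clinical_effects named log-hazard weights `age` (per SD of age)
#'   and `stage` (per ordinal T-stage level above T2).
#' @param platform_transforms length-2 character vector naming the monotone
#'   distortion applied to each cohort.
#' @param seed integer seed; the whole study is a deterministic function of
#'   the parameters.
#' @return a list of class `"simulation_params"`.
#' @export
simulation_params <- function(n_genes = 100L, n_tumor = 300L, n_normal = 50L,
                              n_signal_pairs = 20L,
                              pair_effect_sizes = NULL,
                              flip_prob_tumor = 0.5,
                              flip_correlation = 1.5,
                              signal_gap = 2, noise_sd = 0.4,
                              baseline_hazard = 5e-4,
                              censor_window = 3000,
                              clinical_effects = c(age = 0.3, stage = 0.2),
                              platform_transforms = c("identity", "log1p"),
                              seed = 1L) {
  if (is.null(pair_effect_sizes))
    pair_effect_sizes <- rep_len(c(0.8, -0.8), n_signal_pairs)
  stopifnot(length(pair_effect_sizes) == n_signal_pairs,
            flip_prob_tumor >= 0, flip_prob_tumor <= 1,
            flip_correlation >= 0,
            baseline_hazard > 0, censor_window > 0,
            signal_gap > 0, noise_sd > 0,
            length(platform_transforms) == 2L,
            all(c("age", "stage") %in% names(clinical_effects)))
  if (2L * n_signal_pairs > n_genes)
    stop("n_signal_pairs exceeds pair capacity: need 2 genes per signal pair")
  for (tr in platform_transforms) resolve_transform(tr)
  structure(list(n_genes = as.integer(n_genes),
                 n_tumor = as.integer(n_tumor),
                 n_normal = as.integer(n_normal),
                 n_signal_pairs = as.integer(n_signal_pairs),
                 pair_effect_sizes = as.numeric(pair_effect_sizes),
                 flip_prob_tumor = flip_prob_tumor,
                 flip_correlation = flip_correlation,
                 signal_gap = signal_gap, noise_sd = noise_sd,
                 baseline_hazard = baseline_hazard,
                 censor_window = censor_window,
                 clinical_effects = clinical_effects,
                 platform_transforms = platform_transforms,
                 seed = as.integer(seed)),
            class = "simulation_params")
}

# T/N/M stage frequencies loosely matching a muscle-invasive bladder-cancer
# cohort (mostly T2-T4, nodal spread in a minority, distant status often
# unassessed).
.stage_t_weights <- c(T0 = 0.005, T1 = 0.015, T2 = 0.35, T3 = 0.47,
                      T4 = 0.15, TX = 0.01)
.stage_n_weights <- c(N0 = 0.57, N1 = 0.11, N2 = 0.19, N3 = 0.02, NX = 0.11)
.stage_m_weights <- c(M0 = 0.48, M1 = 0.03, MX = 0.49)

draw_truncated_age <- function(n, mean = 68, sd = 8, lo = 34, hi = 89) {
  age <- round(rnorm(n, mean, sd))
  while (any(bad <- age < lo | age > hi))
    age[bad] <- round(rnorm(sum(bad), mean, sd))
  age
}

# Shared latent layout of gene-level means, drawn once per study so both
# cohorts agree on every within-sample ordering of latent means. Each
# signal pair owns a private value band in which its two genes swap when a
# sample flips; the bands are pairwise disjoint and separated from every
# background gene, so the only non-constant indicator involving a signal
# gene is the pair's own. Without this exclusivity, a third gene inside a
# band yields an indicator column collinear with the planted one and the
# planted pair stops being identifiable by any selection method. The latent
# scale is arbitrary: the pipeline only ever uses within-sample orderings.
gene_layout <- function(params) {
  n_genes <- params$n_genes
  k <- params$n_signal_pairs
  genes <- sprintf("g%04d", seq_len(n_genes))
  baseline <- numeric(n_genes)
  half <- params$signal_gap / 2
  margin <- 2 * params$noise_sd
  spacing <- params$signal_gap + margin
  centre <- if (k > 0L) 4 + half + (seq_len(k) - 1L) * spacing else numeric()
  if (k > 0L) {
    baseline[2L * seq_len(k) - 1L] <- centre - half  # gene_a reference: low
    baseline[2L * seq_len(k)] <- centre + half       # gene_b reference: high
  }
  n_bg <- n_genes - 2L * k
  lo_band <- if (k > 0L) min(centre) - half else 7
  hi_band <- if (k > 0L) max(centre) + half else 7
  bg <- c(runif(ceiling(n_bg / 2), lo_band - 3 - margin, lo_band - margin),
          runif(floor(n_bg / 2), hi_band + margin, hi_band + margin + 3))
  if (n_bg > 0L) baseline[2L * k + seq_len(n_bg)] <- sample(bg)
  list(genes = genes, baseline = baseline, centre = centre)
}

simulate_cohort <- function(params, layout, cohort_id, transform) {
  n_genes <- params$n_genes
  n_s <- params$n_tumor + params$n_normal
  genes <- layout$genes
  samples <- sprintf("%s_s%04d", cohort_id, seq_len(n_s))
  labels <- setNames(rep(c("tumor", "normal"),
                         c(params$n_tumor, params$n_normal)), samples)
  mu <- matrix(layout$baseline, n_genes, n_s, dimnames = list(genes, samples))
  k <- params$n_signal_pairs
  flips <- matrix(0L, k, n_s, dimnames = list(NULL, samples))
  if (k > 0L) {
    idx_a <- 2L * seq_len(k) - 1L
    idx_b <- 2L * seq_len(k)
    tumor_cols <- which(labels == "tumor")
    aggressiveness <- rnorm(length(tumor_cols))
    # the latent pushes each pair's flip in its own risk direction, so
    # hazard-raising orderings co-occur in aggressive tumors and
    # hazard-lowering ones in indolent tumors
    p_flip <- plogis(qlogis(params$flip_prob_tumor) +
                       outer(sign(params$pair_effect_sizes),
                             params$flip_correlation * aggressiveness))
    flips[, tumor_cols] <- matrix(
      rbinom(k * length(tumor_cols), 1L, as.vector(p_flip)),
      k, length(tumor_cols))
    for (j in seq_len(k)) {
      fl <- which(flips[j, ] == 1L)
      if (length(fl)) {
        tmp <- mu[idx_a[j], fl]
        mu[idx_a[j], fl] <- mu[idx_b[j], fl]
        mu[idx_b[j], fl] <- tmp
      }
    }
  }
  values <- pmax(mu + matrix(rnorm(n_genes * n_s, 0, params$noise_sd),
                             n_genes, n_s), 0)
  expr <- expression_matrix(values, sample_labels = labels,
                            cohort_id = cohort_id)
  expr <- apply_platform_transform(expr, transform)
  list(expr = expr, flips = flips,
       signal_pairs = if (k > 0L)
         data.frame(gene_a = genes[2L * seq_len(k) - 1L],
                    gene_b = genes[2L * seq_len(k)],
                    effect = params$pair_effect_sizes,
                    stringsAsFactors = FALSE)
       else NULL)
}

simulate_clinical <- function(params, expr, signal_pairs) {
  tumor_ids <- names(expr$sample_labels)[expr$sample_labels == "tumor"]
  n <- length(tumor_ids)
  age <- draw_truncated_age(n)
  sex <- sample(c("male", "female"), n, replace = TRUE, prob = c(0.75, 0.25))
  stage_t <- sample(names(.stage_t_weights), n, TRUE, .stage_t_weights)
  stage_n <- sample(names(.stage_n_weights), n, TRUE, .stage_n_weights)
  stage_m <- sample(names(.stage_m_weights), n, TRUE, .stage_m_weights)
  eta <- rep(0, n)
  if (!is.null(signal_pairs)) {
    irgp <- build_irgp_matrix(expr, signal_pairs[c("gene_a", "gene_b")])
    ind <- irgp$values[, tumor_ids, drop = FALSE]
    eta <- eta + drop(crossprod(ind, signal_pairs$effect))
  }
  stage_ord <- encode_stage(stage_t)
  stage_ord[is.na(stage_ord)] <- 2L
  eta <- eta + params$clinical_effects[["age"]] * (age - 68) / 8 +
    params$clinical_effects[["stage"]] * (stage_ord - 2L)
  event_time <- rexp(n, rate = params$baseline_hazard * exp(eta))
  censor_time <- if (is.infinite(params$censor_window)) rep(Inf, n)
                 else runif(n, 0, params$censor_window)
  clinical <- data.frame(sample_id = tumor_ids,
                         time_days = pmin(event_time, censor_time),
                         event = as.integer(event_time <= censor_time),
                         endpoint = "OS", age = age, sex = sex,
                         stage_t = stage_t, stage_n = stage_n,
                         stage_m = stage_m, stringsAsFactors = FALSE)
  list(clinical = validate_clinical(clinical), eta = setNames(eta, tumor_ids))
}

#' Simulate a dual-cohort gene-pair survival study
#'
#' Generates two cohorts that share gene-level latent means but are observed
#' through different monotone platform distortions, with tumor/normal
#' labels, planted prognostic signal pairs, proportional-hazards survival,
#' independent censoring, and a copy-number segment-mean table. Deterministic
#' given `params$seed`.
#'
#' @param params a [simulation_params()].
#' @return a list of class `"simulated_study"`: `cohort1` and `cohort2`
#'   (each a list with `expr` and `clinical`), `truth` (signal pairs with
#'   effects, per-sample linear predictors `eta1`/`eta2`), `segment_means`,
#'   and `params`.
#' @export
simulate_study <- function(params = simulation_params()) {
  stopifnot(inherits(params, "simulation_params"))
  with_seed(params$seed, {
    layout <- gene_layout(params)
    c1 <- simulate_cohort(params, layout, "cohort1",
                          params$platform_transforms[1L])
    c2 <- simulate_cohort(params, layout, "cohort2",
                          params$platform_transforms[2L])
    s1 <- simulate_clinical(params, c1$expr, c1$signal_pairs)
    s2 <- simulate_clinical(params, c2$expr, c2$signal_pairs)
    groups <- setNames(rep("high", params$n_tumor), s1$clinical$sample_id)
    groups[s1$eta < stats::median(s1$eta)] <- "low"
    seg <- simulate_segment_means(groups, seed = params$seed)
  })
  structure(list(cohort1 = list(expr = c1$expr, clinical = s1$clinical),
                 cohort2 = list(expr = c2$expr, clinical = s2$clinical),
                 truth = list(signal_pairs = c1$signal_pairs,
                              eta1 = s1$eta, eta2 = s2$eta),
                 segment_means = seg, params = params),
            class = "simulated_study")
}

#' @export
print.simulated_study <- function(x, ...) {
  p <- x$params
  cat(sprintf(paste0("simulated_study: 2 cohorts x (%d tumor + %d normal), ",
                     "%d genes, %d signal pairs\n"),
              p$n_tumor, p$n_normal, p$n_genes, p$n_signal_pairs))
  invisible(x)
}

#' Simulate copy-number segment means with group-specific alteration rates
#'
#' Per gene and sample, draws a loss / neutral / gain component from the
#' group's mixture weights and a segment mean from that component
#' (loss: uniform on (-1, -0.25); neutral: uniform on (-0.15, 0.15); gain:
#' uniform on (0.25, 1)), so calls from [discretize_segment_mean()] recover
#' the component exactly.
#'
#' @param group_assignment named vector sample id -> group label.
#' @param weights named list: per group, a numeric vector
#'   `c(loss, neutral, gain)` summing to 1. Defaults to 10%/80%/10% for
#'   every group.
#' @param n_genes number of simulated genes.
#' @param seed integer seed.
#' @return data.frame `gene`, `sample`, `segment_mean`; the generating
#'   weights are attached as attribute `"truth_weights"`.
#' @export
simulate_segment_means <- function(group_assignment, weights = NULL,
                                   n_genes = 20L, seed = 1L) {
  groups <- unique(unname(group_assignment))
  if (is.null(weights))
    weights <- setNames(rep(list(c(loss = 0.1, neutral = 0.8, gain = 0.1)),
                            length(groups)), groups)
  for (g in groups) {
    w <- weights[[g]]
    if (is.null(w) || length(w) != 3L || abs(sum(w) - 1) > 1e-8)
      stop("weights for group '", g,
           "' must be three values (loss, neutral, gain) summing to 1")
  }
  genes <- sprintf("cnv_g%03d", seq_len(n_genes))
  samples <- names(group_assignment)
  with_seed(seed, {
    rows <- expand.grid(gene = genes, sample = samples,
                        stringsAsFactors = FALSE)
    grp <- unname(group_assignment[rows$sample])
    comp <- vapply(grp, function(g)
      sample(c(-1L, 0L, 1L), 1L, prob = weights[[g]]), integer(1L))
    n <- nrow(rows)
    value <- numeric(n)
    value[comp == -1L] <- runif(sum(comp == -1L), -1, -0.25)
    value[comp == 0L] <- runif(sum(comp == 0L), -0.15, 0.15)
    value[comp == 1L] <- runif(sum(comp == 1L), 0.25, 1)
  })
  out <- data.frame(gene = rows$gene, sample = rows$sample,
                    segment_mean = value, stringsAsFactors = FALSE)
  attr(out, "truth_weights") <- weights
  out
}
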