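#' Pair identifiers
#'
#' The canonical string id of an ordered gene pair is `"geneA|geneB"`.
#'
#' @param pairs data.frame with columns `gene_a`, `gene_b`.
#' @return character vector of pair ids.
#' @export
pair_ids <- function(pairs) paste(pairs$gene_a, pairs$gene_b, sep = "|")

#' Intersect two gene lists
#'
#' @param list_a,list_b character vectors of gene identifiers.
#' @return the sorted, de-duplicated intersection.
#' @export
intersect_gene_lists <- function(list_a, list_b) {
  sort(intersect(unique(as.character(list_a)), unique(as.character(list_b))))
}

#' Enumerate gene pairs
#'
#' Under the `"paper"` convention the full ordered Cartesian product over the
#' sorted gene list is returned, self-pairs included, giving n^2 pairs (1,223
#' genes yield 1,495,729); self-pairs carry constant zero indicators and are
#' removed later by [drop_degenerate_pairs()]. Under `"unordered"` only pairs
#' (i, j) with i < j in sorted order are returned, n(n-1)/2 in total; the two
#' orientations of a pair are complementary so this loses no information.
#' Output order is deterministic: row-major over the sorted gene list.
#'
#' @param genes character vector of unique gene identifiers.
#' @param convention `"paper"` or `"unordered"`.
#' @return data.frame with character columns `gene_a`, `gene_b`.
#' @export
enumerate_pairs <- function(genes, convention = c("paper", "unordered")) {
  convention <- match.arg(convention)
  genes <- as.character(genes)
  if (length(genes) == 0L) stop("empty gene list")
  if (anyDuplicated(genes))
    stop("gene list contains duplicates; deduplicate first")
  g <- sort(genes)
  n <- length(g)
  if (convention == "paper") {
    # row-major: gene_a varies slowest
    pairs <- data.frame(gene_a = rep(g, each = n),
                        gene_b = rep.int(g, n),
                        stringsAsFactors = FALSE)
  } else {
    i <- rep.int(seq_len(n - 1L), (n - 1L):1L)
    j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n),
                use.names = FALSE)
    pairs <- data.frame(gene_a = g[i], gene_b = g[j],
                        stringsAsFactors = FALSE)
  }
  pairs
}

#' Gene-pair indicator
#'
#' Scores 1 when the first expression value strictly exceeds the second,
#' 0 otherwise (ties score 0). Vectorised.
#'
#' @param expr_a,expr_b finite numeric values.
#' @return integer 0/1 of the common length.
#' @export
pair_indicator <- function(expr_a, expr_b) {
  if (!all(is.finite(expr_a)) || !all(is.finite(expr_b)))
    stop("pair_indicator requires finite values")
  as.integer(expr_a > expr_b)
}

#' Build a binary gene-pair indicator matrix
#'
#' Entry (k, s) is 1 when the first gene of pair k has strictly greater
#' expression than the second gene in sample s. Depends on expression values
#' only through within-sample orderings, so any strictly monotone per-sample
#' transform of the input leaves the result unchanged.
#'
#' @param x an [expression_matrix()].
#' @param pairs data.frame with columns `gene_a`, `gene_b`; all genes must be
#'   present in `x`.
#' @return an object of class `"irgp_matrix"`: list with `pairs` (the input
#'   data.frame), `values` (integer 0/1 matrix, pairs x samples, rownames are
#'   pair ids), `sample_labels` and `cohort_id` carried over from `x`.
#' @export
build_irgp_matrix <- function(x, pairs) {
  stopifnot(inherits(x, "expression_matrix"), is.data.frame(pairs))
  missing <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)), rownames(x$values))
  if (length(missing))
    stop("pairs reference genes absent from the matrix: ",
         paste(missing, collapse = ", "))
  values <- (x$values[pairs$gene_a, , drop = FALSE] >
               x$values[pairs$gene_b, , drop = FALSE]) + 0L
  storage.mode(values) <- "integer"
  rownames(values) <- pair_ids(pairs)
  structure(list(pairs = pairs, values = values,
                 sample_labels = x$sample_labels, cohort_id = x$cohort_id),
            class = "irgp_matrix")
}

#' @export
print.irgp_matrix <- function(x, ...) {
  cat(sprintf("irgp_matrix '%s': %d pairs x %d samples\n",
              x$cohort_id %||% "?", nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.irgp_matrix <- function(x) dim(x$values)

#' Drop degenerate pair rows
#'
#' Removes indicator rows constant across all samples (all 0 or all 1); these
#' include every self-pair and any pair whose ordering never varies, for
#' which the downstream association and survival tests are undefined.
#'
#' @param irgp an `irgp_matrix` from [build_irgp_matrix()].
#' @return the `irgp_matrix` restricted to non-constant rows.
#' @export
drop_degenerate_pairs <- function(irgp) {
  stopifnot(inherits(irgp, "irgp_matrix"))
  ones <- rowSums(irgp$values)
  keep <- ones > 0L & ones < ncol(irgp$values)
  irgp$values <- irgp$values[keep, , drop = FALSE]
  irgp$pairs <- irgp$pairs[keep, , drop = FALSE]
  rownames(irgp$pairs) <- NULL
  irgp
}

#' Subset an irgp_matrix by pair id
#'
#' @param irgp an `irgp_matrix`.
#' @param ids character vector of pair ids (`"geneA|geneB"`).
#' @return the `irgp_matrix` restricted to `ids`, in the given order.
#' @export
subset_pairs <- function(irgp, ids) {
  stopifnot(inherits(irgp, "irgp_matrix"))
  idx <- match(ids, rownames(irgp$values))
  if (anyNA(idx))
    stop("unknown pair ids: ", paste(ids[is.na(idx)], collapse = ", "))
  irgp$values <- irgp$values[idx, , drop = FALSE]
  irgp$pairs <- irgp$pairs[idx, , drop = FALSE]
  rownames(irgp$pairs) <- NULL
  irgp
}
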