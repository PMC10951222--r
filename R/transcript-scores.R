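#' RNA-seq quality filter on detected genes
#'
#' A sample passes when the number of genes with nonzero expression reaches
#' the threshold (default 8000, the whole-transcriptome convention;
#' lower it for toy gene universes).
#'
#' @param values numeric vector of one sample's expression (log2(TPM+1)).
#' @param min_genes detected-gene threshold.
#' @return logical pass/fail.
#' @export
rna_qc_filter <- function(values, min_genes = 8000) {
  sum(values > 0, na.rm = TRUE) >= min_genes
}

#' Upper-quartile normalization of a log2(TPM+1) matrix
#'
#' Each sample is rescaled on the TPM scale so that its 75th percentile of
#' nonzero expression equals a common target (default 1000), then re-logged.
#' Per-sample ranks are unchanged, so every downstream rank-based score is
#' invariant; the target constant is arbitrary and only cohort-relative
#' quantities are consumed.
#'
#' @param mat genes x samples matrix of log2(TPM+1) values (raw state).
#' @param target upper-quartile target on the TPM scale.
#' @return normalized matrix, attribute \code{normalization_state} set to
#'   "upper_quartile".
#' @export
upper_quartile_normalize <- function(mat, target = 1000) {
  stopifnot(is.matrix(mat), all(mat >= 0))
  out <- apply(mat, 2, function(col) {
    tpm <- 2^col - 1
    nz <- tpm[tpm > 0]
    if (length(nz) == 0) stop("upper_quartile_normalize: all-zero sample")
    uq <- stats::quantile(nz, 0.75, names = FALSE)
    log2(tpm * (target / uq) + 1)
  })
  dimnames(out) <- dimnames(mat)
  attr(out, "normalization_state") <- "upper_quartile"
  out
}

#' Single-sample gene-set enrichment score
#'
#' Weighted-ECDF single-sample enrichment in its integrated form: genes are
#' ranked by expression in decreasing order; walking down the ranking, the
#' in-set ECDF (weighted by rank^exponent) and the uniform out-of-set ECDF
#' are accumulated, and the enrichment score is the sum of their running
#' difference over all positions. Depends only on the ranks of
#' \code{values}, so any strictly increasing transform of the sample leaves
#' it unchanged. Ties are broken by gene order ("first").
#'
#' @param values named numeric vector of one sample's expression.
#' @param gene_set character vector of gene symbols; must intersect the
#'   universe and be a proper subset of it.
#' @param exponent rank weight exponent (default 0.75; 0 gives the
#'   unweighted Kolmogorov-Smirnov-like form).
#' @return numeric enrichment score.
#' @export
ssgsea_score <- function(values, gene_set, exponent = 0.75) {
  stopifnot(!is.null(names(values)))
  n <- length(values)
  in_set <- names(values) %in% gene_set
  if (!any(in_set)) stop("ssgsea_score: gene set does not intersect universe")
  if (all(in_set)) stop("ssgsea_score: gene set equals the whole universe")
  ord <- order(values, decreasing = TRUE)
  in_ord <- in_set[ord]
  # rank weight: the highest-expressed gene carries rank n
  w <- (n:1)^exponent
  w[!in_ord] <- 0
  p_in <- cumsum(w) / sum(w)
  p_out <- cumsum(!in_ord) / (n - sum(in_set))
  sum(p_in - p_out)
}

#' Score a cohort over a collection of gene sets
#'
#' @param mat genes x samples expression matrix.
#' @param gene_sets named list of character vectors.
#' @param exponent passed to \code{ssgsea_score}.
#' @return sets x samples matrix of enrichment scores.
#' @export
score_signatures <- function(mat, gene_sets, exponent = 0.75) {
  out <- vapply(seq_len(ncol(mat)), function(j) {
    v <- mat[, j]
    names(v) <- rownames(mat)
    vapply(gene_sets, function(s) ssgsea_score(v, s, exponent), numeric(1))
  }, numeric(length(gene_sets)))
  out <- matrix(out, nrow = length(gene_sets),
                dimnames = list(names(gene_sets), colnames(mat)))
  out
}

#' Range-normalized enrichment scores
#'
#' Per set, NES = ES / (max(ES) - min(ES)) over the supplied cohort (trial
#' plus reference); linear in ES within a set. A zero range yields all-zero
#' NES with a warning.
#'
#' @param es numeric vector (one set across samples) or sets x samples
#'   matrix.
#' @return object of the same shape holding NES values.
#' @export
normalize_es <- function(es) {
  norm1 <- function(x) {
    rng <- max(x) - min(x)
    if (rng == 0) {
      warning("normalize_es: zero range, NES set to 0")
      return(rep(0, length(x)))
    }
    x / rng
  }
  if (is.matrix(es)) {
    out <- t(apply(es, 1, norm1))
    dimnames(out) <- dimnames(es)
    out
  } else {
    stopifnot(length(es) >= 2)
    stats::setNames(norm1(es), names(es))
  }
}

#' Build a reference cohort object
#'
#' Stores the reference expression matrix, per-sample receptor status, and
#' reference quantile tables (10th/25th/75th/90th percentiles) for genes
#' and, when gene sets are supplied, for signature NES values.
#'
#' @param mat genes x samples log2(TPM+1) matrix (upper-quartile
#'   normalization is applied internally for the quantile tables).
#' @param receptor_status character vector per sample (e.g. "HR+/HER2-").
#' @param gene_sets optional named list for signature quantiles.
#' @param exponent ssGSEA exponent.
#' @return object of class \code{reference_cohort}.
#' @export
reference_cohort <- function(mat, receptor_status, gene_sets = NULL,
                             exponent = 0.75) {
  stopifnot(ncol(mat) == length(receptor_status))
  norm <- upper_quartile_normalize(mat)
  qs <- c(0.10, 0.25, 0.75, 0.90)
  gene_q <- t(apply(norm, 1, stats::quantile, probs = qs, names = FALSE))
  colnames(gene_q) <- c("p10", "p25", "p75", "p90")
  sig_q <- NULL
  sig_scores <- NULL
  if (!is.null(gene_sets)) {
    sig_scores <- normalize_es(score_signatures(norm, gene_sets, exponent))
    sig_q <- t(apply(sig_scores, 1, stats::quantile, probs = qs,
                     names = FALSE))
    colnames(sig_q) <- c("p10", "p25", "p75", "p90")
  }
  structure(list(expression = norm, receptor_status = receptor_status,
                 gene_quantiles = gene_q, signature_quantiles = sig_q,
                 signature_scores = sig_scores, gene_sets = gene_sets,
                 exponent = exponent),
            class = "reference_cohort")
}

#' Quantile category of a value relative to the reference cohort
#'
#' Ties-inclusive bins: high_decile when >= p90, else high_quartile when
#' >= p75, low_decile when <= p10, low_quartile when <= p25, mid otherwise.
#'
#' @param value observed expression or signature NES.
#' @param feature gene symbol or signature name present in the reference
#'   quantile tables.
#' @param reference a \code{reference_cohort}.
#' @return one of "low_decile", "low_quartile", "mid", "high_quartile",
#'   "high_decile".
#' @export
reference_quantile_category <- function(value, feature, reference) {
  tab <- if (feature %in% rownames(reference$gene_quantiles)) {
    reference$gene_quantiles[feature, ]
  } else if (!is.null(reference$signature_quantiles) &&
             feature %in% rownames(reference$signature_quantiles)) {
    reference$signature_quantiles[feature, ]
  } else {
    stop(sprintf("reference_quantile_category: unknown feature '%s'", feature))
  }
  if (value >= tab[["p90"]]) return("high_decile")
  if (value >= tab[["p75"]]) return("high_quartile")
  if (value <= tab[["p10"]]) return("low_decile")
  if (value <= tab[["p25"]]) return("low_quartile")
  "mid"
}

#' Receptor-balanced resampling of the reference cohort
#'
#' Draws a subsample whose ER-positive fraction matches a target ratio
#' (default 0.64, configurable; used to mimic the receptor balance of the
#' intrinsic-subtype training cohort). Sampling is without replacement
#' within the limiting class; the other class is drawn with replacement
#' when it is too small, and the result is flagged.
#'
#' @param reference a \code{reference_cohort}; ER-positive samples are those
#'   whose receptor status starts with "HR+".
#' @param target_er_pos_fraction target ER+ fraction in (0, 1).
#' @param seed integer seed; identical seeds give identical indices.
#' @param n_out subsample size; defaults to the full cohort size.
#' @return integer index vector with attribute \code{with_replacement}.
#' @export
balanced_resample <- function(reference, target_er_pos_fraction = 0.64,
                              seed = 1L, n_out = NULL) {
  status <- reference$receptor_status
  er_pos <- which(startsWith(status, "HR+"))
  er_neg <- which(startsWith(status, "HR-"))
  if (length(er_pos) == 0 || length(er_neg) == 0) {
    stop("balanced_resample: both ER classes must be present")
  }
  if (is.null(n_out)) n_out <- length(er_pos) + length(er_neg)
  n_pos <- round(n_out * target_er_pos_fraction)
  n_neg <- n_out - n_pos
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  repl_pos <- n_pos > length(er_pos)
  repl_neg <- n_neg > length(er_neg)
  idx <- c(sample(er_pos, n_pos, replace = repl_pos),
           sample(er_neg, n_neg, replace = repl_neg))
  attr(idx, "with_replacement") <- repl_pos || repl_neg
  idx
}

# save/restore the global RNG state so seeded helpers do not perturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Intrinsic subtype assignment by centroid correlation
#'
#' Expression is rescaled by subtracting, per gene, the median of the
#' balanced reference subsample, then Spearman-correlated with each of the
#' five subtype centroids; the argmax centroid is the call, or NC (not
#' classified) when the maximum correlation falls below the threshold.
#' Up to 5 missing centroid genes are tolerated with a warning.
#'
#' @param values named numeric vector of one sample's expression
#'   (upper-quartile scale).
#' @param centroids genes x 5 centroid matrix (columns LumA, LumB, HER2E,
#'   Basal, Normal).
#' @param reference a \code{reference_cohort}.
#' @param balanced_index index from \code{balanced_resample}; defaults to
#'   every reference sample.
#' @param nc_threshold minimum correlation for a call (default 0.10).
#' @return list with \code{subtype}, \code{correlations} (named, 5).
#' @export
pam50_assign <- function(values, centroids, reference,
                         balanced_index = NULL, nc_threshold = 0.10) {
  genes <- rownames(centroids)
  missing <- setdiff(genes, names(values))
  if (length(missing) > 5) {
    stop(sprintf("pam50_assign: %d centroid genes missing", length(missing)))
  }
  if (length(missing) > 0) {
    warning(sprintf("pam50_assign: %d centroid genes missing, using %d",
                    length(missing), length(genes) - length(missing)))
    genes <- setdiff(genes, missing)
  }
  if (is.null(balanced_index)) {
    balanced_index <- seq_len(ncol(reference$expression))
  }
  ref_med <- apply(reference$expression[genes, balanced_index, drop = FALSE],
                   1, stats::median)
  rescaled <- values[genes] - ref_med
  cors <- vapply(colnames(centroids), function(k)
    suppressWarnings(stats::cor(rescaled, centroids[genes, k],
                                method = "spearman")), numeric(1))
  cors[is.na(cors)] <- 0 # degenerate (constant) profiles correlate with nothing
  subtype <- if (max(cors) < nc_threshold) "NC" else names(which.max(cors))
  list(subtype = subtype, correlations = cors)
}

#' Combined activity of several signatures
#'
#' Arithmetic mean of the NES values (used e.g. for the joint mTORC1 +
#' PI3K/AKT/mTOR activity readout).
#'
#' @param nes numeric vector of NES values (>= 1).
#' @return numeric mean.
#' @export
combine_signature_activity <- function(nes) {
  stopifnot(length(nes) >= 1)
  mean(nes)
}
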