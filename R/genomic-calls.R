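#' Copy number above ploidy (CNAP)
#'
#' The amplification metric used throughout: the segment's total copy number
#' minus the sample's genome-wide average ploidy. Negative values indicate
#' copy number below ploidy.
#'
#' @param total_cn segment total copy number (non-negative real).
#' @param ploidy sample genome ploidy (> 0).
#' @return numeric CNAP (vectorized).
#' @examples
#' compute_cnap(11.7, 2.0) # 9.7
#' @export
compute_cnap <- function(total_cn, ploidy) {
  stopifnot(all(ploidy > 0), all(total_cn >= 0))
  total_cn - ploidy
}

#' Ordered copy-number classes
#' @keywords internal
cna_class_levels <- c("DEEP_DEL", "NEUTRAL", "GAIN", "AMP", "HIGH_AMP",
                      "FOCAL_HIGH_AMP")

#' Five-class copy-number call from CNAP
#'
#' Classification precedence: DEEP_DEL when the segment's total copy number
#' is below 0.5; otherwise FOCAL_HIGH_AMP when CNAP >= 9 on a segment of at
#' most 100 genes; HIGH_AMP when CNAP >= 6; AMP when CNAP >= 3; GAIN when
#' CNAP > 1.5; NEUTRAL otherwise. Focality failing only on the gene count
#' (CNAP >= 9, > 100 genes) still yields HIGH_AMP.
#'
#' @param cnap copy number above ploidy.
#' @param total_cn segment total copy number.
#' @param n_genes number of genes on the segment (>= 1).
#' @return character class, one of \code{cna_class_levels} (vectorized).
#' @examples
#' classify_cna(9.7, 11.7, 40) # FOCAL_HIGH_AMP
#' @export
classify_cna <- function(cnap, total_cn, n_genes) {
  stopifnot(all(n_genes >= 1))
  n <- max(length(cnap), length(total_cn), length(n_genes))
  cnap <- rep_len(cnap, n)
  total_cn <- rep_len(total_cn, n)
  n_genes <- rep_len(n_genes, n)
  out <- rep("NEUTRAL", n)
  out[cnap > 1.5] <- "GAIN"
  out[cnap >= 3] <- "AMP"
  out[cnap >= 6] <- "HIGH_AMP"
  out[cnap >= 9 & n_genes <= 100] <- "FOCAL_HIGH_AMP"
  out[total_cn < 0.5] <- "DEEP_DEL"
  out
}

#' Variant classes treated as loss-of-function regardless of annotation
#' @keywords internal
lof_variant_classes <- c("nonsense", "frameshift_del", "frameshift_ins",
                         "nonstop")

#' Biallelic inactivation call for a tumor suppressor
#'
#' TRUE iff the gene's overlapping segment shows loss of heterozygosity
#' (minor copy number zero) and the gene carries a loss-of-function
#' mutation: either annotated effect LOF / likely_LOF, or a truncating
#' variant class (nonsense, frameshift, nonstop).
#'
#' @param gene gene symbol.
#' @param mutations data.frame with columns gene, variant_class, effect.
#' @param segments data.frame with columns genes (list-column or
#'   comma-separated string of symbols) and minor_cn.
#' @return TRUE / FALSE, or NA ("no coverage") when no segment covers the
#'   gene.
#' @export
call_biallelic_inactivation <- function(gene, mutations, segments) {
  covers <- vapply(segments$genes, function(g) {
    if (is.character(g) && length(g) == 1L) g <- strsplit(g, ",", fixed = TRUE)[[1]]
    gene %in% g
  }, logical(1))
  if (!any(covers)) {
    return(NA) # no-coverage result, distinct from FALSE
  }
  loh <- any(segments$minor_cn[covers] == 0)
  mut <- mutations[mutations$gene == gene, , drop = FALSE]
  eff <- if ("effect" %in% names(mut)) mut$effect else character(0)
  lof <- nrow(mut) > 0 && (any(eff %in% c("LOF", "likely_LOF")) ||
                             any(mut$variant_class %in% lof_variant_classes))
  isTRUE(loh && lof)
}

#' Clonality from cancer cell fraction
#'
#' Clonal iff CCF >= threshold (default 0.8, a common convention for
#' purity/ploidy-derived CCF point estimates; the choice is configurable).
#'
#' @param ccf cancer cell fraction in [0, 1].
#' @param threshold clonality cutoff.
#' @return "clonal" or "subclonal" (vectorized).
#' @export
classify_clonality <- function(ccf, threshold = 0.8) {
  stopifnot(all(ccf >= 0 & ccf <= 1))
  ifelse(ccf >= threshold, "clonal", "subclonal")
}

#' Resistance phenotype from prior CDK4/6i treatment duration
#'
#' Post-progression biopsies are labelled acquired resistance when the
#' patient stayed on the prior CDK4/6 inhibitor for more than 6 months and
#' intrinsic resistance otherwise; a missing duration yields "unknown".
#'
#' @param duration_months time on prior CDK4/6i, months (>= 0 or NA).
#' @return list with \code{value} ("acquired" / "intrinsic" / "unknown")
#'   and \code{prior_cdk46i_duration_months}.
#' @export
assign_resistance_phenotype <- function(duration_months) {
  if (is.na(duration_months)) {
    return(list(value = "unknown",
                prior_cdk46i_duration_months = NA_real_))
  }
  stopifnot(duration_months >= 0)
  list(value = if (duration_months > 6) "acquired" else "intrinsic",
       prior_cdk46i_duration_months = duration_months)
}

#' Exome quality filter on tumor purity
#'
#' Samples pass when purity is at least 8\%.
#'
#' @param purity tumor purity in [0, 1].
#' @param min_purity threshold, default 0.08.
#' @return logical (vectorized).
#' @export
wes_qc_filter <- function(purity, min_purity = 0.08) {
  stopifnot(all(purity >= 0 & purity <= 1))
  purity >= min_purity
}

#' Gene-level copy-number calls from a segment table
#'
#' Genes inherit the CNAP and class of the segment covering their midpoint;
#' when a midpoint falls on a boundary shared by two segments the higher-CNAP
#' segment wins.
#'
#' @param segments data.frame with columns chrom, start, end, total_cn,
#'   minor_cn, n_genes, genes (comma-separated symbols).
#' @param ploidy sample ploidy.
#' @param gene_coords optional data.frame gene, chrom, pos (midpoints). When
#'   NULL, genes are taken from the segment's own \code{genes} column.
#' @return data.frame gene, cnap, total_cn, minor_cn, loh, cna_class.
#' @export
gene_copy_number_calls <- function(segments, ploidy, gene_coords = NULL) {
  stopifnot(all(segments$minor_cn <= segments$total_cn))
  rows <- lapply(seq_len(nrow(segments)), function(i) {
    seg <- segments[i, ]
    genes <- strsplit(seg$genes, ",", fixed = TRUE)[[1]]
    if (!is.null(gene_coords)) {
      hit <- gene_coords$chrom == seg$chrom &
        gene_coords$pos >= seg$start & gene_coords$pos <= seg$end
      genes <- union(genes, gene_coords$gene[hit])
    }
    if (length(genes) == 0L) return(NULL)
    cnap <- compute_cnap(seg$total_cn, ploidy)
    data.frame(gene = genes, cnap = cnap, total_cn = seg$total_cn,
               minor_cn = seg$minor_cn, loh = seg$minor_cn == 0,
               cna_class = classify_cna(cnap, seg$total_cn, seg$n_genes),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(gene = character(0), cnap = numeric(0),
                      total_cn = numeric(0), minor_cn = numeric(0),
                      loh = logical(0), cna_class = character(0)))
  }
  # tie-break duplicated genes (segment-boundary spans): keep higher CNAP
  out <- out[order(out$gene, -out$cnap), , drop = FALSE]
  out <- out[!duplicated(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate full genomic calls for one sample
#'
#' Convenience wrapper producing the per-sample discrete call set consumed
#' by the rule engine and the clonal-dynamics comparison: oncogenic
#' annotation and clonality for every mutation, gene-level CNA classes,
#' per-gene multi-hit flags, and biallelic-inactivation calls for mutated
#' genes on LOH segments.
#'
#' @param mutations MAF-like data.frame (gene, protein_change, variant_class,
#'   ccf).
#' @param segments SEG-like data.frame (see \code{gene_copy_number_calls}).
#' @param purity,ploidy sample purity and ploidy.
#' @param knowledge knowledge table from \code{load_knowledge_table()}.
#' @param clonality_threshold CCF cutoff for clonal calls.
#' @param source "tumor" or "ctDNA"; recorded, and used by reporting filters.
#' @return list of class \code{sample_calls}.
#' @export
annotate_sample_calls <- function(mutations, segments, purity, ploidy,
                                  knowledge = load_knowledge_table(),
                                  clonality_threshold = 0.8,
                                  source = "tumor") {
  if (nrow(mutations) > 0) {
    ann <- t(vapply(seq_len(nrow(mutations)), function(i) {
      a <- annotate_oncogenic(mutations$gene[i], mutations$protein_change[i],
                              knowledge,
                              variant_class = mutations$variant_class[i])
      c(a$effect, a$actionability_level)
    }, character(2)))
    mutations$effect <- ann[, 1]
    mutations$actionability_level <- ann[, 2]
    mutations$clonality <- classify_clonality(mutations$ccf,
                                              clonality_threshold)
    multi <- table(mutations$gene[mutations$effect %in%
                                    c("GOF", "likely_GOF")])
    mutations$multi_hit <- mutations$gene %in% names(multi)[multi >= 2]
  } else {
    mutations$effect <- character(0)
    mutations$actionability_level <- character(0)
    mutations$clonality <- character(0)
    mutations$multi_hit <- logical(0)
  }
  cna <- gene_copy_number_calls(segments, ploidy)
  biallelic <- character(0)
  for (g in unique(mutations$gene)) {
    if (isTRUE(call_biallelic_inactivation(g, mutations, segments))) {
      biallelic <- c(biallelic, g)
    }
  }
  structure(list(mutations = mutations, cna = cna, biallelic = biallelic,
                 purity = purity, ploidy = ploidy, source = source,
                 qc_pass = wes_qc_filter(purity)),
            class = "sample_calls")
}

#' Reporting filter for figure-style output
#'
#' Deep deletions are suppressed for ctDNA samples and low-grade
#' amplification classes (GAIN, AMP) for every sample; this is a reporting
#' filter only, the machine-readable calls keep everything.
#'
#' @param cna gene-level CNA call data.frame.
#' @param source "tumor" or "ctDNA".
#' @return filtered data.frame.
#' @export
filter_cna_for_report <- function(cna, source = "tumor") {
  keep <- !(cna$cna_class %in% c("GAIN", "AMP", "NEUTRAL"))
  if (identical(source, "ctDNA")) keep <- keep & cna$cna_class != "DEEP_DEL"
  cna[keep, , drop = FALSE]
}
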