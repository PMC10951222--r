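#' Alteration dynamics between a pre- and a post-treatment sample
#'
#' Compares the discrete calls of two samples from the same patient and
#' assigns every alteration seen in either exactly one status:
#' \itemize{
#'   \item \code{acquired} -- not detected pre, detected post; acquired
#'     subclonal events are legitimate calls, so the post-state clonality is
#'     retained on the record rather than gating the status;
#'   \item \code{enriched} -- subclonal pre and clonal post, or a
#'     copy-number class that strictly increased along
#'     NEUTRAL < GAIN < AMP < HIGH_AMP < FOCAL_HIGH_AMP;
#'   \item \code{shared} -- detected in both without enrichment;
#'   \item \code{lost} -- clonal pre, not detected post;
#'   \item \code{pre_only} -- subclonal pre, not detected post.
#' }
#' Swapping the sample order maps acquired(clonal) <-> lost and
#' acquired(subclonal) <-> pre_only.
#'
#' @param pre,post \code{sample_calls} objects for the paired samples.
#' @param patient_pre,patient_post patient identifiers; must match.
#' @return data.frame with columns alteration, type (mutation / cna), gene,
#'   status, pre_state, post_state.
#' @export
compare_paired_samples <- function(pre, post, patient_pre = NA,
                                   patient_post = NA) {
  if (!is.na(patient_pre) && !is.na(patient_post) &&
      patient_pre != patient_post) {
    stop("compare_paired_samples: samples come from different patients")
  }
  mut_key <- function(calls) {
    m <- calls$mutations
    if (nrow(m) == 0) return(stats::setNames(character(0), character(0)))
    stats::setNames(m$clonality, paste(m$gene, m$protein_change, sep = " "))
  }
  cna_key <- function(calls) {
    cc <- calls$cna
    cc <- cc[cc$cna_class != "NEUTRAL", , drop = FALSE]
    stats::setNames(cc$cna_class, cc$gene)
  }
  pre_m <- mut_key(pre); post_m <- mut_key(post)
  pre_c <- cna_key(pre); post_c <- cna_key(post)
  rows <- list()
  for (k in union(names(pre_m), names(post_m))) {
    p0 <- if (k %in% names(pre_m)) pre_m[[k]] else NA_character_
    p1 <- if (k %in% names(post_m)) post_m[[k]] else NA_character_
    status <- if (is.na(p0)) "acquired"
    else if (is.na(p1)) {
      if (p0 == "clonal") "lost" else "pre_only"
    } else if (p0 == "subclonal" && p1 == "clonal") "enriched"
    else "shared"
    rows[[length(rows) + 1]] <- data.frame(
      alteration = k, type = "mutation",
      gene = strsplit(k, " ", fixed = TRUE)[[1]][1], status = status,
      pre_state = p0, post_state = p1, stringsAsFactors = FALSE)
  }
  ord <- cna_class_levels
  for (g in union(names(pre_c), names(post_c))) {
    c0 <- if (g %in% names(pre_c)) pre_c[[g]] else "NEUTRAL"
    c1 <- if (g %in% names(post_c)) post_c[[g]] else "NEUTRAL"
    i0 <- match(c0, ord); i1 <- match(c1, ord)
    status <- if (c0 == "NEUTRAL" && c1 != "NEUTRAL") "acquired"
    else if (c1 == "NEUTRAL") "lost"
    else if (i1 > i0) "enriched"
    else "shared"
    rows[[length(rows) + 1]] <- data.frame(
      alteration = g, type = "cna", gene = g,
      status = status, pre_state = c0, post_state = c1,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(alteration = character(0), type = character(0),
                      gene = character(0), status = character(0),
                      pre_state = character(0), post_state = character(0))
  }
  rownames(out) <- NULL
  out
}

#' Co-existing lineage detection between concurrent samples
#'
#' Two concurrent samples from one patient (typically tumor biopsy and
#' ctDNA) harbor co-existing tumor lineages when they share at least one
#' clonal (truncal) alteration while each carries at least one private
#' clonal driver mutation absent from the other. Genes activated privately
#' in both samples by distinct events are flagged as convergent evolution.
#' With no shared clonal alteration the result is
#' "unrelated_or_insufficient", never divergent.
#'
#' @param sample_a,sample_b \code{sample_calls} objects.
#' @param driver_genes character vector of cancer driver genes.
#' @param high_clonality_ccf CCF at or above which a ctDNA mutation counts
#'   as high-clonality for private-driver purposes (default 0.6).
#' @return list with \code{divergent}, \code{status}, \code{truncal},
#'   \code{private_a}, \code{private_b}, \code{convergent_genes}.
#' @export
detect_lineage_divergence <- function(sample_a, sample_b, driver_genes,
                                      high_clonality_ccf = 0.6) {
  keyset <- function(calls) {
    m <- calls$mutations
    paste(m$gene, m$protein_change, sep = " ")
  }
  clonal_mask <- function(calls) {
    m <- calls$mutations
    m$clonality == "clonal" |
      (identical(calls$source, "ctDNA") & m$ccf >= high_clonality_ccf)
  }
  a_keys <- keyset(sample_a); b_keys <- keyset(sample_b)
  a_cl <- clonal_mask(sample_a); b_cl <- clonal_mask(sample_b)
  truncal <- intersect(a_keys[a_cl], b_keys[b_cl])
  # shared clonal CNAs also count as truncal evidence
  shared_cna <- intersect(
    sample_a$cna$gene[sample_a$cna$cna_class != "NEUTRAL"],
    sample_b$cna$gene[sample_b$cna$cna_class != "NEUTRAL"])
  if (length(truncal) == 0 && length(shared_cna) == 0) {
    return(list(divergent = FALSE, status = "unrelated_or_insufficient",
                truncal = character(0), private_a = character(0),
                private_b = character(0), convergent_genes = character(0)))
  }
  priv <- function(keys, cl, other_keys, calls) {
    k <- keys[cl & !(keys %in% other_keys)]
    g <- calls$mutations$gene[match(k, keys)]
    k[g %in% driver_genes]
  }
  private_a <- priv(a_keys, a_cl, b_keys, sample_a)
  private_b <- priv(b_keys, b_cl, a_keys, sample_b)
  divergent <- length(private_a) > 0 && length(private_b) > 0
  gene_of <- function(k) vapply(strsplit(k, " ", fixed = TRUE), `[`, "", 1)
  # convergence: same gene privately activated in both samples by distinct
  # events; a private activating mutation in one sample and a private
  # high-grade amplification of the same gene in the other also qualifies
  amp_private <- function(this, other) {
    g <- this$cna$gene[this$cna$cna_class %in% c("HIGH_AMP",
                                                 "FOCAL_HIGH_AMP")]
    setdiff(g, other$cna$gene[other$cna$cna_class %in%
                                c("HIGH_AMP", "FOCAL_HIGH_AMP")])
  }
  act_a <- union(gene_of(private_a), amp_private(sample_a, sample_b))
  act_b <- union(gene_of(private_b), amp_private(sample_b, sample_a))
  convergent <- intersect(act_a, act_b)
  convergent <- convergent[convergent %in% driver_genes]
  list(divergent = divergent,
       status = if (divergent) "divergent" else "single_lineage",
       truncal = truncal, private_a = private_a, private_b = private_b,
       convergent_genes = convergent)
}
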