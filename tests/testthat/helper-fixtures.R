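# shared fixture builders and independent oracles

mut_rows <- function(gene, protein_change, variant_class = "missense",
                     ccf = 1) {
  data.frame(gene = gene, protein_change = protein_change,
             variant_class = variant_class, ccf = ccf,
             stringsAsFactors = FALSE)
}

no_mutations <- function() mut_rows(character(0), character(0),
                                    character(0), numeric(0))

seg_rows <- function(genes, total_cn = 2, minor_cn = 1, n_genes = 50,
                     chrom = 1) {
  k <- length(genes)
  data.frame(chrom = rep_len(chrom, k), start = seq_len(k) * 1e6,
             end = seq_len(k) * 1e6 + 5e5,
             total_cn = rep_len(total_cn, k),
             minor_cn = rep_len(minor_cn, k),
             n_genes = rep_len(n_genes, k), genes = genes,
             stringsAsFactors = FALSE)
}

make_calls <- function(mutations = no_mutations(),
                       segments = seg_rows(character(0)),
                       purity = 0.5, ploidy = 2, source = "tumor") {
  annotate_sample_calls(mutations, segments, purity, ploidy,
                        source = source)
}

# brute-force one-sided Mann-Whitney: enumerate every labeling of
# tie-free scores 1..(n1+n2) and count arrangements with U >= u
mw_brute_p <- function(u, n1, n2) {
  n <- n1 + n2
  combos <- utils::combn(n, n1)
  u_all <- apply(combos, 2, function(pos) {
    neg <- setdiff(seq_len(n), pos)
    sum(outer(pos, neg, ">"))
  })
  mean(u_all >= u)
}

# exhaustive two-sided Fisher by hypergeometric summation over all tables
# with the observed margins
fisher_brute_p <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  a_range <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(a_range, c1, n - c1, r1)
  obs <- stats::dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# brute-force single-sample enrichment score: at every position recompute
# both ECDFs from scratch with an inner loop (explicit double loop)
ssgsea_brute <- function(values, gene_set, exponent) {
  ord <- order(values, decreasing = TRUE)
  genes <- names(values)[ord]
  n <- length(values)
  inset <- genes %in% gene_set
  rankval <- n:1
  denom <- sum(rankval[inset]^exponent)
  n_out <- n - sum(inset)
  es <- 0
  for (i in seq_len(n)) {
    p_in <- 0
    p_out <- 0
    for (j in seq_len(i)) {
      if (inset[j]) p_in <- p_in + rankval[j]^exponent / denom
      else p_out <- p_out + 1 / n_out
    }
    es <- es + (p_in - p_out)
  }
  es
}

# tiny config for fast end-to-end runs
small_config <- function(seed = 1, n_patients = 8, ...) {
  sim_config(seed = seed, n_patients = n_patients, n_genes = 600,
             n_reference_samples = 60,
             reference_receptor_counts = c("HR+/HER2-" = 25,
                                           "HR+/HER2+" = 8,
                                           "HR-/HER2+" = 3,
                                           "HR-/HER2-" = 4), ...)
}
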