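#' The 50 intrinsic-subtype classifier genes
#'
#' Standard PAM50 gene symbols; the expression universe of any cohort fed
#' to \code{pam50_assign} must contain them (up to 5 may be missing).
#'
#' @return character vector of 50 gene symbols.
#' @export
pam50_genes <- function() {
  c("ACTR3B", "ANLN", "BAG1", "BCL2", "BIRC5", "BLVRA", "CCNB1", "CCNE1",
    "CDC20", "CDC6", "CDH3", "CENPF", "CEP55", "CXXC5", "EGFR", "ERBB2",
    "ESR1", "EXO1", "FGFR4", "FOXA1", "FOXC1", "GPR160", "GRB7", "KIF2C",
    "KRT14", "KRT17", "KRT5", "MAPT", "MDM2", "MELK", "MIA", "MKI67",
    "MLPH", "MMP11", "MYBL2", "MYC", "NAT1", "NDC80", "NUF2", "ORC6",
    "PGR", "PHGDH", "PTTG1", "RRM2", "SFRP1", "SLC39A6", "TMEM45B",
    "TYMS", "UBE2C", "UBE2T")
}

#' Functional blocks of the classifier genes
#' @keywords internal
pam50_gene_groups <- function() {
  list(
    luminal = c("ESR1", "PGR", "FOXA1", "NAT1", "MAPT", "BCL2", "SLC39A6",
                "BAG1", "BLVRA", "CXXC5", "GPR160", "MLPH", "MDM2"),
    proliferation = c("MKI67", "CCNB1", "BIRC5", "CDC20", "CDC6", "CENPF",
                      "CEP55", "EXO1", "KIF2C", "MELK", "MYBL2", "NDC80",
                      "NUF2", "ORC6", "PTTG1", "RRM2", "TYMS", "UBE2C",
                      "UBE2T", "ANLN", "CCNE1"),
    her2 = c("ERBB2", "GRB7", "FGFR4", "TMEM45B", "MMP11"),
    basal = c("KRT5", "KRT14", "KRT17", "FOXC1", "MIA", "SFRP1", "EGFR",
              "CDH3", "PHGDH", "ACTR3B", "MYC")
  )
}

#' Mean log2 expression shifts per intrinsic subtype
#'
#' Block-level additive shifts (log2 units, relative to the cohort
#' baseline) that define each subtype's mean profile over the classifier
#' genes. Shared between the synthetic centroids and the synthetic-cohort
#' generator so that planted subtypes are recoverable by construction.
#'
#' @return 4 blocks x 5 subtypes numeric matrix.
#' @keywords internal
pam50_subtype_shifts <- function() {
  m <- rbind(
    luminal       = c(LumA = 2.0, LumB = 1.5, HER2E = -1.0, Basal = -2.0, Normal = 0.0),
    proliferation = c(-1.0, 1.5, 1.0, 2.0, -1.5),
    her2          = c(0.0, 0.0, 2.5, -1.0, 0.0),
    basal         = c(-1.0, -1.0, 0.0, 2.5, 0.5)
  )
  colnames(m) <- c("LumA", "LumB", "HER2E", "Basal", "Normal")
  m
}

#' Synthetic intrinsic-subtype centroid matrix
#'
#' A stand-in for the published PAM50 centroid matrix, which is third-party
#' data not redistributed here: centroids are built from the block-level
#' subtype shift profiles over the 50 standard classifier genes, plus a
#' small deterministic per-(gene, subtype) offset that breaks rank ties.
#' Self-consistent with the synthetic-cohort generator, and intended for
#' synthetic analyses and tests only; drop in the published matrix (same
#' shape: 50 genes x 5 subtype columns) to classify real cohorts.
#'
#' @return 50 x 5 numeric matrix, rows the classifier genes, columns
#'   LumA, LumB, HER2E, Basal, Normal.
#' @export
synthetic_pam50_centroids <- function() {
  genes <- pam50_genes()
  groups <- pam50_gene_groups()
  shifts <- pam50_subtype_shifts()
  out <- matrix(0, nrow = length(genes), ncol = ncol(shifts),
                dimnames = list(genes, colnames(shifts)))
  for (b in names(groups)) {
    out[groups[[b]], ] <- matrix(shifts[b, ], nrow = length(groups[[b]]),
                                 ncol = ncol(shifts), byrow = TRUE)
  }
  # deterministic tie-breaking offsets, small relative to block shifts
  i <- matrix(seq_along(genes), nrow = length(genes), ncol = ncol(shifts))
  j <- matrix(seq_len(ncol(shifts)), nrow = length(genes),
              ncol = ncol(shifts), byrow = TRUE)
  out + (((i * 31 + j * 17) %% 13) - 6) / 30
}
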