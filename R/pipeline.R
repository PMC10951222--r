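#' Run the full synthetic-cohort analysis pipeline
#'
#' Chains the stages end to end on a simulated cohort: simulate reference
#' and trial cohorts, post-process genomic calls per sample, score
#' transcriptomic signatures against the reference quantiles, assign
#' intrinsic subtypes, extract resistance features and per-patient
#' mechanism verdicts, compute the driver-vs-signature association
#' statistics and the benefit screen, summarize trial efficacy, and run
#' paired-sample clonal dynamics plus lineage detection. Deterministic
#' given the config seed.
#'
#' @param config a \code{sim_config}.
#' @param out_dir optional directory; when given, per-patient report JSONs
#'   and summary TSVs are written there.
#' @param qc_min_genes detected-gene threshold for the RNA QC filter
#'   (default 100, matched to the toy gene universe).
#' @return list with cohort, reference, calls, scores, subtypes, reports,
#'   summary, associations, screen, trial, dynamics, lineage.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL,
                         qc_min_genes = 100) {
  rules <- load_rule_table()
  knowledge <- load_knowledge_table()
  sets <- toy_gene_sets()
  # stage 1: simulate
  ref_raw <- simulate_reference_cohort(config)
  cohort <- simulate_trial_cohort(config, rules)
  # stage 2: genomic calls
  calls <- lapply(cohort$bundles, function(b) {
    annotate_sample_calls(
      b$mutations[, c("gene", "protein_change", "variant_class", "ccf")],
      b$segments[, c("chrom", "start", "end", "total_cn", "minor_cn",
                     "n_genes", "genes")],
      b$purity, b$ploidy, knowledge, source = b$source)
  })
  # stage 3: transcriptomic scoring against the reference
  reference <- reference_cohort(ref_raw$expression,
                                ref_raw$receptor_status, sets)
  tumor_ids <- colnames(cohort$expression)
  qc <- vapply(tumor_ids, function(s)
    rna_qc_filter(cohort$expression[, s], qc_min_genes), logical(1))
  expr <- upper_quartile_normalize(
    cohort$expression[, qc, drop = FALSE])
  es <- score_signatures(expr, sets)
  # NES range-normalized over trial + reference jointly, per set
  ref_es <- score_signatures(reference$expression, sets)
  nes_joint <- normalize_es(cbind(es, ref_es))
  nes <- nes_joint[, colnames(es), drop = FALSE]
  # signature quantile tables must come from the same joint normalization
  ref_nes <- nes_joint[, colnames(ref_es), drop = FALSE]
  sq <- t(apply(ref_nes, 1, stats::quantile,
                probs = c(0.10, 0.25, 0.75, 0.90), names = FALSE))
  colnames(sq) <- c("p10", "p25", "p75", "p90")
  reference$signature_quantiles <- sq
  balanced <- balanced_resample(reference, seed = config$seed)
  centroids <- synthetic_pam50_centroids()
  subtypes <- lapply(colnames(expr), function(s) {
    v <- expr[, s]; names(v) <- rownames(expr)
    pam50_assign(v, centroids, reference, balanced)
  })
  names(subtypes) <- colnames(expr)
  sig_cats <- lapply(colnames(expr), function(s) {
    vapply(rownames(nes), function(set)
      reference_quantile_category(nes[set, s], set, reference),
      character(1))
  })
  names(sig_cats) <- colnames(expr)
  marker_genes <- intersect(c("ESR1", "ERBB2", "FGFR1", "IGF1R", "INSR"),
                            rownames(expr))
  expr_cats <- lapply(colnames(expr), function(s) {
    vapply(marker_genes, function(g)
      reference_quantile_category(expr[g, s], g, reference), character(1))
  })
  names(expr_cats) <- colnames(expr)
  # stage 4: per-patient resistance reports (baseline tumor biopsy)
  patients <- unique(cohort$clinical$patient_id)
  reports <- lapply(patients, function(pid) {
    t1 <- paste0(pid, "_T1")
    clin <- cohort$clinical[cohort$clinical$patient_id == pid, ]
    feats <- extract_features(
      calls = calls[[t1]],
      signature_categories = sig_cats[[t1]],
      expression_categories = expr_cats[[t1]],
      subtype = if (t1 %in% names(subtypes)) subtypes[[t1]]$subtype else NA,
      er_loss_ihc = clin$er_loss_ihc, rules = rules)
    assign_mechanisms(feats, pid)
  })
  names(reports) <- patients
  summary <- cohort_summary(reports)
  # stage 5: association statistics (driver status vs signature activity)
  esr1_mut <- vapply(patients, function(pid) {
    m <- calls[[paste0(pid, "_T1")]]$mutations
    any(m$gene == "ESR1" & m$effect %in% c("GOF", "likely_GOF"))
  }, logical(1))
  t1_ids <- paste0(patients, "_T1")
  keep <- t1_ids %in% colnames(nes)
  assoc <- NULL
  if (length(unique(esr1_mut[keep])) == 2) {
    sc <- nes["ESTROGEN_RESPONSE_EARLY", t1_ids[keep]]
    a <- auc_score(sc, esr1_mut[keep])
    mw <- mw_exact_one_sided_p(a$u, a$n_pos, a$n_neg)
    assoc <- data.frame(feature = "ESTROGEN_RESPONSE_EARLY",
                        label = "ESR1_activating", auc = a$auc, u = a$u,
                        p = mw$p, n_pos = a$n_pos, n_neg = a$n_neg,
                        test = "mw_one_sided")
  }
  benefit <- cohort$clinical$clinical_benefit[match(patients,
                                                    cohort$clinical$patient_id)]
  screen <- if (length(unique(benefit[keep])) == 2) {
    hallmark_screen(nes[, t1_ids[keep], drop = FALSE], benefit[keep],
                    reference)
  } else NULL
  trial <- trial_metrics(cohort$clinical)
  # stage 6: clonal dynamics for paired and lineage patients
  dynamics <- list()
  lineage <- list()
  for (pid in patients) {
    pre_id <- paste0(pid, "_A1"); t1 <- paste0(pid, "_T1")
    bb_id <- paste0(pid, "_BB1")
    if (pre_id %in% names(calls)) {
      dynamics[[pid]] <- compare_paired_samples(calls[[pre_id]],
                                                calls[[t1]], pid, pid)
    }
    if (bb_id %in% names(calls)) {
      lineage[[pid]] <- detect_lineage_divergence(
        calls[[t1]], calls[[bb_id]],
        driver_genes = unique(load_knowledge_table()$gene))
    }
  }
  out <- list(cohort = cohort, reference = reference, calls = calls,
              nes = nes, subtypes = subtypes, sig_cats = sig_cats,
              expr_cats = expr_cats, reports = reports, summary = summary,
              associations = assoc, screen = screen, trial = trial,
              dynamics = dynamics, lineage = lineage)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_cohort(cohort, file.path(out_dir, "cohort"))
    for (pid in patients) {
      r <- reports[[pid]]
      jsonlite::write_json(
        list(patient_id = r$patient_id, verdicts = as.list(r$verdicts),
             overall_class = r$overall_class, explained = r$explained,
             features = r$features),
        file.path(out_dir, paste0(pid, "_report.json")),
        digits = 8, auto_unbox = TRUE, pretty = TRUE)
    }
    utils::write.table(
      data.frame(class = names(summary$counts),
                 count = as.integer(summary$counts)),
      file.path(out_dir, "cohort_summary.tsv"), sep = "\t",
      quote = FALSE, row.names = FALSE)
    if (!is.null(screen)) {
      utils::write.table(screen, file.path(out_dir, "benefit_screen.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  out
}
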