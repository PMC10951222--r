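test_that("reference cohort honors receptor class counts and determinism", {
  cfg <- sim_config(seed = 5)
  ref <- simulate_reference_cohort(cfg)
  expect_equal(ncol(ref$expression), 200)
  counts <- table(ref$receptor_status)
  expect_equal(unname(counts[c("HR+/HER2-", "HR+/HER2+", "HR-/HER2+",
                               "HR-/HER2-")]),
               as.integer(c(84, 27, 10, 12)), ignore_attr = TRUE)
  ref2 <- simulate_reference_cohort(cfg)
  expect_identical(ref$expression, ref2$expression)
  # all centroid genes and all toy-set genes are in the universe
  expect_true(all(pam50_genes() %in% rownames(ref$expression)))
  expect_true(all(unlist(toy_gene_sets()) %in% rownames(ref$expression)))
})

test_that("zero noise collapses each receptor class onto its mean profile", {
  cfg <- small_config(seed = 2, noise_sd = 0)
  ref <- simulate_reference_cohort(cfg)
  for (cl in unique(ref$receptor_status)) {
    cols <- ref$expression[, ref$receptor_status == cl, drop = FALSE]
    expect_true(all(abs(cols - cols[, 1]) < 1e-12))
  }
})

test_that("config validation rejects inconsistent setups", {
  expect_error(sim_config(n_reference_samples = 5), "n_reference_samples")
  expect_error(sim_config(coupling_strengths = c(BOGUS = 2)),
               "unknown pathway")
  expect_error(sim_config(driver_spec = data.frame(
    gene = "WHATEVER", kind = "GOF", pathway = "ER", fraction = 0.5)),
    "no planted-driver definition")
  expect_error(sim_config(driver_spec = data.frame(
    gene = "ESR1", kind = "GOF", pathway = "ER", fraction = 1.5)))
  # universe too small for the core panel is a configuration error
  expect_error(gene_universe(sim_config(n_genes = 2000)), NA)
  cfg_bad <- sim_config()
  cfg_bad$n_genes <- 100L
  expect_error(gene_universe(cfg_bad), "too small")
})

test_that("identical config and seed give byte-identical emitted files", {
  cfg <- small_config(seed = 33, n_patients = 5)
  d1 <- file.path(tempdir(), "cohortA")
  d2 <- file.path(tempdir(), "cohortB")
  write_cohort(simulate_trial_cohort(cfg), d1)
  write_cohort(simulate_trial_cohort(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("every planted alteration is recoverable from the emitted tables", {
  cfg <- small_config(seed = 14, n_patients = 12)
  tc <- simulate_trial_cohort(cfg)
  dir <- file.path(tempdir(), "truthcheck")
  write_cohort(tc, dir)
  maf <- read_maf(file.path(dir, "mutations.tsv"))
  for (t in tc$truth) {
    t1 <- paste0(t$patient_id, "_T1")
    pm <- t$planted_mutations
    for (i in seq_len(nrow(pm))) {
      hit <- maf$sample == t1 & maf$gene == pm$gene[i] &
        maf$protein_change == pm$protein_change[i]
      expect_true(any(hit), label = paste(t1, pm$gene[i]))
    }
  }
})

test_that("empty driver spec leaves only passenger mutations", {
  spec <- sim_config()$driver_spec
  spec$fraction <- 0
  cfg <- small_config(seed = 3, n_patients = 6, driver_spec = spec,
                      n_lineage_patients = 0)
  tc <- simulate_trial_cohort(cfg)
  for (b in tc$bundles) {
    expect_true(all(startsWith(b$mutations$gene, "PSG")))
  }
})

test_that("deterministic benefit model ties labels to the mTOR indicator", {
  cfg <- small_config(seed = 9, n_patients = 15,
                      benefit_model = c("TRUE" = 1, "FALSE" = 0),
                      n_lineage_patients = 0)
  tc <- simulate_trial_cohort(cfg)
  for (t in tc$truth) {
    expect_equal(t$benefit, t$mtor_driver, label = t$patient_id)
    clin <- tc$clinical[tc$clinical$patient_id == t$patient_id, ]
    expect_equal(clin$clinical_benefit, t$benefit)
  }
})

test_that("driver coupling shifts the matching signature genes", {
  spec <- data.frame(gene = "ESR1", kind = "GOF", pathway = "ER",
                     fraction = 1)
  cfg <- small_config(seed = 4, n_patients = 4, driver_spec = spec,
                      noise_sd = 0, n_lineage_patients = 0,
                      er_loss_fraction = 0,
                      coupling_strengths = c(ER = 2, RTK = 2, MAPK = 2,
                                             PI3K_AKT_mTOR = 2, P53 = 2))
  spec0 <- spec; spec0$fraction <- 0
  cfg0 <- small_config(seed = 4, n_patients = 4, driver_spec = spec0,
                       noise_sd = 0, n_lineage_patients = 0,
                       er_loss_fraction = 0,
                       coupling_strengths = c(ER = 2, RTK = 2, MAPK = 2,
                                              PI3K_AKT_mTOR = 2, P53 = 2))
  with_d <- simulate_trial_cohort(cfg)$expression
  without <- simulate_trial_cohort(cfg0)$expression
  ere <- toy_gene_sets()$ESTROGEN_RESPONSE_EARLY
  neutral <- toy_gene_sets()$GLYCOLYSIS
  diff_ere <- rowMeans(with_d[ere, , drop = FALSE]) -
    rowMeans(without[ere, , drop = FALSE])
  diff_neu <- rowMeans(with_d[neutral, , drop = FALSE]) -
    rowMeans(without[neutral, , drop = FALSE])
  expect_true(all(diff_ere > 1.5))
  expect_true(all(abs(diff_neu) < 1e-9))
})

test_that("stronger coupling never lowers the mean driver-recovery AUC", {
  spec <- data.frame(gene = "ESR1", kind = "GOF", pathway = "ER",
                     fraction = 0.5)
  mean_auc <- function(strength) {
    aucs <- vapply(1:10, function(s) {
      cfg <- small_config(seed = 100 + s, n_patients = 24,
                          driver_spec = spec, n_lineage_patients = 0,
                          er_loss_fraction = 0,
                          coupling_strengths = c(ER = strength, RTK = 2,
                                                 MAPK = 2,
                                                 PI3K_AKT_mTOR = 2,
                                                 P53 = 2))
      tc <- simulate_trial_cohort(cfg)
      has_driver <- vapply(tc$truth, function(t)
        any(t$drivers$gene == "ESR1"), logical(1))
      if (length(unique(has_driver)) < 2) return(NA_real_)
      sets <- toy_gene_sets()["ESTROGEN_RESPONSE_EARLY"]
      es <- score_signatures(
        upper_quartile_normalize(tc$expression), sets)
      auc_score(es[1, paste0(names(tc$truth), "_T1")], has_driver)$auc
    }, numeric(1))
    mean(aucs, na.rm = TRUE)
  }
  aucs <- vapply(c(0, 1, 3), mean_auc, numeric(1))
  expect_true(all(diff(aucs) >= -0.02))
  expect_gt(aucs[3], 0.9)
})
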