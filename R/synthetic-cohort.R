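#' Toy hallmark-style gene sets
#'
#' Ten 30-gene sets over synthetic gene symbols: two estrogen-response
#' sets, two PI3K/AKT/mTOR sets, a p53 set, three RTK activity signatures
#' (RTK ACT, HER2 MUT, FGFR ACT), and two neutral sets. Full MSigDB GMT
#' files can be dropped in wherever a \code{gene_sets} argument is taken.
#'
#' @return named list of character vectors.
#' @export
toy_gene_sets <- function() {
  mk <- function(prefix) sprintf("%s_%03d", prefix, 1:30)
  list(
    ESTROGEN_RESPONSE_EARLY = mk("ERE"),
    ESTROGEN_RESPONSE_LATE = mk("ERL"),
    MTORC1_SIGNALING = mk("MT1"),
    PI3K_AKT_MTOR_SIGNALING = mk("PAM"),
    P53_PATHWAY = mk("P53"),
    RTK_ACT = mk("RTK"),
    HER2_MUT = mk("H2M"),
    FGFR_ACT = mk("FGA"),
    APOPTOSIS = mk("APO"),
    GLYCOLYSIS = mk("GLY")
  )
}

# planted driver event definitions: canonical protein changes per gene
planted_driver_defs <- function() {
  data.frame(
    gene = c("ESR1", "ERBB2", "BRAF", "AKT1", "MTOR", "PIK3CA", "PIK3CA",
             "TP53", "RB1", "PTEN", "GATA3"),
    kind = c("GOF", "GOF", "GOF", "GOF", "GOF", "double_GOF", "double_GOF",
             "biallelic", "biallelic", "biallelic", "LOF"),
    protein_change = c("D538G", "L869R", "V600E", "E17K", "T1977R",
                       "E545K", "G1007R", "R175H", "R320*", "R130*",
                       "M400fs"),
    variant_class = c("missense", "missense", "missense", "missense",
                      "missense", "missense", "missense", "missense",
                      "nonsense", "nonsense", "frameshift_del"),
    stringsAsFactors = FALSE)
}

# pathway -> coupled signature sets
pathway_sets <- function() {
  list(ER = c("ESTROGEN_RESPONSE_EARLY", "ESTROGEN_RESPONSE_LATE"),
       RTK = c("RTK_ACT", "HER2_MUT"),
       MAPK = c("RTK_ACT", "HER2_MUT"),
       PI3K_AKT_mTOR = c("MTORC1_SIGNALING", "PI3K_AKT_MTOR_SIGNALING"),
       P53 = "P53_PATHWAY",
       cell_cycle = character(0))
}

#' Simulation configuration
#'
#' Validated configuration for the synthetic reference and trial cohorts.
#' Defaults emulate the study conditions: a 200-sample reference expression
#' cohort with receptor classes 84 HR+/HER2-, 27 HR+/HER2+, 10 HR-/HER2+,
#' 12 HR-/HER2- (remainder unlabeled), and a 23-patient trial cohort with
#' planted drivers at landscape-like frequencies. Identical config + seed
#' yields byte-identical output.
#'
#' @param seed integer master seed; all randomness flows from it through
#'   fixed per-stage substreams.
#' @param n_reference_samples reference cohort size (>= 20).
#' @param reference_receptor_counts named counts per receptor class; must
#'   sum to at most \code{n_reference_samples} (remainder is "unknown").
#' @param n_patients trial cohort size.
#' @param n_genes expression universe size (>= 500).
#' @param driver_spec data.frame (gene, kind, pathway, fraction): planted
#'   alteration frequencies. Kinds: GOF, double_GOF, biallelic, HIGH_AMP.
#' @param coupling_strengths named log2-shift per pathway applied to the
#'   coupled signature genes of driver-positive patients (the p53 pathway
#'   shift is applied downward).
#' @param noise_sd per-gene Gaussian noise SD, log2 units.
#' @param benefit_model named probabilities of clinical benefit given the
#'   presence ("TRUE") / absence ("FALSE") of an mTOR-pathway driver.
#' @param passenger_rate Poisson mean of passenger mutations per sample.
#' @param paired_fraction fraction of eligible patients receiving a paired
#'   pre-CDK4/6i bundle.
#' @param n_lineage_patients number of patients planted with a second,
#'   divergent tumor lineage observed through a ctDNA bundle.
#' @param er_loss_fraction probability of ER loss by IHC.
#' @return validated list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L,
                       n_reference_samples = 200L,
                       reference_receptor_counts = c("HR+/HER2-" = 84,
                                                     "HR+/HER2+" = 27,
                                                     "HR-/HER2+" = 10,
                                                     "HR-/HER2-" = 12),
                       n_patients = 23L,
                       n_genes = 2000L,
                       driver_spec = NULL,
                       coupling_strengths = c(ER = 2, RTK = 2, MAPK = 2,
                                              PI3K_AKT_mTOR = 2, P53 = 2),
                       noise_sd = 0.5,
                       benefit_model = c("TRUE" = 0.75, "FALSE" = 0.10),
                       passenger_rate = 30,
                       paired_fraction = 0.25,
                       n_lineage_patients = 2L,
                       er_loss_fraction = 0.05) {
  if (is.null(driver_spec)) {
    driver_spec <- data.frame(
      gene = c("ESR1", "ERBB2", "BRAF", "AKT1", "PIK3CA", "MTOR", "TP53",
               "RB1", "FGFR1"),
      kind = c("GOF", "GOF", "GOF", "GOF", "double_GOF", "GOF", "biallelic",
               "biallelic", "HIGH_AMP"),
      pathway = c("ER", "RTK", "MAPK", "PI3K_AKT_mTOR", "PI3K_AKT_mTOR",
                  "PI3K_AKT_mTOR", "P53", "cell_cycle", "RTK"),
      fraction = c(0.45, 0.10, 0.05, 0.15, 0.10, 0.05, 0.15, 0.10, 0.15),
      stringsAsFactors = FALSE)
  }
  stopifnot(n_reference_samples >= 20, n_patients >= 1, n_genes >= 500,
            sum(reference_receptor_counts) <= n_reference_samples,
            all(driver_spec$fraction >= 0 & driver_spec$fraction <= 1),
            noise_sd >= 0, er_loss_fraction >= 0, er_loss_fraction <= 1,
            all(c("TRUE", "FALSE") %in% names(benefit_model)))
  if (!all(names(coupling_strengths) %in% names(pathway_sets()))) {
    stop("sim_config: coupling_strengths references an unknown pathway")
  }
  if (!all(driver_spec$pathway %in% names(pathway_sets()))) {
    stop("sim_config: driver_spec references an unknown pathway")
  }
  defs <- planted_driver_defs()
  mut_kinds <- c("GOF", "double_GOF", "biallelic", "LOF")
  bad <- driver_spec$gene[driver_spec$kind %in% mut_kinds &
                            !(driver_spec$gene %in% defs$gene)]
  if (length(bad) > 0) {
    stop(sprintf("sim_config: no planted-driver definition for: %s",
                 paste(bad, collapse = ", ")))
  }
  structure(list(seed = as.integer(seed),
                 n_reference_samples = as.integer(n_reference_samples),
                 reference_receptor_counts = reference_receptor_counts,
                 n_patients = as.integer(n_patients),
                 n_genes = as.integer(n_genes),
                 driver_spec = driver_spec,
                 coupling_strengths = coupling_strengths,
                 noise_sd = noise_sd, benefit_model = benefit_model,
                 passenger_rate = passenger_rate,
                 paired_fraction = paired_fraction,
                 n_lineage_patients = as.integer(n_lineage_patients),
                 er_loss_fraction = er_loss_fraction),
            class = "sim_config")
}

#' Expression gene universe of a configuration
#'
#' The 50 subtype-classifier genes, the driver/marker panel, the 300 toy
#' signature genes, and a synthetic passenger/filler pool up to
#' \code{n_genes}.
#'
#' @param config a \code{sim_config}.
#' @return character vector of unique gene symbols.
#' @export
gene_universe <- function(config) {
  markers <- c("PIK3CA", "AKT1", "BRAF", "MTOR", "TP53", "RB1", "PTEN",
               "NF1", "FGFR1", "FGFR2", "AURKA", "IGF1R", "INSR", "GATA3",
               "CDH1", "KRAS")
  core <- c(pam50_genes(), setdiff(markers, pam50_genes()),
            unlist(toy_gene_sets(), use.names = FALSE))
  if (config$n_genes < length(core)) {
    stop("gene_universe: n_genes too small for the core gene panel")
  }
  filler <- sprintf("PSG%04d", seq_len(config$n_genes - length(core)))
  c(core, filler)
}

# synthetic gene coordinates: 100 genes per chromosome, 1 Mb apart
gene_coordinates <- function(universe) {
  i <- seq_along(universe) - 1L
  data.frame(gene = universe, chrom = i %/% 100L + 1L,
             pos = (i %% 100L + 1L) * 1e6, stringsAsFactors = FALSE)
}

# baseline per-gene log2(TPM+1) means, deterministic in the config seed
baseline_means <- function(config) {
  universe <- gene_universe(config)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed %% 100000L * 17L + 3L)
  mu <- pmin(pmax(stats::rnorm(length(universe), 6, 1.5), 0.5), 12)
  stats::setNames(mu, universe)
}

# receptor-class shifts over the subtype marker blocks (log2 units)
receptor_class_shift <- function(class, universe) {
  g <- pam50_gene_groups()
  shift <- stats::setNames(numeric(length(universe)), universe)
  bump <- function(genes, by) {
    genes <- intersect(genes, universe)
    shift[genes] <<- shift[genes] + by
  }
  if (startsWith(class, "HR+")) {
    bump(g$luminal, 1.5); bump("ESR1", 0.5)
  }
  if (endsWith(class, "HER2+")) {
    bump(g$her2, 2); bump("ERBB2", 0.5)
  }
  if (class == "HR-/HER2-") {
    bump(g$basal, 1.5); bump(g$luminal, -1.5)
  }
  shift
}

#' Simulate the receptor-labeled reference expression cohort
#'
#' Per-gene Gaussian model in log2(TPM+1): baseline means shared with the
#' trial generator, receptor-class shifts on the subtype marker blocks,
#' and i.i.d. noise. With \code{noise_sd = 0} every sample of a class
#' equals the class mean profile exactly.
#'
#' @param config a \code{sim_config}.
#' @return list with \code{expression} (genes x samples matrix,
#'   log2(TPM+1)) and \code{receptor_status} (character per sample).
#' @export
simulate_reference_cohort <- function(config) {
  universe <- gene_universe(config)
  missing <- setdiff(pam50_genes(), universe)
  if (length(missing) > 0) {
    stop("simulate_reference_cohort: gene universe missing centroid genes")
  }
  mu <- baseline_means(config)
  counts <- config$reference_receptor_counts
  status <- c(rep(names(counts), counts),
              rep("unknown", config$n_reference_samples - sum(counts)))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed %% 100000L * 17L + 1000L)
  mat <- vapply(status, function(cl) {
    pmax(mu + receptor_class_shift(cl, universe) +
           stats::rnorm(length(mu), 0, config$noise_sd), 0)
  }, numeric(length(mu)))
  colnames(mat) <- sprintf("REF%03d", seq_along(status))
  rownames(mat) <- universe
  list(expression = mat, receptor_status = status)
}

# expected mechanism class implied by a patient's planted genomic/clinical
# features, via the same rule table the engine uses
planted_mechanism_class <- function(driver_rows, er_loss, rules) {
  trig <- c(GOF = "mutation_gof", double_GOF = "double_gof",
            biallelic = "mutation_lof", LOF = "mutation_lof",
            HIGH_AMP = "high_amp")
  feats <- list()
  for (i in seq_len(nrow(driver_rows))) {
    r <- rules[rules$trigger == trig[[driver_rows$kind[i]]] &
                 rules$target == driver_rows$gene[i], , drop = FALSE]
    if (nrow(r) > 0) feats[[length(feats) + 1]] <- r[1, ]
  }
  if (er_loss) {
    feats[[length(feats) + 1]] <- rules[rules$trigger == "er_loss", ][1, ]
  }
  if (length(feats) == 0) {
    return(assign_mechanisms(extract_features(
      calls = empty_sample_calls(), rules = rules))$overall_class)
  }
  f <- do.call(rbind, feats)
  f$description <- f$target; f$source <- "planted"
  assign_mechanisms(f)$overall_class
}

# an empty sample_calls object (used for no-driver patients)
empty_sample_calls <- function(purity = 0.5, ploidy = 2, source = "tumor") {
  annotate_sample_calls(
    data.frame(gene = character(0), protein_change = character(0),
               variant_class = character(0), ccf = numeric(0),
               stringsAsFactors = FALSE),
    data.frame(chrom = integer(0), start = numeric(0), end = numeric(0),
               total_cn = numeric(0), minor_cn = numeric(0),
               n_genes = integer(0), genes = character(0),
               stringsAsFactors = FALSE),
    purity, ploidy, source = source)
}

# build a segment table: neutral background per chromosome, with focal
# overrides for planted CNA / LOH events (genes partition across segments)
build_segments <- function(universe, ploidy, focal) {
  coords <- gene_coordinates(universe)
  rows <- list()
  for (ch in unique(coords$chrom)) {
    genes_ch <- coords$gene[coords$chrom == ch]
    f_ch <- focal[focal$chrom == ch, , drop = FALSE]
    bg_genes <- setdiff(genes_ch, unlist(strsplit(f_ch$genes, ",")))
    if (length(bg_genes) > 0) {
      rows[[length(rows) + 1]] <- data.frame(
        chrom = ch, start = 1, end = 101e6, total_cn = ploidy,
        minor_cn = floor(ploidy / 2), n_genes = length(bg_genes),
        genes = paste(bg_genes, collapse = ","), stringsAsFactors = FALSE)
    }
    if (nrow(f_ch) > 0) rows[[length(rows) + 1]] <- f_ch
  }
  do.call(rbind, rows)
}

empty_focal_frame <- function() {
  data.frame(chrom = integer(0), start = numeric(0), end = numeric(0),
             total_cn = numeric(0), minor_cn = numeric(0),
             n_genes = integer(0), genes = character(0),
             stringsAsFactors = FALSE)
}

# focal segment row for one gene
focal_segment <- function(gene, universe, total_cn, minor_cn,
                          n_genes = 40L) {
  coords <- gene_coordinates(universe)
  co <- coords[coords$gene == gene, ]
  data.frame(chrom = co$chrom, start = co$pos - 4e5, end = co$pos + 4e5,
             total_cn = total_cn, minor_cn = minor_cn, n_genes = n_genes,
             genes = gene, stringsAsFactors = FALSE)
}

#' Simulate the trial cohort with planted ground truth
#'
#' Generates per-patient sample bundles (mutation, segment, purity/ploidy
#' tables, expression, clinical metadata) with planted driver alterations,
#' driver-coupled signature shifts, subtype structure, benefit labels drawn
#' from the benefit model, optional paired pre-CDK4/6i bundles, and
#' optional two-lineage patients with a divergent ctDNA bundle. The truth
#' manifest records every planted alteration (recoverable from the emitted
#' tables by exact gene + protein-change match), the planted subtype,
#' benefit label, and the mechanism class implied by the planted
#' genomic/clinical features under the rule table.
#'
#' @param config a \code{sim_config}.
#' @param rules rule table used to pre-compute planted mechanism classes.
#' @return list with \code{bundles} (per sample), \code{expression}
#'   (genes x tumor samples), \code{clinical} (per patient), \code{truth}.
#' @export
simulate_trial_cohort <- function(config, rules = load_rule_table()) {
  universe <- gene_universe(config)
  mu <- baseline_means(config)
  defs <- planted_driver_defs()
  psets <- pathway_sets()
  sets <- toy_gene_sets()
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed %% 100000L * 17L + 2000L)
  bundles <- list()
  truth <- list()
  expr_cols <- list()
  clin_rows <- list()
  n_paired_left <- ceiling(config$paired_fraction * config$n_patients)
  for (p in seq_len(config$n_patients)) {
    pid <- sprintf("P%02d", p)
    ploidy <- sample(c(2, 2, 2, 3.2), 1)
    purity <- stats::runif(1, 0.2, 0.9)
    is_lineage <- p <= config$n_lineage_patients
    # planted drivers
    spec <- config$driver_spec
    has <- stats::runif(nrow(spec)) < spec$fraction
    drivers <- spec[has, , drop = FALSE]
    if (is_lineage) {
      # force the divergent-lineage wiring: truncal GATA3 LOF, tumor-private
      # ESR1 activation, ctDNA-private MTOR activation
      drivers <- drivers[!(drivers$gene %in% c("ESR1", "MTOR", "GATA3")), ]
      drivers <- rbind(drivers, data.frame(
        gene = c("ESR1", "GATA3"), kind = c("GOF", "LOF"),
        pathway = c("ER", "ER"), fraction = 1))
    }
    er_loss <- stats::runif(1) < config$er_loss_fraction
    # subtype
    subtype <- if (any(drivers$gene %in% c("ERBB2", "BRAF") &
                         drivers$kind == "GOF")) "HER2E"
    else if (any(drivers$gene == "ESR1")) {
      sample(c("LumA", "LumB"), 1, prob = c(0.3, 0.7))
    } else if (er_loss) "Basal"
    else sample(c("LumA", "LumB", "Normal", "Basal"), 1,
                prob = c(0.4, 0.3, 0.2, 0.1))
    # mutations: planted + passengers
    mut_rows <- list()
    planted_mut <- drivers[drivers$kind %in%
                             c("GOF", "double_GOF", "biallelic", "LOF"), ,
                           drop = FALSE]
    for (i in seq_len(nrow(planted_mut))) {
      dd <- defs[defs$gene == planted_mut$gene[i] &
                   defs$kind == planted_mut$kind[i], , drop = FALSE]
      for (j in seq_len(nrow(dd))) {
        mut_rows[[length(mut_rows) + 1]] <- data.frame(
          gene = dd$gene[j], protein_change = dd$protein_change[j],
          variant_class = dd$variant_class[j],
          ccf = stats::runif(1, 0.85, 1), stringsAsFactors = FALSE)
      }
    }
    n_pass <- stats::rpois(1, config$passenger_rate)
    pool <- universe[startsWith(universe, "PSG")]
    if (n_pass > 0 && length(pool) > 0) {
      pg <- sample(pool, min(n_pass, length(pool)))
      aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
      mut_rows[[length(mut_rows) + 1]] <- data.frame(
        gene = pg,
        protein_change = sprintf("%s%d%s",
                                 sample(aa, length(pg), TRUE),
                                 sample(50:900, length(pg), TRUE),
                                 sample(aa, length(pg), TRUE)),
        variant_class = "missense",
        ccf = ifelse(stats::runif(length(pg)) < 0.5,
                     stats::runif(length(pg), 0.85, 1),
                     stats::runif(length(pg), 0.1, 0.5)),
        stringsAsFactors = FALSE)
    }
    mutations <- if (length(mut_rows) > 0) do.call(rbind, mut_rows)
    else empty_sample_calls()$mutations[, c("gene", "protein_change",
                                            "variant_class", "ccf")]
    # segments: focal events for CNA drivers and biallelic LOH
    focal <- list()
    for (i in seq_len(nrow(drivers))) {
      if (drivers$kind[i] == "HIGH_AMP") {
        focal[[length(focal) + 1]] <- focal_segment(
          drivers$gene[i], universe, total_cn = ploidy + 6.5,
          minor_cn = 1, n_genes = 60L)
      } else if (drivers$kind[i] == "biallelic") {
        focal[[length(focal) + 1]] <- focal_segment(
          drivers$gene[i], universe, total_cn = 1, minor_cn = 0,
          n_genes = 30L)
      }
    }
    focal <- if (length(focal) > 0) do.call(rbind, focal)
    else empty_focal_frame()
    segments <- build_segments(universe, ploidy, focal)
    # expression: baseline + subtype + couplings + marker effects + noise
    shift <- stats::setNames(numeric(length(universe)), universe)
    gb <- pam50_gene_groups()
    st_shift <- pam50_subtype_shifts()[, subtype]
    for (b in names(gb)) {
      gg <- intersect(gb[[b]], universe)
      shift[gg] <- shift[gg] + st_shift[[b]]
    }
    for (i in seq_len(nrow(drivers))) {
      pw <- drivers$pathway[i]
      cs <- if (pw %in% names(config$coupling_strengths)) {
        config$coupling_strengths[[pw]]
      } else 0
      sgn <- if (pw == "P53") -1 else 1
      for (s in psets[[pw]]) {
        gg <- intersect(sets[[s]], universe)
        shift[gg] <- shift[gg] + sgn * cs
      }
      if (drivers$kind[i] == "HIGH_AMP") {
        shift[drivers$gene[i]] <- shift[drivers$gene[i]] + 2
      }
      if (drivers$gene[i] == "ESR1") shift["ESR1"] <- shift["ESR1"] + 1
      if (drivers$gene[i] == "ERBB2") shift["ERBB2"] <- shift["ERBB2"] + 1
    }
    if (er_loss) shift["ESR1"] <- shift["ESR1"] - 3
    expr <- pmax(mu + shift +
                   stats::rnorm(length(mu), 0, config$noise_sd), 0)
    # benefit + clinical
    mtor_driver <- any(drivers$pathway == "PI3K_AKT_mTOR")
    p_benefit <- config$benefit_model[[as.character(mtor_driver)]]
    benefit <- stats::runif(1) < p_benefit
    dur_weeks <- if (benefit) stats::runif(1, 24, 60)
    else stats::runif(1, 4, 20)
    best_response <- if (benefit) "SD"
    else if (dur_weeks >= 12) "SD" else "PD"
    prior_months <- stats::runif(1, 2, 30)
    sample_id <- paste0(pid, "_T1")
    bundle <- list(patient_id = pid, sample_id = sample_id,
                   source = "tumor", timepoint = "baseline_tumor",
                   mutations = cbind(sample = sample_id, mutations),
                   segments = cbind(sample = sample_id, segments),
                   purity = purity, ploidy = ploidy)
    bundles[[sample_id]] <- bundle
    expr_cols[[sample_id]] <- expr
    # paired pre-CDK4/6i bundle
    paired <- NULL
    dyn_truth <- NULL
    elig <- nrow(planted_mut) > 0 && !is_lineage
    if (elig && n_paired_left > 0) {
      n_paired_left <- n_paired_left - 1
      pre_mut <- mutations
      pick_gene <- planted_mut$gene[1]
      mode <- sample(c("acquired", "enriched"), 1)
      pick_rows <- which(pre_mut$gene == pick_gene)
      if (mode == "acquired") {
        pre_mut <- pre_mut[-pick_rows, , drop = FALSE]
      } else {
        pre_mut$ccf[pick_rows] <- stats::runif(length(pick_rows), 0.1, 0.5)
      }
      # CNA drivers present as GAIN pre, HIGH_AMP post (enriched)
      pre_focal <- focal
      amp_rows <- which(drivers$kind == "HIGH_AMP")
      cna_truth <- character(0)
      if (length(amp_rows) > 0) {
        for (g in drivers$gene[amp_rows]) {
          pre_focal$total_cn[pre_focal$genes == g] <- ploidy + 2
          cna_truth <- c(cna_truth, g)
        }
      }
      pre_segments <- build_segments(universe, ploidy, pre_focal)
      pre_id <- paste0(pid, "_A1")
      paired <- list(patient_id = pid, sample_id = pre_id,
                     source = "tumor", timepoint = "pre_cdk46i",
                     mutations = cbind(sample = pre_id, pre_mut),
                     segments = cbind(sample = pre_id, pre_segments),
                     purity = stats::runif(1, 0.2, 0.9), ploidy = ploidy)
      bundles[[pre_id]] <- paired
      dyn_truth <- list(
        gene = pick_gene, mode = mode,
        protein_change = defs$protein_change[defs$gene == pick_gene][1],
        enriched_cna = cna_truth)
    }
    # divergent-lineage ctDNA bundle
    if (is_lineage) {
      bb_id <- paste0(pid, "_BB1")
      keep <- mutations$gene != "ESR1" # tumor-private driver stays out
      bb_mut <- mutations[keep, , drop = FALSE]
      # thin shared passengers, add the ctDNA-private driver
      bb_mut <- rbind(bb_mut, data.frame(
        gene = "MTOR", protein_change = "T1977R",
        variant_class = "missense", ccf = stats::runif(1, 0.85, 1),
        stringsAsFactors = FALSE))
      bb_seg <- build_segments(universe, ploidy,
                               focal[focal$minor_cn > 0, , drop = FALSE])
      bundles[[bb_id]] <- list(patient_id = pid, sample_id = bb_id,
                               source = "ctDNA",
                               timepoint = "baseline_blood",
                               mutations = cbind(sample = bb_id, bb_mut),
                               segments = cbind(sample = bb_id, bb_seg),
                               purity = stats::runif(1, 0.1, 0.5),
                               ploidy = ploidy)
    }
    clin_rows[[pid]] <- data.frame(
      patient_id = pid, receptor_status = "HR+/HER2-",
      er_loss_ihc = er_loss,
      prior_cdk46i_duration_months = round(prior_months, 1),
      trial_duration_weeks = round(dur_weeks, 1),
      best_response = best_response,
      response_duration_weeks = round(dur_weeks, 1),
      clinical_benefit = benefit,
      discontinuation_reason = if (benefit) "progression_late"
      else "progression", stringsAsFactors = FALSE)
    truth[[pid]] <- list(
      patient_id = pid,
      drivers = drivers[, c("gene", "kind", "pathway")],
      planted_mutations = mutations[!startsWith(mutations$gene, "PSG"),
                                    c("gene", "protein_change")],
      subtype = subtype, er_loss = er_loss,
      mtor_driver = mtor_driver, benefit = benefit,
      mechanism_class = planted_mechanism_class(drivers, er_loss, rules),
      dynamics = dyn_truth,
      lineage = is_lineage)
  }
  expression <- do.call(cbind, expr_cols)
  rownames(expression) <- universe
  list(bundles = bundles, expression = expression,
       clinical = do.call(rbind, clin_rows), truth = truth,
       config = config)
}
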