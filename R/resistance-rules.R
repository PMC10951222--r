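#' Load the resistance-mechanism rule table
#'
#' The rule engine is data-driven: each row maps a clinical, genomic, or
#' transcriptomic trigger to a resistance pathway, the treatments it applies
#' to, and an evidence label (known mechanism vs plausible mechanism). The
#' shipped defaults transcribe the published landscape of CDK4/6i and
#' endocrine-therapy resistance features; edit the TSV to change the engine.
#'
#' @param path TSV path; defaults to the bundled table.
#' @return data.frame with columns trigger, target, pathway, applies_to,
#'   evidence.
#' @export
load_rule_table <- function(path = system.file("extdata",
                                               "resistance_rules.tsv",
                                               package = "resistscape")) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Extract per-patient resistance features
#'
#' Applies the rule table to one patient's discrete calls. Transcriptomic
#' "high" means high_quartile or above and "low" means low_quartile or
#' below; high-grade copy-number triggers fire on HIGH_AMP /
#' FOCAL_HIGH_AMP (and DEEP_DEL for deep_del rules) only. Deep deletions
#' are ignored for ctDNA-derived calls. The result is a pure function of
#' the inputs: row order never matters.
#'
#' @param calls \code{sample_calls} object (or NULL when only
#'   transcriptomic data exist).
#' @param signature_categories named character vector, signature name ->
#'   quantile category (or NULL).
#' @param expression_categories named character vector, gene ->
#'   quantile category (or NULL).
#' @param subtype PAM50-style subtype string (or NA).
#' @param er_loss_ihc logical, loss of ER by IHC (default FALSE).
#' @param rules rule table from \code{load_rule_table()}.
#' @return data.frame of features (description, trigger, target, source,
#'   pathway, evidence, applies_to), zero rows when nothing fires.
#' @export
extract_features <- function(calls = NULL, signature_categories = NULL,
                             expression_categories = NULL, subtype = NA,
                             er_loss_ihc = FALSE,
                             rules = load_rule_table()) {
  if (is.null(calls) && is.null(signature_categories) &&
      is.null(expression_categories) && is.na(subtype)) {
    stop("extract_features: no genomic or transcriptomic input")
  }
  high <- c("high_quartile", "high_decile")
  low <- c("low_quartile", "low_decile")
  mut <- if (!is.null(calls)) calls$mutations else NULL
  cna <- if (!is.null(calls)) calls$cna else NULL
  feats <- list()
  add <- function(rule, description, source) {
    feats[[length(feats) + 1]] <<- data.frame(
      description = description, trigger = rule$trigger,
      target = rule$target, source = source, pathway = rule$pathway,
      evidence = rule$evidence, applies_to = rule$applies_to,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(rules))) {
    rule <- rules[i, ]
    switch(rule$trigger,
      mutation_gof = {
        hit <- !is.null(mut) && any(mut$gene == rule$target &
                                      mut$effect %in% c("GOF", "likely_GOF"))
        if (hit) {
          pc <- mut$protein_change[mut$gene == rule$target &
                                     mut$effect %in% c("GOF", "likely_GOF")]
          add(rule, sprintf("%s activating mutation (%s)", rule$target,
                            paste(pc, collapse = ";")), "genomic")
        }
      },
      mutation_lof = {
        lof <- !is.null(mut) && any(
          mut$gene == rule$target &
            (mut$effect %in% c("LOF", "likely_LOF") |
               mut$variant_class %in% lof_variant_classes))
        bi <- !is.null(calls) && rule$target %in% calls$biallelic
        if (lof || bi) {
          add(rule, sprintf("%s loss-of-function%s", rule$target,
                            if (bi) " (biallelic)" else ""), "genomic")
        }
      },
      double_gof = {
        hit <- !is.null(mut) && any(mut$gene == rule$target & mut$multi_hit)
        if (hit) {
          add(rule, sprintf("double %s activating mutation", rule$target),
              "genomic")
        }
      },
      high_amp = {
        hit <- !is.null(cna) && any(
          cna$gene == rule$target &
            cna$cna_class %in% c("HIGH_AMP", "FOCAL_HIGH_AMP"))
        if (hit) add(rule, sprintf("%s high amplification", rule$target),
                     "genomic")
      },
      deep_del = {
        hit <- !is.null(cna) && !identical(calls$source, "ctDNA") &&
          any(cna$gene == rule$target & cna$cna_class == "DEEP_DEL")
        if (hit) add(rule, sprintf("%s deep deletion", rule$target),
                     "genomic")
      },
      er_loss = {
        if (isTRUE(er_loss_ihc)) add(rule, "loss of ER by IHC", "clinical")
      },
      subtype = {
        if (!is.na(subtype) && subtype == rule$target) {
          add(rule, sprintf("%s intrinsic subtype", rule$target),
              "transcriptomic")
        }
      },
      signature_high = {
        if (!is.null(signature_categories) &&
            rule$target %in% names(signature_categories) &&
            signature_categories[[rule$target]] %in% high) {
          add(rule, sprintf("high %s signature activity", rule$target),
              "transcriptomic")
        }
      },
      signature_low = {
        if (!is.null(signature_categories) &&
            rule$target %in% names(signature_categories) &&
            signature_categories[[rule$target]] %in% low) {
          add(rule, sprintf("low %s signature activity", rule$target),
              "transcriptomic")
        }
      },
      expression_high = {
        if (!is.null(expression_categories) &&
            rule$target %in% names(expression_categories) &&
            expression_categories[[rule$target]] %in% high) {
          add(rule, sprintf("high %s expression", rule$target),
              "transcriptomic")
        }
      },
      expression_low = {
        if (!is.null(expression_categories) &&
            rule$target %in% names(expression_categories) &&
            expression_categories[[rule$target]] %in% low) {
          add(rule, sprintf("low %s expression", rule$target),
              "transcriptomic")
        }
      },
      stop(sprintf("unknown rule trigger '%s'", rule$trigger)))
  }
  if (length(feats) == 0) {
    return(data.frame(description = character(0), trigger = character(0),
                      target = character(0), source = character(0),
                      pathway = character(0), evidence = character(0),
                      applies_to = character(0)))
  }
  out <- do.call(rbind, feats)
  rownames(out) <- NULL
  out
}

#' Per-patient mechanism verdicts from extracted features
#'
#' Each treatment's verdict is the maximum evidence level among the
#' features that apply to it (known > plausible); a treatment with no
#' applicable feature is unexplained. The patient-level class mirrors the
#' cohort summary convention: "known" when both treatments have a known
#' mechanism, "known_plus_plausible" when one does, "plausible_only" when
#' both are explained but only by plausible features, "unexplained"
#' otherwise. A patient counts as explained iff both treatments have at
#' least one feature. Adding a feature can only promote a verdict.
#'
#' @param features data.frame from \code{extract_features}.
#' @param patient_id optional identifier carried into the report.
#' @return list of class \code{patient_report} with \code{verdicts} (named
#'   for CDK46i and anti_ER), \code{overall_class}, \code{explained},
#'   \code{features}.
#' @export
assign_mechanisms <- function(features, patient_id = NA_character_) {
  treatments <- c("CDK46i", "anti_ER")
  verdicts <- vapply(treatments, function(tx) {
    applies <- vapply(features$applies_to, function(a)
      tx %in% strsplit(a, ";", fixed = TRUE)[[1]], logical(1))
    ev <- features$evidence[applies]
    if (any(ev == "known")) "known"
    else if (any(ev == "plausible")) "plausible_only"
    else "unexplained"
  }, character(1))
  explained <- all(verdicts != "unexplained")
  overall <- if (!explained) "unexplained"
  else if (all(verdicts == "known")) "known"
  else if (any(verdicts == "known")) "known_plus_plausible"
  else "plausible_only"
  structure(list(patient_id = patient_id, features = features,
                 verdicts = verdicts, overall_class = overall,
                 explained = explained),
            class = "patient_report")
}

#' Cohort-level mechanism summary
#'
#' @param reports list of \code{patient_report} objects.
#' @return list with \code{counts} (named: known, known_plus_plausible,
#'   plausible_only, unexplained), \code{n}, \code{explained_fraction}.
#' @export
cohort_summary <- function(reports) {
  stopifnot(length(reports) >= 1)
  classes <- vapply(reports, function(r) r$overall_class, character(1))
  lev <- c("known", "known_plus_plausible", "plausible_only", "unexplained")
  counts <- table(factor(classes, levels = lev))
  list(counts = counts, n = length(reports),
       explained_fraction = mean(classes != "unexplained"))
}
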