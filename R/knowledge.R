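#' Load the bundled oncogenic-knowledge snapshot
#'
#' A static lookup table of known oncogenic effects (gain / loss of
#' function) and actionability level strings for the resistance-gene panel.
#' Three row kinds are supported: exact protein-change matches, positional
#' missense windows (e.g. any ESR1 536-538 missense), and truncating
#' variant-class rules for tumor suppressors.
#'
#' @param path TSV path; defaults to the snapshot shipped with the package.
#' @return data.frame with columns gene, match_type, protein_change,
#'   pos_min, pos_max, variant_classes, effect, level.
#' @export
load_knowledge_table <- function(path = system.file("extdata",
                                                    "oncogenic_knowledge.tsv",
                                                    package = "resistscape")) {
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE, fill = TRUE)
  tab$level[is.na(tab$level)] <- ""
  tab$protein_change[is.na(tab$protein_change)] <- ""
  tab$variant_classes[is.na(tab$variant_classes)] <- ""
  tab
}

#' Parse a short HGVS-p protein change
#'
#' Accepts strings such as "D538G", "E17K", "M400fs", "R130*", "Y537S,L536P"
#' (the first change of a multi-change string is parsed).
#'
#' @param protein_change short protein change string.
#' @return list with ref, pos (integer), alt, and an inferred
#'   \code{variant_class} among missense / nonsense / frameshift_del /
#'   unknown.
#' @keywords internal
parse_protein_change <- function(protein_change) {
  pc <- strsplit(protein_change, ",", fixed = TRUE)[[1]][1]
  m <- regmatches(pc, regexec("^([A-Z*]?)(-?[0-9]+)([A-Za-z*]+.*)$", pc))[[1]]
  if (length(m) == 0) {
    stop(sprintf("malformed protein change string: '%s'", protein_change))
  }
  alt <- m[4]
  cls <- if (grepl("fs", alt)) "frameshift_del"
  else if (alt == "*") "nonsense"
  else if (nchar(alt) == 1 && grepl("^[A-Z]$", alt)) "missense"
  else "unknown"
  list(ref = m[2], pos = as.integer(m[3]), alt = alt, variant_class = cls)
}

#' Oncogenic annotation of a mutation
#'
#' Looks the (gene, protein change) up in the knowledge snapshot: exact
#' matches first, then positional missense windows, then truncating
#' variant-class rules. Every protein change of a comma-separated double
#' mutation is tried and the strongest effect wins (GOF/LOF over
#' likely_GOF/likely_LOF). Unmatched mutations return VUS with an empty
#' level.
#'
#' @param gene gene symbol.
#' @param protein_change short HGVS-p string (comma-separated for double
#'   mutations).
#' @param knowledge knowledge table from \code{load_knowledge_table()}.
#' @param variant_class optional explicit variant class (e.g. from a MAF);
#'   inferred from the protein change when missing.
#' @return list with \code{effect} (GOF, likely_GOF, LOF, likely_LOF, VUS)
#'   and \code{actionability_level} (string, "" when none).
#' @examples
#' kt <- load_knowledge_table()
#' annotate_oncogenic("ERBB2", "L755S", kt) # GOF, Level 3a
#' @export
annotate_oncogenic <- function(gene, protein_change,
                               knowledge = load_knowledge_table(),
                               variant_class = NULL) {
  rules <- knowledge[knowledge$gene == gene, , drop = FALSE]
  rank_eff <- c(VUS = 0, likely_LOF = 1, likely_GOF = 1, LOF = 2, GOF = 2)
  best <- list(effect = "VUS", actionability_level = "")
  parts <- strsplit(protein_change, ",", fixed = TRUE)[[1]]
  if (length(parts) == 0 || !nzchar(protein_change)) {
    stop(sprintf("malformed protein change string: '%s'", protein_change))
  }
  for (pc in parts) {
    parsed <- parse_protein_change(pc)
    vc <- if (is.null(variant_class) || is.na(variant_class) ||
              variant_class == "") parsed$variant_class else variant_class
    hit <- NULL
    ex <- rules[rules$match_type == "exact" & rules$protein_change == pc, ]
    if (nrow(ex) > 0) hit <- ex[1, ]
    if (is.null(hit)) {
      po <- rules[rules$match_type == "position", , drop = FALSE]
      po <- po[!is.na(po$pos_min) & parsed$pos >= po$pos_min &
                 parsed$pos <= po$pos_max & vc == "missense", , drop = FALSE]
      if (nrow(po) > 0) hit <- po[1, ]
    }
    if (is.null(hit)) {
      cl <- rules[rules$match_type == "class", , drop = FALSE]
      if (nrow(cl) > 0) {
        ok <- vapply(cl$variant_classes, function(s)
          vc %in% strsplit(s, ",", fixed = TRUE)[[1]], logical(1))
        if (any(ok)) hit <- cl[which(ok)[1], ]
      }
    }
    if (!is.null(hit) &&
        rank_eff[[hit$effect]] >= rank_eff[[best$effect]]) {
      best <- list(effect = hit$effect, actionability_level = hit$level)
    }
  }
  best
}
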