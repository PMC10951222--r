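#' Write / read the MAF-like mutation dialect
#'
#' Tab-separated with columns sample, gene, protein_change, variant_class,
#' ccf; 1-based inclusive coordinates are declared in the header comment
#' for the segment dialect that carries coordinates.
#'
#' @param mutations data.frame.
#' @param path file path.
#' @export
write_maf <- function(mutations, path) {
  con <- file(path, "w")
  writeLines("# resistscape MAF-like dialect; coordinates 1-based inclusive",
             con)
  utils::write.table(mutations, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
}

#' @rdname write_maf
#' @return data.frame of mutations.
#' @export
read_maf <- function(path) {
  need <- c("sample", "gene", "protein_change", "variant_class")
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) {
    stop(sprintf("read_maf: missing columns: %s", paste(miss, collapse = ", ")))
  }
  if (!("ccf" %in% names(tab))) {
    if (!all(c("t_alt", "t_ref") %in% names(tab))) {
      stop("read_maf: need either a ccf column or t_alt + t_ref counts")
    }
    # crude VAF-doubling proxy when only allele counts are given
    tab$ccf <- pmin(2 * tab$t_alt / (tab$t_alt + tab$t_ref), 1)
  }
  tab
}

#' Write / read the SEG-like segment dialect
#'
#' Columns sample, chrom, start, end, total_cn, minor_cn, n_genes, genes
#' (comma-separated). Rows violating minor_cn <= total_cn are rejected with
#' their line number.
#'
#' @param segments data.frame.
#' @param path file path.
#' @export
write_seg <- function(segments, path) {
  con <- file(path, "w")
  writeLines("# resistscape SEG-like dialect; coordinates 1-based inclusive",
             con)
  utils::write.table(segments, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
}

#' @rdname write_seg
#' @return data.frame of segments.
#' @export
read_seg <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  need <- c("sample", "chrom", "start", "end", "total_cn", "minor_cn",
            "n_genes", "genes")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) {
    stop(sprintf("read_seg: missing columns: %s", paste(miss, collapse = ", ")))
  }
  bad <- which(tab$minor_cn > tab$total_cn)
  if (length(bad) > 0) {
    stop(sprintf("read_seg: minor_cn > total_cn at data line %d", bad[1]))
  }
  tab
}

#' Write / read an expression matrix TSV (genes x samples)
#'
#' @param mat numeric matrix with gene rownames and sample colnames.
#' @param path file path.
#' @export
write_expression_tsv <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_expression_tsv
#' @return numeric matrix.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  mat
}

#' Read / write GMT gene-set files
#'
#' Standard GMT: one set per line, tab-separated name, description, genes.
#' Duplicate genes within a set are dropped with a warning.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop("read_gmt: malformed line (need >= 3 fields)")
    genes <- parts[-(1:2)]
    if (anyDuplicated(genes)) {
      warning(sprintf("read_gmt: duplicate genes in set '%s' de-duplicated",
                      parts[1]))
      genes <- unique(genes)
    }
    sets[[parts[1]]] <- genes
  }
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
}

#' Serialize / deserialize per-sample calls as JSON
#'
#' Floating-point fields are written with fixed precision (8 digits) so
#' rewriting identical calls is byte-identical.
#'
#' @param calls \code{sample_calls} object.
#' @param path JSON path.
#' @export
write_sample_calls_json <- function(calls, path) {
  payload <- list(mutations = calls$mutations, cna = calls$cna,
                  biallelic = calls$biallelic, purity = calls$purity,
                  ploidy = calls$ploidy, source = calls$source,
                  qc_pass = calls$qc_pass)
  jsonlite::write_json(payload, path, digits = 8, auto_unbox = TRUE,
                       pretty = TRUE)
}

#' @rdname write_sample_calls_json
#' @return \code{sample_calls} object.
#' @export
read_sample_calls_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  mut <- as.data.frame(x$mutations, stringsAsFactors = FALSE)
  cna <- as.data.frame(x$cna, stringsAsFactors = FALSE)
  structure(list(mutations = mut, cna = cna,
                 biallelic = as.character(x$biallelic %||% character(0)),
                 purity = x$purity, ploidy = x$ploidy, source = x$source,
                 qc_pass = x$qc_pass),
            class = "sample_calls")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a simulated cohort to disk
#'
#' Emits mutations.tsv (MAF-like), segments.tsv (SEG-like),
#' purity_ploidy.tsv, expression.tsv, clinical.tsv and truth.json into a
#' directory.
#'
#' @param cohort result of \code{simulate_trial_cohort}.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mut <- do.call(rbind, lapply(cohort$bundles, `[[`, "mutations"))
  seg <- do.call(rbind, lapply(cohort$bundles, `[[`, "segments"))
  pp <- do.call(rbind, lapply(cohort$bundles, function(b)
    data.frame(sample = b$sample_id, patient = b$patient_id,
               source = b$source, timepoint = b$timepoint,
               purity = b$purity, ploidy = b$ploidy,
               stringsAsFactors = FALSE)))
  write_maf(mut, file.path(dir, "mutations.tsv"))
  write_seg(seg, file.path(dir, "segments.tsv"))
  utils::write.table(pp, file.path(dir, "purity_ploidy.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_expression_tsv(round(cohort$expression, 6),
                       file.path(dir, "expression.tsv"))
  utils::write.table(cohort$clinical, file.path(dir, "clinical.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       digits = 8, auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
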