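#' Rank-based AUC and Mann-Whitney U statistic
#'
#' Computes the area under the ROC curve for a continuous score against a
#' binary label, together with the Mann-Whitney U statistic it is a rescaling
#' of. U counts (positive, negative) pairs in which the positive sample
#' scores higher, with tied pairs counted 1/2; AUC = U / (n_pos * n_neg).
#'
#' @param scores numeric vector of classifier scores.
#' @param labels logical (or 0/1) vector, \code{TRUE} marking the positive
#'   class, same length as \code{scores}.
#' @return list with \code{auc}, \code{u} (integer or half-integer),
#'   \code{n_pos}, \code{n_neg}.
#' @examples
#' auc_score(c(3, 2, 1), c(TRUE, FALSE, FALSE))
#' @export
auc_score <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  labels <- as.logical(labels)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stop("auc_score: both classes must be non-empty")
  }
  # midranks give the tie-counted-1/2 pair count directly
  r <- rank(scores)
  u <- sum(r[labels]) - n_pos * (n_pos + 1) / 2
  list(auc = u / (n_pos * n_neg), u = u, n_pos = n_pos, n_neg = n_neg)
}

#' Exact null distribution of the Mann-Whitney U statistic
#'
#' Frequency table of U over all \code{choose(m + n, m)} label arrangements
#' of two tie-free groups of sizes m and n, computed by the standard
#' partition-count recursion N(u; m, n) = N(u - n; m - 1, n) + N(u; m, n - 1).
#'
#' @param m,n group sizes.
#' @return numeric vector of counts, index i holding the number of
#'   arrangements with U = i - 1 (so positions 1..m*n+1).
#' @keywords internal
mw_null_counts <- function(m, n) {
  stopifnot(m >= 0, n >= 0)
  # N(u; i, j) = N(u - j; i - 1, j) + N(u; i, j - 1); counts of partitions
  # of u into at most i parts each at most j. prev[[j + 1]] holds the count
  # vector over u for (i - 1, j).
  prev <- rep(list(1), n + 1) # i = 0: point mass at u = 0 for every j
  for (i in seq_len(m)) {
    cur <- vector("list", n + 1)
    cur[[1]] <- 1 # j = 0
    for (j in seq_len(n)) {
      len <- i * j + 1
      pad <- function(v) c(v, numeric(len - length(v)))
      av <- pad(c(numeric(j), prev[[j + 1]])) # shift by j
      cur[[j + 1]] <- av + pad(cur[[j]])
    }
    prev <- cur
  }
  prev[[n + 1]]
}

#' Exact one-sided Mann-Whitney p-value
#'
#' Upper-tail probability P(U' >= u) under the exact permutation null of the
#' Mann-Whitney U statistic for tie-free data: the number of label
#' arrangements with U' >= u divided by \code{choose(n_pos + n_neg, n_pos)}.
#' Half-integer U (ties in the scores) falls back to the tie-corrected
#' normal approximation with \code{approximate = TRUE} in the result, as does
#' any call with \code{n_pos + n_neg} above \code{max_exact}.
#'
#' @param u observed U statistic.
#' @param n_pos,n_neg group sizes.
#' @param max_exact largest total sample size for which the exact null is
#'   enumerated (default 25).
#' @return list with \code{p}, \code{approximate} flag.
#' @examples
#' mw_exact_one_sided_p(36, 6, 6)$p  # 1/924
#' @export
mw_exact_one_sided_p <- function(u, n_pos, n_neg, max_exact = 25L) {
  stopifnot(u >= 0, u <= n_pos * n_neg, n_pos >= 1, n_neg >= 1)
  if (u == round(u) && n_pos + n_neg <= max_exact) {
    counts <- mw_null_counts(n_pos, n_neg)
    p <- sum(counts[(u + 1):(n_pos * n_neg + 1)]) / sum(counts)
    return(list(p = p, approximate = FALSE))
  }
  # normal approximation with continuity correction (used for ties / large n)
  mu <- n_pos * n_neg / 2
  sigma <- sqrt(n_pos * n_neg * (n_pos + n_neg + 1) / 12)
  p <- stats::pnorm((u - 0.5 - mu) / sigma, lower.tail = FALSE)
  list(p = min(max(p, .Machine$double.xmin), 1), approximate = TRUE)
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Standard probability-mass convention: the sum of hypergeometric
#' probabilities, over all tables with the observed margins, that do not
#' exceed the probability of the observed table.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return list with \code{p}, \code{table}.
#' @examples
#' fisher_two_sided(matrix(c(6, 0, 0, 6), 2))$p  # 2/924
#' @export
fisher_two_sided <- function(table) {
  table <- as.matrix(table)
  stopifnot(identical(dim(table), c(2L, 2L)), all(table >= 0),
            all(table == round(table)))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    warning("fisher_two_sided: empty margin, p = 1")
    return(list(p = 1, table = table))
  }
  p <- stats::fisher.test(table)$p.value
  list(p = min(p, 1), table = table)
}

#' Two-sided Welch's t-test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom.
#'
#' @param group_a,group_b numeric vectors, each with at least 2 values.
#' @return list with \code{t}, \code{df}, \code{p}.
#' @export
welch_two_sided <- function(group_a, group_b) {
  stopifnot(length(group_a) >= 2, length(group_b) >= 2)
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0) {
    if (mean(group_a) == mean(group_b)) {
      return(list(t = 0, df = NA_real_, p = 1))
    }
    stop("welch_two_sided: degenerate zero variance in both groups")
  }
  fit <- stats::t.test(group_a, group_b, var.equal = FALSE)
  list(t = unname(fit$statistic), df = unname(fit$parameter),
       p = fit$p.value)
}

#' Screen gene-set signatures against a binary clinical label
#'
#' For every signature (row of \code{score_matrix}) computes the two-sided
#' Welch p-value comparing scores between label classes and the two-sided
#' Fisher p-value for enrichment of upper-quartile (or depletion to
#' lower-quartile) signature activity in the positive class, using
#' reference-cohort quantile categories. No multiple-testing correction is
#' applied to the primary columns; a Benjamini-Hochberg column is appended
#' as clearly-marked optional extra output.
#'
#' @param score_matrix numeric matrix, signatures x samples (NES values).
#' @param labels logical vector per sample (e.g. clinical benefit).
#' @param reference a \code{reference_cohort} (for quantile categories), or
#'   \code{NULL} to dichotomize at the cohort's own quartiles.
#' @param direction "high" to test upper-quartile enrichment (default).
#' @return data.frame sorted by Welch p with columns set, welch_t, welch_p,
#'   fisher_p, bh_welch_p (extra, not part of the primary output).
#' @export
hallmark_screen <- function(score_matrix, labels, reference = NULL,
                            direction = c("high", "low")) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  stopifnot(ncol(score_matrix) == length(labels),
            nrow(score_matrix) >= 1, sum(labels) > 0, sum(!labels) > 0)
  sets <- rownames(score_matrix)
  if (is.null(sets)) sets <- paste0("set", seq_len(nrow(score_matrix)))
  res <- lapply(seq_len(nrow(score_matrix)), function(i) {
    x <- score_matrix[i, ]
    w <- welch_two_sided(x[labels], x[!labels])
    if (!is.null(reference)) {
      cat_i <- vapply(x, function(v)
        reference_quantile_category(v, sets[i], reference), character(1))
      flagged <- if (direction == "high") {
        cat_i %in% c("high_quartile", "high_decile")
      } else {
        cat_i %in% c("low_quartile", "low_decile")
      }
    } else {
      q75 <- stats::quantile(x, if (direction == "high") 0.75 else 0.25,
                             names = FALSE)
      flagged <- if (direction == "high") x >= q75 else x <= q75
    }
    tab <- matrix(c(sum(flagged & labels), sum(flagged & !labels),
                    sum(!flagged & labels), sum(!flagged & !labels)),
                  nrow = 2, byrow = TRUE)
    # degenerate quartile tables (an empty margin) legitimately give p = 1
    fp <- suppressWarnings(fisher_two_sided(tab)$p)
    data.frame(set = sets[i], welch_t = w$t, welch_p = w$p,
               fisher_p = fp, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$welch_p), , drop = FALSE]
  out$bh_welch_p <- stats::p.adjust(out$welch_p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Trial efficacy proportions
#'
#' Clinical benefit rate (CR + PR + SD >= 24 weeks), disease control rate
#' (CR + PR + SD >= 12 weeks) and objective response rate (CR + PR) from a
#' best-response table. Records with a missing best response stay in the
#' denominator and are flagged. Percentages are reported to one decimal.
#'
#' @param clinical data.frame with columns \code{best_response} (one of CR,
#'   PR, SD, PD, NA) and \code{response_duration_weeks} (used for SD).
#' @return list with \code{n}, \code{cbr}, \code{dcr}, \code{orr}
#'   (percentages, one decimal), \code{counts}, \code{n_missing}.
#' @export
trial_metrics <- function(clinical) {
  stopifnot(all(c("best_response", "response_duration_weeks") %in%
                  names(clinical)))
  n <- nrow(clinical)
  br <- clinical$best_response
  dur <- clinical$response_duration_weeks
  n_missing <- sum(is.na(br))
  if (n_missing > 0) {
    warning(sprintf("trial_metrics: %d records with missing best response kept in denominator",
                    n_missing))
  }
  resp <- !is.na(br) & br %in% c("CR", "PR")
  sd24 <- !is.na(br) & br == "SD" & !is.na(dur) & dur >= 24
  sd12 <- !is.na(br) & br == "SD" & !is.na(dur) & dur >= 12
  pct1 <- function(k) floor(1000 * k / n + 0.5) / 10 # half-up to one decimal
  list(n = n,
       cbr = pct1(sum(resp | sd24)),
       dcr = pct1(sum(resp | sd12)),
       orr = pct1(sum(resp)),
       counts = table(factor(br, levels = c("CR", "PR", "SD", "PD"))),
       n_missing = n_missing)
}
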