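# Scoring, chart-review sampling, and approach comparison.

new_eval_report <- function(mode, n_reviewed, tp, fp, fn = NA_integer_,
                            tn = NA_integer_) {
  precision <- if ((tp + fp) > 0) tp / (tp + fp) else NA_real_
  recall <- if (mode == "full" && !is.na(fn) && (tp + fn) > 0) {
    tp / (tp + fn)
  } else {
    NA_real_
  }
  structure(
    list(mode = mode, n_reviewed = n_reviewed, true_positive = tp,
         false_positive = fp, false_negative = fn, true_negative = tn,
         precision = precision, recall = recall),
    class = "ipv_eval_report"
  )
}

#' Score predictions against truth
#'
#' Two coverage modes mirror how rule-based phenotyping is validated in
#' practice:
#'
#' * `mode = "review"`: truth labels exist only for (a sample of) the
#'   predicted-positive encounters, as produced by manual chart review.
#'   Precision is computed over the reviewed encounters; recall is
#'   **undefined** (`NA`) because unflagged encounters were never reviewed.
#' * `mode = "full"`: truth covers the whole corpus; precision and recall
#'   are both computed. A prediction with no matching truth record is a
#'   hard error.
#'
#' @param pred data frame with columns `encounter_id` and `label`
#'   (logical), e.g. the `results` of [classify_corpus()].
#' @param truth data frame with columns `encounter_id` and `is_ipv`
#'   (logical).
#' @param mode `"review"` or `"full"`.
#' @return object of class `ipv_eval_report` with counts, `precision`, and
#'   `recall` (`NA` when undefined).
#' @export
#' @examples
#' # a 199-chart review confirming 16 encounters:
#' pred <- data.frame(encounter_id = as.character(1:199), label = TRUE)
#' truth <- data.frame(encounter_id = as.character(1:199),
#'                     is_ipv = c(rep(TRUE, 16), rep(FALSE, 183)))
#' confusion(pred, truth, mode = "review")
confusion <- function(pred, truth, mode = c("review", "full")) {
  mode <- match.arg(mode)
  stopifnot(all(c("encounter_id", "label") %in% names(pred)),
            all(c("encounter_id", "is_ipv") %in% names(truth)))
  if (anyDuplicated(pred$encounter_id)) {
    stop("duplicate encounter_id in predictions", call. = FALSE)
  }
  if (anyDuplicated(truth$encounter_id)) {
    stop("duplicate encounter_id in truth", call. = FALSE)
  }
  idx <- match(pred$encounter_id, truth$encounter_id)
  if (mode == "full") {
    if (anyNA(idx)) {
      stop("no truth record for encounter: ",
           pred$encounter_id[which(is.na(idx))[1L]], call. = FALSE)
    }
    is_ipv <- truth$is_ipv[idx]
    tp <- sum(pred$label & is_ipv)
    fp <- sum(pred$label & !is_ipv)
    fn <- sum(!pred$label & is_ipv)
    tn <- sum(!pred$label & !is_ipv)
    new_eval_report("full", nrow(pred), tp, fp, fn, tn)
  } else {
    keep <- !is.na(idx)
    is_ipv <- truth$is_ipv[idx[keep]]
    label <- pred$label[keep]
    tp <- sum(label & is_ipv)
    fp <- sum(label & !is_ipv)
    new_eval_report("review", sum(keep), tp, fp)
  }
}

#' Build an evaluation report directly from review tallies
#'
#' For recomputing published validation statistics from their printed
#' counts: `n_reviewed` charts reviewed, of which `n_confirmed` were
#' confirmed positive.
#'
#' @param n_reviewed,n_confirmed non-negative counts,
#'   `n_confirmed <= n_reviewed`.
#' @return an `ipv_eval_report` in review mode.
#' @export
#' @examples
#' review_tally(199, 16)$precision  # 0.0804...
review_tally <- function(n_reviewed, n_confirmed) {
  n_reviewed <- as.integer(n_reviewed)
  n_confirmed <- as.integer(n_confirmed)
  if (is.na(n_reviewed) || is.na(n_confirmed) || n_confirmed < 0 ||
      n_reviewed < n_confirmed) {
    stop("need 0 <= n_confirmed <= n_reviewed", call. = FALSE)
  }
  new_eval_report("review", n_reviewed, n_confirmed,
                  n_reviewed - n_confirmed)
}

#' @export
print.ipv_eval_report <- function(x, ...) {
  cat("IPV evaluation report (", x$mode, " mode)\n", sep = "")
  cat("  reviewed:  ", x$n_reviewed, "\n", sep = "")
  cat("  TP / FP:   ", x$true_positive, " / ", x$false_positive, "\n",
      sep = "")
  if (x$mode == "full") {
    cat("  FN / TN:   ", x$false_negative, " / ", x$true_negative, "\n",
        sep = "")
  }
  cat("  precision: ",
      if (is.na(x$precision)) "undefined" else
        sprintf("%.4f (%.1f%%)", x$precision, 100 * x$precision),
      "\n", sep = "")
  cat("  recall:    ",
      if (is.na(x$recall)) "undefined (positives-only review)" else
        sprintf("%.4f (%.1f%%)", x$recall, 100 * x$recall),
      "\n", sep = "")
  invisible(x)
}

#' Sample predicted positives for manual chart review
#'
#' Draws a uniform random subset of size `round(fraction * n)` from the
#' positive results, optionally stratified by calendar year of the visit
#' date (each year contributes its share, within one encounter of exact
#' proportionality). Deterministic given `seed`.
#'
#' @param results results data frame (as from [classify_corpus()]); rows
#'   with `label == TRUE` are the sampling frame if a `label` column is
#'   present.
#' @param fraction sampling fraction in `(0, 1]`.
#' @param seed integer RNG seed.
#' @param stratify_by_year stratify on `format(visit_date, "%Y")`.
#' @return the sampled subset of `results` rows.
#' @export
sample_for_review <- function(results, fraction, seed,
                              stratify_by_year = FALSE) {
  if (!is.numeric(fraction) || is.na(fraction) || fraction <= 0 ||
      fraction > 1) {
    stop("fraction must be in (0, 1]", call. = FALSE)
  }
  if ("label" %in% names(results)) results <- results[results$label, ,
                                                      drop = FALSE]
  n <- nrow(results)
  if (!n) return(results)
  size <- round(fraction * n)
  if (!size) return(results[0, , drop = FALSE])
  with_seed(as.integer(seed), {
    if (!stratify_by_year) {
      results[sort(sample.int(n, size)), , drop = FALSE]
    } else {
      year <- format(as.Date(results$visit_date), "%Y")
      tab <- table(year)
      exact <- fraction * as.numeric(tab)
      alloc <- floor(exact)
      short <- size - sum(alloc)
      if (short > 0) {
        extra <- order(exact - alloc, decreasing = TRUE)[seq_len(short)]
        alloc[extra] <- alloc[extra] + 1
      } else if (short < 0) {
        trim <- order(exact - alloc)[seq_len(-short)]
        alloc[trim] <- pmax(alloc[trim] - 1, 0)
      }
      picked <- unlist(lapply(seq_along(tab), function(k) {
        rows <- which(year == names(tab)[k])
        if (!alloc[k]) return(integer())
        rows[sample.int(length(rows), min(alloc[k], length(rows)))]
      }))
      results[sort(picked), , drop = FALSE]
    }
  })
}

#' Compare positive sets of two approaches on the same corpus
#'
#' @param a,b results data frames from [classify_corpus()] over the same
#'   corpus (identical encounter id sets; a mismatch is a hard error).
#' @return object of class `ipv_overlap`: encounter counts `a_only`,
#'   `b_only`, `both`, and distinct-patient counts `patients_a_only`,
#'   `patients_b_only`, `patients_both`, plus the approach labels.
#' @export
compare_approaches <- function(a, b) {
  stopifnot(all(c("encounter_id", "label") %in% names(a)),
            all(c("encounter_id", "label") %in% names(b)))
  if (!setequal(a$encounter_id, b$encounter_id) ||
      nrow(a) != nrow(b)) {
    stop("results cover different corpora (encounter id sets differ)",
         call. = FALSE)
  }
  pos_a <- a$encounter_id[a$label]
  pos_b <- b$encounter_id[b$label]
  both <- intersect(pos_a, pos_b)
  out <- list(
    approach_a = if ("approach" %in% names(a)) a$approach[1L] else "a",
    approach_b = if ("approach" %in% names(b)) b$approach[1L] else "b",
    a_only = length(setdiff(pos_a, pos_b)),
    b_only = length(setdiff(pos_b, pos_a)),
    both = length(both)
  )
  if ("patient_id" %in% names(a) && "patient_id" %in% names(b)) {
    pat_a <- unique(a$patient_id[a$label])
    pat_b <- unique(b$patient_id[b$label])
    out$patients_a_only <- length(setdiff(pat_a, pat_b))
    out$patients_b_only <- length(setdiff(pat_b, pat_a))
    out$patients_both <- length(intersect(pat_a, pat_b))
  }
  structure(out, class = "ipv_overlap")
}

#' @export
print.ipv_overlap <- function(x, ...) {
  cat("Approach overlap (", x$approach_a, " vs ", x$approach_b, ")\n",
      sep = "")
  cat("  encounters: ", x$a_only, " only-", x$approach_a, ", ",
      x$b_only, " only-", x$approach_b, ", ", x$both, " shared\n", sep = "")
  if (!is.null(x$patients_both)) {
    cat("  patients:   ", x$patients_a_only, " / ", x$patients_b_only,
        " / ", x$patients_both, " shared\n", sep = "")
  }
  invisible(x)
}
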