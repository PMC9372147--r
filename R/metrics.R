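#' Construct a binary confusion matrix
#'
#' The positive class throughout the package is the transgenic (`"TG"`)
#' group; sensitivity is the true-positive rate on transgenic animals and
#' specificity the true-negative rate on wild types.
#'
#' @param tp,fp,tn,fn Non-negative integer counts.
#' @return Object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fp, tn, fn) {
  v <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(v < 0) || any(v != round(v))) {
    stop_bad("confusion counts must be non-negative integers")
  }
  structure(lapply(as.list(v), as.integer), class = "confusion_matrix")
}

#' Confusion matrix from truth and predicted labels
#'
#' @param truth,predicted Vectors of `"WT"`/`"TG"` labels.
#' @param positive The positive-class label.
#' @return A [confusion_matrix()].
#' @export
confusion_from_predictions <- function(truth, predicted, positive = "TG") {
  t_pos <- truth == positive
  p_pos <- predicted == positive
  confusion_matrix(tp = sum(t_pos & p_pos), fp = sum(!t_pos & p_pos),
                   tn = sum(!t_pos & !p_pos), fn = sum(t_pos & !p_pos))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("confusion matrix: TP=%d FP=%d TN=%d FN=%d\n",
              x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Accuracy, sensitivity, specificity and F1 from a confusion matrix
#'
#' Computes accuracy `(TP+TN)/total`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, and F1 `2TP/(2TP+FP+FN)`. Reported values are rounded half
#' away from zero to three decimals, matching printed-table conventions;
#' the unrounded values are retained in the `"exact"` attribute.
#'
#' @param cm A [confusion_matrix()].
#' @return One-row data frame with columns `accuracy`, `sensitivity`,
#'   `specificity`, `f1`, plus attribute `exact` with unrounded values.
#' @export
compute_metrics <- function(cm) {
  n_pos <- cm$tp + cm$fn
  n_neg <- cm$tn + cm$fp
  if (n_pos == 0L || n_neg == 0L) {
    stop_bad("both classes must be represented (n_pos=%d, n_neg=%d)",
             n_pos, n_neg)
  }
  exact <- c(accuracy = (cm$tp + cm$tn) / (n_pos + n_neg),
             sensitivity = cm$tp / n_pos,
             specificity = cm$tn / n_neg,
             f1 = 2 * cm$tp / (2 * cm$tp + cm$fp + cm$fn))
  out <- as.data.frame(as.list(round_half_up(exact, 3)))
  attr(out, "exact") <- exact
  out
}

#' Recover integer confusion counts from rounded sensitivity/specificity
#'
#' Given a sensitivity and specificity printed to three decimals and the
#' known class sizes, finds the unique integer TP in `[0, n_pos]` whose
#' rate is closest to the printed sensitivity (likewise TN for
#' specificity). An ambiguous recovery — two integers equally close — is an
#' error, surfaced rather than guessed, so downstream consistency checks
#' can only ever use certain reconstructions.
#'
#' @param sens_3dp,spec_3dp Printed sensitivity and specificity.
#' @param n_pos,n_neg Positive- and negative-class test-set sizes.
#' @return A [confusion_matrix()].
#' @export
recover_confusion <- function(sens_3dp, spec_3dp, n_pos, n_neg) {
  if (n_pos <= 0 || n_neg <= 0) stop_bad("class sizes must be positive")
  nearest <- function(target, n, what) {
    cand <- 0:n
    d <- abs(cand / n - target)
    best <- min(d)
    hits <- cand[d <= best + 1e-12]
    if (length(hits) > 1L) {
      stop_bad("ambiguous %s recovery: %s all at distance %.4g",
               what, paste(hits, collapse = ", "), best)
    }
    hits
  }
  tp <- nearest(sens_3dp, n_pos, "TP")
  tn <- nearest(spec_3dp, n_neg, "TN")
  confusion_matrix(tp = tp, fp = n_neg - tn, tn = tn, fn = n_pos - tp)
}

#' Build a per-age error table from per-acquisition predictions
#'
#' Aggregates classification outcomes into a table of errors/cases per
#' (layer, group, age) cell, with per-group subtotals over all ages,
#' per-layer totals, and a grand total over all layers — the layout used to
#' locate which time points drive classification errors. Case counts must
#' agree across layers for every (group, age) cell, since each acquisition
#' yields one image per layer.
#'
#' @param predictions Data frame with columns `layer`, `group`, `age`, and
#'   either logical `correct` or both `truth` and `predicted`.
#' @return Object of class `error_table`.
#' @export
build_error_table <- function(predictions) {
  p <- predictions
  if (!"correct" %in% names(p)) {
    if (!all(c("truth", "predicted") %in% names(p))) {
      stop_bad("predictions need `correct` or `truth` + `predicted`")
    }
    p$correct <- p$truth == p$predicted
  }
  cells <- aggregate(cbind(errors = !p$correct, cases = rep(1L, nrow(p))),
                     by = list(layer = p$layer, group = p$group, age = p$age),
                     FUN = sum)
  error_table(cells)
}

#' Construct an error table from per-cell counts
#'
#' @param cells Data frame with columns `layer`, `group`, `age`, `errors`,
#'   `cases`.
#' @return Object of class `error_table`.
#' @export
error_table <- function(cells) {
  need <- c("layer", "group", "age", "errors", "cases")
  if (!all(need %in% names(cells))) {
    stop_bad("cells must have columns %s", paste(need, collapse = ", "))
  }
  if (any(cells$errors > cells$cases)) {
    stop_bad("cell has more errors than cases")
  }
  if (any(cells$errors < 0) || any(cells$cases < 0)) {
    stop_bad("counts must be non-negative")
  }
  # consistent case counts across layers for each (group, age)
  chk <- aggregate(cases ~ group + age, data = cells,
                   FUN = function(x) length(unique(x)))
  if (any(chk$cases != 1L)) {
    stop_bad("case counts differ across layers for some (group, age) cell")
  }
  cells <- cells[order(match(cells$layer, RETINAL_LAYERS),
                       match(cells$group, STUDY_GROUPS), cells$age), ]
  rownames(cells) <- NULL
  structure(list(cells = cells), class = "error_table")
}

#' Per-group subtotals of an error table
#'
#' @param et An [error_table()].
#' @return Data frame `layer`, `group`, `errors`, `cases`, `pct`.
#' @export
error_subtotals <- function(et) {
  s <- aggregate(cbind(errors, cases) ~ layer + group, data = et$cells,
                 FUN = sum)
  s$pct <- round_half_up(100 * s$errors / s$cases, 1)
  s[order(match(s$layer, RETINAL_LAYERS), match(s$group, STUDY_GROUPS)), ]
}

#' Per-layer totals of an error table
#'
#' @param et An [error_table()].
#' @return Data frame `layer`, `errors`, `cases`, `pct` (1 decimal).
#' @export
layer_totals <- function(et) {
  s <- aggregate(cbind(errors, cases) ~ layer, data = et$cells, FUN = sum)
  s$pct <- round_half_up(100 * s$errors / s$cases, 1)
  s <- s[order(match(s$layer, RETINAL_LAYERS)), ]
  rownames(s) <- NULL
  s
}

#' Grand total of an error table
#'
#' @param et An [error_table()].
#' @return Named list `errors`, `cases`, `pct` (1 decimal).
#' @export
grand_total <- function(et) {
  errors <- sum(et$cells$errors)
  cases <- sum(et$cells$cases)
  list(errors = errors, cases = cases,
       pct = round_half_up(100 * errors / cases, 1))
}

#' Share of classification errors attributable to one age
#'
#' Percentage (rounded to integer) of all errors in the table occurring at
#' the given age, summed over layers and groups.
#'
#' @param et An [error_table()].
#' @param age Age in months.
#' @return Integer percentage.
#' @export
age_error_share <- function(et, age) {
  total <- sum(et$cells$errors)
  if (total == 0L) stop_bad("error share undefined: table has zero errors")
  if (!age %in% et$cells$age) stop_bad("age %s not present in table", age)
  at_age <- sum(et$cells$errors[et$cells$age == age])
  round_half_up(100 * at_age / total)
}

#' Per-eye error balance diagnostic
#'
#' Reports the number of errors per eye; classification errors are expected
#' to distribute roughly evenly between left and right eyes. Diagnostic
#' only, never enforced.
#'
#' @param predictions Data frame with columns `eye` and `correct` (or
#'   `truth`/`predicted`).
#' @return Data frame `eye`, `errors`, `cases`.
#' @export
eye_error_balance <- function(predictions) {
  p <- predictions
  if (!"correct" %in% names(p)) p$correct <- p$truth == p$predicted
  aggregate(cbind(errors = !p$correct, cases = rep(1L, nrow(p))),
            by = list(eye = p$eye), FUN = sum)
}

#' @export
print.error_table <- function(x, ...) {
  lt <- layer_totals(x)
  gt <- grand_total(x)
  cat("Classification errors per layer:\n")
  for (i in seq_len(nrow(lt))) {
    cat(sprintf("  %-8s %d/%d (%.1f%%)\n", lt$layer[i], lt$errors[i],
                lt$cases[i], lt$pct[i]))
  }
  cat(sprintf("  total    %d/%d (%.1f%%)\n", gt$errors, gt$cases, gt$pct))
  invisible(x)
}
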