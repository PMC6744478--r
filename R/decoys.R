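#' Rank candidate models by restraint satisfaction
#'
#' Implements the selection rule for docking decoys: the model with
#' minimal summed crosslink distances wins. Ties fall back to fewer
#' violations, then smaller maximum violation, then input order. Models
#' with any unevaluable restraint are ranked after fully-evaluated ones
#' (truncated side chains should not win by omission, but are not
#' disqualified).
#'
#' @param models list of `xlcal_model` objects.
#' @param restraints a `xlcal_restraints` data.frame.
#' @param policy a [restraint_policy()].
#' @param key `"sum"` (default) or `"mean"` of evaluated distances.
#' @return data.frame of scores with columns `model_id`,
#'   `sum_distances`, `mean_distance`, `n_violations`, `max_violation`,
#'   `n_missing`, `rank`, ordered by rank.
#' @export
rank_decoys <- function(models, restraints, policy = restraint_policy(),
                        key = c("sum", "mean")) {
  key <- match.arg(key)
  if (length(models) == 0) stop("no models to rank")
  rows <- lapply(seq_along(models), function(i) {
    rep <- evaluate_restraints(models[[i]], restraints, policy)
    s <- summarize_restraints(rep)
    data.frame(model_id = models[[i]]$model_id,
               input_order = i,
               sum_distances = s$sum_distances,
               mean_distance = if (s$n_evaluated > 0)
                 s$sum_distances / s$n_evaluated else NA_real_,
               n_violations = s$n_evaluated - s$n_satisfied,
               max_violation = ifelse(is.na(s$max_violation), Inf,
                                      s$max_violation),
               n_missing = s$n_total - s$n_evaluated,
               stringsAsFactors = FALSE)
  })
  sc <- do.call(rbind, rows)
  primary <- if (key == "sum") sc$sum_distances else sc$mean_distance
  primary[is.na(primary)] <- Inf
  ord <- order(sc$n_missing > 0, primary, sc$n_violations,
               sc$max_violation, sc$input_order)
  sc <- sc[ord, ]
  sc$rank <- seq_len(nrow(sc))
  sc$max_violation[is.infinite(sc$max_violation)] <- NA_real_
  sc$input_order <- NULL
  rownames(sc) <- NULL
  sc
}

#' Consistency verdict for the calibration loop
#'
#' The calibrate-remodel cycle repeats until a model is consistent with
#' the XL-MS data; this emits that verdict. PASS means every evaluated
#' restraint has violation at most `tolerance`; FAIL returns the
#' violated restraints sorted by violation (descending), the artifact
#' handed back to the next modeling round.
#'
#' @param model a `xlcal_model`.
#' @param restraints a `xlcal_restraints` data.frame.
#' @param policy a [restraint_policy()].
#' @param tolerance allowed violation, Angstrom (default 0).
#' @return List with `verdict` ("PASS"/"FAIL"), `violated` (report rows
#'   above tolerance, worst first), and `summary`.
#' @export
consistency_report <- function(model, restraints,
                               policy = restraint_policy(), tolerance = 0) {
  rep <- evaluate_restraints(model, restraints, policy)
  bad <- rep[!is.na(rep$distance) & rep$violation > tolerance, , drop = FALSE]
  bad <- bad[order(-bad$violation), , drop = FALSE]
  rownames(bad) <- NULL
  list(verdict = if (nrow(bad) == 0) "PASS" else "FAIL",
       violated = bad,
       summary = summarize_restraints(rep))
}
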