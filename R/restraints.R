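#' DSSO restraint policy
#'
#' Encodes the distance bounds applied to crosslinked lysine pairs. The
#' DSSO spacer arm is ~10 Angstrom, giving a one-sided \[0, 10\] bound on
#' the N-zeta/N-zeta distance for intramolecular links; intermolecular
#' (docking) links use a 10-20 Angstrom band. When a lysine side chain is
#' missing from a model the evaluation falls back to C-alpha atoms with
#' the bounds widened by `fallback_pad` (10 + 13 = 23 Angstrom default
#' upper bound, two extended lysine side chains).
#'
#' @param intra_max upper bound for intramolecular links, Angstrom.
#' @param inter_min,inter_max band for intermolecular links, Angstrom.
#' @param atom_primary atom evaluated when present (default `"NZ"`).
#' @param atom_fallback atom used when the primary is absent.
#' @param fallback_pad Angstrom added to (subtracted from) the upper
#'   (lower) bound under fallback; lower bounds floor at 0.
#' @return A `xlcal_policy` list.
#' @export
restraint_policy <- function(intra_max = 10, inter_min = 10, inter_max = 20,
                             atom_primary = "NZ", atom_fallback = "CA",
                             fallback_pad = 13) {
  stopifnot(intra_max > 0, inter_min <= inter_max, fallback_pad >= 0)
  structure(list(intra_max = intra_max, inter_min = inter_min,
                 inter_max = inter_max, atom_primary = atom_primary,
                 atom_fallback = atom_fallback, fallback_pad = fallback_pad),
            class = "xlcal_policy")
}

#' Build distance restraints from unique residue pairs
#'
#' @param pairs a `xlcal_pairs` data.frame ([dedupe_to_residue_pairs()]).
#' @param policy a [restraint_policy()].
#' @param chain_map named character vector, protein id -> model chain id.
#' @return data.frame (class `xlcal_restraints`): one restraint per pair
#'   with columns `chain_a`, `pos_a`, `chain_b`, `pos_b`, `lower`,
#'   `upper`, `policy_tag` (intra/inter) plus the originating proteins.
#' @export
build_restraints <- function(pairs, policy = restraint_policy(),
                             chain_map) {
  pairs <- as.data.frame(pairs)
  if (nrow(pairs) == 0) {
    out <- data.frame(protein_a = character(0), pos_a = integer(0),
                      protein_b = character(0), pos_b = integer(0),
                      chain_a = character(0), chain_b = character(0),
                      lower = numeric(0), upper = numeric(0),
                      policy_tag = character(0))
    class(out) <- c("xlcal_restraints", "data.frame")
    return(out)
  }
  prots <- unique(c(pairs$protein_a, pairs$protein_b))
  absent <- setdiff(prots, names(chain_map))
  if (length(absent) > 0) {
    stop("protein(s) missing from chain_map: ",
         paste(absent, collapse = ", "))
  }
  intra <- pairs$protein_a == pairs$protein_b
  out <- data.frame(
    protein_a = pairs$protein_a, pos_a = pairs$pos_a,
    protein_b = pairs$protein_b, pos_b = pairs$pos_b,
    chain_a = unname(chain_map[pairs$protein_a]),
    chain_b = unname(chain_map[pairs$protein_b]),
    lower = ifelse(intra, 0, policy$inter_min),
    upper = ifelse(intra, policy$intra_max, policy$inter_max),
    policy_tag = ifelse(intra, "intra", "inter"),
    stringsAsFactors = FALSE)
  class(out) <- c("xlcal_restraints", "data.frame")
  out
}

#' Evaluate distance restraints on a structure model
#'
#' Measures each restrained distance on the model. The primary atoms
#' (N-zeta by default) are used when both are present; otherwise the
#' fallback atoms with bounds widened by the policy pad; when neither
#' atom pair is available the restraint is marked missing and excluded
#' from sums. Missingness is data, never an error. A violation below the
#' lower bound is additionally flagged `lower_bound` because docking
#' restraints state the band's intent ambiguously.
#'
#' @param model a `xlcal_model`.
#' @param restraints a `xlcal_restraints` data.frame.
#' @param policy the [restraint_policy()] used to build them.
#' @return data.frame (class `xlcal_reports`): the restraints plus
#'   `distance` (NA when missing), `atom_used` (primary/fallback/
#'   missing), `satisfied`, `violation` (>= 0), `violation_side`
#'   (none/upper_bound/lower_bound).
#' @export
evaluate_restraints <- function(model, restraints,
                                policy = restraint_policy()) {
  n <- nrow(restraints)
  distance <- rep(NA_real_, n)
  atom_used <- rep("missing", n)
  lower_eff <- restraints$lower
  upper_eff <- restraints$upper
  for (i in seq_len(n)) {
    a <- get_atom(model, restraints$chain_a[i], restraints$pos_a[i],
                  policy$atom_primary)
    b <- get_atom(model, restraints$chain_b[i], restraints$pos_b[i],
                  policy$atom_primary)
    if (!is.null(a) && !is.null(b)) {
      distance[i] <- atom_distance(a, b)
      atom_used[i] <- "primary"
      next
    }
    a <- get_atom(model, restraints$chain_a[i], restraints$pos_a[i],
                  policy$atom_fallback)
    b <- get_atom(model, restraints$chain_b[i], restraints$pos_b[i],
                  policy$atom_fallback)
    if (!is.null(a) && !is.null(b)) {
      distance[i] <- atom_distance(a, b)
      atom_used[i] <- "fallback"
      lower_eff[i] <- max(0, restraints$lower[i] - policy$fallback_pad)
      upper_eff[i] <- restraints$upper[i] + policy$fallback_pad
    }
  }
  violation <- numeric(n)
  side <- rep("none", n)
  above <- !is.na(distance) & distance > upper_eff
  below <- !is.na(distance) & distance < lower_eff
  violation[above] <- distance[above] - upper_eff[above]
  violation[below] <- lower_eff[below] - distance[below]
  side[above] <- "upper_bound"
  side[below] <- "lower_bound"
  out <- cbind(as.data.frame(restraints),
               data.frame(distance = distance, atom_used = atom_used,
                          lower_eff = lower_eff, upper_eff = upper_eff,
                          satisfied = !is.na(distance) & violation == 0,
                          violation = violation, violation_side = side))
  class(out) <- c("xlcal_reports", "data.frame")
  out
}

#' Summarize restraint reports
#'
#' @param reports output of [evaluate_restraints()].
#' @return List (class `xlcal_summary`): `n_total`, `n_evaluated`,
#'   `n_satisfied`, `fraction_satisfied` (NA when nothing evaluated),
#'   `sum_distances`, `sum_violations`, `max_violation` — sums over
#'   evaluated restraints only.
#' @export
summarize_restraints <- function(reports) {
  ev <- !is.na(reports$distance)
  n_eval <- sum(ev)
  structure(list(
    n_total = nrow(reports),
    n_evaluated = n_eval,
    n_satisfied = sum(reports$satisfied[ev]),
    fraction_satisfied = if (n_eval > 0) sum(reports$satisfied[ev]) / n_eval
                         else NA_real_,
    sum_distances = sum(reports$distance[ev]),
    sum_violations = sum(reports$violation[ev]),
    max_violation = if (n_eval > 0) max(reports$violation[ev]) else NA_real_
  ), class = "xlcal_summary")
}

#' @export
print.xlcal_summary <- function(x, ...) {
  cat(sprintf(
    "<restraint summary> %d/%d evaluated, %d satisfied (%.1f%%); sum dist %.2f A, max violation %.2f A\n",
    x$n_evaluated, x$n_total, x$n_satisfied,
    100 * ifelse(is.na(x$fraction_satisfied), 0, x$fraction_satisfied),
    x$sum_distances, ifelse(is.na(x$max_violation), 0, x$max_violation)))
  invisible(x)
}

#' Write restraint reports as CSV
#' @param reports a `xlcal_reports` data.frame.
#' @param path output path.
#' @export
write_reports <- function(reports, path) {
  utils::write.csv(as.data.frame(reports), path, row.names = FALSE)
  invisible(path)
}
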