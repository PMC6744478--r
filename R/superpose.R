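#' Optimal rigid superposition of paired coordinates (Kabsch)
#'
#' Least-squares proper rotation and translation mapping `coords_b` onto
#' `coords_a` via SVD of the cross-covariance matrix; reflections are
#' excluded by sign correction, so the rotation always has determinant
#' +1. Nearly collinear inputs leave the rotation underdetermined about
#' the common axis and are flagged `degenerate` rather than rejected.
#'
#' @param coords_a,coords_b N x 3 matrices (Angstrom), N >= 3, paired by
#'   row.
#' @return `xlcal_superposition`: list with `rotation` (3x3),
#'   `translation` (length 3; `b` maps onto `a` as
#'   `b %*% t(rotation) + translation`), `rmsd`, `n_pairs_used`,
#'   `n_pairs_rejected`, `cycles_run`, `rejected_pairs`, `degenerate`.
#' @export
kabsch <- function(coords_a, coords_b) {
  coords_a <- as.matrix(coords_a); coords_b <- as.matrix(coords_b)
  if (nrow(coords_a) != nrow(coords_b)) stop("coordinate sets differ in length")
  n <- nrow(coords_a)
  if (n < 3) stop("need at least 3 paired atoms, got ", n)
  ca <- colMeans(coords_a); cb <- colMeans(coords_b)
  a0 <- sweep(coords_a, 2, ca); b0 <- sweep(coords_b, 2, cb)
  h <- crossprod(b0, a0)                    # 3x3 cross-covariance
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  degenerate <- sv$d[2] < 1e-8 * max(sv$d[1], 1e-300)
  resid2 <- rowSums((a0 - b0 %*% t(rot))^2)
  structure(list(rotation = rot,
                 translation = as.numeric(ca - rot %*% cb),
                 rmsd = sqrt(mean(resid2)),
                 n_pairs_used = n, n_pairs_rejected = 0L,
                 cycles_run = 0L, rejected_pairs = character(0),
                 degenerate = degenerate),
            class = "xlcal_superposition")
}

#' @export
print.xlcal_superposition <- function(x, ...) {
  cat(sprintf("<superposition> rmsd %.4f A over %d pairs (%d rejected, %d refinement cycle(s))%s\n",
              x$rmsd, x$n_pairs_used, x$n_pairs_rejected, x$cycles_run,
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}

# identity substitution matrix for residue pairing
.identity_submat <- function() {
  letters <- c(.aa1, "X")
  m <- diag(1, length(letters))
  dimnames(m) <- list(letters, letters)
  m
}

#' Pair residues (and atoms) between two models
#'
#' Residues are paired chain-by-chain (chains matched by identifier) via
#' Needleman-Wunsch global alignment of the extracted one-letter
#' sequences with identity scoring (gap opening 10, extension 0.5 —
#' only the pairing topology is consumed, not the scores). Aligned,
#' non-gap positions with the required atoms present in both models are
#' paired: mode `"calpha"` takes one C-alpha per residue; `"all_atom"`
#' pairs identically named atoms within each paired residue, so a
#' side-chain-less lysine contributes its backbone atoms only.
#'
#' @param model_a,model_b `xlcal_model` objects.
#' @param mode `"calpha"` or `"all_atom"`.
#' @return List: `coords_a`, `coords_b` (n x 3), and `map` — data.frame
#'   of chain, paired residue numbers and atom name per row.
#' @export
pair_residues <- function(model_a, model_b, mode = c("calpha", "all_atom")) {
  mode <- match.arg(mode)
  chains <- intersect(model_chains(model_a), model_chains(model_b))
  if (length(chains) == 0) stop("models share no chain identifiers")
  seqs_a <- chain_sequences(model_a); seqs_b <- chain_sequences(model_b)
  submat <- .identity_submat()
  map <- NULL
  for (ch in chains) {
    sa <- seqs_a[[ch]]; sb <- seqs_b[[ch]]
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(sa$seq), Biostrings::AAString(sb$seq),
      substitutionMatrix = submat, gapOpening = 10, gapExtension = 0.5,
      type = "global")
    pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    ia <- 0L; ib <- 0L
    for (k in seq_along(pat)) {
      if (pat[k] != "-") ia <- ia + 1L
      if (sub[k] != "-") ib <- ib + 1L
      if (pat[k] != "-" && sub[k] != "-") {
        map <- rbind(map, data.frame(chain = ch,
                                     resno_a = sa$resno[ia],
                                     resno_b = sb$resno[ib],
                                     stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(map)) stop("no pairable residues between models")

  atoms_for <- function(model, ch, rn) {
    at <- model$atoms
    at[at$chain == ch & at$resno == rn, , drop = FALSE]
  }
  rows <- list(); k <- 0
  for (i in seq_len(nrow(map))) {
    ra <- atoms_for(model_a, map$chain[i], map$resno_a[i])
    rb <- atoms_for(model_b, map$chain[i], map$resno_b[i])
    names_common <- if (mode == "calpha") intersect("CA", intersect(ra$elety, rb$elety))
                    else intersect(ra$elety, rb$elety)
    for (nm in names_common) {
      k <- k + 1
      rows[[k]] <- data.frame(
        chain = map$chain[i], resno_a = map$resno_a[i],
        resno_b = map$resno_b[i], elety = nm,
        xa = ra$x[ra$elety == nm], ya = ra$y[ra$elety == nm],
        za = ra$z[ra$elety == nm],
        xb = rb$x[rb$elety == nm], yb = rb$y[rb$elety == nm],
        zb = rb$z[rb$elety == nm], stringsAsFactors = FALSE)
    }
  }
  if (k == 0) stop("no pairable atoms between models in mode ", mode)
  tab <- do.call(rbind, rows)
  ca <- as.matrix(tab[, c("xa", "ya", "za")])
  cb <- as.matrix(tab[, c("xb", "yb", "zb")])
  colnames(ca) <- colnames(cb) <- c("x", "y", "z")
  list(coords_a = ca, coords_b = cb,
       map = tab[, c("chain", "resno_a", "resno_b", "elety")])
}

#' Superpose two models, with optional iterative outlier rejection
#'
#' The fit is always computed on C-alpha pairs. With `refine = NULL`
#' (no outlier rejection) a single Kabsch pass is made on all pairs.
#' With `refine = reject_outliers()` the fit iterates: superpose,
#' compute per-residue C-alpha residuals, drop residues with residual
#' above `cutoff_sigma` times the residual standard deviation (measured
#' about zero, i.e. the RMS residual of the current fit), re-superpose;
#' stopping when no residue is dropped or `max_cycles` is reached. The reported RMSD is over the surviving residues; in mode
#' `"all_atom"` the C-alpha-fitted transform is applied and the RMSD
#' taken over all paired atoms of surviving residues (the convention for
#' quoting an all-atom RMSD after a C-alpha alignment).
#'
#' @param model_a,model_b `xlcal_model` objects.
#' @param mode `"calpha"` or `"all_atom"` (RMSD atom set).
#' @param refine `NULL` or [reject_outliers()].
#' @return A `xlcal_superposition` (see [kabsch()]) with rejection
#'   bookkeeping filled in.
#' @export
align_models <- function(model_a, model_b, mode = c("calpha", "all_atom"),
                         refine = NULL) {
  mode <- match.arg(mode)
  pr <- pair_residues(model_a, model_b, mode = "calpha")
  n <- nrow(pr$coords_a)
  active <- seq_len(n)
  cycles <- 0L
  repeat {
    if (length(active) < 3) stop("outlier rejection left fewer than 3 pairs; cutoff too aggressive")
    fit <- kabsch(pr$coords_a[active, , drop = FALSE],
                  pr$coords_b[active, , drop = FALSE])
    if (is.null(refine) || cycles >= refine$max_cycles) break
    moved <- sweep(pr$coords_b[active, , drop = FALSE] %*% t(fit$rotation),
                   2, fit$translation, `+`)
    res <- sqrt(rowSums((pr$coords_a[active, , drop = FALSE] - moved)^2))
    s <- sqrt(mean(res^2))
    if (!is.finite(s) || s < 1e-12) break
    drop <- res > refine$cutoff_sigma * s
    if (!any(drop)) break
    if (all(drop)) stop("all pairs rejected; cutoff too aggressive")
    active <- active[!drop]
    cycles <- cycles + 1L
  }
  rejected <- setdiff(seq_len(n), active)
  out <- fit
  out$cycles_run <- cycles
  out$n_pairs_rejected <- length(rejected)
  out$rejected_pairs <- paste0(pr$map$chain[rejected], ":",
                               pr$map$resno_a[rejected])
  if (mode == "all_atom") {
    pa <- pair_residues(model_a, model_b, mode = "all_atom")
    keep_key <- paste(pr$map$chain[active], pr$map$resno_a[active])
    sel <- paste(pa$map$chain, pa$map$resno_a) %in% keep_key
    moved <- sweep(pa$coords_b[sel, , drop = FALSE] %*% t(out$rotation),
                   2, out$translation, `+`)
    out$rmsd <- sqrt(mean(rowSums((pa$coords_a[sel, , drop = FALSE] - moved)^2)))
    out$n_pairs_used <- sum(sel)
  } else {
    out$n_pairs_used <- length(active)
  }
  out
}

#' Outlier-rejection settings for [align_models()]
#'
#' Defaults (2.0 sigma, 5 cycles) mirror common refinement defaults in
#' interactive alignment tools; both are reported in the result.
#'
#' @param cutoff_sigma residual cutoff in standard deviations.
#' @param max_cycles maximum rejection cycles.
#' @export
reject_outliers <- function(cutoff_sigma = 2.0, max_cycles = 5L) {
  stopifnot(cutoff_sigma > 0, max_cycles >= 1)
  list(cutoff_sigma = cutoff_sigma, max_cycles = as.integer(max_cycles))
}
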