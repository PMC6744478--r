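#' Van der Waals radii used for surface calculations
#'
#' Bondi-type radii for the elements found in hydrogen-free protein
#' models. Configurable: pass a modified copy to [shrake_rupley()].
#'
#' @return Named numeric vector, Angstrom.
#' @export
vdw_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)
}

# deterministic generalized-spiral (Fibonacci) point set on the unit sphere
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# molecule-intrinsic orthonormal frame: principal axes of the coordinate
# cloud, signs fixed by third moments so the frame co-rotates with the
# molecule and the sampling lattice is rigid-motion equivariant
.molecular_frame <- function(xyz) {
  cc <- sweep(xyz, 2, colMeans(xyz))
  v <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)$vectors
  skew <- numeric(3)
  for (k in 1:3) {
    skew[k] <- sum((cc %*% v[, k])^3)
    if (skew[k] < 0) {
      v[, k] <- -v[, k]
      skew[k] <- -skew[k]
    }
  }
  if (det(v) < 0) v[, which.min(skew)] <- -v[, which.min(skew)]
  v
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Per-atom SASA by sphere-point sampling: each atom's surface is probed
#' at `n_points` deterministic spiral points on the sphere of radius
#' (vdW + probe); points falling inside any neighbouring atom's expanded
#' sphere are occluded. Deterministic given `n_points` — no random
#' sampling; the lattice is expressed in a molecule-intrinsic principal
#' axis frame, so totals are invariant under rigid motion of the model.
#' Per-residue values sum heavy atoms (models are assumed
#' hydrogen-free).
#'
#' @param model a `xlcal_model`.
#' @param probe_radius solvent probe radius, Angstrom (default 1.4, a
#'   water molecule).
#' @param n_points sphere sample points per atom (default 960).
#' @param radii named element -> radius table, Angstrom.
#' @param orientation optional 3x3 orthonormal matrix fixing the lattice
#'   orientation (default: the model's principal-axis frame); pass a
#'   shared frame to compare sub-models of one complex on an identical
#'   lattice.
#' @return `xlcal_sasa`: list with `per_atom` (numeric, one per atom row
#'   of the model), `per_residue` (named by `chain:resno`), `total`,
#'   `probe_radius`, `n_sphere_points`, `radii_set`.
#' @export
shrake_rupley <- function(model, probe_radius = 1.4, n_points = 960,
                          radii = vdw_radii(), orientation = NULL) {
  at <- model$atoms
  elem <- toupper(at$elem)
  unknown <- !(elem %in% names(radii))
  if (any(unknown)) {
    i <- which(unknown)[1]
    stop(sprintf("no vdW radius for element '%s' (atom %s %s/%d %s)",
                 elem[i], at$chain[i], at$elety[i], at$resno[i],
                 at$resid[i]))
  }
  r <- unname(radii[elem]) + probe_radius
  xyz <- as.matrix(at[, c("x", "y", "z")])
  n <- nrow(xyz)
  if (is.null(orientation)) orientation <- .molecular_frame(xyz)
  pts <- sphere_points(n_points) %*% t(orientation)
  # neighbour lists: spheres i, j can occlude iff centers closer than r_i + r_j
  d2 <- as.matrix(stats::dist(xyz))^2
  per_atom <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (r[i] + r)^2 & seq_len(n) != i)
    p <- sweep(pts * r[i], 2, xyz[i, ], `+`)
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(exposed)) break
      dj <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
            (p[, 3] - xyz[j, 3])^2
      exposed <- exposed & dj >= r[j]^2
    }
    per_atom[i] <- 4 * pi * r[i]^2 * sum(exposed) / n_points
  }
  res_key <- paste0(at$chain, ":", at$resno)
  per_residue <- tapply(per_atom, factor(res_key, levels = unique(res_key)),
                        sum)
  structure(list(per_atom = per_atom,
                 per_residue = per_residue[],
                 total = sum(per_atom),
                 probe_radius = probe_radius,
                 n_sphere_points = n_points,
                 radii_set = "bondi"),
            class = "xlcal_sasa")
}

#' @export
print.xlcal_sasa <- function(x, ...) {
  cat(sprintf("<sasa> total %.1f A^2 over %d atoms (probe %.1f A, %d points)\n",
              x$total, length(x$per_atom), x$probe_radius,
              x$n_sphere_points))
  invisible(x)
}

#' Extract chains into a sub-model
#' @param model a `xlcal_model`.
#' @param chains chain identifiers to keep.
#' @export
subset_chains <- function(model, chains) {
  at <- model$atoms[model$atoms$chain %in% chains, , drop = FALSE]
  if (nrow(at) == 0) stop("no atoms in chain(s) ", paste(chains, collapse = ","))
  structure_model(at, model_id = paste0(model$model_id, "_",
                                        paste(chains, collapse = "")),
                  source = model$source)
}

#' Buried surface area per component of a complex
#'
#' For each component (a set of chains) the SASA is computed on the
#' component extracted alone and on the same atoms within the full
#' complex; the difference is the area buried on complex formation. The
#' components must partition the complex's chains, so the accounting
#' identity sum(buried) = sum(isolated SASA) - complex SASA holds
#' exactly.
#'
#' @param complex_model a multi-chain `xlcal_model`.
#' @param components list of chain-id vectors partitioning the chains.
#' @param ... passed to [shrake_rupley()].
#' @return data.frame: `component`, `sasa_isolated`, `sasa_in_complex`,
#'   `buried` (Angstrom^2), with the complex total as attribute
#'   `complex_total`.
#' @export
buried_surface <- function(complex_model, components, ...) {
  all_ch <- unlist(components)
  if (anyDuplicated(all_ch)) stop("components overlap")
  if (!setequal(all_ch, model_chains(complex_model))) {
    stop("components must partition the complex's chains")
  }
  frame <- .molecular_frame(
    as.matrix(complex_model$atoms[, c("x", "y", "z")]))
  full <- shrake_rupley(complex_model, orientation = frame, ...)
  at_chain <- complex_model$atoms$chain
  rows <- lapply(components, function(chs) {
    iso <- shrake_rupley(subset_chains(complex_model, chs),
                         orientation = frame, ...)
    in_cplx <- sum(full$per_atom[at_chain %in% chs])
    data.frame(component = paste(chs, collapse = "+"),
               sasa_isolated = iso$total,
               sasa_in_complex = in_cplx,
               buried = iso$total - in_cplx,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "complex_total") <- full$total
  out
}

# all permutations of 1..n (n small), one per row
.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  k <- 0
  for (i in seq_len(n)) {
    rows <- seq_len(nrow(sub)) + k * nrow(sub)
    out[rows, 1] <- i
    rest <- setdiff(seq_len(n), i)
    out[rows, -1] <- matrix(rest[sub], nrow(sub), n - 1L)
    k <- k + 1
  }
  out
}

#' Correlation between buried surface area and binding affinity
#'
#' Spearman rank correlation (midranks for ties) with a permutation
#' p-value: exhaustive over all n! pairings for n <= 8, otherwise
#' 10,000 seeded resamples. Two-sided: the p-value is the fraction of
#' permutations with |rho| at least the observed |rho|.
#'
#' @param buried buried areas, Angstrom^2 (one per complex).
#' @param kd equilibrium dissociation constants (same order).
#' @param n_perm resamples when n > 8.
#' @param seed RNG seed for the resampled case.
#' @return List: `rho`, `p_value`, `n`, `method`.
#' @export
burial_affinity_correlation <- function(buried, kd, n_perm = 10000,
                                        seed = 1L) {
  if (length(buried) != length(kd)) stop("inputs differ in length")
  n <- length(buried)
  if (n < 3) stop("need at least 3 paired observations")
  rho_obs <- stats::cor(buried, kd, method = "spearman")
  rb <- rank(buried); rk <- rank(kd)
  if (n <= 8) {
    perms <- .permutations(n)
    rhos <- apply(perms, 1, function(p) stats::cor(rb, rk[p]))
    method <- "exhaustive"
  } else {
    set.seed(seed)
    rhos <- replicate(n_perm, stats::cor(rb, rk[sample.int(n)]))
    method <- "resampled"
  }
  p <- mean(abs(rhos) >= abs(rho_obs) - 1e-12)
  list(rho = rho_obs, p_value = p, n = n, method = method)
}
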