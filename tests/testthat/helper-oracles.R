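# Independent oracles and fixture builders shared across the suite.

# Horn's quaternion superposition: closed-form RMSD from the largest
# eigenvalue of the 4x4 key matrix. Independent of the SVD route used by
# kabsch().
quat_rmsd <- function(a, b) {
  a0 <- sweep(a, 2, colMeans(a))
  b0 <- sweep(b, 2, colMeans(b))
  s <- crossprod(b0, a0)
  k <- matrix(0, 4, 4)
  k[1, 1] <- s[1, 1] + s[2, 2] + s[3, 3]
  k[1, 2] <- k[2, 1] <- s[2, 3] - s[3, 2]
  k[1, 3] <- k[3, 1] <- s[3, 1] - s[1, 3]
  k[1, 4] <- k[4, 1] <- s[1, 2] - s[2, 1]
  k[2, 2] <- s[1, 1] - s[2, 2] - s[3, 3]
  k[2, 3] <- k[3, 2] <- s[1, 2] + s[2, 1]
  k[2, 4] <- k[4, 2] <- s[1, 3] + s[3, 1]
  k[3, 3] <- -s[1, 1] + s[2, 2] - s[3, 3]
  k[3, 4] <- k[4, 3] <- s[2, 3] + s[3, 2]
  k[4, 4] <- -s[1, 1] - s[2, 2] + s[3, 3]
  lam <- max(eigen(k, symmetric = TRUE)$values)
  sqrt(max(0, (sum(a0^2) + sum(b0^2) - 2 * lam) / nrow(a)))
}

# random proper rotation from a normalized quaternion
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# brute-force restraint evaluation: direct data.frame scans and explicit
# arithmetic, no calls into get_atom()/atom_distance()/evaluate_restraints()
brute_restraint_eval <- function(model, restraints, policy) {
  at <- model$atoms
  xyz_of <- function(ch, rn, nm) {
    w <- which(at$chain == ch & at$resno == rn & at$elety == nm)
    if (length(w) != 1) return(NULL)
    c(at$x[w], at$y[w], at$z[w])
  }
  out <- data.frame(distance = rep(NA_real_, nrow(restraints)),
                    violation = 0, atom_used = "missing",
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(restraints))) {
    lo <- restraints$lower[i]; hi <- restraints$upper[i]
    pa <- xyz_of(restraints$chain_a[i], restraints$pos_a[i], policy$atom_primary)
    pb <- xyz_of(restraints$chain_b[i], restraints$pos_b[i], policy$atom_primary)
    used <- "primary"
    if (is.null(pa) || is.null(pb)) {
      pa <- xyz_of(restraints$chain_a[i], restraints$pos_a[i], policy$atom_fallback)
      pb <- xyz_of(restraints$chain_b[i], restraints$pos_b[i], policy$atom_fallback)
      used <- "fallback"
      lo <- max(0, lo - policy$fallback_pad)
      hi <- hi + policy$fallback_pad
    }
    if (is.null(pa) || is.null(pb)) next
    d <- sqrt((pa[1] - pb[1])^2 + (pa[2] - pb[2])^2 + (pa[3] - pb[3])^2)
    out$distance[i] <- d
    out$atom_used[i] <- used
    if (d > hi) out$violation[i] <- d - hi
    if (d < lo) out$violation[i] <- lo - d
  }
  out
}

# varied-sequence C-alpha-only model on helix geometry: residue types
# cycle through all 20 amino acids so sequence alignments are unambiguous
make_varied_model <- function(n, chain = "A", resno = seq_len(n),
                              model_id = "varied") {
  aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
           "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
           "TYR", "VAL")
  i <- seq_len(n)
  ang <- (i - 1) * 100 * pi / 180
  atoms <- data.frame(chain = chain, resno = as.integer(resno), insert = "",
                      resid = aa3[(c(0, cumsum(seq_len(n - 1))) %% 20) + 1],
                      elety = "CA", elem = "C",
                      x = 2.3 * cos(ang), y = 2.3 * sin(ang),
                      z = (i - 1) * 1.5, o = 1, b = 0,
                      stringsAsFactors = FALSE)
  structure_model(atoms, model_id = model_id)
}

# two-helix complex with planted intra and inter lysine crosslinks;
# chains A (origin) and B (offset along +x)
make_two_chain_complex <- function(offset = 9, len = 30) {
  ha <- make_helix_model(len, "A", lysines = seq(2, len, by = 3))
  hb <- make_helix_model(len, "B", origin = c(offset, 0, 0),
                         lysines = seq(2, len, by = 3))
  structure_model(rbind(ha$atoms, hb$atoms), model_id = "two_chain")
}

# random single-chain helix fixture with a random subset of lysines
random_helix_fixture <- function(seed) {
  set.seed(seed)
  len <- sample(20:40, 1)
  lys <- sort(sample(seq_len(len), max(4, len %/% 4)))
  make_helix_model(len, "A", lysines = lys,
                   phase = stats::runif(1, 0, 360))
}

# exhaustive permutations built a different way than the package's
# internal generator: filter all n^n index tuples down to permutations
enumerate_perms <- function(n) {
  grid <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  grid[apply(grid, 1, function(r) length(unique(r)) == n), , drop = FALSE]
}
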