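#' Build an ideal alpha-helix model
#'
#' Deterministic toy helix used as a stand-in for predicted protein
#' models: C-alpha trace on an ideal helix (rise 1.5 Angstrom and 100
#' degrees twist per residue, radius 2.3 Angstrom, giving consecutive
#' C-alpha distances of ~3.8 Angstrom) with a pseudo N-zeta atom for
#' each lysine placed 6.4 Angstrom radially outward from its C-alpha —
#' a geometric stand-in for an extended side chain, not a chemically
#' realistic conformer.
#'
#' @param length number of residues (>= 4).
#' @param chain_id single-character chain identifier.
#' @param origin position of the helix axis at the first residue.
#' @param axis helix axis direction (any nonzero 3-vector).
#' @param lysines residue indices (1-based within the helix) modeled as
#'   lysine; all other residues are alanine.
#' @param resno_start author number of the first residue.
#' @param phase rotation offset of the first residue, degrees.
#' @return A `xlcal_model`.
#' @export
make_helix_model <- function(length, chain_id = "A", origin = c(0, 0, 0),
                             axis = c(0, 0, 1), lysines = integer(0),
                             resno_start = 1L, phase = 0) {
  stopifnot(length >= 4)
  radius <- 2.3; rise <- 1.5; twist <- 100 * pi / 180
  nz_offset <- 6.4
  i <- seq_len(length)
  ang <- phase * pi / 180 + (i - 1) * twist
  ca <- cbind(radius * cos(ang), radius * sin(ang), (i - 1) * rise)
  # rotate local z onto the requested axis (Rodrigues), then translate
  axis <- axis / sqrt(sum(axis^2))
  z <- c(0, 0, 1)
  v <- c(z[2] * axis[3] - z[3] * axis[2],
         z[3] * axis[1] - z[1] * axis[3],
         z[1] * axis[2] - z[2] * axis[1])
  cterm <- sum(z * axis)
  if (sqrt(sum(v^2)) < 1e-12) {
    rot <- if (cterm > 0) diag(3) else diag(c(1, -1, -1))
  } else {
    vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
    rot <- diag(3) + vx + vx %*% vx / (1 + cterm)
  }
  place <- function(xyz) sweep(xyz %*% t(rot), 2, origin, `+`)
  ca_w <- place(ca)
  rows <- list(); k <- 0
  for (j in i) {
    is_lys <- j %in% lysines
    resid <- if (is_lys) "LYS" else "ALA"
    k <- k + 1
    rows[[k]] <- data.frame(chain = chain_id, resno = resno_start + j - 1L,
                            insert = "", resid = resid, elety = "CA",
                            elem = "C", x = ca_w[j, 1], y = ca_w[j, 2],
                            z = ca_w[j, 3], o = 1, b = 0,
                            stringsAsFactors = FALSE)
    if (is_lys) {
      nz <- c((radius + nz_offset) * cos(ang[j]),
              (radius + nz_offset) * sin(ang[j]), (j - 1) * rise)
      nz_w <- place(matrix(nz, 1, 3))
      k <- k + 1
      rows[[k]] <- data.frame(chain = chain_id,
                              resno = resno_start + j - 1L, insert = "",
                              resid = "LYS", elety = "NZ", elem = "N",
                              x = nz_w[1], y = nz_w[2], z = nz_w[3],
                              o = 1, b = 0, stringsAsFactors = FALSE)
    }
  }
  structure_model(do.call(rbind, rows),
                  model_id = sprintf("helix_%s%d", chain_id, length),
                  source = "synthetic")
}

#' Canonical folded test fixture
#'
#' A single-chain bundle of four major helices (35 residues each) and
#' four short helices (8 residues each), lysines every third residue —
#' a deterministic stand-in, of similar size and topology to a small
#' helical membrane-anchor protein, with many lysine pairs inside DSSO
#' reach across neighbouring helices. Used throughout the tests and
#' documentation.
#'
#' @param chain_id chain identifier.
#' @return A `xlcal_model`.
#' @export
make_bundle_fixture <- function(chain_id = "A") {
  spots <- list(c(0, 0), c(9, 0), c(9, 9), c(0, 9),
                c(-8, 4.5), c(17, 4.5), c(4.5, -8), c(4.5, 17))
  lens <- c(35, 35, 35, 35, 8, 8, 8, 8)
  parts <- list()
  start <- 1L
  for (h in seq_along(lens)) {
    ly <- seq(2, lens[h], by = 3)
    parts[[h]] <- make_helix_model(
      lens[h], chain_id = chain_id,
      origin = c(spots[[h]][1], spots[[h]][2], 0),
      axis = c(0, 0, if (h %% 2 == 0) -1 else 1),
      lysines = ly, resno_start = start, phase = 45 * h)
    start <- start + lens[h] + 3L   # numbering gap for the linker
  }
  atoms <- do.call(rbind, lapply(parts, function(m) m$atoms))
  structure_model(atoms, model_id = "bundle_fixture", source = "synthetic")
}

#' Generate decoys by rigid transforms of one chain
#'
#' Stand-in for a docking run's candidate poses: each decoy applies one
#' proper rigid transform to the selected chain(s) of the input model.
#' An identity transform reproduces the input (the planted truth).
#'
#' @param model a `xlcal_model`.
#' @param transforms list of `list(rotation = 3x3, translation = len-3)`.
#' @param chains chains the transform applies to (default: last chain).
#' @return List of `xlcal_model` decoys, ids `<model_id>_decoy<i>`.
#' @export
make_decoys <- function(model, transforms,
                        chains = utils::tail(model_chains(model), 1)) {
  lapply(seq_along(transforms), function(i) {
    tr <- transforms[[i]]
    rot <- if (is.null(tr$rotation)) diag(3) else tr$rotation
    if (abs(det(rot) - 1) > 1e-8) stop("transform ", i, " is not a proper rotation")
    tl <- if (is.null(tr$translation)) c(0, 0, 0) else tr$translation
    d <- transform_model(model, rot, tl, chains = chains)
    d$model_id <- sprintf("%s_decoy%d", model$model_id, i)
    d
  })
}

# one-letter sequence of a chain, as a gap-free string over author numbering
.chain_seq_string <- function(model, chain) {
  cs <- chain_sequences(model)[[chain]]
  full <- rep("A", max(cs$resno))
  full[cs$resno] <- strsplit(cs$seq, "")[[1]]
  paste(full, collapse = "")
}

#' Generate a PSM-level crosslink table from a model
#'
#' Emulates the shape of a search-engine crosslink export: finds lysine
#' pairs whose N-zeta distance in the model satisfies the restraint
#' policy, samples `n_pairs` of them, and emits `psm_multiplicity`
#' redundant rows per pair with varying charge states and alternating
#' orientation (A-B / B-A), as real PSM tables do. Deterministic per
#' seed. By construction, restraints built from the deduplicated table
#' are fully satisfied on the generating model.
#'
#' @param model a `xlcal_model`.
#' @param policy a [restraint_policy()].
#' @param n_pairs unique residue pairs to plant.
#' @param psm_multiplicity PSM rows per pair.
#' @param seed RNG seed.
#' @param protein_map named chain -> protein accession (default:
#'   `"PROT_<chain>"`).
#' @param kind `"intra"`, `"inter"` or `"both"`.
#' @return data.frame in the canonical crosslink-table schema.
#' @export
make_crosslink_table <- function(model, policy = restraint_policy(),
                                 n_pairs, psm_multiplicity = 3, seed = 1L,
                                 protein_map = NULL,
                                 kind = c("intra", "inter", "both")) {
  kind <- match.arg(kind)
  chains <- model_chains(model)
  if (is.null(protein_map)) {
    protein_map <- stats::setNames(paste0("PROT_", chains), chains)
  }
  nz <- model$atoms[model$atoms$elety == "NZ", , drop = FALSE]
  if (nrow(nz) < 2) stop("model has fewer than 2 lysine N-zeta atoms")
  cand <- NULL
  for (i in seq_len(nrow(nz) - 1)) {
    for (j in (i + 1):nrow(nz)) {
      d <- sqrt(sum((nz[i, c("x", "y", "z")] - nz[j, c("x", "y", "z")])^2))
      same <- nz$chain[i] == nz$chain[j]
      ok <- if (same) d <= policy$intra_max
            else d >= policy$inter_min && d <= policy$inter_max
      if (!ok) next
      if (kind == "intra" && !same) next
      if (kind == "inter" && same) next
      cand <- rbind(cand, data.frame(
        chain_a = nz$chain[i], pos_a = nz$resno[i],
        chain_b = nz$chain[j], pos_b = nz$resno[j],
        stringsAsFactors = FALSE))
    }
  }
  n_avail <- if (is.null(cand)) 0 else nrow(cand)
  if (n_avail < n_pairs) {
    stop("only ", n_avail, " lysine pair(s) within policy reach; ",
         n_pairs, " requested")
  }
  set.seed(seed)
  pick <- cand[sample.int(n_avail, n_pairs), , drop = FALSE]
  seqs <- stats::setNames(
    lapply(chains, function(ch) .chain_seq_string(model, ch)), chains)
  pep <- function(ch, pos) {
    s <- seqs[[ch]]
    substr(s, max(1, pos - 3), min(nchar(s), pos + 3))
  }
  rows <- list(); k <- 0
  for (p in seq_len(nrow(pick))) {
    for (m in seq_len(psm_multiplicity)) {
      k <- k + 1
      swap <- m %% 2 == 0       # exercise both reported orientations
      a <- if (swap) "b" else "a"; b <- if (swap) "a" else "b"
      rows[[k]] <- data.frame(
        protein_a = protein_map[[pick[[paste0("chain_", a)]][p]]],
        peptide_a = pep(pick[[paste0("chain_", a)]][p],
                        pick[[paste0("pos_", a)]][p]),
        link_pos_a = pick[[paste0("pos_", a)]][p],
        protein_b = protein_map[[pick[[paste0("chain_", b)]][p]]],
        peptide_b = pep(pick[[paste0("chain_", b)]][p],
                        pick[[paste0("pos_", b)]][p]),
        link_pos_b = pick[[paste0("pos_", b)]][p],
        charge = 2L + (m - 1L) %% 3L + 1L,
        psm_id = sprintf("psm%03d_%d", p, m),
        score = round(20 + 10 * stats::runif(1), 2),
        qvalue = round(0.01 * stats::runif(1), 5),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Generate a multi-concentration sensorgram set
#'
#' One simulated curve per concentration (default grid 0.1x, 0.3x, 1x,
#' 3x, 10x KD, matching the usual 3-5 concentrations per analyte), each
#' with its own derived seed so the set is deterministic as a whole.
#'
#' @param params a [kinetic_params()].
#' @param concentrations analyte concentrations, molar (default
#'   `params$KD * c(0.1, 0.3, 1, 3, 10)`).
#' @param noise_sd Gaussian noise SD, RU.
#' @param seed base RNG seed.
#' @param ... passed to [simulate_1to1()] (`t_assoc`, `t_dissoc`, `dt`).
#' @return List of `xlcal_sensorgram`.
#' @export
make_sensorgram_set <- function(params, concentrations = NULL,
                                noise_sd = 0, seed = 1L, ...) {
  if (is.null(concentrations)) {
    concentrations <- params$KD * c(0.1, 0.3, 1, 3, 10)
  }
  lapply(seq_along(concentrations), function(i) {
    simulate_1to1(params, concentrations[i], noise_sd = noise_sd,
                  seed = seed + i, label = sprintf("curve%02d", i), ...)
  })
}
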