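#' Construct a structure model
#'
#' A `xlcal_model` holds one polypeptide model as a flat atom table, the
#' substrate for restraint evaluation, superposition and surface-area
#' calculations. Author residue numbering is preserved verbatim (1-based,
#' gaps allowed) because crosslink positions are stated in full-protein
#' coordinates.
#'
#' @param atoms data.frame with columns `chain` (single character),
#'   `resno` (integer, author numbering), `insert` (insertion code, ""
#'   if none), `resid` (3-letter residue name), `elety` (atom name, e.g.
#'   "CA", "NZ"), `elem` (element symbol), `x`,`y`,`z` (Angstrom),
#'   `o` (occupancy), `b` (B-factor).
#' @param model_id character scalar identifying the model.
#' @param source file path the model came from, or "synthetic".
#' @return An object of class `xlcal_model`.
#' @export
structure_model <- function(atoms, model_id = "model", source = "synthetic") {
  required <- c("chain", "resno", "insert", "resid", "elety", "elem",
                "x", "y", "z", "o", "b")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0) {
    stop("atom table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(atoms) == 0) stop("model must contain at least one atom")
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(coords))) stop("atom coordinates must be finite")
  if (any(atoms$o < 0 | atoms$o > 1, na.rm = TRUE)) {
    stop("occupancy must lie in [0, 1]")
  }
  # residue order within each chain must be nondecreasing in author numbering
  for (ch in unique(atoms$chain)) {
    rn <- atoms$resno[atoms$chain == ch]
    if (is.unsorted(rn, strictly = FALSE)) {
      stop("residue numbering within chain ", ch, " is not nondecreasing")
    }
  }
  atoms$chain <- as.character(atoms$chain)
  atoms$insert <- as.character(atoms$insert)
  rownames(atoms) <- NULL
  structure(list(model_id = model_id, atoms = atoms, source = source),
            class = "xlcal_model")
}

#' @export
print.xlcal_model <- function(x, ...) {
  nres <- nrow(unique(x$atoms[, c("chain", "resno", "insert")]))
  cat(sprintf("<xlcal_model> %s: %d chain(s), %d residues, %d atoms [%s]\n",
              x$model_id, length(unique(x$atoms$chain)), nres,
              nrow(x$atoms), x$source))
  invisible(x)
}

#' Chains present in a model
#' @param model a `xlcal_model`.
#' @return Character vector of chain identifiers, in file order.
#' @export
model_chains <- function(model) unique(model$atoms$chain)

# standard amino acids retained by the reader
.aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")
.aa1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H",
          "I", "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

aa_3to1 <- function(res3) {
  out <- .aa1[match(res3, .aa3)]
  out[is.na(out)] <- "X"
  out
}

#' Read a PDB file into a structure model
#'
#' Parses fixed-column PDB text (via bio3d), keeping ATOM records of
#' standard amino acids only: HETATM records (waters, ligands) are
#' excluded, and alternate locations are collapsed according to
#' `altloc_policy`. Only the first MODEL of a multi-model file is read.
#'
#' @param path path to a PDB file.
#' @param altloc_policy `"highest_occupancy"` (default; ties broken by
#'   file order) or `"first"` (first altloc encountered in the file).
#' @return A [structure_model()].
#' @export
read_pdb <- function(path, altloc_policy = c("highest_occupancy", "first")) {
  altloc_policy <- match.arg(altloc_policy)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  atom_idx <- grep("^ATOM  |^HETATM", lines)
  if (length(atom_idx) == 0) stop("no ATOM records found in ", path)
  # pre-scan coordinate fields so malformed lines are reported with numbers
  for (i in atom_idx) {
    ln <- lines[i]
    if (nchar(ln) < 54) stop("malformed ATOM line ", i, ": too short")
    fields <- c(substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))
    if (anyNA(suppressWarnings(as.numeric(fields)))) {
      stop("malformed ATOM line ", i, ": non-numeric coordinate field")
    }
  }
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                          verbose = FALSE))
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$resid %in% .aa3, , drop = FALSE]
  if (nrow(at) == 0) stop("no standard amino-acid ATOM records in ", path)
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  at$b[is.na(at$b)] <- 0

  # collapse alternate locations per (chain, resno, insert, atom name)
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  if (anyDuplicated(key)) {
    keep <- logical(nrow(at))
    for (grp in split(seq_len(nrow(at)), key)) {
      if (length(grp) == 1) {
        keep[grp] <- TRUE
      } else if (altloc_policy == "first") {
        keep[grp[1]] <- TRUE
      } else {
        keep[grp[which.max(at$o[grp])]] <- TRUE
      }
    }
    at <- at[keep, , drop = FALSE]
  }
  atoms <- data.frame(chain = at$chain, resno = at$resno, insert = at$insert,
                      resid = at$resid, elety = at$elety,
                      elem = ifelse(is.na(at$elesy) | at$elesy == "",
                                    substr(gsub("[0-9]", "", at$elety), 1, 1),
                                    at$elesy),
                      x = at$x, y = at$y, z = at$z, o = at$o, b = at$b,
                      stringsAsFactors = FALSE)
  structure_model(atoms, model_id = sub("\\.pdb$", "", basename(path)),
                  source = path)
}

#' Write a structure model as PDB text
#'
#' Emits fixed-column ATOM records (coordinates `%8.3f`) with a TER
#' record after each chain, so that `read_pdb(write_pdb(m))` reproduces
#' the residue/atom inventory and coordinates to printed precision.
#'
#' @param model a `xlcal_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(model, path) {
  stopifnot(inherits(model, "xlcal_model"))
  at <- model$atoms
  if (nrow(at) == 0) stop("refusing to write an empty model")
  if (any(nchar(at$chain) != 1)) {
    stop("PDB chain identifiers must be a single character")
  }
  lines <- character(0)
  serial <- 0L
  for (ch in unique(at$chain)) {
    sub <- at[at$chain == ch, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      serial <- serial + 1L
      name4 <- if (nchar(sub$elety[i]) < 4) sprintf(" %-3s", sub$elety[i])
               else sub$elety[i]
      lines <- c(lines, sprintf(
        "ATOM  %5d %4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial %% 100000L, name4, sub$resid[i], ch, sub$resno[i],
        ifelse(sub$insert[i] == "", " ", sub$insert[i]),
        sub$x[i], sub$y[i], sub$z[i], sub$o[i], sub$b[i],
        toupper(sub$elem[i])))
    }
    serial <- serial + 1L
    last <- sub[nrow(sub), ]
    lines <- c(lines, sprintf("TER   %5d      %3s %1s%4d",
                              serial %% 100000L, last$resid, ch, last$resno))
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Look up a single atom
#'
#' Absence (missing side chain, residue not in the model) is data, not an
#' error: the function returns `NULL` in that case. A duplicate atom name
#' within a residue after altloc collapse is a malformed model and errors.
#'
#' @param model a `xlcal_model`.
#' @param chain chain identifier.
#' @param seq_number author residue number.
#' @param atom_name atom label, e.g. `"NZ"`, `"CA"`.
#' @param insert insertion code ("" if none).
#' @return One-row data.frame (the atom record), or `NULL` if absent.
#' @export
get_atom <- function(model, chain, seq_number, atom_name, insert = "") {
  at <- model$atoms
  hit <- at$chain == chain & at$resno == seq_number &
    at$insert == insert & at$elety == atom_name
  n <- sum(hit)
  if (n == 0) return(NULL)
  if (n > 1) {
    stop(sprintf("ambiguous atom: %s %s/%d%s has %d records named %s",
                 model$model_id, chain, seq_number, insert, n, atom_name))
  }
  at[hit, , drop = FALSE]
}

#' Euclidean distance between two atoms
#'
#' @param a,b one-row atom records as returned by [get_atom()].
#' @return Distance in Angstrom.
#' @export
atom_distance <- function(a, b) {
  sqrt((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2)
}

#' Extract coordinates of named atoms
#'
#' @param model a `xlcal_model`.
#' @param elety atom name to select (default `"CA"`).
#' @return Matrix (n x 3) of coordinates with rownames `chain:resno`.
#' @export
model_coords <- function(model, elety = "CA") {
  at <- model$atoms[model$atoms$elety == elety, , drop = FALSE]
  m <- as.matrix(at[, c("x", "y", "z")])
  rownames(m) <- paste0(at$chain, ":", at$resno)
  m
}

#' Apply a rigid transform to (part of) a model
#'
#' @param model a `xlcal_model`.
#' @param rotation 3x3 proper rotation matrix.
#' @param translation length-3 vector, Angstrom.
#' @param chains chains to transform (default: all).
#' @return The transformed model.
#' @export
transform_model <- function(model, rotation = diag(3),
                            translation = c(0, 0, 0), chains = NULL) {
  if (is.null(chains)) chains <- model_chains(model)
  sel <- model$atoms$chain %in% chains
  xyz <- as.matrix(model$atoms[sel, c("x", "y", "z")])
  xyz <- sweep(xyz %*% t(rotation), 2, translation, `+`)
  model$atoms[sel, c("x", "y", "z")] <- xyz
  model
}

#' One-letter sequence of each chain in a model
#'
#' @param model a `xlcal_model`.
#' @return Named list: per chain, a list with `seq` (one-letter string,
#'   non-standard residues as "X") and `resno` (author numbers).
#' @export
chain_sequences <- function(model) {
  out <- list()
  for (ch in model_chains(model)) {
    at <- model$atoms[model$atoms$chain == ch, , drop = FALSE]
    res <- unique(at[, c("resno", "insert", "resid")])
    out[[ch]] <- list(seq = paste(aa_3to1(res$resid), collapse = ""),
                      resno = res$resno)
  }
  out
}
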