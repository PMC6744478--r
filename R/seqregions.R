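#' Kyte-Doolittle hydropathy scale
#'
#' @return Named numeric vector over the 20 standard residues; positive
#'   is hydrophobic.
#' @export
kyte_doolittle <- function() {
  c(I = 4.5, V = 4.2, L = 3.8, F = 2.8, C = 2.5, M = 1.9, A = 1.8,
    G = -0.4, T = -0.7, S = -0.8, W = -0.9, Y = -1.3, P = -1.6,
    H = -3.2, E = -3.5, Q = -3.5, D = -3.5, N = -3.5, K = -3.9, R = -4.5)
}

# side-chain pKa values for the net-charge proxy (EMBOSS-style set)
.sidechain_pka <- c(D = 3.9, E = 4.1, H = 6.0, K = 10.5, R = 12.5)
.termini_pka <- c(nterm = 9.0, cterm = 2.35)

#' Read a multiple sequence alignment
#'
#' @param path aligned FASTA or Clustal file.
#' @param format `"fasta"` or `"clustal"`.
#' @return Named character vector of equal-length aligned sequences
#'   (uppercase, `-` for gaps).
#' @export
read_alignment <- function(path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  aln <- Biostrings::readAAMultipleAlignment(path, format = format)
  seqs <- toupper(as.character(Biostrings::unmasked(aln)))
  seqs <- gsub("\\.", "-", seqs)
  if (length(unique(nchar(seqs))) != 1) stop("ragged alignment")
  seqs
}

#' Find insert regions in a multiple sequence alignment
#'
#' An insert region is a maximal run of alignment columns, at least
#' `min_length` long, in which the same proper nonempty subset of
#' members is entirely gapped while the remaining members are occupied
#' (at least `min_occupancy` non-gap over the run). This is the pattern
#' of a sequence insertion present in some family members and absent in
#' others, e.g. a loop present in two paralogs of a four-member family.
#' Per-member coordinates of the insert are converted from alignment
#' columns to 1-based positions in the ungapped sequence.
#'
#' @param alignment named character vector of equal-length aligned
#'   sequences (see [read_alignment()]).
#' @param min_length minimum run length in columns (default 5).
#' @param min_occupancy minimum non-gap fraction for members carrying
#'   the insert (default 0.9).
#' @return List of insert regions; each is a list with `col_start`,
#'   `col_end` (alignment columns, inclusive), `members_with_insert`,
#'   `members_without`, and `regions` — a data.frame (protein, start,
#'   end, sequence) of per-member sequence coordinates.
#' @export
find_insert_regions <- function(alignment, min_length = 5,
                                min_occupancy = 0.9) {
  if (length(alignment) < 2) stop("need at least 2 aligned sequences")
  if (length(unique(nchar(alignment))) != 1) stop("ragged alignment")
  mat <- do.call(rbind, strsplit(alignment, ""))
  rownames(mat) <- names(alignment)
  ncolumns <- ncol(mat)
  gap <- mat == "-"
  # column signature: which members are gapped (proper nonempty subsets only)
  sig <- apply(gap, 2, function(g) {
    if (!any(g) || all(g)) "" else paste(which(g), collapse = ",")
  })
  out <- list()
  rl <- rle(sig)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1
  for (k in seq_along(rl$values)) {
    if (rl$values[k] == "" || rl$lengths[k] < min_length) next
    cols <- starts[k]:ends[k]
    without <- as.integer(strsplit(rl$values[k], ",")[[1]])
    with_ins <- setdiff(seq_len(nrow(mat)), without)
    occ <- rowMeans(!gap[with_ins, cols, drop = FALSE])
    if (any(occ < min_occupancy)) next
    regions <- do.call(rbind, lapply(with_ins, function(m) {
      # sequence position = count of non-gaps up to the column
      cum <- cumsum(!gap[m, ])
      nz <- cols[!gap[m, cols]]
      data.frame(protein = rownames(mat)[m],
                 start = cum[nz[1]], end = cum[nz[length(nz)]],
                 sequence = paste(mat[m, nz], collapse = ""),
                 stringsAsFactors = FALSE)
    }))
    out[[length(out) + 1]] <- list(
      col_start = starts[k], col_end = ends[k],
      members_with_insert = rownames(mat)[with_ins],
      members_without = rownames(mat)[without],
      regions = regions)
  }
  out
}

#' Sliding-window hydropathy profile
#'
#' Centered sliding-window mean of a per-residue hydropathy scale
#' (Kyte-Doolittle by default). Windows shrink at the termini so the
#' profile covers every residue.
#'
#' @param sequence uppercase amino-acid string.
#' @param window odd window size, at most the sequence length.
#' @param scale named per-residue scores.
#' @param on_nonstandard `"error"` (default) or `"skip"` (non-standard
#'   residues are dropped from window means).
#' @return Numeric vector, one score per residue.
#' @export
hydropathy_profile <- function(sequence, window = 9,
                               scale = kyte_doolittle(),
                               on_nonstandard = c("error", "skip")) {
  on_nonstandard <- match.arg(on_nonstandard)
  aa <- strsplit(sequence, "")[[1]]
  n <- length(aa)
  if (window %% 2 == 0) stop("window must be odd")
  if (window > n) stop("window exceeds sequence length")
  vals <- unname(scale[aa])
  if (anyNA(vals) && on_nonstandard == "error") {
    stop("non-standard residue(s): ",
         paste(unique(aa[is.na(vals)]), collapse = ", "))
  }
  half <- (window - 1) / 2
  vapply(seq_len(n), function(i) {
    w <- vals[max(1, i - half):min(n, i + half)]
    mean(w, na.rm = TRUE)
  }, numeric(1))
}

#' Net charge of a sequence region (Henderson-Hasselbalch proxy)
#'
#' Sums fractional side-chain charges of D, E, K, R and H at the given
#' pH. Terminal charges are off by default because regions of interest
#' are internal stretches, not free peptides. This is a sequence-level
#' proxy for electrostatic character, not a 3D potential map.
#'
#' @param sequence uppercase amino-acid string (may be empty).
#' @param pH solution pH (default 7.4).
#' @param include_termini add free N/C-terminus charges.
#' @return Net charge in elementary units.
#' @export
region_charge <- function(sequence, pH = 7.4, include_termini = FALSE) {
  if (!nzchar(sequence)) return(0)
  aa <- strsplit(sequence, "")[[1]]
  pos <- c("K", "R", "H"); neg <- c("D", "E")
  q <- 0
  for (res in aa) {
    if (res %in% pos) q <- q + 1 / (1 + 10^(pH - .sidechain_pka[[res]]))
    if (res %in% neg) q <- q - 1 / (1 + 10^(.sidechain_pka[[res]] - pH))
  }
  if (include_termini) {
    q <- q + 1 / (1 + 10^(pH - .termini_pka[["nterm"]]))
    q <- q - 1 / (1 + 10^(.termini_pka[["cterm"]] - pH))
  }
  unname(q)
}

#' Compare two sequence regions
#'
#' Reports the difference in mean hydropathy and net charge between two
#' regions plus their percent identity from a global pairwise alignment
#' (identical residues over alignment columns).
#'
#' @param region_a,region_b uppercase amino-acid strings.
#' @param pH pH for the charge proxy.
#' @return List: `hydropathy_delta` (a - b), `charge_delta` (a - b),
#'   `identity_pct`.
#' @export
compare_regions <- function(region_a, region_b, pH = 7.4) {
  if (!nzchar(region_a) || !nzchar(region_b)) stop("regions must be non-empty")
  mh <- function(s) mean(hydropathy_profile(s, window = 1))
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(region_a), Biostrings::AAString(region_b),
    substitutionMatrix = .identity_submat(), gapOpening = 10,
    gapExtension = 0.5, type = "global")
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  list(hydropathy_delta = mh(region_a) - mh(region_b),
       charge_delta = region_charge(region_a, pH) -
         region_charge(region_b, pH),
       identity_pct = 100 * sum(pat == sub & pat != "-") / length(pat))
}
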