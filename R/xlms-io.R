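#' Read protein sequences from FASTA
#'
#' @param path FASTA file.
#' @return Named character vector of uppercase sequences, in file order.
#' @export
read_fasta <- function(path) {
  aas <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(aas))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA identifier(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(aas))
  bad <- lapply(strsplit(seqs, ""), function(s) setdiff(unique(s), .aa1))
  offending <- unique(unlist(bad))
  if (length(offending) > 0) {
    stop("non-amino-acid character(s) in FASTA: ",
         paste(offending, collapse = ", "))
  }
  names(seqs) <- ids
  seqs
}

# canonical crosslink-table schema
.xl_required <- c("protein_a", "peptide_a", "link_pos_a",
                  "protein_b", "peptide_b", "link_pos_b")
.xl_optional <- c("charge", "psm_id", "score", "qvalue")

#' Read a crosslink identification table
#'
#' Reads a delimited PSM-level crosslink table (one row per
#' peptide-spectrum match). The canonical schema is
#' `protein_a,peptide_a,link_pos_a,protein_b,peptide_b,link_pos_b,
#' charge,psm_id,score,qvalue`; third-party exports are adapted with
#' `dialect`, a named character vector mapping canonical names to the
#' file's column names. Link positions are 1-based indices in the full
#' protein sequence. Rows with non-positive or non-integer positions are
#' dropped and reported, not fatal; rows above `qvalue_max` (if set) are
#' dropped likewise — upstream search pipelines typically already filter
#' at 1% FDR, so the default keeps all rows.
#'
#' @param path CSV (or TSV, by extension) file with a header.
#' @param dialect named character vector, canonical -> file column.
#' @param qvalue_max optional q-value cutoff in \[0, 1\].
#' @return data.frame of PSM records (class `xlcal_xl_records`) with an
#'   attribute `rejected` holding the dropped rows and reasons.
#' @export
read_crosslink_table <- function(path, dialect = NULL, qvalue_max = NULL) {
  sep <- if (grepl("\\.tsv$|\\.txt$", path)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(dialect)) {
    for (canon in names(dialect)) {
      if (!dialect[[canon]] %in% names(raw)) {
        stop("dialect maps '", canon, "' to missing column '",
             dialect[[canon]], "'")
      }
      names(raw)[names(raw) == dialect[[canon]]] <- canon
    }
  }
  missing_cols <- setdiff(.xl_required, names(raw))
  if (length(missing_cols) > 0) {
    stop("crosslink table lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in .xl_optional) if (!col %in% names(raw)) raw[[col]] <- NA
  if (is.null(raw$psm_id) || all(is.na(raw$psm_id))) {
    raw$psm_id <- sprintf("psm%04d", seq_len(nrow(raw)))
  }
  rec <- raw[, c(.xl_required, .xl_optional)]

  pos_a <- suppressWarnings(as.numeric(rec$link_pos_a))
  pos_b <- suppressWarnings(as.numeric(rec$link_pos_b))
  ok_pos <- !is.na(pos_a) & !is.na(pos_b) &
    pos_a >= 1 & pos_b >= 1 & pos_a == round(pos_a) & pos_b == round(pos_b)
  reasons <- ifelse(ok_pos, NA_character_, "invalid link position")
  ok_q <- rep(TRUE, nrow(rec))
  if (!is.null(qvalue_max)) {
    ok_q <- is.na(rec$qvalue) | rec$qvalue <= qvalue_max
    reasons[ok_pos & !ok_q] <- "q-value above threshold"
  }
  keep <- ok_pos & ok_q
  rejected <- cbind(rec[!keep, , drop = FALSE],
                    reason = reasons[!keep])
  if (nrow(rejected) > 0) {
    message(nrow(rejected), " row(s) dropped (",
            paste(unique(rejected$reason), collapse = "; "), ")")
  }
  rec <- rec[keep, , drop = FALSE]
  rec$link_pos_a <- as.integer(pos_a[keep])
  rec$link_pos_b <- as.integer(pos_b[keep])
  rownames(rec) <- NULL
  attr(rec, "rejected") <- rejected
  class(rec) <- c("xlcal_xl_records", "data.frame")
  rec
}

#' Locate a peptide within a protein sequence
#'
#' Returns every 1-based start offset at which `peptide` occurs as an
#' exact substring of `protein_seq`, including overlapping occurrences.
#' An empty result means the peptide is absent; the caller decides how to
#' treat multiple placements (ambiguous placements are never guessed).
#'
#' @param peptide uppercase amino-acid string.
#' @param protein_seq uppercase amino-acid string.
#' @return Integer vector of start offsets (possibly empty).
#' @export
map_peptide_to_sequence <- function(peptide, protein_seq) {
  if (!nzchar(peptide)) stop("peptide must be non-empty")
  hits <- gregexpr(paste0("(?=", peptide, ")"), protein_seq,
                   perl = TRUE)[[1]]
  if (hits[1] == -1) integer(0) else as.integer(hits)
}

#' Deduplicate PSM records into unique residue pairs
#'
#' Crosslinked pairs are typically identified by multiple PSMs, often at
#' different charge states; this collapses the PSM-level table to unique
#' lysine-lysine residue pairs. Each pair is canonically ordered
#' ((protein_a, pos_a) <= (protein_b, pos_b)) so both reported
#' orientations of a link merge, classified intra/inter, and annotated
#' with its supporting PSM count and the set of charge states seen.
#'
#' @param records records from [read_crosslink_table()] (or any
#'   data.frame with the canonical columns).
#' @param sequences optional named sequences (from [read_fasta()]); when
#'   supplied, link positions are validated against protein length and,
#'   in strict mode, required to be lysine.
#' @param strict_lysine reject links not on K when sequences are given
#'   (default FALSE: N-terminus links and the like are tolerated).
#' @return data.frame (class `xlcal_pairs`) with columns `protein_a`,
#'   `pos_a`, `protein_b`, `pos_b`, `kind`, `psm_count`, `charges_seen`
#'   (comma-joined, sorted), sorted by (protein_a, pos_a, protein_b,
#'   pos_b); attribute `excluded` holds records dropped by validation.
#' @export
dedupe_to_residue_pairs <- function(records, sequences = NULL,
                                    strict_lysine = FALSE) {
  rec <- as.data.frame(records)
  excluded <- rec[0, ]
  if (!is.null(sequences) && nrow(rec) > 0) {
    ok <- rep(TRUE, nrow(rec))
    for (i in seq_len(nrow(rec))) {
      for (side in c("a", "b")) {
        prot <- rec[[paste0("protein_", side)]][i]
        pos <- rec[[paste0("link_pos_", side)]][i]
        if (!prot %in% names(sequences)) next
        s <- sequences[[prot]]
        if (pos > nchar(s)) {
          ok[i] <- FALSE
        } else if (strict_lysine && substr(s, pos, pos) != "K") {
          ok[i] <- FALSE
        }
      }
    }
    excluded <- rec[!ok, , drop = FALSE]
    if (nrow(excluded) > 0) {
      message(nrow(excluded),
              " record(s) excluded by sequence validation")
    }
    rec <- rec[ok, , drop = FALSE]
  }
  if (nrow(rec) == 0) {
    out <- data.frame(protein_a = character(0), pos_a = integer(0),
                      protein_b = character(0), pos_b = integer(0),
                      kind = character(0), psm_count = integer(0),
                      charges_seen = character(0))
    attr(out, "excluded") <- excluded
    class(out) <- c("xlcal_pairs", "data.frame")
    return(out)
  }
  # canonical orientation: (protein_a, pos_a) <= (protein_b, pos_b)
  swap <- rec$protein_b < rec$protein_a |
    (rec$protein_b == rec$protein_a & rec$link_pos_b < rec$link_pos_a)
  tmp <- rec[swap, ]
  rec[swap, c("protein_a", "peptide_a", "link_pos_a")] <-
    tmp[, c("protein_b", "peptide_b", "link_pos_b")]
  rec[swap, c("protein_b", "peptide_b", "link_pos_b")] <-
    tmp[, c("protein_a", "peptide_a", "link_pos_a")]

  key <- paste(rec$protein_a, rec$link_pos_a,
               rec$protein_b, rec$link_pos_b, sep = "\r")
  grp <- split(seq_len(nrow(rec)), key)
  rows <- lapply(grp, function(idx) {
    r1 <- rec[idx[1], ]
    ch <- sort(unique(stats::na.omit(rec$charge[idx])))
    data.frame(protein_a = r1$protein_a, pos_a = r1$link_pos_a,
               protein_b = r1$protein_b, pos_b = r1$link_pos_b,
               kind = if (r1$protein_a == r1$protein_b) "intra" else "inter",
               psm_count = length(idx),
               charges_seen = paste(ch, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$protein_a, out$pos_a, out$protein_b, out$pos_b), ]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  class(out) <- c("xlcal_pairs", "data.frame")
  out
}

#' Write / read unique residue pairs as CSV
#'
#' @param pairs a `xlcal_pairs` data.frame.
#' @param path output CSV path.
#' @return `path` invisibly; `read_residue_pairs` returns the pairs.
#' @export
write_residue_pairs <- function(pairs, path) {
  utils::write.csv(as.data.frame(pairs), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_residue_pairs
#' @export
read_residue_pairs <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(charges_seen = "character"))
  class(out) <- c("xlcal_pairs", "data.frame")
  out
}
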