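#' Read nucleotide sequences from a FASTA file
#'
#' Reads a FASTA file into a tibble of sequence records. Sequences are
#' validated against the nucleotide alphabet `A, C, G, T, U, N` (case
#' insensitive) and normalized to DNA: `U` is rewritten to `T`, lower case to
#' upper case. RNA input is therefore accepted transparently; set
#' `keep_alphabet = TRUE` to remember which records arrived as RNA so
#' [write_fasta()] can restore the original alphabet.
#'
#' @param path Path to a FASTA file.
#' @param keep_alphabet If `TRUE`, add an `alphabet` column (`"DNA"` or
#'   `"RNA"`) recording the alphabet each record arrived in.
#' @return A tibble with columns `id` (first whitespace-delimited token of the
#'   header), `residues` (normalized DNA string) and `description` (remainder
#'   of the header, possibly empty). One row per FASTA entry, input order
#'   preserved. An empty file yields a zero-row tibble.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">x some 16S gene", "ACGU"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path, keep_alphabet = FALSE) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file does not exist: ", path))
  }
  if (file.size(path) == 0) {
    out <- tibble(id = character(), residues = character(),
                  description = character())
    if (keep_alphabet) out$alphabet <- character()
    return(out)
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(paste0("Malformed FASTA file '", path, "': ",
                                     conditionMessage(e)))
  )
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  raw <- toupper(as.character(set))
  bad <- grepl("[^ACGTUN]", raw)
  if (any(bad)) {
    i <- which(bad)[1]
    sym <- stringr::str_extract(raw[i], "[^ACGTUN]")
    abort(paste0(
      "Disallowed residue '", sym, "' in record '", ids[i],
      "' (FASTA line ", .fasta_offending_line(path, ids[i], sym), ")"
    ))
  }
  if (any(!nzchar(raw))) {
    abort(paste0("Empty sequence for record '", ids[which(!nzchar(raw))[1]], "'"))
  }
  if (anyDuplicated(ids)) {
    abort(paste0("Duplicated sequence id within file: '",
                 ids[duplicated(ids)][1], "'"))
  }
  out <- tibble(
    id = unname(ids),
    residues = unname(gsub("U", "T", raw, fixed = TRUE)),
    description = unname(desc)
  )
  if (keep_alphabet) {
    out$alphabet <- ifelse(grepl("U", raw, fixed = TRUE), "RNA", "DNA")
  }
  out
}

# locate the file line carrying the first disallowed symbol of a record,
# so parse errors point at the offending input line
.fasta_offending_line <- function(path, id, sym) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^>", lines)
  rec <- which(sub("\\s.*$", "", sub("^>", "", lines[starts])) == id)[1]
  if (is.na(rec)) return(NA_integer_)
  from <- starts[rec]
  to <- if (rec < length(starts)) starts[rec + 1] - 1 else length(lines)
  body <- seq(from + 1, to)
  hit <- body[grepl(sym, toupper(lines[body]), fixed = TRUE)]
  if (length(hit)) hit[1] else NA_integer_
}

#' Write sequence records to a FASTA file
#'
#' @param seqs A tibble with columns `id`, `residues` and optionally
#'   `description` and `alphabet` (as produced by [read_fasta()]). When
#'   `alphabet` is present and `restore_alphabet = TRUE`, records flagged
#'   `"RNA"` are written with `T` transcribed back to `U`.
#' @param path Output file path.
#' @param restore_alphabet Restore the original RNA alphabet where recorded.
#' @param width Line width for wrapped sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, restore_alphabet = TRUE, width = 70L) {
  stopifnot(is.data.frame(seqs), all(c("id", "residues") %in% names(seqs)))
  res <- seqs$residues
  if (restore_alphabet && "alphabet" %in% names(seqs)) {
    rna <- seqs$alphabet == "RNA"
    res[rna] <- gsub("T", "U", res[rna], fixed = TRUE)
  }
  desc <- if ("description" %in% names(seqs)) seqs$description else ""
  hdr <- ifelse(nzchar(desc), paste(seqs$id, desc), seqs$id)
  set <- Biostrings::BStringSet(setNames(res, hdr))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

# accept a single sequence as a bare string, a one-row record tibble, or an
# (id, residues) pair; returns list(id=, residues=)
.as_seqrec <- function(x, default_id = "seq") {
  if (is.character(x) && length(x) == 1) {
    return(list(id = default_id, residues = toupper(gsub("U", "T", x))))
  }
  if (is.data.frame(x)) {
    if (nrow(x) != 1) abort("Expected exactly one sequence record")
    return(list(id = x$id[[1]], residues = x$residues[[1]]))
  }
  if (is.list(x) && all(c("id", "residues") %in% names(x))) {
    return(x[c("id", "residues")])
  }
  abort("Sequence must be a string or a one-row record tibble")
}
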