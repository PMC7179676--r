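ALIGN_CHARS <- c(AA20, "-", "X", "?")

#' Read a sequence set from FASTA
#'
#' '?' and 'X' are preserved verbatim. Metadata is parsed from headers that
#' follow the \code{id|species|order|family|signal_end|complete} dialect;
#' other headers are kept whole as the id.
#'
#' @param path FASTA file.
#' @param expect_aligned Require all sequences to be of equal length.
#' @return A \code{sequence_set}: list with \code{ids}, \code{seqs} (named
#'   character vector), \code{meta} (data.frame) and \code{aligned}.
#' @export
read_sequences <- function(path, expect_aligned = FALSE) {
  raw <- Biostrings::readBStringSet(path)
  seqs <- as.character(raw)
  for (i in seq_along(seqs)) {
    chars <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    bad <- which(!chars %in% ALIGN_CHARS)
    if (length(bad))
      stop(sprintf("record '%s': illegal character '%s' at position %d",
                   names(seqs)[i], chars[bad[1]], bad[1]), call. = FALSE)
  }
  new_sequence_set(seqs, names(raw), expect_aligned = expect_aligned)
}

new_sequence_set <- function(seqs, headers, expect_aligned = FALSE) {
  lens <- nchar(seqs)
  aligned <- length(unique(lens)) <= 1L
  if (expect_aligned && !aligned)
    stop(sprintf("ragged aligned input: row lengths %s",
                 paste(lens, collapse = ", ")), call. = FALSE)
  fields <- strsplit(headers, "|", fixed = TRUE)
  dialect <- all(lengths(fields) == 6L)
  meta <- if (dialect) {
    data.frame(id = vapply(fields, `[[`, "", 1L),
               species = vapply(fields, `[[`, "", 2L),
               taxon_order = vapply(fields, `[[`, "", 3L),
               family_id = vapply(fields, `[[`, "", 4L),
               signal_end = as.integer(vapply(fields, `[[`, "", 5L)),
               complete = as.logical(vapply(fields, `[[`, "", 6L)),
               stringsAsFactors = FALSE)
  } else {
    data.frame(id = headers, stringsAsFactors = FALSE)
  }
  names(seqs) <- headers
  structure(list(ids = meta$id, seqs = seqs, meta = meta, aligned = aligned),
            class = "sequence_set")
}

#' Write a sequence set to FASTA
#'
#' Inverse of \code{\link{read_sequences}}: writing then reading reproduces
#' the records.
#'
#' @param seqset A \code{sequence_set}.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_sequences <- function(seqset, path) {
  x <- Biostrings::BStringSet(seqset$seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Split a sequence set by taxon group
#'
#' @param seqset A \code{sequence_set} whose headers follow the precursor
#'   dialect (so \code{taxon_order} metadata is available).
#' @return Named list of per-group \code{sequence_set}s.
#' @export
split_by_group <- function(seqset) {
  if (is.null(seqset$meta$taxon_order))
    stop("sequence set has no taxon_order metadata", call. = FALSE)
  idx <- split(seq_along(seqset$seqs), seqset$meta$taxon_order)
  lapply(idx, function(i)
    new_sequence_set(unname(seqset$seqs[i]), names(seqset$seqs)[i]))
}

#' Build an MSA character matrix
#'
#' @param seqset A \code{sequence_set} with equal-length rows, or a named
#'   character vector of aligned sequences.
#' @return Character matrix (rows = sequences, columns = alignment sites),
#'   class \code{msa}.
#' @export
as_msa <- function(seqset) {
  seqs <- if (inherits(seqset, "sequence_set")) seqset$seqs else seqset
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L)
    stop(sprintf("cannot build MSA from ragged sequences: row lengths %s",
                 paste(lens, collapse = ", ")), call. = FALSE)
  m <- do.call(rbind, strsplit(unname(seqs), "", fixed = TRUE))
  rownames(m) <- names(seqs)
  structure(m, class = c("msa", "matrix", "array"))
}

msa_strings <- function(msa) apply(unclass(msa), 1L, paste, collapse = "")

#' Merge several alignments
#'
#' With a \code{realign_hook}, all rows are degapped, concatenated into one
#' FASTA and re-aligned by the external command; without a hook the input
#' alignments are stacked after padding to a common width with terminal gaps
#' (a documented approximation that keeps within-block columns intact).
#'
#' @param msas List of \code{msa} matrices.
#' @param realign_hook Optional external aligner command template containing
#'   \code{{in}} and \code{{out}} placeholders, e.g.
#'   \code{"mafft --auto {in} > {out}"}. The hook must read FASTA and write
#'   aligned FASTA.
#' @return A single \code{msa}.
#' @export
merge_alignments <- function(msas, realign_hook = NULL) {
  stopifnot(length(msas) >= 1L)
  if (length(msas) == 1L && is.null(realign_hook)) return(msas[[1]])
  if (!is.null(realign_hook)) {
    seqs <- unlist(lapply(msas, function(m) {
      s <- msa_strings(m)
      gsub("-", "", s, fixed = TRUE)
    }))
    fin <- tempfile(fileext = ".fa"); fout <- tempfile(fileext = ".fa")
    on.exit(unlink(c(fin, fout)), add = TRUE)
    Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), fin)
    cmd <- gsub("{in}", shQuote(fin), realign_hook, fixed = TRUE)
    cmd <- gsub("{out}", shQuote(fout), cmd, fixed = TRUE)
    status <- system(paste(cmd, "2> /dev/null"))
    if (status != 0L || !file.exists(fout) || file.size(fout) == 0)
      stop(sprintf("realign hook failed (exit status %d): %s", status, cmd),
           call. = FALSE)
    return(as_msa(read_sequences(fout, expect_aligned = TRUE)))
  }
  width <- max(vapply(msas, ncol, 0L))
  padded <- lapply(msas, function(m) {
    if (ncol(m) < width)
      m <- cbind(unclass(m),
                 matrix("-", nrow(m), width - ncol(m)))
    unclass(m)
  })
  out <- do.call(rbind, padded)
  structure(out, class = c("msa", "matrix", "array"))
}

#' Map ungapped coordinates to alignment columns
#'
#' @param row Character vector or string of one aligned row (with gaps).
#' @param start,end 0-based half-open coordinates in the ungapped sequence.
#' @return Integer vector of 1-based alignment column indices.
#' @export
ungapped_to_columns <- function(row, start, end) {
  chars <- if (length(row) == 1L) strsplit(row, "", fixed = TRUE)[[1]] else row
  resident <- which(chars != "-")
  if (end > length(resident))
    stop(sprintf("coordinates [%d,%d) exceed ungapped length %d",
                 start, end, length(resident)), call. = FALSE)
  if (end <= start) return(integer())
  resident[(start + 1L):end]
}

#' Slice the mature-peptide columns out of an alignment
#'
#' Maps each row's ungapped core coordinates through its gaps and keeps every
#' column covered by at least one row's core (union rule, so indels inside
#' peptides are preserved).
#'
#' @param msa An \code{msa}.
#' @param cores data.frame with columns \code{row} (row index or name),
#'   \code{start}, \code{end}: 0-based half-open coordinates in each row's
#'   ungapped sequence.
#' @return The sub-alignment \code{msa} restricted to covered columns.
#' @export
slice_peptide_columns <- function(msa, cores) {
  if (is.null(cores) || nrow(cores) == 0L)
    stop("no peptide coordinates supplied", call. = FALSE)
  m <- unclass(msa)
  idx <- if (is.character(cores$row)) match(cores$row, rownames(m)) else cores$row
  cols <- sort(unique(unlist(lapply(seq_len(nrow(cores)), function(i) {
    ungapped_to_columns(m[idx[i], ], cores$start[i], cores$end[i])
  }))))
  structure(m[, cols, drop = FALSE], class = c("msa", "matrix", "array"))
}
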