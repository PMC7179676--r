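# Sequence-logo statistics, consensus sequences, and ancestral-depth
# assignment. Logo information content per column is
# info = log2(20) - H(freqs) in bits, over non-gap characters ('-', 'X' and
# '?' all count as gaps). No small-sample correction is applied by default
# (closed forms stay exact); an approximate correction is available via
# small_sample_correction.

#' Per-column sequence-logo statistics
#'
#' @param msa An \code{msa} (or character matrix).
#' @param small_sample_correction Subtract the approximate small-sample bias
#'   e_n = (20 - 1) / (2 ln(2) n) from the information content (floored at
#'   0), where n is the number of non-gap residues in the column.
#' @return data.frame with one row per (column, residue): \code{position}
#'   (0-based column), \code{residue}, \code{freq}, \code{height}
#'   (freq * info), plus per-column \code{info} (bits) and
#'   \code{gap_fraction}. All-gap columns yield a single row with residue NA
#'   and info 0.
#' @export
compute_logo <- function(msa, small_sample_correction = FALSE) {
  m <- unclass(msa)
  stopifnot(is.matrix(m), nrow(m) >= 1L)
  max_info <- log2(20)
  out <- lapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    is_gap <- col %in% AMBIGUOUS
    gap_fraction <- mean(is_gap)
    res <- col[!is_gap]
    if (!length(res))
      return(data.frame(position = j - 1L, residue = NA_character_,
                        freq = NA_real_, height = 0, info = 0,
                        gap_fraction = 1, stringsAsFactors = FALSE))
    freqs <- table(res) / length(res)
    H <- -sum(freqs * log2(freqs))
    info <- max_info - H
    if (small_sample_correction)
      info <- max(0, info - (20 - 1) / (2 * log(2) * length(res)))
    data.frame(position = j - 1L, residue = names(freqs),
               freq = as.numeric(freqs), height = as.numeric(freqs) * info,
               info = info, gap_fraction = gap_fraction,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Consensus sequence with ambiguity masking
#'
#' Per column, the plurality non-gap residue is emitted if its fraction of
#' non-gap characters reaches \code{threshold}; otherwise (including ties and
#' all-gap columns) a lowercase 'x' is written.
#'
#' @param msa An \code{msa}.
#' @param threshold Minimum plurality fraction, in [0.5, 1].
#' @return A \code{consensus_result}: list with \code{sequence},
#'   \code{threshold} and per-position winning fraction \code{support}.
#' @export
consensus_sequence <- function(msa, threshold = 0.5) {
  m <- unclass(msa)
  if (!is.matrix(m) || nrow(m) == 0L) stop("empty alignment", call. = FALSE)
  if (threshold < 0.5 || threshold > 1)
    stop("threshold must lie in [0.5, 1]", call. = FALSE)
  support <- numeric(ncol(m))
  chars <- character(ncol(m))
  for (j in seq_len(ncol(m))) {
    res <- m[, j][!m[, j] %in% AMBIGUOUS]
    if (!length(res)) { chars[j] <- "x"; support[j] <- 0; next }
    tab <- sort(table(res), decreasing = TRUE)
    frac <- tab[1] / length(res)
    tie <- length(tab) > 1L && tab[2] == tab[1]
    support[j] <- frac
    chars[j] <- if (!tie && frac >= threshold) names(tab)[1] else "x"
  }
  structure(list(sequence = paste(chars, collapse = ""),
                 threshold = threshold, support = support),
            class = "consensus_result")
}

DEPTH_LEVELS <- c("undetermined", "Polyneoptera", "Pterygota", "Hexapoda")

#' Assign the ancestral depth of a candidate peptide
#'
#' Presence/absence reasoning over taxon groups and outgroups, after exact
#' string matching of the candidate (PTM flags ignored): a hit in Remipedia
#' (or any deeper outgroup such as Myriapoda or Malacostraca) implies the
#' sequence was present in the hexapod ancestor; a Zygentoma (silverfish)
#' hit implies the pterygote ancestor; with no outgroup hit but presence in
#' at least \code{min_orders} polyneopteran orders the sequence is called
#' ancestral for Polyneoptera; anything less is undetermined.
#'
#' @param candidate Peptide residue string (non-empty).
#' @param occurrence Named logical vector: presence per analyzed order.
#' @param outgroups Named logical vector over outgroup labels; names matched
#'   case-insensitively against "zygentoma", "remipedia"; any other name
#'   counts as a deeper, pre-hexapod outgroup.
#' @param min_orders Minimum number of orders with the candidate present
#'   (default 5, an interpretation of "found in most orders" — configurable).
#' @return An \code{ancestral_call}: list with \code{peptide},
#'   \code{orders_present}, \code{outgroup_hits}, \code{depth},
#'   \code{pre_hexapod} (hit in an outgroup deeper than Remipedia) and
#'   \code{min_orders}.
#' @export
assign_ancestral_depth <- function(candidate, occurrence,
                                   outgroups = logical(), min_orders = 5L) {
  if (!is.character(candidate) || !nzchar(candidate))
    stop("empty candidate peptide", call. = FALSE)
  orders_present <- names(occurrence)[as.logical(occurrence)]
  hits <- names(outgroups)[as.logical(outgroups)]
  key <- tolower(hits)
  deeper <- hits[!key %in% c("zygentoma", "remipedia")]
  has_remipedia <- any(key == "remipedia") || length(deeper) > 0L
  has_zygentoma <- any(key == "zygentoma")
  depth <- if (length(orders_present) < min_orders) {
    "undetermined"
  } else if (has_remipedia) {
    "Hexapoda"
  } else if (has_zygentoma) {
    "Pterygota"
  } else {
    "Polyneoptera"
  }
  structure(list(peptide = candidate, orders_present = orders_present,
                 outgroup_hits = hits, depth = depth,
                 pre_hexapod = length(deeper) > 0L,
                 min_orders = as.integer(min_orders)),
            class = "ancestral_call")
}

#' @export
print.ancestral_call <- function(x, ...) {
  cat(sprintf("<ancestral_call> %s\n  depth: %s (present in %d orders; outgroups: %s; min_orders=%d)\n",
              x$peptide, x$depth, length(x$orders_present),
              if (length(x$outgroup_hits)) paste(x$outgroup_hits, collapse = ", ") else "none",
              x$min_orders))
  invisible(x)
}

#' Export logo stacks as a plain table
#'
#' @param logo Output of \code{\link{compute_logo}}.
#' @param path TSV output path.
#' @return \code{path}, invisibly.
#' @export
write_logo_tsv <- function(logo, path) {
  utils::write.table(format_num(logo), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# fixed 5-decimal rendering for all floating-point columns of a table
format_num <- function(df) {
  for (k in seq_along(df))
    if (is.double(df[[k]])) df[[k]] <- sprintf("%.5f", df[[k]])
  df
}
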