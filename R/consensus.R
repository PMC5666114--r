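# Consensus protein design: redundancy filtering of an alignment to a
# maximum pairwise identity, majority-rule consensus, conservation profile.

#' Read and write aligned FASTA alignments
#'
#' An alignment is a tibble with columns `id` and `seq` (aligned sequences
#' over the 20 amino acids, gap `-` and unknown `X`, all the same length).
#'
#' @param path FASTA file path.
#' @param msa MSA tibble.
#' @return `read_msa` returns an MSA tibble.
#' @export
read_msa <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  out <- tibble(id = names(ss), seq = as.character(ss))
  validate_msa(out)
  out
}

#' @rdname read_msa
#' @export
write_msa <- function(msa, path) {
  validate_msa(msa)
  ss <- Biostrings::AAStringSet(stats::setNames(msa$seq, msa$id))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

validate_msa <- function(msa) {
  if (!all(c("id", "seq") %in% names(msa))) abort("MSA needs columns `id` and `seq`.")
  if (anyDuplicated(msa$id)) abort("MSA ids must be unique.")
  if (nrow(msa) && length(unique(nchar(msa$seq))) != 1) {
    abort("All aligned sequences must have equal length.")
  }
  invisible(msa)
}

msa_matrix <- function(msa) {
  do.call(rbind, strsplit(toupper(msa$seq), ""))
}

#' Pairwise sequence identity of two aligned sequences
#'
#' Identity = matching columns / columns where at least one sequence has a
#' residue; columns where both are gapped are excluded from the denominator.
#'
#' @param a,b Aligned sequences (equal length).
#' @return Fraction in \[0, 1\].
#' @examples
#' pairwise_identity("AA--", "AAC-")  # 2 matches / 3 counted columns
#' @export
pairwise_identity <- function(a, b) {
  va <- strsplit(toupper(a), "")[[1]]
  vb <- strsplit(toupper(b), "")[[1]]
  if (length(va) != length(vb)) {
    abort(sprintf("Sequence lengths differ (%d vs %d).", length(va), length(vb)))
  }
  counted <- !(va == "-" & vb == "-")
  if (!any(counted)) return(0)
  sum(va == vb & counted) / sum(counted)
}

#' Filter an alignment to a maximum pairwise identity
#'
#' Greedy scan in input order: a sequence is kept iff its identity to every
#' already-kept sequence is at most `threshold`. The output therefore has
#' all pairwise identities <= threshold. (Filtering an alignment down to
#' 90% maximum identity removes near-duplicates before consensus building.)
#'
#' @param msa MSA tibble.
#' @param threshold Maximum allowed pairwise identity in (0, 1\].
#' @return Filtered MSA tibble (attribute `n_removed`).
#' @export
filter_max_identity <- function(msa, threshold = 0.9) {
  validate_msa(msa)
  stopifnot(threshold > 0, threshold <= 1)
  kept <- integer(0)
  for (i in seq_len(nrow(msa))) {
    ok <- TRUE
    for (j in kept) {
      if (pairwise_identity(msa$seq[i], msa$seq[j]) > threshold) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  out <- msa[kept, , drop = FALSE]
  attr(out, "n_removed") <- nrow(msa) - length(kept)
  out
}

TIE_ORDER <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

#' Majority-rule consensus of an alignment
#'
#' Per column, the most frequent residue among non-gap symbols; the support
#' of a column is the fraction of *all* sequences carrying the consensus
#' residue. Under `gap_majority_rule = "drop"` (default), columns where gaps
#' are the absolute majority are dropped from the consensus; all-gap columns
#' are always dropped with a warning. Frequency ties are broken by a fixed
#' residue order (`ARNDCQEGHILKMFPSTWYV`) and flagged so designed sequences
#' are auditable.
#'
#' @param msa MSA tibble (>= 2 sequences).
#' @param gap_majority_rule `"drop"` or `"keep"`.
#' @return Object of class `consensus_result`: `consensus` (ungapped
#'   string), `profile` (tibble `column`, `residue`, `support`, `tie`),
#'   `kept_columns`, `tie_columns`, `dropped_columns`.
#' @export
consensus_sequence <- function(msa, gap_majority_rule = c("drop", "keep")) {
  validate_msa(msa)
  gap_majority_rule <- match.arg(gap_majority_rule)
  if (nrow(msa) < 2) abort("Consensus needs at least 2 sequences.")
  m <- msa_matrix(msa)
  n <- nrow(m)
  L <- ncol(m)
  res <- character(L); support <- numeric(L); tie <- logical(L); keep <- logical(L)
  n_allgap <- 0L
  for (j in seq_len(L)) {
    col <- m[, j]
    residues <- col[col != "-"]
    if (!length(residues)) { n_allgap <- n_allgap + 1L; next }
    if (gap_majority_rule == "drop" && sum(col == "-") > n / 2) next
    cnt <- table(residues)
    top <- max(cnt)
    winners <- names(cnt)[cnt == top]
    pick <- if (length(winners) > 1) {
      tie[j] <- TRUE
      ord <- match(winners, TIE_ORDER)
      ord[is.na(ord)] <- length(TIE_ORDER) + 1L
      winners[which.min(ord)]
    } else winners
    res[j] <- pick
    support[j] <- sum(col == pick) / n
    keep[j] <- TRUE
  }
  if (n_allgap > 0) warn(sprintf("%d all-gap column(s) dropped.", n_allgap))
  kept <- which(keep)
  structure(list(
    consensus = paste(res[kept], collapse = ""),
    profile = tibble(column = kept, residue = res[kept],
                     support = support[kept], tie = tie[kept]),
    kept_columns = kept,
    tie_columns = which(tie),
    dropped_columns = which(!keep)), class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("<consensus_result> %d residues (%d column(s) dropped, %d tie(s))\n",
              nchar(x$consensus), length(x$dropped_columns), length(x$tie_columns)))
  cat(sprintf("mean support %.3f\n", mean(x$profile$support)))
  invisible(x)
}

#' @export
tidy.consensus_result <- function(x, ...) x$profile

#' @export
glance.consensus_result <- function(x, ...) {
  tibble(length = nchar(x$consensus), mean_support = mean(x$profile$support),
         n_dropped = length(x$dropped_columns), n_ties = length(x$tie_columns))
}

#' Per-column conservation profile of an alignment
#'
#' The support fraction of the consensus residue in each kept column —
#' the quantity rendered as grayscale conservation shading along a designed
#' consensus sequence.
#'
#' @param msa MSA tibble.
#' @param ... Passed to [consensus_sequence()].
#' @return Tibble with `column`, `residue`, `support`.
#' @export
conservation_profile <- function(msa, ...) {
  consensus_sequence(msa, ...)$profile[, c("column", "residue", "support")]
}

#' @export
autoplot.consensus_result <- function(object, ...) {
  ggplot2::ggplot(object$profile,
                  ggplot2::aes(x = .data$column, y = 1, fill = .data$support)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "grey20", limits = c(0, 1)) +
    ggplot2::labs(x = "alignment column", y = NULL, fill = "support",
                  title = "Consensus conservation profile") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
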