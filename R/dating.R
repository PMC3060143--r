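#' Kimura two-parameter distance between aligned sequences
#'
#' Computes the transition proportion P, transversion proportion Q and the
#' K2P-corrected distance
#' \deqn{K = -\tfrac{1}{2}\ln(1 - 2P - Q) - \tfrac{1}{4}\ln(1 - 2Q)}
#' over the aligned columns in which both sequences carry an unambiguous
#' base (pairwise deletion of gap and ambiguity columns; ambiguity codes
#' are never counted as differences).
#'
#' @param seq_a,seq_b Aligned nucleotide sequences (equal length; `-` for
#'   gaps).
#' @param min_sites Minimum usable columns for a valid estimate.
#' @return A `k2p_result`: list with `P`, `Q`, `K`, `n_sites`, `valid`.
#'   `valid` is `FALSE` (with `K = NA`) when a log argument is
#'   non-positive (saturation) or fewer than `min_sites` columns are
#'   usable.
#' @export
k2p_distance <- function(seq_a, seq_b, min_sites = 50L) {
  if (nchar(seq_a) != nchar(seq_b))
    stop("sequences must be aligned to equal length")
  a <- seq_chars(toupper(seq_a))
  b <- seq_chars(toupper(seq_b))
  use <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  a <- a[use]; b <- b[use]
  n <- length(a)
  if (n == 0L)
    return(structure(list(P = NA_real_, Q = NA_real_, K = NA_real_,
                          n_sites = 0L, valid = FALSE),
                     class = "k2p_result"))
  diff <- a != b
  is_ts <- diff & ((a %in% c("A", "G") & b %in% c("A", "G")) |
                     (a %in% c("C", "T") & b %in% c("C", "T")))
  P <- sum(is_ts) / n
  Q <- sum(diff & !is_ts) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  valid <- n >= min_sites && w1 > 0 && w2 > 0
  K <- if (w1 > 0 && w2 > 0) -0.5 * log(w1) - 0.25 * log(w2) else NA_real_
  structure(list(P = P, Q = Q, K = K, n_sites = n, valid = valid),
            class = "k2p_result")
}

#' @export
print.k2p_result <- function(x, ...) {
  cat(sprintf("<k2p> P=%.4g Q=%.4g K=%s over %d sites (%s)\n", x$P, x$Q,
              if (is.na(x$K)) "NA" else sprintf("%.4g", x$K), x$n_sites,
              if (x$valid) "valid" else "invalid"))
  invisible(x)
}

# Deterministic global (Needleman-Wunsch, affine) alignment of two
# nucleotide sequences; returns the two gapped strings.
align_global <- function(seq_a, seq_b, match = 1, mismatch = -1,
                         gap_open = 4, gap_extend = 1) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = FALSE)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(seq_a), Biostrings::DNAString(seq_b),
    type = "global", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend)
  list(a = as.character(Biostrings::alignedPattern(al)),
       b = as.character(Biostrings::alignedSubject(al)))
}

new_age_estimate <- function(subject_id, k2p, r) {
  structure(list(subject_id = subject_id, P = k2p$P, Q = k2p$Q, K = k2p$K,
                 n_sites = k2p$n_sites, r = r,
                 T = if (isTRUE(k2p$valid)) k2p$K / (2 * r) else NA_real_,
                 valid = isTRUE(k2p$valid)),
            class = "age_estimate")
}

#' @export
print.age_estimate <- function(x, ...) {
  cat(sprintf("<age> %s: K=%s, r=%.3g -> T=%s years (%s)\n", x$subject_id,
              if (is.na(x$K)) "NA" else sprintf("%.4g", x$K), x$r,
              if (is.na(x$T)) "NA" else format(round(x$T), big.mark = ","),
              if (x$valid) "valid" else "not datable"))
  invisible(x)
}

#' Date an LTR-retrotransposon insertion from its LTR divergence
#'
#' The two LTRs of an element are identical at insertion and diverge under
#' the molecular clock, so the insertion age is `T = K / (2r)` where `K`
#' is their K2P distance after global alignment.
#'
#' @param element A `te_element` with two LTRs (`state == "intact"`).
#' @param r Substitution rate, substitutions/site/year (default 1.3e-8,
#'   the rate of the dating method this implements; always carried in the
#'   output, never silent).
#' @param min_sites Minimum aligned columns for a valid estimate.
#' @param ... Alignment parameters passed to the internal global aligner
#'   (`match`, `mismatch`, `gap_open`, `gap_extend`).
#' @return An `age_estimate` (see [date_divergence()]).
#' @export
date_ltr_insertion <- function(element, r = 1.3e-8, min_sites = 50L, ...) {
  if (!identical(element$state, "intact"))
    stop("not datable: element is not intact (needs two LTRs)")
  ltrs <- ltr_pair(element)
  al <- align_global(ltrs$ltr5, ltrs$ltr3, ...)
  k <- k2p_distance(al$a, al$b, min_sites = min_sites)
  new_age_estimate(element$id, k, r)
}

#' Date the divergence of two homologous sequences
#'
#' Global-aligns the sequences, computes the K2P distance and converts it
#' to years via `T = K / (2r)`. Used both for paralog duplication dating
#' and for ortholog divergence dating.
#'
#' @param seq_a,seq_b Homologous nucleotide sequences (unaligned).
#' @param r Substitution rate, substitutions/site/year.
#' @param subject_id Label carried in the result.
#' @param min_sites Minimum aligned columns for a valid estimate.
#' @param ... Alignment parameters, see [date_ltr_insertion()].
#' @return An `age_estimate`: `subject_id`, `P`, `Q`, `K`, `n_sites`, `r`,
#'   `T` (years), `valid`.
#' @export
date_divergence <- function(seq_a, seq_b, r = 1.3e-8,
                            subject_id = "pair", min_sites = 50L, ...) {
  al <- align_global(seq_a, seq_b, ...)
  k <- k2p_distance(al$a, al$b, min_sites = min_sites)
  new_age_estimate(subject_id, k, r)
}
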