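# Insertion dating from 5'/3' LTR divergence under the Kimura two-parameter
# model: T = k / (2 r).

#' Globally align an element's two LTRs
#'
#' Needleman-Wunsch global alignment under the same scoring scheme as
#' [global_identity()] (match +1, mismatch -1, linear gap -2). Substitution
#' counting downstream is symmetric in the two sequences.
#'
#' @param ltr5,ltr3 Non-empty nucleotide strings.
#' @return A list with gapped strings `aln5` and `aln3` (equal length).
#' @export
align_ltr_pair <- function(ltr5, ltr3) {
  if (!nzchar(ltr5) || !nzchar(ltr3)) abort("LTR sequences must be non-empty")
  pa <- nw_alignment(ltr5, ltr3)
  list(
    aln5 = as.character(Biostrings::alignedPattern(pa)),
    aln3 = as.character(Biostrings::alignedSubject(pa))
  )
}

#' Transition and transversion frequencies from an alignment
#'
#' Counts substitutions over gap-free columns: transitions are A<->G and
#' C<->T, everything else is a transversion. Gap columns are excluded from
#' both numerator and denominator.
#'
#' @param alignment A list with `aln5`/`aln3` from [align_ltr_pair()], or two
#'   gapped strings of equal length.
#' @param aln3 Second gapped string when `alignment` is given as a string.
#' @return A list: `p` (transition frequency), `q` (transversion frequency),
#'   `n` (gap-free columns).
#' @export
count_substitutions <- function(alignment, aln3 = NULL) {
  if (is.list(alignment)) {
    a <- alignment$aln5
    b <- alignment$aln3
  } else {
    a <- alignment
    b <- aln3
  }
  ca <- seq_to_chars(a)
  cb <- seq_to_chars(b)
  if (length(ca) != length(cb)) abort("aligned strings must have equal length")
  keep <- ca != "-" & cb != "-"
  n <- sum(keep)
  if (n == 0) abort("no comparable columns")
  ca <- ca[keep]
  cb <- cb[keep]
  diff <- ca != cb
  is_ts <- diff & TRANSITION[ca] == cb
  list(p = sum(is_ts) / n, q = sum(diff & !is_ts) / n, n = n)
}

#' Kimura two-parameter distance
#'
#' `k = -0.5 * ln((1 - 2p - q) * sqrt(1 - 2q))`, the standard K2P form with
#' transitions and transversions separated. Requires `1 - 2p - q > 0` and
#' `1 - 2q > 0`; outside that domain divergence is saturated and the
#' distance is undefined (an error is raised so callers can record the
#' element as undatable). For `q = 0` the distance reduces to
#' `-0.5 * ln(1 - 2p)`.
#'
#' @param p Transition frequency.
#' @param q Transversion frequency.
#' @return Distance in substitutions per site (>= 0; 0 iff `p = q = 0`).
#' @examples
#' k2p_distance(0.1, 0.05) # 0.1701812
#' @export
k2p_distance <- function(p, q) {
  assert_scalar_number(p, "p", 0, 1)
  assert_scalar_number(q, "q", 0, 1)
  if ((1 - 2 * p - q) <= 0 || (1 - 2 * q) <= 0) {
    abort("K2P undefined: divergence saturated (1-2p-q or 1-2q not positive)")
  }
  -0.5 * log((1 - 2 * p - q) * sqrt(1 - 2 * q))
}

#' Insertion time from K2P distance
#'
#' `T = k / (2 r)` years, with `r` the per-site per-year substitution rate
#' (default 1.3e-8).
#'
#' @param k K2P distance (substitutions/site, >= 0).
#' @param r Substitution rate per site per year (> 0).
#' @return Insertion time in years.
#' @examples
#' insertion_time(0.0026) # 1e5 years
#' @export
insertion_time <- function(k, r = 1.3e-8) {
  if (any(r <= 0)) abort("`r` must be positive")
  if (any(k < 0)) abort("`k` must be non-negative")
  k / (2 * r)
}

#' Classify an insertion as recent or late
#'
#' Recent means strictly younger than the boundary (default 0.5 Mya); an
#' insertion exactly at the boundary is late.
#'
#' @param t_years Insertion time in years.
#' @param boundary_years Recency boundary in years.
#' @return Character vector `"recent"` / `"late"`.
#' @export
classify_recency <- function(t_years, boundary_years = 5e5) {
  if_else(t_years < boundary_years, "recent", "late")
}

#' Date every element in a catalog from its LTR pair
#'
#' Extracts both LTR sequences, aligns them, counts substitution
#' frequencies, and converts the K2P distance to an insertion time.
#' Elements whose divergence saturates the K2P domain are reported with
#' `datable = FALSE` and missing `k`/`t_years`.
#'
#' @param rtes Catalog tibble.
#' @param genome `DNAStringSet` or FASTA path.
#' @param r Substitution rate per site per year.
#' @param boundary_years Recency boundary in years.
#' @return Tibble: `rte_id`, `n_columns`, `p`, `q`, `k`, `t_years`, `t_mya`,
#'   `recency`, `datable`.
#' @export
estimate_ages <- function(rtes, genome, r = 1.3e-8, boundary_years = 5e5) {
  ltr5 <- rte_sequences(rtes, genome, "ltr5")
  ltr3 <- rte_sequences(rtes, genome, "ltr3")
  rows <- purrr::map(seq_len(nrow(rtes)), function(i) {
    aln <- align_ltr_pair(ltr5[[i]], ltr3[[i]])
    sub <- count_substitutions(aln)
    k <- tryCatch(k2p_distance(sub$p, sub$q), error = function(e) NA_real_)
    t_years <- if (is.na(k)) NA_real_ else insertion_time(k, r)
    tibble(
      rte_id = rtes$rte_id[i], n_columns = sub$n,
      p = sub$p, q = sub$q, k = k,
      t_years = t_years, t_mya = t_years / 1e6,
      recency = if (is.na(k)) {
        NA_character_
      } else {
        classify_recency(t_years, boundary_years)
      },
      datable = !is.na(k)
    )
  })
  bind_rows(rows)
}
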