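#' Nei–Gojobori (1986) site counts for one codon
#'
#' For each codon position the three possible single-nucleotide changes are
#' classified against the standard genetic code; the synonymous site fraction
#' of a position is the proportion of synonymous changes among the non-stop
#' changes (changes creating stop codons are excluded from the denominator).
#' The codon's synonymous site count is the sum of the three fractions and the
#' nonsynonymous count is its complement to 3.
#'
#' @param codon Character vector of 3-letter codons over A/C/G/T (sense
#'   codons; stop or ambiguous codons are an error).
#' @return Tibble with columns `codon`, `n_sites`, `s_sites`.
#' @examples
#' ng86_sites("TTT") # s_sites = 1/3
#' @export
ng86_sites <- function(codon) {
  tab <- codon_tables()
  codon <- toupper(codon)
  bad <- !(codon %in% tab$sense)
  if (any(bad)) {
    stop("not a sense codon over ACGT: ", paste(unique(codon[bad]), collapse = ", "),
         call. = FALSE)
  }
  tibble(codon = codon,
         n_sites = unname(tab$n_codon[codon]),
         s_sites = unname(tab$s_codon[codon]))
}

#' Pairwise codon alignment container
#'
#' Holds two gap-aligned coding sequences (the reference species first), split
#' into aligned codon columns. Gaps must cover whole codons, sequences must be
#' equally long with length divisible by 3, and no ungapped codon may be a
#' stop (terminal stops are expected to be trimmed upstream).
#'
#' @param ref,alt Aligned nucleotide strings (`-` gaps), reference first.
#' @param ids Character vector of length 2 naming the sequences.
#' @return Object of class `codon_alignment_pair`: list with codon vectors
#'   `ref`, `alt` and `ids`.
#' @export
codon_alignment_pair <- function(ref, alt, ids = c("ref", "alt")) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (nchar(ref) != nchar(alt)) stop("aligned lengths differ", call. = FALSE)
  if (nchar(ref) %% 3 != 0) stop("aligned length not divisible by 3", call. = FALSE)
  split3 <- function(s) {
    n <- nchar(s) / 3
    substring(s, 3 * seq_len(n) - 2, 3 * seq_len(n))
  }
  r <- split3(ref); a <- split3(alt)
  part_gap <- function(x) grepl("-", x) & x != "---"
  if (any(part_gap(r)) || any(part_gap(a))) {
    stop("gaps must cover whole codons", call. = FALSE)
  }
  check_stops <- function(x, who) {
    ung <- x[x != "---" & !grepl("[^ACGT]", x)]
    if (any(is_stop_codon(ung))) {
      stop("internal stop codon in ", who, " sequence", call. = FALSE)
    }
  }
  check_stops(r, "reference"); check_stops(a, "second")
  structure(list(ref = r, alt = a, ids = ids), class = "codon_alignment_pair")
}

#' @export
print.codon_alignment_pair <- function(x, ...) {
  cat(sprintf("<codon_alignment_pair> %s / %s: %d aligned codons (%d shared ungapped)\n",
              x$ids[1], x$ids[2], length(x$ref),
              sum(x$ref != "---" & x$alt != "---")))
  invisible(x)
}

#' Extract the alignment region of a domain
#'
#' Cuts the sub-alignment covering reference amino-acid positions
#' `start_aa..end_aa` (1-based, inclusive). Codon columns gapped in the
#' reference that fall inside the span are kept.
#'
#' @param pair A [codon_alignment_pair()].
#' @param start_aa,end_aa Domain boundaries on the ungapped reference protein.
#' @return A `codon_alignment_pair` restricted to the region.
#' @export
extract_domain_region <- function(pair, start_aa, end_aa) {
  stopifnot(inherits(pair, "codon_alignment_pair"))
  if (start_aa < 1 || end_aa < start_aa) {
    stop("invalid domain coordinates", call. = FALSE)
  }
  ref_cols <- which(pair$ref != "---")   # alignment column of each ref codon
  if (end_aa > length(ref_cols)) {
    stop("domain coordinates exceed reference length (", length(ref_cols), " aa)",
         call. = FALSE)
  }
  # span from the column holding ref codon start_aa to the one holding end_aa;
  # interior columns gapped in the reference are kept
  keep <- seq(ref_cols[start_aa], ref_cols[end_aa])
  structure(list(ref = pair$ref[keep], alt = pair$alt[keep], ids = pair$ids),
            class = "codon_alignment_pair")
}

#' Pairwise dN/dS by NG86 counting with Jukes–Cantor correction
#'
#' Codon columns gapped in either sequence, or containing ambiguous bases, are
#' skipped. Sites are counted per [ng86_sites()] and averaged over the two
#' sequences; differences are counted per codon pair with multi-nucleotide
#' differences averaged over all minimal mutational pathways (pathways through
#' stop codons excluded; a codon pair whose pathways all pass a stop is
#' excluded entirely). Proportions are Jukes–Cantor corrected:
#' d = -3/4 log(1 - 4p/3).
#'
#' @param region A [codon_alignment_pair()] (typically from
#'   [extract_domain_region()]).
#' @return One-row tibble: `aligned_aa_length` (codon pairs compared),
#'   `N_sites`, `S_sites`, `Nd`, `Sd`, `pN`, `pS`, `dN`, `dS`, `omega`
#'   (`NA` when `dS` is 0).
#' @examples
#' p <- codon_alignment_pair("TTTTTT", "TTATTT")
#' estimate_dnds(p)
#' @export
estimate_dnds <- function(region) {
  stopifnot(inherits(region, "codon_alignment_pair"))
  tab <- codon_tables()
  ok <- region$ref %in% tab$sense & region$alt %in% tab$sense
  r <- region$ref[ok]; a <- region$alt[ok]
  if (length(r) == 0) stop("no comparable codons in region", call. = FALSE)
  pm <- pair_count_matrices()
  nd <- pm$nd[cbind(r, a)]
  sd <- pm$sd[cbind(r, a)]
  usable <- !is.na(nd)                  # drop pairs whose pathways all hit stops
  r <- r[usable]; a <- a[usable]; nd <- nd[usable]; sd <- sd[usable]
  if (length(r) == 0) stop("no comparable codons in region", call. = FALSE)
  S_sites <- sum((tab$s_codon[r] + tab$s_codon[a]) / 2)
  N_sites <- 3 * length(r) - S_sites
  Nd <- sum(nd); Sd <- sum(sd)
  pN <- if (N_sites > 0) Nd / N_sites else 0
  pS <- if (S_sites > 0) Sd / S_sites else 0
  if (pN >= 0.75 || pS >= 0.75) {
    stop("substitution saturation: proportion of differences >= 3/4", call. = FALSE)
  }
  dN <- jc_correct(pN); dS <- jc_correct(pS)
  tibble(
    aligned_aa_length = length(r),
    N_sites = N_sites, S_sites = S_sites, Nd = Nd, Sd = Sd,
    pN = pN, pS = pS, dN = dN, dS = dS,
    omega = if (dS > 0) dN / dS else NA_real_
  )
}

jc_correct <- function(p) -0.75 * log(1 - 4 * p / 3)

#' Reliability filters for rate estimates
#'
#' Keeps estimates from regions of at least `min_aa` aligned amino acids with
#' `dN <= max_dn` and `dS <= max_ds` (boundaries inclusive on the keep side;
#' the discard conditions are strict: shorter than 60 aa, dN > 0.5, dS > 2).
#' Filtered-out rows are retained with `pass_filter = FALSE`, never dropped.
#'
#' @param estimates Data frame with columns `aligned_aa_length`, `dN`, `dS`
#'   (e.g. rows from [estimate_dnds()]).
#' @param min_aa,max_dn,max_ds Filter thresholds; defaults 60, 0.5, 2.
#' @return The input tibble with a logical `pass_filter` column added.
#' @export
apply_filters <- function(estimates, min_aa = 60, max_dn = 0.5, max_ds = 2) {
  stopifnot(is.data.frame(estimates))
  dplyr::mutate(
    as_tibble(estimates),
    pass_filter = .data$aligned_aa_length >= min_aa &
      .data$dN <= max_dn & .data$dS <= max_ds
  )
}
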