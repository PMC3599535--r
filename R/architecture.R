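#' Resolve overlapping domain hits
#'
#' Greedy selection of a non-conflicting subset of hits: hits are ranked by
#' E-value (smaller first), then length (longer first), then domain type id,
#' then start, and accepted unless they overlap an already accepted hit by
#' more than `max_overlap` of the shorter hit's length (the default 0 forbids
#' any shared residue). Works across proteins: hits only conflict within the
#' same `protein_id`.
#'
#' @param hits Data frame with columns `protein_id`, `domain_type_id`,
#'   `start`, `end` (1-based aa, inclusive) and `evalue`.
#' @param max_overlap Tolerated overlap as a fraction of the shorter hit.
#' @return Tibble of kept hits, sorted by `protein_id`, `start`.
#' @export
resolve_overlaps <- function(hits, max_overlap = 0) {
  stopifnot(is.data.frame(hits))
  if (nrow(hits) == 0) return(as_tibble(hits))
  if (any(hits$start < 1 | hits$end < hits$start)) {
    stop("invalid hit coordinates", call. = FALSE)
  }
  hits <- as_tibble(hits)
  res <- hits |>
    dplyr::group_split(.data$protein_id) |>
    purrr::map(resolve_overlaps_one, max_overlap = max_overlap) |>
    dplyr::bind_rows()
  dplyr::arrange(res, .data$protein_id, .data$start, .data$end)
}

resolve_overlaps_one <- function(h, max_overlap) {
  len <- h$end - h$start + 1
  ord <- order(h$evalue, -len, h$domain_type_id, h$start)
  kept <- integer(0)
  for (i in ord) {
    conflict <- FALSE
    for (j in kept) {
      ov <- min(h$end[i], h$end[j]) - max(h$start[i], h$start[j]) + 1
      if (ov > max_overlap * min(len[i], len[j])) { conflict <- TRUE; break }
    }
    if (!conflict) kept <- c(kept, i)
  }
  h[sort(kept), ]
}

#' Build domain architectures from resolved hits
#'
#' One row per protein: the ordered tuple of domain types (by start
#' coordinate) and the configuration identity string. For configuration
#' identity, tandem runs of the same type collapse to a single element (so
#' Zn-finger arrays with different copy numbers share one configuration);
#' disable with `collapse_tandem = FALSE`. `ordered = FALSE` uses the sorted
#' set of types instead of the ordered tuple.
#'
#' @param hits Data frame of non-overlapping hits (see [resolve_overlaps()]).
#' @param collapse_tandem Collapse consecutive repeats of a type for the
#'   configuration string (default TRUE).
#' @param ordered Use the ordered tuple as configuration identity (default);
#'   otherwise the unordered type set.
#' @return Tibble with `protein_id`, `types` (list of character vectors, in
#'   start order, uncollapsed), `config` (identity string, types joined by
#'   `;`) and `n_domains`.
#' @export
architectures <- function(hits, collapse_tandem = TRUE, ordered = TRUE) {
  stopifnot(is.data.frame(hits))
  if (nrow(hits) == 0) {
    return(tibble(protein_id = character(), types = list(),
                  config = character(), n_domains = integer()))
  }
  hits |>
    dplyr::arrange(.data$protein_id, .data$start, .data$end) |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(types = list(.data$domain_type_id), .groups = "drop") |>
    dplyr::mutate(
      config = purrr::map_chr(.data$types, config_string,
                              collapse_tandem = collapse_tandem,
                              ordered = ordered),
      n_domains = lengths(.data$types)
    )
}

config_string <- function(types, collapse_tandem = TRUE, ordered = TRUE) {
  if (!ordered) return(paste(sort(unique(types)), collapse = ";"))
  if (collapse_tandem) types <- rle(types)$values
  paste(types, collapse = ";")
}

#' Configurations in which a domain type occurs
#'
#' The set of distinct configuration strings of proteins containing at least
#' one occurrence of the type. A type is "independent" when it occurs in two
#' or more configurations.
#'
#' @param domain_type_id A single domain type.
#' @param archs Architecture table from [architectures()].
#' @return Character vector of configuration strings (possibly empty).
#' @export
configurations_of <- function(domain_type_id, archs) {
  has <- purrr::map_lgl(archs$types, ~ domain_type_id %in% .x)
  sort(unique(archs$config[has]))
}

#' @rdname configurations_of
#' @export
is_independent <- function(domain_type_id, archs) {
  length(configurations_of(domain_type_id, archs)) >= 2
}

#' Classify a young/old domain-type pair
#'
#' Arrangement scenarios for a young domain type co-occurring with an old
#' one: `gain_dependent` (class 1) when the old type, but not the young one,
#' is found in other configurations — compatible with gain of the young
#' domain into an existing protein; `mutual_dependence` (class 2) when
#' neither is; `fusion` (class 3) when both are; `reverse_dependence` when
#' only the young type is found elsewhere (the mirror of class 1, reported
#' separately — no such case was observed in the human data).
#'
#' @param young_type,old_type Domain type ids; they must co-occur in at least
#'   one protein of `archs`.
#' @param archs Architecture table from [architectures()].
#' @return A scenario label (character).
#' @export
classify_pair <- function(young_type, old_type, archs) {
  co <- purrr::map_lgl(archs$types,
                       ~ young_type %in% .x && old_type %in% .x)
  if (!any(co)) {
    stop("types `", young_type, "` and `", old_type,
         "` never co-occur", call. = FALSE)
  }
  yi <- is_independent(young_type, archs)
  oi <- is_independent(old_type, archs)
  if (oi && !yi) "gain_dependent"
  else if (!oi && !yi) "mutual_dependence"
  else if (oi && yi) "fusion"
  else "reverse_dependence"
}

#' Classify every protein combining young and old domains
#'
#' Each young/old type pair in a protein is classified with [classify_pair()];
#' if all pairs agree the protein takes that class, otherwise it is `complex`
#' (class 4, only possible with more than two domains). Classes 1 and 2 are
#' jointly "gain-compatible": both fit the gain of a young domain into an
#' existing older protein.
#'
#' @param archs Architecture table from [architectures()].
#' @param ages Data frame mapping `domain_type_id` to `age_class`.
#' @param ranking A [clade_ranking()] (defines which classes are young).
#' @return Tibble with `protein_id`, `scenario` and `gain_compatible`,
#'   one row per protein containing at least one young and one old domain.
#' @export
classify_scenarios <- function(archs, ages,
                               ranking = default_clade_ranking()) {
  age_of <- setNames(as.character(ages$age_class), ages$domain_type_id)
  rows <- purrr::map_dfr(seq_len(nrow(archs)), function(i) {
    types <- unique(archs$types[[i]])
    ag <- age_of[types]
    if (anyNA(ag)) {
      stop("protein `", archs$protein_id[i],
           "` contains a domain type without an age", call. = FALSE)
    }
    young <- types[is_young(ag, ranking)]
    old <- types[!is_young(ag, ranking)]
    if (length(young) == 0 || length(old) == 0) return(NULL)
    labs <- unlist(lapply(young, function(y)
      vapply(old, function(o) classify_pair(y, o, archs), character(1))))
    scenario <- if (length(unique(labs)) == 1) unname(labs[1]) else "complex"
    tibble(protein_id = archs$protein_id[i], scenario = scenario)
  })
  if (nrow(rows) == 0) {
    return(tibble(protein_id = character(), scenario = character(),
                  gain_compatible = logical()))
  }
  dplyr::mutate(rows, gain_compatible = .data$scenario %in%
                  c("gain_dependent", "mutual_dependence"))
}

#' Position of a young domain within an architecture
#'
#' N-terminal when it is the first domain of the ordered tuple, C-terminal
#' when the last, internal otherwise. Only defined for architectures with at
#' least two domains.
#'
#' @param types Ordered character vector of domain types (by start).
#' @param young_index Index of the young occurrence under consideration.
#' @return `"N_terminal"`, `"internal"` or `"C_terminal"`.
#' @export
young_position <- function(types, young_index) {
  k <- length(types)
  if (k < 2) stop("position undefined for single-domain proteins", call. = FALSE)
  if (young_index < 1 || young_index > k) stop("bad young_index", call. = FALSE)
  if (young_index == 1) "N_terminal"
  else if (young_index == k) "C_terminal"
  else "internal"
}

#' Positions of all young domain occurrences in multi-domain proteins
#'
#' @param archs Architecture table from [architectures()].
#' @param ages Data frame mapping `domain_type_id` to `age_class`.
#' @param ranking A [clade_ranking()].
#' @return Tibble with `protein_id`, `domain_type_id`, `position`, `k`
#'   (domains in the protein) and `stratum` (`"2"` or `">2"`), one row per
#'   young occurrence in a protein with `k >= 2`.
#' @export
young_positions <- function(archs, ages, ranking = default_clade_ranking()) {
  age_of <- setNames(as.character(ages$age_class), ages$domain_type_id)
  purrr::map_dfr(seq_len(nrow(archs)), function(i) {
    types <- archs$types[[i]]
    k <- length(types)
    if (k < 2) return(NULL)
    yidx <- which(is_young(age_of[types], ranking))
    if (length(yidx) == 0) return(NULL)
    tibble(
      protein_id = archs$protein_id[i],
      domain_type_id = types[yidx],
      position = vapply(yidx, function(j) young_position(types, j),
                        character(1)),
      k = k,
      stratum = if (k == 2) "2" else ">2"
    )
  })
}

#' Chi-square test for positional bias of young domains
#'
#' Goodness-of-fit against a uniform-position null, per stratum. In 2-domain
#' proteins a young domain is N- or C-terminal with probability 1/2 each. In
#' k-domain proteins (k > 2) the null probabilities are 1/k (N-terminal),
#' (k-2)/k (internal) and 1/k (C-terminal); expected counts aggregate these
#' over the observed k of each occurrence.
#'
#' @param positions Tibble from [young_positions()] (columns `position`, `k`,
#'   `stratum`).
#' @return Tibble with one row per stratum: observed counts, `statistic`,
#'   `df`, `p_value` and `small_expected` (TRUE when any expected cell is
#'   below 5, flagging an unreliable asymptotic p-value).
#' @export
positional_bias_test <- function(positions) {
  stopifnot(is.data.frame(positions))
  labs <- c("N_terminal", "internal", "C_terminal")
  purrr::map_dfr(split(positions, positions$stratum), function(d) {
    obs <- vapply(labs, function(l) sum(d$position == l), double(1))
    exp_counts <- c(
      N_terminal = sum(1 / d$k),
      internal = sum((d$k - 2) / d$k),
      C_terminal = sum(1 / d$k)
    )
    use <- exp_counts > 0
    stat <- sum((obs[use] - exp_counts[use])^2 / exp_counts[use])
    df <- sum(use) - 1
    tibble(
      stratum = d$stratum[1], n = nrow(d),
      n_N = obs[["N_terminal"]], n_internal = obs[["internal"]],
      n_C = obs[["C_terminal"]],
      statistic = stat, df = df,
      p_value = stats::pchisq(stat, df, lower.tail = FALSE),
      small_expected = any(exp_counts[use] < 5)
    )
  })
}
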