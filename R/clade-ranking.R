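#' Ranked species clades for phylostratigraphic dating
#'
#' A clade ranking orders groups of species from youngest (closest to the
#' reference species) to oldest. Presence of a domain in a species of an old
#' clade implies the domain predates the split with that clade, so the oldest
#' occupied clade dates the domain. The reference species itself (human in the
#' default ranking) belongs to no clade: every profiled domain is present in it
#' by construction.
#'
#' @param clades Named list of character vectors, ordered youngest first,
#'   oldest last. Names are clade labels (used as age-class labels); values are
#'   species identifiers, unique across clades.
#' @param reference Identifier of the reference species (informational).
#'
#' @return An object of class `clade_ranking`: a list with elements `clades`,
#'   `reference`, `ages` (ordered factor levels, youngest first) and `species`
#'   (all species identifiers).
#' @examples
#' rk <- default_clade_ranking()
#' rk$ages
#' @export
clade_ranking <- function(clades, reference = "reference") {
  stopifnot(is.list(clades), length(clades) >= 2)
  if (is.null(names(clades)) || any(!nzchar(names(clades)))) {
    stop("every clade must be named", call. = FALSE)
  }
  if (anyDuplicated(names(clades))) {
    stop("clade names must be unique", call. = FALSE)
  }
  sizes <- vapply(clades, length, integer(1))
  if (any(sizes == 0)) stop("clades must be non-empty", call. = FALSE)
  species <- unlist(clades, use.names = FALSE)
  if (anyDuplicated(species)) {
    stop("species identifiers must be unique across clades", call. = FALSE)
  }
  structure(
    list(
      clades = clades,
      reference = reference,
      ages = names(clades),
      species = species
    ),
    class = "clade_ranking"
  )
}

#' @rdname clade_ranking
#' @details `default_clade_ranking()` returns the 15-species, 4-clade ranking
#'   used for dating human domains: mammals (mouse, rat, cow), non-mammalian
#'   vertebrates (zebrafish, chicken, fugu, xenopus), other metazoans
#'   (anopheles, celegans, ciona, drosophila) and other eukaryotes
#'   (arabidopsis, rice, scerevisiae, spombe), with age labels Mammalian <
#'   Vertebrate < Metazoan < Eukarya.
#' @export
default_clade_ranking <- function() {
  clade_ranking(
    list(
      Mammalian  = c("mouse", "rat", "cow"),
      Vertebrate = c("zebrafish", "chicken", "fugu", "xenopus"),
      Metazoan   = c("anopheles", "celegans", "ciona", "drosophila"),
      Eukarya    = c("arabidopsis", "rice", "scerevisiae", "spombe")
    ),
    reference = "human"
  )
}

#' @export
print.clade_ranking <- function(x, ...) {
  cat("<clade_ranking> reference:", x$reference, "\n")
  for (i in seq_along(x$clades)) {
    cat(sprintf("  %d. %s: %s\n", i, x$ages[i],
                paste(x$clades[[i]], collapse = ", ")))
  }
  invisible(x)
}

#' Age-class helpers
#'
#' Age classes form a total order, youngest first (Mammalian < Vertebrate <
#' Metazoan < Eukarya under the default ranking). For reporting, the two
#' oldest classes are merged into a single `Old` class (both predate the
#' vertebrate radiation by more than ~550 My and show very similar rate
#' distributions); the two youngest are jointly called "young".
#'
#' @param age Character vector of age-class labels.
#' @param ranking A [clade_ranking()].
#' @param old_from Label of the youngest class merged into `Old`. Defaults to
#'   `"Metazoan"` when the ranking has such a class, otherwise to the oldest
#'   class (so only that one is relabelled `Old`).
#' @return `age_factor()` returns an ordered factor; `merge_old()` a factor
#'   with levels `Mammalian, Vertebrate, Old`; `is_young()` a logical vector.
#' @export
age_factor <- function(age, ranking = default_clade_ranking()) {
  factor(age, levels = ranking$ages, ordered = TRUE)
}

#' @rdname age_factor
#' @export
merge_old <- function(age, ranking = default_clade_ranking(),
                      old_from = NULL) {
  f <- age_factor(age, ranking)
  if (is.null(old_from)) {
    old_from <- if ("Metazoan" %in% ranking$ages) "Metazoan"
                else ranking$ages[length(ranking$ages)]
  }
  idx <- match(old_from, ranking$ages)
  if (is.na(idx)) stop("`old_from` is not an age class of the ranking", call. = FALSE)
  young_levels <- ranking$ages[seq_len(idx - 1)]
  out <- ifelse(as.integer(f) >= idx, "Old", as.character(f))
  factor(out, levels = c(young_levels, "Old"), ordered = TRUE)
}

#' @rdname age_factor
#' @export
is_young <- function(age, ranking = default_clade_ranking(),
                     old_from = NULL) {
  merge_old(age, ranking, old_from) != "Old"
}
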