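#' Assign a phylogenetic age class to one phyletic profile
#'
#' The age of a domain type is the age of the oldest clade containing at least
#' one species in which the domain was found ("oldest-hit" rule). Absences in
#' younger clades are treated as secondary losses and never lower the age. A
#' profile with no presence at all refers to a domain known only from the
#' reference lineage; by convention it receives the youngest age (configurable
#' via `empty_age`).
#'
#' @param presence Named logical (or 0/1) vector, one flag per species in
#'   `ranking`. Presence in the reference species is implicit and not part of
#'   the profile.
#' @param ranking A [clade_ranking()].
#' @param empty_age Age label returned when no species has a presence flag;
#'   default the youngest class of the ranking.
#' @return A single age-class label (character).
#' @examples
#' rk <- default_clade_ranking()
#' prof <- setNames(rk$species %in% c("mouse", "cow"), rk$species)
#' assign_domain_age(prof, rk) # "Mammalian"
#' @export
assign_domain_age <- function(presence, ranking = default_clade_ranking(),
                              empty_age = ranking$ages[1]) {
  presence <- check_profile(presence, ranking)
  for (i in rev(seq_along(ranking$clades))) {
    if (any(presence[ranking$clades[[i]]])) return(ranking$ages[i])
  }
  empty_age
}

check_profile <- function(presence, ranking) {
  if (is.numeric(presence)) {
    if (!all(presence %in% c(0, 1))) {
      stop("numeric presence flags must be 0/1", call. = FALSE)
    }
    presence <- setNames(presence == 1, names(presence))
  }
  if (is.null(names(presence)) ||
      !setequal(names(presence), ranking$species) ||
      length(presence) != length(ranking$species)) {
    stop("profile species do not match the clade ranking", call. = FALSE)
  }
  if (anyNA(presence)) stop("presence flags must not be NA", call. = FALSE)
  presence
}

#' Assign age classes to a table of phyletic profiles
#'
#' Data-frame front end to [assign_domain_age()]. One row per domain type,
#' one 0/1 (or logical) column per species of the ranking.
#'
#' @param profiles Data frame with an id column (first argument of `id_col`)
#'   and one presence column per species in `ranking`.
#' @param ranking A [clade_ranking()].
#' @param id_col Name of the identifier column. Default `"domain_type_id"`.
#' @inheritParams assign_domain_age
#' @return A tibble with columns `<id_col>`, `age_class` (ordered factor) and
#'   `age_class_merged` (Old projection applied).
#' @examples
#' rk <- default_clade_ranking()
#' profs <- tibble::tibble(domain_type_id = "D1",
#'   !!!setNames(as.list(as.integer(rk$species == "chicken")), rk$species))
#' assign_domain_ages(profs, rk)
#' @export
assign_domain_ages <- function(profiles, ranking = default_clade_ranking(),
                               id_col = "domain_type_id",
                               empty_age = ranking$ages[1]) {
  stopifnot(is.data.frame(profiles))
  if (!id_col %in% names(profiles)) {
    stop("profiles must have an id column `", id_col, "`", call. = FALSE)
  }
  missing_sp <- setdiff(ranking$species, names(profiles))
  if (length(missing_sp)) {
    stop("profiles lack species columns: ", paste(missing_sp, collapse = ", "),
         call. = FALSE)
  }
  mat <- as.matrix(profiles[ranking$species])
  ages <- vapply(seq_len(nrow(mat)), function(i) {
    assign_domain_age(setNames(mat[i, ], ranking$species), ranking, empty_age)
  }, character(1))
  out <- tibble(
    id = profiles[[id_col]],
    age_class = age_factor(ages, ranking),
    age_class_merged = merge_old(ages, ranking)
  )
  names(out)[1] <- id_col
  out
}

#' Age of a protein from the ages of its domains
#'
#' A protein is as old as the oldest domain it contains. Proteins without any
#' annotated domain are dated from a homology profile (presence/absence of
#' sequence-similarity hits across the same species universe), using the same
#' oldest-hit rule.
#'
#' @param domain_ages Character vector of age labels of the protein's domains
#'   (may be empty).
#' @param fallback Optional named presence vector (homology profile over the
#'   ranking's species), used only when `domain_ages` is empty.
#' @inheritParams assign_domain_age
#' @return A single age-class label.
#' @examples
#' assign_protein_age(c("Vertebrate", "Eukarya")) # "Eukarya"
#' @export
assign_protein_age <- function(domain_ages, fallback = NULL,
                               ranking = default_clade_ranking(),
                               empty_age = ranking$ages[1]) {
  domain_ages <- domain_ages[!is.na(domain_ages)]
  if (length(domain_ages) > 0) {
    f <- age_factor(domain_ages, ranking)
    if (anyNA(f)) stop("unknown age label in `domain_ages`", call. = FALSE)
    return(as.character(max(f)))
  }
  if (is.null(fallback)) {
    stop("protein has no domains and no homology profile: unageable",
         call. = FALSE)
  }
  assign_domain_age(fallback, ranking, empty_age)
}

#' Assign ages to proteins from a domain table, with homology fallback
#'
#' @param domains Data frame with columns `protein_id` and `age_class` (one
#'   row per domain occurrence).
#' @param homology Optional data frame of homology profiles for domainless
#'   proteins: `protein_id` plus one presence column per species.
#' @param proteins Optional character vector of all protein ids to age;
#'   defaults to the union of ids seen in `domains` and `homology`.
#' @inheritParams assign_domain_age
#' @return Tibble with `protein_id`, `age_class`, `age_class_merged` and
#'   `age_basis` (`"domains"` or `"homology"`).
#' @export
assign_protein_ages <- function(domains, homology = NULL, proteins = NULL,
                                ranking = default_clade_ranking(),
                                empty_age = ranking$ages[1]) {
  ids <- proteins %||% union(unique(domains$protein_id),
                             if (!is.null(homology)) unique(homology$protein_id))
  by_prot <- split(as.character(domains$age_class), domains$protein_id)
  hom <- NULL
  if (!is.null(homology)) {
    hmat <- as.matrix(homology[ranking$species])
    hom <- lapply(seq_len(nrow(hmat)),
                  function(i) setNames(hmat[i, ], ranking$species))
    names(hom) <- homology$protein_id
  }
  res <- vapply(ids, function(id) {
    ages <- by_prot[[id]]
    if (!is.null(ages) && length(ages)) {
      c(assign_protein_age(ages, NULL, ranking, empty_age), "domains")
    } else if (!is.null(hom) && id %in% names(hom)) {
      c(assign_domain_age(hom[[id]], ranking, empty_age), "homology")
    } else {
      stop("protein `", id, "` has no domains and no homology profile: unageable",
           call. = FALSE)
    }
  }, character(2))
  tibble(
    protein_id = ids,
    age_class = age_factor(unname(res[1, ]), ranking),
    age_class_merged = merge_old(unname(res[1, ]), ranking),
    age_basis = unname(res[2, ])
  )
}

#' Summaries of domain and protein tables by age class
#'
#' Tabulates, per merged age class, the number of domain occurrences, number
#' of distinct domain types and domain length statistics; and per protein age
#' class, protein counts, domains per protein and protein length. Also derives
#' the headline fractions: share of young domain types, and per age class the
#' share of young types found only in proteins of their own age ("in new
#' genes").
#'
#' @param domain_table Data frame of domain occurrences with columns
#'   `domain_type_id`, `age_class`, `length_aa` and `protein_id`.
#' @param protein_table Data frame with `protein_id`, `age_class`,
#'   `length_aa` and `n_domains` (0 for domainless proteins).
#' @param ranking A [clade_ranking()].
#' @return A list of class `age_summary` with tibbles `domains`, `proteins`
#'   and `fractions`.
#' @export
summarize_ages <- function(domain_table, protein_table,
                           ranking = default_clade_ranking()) {
  empty_dom <- tibble(age_class_merged = factor(character()),
                      n_occurrences = integer(), n_types = integer(),
                      mean_length = double(), median_length = double())
  doms <- if (nrow(domain_table) == 0) empty_dom else {
    domain_table |>
      dplyr::mutate(age_class_merged = merge_old(.data$age_class, ranking)) |>
      dplyr::group_by(.data$age_class_merged) |>
      dplyr::summarise(
        n_occurrences = dplyr::n(),
        n_types = dplyr::n_distinct(.data$domain_type_id),
        mean_length = mean(.data$length_aa),
        median_length = median(.data$length_aa),
        .groups = "drop"
      )
  }
  empty_prot <- tibble(age_class_merged = factor(character()),
                       has_domains = logical(), n_proteins = integer(),
                       domains_per_protein = double(), mean_length = double(),
                       median_length = double())
  prots <- if (nrow(protein_table) == 0) empty_prot else {
    protein_table |>
      dplyr::mutate(age_class_merged = merge_old(.data$age_class, ranking),
                    has_domains = .data$n_domains > 0) |>
      dplyr::group_by(.data$age_class_merged, .data$has_domains) |>
      dplyr::summarise(
        n_proteins = dplyr::n(),
        domains_per_protein = mean(.data$n_domains),
        mean_length = mean(.data$length_aa),
        median_length = median(.data$length_aa),
        .groups = "drop"
      )
  }
  fractions <- young_type_fractions(domain_table, protein_table, ranking)
  structure(list(domains = doms, proteins = prots, fractions = fractions),
            class = "age_summary")
}

# share of young types, and per young age class the share of its types found
# only in proteins of that same (young) age
young_type_fractions <- function(domain_table, protein_table, ranking) {
  if (nrow(domain_table) == 0) {
    return(tibble(statistic = character(), numerator = integer(),
                  denominator = integer(), value = double()))
  }
  types <- domain_table |>
    dplyr::distinct(.data$domain_type_id, .data$age_class)
  n_total <- nrow(types)
  n_young <- sum(is_young(types$age_class, ranking))
  out <- tibble(statistic = "young_type_fraction_pct",
                numerator = n_young, denominator = n_total,
                value = round_half_up(100 * n_young / n_total, 1))
  if (nrow(protein_table) > 0 && "protein_id" %in% names(domain_table)) {
    page <- setNames(as.character(protein_table$age_class),
                     protein_table$protein_id)
    per_type <- domain_table |>
      dplyr::mutate(protein_age = page[.data$protein_id]) |>
      dplyr::group_by(.data$domain_type_id, .data$age_class) |>
      dplyr::summarise(
        own_age_only = all(.data$protein_age == as.character(.data$age_class[1])),
        .groups = "drop"
      )
    for (ac in ranking$ages[is_young(ranking$ages, ranking)]) {
      sub <- per_type[as.character(per_type$age_class) == ac, ]
      if (nrow(sub) == 0) next
      k <- sum(sub$own_age_only)
      out <- dplyr::bind_rows(out, tibble(
        statistic = paste0(tolower(ac), "_types_in_new_genes_pct"),
        numerator = k, denominator = nrow(sub),
        value = round_half_up(100 * k / nrow(sub), 1)
      ))
    }
  }
  out
}

#' @export
print.age_summary <- function(x, ...) {
  cat("<age_summary>\nDomains by age class:\n")
  print(x$domains)
  cat("\nProteins by age class:\n")
  print(x$proteins)
  cat("\nDerived fractions:\n")
  print(x$fractions)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# round half away from zero at `digits` decimals (matches hand-rounding of
# printed percentages; base round() is half-to-even)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
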