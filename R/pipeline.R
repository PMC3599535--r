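#' Run the full domain-age analysis
#'
#' Orchestrates the stages end to end: phylostratigraphic dating of domain
#' types and proteins, architecture parsing with scenario classification and
#' positional-bias testing, per-domain-region dN/dS estimation with
#' reliability filters, young-vs-old rate comparisons, and the derived report
#' statistics.
#'
#' @param bundle A bundle directory path, a list as returned by
#'   [read_bundle()], or a `sim_bundle` from [simulate_dataset()].
#' @param ranking A [clade_ranking()].
#' @param hit_evalue Hits with E-value above this are dropped (default 1e-5).
#' @param min_aa,max_dn,max_ds Rate reliability filters (see
#'   [apply_filters()]).
#' @param alpha Significance level of the paired binomial verdicts.
#' @param filters_enabled When FALSE every estimate passes the filters.
#' @param outdir Optional directory: stage outputs are written there as
#'   TSV/JSON.
#' @param verbose Log per-stage counts to stderr.
#' @return Object of class `domage_report` (a list): `domain_ages`,
#'   `protein_ages`, `architectures`, `scenarios`, `positions`,
#'   `position_tests`, `rates`, `pairs`, `group_comparison`, `summary`,
#'   `percentages`, `log`.
#' @export
run_analysis <- function(bundle,
                         ranking = default_clade_ranking(),
                         hit_evalue = 1e-5,
                         min_aa = 60, max_dn = 0.5, max_ds = 2,
                         alpha = 0.01,
                         filters_enabled = TRUE,
                         outdir = NULL,
                         verbose = FALSE) {
  if (is.character(bundle)) bundle <- read_bundle(bundle)
  say <- function(...) if (verbose) message(...)
  log <- list()

  # ---- stage 1: ages -------------------------------------------------------
  if (nrow(bundle$profiles) == 0) {
    warning("empty input bundle: returning an empty report")
    return(empty_report())
  }
  domain_ages <- assign_domain_ages(bundle$profiles, ranking)
  say("ages: ", nrow(domain_ages), " domain types dated")

  # ---- stage 2: architectures ---------------------------------------------
  hits <- as_tibble(bundle$hits)
  n0 <- nrow(hits)
  hits <- hits[hits$evalue <= hit_evalue, ]
  log$hits_evalue <- c(before = n0, after = nrow(hits))
  hits <- resolve_overlaps(hits)
  log$hits_overlap <- c(before = log$hits_evalue[["after"]], after = nrow(hits))
  archs <- architectures(hits)
  say("architecture: ", nrow(archs), " proteins, ",
      nrow(hits), " hits after filtering")

  occ <- hits |>
    dplyr::left_join(domain_ages, by = "domain_type_id") |>
    dplyr::mutate(length_aa = .data$end - .data$start + 1,
                  occurrence_id = paste0(.data$protein_id, ":",
                                         .data$domain_type_id, ":",
                                         .data$start))
  protein_ages <- assign_protein_ages(occ, ranking = ranking)
  prot_len <- if (!is.null(bundle$proteins)) {
    setNames(bundle$proteins$length_aa, bundle$proteins$protein_id)
  } else {
    tapply(occ$end, occ$protein_id, max)
  }
  protein_table <- protein_ages |>
    dplyr::mutate(
      length_aa = unname(prot_len[.data$protein_id]),
      n_domains = as.integer(table(occ$protein_id)[.data$protein_id])
    )
  scenarios <- classify_scenarios(archs, domain_ages, ranking)
  positions <- young_positions(archs, domain_ages, ranking)
  position_tests <- if (nrow(positions) > 0) positional_bias_test(positions)
                    else tibble()
  say("scenarios: ", nrow(scenarios), " combined proteins classified")

  # ---- stage 3: rates ------------------------------------------------------
  pairs_by_id <- setNames(seq_len(nrow(bundle$alignments)),
                          bundle$alignments$protein_id)
  rates <- purrr::map_dfr(seq_len(nrow(occ)), function(i) {
    row <- occ[i, ]
    j <- pairs_by_id[row$protein_id]
    base <- tibble(occurrence_id = row$occurrence_id,
                   protein_id = row$protein_id,
                   domain_type_id = row$domain_type_id,
                   age_class = row$age_class,
                   age_class_merged = row$age_class_merged)
    if (is.na(j)) return(dplyr::bind_cols(base, na_estimate("no alignment")))
    est <- tryCatch({
      pair <- codon_alignment_pair(bundle$alignments$ref[j],
                                   bundle$alignments$alt[j])
      region <- extract_domain_region(pair, row$start, row$end)
      dplyr::mutate(estimate_dnds(region), note = NA_character_)
    }, error = function(e) na_estimate(conditionMessage(e)))
    dplyr::bind_cols(base, est)
  })
  rates <- if (filters_enabled) {
    apply_filters(rates, min_aa = min_aa, max_dn = max_dn, max_ds = max_ds)
  } else {
    dplyr::mutate(rates, pass_filter = TRUE)
  }
  rates$pass_filter[is.na(rates$dN)] <- FALSE
  log$rates_filter <- c(before = nrow(rates), after = sum(rates$pass_filter))
  say("rates: ", sum(rates$pass_filter), "/", nrow(rates),
      " estimates pass filters")

  # ---- stage 4: comparisons ------------------------------------------------
  usable <- rates[rates$pass_filter & !is.na(rates$omega), ]
  pairs <- within_protein_pairs(usable, ranking, alpha)
  group_comparison <- if (dplyr::n_distinct(usable$age_class_merged) >= 2) {
    compare_age_groups(usable, pairs = pairs)
  } else NULL

  # ---- stage 5: report -----------------------------------------------------
  summary <- summarize_ages(
    occ |> dplyr::select("domain_type_id", "protein_id", "age_class",
                         "length_aa"),
    protein_table, ranking
  )
  percentages <- report_percentages(occ, protein_ages, scenarios, ranking)

  report <- structure(
    list(domain_ages = domain_ages, protein_ages = protein_ages,
         architectures = archs, scenarios = scenarios,
         positions = positions, position_tests = position_tests,
         rates = rates, pairs = pairs, group_comparison = group_comparison,
         summary = summary, percentages = percentages, log = log),
    class = "domage_report"
  )
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

na_estimate <- function(note) {
  tibble(aligned_aa_length = NA_integer_, N_sites = NA_real_,
         S_sites = NA_real_, Nd = NA_real_, Sd = NA_real_, pN = NA_real_,
         pS = NA_real_, dN = NA_real_, dS = NA_real_, omega = NA_real_,
         note = note)
}

# one young-vs-old comparison per protein containing passing estimates of
# both kinds; with several candidates the longest aligned region of each age
# group is used (the most reliable estimate)
within_protein_pairs <- function(usable, ranking, alpha) {
  usable <- dplyr::mutate(usable, young = is_young(.data$age_class, ranking))
  out <- purrr::map_dfr(split(usable, usable$protein_id), function(d) {
    y <- d[d$young, ]; o <- d[!d$young, ]
    if (nrow(y) == 0 || nrow(o) == 0) return(NULL)
    y <- y[which.max(y$aligned_aa_length), ]
    o <- o[which.max(o$aligned_aa_length), ]
    bt <- paired_binomial_test(y, o, alpha = alpha)
    tibble(
      protein_id = d$protein_id[1],
      young_occurrence = y$occurrence_id, old_occurrence = o$occurrence_id,
      omega_young = y$omega, omega_old = o$omega,
      relative_difference = relative_difference(y$omega, o$omega),
      p_value = bt$p_value, verdict = bt$verdict, degenerate = bt$degenerate
    )
  })
  if (nrow(out) == 0) {
    return(tibble(protein_id = character(), young_occurrence = character(),
                  old_occurrence = character(), omega_young = double(),
                  omega_old = double(), relative_difference = double(),
                  p_value = double(), verdict = character(),
                  degenerate = logical()))
  }
  out
}

report_percentages <- function(occ, protein_ages, scenarios, ranking) {
  types <- occ |> dplyr::distinct(.data$domain_type_id, .data$age_class)
  type_counts <- table(merge_old(types$age_class, ranking))
  page <- setNames(as.character(protein_ages$age_class),
                   protein_ages$protein_id)
  per_type <- occ |>
    dplyr::mutate(protein_age = page[.data$protein_id]) |>
    dplyr::group_by(.data$domain_type_id, .data$age_class) |>
    dplyr::summarise(
      own_age_only = all(.data$protein_age == as.character(.data$age_class[1])),
      .groups = "drop"
    )
  young_classes <- ranking$ages[is_young(ranking$ages, ranking)]
  new_gene <- vapply(young_classes, function(ac) {
    sum(per_type$own_age_only[as.character(per_type$age_class) == ac])
  }, double(1))
  names(new_gene) <- young_classes
  scen <- table(factor(scenarios$scenario,
                       levels = c("gain_dependent", "mutual_dependence",
                                  "fusion", "complex", "reverse_dependence")))
  # proteins made exclusively of young domains vs proteins combining both
  prot_young_only <- occ |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(all_young = all(is_young(.data$age_class, ranking)),
                     .groups = "drop")
  derived_percentages(
    type_counts = setNames(as.integer(type_counts), names(type_counts)),
    new_gene_type_counts = new_gene,
    young_type_totals = vapply(young_classes, function(ac)
      sum(as.character(types$age_class) == ac), double(1)),
    scenario_counts = setNames(as.integer(scen), names(scen)),
    n_young_only = sum(prot_young_only$all_young),
    n_combined = nrow(scenarios)
  )
}

#' Derived report percentages and ratios
#'
#' Arithmetic layer of the report: given labelled counts it derives the
#' headline fractions, each with its numerator and denominator. Percentages
#' are rounded half-up to one decimal, ratios to two decimals.
#'
#' @param type_counts Named counts of domain types per merged age class
#'   (young classes plus `Old`).
#' @param new_gene_type_counts Named (per young class) counts of types found
#'   only in proteins of their own age.
#' @param young_type_totals Named totals of types per young class (the
#'   denominators of the previous counts). Defaults to the entries of
#'   `type_counts`.
#' @param scenario_counts Named counts: `gain_dependent`,
#'   `mutual_dependence`, `fusion`, `complex`.
#' @param n_young_only,n_combined Numbers of proteins with only young domains
#'   and with both young and old domains.
#' @return Tibble with `statistic`, `numerator`, `denominator`, `value`.
#' @examples
#' derived_percentages(type_counts = c(Old = 3039, Vertebrate = 363,
#'                                     Mammalian = 63))
#' @export
derived_percentages <- function(type_counts,
                                new_gene_type_counts = NULL,
                                young_type_totals = NULL,
                                scenario_counts = NULL,
                                n_young_only = NULL,
                                n_combined = NULL) {
  pct <- function(num, den) {
    if (is.null(den) || is.na(den) || den == 0) NA_real_
    else round_half_up(100 * num / den, 1)
  }
  rows <- list()
  add <- function(stat, num, den, value) {
    rows[[length(rows) + 1]] <<- tibble(
      statistic = stat, numerator = num,
      denominator = if (is.null(den)) NA_real_ else den, value = value)
  }
  young <- setdiff(names(type_counts), "Old")
  n_young_types <- sum(type_counts[young])
  n_total_types <- sum(type_counts)
  add("young_types_n", n_young_types, NA_real_, n_young_types)
  add("young_type_fraction_pct", n_young_types, n_total_types,
      pct(n_young_types, n_total_types))
  if (!is.null(new_gene_type_counts)) {
    if (is.null(young_type_totals)) {
      young_type_totals <- type_counts[names(new_gene_type_counts)]
    }
    for (ac in names(new_gene_type_counts)) {
      add(paste0(tolower(ac), "_types_in_new_genes_pct"),
          new_gene_type_counts[[ac]], young_type_totals[[ac]],
          pct(new_gene_type_counts[[ac]], young_type_totals[[ac]]))
    }
  }
  if (!is.null(scenario_counts) && !is.null(n_combined)) {
    gc_n <- sum(scenario_counts[c("gain_dependent", "mutual_dependence")],
                na.rm = TRUE)
    add("gain_compatible_pct", gc_n, n_combined, pct(gc_n, n_combined))
    add("fusion_pct", scenario_counts[["fusion"]], n_combined,
        pct(scenario_counts[["fusion"]], n_combined))
  }
  if (!is.null(n_young_only) && !is.null(n_combined)) {
    add("young_only_to_combined_ratio", n_young_only, n_combined,
        if (n_combined > 0) round_half_up(n_young_only / n_combined, 2)
        else NA_real_)
  }
  dplyr::bind_rows(rows)
}

empty_report <- function() {
  structure(
    list(domain_ages = tibble(), protein_ages = tibble(),
         architectures = tibble(), scenarios = tibble(), positions = tibble(),
         position_tests = tibble(), rates = tibble(), pairs = tibble(),
         group_comparison = NULL, summary = NULL,
         percentages = tibble(statistic = character(), numerator = double(),
                              denominator = double(), value = double()),
         log = list()),
    class = "domage_report"
  )
}

write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    if (!is.null(df) && is.data.frame(df) && nrow(df) > 0) {
      readr::write_tsv(df, file.path(outdir, paste0(name, ".tsv")))
    }
  }
  w(report$domain_ages, "domain_ages")
  w(report$protein_ages, "protein_ages")
  w(dplyr::mutate(report$architectures,
                  types = purrr::map_chr(.data$types, paste, collapse = ";")),
    "architectures")
  w(report$scenarios, "scenarios")
  w(report$positions, "positions")
  w(report$position_tests, "position_tests")
  w(report$rates, "rates")
  w(report$pairs, "pairs")
  w(report$percentages, "percentages")
  gl <- list(
    percentages = report$percentages,
    position_tests = report$position_tests,
    group_summary = if (!is.null(report$group_comparison))
      report$group_comparison$groups,
    ks_tests = if (!is.null(report$group_comparison))
      report$group_comparison$ks,
    wilcoxon = if (!is.null(report$group_comparison))
      report$group_comparison$wilcoxon,
    verdicts = if (nrow(report$pairs) > 0)
      as.list(table(report$pairs$verdict)),
    log = report$log
  )
  jsonlite::write_json(gl, file.path(outdir, "report.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(outdir)
}

#' @export
print.domage_report <- function(x, ...) {
  cat("<domage_report>\n")
  if (nrow(x$percentages) > 0) {
    cat("Derived statistics:\n"); print(x$percentages)
  }
  if (nrow(x$rates) > 0) {
    cat(sprintf("\nRates: %d estimates (%d passing filters)\n",
                nrow(x$rates), sum(x$rates$pass_filter)))
  }
  if (nrow(x$pairs) > 0) {
    cat("\nWithin-protein verdicts:\n"); print(table(x$pairs$verdict))
  }
  invisible(x)
}

#' @rdname tidy
#' @export
tidy.domage_report <- function(x, ...) x$percentages

#' @rdname tidy
#' @export
glance.domage_report <- function(x, ...) {
  tibble(
    n_domain_types = nrow(x$domain_ages),
    n_proteins = nrow(x$protein_ages),
    n_combined = nrow(x$scenarios),
    n_rate_estimates = nrow(x$rates),
    n_pass_filter = if (nrow(x$rates)) sum(x$rates$pass_filter) else 0L,
    n_pairs = nrow(x$pairs)
  )
}
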