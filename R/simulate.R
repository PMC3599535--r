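#' Parameters of the synthetic dataset generator
#'
#' Bundles every knob of the generator with defaults emulating the human
#' dataset at a reduced size: a 15-species/4-clade ranking; a type inventory
#' dominated by old types; a proteome mixing young-only, old-only and combined
#' (young + old) proteins with the young-only:combined ratio at 1.43; scenario
#' regimes for combined proteins at the observed class frequencies (243, 16,
#' 40, 31 of 330); a strong N-terminal insertion bias; per-age lognormal
#' omega distributions with medians 0.33 / 0.18 / 0.08 / 0.08
#' (Mammalian / Vertebrate / Metazoan / Eukarya) and a target pairwise dS of
#' 0.5, typical of human-mouse orthologues.
#'
#' @param seed Integer seed; the whole bundle is a deterministic function of
#'   the parameters.
#' @param ranking A [clade_ranking()].
#' @param n_types Named integer vector: domain types per age class.
#' @param loss_prob Per-species probability of secondary loss of a domain.
#' @param guarantee_origin Keep at least one species of the origin clade
#'   present (makes the oldest-hit rule exact).
#' @param composition Named counts of `young_only`, `old_only` and `combined`
#'   proteins.
#' @param scenario_probs Probabilities of the four arrangement regimes for
#'   combined proteins: `gain`, `mutual`, `fusion`, `complex`.
#' @param nterm_bias Probability that a young domain inserted into an existing
#'   architecture goes to the N-terminus; the remainder is split equally
#'   between C-terminal and internal (all to C-terminal when there is a single
#'   old domain).
#' @param duplication_rate Probability that an emitted protein is duplicated
#'   whole (same architecture, new id).
#' @param omega_medians Named per-age medians of the lognormal omega
#'   distribution for domain regions.
#' @param omega_sdlog Log-sd of the omega distribution.
#' @param linker_omega Omega used for inter-domain linker sequence.
#' @param target_ds Target pairwise synonymous divergence per orthologue pair.
#' @param region_len_meanlog,region_len_sdlog Lognormal parameters of domain
#'   region length (aa); lengths are clipped to `[60, 400]`.
#' @param fail_fraction Fraction of domain regions deliberately drawn shorter
#'   than 60 aa so that length filtering is exercised.
#' @param linker_range Uniform range (aa) of linker lengths.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(seed = 1L,
                       ranking = default_clade_ranking(),
                       n_types = c(Mammalian = 30, Vertebrate = 130,
                                   Metazoan = 60, Eukarya = 90),
                       loss_prob = 0.2,
                       guarantee_origin = TRUE,
                       composition = c(young_only = 86, old_only = 154,
                                       combined = 60),
                       scenario_probs = c(gain = 243, mutual = 16,
                                          fusion = 40, complex = 31) / 330,
                       nterm_bias = 0.6,
                       duplication_rate = 0.05,
                       omega_medians = c(Mammalian = 0.33, Vertebrate = 0.18,
                                         Metazoan = 0.08, Eukarya = 0.08),
                       omega_sdlog = 0.5,
                       linker_omega = 0.5,
                       target_ds = 0.5,
                       region_len_meanlog = log(120),
                       region_len_sdlog = 0.35,
                       fail_fraction = 0.05,
                       linker_range = c(5, 50)) {
  p <- list(seed = as.integer(seed), ranking = ranking, n_types = n_types,
            loss_prob = loss_prob, guarantee_origin = guarantee_origin,
            composition = composition, scenario_probs = scenario_probs,
            nterm_bias = nterm_bias, duplication_rate = duplication_rate,
            omega_medians = omega_medians, omega_sdlog = omega_sdlog,
            linker_omega = linker_omega, target_ds = target_ds,
            region_len_meanlog = region_len_meanlog,
            region_len_sdlog = region_len_sdlog,
            fail_fraction = fail_fraction, linker_range = linker_range)
  validate_sim_params(p)
  structure(p, class = "sim_params")
}

validate_sim_params <- function(p) {
  probs <- c(p$loss_prob, p$nterm_bias, p$duplication_rate, p$fail_fraction,
             p$scenario_probs)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0,1]", call. = FALSE)
  if (abs(sum(p$scenario_probs) - 1) > 1e-8) {
    stop("scenario_probs must sum to 1", call. = FALSE)
  }
  if (any(p$n_types < 0) || any(p$composition < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (!setequal(names(p$n_types), p$ranking$ages)) {
    stop("n_types must name every age class of the ranking", call. = FALSE)
  }
  if (!all(c("young_only", "old_only", "combined") %in% names(p$composition))) {
    stop("composition needs young_only, old_only and combined counts", call. = FALSE)
  }
  if (p$composition[["combined"]] > 0 &&
      sum(p$n_types[is_young(names(p$n_types), p$ranking)]) == 0) {
    stop("combined proteins requested but no young domain types", call. = FALSE)
  }
  invisible(p)
}

#' Simulate phyletic profiles with secondary losses
#'
#' Each domain type is given an origin clade according to its age: presence in
#' every species of the origin clade and of all younger clades, then
#' independent losses at `loss_prob`. With `guarantee_origin` one species of
#' the origin clade is kept present, which makes the oldest-hit dating rule
#' recover the true age exactly. A type of the youngest age may lose all its
#' flags (reference-lineage-specific pattern) unless the guarantee is on.
#'
#' @param params A [sim_params()]. The caller controls the RNG (see
#'   [simulate_dataset()] for a fully seeded bundle).
#' @return List with `profiles` (tibble: `domain_type_id` + one 0/1 column per
#'   species) and `types` (truth tibble: `domain_type_id`, `true_age`).
#' @export
simulate_profiles <- function(params) {
  validate_sim_params(params)
  rk <- params$ranking
  ages <- rep(rk$ages, times = params$n_types[rk$ages])
  prefix <- toupper(substr(rk$ages, 1, 3))
  ids <- unlist(lapply(seq_along(rk$ages), function(i) {
    n <- params$n_types[[rk$ages[i]]]
    if (n == 0) character(0) else sprintf("%s%04d", prefix[i], seq_len(n))
  }))
  mat <- matrix(0L, nrow = length(ids), ncol = length(rk$species),
                dimnames = list(NULL, rk$species))
  for (i in seq_along(ids)) {
    r <- match(ages[i], rk$ages)
    present_sp <- unlist(rk$clades[seq_len(r)], use.names = FALSE)
    keep <- runif(length(present_sp)) >= params$loss_prob
    if (params$guarantee_origin) {
      origin_sp <- rk$clades[[r]]
      if (!any(keep[present_sp %in% origin_sp])) {
        survivor <- origin_sp[sample.int(length(origin_sp), 1)]
        keep[present_sp == survivor] <- TRUE
      }
    }
    mat[i, present_sp[keep]] <- 1L
  }
  profiles <- dplyr::bind_cols(tibble(domain_type_id = ids),
                               as_tibble(as.data.frame(mat)))
  list(profiles = profiles,
       types = tibble(domain_type_id = ids, true_age = ages))
}

#' Simulate a proteome of domain architectures
#'
#' Builds young-only, old-only and combined proteins per the composition.
#' Combined proteins receive a fresh young type inserted into an architecture
#' of old types under one of four regimes: `gain` (old types shared with
#' old-only proteins, young type exclusive), `mutual` (one exclusive old
#' type), `fusion` (shared old types, and the young type is also emitted as a
#' standalone young-only protein) and `complex` (one shared plus one exclusive
#' old type, so the type pairs disagree). The insertion position follows the
#' N-terminal bias. Whole proteins are duplicated at `duplication_rate`.
#'
#' @param params A [sim_params()].
#' @param types Type truth tibble from [simulate_profiles()].
#' @return List of tibbles: `hits` (protein_id, domain_type_id, start, end,
#'   evalue), `proteins` (protein_id, length_aa, n_domains, true_age, regime,
#'   young_position) and `regions` (one row per domain occurrence, with its
#'   true omega and target dS).
#' @export
simulate_proteome <- function(params, types) {
  validate_sim_params(params)
  rk <- params$ranking
  young_pool <- types$domain_type_id[is_young(types$true_age, rk)]
  old_pool <- types$domain_type_id[!is_young(types$true_age, rk)]
  age_of <- setNames(types$true_age, types$domain_type_id)
  comp <- params$composition
  n_comb <- comp[["combined"]]; n_yo <- comp[["young_only"]]
  n_oo <- comp[["old_only"]]

  regimes <- if (n_comb > 0) {
    sample(names(params$scenario_probs), n_comb, replace = TRUE,
           prob = params$scenario_probs)
  } else character(0)
  n_fusion <- sum(regimes == "fusion")
  if (n_fusion > n_yo) {
    stop("composition cannot host the fusion regimes: need ", n_fusion,
         " young-only proteins, have ", n_yo, call. = FALSE)
  }
  n_excl_old <- sum(regimes %in% c("mutual", "complex"))
  if (length(old_pool) < n_excl_old + 1 && (n_comb > 0 || n_oo > 0)) {
    stop("not enough old domain types", call. = FALSE)
  }
  old_pool <- sample(old_pool)
  excl_old <- head(old_pool, n_excl_old)
  shared_candidates <- setdiff(old_pool, excl_old)

  # old-only proteins; cycling through the shared pool guarantees every shared
  # type used by a combined protein also occurs in an old-only configuration
  oo_sizes <- if (n_oo > 0) sample(1:3, n_oo, replace = TRUE) else integer(0)
  n_slots <- sum(oo_sizes)
  shared_pool <- head(shared_candidates, min(length(shared_candidates), n_slots))
  if (n_comb > 0 && length(shared_pool) == 0) {
    stop("combined proteins need old types shared with old-only proteins",
         call. = FALSE)
  }
  slot_types <- if (n_slots > 0) {
    extra <- if (n_slots > length(shared_pool)) {
      sample(shared_pool, n_slots - length(shared_pool), replace = TRUE)
    } else character(0)
    sample(c(shared_pool, extra))   # every shared type lands in >=1 slot
  } else character(0)

  # young types: fresh per combined protein, then per young-only protein
  n_young_needed <- n_comb + (n_yo - n_fusion)
  if (length(young_pool) < n_young_needed) {
    stop("not enough young domain types: need ", n_young_needed,
         ", have ", length(young_pool), call. = FALSE)
  }
  young_pool <- sample(young_pool)
  comb_young <- head(young_pool, n_comb)
  solo_young <- young_pool[n_comb + seq_len(n_yo - n_fusion)]

  proteins <- list(); hits <- list(); regions <- list()
  pid <- 0L
  add_protein <- function(type_vec, true_age, regime, young_pos) {
    pid <<- pid + 1L
    id <- sprintf("P%05d", pid)
    n <- length(type_vec)
    linkers <- sample(seq(params$linker_range[1], params$linker_range[2]),
                      n + 1, replace = TRUE)
    lens <- region_lengths(n, params)
    cur <- 0L
    st <- integer(n); en <- integer(n)
    for (j in seq_len(n)) {
      cur <- cur + linkers[j]
      st[j] <- cur + 1L
      cur <- cur + lens[j]
      en[j] <- cur
    }
    total_len <- cur + linkers[n + 1]
    proteins[[length(proteins) + 1]] <<- tibble(
      protein_id = id, length_aa = total_len, n_domains = n,
      true_age = true_age, regime = regime,
      young_position = young_pos %||% NA_character_
    )
    hits[[length(hits) + 1]] <<- tibble(
      protein_id = id, domain_type_id = type_vec, start = st, end = en,
      evalue = 10^-runif(n, 6, 40)
    )
    om <- vapply(type_vec, function(tp) {
      rlnorm(1, meanlog = log(params$omega_medians[[age_of[[tp]]]]),
             sdlog = params$omega_sdlog)
    }, double(1))
    regions[[length(regions) + 1]] <<- tibble(
      protein_id = id, domain_type_id = type_vec, start = st, end = en,
      length_aa = lens, true_omega = unname(om),
      true_ds = params$target_ds
    )
    id
  }

  slot_i <- 0L
  for (i in seq_len(n_oo)) {
    m <- oo_sizes[i]
    tv <- unique(slot_types[slot_i + seq_len(m)])
    slot_i <- slot_i + m
    add_protein(tv, oldest_age(age_of[tv], rk), "old_only", NULL)
  }
  for (i in seq_len(n_comb)) {
    reg <- regimes[i]
    v <- comb_young[i]
    old_types <- switch(reg,
      gain = sample(shared_pool, min(sample(1:3, 1), length(shared_pool))),
      fusion = sample(shared_pool, min(sample(1:3, 1), length(shared_pool))),
      mutual = excl_old[match(i, which(regimes %in% c("mutual", "complex")))],
      complex = c(sample(shared_pool, 1),
                  excl_old[match(i, which(regimes %in% c("mutual", "complex")))])
    )
    ins <- insert_young(old_types, v, params$nterm_bias)
    add_protein(ins$types, oldest_age(age_of[old_types], rk), reg, ins$position)
  }
  for (v in solo_young) add_protein(v, age_of[[v]], "young_only", NULL)
  for (v in comb_young[regimes == "fusion"]) {
    add_protein(v, age_of[[v]], "young_only_fusion_partner", NULL)
  }

  proteins <- dplyr::bind_rows(proteins)
  hits <- dplyr::bind_rows(hits)
  regions <- dplyr::bind_rows(regions)

  # whole-protein duplication
  dup <- proteins$protein_id[runif(nrow(proteins)) < params$duplication_rate]
  if (length(dup) > 0) {
    copy_id <- setNames(sprintf("P%05d", pid + seq_along(dup)), dup)
    dup_rows <- function(df) {
      d <- df[df$protein_id %in% dup, ]
      d$protein_id <- unname(copy_id[d$protein_id])
      d
    }
    proteins <- dplyr::bind_rows(proteins, dup_rows(proteins))
    hits2 <- dup_rows(hits)
    if (nrow(hits2)) hits2$evalue <- 10^-runif(nrow(hits2), 6, 40)
    hits <- dplyr::bind_rows(hits, hits2)
    regions <- dplyr::bind_rows(regions, dup_rows(regions))
  }
  list(proteins = proteins, hits = hits, regions = regions)
}

oldest_age <- function(ages, ranking) {
  as.character(max(age_factor(ages, ranking)))
}

region_lengths <- function(n, params) {
  fail <- runif(n) < params$fail_fraction
  len <- pmin(400, pmax(60, round(rlnorm(n, params$region_len_meanlog,
                                         params$region_len_sdlog))))
  len[fail] <- sample(30:59, sum(fail), replace = TRUE)
  len
}

insert_young <- function(old_types, young_type, beta) {
  m <- length(old_types)
  u <- runif(1)
  if (u < beta) {
    list(types = c(young_type, old_types), position = "N_terminal")
  } else if (m == 1 || u < beta + (1 - beta) / 2) {
    list(types = c(old_types, young_type), position = "C_terminal")
  } else {
    slot <- sample.int(m - 1, 1)   # after old domain `slot`
    list(types = append(old_types, young_type, after = slot),
         position = "internal")
  }
}

#' Simulate one pairwise codon alignment under selection
#'
#' Draws an ancestor of random sense codons and derives a second sequence by
#' a per-nucleotide-site substitution process: each site changes at most once,
#' synonymous changes occur with probability `pS * s_i` and nonsynonymous
#' changes with `pN * (1 - s_i)`, where `s_i` is the site's NG86 synonymous
#' fraction and `pS`, `pN` are the inverse Jukes-Cantor transforms of
#' `target_ds` and `omega * target_ds`. Changes creating stop codons are never
#' proposed. The result is an ungapped aligned pair whose expected NG86
#' estimates equal the targets.
#'
#' @param length_codons Number of codons.
#' @param omega Target dN/dS.
#' @param target_ds Target synonymous divergence (per synonymous site).
#' @param seed Optional integer seed (set only when supplied, so the function
#'   can also run inside an already-seeded simulation).
#' @return A [codon_alignment_pair()] with attribute `truth` (list with
#'   `omega`, `target_ds`).
#' @export
simulate_codon_pair <- function(length_codons, omega, target_ds, seed = NULL) {
  stopifnot(length_codons >= 1, omega >= 0, target_ds >= 0)
  if (!is.null(seed)) set.seed(seed)
  pS <- inv_jc(target_ds)
  pN <- inv_jc(omega * target_ds)
  if (is.na(pS) || is.na(pN) || pS >= 0.75 || pN >= 0.75) {
    stop("saturating targets: expected proportion of differences >= 3/4",
         call. = FALSE)
  }
  tab <- codon_tables()
  anc <- tab$sense[sample.int(length(tab$sense), length_codons, replace = TRUE)]
  der <- mutate_codons(anc, pS, pN, tab)
  pair <- structure(
    list(ref = anc, alt = der, ids = c("ref", "derived")),
    class = "codon_alignment_pair"
  )
  attr(pair, "truth") <- list(omega = omega, target_ds = target_ds)
  pair
}

inv_jc <- function(d) 0.75 * (1 - exp(-4 * d / 3))

# one sweep over the three codon positions; classification of a site follows
# the current codon, so within-codon double hits interact realistically
mutate_codons <- function(codons, pS, pN, tab = codon_tables()) {
  cur <- codons
  for (p in 1:3) {
    idx <- match(cur, tab$sense)
    s_i <- tab$s_frac[cbind(idx, p)]
    psyn <- pS * s_i
    pnon <- pN * (1 - s_i)
    u <- runif(length(cur))
    syn_hit <- which(u < psyn)
    non_hit <- which(u >= psyn & u < psyn + pnon)
    for (i in syn_hit) {
      alts <- tab$syn_alts[[(idx[i] - 1) * 3 + p]]
      if (length(alts)) cur[i] <- alts[sample.int(length(alts), 1)]
    }
    for (i in non_hit) {
      alts <- tab$non_alts[[(idx[i] - 1) * 3 + p]]
      if (length(alts)) cur[i] <- alts[sample.int(length(alts), 1)]
    }
  }
  cur
}

#' Simulate a complete analysis-ready bundle with its truth ledger
#'
#' Runs [simulate_profiles()], [simulate_proteome()] and per-protein codon
#' alignment simulation under one seed. Each protein's coding alignment is the
#' concatenation of linker and domain segments; each domain region evolves at
#' its own true omega, linkers at `linker_omega`, all at the common target dS.
#'
#' @param params A [sim_params()].
#' @return List of class `sim_bundle`: `profiles`, `types`, `proteins`,
#'   `hits`, `regions`, `alignments` (tibble `protein_id`, `ref`, `alt` as
#'   nucleotide strings) and `params`.
#' @export
simulate_dataset <- function(params = sim_params()) {
  validate_sim_params(params)
  set.seed(params$seed)
  prof <- simulate_profiles(params)
  prot <- simulate_proteome(params, prof$types)
  aln <- purrr::map_dfr(unique(prot$proteins$protein_id), function(id) {
    simulate_protein_alignment(id, prot, params)
  })
  structure(
    list(profiles = prof$profiles, types = prof$types,
         proteins = prot$proteins, hits = prot$hits, regions = prot$regions,
         alignments = aln, params = params),
    class = "sim_bundle"
  )
}

simulate_protein_alignment <- function(id, prot, params) {
  len <- prot$proteins$length_aa[prot$proteins$protein_id == id][1]
  regs <- prot$regions[prot$regions$protein_id == id, ]
  regs <- regs[order(regs$start), ]
  ref <- character(len); alt <- character(len)
  segs <- segment_spans(len, regs)
  for (s in seq_len(nrow(segs))) {
    n <- segs$end[s] - segs$start[s] + 1
    om <- if (is.na(segs$omega[s])) params$linker_omega else segs$omega[s]
    pr <- simulate_codon_pair(n, om, params$target_ds)
    ref[segs$start[s]:segs$end[s]] <- pr$ref
    alt[segs$start[s]:segs$end[s]] <- pr$alt
  }
  tibble(protein_id = id,
         ref = paste(ref, collapse = ""), alt = paste(alt, collapse = ""))
}

# alternate linker/domain spans covering 1..len; omega NA marks linkers
segment_spans <- function(len, regs) {
  spans <- tibble(start = integer(), end = integer(), omega = double())
  cur <- 1L
  for (i in seq_len(nrow(regs))) {
    if (regs$start[i] > cur) {
      spans <- tibble::add_row(spans, start = cur, end = regs$start[i] - 1L,
                              omega = NA_real_)
    }
    spans <- tibble::add_row(spans, start = regs$start[i], end = regs$end[i],
                            omega = regs$true_omega[i])
    cur <- regs$end[i] + 1L
  }
  if (cur <= len) {
    spans <- tibble::add_row(spans, start = cur, end = len, omega = NA_real_)
  }
  spans
}

#' @export
print.sim_bundle <- function(x, ...) {
  cat(sprintf(
    "<sim_bundle> seed %d: %d domain types, %d proteins, %d domain hits, %d alignments\n",
    x$params$seed, nrow(x$types), nrow(x$proteins), nrow(x$hits),
    nrow(x$alignments)))
  invisible(x)
}
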