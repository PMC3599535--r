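test_that("per-codon site counts match frozen values and the code's structure", {
  s <- ng86_sites("TTT")
  expect_equal(s$s_sites, 1 / 3)
  expect_equal(s$n_sites, 8 / 3)
  expect_equal(ng86_sites("TGG")$s_sites, 0)    # Trp: every change is nonsyn
  expect_equal(ng86_sites("CTG")$s_sites, 4 / 3) # Leu: 3rd pos 4-fold + 1st pos TTG
  expect_error(ng86_sites("TAA"), "sense codon")
  expect_error(ng86_sites("NTT"), "sense codon")
  # vectorised and n + s == 3 always
  all61 <- ng86_sites(domainage:::codon_tables()$sense)
  expect_equal(all61$n_sites + all61$s_sites, rep(3, 61))
})

test_that("site counts agree with an independent genetic-code oracle on all 61 codons", {
  for (cd in domainage:::codon_tables()$sense) {
    want <- oracle_sites(cd)
    got <- ng86_sites(cd)
    expect_equal(got$s_sites, want[["s"]], tolerance = 1e-12)
    expect_equal(got$n_sites, want[["n"]], tolerance = 1e-12)
  }
})

test_that("pathway-averaged difference counts agree with recursive enumeration", {
  pm <- domainage:::pair_count_matrices()
  sense <- domainage:::codon_tables()$sense
  set.seed(11)
  pairs <- cbind(sample(sense, 120, replace = TRUE),
                 sample(sense, 120, replace = TRUE))
  for (i in seq_len(nrow(pairs))) {
    want <- oracle_pair_counts(pairs[i, 1], pairs[i, 2])
    expect_equal(pm$nd[pairs[i, 1], pairs[i, 2]], want[["nd"]], tolerance = 1e-12)
    expect_equal(pm$sd[pairs[i, 1], pairs[i, 2]], want[["sd"]], tolerance = 1e-12)
  }
  # counting is symmetric and total differences equal the Hamming distance
  expect_equal(pm$nd, t(pm$nd))
  expect_equal(pm$sd, t(pm$sd))
  ham <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  for (i in 1:40) {
    a <- sample(sense, 1); b <- sample(sense, 1)
    tot <- pm$nd[a, b] + pm$sd[a, b]
    if (!is.na(tot)) expect_equal(tot, ham(a, b))
  }
})

test_that("alignment container validates structure", {
  p <- codon_alignment_pair("ATGAAA", "ATGAAG")
  expect_s3_class(p, "codon_alignment_pair")
  expect_identical(p$ref, c("ATG", "AAA"))
  expect_error(codon_alignment_pair("ATGAAA", "ATG"), "lengths differ")
  expect_error(codon_alignment_pair("ATGA", "ATGC"), "divisible by 3")
  expect_error(codon_alignment_pair("AT-GAA", "ATGGAA"), "whole codons")
  expect_error(codon_alignment_pair("ATGTAA", "ATGAAA"), "stop codon")
})

test_that("identical sequences give zero rates; a known pair gives known counts", {
  p <- codon_alignment_pair("ATGAAACCC", "ATGAAACCC")
  e <- estimate_dnds(p)
  expect_equal(e$Nd, 0)
  expect_equal(e$Sd, 0)
  expect_equal(e$dN, 0)
  expect_equal(e$dS, 0)
  expect_true(is.na(e$omega))

  # TTT->TTA is Phe->Leu: one nonsynonymous difference, no synonymous
  e <- estimate_dnds(codon_alignment_pair("TTTTTT", "TTATTT"))
  expect_equal(e$Nd, 1)
  expect_equal(e$Sd, 0)
  expect_gt(e$dN, 0)
  expect_equal(e$dS, 0)
  expect_true(is.na(e$omega))

  # TTT->TTC is synonymous (longer region so pS stays below saturation)
  e <- estimate_dnds(codon_alignment_pair(strrep("TTT", 6),
                                          paste0("TTC", strrep("TTT", 5))))
  expect_equal(e$Nd, 0)
  expect_equal(e$Sd, 1)
  expect_equal(e$dN, 0)
  expect_gt(e$dS, 0)
  expect_equal(e$omega, 0)
})

test_that("estimates are symmetric in sequence order", {
  set.seed(22)
  for (i in 1:20) {
    rp <- random_codon_pair(40, sample(1:10, 1))
    e1 <- estimate_dnds(pair_from_codons(rp$ref, rp$alt))
    e2 <- estimate_dnds(pair_from_codons(rp$alt, rp$ref))
    expect_equal(e1$dN, e2$dN, tolerance = 1e-12)
    expect_equal(e1$dS, e2$dS, tolerance = 1e-12)
    expect_equal(e1$N_sites, e2$N_sites, tolerance = 1e-12)
  }
})

test_that("full estimates agree with the independent oracle on random pairs", {
  set.seed(23)
  for (i in 1:50) {
    rp <- random_codon_pair(sample(10:40, 1), sample(0:8, 1))
    want <- oracle_dnds(rp$ref, rp$alt)
    p_n <- want$Nd / want$N_sites
    p_s <- if (want$S_sites > 0) want$Sd / want$S_sites else 0
    if (p_n >= 0.75 || p_s >= 0.75) {
      expect_error(estimate_dnds(pair_from_codons(rp$ref, rp$alt)),
                   "saturation")
      next
    }
    got <- estimate_dnds(pair_from_codons(rp$ref, rp$alt))
    expect_equal(got$N_sites, want$N_sites, tolerance = 1e-10)
    expect_equal(got$S_sites, want$S_sites, tolerance = 1e-10)
    expect_equal(got$Nd, want$Nd, tolerance = 1e-10)
    expect_equal(got$Sd, want$Sd, tolerance = 1e-10)
    expect_equal(got$dN, want$dN, tolerance = 1e-10)
    expect_equal(got$dS, want$dS, tolerance = 1e-10)
  }
})

test_that("more differences never lower the total difference count", {
  set.seed(24)
  ref <- random_codon_pair(60, 0)$ref
  prev <- 0
  for (nd in c(2, 5, 10, 20)) {
    set.seed(100 + nd)
    alt <- ref
    for (i in sample(60, nd)) {
      repeat {
        cand <- sample(domainage:::codon_tables()$sense, 1)
        if (cand != alt[i]) { alt[i] <- cand; break }
      }
    }
    e <- estimate_dnds(pair_from_codons(ref, alt))
    tot <- e$Nd + e$Sd
    expect_gte(tot, prev)
    prev <- tot
  }
})

test_that("gapped and ambiguous codon columns are skipped", {
  # middle codon gapped in alt: only 2 codon pairs compared
  p <- codon_alignment_pair("ATGAAACCC", "ATG---CCC")
  e <- estimate_dnds(p)
  expect_equal(e$aligned_aa_length, 2)
  p <- codon_alignment_pair("ATGANACCC", "ATGAAACCC")
  expect_equal(estimate_dnds(p)$aligned_aa_length, 2)
  expect_error(estimate_dnds(codon_alignment_pair("---", "ATG")),
               "no comparable codons")
})

test_that("saturated regions raise an error rather than a corrected estimate", {
  # every codon differs at all 3 positions nonsynonymously: pN >= 3/4
  ref <- rep("AAA", 30)  # Lys
  alt <- rep("TGC", 30)  # Cys (TGT/TGC); AAA->TGC is 3 nonsyn changes
  expect_error(estimate_dnds(pair_from_codons(ref, alt)), "saturation")
})

test_that("domain regions are cut on ungapped reference coordinates", {
  p <- codon_alignment_pair("ATGAAACCCGGG", "ATGAAACCCGGG")
  r <- extract_domain_region(p, 1, 4)
  expect_identical(r$ref, c("ATG", "AAA", "CCC", "GGG"))
  r <- extract_domain_region(p, 2, 3)
  expect_identical(r$ref, c("AAA", "CCC"))
  expect_error(extract_domain_region(p, 0, 2), "invalid")
  expect_error(extract_domain_region(p, 3, 2), "invalid")
  expect_error(extract_domain_region(p, 2, 9), "exceed")

  # reference gap inside the span is kept; one after the span is not
  p <- codon_alignment_pair("ATG---AAACCC", "ATGTTTAAACCC")
  r <- extract_domain_region(p, 1, 2)
  expect_identical(r$ref, c("ATG", "---", "AAA"))
  expect_identical(r$alt, c("ATG", "TTT", "AAA"))
  r <- extract_domain_region(p, 2, 3)
  expect_identical(r$ref, c("AAA", "CCC"))

  set.seed(31)
  for (i in 1:25) {
    n <- sample(6:15, 1)
    ref <- sample(domainage:::codon_tables()$sense, n, replace = TRUE)
    alt <- ref
    gaps <- sample(2:(n - 1), sample(0:2, 1))
    ref[gaps] <- "---"
    pr <- codon_alignment_pair(paste(ref, collapse = ""),
                               paste(alt, collapse = ""))
    n_aa <- sum(ref != "---")
    s <- sample(seq_len(n_aa - 1), 1)
    e <- sample(s:n_aa, 1)
    got <- extract_domain_region(pr, s, e)
    want <- oracle_extract(ref, alt, s, e)
    expect_identical(got$ref, want$ref)
    expect_identical(got$alt, want$alt)
  }
})

test_that("reliability filters keep boundaries and retain failing rows", {
  est <- tibble::tibble(
    aligned_aa_length = c(59, 60, 100, 100, 100),
    dN = c(0.1, 0.5, 0.6, 0.1, 0.1),
    dS = c(0.5, 2.0, 0.5, 2.01, 0.5)
  )
  out <- apply_filters(est)
  expect_equal(out$pass_filter, c(FALSE, TRUE, FALSE, FALSE, TRUE))
  expect_equal(nrow(out), 5)   # nothing dropped
  out2 <- apply_filters(est, min_aa = 30, max_dn = 1, max_ds = 3)
  expect_true(all(out2$pass_filter))
})

test_that("relative difference matches its closed form and bounds", {
  expect_equal(relative_difference(0.4, 0.1), 0.75)
  expect_equal(relative_difference(0.1, 0.4), -0.75)
  expect_equal(relative_difference(0, 0), 0)
  expect_equal(relative_difference(0.3, 0.3), 0)
  expect_equal(relative_difference(0.5, 0), 1)
  expect_equal(relative_difference(0, 0.5), -1)
  expect_error(relative_difference(-0.1, 0.5), "non-negative")
  expect_error(relative_difference(NA, 0.5), "undefined")
  set.seed(40)
  y <- runif(100, 0, 2); o <- runif(100, 0, 2)
  rd <- relative_difference(y, o)
  expect_true(all(rd >= -1 & rd <= 1))
  expect_equal(rd, -relative_difference(o, y))  # antisymmetry
})

test_that("paired binomial test matches binomial tails and handles degeneracy", {
  # young counts exactly at the old-implied expectation: p close to 1
  young <- tibble::tibble(Nd = 50, Sd = 50, N_sites = 300, S_sites = 100)
  old <- tibble::tibble(Nd = 30, Sd = 10, N_sites = 300, S_sites = 100)
  # rn = 30/300 = 0.1, rs = 10/100 = 0.1 -> p0 = 30/40 = 0.75;
  # observed 50/100 = 0.5 -> young slower
  r <- paired_binomial_test(young, old)
  expect_equal(r$p0, 0.75)
  expect_equal(r$successes, 50)
  expect_equal(r$trials, 100)
  expect_equal(r$p_value, oracle_binom_p(50, 100, 0.75), tolerance = 1e-9)
  expect_identical(r$verdict, "old_faster")

  # strong excess of nonsynonymous changes in the young domain
  young <- tibble::tibble(Nd = 50, Sd = 5, N_sites = 200, S_sites = 70)
  old <- tibble::tibble(Nd = 10, Sd = 35, N_sites = 200, S_sites = 70)
  r <- paired_binomial_test(young, old)
  expect_lt(r$p_value, 0.01)
  expect_identical(r$verdict, "young_faster")
  expect_equal(r$p_value, oracle_binom_p(50, 55, r$p0), tolerance = 1e-9)

  # counts are rounded half-up before testing
  young <- tibble::tibble(Nd = 10.5, Sd = 4.25, N_sites = 100, S_sites = 40)
  r <- paired_binomial_test(young, old)
  expect_equal(r$successes, 11)
  expect_equal(r$trials, 15)

  # unadjusted null uses the raw old substitution split
  young <- tibble::tibble(Nd = 8, Sd = 8, N_sites = 100, S_sites = 100)
  old <- tibble::tibble(Nd = 30, Sd = 10, N_sites = 300, S_sites = 50)
  r <- paired_binomial_test(young, old, site_adjusted = FALSE)
  expect_equal(r$p0, 0.75)

  # degenerate: no substitutions in the young domain
  young0 <- tibble::tibble(Nd = 0, Sd = 0, N_sites = 100, S_sites = 40)
  r <- paired_binomial_test(young0, old)
  expect_true(r$degenerate)
  expect_identical(r$verdict, "no_difference")
  expect_true(is.na(r$p_value))
  # degenerate: old has no substitutions at all -> p0 undefined
  old0 <- tibble::tibble(Nd = 0, Sd = 0, N_sites = 100, S_sites = 40)
  r <- paired_binomial_test(young, old0)
  expect_true(r$degenerate)
  # p0 = 0 contradicted by observed nonsynonymous changes
  oldS <- tibble::tibble(Nd = 0, Sd = 20, N_sites = 100, S_sites = 40)
  r <- paired_binomial_test(young, oldS)
  expect_true(r$degenerate)
  # p0 = 0 with x = 0 is a valid (if trivial) test
  youngS <- tibble::tibble(Nd = 0, Sd = 10, N_sites = 100, S_sites = 40)
  r <- paired_binomial_test(youngS, oldS)
  expect_false(r$degenerate)
  expect_equal(r$p_value, 1)
})

test_that("group comparisons report distribution tests and medians", {
  set.seed(55)
  x <- runif(60)
  rates <- tibble::tibble(
    age_class_merged = rep(c("Mammalian", "Old"), each = 60),
    omega = c(x, x)
  )
  cmp <- compare_age_groups(rates)
  expect_equal(cmp$ks$statistic, 0)
  expect_equal(cmp$ks$p_value, 1)
  expect_equal(cmp$groups$median[1], cmp$groups$median[2])

  rates2 <- tibble::tibble(
    age_class_merged = rep(c("Mammalian", "Old"), each = 100),
    omega = c(runif(100, 0.5, 1.5), runif(100, 0, 0.3))
  )
  cmp2 <- compare_age_groups(rates2)
  expect_lt(cmp2$ks$p_value, 1e-5)
  expect_gt(cmp2$groups$median[cmp2$groups$group == "Mammalian"],
            cmp2$groups$median[cmp2$groups$group == "Old"])

  # tiny group: KS skipped, not errored
  rates3 <- dplyr::bind_rows(rates2,
    tibble::tibble(age_class_merged = "Vertebrate", omega = 0.2))
  cmp3 <- compare_age_groups(rates3)
  expect_true(any(cmp3$ks$skipped))
  expect_false(all(cmp3$ks$skipped))

  # single group errors
  expect_error(compare_age_groups(rates2[rates2$age_class_merged == "Old", ]),
               "two age groups")

  # paired Wilcoxon detects a consistent within-protein shift
  prs <- tibble::tibble(omega_young = runif(40, 0.4, 0.8),
                        omega_old = runif(40, 0.0, 0.2))
  cmp4 <- compare_age_groups(rates2, pairs = prs)
  expect_lt(cmp4$wilcoxon$p_value, 1e-5)
  expect_equal(cmp4$wilcoxon$n_pairs, 40)

  # by_type collapses abundant types to one median each
  rates5 <- tibble::tibble(
    age_class_merged = rep(c("Mammalian", "Old"), c(90, 10)),
    omega = c(rep(0.9, 90), runif(10, 0, 0.2)),
    domain_type_id = c(rep("M1", 90), paste0("O", 1:10))
  )
  cmp5 <- compare_age_groups(rates5, by_type = TRUE)
  expect_equal(cmp5$groups$n[cmp5$groups$group == "Mammalian"], 1L)

  # broom-style accessors
  expect_identical(tidy(cmp4), cmp4$ks)
  g <- glance(cmp4)
  expect_equal(g$n_groups, 2L)
  expect_equal(g$wilcoxon_p, cmp4$wilcoxon$p_value)
})
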