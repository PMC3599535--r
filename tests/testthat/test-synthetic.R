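test_that("parameter validation rejects impossible settings", {
  expect_error(sim_params(loss_prob = 1.5), "\\[0,1\\]")
  expect_error(sim_params(scenario_probs = c(gain = 0.5, mutual = 0.1,
                                             fusion = 0.1, complex = 0.1)),
               "sum to 1")
  expect_error(sim_params(n_types = c(Mammalian = -1, Vertebrate = 10,
                                      Metazoan = 10, Eukarya = 10)),
               "non-negative")
  expect_error(sim_params(n_types = c(Mammalian = 10)), "every age class")
  expect_error(sim_params(composition = c(young_only = 5, old_only = 5)),
               "combined")
  # combined proteins need young types to exist
  expect_error(sim_params(n_types = c(Mammalian = 0, Vertebrate = 0,
                                      Metazoan = 10, Eukarya = 10)),
               "no young domain types")
})

test_that("simulated profiles respect origin clades", {
  p <- sim_params(seed = 3, loss_prob = 0)
  set.seed(p$seed)
  prof <- simulate_profiles(p)
  rk <- p$ranking
  expect_equal(nrow(prof$profiles), sum(p$n_types))
  # zero loss: presence is exactly the origin clade plus all younger clades
  mat <- as.matrix(prof$profiles[rk$species])
  for (i in seq_len(nrow(mat))) {
    r <- match(prof$types$true_age[i], rk$ages)
    expected_sp <- unlist(rk$clades[seq_len(r)], use.names = FALSE)
    expect_setequal(rk$species[mat[i, ] == 1], expected_sp)
  }
  # no presence ever outside the origin span, whatever the loss rate
  p2 <- sim_params(seed = 4, loss_prob = 0.6)
  set.seed(p2$seed)
  prof2 <- simulate_profiles(p2)
  mat2 <- as.matrix(prof2$profiles[rk$species])
  for (i in seq_len(nrow(mat2))) {
    r <- match(prof2$types$true_age[i], rk$ages)
    allowed <- unlist(rk$clades[seq_len(r)], use.names = FALSE)
    expect_true(all(rk$species[mat2[i, ] == 1] %in% allowed))
  }
})

test_that("proteome composition and regime bookkeeping are conserved", {
  p <- sim_params(seed = 12, duplication_rate = 0)
  set.seed(p$seed)
  prof <- simulate_profiles(p)
  prot <- simulate_proteome(p, prof$types)
  comp <- p$composition
  reg <- prot$proteins$regime
  n_fusion_partners <- sum(reg == "young_only_fusion_partner")
  expect_equal(sum(reg == "old_only"), unname(comp[["old_only"]]))
  expect_equal(sum(reg %in% c("gain", "mutual", "fusion", "complex")),
               unname(comp[["combined"]]))
  expect_equal(sum(reg == "young_only") + n_fusion_partners,
               unname(comp[["young_only"]]))
  expect_equal(n_fusion_partners, sum(reg == "fusion"))
  # hits and regions describe the same occurrences
  expect_equal(nrow(prot$hits), nrow(prot$regions))
  expect_equal(nrow(prot$hits), sum(prot$proteins$n_domains))
  # every hit lies inside its protein and hits never overlap
  lens <- setNames(prot$proteins$length_aa, prot$proteins$protein_id)
  expect_true(all(prot$hits$start >= 1))
  expect_true(all(prot$hits$end <= lens[prot$hits$protein_id]))
  by_p <- split(prot$hits, prot$hits$protein_id)
  for (h in by_p) {
    h <- h[order(h$start), ]
    if (nrow(h) > 1) expect_true(all(h$start[-1] > h$end[-nrow(h)]))
  }
  expect_true(all(prot$hits$evalue <= 1e-6))
})

test_that("combined proteins realise their regimes as classifier scenarios", {
  p <- sim_params(seed = 19, duplication_rate = 0)
  b <- simulate_dataset(p)
  ages <- assign_domain_ages(b$profiles)
  archs <- architectures(resolve_overlaps(b$hits))
  scen <- classify_scenarios(archs, ages)
  truth <- b$proteins[match(scen$protein_id, b$proteins$protein_id), ]
  map <- c(gain = "gain_dependent", mutual = "mutual_dependence",
           fusion = "fusion", complex = "complex")
  expect_identical(scen$scenario, unname(map[truth$regime]))
  # and the recorded young positions match the classifier's reading
  pos <- young_positions(archs, ages)
  tp <- b$proteins[match(pos$protein_id, b$proteins$protein_id), ]
  multi <- !is.na(tp$young_position)
  expect_identical(pos$position[multi], tp$young_position[multi])
})

test_that("full N-terminal bias places every young domain first", {
  p <- sim_params(seed = 23, nterm_bias = 1, duplication_rate = 0)
  set.seed(p$seed)
  prof <- simulate_profiles(p)
  prot <- simulate_proteome(p, prof$types)
  comb <- prot$proteins[prot$proteins$regime %in%
                          c("gain", "mutual", "fusion", "complex"), ]
  expect_true(all(comb$young_position == "N_terminal"))
  first_hit <- prot$hits |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::slice_min(.data$start, n = 1) |>
    dplyr::ungroup()
  young_of <- setNames(prof$types$true_age, prof$types$domain_type_id)
  fh <- first_hit[first_hit$protein_id %in% comb$protein_id, ]
  expect_true(all(is_young(young_of[fh$domain_type_id], p$ranking)))
})

test_that("codon pair simulation honours omega and dS targets in expectation", {
  # omega 0: the mutation process proposes only synonymous changes; pathway
  # averaging over multi-hit codons can still book a fractional Nd, so dN is
  # near zero rather than exactly zero
  pr <- simulate_codon_pair(400, omega = 0, target_ds = 0.5, seed = 61)
  e <- estimate_dnds(pr)
  expect_lt(e$pN, 0.02)
  expect_gt(e$dS, 0.3)
  expect_gt(e$dS, 20 * e$dN)
  # dS 0: identical sequences
  pr <- simulate_codon_pair(200, omega = 0.3, target_ds = 0, seed = 62)
  expect_identical(pr$ref, pr$alt)
  # truth attribute records the targets
  expect_equal(attr(pr, "truth")$omega, 0.3)
  # saturating targets refused
  expect_error(simulate_codon_pair(100, omega = 1, target_ds = Inf, seed = 63),
               "saturating")
  # median recovery near the target over replicates
  set.seed(64)
  est <- replicate(60, {
    e <- estimate_dnds(simulate_codon_pair(300, omega = 0.2, target_ds = 0.5))
    c(e$dS, e$omega)
  })
  expect_equal(median(est[1, ]), 0.5, tolerance = 0.2)
  expect_equal(median(est[2, ]), 0.2, tolerance = 0.2)
})

test_that("a simulated bundle is internally consistent", {
  p <- sim_params(seed = 31, composition = c(young_only = 20, old_only = 30,
                                             combined = 12))
  b <- simulate_dataset(p)
  expect_s3_class(b, "sim_bundle")
  expect_setequal(b$alignments$protein_id, b$proteins$protein_id)
  # alignments are ungapped and 3x protein length
  expect_equal(nchar(b$alignments$ref),
               3 * b$proteins$length_aa[match(b$alignments$protein_id,
                                              b$proteins$protein_id)])
  expect_equal(nchar(b$alignments$ref), nchar(b$alignments$alt))
  expect_false(any(grepl("-", b$alignments$ref)))
  # every alignment passes the container's validation (no internal stops)
  for (i in seq_len(nrow(b$alignments))) {
    expect_silent(codon_alignment_pair(b$alignments$ref[i],
                                       b$alignments$alt[i]))
  }
  # regions sit inside their protein and match the hit table coordinates
  h <- dplyr::arrange(b$hits, .data$protein_id, .data$start)
  r <- dplyr::arrange(b$regions, .data$protein_id, .data$start)
  expect_equal(h[c("protein_id", "domain_type_id", "start", "end")],
               r[c("protein_id", "domain_type_id", "start", "end")])
  expect_true(all(r$true_omega > 0))
})

test_that("emitting a bundle is deterministic and round-trips through disk", {
  p <- sim_params(seed = 77, composition = c(young_only = 10, old_only = 15,
                                             combined = 6))
  d1 <- file.path(withr::local_tempdir(), "a")
  d2 <- file.path(withr::local_tempdir(), "b")
  emit_dataset(p, d1)
  emit_dataset(p, d2)
  files <- c("profiles.tsv", "hits.tsv", "proteins.tsv", "alignments.fa",
             "ledger.json", "params.json")
  for (f in files) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  # a different seed changes the data
  emit_dataset(sim_params(seed = 78, composition = p$composition), d2)
  expect_false(identical(unname(tools::md5sum(file.path(d1, "alignments.fa"))),
                         unname(tools::md5sum(file.path(d2, "alignments.fa")))))

  b <- simulate_dataset(p)
  back <- read_bundle(d1)
  expect_equal(as.data.frame(back$profiles), as.data.frame(b$profiles))
  expect_equal(as.data.frame(back$hits), as.data.frame(b$hits))
  aln <- dplyr::arrange(back$alignments, .data$protein_id)
  expect_equal(as.data.frame(aln),
               as.data.frame(dplyr::arrange(b$alignments, .data$protein_id)))
  expect_identical(back$ledger$types$true_age, b$types$true_age)
  expect_error(read_bundle(withr::local_tempdir()), "missing")
})
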