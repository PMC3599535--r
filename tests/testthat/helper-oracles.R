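# Independent brute-force oracles. These deliberately avoid the package's
# internal lookup tables: the genetic code comes from seqinr, pathway counting
# is a fresh recursion, and age assignment is a plain oldest-first scan.

oracle_domain_age <- function(presence, ranking) {
  for (age in rev(ranking$ages)) {
    sp <- ranking$clades[[age]]
    if (any(presence[sp])) return(age)
  }
  ranking$ages[1]
}

oracle_translate <- function(codon) {
  seqinr::translate(strsplit(tolower(codon), "")[[1]])
}

oracle_sites <- function(codon) {
  aa0 <- oracle_translate(codon)
  s <- 0
  for (p in 1:3) {
    syn <- 0; nonstop <- 0
    for (b in c("A", "C", "G", "T")) {
      if (b == substr(codon, p, p)) next
      mut <- codon
      substr(mut, p, p) <- b
      aa1 <- oracle_translate(mut)
      if (aa1 == "*") next
      nonstop <- nonstop + 1
      if (aa1 == aa0) syn <- syn + 1
    }
    if (nonstop > 0) s <- s + syn / nonstop
  }
  c(n = 3 - s, s = s)
}

# recursive enumeration of minimal mutational pathways between two codons
oracle_pair_counts <- function(c1, c2) {
  walk <- function(cur) {
    pos <- which(strsplit(cur, "")[[1]] != strsplit(c2, "")[[1]])
    if (length(pos) == 0) return(list(c(nd = 0, sd = 0)))
    out <- list()
    for (p in pos) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (oracle_translate(nxt) == "*") next
      step <- if (oracle_translate(nxt) == oracle_translate(cur)) {
        c(nd = 0, sd = 1)
      } else c(nd = 1, sd = 0)
      for (tailc in walk(nxt)) out[[length(out) + 1]] <- step + tailc
    }
    out
  }
  paths <- walk(c1)
  if (length(paths) == 0) return(c(nd = NA_real_, sd = NA_real_))
  Reduce(`+`, paths) / length(paths)
}

# complete NG86 dN/dS from two ungapped codon vectors
oracle_dnds <- function(ref, alt) {
  keep <- !logical(length(ref))
  n_sites <- 0; s_sites <- 0; nd <- 0; sd <- 0
  for (i in seq_along(ref)) {
    cnt <- oracle_pair_counts(ref[i], alt[i])
    if (anyNA(cnt)) next
    sr <- oracle_sites(ref[i]); sa <- oracle_sites(alt[i])
    n_sites <- n_sites + (sr[["n"]] + sa[["n"]]) / 2
    s_sites <- s_sites + (sr[["s"]] + sa[["s"]]) / 2
    nd <- nd + cnt[["nd"]]; sd <- sd + cnt[["sd"]]
  }
  pn <- nd / n_sites
  ps <- if (s_sites > 0) sd / s_sites else 0
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(N_sites = n_sites, S_sites = s_sites, Nd = nd, Sd = sd,
       dN = jc(pn), dS = jc(ps))
}

# two-sided exact binomial p-value by direct tail summation (the
# small-probability-mass definition)
oracle_binom_p <- function(x, n, p0) {
  probs <- dbinom(0:n, n, p0)
  sum(probs[probs <= dbinom(x, n, p0) * (1 + 1e-7)])
}

# direct enumeration: the set of configurations containing a type, from a
# plain list of type tuples
oracle_configs <- function(type, tuples) {
  cfg <- vapply(tuples, function(tp) paste(rle(tp)$values, collapse = ";"),
                character(1))
  sort(unique(cfg[vapply(tuples, function(tp) type %in% tp, logical(1))]))
}

oracle_classify_pair <- function(young, old, tuples) {
  yi <- length(oracle_configs(young, tuples)) >= 2
  oi <- length(oracle_configs(old, tuples)) >= 2
  if (oi && !yi) "gain_dependent"
  else if (!oi && !yi) "mutual_dependence"
  else if (oi && yi) "fusion"
  else "reverse_dependence"
}

# per-pair classification reduced to a protein verdict
oracle_classify_protein <- function(types, young_set, tuples) {
  ys <- unique(types[types %in% young_set])
  os <- unique(types[!types %in% young_set])
  labs <- unlist(lapply(ys, function(y)
    vapply(os, function(o) oracle_classify_pair(y, o, tuples), character(1))))
  if (length(unique(labs)) == 1) unname(labs[1]) else "complex"
}

# column-walking sub-alignment extraction
oracle_extract <- function(ref_codons, alt_codons, start_aa, end_aa) {
  count <- 0L; keep <- integer(0); first <- NA_integer_; last <- NA_integer_
  for (j in seq_along(ref_codons)) {
    if (ref_codons[j] != "---") {
      count <- count + 1L
      if (count == start_aa) first <- j
      if (count == end_aa) { last <- j; break }
    }
  }
  list(ref = ref_codons[first:last], alt = alt_codons[first:last])
}

# architecture tables straight from type tuples, for classifier tests
archs_from_tuples <- function(tuples) {
  tibble::tibble(
    protein_id = sprintf("P%03d", seq_along(tuples)),
    types = lapply(tuples, identity),
    config = vapply(tuples, function(tp) paste(rle(tp)$values, collapse = ";"),
                    character(1)),
    n_domains = lengths(tuples)
  )
}

# random small datasets of architectures over young types V* and old types O*
random_tuples <- function(n_prot = 8, n_young = 3, n_old = 4) {
  young <- paste0("V", seq_len(n_young))
  old <- paste0("O", seq_len(n_old))
  tuples <- lapply(seq_len(n_prot), function(i) {
    k <- sample(1:4, 1)
    sample(c(young, old), k, replace = TRUE)
  })
  list(tuples = tuples, young = young, old = old)
}

random_codon_pair <- function(n_codons, n_diffs) {
  tab <- domainage:::codon_tables()
  ref <- sample(tab$sense, n_codons, replace = TRUE)
  alt <- ref
  for (i in sample(seq_len(n_codons), min(n_diffs, n_codons))) {
    repeat {
      cand <- sample(tab$sense, 1)
      if (cand != alt[i]) { alt[i] <- cand; break }
    }
  }
  list(ref = ref, alt = alt)
}

pair_from_codons <- function(ref, alt) {
  codon_alignment_pair(paste(ref, collapse = ""), paste(alt, collapse = ""))
}
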