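# Codon tables for NG86 counting, built once per session and cached.
# The standard genetic code comes from Biostrings::GENETIC_CODE.

.codon_cache <- new.env(parent = emptyenv())

nucs <- c("A", "C", "G", "T")

codon_tables <- function() {
  if (!is.null(.codon_cache$tab)) return(.codon_cache$tab)
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)
  aa <- unname(gc)
  sense <- codons[aa != "*"]
  aa_of <- setNames(aa, codons)

  # per sense codon x position: the three single-nucleotide neighbours,
  # split into synonymous / nonsynonymous / stop
  neighbours <- function(codon, pos) {
    base <- substr(codon, pos, pos)
    alt <- nucs[nucs != base]
    vapply(alt, function(b) {
      s <- codon
      substr(s, pos, pos) <- b
      s
    }, character(1))
  }
  syn_alts <- vector("list", length(sense) * 3)
  non_alts <- vector("list", length(sense) * 3)
  s_frac <- matrix(0, nrow = length(sense), ncol = 3,
                   dimnames = list(sense, NULL))
  for (i in seq_along(sense)) {
    for (p in 1:3) {
      nb <- neighbours(sense[i], p)
      cls <- ifelse(aa_of[nb] == "*", "stop",
                    ifelse(aa_of[nb] == aa_of[sense[i]], "syn", "non"))
      k <- (i - 1) * 3 + p
      syn_alts[[k]] <- nb[cls == "syn"]
      non_alts[[k]] <- nb[cls == "non"]
      nonstop <- sum(cls != "stop")
      s_frac[i, p] <- if (nonstop > 0) sum(cls == "syn") / nonstop else 0
    }
  }
  s_codon <- rowSums(s_frac)          # synonymous sites per codon
  n_codon <- 3 - s_codon              # nonsynonymous sites per codon

  .codon_cache$tab <- list(
    codons = codons, aa = aa_of, sense = sense,
    syn_alts = syn_alts, non_alts = non_alts,
    s_frac = s_frac, s_codon = s_codon, n_codon = n_codon
  )
  .codon_cache$tab
}

# pathway-averaged nonsynonymous/synonymous difference counts for one codon
# pair; minimal mutational pathways, pathways through stop codons excluded,
# remaining pathways weighted equally. Returns c(nd, sd), or c(NA, NA) when
# every pathway passes a stop.
pair_path_counts <- function(c1, c2, aa_of) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  d <- length(pos)
  if (d == 0) return(c(0, 0))
  perms <- permutations_of(pos)
  nd_tot <- 0; sd_tot <- 0; n_valid <- 0L
  for (ord in perms) {
    cur <- c1
    nd <- 0; sd <- 0; ok <- TRUE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (aa_of[nxt] == "*") { ok <- FALSE; break }
      if (aa_of[nxt] == aa_of[cur]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (ok) {
      nd_tot <- nd_tot + nd; sd_tot <- sd_tot + sd; n_valid <- n_valid + 1L
    }
  }
  if (n_valid == 0L) return(c(NA_real_, NA_real_))
  c(nd_tot, sd_tot) / n_valid
}

permutations_of <- function(x) {
  if (length(x) == 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in permutations_of(x[-i])) out[[length(out) + 1]] <- c(x[i], rest)
  }
  out
}

# 61x61 lookup matrices of pathway-averaged nd / sd counts
pair_count_matrices <- function() {
  if (!is.null(.codon_cache$pairs)) return(.codon_cache$pairs)
  tab <- codon_tables()
  n <- length(tab$sense)
  nd <- matrix(NA_real_, n, n, dimnames = list(tab$sense, tab$sense))
  sd <- nd
  for (i in seq_len(n)) {
    nd[i, i] <- 0; sd[i, i] <- 0
    for (j in seq_len(n)[-i]) {
      if (!is.na(nd[j, i])) { nd[i, j] <- nd[j, i]; sd[i, j] <- sd[j, i]; next }
      cnt <- pair_path_counts(tab$sense[i], tab$sense[j], tab$aa)
      nd[i, j] <- cnt[1]; sd[i, j] <- cnt[2]
    }
  }
  .codon_cache$pairs <- list(nd = nd, sd = sd)
  .codon_cache$pairs
}

is_stop_codon <- function(codon) {
  tab <- codon_tables()
  !is.na(tab$aa[codon]) & tab$aa[codon] == "*"
}
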