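#' Write a synthetic bundle to disk in the pipeline's input formats
#'
#' Emits `profiles.tsv` (phyletic profiles), `hits.tsv` (domain hit table),
#' `proteins.tsv` (protein lengths), `alignments.fa` (pairwise codon
#' alignments, two records per protein named `<id>|ref` and `<id>|alt`),
#' `ledger.json` (ground truth: type ages, protein regimes and positions,
#' per-region omega/dS) and `params.json`. Output is byte-identical for
#' identical parameters and seed.
#'
#' @param bundle A `sim_bundle` from [simulate_dataset()], or a [sim_params()]
#'   (then the bundle is simulated first).
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
emit_dataset <- function(bundle, dir) {
  if (inherits(bundle, "sim_params")) bundle <- simulate_dataset(bundle)
  stopifnot(inherits(bundle, "sim_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory ", dir, call. = FALSE)
  readr::write_tsv(bundle$profiles, file.path(dir, "profiles.tsv"))
  readr::write_tsv(bundle$hits, file.path(dir, "hits.tsv"))
  readr::write_tsv(bundle$proteins[, c("protein_id", "length_aa")],
                   file.path(dir, "proteins.tsv"))
  seqs <- character(2 * nrow(bundle$alignments))
  seqs[c(TRUE, FALSE)] <- bundle$alignments$ref
  seqs[c(FALSE, TRUE)] <- bundle$alignments$alt
  names(seqs) <- paste0(rep(bundle$alignments$protein_id, each = 2),
                        c("|ref", "|alt"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs),
                              file.path(dir, "alignments.fa"))
  ledger <- list(
    types = bundle$types,
    proteins = bundle$proteins,
    regions = bundle$regions
  )
  jsonlite::write_json(ledger, file.path(dir, "ledger.json"),
                       dataframe = "columns", digits = NA)
  pars <- bundle$params
  pars$ranking <- list(clades = pars$ranking$clades,
                       reference = pars$ranking$reference)
  jsonlite::write_json(unclass(pars), file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read an analysis bundle from disk
#'
#' Reads the file formats written by [emit_dataset()] (the same formats that
#' would hold real data: profile TSV, hit TSV, protein-length TSV, paired
#' FASTA alignments, optional truth ledger).
#'
#' @param dir Directory containing the bundle.
#' @return List with `profiles`, `hits`, `proteins`, `alignments` tibbles and,
#'   when present, `ledger` (list of truth tibbles).
#' @export
read_bundle <- function(dir) {
  need <- c("profiles.tsv", "hits.tsv", "alignments.fa")
  miss <- need[!file.exists(file.path(dir, need))]
  if (length(miss)) {
    stop("bundle at ", dir, " is missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  profiles <- readr::read_tsv(file.path(dir, "profiles.tsv"),
                              show_col_types = FALSE)
  hits <- readr::read_tsv(file.path(dir, "hits.tsv"), show_col_types = FALSE)
  proteins <- if (file.exists(file.path(dir, "proteins.tsv"))) {
    readr::read_tsv(file.path(dir, "proteins.tsv"), show_col_types = FALSE)
  } else NULL
  fa <- Biostrings::readBStringSet(file.path(dir, "alignments.fa"))
  ids <- sub("\\|(ref|alt)$", "", names(fa))
  role <- sub("^.*\\|", "", names(fa))
  if (!all(role %in% c("ref", "alt"))) {
    stop("alignment record names must end in |ref or |alt", call. = FALSE)
  }
  refs <- as.character(fa[role == "ref"]); names(refs) <- ids[role == "ref"]
  alts <- as.character(fa[role == "alt"]); names(alts) <- ids[role == "alt"]
  if (!setequal(names(refs), names(alts))) {
    stop("unpaired alignment records", call. = FALSE)
  }
  alignments <- tibble(protein_id = names(refs), ref = unname(refs),
                       alt = unname(alts[names(refs)]))
  ledger <- NULL
  if (file.exists(file.path(dir, "ledger.json"))) {
    lj <- jsonlite::read_json(file.path(dir, "ledger.json"),
                              simplifyVector = TRUE)
    ledger <- lapply(lj, as_tibble)
  }
  list(profiles = profiles, hits = hits, proteins = proteins,
       alignments = alignments, ledger = ledger)
}
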