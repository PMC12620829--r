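#' Enumerate candidate 15-mer peptides
#'
#' Lists all possible 15-residue windows from either a primary protein
#' sequence (with 1-based start coordinates) or a set of eluted
#' peptides (coordinates unknown in the parent protein; `start` is 0
#' and such candidates are treated as mutually non-overlapping by
#' [select_epitopes()]). Eluted peptides shorter than 15 residues are
#' skipped with a warning; duplicate 15-mers from an eluted-peptide
#' list are collapsed to their first occurrence.
#'
#' @param sequence single protein sequence (one-letter amino-acid
#'   codes), or `NULL`.
#' @param peptides character vector of eluted peptides, or `NULL`.
#' @return data.frame with columns `peptide`, `start`.
#' @export
enumerate_candidates <- function(sequence = NULL, peptides = NULL) {
  if (is.null(sequence) == is.null(peptides))
    stop("provide exactly one of sequence or peptides")
  if (!is.null(sequence)) {
    stopifnot(length(sequence) == 1)
    seq <- toupper(sequence)
    check_residues(seq)
    L <- nchar(seq)
    if (L < 15) return(data.frame(peptide = character(0), start = integer(0)))
    starts <- seq_len(L - 14)
    return(data.frame(peptide = substring(seq, starts, starts + 14),
                      start = starts))
  }
  peptides <- toupper(peptides)
  short <- nchar(peptides) < 15
  if (any(short)) {
    warning(sum(short), " eluted peptide(s) shorter than 15 residues skipped")
    peptides <- peptides[!short]
  }
  mers <- unlist(lapply(peptides, function(p) {
    check_residues(p)
    starts <- seq_len(nchar(p) - 14)
    substring(p, starts, starts + 14)
  }))
  mers <- unique(mers)
  data.frame(peptide = mers, start = rep(0L, length(mers)))
}

AA_CODES <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

check_residues <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  bad <- which(!chars %in% AA_CODES)
  if (length(bad))
    stop("invalid residue '", chars[bad[1]], "' at position ", bad[1])
  invisible(TRUE)
}

#' Remove candidate peptides matching the self-proteome
#'
#' A candidate is removed if its 15-mer occurs as an exact,
#' case-insensitive substring of any single proteome record (never
#' across record boundaries), modelling immune tolerance to peptides
#' from self proteins. Exact substring identity stands in for a BLAST
#' alignment screen; a pre-filtered candidate list from a real
#' alignment run can be supplied instead.
#'
#' @param candidates data.frame from [enumerate_candidates()].
#' @param proteome named character vector of protein sequences (e.g.
#'   from [read_fasta()]).
#' @return the retained subset of `candidates`, in input order.
#' @export
filter_self <- function(candidates, proteome) {
  stopifnot(is.data.frame(candidates))
  if (!length(proteome) || !nrow(candidates)) return(candidates)
  seqs <- toupper(proteome)
  hit <- vapply(toupper(candidates$peptide),
                function(p) any(grepl(p, seqs, fixed = TRUE)), NA,
                USE.NAMES = FALSE)
  candidates[!hit, , drop = FALSE]
}

#' Select up to five non-overlapping high-risk epitopes
#'
#' Greedy selection of the strongest-presented, non-overlapping
#' candidate peptides: candidates are ranked by ascending best (lowest)
#' elution rank across the HLA reference set, and accepted unless their
#' 15-residue interval shares any parent-sequence position with an
#' already accepted epitope. Ties break deterministically by smaller
#' start then lexicographic peptide, so the selection is invariant to
#' the input order. This is a greedy, not a globally optimal, interval
#' selection.
#'
#' @param candidates data.frame with columns `peptide`, `start`
#'   (`start` 0 marks eluted-peptide candidates, which never overlap).
#' @param ranks elution-rank table: data.frame with columns `peptide`,
#'   `allele`, `el_rank` (see [read_elution_ranks()]).
#' @param reference_alleles alleles defining "best rank"; defaults to
#'   all alleles in `ranks`.
#' @param max_n maximum number of epitopes (>= 1).
#' @return list of epitopes, each a list with `peptide`, `start`,
#'   `ranks` (named per-allele vector) and `best_rank`.
#' @export
select_epitopes <- function(candidates, ranks,
                            reference_alleles = unique(ranks$allele),
                            max_n = 5) {
  if (max_n < 1) stop("configuration error: max_n must be >= 1")
  stopifnot(is.data.frame(candidates), is.data.frame(ranks))
  if (!nrow(candidates)) return(list())
  ranks <- ranks[ranks$allele %in% reference_alleles, , drop = FALSE]
  best <- vapply(candidates$peptide, function(p) {
    r <- ranks$el_rank[ranks$peptide == p]
    if (!length(r)) NA_real_ else min(r)
  }, 0, USE.NAMES = FALSE)
  if (anyNA(best))
    stop("candidate(s) without any reference-set elution rank: ",
         paste(utils::head(candidates$peptide[is.na(best)], 3), collapse = ", "))
  ord <- order(best, candidates$start, candidates$peptide)
  sel <- list()
  taken <- integer(0)  # occupied parent positions
  for (i in ord) {
    st <- candidates$start[i]
    if (st > 0) {
      iv <- st:(st + 14)
      if (any(iv %in% taken)) next
      taken <- c(taken, iv)
    }
    p <- candidates$peptide[i]
    rr <- ranks[ranks$peptide == p, , drop = FALSE]
    sel[[length(sel) + 1]] <- list(
      peptide = p, start = st,
      ranks = stats::setNames(rr$el_rank, rr$allele),
      best_rank = best[i])
    if (length(sel) == max_n) break
  }
  sel
}

#' Read a per-peptide per-allele elution-rank table
#'
#' Tab-separated file with a header row and columns `peptide`, `allele`
#' and `el_rank` (percentile elution rank in (0, 100], as reported by
#' MHC class II presentation predictors). Duplicate (peptide, allele)
#' rows keep the minimum rank with a warning.
#'
#' @param path TSV file path.
#' @return data.frame with columns `peptide`, `allele`, `el_rank`.
#' @export
read_elution_ranks <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("peptide", "allele", "el_rank")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("elution-rank table is missing column(s): ",
         paste(miss, collapse = ", "))
  tab <- tab[need]
  if (!is.numeric(tab$el_rank)) stop("el_rank must be numeric")
  if (any(tab$el_rank <= 0 | tab$el_rank > 100))
    stop("el_rank values must be in (0, 100]")
  key <- paste(tab$peptide, tab$allele, sep = "\r")
  if (anyDuplicated(key)) {
    warning("duplicate (peptide, allele) rows: keeping the minimum rank")
    tab <- do.call(rbind, lapply(split(tab, key), function(d)
      d[which.min(d$el_rank), , drop = FALSE]))
  }
  tab <- tab[order(tab$peptide, tab$allele), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Write selected epitopes to a TSV file
#'
#' One row per epitope with peptide, 1-based start, best reference-set
#' rank, and one column per allele.
#'
#' @param epitopes list from [select_epitopes()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_epitopes <- function(epitopes, path) {
  alleles <- sort(unique(unlist(lapply(epitopes, function(e) names(e$ranks)))))
  rows <- lapply(epitopes, function(e) {
    r <- stats::setNames(rep(NA_real_, length(alleles)), alleles)
    r[names(e$ranks)] <- e$ranks
    c(list(peptide = e$peptide, start = e$start, best_rank = e$best_rank),
      as.list(r))
  })
  df <- do.call(rbind, lapply(rows, function(x) as.data.frame(x, check.names = FALSE)))
  write_table_stable(df, path, sep = "\t")
  invisible(path)
}
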