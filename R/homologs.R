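# Homolog-set curation: global identity, identity-window filtering, greedy
# identity clustering and coverage-sorted representative selection.

.blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Global pairwise alignment of two protein sequences
#'
#' Needleman-Wunsch global alignment with BLOSUM62 and affine gap costs
#' (open 10, extend 0.5).
#'
#' @param seq_a,seq_b protein sequences (strings, 20-letter alphabet; X
#'   tolerated).
#' @param gap_open,gap_extend affine gap costs (positive).
#' @return list with \code{a}, \code{b} (aligned strings with \code{-} gaps)
#'   and \code{score}.
#' @export
align_global <- function(seq_a, seq_b, gap_open = 10, gap_extend = 0.5) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("empty sequence")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    substitutionMatrix = .blosum62(),
    gapOpening = gap_open, gapExtension = gap_extend, type = "global"
  )
  list(a = as.character(Biostrings::alignedPattern(pa)),
       b = as.character(Biostrings::alignedSubject(pa)),
       score = Biostrings::score(pa))
}

#' Global sequence identity between two sequences
#'
#' Identity is the fraction of identical-residue columns of the global
#' alignment among aligned columns, excluding terminal-gap columns; X never
#' counts as a match. Symmetric in its arguments.
#'
#' @param seq_a,seq_b protein sequences (strings).
#' @return identity fraction in [0, 1].
#' @export
global_identity <- function(seq_a, seq_b) {
  aln <- align_global(seq_a, seq_b)
  alignment_identity(aln$a, aln$b)
}

# identity over an existing pair of aligned strings
alignment_identity <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  core <- .core_columns(ca, cb)
  if (!length(core)) return(0)
  ca <- ca[core]; cb <- cb[core]
  mean(ca == cb & ca != "-" & ca != "X" & cb != "X")
}

# columns excluding terminal gap runs of either sequence
.core_columns <- function(ca, cb) {
  n <- length(ca)
  nz_a <- which(ca != "-"); nz_b <- which(cb != "-")
  if (!length(nz_a) || !length(nz_b)) return(integer(0))
  lo <- max(min(nz_a), min(nz_b))
  hi <- min(max(nz_a), max(nz_b))
  if (lo > hi) return(integer(0))
  seq(lo, hi)
}

#' Query coverage of a homolog
#'
#' Fraction of query positions aligned to a residue (non-gap in both rows)
#' in the global alignment.
#'
#' @param query,homolog protein sequences (strings).
#' @return coverage fraction in [0, 1].
#' @export
query_coverage <- function(query, homolog) {
  aln <- align_global(query, homolog)
  ca <- strsplit(aln$a, "")[[1]]
  cb <- strsplit(aln$b, "")[[1]]
  sum(ca != "-" & cb != "-") / sum(ca != "-")
}

#' Annotate homolog sequences against a query
#'
#' @param query query sequence (string).
#' @param homologs named character vector of homolog sequences.
#' @return data frame with id, sequence, identity_to_query, query_coverage.
#' @export
homolog_records <- function(query, homologs) {
  if (is.null(names(homologs))) names(homologs) <- paste0("h", seq_along(homologs))
  alns <- lapply(homologs, function(s) align_global(query, s))
  ident <- vapply(alns, function(al) alignment_identity(al$a, al$b), 0)
  cov <- vapply(alns, function(al) {
    ca <- strsplit(al$a, "")[[1]]; cb <- strsplit(al$b, "")[[1]]
    sum(ca != "-" & cb != "-") / sum(ca != "-")
  }, 0)
  data.frame(id = names(homologs), sequence = unname(homologs),
             identity_to_query = unname(ident),
             query_coverage = unname(cov), stringsAsFactors = FALSE)
}

#' Filter homologs by identity window
#'
#' Keeps homologs whose identity to the query lies inside the window;
#' bounds are inclusive so the advertised default 30--90\% values remain
#' usable. Input order is preserved.
#'
#' @param records data frame from \code{\link{homolog_records}}.
#' @param min,max identity bounds in [0, 1], \code{min < max}.
#' @return filtered data frame.
#' @export
filter_by_identity <- function(records, min = 0.30, max = 0.90) {
  stopifnot(min >= 0, max <= 1, min < max)
  keep <- records$identity_to_query >= min & records$identity_to_query <= max
  records[keep, , drop = FALSE]
}

#' Greedy identity clustering of sequences
#'
#' Sequences are processed in descending length order (ties: input order);
#' each joins the first existing representative with identity at or above
#' the threshold, otherwise founds a new cluster. This mirrors the greedy
#' pass of sorted-input identity clusterers, using exact pairwise global
#' identity instead of word-index heuristics.
#'
#' @param seqs named character vector of sequences.
#' @param threshold identity threshold in (0, 1].
#' @return list of clusters, each a list with \code{representative} (id) and
#'   \code{members} (ids, representative first).
#' @export
greedy_cluster <- function(seqs, threshold = 0.90) {
  stopifnot(threshold > 0, threshold <= 1)
  if (is.null(names(seqs))) names(seqs) <- paste0("s", seq_along(seqs))
  ord <- order(-nchar(seqs), seq_along(seqs))
  reps <- integer(0)           # indices into seqs
  members <- list()
  for (i in ord) {
    placed <- FALSE
    for (k in seq_along(reps)) {
      if (global_identity(seqs[[reps[k]]], seqs[[i]]) >= threshold) {
        members[[k]] <- c(members[[k]], i)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, i)
      members[[length(reps)]] <- i
    }
  }
  lapply(seq_along(reps), function(k) {
    list(representative = names(seqs)[reps[k]],
         members = names(seqs)[members[[k]]])
  })
}

#' Select cluster representatives for alignment construction
#'
#' One representative per cluster, sorted by query coverage (descending;
#' ties by identity descending, then id) and truncated to \code{cap}.
#'
#' @param clusters output of \code{\link{greedy_cluster}}.
#' @param records homolog annotation table (\code{\link{homolog_records}})
#'   covering every representative id.
#' @param cap maximum number of sequences to keep (default 200).
#' @return data frame of selected representatives in final order.
#' @export
select_representatives <- function(clusters, records, cap = 200) {
  stopifnot(cap >= 1)
  rep_ids <- vapply(clusters, function(cl) cl$representative, "")
  idx <- match(rep_ids, records$id)
  if (anyNA(idx)) stop("representative missing from records: ",
                       paste(rep_ids[is.na(idx)], collapse = ", "))
  sel <- records[idx, , drop = FALSE]
  ord <- order(-sel$query_coverage, -sel$identity_to_query, sel$id)
  sel <- sel[ord, , drop = FALSE]
  rownames(sel) <- NULL
  utils::head(sel, cap)
}

#' Curate a homolog set end to end
#'
#' Identity-window filtering, greedy clustering and capped representative
#' selection in one call.
#'
#' @param query query sequence.
#' @param homologs named character vector of homolog sequences.
#' @param min_id,max_id identity window (defaults 0.30 and 0.90).
#' @param cluster_id clustering identity threshold (default 0.90).
#' @param cap maximum representatives (default 200).
#' @return data frame of selected homolog records.
#' @export
curate_homologs <- function(query, homologs, min_id = 0.30, max_id = 0.90,
                            cluster_id = 0.90, cap = 200) {
  rec <- homolog_records(query, homologs)
  rec <- filter_by_identity(rec, min_id, max_id)
  if (nrow(rec) == 0L) return(rec)
  seqs <- stats::setNames(rec$sequence, rec$id)
  cl <- greedy_cluster(seqs, cluster_id)
  select_representatives(cl, rec, cap)
}
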