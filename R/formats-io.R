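# Input/output: PDB structures, (aligned) FASTA, ddG tables, design reports,
# and the canonical mutation notation used across the package.

#' Read a protein structure from a PDB file
#'
#' Parses ATOM records (plus selenomethionine HETATM records, remapped to
#' methionine), keeps standard amino-acid residues of the selected chains,
#' resolves alternate locations by highest occupancy and preserves the
#' B-factor column. Waters, ligands and other non-standard residues are
#' dropped (with a warning when protein-like residues are lost).
#'
#' @param path path to a PDB file.
#' @param chains optional character vector of chain identifiers to retain;
#'   default keeps all chains.
#' @return an object of class \code{structure_model}: a list with an
#'   \code{atoms} data frame (chain, resno, icode, resid, aa, elety, element,
#'   x, y, z, o, b) and a \code{chains} character vector.
#' @export
read_pdb <- function(path, chains = NULL) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  .validate_pdb_lines(path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  keep_resid <- names(AA_THREE_TO_ONE)
  is_protein <- (at$type == "ATOM" & at$resid %in% keep_resid) |
    (at$resid == "MSE")
  dropped <- unique(at$resid[at$type == "ATOM" & !is_protein[seq_len(nrow(at))] &
                               !(at$resid %in% c("HOH", "WAT"))])
  if (length(dropped))
    warning("dropping non-standard residues: ", paste(dropped, collapse = ", "))
  at <- at[is_protein, , drop = FALSE]
  if (!is.null(chains)) at <- at[at$chain %in% chains, , drop = FALSE]
  if (nrow(at) == 0L) stop("no standard amino-acid residues found in ", path)

  icode <- at$insert
  icode[is.na(icode)] <- ""
  resid <- at$resid
  # selenomethionine -> methionine; selenium atom name normalised
  se <- resid == "MSE"
  resid[se] <- "MET"
  elety <- at$elety
  elety[se & elety == "SE"] <- "SD"
  element <- at$elesy
  if (is.null(element)) element <- NA_character_
  element[is.na(element) | element == ""] <-
    substr(gsub("[^A-Za-z].*", "", elety[is.na(element) | element == ""]), 1, 1)
  element[se & element == "SE"] <- "S"

  atoms <- data.frame(
    chain = at$chain, resno = at$resno, icode = icode,
    resid = resid, aa = unname(AA_THREE_TO_ONE[resid]),
    elety = elety, element = toupper(element),
    x = at$x, y = at$y, z = at$z,
    o = ifelse(is.na(at$o), 1, at$o), b = at$b,
    alt = ifelse(is.na(at$alt), "", at$alt),
    stringsAsFactors = FALSE
  )
  atoms <- .resolve_altloc(atoms)
  atoms$alt <- NULL
  structure_model(atoms)
}

.validate_pdb_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (any(rec)) {
    coords <- substring(lines[rec], 31, 54)
    xyz <- suppressWarnings(cbind(
      as.numeric(substr(coords, 1, 8)),
      as.numeric(substr(coords, 9, 16)),
      as.numeric(substr(coords, 17, 24))
    ))
    bad <- which(apply(is.na(xyz), 1, any))
    if (length(bad)) {
      stop("malformed coordinate field in PDB line ",
           which(rec)[bad[1]], " of ", path)
    }
  }
  invisible(TRUE)
}

.resolve_altloc <- function(atoms) {
  if (all(atoms$alt %in% c("", "A"))) return(atoms)
  key <- paste(atoms$chain, atoms$resno, atoms$icode, atoms$elety)
  keep <- unlist(lapply(split(seq_len(nrow(atoms)), key), function(idx) {
    if (length(idx) == 1L) return(idx)
    idx[which.max(atoms$o[idx])]
  }), use.names = FALSE)
  atoms[sort(keep), , drop = FALSE]
}

#' Construct a structure model from an atom table
#'
#' @param atoms data frame with columns chain, resno, icode, resid, aa,
#'   elety, element, x, y, z, o, b.
#' @return a \code{structure_model}.
#' @export
structure_model <- function(atoms) {
  stopifnot(all(c("chain", "resno", "resid", "elety", "x", "y", "z") %in%
                  names(atoms)))
  if (is.null(atoms$icode)) atoms$icode <- ""
  if (is.null(atoms$aa)) atoms$aa <- unname(AA_THREE_TO_ONE[atoms$resid])
  if (is.null(atoms$o)) atoms$o <- 1
  if (is.null(atoms$b)) atoms$b <- NA_real_
  if (is.null(atoms$element))
    atoms$element <- substr(gsub("[^A-Za-z].*", "", atoms$elety), 1, 1)
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("non-finite atom coordinates")
  rownames(atoms) <- NULL
  obj <- list(atoms = atoms, chains = unique(atoms$chain))
  class(obj) <- "structure_model"
  obj
}

#' @export
print.structure_model <- function(x, ...) {
  rt <- residue_table(x)
  cat("structure_model:", nrow(rt), "residues,", nrow(x$atoms),
      "atoms, chains:", paste(x$chains, collapse = ","), "\n")
  invisible(x)
}

#' Residue-level view of a structure
#'
#' @param structure a \code{structure_model}.
#' @return data frame with one row per residue (chain, resno, icode, resid,
#'   aa, key) in atom-record order.
#' @export
residue_table <- function(structure) {
  a <- structure$atoms
  key <- paste0(a$chain, ":", a$resno, a$icode)
  first <- !duplicated(key)
  data.frame(chain = a$chain[first], resno = a$resno[first],
             icode = a$icode[first], resid = a$resid[first],
             aa = a$aa[first], key = key[first], stringsAsFactors = FALSE)
}

#' Extract the amino-acid sequence of one chain
#'
#' @param structure a \code{structure_model}.
#' @param chain chain identifier; defaults to the first chain.
#' @return list with \code{sequence} (string) and \code{resno}
#'   (author residue numbers, one per letter).
#' @export
chain_sequence <- function(structure, chain = structure$chains[1]) {
  rt <- residue_table(structure)
  rt <- rt[rt$chain == chain, , drop = FALSE]
  if (nrow(rt) == 0L) stop("no residues in chain ", chain)
  list(sequence = paste(rt$aa, collapse = ""), resno = rt$resno)
}

#' Write a structure model to a PDB file
#'
#' @param structure a \code{structure_model}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_pdb <- function(structure, path) {
  a <- structure$atoms
  bio3d::write.pdb(
    pdb = NULL, file = path,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    type = rep("ATOM", nrow(a)),
    resno = a$resno, resid = a$resid, insert = a$icode,
    chain = a$chain, elety = a$elety, eleno = seq_len(nrow(a)),
    o = a$o, b = ifelse(is.na(a$b), 0, a$b)
  )
  invisible(path)
}

# ---------------------------------------------------------------------------
# FASTA / MSA

#' Read (unaligned) FASTA sequences
#'
#' @param path FASTA file.
#' @return named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  out <- toupper(as.character(set))
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(set, filepath = path, width = 60)
  invisible(path)
}

#' Build a multiple-sequence-alignment object
#'
#' Rows are aligned sequences; the designated query row drives the
#' column-to-query-position map (columns gapped in the query map to NA).
#'
#' @param seqs named character vector of equal-length aligned sequences
#'   (gaps \code{-} or \code{.}).
#' @param query_id name of the query row.
#' @return an object of class \code{msa}: list with \code{mat} (character
#'   matrix, rows = sequences), \code{ids}, \code{query} (row index),
#'   \code{colmap} (query position per column or NA) and \code{query_seq}
#'   (ungapped query string).
#' @export
msa <- function(seqs, query_id) {
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  seqs <- toupper(chartr(".", "-", seqs))
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L)
    stop("aligned sequences have unequal lengths: ",
         paste(unique(widths), collapse = ", "))
  qi <- match(query_id, names(seqs))
  if (is.na(qi)) stop("query id not found in alignment: ", query_id)
  mat <- do.call(rbind, strsplit(seqs, ""))
  rownames(mat) <- names(seqs)
  qrow <- mat[qi, ]
  colmap <- ifelse(qrow == "-", NA_integer_, cumsum(qrow != "-"))
  obj <- list(mat = mat, ids = names(seqs), query = qi,
              colmap = as.integer(colmap),
              query_seq = paste(qrow[qrow != "-"], collapse = ""))
  class(obj) <- "msa"
  obj
}

#' @export
print.msa <- function(x, ...) {
  cat("msa:", nrow(x$mat), "sequences x", ncol(x$mat), "columns; query:",
      x$ids[x$query], "(", nchar(x$query_seq), "positions )\n")
  invisible(x)
}

#' Read an aligned FASTA file into an \code{msa}
#'
#' @param path aligned FASTA file (all records equal length).
#' @param query_id identifier of the query record.
#' @return an \code{msa} object.
#' @export
read_aligned_fasta <- function(path, query_id) {
  msa(read_fasta(path), query_id)
}

# ---------------------------------------------------------------------------
# Mutation notation: "<wt><position><mut>" with optional "<chain>/" prefix.

#' Parse a single-point mutation string
#'
#' Notation is \code{<wt><position><mut>} with an optional
#' \code{<chain>/} prefix, e.g. \code{"A123G"} or \code{"B/A123G"}.
#' Without a prefix the chain is taken from \code{chains} when unambiguous.
#'
#' @param text mutation string.
#' @param chains available chain identifiers (for defaulting).
#' @return list of class \code{mutation} with fields \code{chain},
#'   \code{pos}, \code{wt}, \code{mut}.
#' @export
parse_mutation <- function(text, chains = "A") {
  text <- trimws(text)
  m <- regmatches(text, regexec("^(?:([A-Za-z0-9])/)?([A-Z])([0-9]+)([A-Z])$",
                                text))[[1]]
  if (length(m) == 0L) stop("cannot parse mutation string: '", text, "'")
  chain <- m[2]
  wt <- m[3]; pos <- as.integer(m[4]); mut <- m[5]
  if (!is_standard_aa(wt) || !is_standard_aa(mut))
    stop("non-standard amino acid in mutation '", text, "'")
  if (wt == mut) stop("silent mutation not allowed: '", text, "'")
  if (chain == "") {
    if (length(chains) != 1L)
      stop("chain omitted but structure has multiple chains (",
           paste(chains, collapse = ","), "): '", text, "'")
    chain <- chains
  }
  out <- list(chain = chain, pos = pos, wt = wt, mut = mut)
  class(out) <- "mutation"
  out
}

#' Format a mutation as its canonical string
#'
#' @param m a \code{mutation} (or list with chain/pos/wt/mut).
#' @param with_chain prefix the chain id; default only when chain != "A".
#' @return character string.
#' @export
format_mutation <- function(m, with_chain = !identical(m$chain, "A")) {
  core <- paste0(m$wt, m$pos, m$mut)
  if (isTRUE(with_chain)) paste0(m$chain, "/", core) else core
}

#' @export
print.mutation <- function(x, ...) {
  cat(format_mutation(x, with_chain = TRUE), "\n")
  invisible(x)
}

mutation_id <- function(wt, pos, mut) paste0(wt, pos, mut)

# ---------------------------------------------------------------------------
# ddG tables

#' Read a table of predicted stability changes
#'
#' Adapters for three tabular dialects of exported free-energy predictions
#' (kcal/mol, negative = stabilizing):
#' \describe{
#'   \item{tsv}{two tab-separated columns \code{mutation} and \code{ddg};
#'     a header line is detected and skipped.}
#'   \item{foldx-like}{a position-by-amino-acid grid: header line
#'     \code{pos<TAB>A<TAB>C...} over the 20 amino acids, then one row per
#'     position labelled \code{<wt><number>} with 20 values; the wild-type
#'     column is ignored.}
#'   \item{rosetta-like}{lines of the form \code{ddG: <mutation> <value>};
#'     other lines are ignored.}
#' }
#' Duplicate entries for one mutation are averaged with a warning.
#'
#' @param path input file.
#' @param dialect one of \code{"tsv"}, \code{"foldx-like"},
#'   \code{"rosetta-like"}.
#' @return a \code{ddg_table}: named numeric vector (names are mutation
#'   strings) with a \code{provenance} attribute.
#' @export
read_ddg_table <- function(path, dialect = c("tsv", "foldx-like",
                                             "rosetta-like")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  entries <- switch(dialect,
    "tsv" = .parse_ddg_tsv(lines),
    "foldx-like" = .parse_ddg_grid(lines),
    "rosetta-like" = .parse_ddg_rosetta(lines)
  )
  ddg_table(entries$mutation, entries$ddg, provenance = dialect)
}

#' Construct a ddG table from vectors
#'
#' @param mutations mutation strings.
#' @param ddg values in kcal/mol (negative = stabilizing).
#' @param provenance free-text source tag.
#' @return a \code{ddg_table}.
#' @export
ddg_table <- function(mutations, ddg, provenance = "tsv") {
  if (any(!is.finite(ddg))) stop("non-finite ddG value in table")
  if (anyDuplicated(mutations)) {
    warning("duplicate ddG entries averaged for: ",
            paste(unique(mutations[duplicated(mutations)]), collapse = ", "))
    agg <- tapply(ddg, mutations, mean)
    ddg <- as.numeric(agg)
    mutations <- names(agg)
  }
  out <- as.numeric(ddg)
  names(out) <- mutations
  attr(out, "provenance") <- provenance
  class(out) <- "ddg_table"
  out
}

#' @export
print.ddg_table <- function(x, ...) {
  cat("ddg_table:", length(x), "mutations (", attr(x, "provenance"),
      "), range", sprintf("%.2f..%.2f", min(x), max(x)), "kcal/mol\n")
  invisible(x)
}

.parse_ddg_tsv <- function(lines) {
  fields <- strsplit(lines, "\t")
  first <- fields[[1]]
  start <- if (is.na(suppressWarnings(as.numeric(first[2])))) 2L else 1L
  muts <- character(0); vals <- numeric(0)
  for (i in seq(start, length(fields))) {
    f <- fields[[i]]
    v <- suppressWarnings(as.numeric(f[2]))
    if (length(f) < 2L || is.na(v) ||
        !grepl("^([A-Za-z0-9]/)?[A-Z][0-9]+[A-Z]$", trimws(f[1])))
      stop("unparseable ddG row ", i, ": '", lines[i], "'")
    muts <- c(muts, trimws(f[1])); vals <- c(vals, v)
  }
  list(mutation = muts, ddg = vals)
}

.parse_ddg_grid <- function(lines) {
  fields <- strsplit(lines, "\t")
  header <- trimws(fields[[1]])
  aas <- header[-1]
  if (!all(aas %in% AA_ALPHABET))
    stop("foldx-like grid header must list amino-acid columns")
  muts <- character(0); vals <- numeric(0)
  for (i in seq(2L, length(fields))) {
    f <- trimws(fields[[i]])
    lab <- regmatches(f[1], regexec("^([A-Z])([0-9]+)$", f[1]))[[1]]
    if (length(lab) == 0L)
      stop("unparseable ddG row ", i, ": '", lines[i], "'")
    wt <- lab[2]; pos <- lab[3]
    v <- suppressWarnings(as.numeric(f[-1]))
    if (length(v) != length(aas) || any(is.na(v)))
      stop("unparseable ddG row ", i, ": '", lines[i], "'")
    keep <- aas != wt
    muts <- c(muts, paste0(wt, pos, aas[keep]))
    vals <- c(vals, v[keep])
  }
  list(mutation = muts, ddg = vals)
}

.parse_ddg_rosetta <- function(lines) {
  hit <- grepl("^\\s*ddG:", lines)
  muts <- character(0); vals <- numeric(0)
  for (i in which(hit)) {
    f <- strsplit(trimws(sub("^\\s*ddG:", "", lines[i])), "\\s+")[[1]]
    v <- suppressWarnings(as.numeric(f[2]))
    if (length(f) < 2L || is.na(v))
      stop("unparseable ddG row ", i, ": '", lines[i], "'")
    muts <- c(muts, f[1]); vals <- c(vals, v)
  }
  if (length(muts) == 0L) stop("no ddG records found")
  list(mutation = muts, ddg = vals)
}

# ---------------------------------------------------------------------------
# Design reports

#' Write stability designs to FASTA, CSV and JSON reports
#'
#' Produces \code{designs.fasta} (one mutant sequence per design),
#' \code{designs.csv} (one row per mutation with its annotations) and
#' \code{designs.json} (full provenance). Output ordering is deterministic:
#' designs by identifier, mutations by position.
#'
#' @param designs a list of \code{stability_design} objects (or a
#'   \code{stability_designs} container).
#' @param out_dir output directory, created if needed.
#' @return named character vector of the written paths, invisibly.
#' @export
write_designs <- function(designs, out_dir) {
  if (inherits(designs, "stability_designs")) designs <- designs$designs
  if (length(designs) == 0L) stop("no designs to write")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ord <- order(vapply(designs, function(d) d$scenario, ""))
  designs <- designs[ord]

  seqs <- vapply(designs, function(d) d$sequence, "")
  names(seqs) <- vapply(designs, function(d) {
    paste0(d$scenario, " score=", sprintf("%.3f", d$total_score),
           " n_mutations=", nrow(d$mutations))
  }, "")
  fasta_path <- file.path(out_dir, "designs.fasta")
  write_fasta(seqs, fasta_path)

  rows <- lapply(designs, function(d) {
    mt <- d$mutations
    if (nrow(mt) == 0L) return(NULL)
    mt <- mt[order(mt$pos), , drop = FALSE]
    data.frame(design = d$scenario, mutation = mt$mutation,
               chain = mt$chain, position = mt$pos, wild_type = mt$wt,
               mutant = mt$mut, ddg = mt$ddg, source = mt$source,
               stringsAsFactors = FALSE)
  })
  csv <- do.call(rbind, rows)
  csv_path <- file.path(out_dir, "designs.csv")
  if (is.null(csv)) {
    csv <- data.frame(design = character(0), mutation = character(0),
                      chain = character(0), position = integer(0),
                      wild_type = character(0), mutant = character(0),
                      ddg = numeric(0), source = character(0))
  }
  utils::write.csv(csv, csv_path, row.names = FALSE)

  json <- lapply(designs, function(d) {
    mt <- d$mutations[order(d$mutations$pos), , drop = FALSE]
    rownames(mt) <- NULL
    list(scenario = d$scenario, total_score = d$total_score,
         n_mutations = nrow(mt), mutations = mt, sequence = d$sequence)
  })
  names(json) <- vapply(designs, function(d) d$scenario, "")
  json_path <- file.path(out_dir, "designs.json")
  jsonlite::write_json(json, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(c(fasta = fasta_path, csv = csv_path, json = json_path))
}
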