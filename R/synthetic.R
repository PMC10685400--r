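# Synthetic generators with known ground truth: idealised helix structures,
# alignments with engineered conservation/consensus/coupling signal, and
# energy landscapes with planted pair effects. Everything is deterministic
# for a fixed seed and leaves the caller's RNG state untouched.

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Synthetic helical structure with B-factors
#'
#' An idealised alpha-helix backbone (rise 1.5 A, 100 degree twist, 2.3 A
#' helical radius) with N/CA/C/O atoms and a C-beta stub per non-glycine
#' residue. Per-residue B-factors are drawn from a seeded log-normal;
#' selected residues can be made conspicuously flexible. Optionally a
#' residue is enclosed in a shell of occluding pseudo-atoms (an extra
#' chain Z residue) to create a fully buried residue.
#'
#' @param n_residues number of residues (>= 2).
#' @param seed RNG seed.
#' @param sequence optional amino-acid sequence (string, length
#'   \code{n_residues}); sampled from the background distribution by
#'   default.
#' @param flexible integer indices of residues given a 4-fold elevated
#'   B-factor.
#' @param occlude optional residue index to enclose in a dummy-atom shell.
#' @param chain chain identifier (default "A").
#' @return a \code{structure_model}; author numbering is 1..n.
#' @export
synth_structure <- function(n_residues, seed = 1, sequence = NULL,
                            flexible = integer(0), occlude = NULL,
                            chain = "A") {
  stopifnot(n_residues >= 2)
  .with_seed(seed, {
    if (is.null(sequence)) {
      seq_chars <- sample(AA_ALPHABET, n_residues, replace = TRUE,
                          prob = BLOSUM62_BACKGROUND)
    } else {
      seq_chars <- strsplit(sequence, "")[[1]]
      stopifnot(length(seq_chars) == n_residues)
    }
    bres <- stats::rlnorm(n_residues, meanlog = log(20), sdlog = 0.3)
    bres[flexible] <- 4 * stats::median(bres)

    twist <- 100 * pi / 180
    rise <- 1.5
    r_helix <- 2.3
    rows <- list()
    for (i in seq_len(n_residues)) {
      th <- i * twist
      z <- i * rise
      ca <- c(r_helix * cos(th), r_helix * sin(th), z)
      nn <- c(r_helix * cos(th - 0.7), r_helix * sin(th - 0.7), z - 0.6)
      cc <- c(r_helix * cos(th + 0.7), r_helix * sin(th + 0.7), z + 0.6)
      oo <- cc + c(0, 0, 1.23)
      names_ <- c("N", "CA", "C", "O")
      el <- c("N", "C", "C", "O")
      xyz <- rbind(nn, ca, cc, oo)
      if (seq_chars[i] != "G") {
        cb <- c((r_helix + 1.5) * cos(th), (r_helix + 1.5) * sin(th), z)
        xyz <- rbind(xyz, cb)
        names_ <- c(names_, "CB")
        el <- c(el, "C")
      }
      rows[[i]] <- data.frame(
        chain = chain, resno = i, icode = "",
        resid = unname(AA_ONE_TO_THREE[seq_chars[i]]), aa = seq_chars[i],
        elety = names_, element = el,
        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
        o = 1, b = bres[i], stringsAsFactors = FALSE)
    }
    atoms <- do.call(rbind, rows)
    if (!is.null(occlude)) {
      centre <- colMeans(as.matrix(
        atoms[atoms$resno == occlude, c("x", "y", "z")]))
      pts <- .sphere_points(120) * 5.5
      shell <- data.frame(
        chain = "Z", resno = 999L, icode = "", resid = "ALA", aa = "A",
        elety = "CB", element = "C",
        x = pts[, 1] + centre[1], y = pts[, 2] + centre[2],
        z = pts[, 3] + centre[3],
        o = 1, b = 20, stringsAsFactors = FALSE)
      atoms <- rbind(atoms, shell)
    }
    structure_model(atoms)
  })
}

#' Synthetic alignment with engineered signal
#'
#' Generates a gapless alignment of the query plus \code{depth - 1}
#' background rows. Directives plant known signal: \code{conserved}
#' columns are invariant (query residue everywhere);
#' \code{consensus_injections} place a stated non-wild-type residue at a
#' stated frequency; \code{coupled_pairs} impose a bijective residue
#' mapping between two columns. A column may carry at most one directive.
#'
#' @param query query sequence (string); becomes the first row
#'   (\code{"query"}).
#' @param depth total number of sequences including the query (>= 2).
#' @param conserved integer positions made invariant.
#' @param consensus_injections data frame with columns \code{pos},
#'   \code{aa}, \code{freq}: residue \code{aa} is planted in
#'   \code{round(freq * depth)} rows at \code{pos}.
#' @param coupled_pairs list of length-2 integer vectors: column pairs
#'   given a bijective co-variation pattern.
#' @param identity expected per-position identity of the background rows to
#'   the query (default 0.55, the middle of the 30--90\% homolog identity
#'   window): at undirected columns each row carries the query residue with
#'   this probability and a background draw otherwise.
#' @param seed RNG seed.
#' @return an \code{msa} with query id \code{"query"}.
#' @export
synth_msa <- function(query, depth, conserved = integer(0),
                      consensus_injections = NULL,
                      coupled_pairs = list(), identity = 0.55, seed = 1) {
  stopifnot(depth >= 2)
  n <- nchar(query)
  qchars <- strsplit(query, "")[[1]]
  directive_cols <- c(conserved,
                      if (!is.null(consensus_injections))
                        consensus_injections$pos,
                      unlist(coupled_pairs))
  if (anyDuplicated(directive_cols))
    stop("overlapping directives on column(s): ",
         paste(unique(directive_cols[duplicated(directive_cols)]),
               collapse = ", "))
  .with_seed(seed, {
    mat <- matrix("", nrow = depth, ncol = n)
    mat[1, ] <- qchars
    for (j in seq_len(n)) {
      draw <- sample(AA_ALPHABET, depth - 1, replace = TRUE,
                     prob = BLOSUM62_BACKGROUND)
      keep <- stats::runif(depth - 1) < identity
      mat[2:depth, j] <- ifelse(keep, qchars[j], draw)
    }
    for (j in conserved) mat[, j] <- qchars[j]
    if (!is.null(consensus_injections)) {
      for (k in seq_len(nrow(consensus_injections))) {
        pos <- consensus_injections$pos[k]
        aa <- consensus_injections$aa[k]
        n_inj <- round(consensus_injections$freq[k] * depth)
        rows <- sample(2:depth, min(n_inj, depth - 1))
        # keep the column's remaining rows free of the injected residue so
        # the planted frequency is exact
        other <- setdiff(2:depth, rows)
        bad <- other[mat[other, pos] == aa]
        if (length(bad))
          mat[bad, pos] <- sample(setdiff(AA_ALPHABET, aa), length(bad),
                                  replace = TRUE)
        mat[rows, pos] <- aa
      }
    }
    for (cp in coupled_pairs) {
      stopifnot(length(cp) == 2)
      alpha_i <- sample(AA_ALPHABET, 4)
      alpha_j <- sample(setdiff(AA_ALPHABET, alpha_i), 4)
      pick <- sample(4, depth - 1, replace = TRUE)
      mat[2:depth, cp[1]] <- alpha_i[pick]
      mat[2:depth, cp[2]] <- alpha_j[pick]
    }
    seqs <- apply(mat, 1, paste, collapse = "")
    names(seqs) <- c("query", paste0("hom", seq_len(depth - 1)))
    msa(seqs, "query")
  })
}

#' Synthetic energy landscape with planted pair effects
#'
#' Builds a deterministic evaluator from explicit single values; pairs
#' default to exact additivity and can be overridden (e.g. to plant an
#' antagonistic pair).
#'
#' @param singles named numeric vector: mutation string -> ddG (kcal/mol).
#' @param pair_overrides optional named numeric vector keyed
#'   \code{"<mut_a>+<mut_b>"} (mutations sorted by position).
#' @return an \code{energy_evaluator}.
#' @export
synth_landscape <- function(singles, pair_overrides = NULL) {
  parsed <- lapply(names(singles), parse_mutation)
  pos <- vapply(parsed, function(m) m$pos, 0L)
  names(pos) <- names(singles)
  if (!is.null(pair_overrides)) {
    for (key in names(pair_overrides)) {
      muts <- strsplit(key, "+", fixed = TRUE)[[1]]
      if (length(muts) != 2 || !all(muts %in% names(singles)))
        stop("pair override references unknown mutation: ", key)
      if (pos[[muts[1]]] == pos[[muts[2]]])
        stop("pair override at a single position: ", key)
    }
  }
  energy_evaluator(
    single = function(mutation) {
      i <- match(mutation, names(singles))
      if (is.na(i)) stop("mutation not in landscape: ", mutation)
      singles[[i]]
    },
    pair = function(mut_a, mut_b) {
      key <- paste(mut_a, mut_b, sep = "+")
      if (!is.null(pair_overrides) && key %in% names(pair_overrides))
        return(pair_overrides[[key]])
      singles[[mut_a]] + singles[[mut_b]]
    },
    label = "synthetic landscape"
  )
}
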